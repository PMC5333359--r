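#' Additive linear-model association fit for one SNP-trait pair
#'
#' Ordinary least squares of the trait on `[intercept | dosage |
#' covariates]`, with a two-sided t-test on the dosage coefficient
#' (t distribution with `n - k - 1` residual degrees of freedom, not a
#' normal approximation). Samples with any missing value are dropped
#' listwise and the analysis n is recorded.
#'
#' @param dosage numeric vector of additive allele dosages.
#' @param trait numeric trait vector (already on the analysis scale).
#' @param covariates optional numeric matrix of covariates.
#' @param variant_id,trait_id,effect_allele,other_allele,scale labels
#'   carried into the result.
#' @return One-row data.frame: `variant_id`, `trait_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `stat`, `p`, `n`, `scale`. A dosage
#'   with fewer than two distinct values yields a flagged result with
#'   missing `beta`/`se`/`stat`/`p`.
#' @export
fit_additive_model <- function(dosage, trait, covariates = NULL,
                               variant_id = NA_character_,
                               trait_id = NA_character_,
                               effect_allele = NA_character_,
                               other_allele = NA_character_,
                               scale = NA_character_) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  ok <- !is.na(dosage) & !is.na(trait)
  if (!is.null(covariates)) ok <- ok & !apply(is.na(covariates), 1, any)
  d <- dosage[ok]; y <- trait[ok]
  n <- length(d)
  flagged <- data.frame(variant_id = variant_id, trait_id = trait_id,
                        effect_allele = effect_allele,
                        other_allele = other_allele,
                        beta = NA_real_, se = NA_real_, stat = NA_real_,
                        p = NA_real_, n = n, scale = scale,
                        stringsAsFactors = FALSE)
  if (length(unique(d)) < 2L) return(flagged)
  if (stats::var(y) == 0) {            # constant outcome: no association
    flagged$beta <- 0; flagged$p <- 1
    return(flagged)
  }
  X <- cbind(`(Intercept)` = 1, dosage = d,
             if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- n - ncol(X)
  if (df < 1) stop("not enough samples for the requested model")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- fit$coefficients[["dosage"]]
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df)
  out <- flagged
  out$beta <- beta; out$se <- se; out$stat <- stat
  out$p <- max(p, .Machine$double.xmin)   # keep P in (0, 1]
  out
}

#' Genome-wide additive association scan
#'
#' Fits the additive model of [fit_additive_model()] for every variant x
#' trait pair, retaining results at or below a screening threshold.
#' When the aligned data are complete (no missing values) the scan uses a
#' residualization shortcut: trait and dosage are both residualized on the
#' covariates once, and per-pair statistics are obtained from the
#' cross-products, which reproduces the full OLS fit exactly
#' (Frisch-Waugh) with the correct residual degrees of freedom. With
#' missing data, each pair is fitted individually with listwise deletion.
#'
#' @param genotypes a [genotype_matrix()].
#' @param traits a [trait_matrix()]; transformed to `scale` internally if
#'   still raw.
#' @param covariates optional covariate matrix (rownames = sample ids).
#' @param scale analysis scale: `"inverse-normal"` (default), `"log"` or
#'   `"raw"`.
#' @param screen_p retain associations with `p <= screen_p`
#'   (default `1e-5`); use `1` to keep everything.
#' @param chunk_size variants per block in the fast path (memory bound).
#' @return data.frame of retained associations ordered by (variant,
#'   trait): `variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `trait_id`, `n`, `beta`, `se`, `stat`, `p`, `scale`.
#' @export
scan_all <- function(genotypes, traits, covariates = NULL,
                     scale = c("inverse-normal", "log", "raw"),
                     screen_p = 1e-5, chunk_size = 1000L) {
  scale <- match.arg(scale)
  al <- align_samples(genotypes, traits, covariates)
  genotypes <- al$geno; traits <- al$traits; covariates <- al$covariates
  if (traits$scale == "raw" && scale != "raw")
    traits <- transform_traits(traits, scale)
  else if (traits$scale != scale)
    stop("traits already on scale '", traits$scale,
         "', cannot move to '", scale, "'")
  G <- genotypes$dosage
  Y <- traits$values
  v <- genotypes$variants
  n <- nrow(G)
  complete <- !anyNA(G) && !anyNA(Y) &&
    (is.null(covariates) || !anyNA(covariates))
  res <- if (complete) {
    scan_complete(G, Y, covariates, v, screen_p, chunk_size)
  } else {
    scan_pairwise(G, Y, covariates, v, screen_p)
  }
  if (nrow(res)) {
    res$scale <- scale
    res <- res[order(match(res$variant_id, v$variant_id),
                     match(res$trait_id, colnames(Y))), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

# fast path: all-complete data, covariates residualized once
scan_complete <- function(G, Y, covariates, v, screen_p, chunk_size) {
  n <- nrow(G)
  X0 <- cbind(rep(1, n), covariates)
  q0 <- qr(X0)
  if (q0$rank < ncol(X0)) stop("covariate matrix is rank deficient")
  Yr <- qr.resid(q0, Y)
  ss_y <- colSums(Yr^2)
  df <- n - 2L - ncol(X0) + 1L            # n - (intercept + dosage + covs)
  out <- vector("list", ceiling(ncol(G) / chunk_size))
  ci <- 0L
  for (start in seq(1L, ncol(G), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, ncol(G))
    Gr <- qr.resid(q0, G[, idx, drop = FALSE])
    ss_g <- colSums(Gr^2)
    mono <- ss_g <= n * 1e-12
    cross <- crossprod(Gr, Yr)            # variants x traits
    beta <- cross / ss_g
    r2 <- cross^2 / outer(ss_g, ss_y)
    r2 <- pmin(r2, 1 - 1e-15)
    se <- sqrt(sweep(1 - r2, 2, ss_y, `*`) / (df * ss_g))
    stat <- beta / se
    p <- 2 * stats::pt(-abs(stat), df)
    p[p < .Machine$double.xmin] <- .Machine$double.xmin
    if (any(mono)) p[mono, ] <- NA
    keep <- which(!is.na(p) & p <= screen_p, arr.ind = TRUE)
    ci <- ci + 1L
    out[[ci]] <- if (nrow(keep)) {
      vi <- idx[keep[, 1]]
      data.frame(variant_id = v$variant_id[vi], chrom = v$chrom[vi],
                 pos = v$pos[vi], effect_allele = v$alt[vi],
                 other_allele = v$ref[vi],
                 trait_id = colnames(Y)[keep[, 2]], n = n,
                 beta = beta[keep], se = se[keep], stat = stat[keep],
                 p = p[keep], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), effect_allele = character(),
                      other_allele = character(), trait_id = character(),
                      n = integer(), beta = numeric(), se = numeric(),
                      stat = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  out
}

# slow path: per-pair fits with listwise deletion
scan_pairwise <- function(G, Y, covariates, v, screen_p) {
  rows <- list()
  for (j in seq_len(ncol(G))) {
    for (t in seq_len(ncol(Y))) {
      r <- fit_additive_model(G[, j], Y[, t], covariates,
                              variant_id = v$variant_id[j],
                              trait_id = colnames(Y)[t],
                              effect_allele = v$alt[j],
                              other_allele = v$ref[j])
      if (!is.na(r$p) && r$p <= screen_p) {
        r$chrom <- v$chrom[j]; r$pos <- v$pos[j]
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (!length(rows))
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), effect_allele = character(),
                      other_allele = character(), trait_id = character(),
                      n = integer(), beta = numeric(), se = numeric(),
                      stat = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
          "trait_id", "n", "beta", "se", "stat", "p")]
}

#' Bonferroni significance threshold
#'
#' Divides the nominal significance level by the product of the supplied
#' test counts, e.g. `bonferroni_threshold(0.05, 509946, 1124)` for a
#' genome- and proteome-wide scan of 509,946 variants against 1,124
#' traits.
#'
#' @param alpha nominal level in `(0, 1)`.
#' @param ... one or more positive test counts.
#' @return `alpha / prod(counts)`.
#' @export
bonferroni_threshold <- function(alpha, ...) {
  counts <- c(...)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!length(counts) || any(counts < 1)) stop("test counts must be >= 1")
  alpha / prod(counts)
}

#' Genomic inflation factor (lambda_GC)
#'
#' Per-trait lambda is the median of the 1-df chi-square quantiles of the
#' P values divided by the null median 0.4549364; lambda near 1 indicates
#' a calibrated scan.
#'
#' @param p numeric vector of P values (one trait), or a list / matrix of
#'   per-trait P value sets.
#' @return For a vector: a single lambda. Otherwise a list with `lambda`
#'   (per trait), `mean` and `max`.
#' @export
genomic_inflation <- function(p) {
  one <- function(pv) {
    pv <- pv[!is.na(pv)]
    if (any(pv <= 0 | pv > 1)) stop("P values must lie in (0, 1]")
    if (length(pv) < 100)
      warning("fewer than 100 P values; lambda estimate is unstable")
    stats::median(stats::qchisq(pv, df = 1, lower.tail = FALSE)) /
      stats::qchisq(0.5, df = 1)
  }
  if (is.numeric(p) && !is.matrix(p)) return(one(p))
  if (is.matrix(p)) p <- lapply(seq_len(ncol(p)), function(j) p[, j])
  lam <- vapply(p, one, numeric(1))
  list(lambda = lam, mean = mean(lam), max = max(lam))
}

#' p-gain of a trait ratio
#'
#' Fits the genotype association of two traits and of their ratio (formed
#' on the raw scale, then moved to the analysis scale) and reports
#' `pgain = min(p_a, p_b) / p_ratio`: the factor by which the ratio
#' strengthens the strongest single-trait association. A p-gain above the
#' multiple-testing threshold (default `1e4`) marks the ratio association
#' as significant.
#'
#' @param dosage additive dosage vector.
#' @param trait_a,trait_b strictly positive raw-scale trait vectors.
#' @param covariates optional covariate matrix.
#' @param scale analysis scale applied to each trait and to the ratio.
#' @param pgain_threshold significance threshold for the p-gain.
#' @param trait_a_id,trait_b_id,variant_id labels for the result.
#' @return One-row data.frame: `trait_a`, `trait_b`, `variant_id`, `p_a`,
#'   `p_b`, `p_ratio`, `pgain`, `significant`.
#' @export
compute_pgain <- function(dosage, trait_a, trait_b, covariates = NULL,
                          scale = c("inverse-normal", "log", "raw"),
                          pgain_threshold = 1e4,
                          trait_a_id = "trait_a", trait_b_id = "trait_b",
                          variant_id = NA_character_) {
  scale <- match.arg(scale)
  bad <- which(trait_a <= 0 | trait_b <= 0)
  if (length(bad))
    stop("ratio undefined: non-positive raw values in sample(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  ratio <- trait_a / trait_b
  tf <- switch(scale,
               "raw" = identity,
               "log" = log,
               "inverse-normal" = inverse_normal_transform)
  p_of <- function(y) {
    if (length(unique(y[!is.na(y)])) == 1L) return(1)  # constant trait
    fit_additive_model(dosage, tf(y), covariates)$p
  }
  p_a <- p_of(trait_a); p_b <- p_of(trait_b); p_r <- p_of(ratio)
  pgain <- min(p_a, p_b) / p_r
  data.frame(trait_a = trait_a_id, trait_b = trait_b_id,
             variant_id = variant_id, p_a = p_a, p_b = p_b,
             p_ratio = p_r, pgain = pgain,
             significant = pgain > pgain_threshold,
             stringsAsFactors = FALSE)
}
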
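#' Linkage disequilibrium as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of the two variants'
#' additive dosages over their overlapping non-missing samples.
#'
#' @param dosage_a,dosage_b numeric dosage vectors (same samples).
#' @param min_overlap minimum number of complete pairs (default 10).
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_a, dosage_b, min_overlap = 10L) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < min_overlap)
    stop("fewer than ", min_overlap, " overlapping non-missing samples")
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero dosage variance; r2 undefined")
  stats::cor(a, b)^2
}

# r2 of one variant against a set of columns (vectorized, complete data)
ld_r2_vec <- function(dos, j, idx) {
  suppressWarnings(stats::cor(dos[, j], dos[, idx, drop = FALSE]))[1, ]^2
}

#' Per-trait lumping of correlated association signals
#'
#' Greedy clumping for one trait: the lowest-P unassigned variant becomes
#' a sentinel and absorbs every unassigned associated variant within the
#' window whose LD with it exceeds `r2_min`; the procedure repeats until
#' all associated variants are assigned. Ties on P are broken by
#' (chromosome, position), so the result is deterministic.
#'
#' @param results data.frame of associations for a single trait (columns
#'   `variant_id`, `chrom`, `pos`, `p`, plus any others carried through).
#' @param genotypes the [genotype_matrix()] the associations came from.
#' @param r2_min absorb members with sentinel LD r2 above this
#'   (default 0.1).
#' @param window_bp absorb members within this distance of the sentinel
#'   (default 10 Mb); variants on different chromosomes are never lumped.
#' @return The sentinel rows of `results`, each with a `members`
#'   list-column of absorbed variant ids (sentinel included).
#' @export
lump_per_trait <- function(results, genotypes, r2_min = 0.1,
                           window_bp = 1e7) {
  if (!nrow(results)) {
    results$members <- list()
    return(results)
  }
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (length(unique(results$trait_id)) > 1L)
    stop("lump_per_trait expects associations for a single trait")
  ord <- order(results$p, results$chrom, results$pos)
  results <- results[ord, , drop = FALSE]
  dos <- genotypes$dosage
  vidx <- match(results$variant_id, colnames(dos))
  if (anyNA(vidx)) stop("results reference variants absent from genotypes")
  unassigned <- rep(TRUE, nrow(results))
  keep <- integer(0)
  members <- list()
  while (any(unassigned)) {
    s <- which(unassigned)[1]          # lowest P among unassigned
    cand <- which(unassigned &
                    results$chrom == results$chrom[s] &
                    abs(results$pos - results$pos[s]) <= window_bp)
    cand <- setdiff(cand, s)
    absorbed <- if (length(cand)) {
      r2 <- ld_r2_vec(dos, vidx[s], vidx[cand])
      cand[!is.na(r2) & r2 > r2_min]
    } else integer(0)
    unassigned[c(s, absorbed)] <- FALSE
    keep <- c(keep, s)
    members[[length(members) + 1L]] <-
      results$variant_id[c(s, absorbed)]
  }
  out <- results[keep, , drop = FALSE]
  out$members <- members
  rownames(out) <- NULL
  out
}

#' Merge per-trait sentinels into ranked association loci
#'
#' Sentinel variants from all traits are merged transitively: two
#' sentinels join the same locus when their LD r2 exceeds `r2_merge` and
#' they lie within the window on the same chromosome, and loci are the
#' connected components of that graph. Each locus is represented by its
#' smallest-P member, loci are ranked 1..L by sentinel P (1 = strongest),
#' and each trait association at a locus is tiered: `primary` when its P
#' beats the genome- and trait-wide Bonferroni threshold
#' `alpha / n_snps_tested / n_traits_tested`, `secondary` when it beats
#' the locus-count threshold `alpha / n_primary_loci / n_traits_tested`
#' recomputed from the realized number of primary loci, `none` otherwise.
#'
#' @param sentinels data.frame of per-trait sentinel associations (from
#'   [lump_per_trait()] over all traits, rbind-ed), columns `variant_id`,
#'   `chrom`, `pos`, `trait_id`, `p` (and optionally `members`).
#' @param genotypes the [genotype_matrix()].
#' @param r2_merge sentinel-merging LD threshold (default 0.9).
#' @param window_bp merging window (default 10 Mb).
#' @param alpha nominal level (default 0.05).
#' @param n_snps_tested,n_traits_tested Bonferroni denominators for the
#'   primary tier; default to the panel size and the number of distinct
#'   traits in `sentinels`.
#' @return An object of class `pqtl_loci`: list with `loci` (data.frame:
#'   `locus_id`, `sentinel_variant`, `chrom`, `pos`, `n_members`,
#'   `trait_id`, `p`, `tier`, plus beta/se when present), `thresholds`,
#'   and `n_primary_loci`.
#' @export
define_loci <- function(sentinels, genotypes, r2_merge = 0.9,
                        window_bp = 1e7, alpha = 0.05,
                        n_snps_tested = NULL, n_traits_tested = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(n_snps_tested)) n_snps_tested <- ncol(genotypes$dosage)
  if (is.null(n_traits_tested))
    n_traits_tested <- length(unique(sentinels$trait_id))
  thr1 <- bonferroni_threshold(alpha, n_snps_tested, n_traits_tested)
  if (!nrow(sentinels)) {
    return(structure(list(
      loci = data.frame(locus_id = integer(), sentinel_variant = character(),
                        chrom = character(), pos = integer(),
                        n_members = integer(), trait_id = character(),
                        p = numeric(), tier = character(),
                        stringsAsFactors = FALSE),
      thresholds = c(primary = thr1, secondary = NA),
      n_primary_loci = 0L), class = "pqtl_loci"))
  }
  vs <- unique(sentinels[, c("variant_id", "chrom", "pos")])
  vs <- vs[order(vs$chrom, vs$pos), , drop = FALSE]
  dos <- genotypes$dosage
  # edges between co-window, high-LD sentinel variants
  ee <- list()
  for (i in seq_len(nrow(vs))) {
    j <- which(vs$chrom == vs$chrom[i] &
                 abs(vs$pos - vs$pos[i]) <= window_bp &
                 seq_len(nrow(vs)) > i)
    if (!length(j)) next
    r2 <- ld_r2_vec(dos, match(vs$variant_id[i], colnames(dos)),
                    match(vs$variant_id[j], colnames(dos)))
    hit <- j[!is.na(r2) & r2 > r2_merge]
    if (length(hit))
      ee[[length(ee) + 1L]] <- cbind(i, hit)
  }
  g <- igraph::make_empty_graph(n = nrow(vs), directed = FALSE)
  if (length(ee))
    g <- igraph::add_edges(g, t(do.call(rbind, ee)))
  comp <- igraph::components(g)$membership
  vs$component <- comp
  sentinels$component <- vs$component[match(sentinels$variant_id,
                                            vs$variant_id)]
  # sentinel of each locus: smallest P (ties: chrom, pos)
  ordp <- order(sentinels$p, sentinels$chrom, sentinels$pos)
  sent_row <- ordp[!duplicated(sentinels$component[ordp])]
  locus_info <- sentinels[sent_row, c("component", "variant_id", "chrom",
                                      "pos", "p")]
  locus_info <- locus_info[order(locus_info$p, locus_info$chrom,
                                 locus_info$pos), , drop = FALSE]
  locus_info$locus_id <- seq_len(nrow(locus_info))
  sentinels$locus_id <-
    locus_info$locus_id[match(sentinels$component, locus_info$component)]
  sentinels$sentinel_variant <-
    locus_info$variant_id[match(sentinels$component, locus_info$component)]
  n_members <- if (!is.null(sentinels$members))
    tapply(sentinels$members, sentinels$locus_id,
           function(m) length(unique(unlist(m))))
  else tapply(sentinels$variant_id, sentinels$locus_id,
              function(v) NA_integer_)
  # tiering
  primary <- sentinels$p < thr1
  min_locus_p <- tapply(sentinels$p, sentinels$locus_id, min)
  n_primary_loci <- sum(min_locus_p < thr1)
  thr2 <- if (n_primary_loci > 0)
    bonferroni_threshold(alpha, n_primary_loci, n_traits_tested) else NA
  tier <- ifelse(primary, "primary",
                 ifelse(!is.na(thr2) & sentinels$p < thr2,
                        "secondary", "none"))
  # secondary tier applies only at loci that have a primary association
  locus_has_primary <- tapply(primary, sentinels$locus_id, any)
  tier[tier == "secondary" &
         !locus_has_primary[as.character(sentinels$locus_id)]] <- "none"
  loci <- data.frame(
    locus_id = sentinels$locus_id,
    sentinel_variant = sentinels$sentinel_variant,
    chrom = locus_info$chrom[match(sentinels$locus_id,
                                   locus_info$locus_id)],
    pos = locus_info$pos[match(sentinels$locus_id, locus_info$locus_id)],
    n_members = as.integer(n_members[as.character(sentinels$locus_id)]),
    trait_id = sentinels$trait_id,
    variant_id = sentinels$variant_id,
    p = sentinels$p, tier = tier,
    stringsAsFactors = FALSE)
  if ("beta" %in% names(sentinels)) loci$beta <- sentinels$beta
  if ("se" %in% names(sentinels)) loci$se <- sentinels$se
  loci <- loci[order(loci$locus_id, loci$p), , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci,
                 thresholds = c(primary = thr1, secondary = thr2),
                 n_primary_loci = n_primary_loci),
            class = "pqtl_loci")
}

#' @export
print.pqtl_loci <- function(x, ...) {
  cat("pqtl_loci:", length(unique(x$loci$locus_id)), "loci,",
      x$n_primary_loci, "with a primary-tier association\n")
  cat("  thresholds: primary", format(x$thresholds[["primary"]], digits = 3),
      "secondary", format(x$thresholds[["secondary"]], digits = 3), "\n")
  invisible(x)
}

#' Classify an association as cis or trans
#'
#' An association is cis when the variant lies on the same chromosome as
#' the trait's encoding gene and its distance to the gene interval is
#' below `max_dist` (default 10 Mb, "closer than 10 Mb from the gene
#' boundaries"); variants inside the gene have distance 0. Any
#' cross-chromosome association is trans. Traits without gene coordinates
#' are classified `unknown`.
#'
#' @param variant_chrom,variant_pos variant location.
#' @param gene_chrom,gene_start,gene_end 1-based inclusive gene interval.
#' @param max_dist cis distance bound in bp (exclusive).
#' @return `"cis"`, `"trans"` or `"unknown"` (vectorized).
#' @export
classify_cis_trans <- function(variant_chrom, variant_pos, gene_chrom,
                               gene_start, gene_end, max_dist = 1e7) {
  bad <- !is.na(gene_start) & !is.na(gene_end) & gene_start > gene_end
  if (any(bad)) stop("malformed gene interval (start > end)")
  n <- max(length(variant_chrom), length(gene_chrom))
  variant_chrom <- rep_len(as.character(variant_chrom), n)
  variant_pos <- rep_len(variant_pos, n)
  gene_chrom <- rep_len(as.character(gene_chrom), n)
  gene_start <- rep_len(gene_start, n)
  gene_end <- rep_len(gene_end, n)
  dist <- pmax(gene_start - variant_pos, variant_pos - gene_end, 0)
  out <- ifelse(is.na(gene_chrom) | is.na(gene_start) | is.na(gene_end),
                "unknown",
                ifelse(variant_chrom == gene_chrom & dist < max_dist,
                       "cis", "trans"))
  out
}

#' Conditional multi-variant fit and joint variance decomposition
#'
#' A single multiple regression of the trait on `[intercept | all dosages
#' | covariates]`. Each variant's conditional P value is the t-test of its
#' coefficient given all others; the jointly explained variance is
#' `R2(full) - R2(covariates only)`, i.e. the share of trait variance
#' attributable to the genotype terms beyond the covariates.
#'
#' @param trait numeric trait vector (analysis scale).
#' @param dosages matrix of additive dosages, one column per variant.
#' @param covariates optional covariate matrix.
#' @param collinearity_r2 guard: error when any variant pair has dosage
#'   r2 above this (default 0.95).
#' @return List of class `conditional_fit`: `fit` (data.frame variant,
#'   beta, se, stat, conditional_p), `joint_r2`, `n`.
#' @export
conditional_joint_fit <- function(trait, dosages, covariates = NULL,
                                  collinearity_r2 = 0.95) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  ok <- !is.na(trait) & !apply(is.na(dosages), 1, any)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & !apply(is.na(covariates), 1, any)
  }
  y <- trait[ok]; D <- dosages[ok, , drop = FALSE]
  cv <- if (!is.null(covariates)) covariates[ok, , drop = FALSE]
  if (ncol(D) > 1) {
    r2m <- stats::cor(D)^2
    diag(r2m) <- 0
    w <- which(r2m > collinearity_r2, arr.ind = TRUE)
    if (nrow(w))
      stop("collinear variant pair exceeds guard: ",
           colnames(D)[w[1, 1]], " / ", colnames(D)[w[1, 2]],
           " (r2 = ", signif(r2m[w[1, , drop = FALSE]], 3), ")")
  }
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, D, cv)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix rank deficient; collinear column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
               collapse = ", "))
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  jd <- 1 + seq_len(ncol(D))
  se <- sqrt(sigma2 * diag(xtx_inv)[jd])
  beta <- fit$coefficients[jd]
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df)
  tss <- sum((y - mean(y))^2)
  r2_full <- 1 - sum(fit$residuals^2) / tss
  r2_cov <- if (is.null(cv)) 0 else {
    f0 <- stats::lm.fit(cbind(1, cv), y)
    1 - sum(f0$residuals^2) / tss
  }
  structure(list(
    fit = data.frame(variant = colnames(D), beta = beta, se = se,
                     stat = stat, conditional_p = p,
                     stringsAsFactors = FALSE, row.names = NULL),
    joint_r2 = r2_full - r2_cov, n = n), class = "conditional_fit")
}

#' @export
print.conditional_fit <- function(x, ...) {
  cat("conditional_fit: joint genotype R2 =", signif(x$joint_r2, 3),
      "on n =", x$n, "\n")
  print(x$fit, row.names = FALSE)
  invisible(x)
}
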
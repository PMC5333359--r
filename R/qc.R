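#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided test from the genotype counts of a biallelic variant:
#' with the allele counts fixed, the probabilities of all possible
#' heterozygote counts are evaluated and those no more probable than the
#' observed configuration are summed (the plain exact test, not mid-p,
#' matching PLINK's `--hwe` default). Probabilities follow the
#' Levene-Haldane distribution and are computed by a stable recurrence
#' from the modal heterozygote count.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative; total
#'   must be positive).
#' @return Exact two-sided P value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("genotype counts must be non-negative")
  if (sum(cnt) == 0) stop("total genotype count must be positive")
  n <- sum(cnt)
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het   # minor allele count
  if (rare == 0) return(1)                        # monomorphic
  hets <- seq(rare %% 2, rare, by = 2)            # feasible het counts
  probs <- numeric(length(hets))
  # start at the mode and recurse outwards (ratios of adjacent probs)
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  if (mid > rare) mid <- mid - 2
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid > 1) for (i in (i_mid - 1):1) {
    h <- hets[i] + 2                               # step h -> h - 2
    probs[i] <- probs[i + 1] * h * (h - 1) /
      ((rare - h + 2) * (2 * n - rare - h + 2))
  }
  if (i_mid < length(hets)) for (i in (i_mid + 1):length(hets)) {
    h <- hets[i] - 2                               # step h -> h + 2
    probs[i] <- probs[i - 1] *
      (rare - h) * (2 * n - rare - h) / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count is infeasible for ",
                         "the given allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Variant quality-control report
#'
#' Per-stage removal counts of the sequential variant filter chain
#' (duplicates, then call rate, then minor allele frequency, then
#' Hardy-Weinberg), with self-consistency checking of the arithmetic:
#' the variants remaining after each stage must equal the preceding count
#' minus that stage's removals.
#'
#' @param n_input variants entering the chain.
#' @param n_removed_duplicates,n_removed_callrate,n_removed_maf,n_removed_hwe
#'   removals per stage, in filter order.
#' @param thresholds named numeric vector
#'   `(max_missing_fraction, min_maf, min_hwe_p)`.
#' @return An object of class `qc_report` with a per-stage table
#'   (`$stages`: stage, removed, remaining) and `$n_remaining`.
#' @export
qc_report <- function(n_input, n_removed_duplicates = 0,
                      n_removed_callrate = 0, n_removed_maf = 0,
                      n_removed_hwe = 0,
                      thresholds = c(max_missing_fraction = NA,
                                     min_maf = NA, min_hwe_p = NA)) {
  counts <- c(n_input, n_removed_duplicates, n_removed_callrate,
              n_removed_maf, n_removed_hwe)
  if (any(counts < 0)) stop("qc_report counts must be >= 0")
  removed <- c(n_removed_duplicates, n_removed_callrate, n_removed_maf,
               n_removed_hwe)
  remaining <- n_input - cumsum(removed)
  if (any(remaining < 0)) stop("removals exceed input variant count")
  structure(list(
    n_input = n_input,
    n_removed_duplicates = n_removed_duplicates,
    n_removed_callrate = n_removed_callrate,
    n_removed_maf = n_removed_maf,
    n_removed_hwe = n_removed_hwe,
    n_remaining = remaining[length(remaining)],
    stages = data.frame(
      stage = c("duplicates", "callrate", "maf", "hwe"),
      removed = removed, remaining = remaining,
      stringsAsFactors = FALSE),
    thresholds = thresholds), class = "qc_report")
}

#' Check the internal arithmetic of a QC report
#'
#' @param report a [qc_report()].
#' @return `TRUE` invisibly if every stage's remaining count equals the
#'   previous count minus its removals and the total matches; otherwise an
#'   error naming the inconsistent stage.
#' @export
validate_qc_report <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  prev <- report$n_input
  for (i in seq_len(nrow(report$stages))) {
    expect <- prev - report$stages$removed[i]
    if (report$stages$remaining[i] != expect)
      stop("qc_report inconsistent at stage '", report$stages$stage[i],
           "': remaining ", report$stages$remaining[i], " != ", expect)
    prev <- report$stages$remaining[i]
  }
  if (report$n_remaining != prev)
    stop("qc_report n_remaining inconsistent with stage table")
  tot <- report$n_removed_duplicates + report$n_removed_callrate +
    report$n_removed_maf + report$n_removed_hwe
  if (report$n_remaining != report$n_input - tot)
    stop("qc_report n_remaining != n_input - total removals")
  invisible(TRUE)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Variant QC report:", x$n_input, "variants in,",
      x$n_remaining, "remaining\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Sequential variant filter chain
#'
#' Applies, in order: removal of duplicate variants (identical
#' chrom:pos:ref:alt, first occurrence kept), a per-variant missingness
#' filter, a minor-allele-frequency filter, and an exact
#' Hardy-Weinberg filter, recording removal counts per stage. Optionally
#' drops low-call-rate samples first. MAF and HWE are evaluated on the
#' matrix as it stands when the stage runs, so the chain is auditable
#' stage by stage.
#'
#' @param genotypes a [genotype_matrix()].
#' @param max_missing_fraction drop variants missing in more than this
#'   fraction of samples (PLINK `--geno`; default 0.02).
#' @param min_maf drop variants with minor allele frequency below this
#'   (default 0.05).
#' @param min_hwe_p drop variants whose exact HWE P value falls below this
#'   (default 1e-6).
#' @param min_sample_call_rate optional: drop samples with overall call
#'   rate below this before the variant chain runs.
#' @return A list: `genotypes` (filtered [genotype_matrix()]), `report`
#'   (a [qc_report()]), `n_samples_removed`.
#' @export
filter_variants <- function(genotypes, max_missing_fraction = 0.02,
                            min_maf = 0.05, min_hwe_p = 1e-6,
                            min_sample_call_rate = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (max_missing_fraction < 0 || max_missing_fraction > 1 ||
      min_maf < 0 || min_maf > 0.5 || min_hwe_p < 0 || min_hwe_p > 1)
    stop("filter thresholds outside valid ranges")
  n_samples_removed <- 0L
  if (!is.null(min_sample_call_rate)) {
    scr <- rowMeans(!is.na(genotypes$dosage))
    keep <- scr >= min_sample_call_rate
    n_samples_removed <- sum(!keep)
    if (n_samples_removed)
      genotypes <- subset_genotypes(genotypes, samples = which(keep))
  }
  v <- genotypes$variants
  n_input <- nrow(v)

  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  keep_dup <- !duplicated(key)
  n_dup <- sum(!keep_dup)
  genotypes <- subset_genotypes(genotypes, variants = which(keep_dup))

  cr <- genotypes$variants$call_rate
  keep_cr <- (1 - cr) <= max_missing_fraction
  n_cr <- sum(!keep_cr)
  genotypes <- subset_genotypes(genotypes, variants = which(keep_cr))

  keep_maf <- genotypes$variants$maf >= min_maf
  n_maf <- sum(!keep_maf)
  genotypes <- subset_genotypes(genotypes, variants = which(keep_maf))

  d <- round(genotypes$dosage)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  keep_hwe <- hwe_p >= min_hwe_p
  n_hwe <- sum(!keep_hwe)
  genotypes <- subset_genotypes(genotypes, variants = which(keep_hwe))

  if (ncol(genotypes$dosage) == 0L)
    warning("no variants remain after filtering")
  report <- qc_report(n_input, n_dup, n_cr, n_maf, n_hwe,
                      thresholds = c(max_missing_fraction = max_missing_fraction,
                                     min_maf = min_maf,
                                     min_hwe_p = min_hwe_p))
  validate_qc_report(report)
  list(genotypes = genotypes, report = report,
       n_samples_removed = n_samples_removed)
}

#' Rank-based inverse-normal transformation
#'
#' Maps a trait vector to standard normal quantiles via
#' `qnorm((rank - 0.5) / n)` with average ranks for ties; `n` counts the
#' non-missing values and missing values stay missing. The output depends
#' on the input only through its ranks, so any strictly monotone
#' transformation of the input yields identical output.
#'
#' @param values numeric vector (>= 3 non-missing, not all equal).
#' @param trait_id optional label used in error messages.
#' @return Transformed vector of the same length, missing preserved.
#' @export
inverse_normal_transform <- function(values, trait_id = "trait") {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("inverse_normal_transform: fewer than 3 non-missing ",
                  "values for ", trait_id)
  if (length(unique(values[ok])) == 1L)
    stop("inverse_normal_transform: constant values for ", trait_id)
  out <- values
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Transform a trait matrix to the requested analysis scale
#'
#' @param traits a [trait_matrix()] on the raw scale.
#' @param scale `"raw"` (no-op), `"log"` (natural log; requires strictly
#'   positive values) or `"inverse-normal"` (per-trait rank-based
#'   transform).
#' @return A [trait_matrix()] with the scale tag updated.
#' @export
transform_traits <- function(traits,
                             scale = c("inverse-normal", "log", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(traits, "trait_matrix"))
  v <- traits$values
  if (scale == "log") {
    if (any(v <= 0, na.rm = TRUE))
      stop("log scale requires strictly positive trait values")
    v <- log(v)
  } else if (scale == "inverse-normal") {
    v <- vapply(seq_len(ncol(v)), function(j)
      inverse_normal_transform(v[, j], colnames(v)[j]),
      numeric(nrow(v)))
    dimnames(v) <- dimnames(traits$values)
  }
  trait_matrix(v, traits$traits, scale = scale)
}

#' Principal component scores of a samples x features matrix
#'
#' Columns are centered internally; scores are ordered by decreasing
#' explained variance and are mutually orthogonal.
#'
#' @param x numeric matrix, samples in rows.
#' @param k number of components (must not exceed the matrix rank).
#' @return Samples x `k` score matrix (columns `PC1..PCk`).
#' @export
compute_pcs <- function(x, k) {
  x <- as.matrix(x)
  if (k > min(dim(x))) stop("k exceeds matrix dimensions")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = min(dim(xc)), nv = 0)
  rank <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  if (k > rank) stop("k (", k, ") exceeds matrix rank (", rank, ")")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  scores
}
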
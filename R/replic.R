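#' Select a tag SNP for a sentinel in the replication panel
#'
#' Among replication-panel variants whose discovery-panel LD with the
#' sentinel exceeds `r2_min`, the variant with the strongest discovery
#' association for the trait is returned (the sentinel itself is eligible
#' when present, at r2 = 1). When no variant qualifies, the association is
#' untestable and `NULL` is returned.
#'
#' @param sentinel_id sentinel variant id (must exist in the discovery
#'   panel).
#' @param trait_id trait whose discovery association ranks the candidates.
#' @param discovery_genotypes,replication_genotypes [genotype_matrix()]
#'   objects.
#' @param discovery_traits discovery [trait_matrix()] on the analysis
#'   scale (used to rank candidate tags by their association strength).
#' @param discovery_covariates optional covariates for the ranking fits.
#' @param r2_min LD threshold for a usable proxy (default 0.8).
#' @return List `(tag_variant, tag_r2, p_discovery_tag)` or `NULL`.
#' @export
select_tag_snp <- function(sentinel_id, trait_id, discovery_genotypes,
                           replication_genotypes, discovery_traits,
                           discovery_covariates = NULL, r2_min = 0.8) {
  ddos <- discovery_genotypes$dosage
  if (!sentinel_id %in% colnames(ddos))
    stop("sentinel ", sentinel_id, " absent from the discovery panel")
  cand <- intersect(colnames(replication_genotypes$dosage), colnames(ddos))
  if (!length(cand)) return(NULL)
  r2 <- vapply(cand, function(v)
    if (v == sentinel_id) 1
    else tryCatch(ld_r2(ddos[, sentinel_id], ddos[, v]),
                  error = function(e) NA_real_),
    numeric(1))
  cand <- cand[!is.na(r2) & r2 > r2_min]
  r2 <- r2[!is.na(r2) & r2 > r2_min]
  if (!length(cand)) return(NULL)
  y <- discovery_traits$values[, trait_id]
  p <- vapply(cand, function(v)
    fit_additive_model(ddos[, v], y, discovery_covariates)$p, numeric(1))
  best <- which.min(p)
  list(tag_variant = cand[best], tag_r2 = unname(r2[best]),
       p_discovery_tag = unname(p[best]))
}

# Harmonize effect alleles between panels. Returns multiplier for the
# replication beta (+1 match, -1 swapped) or NA when alleles cannot be
# reconciled; flags strand-ambiguous (A/T, C/G) pairs.
harmonize_alleles <- function(ea_disc, oa_disc, ea_repl, oa_repl) {
  ambiguous <- paste0(ea_repl, oa_repl) %in% c("AT", "TA", "CG", "GC")
  flip <- if (ea_disc == ea_repl && oa_disc == oa_repl) 1
          else if (ea_disc == oa_repl && oa_disc == ea_repl) -1
          else NA_real_
  list(flip = flip, ambiguous = ambiguous)
}

#' Attempt replication of one discovery association
#'
#' Fits the additive model for the tag variant in the replication cohort
#' (covariates typically include age, sex, BMI, diabetes state, and the
#' leading genotype and proteome principal components), harmonizes effect
#' alleles between the panels, and grades the outcome: `replicated` when
#' `p < alpha / n_attempted`, `nominal` when `p < alpha`, otherwise
#' `not_replicated`; associations without a usable tag or with
#' irreconcilable alleles are `untestable`.
#'
#' @param locus_id,sentinel_id,trait_id identifiers of the discovery
#'   association.
#' @param beta_discovery,p_discovery discovery effect and P value.
#' @param tag result of [select_tag_snp()] (or `NULL` for untestable).
#' @param replication_genotypes replication [genotype_matrix()].
#' @param replication_traits replication [trait_matrix()] (raw scale;
#'   transformed internally).
#' @param replication_covariates covariate matrix for the replication fit.
#' @param discovery_alleles named character vector
#'   `c(effect = ..., other = ...)` for the sentinel/tag in the discovery
#'   coding.
#' @param n_attempted Bonferroni denominator: realized number of testable
#'   associations.
#' @param alpha nominal level (default 0.05).
#' @param scale analysis scale for the replication fit.
#' @return One-row data.frame with the `ReplicationRecord` fields.
#' @export
replicate_association <- function(locus_id, sentinel_id, trait_id,
                                  beta_discovery, p_discovery, tag,
                                  replication_genotypes,
                                  replication_traits,
                                  replication_covariates,
                                  discovery_alleles,
                                  n_attempted, alpha = 0.05,
                                  scale = "inverse-normal") {
  rec <- data.frame(locus_id = locus_id, sentinel_variant = sentinel_id,
                    tag_variant = NA_character_, tag_r2 = NA_real_,
                    trait_id = trait_id, p_discovery = p_discovery,
                    p_replication = NA_real_,
                    beta_discovery = beta_discovery,
                    beta_replication = NA_real_,
                    direction_consistent = NA, ambiguous_strand = NA,
                    status = "untestable", reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.null(tag)) {
    rec$reason <- "no tag SNP with sufficient LD"
    return(rec)
  }
  rec$tag_variant <- tag$tag_variant
  rec$tag_r2 <- tag$tag_r2
  rv <- replication_genotypes$variants
  ri <- match(tag$tag_variant, rv$variant_id)
  if (is.na(ri)) {
    rec$reason <- "tag absent from replication panel"
    return(rec)
  }
  harm <- harmonize_alleles(discovery_alleles[["effect"]],
                            discovery_alleles[["other"]],
                            rv$alt[ri], rv$ref[ri])
  rec$ambiguous_strand <- harm$ambiguous
  if (is.na(harm$flip)) {
    rec$reason <- "allele mismatch cannot be harmonized"
    return(rec)
  }
  traits <- replication_traits
  if (traits$scale == "raw" && scale != "raw")
    traits <- transform_traits(traits, scale)
  if (!trait_id %in% colnames(traits$values)) {
    rec$reason <- "trait absent from replication panel"
    return(rec)
  }
  common <- intersect(rownames(replication_genotypes$dosage),
                      rownames(traits$values))
  common <- intersect(common, rownames(replication_covariates))
  fit <- fit_additive_model(
    replication_genotypes$dosage[common, tag$tag_variant],
    traits$values[common, trait_id],
    replication_covariates[common, , drop = FALSE])
  if (is.na(fit$p)) {
    rec$status <- "untestable"
    rec$reason <- "tag monomorphic in replication cohort"
    return(rec)
  }
  rec$p_replication <- fit$p
  rec$beta_replication <- fit$beta * harm$flip   # discovery allele coding
  rec$direction_consistent <-
    sign(rec$beta_replication) == sign(beta_discovery)
  rec$status <- if (fit$p < alpha / n_attempted) "replicated"
                else if (fit$p < alpha) "nominal" else "not_replicated"
  rec
}

#' Subsampling-based replication power (p95)
#'
#' Repeatedly draws subsamples of the replication sample size from the
#' discovery cohort without replacement, refits the association on each
#' subsample, and reports the `ceiling(0.05 * reps)`-th largest P value —
#' for 100 repetitions, the 5th largest, i.e. the P value achievable with
#' 95% power at the replication size. An association is well powered when
#' p95 falls below the replication Bonferroni threshold.
#'
#' @param dosage,trait,covariates discovery data for the association
#'   (trait already on the analysis scale).
#' @param m subsample size (replication cohort size; default 338).
#' @param reps number of subsamples (default 100, minimum 20).
#' @param seed integer seed; each repetition derives its own sub-seed.
#' @return List: `p95`, `p_values` (all repetitions), `m`, `reps`.
#' @export
estimate_p95 <- function(dosage, trait, covariates = NULL, m = 338L,
                         reps = 100L, seed = 1L) {
  n <- length(dosage)
  if (m > n) stop("subsample size m (", m, ") exceeds cohort size (", n, ")")
  if (reps < 20L) stop("reps must be >= 20")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  pv <- vapply(seq_len(reps), function(r) {
    set.seed(sub_seed(seed, paste0("p95-rep-", r)))
    idx <- sample.int(n, m)
    fit_additive_model(dosage[idx], trait[idx],
                       if (!is.null(covariates))
                         covariates[idx, , drop = FALSE])$p
  }, numeric(1))
  k <- ceiling(0.05 * reps)
  p95 <- sort(pv, decreasing = TRUE)[k]
  list(p95 = p95, p_values = pv, m = m, reps = reps)
}

#' Summarize a set of replication attempts
#'
#' Counts and percentages of replication outcomes overall and within the
#' well-powered stratum (p95 below the replication Bonferroni threshold,
#' when p95 values are present), plus directional-consistency counts among
#' replicated associations.
#'
#' @param records data.frame of [replicate_association()] rows, optionally
#'   with a `p95` column.
#' @param alpha nominal level (default 0.05).
#' @return List of class `replication_summary` with counts and
#'   percentages; zero denominators are reported as `NA` percentages.
#' @export
summarize_replication <- function(records, alpha = 0.05) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  testable <- records[records$status != "untestable", , drop = FALSE]
  n_att <- nrow(testable)
  n_rep <- sum(testable$status == "replicated")
  n_nom <- n_rep + sum(testable$status == "nominal")
  n_dir <- sum(testable$direction_consistent[
    testable$status == "replicated"], na.rm = TRUE)
  out <- list(
    n_records = nrow(records),
    n_untestable = nrow(records) - n_att,
    n_attempted = n_att,
    n_replicated = n_rep,
    n_nominal = n_nom,
    pct_replicated = pct(n_rep, n_att),
    pct_nominal = pct(n_nom, n_att),
    n_direction_consistent = n_dir,
    pct_direction_consistent = pct(n_dir, n_rep),
    bonferroni_threshold = if (n_att > 0) alpha / n_att else NA_real_)
  if ("p95" %in% names(records) && n_att > 0) {
    wp <- testable[!is.na(testable$p95) &
                     testable$p95 < alpha / n_att, , drop = FALSE]
    out$n_well_powered <- nrow(wp)
    out$n_well_powered_replicated <- sum(wp$status == "replicated")
    out$n_well_powered_nominal <- sum(wp$status %in%
                                        c("replicated", "nominal"))
    out$pct_well_powered_replicated <-
      pct(out$n_well_powered_replicated, out$n_well_powered)
    out$pct_well_powered_nominal <-
      pct(out$n_well_powered_nominal, out$n_well_powered)
  }
  structure(out, class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat("Replication summary:\n")
  cat("  attempted:", x$n_attempted,
      "(untestable:", x$n_untestable, ")\n")
  cat(sprintf("  replicated (Bonferroni): %d (%.1f%%)\n",
              x$n_replicated, x$pct_replicated))
  cat(sprintf("  at least nominal: %d (%.1f%%)\n",
              x$n_nominal, x$pct_nominal))
  if (!is.null(x$n_well_powered))
    cat(sprintf("  well-powered: %d, of which replicated %d (%.1f%%), nominal %d (%.1f%%)\n",
                x$n_well_powered, x$n_well_powered_replicated,
                x$pct_well_powered_replicated, x$n_well_powered_nominal,
                x$pct_well_powered_nominal))
  invisible(x)
}
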
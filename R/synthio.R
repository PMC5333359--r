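#' Configuration for the synthetic paired-cohort generator
#'
#' Bundles and validates the parameters of the synthetic discovery /
#' replication cohort pair. Defaults mirror a typical population-based
#' discovery study of ~1,000 genotyped individuals with SOMAscan-style
#' proteomics and a smaller multi-ethnic replication study.
#'
#' @param n_discovery discovery cohort size (default 997).
#' @param n_replication replication cohort size (default 338).
#' @param n_variants number of common autosomal variants to simulate.
#' @param n_traits number of protein traits.
#' @param ld_block_sizes integer vector of LD block sizes; recycled to
#'   cover `n_variants`.
#' @param within_block_rho adjacent-variant latent correlation in `[0, 1)`;
#'   LD decays as `rho^distance` (in variants) within a block.
#' @param maf_range length-2 numeric, target minor allele frequency range;
#'   lower bound must be >= 0.01 (common variants only).
#' @param n_ethnic_clusters number of ancestry clusters in the replication
#'   cohort (default 3).
#' @param fst Balding-Nichols-style differentiation parameter controlling
#'   how far replication cluster allele frequencies drift from the
#'   discovery frequencies (default 0.05).
#' @param seed integer master seed; all stage-level randomness is derived
#'   deterministically from it.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_discovery = 997, n_replication = 338,
                       n_variants = 1000, n_traits = 100,
                       ld_block_sizes = 10, within_block_rho = 0.8,
                       maf_range = c(0.05, 0.5), n_ethnic_clusters = 3,
                       fst = 0.05, seed = 1L) {
  cfg <- list(n_discovery = as.integer(n_discovery),
              n_replication = as.integer(n_replication),
              n_variants = as.integer(n_variants),
              n_traits = as.integer(n_traits),
              ld_block_sizes = as.integer(ld_block_sizes),
              within_block_rho = within_block_rho,
              maf_range = as.numeric(maf_range),
              n_ethnic_clusters = as.integer(n_ethnic_clusters),
              fst = fst, seed = as.integer(seed))
  for (f in c("n_discovery", "n_replication", "n_variants", "n_traits",
              "n_ethnic_clusters"))
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("sim_config: field '", f, "' must be a count >= 1")
  if (any(cfg$ld_block_sizes < 1L))
    stop("sim_config: field 'ld_block_sizes' must contain counts >= 1")
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1)
    stop("sim_config: field 'within_block_rho' must lie in [0, 1)")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] < 0.01 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("sim_config: field 'maf_range' must be (lo, hi) with lo >= 0.01, hi <= 0.5")
  if (cfg$fst <= 0 || cfg$fst >= 1)
    stop("sim_config: field 'fst' must lie in (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic 32-bit sub-seed for a named simulation stage.
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Shared variant panel: target MAFs, genomic placement and LD block
# assignment, identical between discovery and replication so both cohorts
# carry the same variant definitions. Blocks are laid 20 Mb apart along
# chromosomes 1-22 (variants 5 kb apart within a block) so that distinct
# blocks never fall inside one 10 Mb lumping window.
variant_panel <- function(config) {
  m <- config$n_variants
  sizes <- config$ld_block_sizes
  # recycle block sizes until they cover m variants
  max_blocks <- ceiling(m / min(sizes)) + 1L
  reps <- cumsum(rep(sizes, length.out = max_blocks))
  nblocks <- which(reps >= m)[1]
  block_sizes <- rep(sizes, length.out = nblocks)
  block_of <- rep(seq_len(nblocks), times = block_sizes)[seq_len(m)]
  chrom <- ((seq_len(nblocks) - 1L) %% 22L) + 1L
  slot <- (seq_len(nblocks) - 1L) %/% 22L
  block_start <- 1e6 + slot * 2e7
  within <- stats::ave(seq_len(m), block_of, FUN = seq_along)
  pos <- as.integer(block_start[block_of] + (within - 1L) * 5000L)
  set.seed(sub_seed(config$seed, "panel"))
  target_maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  data.frame(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chrom = as.character(chrom[block_of]),
    pos = pos, ref = "A", alt = "G",
    block = block_of, target_maf = target_maf,
    stringsAsFactors = FALSE)
}

# One haplotype per call: latent AR(1) Gaussian within each block,
# thresholded at the allele-frequency quantile. `freq` may be a vector
# (one frequency for all samples) or a samples x variants matrix
# (per-sample frequencies, used for ethnic-cluster structure).
simulate_haplotype <- function(n, panel, rho, freq) {
  m <- nrow(panel)
  z <- matrix(NA_real_, n, m)
  new_block <- c(TRUE, diff(panel$block) != 0)
  innov <- matrix(stats::rnorm(n * m), n, m)
  for (j in seq_len(m)) {
    z[, j] <- if (new_block[j]) innov[, j]
              else rho * z[, j - 1] + sqrt(1 - rho^2) * innov[, j]
  }
  thr <- if (is.matrix(freq)) stats::qnorm(freq)
         else matrix(stats::qnorm(freq), n, m, byrow = TRUE)
  (z < thr) * 1
}

#' Simulate a genotype panel with LD block structure
#'
#' Draws additive dosages for common autosomal variants under a
#' latent-threshold LD model: within each block a latent AR(1) Gaussian
#' with adjacent correlation `within_block_rho` is thresholded at the
#' variant's allele-frequency quantile to produce one haplotype; two
#' independent haplotypes are summed into the dosage. Columns whose
#' realized minor allele frequency falls below 0.01 are redrawn (fresh
#' independent latent), so every simulated variant is common.
#'
#' @param config a [sim_config()].
#' @param n number of samples; defaults to `config$n_discovery`.
#' @param cluster_freq optional samples x variants matrix of per-sample
#'   allele frequencies (ancestry structure); used internally for the
#'   replication cohort.
#' @param stage seed-derivation label (distinct stages give independent
#'   draws from one master seed).
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `block_map` (named integer vector: variant id -> LD block).
#' @export
simulate_genotypes <- function(config, n = config$n_discovery,
                               cluster_freq = NULL, stage = "genotypes") {
  stopifnot(inherits(config, "sim_config"))
  panel <- variant_panel(config)
  set.seed(sub_seed(config$seed, stage))
  freq <- if (is.null(cluster_freq)) panel$target_maf else cluster_freq
  dos <- simulate_haplotype(n, panel, config$within_block_rho, freq) +
    simulate_haplotype(n, panel, config$within_block_rho, freq)
  # guarantee common variants: redraw columns with realized MAF < 0.01
  for (attempt in seq_len(25)) {
    af <- colMeans(dos) / 2
    low <- which(pmin(af, 1 - af) < 0.01)
    if (!length(low)) break
    f <- if (is.matrix(freq)) freq[, low, drop = FALSE]
         else matrix(freq[low], n, length(low), byrow = TRUE)
    redraw <- (matrix(stats::rnorm(n * length(low)), n) < stats::qnorm(f)) * 1 +
              (matrix(stats::rnorm(n * length(low)), n) < stats::qnorm(f)) * 1
    dos[, low] <- redraw
  }
  rownames(dos) <- sprintf("%s%04d", if (stage == "genotypes") "D" else "R",
                           seq_len(n))
  colnames(dos) <- panel$variant_id
  gm <- genotype_matrix(dos, panel[, c("variant_id", "chrom", "pos",
                                       "ref", "alt")])
  block_map <- stats::setNames(panel$block, panel$variant_id)
  list(genotypes = gm, block_map = block_map)
}

#' Ground truth for a simulated cohort pair
#'
#' Records the planted genetic effects, the residual dependence structure
#' among traits, and the covariate effects, so parameter-recovery tests
#' can score the pipeline against known values.
#'
#' @param effects data.frame with columns `variant_id`, `trait_id`,
#'   `target_variance_fraction` (proportion of trait variance in `[0, 1)`
#'   explained by that variant), optional `sign` (+1/-1, default +1) and
#'   `is_cis` (logical; cis effects place the trait's gene next to the
#'   variant). Fractions for one trait must sum to < 1.
#' @param precision_structure optional data.frame with columns `trait_a`,
#'   `trait_b`, `pcor`: trait pairs given a nonzero residual partial
#'   correlation. The implied precision matrix must be positive definite.
#' @param covariate_betas optional named numeric vector of per-SD effects
#'   of covariates (e.g. `c(age = 0.1, bmi = 0.2)`) applied to every trait.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(effects = NULL, precision_structure = NULL,
                             covariate_betas = NULL) {
  if (is.null(effects)) {
    effects <- data.frame(variant_id = character(), trait_id = character(),
                          target_variance_fraction = numeric(),
                          sign = numeric(), is_cis = logical(),
                          stringsAsFactors = FALSE)
  } else {
    effects <- as.data.frame(effects, stringsAsFactors = FALSE)
    if (!all(c("variant_id", "trait_id", "target_variance_fraction") %in%
             names(effects)))
      stop("effects needs variant_id, trait_id, target_variance_fraction")
    if (!"sign" %in% names(effects)) effects$sign <- 1
    if (!"is_cis" %in% names(effects)) effects$is_cis <- NA
    if (any(effects$target_variance_fraction < 0) ||
        any(effects$target_variance_fraction >= 1))
      stop("target_variance_fraction must lie in [0, 1)")
    tot <- tapply(effects$target_variance_fraction, effects$trait_id, sum)
    if (any(tot >= 1))
      stop("variance fractions sum to >= 1 for trait(s): ",
           paste(names(tot)[tot >= 1], collapse = ", "))
  }
  if (!is.null(precision_structure)) {
    precision_structure <- as.data.frame(precision_structure,
                                         stringsAsFactors = FALSE)
    if (!all(c("trait_a", "trait_b", "pcor") %in% names(precision_structure)))
      stop("precision_structure needs trait_a, trait_b, pcor")
  }
  structure(list(effects = effects,
                 precision_structure = precision_structure,
                 covariate_betas = covariate_betas),
            class = "simulation_truth")
}

# Residual correlation matrix realizing the requested partial-correlation
# structure: precision Omega = I with Omega[a,b] = -pcor(a,b); errors if
# the implied precision is not positive definite.
residual_correlation <- function(trait_ids, precision_structure) {
  tn <- length(trait_ids)
  if (is.null(precision_structure) || nrow(precision_structure) == 0L)
    return(diag(tn))
  omega <- diag(tn)
  ia <- match(precision_structure$trait_a, trait_ids)
  ib <- match(precision_structure$trait_b, trait_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("precision_structure references unknown trait identifiers: ",
         paste(unique(c(precision_structure$trait_a[is.na(ia)],
                        precision_structure$trait_b[is.na(ib)])),
               collapse = ", "))
  omega[cbind(ia, ib)] <- -precision_structure$pcor
  omega[cbind(ib, ia)] <- -precision_structure$pcor
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("implied precision matrix is not positive definite (min eigenvalue ",
         signif(ev, 3), ")")
  stats::cov2cor(solve(omega))
}

#' Simulate baseline covariates (age, sex, BMI, optionally diabetes)
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param sample_ids row names for the covariate matrix.
#' @param diabetes add a binary diabetes indicator (replication design).
#' @param age_range age range (years); the discovery default spans 32-81,
#'   the replication cohort uses 23-71.
#' @return A numeric matrix with columns age, sex, bmi (and diabetes).
#' @export
simulate_covariates <- function(n, seed = 1L, sample_ids = NULL,
                                diabetes = FALSE, age_range = c(32, 81)) {
  set.seed(seed)
  cv <- cbind(age = stats::runif(n, age_range[1], age_range[2]),
              sex = stats::rbinom(n, 1, 0.5),
              bmi = stats::rnorm(n, 27, 4))
  if (diabetes) cv <- cbind(cv, diabetes = stats::rbinom(n, 1, 0.5))
  rownames(cv) <- if (is.null(sample_ids)) sprintf("D%04d", seq_len(n))
                  else sample_ids
  cv
}

#' Simulate trait abundances from genotypes and planted truth
#'
#' Each trait is built as planted genetic effects + covariate effects +
#' a correlated Gaussian residual whose precision matrix realizes the
#' truth's partial-correlation structure. Genetic coefficients are scaled
#' against the realized dosage variance so that each planted
#' `target_variance_fraction` holds in expectation; the residual standard
#' deviation absorbs the remainder, so trait variance is ~1 on the
#' simulated scale. Traits carrying a cis effect have their gene placed
#' within 50 kb of the variant; all other genes are placed at deterministic
#' random positions.
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth a [simulation_truth()].
#' @param covariates optional covariate matrix (samples x covariates);
#'   required when `truth$covariate_betas` is non-empty.
#' @param n_traits total number of traits to emit (>= number referenced by
#'   the truth); unreferenced traits are pure residual.
#' @param seed integer seed.
#' @return A [trait_matrix()] on the `raw` scale (values exponentiated so
#'   raw abundances are positive and log-normal-like).
#' @export
simulate_traits <- function(genotypes, truth, covariates = NULL,
                            n_traits = NULL, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "simulation_truth"))
  eff <- truth$effects
  n <- nrow(genotypes$dosage)
  ref_traits <- unique(c(eff$trait_id,
                         truth$precision_structure$trait_a,
                         truth$precision_structure$trait_b))
  if (is.null(n_traits)) n_traits <- max(length(ref_traits), 1L)
  trait_ids <- sprintf("P%04d", seq_len(n_traits))
  unknown_t <- setdiff(ref_traits, trait_ids)
  if (length(unknown_t))
    stop("truth references unknown trait identifier(s): ",
         paste(unknown_t, collapse = ", "),
         " (panel has traits ", trait_ids[1], "..",
         trait_ids[n_traits], ")")
  tn <- length(trait_ids)
  unknown_v <- setdiff(eff$variant_id, genotypes$variants$variant_id)
  if (length(unknown_v))
    stop("effects reference unknown variant identifier(s): ",
         paste(unknown_v, collapse = ", "))
  if (!is.null(covariates) && nrow(covariates) != n)
    stop("covariates must cover all samples")

  set.seed(seed)
  cmat <- residual_correlation(trait_ids, truth$precision_structure)
  resid <- matrix(stats::rnorm(n * tn), n, tn) %*% chol(cmat)

  gvar <- numeric(tn)                 # planted genetic variance per trait
  G <- matrix(0, n, tn)
  if (nrow(eff)) {
    for (k in seq_len(nrow(eff))) {
      j <- match(eff$trait_id[k], trait_ids)
      d <- genotypes$dosage[, eff$variant_id[k]]
      vd <- stats::var(d)
      if (vd <= 0) stop("planted variant ", eff$variant_id[k],
                        " has zero dosage variance")
      f <- eff$target_variance_fraction[k]
      G[, j] <- G[, j] + eff$sign[k] * sqrt(f / vd) * (d - mean(d))
      gvar[j] <- gvar[j] + f
    }
  }
  C <- matrix(0, n, tn)
  cvar <- 0
  if (!is.null(truth$covariate_betas) && length(truth$covariate_betas)) {
    if (is.null(covariates))
      stop("truth has covariate effects but no covariates supplied")
    b <- truth$covariate_betas
    missing_cv <- setdiff(names(b), colnames(covariates))
    if (length(missing_cv))
      stop("covariate_betas reference unknown covariate(s): ",
           paste(missing_cv, collapse = ", "))
    zs <- scale(covariates[, names(b), drop = FALSE])
    C <- zs %*% matrix(b, ncol = 1) %*% matrix(1, 1, tn)
    cvar <- sum(b^2)
  }
  res_sd <- 1 - gvar - cvar
  if (any(res_sd <= 0))
    stop("planted genetic + covariate variance >= 1 for trait(s): ",
         paste(trait_ids[res_sd <= 0], collapse = ", "))
  latent <- G + C + sweep(resid, 2, sqrt(res_sd), `*`)
  values <- exp(latent)               # positive, log-normal-like raw scale
  rownames(values) <- rownames(genotypes$dosage)
  colnames(values) <- trait_ids

  # gene coordinates: cis traits sit next to their variant
  tinfo <- data.frame(trait_id = trait_ids, chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  vtab <- genotypes$variants
  cis <- eff[!is.na(eff$is_cis) & eff$is_cis, , drop = FALSE]
  for (k in seq_len(nrow(cis))) {
    j <- match(cis$trait_id[k], trait_ids)
    vi <- match(cis$variant_id[k], vtab$variant_id)
    tinfo$chrom[j] <- vtab$chrom[vi]
    tinfo$start[j] <- max(1L, vtab$pos[vi] - 50000L)
    tinfo$end[j] <- vtab$pos[vi] + 50000L
  }
  open <- which(is.na(tinfo$chrom))
  if (length(open)) {
    tinfo$chrom[open] <- as.character(sample(1:22, length(open), TRUE))
    far <- as.integer(sample(2e8:2.4e8, length(open), TRUE))
    tinfo$start[open] <- far
    tinfo$end[open] <- far + 20000L
  }
  trait_matrix(values, tinfo, scale = "raw")
}

#' Simulate the replication cohort (ancestry clusters, diabetes, haemolysis)
#'
#' Generates an independent cohort sharing the discovery variant panel and
#' planted effects, with three realistic complications: cluster-specific
#' allele frequencies drawn from a Balding-Nichols-style perturbation of
#' the discovery frequencies, a binary diabetes covariate, and a latent
#' haemolysis-like factor loading a random subset of traits (emulating
#' pre-analytical variation that proteomics principal components must
#' absorb).
#'
#' @param config a [sim_config()].
#' @param truth the [simulation_truth()] shared with the discovery cohort.
#' @param haemolysis_frac fraction of traits loaded by the latent factor.
#' @param haemolysis_loading loading magnitude (trait SD units).
#' @return A list: `genotypes`, `traits`, `covariates`, `clusters`
#'   (integer cluster label per sample), `block_map`.
#' @export
simulate_replication_cohort <- function(config, truth,
                                        haemolysis_frac = 0.3,
                                        haemolysis_loading = 0.4) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_ethnic_clusters
  if (k < 1L) stop("n_ethnic_clusters must be >= 1")
  n <- config$n_replication
  panel <- variant_panel(config)
  set.seed(sub_seed(config$seed, "replication-structure"))
  clusters <- sample(rep_len(seq_len(k), n))
  fst <- config$fst
  # Balding-Nichols: cluster freq ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
  cl_freq <- sapply(panel$target_maf, function(p)
    pmin(0.99, pmax(0.01,
      stats::rbeta(k, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst))))
  freq_mat <- cl_freq[clusters, , drop = FALSE]   # samples x variants
  sim <- simulate_genotypes(config, n = n, cluster_freq = freq_mat,
                            stage = "replication-genotypes")
  cv <- simulate_covariates(n, seed = sub_seed(config$seed, "replication-cov"),
                            sample_ids = rownames(sim$genotypes$dosage),
                            diabetes = TRUE, age_range = c(23, 71))
  traits <- simulate_traits(sim$genotypes, truth, covariates = cv,
                            n_traits = config$n_traits,
                            seed = sub_seed(config$seed, "replication-traits"))
  set.seed(sub_seed(config$seed, "haemolysis"))
  tn <- ncol(traits$values)
  n_load <- round(haemolysis_frac * tn)
  loaded <- sample(tn, n_load)
  h <- stats::rnorm(n)
  if (n_load > 0) {
    latent <- log(traits$values)
    latent[, loaded] <- latent[, loaded] + h %o% rep(haemolysis_loading, n_load)
    traits <- trait_matrix(exp(latent), traits$traits, scale = "raw")
  }
  list(genotypes = sim$genotypes, traits = traits, covariates = cv,
       clusters = clusters, block_map = sim$block_map,
       haemolysis = h, haemolysis_traits = colnames(traits$values)[loaded])
}
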
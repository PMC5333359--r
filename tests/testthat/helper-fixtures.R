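# Shared fixture builders; everything is generated in code at test time.

# Small genotype matrix with hand-set dosages.
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL,
                          ref = "A", alt = "G") {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq(1e6, by = 5e4, length.out = m)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("v%02d", seq_len(m))
  genotype_matrix(dosage,
                  data.frame(variant_id = colnames(dosage), chrom = chrom,
                             pos = pos, ref = rep_len(ref, m),
                             alt = rep_len(alt, m),
                             stringsAsFactors = FALSE))
}

# Correlated dosage columns: latent-threshold pairs with given latent rho
# and MAF, for LD-dependent tests.
correlated_dosages <- function(n, rho, maf, m = 2, seed = 1) {
  set.seed(seed)
  out <- matrix(0, n, m)
  for (h in 1:2) {
    z <- matrix(rnorm(n * m), n, m)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    out <- out + (z < qnorm(maf))
  }
  colnames(out) <- sprintf("v%02d", seq_len(m))
  out
}

# Closed-form simple-regression oracle (normal equations), no covariates.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  a <- mean(y) - beta * mean(x)
  rss <- sum((y - a - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  stat <- beta / se
  list(beta = beta, se = se, stat = stat,
       p = 2 * pt(-abs(stat), n - 2))
}

# Full-enumeration HWE oracle: Levene-Haldane probabilities by direct
# log-factorial evaluation over every feasible heterozygote count.
hwe_enumeration_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_ref + n_het          # allele A count
  nb <- 2 * n - na
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_comm <- (max(na, nb) - h) / 2
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_comm) + h * log(2) +
      lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Standard cohort + planted-truth fixture used across modules.
planted_fixture <- function(seed = 11, n = 400, n_variants = 200,
                            n_traits = 10) {
  cfg <- sim_config(n_discovery = n, n_replication = 200,
                    n_variants = n_variants, n_traits = n_traits,
                    ld_block_sizes = 10, within_block_rho = 0.8,
                    seed = seed)
  g <- simulate_genotypes(cfg)
  vids <- sprintf("rs%06d", unique(c(1L, ceiling(n_variants / 2),
                                     n_variants)))[1:3]
  vids <- vids[!is.na(vids)]
  truth <- simulation_truth(
    effects = data.frame(
      variant_id = vids,
      trait_id = c("P0001", "P0002", "P0002")[seq_along(vids)],
      target_variance_fraction = c(0.25, 0.2, 0.15)[seq_along(vids)],
      is_cis = c(TRUE, TRUE, FALSE)[seq_along(vids)]),
    covariate_betas = c(age = 0.1, bmi = 0.15))
  cv <- simulate_covariates(n, seed = seed + 1,
                            sample_ids = rownames(g$genotypes$dosage))
  tr <- simulate_traits(g$genotypes, truth, cv, n_traits = n_traits,
                        seed = seed + 2)
  list(config = cfg, geno = g$genotypes, block_map = g$block_map,
       truth = truth, covariates = cv, traits = tr)
}
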
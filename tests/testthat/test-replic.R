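# Shared discovery/replication pair with one strong planted effect.
replication_fixture <- function(seed = 71, frac = 0.25) {
  cfg <- sim_config(n_discovery = 400, n_replication = 338,
                    n_variants = 60, n_traits = 20,
                    ld_block_sizes = 10, within_block_rho = 0.995,
                    maf_range = c(0.3, 0.3), seed = seed)
  truth <- simulation_truth(effects = data.frame(
    variant_id = "rs000001", trait_id = "P0001",
    target_variance_fraction = frac, is_cis = TRUE))
  disc <- simulate_genotypes(cfg)
  cv <- simulate_covariates(cfg$n_discovery, seed = seed + 1,
                            sample_ids = rownames(disc$genotypes$dosage))
  tr <- simulate_traits(disc$genotypes, truth, cv,
                        n_traits = cfg$n_traits, seed = seed + 2)
  rep <- simulate_replication_cohort(cfg, truth)
  rc <- cbind(rep$covariates,
              compute_pcs(rep$genotypes$dosage, 3),
              prot = compute_pcs(log(rep$traits$values), 3))
  list(cfg = cfg, truth = truth, disc_geno = disc$genotypes,
       disc_cov = cv, disc_traits = tr,
       disc_traits_int = transform_traits(tr, "inverse-normal"),
       repl = rep, repl_cov = rc)
}

test_that("tag selection prefers the sentinel and falls back to the best proxy", {
  fx <- replication_fixture()
  tag <- select_tag_snp("rs000001", "P0001", fx$disc_geno,
                        fx$repl$genotypes, fx$disc_traits_int,
                        fx$disc_cov)
  expect_equal(tag$tag_variant, "rs000001")
  expect_equal(tag$tag_r2, 1)
  # sentinel absent from the replication panel: a high-LD proxy steps in
  repl_sub <- subset_genotypes(fx$repl$genotypes,
                               variants = setdiff(
                                 colnames(fx$repl$genotypes$dosage),
                                 "rs000001"))
  tag2 <- select_tag_snp("rs000001", "P0001", fx$disc_geno, repl_sub,
                         fx$disc_traits_int, fx$disc_cov)
  expect_false(is.null(tag2))
  expect_gt(tag2$tag_r2, 0.8)
  expect_true(tag2$tag_variant != "rs000001")
  # no candidate above the threshold: untestable (NULL)
  lone <- subset_genotypes(fx$repl$genotypes, variants = "rs000060")
  expect_null(select_tag_snp("rs000001", "P0001", fx$disc_geno, lone,
                             fx$disc_traits_int, fx$disc_cov))
})

test_that("allele harmonization matches, swaps, and flags ambiguity", {
  h <- pqtlpipe:::harmonize_alleles("G", "A", "G", "A")
  expect_equal(h$flip, 1); expect_false(h$ambiguous)
  h2 <- pqtlpipe:::harmonize_alleles("G", "A", "A", "G")
  expect_equal(h2$flip, -1)
  h3 <- pqtlpipe:::harmonize_alleles("G", "A", "C", "T")
  expect_true(is.na(h3$flip))
  h4 <- pqtlpipe:::harmonize_alleles("A", "T", "A", "T")
  expect_true(h4$ambiguous)
})

test_that("a planted shared effect replicates with consistent direction", {
  fx <- replication_fixture()
  tag <- select_tag_snp("rs000001", "P0001", fx$disc_geno,
                        fx$repl$genotypes, fx$disc_traits_int,
                        fx$disc_cov)
  disc_fit <- fit_additive_model(fx$disc_geno$dosage[, "rs000001"],
                                 fx$disc_traits_int$values[, "P0001"],
                                 fx$disc_cov)
  rec <- replicate_association(
    1, "rs000001", "P0001", disc_fit$beta, disc_fit$p, tag,
    fx$repl$genotypes, fx$repl$traits, fx$repl_cov,
    discovery_alleles = c(effect = "G", other = "A"), n_attempted = 10)
  expect_equal(rec$status, "replicated")
  expect_lt(rec$p_replication, 0.05 / 10)
  expect_true(rec$direction_consistent)
  # flipping the replication allele coding leaves the verdict unchanged
  flipped <- fx$repl$genotypes
  flipped$dosage <- 2 - flipped$dosage
  tmp <- flipped$variants$ref
  flipped$variants$ref <- flipped$variants$alt
  flipped$variants$alt <- tmp
  flipped <- genotype_matrix(flipped$dosage,
                             flipped$variants[, c("variant_id", "chrom",
                                                  "pos", "ref", "alt")])
  rec_f <- replicate_association(
    1, "rs000001", "P0001", disc_fit$beta, disc_fit$p, tag,
    flipped, fx$repl$traits, fx$repl_cov,
    discovery_alleles = c(effect = "G", other = "A"), n_attempted = 10)
  expect_equal(rec_f$status, "replicated")
  expect_identical(rec_f$direction_consistent, rec$direction_consistent)
  expect_equal(rec_f$beta_replication, rec$beta_replication,
               tolerance = 1e-10)
  # irreconcilable alleles: untestable with the reason recorded
  rec_bad <- replicate_association(
    1, "rs000001", "P0001", disc_fit$beta, disc_fit$p, tag,
    fx$repl$genotypes, fx$repl$traits, fx$repl_cov,
    discovery_alleles = c(effect = "C", other = "T"), n_attempted = 10)
  expect_equal(rec_bad$status, "untestable")
  expect_match(rec_bad$reason, "harmonized")
  # missing tag: untestable
  rec_no <- replicate_association(
    1, "rs000001", "P0001", disc_fit$beta, disc_fit$p, NULL,
    fx$repl$genotypes, fx$repl$traits, fx$repl_cov,
    discovery_alleles = c(effect = "G", other = "A"), n_attempted = 10)
  expect_equal(rec_no$status, "untestable")
})

test_that("p95 degenerates to the full-sample P when m = n", {
  set.seed(83)
  n <- 120
  d <- rbinom(n, 2, 0.4)
  y <- 0.3 * d + rnorm(n)
  full_p <- fit_additive_model(d, y)$p
  est <- estimate_p95(d, y, m = n, reps = 25, seed = 9)
  expect_equal(est$p95, full_p, tolerance = 1e-12)
  expect_true(all(abs(est$p_values - full_p) < 1e-12))
  expect_error(estimate_p95(d, y, m = n + 1, reps = 25), "exceeds")
  expect_error(estimate_p95(d, y, m = 50, reps = 5), "reps")
})

test_that("null p95 matches the order-statistics expectation", {
  # under the null, subsample P values are ~Uniform(0,1); the 95th
  # percentile of the empirical distribution concentrates near 0.95
  p95s <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    n <- 400
    d <- rbinom(n, 2, 0.3)
    y <- rnorm(n)
    estimate_p95(d, y, m = 100, reps = 60, seed = s)$p95
  }, numeric(1))
  expect_lt(abs(mean(p95s) - 0.95), 0.05)
})

test_that("p95 is monotone non-increasing in the planted effect size", {
  n <- 500
  set.seed(91)
  d <- rbinom(n, 2, 0.4)
  noise <- rnorm(n)
  p95_of <- function(beta) {
    y <- beta * d + noise
    estimate_p95(d, y, m = 338, reps = 40, seed = 5)$p95
  }
  grid <- vapply(c(0.05, 0.2, 0.5), p95_of, numeric(1))
  expect_true(all(diff(grid) <= 0))
  expect_lt(grid[3], bonferroni_threshold(0.05, 462))
})

test_that("replication summary computes the printed-count percentages", {
  # counts as printed for a 462-attempt replication with a 208-strong
  # well-powered stratum
  records <- data.frame(
    locus_id = seq_len(462),
    status = c(rep("replicated", 234), rep("nominal", 150),
               rep("not_replicated", 78)),
    direction_consistent = c(rep(TRUE, 215), rep(FALSE, 19),
                             rep(TRUE, 228)),
    p95 = c(rep(1e-6, 171), rep(1e-3, 63), rep(1e-6, 27),
            rep(1e-3, 123), rep(1e-6, 10), rep(1e-3, 68)),
    stringsAsFactors = FALSE)
  s <- summarize_replication(records)
  expect_equal(s$n_attempted, 462)
  expect_equal(round(s$pct_replicated, 1), 50.6)    # 234/462
  expect_equal(round(s$pct_nominal, 1), 83.1)       # 384/462
  expect_equal(s$n_well_powered, 171 + 27 + 10)
  expect_equal(round(s$pct_well_powered_replicated, 1), 82.2)  # 171/208
  expect_equal(round(s$pct_well_powered_nominal, 1), 95.2)     # 198/208
  # containment: replicated subset of nominal subset of attempted
  expect_true(s$n_replicated <= s$n_nominal)
  expect_true(s$n_nominal <= s$n_attempted)
  # zero denominators flagged as NA percentages
  empty <- summarize_replication(records[0, ])
  expect_equal(empty$n_attempted, 0)
  expect_true(is.na(empty$pct_replicated))
})
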
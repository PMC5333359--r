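test_that("invalid configuration fields are reported by name", {
  expect_error(sim_config(n_discovery = 0), "n_discovery")
  expect_error(sim_config(within_block_rho = 1), "within_block_rho")
  expect_error(sim_config(maf_range = c(0.005, 0.5)), "maf_range")
  expect_error(sim_config(n_traits = -2), "n_traits")
})

test_that("genotype simulation is deterministic and respects dosage domain", {
  cfg <- sim_config(n_discovery = 120, n_variants = 60, seed = 42)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$block_map, b$block_map)
  expect_true(all(a$genotypes$dosage %in% c(0, 1, 2)))
  ra <- simulate_replication_cohort(cfg, simulation_truth())
  rb <- simulate_replication_cohort(cfg, simulation_truth())
  expect_identical(ra$genotypes$dosage, rb$genotypes$dosage)
  expect_identical(ra$traits$values, rb$traits$values)
})

test_that("realized minor allele frequencies track their targets", {
  cfg <- sim_config(n_discovery = 600, n_variants = 300,
                    maf_range = c(0.05, 0.5), seed = 5)
  g <- simulate_genotypes(cfg)
  target <- pqtlpipe:::variant_panel(cfg)$target_maf
  dev <- abs(g$genotypes$variants$maf - pmin(target, 1 - target))
  expect_gt(mean(dev <= 0.03), 0.95)    # binomial noise at n = 600
  expect_lt(mean(dev), 0.015)
  expect_true(all(g$genotypes$variants$maf >= 0.01))
})

test_that("within-block LD spans the independence and perfect-LD limits", {
  cfg0 <- sim_config(n_discovery = 1000, n_variants = 100,
                     ld_block_sizes = 10, within_block_rho = 0, seed = 8)
  g0 <- simulate_genotypes(cfg0)
  adj <- which(diff(g0$block_map) == 0)
  r2_0 <- vapply(adj, function(j)
    ld_r2(g0$genotypes$dosage[, j], g0$genotypes$dosage[, j + 1]),
    numeric(1))
  expect_lt(mean(r2_0), 0.02)           # ~1/n under independence

  cfg1 <- sim_config(n_discovery = 1000, n_variants = 20,
                     ld_block_sizes = 10, within_block_rho = 0.9999,
                     maf_range = c(0.3, 0.3), seed = 8)
  g1 <- simulate_genotypes(cfg1)
  adj1 <- which(diff(g1$block_map) == 0)
  r2_1 <- vapply(adj1, function(j)
    ld_r2(g1$genotypes$dosage[, j], g1$genotypes$dosage[, j + 1]),
    numeric(1))
  expect_gt(mean(r2_1), 0.97)
})

test_that("realized adjacent-pair r2 matches a brute-force latent-threshold oracle", {
  # oracle: one million allele pairs from the same thresholded bivariate
  # normal; dosage r2 equals allele r2 (sum of two iid haplotypes)
  rho <- 0.8; maf <- 0.3
  set.seed(99)
  z1 <- rnorm(1e6)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1e6)
  a1 <- (z1 < qnorm(maf)) * 1
  a2 <- (z2 < qnorm(maf)) * 1
  oracle_r2 <- cor(a1, a2)^2

  cfg <- sim_config(n_discovery = 2000, n_variants = 200,
                    ld_block_sizes = 10, within_block_rho = rho,
                    maf_range = c(maf, maf), seed = 13)
  g <- simulate_genotypes(cfg)
  adj <- which(diff(g$block_map) == 0)
  r2 <- vapply(adj, function(j)
    ld_r2(g$genotypes$dosage[, j], g$genotypes$dosage[, j + 1]),
    numeric(1))
  expect_lt(abs(mean(r2) - oracle_r2), 0.05)
})

test_that("null traits with identity precision are near-independent Gaussians", {
  cfg <- sim_config(n_discovery = 400, n_variants = 50, n_traits = 10,
                    seed = 3)
  g <- simulate_genotypes(cfg)
  tr <- simulate_traits(g$genotypes, simulation_truth(), n_traits = 10,
                        seed = 4)
  lat <- log(tr$values)                  # simulated latent scale
  cm <- cor(lat)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.2)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.08)
  expect_gt(shapiro.test(lat[sample(length(lat), 500)])$p.value, 1e-4)
})

test_that("planted variance fractions are recovered by regression", {
  cfg <- sim_config(n_discovery = 997, n_variants = 60, n_traits = 5,
                    maf_range = c(0.5, 0.5), seed = 21)
  g <- simulate_genotypes(cfg)
  truth <- simulation_truth(effects = data.frame(
    variant_id = "rs000001", trait_id = "P0001",
    target_variance_fraction = 0.5))
  tr <- simulate_traits(g$genotypes, truth, n_traits = 5, seed = 22)
  r2 <- summary(lm(log(tr$values[, "P0001"]) ~
                     g$genotypes$dosage[, "rs000001"]))$r.squared
  expect_lt(abs(r2 - 0.5), 0.05)
})

test_that("three planted independent variants jointly explain their summed fraction", {
  cfg <- sim_config(n_discovery = 997, n_variants = 120, n_traits = 4,
                    seed = 31)
  g <- simulate_genotypes(cfg)
  truth <- simulation_truth(effects = data.frame(
    variant_id = c("rs000001", "rs000041", "rs000081"),
    trait_id = "P0001",
    target_variance_fraction = c(0.30, 0.21, 0.10)))
  tr <- simulate_traits(g$genotypes, truth, n_traits = 4, seed = 32)
  d <- g$genotypes$dosage
  fit <- lm(log(tr$values[, "P0001"]) ~
              d[, "rs000001"] + d[, "rs000041"] + d[, "rs000081"])
  expect_lt(abs(summary(fit)$r.squared - 0.61), 0.05)
})

test_that("truth referencing unknown identifiers errors", {
  cfg <- sim_config(n_discovery = 100, n_variants = 20, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_traits(
    g$genotypes,
    simulation_truth(effects = data.frame(
      variant_id = "nope", trait_id = "P0001",
      target_variance_fraction = 0.1)), n_traits = 2, seed = 1),
    "unknown variant")
  expect_error(simulate_traits(
    g$genotypes,
    simulation_truth(effects = data.frame(
      variant_id = "rs000001", trait_id = "P9999",
      target_variance_fraction = 0.1)), n_traits = 2, seed = 1),
    "unknown trait")
  expect_error(
    simulation_truth(effects = data.frame(
      variant_id = c("a", "b"), trait_id = "P0001",
      target_variance_fraction = c(0.6, 0.5))),
    "sum to >= 1")
})

test_that("non-positive-definite precision structures are rejected", {
  cfg <- sim_config(n_discovery = 100, n_variants = 20, n_traits = 3,
                    seed = 1)
  g <- simulate_genotypes(cfg)
  bad <- simulation_truth(precision_structure = data.frame(
    trait_a = c("P0001", "P0001"),
    trait_b = c("P0002", "P0003"),
    pcor = c(0.9, 0.9)))   # 0.81 + 0.81 > 1: indefinite precision
  expect_error(simulate_traits(g$genotypes, bad, n_traits = 3, seed = 1),
               "positive definite")
})

test_that("planted partial correlations shape the residual dependence", {
  cfg <- sim_config(n_discovery = 800, n_variants = 20, n_traits = 3,
                    seed = 17)
  g <- simulate_genotypes(cfg)
  truth <- simulation_truth(precision_structure = data.frame(
    trait_a = c("P0001", "P0002"), trait_b = c("P0002", "P0003"),
    pcor = c(0.5, 0.5)))
  tr <- simulate_traits(g$genotypes, truth, n_traits = 3, seed = 18)
  lat <- log(tr$values)
  pc <- partial_correlations(cor(lat))
  expect_lt(abs(pc["P0001", "P0002"] - 0.5), 0.1)
  expect_lt(abs(pc["P0002", "P0003"] - 0.5), 0.1)
  expect_lt(abs(pc["P0001", "P0003"]), 0.1)
})

test_that("replication cohort carries ancestry structure visible in genotype PCs", {
  skip_if_not_installed("cluster")
  cfg <- sim_config(n_discovery = 200, n_replication = 240,
                    n_variants = 400, n_traits = 5,
                    n_ethnic_clusters = 3, seed = 51)
  rep <- simulate_replication_cohort(cfg, simulation_truth())
  pcs <- compute_pcs(rep$genotypes$dosage, 2)
  sil <- cluster::silhouette(rep$clusters, dist(pcs))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_true("diabetes" %in% colnames(rep$covariates))
})

test_that("zero haemolysis loading reproduces the unloaded trait matrix", {
  cfg <- sim_config(n_discovery = 100, n_replication = 80,
                    n_variants = 40, n_traits = 6, seed = 61)
  a <- simulate_replication_cohort(cfg, simulation_truth(),
                                   haemolysis_loading = 0)
  b <- simulate_replication_cohort(cfg, simulation_truth(),
                                   haemolysis_frac = 0)
  expect_equal(a$traits$values, b$traits$values, tolerance = 1e-12)
})

test_that("a strong planted effect reaches replication significance", {
  thr <- bonferroni_threshold(0.05, 462)     # 1.08e-4
  for (seed in 1:5) {
    cfg <- sim_config(n_discovery = 100, n_replication = 338,
                      n_variants = 40, n_traits = 2, seed = 100 + seed)
    truth <- simulation_truth(effects = data.frame(
      variant_id = "rs000001", trait_id = "P0001",
      target_variance_fraction = 0.3))
    rep <- simulate_replication_cohort(cfg, truth)
    y <- inverse_normal_transform(rep$traits$values[, "P0001"])
    p <- fit_additive_model(rep$genotypes$dosage[, "rs000001"], y)$p
    expect_lt(p, thr)
  }
})
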
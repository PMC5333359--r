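test_that("LD r2 matches hand arithmetic and handles degenerate input", {
  a <- c(0, 1, 2, 0, 1, 2)
  b <- c(0, 1, 1, 0, 2, 2)
  # hand computation of the squared Pearson correlation
  sa <- a - mean(a); sb <- b - mean(b)
  hand <- (sum(sa * sb))^2 / (sum(sa^2) * sum(sb^2))
  expect_equal(ld_r2(a, b, min_overlap = 6), hand, tolerance = 1e-12)
  expect_equal(ld_r2(a, a, min_overlap = 6), 1)
  expect_error(ld_r2(a, rep(1, 6), min_overlap = 6), "zero")
  expect_error(ld_r2(a[1:4], b[1:4]), "overlapping")
  set.seed(2)
  x <- rbinom(2000, 2, 0.3); y <- rbinom(2000, 2, 0.3)
  expect_lt(ld_r2(x, y), 0.01)
})

test_that("per-trait lumping is greedy on P with LD and window absorption", {
  # 3 correlated variants in one window: single sentinel at lowest P
  set.seed(7)
  d3 <- correlated_dosages(300, rho = 0.95, maf = 0.3, m = 3)
  geno3 <- toy_genotypes(d3)
  res3 <- data.frame(variant_id = colnames(d3), chrom = "1",
                     pos = geno3$variants$pos, trait_id = "t1",
                     p = c(1e-8, 1e-12, 1e-6))
  lump3 <- lump_per_trait(res3, geno3)
  expect_equal(nrow(lump3), 1)
  expect_equal(lump3$variant_id, "v02")
  expect_setequal(lump3$members[[1]], c("v01", "v02", "v03"))
  # different chromosomes never lump regardless of r2
  d2 <- cbind(d3[, 1], d3[, 1])
  colnames(d2) <- c("w1", "w2")
  geno2 <- toy_genotypes(d2, chrom = c("1", "2"))
  res2 <- data.frame(variant_id = c("w1", "w2"), chrom = c("1", "2"),
                     pos = geno2$variants$pos, trait_id = "t1",
                     p = c(1e-9, 1e-7))
  expect_equal(nrow(lump_per_trait(res2, geno2)), 2)
})

test_that("lumping matches a brute-force oracle on a 5-variant panel", {
  set.seed(13)
  n <- 500
  block_a <- correlated_dosages(n, rho = 0.9, maf = 0.3, m = 2, seed = 13)
  block_b <- correlated_dosages(n, rho = 0.85, maf = 0.4, m = 2, seed = 14)
  lone <- matrix(rbinom(n, 2, 0.25), ncol = 1)
  dos <- cbind(block_a, block_b, lone)
  colnames(dos) <- paste0("v0", 1:5)
  geno <- toy_genotypes(dos)
  res <- data.frame(variant_id = colnames(dos), chrom = "1",
                    pos = geno$variants$pos, trait_id = "t1",
                    p = c(1e-10, 1e-9, 1e-7, 1e-8, 1e-6))
  got <- lump_per_trait(res, geno, r2_min = 0.1)
  # oracle: replay the greedy rule by direct enumeration
  r2m <- cor(dos)^2
  remaining <- order(res$p)
  sentinels <- character(0); members <- list()
  while (length(remaining)) {
    s <- remaining[1]
    grab <- remaining[r2m[s, remaining] > 0.1 | remaining == s]
    sentinels <- c(sentinels, res$variant_id[s])
    members[[length(members) + 1]] <- res$variant_id[grab]
    remaining <- setdiff(remaining, grab)
  }
  expect_equal(got$variant_id, sentinels)
  for (i in seq_along(members))
    expect_setequal(got$members[[i]], members[[i]])
})

test_that("locus definition merges transitively and ranks by sentinel P", {
  # chain A-B r2 > .9, B-C r2 > .9, A-C below the merge threshold:
  # one locus by transitive closure
  set.seed(19)
  n <- 800
  a <- rbinom(n, 2, 0.4)
  b <- a; bi <- sample(n, 22); b[bi] <- rbinom(22, 2, 0.4)
  c_ <- b; ci <- sample(n, 22); c_[ci] <- rbinom(22, 2, 0.4)
  d <- cbind(a, b, c_)
  colnames(d) <- c("v01", "v02", "v03")
  geno <- toy_genotypes(d)
  expect_gt(ld_r2(d[, 1], d[, 2]), 0.9)
  expect_gt(ld_r2(d[, 2], d[, 3]), 0.9)
  expect_lt(ld_r2(d[, 1], d[, 3]), 0.9)
  sent <- data.frame(variant_id = colnames(d), chrom = "1",
                     pos = geno$variants$pos,
                     trait_id = c("t1", "t2", "t3"),
                     p = c(1e-15, 1e-13, 1e-12))
  out <- define_loci(sent, geno, n_snps_tested = 3, n_traits_tested = 3)
  expect_equal(length(unique(out$loci$locus_id)), 1)
  expect_true(all(out$loci$sentinel_variant == "v01"))
  # same variant sentinel for two traits: one locus, two sentinel traits
  sent2 <- data.frame(variant_id = "v01", chrom = "1",
                      pos = geno$variants$pos[1],
                      trait_id = c("t1", "t2"), p = c(1e-15, 1e-9))
  out2 <- define_loci(sent2, geno, n_snps_tested = 3, n_traits_tested = 2)
  expect_equal(length(unique(out2$loci$locus_id)), 1)
  expect_equal(nrow(out2$loci), 2)
  # uncorrelated sentinels: one locus each, ranked 1..L strongest first
  far <- toy_genotypes(matrix(rbinom(2400, 2, 0.3), 800, 3),
                       chrom = c("1", "5", "9"))
  sent3 <- data.frame(variant_id = colnames(far$dosage), chrom = far$variants$chrom,
                      pos = far$variants$pos, trait_id = c("t1", "t2", "t3"),
                      p = c(1e-9, 1e-14, 1e-11))
  out3 <- define_loci(sent3, far, n_snps_tested = 3, n_traits_tested = 3)
  expect_equal(length(unique(out3$loci$locus_id)), 3)
  strongest <- out3$loci[out3$loci$locus_id == 1, ]
  expect_equal(strongest$variant_id, "v02")
})

test_that("tiering uses the primary threshold then the realized locus count", {
  set.seed(23)
  dos <- matrix(rbinom(600 * 4, 2, 0.35), 600, 4)
  geno <- toy_genotypes(dos, chrom = c("1", "4", "8", "12"))
  thr1 <- bonferroni_threshold(0.05, 4, 10)       # 1.25e-3
  sent <- data.frame(variant_id = colnames(geno$dosage),
                     chrom = geno$variants$chrom,
                     pos = geno$variants$pos,
                     trait_id = c("t1", "t2", "t3", "t4"),
                     p = c(1e-8, 1e-6, 5e-4, 0.04))
  out <- define_loci(sent, geno, n_snps_tested = 4, n_traits_tested = 10)
  expect_equal(out$n_primary_loci, 3)
  thr2 <- bonferroni_threshold(0.05, 3, 10)
  expect_equal(unname(out$thresholds["secondary"]), thr2)
  expect_equal(out$loci$tier[match(c("t1", "t2", "t3", "t4"),
                                   out$loci$trait_id)],
               c("primary", "primary", "primary", "none"))
})

test_that("every screened association lands in exactly one locus member set", {
  fx <- planted_fixture(seed = 37, n = 300, n_variants = 100, n_traits = 6)
  res <- scan_all(fx$geno, fx$traits, fx$covariates, screen_p = 1e-4)
  sent <- do.call(rbind, lapply(split(res, res$trait_id), lump_per_trait,
                                genotypes = fx$geno))
  for (tid in unique(res$trait_id)) {
    st <- sent[sent$trait_id == tid, ]
    assigned <- unlist(st$members)
    expect_equal(sort(assigned),
                 sort(res$variant_id[res$trait_id == tid]))
    expect_equal(anyDuplicated(assigned), 0)
  }
})

test_that("cis/trans classification follows the 10 Mb boundary rule", {
  expect_equal(classify_cis_trans("3", 5e6, "3", 4.9e6, 5.2e6), "cis")
  expect_equal(classify_cis_trans("3", 1e6, "3", 1e6 + 1e7 + 1, 1e6 + 2e7),
               "trans")                       # distance 10,000,001
  expect_equal(classify_cis_trans("3", 1e6, "3", 1e6 + 1e7 - 1, 2e7),
               "cis")                         # distance 9,999,999
  expect_equal(classify_cis_trans("3", 5e6, "7", 5e6, 5.1e6), "trans")
  expect_equal(classify_cis_trans("3", 5e6, NA, NA, NA), "unknown")
  expect_error(classify_cis_trans("3", 5e6, "3", 10, 5), "malformed")
})

test_that("conditional fit reduces to the marginal fit and decomposes variance", {
  set.seed(41)
  n <- 400
  d <- rbinom(n, 2, 0.4)
  cv <- cbind(age = runif(n, 30, 80))
  y <- 0.5 * d + 0.01 * cv[, 1] + rnorm(n)
  cj <- conditional_joint_fit(y, matrix(d, ncol = 1), cv)
  marg <- fit_additive_model(d, y, cv)
  expect_equal(cj$fit$conditional_p, marg$p, tolerance = 1e-10)
  expect_equal(cj$fit$beta, marg$beta, tolerance = 1e-10)
  # null variant added to a real one: conditional p is uniform over seeds
  pnull <- vapply(1:40, function(s) {
    set.seed(s)
    d1 <- rbinom(n, 2, 0.4); d0 <- rbinom(n, 2, 0.3)
    yy <- 0.5 * d1 + rnorm(n)
    conditional_joint_fit(yy, cbind(a = d1, b = d0))$fit$conditional_p[2]
  }, numeric(1))
  expect_gt(ks.test(pnull, "punif")$p.value, 0.01)
  # collinearity guard names the offending pair
  x1 <- rbinom(n, 2, 0.4)
  x2 <- x1; x2[1] <- 2 - x2[1]          # near-duplicate, r2 > 0.99
  dd <- cbind(x1 = x1, x2 = x2)
  expect_error(conditional_joint_fit(rnorm(n), dd), "x[12] / x[12]")
})

test_that("three planted independent variants recover 61% joint variance", {
  cfg <- sim_config(n_discovery = 997, n_variants = 120, n_traits = 3,
                    seed = 47)
  g <- simulate_genotypes(cfg)
  vids <- c("rs000001", "rs000041", "rs000081")
  truth <- simulation_truth(effects = data.frame(
    variant_id = vids, trait_id = "P0001",
    target_variance_fraction = c(0.30, 0.21, 0.10)))
  cv <- simulate_covariates(997, seed = 48)
  tr <- simulate_traits(g$genotypes, truth, cv, n_traits = 3, seed = 49)
  cj <- conditional_joint_fit(log(tr$values[, "P0001"]),
                              g$genotypes$dosage[, vids], cv)
  expect_lt(abs(cj$joint_r2 - 0.61), 0.05)
  expect_true(all(cj$fit$conditional_p < 1e-8))
})
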
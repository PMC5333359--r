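#' Pipeline configuration
#'
#' Collects input paths, thresholds, scale and seed for [run_pipeline()].
#' Every analysis default mirrors the package's standard settings:
#' screening at P <= 1e-5, lumping at r2 > 0.1, locus merging at r2 > 0.9,
#' 10 Mb windows, tag SNPs at r2 > 0.8, alpha 0.05, p-gain threshold 1e4.
#'
#' @param genotypes,variants,traits,covariates,gene_map paths to the
#'   discovery TSV inputs ([write_genotypes_tsv()] /
#'   [write_traits_tsv()] / [write_covariates_tsv()] layout).
#' @param replication optional named list with paths `genotypes`,
#'   `variants`, `traits`, `covariates` for the replication cohort.
#' @param disease_table optional SNP-disease annotation TSV.
#' @param out_dir output directory (created if needed).
#' @param scale analysis scale for the scan.
#' @param screen_p,alpha,r2_lump,r2_merge,r2_tag,window_bp,pgain_min,
#'   max_missing_fraction,min_maf,min_hwe_p thresholds.
#' @param ggm_method edge P value mode for the GGM stage.
#' @param p95_reps subsampling repetitions for the power stage (0 skips
#'   p95 estimation).
#' @param seed master seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, variants, traits, covariates,
                            gene_map = NULL, replication = NULL,
                            disease_table = NULL, out_dir = "pqtl-out",
                            scale = "inverse-normal", screen_p = 1e-5,
                            alpha = 0.05, r2_lump = 0.1, r2_merge = 0.9,
                            r2_tag = 0.8, window_bp = 1e7,
                            pgain_min = 1e4, max_missing_fraction = 0.02,
                            min_maf = 0.01, min_hwe_p = 1e-6,
                            ggm_method = "fisher", p95_reps = 100L,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(screen_p > 0, screen_p <= 1, alpha > 0, alpha < 1,
            r2_lump >= 0, r2_lump <= 1, r2_merge >= 0, r2_merge <= 1,
            r2_tag >= 0, r2_tag <= 1, window_bp > 0, pgain_min > 0,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_maf >= 0, min_maf <= 0.5, min_hwe_p >= 0, min_hwe_p <= 1)
  for (p in c(cfg$genotypes, cfg$variants, cfg$traits, cfg$covariates,
              cfg$gene_map, cfg$disease_table, unlist(cfg$replication)))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pQTL pipeline
#'
#' Executes, in order: variant QC, the inverse-normal association scan
#' with inflation diagnostics, two-stage LD lumping into ranked loci with
#' cis/trans classification, replication with tag-SNP selection and
#' optional p95 power estimation (when a replication cohort is
#' configured), the shrinkage GGM of the trait panel, and network
#' assembly. Each stage writes a TSV/JSON output into `out_dir`, and a
#' run manifest records input hashes, thresholds, the seed and per-stage
#' row counts; rerunning with an identical configuration reproduces
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(
    seed = config$seed,
    thresholds = config[c("screen_p", "alpha", "r2_lump", "r2_merge",
                          "r2_tag", "window_bp", "pgain_min",
                          "max_missing_fraction", "min_maf", "min_hwe_p")],
    scale = config$scale, ggm_method = config$ggm_method,
    inputs = lapply(
      c(genotypes = config$genotypes, variants = config$variants,
        traits = config$traits, covariates = config$covariates),
      function(p) unname(tools::md5sum(p))))

  geno <- stage("load", read_genotypes_tsv(config$genotypes,
                                           config$variants))
  gene_map <- if (!is.null(config$gene_map))
    read_gene_map(config$gene_map)
  traits <- stage("load", read_traits_tsv(config$traits, gene_map))
  covars <- stage("load", read_covariates_tsv(config$covariates))

  # 1. QC ------------------------------------------------------------
  qc <- stage("qc", filter_variants(
    geno, max_missing_fraction = config$max_missing_fraction,
    min_maf = config$min_maf, min_hwe_p = config$min_hwe_p))
  utils::write.table(qc$report$stages, out("qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  geno <- qc$genotypes
  manifest$qc <- list(n_input = qc$report$n_input,
                      n_remaining = qc$report$n_remaining)

  # 2. scan ----------------------------------------------------------
  assoc <- stage("scan", scan_all(geno, traits, covars,
                                  scale = config$scale,
                                  screen_p = config$screen_p))
  write_assoc <- assoc
  write_assoc$p <- format(write_assoc$p, digits = 7, scientific = TRUE)
  utils::write.table(write_assoc, out("associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  infl <- stage("scan", {
    pm <- pvalue_matrix(geno, traits, covars, scale = config$scale)
    genomic_inflation(pm)
  })
  manifest$scan <- list(n_retained = nrow(assoc),
                        lambda_mean = infl$mean, lambda_max = infl$max)

  # 3. loci ----------------------------------------------------------
  loci_obj <- stage("loci", {
    sentinels <- if (nrow(assoc)) {
      do.call(rbind, lapply(split(assoc, assoc$trait_id),
        lump_per_trait, genotypes = geno, r2_min = config$r2_lump,
        window_bp = config$window_bp))
    } else {
      data.frame(variant_id = character(), chrom = character(),
                 pos = integer(), trait_id = character(), p = numeric(),
                 stringsAsFactors = FALSE)
    }
    define_loci(sentinels, geno, r2_merge = config$r2_merge,
                window_bp = config$window_bp, alpha = config$alpha,
                n_snps_tested = ncol(geno$dosage),
                n_traits_tested = ncol(traits$values))
  })
  loci_tab <- loci_obj$loci
  loci_tab <- stage("loci", annotate_cis_trans(loci_tab, traits))
  wl <- loci_tab[, setdiff(names(loci_tab), "members")]
  wl$p <- format(wl$p, digits = 7, scientific = TRUE)
  utils::write.table(wl, out("loci.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$loci <- list(n_loci = length(unique(loci_tab$locus_id)),
                        n_primary = loci_obj$n_primary_loci)

  # 4. replication ----------------------------------------------------
  if (!is.null(config$replication)) {
    repl <- stage("replication", {
      rg <- read_genotypes_tsv(config$replication$genotypes,
                               config$replication$variants)
      rt <- read_traits_tsv(config$replication$traits)
      rc <- read_covariates_tsv(config$replication$covariates)
      rc <- cbind(rc,
                  compute_pcs(rg$dosage, 3),
                  prot = compute_pcs(log(rt$values), 3))
      traits_sc <- transform_traits(traits, config$scale)
      sig <- loci_tab[loci_tab$tier != "none", , drop = FALSE]
      tags <- lapply(seq_len(nrow(sig)), function(i)
        select_tag_snp(sig$sentinel_variant[i], sig$trait_id[i], geno,
                       rg, traits_sc, covars, r2_min = config$r2_tag))
      n_att <- sum(!vapply(tags, is.null, logical(1)))
      recs <- lapply(seq_len(nrow(sig)), function(i) {
        vi <- match(sig$sentinel_variant[i], geno$variants$variant_id)
        rec <- replicate_association(
          sig$locus_id[i], sig$sentinel_variant[i], sig$trait_id[i],
          beta_discovery = if ("beta" %in% names(sig)) sig$beta[i] else NA,
          p_discovery = sig$p[i], tag = tags[[i]],
          replication_genotypes = rg, replication_traits = rt,
          replication_covariates = rc,
          discovery_alleles = c(effect = geno$variants$alt[vi],
                                other = geno$variants$ref[vi]),
          n_attempted = max(n_att, 1L), scale = config$scale)
        if (config$p95_reps >= 20) {
          rec$p95 <- estimate_p95(
            geno$dosage[, sig$sentinel_variant[i]],
            traits_sc$values[, sig$trait_id[i]], covars,
            m = min(nrow(rg$dosage), nrow(geno$dosage)),
            reps = config$p95_reps,
            seed = sub_seed(config$seed, paste0("p95-", i)))$p95
        }
        rec
      })
      if (length(recs)) do.call(rbind, recs) else
        data.frame(locus_id = integer(), sentinel_variant = character(),
                   tag_variant = character(), tag_r2 = numeric(),
                   trait_id = character(), p_discovery = numeric(),
                   p_replication = numeric(), beta_discovery = numeric(),
                   beta_replication = numeric(),
                   direction_consistent = logical(),
                   ambiguous_strand = logical(), status = character(),
                   reason = character(), stringsAsFactors = FALSE)
    })
    if (!is.null(repl)) {
      wr <- repl
      for (cc in c("p_discovery", "p_replication", "p95"))
        if (cc %in% names(wr))
          wr[[cc]] <- format(wr[[cc]], digits = 7, scientific = TRUE)
      utils::write.table(wr, out("replication.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      rsum <- summarize_replication(repl, alpha = config$alpha)
      jsonlite::write_json(unclass(rsum), out("replication_summary.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      manifest$replication <- rsum[c("n_attempted", "n_replicated",
                                     "pct_replicated")]
    }
  }

  # 5. GGM -----------------------------------------------------------
  ggm <- stage("ggm", ggm_fit(traits, covars, method = config$ggm_method,
                              alpha = config$alpha,
                              seed = sub_seed(config$seed, "ggm")))
  we <- ggm$edges
  if (nrow(we)) we$p <- format(we$p, digits = 7, scientific = TRUE)
  utils::write.table(we, out("ggm_edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(lambda = ggm$lambda, n = ggm$n,
                            n_traits = ggm$n_traits,
                            p_mode = ggm$method,
                            threshold = ggm$threshold,
                            n_imputed = ggm$n_imputed),
                       out("ggm_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$ggm <- list(lambda = ggm$lambda, n_edges = nrow(ggm$edges))

  # 6. network --------------------------------------------------------
  net <- stage("network", {
    sig <- loci_tab[loci_tab$tier != "none", , drop = FALSE]
    dis <- if (!is.null(config$disease_table))
      read_disease_table(config$disease_table)
    build_network(sig, ggm$edges, dis, genotypes = geno)
  })
  export_network(net, out("network.graphml"), "graphml")
  export_network(net, out("network.json"), "json")
  manifest$network <- list(n_nodes = igraph::vcount(net),
                           n_edges = igraph::ecount(net))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(manifest)
}

#' Annotate locus associations as cis or trans
#'
#' Adds a `cis_trans` column to a loci table using the trait gene map,
#' classifying each sentinel-trait pair by the distance rule of
#' [classify_cis_trans()].
#'
#' @param loci_tab the `loci` data.frame from [define_loci()].
#' @param traits a [trait_matrix()] whose `traits` table carries gene
#'   coordinates.
#' @param max_dist cis distance bound (default 10 Mb).
#' @return `loci_tab` with a `cis_trans` column.
#' @export
annotate_cis_trans <- function(loci_tab, traits, max_dist = 1e7) {
  ti <- match(loci_tab$trait_id, traits$traits$trait_id)
  loci_tab$cis_trans <- classify_cis_trans(
    loci_tab$chrom, loci_tab$pos,
    traits$traits$chrom[ti], traits$traits$start[ti],
    traits$traits$end[ti], max_dist = max_dist)
  loci_tab
}

# per-trait P value matrix for inflation diagnostics (variants x traits);
# same residualization shortcut as the fast scan path.
pvalue_matrix <- function(genotypes, traits, covariates = NULL,
                          scale = "inverse-normal", chunk_size = 1000L) {
  al <- align_samples(genotypes, traits, covariates)
  G <- al$geno$dosage
  tr <- if (al$traits$scale == "raw" && scale != "raw")
    transform_traits(al$traits, scale) else al$traits
  Y <- tr$values
  n <- nrow(G)
  X0 <- cbind(rep(1, n), al$covariates)
  q0 <- qr(X0)
  Yr <- qr.resid(q0, Y)
  ss_y <- colSums(Yr^2)
  df <- n - 1L - ncol(X0)
  P <- matrix(NA_real_, ncol(G), ncol(Y),
              dimnames = list(colnames(G), colnames(Y)))
  for (start in seq(1L, ncol(G), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, ncol(G))
    Gr <- qr.resid(q0, G[, idx, drop = FALSE])
    ss_g <- colSums(Gr^2)
    cross <- crossprod(Gr, Yr)
    r2 <- pmin(cross^2 / outer(ss_g, ss_y), 1 - 1e-15)
    tstat <- sqrt(df * r2 / (1 - r2))
    P[idx, ] <- 2 * stats::pt(-tstat, df)
  }
  pmax(P, .Machine$double.xmin)
}

#' Simulate and write a paired discovery/replication cohort to disk
#'
#' Generates the full synthetic fixture (genotypes as TSV dosage and VCF,
#' traits, covariates, gene map) for both cohorts plus the ground-truth
#' tables, and writes everything under `dir`.
#'
#' @param config a [sim_config()].
#' @param truth a [simulation_truth()]; defaults to an empty truth (pure
#'   null cohorts).
#' @param dir output directory.
#' @return Named list of file paths, invisibly.
#' @export
simulate_cohorts <- function(config, truth = simulation_truth(),
                             dir = "sim-cohorts") {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  disc <- simulate_genotypes(config)
  dcov <- simulate_covariates(config$n_discovery,
                              seed = sub_seed(config$seed, "covariates"),
                              sample_ids = rownames(disc$genotypes$dosage))
  dtr <- simulate_traits(disc$genotypes, truth, covariates = dcov,
                         n_traits = config$n_traits,
                         seed = sub_seed(config$seed, "traits"))
  repl <- simulate_replication_cohort(config, truth)
  paths <- list(
    discovery_dosage = p("discovery_dosage.tsv"),
    discovery_variants = p("discovery_variants.tsv"),
    discovery_vcf = p("discovery.vcf"),
    discovery_traits = p("discovery_traits.tsv"),
    discovery_covariates = p("discovery_covariates.tsv"),
    gene_map = p("gene_map.tsv"),
    replication_dosage = p("replication_dosage.tsv"),
    replication_variants = p("replication_variants.tsv"),
    replication_vcf = p("replication.vcf"),
    replication_traits = p("replication_traits.tsv"),
    replication_covariates = p("replication_covariates.tsv"),
    truth_effects = p("truth_effects.tsv"),
    truth = p("truth.json"))
  write_genotypes_tsv(disc$genotypes, paths$discovery_dosage,
                      paths$discovery_variants)
  write_vcf(disc$genotypes, paths$discovery_vcf)
  write_traits_tsv(dtr, paths$discovery_traits)
  write_covariates_tsv(dcov, paths$discovery_covariates)
  utils::write.table(dtr$traits, paths$gene_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_genotypes_tsv(repl$genotypes, paths$replication_dosage,
                      paths$replication_variants)
  write_vcf(repl$genotypes, paths$replication_vcf)
  write_traits_tsv(repl$traits, paths$replication_traits)
  write_covariates_tsv(repl$covariates, paths$replication_covariates)
  utils::write.table(truth$effects, paths$truth_effects, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config),
         covariate_betas = truth$covariate_betas,
         precision_structure = truth$precision_structure,
         clusters = repl$clusters,
         haemolysis_traits = repl$haemolysis_traits),
    paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
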
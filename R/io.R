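#' Write genotypes as TSV dosage plus variant table
#'
#' The dosage file has samples in rows (first column `sample_id`) and
#' variants in columns; missing calls are written as `NA`. The variant
#' table carries `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param dosage_path,variants_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotypes_tsv <- function(genotypes, dosage_path, variants_path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- data.frame(sample_id = rownames(genotypes$dosage),
                  genotypes$dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(genotypes$variants[, c("variant_id", "chrom", "pos",
                                            "ref", "alt")],
                     variants_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dosage_path, variants_path))
}

#' Read genotypes from TSV dosage plus variant table
#'
#' @param dosage_path,variants_path paths written by
#'   [write_genotypes_tsv()] (or equivalent: dosage values 0-2 with `NA`
#'   for missing).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(dosage_path, variants_path) {
  d <- utils::read.table(dosage_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  v <- utils::read.table(variants_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  genotype_matrix(m, v)
}

#' Write genotypes as a minimal VCF (GT fields only)
#'
#' One line per variant, GRCh-style CHROM/POS, hard genotype calls
#' (`0/0`, `0/1`, `1/1`, `./.`), ALT counted as the dosage allele.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  d <- t(genotypes$dosage)            # variants x samples
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT",
                      rownames(genotypes$dosage)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT fields into additive ALT dosages via the `vcfR` package.
#'
#' @param path VCF path.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  genotype_matrix(t(dos),
                  data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                             pos = as.integer(fix$POS), ref = fix$REF,
                             alt = fix$ALT, stringsAsFactors = FALSE))
}

#' Write / read a trait matrix as TSV
#'
#' Samples in rows, first column `sample_id`, one column per trait.
#'
#' @param traits a [trait_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traits_tsv <- function(traits, path) {
  stopifnot(inherits(traits, "trait_matrix"))
  d <- data.frame(sample_id = rownames(traits$values), traits$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits_tsv
#' @param gene_map optional gene-coordinate table (see [read_gene_map()])
#'   attached to the traits on read.
#' @param scale scale tag of the stored values.
#' @export
read_traits_tsv <- function(path, gene_map = NULL, scale = "raw") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  trait_matrix(m, gene_map, scale = scale)
}

#' Read a probe-to-gene coordinate map
#'
#' Expects columns `trait_id`, `chrom`, `start`, `end`. BED-like input
#' (0-based half-open intervals) is converted to the package's 1-based
#' inclusive convention on read.
#'
#' @param path TSV path.
#' @param zero_based `TRUE` when the file uses BED coordinates.
#' @return data.frame with 1-based inclusive `start`/`end`.
#' @export
read_gene_map <- function(path, zero_based = FALSE) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("trait_id", "chrom", "start", "end")
  if (!all(req %in% names(g)))
    stop("gene map needs columns: ", paste(req, collapse = ", "))
  g$chrom <- as.character(g$chrom)
  if (zero_based) g$start <- g$start + 1L
  g
}

#' Write / read covariates as TSV (samples in rows)
#'
#' @param covariates numeric covariate matrix with sample row names.
#' @param path file path.
#' @return `path` (write) or the covariate matrix (read).
#' @export
write_covariates_tsv <- function(covariates, path) {
  d <- data.frame(sample_id = rownames(covariates), covariates,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  m
}

#' Read a SNP-disease annotation table
#'
#' Expects columns `snp`, `disease`, `p` and optionally `source`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_disease_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "\"")
  if (!all(c("snp", "disease", "p") %in% names(d)))
    stop("disease table needs columns snp, disease, p")
  d
}
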
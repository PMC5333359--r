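#' Genotype container: additive dosages plus per-variant metadata
#'
#' Wraps a samples x variants matrix of additive allele dosages (0, 1, 2,
#' with `NA` for missing calls) together with a per-variant annotation
#' table. Minor allele frequency and call rate are computed from the
#' dosages at construction time so downstream filters always see values
#' consistent with the matrix they receive.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids); values in \{0, 1, 2\} or
#'   `NA`.
#' @param variants data.frame with one row per column of `dosage`, columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`. Row order must match the
#'   column order of `dosage`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `variants`; `variants` gains computed columns `maf` and
#'   `call_rate`.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  stopifnot(is.numeric(dosage))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variants table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop("variants table has ", nrow(variants), " rows but dosage has ",
         ncol(dosage), " columns")
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$variant_id
  if (!identical(colnames(dosage), as.character(variants$variant_id)))
    stop("dosage column names do not match variants$variant_id")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad))
    stop("dosages must be 0, 1, 2 or NA; found e.g. ", bad[[1]])
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  af <- colMeans(dosage, na.rm = TRUE) / 2
  variants$maf <- pmin(af, 1 - af)
  variants$call_rate <- colMeans(!is.na(dosage))
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x",
      ncol(x$dosage), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  cat("  MAF range: ",
      paste(signif(range(x$variants$maf), 3), collapse = " - "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x a `genotype_matrix`.
#' @param samples row (sample) index: integer, logical or character.
#' @param variants column (variant) index: integer, logical or character
#'   (variant ids).
#' @return A `genotype_matrix` restricted to the selection, with MAF and
#'   call rate recomputed on the subset.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  v <- x$variants
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$variant_id)
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  genotype_matrix(d, v[, c("variant_id", "chrom", "pos", "ref", "alt")])
}

#' Trait container: trait abundances plus gene coordinates
#'
#' Wraps a samples x traits matrix (protein or glycan abundances) together
#' with an optional per-trait gene coordinate map used for cis/trans
#' classification, and a scale tag recording which transformation the
#' values carry.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   traits in columns (colnames = trait ids).
#' @param traits optional data.frame with columns `trait_id`, `chrom`,
#'   `start`, `end` (1-based inclusive gene interval); traits without
#'   coordinates may carry `NA` and are classified as `unknown`.
#' @param scale one of `"raw"`, `"log"`, `"inverse-normal"`.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, traits = NULL,
                         scale = c("raw", "log", "inverse-normal")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("T", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(traits)) {
    traits <- data.frame(trait_id = colnames(values),
                         chrom = NA_character_,
                         start = NA_integer_, end = NA_integer_,
                         stringsAsFactors = FALSE)
  } else {
    traits <- as.data.frame(traits, stringsAsFactors = FALSE)
    if (!"trait_id" %in% names(traits)) stop("traits table needs trait_id")
    traits <- traits[match(colnames(values), traits$trait_id), , drop = FALSE]
    if (anyNA(traits$trait_id))
      stop("traits table is missing entries for some trait columns")
    for (col in c("chrom", "start", "end"))
      if (!col %in% names(traits)) traits[[col]] <- NA
    bad <- which(!is.na(traits$start) & !is.na(traits$end) &
                   traits$start > traits$end)
    if (length(bad))
      stop("malformed gene interval (start > end) for trait(s): ",
           paste(traits$trait_id[bad], collapse = ", "))
  }
  rownames(traits) <- NULL
  structure(list(values = values, traits = traits, scale = scale),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "traits (scale:", x$scale, ")\n")
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

# Align samples across genotype, trait and covariate inputs; errors list
# the identifiers that do not match so the caller can fix the input files.
align_samples <- function(geno, traits, covariates = NULL) {
  gs <- rownames(geno$dosage)
  ts <- rownames(traits$values)
  common <- intersect(gs, ts)
  if (!is.null(covariates)) common <- intersect(common, rownames(covariates))
  unmatched <- unique(c(setdiff(gs, common), setdiff(ts, common),
                        if (!is.null(covariates))
                          setdiff(rownames(covariates), common)))
  if (length(common) == 0L)
    stop("no overlapping sample identifiers; unmatched: ",
         paste(utils::head(unmatched, 10), collapse = ", "))
  if (length(unmatched))
    warning(length(unmatched), " sample(s) dropped (unmatched ids): ",
            paste(utils::head(unmatched, 10), collapse = ", "))
  list(
    geno = subset_genotypes(geno, samples = common),
    traits = trait_matrix(traits$values[common, , drop = FALSE],
                          traits$traits, scale = traits$scale),
    covariates = if (!is.null(covariates))
      as.matrix(covariates[common, , drop = FALSE])
  )
}
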
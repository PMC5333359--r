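#' Assemble the integrated SNP-protein-disease network
#'
#' Builds a typed graph from three evidence layers: pQTL edges connecting
#' sentinel SNPs to the proteins they regulate, partial-correlation edges
#' among proteins from the Gaussian graphical model, and SNP-disease
#' association edges from a user-supplied annotation table. Disease edges
#' are filtered at `p_disease_max`, reduced to unique (snp, disease) pairs
#' keeping the smallest P, optionally LD-expanded onto sentinel SNPs via
#' the genotype panel, and excluded when the "disease" is itself the
#' associated protein's level.
#'
#' @param loci_table data.frame of significant pQTL associations (columns
#'   `sentinel_variant`, `trait_id`, `p`; optional `beta`, `cis_trans`,
#'   `chrom`, `pos`) — e.g. the `loci` element of [define_loci()] output
#'   restricted to `tier != "none"`.
#' @param ggm_edges data.frame `trait_i`, `trait_j`, `pcor`, `p` (from
#'   [ggm_fit()]).
#' @param disease_table optional data.frame `snp`, `disease`, `p`,
#'   `source`.
#' @param genotypes optional [genotype_matrix()]: disease SNPs absent
#'   from the network but in LD (r2 > `r2_disease`) with a sentinel are
#'   remapped onto that sentinel.
#' @param p_disease_max disease-edge P filter (default 1e-8).
#' @param r2_disease LD threshold for disease-SNP remapping (default 0.8).
#' @param protein_genes optional named character vector mapping trait ids
#'   to gene symbols (node attribute, and used for the disease-protein
#'   exclusion rule).
#' @return An `igraph` graph of class `pqtl_network`: vertices carry
#'   `type` (`snp` / `protein` / `disease`) and `label`; edges carry
#'   `type` (`pqtl` / `partial_correlation` / `disease_association`) and
#'   the layer's statistics.
#' @export
build_network <- function(loci_table, ggm_edges = NULL,
                          disease_table = NULL, genotypes = NULL,
                          p_disease_max = 1e-8, r2_disease = 0.8,
                          protein_genes = NULL) {
  loci_table <- as.data.frame(loci_table, stringsAsFactors = FALSE)
  snps <- unique(loci_table$sentinel_variant)
  prots <- unique(c(loci_table$trait_id,
                    if (!is.null(ggm_edges)) ggm_edges$trait_i,
                    if (!is.null(ggm_edges)) ggm_edges$trait_j))
  edges <- list()
  if (nrow(loci_table))
    edges$pqtl <- data.frame(
      from = loci_table$sentinel_variant, to = loci_table$trait_id,
      type = "pqtl", p = loci_table$p,
      beta = if ("beta" %in% names(loci_table)) loci_table$beta else NA,
      cis_trans = if ("cis_trans" %in% names(loci_table))
        loci_table$cis_trans else NA_character_,
      pcor = NA_real_, source = NA_character_,
      stringsAsFactors = FALSE)
  if (!is.null(ggm_edges) && nrow(ggm_edges))
    edges$ggm <- data.frame(
      from = ggm_edges$trait_i, to = ggm_edges$trait_j,
      type = "partial_correlation", p = ggm_edges$p, beta = NA,
      cis_trans = NA_character_, pcor = ggm_edges$pcor,
      source = NA_character_, stringsAsFactors = FALSE)
  diseases <- character(0)
  if (!is.null(disease_table) && nrow(disease_table)) {
    dt <- as.data.frame(disease_table, stringsAsFactors = FALSE)
    if (!"source" %in% names(dt)) dt$source <- NA_character_
    dt <- dt[dt$p < p_disease_max, , drop = FALSE]
    # LD-expand disease SNPs onto sentinels
    if (nrow(dt) && !is.null(genotypes)) {
      unknown <- !(dt$snp %in% snps)
      for (i in which(unknown)) {
        if (!dt$snp[i] %in% colnames(genotypes$dosage)) next
        r2 <- vapply(snps, function(s)
          if (s %in% colnames(genotypes$dosage))
            tryCatch(ld_r2(genotypes$dosage[, dt$snp[i]],
                           genotypes$dosage[, s]),
                     error = function(e) NA_real_)
          else NA_real_, numeric(1))
        if (any(!is.na(r2) & r2 > r2_disease))
          dt$snp[i] <- snps[which.max(r2)]
      }
    }
    dropped <- setdiff(unique(dt$snp), snps)
    if (length(dropped)) {
      warning("disease table references SNP(s) outside the network, ",
              "dropped: ", paste(dropped, collapse = ", "))
      dt <- dt[dt$snp %in% snps, , drop = FALSE]
    }
    # exclude diseases that are the associated protein's own level
    if (nrow(dt)) {
      protein_labels <- tolower(unique(c(prots, unname(protein_genes))))
      dt <- dt[!(tolower(dt$disease) %in% protein_labels), , drop = FALSE]
    }
    # curation: unique (snp, disease) pairs, smallest P wins
    if (nrow(dt)) {
      dt <- dt[order(dt$p), , drop = FALSE]
      dt <- dt[!duplicated(dt[, c("snp", "disease")]), , drop = FALSE]
      diseases <- unique(dt$disease)
      edges$disease <- data.frame(
        from = dt$snp, to = dt$disease, type = "disease_association",
        p = dt$p, beta = NA, cis_trans = NA_character_, pcor = NA_real_,
        source = dt$source, stringsAsFactors = FALSE)
    }
  }
  nodes <- data.frame(
    name = c(snps, prots, diseases),
    type = c(rep("snp", length(snps)), rep("protein", length(prots)),
             rep("disease", length(diseases))),
    stringsAsFactors = FALSE)
  nodes$label <- nodes$name
  if (!is.null(protein_genes)) {
    hit <- match(nodes$name, names(protein_genes))
    nodes$label[!is.na(hit)] <- protein_genes[hit[!is.na(hit)]]
  }
  if ("chrom" %in% names(loci_table)) {
    si <- match(nodes$name, loci_table$sentinel_variant)
    nodes$chrom <- loci_table$chrom[si]
    nodes$pos <- loci_table$pos[si]
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(
    if (is.null(el)) data.frame(from = character(), to = character())
    else el, directed = FALSE, vertices = nodes)
  class(g) <- c("pqtl_network", class(g))
  g
}

#' @export
print.pqtl_network <- function(x, ...) {
  tt <- table(igraph::V(x)$type)
  et <- table(igraph::E(x)$type)
  cat("pqtl_network:", igraph::vcount(x), "nodes (",
      paste(names(tt), tt, collapse = ", "), "),",
      igraph::ecount(x), "edges (",
      paste(names(et), et, collapse = ", "), ")\n")
  invisible(x)
}

#' Extract the subnetwork around a query term
#'
#' Matches the query as a case-insensitive substring against node names
#' and labels, then returns the induced subgraph of all nodes within
#' `radius` edges of any matched node.
#'
#' @param graph a [build_network()] graph.
#' @param seed_term query string.
#' @param radius neighbourhood radius in edges (0 = matched nodes only).
#' @return The induced subgraph (empty, with a message, when nothing
#'   matches).
#' @export
query_subnetwork <- function(graph, seed_term, radius = 1L) {
  hits <- which(grepl(seed_term, igraph::V(graph)$name,
                      ignore.case = TRUE, fixed = FALSE) |
                grepl(seed_term, igraph::V(graph)$label,
                      ignore.case = TRUE, fixed = FALSE))
  if (!length(hits)) {
    message("no node matches '", seed_term, "'")
    sub <- igraph::induced_subgraph(graph, integer(0))
    class(sub) <- class(graph)
    return(sub)
  }
  nb <- unique(unlist(igraph::ego(graph, order = radius, nodes = hits)))
  sub <- igraph::induced_subgraph(graph, nb)
  class(sub) <- class(graph)
  sub
}

#' Export a network to GraphML, JSON node-link or edge TSV
#'
#' @param graph a [build_network()] graph.
#' @param path output file path.
#' @param format `"graphml"`, `"json"` (node-link) or `"tsv"` (flat edge
#'   list).
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path,
                           format = c("graphml", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    cg <- graph
    class(cg) <- "igraph"
    igraph::write_graph(cg, path, format = "graphml")
  } else if (format == "json") {
    nodes <- as.data.frame(igraph::vertex_attr(graph),
                           stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(graph)
    links <- cbind(data.frame(from = el[, 1], to = el[, 2],
                              stringsAsFactors = FALSE),
                   as.data.frame(igraph::edge_attr(graph),
                                 stringsAsFactors = FALSE))
    jsonlite::write_json(list(nodes = nodes, links = links), path,
                         dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    el <- igraph::as_edgelist(graph)
    out <- cbind(data.frame(from = el[, 1], to = el[, 2],
                            stringsAsFactors = FALSE),
                 as.data.frame(igraph::edge_attr(graph),
                               stringsAsFactors = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"json"`.
#' @return A `pqtl_network` igraph graph.
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  g <- if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
    links <- as.data.frame(doc$links, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(
      if (nrow(links)) links else data.frame(from = character(),
                                             to = character()),
      directed = FALSE, vertices = nodes)
  }
  class(g) <- c("pqtl_network", class(g))
  g
}
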
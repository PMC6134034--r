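#' Read and write matrices, manifests and network artifacts
#'
#' TSV readers/writers for the pipeline's carriers. Beta matrices are
#' written with full double precision (`%.17g`) so write/read round-trips
#' are exact; ids live in the first column, samples in the header.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @param check_beta validate values as beta fractions; default TRUE.
#' @return `read_beta_tsv` returns the matrix; writers return the path,
#'   invisibly.
#' @name beta_io
NULL

#' @rdname beta_io
#' @export
write_beta_tsv <- function(m, path, check_beta = TRUE) {
  if (check_beta) validate_beta_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname beta_io
#' @export
read_beta_tsv <- function(path, check_beta = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate ids in ", path, ": ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (check_beta) validate_beta_matrix(m)
  m
}

#' Read a probe manifest TSV
#' @param path manifest TSV with the standard columns.
#' @return validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("gene" %in% names(mf)) mf$gene[is.na(mf$gene)] <- ""
  validate_manifest(mf)
  mf
}

#' Read a sample/trait table TSV
#' @param path traits TSV; must contain `sample_id`, `cohort`, `group`.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "group")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trait table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tr$sample_id))
    stop("duplicate sample ids in trait table: ",
         paste(unique(tr$sample_id[duplicated(tr$sample_id)]), collapse = ", "),
         call. = FALSE)
  tr
}

#' Write DMRs as a BED file
#'
#' Converts the 1-based inclusive DMR intervals to BED's 0-based
#' half-open convention. The score column carries `-10 log10(combined_p)`
#' (capped at 3000) and the strand column encodes direction (`+` hyper,
#' `-` hypo).
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(dmrs, path) {
  score <- if (nrow(dmrs) && "combined_p" %in% names(dmrs))
    round(pmin(-10 * log10(pmax(dmrs$combined_p, 1e-300)), 3000), 1)
  else rep(0, nrow(dmrs))
  strand <- if (nrow(dmrs) && "direction" %in% names(dmrs))
    ifelse(dmrs$direction == "hyper", "+", "-") else rep(".", nrow(dmrs))
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end, name = dmrs$dmr_id, score = score,
                    strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a DMR network graph to GraphML
#'
#' Nodes carry degree, network component index, and (when a comparison is
#' supplied) the cross-cohort presence status, so the file loads directly
#' into Cytoscape-compatible viewers.
#'
#' @param g `dmr_network_graph` from [extract_networks()].
#' @param path output path.
#' @param comparison optional `dmr_network_comparison` supplying status.
#' @return the path, invisibly.
#' @export
write_graphml <- function(g, path, comparison = NULL) {
  ig <- g$graph
  igraph::V(ig)$degree <- g$nodes$degree[match(igraph::V(ig)$name,
                                               g$nodes$dmr_id)]
  comp <- g$nodes$network[match(igraph::V(ig)$name, g$nodes$dmr_id)]
  igraph::V(ig)$component <- ifelse(is.na(comp), 0L, comp)
  if (!is.null(comparison)) {
    st <- comparison$node_presence$status[
      match(igraph::V(ig)$name, comparison$node_presence$dmr_id)]
    igraph::V(ig)$status <- ifelse(is.na(st), "absent", st)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a JSON report
#' @param x list to serialize.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
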
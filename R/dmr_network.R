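#' Average topological overlap between DMR pairs
#'
#' The DMR-pair interconnectedness statistic: for two distinct DMRs A and
#' B, the arithmetic mean of `TOM_ij` over all cross pairs i in A, j in B.
#' Pairs of CpGs inside the same DMR never contribute; the diagonal is
#' masked as NA.
#'
#' @param t_mat CpG-level TOM from [tom()].
#' @param dmrs DMR data.frame with `dmr_id` and a `probe_ids` list column;
#'   probe sets must be disjoint and present in `t_mat`.
#' @return symmetric dmr x dmr matrix, diagonal NA.
#' @export
average_tom_by_dmr <- function(t_mat, dmrs) {
  check_square_named(t_mat, "TOM")
  if (!all(c("dmr_id", "probe_ids") %in% names(dmrs)))
    stop("dmrs must carry dmr_id and probe_ids", call. = FALSE)
  probes <- unlist(dmrs$probe_ids)
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("DMR probe sets overlap; shared probes: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  miss <- setdiff(probes, rownames(t_mat))
  if (length(miss))
    stop("DMR probe(s) absent from TOM: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)

  n_dmr <- nrow(dmrs)
  ind <- matrix(0, n_dmr, nrow(t_mat),
                dimnames = list(dmrs$dmr_id, rownames(t_mat)))
  for (i in seq_len(n_dmr)) ind[i, dmrs$probe_ids[[i]]] <- 1
  sums <- ind %*% t_mat %*% t(ind)
  sizes <- vapply(dmrs$probe_ids, length, integer(1))
  avg <- sums / outer(sizes, sizes)
  diag(avg) <- NA_real_
  dimnames(avg) <- list(dmrs$dmr_id, dmrs$dmr_id)
  avg
}

#' Extract DMR networks from an average-TOM matrix
#'
#' Keeps DMR pairs whose average TOM is at or above `cutoff` (inclusive)
#' and returns the connected components of the resulting graph as the DMR
#' networks, ordered by node count (ties broken by summed edge weight,
#' then by lexically smallest member id). Components need at least 2
#' nodes; isolated DMRs are reported separately.
#'
#' @param avg average-TOM matrix from [average_tom_by_dmr()].
#' @param cutoff edge threshold; default 0.15.
#' @return object of class `dmr_network_graph`: `nodes` (dmr_id, degree,
#'   network index or NA), `edges` (dmr_a, dmr_b, avg_tom), `networks`
#'   (list of member-id vectors), `isolated`, `cutoff`, and the underlying
#'   `igraph` object.
#' @export
extract_networks <- function(avg, cutoff = 0.15) {
  check_square_named(avg, "average-TOM matrix")
  ids <- rownames(avg)
  ut <- which(upper.tri(avg) & !is.na(avg) & avg >= cutoff, arr.ind = TRUE)
  edges <- data.frame(dmr_a = ids[ut[, 1]], dmr_b = ids[ut[, 2]],
                      avg_tom = avg[ut], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)

  members <- split(ids, comp$membership[ids])
  members <- members[vapply(members, length, integer(1)) >= 2]
  if (length(members)) {
    wsum <- vapply(members, function(mm) {
      sel <- edges$dmr_a %in% mm
      sum(edges$avg_tom[sel])
    }, numeric(1))
    first_id <- vapply(members, function(mm) min(mm), character(1))
    ord <- order(-vapply(members, length, integer(1)), -wsum, first_id)
    members <- members[ord]
  }
  names(members) <- if (length(members)) sprintf("network%d", seq_along(members))

  net_of <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_along(members)) net_of[members[[i]]] <- i
  nodes <- data.frame(dmr_id = ids, degree = as.integer(deg[ids]),
                      network = unname(net_of[ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, networks = members,
                 isolated = ids[deg[ids] == 0], cutoff = cutoff, graph = g),
            class = "dmr_network_graph")
}

#' @export
print.dmr_network_graph <- function(x, ...) {
  cat("DMR network graph: ", nrow(x$nodes), " DMRs, ", nrow(x$edges),
      " edges at avg-TOM >= ", x$cutoff, "\n", sep = "")
  for (i in seq_along(x$networks))
    cat(sprintf("  %s: %d DMRs\n", names(x$networks)[i],
                length(x$networks[[i]])))
  cat("  isolated:", length(x$isolated), "\n")
  invisible(x)
}

# optimal one-to-one matching of networks (rows) to reference networks
# (cols) maximizing total node overlap; exhaustive over permutations at
# the handful-of-networks scale this pipeline produces, greedy beyond.
.match_networks <- function(overlap) {
  nr <- nrow(overlap); nc <- ncol(overlap)
  k <- min(nr, nc)
  if (max(nr, nc) <= 7) {
    best <- NULL; best_val <- -1
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (p in perms(seq_len(nc))) {
      sel <- p[seq_len(k)]
      val <- sum(overlap[cbind(seq_len(k), sel)])
      if (val > best_val) { best_val <- val; best <- sel }
    }
    stats::setNames(best, rownames(overlap)[seq_len(k)])
  } else {
    used <- integer(0); out <- integer(0)
    for (i in order(-apply(overlap, 1, max))[seq_len(k)]) {
      cand <- order(-overlap[i, ])
      cand <- cand[!cand %in% used][1]
      used <- c(used, cand); out[rownames(overlap)[i]] <- cand
    }
    out
  }
}

#' Compare DMR networks across cohorts
#'
#' Records, for every DMR node, which cohorts' thresholded graphs contain
#' it (as a network member), matches networks across cohorts by maximal
#' node overlap against the first cohort's networks, and reports the
#' common node set per matched network. Nodes present in every cohort get
#' status `present_in_all`; nodes present in all disease cohorts but not
#' in a cohort named `"control"` get `disease_only`; the rest `partial`.
#'
#' @param graphs_by_cohort named list (>= 2) of `dmr_network_graph`
#'   objects sharing a DMR-id namespace.
#' @return object of class `dmr_network_comparison`: `node_presence`
#'   data.frame (dmr_id, per-cohort logicals, status), `matched`
#'   data.frame of network matches, `common` list of common-node sets per
#'   reference network.
#' @export
compare_networks <- function(graphs_by_cohort) {
  if (length(graphs_by_cohort) < 2)
    stop("need graphs from at least 2 cohorts", call. = FALSE)
  if (is.null(names(graphs_by_cohort)))
    names(graphs_by_cohort) <- sprintf("cohort%d", seq_along(graphs_by_cohort))
  node_sets <- lapply(graphs_by_cohort, function(g) g$nodes$dmr_id)
  share <- FALSE
  for (i in seq_along(node_sets)) for (j in seq_along(node_sets))
    if (i < j && length(intersect(node_sets[[i]], node_sets[[j]]))) share <- TRUE
  if (!share)
    stop("cohorts share no DMR ids: disjoint namespaces", call. = FALSE)

  cohorts <- names(graphs_by_cohort)
  disease <- setdiff(cohorts, "control")
  all_ids <- sort(unique(unlist(node_sets)))
  in_net <- vapply(graphs_by_cohort, function(g) {
    member <- g$nodes$dmr_id[!is.na(g$nodes$network)]
    all_ids %in% member
  }, logical(length(all_ids)))
  rownames(in_net) <- all_ids

  status <- apply(in_net, 1, function(row) {
    if (all(row)) "present_in_all"
    else if (all(row[disease]) && "control" %in% cohorts && !row["control"])
      "disease_only"
    else "partial"
  })
  node_presence <- data.frame(dmr_id = all_ids, in_net, status = status,
                              row.names = NULL, stringsAsFactors = FALSE)

  ref <- cohorts[1]
  ref_nets <- graphs_by_cohort[[ref]]$networks
  matched <- list(); common <- list()
  if (length(ref_nets)) {
    common <- lapply(ref_nets, identity)
    for (co in cohorts[-1]) {
      nets <- graphs_by_cohort[[co]]$networks
      if (!length(nets)) { common <- lapply(common, function(x) character(0)); next }
      overlap <- vapply(nets, function(b)
        vapply(ref_nets, function(a) length(intersect(a, b)), numeric(1)),
        numeric(length(ref_nets)))
      overlap <- matrix(overlap, nrow = length(ref_nets),
                        dimnames = list(names(ref_nets), names(nets)))
      assign_cols <- .match_networks(overlap)
      for (i in seq_along(ref_nets)) {
        rn <- names(ref_nets)[i]
        j <- assign_cols[rn]
        if (is.na(j) || is.null(j)) {
          common[[rn]] <- character(0)
        } else {
          common[[rn]] <- intersect(common[[rn]], nets[[j]])
          matched[[length(matched) + 1L]] <- data.frame(
            reference_network = rn, cohort = co,
            cohort_network = names(nets)[j],
            n_overlap = overlap[rn, j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(
    node_presence = node_presence,
    matched = if (length(matched)) do.call(rbind, matched) else NULL,
    common = common,
    cohorts = cohorts
  ), class = "dmr_network_comparison")
}

#' @export
print.dmr_network_comparison <- function(x, ...) {
  cat("DMR network comparison across cohorts:",
      paste(x$cohorts, collapse = ", "), "\n")
  print(table(x$node_presence$status))
  for (rn in names(x$common))
    cat(sprintf("  %s: %d common DMRs\n", rn, length(x$common[[rn]])))
  invisible(x)
}

#' TOM percentiles over a node subset
#'
#' The 25th, 50th and 75th percentiles of the upper-triangle TOM values
#' among the given nodes, using the linear-interpolation percentile
#' definition. When a probe-to-DMR map is supplied, pairs of probes
#' belonging to the same DMR are excluded (matching the convention that
#' within-DMR overlap is not part of the between-DMR statistic).
#'
#' @param t_mat TOM matrix.
#' @param node_subset character vector of node ids, length >= 2.
#' @param dmr_map optional named vector probe id -> DMR id.
#' @return named numeric vector `c(p25, p50, p75)`.
#' @export
tom_percentiles <- function(t_mat, node_subset, dmr_map = NULL) {
  check_square_named(t_mat, "TOM")
  node_subset <- as.character(node_subset)
  if (length(node_subset) < 2)
    stop("node subset must contain at least 2 nodes", call. = FALSE)
  miss <- setdiff(node_subset, rownames(t_mat))
  if (length(miss))
    stop("subset node(s) absent from TOM: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  sub <- t_mat[node_subset, node_subset]
  keep <- upper.tri(sub)
  if (!is.null(dmr_map)) {
    d <- dmr_map[node_subset]
    same <- outer(d, d, `==`)
    same[is.na(same)] <- FALSE
    keep <- keep & !same
  }
  vals <- sub[keep]
  if (!length(vals))
    stop("no eligible node pairs after exclusions", call. = FALSE)
  q <- stats::quantile(vals, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  stats::setNames(q, c("p25", "p50", "p75"))
}
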
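#' Soft-thresholded co-methylation adjacency
#'
#' Builds the weighted-network adjacency over CpG probes: the absolute
#' Pearson correlation between the methylation profiles of every probe
#' pair, raised to the soft-threshold power (an unsigned network,
#' `|PCC|^beta`). Correlations use pairwise-complete observations; probe
#' pairs with fewer than 4 complete observations, and any pair involving a
#' zero-variance probe, get adjacency 0 and are flagged.
#'
#' @param m beta matrix restricted to the CpGs of interest (probes x
#'   samples); at least 4 samples.
#' @param beta_power soft threshold, >= 1.
#' @return symmetric matrix in \[0, 1\] with zero diagonal; attributes
#'   `beta_power` and `flagged` (data.frame of zeroed pairs, if any).
#' @export
adjacency <- function(m, beta_power) {
  validate_beta_matrix(m)
  if (ncol(m) < 4) stop("adjacency needs at least 4 samples", call. = FALSE)
  if (beta_power < 1) stop_config("beta_power", "must be >= 1")

  suppressWarnings(r <- stats::cor(t(m), use = "pairwise.complete.obs"))
  obs <- !is.na(m)
  n_pair <- obs %*% t(obs)
  few <- n_pair < 4
  bad <- is.na(r) | few
  diag(bad) <- FALSE
  flagged <- NULL
  if (any(bad)) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    flagged <- data.frame(probe_a = rownames(m)[idx[, 1]],
                          probe_b = rownames(m)[idx[, 2]],
                          reason = ifelse(few[idx], "few_complete_pairs",
                                          "zero_variance"),
                          stringsAsFactors = FALSE)
    r[bad] <- 0
  }
  a <- abs(r)^beta_power
  diag(a) <- 0
  dimnames(a) <- list(rownames(m), rownames(m))
  attr(a, "beta_power") <- beta_power
  attr(a, "flagged") <- flagged
  a
}

#' Scale-free topology fit index of an adjacency matrix
#'
#' Connectivity `k_i = sum_j a_ij` is discretized into `n_bins`
#' equal-width bins over its range; `log10` of each non-empty bin's node
#' frequency is regressed on `log10` of the bin's mean connectivity. The
#' fit index is the signed `-sign(slope) * R^2` of that regression
#' (standard scale-free-topology convention: the frequency of nodes must
#' decrease with connectivity, so only negative-slope fits count as
#' scale-free).
#'
#' @param a adjacency matrix.
#' @param n_bins number of connectivity bins; default 10.
#' @return list: `fit_index` (signed), `r_squared` (unsigned), `slope`,
#'   `mean_k`. Indices are NA when the fit is undefined (e.g. all-zero
#'   adjacency or a single occupied bin).
#' @export
scale_free_fit <- function(a, n_bins = 10) {
  k <- rowSums(a)
  mean_k <- mean(k)
  na_out <- list(fit_index = NA_real_, r_squared = NA_real_,
                 slope = NA_real_, mean_k = mean_k)
  if (all(k == 0) || length(unique(k)) == 1) return(na_out)
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  dk <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(freq)
  x <- log10(dk[keep]); y <- log10(freq[keep])
  if (length(x) < 2 || stats::sd(x) == 0) return(na_out)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit_index = -sign(slope) * r2, r_squared = r2, slope = slope,
       mean_k = mean_k)
}

#' Choose the soft-threshold power by scale-free fit
#'
#' Scans candidate powers and picks the smallest at which the network
#' exhibits scale-free topology with fit index R^2 above `r2_threshold`
#' (0.70 by default). A candidate additionally needs mean connectivity of
#' at least `min_mean_k`: at extreme powers any network degenerates to a
#' near-empty graph whose few surviving edges mimic a scale-free tail, so
#' fits on such graphs are not accepted. If no candidate qualifies, the
#' chosen power is `NA` and the scan carries a warning flag; callers
#' should then inspect the scan table.
#'
#' @param m beta matrix restricted to the CpGs of interest.
#' @param candidates ascending integer powers to scan; default 1:20.
#' @param r2_threshold scale-free fit R^2 requirement; default 0.70.
#' @param n_bins connectivity bins for the fit index; default 10.
#' @param min_mean_k minimal mean connectivity for a power to qualify;
#'   default 1.
#' @return object of class `soft_threshold_scan`: data.frame `scan`
#'   (power, r_squared, slope, mean_k), `chosen` (power or NA),
#'   `r2_threshold`, `no_qualifier` flag.
#' @export
pick_soft_threshold <- function(m, candidates = 1:20, r2_threshold = 0.70,
                                n_bins = 10, min_mean_k = 1) {
  if (!length(candidates) || is.unsorted(candidates, strictly = TRUE))
    stop_config("candidates", "must be non-empty strictly ascending")
  rows <- lapply(candidates, function(b) {
    f <- scale_free_fit(adjacency(m, b), n_bins = n_bins)
    data.frame(power = b, fit_index = f$fit_index, r_squared = f$r_squared,
               slope = f$slope, mean_k = f$mean_k)
  })
  scan <- do.call(rbind, rows)
  ok <- which(!is.na(scan$fit_index) & scan$fit_index > r2_threshold &
                scan$mean_k >= min_mean_k)
  chosen <- if (length(ok)) scan$power[ok[1]] else NA_integer_
  if (is.na(chosen))
    warning("no candidate power reached scale-free fit R^2 > ", r2_threshold,
            call. = FALSE)
  structure(list(scan = scan, chosen = chosen, r2_threshold = r2_threshold,
                 no_qualifier = is.na(chosen)),
            class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (scale-free fit R^2 > ", x$r2_threshold, ")\n",
      sep = "")
  print(x$scan, row.names = FALSE)
  if (x$no_qualifier) cat("No qualifying power.\n")
  else cat("Chosen power:", x$chosen, "\n")
  invisible(x)
}

#' Topological overlap matrix
#'
#' Unsigned topological overlap of a weighted network:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` and connectivity `k_i = sum_u a_iu`
#' (the adjacency has zero diagonal, so self terms never contribute).
#' The diagonal is set to 1 by convention; a fully isolated pair gets 0.
#'
#' @param a adjacency matrix from [adjacency()].
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
tom <- function(a) {
  check_square_named(a, "adjacency")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  t_mat <- (L + a) / denom
  t_mat[denom == 0] <- 0
  diag(t_mat) <- 1
  attributes(t_mat) <- list(dim = dim(a),
                            dimnames = list(rownames(a), colnames(a)))
  t_mat
}

#' Detect CpG modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`
#' with a static tree cut: the dendrogram is cut at `cut_height`, clusters
#' below `min_module_size` are sent to grey (unassigned), and the
#' remaining clusters are labeled with the size-ordered colour palette
#' (turquoise, blue, brown, yellow, ...).
#'
#' @param t_mat TOM from [tom()].
#' @param cut_height static cut height on 1 - TOM; default 0.99.
#' @param min_module_size smallest cluster kept as a module; default 10.
#' @return named character vector: node id -> module colour.
#' @export
detect_modules <- function(t_mat, cut_height = 0.99, min_module_size = 10) {
  check_square_named(t_mat, "TOM")
  nodes <- rownames(t_mat)
  if (nrow(t_mat) < 3) {
    warning("fewer than 3 nodes: all assigned grey", call. = FALSE)
    return(stats::setNames(rep("grey", length(nodes)), nodes))
  }
  hc <- stats::hclust(stats::as.dist(1 - t_mat), method = "average")
  # average linkage can produce tiny height inversions under tied
  # dissimilarities; a monotone envelope keeps the static cut well defined
  hc$height <- cummax(hc$height)
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # size order, ties broken by first appearance for determinism
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  palette <- module_palette()
  labels <- stats::setNames(rep("grey", length(nodes)), nodes)
  for (i in seq_along(keep)) {
    col <- if (i <= length(palette)) palette[i] else sprintf("module%d", i)
    labels[cl == as.integer(keep[i])] <- col
  }
  labels
}
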
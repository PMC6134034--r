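#' Correlate probe methylation with clinical traits
#'
#' Pearson correlation of each probe's methylation profile with each
#' numeric trait over pairwise-complete samples, with a two-sided
#' t-distributed p-value and BH adjustment within each trait. Constant
#' probes or traits give an undefined correlation (r reported as NA with a
#' flag).
#'
#' @param m beta matrix (probes x samples).
#' @param samples sample table with `sample_id` matching the columns of `m`.
#' @param traits character vector of numeric trait columns in `samples`.
#' @return data.frame: probe_id, trait, r, n, p, q, undefined.
#' @export
correlate_methylation_traits <- function(m, samples, traits) {
  validate_beta_matrix(m)
  if (!all(colnames(m) %in% samples$sample_id))
    stop("sample table does not cover all beta-matrix samples", call. = FALSE)
  s <- samples[match(colnames(m), samples$sample_id), ]
  miss <- setdiff(traits, names(s))
  if (length(miss))
    stop_config("traits", paste("unknown trait(s):", paste(miss, collapse = ", ")))

  out <- list()
  for (tr in traits) {
    y <- as.numeric(s[[tr]])
    res <- .cor_rows(m, y)
    res$trait <- tr
    res$q <- NA_real_
    ok <- !res$undefined
    res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
    out[[tr]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("probe_id", "trait", "r", "n", "p", "q", "undefined")]
}

# Pearson r of every row of m against y, pairwise-complete, with t-test p.
.cor_rows <- function(m, y) {
  r <- rep(NA_real_, nrow(m)); n <- integer(nrow(m)); p <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    ok <- !is.na(x) & !is.na(y)
    n[i] <- sum(ok)
    if (n[i] < 4) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    r[i] <- stats::cor(x[ok], y[ok])
    tt <- r[i] * sqrt((n[i] - 2) / max(1 - r[i]^2, .Machine$double.eps))
    p[i] <- 2 * stats::pt(-abs(tt), n[i] - 2)
  }
  data.frame(probe_id = rownames(m), r = r, n = n, p = p,
             undefined = is.na(r), stringsAsFactors = FALSE)
}

#' Correlate DMR methylation with annotated gene expression
#'
#' Summarizes each DMR as the unweighted mean beta of its member probes
#' per sample and correlates that profile with the expression of the
#' DMR's annotated gene(s) over matched samples. DMRs whose annotated
#' gene is absent from the expression matrix are reported with status
#' `"not_available"` rather than raising an error.
#'
#' @param m beta matrix (probes x samples).
#' @param dmrs DMR data.frame with `dmr_id` and `probe_ids` list column.
#' @param expr gene x sample expression matrix (pre-normalized).
#' @param dmr_gene_map named list or vector mapping dmr_id -> gene id(s).
#' @param q_threshold BH threshold for the direction label; default 0.05.
#' @return data.frame: dmr_id, gene, r, n, p, q, direction
#'   ("negative"/"positive"/"NS"/"not_available").
#' @export
correlate_methylation_expression <- function(m, dmrs, expr, dmr_gene_map,
                                             q_threshold = 0.05) {
  validate_beta_matrix(m)
  shared <- intersect(colnames(m), colnames(expr))
  if (length(shared) < 4)
    stop("fewer than 4 samples shared between methylation and expression",
         call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(dmrs))) {
    id <- dmrs$dmr_id[i]
    genes <- unlist(dmr_gene_map[[id]])
    if (is.null(genes) || !length(genes) || all(genes == "")) next
    meth <- colMeans(m[dmrs$probe_ids[[i]], shared, drop = FALSE])
    for (g in genes) {
      if (!g %in% rownames(expr)) {
        rows[[length(rows) + 1L]] <- data.frame(
          dmr_id = id, gene = g, r = NA_real_, n = NA_integer_,
          p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      e <- expr[g, shared]
      ok <- !is.na(meth) & !is.na(e)
      n <- sum(ok)
      if (n < 4 || stats::sd(meth[ok]) == 0 || stats::sd(e[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          dmr_id = id, gene = g, r = NA_real_, n = n, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      r <- stats::cor(meth[ok], e[ok])
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      rows[[length(rows) + 1L]] <- data.frame(
        dmr_id = id, gene = g, r = r, n = n,
        p = 2 * stats::pt(-abs(tt), n - 2), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(dmr_id = character(0), gene = character(0),
                      r = numeric(0), n = integer(0), p = numeric(0),
                      q = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$direction <- ifelse(!ok, "not_available",
                    ifelse(out$q > q_threshold, "NS",
                      ifelse(out$r < 0, "negative", "positive")))
  rownames(out) <- NULL
  out
}

#' Fisher-z fixed-effect meta-analysis of correlation coefficients
#'
#' Pools per-cohort Pearson correlations by inverse-variance weighting of
#' the Fisher transform `z = atanh(r)` with variance `1/(n - 3)`, and
#' back-transforms the pooled z. Cochran's Q tests heterogeneity. A
#' random-effects (DerSimonian-Laird) estimate is also reported when
#' requested; the fixed-effect estimate is the primary one.
#'
#' @param r vector of per-cohort correlations, each `|r| < 1`.
#' @param n vector of per-cohort sample sizes, each >= 4.
#' @param random also compute the DerSimonian-Laird random-effects pooled
#'   r; default FALSE.
#' @return list: `r_pooled`, `z_pooled`, `se_z`, `p` (two-sided),
#'   `ci_lower`, `ci_upper` (95%), `Q`, `Q_df`, `Q_p`, `per_cohort`
#'   data.frame, and optionally `r_random`.
#' @export
meta_correlation <- function(r, n, random = FALSE) {
  if (length(r) != length(n) || !length(r))
    stop("r and n must be equal-length, non-empty", call. = FALSE)
  if (any(abs(r) >= 1))
    stop("|r| = 1 cannot be pooled (infinite Fisher z)", call. = FALSE)
  if (any(n < 4)) stop("each cohort needs n >= 4", call. = FALSE)
  z <- atanh(r)
  w <- n - 3
  z_pool <- sum(w * z) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (z - z_pool)^2)
  k <- length(r)
  out <- list(
    r_pooled = tanh(z_pool),
    z_pooled = z_pool,
    se_z = se,
    p = 2 * stats::pnorm(-abs(z_pool / se)),
    ci_lower = tanh(z_pool - 1.96 * se),
    ci_upper = tanh(z_pool + 1.96 * se),
    Q = Q, Q_df = k - 1,
    Q_p = if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_,
    per_cohort = data.frame(r = r, n = n, z = z, weight = w)
  )
  if (random) {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (1 / w + tau2)
    out$r_random <- tanh(sum(wr * z) / sum(wr))
    out$tau2 <- tau2
  }
  out
}

#' Compare clinical traits between two groups
#'
#' Welch t-tests for numeric traits and Fisher's exact test for two-level
#' categorical traits between two sample groups (mild vs advanced by
#' default), the standard clinical-table comparison.
#'
#' @param samples sample table with a `group` column.
#' @param numeric_traits columns to t-test; defaults to all numeric
#'   columns except ids.
#' @param categorical_traits columns to Fisher-test.
#' @param groups the two group labels to compare; default mild/advanced.
#' @return data.frame: trait, test, estimate_group1, estimate_group2, p.
#' @export
compare_clinical_groups <- function(samples,
                                    numeric_traits = NULL,
                                    categorical_traits = NULL,
                                    groups = c("mild", "advanced")) {
  g1 <- samples[samples$group == groups[1], , drop = FALSE]
  g2 <- samples[samples$group == groups[2], , drop = FALSE]
  if (!nrow(g1) || !nrow(g2))
    stop("both groups must be non-empty (", groups[1], ": ", nrow(g1),
         ", ", groups[2], ": ", nrow(g2), ")", call. = FALSE)
  if (is.null(numeric_traits)) {
    cand <- setdiff(names(samples), c("sample_id", "cohort", "group"))
    numeric_traits <- cand[vapply(samples[cand], is.numeric, logical(1))]
  }
  rows <- list()
  for (tr in numeric_traits) {
    x <- g1[[tr]]; y <- g2[[tr]]
    p <- if (stats::sd(x, na.rm = TRUE) == 0 && stats::sd(y, na.rm = TRUE) == 0)
      1 else stats::t.test(x, y)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, test = "welch_t",
      estimate_group1 = mean(x, na.rm = TRUE),
      estimate_group2 = mean(y, na.rm = TRUE),
      p = p, stringsAsFactors = FALSE)
  }
  for (tr in categorical_traits) {
    tab <- table(factor(samples$group[samples$group %in% groups],
                        levels = groups),
                 samples[[tr]][samples$group %in% groups])
    p <- if (all(dim(tab) == c(2, 2))) stats::fisher.test(tab)$p.value
         else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, test = "fisher_exact",
      estimate_group1 = NA_real_, estimate_group2 = NA_real_,
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
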
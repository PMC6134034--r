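#' Per-probe differential methylation tests
#'
#' Welch (unequal-variance) t-test on beta values for every probe between
#' two groups. The effect `delta` is mean(level 2) - mean(level 1) of
#' `levels`, i.e. advanced minus mild under the defaults. Probes with zero
#' variance in both groups cannot be tested; they are flagged and given
#' p = 1 when the group means agree (p = 0 when they differ exactly).
#'
#' @param m beta matrix (probes x samples).
#' @param groups character/factor vector along columns of `m` with two
#'   levels of interest.
#' @param levels length-2 vector naming the reference and the comparison
#'   group, in that order; default `c("mild", "advanced")`.
#' @return data.frame: probe_id, delta, t, df, p, zero_variance.
#' @export
probe_tests <- function(m, groups, levels = c("mild", "advanced")) {
  validate_beta_matrix(m)
  if (length(groups) != ncol(m))
    stop("groups must align with the columns of the beta matrix", call. = FALSE)
  i1 <- which(groups == levels[1]); i2 <- which(groups == levels[2])
  if (length(i1) < 3 || length(i2) < 3)
    stop("each group needs at least 3 samples (got ",
         length(i1), " and ", length(i2), ")", call. = FALSE)

  x1 <- m[, i1, drop = FALSE]; x2 <- m[, i2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1, stats::var, na.rm = TRUE)
  delta <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  tval <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tval), df)

  zv <- v1 == 0 & v2 == 0
  if (any(zv)) {
    p[zv] <- ifelse(delta[zv] == 0, 1, 0)
    tval[zv] <- ifelse(delta[zv] == 0, 0, Inf * sign(delta[zv]))
    df[zv] <- NA_real_
  }
  data.frame(probe_id = rownames(m), delta = delta, t = tval, df = df,
             p = p, zero_variance = zv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially methylated regions from probe-level tests
#'
#' A lasso-radius region caller: probe p-values are BH-adjusted and probes
#' significant at `probe_alpha` are chained along each chromosome whenever
#' the gap to the next significant probe is at most `lasso_radius` bp.
#' Chains with at least `min_probes` members become candidate DMRs; member
#' p-values are combined by Stouffer's method (equal weights, signed by
#' the direction of the probe effect), the combined p-values are BH-
#' adjusted across candidates, and regions surviving `region_alpha` are
#' returned sorted by position.
#'
#' @param tests output of [probe_tests()].
#' @param manifest probe manifest covering the tested probes.
#' @param probe_alpha BH-adjusted probe-level significance level; default 0.05.
#' @param lasso_radius maximal neighbor gap in bp within a region; default 1000.
#' @param min_probes minimal member count per DMR; default 3.
#' @param region_alpha BH-adjusted region-level significance level; default 0.05.
#' @return data.frame of DMRs: dmr_id, chrom, start, end (1-based
#'   inclusive), n_probes, direction ("hyper"/"hypo"), mean_delta,
#'   combined_p, combined_q, and a `probe_ids` list column (position order).
#' @export
call_dmrs <- function(tests, manifest, probe_alpha = 0.05,
                      lasso_radius = 1000, min_probes = 3,
                      region_alpha = 0.05) {
  validate_manifest(manifest)
  empty <- data.frame(dmr_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), direction = character(0),
                      mean_delta = numeric(0), combined_p = numeric(0),
                      combined_q = numeric(0), stringsAsFactors = FALSE)
  empty$probe_ids <- list()
  if (nrow(tests) == 0) return(empty)
  miss <- setdiff(tests$probe_id, manifest$probe_id)
  if (length(miss))
    stop("data-integrity error: manifest missing probe(s): ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)

  tests$q <- stats::p.adjust(tests$p, method = "BH")
  sig <- tests[tests$q <= probe_alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)

  mf <- manifest[match(sig$probe_id, manifest$probe_id), ]
  ord <- order(mf$chrom, mf$pos)
  sig <- sig[ord, ]; mf <- mf[ord, ]

  # chain consecutive significant probes within lasso_radius per chromosome
  new_chain <- c(TRUE, mf$chrom[-1] != mf$chrom[-nrow(mf)] |
                   diff(mf$pos) > lasso_radius)
  chain_id <- cumsum(new_chain)

  rows <- list()
  for (cid in unique(chain_id)) {
    idx <- which(chain_id == cid)
    if (length(idx) < min_probes) next
    p_mem <- pmax(sig$p[idx], 1e-300)
    z <- sign(sig$delta[idx]) * stats::qnorm(1 - p_mem / 2)
    Z <- sum(z) / sqrt(length(z))
    comb_p <- 2 * stats::pnorm(-abs(Z))
    md <- mean(sig$delta[idx])
    rows[[length(rows) + 1L]] <- list(
      chrom = mf$chrom[idx[1]],
      start = min(mf$pos[idx]), end = max(mf$pos[idx]),
      n_probes = length(idx),
      direction = if (md >= 0) "hyper" else "hypo",
      mean_delta = md, combined_p = comb_p,
      probe_ids = sig$probe_id[idx])
  }
  if (!length(rows)) return(empty)

  out <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    n_probes = vapply(rows, `[[`, integer(1), "n_probes"),
    direction = vapply(rows, `[[`, character(1), "direction"),
    mean_delta = vapply(rows, `[[`, numeric(1), "mean_delta"),
    combined_p = vapply(rows, `[[`, numeric(1), "combined_p"),
    stringsAsFactors = FALSE)
  out$combined_q <- stats::p.adjust(out$combined_p, method = "BH")
  out$probe_ids <- lapply(rows, `[[`, "probe_ids")
  out <- out[out$combined_q <= region_alpha, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$dmr_id <- sprintf("DMR_%s_%d", out$chrom, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("dmr_id", "chrom", "start", "end", "n_probes", "direction",
          "mean_delta", "combined_p", "combined_q", "probe_ids")]
}

#' Consensus DMRs across cohorts
#'
#' Returns regions where every cohort called a DMR and the called
#' intervals mutually overlap by at least 1 bp. Overlapping intervals are
#' merged to their union; member probe sets are unioned; the provenance
#' (per-cohort member DMR ids) is recorded in a list column.
#'
#' @param dmrs_by_cohort named list (>= 2 cohorts) of DMR data.frames as
#'   returned by [call_dmrs()]. If a data.frame carries a `genome`
#'   attribute, all cohorts must agree on it.
#' @return data.frame of consensus DMRs with `probe_ids` and `provenance`
#'   list columns.
#' @export
consensus_dmrs <- function(dmrs_by_cohort) {
  if (length(dmrs_by_cohort) < 2)
    stop("need DMR calls from at least 2 cohorts", call. = FALSE)
  genomes <- unique(unlist(lapply(dmrs_by_cohort, attr, "genome")))
  if (length(genomes) > 1)
    stop("cohorts are on different genome builds: ",
         paste(genomes, collapse = " vs "), call. = FALSE)
  if (is.null(names(dmrs_by_cohort)))
    names(dmrs_by_cohort) <- sprintf("cohort%d", seq_along(dmrs_by_cohort))

  pooled <- do.call(rbind, lapply(names(dmrs_by_cohort), function(co) {
    d <- dmrs_by_cohort[[co]]
    if (nrow(d) == 0) return(NULL)
    data.frame(cohort = co, dmr_id = d$dmr_id, chrom = d$chrom,
               start = d$start, end = d$end, row = seq_len(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(dmr_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), stringsAsFactors = FALSE)
  empty$probe_ids <- list(); empty$provenance <- list()
  if (is.null(pooled) || nrow(pooled) == 0) return(empty)

  out_rows <- list()
  for (ch in unique(pooled$chrom)) {
    px <- pooled[pooled$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = px$start, end = px$end)
    cl <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, cl)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (g in unique(grp)) {
      members <- px[grp == g, , drop = FALSE]
      if (!setequal(unique(members$cohort), names(dmrs_by_cohort))) next
      probes <- unique(unlist(lapply(seq_len(nrow(members)), function(i) {
        d <- dmrs_by_cohort[[members$cohort[i]]]
        d$probe_ids[[members$row[i]]]
      })))
      prov <- split(members$dmr_id, members$cohort)
      out_rows[[length(out_rows) + 1L]] <- list(
        chrom = ch, start = min(members$start), end = max(members$end),
        probe_ids = probes, provenance = prov)
    }
  }
  if (!length(out_rows)) return(empty)
  out <- data.frame(
    chrom = vapply(out_rows, `[[`, character(1), "chrom"),
    start = vapply(out_rows, `[[`, numeric(1), "start"),
    end = vapply(out_rows, `[[`, numeric(1), "end"),
    stringsAsFactors = FALSE)
  out$n_probes <- vapply(out_rows, function(r) length(r$probe_ids), integer(1))
  out$probe_ids <- lapply(out_rows, `[[`, "probe_ids")
  out$provenance <- lapply(out_rows, `[[`, "provenance")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$dmr_id <- sprintf("cDMR_%s_%d", out$chrom, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("dmr_id", "chrom", "start", "end", "n_probes", "probe_ids",
          "provenance")]
}
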
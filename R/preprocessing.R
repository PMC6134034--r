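#' Apply probe-exclusion rules to a beta matrix
#'
#' Removes probes failing any of the standard 450K quality rules: detection
#' p-value above `detection_p_threshold` in more than `max_failed_samples`
#' samples (strictly more; the default reproduces the "more than one
#' sample" convention), bead count below `bead_min` in at least
#' `bead_fail_fraction` of samples (at least, i.e. `>= ceiling(fraction *
#' n_samples)` samples), SNP-overlapping probes, and cross-reactive probes
#' (both taken from manifest flags). A probe failing several rules is
#' counted under each rule it fails but removed once. Rules whose inputs
#' (`detection_p`, `bead_counts`) are absent are skipped and noted.
#'
#' @param m beta matrix (probes x samples, rownames/colnames set).
#' @param manifest probe manifest covering every probe in `m`.
#' @param detection_p optional matrix of detection p-values, same shape as `m`.
#' @param bead_counts optional integer matrix of bead counts, same shape as `m`.
#' @param detection_p_threshold detection p-value cutoff, in (0, 1); default 0.05.
#' @param max_failed_samples tolerated detection failures per probe; default 1.
#' @param bead_min minimum bead count; default 3.
#' @param bead_fail_fraction fraction of samples at which low bead count
#'   excludes a probe; default 0.05.
#' @return list with `beta` (filtered matrix, input probe order preserved)
#'   and `report` (per-rule exclusion counts, skipped rules, totals).
#' @export
filter_probes <- function(m, manifest,
                          detection_p = NULL, bead_counts = NULL,
                          detection_p_threshold = 0.05,
                          max_failed_samples = 1L,
                          bead_min = 3L,
                          bead_fail_fraction = 0.05) {
  validate_beta_matrix(m)
  validate_manifest(manifest)
  if (detection_p_threshold <= 0 || detection_p_threshold >= 1)
    stop_config("detection_p_threshold", "must lie in (0, 1)")
  if (bead_fail_fraction <= 0 || bead_fail_fraction > 1)
    stop_config("bead_fail_fraction", "must lie in (0, 1]")
  missing_probes <- setdiff(rownames(m), manifest$probe_id)
  if (length(missing_probes))
    stop("data-integrity error: manifest missing probe(s): ",
         paste(utils::head(missing_probes, 10), collapse = ", "), call. = FALSE)

  probes <- rownames(m)
  mf <- manifest[match(probes, manifest$probe_id), ]
  skipped <- character(0)

  fail_detection <- rep(FALSE, length(probes))
  if (!is.null(detection_p)) {
    stopifnot(identical(dim(detection_p), dim(m)))
    fail_detection <- rowSums(detection_p > detection_p_threshold) > max_failed_samples
  } else skipped <- c(skipped, "detection_p")

  fail_beads <- rep(FALSE, length(probes))
  if (!is.null(bead_counts)) {
    stopifnot(identical(dim(bead_counts), dim(m)))
    need <- ceiling(bead_fail_fraction * ncol(m))
    fail_beads <- rowSums(bead_counts < bead_min) >= need
  } else skipped <- c(skipped, "bead_counts")

  fail_snp <- as.logical(mf$is_snp_probe)
  fail_xr <- as.logical(mf$is_cross_reactive)
  fail_any <- fail_detection | fail_beads | fail_snp | fail_xr

  report <- list(
    n_input = length(probes),
    n_removed = sum(fail_any),
    n_surviving = sum(!fail_any),
    removed_by_rule = list(
      detection_p = sum(fail_detection),
      bead_count = sum(fail_beads),
      snp_probe = sum(fail_snp),
      cross_reactive = sum(fail_xr)
    ),
    rules_skipped = skipped,
    parameters = list(detection_p_threshold = detection_p_threshold,
                      max_failed_samples = max_failed_samples,
                      bead_min = bead_min,
                      bead_fail_fraction = bead_fail_fraction)
  )
  list(beta = m[!fail_any, , drop = FALSE], report = report)
}

#' Quantile-normalize a beta matrix across samples
#'
#' Simple full quantile normalization: every sample's sorted value vector
#' is replaced by the cross-sample mean quantile vector, so all columns
#' share an identical distribution. Offered as an optional light-weight
#' normalizer for pipelines whose input has not already been normalized
#' upstream (the pipeline otherwise accepts pre-normalized beta values).
#'
#' @param m beta matrix without missing values.
#' @return normalized beta matrix, same dimnames, values in \[0, 1\].
#' @export
quantile_normalize <- function(m) {
  validate_beta_matrix(m, allow_na = FALSE)
  if (anyNA(m))
    stop("quantile_normalize requires complete data: impute or skip", call. = FALSE)
  ranks <- apply(m, 2, rank, ties.method = "first")
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(ranks, 2, function(r) ref[r])
  dimnames(out) <- dimnames(m)
  out
}
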
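#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in `%s`: %s", field, msg), call. = FALSE)
}

#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions with
#' probe ids as rownames and sample ids as colnames. Values must lie in
#' \[0, 1\]; missing values are allowed (they are handled pairwise in the
#' correlation stages).
#'
#' @param m numeric matrix, probes x samples.
#' @param allow_na logical; permit missing values.
#' @return `m`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(m, allow_na = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("beta matrix must be a numeric matrix (probes x samples)", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("beta matrix must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe ids in beta matrix: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in beta matrix: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  vals <- m[!is.na(m)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("beta values outside [0, 1]", call. = FALSE)
  if (!allow_na && anyNA(m))
    stop("missing beta values are not allowed here", call. = FALSE)
  invisible(m)
}

#' Validate a probe manifest
#'
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based), `gene`, `feature`, `is_snp_probe`, `is_cross_reactive`.
#' @return the manifest, invisibly.
#' @export
validate_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "gene", "feature",
            "is_snp_probe", "is_cross_reactive")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("probe manifest missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$probe_id))
    stop("duplicate probe id in manifest: ",
         paste(unique(manifest$probe_id[duplicated(manifest$probe_id)]),
               collapse = ", "), call. = FALSE)
  if (any(manifest$pos < 1))
    stop("manifest positions must be >= 1 (1-based coordinates)", call. = FALSE)
  invisible(manifest)
}

# Check a square symmetric matrix with named dimnames; used by the network
# stages.
check_square_named <- function(x, what) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(what, " must be a square matrix", call. = FALSE)
  if (is.null(rownames(x)) || !identical(rownames(x), colnames(x)))
    stop(what, " must have identical row and column names", call. = FALSE)
  invisible(x)
}

# Module colour palette in size order, WGCNA-like convention; grey is
# reserved for unassigned nodes.
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}
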
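#' Simulation configuration for multi-cohort methylation data
#'
#' Builds and validates the configuration for [simulate_cohorts()]. The
#' generator emulates the structure of a multi-cohort 450K-style study:
#' two (or more) disease cohorts each split into mild and advanced groups,
#' an optional control cohort, a background of independent CpG probes, and
#' two planted DMR networks driven by latent co-methylation factors that
#' are in turn coupled to clinical traits (fibrosis stage, age, fasting
#' plasma glucose).
#'
#' Signal is composed on the logit scale and squashed back to (0, 1), so
#' beta values never need hard clipping. `dmr_effect_delta` and `noise_sd`
#' are expressed on the beta scale (they are converted to the logit scale
#' using the local slope at each probe's baseline level).
#'
#' @param n_samples_per_group samples per (cohort, group); default 30.
#' @param n_cohorts number of disease cohorts; default 2.
#' @param include_control add a control cohort (single group, zero group
#'   effect, network-2 loading attenuated); default TRUE.
#' @param control_attenuation multiplier on the network-2 loading in the
#'   control cohort; default 0.2.
#' @param n_probes_background count of unplanted independent probes.
#' @param n_dmrs_per_network planted DMRs in each of the two networks.
#' @param probes_per_dmr length-2 integer range of CpGs per planted DMR.
#' @param dmr_effect_delta beta-scale group difference in \[0, 0.5\].
#' @param network_loading latent-factor loading in \[0, 1\].
#' @param noise_sd beta-scale Gaussian noise sd.
#' @param trait_couplings named list mapping a numeric trait name to a
#'   length-2 vector of correlations with the two latent network factors.
#'   Fibrosis stage is handled separately (an ordinal discretization of
#'   factor 2) and must not appear here.
#' @param simulate_expression also emit a gene x sample expression matrix
#'   with expression anti-correlated to planted-DMR methylation.
#' @param seed integer seed; all randomness flows from this single seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples_per_group = 30,
                              n_cohorts = 2,
                              include_control = TRUE,
                              control_attenuation = 0.2,
                              n_probes_background = 500,
                              n_dmrs_per_network = 10,
                              probes_per_dmr = c(3L, 5L),
                              dmr_effect_delta = 0.2,
                              network_loading = 0.9,
                              noise_sd = 0.02,
                              trait_couplings = list(
                                age = c(0.5, 0.5),
                                fasting_glucose = c(0.2, 0.6)
                              ),
                              simulate_expression = TRUE,
                              seed = 1L) {
  if (n_samples_per_group < 1) stop_config("n_samples_per_group", "must be positive")
  if (n_cohorts < 1) stop_config("n_cohorts", "must be positive")
  if (n_probes_background < 0) stop_config("n_probes_background", "must be non-negative")
  if (n_dmrs_per_network < 1) stop_config("n_dmrs_per_network", "must be positive")
  if (length(probes_per_dmr) != 2 || any(probes_per_dmr < 2))
    stop_config("probes_per_dmr", "must be a range with minimum >= 2 (a DMR needs multiple consecutive CpGs)")
  if (probes_per_dmr[1] > probes_per_dmr[2])
    stop_config("probes_per_dmr", "range must be non-decreasing")
  if (dmr_effect_delta < 0 || dmr_effect_delta > 0.5)
    stop_config("dmr_effect_delta", "must lie in [0, 0.5]")
  if (network_loading < 0 || network_loading > 1)
    stop_config("network_loading", "must lie in [0, 1]")
  if (noise_sd <= 0) stop_config("noise_sd", "must be positive")
  if (length(trait_couplings)) {
    if (is.null(names(trait_couplings)) || any(names(trait_couplings) == ""))
      stop_config("trait_couplings", "traits must be named")
    if ("fibrosis_stage" %in% names(trait_couplings))
      stop_config("trait_couplings", "fibrosis_stage is generated from latent factor 2, not via couplings")
    ok <- vapply(trait_couplings, function(w)
      length(w) == 2 && all(abs(w) <= 1), logical(1))
    if (!all(ok))
      stop_config("trait_couplings",
                  paste0("each coupling must be a length-2 vector in [-1, 1]; offending trait: ",
                         paste(names(trait_couplings)[!ok], collapse = ", ")))
  }
  structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_cohorts = as.integer(n_cohorts),
    include_control = isTRUE(include_control),
    control_attenuation = control_attenuation,
    n_probes_background = as.integer(n_probes_background),
    n_dmrs_per_network = as.integer(n_dmrs_per_network),
    probes_per_dmr = as.integer(probes_per_dmr),
    dmr_effect_delta = dmr_effect_delta,
    network_loading = network_loading,
    noise_sd = noise_sd,
    trait_couplings = trait_couplings,
    simulate_expression = isTRUE(simulate_expression),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# beta-scale group difference delta at baseline b0, expressed as a logit
# shift symmetric around b0.
.delta_logit <- function(b0, delta) {
  lo <- pmax(b0 - delta / 2, 1e-3)
  hi <- pmin(b0 + delta / 2, 1 - 1e-3)
  stats::qlogis(hi) - stats::qlogis(lo)
}

# convert a beta-scale sd to logit scale via the local slope 1/(b0 (1-b0))
.sd_logit <- function(b0, sd_beta) sd_beta / (b0 * (1 - b0))

#' Simulate multi-cohort beta-value datasets with planted DMR networks
#'
#' Generates one beta matrix per cohort over a shared probe manifest,
#' together with a sample table (group labels and traits) and the ground
#' truth of the planted structure. Two DMR networks are planted: each
#' planted DMR is a run of consecutive CpGs (inter-probe gap <= 500 bp)
#' whose logit-scale signal combines a per-probe baseline, a group effect
#' of magnitude `dmr_effect_delta` (beta scale) in the DMR's direction,
#' and `network_loading` times the DMR's network latent factor. Background
#' probes carry independent noise only. Traits are generated from the
#' latent factors: fibrosis stage is an ordinal discretization of factor 2
#' (mild samples get stages 0-2, advanced 3-4), other traits are linear in
#' the factors plus Gaussian noise per `trait_couplings`. In the control
#' cohort the group effect is zero and the network-2 loading is attenuated,
#' so network 2 should not replicate there.
#'
#' @param config a [simulation_config()].
#' @return a list with class `dmr_simulation`:
#'   `beta` (named list of cohort beta matrices), `manifest` (probe
#'   manifest data.frame), `samples` (sample table over all cohorts),
#'   `expression` (named list of gene x sample matrices, or NULL), and
#'   `truth` (list: `dmr_intervals` data.frame with `probe_ids` list
#'   column, `latent_factors` per cohort, `trait_table`).
#' @export
simulate_cohorts <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_config("config", "must be built with simulation_config()")
  set.seed(config$seed)

  n_net <- 2L
  n_dmr <- n_net * config$n_dmrs_per_network
  dmr_net <- rep(seq_len(n_net), each = config$n_dmrs_per_network)
  size_range <- seq(config$probes_per_dmr[1], config$probes_per_dmr[2])
  dmr_size <- if (length(size_range) == 1) rep(size_range, n_dmr) else
    sample(size_range, n_dmr, replace = TRUE)
  dmr_dir <- sample(c(1, -1), n_dmr, replace = TRUE)

  # manifest: planted DMRs laid head-to-tail on chr1, 10 kb apart, probes
  # 100-400 bp apart (within the 500 bp consecutive-CpG convention);
  # background probes on chr2 at 500 bp spacing.
  probe_rows <- list()
  cursor <- 1000L
  for (d in seq_len(n_dmr)) {
    gaps <- sample(100:400, dmr_size[d], replace = TRUE)
    pos <- cursor + cumsum(gaps)
    ids <- sprintf("cgP%02d_%02d", d, seq_len(dmr_size[d]))
    probe_rows[[d]] <- data.frame(
      probe_id = ids, chrom = "chr1", pos = pos,
      gene = sprintf("GENE%02d", d), feature = "gene_body",
      is_snp_probe = FALSE, is_cross_reactive = FALSE,
      stringsAsFactors = FALSE)
    cursor <- pos[length(pos)] + 10000L
  }
  planted <- do.call(rbind, probe_rows)
  bg <- if (config$n_probes_background > 0) data.frame(
    probe_id = sprintf("cgB%05d", seq_len(config$n_probes_background)),
    chrom = "chr2",
    pos = 1000L + 500L * seq_len(config$n_probes_background),
    gene = "", feature = "intergenic",
    is_snp_probe = FALSE, is_cross_reactive = FALSE,
    stringsAsFactors = FALSE) else NULL
  manifest <- rbind(planted, bg)
  validate_manifest(manifest)

  # per-probe baseline methylation, shared across cohorts so planted DMRs
  # replicate at the same loci
  b0 <- stats::setNames(numeric(nrow(manifest)), manifest$probe_id)
  b0[planted$probe_id] <- stats::runif(nrow(planted), 0.3, 0.7)
  if (!is.null(bg)) b0[bg$probe_id] <- stats::runif(nrow(bg), 0.05, 0.95)

  cohorts <- c(sprintf("cohort%d", seq_len(config$n_cohorts)),
               if (config$include_control) "control")
  beta <- list(); expr <- list(); factors <- list(); sample_rows <- list()
  n <- config$n_samples_per_group

  for (co in cohorts) {
    is_control <- identical(co, "control")
    if (is_control) {
      groups <- rep("control", n)
    } else {
      groups <- rep(c("mild", "advanced"), each = n)
    }
    ns <- length(groups)
    sid <- sprintf("%s_s%02d", co, seq_len(ns))
    adv <- as.numeric(groups == "advanced")

    # latent factors are group-independent; fibrosis stage tracks factor 2
    # through the within-group ordinal mapping below, so the group effect
    # on planted probes stays exactly dmr_effect_delta
    f <- cbind(stats::rnorm(ns), stats::rnorm(ns))
    loading <- rep(config$network_loading, n_net)
    if (is_control) loading[2] <- loading[2] * config$control_attenuation

    vals <- matrix(NA_real_, nrow(manifest), ns,
                   dimnames = list(manifest$probe_id, sid))
    for (d in seq_len(n_dmr)) {
      ids <- probe_rows[[d]]$probe_id
      w <- dmr_net[d]
      for (p in ids) {
        base <- stats::qlogis(b0[[p]])
        eff <- if (is_control) 0 else dmr_dir[d] * .delta_logit(b0[[p]], config$dmr_effect_delta) * adv
        fac <- dmr_dir[d] * loading[w] * f[, w] * .sd_logit(b0[[p]], 0.15)
        eps <- stats::rnorm(ns, 0, .sd_logit(b0[[p]], config$noise_sd))
        vals[p, ] <- stats::plogis(base + eff + fac + eps)
      }
    }
    if (!is.null(bg)) {
      for (p in bg$probe_id) {
        eps <- stats::rnorm(ns, 0, .sd_logit(b0[[p]], config$noise_sd))
        vals[p, ] <- stats::plogis(stats::qlogis(b0[[p]]) + eps)
      }
    }

    # traits
    fib <- integer(ns)
    if (is_control) {
      fib[] <- 0L
    } else {
      mild_i <- which(groups == "mild"); adv_i <- which(groups == "advanced")
      fib[mild_i] <- as.integer(cut(rank(f[mild_i, 2], ties.method = "first"),
                                    breaks = 3, labels = FALSE)) - 1L
      fib[adv_i] <- 3L + as.integer(rank(f[adv_i, 2], ties.method = "first") >
                                      length(adv_i) / 2)
    }
    tr <- data.frame(sample_id = sid, cohort = co, group = groups,
                     fibrosis_stage = fib, stringsAsFactors = FALSE)
    for (tn in names(config$trait_couplings)) {
      w <- config$trait_couplings[[tn]]
      resid <- sqrt(max(0, 1 - sum(w^2)))
      z <- f %*% w + stats::rnorm(ns, 0, resid)
      tr[[tn]] <- switch(tn,
        age = round(52 + 11 * z),
        fasting_glucose = round(102 + 22 * z, 1),
        as.numeric(z))
    }
    tr$sex <- sample(c("F", "M"), ns, replace = TRUE)
    tr$type2_diabetes <- stats::rbinom(ns, 1, stats::plogis(-1 + 1.2 * adv)) == 1

    if (config$simulate_expression) {
      genes <- sprintf("GENE%02d", seq_len(n_dmr))
      ex <- matrix(NA_real_, n_dmr, ns, dimnames = list(genes, sid))
      for (d in seq_len(n_dmr)) {
        meth <- colMeans(vals[probe_rows[[d]]$probe_id, , drop = FALSE])
        z <- as.numeric(scale(meth))
        ex[d, ] <- 8 - 1.5 * z + stats::rnorm(ns, 0, 0.5)
      }
      expr[[co]] <- ex
    }

    beta[[co]] <- vals
    rownames(f) <- sid
    colnames(f) <- c("factor_net1", "factor_net2")
    factors[[co]] <- f
    sample_rows[[co]] <- tr
  }

  dmr_intervals <- data.frame(
    dmr_id = sprintf("DMR%02d", seq_len(n_dmr)),
    chrom = "chr1",
    start = vapply(probe_rows, function(x) min(x$pos), numeric(1)),
    end = vapply(probe_rows, function(x) max(x$pos), numeric(1)),
    network = dmr_net,
    direction = ifelse(dmr_dir > 0, "hyper", "hypo"),
    gene = sprintf("GENE%02d", seq_len(n_dmr)),
    stringsAsFactors = FALSE)
  dmr_intervals$probe_ids <- lapply(probe_rows, `[[`, "probe_id")

  samples <- do.call(rbind, sample_rows)
  rownames(samples) <- NULL

  structure(list(
    beta = beta,
    manifest = manifest,
    samples = samples,
    expression = if (config$simulate_expression) expr else NULL,
    truth = list(dmr_intervals = dmr_intervals,
                 latent_factors = factors,
                 trait_table = samples),
    config = config
  ), class = "dmr_simulation")
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits one beta-matrix TSV per cohort, the probe manifest TSV, the
#' sample/trait TSV, expression TSVs when present, the ground truth as
#' JSON, and the configuration as YAML. Re-reading the TSVs round-trips
#' values to full double precision.
#'
#' @param dataset a `dmr_simulation` from [simulate_cohorts()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a data.frame manifest of written files (kind, path).
#' @export
write_fixture <- function(dataset, out_dir) {
  if (!inherits(dataset, "dmr_simulation") || !length(dataset$beta))
    stop("empty or invalid dataset: nothing to write", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  files <- list()
  for (co in names(dataset$beta)) {
    p <- file.path(out_dir, sprintf("beta_%s.tsv", co))
    write_beta_tsv(dataset$beta[[co]], p)
    files[[length(files) + 1L]] <- c("beta", p)
  }
  p <- file.path(out_dir, "manifest.tsv")
  utils::write.table(dataset$manifest, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files[[length(files) + 1L]] <- c("manifest", p)
  p <- file.path(out_dir, "traits.tsv")
  utils::write.table(dataset$samples, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files[[length(files) + 1L]] <- c("traits", p)
  if (!is.null(dataset$expression)) {
    for (co in names(dataset$expression)) {
      p <- file.path(out_dir, sprintf("expression_%s.tsv", co))
      write_beta_tsv(dataset$expression[[co]], p, check_beta = FALSE)
      files[[length(files) + 1L]] <- c("expression", p)
    }
  }
  truth <- dataset$truth
  truth$latent_factors <- lapply(truth$latent_factors, function(m)
    as.data.frame(m))
  p <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, p, digits = NA, dataframe = "columns")
  files[[length(files) + 1L]] <- c("ground_truth", p)
  p <- file.path(out_dir, "config.yaml")
  cfg <- unclass(dataset$config)
  cfg$trait_couplings <- lapply(cfg$trait_couplings, as.numeric)
  yaml::write_yaml(cfg, p)
  files[[length(files) + 1L]] <- c("config", p)

  out <- data.frame(kind = vapply(files, `[`, character(1), 1),
                    path = vapply(files, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
  invisible(out)
}
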
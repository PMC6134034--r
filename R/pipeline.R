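#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end DMR-network pipeline
#' with defaults matching the published analysis constants (detection
#' p-value 0.05 in more than one sample; bead count < 3 in at least 5% of
#' samples; scale-free fit R^2 > 0.70; average-TOM cutoff 0.15).
#' Serializes losslessly to and from YAML.
#'
#' @param input_dir directory of fixture TSVs (as written by
#'   [write_fixture()]); may be NULL when a dataset is passed to
#'   [run_all()] directly.
#' @param output_dir where artifacts are written; default `tempdir()` subdir.
#' @param detection_p_threshold,max_failed_samples,bead_min,bead_fail_fraction
#'   probe-filter parameters, see [filter_probes()].
#' @param probe_alpha,lasso_radius,min_probes,region_alpha DMR-caller
#'   parameters, see [call_dmrs()].
#' @param beta_grid candidate soft-threshold powers; default 1:20.
#' @param r2_threshold scale-free fit requirement; default 0.70.
#' @param fallback_power power used when no candidate reaches the fit
#'   threshold; default 6.
#' @param avg_tom_cutoff DMR-network edge threshold; default 0.15.
#' @param cut_height,min_module_size module-detection parameters.
#' @param traits numeric traits to correlate with CpG methylation.
#' @param seed integer seed recorded in the run manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            output_dir = file.path(tempdir(), "dmrnet_run"),
                            detection_p_threshold = 0.05,
                            max_failed_samples = 1L,
                            bead_min = 3L,
                            bead_fail_fraction = 0.05,
                            probe_alpha = 0.05,
                            lasso_radius = 1000,
                            min_probes = 3,
                            region_alpha = 0.05,
                            beta_grid = 1:20,
                            r2_threshold = 0.70,
                            fallback_power = 6,
                            avg_tom_cutoff = 0.15,
                            cut_height = 0.99,
                            min_module_size = 10,
                            traits = c("fibrosis_stage", "age",
                                       "fasting_glucose"),
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              detection_p_threshold = detection_p_threshold,
              max_failed_samples = as.integer(max_failed_samples),
              bead_min = as.integer(bead_min),
              bead_fail_fraction = bead_fail_fraction,
              probe_alpha = probe_alpha, lasso_radius = lasso_radius,
              min_probes = min_probes, region_alpha = region_alpha,
              beta_grid = as.integer(beta_grid),
              r2_threshold = r2_threshold,
              fallback_power = as.integer(fallback_power),
              avg_tom_cutoff = avg_tom_cutoff,
              cut_height = cut_height,
              min_module_size = as.integer(min_module_size),
              traits = traits, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[dmrnet] %-14s %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full DMR-network pipeline
#'
#' Executes filter -> per-cohort DMR calling (or accepts provided DMRs)
#' -> cross-cohort consensus -> per-cohort co-methylation network
#' (soft-threshold scan, adjacency, TOM, modules) -> DMR-level average
#' TOM -> thresholded network extraction -> cross-cohort comparison ->
#' trait correlation with Fisher-z meta-analysis (and expression
#' correlation when expression is available), then writes all artifacts
#' plus a JSON run manifest.
#'
#' Disease cohorts (groups mild/advanced) drive DMR calling; a cohort
#' named `"control"` skips calling but gets the full network analysis
#' over the consensus CpGs, allowing replication checks against controls.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional `dmr_simulation` (bypasses `input_dir`).
#' @param dmrs optional precomputed DMR table (skips calling/consensus).
#' @return invisibly, a list: `results` (all in-memory stage outputs) and
#'   `manifest` (the run manifest, also written as JSON).
#' @export
run_all <- function(config, dataset = NULL, dmrs = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config", "must be built with pipeline_config()")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  # ingest
  inputs <- .stage("ingest", {
    if (!is.null(dataset)) {
      list(beta = dataset$beta, manifest = dataset$manifest,
           samples = dataset$samples, expression = dataset$expression)
    } else {
      if (is.null(config$input_dir))
        stop("neither a dataset nor input_dir supplied")
      files <- list.files(config$input_dir, "^beta_.*\\.tsv$",
                          full.names = TRUE)
      if (!length(files)) stop("no beta_*.tsv found in input_dir")
      beta <- lapply(files, read_beta_tsv)
      names(beta) <- sub("^beta_(.*)\\.tsv$", "\\1", basename(files))
      efiles <- list.files(config$input_dir, "^expression_.*\\.tsv$",
                           full.names = TRUE)
      expr <- if (length(efiles)) {
        e <- lapply(efiles, read_beta_tsv, check_beta = FALSE)
        names(e) <- sub("^expression_(.*)\\.tsv$", "\\1", basename(efiles))
        e
      }
      list(beta = beta,
           manifest = read_manifest(file.path(config$input_dir, "manifest.tsv")),
           samples = read_traits(file.path(config$input_dir, "traits.tsv")),
           expression = expr)
    }
  })
  cohorts <- names(inputs$beta)
  disease <- setdiff(cohorts, "control")
  if (!length(disease)) stop("no disease cohorts found", call. = FALSE)

  # probe filtering
  filtered <- .stage("filter", lapply(inputs$beta, function(b)
    filter_probes(b, inputs$manifest,
                  detection_p_threshold = config$detection_p_threshold,
                  max_failed_samples = config$max_failed_samples,
                  bead_min = config$bead_min,
                  bead_fail_fraction = config$bead_fail_fraction)))
  beta_f <- lapply(filtered, `[[`, "beta")

  # DMR calling per disease cohort + consensus
  if (is.null(dmrs)) {
    calls <- .stage("call_dmrs", lapply(disease, function(co) {
      s <- inputs$samples[inputs$samples$cohort == co, ]
      groups <- s$group[match(colnames(beta_f[[co]]), s$sample_id)]
      tests <- probe_tests(beta_f[[co]], groups)
      call_dmrs(tests, inputs$manifest,
                probe_alpha = config$probe_alpha,
                lasso_radius = config$lasso_radius,
                min_probes = config$min_probes,
                region_alpha = config$region_alpha)
    }))
    names(calls) <- disease
    dmrs <- .stage("consensus", if (length(disease) > 1)
      consensus_dmrs(calls) else calls[[1]])
  } else calls <- NULL
  if (nrow(dmrs) == 0)
    stop("stage `consensus` failed: no DMRs to analyze", call. = FALSE)

  # per-cohort co-methylation network over consensus DMR CpGs
  network <- .stage("network", lapply(cohorts, function(co) {
    probes <- intersect(unlist(dmrs$probe_ids), rownames(beta_f[[co]]))
    sub <- beta_f[[co]][probes, , drop = FALSE]
    scan <- suppressWarnings(
      pick_soft_threshold(sub, candidates = config$beta_grid,
                          r2_threshold = config$r2_threshold))
    power <- if (scan$no_qualifier) config$fallback_power else scan$chosen
    a <- adjacency(sub, power)
    t_mat <- tom(a)
    modules <- detect_modules(t_mat, cut_height = config$cut_height,
                              min_module_size = config$min_module_size)
    keep <- dmrs[vapply(dmrs$probe_ids, function(p) all(p %in% probes),
                        logical(1)), , drop = FALSE]
    avg <- average_tom_by_dmr(t_mat, keep)
    graph <- extract_networks(avg, cutoff = config$avg_tom_cutoff)
    list(scan = scan, power = power, tom = t_mat, modules = modules,
         avg_tom = avg, graph = graph)
  }))
  names(network) <- cohorts

  comparison <- .stage("compare", if (length(cohorts) > 1)
    compare_networks(lapply(network, `[[`, "graph")) else NULL)

  # trait correlations per disease cohort, meta-analyzed across cohorts
  traits_res <- .stage("traits", {
    per_cohort <- lapply(disease, function(co) {
      probes <- intersect(unlist(dmrs$probe_ids), rownames(beta_f[[co]]))
      correlate_methylation_traits(beta_f[[co]][probes, , drop = FALSE],
                                   inputs$samples, config$traits)
    })
    names(per_cohort) <- disease
    meta <- NULL
    if (length(disease) > 1) {
      key0 <- paste(per_cohort[[1]]$probe_id, per_cohort[[1]]$trait)
      rows <- lapply(seq_along(key0), function(i) {
        rs <- vapply(per_cohort, function(pc) pc$r[i], numeric(1))
        ns <- vapply(per_cohort, function(pc) pc$n[i], numeric(1))
        ok <- !is.na(rs) & ns >= 4 & abs(rs) < 1
        if (sum(ok) < 2) return(NULL)
        mc <- meta_correlation(rs[ok], ns[ok])
        data.frame(probe_id = per_cohort[[1]]$probe_id[i],
                   trait = per_cohort[[1]]$trait[i],
                   r_pooled = mc$r_pooled, p = mc$p, Q = mc$Q,
                   stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) {
        meta <- do.call(rbind, rows)
        meta$q <- stats::p.adjust(meta$p, method = "BH")
      }
    }
    clinical <- lapply(disease, function(co)
      compare_clinical_groups(inputs$samples[inputs$samples$cohort == co, ],
                              categorical_traits = c("sex", "type2_diabetes")))
    names(clinical) <- disease
    expr_res <- NULL
    if (!is.null(inputs$expression) && "gene" %in% names(inputs$manifest)) {
      gene_map <- lapply(seq_len(nrow(dmrs)), function(i) {
        g <- unique(inputs$manifest$gene[
          match(dmrs$probe_ids[[i]], inputs$manifest$probe_id)])
        g[g != ""]
      })
      names(gene_map) <- dmrs$dmr_id
      expr_res <- lapply(disease, function(co)
        correlate_methylation_expression(beta_f[[co]], dmrs,
                                         inputs$expression[[co]], gene_map))
      names(expr_res) <- disease
    }
    list(per_cohort = per_cohort, meta = meta, clinical = clinical,
         expression = expr_res)
  })

  # artifacts
  out <- config$output_dir
  .stage("write", {
    write_bed(dmrs, file.path(out, "dmrs.bed"))
    flat <- dmrs[, setdiff(names(dmrs), c("probe_ids", "provenance"))]
    flat$probe_ids <- vapply(dmrs$probe_ids, paste, character(1),
                             collapse = ";")
    utils::write.table(flat, file.path(out, "dmrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (co in cohorts) {
      utils::write.table(network[[co]]$graph$edges,
                         file.path(out, sprintf("edges_%s.tsv", co)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_graphml(network[[co]]$graph,
                    file.path(out, sprintf("network_%s.graphml", co)),
                    comparison = comparison)
    }
    if (!is.null(comparison))
      write_report(list(
        node_presence = comparison$node_presence,
        common = lapply(comparison$common, identity)),
        file.path(out, "comparison.json"))
    if (!is.null(traits_res$meta))
      utils::write.table(traits_res$meta, file.path(out, "trait_meta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    NULL
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("dmrnet")),
    parameters = unclass(config),
    cohorts = cohorts,
    counts = list(
      probes_input = vapply(filtered, function(f) f$report$n_input, numeric(1)),
      probes_surviving = vapply(filtered, function(f) f$report$n_surviving,
                                numeric(1)),
      dmrs = nrow(dmrs),
      dmr_cpgs = length(unlist(dmrs$probe_ids)),
      chosen_power = vapply(network, `[[`, numeric(1), "power"),
      n_networks = vapply(network, function(x) length(x$graph$networks),
                          numeric(1)),
      network_sizes = lapply(network, function(x)
        vapply(x$graph$networks, length, integer(1)))
    )
  )
  write_report(manifest, file.path(out, "run_manifest.json"))

  invisible(list(results = list(inputs = inputs, filtered = filtered,
                                calls = calls, dmrs = dmrs,
                                network = network, comparison = comparison,
                                traits = traits_res),
                 manifest = manifest))
}
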
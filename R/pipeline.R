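#' Pipeline run configuration
#'
#' Single configuration object for the staged analysis. Defaults mirror the
#' study parameters: interpolation `k = 5`, band width 1 visit, symmetric2
#' step pattern with absolute local distance, 3 retained factors, 500
#' bootstrap resamples, 200 stability splits.
#'
#' @param input Path to a long-layout panel CSV, or `NULL` when simulating.
#' @param simulate A [simulation_config()] (used when `input` is `NULL`).
#' @param k Interpolation density per visit gap.
#' @param band_width Band half-width in visit units.
#' @param metric Local distance, `"absolute"` or `"squared"`.
#' @param n_factors Retained compromise factors.
#' @param k_max Largest candidate cluster count for the elbow.
#' @param bootstrap_B Bootstrap resamples for the factor envelopes.
#' @param n_splits Random splits for the stability stage.
#' @param seed Integer seed for every stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, simulate = simulation_config(),
                       k = 5, band_width = 1,
                       metric = c("absolute", "squared"),
                       n_factors = 3, k_max = 10, bootstrap_B = 500,
                       n_splits = 200, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(k >= 0, band_width >= 0, n_factors >= 1, k_max >= 3,
            bootstrap_B >= 1, n_splits >= 1)
  if (is.null(input) && is.null(simulate)) {
    stop("provide an input path or a simulate block")
  }
  structure(list(input = input, simulate = simulate, k = k,
                 band_width = band_width, metric = metric,
                 n_factors = n_factors, k_max = k_max,
                 bootstrap_B = bootstrap_B, n_splits = n_splits,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML mirrors the [run_config()] arguments; a nested `simulate` block
#' mirrors [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  config_from_list(y)
}

config_from_list <- function(y) {
  if (length(y$input) == 0) y$input <- NULL
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    s$symptoms <- NULL
    if (!is.null(s$leadlag_pairs)) {
      s$leadlag_pairs <- lapply(s$leadlag_pairs, as.list)
    }
    sim <- do.call(simulation_config, s)
  }
  y$simulate <- NULL
  do.call(run_config, c(y, list(simulate = sim)))
}

#' Run the staged symptom-dynamics pipeline
#'
#' Chains the stages simulate -> dtw -> distatis -> cluster -> network ->
#' stability, writing each stage's artifacts under `outdir` and, on
#' success, a machine-readable `manifest.json` (parameters, seed, package
#' version, input digest). A `RUNNING` marker guards against mistaking a
#' partial run for a finished one; it is removed when the manifest is
#' written. With a fixed seed, two runs produce byte-identical numeric
#' outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @param stages Subset of
#'   `c("simulate", "dtw", "distatis", "cluster", "network", "stability")`
#'   or `"all"`; later stages require the earlier ones in the same call.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "dtw", "distatis", "cluster", "network",
                  "stability")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(outdir, "RUNNING")
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path)) file.remove(manifest_path)
  file.create(marker)
  res <- list()

  # -- input ---------------------------------------------------------------
  if (!is.null(config$input)) {
    panel <- read_panel(config$input, layout = "long")
    input_path <- config$input
  } else {
    if (!"simulate" %in% stages) stop("missing input: no panel and no simulate stage")
    gen <- generate_panel(config$simulate)
    panel <- gen$panel
    res$truth <- gen$truth
    input_path <- file.path(outdir, "panel.csv")
    write_panel(panel, input_path, layout = "long")
    truth <- gen$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  panel <- filter_complete(panel)
  res$panel <- panel

  if ("dtw" %in% stages) {
    res$matrices <- cohort_matrices(panel, band_width = config$band_width,
                                    k = config$k, metric = config$metric)
    write_matrices(res$matrices, file.path(outdir, "matrices"))
  }

  if ("distatis" %in% stages) {
    if (is.null(res$matrices)) stop("distatis stage requires the dtw stage")
    cps <- lapply(res$matrices, function(m) to_crossproduct(m$symmetric))
    comp <- distatis_compromise(cps, n_factors = config$n_factors)
    boot <- bootstrap_envelopes(cps, B = config$bootstrap_B,
                                seed = config$seed, reference = comp)
    res$compromise <- comp
    res$bootstrap <- boot
    fs <- factor_scores(comp)
    tab <- data.frame(symptom = rownames(fs), fs,
                      check.names = FALSE, row.names = NULL)
    for (f in colnames(fs)) {
      tab[[paste0(f, "_lo")]] <- boot$lower[, f]
      tab[[paste0(f, "_hi")]] <- boot$upper[, f]
    }
    utils::write.csv(tab, file.path(outdir, "factor_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patient = names(comp$weights),
                                weight = unname(comp$weights)),
                     file.path(outdir, "weights.csv"), row.names = FALSE)
    utils::write.csv(comp$compromise, file.path(outdir, "compromise.csv"))
    utils::write.csv(
      data.frame(factor = seq_along(comp$variance_explained),
                 eigenvalue = comp$eigenvalues[
                   seq_along(comp$variance_explained)],
                 variance_explained = comp$variance_explained),
      file.path(outdir, "eigenvalues.csv"), row.names = FALSE)
  }

  if ("cluster" %in% stages) {
    if (is.null(res$compromise)) stop("cluster stage requires distatis")
    sol <- cluster_symptoms(factor_scores(res$compromise),
                            k_max = config$k_max)
    res$clusters <- sol
    write_clusters(sol, outdir)
  }

  if ("network" %in% stages) {
    if (is.null(res$matrices)) stop("network stage requires the dtw stage")
    W <- distance_to_similarity(aggregate_directed(res$matrices))
    labels <- if (!is.null(res$clusters)) res$clusters$labels else NULL
    net <- symptom_network(W, clusters = labels)
    res$network <- net
    write_network(net, outdir)
    if (!is.null(labels)) {
      cl_net <- cluster_level_network(net, labels)
      utils::write.csv(cl_net$weights,
                       file.path(outdir, "cluster_network.csv"))
    }
  }

  if ("stability" %in% stages) {
    if (is.null(res$matrices)) stop("stability stage requires the dtw stage")
    rep <- stability_run(panel, n_splits = config$n_splits,
                         seed = config$seed, matrices = res$matrices)
    res$stability <- rep
    write_stability(rep, file.path(outdir, "stability.json"))
  }

  manifest <- list(
    package = "sympdyn",
    version = as.character(utils::packageVersion("sympdyn")),
    stages = stages,
    seed = config$seed,
    config = serialize_config(config),
    input = unname(tools::md5sum(input_path)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  file.remove(marker)
  invisible(res)
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulate)) {
    sim <- unclass(out$simulate)
    sim$symptoms <- NULL
    if (is.na(sim$n_complete)) sim$n_complete <- NULL
    out$simulate <- sim
  }
  out
}

#' Re-run a pipeline from its manifest
#'
#' Reads the configuration stored in a `manifest.json` and re-executes the
#' same stages with the same seed, reproducing the outputs exactly.
#'
#' @param manifest_path Path to a manifest written by [run_pipeline()].
#' @param outdir Output directory for the re-run.
#' @return Invisibly, the stage results (see [run_pipeline()]).
#' @export
rerun_from_manifest <- function(manifest_path, outdir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- config_from_list(man$config)
  run_pipeline(cfg, outdir, stages = unlist(man$stages))
}
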
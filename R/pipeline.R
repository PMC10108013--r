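#' Pipeline configuration
#'
#' Bundles the tunable options of the two pipeline stages with defaults
#' matching the field assay design: 12-level half-dilution ladders (top
#' 400 uM for LAP, 300 uM for the glucosidases) with 4 replicates, AICc
#' model selection over all four models, LSA with a 1-month maximum delay,
#' 1000 permutations and a BH q <= 0.05 admission threshold.
#'
#' @param starts Multi-start budget passed to [fit_model()] (`NULL` = full
#'   deterministic pool).
#' @param seed Integer master seed.
#' @param D Maximum LSA delay in sampling intervals.
#' @param n_perm Permutations per pair.
#' @param q_threshold BH q-value admitted into the network.
#' @param min_abs_ls Minimum |LS| admitted into the network.
#' @param normalization `"normal_scores"` or `"zscore"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(starts = NULL, seed = 1L, D = 1L, n_perm = 1000L,
                       q_threshold = 0.05, min_abs_ls = 0,
                       normalization = "normal_scores") {
  structure(list(starts = starts, seed = as.integer(seed), D = as.integer(D),
                 n_perm = as.integer(n_perm), q_threshold = q_threshold,
                 min_abs_ls = min_abs_ls, normalization = normalization),
            class = "run_config")
}

## tiny stable polynomial hash over the deparsed config, for run manifests
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Fit and select kinetic models for a set of response curves
#'
#' For every sample x enzyme response curve, attempts all four kinetic
#' models (skipping models with too few distinct substrate levels), selects
#' the AICc winner, and returns the high-/low-affinity parameter table plus
#' the per-model AICc goodness table. Per-curve failures are reported and
#' recorded, never silently dropped.
#'
#' @param curves A list of [response_curve()] objects, a single curve, or a
#'   path to a response-curve CSV (see [read_response_curves()]).
#' @param config A [run_config()].
#' @return List with `parameters` (tibble, one row per curve; see
#'   [kinetic_parameters()]), `aicc` (tibble: `sample_id`, `enzyme`, one
#'   AICc column per model, `selected_model`), `fits` (nested list of
#'   `kinetic_fit`s) and `failures` (character).
#' @export
run_kinetics <- function(curves, config = run_config()) {
  if (is.character(curves)) curves <- read_response_curves(curves)
  if (inherits(curves, "response_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("no response curves supplied", call. = FALSE)

  params <- list(); aicc_rows <- list(); all_fits <- list(); failures <- character(0)
  for (k in seq_along(curves)) {
    cv <- curves[[k]]
    fits <- list()
    for (m in c("M1", "M2", "M3", "M4")) {
      f <- try(fit_model(cv, m, starts = config$starts, seed = config$seed),
               silent = TRUE)
      if (!inherits(f, "try-error")) fits[[m]] <- f
    }
    sel <- try(select_model(fits), silent = TRUE)
    if (inherits(sel, "try-error") || length(fits) == 0L) {
      msg <- sprintf("%s/%s: no model could be fitted", cv$sample_id, cv$enzyme)
      warning(msg, call. = FALSE)
      failures <- c(failures, msg)
      next
    }
    params[[length(params) + 1L]] <- kinetic_parameters(sel, cv)
    arow <- list(sample_id = cv$sample_id, enzyme = cv$enzyme)
    for (m in c("M1", "M2", "M3", "M4")) {
      arow[[paste0("AICc_", m)]] <-
        if (!is.null(fits[[m]])) fits[[m]]$AICc else NA_real_
    }
    arow$selected_model <- sel$model_id
    aicc_rows[[length(aicc_rows) + 1L]] <- tibble::as_tibble(arow)
    all_fits[[paste(cv$sample_id, cv$enzyme, sep = ".")]] <- fits
  }
  if (length(params) == 0L) stop("all samples failed to fit", call. = FALSE)
  list(parameters = do.call(rbind, params),
       aicc = do.call(rbind, aicc_rows),
       fits = all_fits, failures = failures)
}

#' Run local similarity analysis and build the association network
#'
#' Merges (if needed) kinetic-parameter and environmental monthly tables on
#' their `date` column, runs [lsa_all_pairs()], assembles the network, and
#' optionally writes results CSV, SIF/GraphML/edge-CSV exports and a run
#' manifest (seed, config, config hash, package version) to `outdir`.
#'
#' @param table Monthly time-series data frame (with `date` column), or
#'   path to such a CSV.
#' @param environment_table Optional second table merged on `date`.
#' @param config A [run_config()].
#' @param categories Optional node categories (see [build_network()]).
#' @param outdir Optional output directory.
#' @return List with `results` (tibble from [lsa_all_pairs()]) and
#'   `network` (an `association_network`).
#' @export
run_lsa <- function(table, environment_table = NULL, config = run_config(),
                    categories = NULL, outdir = NULL) {
  if (is.character(table)) table <- read_timeseries(table)
  if (!is.null(environment_table)) {
    if (is.character(environment_table)) {
      environment_table <- read_timeseries(environment_table)
    }
    if (!"date" %in% names(table) || !"date" %in% names(environment_table)) {
      stop("both tables need a 'date' column to merge", call. = FALSE)
    }
    table <- merge(table, environment_table, by = "date", all = FALSE)
    if (nrow(table) == 0L) stop("date ranges do not align", call. = FALSE)
  }
  results <- lsa_all_pairs(table, D = config$D, n_perm = config$n_perm,
                           seed = config$seed,
                           normalization = config$normalization)
  net <- build_network(results, q_threshold = config$q_threshold,
                       min_abs_ls = config$min_abs_ls,
                       categories = categories)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(results),
              file.path(outdir, "lsa_results.csv"), row.names = FALSE)
    export_network(net, file.path(outdir, "network.sif"), "sif")
    export_network(net, file.path(outdir, "network.graphml"), "graphml")
    export_network(net, file.path(outdir, "network_edges.csv"), "csv")
    manifest <- list(
      seed = config$seed, config = unclass(config)[
        !vapply(unclass(config), is.null, logical(1L))],
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("eeanet")),
      n_pairs = nrow(results), n_edges = nrow(net$edges))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(results = results, network = net)
}
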
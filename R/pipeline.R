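# End-to-end orchestration: simulate (or load) -> chronologies -> SPEI ->
# window selection -> events -> resilience records -> mixed models -> report.
# Every stage writes its table under the run directory and a manifest records
# the seed, configuration hash and per-file checksums.

#' Run configuration
#'
#' @param synthetic a [synthetic_config()] for simulated input, or `NULL`
#'   when `paths` point at an existing bundle.
#' @param paths named list (`rwl`, `metadata`, `climate`, `soil`) of input
#'   files; ignored when `synthetic` is given.
#' @param window_m pre/post window for the Lloret indices (1..8).
#' @param metrics growth metrics to analyse, subset of `c("TRW", "BAI")`.
#' @param common_period year range for the window-selection regressions.
#' @param calibration_span SPEI calibration year range (`NULL` = full record).
#' @param seed master seed for the run's stochastic stages.
#' @param out_dir run directory.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, paths = NULL, window_m = 4,
                       metrics = c("TRW", "BAI"),
                       common_period = c(1931, 1980), calibration_span = NULL,
                       seed = 1L, out_dir = tempfile("run")) {
  if (window_m < 1 || window_m > 8) stop("window_m must be in 1..8")
  metrics <- match.arg(metrics, c("TRW", "BAI"), several.ok = TRUE)
  if (is.null(synthetic) && is.null(paths)) {
    stop("either a synthetic config or input paths must be given")
  }
  if (!is.null(paths)) {
    need <- c("rwl", "metadata", "climate", "soil")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("paths missing: ", paste(miss, collapse = ", "))
    for (p in unlist(paths)) if (!file.exists(p)) stop("input not found: ", p)
  }
  structure(list(synthetic = synthetic, paths = paths, window_m = window_m,
                 metrics = metrics, common_period = common_period,
                 calibration_span = calibration_span, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, persisting each stage's outputs (CSV/JSON)
#' and skip reasons under `config$out_dir`. Site-level failures in window
#' selection or event detection are logged and the site is excluded; a stage
#' failure that leaves nothing to analyse halts with the stage name.
#'
#' @param config a [run_config()].
#' @return list with `dataset`, `chronologies`, `selections`, `events`,
#'   `records`, `models`, `adjusted_means`, `bootstrap`, `dir`, invisibly
#'   written to disk alongside `manifest.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)

  # -- stage: data ----------------------------------------------------------
  if (!is.null(config$synthetic)) {
    logf("stage simulate:", config$synthetic$n_sites, "sites")
    bundle <- generate_dataset(config$synthetic,
                               file.path(config$out_dir, "data"))
    dataset <- bundle$dataset
  } else {
    logf("stage load:", length(config$paths$rwl), "rwl files")
    bundle <- NULL
    dataset <- assemble_dataset(config$paths$rwl, config$paths$metadata,
                                config$paths$climate, config$paths$soil)
  }
  sites <- dataset$sites$site_id

  # -- stage: chronologies --------------------------------------------------
  logf("stage chronology")
  chronologies <- lapply(stats::setNames(sites, sites),
                         function(sid) build_chronology(dataset, sid))
  chron_tab <- do.call(rbind, c(chronologies, make.row.names = FALSE))
  utils::write.csv(chron_tab, file.path(config$out_dir, "chronologies.csv"),
                   row.names = FALSE)

  # -- stage: spei + window selection --------------------------------------
  logf("stage spei/window selection")
  selections <- list(); spei_best <- list(); aridity <- numeric()
  for (sid in sites) {
    cl <- site_climate(dataset, sid)
    hemi <- dataset$sites$hemisphere[dataset$sites$site_id == sid]
    grid <- spei_grid(cl, hemi, config$calibration_span)
    sel <- select_window(chronologies[[sid]], grid, config$common_period)
    selections[[sid]] <- sel
    spei_best[[sid]] <- spei_series(grid, sel$best$target_month, sel$best$scale)
    aridity[sid] <- aridity_index(cl)
  }
  sel_tab <- do.call(rbind, lapply(selections, function(s) {
    data.frame(site_id = s$site_id, s$table, best = with(s$table,
      target_month == s$best$target_month & scale == s$best$scale))
  }))
  utils::write.csv(sel_tab, file.path(config$out_dir, "window_selection.csv"),
                   row.names = FALSE)

  # -- stage: events --------------------------------------------------------
  logf("stage events")
  events <- list()
  for (sid in sites) {
    deaths <- unlist(lapply(Filter(function(s)
      s$site_id == sid && s$status == "now-dead", dataset$series),
      `[[`, "last_year"))
    if (length(deaths) == 0) { logf("  ", sid, "no deaths; skipped"); next }
    sw <- site_event_search_window(deaths)
    ev <- detect_event(site_mean_trw(dataset, sid), spei_best[[sid]], sw)
    if (is.null(ev)) { logf("  ", sid, "no qualifying drought; discarded"); next }
    events[[sid]] <- cbind(site_id = sid, ev,
                           first_allowed = sw$first_allowed,
                           last_allowed = sw$last_allowed)
  }
  if (length(events) == 0) stop("stage events: no site with a detectable event")
  events <- do.call(rbind, c(events, make.row.names = FALSE))
  utils::write.csv(events, file.path(config$out_dir, "events.csv"),
                   row.names = FALSE)

  # -- stage: indices -------------------------------------------------------
  logf("stage indices")
  soil <- soil_fertility_pc1(dataset$soil)
  records <- build_records(dataset, events, spei_best,
                           window_m = config$window_m,
                           metrics = config$metrics,
                           aridity = aridity, soil_pc1 = soil$scores)
  utils::write.csv(records, file.path(config$out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(records, "skipped"),
                   file.path(config$out_dir, "records_skipped.csv"),
                   row.names = FALSE)
  boot <- growth_pattern_bootstrap(dataset, events, seed = config$seed)
  utils::write.csv(boot, file.path(config$out_dir, "bootstrap_curves.csv"),
                   row.names = FALSE)

  # -- stage: models --------------------------------------------------------
  logf("stage models")
  models <- list(); adj <- list()
  for (metric in config$metrics) {
    for (resp in c("resilience", "resistance", "recovery")) {
      key <- paste(resp, metric, sep = "_")
      red <- reduce_model(build_design(records, resp, metric, on_alias = "drop"))
      models[[key]] <- red
      if ("status" %in% unlist(strsplit(red$fit$terms, ":"))) {
        adj[[key]] <- adjusted_means(red$fit)
      }
      logf("  ", key, "AIC", round(red$fit$aic_ml, 1),
           "dAIC(status)", round(red$fit$delta_aic_status, 1))
    }
  }
  model_tab <- do.call(rbind, lapply(names(models), function(k) {
    cbind(model = k, models[[k]]$fit$coef,
          r2m = models[[k]]$fit$r2[["r2m"]], r2c = models[[k]]$fit$r2[["r2c"]],
          delta_aic_status = models[[k]]$fit$delta_aic_status)
  }))
  utils::write.csv(model_tab, file.path(config$out_dir, "model_coefficients.csv"),
                   row.names = FALSE)
  adj_tab <- do.call(rbind, lapply(names(adj), function(k) {
    cbind(model = k, adj[[k]]$means)
  }))
  if (!is.null(adj_tab)) {
    utils::write.csv(adj_tab, file.path(config$out_dir, "adjusted_means.csv"),
                     row.names = FALSE)
  }

  # -- manifest -------------------------------------------------------------
  files <- list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE,
                      recursive = TRUE)
  manifest <- list(seed = config$seed,
                   window_m = config$window_m, metrics = config$metrics,
                   n_sites = length(sites), n_event_sites = nrow(events),
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done:", nrow(events), "event sites,", nrow(records), "records")

  invisible(list(dataset = dataset, chronologies = chronologies,
                 selections = selections, events = events, records = records,
                 models = models, adjusted_means = adj, bootstrap = boot,
                 soil = soil, dir = config$out_dir))
}

#' Summarise a completed run directory
#'
#' Re-reads the persisted stage tables and writes `report.txt`: the per-site
#' event table, the adjusted-means contrasts, and a compact model summary.
#' Idempotent; errors if a required stage artifact is missing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return path of the report, invisibly.
#' @export
report <- function(run_dir) {
  need <- c("events.csv", "records.csv", "model_coefficients.csv")
  miss <- need[!file.exists(file.path(run_dir, need))]
  if (length(miss)) stop("incomplete run; missing: ", paste(miss, collapse = ", "))
  events <- utils::read.csv(file.path(run_dir, "events.csv"))
  records <- utils::read.csv(file.path(run_dir, "records.csv"))
  coefs <- utils::read.csv(file.path(run_dir, "model_coefficients.csv"))
  path <- file.path(run_dir, "report.txt")
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  w("Drought resilience run summary")
  w("==============================")
  w(sprintf("%d event sites, %d resilience records (%s)", nrow(events),
            nrow(records), paste(unique(records$metric), collapse = ", ")))
  w("")
  w("Per-site drought events:")
  utils::write.table(format(events, digits = 3), con, row.names = FALSE,
                     quote = FALSE)
  if (file.exists(file.path(run_dir, "adjusted_means.csv"))) {
    w("")
    w("Back-transformed adjusted means (ratio scale):")
    utils::write.table(format(utils::read.csv(
      file.path(run_dir, "adjusted_means.csv")), digits = 3), con,
      row.names = FALSE, quote = FALSE)
  }
  w("")
  w("Model coefficients (standardised):")
  utils::write.table(format(coefs, digits = 3), con, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
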
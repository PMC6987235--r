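# Synthetic study generator: seeded monthly climate with a planted extreme
# drought per site, lognormal AR(1) ring-width series coupled to SPEI at a
# site-specific "true" window, status- and taxon-specific resistance/recovery
# deficits for now-dead trees, nested site/species/genus structure, and a
# ten-variable soil table driven by a latent fertility factor. Every planted
# quantity is recorded in a ground-truth ledger so downstream stages have a
# recoverable target.

#' Configuration for the synthetic study generator
#'
#' Defaults describe a desk-scale analogue of the pancontinental database:
#' a 1901-2013 calendar, sites split between angiosperms and gymnosperms,
#' one extreme drought per site between 1950 and 1970, first deaths 10-40
#' years later, and multiplicative index deficits for now-dead trees
#' (angiosperms lose resistance, gymnosperms lose recovery).
#'
#' @param n_sites number of sites (>= 1).
#' @param trees_surviving,trees_dead trees per site by final status (>= 1).
#' @param calendar_span length-2 year range.
#' @param hemisphere `"N"` or `"S"` (month conventions for target windows).
#' @param event_years per-site drought calendar years (recycled); each must
#'   sit at least 4 years inside the span and at least 41 years before its
#'   end so deaths can occur 10-40 years later.
#' @param true_windows data frame with columns `target_month`, `scale`
#'   (recycled over sites); the SPEI window each site's growth actually
#'   responds to.
#' @param beta_climate log-growth slope per SPEI unit.
#' @param ar_coef lag-1 autocorrelation of the log-growth noise, in [0, 1).
#' @param noise_sd innovation standard deviation of the log-growth noise.
#' @param climate_noise_sd lognormal sd of monthly precipitation noise
#'   (0 gives a deterministic seasonal cycle plus planted anomalies).
#' @param event_growth_drop fractional event-year growth reduction shared by
#'   all trees at a site (default 0.2, a 20% drop).
#' @param resist_deficit_dead,recov_deficit_dead named numeric
#'   (`angiosperm`, `gymnosperm`): multiplicative deficits in (0, 1] applied
#'   to now-dead trees' drought-year growth (resistance) and post-drought
#'   growth (recovery), expressed as the expected dead/surviving index ratio.
#' @param trend_params negative-exponential size trend `a * exp(-b * age) + k`
#'   (mm), a list with elements `a`, `b`, `k`.
#' @param seed master RNG seed; per-site, per-stage streams are derived from
#'   it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 10,
                             trees_surviving = 10,
                             trees_dead = 6,
                             calendar_span = c(1901, 2013),
                             hemisphere = "N",
                             event_years = seq(1950, 1970, length.out = n_sites),
                             true_windows = NULL,
                             beta_climate = 0.15,
                             ar_coef = 0.3,
                             noise_sd = 0.2,
                             climate_noise_sd = 0.35,
                             event_growth_drop = 0.2,
                             resist_deficit_dead = c(angiosperm = 0.7,
                                                     gymnosperm = 0.9),
                             recov_deficit_dead = c(angiosperm = 1.0,
                                                    gymnosperm = 0.7),
                             trend_params = list(a = 1.5, b = 0.04, k = 0.8),
                             seed = 1L) {
  stopifnot(n_sites >= 1, trees_surviving >= 1, trees_dead >= 1,
            diff(calendar_span) >= 49, ar_coef >= 0, ar_coef < 1,
            noise_sd >= 0, event_growth_drop >= 0, event_growth_drop < 1,
            all(resist_deficit_dead > 0), all(resist_deficit_dead <= 1),
            all(recov_deficit_dead > 0), all(recov_deficit_dead <= 1))
  hemisphere <- match.arg(hemisphere, c("N", "S"))
  event_years <- as.integer(round(rep_len(event_years, n_sites)))
  if (any(event_years < calendar_span[1] + 4) ||
      any(event_years > calendar_span[2] - 41)) {
    stop("event years must lie >= 4 years after the span start and ",
         ">= 41 years before its end")
  }
  if (is.null(true_windows)) {
    tm <- target_month_table(hemisphere)$target_month
    true_windows <- data.frame(
      target_month = tm[(seq_len(n_sites) - 1) %% length(tm) + 1],
      scale = c(3, 6, 9, 12)[(seq_len(n_sites) - 1) %% 4 + 1])
  } else {
    true_windows <- true_windows[rep_len(seq_len(nrow(true_windows)),
                                         n_sites), , drop = FALSE]
  }
  if (any(true_windows$scale < 1) || any(true_windows$scale > 24)) {
    stop("true window scales must be in 1..24")
  }
  groups <- rep_len(c("angiosperm", "gymnosperm"), n_sites)
  structure(list(n_sites = n_sites, trees_surviving = trees_surviving,
                 trees_dead = trees_dead, calendar_span = calendar_span,
                 hemisphere = hemisphere, event_years = event_years,
                 true_windows = true_windows, groups = groups,
                 beta_climate = beta_climate, ar_coef = ar_coef,
                 noise_sd = noise_sd, climate_noise_sd = climate_noise_sd,
                 event_growth_drop = event_growth_drop,
                 resist_deficit_dead = resist_deficit_dead,
                 recov_deficit_dead = recov_deficit_dead,
                 trend_params = trend_params, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Derived per-site, per-stage seed below 2^31.
stage_seed <- function(config, stage, site) {
  (config$seed %% 100000L) * 10000L +
    match(stage, c("climate", "trees", "soil", "deaths")) * 1000L + site
}

# Seasonal monthly means: winter-wet precipitation, summer-peaked PET.
seasonal_prcp <- function(month) 45 + 20 * cos(2 * pi * (month - 1) / 12)
seasonal_pet <- function(month) 20 + 90 * exp(-0.5 * ((month - 7) / 2.2)^2)

#' Generate one site's monthly climate with a planted extreme drought
#'
#' Precipitation is a winter-wet seasonal cycle with lognormal monthly noise
#' and a site-level wetness multiplier; PET is a summer-peaked cycle with
#' mild noise. In the event year the k months ending at the site's true
#' window are driven into deficit, and the deficit is deepened
#' deterministically until the planted year is the strict site minimum of the
#' aggregated k-month balance at the true window.
#'
#' @param config a [synthetic_config()].
#' @param site site index (1..n_sites).
#' @return data frame `site`, `year`, `month`, `prcp_mm`, `pet_mm`.
#' @export
generate_climate <- function(config, site) {
  span <- config$calendar_span
  if (diff(span) + 1 < 50) stop("calendar span must cover at least 50 years")
  set.seed(stage_seed(config, "climate", site))
  years <- span[1]:span[2]
  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  n <- nrow(grid)
  wetness <- exp(stats::rnorm(1, 0, 0.2))
  prcp <- wetness * seasonal_prcp(grid$month) *
    exp(stats::rnorm(n, 0, config$climate_noise_sd))
  pet <- seasonal_pet(grid$month) *
    exp(stats::rnorm(n, 0, 0.3 * config$climate_noise_sd))

  tw <- config$true_windows[site, ]
  ev <- config$event_years[site]
  # flat month index of the event window's end, then k months back
  flat <- (grid$year - span[1]) * 12 + grid$month
  offset <- if (config$hemisphere == "S" && tw$target_month == 12) -1L else 0L
  end_flat <- (ev + offset - span[1]) * 12 + tw$target_month
  win <- (end_flat - tw$scale + 1):end_flat
  win <- win[win >= 1]
  prcp[win] <- prcp[win] * 0.05
  pet[win] <- pet[win] * 1.3

  # deterministic deepening until the planted year is the strict argmin of
  # the aggregated balance at the true window
  for (i in 1:100) {
    bal <- data.frame(year = grid$year, month = grid$month, d = prcp - pet)
    agg <- aggregate_balance(bal, tw$scale, tw$target_month, offset)
    ev_val <- agg$agg[agg$year == ev]
    if (length(ev_val) == 1 && ev_val < min(agg$agg[agg$year != ev])) break
    prcp[win] <- prcp[win] * 0.5
    pet[win] <- pet[win] + 10
  }
  data.frame(site = paste0("site", sprintf("%03d", site)),
             year = grid$year, month = grid$month,
             prcp_mm = prcp, pet_mm = pet)
}

# Negative-exponential size trend (mm) at cambial age 0, 1, 2, ...
size_trend <- function(age, p) p$a * exp(-p$b * age) + p$k

#' Generate ring-width series for one site plus its ground-truth entries
#'
#' Log ring width = log size trend + `beta_climate` * SPEI(true window) +
#' AR(1) noise. At the event year all trees lose `event_growth_drop` of their
#' growth; now-dead trees are additionally multiplied by the taxon's
#' resistance deficit in the event year, and by resistance x recovery deficit
#' in the four post-event years, so the planted dead/surviving index ratios
#' equal the configured deficits. Now-dead series terminate at a death year
#' drawn uniformly in [event + 10, event + 40].
#'
#' @param config a [synthetic_config()].
#' @param climate that site's climate from [generate_climate()].
#' @param site site index.
#' @return list with `series` (list of [ring_series()]) and `ledger`
#'   (data frame of per-tree planted truths).
#' @export
generate_tree_series <- function(config, climate, site) {
  span <- config$calendar_span
  if (min(climate$year) > span[1] || max(climate$year) < span[2]) {
    stop("climate does not cover the configured span")
  }
  tw <- config$true_windows[site, ]
  offset <- if (config$hemisphere == "S" && tw$target_month == 12) -1L else 0L
  bal <- data.frame(year = climate$year, month = climate$month,
                    d = water_balance(climate$prcp_mm, climate$pet_mm))
  agg <- aggregate_balance(bal, tw$scale, tw$target_month, offset)
  spei <- standardize_loglogistic(agg)

  years <- spei$year[spei$year >= span[1] & spei$year <= span[2]]
  spei_v <- spei$spei[match(years, spei$year)]
  ev <- config$event_years[site]
  group <- config$groups[site]
  rdef <- config$resist_deficit_dead[[group]]
  cdef <- config$recov_deficit_dead[[group]]
  species <- paste0("sp", sprintf("%02d", (site - 1) %% max(2, ceiling(config$n_sites / 2)) + 1))
  genus <- paste0("gen", (site - 1) %% max(2, ceiling(config$n_sites / 4)) + 1)
  site_id <- paste0("site", sprintf("%03d", site))

  set.seed(stage_seed(config, "deaths", site))
  n_dead <- config$trees_dead
  death_years <- pmin(ev + sample(10:40, n_dead, replace = TRUE), span[2] - 1L)

  set.seed(stage_seed(config, "trees", site))
  n_trees <- config$trees_surviving + n_dead
  series <- list()
  ledger <- list()
  for (j in seq_len(n_trees)) {
    dead <- j > config$trees_surviving
    last <- if (dead) death_years[j - config$trees_surviving] else span[2]
    yrs <- years[years <= last]
    age <- yrs - yrs[1]
    e <- stats::filter(stats::rnorm(length(yrs), 0, config$noise_sd),
                       config$ar_coef, method = "recursive")
    logg <- log(size_trend(age, config$trend_params)) +
      config$beta_climate * spei_v[seq_along(yrs)] + as.numeric(e)
    g <- exp(logg)
    g[yrs == ev] <- g[yrs == ev] * (1 - config$event_growth_drop)
    if (dead) {
      g[yrs == ev] <- g[yrs == ev] * rdef
      post <- yrs > ev & yrs <= ev + 4
      g[post] <- g[post] * rdef * cdef
    }
    tree_id <- sprintf("S%03dT%02d", site, j)
    dbh <- round(2 * sum(g) / 10 + 1, 1)
    series[[tree_id]] <- ring_series(
      tree_id, yrs, g, site_id = site_id, species = species, genus = genus,
      group = group, status = if (dead) "now-dead" else "surviving",
      dbh_cm = dbh)
    ledger[[tree_id]] <- data.frame(
      tree_id = tree_id, site_id = site_id, status = series[[tree_id]]$status,
      group = group, death_year = if (dead) last else NA_integer_,
      expected_rt_ratio = if (dead) rdef else 1,
      expected_rc_ratio = if (dead) cdef else 1,
      expected_rs_ratio = if (dead) rdef * cdef else 1)
  }
  list(series = series, ledger = do.call(rbind, c(ledger, make.row.names = FALSE)))
}

#' Generate the per-site soil table
#'
#' Ten soil characteristics driven by a latent fertility factor that loads
#' positively on total nitrogen, organic carbon and available water capacity
#' (so the downstream fertility PC1 is positively associated with nitrogen).
#' Clay, silt and sand contents sum to 100.
#'
#' @param n_sites number of sites (>= 3).
#' @param seed RNG seed.
#' @return data frame with `site` plus the ten soil columns.
#' @export
generate_soil_table <- function(n_sites, seed = 1L) {
  if (n_sites < 3) stop("need at least 3 sites for a soil table")
  set.seed((seed %% 100000L) * 10000L + 3000L)
  f <- stats::rnorm(n_sites)
  oc <- pmax(26 + 8 * f + stats::rnorm(n_sites, 0, 2), 1)
  nitro <- pmax(2 + 0.6 * f + stats::rnorm(n_sites, 0, 0.15), 0.1)
  awc <- pmax(15 + 3 * f + stats::rnorm(n_sites, 0, 1), 1)
  clay <- pmax(25 + 5 * stats::rnorm(n_sites), 2)
  silt <- pmax(35 + 5 * stats::rnorm(n_sites), 2)
  sand <- pmax(40 + 5 * stats::rnorm(n_sites), 2)
  tot <- clay + silt + sand
  data.frame(
    site = paste0("site", sprintf("%03d", seq_len(n_sites))),
    organic_carbon = oc,
    total_nitrogen = nitro,
    cn_ratio = oc / nitro,
    bulk_density = pmax(1.4 - 0.08 * f + stats::rnorm(n_sites, 0, 0.05), 0.5),
    awc = awc,
    depth_bedrock = pmax(150 + 40 * stats::rnorm(n_sites), 10),
    ph = 6 - 0.3 * f + stats::rnorm(n_sites, 0, 0.2),
    clay = 100 * clay / tot,
    silt = 100 * silt / tot,
    sand = 100 * sand / tot)
}

#' Generate and write a complete synthetic study bundle
#'
#' Writes one `.rwl` per site, `metadata.csv`, `climate.csv`, `soil.csv` and
#' `ledger.json` (the ground truth) under `dir`, then reads the bundle back
#' through [assemble_dataset()] so the returned dataset has passed the same
#' validation as any external input.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if absent).
#' @return list with `dataset` (a validated `ring_dataset`), `ledger`
#'   (data frame) and `paths` (the written files).
#' @export
generate_dataset <- function(config, dir = tempfile("synth")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  climate_all <- list(); meta <- list(); ledger <- list(); rwl_paths <- character()
  for (site in seq_len(config$n_sites)) {
    cl <- generate_climate(config, site)
    ts <- generate_tree_series(config, cl, site)
    climate_all[[site]] <- cl
    ledger[[site]] <- ts$ledger
    p <- file.path(dir, sprintf("site%03d.rwl", site))
    write_rwl(ts$series, p, units_dialect = "0.001")
    rwl_paths <- c(rwl_paths, p)
    meta[[site]] <- do.call(rbind, lapply(ts$series, function(s) {
      data.frame(tree_id = s$tree_id, site = s$site_id, species = s$species,
                 genus = s$genus, group = s$group, status = s$status,
                 dbh_cm = s$dbh_cm, last_year = s$last_year,
                 hemisphere = config$hemisphere)
    }))
  }
  meta <- do.call(rbind, c(meta, make.row.names = FALSE))
  climate <- do.call(rbind, climate_all)
  soil <- generate_soil_table(config$n_sites, config$seed)
  ledger <- do.call(rbind, c(ledger, make.row.names = FALSE))
  site_truth <- data.frame(site_id = paste0("site", sprintf("%03d", seq_len(config$n_sites))),
                           event_year = config$event_years,
                           target_month = config$true_windows$target_month,
                           scale = config$true_windows$scale,
                           group = config$groups)

  paths <- list(metadata = file.path(dir, "metadata.csv"),
                climate = file.path(dir, "climate.csv"),
                soil = file.path(dir, "soil.csv"),
                ledger = file.path(dir, "ledger.json"),
                rwl = rwl_paths)
  utils::write.csv(meta, paths$metadata, row.names = FALSE)
  utils::write.csv(climate, paths$climate, row.names = FALSE)
  utils::write.csv(soil, paths$soil, row.names = FALSE)
  jsonlite::write_json(list(sites = site_truth, trees = ledger,
                            seed = config$seed),
                       paths$ledger, digits = NA, dataframe = "rows")
  dataset <- assemble_dataset(rwl_paths, paths$metadata, paths$climate,
                              paths$soil, units_dialect = "0.001")
  list(dataset = dataset,
       ledger = list(sites = site_truth, trees = ledger),
       paths = paths)
}
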
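# Basal area increment, Lloret resistance/recovery/resilience indices, SPEI
# covariates around the event, per-tree model records, and the bootstrapped
# log-ratio growth trajectories.

#' Basal area increment from ring widths and DBH
#'
#' Radii are reconstructed outside-in from DBH at sampling:
#' `r(last) = dbh * 10 / 2` mm and `r(t-1) = r(t) - trw(t)`; then
#' `BAI(t) = pi * (r(t)^2 - r(t-1)^2)`. Locally absent rings (NA) are bridged
#' by linear interpolation for the radius accumulation only. Years whose
#' reconstructed inner radius would be negative are truncated with a warning.
#'
#' @param series a [ring_series()] with known `dbh_cm`.
#' @return data frame `year`, `bai` (mm^2).
#' @export
compute_bai <- function(series) {
  if (!is.finite(series$dbh_cm)) stop(series$tree_id, ": dbh_cm required for BAI")
  trw <- series$trw
  if (anyNA(trw)) {
    trw <- stats::approx(seq_along(trw)[!is.na(trw)], trw[!is.na(trw)],
                         xout = seq_along(trw), rule = 2)$y
  }
  n <- length(trw)
  r <- numeric(n + 1)
  r[n + 1] <- series$dbh_cm * 10 / 2
  for (t in n:1) r[t] <- r[t + 1] - trw[t]
  keep <- which(r[-(n + 1)] >= 0)
  if (length(keep) < n) {
    warning(series$tree_id, ": cumulative widths exceed DBH/2; truncating ",
            n - length(keep), " early years")
  }
  first <- if (length(keep)) min(keep) else stop(series$tree_id,
                                                ": no non-negative radii")
  t_idx <- first:n
  data.frame(year = series$years[t_idx],
             bai = pi * (r[t_idx + 1]^2 - r[t_idx]^2))
}

#' DBH in a given year, reconstructed from subsequent ring widths
#'
#' @param series a [ring_series()].
#' @param year calendar year within the series.
#' @return DBH (cm) in `year`: `dbh_cm - 2 * sum(trw after year) / 10`.
#' @export
dbh_at_year <- function(series, year) {
  if (year < min(series$years) || year > series$last_year) {
    stop(series$tree_id, ": year ", year, " outside series")
  }
  d <- series$dbh_cm - 2 * sum(series$trw[series$years > year], na.rm = TRUE) / 10
  if (d < 0) stop(series$tree_id, ": negative DBH reconstructed at ", year)
  d
}

#' Lloret resistance, recovery and resilience indices
#'
#' With `Dr` the growth in the drought year, `PreDr` the arithmetic mean
#' growth of the `m` years before, and `PostDr` the mean of the `m` years
#' after (event year excluded from both windows):
#' resistance = Dr/PreDr, recovery = PostDr/Dr,
#' resilience = PostDr/PreDr = resistance x recovery.
#'
#' @param growth data frame `year`, `value` of raw growth (TRW mm or BAI
#'   mm^2), all positive.
#' @param event_year drought calendar year.
#' @param window_m pre/post window length in years (1..8, default 4).
#' @return list with `pre_dr`, `dr`, `post_dr`, `resistance`, `recovery`,
#'   `resilience`.
#' @export
lloret_indices <- function(growth, event_year, window_m = 4) {
  stopifnot(window_m >= 1, window_m <= 8)
  g <- function(yrs) {
    v <- growth$value[match(yrs, growth$year)]
    if (anyNA(v)) stop("insufficient growth coverage around ", event_year)
    v
  }
  pre <- mean(g((event_year - window_m):(event_year - 1)))
  dr <- g(event_year)
  post <- mean(g((event_year + 1):(event_year + window_m)))
  if (any(c(pre, dr, post) <= 0)) stop("non-positive growth around event")
  list(pre_dr = pre, dr = dr, post_dr = post,
       resistance = dr / pre, recovery = post / dr, resilience = post / pre)
}

#' SPEI covariates around the drought event
#'
#' @param spei data frame `year`, `spei` at the site's best window.
#' @param event_year drought calendar year.
#' @param window_m pre/post window length (years).
#' @return list with `spei_i`, `pre_spei`, `post_spei`, `speidiff_resist`
#'   (`spei_i - pre_spei`), `speidiff_recov` (`post_spei - spei_i`),
#'   `speidiff_resil` (`post_spei - pre_spei`).
#' @export
spei_covariates <- function(spei, event_year, window_m = 4) {
  g <- function(yrs) {
    v <- spei$spei[match(yrs, spei$year)]
    if (anyNA(v)) stop("missing SPEI years around ", event_year)
    v
  }
  pre <- mean(g((event_year - window_m):(event_year - 1)))
  si <- g(event_year)
  post <- mean(g((event_year + 1):(event_year + window_m)))
  list(spei_i = si, pre_spei = pre, post_spei = post,
       speidiff_resist = si - pre, speidiff_recov = post - si,
       speidiff_resil = post - pre)
}

#' Assemble per-tree resilience records for the mixed models
#'
#' One row per tree and growth metric with the Lloret indices and every model
#' covariate. Trees without `window_m` complete years of positive growth on
#' both sides of the event are skipped; skip reasons are attached as the
#' `"skipped"` attribute.
#'
#' @param dataset a `ring_dataset`.
#' @param events data frame with one row per site: `site_id`, `year` (the
#'   event), plus any columns from [detect_event()].
#' @param spei_list named list (by site_id) of `year`/`spei` data frames at
#'   each site's best window.
#' @param window_m pre/post window length (1..8, default 4).
#' @param metrics subset of `c("TRW", "BAI")`.
#' @param aridity named numeric of site aridity indices.
#' @param soil_pc1 named numeric of site soil-fertility PC1 scores.
#' @return data frame of resilience records (one row per tree x metric).
#' @export
build_records <- function(dataset, events, spei_list, window_m = 4,
                          metrics = c("TRW", "BAI"), aridity = NULL,
                          soil_pc1 = NULL) {
  stopifnot(window_m >= 1, window_m <= 8)
  metrics <- match.arg(metrics, c("TRW", "BAI"), several.ok = TRUE)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(events))) {
    sid <- events$site_id[i]
    ev <- events$year[i]
    sp <- spei_list[[sid]]
    spc <- spei_covariates(sp, ev, window_m)
    series <- Filter(function(s) s$site_id == sid, dataset$series)
    for (s in series) {
      for (metric in metrics) {
        growth <- if (metric == "TRW") {
          data.frame(year = s$years, value = s$trw)
        } else {
          b <- compute_bai(s); data.frame(year = b$year, value = b$bai)
        }
        li <- tryCatch(lloret_indices(growth, ev, window_m), error = identity)
        if (inherits(li, "error")) {
          skipped[[length(skipped) + 1]] <- data.frame(
            tree_id = s$tree_id, metric = metric, reason = conditionMessage(li))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          tree_id = s$tree_id, site_id = sid, species = s$species,
          genus = s$genus, group = s$group, status = s$status,
          metric = metric, window_m = window_m,
          pre_dr = li$pre_dr, dr = li$dr, post_dr = li$post_dr,
          resistance = li$resistance, recovery = li$recovery,
          resilience = li$resilience,
          spei_i = spc$spei_i, pre_spei = spc$pre_spei,
          post_spei = spc$post_spei,
          speidiff_resist = spc$speidiff_resist,
          speidiff_recov = spc$speidiff_recov,
          speidiff_resil = spc$speidiff_resil,
          dbh_i = dbh_at_year(s, ev),
          delta_time = s$last_year - ev,
          aridity = if (is.null(aridity)) NA_real_ else unname(aridity[sid]),
          soil_pc1 = if (is.null(soil_pc1)) NA_real_ else unname(soil_pc1[sid]))
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) stop("no resilience records could be built")
  attr(out, "skipped") <- if (length(skipped)) {
    do.call(rbind, c(skipped, make.row.names = FALSE))
  } else {
    data.frame(tree_id = character(), metric = character(), reason = character())
  }
  out
}

#' Bootstrapped log-ratio growth trajectories around the event
#'
#' For each tree, `log(TRW(t) / PreDr)` over relative years
#' `-window_m .. +half_window`; trees are resampled with replacement within
#' each (taxonomic group, status) stratum and per-year percentile 95%
#' confidence intervals are taken over the bootstrap means.
#'
#' @param dataset a `ring_dataset`.
#' @param events data frame `site_id`, `year`.
#' @param half_window last relative year of the trajectory (default 8).
#' @param n_boot bootstrap resamples (default 1000).
#' @param window_m pre-drought window defining `PreDr` (default 4).
#' @param min_trees minimum trees per stratum (default 5); smaller strata are
#'   skipped with a warning.
#' @param seed RNG seed for the resampling.
#' @return data frame `group`, `status`, `rel_year`, `mean`, `lo`, `hi`, `n`.
#' @export
growth_pattern_bootstrap <- function(dataset, events, half_window = 8,
                                     n_boot = 1000, window_m = 4,
                                     min_trees = 5, seed = 1L) {
  rel <- (-window_m):half_window
  curves <- list(); meta <- list()
  for (i in seq_len(nrow(events))) {
    sid <- events$site_id[i]; ev <- events$year[i]
    for (s in Filter(function(x) x$site_id == sid, dataset$series)) {
      v <- s$trw[match(ev + rel, s$years)]
      pre <- mean(s$trw[match((ev - window_m):(ev - 1), s$years)])
      if (anyNA(v) || !is.finite(pre) || pre <= 0) next
      curves[[length(curves) + 1]] <- log(v / pre)
      meta[[length(meta) + 1]] <- data.frame(group = s$group, status = s$status)
    }
  }
  if (length(curves) == 0) stop("no trees with full trajectory coverage")
  meta <- do.call(rbind, meta)
  mat <- do.call(rbind, curves)
  set.seed(seed)
  out <- list()
  for (g in unique(meta$group)) for (st in unique(meta$status)) {
    idx <- which(meta$group == g & meta$status == st)
    if (length(idx) < min_trees) {
      warning("stratum ", g, "/", st, " skipped: only ", length(idx), " trees")
      next
    }
    sub <- mat[idx, , drop = FALSE]
    boots <- matrix(NA_real_, n_boot, length(rel))
    for (b in seq_len(n_boot)) {
      boots[b, ] <- colMeans(sub[sample(nrow(sub), replace = TRUE), , drop = FALSE])
    }
    out[[length(out) + 1]] <- data.frame(
      group = g, status = st, rel_year = rel, mean = colMeans(sub),
      lo = apply(boots, 2, stats::quantile, 0.025),
      hi = apply(boots, 2, stats::quantile, 0.975), n = length(idx))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
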
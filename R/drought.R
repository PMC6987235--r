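# Per-site SPEI window selection (120 candidates, AIC over common-period OLS
# fits of the residual chronology on SPEI) and detection of the single
# extreme drought event per site: SPEI below the site 10th percentile plus a
# >5% site-mean growth reduction at lag 0 or 1, inside the 10-40-years-
# before-first-death search window.

#' Enumerate the candidate SPEI windows for a hemisphere
#'
#' Five target months (June-October in the north; December of the previous
#' year to April in the south) crossed with aggregation scales 1-24 months:
#' 120 candidates.
#'
#' @param hemisphere `"N"` or `"S"`.
#' @return data frame with columns `target_month`, `year_offset`, `scale`.
#' @export
candidate_windows <- function(hemisphere = "N") {
  tm <- target_month_table(hemisphere)
  out <- merge(tm, data.frame(scale = 1:24))
  out[order(match(out$target_month, tm$target_month), out$scale),
      c("target_month", "year_offset", "scale")]
}

# Gaussian-likelihood AIC of a simple OLS fit, matching stats::AIC on lm
# (3 parameters: intercept, slope, residual variance).
ols_aic <- function(x, y) {
  n <- length(x)
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  aic <- n * (log(2 * pi * rss / n) + 1) + 6
  c(slope = b, r2 = r2, aic = aic)
}

#' Select the best SPEI window for a site by AIC
#'
#' Regresses the residual chronology on each of the 120 candidate SPEI series
#' over the common period and keeps the minimum-AIC candidate; ties break
#' towards the smaller scale, then the earlier target month.
#'
#' @param chronology a `site_chronology` from [build_chronology()].
#' @param grid the site's [spei_grid()].
#' @param common_period length-2 year range the fits are restricted to
#'   (default 1931-1980).
#' @param min_overlap minimum chronology/SPEI overlap within the common
#'   period for a candidate to be fit (default 20 years).
#' @return list of class `window_selection` with `site_id`, `best`
#'   (one-row data frame: `target_month`, `scale`), and `table` (one row per
#'   candidate: `target_month`, `scale`, `slope`, `r2`, `aic`).
#' @export
select_window <- function(chronology, grid, common_period = c(1931, 1980),
                          min_overlap = 20) {
  cand <- candidate_windows(if (grid$months$target_month[1] == 6) "N" else "S")
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sp <- spei_series(grid, cand$target_month[i], cand$scale[i])
    m <- merge(chronology, sp, by = "year")
    m <- m[m$year >= common_period[1] & m$year <= common_period[2], ]
    if (nrow(m) < min_overlap) {
      warning(sprintf("candidate m%02d s%02d dropped: only %d overlapping years",
                      cand$target_month[i], cand$scale[i], nrow(m)))
      next
    }
    st <- ols_aic(m$spei, m$index)
    rows[[i]] <- data.frame(target_month = cand$target_month[i],
                            scale = cand$scale[i], slope = st[["slope"]],
                            r2 = st[["r2"]], aic = st[["aic"]])
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) stop("no candidate window could be fit")
  ord <- order(tab$aic, tab$scale, match(tab$target_month,
                                         cand$target_month[!duplicated(cand$target_month)]))
  structure(list(site_id = chronology$site_id[1],
                 best = tab[ord[1], c("target_month", "scale")],
                 table = tab),
            class = "window_selection")
}

#' Event search window from a site's death years
#'
#' Now-dead trees that died more than 50 years before the site's last death
#' are excluded as exceptional long mortality; with D the first retained
#' death year, the drought event is searched in `[D - 40, D - 10]`.
#'
#' @param death_years integer vector of per-tree death years at one site.
#' @return list with `first_allowed`, `last_allowed`, `retained` (the death
#'   years kept).
#' @export
site_event_search_window <- function(death_years) {
  death_years <- death_years[is.finite(death_years)]
  if (length(death_years) == 0) stop("no death years: site not eligible")
  retained <- death_years[death_years >= max(death_years) - 50]
  D <- min(retained)
  list(first_allowed = D - 40L, last_allowed = D - 10L, retained = retained)
}

#' Site mean raw ring width per year
#'
#' Averages raw TRW over all trees (both statuses) with data in each year;
#' used by the event-detection growth criterion.
#'
#' @param dataset a `ring_dataset`.
#' @param site_id site identifier.
#' @return data frame `year`, `trw`.
#' @export
site_mean_trw <- function(dataset, site_id) {
  series <- Filter(function(s) s$site_id == site_id, dataset$series)
  if (length(series) == 0) stop("no series at site ", site_id)
  years <- sort(unique(unlist(lapply(series, `[[`, "years"))))
  trw <- vapply(years, function(y) {
    v <- unlist(lapply(series, function(s) s$trw[s$years == y]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(year = years, trw = trw)
}

#' Detect the single extreme drought event for a site
#'
#' A year qualifies when (1) SPEI at the site's best window is below the 10th
#' percentile of the full SPEI record and (2) site-mean TRW in the same year
#' or the year after is reduced by more than 5% relative to the mean of the 4
#' preceding years. Among qualifying years inside the search window the one
#' with minimum SPEI is returned; `NULL` when none qualifies (the site is
#' discarded downstream).
#'
#' @param mean_trw data frame `year`, `trw` from [site_mean_trw()].
#' @param spei data frame `year`, `spei` at the site's best window.
#' @param search_window list from [site_event_search_window()].
#' @param percentile SPEI quantile threshold (default 0.10), computed with
#'   linear interpolation over the full record.
#' @param drop_threshold minimum fractional growth reduction (default 0.05).
#' @return one-row data frame (`year`, `spei_i`, `spei_threshold`,
#'   `growth_drop`, `drop_year_lag`) or `NULL`.
#' @export
detect_event <- function(mean_trw, spei, search_window, percentile = 0.10,
                         drop_threshold = 0.05) {
  thr <- unname(stats::quantile(spei$spei, percentile, type = 7))
  yrs <- search_window$first_allowed:search_window$last_allowed
  growth_drop_at <- function(y) {
    prev <- mean_trw$trw[mean_trw$year %in% (y - 4):(y - 1)]
    cur <- mean_trw$trw[mean_trw$year == y]
    if (length(prev) < 4 || length(cur) != 1) return(NA_real_)
    1 - cur / mean(prev)
  }
  hits <- list()
  for (y in yrs) {
    s <- spei$spei[spei$year == y]
    if (length(s) != 1 || s >= thr) next
    d0 <- growth_drop_at(y)
    d1 <- growth_drop_at(y + 1)
    lag <- if (isTRUE(d0 > drop_threshold)) 0L
           else if (isTRUE(d1 > drop_threshold)) 1L else NA_integer_
    if (is.na(lag)) next
    hits[[length(hits) + 1]] <- data.frame(
      year = y, spei_i = s, spei_threshold = thr,
      growth_drop = if (lag == 0L) d0 else d1, drop_year_lag = lag)
  }
  if (length(hits) == 0) return(NULL)
  hits <- do.call(rbind, hits)
  hits[which.min(hits$spei_i), , drop = FALSE]
}
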
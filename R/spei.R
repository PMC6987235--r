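# Multiscale SPEI from monthly precipitation and PET, plus the site aridity
# index. SPEI follows the classic recipe: k-month climatic water balance
# (P - PET), standardised through a 3-parameter log-logistic distribution
# fitted by unbiased probability-weighted moments, then mapped to standard
# normal quantiles. Negative SPEI = dry.

#' Monthly climatic water balance
#'
#' Element-wise difference between precipitation and potential
#' evapotranspiration, the quantity aggregated and standardised into SPEI.
#'
#' @param prcp numeric vector of monthly precipitation (mm).
#' @param pet numeric vector of monthly PET (mm), same length as `prcp`.
#' @return numeric vector `prcp - pet` (mm).
#' @export
water_balance <- function(prcp, pet) {
  if (length(prcp) != length(pet)) {
    stop("prcp and pet must have the same length (got ",
         length(prcp), " and ", length(pet), ")")
  }
  prcp - pet
}

#' Aggregate a monthly balance over a k-month window ending at a target month
#'
#' For each year the k monthly balances ending at (`year`, `target_month`) are
#' summed; the window crosses into the previous calendar year when
#' `scale_k` exceeds the target month index. Years without a complete k-month
#' history are dropped (not zero-filled).
#'
#' @param balance data frame with columns `year`, `month`, `d` (monthly
#'   balance, mm), covering consecutive months.
#' @param scale_k window length in months, 1..24.
#' @param target_month calendar month (1..12) the window ends in.
#' @param year_offset shift applied to the labelling year; used for
#'   southern-hemisphere windows ending in the calendar year before the ring
#'   year (e.g. December of the previous year has `year_offset = -1`).
#' @return data frame with columns `year`, `agg` (mm).
#' @export
aggregate_balance <- function(balance, scale_k, target_month, year_offset = 0) {
  stopifnot(scale_k >= 1, scale_k <= 24, target_month >= 1, target_month <= 12)
  ord <- order(balance$year, balance$month)
  d <- balance$d[ord]
  yr <- balance$year[ord]
  mo <- balance$month[ord]
  idx <- seq_along(d)
  # position of the target month in the flattened monthly sequence
  tgt <- idx[mo == target_month]
  keep <- tgt - scale_k + 1L >= 1L
  tgt <- tgt[keep]
  agg <- vapply(tgt, function(i) sum(d[(i - scale_k + 1L):i]), numeric(1))
  data.frame(year = yr[tgt] - year_offset, agg = agg)
}

# Unbiased probability-weighted moments a0, a1, a2 (weights (1-F)^s), the
# form the classic log-logistic SPEI parameter formulas expect.
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  a0 <- mean(x)
  a1 <- sum((n - i) / (n - 1) * x) / n
  a2 <- sum((n - i) * (n - i - 1) / ((n - 1) * (n - 2)) * x) / n
  c(a0 = a0, a1 = a1, a2 = a2)
}

# Fit the 3-parameter log-logistic distribution by PWM (the parameterisation
# standard in the SPEI literature). Negative shape values are the
# mirrored-skew branch of the same generalized-logistic family (scale and
# origin flip orientation; the CDF stays increasing), which left-skewed
# balance series require. Returns NULL when |shape| <= 1 (mean undefined).
loglogistic_pwm <- function(x) {
  pw <- pwm_unbiased(x)
  b0 <- pw[["a0"]]; b1 <- pw[["a1"]]; b2 <- pw[["a2"]]
  denom <- 6 * b1 - b0 - 6 * b2
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(NULL)
  beta <- (2 * b1 - b0) / denom
  if (!is.finite(beta) || abs(beta) <= 1) return(NULL)
  g <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (b0 - 2 * b1) * beta / g
  if (!is.finite(alpha) || alpha == 0 || sign(alpha) != sign(beta)) return(NULL)
  gam <- b0 - alpha * g
  list(shape = beta, scale = alpha, origin = gam)
}

ploglogistic <- function(x, fit) {
  p <- numeric(length(x))
  if (fit$shape > 0) {            # right-skew branch: support x > origin
    inside <- x > fit$origin
    p[!inside] <- 0
  } else {                        # mirrored branch: support x < origin
    inside <- x < fit$origin
    p[!inside] <- 1
  }
  p[inside] <- (1 + (fit$scale / (x[inside] - fit$origin))^fit$shape)^(-1)
  p
}

#' Standardise an aggregated water-balance series to SPEI
#'
#' Fits a 3-parameter log-logistic distribution to the calibration values by
#' unbiased probability-weighted moments, maps every value through the fitted
#' CDF and then the standard normal quantile function. Probabilities are
#' clamped to `[1e-8, 1 - 1e-8]` so SPEI values stay finite. When the PWM fit
#' degenerates, standardisation falls back to Gringorten empirical quantiles
#' with a warning.
#'
#' @param agg data frame with columns `year`, `agg` as returned by
#'   [aggregate_balance()].
#' @param calibration_span length-2 numeric, first and last calibration year;
#'   `NULL` (default) calibrates on the full series.
#' @return data frame with columns `year`, `spei`.
#' @export
standardize_loglogistic <- function(agg, calibration_span = NULL) {
  if (is.null(calibration_span)) {
    cal <- agg$agg
  } else {
    cal <- agg$agg[agg$year >= calibration_span[1] & agg$year <= calibration_span[2]]
  }
  if (length(cal) < 30) stop("need at least 30 calibration values, got ", length(cal))
  if (stats::sd(cal) == 0) stop("degenerate (constant) aggregated series")
  fit <- loglogistic_pwm(cal)
  if (is.null(fit)) {
    warning("log-logistic PWM fit degenerate; falling back to empirical quantiles")
    # Gringorten plotting positions on the calibration sample, interpolated
    r <- stats::approx(sort(cal), (seq_along(cal) - 0.44) / (length(cal) + 0.12),
                       xout = agg$agg, rule = 2)$y
    p <- r
  } else {
    p <- ploglogistic(agg$agg, fit)
  }
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  data.frame(year = agg$year, spei = stats::qnorm(p))
}

# Target-month table per hemisphere: five summer / early-autumn months ending
# the candidate windows. Southern set is the northern one phase-shifted by six
# months; December belongs to the calendar year before the ring year.
target_month_table <- function(hemisphere) {
  hemisphere <- match.arg(hemisphere, c("N", "S"))
  if (hemisphere == "N") {
    data.frame(target_month = 6:10, year_offset = 0L)
  } else {
    data.frame(target_month = c(12L, 1L, 2L, 3L, 4L),
               year_offset = c(-1L, 0L, 0L, 0L, 0L))
  }
}

#' Compute the full per-site SPEI grid
#'
#' 120 SPEI series per site: 5 target months (June-October in the northern
#' hemisphere; December of the previous year to April in the southern
#' hemisphere) times 24 aggregation scales (1-24 months).
#'
#' @param climate data frame with columns `year`, `month`, `prcp_mm`, `pet_mm`
#'   for one site, with full monthly coverage.
#' @param hemisphere `"N"` or `"S"`.
#' @param calibration_span optional length-2 calibration year range passed to
#'   [standardize_loglogistic()].
#' @return object of class `spei_grid`: a list with `entries` (named list of
#'   data frames keyed `"m<month>_s<scale>"`), `months` (target month table)
#'   and `calibration_span`.
#' @export
spei_grid <- function(climate, hemisphere = "N", calibration_span = NULL) {
  climate <- climate[order(climate$year, climate$month), ]
  yrs <- range(climate$year)
  expect <- (diff(yrs) + 1) * 12
  if (nrow(climate) != expect) {
    full <- paste(rep(yrs[1]:yrs[2], each = 12), 1:12)
    have <- paste(climate$year, climate$month)
    stop("missing months in climate series: ",
         paste(utils::head(setdiff(full, have), 5), collapse = ", "))
  }
  bal <- data.frame(year = climate$year, month = climate$month,
                    d = water_balance(climate$prcp_mm, climate$pet_mm))
  tm <- target_month_table(hemisphere)
  entries <- list()
  for (i in seq_len(nrow(tm))) {
    for (k in 1:24) {
      agg <- aggregate_balance(bal, k, tm$target_month[i], tm$year_offset[i])
      entries[[sprintf("m%02d_s%02d", tm$target_month[i], k)]] <-
        standardize_loglogistic(agg, calibration_span)
    }
  }
  structure(list(entries = entries, months = tm,
                 calibration_span = calibration_span),
            class = "spei_grid")
}

#' Look up one SPEI series from a grid
#'
#' @param grid a [spei_grid()] object.
#' @param target_month calendar month 1..12.
#' @param scale_k aggregation scale 1..24.
#' @return data frame with columns `year`, `spei`.
#' @export
spei_series <- function(grid, target_month, scale_k) {
  key <- sprintf("m%02d_s%02d", target_month, scale_k)
  out <- grid$entries[[key]]
  if (is.null(out)) stop("no SPEI entry for target month ", target_month,
                         ", scale ", scale_k)
  out
}

#' Site aridity index
#'
#' Ratio of mean annual precipitation to mean annual reference
#' evapotranspiration over a reference span (the 1970-2000 analogue).
#' Larger values indicate more humid conditions.
#'
#' @param climate data frame with columns `year`, `month`, `prcp_mm`, `pet_mm`.
#' @param span length-2 year range to average over.
#' @return single numeric aridity index (dimensionless, > 0).
#' @export
aridity_index <- function(climate, span = c(1970, 2000)) {
  sel <- climate$year >= span[1] & climate$year <= span[2]
  if (!any(sel)) stop("climate does not cover the aridity reference span")
  ann_p <- tapply(climate$prcp_mm[sel], climate$year[sel], sum)
  ann_pet <- tapply(climate$pet_mm[sel], climate$year[sel], sum)
  if (mean(ann_pet) <= 0) stop("mean annual PET must be positive")
  unname(mean(ann_p) / mean(ann_pet))
}
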
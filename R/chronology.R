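# Standardisation of individual ring-width series and site-level residual
# chronologies: smoothing-spline detrend (50% frequency response at 67% of
# series length), AR prewhitening with AIC order selection, mean-one scaling,
# and Tukey's biweight robust mean across trees.

# Stiffness of the second-difference penalised smoother giving frequency
# response `f` at wavelength `wl` (years). The discrete penalty has transfer
# function H(w) = 1 / (1 + 16 lambda sin^4(w/2)) away from the boundaries, so
# H = f at w = 2*pi/wl pins lambda analytically.
spline_lambda <- function(wl, f = 0.5) {
  (1 - f) / (f * 16 * sin(pi / wl)^4)
}

# Penalised least-squares smoother: minimises ||y - s||^2 + lambda ||D2 s||^2.
# Sparse banded solve, so long series stay cheap.
penalized_smooth <- function(y, lambda) {
  n <- length(y)
  if (n < 3) return(rep(mean(y), n))
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  as.vector(Matrix::solve(A, y))
}

#' Detrend a ring-width series with a smoothing spline
#'
#' Fits a stiff smoothing spline whose frequency response is 0.50 at a
#' wavelength of 67% of the series length (the classic dendrochronological
#' age/size-trend remover) and returns ratio indices `trw / fitted`.
#'
#' @param trw numeric vector of ring widths (mm), all positive, one value per
#'   consecutive year.
#' @param wavelength_frac fraction of the series length at which the frequency
#'   response is 0.5; default 0.67.
#' @param wavelength absolute cutoff wavelength in years; overrides
#'   `wavelength_frac` when given (useful for measuring the filter's
#'   frequency response on a long series).
#' @return list with `fitted` (the trend curve) and `index` (ratio indices).
#'   Series shorter than 15 years are rejected; a non-positive fitted value
#'   triggers a fallback to horizontal-mean detrending with a warning.
#' @export
spline_detrend <- function(trw, wavelength_frac = 0.67, wavelength = NULL) {
  n <- length(trw)
  if (n < 15) stop("series too short to detrend (", n, " < 15 years)")
  if (any(trw <= 0)) stop("ring widths must be positive")
  if (is.null(wavelength)) wavelength <- wavelength_frac * n
  lambda <- spline_lambda(wavelength)
  fitted <- penalized_smooth(trw, lambda)
  if (any(fitted <= 0)) {
    warning("non-positive spline fit; falling back to horizontal-mean detrend")
    fitted <- rep(mean(trw), n)
  }
  list(fitted = fitted, index = trw / fitted)
}

#' Prewhiten detrended indices with an autoregressive model
#'
#' Fits AR(p) by maximum likelihood with the order chosen by AIC among
#' 0..min(10, N/4) and returns the residuals re-centred on the series mean, so
#' low-order persistence is removed while the level is preserved.
#'
#' @param index numeric vector of detrended growth indices.
#' @return list with `residuals` (same length as input; the first `order`
#'   values are `NA`), `order`, and `coefficients`.
#' @export
ar_prewhiten <- function(index) {
  n <- length(index)
  if (n < 15) stop("need at least 15 observations to prewhiten")
  if (stats::sd(index) == 0) stop("zero-variance input")
  ord_max <- min(10L, floor(n / 4))
  fit <- stats::ar(index, aic = TRUE, order.max = ord_max, method = "mle")
  res <- as.vector(fit$resid) + mean(index)
  list(residuals = res, order = fit$order, coefficients = fit$ar)
}

#' Scale a series so its mean is exactly one
#'
#' @param x numeric vector (NAs allowed and preserved); the non-NA mean must
#'   be positive.
#' @return `x / mean(x, na.rm = TRUE)`.
#' @export
scale_to_mean_one <- function(x) {
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("mean must be positive to scale to one")
  x / m
}

#' Tukey's biweight robust mean
#'
#' Bounded-influence location estimate used to average individual residual
#' indices into a chronology. Iterates from the median with the biweight
#' function at tuning constant `tuning_c` (median +/- c * MAD support) until
#' the estimate moves by less than 1e-10, at most 50 iterations; if the MAD is
#' zero the median is returned.
#'
#' @param values numeric vector with at least one finite value.
#' @param tuning_c biweight tuning constant; dendro convention is 9.
#' @return single numeric robust mean, always within `range(values)`.
#' @export
biweight_mean <- function(values, tuning_c = 9) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values")
  if (length(values) == 1) return(values)
  m <- stats::median(values)
  s <- stats::median(abs(values - m))
  if (s == 0) return(m)
  for (it in 1:50) {
    u <- (values - m) / (tuning_c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m_new <- sum(w * values) / sum(w)
    if (abs(m_new - m) < 1e-10) return(m_new)
    m <- m_new
  }
  m
}

# Standardise one series: detrend, prewhiten, scale to mean one.
standardize_series <- function(trw) {
  det <- spline_detrend(trw)
  pw <- ar_prewhiten(det$index)
  scale_to_mean_one(pw$residuals)
}

#' Build the per-site residual chronology
#'
#' Standardises every usable ring series at a site (spline detrend, AR
#' prewhitening, mean-one scaling) and averages the individual residual
#' indices per year with Tukey's biweight robust mean. Both surviving and
#' now-dead trees contribute.
#'
#' @param dataset a `ring_dataset` from [assemble_dataset()] or
#'   [generate_dataset()].
#' @param site_id site identifier.
#' @param min_length minimum series length to standardise (default 15).
#' @return data frame of class `site_chronology` with columns `site_id`,
#'   `year`, `index`, `sample_depth` (rows restricted to years with at least
#'   one contributing tree).
#' @export
build_chronology <- function(dataset, site_id, min_length = 15) {
  series <- Filter(function(s) s$site_id == site_id, dataset$series)
  if (length(series) == 0) stop("no series at site ", site_id)
  idx_list <- list()
  for (s in series) {
    if (length(s$trw) < min_length) {
      warning("skipping ", s$tree_id, ": series shorter than ", min_length)
      next
    }
    idx_list[[s$tree_id]] <- data.frame(year = s$years,
                                        index = standardize_series(s$trw))
  }
  if (length(idx_list) == 0) stop("no usable series at site ", site_id)
  all_years <- sort(unique(unlist(lapply(idx_list, `[[`, "year"))))
  index <- numeric(length(all_years))
  depth <- integer(length(all_years))
  for (i in seq_along(all_years)) {
    v <- unlist(lapply(idx_list, function(d) d$index[d$year == all_years[i]]))
    v <- v[is.finite(v)]
    depth[i] <- length(v)
    index[i] <- if (length(v)) biweight_mean(v) else NA_real_
  }
  keep <- depth >= 1
  out <- data.frame(site_id = site_id, year = all_years[keep],
                    index = index[keep], sample_depth = depth[keep])
  class(out) <- c("site_chronology", class(out))
  out
}
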
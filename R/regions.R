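#' Default atmospheric regions
#'
#' Closed wavenumber intervals (cm^-1) used by the standard pipeline: the CO2
#' asymmetric-stretch region, removed/interpolated before baseline correction
#' and trimmed again after it, and the high-wavenumber water-vapor region,
#' removed outright. Bounds are conventional choices and are configurable in
#' every caller.
#'
#' @return A numeric vector `c(lo, hi)`.
#' @export
co2_region <- function() c(2300, 2400)

#' @rdname co2_region
#' @export
water_vapor_region <- function() c(3650, 3800)

region_index <- function(wn, region) {
  stopifnot(length(region) == 2L, region[1] < region[2])
  which(wn >= region[1] & wn <= region[2])
}

#' Remove a spectral region
#'
#' Drops every axis point inside the closed interval `region` from the axis
#' and the absorbance matrix; surviving columns keep their order.
#'
#' @param set A `spectra_set`.
#' @param region Numeric `c(lo, hi)` in cm^-1.
#' @return A `spectra_set` without the region. A region disjoint from the
#'   axis is a no-op with a warning.
#' @export
remove_region <- function(set, region) {
  idx <- region_index(set$wavenumber, region)
  if (length(idx) == 0L) {
    warning("region [", region[1], ", ", region[2],
            "] does not overlap the axis; returning input unchanged")
    return(set)
  }
  spectra_set(set$absorbance[, -idx, drop = FALSE], set$wavenumber[-idx],
              labels = set$labels, ids = set$ids, meta = set$meta)
}

#' @rdname remove_region
#' @details `trim_region()` is the identical operation applied after baseline
#'   correction (the CO2 gap is first interpolated so baseline methods see a
#'   contiguous axis, then trimmed again).
#' @export
trim_region <- function(set, region) remove_region(set, region)

#' Linearly interpolate across a spectral region
#'
#' Replaces values inside the closed interval by the straight line between
#' the nearest flanking axis points, per spectrum. The axis is unchanged.
#'
#' @inheritParams remove_region
#' @return A `spectra_set`.
#' @export
interpolate_region <- function(set, region) {
  wn <- set$wavenumber
  idx <- region_index(wn, region)
  if (length(idx) == 0L) return(set)
  lo <- min(idx) - 1L
  hi <- max(idx) + 1L
  if (lo < 1L || hi > length(wn))
    stop("region touches the axis boundary; no flanking point to ",
         "interpolate from", call. = FALSE)
  A <- set$absorbance
  w <- (wn[idx] - wn[lo]) / (wn[hi] - wn[lo])
  A[, idx] <- outer(A[, lo], 1 - w) + outer(A[, hi], w)
  set_absorbance(set, A)
}

#' Estimate the base acquisition noise level
#'
#' Per-spectrum standard deviation of the residual after a linear detrend in
#' a signal-free window (default 1750-1800 cm^-1), summarized by the median
#' across spectra. Used as the default `sigma_base` of [add_scan_noise()].
#'
#' @param set A `spectra_set`.
#' @param window Numeric `c(lo, hi)` in cm^-1.
#' @return A single non-negative number (absorbance units).
#' @export
estimate_noise_sigma <- function(set, window = c(1750, 1800)) {
  idx <- region_index(set$wavenumber, window)
  if (length(idx) < 4L)
    stop("noise window contains fewer than 4 axis points", call. = FALSE)
  x <- set$wavenumber[idx]
  sds <- apply(set$absorbance[, idx, drop = FALSE], 1L, function(y) {
    stats::sd(stats::lm.fit(cbind(1, x), y)$residuals)
  })
  stats::median(sds)
}

#' Add scan-count-equivalent white noise
#'
#' FT-IR noise scales as 1/sqrt(number of co-added scans). To emulate an
#' acquisition with fewer scans, i.i.d. zero-mean Gaussian noise with
#' `sigma_add = sigma_base * sqrt(scans_base / scans_target - 1)` is added,
#' so the total noise level matches `scans_target` acquisitions (independent
#' variances add).
#'
#' @param set A `spectra_set`.
#' @param scans_target Emulated scan count (default 32).
#' @param scans_base Scan count of the input data (default 256).
#' @param sigma_base Base noise standard deviation in absorbance units;
#'   estimated via [estimate_noise_sigma()] when `NULL`.
#' @param seed Integer seed for the noise stream; recorded in `meta`.
#' @return A `spectra_set` with noise added; `meta$noise` records the seed,
#'   `sigma_add`, and scan counts.
#' @export
add_scan_noise <- function(set, scans_target = 32, scans_base = 256,
                           sigma_base = NULL, seed = 1L) {
  if (scans_target > scans_base)
    stop("scans_target must not exceed scans_base", call. = FALSE)
  if (is.null(sigma_base)) sigma_base <- estimate_noise_sigma(set)
  if (sigma_base < 0) stop("sigma_base must be >= 0", call. = FALSE)
  sigma_add <- sigma_base * sqrt(scans_base / scans_target - 1)
  A <- set$absorbance
  if (sigma_add > 0) {
    rng <- local_rng(seed)
    A <- A + matrix(rng$rnorm(length(A), sd = sigma_add), nrow(A), ncol(A))
  }
  meta <- set$meta
  meta$noise <- list(seed = seed, sigma_base = sigma_base,
                     sigma_add = sigma_add, scans_base = scans_base,
                     scans_target = scans_target)
  set_absorbance(set, A, meta = meta)
}

# Seeded RNG stream isolated from the global state: every stochastic
# spectra_set operation draws from its own stream so results are reproducible
# per (operation, seed) without perturbing the caller's RNG.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  draw <- function(f, ...) {
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    restore()
    out
  }
  restore()
  list(
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rlnorm = function(n, meanlog = 0, sdlog = 1)
      draw(stats::rlnorm, n, meanlog, sdlog),
    sample_int = function(n, size) draw(sample.int, n, size)
  )
}

#' Normalize a whole dataset to its global maximum
#'
#' Divides every value by the single global maximum of the set (the
#' exploration-time scaling applied before stacking preprocessing variants
#' for PCA). The output's global maximum is exactly 1.
#'
#' @param set A `spectra_set`.
#' @return A `spectra_set`.
#' @export
max_normalize_dataset <- function(set) {
  m <- max(set$absorbance)
  if (!is.finite(m) || m <= 0)
    stop("dataset global maximum must be positive, got ", m, call. = FALSE)
  set_absorbance(set, set$absorbance / m)
}
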
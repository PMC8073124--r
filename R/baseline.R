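#' Default anchor frequencies for interval-based baseline methods
#'
#' Nine spectroscopically chosen frequencies (cm^-1) bounding the intervals
#' of the rubber-band correction and anchoring the polynomial fit.
#'
#' @return Sorted numeric vector of length 9.
#' @export
default_anchors <- function() {
  c(1001, 1280, 1302, 1761, 1977, 2412, 2825, 2997, 3519)
}

#' Savitzky-Golay second derivative (DER baseline correction)
#'
#' Fits a local polynomial over a moving window and returns its second
#' derivative at each point, scaled by the axis spacing squared. The
#' derivative spectrum replaces the original: slowly varying (baseline)
#' components are annihilated. Study grid: degrees \{2, 3\} by odd frames
#' 19..29 (12 combinations).
#'
#' @param y Numeric vector.
#' @param poly_degree 2 or 3.
#' @param frame Odd window length, `> poly_degree`.
#' @param spacing Axis spacing (cm^-1) used to scale the derivative;
#'   default 1 gives the per-point derivative.
#' @return Second-derivative vector of the same length.
#' @export
savgol_second_derivative <- function(y, poly_degree, frame, spacing = 1) {
  check_savgol(length(y), poly_degree, frame)
  signal::sgolayfilt(y, p = poly_degree, n = frame, m = 2, ts = spacing)
}

#' Rubber-band baseline correction
#'
#' In each interval bounded by consecutive anchor frequencies the spectrum
#' minimum is located; the minima are joined by piecewise-linear
#' interpolation over the full axis (extended flat beyond the terminal
#' minima) and subtracted.
#'
#' @param y Numeric vector (one spectrum).
#' @param axis Wavenumber axis matching `y`.
#' @param anchors Interval-bounding frequencies, see [default_anchors()].
#' @return List with `corrected` and `baseline` vectors.
#' @export
rubberband_correct <- function(y, axis, anchors = default_anchors()) {
  anchors <- sort(anchors)
  if (length(anchors) < 2L) stop("need >= 2 anchors", call. = FALSE)
  min_x <- numeric(0); min_y <- numeric(0)
  for (k in seq_len(length(anchors) - 1L)) {
    idx <- which(axis >= anchors[k] & axis <= anchors[k + 1L])
    if (length(idx) < 1L)
      stop("anchor interval [", anchors[k], ", ", anchors[k + 1L],
           "] contains no axis point", call. = FALSE)
    j <- idx[which.min(y[idx])]
    min_x <- c(min_x, axis[j]); min_y <- c(min_y, y[j])
  }
  baseline <- if (length(min_x) < 2L) rep(min_y, length(axis)) else
    stats::approx(min_x, min_y, xout = axis, rule = 2)$y
  list(corrected = y - baseline, baseline = baseline)
}

#' Anchored polynomial baseline correction (POL)
#'
#' Least-squares polynomial of the chosen degree through the spectrum values
#' at the anchor frequencies (nearest axis points), evaluated over the full
#' axis and subtracted. Study grid: degrees 3..5.
#'
#' @inheritParams rubberband_correct
#' @param degree Polynomial degree, `< length(anchors)`.
#' @return List with `corrected` and `baseline`.
#' @export
polynomial_fit_correct <- function(y, axis, anchors = default_anchors(),
                                   degree = 3) {
  if (degree >= length(anchors))
    stop("degree must be < number of anchors", call. = FALSE)
  j <- vapply(anchors, function(a) which.min(abs(axis - a)), integer(1))
  # centered/scaled axis for conditioning
  t <- (axis - mean(axis)) / (diff(range(axis)) / 2)
  X <- stats::poly(t[j], degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), y[j])
  baseline <- cbind(1, stats::poly(t, degree = degree, raw = TRUE)) %*%
    fit$coefficients
  baseline <- as.numeric(baseline)
  list(corrected = y - baseline, baseline = baseline)
}

#' Asymmetric least squares (ALS) baseline estimation
#'
#' Iterates the weighted Whittaker solve
#' `z = (W + lambda D'D)^{-1} W y` with the asymmetric weight update
#' `w_i = p` where `y_i > z_i` and `w_i = 1 - p` where `y_i <= z_i`, so the
#' smooth curve `z` hugs the lower envelope (the baseline) of a
#' peak-dominated spectrum. Stops when the weights stabilize or after
#' `max_iter` iterations. Study grid: `p = 0.1`,
#' `lambda` in \{1e6, 1e7, 1e8\}.
#'
#' @param y Numeric vector.
#' @param lambda Positive smoothing weight.
#' @param p Asymmetry parameter in (0, 1).
#' @param max_iter Iteration cap (default 50).
#' @return List with `baseline`, `corrected` (= y - baseline), `iterations`,
#'   and `converged` (weights stable before the cap).
#' @export
als_baseline <- function(y, lambda, p = 0.1, max_iter = 50L) {
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  n <- length(y)
  DtD <- lambda * whittaker_penalty(n)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M <- Matrix::Diagonal(n, w) + DtD
    z <- as.numeric(Matrix::solve(M, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) { converged <- TRUE; break }
    w <- w_new
  }
  list(baseline = z, corrected = y - z, iterations = it,
       converged = converged)
}

#' Apply a baseline correction to every spectrum of a set
#'
#' @param set A `spectra_set`.
#' @param method One of `"DER"`, `"RB"`, `"POL"`, `"ALS"`, `"RMIE"`,
#'   `"MEEMSC"`.
#' @param params Named list: `poly_degree` + `frame` (DER), `anchors` (RB,
#'   POL), `degree` (POL), `lambda` + `p` (ALS), [mie_params()] fields and
#'   an optional `reference` `spectra_set` (RMIE/MEEMSC).
#' @return A `spectra_set` (for DER, of second-derivative spectra).
#' @export
baseline_correct <- function(set, method, params = list()) {
  axis <- set$wavenumber
  anchors <- params$anchors %||% default_anchors()
  switch(method,
    DER = {
      h <- mean(diff(axis))
      set_absorbance(set, t(apply(set$absorbance, 1L, function(y)
        savgol_second_derivative(y, params$poly_degree, params$frame,
                                 spacing = h))))
    },
    RB = set_absorbance(set, t(apply(set$absorbance, 1L, function(y)
      rubberband_correct(y, axis, anchors)$corrected))),
    POL = set_absorbance(set, t(apply(set$absorbance, 1L, function(y)
      polynomial_fit_correct(y, axis, anchors,
                             params$degree %||% 3)$corrected))),
    ALS = set_absorbance(set, t(apply(set$absorbance, 1L, function(y)
      als_baseline(y, params$lambda, params$p %||% 0.1)$corrected))),
    RMIE = rmie_emsc(set, reference = params$reference,
                     params = params$mie %||% mie_params()),
    MEEMSC = me_emsc(set, reference = params$reference,
                     params = params$mie %||% mie_params()),
    stop("unknown baseline method: ", method, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
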
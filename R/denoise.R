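#' Whittaker (Eilers) smoother
#'
#' Returns the vector `z` minimizing
#' `sum((y - z)^2) + lambda * sum((diff(z, differences = 2))^2)`
#' (all observation weights equal to one, second-order difference penalty),
#' solved through a sparse banded linear system
#' `(I + lambda * D'D) z = y`. Used as the EIL denoiser with the integer
#' smoothing-weight grid 2..24.
#'
#' @param y Numeric vector, length >= 4, all finite.
#' @param lambda Positive smoothing weight.
#' @return Smoothed vector of the same length.
#' @export
whittaker_smooth <- function(y, lambda) {
  if (!all(is.finite(y))) stop("y must be finite", call. = FALSE)
  n <- length(y)
  if (n < 4L) stop("y must have length >= 4", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  DtD <- whittaker_penalty(n)
  M <- Matrix::Diagonal(n) + lambda * DtD
  as.numeric(Matrix::solve(M, y))
}

# lambda-free part of the penalized system, cached by length
whittaker_penalty <- function(n) {
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  Matrix::crossprod(D)
}

#' Savitzky-Golay smoother
#'
#' Each point is replaced by the center value of the local least-squares
#' polynomial of degree `poly_degree` fitted over a moving window of
#' `frame` points; endpoints come from the polynomial fits of the terminal
#' windows. Thin wrapper over [signal::sgolayfilt()]. The study grid is
#' degrees \{2, 3\} by odd frames 11..29 (20 combinations).
#'
#' @param y Numeric vector.
#' @param poly_degree Polynomial degree (typically 2 or 3).
#' @param frame Odd window length in points, `poly_degree < frame <=
#'   length(y)`.
#' @return Smoothed vector.
#' @export
savgol_smooth <- function(y, poly_degree, frame) {
  check_savgol(length(y), poly_degree, frame)
  signal::sgolayfilt(y, p = poly_degree, n = frame, m = 0)
}

check_savgol <- function(n, poly_degree, frame) {
  if (frame %% 2L == 0L) stop("frame must be odd", call. = FALSE)
  if (frame <= poly_degree)
    stop("frame must exceed poly_degree", call. = FALSE)
  if (frame > n) stop("frame exceeds spectrum length", call. = FALSE)
  invisible(TRUE)
}

#' Fourier low-pass denoiser
#'
#' Transforms the spectrum with the discrete Fourier transform, keeps the
#' `window` lowest one-sided frequency components (the zero-frequency term
#' plus the first `window - 1` positive frequencies and their conjugate
#' mirrors), zeroes the rest, and inverse-transforms. The study grid uses
#' windows of 100 and 320 points.
#'
#' @param y Numeric vector.
#' @param window Number of retained low-frequency components (>= 1),
#'   counting the zero-frequency term; values beyond the spectrum length are
#'   clamped with a warning. A window of at least `floor(n/2) + 1` retains
#'   everything.
#' @return Denoised real vector.
#' @export
fourier_denoise <- function(y, window) {
  n <- length(y)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > n) {
    warning("window ", window, " exceeds spectrum length ", n, "; clamped")
    window <- n
  }
  Y <- stats::fft(y)
  freq <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))  # signed index
  keep <- abs(freq) < window
  Y[!keep] <- 0
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Apply a denoiser to every spectrum of a set
#'
#' @param set A `spectra_set`.
#' @param method `"EIL"`, `"SG"`, or `"FT"`.
#' @param params Named list of method parameters: `lambda` (EIL),
#'   `poly_degree` + `frame` (SG), `window` (FT).
#' @return A `spectra_set`.
#' @export
denoise_spectra <- function(set, method, params = list()) {
  f <- switch(method,
    EIL = function(y) whittaker_smooth(y, params$lambda),
    SG = function(y) savgol_smooth(y, params$poly_degree, params$frame),
    FT = function(y) fourier_denoise(y, params$window),
    stop("unknown denoise method: ", method, call. = FALSE)
  )
  set_absorbance(set, t(apply(set$absorbance, 1L, f)))
}
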
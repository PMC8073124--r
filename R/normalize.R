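#' Normalization to a constant band (CON)
#'
#' Divides each spectrum by the absolute value of its absorbance at the axis
#' point nearest `target` (default the Amide I band, 1656 cm^-1). For
#' ordinary positive spectra the target point becomes exactly 1; for
#' second-derivative spectra the division by the absolute value preserves
#' the derivative's sign (the target point becomes +/-1).
#'
#' @param set A `spectra_set`.
#' @param target Target wavenumber in cm^-1, within the axis range.
#' @param window When non-`NULL`, a `c(lo, hi)` window: the per-spectrum
#'   maximum inside it is used instead of the fixed nearest point.
#' @return A `spectra_set`.
#' @export
constant_normalize <- function(set, target = 1656, window = NULL) {
  wn <- set$wavenumber
  if (target < min(wn) || target > max(wn))
    stop("target ", target, " outside the axis range", call. = FALSE)
  A <- set$absorbance
  if (is.null(window)) {
    j <- which.min(abs(wn - target))
    v <- A[, j]
  } else {
    idx <- region_index(wn, window)
    v <- apply(A[, idx, drop = FALSE], 1L, max)
  }
  bad <- which(v == 0)
  if (length(bad))
    stop("zero absorbance at the normalization point for spectrum ",
         paste(set$ids[bad], collapse = ", "), call. = FALSE)
  set_absorbance(set, A / abs(v))
}

#' Total sum normalization (TSN)
#'
#' Divides each spectrum by the sum of the absolute values of its
#' absorbances (identical to the plain sum for non-negative spectra, and
#' well defined for derivative spectra). Output absolute values sum to 1.
#'
#' @param set A `spectra_set`.
#' @return A `spectra_set`.
#' @export
total_sum_normalize <- function(set) {
  s <- rowSums(abs(set$absorbance))
  bad <- which(s == 0)
  if (length(bad))
    stop("zero total absorbance for spectrum ",
         paste(set$ids[bad], collapse = ", "), call. = FALSE)
  set_absorbance(set, set$absorbance / s)
}

#' Probabilistic quotient normalization (PQN)
#'
#' The standard spectrum is the feature-wise mean of the given set. Per
#' spectrum, quotients `x_i / x_s` are formed on the features where the
#' standard's magnitude exceeds a floor (`1e-8 * max|x_s|`, guarding
#' near-zero baseline-corrected regions), and the spectrum is divided by
#' the median quotient. The standard is computed within the given set only,
#' so calibration and test sets are normalized independently — which is why
#' PQN can behave differently on a small test set than on the set it was
#' explored on.
#'
#' @param set A `spectra_set` with at least 2 spectra.
#' @return A `spectra_set`.
#' @export
pqn_normalize <- function(set) {
  A <- set$absorbance
  if (nrow(A) < 2L) stop("PQN needs >= 2 spectra", call. = FALSE)
  xs <- colMeans(A)
  keep <- abs(xs) > 1e-8 * max(abs(xs))
  if (sum(keep) < ncol(A) / 2)
    warning("standard spectrum near zero on a majority of features")
  f <- apply(A[, keep, drop = FALSE], 1L, function(x)
    stats::median(x / xs[keep]))
  bad <- which(!is.finite(f) | f == 0)
  if (length(bad))
    stop("non-finite or zero PQN scaling factor for spectrum ",
         paste(set$ids[bad], collapse = ", "), call. = FALSE)
  set_absorbance(set, A / f)
}

#' Apply a normalization to a set
#'
#' @param set A `spectra_set`.
#' @param method `"CON"`, `"TSN"`, or `"PQN"`.
#' @param params Named list (`target` for CON).
#' @return A `spectra_set`.
#' @export
normalize_spectra <- function(set, method, params = list()) {
  switch(method,
    CON = constant_normalize(set, target = params$target %||% 1656),
    TSN = total_sum_normalize(set),
    PQN = pqn_normalize(set),
    stop("unknown normalization method: ", method, call. = FALSE)
  )
}
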
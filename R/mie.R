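#' Mie-EMSC engine parameters
#'
#' @param diameter_um Scattering-particle diameter bounds in micrometers
#'   (default `c(2, 8)`).
#' @param ref_index Refractive-index bounds of the sphere (default
#'   `c(1.1, 1.4)`).
#' @param fluct_scale Scale applied to the normalized Kramers-Kronig
#'   refractive-index fluctuation of the reference when composing the
#'   resonant phase term.
#' @param grid_size Samples per physical parameter; the curve family has
#'   `grid_size^2` members.
#' @param n_basis Principal components retained from the curve family
#'   (default 7).
#' @param n_iter Fixed iteration count of the RMie variant (default 5).
#' @param tol Relative stop tolerance of the ME variant (default 1e-4).
#' @param max_iter Iteration cap of the ME variant (default 30).
#' @param damping Reference-update damping of the ME variant: the next
#'   reference is `damping * previous + (1 - damping) * corrected`.
#' @return A named list.
#' @export
mie_params <- function(diameter_um = c(2, 8), ref_index = c(1.1, 1.4),
                       fluct_scale = 0.1, grid_size = 10L, n_basis = 7L,
                       n_iter = 5L, tol = 1e-4, max_iter = 30L,
                       damping = 0.5) {
  stopifnot(diameter_um[1] < diameter_um[2], n_basis >= 1L,
            n_iter >= 1L, tol > 0)
  list(diameter_um = diameter_um, ref_index = ref_index,
       fluct_scale = fluct_scale, grid_size = as.integer(grid_size),
       n_basis = as.integer(n_basis), n_iter = as.integer(n_iter),
       tol = tol, max_iter = as.integer(max_iter), damping = damping)
}

#' Kramers-Kronig refractive-index fluctuation
#'
#' The real refractive index of an absorbing medium fluctuates around its
#' background value with a dispersive line shape linked to the absorption
#' by the Kramers-Kronig relation. This returns that fluctuation as the
#' discrete Hilbert transform (FFT implementation) of the absorbance-derived
#' imaginary part, re-centered to zero mean.
#'
#' @param absorbance Finite numeric vector.
#' @return Zero-mean vector of the same length.
#' @export
kk_fluctuation <- function(absorbance) {
  if (!all(is.finite(absorbance))) stop("input must be finite", call. = FALSE)
  n <- length(absorbance)
  if (n < 2L) return(rep(0, n))
  Y <- stats::fft(absorbance)
  freq <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
  h <- Re(stats::fft(Y * (-1i * sign(freq)), inverse = TRUE)) / n
  h - mean(h)
}

#' Van de Hulst extinction efficiency
#'
#' Anomalous-diffraction approximation of the Mie extinction efficiency of
#' a sphere as a function of the phase parameter `rho`:
#' `Q(rho) = 2 - (4 / rho) sin(rho) + (4 / rho^2) (1 - cos(rho))`,
#' with the analytic limit `Q(0) = 0`. Oscillates toward the asymptote 2.
#'
#' @param rho Non-negative numeric vector.
#' @return Vector of extinction efficiencies.
#' @export
vandehulst_qext <- function(rho) {
  if (any(rho < 0)) stop("rho must be >= 0", call. = FALSE)
  q <- numeric(length(rho))
  # below ~0.01 the closed form cancels catastrophically; use the series
  # Q = rho^2/2 - rho^4/36 + O(rho^6)
  small <- rho < 1e-2
  q[small] <- rho[small]^2 / 2 - rho[small]^4 / 36
  r <- rho[!small]
  q[!small] <- 2 - (4 / r) * sin(r) + (4 / r^2) * (1 - cos(r))
  q
}

#' Build a PCA basis of Mie extinction curves
#'
#' For each (diameter, refractive-index) pair on a `grid_size x grid_size`
#' grid, composes the phase parameter
#' `rho(nu) = 2 pi d nu (n - 1 + fluct_scale * nkk(nu))` — where `nkk` is
#' the Kramers-Kronig fluctuation of the reference scaled to unit maximum
#' modulus — evaluates [vandehulst_qext()], mean-centers the curve family,
#' and returns the top `n_basis` orthonormal principal-component loadings.
#'
#' @param reference Reference spectrum (numeric vector, positive somewhere).
#' @param axis Wavenumber axis in cm^-1.
#' @param params [mie_params()].
#' @return List of class `mie_basis`: `loadings` (`n_basis x n_variables`,
#'   rows orthonormal), `explained_variance` (non-increasing), `center`
#'   (family mean curve).
#' @export
build_mie_basis <- function(reference, axis, params = mie_params()) {
  if (max(reference) <= 0)
    stop("reference must be positive somewhere", call. = FALSE)
  nkk <- kk_fluctuation(reference)
  m <- max(abs(nkk))
  if (m > 0) nkk <- nkk / m
  ds <- seq(params$diameter_um[1], params$diameter_um[2],
            length.out = params$grid_size)
  ns <- seq(params$ref_index[1], params$ref_index[2],
            length.out = params$grid_size)
  fam <- matrix(0, params$grid_size^2, length(axis))
  r <- 1L
  for (d in ds) for (nn in ns) {
    dn <- pmax(nn - 1 + params$fluct_scale * nkk, 0)
    rho <- 2 * pi * (d * 1e-4) * axis * dn
    fam[r, ] <- vandehulst_qext(rho)
    r <- r + 1L
  }
  center <- colMeans(fam)
  famc <- sweep(fam, 2L, center)
  sv <- svd(famc, nu = 0, nv = params$n_basis)
  ev <- sv$d^2 / (nrow(fam) - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  nb <- params$n_basis
  if (rank < nb) {
    warning("curve family rank ", rank, " < n_basis ", nb,
            "; reducing basis size")
    nb <- rank
  }
  structure(list(loadings = t(sv$v[, seq_len(nb), drop = FALSE]),
                 explained_variance = ev[seq_len(nb)],
                 center = center),
            class = "mie_basis")
}

#' Extended multiplicative signal correction fit
#'
#' Least-squares decomposition
#' `y ~ b * reference + a * 1 + sum_k g_k * loading_k`; the corrected
#' spectrum is `(y - a - sum_k g_k * loading_k) / b`, i.e. the additive
#' (constant + interferent) components are removed and the multiplicative
#' coefficient divided out.
#'
#' @param y Spectrum to correct.
#' @param reference Reference spectrum, same length.
#' @param basis Optional `mie_basis` of interferent loadings.
#' @return List with `corrected` and `coefficients`
#'   (`b`, `a`, `g` vector).
#' @export
emsc_fit <- function(y, reference, basis = NULL) {
  if (length(y) != length(reference))
    stop("y and reference lengths differ", call. = FALSE)
  G <- if (is.null(basis)) NULL else t(basis$loadings)
  X <- cbind(reference, 1, G)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  b <- cf[1]
  if (!is.finite(b) || abs(b) < 1e-8)
    stop("multiplicative coefficient |b| < 1e-8: EMSC model not ",
         "identifiable for this spectrum", call. = FALSE)
  a <- cf[2]
  g <- if (is.null(G)) numeric(0) else cf[-(1:2)]
  interf <- if (is.null(G)) 0 else as.numeric(G %*% g)
  list(corrected = (y - a - interf) / b,
       coefficients = list(b = unname(b), a = unname(a), g = unname(g)))
}

mie_correct_one <- function(y, reference, axis, params, fixed_iters,
                            damping = 0) {
  ref <- reference
  it <- 0L
  corrected <- y
  repeat {
    it <- it + 1L
    basis <- build_mie_basis(ref, axis, params)
    new_corr <- emsc_fit(y, ref, basis)$corrected
    delta <- sqrt(mean((new_corr - corrected)^2)) /
      max(sqrt(mean(corrected^2)), 1e-12)
    corrected <- new_corr
    if (!is.na(fixed_iters)) {
      if (it >= fixed_iters) break
      ref <- corrected
    } else {
      if (delta < params$tol || it >= params$max_iter) break
      ref <- damping * ref + (1 - damping) * corrected
    }
  }
  list(corrected = corrected, iterations = it)
}

mie_emsc_apply <- function(set, reference, params, fixed_iters, damping,
                           tag) {
  if (is.null(reference)) reference <- generate_reference(set$wavenumber)
  refv <- if (inherits(reference, "spectra_set"))
    as.numeric(reference$absorbance[1, ]) else as.numeric(reference)
  if (length(refv) != n_variables(set))
    stop("reference length does not match the set axis", call. = FALSE)
  A <- set$absorbance
  iters <- integer(nrow(A))
  failed <- character(0)
  for (i in seq_len(nrow(A))) {
    res <- tryCatch(
      mie_correct_one(A[i, ], refv, set$wavenumber, params, fixed_iters,
                      damping),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- c(failed, set$ids[i])
      message(tag, ": spectrum ", set$ids[i], " passed through uncorrected (",
              conditionMessage(res), ")")
      iters[i] <- 0L
    } else {
      A[i, ] <- res$corrected
      iters[i] <- res$iterations
    }
  }
  meta <- set$meta
  meta[[tag]] <- list(iterations = iters, failed = failed, params = params)
  set_absorbance(set, A, meta = meta)
}

#' Resonant-Mie EMSC correction (fixed iteration count)
#'
#' Per spectrum, iterates \{build the Mie curve basis from the current
#' reference -> EMSC fit -> take the corrected spectrum as the next
#' reference\} exactly `n_iter` times (default 5). A spectrum whose EMSC fit
#' fails is passed through uncorrected and flagged in `meta`.
#'
#' @param set A `spectra_set`.
#' @param reference Reference spectrum (`spectra_set` or numeric vector) on
#'   the same axis; a synthetic protein-matrix stand-in
#'   ([generate_reference()]) when `NULL`.
#' @param params [mie_params()].
#' @return Corrected `spectra_set`; iteration diagnostics in `meta$rmie`.
#' @export
rmie_emsc <- function(set, reference = NULL, params = mie_params()) {
  mie_emsc_apply(set, reference, params, fixed_iters = params$n_iter,
                 damping = 0, tag = "rmie")
}

#' Mie-extinction EMSC correction (converged, damped)
#'
#' Same engine as [rmie_emsc()] but iterates until the relative root mean
#' square change of the corrected spectrum falls below `tol` (default 1e-4)
#' or `max_iter` (default 30) iterations, with the reference update damped
#' (`damping` blend of the previous reference and the corrected spectrum)
#' for stability. Default scattering-diameter bounds are 2 and 8 um.
#'
#' @inheritParams rmie_emsc
#' @return Corrected `spectra_set`; diagnostics in `meta$meemsc`.
#' @export
me_emsc <- function(set, reference = NULL, params = mie_params()) {
  mie_emsc_apply(set, reference, params, fixed_iters = NA,
                 damping = params$damping, tag = "meemsc")
}
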
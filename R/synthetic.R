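#' Evenly spaced wavenumber axis
#'
#' @param lo,hi Interval bounds in cm^-1 (`lo < hi`).
#' @param n_points Number of points (>= 8). The study-shaped default axis is
#'   1582 points over 900-3800 cm^-1.
#' @return Numeric vector from `lo` to `hi` inclusive.
#' @export
make_axis <- function(lo = 900, hi = 3800, n_points = 1582) {
  if (n_points < 8L) stop("n_points must be >= 8", call. = FALSE)
  if (!(lo < hi)) stop("lo must be < hi", call. = FALSE)
  seq(lo, hi, length.out = n_points)
}

#' Band specification
#'
#' One vibrational band as a Gaussian or Lorentzian profile.
#'
#' @param center Band center, cm^-1.
#' @param width Full width at half maximum, cm^-1 (> 0).
#' @param amplitude Peak absorbance (>= 0).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A one-row tibble; `band_profile()` evaluates a set of bands on an
#'   axis.
#' @export
band <- function(center, width, amplitude, shape = "gaussian") {
  stopifnot(width > 0, amplitude >= 0,
            shape %in% c("gaussian", "lorentzian"))
  tibble::tibble(center = center, width = width, amplitude = amplitude,
                 shape = shape)
}

#' @rdname band
#' @param bands A tibble of bands (rows from [band()]).
#' @param axis Wavenumber axis.
#' @export
band_profile <- function(bands, axis) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    c0 <- bands$center[i]; w <- bands$width[i]; a <- bands$amplitude[i]
    if (bands$shape[i] == "gaussian") {
      s <- w / (2 * sqrt(2 * log(2)))
      y <- y + a * exp(-((axis - c0)^2) / (2 * s^2))
    } else {
      g <- w / 2
      y <- y + a * g^2 / ((axis - c0)^2 + g^2)
    }
  }
  y
}

# Protein bands shared by every cell class (Amide I/II/III/A/B, CH
# stretches); class profiles add class-specific amplitudes on top.
shared_bands <- function() {
  dplyr::bind_rows(
    band(1656, 45, 1.00),            # Amide I
    band(1545, 48, 0.62),            # Amide II
    band(1310, 60, 0.12),            # Amide III
    band(1398, 45, 0.20),            # COO- symmetric stretch
    band(3290, 130, 0.38),           # Amide A
    band(3070, 70, 0.10)             # Amide B
  )
}

#' Default class profiles for the synthetic study
#'
#' Five cell classes with 14/7/7/10/10 spectra: one benign line, one primary
#' tumor line, three metastatic lines. All classes share the protein bands
#' (Amide I 1656, Amide II 1545, Amide A 3290, Amide B 3070 cm^-1);
#' class-specific amplitudes in the nucleic-acid (944-1140 cm^-1) and
#' CH2/CH3 stretch (2800-3000 cm^-1) regions increase along the assumed
#' malignancy progression, so classes are separable but overlapping and a
#' monotone class-coded regression target is meaningful.
#'
#' @return A list of profiles, each a list with `name`, `bands` (tibble),
#'   `n_spectra`, `amplitude_jitter` (relative log-normal sd), and
#'   `center_jitter` (cm^-1 sd).
#' @export
default_profiles <- function() {
  # per-class amplitudes: nucleic acids (966, 1086, 1120, 1240) then
  # CH stretches (2852, 2873, 2925, 2960)
  amp <- list(
    "RWPE-1" = c(0.030, 0.10, 0.045, 0.09, 0.085, 0.110, 0.160, 0.200),
    "22Rv1"  = c(0.090, 0.18, 0.070, 0.17, 0.115, 0.130, 0.230, 0.150),
    "PC3"    = c(0.100, 0.26, 0.150, 0.20, 0.075, 0.110, 0.190, 0.210),
    "Du145"  = c(0.080, 0.32, 0.180, 0.25, 0.180, 0.060, 0.310, 0.120),
    "LNCaP"  = c(0.120, 0.38, 0.210, 0.29, 0.210, 0.125, 0.350, 0.240)
  )
  counts <- c("RWPE-1" = 14L, "22Rv1" = 7L, "PC3" = 7L,
              "Du145" = 10L, "LNCaP" = 10L)
  lapply(names(counts), function(cl) {
    a <- amp[[cl]]
    bands <- dplyr::bind_rows(
      shared_bands(),
      band(966, 30, a[1]),          # ribose C-O
      band(1086, 40, a[2]),         # PO2- symmetric
      band(1120, 40, a[3]),         # RNA C-O
      band(1240, 55, a[4]),         # PO2- asymmetric
      band(2852, 22, a[5]),         # CH2 symmetric
      band(2873, 20, a[6]),         # CH3 symmetric
      band(2925, 28, a[7]),         # CH2 asymmetric
      band(2960, 22, a[8])          # CH3 asymmetric
    )
    list(name = cl, bands = bands, n_spectra = counts[[cl]],
         amplitude_jitter = 0.10, center_jitter = 2)
  })
}

#' Render clean (undistorted) spectra for one class profile
#'
#' Each spectrum is the sum of the profile's bands with per-spectrum,
#' per-band jitter: log-normal on amplitude (relative sd
#' `amplitude_jitter`), normal on center (sd `center_jitter` cm^-1).
#'
#' @param profile One element of [default_profiles()].
#' @param axis Wavenumber axis.
#' @param seed Integer seed; same seed, same matrix.
#' @return Matrix `n_spectra x length(axis)`, non-negative.
#' @export
render_clean <- function(profile, axis, seed = 1L) {
  rng <- local_rng(seed)
  nb <- nrow(profile$bands)
  out <- matrix(0, profile$n_spectra, length(axis))
  for (i in seq_len(profile$n_spectra)) {
    b <- profile$bands
    b$amplitude <- b$amplitude *
      rng$rlnorm(nb, meanlog = 0, sdlog = profile$amplitude_jitter)
    b$center <- b$center + rng$rnorm(nb, sd = profile$center_jitter)
    out[i, ] <- band_profile(b, axis)
  }
  out
}

#' Default distortion configuration
#'
#' Parameters of the distortion model
#' `scale * (clean + fringe) + baseline + artifacts + noise`:
#' * `baseline_poly_coeffs_std`: sds of the degree-0..3 Legendre-style
#'   polynomial baseline coefficients on the axis rescaled to \[-1, 1\]
#'   (absorbance units);
#' * `mie_fringe`: sphere-diameter range (um), refractive-index range, and
#'   fringe amplitude of the van de Hulst extinction curve added before
#'   multiplicative scaling;
#' * `multiplicative_scale_range`: per-spectrum uniform scaling;
#' * `artifact_bands`: CO2 doublet near 2349/2337 cm^-1 plus a weak
#'   water-vapor line comb;
#' * `noise_sigma`: homoscedastic Gaussian noise sd (absorbance units) for
#'   the 256-scan base acquisition.
#'
#' @return A named list understood by [apply_distortions()].
#' @export
default_distortions <- function() {
  list(
    baseline_poly_coeffs_std = c(0.08, 0.04, 0.02, 0.01),
    mie_fringe = list(diameter_um = c(2, 8), ref_index = c(1.1, 1.4),
                      amplitude = 0.06),
    multiplicative_scale_range = c(0.7, 1.3),
    co2_amplitude = 0.04,
    water_vapor_amplitude = 0.003,
    noise_sigma = 0.008
  )
}

# narrow rotational-vibrational lines; the 1750-1810 cm^-1 stretch is kept
# clear so a signal-free noise-estimation window exists
water_vapor_lines <- function() {
  c(3750, 3710, 3670, 3630, 3590, 3560,
    1717, 1700, 1670, 1617, 1560, 1540, 1507, 1456, 1419)
}

#' Apply study-shaped distortions to clean spectra
#'
#' Transforms each clean spectrum as
#' `scale * (clean + fringe) + baseline + artifacts + noise` with
#' per-spectrum parameters drawn from the configured ranges. The exact
#' ground-truth components are retained in `meta$truth` so tests can
#' reconstruct each distorted spectrum (noise excluded) to machine
#' precision.
#'
#' @param clean A `spectra_set` of clean spectra.
#' @param cfg Distortion configuration, see [default_distortions()]. Any
#'   component can be disabled by zeroing its amplitude/std (and
#'   `multiplicative_scale_range = c(1, 1)`).
#' @param seed Integer seed.
#' @return A distorted `spectra_set`.
#' @export
apply_distortions <- function(clean, cfg = default_distortions(), seed = 1L) {
  rng <- local_rng(seed + 1000L)
  A <- clean$absorbance
  n <- nrow(A); p <- ncol(A)
  wn <- clean$wavenumber
  t01 <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1

  scale <- rng$runif(n, cfg$multiplicative_scale_range[1],
                     cfg$multiplicative_scale_range[2])

  fringe <- matrix(0, n, p)
  fa <- cfg$mie_fringe$amplitude
  d <- ri <- rep(NA_real_, n)
  if (fa > 0) {
    d <- rng$runif(n, cfg$mie_fringe$diameter_um[1],
                   cfg$mie_fringe$diameter_um[2])
    ri <- rng$runif(n, cfg$mie_fringe$ref_index[1],
                    cfg$mie_fringe$ref_index[2])
    for (i in seq_len(n)) {
      # van de Hulst phase: rho = 2 pi d nu (m - 1), d in cm
      rho <- 2 * pi * (d[i] * 1e-4) * wn * (ri[i] - 1)
      q <- vandehulst_qext(rho)
      fringe[i, ] <- fa * (q - mean(q)) / 2
    }
  }

  baseline <- matrix(0, n, p)
  cs <- cfg$baseline_poly_coeffs_std
  if (any(cs > 0)) {
    basis <- sapply(seq_along(cs) - 1L, function(k) t01^k)
    coef <- matrix(rng$rnorm(n * length(cs)), n) %*% diag(cs, length(cs))
    baseline <- coef %*% t(basis)
  }

  artifacts <- matrix(0, n, p)
  if (cfg$co2_amplitude > 0) {
    co2 <- band_profile(dplyr::bind_rows(band(2349, 12, 1),
                                         band(2337, 12, 0.7)), wn)
    artifacts <- artifacts +
      outer(cfg$co2_amplitude * rng$runif(n, 0.5, 1.5), co2)
  }
  if (cfg$water_vapor_amplitude > 0) {
    wv <- band_profile(
      dplyr::bind_rows(lapply(water_vapor_lines(),
                              function(c0) band(c0, 6, 1, "lorentzian"))), wn)
    artifacts <- artifacts +
      outer(rng$rnorm(n, sd = cfg$water_vapor_amplitude), wv)
  }

  noise <- matrix(0, n, p)
  if (cfg$noise_sigma > 0)
    noise <- matrix(rng$rnorm(n * p, sd = cfg$noise_sigma), n, p)

  out <- A * 0
  for (i in seq_len(n))
    out[i, ] <- scale[i] * (A[i, ] + fringe[i, ]) + baseline[i, ] +
      artifacts[i, ] + noise[i, ]

  meta <- clean$meta
  meta$truth <- list(clean = A, scale = scale, fringe = fringe,
                     mie_diameter = d, mie_ref_index = ri,
                     baseline = baseline, artifacts = artifacts,
                     noise = noise, seed = seed, cfg = cfg)
  set_absorbance(clean, out, meta = meta)
}

#' Synthetic protein-matrix reference spectrum
#'
#' A smooth, strictly positive, Amide-dominated stand-in for the protein
#' gel reference used by the Mie-EMSC corrections, for use when no measured
#' reference is supplied. Flagged synthetic in `meta`.
#'
#' @param axis Wavenumber axis.
#' @return A one-spectrum `spectra_set`, maximum exactly 1, dominant peak at
#'   the Amide I position (1656 cm^-1).
#' @export
generate_reference <- function(axis) {
  bands <- dplyr::bind_rows(
    band(1656, 50, 1.00), band(1545, 52, 0.60), band(1310, 70, 0.12),
    band(1398, 50, 0.18), band(3290, 140, 0.40), band(3070, 80, 0.10),
    band(2930, 40, 0.12), band(2870, 30, 0.06), band(1080, 60, 0.10)
  )
  y <- band_profile(bands, axis) + 0.01   # strictly positive floor
  y <- y / max(y)
  spectra_set(y, axis, labels = "reference", ids = "matrigel_synthetic",
              meta = list(synthetic = TRUE,
                          description = "synthetic protein-matrix reference"))
}

#' Generate the default synthetic study
#'
#' Composes [default_profiles()], [render_clean()] and
#' [apply_distortions()] on the 1582-point, 900-3800 cm^-1 axis: 48 labeled
#' cell spectra in classes of 14/7/7/10/10, with baseline drift, Mie-type
#' fringes, CO2/water-vapor artifact bands and 256-scan base noise.
#'
#' @param seed Integer seed; fully determines the dataset.
#' @param distort Apply the distortion model? `FALSE` returns the clean,
#'   noise-free band spectra (used for separability oracles).
#' @param cfg Distortion configuration.
#' @param axis Wavenumber axis.
#' @return A `spectra_set` of 48 spectra.
#' @export
generate_study <- function(seed = 1L, distort = TRUE,
                           cfg = default_distortions(), axis = make_axis()) {
  profiles <- default_profiles()
  mats <- list(); labels <- character(0)
  for (k in seq_along(profiles)) {
    pr <- profiles[[k]]
    mats[[k]] <- render_clean(pr, axis, seed = seed + k)
    labels <- c(labels, rep(pr$name, pr$n_spectra))
  }
  A <- do.call(rbind, mats)
  set <- spectra_set(A, axis, labels = labels,
                     ids = sprintf("cell%02d", seq_len(nrow(A))),
                     meta = list(seed = seed, scans = 256))
  if (distort) set <- apply_distortions(set, cfg, seed = seed)
  set
}
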
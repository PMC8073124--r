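# axis 900..3800 in 2 cm^-1 steps (1451 points) unless told otherwise
toy_axis <- function(step = 2) seq(900, 3800, by = step)

# n spectra of smooth positive signal on a small axis
toy_set <- function(n = 3, axis = seq(1000, 2000, by = 10), seed = 1) {
  set.seed(seed)
  A <- t(sapply(seq_len(n), function(i)
    0.5 + 0.3 * sin(axis / 150 + i) + 0.1 * i))
  spectra_set(A, axis, labels = letters[seq_len(n)])
}

# constant-value set
flat_set <- function(value = 0.3, n = 2, axis = seq(1000, 2000, by = 10)) {
  spectra_set(matrix(value, n, length(axis)), axis)
}

# dense Whittaker / ALS oracle: explicit dense linear algebra, independent
# of the package's sparse path
dense_whittaker <- function(y, lambda, w = rep(1, length(y))) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  solve(diag(w, n) + lambda * t(D) %*% D, w * y)
}

dense_als <- function(y, lambda, p, max_iter = 50) {
  w <- rep(1, length(y))
  z <- y
  for (it in seq_len(max_iter)) {
    z <- dense_whittaker(y, lambda, w)
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

# explicit DFT-matrix truncation oracle for the Fourier denoiser
dense_fourier <- function(y, window) {
  n <- length(y)
  Fm <- outer(0:(n - 1), 0:(n - 1),
              function(j, k) exp(-2i * pi * j * k / n))
  coef <- Fm %*% y
  freq <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
  coef[abs(freq) >= window] <- 0
  Re(Conj(t(Fm)) %*% coef) / n
}
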
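test_that("kennard_stone_split reproduces the study's 34/14 split", {
  s <- generate_study(seed = 1)
  sp <- kennard_stone_split(s, 0.75)
  expect_equal(sum(sp$subset == "model"), 34L)
  expect_equal(sum(sp$subset == "test"), 14L)
  # per-class model counts are floor(0.75 * n)
  per <- table(sp$label[sp$subset == "model"])
  expect_equal(unname(per[c("RWPE-1", "22Rv1", "PC3", "Du145", "LNCaP")]),
               c(10L, 5L, 5L, 7L, 7L), ignore_attr = TRUE)
  # deterministic
  expect_identical(sp, kennard_stone_split(s, 0.75))
})

test_that("kennard-stone greedy equals the max-min oracle on collinear points", {
  X <- matrix(c(0, 1, 2, 3, 4), ncol = 1)
  sel <- irpreproc:::kennard_stone_select(X, 3)
  # exhaustive: subset of size 3 maximizing the minimum pairwise distance
  combs <- combn(5, 3)
  minds <- apply(combs, 2, function(ix) min(dist(X[ix, , drop = FALSE])))
  oracle <- combs[, which.max(minds)]
  expect_setequal(sel, oracle)        # extremes plus the midpoint
  expect_setequal(sel[1:2], c(1, 5))  # started from the farthest pair
})

test_that("split guards: singleton class and invalid fraction error", {
  ax <- seq_len(10)
  s <- spectra_set(matrix(runif(30), 3), ax, labels = c("a", "a", "b"))
  expect_error(kennard_stone_split(s, 0.75), "fewer than 2")
  s2 <- spectra_set(matrix(runif(40), 4), ax, labels = rep("a", 4))
  expect_error(kennard_stone_split(s2, 1.2), "fraction")
  # a tiny model fraction still keeps at least the starting pair
  sp <- kennard_stone_split(s2, 0.6)
  expect_equal(sum(sp$subset == "model"), 2L)
})

test_that("pls_fit matches least squares at full rank and recovers exactly", {
  set.seed(7)
  X <- matrix(rnorm(60), 10, 6)
  y <- rnorm(10)
  m <- pls_fit(X, y, 6)
  Xc <- scale(X, scale = FALSE)
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_equal(m$beta[, 1, 6], as.numeric(b_ols), tolerance = 1e-8)
  # noiseless linear response is reproduced
  b <- rnorm(6)
  m2 <- pls_fit(X, as.numeric(X %*% b), 6)
  expect_lt(max(abs(pls_predict(m2, X) - X %*% b)), 1e-8)
  # the training mean predicts the response mean
  expect_equal(pls_predict(m, matrix(colMeans(X), 1)), mean(y))
  expect_error(pls_fit(X, y, 10), "exceeds")
  expect_error(pls_predict(m, X[, 1:3]), "columns")
})

test_that("loocv regression curve equals the double-loop oracle", {
  set.seed(11)
  X <- matrix(rnorm(60), 10, 6)
  y <- rnorm(10)
  cv <- loocv_curve_regression(X, y, lv_max = 4)
  oracle <- sapply(1:4, function(a) {
    e <- sapply(1:10, function(i) {
      f <- pls_fit(X[-i, ], y[-i], a)
      y[i] - pls_predict(f, X[i, , drop = FALSE], a)
    })
    sqrt(mean(e^2))
  })
  expect_equal(cv$rmsecv, oracle, tolerance = 1e-10)
  # constant response: zero error
  cvc <- loocv_curve_regression(X, rep(2, 10), lv_max = 3)
  expect_lt(max(cvc$rmsecv), 1e-8)
  # clamping to min(n - 2, p)
  expect_warning(out <- loocv_curve_regression(X, y, lv_max = 9), "clamped")
  expect_equal(max(out$lv), 6L)
})

test_that("loocv regression tracks the noise floor on a linear construct", {
  set.seed(13)
  n <- 30; p <- 12; sigma <- 0.1
  v <- rnorm(p); v <- v / sqrt(sum(v^2))
  y <- rnorm(n)
  X <- outer(y, v) + matrix(rnorm(n * p, sd = sigma), n, p)
  cv <- loocv_curve_regression(X, y, lv_max = 4)
  expect_lt(cv$rmsecv[1], 2 * sigma)
})

test_that("lv selection rules follow the printed procedures", {
  # local minimum followed by two strictly higher values wins
  expect_equal(select_lv_regression(c(5, 3, 2, 2.5, 2.6, 1.9, 1.8, 1.7)), 3)
  expect_equal(select_lv_regression(rev(1:8)), 8L)  # monotone decreasing
  expect_equal(select_lv_regression(1:8), 1)        # increasing: 1 is local
  # classification: argmax, ties to the smaller LV
  expect_equal(select_lv_classification(c(0.5, 0.9, 0.9, 0.6, 0.6, 0.6,
                                          0.6, 0.6)), 2L)
  expect_equal(select_lv_classification(seq(0.1, 0.8, by = 0.1)), 8L)
  expect_equal(select_lv_classification(rep(0.5, 8)), 1L)
})

test_that("loocv classification equals a per-fold oracle and handles noise", {
  set.seed(17)
  # separable 2-class toy: accuracy 1 at LV 1
  X <- rbind(matrix(rnorm(12, mean = 0, sd = 0.1), 4),
             matrix(rnorm(12, mean = 3, sd = 0.1), 4))
  lab <- rep(c("a", "b"), each = 4)
  cv <- loocv_curve_classification(X, lab, lv_max = 2)
  expect_equal(cv$accuracy[1], 1)
  # double-loop oracle on an 8-sample toy
  oracle <- sapply(1:2, function(a) {
    hits <- sapply(1:8, function(i) {
      Y <- membership_matrix(lab[-i], classes = c("a", "b"))
      f <- pls_fit(X[-i, ], Y, 2)
      p <- pls_predict(f, X[i, , drop = FALSE], a)
      c("a", "b")[which.max(p)] == lab[i]
    })
    mean(hits)
  })
  expect_equal(cv$accuracy, oracle)
  # pure noise, random labels: near-chance accuracy
  set.seed(19)
  Xn <- matrix(rnorm(40 * 20), 40)
  labn <- sample(rep(paste0("c", 1:5), 8))
  cvn <- loocv_curve_classification(Xn, labn, lv_max = 3)
  expect_lt(abs(cvn$accuracy[1] - 0.2), 0.15)
})

test_that("membership matrix and argmax assignment behave", {
  lab <- c("RWPE-1", "PC3", "PC3")
  Y <- membership_matrix(lab)
  expect_equal(rowSums(Y), rep(1, 3), ignore_attr = TRUE)
  expect_equal(colnames(Y), c("RWPE-1", "PC3"))
  expect_error(membership_matrix(c("a"), classes = "b"), "outside")
  P <- rbind(c(0.9, 0.1, 0.2, 0.3, 0.1),
             c(0.4, 0.4, 0.1, 0.1, 0.1))
  colnames(P) <- paste0("k", 1:5)
  expect_message(out <- plsda_assign(P), "tie")
  expect_equal(out, c("k1", "k1"))
  # block-identity predictions assign perfectly
  B <- diag(5); colnames(B) <- paste0("k", 1:5)
  expect_equal(plsda_assign(B), paste0("k", 1:5))
})

test_that("rmsep and accuracy compute their definitions", {
  expect_equal(rmsep(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsep(c(0, 0), c(1, -1)), 1)
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(c("a", "b", "c", "d"), c("a", "b", "c", "x")), 0.75)
  expect_error(rmsep(1:3, 1:2), "mismatch")
  expect_error(accuracy(letters[1:3], letters[1:2]), "mismatch")
})

test_that("loocv curves are invariant to sample order", {
  set.seed(23)
  X <- matrix(rnorm(80), 10, 8)
  y <- rnorm(10)
  perm <- sample(10)
  a <- loocv_curve_regression(X, y, 3)
  b <- loocv_curve_regression(X[perm, ], y[perm], 3)
  expect_equal(a$rmsecv, b$rmsecv, tolerance = 1e-10)
})

test_that("plsr on the synthetic study recovers the class trend", {
  s0 <- generate_study(seed = 4, distort = FALSE)
  sp <- kennard_stone_split(s0)
  pair <- split_spectra(s0, sp)
  y_m <- unname(class_coding()[pair$model$labels])
  y_t <- unname(class_coding()[pair$test$labels])
  cv <- loocv_curve_regression(pair$model$absorbance, y_m, 8)
  lv <- select_lv_regression(cv$rmsecv)
  fit <- pls_fit(pair$model$absorbance, y_m, lv)
  err <- rmsep(y_t, pls_predict(fit, pair$test$absorbance))
  # class scores span [-2, 2]; recovery well under the class gap of 1
  expect_lt(err, 0.5)
})

test_that("tidy and glance expose the fitted model", {
  set.seed(29)
  X <- matrix(rnorm(60), 10, 6)
  m <- pls_fit(X, rnorm(10), 3)
  td <- generics::tidy(m, wavenumber = seq(1000, 1050, by = 10))
  expect_equal(nrow(td), 6L)
  expect_named(td, c("term", "response", "estimate", "wavenumber"))
  gl <- generics::glance(m)
  expect_equal(gl$n_lv, 3L)
  expect_equal(gl$n_variables, 6L)
})
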
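test_that("the default grid enumerates 2835 combinations", {
  g <- default_grid()
  expect_equal(sum(g$step == "denoise"), 45L)
  expect_equal(sum(g$step == "baseline"), 21L)
  expect_equal(sum(g$step == "normalize"), 3L)
  combos <- enumerate_combinations(g)
  expect_equal(nrow(combos), 2835L)
  expect_equal(nrow(combos), 45L * 21L * 3L)
  # stable deterministic ordering with unique ids
  expect_equal(combos$combo_id, seq_len(2835L))
  expect_identical(combos, enumerate_combinations(g))
})

test_that("enumeration is a product and invariant to row order", {
  g <- default_grid()
  small <- dplyr::bind_rows(
    g[g$step == "denoise", ][1:2, ],
    g[g$step == "baseline", ][c(13, 14), ],
    g[g$step == "normalize", ][1:3, ])
  combos <- enumerate_combinations(small)
  expect_equal(nrow(combos), 2L * 2L * 3L)
  shuffled <- small[c(4, 1, 7, 3, 2, 6, 5), ]
  expect_equal(nrow(enumerate_combinations(shuffled)), 12L)
  # single triple
  one <- dplyr::bind_rows(g[g$step == "denoise", ][1, ],
                          g[g$step == "baseline", ][13, ],
                          g[g$step == "normalize", ][1, ])
  expect_equal(nrow(enumerate_combinations(one)), 1L)
  # unknown method fails before execution
  bad <- small
  bad$method[1] <- "WAVELET"
  expect_error(enumerate_combinations(bad), "unknown denoise")
  expect_error(enumerate_combinations(small[small$step != "normalize", ]),
               "empty")
})

test_that("preprocess_set runs the documented stage order", {
  s <- generate_study(seed = 21)
  g <- default_grid()
  combos <- enumerate_combinations(g)
  co <- combos[combos$denoise_method == "SG" &
                 combos$baseline_method == "ALS" &
                 combos$normalize_method == "CON", ][1, ]
  out <- preprocess_set(s, co)
  # water vapor region gone, CO2 region trimmed
  expect_false(any(out$wavenumber >= 3650))
  expect_false(any(out$wavenumber >= 2300 & out$wavenumber <= 2400))
  # CON: unit absolute value at the Amide I point
  j <- which.min(abs(out$wavenumber - 1656))
  expect_equal(unname(abs(out$absorbance[, j])), rep(1, 48))
})

test_that("run_combination returns complete records and survives failures", {
  s <- generate_study(seed = 22)
  sp <- kennard_stone_split(s)
  pair <- split_spectra(s, sp)
  combos <- enumerate_combinations(default_grid())
  co <- combos[combos$denoise_method == "EIL" &
                 combos$baseline_method == "RB" &
                 combos$normalize_method == "TSN", ][1, ]
  rec <- run_combination(pair$model, pair$test, co, "classification")
  expect_false(rec$failed)
  expect_true(is.finite(rec$internal) && is.finite(rec$external))
  expect_gte(rec$chosen_lv, 1L)
  expect_lte(rec$chosen_lv, 8L)
  reg <- run_combination(pair$model, pair$test, co, "regression")
  expect_false(reg$failed)
  expect_gte(reg$internal, 0)
  # an absurd configuration yields a failed record, not an error
  bad <- co
  bad$baseline_method <- "POL"
  bad$baseline_params <- list(list(degree = 3,
                                   anchors = c(1100, 1200)))
  recb <- run_combination(pair$model, pair$test, bad, "classification")
  expect_true(recb$failed)
  expect_match(recb$message, "degree")
})

test_that("separable clean data passes a gentle triple end to end", {
  s0 <- generate_study(seed = 1, distort = FALSE)
  sp <- kennard_stone_split(s0)
  pair <- split_spectra(s0, sp)
  co <- list(combo_id = 1L, denoise_method = "EIL",
             denoise_params = list(lambda = 1e-6),
             baseline_method = "RB", baseline_params = list(),
             normalize_method = "CON", normalize_params = list())
  rec <- run_combination(pair$model, pair$test, co, "classification")
  expect_false(rec$failed)
  expect_gte(rec$internal, 0.9)
  expect_gte(rec$external, 0.9)
})

test_that("run_grid bookkeeping: records, noise doubling, cache determinism", {
  s <- generate_study(seed = 23)
  g <- default_grid()
  mini <- dplyr::bind_rows(
    g[g$step == "denoise" & g$method == "FT", ][1, ],
    g[g$step == "baseline" & g$method == "RB", ],
    g[g$step == "baseline" & g$method == "POL", ][1, ],
    g[g$step == "normalize" & g$method %in% c("CON", "TSN"), ])
  combos <- enumerate_combinations(mini)
  expect_equal(nrow(combos), 4L)
  recs <- run_grid(s, combos = combos[1:2, ])
  expect_equal(nrow(recs), 4L)  # 2 combos x 2 tasks
  expect_true(all(!recs$noisy))
  cache <- withr::local_tempdir()
  recs_n <- run_grid(s, combos = combos[1:2, ], noise = TRUE,
                     cache_dir = cache)
  expect_equal(nrow(recs_n), 8L)
  expect_equal(sum(recs_n$noisy), 4L)
  # cached rerun reproduces the table exactly
  recs_n2 <- run_grid(s, combos = combos[1:2, ], noise = TRUE,
                      cache_dir = cache)
  expect_identical(recs_n, recs_n2)
  # clean rows agree with the no-noise run
  expect_equal(recs_n$internal[!recs_n$noisy], recs$internal)
})

test_that("pca_explore matches an eigendecomposition oracle", {
  set.seed(31)
  X <- matrix(rnorm(200), 20, 10)
  s <- spectra_set(abs(X) + 0.1, seq_len(10))
  ex <- pca_explore(list(s), n_pc = 3)
  A <- max_normalize_dataset(s)$absorbance
  C <- cov(A)
  ei <- eigen(C, symmetric = TRUE)
  sc_oracle <- sweep(A, 2, colMeans(A)) %*% ei$vectors[, 1:3]
  for (k in 1:3) {
    expect_equal(abs(ex$scores[[paste0("PC", k)]]), abs(sc_oracle[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_true(all(diff(ex$explained_variance$variance) <= 1e-10))
  expect_lte(sum(ex$explained_variance$proportion), 1 + 1e-10)
  # duplicated variant duplicates scores
  ex2 <- pca_explore(list(s, s), tags = tibble::tibble(tag = c("a", "b")))
  expect_equal(ex2$scores$PC1[ex2$scores$variant == 1],
               ex2$scores$PC1[ex2$scores$variant == 2])
  expect_error(pca_explore(list(s, toy_set(n = 2))), "inconsistent")
})

test_that("threshold counts group qualifying classification records", {
  recs <- tibble::tibble(
    task = "classification", failed = FALSE,
    denoise = "EIL(lambda=2)",
    baseline = c("RB", "RB", "POL(degree=3)", "ALS(lambda=1e+06,p=0.1)",
                 "RB"),
    normalize = c("CON", "CON", "TSN", "CON", "PQN"),
    internal = c(0.9, 0.85, 0.95, 0.7, 0.9),
    external = c(0.85, 0.5, 0.9, 0.9, 0.81))
  out <- summarize_threshold_counts(recs, 0.8)
  expect_equal(sum(out$n), 3L)
  expect_equal(out$n[out$baseline_method == "RB" &
                       out$normalize_method == "CON"], 1L)
  none <- summarize_threshold_counts(recs, 1.1)
  expect_equal(nrow(none), 0L)
})

test_that("best-decile selection keeps joint low-error combinations", {
  n <- 20
  recs <- tibble::tibble(
    task = "regression", failed = FALSE,
    denoise = paste0("EIL(lambda=", 1:n, ")"),
    baseline = rep(c("RB", "POL(degree=3)"), 10),
    normalize = rep(c("CON", "TSN"), each = 10),
    internal = c(0.1, 0.2, seq(1, 1.9, length.out = 18)),
    external = c(0.15, 0.1, seq(1, 2, length.out = 18)))
  out <- summarize_best_decile(recs)
  expect_equal(nrow(out$selected), 2L)  # ceil(0.1 * 20)
  expect_setequal(out$selected$internal, c(0.1, 0.2))
  expect_equal(sum(out$histogram$n), 2L * 3L)
  # all identical: decile by stable order, size ceil(0.1 n)
  same <- recs
  same$internal <- 1; same$external <- 1
  outs <- summarize_best_decile(same)
  expect_equal(nrow(outs$selected), 2L)
})

test_that("mean errors per method match hand arithmetic", {
  recs <- tibble::tibble(
    task = "regression", failed = FALSE,
    denoise = c("EIL(lambda=2)", "EIL(lambda=2)", "SG(poly_degree=2,frame=11)",
                "SG(poly_degree=2,frame=11)"),
    baseline = "RB", normalize = c("CON", "TSN", "CON", "TSN"),
    internal = c(1, 2, 3, 4), external = c(2, 2, 4, 6))
  out <- summarize_mean_errors(recs)
  eil <- out[out$step == "denoise" & out$method == "EIL", ]
  expect_equal(eil$mean_rmsecv, 1.5)
  expect_equal(eil$sd_rmsecv, sd(c(1, 2)))
  expect_equal(eil$mean_rmsep, 2)
  rb <- out[out$step == "baseline" & out$method == "RB", ]
  expect_equal(rb$mean_rmsecv, 2.5)   # single-method step: grand mean
  expect_equal(rb$n, 4L)
  con <- out[out$step == "normalize" & out$method == "CON", ]
  expect_equal(con$mean_rmsep, 3)
})

test_that("plot helpers return ggplot objects", {
  s <- toy_set(n = 2)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  recs <- tibble::tibble(
    task = "regression", failed = FALSE, denoise = "EIL(lambda=2)",
    baseline = "RB", normalize = c("CON", "TSN"),
    internal = c(1, 2), external = c(2, 3))
  expect_s3_class(plot_mean_errors(summarize_mean_errors(recs)), "ggplot")
  ex <- pca_explore(list(toy_set(n = 3)))
  expect_s3_class(plot_pca_explore(ex), "ggplot")
  cls <- tibble::tibble(task = "classification", failed = FALSE,
                        denoise = "FT(window=100)", baseline = "RB",
                        normalize = "CON", internal = 0.9, external = 0.9)
  expect_s3_class(plot_threshold_counts(summarize_threshold_counts(cls)),
                  "ggplot")
})
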
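#' The default preprocessing grid
#'
#' One row per expanded method/parameter choice of each step, reproducing
#' the full study grid of 2835 combinations:
#' * denoise (45): EIL with integer smoothing weight 2..24 (23), SG with
#'   degrees \{2, 3\} by odd frames 11..29 (20), FT with windows
#'   \{100, 320\} (2);
#' * baseline (21): DER with degrees \{2, 3\} by odd frames 19..29 (12),
#'   RB (1), POL with degrees 3..5 (3), ALS with `p = 0.1` and smoothing
#'   weight \{1e6, 1e7, 1e8\} (3), RMIE (1), MEEMSC (1);
#' * normalize (3): CON, TSN, PQN.
#'
#' The printed parameter ranges pin the totals; per-method step sizes are
#' configurable by editing the returned tibble (or supplying your own with
#' the same columns).
#'
#' @return A tibble with columns `step`, `method`, `params` (list column),
#'   `spec_label`.
#' @export
default_grid <- function() {
  rows <- list()
  add <- function(step, method, params) {
    lbl <- if (length(params) == 0) method else
      paste0(method, "(", paste(names(params), unlist(params), sep = "=",
                                collapse = ","), ")")
    rows[[length(rows) + 1L]] <<-
      tibble::tibble(step = step, method = method, params = list(params),
                     spec_label = lbl)
  }
  for (lam in 2:24) add("denoise", "EIL", list(lambda = lam))
  for (d in 2:3) for (fr in seq(11, 29, by = 2))
    add("denoise", "SG", list(poly_degree = d, frame = fr))
  for (w in c(100, 320)) add("denoise", "FT", list(window = w))

  for (d in 2:3) for (fr in seq(19, 29, by = 2))
    add("baseline", "DER", list(poly_degree = d, frame = fr))
  add("baseline", "RB", list())
  for (d in 3:5) add("baseline", "POL", list(degree = d))
  for (lam in c(1e6, 1e7, 1e8))
    add("baseline", "ALS", list(lambda = lam, p = 0.1))
  add("baseline", "RMIE", list())
  add("baseline", "MEEMSC", list())

  for (m in c("CON", "TSN", "PQN")) add("normalize", m, list())
  dplyr::bind_rows(rows)
}

#' Enumerate all denoise x baseline x normalize combinations
#'
#' Cartesian product of the per-step method/parameter expansions, in a
#' stable deterministic order (denoise fastest-varying last). The count is
#' the product of the per-step totals; the shipped [default_grid()] gives
#' 2835.
#'
#' @param grid A grid tibble, see [default_grid()].
#' @return A tibble with one row per combination: `combo_id`,
#'   `denoise_method`, `denoise_params`, `baseline_method`,
#'   `baseline_params`, `normalize_method`, `normalize_params`, and the
#'   three `*_label` columns.
#' @export
enumerate_combinations <- function(grid) {
  need <- c("step", "method", "params")
  if (!all(need %in% names(grid)))
    stop("grid must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  known <- list(denoise = c("EIL", "SG", "FT"),
                baseline = c("DER", "RB", "POL", "ALS", "RMIE", "MEEMSC"),
                normalize = c("CON", "TSN", "PQN"))
  for (st in names(known)) {
    sub <- grid[grid$step == st, ]
    if (nrow(sub) == 0L) stop("grid step '", st, "' is empty", call. = FALSE)
    bad <- setdiff(unique(sub$method), known[[st]])
    if (length(bad))
      stop("unknown ", st, " method: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  dn <- grid[grid$step == "denoise", ]
  bl <- grid[grid$step == "baseline", ]
  nm <- grid[grid$step == "normalize", ]
  idx <- expand.grid(n = seq_len(nrow(nm)), b = seq_len(nrow(bl)),
                     d = seq_len(nrow(dn)))
  tibble::tibble(
    combo_id = seq_len(nrow(idx)),
    denoise_method = dn$method[idx$d],
    denoise_params = dn$params[idx$d],
    denoise_label = dn$spec_label[idx$d],
    baseline_method = bl$method[idx$b],
    baseline_params = bl$params[idx$b],
    baseline_label = bl$spec_label[idx$b],
    normalize_method = nm$method[idx$n],
    normalize_params = nm$params[idx$n],
    normalize_label = nm$spec_label[idx$n]
  )
}

#' Preprocess one set through a full combination
#'
#' The standard stage order: remove the water-vapor region, interpolate
#' across the CO2 region, denoise, baseline-correct, trim the CO2 region,
#' normalize.
#'
#' @param set A `spectra_set`.
#' @param combo One row of [enumerate_combinations()] output (a list or
#'   one-row tibble with the `*_method` / `*_params` fields).
#' @param co2,water Region bounds; `NULL` skips the region handling (for
#'   toy axes that do not cover them).
#' @param reference Optional EMSC reference (`spectra_set` on the
#'   post-water-removal axis).
#' @return The preprocessed `spectra_set`.
#' @export
preprocess_set <- function(set, combo, co2 = co2_region(),
                           water = water_vapor_region(), reference = NULL) {
  s <- set
  if (!is.null(water) && any(s$wavenumber >= water[1] &
                             s$wavenumber <= water[2]))
    s <- remove_region(s, water)
  has_co2 <- !is.null(co2) && any(s$wavenumber >= co2[1] &
                                  s$wavenumber <= co2[2])
  if (has_co2) s <- interpolate_region(s, co2)
  s <- denoise_spectra(s, combo$denoise_method,
                       first_el(combo$denoise_params))
  bp <- first_el(combo$baseline_params)
  if (combo$baseline_method %in% c("RMIE", "MEEMSC") &&
      !is.null(reference))
    bp$reference <- reference
  s <- baseline_correct(s, combo$baseline_method, bp)
  if (has_co2) s <- trim_region(s, co2)
  s <- normalize_spectra(s, combo$normalize_method,
                         first_el(combo$normalize_params))
  s
}

# params columns are list-columns; accept either the bare list or the
# one-row list-column wrapper
first_el <- function(x) {
  if (is.null(x)) return(list())
  if (is.list(x) && length(x) == 1L && is.list(x[[1]]) &&
      is.null(names(x))) return(x[[1]])
  x
}

#' Run one combination on a model/test pair
#'
#' Preprocesses the model and test sets independently through the
#' combination, fits the task on the model set with LOOCV latent-variable
#' selection, and evaluates the independent test set.
#'
#' @param model_set,test_set `spectra_set`s sharing an axis.
#' @param combo One row of [enumerate_combinations()].
#' @param task `"classification"` (PLS-DA, accuracy) or `"regression"`
#'   (PLSR on the class coding, RMSECV/RMSEP).
#' @param lv_max Latent-variable search range (default 8).
#' @param coding Class coding map for the regression task.
#' @param ... Passed to [preprocess_set()].
#' @return One-row tibble: combination labels, `task`, `chosen_lv`,
#'   `internal` (LOOCV accuracy or RMSECV), `external` (test accuracy or
#'   RMSEP), `failed`, `message`.
#' @export
run_combination <- function(model_set, test_set, combo, task, lv_max = 8L,
                            coding = class_coding(), ...) {
  rec <- tibble::tibble(
    combo_id = combo$combo_id %||% NA_integer_,
    denoise = combo$denoise_label %||% combo$denoise_method,
    baseline = combo$baseline_label %||% combo$baseline_method,
    normalize = combo$normalize_label %||% combo$normalize_method,
    task = task, chosen_lv = NA_integer_,
    internal = NA_real_, external = NA_real_,
    failed = FALSE, message = NA_character_
  )
  out <- tryCatch({
    m <- preprocess_set(model_set, combo, ...)
    te <- preprocess_set(test_set, combo, ...)
    if (task == "classification") {
      curve <- loocv_curve_classification(m$absorbance, m$labels, lv_max)
      lv <- select_lv_classification(curve$accuracy)
      fit <- pls_fit(m$absorbance, membership_matrix(m$labels), lv)
      pred <- pls_predict(fit, te$absorbance)
      rec$chosen_lv <- as.integer(lv)
      rec$internal <- curve$accuracy[lv]
      rec$external <- accuracy(te$labels, plsda_assign(pred))
    } else if (task == "regression") {
      y_m <- unname(coding[m$labels])
      y_t <- unname(coding[te$labels])
      if (anyNA(y_m) || anyNA(y_t))
        stop("labels missing from the class coding map")
      curve <- loocv_curve_regression(m$absorbance, y_m, lv_max)
      lv <- select_lv_regression(curve$rmsecv)
      fit <- pls_fit(m$absorbance, y_m, lv)
      rec$chosen_lv <- as.integer(lv)
      rec$internal <- curve$rmsecv[lv]
      rec$external <- rmsep(y_t, pls_predict(fit, te$absorbance))
    } else stop("unknown task: ", task)
    rec
  }, error = function(e) {
    rec$failed <- TRUE
    rec$message <- conditionMessage(e)
    rec
  })
  out
}

#' Run the preprocessing grid
#'
#' Splits the raw data once with per-class Kennard-Stone, then executes
#' every combination for both tasks on the independently preprocessed
#' model/test pair; optionally repeats everything on a noise-added copy of
#' the raw data (same split). Deterministic given the input set and
#' `noise_seed`. Failed combinations yield flagged records, never abort the
#' grid.
#'
#' @param set The raw `spectra_set`.
#' @param grid Grid tibble (default [default_grid()]).
#' @param combos Optional pre-enumerated (possibly subsampled) combination
#'   tibble; default enumerates `grid`.
#' @param tasks Character subset of `c("classification", "regression")`.
#' @param noise Also run on a 32-scan noise-added copy?
#' @param noise_seed,scans_target,sigma_base Noise parameters, see
#'   [add_scan_noise()].
#' @param fraction Kennard-Stone model fraction.
#' @param lv_max Latent-variable search range.
#' @param cache_dir Optional directory for per-combination result caching
#'   (files keyed by combination, task, and noise state); reruns reuse
#'   cached records.
#' @param progress Print one line per combination?
#' @return Records tibble: one row per combination x task (x noise state),
#'   with a logical `noisy` column.
#' @export
run_grid <- function(set, grid = default_grid(), combos = NULL,
                     tasks = c("classification", "regression"),
                     noise = FALSE, noise_seed = 1L, scans_target = 32,
                     sigma_base = NULL, fraction = 0.75, lv_max = 8L,
                     cache_dir = NULL, progress = FALSE) {
  if (is.null(combos)) combos <- enumerate_combinations(grid)
  split <- kennard_stone_split(set, fraction)
  variants <- list(list(noisy = FALSE, set = set))
  if (noise)
    variants <- c(variants, list(list(
      noisy = TRUE,
      set = add_scan_noise(set, scans_target = scans_target,
                           sigma_base = sigma_base, seed = noise_seed))))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  reference <- NULL
  recs <- list()
  for (v in variants) {
    pair <- split_spectra(v$set, split)
    for (k in seq_len(nrow(combos))) {
      combo <- combos[k, ]
      for (task in tasks) {
        key <- sprintf("c%05d_%s_%s", combo$combo_id, substr(task, 1, 3),
                       if (v$noisy) "noisy" else "clean")
        cache_file <- if (is.null(cache_dir)) NULL else
          file.path(cache_dir, paste0(key, ".rds"))
        if (!is.null(cache_file) && file.exists(cache_file)) {
          rec <- readRDS(cache_file)
        } else {
          rec <- run_combination(pair$model, pair$test, combo, task,
                                 lv_max = lv_max)
          if (!is.null(cache_file)) saveRDS(rec, cache_file)
        }
        rec$noisy <- v$noisy
        recs[[length(recs) + 1L]] <- rec
        if (progress)
          cat(key, ":", rec$denoise, "/", rec$baseline, "/", rec$normalize,
              "->", if (rec$failed) "FAILED" else
                sprintf("int %.3f ext %.3f lv %d", rec$internal,
                        rec$external, rec$chosen_lv), "\n")
      }
    }
  }
  dplyr::bind_rows(recs)
}

#' PCA exploration of preprocessing variants
#'
#' Max-normalizes each variant set to its global maximum, stacks all
#' spectra, and runs mean-centered PCA, tagging every score row with its
#' variant's step methods for coloring.
#'
#' @param variant_sets List of `spectra_set`s with a common axis length.
#' @param tags Optional data frame / tibble with one row of method tags per
#'   variant (recycled over the variant's spectra).
#' @param n_pc Number of components to keep (default 5).
#' @return List with `scores` (tibble: `variant`, tag columns, `id`,
#'   `label`, `PC1`, ...) and `explained_variance` (tibble: `pc`,
#'   `variance`, `proportion`).
#' @export
pca_explore <- function(variant_sets, tags = NULL, n_pc = 5L) {
  lens <- vapply(variant_sets, n_variables, integer(1))
  if (length(unique(lens)) != 1L)
    stop("variant sets have inconsistent axis lengths", call. = FALSE)
  normed <- lapply(variant_sets, max_normalize_dataset)
  X <- do.call(rbind, lapply(normed, function(s) s$absorbance))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(n_pc), drop = FALSE])
  meta <- dplyr::bind_rows(lapply(seq_along(variant_sets), function(k) {
    s <- variant_sets[[k]]
    out <- tibble::tibble(variant = k, id = s$ids, label = s$labels)
    if (!is.null(tags)) out <- dplyr::bind_cols(
      out, tags[rep(k, n_spectra(s)), , drop = FALSE])
    out
  }))
  var_all <- pc$sdev^2
  list(scores = dplyr::bind_cols(meta, scores),
       explained_variance = tibble::tibble(
         pc = seq_along(var_all), variance = var_all,
         proportion = var_all / sum(var_all)))
}

#' Count combinations exceeding an accuracy threshold
#'
#' Counts classification records whose internal AND external accuracy both
#' exceed `threshold`, grouped by baseline and normalization method.
#'
#' @param records Records tibble from [run_grid()] (classification rows are
#'   selected automatically).
#' @param threshold Accuracy threshold (default 0.8).
#' @return Tibble: `baseline_method`, `normalize_method`, `n`.
#' @export
summarize_threshold_counts <- function(records, threshold = 0.8) {
  records |>
    dplyr::filter(.data$task == "classification", !.data$failed) |>
    dplyr::mutate(baseline_method = method_of(.data$baseline),
                  normalize_method = method_of(.data$normalize)) |>
    dplyr::filter(.data$internal > threshold,
                  .data$external > threshold) |>
    dplyr::count(.data$baseline_method, .data$normalize_method, name = "n")
}

method_of <- function(label) sub("\\(.*$", "", label)

#' Methods populating the joint best decile
#'
#' Selects the 10% of regression combinations with the lowest RMSECV and
#' RMSEP jointly: the intersection of the two bottom-decile sets, topped up
#' (when the intersection is smaller than a decile) by the best remaining
#' summed-rank combinations; ties resolved by summed rank then stable
#' order. Returns the per-step method histogram of the selected set.
#'
#' @param records Records tibble (regression rows used).
#' @return List with `selected` (the chosen records plus rank columns) and
#'   `histogram` (tibble: `step`, `method`, `n`).
#' @export
summarize_best_decile <- function(records) {
  reg <- records |>
    dplyr::filter(.data$task == "regression", !.data$failed)
  n <- nrow(reg)
  if (n == 0L) stop("no regression records", call. = FALSE)
  k <- ceiling(0.1 * n)
  reg <- reg |>
    dplyr::mutate(rank_cv = rank(.data$internal, ties.method = "first"),
                  rank_p = rank(.data$external, ties.method = "first"),
                  rank_sum = .data$rank_cv + .data$rank_p)
  in_both <- reg$rank_cv <= k & reg$rank_p <= k
  sel_idx <- which(in_both)
  if (length(sel_idx) < k) {
    rest <- setdiff(order(reg$rank_sum), sel_idx)
    sel_idx <- c(sel_idx, rest[seq_len(k - length(sel_idx))])
  } else if (length(sel_idx) > k) {
    sel_idx <- sel_idx[order(reg$rank_sum[sel_idx])][seq_len(k)]
  }
  selected <- reg[sort(sel_idx), ]
  histogram <- selected |>
    tidyr::pivot_longer(cols = c("denoise", "baseline", "normalize"),
                        names_to = "step", values_to = "label") |>
    dplyr::mutate(method = method_of(.data$label)) |>
    dplyr::count(.data$step, .data$method, name = "n")
  list(selected = selected, histogram = histogram)
}

#' Per-method mean errors
#'
#' For each method of each preprocessing step, the mean and standard
#' deviation of RMSECV and RMSEP over all (non-failed) regression
#' combinations containing that method.
#'
#' @param records Records tibble.
#' @return Tibble: `step`, `method`, `mean_rmsecv`, `sd_rmsecv`,
#'   `mean_rmsep`, `sd_rmsep`, `n`.
#' @export
summarize_mean_errors <- function(records) {
  records |>
    dplyr::filter(.data$task == "regression", !.data$failed) |>
    tidyr::pivot_longer(cols = c("denoise", "baseline", "normalize"),
                        names_to = "step", values_to = "label") |>
    dplyr::mutate(method = method_of(.data$label)) |>
    dplyr::group_by(.data$step, .data$method) |>
    dplyr::summarise(
      mean_rmsecv = mean(.data$internal),
      sd_rmsecv = stats::sd(.data$internal),
      mean_rmsep = mean(.data$external),
      sd_rmsep = stats::sd(.data$external),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(dplyr::across(c("sd_rmsecv", "sd_rmsep"),
                                ~ ifelse(is.na(.x), 0, .x)))
}

#' Plot per-method mean errors
#'
#' @param summary Output of [summarize_mean_errors()].
#' @return A ggplot object (mean +/- sd per method, faceted by step).
#' @export
plot_mean_errors <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(cols = c("mean_rmsecv", "mean_rmsep"),
                        names_to = "metric", values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$metric == "mean_rmsecv", .data$sd_rmsecv,
                  .data$sd_rmsep),
      metric = ifelse(.data$metric == "mean_rmsecv", "RMSECV", "RMSEP"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$mean,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::facet_wrap(~ step, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Error") +
    ggplot2::theme_minimal()
}

#' Plot threshold counts
#'
#' @param counts Output of [summarize_threshold_counts()].
#' @return A ggplot tile plot of counts per baseline x normalization cell.
#' @export
plot_threshold_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$normalize_method,
                                       y = .data$baseline_method,
                                       fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "Normalization", y = "Baseline correction",
                  fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot PCA exploration scores
#'
#' @param explore Output of [pca_explore()].
#' @param colour_by Column of the scores tibble to color by.
#' @return A ggplot object of PC1 vs PC2.
#' @export
plot_pca_explore <- function(explore, colour_by = "label") {
  ev <- explore$explained_variance
  ggplot2::ggplot(explore$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ev$proportion[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ev$proportion[2])) +
    ggplot2::theme_minimal()
}
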
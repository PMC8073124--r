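#' Class coding for the regression task
#'
#' Fixed class-to-score map used as the PLSR response, ordered by assumed
#' cancer progression: benign -2, primary tumor -1, metastatic lines 0, 1, 2
#' (arbitrary order within the metastatic group).
#'
#' @return Named numeric vector.
#' @export
class_coding <- function() {
  c("RWPE-1" = -2, "22Rv1" = -1, "PC3" = 0, "Du145" = 1, "LNCaP" = 2)
}

#' Class-membership indicator matrix
#'
#' @param labels Character vector of class labels.
#' @param classes Class order for the columns (default: order of
#'   [class_coding()] restricted to the observed classes).
#' @return 0/1 matrix `n x n_classes`, each row summing to 1.
#' @export
membership_matrix <- function(labels, classes = NULL) {
  if (is.null(classes)) {
    known <- names(class_coding())
    classes <- c(intersect(known, unique(labels)),
                 setdiff(unique(labels), known))
  }
  if (!all(labels %in% classes))
    stop("labels outside the class set: ",
         paste(setdiff(labels, classes), collapse = ", "), call. = FALSE)
  Y <- outer(labels, classes, `==`) * 1
  colnames(Y) <- classes
  Y
}

#' Kennard-Stone calibration/test split, per class
#'
#' Within each class independently: start from the pair of spectra with the
#' largest Euclidean distance, then repeatedly add the candidate whose
#' minimum distance to the already-selected spectra is largest, until
#' `floor(fraction * class size)` spectra are selected. Selected spectra
#' form the model (calibration) set, the remainder the test set. The
#' procedure is fully deterministic. With the study's class sizes
#' (14, 7, 7, 10, 10) and `fraction = 0.75` this yields 34 model and 14
#' test spectra.
#'
#' @param set A `spectra_set` (distances on the raw spectra).
#' @param fraction Model-set fraction in (0, 1), default 0.75.
#' @return A tibble with columns `id`, `label`, `subset`
#'   (`"model"`/`"test"`); attribute `fraction`.
#' @export
kennard_stone_split <- function(set, fraction = 0.75) {
  stopifnot(fraction > 0, fraction < 1)
  out <- tibble::tibble(id = set$ids, label = set$labels,
                        subset = NA_character_)
  for (cl in unique(set$labels)) {
    rows <- which(set$labels == cl)
    if (length(rows) < 2L)
      stop("class '", cl, "' has fewer than 2 spectra", call. = FALSE)
    k <- floor(fraction * length(rows))
    if (k >= length(rows))
      warning("class '", cl, "' has an empty test set at fraction ",
              fraction)
    sel <- kennard_stone_select(set$absorbance[rows, , drop = FALSE], k)
    out$subset[rows] <- "test"
    out$subset[rows[sel]] <- "model"
  }
  attr(out, "fraction") <- fraction
  out
}

# greedy max-min selection of k rows of X; returns row indices
kennard_stone_select <- function(X, k) {
  n <- nrow(X)
  if (k <= 0L) return(integer(0))
  D <- as.matrix(stats::dist(X))
  start <- which(D == max(D), arr.ind = TRUE)[1, ]
  sel <- sort(unname(start))
  if (k == 1L) return(sel[1])
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    mind <- apply(D[cand, sel, drop = FALSE], 1L, min)
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

#' Materialize a split into model/test spectra sets
#'
#' @param set A `spectra_set`.
#' @param split Output of [kennard_stone_split()].
#' @return Named list of `spectra_set`s: `model`, `test`.
#' @export
split_spectra <- function(set, split) {
  list(model = subset_spectra(set, split$id[split$subset == "model"]),
       test = subset_spectra(set, split$id[split$subset == "test"]))
}

#' Fit a partial least squares model (NIPALS)
#'
#' Mean-centered NIPALS PLS1. A matrix response is fitted as independent
#' single-response models sharing the latent-variable count, one per column
#' (the one-vs-all convention used for the discriminant analysis). No
#' variable scaling is applied.
#'
#' @param X Predictor matrix `n x p`.
#' @param Y Response vector, or matrix with one model per column.
#' @param n_lv Number of latent variables,
#'   `1 <= n_lv <= min(n - 1, p)`.
#' @return A `pls_model`: centering vectors, per-response weights `W`,
#'   loadings `P`, response loadings `q`, scores `T`, and the
#'   regression-coefficient array `beta` (`p x n_responses x n_lv`,
#'   coefficients for every nested component count).
#' @export
pls_fit <- function(X, Y, n_lv) {
  X <- as.matrix(X)
  yv <- is.null(dim(Y))
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y row counts differ", call. = FALSE)
  if (n_lv > min(n - 1L, p))
    stop("n_lv = ", n_lv, " exceeds min(n - 1, p) = ", min(n - 1L, p),
         call. = FALSE)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc0 <- sweep(X, 2L, x_mean)
  beta <- array(0, dim = c(p, m, n_lv))
  comps <- vector("list", m)
  for (j in seq_len(m)) {
    Xc <- Xc0
    yc <- Y[, j] - y_mean[j]
    W <- P <- matrix(0, p, n_lv)
    Tm <- matrix(0, n, n_lv)
    q <- numeric(n_lv)
    for (a in seq_len(n_lv)) {
      w <- crossprod(Xc, yc)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) { W <- W[, seq_len(a - 1L), drop = FALSE]; break }
      w <- w / nw
      t <- as.numeric(Xc %*% w)
      tt <- sum(t^2)
      pvec <- crossprod(Xc, t) / tt
      qa <- sum(yc * t) / tt
      Xc <- Xc - tcrossprod(t, pvec)
      yc <- yc - qa * t
      W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
    }
    A_eff <- ncol(W)
    for (a in seq_len(A_eff)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      R <- Wa %*% solve(crossprod(Pa, Wa))
      beta[, j, a] <- R %*% q[seq_len(a)]
    }
    if (A_eff < n_lv) for (a in seq((A_eff %||% 0) + 1L, n_lv))
      beta[, j, a] <- beta[, j, max(A_eff, 1L)]
    comps[[j]] <- list(W = W, P = P, scores = Tm, q = q)
  }
  structure(list(n_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
                 beta = beta, components = comps,
                 vector_response = yv),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' `yhat = (X - x_mean) %*% beta[, , n_lv] + y_mean`.
#'
#' @param model A `pls_model`.
#' @param X New predictor matrix with matching columns.
#' @param n_lv Component count to use (default: the fitted maximum).
#' @return Vector (single-response fit) or matrix of predictions.
#' @export
pls_predict <- function(model, X, n_lv = model$n_lv) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean))
    stop("X has ", ncol(X), " columns; model expects ",
         length(model$x_mean), call. = FALSE)
  stopifnot(n_lv >= 1L, n_lv <= model$n_lv)
  Xc <- sweep(X, 2L, model$x_mean)
  pred <- Xc %*% model$beta[, , n_lv, drop = TRUE]
  pred <- matrix(pred, nrow = nrow(X))
  pred <- sweep(pred, 2L, model$y_mean, `+`)
  colnames(pred) <- names(model$y_mean)
  if (model$vector_response) as.numeric(pred) else pred
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$x_mean), " variables, ",
      dim(x$beta)[2], " response(s), ", x$n_lv, " latent variable(s)\n",
      sep = "")
  invisible(x)
}

#' Tidy a PLS model
#'
#' @param x A `pls_model`.
#' @param n_lv Component count for the reported coefficients.
#' @param wavenumber Optional axis to attach to the terms.
#' @param ... Unused.
#' @return Tibble with `term` (variable index), optional `wavenumber`,
#'   `response`, and `estimate` (beta coefficient).
#' @importFrom generics tidy
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, n_lv = x$n_lv, wavenumber = NULL, ...) {
  B <- matrix(x$beta[, , n_lv, drop = TRUE], nrow = dim(x$beta)[1])
  resp <- names(x$y_mean) %||% paste0("y", seq_len(ncol(B)))
  out <- tibble::tibble(
    term = rep(seq_len(nrow(B)), times = ncol(B)),
    response = rep(resp, each = nrow(B)),
    estimate = as.vector(B)
  )
  if (!is.null(wavenumber)) out$wavenumber <- rep(wavenumber, ncol(B))
  out
}

#' Glance at a PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_lv`, `n_variables`, `n_responses`.
#' @importFrom generics glance
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, n_variables = length(x$x_mean),
                 n_responses = dim(x$beta)[2])
}

# held-out predictions for every sample and every component count 1..lv_max
loocv_predictions <- function(X, Y, lv_max) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  lv_max <- as.integer(lv_max)
  cap <- min(n - 2L, ncol(X))
  if (lv_max > cap) {
    warning("lv_max clamped from ", lv_max, " to ", cap)
    lv_max <- cap
  }
  pred <- array(NA_real_, dim = c(n, ncol(Y), lv_max))
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], lv_max)
    for (a in seq_len(lv_max))
      pred[i, , a] <- pls_predict(fit, X[i, , drop = FALSE], a)
  }
  pred
}

#' LOOCV error curve for PLS regression
#'
#' For each latent-variable count 1..`lv_max`, holds out each sample once,
#' fits on the rest, predicts the held-out sample, and reports
#' `RMSECV = sqrt(mean((y - yhat)^2))`.
#'
#' @param X Predictor matrix (`n >= 3` rows).
#' @param y Numeric response.
#' @param lv_max Largest component count (default 8; clamped to `n - 2`
#'   with a warning).
#' @return Tibble with columns `lv`, `rmsecv`.
#' @export
loocv_curve_regression <- function(X, y, lv_max = 8L) {
  if (nrow(as.matrix(X)) < 3L) stop("need n >= 3", call. = FALSE)
  pred <- loocv_predictions(X, matrix(y, ncol = 1), lv_max)
  rmsecv <- apply(pred[, 1, , drop = FALSE], 3L, function(p)
    sqrt(mean((y - p)^2)))
  tibble::tibble(lv = seq_along(rmsecv), rmsecv = rmsecv)
}

#' Latent-variable choice for regression
#'
#' Scans components 1..8 (or the curve length): the chosen LV is the
#' smallest `m` whose RMSECV is strictly below the RMSECV of both of the
#' two following component counts (a local minimum followed by two higher
#' values); when no such local minimum exists the global-minimum LV is
#' taken.
#'
#' @param rmsecv Numeric RMSECV values for LV 1, 2, ....
#' @return Chosen LV (integer).
#' @export
select_lv_regression <- function(rmsecv) {
  n <- length(rmsecv)
  for (m in seq_len(max(n - 2L, 0L))) {
    if (rmsecv[m] < rmsecv[m + 1L] && rmsecv[m] < rmsecv[m + 2L])
      return(m)
  }
  which.min(rmsecv)
}

#' LOOCV accuracy curve for PLS-DA classification
#'
#' For each latent-variable count, leave-one-out folds fit the one-vs-all
#' membership models on the retained samples and assign the held-out sample
#' to the class with the highest predicted membership; the curve reports
#' the fraction of correct assignments.
#'
#' @param X Predictor matrix.
#' @param labels Class labels (>= 2 classes present).
#' @param lv_max Largest component count (default 8).
#' @param classes Class column order (default from [membership_matrix()]).
#' @return Tibble with columns `lv`, `accuracy`.
#' @export
loocv_curve_classification <- function(X, labels, lv_max = 8L,
                                       classes = NULL) {
  if (length(unique(labels)) < 2L)
    stop("need >= 2 classes", call. = FALSE)
  Y <- membership_matrix(labels, classes)
  n <- nrow(as.matrix(X))
  for (i in seq_len(n)) {
    if (length(unique(labels[-i])) < length(unique(labels))) {
      warning("a LOOCV fold loses an entire class; proceeding")
      break
    }
  }
  pred <- loocv_predictions(X, Y, lv_max)
  acc <- apply(pred, 3L, function(p) {
    assigned <- plsda_assign(matrix(p, nrow = n,
                                    dimnames = list(NULL, colnames(Y))))
    mean(assigned == labels)
  })
  tibble::tibble(lv = seq_along(acc), accuracy = acc)
}

#' Latent-variable choice for classification
#'
#' The LV with the highest LOOCV accuracy; ties broken toward the smallest
#' LV.
#'
#' @param acc Numeric accuracies for LV 1, 2, ....
#' @return Chosen LV (integer).
#' @export
select_lv_classification <- function(acc) {
  which.max(acc)
}

#' Assign classes from predicted memberships
#'
#' Per row, the class of the column with the highest predicted membership;
#' exact ties go to the lowest class index (and are reported via a
#' message).
#'
#' @param predicted Matrix `n x n_classes` with class names as column
#'   names, columns in the fixed class order.
#' @return Character vector of assigned classes.
#' @export
plsda_assign <- function(predicted) {
  cls <- colnames(predicted)
  if (is.null(cls)) cls <- paste0("class", seq_len(ncol(predicted)))
  idx <- apply(predicted, 1L, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1L)
      message("tie in predicted membership; assigned to lowest class index")
    w[1]
  })
  cls[idx]
}

#' Root mean square error of prediction
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmsep <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch", call. = FALSE)
  sqrt(mean((y_true - y_pred)^2))
}

#' Classification accuracy
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @return Fraction of equal entries.
#' @export
accuracy <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("length mismatch", call. = FALSE)
  mean(labels_true == labels_pred)
}
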
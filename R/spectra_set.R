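#' Construct a spectra set
#'
#' A `spectra_set` bundles a strictly increasing wavenumber axis (cm^-1), an
#' absorbance matrix (one row per spectrum), per-spectrum class labels and
#' unique ids, and a free-form metadata list. It is the object every
#' preprocessing stage transforms.
#'
#' @param absorbance Numeric matrix, `n_spectra x n_variables`, unitless
#'   absorbance. A single spectrum may be given as a vector.
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, one per column of
#'   `absorbance`. Need not be sorted; columns are permuted so the stored axis
#'   is strictly increasing.
#' @param labels Character vector of class labels, one per spectrum.
#' @param ids Character vector of unique spectrum identifiers. Defaults to
#'   `"s1", "s2", ...`.
#' @param meta Named list of metadata (provenance, seeds, ground-truth
#'   components for synthetic data, ...).
#'
#' @return An object of class `spectra_set`.
#' @export
#' @examples
#' s <- spectra_set(matrix(runif(20), 2), seq(1000, 1900, length.out = 10),
#'                  labels = c("a", "b"))
#' s
spectra_set <- function(absorbance, wavenumber, labels = NULL, ids = NULL,
                        meta = list()) {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1L)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumber <- as.numeric(wavenumber)
  n <- nrow(absorbance)
  if (is.null(labels)) labels <- rep("unlabelled", n)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  labels <- as.character(labels)
  ids <- as.character(ids)

  if (length(wavenumber) != ncol(absorbance))
    stop("wavenumber length (", length(wavenumber),
         ") != absorbance columns (", ncol(absorbance), ")", call. = FALSE)
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]
  absorbance <- absorbance[, ord, drop = FALSE]

  x <- structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         labels = labels, ids = ids, meta = meta),
    class = "spectra_set"
  )
  validate_spectra_set(x)
}

validate_spectra_set <- function(x) {
  wn <- x$wavenumber
  A <- x$absorbance
  if (length(wn) != ncol(A))
    stop("wavenumber length (", length(wn), ") != absorbance columns (",
         ncol(A), ")", call. = FALSE)
  if (any(diff(wn) <= 0))
    stop("wavenumber axis must be strictly increasing (duplicated values?)",
         call. = FALSE)
  if (length(x$labels) != nrow(A) || length(x$ids) != nrow(A))
    stop("labels/ids length must equal the number of spectra", call. = FALSE)
  if (anyDuplicated(x$ids))
    stop("spectrum ids must be unique: ",
         paste(unique(x$ids[duplicated(x$ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(A)))
    stop("absorbance values must all be finite", call. = FALSE)
  dimnames(x$absorbance) <- list(x$ids, NULL)
  x
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra x ",
      length(x$wavenumber), " wavenumbers [",
      format(min(x$wavenumber)), ", ", format(max(x$wavenumber)),
      "] cm^-1\n", sep = "")
  tb <- table(x$labels)
  cat("  classes: ", paste(names(tb), tb, sep = ":", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of spectra / variables in a set
#' @param x A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(x) nrow(x$absorbance)

#' @rdname n_spectra
#' @export
n_variables <- function(x) length(x$wavenumber)

#' Subset the spectra (rows) of a set
#'
#' @param x A `spectra_set`.
#' @param i Row index (logical, integer, or character ids).
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  spectra_set(x$absorbance[i, , drop = FALSE], x$wavenumber,
              labels = x$labels[i], ids = x$ids[i], meta = x$meta)
}

#' Replace the absorbance matrix, keeping axis and annotation
#'
#' Internal convenience used by every per-spectrum transform.
#' @param x A `spectra_set`.
#' @param A Replacement matrix with the same dimensions.
#' @param meta Optional replacement metadata list.
#' @return A `spectra_set`.
#' @keywords internal
set_absorbance <- function(x, A, meta = x$meta) {
  spectra_set(A, x$wavenumber, labels = x$labels, ids = x$ids, meta = meta)
}

#' Tidy view of a spectra set
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `label`, `wavenumber`, `absorbance`
#'   (one row per spectrum x wavenumber).
#' @importFrom tibble as_tibble
#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  tibble::tibble(
    id = rep(x$ids, each = length(x$wavenumber)),
    label = rep(x$labels, each = length(x$wavenumber)),
    wavenumber = rep(x$wavenumber, times = nrow(x$absorbance)),
    absorbance = as.vector(t(x$absorbance))
  )
}

#' Plot the spectra of a set
#'
#' @param object A `spectra_set`.
#' @param colour_by `"label"` (default) or `"id"`.
#' @param ... Unused.
#' @return A ggplot object (wavenumber axis reversed, spectroscopy
#'   convention).
#' @importFrom ggplot2 autoplot
#' @method autoplot spectra_set
#' @export
autoplot.spectra_set <- function(object, colour_by = c("label", "id"), ...) {
  colour_by <- match.arg(colour_by)
  df <- as_tibble.spectra_set(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$wavenumber, y = .data$absorbance,
    group = .data$id, colour = .data[[colour_by]]
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance",
                  colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Read spectra from delimited text
#'
#' Two orientations are accepted and auto-detected:
#' * tall: first column named `wavenumber`, one column per spectrum, header
#'   row holding spectrum ids;
#' * wide: first column `id` (optionally a `label` column), remaining column
#'   names numeric wavenumbers, one row per spectrum.
#'
#' Labels for the tall orientation come from a companion file
#' `<path>.labels` (two columns: `id`, `label`) when present.
#'
#' @param path Path to a TSV/CSV file (delimiter sniffed from the first line).
#' @return A validated `spectra_set`; the axis is sorted ascending with
#'   columns permuted consistently.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  nm <- names(df)
  if (identical(nm[1], "wavenumber")) {
    wn <- df$wavenumber
    if (ncol(df) < 2L) stop("no spectrum columns in ", path, call. = FALSE)
    A <- t(as.matrix(df[, -1, drop = FALSE]))
    ids <- nm[-1]
    labels <- NULL
    lf <- paste0(path, ".labels")
    if (file.exists(lf)) {
      lab <- readr::read_tsv(lf, show_col_types = FALSE, progress = FALSE)
      labels <- lab$label[match(ids, lab$id)]
    }
    spectra_set(A, wn, labels = labels, ids = ids)
  } else if (identical(nm[1], "id")) {
    ids <- as.character(df$id)
    labels <- if ("label" %in% nm) as.character(df$label) else NULL
    val_cols <- setdiff(nm, c("id", "label"))
    wn <- suppressWarnings(as.numeric(val_cols))
    if (anyNA(wn))
      stop("malformed matrix in ", path, ": non-numeric wavenumber column ",
           val_cols[which(is.na(wn))[1]], call. = FALSE)
    spectra_set(as.matrix(df[, val_cols, drop = FALSE]), wn,
                labels = labels, ids = ids)
  } else {
    stop("malformed matrix in ", path,
         ": first column must be 'wavenumber' (tall) or 'id' (wide), got '",
         nm[1], "'", call. = FALSE)
  }
}

#' Write spectra to delimited text
#'
#' Writes the tall orientation understood by [read_spectra()] plus a
#' companion `<path>.labels` file. Doubles round-trip losslessly.
#'
#' @param set A `spectra_set`.
#' @param path Output path; `.tsv` recommended.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  df <- tibble::as_tibble(as.data.frame(t(set$absorbance)),
                          .name_repair = "minimal")
  names(df) <- set$ids
  df <- dplyr::bind_cols(tibble::tibble(wavenumber = set$wavenumber), df)
  readr::write_tsv(df, path, progress = FALSE)
  readr::write_tsv(tibble::tibble(id = set$ids, label = set$labels),
                   paste0(path, ".labels"), progress = FALSE)
  invisible(path)
}
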
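# Readers/writers for the supported on-disk formats: dense CSV/TSV with a
# header of feature names and a first column of cell ids, MatrixMarket
# sparse matrices with feature/barcode sidecars, and two-column label files.

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", tsv = "tsv", mtx = "mtx",
    abort(sprintf("cannot infer format from extension '.%s'; pass `format`", ext))
  )
}

#' Read a cells-by-features matrix
#'
#' Dense CSV/TSV files must have a header row of feature names and a first
#' column of cell identifiers. MatrixMarket (`.mtx`) files are read together
#' with `features.tsv` and `barcodes.tsv` sidecars in the same directory
#' (the usual genes-by-cells orientation on disk is transposed so that cells
#' are rows; pass `transpose = FALSE` if the file is already cells-by-genes).
#'
#' @param path Input file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; inferred from the extension
#'   when `NULL`.
#' @param transpose For `mtx`: whether the on-disk matrix is
#'   features-by-cells and must be transposed (default `TRUE`, the common
#'   convention).
#' @return A numeric matrix with cell ids as rownames and feature ids as
#'   colnames.
#' @export
read_matrix <- function(path, format = NULL, transpose = TRUE) {
  format <- format %||% format_from_path(path)
  if (format %in% c("csv", "tsv")) {
    df <- readr::read_delim(path, delim = if (format == "csv") "," else "\t",
                            show_col_types = FALSE, progress = FALSE)
    if (ncol(df) < 2) abort("expected a cell-id column plus at least one feature column")
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    if (length(bad)) {
      abort(sprintf("non-numeric feature column(s): %s",
                    paste(names(df[-1])[bad], collapse = ", ")))
    }
    m <- as.matrix(df[-1])
    rownames(m) <- as.character(df[[1]])
    as_cell_matrix(m)
  } else if (format == "mtx") {
    dir <- dirname(path)
    fpath <- file.path(dir, "features.tsv")
    bpath <- file.path(dir, "barcodes.tsv")
    if (!file.exists(fpath) || !file.exists(bpath)) {
      abort("mtx input requires features.tsv and barcodes.tsv sidecars in the same directory")
    }
    m <- as.matrix(Matrix::readMM(path))
    features <- readr::read_tsv(fpath, col_names = FALSE, show_col_types = FALSE,
                                progress = FALSE)[[1]]
    barcodes <- readr::read_tsv(bpath, col_names = FALSE, show_col_types = FALSE,
                                progress = FALSE)[[1]]
    if (transpose) m <- t(m)
    if (nrow(m) != length(barcodes) || ncol(m) != length(features)) {
      abort(sprintf("matrix is %d x %d after orientation but sidecars give %d cells x %d features",
                    nrow(m), ncol(m), length(barcodes), length(features)))
    }
    dimnames(m) <- list(barcodes, features)
    as_cell_matrix(m)
  } else {
    abort(sprintf("unknown format '%s'", format))
  }
}

#' Write a cells-by-features matrix
#'
#' @param x Matrix or data frame (see [as_cell_matrix()]).
#' @param path Output file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; inferred from the extension
#'   when `NULL`. `mtx` writes `features.tsv` and `barcodes.tsv` sidecars
#'   next to the matrix, in features-by-cells orientation.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = NULL) {
  x <- as_cell_matrix(x)
  format <- format %||% format_from_path(path)
  ids <- rownames(x) %||% sprintf("cell%d", seq_len(nrow(x)))
  feats <- colnames(x) %||% sprintf("f%d", seq_len(ncol(x)))
  if (format %in% c("csv", "tsv")) {
    df <- tibble::as_tibble(x, .name_repair = ~feats)
    df <- dplyr::bind_cols(tibble::tibble(cell_id = ids), df)
    readr::write_delim(df, path, delim = if (format == "csv") "," else "\t")
  } else if (format == "mtx") {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(t(x), sparse = TRUE), path)
    readr::write_tsv(tibble::tibble(feature = feats), file.path(dir, "features.tsv"),
                     col_names = FALSE)
    readr::write_tsv(tibble::tibble(barcode = ids), file.path(dir, "barcodes.tsv"),
                     col_names = FALSE)
  } else {
    abort(sprintf("unknown format '%s'", format))
  }
  invisible(path)
}

#' Read / write cluster labels
#'
#' Labels are stored as a two-column CSV (`cell_id`, `label`).
#'
#' @param path File path.
#' @return `read_labels()`: a tibble with columns `cell_id` and `label`.
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("cell_id", "label") %in% names(df))) {
    abort("label file must have columns `cell_id` and `label`")
  }
  if (is.numeric(df$label) && all(df$label == round(df$label))) {
    df$label <- as.integer(df$label)
  }
  df
}

#' @rdname read_labels
#' @param labels Label vector or `pm_clusters`.
#' @param cell_ids Optional cell identifiers (default `cell1..celln`).
#' @export
write_labels <- function(labels, path, cell_ids = NULL) {
  labels <- label_vector(labels)
  cell_ids <- cell_ids %||% sprintf("cell%d", seq_along(labels))
  readr::write_csv(tibble::tibble(cell_id = cell_ids, label = labels), path)
  invisible(path)
}
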
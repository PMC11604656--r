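#' Spot-level expression dataset
#'
#' Container for a spot-by-gene count matrix with spot positions, an optional
#' normalized expression layer, and a record of applied quality-control
#' filters. Counts are stored as a sparse [Matrix::Matrix] with spots in rows
#' (named by barcode) and genes in columns.
#'
#' @param counts Non-negative integer matrix or sparse Matrix, spots x genes,
#'   with unique row (barcode) and column (gene) names.
#' @param positions Data frame with one row per barcode and columns
#'   `barcode`, `in_tissue` (0/1), `array_row`, `array_col`, `x_um`, `y_um`.
#'   Must cover every barcode in `counts`; may contain additional
#'   out-of-tissue barcodes.
#' @param normalized Optional numeric matrix of the same shape as `counts`
#'   (a normalized layer).
#' @param qc_state Named list recording applied filters.
#'
#' @return An object of class `spot_dataset`.
#' @export
spot_dataset <- function(counts, positions, normalized = NULL,
                         qc_state = list()) {
  counts <- as_count_matrix(counts)
  positions <- as_tibble(positions)
  req <- c("barcode", "in_tissue", "array_row", "array_col", "x_um", "y_um")
  missing_cols <- setdiff(req, names(positions))
  if (length(missing_cols) > 0) {
    abort(paste0("positions is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate barcodes in counts")
  if (anyDuplicated(colnames(counts))) abort("duplicate gene ids in counts")
  if (anyDuplicated(positions$barcode)) abort("duplicate barcodes in positions")
  if (!all(rownames(counts) %in% positions$barcode)) {
    abort("positions do not cover all count matrix barcodes")
  }
  if (!is.null(normalized)) {
    if (!identical(dim(normalized), dim(counts))) {
      abort("normalized layer dimensions differ from counts")
    }
    dimnames(normalized) <- dimnames(counts)
  }
  structure(
    list(counts = counts, positions = positions, normalized = normalized,
         qc_state = qc_state),
    class = "spot_dataset"
  )
}

as_count_matrix <- function(m) {
  if (is.null(rownames(m)) || (ncol(m) > 0 && is.null(colnames(m)))) {
    abort("counts must have barcode rownames and gene colnames")
  }
  m <- methods::as(methods::as(Matrix(m, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  v <- m@x
  if (any(v < 0) || any(v != round(v))) {
    abort("counts must be non-negative integers")
  }
  m
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat("<spot_dataset> ", nrow(x$counts), " spots x ", ncol(x$counts),
      " genes\n", sep = "")
  cat("  total counts: ", sum(x$counts), "\n", sep = "")
  cat("  normalized layer: ", ifelse(is.null(x$normalized), "absent",
                                     "present"), "\n", sep = "")
  if (length(x$qc_state) > 0) {
    cat("  qc: ", paste(names(x$qc_state), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of spots / genes in a dataset
#' @param ds A [spot_dataset()].
#' @return Integer count.
#' @export
n_spots <- function(ds) nrow(ds$counts)

#' @rdname n_spots
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' Spot barcodes of a dataset
#' @param ds A [spot_dataset()].
#' @return Character vector of barcodes, in matrix row order.
#' @export
spot_barcodes <- function(ds) rownames(ds$counts)

#' Positions of in-matrix spots, in matrix row order
#' @param ds A [spot_dataset()].
#' @return Tibble of positions aligned with the count matrix rows.
#' @export
spot_positions <- function(ds) {
  ds$positions[match(rownames(ds$counts), ds$positions$barcode), ]
}
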
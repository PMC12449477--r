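#' Cell table: the universal per-cell input record
#'
#' A `cell_table` bundles per-cell geometry (centroid, area) with a sparse
#' cell-by-gene count matrix bound to a fixed gene panel. Coordinates follow
#' the image convention of instrument exports (x rightward, y downward), all
#' distances in micrometres and areas in square micrometres.
#'
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `area`.
#' @param counts sparse or dense numeric matrix, cells in rows (rownames =
#'   `cell_id`), genes in columns (colnames = panel genes). Raw tables must be
#'   non-negative integers; normalized tables (see `normalized`) may hold
#'   non-integral values.
#' @param panel character vector of panel gene symbols; defaults to
#'   `colnames(counts)`.
#' @param normalized logical; `TRUE` marks library-size-normalized expression
#'   for which the integer invariant is waived.
#'
#' @return An object of class `cell_table`: a list with elements `cells`
#'   (data.table), `counts` (dgCMatrix), `panel` (character) and `normalized`.
#' @export
cell_table <- function(cells, counts, panel = colnames(counts),
                       normalized = FALSE) {
  cells <- data.table::as.data.table(cells)
  need <- c("cell_id", "x", "y", "area")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  cells[, cell_id := as.character(cell_id)]
  if (anyDuplicated(cells$cell_id))
    stop("cell_id values must be unique")
  if (any(!is.finite(cells$area)) || any(cells$area <= 0))
    stop("cell areas must be strictly positive")
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y)))
    stop("cell centroids must be finite")

  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != nrow(cells))
    stop("counts has ", nrow(counts), " rows but cell table has ",
         nrow(cells), " cells")
  if (is.null(colnames(counts)))
    colnames(counts) <- panel
  if (is.null(panel)) stop("a gene panel is required")
  panel <- as.character(panel)
  if (anyDuplicated(panel)) stop("panel gene names must be unique")
  if (!all(colnames(counts) %in% panel))
    stop("counts columns contain genes absent from the panel: ",
         paste(utils::head(setdiff(colnames(counts), panel), 5),
               collapse = ", "))
  if (!identical(colnames(counts), panel)) {
    # widen to the full panel so every table over a panel is conformable
    full <- Matrix::Matrix(0, nrow(counts), length(panel), sparse = TRUE,
                           dimnames = list(rownames(counts), panel))
    full[, colnames(counts)] <- counts
    counts <- methods::as(full, "CsparseMatrix")
  }
  rownames(counts) <- cells$cell_id

  v <- counts@x
  if (any(v < 0)) stop("counts must be non-negative")
  if (!normalized && any(v != round(v)))
    stop("counts must be integers; found non-integral values")

  structure(list(cells = cells, counts = counts, panel = panel,
                 normalized = isTRUE(normalized)),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf(
    "<cell_table> %d cells x %d panel genes (%s counts)\n",
    nrow(x$cells), length(x$panel),
    if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  field: x [%.1f, %.1f] um, y [%.1f, %.1f] um, %d nonzeros\n",
              min(x$cells$x), max(x$cells$x), min(x$cells$y), max(x$cells$y),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) c(nrow(x$cells), length(x$panel))

#' Counts for one gene across all cells
#' @param table a `cell_table`.
#' @param gene gene symbol, must be in the panel.
#' @return numeric vector of counts, one per cell.
#' @export
gene_counts <- function(table, gene) {
  stopifnot(inherits(table, "cell_table"))
  if (!gene %in% table$panel)
    stop("gene '", gene, "' is not in the panel")
  as.numeric(table$counts[, gene])
}

#' Subset a cell table by cell
#' @param table a `cell_table`.
#' @param keep logical or integer index, or character cell ids.
#' @return a `cell_table` with the selected cells.
#' @export
subset_cells <- function(table, keep) {
  stopifnot(inherits(table, "cell_table"))
  if (is.character(keep)) keep <- match(keep, table$cells$cell_id)
  cell_table(table$cells[keep, ], table$counts[keep, , drop = FALSE],
             panel = table$panel, normalized = table$normalized)
}
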
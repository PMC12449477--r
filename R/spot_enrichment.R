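#' Filter low-count genes and cells, then library-size normalize
#'
#' Removes genes with fewer than `min_gene_counts` total counts, then cells
#' with fewer than `min_cell_counts` remaining counts, then scales each
#' surviving cell so its total equals the median per-cell total of the
#' unfiltered input (total-count normalization).
#'
#' @param table a raw [cell_table()].
#' @param min_gene_counts gene total-count floor (default 10; a gene with
#'   total 9 is removed, 10 retained).
#' @param min_cell_counts cell total-count floor (default 10).
#' @return a normalized `cell_table` restricted to the surviving genes and
#'   cells (the panel shrinks to the retained genes).
#' @export
filter_and_normalize <- function(table, min_gene_counts = 10,
                                 min_cell_counts = 10) {
  stopifnot(inherits(table, "cell_table"))
  target <- stats::median(Matrix::rowSums(table$counts))
  gkeep <- Matrix::colSums(table$counts) >= min_gene_counts
  m <- table$counts[, gkeep, drop = FALSE]
  ckeep <- Matrix::rowSums(m) >= min_cell_counts
  if (!any(ckeep))
    stop("filtering removed every cell")
  m <- m[ckeep, , drop = FALSE]
  tot <- Matrix::rowSums(m)
  m <- Matrix::Diagonal(x = target / tot) %*% m
  cell_table(table$cells[ckeep, ], m, panel = colnames(m), normalized = TRUE)
}

#' Grid the field of view into k x k spots
#'
#' Divides the bounding box of the cell centroids into `k` equal bins per
#' axis (k = 125 gives the 15,625-spot configuration) and sums the member
#' cells' expression per spot.
#'
#' @param table a [cell_table()] (usually [filter_and_normalize()]d).
#' @param k spots per axis (>= 2).
#' @return object of class `spot_grid`: `k`, `expr` (sparse k^2 x genes,
#'   spot linear index ix + (iy-1)*k), `spot_ix` / `spot_iy`, `bbox`, and
#'   `cell_spot` (per-cell spot index).
#' @export
spot_grid <- function(table, k = 125) {
  stopifnot(inherits(table, "cell_table"))
  if (k < 2) stop("spot grid needs k >= 2")
  if (nrow(table$cells) == 0) stop("cannot grid an empty cell table")
  x <- table$cells$x; y <- table$cells$y
  bbox <- c(xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y))
  sx <- (bbox["xmax"] - bbox["xmin"]) / k
  sy <- (bbox["ymax"] - bbox["ymin"]) / k
  ix <- pmin(floor((x - bbox["xmin"]) / sx) + 1L, k)  # right edge closes
  iy <- pmin(floor((y - bbox["ymin"]) / sy) + 1L, k)
  lin <- as.integer(ix + (iy - 1L) * k)
  S <- Matrix::sparseMatrix(i = lin, j = seq_along(lin), x = 1,
                            dims = c(k * k, length(lin)))
  expr <- methods::as(S %*% table$counts, "CsparseMatrix")
  grid_iy <- rep(seq_len(k), each = k)
  grid_ix <- rep(seq_len(k), times = k)
  structure(list(k = as.integer(k), expr = expr, spot_ix = grid_ix,
                 spot_iy = grid_iy, bbox = bbox, cell_spot = lin,
                 panel = colnames(expr)),
            class = "spot_grid")
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("<spot_grid> %d x %d = %d spots, %d genes\n",
              x$k, x$k, x$k^2, ncol(x$expr)))
  invisible(x)
}

#' Nearest-rank upper quantile cutoff
#'
#' The ceiling nearest-rank definition: the cutoff is the value at sorted
#' rank `ceiling(q * n)`, unambiguous on integers and reproducible across
#' platforms.
#'
#' @param v numeric vector.
#' @param q quantile in (0, 1).
#' @return the cutoff value.
#' @export
nearest_rank_quantile <- function(v, q) {
  sort(v)[ceiling(q * length(v))]
}

#' Call per-spot DEGs by the top-quantile rule
#'
#' A gene is a DEG in a spot when its expression there is in the top
#' `1 - q` of its own expression across all spots (at or above the
#' per-gene nearest-rank `q`-quantile) and strictly positive. A gene that
#' is constant and positive across spots saturates the rule (DEG
#' everywhere); such genes are flagged. The alternative per-spot-across-
#' genes reading is available via `per = "spot"`.
#'
#' @param grid a [spot_grid()].
#' @param q quantile (default 0.95, the top-5% rule).
#' @param per `"gene"` (default: rank each gene across spots) or `"spot"`
#'   (rank genes within each spot).
#' @return logical spots x genes matrix of class `spot_deg_set` with
#'   attributes `cutoff` (per-gene vector, for `per = "gene"`) and
#'   `degenerate` (constant-positive genes).
#' @export
call_spot_degs <- function(grid, q = 0.95, per = c("gene", "spot")) {
  stopifnot(inherits(grid, "spot_grid"))
  if (q <= 0 || q >= 1) stop("quantile must lie in (0, 1)")
  per <- match.arg(per)
  E <- as.matrix(grid$expr)
  if (per == "gene") {
    cutoff <- apply(E, 2, nearest_rank_quantile, q = q)
    deg <- sweep(E, 2, cutoff, ">=") & E > 0
    degenerate <- apply(E, 2, function(v) min(v) == max(v) && v[1] > 0)
  } else {
    cutoff <- apply(E, 1, nearest_rank_quantile, q = q)
    deg <- sweep(E, 1, cutoff, ">=") & E > 0
    degenerate <- rep(FALSE, ncol(E))
  }
  names(degenerate) <- colnames(E)
  if (any(degenerate))
    warning("top-quantile rule saturates for constant positive gene(s): ",
            paste(names(degenerate)[degenerate], collapse = ", "))
  structure(deg, cutoff = cutoff, degenerate = degenerate,
            class = c("spot_deg_set", class(deg)))
}

#' Hypergeometric over-representation maps per spot
#'
#' For every spot and gene set: the one-sided hypergeometric upper-tail
#' probability of observing at least the realised overlap between the
#' spot's DEG set and the term's genes, given the panel background; BH
#' adjustment is applied across terms within each spot (each spot's DEG
#' set is one query). Map values are `-log10` of the (floored) p-values;
#' both raw and adjusted maps are returned.
#'
#' @param degs a [call_spot_degs()] result (or any logical spots x genes
#'   matrix).
#' @param sets named list of gene sets (e.g. from [read_gmt()]); every set
#'   must be a subset of the background.
#' @param background character vector of background genes (the panel;
#'   302 genes in the reference configuration). Defaults to the DEG matrix
#'   columns.
#' @param floor p-value floor before `-log10` (default 1e-300).
#' @return object of class `enrichment_map`: list with `p` and `q`
#'   (spots x terms matrices), `minus_log10_q`, `minus_log10_p`, and
#'   `background_size`.
#' @export
enrich_spots <- function(degs, sets, background = colnames(degs),
                         floor = 1e-300) {
  deg <- as.matrix(degs)
  if (!all(colnames(deg) %in% background))
    stop("DEG genes must be contained in the background")
  bad <- names(sets)[!vapply(sets, function(s) all(s %in% background), TRUE)]
  if (length(bad))
    stop("gene set(s) not a subset of the background: ",
         paste(bad, collapse = ", "))
  N <- length(background)
  ndeg <- rowSums(deg)
  P <- matrix(NA_real_, nrow(deg), length(sets),
              dimnames = list(NULL, names(sets)))
  for (j in seq_along(sets)) {
    K <- length(sets[[j]])
    inset <- colnames(deg) %in% sets[[j]]
    x <- rowSums(deg[, inset, drop = FALSE])
    P[, j] <- stats::phyper(x - 1, K, N - K, ndeg, lower.tail = FALSE)
  }
  Q <- t(apply(P, 1, stats::p.adjust, method = "BH"))
  if (length(sets) == 1L) Q <- matrix(Q, ncol = 1,
                                      dimnames = dimnames(P))
  structure(list(p = P, q = Q,
                 minus_log10_p = -log10(pmax(P, floor)),
                 minus_log10_q = -log10(pmax(Q, floor)),
                 background_size = N),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("<enrichment_map> %d spots x %d terms (background %d genes)\n",
              nrow(x$p), ncol(x$p), x$background_size))
  invisible(x)
}

#' Pearson correlation between two spot maps
#'
#' @param map_a,map_b numeric vectors over the same spots (e.g. a gene's
#'   per-spot expression and a term's -log10 adjusted p map).
#' @return the Pearson product-moment correlation; `NA` with a warning when
#'   either map has zero variance or fewer than 3 spots.
#' @export
correlate_map <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stop("maps must cover the same spots")
  if (length(map_a) < 3 ||
      stats::var(map_a) == 0 || stats::var(map_b) == 0) {
    warning("map correlation undefined (zero variance or < 3 spots)")
    return(NA_real_)
  }
  stats::cor(map_a, map_b)
}
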
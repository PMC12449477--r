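#' Gene density (counts per square micrometre)
#'
#' Per-cell density divides each cell's counts by its area; per-region
#' density pools counts and areas of the member cells (sum of counts over
#' sum of areas), with membership by centroid-in-polygon.
#'
#' @param table a [cell_table()].
#' @param grouping `"cell"` or `"region"`.
#' @param regions list of [region_polygon()] (required for `"region"`).
#' @return for `"cell"`: a dense-or-sparse matrix cells x genes of densities;
#'   for `"region"`: a matrix regions x genes with region labels as rownames.
#' @export
density_profile <- function(table, grouping = c("cell", "region"),
                            regions = NULL) {
  stopifnot(inherits(table, "cell_table"))
  grouping <- match.arg(grouping)
  if (grouping == "cell") {
    d <- Matrix::Diagonal(x = 1 / table$cells$area) %*% table$counts
    rownames(d) <- table$cells$cell_id
    return(d)
  }
  if (is.null(regions)) stop("region densities need region polygons")
  out <- matrix(0, length(regions), length(table$panel),
                dimnames = list(vapply(regions, `[[`, "", "label"),
                                table$panel))
  for (i in seq_along(regions)) {
    inside <- point_in_polygon(table$cells$x, table$cells$y, regions[[i]])
    if (!any(inside))
      stop("region '", regions[[i]]$label, "' contains no cells")
    out[i, ] <- Matrix::colSums(table$counts[inside, , drop = FALSE]) /
      sum(table$cells$area[inside])
  }
  out
}

#' Welch's t, BH correction and Cohen's d for a two-group contrast
#'
#' Per gene (column): Welch's unequal-variance t statistic with
#' Welch-Satterthwaite degrees of freedom and a two-sided p (A - B
#' orientation), Benjamini-Hochberg step-up q over the genes tested in this
#' call, and Cohen's d with the pooled Bessel-corrected standard deviation.
#' Degenerate genes: when both groups are constant and equal the test is
#' vacuous (t = 0, p = 1, d = 0); when both are constant but unequal, t, p
#' and d are undefined and flagged.
#'
#' @param A,B numeric matrices (units x genes, same columns) or vectors
#'   (one gene) of densities; each group needs >= 2 units.
#' @param var_equal use the pooled-variance Student t instead of Welch
#'   (provided for comparability; Welch is the default).
#' @return data.table of class `comparison_table`: `gene`, `n_A`, `n_B`,
#'   `mean_A`, `mean_B`, `t`, `p`, `q`, `d`, `undefined`.
#' @export
welch_bh_cohen <- function(A, B, var_equal = FALSE) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 1, dimnames = list(NULL, "gene"))
  if (is.null(dim(B))) B <- matrix(B, ncol = 1, dimnames = list(NULL, "gene"))
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must cover the same genes")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 units")
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)

  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(mA))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1)))
  }
  t <- (mA - mB) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)

  sp <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2))
  d <- (mA - mB) / sp

  zero <- vA == 0 & vB == 0
  vac <- zero & mA == mB      # constant and equal: nothing to test
  und <- zero & mA != mB      # constant but unequal: statistics undefined
  t[vac] <- 0; p[vac] <- 1; d[vac] <- 0
  t[und] <- NA_real_; p[und] <- NA_real_; d[und] <- NA_real_

  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")

  genes <- colnames(A)
  if (is.null(genes)) genes <- paste0("g", seq_along(mA))
  out <- data.table::data.table(
    gene = genes, n_A = nA, n_B = nB, mean_A = mA, mean_B = mB,
    t = t, p = p, q = q, d = d, undefined = und)
  data.table::setattr(out, "class",
                      c("comparison_table", class(out)))
  out
}

#' Hot/cold tumour-cell classification
#'
#' A cell is immune-hot when its basis-gene (default CD274) count is at
#' least 2, immune-cold when the count is 1 or 0.
#'
#' @param table a [cell_table()].
#' @param basis_gene classification gene; must be in the panel.
#' @return data.table of `cell_id`, `label` ("hot"/"cold"), with the class
#'   counts attached as attribute `counts` and reported via `message()`.
#' @export
classify_hotcold <- function(table, basis_gene = "CD274") {
  stopifnot(inherits(table, "cell_table"))
  if (!basis_gene %in% table$panel)
    stop("hot/cold basis gene '", basis_gene, "' is not in the panel")
  cnt <- gene_counts(table, basis_gene)
  label <- ifelse(cnt >= 2, "hot", "cold")
  out <- data.table::data.table(cell_id = table$cells$cell_id, label = label)
  tab <- c(hot = sum(label == "hot"), cold = sum(label == "cold"))
  message(sprintf("hot/cold by %s >= 2: %d hot, %d cold",
                  basis_gene, tab["hot"], tab["cold"]))
  attr(out, "counts") <- tab
  out
}

#' Hot vs cold gene-density contrast
#'
#' Per-gene contrast of per-cell (or per-region) gene density between hot
#' and cold cells via [welch_bh_cohen()] (A = hot, B = cold, so d > 0 means
#' higher in hot). Poorly segmented cells can be excluded by id.
#'
#' @param table a [cell_table()].
#' @param labels data.table from [classify_hotcold()] (or any `cell_id` /
#'   `label` table with levels "hot" and "cold").
#' @param level `"cell"` or `"region"`.
#' @param exclude character vector of cell ids to drop before testing.
#' @param hot_regions,cold_regions lists of [region_polygon()] delineating
#'   the two region sets (required for `level = "region"`).
#' @return a `comparison_table` (see [welch_bh_cohen()]).
#' @export
hotcold_contrast <- function(table, labels, level = c("cell", "region"),
                             exclude = NULL,
                             hot_regions = NULL, cold_regions = NULL) {
  stopifnot(inherits(table, "cell_table"))
  level <- match.arg(level)
  if (length(exclude)) {
    keep <- !table$cells$cell_id %in% exclude
    table <- subset_cells(table, keep)
  }
  if (level == "cell") {
    lab <- labels$label[match(table$cells$cell_id, labels$cell_id)]
    if (!any(lab == "hot", na.rm = TRUE) || !any(lab == "cold", na.rm = TRUE))
      stop("hot/cold contrast needs both classes non-empty")
    dens <- as.matrix(density_profile(table, "cell"))
    welch_bh_cohen(dens[which(lab == "hot"), , drop = FALSE],
                   dens[which(lab == "cold"), , drop = FALSE])
  } else {
    if (is.null(hot_regions) || is.null(cold_regions))
      stop("region-level contrast needs hot_regions and cold_regions")
    if (!length(hot_regions) || !length(cold_regions))
      stop("hot/cold contrast needs both classes non-empty")
    dh <- density_profile(table, "region", hot_regions)
    dc <- density_profile(table, "region", cold_regions)
    welch_bh_cohen(dh, dc)
  }
}
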
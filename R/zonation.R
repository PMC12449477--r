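#' Aggregate a cell table onto a regular grid
#'
#' Lays a square lattice of spacing `s` (default 10 um) over the bounding box
#' of the cell centroids and pools each cell's counts into the grid cell
#' containing its centroid, under half-open bins `[x0 + i*s, x0 + (i+1)*s)`.
#'
#' @param table a [cell_table()].
#' @param s grid spacing in micrometres (> 0).
#' @param origin optional `c(x0, y0)`; defaults to the centroid minimum.
#' @return object of class `grid_field`: `origin`, `s`, `nx`, `ny`, sparse
#'   `counts` (grid cells x genes, linear index ix + (iy-1)*nx), and
#'   `cell_index` (per input cell linear grid index).
#' @export
build_grid <- function(table, s = 10, origin = NULL) {
  stopifnot(inherits(table, "cell_table"))
  if (s <= 0) stop("grid spacing must be > 0")
  if (nrow(table$cells) == 0) stop("cannot grid an empty cell table")
  x <- table$cells$x; y <- table$cells$y
  if (is.null(origin)) origin <- c(min(x), min(y))
  ix <- floor((x - origin[1]) / s) + 1L
  iy <- floor((y - origin[2]) / s) + 1L
  if (any(ix < 1 | iy < 1))
    stop("cells found left/above the grid origin")
  nx <- max(ix); ny <- max(iy)
  lin <- ix + (iy - 1L) * nx
  S <- Matrix::sparseMatrix(i = lin, j = seq_along(lin), x = 1,
                            dims = c(nx * ny, length(lin)))
  counts <- S %*% table$counts
  structure(list(origin = origin, s = s, nx = nx, ny = ny,
                 counts = methods::as(counts, "CsparseMatrix"),
                 cell_index = lin, panel = table$panel),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %d x %d cells at %g um (origin %.1f, %.1f)\n",
              x$nx, x$ny, x$s, x$origin[1], x$origin[2]))
  invisible(x)
}

grid_gene_matrix <- function(grid, gene) {
  matrix(grid$counts[, gene], grid$nx, grid$ny)
}

#' Tumour mask from a grid-level marker rule
#'
#' A grid cell is tumour when its aggregated count is at least `min_pos` for
#' every positive marker and exactly 0 for every negative marker (the
#' positive/negative grid rule; the per-cell n >= 2 threshold does not carry
#' to grids, which pool several cells, so the minimal literal reading
#' `min_pos = 1` is the default and exposed as an argument).
#'
#' @param grid a [build_grid()] result.
#' @param rule a [marker_config()] with `tumour_rule`, or a list with
#'   `positive` / `negative` marker vectors.
#' @param min_pos aggregated-count threshold for positive markers.
#' @return logical `nx x ny` matrix (`mask[ix, iy]`).
#' @export
tumour_mask <- function(grid, rule, min_pos = 1L) {
  stopifnot(inherits(grid, "grid_field"))
  if (inherits(rule, "marker_config")) rule <- rule$tumour_rule
  if (is.null(rule$positive)) stop("tumour rule needs positive markers")
  missing <- setdiff(c(rule$positive, rule$negative), grid$panel)
  if (length(missing))
    stop("tumour rule references genes not in panel: ",
         paste(missing, collapse = ", "))
  ok <- rep(TRUE, grid$nx * grid$ny)
  for (g in rule$positive)
    ok <- ok & (as.numeric(grid$counts[, g]) >= min_pos)
  for (g in rule$negative)
    ok <- ok & (as.numeric(grid$counts[, g]) == 0)
  matrix(ok, grid$nx, grid$ny)
}

# 3x3 neighbourhood sum with replicate padding at the borders
neigh_sum3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- m[c(1, seq_len(nx), nx), c(1, seq_len(ny), ny)]
  acc <- matrix(0, nx, ny)
  for (dx in 0:2) for (dy in 0:2)
    acc <- acc + p[dx + seq_len(nx), dy + seq_len(ny)]
  acc
}

#' Smooth a binary mask (3x3 median, then 3x3 mean re-binarized)
#'
#' Clarifies the tumour boundary: a 3x3 median filter removes salt-and-pepper
#' speckle, then a 3x3 uniform mean filter re-binarized at >= 0.5 rounds the
#' outline. Borders are padded by replication. (On binary input both steps
#' reduce to "at least 5 of the 9 neighbours"; they are kept as written so
#' each filter states its own rule.)
#'
#' @param mask logical matrix.
#' @return smoothed logical matrix of the same shape.
#' @export
smooth_mask <- function(mask) {
  med <- neigh_sum3(mask * 1) >= 5          # median of 9 booleans
  blur <- neigh_sum3(med * 1) / 9           # uniform 3x3 mean
  blur >= 0.5
}

# 8-connected component label of each true cell, flood fill with an
# explicit stack of linear indices; component ids follow raster-scan order
# (rows/y outer, columns/x inner) of each component's first pixel
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  offs <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  stack <- integer(nx * ny)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (!mask[ix, iy] || lab[ix, iy] > 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- ix + (iy - 1L) * nx
    lab[ix, iy] <- cur
    while (top > 0L) {
      lin <- stack[top]; top <- top - 1L
      px <- ((lin - 1L) %% nx) + 1L
      py <- ((lin - 1L) %/% nx) + 1L
      for (k in 1:8) {
        qx <- px + offs[k, 1]; qy <- py + offs[k, 2]
        if (qx < 1 || qy < 1 || qx > nx || qy > ny) next
        if (mask[qx, qy] && lab[qx, qy] == 0L) {
          lab[qx, qy] <- cur
          top <- top + 1L
          stack[top] <- qx + (qy - 1L) * nx
        }
      }
    }
  }
  lab
}

# clockwise Moore neighbourhood starting east, in (dx, dy) pairs
moore <- matrix(c(1, 0, 1, 1, 0, 1, -1, 1, -1, 0, -1, -1, 0, -1, 1, -1),
                ncol = 2, byrow = TRUE)

#' Extract the tumour surface contour
#'
#' Border following on the smoothed mask: connected components are found in
#' raster-scan order and only the first outer contour in that hierarchy is
#' traced (Moore boundary tracing), mirroring hierarchical contour
#' extraction on images; `which = "largest"` instead selects the
#' maximal-area component, since raster order is an artefact of the origin.
#'
#' @param mask logical matrix (the smoothed tumour mask).
#' @param which `"first"` (raster-order first component) or `"largest"`.
#' @return data.table of `ix`, `iy` in boundary-walk order (closed walk; a
#'   single-cell component yields that one cell).
#' @export
extract_contour <- function(mask, which = c("first", "largest")) {
  which <- match.arg(which)
  if (!any(mask)) stop("cannot extract a contour from an empty mask")
  lab <- label_components(mask)
  comp <- if (which == "first") 1L else which.max(tabulate(lab[lab > 0L]))
  m <- lab == comp
  nx <- nrow(m); ny <- ncol(m)
  inm <- function(x, y) x >= 1 && y >= 1 && x <= nx && y <= ny && m[x, y]

  # start: first component pixel in raster order, entered from the west
  start <- NULL
  for (iy in seq_len(ny)) {
    xs <- which(m[, iy])
    if (length(xs)) { start <- c(xs[1], iy); break }
  }
  path <- list(start)
  # direction index of the backtrack pixel relative to current (west = 5)
  p <- start; bdir <- 5L
  first_move <- NULL
  max_steps <- 4L * sum(m) + 8L             # walk length bound
  steps <- 0L
  repeat {
    found <- FALSE
    for (k in seq_len(8)) {
      dir <- ((bdir - 1L + k) %% 8L) + 1L   # clockwise from backtrack
      q <- p + moore[dir, ]
      if (inm(q[1], q[2])) {
        move <- list(p = p, dir = dir)
        if (!is.null(first_move) &&
            identical(move, first_move)) {
          found <- FALSE                    # closed the walk
        } else {
          if (is.null(first_move)) first_move <- move
          path[[length(path) + 1L]] <- q
          bdir <- ((dir + 3L) %% 8L) + 1L   # new backtrack: towards old p
          p <- q
          found <- TRUE
        }
        break
      }
    }
    steps <- steps + 1L
    if (!found || steps > max_steps) break  # isolated pixel or walk closed
  }
  pts <- do.call(rbind, path)
  out <- data.table::data.table(ix = pts[, 1], iy = pts[, 2])
  unique(out)
}

#' Signed shortest-path distance field from the tumour surface
#'
#' The grid is treated as a graph with nodes at the grid cells and edges
#' between neighbours weighted by their Euclidean separation (`s` for
#' orthogonal moves, `s * sqrt(2)` for diagonal under 8-connectivity).
#' Multi-source shortest paths from the contour cells are computed by
#' synchronous min-plus relaxation iterated to fixpoint (exact for positive
#' edge weights). The sign is negative inside the tumour mask (off the
#' contour), zero on the contour, positive outside.
#'
#' @param mask logical matrix (the smoothed tumour mask).
#' @param contour data.table of contour `ix`, `iy` (sources at distance 0).
#' @param s grid spacing, micrometres.
#' @param connectivity 8 (default) or 4.
#' @return object of class `distance_field`: signed distance matrix `d`
#'   (micrometres; `NA` flags unreachable cells), plus `s`, `connectivity`
#'   and the `contour`.
#' @export
distance_field <- function(mask, contour, s = 10, connectivity = 8) {
  if (nrow(contour) == 0) stop("contour must be non-empty")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nx <- nrow(mask); ny <- ncol(mask)
  D <- matrix(Inf, nx, ny)
  D[cbind(contour$ix, contour$iy)] <- 0

  shifts <- list(c(1, 0, s), c(-1, 0, s), c(0, 1, s), c(0, -1, s))
  if (connectivity == 8) {
    sd <- s * sqrt(2)
    shifts <- c(shifts, list(c(1, 1, sd), c(1, -1, sd),
                             c(-1, 1, sd), c(-1, -1, sd)))
  }
  shifted_plus <- function(M, dx, dy, w) {
    out <- matrix(Inf, nx, ny)
    xs <- seq_len(nx); ys <- seq_len(ny)
    xd <- xs - dx; yd <- ys - dy
    okx <- xd >= 1 & xd <= nx; oky <- yd >= 1 & yd <= ny
    out[xs[okx], ys[oky]] <- M[xd[okx], yd[oky]] + w
    out
  }
  repeat {
    changed <- FALSE
    for (sh in shifts) {
      cand <- shifted_plus(D, sh[1], sh[2], sh[3])
      upd <- cand < D
      if (any(upd)) { D[upd] <- cand[upd]; changed <- TRUE }
    }
    if (!changed) break
  }

  signed <- D
  inside <- mask & D > 0       # mask-true and off the contour
  signed[inside] <- -D[inside]
  signed[is.infinite(D)] <- NA_real_
  structure(list(d = signed, s = s, connectivity = connectivity,
                 contour = contour,
                 unreachable = is.infinite(D)),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  rng <- range(x$d, na.rm = TRUE)
  cat(sprintf(
    "<distance_field> %d x %d at %g um, signed range [%.1f, %.1f] um, %d contour cells\n",
    nrow(x$d), ncol(x$d), x$s, rng[1], rng[2], nrow(x$contour)))
  invisible(x)
}

#' Distance-band partition
#'
#' Named half-open intervals `[lo, hi)` of signed distance. The default is
#' the outside zonation peri `[0, 20)`, mid `[20, 70)`, distal `[70, 120)`
#' micrometres (so a cell at exactly 20 um falls in mid, matching the
#' "< 20 um" peritumour convention).
#'
#' @param lo,hi interval edges (micrometres), equal length.
#' @param name band names.
#' @return data.frame of class `band_partition`.
#' @export
band_partition <- function(lo = c(0, 20, 70), hi = c(20, 70, 120),
                           name = c("peri", "mid", "distal")) {
  if (length(lo) != length(hi) || length(lo) != length(name))
    stop("band definition lengths differ")
  if (any(hi <= lo)) stop("band upper edges must exceed lower edges")
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]; name <- name[o]
  if (any(utils::head(hi, -1) > utils::tail(lo, -1)))
    stop("band definition error: overlapping bands")
  structure(data.frame(name = name, lo = lo, hi = hi,
                       stringsAsFactors = FALSE),
            class = c("band_partition", "data.frame"))
}

#' Uniform bands at a fixed interval
#' @param from,to overall range (micrometres; negative = inside tumour).
#' @param by band width (default 30 um contour interval).
#' @return a [band_partition()], names like `"[-60,-30)"`.
#' @export
uniform_bands <- function(from = -60, to = 150, by = 30) {
  lo <- seq(from, to - by, by = by)
  band_partition(lo, lo + by, sprintf("[%g,%g)", lo, lo + by))
}

band_of <- function(d, bands) {
  out <- rep("beyond", length(d))
  for (i in seq_len(nrow(bands)))
    out[!is.na(d) & d >= bands$lo[i] & d < bands$hi[i]] <- bands$name[i]
  out[is.na(d)] <- "unassigned"
  out
}

#' Assign cells to distance bands and profile the bands
#'
#' Each cell inherits the signed distance of the grid cell holding its
#' centroid and falls into the band containing that distance (or "beyond" /
#' "unassigned" for unreachable grid cells). Band gene densities divide the
#' band's pooled counts by its grid area (grid-cell count times s^2).
#'
#' @param table a [cell_table()].
#' @param grid the [build_grid()] result for `table`.
#' @param dfield a [distance_field()] on that grid.
#' @param bands a [band_partition()].
#' @return list: `labels` (data.table `cell_id`, `distance`, `band`),
#'   `profile` (data.table `band`, `gene`, `density` in counts/um^2), and
#'   `band_area` (named vector, um^2).
#' @export
assign_bands <- function(table, grid, dfield, bands = band_partition()) {
  stopifnot(inherits(table, "cell_table"), inherits(grid, "grid_field"),
            inherits(dfield, "distance_field"),
            inherits(bands, "band_partition"))
  dcell <- as.numeric(dfield$d)[grid$cell_index]
  lab <- band_of(dcell, bands)
  labels <- data.table::data.table(cell_id = table$cells$cell_id,
                                   distance = dcell, band = lab)
  dgrid <- as.numeric(dfield$d)
  gband <- band_of(dgrid, bands)
  prof <- list()
  areas <- numeric(0)
  for (b in bands$name) {
    gsel <- gband == b
    area <- sum(gsel) * grid$s^2
    areas[b] <- area
    tot <- if (any(gsel))
      Matrix::colSums(grid$counts[gsel, , drop = FALSE]) else
        stats::setNames(rep(0, length(grid$panel)), grid$panel)
    prof[[b]] <- data.table::data.table(
      band = b, gene = grid$panel,
      density = if (area > 0) as.numeric(tot) / area else NA_real_)
  }
  list(labels = labels, profile = data.table::rbindlist(prof),
       band_area = areas)
}

#' Per-band class proportions
#'
#' Proportion of each compared class among the classified cells of each
#' band (e.g. CXCL13+CD8+ vs CXCL13-CD8+ T cells); proportions within a
#' band sum to 1 over the compared classes.
#'
#' @param band_labels character vector of band names, one per cell.
#' @param classes character vector of class labels, one per cell; `NA`
#'   cells are excluded from the comparison.
#' @return data.table `band`, `class`, `n`, `proportion`.
#' @export
band_proportions <- function(band_labels, classes) {
  keep <- !is.na(classes)
  dt <- data.table::data.table(band = band_labels[keep],
                               class = classes[keep])
  out <- dt[, list(n = .N), by = c("band", "class")]
  out[, proportion := n / sum(n), by = "band"]
  out[order(band, class)]
}

#' Centroid-linkage (UPGMC) clustering of band profiles
#'
#' Agglomerative clustering of gene-density vectors under Euclidean
#' distance with centroid linkage: the distance between two clusters is the
#' Euclidean distance between their centroids. Merge heights are reported on
#' the Euclidean (not squared) scale; centroid-linkage inversions, if any,
#' are clamped to 0 and flagged.
#'
#' @param profiles numeric matrix, one row per profile (e.g. band x gene
#'   densities), rownames used as labels.
#' @param genes optional subset of columns to cluster on.
#' @return list: `hclust` (merge heights on the Euclidean scale), `newick`
#'   (dendrogram string with branch lengths from the merge heights),
#'   `inversions` (logical).
#' @export
upgmc_cluster <- function(profiles, genes = NULL) {
  profiles <- as.matrix(profiles)
  if (!is.null(genes)) profiles <- profiles[, genes, drop = FALSE]
  if (nrow(profiles) < 2)
    stop("centroid clustering needs at least 2 profiles")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("profile_", seq_len(nrow(profiles)))
  # hclust's centroid method expects squared Euclidean distances and
  # reports merge heights on that squared scale
  hc <- stats::hclust(stats::dist(profiles)^2, method = "centroid")
  inv <- any(diff(hc$height) < 0) || any(hc$height < 0)
  hc$height <- sqrt(pmax(hc$height, 0))
  hc$method <- "UPGMC (Euclidean)"
  phylo <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phylo), inversions = inv)
}
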
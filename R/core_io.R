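#' @importFrom data.table := .N .SD data.table as.data.table fread setnames
NULL

open_text <- function(path) {
  # gzfile() transparently reads both gzip-compressed and plain text
  gzfile(path, open = "rt")
}

read_delim_file <- function(path, header = TRUE, sep = ",") {
  con <- open_text(path)
  on.exit(close(con))
  utils::read.table(con, header = header, sep = sep,
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, quote = "\"")
}

#' Read a cell/matrix/features export bundle
#'
#' Ingests the standard imaging-platform export dialect: a per-cell metadata
#' CSV (`cell_id`, `x_centroid`, `y_centroid`, `cell_area`), a MatrixMarket
#' coordinate count matrix, and gene / cell identifier lists. Inputs may be
#' gzip-compressed. Matrix orientation (genes x cells vs cells x genes) is
#' resolved by matching the feature and cell list lengths against the declared
#' dimensions; when both orientations are consistent (square matrix) the
#' feature-major instrument convention (genes x cells) is preferred, and the
#' choice is reported via `message()`.
#'
#' @param cells_path path to cells.csv(.gz).
#' @param matrix_path path to matrix.mtx(.gz).
#' @param features_path path to features.tsv(.gz), first column = gene symbol.
#' @param cell_ids_path optional path to cells.tsv(.gz) listing cell ids in
#'   matrix order; defaults to the order of `cells_path`.
#' @return a [cell_table()].
#' @export
read_cell_bundle <- function(cells_path, matrix_path, features_path,
                             cell_ids_path = NULL) {
  cells <- read_delim_file(cells_path, sep = ",")
  need <- c("cell_id", "x_centroid", "y_centroid", "cell_area")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells table is missing column(s): ", paste(miss, collapse = ", "))
  cells <- data.table::data.table(
    cell_id = as.character(cells$cell_id),
    x = as.numeric(cells$x_centroid),
    y = as.numeric(cells$y_centroid),
    area = as.numeric(cells$cell_area))

  features <- read_delim_file(features_path, header = FALSE, sep = "\t")[[1]]
  features <- as.character(features)

  ids <- if (is.null(cell_ids_path)) cells$cell_id else
    as.character(read_delim_file(cell_ids_path, header = FALSE, sep = "\t")[[1]])

  con <- open_text(matrix_path)
  on.exit(close(con))
  m <- Matrix::readMM(con)

  nf <- length(features); nc <- length(ids)
  if (nrow(m) == nf && ncol(m) == nc) {
    if (nf == nc)
      message("square count matrix: assuming feature-major (genes x cells) ",
              "orientation")
    m <- Matrix::t(m)          # -> cells x genes
  } else if (nrow(m) == nc && ncol(m) == nf) {
    message("count matrix is cell-major (cells x genes); no transpose applied")
  } else {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither genes x cells (", nf, " x ", nc,
         ") nor cells x genes")
  }
  dimnames(m) <- list(ids, features)

  if (!identical(sort(ids), sort(cells$cell_id)))
    stop("cell ids in the matrix bundle do not match the cells table")
  m <- m[cells$cell_id, , drop = FALSE]

  x <- m@x
  if (any(x < 0)) stop("negative counts in matrix")
  if (any(x != round(x))) stop("non-integral counts in matrix")

  cell_table(cells, m, panel = features)
}

#' Write a cell/matrix/features bundle
#'
#' Emits the same dialect [read_cell_bundle()] consumes:
#' `cells.csv.gz`, `matrix.mtx.gz` (genes x cells), `features.tsv`,
#' `cells.tsv`.
#'
#' @param table a [cell_table()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cell_bundle <- function(table, dir) {
  stopifnot(inherits(table, "cell_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc <- table$cells
  con <- gzfile(file.path(dir, "cells.csv.gz"), "wt")
  utils::write.csv(data.frame(cell_id = cc$cell_id, x_centroid = cc$x,
                              y_centroid = cc$y, cell_area = cc$area),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  writeLines(table$panel, file.path(dir, "features.tsv"))
  writeLines(cc$cell_id, file.path(dir, "cells.tsv"))
  mm_tmp <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::t(table$counts), mm_tmp)  # feature-major on disk
  txt <- readLines(mm_tmp)
  con <- gzfile(file.path(dir, "matrix.mtx.gz"), "wt")
  writeLines(txt, con); close(con)
  unlink(mm_tmp)
  invisible(dir)
}

## ---- region polygons ------------------------------------------------------

ring_area2 <- function(xy) {
  # twice the shoelace signed area
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  sum(xy[j, 1] * xy[, 2] - xy[, 1] * xy[j, 2])
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

ring_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next   # closing edge shares vertex 1
      if (segments_intersect(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' A labelled region polygon
#'
#' Closed ring in micrometre coordinates. The closing vertex (first == last)
#' is de-duplicated and winding is normalized counter-clockwise (positive
#' shoelace area in the x-right / y-down convention used throughout).
#'
#' @param vertices two-column matrix of (x, y) vertices.
#' @param label region label.
#' @return object of class `region_polygon` with elements `label`, `vertices`.
#' @export
region_polygon <- function(vertices, label = "region") {
  xy <- as.matrix(vertices)
  if (ncol(xy) != 2) stop("polygon vertices must be two-column (x, y)")
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n >= 2 && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3)
    stop("polygon '", label, "' needs at least 3 distinct vertices")
  if (ring_self_intersects(xy))
    stop("polygon '", label, "' ring is self-intersecting")
  if (ring_area2(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  colnames(xy) <- c("x", "y")
  structure(list(label = as.character(label), vertices = xy),
            class = "region_polygon")
}

#' @export
print.region_polygon <- function(x, ...) {
  cat(sprintf("<region_polygon> '%s', %d vertices, area %.1f um^2\n",
              x$label, nrow(x$vertices), abs(ring_area2(x$vertices)) / 2))
  invisible(x)
}

#' Read region polygons from a GeoJSON-style file
#'
#' Accepts a FeatureCollection of Polygon features carrying a `label`
#' property (coordinates in micrometres). Only the outer ring of each polygon
#' is used; rings are validated and normalized by [region_polygon()].
#'
#' @param path path to a .geojson file.
#' @return list of `region_polygon`.
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  lapply(feats, function(f) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (!identical(geom$type, "Polygon"))
      stop("unsupported geometry type '", geom$type,
           "': only Polygon regions are accepted")
    ring <- geom$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    label <- if (!is.null(f$properties$label)) f$properties$label else "region"
    region_polygon(xy, label)
  })
}

#' Write region polygons to GeoJSON
#' @param polys list of [region_polygon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polys, path) {
  feats <- lapply(polys, function(p) {
    ring <- lapply(seq_len(nrow(p$vertices)), function(i)
      as.numeric(p$vertices[i, ]))
    ring <- c(ring, ring[1])   # close the ring on disk
    list(type = "Feature",
         properties = list(label = p$label),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Point-in-polygon test (even-odd ray casting)
#' @param x,y point coordinates.
#' @param poly a [region_polygon()].
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  xy <- poly$vertices
  n <- nrow(xy)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## ---- marker configuration -------------------------------------------------

#' Marker configuration for cell typing and the tumour grid rule
#'
#' @param cell_types ordered list of rules; each rule is a list with `label`,
#'   `positive_markers` (non-empty character), optional `negative_markers`,
#'   and optional `mode` ("any", the default, calls the type when any positive
#'   marker is positive; "all" requires every one). Order is the match
#'   priority.
#' @param tumour_rule list with `positive` and `negative` marker vectors used
#'   for the grid-level tumour mask.
#' @param hotcold_gene optional basis gene of the hot/cold rule (e.g.
#'   "CD274"); validated against the panel only when set.
#' @param panel optional panel to validate gene references against.
#' @return object of class `marker_config`.
#' @export
marker_config <- function(cell_types, tumour_rule = NULL,
                          hotcold_gene = NULL, panel = NULL) {
  for (rule in cell_types) {
    if (is.null(rule$label) || !nzchar(rule$label))
      stop("every cell-type rule needs a label")
    if (length(rule$positive_markers) == 0)
      stop("cell type '", rule$label, "' has no positive markers")
  }
  cfg <- structure(list(cell_types = cell_types, tumour_rule = tumour_rule,
                        hotcold_gene = hotcold_gene),
                   class = "marker_config")
  if (!is.null(panel)) validate_config(cfg, panel)
  cfg
}

#' @export
print.marker_config <- function(x, ...) {
  cat(sprintf("<marker_config> %d cell-type rules (priority order): %s\n",
              length(x$cell_types),
              paste(vapply(x$cell_types, `[[`, "", "label"),
                    collapse = " > ")))
  if (!is.null(x$tumour_rule))
    cat(sprintf("  tumour grid rule: %s+ / %s-\n",
                paste(x$tumour_rule$positive, collapse = "+ "),
                paste(x$tumour_rule$negative, collapse = "- ")))
  invisible(x)
}

config_genes <- function(cfg) {
  unique(c(unlist(lapply(cfg$cell_types, function(r)
    c(r$positive_markers, r$negative_markers))),
    cfg$tumour_rule$positive, cfg$tumour_rule$negative, cfg$hotcold_gene))
}

#' Validate a marker configuration against a gene panel
#' @param cfg a [marker_config()].
#' @param panel character vector of panel genes.
#' @return `cfg`, invisibly; errors when a rule references an unknown gene.
#' @export
validate_config <- function(cfg, panel) {
  unknown <- setdiff(config_genes(cfg), panel)
  if (length(unknown))
    stop("marker config references genes absent from the panel: ",
         paste(unknown, collapse = ", "))
  invisible(cfg)
}

#' Read a marker/panel configuration from YAML
#'
#' Schema (see `inst/extdata/panel.yaml` for a worked example):
#' ```
#' cell_types:          # ordered: first match wins
#'   - label: epithelial
#'     positive_markers: [CDH1, KRT5]
#'     mode: any
#' tumour_rule:
#'   positive: [CDH1, SFTPB, SFTPC]
#'   negative: [SFTPD]
#' hotcold_gene: CD274
#' ```
#' @param path YAML file path.
#' @param panel optional panel for validation.
#' @return a [marker_config()].
#' @export
read_marker_config <- function(path, panel = NULL) {
  y <- yaml::read_yaml(path)
  marker_config(cell_types = y$cell_types, tumour_rule = y$tumour_rule,
                hotcold_gene = y$hotcold_gene, panel = panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an optional transcript-level table
#'
#' Transcript spots with coordinates, gene and detection quality
#' (`x`, `y`, `feature_name`, `qv`). Whether per-cell counting should be
#' preceded by a quality filter is assay-dependent, so the threshold is
#' exposed but off by default (no filtering).
#'
#' @param path transcripts.csv(.gz).
#' @param min_qv optional quality threshold; transcripts with `qv <
#'   min_qv` are dropped when set.
#' @return data.table with `x`, `y`, `feature_name`, `qv`.
#' @export
read_transcripts <- function(path, min_qv = NULL) {
  tx <- read_delim_file(path, sep = ",")
  need <- c("x", "y", "feature_name", "qv")
  miss <- setdiff(need, names(tx))
  if (length(miss))
    stop("transcript table is missing column(s): ",
         paste(miss, collapse = ", "))
  tx <- data.table::as.data.table(tx[need])
  if (!is.null(min_qv)) tx <- tx[tx$qv >= min_qv, ]
  tx[]
}

#' Read gene sets in GMT format
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

## ---- tabular output -------------------------------------------------------

output_schemas <- list(
  comparison       = c("gene", "n_A", "n_B", "mean_A", "mean_B",
                       "t", "p", "q", "d"),
  band_profile     = c("band", "gene", "density"),
  band_proportions = c("band", "class", "n", "proportion"),
  enrichment       = c("spot_ix", "spot_iy", "term", "minus_log10_q"),
  marker_summary   = c("group", "marker", "mean", "z", "pct_positive"),
  celltypes        = c("cell_id", "label", "markers"),
  labels           = c("cell_id", "label"),
  correlations     = c("map_a", "map_b", "r", "n_spots"),
  distance_field   = c("ix", "iy", "x_centre", "y_centre",
                       "signed_distance", "band")
)

#' Write a typed result table as TSV
#'
#' Validates the rows against one of the pipeline's declared output schemas,
#' then writes a header-bearing TSV with numeric columns at fixed precision
#' (10 significant digits; re-reading reproduces values to that precision).
#' Any schema carrying a `p` column must carry its `q` companion.
#'
#' @param rows data.frame conforming to `format`.
#' @param path output path.
#' @param format one of `r paste(names(output_schemas), collapse=", ")`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format) {
  if (!format %in% names(output_schemas))
    stop("unknown output schema '", format, "'")
  want <- output_schemas[[format]]
  rows <- as.data.frame(rows)
  miss <- setdiff(want, names(rows))
  if (length(miss))
    stop("table for schema '", format, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  if ("p" %in% want && !"q" %in% names(rows))
    stop("tables with p-values must carry BH-adjusted q-values")
  rows <- rows[, want, drop = FALSE]
  out <- rows
  for (cn in names(out))
    if (is.double(out[[cn]]))
      out[[cn]] <- formatC(out[[cn]], digits = 10, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a typed result table
#' @param path TSV written by [write_table()].
#' @param format declared schema name.
#' @return data.frame.
#' @export
read_table <- function(path, format) {
  if (!format %in% names(output_schemas))
    stop("unknown output schema '", format, "'")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
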
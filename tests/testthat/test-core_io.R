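test_that("cell bundle ingest reproduces the triplet entries exactly", {
  dir <- withr::local_tempdir()
  writeLines(c("cell_id,x_centroid,y_centroid,cell_area",
               "c1,1.5,2.5,100", "c2,11.5,2.5,90", "c3,21.5,2.5,80"),
             file.path(dir, "cells.csv"))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 2", "1 1 2", "2 3 1"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2", "c3"), file.path(dir, "cells.tsv"))

  tab <- read_cell_bundle(file.path(dir, "cells.csv"),
                          file.path(dir, "matrix.mtx"),
                          file.path(dir, "features.tsv"),
                          file.path(dir, "cells.tsv"))
  expect_s3_class(tab, "cell_table")
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(as.numeric(tab$counts["c1", "g1"]), 2)
  expect_equal(as.numeric(tab$counts["c3", "g2"]), 1)
  expect_equal(sum(tab$counts), 3)
})

test_that("ingest errors name the problem: schema, dimensions, bad values", {
  dir <- withr::local_tempdir()
  writeLines(c("cell_id,x_centroid,y_centroid", "c1,1,2"),
             file.path(dir, "bad_cells.csv"))
  expect_error(
    read_cell_bundle(file.path(dir, "bad_cells.csv"), "x", "y"),
    "cell_area")

  writeLines(c("cell_id,x_centroid,y_centroid,cell_area", "c1,1,2,50"),
             file.path(dir, "cells.csv"))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 1 1", "1 1 2"), file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
  expect_error(
    read_cell_bundle(file.path(dir, "cells.csv"),
                     file.path(dir, "matrix.mtx"),
                     file.path(dir, "features.tsv")),
    "dimensions")

  expect_error(
    cell_table(data.frame(cell_id = "c1", x = 1, y = 2, area = 0),
               matrix(1, 1, 1, dimnames = list(NULL, "g1"))),
    "positive")
  expect_error(
    cell_table(data.frame(cell_id = "c1", x = 1, y = 2, area = 10),
               matrix(1.5, 1, 1, dimnames = list(NULL, "g1"))),
    "integer")
  expect_error(
    cell_table(data.frame(cell_id = c("c1", "c1"), x = 1:2, y = 1:2,
                          area = c(10, 10)),
               matrix(0L, 2, 1, dimnames = list(NULL, "g1"))),
    "unique")
})

test_that("bundle round-trip preserves cells, genes and nonzeros exactly", {
  sim <- generate_tissue(small_spec(seed = 11))
  dir <- withr::local_tempdir()
  write_cell_bundle(sim$table, dir)
  back <- suppressMessages(read_cell_bundle(
    file.path(dir, "cells.csv.gz"), file.path(dir, "matrix.mtx.gz"),
    file.path(dir, "features.tsv"), file.path(dir, "cells.tsv")))
  expect_equal(dim(back), dim(sim$table))
  expect_equal(back$panel, sim$table$panel)
  expect_true(all(back$counts == sim$table$counts))
  expect_equal(back$cells$area, sim$table$cells$area, tolerance = 1e-12)

  # determinism of orientation inference: same input, same result
  back2 <- suppressMessages(read_cell_bundle(
    file.path(dir, "cells.csv.gz"), file.path(dir, "matrix.mtx.gz"),
    file.path(dir, "features.tsv"), file.path(dir, "cells.tsv")))
  expect_identical(back$counts, back2$counts)
})

test_that("polygon rings are validated, deduplicated and wound consistently", {
  sq <- region_polygon(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)), "unit")
  expect_equal(nrow(sq$vertices), 4)

  # repeated first==last closing vertex is dropped
  closed <- region_polygon(rbind(c(0, 0), c(0, 2), c(2, 2), c(2, 0), c(0, 0)))
  expect_equal(nrow(closed$vertices), 4)

  # winding normalized: shoelace area positive regardless of input order
  a1 <- region_polygon(rbind(c(0, 0), c(0, 1), c(1, 1)))
  a2 <- region_polygon(rbind(c(0, 0), c(1, 1), c(0, 1)))
  shoelace <- function(v) {
    n <- nrow(v); j <- c(n, seq_len(n - 1))
    sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2
  }
  expect_gt(shoelace(a1$vertices), 0)
  expect_gt(shoelace(a2$vertices), 0)

  expect_error(region_polygon(rbind(c(0, 0), c(1, 1))), "3 distinct")
  expect_error(
    region_polygon(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)), "bowtie"),
    "self-intersecting")
})

test_that("GeoJSON round-trip preserves labels and vertices", {
  polys <- list(
    region_polygon(rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0)), "A"),
    region_polygon(rbind(c(20, 20), c(30, 25), c(25, 35)), "B"))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_polygons(polys, path)
  back <- read_polygons(path)
  expect_length(back, 2)
  expect_equal(vapply(back, `[[`, "", "label"), c("A", "B"))
  expect_equal(back[[1]]$vertices, polys[[1]]$vertices)

  writeLines('{"type":"FeatureCollection","features":[{"type":"Feature",
    "properties":{"label":"pt"},
    "geometry":{"type":"Point","coordinates":[1,2]}}]}', path)
  expect_error(read_polygons(path), "Polygon")
})

test_that("typed table writing enforces schemas and round-trips numerically", {
  cmp <- welch_bh_cohen(matrix(rnorm(20, 5), 10, 2,
                               dimnames = list(NULL, c("gA", "gB"))),
                        matrix(rnorm(20, 6), 10, 2,
                               dimnames = list(NULL, c("gA", "gB"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(cmp, path, "comparison")
  back <- read_table(path, "comparison")
  expect_equal(back$t, cmp$t, tolerance = 1e-8)
  expect_equal(back$q, cmp$q, tolerance = 1e-8)

  # header-only file for an empty table
  empty <- cmp[0, ]
  write_table(empty, path, "comparison")
  expect_equal(length(readLines(path)), 1L)

  expect_error(write_table(cmp, path, "no_such_schema"), "unknown")
  noq <- cmp; noq$q <- NULL
  expect_error(write_table(noq, path, "comparison"), "q")
})

test_that("marker config validates labels and gene references", {
  cfg <- marker_config(list(
    list(label = "CAF", positive_markers = "COL1A1")),
    tumour_rule = list(positive = c("CDH1"), negative = "SFTPD"))
  expect_error(validate_config(cfg, c("CDH1", "SFTPD")), "COL1A1")
  expect_silent(validate_config(cfg, c("CDH1", "SFTPD", "COL1A1")))
  expect_error(marker_config(list(list(label = "x",
                                       positive_markers = character(0)))),
               "no positive markers")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cell_types:",
               "  - label: CAF",
               "    positive_markers: [COL1A1]",
               "tumour_rule:",
               "  positive: [CDH1]",
               "  negative: [SFTPD]",
               "hotcold_gene: CD274"), path)
  cfg2 <- read_marker_config(path)
  expect_equal(cfg2$cell_types[[1]]$label, "CAF")
  expect_equal(cfg2$hotcold_gene, "CD274")
})

test_that("transcript tables read with the optional quality filter off/on", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,feature_name,qv",
               "1.5,2.0,CXCL9,40", "3.0,4.0,CXCL9,10", "5.0,6.0,CD8A,25"),
             path)
  tx <- read_transcripts(path)           # default: no filtering
  expect_equal(nrow(tx), 3)
  tx20 <- read_transcripts(path, min_qv = 20)
  expect_equal(nrow(tx20), 2)
  expect_true(all(tx20$qv >= 20))
  writeLines(c("x,y,gene", "1,2,CXCL9"), path)
  expect_error(read_transcripts(path), "feature_name")
})

test_that("GMT gene sets parse into named lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ifn_program\tdesc\tIFNG\tCXCL9\tCXCL10",
               "b_cells\tdesc\tCD19\tPOU2AF1"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("ifn_program", "b_cells"))
  expect_equal(sets$ifn_program, c("IFNG", "CXCL9", "CXCL10"))
})
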
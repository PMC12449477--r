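#' @title Pipeline orchestration
#' @name pipeline
#' @description Runs the full analysis over one tissue: (optional) synthetic
#'   simulation, cell typing, densities, zonation, band clustering, spot
#'   enrichment and hot/cold contrast, with every stage's effective
#'   configuration embedded in the output manifest.
NULL

# tiny polynomial rolling hash: stable fingerprint for manifests, no extra
# deps (kept within double-precision exact-integer range)
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = TRUE,             # generate synthetic tissue; else read input_dir
    input_dir = NULL,
    spacing = 10,                # zonation grid spacing, um
    tau = 2L,                    # positivity threshold
    band_edges = c(0, 20, 70, 120),
    k = 125L,                    # spot grid
    deg_quantile = 0.95,
    min_gene_counts = 10,
    min_cell_counts = 10,
    mask_min_pos = 1L,
    contour = "first",
    connectivity = 8,
    hotcold_gene = "CD274",
    gene_sets = NULL             # path to a GMT file (optional)
  )
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> typecells -> density -> zonate ->
#' cluster -> enrich -> hotcold, writing each stage's tables plus
#' `manifest.json` (effective config, config hash, package version) under
#' `out_dir`. Identical config and seed reproduce identical outputs; a
#' stage failure stops with the stage name and marks the manifest
#' incomplete.
#'
#' @param config list overriding the defaults (see source of
#'   `default_pipeline_config`): seed, spacing, tau, band_edges, k,
#'   deg_quantile, filters, mask/contour/connectivity flags, hotcold gene,
#'   optional GMT path, and either `simulate = TRUE` or an `input_dir`
#'   holding a cell bundle.
#' @param out_dir output directory.
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                               digits = NA, null = "null")
  manifest <- list(config = cfg, config_hash = fnv1a(as.character(cfg_json)),
                   package_version = as.character(
                     utils::packageVersion("perizone")),
                   complete = FALSE)
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  write_manifest()

  stage <- function(name, expr) {
    message(sprintf("[%s] stage %s: start", format(Sys.time()), name))
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] stage %s: done", format(Sys.time()), name))
    res
  }

  sim <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      spec <- tissue_spec(seed = cfg$seed)
      generate_tissue(spec)
    })
    table <- sim$table
    regions <- sim$regions
  } else {
    if (is.null(cfg$input_dir))
      stop("config error: input_dir is required when simulate = FALSE")
    table <- stage("ingest", read_cell_bundle(
      file.path(cfg$input_dir, "cells.csv.gz"),
      file.path(cfg$input_dir, "matrix.mtx.gz"),
      file.path(cfg$input_dir, "features.tsv"),
      file.path(cfg$input_dir, "cells.tsv")))
    rg <- file.path(cfg$input_dir, "regions.geojson")
    regions <- if (file.exists(rg)) read_polygons(rg) else list()
  }

  mc <- default_tissue_marker_config(table$panel)

  calls <- stage("typecells", assign_cell_types(table, mc, tau = cfg$tau))
  write_table(calls, file.path(out_dir, "celltypes.tsv"), "celltypes")

  zon <- stage("zonate", {
    grid <- build_grid(table, s = cfg$spacing)
    mask <- smooth_mask(tumour_mask(grid, mc, min_pos = cfg$mask_min_pos))
    contour <- extract_contour(mask, which = cfg$contour)
    dfield <- distance_field(mask, contour, s = cfg$spacing,
                             connectivity = cfg$connectivity)
    e <- cfg$band_edges
    bands <- band_partition(utils::head(e, -1), utils::tail(e, -1),
                            c("peri", "mid", "distal")[seq_len(length(e) - 1)])
    ab <- assign_bands(table, grid, dfield, bands)
    list(grid = grid, mask = mask, contour = contour, dfield = dfield,
         bands = bands, assignment = ab)
  })
  write_table(zon$assignment$profile,
              file.path(out_dir, "band_profile.tsv"), "band_profile")

  clus <- stage("cluster", {
    prof <- data.table::dcast(zon$assignment$profile, band ~ gene,
                              value.var = "density")
    m <- as.matrix(prof[, -1]); rownames(m) <- prof$band
    upgmc_cluster(m)
  })
  writeLines(clus$newick, file.path(out_dir, "band_dendrogram.nwk"))

  enr <- stage("enrich", {
    norm <- filter_and_normalize(table, cfg$min_gene_counts,
                                 cfg$min_cell_counts)
    sg <- spot_grid(norm, k = cfg$k)
    degs <- call_spot_degs(sg, q = cfg$deg_quantile)
    sets <- if (!is.null(cfg$gene_sets)) read_gmt(cfg$gene_sets) else NULL
    emap <- if (!is.null(sets))
      enrich_spots(degs, sets, background = table$panel) else NULL
    list(grid = sg, degs = degs, map = emap)
  })

  hc <- stage("hotcold", {
    labels <- classify_hotcold(table, cfg$hotcold_gene)
    tum <- calls$cell_id[calls$label == "epithelial"]
    tumour_tab <- subset_cells(table, table$cells$cell_id %in% tum)
    contrast <- hotcold_contrast(
      tumour_tab, labels[labels$cell_id %in% tum], level = "cell")
    list(labels = labels, contrast = contrast)
  })
  write_table(hc$labels, file.path(out_dir, "hotcold_labels.tsv"), "labels")
  write_table(hc$contrast, file.path(out_dir, "hotcold_comparison.tsv"),
              "comparison")

  manifest$complete <- TRUE
  write_manifest()
  invisible(list(table = table, regions = regions, calls = calls,
                 zonation = zon, clustering = clus, enrichment = enr,
                 hotcold = hc, manifest = manifest))
}

#' Default marker configuration for the synthetic panel
#'
#' The priority-ordered typing rules matching [default_panel()] /
#' [default_expression_rates()], plus the tumour grid rule
#' (CDH1+/SFTPB+/SFTPC+ with SFTPD-) and the CD274 hot/cold basis.
#'
#' @param panel optional panel for validation.
#' @return a [marker_config()].
#' @export
default_tissue_marker_config <- function(panel = NULL) {
  marker_config(
    cell_types = list(
      list(label = "epithelial",
           positive_markers = c("CDH1", "KRT5", "KRT8", "EPCAM"),
           mode = "any"),
      list(label = "CAF", positive_markers = "COL1A1"),
      list(label = "myeloid", positive_markers = c("CD68", "CD163"),
           mode = "any"),
      list(label = "LYM", positive_markers = c("PTPRC", "CD3E", "CD8A"),
           mode = "any"),
      list(label = "plasma", positive_markers = "POU2AF1")),
    tumour_rule = list(positive = c("CDH1", "SFTPB", "SFTPC"),
                       negative = "SFTPD"),
    hotcold_gene = "CD274",
    panel = panel)
}
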
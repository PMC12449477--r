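# Shared fixtures, all built in code at test time.

# tiny hand-specified cell table over a named panel
make_tiny_table <- function(counts, x = NULL, y = NULL, area = NULL) {
  n <- nrow(counts)
  cells <- data.frame(
    cell_id = sprintf("c%d", seq_len(n)),
    x = if (is.null(x)) seq_len(n) * 10 else x,
    y = if (is.null(y)) rep(5, n) else y,
    area = if (is.null(area)) rep(100, n) else area)
  cell_table(cells, counts)
}

# small, fast tissue spec (same structure as the default study conditions,
# scaled down) for tests that only need plumbing, not statistical power
small_spec <- function(seed = 1L, ...) {
  tissue_spec(field_size = c(400, 400), n_cells = 4000L,
              tumour_nests = list(c(200, 200, 150)), seed = seed, ...)
}

# default-conditions simulation, cached per seed across the test run
.sim_cache <- new.env(parent = emptyenv())
get_default_sim <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_tissue(tissue_spec(seed = seed))
  .sim_cache[[key]]
}

# full zonation path (grid -> mask -> contour -> distances -> bands)
run_zonation <- function(table, s = 10, bands = band_partition()) {
  grid <- build_grid(table, s = s)
  mc <- default_tissue_marker_config(table$panel)
  mask <- smooth_mask(tumour_mask(grid, mc))
  contour <- extract_contour(mask)
  dfield <- distance_field(mask, contour, s = s)
  ab <- assign_bands(table, grid, dfield, bands)
  list(grid = grid, mask = mask, contour = contour, dfield = dfield,
       assignment = ab)
}

# peri/distal mean chemokine-count ratio among immune-typed cells
peri_distal_ratio <- function(sim) {
  z <- run_zonation(sim$table)
  calls <- assign_cell_types(sim$table,
                             default_tissue_marker_config(sim$table$panel))
  imm <- calls$label %in% c("myeloid", "LYM")
  chem <- gene_counts(sim$table, "CXCL9") + gene_counts(sim$table, "CXCL13")
  band <- z$assignment$labels$band
  mean(chem[imm & band == "peri"]) / mean(chem[imm & band == "distal"])
}
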
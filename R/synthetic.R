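#' Default 302-gene synthetic panel
#'
#' A synthetic stand-in for a targeted lung/immune in situ panel: canonical
#' epithelial, stromal, myeloid, lymphocyte, plasma, chemokine, interferon and
#' checkpoint markers, padded with filler genes (`GENE###`) to the 302-gene
#' panel size used as the enrichment background.
#'
#' @param size panel size (default 302).
#' @return character vector of gene symbols.
#' @export
default_panel <- function(size = 302L) {
  markers <- c("CDH1", "KRT5", "KRT8", "EPCAM", "SFTPB", "SFTPC", "SFTPD",
               "COL1A1", "CD68", "CD163", "MSR1", "PTPRC", "CD3E", "CD4",
               "CD8A", "CD19", "POU2AF1", "GZMB", "CXCL9", "CXCL10",
               "CXCL13", "CXCL16", "CXCR6", "IFNG", "CD274", "CTLA4",
               "MKI67", "CTNNB1", "IDO1", "LAG3")
  if (size < length(markers)) stop("panel size too small for marker set")
  c(markers, sprintf("GENE%03d", seq_len(size - length(markers))))
}

default_expression_rates <- function() {
  list(
    epithelial = c(CDH1 = 4, KRT5 = 4, KRT8 = 4, EPCAM = 4, SFTPB = 4,
                   SFTPC = 4, CTNNB1 = 1),
    CAF        = c(COL1A1 = 6),
    myeloid    = c(CD68 = 4, CD163 = 4, MSR1 = 2, CXCL9 = 0.8,
                   CXCL16 = 1, CXCL10 = 0.4),
    LYM        = c(PTPRC = 4, CD3E = 4, CD8A = 2, CD4 = 1, GZMB = 1,
                   CXCL13 = 0.8, IFNG = 0.4, CXCR6 = 1, CTLA4 = 0.5),
    plasma     = c(POU2AF1 = 6, CD19 = 1),
    other      = c()
  )
}

#' Synthetic tissue specification
#'
#' The study conditions the generator emulates: tumour nests of epithelial
#' cells inside an otherwise uniformly mixed stroma, chemokine expression in
#' immune cells enriched near the nest surface, an interferon-coupled latent
#' field correlating designated gene maps, and a mosaic of hot/cold
#' (CD274-high/low) tumour subclones.
#'
#' @param field_size c(width, height) in micrometres.
#' @param n_cells number of cells to place.
#' @param tumour_nests list of `c(x, y, r)` circles (micrometres).
#' @param cell_type_mixture named proportions over cell types; must sum to 1.
#'   The `epithelial` fraction is confined to the nests, all other types are
#'   placed by complete spatial randomness over the whole field.
#' @param expression_rates named list: type -> named Poisson mean vector for
#'   that type's marker genes.
#' @param background_rate Poisson mean applied to every panel gene in every
#'   cell (ambient background).
#' @param chemokine_genes genes whose immune-cell rates are multiplied by
#'   `peri_fold` near the nest surface.
#' @param immune_types cell types subject to peri-enrichment.
#' @param peri_fold fold-change f (> 0) applied within `d_peri` of a nest
#'   boundary (both sides of the surface).
#' @param d_peri enrichment half-width around the nest boundary, micrometres.
#' @param hotcold list: `patch` (patch size, um), `hot_fraction` in [0, 1],
#'   `lambda_hot` / `lambda_cold` (CD274 rates, >= 2 and <= 0.2 so the
#'   downstream >= 2 / <= 1 rule is recoverable), `prolif_gene`,
#'   `prolif_hot` / `prolif_cold` (proliferation-marker rates).
#' @param coupling list: `rho` in [0, 1], `genes` sharing the latent field,
#'   `sigma` (log-scale sd), `cell` (latent lattice spacing, um).
#' @param area list: `meanlog`, `sdlog`, `min` of the lognormal cell-area
#'   distribution (um^2).
#' @param panel gene panel (default [default_panel()]).
#' @param seed integer RNG seed.
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(field_size = c(800, 800),
                        n_cells = 20000L,
                        tumour_nests = list(c(400, 400, 300)),
                        cell_type_mixture = c(epithelial = 0.50, CAF = 0.12,
                                              myeloid = 0.13, LYM = 0.17,
                                              plasma = 0.04, other = 0.04),
                        expression_rates = default_expression_rates(),
                        background_rate = 0.01,
                        chemokine_genes = c("CXCL9", "CXCL13"),
                        immune_types = c("myeloid", "LYM"),
                        peri_fold = 3,
                        d_peri = 20,
                        hotcold = list(patch = 100, hot_fraction = 0.5,
                                       lambda_hot = 3, lambda_cold = 0.1,
                                       prolif_gene = "MKI67",
                                       prolif_hot = 0.5, prolif_cold = 2.5),
                        coupling = list(rho = 0.74,
                                        genes = c("IFNG", "CXCL9", "CXCL10",
                                                  "CXCL13"),
                                        sigma = 0.5, cell = 25),
                        area = list(meanlog = log(80), sdlog = 0.4, min = 10),
                        panel = default_panel(),
                        seed = 1L) {
  if (n_cells < 1) stop("tissue spec error: n_cells must be positive")
  if (abs(sum(cell_type_mixture) - 1) > 1e-8)
    stop("tissue spec error: cell_type_mixture must sum to 1")
  if (any(cell_type_mixture < 0))
    stop("tissue spec error: negative mixture proportion")
  if (peri_fold <= 0) stop("tissue spec error: peri_fold must be > 0")
  if (coupling$rho < 0 || coupling$rho > 1)
    stop("tissue spec error: coupling rho must lie in [0, 1]")
  if (hotcold$hot_fraction < 0 || hotcold$hot_fraction > 1)
    stop("tissue spec error: hot fraction must lie in [0, 1]")
  for (nest in tumour_nests) {
    if (nest[3] <= 0) stop("tissue spec error: nest radius must be > 0")
    if (nest[1] - nest[3] < 0 || nest[2] - nest[3] < 0 ||
        nest[1] + nest[3] > field_size[1] || nest[2] + nest[3] > field_size[2])
      stop("tissue spec error: nest exceeds field bounds")
  }
  rates <- unlist(expression_rates)
  if (length(rates) && any(rates < 0))
    stop("tissue spec error: expression rates must be >= 0")
  unknown <- setdiff(unique(unlist(lapply(expression_rates, names))), panel)
  if (length(unknown))
    stop("tissue spec error: rate genes not in panel: ",
         paste(unknown, collapse = ", "))
  structure(list(field_size = field_size, n_cells = as.integer(n_cells),
                 tumour_nests = tumour_nests,
                 cell_type_mixture = cell_type_mixture,
                 expression_rates = expression_rates,
                 background_rate = background_rate,
                 chemokine_genes = chemokine_genes,
                 immune_types = immune_types,
                 peri_fold = peri_fold, d_peri = d_peri,
                 hotcold = hotcold, coupling = coupling, area = area,
                 panel = panel, seed = as.integer(seed)),
            class = "tissue_spec")
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat(sprintf(
    "<tissue_spec> %d cells on %g x %g um, %d nest(s), f=%g within %g um, rho=%g, seed=%d\n",
    x$n_cells, x$field_size[1], x$field_size[2], length(x$tumour_nests),
    x$peri_fold, x$d_peri, x$coupling$rho, x$seed))
  invisible(x)
}

# signed analytic distance (um) to the nearest nest boundary:
# negative inside a nest, positive outside, computed from the circles alone
# so generator truth never depends on the grid pipeline under test
nest_signed_distance <- function(x, y, nests) {
  d <- rep(Inf, length(x))
  for (nest in nests)
    d <- pmin(d, sqrt((x - nest[1])^2 + (y - nest[2])^2) - nest[3])
  d
}

#' Mosaic hot/cold patch labels
#'
#' Tiles the field with square patches of side `patch_size` and labels each
#' patch hot with probability `hot_fraction`; cells inherit their patch's
#' label, producing spatially autocorrelated mosaic subclones.
#'
#' @param x,y cell coordinates (micrometres).
#' @param patch_size patch side, micrometres.
#' @param hot_fraction probability a patch is hot; in [0, 1].
#' @param seed RNG seed.
#' @return data.table with `patch_id` and `label` ("hot"/"cold") per cell.
#' @export
mosaic_hotcold_labels <- function(x, y, patch_size, hot_fraction, seed = 1L) {
  if (hot_fraction < 0 || hot_fraction > 1)
    stop("tissue spec error: hot fraction must lie in [0, 1]")
  pid <- paste(floor(x / patch_size), floor(y / patch_size), sep = "_")
  ids <- sort(unique(pid))
  set.seed(seed)
  hot <- stats::runif(length(ids)) < hot_fraction
  names(hot) <- ids
  data.table::data.table(patch_id = pid,
                         label = ifelse(hot[pid], "hot", "cold"))
}

#' Generate a seeded synthetic tissue
#'
#' Places `n_cells` cells (epithelial cells uniformly within the tumour
#' nests, all other types by complete spatial randomness over the field),
#' draws per-gene counts as Poisson with type-specific rates, multiplies
#' chemokine rates by `peri_fold` for immune cells within `d_peri` of a nest
#' boundary, couples the designated gene group through a shared lattice
#' latent Gaussian log-intensity field with correlation `rho`, assigns mosaic
#' hot/cold labels to tumour cells, and records every latent assignment in a
#' truth table. Identical spec (including seed) reproduces identical output.
#'
#' @param spec a [tissue_spec()].
#' @return list with elements `table` (a [cell_table()]), `regions` (list of
#'   [region_polygon()], one 64-gon per nest), and `truth` (list: `cells`
#'   data.table with per-cell type, analytic signed distance to the nest
#'   surface, enrichment flag, band, patch and hot/cold label; `coupling`
#'   calibration record; `spec`).
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  types <- names(spec$cell_type_mixture)
  type <- sample(types, n, replace = TRUE, prob = spec$cell_type_mixture)

  x <- stats::runif(n, 0, spec$field_size[1])
  y <- stats::runif(n, 0, spec$field_size[2])
  # tumour cells: uniform over the union of nests (nest by area, then polar)
  tum <- which(type == "epithelial")
  if (length(tum)) {
    areas <- vapply(spec$tumour_nests, function(z) pi * z[3]^2, 0)
    pick <- sample.int(length(spec$tumour_nests), length(tum),
                       replace = TRUE, prob = areas)
    rr <- vapply(spec$tumour_nests, `[[`, 0, 3)[pick]
    cx <- vapply(spec$tumour_nests, `[[`, 0, 1)[pick]
    cy <- vapply(spec$tumour_nests, `[[`, 0, 2)[pick]
    rad <- rr * sqrt(stats::runif(length(tum)))
    th <- stats::runif(length(tum), 0, 2 * pi)
    x[tum] <- cx + rad * cos(th)
    y[tum] <- cy + rad * sin(th)
  }

  area <- pmax(spec$area$min,
               stats::rlnorm(n, spec$area$meanlog, spec$area$sdlog))

  d_surface <- nest_signed_distance(x, y, spec$tumour_nests)
  enriched <- type %in% spec$immune_types & abs(d_surface) < spec$d_peri

  hc <- mosaic_hotcold_labels(x, y, spec$hotcold$patch,
                              spec$hotcold$hot_fraction,
                              seed = spec$seed + 1L)
  hotcold <- ifelse(type == "epithelial", hc$label, NA_character_)

  # rate matrix: background everywhere, type-specific marker rates on top
  lambda <- matrix(spec$background_rate, n, length(spec$panel),
                   dimnames = list(NULL, spec$panel))
  for (ty in names(spec$expression_rates)) {
    r <- spec$expression_rates[[ty]]
    if (!length(r)) next
    rows <- type == ty
    for (g in names(r)) lambda[rows, g] <- lambda[rows, g] + r[[g]]
  }
  if (any(enriched) && length(spec$chemokine_genes))
    lambda[enriched, spec$chemokine_genes] <-
      lambda[enriched, spec$chemokine_genes] * spec$peri_fold
  ish <- !is.na(hotcold) & hotcold == "hot"
  isc <- !is.na(hotcold) & hotcold == "cold"
  lambda[ish, "CD274"] <- spec$hotcold$lambda_hot
  lambda[isc, "CD274"] <- spec$hotcold$lambda_cold
  lambda[ish, spec$hotcold$prolif_gene] <- spec$hotcold$prolif_hot
  lambda[isc, spec$hotcold$prolif_gene] <- spec$hotcold$prolif_cold

  # shared latent lattice field: log-intensity correlation between coupled
  # genes equals rho exactly; exp(sigma Z - sigma^2/2) keeps E[multiplier]=1
  cp <- spec$coupling
  if (length(cp$genes) && cp$sigma > 0) {
    nxl <- ceiling(spec$field_size[1] / cp$cell)
    nyl <- ceiling(spec$field_size[2] / cp$cell)
    idx <- (pmin(floor(x / cp$cell), nxl - 1)) * nyl +
      pmin(floor(y / cp$cell), nyl - 1) + 1
    z0 <- stats::rnorm(nxl * nyl)
    for (g in intersect(cp$genes, spec$panel)) {
      zg <- sqrt(cp$rho) * z0 + sqrt(1 - cp$rho) * stats::rnorm(nxl * nyl)
      lambda[, g] <- lambda[, g] * exp(cp$sigma * zg[idx] - cp$sigma^2 / 2)
    }
  }

  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = n,
                   dimnames = dimnames(lambda))
  cells <- data.table::data.table(
    cell_id = sprintf("cell_%05d", seq_len(n)), x = x, y = y, area = area)
  table <- cell_table(cells, counts, panel = spec$panel)

  regions <- lapply(seq_along(spec$tumour_nests), function(i) {
    nest <- spec$tumour_nests[[i]]
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    region_polygon(cbind(nest[1] + nest[3] * cos(th),
                         nest[2] + nest[3] * sin(th)),
                   label = paste0("tumour_", i))
  })

  truth_cells <- data.table::data.table(
    cell_id = cells$cell_id, x = x, y = y, type = type,
    d_surface = d_surface, peri_enriched = enriched,
    band = band_name_of(d_surface), patch_id = hc$patch_id,
    hotcold = hotcold)

  list(table = table, regions = regions,
       truth = list(cells = truth_cells,
                    coupling = list(rho = cp$rho, sigma = cp$sigma,
                                    genes = cp$genes,
                                    construction = "shared latent Gaussian log-intensity; corr(log lambda_g1, log lambda_g2) = rho"),
                    spec = spec))
}

# analytic band name under the default peri/mid/distal partition
band_name_of <- function(d) {
  out <- rep("beyond", length(d))
  out[d < 0] <- "intratumour"
  out[d >= 0 & d < 20] <- "peri"
  out[d >= 20 & d < 70] <- "mid"
  out[d >= 70 & d < 120] <- "distal"
  out
}

#' Hot/cold truth labels for the tumour cells of a spec
#'
#' Regenerates the tissue deterministically and returns the generator's
#' per-tumour-cell hot/cold assignment.
#'
#' @param spec a [tissue_spec()] with `hotcold` set.
#' @return data.table with `cell_id`, `patch_id`, `label` for tumour cells.
#' @export
generate_hotcold_truth <- function(spec) {
  tr <- generate_tissue(spec)$truth$cells
  tr <- tr[tr$type == "epithelial",
           c("cell_id", "patch_id", "hotcold"), with = FALSE]
  data.table::setnames(tr, "hotcold", "label")
  tr[]
}

#' Simulate a pair of latent-coupled spot maps
#'
#' Two spot-level latent intensity fields sharing a common Gaussian component
#' with weight `sqrt(rho)`, so their population Pearson correlation equals
#' `rho`; used to probe map-correlation recovery at a known latent coupling.
#'
#' @param n_spots number of spots.
#' @param rho latent correlation in [0, 1].
#' @param seed RNG seed.
#' @return data.frame with columns `map_a`, `map_b`.
#' @export
simulate_coupled_spot_fields <- function(n_spots, rho, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  set.seed(seed)
  z0 <- stats::rnorm(n_spots)
  data.frame(
    map_a = sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n_spots),
    map_b = sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n_spots))
}

#' Write a generated tissue as an input bundle plus truth record
#'
#' Emits exactly the dialect [read_cell_bundle()] and [read_polygons()]
#' consume (`cells.csv.gz`, `matrix.mtx.gz`, `features.tsv`, `cells.tsv`,
#' `regions.geojson`) plus `truth.json`.
#'
#' @param sim result of [generate_tissue()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tissue_bundle <- function(sim, dir) {
  write_cell_bundle(sim$table, dir)
  write_polygons(sim$regions, file.path(dir, "regions.geojson"))
  truth <- sim$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
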
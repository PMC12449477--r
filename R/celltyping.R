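#' Per-cell marker positivity
#'
#' A cell is positive for a gene when its transcript count is at least `tau`
#' (default 2, the count threshold that gives a specific evaluation on
#' targeted in situ panels). Negativity, where needed for negative-marker
#' rules, is the stricter condition count == 0: a count of exactly 1 under
#' the default threshold is neither positive nor negative ("indeterminate"),
#' keeping both rules literal.
#'
#' @param table a [cell_table()].
#' @param tau positivity threshold, integer >= 1.
#' @return sparse logical cells x genes matrix of class `positivity_matrix`
#'   with the threshold attached as attribute `tau`.
#' @export
call_positivity <- function(table, tau = 2L) {
  stopifnot(inherits(table, "cell_table"))
  if (tau < 1) stop("positivity threshold tau must be >= 1")
  pos <- table$counts >= tau
  pos <- methods::as(pos, "CsparseMatrix")
  attr(pos, "tau") <- as.integer(tau)
  class(pos) <- c(class(pos))
  pos
}

rule_matches <- function(pos, counts, rule) {
  mode <- rule$mode %||% "any"
  pm <- rule$positive_markers
  hit <- if (identical(mode, "all")) {
    Matrix::rowSums(pos[, pm, drop = FALSE]) == length(pm)
  } else {
    Matrix::rowSums(pos[, pm, drop = FALSE]) >= 1
  }
  if (length(rule$negative_markers))
    hit <- hit & Matrix::rowSums(
      counts[, rule$negative_markers, drop = FALSE]) == 0
  hit
}

#' Marker-based cell-type assignment
#'
#' First-match over the ordered rule list in the marker configuration: each
#' cell receives the label of the first rule it satisfies (any/all of the
#' rule's positive markers at threshold, and zero counts for its negative
#' markers); cells matching no rule are labelled `"U.C."` (unclassified).
#'
#' @param table a [cell_table()].
#' @param cfg a [marker_config()].
#' @param tau positivity threshold passed to [call_positivity()].
#' @return data.table with `cell_id`, `label`, and `markers` (the supporting
#'   positive markers, "+"-separated; empty for U.C.).
#' @export
assign_cell_types <- function(table, cfg, tau = 2L) {
  stopifnot(inherits(table, "cell_table"), inherits(cfg, "marker_config"))
  validate_config(cfg, table$panel)
  pos <- call_positivity(table, tau)
  n <- nrow(table$cells)
  label <- rep("U.C.", n)
  support <- rep("", n)
  unassigned <- rep(TRUE, n)
  for (rule in cfg$cell_types) {
    hit <- unassigned & rule_matches(pos, table$counts, rule)
    if (!any(hit)) next
    label[hit] <- rule$label
    sub <- pos[hit, rule$positive_markers, drop = FALSE]
    support[hit] <- apply(sub, 1, function(z)
      paste(rule$positive_markers[as.logical(z)], collapse = "+"))
    unassigned <- unassigned & !hit
  }
  data.table::data.table(cell_id = table$cells$cell_id, label = label,
                         markers = support)
}

#' Compound positivity label (conjunction of markers)
#'
#' Flags cells positive for every gene in `genes` — e.g.
#' `c("CXCL13", "CD8A")` selects CXCL13+CD8+ cells.
#'
#' @param table a [cell_table()].
#' @param genes character vector of genes, all required positive.
#' @param tau positivity threshold.
#' @return logical vector over cells.
#' @export
compound_positive <- function(table, genes, tau = 2L) {
  pos <- call_positivity(table, tau)
  missing <- setdiff(genes, colnames(pos))
  if (length(missing))
    stop("compound label references genes not in panel: ",
         paste(missing, collapse = ", "))
  Matrix::rowSums(pos[, genes, drop = FALSE]) == length(genes)
}

#' Marker summary across cell groups
#'
#' For each marker and group: the group mean of raw counts, the z score of
#' that mean across the set of group means (population standard deviation —
#' the descriptive convention of marker bubble charts, so the z scores of a
#' marker across groups always average 0), and the percentage of cells in
#' the group positive at `tau`.
#'
#' @param table a [cell_table()].
#' @param groups factor/character vector of group labels, one per cell
#'   (cells with `NA` are dropped). At least two groups are required for the
#'   z scores.
#' @param markers genes to summarise.
#' @param tau positivity threshold for the percent-positive column.
#' @return data.table with `group`, `marker`, `mean`, `z`, `pct_positive`,
#'   and `zero_variance` flag (z reported 0 when all group means coincide).
#' @export
marker_summary <- function(table, groups, markers, tau = 2L) {
  stopifnot(inherits(table, "cell_table"))
  groups <- as.character(groups)
  keep <- !is.na(groups)
  gl <- unique(groups[keep])
  if (length(gl) < 2)
    stop("marker_summary needs at least 2 groups for z-scoring")
  missing <- setdiff(markers, table$panel)
  if (length(missing))
    stop("markers not in panel: ", paste(missing, collapse = ", "))
  out <- list()
  for (m in markers) {
    cnt <- gene_counts(table, m)[keep]
    g <- groups[keep]
    mu <- tapply(cnt, g, mean)[gl]
    pp <- tapply(cnt >= tau, g, mean)[gl] * 100
    sdp <- sqrt(mean((mu - mean(mu))^2))   # population sd across group means
    z <- if (sdp == 0) rep(0, length(mu)) else (mu - mean(mu)) / sdp
    out[[m]] <- data.table::data.table(
      group = gl, marker = m, mean = as.numeric(mu), z = as.numeric(z),
      pct_positive = as.numeric(pp), zero_variance = sdp == 0)
  }
  data.table::rbindlist(out)
}
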
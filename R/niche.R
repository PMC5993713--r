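# Climatic niche widths, positions and geographic extents from per-cell
# climate values. Widths follow the standardized-range protocol: the raw
# range of each bioclim variable over an entity's occupied cells is rescaled
# against the pool-wide minimum and maximum of that variable's ranges, and
# the overall niche width is the product of the six standardized ranges.

#' The six bioclim variables used throughout the package
#'
#' Annual mean temperature (BIO1), maximum temperature of the warmest month
#' (BIO5), minimum temperature of the coldest month (BIO6), annual
#' precipitation (BIO12), precipitation of the wettest (BIO16) and driest
#' (BIO17) quarter.
#' @export
BIOCLIM_VARS <- c("BIO1", "BIO5", "BIO6", "BIO12", "BIO16", "BIO17")

#' Validate a climate grid
#'
#' A grid is a data frame with columns `cell_id`, `x`, `y`, `area_km2` and
#' the six bioclim variables. Cell-level orderings (BIO5 >= BIO1 >= BIO6,
#' BIO12 >= BIO16 >= BIO17 >= 0) and positive areas are enforced.
#'
#' @param grid Data frame.
#' @return The grid, invisibly, or an error.
#' @export
validate_climate_grid <- function(grid) {
  need <- c("cell_id", "x", "y", "area_km2", BIOCLIM_VARS)
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop("grid is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(grid$cell_id)) stop("grid cell ids are not unique")
  if (any(grid$area_km2 <= 0)) stop("grid cell areas must be positive")
  tol <- 1e-8
  if (any(grid$BIO5 < grid$BIO1 - tol) || any(grid$BIO1 < grid$BIO6 - tol))
    stop("temperature ordering violated: need BIO5 >= BIO1 >= BIO6 in every cell")
  if (any(grid$BIO12 < grid$BIO16 - tol) || any(grid$BIO16 < grid$BIO17 - tol) ||
      any(grid$BIO17 < -tol))
    stop("precipitation ordering violated: need BIO12 >= BIO16 >= BIO17 >= 0")
  invisible(grid)
}

#' Per-variable niche summary for one entity
#'
#' Min, max, mean and raw range (max - min) of each bioclim variable over a
#' set of occupied grid cells.
#'
#' @param grid Climate grid (see [validate_climate_grid()]).
#' @param cells Character vector of occupied cell ids (non-empty).
#' @return Data frame with columns `variable`, `min`, `max`, `mean`, `range`.
#' @examples
#' g <- data.frame(cell_id = c("a", "b"), x = 1:2, y = 1, area_km2 = 1,
#'                 BIO1 = c(10, 20), BIO5 = c(18, 28), BIO6 = c(2, 12),
#'                 BIO12 = c(1000, 1400), BIO16 = c(500, 700),
#'                 BIO17 = c(100, 140))
#' summarize_niche(g, c("a", "b"))
#' @export
summarize_niche <- function(grid, cells) {
  if (length(cells) == 0L) stop("empty cell set")
  idx <- match(unique(cells), grid$cell_id)
  if (anyNA(idx))
    stop("cell id(s) absent from grid: ",
         paste(unique(cells)[is.na(idx)], collapse = ", "))
  vals <- grid[idx, BIOCLIM_VARS, drop = FALSE]
  data.frame(
    variable = BIOCLIM_VARS,
    min = vapply(vals, min, numeric(1)),
    max = vapply(vals, max, numeric(1)),
    mean = vapply(vals, mean, numeric(1)),
    range = vapply(vals, function(v) max(v) - min(v), numeric(1)),
    row.names = NULL
  )
}

#' Niche summaries for many entities at once
#'
#' Vectorized companion to [summarize_niche()]: takes a long occupancy table
#' and returns one wide row per entity with `<VAR>_min`, `<VAR>_max`,
#' `<VAR>_mean` and `<VAR>_range` columns, plus the occupied-cell count,
#' summed cell area, and the occupancy centroid (`x`, `y`).
#'
#' @param grid Climate grid.
#' @param ranges Long data frame with columns `entity_id` (or `species_id`)
#'   and `cell_id`.
#' @return Wide data frame, one row per entity.
#' @export
niche_summary_table <- function(grid, ranges) {
  id_col <- if ("entity_id" %in% names(ranges)) "entity_id" else "species_id"
  if (!all(c(id_col, "cell_id") %in% names(ranges)))
    stop("ranges must have columns entity_id/species_id and cell_id")
  ranges <- unique(ranges[, c(id_col, "cell_id")])
  idx <- match(ranges$cell_id, grid$cell_id)
  if (anyNA(idx))
    stop("cell id(s) absent from grid: ",
         paste(unique(ranges$cell_id[is.na(idx)]), collapse = ", "))
  f <- factor(ranges[[id_col]])
  out <- data.frame(entity_id = levels(f), stringsAsFactors = FALSE)
  for (v in BIOCLIM_VARS) {
    vals <- grid[[v]][idx]
    mn <- tapply(vals, f, min)
    mx <- tapply(vals, f, max)
    out[[paste0(v, "_min")]] <- as.numeric(mn)
    out[[paste0(v, "_max")]] <- as.numeric(mx)
    out[[paste0(v, "_mean")]] <- as.numeric(tapply(vals, f, mean))
    out[[paste0(v, "_range")]] <- as.numeric(mx - mn)
  }
  out$n_cells <- as.integer(tabulate(f))
  out$area_km2 <- as.numeric(tapply(grid$area_km2[idx], f, sum))
  out$x <- as.numeric(tapply(grid$x[idx], f, mean))
  out$y <- as.numeric(tapply(grid$y[idx], f, mean))
  out
}

#' Extract the raw-range block of a niche summary table
#'
#' Returns `entity_id` plus one column per bioclim variable holding the raw
#' range (max - min), the layout [standardize_widths()] consumes.
#'
#' @param summary_table Output of [niche_summary_table()].
#' @return Data frame: `entity_id` and six raw-range columns.
#' @export
raw_range_table <- function(summary_table) {
  out <- data.frame(entity_id = summary_table$entity_id,
                    stringsAsFactors = FALSE)
  for (v in BIOCLIM_VARS) out[[v]] <- summary_table[[paste0(v, "_range")]]
  out
}

#' Standardized niche widths
#'
#' Rescales each entity's raw range of each variable against the pool-wide
#' minimum and maximum of that variable's ranges:
#' `StRg_i = (Rg_i - min(Rg)) / (max(Rg) - min(Rg))`,
#' and multiplies the six standardized ranges into the overall niche width
#' `nw`. When the pool is the entity set itself every `StRg` lies in
#' \[0, 1\] and each variable attains 0 and 1 at least once; with an external
#' pool (e.g. family ranges standardized against the species pool) values
#' above 1 are possible and retained.
#'
#' @param raw_ranges Data frame: `entity_id` plus one raw-range column per
#'   bioclim variable (as from [raw_range_table()]).
#' @param pool Data frame in the same layout defining the standardization
#'   pool; defaults to `raw_ranges` itself.
#' @return Data frame: `entity_id`, `StRg_<VAR>` columns and `nw`.
#' @export
standardize_widths <- function(raw_ranges, pool = raw_ranges) {
  if (nrow(pool) < 2L) stop("standardization pool needs at least 2 entities")
  out <- data.frame(entity_id = raw_ranges$entity_id, stringsAsFactors = FALSE)
  nw <- rep(1, nrow(raw_ranges))
  for (v in BIOCLIM_VARS) {
    if (!v %in% names(raw_ranges)) stop("raw_ranges is missing variable ", v)
    lo <- min(pool[[v]]); hi <- max(pool[[v]])
    if (hi <= lo)
      stop("degenerate standardization pool for ", v,
           ": max(Rg) must exceed min(Rg)")
    st <- (raw_ranges[[v]] - lo) / (hi - lo)
    out[[paste0("StRg_", v)]] <- st
    nw <- nw * st
  }
  out$nw <- nw
  out
}

#' Family-level niche records
#'
#' For each family, pools the occupied cells of all member species and
#' computes: per-variable raw ranges over the union, the family niche width
#' (standardized against `pool`), the niche position (per-variable mean over
#' the union cells), the geographic extent (summed area of union cells), and
#' the mean of the member species' niche widths (standardized against the
#' same pool).
#'
#' @param grid Climate grid.
#' @param ranges Long occupancy table (`species_id`, `cell_id`).
#' @param membership Data frame (`species_id`, `family_id`).
#' @param pool Raw-range standardization pool; defaults to the raw ranges of
#'   all species in `ranges`.
#' @return Data frame, one row per family: `family_id`, `n_species`, `nw`,
#'   `mean_species_nw`, `extent_km2`, `pos_<VAR>` and `rg_<VAR>` columns.
#' @export
family_niche <- function(grid, ranges, membership, pool = NULL) {
  if (!all(c("species_id", "family_id") %in% names(membership)))
    stop("membership must have columns species_id and family_id")
  if (nrow(membership) == 0L) stop("empty membership table")
  sp_sum <- niche_summary_table(grid, ranges)
  sp_rg <- raw_range_table(sp_sum)
  if (is.null(pool)) pool <- sp_rg
  sp_nw <- standardize_widths(sp_rg, pool)
  fam_of <- membership$family_id[match(sp_sum$entity_id, membership$species_id)]
  if (anyNA(fam_of))
    stop("species without family membership: ",
         paste(sp_sum$entity_id[is.na(fam_of)], collapse = ", "))
  fr <- merge(ranges, membership, by = "species_id")
  fr <- data.frame(entity_id = fr$family_id, cell_id = fr$cell_id)
  fam_sum <- niche_summary_table(grid, fr)
  fam_rg <- raw_range_table(fam_sum)
  fam_nw <- standardize_widths(fam_rg, pool)
  ord <- fam_sum$entity_id
  msnw <- tapply(sp_nw$nw, fam_of, mean)[ord]
  out <- data.frame(
    family_id = ord,
    n_species = as.integer(table(fam_of)[ord]),
    nw = fam_nw$nw,
    mean_species_nw = as.numeric(msnw),
    extent_km2 = fam_sum$area_km2,
    stringsAsFactors = FALSE
  )
  for (v in BIOCLIM_VARS) out[[paste0("pos_", v)]] <- fam_sum[[paste0(v, "_mean")]]
  for (v in BIOCLIM_VARS) out[[paste0("rg_", v)]] <- fam_sum[[paste0(v, "_range")]]
  rownames(out) <- out$family_id
  out
}

#' PCA-based family niche width
#'
#' Alternative two-axis width: the six climate variables are centred and
#' scaled across all grid cells and the first two principal axes extracted;
#' each family's union cells are projected and the family width is the
#' product of the two axis ranges.
#'
#' @param grid Climate grid (>= 3 cells).
#' @param ranges Long occupancy table (`species_id`, `cell_id`).
#' @param membership Data frame (`species_id`, `family_id`).
#' @return Data frame `family_id`, `width_pc1`, `width_pc2`, `pca_width`,
#'   with the proportion of variance of the first two axes as attribute
#'   `"var_explained"`.
#' @export
pca_family_width <- function(grid, ranges, membership) {
  if (nrow(grid) < 3L) stop("PCA width needs a grid with at least 3 cells")
  X <- scale(as.matrix(grid[, BIOCLIM_VARS]))
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  fr <- merge(ranges, membership, by = "species_id")
  idx <- match(fr$cell_id, grid$cell_id)
  if (anyNA(idx)) stop("cell id(s) absent from grid")
  f <- factor(fr$family_id)
  w1 <- tapply(scores[idx, 1], f, function(z) max(z) - min(z))
  w2 <- tapply(scores[idx, 2], f, function(z) max(z) - min(z))
  out <- data.frame(family_id = levels(f),
                    width_pc1 = as.numeric(w1),
                    width_pc2 = as.numeric(w2),
                    pca_width = as.numeric(w1 * w2),
                    stringsAsFactors = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve[1:2]
  out
}
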
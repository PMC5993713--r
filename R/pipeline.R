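# Orchestration: assemble the per-family analysis table, compute the
# niche-divergence statistic, run the univariate regression suite, the
# variance partitioning, and the fixed-stem-age clade robustness variant.

.rate_col <- function(eps) sprintf("rate_eps%g", eps)

#' Build the per-family analysis table
#'
#' Consolidates, for every family that survives the exclusion rules, the
#' richness `n`, stem age `t`, net diversification rates for each `eps`,
#' family niche width `nw`, mean species niche width, niche position per
#' variable, geographic extent, and the BM rates of temperature and
#' precipitation niche evolution. Exclusions (no stem age in the family
#' tree, fewer than two sampled tips, paraphyly in the species tree) are
#' returned with reason codes. Any surviving family with a missing value or
#' a zero niche width is a hard error.
#'
#' @param grid Climate grid.
#' @param ranges Long occupancy table (`species_id`, `cell_id`).
#' @param membership Data frame (`species_id`, `family_id`).
#' @param family_tree Ultrametric family-level `phylo` (tips = family ids).
#' @param species_tree Species-level `phylo` (tips = species ids).
#' @param eps Relative extinction fractions (default `c(0, 0.45, 0.9)`).
#' @return Object of class `family_table`: `table` (row names = family id),
#'   `exclusions` (family, reason), `species` (per-species niche summary
#'   with `nw`), `meta`.
#' @export
build_family_table <- function(grid, ranges, membership, family_tree,
                               species_tree, eps = c(0, 0.45, 0.9)) {
  validate_climate_grid(grid)
  sp_sum <- niche_summary_table(grid, ranges)
  sp_rg <- raw_range_table(sp_sum)
  sp_nw <- standardize_widths(sp_rg, sp_rg)
  sp_sum$nw <- sp_nw$nw
  membership <- membership[membership$species_id %in% sp_sum$entity_id, ]
  sp_sum$family_id <- membership$family_id[match(sp_sum$entity_id,
                                                 membership$species_id)]
  fams <- sort(unique(membership$family_id))
  excl <- list()
  keep <- character(0)
  rates_tab <- family_rates(species_tree, membership,
                            stats::setNames(sp_sum[, c("entity_id", "BIO1_mean", "BIO12_mean")],
                                            c("species_id", "BIO1_mean", "BIO12_mean")))
  for (fam in fams) {
    if (!fam %in% family_tree$tip.label) {
      excl[[fam]] <- "no_stem_age"; next
    }
    reason <- rates_tab[fam, "skip_reason"]
    if (!is.na(reason)) { excl[[fam]] <- reason; next }
    keep <- c(keep, fam)
  }
  if (length(keep) < 2L)
    stop("fewer than two families survive the exclusion rules; ",
         "regressions are undefined")
  memb_keep <- membership[membership$family_id %in% keep, ]
  ranges_keep <- ranges[ranges$species_id %in% memb_keep$species_id, ]
  fam_niche <- family_niche(grid, ranges_keep, memb_keep, pool = sp_rg)
  fam_niche <- fam_niche[keep, ]
  stem <- vapply(keep, function(f) stem_age(family_tree, f), numeric(1))
  n_sp <- fam_niche$n_species
  tab <- data.frame(
    family_id = keep,
    n = n_sp,
    stem_age = stem,
    stringsAsFactors = FALSE
  )
  for (e in eps) tab[[.rate_col(e)]] <- stem_diversification_rate(n_sp, stem, e)
  tab$nw <- fam_niche$nw
  tab$mean_species_nw <- fam_niche$mean_species_nw
  tab$extent_km2 <- fam_niche$extent_km2
  for (v in BIOCLIM_VARS) tab[[paste0("pos_", v)]] <- fam_niche[[paste0("pos_", v)]]
  tab$sigma2_bio1 <- rates_tab[keep, "sigma2_bio1"]
  tab$sigma2_bio12 <- rates_tab[keep, "sigma2_bio12"]
  rownames(tab) <- tab$family_id
  bad_nw <- tab$family_id[tab$nw <= 0 | tab$mean_species_nw <= 0]
  if (length(bad_nw))
    stop("zero niche width for family(ies): ", paste(bad_nw, collapse = ", "),
         "; ln-transforms are undefined")
  bad_s2 <- tab$family_id[!is.na(tab$sigma2_bio1) &
                            (tab$sigma2_bio1 <= 0 | tab$sigma2_bio12 <= 0)]
  if (length(bad_s2))
    stop("zero niche-evolution rate (constant trait) for family(ies): ",
         paste(bad_s2, collapse = ", "), "; ln-transforms are undefined")
  if (anyNA(tab))
    stop("missing values in analysis rows for: ",
         paste(tab$family_id[!stats::complete.cases(tab)], collapse = ", "))
  exclusions <- data.frame(family_id = names(excl),
                           reason = unlist(excl, use.names = FALSE),
                           stringsAsFactors = FALSE)
  structure(list(table = tab,
                 exclusions = exclusions,
                 species = sp_sum,
                 meta = list(eps = eps,
                             standardization_pool = "species",
                             n_families = nrow(tab),
                             n_species = nrow(sp_sum))),
            class = "family_table")
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("family_table: %d analysis families, %d species; %d excluded\n",
              nrow(x$table), x$meta$n_species, nrow(x$exclusions)))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}

#' Niche divergence: residuals of family niche width on mean species width
#'
#' Fits `ln(family NW) ~ ln(mean species NW)` by PGLS on the family tree and
#' returns the raw residuals: families whose member species tile
#' little-overlapping climates lie above the line (positive divergence),
#' perfectly conservative families lie on it.
#'
#' @param table The `table` data frame of a [build_family_table()] result
#'   (or the object itself).
#' @param family_tree Family-level `phylo` or [pgls_context()].
#' @return List: `nd` (named residual vector), `fit` (the underlying
#'   [pgls_fit()]).
#' @export
niche_divergence <- function(table, family_tree) {
  tab <- if (inherits(table, "family_table")) table$table else table
  d <- data.frame(ln_nw = log(tab$nw),
                  ln_msnw = log(tab$mean_species_nw),
                  row.names = rownames(tab))
  fit <- pgls_fit(ln_nw ~ ln_msnw, d, family_tree)
  list(nd = pgls_residuals(fit), fit = fit)
}

# derived (transformed) regressor columns used by the suite
.analysis_frame <- function(tab, response_col) {
  d <- data.frame(
    ln_rate = log(tab[[response_col]]),
    ln_n = log(tab$n),
    ln_nw = log(tab$nw),
    ln_msnw = log(tab$mean_species_nw),
    ln_extent = log(tab$extent_km2),
    ln_s2_bio1 = log(tab$sigma2_bio1),
    ln_s2_bio12 = log(tab$sigma2_bio12),
    nd = tab$nd,
    row.names = rownames(tab)
  )
  for (v in BIOCLIM_VARS) d[[paste0("pos_", v)]] <- tab[[paste0("pos_", v)]]
  d
}

#' Univariate PGLS suite for diversification (or richness) correlates
#'
#' Fits the panel of regressions relating the response (ln net
#' diversification rate, or ln richness) to: ln family niche width, ln mean
#' species niche width, niche divergence (untransformed), stepwise-selected
#' niche position variables (untransformed), ln geographic extent, ln
#' temperature and ln precipitation niche-evolution rates, and the
#' two-predictor niche-evolution model; plus the niche divergence ~ rates
#' bivariate model and, for a rate response, the rate ~ ln richness
#' association. Follows the convention that all variables except niche
#' divergence and niche position are ln-transformed.
#'
#' @param table A [build_family_table()] result or its `table` data frame
#'   (a niche-divergence column `nd` is added if absent).
#' @param family_tree Family-level `phylo` or [pgls_context()].
#' @param response `"rate"` (default) or `"richness"`.
#' @param eps Which extinction fraction's rate is the headline response
#'   (default 0.45).
#' @param alpha_enter Stepwise entry threshold.
#' @return List with class `univariate_suite`: `fits` (named list of
#'   [pgls_fit()]), `summary` data frame (model, r2, F, df, p, slope, CI),
#'   `stepwise`, `nd_fit`, `response_col`.
#' @export
run_univariate_suite <- function(table, family_tree, response = c("rate", "richness"),
                                 eps = 0.45, alpha_enter = 0.05) {
  response <- match.arg(response)
  tab <- if (inherits(table, "family_table")) table$table else table
  ctx <- if (inherits(family_tree, "pgls_context")) family_tree
         else pgls_context(family_tree, rownames(tab))
  nd_fit <- NULL
  if (!"nd" %in% names(tab)) {
    ndres <- niche_divergence(tab, ctx)
    tab$nd <- ndres$nd[rownames(tab)]
    nd_fit <- ndres$fit
  }
  response_col <- if (response == "rate") .rate_col(eps) else "n"
  if (!response_col %in% names(tab))
    stop("response column ", response_col, " not present in table")
  d <- .analysis_frame(tab, response_col)
  fits <- list(
    family_nw = pgls_fit(ln_rate ~ ln_nw, d, ctx),
    mean_species_nw = pgls_fit(ln_rate ~ ln_msnw, d, ctx),
    niche_divergence = pgls_fit(ln_rate ~ nd, d, ctx),
    extent = pgls_fit(ln_rate ~ ln_extent, d, ctx),
    temp_evol_rate = pgls_fit(ln_rate ~ ln_s2_bio1, d, ctx),
    precip_evol_rate = pgls_fit(ln_rate ~ ln_s2_bio12, d, ctx),
    niche_evol_both = pgls_fit(ln_rate ~ ln_s2_bio1 + ln_s2_bio12, d, ctx),
    nd_vs_evol_rates = pgls_fit(nd ~ ln_s2_bio1 + ln_s2_bio12, d, ctx)
  )
  step <- forward_stepwise("ln_rate", paste0("pos_", BIOCLIM_VARS), d, ctx,
                           alpha_enter = alpha_enter)
  fits$niche_position <- step$fit
  if (response == "rate")
    fits$richness <- pgls_fit(ln_rate ~ ln_n, d, ctx)
  summ <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    slope <- if (length(f$predictors) == 1L) f$coefficients[[2]] else NA_real_
    ci <- if (length(f$predictors) == 1L) f$ci_halfwidth[[2]] else NA_real_
    data.frame(model = nm, predictors = paste(f$predictors, collapse = "+"),
               r2 = f$r_squared, F = f$F, df1 = f$df[["num"]],
               df2 = f$df[["den"]], p = f$p_value, lambda = f$lambda,
               slope = slope, ci95 = ci,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(fits = fits, summary = summ, stepwise = step,
                 nd_fit = nd_fit, response_col = response_col,
                 alpha_enter = alpha_enter),
            class = "univariate_suite")
}

#' @export
print.univariate_suite <- function(x, ...) {
  cat(sprintf("Univariate PGLS suite (response: %s)\n", x$response_col))
  s <- x$summary
  s[, c("r2", "F", "p", "lambda", "slope", "ci95")] <-
    lapply(s[, c("r2", "F", "p", "lambda", "slope", "ci95")], signif, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Variance partitioning of the four-block full model
#'
#' Commonality analysis of the full PGLS model of the response on the four
#' predictor blocks: family niche width (NW), geographic extent (GE), niche
#' divergence (ND) and the niche-evolution rates (NE: temperature and
#' precipitation rates as one block).
#'
#' @param table A [build_family_table()] result or its `table` data frame
#'   (with an `nd` column, added if absent).
#' @param family_tree Family-level `phylo` or [pgls_context()].
#' @param response `"rate"` or `"richness"`.
#' @param eps Extinction fraction for the rate response.
#' @return A [variance_partition()] result.
#' @export
variance_partition_suite <- function(table, family_tree,
                                     response = c("rate", "richness"),
                                     eps = 0.45) {
  response <- match.arg(response)
  tab <- if (inherits(table, "family_table")) table$table else table
  ctx <- if (inherits(family_tree, "pgls_context")) family_tree
         else pgls_context(family_tree, rownames(tab))
  if (!"nd" %in% names(tab)) tab$nd <- niche_divergence(tab, ctx)$nd[rownames(tab)]
  response_col <- if (response == "rate") .rate_col(eps) else "n"
  d <- .analysis_frame(tab, response_col)
  variance_partition("ln_rate",
                     blocks = list(NW = "ln_nw", GE = "ln_extent", ND = "nd",
                                   NE = c("ln_s2_bio1", "ln_s2_bio12")),
                     d, ctx)
}

#' Fixed-stem-age clade robustness analysis
#'
#' Replaces named families with clades of similar stem age: the master
#' species tree is sliced at `target_age` (each root-to-tip path cut at the
#' clade whose stem age is the smallest value >= the target), monospecific
#' clades are excluded, and the niche metrics, diversification rates,
#' niche-evolution rates, univariate suite and variance partitioning are
#' recomputed with ln clade richness as the response.
#'
#' @param species_tree Ultrametric species-level `phylo`.
#' @param grid Climate grid.
#' @param ranges Long occupancy table.
#' @param target_age Cut age in Myr (e.g. the mean family stem age).
#' @param eps Extinction fractions for the rate columns.
#' @return List with class `clade_robustness`: `clades` (slice table),
#'   `table` (per-clade analysis rows), `suite`, `varpart`, `excluded`.
#' @export
clade_robustness <- function(species_tree, grid, ranges, target_age,
                             eps = c(0, 0.45, 0.9)) {
  slices <- slice_clades_by_stem_age(species_tree, target_age)
  keep <- !slices$monospecific
  excluded <- slices[!keep, c("clade_id", "n_tips")]
  slices_keep <- slices[keep, ]
  memb <- do.call(rbind, lapply(seq_len(nrow(slices_keep)), function(i)
    data.frame(species_id = slices_keep$tips[[i]],
               family_id = slices_keep$clade_id[i],
               stringsAsFactors = FALSE)))
  # clade-level tree: one representative tip per clade, relabelled
  reps <- vapply(slices_keep$tips, `[[`, character(1), 1L)
  clade_tree <- ape::keep.tip(species_tree, reps)
  clade_tree$tip.label <-
    slices_keep$clade_id[match(clade_tree$tip.label, reps)]
  ft <- build_family_table(grid, ranges, memb, clade_tree, species_tree,
                           eps = eps)
  tab <- ft$table
  tab$stem_age <- slices_keep$stem_age[match(tab$family_id, slices_keep$clade_id)]
  for (e in eps) tab[[.rate_col(e)]] <-
    stem_diversification_rate(tab$n, tab$stem_age, e)
  ctx <- pgls_context(clade_tree, rownames(tab))
  ndres <- niche_divergence(tab, ctx)
  tab$nd <- ndres$nd[rownames(tab)]
  suite <- run_univariate_suite(tab, ctx, response = "richness")
  vp <- variance_partition_suite(tab, ctx, response = "richness")
  structure(list(clades = slices, table = tab, nd_fit = ndres$fit,
                 suite = suite, varpart = vp, excluded = excluded,
                 target_age = target_age),
            class = "clade_robustness")
}

#' Run the full analysis pipeline on a dataset
#'
#' Convenience wrapper: builds the family table, attaches niche divergence,
#' runs the univariate suite and the variance partitioning, and optionally
#' the null models and the fixed-age clade robustness variant.
#'
#' @param data A `scenario_data` object from [simulate_scenario()], or any
#'   list with `grid`, `ranges`, `membership`, `family_tree`,
#'   `species_tree`.
#' @param eps Extinction fractions; the headline response uses
#'   `headline_eps`.
#' @param headline_eps Extinction fraction of the headline response (0.45).
#' @param null_reps Null-model replicates per model type (0 skips the null
#'   models).
#' @param null_types Null model types to run.
#' @param robustness Logical: run the clade-slicing robustness variant at
#'   the mean family stem age.
#' @param seed Seed for the null-model resampling.
#' @return List with class `macroniche_pipeline`: `family_table`, `nd_fit`,
#'   `suite`, `suite_richness`, `varpart`, `nulls`, `robustness`.
#' @export
run_pipeline <- function(data, eps = c(0, 0.45, 0.9), headline_eps = 0.45,
                         null_reps = 0,
                         null_types = c("unconstrained", "spatial", "climatic"),
                         robustness = FALSE, seed = 1) {
  ft <- build_family_table(data$grid, data$ranges, data$membership,
                           data$family_tree, data$species_tree, eps = eps)
  ctx <- pgls_context(data$family_tree, rownames(ft$table))
  ndres <- niche_divergence(ft$table, ctx)
  ft$table$nd <- ndres$nd[rownames(ft$table)]
  suite <- run_univariate_suite(ft, ctx, response = "rate", eps = headline_eps)
  suite_richness <- run_univariate_suite(ft, ctx, response = "richness")
  vp <- variance_partition_suite(ft, ctx, response = "rate", eps = headline_eps)
  nulls <- NULL
  if (null_reps > 0) {
    nulls <- lapply(stats::setNames(null_types, null_types), function(ty)
      null_model(ft, ctx, type = ty, reps = null_reps,
                 seed = seed, eps = headline_eps))
  }
  rob <- NULL
  if (robustness) {
    rob <- clade_robustness(data$species_tree, data$grid, data$ranges,
                            target_age = mean(ft$table$stem_age), eps = eps)
  }
  structure(list(family_table = ft, nd_fit = ndres$fit, suite = suite,
                 suite_richness = suite_richness, varpart = vp,
                 nulls = nulls, robustness = rob,
                 headline_eps = headline_eps),
            class = "macroniche_pipeline")
}
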
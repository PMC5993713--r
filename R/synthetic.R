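# Synthetic-data generator: climate grid, dated family and species trees,
# and climate-envelope species ranges with known ground truth (per-family
# net diversification rate, per-family sigma^2, coupling regime). The
# defaults define the study conditions used throughout the tests: 92
# families on a 60 x 120 grid, mean family stem age 41.65 Myr, richness
# 2-150 (ln-skewed).

#' Scenario configuration for the synthetic generator
#'
#' @param seed Integer master seed. Stages derive sub-seeds as `seed + 11`
#'   (grid), `seed + 22` (trees), `seed + 33` (traits and ranges) so each
#'   stage is independently reproducible.
#' @param coupling `"h2"` (rates of niche evolution positively coupled to
#'   net diversification rates: divergence-driven speciation), `"decoupled"`
#'   (independent), or `"h0"` (neutral: identical niche-evolution rate in
#'   every family, so family niche structure varies by sampling alone).
#' @param n_families Number of families (92).
#' @param mean_stem_age Mean family stem age in Myr (41.65).
#' @param min_stem_age Minimum family stem age in Myr (8): every internal
#'   node of the family tree is pushed back by this amount (pendant edges
#'   lengthened, tips kept at the present), so no family has a vanishing
#'   stem age and hence an unboundedly large rate estimate.
#' @param grid_nx,grid_ny Grid dimensions (120 x 60).
#' @param cell_area_km2 Equal per-cell area.
#' @param bio1_range,bio12_range Latitudinal span of annual mean temperature
#'   (deg C) and longitudinal span of annual precipitation (mm).
#' @param noise_sd_temp,noise_sd_precip Cell-level climatic noise sd.
#' @param richness_meanlog,richness_sdlog Log-normal distribution of the
#'   per-family expected richness target; the family's true net
#'   diversification rate is `r_f = ln(E n_f) / t_f` (exact for a pure-birth
#'   process), so rates vary log-normally around
#'   `richness_meanlog / mean_stem_age`.
#' @param sigma2_scale Baseline BIO1 niche-evolution rate (deg C^2 / Myr).
#' @param sigma2_pow H2 coupling exponent: `sigma2 = sigma2_scale *
#'   (r / exp(r_meanlog))^sigma2_pow * lognormal noise`.
#' @param sigma2_sdlog Log-sd of the sigma2 noise.
#' @param precip_sigma_factor Ratio of BIO12 to BIO1 Brownian sd (unit
#'   conversion between mm and deg C scales).
#' @param width_temp_meanlog,width_precip_meanlog,width_sdlog Log-normal
#'   species climate-envelope widths (deg C / mm); a family-level random
#'   effect of log-sd `width_family_sdlog` makes mean species niche width
#'   vary across families independently of diversification.
#' @param width_family_sdlog Family-level width effect log-sd.
#' @param richness_min,richness_max Accepted per-family richness window;
#'   birth simulations outside it are redrawn (and counted).
#' @return List with class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            coupling = c("h2", "decoupled", "h0"),
                            n_families = 92,
                            mean_stem_age = 41.65,
                            min_stem_age = 8,
                            grid_nx = 120, grid_ny = 60,
                            cell_area_km2 = 100,
                            bio1_range = c(-8, 27),
                            bio12_range = c(100, 3000),
                            noise_sd_temp = 0.8,
                            noise_sd_precip = 60,
                            richness_meanlog = log(12),
                            richness_sdlog = 0.9,
                            sigma2_scale = 0.15,
                            sigma2_pow = 2,
                            sigma2_sdlog = 0.3,
                            precip_sigma_factor = 60,
                            width_temp_meanlog = log(3),
                            width_precip_meanlog = log(400),
                            width_sdlog = 0.25,
                            width_family_sdlog = 0.6,
                            richness_min = 2,
                            richness_max = 150) {
  coupling <- match.arg(coupling)
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

#' Synthetic climate grid
#'
#' A rectangular equal-area grid with a latitudinal temperature gradient
#' (BIO1, warm at low `y`), a longitudinal precipitation gradient (BIO12,
#' wet at low `x`), plus cell-level noise. BIO5/BIO6 are BIO1 plus/minus a
#' positive seasonal offset; BIO16/BIO17 are wet- and dry-season fractions
#' of BIO12. All cell-level orderings (BIO5 >= BIO1 >= BIO6,
#' BIO12 >= BIO16 >= BIO17 >= 0) hold by construction.
#'
#' @param config A [scenario_config()].
#' @return Climate grid data frame (see [validate_climate_grid()]).
#' @export
make_climate_grid <- function(config) {
  set.seed(config$seed + 11L)
  nx <- config$grid_nx; ny <- config$grid_ny
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  ncell <- nrow(g)
  t_span <- config$bio1_range
  p_span <- config$bio12_range
  bio1_base <- t_span[2] - (g$y - 1) / max(ny - 1, 1) * (t_span[2] - t_span[1])
  bio1 <- bio1_base + stats::rnorm(ncell, 0, config$noise_sd_temp)
  bio12_base <- p_span[2] - (g$x - 1) / max(nx - 1, 1) * (p_span[2] - p_span[1])
  bio12 <- pmax(0, bio12_base + stats::rnorm(ncell, 0, config$noise_sd_precip))
  wet <- stats::runif(ncell, 0.35, 0.6)
  dry <- stats::runif(ncell, 0.05, 0.2)
  grid <- data.frame(
    cell_id = sprintf("c%06d", seq_len(ncell)),
    x = g$x, y = g$y,
    area_km2 = config$cell_area_km2,
    BIO1 = bio1,
    BIO5 = bio1 + stats::runif(ncell, 8, 12),
    BIO6 = bio1 - stats::runif(ncell, 8, 12),
    BIO12 = bio12,
    BIO16 = wet * bio12,
    BIO17 = dry * bio12,
    stringsAsFactors = FALSE
  )
  validate_climate_grid(grid)
  grid
}

# forward pure-birth simulation from one stem lineage over [0, t_total];
# returns a Newick fragment "(...):root_edge" (drop-in replacement for a
# "label:length" tip of total depth t_total) plus tip count.
.sim_yule_stem <- function(rate, t_total, prefix, n_cap = Inf) {
  start <- 0
  split <- NA_real_
  ch1 <- NA_integer_; ch2 <- NA_integer_
  active <- 1L
  time <- 0
  repeat {
    k <- length(active)
    if (k > n_cap) return(list(fragment = NULL, n = k, tips = NULL))
    wait <- stats::rexp(1, rate * k)
    time <- time + wait
    if (time > t_total) break
    i <- active[sample.int(k, 1L)]
    m <- length(start)
    start <- c(start, time, time)
    split <- c(split, NA_real_, NA_real_)
    ch1 <- c(ch1, NA_integer_, NA_integer_)
    ch2 <- c(ch2, NA_integer_, NA_integer_)
    split[i] <- time
    ch1[i] <- m + 1L; ch2[i] <- m + 2L
    active <- c(setdiff(active, i), m + 1L, m + 2L)
  }
  tip_ids <- which(is.na(split))
  labels <- character(length(start))
  labels[tip_ids] <- sprintf("%s_s%03d", prefix, seq_along(tip_ids))
  fmt <- function(v) sprintf("%.12g", v)
  bld <- function(i) {
    if (is.na(split[i]))
      paste0(labels[i], ":", fmt(t_total - start[i]))
    else
      paste0("(", bld(ch1[i]), ",", bld(ch2[i]), "):", fmt(split[i] - start[i]))
  }
  list(fragment = bld(1L), n = length(tip_ids),
       tips = labels[tip_ids])
}

#' Simulate the dated family tree and within-family species trees
#'
#' The family tree is a constant-rate birth tree rescaled so that the mean
#' family stem age equals `mean_stem_age`. Each family then receives a true
#' net diversification rate drawn log-normally and a pure-birth species tree
#' simulated forward from a single stem lineage over its stem age,
#' conditioned on a richness inside `[richness_min, richness_max]`
#' (out-of-window draws are redrawn and counted). The species trees are
#' grafted onto the family tree's pendant edges to form an ultrametric
#' master species tree.
#'
#' @param config A [scenario_config()].
#' @return List: `family_tree`, `species_tree` (master), `species_trees`
#'   (per family, with root edge), `membership`, `r_true`, `stem_ages`,
#'   `richness` (named by family), `redraws`.
#' @export
simulate_trees <- function(config) {
  set.seed(config$seed + 22L)
  nf <- config$n_families
  fam_tree <- ape::rphylo(nf, birth = 0.03, death = 0)
  fam_tree$tip.label <- sprintf("F%03d", seq_len(nf))
  ages <- node_ages(fam_tree)
  parent_of <- integer(ape::Ntip(fam_tree) + fam_tree$Nnode)
  parent_of[fam_tree$edge[, 2]] <- fam_tree$edge[, 1]
  stem0 <- ages[parent_of[seq_len(nf)]]
  pad <- config$min_stem_age
  fam_tree$edge.length <- fam_tree$edge.length *
    ((config$mean_stem_age - pad) / mean(stem0))
  # push every internal node back by the padding: pendant edges lengthen,
  # tips stay at the present, the tree stays ultrametric
  tip_edges <- fam_tree$edge[, 2] <= nf
  fam_tree$edge.length[tip_edges] <- fam_tree$edge.length[tip_edges] + pad
  ages <- node_ages(fam_tree)
  stem_ages <- stats::setNames(ages[parent_of[seq_len(nf)]], fam_tree$tip.label)
  # expected-richness targets; true rate is exact for pure birth: E n = e^(r t)
  en_target <- pmin(pmax(stats::rlnorm(nf, config$richness_meanlog,
                                       config$richness_sdlog),
                         config$richness_min + 0.5),
                    config$richness_max * 0.8)
  r_true <- stats::setNames(log(en_target) / stem_ages, fam_tree$tip.label)
  newick <- write_newick(fam_tree, digits = 12)
  species_trees <- vector("list", nf)
  names(species_trees) <- fam_tree$tip.label
  richness <- stats::setNames(integer(nf), fam_tree$tip.label)
  membership <- list()
  redraws <- 0L
  for (fam in fam_tree$tip.label) {
    tf <- stem_ages[[fam]]
    repeat {
      sim <- .sim_yule_stem(r_true[[fam]], tf, fam, n_cap = config$richness_max)
      if (!is.null(sim$fragment) &&
          sim$n >= config$richness_min && sim$n <= config$richness_max) break
      redraws <- redraws + 1L
      if (redraws > 50000L) stop("richness conditioning failed to converge")
    }
    richness[[fam]] <- sim$n
    species_trees[[fam]] <- ape::read.tree(text = paste0(sim$fragment, ";"))
    membership[[fam]] <- data.frame(species_id = sim$tips, family_id = fam,
                                    stringsAsFactors = FALSE)
    newick <- sub(paste0("([(,])", fam, ":[0-9.eE+-]+"),
                  paste0("\\1", sim$fragment), newick)
  }
  master <- ape::read.tree(text = newick)
  list(family_tree = fam_tree,
       species_tree = master,
       species_trees = species_trees,
       membership = do.call(rbind, unname(membership)),
       r_true = r_true,
       stem_ages = stem_ages,
       richness = richness,
       redraws = redraws)
}

#' Evolve niche positions and place species ranges on the grid
#'
#' Species niche positions (target BIO1 and BIO12) evolve by Brownian motion
#' on each within-family tree (root edge included) at the family's true rate
#' `sigma2_f`; under `"h2"` coupling `sigma2_f` increases with the family's
#' true net diversification rate, under `"decoupled"` it is independent, and
#' under `"h0"` it is identical across families. Each species' range is the
#' set of grid cells whose BIO1 and BIO12 lie within a climate envelope
#' centred on its niche position; envelope widths are log-normal per species
#' with a family-level random effect, independent of diversification.
#' Envelopes are widened (x 1.4, counted) until they hold >= 2 cells, and
#' positions outside the grid support are clipped (counted).
#'
#' @param config A [scenario_config()].
#' @param grid Climate grid from [make_climate_grid()].
#' @param trees Output of [simulate_trees()].
#' @return List: `ranges` (long `species_id`/`cell_id`), `membership`,
#'   `sigma2_true` (named by family), `niche_targets` (per species),
#'   `n_widened`, `n_clipped`.
#' @export
evolve_and_place <- function(config, grid, trees) {
  set.seed(config$seed + 33L)
  fams <- trees$family_tree$tip.label
  nf <- length(fams)
  r0 <- config$richness_meanlog / config$mean_stem_age
  sigma2_true <- switch(config$coupling,
    h2 = config$sigma2_scale * (trees$r_true / r0)^config$sigma2_pow *
      stats::rlnorm(nf, 0, config$sigma2_sdlog),
    decoupled = stats::rlnorm(nf, log(config$sigma2_scale), 0.6),
    h0 = rep(config$sigma2_scale, nf))
  names(sigma2_true) <- fams
  t_lim <- range(grid$BIO1)
  p_lim <- range(grid$BIO12)
  t_root <- stats::runif(nf, t_lim[1] + 0.25 * diff(t_lim),
                         t_lim[2] - 0.25 * diff(t_lim))
  p_root <- stats::runif(nf, p_lim[1] + 0.25 * diff(p_lim),
                         p_lim[2] - 0.25 * diff(p_lim))
  w_fam <- stats::rlnorm(nf, 0, config$width_family_sdlog)
  n_widened <- 0L; n_clipped <- 0L
  targets <- list(); ranges <- list()
  for (i in seq_len(nf)) {
    fam <- fams[i]
    tr <- trees$species_trees[[fam]]
    s2 <- sigma2_true[[fam]]
    root_edge <- if (is.null(tr$root.edge)) 0 else tr$root.edge
    # shared stem-edge displacement, then BM over the crown tree
    rv_t <- t_root[i] + stats::rnorm(1, 0, sqrt(s2 * root_edge))
    rv_p <- p_root[i] + stats::rnorm(1, 0, sqrt(s2 * root_edge)) *
      config$precip_sigma_factor
    tt <- ape::rTraitCont(tr, model = "BM", sigma = sqrt(s2), root.value = rv_t)
    tp <- ape::rTraitCont(tr, model = "BM",
                          sigma = sqrt(s2) * config$precip_sigma_factor,
                          root.value = rv_p)
    wt <- stats::rlnorm(length(tt), config$width_temp_meanlog,
                        config$width_sdlog) * w_fam[i]
    wp <- stats::rlnorm(length(tt), config$width_precip_meanlog,
                        config$width_sdlog) * w_fam[i]
    fam_cells <- vector("list", length(tt))
    fam_pars <- vector("list", length(tt))
    for (k in seq_along(tt)) {
      sp <- names(tt)[k]
      Tk <- min(max(tt[[k]], t_lim[1]), t_lim[2])
      Pk <- min(max(tp[[k]], p_lim[1]), p_lim[2])
      if (Tk != tt[[k]] || Pk != tp[[k]]) n_clipped <- n_clipped + 1L
      wT <- wt[k]; wP <- wp[k]
      repeat {
        cells <- which(abs(grid$BIO1 - Tk) <= wT / 2 &
                       abs(grid$BIO12 - Pk) <= wP / 2)
        if (length(cells) >= 2L) break
        wT <- wT * 1.4; wP <- wP * 1.4
        n_widened <- n_widened + 1L
      }
      fam_cells[[k]] <- cells
      fam_pars[[k]] <- c(Tk, Pk, wT, wP)
    }
    # guarantee heterogeneous ranges within the family: pairwise-identical
    # member cell sets would make family (or sliced-clade) widths collapse
    # onto a single species' width and traits exactly constant
    tries <- 0L
    repeat {
      keys <- vapply(fam_cells, function(cs) paste(sort(cs), collapse = ","),
                     character(1))
      dup <- which(duplicated(keys))
      if (!length(dup) || tries >= 20L) break
      for (k in dup) {
        fam_pars[[k]][3:4] <- fam_pars[[k]][3:4] * 1.4
        n_widened <- n_widened + 1L
        fam_cells[[k]] <- which(abs(grid$BIO1 - fam_pars[[k]][1]) <=
                                  fam_pars[[k]][3] / 2 &
                                abs(grid$BIO12 - fam_pars[[k]][2]) <=
                                  fam_pars[[k]][4] / 2)
      }
      tries <- tries + 1L
    }
    for (k in seq_along(tt)) {
      sp <- names(tt)[k]
      ranges[[sp]] <- fam_cells[[k]]
      targets[[sp]] <- data.frame(species_id = sp, family_id = fam,
                                  target_bio1 = fam_pars[[k]][1],
                                  target_bio12 = fam_pars[[k]][2],
                                  width_bio1 = fam_pars[[k]][3],
                                  width_bio12 = fam_pars[[k]][4],
                                  stringsAsFactors = FALSE)
    }
  }
  targets <- do.call(rbind, unname(targets))
  # global post-pass: no family's union range may sit exactly at the
  # species-pool minimum range on any variable, which would give the family
  # a standardized width of zero and an undefined ln-transform. Offending
  # families get their last member's envelope widened until resolved.
  vars <- as.matrix(grid[, BIOCLIM_VARS])
  fam_of_sp <- stats::setNames(targets$family_id, targets$species_id)
  for (sweep in 1:10) {
    sp_rg <- t(vapply(ranges, function(cells)
      apply(vars[cells, , drop = FALSE], 2, max) -
        apply(vars[cells, , drop = FALSE], 2, min), numeric(6)))
    pool_min <- apply(sp_rg, 2, min)
    offenders <- character(0)
    for (fam in fams) {
      members <- names(ranges)[fam_of_sp[names(ranges)] == fam]
      ucells <- unique(unlist(ranges[members], use.names = FALSE))
      urg <- apply(vars[ucells, , drop = FALSE], 2, max) -
        apply(vars[ucells, , drop = FALSE], 2, min)
      if (any(urg <= pool_min + 1e-12)) offenders <- c(offenders, fam)
    }
    if (!length(offenders)) break
    for (fam in offenders) {
      members <- names(ranges)[fam_of_sp[names(ranges)] == fam]
      sp <- members[length(members)]
      row <- which(targets$species_id == sp)
      targets$width_bio1[row] <- targets$width_bio1[row] * 1.4
      targets$width_bio12[row] <- targets$width_bio12[row] * 1.4
      n_widened <- n_widened + 1L
      ranges[[sp]] <- which(
        abs(grid$BIO1 - targets$target_bio1[row]) <= targets$width_bio1[row] / 2 &
        abs(grid$BIO12 - targets$target_bio12[row]) <= targets$width_bio12[row] / 2)
    }
  }
  long <- do.call(rbind, lapply(names(ranges), function(sp)
    data.frame(species_id = sp, cell_id = grid$cell_id[ranges[[sp]]],
               stringsAsFactors = FALSE)))
  list(ranges = long,
       membership = trees$membership,
       sigma2_true = sigma2_true,
       niche_targets = targets,
       n_widened = n_widened,
       n_clipped = n_clipped)
}

#' Generate a complete synthetic scenario
#'
#' Runs [make_climate_grid()], [simulate_trees()] and [evolve_and_place()]
#' and bundles everything the pipeline consumes, together with the ground
#' truth.
#'
#' @param config A [scenario_config()] (or arguments forwarded to it).
#' @param ... Passed to [scenario_config()] when `config` is missing.
#' @return List with class `scenario_data`: `config`, `grid`, `ranges`,
#'   `membership`, `family_tree`, `species_tree`, `species_trees`, `truth`
#'   (list: `r_true`, `sigma2_true`, `richness`, `stem_ages`).
#' @examples
#' \donttest{
#' sc <- simulate_scenario(scenario_config(seed = 42, n_families = 20))
#' }
#' @export
simulate_scenario <- function(config = scenario_config(...), ...) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- make_climate_grid(config)
  trees <- simulate_trees(config)
  placed <- evolve_and_place(config, grid, trees)
  structure(list(
    config = config,
    grid = grid,
    ranges = placed$ranges,
    membership = placed$membership,
    family_tree = trees$family_tree,
    species_tree = trees$species_tree,
    species_trees = trees$species_trees,
    truth = list(r_true = trees$r_true,
                 sigma2_true = placed$sigma2_true,
                 richness = trees$richness,
                 stem_ages = trees$stem_ages,
                 niche_targets = placed$niche_targets,
                 redraws = trees$redraws,
                 n_widened = placed$n_widened,
                 n_clipped = placed$n_clipped)
  ), class = "scenario_data")
}
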
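# Shared fixtures and independent brute-force oracles. Everything is built
# in code; nothing is read from disk.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# balanced 4-tip tree: root at 100 Ma, two cherries splitting at 40 Ma
toy_slice_tree <- function()
  read_newick("((A:40,B:40):60,(C:40,D:40):60);")

# tiny 2x3 grid with hand-checkable values
toy_grid <- function() {
  data.frame(
    cell_id = paste0("g", 1:6),
    x = c(1, 2, 3, 1, 2, 3), y = c(1, 1, 1, 2, 2, 2),
    area_km2 = 10,
    BIO1 = c(10, 20, 30, 12, 22, 32),
    BIO5 = c(18, 28, 38, 20, 30, 40),
    BIO6 = c(2, 12, 22, 4, 14, 24),
    BIO12 = c(1000, 1400, 1800, 900, 1300, 1700),
    BIO16 = c(500, 700, 900, 450, 650, 850),
    BIO17 = c(100, 140, 180, 90, 130, 170),
    stringsAsFactors = FALSE
  )
}

# independent oracle: root-to-tip distance by explicit path summation
bf_tip_depths <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  vapply(seq_len(ntip), function(tip) {
    d <- 0; v <- tip
    while (v != root) { d <- d + elen[v]; v <- parent[v] }
    d
  }, numeric(1))
}

# independent oracle: covariance entry by pairwise MRCA depth search
bf_vcv <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  anc <- function(v) {
    path <- v
    while (v != root) { v <- parent[v]; path <- c(path, v) }
    path
  }
  depth_of <- function(v) {
    d <- 0
    while (v != root) { d <- d + elen[v]; v <- parent[v] }
    d
  }
  M <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    mrca <- intersect(anc(i), anc(j))
    M[i, j] <- max(vapply(mrca, depth_of, numeric(1)))
    if (i == j) M[i, j] <- depth_of(i)
  }
  M
}

# brute-force BM likelihood over an explicit (mu, sigma2) grid
bf_bm_grid <- function(tree, x, mu_grid, s2_grid) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  best <- c(lnl = -Inf, mu = NA, sigma2 = NA)
  for (mu in mu_grid) for (s2 in s2_grid) {
    V <- s2 * C
    lnl <- tryCatch(
      -0.5 * (length(x) * log(2 * pi) + determinant(V)$modulus +
                t(x - mu) %*% solve(V, x - mu)),
      error = function(e) -Inf)
    if (lnl > best[["lnl"]]) best <- c(lnl = as.numeric(lnl), mu = mu, sigma2 = s2)
  }
  best
}

# small default H2 scenario, built once per test run
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_scenario(scenario_config(seed = 101, n_families = 25))
    cache
  }
})

# i.i.d. species pool on a synthetic grid (no family structure): the
# substrate for exchangeable null-model calibration
make_iid_pool <- function(seed, npool = 120, nx = 40, ny = 30) {
  grid <- make_climate_grid(scenario_config(seed = seed, grid_nx = nx,
                                            grid_ny = ny))
  set.seed(seed + 1L)
  tl <- range(grid$BIO1); pl <- range(grid$BIO12)
  ranges <- do.call(rbind, lapply(seq_len(npool), function(i) {
    Tk <- stats::runif(1, tl[1], tl[2]); Pk <- stats::runif(1, pl[1], pl[2])
    wT <- stats::rlnorm(1, log(4), 0.4); wP <- stats::rlnorm(1, log(500), 0.4)
    repeat {
      cells <- which(abs(grid$BIO1 - Tk) <= wT / 2 &
                     abs(grid$BIO12 - Pk) <= wP / 2)
      if (length(cells) >= 2) break
      wT <- wT * 1.4; wP <- wP * 1.4
    }
    data.frame(species_id = sprintf("s%03d", i), cell_id = grid$cell_id[cells],
               stringsAsFactors = FALSE)
  }))
  sp <- niche_summary_table(grid, ranges)
  rg <- raw_range_table(sp)
  sp$nw <- standardize_widths(rg, rg)$nw
  sp$family_id <- NA_character_
  list(grid = grid, ranges = ranges, species = sp, raw_ranges = rg)
}

# family summary computed exactly the way the null model computes null
# families (member min/max extremes, species-pool standardization), so
# observed and null families are exchangeable by construction
exchangeable_family <- function(pool, n) {
  sp <- pool$species
  vars <- BIOCLIM_VARS
  rg_lo <- vapply(vars, function(v) min(pool$raw_ranges[[v]]), numeric(1))
  rg_hi <- vapply(vars, function(v) max(pool$raw_ranges[[v]]), numeric(1))
  repeat {
    pick <- sample.int(nrow(sp), n, replace = TRUE)
    lo <- vapply(vars, function(v) min(sp[[paste0(v, "_min")]][pick]), numeric(1))
    hi <- vapply(vars, function(v) max(sp[[paste0(v, "_max")]][pick]), numeric(1))
    w <- prod((hi - lo - rg_lo) / (rg_hi - rg_lo))
    m <- mean(sp$nw[pick])
    if (w > 0 && m > 0) return(c(nw = w, msnw = m))
  }
}

# family_table-shaped object for null-model tests, from an i.i.d. pool
exchangeable_family_table <- function(pool, tree, richness, rates) {
  wm <- t(vapply(richness, function(n) exchangeable_family(pool, n), numeric(2)))
  tab <- data.frame(family_id = tree$tip.label, n = richness,
                    nw = wm[, "nw"], mean_species_nw = wm[, "msnw"],
                    row.names = tree$tip.label, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab[["rate_eps0.45"]] <- rates
  structure(list(table = tab, species = pool$species,
                 exclusions = data.frame(), meta = list(eps = 0.45)),
            class = "family_table")
}
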
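test_that("niche summaries match hand arithmetic and the exhaustive scan", {
  g <- toy_grid()
  s1 <- summarize_niche(g, "g1")
  expect_true(all(s1$range == 0))
  expect_equal(s1$min, s1$max)

  s <- summarize_niche(g, c("g1", "g2", "g3"))
  b1 <- s[s$variable == "BIO1", ]
  expect_equal(c(b1$min, b1$max, b1$mean, b1$range), c(10, 30, 20, 20))

  expect_error(summarize_niche(g, c("g1", "nope")), "nope")
  expect_error(summarize_niche(g, character(0)), "empty")

  # random ranges vs per-cell brute-force scan
  grid <- make_climate_grid(scenario_config(seed = 3, grid_nx = 30, grid_ny = 20))
  set.seed(31)
  for (i in 1:50) {
    cells <- sample(grid$cell_id, sample(2:50, 1))
    s <- summarize_niche(grid, cells)
    for (v in BIOCLIM_VARS) {
      vals <- grid[[v]][grid$cell_id %in% cells]
      row <- s[s$variable == v, ]
      expect_equal(c(row$min, row$max, row$mean, row$range),
                   c(min(vals), max(vals), mean(vals), max(vals) - min(vals)))
    }
  }
})

test_that("wide summary table agrees with the single-entity summary", {
  g <- toy_grid()
  ranges <- data.frame(species_id = c("u", "u", "v", "v", "v"),
                       cell_id = c("g1", "g4", "g2", "g3", "g6"))
  w <- niche_summary_table(g, ranges)
  for (sp in c("u", "v")) {
    s <- summarize_niche(g, ranges$cell_id[ranges$species_id == sp])
    for (v in BIOCLIM_VARS) {
      expect_equal(w[w$entity_id == sp, paste0(v, "_mean")],
                   s$mean[s$variable == v])
      expect_equal(w[w$entity_id == sp, paste0(v, "_range")],
                   s$range[s$variable == v])
    }
  }
  expect_equal(w$area_km2, c(20, 30))
})

test_that("standardized widths follow the printed rescaling formula", {
  rg <- data.frame(entity_id = c("a", "b", "c"),
                   BIO1 = c(2, 4, 10), BIO5 = c(1, 2, 3), BIO6 = c(1, 2, 3),
                   BIO12 = c(5, 6, 7), BIO16 = c(5, 6, 7), BIO17 = c(1, 2, 3))
  st <- standardize_widths(rg)
  expect_equal(st$StRg_BIO1, c(0, 0.25, 1))   # (Rg - 2) / (10 - 2)
  expect_equal(st$nw[1], 0)                   # pool minimum on a variable
  expect_equal(st$nw[3], 1)                   # pool maximum on every variable
  expect_true(all(st$nw >= 0 & st$nw <= 1))

  # degenerate pool is refused, naming the variable
  rg$BIO5 <- 1
  expect_error(standardize_widths(rg), "BIO5")

  # each variable attains 0 and 1 at least once on any self-pool
  set.seed(8)
  rg2 <- data.frame(entity_id = letters[1:10])
  for (v in BIOCLIM_VARS) rg2[[v]] <- runif(10, 1, 5)
  st2 <- standardize_widths(rg2)
  for (v in BIOCLIM_VARS) {
    col <- st2[[paste0("StRg_", v)]]
    expect_equal(min(col), 0)
    expect_equal(max(col), 1)
    expect_true(all(col >= 0 & col <= 1))
  }
})

test_that("family niches pool member cells: union extremes and extent", {
  g <- toy_grid()
  # two disjoint species: BIO1 [10,20] and [30,32]
  ranges <- data.frame(species_id = c("u", "u", "v", "v"),
                       cell_id = c("g1", "g2", "g3", "g6"))
  memb <- data.frame(species_id = c("u", "v"), family_id = c("fam1", "fam1"))
  pool <- data.frame(entity_id = c("p", "q"),
                     BIO1 = c(0, 40), BIO5 = c(0, 40), BIO6 = c(0, 40),
                     BIO12 = c(0, 2000), BIO16 = c(0, 1000),
                     BIO17 = c(0, 200))
  fam <- family_niche(g, ranges, memb, pool)
  expect_equal(fam$rg_BIO1, 22)         # 32 - 10 across the union
  expect_equal(fam$extent_km2, 40)
  expect_equal(fam$n_species, 2L)
  expect_equal(fam$pos_BIO1, mean(c(10, 20, 30, 32)))

  # a one-species family reproduces the species' raw ranges and extent
  memb1 <- data.frame(species_id = "u", family_id = "solo")
  fam1 <- family_niche(g, ranges[ranges$species_id == "u", ], memb1, pool)
  expect_equal(fam1$rg_BIO1, 10)
  expect_equal(fam1$extent_km2, 20)
  expect_equal(fam1$nw, fam1$mean_species_nw)
})

test_that("family raw ranges dominate members and grow with added species", {
  sc <- small_scenario()
  memb <- sc$membership
  fams <- unique(memb$family_id)[1:8]
  sp_sum <- niche_summary_table(sc$grid, sc$ranges)
  pool <- raw_range_table(sp_sum)
  fam <- family_niche(sc$grid, sc$ranges, memb, pool)
  for (f in fams) {
    members <- memb$species_id[memb$family_id == f]
    for (v in BIOCLIM_VARS) {
      mem_rg <- sp_sum[[paste0(v, "_range")]][sp_sum$entity_id %in% members]
      expect_gte(fam[f, paste0("rg_", v)], max(mem_rg) - 1e-10)
    }
    expect_gte(fam[f, "extent_km2"],
               max(sp_sum$area_km2[sp_sum$entity_id %in% members]) - 1e-10)
  }

  # adding a species never shrinks range, extent, or (fixed pool) family NW
  f <- fams[which.max(table(memb$family_id)[fams])]
  members <- memb$species_id[memb$family_id == f]
  sub <- memb$species_id %in% members[-length(members)]
  fam_small <- family_niche(sc$grid, sc$ranges[sc$ranges$species_id %in%
                                                 memb$species_id[sub], ],
                            memb[sub, ], pool)
  expect_lte(fam_small[f, "extent_km2"], fam[f, "extent_km2"] + 1e-10)
  expect_lte(fam_small[f, "nw"], fam[f, "nw"] + 1e-12)
  for (v in BIOCLIM_VARS)
    expect_lte(fam_small[f, paste0("rg_", v)], fam[f, paste0("rg_", v)] + 1e-10)
})

test_that("PCA family widths behave on degenerate and structured grids", {
  # rank-1 grid: all six variables multiples of one latent gradient
  lat <- seq(-1, 1, length.out = 30)
  g1 <- data.frame(cell_id = paste0("c", 1:30), x = 1:30, y = 1,
                   area_km2 = 1,
                   BIO1 = 10 * lat + 10, BIO5 = 12 * lat + 25,
                   BIO6 = 8 * lat - 5, BIO12 = 500 * lat + 1000,
                   BIO16 = 300 * lat + 500, BIO17 = 50 * lat + 100)
  ranges <- data.frame(species_id = "s1", cell_id = paste0("c", 1:10))
  memb <- data.frame(species_id = "s1", family_id = "f1")
  pw <- pca_family_width(g1, ranges, memb)
  ve <- attr(pw, "var_explained")
  expect_gt(ve[1], 0.999)
  expect_lt(pw$width_pc2, 1e-6 * pw$width_pc1)

  # single-cell family: both axis ranges zero
  pw1 <- pca_family_width(g1, data.frame(species_id = "s1", cell_id = "c1"),
                          memb)
  expect_equal(pw1$pca_width, 0)
  expect_equal(pw1$width_pc1, 0)

  expect_error(pca_family_width(g1[1:2, ], ranges, memb), "at least 3")

  # PCA widths rank-correlate positively with product widths across families
  sc <- small_scenario()
  pw2 <- pca_family_width(sc$grid, sc$ranges, sc$membership)
  fam <- family_niche(sc$grid, sc$ranges, sc$membership)
  rho <- cor(pw2$pca_width, fam[pw2$family_id, "nw"], method = "spearman")
  expect_gt(rho, 0.5)
})
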
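test_that("stem diversification estimator matches the closed form", {
  expect_equal(stem_diversification_rate(1, 10, 0), 0)       # ln(1) = 0
  expect_equal(stem_diversification_rate(10, 41.65, 0), log(10) / 41.65)
  expect_equal(stem_diversification_rate(10, 41.65, 0.45), log(5.95) / 41.65)
  expect_equal(stem_diversification_rate(10, 41.65, 0.9), log(1.9) / 41.65)

  expect_error(stem_diversification_rate(0, 10, 0), "n must be")
  expect_error(stem_diversification_rate(5, 0, 0), "t must be")
  expect_error(stem_diversification_rate(5, 10, 1), "eps")
})

test_that("stem rate is monotone in n, t and eps over a grid", {
  ns <- c(2, 5, 10, 50, 200)
  ts <- c(5, 20, 41.65, 80)
  es <- c(0, 0.45, 0.9)
  for (t in ts) for (e in es)
    expect_true(all(diff(stem_diversification_rate(ns, t, e)) > 0))
  for (n in ns) for (e in es)
    expect_true(all(diff(stem_diversification_rate(n, ts, e)) < 0))
  for (n in ns) for (t in ts)
    expect_true(all(diff(stem_diversification_rate(n, t, es)) <= 0))
})

test_that("stem rate recovers the generating rate of pure-birth richness", {
  # exact through the mean: ln E[n] = r t; the median-based estimate is
  # asymptotically r - ln(1/ln 2)/t, so it sits within 10% once r t >= 4
  set.seed(210)
  t <- 50
  for (r in c(0.08, 0.12)) {   # r t = 4 and 6
    n <- vapply(1:1000, function(i)
      macroniche:::.sim_yule_stem(r, t, "x")$n, numeric(1))
    r_mean <- stem_diversification_rate(mean(n), t, 0)
    expect_lt(abs(r_mean - r) / r, 0.05)
    r_med <- stem_diversification_rate(stats::median(n), t, 0)
    expect_lt(abs(r_med - r) / r, 0.10)
  }
})

test_that("BM sigma2 ML matches closed forms and is affine-equivariant", {
  # two independent tips, branch length 1: mu = mean, sigma2 = var/2 (ML)
  st <- read_newick("(A:1,B:1);")
  e <- bm_sigma2_ml(st, c(A = 0, B = 2))
  expect_equal(e$mu, 1)
  expect_equal(e$sigma2, 1)

  expect_warning(e0 <- bm_sigma2_ml(st, c(A = 3, B = 3)), "constant")
  expect_equal(e0$sigma2, 0)

  set.seed(77)
  tr <- ape::rcoal(15)
  x <- ape::rTraitCont(tr, sigma = 1.3)
  e1 <- bm_sigma2_ml(tr, x)
  e2 <- bm_sigma2_ml(tr, x + 100)       # shift invariance
  expect_equal(e1$sigma2, e2$sigma2, tolerance = 1e-10)
  e3 <- bm_sigma2_ml(tr, 3 * x)         # scale equivariance: c^2
  expect_equal(e3$sigma2, 9 * e1$sigma2, tolerance = 1e-10)

  expect_error(bm_sigma2_ml(tr, x[-1]), "missing trait")
})

test_that("3-tip BM fit agrees with a dense likelihood-grid search", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 0.3, B = 1.1, C = -0.8)
  fit <- bm_sigma2_ml(tr, x)
  coarse <- bf_bm_grid(tr, x,
                       mu_grid = seq(-1, 1, by = 0.01),
                       s2_grid = seq(0.05, 3, by = 0.01))
  bf <- bf_bm_grid(tr, x,
                   mu_grid = seq(coarse[["mu"]] - 0.02, coarse[["mu"]] + 0.02,
                                 by = 5e-5),
                   s2_grid = seq(coarse[["sigma2"]] - 0.02,
                                 coarse[["sigma2"]] + 0.02, by = 5e-5))
  expect_lt(abs(fit$mu - bf[["mu"]]), 1e-4)
  expect_lt(abs(fit$sigma2 - bf[["sigma2"]]), 1e-4)
  expect_gte(fit$lnl, bf[["lnl"]] - 1e-6)  # ML at least as good as the grid
})

test_that("mean BM sigma2 over many replicates is near truth (ML bias allowed)", {
  set.seed(88)
  est <- numeric(300)
  k <- 0
  for (i in 1:15) {
    tr <- ape::rcoal(50)
    for (j in 1:20) {
      k <- k + 1
      est[k] <- bm_sigma2_ml(tr, ape::rTraitCont(tr, sigma = 1))$sigma2
    }
  }
  expect_gt(mean(est), 0.9)
  expect_lt(mean(est), 1.1)
})

test_that("lambda model nests BM and recovers signal and no-signal limits", {
  set.seed(99)
  tr <- ape::rcoal(60)
  x <- ape::rTraitCont(tr, sigma = 1)
  bm <- bm_sigma2_ml(tr, x)
  lf <- lambda_model_fit(tr, x)
  expect_gte(lf$lnl, bm$lnl - 1e-8)            # nesting
  expect_true(lf$lambda >= 0 && lf$lambda <= 1)
  # lambda = 1 reproduces the BM profile exactly
  C <- ape::vcv(tr)
  p1 <- macroniche:::.bm_profile(x[rownames(C)], C)
  expect_equal(p1$sigma2, bm$sigma2, tolerance = 1e-12)

  # BM-generated data: lambda near 1 in the median
  lams <- vapply(1:40, function(i) {
    t2 <- ape::rcoal(120)
    lambda_model_fit(t2, ape::rTraitCont(t2, sigma = 1))$lambda
  }, numeric(1))
  expect_gte(stats::median(lams), 0.9)

  # i.i.d. noise on a deep tree: lambda near 0
  lam0 <- vapply(1:20, function(i) {
    t2 <- ape::rcoal(80)
    z <- stats::rnorm(80)
    names(z) <- t2$tip.label
    lambda_model_fit(t2, z)$lambda
  }, numeric(1))
  expect_lt(stats::median(lam0), 0.1)

  expect_error(lambda_model_fit(read_newick("(A:1,B:1);"), c(A = 1, B = 2)),
               "at least 3")
})

test_that("lambda fit agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(123)
  tr <- ape::rcoal(40)
  x <- ape::rTraitCont(tr, sigma = 1) + stats::rnorm(40, 0, 0.6)
  names(x) <- tr$tip.label
  lf <- lambda_model_fit(tr, x)
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(lf$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(lf$lnl, ps$logL, tolerance = 1e-4)
})

test_that("family rates skip monospecific/paraphyletic families with reasons", {
  # master tree: ((a1,a2),(b1,(c1,b2))) -> famB is paraphyletic
  tr <- read_newick("((a1:1,a2:1):3,(b1:2,(c1:1,b2:1):1):2);")
  memb <- data.frame(species_id = c("a1", "a2", "b1", "b2", "c1", "d1"),
                     family_id = c("famA", "famA", "famB", "famB", "famC", "famD"))
  traits <- data.frame(species_id = memb$species_id,
                       BIO1_mean = c(1, 2, 5, 6, 3, 0),
                       BIO12_mean = c(100, 150, 300, 200, 250, 0))
  fr <- family_rates(tr, memb, traits)
  expect_equal(fr["famA", "skip_reason"], NA_character_)
  expect_equal(fr["famB", "skip_reason"], "paraphyletic")
  expect_equal(fr["famC", "skip_reason"], "monospecific")
  expect_equal(fr["famD", "skip_reason"], "not_in_tree")
  # two-tip family: BM sigma2 equals the closed form on its cherry
  sub <- ape::keep.tip(tr, c("a1", "a2"))
  e <- bm_sigma2_ml(sub, c(a1 = 1, a2 = 2))
  expect_equal(fr["famA", "sigma2_bio1"], e$sigma2)
})

test_that("per-family sigma2 estimates recover the true rate ordering", {
  set.seed(321)
  hits <- 0L
  nrep <- 30L
  for (i in seq_len(nrep)) {
    s2 <- c(0.01, 0.1, 1)
    est <- vapply(s2, function(s) {
      tr <- ape::rcoal(50)
      bm_sigma2_ml(tr, ape::rTraitCont(tr, sigma = sqrt(s)))$sigma2
    }, numeric(1))
    if (all(order(est) == 1:3)) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * nrep))
})
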
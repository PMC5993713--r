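make_pgls_data <- function(n = 30, seed = 1, beta = 0.5, noise = 0.7) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  x <- ape::rTraitCont(tr, sigma = 1)
  y <- beta * x + ape::rTraitCont(tr, sigma = noise)
  list(tree = tr, data = data.frame(x = x, y = y, row.names = tr$tip.label))
}

test_that("lambda = 0 reproduces OLS and the star tree neutralizes lambda", {
  d <- make_pgls_data(40, seed = 2)
  f0 <- pgls_fit(y ~ x, d$data, d$tree, lambda = 0)
  ols <- lm(y ~ x, d$data)
  expect_lt(max(abs(coef(f0) - coef(ols))), 1e-8)
  expect_lt(abs(f0$r_squared - summary(ols)$r.squared), 1e-8)
  expect_lt(max(abs(pgls_residuals(f0) - resid(ols)[names(f0$residuals)])), 1e-8)
  expect_equal(unname(f0$df), c(1, 38))

  # star phylogeny: diagonal covariance, so the ML fit is OLS whatever lambda
  star <- ape::stree(25, type = "star")
  star$edge.length <- rep(1, 25)
  set.seed(3)
  ds <- data.frame(x = rnorm(25), row.names = star$tip.label)
  ds$y <- 1.5 * ds$x + rnorm(25)
  fs <- pgls_fit(y ~ x, ds, star)
  olss <- lm(y ~ x, ds)
  expect_lt(max(abs(coef(fs) - coef(olss))), 1e-8)
  expect_lt(abs(fs$r_squared - summary(olss)$r.squared), 1e-8)
})

test_that("fixed-lambda fits match explicit GLS matrix algebra", {
  d <- make_pgls_data(25, seed = 4)
  C <- phylo_covariance(d$tree)
  X <- cbind(1, d$data[rownames(C), "x"])
  y <- d$data[rownames(C), "y"]
  for (lam in c(0.25, 0.6, 1)) {
    Cl <- C * lam; diag(Cl) <- diag(C)
    Ci <- solve(Cl)
    beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
    f <- pgls_fit(y ~ x, d$data, d$tree, lambda = lam)
    expect_lt(max(abs(coef(f) - drop(beta))), 1e-8)
    # F from whitened-space sums of squares against the GLS mean
    mu0 <- drop(solve(t(rep(1, 25)) %*% Ci %*% rep(1, 25),
                      t(rep(1, 25)) %*% Ci %*% y))
    rss <- drop(t(y - X %*% beta) %*% Ci %*% (y - X %*% beta))
    tss <- drop(t(y - mu0) %*% Ci %*% (y - mu0))
    Fref <- (tss - rss) / (rss / (25 - 2))
    expect_equal(f$F, Fref, tolerance = 1e-8)
    expect_equal(f$p_value, pf(Fref, 1, 23, lower.tail = FALSE),
                 tolerance = 1e-8)
    expect_equal(f$r_squared, 1 - rss / tss, tolerance = 1e-10)
    # SE from GLS theory
    se <- sqrt(diag(solve(t(X) %*% Ci %*% X)) * rss / 23)
    expect_lt(max(abs(f$se - se)), 1e-8)
  }
})

test_that("fixed-lambda fits match nlme::gls with corPagel", {
  skip_if_not_installed("nlme")
  d <- make_pgls_data(30, seed = 5)
  dd <- d$data
  dd$species <- rownames(dd)
  for (lam in c(0.3, 0.8)) {
    f <- pgls_fit(y ~ x, dd, d$tree, lambda = lam)
    g <- nlme::gls(y ~ x, data = dd,
                   correlation = ape::corPagel(lam, d$tree, form = ~species,
                                               fixed = TRUE),
                   method = "ML")
    expect_lt(max(abs(coef(f) - coef(g))), 1e-10)
    expect_lt(abs(f$se[2] - sqrt(vcov(g)[2, 2])), 1e-10)
    expect_lt(abs(f$log_lik - as.numeric(stats::logLik(g))), 1e-8)
  }
})

test_that("degenerate and identity fits behave: y == x, reconstruction", {
  d <- make_pgls_data(20, seed = 6)
  dd <- d$data
  dd$y <- dd$x
  f <- pgls_fit(y ~ x, dd, d$tree)
  expect_equal(unname(coef(f)), c(0, 1), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  expect_lt(max(abs(pgls_residuals(f))), 1e-10)

  # fitted + residuals reconstruct the response
  f2 <- pgls_fit(y ~ x, d$data, d$tree)
  expect_lt(max(abs(f2$fitted + f2$residuals - f2$y)), 1e-10)

  # GLS-weighted residual mean is zero under the fitted covariance
  C <- phylo_covariance(d$tree)
  Cl <- C * f2$lambda; diag(Cl) <- diag(C)
  expect_lt(abs(sum(solve(Cl, f2$residuals[rownames(C)]))), 1e-6)

  expect_error(pgls_fit(y ~ x, d$data[1:2, ], d$tree), "align|observations")
})

test_that("r2 is invariant to affine predictor rescaling; slope rescales", {
  d <- make_pgls_data(30, seed = 7)
  f1 <- pgls_fit(y ~ x, d$data, d$tree)
  d2 <- d$data
  d2$x <- 10 * d2$x + 3
  f2 <- pgls_fit(y ~ x, d2, d$tree)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-8)
  expect_equal(coef(f1)[["x"]], 10 * coef(f2)[["x"]], tolerance = 1e-6)
  expect_equal(f1$F, f2$F, tolerance = 1e-6)
})

test_that("profile likelihood at the ML lambda dominates a lambda grid", {
  for (seed in 8:10) {
    d <- make_pgls_data(30, seed = seed, noise = 1)
    f <- pgls_fit(y ~ x, d$data, d$tree)
    ctx <- pgls_context(d$tree)
    y <- d$data[ctx$tips, "y"]; X <- cbind(1, d$data[ctx$tips, "x"])
    for (lam in c(0, 0.5, 1)) {
      a <- macroniche:::.pgls_at_lambda(y, X, ctx, lam)
      expect_gte(f$log_lik + 1e-6,
                 macroniche:::.pgls_lnl(a$rss, a$logdet, ctx$n))
    }
    expect_true(f$lambda >= 0 && f$lambda <= 1)
  }
})

test_that("PGLS slope recovery is unbiased with BM residuals", {
  set.seed(30)
  tr <- ape::rcoal(92)
  tr$edge.length <- tr$edge.length / tree_height(tr) * 41.65
  ctx <- pgls_context(tr)
  betas <- lams <- numeric(100)
  for (i in 1:100) {
    x <- ape::rTraitCont(tr, sigma = 1)
    y <- 0.4 * x + ape::rTraitCont(tr, sigma = 0.5)
    dd <- data.frame(x = x[ctx$tips], y = y[ctx$tips], row.names = ctx$tips)
    f <- pgls_fit(y ~ x, dd, ctx)
    betas[i] <- coef(f)[["x"]]; lams[i] <- f$lambda
  }
  expect_lt(abs(mean(betas) - 0.4), 0.03)
  expect_gte(stats::median(lams), 0.8)
})

test_that("forward stepwise selects the signal and rejects duplicates", {
  set.seed(41)
  tr <- ape::rcoal(60)
  ctx <- pgls_context(tr)
  hits <- 0L
  nrep <- 40L
  for (i in seq_len(nrep)) {
    x1 <- ape::rTraitCont(tr, sigma = 1)
    noise <- replicate(3, ape::rTraitCont(tr, sigma = 1))
    y <- 0.8 * x1 + ape::rTraitCont(tr, sigma = 0.5)
    dd <- data.frame(y = y[ctx$tips], x1 = x1[ctx$tips],
                     n1 = noise[, 1][ctx$tips], n2 = noise[, 2][ctx$tips],
                     n3 = noise[, 3][ctx$tips], row.names = ctx$tips)
    st <- forward_stepwise("y", c("x1", "n1", "n2", "n3"), dd, ctx)
    if (identical(st$selected[1], "x1")) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * nrep))

  # duplicated candidate never enters twice
  dd$x1b <- dd$x1
  st2 <- forward_stepwise("y", c("x1", "x1b"), dd, ctx)
  expect_false(all(c("x1", "x1b") %in% st2$selected))

  # pure-noise candidates: occasional entries from multiplicity, but not many
  set.seed(42)
  enter <- vapply(1:40, function(i) {
    y <- ape::rTraitCont(tr, sigma = 1)
    nn <- replicate(4, ape::rTraitCont(tr, sigma = 1))
    dd <- data.frame(y = y[ctx$tips], row.names = ctx$tips)
    for (j in 1:4) dd[[paste0("n", j)]] <- nn[, j][ctx$tips]
    length(forward_stepwise("y", paste0("n", 1:4), dd, ctx)$selected) > 0
  }, logical(1))
  expect_lte(mean(enter), 0.45)
})

test_that("the fast null-model fit agrees with the full PGLS engine", {
  set.seed(50)
  tr <- ape::rcoal(25)
  ctx <- pgls_context(tr)
  for (i in 1:10) {
    y <- ape::rTraitCont(tr) + rnorm(25, 0, 0.5)
    x <- ape::rTraitCont(tr)
    q <- macroniche:::.pgls_quick(y[ctx$tips], x[ctx$tips], ctx)
    dd <- data.frame(y = y[ctx$tips], x = x[ctx$tips], row.names = ctx$tips)
    f <- pgls_fit(y ~ x, dd, ctx)
    expect_equal(q$r_squared, f$r_squared, tolerance = 1e-6)
    expect_equal(q$lambda, f$lambda, tolerance = 1e-4)
    expect_lt(max(abs(q$residuals - f$residuals)), 1e-6)
  }
})
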
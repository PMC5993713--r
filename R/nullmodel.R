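# Resampling null models: null families are drawn with replacement from a
# species pool, keeping the observed richness of each family, the observed
# family tree and the observed diversification rates; only the niche
# variables (family niche width, mean species niche width, niche
# divergence) are rebuilt per replicate. Empirical p-values use the add-one
# estimator, both tails.

# per-species table the null models need: raw ranges, nw, per-variable
# means, centroid. Built from a family_table's `species` slot.
.null_species_pool <- function(species) {
  need <- c("entity_id", "nw", "x", "y",
            paste0(BIOCLIM_VARS, "_min"), paste0(BIOCLIM_VARS, "_max"),
            paste0(BIOCLIM_VARS, "_mean"), paste0(BIOCLIM_VARS, "_range"))
  miss <- setdiff(need, names(species))
  if (length(miss)) stop("species table missing: ", paste(miss, collapse = ", "))
  species
}

#' Resampling null model for the niche-diversification regressions
#'
#' Draws, per replicate, one null family for each observed family: the same
#' species richness, species sampled with replacement from a pool that is
#' (1) all species (`"unconstrained"`), (2) species whose range centroid
#' falls inside the family's longitude/latitude bounding box (`"spatial"`),
#' or (3) species whose per-variable mean climate lies inside the family's
#' six-variable min-max envelope (`"climatic"`). Family niche width (over
#' the resampled members, standardized against the species pool), mean
#' species niche width and null niche divergence are rebuilt; the family
#' tree and observed diversification rates are kept fixed. Four PGLS
#' regressions are refitted per replicate: (a) family NW ~ mean species NW,
#' (b) rate ~ family NW, (c) rate ~ mean species NW, (d) rate ~ null niche
#' divergence (all ln-transformed except divergence), and the r^2
#' distributions are compared with the observed ones:
#' `p_upper = (#(null >= obs) + 1) / (reps + 1)`, mirrored for `p_lower`.
#'
#' An empty constrained pool falls back to the unconstrained pool with a
#' logged warning; a resampled family with zero niche width is redrawn
#' (counted in `n_redrawn`).
#'
#' @param family_table A [build_family_table()] result.
#' @param family_tree Family-level `phylo` or [pgls_context()].
#' @param type Null model type.
#' @param reps Number of replicates (default 1000).
#' @param seed Optional integer seed.
#' @param eps Extinction fraction of the fixed observed rates.
#' @return Object of class `null_model_result`: `type`, `reps`, `observed`
#'   (named r^2 vector for a-d), `null_r2` (reps x 4 matrix), `p_upper`,
#'   `p_lower`, `n_fallback`, `n_redrawn`.
#' @export
null_model <- function(family_table, family_tree,
                       type = c("unconstrained", "spatial", "climatic"),
                       reps = 1000, seed = NULL, eps = 0.45) {
  type <- match.arg(type)
  stopifnot(inherits(family_table, "family_table"))
  if (!is.null(seed)) set.seed(seed)
  tab <- family_table$table
  sp <- .null_species_pool(family_table$species)
  nfam <- nrow(tab)
  ctx <- if (inherits(family_tree, "pgls_context")) family_tree
         else pgls_context(family_tree, rownames(tab))
  tab <- tab[match(ctx$tips, rownames(tab)), ]
  richness <- tab$n
  ln_rate <- log(tab[[.rate_col(eps)]])
  # species-pool standardization bounds per variable
  rg_lo <- vapply(BIOCLIM_VARS, function(v) min(sp[[paste0(v, "_range")]]), numeric(1))
  rg_hi <- vapply(BIOCLIM_VARS, function(v) max(sp[[paste0(v, "_range")]]), numeric(1))
  mins <- as.matrix(sp[, paste0(BIOCLIM_VARS, "_min")])
  maxs <- as.matrix(sp[, paste0(BIOCLIM_VARS, "_max")])
  means <- as.matrix(sp[, paste0(BIOCLIM_VARS, "_mean")])
  n_fallback <- 0L
  pools <- lapply(seq_len(nfam), function(i) {
    fam <- rownames(tab)[i]
    if (type == "unconstrained") return(seq_len(nrow(sp)))
    members <- which(sp$family_id == fam)
    if (type == "spatial") {
      bx <- range(sp$x[members]); by <- range(sp$y[members])
      idx <- which(sp$x >= bx[1] & sp$x <= bx[2] &
                   sp$y >= by[1] & sp$y <= by[2])
    } else {
      lo <- apply(mins[members, , drop = FALSE], 2, min)
      hi <- apply(maxs[members, , drop = FALSE], 2, max)
      ok <- rep(TRUE, nrow(sp))
      for (j in seq_along(BIOCLIM_VARS))
        ok <- ok & means[, j] >= lo[j] & means[, j] <= hi[j]
      idx <- which(ok)
    }
    if (!length(idx)) {
      n_fallback <<- n_fallback + 1L
      warning("empty ", type, " pool for family ", fam,
              "; falling back to the unconstrained pool")
      idx <- seq_len(nrow(sp))
    }
    idx
  })
  # observed regressions (a)-(d)
  d_obs <- data.frame(ln_fnw = log(tab$nw), ln_msnw = log(tab$mean_species_nw),
                      ln_rate = ln_rate, row.names = rownames(tab))
  fit_a <- pgls_fit(ln_fnw ~ ln_msnw, d_obs, ctx)
  d_obs$nd <- pgls_residuals(fit_a)[rownames(d_obs)]
  observed <- c(
    a_fnw_msnw = fit_a$r_squared,
    b_rate_fnw = pgls_fit(ln_rate ~ ln_fnw, d_obs, ctx)$r_squared,
    c_rate_msnw = pgls_fit(ln_rate ~ ln_msnw, d_obs, ctx)$r_squared,
    d_rate_nd = pgls_fit(ln_rate ~ nd, d_obs, ctx)$r_squared
  )
  n_redrawn <- 0L
  null_r2 <- matrix(NA_real_, reps, 4,
                    dimnames = list(NULL, names(observed)))
  for (r in seq_len(reps)) {
    fnw <- msnw <- numeric(nfam)
    for (i in seq_len(nfam)) {
      tries <- 0L
      repeat {
        pick <- pools[[i]][sample.int(length(pools[[i]]), richness[i],
                                      replace = TRUE)]
        lo <- hi <- numeric(length(BIOCLIM_VARS))
        for (j in seq_along(lo)) {
          lo[j] <- min(mins[pick, j])
          hi[j] <- max(maxs[pick, j])
        }
        st <- (hi - lo - rg_lo) / (rg_hi - rg_lo)
        w <- prod(st)
        m <- mean(sp$nw[pick])
        if (w > 0 && m > 0) break
        tries <- tries + 1L
        n_redrawn <- n_redrawn + 1L
        if (tries > 100L) stop("null family with zero niche width persisted")
      }
      fnw[i] <- w; msnw[i] <- m
    }
    d <- data.frame(ln_fnw = log(fnw), ln_msnw = log(msnw),
                    ln_rate = ln_rate, row.names = rownames(tab))
    fa <- .pgls_quick(d$ln_fnw, d$ln_msnw, ctx)
    d$nd <- fa$residuals
    null_r2[r, ] <- c(fa$r_squared,
                      .pgls_quick(d$ln_rate, d$ln_fnw, ctx)$r_squared,
                      .pgls_quick(d$ln_rate, d$ln_msnw, ctx)$r_squared,
                      .pgls_quick(d$ln_rate, d$nd, ctx)$r_squared)
  }
  p_upper <- (colSums(sweep(null_r2, 2, observed, `>=`)) + 1) / (reps + 1)
  p_lower <- (colSums(sweep(null_r2, 2, observed, `<=`)) + 1) / (reps + 1)
  structure(list(type = type, reps = reps, observed = observed,
                 null_r2 = null_r2, p_upper = p_upper, p_lower = p_lower,
                 n_fallback = n_fallback, n_redrawn = n_redrawn,
                 eps = eps, seed = seed),
            class = "null_model_result")
}

# minimal single-predictor PGLS with ML lambda on a precomputed context:
# returns r_squared, raw residuals, lambda. Same model as pgls_fit (their
# agreement is tested); the simple-regression normal equations are solved
# in closed form in the eigenbasis, O(n) per lambda evaluation.
.pgls_quick <- function(y, x, ctx) {
  if (!ctx$ultrametric) {
    X <- cbind(1, x)
    ml <- .pgls_ml_lambda(y, X, ctx)
    f <- .pgls_at_lambda(y, X, ctx, ml$lambda)
    beta <- qr.coef(f$qx, f$yw)
    f0 <- .pgls_at_lambda(y, matrix(1, ctx$n, 1), ctx, ml$lambda)
    resid <- drop(y - X %*% beta)
    names(resid) <- ctx$tips
    return(list(r_squared = if (f0$rss > 0) max(0, 1 - f$rss / f0$rss) else 0,
                residuals = resid, lambda = ml$lambda))
  }
  n <- ctx$n
  ty <- drop(ctx$Ut %*% y)
  tx <- drop(ctx$Ut %*% x)
  t1 <- drop(ctx$Ut %*% rep(1, n))  # the intercept column in the eigenbasis
  dh <- ctx$values - ctx$h
  at_lam <- function(lam) {
    d <- lam * dh + ctx$h
    if (any(d <= 1e-12 * ctx$h)) return(NULL)
    w <- 1 / d
    S11 <- sum(w * t1 * t1); S1x <- sum(w * t1 * tx); S1y <- sum(w * t1 * ty)
    Sxx <- sum(w * tx * tx); Sxy <- sum(w * tx * ty); Syy <- sum(w * ty * ty)
    den <- S11 * Sxx - S1x * S1x
    if (den <= 0) return(NULL)
    beta <- (S11 * Sxy - S1x * S1y) / den
    alpha <- (S1y - beta * S1x) / S11
    rss <- Syy - alpha * S1y - beta * Sxy
    rss0 <- Syy - S1y * S1y / S11
    list(rss = max(rss, 0), rss0 = max(rss0, 0), logdet = sum(log(d)),
         alpha = alpha, beta = beta)
  }
  obj <- function(lam) {
    f <- at_lam(lam)
    if (is.null(f)) return(-Inf)
    .pgls_lnl(f$rss, f$logdet, n)
  }
  grid <- seq(0, 1, length.out = 21)
  lnl <- vapply(grid, obj, numeric(1))
  i <- which.max(lnl)
  lam <- grid[i]; best <- lnl[i]
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(21L, i + 1L)]
  if (hi > lo) {
    op <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
    if (is.finite(op$objective) && op$objective > best) lam <- op$maximum
  }
  f <- at_lam(lam)
  resid <- y - f$alpha - f$beta * x
  names(resid) <- ctx$tips
  list(r_squared = if (f$rss0 > 0) max(0, 1 - f$rss / f$rss0) else 0,
       residuals = resid, lambda = lam)
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("Null model (%s), %d replicates (eps = %g)\n",
              x$type, x$reps, x$eps))
  out <- data.frame(observed_r2 = x$observed,
                    null_mean_r2 = colMeans(x$null_r2),
                    p_upper = x$p_upper, p_lower = x$p_lower)
  print(round(out, 4))
  if (x$n_fallback) cat("pool fallbacks:", x$n_fallback, "\n")
  invisible(x)
}
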
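# Phylogenetic generalized least squares with profile-ML Pagel's lambda.
# The error covariance is the lambda transform of the phylogenetic
# covariance C (off-diagonals multiplied by lambda; kappa and delta fixed
# at 1, i.e. no branch-length power or node-depth transforms). lambda is
# estimated by profile maximum likelihood of the regression residual model
# on [0, 1] via a 21-point grid pre-scan plus golden-section refinement.

#' Precompute the PGLS whitening context for a tree
#'
#' Eigendecomposes the phylogenetic covariance once so that repeated fits on
#' the same tree (stepwise selection, variance partitioning, null-model
#' replicates) are cheap. On an ultrametric tree every lambda transform is
#' diagonal in the same eigenbasis, so the per-lambda cost is a diagonal
#' rescaling; for non-ultrametric trees a Cholesky factorization per lambda
#' is used instead.
#'
#' @param tree A `phylo` object.
#' @param ids Optional tip subset/order; defaults to all tips.
#' @return List with class `pgls_context`.
#' @export
pgls_context <- function(tree, ids = NULL) {
  C <- phylo_covariance(tree, ids)
  h <- mean(diag(C))
  ultra <- max(abs(diag(C) - h)) <= 1e-8 * max(h, 1)
  eig <- eigen(C, symmetric = TRUE)
  structure(list(C = C, tips = rownames(C), n = nrow(C), h = h,
                 ultrametric = ultra,
                 values = eig$values, Ut = t(eig$vectors)),
            class = "pgls_context")
}

# whitened regression at a given lambda.
# y: response vector, X: model matrix (both already in ctx tip order).
# Returns rss, logdet, qr of whitened X, whitened y/X.
.pgls_at_lambda <- function(y, X, ctx, lambda, Uty = NULL, UtX = NULL) {
  n <- ctx$n
  if (ctx$ultrametric) {
    d <- lambda * (ctx$values - ctx$h) + ctx$h
    if (any(d <= 1e-12 * ctx$h))
      return(list(rss = Inf, logdet = -Inf, ok = FALSE))
    if (is.null(Uty)) Uty <- drop(ctx$Ut %*% y)
    if (is.null(UtX)) UtX <- ctx$Ut %*% X
    s <- 1 / sqrt(d)
    yw <- Uty * s
    Xw <- UtX * s
    logdet <- sum(log(d))
  } else {
    Cl <- .lambda_transform(ctx$C, lambda)
    R <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(R)) return(list(rss = Inf, logdet = -Inf, ok = FALSE))
    yw <- backsolve(R, y, transpose = TRUE)
    Xw <- backsolve(R, X, transpose = TRUE)
    logdet <- 2 * sum(log(diag(R)))
  }
  qx <- qr(Xw)
  rss <- sum(qr.resid(qx, yw)^2)
  list(rss = rss, logdet = logdet, qx = qx, yw = yw, Xw = Xw, ok = TRUE)
}

# profile log-likelihood of the residual model at lambda (sigma2 profiled)
.pgls_lnl <- function(rss, logdet, n) {
  if (!is.finite(rss) || rss <= 0) rss <- max(rss, 1e-300)
  -0.5 * (n * log(2 * pi * rss / n) + logdet + n)
}

# maximize profile lnL over lambda in [0, 1]
.pgls_ml_lambda <- function(y, X, ctx, Uty = NULL, UtX = NULL) {
  n <- ctx$n
  obj <- function(lam) {
    f <- .pgls_at_lambda(y, X, ctx, lam, Uty, UtX)
    if (!f$ok) return(-Inf)
    .pgls_lnl(f$rss, f$logdet, n)
  }
  grid <- seq(0, 1, length.out = 21)
  lnl <- vapply(grid, obj, numeric(1))
  i <- which.max(lnl)
  lam <- grid[i]; best <- lnl[i]
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(21L, i + 1L)]
  if (hi > lo) {
    op <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
    if (is.finite(op$objective) && op$objective > best) {
      lam <- op$maximum; best <- op$objective
    }
  }
  list(lambda = lam, lnl = best)
}

#' Phylogenetic generalized least squares with ML lambda
#'
#' Fits `formula` on `data` with error covariance equal to the Pagel-lambda
#' transform of the tree's phylogenetic covariance. `lambda` is estimated by
#' profile maximum likelihood on \[0, 1\] unless fixed numerically. With
#' `lambda = 0` the fit reduces to ordinary least squares; with `lambda = 1`
#' to GLS under the raw Brownian covariance. `r^2` is computed in the
#' whitened space against the GLS intercept-only fit under the same lambda,
#' so it always lies in \[0, 1\]; F, p and the t-based 95% slope CIs follow
#' standard GLS theory with `df = (k - 1, n - k)`.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data Data frame whose rows are clades/tips; row names (or an `id`
#'   column) must match tree tip labels.
#' @param tree A `phylo` object, or a precomputed [pgls_context()].
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @return Object of class `pgls_fit`: coefficients, standard errors,
#'   `ci_halfwidth` (95%, t-based), `lambda`, `r_squared`, `F`, `df`,
#'   `p_value`, raw-scale `residuals` and `fitted` (both id-named),
#'   `log_lik`, `n`.
#' @examples
#' tr <- ape::rcoal(20)
#' d <- data.frame(x = rnorm(20), row.names = tr$tip.label)
#' d$y <- 2 * d$x + rnorm(20)
#' fit <- pgls_fit(y ~ x, d, tr)
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML") {
  ids <- if ("id" %in% names(data) && !anyDuplicated(data$id)) data$id else rownames(data)
  if (is.null(ids)) stop("data must carry clade ids as row names or an `id` column")
  ctx <- if (inherits(tree, "pgls_context")) tree else pgls_context(tree, ids)
  if (!setequal(ids, ctx$tips))
    stop("data ids and tree tips do not align: ",
         paste(union(setdiff(ids, ctx$tips), setdiff(ctx$tips, ids)), collapse = ", "))
  data <- data[match(ctx$tips, ids), , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("need more observations than coefficients")
  if (qr(X)$rank < k) stop("singular design matrix")
  Uty <- if (ctx$ultrametric) drop(ctx$Ut %*% y) else NULL
  UtX <- if (ctx$ultrametric) ctx$Ut %*% X else NULL
  if (identical(lambda, "ML")) {
    ml <- .pgls_ml_lambda(y, X, ctx, Uty, UtX)
    lam <- ml$lambda
    lambda_ml <- TRUE
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam <- lambda
    lambda_ml <- FALSE
  }
  f <- .pgls_at_lambda(y, X, ctx, lam, Uty, UtX)
  if (!f$ok) stop("degenerate covariance at lambda = ", signif(lam, 4))
  beta <- qr.coef(f$qx, f$yw)
  names(beta) <- colnames(X)
  rss <- f$rss
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  names(resid) <- names(fitted) <- ctx$tips
  # intercept-only null in the same whitened space
  has_int <- "(Intercept)" %in% colnames(X)
  X0 <- matrix(1, n, 1)
  f0 <- .pgls_at_lambda(y, X0, ctx, lam, Uty,
                        if (ctx$ultrametric) ctx$Ut %*% X0 else NULL)
  tss <- f0$rss
  df_den <- n - k
  p_num <- k - has_int
  sigma2 <- rss / df_den
  XtX_inv <- chol2inv(chol(crossprod(f$Xw)))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  names(se) <- colnames(X)
  r2 <- if (p_num >= 1 && tss > 0) max(0, 1 - rss / tss) else 0
  Fstat <- if (p_num >= 1) {
    if (rss <= 1e-12 * max(tss, 1)) Inf
    else ((tss - rss) / p_num) / (rss / df_den)
  } else NA_real_
  pval <- if (is.na(Fstat)) NA_real_
          else stats::pf(Fstat, p_num, df_den, lower.tail = FALSE)
  structure(list(
    formula = formula,
    response = deparse(formula[[2]]),
    predictors = setdiff(colnames(X), "(Intercept)"),
    coefficients = beta,
    se = se,
    ci_halfwidth = stats::qt(0.975, df_den) * se,
    lambda = lam,
    lambda_ml = lambda_ml,
    r_squared = r2,
    F = Fstat,
    df = c(num = p_num, den = df_den),
    p_value = pval,
    residuals = resid,
    fitted = fitted,
    y = stats::setNames(y, ctx$tips),
    rss = rss,
    tss = tss,
    sigma2 = sigma2,
    log_lik = .pgls_lnl(rss, f$logdet, n),
    n = n
  ), class = "pgls_fit")
}

#' Raw-scale residuals of a PGLS fit
#'
#' Residuals on the original scale (`y - X beta`), id-aligned: the quantity
#' used as the niche-divergence statistic when the fit is family niche width
#' on mean species niche width.
#'
#' @param fit A `pgls_fit`.
#' @return Named numeric vector.
#' @export
pgls_residuals <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$residuals
}

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: %s  (n = %d)\n", deparse(x$formula), x$n))
  cat(sprintf("  lambda = %.4f%s   r2 = %.4f   F(%d,%d) = %.4g   p = %.4g\n",
              x$lambda, if (x$lambda_ml) " (ML)" else " (fixed)",
              x$r_squared, x$df[["num"]], x$df[["den"]], x$F, x$p_value))
  ct <- cbind(Estimate = x$coefficients, SE = x$se,
              `CI95 halfwidth` = x$ci_halfwidth)
  print(signif(ct, 4))
  invisible(x)
}

#' Forward stepwise PGLS predictor selection
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' with the largest partial F statistic, provided its entry p-value is below
#' `alpha_enter`; stops otherwise. The partial F compares the candidate
#' model (lambda re-estimated by ML) with the current model refitted at the
#' candidate model's lambda, in the same whitened space. Rank-deficient
#' additions (e.g. a duplicated column) get partial F = 0 and never enter.
#'
#' @param response Name of the response column in `data`.
#' @param candidates Character vector of candidate predictor columns.
#' @param data Data frame with ids as row names (or an `id` column).
#' @param tree A `phylo` object or [pgls_context()].
#' @param alpha_enter Entry threshold (default 0.05; reported in the output).
#' @return List: `fit` (final [pgls_fit()]; intercept-only if nothing
#'   entered), `selected`, `path` (one row per step: best candidate, partial
#'   F, p, entered flag), `alpha_enter`.
#' @export
forward_stepwise <- function(response, candidates, data, tree,
                             alpha_enter = 0.05) {
  if (length(candidates) < 1L) stop("need at least one candidate predictor")
  ids <- if ("id" %in% names(data) && !anyDuplicated(data$id)) data$id else rownames(data)
  ctx <- if (inherits(tree, "pgls_context")) tree else pgls_context(tree, ids)
  current <- character(0)
  path <- list()
  repeat {
    remaining <- setdiff(candidates, current)
    if (!length(remaining)) break
    stats_tab <- lapply(remaining, function(cand) {
      fml <- stats::as.formula(paste(
        response, "~", paste(c(current, cand), collapse = " + ")))
      full <- tryCatch(pgls_fit(fml, data, ctx), error = function(e) NULL)
      if (is.null(full)) return(c(F = 0, p = 1, lambda = NA_real_))
      red_fml <- stats::as.formula(paste(
        response, "~", if (length(current)) paste(current, collapse = " + ") else "1"))
      red <- pgls_fit(red_fml, data, ctx, lambda = full$lambda)
      df_den <- full$df[["den"]]
      extra <- red$rss - full$rss
      if (extra <= 1e-12 * max(red$rss, 1)) return(c(F = 0, p = 1, lambda = full$lambda))
      Fp <- (extra / 1) / (full$rss / df_den)
      c(F = Fp, p = stats::pf(Fp, 1, df_den, lower.tail = FALSE),
        lambda = full$lambda)
    })
    Fs <- vapply(stats_tab, `[[`, numeric(1), "F")
    i <- which.max(Fs)
    entered <- stats_tab[[i]][["p"]] < alpha_enter
    path[[length(path) + 1L]] <- data.frame(
      step = length(path) + 1L, variable = remaining[i],
      partial_F = Fs[i], p_value = stats_tab[[i]][["p"]],
      entered = entered, stringsAsFactors = FALSE)
    if (!entered) break
    current <- c(current, remaining[i])
  }
  fml <- stats::as.formula(paste(
    response, "~", if (length(current)) paste(current, collapse = " + ") else "1"))
  list(fit = pgls_fit(fml, data, ctx),
       selected = current,
       path = if (length(path)) do.call(rbind, path) else
         data.frame(step = integer(0), variable = character(0),
                    partial_F = numeric(0), p_value = numeric(0),
                    entered = logical(0)),
       alpha_enter = alpha_enter)
}
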
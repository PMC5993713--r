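# Net diversification rates from clade age and richness, and rates of
# climatic niche evolution (Brownian-motion and Pagel's-lambda sigma^2)
# from species trait values on within-clade trees.

#' Method-of-moments net diversification rate for stem groups
#'
#' `r_hat = (1/t) * ln(n * (1 - eps) + eps)` where `n` is extant richness,
#' `t` the stem age (Myr) and `eps` the assumed relative extinction fraction
#' (extinction/speciation). Vectorized over all three arguments.
#'
#' @param n Extant species richness (>= 1).
#' @param t Stem age in Myr (> 0).
#' @param eps Relative extinction fraction in \[0, 1). Conventional values
#'   are 0 (no extinction), 0.45 (intermediate) and 0.9 (high).
#' @return Net diversification rate per lineage per Myr.
#' @examples
#' stem_diversification_rate(10, 41.65, 0)     # ln(10)/41.65
#' stem_diversification_rate(10, 41.65, 0.45)  # ln(5.95)/41.65
#' @export
stem_diversification_rate <- function(n, t, eps = 0.45) {
  if (any(n < 1)) stop("richness n must be >= 1")
  if (any(t <= 0)) stop("stem age t must be positive")
  if (any(eps < 0 | eps >= 1)) stop("eps must lie in [0, 1)")
  log(n * (1 - eps) + eps) / t
}

# log-likelihood machinery shared by the BM and lambda fits: multivariate
# normal with mean mu * 1 and covariance sigma2 * C, mu and sigma2 profiled.
.bm_profile <- function(x, C) {
  n <- length(x)
  R <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is singular: ", conditionMessage(e)))
  logdet <- 2 * sum(log(diag(R)))
  w1 <- backsolve(R, rep(1, n), transpose = TRUE)
  wx <- backsolve(R, x, transpose = TRUE)
  mu <- sum(w1 * wx) / sum(w1 * w1)
  q <- sum((wx - mu * w1)^2)
  sigma2 <- q / n
  lnl <- if (sigma2 <= 0) Inf else
    -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(mu = mu, sigma2 = sigma2, lnl = lnl, logdet = logdet)
}

#' Maximum-likelihood Brownian-motion rate of trait evolution
#'
#' Fits the single-rate BM model to tip values: the trait vector is
#' multivariate normal with mean `mu * 1` and covariance `sigma2 * C`, where
#' `C` is the phylogenetic covariance of the tree. Both parameters are ML
#' estimates (`sigma2` divides by N, so the familiar (N-1)/N downward bias
#' relative to REML is expected and documented).
#'
#' @param tree A `phylo` object with >= 2 tips. A root edge, if present, is
#'   ignored (standard comparative-methods convention).
#' @param x Named numeric vector of tip values (names = tip labels).
#' @return List with class `rate_estimate`: `sigma2`, `mu`, `lnl`, `lambda`
#'   (fixed at 1 for BM), `model = "BM"`, `n`.
#' @export
bm_sigma2_ml <- function(tree, x) {
  if (ape::Ntip(tree) < 2L) stop("BM rate needs at least 2 tips")
  x <- .align_tip_values(tree, x)
  if (stats::var(x) == 0) {
    warning("constant trait: sigma2 is 0 and the likelihood is degenerate")
    return(structure(list(sigma2 = 0, mu = x[[1]], lnl = NA_real_,
                          lambda = 1, model = "BM", n = length(x)),
                     class = "rate_estimate"))
  }
  C <- ape::vcv(tree)
  p <- .bm_profile(x, C)
  structure(list(sigma2 = p$sigma2, mu = p$mu, lnl = p$lnl,
                 lambda = 1, model = "BM", n = length(x)),
            class = "rate_estimate")
}

.align_tip_values <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree))
      stop("unnamed trait vector of wrong length")
    names(x) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("missing trait value(s) for tip(s): ", paste(miss, collapse = ", "))
  x[tree$tip.label]
}

# lambda transform: multiply off-diagonal entries of C by lambda
.lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Maximum-likelihood Pagel's-lambda model of trait evolution
#'
#' Joint ML fit of `lambda` in \[0, 1\] (multiplier on the off-diagonal
#' phylogenetic covariance) and the rate `sigma2`, by bounded scalar search
#' (21-point grid pre-scan plus [stats::optimize()], tolerance 1e-8) over
#' the profile likelihood. `lambda = 1` recovers the BM fit exactly, so the
#' maximized log-likelihood is always >= the BM log-likelihood.
#'
#' @param tree A `phylo` object with >= 3 tips.
#' @param x Named numeric vector of tip values.
#' @return List with class `rate_estimate`: `sigma2`, `mu`, `lnl`, `lambda`,
#'   `model = "lambda"`, `n`.
#' @export
lambda_model_fit <- function(tree, x) {
  if (ape::Ntip(tree) < 3L)
    stop("lambda model needs at least 3 tips")
  x <- .align_tip_values(tree, x)
  if (stats::var(x) == 0) {
    warning("constant trait: degenerate likelihood")
    return(structure(list(sigma2 = 0, mu = x[[1]], lnl = NA_real_,
                          lambda = NA_real_, model = "lambda", n = length(x)),
                     class = "rate_estimate"))
  }
  C <- ape::vcv(tree)
  obj <- function(lam) .bm_profile(x, .lambda_transform(C, lam))$lnl
  grid <- seq(0, 1, length.out = 21)
  lnl_grid <- vapply(grid, obj, numeric(1))
  i <- which.max(lnl_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  lam_hat <- grid[i]
  lnl_hat <- lnl_grid[i]
  if (hi > lo) {
    op <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
    if (op$objective > lnl_hat) {
      lam_hat <- op$maximum
      lnl_hat <- op$objective
    }
  }
  # boundary ties resolved toward the boundary value itself
  for (b in c(0, 1)) {
    lb <- obj(b)
    if (lb >= lnl_hat - 1e-10 && lb >= lnl_hat) {
      lam_hat <- b; lnl_hat <- lb
    }
  }
  p <- .bm_profile(x, .lambda_transform(C, lam_hat))
  structure(list(sigma2 = p$sigma2, mu = p$mu, lnl = p$lnl,
                 lambda = lam_hat, model = "lambda", n = length(x)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate estimate (n = %d tips)\n", x$model, x$n))
  cat(sprintf("  sigma2 = %.6g  mu = %.6g  lnL = %.4f", x$sigma2, x$mu, x$lnl))
  if (x$model == "lambda") cat(sprintf("  lambda = %.4f", x$lambda))
  cat("\n")
  invisible(x)
}

# short tag for trait-derived column names: "BIO1_mean" -> "bio1"
.trait_tag <- function(tc) sub("_mean$", "", tolower(tc))

#' Per-family rates of climatic niche evolution
#'
#' Brownian-motion `sigma2` for each family and trait column, computed on
#' the family's subtree of the species-level tree. Families are skipped,
#' with a logged reason, when they have no sampled tips (`not_in_tree`),
#' a single sampled tip (`monospecific`), or are not monophyletic on the
#' sampled tips (`paraphyletic`). Exclusions are applied to the analysis
#' tree, not the membership table.
#'
#' @param tree Species-level `phylo` object.
#' @param membership Data frame (`species_id`, `family_id`).
#' @param traits Data frame with `species_id` and the columns in
#'   `trait_cols` (species means of the climate variables).
#' @param trait_cols Character vector of trait column names
#'   (default `c("BIO1_mean", "BIO12_mean")`).
#' @return Data frame: `family_id`, `n_tips`, `skip_reason` (NA when
#'   computed) and, per trait, `sigma2_<col>` and `lnl_<col>`.
#' @export
family_rates <- function(tree, membership, traits,
                         trait_cols = c("BIO1_mean", "BIO12_mean")) {
  if (!all(c("species_id", "family_id") %in% names(membership)))
    stop("membership must have columns species_id and family_id")
  miss <- setdiff(c("species_id", trait_cols), names(traits))
  if (length(miss)) stop("traits is missing column(s): ", paste(miss, collapse = ", "))
  fams <- unique(membership$family_id)
  rows <- lapply(fams, function(fam) {
    members <- membership$species_id[membership$family_id == fam]
    tips <- intersect(members, tree$tip.label)
    rec <- list(family_id = fam, n_tips = length(tips), skip_reason = NA_character_)
    for (tc in trait_cols) {
      nm <- .trait_tag(tc)
      rec[[paste0("sigma2_", nm)]] <- NA_real_
      rec[[paste0("lnl_", nm)]] <- NA_real_
    }
    if (length(tips) == 0L) { rec$skip_reason <- "not_in_tree"; return(rec) }
    if (length(tips) == 1L) { rec$skip_reason <- "monospecific"; return(rec) }
    if (!is_monophyletic(tree, tips)) { rec$skip_reason <- "paraphyletic"; return(rec) }
    sub <- ape::keep.tip(tree, tips)
    for (tc in trait_cols) {
      xv <- traits[[tc]][match(sub$tip.label, traits$species_id)]
      if (anyNA(xv)) { rec$skip_reason <- "missing_trait"; return(rec) }
      names(xv) <- sub$tip.label
      est <- bm_sigma2_ml(sub, xv)
      nm <- .trait_tag(tc)
      rec[[paste0("sigma2_", nm)]] <- est$sigma2
      rec[[paste0("lnl_", nm)]] <- est$lnl
    }
    rec
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- out$family_id
  out
}
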
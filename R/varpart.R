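# Commonality analysis: decomposition of a full PGLS model's r^2 into
# unique and shared components across predictor blocks, via
# inclusion-exclusion over the r^2 of all block subsets.

#' Variance partitioning over predictor blocks
#'
#' Fits a PGLS model for every non-empty subset of the predictor blocks
#' (2^k - 1 models) and decomposes the full model's `r^2` into commonality
#' components: for each block subset S the commonality coefficient is
#' `C(S) = -sum over T in subsets(S) of (-1)^|T| r2(T union complement(S))`,
#' so that the components sum to the full-model `r^2` identically and the
#' singleton components are the unique contributions
#' `r2(full) - r2(full minus block)`. Negative shared components can occur
#' (suppression) and are reported as computed.
#'
#' @param response Name of the response column in `data`.
#' @param blocks Named list; each element is a character vector of column
#'   names forming one predictor block.
#' @param data Data frame with ids as row names (or an `id` column).
#' @param tree A `phylo` object or [pgls_context()].
#' @return Object of class `varpart`: `components` (data frame: blocks in
#'   the component, commonality value), `unique` (named vector),
#'   `full_r2`, `subset_r2` (named vector over subsets), `full_fit`.
#' @export
variance_partition <- function(response, blocks, data, tree) {
  k <- length(blocks)
  if (k < 2L) stop("need at least 2 predictor blocks")
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be a named list")
  ids <- if ("id" %in% names(data) && !anyDuplicated(data$id)) data$id else rownames(data)
  ctx <- if (inherits(tree, "pgls_context")) tree else pgls_context(tree, ids)
  bnames <- names(blocks)
  subsets <- lapply(1:(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  subset_key <- vapply(subsets, function(s) paste(bnames[s], collapse = ":"),
                       character(1))
  r2 <- numeric(2^k)  # index m + 1; r2[1] = r2 of empty set = 0
  fits <- vector("list", 2^k - 1)
  for (m in 1:(2^k - 1)) {
    cols <- unlist(blocks[subsets[[m]]], use.names = FALSE)
    fml <- stats::as.formula(paste(response, "~", paste(cols, collapse = " + ")))
    fits[[m]] <- pgls_fit(fml, data, ctx)
    r2[m + 1] <- fits[[m]]$r_squared
  }
  full_mask <- 2^k - 1
  comp <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    S <- subsets[[i]]
    Smask <- sum(2^(S - 1))
    comp_mask <- bitwAnd(full_mask, bitwNot(Smask))
    # sum over subsets T of S
    Tsubs <- 0:(2^length(S) - 1)
    val <- 0
    for (tm in Tsubs) {
      Tmask <- sum(2^(S[which(bitwAnd(tm, 2^(0:(length(S) - 1))) > 0)] - 1))
      sz <- sum(bitwAnd(tm, 2^(0:(length(S) - 1))) > 0)
      val <- val + (-1)^sz * r2[bitwOr(Tmask, comp_mask) + 1]
    }
    comp[i] <- -val
  }
  names(comp) <- subset_key
  uniq <- comp[vapply(subsets, length, integer(1)) == 1L]
  names(uniq) <- bnames
  structure(list(
    components = data.frame(component = subset_key,
                            n_blocks = vapply(subsets, length, integer(1)),
                            commonality = comp,
                            stringsAsFactors = FALSE, row.names = NULL),
    unique = uniq,
    full_r2 = r2[full_mask + 1],
    subset_r2 = stats::setNames(r2[-1], subset_key),
    full_fit = fits[[full_mask]]
  ), class = "varpart")
}

#' @export
print.varpart <- function(x, ...) {
  cat(sprintf("Variance partitioning: full-model r2 = %.4f\n", x$full_r2))
  cat("Unique contributions:\n")
  print(round(x$unique, 4))
  shared <- sum(x$components$commonality) - sum(x$unique)
  cat(sprintf("Total shared: %.4f (components sum to %.6f)\n",
              shared, sum(x$components$commonality)))
  invisible(x)
}
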
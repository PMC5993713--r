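# Tree I/O, ages, clade extraction and phylogenetic covariance.
# Trees are ape "phylo" objects throughout; branch lengths in Myr.

#' Read a Newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: branch lengths present and non-negative,
#' unique tip labels, a single root.
#'
#' @param text Newick string (mutually exclusive with `file`).
#' @param file Path to a Newick file.
#' @return An object of class `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  .check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: string could not be parsed")
  validate_phylogeny(tr)
  tr
}

# report the position of the first structural problem before handing to ape
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unmatched ')' at position %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop(sprintf("Newick parse error: missing terminal ';' at position %d",
                 nchar(text)), call. = FALSE)
  invisible(TRUE)
}

#' Validate a phylogeny against the package's invariants
#'
#' Checks for branch lengths, non-negativity, unique tip labels.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, or an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length))
    stop("validation error: tree has no branch lengths")
  if (anyNA(tree$edge.length))
    stop("validation error: missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("validation error: negative branch length(s): ",
         paste(signif(tree$edge.length[tree$edge.length < 0], 4), collapse = ", "))
  if (anyDuplicated(tree$tip.label))
    stop("validation error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return Newick string (invisibly if written to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# node ages (time before present) for every node; requires branch lengths.
# On an ultrametric tree tips have age ~0.
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Total height (root age) of a tree
#' @param tree A `phylo` object.
#' @return Height in branch-length units (Myr).
#' @export
tree_height <- function(tree) max(ape::node.depth.edgelength(tree))

.assert_known_tips <- function(tree, tips) {
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad))
    stop("unknown tip label(s): ", paste(bad, collapse = ", "))
}

#' Test monophyly of a tip set
#'
#' TRUE iff the smallest clade containing `tips` contains no other tips.
#' Singletons and the full tip set are monophyletic by convention.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, tips) {
  tips <- unique(tips)
  .assert_known_tips(tree, tips)
  if (length(tips) <= 1L || length(tips) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Stem age of a clade
#'
#' Age (time before present, on an ultrametric tree) of the start of the
#' branch subtending the smallest clade containing `tips`. Two sister clades
#' therefore share the same stem age. For a single tip this is the age of its
#' parent node.
#'
#' @param tree Ultrametric `phylo` object.
#' @param tips Character vector of tip labels forming a monophyletic group
#'   (or a single tip).
#' @return Stem age in Myr.
#' @export
stem_age <- function(tree, tips) {
  tips <- unique(tips)
  .assert_known_tips(tree, tips)
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stop("stem_age requires an ultrametric tree")
  ages <- node_ages(tree)
  root <- ape::Ntip(tree) + 1L
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
  } else {
    if (!is_monophyletic(tree, tips))
      stop("tip set is not monophyletic; stem age undefined")
    node <- ape::getMRCA(tree, tips)
  }
  if (node == root) {
    if (!is.null(tree$root.edge)) return(ages[root] + tree$root.edge)
    stop("clade spans the whole tree and the tree has no root edge; ",
         "stem age undefined")
  }
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  ages[parent]
}

#' Phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. This is the Brownian-motion trait
#' covariance up to the rate constant, the substrate for PGLS and the BM /
#' lambda likelihoods.
#'
#' @param tree A `phylo` object.
#' @param tips Optional subset of tip labels; the tree is pruned (branch
#'   lengths retained) before the matrix is formed.
#' @return Square numeric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree, tips = NULL) {
  if (!is.null(tips)) {
    tips <- unique(tips)
    if (length(tips) == 0L) stop("empty tip set")
    .assert_known_tips(tree, tips)
    tree <- ape::keep.tip(tree, tips)
  }
  ape::vcv(tree)
}

#' Slice a tree into clades by stem age
#'
#' Cuts an ultrametric tree at `target_age`: along each root-to-tip path the
#' selected clade is the one whose stem age is the smallest value still >=
#' `target_age`. The selected clades are mutually disjoint and cover every
#' tip. When nested clades tie on stem age (zero-length internal branches)
#' the larger, more rootward clade is selected.
#'
#' @param tree Ultrametric `phylo` object.
#' @param target_age Cut age in Myr, strictly less than the tree height.
#' @return A data frame with one row per clade: `clade_id`, `stem_age`,
#'   `crown_age`, `n_tips`, `monospecific`, and a list column `tips`.
#' @export
slice_clades_by_stem_age <- function(tree, target_age) {
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stop("slice_clades_by_stem_age requires an ultrametric tree")
  H <- tree_height(tree)
  if (target_age >= H)
    stop(sprintf("target_age (%.4g) must be smaller than tree height (%.4g)",
                 target_age, H))
  if (target_age <= 0) stop("target_age must be positive")
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  # stem age of node v = age of its parent
  stem_of <- function(v) ages[parent_of[v]]
  # initial selection: crossing edges age[parent] >= target > age[child]
  sel <- tree$edge[, 2][ages[tree$edge[, 1]] >= target_age &
                          ages[tree$edge[, 2]] < target_age]
  # tie walk: while the parent clade has the same stem age, take the parent
  sel <- vapply(sel, function(v) {
    while (parent_of[v] != 0L && parent_of[v] != root &&
           isTRUE(all.equal(stem_of(parent_of[v]), stem_of(v))))
      v <- parent_of[v]
    v
  }, integer(1))
  sel <- unique(sel)
  tips_of <- .tips_under(tree, sel)
  data.frame(
    clade_id = sprintf("clade%03d", seq_along(sel)),
    stem_age = vapply(sel, stem_of, numeric(1)),
    crown_age = ifelse(sel <= ntip, 0, ages[sel]),
    n_tips = lengths(tips_of),
    monospecific = lengths(tips_of) == 1L,
    tips = I(tips_of),
    stringsAsFactors = FALSE
  )
}

# tip labels under each node in `nodes`
.tips_under <- function(tree, nodes) {
  ntip <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  lapply(nodes, function(v) {
    if (v <= ntip) tree$tip.label[v] else tree$tip.label[pp[[v - ntip]]]
  })
}
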
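# Phylogeny input, patristic distances, MNTD and between-assemblage
# nearest-taxon distance.

#' Read a rooted phylogeny from a Newick file
#'
#' Thin validated wrapper around [ape::read.tree()]. Branch lengths are
#' required on every edge (a missing length is an error, never a silent
#' zero), tip labels must be unique, and polytomies are allowed — mega-trees
#' contain many.
#'
#' @param path path to a Newick file containing a single tree.
#' @param tip_names `"as_is"` keeps labels untouched, `"underscores"`
#'   replaces spaces with underscores, `"spaces"` the reverse.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path, tip_names = c("as_is", "underscores", "spaces")) {
  tip_names <- match.arg(tip_names)
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick in ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  tree$tip.label <- switch(tip_names,
                           as_is = tree$tip.label,
                           underscores = gsub(" ", "_", tree$tip.label, fixed = TRUE),
                           spaces = gsub("_", " ", tree$tip.label, fixed = TRUE))
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  bad <- which(is.na(tree$edge.length))
  if (length(bad))
    stop("missing branch length on edge(s) ",
         paste(apply(tree$edge[bad, , drop = FALSE], 1L, paste, collapse = "->"),
               collapse = ", "), call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)", call. = FALSE)
  if (!any(tree$edge.length > 0))
    stop("all branch lengths are zero", call. = FALSE)
  invisible(tree)
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' Dense symmetric matrix of path-length distances between all tip pairs, in
#' branch-length units, computed via [ape::cophenetic.phylo()]. The matrix,
#' not the traversal, is the contract: all nearest-taxon statistics consume
#' it. Dense storage is fine at regional-checklist scale (a few thousand
#' tips).
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Numeric matrix with tip labels as dimnames; zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  ape::cophenetic.phylo(tree)
}

validate_dm <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (is.null(rownames(dm)))
    stop("distance matrix must carry tip labels as dimnames", call. = FALSE)
  invisible(dm)
}

match_labels <- function(dm, taxa, what = "assemblage") {
  idx <- match(taxa, rownames(dm))
  if (anyNA(idx))
    stop(sprintf("%s taxa absent from the distance matrix: %s", what,
                 paste(utils::head(taxa[is.na(idx)], 5L), collapse = ", ")),
         call. = FALSE)
  idx
}

#' Mean nearest taxon distance within an assemblage
#'
#' For each taxon in the assemblage, the patristic distance to its nearest
#' relative *within* the assemblage; MNTD is the mean of these nearest-taxon
#' distances.
#'
#' @param dm patristic matrix from [patristic_matrix()].
#' @param assemblage character vector of at least two tip labels.
#' @return Single numeric, in branch-length units.
#' @export
mntd <- function(dm, assemblage) {
  validate_dm(dm)
  assemblage <- unique(assemblage)
  if (length(assemblage) < 2L)
    stop("MNTD needs an assemblage of at least 2 taxa", call. = FALSE)
  idx <- match_labels(dm, assemblage)
  cpp_mntd(dm, idx)
}

#' Mean nearest taxon distance between two assemblages (comdistnt)
#'
#' Abundance-unweighted: each taxon of `a` is matched to its nearest taxon in
#' `b` and vice versa, and the `|a| + |b|` nearest distances are averaged.
#' A taxon present in both sets contributes distance 0 by default; with
#' `exclude_conspecifics = TRUE` its nearest neighbour is taken over the other
#' set *minus itself*. The default matters for nested assemblages (invasive ⊂
#' naturalized ⊂ alien), where shared species pull the value toward zero.
#'
#' @param dm patristic matrix.
#' @param a,b non-empty character vectors of tip labels.
#' @param exclude_conspecifics drop self-matches of shared taxa.
#' @return Single numeric, in branch-length units. Symmetric in `a`, `b`.
#' @export
comdistnt <- function(dm, a, b, exclude_conspecifics = FALSE) {
  validate_dm(dm)
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("comdistnt needs two non-empty assemblages", call. = FALSE)
  ia <- match_labels(dm, a, "first")
  ib <- match_labels(dm, b, "second")
  sub <- dm[ia, ib, drop = FALSE]
  if (exclude_conspecifics) {
    shared <- intersect(a, b)
    sub[cbind(match(shared, a), match(shared, b))] <- Inf
  }
  da <- apply(sub, 1L, min)
  db <- apply(sub, 2L, min)
  if (any(!is.finite(c(da, db))))
    stop("excluding conspecifics left a taxon with no candidate neighbour",
         call. = FALSE)
  mean(c(da, db))
}

#' Match checklist species names to tree tips
#'
#' Exact match after replacing spaces with underscores (the usual Newick
#' convention). Unmatched species are reported so the caller can drop and
#' log them.
#'
#' @param species character vector of checklist species names.
#' @param tree a `phylo` object (or a patristic matrix).
#' @return List with `matched` (tip labels, in input order) and `dropped`
#'   (original names without a tip).
#' @export
match_tree_tips <- function(species, tree) {
  tips <- if (inherits(tree, "phylo")) tree$tip.label else rownames(tree)
  key <- gsub(" ", "_", species, fixed = TRUE)
  hit <- key %in% tips
  list(matched = key[hit], dropped = species[!hit])
}
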
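# Brute-force oracles, independent of the package's computation paths:
# patristic distances by per-pair path walking (ape::nodepath), nearest
# taxon statistics by direct enumeration over the oracle matrix, and the
# exhaustive null by listing every same-richness subset.

oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  m <- max(tree$edge)
  adj <- vector("list", m)   # undirected weighted adjacency over tree edges
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  walk_from <- function(src) {  # breadth-first walk; a tree has unique paths
    d <- rep(NA_real_, m); d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1L]
        if (is.na(d[u])) { d[u] <- d[v] + adj[[v]][r, 2L]; queue <- c(queue, u) }
      }
    }
    d
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) d[i, ] <- walk_from(i)[seq_len(n)]
  d
}

oracle_mntd <- function(d, taxa) {
  vals <- vapply(taxa, function(t) min(d[t, setdiff(taxa, t)]), numeric(1))
  mean(vals)
}

oracle_comdistnt <- function(d, a, b, exclude_conspecifics = FALSE) {
  near <- function(t, other) {
    cand <- if (exclude_conspecifics) setdiff(other, t) else other
    min(d[t, cand])
  }
  mean(c(vapply(a, near, numeric(1), other = b),
         vapply(b, near, numeric(1), other = a)))
}

oracle_nti_exhaustive <- function(d, assemblage, pool) {
  k <- length(assemblage)
  subsets <- utils::combn(pool, k, simplify = FALSE)
  null <- vapply(subsets, function(s) oracle_mntd(d, s), numeric(1))
  obs <- oracle_mntd(d, assemblage)
  list(obs = obs, null_mean = mean(null), null_sd = stats::sd(null),
       nti = -(obs - mean(null)) / stats::sd(null))
}

# Random tree with positive branch lengths and tips A, B, C, ...
random_small_tree <- function(n) {
  tree <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
  tree$tip.label <- LETTERS[seq_len(n)]
  tree
}

# Five-tip and four-tip reference trees used across tests.
tree5 <- function() ape::read.tree(text = "((A:1,B:1):3,((C:1,D:1):1,E:2):2);")
tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# Small hand-built checklist data frame.
toy_checklist_df <- function() {
  data.frame(
    species = c("Aster one", "Aster two", "Aster three", "Poa one",
                "Faba one", "Faba two"),
    family = c("Asteraceae", "Asteraceae", "Asteraceae", "Poaceae",
               "Fabaceae", "Fabaceae"),
    genus = c("Aster", "Aster", "Aster", "Poa", "Faba", "Faba"),
    lifeform = c("annual", "perennial", "biennial", "annual", "woody", "annual"),
    origin = c("America", "America;Europe", "Europe", "tropical Asia",
               "Africa", "unknown"),
    pathway = c("ornamental", "forage", "medicinal", "unintentional",
                "natural", "unknown"),
    status = c("invasive", "naturalized", "casual", "naturalized",
               "casual", "invasive"),
    stringsAsFactors = FALSE)
}

write_checklist_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

# Random checklist with arbitrary statuses for property tests.
random_checklist <- function(n) {
  as_checklist(data.frame(
    species = sprintf("Genus%03d species", seq_len(n)),
    family = sample(c("Asteraceae", "Poaceae", "Fabaceae", "Rosaceae"),
                    n, replace = TRUE),
    genus = sprintf("Genus%03d", seq_len(n)),
    lifeform = sample(alienflora::lifeform_levels, n, replace = TRUE),
    origin = sample(c("America", "Europe", "Africa;Europe", "tropical Asia"),
                    n, replace = TRUE),
    pathway = sample(alienflora::pathway_levels, n, replace = TRUE),
    status = sample(alienflora::status_levels, n, replace = TRUE),
    stringsAsFactors = FALSE))
}
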
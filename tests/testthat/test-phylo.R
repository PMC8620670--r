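write_newick <- function(txt) {
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  f
}

test_that("read_newick parses valid trees and rejects invalid ones", {
  tree <- read_newick(write_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("A", "B", "C", "D"))

  expect_error(read_newick(write_newick("((A:1,A:1):1,(C:1,D:1):1);")),
               "duplicate tip")
  # internal edge lengths absent: an error naming the edge, not silent zeros
  expect_error(read_newick(write_newick("((A:1,B:1),(C:1,D:1));")),
               "branch length")
  expect_error(read_newick(write_newick("((A:1,B:1,(C:1;")), "malformed")
  expect_error(read_newick(tempfile()), "not found")

  f <- write_newick("((Aster_alpinus:1,Aster_amellus:1):1,(C:1,D:1):1);")
  expect_true("Aster alpinus" %in% read_newick(f, tip_names = "spaces")$tip.label)
})

test_that("patristic distances equal hand sums and a naive path-walk oracle", {
  dm <- patristic_matrix(tree4())
  expect_equal(dm["A", "B"], 2)
  expect_equal(dm["A", "C"], 4)
  expect_equal(dm["C", "D"], 2)
  expect_equal(diag(dm), setNames(rep(0, 4), rownames(dm)))
  expect_true(isSymmetric(dm))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  dms <- patristic_matrix(star)
  expect_true(all(dms[upper.tri(dms)] == 2))

  set.seed(42)
  for (i in 1:20) {
    tree <- random_small_tree(sample(4:10, 1))
    expect_equal(patristic_matrix(tree),
                 oracle_patristic(tree)[rownames(patristic_matrix(tree)),
                                        colnames(patristic_matrix(tree))],
                 tolerance = 1e-9)
  }

  # linearity: scaling branch lengths scales every entry
  tree <- random_small_tree(8)
  scaled <- tree; scaled$edge.length <- scaled$edge.length * 3.5
  expect_equal(patristic_matrix(scaled), 3.5 * patristic_matrix(tree),
               tolerance = 1e-12)
})

test_that("MNTD equals nearest-relative enumeration and respects bounds", {
  dm <- patristic_matrix(tree4())
  expect_equal(mntd(dm, c("A", "B")), 2)          # two-taxon case: pair distance
  expect_equal(mntd(dm, c("A", "B", "C")), 8 / 3) # nearest distances 2, 2, 4

  expect_error(mntd(dm, "A"), "at least 2")
  expect_error(mntd(dm, c("A", "Zed")), "absent.*Zed")

  set.seed(7)
  for (i in 1:30) {
    tree <- random_small_tree(sample(4:10, 1))
    dmr <- patristic_matrix(tree)
    taxa <- sample(rownames(dmr), sample(2:nrow(dmr), 1))
    val <- mntd(dmr, taxa)
    expect_equal(val, oracle_mntd(dmr, taxa), tolerance = 1e-9)
    off <- dmr[upper.tri(dmr)]
    expect_gte(val, min(off))
    expect_lte(val, max(off))
    # invariant to tip-label ordering
    expect_equal(mntd(dmr, rev(taxa)), val)
  }
})

test_that("mntd agrees with the picante reference implementation", {
  set.seed(99)
  for (i in 1:10) {
    tree <- random_small_tree(sample(5:10, 1))
    dmr <- patristic_matrix(tree)
    taxa <- sample(rownames(dmr), sample(2:nrow(dmr), 1))
    comm <- matrix(as.integer(rownames(dmr) %in% taxa), nrow = 1,
                   dimnames = list("s", rownames(dmr)))
    expect_equal(mntd(dmr, taxa), picante::mntd(comm, dmr), tolerance = 1e-9)
  }
})

test_that("comdistnt averages nearest cross-assemblage distances symmetrically", {
  dm <- patristic_matrix(tree4())
  expect_equal(comdistnt(dm, c("A", "B"), c("C", "D")), 4)
  # shared taxon contributes 0 when conspecifics included
  expect_equal(comdistnt(dm, c("A", "B"), c("A", "C")), 1.5)
  expect_equal(comdistnt(dm, c("A", "B"), c("A", "B")), 0)
  # excluding conspecifics: A is matched to the other set minus itself
  expect_equal(comdistnt(dm, c("A", "B"), c("A", "C"),
                         exclude_conspecifics = TRUE), 3)
  expect_error(comdistnt(dm, "A", "A", exclude_conspecifics = TRUE),
               "no candidate")
  expect_error(comdistnt(dm, character(0), "A"), "non-empty")

  set.seed(13)
  for (i in 1:30) {
    tree <- random_small_tree(sample(4:10, 1))
    dmr <- patristic_matrix(tree)
    a <- sample(rownames(dmr), sample(1:nrow(dmr), 1))
    b <- sample(rownames(dmr), sample(1:nrow(dmr), 1))
    val <- comdistnt(dmr, a, b)
    expect_equal(val, oracle_comdistnt(dmr, a, b), tolerance = 1e-9)
    expect_equal(comdistnt(dmr, b, a), val)   # symmetry
  }
})

test_that("comdistnt agrees with the picante reference implementation", {
  set.seed(31)
  for (i in 1:10) {
    tree <- random_small_tree(sample(5:10, 1))
    dmr <- patristic_matrix(tree)
    a <- sample(rownames(dmr), sample(2:nrow(dmr), 1))
    b <- sample(rownames(dmr), sample(2:nrow(dmr), 1))
    comm <- rbind(a = as.integer(rownames(dmr) %in% a),
                  b = as.integer(rownames(dmr) %in% b))
    colnames(comm) <- rownames(dmr)
    ref <- as.matrix(picante::comdistnt(comm, dmr))["a", "b"]
    expect_equal(comdistnt(dmr, a, b), unname(ref), tolerance = 1e-9)
  }
})

test_that("branch-length scaling multiplies MNTD and comdistnt by the factor", {
  tree <- random_small_tree(9)
  dm1 <- patristic_matrix(tree)
  tree$edge.length <- tree$edge.length * 7.3
  dm2 <- patristic_matrix(tree)
  taxa <- c("A", "C", "F", "H")
  expect_equal(mntd(dm2, taxa), 7.3 * mntd(dm1, taxa), tolerance = 1e-12)
  expect_equal(comdistnt(dm2, c("A", "B"), c("D", "E")),
               7.3 * comdistnt(dm1, c("A", "B"), c("D", "E")),
               tolerance = 1e-12)
})

test_that("checklist names match tree tips after space-underscore translation", {
  tree <- ape::read.tree(text = "((Aster_alpinus:1,Poa_annua:1):1,Zea_mays:2);")
  m <- match_tree_tips(c("Aster alpinus", "Poa annua", "Missing species"), tree)
  expect_equal(m$matched, c("Aster_alpinus", "Poa_annua"))
  expect_equal(m$dropped, "Missing species")
})
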
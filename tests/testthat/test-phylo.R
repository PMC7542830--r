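test_that("Newick parsing preserves labels and branch lengths", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  depths <- diag(phylo_covariance(tr)$C)
  expect_equal(unname(depths[c("A", "B", "C")]), c(2, 2, 2))

  cherry <- read_newick(text = "(A:1,B:1);")
  expect_equal(ape::Ntip(cherry), 2)

  # round-trip: write then read gives the same distances and labels
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  tr2 <- read_newick(tf)
  expect_equal(tip_distances(tr2)[tr$tip.label, tr$tip.label],
               tip_distances(tr)[tr$tip.label, tr$tip.label])
})

test_that("Newick validation flags duplicates, missing and negative lengths", {
  expect_error(read_newick(text = "((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick(text = "((A,B),C);"), "branch length")
  expect_error(read_newick(text = "((A:1,B:-1):1,C:2);"), "negative")
  # spaces and underscores are interchangeable
  tr <- read_newick(text = "(('Rana temporaria':1,B:1):1,C:2);")
  expect_true("Rana_temporaria" %in% tr$tip.label)
})

test_that("pruning keeps exact path lengths among retained tips", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  pruned <- prune_to_taxa(tr, c("A", "C"))
  expect_setequal(pruned$tip.label, c("A", "C"))
  expect_equal(tip_distances(pruned)["A", "C"], 4)
  expect_equal(unname(diag(phylo_covariance(pruned)$C)), c(2, 2))

  # identity when keeping everything
  expect_equal(prune_to_taxa(tr, tr$tip.label), tr)
  expect_error(prune_to_taxa(tr, c("A", "ZZ")), "ZZ")

  # random tree: all pairwise distances among kept tips unchanged
  big <- random_tree(30, seed = 5)
  keep <- sort(big$tip.label)[1:12]
  sub <- prune_to_taxa(big, keep)
  expect_equal(tip_distances(sub)[keep, keep],
               tip_distances(big)[keep, keep], tolerance = 1e-10)
})

test_that("tip substitution relabels without touching the metric", {
  tr <- random_tree(15, seed = 3)
  expect_equal(substitute_tips(tr, character(0)), tr)

  a <- tr$tip.label[1]; b <- tr$tip.label[2]
  # swap two labels via a temporary name
  s1 <- suppressMessages(substitute_tips(tr, stats::setNames("tmpA", a)))
  s2 <- suppressMessages(substitute_tips(s1, stats::setNames(a, b)))
  s3 <- suppressMessages(substitute_tips(s2, stats::setNames(b, "tmpA")))
  d0 <- tip_distances(tr)
  d1 <- tip_distances(s3)
  others <- setdiff(tr$tip.label, c(a, b))
  # a and b exchanged their distances to every other tip
  expect_equal(d1[a, others], d0[b, others])
  expect_equal(d1[b, others], d0[a, others])
  expect_equal(d1[others, others], d0[others, others])

  expect_error(substitute_tips(tr, stats::setNames("zzz", "not_there")),
               "not in tree")
  expect_error(
    substitute_tips(tr, stats::setNames(tr$tip.label[3], tr$tip.label[1])),
    "duplicate")
})

test_that("grafting adds an exchangeable polytomous sister", {
  cherry <- read_newick(text = "(A:1,B:1);")
  tri <- suppressMessages(graft_polytomy_tip(cherry, "X", "A"))
  expect_setequal(tri$tip.label, c("A", "B", "X"))
  d <- tip_distances(tri)
  expect_equal(d["X", "A"], 2)  # twice the sister's pendant branch
  expect_equal(d["X", "B"], d["A", "B"])

  tr <- random_tree(12, seed = 9)
  d0 <- tip_distances(tr)
  sisters <- tr$tip.label[1:5]
  out <- tr
  for (i in seq_along(sisters)) {
    out <- suppressMessages(
      graft_polytomy_tip(out, paste0("new", i), sisters[i]))
  }
  expect_equal(ape::Ntip(out), 17)
  # pre-existing distances untouched
  expect_equal(tip_distances(out)[tr$tip.label, tr$tip.label], d0,
               tolerance = 1e-10)
  expect_error(suppressMessages(graft_polytomy_tip(tr, "Y", "nope")),
               "sister")
  expect_error(suppressMessages(
    graft_polytomy_tip(tr, tr$tip.label[2], tr$tip.label[1])), "present")
})

test_that("random polytomy resolution is seeded and metric-preserving", {
  tr <- random_tree(8, seed = 1)
  expect_equal(resolve_polytomies(tr, seed = 1), tr)  # already binary

  poly <- read_newick(text = "((A:1,B:1,C:1,D:1):1,E:2);")
  r1 <- resolve_polytomies(poly, seed = 7)
  r2 <- resolve_polytomies(poly, seed = 7)
  expect_true(ape::is.binary(r1))
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
  labs <- poly$tip.label
  expect_equal(tip_distances(r1)[labs, labs], tip_distances(poly)[labs, labs],
               tolerance = 1e-12)
  # the covariance is resolution-invariant
  expect_equal(phylo_covariance(r1)$C[labs, labs],
               phylo_covariance(poly)$C[labs, labs], tolerance = 1e-12)
})

test_that("phylogenetic covariance equals shared ancestor depths", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)$C
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))

  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  Cs <- phylo_covariance(star)$C
  expect_equal(Cs, diag(4) * 1, ignore_attr = TRUE)

  big <- random_tree(20, seed = 11)
  expect_equal(phylo_covariance(big)$C, brute_force_cov(big),
               tolerance = 1e-12)
})

test_that("lambda transform scales off-diagonals only and keeps PD", {
  tr <- random_tree(12, seed = 2)
  cv <- phylo_covariance(tr)
  expect_equal(apply_lambda(cv, 1)$C, cv$C)
  l0 <- apply_lambda(cv, 0)$C
  expect_equal(l0, diag(diag(cv$C)), ignore_attr = TRUE)
  half <- apply_lambda(cv, 0.5)$C
  off <- row(cv$C) != col(cv$C)
  expect_equal(half[off], 0.5 * cv$C[off])
  expect_equal(diag(half), diag(cv$C))
  # linearity in lambda on off-diagonals
  l3 <- apply_lambda(cv, 0.3)$C
  l6 <- apply_lambda(cv, 0.6)$C
  expect_equal(l6[off], 2 * l3[off], tolerance = 1e-12)
  for (lam in c(0, 0.5, 0.99)) {
    expect_gt(min(eigen(apply_lambda(cv, lam)$C)$values), 0)
  }
  expect_error(apply_lambda(cv, 1.2), "lambda")
  expect_error(apply_lambda(cv, -0.1), "lambda")
})
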
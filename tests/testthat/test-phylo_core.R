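test_that("parse_newick reads a hand-readable tree and validates it", {
  tr <- tree3()
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(2, 3))
})

test_that("malformed or invalid Newick is rejected with a useful message", {
  expect_error(parse_newick("((A:1.0,B:1.0):1.0,C:2.0;"),
               "character offset")
  expect_error(parse_newick("((A:1,B:1):1,C:2)"), "';'")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(parse_newick("((A,B),C);"), "branch length")
  expect_error(parse_newick("A;"), "at least 2 tips")
})

test_that("square-bracket comments are stripped and quoted labels kept", {
  tr <- parse_newick("(('A b':1.0[x],B:1.0):1.0,C:2.0);")
  expect_true("A b" %in% tr$tip.label)
})

test_that("Newick round-trip preserves distances to machine precision", {
  tr <- tree3()
  tr2 <- parse_newick(write_newick(tr))
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(tr2)
  expect_equal(d2[rownames(d1), colnames(d1)], d1)

  big <- random_ultrametric_tree(100, seed = 42)
  big2 <- parse_newick(write_newick(big))
  d1 <- ape::cophenetic.phylo(big); d2 <- ape::cophenetic.phylo(big2)
  expect_matrix_equal(d2[rownames(d1), colnames(d1)], d1, tol = 1e-12)
})

test_that("zero-length branches survive a Newick round trip", {
  tr <- resolve_polytomies(parse_newick("(A:1,B:1,C:1);"), seed = 1)
  txt <- write_newick(tr)
  tr2 <- parse_newick(txt)
  d <- ape::cophenetic.phylo(tr2)
  expect_equal(unname(d[d > 0]), rep(2, 6))
})

test_that("resolve_polytomies returns binary trees and preserves distances", {
  tr <- tree3()
  expect_identical(resolve_polytomies(tr, seed = 1), tr)  # already binary

  poly <- parse_newick("(A:1,B:1,C:1);")
  res <- resolve_polytomies(poly, seed = 3)
  expect_true(ape::is.binary(res))
  d <- ape::cophenetic.phylo(res)
  expect_equal(unname(d[upper.tri(d)]), rep(2, 3))

  # collapse internal branches of a random tree into polytomies, then check
  # the induced covariance is unchanged by resolution
  big <- random_ultrametric_tree(50, seed = 9)
  short <- big$edge[, 2L] > ape::Ntip(big) &
    big$edge.length < stats::quantile(big$edge.length, 0.25)
  big$edge.length[short] <- 0
  multi <- ape::di2multi(big, tol = 1e-12)
  expect_false(ape::is.binary(multi))
  res <- resolve_polytomies(multi, seed = 5)
  expect_true(ape::is.binary(res))
  C1 <- vcv_matrix(multi); C2 <- vcv_matrix(res)
  expect_matrix_equal(C2[rownames(C1), colnames(C1)], C1, tol = 1e-9)

  # resolution order is deterministic in the seed
  expect_identical(write_newick(resolve_polytomies(multi, seed = 7)),
                   write_newick(resolve_polytomies(multi, seed = 7)))
})

test_that("vcv_matrix equals hand path sums and is symmetric PSD", {
  C <- vcv_matrix(tree3())
  expect_equal(C["A", "A"], 2); expect_equal(C["B", "B"], 2)
  expect_equal(C["C", "C"], 2); expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0); expect_equal(C["B", "C"], 0)

  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  Cs <- vcv_matrix(star)
  expect_true(all(diag(Cs) > 0))
  expect_equal(max(abs(Cs[upper.tri(Cs)])), 0)

  for (seed in c(1, 2, 3)) {
    tr <- random_rough_tree(20, seed)
    C <- vcv_matrix(tr)
    expect_matrix_equal(C, oracle_vcv(tr), tol = 1e-10)
    expect_matrix_equal(C, t(C), tol = 1e-12)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9 * sum(diag(C)))
  }
})

test_that("ultrametric trees have constant vcv diagonal", {
  tr <- random_ultrametric_tree(40, seed = 4)
  C <- vcv_matrix(tr)
  expect_lt(max(diag(C)) - min(diag(C)), 1e-9 * max(diag(C)))
})

test_that("lambda_transform scales off-diagonals only and composes", {
  C <- vcv_matrix(tree3())
  expect_equal(lambda_transform(C, 1), C)
  C0 <- lambda_transform(C, 0)
  expect_equal(C0, diag(diag(C)), ignore_attr = TRUE)
  Ch <- lambda_transform(C, 0.5)
  expect_equal(Ch["A", "B"], 0.5)
  expect_equal(diag(Ch), diag(C))
  # composition multiplies on off-diagonals
  expect_equal(lambda_transform(lambda_transform(C, 0.6), 0.5),
               lambda_transform(C, 0.3))
  expect_error(lambda_transform(C, 1.2), "lambda")
  expect_error(lambda_transform(C, -0.1), "lambda")
  # PSD is preserved on an ultrametric tree
  tr <- random_ultrametric_tree(30, seed = 8)
  for (lam in c(0, 0.3, 0.9)) {
    ev <- eigen(lambda_transform(vcv_matrix(tr), lam),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9 * ape::Ntip(tr))
  }
})

test_that("is_ultrametric applies a relative tolerance", {
  expect_true(is_ultrametric(tree3()))
  expect_false(is_ultrametric(parse_newick("(A:1,B:2);")))
  tr <- random_ultrametric_tree(20, seed = 2)
  tip_edge <- which(tr$edge[, 2L] == 1L)
  tr$edge.length[tip_edge] <- tr$edge.length[tip_edge] + 1e-12
  expect_true(is_ultrametric(tr, rel_tol = 1e-8))
  expect_false(is_ultrametric(tr, rel_tol = 1e-16))
})
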
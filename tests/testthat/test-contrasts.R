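test_that("contrasts match the hand recursion on the 3-taxon fixture", {
  tr <- tree3()
  cs <- pic_contrasts(tr, c(A = 1, B = 2, C = 4))
  # cherry (A,B): (1 - 2)/sqrt(2); A is the minuend (smaller label)
  cherry <- cs$contrast[cs$node == 5L]
  expect_equal(cherry, -1 / sqrt(2), tolerance = 1e-12)
  # root contrast: node value (1*1 + 1*2)/2 = 1.5 on a lengthened branch
  # 1 + 1*1/2 = 1.5 against C (branch 2): (1.5 - 4)/sqrt(3.5)
  root <- cs$contrast[cs$node == 4L]
  expect_equal(root, (1.5 - 4) / sqrt(3.5), tolerance = 1e-12)
})

test_that("constant traits give all-zero contrasts", {
  tr <- random_ultrametric_tree(20, seed = 1)
  cs <- pic_contrasts(tr, stats::setNames(rep(3, 20), tr$tip.label))
  expect_equal(cs$contrast, rep(0, 19))
})

test_that("a binary n-tip tree yields n-1 finite contrasts matching ape", {
  for (seed in 1:5) {
    n <- c(8, 16, 33, 64, 101)[seed]
    tr <- random_ultrametric_tree(n, seed = seed)
    x <- simulate_trait_bm(tr, lambda = 1, seed = seed + 10)
    cs <- pic_contrasts(tr, x)
    expect_equal(nrow(cs), n - 1L)
    expect_true(all(is.finite(cs$contrast)))
    ref <- ape::pic(x, tr)
    expect_equal(abs(cs$contrast),
                 abs(unname(ref[as.character(cs$node)])), tolerance = 1e-10)
  }
})

test_that("child reordering flips contrast signs but not correlations", {
  tr <- random_ultrametric_tree(24, seed = 7)
  x <- simulate_trait_bm(tr, lambda = 1, seed = 8)
  y <- simulate_trait_bm(tr, lambda = 1, seed = 9)
  r0 <- pearson_pic(pic_contrasts(tr, x), pic_contrasts(tr, y))$r
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))  # re-order children
  rx <- pearson_pic(pic_contrasts(rot, x), pic_contrasts(rot, y))$r
  expect_equal(rx, r0, tolerance = 1e-10)
})

test_that("zero-length sibling branches follow the stated policy", {
  tr <- parse_newick("((A:0,B:0):1,C:2);")
  expect_error(pic_contrasts(tr, c(A = 1, B = 2, C = 3), "error"),
               "zero combined branch length")
  cs <- pic_contrasts(tr, c(A = 1, B = 2, C = 3))
  expect_true(all(is.finite(cs$contrast)))
  expect_equal(attr(cs, "n_jittered"), 1L)
})

test_that("PIC correlation is invariant to the polytomy resolution", {
  poly <- parse_newick("((A:1,B:1,C:1,D:1):1,(E:1.5,F:1.5):0.5);")
  x <- c(A = 0.1, B = 2, C = 1.4, D = -1, E = 3, F = 2.2)
  y <- c(A = 1.0, B = 0.3, C = 0.9, D = 2.1, E = -0.5, F = 0.4)
  rs <- sapply(1:4, function(s) {
    bt <- resolve_polytomies(poly, seed = s)
    pearson_pic(pic_contrasts(bt, x), pic_contrasts(bt, y))$r
  })
  expect_lt(max(rs) - min(rs), 1e-9)
})

test_that("standardized contrasts have unit variance under BM", {
  tr <- random_ultrametric_tree(64, seed = 3)
  msq <- sapply(1:60, function(s) {
    x <- simulate_trait_bm(tr, lambda = 1, sigma2 = 1, seed = 100 + s)
    mean(pic_contrasts(tr, x)$contrast^2)
  })
  expect_equal(mean(msq), 1, tolerance = 0.1)   # Monte-Carlo bound
})

test_that("star-tree PIC correlation approaches the tip correlation", {
  star <- ape::stree(40, "star"); star$edge.length <- rep(1, 40)
  star$tip.label <- paste0("t", 1:40)
  bt <- resolve_polytomies(star, seed = 2)
  diffs <- sapply(1:40, function(s) {
    x <- with_seed(200 + s, rnorm(40)); names(x) <- star$tip.label
    y <- with_seed(300 + s, x * 0.5 + rnorm(40) * sqrt(0.75))
    abs(pearson_pic(pic_contrasts(bt, x), pic_contrasts(bt, y))$r -
          pearson_raw(x, y)$r)
  })
  expect_lt(mean(diffs), 0.12)
})

test_that("pearson_raw matches the closed-form on a printed fixture", {
  x <- c(1.2, 0.7, 2.4, 3.1, 1.9)
  y <- c(0.4, 0.9, 0.2, -0.6, 0.3)
  res <- pearson_raw(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), 3), tolerance = 1e-12)
  expect_equal(res$p_value, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(pearson_raw(x, x)$r, 1)
  expect_error(pearson_raw(x, rep(1, 5)), "zero variance")
})

test_that("pearson_pic identities: self, sign flip, origin-forced slope", {
  u <- c(0.5, -1.2, 0.3, 2.2, -0.4)
  v <- c(0.8, -0.9, 0.1, 1.4, 0.2)
  expect_equal(pearson_pic(u, u)$r, 1)
  expect_equal(pearson_pic(u, -u)$r, -1)
  res <- pearson_pic(u, v)
  expect_equal(res$slope, sum(u * v) / sum(u^2), tolerance = 1e-12)
  expect_equal(res$df, 4L)
  # through-origin slope equals lm with intercept suppressed
  expect_equal(res$slope, unname(coef(stats::lm(v ~ u + 0))[1]),
               tolerance = 1e-10)
  # mismatched node sets are refused
  tr <- random_ultrametric_tree(10, seed = 1)
  tr2 <- random_ultrametric_tree(12, seed = 2)
  a <- pic_contrasts(tr, simulate_trait_bm(tr, seed = 3))
  b <- pic_contrasts(tr2, simulate_trait_bm(tr2, seed = 4))
  expect_error(pearson_pic(a, b), "different trees|node order")
})
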
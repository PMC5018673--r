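test_that("bm_loglik reduces to iid normal density on a unit star tree", {
  star <- parse_newick("(A:1,B:1);")
  C <- vcv_matrix(star)
  expect_equal(bm_loglik(c(0, 0), C, sigma2 = 1, mu = 0),
               -log(2 * pi), tolerance = 1e-12)   # -1.8379
  expect_equal(bm_loglik(c(0, 0), C, sigma2 = 1, mu = 0),
               sum(stats::dnorm(c(0, 0), log = TRUE)), tolerance = 1e-12)
})

test_that("bm_loglik matches a dense multivariate-normal oracle", {
  C <- vcv_matrix(tree3())
  x <- c(A = 1, B = 2, C = 4)[rownames(C)]
  expect_equal(bm_loglik(x, C, sigma2 = 1, mu = 2),
               oracle_mvn_loglik(x, C, 2), tolerance = 1e-10)
  for (seed in 1:5) {
    tr <- random_rough_tree(10, seed)
    Cr <- vcv_matrix(tr)
    xr <- with_seed(seed + 100, rnorm(10, 1, 2))
    expect_equal(bm_loglik(xr, Cr, sigma2 = 1.7, mu = 0.4),
                 oracle_mvn_loglik(xr, 1.7 * Cr, 0.4), tolerance = 1e-8)
  }
})

test_that("bm_loglik obeys the trait-rescaling change of variables", {
  tr <- random_ultrametric_tree(15, seed = 3)
  C <- vcv_matrix(tr)
  x <- with_seed(11, rnorm(15))
  cc <- 4
  ll1 <- bm_loglik(x, C, sigma2 = 2, mu = 0)
  ll2 <- bm_loglik(x / sqrt(cc), C, sigma2 = 2 / cc, mu = 0)
  expect_equal(ll1, ll2 - 15 * log(sqrt(cc)), tolerance = 1e-9)
})

test_that("profile_estimates reduce to sample moments on equal star trees", {
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  x <- c(1, 3, 2, 6)
  fit <- profile_estimates(x, vcv_matrix(star))
  expect_equal(fit$mu, mean(x))
  expect_equal(fit$sigma2, mean((x - mean(x))^2))
})

test_that("profile_estimates match a grid-search oracle", {
  C <- vcv_matrix(tree3())
  x <- c(A = 1, B = 2, C = 4)[rownames(C)]
  fit <- profile_estimates(x, C)
  # oracle: dense grid over (mu, sigma2) with refinement
  mu0 <- mean(x); w <- 4; best <- c(-Inf, NA, NA)
  lw <- log(70); ls0 <- log(1)
  for (round in 1:7) {
    for (m in seq(mu0 - w, mu0 + w, length.out = 41)) {
      for (s in exp(seq(ls0 - lw, ls0 + lw, length.out = 41))) {
        ll <- oracle_mvn_loglik(x, s * C, m)
        if (ll > best[1]) best <- c(ll, m, s)
      }
    }
    mu0 <- best[2]; w <- w / 8; ls0 <- log(best[3]); lw <- lw / 8
  }
  expect_equal(fit$loglik, best[1], tolerance = 1e-5)
  expect_equal(fit$mu, best[2], tolerance = 1e-3)
  expect_equal(fit$sigma2, best[3], tolerance = 1e-3)
  # no (mu, sigma2) on the grid beats the closed form
  expect_gte(fit$loglik + 1e-9, best[1])
})

test_that("constant traits are flagged degenerate with zero rate", {
  C <- vcv_matrix(tree3())
  fit <- profile_estimates(c(2, 2, 2), C)
  expect_true(fit$degenerate)
  expect_equal(fit$sigma2, 0)
})

test_that("lambda is unidentifiable on a star tree", {
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  x <- with_seed(2, rnorm(5))
  f0 <- fit_lambda(star, x, "fixed_zero")
  f1 <- fit_lambda(star, x, "fixed_one")
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-10)
})

test_that("ML lambda recovers Brownian motion on large simulated trees", {
  tr <- random_ultrametric_tree(500, seed = 21)
  x <- simulate_trait_bm(tr, lambda = 1, sigma2 = 0.5, mu = 2, seed = 22)
  fit <- fit_lambda(tr, x, "ml")
  expect_gte(fit$lambda, 0.9)
  expect_lte(fit$lambda, 1)
  expect_equal(fit$k, 3L)
})

test_that("ML loglik dominates both fixed fits and boundary AIC is exact", {
  tr <- random_ultrametric_tree(80, seed = 31)
  for (seed in 1:4) {
    x <- simulate_trait_bm(tr, lambda = c(0, 0.5, 1, 0.8)[seed], seed = seed)
    fits <- lapply(c("ml", "fixed_zero", "fixed_one"),
                   function(m) fit_lambda(tr, x, m))
    expect_gte(fits[[1]]$loglik, fits[[2]]$loglik - 1e-6)
    expect_gte(fits[[1]]$loglik, fits[[3]]$loglik - 1e-6)
    if (fits[[1]]$lambda == 1)
      expect_equal(fits[[1]]$aic, fits[[3]]$aic + 2, tolerance = 1e-8)
    if (fits[[1]]$lambda == 0)
      expect_equal(fits[[1]]$aic, fits[[2]]$aic + 2, tolerance = 1e-8)
  }
})

test_that("fits are scale-equivariant in branch-length units", {
  tr <- random_ultrametric_tree(60, seed = 41)
  x <- simulate_trait_bm(tr, lambda = 0.6, seed = 42)
  f1 <- fit_lambda(tr, x, "ml")
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 10   # Myr -> 10 Myr units
  f2 <- fit_lambda(tr2, x, "ml")
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-5)
  expect_equal(f2$sigma2, f1$sigma2 / 10, tolerance = 1e-5)
  n <- f1$n
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)  # sigma2 absorbs scale
})

test_that("ML lambda agrees with an independent reference implementation", {
  skip_if_not_installed("phytools")
  tr <- random_ultrametric_tree(120, seed = 51)
  x <- simulate_trait_bm(tr, lambda = 0.4, seed = 52)
  fit <- fit_lambda(tr, x, "ml")
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(fit$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(fit$loglik, ref$logL, tolerance = 1e-4)
})

test_that("compare_models follows the best-is-zero sign convention", {
  tr <- random_ultrametric_tree(100, seed = 61)
  x <- simulate_trait_bm(tr, lambda = 0.3, seed = 62)
  cmp <- compare_models(tr, x)
  expect_equal(cmp$table$delta_aic[cmp$table$mode == cmp$best_mode], 0)
  expect_true(all(cmp$table$delta_aic <= 0))
  expect_equal(cmp$table$lambda[cmp$table$mode == "fixed_zero"], 0)
  expect_equal(cmp$table$lambda[cmp$table$mode == "fixed_one"], 1)
  expect_equal(cmp$fits$ml$k, 3L)
  expect_equal(cmp$fits$fixed_one$k, 2L)
})

test_that("iid data on a star tree ties the two fixed models", {
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  x <- with_seed(9, rnorm(6))
  cmp <- compare_models(star, x)
  lls <- cmp$table$loglik
  expect_lt(max(lls) - min(lls), 1e-8)
  expect_true(cmp$best_mode %in% c("fixed_zero", "fixed_one"))
})
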
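# Independent oracles and fixture builders shared across the test files.
# Everything here deliberately avoids the package's Cholesky/backsolve code
# paths: covariances are built by explicit root-to-MRCA path sums and
# likelihoods are evaluated with dense solve()/determinant().

tree3 <- function() parse_newick("((A:1.0,B:1.0):1.0,C:2.0);")

random_ultrametric_tree <- function(n, seed) {
  with_seed(seed, ape::rphylo(n, birth = 0.1, death = 0, fossils = FALSE))
}

random_rough_tree <- function(n, seed) {
  with_seed(seed, ape::rtree(n))   # non-ultrametric, random branch lengths
}

# Tip covariance by explicit path walking: for each tip pair, ascend parent
# pointers to the root and sum the branch lengths of shared edges.
oracle_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  blen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen[tree$edge[, 2L]] <- tree$edge.length
  path_to_root <- function(i) {
    p <- integer(0)
    while (i != root) { p <- c(p, i); i <- parent[i] }
    p
  }
  paths <- lapply(seq_len(n), path_to_root)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- C[j, i] <- sum(blen[shared])
  }
  C
}

# Dense multivariate-normal log-density (no Cholesky).
oracle_mvn_loglik <- function(x, V, mu) {
  n <- length(x)
  r <- x - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(crossprod(r, solve(V, r))))
}

# Brute-force fit of (lambda, mu, sigma2) by enumeration with iterative
# refinement: coarse lambda grid (step 0.01) with a refined (mu, sigma2)
# grid at each lambda, then a fine local lambda sweep around the best point.
oracle_grid_fit <- function(x, C, lambda_step = 0.01) {
  lam_off <- function(lam) { C2 <- C * lam; diag(C2) <- diag(C); C2 }
  n <- length(x)
  # Enumerative search over (mu, sigma2) for a fixed covariance shape:
  # V is factored once with solve()/determinant(), after which the
  # log-likelihood over the grid is plain arithmetic in the quadratic-form
  # coefficients, so the grid can be swept densely and re-narrowed.
  best_mu_sig <- function(V) {
    ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
    Vi1 <- solve(V, rep(1, n)); Vix <- solve(V, x)
    a11 <- sum(Vi1); a1x <- sum(x * Vi1); axx <- sum(x * Vix)
    mu0 <- mean(x); mu_w <- 4 * stats::sd(x) + 1e-3
    ls0 <- log(max(stats::var(x), 1e-8)); lw <- log(300)
    best <- c(-Inf, mu0, exp(ls0))
    for (round in 1:7) {
      mus <- seq(mu0 - mu_w, mu0 + mu_w, length.out = 41L)
      sigs <- exp(seq(ls0 - lw, ls0 + lw, length.out = 41L))
      quad <- axx - 2 * mus * a1x + mus^2 * a11        # q(mu)
      ll <- -0.5 * (n * log(2 * pi) + ld +
                      outer(quad, sigs, function(q, s) n * log(s) + q / s))
      k <- arrayInd(which.max(ll), dim(ll))
      if (max(ll) > best[1L]) best <- c(max(ll), mus[k[1L]], sigs[k[2L]])
      mu0 <- best[2L]; mu_w <- mu_w / 6
      ls0 <- log(best[3L]); lw <- lw / 6
    }
    best
  }
  lams <- seq(0, 1, by = lambda_step)
  lls <- vapply(lams, function(l) best_mu_sig(lam_off(l))[1L], 0.0)
  l0 <- lams[which.max(lls)]
  fine <- seq(max(0, l0 - lambda_step), min(1, l0 + lambda_step),
              by = lambda_step / 20)
  flls <- vapply(fine, function(l) best_mu_sig(lam_off(l))[1L], 0.0)
  k <- which.max(flls)
  list(lambda = fine[k], loglik = flls[k])
}

# Per-node ancestral-state oracle: enumerates candidate values for one
# node's state and maximizes the joint likelihood of (tips, node state),
# with the joint covariance built by explicit path sums over the full tree.
oracle_asr <- function(tree, x, node) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  ntot <- n + tree$Nnode
  parent <- integer(ntot); blen <- numeric(ntot)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen[tree$edge[, 2L]] <- tree$edge.length
  path_to_root <- function(i) {
    p <- integer(0)
    while (i != root) { p <- c(p, i); i <- parent[i] }
    p
  }
  ids <- c(seq_len(n), node)
  paths <- lapply(ids, path_to_root)
  m <- length(ids)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(i)) {
    V[i, j] <- V[j, i] <- sum(blen[intersect(paths[[i]], paths[[j]])])
  }
  Vtt <- V[1:n, 1:n, drop = FALSE]
  ones <- rep(1, n)
  mu <- drop(crossprod(ones, solve(Vtt, x))) /
    drop(crossprod(ones, solve(Vtt, ones)))
  sigma2 <- drop(crossprod(x - mu, solve(Vtt, x - mu))) / n
  Vs <- sigma2 * V
  fit <- list(mu = mu)
  width <- 4 * stats::sd(x) + 1e-3
  center <- mean(x)
  for (round in 1:8) {
    grid <- seq(center - width, center + width, length.out = 41L)
    lls <- vapply(grid, function(a)
      oracle_mvn_loglik(c(x, a), Vs, fit$mu), 0.0)
    center <- grid[which.max(lls)]
    width <- width / 10
  }
  center
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  testthat::expect_lt(max(abs(a - b)), tol)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
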
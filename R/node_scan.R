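#' Maximum-likelihood ancestral state reconstruction under Brownian motion
#'
#' For each internal node the ML estimate of the ancestral value is the GLS
#' estimate given the tips — equivalently the mean obtained by re-rooting the
#' tree at that node, and also the conditional expectation of the node's
#' state given the tip values: `a_hat = mu_hat + C_at C_tt^-1 (x - mu_hat)`,
#' where `C_tt` is the tip covariance, `C_at` the internal-node-by-tip shared
#' path lengths, and `mu_hat` the GLS root mean. The root estimate equals
#' `mu_hat` exactly. The estimates do not depend on sigma2.
#'
#' @param tree A `"phylo"` object with branch lengths (multifurcations
#'   allowed).
#' @param x Named trait vector or vector in tip order.
#' @return Named numeric vector of ancestral estimates, one per internal
#'   node, named by ape node id (`n+1` = root, ...).
#' @export
asr_ml <- function(tree, x) {
  x <- align_trait_vector(tree, x)
  A <- asr_operator(tree)
  drop(A %*% x)
}

#' Linear operator mapping tip values to ML ancestral estimates
#'
#' The BM/GLS ancestral reconstruction is linear in the tip values; this
#' returns the (n_internal x n_tips) matrix `A` with `asr = A %*% x`. Used
#' internally by [asr_ml()] and, crucially, by [permutation_scan()], where
#' reconstructing under thousands of tip randomizations reduces to one
#' matrix product.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Matrix with rownames = internal node ids, colnames = tip labels.
#' @export
asr_operator <- function(tree) {
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  root <- n + 1L
  D <- ape::dist.nodes(tree)
  depth <- D[root, ]
  # shared path length from root for every node pair
  internal <- (n + 1L):ntot
  # C_full[i, j] = (depth_i + depth_j - D[i, j]) / 2
  Ctt <- (outer(depth[1:n], depth[1:n], "+") - D[1:n, 1:n]) / 2
  Cat <- (outer(depth[internal], depth[1:n], "+") - D[internal, 1:n]) / 2
  U <- chol_with_jitter(Ctt)
  ones <- rep(1, n)
  Ci1 <- backsolve(U, backsolve(U, ones, transpose = TRUE))
  w <- Ci1 / sum(Ci1)                       # GLS mean weights: mu_hat = w'x
  B <- t(backsolve(U, backsolve(U, t(Cat), transpose = TRUE)))  # Cat Ctt^-1
  A <- B + (1 - B %*% ones) %*% t(w)        # mu_hat + B (x - mu_hat 1)
  rownames(A) <- as.character(internal)
  colnames(A) <- tree$tip.label
  A
}

#' Tip-randomization significance scan over internal nodes
#'
#' Identifies lineages whose reconstructed ancestral value is unusually high
#' or low for the trait. The observed ML reconstruction at every internal
#' node is compared with the reconstructions obtained after randomly
#' shuffling the trait values across the tips `n_perm` times (the tree is
#' untouched; only the trait-to-tip assignment is permuted, over the tips
#' present in the matched dataset). For each node, `prob_smaller` is the
#' fraction of randomizations whose reconstructed value is strictly below
#' the observed one; ties count as not-smaller, which is conservative at
#' both tails. A node is classified `high` if `prob_smaller > 0.975`, `low`
#' if `prob_smaller < 0.025`, otherwise `ns`. No multiple-testing correction
#' is applied across nodes; the thresholds are per-node.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param x Named trait vector or vector in tip order.
#' @param n_perm Number of tip randomizations (default 1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A data.frame of class `"node_scan"` with columns `node`,
#'   `estimate`, `prob_smaller`, `classification`; attributes `n_perm` and
#'   `seed`.
#' @export
permutation_scan <- function(tree, x, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  x <- align_trait_vector(tree, x)
  n <- length(x)
  A <- asr_operator(tree)
  obs <- drop(A %*% x)
  perm_idx <- with_seed(seed,
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  X <- matrix(x[perm_idx], nrow = n)        # one randomized dataset per column
  R <- A %*% X                              # node x replicate reconstructions
  # reconstructions equal up to BLAS rounding must count as ties, so the
  # strict comparisons carry a small absolute tolerance
  tol <- 1e-9 * max(1, max(abs(obs)))
  prob_smaller <- rowSums(R < obs - tol) / n_perm
  prob_greater <- rowSums(R > obs + tol) / n_perm
  # Strict inequalities on both sides: ties count toward neither tail, so a
  # constant trait (all reconstructions tied) classifies every node "ns".
  # For continuous traits prob_greater = 1 - prob_smaller and the "low" rule
  # reduces to prob_smaller < 0.025.
  cls <- ifelse(prob_smaller > 0.975, "high",
                ifelse(prob_greater > 0.975, "low", "ns"))
  out <- data.frame(node = as.integer(rownames(A)),
                    estimate = unname(obs),
                    prob_smaller = unname(prob_smaller),
                    classification = unname(cls),
                    stringsAsFactors = FALSE)
  structure(out, class = c("node_scan", "data.frame"),
            n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Tabulate a node scan as a lineage report
#'
#' One row per internal node (or per labeled node if `include_all = FALSE`),
#' in tree-traversal (node id) order: lineage name, reconstructed value, the
#' probability that a randomized dataset reconstructs a smaller value, and
#' the high/low/ns classification. Unlabeled nodes get synthetic
#' `node_<id>` identifiers when included.
#'
#' @param scan A `"node_scan"` data.frame from [permutation_scan()].
#' @param labels Optional named character vector mapping node id (as given in
#'   `scan$node`) to a lineage name.
#' @param include_all Include unlabeled nodes with synthetic ids (default
#'   `TRUE`).
#' @return Data.frame with columns `lineage`, `node`, `estimate`,
#'   `prob_smaller`, `classification`.
#' @export
scan_report <- function(scan, labels = NULL, include_all = TRUE) {
  stopifnot(inherits(scan, "node_scan") || is.data.frame(scan))
  out <- as.data.frame(scan)
  out$lineage <- paste0("node_", out$node)
  if (!is.null(labels)) {
    ids <- suppressWarnings(as.integer(names(labels)))
    if (anyNA(ids) || !all(ids %in% out$node))
      stop("labels reference unknown node id(s): ",
           paste(names(labels)[is.na(ids) | !(ids %in% out$node)],
                 collapse = ", "), call. = FALSE)
    out$lineage[match(ids, out$node)] <- unname(labels)
  }
  if (!include_all && !is.null(labels)) {
    out <- out[out$node %in% as.integer(names(labels)), , drop = FALSE]
  }
  out <- out[order(out$node),
             c("lineage", "node", "estimate", "prob_smaller",
               "classification")]
  rownames(out) <- NULL
  out
}

#' Annotate a tree's internal nodes with scan classifications
#'
#' Writes the high/low/ns classification into the tree's internal node
#' labels so the annotated Newick can drive downstream node coloring
#' (e.g. blue for significantly high lineages, red for significantly low
#' ones).
#'
#' @param tree The `"phylo"` object the scan was run on.
#' @param scan A `"node_scan"` data.frame.
#' @return The tree with `node.label` set to the classifications.
#' @export
annotate_tree_with_scan <- function(tree, scan) {
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  lab <- rep("ns", tree$Nnode)
  idx <- scan$node - n
  stopifnot(all(idx >= 1L), all(idx <= tree$Nnode))
  lab[idx] <- scan$classification
  tree$node.label <- lab
  tree
}
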
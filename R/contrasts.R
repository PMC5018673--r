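#' Phylogenetically independent contrasts
#'
#' Felsenstein's recursion on a strictly binary tree, post-order: at each
#' internal node with children i, j carrying (possibly lengthened) branch
#' lengths b_i, b_j and values x_i, x_j, the standardized contrast is
#' `(x_i - x_j) / sqrt(b_i + b_j)`; the node is assigned the branch-length-
#' weighted average value and its own parent branch is lengthened by
#' `b_i * b_j / (b_i + b_j)`. Under Brownian motion the n - 1 contrasts are
#' independent with variance sigma2.
#'
#' Orientation is deterministic: the child whose subtree contains the
#' lexicographically smallest tip label is the minuend. Correlations are
#' orientation-invariant either way.
#'
#' If both child branches at a contrast have length zero (as can happen after
#' zero-length polytomy resolution), the default policy adds
#' `1e-8 * tree depth` to both siblings for that contrast (recorded in the
#' `n_jittered` attribute); with `zero_branch = "error"` it aborts instead.
#'
#' @param tree A strictly binary `"phylo"` object (see
#'   [resolve_polytomies()]).
#' @param x Named trait vector or vector in tip order.
#' @param zero_branch `"jitter"` (default) or `"error"`.
#' @return A data.frame of class `"contrast_set"` with columns `node`
#'   (internal node id in ape numbering) and `contrast`; attributes
#'   `node_values`, `lengthened` and `n_jittered`.
#' @export
pic_contrasts <- function(tree, x, zero_branch = c("jitter", "error")) {
  zero_branch <- match.arg(zero_branch)
  validate_phylogeny(tree)
  if (!ape::is.binary(tree))
    stop("tree must be strictly binary; run resolve_polytomies() first",
         call. = FALSE)
  x <- align_trait_vector(tree, x)
  n <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ntot <- n + nnode
  depth <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-8 * max(depth, 1)

  # branch length above each node (root keeps 0)
  blen <- numeric(ntot)
  blen[tree$edge[, 2L]] <- tree$edge.length
  val <- c(x, numeric(nnode))
  # smallest tip label in each node's subtree, for deterministic orientation
  minlab <- c(tree$tip.label, rep(NA_character_, nnode))

  edge <- ape::reorder.phylo(tree, "postorder")$edge
  parents <- edge[seq(1, nrow(edge), by = 2L), 1L]  # each internal node once
  contrast <- numeric(nnode)
  names(contrast) <- as.character(parents)
  n_jittered <- 0L

  for (r in seq(1, nrow(edge), by = 2L)) {
    node <- edge[r, 1L]
    ch <- edge[c(r, r + 1L), 2L]
    b <- blen[ch]
    if (sum(b) <= 0) {
      if (zero_branch == "error")
        stop("zero combined branch length at node ", node,
             "; use zero_branch = 'jitter' or jitter the tree", call. = FALSE)
      b <- b + eps
      n_jittered <- n_jittered + 1L
    }
    # orient: child subtree containing the lexicographically smaller label
    # is the minuend
    if (minlab[ch[2L]] < minlab[ch[1L]]) ch <- rev(ch); b <- blen[ch]
    if (sum(b) <= 0) b <- b + eps
    contrast[as.character(node)] <- (val[ch[1L]] - val[ch[2L]]) / sqrt(sum(b))
    val[node] <- (b[2L] * val[ch[1L]] + b[1L] * val[ch[2L]]) / sum(b)
    blen[node] <- blen[node] + b[1L] * b[2L] / sum(b)
    minlab[node] <- min(minlab[ch])
  }

  out <- data.frame(node = parents,
                    contrast = unname(contrast[as.character(parents)]))
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contrast_set", "data.frame"),
            node_values = val[(n + 1L):ntot],
            lengthened = blen[(n + 1L):ntot],
            n_jittered = n_jittered)
}

#' Pearson correlation of raw trait values
#'
#' Standard centered Pearson correlation with a two-sided p-value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom, plus the ordinary least-squares slope of y on x.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list of class `"correlation_result"`: `r`, `n_effective`,
#'   `df`, `p_value`, `slope`, `variant = "raw"`.
#' @export
pearson_raw <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  n <- length(x)
  df <- n - 2L
  p <- corr_p_value(r, df)
  slope <- r * stats::sd(y) / stats::sd(x)
  structure(list(r = r, n_effective = n, df = df, p_value = p,
                 slope = slope, variant = "raw"),
            class = "correlation_result")
}

#' Correlation of independent contrasts, forced through the origin
#'
#' Contrasts have arbitrary sign, so their association is measured without
#' centering: `r = sum(u v) / sqrt(sum(u^2) sum(v^2))`, with the best-fit
#' line through the origin (`slope = sum(u v) / sum(u^2)`). The t transform
#' uses one fewer degree of freedom than the number of contrasts (the single
#' fitted parameter is the slope).
#'
#' @param u,v `"contrast_set"` objects from [pic_contrasts()] on the same
#'   tree, or plain numeric contrast vectors of equal length.
#' @return A `"correlation_result"` with `variant = "pic_through_origin"`.
#' @export
pearson_pic <- function(u, v) {
  if (inherits(u, "contrast_set") && inherits(v, "contrast_set")) {
    if (!identical(u$node, v$node))
      stop("contrast sets come from different trees or node orders",
           call. = FALSE)
    u <- u$contrast; v <- v$contrast
  }
  stopifnot(is.numeric(u), is.numeric(v), length(u) == length(v),
            length(u) >= 2L, all(is.finite(u)), all(is.finite(v)))
  su2 <- sum(u^2); sv2 <- sum(v^2)
  if (su2 == 0 || sv2 == 0)
    stop("correlation undefined: all-zero contrasts", call. = FALSE)
  r <- sum(u * v) / sqrt(su2 * sv2)
  n <- length(u)
  df <- n - 1L
  structure(list(r = r, n_effective = n, df = df,
                 p_value = corr_p_value(r, df),
                 slope = sum(u * v) / su2, variant = "pic_through_origin"),
            class = "correlation_result")
}

corr_p_value <- function(r, df) {
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation (%s): r = %.3f, n = %d, p = %.3g\n",
              x$variant, x$r, x$n_effective, x$p_value))
  cat(sprintf("  slope%s = %.4g\n",
              if (x$variant == "pic_through_origin") " (through origin)" else "",
              x$slope))
  invisible(x)
}
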
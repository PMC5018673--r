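#' @importFrom ape read.tree write.tree is.binary multi2di keep.tip
#'   node.depth.edgelength dist.nodes vcv.phylo Ntip Nnode reorder.phylo
#' @importFrom stats optimize pt pf ptukey cor sd var rnorm setNames
#' @importFrom utils read.csv read.delim write.table
NULL

#' Parse a Newick string into a validated phylogeny
#'
#' Trees are represented as `ape` `"phylo"` objects throughout the package.
#' Beyond parsing, this checks the invariants every downstream method relies
#' on: at least two tips, unique non-empty tip labels, branch lengths present
#' on every edge and non-negative. Square-bracket comments are stripped;
#' quoted labels are handled by the Newick reader.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return An object of class `"phylo"`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1.0,B:1.0):1.0,C:2.0);")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)  # strip comments
  check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: reader returned no tree",
                        call. = FALSE)
  tr$tip.label <- gsub("^'(.*)'$|^\"(.*)\"$", "\\1\\2", tr$tip.label)
  validate_phylogeny(tr)
  tr
}

# Cheap structural pre-check so malformed input fails with a character offset
# instead of an opaque reader error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at character offset ",
         nchar(text), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminating ';' at character offset ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Validate the structural invariants of a phylogeny
#'
#' @param tree A `"phylo"` object.
#' @param require_branch_lengths All edges must carry finite, non-negative
#'   lengths (default `TRUE`).
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree, require_branch_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  n <- ape::Ntip(tree)
  if (n < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs)) || anyNA(labs))
    stop("tip labels must be non-empty", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  if (require_branch_lengths) {
    if (is.null(tree$edge.length))
      stop("tree has no branch lengths", call. = FALSE)
    if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
      stop("missing or non-finite branch lengths", call. = FALSE)
    if (any(tree$edge.length < 0))
      stop("negative branch lengths", call. = FALSE)
  }
  # each non-root node has exactly one parent; ape guarantees the edge matrix
  # encodes a tree, but verify no node appears twice as a child
  if (anyDuplicated(tree$edge[, 2L]))
    stop("a node has more than one parent", call. = FALSE)
  invisible(tree)
}

#' Serialize a phylogeny to a Newick string
#'
#' Round-trip stable: parsing the output recovers identical topology, labels
#' and branch lengths to machine precision (branch lengths are written with
#' full double precision).
#'
#' @param tree A `"phylo"` object.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
  validate_phylogeny(tree, require_branch_lengths = !is.null(tree$edge.length))
  ape::write.tree(tree, digits = 17)
}

#' Resolve polytomies into zero-length binary branches
#'
#' All-compatible consensus trees may contain multifurcations, but the
#' contrast recursion and ancestral reconstruction assume a strictly binary
#' tree. Multifurcations are broken into a cascade of zero-length branches,
#' which leaves every tip-to-tip path length — and hence the induced
#' phylogenetic covariance — unchanged. The resolution order is a
#' deterministic function of `seed`.
#'
#' @param tree A `"phylo"` object.
#' @param seed Integer seed controlling the (arbitrary) resolution order.
#' @return A strictly binary `"phylo"` object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  validate_phylogeny(tree)
  if (ape::is.binary(tree)) return(tree)
  out <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  # multi2di inserts NA-length edges on trees with branch lengths in some
  # versions; force them to zero
  if (!is.null(out$edge.length)) out$edge.length[is.na(out$edge.length)] <- 0
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. Under Brownian motion the tip values
#' are multivariate normal with covariance proportional to this matrix.
#' Multifurcating trees are accepted.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
vcv_matrix <- function(tree) {
  validate_phylogeny(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is the Brownian-motion covariance; `lambda = 0`
#' is a star phylogeny (no phylogenetic dependence). For ultrametric trees
#' any `lambda` in \[0, 1\] keeps the matrix positive semi-definite.
#'
#' @param C Covariance matrix from [vcv_matrix()].
#' @param lambda Scalar in \[0, 1\].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a scalar in [0, 1]", call. = FALSE)
  d <- diag(C)
  C2 <- C * lambda
  diag(C2) <- d
  C2
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param rel_tol Maximum allowed spread of root-to-tip distances, relative
#'   to tree depth.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_phylogeny(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(depths)
  if (depth == 0) return(TRUE)
  (max(depths) - min(depths)) < rel_tol * depth
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded operations never perturb surrounding randomness. Used by every
#' stochastic operation in the package.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
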
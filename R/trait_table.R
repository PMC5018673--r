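#' Load a species-level trait table
#'
#' Reads a delimited text file (comma for `.csv`, tab for `.tsv`/`.txt`)
#' with one row per species and columns `genus`, `species`, `range_size`,
#' `abundance`. Missing range or abundance cells are kept as `NA` — species
#' without a plot-based abundance estimate simply have no value, never zero.
#'
#' @param path Path to the delimited file.
#' @return A data.frame of species records.
#' @export
load_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  needed <- c("genus", "species", "range_size", "abundance")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L) stop("species table has no rows", call. = FALSE)
  if (any(!nzchar(raw$genus)) || any(!nzchar(raw$species)))
    stop("empty genus or species name", call. = FALSE)
  num <- function(col) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1L],
           ": '", v[bad[1L]], "'", call. = FALSE)
    neg <- which(!is.na(out) & out <= 0)
    if (length(neg))
      stop("non-positive value in column '", col, "' at data row ", neg[1L],
           call. = FALSE)
    out
  }
  data.frame(genus = raw$genus, species = raw$species,
             range_size = num("range_size"), abundance = num("abundance"),
             stringsAsFactors = FALSE)
}

#' Aggregate species records to genus-level characteristics
#'
#' Species richness is the record count per genus; mean range size and mean
#' abundance are averaged over the constituent species that carry a value.
#' Genera with no abundance estimate for any species get `NA` mean abundance
#' and are later dropped from abundance analyses only (per-trait matching,
#' not listwise deletion).
#'
#' @param records Data.frame from [load_species_table()].
#' @return A genus-level data.frame with columns `genus`, `species_richness`,
#'   `mean_range_size`, `mean_abundance`.
#' @export
aggregate_to_genus <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  stopifnot(all(c("genus", "range_size", "abundance") %in% names(records)))
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sp <- split(records, records$genus)
  out <- data.frame(
    genus            = names(sp),
    species_richness = vapply(sp, nrow, integer(1)),
    mean_range_size  = vapply(sp, function(d) mean_or_na(d$range_size), 0.0),
    mean_abundance   = vapply(sp, function(d) mean_or_na(d$abundance), 0.0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$genus), , drop = FALSE]
}

#' Add log10-transformed characteristics to a genus table
#'
#' All three characteristics are analyzed on the log10 scale. Values must be
#' strictly positive where present; `NA` stays `NA`.
#'
#' @param table Genus-level data.frame (see [aggregate_to_genus()]).
#' @return The table with `log10_species_richness`, `log10_mean_range_size`,
#'   `log10_mean_abundance` columns appended.
#' @export
log10_transform <- function(table) {
  stopifnot(is.data.frame(table), "genus" %in% names(table))
  for (col in c("species_richness", "mean_range_size", "mean_abundance")) {
    if (!col %in% names(table)) next
    v <- table[[col]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop("cannot log10-transform non-positive ", col, " for genus ",
           table$genus[bad[1L]], call. = FALSE)
    table[[paste0("log10_", col)]] <- log10(as.numeric(v))
  }
  table
}

#' Match a phylogeny with a trait vector
#'
#' Restricts the analysis to genera that are both tips of the tree and carry
#' a non-missing value for the chosen trait; the tree is pruned to that set
#' (dangling internal nodes removed, their branch lengths merged, so pairwise
#' distances among retained tips are preserved) and the trait vector is
#' returned in the pruned tree's tip order.
#'
#' @param tree A `"phylo"` object.
#' @param table Genus-level data.frame with a `genus` column.
#' @param trait Name of the trait column to extract.
#' @return List with elements `tree` (pruned phylogeny) and `x` (named
#'   numeric vector aligned to `tree$tip.label`).
#' @export
match_tree_and_traits <- function(tree, table, trait) {
  validate_phylogeny(tree)
  stopifnot(is.data.frame(table), "genus" %in% names(table))
  if (!trait %in% names(table))
    stop("trait column '", trait, "' not found", call. = FALSE)
  vals <- stats::setNames(table[[trait]], table$genus)
  vals <- vals[!is.na(vals)]
  shared <- intersect(tree$tip.label, names(vals))
  if (length(shared) < 3L)
    stop("insufficient data: only ", length(shared),
         " genera shared between tree and '", trait, "' values (need >= 3)",
         call. = FALSE)
  pruned <- if (length(shared) == ape::Ntip(tree)) tree else
    ape::keep.tip(tree, shared)
  list(tree = pruned, x = vals[pruned$tip.label])
}
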
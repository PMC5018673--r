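#' Run the full genus-level comparative analysis
#'
#' Orchestrates the four analysis stages over a tree, a genus-level trait
#' table and a clade classification: (1) phylogenetic-signal model
#' comparison (Pagel's lambda, AIC) per trait; (2) raw and
#' independent-contrast Pearson correlations for every trait pair (raw
#' below the diagonal, PIC above, mirroring the pairs-plot layout); (3) the
#' tip-randomization node scan per trait, with a lineage report and an
#' annotated Newick tree; (4) one-way ANOVA + Tukey HSD across major
#' clades per trait. Each trait is matched to the tree independently, so
#' per-trait sample sizes differ when values are missing (e.g. abundance).
#'
#' All outputs are plain text (TSV tables, Newick trees, a JSON manifest)
#' and are byte-identical across reruns with the same inputs and seed.
#'
#' @param tree A `"phylo"` object.
#' @param traits Genus-level data.frame with `genus` and
#'   `log10_*` columns (see [log10_transform()]).
#' @param clades Named character vector mapping genus to major clade, or
#'   `NULL` to skip the clade stage.
#' @param out_dir Output directory (created if needed).
#' @param trait_cols Trait columns to analyze.
#' @param n_perm Randomizations for the node scan.
#' @param seed Integer seed (node scan and polytomy resolution).
#' @param stages Character subset of
#'   `c("signal", "correlations", "nodescan", "clades")`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_full_analysis <- function(tree, traits, clades = NULL,
                              out_dir = ".",
                              trait_cols = c("log10_species_richness",
                                             "log10_mean_range_size",
                                             "log10_mean_abundance"),
                              n_perm = 1000L, seed = 1L,
                              stages = c("signal", "correlations",
                                         "nodescan", "clades")) {
  stages <- match.arg(stages, several.ok = TRUE)
  validate_phylogeny(tree)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  results <- list()
  timings <- list()
  matched <- lapply(stats::setNames(trait_cols, trait_cols), function(tc)
    match_tree_and_traits(tree, traits, tc))
  n_per_trait <- vapply(matched, function(m) length(m$x), 0L)

  stage_time <- function(name, expr) {
    s <- Sys.time()
    r <- expr
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    r
  }

  if ("signal" %in% stages) {
    results$signal <- stage_time("signal", {
      out <- lapply(matched, function(m) compare_models(m$tree, m$x))
      for (tc in names(out))
        write_tsv(out[[tc]]$table[, c("model", "lambda", "loglik", "aic",
                                      "delta_aic")],
                  file.path(out_dir, paste0("signal_", tc, ".tsv")))
      out
    })
  }

  if ("correlations" %in% stages) {
    results$correlations <- stage_time("correlations", {
      tab <- correlation_matrix(tree, traits, trait_cols, seed = seed)
      write_tsv(tab, file.path(out_dir, "correlations.tsv"))
      tab
    })
  }

  if ("nodescan" %in% stages) {
    results$nodescan <- stage_time("nodescan", {
      out <- lapply(names(matched), function(tc) {
        m <- matched[[tc]]
        scan <- permutation_scan(m$tree, m$x, n_perm = n_perm, seed = seed)
        rep <- scan_report(scan)
        write_tsv(rep, file.path(out_dir, paste0("nodescan_", tc, ".tsv")))
        ann <- annotate_tree_with_scan(m$tree, scan)
        writeLines(write_newick(ann),
                   file.path(out_dir, paste0("nodescan_", tc, ".nwk")))
        scan
      })
      stats::setNames(out, names(matched))
    })
  }

  if ("clades" %in% stages && !is.null(clades)) {
    results$clades <- stage_time("clades", {
      out <- lapply(stats::setNames(trait_cols, trait_cols), function(tc) {
        v <- traits[[tc]]
        g <- unname(clades[traits$genus])
        an <- one_way_anova(v, g)
        hdr <- data.frame(statistic = c("F", "df_between", "df_within",
                                        "p_value", "r_squared"),
                          value = c(an$F, an$df_between, an$df_within,
                                    an$p_value, an$r_squared))
        write_tsv(hdr, file.path(out_dir, paste0("anova_", tc, ".tsv")))
        write_tsv(an$tukey, file.path(out_dir, paste0("tukey_", tc, ".tsv")))
        an
      })
      out
    })
  }

  manifest <- list(
    package = "amazontraits",
    version = as.character(utils::packageVersion("amazontraits")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    n_perm = as.integer(n_perm),
    n_tips_tree = ape::Ntip(tree),
    n_per_trait = as.list(n_per_trait),
    stages = stages,
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Pairwise raw and PIC correlations among traits
#'
#' For every unordered trait pair: the raw Pearson correlation over genera
#' carrying both traits, and the through-origin PIC correlation on the tree
#' pruned to those genera (polytomies resolved with `seed`).
#'
#' @inheritParams run_full_analysis
#' @return Data.frame with one row per pair and columns `trait_x`,
#'   `trait_y`, `n_raw`, `r_raw`, `p_raw`, `n_contrasts`, `r_pic`, `p_pic`.
#' @export
correlation_matrix <- function(tree, traits,
                               trait_cols = c("log10_species_richness",
                                              "log10_mean_range_size",
                                              "log10_mean_abundance"),
                               seed = 1L) {
  pairs <- utils::combn(trait_cols, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ta <- pairs[1L, j]; tb <- pairs[2L, j]
    keep <- !is.na(traits[[ta]]) & !is.na(traits[[tb]])
    sub <- traits[keep, , drop = FALSE]
    ma <- match_tree_and_traits(tree, sub, ta)
    mb <- match_tree_and_traits(tree, sub, tb)
    raw <- pearson_raw(ma$x, mb$x[names(ma$x)])
    btree <- resolve_polytomies(ma$tree, seed = seed)
    pic_a <- pic_contrasts(btree, ma$x)
    pic_b <- pic_contrasts(btree, mb$x[btree$tip.label])
    pp <- pearson_pic(pic_a, pic_b)
    data.frame(trait_x = ta, trait_y = tb,
               n_raw = raw$n_effective, r_raw = raw$r, p_raw = raw$p_value,
               n_contrasts = pp$n_effective, r_pic = pp$r,
               p_pic = pp$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
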
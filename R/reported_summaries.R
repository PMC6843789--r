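# Worked examples over the published 106-genome Lactobacillus EPS survey
# that this pipeline re-implements at desk scale. The printed integer inputs
# (per-gene protein/family/cluster counts and the strain-level cluster-count
# distribution) are shipped as package data; the functions below recompute
# the survey's derived bookkeeping quantities from them with the same
# formulas the pipeline uses on synthetic runs.

#' Published per-gene family summary of the Lactobacillus EPS survey
#'
#' The printed integer columns of the original survey's essential-gene
#' summary table: per gene, the total protein count, the number of
#' genus-level ("strict") and cross-genus ("loose") families, the number of
#' clusters lacking the gene, the multicopy-cluster count, and the printed
#' (1-decimal) ratio columns for cross-checking.
#'
#' @return data.frame, one row per essential/dispensable gene.
#' @export
eps_survey_summary <- function() {
  path <- system.file("extdata", "lactobacillus_eps_survey_summary.tsv",
                      package = "epsclust")
  read_tsv(path)
}

#' Recompute the survey's ratio columns from its printed integers
#'
#' Applies the diversity-statistic formulas (proteins per strict family,
#' strict families per loose family, each rounded to 1 decimal) to the
#' printed integer inputs.
#'
#' @param summary data.frame from [eps_survey_summary()].
#' @return the input with `proteins_per_family_recomputed` and
#'   `families_per_loose_recomputed` columns added.
#' @export
recompute_survey_ratios <- function(summary = eps_survey_summary()) {
  summary$proteins_per_family_recomputed <-
    round1(summary$n_proteins / summary$n_families)
  summary$families_per_loose_recomputed <-
    round1(summary$n_families / summary$n_loose_families)
  summary
}

#' Cluster-count bookkeeping from the strain-level distribution
#'
#' The survey reports how many strains carry one, two, three or four EPS
#' clusters; the totals follow by arithmetic.
#'
#' @param strains_by_count integer vector: number of strains with 1, 2, 3, 4
#'   clusters.
#' @return list with `n_strains_with_clusters` and `n_clusters`.
#' @export
cluster_count_bookkeeping <- function(strains_by_count = c(65L, 25L, 9L, 1L)) {
  k <- seq_along(strains_by_count)
  list(n_strains_with_clusters = sum(strains_by_count),
       n_clusters = sum(k * strains_by_count))
}

#' Phosphoregulatory-module bookkeeping
#'
#' The survey partitions its clusters by phosphoregulatory-module content:
#' all three genes (epsB, epsC, epsD) present; all three absent; only epsD
#' absent; only epsC absent; exactly one of the three present. The category
#' counts must sum to the cluster total, and the number of clusters lacking
#' epsD follows: every all-absent, epsD-only-absent and single-gene cluster
#' lacks epsD (the single-gene clusters retain epsB or epsC -- forced by the
#' epsD gene total, since epsD is never multicopy: clusters with epsD =
#' number of epsD genes).
#'
#' @param counts named integer vector with elements `all_three`, `none`,
#'   `missing_epsD_only`, `missing_epsC_only`, `single_gene`.
#' @param n_epsD_genes total epsD gene count, for the consistency
#'   cross-check.
#' @return list with `n_clusters`, `n_missing_epsD`, and
#'   `consistent_with_gene_total`.
#' @export
phosphoregulatory_bookkeeping <- function(counts = c(all_three = 95L,
                                                     none = 21L,
                                                     missing_epsD_only = 17L,
                                                     missing_epsC_only = 2L,
                                                     single_gene = 11L),
                                          n_epsD_genes = 97L) {
  needed <- c("all_three", "none", "missing_epsD_only", "missing_epsC_only",
              "single_gene")
  stopifnot(all(needed %in% names(counts)))
  n_clusters <- sum(counts)
  n_missing_epsD <- unname(counts["none"] + counts["missing_epsD_only"] +
                             counts["single_gene"])
  list(n_clusters = n_clusters,
       n_missing_epsD = n_missing_epsD,
       consistent_with_gene_total =
         (n_clusters - n_epsD_genes) == n_missing_epsD)
}
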
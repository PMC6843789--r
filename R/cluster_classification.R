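# Cluster-level classification: generic vs non-generic gene order,
# essential-gene completeness, multicopy tallies, GC deviation from the
# genome background, and transposase adjacency.

.essential_roles <- c(epsE = "EpsE", gt = "GT", wzx = "Wzx", wzy = "Wzy",
                      epsC = "EpsC", epsB = "EpsB")
.dispensable_roles <- c(epsA = "EpsA", epsD = "EpsD")

# member roles in 5'->3' operon order: clusters on the minus strand are
# drawn left-to-right by reversing the feature order
oriented_roles <- function(role_table, strand) {
  rt <- role_table[order(role_table$start), , drop = FALSE]
  if (strand == "-") rt <- rt[rev(seq_len(nrow(rt))), , drop = FALSE]
  rt
}

#' Is a cluster generic?
#'
#' A cluster is generic when, after orienting it 5'->3' (majority-strand
#' convention), its first five non-transposase genes carry the roles EpsA,
#' EpsB, EpsC, EpsD, EpsE in exactly that order. Interleaved transposases are
#' skipped: mobile elements are insertions, not cluster architecture.
#'
#' @param role_table role rows of one cluster (from
#'   [assign_cluster_roles()]).
#' @param strand majority strand of the cluster (`"+"` or `"-"`).
#' @return logical.
#' @export
is_generic <- function(role_table, strand = "+") {
  rt <- oriented_roles(role_table, strand)
  roles <- rt$role[rt$role != "Transposase"]
  length(roles) >= 5 &&
    identical(roles[1:5], c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE"))
}

#' Essential- and dispensable-gene completeness
#'
#' A role counts as present only when carried by at least one non-pseudo,
#' non-truncated gene (pseudogenes and truncated proteins count as missing;
#' set `truncated_as_present` to flip the truncation rule).
#'
#' @param role_table role rows of one cluster.
#' @param truncated_as_present logical.
#' @return list `missing_essential`, `missing_dispensable` (character subsets
#'   of `epsE, gt, wzx, wzy, epsC, epsB` and `epsA, epsD`).
#' @export
completeness <- function(role_table, truncated_as_present = FALSE) {
  ok <- !role_table$is_pseudo
  if (!truncated_as_present) ok <- ok & !role_table$is_truncated
  present <- unique(role_table$role[ok])
  list(missing_essential =
         names(.essential_roles)[!(.essential_roles %in% present)],
       missing_dispensable =
         names(.dispensable_roles)[!(.dispensable_roles %in% present)])
}

#' Per-role GC deviation of a cluster from its genome
#'
#' Pools the nucleotide composition of all member genes of each role and
#' compares it to the whole-record GC.
#'
#' @param role_table role rows of one cluster (with `start`/`end`).
#' @param genome the [genome_record()].
#' @return data.frame `role gene_gc genome_gc delta`.
#' @export
gc_deviation <- function(role_table, genome) {
  genome_gc <- compute_gc(genome$sequence)
  roles <- unique(role_table$role)
  rows <- lapply(roles, function(r) {
    sub <- role_table[role_table$role == r, , drop = FALSE]
    seqs <- substring(genome$sequence, sub$start + 1L, sub$end)
    gene_gc <- compute_gc(paste(seqs, collapse = ""))
    data.frame(role = r, gene_gc = gene_gc, genome_gc = genome_gc,
               delta = gene_gc - genome_gc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Transposase adjacency within a cluster
#'
#' A role is transposase-adjacent when a Transposase-role gene is an
#' immediate feature-order neighbor of (or nested within the span of) a gene
#' of that role. "Adjoining" is fixed to immediate neighbors; no base-pair
#' distance is used.
#'
#' @param role_table role rows of one cluster.
#' @return list with `adjacent_roles` (character set) and `flags` (logical
#'   per gene, feature order).
#' @export
transposase_adjacency <- function(role_table) {
  rt <- role_table[order(role_table$start), , drop = FALSE]
  n <- nrow(rt)
  is_tn <- rt$role == "Transposase"
  flags <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is_tn[i]) next
    if (i > 1 && is_tn[i - 1]) flags[i] <- TRUE
    if (i < n && is_tn[i + 1]) flags[i] <- TRUE
    nested <- is_tn & rt$start >= rt$start[i] & rt$end <= rt$end[i]
    nested[i] <- FALSE
    if (any(nested)) flags[i] <- TRUE
  }
  list(adjacent_roles = unique(rt$role[flags]), flags = flags,
       feature_id = rt$feature_id)
}

#' Full classification of one cluster
#'
#' @param role_table role rows of one cluster.
#' @param genome its [genome_record()].
#' @param strand majority strand.
#' @param cluster_id id carried through.
#' @return list of class `cluster_classification` with `is_generic`,
#'   `missing_essential`, `missing_dispensable`, `multicopy`, `gc_by_role`,
#'   `transposase_adjacent_roles`.
#' @export
classify_cluster <- function(role_table, genome, strand = "+",
                             cluster_id = role_table$cluster_id[1]) {
  comp <- completeness(role_table)
  counts <- table(role_table$role)
  multicopy <- counts[counts >= 2]
  structure(list(
    cluster_id = cluster_id,
    is_generic = is_generic(role_table, strand),
    missing_essential = comp$missing_essential,
    missing_dispensable = comp$missing_dispensable,
    multicopy = stats::setNames(as.integer(multicopy), names(multicopy)),
    gc_by_role = gc_deviation(role_table, genome),
    transposase = transposase_adjacency(role_table)),
    class = "cluster_classification")
}

#' Flatten classifications into one row per cluster
#' @param classifications list of [classify_cluster()] results.
#' @return data.frame.
#' @export
classification_table <- function(classifications) {
  rows <- lapply(classifications, function(cc) {
    data.frame(
      cluster_id = cc$cluster_id,
      is_generic = cc$is_generic,
      missing_essential = paste(cc$missing_essential, collapse = ","),
      missing_dispensable = paste(cc$missing_dispensable, collapse = ","),
      multicopy = paste(sprintf("%s:%d", names(cc$multicopy), cc$multicopy),
                        collapse = ","),
      transposase_adjacent = paste(cc$transposase$adjacent_roles,
                                   collapse = ","),
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(cluster_id = character(), is_generic = logical(),
                      missing_essential = character(),
                      missing_dispensable = character(),
                      multicopy = character(),
                      transposase_adjacent = character()))
  do.call(rbind, rows)
}

#' Run-level classification summary
#'
#' Aggregates per-cluster classifications into the run-level counts: how many
#' clusters lack each essential/dispensable gene, multicopy tallies, mean GC
#' deltas per role, and the proportion of genes of each role with an
#' adjoining transposase.
#'
#' @param classifications list of [classify_cluster()] results.
#' @param role_tables list of per-cluster role tables (same order).
#' @return list (JSON-serializable).
#' @export
summarize_classifications <- function(classifications, role_tables) {
  all_missing <- unlist(lapply(classifications, function(cc)
    c(cc$missing_essential, cc$missing_dispensable)))
  missing_counts <- as.list(table(all_missing))

  n_generic <- sum(vapply(classifications, `[[`, logical(1), "is_generic"))

  gc_all <- do.call(rbind, lapply(classifications, `[[`, "gc_by_role"))
  gc_mean <- if (!is.null(gc_all) && nrow(gc_all)) {
    out <- stats::aggregate(delta ~ role, gc_all, mean)
    stats::setNames(as.list(out$delta), out$role)
  } else list()

  # transposase adjacency proportions per role, over all cluster genes
  flags <- unlist(lapply(classifications, function(cc) cc$transposase$flags))
  roles <- unlist(lapply(classifications, function(cc) {
    rt <- role_tables[[cc$cluster_id]]
    rt[order(rt$start), "role"]
  }))
  tn_prop <- if (length(roles)) {
    tapply(flags, roles, function(x) 100 * mean(x))
  } else numeric(0)

  multicopy_clusters <- lapply(classifications, `[[`, "multicopy")
  roles_multi <- unique(unlist(lapply(multicopy_clusters, names)))
  multicopy_counts <- stats::setNames(lapply(roles_multi, function(r) {
    sum(vapply(multicopy_clusters, function(m) r %in% names(m), logical(1)))
  }), roles_multi)

  list(n_clusters = length(classifications),
       n_generic = n_generic,
       n_non_generic = length(classifications) - n_generic,
       missing_counts = missing_counts,
       multicopy_cluster_counts = multicopy_counts,
       mean_gc_delta_by_role = gc_mean,
       transposase_adjacent_percent_by_role = as.list(tn_prop))
}
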
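# Comparative analysis of detected clusters: family presence/absence matrix,
# agglomerative clustering of cluster profiles (Jaccard distance, average
# linkage -- natural choices for binary profiles; both configurable), group
# cutting, and habitat-sharing partitions over the 7 regions of a
# three-habitat Venn decomposition.

#' Family-by-cluster presence/absence matrix
#'
#' @param families a `family_set` from [build_two_level_families()].
#' @param role_table combined role table mapping `feature_id` to
#'   `cluster_id`.
#' @param level `"strict"` or `"loose"`.
#' @return binary matrix; rows = family ids, columns = cluster ids, both in
#'   lexicographic order. Rows with no member in any cluster are absent by
#'   construction.
#' @export
build_matrix <- function(families, role_table, level = c("strict", "loose")) {
  level <- match.arg(level)
  membership <- families[[level]]
  rt <- role_table[role_table$feature_id %in% names(membership), , drop = FALSE]
  fam <- membership[rt$feature_id]
  clusters <- sort(unique(rt$cluster_id))
  fams <- sort(unique(unname(fam)))
  mat <- matrix(0L, length(fams), length(clusters),
                dimnames = list(fams, clusters))
  mat[cbind(match(fam, fams), match(rt$cluster_id, clusters))] <- 1L
  mat
}

#' Hierarchical clustering of cluster profiles
#'
#' Agglomerative clustering of the matrix columns with Jaccard distance on
#' the presence entries and average linkage. Identical columns merge at
#' height 0. Leaf order is made deterministic by the lexicographic column
#' ordering of [build_matrix()].
#'
#' @param mat presence/absence matrix from [build_matrix()].
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list of class `eps_hcl`: `hclust`, `phylo` (ape tree with branch
#'   lengths), `dist`, `cophenetic`.
#' @export
hcl_clusters <- function(mat, linkage = "average") {
  if (ncol(mat) < 2) stop("need at least 2 clusters to build a tree")
  # lexicographic column order makes tie-breaking order-independent
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- stats::dist(t(mat), method = "binary")   # Jaccard distance on 1-entries
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, phylo = ape::as.phylo(hc), dist = d,
                 cophenetic = stats::cophenetic(hc)),
            class = "eps_hcl")
}

#' Export the dendrogram as Newick
#' @param hcl an `eps_hcl`.
#' @param path output file.
#' @export
write_newick <- function(hcl, path) {
  ape::write.tree(hcl$phylo, file = path)
  invisible(path)
}

#' Cut the dendrogram into k groups
#'
#' @param hcl an `eps_hcl`.
#' @param k number of groups (1..number of leaves).
#' @param habitats optional named habitat vector (by cluster id) for the
#'   per-group composition table.
#' @return list: `groups` (named integer vector) and, with habitats,
#'   `composition` (group x habitat count table).
#' @export
cut_groups <- function(hcl, k, habitats = NULL) {
  n <- length(hcl$hclust$labels)
  if (k > n) stop("k = ", k, " exceeds the number of clusters (", n, ")")
  if (k < 1) stop("k must be >= 1")
  groups <- stats::cutree(hcl$hclust, k = k)
  out <- list(groups = groups)
  if (!is.null(habitats)) {
    out$composition <- table(group = groups,
                             habitat = habitats[names(groups)])
  }
  out
}

.known_habitats <- c("host-adapted", "nomadic", "free-living")

#' The 7 habitat-region keys
#' @noRd
venn_regions <- function() {
  c("host-adapted", "nomadic", "free-living",
    "host-adapted+nomadic", "host-adapted+free-living",
    "nomadic+free-living", "host-adapted+nomadic+free-living")
}

#' Habitat-sharing partition of protein families
#'
#' For each role, every family is placed in one of the 7 regions of the
#' three-habitat Venn decomposition according to the set of habitats its
#' member proteins come from; families whose members all lie in
#' unknown-habitat clusters are excluded (and reported). Multi-member and
#' singleton families are tallied separately.
#'
#' @param families a `family_set`.
#' @param role_table combined role table (`feature_id`, `role`,
#'   `cluster_id`).
#' @param cluster_habitats named habitat vector by cluster id.
#' @param level family level used.
#' @param roles roles analyzed (default: the eight canonical roles; mobile
#'   elements and unclassified genes are not habitat-partitioned).
#' @return list of class `sharing_partition`, one element per role: `regions`
#'   (list of `c(multi, singleton)` counts), `n_families`,
#'   `n_excluded_unknown`.
#' @export
habitat_sharing <- function(families, role_table, cluster_habitats,
                            level = c("strict", "loose"),
                            roles = c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE",
                                      "GT", "Wzx", "Wzy")) {
  level <- match.arg(level)
  membership <- families[[level]]
  rt <- role_table[role_table$feature_id %in% names(membership), , drop = FALSE]
  rt$family <- membership[rt$feature_id]
  rt$habitat <- unname(cluster_habitats[rt$cluster_id])
  out <- lapply(roles, function(r) {
    sub <- rt[rt$role == r, , drop = FALSE]
    fams <- split(sub, sub$family)
    regions <- stats::setNames(
      rep(list(c(multi = 0L, singleton = 0L)), length(venn_regions())),
      venn_regions())
    excluded <- 0L
    for (fm in fams) {
      # canonical region key order: host-adapted, nomadic, free-living
      habs <- .known_habitats[.known_habitats %in% fm$habitat]
      if (!length(habs)) { excluded <- excluded + 1L; next }
      key <- paste(habs, collapse = "+")
      slot <- if (nrow(fm) >= 2) "multi" else "singleton"
      regions[[key]][slot] <- regions[[key]][slot] + 1L
    }
    list(regions = regions, n_families = length(fams),
         n_excluded_unknown = excluded)
  })
  structure(stats::setNames(out, roles), class = "sharing_partition")
}

#' Serialize a sharing partition as JSON
#' @param sharing a `sharing_partition`.
#' @param path output file.
#' @export
write_sharing_json <- function(sharing, path) {
  payload <- lapply(unclass(sharing), function(x) {
    list(regions = lapply(x$regions, as.list),
         n_families = x$n_families,
         n_excluded_unknown = x$n_excluded_unknown)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the presence matrix as TSV and MatrixMarket
#' @param mat presence matrix.
#' @param tsv_path,mtx_path output files (either may be NULL).
#' @export
write_matrix <- function(mat, tsv_path = NULL, mtx_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(family = rownames(mat), mat, check.names = FALSE)
    write_tsv(df, tsv_path)
  }
  if (!is.null(mtx_path)) {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), mtx_path)
  }
  invisible(NULL)
}
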
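# Two-level protein families by Markov clustering (MCL) of the similarity
# graph, plus family diversity statistics. The two identity thresholds
# (35% loose / 50% strict) emulate global-vs-genus-level family hierarchies:
# every strict family is a subset of exactly one loose family by
# construction (strict MCL runs independently inside each loose family).

#' Markov clustering of a similarity graph
#'
#' Builds a column-stochastic transition matrix from identity-weighted edges
#' with self-loops (weight = the node's maximum incident weight, 1 for
#' isolated nodes), then alternates expansion (matrix squaring) and inflation
#' (elementwise power, renormalization), pruning entries below `prune`, until
#' the maximum elementwise change drops below `tol` or `max_iter` iterations
#' (non-convergence yields a warning and the current interpretation).
#' Clusters are the connected attractor systems of the limit matrix; isolated
#' proteins become singletons. Family ids are assigned deterministically in
#' order of each family's lexicographically smallest member.
#'
#' @param edges data.frame with `protein_a`, `protein_b` and a weight column
#'   (`weight`, or `percent_identity` interpreted as weight/100).
#' @param proteins optional character vector of all node ids (to include
#'   isolated nodes).
#' @param inflation inflation exponent, in \[1.2, 6\].
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max elementwise change.
#' @param max_iter iteration cap.
#' @param id_prefix prefix of generated family ids.
#' @return list of class `mcl_result`: `membership` (named by protein),
#'   `families` (list of member vectors by family id), `iterations`,
#'   `converged`.
#' @export
mcl <- function(edges, proteins = NULL, inflation = 2, prune = 1e-5,
                tol = 1e-8, max_iter = 200L, id_prefix = "F") {
  stopifnot(inflation >= 1.2, inflation <= 6)
  nodes <- sort(unique(c(proteins, edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  if (n == 0)
    return(structure(list(membership = stats::setNames(character(0), character(0)),
                          families = list(), iterations = 0L,
                          converged = TRUE), class = "mcl_result"))
  w <- if ("weight" %in% names(edges)) edges$weight else
    edges$percent_identity / 100
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- match(edges$protein_a, nodes); ib <- match(edges$protein_b, nodes)
    for (k in seq_along(ia)) {
      A[ia[k], ib[k]] <- max(A[ia[k], ib[k]], w[k])
      A[ib[k], ia[k]] <- max(A[ib[k], ia[k]], w[k])
    }
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Mexp <- M %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    dead <- cs == 0
    if (any(dead)) {
      Minf[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Minf <- sweep(Minf, 2, cs, "/")
    if (max(abs(Minf - M)) < tol) { M <- Minf; converged <- TRUE; break }
    M <- Minf
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current interpretation")
  g <- igraph::graph_from_adjacency_matrix(M > 0 | t(M) > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  fam_members <- split(nodes, comp)
  ord <- order(vapply(fam_members, min, character(1)))
  fam_members <- fam_members[ord]
  ids <- sprintf("%s%04d", id_prefix, seq_along(fam_members))
  names(fam_members) <- ids
  membership <- stats::setNames(rep(ids, lengths(fam_members)),
                                unlist(fam_members, use.names = FALSE))
  membership <- membership[nodes]
  structure(list(membership = membership, families = fam_members,
                 iterations = it, converged = converged),
            class = "mcl_result")
}

#' Two-level (strict within loose) protein families
#'
#' The loose level clusters the similarity graph at identity >= 35% (coverage
#' >= 50%, inflation 1.5); the strict level re-clusters each loose family on
#' its identity >= 50% sub-edges (inflation 2.0). Strict-within-loose nesting
#' holds by construction.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param params a [scoring_params()] (edge coverage threshold reused).
#' @param loose_identity,strict_identity identity thresholds (percent).
#' @param loose_inflation,strict_inflation MCL inflation per level.
#' @param edges optional precomputed [all_vs_all()] edges at (or below) the
#'   loose threshold.
#' @return list of class `family_set`: `strict`, `loose` (named membership
#'   vectors), `strict_to_loose` map, `edges`.
#' @export
build_two_level_families <- function(proteins, params = scoring_params(),
                                     loose_identity = 35,
                                     strict_identity = 50,
                                     loose_inflation = 1.5,
                                     strict_inflation = 2,
                                     edges = NULL) {
  if (is.null(edges)) {
    p <- params
    p$edge_min_identity <- loose_identity
    edges <- all_vs_all(proteins, p)
  }
  ids <- names(proteins)
  loose <- mcl(edges, proteins = ids, inflation = loose_inflation,
               id_prefix = "LF")
  strict_membership <- stats::setNames(rep(NA_character_, length(ids)), ids)
  strict_to_loose <- character(0)
  k <- 0L
  # deterministic: loose families are already ordered by smallest member
  for (lf in names(loose$families)) {
    members <- loose$families[[lf]]
    sub <- edges[edges$protein_a %in% members & edges$protein_b %in% members &
                   edges$percent_identity >= strict_identity, , drop = FALSE]
    part <- mcl(sub, proteins = members, inflation = strict_inflation,
                id_prefix = "tmp")
    for (fam in part$families) {
      k <- k + 1L
      sid <- sprintf("SF%04d", k)
      strict_membership[fam] <- sid
      strict_to_loose[sid] <- lf
    }
  }
  structure(list(strict = strict_membership, loose = loose$membership,
                 strict_to_loose = strict_to_loose, edges = edges),
            class = "family_set")
}

#' Write the family table TSV
#' @param families a `family_set`.
#' @param path output file.
#' @export
write_family_tsv <- function(families, path) {
  df <- data.frame(protein_id = names(families$strict),
                   strict_family = unname(families$strict),
                   loose_family = unname(families$loose[names(families$strict)]))
  write_tsv(df, path)
}

#' Family diversity statistics per role
#'
#' For each role: protein and family counts at both levels, proteins per
#' strict family, strict per loose family, singleton-family percentage, and
#' the multicopy statistics (for clusters carrying >= 2 copies of the role,
#' the mean copy number and the mean number of distinct strict families those
#' copies fall into -- a copies:families ratio near 1 indicates
#' non-redundant duplicates). Ratio columns are rounded to 1 decimal.
#'
#' @param families a `family_set`.
#' @param role_table combined role table (`feature_id`, `role`,
#'   `cluster_id`); only non-pseudo proteins present in `families` are
#'   counted.
#' @param missing_counts optional named vector: clusters lacking each gene
#'   (from [summarize_classifications()]), merged into the output.
#' @param roles roles to report (default: the eight canonical ones).
#' @return data.frame, one row per role.
#' @export
diversity_stats <- function(families, role_table, missing_counts = NULL,
                            roles = c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE",
                                      "GT", "Wzx", "Wzy")) {
  rt <- role_table[role_table$feature_id %in% names(families$strict), ,
                   drop = FALSE]
  rows <- lapply(roles, function(r) {
    sub <- rt[rt$role == r, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) {
      return(data.frame(role = r, n_proteins = 0L, n_strict_families = 0L,
                        n_loose_families = 0L, proteins_per_strict_family = 0,
                        strict_per_loose = 0, singleton_percent = 0,
                        n_clusters_missing = NA_integer_,
                        n_clusters_multicopy = 0L,
                        mean_copies_when_multicopy = NA_real_,
                        mean_families_when_multicopy = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sf <- families$strict[sub$feature_id]
    lf <- families$loose[sub$feature_id]
    sf_sizes <- table(sf)
    per_cluster <- split(sub$feature_id, sub$cluster_id)
    copies <- lengths(per_cluster)
    multi <- copies >= 2
    mean_fams <- if (any(multi)) {
      mean(vapply(per_cluster[multi], function(ids)
        length(unique(families$strict[ids])), numeric(1)))
    } else NA_real_
    data.frame(
      role = r, n_proteins = n,
      n_strict_families = length(unique(sf)),
      n_loose_families = length(unique(lf)),
      proteins_per_strict_family = round1(n / length(unique(sf))),
      strict_per_loose = round1(length(unique(sf)) / length(unique(lf))),
      singleton_percent = round1(100 * sum(sf_sizes == 1) / length(sf_sizes)),
      n_clusters_missing = NA_integer_,
      n_clusters_multicopy = sum(multi),
      mean_copies_when_multicopy = if (any(multi))
        round(mean(copies[multi]), 2) else NA_real_,
      mean_families_when_multicopy = if (any(multi))
        round(mean_fams, 2) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(missing_counts)) {
    gene_key <- c(EpsA = "epsA", EpsB = "epsB", EpsC = "epsC", EpsD = "epsD",
                  EpsE = "epsE", GT = "gt", Wzx = "wzx", Wzy = "wzy")
    mk <- gene_key[out$role]
    out$n_clusters_missing <-
      as.integer(unlist(missing_counts)[mk])
    out$n_clusters_missing[is.na(out$n_clusters_missing) & !is.na(mk)] <- 0L
  }
  out
}
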
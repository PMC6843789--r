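# EPS gene-cluster discovery: locate seed-gene hits (epsA-E homologs), then
# expand across the genomic neighborhood and merge overlapping expansions.
#
# The neighborhood rule formalizes a manual curation step: a neighbor belongs
# to the cluster when it is homologous to any reference-library protein or its
# annotation matches a curated EPS keyword; extension stops after `max_gap`
# consecutive unrelated genes and unrelated genes are trimmed from both ends.
# Adjacency is feature order, not base-pair distance.

.seed_roles <- c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE")

#' Curated EPS-annotation keywords
#'
#' Product-text keywords that mark a gene as EPS-biosynthesis-related during
#' neighborhood expansion and keyword-based role assignment.
#' @export
eps_keywords <- function() {
  c("glycosyltransferase", "polysaccharide", "flippase", "polymerase",
    "epimerase", "mutase", "dehydratase", "transposase", "acetyltransferase")
}

#' Read a role-tagged reference protein library
#'
#' FASTA headers carry whitespace-separated `key=value` tags after the id:
#' `role` (EpsA..EpsE, GT, Wzx, Wzy, Precursor, Transposase), optional
#' `family` (CAZy-style GT family), `enzyme` (precursor enzyme name) and
#' `seed` (1 marks the protein as a seed query).
#'
#' @param path FASTA file.
#' @return data.frame `id`, `role`, `family`, `enzyme`, `seed`, `seq`.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("no such reference FASTA: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("empty reference library: ", path)
  parse_tag <- function(header, tag) {
    m <- regmatches(header, regexec(paste0("\\b", tag, "=([^ ]+)"), header))[[1]]
    # spaces inside tag values are encoded as underscores in headers
    if (length(m) == 2) gsub("_", " ", m[2]) else NA_character_
  }
  headers <- names(aa)
  data.frame(
    id = vapply(headers, function(h) strsplit(h, "\\s+")[[1]][1], character(1),
                USE.NAMES = FALSE),
    role = vapply(headers, parse_tag, character(1), tag = "role",
                  USE.NAMES = FALSE),
    family = vapply(headers, parse_tag, character(1), tag = "family",
                    USE.NAMES = FALSE),
    enzyme = vapply(headers, parse_tag, character(1), tag = "enzyme",
                    USE.NAMES = FALSE),
    seed = vapply(headers, function(h) identical(parse_tag(h, "seed"), "1"),
                  logical(1), USE.NAMES = FALSE),
    seq = as.character(aa), stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a role-tagged reference library FASTA
#' @param lib data.frame as returned by [read_reference_fasta()].
#' @param path output FASTA.
#' @export
write_reference_fasta <- function(lib, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(lib))) {
    tags <- sprintf("role=%s", lib$role[i])
    if (!is.na(lib$family[i])) tags <- paste(tags, sprintf("family=%s", lib$family[i]))
    if (!is.na(lib$enzyme[i]))
      tags <- paste(tags, sprintf("enzyme=%s", gsub(" ", "_", lib$enzyme[i])))
    if (isTRUE(lib$seed[i])) tags <- paste(tags, "seed=1")
    writeLines(sprintf(">%s %s", lib$id[i], tags), con)
    writeLines(gsub("(.{70})", "\\1\n", lib$seq[i]), con)
  }
  invisible(path)
}

#' Locate seed-gene hits in a genome
#'
#' Aligns every non-pseudo CDS against the seed queries (epsA-E reference
#' proteins) and reports, per passing CDS, the best-scoring seed role.
#'
#' @param genome a [genome_record()].
#' @param ref_lib reference library data.frame; rows with `seed = TRUE` and a
#'   seed role are used as queries.
#' @param params a [scoring_params()].
#' @return data.frame of seed hits (`record_id`, `feature_id`, `seed_role`,
#'   `best_identity`, `best_reference_id`).
#' @export
find_seeds <- function(genome, ref_lib, params = scoring_params()) {
  seeds <- ref_lib[ref_lib$seed & ref_lib$role %in% .seed_roles, , drop = FALSE]
  if (!nrow(seeds)) stop("reference library contains no seed proteins")
  f <- genome$features
  out <- list()
  for (i in seq_len(nrow(f))) {
    if (f$is_pseudo[i] || !nzchar(f$translation[i])) next
    hit <- best_reference_hit(f$translation[i], seeds, params)
    if (!is.null(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        record_id = genome$record_id, feature_id = f$feature_id[i],
        seed_role = hit$role, best_identity = hit$identity,
        best_reference_id = hit$ref_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(record_id = character(), feature_id = character(),
                      seed_role = character(), best_identity = numeric(),
                      best_reference_id = character()))
  do.call(rbind, out)
}

# is feature i of the record EPS-related? (homology to any library protein,
# or curated keyword in the product text); memoised per record in `cache`
eps_related <- function(genome, i, ref_lib, params, cache) {
  key <- as.character(i)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- genome$features
  related <- any(vapply(eps_keywords(), grepl, logical(1),
                        x = tolower(f$product[i]), fixed = TRUE))
  if (!related && !f$is_pseudo[i] && nzchar(f$translation[i])) {
    related <- !is.null(best_reference_hit(f$translation[i], ref_lib, params))
  }
  if (!related && f$is_pseudo[i] && nzchar(f$translation[i])) {
    # pseudogenes are kept in the model; their conceptual translation still
    # counts for neighborhood membership
    related <- !is.null(best_reference_hit(f$translation[i], ref_lib, params))
  }
  assign(key, related, envir = cache)
  related
}

#' Expand a seed hit into a gene cluster
#'
#' Walks left and right from the seed over the record's feature order,
#' including every EPS-related gene; extension stops after `max_gap`
#' consecutive unrelated genes and unrelated genes are trimmed from both
#' ends. Returns `NULL` when the expansion yields fewer than two members.
#'
#' @param genome a [genome_record()].
#' @param seed one row of [find_seeds()] output (or a list with
#'   `feature_id`).
#' @param ref_lib reference library.
#' @param params a [scoring_params()].
#' @param max_gap maximum run of unrelated genes crossed (default 2).
#' @param cache optional environment memoising per-feature relatedness.
#' @return list with `record_id`, `member_ids`, `start`, `end`, `strand`,
#'   `seed_ids`, or `NULL`.
#' @export
expand_cluster <- function(genome, seed, ref_lib, params = scoring_params(),
                           max_gap = 2L, cache = new.env(parent = emptyenv())) {
  f <- genome$features
  idx <- match(seed$feature_id, f$feature_id)
  if (is.na(idx)) stop("seed feature not in genome: ", seed$feature_id)
  related <- function(i) eps_related(genome, i, ref_lib, params, cache)

  lo <- idx; gap <- 0L; i <- idx - 1L
  while (i >= 1L && gap <= max_gap) {
    if (related(i)) { lo <- i; gap <- 0L } else gap <- gap + 1L
    i <- i - 1L
  }
  hi <- idx; gap <- 0L; i <- idx + 1L
  while (i <= nrow(f) && gap <= max_gap) {
    if (related(i)) { hi <- i; gap <- 0L } else gap <- gap + 1L
    i <- i + 1L
  }
  members <- lo:hi
  if (length(members) < 2L) return(NULL)
  strands <- f$strand[members]
  list(record_id = genome$record_id,
       member_ids = f$feature_id[members],
       start = min(f$start[members]), end = max(f$end[members]),
       strand = if (mean(strands == "+") >= 0.5) "+" else "-",
       seed_ids = seed$feature_id)
}

#' Merge overlapping cluster expansions and assign ids
#'
#' Clusters (from one genome record) sharing at least one member are merged;
#' output is sorted by span start. Cluster ids follow
#' `strain.record_id.N`; when a strain carries several clusters they
#' additionally receive letter labels (a, b, c, ...) in genomic order.
#'
#' @param clusters list of [expand_cluster()] results.
#' @param genome the [genome_record()] the clusters came from.
#' @return list of merged clusters, each with `cluster_id` and `label`.
#' @export
merge_and_deduplicate <- function(clusters, genome) {
  clusters <- Filter(Negate(is.null), clusters)
  if (!length(clusters)) return(list())
  n <- length(clusters)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (length(intersect(clusters[[i]]$member_ids,
                         clusters[[j]]$member_ids))) {
      parent[find(j)] <- find(i)
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  merged <- lapply(groups, function(g) {
    ids <- unique(unlist(lapply(clusters[g], `[[`, "member_ids")))
    f <- genome$features
    m <- f[f$feature_id %in% ids, , drop = FALSE]
    strands <- m$strand
    list(record_id = genome$record_id,
         member_ids = m$feature_id,   # feature order (sorted by start)
         start = min(m$start), end = max(m$end),
         strand = if (mean(strands == "+") >= 0.5) "+" else "-",
         seed_ids = unique(unlist(lapply(clusters[g], `[[`, "seed_ids"))))
  })
  merged <- merged[order(vapply(merged, `[[`, numeric(1), "start"))]
  for (k in seq_along(merged)) {
    merged[[k]]$cluster_id <- sprintf("%s.%s.%d", genome$strain,
                                      genome$record_id, k)
  }
  merged
}

#' Detect all EPS clusters in one genome record
#'
#' Convenience wrapper: [find_seeds()], [expand_cluster()] per seed, then
#' [merge_and_deduplicate()].
#'
#' @inheritParams find_seeds
#' @param max_gap see [expand_cluster()].
#' @return list of clusters.
#' @export
detect_clusters <- function(genome, ref_lib, params = scoring_params(),
                            max_gap = 2L) {
  seeds <- find_seeds(genome, ref_lib, params)
  if (!nrow(seeds)) return(list())
  cache <- new.env(parent = emptyenv())
  expansions <- lapply(seq_len(nrow(seeds)), function(i) {
    expand_cluster(genome, seeds[i, ], ref_lib, params, max_gap, cache)
  })
  merge_and_deduplicate(expansions, genome)
}

#' Flatten detected clusters into the cluster table
#'
#' @param clusters list of clusters (possibly from several genomes).
#' @param records named list of `genome_record` keyed by record_id.
#' @return data.frame `cluster_id strain record start end n_genes replicon
#'   strand label`.
#' @export
cluster_table <- function(clusters, records) {
  rows <- lapply(clusters, function(cl) {
    rec <- records[[cl$record_id]]
    data.frame(cluster_id = cl$cluster_id, strain = rec$strain,
               record = cl$record_id, start = cl$start, end = cl$end,
               n_genes = length(cl$member_ids),
               replicon = rec$replicon_kind, strand = cl$strand,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(cluster_id = character(), strain = character(),
                      record = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      replicon = character(), strand = character(),
                      label = character()))
  df <- do.call(rbind, rows)
  # letter labels for strains carrying several clusters, in genomic order
  df <- df[order(df$strain, df$record, df$start), , drop = FALSE]
  df$label <- df$strain
  for (s in unique(df$strain)) {
    i <- which(df$strain == s)
    if (length(i) > 1) df$label[i] <- paste0(s, letters[seq_along(i)])
  }
  rownames(df) <- NULL
  df
}

#' Per-cluster BED line (0-based half-open)
#' @param clusters cluster list.
#' @param path output BED file.
#' @export
write_cluster_bed <- function(clusters, path) {
  lines <- vapply(clusters, function(cl) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", cl$record_id, cl$start, cl$end,
            cl$cluster_id, cl$strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
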
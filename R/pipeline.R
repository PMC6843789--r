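# Pipeline orchestration: run_detect (seed search -> expansion -> roles ->
# topology -> classification) and run_compare (similarity graph -> two-level
# families -> diversity -> presence matrix -> HCL -> habitat sharing), with
# a run manifest recording the configuration and input checksums.

#' Detect, annotate and classify EPS clusters across a set of genomes
#'
#' Stages run in fixed order: seed search, neighborhood expansion, merging,
#' role assignment, membrane topology of flippase/polymerase candidates,
#' cluster classification. Inputs are given either as an in-memory
#' [generate_run()] object or as file paths.
#'
#' @param run a `sim_run` (or a list with `records`, `ref_lib`,
#'   `habitat_table`), or `NULL` when using paths.
#' @param genbank_paths character vector of GenBank files (used when `run`
#'   is NULL).
#' @param reference_fasta,habitat_tsv input paths (used when `run` is NULL).
#' @param params a [scoring_params()].
#' @param max_gap neighborhood-expansion gap (see [expand_cluster()]).
#' @param out_dir optional output directory for the TSV/JSON artifacts.
#' @return list of class `eps_detection`: `clusters` (table), `cluster_list`,
#'   `roles` (combined role table), `role_tables` (per cluster),
#'   `classifications`, `summary`, `topology`, `proteins`, `records`,
#'   `habitat_table`, `cluster_habitats`.
#' @export
run_detect <- function(run = NULL, genbank_paths = NULL,
                       reference_fasta = NULL, habitat_tsv = NULL,
                       params = scoring_params(), max_gap = 2L,
                       out_dir = NULL) {
  if (is.null(run)) {
    if (is.null(genbank_paths) || is.null(reference_fasta) ||
        is.null(habitat_tsv))
      stop("either a sim_run or genbank_paths + reference_fasta + habitat_tsv")
    missing_in <- c(genbank_paths, reference_fasta, habitat_tsv)
    missing_in <- missing_in[!file.exists(missing_in)]
    if (length(missing_in))
      stop("missing input file(s): ", paste(missing_in, collapse = ", "))
    records <- do.call(c, lapply(genbank_paths, read_genbank))
    names(records) <- vapply(records, `[[`, character(1), "record_id")
    ref_lib <- read_reference_fasta(reference_fasta)
    habitat_table <- read_habitat_table(habitat_tsv)
  } else {
    records <- run$records
    ref_lib <- run$ref_lib
    habitat_table <- run$habitat_table
  }

  cluster_list <- list()
  for (rec in records) {
    cluster_list <- c(cluster_list,
                      detect_clusters(rec, ref_lib, params, max_gap))
  }
  clusters_df <- cluster_table(cluster_list, records)

  role_tables <- list()
  classifications <- list()
  proteins <- character(0)
  for (cl in cluster_list) {
    rec <- records[[cl$record_id]]
    rt <- assign_cluster_roles(cl, rec, ref_lib, params)
    role_tables[[cl$cluster_id]] <- rt
    classifications[[cl$cluster_id]] <-
      classify_cluster(rt, rec, cl$strand, cl$cluster_id)
    f <- rec$features
    idx <- match(cl$member_ids, f$feature_id)
    keep <- !f$is_pseudo[idx] & nzchar(f$translation[idx])
    proteins <- c(proteins,
                  stats::setNames(f$translation[idx][keep],
                                  f$feature_id[idx][keep]))
  }
  roles <- if (length(role_tables)) do.call(rbind, role_tables) else
    data.frame()
  rownames(roles) <- NULL

  tm_candidates <- roles[roles$role %in% c("Wzx", "Wzy"), , drop = FALSE]
  topology <- tm_profile_table(proteins[intersect(tm_candidates$feature_id,
                                                  names(proteins))])
  summary <- summarize_classifications(classifications, role_tables)

  cluster_habitats <- stats::setNames(
    habitat_of(habitat_table, clusters_df$strain), clusters_df$cluster_id)

  out <- structure(list(clusters = clusters_df, cluster_list = cluster_list,
                        roles = roles, role_tables = role_tables,
                        classifications = classifications, summary = summary,
                        topology = topology, proteins = proteins,
                        records = records, habitat_table = habitat_table,
                        cluster_habitats = cluster_habitats,
                        ref_lib = ref_lib,
                        params = params, max_gap = max_gap),
                   class = "eps_detection")
  if (!is.null(out_dir)) write_detection(out, out_dir)
  out
}

write_detection <- function(det, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(det$clusters, file.path(out_dir, "clusters.tsv"))
  if (nrow(det$roles))
    write_tsv(det$roles, file.path(out_dir, "roles.tsv"))
  write_tsv(classification_table(det$classifications),
            file.path(out_dir, "classification.tsv"))
  if (nrow(det$topology))
    write_tsv(det$topology, file.path(out_dir, "topology.tsv"))
  jsonlite::write_json(det$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_cluster_bed(det$cluster_list, file.path(out_dir, "clusters.bed"))
  write_manifest(out_dir,
                 list(stage = "detect",
                      params = unclass(det$params), max_gap = det$max_gap,
                      n_records = length(det$records),
                      n_clusters = nrow(det$clusters)),
                 c("clusters.tsv", "classification.tsv", "summary.json"))
  invisible(out_dir)
}

write_manifest <- function(out_dir, config, expected_files) {
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("epsclust")),
                   config = config,
                   outputs = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  missing <- setdiff(expected_files, files)
  if (length(missing))
    stop("declared outputs missing: ", paste(missing, collapse = ", "))
  invisible(manifest)
}

#' Family construction and comparative analysis over a detection
#'
#' Builds the all-vs-all similarity graph of the (non-pseudo) cluster
#' proteins, the two-level MCL families, family-diversity statistics, the
#' family-by-cluster presence matrix, the HCL dendrogram (Jaccard/average),
#' an optional k-group cut, GT family calls, precursor inventories, and the
#' habitat-sharing partition.
#'
#' @param det an `eps_detection` from [run_detect()].
#' @param params a [scoring_params()].
#' @param level family level of the presence matrix / sharing analysis.
#' @param k optional number of HCL groups to cut.
#' @param out_dir optional output directory.
#' @return list of class `eps_comparison`.
#' @export
run_compare <- function(det, params = scoring_params(),
                        level = c("strict", "loose"), k = NULL,
                        out_dir = NULL) {
  level <- match.arg(level)
  families <- build_two_level_families(det$proteins, params)
  stats_df <- diversity_stats(families, det$roles,
                              missing_counts = det$summary$missing_counts)
  mat <- build_matrix(families, det$roles, level)
  hcl <- if (ncol(mat) >= 2) hcl_clusters(mat) else NULL
  groups <- if (!is.null(hcl) && !is.null(k))
    cut_groups(hcl, k, det$cluster_habitats) else NULL
  gt_lib <- det_gt_library(det)
  gt_calls <- classify_gt_table(det$roles, det$proteins, gt_lib, params)
  precursors <- lapply(det$role_tables, inventory_precursors)
  sharing <- habitat_sharing(families, det$roles, det$cluster_habitats,
                             level)
  out <- structure(list(families = families, diversity = stats_df,
                        matrix = mat, hcl = hcl, groups = groups,
                        gt_calls = gt_calls, precursors = precursors,
                        sharing = sharing, level = level, k = k),
                   class = "eps_comparison")
  if (!is.null(out_dir)) write_comparison(out, det, out_dir)
  out
}

# the GT reference rows used for CAZy-style family voting
det_gt_library <- function(det) {
  lib <- det$ref_lib
  if (is.null(lib)) stop("detection carries no GT reference library")
  lib[lib$role == "GT" & !is.na(lib$family), , drop = FALSE]
}

write_comparison <- function(cmp, det, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_family_tsv(cmp$families, file.path(out_dir, "families.tsv"))
  write_edges_tsv(cmp$families$edges, file.path(out_dir, "edges.tsv"))
  write_tsv(cmp$diversity, file.path(out_dir, "diversity.tsv"))
  write_matrix(cmp$matrix, file.path(out_dir, "matrix.tsv"),
               file.path(out_dir, "matrix.mtx"))
  if (!is.null(cmp$hcl)) write_newick(cmp$hcl, file.path(out_dir, "tree.nwk"))
  if (!is.null(cmp$groups)) {
    write_tsv(data.frame(cluster_id = names(cmp$groups$groups),
                         group = unname(cmp$groups$groups),
                         habitat = unname(
                           det$cluster_habitats[names(cmp$groups$groups)])),
              file.path(out_dir, "groups.tsv"))
  }
  if (nrow(cmp$gt_calls))
    write_tsv(cmp$gt_calls, file.path(out_dir, "gt_families.tsv"))
  write_sharing_json(cmp$sharing, file.path(out_dir, "sharing.json"))
  write_manifest(out_dir, list(stage = "compare", level = cmp$level,
                               k = cmp$k),
                 c("families.tsv", "diversity.tsv", "matrix.tsv"))
  invisible(out_dir)
}
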
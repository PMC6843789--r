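# The default synthetic benchmark (20 genomes, seed 42) shared across tests.
# Built lazily and cached for the session: generation + detection + family
# comparison together take about a minute and a half.

.benchmark_cache <- new.env(parent = emptyenv())

benchmark_run <- function() {
  if (is.null(.benchmark_cache$run))
    .benchmark_cache$run <- generate_run(sim_config(n_genomes = 20L,
                                                    seed = 42L))
  .benchmark_cache$run
}

benchmark_detection <- function() {
  if (is.null(.benchmark_cache$det))
    .benchmark_cache$det <- run_detect(benchmark_run())
  .benchmark_cache$det
}

benchmark_comparison <- function() {
  if (is.null(.benchmark_cache$cmp))
    .benchmark_cache$cmp <- run_compare(benchmark_detection(), k = 3)
  .benchmark_cache$cmp
}

# match each detected cluster to the planted cluster it overlaps (if unique)
match_truth_cluster <- function(detected, truth_clusters) {
  hits <- Filter(function(cl) {
    cl$record_id == detected$record_id &&
      length(intersect(cl$member_feature_ids, detected$member_ids)) > 0
  }, truth_clusters)
  if (length(hits) == 1) hits[[1]] else NULL
}

# planted helix counts by feature id across all truth clusters
truth_helix_counts <- function(run) {
  unlist(lapply(run$truth$clusters, function(cl) {
    v <- vapply(cl$genes, function(g) {
      if (is.null(g$n_helices) || is.na(g$n_helices)) NA_integer_
      else as.integer(g$n_helices)
    }, integer(1))
    names(v) <- vapply(cl$genes, `[[`, character(1), "feature_id")
    v[!is.na(v)]
  }))
}
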
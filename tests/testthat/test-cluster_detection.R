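# Seed search, neighborhood expansion, merging, and planted-cluster recovery

test_that("planted clusters are recovered with exact member sets", {
  run <- generate_run(sim_config(n_genomes = 3L, seed = 101L))
  det <- run_detect(run)
  truth <- run$truth$clusters
  seeded <- Filter(function(cl)
    any(cl$roles_5to3 %in% c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE")), truth)
  truth_sets <- lapply(seeded, function(cl) sort(cl$member_feature_ids))
  det_sets <- lapply(det$cluster_list, function(cl) sort(cl$member_ids))
  for (s in truth_sets) {
    expect_true(any(vapply(det_sets, identical, logical(1), s)),
                info = paste("missed planted cluster", s[1]))
  }
  for (s in det_sets) {
    expect_true(any(vapply(truth_sets, identical, logical(1), s)),
                info = paste("spurious cluster around", s[1]))
  }
})

test_that("random genomes without planted clusters yield no seeds", {
  run <- generate_run(sim_config(n_genomes = 2L, seed = 55L))
  set.seed(77)
  # a record of filler genes only
  feats <- list()
  parts <- character(0); pos <- 0L
  for (i in 1:10) {
    p <- random_protein(220)
    d <- back_translate(p, 0.42)
    feats[[i]] <- list(id = sprintf("hk%02d", i), start = pos,
                       end = pos + nchar(d), tr = p)
    parts <- c(parts, d); pos <- pos + nchar(d)
  }
  rec <- genome_record("RND", strain = "X", sequence = paste(parts, collapse = ""),
                       features = gene_features(
                         vapply(feats, `[[`, character(1), "id"),
                         vapply(feats, `[[`, numeric(1), "start"),
                         vapply(feats, `[[`, numeric(1), "end"),
                         rep("+", 10),
                         vapply(feats, `[[`, character(1), "tr"),
                         rep("ribosomal protein", 10), rep(FALSE, 10)))
  expect_equal(nrow(find_seeds(rec, run$ref_lib)), 0)
})

test_that("a feature matching several seed roles yields one hit with the best role", {
  run <- generate_run(sim_config(n_genomes = 2L, seed = 56L))
  seeds <- find_seeds(run$records[[1]], run$ref_lib)
  expect_false(any(duplicated(seeds$feature_id)))
  expect_true(all(seeds$best_identity > 30))
})

test_that("a mid-cluster unrelated gene is crossed when within the gap allowance", {
  run <- generate_run(sim_config(n_genomes = 4L, seed = 77L,
                                 hypothetical_rate = 1))
  det <- run_detect(run)
  # every planted cluster contains its inserted hypothetical gene; exact
  # member recovery shows the gap rule spans it
  truth_sets <- lapply(run$truth$clusters,
                       function(cl) sort(cl$member_feature_ids))
  det_sets <- lapply(det$cluster_list, function(cl) sort(cl$member_ids))
  with_hypo <- Filter(function(cl)
    any(vapply(cl$genes, function(g) g$role == "Other", logical(1)) &
      any(cl$roles_5to3 %in% c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE"))),
    run$truth$clusters)
  expect_gt(length(with_hypo), 0)
  for (cl in with_hypo) {
    s <- sort(cl$member_feature_ids)
    expect_true(any(vapply(det_sets, identical, logical(1), s)))
  }
})

test_that("multiple clusters per strain stay separate and get letter labels", {
  run <- generate_run(sim_config(n_genomes = 2L, seed = 88L,
                                 cluster_count_probs = c(0, 0, 1, 0)))
  det <- run_detect(run)
  expect_equal(nrow(det$clusters), length(run$truth$clusters))
  for (s in unique(det$clusters$strain)) {
    labs <- det$clusters$label[det$clusters$strain == s]
    if (length(labs) > 1) {
      expect_equal(labs, paste0(s, letters[seq_along(labs)]))
    }
  }
})

test_that("overlapping expansions merge to a single cluster; disjoint ones do not", {
  run <- generate_run(sim_config(n_genomes = 2L, seed = 59L))
  rec <- run$records[[1]]
  seeds <- find_seeds(rec, run$ref_lib)
  expansions <- lapply(seq_len(nrow(seeds)), function(i)
    expand_cluster(rec, seeds[i, ], run$ref_lib))
  merged <- merge_and_deduplicate(expansions, rec)
  # seeds inside one planted cluster collapse to one merged cluster per span
  spans <- vapply(merged, function(cl) paste(cl$start, cl$end), character(1))
  expect_false(any(duplicated(spans)))
  # merging is idempotent
  again <- merge_and_deduplicate(merged, rec)
  expect_equal(length(again), length(merged))
})

test_that("detection output is deterministic (byte-identical cluster table)", {
  run <- generate_run(sim_config(n_genomes = 2L, seed = 60L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_detect(run, out_dir = d1)
  run_detect(run, out_dir = d2)
  expect_equal(readLines(file.path(d1, "clusters.tsv")),
               readLines(file.path(d2, "clusters.tsv")))
  expect_equal(readLines(file.path(d1, "roles.tsv")),
               readLines(file.path(d2, "roles.tsv")))
})

test_that("no cluster crosses a replicon boundary", {
  det <- benchmark_detection()
  for (cl in det$cluster_list) {
    rec <- det$records[[cl$record_id]]
    expect_true(all(cl$member_ids %in% rec$features$feature_id))
  }
})
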
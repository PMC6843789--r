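# The synthetic-genome generator and its truth bookkeeping

test_that("mutate_protein applies the exact substitution count", {
  set.seed(50)
  s <- random_protein(100)
  expect_equal(mutate_protein(s, 1.0), s)
  m <- mutate_protein(s, 0.8)
  diff <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(diff, 20)
  expect_equal(nchar(m), 100)
  expect_error(mutate_protein(s, 0.01), "target_identity")
})

test_that("mutant realigned to its reference lands near the target identity", {
  set.seed(51)
  for (t in c(0.9, 0.7, 0.5)) {
    s <- random_protein(200)
    m <- mutate_protein(s, t)
    r <- align_pair(s, m)
    expect_equal(r$percent_identity, 100 * t, tolerance = 3)
  }
})

test_that("indel mode changes length but keeps alignability", {
  set.seed(52)
  s <- random_protein(120)
  m <- mutate_protein(s, 0.9, indels = 3L)
  r <- align_pair(s, m)
  expect_gt(r$percent_identity, 70)
})

test_that("back-translation hits the GC target and round-trips the protein", {
  set.seed(53)
  for (gc in c(0.32, 0.42, 0.55)) {
    p <- random_protein(150)
    d <- back_translate(p, gc)
    expect_equal(compute_gc(d), gc, tolerance = 0.02)
    expect_equal(translate_cds(d), p)
  }
})

test_that("generate_run is byte-deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_run(sim_config(n_genomes = 3L, seed = 9L), out_dir = d1)
  generate_run(sim_config(n_genomes = 3L, seed = 9L), out_dir = d2)
  for (f in list.files(d1)) {
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                 info = f)
  }
  d3 <- withr::local_tempdir()
  generate_run(sim_config(n_genomes = 3L, seed = 10L), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "S001.gbk")),
                         readLines(file.path(d3, "S001.gbk"))))
})

test_that("generated GenBank files parse back to the in-memory records", {
  dir <- withr::local_tempdir()
  run <- generate_run(sim_config(n_genomes = 2L, seed = 11L), out_dir = dir)
  for (strain in run$habitat_table$strain) {
    recs <- read_genbank(file.path(dir, paste0(strain, ".gbk")))
    mem <- Filter(function(r) r$strain == strain, run$records)
    expect_equal(length(recs), length(mem))
    for (i in seq_along(recs)) {
      expect_equal(recs[[i]]$sequence, mem[[i]]$sequence)
      expect_equal(recs[[i]]$features$translation,
                   mem[[i]]$features$translation)
      expect_equal(recs[[i]]$replicon_kind, mem[[i]]$replicon_kind)
    }
  }
  lib <- read_reference_fasta(file.path(dir, "reference.fasta"))
  expect_setequal(unique(lib$role[lib$seed]),
                  c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE"))
  ht <- read_habitat_table(file.path(dir, "habitat.tsv"))
  expect_setequal(ht$strain, run$habitat_table$strain)
})

test_that("strain cluster counts follow the configured distribution", {
  run <- benchmark_run()
  per_strain <- table(factor(
    vapply(run$truth$clusters, `[[`, character(1), "strain"),
    levels = run$habitat_table$strain))
  counts <- table(factor(per_strain, levels = 1:4))
  probs <- run$config$cluster_count_probs
  n <- sum(counts)
  for (k in 1:4) {
    # binomial 95% interval per category
    ci <- stats::qbinom(c(0.025, 0.975), n, probs[k])
    expect_gte(counts[[k]], ci[1])
    expect_lte(counts[[k]], ci[2])
  }
})

test_that("planted gene GC matches its target composition", {
  run <- benchmark_run()
  errs <- c()
  for (cl in run$truth$clusters) {
    rec <- run$records[[cl$record_id]]
    f <- rec$features
    for (g in cl$genes) {
      if (g$truncated) next
      i <- match(g$feature_id, f$feature_id)
      gc <- compute_gc(rec$sequence, f$start[i], f$end[i])
      errs <- c(errs, abs(gc - g$gc_target))
    }
  }
  expect_lt(max(errs), 0.02)
})

test_that("within-family identities bracket the configured level", {
  run <- benchmark_run()
  truth <- run$truth$proteins
  # realign a sample of planted proteins to a sibling of the same family
  fams <- split(truth$feature_id, truth$family_id)
  fams <- Filter(function(x) length(x) >= 2, fams)
  feats <- do.call(rbind, lapply(run$records, function(r) r$features))
  set.seed(60)
  idents <- vapply(fams[sample(length(fams), min(20, length(fams)))],
                   function(ids) {
    tr <- feats$translation[match(ids[1:2], feats$feature_id)]
    if (any(!nzchar(tr)) || any(nchar(tr) < 50)) return(NA_real_)
    align_pair(tr[1], tr[2])$percent_identity
  }, numeric(1))
  idents <- idents[!is.na(idents)]
  # members sit at ~90% of a shared founder: pairwise ~81% plus chance
  expect_equal(mean(idents), 83, tolerance = 5)
})

test_that("plant_cluster appends a cluster and records truth", {
  set.seed(61)
  run <- generate_run(sim_config(n_genomes = 2L, seed = 12L))
  arch_rec <- run$records[[1]]
  base <- genome_record("NEW1", strain = "S900", species = "L. synthetic",
                        sequence = random_dna(2000, 0.42))
  out <- plant_cluster(base, run$config, run$pools, "nomadic")
  expect_gt(nrow(out$record$features), 1)
  expect_equal(length(out$truth$member_feature_ids),
               nrow(out$record$features))
  expect_equal(out$truth$habitat, "nomadic")
  expect_type(out$truth$is_generic, "logical")
})
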
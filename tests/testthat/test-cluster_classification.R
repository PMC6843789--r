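# Generic/non-generic calls, completeness, GC deviation, transposase adjacency

role_tbl <- function(roles, strand = "+", pseudo = NULL, trunc = NULL) {
  n <- length(roles)
  starts <- seq(0L, by = 1000L, length.out = n)
  data.frame(cluster_id = "c1", feature_id = sprintf("g%02d", seq_len(n)),
             role = roles, evidence = "homology", identity = 90,
             is_truncated = trunc %||% rep(FALSE, n),
             is_pseudo = pseudo %||% rep(FALSE, n),
             start = starts, end = starts + 900L,
             strand = strand, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("the intact ordered epsABCDE stretch defines a generic cluster", {
  generic <- c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE", "GT", "GT", "Wzx",
               "Wzy")
  expect_true(is_generic(role_tbl(generic)))
  # epsA moved after wzx
  moved <- c("EpsB", "EpsC", "EpsD", "EpsE", "GT", "GT", "Wzx", "EpsA",
             "Wzy")
  expect_false(is_generic(role_tbl(moved)))
  # epsA absent
  expect_false(is_generic(role_tbl(generic[-1])))
})

test_that("minus-strand clusters are re-oriented and transposases skipped", {
  generic <- c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE", "GT", "Wzx", "Wzy")
  # genomic order of a minus-strand operon is reversed
  expect_true(is_generic(role_tbl(rev(generic)), strand = "-"))
  expect_false(is_generic(role_tbl(generic), strand = "-"))
  # transposase interleaved in the 5' stretch does not break genericity
  interrupted <- c("EpsA", "EpsB", "Transposase", "EpsC", "EpsD", "EpsE",
                   "GT", "Wzx", "Wzy")
  expect_true(is_generic(role_tbl(interrupted)))
})

test_that("completeness reports missing essential and dispensable genes", {
  full <- c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE", "GT", "Wzx", "Wzy")
  comp <- completeness(role_tbl(full))
  expect_length(comp$missing_essential, 0)
  expect_length(comp$missing_dispensable, 0)

  comp2 <- completeness(role_tbl(setdiff(full, "Wzy")))
  expect_equal(comp2$missing_essential, "wzy")

  # pseudogene counts as missing
  pseudo <- rep(FALSE, 8); pseudo[4] <- TRUE   # epsD
  comp3 <- completeness(role_tbl(full, pseudo = pseudo))
  expect_equal(comp3$missing_dispensable, "epsD")

  # truncated counts as missing unless the flag is flipped
  trunc <- rep(FALSE, 8); trunc[6] <- TRUE     # the only gt
  comp4 <- completeness(role_tbl(full, trunc = trunc))
  expect_true("gt" %in% comp4$missing_essential)
  comp5 <- completeness(role_tbl(full, trunc = trunc),
                        truncated_as_present = TRUE)
  expect_false("gt" %in% comp5$missing_essential)
})

test_that("completeness is monotone under gene deletion", {
  set.seed(42)
  full <- c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE", "GT", "GT", "Wzx", "Wzy")
  for (rep in 1:10) {
    keep <- sort(sample(seq_along(full), sample(2:8, 1)))
    sub <- role_tbl(full[keep])
    whole <- completeness(role_tbl(full))
    part <- completeness(sub)
    expect_true(all(whole$missing_essential %in% part$missing_essential))
    expect_true(all(whole$missing_dispensable %in% part$missing_dispensable))
  }
})

test_that("per-role GC deviation recovers planted composition offsets", {
  set.seed(43)
  # a record whose gt gene is composed at GC 0.35 against an 0.45 background
  gt_prot <- random_protein(250); eps_prot <- random_protein(250)
  gt_dna <- back_translate(gt_prot, 0.35)
  eps_dna <- back_translate(eps_prot, 0.45)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                     prob = c(.275, .225, .225, .275)),
                              collapse = "")
  s <- paste0(filler(5000), eps_dna, filler(200), gt_dna, filler(5000))
  e_start <- 5000L; e_end <- e_start + nchar(eps_dna)
  g_start <- e_end + 200L; g_end <- g_start + nchar(gt_dna)
  rec <- genome_record("R1", sequence = s, features = gene_features(
    c("e1", "g1"), c(e_start, g_start), c(e_end, g_end), c("+", "+"),
    c(eps_prot, gt_prot), c("epsC", "gt"), c(FALSE, FALSE)))
  rt <- data.frame(cluster_id = "c1", feature_id = c("e1", "g1"),
                   role = c("EpsC", "GT"), evidence = "homology",
                   identity = 90, is_truncated = FALSE, is_pseudo = FALSE,
                   start = c(e_start, g_start), end = c(e_end, g_end),
                   strand = "+", stringsAsFactors = FALSE)
  gc <- gc_deviation(rt, rec)
  gt_row <- gc[gc$role == "GT", ]
  eps_row <- gc[gc$role == "EpsC", ]
  expect_lt(abs(gt_row$delta - (0.35 - 0.45)), 0.02)
  expect_lt(abs(eps_row$delta), 0.015)
  # absent roles are absent from the map
  expect_false("Wzx" %in% gc$role)
})

test_that("transposase adjacency is immediate-neighbor only", {
  roles <- c("EpsA", "EpsB", "Transposase", "Wzx", "GT", "GT", "Wzy")
  adj <- transposase_adjacency(role_tbl(roles))
  expect_setequal(adj$adjacent_roles, c("EpsB", "Wzx"))
  # three genes away is not adjacent
  roles2 <- c("Transposase", "EpsA", "EpsB", "EpsC", "Wzx")
  adj2 <- transposase_adjacency(role_tbl(roles2))
  expect_false("Wzx" %in% adj2$adjacent_roles)
  # no transposase
  adj3 <- transposase_adjacency(role_tbl(c("EpsA", "GT")))
  expect_length(adj3$adjacent_roles, 0)
})

test_that("every benchmark cluster is exactly one of generic or non-generic", {
  det <- benchmark_detection()
  flags <- vapply(det$classifications, `[[`, logical(1), "is_generic")
  expect_equal(length(flags), nrow(det$clusters))
  expect_type(flags, "logical")
  expect_false(any(is.na(flags)))
  s <- det$summary
  expect_equal(s$n_generic + s$n_non_generic, s$n_clusters)
})
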
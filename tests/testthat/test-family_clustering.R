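# Markov clustering, the two-level family hierarchy, diversity statistics

test_that("disconnected cliques never merge; isolated proteins become singletons", {
  e <- rbind(clique_edges(c("a", "b", "c")), clique_edges(c("d", "e", "f")))
  r <- mcl(e, inflation = 2)
  expect_equal(sort(unname(lengths(r$families))), c(3L, 3L))
  expect_true(same_partition(r$families, list(c("a", "b", "c"),
                                              c("d", "e", "f"))))

  r2 <- mcl(data.frame(protein_a = character(), protein_b = character(),
                       weight = numeric()), proteins = letters[1:5])
  expect_equal(lengths(r2$families), rep(1L, 5), ignore_attr = TRUE)
})

test_that("a 6-path with one weak middle edge splits into two 3-families", {
  e <- data.frame(protein_a = c("a", "b", "c", "d", "e"),
                  protein_b = c("b", "c", "d", "e", "f"),
                  weight = c(1, 1, 0.1, 1, 1))
  r <- mcl(e, inflation = 2)
  expect_true(same_partition(r$families, list(c("a", "b", "c"),
                                              c("d", "e", "f"))))
  expect_true(same_partition(r$families, mcl_oracle(e, inflation = 2)))
})

test_that("mcl matches the independent dense oracle on all small fixture graphs", {
  fixtures <- list(
    rbind(clique_edges(c("a", "b", "c")), clique_edges(c("d", "e", "f"))),
    data.frame(protein_a = c("a", "b", "c", "d", "e"),
               protein_b = c("b", "c", "d", "e", "f"),
               weight = c(1, 1, 0.1, 1, 1)),
    data.frame(protein_a = rep("hub", 4),
               protein_b = paste0("s", 1:4), weight = 1),
    clique_edges(letters[1:8], weight = 0.8))
  set.seed(99)
  for (i in 1:20) fixtures[[length(fixtures) + 1]] <-
    random_graph_edges(sample(4:8, 1))
  for (i in seq_along(fixtures)) {
    e <- fixtures[[i]]
    if (!nrow(e)) next
    r <- mcl(e, inflation = 2)
    o <- mcl_oracle(e, inflation = 2)
    expect_true(same_partition(r$families, o), info = paste("fixture", i))
  }
})

test_that("mcl is invariant to edge order and node relabeling", {
  set.seed(13)
  e <- random_graph_edges(7, p = 0.5)
  r1 <- mcl(e, inflation = 2)
  r2 <- mcl(e[sample(nrow(e)), ], inflation = 2)
  expect_true(same_partition(r1$families, r2$families))
  # relabel nodes: partition isomorphic under the renaming
  map <- stats::setNames(sprintf("x%02d", seq_len(26)),
                         sprintf("n%02d", seq_len(26)))
  e3 <- data.frame(protein_a = map[e$protein_a], protein_b = map[e$protein_b],
                   weight = e$weight)
  r3 <- mcl(e3, inflation = 2)
  renamed <- lapply(r1$families, function(f) unname(map[f]))
  expect_true(same_partition(renamed, r3$families))
})

test_that("family sizes conserve the protein count at both levels", {
  pf <- plant_protein_families(4, 4, within = 0.9, between = 0.25,
                               length = 150, seed = 20)
  fams <- build_two_level_families(pf$proteins)
  expect_equal(length(fams$strict), length(pf$proteins))
  expect_equal(length(fams$loose), length(pf$proteins))
  expect_false(any(is.na(fams$strict)))
})

test_that("two trios at moderate divergence give 2 strict families in 1 loose family", {
  pf <- plant_protein_families(2, 3, within = 0.9, between = 0.5,
                               length = 200, seed = 77)
  fams <- build_two_level_families(pf$proteins)
  expect_equal(length(unique(fams$strict)), 2)
  expect_equal(length(unique(fams$loose)), 1)
  # strongly diverged trios separate at both levels
  pf2 <- plant_protein_families(2, 3, within = 0.9, between = 0.1,
                                length = 200, seed = 78)
  fams2 <- build_two_level_families(pf2$proteins)
  expect_equal(length(unique(fams2$strict)), 2)
  expect_equal(length(unique(fams2$loose)), 2)
})

test_that("strict families nest inside loose families", {
  for (seed in c(5, 6)) {
    pf <- plant_protein_families(4, 3, within = 0.85, between = 0.25,
                                 length = 150, seed = seed)
    fams <- build_two_level_families(pf$proteins)
    tab <- table(fams$strict, fams$loose)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_equal(unname(fams$strict_to_loose[fams$strict]),
                 unname(fams$loose), ignore_attr = TRUE)
  }
})

test_that("planted families are recovered exactly across k", {
  for (k in c(2, 5, 10)) {
    pf <- plant_protein_families(k, 3, within = 0.85, between = 0.25,
                                 length = 150, seed = 100 + k)
    fams <- build_two_level_families(pf$proteins)
    expect_equal(length(unique(fams$strict)), k, info = paste("k =", k))
    # members of one planted family share one strict family
    for (i in seq_len(k)) {
      members <- names(pf$truth)[pf$truth == i]
      expect_equal(length(unique(fams$strict[members])), 1)
    }
  }
})

test_that("diversity statistics reproduce the ratio formulas", {
  # 97 proteins in 11 strict families in 1 loose family: 8.8 proteins/family
  strict <- sprintf("SF%04d", c(rep(1:10, 9), rep(11, 7)))
  ids <- sprintf("p%03d", seq_along(strict))
  families <- structure(list(
    strict = stats::setNames(strict, ids),
    loose = stats::setNames(rep("LF0001", length(ids)), ids),
    strict_to_loose = stats::setNames(rep("LF0001", 11),
                                      sprintf("SF%04d", 1:11)),
    edges = NULL), class = "family_set")
  rt <- data.frame(feature_id = ids, role = "EpsD",
                   cluster_id = sprintf("c%03d", seq_along(ids)),
                   stringsAsFactors = FALSE)
  st <- diversity_stats(families, rt, roles = "EpsD")
  expect_equal(st$n_proteins, 97)
  expect_equal(st$proteins_per_strict_family, 8.8)
  expect_equal(st$strict_per_loose, 11)
  expect_equal(st$n_clusters_multicopy, 0)

  # 8 strict in 2 loose: ratio 4; one singleton among one family: 100%
  strict2 <- sprintf("SF%04d", 1:8)
  loose2 <- c(rep("LF0001", 4), rep("LF0002", 4))
  fam2 <- structure(list(
    strict = stats::setNames(strict2, sprintf("q%d", 1:8)),
    loose = stats::setNames(loose2, sprintf("q%d", 1:8)),
    strict_to_loose = stats::setNames(loose2, strict2), edges = NULL),
    class = "family_set")
  rt2 <- data.frame(feature_id = sprintf("q%d", 1:8), role = "EpsA",
                    cluster_id = sprintf("c%d", 1:8),
                    stringsAsFactors = FALSE)
  st2 <- diversity_stats(fam2, rt2, roles = "EpsA")
  expect_equal(st2$strict_per_loose, 4)
  expect_equal(st2$singleton_percent, 100)
})
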
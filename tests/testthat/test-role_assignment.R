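# Functional role calls, GT family voting, precursor inventory

make_lib_fixture <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      set.seed(300)
      gt2 <- random_protein(300); gt4 <- random_protein(300)
      wzx_arch <- tm_architecture(14)
      lib <- data.frame(
        id = c("rA", "rGT2", "rGT4", "rWzx"),
        role = c("EpsA", "GT", "GT", "Wzx"),
        family = c(NA, "GT2", "GT4", NA),
        enzyme = NA_character_,
        seed = c(TRUE, FALSE, FALSE, FALSE),
        seq = c(random_protein(310), gt2, gt4, wzx_arch$seq),
        stringsAsFactors = FALSE)
      cached <<- list(lib = lib, wzx_arch = wzx_arch)
    }
    cached
  }
})

make_lib <- function() make_lib_fixture()$lib

feat <- function(tr, product = "", pseudo = FALSE, id = "f1") {
  list(feature_id = id, translation = tr, product = product,
       is_pseudo = pseudo)
}

test_that("homology sets the role; keywords are the fallback; no hit means Other", {
  lib <- make_lib()
  set.seed(301)
  gt_gene <- mutate_protein(lib$seq[lib$id == "rGT2"], 0.7)
  r <- assign_role(feat(gt_gene), lib)
  expect_equal(r$role, "GT")
  expect_equal(r$evidence, "homology")
  expect_gt(r$identity, 30)

  r2 <- assign_role(feat(random_protein(200), "hypothetical protein"), lib)
  expect_equal(r2$role, "Other")

  r3 <- assign_role(feat(random_protein(200),
                         "UDP-galactopyranose mutase"), lib)
  expect_equal(r3$role, "Precursor:UDP-galactopyranose mutase")
  expect_equal(r3$evidence, "keyword")
})

test_that("flippase calls require both homology and >= 8 predicted helices", {
  lib <- make_lib()
  arch <- make_lib_fixture()$wzx_arch
  set.seed(302)
  wzx_gene <- mutate_protein(arch$seq, 0.6, classes = arch$classes)
  r <- assign_role(feat(wzx_gene), lib)
  expect_equal(r$role, "Wzx")
  expect_equal(r$evidence, "combined")
  expect_equal(tm_profile("x", wzx_gene)$n_helices, 14)

  # keyword flippase without membrane topology falls to Other
  r2 <- assign_role(feat(random_protein(150), "polysaccharide flippase Wzx"),
                    lib)
  expect_equal(r2$role, "Other")
  expect_equal(r2$evidence, "topology")
})

test_that("short proteins are flagged truncated against the role median length", {
  lib <- make_lib()
  set.seed(303)
  full <- mutate_protein(lib$seq[lib$id == "rGT2"], 0.8)
  short <- substr(full, 1, 100)      # < 50% of the 300-residue GT median
  r <- assign_role(feat(short, "glycosyltransferase"), lib)
  expect_true(r$is_truncated)
  r2 <- assign_role(feat(full), lib)
  expect_false(r2$is_truncated)
})

test_that("GT family calls need two concurring methods", {
  lib <- make_lib()
  gt_lib <- lib[lib$role == "GT", ]
  set.seed(304)
  # direct copy: both methods agree
  call <- classify_gt(gt_lib$seq[gt_lib$family == "GT4"], lib)
  expect_equal(call$family, "GT4")
  expect_equal(call$method_agreement, 2L)
  # chimera of GT2 and GT4 halves: methods disagree or fall under containment
  g2 <- gt_lib$seq[gt_lib$family == "GT2"]
  g4 <- gt_lib$seq[gt_lib$family == "GT4"]
  chimera <- paste0(substr(g2, 1, 150), substr(g4, 151, 300))
  call2 <- classify_gt(chimera, lib)
  if (call2$family != "unknown") {
    # a chimera may legitimately resolve only if both methods pick the
    # same parent; the conservative invariant is agreement >= 2
    expect_equal(call2$method_agreement, 2L)
  }
  # random proteins are never classified
  for (i in 1:5) {
    call3 <- classify_gt(random_protein(300), lib)
    expect_equal(call3$family, "unknown")
    expect_lt(call3$method_agreement, 2L)
  }
  expect_error(classify_gt("MKT", lib[lib$role != "GT", ]), "empty")
})

test_that("labeled GT families always carry method_agreement == 2", {
  set.seed(305)
  lib <- make_lib()
  for (t in c(0.95, 0.8, 0.65, 0.5, 0.35)) {
    q <- mutate_protein(lib$seq[lib$id == "rGT2"], t)
    call <- classify_gt(q, lib)
    if (call$family != "unknown") expect_equal(call$method_agreement, 2L)
  }
})

test_that("precursor inventory counts enzymes and checks the rml operon", {
  rt <- data.frame(
    feature_id = paste0("g", 1:6),
    role = c("Precursor:rmlA", "Precursor:rmlB", "Precursor:rmlC",
             "Precursor:rmlD", "Precursor:UDP-galactopyranose mutase", "GT"),
    stringsAsFactors = FALSE)
  inv <- inventory_precursors(rt)
  expect_true(inv$rml_operon_complete)
  expect_equal(inv$counts[["UDP-galactopyranose mutase"]], 1L)

  inv2 <- inventory_precursors(rt[-4, ])     # drop rmlD
  expect_false(inv2$rml_operon_complete)
})

test_that("roles partition cluster genes (each gene tallied exactly once)", {
  det <- benchmark_detection()
  for (cid in names(det$role_tables)) {
    rt <- det$role_tables[[cid]]
    expect_equal(length(rt$feature_id), length(unique(rt$feature_id)))
    expect_true(all(nzchar(rt$role)))
  }
})

test_that("role calls match planted truth for within-threshold divergence", {
  run <- benchmark_run()
  det <- benchmark_detection()
  truth <- run$truth$proteins
  checked <- 0L
  for (cid in names(det$role_tables)) {
    rt <- det$role_tables[[cid]]
    for (i in seq_len(nrow(rt))) {
      j <- match(rt$feature_id[i], truth$feature_id)
      if (is.na(j)) next
      planted <- truth$role[j]
      called <- rt$role[i]
      # truncated or pseudo copies may legitimately lose their role call
      tr_flag <- rt$is_truncated[i] | rt$is_pseudo[i]
      if (planted %in% c("Other") || tr_flag) next
      checked <- checked + 1L
      expect_equal(called, planted,
                   info = paste(cid, rt$feature_id[i]))
    }
  }
  expect_gt(checked, 100)
})
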
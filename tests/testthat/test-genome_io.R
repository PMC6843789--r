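# GenBank / GFF3 readers, GC computation, habitat metadata, JSON round trip

make_toy_record <- function() {
  # three CDS: plus strand, minus strand, pseudo
  set.seed(101)
  p1 <- random_protein(40); p2 <- random_protein(30); p3 <- random_protein(25)
  d1 <- back_translate(p1, 0.5); d2 <- back_translate(p2, 0.4)
  d3 <- back_translate(p3, 0.45)
  spacer <- function(n) paste(rep("A", n), collapse = "")
  seqs <- paste0(spacer(50), d1, spacer(30), reverse_complement(d2),
                 spacer(20), d3, spacer(40))
  s1 <- 50L; e1 <- s1 + nchar(d1)
  s2 <- e1 + 30L; e2 <- s2 + nchar(d2)
  s3 <- e2 + 20L; e3 <- s3 + nchar(d3)
  feats <- gene_features(
    feature_id = c("g1", "g2", "g3"),
    start = c(s1, s2, s3), end = c(e1, e2, e3),
    strand = c("+", "-", "+"),
    translation = c(p1, p2, p3),
    product = c("glycosyltransferase", "polysaccharide flippase Wzx",
                "hypothetical protein"),
    is_pseudo = c(FALSE, FALSE, TRUE))
  genome_record("REC1", strain = "S001", species = "Lactobacillus synth01",
                replicon_kind = "chromosome", sequence = seqs,
                features = feats)
}

test_that("GenBank round trip preserves counts, coordinates and translations", {
  rec <- make_toy_record()
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  back <- read_genbank(path)
  expect_length(back, 1)
  b <- back[[1]]
  expect_equal(b$record_id, rec$record_id)
  expect_equal(nrow(b$features), 3)
  expect_equal(b$features$start, rec$features$start)
  expect_equal(b$features$end, rec$features$end)
  expect_equal(b$features$strand, rec$features$strand)
  expect_equal(b$features$translation, rec$features$translation)
  expect_equal(b$features$is_pseudo, rec$features$is_pseudo)
  expect_equal(b$sequence, rec$sequence)
  expect_equal(b$replicon_kind, "chromosome")
})

test_that("minus-strand CDS without /translation is translated from the reverse complement", {
  rec <- make_toy_record()
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  # strip the stored translations so the reader must translate
  lines <- readLines(path)
  drop <- grepl("/translation=", lines) |
    (!grepl("/", lines) & grepl("^ {21}[A-Z]+\"?$", lines))
  writeLines(lines[!drop], path)
  b <- read_genbank(path)[[1]]
  f <- b$features[b$features$strand == "-", ]
  interval <- substr(b$sequence, f$start + 1, f$end)
  # independent oracle: Biostrings translation of the reverse complement
  oracle <- as.character(Biostrings::translate(
    Biostrings::reverseComplement(Biostrings::DNAString(interval)),
    genetic.code = Biostrings::getGeneticCode("11")))
  oracle <- sub("\\*$", "", oracle)
  expect_equal(f$translation, oracle)
})

test_that("plasmid keyword in DEFINITION sets replicon_kind", {
  rec <- make_toy_record()
  rec$replicon_kind <- "plasmid"
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  expect_equal(read_genbank(path)[[1]]$replicon_kind, "plasmid")
})

test_that("unparseable locations and compound joins raise errors naming the line", {
  rec <- make_toy_record()
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  lines <- readLines(path)
  i <- grep("^     CDS", lines)[1]
  lines[i] <- "     CDS             join(10..20,30..40)"
  writeLines(lines, path)
  expect_error(read_genbank(path), "join")
  expect_error(read_genbank(tempfile()), "no such file")
})

test_that("GFF3 + FASTA route matches the GenBank route and respects phase", {
  rec <- make_toy_record()
  gbk <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(rec, gbk)
  via_gbk <- read_genbank(gbk)[[1]]

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">REC1", rec$sequence), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  f <- rec$features
  writeLines(c("##gff-version 3", vapply(seq_len(nrow(f)), function(i) {
    sprintf("REC1\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s%s",
            f$start[i] + 1L, f$end[i], f$strand[i], f$feature_id[i],
            f$product[i], if (f$is_pseudo[i]) ";pseudo=true" else "")
  }, character(1))), gff)
  via_gff <- read_gff_fasta(gff, fa)[[1]]
  expect_equal(via_gff$features$start, via_gbk$features$start)
  expect_equal(via_gff$features$translation, via_gbk$features$translation)

  # phase 1: translation starts at offset 1 of a toy 13-nt CDS
  toy_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">T1", "AATGAAACCCTTTGG"), toy_fa)
  toy_gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "T1\tsim\tCDS\t1\t13\t.\t+\t1\tID=c1"), toy_gff)
  recs <- read_gff_fasta(toy_gff, toy_fa)
  # manual translation of ATG AAA CCC TTT (offset 1): M K P F
  expect_equal(recs[[1]]$features$translation, "MKPF")

  # empty GFF3 body: one record, zero features, warning
  empty_gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty_gff)
  expect_warning(r0 <- read_gff_fasta(empty_gff, toy_fa), "no CDS")
  expect_equal(nrow(r0[[1]]$features), 0)

  # seqid missing from FASTA
  bad_gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "NOPE\tsim\tCDS\t1\t12\t.\t+\t0\tID=x"),
             bad_gff)
  expect_error(read_gff_fasta(bad_gff, toy_fa), "NOPE")
})

test_that("compute_gc handles composition, N exclusion and degenerate input", {
  expect_equal(compute_gc("ATGC"), 0.5)
  expect_equal(compute_gc("GGGG"), 1.0)
  expect_equal(compute_gc("ATNNGC"), 0.5)      # N excluded from denominator
  expect_true(is.na(compute_gc("NNNN")))       # undefined, not zero
  expect_equal(compute_gc("ATGCATGC", from = 2L, to = 4L),
               compute_gc("GC"))
  # strand symmetry property
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE), collapse = "")
    expect_equal(compute_gc(s), compute_gc(reverse_complement(s)))
  }
})

test_that("JSON dump round-trips records field by field", {
  rec <- make_toy_record()
  path <- withr::local_tempfile(fileext = ".json")
  records_to_json(list(rec), path)
  back <- records_from_json(path)[[1]]
  expect_equal(unclass(back), unclass(rec))
})

test_that("habitat lookup falls back to species and never errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tspecies\thabitat",
               "S001\tLactobacillus a\thost-adapted",
               "S002\tLactobacillus b\tnomadic"), path)
  tbl <- read_habitat_table(path)
  expect_equal(habitat_of(tbl, "S001"), "host-adapted")
  expect_equal(habitat_of(tbl, "S999"), "unknown")
  expect_equal(habitat_of(tbl, "S999", species = "Lactobacillus b"),
               "nomadic")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tspecies\thabitat", "S1\tx\tmarine"), bad)
  expect_error(read_habitat_table(bad), "marine")
})
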
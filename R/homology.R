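# Pairwise protein alignment and the all-against-all similarity graph.
#
# Local Smith-Waterman alignment with BLOSUM62 and affine gaps (open 11,
# extend 1) stands in for BLASTP throughout; identity is matches over
# alignment length (gaps included), and coverage is aligned residues over the
# full unaligned length of each sequence, mirroring BLAST's "query coverage".
# No E-values are computed: the seed-search threshold is raw identity and
# reference coverage (see `scoring_params`).

.pkg_cache <- new.env(parent = emptyenv())

blosum62_x0 <- function() {
  if (is.null(.pkg_cache$blosum)) {
    mat <- get_blosum62()
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .pkg_cache$blosum <- mat
  }
  .pkg_cache$blosum
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Alignment and threshold parameters
#'
#' Bundles the scoring scheme (BLOSUM62, affine gaps open 11 / extend 1 --
#' the BLASTP defaults; the substitution matrix and gap costs are assumptions
#' recorded here, not inferences) with the homology thresholds used across the
#' pipeline:
#' * `seed_min_identity` / `seed_min_coverage`: seed and neighborhood search
#'   (identity strictly greater than 30, coverage of the *reference* protein
#'   at least 50) -- the raw-score analog of a translated homology screen.
#' * `edge_min_identity` / `edge_min_coverage`: all-vs-all similarity edges
#'   (both-direction query coverage at least 50).
#' * `prescreen_k` / `use_prescreen`: pairs sharing no amino-acid k-mer are
#'   skipped before alignment; verified against the no-prescreen route in the
#'   test suite.
#'
#' @param gap_opening,gap_extension affine gap costs.
#' @param seed_min_identity,seed_min_coverage seed/neighbor thresholds (percent).
#' @param edge_min_identity,edge_min_coverage similarity-edge thresholds (percent).
#' @param prescreen_k k-mer length of the shared-k-mer prescreen.
#' @param use_prescreen logical; disable to force full alignment of all pairs.
#' @return a list of class `scoring_params`.
#' @export
scoring_params <- function(gap_opening = 11, gap_extension = 1,
                           seed_min_identity = 30, seed_min_coverage = 50,
                           edge_min_identity = 50, edge_min_coverage = 50,
                           prescreen_k = 4L, use_prescreen = TRUE) {
  structure(list(gap_opening = gap_opening, gap_extension = gap_extension,
                 matrix = "BLOSUM62 (X scored 0)",
                 seed_min_identity = seed_min_identity,
                 seed_min_coverage = seed_min_coverage,
                 edge_min_identity = edge_min_identity,
                 edge_min_coverage = edge_min_coverage,
                 prescreen_k = as.integer(prescreen_k),
                 use_prescreen = use_prescreen),
            class = "scoring_params")
}

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps). Identity is
#' matches / alignment length (gaps counted); each coverage is the number of
#' that sequence's residues inside the local alignment divided by its full
#' length.
#'
#' @param a,b amino-acid strings (20-letter alphabet; `X` tolerated, scored 0).
#' @param params a [scoring_params()] object.
#' @return list of class `alignment_result` with `score`, `percent_identity`,
#'   `query_coverage`, `subject_coverage`, `aligned_length`.
#' @export
align_pair <- function(a, b, params = scoring_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62_x0(),
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  alen <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  q_res <- Biostrings::end(p) - Biostrings::start(p) + 1L
  s_res <- Biostrings::end(s) - Biostrings::start(s) + 1L
  structure(list(
    score = Biostrings::score(aln),
    percent_identity = if (alen > 0) 100 * matches / alen else 0,
    query_coverage = 100 * q_res / nchar(a),
    subject_coverage = 100 * s_res / nchar(b),
    aligned_length = alen), class = "alignment_result")
}

#' Reciprocal similarity edge between two proteins
#'
#' Emits an edge only when the alignment passes the identity cut-off and the
#' coverage cut-off on *both* sequences (the query-coverage test applied in
#' both directions; local alignment is symmetric under swapping the two
#' sequences, so a single alignment decides both). `min_coverage` is the
#' smaller of the two coverages.
#'
#' @param a,b amino-acid strings.
#' @param id_a,id_b protein identifiers; the edge is stored with the
#'   lexicographically smaller id first.
#' @param params a [scoring_params()]; uses `edge_min_identity` and
#'   `edge_min_coverage`.
#' @return one-row data.frame (`protein_a`, `protein_b`, `percent_identity`,
#'   `min_coverage`) or `NULL` when the pair fails.
#' @export
bidirectional_hit <- function(a, b, id_a = "a", id_b = "b",
                              params = scoring_params()) {
  r <- align_pair(a, b, params)
  if (r$percent_identity < params$edge_min_identity ||
      r$query_coverage < params$edge_min_coverage ||
      r$subject_coverage < params$edge_min_coverage) return(NULL)
  ids <- sort(c(id_a, id_b))
  data.frame(protein_a = ids[1], protein_b = ids[2],
             percent_identity = r$percent_identity,
             min_coverage = min(r$query_coverage, r$subject_coverage),
             stringsAsFactors = FALSE)
}

#' All-against-all similarity edges
#'
#' Aligns every unordered pair of proteins and keeps the pairs passing
#' [bidirectional_hit()]. When `params$use_prescreen` is set, pairs sharing no
#' `prescreen_k`-mer are skipped without alignment (unrelated proteins almost
#' never share a 4-mer; homologs above the edge threshold share many).
#'
#' @param proteins named character vector of amino-acid sequences; names are
#'   the (unique) protein ids.
#' @param params a [scoring_params()].
#' @return data.frame of similarity edges (possibly 0 rows).
#' @export
all_vs_all <- function(proteins, params = scoring_params()) {
  ids <- names(proteins)
  if (is.null(ids) || any(!nzchar(ids))) stop("proteins must be named")
  if (anyDuplicated(ids)) stop("duplicate protein ids")
  n <- length(proteins)
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      percent_identity = numeric(), min_coverage = numeric(),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  km <- if (params$use_prescreen)
    lapply(proteins, aa_kmers, k = params$prescreen_k) else NULL
  out <- list()
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    if (!is.null(km)) {
      keep <- vapply(js, function(j)
        shared_kmer_count(km[[i]], km[[j]]) > 0L, logical(1))
      js <- js[keep]
    }
    if (!length(js)) next
    res <- align_batch(proteins[js], proteins[[i]], params)
    pass <- res$percent_identity >= params$edge_min_identity &
      res$pattern_coverage >= params$edge_min_coverage &
      res$subject_coverage >= params$edge_min_coverage
    if (!any(pass)) next
    jj <- js[pass]
    a <- pmin(ids[i], ids[jj]); b <- pmax(ids[i], ids[jj])
    out[[length(out) + 1L]] <- data.frame(
      protein_a = a, protein_b = b,
      percent_identity = res$percent_identity[pass],
      min_coverage = pmin(res$pattern_coverage[pass],
                          res$subject_coverage[pass]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  edges <- do.call(rbind, out)
  edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

# batch local alignment of many patterns against one subject; coverages are
# relative to each sequence's full length
align_batch <- function(patterns, subject, params = scoring_params()) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(patterns)), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62_x0(),
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  alen <- Biostrings::nchar(aln)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  p_res <- Biostrings::end(p) - Biostrings::start(p) + 1L
  s_res <- Biostrings::end(s) - Biostrings::start(s) + 1L
  data.frame(score = Biostrings::score(aln),
             percent_identity = ifelse(alen > 0,
                                       100 * Biostrings::nmatch(aln) / alen, 0),
             pattern_coverage = 100 * p_res / nchar(patterns),
             subject_coverage = 100 * s_res / nchar(subject),
             aligned_length = alen)
}

#' Write similarity edges as TSV
#' @param edges data.frame from [all_vs_all()].
#' @param path output file.
#' @export
write_edges_tsv <- function(edges, path) {
  df <- data.frame(protein_a = edges$protein_a, protein_b = edges$protein_b,
                   identity = edges$percent_identity,
                   min_coverage = edges$min_coverage)
  write_tsv(df, path)
}

# best passing hit of a candidate protein against a reference library subset;
# coverage is required on the reference side (see scoring_params docs)
best_reference_hit <- function(seq, lib, params = scoring_params(),
                               kmers_seq = NULL) {
  if (!nrow(lib)) return(NULL)
  rows <- seq_len(nrow(lib))
  if (params$use_prescreen) {
    if (is.null(kmers_seq)) kmers_seq <- aa_kmers(seq, params$prescreen_k)
    keep <- vapply(rows, function(i)
      shared_kmer_count(aa_kmers_cached(lib$seq[i], params$prescreen_k),
                        kmers_seq) > 0L, logical(1))
    rows <- rows[keep]
  }
  if (!length(rows)) return(NULL)
  res <- align_batch(lib$seq[rows], seq, params)   # references as queries
  pass <- res$percent_identity > params$seed_min_identity &
    res$pattern_coverage >= params$seed_min_coverage
  if (!any(pass)) return(NULL)
  best_i <- which(pass)[which.max(res$score[pass])]
  i <- rows[best_i]
  list(ref_id = lib$id[i], role = lib$role[i], family = lib$family[i],
       enzyme = lib$enzyme[i], score = res$score[best_i],
       identity = res$percent_identity[best_i],
       ref_coverage = res$pattern_coverage[best_i])
}

# memoised k-mer sets for reference sequences (keyed by sequence)
aa_kmers_cached <- function(seq, k) {
  key <- paste0(k, "#", seq)
  if (is.null(.pkg_cache$kmers)) .pkg_cache$kmers <- new.env(parent = emptyenv())
  hit <- .pkg_cache$kmers[[key]]
  if (!is.null(hit)) return(hit)
  val <- aa_kmers(seq, k)
  assign(key, val, envir = .pkg_cache$kmers)
  val
}
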
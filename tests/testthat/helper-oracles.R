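# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation.

# --- exhaustive Gotoh dynamic-programming oracle for local alignment ------
# Affine gaps: a gap of length L costs open + ext * L.
sw_score_oracle <- function(a, b, open = 11, ext = 1) {
  B <- blosum_oracle()
  A <- strsplit(a, "")[[1]]
  Bb <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(Bb)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + B[A[i - 1], Bb[j - 1]])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

blosum_oracle <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <- e$BLOSUM62
      mat["X", ] <- 0L
      mat[, "X"] <- 0L
      cached <<- mat
    }
    cached
  }
})

# --- independent dense Markov-clustering oracle ---------------------------
# Same model (identity-weighted graph, max-incident self-loops), but an
# independent implementation: no pruning, iteration to machine precision,
# component extraction by boolean reachability instead of igraph.
mcl_oracle <- function(edges, proteins = NULL, inflation = 2) {
  nodes <- sort(unique(c(proteins, edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  w <- if ("weight" %in% names(edges)) edges$weight else
    edges$percent_identity / 100
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$protein_a[k], nodes)
    j <- match(edges$protein_b[k], nodes)
    A[i, j] <- max(A[i, j], w[k]); A[j, i] <- max(A[j, i], w[k])
  }
  self <- apply(A, 2, max); self[self == 0] <- 1
  diag(A) <- self
  M <- A %*% diag(1 / colSums(A), n)
  for (it in 1:1000) {
    Mn <- M %*% M
    Mn <- Mn^inflation
    Mn <- Mn %*% diag(1 / colSums(Mn), n)
    if (max(abs(Mn - M)) < 1e-13) { M <- Mn; break }
    M <- Mn
  }
  # connected components of the support, by boolean reachability
  S <- (M > 1e-9) | t(M > 1e-9); diag(S) <- TRUE
  R <- S
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R > 0)) break
    R <- R2
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { cid <- cid + 1L; comp[R[i, ] > 0] <- cid }
  }
  unname(split(nodes, comp))
}

# partition comparison helper: equality as sets of sets
same_partition <- function(p1, p2) {
  s1 <- lapply(p1, function(x) sort(unlist(x)))
  s2 <- lapply(p2, function(x) sort(unlist(x)))
  setequal(vapply(s1, paste, character(1), collapse = "|"),
           vapply(s2, paste, character(1), collapse = "|"))
}

# small deterministic edge-list builders
clique_edges <- function(members, weight = 1) {
  cmb <- t(utils::combn(members, 2))
  data.frame(protein_a = cmb[, 1], protein_b = cmb[, 2], weight = weight,
             stringsAsFactors = FALSE)
}

random_graph_edges <- function(n, p = 0.4) {
  nodes <- sprintf("n%02d", seq_len(n))
  cmb <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(cmb)) < p
  data.frame(protein_a = cmb[keep, 1], protein_b = cmb[keep, 2],
             weight = stats::runif(sum(keep), 0.3, 1),
             stringsAsFactors = FALSE)
}
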
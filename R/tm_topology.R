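# Transmembrane topology of Wzx/Wzy candidates: Kyte-Doolittle hydropathy for
# helix calling plus the positive-inside rule for orientation. This is a
# self-contained hydropathy heuristic, not an HMM: outputs approximate, and do
# not reproduce, trained-model predictors.

# Kyte & Doolittle (1982) hydropathy scale
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2, X = 0, U = 0, B = -3.5, Z = -3.5)

#' Predict transmembrane helix segments
#'
#' Slides a hydropathy window over the sequence; every window whose mean
#' Kyte-Doolittle score reaches `threshold` is a candidate helix, and
#' overlapping candidates are resolved greedily by descending mean score
#' (ties by position), enforcing a minimum loop of `min_loop` residues
#' between accepted helices.
#'
#' @param seq amino-acid string (length >= `window` to yield any helix).
#' @param window hydropathy window length (residues).
#' @param threshold minimum window mean.
#' @param min_loop minimum separation between helices (residues).
#' @return data.frame with `start`, `end` (1-based, inclusive) and `mean_kd`,
#'   sorted by position; zero rows when no helix is found.
#' @export
predict_helices <- function(seq, window = 19L, threshold = 1.6, min_loop = 3L) {
  empty <- data.frame(start = integer(), end = integer(), mean_kd = numeric())
  n <- nchar(seq)
  if (n < window) return(empty)
  vals <- .kd_scale[strsplit(toupper(seq), "")[[1]]]
  vals[is.na(vals)] <- 0
  cs <- cumsum(c(0, vals))
  starts <- seq_len(n - window + 1L)
  means <- (cs[starts + window] - cs[starts]) / window
  cand <- which(means >= threshold)
  if (!length(cand)) return(empty)
  ord <- cand[order(-means[cand], cand)]
  sel_start <- integer(0); sel_end <- integer(0)
  for (s in ord) {
    e <- s + window - 1L
    # enforce both non-overlap and the minimum loop between helices
    if (!any(s <= sel_end + min_loop & e >= sel_start - min_loop)) {
      sel_start <- c(sel_start, s); sel_end <- c(sel_end, e)
    }
  }
  o <- order(sel_start)
  data.frame(start = sel_start[o], end = sel_end[o],
             mean_kd = means[sel_start[o]])
}

#' Orient a predicted topology by the positive-inside rule
#'
#' Loops (the inter-helix regions plus both termini tails) alternate sides of
#' the membrane. Of the two possible topologies, the one placing more
#' lysine+arginine residues on the cytoplasmic (inside) face wins; ties fall
#' to an inside N-terminus. With zero helices both termini are reported
#' inside (soluble convention).
#'
#' @param seq amino-acid string.
#' @param segments helix table from [predict_helices()].
#' @return list with `n_terminus_side` and `c_terminus_side` (each
#'   `"inside"` or `"outside"`).
#' @export
predict_orientation <- function(seq, segments) {
  k <- nrow(segments)
  if (k == 0)
    return(list(n_terminus_side = "inside", c_terminus_side = "inside"))
  aa <- strsplit(toupper(seq), "")[[1]]
  bounds_lo <- c(1L, segments$end + 1L)
  bounds_hi <- c(segments$start - 1L, length(aa))
  kr_per_loop <- vapply(seq_len(k + 1L), function(i) {
    if (bounds_lo[i] > bounds_hi[i]) return(0L)
    sum(aa[bounds_lo[i]:bounds_hi[i]] %in% c("K", "R"))
  }, integer(1))
  # loops 1,3,5,... share the N-terminal side; 2,4,... the opposite side
  odd <- sum(kr_per_loop[seq(1L, k + 1L, by = 2L)])
  even <- sum(kr_per_loop[seq_len(k + 1L)[-seq(1L, k + 1L, by = 2L)]])
  n_side <- if (odd >= even) "inside" else "outside"
  flip <- function(x) if (x == "inside") "outside" else "inside"
  c_side <- if (k %% 2L == 0L) n_side else flip(n_side)
  list(n_terminus_side = n_side, c_terminus_side = c_side)
}

#' Full transmembrane profile of a protein
#'
#' @param feature_id identifier carried into the profile.
#' @param seq amino-acid string.
#' @inheritParams predict_helices
#' @return list of class `tm_profile`: `feature_id`, `helix_segments`,
#'   `n_helices`, `n_terminus_side`, `c_terminus_side`. The parity invariant
#'   (C side equals N side iff the helix count is even) holds by construction.
#' @export
tm_profile <- function(feature_id, seq, window = 19L, threshold = 1.6,
                       min_loop = 3L) {
  segs <- predict_helices(seq, window, threshold, min_loop)
  orient <- predict_orientation(seq, segs)
  structure(list(feature_id = feature_id, helix_segments = segs,
                 n_helices = nrow(segs),
                 n_terminus_side = orient$n_terminus_side,
                 c_terminus_side = orient$c_terminus_side),
            class = "tm_profile")
}

#' Topology table for a set of proteins
#'
#' @param proteins named character vector of amino-acid sequences.
#' @return data.frame `feature_id`, `n_helices`, `n_side`, `c_side`,
#'   `segments` (compact `start-end` list).
#' @export
tm_profile_table <- function(proteins) {
  rows <- lapply(names(proteins), function(id) {
    p <- tm_profile(id, proteins[[id]])
    data.frame(feature_id = id, n_helices = p$n_helices,
               n_side = p$n_terminus_side, c_side = p$c_terminus_side,
               segments = paste(sprintf("%d-%d", p$helix_segments$start,
                                        p$helix_segments$end),
                                collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(feature_id = character(), n_helices = integer(),
                      n_side = character(), c_side = character(),
                      segments = character()))
  do.call(rbind, rows)
}
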
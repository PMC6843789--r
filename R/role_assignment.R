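# Functional role calls for cluster genes, CAZy-style GT family assignment by
# a two-method vote, and the precursor-enzyme inventory.

#' Controlled vocabulary of precursor enzymes
#'
#' Sugar-nucleotide precursor biosynthesis enzymes recognized in product
#' annotations and reference libraries. The dTDP-L-rhamnose pathway genes are
#' named rmlA-D.
#' @export
precursor_enzymes <- function() {
  c("UDP-galactopyranose mutase"                 = "UDP-galactopyranose mutase",
    "UDP-glucose 4-epimerase"                    = "UDP-glucose 4-epimerase",
    "glucose-1-phosphate thymidylyltransferase"  = "rmlA",
    "dTDP-glucose 4,6-dehydratase"               = "rmlB",
    "dTDP-4-dehydrorhamnose 3,5-epimerase"       = "rmlC",
    "dTDP-4-dehydrorhamnose reductase"           = "rmlD",
    "UDP-N-acetylglucosamine 2-epimerase"        = "UDP-N-acetylglucosamine 2-epimerase",
    "UTP-glucose-1-phosphate uridylyltransferase" = "UTP-glucose-1-phosphate uridylyltransferase",
    "UDP-glucose 6-dehydrogenase"                = "UDP-glucose 6-dehydrogenase")
}

keyword_role <- function(product) {
  p <- tolower(product)
  for (txt in names(precursor_enzymes())) {
    if (grepl(tolower(txt), p, fixed = TRUE))
      return(paste0("Precursor:", precursor_enzymes()[[txt]]))
  }
  if (grepl("transposase", p)) return("Transposase")
  if (grepl("flippase", p) || grepl("wzx", p)) return("Wzx")
  if (grepl("polysaccharide polymerase", p) || grepl("wzy", p) ||
      grepl("polymerase", p)) return("Wzy")
  if (grepl("priming glycosyltransferase", p)) return("EpsE")
  if (grepl("glycosyltransferase", p)) return("GT")
  if (grepl("marr", p)) return("Regulator:MarR")
  if (grepl("arac", p)) return("Regulator:AraC")
  if (grepl("regulator", p)) return("Regulator:other")
  if (grepl("adhesin", p)) return("Adhesin")
  "Other"
}

ref_role_label <- function(hit) {
  if (hit$role == "Precursor") paste0("Precursor:", hit$enzyme) else hit$role
}

# median reference length per role, for the truncation flag
role_median_lengths <- function(ref_lib) {
  tapply(nchar(ref_lib$seq), ref_lib$role, stats::median)
}

#' Assign a functional role to one gene
#'
#' The best reference hit (identity > 30, reference coverage >= 50) sets the
#' role; with no hit, a curated keyword match on the product text sets it with
#' `evidence = "keyword"`. Flippase (Wzx) and polymerase (Wzy) calls
#' additionally require a consistent membrane topology (>= 8 predicted
#' helices); failing that the gene falls to `Other`. Proteins shorter than
#' half the reference-role median length are flagged truncated. Pseudogenes
#' are called from their conceptual translation and keep `is_pseudo`.
#'
#' @param feature one row of a [gene_features()] table (data.frame or list).
#' @param ref_lib reference library data.frame.
#' @param topology optional [tm_profile()] for the feature (computed on
#'   demand for Wzx/Wzy candidates when absent).
#' @param params a [scoring_params()].
#' @param min_tm_helices topology gate for Wzx/Wzy calls.
#' @return one-row data.frame: `feature_id role evidence identity
#'   is_truncated is_pseudo`.
#' @export
assign_role <- function(feature, ref_lib, topology = NULL,
                        params = scoring_params(), min_tm_helices = 8L) {
  tr <- feature$translation
  role <- "Other"; evidence <- "none"; identity <- NA_real_
  if (nzchar(tr)) {
    hit <- best_reference_hit(tr, ref_lib, params)
    if (!is.null(hit)) {
      role <- ref_role_label(hit); evidence <- "homology"
      identity <- hit$identity
    }
  }
  if (role == "Other") {
    kw <- keyword_role(feature$product)
    if (kw != "Other") { role <- kw; evidence <- "keyword" }
  }
  if (role %in% c("Wzx", "Wzy") && nzchar(tr)) {
    prof <- topology %||% tm_profile(feature$feature_id, tr)
    if (prof$n_helices < min_tm_helices) {
      role <- "Other"; evidence <- "topology"
    } else if (evidence == "homology") evidence <- "combined"
  }
  is_trunc <- FALSE
  base_role <- sub(":.*$", "", role)
  med <- role_median_lengths(ref_lib)
  med_role <- if (base_role %in% names(med)) med[[base_role]] else NA_real_
  if (!is.na(med_role) && nzchar(tr) && nchar(tr) < 0.5 * med_role)
    is_trunc <- TRUE
  data.frame(feature_id = feature$feature_id, role = role,
             evidence = evidence, identity = identity,
             is_truncated = is_trunc,
             is_pseudo = isTRUE(feature$is_pseudo),
             stringsAsFactors = FALSE)
}

#' Role table for a detected cluster
#'
#' Applies [assign_role()] to every member gene, in feature order.
#'
#' @param cluster a cluster from [detect_clusters()].
#' @param genome its [genome_record()].
#' @param ref_lib reference library.
#' @param params a [scoring_params()].
#' @return data.frame with one row per member, plus `cluster_id`, `start`,
#'   `end`, `strand`.
#' @export
assign_cluster_roles <- function(cluster, genome, ref_lib,
                                 params = scoring_params()) {
  f <- genome$features
  rows <- lapply(cluster$member_ids, function(id) {
    i <- match(id, f$feature_id)
    r <- assign_role(f[i, ], ref_lib, params = params)
    cbind(data.frame(cluster_id = cluster$cluster_id,
                     stringsAsFactors = FALSE),
          r,
          data.frame(start = f$start[i], end = f$end[i],
                     strand = f$strand[i], stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Classify a glycosyltransferase into a CAZy-style family
#'
#' Two independent methods vote: (1) best-hit -- top-scoring alignment to the
#' family-labeled GT references (identity > 30, reference coverage >= 50);
#' (2) k-mer profile -- the family whose concatenated references share the
#' largest fraction of the protein's distinct 4-mers, requiring containment
#' >= `min_containment`. A family is assigned only when both methods agree;
#' otherwise the call is `unknown` (`method_agreement` < 2 never yields a
#' labeled family).
#'
#' @param seq amino-acid sequence of the GT candidate.
#' @param gt_lib reference library rows with role `GT` and a `family` tag.
#' @param params a [scoring_params()].
#' @param min_containment minimum 4-mer containment for the k-mer vote.
#' @return list with `family` and `method_agreement`.
#' @export
classify_gt <- function(seq, gt_lib, params = scoring_params(),
                        min_containment = 0.2) {
  gt_lib <- gt_lib[gt_lib$role == "GT" & !is.na(gt_lib$family), , drop = FALSE]
  if (!nrow(gt_lib)) stop("empty GT reference library")
  hit <- best_reference_hit(seq, gt_lib, params)
  fam_hit <- if (!is.null(hit)) hit$family else NA_character_

  q_kmers <- aa_kmers(seq, 4L)
  fams <- unique(gt_lib$family)
  containment <- vapply(fams, function(fm) {
    ref_kmers <- unique(unlist(lapply(gt_lib$seq[gt_lib$family == fm],
                                      aa_kmers_cached, k = 4L)))
    if (!length(q_kmers)) return(0)
    shared_kmer_count(q_kmers, ref_kmers) / length(q_kmers)
  }, numeric(1))
  fam_kmer <- if (max(containment) >= min_containment)
    fams[which.max(containment)] else NA_character_

  agree <- !is.na(fam_hit) && !is.na(fam_kmer) && fam_hit == fam_kmer
  # method_agreement is the vote count of the best-supported family (2 only
  # when both methods concur; a labeled family is never returned otherwise)
  list(family = if (agree) fam_hit else "unknown",
       method_agreement = if (agree) 2L
         else as.integer(!is.na(fam_hit) || !is.na(fam_kmer)))
}

#' GT family calls for all GT/EpsE genes of a role table
#'
#' @param role_table output of [assign_cluster_roles()] (any number of
#'   clusters).
#' @param proteins named amino-acid sequences keyed by feature_id.
#' @param gt_lib GT reference rows.
#' @param params a [scoring_params()].
#' @return data.frame `cluster_id feature_id family method_agreement`.
#' @export
classify_gt_table <- function(role_table, proteins, gt_lib,
                              params = scoring_params()) {
  idx <- which(role_table$role %in% c("GT", "EpsE") & !role_table$is_pseudo)
  rows <- lapply(idx, function(i) {
    fid <- role_table$feature_id[i]
    if (is.na(proteins[fid]) || !nzchar(proteins[[fid]])) return(NULL)
    call <- classify_gt(proteins[[fid]], gt_lib, params)
    data.frame(cluster_id = role_table$cluster_id[i], feature_id = fid,
               family = call$family,
               method_agreement = call$method_agreement,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(cluster_id = character(), feature_id = character(),
                      family = character(), method_agreement = integer()))
  do.call(rbind, rows)
}

#' Precursor-enzyme inventory of a cluster
#'
#' @param role_table role rows of one cluster.
#' @return list with `counts` (named integer vector per enzyme) and
#'   `rml_operon_complete` (all of rmlA-D present).
#' @export
inventory_precursors <- function(role_table) {
  prec <- role_table$role[startsWith(role_table$role, "Precursor:")]
  enz <- sub("^Precursor:", "", prec)
  counts <- if (length(enz)) table(enz) else integer(0)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       rml_operon_complete = all(c("rmlA", "rmlB", "rmlC", "rmlD") %in% enz))
}
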
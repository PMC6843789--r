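# Synthetic genomes, reference libraries and habitat metadata with the
# statistical structure the analysis assumes, plus a machine-readable truth
# table. The generator emulates: multi-gene EPS clusters with the generic
# epsABCDE -> gt... -> wzx -> wzy layout and shuffled/incomplete variants;
# lower GC in gt/wzx/wzy than the genome background; transposase insertions
# biased toward wzx; and per-habitat protein-family pools whose divergence
# levels straddle the 50%-identity strict-family cut-off.

# background amino-acid frequencies (roughly bacterial averages)
.aa_alphabet <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V")
.aa_freq <- c(A=.085,R=.050,N=.040,D=.053,C=.012,Q=.038,E=.061,G=.072,
              H=.021,I=.065,L=.100,K=.058,M=.023,F=.042,P=.041,S=.060,
              T=.055,W=.013,Y=.032,V=.079)

.hydro_alpha <- c("I","L","V","F","A","M")
.hydro_freq  <- c(.25,.25,.20,.12,.10,.08)
.loop_in_alpha <- c("K","R","D","E","S","N","G","P")
.loop_in_freq  <- c(.28,.28,.07,.07,.10,.08,.07,.05)
.loop_out_alpha <- c("D","E","S","N","Q","G","T","P")
.loop_out_freq  <- rep(1/8, 8)

#' Random protein sequence
#'
#' Draws from background amino-acid frequencies; the first residue is always
#' methionine.
#'
#' @param length protein length (residues).
#' @return amino-acid string.
#' @export
random_protein <- function(length) {
  aas <- sample(.aa_alphabet, length, replace = TRUE, prob = .aa_freq)
  aas[1] <- "M"
  paste(aas, collapse = "")
}

#' Mutate a protein to a target identity
#'
#' Introduces exactly `ceiling((1 - target_identity) * L)` substitutions at
#' uniformly random positions; replacement residues are BLOSUM62-biased
#' (weights 2^score over the 19 alternatives), or drawn from per-position
#' class alphabets when `classes` is given (used to preserve transmembrane
#' architecture). No indels are introduced unless `indels > 0`, in which case
#' that many single-residue insertions/deletions are added at random
#' positions.
#'
#' @param seq amino-acid string.
#' @param target_identity in (0.05, 1].
#' @param classes optional per-position class vector (`"H"` helix, `"LI"`
#'   inside loop, `"LO"` outside loop, `NA` unconstrained).
#' @param indels optional count of single-residue indels.
#' @return mutated amino-acid string.
#' @export
mutate_protein <- function(seq, target_identity, classes = NULL, indels = 0L) {
  if (target_identity <= 0.05 || target_identity > 1)
    stop("target_identity must be in (0.05, 1]")
  L <- nchar(seq)
  k <- ceiling((1 - target_identity) * L)
  aa <- strsplit(seq, "")[[1]]
  if (k > 0) {
    pos <- sample.int(L, k)
    blos <- blosum62_x0()
    for (p in pos) {
      orig <- aa[p]
      cls <- if (!is.null(classes)) classes[p] else NA
      if (!is.na(cls)) {
        alpha <- switch(cls, H = .hydro_alpha, LI = .loop_in_alpha,
                        LO = .loop_out_alpha, .aa_alphabet)
        freq <- switch(cls, H = .hydro_freq, LI = .loop_in_freq,
                       LO = .loop_out_freq, .aa_freq)
        keep <- alpha != orig
        aa[p] <- sample(alpha[keep], 1, prob = freq[keep])
      } else {
        others <- setdiff(.aa_alphabet, orig)
        w <- 2^blos[orig, others]
        aa[p] <- sample(others, 1, prob = w)
      }
    }
  }
  if (indels > 0L) {
    for (i in seq_len(indels)) {
      if (stats::runif(1) < 0.5 && length(aa) > 10) {
        aa <- aa[-sample.int(length(aa), 1)]
      } else {
        at <- sample.int(length(aa), 1)
        ins <- sample(.aa_alphabet, 1, prob = .aa_freq)
        aa <- append(aa, ins, after = at)
      }
    }
  }
  paste(aa, collapse = "")
}

# ---------------------------------------------------------------------------
# transmembrane architecture

#' Build a transmembrane protein architecture
#'
#' Alternating hydrophobic helices (fixed length) and hydrophilic loops;
#' cytoplasmic ("inside") loops are lysine/arginine-rich per the
#' positive-inside rule, with an inside N-terminal tail. Returns the sequence
#' together with a per-position class vector used for architecture-preserving
#' mutation.
#'
#' @param n_helices helix count.
#' @param helix_len,loop_len,tail_n,tail_c segment lengths (residues).
#' @return list `seq`, `classes`, `n_helices`.
#' @export
tm_architecture <- function(n_helices, helix_len = 21L, loop_len = 9L,
                            tail_n = 15L, tail_c = 12L) {
  piece <- function(n, cls) {
    alpha <- switch(cls, H = .hydro_alpha, LI = .loop_in_alpha,
                    LO = .loop_out_alpha)
    freq <- switch(cls, H = .hydro_freq, LI = .loop_in_freq,
                   LO = .loop_out_freq)
    list(seq = paste(sample(alpha, n, replace = TRUE, prob = freq),
                     collapse = ""),
         classes = rep(cls, n))
  }
  parts <- list(piece(tail_n, "LI"))
  for (h in seq_len(n_helices)) {
    parts[[length(parts) + 1L]] <- piece(helix_len, "H")
    if (h < n_helices) {
      # loop after helix h: outside when h is odd (N-terminus inside)
      parts[[length(parts) + 1L]] <-
        piece(loop_len, if (h %% 2L == 1L) "LO" else "LI")
    }
  }
  c_cls <- if (n_helices %% 2L == 0L) "LI" else "LO"
  parts[[length(parts) + 1L]] <- piece(tail_c, c_cls)
  list(seq = paste(vapply(parts, `[[`, character(1), "seq"), collapse = ""),
       classes = unlist(lapply(parts, `[[`, "classes")),
       n_helices = n_helices)
}

# derive an n-helix variant of a TM archetype by truncating to its first n
# helices and rebuilding the C-tail, then mutating within classes
tm_derive <- function(arch, n_helices, target_identity) {
  if (n_helices > arch$n_helices)
    stop("cannot derive more helices than the archetype has")
  # boundaries of each helix in the archetype
  helix_idx <- which(arch$classes == "H")
  breaks <- which(diff(helix_idx) > 1)
  helix_ends <- helix_idx[c(breaks, length(helix_idx))]
  cut_at <- helix_ends[n_helices]
  seq <- substr(arch$seq, 1, cut_at)
  classes <- arch$classes[1:cut_at]
  c_cls <- if (n_helices %% 2L == 0L) "LI" else "LO"
  alpha <- if (c_cls == "LI") .loop_in_alpha else .loop_out_alpha
  freq <- if (c_cls == "LI") .loop_in_freq else .loop_out_freq
  tail_c <- paste(sample(alpha, 12L, replace = TRUE, prob = freq),
                  collapse = "")
  seq <- paste0(seq, tail_c)
  classes <- c(classes, rep(c_cls, 12L))
  list(seq = mutate_protein(seq, target_identity, classes = classes),
       classes = classes, n_helices = n_helices)
}

# ---------------------------------------------------------------------------
# GC-targeted back-translation

codon_tables <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc11 <- Biostrings::getGeneticCode("11")
    codons <- names(gc11)[gc11 != "*"]
    aa <- gc11[gc11 != "*"]
    gc_count <- vapply(codons, function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")), integer(1))
    .pkg_cache$codons <- list(by_aa = split(codons, aa),
                              gc = stats::setNames(gc_count, codons))
  }
  .pkg_cache$codons
}

#' Back-translate a protein with GC-targeted codon choice
#'
#' Per-residue codons are sampled with weights exp(lambda * GC(codon)),
#' lambda solved so the expected coding GC equals `target_gc` (clamped to the
#' achievable range for the amino-acid sequence); a synonymous-swap repair
#' pass then nudges the realized GC to within `tol` of the target. A TAA stop
#' codon is appended.
#'
#' @param protein amino-acid string.
#' @param target_gc desired GC fraction of the coding sequence.
#' @param tol repair tolerance on the realized GC.
#' @return DNA string (length `3 * (nchar(protein) + 1)`).
#' @export
back_translate <- function(protein, target_gc, tol = 0.005) {
  ct <- codon_tables()
  aa <- strsplit(protein, "")[[1]]
  choices <- lapply(aa, function(a) {
    cods <- ct$by_aa[[a]]
    if (is.null(cods)) stop("cannot back-translate residue ", a)
    cods
  })
  gcs <- lapply(choices, function(cods) ct$gc[cods])
  lo <- sum(vapply(gcs, min, numeric(1))) / (3 * length(aa))
  hi <- sum(vapply(gcs, max, numeric(1))) / (3 * length(aa))
  tgt <- min(max(target_gc, lo), hi)
  expected_gc <- function(lambda) {
    e <- vapply(gcs, function(g) {
      w <- exp(lambda * g)
      sum(w * g) / sum(w)
    }, numeric(1))
    sum(e) / (3 * length(aa))
  }
  # solve for lambda; when the target sits at (or beyond) the achievable
  # boundary the bracket has no sign change and the extreme lambda is used
  f <- function(l) expected_gc(l) - tgt
  lambda <- if (abs(f(0)) < 1e-12) 0
    else if (f(0) > 0) { if (f(-30) >= 0) -30 else
      stats::uniroot(f, c(-30, 0))$root }
    else { if (f(30) <= 0) 30 else stats::uniroot(f, c(0, 30))$root }
  picked <- vapply(seq_along(aa), function(i) {
    g <- gcs[[i]]
    w <- exp(lambda * g)
    sample(choices[[i]], 1, prob = w)
  }, character(1))
  # repair pass: greedy synonymous swaps toward the target
  total_nt <- 3 * length(aa)
  cur <- sum(ct$gc[picked])
  goal <- tgt * total_nt
  order_idx <- sample(seq_along(aa))
  for (i in order_idx) {
    if (abs(cur - goal) <= tol * total_nt) break
    g_now <- ct$gc[[picked[i]]]
    alts <- choices[[i]]
    g_alt <- ct$gc[alts]
    want_up <- cur < goal
    cand <- if (want_up) alts[g_alt > g_now] else alts[g_alt < g_now]
    if (!length(cand)) next
    newc <- cand[which.min(abs((cur - g_now + ct$gc[cand]) - goal))]
    cur <- cur - g_now + ct$gc[[newc]]
    picked[i] <- newc
  }
  paste0(paste(picked, collapse = ""), "TAA")
}

#' Random DNA at a given GC content
#' @param n length in nucleotides.
#' @param gc GC fraction.
#' @return DNA string.
#' @export
random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---------------------------------------------------------------------------
# simulation configuration

#' Simulation configuration
#'
#' Defaults define the package's standard synthetic study conditions:
#' 20 genomes; habitat mix host-adapted/nomadic/free-living = 0.4/0.4/0.2;
#' strain cluster counts drawn from (1,2,3,4) with probabilities
#' (0.65, 0.25, 0.09, 0.01); background GC 0.42 with a -0.10 offset for
#' gt/wzx/wzy genes; template mix generic/shuffled/incomplete =
#' 0.30/0.35/0.35; per-habitat family pools diverged ~50% from the role
#' archetypes (members at 90% of their family founder), straddling the
#' 50%-identity strict-family cut-off; transposase insertion rate 0.25 with
#' 0.6 placement bias toward wzx; GT CAZy archetypes partitioned across
#' habitats.
#'
#' @param n_genomes number of strains.
#' @param seed mandatory RNG seed.
#' @param ... overrides of any default listed above (see the returned list).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 20L, seed, ...) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    seed = as.integer(seed),
    genome_gc = 0.42,
    eps_gc_offset = -0.10,
    n_housekeeping = 25L,
    habitat_props = c("host-adapted" = 0.4, "nomadic" = 0.4,
                      "free-living" = 0.2),
    cluster_count_probs = c(0.65, 0.25, 0.09, 0.01),
    template_probs = c(generic = 0.30, shuffled = 0.35, incomplete = 0.35),
    dropout = c(epsA = 0.3, epsB = 0.3, epsC = 0.3, epsD = 0.3, epsE = 0.15,
                wzx = 0.2, wzy = 0.5),
    transposase_rate = 0.25,
    transposase_wzx_bias = 0.6,
    hypothetical_rate = 0.15,
    pseudo_rate = 0.05,
    truncation_rate = 0.05,
    multi_wzx_rate = 0.08,
    plasmid_rate = 0.05,
    founder_identity = 0.5,
    tm_founder_identity = 0.45,
    gt_founder_identity = 0.8,
    within_identity = 0.9,
    spacer_range = c(20L, 120L),
    n_species_per_habitat = 2L,
    gt_families_by_habitat = list(
      "host-adapted" = c("GT2", "GT8"),
      "nomadic" = c("GT4", "GT32"),
      "free-living" = c("GT1", "GT14")),
    n_families = c(EpsA = 1L, EpsB = 2L, EpsC = 2L, EpsD = 1L, EpsE = 2L,
                   Wzx = 2L, Wzy = 2L))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(abs(sum(cfg$habitat_props) - 1) < 1e-9,
            abs(sum(cfg$cluster_count_probs) - 1) < 1e-9)
  structure(cfg, class = "sim_config")
}

# ---------------------------------------------------------------------------
# archetypes, reference library, family pools

.archetype_lengths <- c(EpsA = 310L, EpsB = 240L, EpsC = 230L, EpsD = 250L,
                        EpsE = 225L, GT = 300L, Transposase = 280L)
.precursor_lengths <- c("UDP-galactopyranose mutase" = 380L,
                        "UDP-glucose 4-epimerase" = 330L,
                        rmlA = 290L, rmlB = 350L, rmlC = 180L, rmlD = 290L,
                        "UDP-N-acetylglucosamine 2-epimerase" = 380L)

make_archetypes <- function(cfg) {
  arch <- list()
  for (r in c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE", "Transposase"))
    arch[[r]] <- random_protein(.archetype_lengths[[r]])
  gt_fams <- sort(unique(unlist(cfg$gt_families_by_habitat)))
  arch$GT <- stats::setNames(
    lapply(gt_fams, function(f) random_protein(.archetype_lengths[["GT"]])),
    gt_fams)
  arch$Precursor <- stats::setNames(
    lapply(names(.precursor_lengths),
           function(e) random_protein(.precursor_lengths[[e]])),
    names(.precursor_lengths))
  arch$Wzx <- tm_architecture(14L)
  arch$Wzy <- tm_architecture(12L)
  arch
}

archetypes_to_reference <- function(arch) {
  rows <- list(
    data.frame(id = paste0("ref_", c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE")),
               role = c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE"),
               family = NA_character_, enzyme = NA_character_, seed = TRUE,
               seq = unlist(arch[c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE")]),
               stringsAsFactors = FALSE),
    data.frame(id = paste0("ref_", names(arch$GT)), role = "GT",
               family = names(arch$GT), enzyme = NA_character_, seed = FALSE,
               seq = unlist(arch$GT), stringsAsFactors = FALSE),
    data.frame(id = c("ref_Wzx", "ref_Wzy"), role = c("Wzx", "Wzy"),
               family = NA_character_, enzyme = NA_character_, seed = FALSE,
               seq = c(arch$Wzx$seq, arch$Wzy$seq), stringsAsFactors = FALSE),
    data.frame(id = paste0("ref_prec", seq_along(arch$Precursor)),
               role = "Precursor", family = NA_character_,
               enzyme = names(arch$Precursor), seed = FALSE,
               seq = unlist(arch$Precursor), stringsAsFactors = FALSE),
    data.frame(id = "ref_Tnp", role = "Transposase", family = NA_character_,
               enzyme = NA_character_, seed = FALSE,
               seq = arch$Transposase, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-habitat family pools; each family carries a founder sequence (and
# classes for TM roles) from which cluster genes are mutated
make_family_pools <- function(cfg, arch) {
  habitats <- names(cfg$habitat_props)
  hab_abbrev <- c("host-adapted" = "HA", "nomadic" = "NO",
                  "free-living" = "FL")
  tm_counts <- list(
    Wzx = list(values = 10:14, probs = c(.08, .12, .15, .20, .45)),
    Wzy = list(values = 8:12, probs = c(.10, .15, .40, .20, .15)))
  pools <- list()
  for (hb in habitats) {
    ab <- hab_abbrev[[hb]]
    pool <- list()
    for (r in c("EpsA", "EpsB", "EpsC", "EpsD", "EpsE")) {
      pool[[r]] <- lapply(seq_len(cfg$n_families[[r]]), function(i) {
        list(family_id = sprintf("T:%s:%s:%d", ab, r, i), type = "plain",
             founder = mutate_protein(arch[[r]], cfg$founder_identity),
             role = r)
      })
    }
    for (r in c("Wzx", "Wzy")) {
      tc <- tm_counts[[r]]
      pool[[r]] <- lapply(seq_len(cfg$n_families[[r]]), function(i) {
        nh <- sample(tc$values, 1, prob = tc$probs)
        d <- tm_derive(arch[[r]], nh, cfg$tm_founder_identity)
        list(family_id = sprintf("T:%s:%s:%d", ab, r, i), type = "tm",
             founder = d$seq, classes = d$classes, n_helices = nh, role = r)
      })
    }
    pool$GT <- lapply(cfg$gt_families_by_habitat[[hb]], function(fam) {
      list(family_id = sprintf("T:%s:GT:%s", ab, fam), type = "plain",
           founder = mutate_protein(arch$GT[[fam]], cfg$gt_founder_identity),
           role = "GT", cazy = fam)
    })
    pool$Precursor <- stats::setNames(
      lapply(names(arch$Precursor), function(e) {
        list(family_id = sprintf("T:%s:Prec:%s", ab, e), type = "plain",
             founder = mutate_protein(arch$Precursor[[e]],
                                      cfg$founder_identity),
             role = paste0("Precursor:", e), enzyme = e)
      }), names(arch$Precursor))
    pools[[hb]] <- pool
  }
  # transposases are a single mobile pool shared by all habitats
  pools$Transposase <- list(family_id = "T:ALL:Transposase", type = "plain",
                            founder = mutate_protein(arch$Transposase, 0.9),
                            role = "Transposase")
  pools
}

# ---------------------------------------------------------------------------
# cluster instantiation

.role_products <- c(
  EpsA = "polysaccharide biosynthesis transcriptional regulator EpsA",
  EpsB = "tyrosine kinase modulator EpsB",
  EpsC = "capsular polysaccharide biosynthesis tyrosine kinase EpsC",
  EpsD = "phosphotyrosine phosphatase EpsD",
  EpsE = "priming glycosyltransferase EpsE",
  GT = "glycosyltransferase",
  Wzx = "polysaccharide flippase Wzx",
  Wzy = "polysaccharide polymerase Wzy",
  Transposase = "IS30 family transposase")

.precursor_products <- c(
  "UDP-galactopyranose mutase" = "UDP-galactopyranose mutase",
  "UDP-glucose 4-epimerase" = "UDP-glucose 4-epimerase GalE",
  rmlA = "glucose-1-phosphate thymidylyltransferase RmlA",
  rmlB = "dTDP-glucose 4,6-dehydratase RmlB",
  rmlC = "dTDP-4-dehydrorhamnose 3,5-epimerase RmlC",
  rmlD = "dTDP-4-dehydrorhamnose reductase RmlD",
  "UDP-N-acetylglucosamine 2-epimerase" = "UDP-N-acetylglucosamine 2-epimerase")

.housekeeping_products <- c(
  "ribosomal protein L3", "elongation factor Tu",
  "ABC transporter ATP-binding protein", "phosphoglycerate kinase",
  "enolase", "chaperone protein DnaK", "cell division protein FtsZ",
  "30S ribosomal protein S4", "alanine--tRNA ligase",
  "PTS sugar transporter subunit IIA")

# draw one cluster gene list (template instantiation); returns a list of
# gene specs: role, family_id, protein, classes, product, gc_offset,
# pseudo, truncated, n_helices, mutations
instantiate_cluster <- function(cfg, pool, tn_pool) {
  template <- sample(names(cfg$template_probs), 1, prob = cfg$template_probs)
  base <- c("epsA", "epsB", "epsC", "epsD", "epsE",
            rep("gt", sample(2:3, 1)), "wzx", "wzy")
  if (stats::runif(1) < cfg$multi_wzx_rate)
    base <- append(base, "wzx", after = which(base == "wzx")[1])
  # precursor block at the 3' end
  prec <- character(0)
  if (stats::runif(1) < 0.40) prec <- c(prec, "UDP-galactopyranose mutase")
  if (stats::runif(1) < 0.35) prec <- c(prec, "UDP-glucose 4-epimerase")
  if (stats::runif(1) < 0.20) prec <- c(prec, "rmlA", "rmlB", "rmlC", "rmlD")
  if (stats::runif(1) < 0.15)
    prec <- c(prec, "UDP-N-acetylglucosamine 2-epimerase")
  genes <- c(base, prec)

  if (template == "shuffled") {
    mv <- sample(c("epsA", "epsB", "epsC", "epsD", "epsE"), 1)
    i <- which(genes == mv)
    genes <- genes[-i]
    at <- sample(seq(which(genes == "wzx")[1], length(genes)), 1)
    genes <- append(genes, mv, after = at)
  } else if (template == "incomplete") {
    keep <- rep(TRUE, length(genes))
    for (g in names(cfg$dropout)) {
      idx <- which(genes == g)
      for (i in idx) if (stats::runif(1) < cfg$dropout[[g]]) keep[i] <- FALSE
    }
    # never drop every gt
    gt_idx <- which(genes == "gt")
    if (all(!keep[gt_idx])) keep[gt_idx[1]] <- TRUE
    genes <- genes[keep]
    if (length(genes) < 2) genes <- c(genes, "gt")
  }

  role_of <- function(g) switch(g, epsA = "EpsA", epsB = "EpsB",
                                epsC = "EpsC", epsD = "EpsD", epsE = "EpsE",
                                gt = "GT", wzx = "Wzx", wzy = "Wzy",
                                paste0("Precursor:", g))
  specs <- lapply(genes, function(g) {
    role <- role_of(g)
    fam <- if (startsWith(role, "Precursor:")) {
      pool$Precursor[[sub("^Precursor:", "", role)]]
    } else {
      fams <- pool[[role]]
      fams[[sample.int(length(fams), 1)]]
    }
    mut_target <- cfg$within_identity
    prot <- if (fam$type == "tm")
      mutate_protein(fam$founder, mut_target, classes = fam$classes)
    else mutate_protein(fam$founder, mut_target)
    product <- if (startsWith(role, "Precursor:"))
      .precursor_products[[sub("^Precursor:", "", role)]]
    else .role_products[[role]]
    list(role = role, family_id = fam$family_id, protein = prot,
         product = product,
         gc_offset = if (role %in% c("GT", "Wzx", "Wzy"))
           cfg$eps_gc_offset else 0,
         pseudo = FALSE, truncated = FALSE,
         n_helices = fam$n_helices %||% NA_integer_,
         mutations = ceiling((1 - mut_target) * nchar(fam$founder)))
  })

  # optional mid-cluster hypothetical gene
  if (stats::runif(1) < cfg$hypothetical_rate && length(specs) >= 3) {
    at <- sample(seq_len(length(specs) - 1L)[-1], 1)
    specs <- append(specs, list(list(
      role = "Other", family_id = NA_character_,
      protein = random_protein(150L), product = "hypothetical protein",
      gc_offset = 0, pseudo = FALSE, truncated = FALSE,
      n_helices = NA_integer_, mutations = 0L)), after = at)
  }
  # transposase insertion, biased toward wzx
  if (stats::runif(1) < cfg$transposase_rate) {
    roles <- vapply(specs, `[[`, character(1), "role")
    wzx_at <- which(roles == "Wzx")
    at <- if (length(wzx_at) && stats::runif(1) < cfg$transposase_wzx_bias) {
      wzx_at[1] - sample(0:1, 1)   # immediately before or after wzx
    } else sample(0:length(specs), 1)
    specs <- append(specs, list(list(
      role = "Transposase", family_id = tn_pool$family_id,
      protein = mutate_protein(tn_pool$founder, cfg$within_identity),
      product = .role_products[["Transposase"]], gc_offset = 0,
      pseudo = FALSE, truncated = FALSE, n_helices = NA_integer_,
      mutations = ceiling((1 - cfg$within_identity) *
                            nchar(tn_pool$founder)))), after = at)
  }
  # pseudogene (prefer wzy, mirroring its frequent loss)
  if (stats::runif(1) < cfg$pseudo_rate) {
    roles <- vapply(specs, `[[`, character(1), "role")
    cand <- if ("Wzy" %in% roles) which(roles == "Wzy")[1] else
      sample(seq_along(specs), 1)
    specs[[cand]]$pseudo <- TRUE
  }
  # truncation of a duplicate gt
  roles <- vapply(specs, `[[`, character(1), "role")
  gt_at <- which(roles == "GT")
  if (length(gt_at) >= 2 && stats::runif(1) < cfg$truncation_rate) {
    i <- gt_at[length(gt_at)]
    p <- specs[[i]]$protein
    specs[[i]]$protein <- substr(p, 1, floor(0.4 * nchar(p)))
    specs[[i]]$truncated <- TRUE
  }
  list(template = template, specs = specs,
       strand = sample(c("+", "-"), 1))
}

# ---------------------------------------------------------------------------
# genome assembly

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character(0)
  env$len <- 0L
  env$features <- list()
  env
}

builder_spacer <- function(b, cfg) {
  n <- sample(seq(cfg$spacer_range[1], cfg$spacer_range[2]), 1)
  b$parts <- c(b$parts, random_dna(n, cfg$genome_gc))
  b$len <- b$len + n
}

builder_gene <- function(b, cfg, feature_id, protein, product, strand,
                         gc_target, pseudo = FALSE) {
  cds <- back_translate(protein, gc_target)
  genomic <- if (strand == "-") reverse_complement(cds) else cds
  start <- b$len
  b$parts <- c(b$parts, genomic)
  b$len <- b$len + nchar(genomic)
  b$features[[length(b$features) + 1L]] <-
    list(feature_id = feature_id, start = start, end = b$len, strand = strand,
         translation = protein, product = product, is_pseudo = pseudo)
  invisible(b)
}

builder_record <- function(b, record_id, strain, species, replicon) {
  f <- do.call(rbind, lapply(b$features, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  feats <- if (is.null(f)) gene_features() else
    gene_features(f$feature_id, f$start, f$end, f$strand, f$translation,
                  f$product, f$is_pseudo)
  genome_record(record_id, strain = strain, species = species,
                replicon_kind = replicon,
                sequence = paste(b$parts, collapse = ""), features = feats)
}

# append one instantiated cluster to a builder; returns truth genes
append_cluster_genes <- function(b, cfg, inst, strain, counter_env) {
  specs <- inst$specs
  if (inst$strand == "-") specs <- rev(specs)   # genomic order of a - operon
  truth_genes <- list()
  for (sp in specs) {
    counter_env$i <- counter_env$i + 1L
    fid <- sprintf("%s_g%03d", strain, counter_env$i)
    builder_gene(b, cfg, fid, sp$protein, sp$product, inst$strand,
                 cfg$genome_gc + sp$gc_offset, pseudo = sp$pseudo)
    truth_genes[[length(truth_genes) + 1L]] <-
      list(feature_id = fid, role = sp$role, family_id = sp$family_id,
           gc_target = cfg$genome_gc + sp$gc_offset,
           pseudo = sp$pseudo, truncated = sp$truncated,
           n_helices = sp$n_helices, mutations = sp$mutations)
    builder_spacer(b, cfg)
  }
  if (inst$strand == "-") truth_genes <- rev(truth_genes)  # back to 5'->3'
  truth_genes
}

# truth-side generic call: first five non-transposase roles in operon order
truth_is_generic <- function(roles_5to3) {
  r <- roles_5to3[roles_5to3 != "Transposase"]
  length(r) >= 5 && identical(r[1:5], c("EpsA", "EpsB", "EpsC", "EpsD",
                                        "EpsE"))
}

truth_missing_essential <- function(genes_5to3) {
  ok_roles <- vapply(genes_5to3, function(g) {
    if (g$pseudo || g$truncated) "" else g$role
  }, character(1))
  names(.essential_roles)[!(.essential_roles %in% ok_roles)]
}

#' Plant one EPS cluster into a genome record
#'
#' Instantiates a cluster from the habitat's family pools (layout template,
#' strand, optional transposase/hypothetical insertions) and appends its
#' back-translated genes, with 20-120 nt spacers, to the record sequence.
#'
#' @param record a [genome_record()].
#' @param cfg a [sim_config()].
#' @param pools family pools from the generator (see [generate_run()]).
#' @param habitat habitat whose pools to draw from.
#' @return list `record` (updated) and `truth` (cluster truth entry).
#' @export
plant_cluster <- function(record, cfg, pools, habitat) {
  if (nchar(record$sequence) < 1L) stop("genome record too short")
  inst <- instantiate_cluster(cfg, pools[[habitat]], pools$Transposase)
  b <- new_builder()
  b$parts <- record$sequence
  b$len <- nchar(record$sequence)
  b$features <- lapply(seq_len(nrow(record$features)), function(i)
    as.list(record$features[i, ]))
  builder_spacer(b, cfg)
  counter_env <- new.env(); counter_env$i <- nrow(record$features)
  truth_genes <- append_cluster_genes(b, cfg, inst, record$strain,
                                      counter_env)
  rec <- builder_record(b, record$record_id, record$strain, record$species,
                        record$replicon_kind)
  roles <- vapply(truth_genes, `[[`, character(1), "role")
  truth <- list(strain = record$strain, record_id = record$record_id,
                habitat = habitat, template = inst$template,
                strand = inst$strand,
                member_feature_ids = vapply(truth_genes, `[[`, character(1),
                                            "feature_id"),
                roles_5to3 = roles,
                is_generic = truth_is_generic(roles),
                missing_essential = truth_missing_essential(truth_genes),
                genes = truth_genes)
  list(record = rec, truth = truth)
}

# build one strain's records (chromosome, maybe plasmid) with planted
# clusters interleaved among housekeeping genes
generate_strain <- function(cfg, strain, species, habitat, pools, hk_pool) {
  n_clusters <- sample(1:4, 1, prob = cfg$cluster_count_probs)
  on_plasmid <- n_clusters >= 1 && stats::runif(1) < cfg$plasmid_rate
  n_chrom <- n_clusters - as.integer(on_plasmid)

  counter_env <- new.env(); counter_env$i <- 0L
  hk_gene <- function(b) {
    counter_env$i <- counter_env$i + 1L
    fid <- sprintf("%s_g%03d", strain, counter_env$i)
    src <- hk_pool[[sample.int(length(hk_pool), 1)]]
    builder_gene(b, cfg, fid, mutate_protein(src$protein, 0.95),
                 src$product, sample(c("+", "-"), 1), cfg$genome_gc)
    builder_spacer(b, cfg)
  }

  # choose insertion slots, separated by at least 4 housekeeping genes
  slots <- integer(0)
  if (n_chrom > 0) {
    cand <- 2:(cfg$n_housekeeping - 2L)
    while (TRUE) {
      slots <- sort(sample(cand, n_chrom))
      if (n_chrom == 1 || min(diff(slots)) >= 4L) break
    }
  }

  truths <- list()
  b <- new_builder()
  builder_spacer(b, cfg)
  for (i in seq_len(cfg$n_housekeeping)) {
    hk_gene(b)
    if (i %in% slots) {
      inst <- instantiate_cluster(cfg, pools[[habitat]], pools$Transposase)
      truth_genes <- append_cluster_genes(b, cfg, inst, strain, counter_env)
      roles <- vapply(truth_genes, `[[`, character(1), "role")
      truths[[length(truths) + 1L]] <-
        list(strain = strain, record_id = paste0(strain, "_chr"),
             habitat = habitat, template = inst$template,
             strand = inst$strand,
             member_feature_ids = vapply(truth_genes, `[[`, character(1),
                                         "feature_id"),
             roles_5to3 = roles,
             is_generic = truth_is_generic(roles),
             missing_essential = truth_missing_essential(truth_genes),
             genes = truth_genes)
    }
  }
  records <- list(builder_record(b, paste0(strain, "_chr"), strain, species,
                                 "chromosome"))
  if (on_plasmid) {
    bp <- new_builder()
    builder_spacer(bp, cfg)
    for (i in 1:4) hk_gene(bp)
    inst <- instantiate_cluster(cfg, pools[[habitat]], pools$Transposase)
    truth_genes <- append_cluster_genes(bp, cfg, inst, strain, counter_env)
    for (i in 1:2) hk_gene(bp)
    roles <- vapply(truth_genes, `[[`, character(1), "role")
    truths[[length(truths) + 1L]] <-
      list(strain = strain, record_id = paste0(strain, "_p1"),
           habitat = habitat, template = inst$template, strand = inst$strand,
           member_feature_ids = vapply(truth_genes, `[[`, character(1),
                                       "feature_id"),
           roles_5to3 = roles,
           is_generic = truth_is_generic(roles),
           missing_essential = truth_missing_essential(truth_genes),
           genes = truth_genes)
    records[[2]] <- builder_record(bp, paste0(strain, "_p1"), strain,
                                   species, "plasmid")
  }
  list(records = records, clusters = truths)
}

#' Generate a full synthetic run
#'
#' Deterministic given the config seed. Produces genomes (with planted EPS
#' clusters), the strain-habitat table, the role-tagged reference library
#' and the truth table; optionally writes everything (GenBank per strain,
#' habitat TSV, reference FASTA, truth JSON) to `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return (invisibly when writing) list of class `sim_run`: `records`
#'   (named by record_id), `habitat_table`, `ref_lib`, `truth`, `config`.
#' @export
generate_run <- function(cfg, out_dir = NULL) {
  run <- with_seed(cfg$seed, {
    arch <- make_archetypes(cfg)
    ref_lib <- archetypes_to_reference(arch)
    pools <- make_family_pools(cfg, arch)
    hk_pool <- lapply(seq_len(30L), function(i) {
      list(protein = random_protein(sample(180:330, 1)),
           product = .housekeeping_products[
             ((i - 1L) %% length(.housekeeping_products)) + 1L])
    })
    habitats <- names(cfg$habitat_props)
    species_names <- unlist(lapply(seq_along(habitats), function(h) {
      sprintf("Lactobacillus synth%02d",
              (h - 1L) * cfg$n_species_per_habitat +
                seq_len(cfg$n_species_per_habitat))
    }))
    species_habitat <- rep(habitats, each = cfg$n_species_per_habitat)
    strain_ids <- sprintf("S%03d", seq_len(cfg$n_genomes))
    # exact proportional allocation (largest-remainder), then shuffled:
    # the configured habitat mix is a study condition, not a sampling rate
    quota <- cfg$habitat_props * cfg$n_genomes
    counts <- floor(quota)
    rem <- cfg$n_genomes - sum(counts)
    if (rem > 0) {
      extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    strain_habitat <- sample(rep(habitats, counts))
    strain_species <- vapply(strain_habitat, function(hb) {
      sample(species_names[species_habitat == hb], 1)
    }, character(1))
    habitat_table <- data.frame(strain = strain_ids,
                                species = strain_species,
                                habitat = strain_habitat,
                                stringsAsFactors = FALSE)
    class(habitat_table) <- c("habitat_table", class(habitat_table))

    records <- list(); clusters <- list()
    for (i in seq_len(cfg$n_genomes)) {
      g <- generate_strain(cfg, strain_ids[i], strain_species[i],
                           strain_habitat[i], pools, hk_pool)
      for (r in g$records) records[[r$record_id]] <- r
      clusters <- c(clusters, g$clusters)
    }
    truth <- list(clusters = clusters,
                  proteins = truth_protein_table(clusters))
    list(records = records, habitat_table = habitat_table,
         ref_lib = ref_lib, truth = truth, config = cfg, pools = pools)
  })
  class(run) <- "sim_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (strain in unique(run$habitat_table$strain)) {
      recs <- Filter(function(r) r$strain == strain, run$records)
      write_genbank(recs, file.path(out_dir, paste0(strain, ".gbk")))
    }
    ht <- run$habitat_table; class(ht) <- "data.frame"
    write_tsv(ht, file.path(out_dir, "habitat.tsv"))
    write_reference_fasta(run$ref_lib, file.path(out_dir, "reference.fasta"))
    jsonlite::write_json(run$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(run))
  }
  run
}

truth_protein_table <- function(clusters) {
  rows <- lapply(clusters, function(cl) {
    data.frame(feature_id = vapply(cl$genes, `[[`, character(1), "feature_id"),
               role = vapply(cl$genes, `[[`, character(1), "role"),
               family_id = vapply(cl$genes, function(g)
                 g$family_id %||% NA_character_, character(1)),
               mutations = vapply(cl$genes, function(g)
                 as.integer(g$mutations), integer(1)),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(data.frame(feature_id = character(),
                                       role = character(),
                                       family_id = character(),
                                       mutations = integer()))
  do.call(rbind, rows)
}

#' Plant k protein families for family-recovery benchmarks
#'
#' Family founders: the first is random; each further founder is a mutated
#' copy of the first at `between` identity. Members are mutated copies of
#' their founder at `within` identity.
#'
#' @param k number of families.
#' @param members_per_family members per family.
#' @param within,between target identities.
#' @param length protein length.
#' @param seed RNG seed.
#' @return list `proteins` (named vector) and `truth` (named family index).
#' @export
plant_protein_families <- function(k, members_per_family = 3L, within = 0.85,
                                   between = 0.25, length = 200L, seed = 1L) {
  with_seed(seed, {
    f1 <- random_protein(length)
    founders <- c(list(f1), lapply(seq_len(k - 1L), function(i)
      mutate_protein(f1, between)))
    proteins <- character(0); truth <- integer(0)
    for (i in seq_len(k)) {
      for (j in seq_len(members_per_family)) {
        nm <- sprintf("fam%02d_m%02d", i, j)
        proteins[nm] <- mutate_protein(founders[[i]], within)
        truth[nm] <- i
      }
    }
    list(proteins = proteins, truth = truth)
  })
}
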
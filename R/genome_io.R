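# Genome input/output: GenBank flat files, GFF3+FASTA, habitat metadata,
# GC content, and a JSON dump of the internal model.
#
# Internal model
#  - a genome record is a list (class "genome_record") with fields
#    record_id, strain, species, replicon_kind, sequence and a features
#    data.frame (feature_id, start, end, strand, translation, product,
#    is_pseudo), sorted by start.  Coordinates are 0-based half-open; GenBank's
#    1-based inclusive coordinates are converted at the parsing boundary.

#' Construct a gene-feature table
#'
#' @param feature_id,start,end,strand,translation,product,is_pseudo parallel
#'   vectors describing CDS features. Coordinates are 0-based half-open.
#' @return a data.frame sorted by `start`.
#' @export
gene_features <- function(feature_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          translation = character(), product = character(),
                          is_pseudo = logical()) {
  df <- data.frame(feature_id = as.character(feature_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   translation = as.character(translation),
                   product = as.character(product),
                   is_pseudo = as.logical(is_pseudo),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$end > df$start), all(df$strand %in% c("+", "-")))
    if (anyDuplicated(df$feature_id))
      stop("duplicate feature_id within record")
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Construct a genome record
#'
#' @param record_id unique record identifier.
#' @param strain,species strain and species labels.
#' @param replicon_kind one of `"chromosome"`, `"plasmid"`, `"unknown"`.
#' @param sequence DNA string over A/C/G/T/N.
#' @param features a [gene_features()] data.frame.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(record_id, strain = "", species = "",
                          replicon_kind = c("chromosome", "plasmid", "unknown"),
                          sequence = "", features = gene_features()) {
  replicon_kind <- match.arg(replicon_kind)
  if (nrow(features) && any(features$end > nchar(sequence)))
    stop("feature interval outside sequence bounds in record ", record_id)
  structure(list(record_id = record_id, strain = strain, species = species,
                 replicon_kind = replicon_kind, sequence = sequence,
                 features = features),
            class = "genome_record")
}

#' @exportS3Method base::print
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s> %s (%s), %s, %d bp, %d features\n",
              x$record_id, x$strain, x$species, x$replicon_kind,
              nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# translation

#' Translate a CDS nucleotide sequence (bacterial table 11)
#'
#' Minus-strand sequences are reverse-complemented first; `phase` skips the
#' given number of leading nucleotides (GFF3 semantics). Incomplete trailing
#' codons are dropped with a warning, and a trailing stop is stripped.
#'
#' @param dna CDS nucleotide string (already excised from the genome).
#' @param strand `"+"` or `"-"`.
#' @param phase integer 0/1/2.
#' @return amino-acid string.
#' @export
translate_cds <- function(dna, strand = "+", phase = 0L) {
  if (strand == "-") dna <- reverse_complement(dna)
  if (phase > 0L) dna <- substr(dna, phase + 1L, nchar(dna))
  n <- nchar(dna)
  r <- n %% 3L
  if (r != 0L) {
    warning("CDS length not a multiple of 3; translating in-frame prefix")
    dna <- substr(dna, 1L, n - r)
  }
  if (nchar(dna) == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

# ---------------------------------------------------------------------------
# GC content

#' GC fraction of a DNA interval
#'
#' Computes (G+C)/(A+C+G+T) over the interval; `N` bases contribute to neither
#' numerator nor denominator. An interval with no A/C/G/T yields `NA`.
#'
#' @param sequence DNA string.
#' @param from,to optional 0-based half-open interval; defaults to the whole
#'   sequence.
#' @return fraction in \[0, 1\], or `NA_real_`.
#' @export
compute_gc <- function(sequence, from = NULL, to = NULL) {
  if (!is.null(from) || !is.null(to)) {
    from <- from %||% 0L
    to <- to %||% nchar(sequence)
    stopifnot(from >= 0, to <= nchar(sequence), to >= from)
    sequence <- substr(sequence, from + 1L, to)
  }
  if (nchar(sequence) == 0L) return(NA_real_)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  unname((f[["C"]] + f[["G"]]) / denom)
}

# ---------------------------------------------------------------------------
# GenBank flat file

#' Read a GenBank flat file
#'
#' Parses one [genome_record()] per LOCUS. CDS `/translation` qualifiers are
#' used verbatim; CDS without one are translated from the spanned sequence
#' (table 11). `/pseudo` sets `is_pseudo`. A record is called a plasmid when
#' its LOCUS or DEFINITION line contains the word "plasmid". Only simple
#' `start..end` and `complement(start..end)` locations are supported.
#'
#' @param path GenBank file path.
#' @return list of `genome_record`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    records[[i]] <- parse_genbank_record(lines[starts[i]:ends[i]])
  }
  records
}

parse_genbank_record <- function(lines) {
  locus_line <- lines[1]
  record_id <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]][1]

  # DEFINITION may wrap onto continuation lines
  def_i <- grep("^DEFINITION", lines)
  definition <- ""
  if (length(def_i)) {
    j <- def_i[1]
    parts <- sub("^DEFINITION\\s*", "", lines[j])
    j <- j + 1L
    while (j <= length(lines) && grepl("^\\s", lines[j])) {
      parts <- c(parts, trimws(lines[j])); j <- j + 1L
    }
    definition <- paste(parts, collapse = " ")
  }

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (!length(orig_i)) stop("GenBank record without ORIGIN: ", record_id)
  seq_end <- if (length(end_i)) end_i[1] - 1L else length(lines)
  seq_lines <- lines[(orig_i[1] + 1L):seq_end]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  strain <- ""; species <- ""
  feats <- list()
  if (length(feat_i)) {
    flines <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    blocks <- split_feature_blocks(flines)
    n_auto <- 0L
    for (b in blocks) {
      key <- b$key
      quals <- b$qualifiers
      if (key == "source") {
        strain <- quals[["strain"]] %||% strain
        species <- quals[["organism"]] %||% species
      } else if (key == "CDS") {
        loc <- parse_gb_location(b$location)
        n_auto <- n_auto + 1L
        fid <- quals[["locus_tag"]] %||% sprintf("%s_cds%03d", record_id, n_auto)
        is_pseudo <- isTRUE(quals[[".flag.pseudo"]])
        tr <- quals[["translation"]]
        if (is.null(tr)) {
          dna <- substr(sequence, loc$start + 1L, loc$end)
          tr <- if (nchar(dna)) translate_cds(dna, loc$strand) else ""
        }
        feats[[length(feats) + 1L]] <- list(
          feature_id = fid, start = loc$start, end = loc$end,
          strand = loc$strand, translation = tr,
          product = quals[["product"]] %||% "", is_pseudo = is_pseudo)
      }
    }
  }
  if (!length(feats))
    warning("record ", record_id, " has no CDS features")
  fdf <- if (length(feats)) {
    do.call(rbind, lapply(feats, function(f) as.data.frame(f, stringsAsFactors = FALSE)))
  } else gene_features()
  fdf <- gene_features(fdf$feature_id, fdf$start, fdf$end, fdf$strand,
                       fdf$translation, fdf$product, fdf$is_pseudo)
  replicon <- if (grepl("plasmid", paste(locus_line, definition),
                        ignore.case = TRUE)) "plasmid" else "chromosome"
  if (strain == "" && grepl("strain ([^ ,.]+)", definition))
    strain <- sub(".*strain ([^ ,.]+).*", "\\1", definition)
  genome_record(record_id, strain = strain, species = species,
                replicon_kind = replicon, sequence = sequence, features = fdf)
}

# split the FEATURES table into blocks of (key, location, qualifiers)
split_feature_blocks <- function(flines) {
  blocks <- list()
  cur <- NULL
  cur_qual <- NULL   # name of qualifier currently being continued
  flush_block <- function() if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  for (ln in flines) {
    if (!nzchar(trimws(ln))) next
    keyfield <- substr(ln, 6L, 20L)
    rest <- trimws(substr(ln, 21L, nchar(ln)))
    if (nzchar(trimws(keyfield))) {           # new feature
      flush_block()
      cur <- list(key = trimws(keyfield), location = rest, qualifiers = list())
      cur_qual <- NULL
    } else if (startsWith(rest, "/")) {       # qualifier
      if (is.null(cur)) stop("malformed FEATURES line: ", ln)
      q <- sub("^/", "", rest)
      if (grepl("=", q)) {
        name <- sub("=.*$", "", q)
        raw_val <- sub("^[^=]*=", "", q)
        open_quote <- grepl("^\"", raw_val) &&
          !grepl("\"$", raw_val) || raw_val == "\""
        cur$qualifiers[[name]] <- gsub("^\"|\"$", "", raw_val)
        cur_qual <- if (open_quote) name else NULL
      } else {
        cur$qualifiers[[paste0(".flag.", q)]] <- TRUE
        cur_qual <- NULL
      }
    } else {                                   # continuation line
      if (is.null(cur)) stop("malformed FEATURES line: ", ln)
      if (!is.null(cur_qual)) {
        val <- gsub("\"$", "", rest)
        sep <- if (cur_qual == "translation") "" else " "
        cur$qualifiers[[cur_qual]] <- paste0(cur$qualifiers[[cur_qual]], sep, val)
        if (grepl("\"$", rest)) cur_qual <- NULL
      } else {
        cur$location <- paste0(cur$location, rest)
      }
    }
  }
  flush_block()
  blocks
}

parse_gb_location <- function(loc) {
  raw <- loc
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order", loc))
    stop("unsupported compound location: ", raw)
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3L) stop("unparseable location: ", raw)
  list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]), strand = strand)
}

#' Write genome records as a GenBank flat file
#'
#' The inverse of [read_genbank()] for the internal model; emits one LOCUS per
#' record with source and CDS features.
#'
#' @param records list of `genome_record`.
#' @param path output file.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    n <- nchar(rec$sequence)
    repl_word <- switch(rec$replicon_kind, plasmid = " plasmid", "")
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2024",
                       rec$record_id, n), con)
    writeLines(sprintf("DEFINITION  %s strain %s%s, complete sequence.",
                       rec$species, rec$strain, repl_word), con)
    writeLines(sprintf("ACCESSION   %s", rec$record_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    writeLines(sprintf("                     /organism=\"%s\"", rec$species), con)
    writeLines(sprintf("                     /strain=\"%s\"", rec$strain), con)
    f <- rec$features
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", f$feature_id[i]), con)
      writeLines(sprintf("                     /product=\"%s\"", f$product[i]), con)
      if (f$is_pseudo[i]) writeLines("                     /pseudo", con)
      if (nzchar(f$translation[i])) {
        wrapped <- wrap_qualifier(sprintf("/translation=\"%s\"", f$translation[i]))
        writeLines(wrapped, con)
      }
    }
    writeLines("ORIGIN", con)
    pos <- 1L
    while (pos <= n) {
      chunk_end <- min(pos + 59L, n)
      chunk <- substr(rec$sequence, pos, chunk_end)
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", pos, paste(tolower(tens), collapse = " ")), con)
      pos <- chunk_end + 1L
    }
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(text, width = 58L, indent = 21L) {
  pad <- strrep(" ", indent)
  out <- character(0)
  while (nchar(text) > width) {
    out <- c(out, paste0(pad, substr(text, 1L, width)))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, paste0(pad, text))
}

# ---------------------------------------------------------------------------
# GFF3 + FASTA

#' Read a GFF3 annotation with its genomic FASTA
#'
#' Produces the same model as [read_genbank()]; CDS phase is respected during
#' translation. Every GFF3 seqid must be present in the FASTA.
#'
#' @param gff_path GFF3 file.
#' @param fasta_path genomic FASTA file.
#' @param strain,species optional labels applied to all records.
#' @return list of `genome_record`.
#' @export
read_gff_fasta <- function(gff_path, fasta_path, strain = "", species = "") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (length(gr)) {
    missing <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                       names(seqs))
    if (length(missing))
      stop("GFF3 seqids missing from FASTA: ", paste(missing, collapse = ", "))
  }
  records <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    sid <- names(seqs)[i]
    seq <- as.character(seqs[[i]])
    feats <- gene_features()
    if (length(gr)) {
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == sid &
                  as.character(gr$type) == "CDS"]
      if (length(sub)) {
        md <- S4Vectors::mcols(sub)
        fid <- if (!is.null(md$ID)) as.character(md$ID)
               else sprintf("%s_cds%03d", sid, seq_along(sub))
        product <- if (!is.null(md$product)) as.character(md$product) else
          rep("", length(sub))
        product[is.na(product)] <- ""
        pseudo <- if (!is.null(md$pseudo)) !is.na(md$pseudo) else
          rep(FALSE, length(sub))
        phase <- if (!is.null(md$phase)) {
          p <- suppressWarnings(as.integer(as.character(md$phase)))
          ifelse(is.na(p), 0L, p)
        } else rep(0L, length(sub))
        st <- GenomicRanges::start(sub) - 1L
        en <- GenomicRanges::end(sub)
        strnd <- as.character(GenomicRanges::strand(sub))
        strnd[strnd == "*"] <- "+"
        tr <- vapply(seq_along(sub), function(j) {
          translate_cds(substr(seq, st[j] + 1L, en[j]), strnd[j], phase[j])
        }, character(1))
        feats <- gene_features(fid, st, en, strnd, tr, product, pseudo)
      }
    }
    if (!nrow(feats))
      warning("no CDS features for seqid ", sid)
    records[[i]] <- genome_record(sid, strain = strain, species = species,
                                  replicon_kind = "unknown",
                                  sequence = seq, features = feats)
  }
  records
}

# ---------------------------------------------------------------------------
# habitat metadata

.habitats <- c("host-adapted", "nomadic", "free-living", "unknown")

#' Read a strain-habitat metadata table
#'
#' @param path TSV with header `strain`, `species`, `habitat`; habitat values
#'   must be one of host-adapted, nomadic, free-living, unknown.
#' @return data.frame of class `habitat_table`.
#' @export
read_habitat_table <- function(path) {
  df <- read_tsv(path)
  if (!all(c("strain", "species", "habitat") %in% names(df)))
    stop("habitat table needs columns strain, species, habitat")
  bad <- setdiff(unique(df$habitat), .habitats)
  if (length(bad))
    stop("unknown habitat values: ", paste(bad, collapse = ", "))
  class(df) <- c("habitat_table", class(df))
  df
}

#' Habitat of a strain (species fallback, never an error)
#'
#' Looks the strain up in the table; falls back to a species-level assignment;
#' unknown strains yield `"unknown"`.
#'
#' @param table a [read_habitat_table()] data.frame.
#' @param strain strain name(s).
#' @param species optional species name(s) for fallback.
#' @return character vector of habitats.
#' @export
habitat_of <- function(table, strain, species = NULL) {
  out <- table$habitat[match(strain, table$strain)]
  if (!is.null(species)) {
    sp_map <- table$habitat[match(species, table$species)]
    out[is.na(out)] <- sp_map[is.na(out)]
  }
  out[is.na(out)] <- "unknown"
  out
}

# ---------------------------------------------------------------------------
# JSON round trip of the internal model

#' Serialize genome records to JSON
#' @param records list of `genome_record`.
#' @param path output file.
#' @export
records_to_json <- function(records, path) {
  payload <- lapply(records, function(r) {
    list(record_id = r$record_id, strain = r$strain, species = r$species,
         replicon_kind = r$replicon_kind, sequence = r$sequence,
         features = r$features)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read genome records back from their JSON dump
#' @param path file written by [records_to_json()].
#' @return list of `genome_record`.
#' @export
records_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    f <- payload$features[[i]]
    feats <- if (is.null(f) || !length(f) || !NROW(f)) gene_features() else
      gene_features(f$feature_id, f$start, f$end, f$strand, f$translation,
                    f$product, f$is_pseudo)
    genome_record(payload$record_id[i], payload$strain[i], payload$species[i],
                  payload$replicon_kind[i], payload$sequence[i], feats)
  })
}
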
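# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

round1 <- function(x) round(x, 1)

#' Distinct amino-acid k-mers of a sequence
#' @noRd
aa_kmers <- function(seq, k = 4L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Count of k-mers of `a` also present in `b`
#' @noRd
shared_kmer_count <- function(kmers_a, kmers_b) sum(kmers_a %in% kmers_b)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

#' Evaluate `code` under a fixed RNG state, restoring the caller's state after
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of a DNA string (A/C/G/T/N)
#'
#' @param s character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  vapply(s, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}
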
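# Shared low-level helpers: alphabets, RNG fan-out, IUPAC handling,
# small sequence utilities used across modules.

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible per-stage seed from one master seed
#'
#' A single pipeline seed fans out to independent per-stage seeds so that
#' stages can be rerun in isolation yet reproducibly. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage stage name (character) or index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((abs(seed) * 48271 + stage * 16807) %% 2147483629L)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

resolve_submatrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  if (identical(matrix, "BLOSUM62")) return(blosum62())
  stop("unknown substitution matrix: ", matrix)
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

#' Random background nucleotide sequence with configurable GC content
#'
#' @param n length in bp.
#' @param gc GC fraction (default 0.40, AT-rich Firmicute-like background).
#' @return a character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.40) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

#' Expand an IUPAC nucleotide code into its concrete bases
#' @noRd
iupac_bases <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "", fixed = TRUE)[[1]]
}

#' Collapse a set of bases to the IUPAC letter covering them
#' @noRd
bases_to_iupac <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[vapply(map, function(m) {
    paste(sort(strsplit(m, "")[[1]]), collapse = "") == key
  }, logical(1))]
  if (length(hit) == 0) stop("no IUPAC code for bases: ", key)
  hit[1]
}

#' Draw one concrete instance of an IUPAC motif
#' @noRd
sample_iupac_instance <- function(motif) {
  paste(vapply(seq_chars(motif), function(ch) {
    sample(iupac_bases(ch), 1)
  }, character(1)), collapse = "")
}

#' Test whether a concrete sequence matches an IUPAC motif
#' @noRd
matches_iupac <- function(x, motif) {
  xs <- seq_chars(x)
  ms <- seq_chars(motif)
  if (length(xs) != length(ms)) return(FALSE)
  all(mapply(function(b, code) b %in% iupac_bases(code), xs, ms))
}

#' Modal value with explicit tie rule
#' @noRd
modal_value <- function(x, tie = c("min", "max")) {
  tie <- match.arg(tie)
  tab <- table(x)
  best <- as.numeric(names(tab)[tab == max(tab)])
  if (tie == "min") min(best) else max(best)
}

#' Mutate a protein sequence by i.i.d. per-site substitution
#'
#' Each non-exempt site is replaced, with probability `rate`, by a residue
#' drawn uniformly from the 19 alternatives. No indels.
#' @noRd
mutate_protein <- function(seq, rate, exempt = integer()) {
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, exempt)
  for (i in hit) {
    ch[i] <- sample(setdiff(AA_ALPHABET20, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Mutate a DNA sequence by i.i.d. per-site substitution
#' @noRd
mutate_dna <- function(seq, rate, exempt = integer()) {
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, exempt)
  for (i in hit) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Corrupt a consensus box with a per-base substitution probability
#' @noRd
corrupt_box <- function(box, prob) mutate_dna(box, prob)

as_dna_string <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

as_aa_set <- function(x) {
  if (is(x, "AAStringSet")) return(x)
  if (is.character(x)) return(Biostrings::AAStringSet(x))
  stop("expected an AAStringSet or named character vector")
}

#' Write a minimal GFF3 file from a feature data.frame
#'
#' Used for the synthetic truth table and TE annotations. Coordinates are
#' 1-based inclusive. Attribute columns (everything beyond the core eight)
#' are serialized as `key=value` pairs in column 9.
#' @noRd
write_gff3 <- function(df, path, source = "mulekit", type = "mobile_genetic_element") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  core <- c("genome_id", "start", "end", "strand")
  extra <- setdiff(names(df), core)
  for (i in seq_len(nrow(df))) {
    attrs <- paste(vapply(extra, function(k) {
      paste0(k, "=", as.character(df[[k]][i]))
    }, character(1)), collapse = ";")
    writeLines(paste(df$genome_id[i], source, type, df$start[i], df$end[i],
                     ".", df$strand[i], ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}
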
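# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based, half-open; on-disk interval output follows BED.

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' ACGTN). Thin wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGAGTTTTTGT"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a genome argument (named character vector, DNAStringSet, or FASTA
# path) to a named uppercase character vector.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
  } else if (is.character(genome) && length(genome) == 1L &&
             !grepl("^[ACGTNacgtn]*$", genome) && file.exists(genome)) {
    out <- toupper(as.character(Biostrings::readDNAStringSet(genome)))
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    abort("`genome` must be a named character vector, DNAStringSet, or FASTA path.")
  }
  if (length(out) > 0 && is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  # FASTA headers: keep the first word, as aligners do
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

# Hamming distance between two equal-length strings (vectorised over x).
hamming <- function(x, y) {
  stopifnot(length(y) == 1L || all(nchar(x) == nchar(y)))
  xm <- strsplit(x, "", fixed = TRUE)
  ym <- strsplit(y, "", fixed = TRUE)
  if (length(ym) == 1L) ym <- rep(ym, length(xm))
  mapply(function(a, b) sum(a != b), xm, ym, USE.NAMES = FALSE)
}

# Deterministic RNG scope: run `expr` under a seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Random DNA of given lengths (vectorised).
random_dna <- function(n_bases) {
  vapply(n_bases, function(k) {
    paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
  }, character(1))
}
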
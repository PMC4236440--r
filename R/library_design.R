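# The multiplexed 2b-RAD construct. Adapter1 carries a 5-9 nt inline
# barcode and a degenerate overhang complementary to the enzyme's sticky
# end; adapter2 is common. After PCR with the Illumina multiplexing primer
# 1.0 and a 6-nt indexed primer, the sequencer reads
# barcode + 33-nt tag + adapter2 read-through on one strand or the other.

ADAPTER1_COMMON <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
ADAPTER2_TOP <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
PRIMER1_0 <- "AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT"
INDEX_PRIMER_TEMPLATE <-
  "CAAGCAGAAGACGGCATACGAGATXXXXXXGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"

#' Build a 2b-RAD library design
#'
#' Bundles the fixed construct sequences (adapter1 common arm, adapter2
#' top strand, multiplexing PCR primer 1.0, the indexed primer with its
#' 6-nt index slot), a barcode set, the adapter overhang specification and
#' the enzyme model. The stored sequences satisfy the construct's
#' complementarity: primer 1.0 ends with the adapter1 common arm, and the
#' final 34 nt of the index primer are the reverse complement of the
#' adapter2 top strand.
#'
#' @param barcode_set Tibble with columns `sample_id`, `barcode`
#'   (optional; may be added later).
#' @param overhang_spec String over `N` and fixed bases, one character per
#'   overhang base (default `"NNN"`, i.e. unselective 3-nt ends).
#' @param enzyme Enzyme name or `enzyme_spec` (default BsaXI).
#' @return A `library_design` object (list).
#' @export
#' @examples
#' d <- library_design()
#' amplicon_length(d, "ACGTA")
library_design <- function(barcode_set = NULL, overhang_spec = "NNN",
                           enzyme = "BsaXI") {
  e <- enzyme_spec(enzyme)
  if (nchar(overhang_spec) != e$overhang_length) {
    abort(paste0("`overhang_spec` must have length ", e$overhang_length,
                 " for ", e$name, "."))
  }
  if (!grepl("^[ACGTN]+$", overhang_spec)) {
    abort("`overhang_spec` must be over {A, C, G, T, N}.")
  }
  stopifnot(
    endsWith(PRIMER1_0, ADAPTER1_COMMON),
    substr(INDEX_PRIMER_TEMPLATE, 31, 64) == revcomp(ADAPTER2_TOP)
  )
  structure(
    list(
      adapter1_common = ADAPTER1_COMMON,
      adapter2_top = ADAPTER2_TOP,
      primer1_0 = PRIMER1_0,
      index_primer_template = INDEX_PRIMER_TEMPLATE,
      barcode_set = barcode_set,
      overhang_spec = overhang_spec,
      enzyme = e
    ),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design> enzyme ", x$enzyme$name,
      ", overhang spec ", x$overhang_spec, "\n", sep = "")
  cat("  barcodes: ",
      if (is.null(x$barcode_set)) "none" else nrow(x$barcode_set),
      "\n", sep = "")
  invisible(x)
}

#' Amplicon length for a given barcode
#'
#' Total amplified fragment length computed from the printed construct
#' sequences: primer 1.0 (58 nt) + barcode + tag (33 nt) + index primer
#' (64 nt), i.e. 160-164 bp over the 5-9-nt barcode range.
#'
#' @param design A [library_design()].
#' @param barcode Barcode sequence (length 5-9) or its length.
#' @return Length in bp.
#' @export
amplicon_length <- function(design, barcode) {
  b <- if (is.numeric(barcode)) as.integer(barcode) else nchar(barcode)
  if (b < 5L || b > 9L) abort("Barcode length must be between 5 and 9 nt.")
  nchar(design$primer1_0) + b + tag_length(design$enzyme) +
    nchar(design$index_primer_template)
}

#' Enumerate the distinct single-end overhang sequences of an enzyme
#'
#' @param enzyme Enzyme name or spec.
#' @return Integer count (`4^overhang_length`); the explicit list is in
#'   the `"overhangs"` attribute.
#' @export
#' @examples
#' enumerate_overhangs("BsaXI") # 64
enumerate_overhangs <- function(enzyme) {
  e <- enzyme_spec(enzyme)
  combos <- do.call(expand.grid, rep(list(DNA_BASES), e$overhang_length))
  seqs <- do.call(paste0, rev(combos))
  structure(length(seqs), overhangs = sort(seqs))
}

overhang_matches_spec <- function(overhangs, spec) {
  sp <- strsplit(spec, "", fixed = TRUE)[[1]]
  vapply(strsplit(overhangs, "", fixed = TRUE), function(o) {
    all(sp == "N" | sp == o)
  }, logical(1))
}

#' Fraction of enzyme sites targeted by a fixed-base overhang adapter
#'
#' Selective adapters fix one or more overhang bases (e.g. `NNF`, one
#' fixed base), so only fragments whose two sticky ends are both
#' compatible ligate and amplify. The fraction is computed by exhaustive
#' enumeration of all ordered overhang pairs (both fragment ends): with a
#' k-fixed-base spec per end the fraction is 4^(-2k), e.g. 1/16 for BsaXI
#' `NNF` adapters and 1/16 for AlfI `NF` adapters. An all-`N` spec returns 1.
#'
#' @param overhang_spec Spec string over `N`/fixed bases, length equal to
#'   the enzyme's overhang.
#' @param enzyme Enzyme name or spec.
#' @return The targeted fraction as a number in (0, 1].
#' @export
#' @examples
#' overhang_fraction("NNT", "BsaXI") # 1/16
overhang_fraction <- function(overhang_spec, enzyme) {
  e <- enzyme_spec(enzyme)
  if (nchar(overhang_spec) != e$overhang_length) {
    abort(paste0("`overhang_spec` must have length ", e$overhang_length,
                 " for ", e$name, "."))
  }
  singles <- attr(enumerate_overhangs(e), "overhangs")
  ok <- overhang_matches_spec(singles, overhang_spec)
  pairs <- expand.grid(end1 = seq_along(singles), end2 = seq_along(singles))
  sum(ok[pairs$end1] & ok[pairs$end2]) / nrow(pairs)
}

# -- barcodes ----------------------------------------------------------------

as_barcode_tbl <- function(barcodes) {
  if (is.data.frame(barcodes)) return(as_tibble(barcodes))
  tibble(sample_id = paste0("S", seq_along(barcodes)),
         barcode = unname(barcodes))
}

# TRUE if the pattern can occur in `context` in a window touching the
# barcode region, where context 'N' positions (unknown insert bases) may
# take any value: a window matches when no concrete context base conflicts
# with a concrete pattern base. Vectorised over window offsets.
pattern_possible_in_context <- function(context, pattern, over_positions) {
  pl <- nchar(pattern)
  ctx <- strsplit(context, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n_off <- length(ctx) - pl + 1L
  if (n_off < 1L) return(FALSE)
  offs <- seq_len(n_off)
  keep <- offs + pl - 1L >= min(over_positions) & offs <= max(over_positions)
  offs <- offs[keep]
  if (length(offs) == 0L) return(FALSE)
  idx <- outer(offs - 1L, seq_len(pl), "+")
  win <- matrix(ctx[idx], nrow = length(offs))
  patm <- matrix(pat, nrow = length(offs), ncol = pl, byrow = TRUE)
  conflict <- patm != "N" & win != "N" & win != patm
  any(rowSums(conflict) == 0L)
}

# Criterion-3 check for a single barcode against all overhang completions.
barcode_creates_site <- function(barcode, design) {
  e <- design$enzyme
  overhangs <- attr(enumerate_overhangs(e), "overhangs")
  insert_n <- strrep("N", tag_length(e))
  pre <- nchar(design$adapter1_common)
  over_pos <- (pre + 1L):(pre + nchar(barcode))
  for (ov in overhangs) {
    ctx <- paste0(design$adapter1_common, barcode, ov, insert_n)
    if (pattern_possible_in_context(ctx, e$plus_pattern, over_pos)) return(TRUE)
    if (!is.null(e$minus_pattern) &&
        pattern_possible_in_context(ctx, e$minus_pattern, over_pos)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Validate an inline barcode set
#'
#' Checks the published design criteria for variable-length inline
#' barcodes: (1) lengths within 5-9 nt; (2) every pair at least 2 apart —
#' implemented as Levenshtein distance >= 2, since the barcodes have
#' unequal lengths — plus prefix-freeness, which inline demultiplexing
#' needs for unambiguous boundaries; (3) no barcode may contain, or
#' recreate after ligation, a BsaXI recognition site: the ligated context
#' (adapter1 common arm + barcode + overhang + insert) is scanned for both
#' BsaXI patterns over every overhang completion, treating unknown insert
#' bases conservatively as wildcards.
#'
#' @param barcodes Character vector of barcodes or a tibble with columns
#'   `sample_id`, `barcode`.
#' @param design A [library_design()] (defaults to the standard BsaXI
#'   design).
#' @return A tibble with one row per barcode and logical flag columns
#'   `bad_length`, `too_close`, `prefix_clash`, `creates_site`, `pass`;
#'   attribute `pass` gives the overall verdict.
#' @export
#' @examples
#' validate_barcode_set(c("AACGC", "CGTAAT"))
validate_barcode_set <- function(barcodes, design = library_design()) {
  tbl <- as_barcode_tbl(barcodes)
  if (nrow(tbl) == 0L) abort("Barcode set is empty.")
  bc <- tbl$barcode
  n <- length(bc)
  len <- nchar(bc)
  bad_length <- len < 5L | len > 9L

  dmat <- utils::adist(bc)
  diag(dmat) <- Inf
  too_close <- apply(dmat, 1L, min) < 2L
  if (n == 1L) too_close <- FALSE

  prefix_clash <- vapply(seq_len(n), function(i) {
    any(startsWith(bc[-i], bc[i]) | startsWith(bc[i], bc[-i]))
  }, logical(1))

  creates_site <- vapply(bc, barcode_creates_site, logical(1),
                         design = design, USE.NAMES = FALSE)

  out <- tbl %>%
    dplyr::mutate(
      length = len, bad_length = bad_length, too_close = too_close,
      prefix_clash = prefix_clash, creates_site = creates_site,
      pass = !(bad_length | too_close | prefix_clash | creates_site)
    )
  attr(out, "pass") <- all(out$pass)
  out
}

base_imbalance <- function(barcodes) {
  # Sum over positions of the range of base frequencies; lower is more
  # balanced. Positions are counted over barcodes long enough to reach them.
  maxlen <- max(nchar(barcodes))
  tot <- 0
  for (p in seq_len(maxlen)) {
    ch <- substr(barcodes, p, p)
    ch <- ch[ch != ""]
    cnt <- table(factor(ch, DNA_BASES))
    tot <- tot + diff(range(cnt))
  }
  tot
}

#' Design a set of inline barcodes
#'
#' Greedy seeded search: candidate barcodes are drawn at random over the
#' requested lengths; a candidate is kept only if the grown set still
#' passes [validate_barcode_set()], and among a pool of admissible
#' candidates the one minimising per-position base-composition imbalance
#' is taken. Deterministic given `seed`.
#'
#' @param n Number of barcodes.
#' @param lengths Allowed lengths, a subset of 5:9 (default all, cycled so
#'   lengths are represented evenly).
#' @param design A [library_design()].
#' @param seed Integer seed.
#' @param pool_size Candidates scored per accepted barcode.
#' @param max_attempts Candidate budget before giving up.
#' @return A tibble with columns `sample_id`, `barcode`, passing
#'   validation.
#' @export
#' @examples
#' design_barcodes(4, lengths = 5:6, seed = 1)
design_barcodes <- function(n, lengths = 5:9, design = library_design(),
                            seed = 1L, pool_size = 48L,
                            max_attempts = 20000L) {
  if (n < 1L) abort("`n` must be >= 1.")
  if (!all(lengths %in% 5:9)) abort("`lengths` must be within 5..9.")
  with_seed(seed, {
    chosen <- character()
    want_len <- rep_len(sort(lengths), n)
    attempts <- 0L
    for (i in seq_len(n)) {
      best <- NULL
      best_score <- Inf
      tried <- 0L
      while (tried < pool_size) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort(paste0(
            "Barcode design infeasible: only ", length(chosen), " of ", n,
            " barcodes found within the attempt budget; the pairwise-",
            "distance constraint over lengths {",
            paste(lengths, collapse = ","), "} is binding."
          ))
        }
        cand <- random_dna(want_len[i])
        tried <- tried + 1L
        # incremental admissibility: site creation is per-barcode; the
        # pairwise constraints only involve the candidate vs the chosen set
        if (length(chosen) > 0L) {
          if (any(utils::adist(cand, chosen) < 2L)) next
          if (any(startsWith(chosen, cand) | startsWith(cand, chosen))) next
        }
        if (barcode_creates_site(cand, design)) next
        score <- base_imbalance(c(chosen, cand))
        if (score < best_score) {
          best <- cand
          best_score <- score
        }
      }
      if (is.null(best)) {
        abort(paste0(
          "Barcode design infeasible after ", attempts, " attempts: no ",
          "admissible candidate of length ", want_len[i], " extends the ",
          "current set of ", length(chosen), "."
        ))
      }
      chosen <- c(chosen, best)
    }
    tibble(sample_id = paste0("S", sprintf("%02d", seq_len(n))),
           barcode = chosen)
  })
}

#' Build the sequencer-visible read for one fragment
#'
#' Concatenates barcode, 33-nt tag (in whichever strand orientation the
#' caller chose) and the adapter2 top strand, then truncates to the read
#' length; with a 5-nt barcode an SE50 read therefore ends in 12 nt of
#' adapter read-through.
#'
#' @param design A [library_design()].
#' @param barcode Barcode sequence(s).
#' @param tag 33-nt tag sequence(s), canonical or reverse-complemented.
#' @param read_length Read length (default 50, the SE50 regime).
#' @return Character vector of reads.
#' @export
construct_read <- function(design, barcode, tag, read_length = 50L) {
  if (any(nchar(tag) != tag_length(design$enzyme))) {
    abort(paste0("Tags must be ", tag_length(design$enzyme), " nt."))
  }
  if (read_length < max(nchar(barcode)) + 1L) {
    abort("`read_length` must exceed the barcode length.")
  }
  substr(paste0(barcode, tag, design$adapter2_top), 1L, read_length)
}

#' Write/read barcode sets as TSV
#'
#' @param barcode_set Tibble with `sample_id`, `barcode`.
#' @param path File path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_barcodes_tsv <- function(barcode_set, path) {
  readr::write_tsv(barcode_set, path)
  invisible(path)
}

#' @rdname write_barcodes_tsv
#' @export
read_barcodes_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}
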
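# Enzyme models, IUPAC motif scanning, 2b-RAD tag extraction and
# canonicalization.
#
# A type IIB enzyme such as BsaXI cuts on both sides of its recognition
# sequence and releases a fixed-length fragment: for BsaXI a 33-nt tag with
# the 11-nt recognition pattern ACNNNNNCTCC offset 12 nt from the fragment
# start (12-nt upstream flank, 10-nt downstream flank). Because the pattern
# is not self-complementary the same physical site is seen on the plus
# strand either as ACNNNNNCTCC (plus form) or as its reverse complement
# GGAGNNNNNGT (minus form); canonicalization collapses both to the AC...CTCC
# orientation so each locus has one sequence.

# -- registry ----------------------------------------------------------------

.enzyme_registry <- local({
  mk <- function(name, plus, minus, up, down, per_site, overhang, extract) {
    structure(
      list(
        name = name, plus_pattern = plus, minus_pattern = minus,
        upstream_flank = up, downstream_flank = down,
        tags_per_site = per_site, overhang_length = overhang,
        supports_tag_extraction = extract
      ),
      class = "enzyme_spec"
    )
  }
  list(
    BsaXI   = mk("BsaXI", "ACNNNNNCTCC", "GGAGNNNNNGT", 12L, 10L, 1L, 3L, TRUE),
    AlfI    = mk("AlfI", "GCANNNNNNTGC", NULL, 0L, 0L, 1L, 2L, FALSE),
    EcoRI   = mk("EcoRI", "GAATTC", NULL, 0L, 0L, 2L, 4L, FALSE),
    SbfI    = mk("SbfI", "CCTGCAGG", NULL, 0L, 0L, 2L, 4L, FALSE),
    HindIII = mk("HindIII", "AAGCTT", NULL, 0L, 0L, 2L, 4L, FALSE)
  )
})

#' Look up a restriction enzyme model
#'
#' The built-in registry holds the five enzymes used throughout the
#' package: the type IIB enzymes BsaXI (plus-form pattern `ACNNNNNCTCC`,
#' minus form `GGAGNNNNNGT`, 12/10-nt flanks, 33-nt tag, 3-nt overhangs,
#' one tag per site) and AlfI (`GCANNNNNNTGC`, self-complementary, 2-nt
#' overhangs), and the type IIP enzymes EcoRI, SbfI and HindIII
#' (self-complementary, two RAD tags per site). Only BsaXI supports tag
#' extraction: its fragment geometry is fully specified, AlfI's is not.
#'
#' @param enzyme An `enzyme_spec` or the name of a registered enzyme.
#' @return An `enzyme_spec` object.
#' @export
#' @examples
#' enzyme_spec("BsaXI")
enzyme_spec <- function(enzyme) {
  if (inherits(enzyme, "enzyme_spec")) return(enzyme)
  if (!is.character(enzyme) || length(enzyme) != 1L ||
      !enzyme %in% names(.enzyme_registry)) {
    abort(paste0(
      "Unknown enzyme ", deparse(enzyme), ". Registered: ",
      paste(names(.enzyme_registry), collapse = ", "), "."
    ))
  }
  .enzyme_registry[[enzyme]]
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat("<enzyme_spec> ", x$name, "\n", sep = "")
  cat("  pattern: ", x$plus_pattern,
      if (!is.null(x$minus_pattern)) paste0(" / ", x$minus_pattern), "\n",
      sep = "")
  cat("  tags/site: ", x$tags_per_site,
      ", overhang: ", x$overhang_length, " nt",
      if (x$supports_tag_extraction)
        paste0(", tag length: ", tag_length(x), " nt"),
      "\n", sep = "")
  invisible(x)
}

#' List registered enzymes
#'
#' @return A tibble with one row per registered enzyme.
#' @export
list_enzymes <- function() {
  purrr::map_dfr(.enzyme_registry, function(e) {
    tibble(
      enzyme = e$name, plus_pattern = e$plus_pattern,
      minus_pattern = e$minus_pattern %||% NA_character_,
      tags_per_site = e$tags_per_site, overhang_length = e$overhang_length,
      supports_tag_extraction = e$supports_tag_extraction
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tag_length <- function(enzyme) {
  e <- enzyme_spec(enzyme)
  e$upstream_flank + nchar(e$plus_pattern) + e$downstream_flank
}

# -- scanning ----------------------------------------------------------------

# Match an IUPAC pattern on the plus strand of one sequence; returns 0-based
# starts. N in the subject never matches any pattern position, so candidate
# windows containing N are discarded after the degenerate match.
scan_pattern <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(integer())
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = FALSE)
  if (length(m) == 0L) return(integer())
  hits <- Biostrings::start(m)
  win <- as.character(Biostrings::extractAt(
    Biostrings::DNAString(seq),
    IRanges::IRanges(hits, width = nchar(pattern))
  ))
  hits[!grepl("N", win, fixed = TRUE)] - 1L
}

#' Scan a genome for enzyme recognition sites
#'
#' Reports every occurrence of the enzyme's recognition pattern on the
#' given (plus) strand. For non-self-complementary patterns (BsaXI) the
#' reverse-complement pattern is scanned as well and reported as
#' `minus_form`; self-complementary patterns are counted once per
#' occurrence. Overlapping occurrences are all reported, and windows
#' containing N never match.
#'
#' @param genome Named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA file path.
#' @param enzyme Enzyme name or `enzyme_spec`.
#' @return A tibble with columns `sequence_id`, `start` (0-based position
#'   of the first pattern base), `orientation` (`"plus_form"` /
#'   `"minus_form"`) and `enzyme`, sorted by (`sequence_id`, `start`).
#' @export
#' @examples
#' scan_sites(c(chr1 = "GCAAAAAAATGC"), "AlfI")
scan_sites <- function(genome, enzyme) {
  e <- enzyme_spec(enzyme)
  g <- as_genome(genome)
  if (length(g) == 0L) {
    return(tibble(sequence_id = character(), start = integer(),
                  orientation = character(), enzyme = character()))
  }
  per_seq <- purrr::imap(g, function(seq, id) {
    plus <- scan_pattern(seq, e$plus_pattern)
    minus <- if (!is.null(e$minus_pattern)) {
      scan_pattern(seq, e$minus_pattern)
    } else integer()
    tibble(
      sequence_id = id,
      start = c(plus, minus),
      orientation = rep(c("plus_form", "minus_form"),
                        c(length(plus), length(minus)))
    )
  })
  dplyr::bind_rows(per_seq) %>%
    dplyr::mutate(enzyme = e$name) %>%
    dplyr::arrange(.data$sequence_id, .data$start)
}

#' Count tags produced by a set of recognition sites
#'
#' Type IIB enzymes excise one tag per site; RAD-style type IIP digestion
#' yields a tag on each side of the cut, i.e. two per site.
#'
#' @param sites Tibble from [scan_sites()].
#' @param enzyme Enzyme name or `enzyme_spec`.
#' @return Integer tag count (`nrow(sites) * tags_per_site`).
#' @export
count_tags <- function(sites, enzyme) {
  e <- enzyme_spec(enzyme)
  nrow(sites) * e$tags_per_site
}

# -- tag extraction ----------------------------------------------------------

#' Extract 2b-RAD tags around recognition sites
#'
#' For each site the excised fragment is read from the plus strand of the
#' genome: a plus-form BsaXI site at (0-based) position `s` yields the
#' interval `[s - 12, s + 21)`, a minus-form site `[s - 10, s + 23)`; both
#' are 33 nt. Tags that would extend past the sequence ends are dropped
#' and counted in the `n_dropped` attribute. Each tag carries its
#' canonical (AC...CTCC-oriented) sequence.
#'
#' @param genome As in [scan_sites()].
#' @param sites Tibble from [scan_sites()] for the same genome/enzyme.
#' @param enzyme Enzyme name or `enzyme_spec`; must support tag extraction.
#' @return A tibble with columns `site_id`, `sequence_id`, `site_start`,
#'   `orientation`, `tag_start`, `tag_end` (0-based half-open), `sequence`
#'   (plus-strand) and `canonical_sequence`; attribute `n_dropped` counts
#'   out-of-bounds sites.
#' @export
extract_tags <- function(genome, sites, enzyme) {
  e <- enzyme_spec(enzyme)
  if (!e$supports_tag_extraction) {
    abort(paste0("Tag extraction is not supported for ", e$name, "."))
  }
  g <- as_genome(genome)
  pat_len <- nchar(e$plus_pattern)
  res <- sites %>%
    dplyr::mutate(
      tag_start = ifelse(.data$orientation == "plus_form",
                         .data$start - e$upstream_flank,
                         .data$start - e$downstream_flank),
      tag_end = .data$tag_start + tag_length(e),
      seq_len = nchar(g)[.data$sequence_id],
      in_bounds = .data$tag_start >= 0L & .data$tag_end <= .data$seq_len
    )
  n_dropped <- sum(!res$in_bounds)
  res <- res %>% dplyr::filter(.data$in_bounds)
  seqs <- substr(g[res$sequence_id], res$tag_start + 1L, res$tag_end)
  out <- res %>%
    dplyr::transmute(
      site_id = paste0(.data$sequence_id, ":", .data$start, ":",
                       .data$orientation),
      sequence_id = .data$sequence_id,
      site_start = .data$start,
      orientation = .data$orientation,
      tag_start = as.integer(.data$tag_start),
      tag_end = as.integer(.data$tag_end),
      sequence = unname(seqs),
      canonical_sequence = ifelse(.data$orientation == "plus_form",
                                  .data$sequence, revcomp(.data$sequence))
    )
  attr(out, "n_dropped") <- n_dropped
  out
}

# -- canonicalization --------------------------------------------------------

is_ac_form <- function(x) {
  substr(x, 13, 14) == "AC" & substr(x, 20, 23) == "CTCC"
}
is_ggag_form <- function(x) {
  substr(x, 11, 14) == "GGAG" & substr(x, 20, 21) == "GT"
}

#' Canonicalize 33-nt 2b-RAD tag sequences
#'
#' A BsaXI locus can be sequenced from either strand, so the same locus
#' appears either with `AC` at (0-based) positions 12-13 and `CTCC` at
#' 19-22, or as the reverse complement with `GGAG` at 10-13 and `GT` at
#' 19-20. Tags in the GGAG form are reverse-complemented into the
#' AC...CTCC form; AC-form tags pass through unchanged. Idempotent.
#'
#' @param x Character vector of 33-nt tag sequences (alphabet ACGT).
#' @return Character vector of canonical tags.
#' @export
#' @examples
#' tag <- paste0(strrep("A", 12), "ACGGGGGCTCC", strrep("A", 10))
#' identical(canonicalize(revcomp(tag)), tag)
canonicalize <- function(x) {
  if (length(x) == 0L) return(character())
  if (any(nchar(x) != 33L)) abort("Tags must be 33 nt long.")
  ac <- is_ac_form(x)
  gg <- is_ggag_form(x)
  if (any(!ac & !gg)) {
    abort(paste0(
      sum(!ac & !gg), " sequence(s) match neither the AC...CTCC nor the ",
      "GGAG...GT positional form; not 2b-RAD tags."
    ))
  }
  out <- x
  out[gg] <- revcomp(x[gg])
  out
}

# -- uniqueness and overlap --------------------------------------------------

#' Flag tags whose canonical sequence is unique genome-wide
#'
#' Unique tags are the expected potential markers: a read carrying them can
#' be assigned to a single locus. With `max_mismatch = 0` a tag is unique
#' iff its canonical sequence occurs at exactly one site. The optional
#' mismatch-tolerant mode (all-pairs Hamming comparison, intended for
#' desk-scale genomes) also declares non-unique any tag within
#' `max_mismatch` substitutions of another site's tag.
#'
#' @param tags Tibble from [extract_tags()] (canonical sequences present).
#' @param max_mismatch 0 (exact, default), 1 or 2.
#' @return `tags` with a logical `unique` column added.
#' @export
find_unique_tags <- function(tags, max_mismatch = 0L) {
  if (max_mismatch > 2L) {
    abort("`max_mismatch` must be 0, 1 or 2.")
  }
  counts <- table(tags$canonical_sequence)
  uniq <- as.vector(counts[tags$canonical_sequence] == 1L)
  if (max_mismatch > 0L && nrow(tags) > 1L) {
    seqs <- tags$canonical_sequence
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    for (i in seq_len(nrow(tags) - 1L)) {
      if (!uniq[i] && all(!uniq)) break
      d <- colSums(t(mat[(i + 1L):nrow(mat), , drop = FALSE]) != mat[i, ])
      close_j <- which(d <= max_mismatch) + i
      if (length(close_j) > 0L) {
        uniq[c(i, close_j)] <- FALSE
      }
    }
  }
  dplyr::mutate(tags, unique = unname(uniq))
}

#' Find pairs of tags with overlapping genomic intervals
#'
#' Two nearby recognition sites can excise fragments that share bases;
#' downstream such loci produce overlapping markers. Reports every pair of
#' tags on the same sequence whose `[tag_start, tag_end)` intervals
#' intersect, each pair once.
#'
#' @param tags Tibble from [extract_tags()].
#' @return A tibble with columns `site_id_1`, `site_id_2`, `sequence_id`,
#'   `overlap_bp`.
#' @export
find_overlapping_tags <- function(tags) {
  empty <- tibble(site_id_1 = character(), site_id_2 = character(),
                  sequence_id = character(), overlap_bp = integer())
  if (nrow(tags) < 2L) return(empty)
  per_seq <- tags %>%
    dplyr::group_by(.data$sequence_id) %>%
    dplyr::group_map(function(d, key) {
      ir <- IRanges::IRanges(start = d$tag_start + 1L, end = d$tag_end)
      hits <- IRanges::findOverlaps(ir, drop.self = TRUE,
                                    drop.redundant = TRUE)
      if (length(hits) == 0L) return(NULL)
      i <- S4Vectors::queryHits(hits)
      j <- S4Vectors::subjectHits(hits)
      ov <- pmin(d$tag_end[i], d$tag_end[j]) -
        pmax(d$tag_start[i], d$tag_start[j])
      tibble(site_id_1 = d$site_id[i], site_id_2 = d$site_id[j],
             sequence_id = key$sequence_id, overlap_bp = as.integer(ov))
    })
  out <- dplyr::bind_rows(per_seq)
  if (nrow(out) == 0L) empty else out
}

# -- writers -----------------------------------------------------------------

#' Write recognition sites as 6-column BED
#'
#' BED is 0-based half-open, matching the package's internal convention.
#' The name field is `enzyme:orientation`; strand maps `plus_form` to `+`
#' and `minus_form` to `-`.
#'
#' @param sites Tibble from [scan_sites()].
#' @param path Output file.
#' @param enzyme Enzyme name or spec (for the interval width).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, enzyme) {
  e <- enzyme_spec(enzyme)
  bed <- sites %>%
    dplyr::transmute(
      chrom = .data$sequence_id,
      start = .data$start,
      end = .data$start + nchar(e$plus_pattern),
      name = paste0(.data$enzyme, ":", .data$orientation),
      score = 0L,
      strand = ifelse(.data$orientation == "plus_form", "+", "-")
    )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write extracted tags as TSV
#'
#' @param tags Tibble from [extract_tags()] (optionally annotated by
#'   [find_unique_tags()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tags_tsv <- function(tags, path) {
  readr::write_tsv(tags, path)
  invisible(path)
}
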
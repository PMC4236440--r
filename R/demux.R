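# The two-step sequence-based read filter. Step 1 assigns each read to a
# sample by its inline barcode, allowing one mismatch; step 2 requires the
# 33 bases after the barcode to match a BsaXI fragment positionally
# (AC at 12-13 / CTCC at 19-22, or GGAG at 10-13 / GT at 19-20; 0-based)
# with no N anywhere in the 33-mer, trims read-through, and canonicalizes
# the accepted tag. Quality scores play no role.

#' Assign reads to samples by inline barcode
#'
#' Exact prefix match wins; otherwise the unique barcode at Hamming
#' distance 1 over its own length wins. Zero or two or more candidates at
#' the best tier leave the read unassigned (`no_match` / `ambiguous`). A
#' read is never tested against a barcode longer than the read minus the
#' 33-nt tag, and reads shorter than the shortest barcode plus 33 are
#' `too_short`. On assignment the barcode prefix is removed.
#'
#' @param reads Character vector of read sequences.
#' @param barcode_set Tibble with `sample_id`, `barcode` (validated,
#'   prefix-free).
#' @return A tibble with one row per read: `read`, `sample_id`, `barcode`,
#'   `n_mismatch`, `trimmed` (read minus barcode) and `reason`
#'   (`assigned`, `no_match`, `ambiguous`, `too_short`).
#' @export
match_barcode <- function(reads, barcode_set) {
  bc_tbl <- as_barcode_tbl(barcode_set)
  bcs <- bc_tbl$barcode
  n <- length(reads)
  sample_id <- rep(NA_character_, n)
  barcode <- rep(NA_character_, n)
  n_mismatch <- rep(NA_integer_, n)
  reason <- rep("no_match", n)
  rl <- nchar(reads)
  too_short <- rl < min(nchar(bcs)) + 33L
  reason[too_short] <- "too_short"

  ord <- order(nchar(bcs), decreasing = TRUE)
  open <- !too_short
  for (k in ord) {
    b <- bcs[k]
    L <- nchar(b)
    hit <- open & rl >= L + 33L & substr(reads, 1L, L) == b
    sample_id[hit] <- bc_tbl$sample_id[k]
    barcode[hit] <- b
    n_mismatch[hit] <- 0L
    reason[hit] <- "assigned"
    open <- open & !hit
  }

  if (any(open)) {
    idx <- which(open)
    cand_n <- integer(length(idx))
    cand_k <- integer(length(idx))
    for (k in seq_along(bcs)) {
      b <- bcs[k]
      L <- nchar(b)
      ok <- rl[idx] >= L + 33L
      d <- rep(Inf, length(idx))
      if (any(ok)) {
        pre <- substr(reads[idx[ok]], 1L, L)
        mm <- integer(sum(ok))
        for (p in seq_len(L)) {
          mm <- mm + (substr(pre, p, p) != substr(b, p, p))
        }
        d[ok] <- mm
      }
      one <- d == 1
      cand_n[one] <- cand_n[one] + 1L
      cand_k[one] <- k
    }
    uni <- cand_n == 1L
    amb <- cand_n >= 2L
    sample_id[idx[uni]] <- bc_tbl$sample_id[cand_k[uni]]
    barcode[idx[uni]] <- bcs[cand_k[uni]]
    n_mismatch[idx[uni]] <- 1L
    reason[idx[uni]] <- "assigned"
    reason[idx[amb]] <- "ambiguous"
  }

  trimmed <- rep(NA_character_, n)
  got <- reason == "assigned"
  trimmed[got] <- substr(reads[got], nchar(barcode[got]) + 1L, rl[got])
  tibble(read = seq_len(n), sample_id = sample_id, barcode = barcode,
         n_mismatch = n_mismatch, trimmed = trimmed, reason = reason)
}

#' Match trimmed reads against the BsaXI fragment patterns
#'
#' Accepts a trimmed read iff its first 33 bases contain no N and satisfy
#' either positional fragment form; the "perfect match" applies to the 11
#' fixed recognition positions, while the degenerate positions may be any
#' of ACGT. Bases beyond 33 (adapter read-through) are discarded and
#' accepted tags are canonicalized to the AC...CTCC form.
#'
#' @param trimmed Character vector of barcode-trimmed read sequences.
#' @return A tibble with `trimmed`, `tag` (canonical 33-mer or NA) and
#'   `reason` (`accepted`, `has_N`, `no_site`, `too_short`).
#' @export
match_tag <- function(trimmed) {
  n <- length(trimmed)
  first33 <- substr(trimmed, 1L, 33L)
  too_short <- nchar(trimmed) < 33L
  has_n <- !too_short & grepl("N", first33, fixed = TRUE)
  testable <- !too_short & !has_n
  ac <- testable & is_ac_form(first33)
  gg <- testable & is_ggag_form(first33)
  tag <- rep(NA_character_, n)
  tag[ac] <- first33[ac]
  tag[gg] <- revcomp(first33[gg])
  reason <- dplyr::case_when(
    too_short ~ "too_short",
    has_n ~ "has_N",
    ac | gg ~ "accepted",
    TRUE ~ "no_site"
  )
  tibble(trimmed = trimmed, tag = tag, reason = reason)
}

#' Demultiplex and filter a set of single-end reads
#'
#' Runs the two-step filter over a read collection and accumulates
#' per-sample and per-stage statistics. Every input read lands in exactly
#' one outcome class: assigned-and-accepted (high quality),
#' assigned-but-rejected by the site/N filter, or unassigned.
#'
#' @param reads Character vector of read sequences, a tibble with columns
#'   `read_id`/`sequence`, or a FASTQ file path.
#' @param sample_sheet Tibble with `sample_id`, `barcode`.
#' @param outdir Optional directory; per-sample canonical tags are written
#'   as FASTA (`<sample_id>.tags.fasta`, tag counts in headers).
#' @return A list of class `rad2b_demux` with elements `reads` (per-read
#'   tibble: `read_id`, `sample_id`, `tag`, `outcome`), `tags` (accepted
#'   reads only) and `stats` (a `filter_stats` object, see
#'   [filter_stats()]).
#' @export
demux_fastq <- function(reads, sample_sheet, outdir = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fq|fastq)(\\.gz)?$", reads)) {
    reads <- read_fastq(reads)
  }
  if (is.data.frame(reads)) {
    read_id <- reads$read_id
    seqs <- reads$sequence
  } else {
    seqs <- unname(reads)
    read_id <- paste0("read", seq_along(seqs))
  }
  bc <- match_barcode(seqs, sample_sheet)
  tg <- match_tag(ifelse(is.na(bc$trimmed), "", bc$trimmed))
  outcome <- dplyr::case_when(
    bc$reason != "assigned" ~ paste0("unassigned_", bc$reason),
    tg$reason == "accepted" ~ "high_quality",
    TRUE ~ paste0("rejected_", tg$reason)
  )
  per_read <- tibble(
    read_id = read_id, sample_id = bc$sample_id, barcode = bc$barcode,
    tag = ifelse(outcome == "high_quality", tg$tag, NA_character_),
    outcome = outcome
  )
  tags <- per_read %>%
    dplyr::filter(.data$outcome == "high_quality") %>%
    dplyr::select("read_id", "sample_id", "tag")
  stats <- filter_stats(per_read, sample_sheet)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (sid in unique(tags$sample_id)) {
      cnt <- tags %>%
        dplyr::filter(.data$sample_id == sid) %>%
        dplyr::count(.data$tag, name = "count")
      ss <- Biostrings::DNAStringSet(cnt$tag)
      names(ss) <- paste0(sid, "_tag", seq_len(nrow(cnt)),
                          " count=", cnt$count)
      Biostrings::writeXStringSet(ss, file.path(outdir,
                                                paste0(sid, ".tags.fasta")))
    }
  }
  structure(list(reads = per_read, tags = tags, stats = stats),
            class = "rad2b_demux")
}

#' Per-stage filtering statistics
#'
#' Builds the counting object for a demultiplexing run: total reads,
#' barcode-matched reads, high-quality reads (both filters passed), the
#' two rejection tallies, per-sample counts at both stages, and the
#' evenness ratio (maximum per-sample high-quality count over the
#' minimum). Conservation holds by construction: total = barcode_matched +
#' rejected_barcode and barcode_matched = high_quality +
#' rejected_site_or_N.
#'
#' @param per_read Per-read outcome tibble (from [demux_fastq()]).
#' @param sample_sheet Tibble with `sample_id`, `barcode`.
#' @return A `filter_stats` object.
#' @export
filter_stats <- function(per_read, sample_sheet) {
  assigned <- !startsWith(per_read$outcome, "unassigned")
  hq <- per_read$outcome == "high_quality"
  per_sample <- tibble(sample_id = sample_sheet$sample_id) %>%
    dplyr::left_join(
      per_read %>%
        dplyr::filter(assigned) %>%
        dplyr::group_by(.data$sample_id) %>%
        dplyr::summarise(
          barcode_matched = dplyr::n(),
          high_quality = sum(.data$outcome == "high_quality")
        ),
      by = "sample_id"
    ) %>%
    tidyr::replace_na(list(barcode_matched = 0L, high_quality = 0L))
  evenness <- if (nrow(per_sample) > 0 && min(per_sample$high_quality) > 0) {
    max(per_sample$high_quality) / min(per_sample$high_quality)
  } else {
    NA_real_
  }
  structure(
    list(
      total_reads = nrow(per_read),
      barcode_matched = sum(assigned),
      high_quality = sum(hq),
      rejected_barcode = sum(!assigned),
      rejected_site_or_N = sum(assigned & !hq),
      per_sample = per_sample,
      evenness_ratio = evenness
    ),
    class = "filter_stats"
  )
}

#' @export
print.filter_stats <- function(x, ...) {
  pct <- function(k) sprintf("%d (%.1f%%)", k,
                             if (x$total_reads) 100 * k / x$total_reads else 0)
  cat("<filter_stats>\n")
  cat("  total reads:     ", x$total_reads, "\n")
  cat("  barcode matched: ", pct(x$barcode_matched), "\n")
  cat("  high quality:    ", pct(x$high_quality), "\n")
  cat("  rejected barcode:", pct(x$rejected_barcode), "\n")
  cat("  rejected site/N: ", pct(x$rejected_site_or_N), "\n")
  if (!is.na(x$evenness_ratio))
    cat("  evenness ratio:  ", sprintf("%.2f", x$evenness_ratio), "\n")
  invisible(x)
}

#' @rdname filter_stats
#' @param x A `filter_stats` object.
#' @param ... Unused.
#' @export
glance.filter_stats <- function(x, ...) {
  tibble(
    total_reads = x$total_reads, barcode_matched = x$barcode_matched,
    high_quality = x$high_quality, rejected_barcode = x$rejected_barcode,
    rejected_site_or_N = x$rejected_site_or_N,
    evenness_ratio = x$evenness_ratio
  )
}

#' @rdname filter_stats
#' @export
tidy.filter_stats <- function(x, ...) {
  x$per_sample
}

#' Plot per-sample read counts across filter stages
#'
#' @param stats A `filter_stats` object.
#' @return A ggplot object.
#' @export
plot_filter_stats <- function(stats) {
  long <- stats$per_sample %>%
    tidyr::pivot_longer(c("barcode_matched", "high_quality"),
                        names_to = "stage", values_to = "reads")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$reads,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "reads",
                  title = "Reads per sample by filter stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Classify rejected reads against a genome
#'
#' Reads that matched a barcode but failed the recognition-site filter are
#' often genuine genomic fragments lying between two recognition sites
#' (they survive size selection but carry no site). This reports the count
#' and fraction of rejected reads whose first 33 bases occur verbatim in
#' the genome on either strand — an exact-match simplification of
#' mismatch-tolerant alignment.
#'
#' @param rejected Character vector of rejected (barcode-trimmed) reads.
#' @param genome As in [scan_sites()].
#' @return A one-row tibble: `n_rejected`, `n_genomic`, `fraction`.
#' @export
classify_rejected <- function(rejected, genome) {
  g <- as_genome(genome)
  n <- length(rejected)
  if (n == 0L) {
    return(tibble(n_rejected = 0L, n_genomic = 0L, fraction = NA_real_))
  }
  first33 <- substr(rejected, 1L, 33L)
  eligible <- nchar(first33) == 33L & !grepl("N", first33, fixed = TRUE)
  matched <- logical(n)
  if (any(eligible)) {
    qset <- unique(first33[eligible])
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(qset))
    subj <- Biostrings::DNAStringSet(c(g, revcomp(g)))
    cnt <- rowSums(Biostrings::vcountPDict(pd, subj))
    found <- qset[cnt > 0L]
    matched[eligible] <- first33[eligible] %in% found
  }
  tibble(n_rejected = n, n_genomic = sum(matched),
         fraction = sum(matched) / n)
}

# -- FASTQ / sample sheet IO -------------------------------------------------

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (gzip allowed).
#' @return Tibble with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(toupper(as.character(x))))
}

#' Write reads as FASTQ
#'
#' Quality strings are constant `"I"` — the downstream filter is purely
#' sequence-based.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Expects columns `sample_id` and `barcode` (extra columns such as a
#' library/index label are kept). Sample ids must be unique and barcodes
#' unique within a library.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("sample_id", "barcode") %in% names(sheet))) {
    abort("Sample sheet needs `sample_id` and `barcode` columns.")
  }
  if (anyDuplicated(sheet$sample_id)) abort("Sample ids must be unique.")
  grp <- if ("library" %in% names(sheet)) sheet$library else "lib1"
  if (any(tapply(sheet$barcode, grp, anyDuplicated) > 0)) {
    abort("Barcodes must be unique within a library.")
  }
  sheet
}
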
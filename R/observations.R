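# Locus-observation collection for genotyping: assign each canonical
# sample tag to a reference site, tolerating the mismatches a parental
# allele can legitimately carry (up to 2 SNPs, the catalog-merge
# tolerance), and reduce reads to per-(sample, site) allele counts with
# light error suppression.

# Hamming distances between two sets of equal-length strings, as an
# n x m integer matrix; vectorised position-slice comparison.
hamming_matrix <- function(x, y) {
  L <- nchar(x[1])
  xm <- matrix(utf8ToInt(paste(x, collapse = "")), ncol = L, byrow = TRUE)
  ym <- matrix(utf8ToInt(paste(y, collapse = "")), ncol = L, byrow = TRUE)
  d <- matrix(0L, length(x), length(y))
  for (p in seq_len(L)) {
    d <- d + outer(xm[, p], ym[, p], "!=")
  }
  d
}

#' Collect per-locus allele observations from demultiplexed tags
#'
#' Assigns each canonical sample tag to a unique reference tag site:
#' exact canonical match first, then (for `max_mismatch > 0`) the site
#' with the smallest Hamming distance within `max_mismatch`, required to
#' be unique at that best distance. The default tolerance of 2 matches the
#' number of SNPs an alternate parental allele may carry relative to the
#' reference. Reads are then tabulated into allele counts per
#' (sample, site); when `drop_singletons` is set, alleles supported by a
#' single read are discarded at loci where another allele has two or more
#' reads — suppressing lone sequencing-error haplotypes the way a
#' minimum-stack-depth rule does.
#'
#' @param tags Tibble with `sample_id`, `tag` (from [demux_fastq()]).
#' @param ref_tags Reference tag tibble from [extract_tags()].
#' @param max_mismatch Maximum Hamming distance for assignment
#'   (default 2).
#' @param drop_singletons Drop 1-read alleles at loci with a >= 2-read
#'   allele (default TRUE).
#' @return Tibble of locus observations: `sample_id`, `site_id`,
#'   `allele`, `count`; attribute `n_unassigned` counts dropped reads.
#' @export
collect_observations <- function(tags, ref_tags, max_mismatch = 2L,
                                 drop_singletons = TRUE) {
  index <- build_tag_index(ref_tags)
  uniq <- index[index$n_sites == 1L, ]
  site_of <- stats::setNames(vapply(uniq$site_ids, `[[`, character(1), 1L),
                             uniq$canonical_sequence)
  distinct_tags <- unique(tags$tag)
  site <- unname(site_of[distinct_tags])
  if (max_mismatch > 0L && anyNA(site) && length(site_of) > 0L) {
    # distance-1 tier via the index-side neighbour hash
    nbmap <- neighbour_site_map(site_of)
    miss1 <- which(is.na(site))
    hit1 <- match(distinct_tags[miss1], nbmap$neighbour)
    site[miss1] <- nbmap$site[hit1]
    amb1 <- miss1[!is.na(hit1) & is.na(nbmap$site[hit1])]
    if (max_mismatch >= 2L) {
      # distance-2 tier: full Hamming profile against the reference,
      # chunked; requires a unique best site within tolerance
      miss2 <- setdiff(which(is.na(site)), amb1)
      refs <- names(site_of)
      chunk <- 5000L
      if (length(miss2) > 0L) {
        for (lo in seq(1L, length(miss2), by = chunk)) {
          hi <- min(lo + chunk - 1L, length(miss2))
          idx <- miss2[lo:hi]
          d <- hamming_matrix(distinct_tags[idx], refs)
          best <- apply(d, 1L, min)
          n_best <- rowSums(d == best)
          ok <- best <= max_mismatch & n_best == 1L
          site[idx[ok]] <- unname(site_of[refs[apply(
            d[ok, , drop = FALSE], 1L, which.min)]])
        }
      }
    }
  }
  tag_site <- stats::setNames(site, distinct_tags)
  assigned <- tibble(
    sample_id = tags$sample_id,
    site_id = unname(tag_site[tags$tag]),
    allele = tags$tag
  )
  n_unassigned <- sum(is.na(assigned$site_id))
  obs <- assigned %>%
    dplyr::filter(!is.na(.data$site_id)) %>%
    dplyr::count(.data$sample_id, .data$site_id, .data$allele,
                 name = "count")
  if (drop_singletons && nrow(obs) > 0L) {
    obs <- obs %>%
      dplyr::group_by(.data$sample_id, .data$site_id) %>%
      dplyr::filter(.data$count > 1L | max(.data$count) < 2L) %>%
      dplyr::ungroup()
  }
  attr(obs, "n_unassigned") <- n_unassigned
  obs
}
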
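# Simplified reference-anchored F2 genotyper. Loci are the reference tag
# sites; per sample and site the canonical-allele read stack is reduced to
# hom / het / missing by depth and second-allele-frequency thresholds, the
# two inbred parents define aa x bb markers (alleles differing at 1-2
# positions), progeny are coded aa / ab / bb / missing, and markers are
# filtered on missing rate and a 1:2:1 chi-square segregation test.

#' Call hom/het/missing genotypes from per-locus read stacks
#'
#' Per (sample, site): total depth below `min_depth` is missing; otherwise
#' let f be the frequency of the second-most-frequent allele. f below
#' `min_het` calls a homozygote for the top allele, f above `max_het`
#' calls a heterozygote for the top two, and f inside `[min_het, max_het]`
#' is deliberately uncallable (missing). The narrow ambiguous zone takes
#' the place of an automated-correction pass. Ties between the top two
#' alleles are broken lexicographically and flagged.
#'
#' @param obs Tibble of locus observations: `sample_id`, `site_id`,
#'   `allele` (canonical 33-mer), `count`.
#' @param min_depth Minimum reads to call a genotype (default 2).
#' @param min_het Second-allele frequency below which the call is
#'   homozygous (default 0.010).
#' @param max_het Second-allele frequency above which the call is
#'   heterozygous (default 0.011).
#' @return Tibble with `sample_id`, `site_id`, `call` (`hom`/`het`/
#'   `missing`), `allele1`, `allele2` (NA unless het), `depth`,
#'   `tie_broken`.
#' @export
call_sample_genotype <- function(obs, min_depth = 2L, min_het = 0.010,
                                 max_het = 0.011) {
  if (nrow(obs) == 0L) {
    return(tibble(sample_id = character(), site_id = character(),
                  call = character(), allele1 = character(),
                  allele2 = character(), depth = integer(),
                  tie_broken = logical()))
  }
  obs %>%
    dplyr::group_by(.data$sample_id, .data$site_id) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$allele,
                   .by_group = TRUE) %>%
    dplyr::summarise(
      depth = sum(.data$count),
      top = .data$allele[1],
      second = if (dplyr::n() > 1L) .data$allele[2] else NA_character_,
      f2 = if (dplyr::n() > 1L) .data$count[2] / sum(.data$count) else 0,
      tie_broken = dplyr::n() > 1L && .data$count[1] == .data$count[2],
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      call = dplyr::case_when(
        .data$depth < min_depth ~ "missing",
        .data$f2 < min_het ~ "hom",
        .data$f2 > max_het ~ "het",
        TRUE ~ "missing"
      ),
      allele1 = ifelse(.data$call == "missing", NA_character_, .data$top),
      allele2 = ifelse(.data$call == "het", .data$second, NA_character_)
    ) %>%
    dplyr::select("sample_id", "site_id", "call", "allele1", "allele2",
                  "depth", "tie_broken")
}

#' Discover aa x bb markers between two inbred parents
#'
#' A site yields a marker iff both parents are homozygous for different
#' alleles differing at no more than `max_snps` positions (matching a
#' catalog-merge tolerance of 2 mismatches). Sites where either parent is
#' heterozygous, missing, or too divergent are reported with skip reasons.
#'
#' @param calls_a,calls_b Parent call tibbles from
#'   [call_sample_genotype()].
#' @param max_snps Maximum SNPs between parental alleles (default 2).
#' @return Tibble of markers: `site_id`, `parent_a`, `parent_b`,
#'   `n_snps`, `snp_positions` (list of 0-based offsets); attribute
#'   `skipped` tabulates skip reasons.
#' @export
discover_markers <- function(calls_a, calls_b, max_snps = 2L) {
  joined <- dplyr::inner_join(
    calls_a %>% dplyr::select("site_id", call_a = "call", a = "allele1"),
    calls_b %>% dplyr::select("site_id", call_b = "call", b = "allele1"),
    by = "site_id"
  )
  status <- with(joined, dplyr::case_when(
    call_a != "hom" | call_b != "hom" ~ "parent_not_hom",
    a == b ~ "monomorphic",
    TRUE ~ "candidate"
  ))
  cand <- joined[status == "candidate", ]
  n_snps <- hamming(cand$a, cand$b)
  ok <- n_snps <= max_snps
  skipped <- table(c(status[status != "candidate"],
                     rep("too_divergent", sum(!ok))))
  out <- tibble(
    site_id = cand$site_id[ok],
    parent_a = cand$a[ok],
    parent_b = cand$b[ok],
    n_snps = as.integer(n_snps[ok])
  )
  out$snp_positions <- purrr::map2(out$parent_a, out$parent_b, function(x, y) {
    which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) - 1L
  })
  attr(out, "skipped") <- skipped
  out
}

#' Genotype F2 progeny at discovered markers
#'
#' A progeny call homozygous for the parent-A allele codes `aa`, for the
#' parent-B allele `bb`; a heterozygote carrying both parental alleles
#' codes `ab`; anything else — missing call, a foreign allele (e.g. a
#' sequencing-error stack), or an absent sample — is `missing`.
#'
#' @param markers Tibble from [discover_markers()].
#' @param progeny_calls Call tibble from [call_sample_genotype()] over all
#'   progeny.
#' @param progeny_ids Optional character vector fixing the full progeny
#'   panel (so absent samples count as missing).
#' @return A `rad2b_genotypes` tibble: one row per (marker, progeny) with
#'   `site_id`, `sample_id`, `genotype` in \{aa, ab, bb, missing\}.
#' @export
genotype_progeny <- function(markers, progeny_calls, progeny_ids = NULL) {
  if (is.null(progeny_ids)) progeny_ids <- unique(progeny_calls$sample_id)
  grid <- tidyr::expand_grid(site_id = markers$site_id,
                             sample_id = progeny_ids)
  out <- grid %>%
    dplyr::left_join(
      markers %>% dplyr::select("site_id", "parent_a", "parent_b"),
      by = "site_id"
    ) %>%
    dplyr::left_join(progeny_calls, by = c("site_id", "sample_id")) %>%
    dplyr::mutate(
      genotype = dplyr::case_when(
        is.na(.data$call) | .data$call == "missing" ~ "missing",
        .data$call == "hom" & .data$allele1 == .data$parent_a ~ "aa",
        .data$call == "hom" & .data$allele1 == .data$parent_b ~ "bb",
        .data$call == "het" &
          ((.data$allele1 == .data$parent_a &
              .data$allele2 == .data$parent_b) |
             (.data$allele1 == .data$parent_b &
                .data$allele2 == .data$parent_a)) ~ "ab",
        TRUE ~ "missing"
      )
    ) %>%
    dplyr::select("site_id", "sample_id", "genotype")
  structure(out, class = c("rad2b_genotypes", class(out)))
}

marker_counts <- function(genotypes) {
  genotypes %>%
    dplyr::group_by(.data$site_id) %>%
    dplyr::summarise(
      n_aa = sum(.data$genotype == "aa"),
      n_ab = sum(.data$genotype == "ab"),
      n_bb = sum(.data$genotype == "bb"),
      n_missing = sum(.data$genotype == "missing"),
      n_progeny = dplyr::n(),
      missing_rate = .data$n_missing / .data$n_progeny
    )
}

chisq_121 <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  e <- cbind(n / 4, n / 2, n / 4)
  o <- cbind(n_aa, n_ab, n_bb)
  stat <- rowSums((o - e)^2 / e)
  stat[n == 0] <- NA_real_
  tibble(chi2_statistic = stat,
         chi2_p = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Filter markers on missing rate and 1:2:1 segregation
#'
#' Markers with `missing_rate >= max_missing` are dropped; survivors are
#' tested against the F2 expectation (n/4, n/2, n/4) over their non-missing
#' progeny with a 2-df chi-square (asymptotic, no continuity correction)
#' and dropped when p < `alpha` (segregation distortion).
#'
#' @param genotypes A `rad2b_genotypes` tibble from [genotype_progeny()].
#' @param max_missing Missing-rate cutoff (default 0.20).
#' @param alpha Distortion significance level (default 0.01).
#' @return A `rad2b_segregation` object: per-marker tibble with counts,
#'   missing rate, chi-square statistic/p and `status` in
#'   \{retained, dropped_missing, dropped_distorted, dropped_all_missing\};
#'   `glance()` summarises the stage counts.
#' @export
segregation_filter <- function(genotypes, max_missing = 0.20, alpha = 0.01) {
  if (nrow(genotypes) == 0L) abort("Empty genotype matrix.")
  per <- marker_counts(genotypes)
  per <- dplyr::bind_cols(per, chisq_121(per$n_aa, per$n_ab, per$n_bb))
  per <- per %>%
    dplyr::mutate(status = dplyr::case_when(
      .data$missing_rate >= max_missing ~ "dropped_missing",
      is.na(.data$chi2_statistic) ~ "dropped_all_missing",
      .data$chi2_p < alpha ~ "dropped_distorted",
      TRUE ~ "retained"
    ))
  structure(per, class = c("rad2b_segregation", class(per)),
            max_missing = max_missing, alpha = alpha)
}

#' @rdname segregation_filter
#' @param x A `rad2b_segregation` object.
#' @param ... Unused.
#' @export
tidy.rad2b_segregation <- function(x, ...) {
  as_tibble(x)
}

#' @rdname segregation_filter
#' @export
glance.rad2b_segregation <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    retained = sum(x$status == "retained"),
    dropped_missing = sum(x$status == "dropped_missing"),
    dropped_distorted = sum(x$status == "dropped_distorted"),
    dropped_all_missing = sum(x$status == "dropped_all_missing"),
    max_missing = attr(x, "max_missing"),
    alpha = attr(x, "alpha")
  )
}

#' @rdname segregation_filter
#' @param object A `rad2b_segregation` object.
#' @export
autoplot.rad2b_segregation <- function(object, ...) {
  d <- as_tibble(object) %>% dplyr::filter(!is.na(.data$chi2_p))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chi2_p,
                                  fill = .data$status)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = attr(object, "alpha"),
                        linetype = "dashed") +
    ggplot2::labs(x = "1:2:1 chi-square p-value", y = "markers",
                  title = "Segregation-test p-values") +
    ggplot2::theme_minimal()
}

#' Overall missing rate of a genotype matrix
#'
#' Total missing cells divided by (markers x progeny).
#'
#' @param genotypes A `rad2b_genotypes` tibble.
#' @return A fraction in \[0, 1\].
#' @export
overall_missing_rate <- function(genotypes) {
  mean(genotypes$genotype == "missing")
}

#' Write genotypes as a markers-by-samples TSV
#'
#' Symbols aa/ab/bb and `-` for missing. `format = "joinmap"` instead
#' writes locus rows `<locus> <a|h|b|-> ...` for downstream linkage
#' mapping tools.
#'
#' @param genotypes A `rad2b_genotypes` tibble.
#' @param path Output file.
#' @param format `"matrix"` (default) or `"joinmap"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, format = c("matrix",
                                                        "joinmap")) {
  format <- match.arg(format)
  wide <- genotypes %>%
    dplyr::mutate(genotype = dplyr::recode(.data$genotype,
                                           missing = "-")) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "genotype")
  if (format == "matrix") {
    readr::write_tsv(wide, path)
  } else {
    sym <- function(g) c(aa = "a", ab = "h", bb = "b", "-" = "-")[g]
    lines <- apply(wide, 1L, function(r) {
      paste(c(r[["site_id"]], sym(unlist(r[-1]))), collapse = " ")
    })
    writeLines(lines, path)
  }
  invisible(path)
}
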
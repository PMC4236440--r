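# End-to-end orchestration: demultiplex per library, assign tags to
# reference loci, summarise coverage, call genotypes and filter markers.

#' Run the full analysis pipeline on a read collection
#'
#' Chains the two-step read filter (per library), reference-tag coverage
#' accounting, per-sample genotype calling, aa x bb marker discovery
#' between the two parents, progeny genotyping and the missing-rate /
#' segregation filters.
#'
#' @param reads Tibble with `read_id`, `library`, `sample_id` is not
#'   required; only `library` and `sequence` are used (e.g. the `reads`
#'   element of [simulate_experiment()], or rows built from FASTQ files).
#' @param sample_sheet Tibble with `sample_id`, `library`, `barcode`.
#' @param ref_tags Reference tags from [extract_tags()].
#' @param parent_ids Character vector of length 2: the sample ids of
#'   parent A and parent B.
#' @param min_depth,min_het,max_het Genotype-calling thresholds, see
#'   [call_sample_genotype()].
#' @param max_missing,alpha Marker filters, see [segregation_filter()].
#' @param assign_mismatch Mismatch tolerance for locus assignment
#'   (default 2; see [collect_observations()]).
#' @return A `rad2b_result` list: `stats` (per-library `filter_stats`),
#'   `tags`, `coverage` (a `coverage_report`), `calls`, `markers`,
#'   `genotypes`, `segregation`, `overall_missing_rate`.
#' @export
run_pipeline <- function(reads, sample_sheet, ref_tags,
                         parent_ids = c("P_A", "P_B"),
                         min_depth = 2L, min_het = 0.010, max_het = 0.011,
                         max_missing = 0.20, alpha = 0.01,
                         assign_mismatch = 2L) {
  if (!"library" %in% names(reads)) reads$library <- "L01"
  if (!"library" %in% names(sample_sheet)) sample_sheet$library <- "L01"
  libs <- unique(reads$library)
  demux <- purrr::map(stats::setNames(libs, libs), function(lib) {
    demux_fastq(reads[reads$library == lib, , drop = FALSE],
                sample_sheet[sample_sheet$library == lib, , drop = FALSE])
  })
  tags <- dplyr::bind_rows(purrr::map(demux, "tags"))
  stats <- purrr::map(demux, "stats")

  index <- build_tag_index(ref_tags)
  cov <- assign_reads(tags, index, max_mismatch = 1L)
  coverage <- coverage_report(cov$depth)

  obs <- collect_observations(tags, ref_tags,
                              max_mismatch = assign_mismatch)
  calls <- call_sample_genotype(obs, min_depth = min_depth,
                                min_het = min_het, max_het = max_het)
  calls_a <- calls[calls$sample_id == parent_ids[1], ]
  calls_b <- calls[calls$sample_id == parent_ids[2], ]
  markers <- discover_markers(calls_a, calls_b)
  progeny_ids <- setdiff(sample_sheet$sample_id, parent_ids)
  progeny_ids <- intersect(progeny_ids, unique(tags$sample_id)) %>%
    union(progeny_ids)
  genotypes <- genotype_progeny(markers,
                                calls[!calls$sample_id %in% parent_ids, ],
                                progeny_ids = progeny_ids)
  seg <- if (nrow(genotypes) > 0L) {
    segregation_filter(genotypes, max_missing = max_missing, alpha = alpha)
  } else NULL
  structure(
    list(
      stats = stats, tags = tags, coverage = coverage, calls = calls,
      markers = markers, genotypes = genotypes, segregation = seg,
      overall_missing_rate = if (nrow(genotypes) > 0L) {
        overall_missing_rate(genotypes)
      } else NA_real_
    ),
    class = "rad2b_result"
  )
}

#' @export
print.rad2b_result <- function(x, ...) {
  cat("<rad2b_result>\n")
  tot <- sum(vapply(x$stats, function(s) s$total_reads, numeric(1)))
  hq <- sum(vapply(x$stats, function(s) s$high_quality, numeric(1)))
  cat(sprintf("  reads: %d total, %d high quality (%.1f%%)\n", tot, hq,
              if (tot) 100 * hq / tot else 0))
  cat(sprintf("  coverage: %.2f%% of %d sites, mean depth %.2f\n",
              100 * x$coverage$coverage_rate, x$coverage$total_sites,
              x$coverage$mean_depth))
  cat(sprintf("  markers: %d discovered", nrow(x$markers)))
  if (!is.null(x$segregation)) {
    cat(sprintf(", %d retained after filters",
                sum(x$segregation$status == "retained")))
  }
  cat("\n")
  if (!is.na(x$overall_missing_rate)) {
    cat(sprintf("  overall missing rate: %.1f%%\n",
                100 * x$overall_missing_rate))
  }
  invisible(x)
}

#' Run the pipeline on a simulated experiment
#'
#' Convenience wrapper: feeds a [simulate_experiment()] result through
#' [run_pipeline()] against its own reference tags.
#'
#' @param sim A `rad2b_sim`.
#' @param ... Passed to [run_pipeline()].
#' @return A `rad2b_result`.
#' @export
run_pipeline_sim <- function(sim, ...) {
  run_pipeline(sim$reads, sim$sample_sheet, sim$ref_tags,
               parent_ids = c("P_A", "P_B"), ...)
}

#' Compare pipeline genotypes with simulator truth
#'
#' Joins the called genotype matrix with the truth matrix on
#' (marker site, progeny) and reports non-missing concordance.
#'
#' @param result A `rad2b_result`.
#' @param sim The `rad2b_sim` it was computed from.
#' @return One-row tibble: `n_cells`, `n_called`, `n_concordant`,
#'   `concordance`, `missing_rate`.
#' @export
genotype_concordance <- function(result, sim) {
  joined <- result$genotypes %>%
    dplyr::inner_join(sim$genotypes, by = c("site_id", "sample_id"),
                      suffix = c("_called", "_truth"))
  called <- joined$genotype_called != "missing"
  tibble(
    n_cells = nrow(joined),
    n_called = sum(called),
    n_concordant = sum(called &
                         joined$genotype_called == joined$genotype_truth),
    concordance = sum(called & joined$genotype_called ==
                        joined$genotype_truth) / sum(called),
    missing_rate = mean(!called)
  )
}
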
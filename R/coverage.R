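# Restriction-site coverage accounting. Reference tags anchor the loci;
# sample tags are looked up in a canonical-sequence index and per-site
# depths summarised. "Depth" divides assigned reads by the total expected
# sites (not by the covered ones), and "coverage rate" divides sites seen
# at depth >= 1 by the total — the saturation the method approaches as
# sequencing depth doubles.

#' Build a canonical-sequence index over reference tags
#'
#' @param ref_tags Tibble from [extract_tags()] (canonical sequences
#'   present).
#' @return A tibble keyed by `canonical_sequence` with list-column
#'   `site_ids` and `n_sites`; unique tags map to one site.
#' @export
build_tag_index <- function(ref_tags) {
  if (nrow(ref_tags) == 0L) {
    return(tibble(canonical_sequence = character(), site_ids = list(),
                  n_sites = integer()))
  }
  ref_tags %>%
    dplyr::group_by(.data$canonical_sequence) %>%
    dplyr::summarise(site_ids = list(.data$site_id),
                     n_sites = dplyr::n()) %>%
    dplyr::ungroup()
}

# All 3*33 = 99 single-substitution neighbours of each 33-mer, as a long
# tibble (query index, neighbour).
substitution_neighbours <- function(seqs) {
  L <- nchar(seqs[1])
  out <- vector("list", L * 3L)
  k <- 0L
  for (p in seq_len(L)) {
    cur <- substr(seqs, p, p)
    for (b in DNA_BASES) {
      k <- k + 1L
      nb <- seqs
      substr(nb, p, p) <- b
      keep <- cur != b
      out[[k]] <- tibble(query = which(keep), neighbour = nb[keep])
    }
  }
  dplyr::bind_rows(out)
}

# Map every single-substitution neighbour of the unique-site reference
# tags to its site; neighbours reachable from tags of two or more sites
# are marked NA (ambiguous). Enumerating the index side keeps the
# neighbourhood size bounded by the reference, not the read count.
neighbour_site_map <- function(site_of) {
  if (length(site_of) == 0L) {
    return(tibble(neighbour = character(), site = character()))
  }
  nb <- substitution_neighbours(names(site_of))
  nb$site <- unname(site_of[nb$query])
  nb %>%
    dplyr::distinct(.data$neighbour, .data$site) %>%
    dplyr::group_by(.data$neighbour) %>%
    dplyr::summarise(site = if (dplyr::n() == 1L) .data$site[1]
                     else NA_character_)
}

#' Assign canonical sample tags to reference sites
#'
#' Exact canonical-sequence lookup; with `max_mismatch = 1` a failed exact
#' lookup enumerates all 99 single-substitution neighbours and assigns the
#' read iff exactly one site is hit. Reads matching tags present at more
#' than one site are left unassigned, mirroring unique-mapping alignment
#' (multi-mapped loci are excluded from coverage by default).
#'
#' @param tags Character vector of canonical 33-nt sample tags, or the
#'   `tags` tibble from [demux_fastq()] (its `tag` column is used).
#' @param index Tibble from [build_tag_index()].
#' @param max_mismatch 0 (default) or 1.
#' @return A list with `depth` (tibble `site_id`, `depth` covering every
#'   indexed unique site) and `n_unassigned`.
#' @export
assign_reads <- function(tags, index, max_mismatch = 0L) {
  if (max_mismatch > 1L) abort("`max_mismatch` must be 0 or 1.")
  if (is.data.frame(tags)) tags <- tags$tag
  uniq_index <- index %>% dplyr::filter(.data$n_sites == 1L)
  site_of <- stats::setNames(
    vapply(uniq_index$site_ids, `[[`, character(1), 1L),
    uniq_index$canonical_sequence
  )
  assigned_site <- unname(site_of[tags])
  if (max_mismatch == 1L && anyNA(assigned_site) && length(tags) > 0L) {
    nbmap <- neighbour_site_map(site_of)
    miss <- which(is.na(assigned_site))
    hit <- match(tags[miss], nbmap$neighbour)
    assigned_site[miss] <- nbmap$site[hit]
  }
  depth_tbl <- tibble(site_id = vapply(uniq_index$site_ids, `[[`,
                                       character(1), 1L)) %>%
    dplyr::left_join(
      tibble(site_id = assigned_site[!is.na(assigned_site)]) %>%
        dplyr::count(.data$site_id, name = "depth"),
      by = "site_id"
    ) %>%
    tidyr::replace_na(list(depth = 0L))
  list(depth = depth_tbl, n_unassigned = sum(is.na(assigned_site)))
}

#' Summarise site coverage
#'
#' @param depth Tibble with `site_id`, `depth` (from [assign_reads()]).
#' @return A `coverage_report` object: total sites, covered sites
#'   (depth >= 1), coverage rate, assigned read count, mean depth
#'   (assigned reads over total sites) and the per-site depth histogram.
#' @export
coverage_report <- function(depth) {
  if (nrow(depth) == 0L) abort("No sites: cannot build a coverage report.")
  total <- nrow(depth)
  covered <- sum(depth$depth >= 1L)
  assigned <- sum(depth$depth)
  structure(
    list(
      total_sites = total, covered_sites = covered,
      coverage_rate = covered / total,
      assigned_read_count = assigned,
      mean_depth = assigned / total,
      depth_histogram = depth %>% dplyr::count(.data$depth, name = "n_sites")
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  cat(sprintf("  sites covered: %d / %d (%.2f%%)\n", x$covered_sites,
              x$total_sites, 100 * x$coverage_rate))
  cat(sprintf("  assigned reads: %d, mean depth %.2f\n",
              x$assigned_read_count, x$mean_depth))
  invisible(x)
}

#' @rdname coverage_report
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @export
glance.coverage_report <- function(x, ...) {
  tibble(
    total_sites = x$total_sites, covered_sites = x$covered_sites,
    coverage_rate = x$coverage_rate,
    assigned_read_count = x$assigned_read_count, mean_depth = x$mean_depth
  )
}

#' Coverage as a function of sequencing effort
#'
#' Subsamples the assigned reads without replacement at the given
#' fractions and recomputes mean depth and coverage rate, tracing the
#' saturation curve (in the uniform-Poisson limit, coverage at mean depth
#' d approaches 1 - exp(-d)).
#'
#' @param assignment Result of [assign_reads()], or a depth tibble.
#' @param fractions Numeric vector in (0, 1].
#' @param seed Integer seed for the subsampling.
#' @return A `rad2b_saturation` tibble: `fraction`, `n_reads`,
#'   `mean_depth`, `coverage_rate`.
#' @export
saturation_curve <- function(assignment, fractions = c(0.1, 0.25, 0.5,
                                                       0.75, 1),
                             seed = 1L) {
  depth <- if (is.data.frame(assignment)) assignment else assignment$depth
  if (any(fractions <= 0 | fractions > 1)) {
    abort("`fractions` must lie in (0, 1].")
  }
  reads <- rep(depth$site_id, depth$depth)
  if (length(reads) == 0L) {
    return(structure(tibble(fraction = numeric(), n_reads = integer(),
                            mean_depth = numeric(),
                            coverage_rate = numeric()),
                     class = c("rad2b_saturation", "tbl_df", "tbl",
                               "data.frame")))
  }
  total_sites <- nrow(depth)
  out <- with_seed(seed, {
    purrr::map_dfr(sort(fractions), function(f) {
      k <- round(f * length(reads))
      sub <- if (k >= length(reads)) reads else sample(reads, k)
      tibble(
        fraction = f, n_reads = k,
        mean_depth = k / total_sites,
        coverage_rate = length(unique(sub)) / total_sites
      )
    })
  })
  structure(out, class = c("rad2b_saturation", class(out)))
}

#' @rdname saturation_curve
#' @param object A `rad2b_saturation` tibble.
#' @param ... Unused.
#' @export
autoplot.rad2b_saturation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_depth,
                                       y = .data$coverage_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::stat_function(fun = function(d) 1 - exp(-d),
                           linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "mean depth (reads / site)", y = "coverage rate",
                  title = "Site-coverage saturation",
                  subtitle = "dashed: 1 - exp(-depth), uniform Poisson limit") +
    ggplot2::theme_minimal()
}

#' Write a per-site depth table as TSV
#'
#' @param depth Tibble `site_id`, `depth`; site ids of the form
#'   `sequence:start:orientation` are expanded into coordinate columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth, path) {
  parts <- stringr::str_split_fixed(depth$site_id, ":", 3)
  out <- depth %>%
    dplyr::mutate(sequence_id = parts[, 1],
                  site_start = suppressWarnings(as.integer(parts[, 2])),
                  .after = "site_id")
  readr::write_tsv(out, path)
  invisible(path)
}
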
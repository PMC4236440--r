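# Fixed-window enzyme-landscape simulation: tile a genome into windows the
# size of a typical small scaffold and classify each by how many recognition
# sites it holds. A window with 0 sites cannot be anchored to a chromosome
# by tag markers, 1 site anchors it without orientation, >= 2 allow an
# oriented placement — the "assembly potentiality" classes.

#' Tile sequences into fixed non-overlapping windows
#'
#' Windows are consecutive, non-overlapping and per-sequence; a trailing
#' remainder shorter than `window_size` is discarded and counted in the
#' `n_discarded_remainders` attribute.
#'
#' @param seq_lengths Named integer vector of sequence lengths, or a
#'   genome accepted by [scan_sites()] (lengths are taken from it).
#' @param window_size Window size in bp (default 4000, roughly one EcoRI
#'   site's worth of sequence in plant and animal genomes).
#' @return Tibble with columns `window_id`, `sequence_id`, `start`, `end`
#'   (0-based half-open).
#' @export
#' @examples
#' tile_windows(c(chr1 = 12000L), window_size = 4000)
tile_windows <- function(seq_lengths, window_size = 4000L) {
  if (window_size <= 0L) abort("`window_size` must be >= 1.")
  if (!is.numeric(seq_lengths)) {
    seq_lengths <- nchar(as_genome(seq_lengths))
  }
  if (is.null(names(seq_lengths))) {
    names(seq_lengths) <- paste0("seq", seq_along(seq_lengths))
  }
  n_win <- floor(seq_lengths / window_size)
  out <- purrr::imap(seq_lengths, function(len, id) {
    k <- floor(len / window_size)
    if (k == 0L) return(NULL)
    start <- as.integer((seq_len(k) - 1L) * window_size)
    tibble(sequence_id = id, start = start,
           end = as.integer(start + window_size))
  }) %>%
    dplyr::bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble(sequence_id = character(), start = integer(),
                  end = integer())
  }
  out <- dplyr::mutate(out, window_id = dplyr::row_number(),
                       .before = "sequence_id")
  attr(out, "n_discarded_remainders") <-
    sum(seq_lengths %% window_size > 0L)
  out
}

site_class <- function(count) {
  dplyr::case_when(count == 0L ~ "zero", count == 1L ~ "one",
                   TRUE ~ "many")
}

#' Count and classify enzyme sites per window
#'
#' A site is assigned to the window containing its pattern start
#' coordinate; sites falling in a discarded trailing remainder are
#' excluded and tallied in the `n_sites_outside_windows` attribute. For
#' each enzyme the window gains a `count_<enzyme>` column and a
#' `class_<enzyme>` column over \{zero, one, many\}.
#'
#' @param windows Tibble from [tile_windows()].
#' @param sites Named list of site tibbles from [scan_sites()], one per
#'   enzyme (names are enzyme names), or a single site tibble.
#' @return `windows` with per-enzyme count and class columns.
#' @export
classify_windows <- function(windows, sites) {
  if (is.data.frame(sites)) {
    sites <- stats::setNames(list(sites), sites$enzyme[1] %||% "enzyme")
  }
  window_size <- if (nrow(windows) > 0) windows$end[1] - windows$start[1] else 1L
  n_outside <- 0L
  for (enz in names(sites)) {
    s <- sites[[enz]]
    key <- paste0(s$sequence_id, ":", floor(s$start / window_size))
    wkey <- paste0(windows$sequence_id, ":", windows$start / window_size)
    hit <- table(key[key %in% wkey])
    n_outside <- n_outside + sum(!key %in% wkey)
    cnt <- as.integer(hit[wkey])
    cnt[is.na(cnt)] <- 0L
    windows[[paste0("count_", enz)]] <- cnt
    windows[[paste0("class_", enz)]] <- site_class(cnt)
  }
  attr(windows, "n_sites_outside_windows") <- n_outside
  windows
}

#' Cross-tabulate two enzymes' window occupancy
#'
#' Summarises how a second enzyme rescues windows that the first cannot
#' anchor: marginal class counts for enzyme A, the windows where A has no
#' site but B has two or more, where A has exactly one and B at least one,
#' and the windows whose combined A+B site count reaches two (orientable
#' scaffolds).
#'
#' @param windows Tibble from [classify_windows()], classified for both
#'   enzymes.
#' @param enzyme_a,enzyme_b Enzyme names present in `windows`.
#' @return A one-row tibble of counts and fractions.
#' @export
cross_tabulate <- function(windows, enzyme_a, enzyme_b) {
  for (enz in c(enzyme_a, enzyme_b)) {
    if (!paste0("class_", enz) %in% names(windows)) {
      abort(paste0("Windows are not classified for ", enz,
                   "; run classify_windows() first."))
    }
  }
  ca <- windows[[paste0("class_", enzyme_a)]]
  cb <- windows[[paste0("class_", enzyme_b)]]
  na_ <- windows[[paste0("count_", enzyme_a)]]
  nb <- windows[[paste0("count_", enzyme_b)]]
  n <- nrow(windows)
  frac <- function(k) if (n == 0L) 0 else k / n
  tibble(
    n_windows = n,
    a_zero = sum(ca == "zero"), a_one = sum(ca == "one"),
    a_many = sum(ca == "many"),
    a_zero_b_many = sum(ca == "zero" & cb == "many"),
    a_one_b_any = sum(ca == "one" & cb != "zero"),
    combined_ge2 = sum(na_ + nb >= 2L),
    frac_a_zero = frac(.data$a_zero),
    frac_a_zero_b_many = frac(.data$a_zero_b_many),
    frac_a_one_b_any = frac(.data$a_one_b_any),
    frac_combined_ge2 = frac(.data$combined_ge2)
  )
}

#' Plot window occupancy classes
#'
#' Stacked per-enzyme bar chart of the zero/one/many window classes.
#'
#' @param windows Tibble from [classify_windows()].
#' @return A ggplot object.
#' @export
plot_window_classes <- function(windows) {
  long <- windows %>%
    dplyr::select("window_id", dplyr::starts_with("class_")) %>%
    tidyr::pivot_longer(-"window_id", names_to = "enzyme",
                        names_prefix = "class_", values_to = "class") %>%
    dplyr::mutate(class = factor(.data$class, c("zero", "one", "many")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$enzyme, fill = .data$class)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "windows",
                  title = "Recognition-site occupancy per window") +
    ggplot2::theme_minimal()
}
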
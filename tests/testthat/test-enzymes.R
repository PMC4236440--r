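test_that("registry holds the five enzymes with their geometries", {
  b <- enzyme_spec("BsaXI")
  expect_equal(b$plus_pattern, "ACNNNNNCTCC")
  expect_equal(b$minus_pattern, "GGAGNNNNNGT")
  expect_equal(b$upstream_flank + nchar(b$plus_pattern) + b$downstream_flank,
               33L)
  expect_equal(b$minus_pattern, brute_revcomp(b$plus_pattern))
  a <- enzyme_spec("AlfI")
  expect_equal(a$plus_pattern, brute_revcomp(a$plus_pattern))
  expect_false(a$supports_tag_extraction)
  expect_equal(enzyme_spec("EcoRI")$tags_per_site, 2L)
  expect_error(enzyme_spec("DpnII"), "Unknown enzyme")
})

test_that("scan_sites finds literal pattern instances and honours N", {
  expect_equal(scan_sites(c(chr1 = "GCAAAAAAATGC"), "AlfI")$start, 0L)
  expect_equal(nrow(scan_sites(character(), "BsaXI")), 0L)
  expect_equal(nrow(scan_sites(c(chr1 = ""), "BsaXI")), 0L)
  # an N inside the window kills the match
  expect_equal(nrow(scan_sites(c(chr1 = "GCAAAANAATGC"), "AlfI")), 0L)
  # both BsaXI forms on the plus strand, with orientations
  g <- c(chr1 = paste0("ACGGGGGCTCC", "TTTT", "GGAGCCCCCGT"))
  s <- scan_sites(g, "BsaXI")
  expect_equal(s$start, c(0L, 15L))
  expect_equal(s$orientation, c("plus_form", "minus_form"))
})

test_that("scan_sites equals the brute-force positional oracle", {
  for (seed in 1:3) {
    g <- random_genome(100000, seed)
    for (enz in c("BsaXI", "EcoRI", "AlfI")) {
      e <- enzyme_spec(enz)
      got <- scan_sites(g, enz)
      want_plus <- brute_scan(g[[1]], e$plus_pattern)
      expect_equal(got$start[got$orientation == "plus_form"], want_plus)
      if (!is.null(e$minus_pattern)) {
        want_minus <- brute_scan(g[[1]], e$minus_pattern)
        expect_equal(got$start[got$orientation == "minus_form"],
                     sort(want_minus))
      }
    }
  }
})

test_that("plus/minus site totals are invariant under reverse complement", {
  g <- random_genome(200000, 42)
  s1 <- scan_sites(g, "BsaXI")
  s2 <- scan_sites(stats::setNames(brute_revcomp(g[[1]]), "chr1"), "BsaXI")
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(sum(s1$orientation == "plus_form"),
               sum(s2$orientation == "minus_form"))
})

test_that("count_tags multiplies by tags per site", {
  sites5 <- tibble::tibble(sequence_id = "c", start = 1:5,
                           orientation = "plus_form", enzyme = "x")
  expect_equal(count_tags(sites5, "EcoRI"), 10L)
  expect_equal(count_tags(sites5, "BsaXI"), 5L)
  g <- random_genome(50000, 9)
  s <- scan_sites(g, "EcoRI")
  expect_equal(count_tags(s, "EcoRI"),
               2L * length(brute_scan(g[[1]], "GAATTC")))
})

test_that("extract_tags reproduces the 33-nt fragment geometry", {
  g <- stats::setNames(plant_site(random_genome(33, 3)[[1]], 12), "chr1")
  s <- scan_sites(g, "BsaXI")
  expect_equal(s$start, 12L)
  tg <- extract_tags(g, s, "BsaXI")
  expect_equal(tg$tag_start, 0L)
  expect_equal(tg$tag_end, 33L)
  expect_equal(nchar(tg$sequence), 33L)
  expect_equal(tg$sequence, g[[1]])
  expect_equal(attr(tg, "n_dropped"), 0L)
})

test_that("out-of-bounds tags are dropped and counted", {
  # site at start 5: upstream flank of 12 cannot fit
  g <- stats::setNames(plant_site(random_genome(60, 4)[[1]], 5), "chr1")
  s <- scan_sites(g, "BsaXI")
  s <- s[s$start == 5L, ]
  tg <- extract_tags(g, s, "BsaXI")
  expect_equal(nrow(tg), 0L)
  expect_equal(attr(tg, "n_dropped"), 1L)
  expect_error(extract_tags(g, s, "AlfI"), "not supported")
})

test_that("every extracted tag satisfies the canonical positional form", {
  g <- random_genome(300000, 77)
  tg <- extract_tags(g, scan_sites(g, "BsaXI"), "BsaXI")
  expect_gt(nrow(tg), 10)
  expect_true(all(nchar(tg$canonical_sequence) == 33L))
  expect_true(all(substr(tg$canonical_sequence, 13, 14) == "AC"))
  expect_true(all(substr(tg$canonical_sequence, 20, 23) == "CTCC"))
  # plus-form tags pass through; minus-form are reverse complements
  plus <- tg$orientation == "plus_form"
  expect_equal(tg$canonical_sequence[plus], tg$sequence[plus])
  expect_equal(tg$canonical_sequence[!plus],
               brute_revcomp(tg$sequence[!plus]))
})

test_that("canonicalize is an idempotent involution-composition", {
  tag <- make_tag(seed = 5)
  expect_equal(canonicalize(tag), tag)
  expect_equal(canonicalize(brute_revcomp(tag)), tag)
  set.seed(8)
  tags <- vapply(1:200, function(i) make_tag(seed = i), character(1))
  flip <- sample(c(TRUE, FALSE), 200, TRUE)
  x <- ifelse(flip, brute_revcomp(tags), tags)
  expect_equal(canonicalize(canonicalize(x)), canonicalize(x))
  expect_equal(canonicalize(x), tags)
  expect_error(canonicalize(strrep("A", 33)), "neither")
  expect_error(canonicalize("ACGT"), "33 nt")
})

test_that("uniqueness flags exact duplicates and optional near-duplicates", {
  tags <- tibble::tibble(
    site_id = paste0("s", 1:4),
    canonical_sequence = c(make_tag(seed = 1), make_tag(seed = 1),
                           make_tag(seed = 2), make_tag(seed = 3))
  )
  u <- find_unique_tags(tags)
  expect_equal(u$unique, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sum(u$unique), nrow(tags) - 2L)
  # hamming mode: plant a 1-mismatch pair
  t4 <- make_tag(seed = 2)
  substr(t4, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(t4, 1, 1))[1]
  tags2 <- tibble::tibble(site_id = paste0("s", 1:3),
                          canonical_sequence = c(make_tag(seed = 2), t4,
                                                 make_tag(seed = 9)))
  u2 <- find_unique_tags(tags2, max_mismatch = 1L)
  expect_equal(u2$unique, c(FALSE, FALSE, TRUE))
  expect_error(find_unique_tags(tags2, max_mismatch = 3L), "0, 1 or 2")
})

test_that("overlapping tag pairs match the quadratic oracle", {
  g <- random_genome(300000, 13)
  tg <- extract_tags(g, scan_sites(g, "BsaXI"), "BsaXI")
  got <- find_overlapping_tags(tg)
  # quadratic brute force
  want <- 0L
  for (i in seq_len(nrow(tg) - 1L)) {
    for (j in (i + 1L):nrow(tg)) {
      if (tg$tag_start[j] < tg$tag_end[i] && tg$tag_start[i] < tg$tag_end[j])
        want <- want + 1L
    }
  }
  expect_equal(nrow(got), want)
  # two sites 40 bp apart do not overlap; adjacent sites do
  far <- tibble::tibble(site_id = c("a", "b"), sequence_id = "c",
                        tag_start = c(0L, 40L), tag_end = c(33L, 73L))
  expect_equal(nrow(find_overlapping_tags(far)), 0L)
  near <- tibble::tibble(site_id = c("a", "b"), sequence_id = "c",
                         tag_start = c(0L, 20L), tag_end = c(33L, 53L))
  expect_equal(nrow(find_overlapping_tags(near)), 1L)
})

test_that("site density on random sequence matches 2/4^6 per position", {
  g <- random_genome(2000000, 1234)
  n <- nrow(scan_sites(g, "BsaXI"))
  expected <- 2 * (1 / 4)^6 * (nchar(g[[1]]) - 10)
  expect_lt(abs(n - expected), 5 * sqrt(expected))
})

test_that("BED and TSV writers round-trip coordinates", {
  g <- random_genome(50000, 21)
  s <- scan_sites(g, "BsaXI")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(s, bed, "BsaXI")
  back <- readr::read_tsv(bed, col_names = c("chrom", "start", "end",
                                             "name", "score", "strand"),
                          show_col_types = FALSE)
  expect_equal(back$start, s$start)
  expect_equal(back$end - back$start, rep(11, nrow(s)))
  expect_equal(back$strand == "+", s$orientation == "plus_form")
})
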
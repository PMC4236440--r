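sheet3 <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                         barcode = c("AACGC", "CGTAAT", "TTGCGAT"))

test_that("barcode matching: exact, one mismatch, ambiguity, too short", {
  tag <- make_tag(seed = 1)
  r_exact <- paste0("AACGC", tag)
  r_mm1 <- paste0("TACGC", tag)     # Hamming 1 from AACGC only
  r_short <- "AACGCAC"
  m <- match_barcode(c(r_exact, r_mm1, r_short), sheet3)
  expect_equal(m$reason, c("assigned", "assigned", "too_short"))
  expect_equal(m$sample_id[1:2], c("S1", "S1"))
  expect_equal(m$n_mismatch[1:2], c(0L, 1L))
  expect_equal(m$trimmed[1], tag)

  # a prefix Hamming-1 from two barcodes of the same length is ambiguous
  sheet_amb <- tibble::tibble(sample_id = c("A", "B"),
                              barcode = c("AAAAA", "AAAAT"))
  r_amb <- paste0("AAAAG", tag)  # distance 1 from both
  m2 <- match_barcode(r_amb, sheet_amb)
  expect_equal(m2$reason, "ambiguous")
  # no candidate at distance <= 1
  m3 <- match_barcode(paste0("GGGGG", tag), sheet_amb)
  expect_equal(m3$reason, "no_match")
})

test_that("longer exact barcode wins over shorter mismatch candidates", {
  tag <- make_tag(seed = 3)
  sheet <- tibble::tibble(sample_id = c("S", "L"),
                          barcode = c("AACGC", "AACGCTT"))
  # read starts with the longer barcode exactly; prefix-freeness is
  # violated here on purpose to pin the longest-first rule
  m <- match_barcode(paste0("AACGCTT", tag), sheet)
  expect_equal(m$sample_id, "L")
})

test_that("tag matching enforces the positional forms and the N rule", {
  tag <- make_tag(seed = 4)
  plus <- match_tag(paste0(tag, "AGATCGGAAGAG"))
  expect_equal(plus$reason, "accepted")
  expect_equal(plus$tag, tag)

  minus <- match_tag(brute_revcomp(tag))
  expect_equal(minus$reason, "accepted")
  expect_equal(minus$tag, tag)

  with_n <- tag
  substr(with_n, 20, 20) <- "N"
  expect_equal(match_tag(with_n)$reason, "has_N")
  expect_equal(match_tag(strrep("A", 33))$reason, "no_site")
  expect_equal(match_tag("ACGT")$reason, "too_short")
})

test_that("demultiplexing satisfies read conservation and truth counts", {
  cfg <- sim_config(seed = 20, chromosome_lengths = c(chr1 = 30000L),
                    n_planted_sites = 40L, snp_rate = 0.2, n_progeny = 10L,
                    lambda = 8, error_rate = 0, contaminant_fraction = 0.1)
  sim <- simulate_experiment(cfg)
  lib <- sim$reads$library[1]
  reads <- sim$reads[sim$reads$library == lib, ]
  res <- demux_fastq(reads, sim$sample_sheet[sim$sample_sheet$library ==
                                               lib, ])
  st <- res$stats
  expect_equal(st$total_reads, nrow(reads))
  expect_equal(st$total_reads, st$barcode_matched + st$rejected_barcode)
  expect_equal(st$barcode_matched,
               st$high_quality + st$rejected_site_or_N)
  # with zero error every non-contaminant read is high quality
  truth <- sim$read_truth[sim$read_truth$library == lib, ]
  expect_equal(st$high_quality, sum(!truth$contaminant))
  expect_equal(st$rejected_barcode, 0L)
  # output stream is purely canonical
  expect_true(all(substr(res$tags$tag, 13, 14) == "AC"))
  expect_true(all(substr(res$tags$tag, 20, 23) == "CTCC"))
  # per-read outcomes partition the input
  expect_equal(nrow(res$reads), nrow(reads))
  expect_true(all(res$reads$outcome %in%
                    c("high_quality", "rejected_has_N", "rejected_no_site",
                      "rejected_too_short", "unassigned_no_match",
                      "unassigned_ambiguous", "unassigned_too_short")))
})

test_that("evenness ratio is 1 for a symmetric fixture", {
  set <- design_barcodes(3, lengths = 5, seed = 6)
  d <- library_design(barcode_set = set)
  tag <- make_tag(seed = 7)
  reads <- unlist(lapply(set$barcode, function(b) {
    rep(construct_read(d, b, tag), 10)
  }))
  res <- demux_fastq(reads, set)
  expect_equal(res$stats$evenness_ratio, 1)
  expect_equal(glance(res$stats)$high_quality, 30L)
  expect_equal(nrow(tidy(res$stats)), 3L)
})

test_that("empty input yields zeroed statistics", {
  res <- demux_fastq(character(), sheet3)
  expect_equal(res$stats$total_reads, 0L)
  expect_equal(res$stats$high_quality, 0L)
  expect_equal(nrow(res$tags), 0L)
})

test_that("site-filter rejection rate follows the fixed-position model", {
  # with substitution rate e, a read fails the site test iff any of the
  # 6 fixed pattern bases (AC + CTCC) mutates: P(pass) = (1 - e)^6
  tag <- make_tag(seed = 9)
  e <- 0.05
  n <- 20000
  set.seed(10)
  reads <- rep(tag, n)
  L <- 33L
  n_err <- stats::rbinom(n, L, e)
  for (i in which(n_err > 0)) {
    for (p in sample(L, n_err[i])) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                       1)
    }
  }
  acc <- mean(match_tag(reads)$reason == "accepted")
  expected <- (1 - e)^6
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(acc - expected), 5 * se)
})

test_that("rejected reads are classified against the genome", {
  g <- random_genome(20000, 44)
  frag <- substr(g[[1]], 101, 133)
  # the fixture fragment must not itself be a valid tag (fixed seed)
  expect_equal(match_tag(frag)$reason, "no_site")
  random_read <- paste(rep("ACGT", 9), collapse = "")
  cr <- classify_rejected(c(frag, substr(random_read, 1, 33)), g)
  expect_equal(cr$n_rejected, 2L)
  expect_equal(cr$n_genomic, 1L)
  expect_equal(cr$fraction, 0.5)

  # simulator contaminants are genomic by construction
  cfg <- sim_config(seed = 21, chromosome_lengths = c(chr1 = 30000L),
                    n_planted_sites = 30L, n_progeny = 5L, lambda = 6,
                    error_rate = 0, contaminant_fraction = 0.2)
  sim <- simulate_experiment(cfg)
  lib <- sim$reads$library[1]
  res <- demux_fastq(sim$reads[sim$reads$library == lib, ],
                     sim$sample_sheet[sim$sample_sheet$library == lib, ])
  rej <- res$reads$outcome == "rejected_no_site"
  truth <- sim$read_truth[sim$read_truth$library == lib, ]
  bc_len <- nchar(sim$sample_sheet$barcode[
    match(truth$sample_id, sim$sample_sheet$sample_id)])
  trimmed <- substr(truth$sequence, bc_len + 1L, nchar(truth$sequence))
  cr2 <- classify_rejected(trimmed[rej], sim$genome)
  expect_equal(cr2$fraction, 1)
  expect_equal(cr2$n_rejected, sum(truth$contaminant))
})

test_that("FASTQ round-trips through the writers and readers", {
  reads <- tibble::tibble(read_id = c("r1", "r2"),
                          sequence = c(make_tag(seed = 1),
                                       make_tag(seed = 2)))
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, reads)
})
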
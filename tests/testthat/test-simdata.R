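test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(error_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(lambda = -1), ">= 0")
  expect_error(sim_config(chromosome_lengths = c(chr1 = 50L)), ">= 100")
})

test_that("genome generation is seeded and plants detectable sites", {
  cfg <- sim_config(seed = 2, chromosome_lengths = c(chr1 = 20000L),
                    n_planted_sites = 25L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_equal(nrow(g1$planted_sites), 25L)
  found <- scan_sites(g1$genome, "BsaXI")
  expect_gte(nrow(found), 25L)
  # every planted site is found at its position and orientation
  key <- paste(found$start, found$orientation)
  expect_true(all(paste(g1$planted_sites$start,
                        g1$planted_sites$orientation) %in% key))
  expect_error(generate_genome(sim_config(
    chromosome_lengths = c(chr1 = 1000L), n_planted_sites = 100L
  )), "Cannot place")
})

test_that("background site density matches the closed form", {
  cfg <- sim_config(seed = 3, chromosome_lengths = c(chr1 = 1000000L),
                    n_planted_sites = NULL)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$planted_sites), 0L)
  n <- nrow(scan_sites(g$genome, "BsaXI"))
  expected <- 2 * (1 / 4)^6 * 1e6
  expect_lt(abs(n - expected), 5 * sqrt(expected))
})

test_that("parental SNPs respect tag footprints and recognition bases", {
  cfg <- sim_config(seed = 4, chromosome_lengths = c(chr1 = 30000L),
                    n_planted_sites = 40L, snp_rate = 1, two_snp_prob = 0.3)
  gen <- generate_genome(cfg)
  sites <- scan_sites(gen$genome, "BsaXI")
  tags <- extract_tags(gen$genome, sites, "BsaXI")
  par <- generate_parents(gen$genome, tags, cfg)
  expect_identical(par$parent_a, gen$genome)
  expect_false(identical(par$parent_b, gen$genome))
  # recognition positions untouched: no site is lost in parent B
  sites_b <- scan_sites(par$parent_b, "BsaXI")
  expect_true(all(paste(sites$start, sites$orientation) %in%
                    paste(sites_b$start, sites_b$orientation)))
  expect_true(all(par$snps$tag_offset %in%
                    setdiff(0:32, c(12, 13, 19:22))))
  expect_true(all(table(par$snps$site_id) <= 2))

  # rate 0: identical parents, no downstream markers
  cfg0 <- sim_config(seed = 4, chromosome_lengths = c(chr1 = 30000L),
                     n_planted_sites = 40L, snp_rate = 0)
  par0 <- generate_parents(gen$genome, tags, cfg0)
  expect_identical(par0$parent_b, gen$genome)
  expect_equal(nrow(par0$snps), 0L)
})

test_that("F2 genotypes segregate 1:2:1", {
  cfg <- sim_config(seed = 5, n_progeny = 10000L)
  g <- generate_f2("site1", cfg)
  expect_equal(nrow(g), 10000L)
  p <- table(g$genotype) / nrow(g)
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
  expect_lt(abs(p[["aa"]] - 0.25), 3 * se[1])
  expect_lt(abs(p[["ab"]] - 0.50), 3 * se[2])
  expect_lt(abs(p[["bb"]] - 0.25), 3 * se[3])
  # n = 1 yields one valid row
  g1 <- generate_f2("site1", sim_config(n_progeny = 1L))
  expect_equal(nrow(g1), 1L)
  expect_true(g1$genotype %in% c("aa", "ab", "bb"))
})

test_that("linked mode keeps co-located markers identical", {
  sites <- tibble::tibble(site_id = c("a", "b"), sequence_id = "chr1",
                          site_start = c(500L, 500L))
  cfg <- sim_config(seed = 6, n_progeny = 50L)
  g <- generate_f2(sites, cfg, recombination = "poisson",
                   map_length_cM = 100)
  wide <- tidyr::pivot_wider(g, names_from = "site_id",
                             values_from = "genotype")
  expect_equal(wide$a, wide$b)
})

test_that("read simulation is reproducible and consistent with truth", {
  cfg <- sim_config(seed = 7, chromosome_lengths = c(chr1 = 20000L),
                    n_planted_sites = 20L, n_progeny = 5L, lambda = 5,
                    error_rate = 0, contaminant_fraction = 0.1)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$genotypes, s2$genotypes)
  # truth bookkeeping is consistent with the emitted reads
  expect_equal(nrow(s1$reads), nrow(s1$read_truth))
  expect_equal(sum(is.na(s1$read_truth$site_id)),
               sum(s1$read_truth$contaminant))
  # at error 0, non-contaminant reads reconstruct from their truth fields
  rt <- s1$read_truth[!s1$read_truth$contaminant, ][1:50, ]
  alle <- s1$parent_alleles
  bc <- stats::setNames(s1$sample_sheet$barcode, s1$sample_sheet$sample_id)
  for (i in seq_len(nrow(rt))) {
    gt <- if (rt$sample_id[i] == "P_A") "aa"
          else if (rt$sample_id[i] == "P_B") "bb"
          else s1$genotypes$genotype[s1$genotypes$sample_id ==
                                       rt$sample_id[i] &
                                     s1$genotypes$site_id == rt$site_id[i]]
    cand <- c(alle$allele_a[alle$site_id == rt$site_id[i]],
              alle$allele_b[alle$site_id == rt$site_id[i]])
    if (gt == "aa") cand <- cand[1]
    if (gt == "bb") cand <- cand[2]
    if (rt$strand[i] == "minus") cand <- brute_revcomp(cand)
    built <- substr(rt$sequence[i], nchar(bc[[rt$sample_id[i]]]) + 1L,
                    nchar(bc[[rt$sample_id[i]]]) + 33L)
    expect_true(built %in% cand)
  }
})

test_that("saturated error rate destroys the site filter pass rate", {
  cfg <- sim_config(seed = 8, chromosome_lengths = c(chr1 = 15000L),
                    n_planted_sites = 15L, n_progeny = 3L, lambda = 5,
                    error_rate = 1, contaminant_fraction = 0)
  sim <- simulate_experiment(cfg)
  lib <- sim$reads$library[1]
  res <- demux_fastq(sim$reads[sim$reads$library == lib, ],
                     sim$sample_sheet[sim$sample_sheet$library == lib, ])
  expect_lt(res$stats$high_quality / res$stats$total_reads, 0.01)
})

test_that("simulator outputs round-trip through disk", {
  cfg <- sim_config(seed = 9, chromosome_lengths = c(chr1 = 15000L),
                    n_planted_sites = 10L, n_progeny = 3L, lambda = 3)
  sim <- simulate_experiment(cfg)
  out <- withr::local_tempdir()
  write_sim(sim, out)
  genome_back <- Biostrings::readDNAStringSet(file.path(out,
                                                        "genome.fasta"))
  expect_equal(as.character(genome_back)[["chr1"]], sim$genome[["chr1"]])
  lib <- sim$reads$library[1]
  fq <- read_fastq(file.path(out, paste0(lib, ".fastq.gz")))
  expect_equal(fq$sequence,
               sim$reads$sequence[sim$reads$library == lib])
  sheet <- read_sample_sheet(file.path(out, "sample_sheet.tsv"))
  expect_equal(sheet$sample_id, sim$sample_sheet$sample_id)
})

test_that("missing rate rises when depth drops", {
  base <- list(seed = 31, chromosome_lengths = c(chr1 = 25000L),
               n_planted_sites = 30L, snp_rate = 1, n_progeny = 30L,
               error_rate = 0.001)
  lo <- do.call(sim_config, c(base, lambda = 3))
  hi <- do.call(sim_config, c(base, lambda = 20))
  m <- vapply(list(lo, hi), function(cfg) {
    res <- run_pipeline_sim(simulate_experiment(cfg))
    res$overall_missing_rate
  }, numeric(1))
  expect_gt(m[1], m[2])
})
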
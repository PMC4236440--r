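# Synthetic-data generator. Emulates the study design the pipeline
# assumes: a diploid F2 cross between two homozygous parents that differ
# by 1-2 SNPs inside some 33-nt tag footprints, 1:2:1 progeny segregation,
# Poisson per-site read depth, i.i.d. substitution sequencing error,
# a random strand of origin per read (fair coin by default), 5-9-nt inline
# barcodes with adapter read-through, and an optional fraction of
# between-site contaminant fragments. Every stochastic choice is recorded
# in truth tables so downstream modules can be tested against ground truth.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: 277 F2
#' progeny plus two parents, libraries of 12 samples sharing a barcode
#' set, SE50 reads, Poisson per-site depth lambda = 10, per-base
#' substitution error 0.001, strand flipped with probability 0.5 and a
#' 10% contaminant (between-site fragment) load. A small fraction of
#' polymorphic tags (default 5%) reflects a cross between close relatives;
#' 1 SNP per mutated tag with an occasional second (7%).
#'
#' @param seed Master seed; all generator randomness derives from it.
#' @param chromosome_lengths Named integer vector of chromosome lengths.
#' @param n_planted_sites Recognition sites planted per genome (NULL for
#'   natural background density only).
#' @param snp_rate Fraction of tag footprints carrying parental SNPs.
#' @param two_snp_prob Probability a mutated tag carries 2 SNPs (else 1).
#' @param n_progeny F2 progeny count.
#' @param lambda Poisson mean reads per site per sample.
#' @param error_rate Per-base substitution error.
#' @param contaminant_fraction Fraction of reads replaced by site-free
#'   genomic 33-mers.
#' @param strand_flip_prob Probability a read comes from the minus strand.
#' @param read_length Read length (SE50 default).
#' @return A `sim_config` list; rates validated to lie in \[0, 1\].
#' @export
sim_config <- function(seed = 1L,
                       chromosome_lengths = c(chr1 = 100000L),
                       n_planted_sites = 50L,
                       snp_rate = 0.05,
                       two_snp_prob = 0.07,
                       n_progeny = 277L,
                       lambda = 10,
                       error_rate = 0.001,
                       contaminant_fraction = 0.1,
                       strand_flip_prob = 0.5,
                       read_length = 50L) {
  rates <- c(snp_rate, two_snp_prob, error_rate, contaminant_fraction,
             strand_flip_prob)
  if (any(rates < 0 | rates > 1)) abort("All rates must lie in [0, 1].")
  if (lambda < 0) abort("`lambda` must be >= 0.")
  if (any(chromosome_lengths < 100L)) {
    abort("Chromosome lengths must be >= 100.")
  }
  structure(
    list(
      seed = as.integer(seed), chromosome_lengths = chromosome_lengths,
      n_planted_sites = n_planted_sites, snp_rate = snp_rate,
      two_snp_prob = two_snp_prob, n_progeny = as.integer(n_progeny),
      lambda = lambda, error_rate = error_rate,
      contaminant_fraction = contaminant_fraction,
      strand_flip_prob = strand_flip_prob,
      read_length = as.integer(read_length)
    ),
    class = "sim_config"
  )
}

#' Generate a random genome with planted recognition sites
#'
#' The background is i.i.d. uniform ACGT. In planted mode the requested
#' number of BsaXI sites (random plus/minus form, degenerate positions
#' random) are written at positions spaced widely enough for full 33-nt
#' tags; the background may contribute further natural sites, so the
#' planted list is a lower bound on what [scan_sites()] finds.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector) and
#'   `planted_sites` (tibble `sequence_id`, `start`, `orientation`).
#' @export
generate_genome <- function(config) {
  e <- enzyme_spec("BsaXI")
  with_seed(config$seed, {
    genome <- stats::setNames(
      random_dna(config$chromosome_lengths),
      names(config$chromosome_lengths)
    )
    planted <- tibble(sequence_id = character(), start = integer(),
                      orientation = character())
    if (!is.null(config$n_planted_sites) && config$n_planted_sites > 0L) {
      # spread sites across chromosomes proportionally to length
      lens <- config$chromosome_lengths
      n_per <- round(config$n_planted_sites * lens / sum(lens))
      n_per[1] <- config$n_planted_sites - sum(n_per[-1])
      spacing <- 80L  # > tag length, keeps planted tags non-overlapping
      for (ci in seq_along(lens)) {
        usable <- lens[ci] - 2L * spacing
        if (n_per[ci] > 0L && usable < n_per[ci] * spacing) {
          abort(paste0("Cannot place ", n_per[ci], " sites in ",
                       names(lens)[ci], " (", lens[ci], " bp)."))
        }
        if (n_per[ci] == 0L) next
        slots <- seq(spacing, lens[ci] - spacing, length.out = n_per[ci])
        starts <- as.integer(round(slots))
        orient <- sample(c("plus_form", "minus_form"), n_per[ci], TRUE)
        pat <- ifelse(orient == "plus_form", e$plus_pattern,
                      e$minus_pattern)
        # resolve degenerate positions at random
        site_seq <- vapply(pat, function(p) {
          ch <- strsplit(p, "")[[1]]
          ch[ch == "N"] <- sample(DNA_BASES, sum(ch == "N"), TRUE)
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
        for (k in seq_len(n_per[ci])) {
          substr(genome[ci], starts[k] + 1L,
                 starts[k] + nchar(site_seq[k])) <- site_seq[k]
        }
        planted <- dplyr::bind_rows(planted, tibble(
          sequence_id = names(lens)[ci], start = starts,
          orientation = orient
        ))
      }
    }
    list(genome = genome, planted_sites = planted)
  })
}

# canonical-tag offset -> genome position and strand-aware base mapping
canonical_offset_to_genome <- function(tags, offsets) {
  ifelse(tags$orientation == "plus_form",
         tags$tag_start + offsets,
         tags$tag_end - 1L - offsets)
}

# tag offsets that may carry SNPs: outside the 6 fixed recognition
# positions of the canonical form (0-based 12-13 and 19-22)
SNP_SAFE_OFFSETS <- setdiff(0:32, c(12L, 13L, 19L, 20L, 21L, 22L))

#' Derive two inbred parent genomes
#'
#' Parent A is the reference. Parent B carries substitutions only inside
#' tag footprints: each tag is mutated with probability `snp_rate`,
#' receiving 1 SNP (or 2 with probability `two_snp_prob`) at degenerate
#' positions — never the 6 fixed recognition bases, so digestibility and
#' the site lists are identical in both parents.
#'
#' @param genome Named character vector (from [generate_genome()]).
#' @param ref_tags Tibble from [extract_tags()] on that genome.
#' @param config A [sim_config()].
#' @return List with `parent_a`, `parent_b` (genomes), and `snps` (tibble
#'   `site_id`, `tag_offset`, `sequence_id`, `position`, `ref`, `alt` on
#'   the canonical tag strand).
#' @export
generate_parents <- function(genome, ref_tags, config) {
  with_seed(config$seed + 1L, {
    parent_b <- genome
    n_tags <- nrow(ref_tags)
    mutate_tag <- stats::runif(n_tags) < config$snp_rate
    recs <- list()
    for (i in which(mutate_tag)) {
      k <- 1L + (stats::runif(1) < config$two_snp_prob)
      offs <- sort(sample(SNP_SAFE_OFFSETS, k))
      for (o in offs) {
        gpos <- canonical_offset_to_genome(ref_tags[i, ], o)  # 0-based
        sid <- ref_tags$sequence_id[i]
        ref_plus <- substr(genome[sid], gpos + 1L, gpos + 1L)
        alt_plus <- sample(setdiff(DNA_BASES, ref_plus), 1L)
        substr(parent_b[sid], gpos + 1L, gpos + 1L) <- alt_plus
        on_canonical <- ref_tags$orientation[i] == "plus_form"
        recs[[length(recs) + 1L]] <- tibble(
          site_id = ref_tags$site_id[i], tag_offset = o,
          sequence_id = sid, position = gpos,
          ref = if (on_canonical) ref_plus else revcomp(ref_plus),
          alt = if (on_canonical) alt_plus else revcomp(alt_plus)
        )
      }
    }
    snps <- if (length(recs)) dplyr::bind_rows(recs) else {
      tibble(site_id = character(), tag_offset = integer(),
             sequence_id = character(), position = integer(),
             ref = character(), alt = character())
    }
    list(parent_a = genome, parent_b = parent_b, snps = snps)
  })
}

#' Simulate F2 genotypes
#'
#' Mode `"none"`: every site segregates independently with probabilities
#' (1/4, 1/2, 1/4) for (aa, ab, bb). Mode `"poisson"`: per-chromosome
#' gamete formation with Poisson-distributed crossovers at the stated map
#' length (centimorgans), preserving linkage between nearby sites.
#'
#' @param sites Character vector of site ids, or the ref-tag tibble (its
#'   `site_id`, `sequence_id`, `site_start` columns are used for linkage).
#' @param config A [sim_config()].
#' @param recombination `"none"` (default) or `"poisson"`.
#' @param map_length_cM Per-chromosome map length for `"poisson"` mode.
#' @return Tibble `sample_id` x `site_id` with `genotype` in
#'   \{aa, ab, bb\}.
#' @export
generate_f2 <- function(sites, config, recombination = c("none", "poisson"),
                        map_length_cM = 100) {
  recombination <- match.arg(recombination)
  if (is.data.frame(sites)) {
    tbl <- sites
  } else {
    tbl <- tibble(site_id = sites, sequence_id = "chr1",
                  site_start = seq_along(sites))
  }
  ids <- paste0("F2_", sprintf("%03d", seq_len(config$n_progeny)))
  with_seed(config$seed + 2L, {
    if (recombination == "none") {
      g <- sample(c("aa", "ab", "bb"), config$n_progeny * nrow(tbl),
                  replace = TRUE, prob = c(0.25, 0.5, 0.25))
      out <- tidyr::expand_grid(sample_id = ids, site_id = tbl$site_id)
      out$genotype <- g
    } else {
      gamete <- function() {
        # one meiosis across all chromosomes; returns 0/1 (A/B) per site
        per_chr <- lapply(unname(split(tbl, tbl$sequence_id)), function(d) {
          pos <- d$site_start / max(d$site_start + 1L)
          n_xo <- stats::rpois(1, map_length_cM / 100)
          breaks <- sort(stats::runif(n_xo))
          phase <- sample(0:1, 1L)
          seg <- findInterval(pos, breaks)
          stats::setNames((phase + seg) %% 2L, d$site_id)
        })
        do.call(c, per_chr)
      }
      rows <- lapply(ids, function(id) {
        g1 <- gamete()
        g2 <- gamete()
        code <- g1 + g2[names(g1)]
        tibble(sample_id = id, site_id = names(g1),
               genotype = c("aa", "ab", "bb")[code + 1L])
      })
      out <- dplyr::bind_rows(rows)
    }
    out
  })
}

apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) {
    return(list(seqs = seqs, n_errors = integer(length(seqs))))
  }
  L <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), L, error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample(L[i], n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  list(seqs = seqs, n_errors = n_err)
}

# sample site-free genomic 33-mers (between-site fragments)
sample_contaminant_fragments <- function(genome, n, rng_burn = 0L) {
  if (n == 0L) return(character())
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 50L) {
    guard <- guard + 1L
    need <- (n - length(out)) * 2L
    ci <- sample(length(genome), need, replace = TRUE)
    maxs <- nchar(genome)[ci] - 33L
    st <- floor(stats::runif(need) * maxs) + 1L
    frag <- substr(genome[ci], st, st + 32L)
    ok <- !is_ac_form(frag) & !is_ggag_form(frag) &
      !grepl("N", frag, fixed = TRUE)
    out <- c(out, frag[ok])
  }
  out[seq_len(n)]
}

#' Simulate sequencer reads for a full F2 experiment
#'
#' For every sample (two parents and all progeny) and every reference
#' site, the read count is Poisson(`lambda`). Each read draws a haplotype
#' according to the sample's genotype, a strand with probability
#' `strand_flip_prob`, is built with [construct_read()] (barcode + tag +
#' adapter read-through, truncated to the read length), and then receives
#' i.i.d. substitution errors. A `contaminant_fraction` of reads is
#' replaced by site-free genomic 33-mers with barcodes attached. Samples
#' are packed into libraries of up to 12 sharing the barcode set.
#'
#' @param truth List as produced by [simulate_experiment()] internals:
#'   needs `ref_tags`, `parent_alleles` (tibble `site_id`, `allele_a`,
#'   `allele_b`), `genotypes` (from [generate_f2()]), `genome`.
#' @param design A [library_design()] whose `barcode_set` is set.
#' @param config A [sim_config()].
#' @return List with `reads` (tibble `read_id`, `library`, `sample_id`,
#'   `sequence`) and `read_truth` (adds `site_id`, `strand`, `n_errors`,
#'   `contaminant`), plus the `sample_sheet`.
#' @export
simulate_reads <- function(truth, design, config) {
  bcs <- design$barcode_set
  if (is.null(bcs)) abort("`design$barcode_set` is required.")
  samples <- c("P_A", "P_B",
               paste0("F2_", sprintf("%03d", seq_len(config$n_progeny))))
  n_lib <- ceiling(length(samples) / nrow(bcs))
  sheet <- tibble(
    sample_id = samples,
    library = paste0("L", sprintf("%02d", rep(seq_len(n_lib),
                                              each = nrow(bcs))[
                                                seq_along(samples)])),
    barcode = rep(bcs$barcode, length.out = length(samples))
  )
  pa <- truth$parent_alleles
  geno <- dplyr::bind_rows(
    tidyr::expand_grid(sample_id = "P_A", site_id = pa$site_id) %>%
      dplyr::mutate(genotype = "aa"),
    tidyr::expand_grid(sample_id = "P_B", site_id = pa$site_id) %>%
      dplyr::mutate(genotype = "bb"),
    truth$genotypes
  )
  with_seed(config$seed + 3L, {
    counts <- geno %>%
      dplyr::mutate(n_reads = stats::rpois(dplyr::n(), config$lambda)) %>%
      dplyr::filter(.data$n_reads > 0L)
    reads <- counts[rep(seq_len(nrow(counts)), counts$n_reads),
                    c("sample_id", "site_id", "genotype")]
    n <- nrow(reads)
    allele_a <- stats::setNames(pa$allele_a, pa$site_id)
    allele_b <- stats::setNames(pa$allele_b, pa$site_id)
    use_b <- dplyr::case_when(
      reads$genotype == "aa" ~ FALSE,
      reads$genotype == "bb" ~ TRUE,
      TRUE ~ stats::runif(n) < 0.5
    )
    tag <- ifelse(use_b, allele_b[reads$site_id],
                  allele_a[reads$site_id])
    minus <- stats::runif(n) < config$strand_flip_prob
    tag[minus] <- revcomp(tag[minus])
    contaminant <- stats::runif(n) < config$contaminant_fraction
    if (any(contaminant)) {
      frags <- sample_contaminant_fragments(truth$genome, sum(contaminant))
      tag[contaminant] <- frags
      reads$site_id[contaminant] <- NA_character_
    }
    bc_of <- stats::setNames(sheet$barcode, sheet$sample_id)
    lib_of <- stats::setNames(sheet$library, sheet$sample_id)
    seqs <- construct_read(design, bc_of[reads$sample_id], tag,
                           config$read_length)
    err <- apply_substitution_errors(unname(seqs), config$error_rate)
    read_truth <- tibble(
      read_id = paste0("r", seq_len(n)),
      library = unname(lib_of[reads$sample_id]),
      sample_id = reads$sample_id,
      site_id = reads$site_id,
      strand = ifelse(minus, "minus", "plus"),
      n_errors = err$n_errors,
      contaminant = contaminant,
      sequence = err$seqs
    )
    list(
      reads = read_truth[, c("read_id", "library", "sample_id",
                             "sequence")],
      read_truth = read_truth,
      sample_sheet = sheet
    )
  })
}

#' Run the full synthetic-experiment generator
#'
#' Chains [generate_genome()], reference-tag extraction,
#' [generate_parents()], [generate_f2()] and [simulate_reads()] under one
#' configuration, returning every intermediate plus the truth tables.
#'
#' @param config A [sim_config()].
#' @param design Optional [library_design()]; by default one is built with
#'   12 designed barcodes (seeded from the config).
#' @param recombination Passed to [generate_f2()].
#' @return A `rad2b_sim` list: `config`, `genome`, `planted_sites`,
#'   `ref_tags`, `parents` (with `snps`), `parent_alleles`, `genotypes`
#'   (truth), `reads`, `read_truth`, `sample_sheet`, `design`.
#' @export
simulate_experiment <- function(config = sim_config(), design = NULL,
                                recombination = "none") {
  if (is.null(design)) {
    design <- library_design(
      barcode_set = design_barcodes(12L, seed = config$seed)
    )
  }
  gen <- generate_genome(config)
  sites <- scan_sites(gen$genome, "BsaXI")
  ref_tags <- extract_tags(gen$genome, sites, "BsaXI")
  parents <- generate_parents(gen$genome, ref_tags, config)
  tags_b <- extract_tags(parents$parent_b, sites, "BsaXI")
  parent_alleles <- tibble(
    site_id = ref_tags$site_id,
    allele_a = ref_tags$canonical_sequence,
    allele_b = tags_b$canonical_sequence
  )
  genotypes <- generate_f2(
    ref_tags %>% dplyr::select("site_id", "sequence_id", "site_start"),
    config, recombination = recombination
  )
  sim_reads <- simulate_reads(
    list(ref_tags = ref_tags, parent_alleles = parent_alleles,
         genotypes = genotypes, genome = gen$genome),
    design, config
  )
  structure(
    c(list(config = config, genome = gen$genome,
           planted_sites = gen$planted_sites, ref_tags = ref_tags,
           parents = parents, parent_alleles = parent_alleles,
           genotypes = genotypes, design = design),
      sim_reads),
    class = "rad2b_sim"
  )
}

#' Write simulator outputs to disk
#'
#' Genome and parent FASTAs, per-library FASTQ, sample sheet and truth
#' tables (TSV).
#'
#' @param sim A `rad2b_sim` from [simulate_experiment()].
#' @param outdir Output directory (created).
#' @param gzip Compress FASTQ (default TRUE).
#' @return `outdir`, invisibly.
#' @export
write_sim <- function(sim, outdir, gzip = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wfa <- function(x, f) {
    ss <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(ss, file.path(outdir, f))
  }
  wfa(sim$genome, "genome.fasta")
  wfa(sim$parents$parent_b, "parent_b.fasta")
  for (lib in unique(sim$reads$library)) {
    d <- sim$reads[sim$reads$library == lib, ]
    write_fastq(d, file.path(outdir, paste0(lib, ".fastq",
                                            if (gzip) ".gz" else "")))
  }
  readr::write_tsv(sim$sample_sheet, file.path(outdir, "sample_sheet.tsv"))
  readr::write_tsv(sim$read_truth %>% dplyr::select(-"sequence"),
                   file.path(outdir, "read_truth.tsv"))
  readr::write_tsv(sim$genotypes, file.path(outdir, "genotype_truth.tsv"))
  readr::write_tsv(sim$parents$snps, file.path(outdir, "snp_truth.tsv"))
  invisible(outdir)
}
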
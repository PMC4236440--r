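---
title: "Methods and design notes for rad2b"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rad2b}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad2b)
```

## The measurement model

2b-RAD reduces a genome to the set of 33-bp fragments that a type IIB
enzyme excises around its recognition sites. For BsaXI the fragment
geometry is fixed: 12 nt of upstream flank, the 11-nt bipartite pattern
`AC(N5)CTCC`, and 10 nt of downstream flank. Only 6 of the 33 positions
are constrained (`AC` at 0-based offsets 12–13, `CTCC` at 19–22); the
rest are free sequence, which is what makes the tag informative as a
marker. Because the pattern is not self-complementary, the plus strand of
a genome shows a site either in the `AC...CTCC` orientation or as the
reverse complement `GGAG(N5)GT`; a sequencer likewise reads a given
fragment from either strand with roughly equal probability. Every
component of this package therefore works on *canonical* tags: any 33-mer
in the GGAG form is reverse-complemented into the AC form, so both
sequencing strands of one locus collapse to a single key.

Coordinates are 0-based and half-open throughout, matching BED, and
interval output is written as BED.

### Site scanning

`scan_sites()` matches the IUPAC pattern (and, for non-self-complementary
enzymes, its reverse complement) on the supplied strand only, so a
self-complementary pattern such as EcoRI's `GAATTC` is counted once per
occurrence. Overlapping occurrences are all reported — the simplest
deterministic rule — and `N` bases in the genome never match any pattern
position, which avoids phantom sites in gapped assemblies. Matching is
delegated to Biostrings with a post-filter enforcing the N rule; the test
suite pins the result to an independent character-by-character oracle on
seeded 100-kb sequences.

AlfI participates in site counting and overhang arithmetic only: its
published fragment geometry is not specified to the base, so tag
extraction is deliberately unsupported for it.

### Window occupancy

`tile_windows()`/`classify_windows()` implement the scaffold-anchoring
simulation: the genome is tiled into fixed windows (default 4000 bp,
about one EcoRI site's worth of sequence in plant and animal genomes) and
each window is classed `zero`/`one`/`many` by its site count. A trailing
remainder shorter than the window is discarded (and counted) rather than
kept as a short window, so classes stay comparable across windows; sites
are binned by their pattern start coordinate. Tiling is per sequence, not
over a concatenated genome.

## Library design

`library_design()` stores the construct verbatim: the 33-nt adapter1
common arm, the 34-nt adapter2 top strand, the 58-nt multiplexing PCR
primer 1.0 (which ends with the adapter1 arm) and the 64-nt indexed
primer whose final 34 nt are the reverse complement of adapter2. The
amplicon is then pure arithmetic, `58 + barcode + 33 + 64`, i.e. 160–164
bp over the 5–9-nt barcode range. Index sequences are treated as opaque
labels — index demultiplexing is the sequencer pipeline's job.

Barcode criteria, as implemented by `validate_barcode_set()`:

1. lengths 5–9 nt (variable lengths stagger the recognition pattern
   across sequencing cycles, improving base balance);
2. every pair at distance >= 2 — implemented as *Levenshtein* distance
   because the barcodes have unequal lengths, plus prefix-freeness, which
   inline demultiplexing needs for unambiguous boundaries;
3. no barcode may contain or recreate a BsaXI site after ligation. The
   check runs over the fully resolved ligated context (adapter arm +
   barcode + each of the 64 overhang completions + unknown insert) and
   treats unknown insert bases as wildcards, i.e. a barcode fails if
   *any* insert could complete a site through it. This is conservative:
   it forbids, for example, barcodes ending in `A` (an overhang starting
   `C` would complete `AC` two bases before an unconstrained insert).

`design_barcodes()` is a greedy seeded search over random candidates;
among admissible candidates it keeps the one minimising per-position
base-composition imbalance of the accepted set. The objective is the
published one; the algorithm is this package's choice, since none was
specified. Infeasible requests (e.g. 2000 barcodes of length 5 at
pairwise distance 2) terminate with an explicit infeasibility error after
a bounded attempt budget.

Selective adapters: `overhang_fraction()` enumerates all ordered overhang
pairs for both fragment ends and counts the pairs compatible with a spec
such as `NNF` (one fixed base per end). With k fixed bases per end the
fraction is 4^(-2k) — 1/16 for BsaXI `NNF` and 1/16 for AlfI `NF` — the
lever for thinning marker density in QTL-scale designs.

## The two-step read filter

Step 1 (`match_barcode()`): exact prefix match wins (the validated set is
prefix-free, so at most one exact match exists); otherwise the unique
barcode at Hamming distance 1 over its own length wins. Zero or several
candidates at the best tier leave the read unassigned — discarding
ambiguous reads is the conservative resolution of a rule that only says
"one mismatch allowed". A read is never tested against a barcode longer
than the read minus 33 nt. The mismatch may sit anywhere in the barcode,
including the first base.

Step 2 (`match_tag()`): the 33 bases after the barcode must contain no N
and match either positional form at its 6 fixed bases; the degenerate
positions may be any of ACGT. Anything beyond 33 nt (adapter
read-through) is discarded, and accepted tags are canonicalized. Base
qualities play no role in the filter; emitted FASTQ carries constant
quality strings.

The per-read outcome is always exactly one of
`high_quality`, `rejected_{has_N, no_site, too_short}` or
`unassigned_{no_match, ambiguous, too_short}`, which the statistics
object (`filter_stats`) checks by construction: totals are conserved at
both stages, and the evenness ratio (max/min per-sample high-quality
count) summarises pooling balance.

`classify_rejected()` quantifies the main contaminant class — fragments
lying *between* two recognition sites that survive size selection — by
exact lookup of the first 33 bases in the reference (both strands). Exact
matching is a documented simplification of mismatch-tolerant alignment;
with error-free simulated reads it recovers the contaminant fraction
exactly.

## Coverage accounting

`assign_reads()` looks canonical tags up in the reference-tag index;
tags occurring at more than one site are excluded (mirroring
unique-mapping alignment flags). With one mismatch allowed, the
single-substitution neighbourhood of the *index* is enumerated once and
reads are resolved by hash lookup — the read-side neighbourhood would be
two orders of magnitude larger. Mean depth divides assigned reads by the
*total expected* sites, not the covered ones; both conventions exist and
the choice matters when coverage is incomplete. Under uniform Poisson
depth the coverage rate approaches `1 - exp(-depth)`, the closed form the
saturation tests check at depths 1–20.

## Genotyping

The caller is deliberately simple and reference-anchored: loci are the
reference tag sites, and no de-novo tag clustering is performed (the
simulator always provides a reference; this is the principal
simplification relative to catalog-based callers, and it removes the
multi-location marker class entirely — multi-mapping tags are excluded
upstream).

Observation collection (`collect_observations()`) assigns each canonical
sample tag to a unique reference site, tolerating up to 2 mismatches —
the number of SNPs an alternate parental allele may legitimately carry —
with a unique-best-site rule. One mismatch would silently delete every
two-SNP marker, so the tolerance follows the allele model, not the
coverage module's stricter unique-mapping default. Within a locus,
alleles supported by a single read are dropped when another allele has
two or more reads: lone sequencing-error haplotypes otherwise defeat the
het-frequency thresholds below (a single error read at depth 20 has
frequency 0.05, well above `max_het`). The cost is that a genuine second
allele sampled exactly once is also dropped; at depth 20 that is a
~1e-4 event per heterozygous cell, and it is the dominant residual error
mode in the recovery benchmarks.

Calls (`call_sample_genotype()`): depth < 2 is missing; otherwise with f
the second-allele frequency, f < 0.010 calls a homozygote, f > 0.011 a
heterozygote, and the in-between zone is deliberately uncallable —
a stand-in for an automated-correction pass, pushing borderline cells to
missing rather than to a wrong call. Ties between the top alleles are
broken lexicographically and flagged.

Markers are aa x bb sites: both parents homozygous, alleles different,
differing at <= 2 positions. Progeny code as aa/ab/bb by matching the
parental alleles; missing calls, foreign alleles and absent samples are
all `missing`. `segregation_filter()` drops markers with missing rate
>= 0.20 (strict inequality preserved: "< 20% missing" survives), then
tests survivors against (n/4, n/2, n/4) over non-missing n with a 2-df
chi-square, no continuity correction, dropping at p < 0.01. The
asymptotic test is used because that is the field's standard; full
enumeration at n = 12 shows it tracks the exact multinomial tail to
within 0.02 wherever p < 0.1 and always agrees with the exact test on
the 0.01 decision, though in the centre of the distribution the discrete
exact tail can differ by more.

## The simulator

`simulate_experiment()` emulates the study design the pipeline assumes:
an i.i.d. uniform ACGT genome with a requested number of planted BsaXI
sites (plus natural background sites, ~2/4^6 per bp); parent A equal to
the reference and parent B carrying 1–2 substitutions per mutated tag
footprint, never at the 6 fixed recognition bases (so both parents digest
identically; an optional site-destroying mode is out of scope); F2
genotypes drawn 1:2:1 independently per site, or with Poisson crossovers
per chromosome when linkage matters; per sample and site Poisson(lambda)
reads, each drawing a haplotype by genotype, a strand by a fair coin,
i.i.d. substitution errors, and a barcode with adapter read-through; and
a contaminant fraction replaced by site-free genomic 33-mers. Errors are
substitution-only: in the SE50 regime an indel breaks the fixed-offset
filter exactly as in the real protocol, so indels act as read loss, not
alignment.

Defaults are the study conditions the package targets: 277 progeny,
libraries of 12 samples over barcodes of lengths 5–9, SE50 reads, depth
lambda = 10 (the pooled average depth of the motivating design, 10.67,
rounded), per-base error 0.001 (Q30-scale), strand-flip 0.5, contaminant
fraction 0.1 (the order of the between-site read load seen in practice),
snp_rate 0.05 with a 7% chance of a second SNP (close-relative parents;
about 1 marker per 20 tags, two-SNP markers a small minority). These were
fixed once when the generator was written.

What the simulator does *not* model — PCR duplicates, GC bias, quality
profiles, restriction-site polymorphism between parents, indels — bounds
what passing tests show about real data: the pipeline's logic and
statistics are validated, not its robustness to library-prep artefacts.

## Problem sizes and reproducibility

All generators and subsampling run under explicit integer seeds and are
bit-reproducible. The test suite works at desk scale by design: oracle
equivalence on twenty seeded 100-kb sequences, density checks on 1–2-Mb
sequences, coverage saturation on ~470 sites, and genotype recovery on
~520 markers x 200 progeny at depth 20 (~2.1 million reads), which
completes in about a minute. The simulator's read stage is the only
memory-conscious component; locus assignment enumerates the reference
neighbourhood rather than the read neighbourhood for that reason.

## Known limitations

* No de-novo locus discovery: samples without a reference genome (the
  classic de-novo RAD use case) are out of scope.
* Exact-match contaminant classification understates the genomic
  fraction for error-carrying reads.
* The barcode criterion-3 check is conservative; it may reject barcodes
  a specific insert library could tolerate.
* The mismatch-tolerant uniqueness mode is all-pairs and intended for
  desk-scale genomes, not full assemblies.
* Linkage-group formation, map ordering and genetic distances are
  downstream of this package; `write_genotypes(format = "joinmap")`
  exports the locus file those tools consume.
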
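# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's scanning/binning code paths: plain character
# comparison, quadratic loops, exact enumeration.

# IUPAC-N motif scan by sliding a window one position at a time and
# comparing characters; N in the sequence never matches. 0-based starts.
brute_scan <- function(seq, pattern) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(p)
  if (length(s) < L) return(integer())
  n_off <- length(s) - L + 1L
  ok <- rep(TRUE, n_off)
  for (j in seq_len(L)) {
    w <- s[seq_len(n_off) + j - 1L]
    ok <- ok & w != "N" & (p[j] == "N" | w == p[j])
  }
  which(ok) - 1L
}

# complement/reverse by lookup, independent of Biostrings
brute_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""),
    name
  )
}

# a 33-nt plus-form tag with given overhangs at both ends (seeded middle)
make_tag <- function(ov1 = "AAA", ov2 = "TTT", seed = 1) {
  set.seed(seed)
  mid <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE),
                           collapse = "")
  paste0(ov1, mid(9), "AC", mid(5), "CTCC", mid(7), ov2)
}

# plant a resolved plus-form BsaXI site into a background sequence at a
# 0-based position (overwrites 11 bases)
plant_site <- function(seq, pos, seed = 1) {
  set.seed(seed)
  n5 <- paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = "")
  site <- paste0("AC", n5, "CTCC")
  substr(seq, pos + 1, pos + 11) <- site
  seq
}

# exact 1:2:1 chi-square tail probability by multinomial enumeration
exact_chisq_121_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  stat_of <- function(a, h, b) {
    e <- c(n / 4, n / 2, n / 4)
    sum((c(a, h, b) - e)^2 / e)
  }
  obs <- stat_of(n_aa, n_ab, n_bb)
  p <- 0
  for (a in 0:n) {
    for (h in 0:(n - a)) {
      b <- n - a - h
      if (stat_of(a, h, b) >= obs - 1e-9) {
        p <- p + exp(lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) -
                       lgamma(b + 1) + a * log(0.25) + h * log(0.5) +
                       b * log(0.25))
      }
    }
  }
  p
}
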
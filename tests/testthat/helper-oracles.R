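# independent oracles used by the property-style tests; deliberately naive
# implementations that share no code with the package internals

# cluster filter: enumerate every window start covering each position
cluster_oracle <- function(positions, window, min_count) {
  u <- unique(positions)
  vapply(positions, function(p) {
    starts <- (p - window + 1):p
    any(vapply(starts, function(s) {
      sum(u >= s & u <= s + window - 1) >= min_count
    }, logical(1)))
  }, logical(1))
}

# BH step-up from first principles: q_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail P(X >= k) by exhaustive pmf summation
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  xs <- k:min(n, K)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# protein sequence of a CDS via Biostrings (independent of codon indexing)
translate_oracle <- function(cds_seq) {
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(cds_seq),
                          if.fuzzy.codon = "X")))
}

# substitute one base of a CDS string
mutate_cds <- function(cds_seq, pos, base) {
  substr(cds_seq, pos, pos) <- base
  cds_seq
}

# Mendelian consistency: can the child's genotype arise from the parents?
mendel_consistent <- function(child, father, mother) {
  alleles <- function(gt) switch(gt, "0/0" = list(0, 0), "0/1" = list(0, 1),
                                 "1/1" = list(1, 1), NULL)
  ch <- alleles(child); fa <- alleles(father); mo <- alleles(mother)
  if (is.null(ch) || is.null(fa) || is.null(mo)) return(TRUE)  # missing: skip
  c1 <- ch[[1]]; c2 <- ch[[2]]
  (c1 %in% unlist(fa) && c2 %in% unlist(mo)) ||
    (c2 %in% unlist(fa) && c1 %in% unlist(mo))
}
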
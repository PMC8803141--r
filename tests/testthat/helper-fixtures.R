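# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk except files the tests themselves write.

# small demo screen: 50 kb, 40 genes, paper-scale insertion density
demo_genome <- function(seed = 1L) {
  generate_genome(50000L, 40L, 0.5, seed = seed)
}

demo_effects <- function(genome, n_ess = 4L, n_loss = 3L, n_gain = 2L,
                         loss_log2 = -3, gain_log2 = 2) {
  ids <- genome$genes$gene_id
  effect_map(
    genome,
    essential = ids[seq_len(n_ess)],
    fitness_log2 = c(
      setNames(rep(loss_log2, n_loss), ids[n_ess + seq_len(n_loss)]),
      setNames(rep(gain_log2, n_gain), ids[n_ess + n_loss + seq_len(n_gain)])))
}

# a tiny genome with a planted exact 2-copy repeat for ambiguity tests;
# built from a fixed-seed random backbone long enough for unique seeds
repeat_genome <- function(seed = 42L, unit_len = 60L) {
  g <- generate_genome(4000L, 0L, 0.5, seed = seed)
  s <- g$sequence
  unit <- substr(s, 501, 500 + unit_len)
  s <- paste0(substr(s, 1, 2000), unit, substring(s, 2001 + unit_len))
  tn_genome("chr", s, data.frame())
}

# brute-force both-strand scan: every placement of `junction` in `genome`
# with at most max_mm substitutions; independent of the k-mer index path
scan_placements <- function(junction, genome, max_mm = 0) {
  L <- nchar(genome$sequence)
  len <- nchar(junction)
  jb <- charToRaw(junction)
  res <- list()
  fwd <- genome$sequence
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))
  for (start in seq_len(L - len + 1L)) {
    if (sum(charToRaw(substr(fwd, start, start + len - 1L)) != jb) <= max_mm)
      res[[length(res) + 1L]] <- c(pos = start, strand = "+")
    if (sum(charToRaw(substr(rc, start, start + len - 1L)) != jb) <= max_mm)
      res[[length(res) + 1L]] <- c(pos = L - start + 1L, strand = "-")
  }
  res
}

# exhaustive conditional-split oracle for the two-sided NB exact test:
# enumerates the joint probability of every split of total t between a
# pooled control (n1 replicates) and treated (n2 replicates) condition
exact_test_oracle <- function(A, t, n1, n2, phi) {
  k <- 0:t
  pr <- if (phi > 0) {
    dnbinom(k, size = n1 / phi, prob = 0.5) *
      dnbinom(t - k, size = n2 / phi, prob = 0.5)
  } else {
    dbinom(k, t, n1 / (n1 + n2))
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[A + 1] * (1 + 1e-9)])
}

# brute-force hypergeometric upper tail by enumerating all size-n draws
hyper_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k) # genes 1..K carry the term
}
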
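test_that("generated genomes satisfy the gene-model invariants", {
  g <- generate_genome(50000, 40, 0.5, seed = 1)
  expect_s3_class(g, "tn_genome")
  expect_equal(nrow(g$genes), 40)
  expect_true(all(g$genes$start >= 1 & g$genes$end <= 50000))
  expect_true(all(g$genes$start <= g$genes$end))
  expect_true(all(g$genes$length_bp == g$genes$end - g$genes$start + 1))
  o <- order(g$genes$start)
  expect_true(all(g$genes$start[o][-1] > g$genes$end[o][-40] + 0)) # gaps >= 1
  expect_false(anyDuplicated(g$genes$gene_id) > 0)
  expect_setequal(strsplit(g$sequence, "")[[1]], c("A", "C", "G", "T"))
})

test_that("gene-free genomes and impossible packings are handled", {
  g0 <- generate_genome(1000, 0, 0.5, seed = 1)
  expect_equal(nchar(g0$sequence), 1000)
  expect_equal(nrow(g0$genes), 0)
  expect_error(generate_genome(3000, 40, 0.5, seed = 1),
               class = "tn_sizing_error")
})

test_that("genome generation is deterministic: identical FASTA/GFF3 bytes", {
  d1 <- withr::local_tempdir()
  g <- generate_genome(20000, 10, 0.4, seed = 7)
  write_genome(g, file.path(d1, "a.fasta"), file.path(d1, "a.gff3"))
  g2 <- generate_genome(20000, 10, 0.4, seed = 7)
  write_genome(g2, file.path(d1, "b.fasta"), file.path(d1, "b.gff3"))
  expect_identical(readLines(file.path(d1, "a.fasta")),
                   readLines(file.path(d1, "b.fasta")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d1, "b.gff3")))
  # and a different seed changes the sequence
  expect_false(identical(g$sequence,
                         generate_genome(20000, 10, 0.4, seed = 8)$sequence))
})

test_that("genome FASTA+GFF3 round-trips through read_genome", {
  d <- withr::local_tempdir()
  g <- demo_genome()
  write_genome(g, file.path(d, "g.fasta"), file.path(d, "g.gff3"))
  g2 <- read_genome(file.path(d, "g.fasta"), file.path(d, "g.gff3"))
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$genes[c("gene_id", "start", "end", "strand")],
               g$genes[c("gene_id", "start", "end", "strand")])
})

test_that("library simulation respects density, essentiality and degeneracy", {
  g <- demo_genome()
  eff <- demo_effects(g)
  empty <- simulate_library(g, eff, insertions_per_bp = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_equal(total_reads(empty), 0)

  lib <- simulate_library(g, eff, seed = 1)
  expect_equal(total_reads(lib), sum(lib$count))
  expect_true(all(lib$count >= 1))
  expect_true(all(lib$position >= 1 & lib$position <= nchar(g$sequence)))
  # no insertion strictly inside any essential gene
  ess <- g$genes[eff$essential[match(g$genes$gene_id, eff$gene_id)], ]
  for (i in seq_len(nrow(ess))) {
    expect_false(any(lib$position >= ess$start[i] & lib$position <= ess$end[i]),
                 label = sprintf("essential gene %s carries insertions",
                                 ess$gene_id[i]))
  }
  # unique-site count near its Bernoulli expectation (gene-free genome)
  gf <- generate_genome(1e6, 0, 0.5, seed = 3)
  eff0 <- effect_map(gf)
  p <- 1 / 10.3
  lib2 <- simulate_library(gf, eff0, seed = 3)
  n_eff <- 1e6 - 200 # end margins carry no sites
  expect_lt(abs(nrow(lib2) - n_eff * p), 3 * sqrt(n_eff * p * (1 - p)))
  # missing gene in the effect map is a configuration error
  expect_error(simulate_library(g, eff[-1, ], seed = 1),
               class = "tn_config_error")
})

test_that("selection reweights read shares by 2^fitness and conserves totals", {
  g <- demo_genome()
  ids <- g$genes$gene_id
  eff0 <- effect_map(g)
  lib <- simulate_library(g, eff0, seed = 2)

  # neutral selection: per-site expectation equals control proportions
  reps <- sapply(1:40, function(i)
    apply_selection(lib, g, eff0, seed = 100 + i)$count[1] /
      total_reads(lib))
  expect_lt(abs(mean(reps) - lib$count[1] / total_reads(lib)),
            4 * sd(reps) / sqrt(40) + 1e-12)

  # closed-form depletion of one gene at log2 effect -3
  target <- ids[5]
  eff1 <- effect_map(g, fitness_log2 = setNames(-3, target))
  tg <- g$genes[g$genes$gene_id == target, ]
  in_gene <- lib$position >= tg$start & lib$position <= tg$end
  share0 <- sum(lib$count[in_gene]) / total_reads(lib)
  expected <- share0 * 2^-3 / (1 - share0 + share0 * 2^-3)
  shares <- sapply(1:40, function(i) {
    t1 <- apply_selection(lib, g, eff1, seed = 200 + i)
    sum(t1$count[t1$position >= tg$start & t1$position <= tg$end]) /
      total_reads(t1)
  })
  expect_lt(abs(mean(shares) - expected), 4 * sd(shares) / sqrt(40))

  # hard kill: -Inf effect leaves the gene with zero treated reads
  effk <- effect_map(g, fitness_log2 = setNames(-Inf, target))
  tk <- apply_selection(lib, g, effk, seed = 5)
  expect_equal(sum(tk$count[tk$position >= tg$start & tk$position <= tg$end]), 0)

  # conservation and site-subset invariants
  t2 <- apply_selection(lib, g, eff1, seed = 6)
  expect_identical(total_reads(t2), total_reads(lib))
  expect_true(all(paste(t2$position, t2$strand) %in%
                    paste(lib$position, lib$strand)))
  expect_error(apply_selection(lib[0, ], g, eff1, seed = 1), "empty")
})

test_that("emitted reads are barcode + tag + junction with exact bookkeeping", {
  g <- demo_genome()
  prof <- tn_profile(c(100L, 2000L), c("+", "-"), c(3L, 2L),
                     sample_id = "s1", replicon_id = "chr")
  reads <- emit_reads(prof, g, tag_seq = "TGTTAGGCCT", barcode = "ACGTAC",
                      read_length = 50, error_rate = 0, seed = 1)
  expect_equal(nrow(reads), 5) # one record per counted read
  expect_true(all(nchar(reads$sequence) == nchar(reads$qualities)))
  plus <- reads[startsWith(reads$read_id, "s1:100:+"), ]
  expect_equal(nrow(plus), 3)
  expect_equal(unique(substring(plus$sequence, 17)),
               substr(g$sequence, 100, 100 + 34 - 1)) # 50 - 6 - 10 junction bp
  minus <- reads[startsWith(reads$read_id, "s1:2000:-"), ]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substr(g$sequence, 2000 - 33, 2000))))
  expect_equal(unique(substring(minus$sequence, 17)), rc)

  # a site near the replicon end yields a truncated, never wrapped, read
  L <- nchar(g$sequence)
  edge <- tn_profile(L - 9L, "+", 1L, sample_id = "s1", replicon_id = "chr")
  r2 <- emit_reads(edge, g, "TGTTAGGCCT", "ACGTAC", read_length = 50,
                   seed = 1)
  expect_equal(nchar(r2$sequence), 6 + 10 + 10)
  expect_equal(substring(r2$sequence, 17), substr(g$sequence, L - 9, L))
})

test_that("substitution errors land at the configured binomial rate", {
  g <- demo_genome()
  eff <- effect_map(g)
  lib <- simulate_library(g, eff, seed = 4)
  lib <- lib[seq_len(200), ] # enough junction bases for a stable rate
  lib <- tn_profile(lib$position, lib$strand, rep(1L, nrow(lib)),
                    sample_id = "s", replicon_id = "chr")
  clean <- emit_reads(lib, g, "TGTTAGGCCT", "ACGTAC", read_length = 66,
                      error_rate = 0, seed = 7)
  noisy <- emit_reads(lib, g, "TGTTAGGCCT", "ACGTAC", read_length = 66,
                      error_rate = 0.01, seed = 7)
  mism <- sum(mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                     clean$sequence, noisy$sequence))
  nbases <- sum(nchar(clean$sequence) - 16) # errors only in the junction
  expect_lt(abs(mism - nbases * 0.01), 3 * sqrt(nbases * 0.01 * 0.99))
})

test_that("FASTQ and effect-table writers round-trip", {
  d <- withr::local_tempdir()
  g <- demo_genome()
  prof <- tn_profile(c(500L, 600L), c("+", "-"), c(2L, 1L),
                     sample_id = "s1", replicon_id = "chr")
  reads <- emit_reads(prof, g, "TGTTAGGCCT", "ACGTAC", seed = 1)
  fq <- file.path(d, "r.fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, reads)
  expect_equal(length(readLines(fq)), 4 * nrow(reads))

  eff <- demo_effects(g)
  write_effects(eff, file.path(d, "eff.tsv"))
  expect_equal(read_effects(file.path(d, "eff.tsv")), eff)
})
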
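# Simulation of annotated genomes, saturated transposon libraries under known
# selection, and barcoded junction reads. The generator is the ground-truth
# source for every downstream stage.

#' Generate a random annotated genome
#'
#' Draws a random linear A/C/G/T sequence at the requested GC content and
#' places `n_genes` non-overlapping genes (gamma-distributed lengths, mean
#' `mean_gene_length`, minimum 100 bp) separated by intergenic gaps of at
#' least 1 bp, with random slack distributed among the gaps. Coordinates are
#' 1-based inclusive; the replicon is treated as linear throughout.
#'
#' @param length_bp genome length in bp; must be at least `100 * n_genes`.
#' @param n_genes number of genes (0 allowed).
#' @param gc_fraction GC content in (0, 1).
#' @param mean_gene_length mean gene length in bp (default 900, a typical
#'   bacterial CDS).
#' @param seed integer seed; output is deterministic given all arguments.
#' @param replicon_id replicon name.
#' @return A [tn_genome()].
#' @export
#' @examples
#' g <- generate_genome(50000, 40, 0.5, seed = 1)
#' nrow(g$genes)
generate_genome <- function(length_bp, n_genes, gc_fraction = 0.5,
                            mean_gene_length = 900, seed,
                            replicon_id = "chr") {
  .assert(gc_fraction > 0 && gc_fraction < 1, "gc_fraction must be in (0,1)")
  .assert(length_bp >= n_genes * 100,
          "genome too short for requested gene count", "tn_sizing_error")
  set.seed(derive_seed(seed, "genome"))
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  seq <- paste(sample(c("A", "C", "G", "T"), length_bp, TRUE, prob = p),
               collapse = "")
  if (n_genes == 0) return(tn_genome(replicon_id, seq, data.frame()))

  # gamma lengths (CV 0.25) floored at 100 bp, shrunk uniformly if they
  # cannot be packed with n_genes + 1 gaps of >= 1 bp
  len <- pmax(100L, as.integer(round(
    rgamma(n_genes, shape = 16, rate = 16 / mean_gene_length))))
  slack <- length_bp - sum(len) - (n_genes + 1L)
  if (slack < 0) {
    len <- pmax(100L, as.integer(floor(len * (length_bp - (n_genes + 1L)) / sum(len))))
    slack <- length_bp - sum(len) - (n_genes + 1L)
    .assert(slack >= 0, "genes cannot be packed into the genome",
            "tn_sizing_error")
  }
  extra <- if (slack > 0) rmultinom(1, slack, rep(1, n_genes + 1L))[, 1] else
    rep(0L, n_genes + 1L)
  gaps <- 1L + extra # gap i precedes gene i; gaps[n+1] trails the last gene
  starts <- cumsum(gaps[seq_len(n_genes)] + c(0L, len[-n_genes])) + 1L
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    start = as.integer(starts),
    end = as.integer(starts + len - 1L),
    strand = sample(c("+", "-"), n_genes, TRUE),
    stringsAsFactors = FALSE)
  tn_genome(replicon_id, seq, genes)
}

#' Build a per-gene effect map
#'
#' The effect map is the simulation ground truth: which genes are essential
#' (and therefore carry no insertions at all) and the per-gene fitness effect
#' of disruption, expressed as a log2 change in read share per unit of
#' selection. `-Inf` marks a hard kill (zero surviving reads).
#'
#' @param genome a [tn_genome()].
#' @param essential character vector of essential gene ids.
#' @param fitness_log2 named numeric vector of log2 effects for non-neutral
#'   genes; unnamed genes default to 0.
#' @return data.frame with columns `gene_id`, `essential`, `fitness_log2`
#'   covering every gene exactly once.
#' @export
effect_map <- function(genome, essential = character(),
                       fitness_log2 = numeric()) {
  ids <- genome$genes$gene_id
  .assert(all(essential %in% ids), "essential gene not in genome",
          "tn_config_error")
  .assert(all(names(fitness_log2) %in% ids),
          "fitness_log2 names not in genome", "tn_config_error")
  eff <- setNames(rep(0, length(ids)), ids)
  eff[names(fitness_log2)] <- fitness_log2
  ess <- ids %in% essential
  eff[ess] <- 0 # essential genes never receive a selection effect
  data.frame(gene_id = ids, essential = ess, fitness_log2 = unname(eff),
             stringsAsFactors = FALSE)
}

.check_effects <- function(genome, effects) {
  .assert(is.data.frame(effects) &&
            all(c("gene_id", "essential", "fitness_log2") %in% names(effects)),
          "effects must have gene_id/essential/fitness_log2", "tn_config_error")
  .assert(setequal(effects$gene_id, genome$genes$gene_id) &&
            !anyDuplicated(effects$gene_id),
          "effect map must cover every gene exactly once", "tn_config_error")
  effects[match(genome$genes$gene_id, effects$gene_id), , drop = FALSE]
}

# zero-truncated negative binomial (dispersion = 0 falls back to Poisson);
# variance mu + dispersion * mu^2 before truncation
.rztnb <- function(n, mu, dispersion) {
  if (n == 0L) return(integer())
  if (dispersion > 0) {
    size <- 1 / dispersion
    u <- runif(n, pnbinom(0, size = size, mu = mu), 1)
    pmax(1L, as.integer(qnbinom(u, size = size, mu = mu)))
  } else {
    u <- runif(n, ppois(0, mu), 1)
    pmax(1L, as.integer(qpois(u, mu)))
  }
}

#' Simulate a saturated transposon insertion library
#'
#' Each genomic base outside essential genes becomes a unique insertion site
#' with probability `insertions_per_bp` (the default, one insertion per
#' 10.3 bp, is the density of a saturated mini-Tn5 library in *E. coli*);
#' bases strictly inside essential genes never do.
#' Each site gets a uniform random strand and a zero-truncated
#' negative-binomial read count with mean `mean_reads_per_site` and variance
#' `mu + nb_dispersion * mu^2`, emulating PCR-amplified junction libraries.
#'
#' @param genome a [tn_genome()].
#' @param effects effect map from [effect_map()]; must cover every gene.
#' @param insertions_per_bp per-base insertion probability (> 0 unless 0 for
#'   an empty library).
#' @param mean_reads_per_site mean junction reads per unique site.
#' @param nb_dispersion negative-binomial dispersion alpha (>= 0; 0 gives
#'   Poisson counts).
#' @param seed integer seed.
#' @param sample_id sample name for the profile.
#' @param end_margin bases excluded at each replicon end (default 100, about
#'   one read length). The real chromosome is circular, so junctions never
#'   run off an end; on the linear simulated replicon this margin plays the
#'   same role without modeling wraparound.
#' @return A [tn_profile()].
#' @export
simulate_library <- function(genome, effects,
                             insertions_per_bp = 1 / 10.3,
                             mean_reads_per_site = 20,
                             nb_dispersion = 0.3, seed,
                             sample_id = "library", end_margin = 100L) {
  .assert(insertions_per_bp >= 0, "insertions_per_bp must be >= 0")
  .assert(mean_reads_per_site > 0, "mean_reads_per_site must be > 0")
  .assert(nb_dispersion >= 0, "nb_dispersion must be >= 0")
  effects <- .check_effects(genome, effects)
  set.seed(derive_seed(seed, "library"))
  L <- nchar(genome$sequence)
  pos <- which(runif(L) < insertions_per_bp)
  pos <- pos[pos > end_margin & pos <= L - end_margin]
  if (any(effects$essential)) {
    ess <- genome$genes[effects$essential, , drop = FALSE]
    inside <- IRanges::overlapsAny(
      IRanges::IRanges(pos, width = 1L),
      IRanges::IRanges(ess$start, ess$end))
    pos <- pos[!inside]
  }
  n <- length(pos)
  tn_profile(pos, sample(c("+", "-"), n, TRUE),
             .rztnb(n, mean_reads_per_site, nb_dispersion),
             sample_id = sample_id, replicon_id = genome$replicon_id)
}

#' Apply selection to a library by multinomial resampling
#'
#' Models outgrowth under a condition: the treated profile is a multinomial
#' resample of the control's `total_reads` reads with per-site weight
#' proportional to `count * 2^(scale * fitness_log2)` of the containing gene
#' (0 for intergenic sites; `-Inf` effects give weight zero). Sites drawn
#' zero times are dropped, so the treated site set is a subset of the
#' control's and total reads are conserved exactly.
#'
#' @param control a non-empty [tn_profile()].
#' @param genome a [tn_genome()].
#' @param effects effect map covering every gene.
#' @param seed integer seed.
#' @param scale multiplier on `fitness_log2` (selection strength; 0 gives a
#'   neutral technical replicate).
#' @param sample_id sample name for the output profile.
#' @return A [tn_profile()].
#' @export
apply_selection <- function(control, genome, effects, seed, scale = 1,
                            sample_id = "treated") {
  .assert(nrow(control) > 0, "control profile is empty")
  effects <- .check_effects(genome, effects)
  set.seed(derive_seed(seed, "selection"))
  gene <- .position_gene(control$position, genome)
  eff <- rep(0, nrow(control))
  hit <- gene != ""
  eff[hit] <- effects$fitness_log2[match(gene[hit], effects$gene_id)]
  w <- control$count * 2^(scale * eff)
  w[!is.finite(w)] <- 0 # -Inf effect: hard kill
  .assert(sum(w) > 0, "all selection weights are zero")
  new <- rmultinom(1, total_reads(control), prob = w)[, 1]
  tn_profile(control$position, control$strand, new,
             sample_id = sample_id, replicon_id = attr(control, "replicon_id"))
}

#' Emit transposon-junction reads for an insertion profile
#'
#' Each counted read is `barcode + tag_seq + genomic junction`, where the
#' junction starts at the insertion position on the recorded strand and
#' extends until the read is full or the linear replicon ends (reads near an
#' end are truncated, never wrapped). Substitution errors at `error_rate`
#' are applied to the genomic portion only — the barcode and transposon tag
#' are synthetic handles added after the error-prone template. Base
#' qualities are constant (default Q30).
#'
#' Read ids encode the true origin as `sample:position:strand:serial`, which
#' downstream accuracy checks against ground truth rely on.
#'
#' @param profile a [tn_profile()].
#' @param genome a [tn_genome()].
#' @param tag_seq transposon-end tag sequence appearing after the barcode.
#' @param barcode inline sample barcode at the read start.
#' @param read_length total read length; must exceed
#'   `nchar(barcode) + nchar(tag_seq) + 10`.
#' @param error_rate per-base substitution probability in the junction.
#' @param seed integer seed.
#' @param base_quality constant Phred quality (default 30).
#' @return data.frame with columns `read_id`, `sequence`, `qualities`.
#' @export
emit_reads <- function(profile, genome, tag_seq, barcode, read_length = 100,
                       error_rate = 0, seed, base_quality = 30L) {
  nb <- nchar(barcode); nt <- nchar(tag_seq)
  .assert(nt > 0, "tag_seq must be non-empty")
  .assert(read_length > nb + nt + 10, "read_length too short for junction")
  set.seed(derive_seed(seed, "reads"))
  gl <- read_length - nb - nt
  L <- nchar(genome$sequence)
  sample_id <- attr(profile, "sample_id")
  if (!nrow(profile)) {
    return(data.frame(read_id = character(), sequence = character(),
                      qualities = character(), stringsAsFactors = FALSE))
  }
  plus <- profile$strand == "+"
  from <- ifelse(plus, profile$position, pmax(1L, profile$position - gl + 1L))
  to <- ifelse(plus, pmin(L, profile$position + gl - 1L), profile$position)
  junc <- substring(genome$sequence, from, to)
  junc[!plus] <- .revcomp(junc[!plus])
  idx <- rep(seq_len(nrow(profile)), profile$count)
  junc <- junc[idx]
  if (error_rate > 0) {
    jl <- nchar(junc)
    nerr <- rbinom(length(junc), jl, error_rate)
    for (i in which(nerr > 0)) {
      at <- sample.int(jl[i], nerr[i])
      ch <- strsplit(junc[i], "")[[1]]
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      junc[i] <- paste(ch, collapse = "")
    }
  }
  seqs <- paste0(barcode, tag_seq, junc)
  serial <- stats::ave(idx, idx, FUN = seq_along)
  data.frame(
    read_id = sprintf("%s:%d:%s:%d", sample_id, profile$position[idx],
                      profile$strand[idx], serial),
    sequence = seqs,
    qualities = strrep(rawToChar(as.raw(33L + base_quality)), nchar(seqs)),
    stringsAsFactors = FALSE)
}

## --- plain-text IO -------------------------------------------------------

#' Write a genome as FASTA plus GFF3 gene models
#' @param genome a [tn_genome()].
#' @param fasta,gff output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta, gff) {
  dss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$replicon_id))
  Biostrings::writeXStringSet(dss, fasta)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genome$replicon_id,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = if (nrow(g)) g$strand else character(),
    type = rep("gene", nrow(g)), ID = g$gene_id)
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Read a genome from FASTA plus GFF3
#' @param fasta,gff input paths; the GFF3 must carry `type=gene` rows with an
#'   `ID` attribute.
#' @return A [tn_genome()].
#' @export
read_genome <- function(fasta, gff) {
  dss <- Biostrings::readDNAStringSet(fasta)
  .assert(length(dss) == 1, "expected a single replicon FASTA")
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = gr$ID,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  # strip any description after the first whitespace in the FASTA header
  tn_genome(sub("\\s.*$", "", names(dss)[1]), as.character(dss[[1]]), genes)
}

#' Write / read a ground-truth effect table (TSV)
#' @param effects effect map data.frame.
#' @param path file path.
#' @return `write_effects` invisibly returns `path`; `read_effects` the
#'   data.frame.
#' @export
write_effects <- function(effects, path) {
  write.table(effects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$essential <- as.logical(df$essential)
  df
}

#' Write reads as a 4-line-record FASTQ file
#' @param reads data.frame from [emit_reads()].
#' @param path output path (".gz" suffix compresses).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads$sequence)
  names(dss) <- reads$read_id
  Biostrings::writeXStringSet(
    dss, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ path (gzip allowed).
#' @return data.frame with `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(read_id = names(dss),
             sequence = as.character(dss),
             qualities = as.character(S4Vectors::mcols(dss)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
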
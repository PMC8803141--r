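#' tnfitness: conditional gene fitness from transposon insertion sequencing
#'
#' Simulation and analysis of TraDIS/Tn-seq conditional-fitness screens:
#' saturated insertion-library simulation under known selection, junction-read
#' demultiplexing and mapping, per-gene insertion indices, gamma-mixture
#' essentiality calling, negative-binomial exact-test fitness scoring with a
#' Bonferroni-corrected significance gate, hypergeometric term enrichment, and
#' competition-assay selection rates.
#'
#' @importFrom stats dgamma rgamma runif rnorm rbinom rmultinom pnbinom qnbinom
#'   dnbinom ppois qpois dbinom cor sd var median quantile setNames phyper
#'   aggregate na.omit ave
#' @importFrom utils head tail write.table read.table read.csv modifyList
#' @importFrom data.table data.table setkey rbindlist := .N
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

.stage_offsets <- c(
  genome = 101L, effects = 157L, library = 211L, selection = 307L,
  reads = 401L, replicate = 503L, mixture = 557L, fitness = 601L,
  misc = 701L
)

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from one master seed through this
#' deterministic map, so that every stage of a run is independently
#' reproducible. The result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param stage one of "genome", "effects", "library", "selection", "reads",
#'   "replicate", "mixture", "fitness", "misc".
#' @param index optional integer distinguishing repeated uses of one stage
#'   (e.g. replicate number).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "library")
#' derive_seed(1L, "selection", index = 2L)
derive_seed <- function(seed, stage, index = 0L) {
  stage <- match.arg(stage, names(.stage_offsets))
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) %% 2147483629 * 48271 +
                off * 9973 + as.numeric(index) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg, class = "tn_error") {
  if (!isTRUE(ok)) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(TRUE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Annotated genome container
#'
#' Bundles a single linear replicon sequence with 1-based, inclusive,
#' non-overlapping gene models.
#'
#' @param replicon_id replicon name.
#' @param sequence genome sequence as a single A/C/G/T character string.
#' @param genes data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `length_bp`; coordinates 1-based inclusive, `start <= end`.
#' @return An object of class `tn_genome`.
#' @export
tn_genome <- function(replicon_id, sequence, genes) {
  sequence <- as.character(sequence)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    need <- c("gene_id", "start", "end", "strand")
    .assert(all(need %in% names(genes)), "genes must have gene_id/start/end/strand")
    genes$length_bp <- genes$end - genes$start + 1L
    .assert(all(genes$start >= 1L & genes$end <= nchar(sequence)),
            "gene coordinates outside [1, genome length]")
    .assert(all(genes$length_bp >= 1L), "gene with end < start")
    .assert(!anyDuplicated(genes$gene_id), "duplicated gene_id")
    o <- order(genes$start)
    .assert(all(diff(genes$start[o]) > 0) &&
              all(genes$end[o][-nrow(genes)] < genes$start[o][-1]),
            "overlapping genes")
  } else {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        length_bp = integer(), stringsAsFactors = FALSE)
  }
  structure(list(replicon_id = replicon_id, sequence = sequence, genes = genes),
            class = "tn_genome")
}

#' @export
print.tn_genome <- function(x, ...) {
  cat(sprintf("tn_genome '%s': %s bp, %d genes\n", x$replicon_id,
              format(nchar(x$sequence), big.mark = ","), nrow(x$genes)))
  invisible(x)
}

#' Insertion profile container
#'
#' Per-sample map from (position, strand) to junction read count. Zero-count
#' entries are never stored; `total_reads` equals the sum of counts.
#'
#' @param position integer vector of 1-based insertion positions.
#' @param strand character vector of "+"/"-".
#' @param count positive integer read counts.
#' @param sample_id,replicon_id identifiers carried as attributes.
#' @return A data.frame of class `tn_profile`, sorted by position then strand.
#' @export
tn_profile <- function(position, strand, count, sample_id, replicon_id) {
  .assert(length(position) == length(strand) && length(strand) == length(count),
          "position/strand/count lengths differ")
  keep <- count > 0
  df <- data.frame(position = as.integer(position[keep]),
                   strand = as.character(strand[keep]),
                   count = as.integer(count[keep]), stringsAsFactors = FALSE)
  .assert(!nrow(df) || all(df$strand %in% c("+", "-")), "strand must be +/-")
  .assert(!anyDuplicated(df[c("position", "strand")]),
          "duplicate (position, strand) entries")
  df <- df[order(df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, replicon_id = replicon_id,
            total_reads = sum(df$count),
            class = c("tn_profile", "data.frame"))
}

#' @export
print.tn_profile <- function(x, ...) {
  cat(sprintf("tn_profile '%s' on '%s': %d unique sites, %s reads\n",
              attr(x, "sample_id"), attr(x, "replicon_id"), nrow(x),
              format(attr(x, "total_reads"), big.mark = ",")))
  invisible(x)
}

#' Total mapped reads of an insertion profile
#' @param profile a [tn_profile()].
#' @return Integer read total.
#' @export
total_reads <- function(profile) attr(profile, "total_reads")

.gene_ranges <- function(genome, end_trim_fraction = 0) {
  g <- genome$genes
  trim <- as.integer(floor(end_trim_fraction * g$length_bp))
  IRanges::IRanges(start = g$start + trim, end = g$end - trim, names = g$gene_id)
}

# gene_id containing each position ("" if intergenic); genes non-overlapping
.position_gene <- function(positions, genome, end_trim_fraction = 0) {
  out <- character(length(positions))
  if (!nrow(genome$genes) || !length(positions)) return(out)
  hits <- IRanges::findOverlaps(IRanges::IRanges(positions, width = 1L),
                                .gene_ranges(genome, end_trim_fraction))
  out[S4Vectors::queryHits(hits)] <- genome$genes$gene_id[S4Vectors::subjectHits(hits)]
  out
}
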
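# Per-gene summaries of insertion profiles: unique insertions, read counts,
# insertion indices, genome-wide density, replicate agreement.

#' Insertion index of a gene
#'
#' Unique insertion sites divided by gene length; the central per-gene
#' statistic of saturated transposon screens (low values flag essentiality).
#'
#' @param unique_insertions number of distinct insertion sites in the gene.
#' @param length_bp gene length (>= 1).
#' @return `unique_insertions / length_bp`.
#' @export
#' @examples
#' insertion_index(10, 1000)
insertion_index <- function(unique_insertions, length_bp) {
  .assert(all(length_bp >= 1), "length_bp must be >= 1", "tn_domain_error")
  .assert(all(unique_insertions >= 0), "unique_insertions must be >= 0",
          "tn_domain_error")
  unique_insertions / length_bp
}

#' Genome-wide insertion density
#'
#' @param n_unique_sites number of unique insertion sites (>= 1).
#' @param genome_length_bp genome length.
#' @return Base pairs per insertion (`genome_length_bp / n_unique_sites`);
#'   summary reports round it to one decimal.
#' @export
#' @examples
#' genome_density(1000, 10000) # 10 bp per insertion
genome_density <- function(n_unique_sites, genome_length_bp) {
  .assert(all(n_unique_sites >= 1), "need at least one site", "tn_domain_error")
  genome_length_bp / n_unique_sites
}

#' Summarize an insertion profile per gene
#'
#' Assigns each site to the gene whose (symmetrically end-trimmed) interval
#' contains its position; intergenic sites are ignored. With overlapping
#' annotations every covering gene is credited. `unique_insertions` counts
#' distinct sites — per (position, strand) by default, per position with
#' `collapse_strands`.
#'
#' @param profile a [tn_profile()].
#' @param genome a [tn_genome()].
#' @param end_trim_fraction fraction (in `[0, 0.5)`) trimmed from each gene
#'   end before assignment; accommodates insertion-tolerant gene ends.
#' @param collapse_strands count sites per position rather than per
#'   (position, strand).
#' @return data.frame with `gene_id`, `length_bp`, `unique_insertions`,
#'   `read_count`, `insertion_index`, in genome gene order.
#' @export
summarize_genes <- function(profile, genome, end_trim_fraction = 0,
                            collapse_strands = FALSE) {
  .assert(end_trim_fraction >= 0 && end_trim_fraction < 0.5,
          "end_trim_fraction must be in [0, 0.5)")
  g <- genome$genes
  out <- data.frame(gene_id = g$gene_id, length_bp = g$length_bp,
                    unique_insertions = 0L, read_count = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(g) && nrow(profile)) {
    sites <- if (collapse_strands) {
      dt <- data.table::data.table(position = profile$position,
                                   count = profile$count)
      as.data.frame(dt[, .(count = sum(count)), by = position])
    } else profile
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$position, width = 1L),
      .gene_ranges(genome, end_trim_fraction))
    if (length(hits)) {
      dt <- data.table::data.table(gene = S4Vectors::subjectHits(hits),
                                   count = sites$count[S4Vectors::queryHits(hits)])
      agg <- dt[, .(unique_insertions = .N, read_count = sum(count)), by = gene]
      out$unique_insertions[agg$gene] <- agg$unique_insertions
      out$read_count[agg$gene] <- as.integer(agg$read_count)
    }
  }
  out$insertion_index <- insertion_index(out$unique_insertions, out$length_bp)
  out
}

#' Replicate agreement of per-gene insertion indices
#'
#' Pearson correlation of insertion indices between two replicates over the
#' shared gene universe, matched by `gene_id`.
#'
#' @param stats_a,stats_b per-gene tables from [summarize_genes()] over the
#'   same genes.
#' @return list with `n_genes`, `pearson_r`, `r_squared`.
#' @export
replicate_correlation <- function(stats_a, stats_b) {
  .assert(setequal(stats_a$gene_id, stats_b$gene_id),
          "replicates cover different gene universes")
  b <- stats_b[match(stats_a$gene_id, stats_b$gene_id), ]
  x <- stats_a$insertion_index
  y <- b$insertion_index
  .assert(sd(x) > 0 && sd(y) > 0,
          "zero variance: correlation undefined", "tn_domain_error")
  r <- cor(x, y)
  list(n_genes = length(x), pearson_r = r, r_squared = r^2)
}

#' Write a per-gene insertion summary (TSV)
#' @param stats data.frame from [summarize_genes()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene insertion summary (TSV)
#' @param path input path.
#' @return data.frame.
#' @export
read_gene_stats <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a per-position count track (BED-like 4-column TSV)
#'
#' Columns `replicon  start0  end  count` with 0-based half-open intervals,
#' for genome-browser style plotting of insertion frequency.
#'
#' @param profile a [tn_profile()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_track <- function(profile, path) {
  dt <- data.table::data.table(position = profile$position,
                               count = profile$count)
  agg <- dt[, .(count = sum(count)), by = position][order(position)]
  df <- data.frame(replicon = attr(profile, "replicon_id"),
                   start = agg$position - 1L, end = agg$position,
                   count = agg$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
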
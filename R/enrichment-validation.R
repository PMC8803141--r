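# Downstream statistics: hypergeometric term enrichment of significant gene
# sets against a genome background, and the competition-assay selection-rate
# statistic used for wet-lab validation.

#' Hypergeometric term enrichment of a significant gene set
#'
#' For each term with `K` background genes out of `N`, and `k` of the `n`
#' significant genes carrying it, the one-sided upper-tail p-value
#' `P[X >= k]` with `X ~ Hypergeometric(N, K, n)` measures over-representation.
#' Terms absent from the background (`K = 0`) are skipped with a warning.
#' The significance flag is inclusive (`p <= alpha`).
#'
#' @param sig_genes character vector of significant gene ids (subset of
#'   `background`).
#' @param terms named list `term_id -> character vector of gene ids`, or a
#'   2-column data.frame (`gene_id`, `term_id`).
#' @param background character vector of all annotated gene ids.
#' @param alpha inclusive significance threshold (default 0.005).
#' @return data.frame sorted by ascending p with columns `term_id`, `k`,
#'   `n`, `K`, `N`, `p_value`, `significant`.
#' @export
enrich <- function(sig_genes, terms, background, alpha = 0.005) {
  if (is.data.frame(terms)) {
    .assert(ncol(terms) >= 2, "term map needs gene_id and term_id columns",
            "tn_config_error")
    terms <- split(terms[[1]], terms[[2]])
  }
  background <- unique(background)
  sig_genes <- unique(sig_genes)
  .assert(all(sig_genes %in% background),
          "significant genes outside the background universe",
          "tn_config_error")
  N <- length(background)
  n <- length(sig_genes)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), background)
    K <- length(members)
    if (K == 0) {
      warning(sprintf("term '%s' has no background genes; skipped", tm))
      return(NULL)
    }
    k <- length(intersect(sig_genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric())
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  out$significant <- out$p_value <= alpha
  rownames(out) <- NULL
  out
}

#' Competition-assay selection rate
#'
#' The relative competitive index of a mutant (R) against wild type (V)
#' from colony counts at time 0 and t:
#' `r = ln(Rt/R0) - ln(Vt/V0)`. Vectorized over replicates. A zero count at
#' time t leaves `r` undefined; the default policy flags it (`r = NA`,
#' `undefined = TRUE`, mirroring a mutant eliminated below the detection
#' limit), the alternative adds 0.5 to all four counts.
#'
#' @param R0,Rt mutant colony counts (CFU) at time 0 and t.
#' @param V0,Vt wild-type colony counts at time 0 and t.
#' @param zero_policy `"flag"` (default) or `"pseudocount"`.
#' @return data.frame with `r`, `undefined`, `pseudo_applied`, one row per
#'   replicate.
#' @export
#' @examples
#' selection_rate(100, 50, 100, 100) # r = ln(0.5)
selection_rate <- function(R0, Rt, V0, Vt,
                           zero_policy = c("flag", "pseudocount")) {
  zero_policy <- match.arg(zero_policy)
  m <- cbind(R0, Rt, V0, Vt) # recycles scalars across replicates
  .assert(all(m >= 0), "colony counts must be non-negative")
  .assert(all(m[, "R0"] > 0 & m[, "V0"] > 0),
          "zero baseline count: no time-0 population", "tn_data_error")
  zero_t <- m[, "Rt"] == 0 | m[, "Vt"] == 0
  pseudo <- zero_policy == "pseudocount" & zero_t
  m[pseudo, ] <- m[pseudo, , drop = FALSE] + 0.5
  r <- log(m[, "Rt"] / m[, "R0"]) - log(m[, "Vt"] / m[, "V0"])
  undefined <- zero_t & zero_policy == "flag"
  r[undefined] <- NA_real_
  data.frame(r = r, undefined = undefined, pseudo_applied = pseudo,
             row.names = NULL)
}

#' Read a gene-to-term map (2-column TSV)
#'
#' One `gene_id<TAB>term_id` pair per line, with or without a header.
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("gene_id", first, fixed = TRUE)
  df <- read.table(path, header = header, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("gene_id", "term_id"))
  df
}

#' Read colony counts for competition assays (CSV)
#'
#' Long format with columns `strain`, `timepoint`, `replicate`, `R`, `V`
#' (mutant and wild-type CFU).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_competition_counts <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Selection rates for a colony-count table
#'
#' Joins each strain/timepoint's counts at time t with its time-0 baseline
#' (timepoint `0`, matched by replicate) and computes per-replicate and mean
#' selection rates.
#'
#' @param counts data.frame as from [read_competition_counts()].
#' @param zero_policy passed to [selection_rate()].
#' @return list with `per_replicate` and `summary` (mean r per
#'   strain/timepoint over defined replicates) data.frames.
#' @export
competition_selection_rates <- function(counts, zero_policy = "flag") {
  .assert(all(c("strain", "timepoint", "replicate", "R", "V") %in%
                names(counts)), "missing colony-count columns",
          "tn_config_error")
  base <- counts[counts$timepoint == 0, ]
  post <- counts[counts$timepoint != 0, ]
  key <- function(d) paste(d$strain, d$replicate)
  i <- match(key(post), key(base))
  .assert(!anyNA(i), "competition sample without a time-0 baseline",
          "tn_data_error")
  sr <- selection_rate(base$R[i], post$R, base$V[i], post$V,
                       zero_policy = zero_policy)
  per <- cbind(post[c("strain", "timepoint", "replicate")], sr)
  agg <- stats::aggregate(r ~ strain + timepoint, data = per, FUN = mean,
                          na.action = stats::na.omit)
  list(per_replicate = per, summary = agg)
}
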
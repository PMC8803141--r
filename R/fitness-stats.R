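# The analytical core: gamma-mixture essentiality calling on insertion
# indices, negative-binomial exact-test log2 fold changes between treated and
# control insertion counts, Bonferroni correction, the magnitude/significance
# gate, and time-point set bookkeeping.

# weighted gamma MLE; shape by Newton on log(a) - digamma(a) = s
.wgamma_fit <- function(x, w, shape_max = 1e4) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  s <- log(m) - sum(w * log(x)) / sw
  if (!is.finite(s) || s <= 1e-12) {
    a <- shape_max # (near-)degenerate weighted sample: all mass on one value
  } else {
    a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (i in 1:25) {
      step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
      a <- a - step
      if (!is.finite(a) || a <= 0) { a <- 1e-3; break }
      if (abs(step) < 1e-10 * a) break
    }
    a <- min(max(a, 1e-3), shape_max)
  }
  c(shape = a, scale = m / a)
}

#' Fit a two-component gamma mixture to insertion indices
#'
#' Models the genome-wide insertion-index distribution as a mixture of a
#' low-index (essential) and a high-index (non-essential) gamma component,
#' fit by expectation-maximization. Zero indices are accommodated by adding
#' a small pseudo-index to every value before fitting (recommended:
#' `1 / (2 * max gene length)`), which gives the left component a proper
#' support point for insertion-free genes. Components are returned in
#' increasing-mean order regardless of initialization; the fit is
#' deterministic given the data and `pseudo`.
#'
#' @param indices non-negative insertion indices, one per gene (>= 100).
#' @param pseudo pseudo-index added to every value; default half the
#'   smallest positive index.
#' @param max_iter maximum EM iterations.
#' @param tol convergence: log-likelihood improvement below `tol` for 3
#'   consecutive iterations (default 1e-8).
#' @param shape_max cap on the gamma shape, which diverges when one
#'   component collapses onto a single value (e.g. all-zero indices).
#' @param min_separation minimal ratio of non-essential to essential
#'   component means (default 5). Genuinely bimodal insertion-index data
#'   separate the modes by two orders of magnitude; a fit whose components
#'   sit closer than this describes unimodal data and raises a
#'   degenerate-fit error instructing a fixed-threshold fallback.
#' @return An object of class `tn_essentiality_model`: list with `pi`
#'   (essential-component weight), `shape0`, `scale0`, `shape1`, `scale1`,
#'   `loglik`, `n_genes`, `pseudo`, `iterations`.
#' @export
fit_essentiality_mixture <- function(indices, pseudo = NULL, max_iter = 500,
                                     tol = 1e-8, shape_max = 1e4,
                                     min_separation = 5) {
  .assert(length(indices) >= 100, "need at least 100 genes")
  .assert(all(indices >= 0), "indices must be non-negative")
  if (is.null(pseudo)) {
    pos <- indices[indices > 0]
    .assert(length(pos) > 0, "all indices are zero: degenerate fit",
            "tn_degenerate_fit")
    pseudo <- min(pos) / 2
  }
  x <- indices + pseudo
  .assert(diff(range(x)) > 0, "all indices identical: degenerate fit",
          "tn_degenerate_fit")

  # deterministic init: split at the geometric midpoint of the range
  thr <- exp(mean(range(log(x))))
  z <- ifelse(x < thr, 0.95, 0.05)
  if (all(z == z[1])) z <- ifelse(x <= median(x), 0.95, 0.05)
  pi0 <- mean(z)
  f0 <- .wgamma_fit(x, z, shape_max)
  f1 <- .wgamma_fit(x, 1 - z, shape_max)

  ll_old <- -Inf; below <- 0L; it <- 0L
  repeat {
    it <- it + 1L
    d0 <- dgamma(x, shape = f0["shape"], scale = f0["scale"], log = TRUE) +
      log(pi0)
    d1 <- dgamma(x, shape = f1["shape"], scale = f1["scale"], log = TRUE) +
      log1p(-pi0)
    mx <- pmax(d0, d1)
    ll <- sum(mx + log(exp(d0 - mx) + exp(d1 - mx)))
    z <- 1 / (1 + exp(d1 - d0))
    pi0 <- mean(z)
    if (pi0 < 1e-3 || pi0 > 1 - 1e-3) {
      .assert(FALSE, paste0("mixture collapsed (pi = ", signif(pi0, 3),
                            "): data look unimodal; fall back to a fixed ",
                            "insertion-index threshold"), "tn_degenerate_fit")
    }
    f0 <- .wgamma_fit(x, z, shape_max)
    f1 <- .wgamma_fit(x, 1 - z, shape_max)
    below <- if (is.finite(ll_old) && ll - ll_old < tol) below + 1L else 0L
    if (below >= 3L || it >= max_iter) break
    ll_old <- ll
  }
  m0 <- unname(f0["shape"] * f0["scale"])
  m1 <- unname(f1["shape"] * f1["scale"])
  if (m0 > m1) { tmp <- f0; f0 <- f1; f1 <- tmp; pi0 <- 1 - pi0; tmp <- m0; m0 <- m1; m1 <- tmp }
  .assert(m1 > min_separation * m0,
          paste0("component means are not separated (ratio ",
                 signif(m1 / max(m0, .Machine$double.eps), 3),
                 "): data look unimodal; fall back to a fixed ",
                 "insertion-index threshold"), "tn_degenerate_fit")
  structure(list(pi = pi0,
                 shape0 = unname(f0["shape"]), scale0 = unname(f0["scale"]),
                 shape1 = unname(f1["shape"]), scale1 = unname(f1["scale"]),
                 mean0 = m0, mean1 = m1,
                 loglik = ll, n_genes = length(indices), pseudo = pseudo,
                 iterations = it),
            class = "tn_essentiality_model")
}

#' @export
print.tn_essentiality_model <- function(x, ...) {
  cat(sprintf(paste0("tn_essentiality_model: pi = %.3f, essential mean = %.2e,",
                     " non-essential mean = %.2e (n = %d, loglik = %.1f)\n"),
              x$pi, x$mean0, x$mean1, x$n_genes, x$loglik))
  invisible(x)
}

#' Call essentiality from insertion indices under a fitted mixture
#'
#' The log2 likelihood ratio of the essential versus non-essential component
#' (including mixture weights) is thresholded: at or above `llr_hi` the gene
#' is `essential`, at or below `llr_lo` `nonessential`, in between
#' `ambiguous`.
#'
#' @param indices insertion indices (vector).
#' @param model a `tn_essentiality_model`.
#' @param llr_lo,llr_hi log2-odds thresholds (defaults -2 and +2).
#' @param gene_id optional gene ids for the output.
#' @return data.frame with `gene_id`, `insertion_index`,
#'   `log2_likelihood_ratio`, `call`.
#' @export
call_essentiality <- function(indices, model, llr_lo = -2, llr_hi = 2,
                              gene_id = NULL) {
  .assert(llr_lo < llr_hi, "llr_lo must be below llr_hi")
  x <- indices + model$pseudo
  d0 <- dgamma(x, shape = model$shape0, scale = model$scale0, log = TRUE)
  d1 <- dgamma(x, shape = model$shape1, scale = model$scale1, log = TRUE)
  llr <- (log(model$pi) + d0 - log1p(-model$pi) - d1) / log(2)
  call <- ifelse(llr >= llr_hi, "essential",
                 ifelse(llr <= llr_lo, "nonessential", "ambiguous"))
  data.frame(gene_id = gene_id %||% sprintf("gene_%04d", seq_along(indices)),
             insertion_index = indices, log2_likelihood_ratio = llr,
             call = call, stringsAsFactors = FALSE)
}

#' Library-size factors and common dispersion from a count matrix
#'
#' Size factor per sample is its library size (total mapped reads),
#' optionally multiplied by a trimmed-mean-of-ratios factor. The common
#' negative-binomial dispersion (variance `mu + phi * mu^2`) is estimated by
#' method of moments on within-condition replicates of counts scaled to the
#' mean library size, with an unbiased-denominator correction and a floor at
#' zero.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param design character/factor of `"control"`/`"treated"` per sample.
#' @param method `"libsize"` (default) or `"tmm"` (adds a 30%-trimmed mean
#'   of log ratios against the first sample).
#' @return list with `size_factors` (per sample) and `dispersion` (scalar
#'   `phi >= 0`).
#' @export
normalize_and_dispersion <- function(counts, design,
                                     method = c("libsize", "tmm")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  design <- as.character(design)
  .assert(length(design) == ncol(counts), "design length != sample count")
  .assert(all(c("control", "treated") %in% design) ||
            length(unique(design)) >= 1,
          "design must label samples control/treated")
  libs <- colSums(counts)
  .assert(all(libs > 0), "sample with zero total reads", "tn_data_error")
  sf <- libs
  if (method == "tmm") {
    ref <- counts[, 1] / libs[1]
    tmm <- vapply(seq_len(ncol(counts)), function(j) {
      obs <- counts[, j] / libs[j]
      ok <- obs > 0 & ref > 0
      if (!any(ok)) return(1)
      2^mean(log2(obs[ok] / ref[ok]), trim = 0.3)
    }, 0)
    sf <- sf * tmm
  }
  scaled <- sweep(counts, 2, mean(libs) / libs, `*`)
  num <- 0; den <- 0
  for (cond in unique(design)) {
    j <- which(design == cond)
    if (length(j) < 2) next
    m <- rowMeans(scaled[, j, drop = FALSE])
    v <- apply(scaled[, j, drop = FALSE], 1, var)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(pmax(m[keep]^2 - v[keep] / length(j), 0))
  }
  phi <- if (den > 0) max(0, num / den) else 0
  list(size_factors = sf, dispersion = phi)
}

# quantile-to-quantile adjustment of one count to a common library size
# (mid-p tail matching under NB with common dispersion; phi = 0 -> Poisson)
.q2q <- function(y, mu_in, mu_out, phi) {
  if (mu_in <= 0 || mu_out <= 0) return(y)
  if (phi > 0) {
    size <- 1 / phi
    u <- 0.5 * (pnbinom(y - 1, size = size, mu = mu_in) +
                  pnbinom(y, size = size, mu = mu_in))
    qnbinom(pmin(u, 1 - 1e-12), size = size, mu = mu_out)
  } else {
    u <- 0.5 * (ppois(y - 1, mu_in) + ppois(y, mu_in))
    qpois(pmin(u, 1 - 1e-12), mu_out)
  }
}

#' Negative-binomial exact test for one gene
#'
#' Replicate counts are mapped to a common library size by
#' quantile-to-quantile adjustment under the common dispersion, then pooled
#' per condition. Conditional on the pooled total, the split between
#' conditions follows a distribution free of the unknown gene abundance
#' (binomial when `phi = 0`, the negative-binomial analogue otherwise); the
#' two-sided exact p-value sums the probabilities of all splits no more
#' probable than the observed one.
#'
#' @param gene_control_counts,gene_treated_counts per-replicate counts for
#'   one gene.
#' @param size_factors size factors for `c(control, treated)` samples, in
#'   that order (default: all equal).
#' @param phi common dispersion (>= 0).
#' @return Two-sided exact p-value in `(0, 1]`.
#' @export
nb_exact_test <- function(gene_control_counts, gene_treated_counts,
                          size_factors = NULL, phi = 0) {
  .assert(phi >= 0, "dispersion must be >= 0", "tn_domain_error")
  y1 <- gene_control_counts; y2 <- gene_treated_counts
  n1 <- length(y1); n2 <- length(y2)
  sf <- size_factors %||% rep(1, n1 + n2)
  .assert(length(sf) == n1 + n2, "size_factors length mismatch")
  sf <- sf / mean(sf)
  y <- c(y1, y2)
  if (any(sf != 1)) {
    p_hat <- sum(y) / sum(sf) # common relative abundance under the null
    y <- vapply(seq_along(y), function(j)
      .q2q(y[j], p_hat * sf[j], p_hat, phi), 0)
  }
  A <- round(sum(y[seq_len(n1)]))
  t <- round(sum(y))
  if (t == 0) return(1)
  k <- 0:t
  if (phi > 0) {
    lp <- dnbinom(k, size = n1 / phi, prob = 0.5, log = TRUE) +
      dnbinom(t - k, size = n2 / phi, prob = 0.5, log = TRUE)
  } else {
    lp <- dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  min(1, sum(p[p <= p[A + 1] * (1 + 1e-9)]))
}

#' Log2 fold change of normalized mean counts
#'
#' @param gene_control_counts,gene_treated_counts per-replicate counts for
#'   one gene.
#' @param size_factors size factors for `c(control, treated)` samples;
#'   counts are scaled to their mean before averaging.
#' @param prior_count prior added to both means to guard zeros (default
#'   0.5).
#' @return `log2((mean treated + prior) / (mean control + prior))`.
#' @export
log2_fold_change <- function(gene_control_counts, gene_treated_counts,
                             size_factors = NULL, prior_count = 0.5) {
  .assert(prior_count > 0, "prior_count must be > 0")
  n1 <- length(gene_control_counts); n2 <- length(gene_treated_counts)
  sf <- size_factors %||% rep(1, n1 + n2)
  sf <- sf / mean(sf)
  y <- c(gene_control_counts, gene_treated_counts) / sf
  mc <- mean(y[seq_len(n1)])
  mt <- mean(y[n1 + seq_len(n2)])
  log2((mt + prior_count) / (mc + prior_count))
}

#' Bonferroni correction
#' @param p p-value(s).
#' @param n_tests number of tests (the non-essential genes tested).
#' @return `min(1, p * n_tests)` elementwise.
#' @export
bonferroni <- function(p, n_tests) {
  .assert(all(p >= 0 & p <= 1), "p outside [0,1]")
  .assert(n_tests >= 1, "n_tests must be >= 1")
  pmin(1, p * n_tests)
}

#' Significance gate on fold change and adjusted p-value
#'
#' A gene is a fitness `loss` if `log2fc < -lfc_threshold` and
#' `adj_p < alpha`, a `gain` if `log2fc > lfc_threshold` and
#' `adj_p < alpha`, otherwise `ns`. Both inequalities are strict: a fold
#' change of exactly the threshold magnitude is fractionally below the
#' cut-off, and the p threshold itself does not pass.
#'
#' @param log2fc log2 fold change(s).
#' @param adj_p adjusted p-value(s).
#' @param lfc_threshold magnitude threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.005).
#' @return Character vector in `{"loss", "gain", "ns"}`.
#' @export
#' @examples
#' gate_significance(c(-3.323, -0.961, 8.392), c(1.13e-27, 0.0026, 5.06e-134))
gate_significance <- function(log2fc, adj_p, lfc_threshold = 1,
                              alpha = 0.005) {
  ifelse(adj_p < alpha & log2fc < -lfc_threshold, "loss",
         ifelse(adj_p < alpha & log2fc > lfc_threshold, "gain", "ns"))
}

#' Partition significant genes by time point
#'
#' @param sig_early,sig_late character vectors of genes significant at the
#'   early and late time point.
#' @return list of disjoint sets `both`, `early_only`, `late_only`.
#' @export
classify_timepoints <- function(sig_early, sig_late) {
  list(both = sort(intersect(sig_early, sig_late)),
       early_only = sort(setdiff(sig_early, sig_late)),
       late_only = sort(setdiff(sig_late, sig_early)))
}

#' Per-gene fitness test between treated and control samples
#'
#' Runs [normalize_and_dispersion()], then per gene the exact test and log2
#' fold change, Bonferroni correction over the genes with any reads, and the
#' significance gate.
#'
#' @param counts genes x samples count matrix with gene ids as rownames.
#' @param design `"control"`/`"treated"` per column.
#' @param lfc_threshold,alpha gate parameters (defaults 1 and 0.005).
#' @param prior_count fold-change prior (default 0.5).
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @param norm_method passed to [normalize_and_dispersion()].
#' @return data.frame with `gene_id`, `mean_control_count`,
#'   `mean_treated_count`, `log2fc`, `p_value`, `adj_p`, `sig_class`.
#' @export
fitness_test <- function(counts, design, lfc_threshold = 1, alpha = 0.005,
                         prior_count = 0.5, dispersion = NULL,
                         norm_method = "libsize") {
  counts <- as.matrix(counts)
  design <- as.character(design)
  nd <- normalize_and_dispersion(counts, design, method = norm_method)
  phi <- dispersion %||% nd$dispersion
  ctrl <- which(design == "control")
  trt <- which(design == "treated")
  .assert(length(ctrl) >= 1 && length(trt) >= 1,
          "need at least one control and one treated sample")
  sf <- nd$size_factors[c(ctrl, trt)]
  ng <- nrow(counts)
  p <- numeric(ng); lfc <- numeric(ng)
  for (g in seq_len(ng)) {
    yc <- counts[g, ctrl]; yt <- counts[g, trt]
    p[g] <- nb_exact_test(yc, yt, size_factors = sf, phi = phi)
    lfc[g] <- log2_fold_change(yc, yt, size_factors = sf,
                               prior_count = prior_count)
  }
  n_tests <- sum(rowSums(counts) > 0)
  adj <- bonferroni(p, max(1L, n_tests))
  sfn <- nd$size_factors / mean(nd$size_factors)
  norm <- sweep(counts, 2, sfn, `/`)
  data.frame(
    gene_id = rownames(counts) %||% sprintf("gene_%04d", seq_len(ng)),
    mean_control_count = rowMeans(norm[, ctrl, drop = FALSE]),
    mean_treated_count = rowMeans(norm[, trt, drop = FALSE]),
    log2fc = lfc, p_value = p, adj_p = adj,
    sig_class = gate_significance(lfc, adj, lfc_threshold, alpha),
    stringsAsFactors = FALSE)
}
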
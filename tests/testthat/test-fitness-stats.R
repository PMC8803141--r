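test_that("the gamma-mixture EM recovers known mixtures and orders components", {
  set.seed(301)
  n <- 4000
  z <- runif(n) < 0.1
  x <- ifelse(z, rgamma(n, shape = 3, scale = 0.0005),
              rgamma(n, shape = 3, scale = 0.045))
  m <- fit_essentiality_mixture(x, pseudo = 1e-4)
  expect_lt(abs(m$pi - 0.1), 0.03)
  expect_lt(abs(m$mean0 - 0.0015) / 0.0015, 0.30) # pseudo shifts the low mode
  expect_lt(abs(m$mean1 - 0.135) / 0.135, 0.15)
  expect_lt(m$mean0, m$mean1) # increasing-mean order is guaranteed
  expect_true(is.finite(m$loglik))

  expect_error(fit_essentiality_mixture(rep(0.05, 500)),
               class = "tn_degenerate_fit")
  # unimodal data collapse to a degenerate fit with a clear instruction
  set.seed(302)
  expect_error(fit_essentiality_mixture(rgamma(1000, 50, scale = 0.002)),
               class = "tn_degenerate_fit")
  expect_error(fit_essentiality_mixture(x[1:50]), "100")
})

test_that("essentiality calls follow the log2 likelihood-ratio thresholds", {
  set.seed(303)
  n <- 4000
  z <- runif(n) < 0.1
  x <- ifelse(z, rgamma(n, shape = 3, scale = 0.0005),
              rgamma(n, shape = 3, scale = 0.045))
  m <- fit_essentiality_mixture(x, pseudo = 1e-4)

  # an insertion-free gene sits far inside the left mode
  expect_equal(call_essentiality(0, m)$call, "essential")
  # the non-essential component mean is confidently non-essential
  expect_equal(call_essentiality(m$mean1, m)$call, "nonessential")
  # at the density crossover the likelihood ratio is ~0: ambiguous
  llr_fun <- function(ix) call_essentiality(ix, m)$log2_likelihood_ratio
  cross <- uniroot(llr_fun, c(1e-6, m$mean1), tol = 1e-12)$root
  expect_equal(call_essentiality(cross, m)$call, "ambiguous")
  expect_lt(abs(llr_fun(cross)), 1e-6)
  expect_error(call_essentiality(0.1, m, llr_lo = 2, llr_hi = -2), "llr_lo")
})

test_that("size factors track library size and dispersion is recovered", {
  # identical replicates: equal size factors, zero dispersion
  cnt <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  nd <- normalize_and_dispersion(cnt, c("control", "treated"))
  expect_equal(unname(nd$size_factors[1]), unname(nd$size_factors[2]))
  expect_equal(nd$dispersion, 0)

  # doubling one library's every count doubles only its size factor
  cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 2
  nd2 <- normalize_and_dispersion(cnt2, c("control", "treated"))
  expect_equal(unname(nd2$size_factors[2] / nd$size_factors[2]), 2)
  expect_equal(unname(nd2$size_factors[1]), unname(nd$size_factors[1]))
  expect_equal(nd2$dispersion, nd$dispersion)

  # moment estimator recovers the simulated dispersion
  set.seed(304)
  cnt3 <- matrix(rnbinom(4000 * 4, mu = 250, size = 1 / 0.3), ncol = 4)
  nd3 <- normalize_and_dispersion(
    cnt3, c("control", "control", "treated", "treated"))
  expect_lt(abs(nd3$dispersion - 0.3), 0.1)

  expect_error(normalize_and_dispersion(cbind(c(0, 0), c(1, 2)),
                                        c("control", "treated")),
               class = "tn_data_error")
})

test_that("the exact test matches enumeration, the binomial limit and edgeR", {
  # exhaustive split enumeration for all totals <= 30 at phi in {0, 0.3}
  for (phi in c(0, 0.3)) {
    for (t in c(1, 2, 6, 13, 30)) {
      for (A in 0:t) {
        p <- nb_exact_test(A, t - A, phi = phi)
        expect_equal(p, exact_test_oracle(A, t, 1, 1, phi),
                     tolerance = 1e-12,
                     label = sprintf("A=%d t=%d phi=%g", A, t, phi))
      }
    }
  }
  # phi = 0 reduces to the exact binomial test for all totals <= 50
  set.seed(305)
  for (i in 1:25) {
    t <- sample(1:50, 1)
    A <- sample(0:t, 1)
    expect_equal(nb_exact_test(A, t - A, phi = 0),
                 binom.test(A, t, 0.5)$p.value, tolerance = 1e-12)
  }
  # equal normalized counts give p = 1
  expect_equal(nb_exact_test(c(50, 50), c(50, 50), phi = 0.3), 1,
               tolerance = 1e-9)
  expect_error(nb_exact_test(3, 5, phi = -0.1), class = "tn_domain_error")

  # independent route: edgeR's exact test with the same rejection rule
  set.seed(306)
  cnt <- matrix(rnbinom(200 * 4, mu = 80, size = 1 / 0.3), ncol = 4)
  d <- edgeR::DGEList(counts = cnt, group = c(1, 1, 2, 2))
  d$samples$lib.size <- rep(1e5, 4)
  ref <- edgeR::exactTest(d, dispersion = 0.3,
                          rejection.region = "smallp")$table$PValue
  mine <- vapply(seq_len(nrow(cnt)), function(g)
    nb_exact_test(cnt[g, 1:2], cnt[g, 3:4], rep(1e5, 4), phi = 0.3), 0)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("swapping conditions negates log2FC and preserves the p-value", {
  set.seed(307)
  for (i in 1:20) {
    yc <- rnbinom(2, mu = 150, size = 4)
    yt <- rnbinom(2, mu = 40, size = 4)
    expect_equal(nb_exact_test(yc, yt, phi = 0.2),
                 nb_exact_test(yt, yc, phi = 0.2), tolerance = 1e-12)
    expect_equal(log2_fold_change(yc, yt), -log2_fold_change(yt, yc),
                 tolerance = 1e-12)
  }
})

test_that("log2 fold changes use normalized means with a zero-guard prior", {
  expect_equal(log2_fold_change(c(100, 100), c(100, 100)), 0)
  expect_equal(log2_fold_change(1000, 4000), 2, tolerance = 0.01)
  expect_equal(log2_fold_change(100, 0), log2(0.5 / 100.5))
  # unequal library sizes are divided out
  expect_equal(log2_fold_change(100, 200, size_factors = c(1, 2)), 0,
               tolerance = 1e-12)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.001, 10), 0.01)
  expect_equal(bonferroni(0.0005, 4000), 1)
  expect_equal(bonferroni(0, 1000), 0)
  expect_error(bonferroni(1.2, 10), "outside")
})

test_that("the significance gate applies strict dual thresholds", {
  # printed score/p pairs: strong depletion, strong enrichment, and a
  # magnitude fractionally below the cut-off
  expect_equal(gate_significance(-3.323, 1.13e-27), "loss")
  expect_equal(gate_significance(-0.961, 0.0026), "ns")
  expect_equal(gate_significance(8.392, 5.06e-134), "gain")
  expect_equal(gate_significance(-1.061, 0.0041), "loss")
  expect_equal(gate_significance(1.5, 0.01), "ns")
  # both inequalities are strict
  expect_equal(gate_significance(-1, 1e-10), "ns")
  expect_equal(gate_significance(-1.5, 0.005), "ns")
  expect_equal(gate_significance(c(-2, 2, 0), c(1e-5, 1e-5, 1e-5)),
               c("loss", "gain", "ns"))
})

test_that("time-point classification partitions into disjoint sets", {
  tc <- classify_timepoints(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(tc$both, c("b", "c"))
  expect_equal(tc$early_only, "a")
  expect_equal(tc$late_only, "d")
  expect_length(intersect(tc$both, c(tc$early_only, tc$late_only)), 0)
  t0 <- classify_timepoints(character(), c("x", "y"))
  expect_equal(t0$both, character())
  expect_equal(t0$late_only, c("x", "y"))
  ts <- classify_timepoints(c("g1", "g2"), c("g1", "g2"))
  expect_equal(ts$both, c("g1", "g2"))
  expect_length(ts$early_only, 0)
})

test_that("fitness_test assembles per-gene results with a shared gate", {
  set.seed(308)
  ng <- 200
  mu <- rep(100, ng)
  lfc_true <- rep(0, ng); lfc_true[1:5] <- -3; lfc_true[6:8] <- 2
  ctrl <- matrix(rnbinom(ng * 2, mu = mu, size = 20), ncol = 2)
  trt <- matrix(rnbinom(ng * 2, mu = mu * 2^lfc_true, size = 20), ncol = 2)
  counts <- cbind(ctrl, trt)
  rownames(counts) <- sprintf("g%03d", seq_len(ng))
  res <- fitness_test(counts, c("control", "control", "treated", "treated"))
  expect_equal(res$sig_class[1:5], rep("loss", 5))
  expect_equal(res$sig_class[6:8], rep("gain", 3))
  expect_true(all(res$adj_p >= res$p_value))
  expect_true(all(res$sig_class[abs(res$log2fc) <= 1 | res$adj_p >= 0.005] ==
                    "ns"))
})
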
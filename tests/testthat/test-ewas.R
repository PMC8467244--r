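mk_beta <- function(x, probes = rownames(x), samples = colnames(x)) {
  if (is.null(probes)) probes <- paste0("cg", seq_len(nrow(x)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(x)))
  dimnames(x) <- list(probes, samples)
  beta_matrix(x)
}

test_that("qc_samples separates bimodal, uniform and degenerate samples", {
  set.seed(50)
  n <- 10000
  bimodal <- ifelse(runif(n) < 0.5, rbeta(n, 1, 10), rbeta(n, 10, 1))
  unif <- runif(n)
  zeros <- rep(0, n)
  qc <- qc_samples(mk_beta(cbind(bimodal, unif, zeros)))
  expect_identical(qc$pass, c(TRUE, FALSE, TRUE))
  # Beta CDF oracle: expected intermediate fraction of the mixture
  expected <- 0.5 * (pbeta(0.75, 1, 10) - pbeta(0.25, 1, 10)) +
              0.5 * (pbeta(0.75, 10, 1) - pbeta(0.25, 10, 1))
  expect_lt(abs(qc$fraction_intermediate[1] - expected), 0.015)
  expect_lt(abs(qc$fraction_intermediate[2] - 0.5), 0.02)
  expect_identical(qc$fraction_intermediate[3], 0)
})

test_that("call_state follows the 0.2/0.6 rule with closed boundaries", {
  expect_identical(as.character(call_state(c(0.1, 0.4, 0.7))),
                   c("unmethylated", "hemimethylated", "methylated"))
  # boundary stability: both printed thresholds belong to the
  # hemimethylated band
  expect_identical(as.character(call_state(c(0.2, 0.6))),
                   c("hemimethylated", "hemimethylated"))
  expect_identical(as.character(call_state(c(0, 1))),
                   c("unmethylated", "methylated"))
  expect_error(call_state(1.3), "outside")
  # exhaustive over a grid: every value gets exactly one state
  expect_false(anyNA(call_state(seq(0, 1, by = 0.001))))
})

test_that("ewas matches the direct-formula t-test and handles degenerate
           probes", {
  # fixed printed 4+4 vectors
  tv <- c(0.42, 0.38, 0.45, 0.40); cv <- c(0.05, 0.07, 0.04, 0.06)
  b <- mk_beta(matrix(c(tv, cv), nrow = 1), probes = "cgA")
  res <- ewas(b, paste0("s", 1:4), paste0("s", 5:8))
  orc <- oracle_t_test(tv, cv)
  expect_equal(res$t_stat, orc$t, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-9)
  expect_equal(res$p, t.test(tv, cv, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(res$delta_beta, mean(tv) - mean(cv))
  expect_identical(as.character(res$state_tumor), "hemimethylated")
  expect_identical(as.character(res$state_control), "unmethylated")

  # identical betas in both arms: t = 0, p = 1, delta 0
  b2 <- mk_beta(matrix(c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.31, 0.29),
                       nrow = 2, byrow = TRUE))
  res2 <- ewas(b2, c("s1", "s2"), c("s3", "s4"))
  expect_equal(res2$t_stat[1], 0)
  expect_equal(res2$p[1], 1)
  expect_equal(res2$delta_beta[1], 0)

  # Bonferroni invariant across all probes
  expect_true(all(res2$p_bonferroni >= res2$p))
  expect_equal(res2$p_bonferroni, pmin(1, res2$p * 2))
})

test_that("planted 4-vs-72 hemimethylated probe is Bonferroni-significant
           with high Monte-Carlo power", {
  set.seed(51)
  m_probes <- 20000
  hits <- 0L
  reps <- 200
  for (i in seq_len(reps)) {
    tv <- rbeta(4, 38.0, 57.0)    # mean 0.4, sd ~0.05
    cv <- rbeta(72, 5.9, 112.1)   # mean 0.05, sd ~0.02
    p <- t.test(tv, cv, var.equal = TRUE)$p.value
    if (p * m_probes < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.99)

  # and the packaged pipeline flags it on one draw
  set.seed(52)
  bg <- matrix(rbeta(200 * 76, 1, 10), 200, 76)
  bg[1, 1:4] <- rbeta(4, 38, 57)
  bg[1, 5:76] <- rbeta(72, 5.9, 112.1)
  b <- mk_beta(bg)
  res <- ewas(b, paste0("s", 1:4), paste0("s", 5:76))
  expect_lt(res$p_bonferroni[1], 0.05)
  expect_identical(as.character(res$state_tumor[1]), "hemimethylated")
  expect_identical(as.character(res$state_control[1]), "unmethylated")
})

test_that("smooth_pvalues reproduces hand arithmetic and the windowed-mean
           oracle, independently per chromosome", {
  # printed example: radius 3, first probe of (1e-8, 1 x 6)
  p <- c(1e-8, 1, 1, 1, 1, 1, 1)
  man <- probe_manifest(paste0("p", 1:7), "chr1", seq(10, 70, 10))
  res <- data.frame(probe_id = paste0("p", 1:7), p = p)
  sm <- smooth_pvalues(res, man, radius = 3)
  expect_equal(sm$p_smoothed[1], 1e-2, tolerance = 1e-12)
  expect_equal(sm$p_smoothed, oracle_smooth(p, 3))

  # constant p: smoothing is the identity
  resc <- data.frame(probe_id = paste0("p", 1:7), p = rep(0.37, 7))
  expect_equal(smooth_pvalues(resc, man, radius = 3)$p_smoothed,
               rep(0.37, 7))

  # single-probe chromosome: p_smoothed = p; chromosomes independent
  man2 <- probe_manifest(paste0("q", 1:4), c("chr1", "chr1", "chr1", "chr2"),
                         c(10, 20, 30, 10))
  res2 <- data.frame(probe_id = paste0("q", 1:4),
                     p = c(1e-4, 1e-2, 1, 1e-6))
  sm2 <- smooth_pvalues(res2, man2, radius = 3)
  expect_equal(sm2$p_smoothed[4], 1e-6)
  expect_equal(sm2$p_smoothed[1:3], oracle_smooth(res2$p[1:3], 3))

  # probes without coordinates get NA
  res3 <- data.frame(probe_id = c("q1", "zz"), p = c(0.5, 0.5))
  sm3 <- smooth_pvalues(res3, man2, radius = 3)
  expect_true(is.na(sm3$p_smoothed[2]))
})

test_that("smoothing is a contraction of the score range", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    p <- 10^(-runif(n, 0, 8))
    man <- probe_manifest(paste0("p", 1:n), "chr1", seq_len(n) * 100)
    res <- data.frame(probe_id = paste0("p", 1:n), p = p)
    sm <- smooth_pvalues(res, man, radius = sample(1:4, 1))$p_smoothed
    expect_lte(max(-log10(sm)), max(-log10(p)) + 1e-12)
    expect_gte(min(-log10(sm)), min(-log10(p)) - 1e-12)
  }
})

test_that("locus_analysis verdicts and the extra (QC-failed) arm", {
  man <- probe_manifest(paste0("p", 1:5), "chr12", 1:5 * 100,
                        gene = "CACNA1C-AS1",
                        island_id = c(rep("CpG:84", 4), ""))
  res <- data.frame(probe_id = paste0("p", 1:5),
                    mean_beta_tumor = c(0.3, 0.4, 0.5, 0.35, 0.1),
                    mean_beta_control = c(0.05, 0.1, 0.02, 0.15, 0.1),
                    p = 0.01)
  res$state_tumor <- call_state(res$mean_beta_tumor)
  res$state_control <- call_state(res$mean_beta_control)
  loc <- locus_analysis(res, man, "CpG:84")
  expect_identical(loc$verdict, "concordant_hemimethylation")
  expect_equal(loc$n_hemimethylated_tumor, 4L)

  # one methylated control probe -> mixed
  res_mixed <- res
  res_mixed$mean_beta_control[2] <- 0.8
  res_mixed$state_control <- call_state(res_mixed$mean_beta_control)
  expect_identical(locus_analysis(res_mixed, man, "CpG:84")$verdict, "mixed")

  # no hemimethylated tumor probe -> null verdict
  res_null <- res
  res_null$mean_beta_tumor <- rep(0.05, 5)
  res_null$state_tumor <- call_state(res_null$mean_beta_tumor)
  expect_identical(locus_analysis(res_null, man, "CpG:84")$verdict, "null")

  # extra arm: QC-failed samples still show the hemimethylated profile
  set.seed(54)
  eb <- mk_beta(matrix(rbeta(5 * 3, 38, 57), 5, 3,
                       dimnames = list(paste0("p", 1:5), paste0("b", 1:3))))
  loc2 <- locus_analysis(res, man, "CpG:84", extra_beta = eb)
  expect_true(all(loc2$probes$state_extra == "hemimethylated"))
  # empty extra matrix: identical to the plain summary
  loc3 <- locus_analysis(res, man, "CpG:84",
                         extra_beta = NULL)
  expect_identical(loc3$probes$mean_beta_tumor, loc$probes$mean_beta_tumor)

  expect_error(locus_analysis(res, man, "CpG:999"), "no probes")
})

test_that("manhattan/volcano exports are sorted and arithmetically exact", {
  man <- probe_manifest(c("a", "b", "c"), c("chr2", "chr1", "chr1"),
                        c(50, 200, 100))
  res <- data.frame(probe_id = c("a", "b", "c"),
                    delta_beta = c(0.3, -0.1, 0.2),
                    p = c(1e-4, 0.5, 1e-2),
                    p_smoothed = c(1e-3, NA, 1e-2))
  mv <- export_manhattan_volcano(res, man)
  expect_equal(nrow(mv$manhattan), 2L)       # NA smoothed row dropped
  expect_identical(mv$manhattan$probe_id, c("c", "a"))  # genomic sort
  expect_equal(nrow(mv$volcano), 3L)         # volcano keeps all rows
  expect_equal(mv$manhattan$neglog10_p_smoothed,
               -log10(res$p_smoothed[match(mv$manhattan$probe_id,
                                           res$probe_id)]),
               tolerance = 1e-12)
  expect_equal(mv$volcano$neglog10_p,
               -log10(res$p[match(mv$volcano$probe_id, res$probe_id)]),
               tolerance = 1e-12)
})
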
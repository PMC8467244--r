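mk_norm <- function(x, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(x)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(x)))
  dimnames(x) <- list(genes, samples)
  structure(x, class = c("normalized_matrix", "matrix", "array"))
}

planted_two_archetypes <- function(seed = 5, n_per = 50, n_samp = 20,
                                   noise_sd = 0.1) {
  set.seed(seed)
  up <- c(rep(0, n_samp / 2), rep(1, n_samp / 2))
  x <- rbind(
    matrix(rep(up, n_per), nrow = n_per, byrow = TRUE),
    matrix(rep(-up, n_per), nrow = n_per, byrow = TRUE)
  ) + matrix(rnorm(2 * n_per * n_samp, sd = noise_sd), ncol = n_samp)
  list(norm = mk_norm(x), truth = rep(1:2, each = n_per))
}

test_that("planted two-archetype partition is recovered exactly (ARI = 1)", {
  d <- planted_two_archetypes()
  cl <- kmeans_profiles(d$norm, k = 2, runs = 10, seed = 1)
  expect_equal(oracle_ari(cl$assignment, d$truth), 1.0)
  # exhaustive check: equals planted partition up to label permutation
  expect_true(identical(as.integer(cl$assignment), d$truth) ||
              identical(as.integer(cl$assignment), 3L - d$truth))
})

test_that("k = n gives singleton clusters with zero objective;
           duplicates always co-cluster", {
  set.seed(6)
  x <- matrix(rnorm(6 * 8), nrow = 6)
  cl <- kmeans_profiles(mk_norm(x), k = 6, runs = 20, seed = 2)
  expect_equal(length(unique(cl$assignment)), 6L)
  expect_equal(cl$objective, 0, tolerance = 1e-10)

  xd <- rbind(x, x[1, , drop = FALSE])  # duplicate of gene 1
  cld <- kmeans_profiles(mk_norm(xd), k = 3, runs = 20, seed = 3)
  expect_equal(unname(cld$assignment[1]), unname(cld$assignment[7]))
})

test_that("objective is non-increasing within the winning run and
           clustering is reproducible given a seed", {
  d <- planted_two_archetypes(seed = 9, noise_sd = 0.4)
  cl <- kmeans_profiles(d$norm, k = 4, runs = 25, seed = 11)
  expect_true(all(diff(cl$trace) <= 1e-10))
  expect_true(cl$objective <= min(cl$run_objectives) + 1e-10)
  cl2 <- kmeans_profiles(d$norm, k = 4, runs = 25, seed = 11)
  expect_identical(cl$assignment, cl2$assignment)
  expect_identical(cl$objective, cl2$objective)

  # reported objective matches its definition: sum of 1 - r(gene, centroid
  # direction), centroid direction = normalized mean standardized profile
  xs <- t(scale(t(unclass(d$norm))))
  xs <- xs / sqrt(rowSums(xs^2))
  obj <- 0
  for (j in sort(unique(cl$assignment))) {
    cs <- colMeans(xs[cl$assignment == j, , drop = FALSE])
    cs <- cs / sqrt(sum(cs^2))
    obj <- obj + sum(1 - xs[cl$assignment == j, , drop = FALSE] %*% cs)
  }
  expect_equal(cl$objective, obj, tolerance = 1e-8)
})

test_that("constant-profile genes are excluded with a warning", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40), 5, 8), rep(3, 8))
  expect_warning(cl <- kmeans_profiles(mk_norm(x), k = 2, runs = 5, seed = 1),
                 "constant")
  expect_equal(length(cl$assignment), 5L)
  expect_identical(cl$excluded, "g6")
})

test_that("cluster_group_profiles: null case keeps nominal type-I control", {
  # all groups drawn from the same distribution: after Bonferroni over
  # k x 3 tests, a family-wise rejection should be rare; over 100
  # simulations the rejection rate must stay below 0.05 + 3 binomial sd
  set.seed(21)
  rejections <- 0L
  sheet <- sample_sheet(paste0("s", 1:20), rep(c("N", "E", "C", "T"), 5))
  for (i in 1:100) {
    x <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
    cl <- kmeans_profiles(mk_norm(x), k = 3, runs = 5)
    prof <- cluster_group_profiles(cl, mk_norm(x), sheet)
    if (any(prof$p_bonferroni < 0.05, na.rm = TRUE)) rejections <- rejections + 1L
  }
  expect_lte(rejections / 100, 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("cluster_group_profiles: planted +1 log2 shift in T is detected
           and a single-sample group yields NA", {
  set.seed(22)
  n_per <- 13
  sheet <- sample_sheet(paste0("s", 1:(4 * n_per)),
                        rep(c("N", "E", "C", "T"), each = n_per))
  shift <- c(rep(0, 3 * n_per), rep(1, n_per))
  x <- matrix(rnorm(20 * 4 * n_per, sd = 0.3), 20, 4 * n_per, byrow = FALSE)
  x <- sweep(x, 2, shift, "+")
  dimnames(x) <- list(paste0("g", 1:20), sheet$sample_id)
  cl <- kmeans_profiles(mk_norm(x), k = 2, runs = 10, seed = 4)
  prof <- cluster_group_profiles(cl, mk_norm(x), sheet)
  t_rows <- prof[prof$group == "T", ]
  expect_true(any(t_rows$p_bonferroni < 0.05))
  # analytic power oracle: per-sample cluster mean has sd ~ 0.3/sqrt(20);
  # noncentrality for n=13 vs 13 with delta=1 is enormous, power ~ 1
  se <- 0.3 / sqrt(20) * sqrt(2 / n_per)
  expect_gt(1 / se, 10)  # sanity: the planted design is far from the null

  sheet1 <- sample_sheet(paste0("s", 1:5), c("N", "N", "N", "T", "E"))
  x1 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  cl1 <- kmeans_profiles(mk_norm(x1), k = 2, runs = 5, seed = 5)
  prof1 <- cluster_group_profiles(cl1, mk_norm(x1), sheet1)
  expect_true(all(is.na(prof1$p_vs_N[prof1$group == "T"])))
  expect_true(all(is.na(prof1$sd[prof1$group == "T"])))
})

test_that("gene_stats matches direct-formula oracles and handles edge cases", {
  sheet <- sample_sheet(paste0("s", 1:10), rep(c("T", "N"), each = 5))
  # fixed 5+5 vectors: p within 1e-12 of the hand-computed test
  xa <- c(2.3, 1.9, 2.8, 2.1, 2.4); xb <- c(1.2, 1.6, 0.9, 1.4, 1.1)
  norm <- mk_norm(matrix(c(xa, xb), nrow = 1), genes = "g1",
                  samples = sheet$sample_id)
  unl <- expression_matrix(2^unclass(norm))
  st <- gene_stats(norm, unl, sheet, "T", "N")
  orc <- oracle_t_test(xa, xb)
  expect_equal(st$t, orc$t, tolerance = 1e-12)
  expect_equal(st$p, orc$p, tolerance = 1e-9)
  tt <- t.test(xa, xb, var.equal = TRUE)
  expect_equal(st$p, tt$p.value, tolerance = 1e-12)
  expect_equal(st$t, unname(tt$statistic), tolerance = 1e-12)

  # identical group values: t = 0, p = 1, FC = 1
  v <- c(1, 2, 3, 2, 1)
  norm2 <- mk_norm(matrix(c(v, v), nrow = 1), genes = "g1",
                   samples = sheet$sample_id)
  unl2 <- expression_matrix(2^unclass(norm2))
  st2 <- gene_stats(norm2, unl2, sheet, "T", "N")
  expect_equal(st2$t, 0)
  expect_equal(st2$p, 1)
  expect_equal(st2$fc, 1)

  # noise-free multiplicative effect 2.0: FC exactly 2
  unl3 <- expression_matrix(matrix(c(rep(200, 5), rep(100, 5)), nrow = 1,
    dimnames = list("g1", sheet$sample_id)))
  st3 <- gene_stats(norm, unl3, sheet, "T", "N")
  expect_identical(st3$fc, 2)

  # p-values invariant under gene and sample reordering
  set.seed(30)
  x <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("g", 1:6), sheet$sample_id))
  u <- expression_matrix(2^x)
  a <- gene_stats(mk_norm(x), u, sheet, "T", "N")
  perm_g <- sample(6); perm_s <- sample(10)
  xp <- x[perm_g, perm_s]
  norm_p <- structure(xp, class = c("normalized_matrix", "matrix", "array"))
  b <- gene_stats(norm_p, expression_matrix(2^xp), sheet, "T", "N")
  expect_equal(b$p[match(a$gene, b$gene)], a$p)
})
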
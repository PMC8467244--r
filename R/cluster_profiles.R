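# Gene profile clustering (restarted k-means under correlation distance)
# and per-cluster, per-group significance against the normal group.

#' Cluster gene profiles with restarted k-means
#'
#' Genes are grouped by profile shape with k-means under correlation
#' distance d(x, c) = 1 - Pearson(x, c). Each run starts from a random
#' partition of the genes into k clusters and alternates assignment
#' (each gene to its nearest centroid; ties to the lowest cluster id) and
#' centroid update until the assignment is stable or `max_iter` iterations
#' are reached; the run with the smallest objective wins.
#'
#' In correlation mode the update operates on row-standardized profiles
#' (the spherical k-means update), which makes the within-run objective
#' non-increasing; the reported `centroids` are the per-cluster mean
#' profiles on the input scale. `method = "euclidean"` runs classic Lloyd
#' k-means on the raw rows (squared-distance objective) for comparison.
#'
#' Constant-profile genes have no defined correlation and are excluded
#' with a warning (listed in `$excluded`).
#'
#' @param norm a `normalized_matrix` (genes x samples, log2
#'   median-centered).
#' @param k number of clusters (default 10).
#' @param runs number of random restarts (default 100).
#' @param seed optional integer seed for the restarts.
#' @param method "correlation" (default) or "euclidean".
#' @param max_iter iteration cap per run (default 100).
#' @return a `gene_clustering` list: `k`, `assignment` (named integer
#'   vector gene -> cluster), `centroids` (k x sample matrix of mean
#'   member profiles), `objective`, `run_objectives`, `trace` (objective
#'   per iteration of the winning run), `seed`, `n_runs`, `method`,
#'   `excluded`.
#' @export
kmeans_profiles <- function(norm, k = 10, runs = 100, seed = NULL,
                            method = c("correlation", "euclidean"),
                            max_iter = 100) {
  method <- match.arg(method)
  x <- unclass(norm)
  const <- apply(x, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || diff(range(v)) < 1e-12
  })
  if (any(const)) {
    warning(sum(const), " constant-profile gene(s) excluded from clustering",
            call. = FALSE)
    x <- x[!const, , drop = FALSE]
  }
  if (nrow(x) < k) stop("k exceeds the number of usable genes", call. = FALSE)
  if (anyNA(x)) stop("clustering input must be complete (no NA)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  inits <- vapply(seq_len(runs), function(i) sample.int(k, nrow(x), replace = TRUE),
                  integer(nrow(x)))
  fit <- .kmeans_profiles_cpp(x, inits, as.integer(k), as.integer(max_iter),
                              method == "correlation")
  assignment <- setNames(fit$assignment, rownames(x))
  centroids <- .cluster_centroids(x, assignment, k)
  structure(list(
    k = k,
    assignment = assignment,
    centroids = centroids,
    objective = fit$objective,
    run_objectives = fit$run_objectives,
    trace = fit$trace,
    best_run = fit$best_run,
    reseeds = fit$reseeds,
    seed = seed,
    n_runs = runs,
    method = method,
    excluded = rownames(norm)[const]
  ), class = "gene_clustering")
}

.cluster_centroids <- function(x, assignment, k) {
  cent <- matrix(NA_real_, nrow = k, ncol = ncol(x),
                 dimnames = list(paste0("cluster", seq_len(k)), colnames(x)))
  for (j in seq_len(k)) {
    members <- names(assignment)[assignment == j]
    if (length(members) > 0) {
      cent[j, ] <- colMeans(x[members, , drop = FALSE])
    }
  }
  cent
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat("gene_clustering: k =", x$k, "|", length(x$assignment), "genes |",
      x$n_runs, "runs (", x$method, ") | objective =",
      format(x$objective, digits = 6), "\n")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Per-cluster, per-group mean profiles and significance vs the N group
#'
#' For each cluster, every sample is summarized by the mean expression of
#' the cluster's member genes; these per-sample cluster means are then
#' summarized per group (mean, sd, n) and each non-normal group (E, C, T)
#' is compared with the N group by a two-sided pooled-variance Student
#' t-test. Bonferroni correction uses m = k x 3 tests. Samples, not genes,
#' are the independent units: member genes are correlated, so pooling them
#' into one test would overstate significance.
#'
#' @param clust a `gene_clustering`.
#' @param norm the `normalized_matrix` that was clustered.
#' @param sheet a [sample_sheet()] covering all columns of `norm`.
#' @return data frame with one row per (cluster, group): mean, sd, n,
#'   p_vs_N (NA for N itself or when either side has < 2 samples) and
#'   p_bonferroni = min(1, p_vs_N * k * 3).
#' @export
cluster_group_profiles <- function(clust, norm, sheet) {
  x <- unclass(norm)
  grp <- .group_lookup(sheet, colnames(x))
  m_tests <- clust$k * 3
  rows <- list()
  for (j in seq_len(clust$k)) {
    members <- names(clust$assignment)[clust$assignment == j]
    if (length(members) == 0) next
    per_sample <- colMeans(x[members, , drop = FALSE])
    ref <- per_sample[grp == "N"]
    for (g in GROUP_LEVELS) {
      v <- per_sample[grp == g]
      p <- NA_real_
      if (g != "N") {
        if (length(v) >= 2 && length(ref) >= 2) {
          p <- .pooled_t_test(v, ref)$p
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        cluster = j, group = g, mean = mean(v),
        sd = if (length(v) >= 2) sd(v) else NA_real_,
        n = length(v), p_vs_N = p,
        p_bonferroni = if (is.na(p)) NA_real_ else min(1, p * m_tests),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = GROUP_LEVELS)
  out
}

#' Per-gene two-group statistics: t, p, Bonferroni p and fold change
#'
#' The t-test is the two-sided pooled-variance Student t-test on the log2
#' median-centered values; the fold change is the ratio of unlogged group
#' means, mean(A) / mean(B), computed from the unlogged original
#' intensities (pass the raw matrix; a LOWESS-normalized unlogged matrix
#' can be passed instead to get the post-normalization convention).
#' NA handling is listwise within a gene (NA values dropped per group).
#'
#' @param norm `normalized_matrix` (log2 scale) for the test.
#' @param unlogged [expression_matrix()] on the same genes/samples for the
#'   fold change (conventionally the unlogged original data).
#' @param sheet a [sample_sheet()].
#' @param group_a,group_b character vectors of group labels; e.g.
#'   `group_a = "T", group_b = "N"` for FC_T/N, or `c("C","T")` vs
#'   `c("N","E")` for the predictor contrast.
#' @return data frame: gene, n_a, n_b, mean_log_a, mean_log_b, t, p,
#'   p_bonferroni (m = number of genes), fc.
#' @export
gene_stats <- function(norm, unlogged, sheet, group_a = "T", group_b = "N") {
  stopifnot(identical(rownames(norm), rownames(unlogged)),
            identical(colnames(norm), colnames(unlogged)))
  grp <- .group_lookup(sheet, colnames(norm))
  ia <- grp %in% group_a
  ib <- grp %in% group_b
  if (sum(ia) < 2 || sum(ib) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  tt <- .row_pooled_t(unclass(norm)[, ia, drop = FALSE],
                      unclass(norm)[, ib, drop = FALSE])
  mu_a <- rowMeans(unclass(unlogged)[, ia, drop = FALSE], na.rm = TRUE)
  mu_b <- rowMeans(unclass(unlogged)[, ib, drop = FALSE], na.rm = TRUE)
  fc <- mu_a / mu_b
  zero <- !is.na(mu_b) & mu_b == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero denominator mean: FC set to NA",
            call. = FALSE)
    fc[zero] <- NA_real_
  }
  m <- nrow(norm)
  data.frame(gene = rownames(norm),
             n_a = tt$n1, n_b = tt$n2,
             mean_log_a = tt$m1, mean_log_b = tt$m2,
             t = tt$t, p = tt$p,
             p_bonferroni = pmin(1, tt$p * m),
             fc = fc,
             stringsAsFactors = FALSE, row.names = NULL)
}

# vectorized two-sided pooled-variance Student t-test over matrix rows;
# degenerate rows: zero pooled variance -> t = 0, p = 1 when means equal,
# |t| = Inf, p = 0 otherwise
.row_pooled_t <- function(a, b) {
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  ss1 <- rowSums((a - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((b - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  zerovar <- !is.na(se) & se == 0
  eq <- zerovar & (m1 == m2)
  t[eq] <- 0; p[eq] <- 1
  t[zerovar & !eq] <- sign(m1 - m2)[zerovar & !eq] * Inf
  p[zerovar & !eq] <- 0
  bad <- df < 1 | n1 < 2 | n2 < 2
  t[bad] <- NA_real_; p[bad] <- NA_real_
  list(t = t, p = p, n1 = n1, n2 = n2, m1 = m1, m2 = m2)
}

.pooled_t_test <- function(x, y) {
  r <- .row_pooled_t(matrix(x, nrow = 1), matrix(y, nrow = 1))
  list(t = r$t[1], p = r$p[1])
}

.group_lookup <- function(sheet, sample_ids) {
  idx <- match(sample_ids, sheet$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from sheet: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  setNames(as.character(sheet$group[idx]), sample_ids)
}
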
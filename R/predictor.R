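# Centroid-correlation diagnostic predictor: top discriminant genes from
# two clusters, a mean C/T reference profile, per-sample Pearson
# correlation, a +/-0.25 abstention band, and Fisher-exact /
# sensitivity / specificity evaluation (in-sample or leave-one-out).

#' Pick the two predictor source clusters
#'
#' Default rule for which clusters feed the predictor: for each cluster,
#' the per-sample cluster-mean expression is tested (pooled-variance
#' Student t) for C/T vs N/E; the cluster with the smallest p-value is
#' taken first, then the smallest-p cluster whose effect has the opposite
#' sign. This is robust to cluster renumbering across runs.
#'
#' @param clust a `gene_clustering`.
#' @param norm the clustered `normalized_matrix`.
#' @param sheet a [sample_sheet()].
#' @return integer vector of two cluster ids.
#' @export
select_predictor_clusters <- function(clust, norm, sheet) {
  x <- unclass(norm)
  grp <- .group_lookup(sheet, colnames(x))
  pos <- grp %in% c("C", "T"); neg <- grp %in% c("N", "E")
  stats <- data.frame(cluster = integer(), t = numeric(), p = numeric())
  for (j in seq_len(clust$k)) {
    members <- names(clust$assignment)[clust$assignment == j]
    if (length(members) == 0) next
    per_sample <- colMeans(x[members, , drop = FALSE])
    r <- .pooled_t_test(per_sample[pos], per_sample[neg])
    stats <- rbind(stats, data.frame(cluster = j, t = r$t, p = r$p))
  }
  stats <- stats[!is.na(stats$p), ]
  stats <- stats[order(stats$p, stats$cluster), ]
  first <- stats[1, ]
  opp <- stats[sign(stats$t) == -sign(first$t), ]
  if (nrow(opp) == 0) {
    stop("no cluster with an opposite-direction C/T vs N/E effect",
         call. = FALSE)
  }
  c(first$cluster, opp$cluster[1])
}

#' Select top discriminant genes from named clusters
#'
#' Within each named cluster, genes are ranked by |t| of the C/T vs N/E
#' contrast (descending; ties broken by gene id) and the top `n_top` from
#' each cluster are concatenated. A cluster with fewer than `n_top` genes
#' contributes all of them, with a warning.
#'
#' @param stats a [gene_stats()] table for the C/T vs N/E contrast.
#' @param clustering a `gene_clustering`.
#' @param clusters integer vector (normally length 2) of cluster ids.
#' @param n_top genes to take per cluster (default 100).
#' @return character vector of gene ids.
#' @export
select_discriminant_genes <- function(stats, clustering, clusters,
                                      n_top = 100) {
  if (!all(clusters %in% seq_len(clustering$k))) {
    stop("unknown cluster id(s): ",
         paste(setdiff(clusters, seq_len(clustering$k)), collapse = ", "),
         call. = FALSE)
  }
  out <- character()
  for (j in clusters) {
    members <- names(clustering$assignment)[clustering$assignment == j]
    tab <- stats[stats$gene %in% members, c("gene", "t")]
    tab <- tab[order(-abs(tab$t), tab$gene), ]
    if (nrow(tab) < n_top) {
      warning("cluster ", j, " has only ", nrow(tab), " genes (< ", n_top,
              "); taking all", call. = FALSE)
    }
    out <- c(out, tab$gene[seq_len(min(n_top, nrow(tab)))])
  }
  out
}

#' Build the predictor model (mean C/T reference profile)
#'
#' The reference profile is, for each selected gene, the mean of the log2
#' median-centered values over the C and T samples (optionally restricted
#' to a training subset, enabling leave-one-out evaluation).
#'
#' @param norm `normalized_matrix`.
#' @param sheet [sample_sheet()].
#' @param genes gene ids in the model (from
#'   [select_discriminant_genes()]).
#' @param samples optional character vector restricting the samples used
#'   to build the reference (training set); defaults to all columns.
#' @param thresholds numeric length-2 `(lo, hi)` correlation thresholds of
#'   the abstention band, default c(-0.25, 0.25).
#' @return a `predictor_model` list: `gene_ids`, `reference`,
#'   `threshold_lo`, `threshold_hi`, `training_samples`.
#' @export
build_model <- function(norm, sheet, genes, samples = NULL,
                        thresholds = c(-0.25, 0.25)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  missing <- setdiff(genes, rownames(norm))
  if (length(missing) > 0) {
    stop("model genes absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples)) samples <- colnames(norm)
  grp <- .group_lookup(sheet, samples)
  ct <- samples[grp %in% c("C", "T")]
  if (length(ct) == 0) stop("no C or T samples to build a reference from",
                            call. = FALSE)
  reference <- rowMeans(unclass(norm)[genes, ct, drop = FALSE])
  structure(list(gene_ids = genes, reference = reference,
                 threshold_lo = thresholds[1], threshold_hi = thresholds[2],
                 training_samples = samples),
            class = "predictor_model")
}

#' Score samples against the reference profile and classify
#'
#' For every sample, the Pearson correlation r between its profile on the
#' model genes and the reference profile is computed
#' (pairwise-complete). Calls: r > hi -> tumor_like; r < lo ->
#' healthy_like; otherwise (the weak-correlation abstention band,
#' including r = NA from a zero-variance profile) -> unpredictable.
#'
#' @param model a `predictor_model`.
#' @param norm `normalized_matrix` containing all model genes.
#' @param samples optional subset of samples to score.
#' @return data frame: sample_id, r, call.
#' @export
score_and_classify <- function(model, norm, samples = NULL) {
  missing <- setdiff(model$gene_ids, rownames(norm))
  if (length(missing) > 0) {
    stop("model genes absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples)) samples <- colnames(norm)
  x <- unclass(norm)[model$gene_ids, samples, drop = FALSE]
  r <- vapply(seq_along(samples), function(i) {
    v <- x[, i]
    ok <- !is.na(v) & !is.na(model$reference)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(model$reference[ok]) == 0) {
      return(NA_real_)
    }
    cor(v[ok], model$reference[ok])
  }, numeric(1))
  call <- rep("unpredictable", length(r))
  call[!is.na(r) & r > model$threshold_hi] <- "tumor_like"
  call[!is.na(r) & r < model$threshold_lo] <- "healthy_like"
  data.frame(sample_id = samples, r = r,
             call = factor(call, levels = PREDICTION_LEVELS),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate predictions against the sample sheet
#'
#' Truth-positive samples are groups C and T; truth-negative are N and E.
#' Sensitivity = TP/(TP+FN) (true positive rate), specificity =
#' TN/(TN+FP) (true negative rate), and separation quality is a two-sided
#' Fisher exact test on the 2x2 table of truth vs tumor_like call.
#' Abstentions: with `policy = "count_as_error"` (default, conservative)
#' an unpredictable positive counts as FN and an unpredictable negative
#' as FP; with `policy = "exclude"` unpredictable samples are dropped
#' before the rates are computed.
#'
#' @param results a [score_and_classify()] data frame.
#' @param sheet [sample_sheet()] with the truth groups.
#' @param policy "count_as_error" or "exclude".
#' @return a `predictor_evaluation` list: `table` (2x2 counts),
#'   `sensitivity`, `specificity`, `fisher_p`, `n_unpredictable`,
#'   `policy`.
#' @export
evaluate_predictor <- function(results, sheet,
                               policy = c("count_as_error", "exclude")) {
  policy <- match.arg(policy)
  grp <- .group_lookup(sheet, results$sample_id)
  truth_pos <- grp %in% c("C", "T")
  call <- as.character(results$call)
  n_unpred <- sum(call == "unpredictable")
  keep <- rep(TRUE, length(call))
  if (policy == "exclude") keep <- call != "unpredictable"
  tp <- sum(keep & truth_pos & call == "tumor_like")
  fn <- sum(keep & truth_pos & call != "tumor_like")
  tn <- sum(keep & !truth_pos & call == "healthy_like")
  fp_abst <- if (policy == "count_as_error") {
    sum(!truth_pos & call == "unpredictable")
  } else 0
  fp <- sum(keep & !truth_pos & call == "tumor_like") + fp_abst
  tab <- matrix(c(tp, fn, fp, tn), nrow = 2, byrow = TRUE,
                dimnames = list(truth = c("C/T", "N/E"),
                                call = c("tumor_like", "not")))
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  fisher_p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
  structure(list(table = tab, sensitivity = sens, specificity = spec,
                 fisher_p = fisher_p, n_unpredictable = n_unpred,
                 policy = policy),
            class = "predictor_evaluation")
}

#' @export
print.predictor_evaluation <- function(x, ...) {
  cat("predictor evaluation (abstention policy:", x$policy, ")\n")
  print(x$table)
  cat(sprintf("sensitivity = %.3f  specificity = %.3f  Fisher p = %.3g  (%d unpredictable)\n",
              x$sensitivity, x$specificity, x$fisher_p, x$n_unpredictable))
  invisible(x)
}

#' Leave-one-out evaluation of the full predictor pipeline
#'
#' For every sample, the predictor is rebuilt from scratch on the
#' remaining samples — gene clustering, C/T-vs-N/E gene statistics,
#' source-cluster selection, top-gene selection and the mean C/T
#' reference — and the held-out sample is then scored and classified.
#' Preprocessing (LOWESS + median centering) is done once on the full
#' matrix: it is per-sample against a median reference and carries no
#' per-class information.
#'
#' @param norm `normalized_matrix`.
#' @param unlogged matching [expression_matrix()] (for gene statistics).
#' @param sheet [sample_sheet()].
#' @param k,runs,n_top,thresholds,max_iter predictor/k-means parameters.
#' @param seed integer; each held-out fit uses `seed + i` for its k-means
#'   restarts so the whole procedure is reproducible.
#' @param policy abstention policy passed to [evaluate_predictor()].
#' @return list with `results` (per-sample r and call) and `evaluation`
#'   (a `predictor_evaluation`).
#' @export
loo_evaluate <- function(norm, unlogged, sheet, k = 10, runs = 100,
                         n_top = 100, thresholds = c(-0.25, 0.25),
                         max_iter = 100, seed = 1,
                         policy = "count_as_error") {
  samples <- colnames(norm)
  res <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    train <- setdiff(samples, samples[i])
    norm_tr <- structure(unclass(norm)[, train, drop = FALSE],
                         class = class(norm))
    unl_tr <- structure(unclass(unlogged)[, train, drop = FALSE],
                        class = class(unlogged))
    clust <- kmeans_profiles(norm_tr, k = k, runs = runs,
                             seed = seed + i, max_iter = max_iter)
    stats <- gene_stats(norm_tr, unl_tr, sheet,
                        group_a = c("C", "T"), group_b = c("N", "E"))
    src <- select_predictor_clusters(clust, norm_tr, sheet)
    genes <- suppressWarnings(
      select_discriminant_genes(stats, clust, src, n_top = n_top))
    model <- build_model(norm_tr, sheet, genes, samples = train,
                         thresholds = thresholds)
    res[[i]] <- score_and_classify(model, norm, samples = samples[i])
  }
  results <- do.call(rbind, res)
  list(results = results,
       evaluation = evaluate_predictor(results, sheet, policy = policy))
}
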
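# Cross-dataset replication: after normalizing two expression datasets
# independently, intersect their genes and count tumor-vs-normal
# direction agreement, overall and restricted to genes significant in
# both datasets.

#' Sign concordance between two per-gene statistics tables
#'
#' Genes are matched by exact symbol. A gene is concordant when the sign
#' of its tumor-vs-normal effect agrees between datasets (a zero sign is
#' always discordant). The "significant" subset requires nominal
#' p < alpha in both datasets. Duplicate symbols within a table are
#' collapsed to the row with the largest |t| (logged via message).
#'
#' @param stats_a,stats_b [gene_stats()]-style tables with columns
#'   `gene`, `t` (direction = sign of the logged group-mean difference)
#'   and `p`.
#' @param alpha nominal significance level (default 0.05).
#' @return a `concordance_report` list: `n_common`, `n_concordant`,
#'   `n_significant_both`, `n_concordant_significant`, `genes` (per-gene
#'   rows: gene, sign_a, sign_b, p_a, p_b, concordant,
#'   significant_both).
#' @export
concordance <- function(stats_a, stats_b, alpha = 0.05) {
  a <- .collapse_dupes(stats_a, "A")
  b <- .collapse_dupes(stats_b, "B")
  common <- intersect(a$gene, b$gene)
  if (length(common) == 0) stop("no common genes", call. = FALSE)
  ia <- match(common, a$gene); ib <- match(common, b$gene)
  sign_a <- sign(a$t[ia]); sign_b <- sign(b$t[ib])
  conc <- !is.na(sign_a) & !is.na(sign_b) & sign_a == sign_b & sign_a != 0
  sig <- !is.na(a$p[ia]) & !is.na(b$p[ib]) & a$p[ia] < alpha & b$p[ib] < alpha
  genes <- data.frame(gene = common, sign_a = sign_a, sign_b = sign_b,
                      p_a = a$p[ia], p_b = b$p[ib],
                      concordant = conc, significant_both = sig,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(n_common = length(common),
                 n_concordant = sum(conc),
                 n_significant_both = sum(sig),
                 n_concordant_significant = sum(conc & sig),
                 alpha = alpha, genes = genes),
            class = "concordance_report")
}

.collapse_dupes <- function(stats, label) {
  need <- c("gene", "t", "p")
  if (!all(need %in% names(stats))) {
    stop("stats table ", label, " needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(stats$gene)) {
    message("dataset ", label, ": collapsing ",
            sum(duplicated(stats$gene)),
            " duplicate symbol row(s) to largest |t|")
    ord <- order(stats$gene, -abs(stats$t))
    stats <- stats[ord, ]
    stats <- stats[!duplicated(stats$gene), ]
  }
  stats
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: %d/%d genes with the same direction; %d/%d among genes significant in both (alpha = %g)\n",
    x$n_concordant, x$n_common, x$n_concordant_significant,
    x$n_significant_both, x$alpha))
  invisible(x)
}
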
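# Beta-value EWAS: per-sample QC against the expected bimodal (beta-
# distribution-shaped) methylome, per-probe pooled t-tests with Bonferroni,
# window-smoothed P-values over genomic probe order, methylation-state
# calling at the 0.2 / 0.6 thresholds, locus-level secondary analysis and
# Manhattan/volcano exports.

#' Per-sample methylome quality control
#'
#' A good methylome is bimodal: most probes are near 0 or near 1, so the
#' fraction of probes with intermediate beta (in the open interval
#' (0.25, 0.75)) is small. Samples whose intermediate fraction is >= the
#' threshold fail QC; failed tumor samples are excluded from the EWAS but
#' remain usable in the secondary locus-specific analysis.
#'
#' @param beta a [beta_matrix()] (>= 100 probes recommended).
#' @param threshold pass iff fraction_intermediate < threshold
#'   (default 0.35).
#' @return data frame: sample_id, fraction_intermediate, pass, threshold.
#' @export
qc_samples <- function(beta, threshold = 0.35) {
  b <- unclass(beta)
  frac <- colMeans(b > 0.25 & b < 0.75, na.rm = TRUE)
  data.frame(sample_id = colnames(b),
             fraction_intermediate = as.numeric(frac),
             pass = as.numeric(frac) < threshold,
             threshold = threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call the methylation state of a (mean) beta value
#'
#' beta < 0.2 is unmethylated; 0.2 <= beta <= 0.6 is hemimethylated (the
#' closed interval: the 0.2 boundary delimits unmethylated from
#' hemimethylated and the stated hemimethylated band is "between 0.2 and
#' 0.6"); beta > 0.6 is methylated.
#'
#' @param mean_beta numeric vector in \[0, 1\].
#' @return factor with levels unmethylated/hemimethylated/methylated.
#' @export
call_state <- function(mean_beta) {
  if (any(!is.na(mean_beta) & (mean_beta < 0 | mean_beta > 1))) {
    stop("mean beta outside [0,1]", call. = FALSE)
  }
  out <- rep(NA_character_, length(mean_beta))
  out[!is.na(mean_beta) & mean_beta < 0.2] <- "unmethylated"
  out[!is.na(mean_beta) & mean_beta >= 0.2 & mean_beta <= 0.6] <-
    "hemimethylated"
  out[!is.na(mean_beta) & mean_beta > 0.6] <- "methylated"
  factor(out, levels = METHYLATION_STATES)
}

#' Probe-wise EWAS between tumor and control arms
#'
#' For each probe, a two-sided pooled-variance Student t-test compares
#' beta values between the tumor and control samples (beta values
#' directly, not M-values). Bonferroni correction uses m = number of
#' probes tested. Delta beta = mean(tumor) - mean(control), and the
#' 0.2/0.6 state call is attached per arm. A probe with zero variance in
#' both arms and equal means gets t = 0, p = 1.
#'
#' @param beta [beta_matrix()] containing both arms.
#' @param tumor_ids,control_ids sample id vectors (>= 2 each).
#' @return an `ewas_result` data frame: probe_id, mean_beta_tumor,
#'   mean_beta_control, delta_beta, t_stat, p, p_bonferroni, p_smoothed
#'   (NA until [smooth_pvalues()]), state_tumor, state_control.
#' @export
ewas <- function(beta, tumor_ids, control_ids) {
  b <- unclass(beta)
  missing <- setdiff(c(tumor_ids, control_ids), colnames(b))
  if (length(missing) > 0) {
    stop("samples absent from beta matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(tumor_ids) < 2 || length(control_ids) < 2) {
    stop("each arm needs >= 2 samples", call. = FALSE)
  }
  tt <- .row_pooled_t(b[, tumor_ids, drop = FALSE],
                      b[, control_ids, drop = FALSE])
  m <- nrow(b)
  out <- data.frame(probe_id = rownames(b),
                    mean_beta_tumor = tt$m1,
                    mean_beta_control = tt$m2,
                    delta_beta = tt$m1 - tt$m2,
                    t_stat = tt$t,
                    p = tt$p,
                    p_bonferroni = pmin(1, tt$p * m),
                    p_smoothed = NA_real_,
                    state_tumor = call_state(tt$m1),
                    state_control = call_state(tt$m2),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Window-smoothed P-values over genomic probe order
#'
#' Probes are ordered by (chromosome, position) from the manifest; within
#' each chromosome the score -log10(p) is averaged over the probe-index
#' window \[i - radius, i + radius\] (truncated at chromosome ends) and
#' transformed back: p_smoothed = 10^(-mean score). Chromosomes are
#' processed independently. Probes without manifest coordinates get
#' p_smoothed = NA.
#'
#' @param results an [ewas()] result.
#' @param manifest a [probe_manifest()].
#' @param radius window radius in probes (default 3, i.e. up to a 7-probe
#'   window).
#' @return `results` with the `p_smoothed` column filled (original row
#'   order preserved).
#' @export
smooth_pvalues <- function(results, manifest, radius = 3) {
  stopifnot(radius >= 0)
  idx <- match(results$probe_id, manifest$probe_id)
  results$p_smoothed <- NA_real_
  mapped <- which(!is.na(idx))
  if (length(mapped) == 0) return(results)
  chrom <- manifest$chromosome[idx[mapped]]
  pos <- manifest$position[idx[mapped]]
  score <- -log10(results$p[mapped])
  sm <- rep(NA_real_, length(mapped))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ord <- sel[order(pos[sel])]
    s <- score[ord]
    n <- length(s)
    smoothed <- vapply(seq_len(n), function(i) {
      w <- max(1, i - radius):min(n, i + radius)
      mean(s[w])
    }, numeric(1))
    sm[ord] <- smoothed
  }
  results$p_smoothed[mapped] <- 10^(-sm)
  results
}

#' Locus-level secondary analysis of one CpG island
#'
#' Restricts the EWAS table to the probes of one island and summarizes
#' their states; optionally recomputes per-probe mean beta and state on
#' an extra beta matrix (e.g. the QC-failed tumor samples, which are
#' routed here instead of the EWAS). Verdict:
#' `concordant_hemimethylation` iff every probe is hemimethylated in
#' tumor and unmethylated in control; `null` if no probe is
#' hemimethylated in tumor; `mixed` otherwise.
#'
#' @param results an [ewas()] result (smoothed or not).
#' @param manifest a [probe_manifest()].
#' @param island_id island to analyze (e.g. "CpG:84").
#' @param extra_beta optional [beta_matrix()] of additional samples.
#' @return a `locus_summary` list: `island_id`, `probes` (per-probe
#'   rows, with `mean_beta_extra`/`state_extra` when `extra_beta` is
#'   given), `n_hemimethylated_tumor`, `verdict`.
#' @export
locus_analysis <- function(results, manifest, island_id, extra_beta = NULL) {
  probes <- manifest$probe_id[manifest$island_id == island_id]
  probes <- probes[probes %in% results$probe_id]
  if (length(probes) == 0) {
    stop("island '", island_id, "' has no probes in the results",
         call. = FALSE)
  }
  rows <- results[match(probes, results$probe_id), ]
  if (!is.null(extra_beta) && ncol(extra_beta) > 0) {
    eb <- unclass(extra_beta)
    present <- intersect(probes, rownames(eb))
    mb <- setNames(rep(NA_real_, length(probes)), probes)
    mb[present] <- rowMeans(eb[present, , drop = FALSE], na.rm = TRUE)
    rows$mean_beta_extra <- as.numeric(mb)
    rows$state_extra <- call_state(as.numeric(mb))
  }
  n_hemi <- sum(rows$state_tumor == "hemimethylated", na.rm = TRUE)
  verdict <- if (all(rows$state_tumor == "hemimethylated") &&
                 all(rows$state_control == "unmethylated")) {
    "concordant_hemimethylation"
  } else if (n_hemi == 0) "null" else "mixed"
  structure(list(island_id = island_id, probes = rows,
                 n_hemimethylated_tumor = n_hemi, verdict = verdict),
            class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat("locus", x$island_id, ":", nrow(x$probes), "probes,",
      x$n_hemimethylated_tumor, "hemimethylated in tumor ->", x$verdict,
      "\n")
  invisible(x)
}

#' Rank CpG islands by their minimum smoothed P-value
#'
#' Convenience for top-locus reporting: for every non-empty island id in
#' the manifest, the minimum p_smoothed over its probes.
#'
#' @param results a smoothed [ewas()] result.
#' @param manifest a [probe_manifest()].
#' @return data frame sorted ascending by `min_p_smoothed`.
#' @export
rank_loci <- function(results, manifest) {
  idx <- match(results$probe_id, manifest$probe_id)
  island <- manifest$island_id[idx]
  keep <- !is.na(island) & island != "" & !is.na(results$p_smoothed)
  if (!any(keep)) return(data.frame(island_id = character(),
                                    min_p_smoothed = numeric()))
  agg <- tapply(results$p_smoothed[keep], island[keep], min)
  out <- data.frame(island_id = names(agg), min_p_smoothed = as.numeric(agg),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$min_p_smoothed, out$island_id), , drop = FALSE]
}

#' Plot-ready Manhattan and volcano tables
#'
#' Manhattan: (chromosome, position, -log10 p_smoothed), genomically
#' sorted, rows with NA p_smoothed omitted. Volcano: (delta_beta,
#' -log10 p) for every probe, NA p_smoothed or not.
#'
#' @param results a smoothed [ewas()] result.
#' @param manifest a [probe_manifest()].
#' @return list with data frames `manhattan` and `volcano`.
#' @export
export_manhattan_volcano <- function(results, manifest) {
  idx <- match(results$probe_id, manifest$probe_id)
  man <- data.frame(probe_id = results$probe_id,
                    chromosome = manifest$chromosome[idx],
                    position = manifest$position[idx],
                    neglog10_p_smoothed = -log10(results$p_smoothed),
                    stringsAsFactors = FALSE, row.names = NULL)
  man <- man[!is.na(man$neglog10_p_smoothed) & !is.na(man$chromosome), ]
  man <- man[order(man$chromosome, man$position), , drop = FALSE]
  rownames(man) <- NULL
  vol <- data.frame(probe_id = results$probe_id,
                    delta_beta = results$delta_beta,
                    neglog10_p = -log10(results$p),
                    stringsAsFactors = FALSE, row.names = NULL)
  vol <- vol[order(vol$delta_beta), , drop = FALSE]
  rownames(vol) <- NULL
  list(manhattan = man, volcano = vol)
}
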
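# Synthetic data with planted truth. The expression generator emulates
# the cohort structure (four groups N/E/C/T, cluster-structured gene
# profiles, two named genes with planted tumor fold changes, per-sample
# intensity-dependent bias); the methylation generator emulates bimodal
# beta-value methylomes with two planted tumor-hemimethylated CpG
# islands and a set of QC-failing (flattened) tumor samples.

#' Expression simulation scenario
#'
#' Defaults mirror the study cohort: 13 N / 16 E / 13 C / 13 T samples
#' (three tumor-side samples of the 16 tumor patients are excluded from
#' transcriptomics) and ten profile archetypes of which four are
#' differential — up in C+T, down in C+T, up in T only, down in T only
#' (one log2 unit each) — and six are null. Two named genes carry planted
#' tumor-vs-normal fold changes on the unlogged group-mean scale:
#' CDX2 (FC 2.46, also elevated in a random half of C samples) and
#' CACNA1C (FC 1.52). Because noise is homoscedastic log-normal across
#' groups, planting log2(FC) on the log scale makes the expected ratio of
#' unlogged group means equal the target FC exactly.
#'
#' @param n_genes total genes (default 2000), split evenly over the
#'   archetypes.
#' @param n_per_group named integer vector for N, E, C, T.
#' @param archetypes 10 x 4 matrix of per-group log2 offsets
#'   (rows = archetypes, columns N/E/C/T).
#' @param noise_sd log2-scale residual sd (default 0.3).
#' @param baseline_log2_mean,baseline_log2_sd log-normal baseline
#'   intensity distribution (log2 mean 8, sd 1).
#' @param bias_amplitude per-sample intensity-dependent bias: each sample
#'   draws an amplitude in (-a, a) multiplying a sinusoid of the baseline
#'   log2 intensity (what LOWESS is there to remove); default 0.3.
#' @param planted_genes data frame with columns gene, fc_t (unlogged
#'   T/N fold change) and c_fraction (fraction of C samples carrying the
#'   full effect).
#' @return an `expression_scenario` list.
#' @export
expression_scenario <- function(n_genes = 2000,
                                n_per_group = c(N = 13, E = 16, C = 13, T = 13),
                                archetypes = default_archetypes(),
                                noise_sd = 0.3,
                                baseline_log2_mean = 8,
                                baseline_log2_sd = 1,
                                bias_amplitude = 0.3,
                                planted_genes = data.frame(
                                  gene = c("CDX2", "CACNA1C"),
                                  fc_t = c(2.46, 1.52),
                                  c_fraction = c(0.5, 0),
                                  stringsAsFactors = FALSE)) {
  stopifnot(all(GROUP_LEVELS %in% names(n_per_group)))
  if (any(n_per_group[GROUP_LEVELS] < 1)) {
    stop("every group needs at least one sample", call. = FALSE)
  }
  stopifnot(is.matrix(archetypes), ncol(archetypes) == 4,
            n_genes >= nrow(archetypes) + nrow(planted_genes),
            noise_sd >= 0, bias_amplitude >= 0)
  colnames(archetypes) <- GROUP_LEVELS
  structure(list(n_genes = n_genes,
                 n_per_group = n_per_group[GROUP_LEVELS],
                 archetypes = archetypes,
                 noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 bias_amplitude = bias_amplitude,
                 planted_genes = planted_genes),
            class = "expression_scenario")
}

#' Default archetype matrix (10 archetypes x 4 groups, log2 offsets)
#'
#' Archetype 1: up in C and T; 3: down in C and T; 4: up in T only;
#' 5: down in T only; the rest are null.
#' @export
default_archetypes <- function() {
  a <- matrix(0, nrow = 10, ncol = 4,
              dimnames = list(paste0("A", 1:10), GROUP_LEVELS))
  a[1, c("C", "T")] <- 1
  a[3, c("C", "T")] <- -1
  a[4, "T"] <- 1
  a[5, "T"] <- -1
  a
}

#' Generate a synthetic expression dataset with planted truth
#'
#' @param scenario an [expression_scenario()].
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return list: `expr` ([expression_matrix()] of raw intensities),
#'   `sheet` ([sample_sheet()]), `truth` (list with `genes` — gene,
#'   archetype, planted fc —, `elevated_c_samples` per planted gene, and
#'   `bias` per sample).
#' @export
generate_expression <- function(scenario = expression_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "expression_scenario"))
  set.seed(seed)
  npg <- scenario$n_per_group
  sample_id <- unlist(lapply(GROUP_LEVELS, function(g) {
    sprintf("%s%02d", g, seq_len(npg[[g]]))
  }))
  group <- rep(GROUP_LEVELS, times = npg)
  sheet <- sample_sheet(sample_id, group)

  n_arch <- nrow(scenario$archetypes)
  gene_id <- sprintf("G%04d", seq_len(scenario$n_genes))
  archetype <- rep(seq_len(n_arch), length.out = scenario$n_genes)
  archetype <- sort(archetype)

  # planted genes replace null-archetype genes (archetype 2 is null by
  # default) so they do not disturb the archetype block structure
  planted <- scenario$planted_genes
  null_arch <- which(rowSums(scenario$archetypes != 0) == 0)
  host <- if (length(null_arch) > 0) null_arch[1] else n_arch
  slots <- which(archetype == host)[seq_len(nrow(planted))]
  gene_id[slots] <- planted$gene

  mu <- rnorm(scenario$n_genes, scenario$baseline_log2_mean,
              scenario$baseline_log2_sd)
  amp <- runif(length(sample_id), -scenario$bias_amplitude,
               scenario$bias_amplitude)

  # per-gene, per-sample log2 signal
  eff <- scenario$archetypes[archetype, group, drop = FALSE]  # gene x sample
  elevated <- list()
  for (i in seq_len(nrow(planted))) {
    g <- slots[i]
    d <- log2(planted$fc_t[i])
    eff[g, group == "T"] <- d
    c_ids <- sample_id[group == "C"]
    n_up <- round(planted$c_fraction[i] * length(c_ids))
    up <- if (n_up > 0) sample(c_ids, n_up) else character()
    eff[g, match(up, sample_id)] <- d
    elevated[[planted$gene[i]]] <- up
  }

  bias <- outer(sin(mu), amp)  # intensity-dependent, per-sample amplitude
  noise <- matrix(rnorm(scenario$n_genes * length(sample_id),
                        sd = scenario$noise_sd),
                  nrow = scenario$n_genes)
  lx <- mu + eff + bias + noise
  values <- 2^lx
  dimnames(values) <- list(gene_id, sample_id)

  truth_genes <- data.frame(gene = gene_id, archetype = archetype,
                            stringsAsFactors = FALSE)
  truth_genes$planted_fc_t <- NA_real_
  truth_genes$planted_fc_t[slots] <- planted$fc_t
  list(expr = expression_matrix(values),
       sheet = sheet,
       truth = list(genes = truth_genes,
                    elevated_c_samples = elevated,
                    bias = data.frame(sample_id = sample_id, amplitude = amp,
                                      stringsAsFactors = FALSE)))
}

#' Methylation simulation scenario
#'
#' Defaults mirror the methylome arm of the study: 4 tumor samples with
#' good quality metrics (the EWAS arm), 7 tumor samples with flattened
#' beta distributions that fail QC (the secondary locus-specific arm)
#' and 72 external non-tumor control methylomes. The background
#' methylome is the usual bimodal mixture — each probe is either lowly
#' methylated, Beta(1, 10), or highly methylated, Beta(10, 1), in both
#' arms — and two planted CpG islands (6 probes for CpG:84 /
#' CACNA1C-AS1, 9 probes for CpG:41 / SLC26A10, both placed on chr12)
#' are hemimethylated in tumor (mean beta 0.4, sd 0.05) and unmethylated
#' in controls (mean 0.05, sd 0.02). Null islands of contiguous
#' background probes provide the locus-ranking null.
#'
#' @param n_probes total probes (default 20000).
#' @param n_tumor_good,n_tumor_bad,n_control arm sizes (4 / 7 / 72).
#' @param planted data frame: island_id, gene, n_probes, tumor_mean,
#'   tumor_sd, control_mean, control_sd.
#' @param low_shape,high_shape length-2 Beta shape pairs of the two
#'   background components.
#' @param bad_shape length-2 Beta shapes of QC-failing samples
#'   (default c(2, 2): intermediate fraction ~0.69).
#' @param n_null_islands,null_island_size null locus layout.
#' @param chromosomes chromosome names the probes are spread over.
#' @return a `methylation_scenario` list.
#' @export
methylation_scenario <- function(n_probes = 20000,
                                 n_tumor_good = 4, n_tumor_bad = 7,
                                 n_control = 72,
                                 planted = data.frame(
                                   island_id = c("CpG:84", "CpG:41"),
                                   gene = c("CACNA1C-AS1", "SLC26A10"),
                                   n_probes = c(6L, 9L),
                                   tumor_mean = 0.4, tumor_sd = 0.05,
                                   control_mean = 0.05, control_sd = 0.02,
                                   stringsAsFactors = FALSE),
                                 low_shape = c(1, 10),
                                 high_shape = c(10, 1),
                                 bad_shape = c(2, 2),
                                 n_null_islands = 100,
                                 null_island_size = 8,
                                 chromosomes = c("chr1", "chr2", "chr3",
                                                 "chr5", "chr8", "chr12")) {
  if (sum(planted$n_probes) + n_null_islands * null_island_size > n_probes) {
    stop("island layout exceeds the probe budget", call. = FALSE)
  }
  stopifnot(n_tumor_good >= 2, n_control >= 2, n_probes >= 100)
  structure(list(n_probes = n_probes, n_tumor_good = n_tumor_good,
                 n_tumor_bad = n_tumor_bad, n_control = n_control,
                 planted = planted, low_shape = low_shape,
                 high_shape = high_shape, bad_shape = bad_shape,
                 n_null_islands = n_null_islands,
                 null_island_size = null_island_size,
                 chromosomes = chromosomes),
            class = "methylation_scenario")
}

.beta_shapes <- function(mean, sd) {
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  if (k <= 0) stop("beta sd too large for the requested mean", call. = FALSE)
  c(mean * k, (1 - mean) * k)
}

#' Generate a synthetic methylation dataset with planted truth
#'
#' @param scenario a [methylation_scenario()].
#' @param seed integer seed.
#' @return list: `tumor` ([beta_matrix()] of good + QC-bad tumor
#'   samples), `control` ([beta_matrix()]), `manifest`
#'   ([probe_manifest()]), `truth` (list: `planted_probes` data frame,
#'   `bad_samples`, `good_samples`, `null_islands`).
#' @export
generate_methylation <- function(scenario = methylation_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "methylation_scenario"))
  set.seed(seed)
  n <- scenario$n_probes
  probe_id <- sprintf("cg%07d", seq_len(n))
  n_chr <- length(scenario$chromosomes)
  chr_of <- sort(rep(seq_len(n_chr), length.out = n))
  chromosome <- scenario$chromosomes[chr_of]
  position <- integer(n)
  for (ch in seq_len(n_chr)) {
    sel <- chr_of == ch
    position[sel] <- cumsum(sample(100:5000, sum(sel), replace = TRUE))
  }

  island_id <- rep("", n)
  gene <- rep("", n)

  # planted islands: contiguous probe runs on the last chromosome
  planted <- scenario$planted
  last_chr <- which(chr_of == n_chr)
  offset <- floor(length(last_chr) / (nrow(planted) + 1))
  planted_idx <- list()
  for (i in seq_len(nrow(planted))) {
    start <- last_chr[1] + i * offset
    idx <- start:(start + planted$n_probes[i] - 1)
    planted_idx[[planted$island_id[i]]] <- idx
    island_id[idx] <- planted$island_id[i]
    gene[idx] <- planted$gene[i]
  }

  # null islands: contiguous runs spread over the genome, avoiding the
  # planted runs
  taken <- unlist(planted_idx)
  sz <- scenario$null_island_size
  block <- floor(n / scenario$n_null_islands)
  for (i in seq_len(scenario$n_null_islands)) {
    lo <- (i - 1) * block + 1
    start <- lo + sample.int(max(1, block - sz), 1) - 1
    idx <- start:(start + sz - 1)
    if (any(idx %in% taken) ||
        length(unique(chr_of[idx])) > 1) next
    island_id[idx] <- sprintf("CpG:null%03d", i)
  }

  manifest <- probe_manifest(probe_id, chromosome, position, gene, island_id)

  good_ids <- sprintf("TG%02d", seq_len(scenario$n_tumor_good))
  bad_ids <- if (scenario$n_tumor_bad > 0) {
    sprintf("TB%02d", seq_len(scenario$n_tumor_bad))
  } else character()
  ctrl_ids <- sprintf("NC%02d", seq_len(scenario$n_control))

  component <- sample(c("low", "high"), n, replace = TRUE)
  sh <- list(low = scenario$low_shape, high = scenario$high_shape)

  draw_background <- function(ids) {
    m <- matrix(NA_real_, nrow = n, ncol = length(ids),
                dimnames = list(probe_id, ids))
    for (cmp in c("low", "high")) {
      sel <- component == cmp
      m[sel, ] <- rbeta(sum(sel) * length(ids), sh[[cmp]][1], sh[[cmp]][2])
    }
    m
  }

  tumor <- cbind(draw_background(good_ids),
                 if (length(bad_ids) > 0) {
                   matrix(rbeta(n * length(bad_ids), scenario$bad_shape[1],
                                scenario$bad_shape[2]),
                          nrow = n, dimnames = list(probe_id, bad_ids))
                 })
  control <- draw_background(ctrl_ids)

  # planted probes: hemimethylated in every tumor sample (good and bad:
  # the locus signal survives poor global quality), unmethylated in
  # controls
  for (i in seq_len(nrow(planted))) {
    idx <- planted_idx[[planted$island_id[i]]]
    ts <- .beta_shapes(planted$tumor_mean[i], planted$tumor_sd[i])
    cs <- .beta_shapes(planted$control_mean[i], planted$control_sd[i])
    tumor[idx, ] <- rbeta(length(idx) * ncol(tumor), ts[1], ts[2])
    control[idx, ] <- rbeta(length(idx) * ncol(control), cs[1], cs[2])
  }

  planted_probes <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
    data.frame(probe_id = probe_id[planted_idx[[planted$island_id[i]]]],
               island_id = planted$island_id[i],
               gene = planted$gene[i],
               tumor_mean = planted$tumor_mean[i],
               control_mean = planted$control_mean[i],
               stringsAsFactors = FALSE)
  }))
  list(tumor = beta_matrix(tumor),
       control = beta_matrix(control),
       manifest = manifest,
       truth = list(planted_probes = planted_probes,
                    good_samples = good_ids,
                    bad_samples = bad_ids,
                    null_islands = setdiff(unique(island_id),
                                           c("", planted$island_id))))
}
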
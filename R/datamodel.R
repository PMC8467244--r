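#' @useDynLib itacscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor fisher.test lowess median pt rbeta rbinom
#'   rlnorm rnorm runif sd setNames
#' @importFrom utils read.delim write.table
"_PACKAGE"

GROUP_LEVELS <- c("N", "E", "C", "T")
PREDICTION_LEVELS <- c("tumor_like", "healthy_like", "unpredictable")
METHYLATION_STATES <- c("unmethylated", "hemimethylated", "methylated")

#' Construct an expression matrix
#'
#' A gene x sample matrix of raw positive fluorescence intensities.
#' Gene and sample identifiers must be unique and every value must be
#' strictly positive (the raw scale precedes any log transform).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @return an `expression_matrix` (a validated numeric matrix).
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .check_ids(rownames(values), "gene")
  .check_ids(colnames(values), "sample")
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-positive intensity at gene '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, 1], bad[1, 2]]
    ), call. = FALSE)
  }
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' Construct a beta-value matrix
#'
#' A CpG-probe x sample matrix of methylation beta values. Each value is
#' the methylated fraction at a probe, so it must lie in \[0, 1\];
#' out-of-range values are rejected, never clipped.
#'
#' @param beta numeric matrix with probe rownames and sample colnames.
#' @return a `beta_matrix`.
#' @export
beta_matrix <- function(beta) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  .check_ids(rownames(beta), "probe")
  .check_ids(colnames(beta), "sample")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value outside [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      beta[bad[1, 1], bad[1, 2]]
    ), call. = FALSE)
  }
  structure(beta, class = c("beta_matrix", "matrix", "array"))
}

#' Construct a sample sheet
#'
#' Maps each sample to one of the four cohort groups:
#' N = normal unexposed mucosa, E = wood-dust-exposed mucosa without tumor,
#' C = contralateral (non-tumor) side of a tumor patient, T = tumor.
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character vector of group labels drawn from N/E/C/T.
#' @param quality_note optional free-text per-sample note.
#' @return a `sample_sheet` data frame.
#' @export
sample_sheet <- function(sample_id, group, quality_note = NA_character_) {
  .check_ids(sample_id, "sample")
  group <- as.character(group)
  if (!all(group %in% GROUP_LEVELS)) {
    stop("group labels must be one of ", paste(GROUP_LEVELS, collapse = "/"),
         call. = FALSE)
  }
  structure(
    data.frame(sample_id = as.character(sample_id),
               group = factor(group, levels = GROUP_LEVELS),
               quality_note = quality_note,
               stringsAsFactors = FALSE),
    class = c("sample_sheet", "data.frame")
  )
}

#' Construct a probe manifest
#'
#' Genomic annotation for CpG probes: chromosome, 1-based position, gene
#' symbol and CpG-island id (e.g. "CpG:84"). Probe ids must be unique;
#' (chromosome, position) define the genomic sort used by P-value smoothing.
#'
#' @param probe_id,chromosome,position,gene,island_id vectors of equal length.
#' @return a `probe_manifest` data frame.
#' @export
probe_manifest <- function(probe_id, chromosome, position, gene = "",
                           island_id = "") {
  .check_ids(probe_id, "probe")
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1)) {
    stop("positions must be 1-based positive integers", call. = FALSE)
  }
  structure(
    data.frame(probe_id = as.character(probe_id),
               chromosome = as.character(chromosome),
               position = position,
               gene = as.character(gene),
               island_id = as.character(island_id),
               stringsAsFactors = FALSE),
    class = c("probe_manifest", "data.frame")
  )
}

.check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(ids == "")) {
    stop(what, " ids must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated ", what, " id: ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---- tabular IO -------------------------------------------------------------
# Dialect: UTF-8, tab-separated, '.' decimal, no quoting, NA written as "NA",
# first header cell fixed to "id". Row/column order is preserved verbatim.

.read_tsv_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs an id column plus >=1 sample")
  if (names(df)[1] != "id") {
    stop("first header cell must be 'id', got '", names(df)[1], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

.write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read an expression matrix with its sample sheet
#'
#' @param path TSV of raw intensities; first column `id` (gene ids), one
#'   column per sample.
#' @param sheet_path TSV with columns `sample_id`, `group` and optional
#'   `quality_note`.
#' @return list with elements `expr` (an [expression_matrix()]) and
#'   `sheet` (a [sample_sheet()]). Every matrix sample must appear in the
#'   sheet; extra sheet rows are allowed and kept.
#' @export
read_expression <- function(path, sheet_path) {
  m <- .read_tsv_matrix(path)
  expr <- expression_matrix(m)
  sheet <- read_sample_sheet(sheet_path)
  missing <- setdiff(colnames(expr), sheet$sample_id)
  if (length(missing) > 0) {
    stop("samples absent from sheet: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(expr = expr, sheet = sheet)
}

#' Write an expression (or any gene x sample) matrix to canonical TSV
#' @param expr matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) .write_tsv_matrix(expr, path)

#' Read a sample sheet TSV
#' @param path TSV with `sample_id` and `group` columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  qn <- if ("quality_note" %in% names(df)) df$quality_note else NA_character_
  sample_sheet(df$sample_id, df$group, qn)
}

#' Write a sample sheet to TSV
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  out <- data.frame(sample_id = sheet$sample_id,
                    group = as.character(sheet$group),
                    quality_note = sheet$quality_note,
                    stringsAsFactors = FALSE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a beta-value matrix with its probe manifest
#'
#' Probes present in the beta matrix but absent from the manifest are not an
#' error: they are recorded in the `unmapped_probes` attribute and excluded
#' from position-dependent operations (P-value smoothing, locus analysis)
#' only.
#'
#' @param path TSV of beta values (`id` column = probe ids).
#' @param manifest_path TSV with columns probe_id, chromosome, position,
#'   gene, island_id.
#' @return list with `beta` ([beta_matrix()], carrying `unmapped_probes`)
#'   and `manifest` ([probe_manifest()]).
#' @export
read_beta <- function(path, manifest_path) {
  beta <- beta_matrix(.read_tsv_matrix(path))
  manifest <- read_probe_manifest(manifest_path)
  unmapped <- setdiff(rownames(beta), manifest$probe_id)
  if (length(unmapped) > 0) {
    warning(length(unmapped),
            " probe(s) absent from manifest; excluded from smoothing/locus",
            " analysis only", call. = FALSE)
  }
  attr(beta, "unmapped_probes") <- unmapped
  list(beta = beta, manifest = manifest)
}

#' Write a beta matrix to canonical TSV
#' @param beta a [beta_matrix()].
#' @param path output path.
#' @export
write_beta <- function(beta, path) .write_tsv_matrix(beta, path)

#' Read a probe manifest TSV
#' @param path TSV path.
#' @export
read_probe_manifest <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                   stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position", "gene", "island_id")
  if (!all(need %in% names(df))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  probe_manifest(df$probe_id, df$chromosome, df$position, df$gene,
                 df$island_id)
}

#' Write a probe manifest to TSV
#' @param manifest a [probe_manifest()].
#' @param path output path.
#' @export
write_probe_manifest <- function(manifest, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(as.data.frame(manifest), con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
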
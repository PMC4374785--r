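#' Read a GCT expression matrix (versions 1.2 and 1.3)
#'
#' GCT is the tab-delimited gene-by-sample matrix format used by landmark
#' profiling pipelines: a version line (`#1.2` or `#1.3`), a dimensions
#' line, a header, then one row per gene. Version 1.3 files may carry
#' additional row-metadata columns and column-metadata lines, which are
#' skipped; only the expression values, gene ids, gene descriptions and
#' sample ids are retained. Missing cells are an error — downstream
#' statistics assume a complete matrix.
#'
#' @param path GCT file path.
#' @return numeric matrix (genes x samples) with `rownames` = gene ids,
#'   `colnames` = sample ids and attribute `description` (per-gene
#'   description column, when present).
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GCT file ", path, " is truncated")
  version <- trimws(lines[1L])
  if (!version %in% c("#1.2", "#1.3")) {
    stop("unsupported GCT version line '", version, "' in ", path)
  }
  dims <- as.integer(strsplit(trimws(lines[2L]), "\t|[ ]+")[[1L]])
  n_genes <- dims[1L]; n_samples <- dims[2L]
  if (version == "#1.3" && length(dims) >= 4L) {
    n_rmeta <- dims[3L]; n_cmeta <- dims[4L]
  } else {
    n_rmeta <- 1L  # the Description column of 1.2
    n_cmeta <- 0L
  }
  header <- strsplit(lines[3L], "\t")[[1L]]
  sample_ids <- utils::tail(header, n_samples)
  data_start <- 4L + n_cmeta
  rows <- strsplit(lines[seq(data_start, length.out = n_genes)], "\t")
  ids <- vapply(rows, `[`, "", 1L)
  desc <- if (n_rmeta >= 1L) vapply(rows, `[`, "", 2L) else NULL
  vals <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(
      r[seq(n_rmeta + 2L, length.out = n_samples)]))
    v
  }, numeric(n_samples)))
  if (n_samples == 1L) vals <- matrix(vals, ncol = 1L)
  if (anyNA(vals)) {
    stop("GCT file ", path, " has missing or non-numeric expression cells")
  }
  dimnames(vals) <- list(ids, sample_ids)
  attr(vals, "description") <- desc
  vals
}

#' Write an expression matrix as GCT 1.2
#'
#' @param mat numeric matrix, genes x samples, with dimnames.
#' @param path output file path.
#' @param description optional per-gene description column; defaults to the
#'   matrix's `description` attribute, else the gene ids.
#' @return `path`, invisibly.
#' @export
write_gct <- function(mat, path, description = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (is.null(description)) description <- attr(mat, "description")
  if (is.null(description)) description <- rownames(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(mat)),
                   collapse = "\t"), con)
  body <- cbind(rownames(mat), description,
                format(mat, trim = TRUE, digits = 15))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's sorted values are replaced by the row-wise mean of all columns'
#' sorted values, then returned to the column's original order. After
#' normalization all columns share one sorted value vector and the
#' transformation is idempotent. Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat numeric matrix, genes x samples, at least 2 samples,
#'   positive intensities.
#' @return normalized matrix with dimnames preserved.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) {
    stop("quantile normalization needs at least 2 samples, got ", ncol(mat))
  }
  if (any(mat <= 0)) stop("expression intensities must be positive")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Treatment design for a profiling experiment
#'
#' @param sample sample (column) identifiers.
#' @param treatment treatment identifiers ("DMSO", compound names, ...).
#' @param is_vehicle logical; TRUE for vehicle-control samples.
#' @param timepoint optional stratification (e.g. "6h", "24h"); fold
#'   changes are always computed against vehicle samples of the same
#'   timepoint.
#' @param replicate optional replicate labels.
#' @return a `treatment_design` data frame.
#' @export
treatment_design <- function(sample, treatment, is_vehicle,
                             timepoint = NA_character_,
                             replicate = NA_integer_) {
  n <- length(sample)
  out <- data.frame(sample = as.character(sample),
                    treatment = as.character(treatment),
                    is_vehicle = as.logical(rep_len(is_vehicle, n)),
                    timepoint = as.character(rep_len(timepoint, n)),
                    replicate = rep_len(replicate, n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample)) stop("duplicate sample ids in design")
  class(out) <- c("treatment_design", "data.frame")
  out
}

#' Replicate-averaged log2 fold change versus matched vehicle
#'
#' For each non-vehicle condition (treatment, stratified by timepoint when
#' present), LFC per gene is the mean over replicates of log2 expression
#' minus the mean over the matched vehicle replicates of the same
#' timepoint. Vehicle samples compared against themselves give LFC zero by
#' construction, and multiplying the whole matrix by a positive constant
#' leaves every LFC unchanged.
#'
#' @param mat positive expression matrix, genes x samples (typically
#'   quantile-normalized first).
#' @param design a [treatment_design()] covering the matrix columns.
#' @return genes x conditions matrix of LFC values; condition labels are
#'   `treatment` or `treatment@timepoint`. A condition without a matched
#'   vehicle stratum is an error.
#' @export
lfc <- function(mat, design) {
  stopifnot(is.matrix(mat), inherits(design, "treatment_design"))
  if (any(mat <= 0)) stop("expression values must be positive for log2 LFC")
  missing <- setdiff(design$sample, colnames(mat))
  if (length(missing)) {
    stop("design sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  lm2 <- log2(mat[, design$sample, drop = FALSE])
  trt <- design[!design$is_vehicle, , drop = FALSE]
  if (nrow(trt) == 0L) stop("design has no treated samples")
  strata <- unique(trt[, c("treatment", "timepoint")])
  cond_label <- function(treatment, timepoint) {
    if (is.na(timepoint)) treatment else paste0(treatment, "@", timepoint)
  }
  labels <- unname(vapply(seq_len(nrow(strata)), function(i)
    cond_label(strata$treatment[i], strata$timepoint[i]), ""))
  out <- matrix(NA_real_, nrow(mat), nrow(strata),
                dimnames = list(rownames(mat), labels))
  for (i in seq_len(nrow(strata))) {
    tp <- strata$timepoint[i]
    same_tp <- if (is.na(tp)) is.na(design$timepoint) else
      !is.na(design$timepoint) & design$timepoint == tp
    t_samples <- design$sample[!design$is_vehicle & same_tp &
                                 design$treatment == strata$treatment[i]]
    v_samples <- design$sample[design$is_vehicle & same_tp]
    if (length(v_samples) == 0L) {
      stop("condition '", colnames(out)[i],
           "' has no matched vehicle samples")
    }
    out[, i] <- rowMeans(lm2[, t_samples, drop = FALSE]) -
      rowMeans(lm2[, v_samples, drop = FALSE])
  }
  out
}

#' Two-group marker selection by signal-to-noise ratio
#'
#' Ranks genes by the difference in response between two sample groups
#' (e.g. target-gene inducers versus inhibitors). The default statistic is
#' the signal-to-noise ratio `(mean_A - mean_B) / (sd_A + sd_B)`; a
#' Welch-style t statistic is available as an alternative. Each group SD is
#' floored at `max(0.2 |group mean|, 1e-8)` so near-constant genes cannot
#' blow up the ratio. Ranks run from the most A-skewed gene (rank 1) to
#' the most B-skewed; ties are broken by the raw mean difference, then by
#' gene label.
#'
#' @param mat numeric matrix, genes x samples (LFC values or log-scale
#'   expression).
#' @param group_a,group_b non-overlapping character vectors of column
#'   names; each group needs >= 2 samples for the dispersion terms.
#' @param method `"snr"` (default) or `"tlike"`.
#' @param n_perm optional number of sample-label permutations for an
#'   empirical two-sided p-value per gene (0 = none).
#' @return a `marker_scores` data frame in rank order: `gene`, `score`,
#'   `rank` (and `p_value` when `n_perm > 0`).
#' @export
marker_selection <- function(mat, group_a, group_b,
                             method = c("snr", "tlike"), n_perm = 0L) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), length(group_a) >= 1L, length(group_b) >= 1L)
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  }
  missing <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing)) {
    stop("group sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples for dispersion estimates")
  }
  score_fun <- function(cols_a, cols_b) {
    a <- mat[, cols_a, drop = FALSE]
    b <- mat[, cols_b, drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    sa <- apply(a, 1L, stats::sd); sb <- apply(b, 1L, stats::sd)
    if (method == "snr") {
      sa <- pmax(sa, 0.2 * abs(ma), 1e-8)
      sb <- pmax(sb, 0.2 * abs(mb), 1e-8)
      (ma - mb) / (sa + sb)
    } else {
      se <- sqrt(pmax(sa, 1e-8)^2 / ncol(a) + pmax(sb, 1e-8)^2 / ncol(b))
      (ma - mb) / se
    }
  }
  score <- score_fun(group_a, group_b)
  mean_diff <- rowMeans(mat[, group_a, drop = FALSE]) -
    rowMeans(mat[, group_b, drop = FALSE])
  genes <- rownames(mat)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(mat)))
  ord <- order(-score, -mean_diff, genes)
  out <- data.frame(gene = genes[ord], score = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (n_perm > 0L) {
    pool <- c(group_a, group_b)
    na <- length(group_a)
    exceed <- numeric(nrow(mat))
    obs <- abs(score)
    for (p in seq_len(n_perm)) {
      perm <- sample(pool)
      ps <- score_fun(perm[seq_len(na)], perm[-seq_len(na)])
      exceed <- exceed + (abs(ps) >= obs)
    }
    pv <- (exceed + 1) / (n_perm + 1)
    out$p_value <- pv[ord]
  }
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  class(out) <- c("marker_scores", "data.frame")
  out
}

#' Extreme-ranked marker genes from both tails
#'
#' @param scores a `marker_scores` data frame from [marker_selection()].
#' @param n_each_tail number of genes per tail; the canonical landmark
#'   heatmap uses 30 per tail (60 genes).
#' @return character vector: the `n_each_tail` highest-scoring genes
#'   followed by the `n_each_tail` lowest-scoring ones, in rank order.
#' @export
top_markers <- function(scores, n_each_tail) {
  stopifnot(inherits(scores, "marker_scores"), n_each_tail >= 0L)
  n <- nrow(scores)
  if (n_each_tail > n / 2) {
    stop("n_each_tail = ", n_each_tail, " exceeds half the gene count (",
         n, ")")
  }
  if (n_each_tail == 0L) return(character())
  scores <- scores[order(scores$rank), , drop = FALSE]
  c(scores$gene[seq_len(n_each_tail)],
    scores$gene[seq(n - n_each_tail + 1L, n)])
}
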
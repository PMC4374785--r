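#' Per-well delta-Ct between a target and a calibrator gene
#'
#' For each well carrying both genes, computes
#' `delta_ct = Ct_target - Ct_calibrator`. Because Ct is a log2-scale
#' quantity (one cycle = one doubling of template), delta-Ct is the log2
#' ratio of calibrator to target abundance; subtracting the calibrator
#' removes per-well differences in cell number and RNA recovery.
#'
#' @param ct_table a [ct_table()].
#' @param target_gene,calibrator_gene gene names; the calibrator is a
#'   housekeeping transcript (GAPDH or B2M in the screen this package
#'   models).
#' @param wells optional character vector restricting the computation to
#'   these wells (typically the output of [analyzable_wells()]).
#' @return a `delta_ct` data frame with columns `well`, `ct_target`,
#'   `ct_calibrator`, `delta_ct`, `censored_target`, `censored_calibrator`
#'   and attributes `plate_id`, `target_gene`, `calibrator_gene`. Wells
#'   missing either gene are omitted with a warning; an empty result is an
#'   error.
#' @export
delta_ct <- function(ct_table, target_gene, calibrator_gene, wells = NULL) {
  stopifnot(inherits(ct_table, "ct_table"),
            is.character(target_gene), is.character(calibrator_gene))
  if (identical(target_gene, calibrator_gene)) {
    stop("target and calibrator gene must differ")
  }
  tg <- ct_table[ct_table$gene == target_gene, , drop = FALSE]
  cg <- ct_table[ct_table$gene == calibrator_gene, , drop = FALSE]
  if (!is.null(wells)) {
    wells <- canonical_well(wells)
    tg <- tg[tg$well %in% wells, , drop = FALSE]
    cg <- cg[cg$well %in% wells, , drop = FALSE]
  }
  common <- intersect(tg$well, cg$well)
  if (length(common) == 0L) {
    stop("no well carries both '", target_gene, "' and '",
         calibrator_gene, "'")
  }
  only_one <- union(setdiff(tg$well, cg$well), setdiff(cg$well, tg$well))
  if (length(only_one)) {
    warning(length(only_one), " well(s) omitted: missing one of the two ",
            "genes (", paste(utils::head(sort(only_one), 5L),
                             collapse = ", "),
            if (length(only_one) > 5L) ", ..." else "", ")")
  }
  it <- match(common, tg$well)
  ic <- match(common, cg$well)
  out <- data.frame(
    well = common,
    ct_target = tg$ct[it],
    ct_calibrator = cg$ct[ic],
    delta_ct = tg$ct[it] - cg$ct[ic],
    censored_target = tg$censored[it],
    censored_calibrator = cg$censored[ic],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$well), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "plate_id") <- plate_id(ct_table)
  attr(out, "target_gene") <- target_gene
  attr(out, "calibrator_gene") <- calibrator_gene
  class(out) <- c("delta_ct", "data.frame")
  out
}

#' In-plate DMSO vehicle reference statistics
#'
#' Summarizes the vehicle null distribution of one plate: the mean and
#' sample standard deviation of delta-Ct over the DMSO wells (the screening
#' design places 32 per plate), and the mean and SD of the raw calibrator
#' Ct over the same wells. The delta-Ct statistics define the fold-change
#' reference and the Z-score null; the calibrator statistics back the
#' calibrator-Z quality gate.
#'
#' @param plate_map a [plate_map()] for the same plate.
#' @param delta_cts a [delta_ct()] result.
#' @return a `dmso_reference` list: `plate_id`, `target_gene`,
#'   `calibrator_gene`, `mean_delta_ct`, `sd_delta_ct`,
#'   `mean_calibrator_ct`, `sd_calibrator_ct`, `n_wells`. Fewer than 2
#'   usable vehicle wells is an error. A zero SD is retained here (it is
#'   the Z-score stage that requires a non-degenerate null).
#' @export
dmso_reference <- function(plate_map, delta_cts) {
  stopifnot(inherits(plate_map, "plate_map"), inherits(delta_cts, "delta_ct"))
  if (!identical(plate_id(plate_map), attr(delta_cts, "plate_id"))) {
    stop("plate id mismatch between plate map and delta-Ct table")
  }
  dmso_wells <- plate_map$well[plate_map$kind == "dmso"]
  d <- delta_cts[delta_cts$well %in% dmso_wells, , drop = FALSE]
  if (nrow(d) < 2L) {
    stop("need at least 2 DMSO wells with valid delta-Ct, found ", nrow(d))
  }
  ref <- list(
    plate_id = attr(delta_cts, "plate_id"),
    target_gene = attr(delta_cts, "target_gene"),
    calibrator_gene = attr(delta_cts, "calibrator_gene"),
    mean_delta_ct = mean(d$delta_ct),
    sd_delta_ct = stats::sd(d$delta_ct),
    mean_calibrator_ct = mean(d$ct_calibrator),
    sd_calibrator_ct = stats::sd(d$ct_calibrator),
    n_wells = nrow(d)
  )
  class(ref) <- "dmso_reference"
  ref
}

#' @export
print.dmso_reference <- function(x, ...) {
  cat(sprintf(
    "DMSO reference for plate %s (%s vs %s), n = %d wells\n", x$plate_id,
    x$target_gene, x$calibrator_gene, x$n_wells))
  cat(sprintf("  delta-Ct: mean %.4f, sd %.4f cycles\n",
              x$mean_delta_ct, x$sd_delta_ct))
  cat(sprintf("  calibrator Ct: mean %.4f, sd %.4f cycles\n",
              x$mean_calibrator_ct, x$sd_calibrator_ct))
  invisible(x)
}

#' Delta-delta-Ct and fold change against the vehicle reference
#'
#' Applies the Livak relative-quantification step: for each well,
#' `ddct = delta_ct - mean_delta_ct(DMSO)` and `fold = 2^-ddct`. Under this
#' sign convention upregulation of the target gives negative ddct and fold
#' above 1; the ddct of the vehicle wells averages exactly zero by
#' construction.
#'
#' @param delta_cts a [delta_ct()] result.
#' @param reference the matching [dmso_reference()]; plate and gene pair
#'   must agree.
#' @return a `relative_expression` data frame: the delta-Ct columns plus
#'   `ddct` and `fold`, with the gene pair and plate id as attributes.
#' @export
ddct_fold <- function(delta_cts, reference) {
  stopifnot(inherits(delta_cts, "delta_ct"),
            inherits(reference, "dmso_reference"))
  if (!identical(attr(delta_cts, "plate_id"), reference$plate_id)) {
    stop("reference is for plate '", reference$plate_id,
         "' but delta-Ct table is for plate '",
         attr(delta_cts, "plate_id"), "'")
  }
  if (!identical(attr(delta_cts, "target_gene"), reference$target_gene) ||
      !identical(attr(delta_cts, "calibrator_gene"),
                 reference$calibrator_gene)) {
    stop("gene pair mismatch: reference is ", reference$target_gene, "/",
         reference$calibrator_gene, ", wells are ",
         attr(delta_cts, "target_gene"), "/",
         attr(delta_cts, "calibrator_gene"))
  }
  out <- as.data.frame(delta_cts)
  out$ddct <- out$delta_ct - reference$mean_delta_ct
  out$fold <- 2^(-out$ddct)
  attr(out, "plate_id") <- attr(delta_cts, "plate_id")
  attr(out, "target_gene") <- reference$target_gene
  attr(out, "calibrator_gene") <- reference$calibrator_gene
  class(out) <- c("relative_expression", "data.frame")
  out
}
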
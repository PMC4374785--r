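#' Hit-calling thresholds
#'
#' The screen calls a compound well a hit when all three criteria hold,
#' with strict inequalities:
#' \itemize{
#'   \item fold change above `min_fold` (default 2: more than 2-fold
#'     target upregulation over the calibrator),
#'   \item ddCt Z-score below `max_ddct_z` (default -2: more than two
#'     vehicle SDs of target induction),
#'   \item calibrator Ct Z-score strictly inside
#'     `(-calibrator_z_bound, calibrator_z_bound)` (default 10: the
#'     housekeeping gene itself is not grossly perturbed).
#' }
#' Boundary values are non-hits.
#'
#' @param min_fold minimum fold change, > 1.
#' @param max_ddct_z ddCt Z-score cut, < 0.
#' @param calibrator_z_bound symmetric calibrator-Z gate half-width, > 0.
#' @return a `hit_thresholds` list.
#' @export
hit_thresholds <- function(min_fold = 2, max_ddct_z = -2,
                           calibrator_z_bound = 10) {
  stopifnot(is.numeric(min_fold), min_fold > 1,
            is.numeric(max_ddct_z), max_ddct_z < 0,
            is.numeric(calibrator_z_bound), calibrator_z_bound > 0)
  structure(list(min_fold = min_fold, max_ddct_z = max_ddct_z,
                 calibrator_z_bound = calibrator_z_bound),
            class = "hit_thresholds")
}

#' @export
print.hit_thresholds <- function(x, ...) {
  cat(sprintf(
    "Hit thresholds: fold > %g, ddCt Z < %g, |calibrator Z| < %g\n",
    x$min_fold, x$max_ddct_z, x$calibrator_z_bound))
  invisible(x)
}

#' Per-well ddCt Z-scores against the vehicle null
#'
#' `Z = ddct / sd_delta_ct(DMSO)`. Because ddct is delta-Ct minus the
#' vehicle mean, its SD equals the vehicle delta-Ct SD and its vehicle mean
#' is zero, so this is the usual (x - mean)/sd standardization against the
#' in-plate DMSO distribution.
#'
#' @param rel a `relative_expression` from [ddct_fold()].
#' @param reference the matching [dmso_reference()]; `sd_delta_ct` must be
#'   positive (a zero-variance vehicle set is a degenerate null).
#' @return numeric vector of Z-scores, named by well.
#' @export
ddct_zscores <- function(rel, reference) {
  stopifnot(inherits(rel, "relative_expression"),
            inherits(reference, "dmso_reference"))
  if (!isTRUE(reference$sd_delta_ct > 0)) {
    stop("degenerate vehicle null: DMSO delta-Ct SD is ",
         reference$sd_delta_ct, "; Z-scores are undefined")
  }
  stats::setNames(rel$ddct / reference$sd_delta_ct, rel$well)
}

#' Per-well calibrator-gene Ct Z-scores
#'
#' `Z = (Ct_calibrator - mean_calibrator_ct(DMSO)) / sd_calibrator_ct(DMSO)`.
#' Large |Z| flags wells where the housekeeping transcript itself moved
#' (toxicity, pipetting failure, off-target effects), which invalidates the
#' fold-change normalization.
#'
#' @param rel a `relative_expression` from [ddct_fold()] (carries each
#'   well's calibrator Ct).
#' @param reference the matching [dmso_reference()]; `sd_calibrator_ct`
#'   must be positive.
#' @return numeric vector of Z-scores, named by well.
#' @export
calibrator_ct_zscores <- function(rel, reference) {
  stopifnot(inherits(rel, "relative_expression"),
            inherits(reference, "dmso_reference"))
  if (!isTRUE(reference$sd_calibrator_ct > 0)) {
    stop("degenerate vehicle null: DMSO calibrator Ct SD is ",
         reference$sd_calibrator_ct, "; Z-scores are undefined")
  }
  stats::setNames(
    (rel$ct_calibrator - reference$mean_calibrator_ct) /
      reference$sd_calibrator_ct,
    rel$well)
}

#' Apply the triple hit criterion to one plate
#'
#' Combines fold change, ddCt Z and calibrator Z into per-well hit calls.
#' Hits are always called within a single plate against that plate's own
#' vehicle wells; plates are never pooled.
#'
#' @param rel a `relative_expression` from [ddct_fold()].
#' @param reference the matching [dmso_reference()].
#' @param plate_map the plate's [plate_map()], used to annotate compound id
#'   and concentration and to mark well kind.
#' @param thresholds a [hit_thresholds()].
#' @return a `hit_calls` data frame with one row per analyzed well:
#'   `plate_id`, `well`, `kind`, `compound_id`, `concentration_uM`, `fold`,
#'   `ddct_z`, `calibrator_ct_z`, `pass_fold`, `pass_z`, `pass_calibrator`,
#'   `is_hit` (the conjunction of the three pass flags).
#' @export
call_hits <- function(rel, reference, plate_map,
                      thresholds = hit_thresholds()) {
  stopifnot(inherits(rel, "relative_expression"),
            inherits(thresholds, "hit_thresholds"),
            inherits(plate_map, "plate_map"))
  if (!identical(attr(rel, "plate_id"), plate_id(plate_map))) {
    stop("plate id mismatch between expression table and plate map")
  }
  zd <- ddct_zscores(rel, reference)
  zc <- calibrator_ct_zscores(rel, reference)
  i <- match(rel$well, plate_map$well)
  if (anyNA(i)) {
    stop("well(s) absent from plate map: ",
         paste(rel$well[is.na(i)], collapse = ", "))
  }
  out <- data.frame(
    plate_id = attr(rel, "plate_id"),
    well = rel$well,
    kind = plate_map$kind[i],
    compound_id = plate_map$compound_id[i],
    concentration_uM = plate_map$concentration_uM[i],
    fold = rel$fold,
    ddct_z = as.numeric(zd),
    calibrator_ct_z = as.numeric(zc),
    stringsAsFactors = FALSE
  )
  out$pass_fold <- out$fold > thresholds$min_fold
  out$pass_z <- out$ddct_z < thresholds$max_ddct_z
  out$pass_calibrator <-
    out$calibrator_ct_z > -thresholds$calibrator_z_bound &
    out$calibrator_ct_z < thresholds$calibrator_z_bound
  out$is_hit <- out$pass_fold & out$pass_z & out$pass_calibrator
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' Reconcile duplicate-replicate hit calls across a campaign
#'
#' The screen plates each compound in duplicate at a single dose; this step
#' collapses per-plate, per-well hit calls into one campaign-level call per
#' compound. Under rule `"both"` (default, conservative) a compound is a
#' campaign hit only if every replicate well is a hit; under `"any"` one
#' hitting replicate suffices.
#'
#' @param hit_calls one `hit_calls` data frame or a list of them (one per
#'   plate); compound wells from all of them are pooled by `compound_id`.
#' @param rule `"both"` or `"any"`.
#' @return a `campaign_hits` data frame: `compound_id`, `n_replicates`,
#'   `n_hit_replicates`, `max_fold`, `min_ddct_z`, `campaign_hit`, with the
#'   rule as an attribute.
#' @export
reconcile_replicates <- function(hit_calls, rule = c("both", "any")) {
  rule <- match.arg(rule)
  if (inherits(hit_calls, "hit_calls")) hit_calls <- list(hit_calls)
  stopifnot(all(vapply(hit_calls, inherits, TRUE, "hit_calls")))
  all_calls <- do.call(rbind, lapply(hit_calls, as.data.frame))
  cw <- all_calls[all_calls$kind == "compound", , drop = FALSE]
  if (nrow(cw) == 0L) stop("no compound wells among the hit calls")
  sp <- split(cw, cw$compound_id)
  out <- data.frame(
    compound_id = names(sp),
    n_replicates = vapply(sp, nrow, 1L),
    n_hit_replicates = vapply(sp, function(d) sum(d$is_hit), 1L),
    max_fold = vapply(sp, function(d) max(d$fold), 1),
    min_ddct_z = vapply(sp, function(d) min(d$ddct_z), 1),
    stringsAsFactors = FALSE
  )
  out$campaign_hit <- if (rule == "both") {
    out$n_hit_replicates == out$n_replicates
  } else {
    out$n_hit_replicates >= 1L
  }
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  class(out) <- c("campaign_hits", "data.frame")
  out
}
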
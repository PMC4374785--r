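#' Run the full screening pipeline over a set of plates
#'
#' Chains the per-plate stages in order — validation, delta-Ct, vehicle
#' reference, ddCt/fold, Z-scores, hit calling — then reconciles duplicate
#' replicates into campaign-level calls. A plate that fails validation
#' aborts the run with a stage-named diagnostic.
#'
#' @param plates list of `list(plate_map, ct_table)` pairs (e.g. the
#'   `plates` element of [simulate_campaign()], or maps/tables read from
#'   CSV).
#' @param target_gene,calibrator_gene gene names.
#' @param thresholds a [hit_thresholds()].
#' @param replicate_rule `"both"` (default) or `"any"`; see
#'   [reconcile_replicates()].
#' @param min_dmso minimum vehicle wells per plate.
#' @param output_dir optional directory; when given, per-well hit calls
#'   (`hit_calls.csv`), campaign calls (`campaign_hits.csv`) and a JSON
#'   run manifest (`manifest.json`, with the configuration and MD5 digests
#'   of every output) are written there. Re-running with unchanged inputs
#'   and configuration reproduces the files byte-identically.
#' @return a `screen_result` list: `per_plate` (per plate: validation
#'   report, vehicle reference, hit calls), `hit_calls` (all plates,
#'   row-bound), `campaign` (campaign-level calls), `config`, and
#'   `manifest` (when `output_dir` is given).
#' @export
run_screen_pipeline <- function(plates, target_gene, calibrator_gene,
                                thresholds = hit_thresholds(),
                                replicate_rule = c("both", "any"),
                                min_dmso = 2L, output_dir = NULL) {
  replicate_rule <- match.arg(replicate_rule)
  stopifnot(is.list(plates), length(plates) >= 1L,
            inherits(thresholds, "hit_thresholds"))
  config <- list(
    target_gene = target_gene, calibrator_gene = calibrator_gene,
    min_fold = thresholds$min_fold, max_ddct_z = thresholds$max_ddct_z,
    calibrator_z_bound = thresholds$calibrator_z_bound,
    replicate_rule = replicate_rule, min_dmso = min_dmso,
    n_plates = length(plates)
  )

  per_plate <- lapply(plates, function(p) {
    pm <- p$plate_map; tab <- p$ct_table
    report <- validate_plate(pm, tab,
                             required_genes = c(target_gene,
                                                calibrator_gene),
                             min_dmso = min_dmso,
                             calibrator_gene = calibrator_gene)
    if (!report$ok) {
      stop("[validate] plate ", plate_id(pm), " rejected: ",
           paste(report$errors, collapse = "; "))
    }
    wells <- analyzable_wells(pm, report)
    dct <- delta_ct(tab, target_gene, calibrator_gene, wells = wells)
    ref <- dmso_reference(pm, dct)
    rel <- ddct_fold(dct, ref)
    hits <- call_hits(rel, ref, pm, thresholds)
    list(validation = report, reference = ref, hits = hits)
  })

  all_hits <- do.call(rbind, lapply(per_plate, function(x)
    as.data.frame(x$hits)))
  rownames(all_hits) <- NULL
  class(all_hits) <- c("hit_calls", "data.frame")
  campaign <- reconcile_replicates(lapply(per_plate, `[[`, "hits"),
                                   rule = replicate_rule)

  result <- list(per_plate = per_plate, hit_calls = all_hits,
                 campaign = campaign, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    hits_path <- file.path(output_dir, "hit_calls.csv")
    camp_path <- file.path(output_dir, "campaign_hits.csv")
    utils::write.csv(all_hits, hits_path, row.names = FALSE, na = "")
    utils::write.csv(as.data.frame(campaign), camp_path,
                     row.names = FALSE, na = "")
    manifest <- list(
      tool = "ctscreen",
      version = as.character(utils::packageVersion("ctscreen")),
      config = config,
      outputs = list(
        hit_calls = list(path = "hit_calls.csv",
                         md5 = unname(tools::md5sum(hits_path))),
        campaign_hits = list(path = "campaign_hits.csv",
                             md5 = unname(tools::md5sum(camp_path)))
      )
    )
    jsonlite::write_json(manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
  }
  class(result) <- "screen_result"
  result
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screening pipeline result:", x$config$n_plates, "plates,",
      nrow(x$campaign), "compounds,",
      sum(x$campaign$campaign_hit), "campaign hits (rule",
      attr(x$campaign, "rule"), ")\n")
  invisible(x)
}

#' Confirmation-stage analysis of hit compounds
#'
#' Fits a 4PL dose-response curve per compound/gene series, extracts EC50s
#' from converged fits, and summarizes each series as a minimal effective
#' concentration (or "IA [max fold]" when inactive). Hit compounds without
#' dose data produce a warning row rather than an abort.
#'
#' @param dose_data data frame with columns `compound_id`, `gene`,
#'   `dose` (or `dose_uM`), `fold`, and optionally `replicate`.
#' @param hit_compounds optional character vector of compound ids expected
#'   to be covered (e.g. campaign hits); ids without dose data are warned
#'   about and reported with NA fits.
#' @param threshold_fold MEC fold threshold (default 2).
#' @return a `confirmation_result` list: `fits` (named list of
#'   [fit_4pl()] objects keyed `compound/gene`), `ec50_table` (compound,
#'   gene, ec50, converged, ec50_in_range, rss) and `mec_table` (compound,
#'   gene, mec_uM, inactive, max_fold, formatted summary cell).
#' @export
run_confirmation <- function(dose_data, hit_compounds = NULL,
                             threshold_fold = 2) {
  if (!"dose" %in% names(dose_data) && "dose_uM" %in% names(dose_data)) {
    dose_data$dose <- dose_data$dose_uM
  }
  stopifnot(all(c("compound_id", "gene", "dose", "fold") %in%
                  names(dose_data)))
  if (!is.null(hit_compounds)) {
    uncovered <- setdiff(hit_compounds, dose_data$compound_id)
    if (length(uncovered)) {
      warning("no dose data for hit compound(s): ",
              paste(uncovered, collapse = ", "))
    }
  } else {
    uncovered <- character()
  }
  sp <- split(dose_data, interaction(dose_data$compound_id,
                                     dose_data$gene, drop = TRUE,
                                     sep = "/"))
  fits <- lapply(sp, fit_4pl)
  ec50_rows <- lapply(names(sp), function(key) {
    f <- fits[[key]]
    d <- sp[[key]]
    data.frame(
      compound_id = d$compound_id[1L], gene = d$gene[1L],
      ec50 = if (isTRUE(f$converged)) unname(f$coefficients["ec50"])
      else NA_real_,
      converged = f$converged, ec50_in_range = f$ec50_in_range,
      rss = f$rss, stringsAsFactors = FALSE)
  })
  mec_rows <- lapply(names(sp), function(key) {
    d <- sp[[key]]
    m <- minimal_effective_concentration(d, threshold_fold,
                                         compound_id = d$compound_id[1L],
                                         gene = d$gene[1L])
    data.frame(compound_id = m$compound_id, gene = m$gene,
               mec_uM = m$mec, inactive = m$inactive,
               max_fold = m$max_fold, summary = format_mec(m),
               stringsAsFactors = FALSE)
  })
  ec50_table <- do.call(rbind, ec50_rows)
  mec_table <- do.call(rbind, mec_rows)
  if (length(uncovered)) {
    ec50_table <- rbind(ec50_table, data.frame(
      compound_id = uncovered, gene = NA_character_, ec50 = NA_real_,
      converged = NA, ec50_in_range = NA, rss = NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(ec50_table) <- rownames(mec_table) <- NULL
  structure(list(fits = fits, ec50_table = ec50_table,
                 mec_table = mec_table,
                 threshold_fold = threshold_fold),
            class = "confirmation_result")
}

#' @export
print.confirmation_result <- function(x, ...) {
  cat("Confirmation analysis:", length(x$fits), "dose-response series\n")
  print(x$ec50_table)
  invisible(x)
}
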
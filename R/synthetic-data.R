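#' Noise model for simulated screening data
#'
#' Three noise magnitudes drive the simulators: `sigma_ct`, the well-level
#' Gaussian SD on each Ct measurement (cycles; applied independently per
#' gene and well, so the vehicle delta-Ct SD is `sqrt(2) * sigma_ct`);
#' `plate_shift_sd`, the SD of an additive per-plate, per-gene Ct offset
#' (cycles) emulating batch effects, to which the ddCt statistic is exactly
#' invariant; and `dr_cv`, the coefficient of variation of multiplicative
#' lognormal noise on dose-response fold values.
#'
#' @param sigma_ct well-level Ct SD in cycles (default 0.25).
#' @param plate_shift_sd per-plate, per-gene offset SD in cycles
#'   (default 0.5).
#' @param dr_cv lognormal CV for dose-response folds (default 0.10).
#' @return a `noise_model` list.
#' @export
noise_model <- function(sigma_ct = 0.25, plate_shift_sd = 0.5,
                        dr_cv = 0.10) {
  stopifnot(sigma_ct >= 0, plate_shift_sd >= 0, dr_cv >= 0)
  structure(list(sigma_ct = sigma_ct, plate_shift_sd = plate_shift_sd,
                 dr_cv = dr_cv), class = "noise_model")
}

# deterministic per-plate seed derived from the campaign seed; kept within
# 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 1009) %%
               .Machine$integer.max)
}

#' Simulate a screening campaign with known ground truth
#'
#' Generates duplicate 384-well Ct plates emulating a single-dose qRT-PCR
#' screen: each plate carries `n_dmso` DMSO vehicle wells (the screen
#' design uses 32) and one compound per remaining well at the screening
#' dose (12 uM in the modeled campaign). A fraction of compounds is active:
#' an active's target-gene Ct is shifted by `-log2(fold)` where the fold is
#' realized at the plated dose through the compound's own 4PL curve; the
#' calibrator gene is untouched unless an off-target shift is requested.
#' Every compound set is plated `n_replicates` times (duplicate plates with
#' identical layout), and the whole campaign is a pure function of its
#' parameters and `seed`.
#'
#' @param n_compound_sets number of distinct compound sets (each set fills
#'   one plate layout and is plated in duplicate).
#' @param active_fraction fraction of compounds that are active, in [0,1].
#' @param active_fold target fold induction of actives at the screening
#'   dose (scalar, or vector recycled over actives). Default 3.5, the
#'   average induction the modeled screen's lead compound produced.
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds reproduce the campaign
#'   byte-for-byte.
#' @param wells_per_plate,n_dmso plate design (defaults 384 and 32).
#' @param n_replicates plates per compound set (default 2, the screen's
#'   duplicate design).
#' @param screening_dose_uM single screening dose (default 12).
#' @param target_gene,calibrator_gene gene names (defaults TRIB1 / GAPDH).
#' @param baseline_ct named numeric: baseline Ct of target and calibrator
#'   (defaults 24 and 18 cycles).
#' @param ec50_uM,hill 4PL parameters given to every active compound; the
#'   top asymptote is solved so the curve passes through `active_fold` at
#'   the screening dose.
#' @param calibrator_shift_ct off-target additive shift (cycles) applied to
#'   the calibrator Ct in active-compound wells; default 0. Positive values
#'   exercise the calibrator-Z quality gate.
#' @param max_cycles censoring ceiling for the generated Ct tables.
#' @return a `screen_simulation` list: `plates` (list of
#'   `list(plate_map, ct_table)`), and `truth` (a `simulation_truth` list
#'   with the design, the per-compound effect table and all parameters).
#' @export
simulate_campaign <- function(n_compound_sets = 1L,
                              active_fraction = 0,
                              active_fold = 3.5,
                              noise = noise_model(),
                              seed = 1L,
                              wells_per_plate = 384L,
                              n_dmso = 32L,
                              n_replicates = 2L,
                              screening_dose_uM = 12,
                              target_gene = "TRIB1",
                              calibrator_gene = "GAPDH",
                              baseline_ct = c(target = 24, calibrator = 18),
                              ec50_uM = 2.3, hill = 1.2,
                              calibrator_shift_ct = 0,
                              max_cycles = 55) {
  stopifnot(active_fraction >= 0, active_fraction <= 1,
            n_dmso >= 2L, n_dmso < wells_per_plate,
            inherits(noise, "noise_model"))
  n_compounds_per_set <- wells_per_plate - n_dmso
  n_compounds <- n_compound_sets * n_compounds_per_set

  set.seed(seed)
  n_active <- round(active_fraction * n_compounds)
  active <- rep(FALSE, n_compounds)
  if (n_active > 0L) active[sample.int(n_compounds, n_active)] <- TRUE
  fold_at_dose <- rep(1, n_compounds)
  fold_at_dose[active] <- rep_len(active_fold, n_active)
  # solve the 4PL top so the curve passes through fold_at_dose at the
  # screening dose (bottom fixed at 1)
  top <- 1 + (fold_at_dose - 1) * (1 + (ec50_uM / screening_dose_uM)^hill)
  compounds <- data.frame(
    compound_id = sprintf("CPD%05d", seq_len(n_compounds)),
    set = rep(seq_len(n_compound_sets), each = n_compounds_per_set),
    active = active,
    fold_at_dose = fold_at_dose,
    bottom = 1, top = top, ec50_uM = ec50_uM, hill = hill,
    calibrator_shift_ct = ifelse(active, calibrator_shift_ct, 0),
    stringsAsFactors = FALSE
  )

  all_wells <- plate_wells()[seq_len(wells_per_plate)]
  layouts <- lapply(seq_len(n_compound_sets), function(s) {
    dmso_wells <- sort(sample(all_wells, n_dmso))
    kind <- ifelse(all_wells %in% dmso_wells, "dmso", "compound")
    cid <- rep(NA_character_, wells_per_plate)
    cid[kind == "compound"] <-
      compounds$compound_id[compounds$set == s]
    data.frame(well = all_wells, kind = kind, compound_id = cid,
               stringsAsFactors = FALSE)
  })

  plate_design <- expand.grid(replicate = seq_len(n_replicates),
                              set = seq_len(n_compound_sets))
  plate_design <- plate_design[order(plate_design$set,
                                     plate_design$replicate), ]
  plate_design$plate_index <- seq_len(nrow(plate_design))
  plate_design$plate_id <- sprintf("SIM-S%02dR%d", plate_design$set,
                                   plate_design$replicate)
  rownames(plate_design) <- NULL

  truth <- structure(list(
    seed = seed,
    target_gene = target_gene,
    calibrator_gene = calibrator_gene,
    baseline_ct = baseline_ct,
    screening_dose_uM = screening_dose_uM,
    n_dmso = n_dmso,
    wells_per_plate = wells_per_plate,
    max_cycles = max_cycles,
    noise = noise,
    compounds = compounds,
    layouts = layouts,
    plate_design = plate_design
  ), class = "simulation_truth")

  plates <- lapply(plate_design$plate_index, function(i) {
    simulate_ct_plate(truth, noise, plate_index = i,
                      seed = derive_seed(seed, i))
  })
  names(plates) <- plate_design$plate_id
  structure(list(plates = plates, truth = truth),
            class = "screen_simulation")
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat("Simulated screening campaign:", length(x$plates), "plates,",
      nrow(x$truth$compounds), "compounds (",
      sum(x$truth$compounds$active), "active ), seed", x$truth$seed, "\n")
  invisible(x)
}

#' Simulate one Ct plate from a campaign truth
#'
#' Target and calibrator Ct per well are
#' `baseline + plate shift + well noise`; compound wells of active
#' compounds additionally shift the target Ct by `-log2(fold)`, the fold
#' realized at the plated dose through the compound's 4PL. Generated Ct
#' values above `max_cycles` are censored at the ceiling.
#'
#' @param truth a `simulation_truth` (from [simulate_campaign()]).
#' @param noise a [noise_model()]; defaults to the truth's own.
#' @param plate_index row of the truth's plate design to generate.
#' @param seed integer seed for this plate's random draws.
#' @return `list(plate_map, ct_table)`.
#' @export
simulate_ct_plate <- function(truth, noise = NULL, plate_index = 1L,
                              seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(noise)) noise <- truth$noise
  pd <- truth$plate_design[truth$plate_design$plate_index == plate_index, ]
  if (nrow(pd) != 1L) stop("plate_index ", plate_index, " not in design")
  layout <- truth$layouts[[pd$set]]
  cmp <- truth$compounds

  pm <- plate_map(
    plate_id = pd$plate_id,
    well = layout$well,
    kind = layout$kind,
    compound_id = layout$compound_id,
    concentration_uM = ifelse(layout$kind == "compound",
                              truth$screening_dose_uM, NA_real_)
  )

  set.seed(seed)
  n <- nrow(layout)
  shift_t <- stats::rnorm(1L, 0, noise$plate_shift_sd)
  shift_c <- stats::rnorm(1L, 0, noise$plate_shift_sd)
  ct_t <- truth$baseline_ct[["target"]] + shift_t +
    stats::rnorm(n, 0, noise$sigma_ct)
  ct_c <- truth$baseline_ct[["calibrator"]] + shift_c +
    stats::rnorm(n, 0, noise$sigma_ct)

  is_cmpd <- layout$kind == "compound"
  i <- match(layout$compound_id[is_cmpd], cmp$compound_id)
  realized_fold <- cmp$bottom[i] + (cmp$top[i] - cmp$bottom[i]) /
    (1 + (cmp$ec50_uM[i] / truth$screening_dose_uM)^cmp$hill[i])
  ct_t[is_cmpd] <- ct_t[is_cmpd] - log2(realized_fold)
  ct_c[is_cmpd] <- ct_c[is_cmpd] + cmp$calibrator_shift_ct[i]

  clamp <- function(ct) {
    cens <- ct > truth$max_cycles
    ct[cens] <- truth$max_cycles
    ct <- pmax(ct, 1e-3)
    list(ct = ct, censored = cens)
  }
  t_cl <- clamp(ct_t); c_cl <- clamp(ct_c)

  tab <- ct_table(
    plate_id = pd$plate_id,
    well = rep(layout$well, 2L),
    gene = rep(c(truth$target_gene, truth$calibrator_gene), each = n),
    ct = c(t_cl$ct, c_cl$ct),
    censored = c(t_cl$censored, c_cl$censored),
    max_cycles = truth$max_cycles
  )
  list(plate_map = pm, ct_table = tab)
}

#' Simulate a dose-response dataset from known 4PL parameters
#'
#' Fold values are the 4PL curve evaluated at each dose, multiplied by
#' unit-mean lognormal noise with coefficient of variation `dr_cv`
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2/2`).
#'
#' @param params list or named vector with `bottom`, `top`, `ec50`, `hill`.
#' @param doses positive dose vector; default is the confirmation-assay
#'   design of 8 two-fold dilutions from 25 uM.
#' @param n_replicates replicates per dose (default 3).
#' @param dr_cv lognormal CV (default 0.10).
#' @param seed optional integer seed.
#' @param compound_id,gene optional labels.
#' @return data frame `compound_id`, `gene`, `dose`, `fold`, `replicate`,
#'   suitable for [fit_4pl()] and [minimal_effective_concentration()].
#' @export
simulate_dose_response <- function(params, doses = 25 / 2^(0:7),
                                   n_replicates = 3L, dr_cv = 0.10,
                                   seed = NULL,
                                   compound_id = NA_character_,
                                   gene = NA_character_) {
  params <- as.list(params)
  stopifnot(all(c("bottom", "top", "ec50", "hill") %in% names(params)),
            all(doses > 0), n_replicates >= 1L, dr_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  dose <- rep(doses, each = n_replicates)
  mu <- four_pl(dose, params$bottom, params$top, params$ec50, params$hill)
  mult <- if (dr_cv > 0) {
    sdlog <- sqrt(log(1 + dr_cv^2))
    stats::rlnorm(length(dose), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, length(dose))
  }
  data.frame(compound_id = compound_id, gene = gene, dose = dose,
             fold = mu * mult,
             replicate = rep(seq_len(n_replicates), length(doses)),
             stringsAsFactors = FALSE)
}

#' Simulate a two-group landmark expression profile
#'
#' Generates log-normal intensities for `n_genes` genes over a vehicle
#' condition plus one condition per treatment group, each in triplicate by
#' default. Marker genes named in `marker_spec` respond with the given
#' log2 fold change in their assigned group; all other gene/group effects
#' are zero. Per-gene baseline log2 levels are drawn once (N(7, 1)), and
#' every sample adds independent N(0, `noise_sd`) log2 noise.
#'
#' @param n_genes number of genes; gene ids are `G0001`, ...
#' @param groups character vector of treatment-group names (default
#'   `c("inducer", "inhibitor")`, mirroring an inducer-versus-inhibitor
#'   profiling contrast).
#' @param marker_spec data frame with columns `gene`, `group`, `lfc`
#'   assigning signed log2 effects; duplicate (gene, group) assignments
#'   are an error.
#' @param noise_sd log2-scale per-sample noise SD (default 0.25).
#' @param n_replicates samples per condition (default 3).
#' @param seed optional integer seed.
#' @return `list(matrix, design)`: positive intensity matrix (genes x
#'   samples) and the matching [treatment_design()] with a DMSO vehicle
#'   condition.
#' @export
simulate_profiles <- function(n_genes = 100L,
                              groups = c("inducer", "inhibitor"),
                              marker_spec = NULL,
                              noise_sd = 0.25, n_replicates = 3L,
                              seed = NULL) {
  stopifnot(n_genes >= 1L, length(groups) >= 1L, noise_sd >= 0,
            n_replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(marker_spec)) {
    stopifnot(all(c("gene", "group", "lfc") %in% names(marker_spec)))
    if (anyDuplicated(marker_spec[, c("gene", "group")])) {
      stop("contradictory marker assignments: duplicate (gene, group) rows")
    }
    if (!all(marker_spec$gene %in% genes)) {
      stop("marker_spec names unknown gene(s)")
    }
    if (!all(marker_spec$group %in% groups)) {
      stop("marker_spec names unknown group(s)")
    }
  }
  conditions <- c("DMSO", groups)
  samples <- as.vector(vapply(conditions, function(g)
    sprintf("%s_r%d", g, seq_len(n_replicates)),
    character(n_replicates)))
  design <- treatment_design(
    sample = samples,
    treatment = rep(conditions, each = n_replicates),
    is_vehicle = rep(conditions == "DMSO", each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(conditions))
  )
  baseline <- stats::rnorm(n_genes, 7, 1)
  effect <- matrix(0, n_genes, length(conditions),
                   dimnames = list(genes, conditions))
  if (!is.null(marker_spec)) {
    for (k in seq_len(nrow(marker_spec))) {
      effect[marker_spec$gene[k], marker_spec$group[k]] <-
        marker_spec$lfc[k]
    }
  }
  log2_vals <- baseline +
    effect[, rep(conditions, each = n_replicates), drop = FALSE] +
    matrix(stats::rnorm(n_genes * length(samples), 0, noise_sd),
           n_genes, length(samples))
  mat <- 2^log2_vals
  dimnames(mat) <- list(genes, samples)
  list(matrix = mat, design = design)
}

#' Evaluate campaign hit calls against simulation truth
#'
#' @param campaign_hits a `campaign_hits` data frame from
#'   [reconcile_replicates()].
#' @param truth the `simulation_truth` the campaign was generated from;
#'   hit compound ids absent from the truth are an error.
#' @param hit_calls optional `hit_calls` (or list of them) for per-plate
#'   hit counts.
#' @return a `screen_metrics` list: `n_actives`, `n_called`,
#'   `true_positives`, `false_positives`, `false_negatives`, `recall`
#'   (TP / actives; `NA` when the truth has no actives),
#'   `false_discovery_rate` (FP / max(1, called), so an empty call set has
#'   FDR 0), and `per_plate_hit_counts` when `hit_calls` is given.
#' @export
evaluate_screen <- function(campaign_hits, truth, hit_calls = NULL) {
  stopifnot(inherits(campaign_hits, "campaign_hits"),
            inherits(truth, "simulation_truth"))
  unknown <- setdiff(campaign_hits$compound_id, truth$compounds$compound_id)
  if (length(unknown)) {
    stop("hit compound id(s) absent from truth: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  actives <- truth$compounds$compound_id[truth$compounds$active]
  called <- campaign_hits$compound_id[campaign_hits$campaign_hit]
  tp <- length(intersect(called, actives))
  fp <- length(setdiff(called, actives))
  fn <- length(setdiff(actives, called))
  per_plate <- NULL
  if (!is.null(hit_calls)) {
    if (inherits(hit_calls, "hit_calls")) hit_calls <- list(hit_calls)
    per_plate <- vapply(hit_calls, function(h)
      sum(h$is_hit & h$kind == "compound"), 1L)
    names(per_plate) <- vapply(hit_calls, function(h) h$plate_id[1L], "")
  }
  structure(list(
    n_actives = length(actives),
    n_called = length(called),
    true_positives = tp,
    false_positives = fp,
    false_negatives = fn,
    recall = if (length(actives)) tp / length(actives) else NA_real_,
    false_discovery_rate = fp / max(1L, length(called)),
    per_plate_hit_counts = per_plate
  ), class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat(sprintf(
    "Screen evaluation: %d actives, %d called; recall %s, FDR %.4f\n",
    x$n_actives, x$n_called,
    ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall)),
    x$false_discovery_rate))
  invisible(x)
}
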
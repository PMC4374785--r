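#' Well addresses on a 384-well plate
#'
#' A 384-well plate has rows A--P and columns 1--24. The canonical string
#' form is the row letter followed by the zero-padded two-digit column
#' ("A01" .. "P24"); single-digit forms such as "A1" are accepted on input
#' and canonicalized.
#'
#' @param x character vector of well addresses (e.g. "A1", "B02", "p24").
#' @return `canonical_well()` returns the canonical zero-padded form;
#'   `well_row()` the row letter; `well_col()` the integer column.
#' @examples
#' canonical_well(c("A1", "b02", "P24"))
#' @export
canonical_well <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-P])([0-9]{1,2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(unique(x[bad]), collapse = ", "),
         " (expected row A-P followed by column 1-24)")
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1L | col > 24L)) {
    stop("well column out of range 1-24: ",
         paste(unique(x[col < 1L | col > 24L]), collapse = ", "))
  }
  sprintf("%s%02d", row, col)
}

#' @rdname canonical_well
#' @export
well_row <- function(x) substr(canonical_well(x), 1L, 1L)

#' @rdname canonical_well
#' @export
well_col <- function(x) as.integer(substr(canonical_well(x), 2L, 3L))

#' All well addresses of a 384-well plate
#'
#' @param n_rows,n_cols plate geometry; defaults give the standard
#'   16 x 24 = 384 layout.
#' @return character vector of canonical well addresses in row-major order.
#' @export
plate_wells <- function(n_rows = 16L, n_cols = 24L) {
  stopifnot(n_rows >= 1L, n_rows <= 16L, n_cols >= 1L, n_cols <= 24L)
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols),
                    function(r, c) sprintf("%s%02d", r, c))))
}

well_kinds <- c("dmso", "compound", "empty")

#' Construct a plate map
#'
#' A plate map assigns each populated well of a screening plate one of three
#' contents: DMSO vehicle control, a compound at a concentration, or empty.
#' The screening design this package targets places 32 DMSO wells on every
#' 384-well plate; `plate_map()` enforces only the weaker invariant of at
#' least two vehicle wells, which is the minimum for a vehicle null
#' distribution.
#'
#' @param plate_id scalar character plate identifier.
#' @param well character vector of well addresses (canonicalized).
#' @param kind one of "dmso", "compound", "empty" per well.
#' @param compound_id compound identifier; required for compound wells, must
#'   be absent (NA) otherwise.
#' @param concentration_uM dose in micromolar; required positive for compound
#'   wells, must be absent (NA) otherwise.
#' @return a `plate_map` data frame with columns `well`, `kind`,
#'   `compound_id`, `concentration_uM` and attribute `plate_id`.
#' @export
plate_map <- function(plate_id, well, kind, compound_id = NA_character_,
                      concentration_uM = NA_real_) {
  stopifnot(is.character(plate_id), length(plate_id) == 1L, nzchar(plate_id))
  well <- canonical_well(well)
  kind <- as.character(kind)
  n <- length(well)
  compound_id <- rep_len(as.character(compound_id), n)
  concentration_uM <- rep_len(as.numeric(concentration_uM), n)
  compound_id[!is.na(compound_id) & !nzchar(compound_id)] <- NA_character_

  if (anyDuplicated(well)) {
    stop("duplicate well addresses in plate map: ",
         paste(unique(well[duplicated(well)]), collapse = ", "))
  }
  if (!all(kind %in% well_kinds)) {
    stop("unknown well kind: ",
         paste(setdiff(unique(kind), well_kinds), collapse = ", "))
  }
  cmpd <- kind == "compound"
  if (any(cmpd & (is.na(compound_id) | is.na(concentration_uM)))) {
    stop("compound wells must carry compound_id and concentration_uM: ",
         paste(well[cmpd & (is.na(compound_id) | is.na(concentration_uM))],
               collapse = ", "))
  }
  if (any(cmpd & concentration_uM <= 0, na.rm = TRUE)) {
    stop("compound concentrations must be positive")
  }
  if (any(!cmpd & (!is.na(compound_id) | !is.na(concentration_uM)))) {
    stop("dmso/empty wells must not carry compound_id or concentration: ",
         paste(well[!cmpd & (!is.na(compound_id) | !is.na(concentration_uM))],
               collapse = ", "))
  }
  if (sum(kind == "dmso") < 2L) {
    stop("plate map needs at least 2 DMSO vehicle wells, found ",
         sum(kind == "dmso"))
  }
  out <- data.frame(well = well, kind = kind, compound_id = compound_id,
                    concentration_uM = concentration_uM,
                    stringsAsFactors = FALSE)
  attr(out, "plate_id") <- plate_id
  class(out) <- c("plate_map", "data.frame")
  out
}

#' @export
print.plate_map <- function(x, ...) {
  cat("Plate map:", plate_id(x), "-", nrow(x), "wells (",
      sum(x$kind == "dmso"), "DMSO,", sum(x$kind == "compound"),
      "compound,", sum(x$kind == "empty"), "empty )\n")
  invisible(x)
}

#' Plate identifier of a plate map or Ct table
#' @param x a `plate_map` or `ct_table` object.
#' @return scalar character.
#' @export
plate_id <- function(x) attr(x, "plate_id")

#' Read a plate map from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `well`, `kind`,
#' `compound_id`, `concentration_uM`. Malformed well addresses, compound rows
#' without a concentration, and duplicate wells are parse errors that name
#' the offending data row.
#'
#' @param path CSV file path.
#' @param plate_id plate identifier; defaults to the file name without
#'   extension (the map CSV itself carries no plate column).
#' @return a [plate_map()] object.
#' @export
read_plate_map <- function(path, plate_id = NULL) {
  if (is.null(plate_id)) {
    plate_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("well", "kind", "compound_id", "concentration_uM")
  if (!all(need %in% names(df))) {
    stop("plate map ", path, " must have header columns ",
         paste(need, collapse = ", "))
  }
  raw_well <- trimws(df$well)
  bad <- !grepl("^[A-Pa-p]([1-9]|0[1-9]|1[0-9]|2[0-4])$", raw_well)
  if (any(bad)) {
    stop("parse error in ", path, " row(s) ",
         paste(which(bad) + 1L, collapse = ", "),
         ": malformed well address ",
         paste(unique(raw_well[bad]), collapse = ", "))
  }
  well <- canonical_well(raw_well)
  if (anyDuplicated(well)) {
    dup_rows <- which(well %in% well[duplicated(well)])
    stop("parse error in ", path, ": duplicate well(s) ",
         paste(unique(well[duplicated(well)]), collapse = ", "),
         " at data row(s) ", paste(dup_rows + 1L, collapse = ", "))
  }
  conc <- suppressWarnings(as.numeric(df$concentration_uM))
  conc[!nzchar(trimws(df$concentration_uM))] <- NA_real_
  miss <- df$kind == "compound" & is.na(conc)
  if (any(miss)) {
    stop("parse error in ", path, " row(s) ",
         paste(which(miss) + 1L, collapse = ", "),
         ": compound well missing numeric concentration_uM")
  }
  plate_map(plate_id, well, df$kind, df$compound_id, conc)
}

#' Write a plate map to CSV
#'
#' Emits the canonical dialect read back by [read_plate_map()]: comma
#' separators, header, "." decimal, wells in canonical zero-padded form
#' sorted row-major. Writing then re-reading is the identity on the
#' canonicalized map.
#'
#' @param x a `plate_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(x, path) {
  stopifnot(inherits(x, "plate_map"))
  x <- x[order(x$well), , drop = FALSE]
  utils::write.csv(as.data.frame(x)[, c("well", "kind", "compound_id",
                                        "concentration_uM")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a Ct table
#'
#' Per-well, per-gene threshold-cycle (Ct) measurements from a qPCR run.
#' Reactions that never crossed the detection threshold ("Undetermined" in
#' thermocycler exports) are right-censored at `max_cycles` (default 55, the
#' cycle count of the screening protocol) rather than dropped, preserving
#' the direction of extreme expression losses.
#'
#' @param plate_id scalar plate identifier.
#' @param well,gene,ct parallel vectors; `ct` in cycles.
#' @param censored logical; TRUE where the reaction was undetermined. Such
#'   records must carry `ct = max_cycles`.
#' @param max_cycles censoring ceiling in cycles.
#' @return a `ct_table` data frame with columns `plate_id`, `well`, `gene`,
#'   `ct`, `censored` and attribute `max_cycles`.
#' @export
ct_table <- function(plate_id, well, gene, ct, censored = FALSE,
                     max_cycles = 55) {
  stopifnot(is.character(plate_id), length(unique(plate_id)) == 1L,
            max_cycles > 0)
  well <- canonical_well(well)
  gene <- as.character(gene)
  ct <- as.numeric(ct)
  n <- length(well)
  censored <- rep_len(as.logical(censored), n)
  plate <- plate_id[1L]
  if (any(is.na(ct))) stop("Ct values must be numeric (use censored = TRUE ",
                           "with ct = max_cycles for undetermined reactions)")
  if (any(ct <= 0 | ct > max_cycles)) {
    stop("Ct values must lie in (0, ", max_cycles, "]")
  }
  if (any(censored & ct != max_cycles)) {
    stop("censored records must carry ct = max_cycles")
  }
  key <- paste(well, gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (well, gene) records: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  out <- data.frame(plate_id = plate, well = well, gene = gene, ct = ct,
                    censored = censored, stringsAsFactors = FALSE)
  attr(out, "plate_id") <- plate
  attr(out, "max_cycles") <- max_cycles
  class(out) <- c("ct_table", "data.frame")
  out
}

#' @export
print.ct_table <- function(x, ...) {
  cat("Ct table:", plate_id(x), "-", nrow(x), "records,",
      length(unique(x$gene)), "gene(s),", length(unique(x$well)),
      "wells;", sum(x$censored), "censored (max", attr(x, "max_cycles"),
      "cycles)\n")
  invisible(x)
}

#' Read a Ct table from CSV
#'
#' Expects columns `plate_id`, `well`, `gene`, `ct`, where `ct` is either a
#' number in cycles or the token `Undetermined` (case-insensitive), which is
#' censored at `max_cycles`. Out-of-range Ct values, unknown tokens and
#' duplicate (well, gene) records are errors.
#'
#' @param path CSV file path.
#' @param max_cycles censoring ceiling in cycles (default 55).
#' @return a [ct_table()] object.
#' @export
read_ct_table <- function(path, max_cycles = 55) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("plate_id", "well", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table ", path, " must have header columns ",
         paste(need, collapse = ", "))
  }
  raw <- trimws(df$ct)
  undet <- tolower(raw) == "undetermined"
  ct <- suppressWarnings(as.numeric(raw))
  bad <- !undet & is.na(ct)
  if (any(bad)) {
    stop("parse error in ", path, " row(s) ",
         paste(which(bad) + 1L, collapse = ", "),
         ": Ct must be numeric or 'Undetermined', got ",
         paste(unique(raw[bad]), collapse = ", "))
  }
  ct[undet] <- max_cycles
  if (length(unique(df$plate_id)) > 1L) {
    stop("Ct table ", path, " mixes plate ids: ",
         paste(unique(df$plate_id), collapse = ", "))
  }
  ct_table(df$plate_id, df$well, df$gene, ct, censored = undet,
           max_cycles = max_cycles)
}

#' Write a Ct table to CSV
#'
#' Censored records are written back as the token `Undetermined`, so the
#' write/read cycle is the identity on canonicalized tables.
#'
#' @param x a `ct_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  x <- x[order(x$well, x$gene), , drop = FALSE]
  out <- data.frame(plate_id = x$plate_id, well = x$well, gene = x$gene,
                    ct = ifelse(x$censored, "Undetermined",
                                format(x$ct, trim = TRUE, digits = 15)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a plate before analysis
#'
#' Cross-checks a plate map against its Ct table. Plate-level problems
#' (too few vehicle wells; a required gene missing from every well) are
#' errors that reject the plate for downstream analysis. Well-level problems
#' produce warnings and put the well on the exclusion list: a populated well
#' missing a required gene's record, or a well whose calibrator-gene
#' reaction is censored (a failed calibrator invalidates normalization,
#' whereas a censored *target* is retained as a strong downregulation
#' signal).
#'
#' @param plate_map a [plate_map()].
#' @param ct_table a [ct_table()] from the same plate; mismatched plate ids
#'   are a hard error.
#' @param required_genes character vector of genes every populated well must
#'   carry (typically the target and the calibrator).
#' @param min_dmso minimum number of vehicle wells (default 2; the screen
#'   design uses 32).
#' @param calibrator_gene optional calibrator gene name; when given, wells
#'   with a censored calibrator reaction are excluded.
#' @return a `plate_validation` list with elements `plate_id`, `errors`,
#'   `warnings`, `wells_excluded` (data frame of well, reason) and `ok`
#'   (TRUE iff no errors).
#' @export
validate_plate <- function(plate_map, ct_table, required_genes,
                           min_dmso = 2L, calibrator_gene = NULL) {
  stopifnot(inherits(plate_map, "plate_map"), inherits(ct_table, "ct_table"))
  if (!identical(plate_id(plate_map), plate_id(ct_table))) {
    stop("plate id mismatch: map is '", plate_id(plate_map),
         "', Ct table is '", plate_id(ct_table), "'")
  }
  errors <- character()
  warnings <- character()
  excl_well <- character()
  excl_reason <- character()

  n_dmso <- sum(plate_map$kind == "dmso")
  if (n_dmso < min_dmso) {
    errors <- c(errors, sprintf(
      "insufficient vehicle wells: %d DMSO wells, need >= %d",
      n_dmso, min_dmso))
  }
  populated <- plate_map$well[plate_map$kind != "empty"]
  for (g in required_genes) {
    wells_with_g <- unique(ct_table$well[ct_table$gene == g])
    if (!any(populated %in% wells_with_g)) {
      errors <- c(errors, sprintf(
        "required gene '%s' absent from every populated well", g))
      next
    }
    missing <- setdiff(populated, wells_with_g)
    if (length(missing)) {
      warnings <- c(warnings, sprintf(
        "%d well(s) lack a record for required gene '%s'",
        length(missing), g))
      excl_well <- c(excl_well, missing)
      excl_reason <- c(excl_reason,
                       rep(sprintf("missing gene %s", g), length(missing)))
    }
  }
  if (!is.null(calibrator_gene)) {
    cens <- ct_table$well[ct_table$gene == calibrator_gene &
                            ct_table$censored]
    cens <- intersect(cens, populated)
    if (length(cens)) {
      warnings <- c(warnings, sprintf(
        "%d well(s) have a censored calibrator ('%s') reaction",
        length(cens), calibrator_gene))
      excl_well <- c(excl_well, cens)
      excl_reason <- c(excl_reason,
                       rep("censored calibrator", length(cens)))
    }
  }
  keep <- !duplicated(excl_well)
  report <- list(
    plate_id = plate_id(plate_map),
    errors = errors,
    warnings = warnings,
    wells_excluded = data.frame(well = excl_well[keep],
                                reason = excl_reason[keep],
                                stringsAsFactors = FALSE),
    ok = length(errors) == 0L
  )
  class(report) <- "plate_validation"
  report
}

#' @export
print.plate_validation <- function(x, ...) {
  cat("Validation of plate", x$plate_id, "-",
      if (x$ok) "OK" else "REJECTED", "\n")
  if (length(x$errors)) cat("  errors:  ",
                            paste(x$errors, collapse = "\n           "), "\n")
  if (length(x$warnings)) cat("  warnings:",
                              paste(x$warnings, collapse = "\n           "),
                              "\n")
  if (nrow(x$wells_excluded)) {
    cat("  excluded wells:", nrow(x$wells_excluded), "\n")
  }
  invisible(x)
}

#' Wells of a plate that survive validation
#'
#' @param plate_map a `plate_map`.
#' @param report a `plate_validation` from [validate_plate()].
#' @return character vector of populated, non-excluded well addresses.
#' @export
analyzable_wells <- function(plate_map, report) {
  stopifnot(inherits(report, "plate_validation"))
  if (!report$ok) {
    stop("plate ", report$plate_id, " was rejected by validation: ",
         paste(report$errors, collapse = "; "))
  }
  setdiff(plate_map$well[plate_map$kind != "empty"],
          report$wells_excluded$well)
}
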
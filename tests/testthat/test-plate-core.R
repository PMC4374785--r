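test_that("well addresses canonicalize, decompose and reject garbage", {
  expect_equal(canonical_well(c("A1", "b02", "P24")),
               c("A01", "B02", "P24"))
  expect_equal(canonical_well(canonical_well("p9")), "P09")  # round-trip
  expect_equal(well_row("c11"), "C")
  expect_equal(well_col("c11"), 11L)
  expect_error(canonical_well("Q01"), "malformed")
  expect_error(canonical_well("A25"), "malformed|out of range")
  expect_error(canonical_well("A0"), "malformed|out of range")
  expect_length(plate_wells(), 384L)
  expect_equal(plate_wells()[1:3], c("A01", "A02", "A03"))
  expect_false(anyDuplicated(plate_wells()) > 0)
})

test_that("plate map CSV parses compound, vehicle and error rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,kind,compound_id,concentration_uM",
               "A01,dmso,,",
               "A02,dmso,,",
               "B02,compound,BRD0418,12.0"), path)
  pm <- read_plate_map(path, plate_id = "P1")
  expect_s3_class(pm, "plate_map")
  b02 <- pm[pm$well == "B02", ]
  expect_equal(b02$kind, "compound")
  expect_equal(b02$compound_id, "BRD0418")
  expect_equal(b02$concentration_uM, 12)
  a01 <- pm[pm$well == "A01", ]
  expect_equal(a01$kind, "dmso")
  expect_true(is.na(a01$compound_id) && is.na(a01$concentration_uM))

  # duplicate wells are a parse error naming the duplicates
  writeLines(c("well,kind,compound_id,concentration_uM",
               paste0("A0", 1:5, ",dmso,,"),
               paste0("A0", 1:5, ",dmso,,")), path)
  expect_error(read_plate_map(path), "duplicate.*A01")

  # compound row without a concentration names its row
  writeLines(c("well,kind,compound_id,concentration_uM",
               "A01,dmso,,", "A02,dmso,,",
               "B01,compound,CPDX,"), path)
  expect_error(read_plate_map(path), "row\\(s\\) 4.*missing")
})

test_that("plate map writing then reading is the identity", {
  pl <- make_test_plate(rep(24, 8), rep(18, 8), n_dmso = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_map(pl$plate_map, path)
  back <- read_plate_map(path, plate_id = plate_id(pl$plate_map))
  expect_equal(as.data.frame(back), as.data.frame(pl$plate_map))
  # byte-identical on a rewrite of the canonicalized map
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_map(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("Ct table parsing censors Undetermined and rejects bad values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,well,gene,ct",
               "P1,A01,TRIB1,24.31",
               "P1,A02,TRIB1,Undetermined"), path)
  tab <- read_ct_table(path, max_cycles = 55)
  a01 <- tab[tab$well == "A01", ]
  expect_equal(a01$ct, 24.31)
  expect_false(a01$censored)
  a02 <- tab[tab$well == "A02", ]
  expect_equal(a02$ct, 55)
  expect_true(a02$censored)

  writeLines(c("plate_id,well,gene,ct", "P1,A01,TRIB1,not_a_number"), path)
  expect_error(read_ct_table(path), "numeric or 'Undetermined'")
  writeLines(c("plate_id,well,gene,ct", "P1,A01,TRIB1,60"), path)
  expect_error(read_ct_table(path), "\\(0, 55\\]")
  writeLines(c("plate_id,well,gene,ct", "P1,A01,TRIB1,-3"), path)
  expect_error(read_ct_table(path), "\\(0, 55\\]")
  writeLines(c("plate_id,well,gene,ct",
               "P1,A01,TRIB1,24", "P1,A01,TRIB1,25"), path)
  expect_error(read_ct_table(path), "duplicate")
})

test_that("a full 384-well x 2-gene Ct table round-trips through CSV", {
  set.seed(11)
  wells <- plate_wells()
  tab <- ct_table("P7", rep(wells, 2L),
                  rep(c("TRIB1", "GAPDH"), each = 384L),
                  round(c(rnorm(384, 24, 0.3), rnorm(384, 18, 0.3)), 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(tab, path)
  back <- read_ct_table(path)
  canon <- function(x) {
    d <- as.data.frame(x)
    d <- d[order(d$well, d$gene), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(canon(back), canon(tab))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("plate validation flags vehicle shortage, missing genes and censored calibrators", {
  pl <- make_test_plate(rnorm(40, 24, 0.2), rnorm(40, 18, 0.2),
                        n_dmso = 32)
  rep_ok <- validate_plate(pl$plate_map, pl$ct_table,
                           required_genes = c("TRIB1", "GAPDH"),
                           calibrator_gene = "GAPDH")
  expect_true(rep_ok$ok)
  expect_length(rep_ok$errors, 0)
  expect_length(rep_ok$warnings, 0)
  expect_equal(nrow(rep_ok$wells_excluded), 0)

  # 1 DMSO well with min_dmso = 2: plate_map() itself enforces >= 2, so
  # drive the check through min_dmso above the map's vehicle count
  rep_bad <- validate_plate(pl$plate_map, pl$ct_table,
                            required_genes = c("TRIB1", "GAPDH"),
                            min_dmso = 33)
  expect_false(rep_bad$ok)
  expect_match(rep_bad$errors, "insufficient vehicle wells", all = FALSE)

  # drop B07's GAPDH record: B07 is excluded, not the plate
  tab2 <- pl$ct_table[!(pl$ct_table$well == "B07" &
                          pl$ct_table$gene == "GAPDH"), ]
  attr(tab2, "plate_id") <- "P1"; attr(tab2, "max_cycles") <- 55
  class(tab2) <- c("ct_table", "data.frame")
  rep2 <- validate_plate(pl$plate_map, tab2, c("TRIB1", "GAPDH"))
  expect_true(rep2$ok)
  expect_true("B07" %in% rep2$wells_excluded$well)

  # censored calibrator excludes the well when the calibrator is named
  tab3 <- pl$ct_table
  i <- which(tab3$well == "B03" & tab3$gene == "GAPDH")
  tab3$ct[i] <- 55; tab3$censored[i] <- TRUE
  rep3 <- validate_plate(pl$plate_map, tab3, c("TRIB1", "GAPDH"),
                         calibrator_gene = "GAPDH")
  expect_true("B03" %in% rep3$wells_excluded$well)
  expect_match(rep3$wells_excluded$reason[
    rep3$wells_excluded$well == "B03"], "censored calibrator")

  # required gene absent everywhere rejects the plate
  rep4 <- validate_plate(pl$plate_map, pl$ct_table,
                         required_genes = c("TRIB1", "B2M"))
  expect_false(rep4$ok)

  # mismatched plate ids are a hard error
  pl2 <- make_test_plate(rep(24, 5), rep(18, 5), 2, plate = "OTHER")
  expect_error(validate_plate(pl$plate_map, pl2$ct_table, "TRIB1"),
               "plate id mismatch")
})

test_that("excluded plus analyzable wells partition the populated wells", {
  pl <- make_test_plate(rnorm(96, 24, 0.2), rnorm(96, 18, 0.2),
                        n_dmso = 16)
  drop <- c("C07", "D01", "A05")
  tab <- pl$ct_table[!(pl$ct_table$well %in% drop &
                         pl$ct_table$gene == "TRIB1"), ]
  attr(tab, "plate_id") <- "P1"; attr(tab, "max_cycles") <- 55
  class(tab) <- c("ct_table", "data.frame")
  rep <- validate_plate(pl$plate_map, tab, c("TRIB1", "GAPDH"))
  analyzable <- analyzable_wells(pl$plate_map, rep)
  populated <- pl$plate_map$well[pl$plate_map$kind != "empty"]
  expect_equal(sort(c(analyzable, rep$wells_excluded$well)),
               sort(populated))
  expect_setequal(rep$wells_excluded$well, drop)
})
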
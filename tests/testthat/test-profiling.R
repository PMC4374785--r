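test_that("GCT 1.2 matrices round-trip through write and read", {
  set.seed(81)
  mat <- matrix(round(runif(12, 1, 100), 4), 4, 3,
                dimnames = list(sprintf("G%d", 1:4),
                                sprintf("S%d", 1:3)))
  path <- withr::local_tempfile(fileext = ".gct")
  write_gct(mat, path)
  back <- read_gct(path)
  expect_equal(back, mat, ignore_attr = TRUE)
  expect_equal(dimnames(back), dimnames(mat))
  expect_identical(readLines(path)[1], "#1.2")
})

test_that("the GCT reader tolerates the 1.3 dialect", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c(
    "#1.3",
    "2\t3\t2\t1",
    "id\tpr_analyte\tpr_bead\tS1\tS2\tS3",
    "group\tna\tna\tA\tA\tB",          # one column-metadata line
    "TRIB1\tx\ty\t5.5\t6.5\t7.5",
    "GAPDH\tx\ty\t1\t2\t3"), path)
  m <- read_gct(path)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(rownames(m), c("TRIB1", "GAPDH"))
  expect_equal(colnames(m), c("S1", "S2", "S3"))
  expect_equal(unname(m["GAPDH", ]), c(1, 2, 3))
})

test_that("quantile normalization has its defining properties", {
  # identical columns are a fixed point
  m_id <- matrix(rep(c(1, 5, 9), 3), 3, 3,
                 dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_equal(quantile_normalize(m_id), m_id)

  # all columns share one sorted value vector afterwards
  set.seed(82)
  m <- matrix(rexp(60, 0.1) + 0.1, 12, 5,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:5)))
  qn <- quantile_normalize(m)
  sorted_cols <- apply(qn, 2L, sort)
  for (j in 2:5) expect_equal(sorted_cols[, j], sorted_cols[, 1])
  # column means equalize and ranks within columns are preserved
  expect_equal(colMeans(qn), colMeans(qn)[c(1, 1, 1, 1, 1)],
               ignore_attr = TRUE)
  for (j in 1:5) expect_equal(order(qn[, j]), order(m[, j]))
  # idempotence
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  # 3x3 against the hand sort/average/unsort oracle
  m3 <- matrix(c(2, 7, 1, 9, 3, 5, 4, 8, 6), 3, 3,
               dimnames = list(c("a", "b", "c"), c("X", "Y", "Z")))
  expect_equal(quantile_normalize(m3), oracle_quantile_normalize(m3))
  # larger distinct-valued matrix against the same oracle
  expect_equal(qn, oracle_quantile_normalize(m))
  expect_error(quantile_normalize(m[, 1, drop = FALSE]), "at least 2")
})

test_that("LFC is the replicate-mean log2 ratio against matched vehicle", {
  genes <- sprintf("g%d", 1:5)
  veh <- matrix(2^rnorm(15, 7), 5, 3)
  design <- treatment_design(
    sample = c(paste0("v", 1:3), paste0("t", 1:3)),
    treatment = rep(c("DMSO", "cpd"), each = 3),
    is_vehicle = rep(c(TRUE, FALSE), each = 3))
  # treated identical to vehicle: LFC 0
  m0 <- cbind(veh, veh)
  dimnames(m0) <- list(genes, design$sample)
  expect_equal(unname(lfc(m0, design)[, "cpd"]), rep(0, 5))
  # treated exactly 2x vehicle: LFC 1
  m1 <- cbind(veh, 2 * veh)
  dimnames(m1) <- list(genes, design$sample)
  expect_equal(unname(lfc(m1, design)[, "cpd"]), rep(1, 5))
  # scaling the whole matrix leaves LFC unchanged
  expect_equal(lfc(m1 * 37.5, design), lfc(m1, design))
})

test_that("LFC matches brute-force per-gene computation and strata match", {
  set.seed(83)
  n_genes <- 8
  design <- treatment_design(
    sample = sprintf("s%02d", 1:12),
    treatment = rep(c("DMSO", "cpd", "DMSO", "cpd"), each = 3),
    is_vehicle = rep(c(TRUE, FALSE, TRUE, FALSE), each = 3),
    timepoint = rep(c("6h", "6h", "24h", "24h"), each = 3))
  m <- matrix(2^rnorm(n_genes * 12, 7, 1), n_genes, 12,
              dimnames = list(sprintf("g%d", 1:n_genes), design$sample))
  res <- lfc(m, design)
  expect_equal(sort(colnames(res)), sort(c("cpd@6h", "cpd@24h")))
  for (g in seq_len(n_genes)) {
    expect_equal(res[g, "cpd@6h"],
                 mean(log2(m[g, 4:6])) - mean(log2(m[g, 1:3])),
                 ignore_attr = TRUE)
    expect_equal(res[g, "cpd@24h"],
                 mean(log2(m[g, 10:12])) - mean(log2(m[g, 7:9])),
                 ignore_attr = TRUE)
  }
  # a condition without matched vehicle is an error
  design2 <- design
  design2$is_vehicle[design2$timepoint == "24h"] <- FALSE
  expect_error(lfc(m, design2), "no matched vehicle")
})

test_that("marker scores equal the SNR oracle and are antisymmetric", {
  set.seed(84)
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10),
                              c(paste0("a", 1:3), paste0("b", 1:3))))
  ga <- paste0("a", 1:3); gb <- paste0("b", 1:3)
  sc <- marker_selection(m, ga, gb)
  oracle <- oracle_snr(m, ga, gb)
  expect_equal(sc$score, unname(oracle[sc$gene]))
  expect_equal(sc$rank, seq_len(10))
  expect_equal(order(sc$score, decreasing = TRUE), seq_len(10))
  # swapping the groups negates all scores and reverses the ranking
  sc_swap <- marker_selection(m, gb, ga)
  expect_equal(sc_swap$score[match(sc$gene, sc_swap$gene)], -sc$score)
  expect_equal(sc_swap$gene, rev(sc$gene))
  # identical values in both groups score zero
  m2 <- m; m2[3, ] <- 1.7
  sc2 <- marker_selection(m2, ga, gb)
  expect_equal(sc2$score[sc2$gene == "g03"], 0)
  # group order within a group does not matter
  sc3 <- marker_selection(m, rev(ga), sample(gb))
  expect_equal(sc3$score, sc$score)
  expect_error(marker_selection(m, ga, c("a1", "b1")), "overlap")
  expect_error(marker_selection(m, "a1", gb), "at least 2")
})

test_that("simulated opposite-sign markers occupy the extreme ranks", {
  # G0001 responds only in the inducer group, G0002 only in the
  # inhibitor group, so the inducer-vs-inhibitor contrast puts them at
  # opposite extremes
  spec <- data.frame(gene = c("G0001", "G0002"),
                     group = c("inducer", "inhibitor"),
                     lfc = c(3, 3))
  sim <- simulate_profiles(n_genes = 50, marker_spec = spec,
                           noise_sd = 0.2, seed = 85)
  qn <- quantile_normalize(sim$matrix)
  l <- lfc(qn, sim$design)
  # contrast the two groups on replicate-level log2 data
  ind <- sim$design$sample[sim$design$treatment == "inducer"]
  inh <- sim$design$sample[sim$design$treatment == "inhibitor"]
  sc <- marker_selection(log2(qn), ind, inh)
  expect_equal(sc$gene[1], "G0001")          # strongest inducer-skewed
  expect_equal(sc$gene[nrow(sc)], "G0002")   # strongest inhibitor-skewed
  expect_equal(l["G0001", "inducer"], 3, tolerance = 0.5)
  expect_equal(l["G0002", "inhibitor"], 3, tolerance = 0.5)
})

test_that("top_markers slices both tails in rank order", {
  set.seed(86)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20),
                              c(paste0("a", 1:3), paste0("b", 1:3))))
  sc <- marker_selection(m, paste0("a", 1:3), paste0("b", 1:3))
  tm <- top_markers(sc, 4)
  expect_length(tm, 8)
  ord <- sc$gene[order(sc$rank)]
  expect_equal(tm, c(head(ord, 4), tail(ord, 4)))
  expect_equal(top_markers(sc, 0), character())
  expect_error(top_markers(sc, 11), "exceeds half")
})
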
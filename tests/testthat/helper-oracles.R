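# Independent brute-force oracles, deliberately written with plain loops
# and closed forms so they share no code with the package internals.

# grid-search 4PL oracle: coarse grid over (log ec50, hill), analytic
# least-squares bottom/top per grid point (the model is linear in them)
oracle_4pl_grid <- function(data, n_ec50 = 80L, n_hill = 40L) {
  dmin <- min(data$dose); dmax <- max(data$dose)
  ec50_grid <- exp(seq(log(dmin / 10), log(dmax * 10), length.out = n_ec50))
  hill_grid <- seq(0.2, 5, length.out = n_hill)
  best <- list(rss = Inf)
  for (e in ec50_grid) {
    for (h in hill_grid) {
      w <- 1 / (1 + (e / data$dose)^h)
      X <- cbind(1 - w, w)
      cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, data$fold)),
                     error = function(err) NULL)
      if (is.null(cf)) next
      rss <- sum((data$fold - X %*% cf)^2)
      if (rss < best$rss) {
        best <- list(bottom = cf[1L], top = cf[2L], ec50 = e, hill = h,
                     rss = rss)
      }
    }
  }
  best
}

# per-well brute-force evaluation of the triple hit criterion from raw Ct
oracle_hits <- function(pm, tab, target, calibrator,
                        min_fold = 2, z_cut = -2, cal_bound = 10) {
  get_ct <- function(w, g) {
    v <- tab$ct[tab$well == w & tab$gene == g]
    if (length(v) == 1L) v else NA_real_
  }
  dmso <- pm$well[pm$kind == "dmso"]
  dmso_dct <- sapply(dmso, function(w)
    get_ct(w, target) - get_ct(w, calibrator))
  dmso_cal <- sapply(dmso, function(w) get_ct(w, calibrator))
  m_dct <- mean(dmso_dct); s_dct <- sd(dmso_dct)
  m_cal <- mean(dmso_cal); s_cal <- sd(dmso_cal)
  wells <- pm$well[pm$kind != "empty"]
  res <- data.frame(well = wells, is_hit = NA)
  for (k in seq_along(wells)) {
    w <- wells[k]
    dct <- get_ct(w, target) - get_ct(w, calibrator)
    ddct <- dct - m_dct
    fold <- 2^(-ddct)
    z <- ddct / s_dct
    zc <- (get_ct(w, calibrator) - m_cal) / s_cal
    res$is_hit[k] <- (fold > min_fold) && (z < z_cut) &&
      (zc > -cal_bound) && (zc < cal_bound)
  }
  res
}

# hand quantile normalization: sort each column, average across columns
# rank-wise, put back in original order
oracle_quantile_normalize <- function(mat) {
  sorted <- apply(mat, 2L, sort)
  target <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    out[order(mat[, j]), j] <- target
  }
  out
}

# loop-based signal-to-noise marker statistic with the package's SD floor
oracle_snr <- function(mat, group_a, group_b) {
  scores <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    a <- mat[g, group_a]; b <- mat[g, group_b]
    sa <- max(sd(a), 0.2 * abs(mean(a)), 1e-8)
    sb <- max(sd(b), 0.2 * abs(mean(b)), 1e-8)
    scores[g] <- (mean(a) - mean(b)) / (sa + sb)
  }
  names(scores) <- rownames(mat)
  scores
}

# small hand-built plate: n_dmso vehicle wells then compound wells, one
# compound per well at 12 uM, two genes with given Ct vectors
make_test_plate <- function(ct_target, ct_calibrator, n_dmso,
                            plate = "P1", target = "TRIB1",
                            calibrator = "GAPDH") {
  n <- length(ct_target)
  stopifnot(length(ct_calibrator) == n, n_dmso < n)
  wells <- plate_wells()[seq_len(n)]
  kind <- c(rep("dmso", n_dmso), rep("compound", n - n_dmso))
  cid <- c(rep(NA_character_, n_dmso),
           sprintf("C%03d", seq_len(n - n_dmso)))
  pm <- plate_map(plate, wells, kind, cid,
                  ifelse(kind == "compound", 12, NA_real_))
  tab <- ct_table(plate, rep(wells, 2L),
                  rep(c(target, calibrator), each = n),
                  c(ct_target, ct_calibrator))
  list(plate_map = pm, ct_table = tab)
}
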
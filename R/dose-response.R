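#' Four-parameter logistic dose-response function
#'
#' `fold = bottom + (top - bottom) / (1 + (ec50/dose)^hill)`, the Hill form
#' of the 4PL sigmoid on log-dose. With `hill > 0` the curve runs from
#' `bottom` at vanishing dose to `top` at saturating dose, crossing the
#' midpoint `(bottom + top)/2` exactly at `dose = ec50`. Induction curves
#' have `top > bottom`; inhibition curves are represented with
#' `top < bottom` rather than a negative Hill slope.
#'
#' @param dose dose vector, strictly positive (same unit as `ec50`).
#' @param bottom,top asymptotic responses (fold change here).
#' @param ec50 dose of half-maximal effect, > 0.
#' @param hill Hill slope, > 0.
#' @return numeric vector of responses.
#' @export
four_pl <- function(dose, bottom, top, ec50, hill) {
  stopifnot(all(dose > 0), ec50 > 0)
  bottom + (top - bottom) / (1 + (ec50 / dose)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit of fold change on dose by Levenberg-Marquardt
#' (via [minpack.lm::nlsLM]), the model Prism-style confirmation assays
#' use. EC50 is fitted on the log scale. Replicates enter the loss as
#' individual points; no pre-averaging.
#'
#' Initialization takes `bottom`/`top` from the mean response at the lowest
#' and highest dose, `ec50` at the geometric-mean dose and `hill = 1`, and
#' adds `n_restarts` jittered restarts (random EC50 and Hill perturbations,
#' drawn from the current RNG stream) to escape poor local optima; the best
#' residual sum of squares wins. Bounds keep
#' `ec50` in `[min_dose/100, max_dose * 100]` and `hill` in `[0.1, 10]`;
#' an EC50 fitted outside the tested dose range is flagged as extrapolated
#' (`ec50_in_range = FALSE`). Optimizer failure never raises: the fit is
#' returned with `converged = FALSE`. Response-less data (all folds equal)
#' yield a degenerate fit with `converged = FALSE` and `ec50 = NA`.
#'
#' @param data data frame with columns `dose` (or `dose_uM`) and `fold`;
#'   at least 4 distinct positive doses are required.
#' @param n_restarts number of jittered restarts on top of the default
#'   start (default 5).
#' @param ec50_bounds,hill_bounds optional length-2 numeric overrides of
#'   the parameter bounds.
#' @return a `fit_4pl` object: list with `coefficients` (named vector
#'   bottom, top, ec50, hill), `rss`, `converged`, `ec50_in_range`,
#'   `data`, `fitted.values`, `residuals`, `dose_range`, `n_points`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @seealso [ec50()], [minimal_effective_concentration()],
#'   [simulate_dose_response()]
#' @examples
#' d <- data.frame(dose = rep(25 / 2^(0:7), each = 3))
#' d$fold <- four_pl(d$dose, 1, 3.5, 2.3, 1.2)
#' fit <- fit_4pl(d)
#' coef(fit)
#' @export
fit_4pl <- function(data, n_restarts = 5L, ec50_bounds = NULL,
                    hill_bounds = c(0.1, 10)) {
  if (!"dose" %in% names(data) && "dose_uM" %in% names(data)) {
    data$dose <- data$dose_uM
  }
  stopifnot(is.data.frame(data), all(c("dose", "fold") %in% names(data)))
  data <- data[is.finite(data$dose) & is.finite(data$fold), , drop = FALSE]
  if (any(data$dose <= 0)) stop("doses must be strictly positive")
  doses <- sort(unique(data$dose))
  if (length(doses) < 4L) {
    stop("need at least 4 distinct doses to fit a 4PL, got ", length(doses))
  }
  dmin <- min(doses); dmax <- max(doses)
  if (is.null(ec50_bounds)) ec50_bounds <- c(dmin / 100, dmax * 100)

  out <- list(
    data = data.frame(dose = data$dose, fold = data$fold),
    dose_range = c(dmin, dmax),
    n_points = nrow(data)
  )

  if (diff(range(data$fold)) == 0) {
    # no response at any dose: EC50 is unidentifiable
    out$coefficients <- c(bottom = data$fold[1L], top = data$fold[1L],
                          ec50 = NA_real_, hill = NA_real_)
    out$rss <- 0
    out$converged <- FALSE
    out$ec50_in_range <- FALSE
    out$fitted.values <- data$fold
    out$residuals <- rep(0, nrow(data))
    class(out) <- "fit_4pl"
    return(out)
  }

  mean_low <- mean(data$fold[data$dose == dmin])
  mean_high <- mean(data$fold[data$dose == dmax])
  geo_mid <- exp(mean(log(doses)))
  lower <- c(bottom = -Inf, top = -Inf, lec50 = log(ec50_bounds[1L]),
             hill = hill_bounds[1L])
  upper <- c(bottom = Inf, top = Inf, lec50 = log(ec50_bounds[2L]),
             hill = hill_bounds[2L])

  starts <- list(c(bottom = mean_low, top = mean_high,
                   lec50 = log(geo_mid), hill = 1))
  for (k in seq_len(n_restarts)) {
    starts[[k + 1L]] <- c(
      bottom = mean_low,
      top = mean_high,
      lec50 = log(geo_mid) + stats::rnorm(1L, sd = 1),
      hill = exp(stats::runif(1L, log(0.3), log(3)))
    )
  }

  best <- NULL
  for (st in starts) {
    st["lec50"] <- min(max(st["lec50"], lower["lec50"]), upper["lec50"])
    st["hill"] <- min(max(st["hill"], lower["hill"]), upper["hill"])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fold ~ bottom + (top - bottom) / (1 + exp(hill * (lec50 - log(dose)))),
        data = data, start = as.list(st),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss,
                   converged = isTRUE(fit$convInfo$isConv))
    }
  }

  if (is.null(best)) {
    out$coefficients <- c(bottom = mean_low, top = mean_high,
                          ec50 = geo_mid, hill = 1)
    out$rss <- sum((data$fold - four_pl(data$dose, mean_low, mean_high,
                                        geo_mid, 1))^2)
    out$converged <- FALSE
  } else {
    cf <- stats::coef(best$fit)
    out$coefficients <- c(bottom = unname(cf["bottom"]),
                          top = unname(cf["top"]),
                          ec50 = exp(unname(cf["lec50"])),
                          hill = unname(cf["hill"]))
    out$rss <- best$rss
    out$converged <- best$converged
  }
  cf <- out$coefficients
  out$ec50_in_range <- is.finite(cf["ec50"]) &&
    cf["ec50"] >= dmin && cf["ec50"] <= dmax
  out$fitted.values <- four_pl(data$dose, cf["bottom"], cf["top"],
                               cf["ec50"], cf["hill"])
  out$residuals <- data$fold - out$fitted.values
  class(out) <- "fit_4pl"
  out
}

#' @export
print.fit_4pl <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("4PL dose-response fit (", x$n_points, " points, doses ",
      format(x$dose_range[1L], digits = digits), "-",
      format(x$dose_range[2L], digits = digits), ")\n", sep = "")
  cat(sprintf("  bottom %s  top %s  ec50 %s  hill %s\n",
              format(cf["bottom"], digits = digits),
              format(cf["top"], digits = digits),
              format(cf["ec50"], digits = digits),
              format(cf["hill"], digits = digits)))
  cat(sprintf("  rss %s  converged %s%s\n",
              format(x$rss, digits = digits), x$converged,
              if (!isTRUE(x$ec50_in_range)) "  [EC50 outside tested range]"
              else ""))
  invisible(x)
}

#' @export
coef.fit_4pl <- function(object, ...) object$coefficients

#' @export
fitted.fit_4pl <- function(object, ...) object$fitted.values

#' @export
residuals.fit_4pl <- function(object, ...) object$residuals

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) {
    object$data$dose
  } else if (is.data.frame(newdata)) {
    newdata$dose
  } else {
    as.numeric(newdata)
  }
  cf <- object$coefficients
  four_pl(dose, cf["bottom"], cf["top"], cf["ec50"], cf["hill"])
}

#' @export
summary.fit_4pl <- function(object, ...) {
  structure(list(fit = object,
                 sigma = sqrt(object$rss /
                                max(1L, object$n_points - 4L))),
            class = "summary.fit_4pl")
}

#' @export
print.summary.fit_4pl <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD %s on %d degrees of freedom\n",
              format(x$sigma, digits = 4), x$fit$n_points - 4L))
  invisible(x)
}

#' @export
plot.fit_4pl <- function(x, n_curve = 200L, xlab = "dose",
                         ylab = "fold change", ...) {
  graphics::plot(x$data$dose, x$data$fold, log = "x", xlab = xlab,
                 ylab = ylab, ...)
  dd <- exp(seq(log(x$dose_range[1L]), log(x$dose_range[2L]),
                length.out = n_curve))
  graphics::lines(dd, predict(x, dd))
  if (isTRUE(x$ec50_in_range)) {
    graphics::abline(v = x$coefficients["ec50"], lty = 3)
  }
  invisible(x)
}

#' EC50 of a converged 4PL fit
#'
#' @param fit a [fit_4pl()] object; a non-converged fit is an error.
#' @return the fitted EC50 (same unit as the doses). Warns when the EC50
#'   lies outside the tested dose range (extrapolated estimate).
#' @export
ec50 <- function(fit) {
  stopifnot(inherits(fit, "fit_4pl"))
  if (!isTRUE(fit$converged)) {
    stop("EC50 requested from a non-converged 4PL fit")
  }
  if (!isTRUE(fit$ec50_in_range)) {
    warning(sprintf(
      "EC50 %.4g lies outside the tested dose range [%.4g, %.4g]; extrapolated",
      fit$coefficients["ec50"], fit$dose_range[1L], fit$dose_range[2L]))
  }
  unname(fit$coefficients["ec50"])
}

#' Minimal effective concentration
#'
#' The lowest tested dose at which the replicate-averaged fold change
#' reaches `threshold_fold` (comparison is `>=`). When no dose reaches the
#' threshold the compound is reported inactive together with the maximal
#' mean fold observed — the bracketed value of the "IA [max]" summary
#' convention.
#'
#' @param data data frame with columns `dose` (or `dose_uM`) and `fold`;
#'   replicate folds are averaged per dose first.
#' @param threshold_fold fold threshold (default 2).
#' @param compound_id,gene optional labels carried into the result.
#' @return a `mec_result` list: `compound_id`, `gene`, `threshold_fold`,
#'   `mec` (dose, or `NA` if inactive), `inactive` flag, `max_fold`
#'   (maximal per-dose mean fold; reported in brackets when inactive).
#' @export
minimal_effective_concentration <- function(data, threshold_fold = 2,
                                            compound_id = NA_character_,
                                            gene = NA_character_) {
  if (!"dose" %in% names(data) && "dose_uM" %in% names(data)) {
    data$dose <- data$dose_uM
  }
  stopifnot(is.data.frame(data), all(c("dose", "fold") %in% names(data)),
            nrow(data) >= 1L, all(data$dose > 0), threshold_fold > 0)
  means <- tapply(data$fold, data$dose, mean)
  dose_levels <- as.numeric(names(means))
  ord <- order(dose_levels)
  dose_levels <- dose_levels[ord]
  means <- as.numeric(means)[ord]
  active <- means >= threshold_fold
  out <- list(
    compound_id = compound_id,
    gene = gene,
    threshold_fold = threshold_fold,
    mec = if (any(active)) dose_levels[which(active)[1L]] else NA_real_,
    inactive = !any(active),
    max_fold = max(means)
  )
  class(out) <- "mec_result"
  out
}

#' Format an MEC result in the "dose or IA [max]" convention
#'
#' @param x a `mec_result`.
#' @param digits significant digits.
#' @return scalar character: the MEC dose for active compounds, or
#'   `"IA [<max fold>]"` for inactive ones.
#' @export
format_mec <- function(x, digits = 2) {
  stopifnot(inherits(x, "mec_result"))
  if (x$inactive) {
    sprintf("IA [%s]", format(x$max_fold, digits = digits))
  } else {
    format(x$mec, digits = digits)
  }
}

#' @export
print.mec_result <- function(x, ...) {
  cat(sprintf(
    "MEC (fold >= %g) for %s / %s: %s\n", x$threshold_fold,
    ifelse(is.na(x$compound_id), "<compound>", x$compound_id),
    ifelse(is.na(x$gene), "<gene>", x$gene), format_mec(x)))
  invisible(x)
}
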
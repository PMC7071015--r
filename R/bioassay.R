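# Reporter-assay dose-response analysis: absorbance readings are normalised
# to percent inhibition between a negative control (full reporter response,
# 0% inhibition) and a 100%-inhibition anchor (neutralising-antibody positive
# control when present, otherwise the vehicle blank), and a four-parameter
# logistic is fitted to per-well points by Levenberg-Marquardt least squares.

#' Normalise plate absorbances to percent inhibition
#'
#' `%inhibition = 100 * (A_neg - A) / (A_neg - A_baseline)` where `A_neg` is
#' the negative-control mean (reporter fully activated) and the baseline is
#' the positive-control mean when positive-control wells exist, otherwise the
#' blank mean. The negative control maps exactly to 0% and the baseline to
#' 100%.
#'
#' @param readings Data frame with columns `compound`, `conc_uM`, `a620`,
#'   `role` (one of `sample`, `negative`, `positive`, `blank`).
#' @return Per-well data frame `compound`, `conc_uM`, `inhibition_pct` for the
#'   sample wells, with the anchors and a per-dose summary (mean, standard
#'   error, n) carried as attributes `anchors` and `summary`.
#' @export
normalize_inhibition <- function(readings) {
  need <- c("compound", "conc_uM", "a620", "role")
  miss <- setdiff(need, names(readings))
  if (length(miss) > 0) stop("readings lack column(s): ",
                             paste(miss, collapse = ", "))
  stopifnot(all(readings$conc_uM >= 0))
  neg <- readings$a620[readings$role == "negative"]
  if (length(neg) == 0) stop("no negative-control wells")
  pos <- readings$a620[readings$role == "positive"]
  blank <- readings$a620[readings$role == "blank"]
  baseline <- if (length(pos) > 0) mean(pos) else if (length(blank) > 0)
    mean(blank) else stop("no positive-control or blank wells for the 100% anchor")
  a_neg <- mean(neg)
  if (abs(a_neg - baseline) < 1e-9 * max(1, abs(a_neg))) {
    stop("zero dynamic range: negative control equals the baseline anchor")
  }
  if (a_neg <= baseline) stop("negative-control mean not above the baseline")
  smp <- readings[readings$role == "sample", , drop = FALSE]
  out <- data.frame(compound = smp$compound, conc_uM = smp$conc_uM,
                    inhibition_pct = 100 * (a_neg - smp$a620) /
                      (a_neg - baseline),
                    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(out, list(out$compound, out$conc_uM), drop = TRUE),
    function(g) data.frame(compound = g$compound[1], conc_uM = g$conc_uM[1],
                           mean_pct = mean(g$inhibition_pct),
                           se_pct = if (nrow(g) > 1)
                             sd(g$inhibition_pct) / sqrt(nrow(g)) else NA_real_,
                           n = nrow(g))))
  agg <- agg[order(agg$compound, agg$conc_uM), , drop = FALSE]
  rownames(agg) <- NULL
  attr(out, "anchors") <- c(a_negative = a_neg, a_baseline = baseline)
  attr(out, "summary") <- agg
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (ic50/x)^hill)`
#' to per-well percent-inhibition points, with `bottom` and `top` bounded in
#' [-20, 120] and the Hill slope unconstrained in sign. The IC50 is flagged
#' as extrapolated when it falls outside the tested concentration range.
#'
#' @param points Data frame with columns `conc_uM` (> 0) and
#'   `inhibition_pct`, e.g. from [normalize_inhibition()]; replicate wells
#'   enter individually.
#' @return A `dose_response_fit`: `bottom`, `top`, `ic50`, `hill`,
#'   per-parameter standard errors, `extrapolated`, `rss`, `fitted`.
#' @export
fit_4pl <- function(points) {
  stopifnot(all(c("conc_uM", "inhibition_pct") %in% names(points)))
  pts <- points[points$conc_uM > 0, , drop = FALSE]
  pts <- pts[order(pts$conc_uM, pts$inhibition_pct), , drop = FALSE]
  x <- pts$conc_uM
  y <- pts$inhibition_pct
  if (length(unique(x)) < 4) stop("need at least 4 distinct concentrations")
  if (diff(range(y)) < 1e-8) stop("flat data: all responses equal, no dose-response to fit")
  start <- list(bottom = max(-20, min(y)), top = min(120, max(y)),
                log_ic50 = mean(log(x)), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (exp(log_ic50) / x)^hill),
      start = start,
      lower = c(bottom = -20, top = -20, log_ic50 = log(min(x)) - 25,
                hill = -10),
      upper = c(bottom = 120, top = 120, log_ic50 = log(max(x)) + 25,
                hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("4PL fit failed to converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  ic50 <- exp(cf[["log_ic50"]])
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, 4))
  names(se) <- names(cf)
  # delta method for the IC50 standard error from the log-scale fit
  se_ic50 <- unname(ic50 * se["log_ic50"])
  structure(list(bottom = cf[["bottom"]], top = cf[["top"]], ic50 = ic50,
                 hill = cf[["hill"]],
                 se = c(bottom = unname(se["bottom"]), top = unname(se["top"]),
                        ic50 = se_ic50, hill = unname(se["hill"])),
                 extrapolated = ic50 < min(x) || ic50 > max(x),
                 rss = sum(resid(fit)^2),
                 fitted = data.frame(conc_uM = x, inhibition_pct = y,
                                     fit = stats::fitted(fit)),
                 dose_range = range(x)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: IC50 = %.4g uM%s, hill = %.3f, bottom = %.2f%%, top = %.2f%% (rss %.3g)\n",
    x$ic50, if (x$extrapolated) " (by extrapolation)" else "", x$hill,
    x$bottom, x$top, x$rss))
  invisible(x)
}
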
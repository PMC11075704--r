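# Windowed power-law growth kinetics of the cumulative bubble volume.
#
# The early cumulative growth is approximated by
#   V_C(t) = k (t - t_bo)^alpha  for t in [t_bo, t_bo + fit window],
# a rect-windowed power law. The growth exponent alpha discriminates the
# metastable state of the embedding liquid: highly degassed samples show a
# consistent alpha near 3, non-degassed samples a sample-dependent exponent.

#' Fit the windowed power-law growth model
#'
#' Fits `V_C(t) = k * (t - t_bo)^alpha` over the rect window
#' `(t_bo, t_bo + fit_duration]` (open at `t_bo` by one frame period, so the
#' logarithm is defined). Two methods:
#' * `"loglog"` (default): linear least squares of `log V_C` on
#'   `log (t - t_bo)` - robust under multiplicative measurement error;
#' * `"nls"`: nonlinear least squares on the linear scale
#'   (Levenberg-Marquardt), started from the log-log estimates; if it fails
#'   to converge the log-log fit is returned with a warning.
#'
#' `t_bo` is held fixed (onset first, then fit); set `cofit_onset = TRUE` to
#' additionally free `t_bo` in the nonlinear fit for sensitivity analysis.
#'
#' @param vs A [volume_series()] with `V_C_mm3` filled.
#' @param onset An `onset_estimate` or numeric onset time, s.
#' @param fit_duration Window length after onset, s (10 min).
#' @param method `"loglog"` or `"nls"`.
#' @param cofit_onset Free `t_bo` in the nonlinear fit.
#' @return Object of class `growth_fit`: `alpha`, `k`, `alpha_se`, `k_se`,
#'   `t_bo_used`, `window`, `n`, `residual_norm`, `method`.
#' @export
fit_power_law <- function(vs, onset, fit_duration = 600,
                          method = c("loglog", "nls"), cofit_onset = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(vs, "volume_series"))
  t_bo <- if (inherits(onset, "onset_estimate")) onset$t_bo else onset
  if (is.na(t_bo)) stop_bub("onset is required for the power-law fit")
  dt <- stats::median(diff(vs$time))
  inw <- vs$time > t_bo + dt / 2 & vs$time <= t_bo + fit_duration
  tabo <- vs$time[inw] - t_bo
  V <- vs$V_C_mm3[inw]
  pos <- V > 0
  if (sum(pos) < 20L)
    stop_bub("only %d positive samples in the fit window; at least 20 required",
             sum(pos))
  tabo <- tabo[pos]; V <- V[pos]

  ll <- stats::lm(log(V) ~ log(tabo))
  # exact data trips the "essentially perfect fit" notice; SEs are then ~0
  s <- suppressWarnings(summary(ll))$coefficients
  alpha <- unname(coef(ll)[2]); k <- exp(unname(coef(ll)[1]))
  alpha_se <- s[2, 2]; k_se <- k * s[1, 2]
  resid_norm <- sqrt(sum((k * tabo^alpha - V)^2))
  out <- list(alpha = alpha, k = k, alpha_se = alpha_se, k_se = k_se,
              t_bo_used = t_bo, window = c(t_bo + dt, t_bo + fit_duration),
              n = length(V), residual_norm = resid_norm, method = "loglog")

  if (method == "nls") {
    fit <- tryCatch({
      if (cofit_onset) {
        times_abs <- tabo + t_bo
        minpack.lm::nlsLM(V ~ k * pmax(times_abs - tb, 1e-9)^a,
                          start = list(k = k, a = alpha, tb = t_bo),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(V ~ k * tabo^a, start = list(k = k, a = alpha),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warning("nonlinear fit did not converge; falling back to log-log")
    } else {
      cf <- coef(fit); se <- summary(fit)$coefficients
      out$alpha <- unname(cf["a"]); out$k <- unname(cf["k"])
      out$alpha_se <- se["a", 2]; out$k_se <- se["k", 2]
      if (cofit_onset) out$t_bo_used <- unname(cf["tb"])
      out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
      out$method <- if (cofit_onset) "nls_cofit" else "nls"
    }
  }
  structure(out, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> alpha = %.3f +/- %.3f, k = %.3g mm^3 s^-alpha (%s, n = %d)\n",
              x$alpha, x$alpha_se, x$k, x$method, x$n))
  invisible(x)
}

#' Compare growth exponents across sample groups
#'
#' Summarizes fitted exponents per group: mean, spread (max minus min, the
#' statistic behind "alpha varies by at least 0.4"), and pairwise
#' differences of group means.
#'
#' @param fits List of `growth_fit` objects (or numeric alphas).
#' @param groups Group label per fit.
#' @return List: `summary` (per-group data frame: `group`, `n`, `mean_alpha`,
#'   `spread`), `pairwise` (data frame of group-mean differences).
#' @export
compare_exponents <- function(fits, groups) {
  alphas <- vapply(fits, function(f)
    if (inherits(f, "growth_fit")) f$alpha else as.numeric(f), numeric(1))
  if (length(alphas) != length(groups)) stop_bub("one group label per fit required")
  gs <- unique(groups)
  summary_df <- do.call(rbind, lapply(gs, function(g) {
    a <- alphas[groups == g]
    data.frame(group = g, n = length(a), mean_alpha = mean(a),
               spread = max(a) - min(a))
  }))
  pairs <- if (length(gs) >= 2L) {
    cmb <- utils::combn(gs, 2L)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      data.frame(group1 = cmb[1, i], group2 = cmb[2, i],
                 mean_diff = summary_df$mean_alpha[summary_df$group == cmb[1, i]] -
                   summary_df$mean_alpha[summary_df$group == cmb[2, i]])
    }))
  } else data.frame(group1 = character(0), group2 = character(0),
                    mean_diff = numeric(0))
  list(summary = summary_df, pairwise = pairs)
}
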
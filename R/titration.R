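#' pH-titration curve of a metal-free zinc finger peptide
#'
#' Container for a single-wavelength UV absorbance trace recorded while
#' titrating an acidified apo-peptide with base. The absorbance increase
#' (thiolate n -> sigma* band, typically monitored at 218 nm) reports the
#' deprotonation of the two cysteine thiols.
#'
#' @param ph Numeric vector of pH values, strictly increasing.
#' @param absorbance Numeric vector of absorbances (AU), same length.
#' @param peptide_id Identifier of the peptide, e.g. `"CP1-1991"`.
#' @param wavelength Monitored wavelength in nm (default 218).
#' @return An object of class `ph_titration_curve` wrapping a data frame
#'   with columns `ph` and `absorbance`.
#' @seealso [fit_pka()], [gen_ph_titration()]
#' @export
ph_titration_curve <- function(ph, absorbance, peptide_id = "", wavelength = 218) {
  if (length(ph) != length(absorbance)) {
    zf_error("zf_invalid_input", "ph and absorbance must have equal length")
  }
  if (length(ph) < 8) {
    zf_error("zf_insufficient_data", "a titration curve needs at least 8 points")
  }
  zf_assert_finite(ph, "ph")
  zf_assert_finite(absorbance, "absorbance")
  if (any(diff(ph) <= 0)) {
    zf_error("zf_invalid_input", "pH values must be strictly increasing")
  }
  structure(
    list(peptide_id = peptide_id,
         data = data.frame(ph = ph, absorbance = absorbance),
         wavelength = wavelength),
    class = "ph_titration_curve"
  )
}

#' @export
print.ph_titration_curve <- function(x, ...) {
  cat(sprintf("pH-titration curve%s: %d points, pH %.2f-%.2f, %g nm\n",
              if (nzchar(x$peptide_id)) paste0(" [", x$peptide_id, "]") else "",
              nrow(x$data), min(x$data$ph), max(x$data$ph), x$wavelength))
  invisible(x)
}

#' Two-proton dissociation model for thiol absorbance
#'
#' Predicted absorbance of a diprotic (two-cysteine) system as a function of
#' pH, using macroscopic acid-dissociation constants:
#'
#' \deqn{A(\mathrm{pH}) = \frac{A_0 + A_1\,10^{\mathrm{pH}-pK_1}
#'   + 2 A_2\,10^{2\,\mathrm{pH}-pK_1-pK_2}}
#'   {1 + 10^{\mathrm{pH}-pK_1} + 2\cdot 10^{2\,\mathrm{pH}-pK_1-pK_2}}}
#'
#' \eqn{A_0}, \eqn{A_1} and \eqn{A_2} are the plateau absorbances of the
#' fully protonated, singly deprotonated and fully deprotonated species.
#' Exponentials are rescaled by their maximum before mixing, so the value is
#' finite for any pH.
#'
#' @param fit A [pka_fit] object, or any list with elements `pk1`, `pk2`,
#'   `a0`, `a1`, `a2`.
#' @param ph Numeric vector of pH values.
#' @return Predicted absorbance(s), AU.
#' @examples
#' f <- list(pk1 = 8, pk2 = 8, a0 = 0, a1 = 0.5, a2 = 1)
#' predict_titration_absorbance(f, 8)  # 0.625
#' @export
predict_titration_absorbance <- function(fit, ph) {
  p <- c(fit$pk1, fit$pk2, fit$a0, fit$a1, fit$a2)
  zf_assert_finite(p, "pKa fit parameters")
  zf_assert_finite(ph, "ph")
  .eq3_absorbance(ph, fit$pk1, fit$pk2, fit$a0, fit$a1, fit$a2)
}

.eq3_absorbance <- function(ph, pk1, pk2, a0, a1, a2) {
  l1 <- ph - pk1              # log10 weight of the singly deprotonated state
  l2 <- 2 * ph - pk1 - pk2    # log10 weight of the doubly deprotonated state
  m <- pmax(0, l1, l2)
  w0 <- 10^(-m)
  w1 <- 10^(l1 - m)
  w2 <- 2 * 10^(l2 - m)
  (a0 * w0 + a1 * w1 + a2 * w2) / (w0 + w1 + w2)
}

#' Fit a pH-titration curve to the two-proton dissociation model
#'
#' Nonlinear least-squares fit of [predict_titration_absorbance()]'s model
#' to an absorbance trace, estimating the two macroscopic thiol pKa values
#' and the three plateau absorbances. pKa values are reported with the
#' convention `pk1 <= pk2` (labels swapped on exit if needed). Fitting uses
#' bounded Levenberg-Marquardt least squares (relative tolerance 1e-10, at
#' most 10000 function evaluations); pKa values are bounded to the sampled
#' pH range widened by 3 units.
#'
#' @param curve A [ph_titration_curve], or a data frame with columns `ph`
#'   and `absorbance`.
#' @param init Optional named list of starting values (`pk1`, `pk2`, `a0`,
#'   `a1`, `a2`). Defaults: plateaus from the curve extremes (`a0` = min,
#'   `a2` = max, `a1` = midpoint) and pKa values at the 1/3 and 2/3
#'   quantiles of the pH range.
#' @return An object of class `pka_fit` with elements `pk1`, `pk2`, `a0`,
#'   `a1`, `a2`, `se` (named standard errors), `rss`, and a
#'   `pk_out_of_range` flag set when a fitted pKa falls outside the sampled
#'   pH range by more than 1 unit.
#' @export
fit_pka <- function(curve, init = NULL) {
  d <- if (inherits(curve, "ph_titration_curve")) curve$data else as.data.frame(curve)
  if (!all(c("ph", "absorbance") %in% names(d))) {
    zf_error("zf_invalid_input", "curve needs columns ph and absorbance")
  }
  if (nrow(d) < 5) {
    zf_error("zf_insufficient_data", "fit_pka needs at least 5 points")
  }
  rng <- range(d$absorbance)
  if (diff(rng) < 1e-9 * max(1, abs(mean(d$absorbance)))) {
    zf_error("zf_fit_failure",
             "flat absorbance trace: pKa values are unidentifiable")
  }
  ph_rng <- range(d$ph)
  if (is.null(init)) {
    # several pKa placements guard against local minima when the upper
    # transition is only partially sampled (titrations often stop near pH 8)
    starts <- lapply(list(c(1, 2) / 3, c(1, 2) / 2.4, c(0.7, 1.05), c(0.85, 1.2)),
                     function(q) {
                       list(pk1 = ph_rng[1] + q[1] * diff(ph_rng),
                            pk2 = ph_rng[1] + q[2] * diff(ph_rng),
                            a0 = rng[1], a1 = mean(rng), a2 = rng[2])
                     })
  } else {
    starts <- list(init)
  }
  one_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        absorbance ~ .eq3_absorbance(ph, pk1, pk2, a0, a1, a2),
        data = d,
        start = st[c("pk1", "pk2", "a0", "a1", "a2")],
        lower = c(ph_rng[1] - 3, ph_rng[1] - 3, -Inf, -Inf, -Inf),
        upper = c(ph_rng[2] + 3, ph_rng[2] + 3, Inf, Inf, Inf),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxfev = 10000, maxiter = 500)
      ),
      error = function(e) NULL
    )
  }
  fits <- Filter(Negate(is.null), lapply(starts, one_fit))
  if (length(fits) == 0) {
    zf_error("zf_fit_failure", "pKa fit did not converge from any start",
             last_init = starts)
  }
  fit <- fits[[which.min(vapply(fits, function(f) sum(residuals(f)^2),
                                numeric(1)))]]
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 5))
  names(se) <- names(cf)
  if (cf[["pk1"]] > cf[["pk2"]]) {     # ordering convention
    tmp <- cf[["pk1"]]; cf[["pk1"]] <- cf[["pk2"]]; cf[["pk2"]] <- tmp
    tmp <- se[["pk1"]]; se[["pk1"]] <- se[["pk2"]]; se[["pk2"]] <- tmp
  }
  out_of_range <- cf[["pk1"]] < ph_rng[1] - 1 || cf[["pk2"]] > ph_rng[2] + 1
  structure(
    list(pk1 = unname(cf[["pk1"]]), pk2 = unname(cf[["pk2"]]),
         a0 = unname(cf[["a0"]]), a1 = unname(cf[["a1"]]),
         a2 = unname(cf[["a2"]]),
         se = se, rss = sum(residuals(fit)^2),
         pk_out_of_range = out_of_range),
    class = "pka_fit"
  )
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("Thiol pKa fit: pK1 = %.3f, pK2 = %.3f (RSS %.3g)%s\n",
              x$pk1, x$pk2, x$rss,
              if (isTRUE(x$pk_out_of_range)) " [pKa outside sampled range]" else ""))
  invisible(x)
}

#' Average thiol protonation at a given pH
#'
#' Mean number of protons bound to the two cysteine thiols, computed from
#' the macroscopic two-proton partition function:
#' \deqn{\bar n_H = \frac{10^{pK_2-\mathrm{pH}} + 2\cdot 10^{pK_1+pK_2-2\,\mathrm{pH}}}
#'   {1 + 10^{pK_2-\mathrm{pH}} + 10^{pK_1+pK_2-2\,\mathrm{pH}}}}
#' Bounded in \[0, 2\] and monotone nonincreasing in pH. When Zn(II) binds
#' and displaces all thiol protons, \eqn{\bar n_H} at the working pH is the
#' number of protons released to the buffer (the `n_h` used by
#' [decompose()]).
#'
#' @param pk1,pk2 Macroscopic pKa values (`pk1 <= pk2` by convention; the
#'   formula does not require it).
#' @param ph pH at which to evaluate (vectorised).
#' @return Average protonation, dimensionless in \[0, 2\].
#' @examples
#' average_protonation(8, 8, 8)       # exactly 1
#' average_protonation(6.6, 7.9, 7.4) # typical CCHH-peptide value ~ 1.6
#' @export
average_protonation <- function(pk1, pk2, ph) {
  zf_assert_finite(c(pk1, pk2, ph), "average_protonation arguments")
  l1 <- pk2 - ph
  l2 <- pk1 + pk2 - 2 * ph
  m <- pmax(0, l1, l2)
  (10^(l1 - m) + 2 * 10^(l2 - m)) / (10^(-m) + 10^(l1 - m) + 10^(l2 - m))
}

#' Chelator-competition ellipticity series
#'
#' Mean residue ellipticity of a zinc finger peptide equilibrated against a
#' set of metal buffers that clamp free Zn(II) at known pZn values. Folding
#' on Zn(II) binding changes the CD signal near 220 nm, so ellipticity
#' traces complex saturation.
#'
#' @param pzn Numeric vector, \eqn{-\log_{10}} of free Zn(II) (M); values
#'   must be distinct.
#' @param ellipticity Numeric vector, mean residue ellipticity
#'   (deg cm^2 dmol^-1).
#' @param peptide_id Peptide identifier.
#' @param wavelength Monitored wavelength, nm (default 220).
#' @param replicate_count Number of kinetic reads averaged per point.
#' @return An object of class `competition_series`.
#' @export
competition_series <- function(pzn, ellipticity, peptide_id = "",
                               wavelength = 220, replicate_count = 1) {
  if (length(pzn) != length(ellipticity)) {
    zf_error("zf_invalid_input", "pzn and ellipticity must have equal length")
  }
  zf_assert_finite(pzn, "pzn")
  zf_assert_finite(ellipticity, "ellipticity")
  if (anyDuplicated(pzn)) {
    zf_error("zf_invalid_input", "pzn values must be distinct")
  }
  o <- order(pzn)
  structure(
    list(peptide_id = peptide_id,
         data = data.frame(pzn = pzn[o], ellipticity = ellipticity[o]),
         wavelength = wavelength, replicate_count = replicate_count),
    class = "competition_series"
  )
}

#' @export
print.competition_series <- function(x, ...) {
  cat(sprintf("Competition series%s: %d points, pZn %.2f-%.2f, %g nm\n",
              if (nzchar(x$peptide_id)) paste0(" [", x$peptide_id, "]") else "",
              nrow(x$data), min(x$data$pzn), max(x$data$pzn), x$wavelength))
  invisible(x)
}

#' Hill saturation model for competition data
#'
#' Evaluates the Hill equation in the convention used throughout this
#' package, with the free-Zn(II)-weighted term paired with
#' \eqn{\Theta_{min}}:
#' \deqn{\Theta(x) = \Theta_{min}\frac{x^n}{x^n + [\mathrm{Zn}]_{0.5}^n}
#'  + \Theta_{max}\frac{[\mathrm{Zn}]_{0.5}^n}{x^n + [\mathrm{Zn}]_{0.5}^n}}
#' so \eqn{\Theta \to \Theta_{max}} as \eqn{x \to 0} and
#' \eqn{\Theta \to \Theta_{min}} at saturating free Zn(II). For a folding
#' zinc finger monitored near 220 nm the saturated signal is the more
#' negative one. The half-saturation point \eqn{x = [\mathrm{Zn}]_{0.5}} is
#' unaffected by which plateau carries which weight.
#'
#' @param fit A [hill_fit] object or list with `theta_min`, `theta_max`,
#'   `hill_n`, `zn_half`.
#' @param free_zn Free Zn(II) concentration(s), M; must be nonnegative.
#' @return Predicted ellipticity (deg cm^2 dmol^-1).
#' @export
predict_hill <- function(fit, free_zn) {
  zf_assert_finite(free_zn, "free_zn")
  if (any(free_zn < 0)) {
    zf_error("zf_invalid_input", "free_zn must be nonnegative")
  }
  .hill_theta(free_zn, fit$theta_min, fit$theta_max, fit$hill_n, fit$zn_half)
}

.hill_theta <- function(x, theta_min, theta_max, n, zn_half) {
  # evaluate in a ratio form that is stable for x spanning many decades
  rho <- (x / zn_half)^n
  (theta_min * rho + theta_max) / (rho + 1)
}

#' Fit a competition series to the Hill equation
#'
#' Least-squares fit of [predict_hill()]'s model to an ellipticity-vs-pZn
#' series. The half-saturation free Zn(II) is fitted on the \eqn{\log_{10}}
#' scale for conditioning. Replicate readings sharing a pZn value are
#' averaged before fitting.
#'
#' @param series A [competition_series], or a data frame with columns `pzn`
#'   and `ellipticity`.
#' @param init Optional starting values (`theta_min`, `theta_max`,
#'   `hill_n`, `zn_half`). Defaults: plateaus from the data extremes,
#'   `hill_n = 1`, and `zn_half` from the pZn at which the signal crosses
#'   its midpoint.
#' @return An object of class `hill_fit` with `theta_min`, `theta_max`,
#'   `hill_n`, `zn_half` (M), `se`, `rss`.
#' @export
fit_hill <- function(series, init = NULL) {
  d <- if (inherits(series, "competition_series")) series$data else as.data.frame(series)
  if (!all(c("pzn", "ellipticity") %in% names(d))) {
    zf_error("zf_invalid_input", "series needs columns pzn and ellipticity")
  }
  # average replicate readings at identical pZn
  if (anyDuplicated(d$pzn)) {
    d <- aggregate(ellipticity ~ pzn, data = d, FUN = mean)
  }
  d <- d[order(d$pzn), ]
  if (nrow(d) < 6) {
    zf_error("zf_insufficient_data", "fit_hill needs at least 6 distinct points")
  }
  if (diff(range(d$pzn)) < 2) {
    warning("pZn span < 2 units; Hill fit may be poorly constrained")
  }
  rng <- range(d$ellipticity)
  if (diff(rng) < 1e-9 * max(1, abs(mean(d$ellipticity)))) {
    zf_error("zf_unidentifiable_fit",
             "flat ellipticity series: transition not sampled")
  }
  if (is.null(init)) {
    # theta_min is approached at high free Zn (low pzn)
    y_lo <- d$ellipticity[which.min(d$pzn)]
    y_hi <- d$ellipticity[which.max(d$pzn)]
    mid <- mean(rng)
    cross <- tryCatch(approx(d$ellipticity, d$pzn, xout = mid, ties = mean)$y,
                      error = function(e) NA_real_)
    if (!is.finite(cross)) cross <- mean(range(d$pzn))
    init <- list(theta_min = y_lo, theta_max = y_hi, hill_n = 1,
                 zn_half = 10^(-cross))
  }
  start <- list(theta_min = init$theta_min, theta_max = init$theta_max,
                hill_n = init$hill_n, lk = log10(init$zn_half))
  pzn_rng <- range(d$pzn)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ellipticity ~ .hill_theta(10^(-pzn), theta_min, theta_max, hill_n, 10^lk),
      data = d, start = start,
      lower = c(-Inf, -Inf, 0.05, -pzn_rng[2] - 3),
      upper = c(Inf, Inf, 10, -pzn_rng[1] + 3),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxfev = 10000, maxiter = 500)
    ),
    error = function(e) zf_error("zf_fit_failure",
                                 paste("Hill fit did not converge:",
                                       conditionMessage(e)))
  )
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  amp <- abs(cf[["theta_max"]] - cf[["theta_min"]])
  if (diff(rng) < 0.2 * amp) {
    zf_error("zf_unidentifiable_fit", paste(
      "series does not span the transition:",
      sprintf("observed change is %.0f%% of the fitted amplitude",
              100 * diff(rng) / amp)))
  }
  if (-cf[["lk"]] < pzn_rng[1] - 0.5 || -cf[["lk"]] > pzn_rng[2] + 0.5) {
    zf_error("zf_unidentifiable_fit", sprintf(
      "fitted half-saturation point (pZn %.2f) lies outside the sampled range %.2f-%.2f",
      -cf[["lk"]], pzn_rng[1], pzn_rng[2]))
  }
  # plateau-only sampling shows up as an amplitude indistinguishable from
  # the residual scatter
  sigma <- sqrt(sum(residuals(fit)^2) / max(nrow(d) - 4, 1))
  if (amp < 5 * sigma) {
    zf_error("zf_unidentifiable_fit", sprintf(
      "fitted transition amplitude (%.3g) is not resolved above the residual noise (%.3g)",
      amp, sigma))
  }
  zn_half <- 10^cf[["lk"]]
  se_zn <- if (is.finite(se[["lk"]])) log(10) * zn_half * se[["lk"]] else NA_real_
  structure(
    list(theta_min = unname(cf[["theta_min"]]),
         theta_max = unname(cf[["theta_max"]]),
         hill_n = unname(cf[["hill_n"]]),
         zn_half = unname(zn_half),
         se = c(theta_min = unname(se[["theta_min"]]),
                theta_max = unname(se[["theta_max"]]),
                hill_n = unname(se[["hill_n"]]),
                zn_half = unname(se_zn),
                neg_log_zn_half = unname(se[["lk"]])),
         rss = sum(residuals(fit)^2)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: n = %.3f, [Zn]0.5 = %.3g M (-log10 = %.2f)\n",
              x$hill_n, x$zn_half, -log10(x$zn_half)))
  invisible(x)
}

#' Dissociation constant from a competition Hill fit
#'
#' For a 1:1 Zn(II)-peptide complex, the free Zn(II) concentration at
#' half-saturation equals the apparent dissociation constant
#' \eqn{K_d = [\mathrm{Zn}][L]/[\mathrm{Zn}L]} at the working pH.
#'
#' @param fit A [hill_fit] object.
#' @param ph Working pH of the competition experiment (default 7.4).
#' @return An object of class `kd_result` with `kd` (M), `neg_log_kd`,
#'   `ph`, `method = "competition"`, and (when available) `se_neg_log_kd`.
#' @examples
#' f <- list(theta_min = -1, theta_max = 0, hill_n = 1, zn_half = 5.01e-13)
#' class(f) <- "hill_fit"
#' kd_from_hill(f)$neg_log_kd  # 12.30
#' @export
kd_from_hill <- function(fit, ph = 7.4) {
  if (!is.finite(fit$zn_half) || fit$zn_half <= 0) {
    zf_error("zf_invalid_fit", "zn_half must be positive")
  }
  structure(
    list(kd = fit$zn_half, neg_log_kd = -log10(fit$zn_half), ph = ph,
         method = "competition",
         se_neg_log_kd = if (!is.null(fit$se)) unname(fit$se["neg_log_zn_half"]) else NA_real_),
    class = "kd_result"
  )
}

#' @export
print.kd_result <- function(x, ...) {
  cat(sprintf("Kd (%s, pH %.1f): %.3g M  (-logKd = %.2f)\n",
              x$method, x$ph, x$kd, x$neg_log_kd))
  invisible(x)
}
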
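#' Chelator with proton- and Zn(II)-binding constants
#'
#' Describes one competing chelator as used in metal-buffer speciation:
#' stepwise log10 proton-association constants (highest first) and the
#' log10 formation constant of its 1:1 Zn(II) complex, optionally with a
#' protonated ternary ZnHL complex. Constants are conditional values at the
#' stated medium; no ionic-strength or temperature corrections are applied.
#'
#' @param name Chelator name, e.g. `"EDTA"`.
#' @param log_protonation_constants Numeric vector of stepwise log10
#'   proton-association constants (logK1 >= logK2 >= ...). May be empty.
#' @param log_beta_znl log10 formation constant of ZnL
#'   (\eqn{\beta = [\mathrm{Zn}L]/([\mathrm{Zn}][L])}).
#' @param log_beta_znhl Optional log10 formation constant of ZnHL
#'   (\eqn{[\mathrm{Zn}HL]/([\mathrm{Zn}][H][L])}).
#' @param reference Free-text source note for the constants.
#' @return An object of class `chelator`.
#' @seealso [load_chelators()] for the shipped constants file.
#' @export
chelator <- function(name, log_protonation_constants, log_beta_znl,
                     log_beta_znhl = NULL, reference = NULL) {
  lk <- as.numeric(log_protonation_constants)
  zf_assert_finite(c(lk, log_beta_znl), "chelator constants")
  if (length(lk) > 1 && any(diff(lk) > 1e-9)) {
    zf_error("zf_invalid_input",
             "stepwise protonation constants must be nonincreasing")
  }
  structure(
    list(name = name, log_protonation_constants = lk,
         log_beta_znl = log_beta_znl, log_beta_znhl = log_beta_znhl,
         reference = reference),
    class = "chelator"
  )
}

#' @export
print.chelator <- function(x, ...) {
  cat(sprintf("Chelator %s: logK_H = {%s}, logB(ZnL) = %.2f%s\n",
              x$name, paste(format(x$log_protonation_constants), collapse = ", "),
              x$log_beta_znl,
              if (!is.null(x$log_beta_znhl))
                sprintf(", logB(ZnHL) = %.2f", x$log_beta_znhl) else ""))
  invisible(x)
}

#' Load chelator constants from a YAML config file
#'
#' Reads a chelator-constants file (one record per chelator with fields
#' `name`, `logK` (list), `logB_ZnL`, optional `logB_ZnHL`, `reference`).
#' The package ships a default set for the chelators used in zinc finger
#' competition work (EDTA, EGTA, HEDTA, NDAP, EDDS, TPEN) under
#' `inst/extdata/chelators.yaml`; these are literature-compilation values
#' and should be reviewed against the medium at hand.
#'
#' @param path Path to the YAML file; defaults to the shipped set.
#' @return Named list of [chelator] objects.
#' @export
load_chelators <- function(path = system.file("extdata", "chelators.yaml",
                                              package = "zfthermo")) {
  recs <- yaml::read_yaml(path)
  out <- lapply(recs, function(r) {
    chelator(r$name, unlist(r$logK), r$logB_ZnL,
             log_beta_znhl = r$logB_ZnHL, reference = r$reference)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Proton side-reaction coefficient of a chelator
#'
#' \deqn{\alpha_H(L) = 1 + \sum_i 10^{\left(\sum_{j\le i}\log K_j\right) - i\,\mathrm{pH}}}
#' i.e. the factor by which protonation inflates the apparent free-ligand
#' pool at a given pH. Equals 1 when the pH is far above every logK.
#'
#' @param chel A [chelator].
#' @param ph pH (fixed by the buffer).
#' @return alpha_H >= 1, dimensionless.
#' @export
proton_side_coefficient <- function(chel, ph) {
  lk <- chel$log_protonation_constants
  if (length(lk) == 0) return(1)
  i <- seq_along(lk)
  1 + sum(10^(cumsum(lk) - i * ph))
}

#' Conditional Zn(II)-complex formation constant at fixed pH
#'
#' Folds ligand protonation (and, when parameterised, the ZnHL ternary
#' complex) into a single conditional constant
#' \deqn{\beta' = \frac{10^{\log\beta_{ZnL}} + 10^{\log\beta_{ZnHL}-\mathrm{pH}}}{\alpha_H(L)}}
#' such that \eqn{[\mathrm{Zn}L]_{tot} = \beta'\,[\mathrm{Zn}][L']} with
#' \eqn{[L']} the total uncomplexed ligand.
#'
#' @inheritParams proton_side_coefficient
#' @return beta-prime, 1/M (dimensionless ratio per molar).
#' @export
conditional_beta <- function(chel, ph) {
  a <- proton_side_coefficient(chel, ph)
  b <- 10^chel$log_beta_znl
  if (!is.null(chel$log_beta_znhl)) {
    b <- b + 10^(chel$log_beta_znhl - ph)
  }
  b / a
}

#' Metal buffer specification
#'
#' A chelator/Zn(II) mixture at fixed pH that clamps free Zn(II) at a
#' calculable concentration, optionally together with the zinc finger
#' peptide that competes for the metal.
#'
#' @param chelator A [chelator] object.
#' @param total_chelator Total chelator concentration, M (> 0).
#' @param total_zn Total Zn(II) concentration, M.
#' @param ph pH, in \[2, 12\].
#' @param peptide_total Optional total peptide concentration, M.
#' @param peptide_kd Optional Zn(II)-peptide dissociation constant, M.
#' @return An object of class `metal_buffer`.
#' @export
metal_buffer <- function(chelator, total_chelator, total_zn, ph,
                         peptide_total = NULL, peptide_kd = NULL) {
  stopifnot(inherits(chelator, "chelator"))
  if (total_chelator <= 0) {
    zf_error("zf_invalid_input", "total_chelator must be positive")
  }
  if (total_zn < 0) zf_error("zf_invalid_input", "total_zn must be nonnegative")
  if (ph < 2 || ph > 12) {
    zf_error("zf_invalid_input", "ph must lie in [2, 12]")
  }
  if (total_zn > total_chelator) {
    warning("total_zn exceeds total_chelator: free Zn is essentially unbuffered")
  }
  structure(
    list(chelator = chelator, total_chelator = total_chelator,
         total_zn = total_zn, ph = ph,
         peptide_total = peptide_total, peptide_kd = peptide_kd),
    class = "metal_buffer"
  )
}

#' Solve for free Zn(II) in a metal buffer
#'
#' Solves the two conditional mass balances
#' \deqn{Zn_{tot} = [\mathrm{Zn}] + \beta'[\mathrm{Zn}][L'], \qquad
#'       L_{tot} = [L'] + \beta'[\mathrm{Zn}][L']}
#' for the free metal and uncomplexed ligand by a damped Newton iteration
#' on log-concentrations (which keeps both unknowns positive across the
#' ~15 orders of magnitude the buffers span), started from the
#' excess-ligand closed form. Convergence requires both relative
#' mass-balance residuals below 1e-10; failure after 200 iterations raises
#' a `zf_numerical_failure` carrying the last residuals.
#'
#' @param buffer A [metal_buffer] (peptide fields ignored here; see
#'   [peptide_corrected_pzn()]).
#' @return An object of class `speciation_result`: `free_zn` (M), `pzn`,
#'   `species` (named molar concentrations of `Zn`, `L'`, `ZnL'`),
#'   `mass_balance_residuals`, `iterations`, `degenerate` flag.
#' @examples
#' ch <- chelator("toy", numeric(0), log_beta_znl = 13.6)
#' solve_free_zn(metal_buffer(ch, 1e-3, 5e-4, 7.4))$pzn
#' @export
solve_free_zn <- function(buffer) {
  stopifnot(inherits(buffer, "metal_buffer"))
  bp <- conditional_beta(buffer$chelator, buffer$ph)
  zt <- buffer$total_zn
  lt <- buffer$total_chelator
  if (zt == 0) {
    return(structure(
      list(free_zn = 1e-30, pzn = 30,
           species = c(Zn = 0, `L'` = lt, `ZnL'` = 0),
           mass_balance_residuals = c(zn = 0, ligand = 0),
           iterations = 0L, degenerate = TRUE),
      class = "speciation_result"))
  }
  # start: excess-ligand first-order estimate (or its mirror image)
  if (lt > zt) {
    l0 <- lt - zt
    z0 <- zt / (1 + bp * l0)
  } else {
    z0 <- max(zt - lt, zt * 1e-9)
    l0 <- lt / (1 + bp * z0)
  }
  u <- log(z0); v <- log(l0)
  resid <- function(u, v) {
    z <- exp(u); l <- exp(v); c_zl <- bp * z * l
    c((z + c_zl) / zt - 1, (l + c_zl) / lt - 1)
  }
  f <- resid(u, v)
  it <- 0L
  while (max(abs(f)) > 1e-12 && it < 200L) {
    it <- it + 1L
    z <- exp(u); l <- exp(v); c_zl <- bp * z * l
    jac <- matrix(c((z + c_zl) / zt, c_zl / zt,
                    c_zl / lt, (l + c_zl) / lt),
                  nrow = 2, byrow = TRUE)
    step <- tryCatch(solve(jac, f), error = function(e) f)  # fall back to residual direction
    lam <- 1
    repeat {
      f_new <- resid(u - lam * step[1], v - lam * step[2])
      if (max(abs(f_new)) < max(abs(f)) || lam < 2^-30) break
      lam <- lam / 2
    }
    u <- u - lam * step[1]; v <- v - lam * step[2]
    f <- f_new
  }
  if (max(abs(f)) > 1e-8) {
    zf_error("zf_numerical_failure",
             sprintf("speciation solver did not converge (residuals %.3g, %.3g)",
                     f[1], f[2]),
             residuals = f)
  }
  z <- exp(u); l <- exp(v)
  structure(
    list(free_zn = z, pzn = -log10(z),
         species = c(Zn = z, `L'` = l, `ZnL'` = bp * z * l),
         mass_balance_residuals = c(zn = abs(f[1]), ligand = abs(f[2])),
         iterations = it, degenerate = FALSE),
    class = "speciation_result"
  )
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("Free Zn(II) = %.3g M (pZn = %.3f), %d iterations\n",
              x$free_zn, x$pzn, x$iterations))
  invisible(x)
}

#' Free Zn(II) corrected for Zn(II) bound by the peptide
#'
#' Accounts for the Zn(II) withdrawn from the metal buffer by the zinc
#' finger peptide: the saturated fraction of `peptide_total` is subtracted
#' from total Zn(II) and the buffer re-solved. When `peptide_kd` is set in
#' the buffer, the saturation is recomputed from the resulting free Zn(II)
#' (1:1 binding, \eqn{f = [\mathrm{Zn}]/([\mathrm{Zn}]+K_d)}) and the
#' correction iterated to a fixed point with |delta pZn| < 1e-6.
#'
#' @param buffer A [metal_buffer] with `peptide_total` set.
#' @param saturation_fraction Fraction of peptide Zn(II)-loaded, in
#'   \[0, 1\]. Used as-is when `peptide_kd` is absent, otherwise as the
#'   starting value of the fixed-point iteration (default 0.5).
#' @return A `speciation_result` with additional fields
#'   `peptide_saturation` and `peptide_bound` (M).
#' @export
peptide_corrected_pzn <- function(buffer, saturation_fraction = NULL) {
  stopifnot(inherits(buffer, "metal_buffer"))
  if (is.null(buffer$peptide_total)) {
    zf_error("zf_invalid_input", "buffer has no peptide_total to correct for")
  }
  pt <- buffer$peptide_total
  iterate <- !is.null(buffer$peptide_kd)
  sat <- if (!is.null(saturation_fraction)) saturation_fraction else 0.5
  if (!iterate && is.null(saturation_fraction)) {
    zf_error("zf_invalid_input",
             "saturation_fraction is required when peptide_kd is not set")
  }
  if (sat < 0 || sat > 1) {
    zf_error("zf_invalid_input", "saturation_fraction must lie in [0, 1]")
  }
  solve_at <- function(sat) {
    zt <- buffer$total_zn - sat * pt
    if (zt <= 0) {
      zf_error("zf_infeasible_buffer",
               "peptide correction exhausts total Zn(II)")
    }
    b2 <- buffer; b2$total_zn <- zt; b2$peptide_total <- NULL
    solve_free_zn(b2)
  }
  res <- solve_at(sat)
  if (iterate) {
    kd <- buffer$peptide_kd
    for (i in 1:100) {
      sat_new <- res$free_zn / (res$free_zn + kd)
      res_new <- solve_at(sat_new)
      done <- abs(res_new$pzn - res$pzn) < 1e-6
      res <- res_new; sat <- sat_new
      if (done) break
    }
    if (!done) {
      zf_error("zf_numerical_failure",
               "peptide-correction fixed point did not converge in 100 iterations")
    }
  }
  res$peptide_saturation <- sat
  res$peptide_bound <- sat * pt
  res
}

#' pZn series across a metal-buffer titration
#'
#' Solves [solve_free_zn()] for each total Zn(II) in `zn_tots` at fixed
#' total chelator and pH, as used to build a competition series (e.g.
#' 0.05-0.95 mM Zn(II) against 1.0 mM chelator).
#'
#' @param chel A [chelator].
#' @param l_tot Total chelator concentration, M.
#' @param zn_tots Numeric vector of total Zn(II) concentrations, M.
#' @param ph pH.
#' @return Data frame with columns `zn_tot` and `pzn`; pZn is strictly
#'   decreasing in `zn_tot`.
#' @export
competition_pzn_series <- function(chel, l_tot, zn_tots, ph) {
  if (length(zn_tots) == 0) {
    zf_error("zf_invalid_input", "zn_tots must be nonempty")
  }
  pzn <- vapply(zn_tots, function(zt) {
    solve_free_zn(metal_buffer(chel, l_tot, zt, ph))$pzn
  }, numeric(1))
  data.frame(zn_tot = zn_tots, pzn = pzn)
}
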
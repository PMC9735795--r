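#' Reference enthalpies and physical constants for the decomposition
#'
#' Bundles the constants entering the proton-linkage enthalpy
#' decomposition. Defaults: HEPES buffer-protonation heat 5.02 kcal/mol,
#' cysteine thiol deprotonation heat 8.5 kcal/mol per proton, Zn-S(thiolate)
#' and Zn-N(imidazole) bond enthalpies (relative to Zn-OH2) both
#' -5.0 kcal/mol, R = 1.9872e-3 kcal/(mol K), T = 298.15 K.
#'
#' @param dh_buff Buffer protonation enthalpy, kcal/mol.
#' @param dh_cysh_per_proton Thiol deprotonation enthalpy, kcal/mol per
#'   proton.
#' @param dh_zn_s,dh_zn_n Zn-S and Zn-N bond enthalpies, kcal/mol.
#' @param gas_constant R in kcal/(mol K).
#' @param temperature Temperature, K.
#' @return An object of class `thermo_constants`.
#' @export
thermo_constants <- function(dh_buff = 5.02, dh_cysh_per_proton = 8.5,
                             dh_zn_s = -5.0, dh_zn_n = -5.0,
                             gas_constant = 1.9872e-3, temperature = 298.15) {
  x <- list(dh_buff = dh_buff, dh_cysh_per_proton = dh_cysh_per_proton,
            dh_zn_s = dh_zn_s, dh_zn_n = dh_zn_n,
            gas_constant = gas_constant, temperature = temperature)
  zf_assert_finite(unlist(x), "thermo_constants")
  structure(x, class = "thermo_constants")
}

#' ITC titration experiment
#'
#' A single isothermal titration calorimetry run: Zn(II) titrant injected
#' stepwise into the peptide solution in the cell. Heats are integrated
#' per-injection values (instrument-export style), with the dilution
#' control either already subtracted or left to the fitted offset.
#'
#' @param cell_volume Active cell volume, mL.
#' @param cell_concentration Peptide concentration in the cell, M.
#' @param syringe_concentration Zn(II) concentration in the syringe, M.
#' @param injection_volumes Numeric vector of injection volumes, uL.
#' @param heats Optional numeric vector of integrated heats, ucal (one per
#'   injection); may be `NULL` for a bare injection design.
#' @param temperature Temperature, K (default 298.15).
#' @param buffer_name Buffer identifier (default `"HEPES"`).
#' @return An object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_volume, cell_concentration,
                           syringe_concentration, injection_volumes,
                           heats = NULL, temperature = 298.15,
                           buffer_name = "HEPES") {
  if (any(injection_volumes <= 0) || cell_volume <= 0) {
    zf_error("zf_invalid_input", "volumes must be positive")
  }
  if (length(injection_volumes) < 10) {
    zf_error("zf_insufficient_data", "an ITC run needs at least 10 injections")
  }
  if (!is.null(heats) && length(heats) != length(injection_volumes)) {
    zf_error("zf_invalid_input", "heats must match injection_volumes in length")
  }
  structure(
    list(cell_volume = cell_volume, cell_concentration = cell_concentration,
         syringe_concentration = syringe_concentration,
         injection_volumes = injection_volumes, heats = heats,
         temperature = temperature, buffer_name = buffer_name),
    class = "itc_experiment"
  )
}

#' Default injection design used throughout the package
#'
#' 25 injections of 6.82 uL of 0.35 mM Zn(II) into 30 uM peptide in a 1 mL
#' cell at 298.15 K (final molar ratio ~ 2).
#'
#' @return An [itc_experiment] without heats.
#' @export
default_itc_design <- function() {
  itc_experiment(cell_volume = 1, cell_concentration = 30e-6,
                 syringe_concentration = 0.35e-3,
                 injection_volumes = rep(6.82, 25))
}

# Equilibrium complex concentration for single-site binding:
# sites S = n * P_tot, titrant X_tot, association constant kb (1/M).
.single_site_complex <- function(s_tot, x_tot, kb) {
  b <- s_tot + x_tot + 1 / kb
  disc <- b^2 - 4 * s_tot * x_tot
  (b - sqrt(pmax(disc, 0))) / 2
}

#' Simulate a single-site ITC isotherm
#'
#' Forward model for the injection heats of a 1:1 binding experiment with
#' exact volume-displacement bookkeeping: the cell volume is constant, each
#' injection displaces an equal volume of the pre-injection (well-mixed)
#' cell content, and the displaced liquid is thermally inert. The heat of
#' injection i is the enthalpy times the moles of complex newly formed in
#' the cell, plus a constant dilution offset.
#'
#' @param kb Association constant, 1/M.
#' @param dh Binding enthalpy, kcal/mol of complex formed.
#' @param n Stoichiometry (sites per peptide).
#' @param design An [itc_experiment] providing volumes and concentrations.
#' @param dilution_offset Constant heat added per injection, ucal.
#' @return Numeric vector of per-injection heats, ucal.
#' @export
simulate_isotherm <- function(kb, dh, n, design = default_itc_design(),
                              dilution_offset = 0) {
  stopifnot(inherits(design, "itc_experiment"))
  if (kb <= 0) zf_error("zf_invalid_input", "kb must be positive")
  v0 <- design$cell_volume * 1e-3          # L
  p <- design$cell_concentration           # M, peptide in cell
  x <- 0                                   # M, titrant in cell
  c_prev <- 0                              # M, complex in cell
  q <- numeric(length(design$injection_volumes))
  for (i in seq_along(q)) {
    v <- design$injection_volumes[i] * 1e-6   # L
    dil <- 1 - v / v0
    p <- p * dil
    x <- x * dil + design$syringe_concentration * (v / v0)
    c_new <- .single_site_complex(n * p, x, kb)
    # moles of complex formed this injection (displaced complex left inert)
    q[i] <- dh * (c_new - c_prev * dil) * v0 * 1e9 + dilution_offset
    c_prev <- c_new
  }
  q
}

#' Fit an ITC isotherm to the single-site binding model
#'
#' Levenberg-Marquardt least-squares fit of [simulate_isotherm()] to the
#' observed per-injection heats, estimating stoichiometry, association
#' constant (on the log10 scale internally), binding enthalpy and a
#' constant dilution offset.
#'
#' @param exp An [itc_experiment] with heats.
#' @param init Optional starting values (`n`, `kb`, `dh`, `offset`).
#' @return An object of class `itc_fit` with `stoichiometry_n`, `kb`
#'   (1/M), `dh_itc` (kcal/mol), `dilution_offset` (ucal), `se`, `rss`,
#'   and a `saturation_warning` flag when the titration ends below a molar
#'   ratio of 1.2 times the fitted stoichiometry.
#' @export
fit_isotherm <- function(exp, init = NULL) {
  stopifnot(inherits(exp, "itc_experiment"))
  q <- exp$heats
  if (is.null(q)) zf_error("zf_invalid_input", "experiment carries no heats")
  if (diff(range(q)) < 1e-9) {
    zf_error("zf_fit_failure",
             "heats carry no signal: binding enthalpy unidentifiable")
  }
  if (is.null(init)) {
    mol_inj <- exp$injection_volumes[1] * 1e-6 * exp$syringe_concentration
    init <- list(n = 1, kb = 1e7,
                 dh = (q[1] - q[length(q)]) / (mol_inj * 1e9),
                 offset = mean(tail(q, 3)))
  }
  d <- data.frame(q = q)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      q ~ simulate_isotherm(10^lkb, dh, n, exp, offset),
      data = d,
      start = list(n = init$n, lkb = log10(init$kb), dh = init$dh,
                   offset = init$offset),
      lower = c(0.05, 2, -Inf, -Inf),
      upper = c(2, 14, Inf, Inf),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxfev = 10000, maxiter = 500)
    ),
    error = function(e) zf_error("zf_fit_failure",
                                 paste("isotherm fit did not converge:",
                                       conditionMessage(e)))
  )
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  # final molar ratio titrant:peptide in the cell
  v0 <- exp$cell_volume * 1e-3
  dil <- cumprod(1 - exp$injection_volumes * 1e-6 / v0)
  p_end <- exp$cell_concentration * dil[length(dil)]
  x_end <- 0
  for (v in exp$injection_volumes * 1e-6) {
    x_end <- x_end * (1 - v / v0) + exp$syringe_concentration * v / v0
  }
  sat_warn <- (x_end / p_end) < 1.2 * cf[["n"]]
  if (sat_warn) {
    warning("titration ends below 1.2 x n molar ratio; saturation not reached")
  }
  kb <- 10^cf[["lkb"]]
  structure(
    list(stoichiometry_n = unname(cf[["n"]]), kb = unname(kb),
         dh_itc = unname(cf[["dh"]]),
         dilution_offset = unname(cf[["offset"]]),
         se = c(n = unname(se[["n"]]),
                kb = unname(if (is.finite(se[["lkb"]])) log(10) * kb * se[["lkb"]] else NA_real_),
                dh_itc = unname(se[["dh"]]),
                dilution_offset = unname(se[["offset"]])),
         rss = sum(residuals(fit)^2),
         saturation_warning = sat_warn),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("ITC fit: n = %.3f, Kb = %.3g 1/M, dH_ITC = %.2f kcal/mol\n",
              x$stoichiometry_n, x$kb, x$dh_itc))
  invisible(x)
}

#' Buffer-ionisation correction of the observed ITC enthalpy
#'
#' Each proton released from the thiols on Zn(II) binding is taken up by
#' the buffer, whose protonation heat contaminates the observed enthalpy.
#' The standard binding enthalpy is recovered as
#' \deqn{\Delta H^\circ = \Delta H_{ITC} + n_H\,\Delta H^\circ_{buff}}
#' The sign convention is fixed by the requirement that buffer protonation
#' (exothermic uptake of the released protons, here entering through the
#' endothermic \eqn{\Delta H^\circ_{buff}} of the reverse process) be
#' removed from, not added to, the observed heat; for HEPES
#' (\eqn{\Delta H^\circ_{buff}} = 5.02 kcal/mol) this reproduces the
#' reference enthalpy ledgers for Cys2His2 peptides.
#'
#' @param dh_itc Observed ITC enthalpy, kcal/mol.
#' @param n_h Protons released at the working pH (see
#'   [average_protonation()]).
#' @param constants A [thermo_constants] object.
#' @return Standard binding enthalpy, kcal/mol.
#' @examples
#' buffer_corrected_enthalpy(-20.87, 1.56)  # -13.04
#' @export
buffer_corrected_enthalpy <- function(dh_itc, n_h,
                                      constants = thermo_constants()) {
  zf_assert_finite(c(dh_itc, n_h), "buffer_corrected_enthalpy inputs")
  dh_itc + n_h * constants$dh_buff
}

#' Thiol-deprotonation enthalpy
#'
#' Enthalpy cost of deprotonating the Zn(II)-binding cysteine thiols:
#' `n_h` protons at 8.5 kcal/mol each (default constants).
#'
#' @inheritParams buffer_corrected_enthalpy
#' @return kcal/mol.
#' @export
cys_deprotonation_enthalpy <- function(n_h, constants = thermo_constants()) {
  zf_assert_finite(n_h, "n_h")
  if (n_h < 0 || n_h > 2) {
    zf_error("zf_invalid_input", "n_h must lie in [0, 2] for a two-Cys site")
  }
  n_h * constants$dh_cysh_per_proton
}

#' Zn(II)-to-deprotonated-peptide binding enthalpy
#'
#' Removes the thiol-deprotonation cost from the standard binding
#' enthalpy: \eqn{\Delta H^\circ_{Zn\textrm{-}pep} = \Delta H^\circ -
#' \Delta H_{CysH}}.
#'
#' @param dh_std Standard binding enthalpy, kcal/mol.
#' @param dh_cysh Thiol-deprotonation enthalpy, kcal/mol (already
#'   multiplied by `n_h`).
#' @return kcal/mol.
#' @export
zn_pep_enthalpy <- function(dh_std, dh_cysh) {
  zf_assert_finite(c(dh_std, dh_cysh), "zn_pep_enthalpy inputs")
  dh_std - dh_cysh
}

#' Folding enthalpy from the Zn-ligand bond budget
#'
#' Subtracts the coordination-bond enthalpies from the Zn-peptide binding
#' enthalpy of a four-coordinate site with `n_his` imidazole and
#' `4 - n_his` thiolate ligands:
#' \deqn{\Delta H^\circ_{folding} = \Delta H^\circ_{Zn\textrm{-}pep}
#'   - (4-n_{His})\Delta H^\circ_{Zn\textrm{-}S}
#'   - n_{His}\Delta H^\circ_{Zn\textrm{-}N}}
#' With the default -5.0 kcal/mol for both bond types this is
#' `dh_zn_pep + 20`.
#'
#' @param dh_zn_pep Zn-peptide binding enthalpy, kcal/mol.
#' @param n_his Number of His ligands, integer 0-4 (2 for a classical
#'   CCHH finger).
#' @param constants A [thermo_constants] object.
#' @return kcal/mol.
#' @export
folding_enthalpy <- function(dh_zn_pep, n_his,
                             constants = thermo_constants()) {
  zf_assert_finite(dh_zn_pep, "dh_zn_pep")
  if (!n_his %in% 0:4) {
    zf_error("zf_invalid_input", "n_his must be an integer in 0..4")
  }
  dh_zn_pep - (4 - n_his) * constants$dh_zn_s - n_his * constants$dh_zn_n
}

#' Gibbs free energy from a -logKd value
#'
#' \deqn{\Delta G^\circ = -RT\ln K_b = -(\ln 10)\,R\,T\,(-\log_{10} K_d)}
#'
#' @param neg_log_kd \eqn{-\log_{10} K_d} (positive for sub-molar
#'   affinity).
#' @param constants A [thermo_constants] object.
#' @return kcal/mol.
#' @examples
#' gibbs_from_neg_log_kd(14.49)  # -19.77
#' @export
gibbs_from_neg_log_kd <- function(neg_log_kd,
                                  constants = thermo_constants()) {
  zf_assert_finite(neg_log_kd, "neg_log_kd")
  if (any(neg_log_kd <= 0)) {
    zf_error("zf_invalid_input", "neg_log_kd must be positive")
  }
  -log(10) * constants$gas_constant * constants$temperature * neg_log_kd
}

#' Entropic term of binding
#'
#' \eqn{-T\Delta S^\circ = \Delta G^\circ - \Delta H^\circ}.
#'
#' @param dg Gibbs free energy, kcal/mol.
#' @param dh_std Standard binding enthalpy, kcal/mol.
#' @return kcal/mol.
#' @export
entropy_term <- function(dg, dh_std) {
  zf_assert_finite(c(dg, dh_std), "entropy_term inputs")
  dg - dh_std
}

#' Full proton-linkage enthalpy/entropy decomposition
#'
#' Chains the decomposition for one peptide: buffer correction, thiol
#' deprotonation, Zn-peptide enthalpy, folding enthalpy, Gibbs energy from
#' the competition-derived \eqn{-\log K_d}, and the entropic term. The
#' resulting ledger satisfies, by construction,
#' \eqn{\Delta G^\circ = \Delta H^\circ + (-T\Delta S^\circ)},
#' \eqn{\Delta H^\circ = \Delta H_{Zn\textrm{-}pep} + \Delta H_{CysH}} and
#' the bond-budget identity of [folding_enthalpy()].
#'
#' @param dh_itc Observed ITC enthalpy, kcal/mol.
#' @param n_h Protons released at the working pH.
#' @param neg_log_kd Competition-derived \eqn{-\log_{10} K_d}.
#' @param n_his Number of His ligands (2 for CCHH).
#' @param constants A [thermo_constants] object.
#' @param reference_dg Optional reference Gibbs energy (kcal/mol) for the
#'   \eqn{\Delta\Delta G^\circ} column; 0 reported when omitted.
#' @return An object of class `thermo_decomposition` with fields `dg`,
#'   `ddg_vs_reference`, `minus_tds`, `dh_itc`, `dh_std`, `dh_cysh`,
#'   `dh_zn_pep`, `dh_folding`, `n_h`, `n_his`.
#' @examples
#' decompose(dh_itc = -20.87, n_h = 1.56, neg_log_kd = 14.49, n_his = 2)
#' @export
decompose <- function(dh_itc, n_h, neg_log_kd, n_his,
                      constants = thermo_constants(), reference_dg = NULL) {
  dh_std <- buffer_corrected_enthalpy(dh_itc, n_h, constants)
  dh_cysh <- cys_deprotonation_enthalpy(n_h, constants)
  dh_zn_pep <- zn_pep_enthalpy(dh_std, dh_cysh)
  dh_folding <- folding_enthalpy(dh_zn_pep, n_his, constants)
  dg <- gibbs_from_neg_log_kd(neg_log_kd, constants)
  minus_tds <- entropy_term(dg, dh_std)
  structure(
    list(dg = dg,
         ddg_vs_reference = if (is.null(reference_dg)) 0 else dg - reference_dg,
         minus_tds = minus_tds, dh_itc = dh_itc, dh_std = dh_std,
         dh_cysh = dh_cysh, dh_zn_pep = dh_zn_pep, dh_folding = dh_folding,
         n_h = n_h, n_his = n_his),
    class = "thermo_decomposition"
  )
}

#' @export
print.thermo_decomposition <- function(x, digits = 2, ...) {
  cat("Zn(II)-binding thermodynamic ledger (kcal/mol):\n")
  cat(sprintf("  dG = %.*f  ddG(ref) = %.*f  -TdS = %.*f\n",
              digits, x$dg, digits, x$ddg_vs_reference, digits, x$minus_tds))
  cat(sprintf("  dH_ITC = %.*f  dH = %.*f  dH_CysH = %.*f\n",
              digits, x$dh_itc, digits, x$dh_std, digits, x$dh_cysh))
  cat(sprintf("  dH_Zn-pep = %.*f  dH_folding = %.*f  (n_H = %.2f, n_His = %d)\n",
              digits, x$dh_zn_pep, digits, x$dh_folding, x$n_h, x$n_his))
  invisible(x)
}

#' @export
as.data.frame.thermo_decomposition <- function(x, ...) {
  data.frame(dg = x$dg, ddg_vs_reference = x$ddg_vs_reference,
             minus_tds = x$minus_tds, dh_itc = x$dh_itc, dh_std = x$dh_std,
             dh_cysh = x$dh_cysh, dh_zn_pep = x$dh_zn_pep,
             dh_folding = x$dh_folding, n_h = x$n_h, n_his = x$n_his)
}
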
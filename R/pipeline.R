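#' Per-peptide input record for the reporting pipeline
#'
#' Bundles everything [run_pipeline()] needs for one peptide. Each stage
#' can be supplied either as data (to be fitted) or as an already-known
#' parameter (to be used directly); missing stages are skipped and
#' flagged.
#'
#' @param peptide_id Unique identifier.
#' @param n_his Number of His ligands in the Zn(II) site (2 for a
#'   classical CCHH finger).
#' @param titration Optional [ph_titration_curve] (fitted for pKa values).
#' @param competition Optional [competition_series] (fitted for Kd).
#' @param itc Optional [itc_experiment] with heats (fitted for dH_ITC).
#' @param pk1,pk2 Optional known thiol pKa values (used when no titration
#'   data are given).
#' @param n_h Optional known proton-release count (overrides pKa-derived
#'   value).
#' @param neg_log_kd Optional known affinity (used when no competition
#'   data are given).
#' @param dh_itc Optional known ITC enthalpy, kcal/mol.
#' @return An object of class `peptide_record`.
#' @export
peptide_record <- function(peptide_id, n_his = 2, titration = NULL,
                           competition = NULL, itc = NULL,
                           pk1 = NULL, pk2 = NULL, n_h = NULL,
                           neg_log_kd = NULL, dh_itc = NULL) {
  if (!nzchar(peptide_id)) zf_error("zf_invalid_input", "peptide_id required")
  structure(
    list(peptide_id = peptide_id, n_his = n_his, titration = titration,
         competition = competition, itc = itc, pk1 = pk1, pk2 = pk2,
         n_h = n_h, neg_log_kd = neg_log_kd, dh_itc = dh_itc),
    class = "peptide_record"
  )
}

#' Construct a thermodynamic ledger directly from its entries
#'
#' Builds a `thermo_decomposition` from externally supplied values (for
#' example a published table row) without recomputing the chain, so that
#' [validate_ledger()] can audit it.
#'
#' @param dg,ddg_vs_reference,minus_tds,dh_itc,dh_std,dh_cysh,dh_zn_pep,dh_folding
#'   Ledger entries, kcal/mol.
#' @param n_h Proton-release count.
#' @param n_his Number of His ligands.
#' @return A `thermo_decomposition` object.
#' @export
as_thermo_decomposition <- function(dg, ddg_vs_reference = 0, minus_tds,
                                    dh_itc, dh_std, dh_cysh, dh_zn_pep,
                                    dh_folding, n_h, n_his = 2) {
  structure(
    list(dg = dg, ddg_vs_reference = ddg_vs_reference,
         minus_tds = minus_tds, dh_itc = dh_itc, dh_std = dh_std,
         dh_cysh = dh_cysh, dh_zn_pep = dh_zn_pep, dh_folding = dh_folding,
         n_h = n_h, n_his = n_his),
    class = "thermo_decomposition"
  )
}

#' Audit the internal consistency of a thermodynamic ledger
#'
#' Checks the three identities every decomposition must satisfy:
#' \enumerate{
#'   \item \eqn{\Delta G^\circ = \Delta H^\circ + (-T\Delta S^\circ)}
#'   \item \eqn{\Delta H^\circ = \Delta H_{Zn\textrm{-}pep} + \Delta H_{CysH}}
#'   \item \eqn{\Delta H_{Zn\textrm{-}pep} = (4-n_{His})\Delta H_{Zn\textrm{-}S}
#'         + n_{His}\Delta H_{Zn\textrm{-}N} + \Delta H_{folding}}
#' }
#' Useful both as a pipeline guard and to audit externally tabulated
#' ledgers, whose rounding can propagate into real inconsistencies.
#'
#' @param decomp A `thermo_decomposition`.
#' @param tol Tolerance, kcal/mol (default 0.05, the propagation of
#'   2-decimal rounding).
#' @param constants A [thermo_constants] for the bond-budget identity.
#' @return Character vector of violation messages; empty iff all
#'   identities hold within `tol`.
#' @export
validate_ledger <- function(decomp, tol = 0.05,
                            constants = thermo_constants()) {
  v <- character(0)
  d1 <- decomp$dg - (decomp$dh_std + decomp$minus_tds)
  if (abs(d1) > tol) {
    v <- c(v, sprintf("dG != dH + (-TdS): off by %.3f kcal/mol", d1))
  }
  d2 <- decomp$dh_std - (decomp$dh_zn_pep + decomp$dh_cysh)
  if (abs(d2) > tol) {
    v <- c(v, sprintf("dH != dH_Zn-pep + dH_CysH: off by %.3f kcal/mol", d2))
  }
  bonds <- (4 - decomp$n_his) * constants$dh_zn_s +
    decomp$n_his * constants$dh_zn_n
  d3 <- decomp$dh_zn_pep - (bonds + decomp$dh_folding)
  if (abs(d3) > tol) {
    v <- c(v, sprintf("dH_Zn-pep != bond budget + dH_folding: off by %.3f kcal/mol", d3))
  }
  v
}

#' Run the full affinity/thermodynamics pipeline over peptide records
#'
#' For each record: fit the pH titration (pKa values) when given, derive
#' `n_h` at the working pH, fit the competition series and convert to Kd,
#' fit the ITC isotherm, then chain the enthalpy decomposition. Affinity
#' and Gibbs-energy difference columns are computed against a reference
#' peptide (by default the highest-affinity record, i.e. largest
#' \eqn{-\log K_d}). Stage failures are caught per peptide and recorded as
#' flags without aborting the run.
#'
#' @param records List of [peptide_record]s with unique ids.
#' @param reference_id Optional id of the reference peptide.
#' @param ph Working pH for `n_h` (default 7.4).
#' @param constants A [thermo_constants] object.
#' @return An object of class `run_report`: `table1` (peptide,
#'   neg_log_kd, kd_fM, delta_neg_log_kd), `table2` (full ledger columns),
#'   `decompositions` (named list), `flags` (named list of per-peptide
#'   messages), `reference_id`, `metadata`.
#' @export
run_pipeline <- function(records, reference_id = NULL, ph = 7.4,
                         constants = thermo_constants()) {
  ids <- vapply(records, `[[`, "", "peptide_id")
  if (anyDuplicated(ids)) {
    zf_error("zf_invalid_input", "peptide_id values must be unique")
  }
  if (!is.null(reference_id) && !reference_id %in% ids) {
    zf_error("zf_invalid_input", "reference_id not among the records")
  }
  res <- list()
  flags <- list()
  for (rec in records) {
    id <- rec$peptide_id
    fl <- character(0)
    note <- function(stage, e) {
      fl <<- c(fl, sprintf("%s: %s", stage, conditionMessage(e)))
      NULL
    }
    pka <- NULL
    if (!is.null(rec$titration)) {
      pka <- tryCatch(fit_pka(rec$titration), error = function(e) note("pka", e))
    }
    pk1 <- if (!is.null(pka)) pka$pk1 else rec$pk1
    pk2 <- if (!is.null(pka)) pka$pk2 else rec$pk2
    n_h <- rec$n_h
    if (is.null(n_h) && !is.null(pk1) && !is.null(pk2)) {
      n_h <- average_protonation(pk1, pk2, ph)
    }
    kd <- NULL
    if (!is.null(rec$competition)) {
      kd <- tryCatch(kd_from_hill(fit_hill(rec$competition), ph = ph),
                     error = function(e) note("hill", e))
    }
    nlk <- if (!is.null(kd)) kd$neg_log_kd else rec$neg_log_kd
    dh_itc <- rec$dh_itc
    if (is.null(dh_itc) && !is.null(rec$itc)) {
      fitted <- tryCatch(fit_isotherm(rec$itc), error = function(e) note("itc", e))
      if (!is.null(fitted)) dh_itc <- fitted$dh_itc
    }
    if (is.null(nlk)) fl <- c(fl, "affinity: no competition data or neg_log_kd")
    if (is.null(dh_itc)) fl <- c(fl, "itc: no isotherm data or dh_itc")
    if (is.null(n_h)) fl <- c(fl, "protonation: no pKa data or n_h")
    res[[id]] <- list(pk1 = pk1, pk2 = pk2, n_h = n_h,
                      neg_log_kd = nlk, dh_itc = dh_itc,
                      n_his = rec$n_his)
    flags[[id]] <- fl
  }
  # reference: requested id, else highest affinity among records with a Kd
  nlks <- vapply(res, function(r) {
    if (is.null(r$neg_log_kd)) NA_real_ else r$neg_log_kd
  }, numeric(1))
  if (is.null(reference_id)) {
    if (all(is.na(nlks))) {
      zf_error("zf_invalid_input", "no record carries an affinity")
    }
    reference_id <- names(nlks)[which.max(nlks)]
  }
  ref_nlk <- nlks[[reference_id]]
  ref_dg <- if (is.finite(ref_nlk)) {
    gibbs_from_neg_log_kd(ref_nlk, constants)
  } else NA_real_
  decomps <- list()
  t1 <- t2 <- NULL
  for (id in names(res)) {
    r <- res[[id]]
    nlk <- r$neg_log_kd
    t1 <- rbind(t1, data.frame(
      peptide = id,
      neg_log_kd = if (is.null(nlk)) NA_real_ else nlk,
      kd_fM = if (is.null(nlk)) NA_real_ else 10^(-nlk) * 1e15,
      delta_neg_log_kd = if (is.null(nlk) || is.na(ref_nlk)) NA_real_
                         else ref_nlk - nlk))
    complete <- !is.null(nlk) && !is.null(r$dh_itc) && !is.null(r$n_h)
    if (complete) {
      dec <- decompose(r$dh_itc, r$n_h, nlk, r$n_his, constants,
                       reference_dg = ref_dg)
      bad <- validate_ledger(dec, constants = constants)
      if (length(bad) > 0) {
        flags[[id]] <- c(flags[[id]], paste("ledger:", bad))
      }
      decomps[[id]] <- dec
      t2 <- rbind(t2, cbind(peptide = id, as.data.frame(dec)))
    }
  }
  structure(
    list(table1 = t1, table2 = t2, decompositions = decomps,
         flags = flags, reference_id = reference_id,
         metadata = list(ph = ph,
                         package_version = as.character(utils::packageVersion("zfthermo")),
                         constants = unclass(constants))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline report (reference: %s)\n", x$reference_id))
  cat("\nAffinity table:\n")
  print(x$table1, row.names = FALSE, digits = 4)
  if (!is.null(x$table2)) {
    cat("\nThermodynamic ledger (kcal/mol):\n")
    print(x$table2, row.names = FALSE, digits = 4)
  }
  n_fl <- sum(lengths(x$flags) > 0)
  if (n_fl > 0) {
    cat(sprintf("\n%d peptide(s) carry flags; see $flags\n", n_fl))
  }
  invisible(x)
}

#' Write a pipeline report to CSV and JSON
#'
#' Emits `table1.csv` (affinities), `table2.csv` (ledger) and
#' `report.json` (both tables plus flags and metadata) under `dir`.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$table1, file.path(dir, "table1.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(report$table2)) {
    write.csv(report$table2, file.path(dir, "table2.csv"),
              row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(reference_id = report$reference_id, table1 = report$table1,
         table2 = report$table2, flags = report$flags,
         metadata = report$metadata),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
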
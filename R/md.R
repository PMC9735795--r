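#' Parameters of the rational switching function
#'
#' @param r0 Reference distance, Angstrom (default 2.8, the Zn-ligand
#'   contact cut-off).
#' @param n_exp,m_exp Numerator and denominator exponents (defaults 8 and
#'   12); must satisfy `0 < n_exp < m_exp`.
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(r0 = 2.8, n_exp = 8, m_exp = 12) {
  if (r0 <= 0) zf_error("zf_invalid_input", "r0 must be positive")
  if (!(n_exp > 0 && m_exp > n_exp)) {
    zf_error("zf_invalid_input", "exponents must satisfy 0 < n_exp < m_exp")
  }
  structure(list(r0 = r0, n_exp = n_exp, m_exp = m_exp),
            class = "switching_params")
}

#' Rational switching function for smooth contact counting
#'
#' \deqn{s(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m}}
#' the PLUMED-style coordination kernel: \eqn{s(0)=1}, strictly
#' decreasing, and \eqn{s \to 0} as \eqn{r \to \infty}. The removable
#' singularity at \eqn{r = r_0} evaluates to \eqn{n/m}; a first-order
#' expansion is used in a narrow window around \eqn{r_0} for numerical
#' continuity.
#'
#' @param r Distance(s), Angstrom, nonnegative.
#' @param params A [switching_params] object.
#' @return s(r), dimensionless in (0, 1\].
#' @examples
#' switching_value(2.8)                 # 8/12
#' switching_value(5.6)                 # 255/4095
#' @export
switching_value <- function(r, params = switching_params()) {
  if (any(r < 0)) zf_error("zf_invalid_input", "distances must be nonnegative")
  x <- r / params$r0
  n <- params$n_exp; m <- params$m_exp
  s <- (1 - x^n) / (1 - x^m)
  near <- abs(x - 1) < 1e-8
  if (any(near)) {
    # L'Hopital limit n/m with first-order correction in (x - 1)
    s[near] <- (n / m) * (1 + (n - m) / 2 * (x[near] - 1))
  }
  s
}

#' Smooth Zn-ligand contact number for one frame
#'
#' Sum of [switching_value()] over all pairs between the Zn(II) atom and
#' the coordinating atoms of one ligand residue (Sgamma for Cys, the
#' coordinating N for His).
#'
#' @param frame Numeric matrix of coordinates (rows = atoms, columns
#'   x/y/z, Angstrom) with atom identifiers as row names.
#' @param zn_id Row name of the Zn(II) atom.
#' @param ligand_atom_ids Row names of the ligand atoms.
#' @param params A [switching_params] object.
#' @return Contact number, dimensionless.
#' @export
contact_number <- function(frame, zn_id, ligand_atom_ids,
                           params = switching_params()) {
  ids <- rownames(frame)
  missing <- setdiff(c(zn_id, ligand_atom_ids), ids)
  if (length(missing) > 0) {
    zf_error("zf_selection_error",
             paste("atoms not present in frame:", paste(missing, collapse = ", ")))
  }
  zn <- frame[zn_id, ]
  lig <- frame[ligand_atom_ids, , drop = FALSE]
  d <- sqrt(rowSums(sweep(lig, 2, zn)^2))
  sum(switching_value(d, params))
}

#' Per-ligand contact-number time series over a trajectory
#'
#' @param traj A [trajectory] object.
#' @param zn_id Atom id of the Zn(II) ion.
#' @param ligand_selections Named list mapping each ligand id (e.g.
#'   `"Cys3"`) to the atom id(s) of its coordinating atom(s).
#' @param params A [switching_params] object.
#' @return An object of class `contact_series`: a frames x ligands numeric
#'   matrix of contact numbers.
#' @export
contact_series <- function(traj, zn_id, ligand_selections,
                           params = switching_params()) {
  stopifnot(inherits(traj, "trajectory"))
  cn <- vapply(traj$frames, function(fr) {
    vapply(ligand_selections, function(sel) {
      contact_number(fr, zn_id, sel, params)
    }, numeric(1))
  }, numeric(length(ligand_selections)))
  cn <- t(matrix(cn, nrow = length(ligand_selections),
                 dimnames = list(names(ligand_selections), NULL)))
  structure(cn, class = c("contact_series", class(cn)))
}

#' Classify the Zn-ligand dissociation pathway of one pulling run
#'
#' A ligand is scored as released at the first frame opening a run of at
#' least `persistence` consecutive frames with contact number below
#' `bound_threshold` (brief sub-threshold dips shorter than `persistence`
#' are treated as rebinding and ignored). Ligands already below threshold
#' at the first frame are flagged as pre-dissociated and excluded from the
#' release order. Intermediates are labelled ZnL4 down to ZnL(4-k) after
#' the k-th release.
#'
#' @param series A [contact_series] (frames x ligands matrix).
#' @param bound_threshold Contact number below which a ligand counts as
#'   detached (default 0.5 per coordinating atom).
#' @param persistence Minimum number of consecutive sub-threshold frames
#'   for a release to count (default 50).
#' @return An object of class `dissociation_pathway`: `release_order`
#'   (data frame `ligand`, `frame`), `intermediate_labels`,
#'   `pre_dissociated` (character vector).
#' @export
classify_pathway <- function(series, bound_threshold = 0.5, persistence = 50) {
  cn <- unclass(series)
  if (is.null(colnames(cn))) {
    zf_error("zf_invalid_input", "contact series must carry ligand names")
  }
  ligands <- colnames(cn)
  release_frame <- setNames(rep(NA_real_, length(ligands)), ligands)
  pre <- character(0)
  for (lig in ligands) {
    below <- cn[, lig] < bound_threshold
    if (below[1]) {
      pre <- c(pre, lig)
      next
    }
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(r$values & r$lengths >= persistence)
    if (length(ok) > 0) release_frame[lig] <- starts[ok[1]]
  }
  released <- release_frame[!is.na(release_frame)]
  o <- order(released)
  order_df <- data.frame(ligand = names(released)[o],
                         frame = as.integer(released[o]))
  k <- nrow(order_df)
  structure(
    list(release_order = order_df,
         intermediate_labels = paste0("ZnL", 4 - seq_len(k + 1) + 1),
         pre_dissociated = pre),
    class = "dissociation_pathway"
  )
}

#' @export
print.dissociation_pathway <- function(x, ...) {
  if (nrow(x$release_order) == 0) {
    cat("Dissociation pathway: no release events (ZnL4 throughout)\n")
  } else {
    cat(sprintf("Dissociation pathway: %s (%s)\n",
                paste(x$release_order$ligand, collapse = " > "),
                paste(x$intermediate_labels, collapse = " -> ")))
  }
  if (length(x$pre_dissociated) > 0) {
    cat("  pre-dissociated:", paste(x$pre_dissociated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Census of dissociation pathways across replicas
#'
#' Tallies the ordered ligand-release signatures over a set of pulling
#' replicas, e.g. to report a dominant unbinding mechanism.
#'
#' @param pathways Nonempty list of [classify_pathway()] results.
#' @return Data frame with columns `signature` (ligand order joined by
#'   `>`), `count`, `fraction` (summing to 1), sorted by decreasing count.
#' @export
pathway_census <- function(pathways) {
  if (length(pathways) == 0) {
    zf_error("zf_invalid_input", "pathway list must be nonempty")
  }
  sigs <- vapply(pathways, function(p) {
    paste(p$release_order$ligand, collapse = ">")
  }, character(1))
  tab <- sort(table(sigs), decreasing = TRUE)
  data.frame(signature = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(sigs),
             row.names = NULL)
}

#' Rupture forces and pulling work of one steered-MD replica
#'
#' For each release event the rupture force is the maximum pulling force
#' in the window from the preceding release (or the first frame) up to the
#' event frame; the per-replica rupture force is the global force maximum;
#' the total work is the trapezoidal integral of force over the reaction
#' coordinate.
#'
#' @param traj A [trajectory] with `pulling_force` and
#'   `reaction_coordinate` channels.
#' @param series The [contact_series] of the run (kept for provenance).
#' @param pathway The [classify_pathway()] result for the run.
#' @return An object of class `rupture_stats`: `per_event` (data frame
#'   `ligand`, `frame`, `force`), `rupture_force` (global maximum),
#'   `total_work` (kcal/mol).
#' @export
rupture_statistics <- function(traj, series, pathway) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$pulling_force
  rc <- traj$reaction_coordinate
  if (is.null(f) || is.null(rc)) {
    zf_error("zf_unavailable_channel",
             "trajectory carries no pulling_force/reaction_coordinate channel")
  }
  ev <- pathway$release_order
  per_event <- data.frame(ligand = character(0), frame = integer(0),
                          force = numeric(0))
  prev <- 0L
  if (nrow(ev) > 0) {
    force_at <- numeric(nrow(ev))
    for (k in seq_len(nrow(ev))) {
      win <- (prev + 1L):ev$frame[k]
      force_at[k] <- max(f[win])
      prev <- ev$frame[k]
    }
    per_event <- data.frame(ligand = ev$ligand, frame = ev$frame,
                            force = force_at)
  }
  structure(
    list(per_event = per_event,
         rupture_force = max(f),
         total_work = pracma::trapz(rc, f)),
    class = "rupture_stats"
  )
}

#' Summarise rupture statistics over replicas
#'
#' @param stats_list List of [rupture_statistics()] results.
#' @return List with `per_replica_rupture_force`, `mean_rupture_force`,
#'   `per_replica_work`, `mean_total_work`.
#' @export
rupture_summary <- function(stats_list) {
  rf <- vapply(stats_list, `[[`, numeric(1), "rupture_force")
  w <- vapply(stats_list, `[[`, numeric(1), "total_work")
  list(per_replica_rupture_force = rf, mean_rupture_force = mean(rf),
       per_replica_work = w, mean_total_work = mean(w))
}

#' Probability-based free-energy surface over two projection coordinates
#'
#' Bins samples (typically projections onto the first two principal
#' components of the alpha-carbon covariance) on a regular 2-D grid and
#' converts occupation probabilities to free energies,
#' \eqn{F = -RT\,\ln(p/p_{max})}, so the most populated cell sits at 0 and
#' empty cells are infinite. Local minima are grid cells not exceeded by
#' any of their 8 neighbours.
#'
#' @param xy_samples Two-column matrix or data frame of projected samples
#'   (at least 100 rows).
#' @param bins Number of bins per axis (default 30).
#' @param temperature Temperature, K.
#' @param gas_constant R, kcal/(mol K).
#' @return An object of class `fes_2d`: `free_energy` (bins x bins
#'   matrix, kcal/mol), `x_breaks`, `y_breaks`, `minima` (data frame
#'   `i`, `j`, `free_energy`).
#' @export
free_energy_surface <- function(xy_samples, bins = 30,
                                temperature = 298.15,
                                gas_constant = 1.9872e-3) {
  xy <- as.matrix(xy_samples)
  if (nrow(xy) < 100) {
    zf_error("zf_insufficient_data",
             "free_energy_surface needs at least 100 samples")
  }
  if (ncol(xy) != 2) {
    zf_error("zf_invalid_input", "xy_samples must have exactly two columns")
  }
  pad <- function(r) {
    if (diff(r) == 0) r + c(-0.5, 0.5) else r + c(-1, 1) * 1e-9 * diff(r)
  }
  xb <- seq(pad(range(xy[, 1]))[1], pad(range(xy[, 1]))[2], length.out = bins + 1)
  yb <- seq(pad(range(xy[, 2]))[1], pad(range(xy[, 2]))[2], length.out = bins + 1)
  ix <- findInterval(xy[, 1], xb, rightmost.closed = TRUE)
  iy <- findInterval(xy[, 2], yb, rightmost.closed = TRUE)
  counts <- matrix(0, bins, bins)
  for (k in seq_len(nrow(xy))) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  p <- counts / nrow(xy)
  fe <- matrix(Inf, bins, bins)
  nz <- p > 0
  fe[nz] <- -gas_constant * temperature * log(p[nz] / max(p))
  # local minima on the 8-neighbour stencil (Inf neighbours count as higher)
  minima <- data.frame(i = integer(0), j = integer(0), free_energy = numeric(0))
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      if (!is.finite(fe[i, j])) next
      nb <- expand.grid(di = -1:1, dj = -1:1)
      nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
      ii <- i + nb$di; jj <- j + nb$dj
      keep <- ii >= 1 & ii <= bins & jj >= 1 & jj <= bins
      vals <- fe[cbind(ii[keep], jj[keep])]
      if (all(fe[i, j] <= vals)) {
        minima <- rbind(minima, data.frame(i = i, j = j,
                                           free_energy = fe[i, j]))
      }
    }
  }
  structure(
    list(free_energy = fe, x_breaks = xb, y_breaks = yb, minima = minima),
    class = "fes_2d"
  )
}

#' @export
print.fes_2d <- function(x, ...) {
  cat(sprintf("2-D free-energy surface: %d x %d bins, %d local minima\n",
              nrow(x$free_energy), ncol(x$free_energy), nrow(x$minima)))
  invisible(x)
}
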
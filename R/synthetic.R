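#' Synthetic pH-titration curve with known ground truth
#'
#' Evaluates the two-proton dissociation model on a pH grid and adds
#' additive Gaussian noise, emulating a spectrophotometric titration of an
#' acidified apo zinc finger carried through both thiol transitions
#' (default grid: pH 3 to 11 in steps of 0.1). Default plateaus correspond
#' to a 25 uM peptide whose two thiolates each add ~0.2 AU at 218 nm.
#' Deterministic for a fixed seed; the generating parameters are attached
#' as the `truth` attribute.
#'
#' @param pk1,pk2 Macroscopic thiol pKa values (`pk1 <= pk2`).
#' @param a0,a1,a2 Plateau absorbances (AU) of the fully protonated,
#'   singly and doubly deprotonated species.
#' @param ph_grid pH sampling grid.
#' @param noise_sd Gaussian noise standard deviation, AU.
#' @param seed RNG seed.
#' @param peptide_id Identifier stored on the curve.
#' @return A [ph_titration_curve] with attribute `truth`.
#' @export
gen_ph_titration <- function(pk1 = 7.6, pk2 = 8.8, a0 = 0.10, a1 = 0.30,
                             a2 = 0.50, ph_grid = seq(3, 11, by = 0.1),
                             noise_sd = 0.002, seed = 1,
                             peptide_id = "synthetic") {
  if (pk1 > pk2) zf_error("zf_invalid_input", "pk1 must not exceed pk2")
  a <- .eq3_absorbance(ph_grid, pk1, pk2, a0, a1, a2)
  if (noise_sd > 0) {
    a <- a + with_seed(seed, rnorm(length(a), sd = noise_sd))
  }
  out <- ph_titration_curve(ph_grid, a, peptide_id = peptide_id)
  attr(out, "truth") <- list(pk1 = pk1, pk2 = pk2, a0 = a0, a1 = a1, a2 = a2,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic chelator-competition ellipticity series
#'
#' Hill-equation saturation curve over a pZn grid centred on the
#' transition, with Gaussian noise proportional to the signal range.
#' Defaults emulate a folding Cys2His2 peptide monitored near 220 nm:
#' apo plateau around -3000 and Zn(II)-saturated plateau around
#' -11000 deg cm^2 dmol^-1, Kd in the sub-picomolar regime.
#'
#' @param kd Ground-truth dissociation constant, M (equals the
#'   half-saturation free Zn(II)).
#' @param hill_n Hill coefficient.
#' @param theta_min,theta_max Saturated (high free Zn) and apo plateaus,
#'   deg cm^2 dmol^-1.
#' @param pzn_grid pZn sampling grid; default 15 points spanning +/- 1.4
#'   units around `-log10(kd)`.
#' @param noise_frac Noise SD as a fraction of the plateau-to-plateau
#'   range.
#' @param seed RNG seed.
#' @param peptide_id Identifier stored on the series.
#' @return A [competition_series] with attribute `truth`.
#' @export
gen_competition_series <- function(kd = 5e-13, hill_n = 1,
                                   theta_min = -11000, theta_max = -3000,
                                   pzn_grid = NULL, noise_frac = 0.01,
                                   seed = 1, peptide_id = "synthetic") {
  if (kd <= 0) zf_error("zf_invalid_input", "kd must be positive")
  if (is.null(pzn_grid)) {
    pzn_grid <- seq(-log10(kd) - 1.4, -log10(kd) + 1.4, by = 0.2)
  }
  x <- 10^(-pzn_grid)
  th <- .hill_theta(x, theta_min, theta_max, hill_n, kd)
  if (noise_frac > 0) {
    sd <- noise_frac * abs(theta_max - theta_min)
    th <- th + with_seed(seed, rnorm(length(th), sd = sd))
  }
  out <- competition_series(pzn_grid, th, peptide_id = peptide_id)
  attr(out, "truth") <- list(kd = kd, hill_n = hill_n,
                             theta_min = theta_min, theta_max = theta_max,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Synthetic single-site ITC isotherm
#'
#' Forward-simulates [simulate_isotherm()] on an injection design and adds
#' heat noise proportional to the absolute heat plus a floor term,
#' emulating integrated per-injection heats of a Zn(II)-into-peptide
#' titration (default design: 25 x 6.82 uL of 0.35 mM Zn(II) into 30 uM
#' peptide in a 1 mL cell).
#'
#' @param kb Ground-truth association constant, 1/M.
#' @param dh Ground-truth binding enthalpy, kcal/mol.
#' @param n Ground-truth stoichiometry.
#' @param design An [itc_experiment] design (heats ignored).
#' @param dilution_offset Constant per-injection heat, ucal.
#' @param noise_frac Proportional noise fraction.
#' @param noise_floor Additive noise floor, ucal.
#' @param seed RNG seed.
#' @return An [itc_experiment] carrying the noisy heats, with attribute
#'   `truth`.
#' @export
gen_itc_isotherm <- function(kb = 1e8, dh = -20, n = 1,
                             design = default_itc_design(),
                             dilution_offset = 0, noise_frac = 0.01,
                             noise_floor = 0.05, seed = 1) {
  q <- simulate_isotherm(kb, dh, n, design, dilution_offset)
  if (noise_frac > 0 || noise_floor > 0) {
    sd <- noise_frac * abs(q) + noise_floor
    q <- q + with_seed(seed, rnorm(length(q), sd = sd))
  }
  out <- design
  out$heats <- q
  attr(out, "truth") <- list(kb = kb, dh = dh, n = n,
                             dilution_offset = dilution_offset,
                             noise_frac = noise_frac, seed = seed)
  out
}

# sawtooth rupture peak: linear rise to `peak` at frame f0, collapse back
# to zero within `fall` frames (force releases once the bond breaks)
.rupture_peak <- function(t, f0, peak, rise, fall = 2) {
  ifelse(t <= f0, pmax(0, peak * (1 - (f0 - t) / rise)),
         pmax(0, peak * (1 - (t - f0) / fall)))
}

# unit directions (tetrahedral-like) for the four ligand atoms
.ligand_directions <- function() {
  d <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  d / sqrt(3)
}

#' Synthetic steered-MD pulling trajectory with scripted release order
#'
#' Builds a minimal Zn(Cys2His2)-site trajectory: the Zn(II) atom at the
#' origin and one coordinating atom per ligand (Cys Sgamma / His N)
#' placed along fixed directions. Each ligand sits at a bound distance
#' (~2.3 A) until its scripted release frame, ramps to an unbound distance
#' (> 8 A) over a few frames, and stays released. Coordinates carry
#' uniform-in-sphere jitter small enough not to defeat the persistence
#' criterion. The force channel is a small baseline plus one sawtooth peak
#' per release event (linear build-up to the release frame, rapid collapse
#' once the bond breaks); the reaction coordinate grows linearly.
#'
#' @param release_order Character vector of ligand ids in release order.
#' @param release_frames Strictly increasing release frames, same length.
#' @param frame_count Total frames (must exceed the last release by a
#'   comfortable persistence margin).
#' @param noise_amplitude Coordinate jitter radius, Angstrom.
#' @param force_peaks Peak heights (kcal mol^-1 A^-1), one per release;
#'   the first event is typically the hardest.
#' @param force_baseline Baseline force level.
#' @param peak_half_width Rise length of each force peak, frames.
#' @param seed RNG seed.
#' @return A [trajectory] with `pulling_force` and `reaction_coordinate`
#'   channels and attribute `truth`.
#' @export
gen_smd_trajectory <- function(release_order = c("Cys3", "His19", "His23", "Cys6"),
                               release_frames = c(150, 300, 450, 600),
                               frame_count = 700, noise_amplitude = 0.05,
                               force_peaks = c(100, 65, 60, 75),
                               force_baseline = 5, peak_half_width = 30,
                               seed = 1) {
  if (length(release_order) != length(release_frames)) {
    zf_error("zf_invalid_input", "release_order and release_frames lengths differ")
  }
  if (any(diff(release_frames) <= 0)) {
    zf_error("zf_invalid_input", "release_frames must be strictly increasing")
  }
  if (length(force_peaks) < length(release_frames)) {
    force_peaks <- rep_len(force_peaks, length(release_frames))
  }
  ligands <- release_order
  dirs <- .ligand_directions()[seq_along(ligands), , drop = FALSE]
  bound_d <- 2.3; unbound_d <- 9; ramp <- 10
  dist_profile <- function(f_rel, t) {
    # bound until f_rel, linear ramp over `ramp` frames, then drift out
    ifelse(t < f_rel, bound_d,
           ifelse(t < f_rel + ramp,
                  bound_d + (unbound_d - bound_d) * (t - f_rel + 1) / ramp,
                  unbound_d + 0.01 * (t - f_rel - ramp)))
  }
  t <- seq_len(frame_count)
  with_seed(seed, {
    jitter <- function() {
      # uniform within a sphere of radius noise_amplitude
      v <- matrix(rnorm(3 * frame_count), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      v * noise_amplitude * runif(frame_count)^(1 / 3)
    }
    dmat <- vapply(seq_along(ligands), function(k) {
      dist_profile(release_frames[k], t)
    }, numeric(frame_count))
    jit <- lapply(seq_along(ligands), function(k) jitter())
    frames <- lapply(t, function(i) {
      m <- rbind(Zn = c(0, 0, 0),
                 do.call(rbind, lapply(seq_along(ligands), function(k) {
                   dirs[k, ] * dmat[i, k] + jit[[k]][i, ]
                 })))
      rownames(m) <- c("Zn", ligands)
      m
    })
    force <- rep(force_baseline, frame_count)
    for (k in seq_along(release_frames)) {
      force <- pmax(force, force_baseline +
                      .rupture_peak(t, release_frames[k], force_peaks[k],
                                    rise = peak_half_width))
    }
    rc <- seq(2, 12, length.out = frame_count)
    out <- trajectory(frames, pulling_force = force,
                      reaction_coordinate = rc)
  })
  attr(out, "truth") <- list(release_order = release_order,
                             release_frames = release_frames,
                             force_peaks = force_peaks[seq_along(release_frames)],
                             seed = seed)
  out
}

#' Convenience ligand selections for generated pulling trajectories
#'
#' @param ligands Ligand ids (defaults to the classical CCHH set).
#' @return Named list mapping each ligand id to its single coordinating
#'   atom id, as expected by [contact_series()].
#' @export
smd_ligand_selections <- function(ligands = c("Cys3", "Cys6", "His19", "His23")) {
  setNames(as.list(ligands), ligands)
}

#' Synthetic hydrogen-bond test structure with exact geometry
#'
#' Places one donor/hydrogen/acceptor triplet per specification row at an
#' exactly requested donor-acceptor distance and deviation-from-linearity,
#' widely separated (50 A) so triplets cannot cross-talk. The D-H bond
#' length is 1.0 A. Expected pass/fail labels under the default criteria
#' (distance < 3 A, deviation < 20 degrees) are recorded.
#'
#' @param specs Data frame with columns `d_a` (donor-acceptor distance,
#'   Angstrom) and `dev_deg` (deviation from linearity, degrees).
#' @param d_max,angle_max Criteria used for the expected labels.
#' @return List with `coords` (matrix, atoms x 3), `donors` (data frame
#'   `donor`, `hydrogen`), `acceptors`, and `expected` (the specs plus a
#'   logical `should_pass` column).
#' @export
gen_hbond_structure <- function(specs, d_max = 3.0, angle_max = 20.0) {
  specs <- as.data.frame(specs)
  if (!all(c("d_a", "dev_deg") %in% names(specs))) {
    zf_error("zf_invalid_input", "specs needs columns d_a and dev_deg")
  }
  coords <- NULL; donors <- NULL; acceptors <- character(0)
  for (k in seq_len(nrow(specs))) {
    d <- specs$d_a[k]; dev <- specs$dev_deg[k] * pi / 180
    if (d <= 1 || specs$dev_deg[k] < 0 || specs$dev_deg[k] >= 90) {
      zf_error("zf_invalid_spec",
               "need d_a > 1 A (D-H bond length) and deviation in [0, 90)")
    }
    # D at origin, H at (1,0,0); A along a ray from H making the requested
    # deviation, at ray length t solving |A - D| = d
    disc <- cos(dev)^2 - 1 + d^2
    if (disc < 0) zf_error("zf_invalid_spec", "geometrically infeasible spec")
    t_ray <- -cos(dev) + sqrt(disc)
    off <- c(0, 50 * (k - 1), 0)
    D <- off; H <- off + c(1, 0, 0)
    A <- H + t_ray * c(cos(dev), 0, sin(dev))
    block <- rbind(D, H, A)
    rownames(block) <- paste0(c("D", "H", "A"), k)
    coords <- rbind(coords, block)
    donors <- rbind(donors, data.frame(donor = paste0("D", k),
                                       hydrogen = paste0("H", k)))
    acceptors <- c(acceptors, paste0("A", k))
  }
  expected <- specs
  expected$should_pass <- specs$d_a < d_max & specs$dev_deg < angle_max
  list(coords = coords, donors = donors, acceptors = acceptors,
       expected = expected)
}

#' Write a generated hydrogen-bond structure to a PDB file
#'
#' @param hb Result of [gen_hbond_structure()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_hbond_pdb <- function(hb, path) {
  m <- hb$coords
  n <- nrow(m)
  bio3d::write.pdb(file = path, xyz = .as_xyz_vec(m),
                   resno = rep(seq_len(n %/% 3 + (n %% 3 > 0)), each = 3)[seq_len(n)],
                   resid = rep("HBX", n),
                   elety = rownames(m))
  invisible(path)
}
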
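# Independent oracles used across the suite. Each one re-derives the
# quantity by a different route (bisection, grid search, stepwise
# equilibria, exhaustive geometry) so that agreement is informative.

# Average protonation via stepwise macrostate concentrations:
# [LH]/[L] = [H]/Ka2, [LH2]/[LH] = [H]/Ka1.
oracle_protonation <- function(pk1, pk2, ph) {
  h <- 10^(-ph)
  c_l <- 1
  c_lh <- c_l * h / 10^(-pk2)
  c_lh2 <- c_lh * h / 10^(-pk1)
  (c_lh + 2 * c_lh2) / (c_l + c_lh + c_lh2)
}

# Free Zn in the one-complex metal buffer by log-space bisection on the
# monotone mass-balance polynomial z * (1 + beta * (L - Z + z)) - Z = 0.
oracle_free_zn <- function(beta_cond, l_tot, zn_tot, lo = 1e-25) {
  f <- function(z) z * (1 + beta_cond * (l_tot - zn_tot + z)) - zn_tot
  hi <- zn_tot
  for (i in 1:300) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# Free Zn with a competing peptide: coarse grid bracket over
# [Zn] in 10^-18..10^-6, then bisection on the three-species balance.
oracle_free_zn_peptide <- function(beta_cond, l_tot, zn_tot, pep_tot, pep_kd) {
  total_at <- function(z) {
    l <- l_tot / (1 + beta_cond * z)
    z + beta_cond * z * l + pep_tot * z / (z + pep_kd)
  }
  grid <- 10^seq(-18, -6, by = 0.05)
  resid <- vapply(grid, total_at, numeric(1)) - zn_tot
  k <- which(diff(sign(resid)) != 0)[1]
  lo <- grid[k]; hi <- grid[k + 1]
  for (i in 1:300) {
    mid <- sqrt(lo * hi)
    if (total_at(mid) > zn_tot) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# Per-injection ITC heats with the complex concentration found by
# bisection on the mass-action residual instead of the closed form.
oracle_itc_heats <- function(kb, dh, n, design, offset = 0) {
  v0 <- design$cell_volume * 1e-3
  p <- design$cell_concentration
  x <- 0; c_prev <- 0
  q <- numeric(length(design$injection_volumes))
  for (i in seq_along(q)) {
    v <- design$injection_volumes[i] * 1e-6
    dil <- 1 - v / v0
    p <- p * dil
    x <- x * dil + design$syringe_concentration * (v / v0)
    s <- n * p
    f <- function(cc) kb * (s - cc) * (x - cc) - cc
    lo <- 0; hi <- min(s, x)
    for (j in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    cc <- (lo + hi) / 2
    q[i] <- dh * (cc - c_prev * dil) * v0 * 1e9 + offset
    c_prev <- cc
  }
  q
}

# Exhaustive O(N^2) hydrogen-bond check with independently written
# geometry (law of cosines for the linearity deviation).
oracle_hbonds <- function(coords, donors, acceptors, d_max = 3, angle_max = 20) {
  hits <- list()
  for (k in seq_len(nrow(donors))) {
    D <- coords[donors$donor[k], ]
    H <- coords[donors$hydrogen[k], ]
    for (a in acceptors) {
      if (a %in% c(donors$donor[k], donors$hydrogen[k])) next
      A <- coords[a, ]
      da <- sqrt(sum((A - D)^2))
      dh <- sqrt(sum((D - H)^2))
      ha <- sqrt(sum((A - H)^2))
      cos_dha <- (dh^2 + ha^2 - da^2) / (2 * dh * ha)
      dev <- 180 - acos(min(max(cos_dha, -1), 1)) * 180 / pi
      if (da < d_max && dev < angle_max) {
        hits[[length(hits) + 1]] <- c(donor = donors$donor[k], acceptor = a)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(donor = character(0), acceptor = character(0)))
  }
  as.data.frame(do.call(rbind, hits))
}

# Standard CCHH ligand set used by the pulling-trajectory tests.
cchh_ligands <- c("Cys3", "Cys6", "His19", "His23")
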
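test_that("switching function matches direct evaluation and its limit", {
  expect_equal(switching_value(0), 1)
  expect_equal(switching_value(2.8), 8 / 12)
  expect_equal(switching_value(5.6), (1 - 2^8) / (1 - 2^12))
  # continuity through the removable singularity
  for (eps in c(1e-9, -1e-9)) {
    expect_lt(abs(switching_value(2.8 + eps) - 8 / 12), 1e-6)
  }
})

test_that("switching function is bounded and strictly decreasing", {
  set.seed(5)
  for (i in 1:20) {
    m <- sample(3:14, 1)
    n <- sample(seq_len(m - 1), 1)
    p <- switching_params(r0 = runif(1, 1, 5), n_exp = n, m_exp = m)
    r <- seq(0, 4 * p$r0, length.out = 400)
    s <- switching_value(r, p)
    expect_true(all(s > 0 & s <= 1))
    # nonincreasing everywhere; strictly decreasing once clear of the
    # floating-point plateau at s = 1 near r = 0
    expect_true(all(diff(s) <= 0))
    s_mid <- switching_value(seq(0.5 * p$r0, 3 * p$r0, length.out = 200), p)
    expect_true(all(diff(s_mid) < 0))
  }
  expect_error(switching_params(n_exp = 12, m_exp = 8),
               class = "zf_invalid_input")
})

test_that("contact number sums switching values over the selection", {
  fr <- rbind(Zn = c(0, 0, 0), S1 = c(2, 0, 0), S2 = c(0, 2, 0),
              FAR = c(200, 0, 0))
  expect_equal(contact_number(fr, "Zn", "S1"), switching_value(2))
  expect_equal(contact_number(fr, "Zn", c("S1", "S2")),
               2 * switching_value(2))
  # the rational tail decays as (r/r0)^(n-m): negligible for detached atoms
  expect_lt(contact_number(fr, "Zn", "FAR"), 1e-6)
  expect_error(contact_number(fr, "Zn", "missing"),
               class = "zf_selection_error")
})

test_that("pathway classifier recovers the scripted release order", {
  tr <- gen_smd_trajectory(seed = 1)
  cs <- contact_series(tr, "Zn", smd_ligand_selections(cchh_ligands))
  pw <- classify_pathway(cs)
  expect_equal(pw$release_order$ligand, c("Cys3", "His19", "His23", "Cys6"))
  expect_true(all(diff(pw$release_order$frame) > 0))
  expect_equal(pw$intermediate_labels,
               c("ZnL4", "ZnL3", "ZnL2", "ZnL1", "ZnL0"))
})

test_that("classifier recovers random scripted orders across replicas", {
  set.seed(99)
  for (i in 1:50) {
    ord <- sample(cchh_ligands)
    tr <- gen_smd_trajectory(release_order = ord, seed = i)
    cs <- contact_series(tr, "Zn", smd_ligand_selections(ord))
    expect_equal(classify_pathway(cs)$release_order$ligand, ord)
  }
})

test_that("brief sub-threshold dips are treated as rebinding", {
  n <- 300
  cn <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "Cys3"))
  cn[100:120, 1] <- 0.1              # 21-frame dip, below persistence
  pw <- classify_pathway(structure(cn, class = "contact_series"),
                         persistence = 50)
  expect_equal(nrow(pw$release_order), 0)
  cn[200:260, 1] <- 0.1              # 61-frame run: genuine release
  pw2 <- classify_pathway(structure(cn, class = "contact_series"),
                          persistence = 50)
  expect_equal(pw2$release_order$frame, 200L)
  # never-released ligand gives an empty order; pre-dissociated is flagged
  cn0 <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "Cys3"))
  expect_equal(nrow(classify_pathway(
    structure(cn0, class = "contact_series"))$release_order), 0)
  cn0[1, 1] <- 0.2
  expect_equal(classify_pathway(
    structure(cn0, class = "contact_series"))$pre_dissociated, "Cys3")
})

test_that("pathway census fractions sum to one and are order-invariant", {
  mk <- function(ord) list(release_order = data.frame(
    ligand = ord, frame = seq_along(ord)))
  pws <- c(rep(list(mk(c("A", "B"))), 3), rep(list(mk(c("B", "A"))), 1))
  cen <- pathway_census(pws)
  expect_equal(sum(cen$fraction), 1)
  expect_equal(cen$fraction[cen$signature == "A>B"], 0.75)
  cen2 <- pathway_census(rev(pws))
  expect_equal(cen[order(cen$signature), ], cen2[order(cen2$signature), ],
               ignore_attr = TRUE)
  expect_equal(pathway_census(list(mk("A")))$fraction, 1)
})

test_that("rupture statistics attribute forces per event and integrate work", {
  # single sawtooth peak of height 100 at the first release
  tr <- gen_smd_trajectory(release_order = "Cys3", release_frames = 150,
                           frame_count = 400, force_peaks = 100,
                           force_baseline = 0, seed = 2)
  cs <- contact_series(tr, "Zn", smd_ligand_selections("Cys3"))
  pw <- classify_pathway(cs)
  rs <- rupture_statistics(tr, cs, pw)
  expect_equal(rs$per_event$force, 100)
  expect_equal(rs$rupture_force, 100)
  # constant force F over extension L gives W = F * L
  tr$pulling_force <- rep(3, 400)
  tr$reaction_coordinate <- seq(0, 10, length.out = 400)
  rs2 <- rupture_statistics(tr, cs, pw)
  expect_equal(rs2$total_work, 30)
  # zero force throughout
  tr$pulling_force <- rep(0, 400)
  rs3 <- rupture_statistics(tr, cs, pw)
  expect_equal(rs3$total_work, 0)
  expect_equal(rs3$per_event$force, 0)
  tr$pulling_force <- NULL
  expect_error(rupture_statistics(tr, cs, pw),
               class = "zf_unavailable_channel")
})

test_that("work integral is stable under stride refinement for smooth force", {
  f <- function(x) 50 + 40 * sin(x / 2)
  x1 <- seq(0, 10, length.out = 2001)
  x2 <- seq(0, 10, length.out = 101)
  mk <- function(x) {
    frames <- rep(list(matrix(0, 1, 3, dimnames = list("Zn", NULL))),
                  length(x))
    trajectory(frames, pulling_force = f(x), reaction_coordinate = x)
  }
  pw <- list(release_order = data.frame(ligand = character(0),
                                        frame = integer(0)))
  w1 <- rupture_statistics(mk(x1), NULL, pw)$total_work
  w2 <- rupture_statistics(mk(x2), NULL, pw)$total_work
  expect_lt(abs(w2 / w1 - 1), 0.01)
})

test_that("rupture summary averages replicas arithmetically", {
  mk <- function(rf, w) structure(list(rupture_force = rf, total_work = w),
                                  class = "rupture_stats")
  s <- rupture_summary(list(mk(10, 1), mk(20, 3)))
  expect_equal(s$mean_rupture_force, 15)
  expect_equal(s$mean_total_work, 2)
})

test_that("hydrogen-bond detection applies both geometric criteria", {
  hb <- gen_hbond_structure(data.frame(
    d_a = c(2.9, 3.2, 2.8, 2.8, 2.5), dev_deg = c(0, 0, 19.9, 20.1, 10)))
  got <- detect_hbonds(hb$coords, hb$donors, hb$acceptors)
  expect_setequal(got$donor,
                  paste0("D", which(hb$expected$should_pass)))
  # recorded geometry matches the construction
  row <- got[got$donor == "D3", ]
  expect_equal(row$distance, 2.8, tolerance = 1e-9)
  expect_equal(row$angle, 19.9, tolerance = 1e-9)
  expect_error(detect_hbonds(hb$coords,
                             data.frame(donor = "D1", hydrogen = "HX"),
                             hb$acceptors),
               class = "zf_selection_error")
})

test_that("hydrogen-bond detection agrees with the exhaustive oracle", {
  set.seed(21)
  for (rep in 1:5) {
    specs <- data.frame(d_a = runif(6, 2.2, 3.6), dev_deg = runif(6, 0, 35))
    hb <- gen_hbond_structure(specs)
    got <- detect_hbonds(hb$coords, hb$donors, hb$acceptors)
    want <- oracle_hbonds(hb$coords, hb$donors, hb$acceptors)
    expect_setequal(paste(got$donor, got$acceptor),
                    paste(want$donor, want$acceptor))
    expect_equal(sort(as.integer(sub("D", "", got$donor))),
                 which(hb$expected$should_pass))
  }
})

test_that("RMSD removes rigid translation only under superposition", {
  set.seed(31)
  f1 <- matrix(rnorm(30), ncol = 3,
               dimnames = list(paste0("a", 1:10), NULL))
  expect_equal(rmsd_frames(f1, f1), 0)
  f2 <- sweep(f1, 2, c(-3, -4, 0))
  expect_equal(rmsd_frames(f2, f1), 5)
  expect_lt(rmsd_frames(f2, f1, superpose = TRUE), 1e-8)
  expect_error(rmsd_frames(f1[1:5, ], f1), class = "zf_selection_error")
})

test_that("RMSF reflects per-atom fluctuation amplitudes", {
  set.seed(32)
  n_frames <- 200
  base <- matrix(0, 2, 3, dimnames = list(c("quiet", "mobile"), NULL))
  frames <- lapply(seq_len(n_frames), function(i) {
    base + rbind(rnorm(3, sd = 0.1), rnorm(3, sd = 1.0))
  })
  rf <- rmsf_frames(trajectory(frames), superpose = FALSE)
  expect_lt(rf[["quiet"]], rf[["mobile"]])
  expect_equal(rf[["mobile"]], sqrt(3), tolerance = 0.15)
})

test_that("free-energy surface reproduces closed-form population ratios", {
  set.seed(41)
  xy <- rbind(matrix(rnorm(1800, 0, 0.05), ncol = 2),
              matrix(rnorm(200, 5, 0.05), ncol = 2))
  fes <- free_energy_surface(xy, bins = 8)
  expect_equal(min(fes$free_energy), 0)
  expect_equal(nrow(fes$minima), 2)
  d_f <- max(fes$minima$free_energy)
  expect_equal(d_f, -1.9872e-3 * 298.15 * log(1 / 9), tolerance = 0.05)
  # uniform two-cell occupancy: both minima at ~0
  xy2 <- rbind(matrix(rnorm(1000, 0, 0.05), ncol = 2),
               matrix(rnorm(1000, 5, 0.05), ncol = 2))
  fes2 <- free_energy_surface(xy2, bins = 4)
  expect_lt(max(fes2$minima$free_energy), 0.05)
  expect_error(free_energy_surface(xy[1:50, ]),
               class = "zf_insufficient_data")
})

test_that("XYZ trajectory round-trip preserves coordinates and ids", {
  tr <- gen_smd_trajectory(frame_count = 40,
                           release_order = "Cys3", release_frames = 10,
                           seed = 3)
  tmp <- tempfile(fileext = ".xyz")
  write_xyz(tr, tmp)
  tr2 <- read_xyz(tmp)
  expect_equal(length(tr2$frames), 40)
  expect_equal(rownames(tr2$frames[[1]]), rownames(tr$frames[[1]]))
  expect_equal(tr2$frames[[17]], tr$frames[[17]], tolerance = 1e-5)
  unlink(tmp)
})

test_that("PDB round-trip preserves hydrogen-bond geometry", {
  hb <- gen_hbond_structure(data.frame(d_a = c(2.9, 3.2), dev_deg = c(5, 0)))
  tmp <- tempfile(fileext = ".pdb")
  write_hbond_pdb(hb, tmp)
  m <- read_structure_pdb(tmp)
  rownames(m) <- sub(":.*", "", rownames(m))
  got <- detect_hbonds(m, hb$donors, hb$acceptors)
  expect_equal(got$donor, "D1")
  expect_equal(got$distance, 2.9, tolerance = 1e-3)
  unlink(tmp)
})
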
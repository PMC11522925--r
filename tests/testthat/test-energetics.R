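test_that("pair energy reproduces closed-form Coulomb and LJ values", {
  # two unit charges 1 A apart, no LJ: E = k q1 q2 / r = 332.0636 kcal/mol
  poly <- poly_beads(1, charge = 1)
  sys <- micro_system(poly, matrix(c(0, 0, 1), 1), og_charge = 1)
  xyz <- attr(sys, "coords")
  xyz[2, ] <- c(0, 0, 0)  # OG at origin, bead at (0,0,1)
  e <- pair_energy(xyz, groupA = 2, groupB = 5, sys)
  expect_equal(e$coulomb, 332.0636, tolerance = 1e-12)
  expect_equal(e$lj, 0)
  expect_equal(e$total, e$coulomb + e$lj)

  # two neutral atoms at the LJ minimum r = 2^(1/6) sigma: E = -eps
  poly2 <- poly_beads(2, charge = 0, sigma = 3.4, epsilon = 0.25)
  r_min <- 2^(1 / 6) * 3.4
  sys2 <- micro_system(poly2, rbind(c(0, 0, 5), c(0, 0, 5 + r_min)))
  e2 <- pair_energy(attr(sys2, "coords"), groupA = 5, groupB = 6, sys2)
  expect_equal(e2$lj, -0.25, tolerance = 1e-12)
  expect_equal(e2$coulomb, 0)
})

test_that("pair energy matches the double-loop oracle on a 12-atom fixture", {
  set.seed(21)
  poly <- poly_beads(8, charge = round(rnorm(8, 0, 0.4), 3),
                     sigma = round(runif(8, 2.5, 3.8), 3),
                     epsilon = round(runif(8, 0.05, 0.3), 3))
  pos <- matrix(runif(24, 0, 14), ncol = 3)
  sys <- micro_system(poly, pos, og_charge = -0.3)
  sys$atoms$sigma[1:4] <- c(3.4, 3.0, 0, 0)
  sys$atoms$epsilon[1:4] <- c(0.1, 0.15, 0, 0)
  xyz <- attr(sys, "coords")
  cfg <- analysis_config()
  gA <- 1:4; gB <- 5:12
  e <- pair_energy(xyz, gA, gB, sys, cfg)
  o <- brute_pair_energy(xyz, gA, gB, sys, cfg)
  expect_equal(e$coulomb, o$coulomb, tolerance = 1e-9)
  expect_equal(e$lj, o$lj, tolerance = 1e-9)
  # with a periodic box
  eb <- pair_energy(xyz, gA, gB, sys, cfg, box = c(15, 15, 15))
  ob <- brute_pair_energy(xyz, gA, gB, sys, cfg, box = c(15, 15, 15))
  expect_equal(eb$total, ob$total, tolerance = 1e-9)
})

test_that("pair energy is symmetric, linear in charge, and cutoff-local", {
  set.seed(22)
  poly <- poly_beads(6, charge = round(rnorm(6, 0, 0.3), 3), sigma = 3.2,
                     epsilon = 0.12)
  pos <- matrix(runif(18, 0, 10), ncol = 3)
  sys <- micro_system(poly, pos, og_charge = 0.4)
  xyz <- attr(sys, "coords")
  e1 <- pair_energy(xyz, 1:4, 5:10, sys)
  e2 <- pair_energy(xyz, 5:10, 1:4, sys)
  expect_equal(e1$total, e2$total, tolerance = 1e-12)
  # doubling all charges of one group doubles the Coulomb part
  sys2 <- sys; sys2$atoms$charge[5:10] <- 2 * sys$atoms$charge[5:10]
  expect_equal(pair_energy(xyz, 1:4, 5:10, sys2)$coulomb, 2 * e1$coulomb,
               tolerance = 1e-12)
  expect_equal(pair_energy(xyz, 1:4, 5:10, sys2)$lj, e1$lj)
  # atoms beyond the cutoff do not change the energy
  poly3 <- poly_beads(7, charge = c(round(rnorm(6, 0, 0.3), 3), 5),
                      sigma = 3.2, epsilon = 0.12)
  poly3$charge[1:6] <- sys$atoms$charge[5:10]
  sys3 <- micro_system(poly3, rbind(pos, c(100, 100, 100)), og_charge = 0.4)
  expect_equal(pair_energy(attr(sys3, "coords"), 1:4, 5:11, sys3)$total,
               e1$total, tolerance = 1e-12)
  # error cases
  expect_error(pair_energy(xyz, 1:4, 4:6, sys), "overlap")
  xyz0 <- xyz; xyz0[5, ] <- xyz0[1, ]
  expect_error(pair_energy(xyz0, 1:4, 5:10, sys), "zero interatomic")
})

test_that("per-residue series agree with direct pair energies", {
  sys <- make_toy_system(n_residues = 12, n_units = 3, seed = 13)
  traj <- simulate_entry(sys, corridor = 2, seed = 13, n_frames = 24,
                         noise = 0.2)
  cfg <- analysis_config()
  ser <- residue_energy_series(traj, sys, cfg)
  at <- sys$atoms
  pids <- at$id[at$segment == "polymer"]
  # spot-check two residues against frame-wise brute force
  for (r in c("1", "5")) {
    gids <- at$id[at$segment == "enzyme" & at$resid == as.integer(r)]
    for (f in c(1, 10, 24)) {
      o <- brute_pair_energy(frame_coords(traj, f), gids, pids, sys, cfg)
      expect_equal(ser[[r]]$total[f], o$total, tolerance = 1e-9)
    }
  }
  # total = coulomb + lj throughout
  for (s in ser) expect_equal(s$total, s$coulomb + s$lj)
})

test_that("residues beyond the nonbonded cutoff give all-zero series", {
  poly <- poly_beads(2, charge = 0.3, sigma = 3.2, epsilon = 0.1)
  sys <- micro_system(poly, rbind(c(0, 0, 5), c(0, 0, 7)), og_charge = -0.2)
  co <- attr(sys, "coords")
  co[3, ] <- c(200, 0, 0)  # residue 2 (HN1) parked far away
  sys$atoms$charge[3] <- 0.4
  traj <- multi_frame_traj(list(co, co + 0.1))
  ser <- residue_energy_series(traj, sys, analysis_config())
  expect_equal(ser[["2"]]$total, c(0, 0))
  expect_true(any(ser[["1"]]$total != 0))
})

test_that("class profile scales by the number of contacting residues", {
  mk_series <- function(vals) {
    out <- lapply(vals, function(v)
      structure(data.frame(frame = 1:2, time = 1:2, coulomb = v, lj = 0,
                           total = v),
                weight = c(1, 1), class = c("energy_series", "data.frame")))
    names(out) <- names(vals)
    out
  }
  sys <- make_toy_system(n_residues = 12, n_units = 3, seed = 1)
  sys$atoms$resname[sys$atoms$resid == 4] <- "SER"   # polar
  sys$atoms$resname[sys$atoms$resid == 5] <- "THR"   # polar
  sys$atoms$resname[sys$atoms$resid == 6] <- "PHE"   # aromatic
  ser <- mk_series(c("4" = -4, "5" = -2, "6" = -7))
  # one polar residue in contact: class mean is its mean
  p1 <- class_profile(ser, contacts = 4, sys)
  expect_equal(unname(p1$class_energy["polar"]), -4)
  # two polar residues -2 and -4: scaled mean -3
  p2 <- class_profile(ser, contacts = c(4, 5, 6), sys)
  expect_equal(unname(p2$class_energy["polar"]), -3)
  expect_equal(unname(p2$class_energy["aromatic"]), -7)
  expect_equal(unname(p2$n_contacting["polar"]), 2L)
  expect_error(class_profile(ser, contacts = integer(0), sys), "empty")
})

test_that("polymer unit-unit energies respect adjacency and the oracle", {
  sys <- make_toy_system(n_residues = 12, n_units = 5, seed = 17)
  traj <- simulate_entry(sys, corridor = 1, seed = 17, n_frames = 30,
                         noise = 0.1)
  cfg <- analysis_config()
  expect_error(pet_internal_energy(traj, sys, cfg, i = 2, j = 3),
               "non-adjacent")
  expect_error(pet_internal_energy(traj, sys, cfg, i = 3, j = 3),
               "non-adjacent")
  e13 <- pet_internal_energy(traj, sys, cfg, i = 1, j = 3)
  o <- brute_pair_energy(frame_coords(traj, 7), sys$polymer_units[[1]],
                         sys$polymer_units[[3]], sys, cfg)
  expect_equal(e13$total[7], o$total, tolerance = 1e-9)
  # units far beyond the cutoff: zero energy
  far_sys <- sys
  co <- attr(sys, "coords")
  rows5 <- match(sys$polymer_units[[5]], sys$atoms$id)
  co[rows5, ] <- co[rows5, ] + 500
  attr(far_sys, "coords") <- co
  tr0 <- one_frame_traj(co)
  expect_equal(pet_internal_energy(tr0, far_sys, cfg, 1, 5)$total, 0)
})

test_that("binding onset finds the first crossing below the threshold", {
  mk <- function(tot) structure(
    data.frame(frame = seq_along(tot), time = seq_along(tot) * 0.1,
               coulomb = tot, lj = 0, total = tot),
    weight = rep(1, length(tot)), class = c("energy_series", "data.frame"))
  expect_equal(binding_onset(mk(rep(-12, 5))), 0.1)
  expect_true(is.na(binding_onset(mk(rep(-8, 5)))))
  # planted crossing at frame 37
  tot <- c(rep(-3, 36), rep(-15, 14))
  expect_equal(binding_onset(mk(tot)), 3.7)
  expect_error(binding_onset(mk(rep(-12, 3)), threshold = 2), "negative")
})

test_that("site-wise energy differences recover planted shifts", {
  mk <- function(vals) {
    out <- lapply(vals, function(v) structure(
      data.frame(frame = 1:3, time = 1:3, coulomb = v, lj = 0, total = v),
      weight = rep(1, 3), class = c("energy_series", "data.frame")))
    names(out) <- names(vals)
    out
  }
  parent <- mk(c("68" = -6, "93" = -3, "212" = -9))
  expect_equal(site_delta_eint(parent, parent, c(68, 93, 212))$delta,
               c(0, 0, 0))
  shifted <- mk(c("68" = -4, "93" = -1, "212" = -7))
  expect_equal(site_delta_eint(parent, shifted, c(68, 93, 212))$delta,
               c(2, 2, 2))
  planted <- c(1.5, -0.5, 3)
  variant <- mk(stats::setNames(c(-6, -3, -9) + planted,
                                c("68", "93", "212")))
  expect_equal(site_delta_eint(parent, variant, c(68, 93, 212))$delta,
               planted)
  expect_error(site_delta_eint(parent, variant, c(68, 999)), "missing")
})
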
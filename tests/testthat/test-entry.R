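# Geometry helpers shared by the entry tests: a one-ester system whose
# atoms can be placed freely.
ester_system <- function() {
  poly <- poly_beads(3)
  poly$name <- c("C1", "O1", "OE")
  poly$element <- c("C", "O", "O")
  poly$resid <- 10L
  micro_system(poly, rbind(c(0, 0, 4.5), c(1.23, 0, 4.5), c(-0.6, 1.2, 4.5)),
               ester = matrix(c(5, 6, 7), 1))
}

test_that("productive flag requires all three distances at or below 4 A", {
  sys <- ester_system()
  co <- attr(sys, "coords")
  # OG at (0,0,1); put the carbonyl C 3.5 A from OG, carbonyl O 3 A from
  # both donor hydrogens at (+-1.2, 0, 1.6)
  co[5, ] <- c(0, 0, 4.5)          # SER-C = 3.5
  co[6, ] <- c(0, 0, 4.35)         # O1 close to both HN
  es <- entry_series(one_frame_traj(co), sys)
  expect_equal(es$ser_c, 3.5)
  expect_true(all(c(es$oxy1, es$oxy2) <= 4))
  expect_true(es$productive)
  # one oxyanion distance pushed past 4 A: not productive
  co2 <- co; co2[6, ] <- c(5.5, 0, 2.0)
  es2 <- entry_series(one_frame_traj(co2), sys)
  expect_lte(es2$ser_c, 4)
  expect_gt(es2$oxy1, 4)
  expect_false(es2$productive)
  # SER-C past 4 A: not productive even with good oxyanion contacts
  co3 <- co; co3[5, ] <- c(0, 0, 5.5); co3[6, ] <- c(0, 0, 4)
  expect_false(entry_series(one_frame_traj(co3), sys)$productive)
})

test_that("the nearest ester bond is tracked per frame", {
  poly <- poly_beads(6)
  poly$name <- rep(c("C1", "O1", "OE"), 2)
  poly$element <- rep(c("C", "O", "O"), 2)
  poly$resid <- rep(c(10L, 11L), each = 3)
  sys <- micro_system(poly,
                      rbind(c(0, 0, 8), c(1, 0, 8.6), c(-1, 0.6, 8.2),
                            c(0, 0, 4), c(1, 0, 4.6), c(-1, 0.6, 4.2)),
                      units = list(5:7, 8:10),
                      ester = rbind(c(5, 6, 7), c(8, 9, 10)))
  es <- entry_series(one_frame_traj(attr(sys, "coords")), sys)
  # esters at 7 and 3 A from OG (0,0,1): the second is tracked
  expect_identical(es$ester, 2L)
  expect_equal(es$ser_c, 3)
})

test_that("si/re labels are anchored to the shipped reference geometry", {
  ref <- system.file("extdata", "si_reference.pdb", package = "petentry")
  ann <- list(polymer_resnames = "PET", serine_resid = 1,
              oxyanion = data.frame(resid = c(2, 3),
                                    atom = c("HN1", "HN2")),
              ester_template = list(carbon = "C1", carbonyl_oxygen = "O1",
                                    ester_oxygen = "OE"))
  sys <- read_topology(ref, ann)
  xyz <- attr(sys, "coords")
  expect_identical(face_label(xyz, sys, 1), "si")
  # mirroring through the ester plane (z -> -z here) flips the face
  xyz_m <- xyz; xyz_m[, 3] <- -xyz_m[, 3]
  expect_identical(face_label(xyz_m, sys, 1), "re")
  # serine oxygen inside the delta band around the plane: undefined
  xyz_p <- xyz; xyz_p[2, ] <- c(0.3, -0.5, 0.05)
  expect_identical(face_label(xyz_p, sys, 1), "undefined")
  # collinear triplet: warning plus undefined
  xyz_c <- xyz; xyz_c[6, ] <- c(1, 0, 0); xyz_c[7, ] <- c(2, 0, 0)
  expect_warning(lab <- face_label(xyz_c, sys, 1), "degenerate")
  expect_identical(lab, "undefined")
})

test_that("distances, flags and faces are invariant under rigid motion", {
  sys <- make_toy_system(n_residues = 14, n_units = 3, seed = 6)
  traj <- simulate_entry(sys, corridor = 3, seed = 6, n_frames = 30,
                         noise = 0.2)
  es <- entry_series(traj, sys)
  R <- random_rotation(31)
  moved <- transform_traj(traj, R = R, shift = c(5, -3, 11))
  es_m <- entry_series(moved, sys)
  expect_equal(es_m$ser_c, es$ser_c, tolerance = 1e-10)
  expect_equal(es_m$oxy1, es$oxy1, tolerance = 1e-10)
  expect_identical(es_m$productive, es$productive)
  expect_identical(es_m$face, es$face)
})

test_that("mirror reflection flips every si/re label and nothing else", {
  sys <- make_toy_system(n_residues = 14, n_units = 3, seed = 8)
  traj <- simulate_entry(sys, corridor = 1, seed = 8, n_frames = 30,
                         noise = 0.2)
  es <- entry_series(traj, sys)
  mir <- transform_traj(traj, mirror = TRUE)
  es_m <- entry_series(mir, sys)
  expect_equal(es_m$ser_c, es$ser_c, tolerance = 1e-10)
  expect_identical(es_m$productive, es$productive)
  flip <- c(si = "re", re = "si", undefined = "undefined")
  expect_identical(es_m$face, unname(flip[es$face]))
})

test_that("phase segmentation follows the 6/4 A boundary convention", {
  cfg <- analysis_config()
  # strictly decreasing 8 -> 2 A: one event with phases at the crossings
  d <- seq(8, 2, by = -0.5)
  ev <- segment_entries(fake_entry_series(d), cfg)
  expect_length(ev, 1)
  expect_identical(max(ev[[1]]$outside), max(which(d > 6)))
  expect_identical(min(ev[[1]]$inside), min(which(d < 4)))
  expect_identical(ev[[1]]$entry,
                   seq.int(max(which(d > 6)) + 1L, min(which(d < 4)) - 1L))
  expect_true(ev[[1]]$productive)
  # a series that never leaves the outside region yields no events
  expect_length(segment_entries(fake_entry_series(seq(9, 6.5, -0.1)), cfg), 0)
  # three planted crossings are all recovered with their boundaries
  d3 <- c(8, 7, 5, 3.5, 3, 6.5, 8, 5, 3.9, 7, 6.2, 8, 4.8, 3.2, 3.1)
  ev3 <- segment_entries(fake_entry_series(d3), cfg)
  expect_length(ev3, 3)
  expect_identical(vapply(ev3, function(e) min(e$inside), integer(1)),
                   c(4L, 9L, 14L))
  expect_identical(vapply(ev3, function(e) max(e$outside), integer(1)),
                   c(2L, 7L, 12L))
})

test_that("segmentation is directional", {
  d <- seq(8, 2, by = -0.25)
  fwd <- segment_entries(fake_entry_series(d))
  rev_ev <- segment_entries(fake_entry_series(rev(d)))
  expect_length(fwd, 1)
  expect_length(rev_ev, 0)  # a pure exit is not an entry
})

test_that("an event is productive only via its inside phase", {
  # dips below 4 A but with productive flag false everywhere
  d <- c(8, 7, 5, 3.5, 3.2, 5, 8)
  ev <- segment_entries(fake_entry_series(d, productive = rep(FALSE, 7)))
  expect_length(ev, 1)
  expect_false(ev[[1]]$productive)
  expect_true(is.na(ev[[1]]$face))
})

test_that("tallies aggregate events and frame fractions", {
  mk_ev <- function(prod, face) structure(
    list(outside = 1:2, entry = 3:4, inside = 5:6, productive = prod,
         face = face, ester = 1L), class = "entry_event")
  evs <- list(mk_ev(TRUE, "si"), mk_ev(TRUE, "si"), mk_ev(TRUE, "re"))
  t1 <- tally_entries(evs)
  expect_identical(t1$n_events, 3L)
  expect_equal(t1$n_productive, 3)
  expect_equal(t1$n_si, 2)
  expect_equal(t1$n_re, 1)
  # empty input gives zeros
  t0 <- tally_entries(list())
  expect_identical(t0$n_events, 0L)
  expect_equal(t0$n_productive + t0$n_si + t0$n_re, 0)
  # weighted productive-frame fraction from the series
  s <- fake_entry_series(c(8, 5, 3, 3), weight = c(1, 1, 1, 3))
  t2 <- tally_entries(evs, series = s)
  expect_equal(t2$productive_frame_fraction, 4 / 6)
})

test_that("noisy planted entries are recovered with tight boundaries", {
  sys <- make_toy_system(seed = 3)
  hits <- 0
  for (i in 1:20) {
    tr <- simulate_entry(sys, corridor = (i - 1) %% 3 + 1, seed = 300 + i,
                         noise = 0.3)
    ev <- segment_entries(entry_series(tr, sys))
    truth <- attr(tr, "truth")
    if (length(ev) == 1 &&
        abs(max(ev[[1]]$outside) - max(truth$outside)) <= 2 &&
        abs(min(ev[[1]]$inside) - min(truth$inside)) <= 2)
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})
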
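test_that("feature rows are ester-C-to-CA distances with range selection", {
  # system with three extra CA beads at 4, 9 and 11 A from the ester carbon
  poly <- poly_beads(3)
  poly$name <- c("C1", "O1", "OE")
  poly$element <- c("C", "O", "O")
  poly$resid <- 10L
  enz <- data.frame(name = "CA", element = "C", charge = 0, sigma = 0,
                    epsilon = 0, resid = 4:6, resname = "ALA",
                    segment = "enzyme", stringsAsFactors = FALSE)
  poly$segment <- "polymer"
  atoms <- rbind(
    data.frame(name = c("CA", "OG", "HN1", "HN2"),
               element = c("C", "O", "H", "H"), charge = 0, sigma = 0,
               epsilon = 0, resid = c(1, 1, 2, 3),
               resname = c("SER", "SER", "GLY", "GLY"), segment = "enzyme",
               stringsAsFactors = FALSE),
    enz, poly)
  atoms$id <- seq_len(nrow(atoms))
  sys <- molecular_system(atoms, serine_ogamma = 2,
                          oxyanion_donors = c(3, 4),
                          polymer_units = list(8:10),
                          ester_bonds = matrix(c(8, 9, 10), 1))
  co <- rbind(c(0, 0, -30), c(0, 0, -29),      # SER far below
              c(30, 0, 0), c(-30, 0, 0),       # donors far away
              c(4, 0, 0), c(9, 0, 0), c(11, 0, 0),  # the three CAs
              c(0, 0, 0), c(1, 0, 0.5), c(-1, 0.5, 0))  # ester at origin
  traj <- multi_frame_traj(list(co, co))
  ev <- structure(list(outside = 1L, entry = integer(0), inside = 2L,
                       productive = TRUE, face = "si", ester = 1L),
                  class = "entry_event")
  fm <- entry_feature_matrix(list(list(ev)), list(traj), sys, radius = 10)
  # residue 6 (11 A away) is excluded; residues 4 and 9 A are kept
  expect_identical(fm$resid, c(4L, 5L))
  expect_equal(unname(fm$matrix[1, ]), c(4, 9))
  # distances are capped at 2 * radius
  co2 <- co; co2[5, ] <- c(25, 0, 0)
  traj2 <- multi_frame_traj(list(co, co2))
  ev2 <- structure(list(outside = integer(0), entry = 1L, inside = 2L,
                        productive = TRUE, face = "si", ester = 1L),
                   class = "entry_event")
  fm2 <- entry_feature_matrix(list(list(ev2)), list(traj2), sys, radius = 10)
  expect_equal(unname(fm2$matrix[2, "4"]), 20)
  expect_equal(fm2$cap, 20)
})

test_that("weighted PCA matches its eigen identities and the dense oracle", {
  # collinear 2D points: PC1 explains everything
  t_line <- seq(-2, 2, length.out = 40)
  line <- cbind(1 + 2 * t_line, -1 + t_line)
  m_line <- pca_fit(line)
  expect_equal(m_line$explained[1], 1.0, tolerance = 1e-12)
  # isotropic Gaussian: both components near 0.5
  set.seed(41)
  iso <- matrix(rnorm(2e4), ncol = 2)
  m_iso <- pca_fit(iso)
  expect_equal(m_iso$explained, c(0.5, 0.5), tolerance = 0.02)
  # dense covariance + eigen oracle on a random 8-column matrix
  set.seed(42)
  x <- matrix(rnorm(400), ncol = 8) %*% matrix(rnorm(64), 8)
  m <- pca_fit(x)
  o <- brute_pca(x)
  expect_equal(m$eigenvalues, o$values, tolerance = 1e-9)
  for (k in 1:8)
    expect_equal(abs(sum(m$loadings[, k] * o$vectors[, k])), 1,
                 tolerance = 1e-8)
  # loadings orthonormal, explained fractions sorted and summing to 1
  expect_equal(crossprod(m$loadings), diag(8), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_equal(sum(m$explained), 1)
})

test_that("full-rank reconstruction and column-permutation equivariance hold", {
  set.seed(43)
  x <- matrix(rnorm(150), ncol = 5)
  w <- runif(30, 0.5, 2)
  m <- pca_fit(x, weights = w)
  xc <- sweep(x, 2, m$center)
  expect_equal(xc %*% m$loadings %*% t(m$loadings), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  perm <- c(3, 1, 5, 2, 4)
  mp <- pca_fit(x[, perm], weights = w)
  expect_equal(abs(mp$loadings), abs(m$loadings[perm, ]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_fit(matrix(1, 5, 3)), "zero-variance")
})

test_that("projection reproduces PCA identities and feeds the FES", {
  set.seed(44)
  x <- matrix(rnorm(300), ncol = 3) + rep(c(5, -2, 0), each = 100)
  m <- pca_fit(x)
  pr <- project_and_fes(m, x)
  # zero mean per component, variance along PC1 = first eigenvalue
  expect_equal(colMeans(pr$projections), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mean(pr$projections[, 1]^2), m$eigenvalues[1],
               tolerance = 1e-10)
  expect_s3_class(pr$fes, "fes_grid")
  colnames(x) <- c("a", "b", "c")
  expect_error(project_and_fes(m, x[, c(2, 1, 3)]), "does not match")
})

test_that("contribution ranking and significance follow the loadings", {
  x <- cbind(c(0.8, -0.8), c(0.6, -0.6)) * sqrt(2)
  x <- rbind(x, -x, x)  # points along (0.8, 0.6): loadings (0.8, 0.6)
  m <- pca_fit(x)
  cc <- pc_contributions(m, 1)
  expect_identical(cc$resid, c("f1", "f2"))
  expect_equal(cc$contribution, c(0.8, 0.6), tolerance = 1e-10)
  expect_error(pc_contributions(m, 5), "out of range")
  # equal loadings sit exactly at the 1/sqrt(d) baseline: none clears the
  # strict threshold
  y <- rbind(c(1, 1), c(-1, -1), c(2, 2), c(-2, -2))
  my <- pca_fit(y)
  ccy <- pc_contributions(my, 1)
  expect_equal(ccy$contribution, rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_false(any(pc_contributions(my, 1,
                                    threshold = max(ccy$contribution))
                   $significant))
})

test_that("pathway assignment is seeded, ordered by PC1 and exact on clean clusters", {
  set.seed(45)
  centers <- rbind(c(-5, 0), c(0, 4), c(5, -1))
  truth <- rep(1:3, each = 12)
  proj <- centers[truth, ] + matrix(rnorm(72, 0, 0.3), ncol = 2)
  event <- seq_along(truth)
  pw <- assign_pathways(proj, event, k = 3, seed = 9)
  # labels ordered by mean PC1: cluster at -5 is pathway 1, at +5 pathway 3
  expect_identical(pw$pathway, truth)
  # determinism on a duplicated event set
  pw2 <- assign_pathways(proj, event, k = 3, seed = 9)
  expect_identical(pw, pw2)
  # k = 1: everything is one pathway
  expect_true(all(assign_pathways(proj, event, k = 1, seed = 1)$pathway == 1))
  expect_error(assign_pathways(proj[1:2, ], event[1:2], k = 3, seed = 1),
               "fewer events")
})

test_that("planted corridors are recovered from simulated entries", {
  sys <- make_toy_system(seed = 2)
  trajs <- list(); evs <- list(); labels <- integer(0)
  for (i in 1:12) {
    cor <- (i - 1) %% 3 + 1
    tr <- simulate_entry(sys, corridor = cor, seed = 700 + i, noise = 0.3)
    trajs[[i]] <- tr
    evs[[i]] <- segment_entries(entry_series(tr, sys))
    labels <- c(labels, cor)
  }
  fm <- entry_feature_matrix(evs, trajs, sys, radius = 10)
  m <- pca_fit(fm)
  pr <- project_and_fes(m, fm)
  pw <- assign_pathways(pr$projections, fm$event, weights = fm$weight,
                        k = 3, seed = 2)
  expect_gte(best_label_agreement(pw$pathway, labels), 0.9)
})
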
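# Synthetic fixtures with known ground truth: toy enzyme/polymer systems,
# entry trajectories along planted corridors, Boltzmann samples from
# analytic 2D potentials, and noisy Michaelis-Menten rate data.
#
# Every generator is a pure function of its arguments and seed: the same
# seed yields byte-identical output.

#' Build a toy enzyme/polymer system with known geometry
#'
#' The pseudo-enzyme is a C-alpha bead shell of radius `shell_radius`
#' centered at the origin, with a catalytic site at the +z pole: a serine
#' gamma-oxygen bead on the shell surface and two oxyanion amide-hydrogen
#' beads flanking it just outside. The polymer is a bead chain of
#' `n_units` repeat units; every unit junction carries an ester triplet
#' (carbonyl C `C1`, carbonyl O `O1`, ester O `OE`), i.e. `n_units - 1`
#' triplets on units 2..n. Three beads are planted on the shell next to the
#' mouths of the three entry corridors used by [simulate_entry()]; their
#' residue indices are recorded as the planted pathway-discriminating set.
#' Toy charges and LJ parameters are assigned (seeded).
#'
#' @param n_residues Number of enzyme residues (>= 10; default 30).
#' @param n_units Number of polymer repeat units (>= 3; default 5).
#' @param seed RNG seed.
#' @param shell_radius Enzyme shell radius, Angstrom (default 12).
#' @return A `molecular_system` with reference coordinates in attribute
#'   `"coords"` and a `"truth"` attribute listing the serine residue, the
#'   corridor directions and the planted discriminating residues.
#' @export
make_toy_system <- function(n_residues = 30, n_units = 5, seed = 1,
                            shell_radius = 12) {
  if (n_residues < 10) stop("n_residues must be >= 10")
  if (n_units < 3) stop("n_units must be >= 3")
  set.seed(seed)
  R <- shell_radius
  og_pos <- c(0, 0, R)
  dirs <- corridor_directions()
  # three planted beads protrude from the shell like surface loops, each
  # sitting just beside one corridor's guide path so its distance feature
  # discriminates that entry route; the rest tile the shell (Fibonacci)
  zhat <- c(0, 0, 1)
  mouth <- lapply(dirs, function(u) {
    w <- c(u[2] * zhat[3] - u[3] * zhat[2],
           u[3] * zhat[1] - u[1] * zhat[3],
           u[1] * zhat[2] - u[2] * zhat[1])
    w <- w / sqrt(sum(w^2))
    og_pos + 6.5 * u + 1.2 * w
  })
  n_fib <- n_residues - 3
  golden <- pi * (3 - sqrt(5))
  fib <- t(vapply(seq_len(n_fib), function(i) {
    z <- 1 - 2 * (i - 0.5) / n_fib
    r <- sqrt(1 - z^2)
    th <- golden * i
    R * c(r * cos(th), r * sin(th), z)
  }, numeric(3)))
  ca_pos <- rbind(mouth[[1]], mouth[[2]], mouth[[3]], fib)
  planted <- 1:3
  aa <- names(default_class_map())
  resnames <- sample(aa, n_residues, replace = TRUE)
  ser_res <- 3L + which.max(fib[, 3])  # shell bead nearest the +z pole
  resnames[ser_res] <- "SER"
  atoms <- data.frame(id = integer(0), name = character(0),
                      element = character(0), charge = numeric(0),
                      sigma = numeric(0), epsilon = numeric(0),
                      resid = integer(0), resname = character(0),
                      segment = character(0), stringsAsFactors = FALSE)
  coords <- NULL
  aid <- 0L
  add <- function(name, element, charge, sigma, epsilon, resid, resname,
                  segment, pos) {
    aid <<- aid + 1L
    atoms[nrow(atoms) + 1L, ] <<- list(aid, name, element, charge, sigma,
                                       epsilon, resid, resname, segment)
    coords <<- rbind(coords, pos)
    aid
  }
  # toy CA charges keyed by residue type, as a parameter table would be
  aa_q <- round(-0.15 + 0.015 * seq_along(aa), 3)
  names(aa_q) <- aa
  for (r in seq_len(n_residues))
    add("CA", "C", unname(aa_q[resnames[r]]), 3.4, 0.1,
        r, resnames[r], "enzyme", ca_pos[r, ])
  og_id <- add("OG", "O", -0.4, 3.0, 0.15, ser_res, "SER", "enzyme", og_pos)
  don1 <- add("HN1", "H", 0.3, 1.0, 0.03, n_residues + 1L, "GLY", "enzyme",
              c(1.2, 0, R + 0.6))
  ca_d1 <- add("CA", "C", unname(aa_q["GLY"]), 3.4, 0.1, n_residues + 1L, "GLY", "enzyme",
               c(2.4, 0, R - 0.5))
  don2 <- add("HN2", "H", 0.3, 1.0, 0.03, n_residues + 2L, "GLY", "enzyme",
              c(-1.2, 0, R + 0.6))
  ca_d2 <- add("CA", "C", unname(aa_q["GLY"]), 3.4, 0.1, n_residues + 2L, "GLY", "enzyme",
               c(-2.4, 0, R - 0.5))
  # polymer chain, parked far above the shell in the reference frame
  trail <- c(0.3, 0.3, 0.9) / sqrt(sum(c(0.3, 0.3, 0.9)^2))
  base <- c(0, 0, R + 30)
  units <- vector("list", n_units)
  ester <- NULL
  pres0 <- n_residues + 2L
  for (u in seq_len(n_units)) {
    ids <- integer(0)
    orig <- base + (u - 1) * 3.0 * trail
    ids <- c(ids, add("CR", "C", 0.05, 3.55, 0.07, pres0 + u, "PET",
                      "polymer", orig))
    if (u >= 2) {
      c1 <- add("C1", "C", 0.55, 3.4, 0.086, pres0 + u, "PET", "polymer",
                orig + c(0.8, 0, -0.9))
      o1 <- add("O1", "O", -0.5, 3.0, 0.21, pres0 + u, "PET", "polymer",
                orig + c(1.4, 0, -2.0))
      oe <- add("OE", "O", -0.35, 3.0, 0.17, pres0 + u, "PET", "polymer",
                orig + c(-0.3, 0.6, -0.7))
      ids <- c(ids, c1, o1, oe)
      ester <- rbind(ester, c(c1, o1, oe))
    }
    units[[u]] <- ids
  }
  sys <- molecular_system(atoms, serine_ogamma = og_id,
                          oxyanion_donors = c(don1, don2),
                          polymer_units = units, ester_bonds = ester,
                          params_present = TRUE)
  rownames(coords) <- NULL
  attr(sys, "coords") <- coords
  attr(sys, "truth") <- list(serine_residue = ser_res,
                             shell_radius = R,
                             og_pos = og_pos,
                             corridor_dirs = dirs,
                             planted_pc_residues = planted,
                             oxyanion_ca = c(ca_d1, ca_d2))
  sys
}

#' @keywords internal
corridor_directions <- function() {
  # three approach directions 120 degrees apart around the +z catalytic
  # pole, each tilted 60 degrees off the pole axis
  norm1 <- function(v) v / sqrt(sum(v^2))
  lapply(c(210, 90, 330) * pi / 180, function(th)
    norm1(c(0.87 * cos(th), 0.87 * sin(th), 0.5)))
}

#' Simulate one substrate-entry trajectory along a planted corridor
#'
#' The tracked ester carbon (first ester triplet) follows a corridor-specific
#' guide curve: it hovers outside (about 9.5 A from the serine gamma-oxygen),
#' ramps in at roughly 0.45 A per frame, and dwells in the final productive
#' pose at 2.8 A; the whole polymer translates rigidly with it. Gaussian
#' positional noise of amplitude `noise` is added to every polymer atom in
#' every frame (noise, not Langevin dynamics, so the ground-truth phase
#' boundaries stay analytically known: they are the 6/4 A crossings of the
#' noiseless guide curve). The carbonyl oxygen's offset places the final
#' pose within the productive criteria; mirroring the ester-oxygen offset
#' plants the approach face.
#'
#' @param system A system from [make_toy_system()].
#' @param corridor Corridor id 1, 2 or 3.
#' @param seed RNG seed.
#' @param n_frames Total frames (default 60).
#' @param noise Positional noise amplitude, Angstrom (default 0.3).
#' @param face Planted approach face, `"si"` or `"re"` (default `"si"`).
#' @return A `trajectory`; attribute `"truth"` holds the ground-truth
#'   `entry_event` frame ranges, the corridor id and the planted face.
#' @export
simulate_entry <- function(system, corridor = 1, seed = 1, n_frames = 60,
                           noise = 0.3, face = c("si", "re")) {
  if (!corridor %in% 1:3) stop("corridor must be 1, 2 or 3")
  face <- match.arg(face)
  set.seed(seed)
  truth0 <- attr(system, "truth")
  og <- truth0$og_pos
  u0 <- truth0$corridor_dirs[[corridor]]
  zhat <- c(0, 0, 1)
  d_out <- 9.5; d_in <- 2.8; step <- 0.45
  n_ramp <- ceiling((d_out - d_in) / step)
  n_pre <- max(3L, round(n_frames * 0.2))
  n_post <- n_frames - n_pre - n_ramp
  if (n_post < 3L) stop("n_frames too small for the guide curve")
  d_guide <- c(rep(d_out, n_pre),
               d_out - step * seq_len(n_ramp - 1),
               rep(d_in, n_post + 1L))
  s <- c(rep(0, n_pre), seq_len(n_ramp - 1) / (n_ramp - 1),
         rep(1, n_post + 1L))
  # the approach direction relaxes toward the pole but keeps a residual
  # corridor-specific tilt, so the bound pose still remembers its route
  u_end <- 0.25 * u0 + zhat
  u_end <- u_end / sqrt(sum(u_end^2))
  guide <- t(vapply(seq_len(n_frames), function(k) {
    u <- (1 - s[k]) * u0 + s[k] * u_end
    u <- u / sqrt(sum(u^2))
    og + d_guide[k] * u
  }, numeric(3)))
  # rigid polymer conformation anchored at the tracked ester carbon
  at <- system$atoms
  prows <- which(at$segment == "polymer")
  c1 <- atom_rows(system, system$ester_bonds[1, "carbon"])
  ref <- pose_conformation(system, face)
  offs <- sweep(ref, 2, ref[match(c1, prows), ], "-")
  coords <- array(NA_real_, c(n_frames, nrow(at), 3))
  base <- attr(system, "coords")
  for (f in seq_len(n_frames)) {
    xyz <- base
    xyz[prows, ] <- sweep(offs, 2, guide[f, ], "+") +
      matrix(stats::rnorm(3 * length(prows), 0, noise), ncol = 3)
    coords[f, , ] <- xyz
  }
  last_out <- max(which(d_guide > 6))
  first_in <- min(which(d_guide < 4))
  truth <- list(
    outside = seq_len(last_out),
    entry = if (first_in - last_out > 1L)
      seq.int(last_out + 1L, first_in - 1L) else integer(0),
    inside = seq.int(first_in, n_frames),
    corridor = corridor, face = face, productive = TRUE)
  traj <- trajectory(coords, time = seq_len(n_frames))
  attr(traj, "truth") <- truth
  traj
}

# Polymer conformation in the productive pose, tracked ester carbon at the
# origin. The carbonyl oxygen points down toward the oxyanion hydrogens;
# flipping the ester-oxygen offset across the xz-plane mirrors the ester
# plane and swaps the approach face.
#' @keywords internal
pose_conformation <- function(system, face = "si") {
  at <- system$atoms
  prows <- which(at$segment == "polymer")
  trail <- c(0.3, 0.3, 0.9) / sqrt(sum(c(0.3, 0.3, 0.9)^2))
  conf <- matrix(NA_real_, length(prows), 3)
  oe_y <- if (face == "si") -0.6 else 0.6
  c1_id <- system$ester_bonds[1, "carbon"]
  c1_unit <- which(vapply(system$polymer_units, function(u)
    c1_id %in% u, logical(1)))
  for (i in seq_along(prows)) {
    r <- prows[i]
    unit <- which(vapply(system$polymer_units, function(u)
      at$id[r] %in% u, logical(1)))
    orig <- (unit - c1_unit) * 3.0 * trail
    conf[i, ] <- orig + switch(at$name[r],
                               CR = c(-0.8, 0, 0.9),
                               C1 = c(0, 0, 0),
                               O1 = c(0.6, 0, -1.1),
                               OE = c(-1.1, oe_y, 0.2),
                               c(0, 0, 0))
  }
  conf
}

#' Trajectory with a planted persistent-contact residue set
#'
#' In a seeded `fraction` of the frames the first polymer heavy atoms sit
#' 2.5 A outside the shell beads of the planted residues (contact); in the
#' remaining frames the polymer is parked far away. All other residues stay
#' out of contact throughout, so [persistence_filter()] at any threshold
#' below `fraction` must recover exactly the planted set.
#'
#' @param system A system from [make_toy_system()].
#' @param persistent Integer residue indices to plant (must have CA beads).
#' @param n_frames Number of frames (default 100).
#' @param fraction Fraction of frames in contact (default 0.8).
#' @param seed RNG seed.
#' @return A `trajectory`; attribute `"truth"` holds the planted set and
#'   the exact contact fraction.
#' @export
make_contact_trajectory <- function(system, persistent, n_frames = 100,
                                    fraction = 0.8, seed = 1) {
  set.seed(seed)
  at <- system$atoms
  base <- attr(system, "coords")
  prows <- which(at$segment == "polymer" & at$element != "H")
  if (length(persistent) > length(prows))
    stop("more planted residues than polymer heavy atoms")
  ca <- vapply(persistent, function(r) {
    hit <- which(at$segment == "enzyme" & at$resid == r & at$name == "CA")
    if (!length(hit)) stop("residue ", r, " has no CA bead")
    hit[1]
  }, integer(1))
  n_contact <- round(fraction * n_frames)
  contact_frames <- sort(sample.int(n_frames, n_contact))
  far <- base
  far[at$segment == "polymer", 3] <- far[at$segment == "polymer", 3] + 100
  near <- far
  for (i in seq_along(persistent)) {
    p <- base[ca[i], ]
    near[prows[i], ] <- p * (1 + 2.5 / sqrt(sum(p^2)))
  }
  coords <- array(NA_real_, c(n_frames, nrow(at), 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- if (f %in% contact_frames) near else far
  traj <- trajectory(coords, time = seq_len(n_frames))
  attr(traj, "truth") <- list(persistent = persistent,
                              contact_fraction = n_contact / n_frames,
                              contact_frames = contact_frames)
  traj
}

#' Analytic 2D potentials for sampler validation
#'
#' `harmonic_potential(k)`: U = k/2 (x^2 + y^2).
#' `double_well_potential(v0, x0, w, ky, y0)`: a symmetric double well along
#' x, U = v0 (((x - x0)/w)^2 - 1)^2 + ky/2 (y - y0)^2, with minima at
#' x0 +/- w and a barrier of height v0 at x0. Units kJ/mol.
#'
#' @param k,v0,x0,w,ky,y0 Potential parameters (kJ/mol and Angstrom).
#' @return List with `fn(x, y)`, a `start` point and a `name`.
#' @export
harmonic_potential <- function(k = 1) {
  list(fn = function(x, y) 0.5 * k * (x^2 + y^2),
       start = c(0, 0), name = "harmonic", k = k)
}

#' @rdname harmonic_potential
#' @export
double_well_potential <- function(v0 = 6, x0 = 5, w = 2, ky = 1, y0 = 0) {
  list(fn = function(x, y)
    v0 * (((x - x0) / w)^2 - 1)^2 + 0.5 * ky * (y - y0)^2,
    start = c(x0 + w, y0), name = "double_well",
    v0 = v0, x0 = x0, w = w, ky = ky, y0 = y0)
}

#' Metropolis samples from a 2D Boltzmann density
#'
#' Random-walk Metropolis chain targeting exp(-U/kB T), with burn-in and
#' thinning. Proposals are isotropic Gaussian steps.
#'
#' @param potential A potential from [harmonic_potential()] or
#'   [double_well_potential()] (or any list with `fn` and `start`).
#' @param n Number of retained samples.
#' @param temperature Temperature, K (default 303).
#' @param seed RNG seed.
#' @param step Proposal standard deviation, Angstrom (default 0.4).
#' @param burn Burn-in iterations (default 1000).
#' @param thin Thinning stride (default 10).
#' @return data.frame `x`, `y`, `w` (unit weights); attributes
#'   `"acceptance"` and `"ess"` (effective sample size of x).
#' @export
sample_boltzmann2d <- function(potential, n, temperature = 303, seed = 1,
                               step = 0.4, burn = 1000, thin = 10) {
  set.seed(seed)
  kT <- KB_KJ * temperature
  total <- burn + n * thin
  prop <- matrix(stats::rnorm(2 * total, 0, step), ncol = 2)
  logu <- log(stats::runif(total))
  xs <- numeric(n); ys <- numeric(n)
  cur <- potential$start
  ucur <- potential$fn(cur[1], cur[2])
  acc <- 0L
  j <- 0L
  for (i in seq_len(total)) {
    cand <- cur + prop[i, ]
    ucand <- potential$fn(cand[1], cand[2])
    if (logu[i] < (ucur - ucand) / kT) {
      cur <- cand; ucur <- ucand; acc <- acc + 1L
    }
    if (i > burn && (i - burn) %% thin == 0L) {
      j <- j + 1L
      xs[j] <- cur[1]; ys[j] <- cur[2]
    }
  }
  if (acc == 0L)
    stop("zero acceptance over the whole run; decrease the step size")
  out <- data.frame(x = xs, y = ys, w = rep(1, n))
  rho <- stats::acf(xs, lag.max = 50, plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  tau <- 1 + 2 * sum(rho[seq_len(if (length(pos)) pos[1] else 50)])
  attr(out, "acceptance") <- acc / total
  attr(out, "ess") <- n / max(1, tau)
  out
}

#' Generate a noisy Michaelis-Menten rate dataset
#'
#' x values are log-spaced from K_m/10 to 10 K_m; rates are the model plus
#' Gaussian noise with sd `noise * V_max`, truncated at zero.
#'
#' @param km,vmax True parameters.
#' @param mode `"conv"` or `"inv"`.
#' @param n Number of points (>= 4, default 8).
#' @param noise Noise fraction of V_max (default 0.05).
#' @param seed RNG seed.
#' @param fixed,fixed_unit Fixed-partner annotation.
#' @return A `kinetic_dataset`; attribute `"truth"` holds km and vmax.
#' @export
make_kinetic_data <- function(km, vmax, mode = "conv", n = 8, noise = 0.05,
                              seed = 1, fixed = NA, fixed_unit = "") {
  if (n < 4) stop("n must be >= 4")
  set.seed(seed)
  x <- exp(seq(log(km / 10), log(10 * km), length.out = n))
  v <- vmax * x / (km + x)
  if (noise > 0) v <- pmax(0, v + stats::rnorm(n, 0, noise * vmax))
  ds <- kinetic_dataset(x, v, mode = mode, fixed = fixed,
                        fixed_unit = fixed_unit)
  attr(ds, "truth") <- list(km = km, vmax = vmax, noise = noise)
  ds
}

#' Write a complete fixture bundle to a directory
#'
#' Emits the toy topology (PDB), a parameter table (TSV), one entry
#' trajectory per corridor (frame-table dialect) and the ground truth
#' (JSON) so every reader in the package can be exercised on files.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param n_events Entry trajectories to write (cycled over corridors).
#' @param noise Positional noise, Angstrom.
#' @return Invisibly, the list of paths written.
#' @export
write_fixture_bundle <- function(dir, seed = 1, n_events = 3, noise = 0.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sys <- make_toy_system(seed = seed)
  paths <- list(topology = file.path(dir, "toy_system.pdb"),
                params = file.path(dir, "toy_params.tsv"),
                truth = file.path(dir, "truth.json"))
  write_system_pdb(sys, attr(sys, "coords"), paths$topology)
  write_param_table(sys$atoms, paths$params)
  truths <- list()
  for (i in seq_len(n_events)) {
    corridor <- (i - 1L) %% 3L + 1L
    traj <- simulate_entry(sys, corridor = corridor, seed = seed + i,
                           noise = noise)
    p <- file.path(dir, sprintf("entry_%02d.traj", i))
    write_trajectory_table(traj, p)
    paths[[sprintf("entry_%02d", i)]] <- p
    tr <- attr(traj, "truth")
    truths[[i]] <- list(corridor = tr$corridor, face = tr$face,
                        outside = range(tr$outside),
                        inside = range(tr$inside))
  }
  jsonlite::write_json(list(seed = seed, events = truths), paths$truth,
                       auto_unbox = TRUE)
  invisible(paths)
}
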
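# Small systems and trajectories built in code for the unit tests.

# Minimal annotated system: SER (CA + OG) at residue 1, two oxyanion
# hydrogens at residues 2/3, then a polymer whose atoms are given by the
# caller. Positions are supplied alongside as a matrix in atom order.
micro_system <- function(poly, poly_pos,
                         enz_pos = rbind(c(0, 0, 0),      # CA
                                         c(0, 0, 1),      # OG
                                         c(1.2, 0, 1.6),  # HN1
                                         c(-1.2, 0, 1.6)),# HN2
                         og_charge = 0, units = NULL, ester = NULL) {
  enz <- data.frame(name = c("CA", "OG", "HN1", "HN2"),
                    element = c("C", "O", "H", "H"),
                    charge = c(0, og_charge, 0, 0), sigma = 0, epsilon = 0,
                    resid = c(1, 1, 2, 3),
                    resname = c("SER", "SER", "GLY", "GLY"),
                    segment = "enzyme", stringsAsFactors = FALSE)
  poly$segment <- "polymer"
  atoms <- rbind(enz, poly)
  atoms$id <- seq_len(nrow(atoms))
  if (is.null(units)) units <- list(atoms$id[atoms$segment == "polymer"])
  sys <- molecular_system(atoms, serine_ogamma = 2,
                          oxyanion_donors = c(3, 4),
                          polymer_units = units,
                          ester_bonds = if (is.null(ester))
                            matrix(integer(0), ncol = 3) else ester)
  attr(sys, "coords") <- rbind(enz_pos, poly_pos)
  sys
}

poly_beads <- function(n, name = "P", element = "C", charge = 0,
                       sigma = 0, epsilon = 0, resid0 = 10) {
  data.frame(name = paste0(name, seq_len(n)), element = element,
             charge = charge, sigma = sigma, epsilon = epsilon,
             resid = resid0 + seq_len(n) - 1L, resname = "PET",
             stringsAsFactors = FALSE)
}

one_frame_traj <- function(coords) {
  trajectory(array(coords, c(1, nrow(coords), 3)))
}

multi_frame_traj <- function(frames, ...) {
  coords <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, ...)
}

# Entry series assembled directly (for segmentation tests)
fake_entry_series <- function(ser_c, productive = NULL, face = NULL,
                              weight = NULL) {
  n <- length(ser_c)
  structure(data.frame(frame = seq_len(n), time = seq_len(n),
                       ser_c = ser_c, ester = 1L,
                       oxy1 = ser_c, oxy2 = ser_c,
                       productive = if (is.null(productive)) ser_c <= 4
                                    else productive,
                       face = if (is.null(face)) rep("si", n) else face,
                       stringsAsFactors = FALSE),
            weight = if (is.null(weight)) rep(1, n) else weight,
            class = c("entry_series", "data.frame"))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

transform_traj <- function(traj, R = diag(3), shift = c(0, 0, 0),
                           mirror = FALSE) {
  M <- if (mirror) diag(c(-1, 1, 1)) else diag(3)
  coords <- traj$coords
  for (f in seq_len(traj$n_frames)) {
    xyz <- matrix(coords[f, , ], ncol = 3) %*% t(M) %*% t(R)
    coords[f, , ] <- sweep(xyz, 2, shift, "+")
  }
  trajectory(coords, time = traj$time, box = traj$box,
             replica = traj$replica, weight = traj$weight)
}

best_label_agreement <- function(assigned, truth, k = 3) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  max(vapply(perms(seq_len(k)), function(p)
    mean(p[truth] == assigned), numeric(1)))
}
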
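# Independent brute-force oracles the implementations are checked against.

# All-pairs residue-polymer contact matrix: plain double loop, no cell list.
brute_contact_matrix <- function(traj, system, cutoff) {
  at <- system$atoms
  erows <- which(at$segment == "enzyme" & at$element != "H")
  prows <- which(at$segment == "polymer" & at$element != "H")
  resids <- unique(at$resid[erows])
  mat <- matrix(FALSE, length(resids), traj$n_frames,
                dimnames = list(resids, NULL))
  mi <- function(d, L) d - L * round(d / L)
  for (f in seq_len(traj$n_frames)) {
    xyz <- matrix(traj$coords[f, , ], ncol = 3)
    for (ri in seq_along(resids)) {
      rows <- erows[at$resid[erows] == resids[ri]]
      found <- FALSE
      for (i in rows) {
        for (j in prows) {
          d <- xyz[i, ] - xyz[j, ]
          if (!is.null(traj$box)) d <- mi(d, traj$box[f, ])
          if (sqrt(sum(d^2)) <= cutoff) { found <- TRUE; break }
        }
        if (found) break
      }
      mat[ri, f] <- found
    }
  }
  mat
}

# Plain double-loop nonbonded energy, no vectorization, no cell list.
brute_pair_energy <- function(xyz, groupA, groupB, system, config,
                              box = NULL) {
  at <- system$atoms
  k <- config$coulomb_constant
  coul <- lj <- 0
  for (ia in groupA) {
    for (ib in groupB) {
      i <- match(ia, at$id); j <- match(ib, at$id)
      d <- xyz[i, ] - xyz[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r <= config$nonbonded_cutoff) {
        coul <- coul + k * at$charge[i] * at$charge[j] / r
        sij <- (at$sigma[i] + at$sigma[j]) / 2
        eij <- sqrt(at$epsilon[i] * at$epsilon[j])
        lj <- lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
      }
    }
  }
  list(coulomb = coul, lj = lj, total = coul + lj)
}

# Dense covariance + eigen PCA oracle (unit weights).
brute_pca <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  cv <- crossprod(xc) / nrow(x)
  eigen(cv, symmetric = TRUE)
}
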
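# Pairwise nonbonded interaction energies (truncated Coulomb + Lennard-Jones
# 12-6, Lorentz-Berthelot combination), aggregated per residue and per
# physicochemical residue class.

#' Nonbonded interaction energy between two atom groups in one frame
#'
#' E = sum over pairs (i in A, j in B) with r_ij <= cutoff of
#' k q_i q_j / r_ij + 4 eps_ij ((sig_ij/r_ij)^12 - (sig_ij/r_ij)^6),
#' with sig_ij = (sig_i + sig_j)/2 and eps_ij = sqrt(eps_i eps_j).
#' Plain truncation, dielectric 1, no switching or long-range correction:
#' only orderings and differences of these energies are used downstream, and
#' those are robust to the truncation scheme.
#'
#' @param xyz Frame coordinates, atoms x 3 (rows in system atom order).
#' @param groupA,groupB Disjoint atom-id vectors.
#' @param system `molecular_system` carrying charges and LJ parameters.
#' @param config An `analysis_config` (Coulomb constant, cutoff).
#' @param box Optional length-3 periodic box (minimum image).
#' @return List with `coulomb`, `lj`, `total` (kcal/mol).
#' @export
pair_energy <- function(xyz, groupA, groupB, system,
                        config = analysis_config(), box = NULL) {
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ",
         paste(intersect(groupA, groupB), collapse = ", "))
  ra <- atom_rows(system, groupA)
  rb <- atom_rows(system, groupB)
  if (anyNA(ra) || anyNA(rb)) stop("unknown atom id in group")
  r <- dist_pairs(xyz[ra, , drop = FALSE], xyz[rb, , drop = FALSE], box)
  within <- r <= config$nonbonded_cutoff
  if (any(within & r == 0))
    stop("clashing coordinates: zero interatomic distance")
  at <- system$atoms
  qq <- outer(at$charge[ra], at$charge[rb])
  sig <- outer(at$sigma[ra], at$sigma[rb], function(a, b) (a + b) / 2)
  eps <- outer(at$epsilon[ra], at$epsilon[rb], function(a, b) sqrt(a * b))
  coul <- lj <- 0
  if (any(within)) {
    rr <- r[within]
    coul <- sum(config$coulomb_constant * qq[within] / rr)
    sr6 <- (sig[within] / rr)^6
    lj <- sum(4 * eps[within] * (sr6 * sr6 - sr6))
  }
  list(coulomb = coul, lj = lj, total = coul + lj)
}

#' @keywords internal
new_energy_series <- function(frame, time, coulomb, lj, weight, group) {
  structure(data.frame(frame = frame, time = time, coulomb = coulomb,
                       lj = lj, total = coulomb + lj),
            weight = weight, group = group,
            class = c("energy_series", "data.frame"))
}

#' Per-residue interaction-energy series against the whole polymer
#'
#' One energy series per enzyme residue; residues that never come within the
#' nonbonded cutoff contribute all-zero series.
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` (parameters required).
#' @param config An `analysis_config`.
#' @param residues Optional residue indices (default: all enzyme residues).
#' @return Named list (residue index) of `energy_series` data.frames.
#' @export
residue_energy_series <- function(traj, system, config = analysis_config(),
                                  residues = NULL) {
  at <- system$atoms
  pids <- at$id[at$segment == "polymer"]
  if (is.null(residues))
    residues <- unique(at$resid[at$segment == "enzyme"])
  out <- vector("list", length(residues))
  names(out) <- residues
  for (k in seq_along(residues)) {
    gids <- at$id[at$segment == "enzyme" & at$resid == residues[k]]
    coul <- lj <- numeric(traj$n_frames)
    for (f in seq_len(traj$n_frames)) {
      e <- pair_energy(frame_coords(traj, f), gids, pids, system, config,
                       box = if (is.null(traj$box)) NULL else traj$box[f, ])
      coul[f] <- e$coulomb; lj[f] <- e$lj
    }
    out[[k]] <- new_energy_series(seq_len(traj$n_frames), traj$time,
                                  coul, lj, traj$weight,
                                  group = as.character(residues[k]))
  }
  out
}

#' Weighted mean total energy of a series
#' @param series An `energy_series`.
#' @export
mean_energy <- function(series) {
  w <- attr(series, "weight")
  if (is.null(w)) w <- rep(1, nrow(series))
  sum(series$total * w) / sum(w)
}

#' Default physicochemical residue classes
#'
#' apolar: A V L I M G P C; polar: S T N Q; charged: D E K R H;
#' aromatic: F Y W. Histidine sits in `charged`; override by supplying a
#' modified map to [class_profile()].
#' @return Named character vector, 3-letter code to class.
#' @export
default_class_map <- function() {
  c(ALA = "apolar", VAL = "apolar", LEU = "apolar", ILE = "apolar",
    MET = "apolar", GLY = "apolar", PRO = "apolar", CYS = "apolar",
    SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
    ASP = "charged", GLU = "charged", LYS = "charged", ARG = "charged",
    HIS = "charged",
    PHE = "aromatic", TYR = "aromatic", TRP = "aromatic")
}

#' Interaction-energy profile per physicochemical residue class
#'
#' The class value is the sum of the per-residue weighted mean energies of
#' the contacting residues in that class, scaled by (divided by) the number
#' of contacting residues of the class.
#'
#' @param series Named list of per-residue `energy_series`
#'   (from [residue_energy_series()]).
#' @param contacts Residue indices in contact (e.g. [persistence_filter()]
#'   output, or all residues ever in contact).
#' @param system `molecular_system` (residue names).
#' @param class_map Amino-acid to class map (default [default_class_map()]).
#' @return List of class `class_profile`: per-class scaled means, per-residue
#'   unscaled means, contacting-residue counts.
#' @export
class_profile <- function(series, contacts, system,
                          class_map = default_class_map()) {
  if (!length(contacts)) stop("contact set is empty")
  resids <- as.integer(names(series))
  keep <- resids %in% contacts
  if (!any(keep)) stop("no energy series for any contacting residue")
  resids <- resids[keep]
  means <- vapply(series[keep], mean_energy, numeric(1))
  rn <- system$atoms$resname[match(resids, system$atoms$resid)]
  cls <- unname(class_map[rn])
  if (anyNA(cls))
    stop("residue name(s) missing from class map: ",
         paste(unique(rn[is.na(cls)]), collapse = ", "))
  agg <- tapply(means, cls, sum)
  cnt <- tapply(means, cls, length)
  structure(list(class_energy = agg / cnt,
                 n_contacting = cnt,
                 residue_mean = stats::setNames(means, resids),
                 residue_class = stats::setNames(cls, resids)),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat("<class_profile> scaled mean E_int (kcal/mol) per class:\n")
  print(round(x$class_energy, 3))
  invisible(x)
}

#' Intramolecular polymer unit-unit interaction energy
#'
#' Nonbonded energy between two non-adjacent repeat units of the polymer
#' chain (|i - j| >= 2; adjacent units share an ester bond and their
#' interaction is dominated by bonded terms that this model excludes).
#'
#' @param traj,system,config As in [residue_energy_series()].
#' @param i,j Unit indices (1-based along the chain).
#' @return An `energy_series`.
#' @export
pet_internal_energy <- function(traj, system, config = analysis_config(),
                                i, j) {
  n <- length(system$polymer_units)
  if (i < 1 || j < 1 || i > n || j > n) stop("unit index out of range")
  if (abs(i - j) < 2) stop("units must be non-adjacent (|i - j| >= 2)")
  coul <- lj <- numeric(traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    e <- pair_energy(frame_coords(traj, f), system$polymer_units[[i]],
                     system$polymer_units[[j]], system, config,
                     box = if (is.null(traj$box)) NULL else traj$box[f, ])
    coul[f] <- e$coulomb; lj[f] <- e$lj
  }
  new_energy_series(seq_len(traj$n_frames), traj$time, coul, lj,
                    traj$weight, group = paste0("unit", i, "-unit", j))
}

#' Time of binding onset
#'
#' First frame time at which the total interaction energy drops below the
#' threshold; `NA` if it never does.
#'
#' @param series An `energy_series`.
#' @param threshold Negative energy threshold, kcal/mol (default -10).
#' @export
binding_onset <- function(series, threshold = -10) {
  if (threshold >= 0) stop("threshold must be negative")
  hit <- which(series$total < threshold)
  if (!length(hit)) NA_real_ else series$time[hit[1]]
}

#' Per-site mean-energy comparison between parent and variant
#'
#' @param parent,variant Named lists of per-residue `energy_series` for the
#'   two systems.
#' @param sites Residue indices to compare (e.g. mutation sites).
#' @return data.frame with `site`, `parent_mean`, `variant_mean`, `delta`
#'   (variant - parent; positive = weakened binding).
#' @export
site_delta_eint <- function(parent, variant, sites) {
  miss <- setdiff(as.character(sites),
                  intersect(names(parent), names(variant)))
  if (length(miss))
    stop("site(s) missing in parent or variant: ",
         paste(miss, collapse = ", "))
  pm <- vapply(parent[as.character(sites)], mean_energy, numeric(1))
  vm <- vapply(variant[as.character(sites)], mean_energy, numeric(1))
  data.frame(site = as.integer(sites), parent_mean = unname(pm),
             variant_mean = unname(vm), delta = unname(vm - pm))
}

#' Write per-residue energy series to TSV
#' @param series Named list of `energy_series`.
#' @param path Output TSV (`frame residue coulomb lj total`).
#' @export
write_energy_table <- function(series, path) {
  out <- do.call(rbind, lapply(names(series), function(r) {
    s <- series[[r]]
    data.frame(frame = s$frame, residue = r, coulomb = s$coulomb,
               lj = s$lj, total = s$total)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
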
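# Shared data model: annotated molecular systems, trajectories, configuration,
# and readers/writers for the PDB and plain-text frame-table formats.

#' Construct an annotated molecular system
#'
#' A `molecular_system` bundles an atom table with the annotations every
#' downstream analysis needs: the catalytic serine's gamma-oxygen, the two
#' oxyanion-hole amide hydrogens, the ordered polymer units and the ester-bond
#' atom triplets (carbonyl carbon, carbonyl oxygen, ester oxygen).
#'
#' @param atoms data.frame with columns `id` (integer, unique), `name`,
#'   `element`, `charge` (e), `sigma` (Angstrom), `epsilon` (kcal/mol),
#'   `resid` (integer residue index), `resname` (3-letter code), `segment`
#'   (`"enzyme"` or `"polymer"`).
#' @param serine_ogamma Atom id of the catalytic serine gamma-oxygen.
#' @param histidine_residue,aspartate_residue Residue indices of the other
#'   two triad members (annotation only; not used geometrically).
#' @param oxyanion_donors Integer vector of length 2: atom ids of the two
#'   oxyanion-hole amide hydrogens.
#' @param polymer_units List of integer vectors, ordered along the chain; each
#'   vector holds the atom ids of one repeat unit. Units must be disjoint.
#' @param ester_bonds Integer matrix with 3 columns (carbonyl C, carbonyl O,
#'   ester O), one row per ester bond, ordered along the chain.
#' @param params_present Logical; `FALSE` when charges/LJ parameters were
#'   defaulted to zero because no parameter table was supplied.
#' @param serine_resname Expected residue name at the serine site (override
#'   for non-standard naming).
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, serine_ogamma, histidine_residue = NA_integer_,
                             aspartate_residue = NA_integer_, oxyanion_donors,
                             polymer_units, ester_bonds,
                             params_present = TRUE, serine_resname = "SER") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("id", "name", "element", "charge", "sigma", "epsilon",
              "resid", "resname", "segment")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$id))
    stop("duplicate atom ids: ",
         paste(unique(atoms$id[duplicated(atoms$id)]), collapse = ", "))
  if (!all(atoms$segment %in% c("enzyme", "polymer")))
    stop("segment must be 'enzyme' or 'polymer'")
  ester_bonds <- matrix(as.integer(ester_bonds), ncol = 3,
                        dimnames = list(NULL, c("carbon", "carbonyl_oxygen",
                                                "ester_oxygen")))
  sys <- structure(list(
    atoms = atoms,
    catalytic = list(serine_ogamma = as.integer(serine_ogamma),
                     histidine_residue = as.integer(histidine_residue),
                     aspartate_residue = as.integer(aspartate_residue)),
    oxyanion_donors = as.integer(oxyanion_donors),
    polymer_units = lapply(polymer_units, as.integer),
    ester_bonds = ester_bonds,
    params_present = isTRUE(params_present)
  ), class = "molecular_system")
  validate_system(sys, serine_resname = serine_resname)
  sys
}

#' @keywords internal
validate_system <- function(sys, serine_resname = "SER") {
  at <- sys$atoms
  row_of <- function(ids, what) {
    idx <- match(ids, at$id)
    if (anyNA(idx))
      stop(what, ": atom id(s) not found: ",
           paste(ids[is.na(idx)], collapse = ", "))
    idx
  }
  og <- row_of(sys$catalytic$serine_ogamma, "serine_ogamma")
  if (at$resname[og] != serine_resname)
    stop("serine_ogamma atom belongs to residue '", at$resname[og],
         "', expected '", serine_resname, "'")
  if (length(sys$oxyanion_donors) != 2L)
    stop("exactly two oxyanion donor hydrogens required")
  don <- row_of(sys$oxyanion_donors, "oxyanion donor")
  if (!all(at$segment[don] == "enzyme"))
    stop("oxyanion donors must belong to the enzyme segment")
  eb <- as.vector(sys$ester_bonds)
  if (length(eb)) {
    ebr <- row_of(eb, "ester bond")
    if (!all(at$segment[ebr] == "polymer"))
      stop("ester-bond atoms must belong to the polymer segment")
  }
  pu <- unlist(sys$polymer_units)
  if (anyDuplicated(pu))
    stop("polymer units are not disjoint")
  row_of(pu, "polymer unit")
  invisible(sys)
}

#' @export
print.molecular_system <- function(x, ...) {
  at <- x$atoms
  cat("<molecular_system> ", nrow(at), " atoms (",
      sum(at$segment == "enzyme"), " enzyme, ",
      sum(at$segment == "polymer"), " polymer), ",
      length(x$polymer_units), " polymer units, ",
      nrow(x$ester_bonds), " ester bonds\n", sep = "")
  cat("  serine Ogamma atom ", x$catalytic$serine_ogamma,
      "; oxyanion donors ", paste(x$oxyanion_donors, collapse = ", "),
      "; parameters ", if (x$params_present) "present" else "absent (zeroed)",
      "\n", sep = "")
  invisible(x)
}

# -- atom-selection helpers ---------------------------------------------------

#' @keywords internal
atom_rows <- function(sys, ids) match(ids, sys$atoms$id)

#' @keywords internal
enzyme_heavy_rows <- function(sys) {
  which(sys$atoms$segment == "enzyme" & sys$atoms$element != "H")
}

#' @keywords internal
polymer_heavy_rows <- function(sys) {
  which(sys$atoms$segment == "polymer" & sys$atoms$element != "H")
}

#' Construct a trajectory object
#'
#' @param coords Numeric array `frames x atoms x 3` (Angstrom).
#' @param time Numeric vector of frame times (ns), strictly increasing.
#'   Defaults to `1:n_frames`.
#' @param box Optional `frames x 3` matrix of orthorhombic box lengths
#'   (Angstrom); `NULL` for free-space.
#' @param replica Optional integer replica index per frame.
#' @param weight Non-negative frame weights; default 1.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, time = NULL, box = NULL, replica = NULL,
                       weight = NULL) {
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  nf <- d[1]
  if (is.null(time)) time <- seq_len(nf)
  if (length(time) != nf) stop("time length must equal number of frames")
  if (nf > 1L && any(diff(time) <= 0))
    stop("time must be strictly increasing")
  if (!is.null(box)) {
    box <- matrix(box, nrow = nf, ncol = 3)
    if (any(box <= 0)) stop("box lengths must be positive")
  }
  if (is.null(weight)) weight <- rep(1, nf)
  if (length(weight) != nf) stop("weight length must equal number of frames")
  if (any(weight < 0) || all(weight == 0))
    stop("weights must be >= 0 with at least one > 0")
  if (!is.null(replica) && length(replica) != nf)
    stop("replica length must equal number of frames")
  structure(list(coords = coords, time = as.numeric(time), box = box,
                 replica = if (is.null(replica)) NULL else as.integer(replica),
                 weight = as.numeric(weight), n_frames = nf,
                 n_atoms = d[2]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$n_frames, " frames x ", x$n_atoms, " atoms",
      if (!is.null(x$box)) ", periodic box" else ", free space",
      if (!is.null(x$replica)) ", replica-indexed" else "", "\n", sep = "")
  invisible(x)
}

#' Frame coordinates as an atoms x 3 matrix
#' @param traj A `trajectory`.
#' @param i Frame index.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Analysis configuration with package defaults
#'
#' Central container for the geometric and energetic thresholds used across
#' the pipeline. Distances are Angstrom, energies kcal/mol, temperature K.
#'
#' @param contact_cutoff Residue-polymer heavy-atom contact cutoff (default 3).
#' @param persistence_fraction Minimum fraction of simulation time a contact
#'   must persist (default 0.75).
#' @param proximal_radius Polymer-to-serine-Ogamma distance separating
#'   proximal from distal binding (default 12).
#' @param productive_cutoff Distance bound on SER-C and both oxyanion-hole
#'   distances for a productive pose (default 4).
#' @param outer_boundary Outer SER-C boundary marking the outside phase
#'   (default 6).
#' @param pca_radius Radius for selecting C-alpha atoms around the tracked
#'   ester carbon (default 10).
#' @param binding_energy_threshold Interaction energy marking binding onset
#'   (default -10 kcal/mol).
#' @param temperature Temperature used for free-energy surfaces (default 303).
#' @param coulomb_constant Electrostatic prefactor, kcal A / (mol e^2).
#' @param nonbonded_cutoff Pairwise nonbonded cutoff (default 12).
#' @param seed Integer seed echoed to generators.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(contact_cutoff = 3.0, persistence_fraction = 0.75,
                            proximal_radius = 12.0, productive_cutoff = 4.0,
                            outer_boundary = 6.0, pca_radius = 10.0,
                            binding_energy_threshold = -10.0,
                            temperature = 303, coulomb_constant = 332.0636,
                            nonbonded_cutoff = 12.0, seed = 1L) {
  cfg <- list(contact_cutoff = contact_cutoff,
              persistence_fraction = persistence_fraction,
              proximal_radius = proximal_radius,
              productive_cutoff = productive_cutoff,
              outer_boundary = outer_boundary,
              pca_radius = pca_radius,
              binding_energy_threshold = binding_energy_threshold,
              temperature = temperature,
              coulomb_constant = coulomb_constant,
              nonbonded_cutoff = nonbonded_cutoff,
              seed = as.integer(seed))
  dists <- c("contact_cutoff", "proximal_radius", "productive_cutoff",
             "outer_boundary", "pca_radius", "nonbonded_cutoff")
  for (d in dists)
    if (cfg[[d]] <= 0) stop(d, " must be > 0")
  if (cfg$productive_cutoff >= cfg$outer_boundary)
    stop("productive_cutoff must be smaller than outer_boundary")
  if (cfg$persistence_fraction <= 0 || cfg$persistence_fraction > 1)
    stop("persistence_fraction must lie in (0, 1]")
  structure(cfg, class = "analysis_config")
}

# -- PDB topology -------------------------------------------------------------

#' Read an annotated topology from a PDB file
#'
#' Reads a PDB file (via bio3d) and attaches the catalytic-site and polymer
#' annotations required by the analyses. Residue numbering is taken verbatim
#' from the PDB residue field (author numbering, no renumbering).
#'
#' @param path PDB file.
#' @param annotations List with entries:
#'   \describe{
#'     \item{polymer_resnames}{character; residue names forming the polymer
#'       segment (all other residues are the enzyme).}
#'     \item{serine_resid}{residue index of the catalytic serine.}
#'     \item{serine_atom}{atom name of its gamma-oxygen (default `"OG"`).}
#'     \item{oxyanion}{data.frame with columns `resid`, `atom` (2 rows), the
#'       oxyanion-hole amide hydrogens.}
#'     \item{ester_template}{named list `carbon`, `carbonyl_oxygen`,
#'       `ester_oxygen` of atom names; every polymer residue carrying all
#'       three yields one ester triplet. Alternatively supply
#'       `ester_bonds`, an explicit 3-column matrix of atom serials.}
#'     \item{histidine_resid, aspartate_resid}{optional triad annotation.}
#'     \item{serine_resname}{optional expected residue name (default SER).}
#'   }
#' @param params Optional nonbonded parameter table (path to a TSV or a
#'   data.frame; see [read_param_table()]). Absent parameters default to 0
#'   and the system is flagged `params_present = FALSE`.
#' @return A `molecular_system`; reference coordinates are attached as
#'   attribute `"coords"` (atoms x 3 matrix).
#' @export
read_topology <- function(path, annotations, params = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (anyDuplicated(at$eleno))
    stop("duplicate atom serials in ", path)
  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  poly <- at$resid %in% annotations$polymer_resnames
  atoms <- data.frame(id = at$eleno,
                      name = trimws(at$elety),
                      element = trimws(element),
                      charge = 0, sigma = 0, epsilon = 0,
                      resid = at$resno,
                      resname = trimws(at$resid),
                      segment = ifelse(poly, "polymer", "enzyme"),
                      stringsAsFactors = FALSE)
  params_present <- FALSE
  if (!is.null(params)) {
    tab <- if (is.character(params)) read_param_table(params) else params
    atoms <- apply_param_table(atoms, tab)
    params_present <- TRUE
  }
  find_atom <- function(resid, name, what) {
    hit <- which(atoms$resid == resid & atoms$name == name)
    if (length(hit) != 1L)
      stop(what, ": ", name, " atom not found in residue ", resid)
    atoms$id[hit]
  }
  ser_atom <- annotations$serine_atom %||% "OG"
  og <- find_atom(annotations$serine_resid, ser_atom, "catalytic serine")
  oxy <- annotations$oxyanion
  don <- vapply(seq_len(nrow(oxy)), function(i)
    find_atom(oxy$resid[i], oxy$atom[i], "oxyanion donor"), integer(1))
  units <- split(atoms$id[poly], factor(atoms$resid[poly],
                                        levels = unique(atoms$resid[poly])))
  if (!is.null(annotations$ester_bonds)) {
    eb <- matrix(as.integer(annotations$ester_bonds), ncol = 3)
  } else {
    tpl <- annotations$ester_template
    if (is.null(tpl))
      stop("annotations need either ester_bonds or ester_template")
    eb <- do.call(rbind, lapply(unique(atoms$resid[poly]), function(r) {
      ids <- vapply(c(tpl$carbon, tpl$carbonyl_oxygen, tpl$ester_oxygen),
                    function(nm) {
                      hit <- which(atoms$resid == r & atoms$name == nm)
                      if (length(hit) == 1L) atoms$id[hit] else NA_integer_
                    }, integer(1))
      if (anyNA(ids)) NULL else ids
    }))
    if (is.null(eb)) eb <- matrix(integer(0), ncol = 3)
  }
  sys <- molecular_system(
    atoms, serine_ogamma = og,
    histidine_residue = annotations$histidine_resid %||% NA_integer_,
    aspartate_residue = annotations$aspartate_resid %||% NA_integer_,
    oxyanion_donors = don, polymer_units = unname(units), ester_bonds = eb,
    params_present = params_present,
    serine_resname = annotations$serine_resname %||% "SER")
  attr(sys, "coords") <- matrix(c(at$x, at$y, at$z), ncol = 3)
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a nonbonded parameter table
#'
#' TSV with columns `atom_name`, `residue_name`, `charge`, `sigma`,
#' `epsilon`. `residue_name` may be `"*"` to match any residue.
#' @param path TSV file.
#' @export
read_param_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("atom_name", "residue_name", "charge", "sigma", "epsilon")
  if (!all(needed %in% names(tab)))
    stop("parameter table needs columns: ", paste(needed, collapse = ", "))
  tab
}

#' @keywords internal
apply_param_table <- function(atoms, tab) {
  key_exact <- paste(atoms$resname, atoms$name)
  hit <- match(key_exact, paste(tab$residue_name, tab$atom_name))
  wild <- match(atoms$name, tab$atom_name[tab$residue_name == "*"])
  wild_rows <- which(tab$residue_name == "*")[wild]
  use <- ifelse(is.na(hit), wild_rows, hit)
  ok <- !is.na(use)
  atoms$charge[ok] <- tab$charge[use[ok]]
  atoms$sigma[ok] <- tab$sigma[use[ok]]
  atoms$epsilon[ok] <- tab$epsilon[use[ok]]
  atoms
}

#' Write a nonbonded parameter table
#' @param atoms Atom table of a `molecular_system`.
#' @param path Output TSV.
#' @export
write_param_table <- function(atoms, path) {
  tab <- unique(data.frame(atom_name = atoms$name,
                           residue_name = atoms$resname,
                           charge = atoms$charge, sigma = atoms$sigma,
                           epsilon = atoms$epsilon,
                           stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- trajectories -------------------------------------------------------------

#' Read a coordinate trajectory
#'
#' Two dialects: multi-model PDB (`"multi-model-pdb"`), and the package's
#' plain-text frame table (`"frame-table"`) whose header is
#' `#frame time atom x y z [box_x box_y box_z] [replica] [weight]`, one row
#' per atom per frame, whitespace-separated, coordinates with 4 decimals.
#'
#' @param path Input file.
#' @param system The matching `molecular_system` (atom-count check).
#' @param dialect `"multi-model-pdb"` or `"frame-table"`.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, system,
                            dialect = c("frame-table", "multi-model-pdb")) {
  dialect <- match.arg(dialect)
  n_at <- nrow(system$atoms)
  if (dialect == "multi-model-pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    nf <- nrow(xyz)
    if (ncol(xyz) != 3L * n_at)
      stop("atom-count mismatch in frame 1: trajectory has ",
           ncol(xyz) / 3, " atoms, system has ", n_at)
    coords <- array(NA_real_, c(nf, n_at, 3))
    for (f in seq_len(nf))
      coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    return(trajectory(coords, time = seq_len(nf)))
  }
  lines <- readLines(path)
  hdr_i <- grep("^#frame", lines)[1]
  if (is.na(hdr_i)) stop("frame-table header line '#frame ...' not found")
  cols <- strsplit(sub("^#", "", lines[hdr_i]), "[[:space:]]+")[[1]]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  tab <- utils::read.table(text = body, col.names = cols)
  frames <- unique(tab$frame)
  nf <- length(frames)
  per <- nrow(tab) / nf
  if (per != n_at) {
    bad <- which(tabulate(factor(tab$frame, levels = frames)) != n_at)[1]
    stop("atom-count mismatch in frame ",
         if (is.na(bad)) frames[1] else frames[bad],
         ": expected ", n_at, " atoms per frame")
  }
  ord <- order(match(tab$frame, frames))
  tab <- tab[ord, ]
  coords <- array(NA_real_, c(nf, n_at, 3))
  coords[, , 1] <- matrix(tab$x, nrow = nf, byrow = TRUE)
  coords[, , 2] <- matrix(tab$y, nrow = nf, byrow = TRUE)
  coords[, , 3] <- matrix(tab$z, nrow = nf, byrow = TRUE)
  first <- !duplicated(tab$frame)
  tm <- tab$time[first]
  if (nf > 1L && any(diff(tm) <= 0))
    stop("frame times must be strictly increasing")
  box <- if (all(c("box_x", "box_y", "box_z") %in% cols))
    cbind(tab$box_x[first], tab$box_y[first], tab$box_z[first]) else NULL
  trajectory(coords, time = tm, box = box,
             replica = if ("replica" %in% cols) tab$replica[first] else NULL,
             weight = if ("weight" %in% cols) tab$weight[first] else NULL)
}

#' Write a trajectory in the frame-table dialect
#' @param traj A `trajectory`.
#' @param path Output file.
#' @export
write_trajectory_table <- function(traj, path) {
  cols <- c("frame", "time", "atom", "x", "y", "z")
  if (!is.null(traj$box)) cols <- c(cols, "box_x", "box_y", "box_z")
  if (!is.null(traj$replica)) cols <- c(cols, "replica")
  cols <- c(cols, "weight")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = " ")), con)
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    row <- data.frame(frame = f, time = traj$time[f],
                      atom = seq_len(traj$n_atoms),
                      x = sprintf("%.4f", xyz[, 1]),
                      y = sprintf("%.4f", xyz[, 2]),
                      z = sprintf("%.4f", xyz[, 3]))
    if (!is.null(traj$box)) {
      row$box_x <- traj$box[f, 1]; row$box_y <- traj$box[f, 2]
      row$box_z <- traj$box[f, 3]
    }
    if (!is.null(traj$replica)) row$replica <- traj$replica[f]
    row$weight <- traj$weight[f]
    utils::write.table(row, con, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a system (and optional trajectory) as PDB
#'
#' @param system A `molecular_system`.
#' @param coords Atoms x 3 matrix, or a `trajectory` for a multi-model file.
#' @param path Output PDB.
#' @export
write_system_pdb <- function(system, coords, path) {
  at <- system$atoms
  resno <- at$resid
  chain <- ifelse(at$segment == "enzyme", "A", "B")
  if (inherits(coords, "trajectory")) {
    xyz <- do.call(rbind, lapply(seq_len(coords$n_frames), function(f)
      as.vector(t(frame_coords(coords, f)))))
  } else {
    xyz <- as.vector(t(coords))
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = at$resname,
                   eleno = at$id, elety = at$name, chain = chain,
                   elesy = at$element)
  invisible(path)
}

# -- geometry helpers (shared) ------------------------------------------------

#' Pairwise distances with optional minimum-image convention
#' @param a,b Coordinate matrices (n x 3, m x 3).
#' @param box Optional length-3 orthorhombic box.
#' @return n x m distance matrix (Angstrom).
#' @keywords internal
dist_pairs <- function(a, b, box = NULL) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}
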
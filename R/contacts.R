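# Residue-polymer contact detection, persistence filtering and the
# proximal/distal classification around the catalytic serine.

#' Per-frame residue-polymer contact matrix
#'
#' A residue is in contact with the polymer in a frame iff the minimum
#' heavy-atom/heavy-atom distance between the residue and any polymer atom is
#' at or below the cutoff (inclusive boundary). Hydrogens are excluded.
#' Free-space frames use a cell-list neighbour search with cell size equal to
#' the cutoff; frames with a periodic box use a dense minimum-image path.
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` with a non-empty polymer segment.
#' @param cutoff Contact cutoff, Angstrom (default 3).
#' @return A `contact_map`: logical matrix residues x frames plus weighted
#'   per-residue contact fractions.
#' @export
contact_matrix <- function(traj, system, cutoff = 3.0) {
  erows <- enzyme_heavy_rows(system)
  prows <- polymer_heavy_rows(system)
  if (!length(prows)) stop("polymer segment is empty")
  if (cutoff <= 0) stop("cutoff must be > 0")
  eres <- system$atoms$resid[erows]
  resids <- unique(eres)
  res_f <- match(eres, resids)
  mat <- matrix(FALSE, length(resids), traj$n_frames,
                dimnames = list(resids, NULL))
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    hit <- if (is.null(box))
      cell_contact_hits(xyz[erows, , drop = FALSE],
                        xyz[prows, , drop = FALSE], cutoff)
    else
      apply(dist_pairs(xyz[erows, , drop = FALSE],
                       xyz[prows, , drop = FALSE], box) <= cutoff, 1, any)
    if (any(hit))
      mat[unique(res_f[hit]), f] <- TRUE
  }
  w <- traj$weight
  frac <- as.vector(mat %*% w) / sum(w)
  structure(list(contact = mat, resid = resids,
                 fraction = stats::setNames(frac, resids),
                 weight = w, cutoff = cutoff),
            class = "contact_map")
}

# Cell-list membership test: for each point in `a`, is any point of `b`
# within `cutoff`? Free space only; cells of edge `cutoff`.
#' @keywords internal
cell_contact_hits <- function(a, b, cutoff) {
  origin <- pmin(apply(a, 2, min), apply(b, 2, min))
  key <- function(m) {
    ix <- floor(sweep(m, 2, origin) / cutoff)
    ix
  }
  bi <- key(b)
  bkey <- paste(bi[, 1], bi[, 2], bi[, 3])
  bmap <- split(seq_len(nrow(b)), bkey)
  ai <- key(a)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  vapply(seq_len(nrow(a)), function(i) {
    for (o in seq_len(nrow(offs))) {
      k <- paste(ai[i, 1] + offs[o, 1], ai[i, 2] + offs[o, 2],
                 ai[i, 3] + offs[o, 3])
      cand <- bmap[[k]]
      if (!is.null(cand)) {
        d2 <- colSums((t(b[cand, , drop = FALSE]) - a[i, ])^2)
        if (any(d2 <= cutoff^2)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", nrow(x$contact), " residues x ", ncol(x$contact),
      " frames, cutoff ", x$cutoff, " A; ",
      sum(x$fraction > 0), " residues ever in contact\n", sep = "")
  invisible(x)
}

#' Persistent-contact filter
#'
#' Retains residues whose weighted contact fraction is at least `fraction`
#' of the simulation time.
#'
#' @param map A `contact_map`.
#' @param fraction Persistence threshold in (0, 1] (default 0.75).
#' @return Integer vector of residue indices.
#' @export
persistence_filter <- function(map, fraction = 0.75) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  map$resid[map$fraction >= fraction]
}

#' Proximal/distal classification of contact sites
#'
#' A residue's contact in a frame is proximal iff the polymer atoms in
#' contact with that residue come within `radius` of the catalytic serine's
#' gamma-oxygen in that frame. A residue whose contact frames are at least
#' `majority` proximal (distal) is labelled `"proximal"` (`"distal"`);
#' mixtures are `"both"`; residues never in contact are `"none"`.
#'
#' @param map A `contact_map` (its cutoff is reused to find the contacting
#'   polymer atoms).
#' @param traj,system As in [contact_matrix()].
#' @param radius Proximal radius, Angstrom (default 12).
#' @param majority Aggregation threshold (default 0.9).
#' @return data.frame with columns `resid`, `label`, `prox_fraction`.
#' @export
proximal_distal_split <- function(map, traj, system, radius = 12.0,
                                  majority = 0.9) {
  if (radius <= 0) stop("radius must be > 0")
  og_row <- atom_rows(system, system$catalytic$serine_ogamma)
  if (is.na(og_row)) stop("serine gamma-oxygen annotation absent")
  erows <- enzyme_heavy_rows(system)
  prows <- polymer_heavy_rows(system)
  eres <- system$atoms$resid[erows]
  n_res <- length(map$resid)
  prox_w <- numeric(n_res); tot_w <- numeric(n_res)
  for (f in seq_len(traj$n_frames)) {
    in_contact <- which(map$contact[, f])
    if (!length(in_contact)) next
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    dmat <- dist_pairs(xyz[erows, , drop = FALSE],
                       xyz[prows, , drop = FALSE], box)
    d_og <- dist_pairs(xyz[og_row, , drop = FALSE],
                       xyz[prows, , drop = FALSE], box)[1, ]
    for (r in in_contact) {
      patoms <- which(apply(dmat[eres == map$resid[r], , drop = FALSE] <=
                              map$cutoff, 2, any))
      tot_w[r] <- tot_w[r] + traj$weight[f]
      if (length(patoms) && min(d_og[patoms]) <= radius)
        prox_w[r] <- prox_w[r] + traj$weight[f]
    }
  }
  pf <- ifelse(tot_w > 0, prox_w / tot_w, NA_real_)
  label <- rep("none", n_res)
  seen <- tot_w > 0
  label[seen & pf >= majority] <- "proximal"
  label[seen & pf <= 1 - majority] <- "distal"
  label[seen & pf > 1 - majority & pf < majority] <- "both"
  data.frame(resid = map$resid, label = label, prox_fraction = pf)
}

#' Write a contact summary table
#' @param map A `contact_map`.
#' @param split Optional result of [proximal_distal_split()].
#' @param system The `molecular_system` (residue names).
#' @param path Output TSV.
#' @export
write_contact_table <- function(map, split = NULL, system, path) {
  rn <- system$atoms$resname[match(map$resid, system$atoms$resid)]
  out <- data.frame(residue_index = map$resid, residue_name = rn,
                    contact_fraction = unname(map$fraction),
                    label = if (is.null(split)) NA_character_ else split$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
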
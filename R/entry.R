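# SER-C reaction coordinate, productive-pose detection with si/re face
# labels, and segmentation of trajectories into outside/entry/inside phases.

#' Per-frame entry series
#'
#' For every frame: the distance between the catalytic serine gamma-oxygen
#' and the carbonyl carbon of the nearest polymer ester (SER-C distance), the
#' index of that ester, the distances between the same ester's carbonyl
#' oxygen and the two oxyanion-hole amide hydrogens, a productive flag
#' (all three distances at or below `productive_cutoff`) and a si/re face
#' label.
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` with at least one ester bond.
#' @param config An `analysis_config`.
#' @return A data.frame of class `entry_series`: `frame`, `time`, `ser_c`,
#'   `ester`, `oxy1`, `oxy2`, `productive`, `face`; frame weights in
#'   attribute `"weight"`.
#' @export
entry_series <- function(traj, system, config = analysis_config()) {
  if (!nrow(system$ester_bonds)) stop("system has no ester bonds")
  og <- atom_rows(system, system$catalytic$serine_ogamma)
  don <- atom_rows(system, system$oxyanion_donors)
  c_rows <- atom_rows(system, system$ester_bonds[, "carbon"])
  o_rows <- atom_rows(system, system$ester_bonds[, "carbonyl_oxygen"])
  nf <- traj$n_frames
  ser_c <- oxy1 <- oxy2 <- numeric(nf)
  ester <- integer(nf)
  face <- character(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    dc <- dist_pairs(xyz[og, , drop = FALSE],
                     xyz[c_rows, , drop = FALSE], box)[1, ]
    e <- which.min(dc)
    ester[f] <- e
    ser_c[f] <- dc[e]
    doh <- dist_pairs(xyz[o_rows[e], , drop = FALSE],
                      xyz[don, , drop = FALSE], box)[1, ]
    oxy1[f] <- doh[1]; oxy2[f] <- doh[2]
    face[f] <- face_label(xyz, system, e)
  }
  pc <- config$productive_cutoff
  structure(data.frame(frame = seq_len(nf), time = traj$time,
                       ser_c = ser_c, ester = ester, oxy1 = oxy1,
                       oxy2 = oxy2,
                       productive = ser_c <= pc & oxy1 <= pc & oxy2 <= pc,
                       face = face, stringsAsFactors = FALSE),
            weight = traj$weight,
            class = c("entry_series", "data.frame"))
}

#' si/re face label of the serine approach
#'
#' The unit normal of the ester plane is the cross product of
#' (carbonyl O - C) and (ester O - C), in that order. The label is `"si"`
#' when the serine gamma-oxygen lies on the positive-normal side (projection
#' > delta), `"re"` on the negative side, `"undefined"` within the delta
#' band. The sign-to-label assignment is anchored to the shipped reference
#' geometry `system.file("extdata", "si_reference.pdb")`, in which the
#' serine oxygen sits on the positive side and which is documented as
#' si-face; a mirror reflection of any geometry flips the label.
#'
#' @param xyz Frame coordinates (atoms x 3, system atom order).
#' @param system A `molecular_system`.
#' @param ester Ester-bond index (row of `system$ester_bonds`).
#' @param delta Half-width of the undefined band, Angstrom (default 0.1).
#' @return `"si"`, `"re"` or `"undefined"`.
#' @export
face_label <- function(xyz, system, ester, delta = 0.1) {
  eb <- system$ester_bonds[ester, ]
  cc <- xyz[atom_rows(system, eb["carbon"]), ]
  co <- xyz[atom_rows(system, eb["carbonyl_oxygen"]), ]
  eo <- xyz[atom_rows(system, eb["ester_oxygen"]), ]
  og <- xyz[atom_rows(system, system$catalytic$serine_ogamma), ]
  v1 <- co - cc; v2 <- eo - cc
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {
    warning("degenerate (collinear) ester triplet; face undefined")
    return("undefined")
  }
  proj <- sum(n / nn * (og - cc))
  if (proj > delta) "si" else if (proj < -delta) "re" else "undefined"
}

#' Segment an entry series into outside/entry/inside phases
#'
#' An entry event is a maximal run in which the SER-C distance passes from
#' above the outer boundary to below the inner (productive) boundary. The
#' outside phase is the run of frames above the outer boundary, the entry
#' phase the frames strictly between the last frame above the outer boundary
#' and the first frame below the inner boundary, and the inside phase lasts
#' until the distance next exceeds the outer boundary (or the series ends).
#' One frame below the inner boundary suffices to close an event; an
#' optional median filter (width 5) smooths the distance series first.
#'
#' @param series An `entry_series`.
#' @param config An `analysis_config` (`outer_boundary`, `productive_cutoff`
#'   as outer/inner boundaries).
#' @param smooth Apply a running-median filter of width 5 before
#'   thresholding (default `FALSE`).
#' @return List of `entry_event` objects: integer frame ranges `outside`,
#'   `entry`, `inside`, the `face` at the first productive frame,
#'   `productive` flag and modal `ester` index.
#' @export
segment_entries <- function(series, config = analysis_config(),
                            smooth = FALSE) {
  d <- series$ser_c
  if (smooth && length(d) >= 5) d <- stats::runmed(d, 5)
  outer <- config$outer_boundary
  inner <- config$productive_cutoff
  events <- list()
  n <- length(d)
  i <- 1L
  while (i <= n) {
    # find the next outside run
    while (i <= n && d[i] <= outer) i <- i + 1L
    if (i > n) break
    out_start <- i
    # advance to the first frame below the inner boundary, tracking the
    # last frame above the outer boundary
    last_above <- i
    j <- i
    crossed <- FALSE
    while (j <= n) {
      if (d[j] > outer) last_above <- j
      if (d[j] < inner) { crossed <- TRUE; break }
      j <- j + 1L
    }
    if (!crossed) break
    first_below <- j
    # inside phase: until the distance exceeds the outer boundary again
    k <- first_below
    while (k < n && d[k + 1L] <= outer) k <- k + 1L
    inside <- seq.int(first_below, k)
    prod_frames <- inside[series$productive[inside]]
    events[[length(events) + 1L]] <- structure(list(
      outside = seq.int(out_start, last_above),
      entry = if (first_below - last_above > 1L)
        seq.int(last_above + 1L, first_below - 1L) else integer(0),
      inside = inside,
      productive = length(prod_frames) > 0L,
      face = if (length(prod_frames)) series$face[prod_frames[1L]]
             else NA_character_,
      ester = as.integer(stats::median(series$ester[inside]))
    ), class = "entry_event")
    i <- k + 1L
  }
  events
}

#' @export
print.entry_event <- function(x, ...) {
  cat("<entry_event> outside ", x$outside[1], "-", max(x$outside),
      ", entry ", if (length(x$entry)) paste0(x$entry[1], "-", max(x$entry))
      else "(none)",
      ", inside ", x$inside[1], "-", max(x$inside),
      "; ", if (x$productive) paste0("productive (", x$face, "-face)")
      else "non-productive", "\n", sep = "")
  invisible(x)
}

#' Tally entry events
#'
#' @param events List of `entry_event` (possibly pooled over trajectories).
#' @param series Optional list of the matching `entry_series`, used to
#'   report the weighted fraction of frames in productive states.
#' @return List: `n_events`, `n_productive`, `n_si`, `n_re`,
#'   `productive_frame_fraction` (NA when no series given).
#' @export
tally_entries <- function(events, series = NULL) {
  faces <- vapply(events, function(e)
    if (isTRUE(e$productive)) e$face else NA_character_, character(1))
  frac <- NA_real_
  if (!is.null(series)) {
    if (inherits(series, "entry_series")) series <- list(series)
    w_all <- unlist(lapply(series, attr, "weight"))
    p_all <- unlist(lapply(series, `[[`, "productive"))
    frac <- sum(w_all * p_all) / sum(w_all)
  }
  list(n_events = length(events),
       n_productive = sum(vapply(events, `[[`, logical(1), "productive")),
       n_si = sum(faces == "si", na.rm = TRUE),
       n_re = sum(faces == "re", na.rm = TRUE),
       productive_frame_fraction = frac)
}

#' Serialize entry events to JSON
#' @param events List of `entry_event`.
#' @param path Output JSON file.
#' @export
write_entry_events <- function(events, path) {
  payload <- lapply(events, function(e)
    list(outside = range(e$outside),
         entry = if (length(e$entry)) range(e$entry) else NULL,
         inside = range(e$inside), productive = e$productive,
         face = e$face, ester = e$ester))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
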
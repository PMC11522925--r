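# Entry-pathway decomposition: ester-carbon-to-C-alpha distance features,
# weighted PCA, projection onto the PC plane, per-residue contributions and
# k-means pathway assignment.

#' Ester-C-to-C-alpha distance feature matrix over entry events
#'
#' For every frame of every event's entry and inside phases, the distance
#' from the tracked ester carbon to each enzyme C-alpha. The feature residue
#' set is the union, over those frames, of residues whose C-alpha comes
#' within `radius` of the ester carbon; distances of selected residues that
#' drift out of range are capped at `2 * radius` so every row is complete
#' while out-of-range frames cannot dominate the variance.
#'
#' @param events List of `entry_event` per trajectory: a list parallel to
#'   `trajs`, each element a list of events.
#' @param trajs List of `trajectory` objects.
#' @param system A `molecular_system` (C-alpha atoms are atoms named `"CA"`
#'   in the enzyme segment).
#' @param radius Selection radius, Angstrom (default 10).
#' @return List of class `entry_features`: `matrix` (frames x residues),
#'   `resid` (column residues), `event` (event id per row), `weight`
#'   (frame weight per row), `cap` (the distance cap used).
#' @export
entry_feature_matrix <- function(events, trajs, system, radius = 10.0) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (length(events) && inherits(events[[1]], "entry_event"))
    events <- list(events)
  if (!length(unlist(events, recursive = FALSE)))
    stop("no entry events supplied")
  at <- system$atoms
  ca_rows <- which(at$segment == "enzyme" & at$name == "CA")
  if (!length(ca_rows)) stop("system has no enzyme C-alpha atoms")
  ca_res <- at$resid[ca_rows]
  c_ids <- system$ester_bonds[, "carbon"]
  rows <- list(); ev_id <- integer(0); wts <- numeric(0)
  eid <- 0L
  for (t in seq_along(trajs)) {
    traj <- trajs[[t]]
    for (e in events[[t]]) {
      eid <- eid + 1L
      frames <- c(e$entry, e$inside)
      for (f in frames) {
        xyz <- frame_coords(traj, f)
        box <- if (is.null(traj$box)) NULL else traj$box[f, ]
        cpos <- xyz[atom_rows(system, c_ids[e$ester]), , drop = FALSE]
        d <- dist_pairs(cpos, xyz[ca_rows, , drop = FALSE], box)[1, ]
        rows[[length(rows) + 1L]] <- d
        ev_id <- c(ev_id, eid)
        wts <- c(wts, traj$weight[f])
      }
    }
  }
  dm <- do.call(rbind, rows)
  sel <- which(apply(dm <= radius, 2, any))
  if (!length(sel)) stop("no residues within radius in any entry frame")
  dm <- pmin(dm[, sel, drop = FALSE], 2 * radius)
  colnames(dm) <- ca_res[sel]
  structure(list(matrix = dm, resid = as.integer(ca_res[sel]),
                 event = ev_id,
                 weight = wts, cap = 2 * radius),
            class = "entry_features")
}

#' Weighted principal component analysis of a feature matrix
#'
#' Eigendecomposition of the weighted covariance of the column-centered
#' features. Components are sorted by decreasing eigenvalue; each loading's
#' sign is fixed so that its largest-magnitude entry is positive.
#'
#' @param x Numeric matrix (rows = observations) or an `entry_features`
#'   object (its weights are then the default).
#' @param weights Optional non-negative row weights.
#' @return List of class `pc_model`: `resid` (feature labels), `center`,
#'   `loadings` (features x components), `eigenvalues`,
#'   `explained` (variance fractions), `contribution` (absolute loading,
#'   features x components).
#' @export
pca_fit <- function(x, weights = NULL) {
  if (inherits(x, "entry_features")) {
    if (is.null(weights)) weights <- x$weight
    labs <- x$resid
    x <- x$matrix
  } else {
    labs <- colnames(x)
    if (is.null(labs)) labs <- paste0("f", seq_len(ncol(x)))
  }
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 rows and 2 columns")
  if (anyNA(x)) stop("missing values in feature matrix")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  w <- weights / sum(weights)
  ctr <- colSums(x * w)
  xc <- sweep(x, 2, ctr)
  cov <- crossprod(xc * sqrt(w))
  if (max(abs(cov)) < 1e-12) stop("zero-variance feature matrix")
  eig <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  L <- eig$vectors
  for (k in seq_len(ncol(L))) {
    m <- which.max(abs(L[, k]))
    if (L[m, k] < 0) L[, k] <- -L[, k]
  }
  rownames(L) <- labs
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  structure(list(resid = labs, center = ctr, loadings = L,
                 eigenvalues = ev, explained = ev / sum(ev),
                 contribution = abs(L)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("<pc_model> ", length(x$resid), " features; explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(x$explained))),
                    100 * x$explained[seq_len(min(3, length(x$explained)))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project features onto the PC plane and build the free-energy surface
#'
#' @param model A `pc_model`.
#' @param x Feature matrix or `entry_features` compatible with the model's
#'   residue list.
#' @param weights Optional row weights (taken from `entry_features` when
#'   omitted).
#' @param temperature Temperature for the FES (default 303 K).
#' @param bins Bins per axis (default 50).
#' @return List: `projections` (rows x components), `fes` (a `fes_grid`
#'   over PC1/PC2), plus the row weights used.
#' @export
project_and_fes <- function(model, x, weights = NULL, temperature = 303,
                            bins = 50) {
  if (inherits(x, "entry_features")) {
    if (is.null(weights)) weights <- x$weight
    labs <- x$resid
    x <- x$matrix
  } else labs <- colnames(x)
  if (!is.null(labs) && !identical(as.character(labs),
                                   as.character(model$resid)))
    stop("feature residue list does not match the fitted model")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  proj <- sweep(as.matrix(x), 2, model$center) %*% model$loadings
  grid <- fes2d(proj[, 1], proj[, 2], w = weights, bins = bins,
                temperature = temperature)
  list(projections = proj, fes = grid, weights = weights)
}

#' Per-residue contributions to a principal component
#'
#' Residues ranked by absolute loading on the chosen component; a residue is
#' flagged significant when its absolute loading exceeds the threshold
#' (default `1/sqrt(d)`, the uniform-loading baseline for `d` features).
#'
#' @param model A `pc_model`.
#' @param component Component index (default 1).
#' @param threshold Significance threshold on |loading|.
#' @return data.frame `resid`, `loading`, `contribution`, `significant`,
#'   sorted by decreasing contribution.
#' @export
pc_contributions <- function(model, component = 1, threshold = NULL) {
  if (component < 1 || component > ncol(model$loadings))
    stop("component out of range")
  if (is.null(threshold)) threshold <- 1 / sqrt(nrow(model$loadings))
  l <- model$loadings[, component]
  out <- data.frame(resid = model$resid, loading = unname(l),
                    contribution = unname(abs(l)),
                    significant = unname(abs(l) > threshold))
  out[order(-out$contribution), ]
}

#' Assign entry events to pathways by clustering in the PC plane
#'
#' Events are summarized by the weighted mean of their (PC1, PC2)
#' projections and clustered with k-means (50 restarts, seeded). Cluster
#' labels are renumbered by increasing mean PC1, so pathway 1 sits at the
#' most negative PC1 values.
#'
#' @param projections Rows x components matrix (>= 2 columns).
#' @param event Event id per row.
#' @param weights Optional row weights.
#' @param k Number of pathways (default 3).
#' @param seed RNG seed for k-means restarts.
#' @return data.frame `event`, `pathway`, `pc1`, `pc2` (one row per event).
#' @export
assign_pathways <- function(projections, event, weights = NULL, k = 3,
                            seed = 1) {
  ev <- unique(event)
  if (length(ev) < k)
    stop("fewer events (", length(ev), ") than pathways (", k, ")")
  if (is.null(weights)) weights <- rep(1, nrow(projections))
  means <- t(vapply(ev, function(e) {
    rows <- which(event == e)
    w <- weights[rows] / sum(weights[rows])
    colSums(projections[rows, 1:2, drop = FALSE] * w)
  }, numeric(2)))
  set.seed(seed)
  km <- stats::kmeans(means, centers = k, nstart = 50)
  relabel <- rank(km$centers[, 1], ties.method = "first")
  data.frame(event = ev, pathway = as.integer(relabel[km$cluster]),
             pc1 = means[, 1], pc2 = means[, 2])
}

#' Serialize a `pc_model` to JSON
#' @param model A `pc_model`.
#' @param path Output JSON file.
#' @export
write_pc_model <- function(model, path) {
  jsonlite::write_json(list(residues = model$resid,
                            center = model$center,
                            loadings = model$loadings,
                            explained = model$explained),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
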
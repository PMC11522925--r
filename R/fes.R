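# Weighted 2D free-energy surfaces: replica pooling, Boltzmann inversion of
# a weighted histogram, feature extraction (minima, barrier) and
# parent-variant comparison.

#' Boltzmann constant in kJ/(mol K)
#' @keywords internal
KB_KJ <- 0.0083145

#' Pool replica-resolved samples into one weighted sample set
#'
#' Each frame's pooled weight is its frame weight times its replica weight.
#' The replica-weight scheme is data, not code: supply either `"uniform"`
#' (all replicas weight 1) or a named numeric vector keyed by replica index.
#'
#' @param samples data.frame with columns `x`, `y`, `replica`, and
#'   optionally `weight` (default 1).
#' @param scheme `"uniform"` or a named numeric vector of per-replica
#'   weights covering every replica index present.
#' @return data.frame with columns `x`, `y`, `w`.
#' @export
pool_replicas <- function(samples, scheme = "uniform") {
  if (!all(c("x", "y", "replica") %in% names(samples)))
    stop("samples need columns x, y, replica")
  fw <- if ("weight" %in% names(samples)) samples$weight else
    rep(1, nrow(samples))
  if (identical(scheme, "uniform")) {
    rw <- rep(1, nrow(samples))
  } else {
    idx <- match(as.character(samples$replica), names(scheme))
    if (anyNA(idx))
      stop("missing replica weight for replica(s): ",
           paste(unique(samples$replica[is.na(idx)]), collapse = ", "))
    rw <- unname(scheme[idx])
  }
  data.frame(x = samples$x, y = samples$y, w = fw * rw)
}

#' Two-dimensional free-energy surface from weighted samples
#'
#' The weighted 2D histogram is normalized to total probability 1 and
#' inverted: Delta G(bin) = -kB T ln(P(bin)/P_max), so the most populated
#' bin sits at 0 and every sampled bin is >= 0. Unsampled bins are masked
#' (NA), never padded with pseudo-counts. Free energies are kJ/mol.
#'
#' @param x,y Sample coordinates.
#' @param w Optional non-negative weights (default 1).
#' @param bins Number of bins per axis (default 50) or a length-2 vector.
#' @param temperature Temperature in K (default 303).
#' @param xlim,ylim Optional axis limits; default is the sampled range
#'   expanded by 5%.
#' @return An object of class `fes_grid`: bin edges, `dG` matrix (NA =
#'   unsampled), probability matrix, effective sample count per bin,
#'   temperature.
#' @export
fes2d <- function(x, y, w = NULL, bins = 50, temperature = 303,
                  xlim = NULL, ylim = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("w must match x, y in length")
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("all weights are zero")
  bins <- rep(bins, length.out = 2)
  expand <- function(r) {
    if (diff(r) == 0) r + c(-0.5, 0.5) else r + c(-1, 1) * 0.025 * diff(r)
  }
  if (is.null(xlim)) xlim <- expand(range(x))
  if (is.null(ylim)) ylim <- expand(range(y))
  xe <- seq(xlim[1], xlim[2], length.out = bins[1] + 1)
  ye <- seq(ylim[1], ylim[2], length.out = bins[2] + 1)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = FALSE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = FALSE)
  keep <- ix >= 1 & ix <= bins[1] & iy >= 1 & iy <= bins[2]
  ix <- ix[keep]; iy <- iy[keep]; wk <- w[keep]
  flat <- (iy - 1L) * bins[1] + ix
  wsum <- numeric(bins[1] * bins[2])
  w2sum <- numeric(bins[1] * bins[2])
  agg <- rowsum(cbind(wk, wk^2), flat)
  at <- as.integer(rownames(agg))
  wsum[at] <- agg[, 1]; w2sum[at] <- agg[, 2]
  P <- matrix(wsum / sum(wsum), bins[1], bins[2])
  neff <- matrix(ifelse(w2sum > 0, wsum^2 / w2sum, 0), bins[1], bins[2])
  dG <- matrix(NA_real_, bins[1], bins[2])
  sampled <- P > 0
  dG[sampled] <- -KB_KJ * temperature * log(P[sampled] / max(P))
  structure(list(xedges = xe, yedges = ye, dG = dG, P = P, neff = neff,
                 sampled = sampled, temperature = temperature),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid> ", nrow(x$dG), " x ", ncol(x$dG), " bins, ",
      sum(x$sampled), " sampled, T = ", x$temperature, " K, max dG = ",
      round(max(x$dG, na.rm = TRUE), 2), " kJ/mol\n", sep = "")
  invisible(x)
}

#' Bin-center vectors of a `fes_grid`
#' @param grid A `fes_grid`.
#' @export
fes_centers <- function(grid) {
  list(x = (grid$xedges[-1] + grid$xedges[-length(grid$xedges)]) / 2,
       y = (grid$yedges[-1] + grid$yedges[-length(grid$yedges)]) / 2)
}

#' @keywords internal
local_minima <- function(dG) {
  nr <- nrow(dG); nc <- ncol(dG)
  idx <- which(!is.na(dG), arr.ind = TRUE)
  strict <- matrix(FALSE, nr, nc)
  nonstrict <- matrix(FALSE, nr, nc)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    nb <- dG[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    nb <- nb[!is.na(nb)]
    v <- dG[i, j]
    strict[i, j] <- sum(nb < v) == 0 && sum(nb == v) == 1  # only itself
    nonstrict[i, j] <- all(nb >= v)
  }
  if (any(strict)) return(which(strict, arr.ind = TRUE))
  # degenerate (plateau) case: non-strict minima, lowest linear index wins
  cand <- which(nonstrict)
  if (!length(cand)) return(matrix(integer(0), ncol = 2))
  matrix(c(row(dG)[cand[1]], col(dG)[cand[1]]), ncol = 2)
}

#' @keywords internal
bottleneck_barrier <- function(dG, from, to) {
  # minimax path over 8-connected sampled bins; masked bins impassable
  nr <- nrow(dG); nc <- ncol(dG)
  flat <- function(ij) (ij[2] - 1L) * nr + ij[1]
  best <- rep(Inf, nr * nc)
  done <- rep(FALSE, nr * nc)
  s <- flat(from); t <- flat(to)
  best[s] <- dG[s]
  repeat {
    u <- which(!done & is.finite(best))
    if (!length(u)) return(Inf)
    u <- u[which.min(best[u])]
    if (u == t) return(best[t])
    done[u] <- TRUE
    ui <- (u - 1L) %% nr + 1L; uj <- (u - 1L) %/% nr + 1L
    for (di in -1:1) for (dj in -1:1) {
      vi <- ui + di; vj <- uj + dj
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      v <- (vj - 1L) * nr + vi
      if (done[v] || is.na(dG[v])) next
      cand <- max(best[u], dG[v])
      if (cand < best[v]) best[v] <- cand
    }
  }
}

#' Extract free-energy-surface features
#'
#' Finds local minima (bins lower than all sampled 8-neighbours; on a flat
#' plateau the lowest-linear-index bin is returned with depth 0), splits
#' them at `boundary` along the distance axis into productive and
#' nonproductive, and computes the barrier separating the deepest minima of
#' each kind as the maximum Delta G along the minimum-energy path
#' (bottleneck path over sampled bins; masked bins are impassable).
#'
#' @param grid A `fes_grid` whose distance axis is `axis`.
#' @param boundary Productive-region boundary on the distance axis
#'   (Angstrom; e.g. the 4 A productive cutoff).
#' @param axis Which axis carries the distance coordinate (`"x"` or `"y"`).
#' @return List of class `fes_features`: `minima` data.frame (`ix`, `iy`,
#'   `x`, `y`, `dG`, `productive`), `deepest_productive`,
#'   `deepest_nonproductive` (rows or NULL), `barrier` (kJ/mol; NA when
#'   either side has no minimum, Inf when disconnected).
#' @export
fes_features <- function(grid, boundary, axis = c("x", "y")) {
  axis <- match.arg(axis)
  ctr <- fes_centers(grid)
  mins <- local_minima(grid$dG)
  if (!nrow(mins)) {
    return(structure(list(minima = NULL, deepest_productive = NULL,
                          deepest_nonproductive = NULL, barrier = NA_real_),
                     class = "fes_features"))
  }
  df <- data.frame(ix = mins[, 1], iy = mins[, 2],
                   x = ctr$x[mins[, 1]], y = ctr$y[mins[, 2]],
                   dG = grid$dG[mins])
  dcoord <- if (axis == "x") df$x else df$y
  df$productive <- dcoord < boundary
  prod <- df[df$productive, , drop = FALSE]
  nonp <- df[!df$productive, , drop = FALSE]
  dp <- if (nrow(prod)) prod[which.min(prod$dG), ] else NULL
  dn <- if (nrow(nonp)) nonp[which.min(nonp$dG), ] else NULL
  barrier <- NA_real_
  if (!is.null(dp) && !is.null(dn))
    barrier <- bottleneck_barrier(grid$dG, c(dp$ix, dp$iy), c(dn$ix, dn$iy))
  structure(list(minima = df, deepest_productive = dp,
                 deepest_nonproductive = dn, barrier = barrier),
            class = "fes_features")
}

#' @export
print.fes_features <- function(x, ...) {
  n <- if (is.null(x$minima)) 0 else nrow(x$minima)
  cat("<fes_features> ", n, " local minima",
      if (!is.null(x$deepest_productive))
        paste0("; deepest productive dG = ",
               round(x$deepest_productive$dG, 2), " kJ/mol") else "",
      if (!is.null(x$deepest_nonproductive))
        paste0("; deepest nonproductive dG = ",
               round(x$deepest_nonproductive$dG, 2), " kJ/mol") else "",
      if (is.finite(x$barrier)) paste0("; barrier = ",
                                       round(x$barrier, 2), " kJ/mol")
      else "", "\n", sep = "")
  invisible(x)
}

#' Classify variant-vs-parent free-energy-surface changes
#'
#' Compares the features of two surfaces on identical binning and returns
#' the subset of \{`"stabilized-productive"`, `"reduced-nonproductive"`,
#' `"smoother-path"`\} supported by more than 1 kB T (at the grids'
#' temperature): a deeper productive minimum, a shallower nonproductive
#' minimum, or a lower entry barrier in the variant, respectively. Each
#' label compares its own feature between the two min-referenced surfaces.
#'
#' @param parent,variant `fes_grid` objects with identical bin edges.
#' @param boundary,axis As in [fes_features()].
#' @return Character vector (possibly empty) of classification labels;
#'   feature reports attached as attribute `"features"`.
#' @export
compare_fes <- function(parent, variant, boundary, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (!isTRUE(all.equal(parent$xedges, variant$xedges)) ||
      !isTRUE(all.equal(parent$yedges, variant$yedges)))
    stop("parent and variant grids must share identical binning")
  kT <- KB_KJ * parent$temperature
  fp <- fes_features(parent, boundary, axis)
  fv <- fes_features(variant, boundary, axis)
  out <- character(0)
  if (!is.null(fp$deepest_productive) && !is.null(fv$deepest_productive) &&
      fv$deepest_productive$dG < fp$deepest_productive$dG - kT)
    out <- c(out, "stabilized-productive")
  if (!is.null(fp$deepest_nonproductive) &&
      !is.null(fv$deepest_nonproductive) &&
      fv$deepest_nonproductive$dG > fp$deepest_nonproductive$dG + kT)
    out <- c(out, "reduced-nonproductive")
  if (is.finite(fp$barrier) && is.finite(fv$barrier) &&
      fv$barrier < fp$barrier - kT)
    out <- c(out, "smoother-path")
  attr(out, "features") <- list(parent = fp, variant = fv)
  out
}

#' Write a `fes_grid` as a TSV matrix with header metadata
#' @param grid A `fes_grid`.
#' @param path Output TSV.
#' @export
write_fes_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# edges_x", paste(grid$xedges, collapse = " ")),
               paste("# edges_y", paste(grid$yedges, collapse = " ")),
               paste("# temperature", grid$temperature)), con)
  utils::write.table(grid$dG, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
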
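# Spectral-topographic map construction: electrode projection, thin-plate
# (biharmonic) interpolation onto a 32x32 grid, band/FAA plane stacking and
# K-window sequence assembly.

#' Standard 14-channel electrode layout
#'
#' The wireless 14-channel montage (AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8,
#' FC6, F4, F8, AF4) at standard 10-20 scalp positions on the unit sphere,
#' together with their azimuthal-equidistant planar projection. Left/right
#' homolog pairs mirror exactly across the midline.
#'
#' @return data.frame of class `tg_layout` with columns `label`, `x`, `y`,
#'   `z` (unit-sphere coordinates; +x nose, +y left ear, +z vertex) and
#'   `px`, `py` (projected plane; +px nose, +py left).
#' @export
electrode_layout <- function() {
  # inclination from vertex / azimuth from nose (degrees, left positive)
  tab <- data.frame(
    label = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
              "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"),
    inc = c(74, 90, 62, 73, 90, 90, 90, 90, 90, 90, 73, 62, 90, 74),
    azi = c(22, 54, 39, 69, 90, 126, 162, -162, -126, -90, -69, -39, -54, -22),
    stringsAsFactors = FALSE)
  inc <- tab$inc * pi / 180
  azi <- tab$azi * pi / 180
  out <- data.frame(
    label = tab$label,
    x = sin(inc) * cos(azi),
    y = sin(inc) * sin(azi),
    z = cos(inc),
    stringsAsFactors = FALSE)
  p <- project_layout(as.matrix(out[, c("x", "y", "z")]))
  out$px <- p[, 1]
  out$py <- p[, 2]
  rownames(out) <- out$label
  class(out) <- c("tg_layout", "data.frame")
  out
}

#' Azimuthal equidistant projection of scalp coordinates
#'
#' Maps unit-sphere electrode positions to the plane so that the planar
#' distance from the map centre equals the great-circle arc length from the
#' vertex, with azimuth preserved.
#'
#' @param sphere_coords n x 3 matrix of (x, y, z) positions on or near the
#'   unit sphere (+z is the vertex).
#' @return n x 2 matrix of planar coordinates (radians of arc).
#' @export
project_layout <- function(sphere_coords) {
  m <- as.matrix(sphere_coords)
  stopifnot(ncol(m) == 3)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < .Machine$double.eps)) tg_stop("project_layout: zero-length coordinate")
  m <- m / nrm
  if (any(m[, 3] < -1 + 1e-9)) {
    tg_stop("project_layout: point at the antipode of the vertex; projection is singular there")
  }
  r <- acos(pmin(1, pmax(-1, m[, 3])))
  a <- atan2(m[, 2], m[, 1])
  cbind(px = r * cos(a), py = r * sin(a))
}

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Fit a thin-plate (biharmonic) scalp interpolator
#'
#' Exact thin-plate spline interpolation from the electrode sites onto a
#' square pixel grid: radial kernel `r^2 log r` plus an affine part, so the
#' interpolant reproduces electrode values exactly and affine fields
#' everywhere. Pixels outside the scalp disc (circumscribing the projected
#' electrodes with a 1.1 margin) are masked to zero.
#'
#' @param layout an [electrode_layout()] (or any `tg_layout`).
#' @param grid_n grid resolution per side (default 32).
#' @param margin mask radius as a multiple of the outermost electrode radius.
#' @return object of class `tg_topo_interp`.
#' @export
fit_topo_interpolator <- function(layout, grid_n = 32L, margin = 1.1) {
  pts <- cbind(layout$px, layout$py)
  if (anyDuplicated(round(pts, 12))) {
    tg_stop("fit_topo_interpolator: duplicate electrode positions")
  }
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  K <- tps_kernel(D)
  P <- cbind(1, pts)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Linv <- solve(L)
  R <- margin * max(sqrt(rowSums(pts^2)))
  g <- seq(-R, R, length.out = grid_n)
  grid <- cbind(rep(g, times = grid_n), rep(g, each = grid_n))  # (px, py) pairs
  # basis at grid points: kernel distances to sites + affine part
  GD <- sqrt(outer(grid[, 1], pts[, 1], "-")^2 + outer(grid[, 2], pts[, 2], "-")^2)
  G <- cbind(tps_kernel(GD), 1, grid)
  M <- G %*% Linv[, seq_len(n)]              # grid values = M %*% site values
  mask <- sqrt(rowSums(grid^2)) <= R + 1e-12
  structure(list(labels = layout$label, pts = pts, Linv = Linv, M = M,
                 mask = mask, grid_n = grid_n, grid_axis = g, radius = R),
            class = "tg_topo_interp")
}

#' Interpolate electrode values to a scalp map
#'
#' @param values numeric vector, one value per electrode; if named, names are
#'   matched against the layout labels.
#' @param interp a fitted [fit_topo_interpolator()].
#' @return `grid_n` x `grid_n` matrix; out-of-scalp pixels are 0.
#' @export
interpolate_topomap <- function(values, interp) {
  stopifnot(inherits(interp, "tg_topo_interp"))
  if (!is.null(names(values))) values <- values[interp$labels]
  if (length(values) != nrow(interp$pts) || any(!is.finite(values))) {
    tg_stop("interpolate_topomap: need one finite value per electrode")
  }
  v <- as.vector(interp$M %*% values)
  v[!interp$mask] <- 0
  matrix(v, interp$grid_n, interp$grid_n)
}

#' Evaluate a fitted scalp interpolant at arbitrary points
#'
#' @param interp a fitted [fit_topo_interpolator()].
#' @param values electrode values (as in [interpolate_topomap()]).
#' @param points m x 2 matrix of planar coordinates.
#' @return numeric vector of interpolant values.
#' @export
eval_topo_interpolator <- function(interp, values, points) {
  if (!is.null(names(values))) values <- values[interp$labels]
  n <- nrow(interp$pts)
  coefs <- interp$Linv[, seq_len(n)] %*% values
  pd <- sqrt(outer(points[, 1], interp$pts[, 1], "-")^2 +
             outer(points[, 2], interp$pts[, 2], "-")^2)
  as.vector(cbind(tps_kernel(pd), 1, points) %*% coefs)
}

#' Build one spectral-topographic map stack from an EEG window
#'
#' Interpolates per-channel log10 band power (theta, alpha, beta) to three
#' 32x32 planes and appends the frontal-alpha-asymmetry value as a constant
#' fourth plane, giving the 32 x 32 x 4 stack consumed by the decoder.
#'
#' @param window a preprocessed [raw_window()].
#' @param interp a fitted [fit_topo_interpolator()].
#' @return array 32 x 32 x 4 of class `tg_map_stack` (bands
#'   `theta`, `alpha`, `beta`, `faa`), attribute `start_time_s`.
#' @export
build_map_stack <- function(window, interp) {
  bp <- band_power_welch(window)
  faa <- compute_faa(bp)
  planes <- vapply(colnames(bp), function(b) {
    v <- log10(pmax(bp[, b], .Machine$double.xmin))
    names(v) <- rownames(bp)
    interpolate_topomap(v, interp)
  }, matrix(0, interp$grid_n, interp$grid_n))
  out <- array(0, dim = c(interp$grid_n, interp$grid_n, 4),
               dimnames = list(NULL, NULL, c("theta", "alpha", "beta", "faa")))
  out[, , 1:3] <- planes
  out[, , 4] <- faa
  structure(out, start_time_s = window$start_time_s,
            class = c("tg_map_stack", "array"))
}

#' Assemble K-window map sequences
#'
#' Emits sliding sequences of `K` consecutive stacks (stride one stack, no
#' padding: the first sequence appears only once `K` stacks exist). With 1 s
#' windows and 100 ms stride the sequence spans 1.9 s.
#'
#' @param stacks list of `tg_map_stack` objects on a contiguous 100 ms grid.
#' @param K sequence length in stacks (default 10).
#' @param stride_s expected stack spacing in seconds.
#' @return list of arrays `grid x grid x 4 x K` (class `tg_map_seq`), each
#'   with attribute `start_time_s`; empty list if fewer than `K` stacks.
#' @export
build_sequence <- function(stacks, K = 10L, stride_s = 0.1) {
  if (length(stacks) < K) return(list())
  t0 <- vapply(stacks, attr, 0, "start_time_s")
  if (any(abs(diff(t0) - stride_s) > 1e-6)) {
    tg_stop("build_sequence: gap in the stack timeline; stacks must be contiguous")
  }
  d <- dim(stacks[[1]])
  lapply(seq_len(length(stacks) - K + 1L), function(i) {
    a <- array(0, dim = c(d, K))
    for (k in seq_len(K)) a[, , , k] <- stacks[[i + k - 1L]]
    structure(a, start_time_s = t0[i], class = c("tg_map_seq", "array"))
  })
}

# Fast path: maps for every window of a session from vectorized band powers.
# bp: result of session_band_powers(..., normalize = TRUE). Returns a
# grid x grid x 4 x nwin array (bands theta/alpha/beta/faa).
session_map_array <- function(bp, interp) {
  nwin <- length(bp$starts_s)
  gn <- interp$grid_n
  out <- array(0, dim = c(gn, gn, 4, nwin),
               dimnames = list(NULL, NULL, c("theta", "alpha", "beta", "faa"), NULL))
  ord <- match(interp$labels, colnames(bp$theta))
  for (b in 1:3) {
    pw <- bp[[c("theta", "alpha", "beta")[b]]][, ord, drop = FALSE]
    lg <- t(log10(pmax(pw, .Machine$double.xmin)))   # electrodes x nwin
    planes <- interp$M %*% lg                        # pixels x nwin
    planes[!interp$mask, ] <- 0
    out[, , b, ] <- planes
  }
  out[, , 4, ] <- rep(bp$faa, each = gn * gn)
  attr(out, "starts_s") <- bp$starts_s
  out
}
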
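#' Lumen contour polygon
#'
#' @param x_mm,y_mm Ordered planar vertex coordinates in mm (closed polygon;
#'   do not repeat the first vertex).
#' @param slice_id,phase_id Identifiers.
#' @param check_simple Verify the polygon does not self-intersect (O(n^2);
#'   disable for large trusted contours).
#' @return An object of class `lumen_contour` with a `poly` vertex matrix.
#' @export
lumen_contour <- function(x_mm, y_mm, slice_id = 1L, phase_id = 1L,
                          check_simple = TRUE) {
  if (length(x_mm) != length(y_mm) || length(x_mm) < 3L)
    pwv_abort("degenerate_geometry_error", "contour needs >= 3 points")
  poly <- cbind(x = as.numeric(x_mm), y = as.numeric(y_mm))
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L)
    pwv_abort("degenerate_geometry_error", "contour needs >= 3 distinct points")
  if (abs(.shoelace_area(poly)) <= 0)
    pwv_abort("degenerate_geometry_error", "contour has zero area")
  if (check_simple && .self_intersects(poly))
    pwv_abort("degenerate_geometry_error", "self-intersecting contour polygon")
  structure(list(slice_id = slice_id, phase_id = phase_id, poly = poly),
            class = "lumen_contour")
}

# signed shoelace area of an open vertex matrix
.shoelace_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[i %% n + 1L, ])
  for (i in seq_len(n - 2L)) {
    a <- poly[i, ]; b <- poly[i %% n + 1L, ]
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      c_ <- poly[j, ]; d <- poly[j %% n + 1L, ]
      if (.segments_cross(a, b, c_, d)) return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(a, b, c_, d) {
  o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) -
                              (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- o(a, b, c_); o2 <- o(a, b, d); o3 <- o(c_, d, a); o4 <- o(c_, d, b)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

# Euclidean distance from points to the polygon boundary (vectorized over
# points, looped over edges)
.dist_to_boundary <- function(px, py, poly) {
  m <- nrow(poly)
  d2 <- rep(Inf, length(px))
  for (k in seq_len(m)) {
    a <- poly[k, ]
    b <- poly[k %% m + 1L, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    l2 <- abx * abx + aby * aby
    if (l2 == 0) next
    tt <- pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / l2))
    dx <- px - (a[1] + tt * abx)
    dy <- py - (a[2] + tt * aby)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# moving average with reflective end padding (keeps the endpoints of a
# locally straight path in place)
.moving_average <- function(v, window) {
  if (window <= 1L || length(v) <= window) return(v)
  h <- window %/% 2L
  n <- length(v)
  vp <- c(2 * v[1L] - v[(h + 1L):2L], v, 2 * v[n] - v[(n - 1L):(n - h)])
  as.numeric(stats::filter(vp, rep(1 / window, window), sides = 2))[
    (h + 1L):(h + n)]
}

#' Aortic centerline
#'
#' Ordered centerline points with cumulative arc length and unit tangents,
#' oriented from the ascending towards the descending aorta.
#'
#' @param points n x 2 matrix of planar points, mm.
#' @return An object of class `centerline` with fields `points` (mm),
#'   `arc_length_m` (metres, strictly increasing) and `tangents` (unit rows).
#' @export
centerline <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 2L)
  d <- sqrt(rowSums(diff(points)^2))
  if (any(d <= 0))
    pwv_abort("degenerate_geometry_error", "repeated centerline points")
  arc_mm <- c(0, cumsum(d))
  n <- nrow(points)
  # tangents from central secants over a +/-3-point stencil (clamped at the
  # ends): wider than one step so isolated path kinks do not tilt the chords
  k <- min(3L, n - 1L)
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  tang <- points[hi, , drop = FALSE] - points[lo, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, arc_length_m = arc_mm / 1000,
                 tangents = tang),
            class = "centerline")
}

#' Extract the centerline of an elongated lumen contour
#'
#' Medial-path extraction: the polygon interior is rasterized on a square
#' grid (default 0.5 mm), each interior pixel is weighted by its Euclidean
#' distance to the lumen boundary, and the minimum-cost 8-connected path
#' between the pixels nearest the two endpoint hints is found with edge cost
#' step_length / mean(boundary distance)^2 — the path therefore follows the
#' distance-transform medial ridge. The path is smoothed with a moving
#' average and resampled to uniform arc spacing.
#'
#' @param contour A `lumen_contour` describing the full vessel band.
#' @param hint_start,hint_end Planar points (mm) near the intended start
#'   (ascending) and end (descending) of the band.
#' @param pixel_mm Rasterization step, mm.
#' @param smooth_window Moving-average window (samples).
#' @param spacing_mm Target arc spacing of the resampled centerline, mm.
#' @return A `centerline`.
#' @export
centerline_from_contour <- function(contour, hint_start, hint_end,
                                    pixel_mm = 0.5, smooth_window = 9L,
                                    spacing_mm = pixel_mm) {
  stopifnot(inherits(contour, "lumen_contour"))
  poly <- contour$poly
  gx <- seq(floor(min(poly[, 1]) / pixel_mm) * pixel_mm,
            ceiling(max(poly[, 1]) / pixel_mm) * pixel_mm, by = pixel_mm)
  gy <- seq(floor(min(poly[, 2]) / pixel_mm) * pixel_mm,
            ceiling(max(poly[, 2]) / pixel_mm) * pixel_mm, by = pixel_mm)
  nc <- length(gx); nr <- length(gy)
  px <- rep(gx, times = nr)
  py <- rep(gy, each = nc)
  inside <- pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = TRUE)
  if (sum(inside) < 2L)
    pwv_abort("degenerate_geometry_error", "contour interior rasterizes to < 2 pixels")
  dist <- rep(NA_real_, length(px))
  dist[inside] <- .dist_to_boundary(px[inside], py[inside], poly)

  # 8-connected grid graph over interior pixels; cost penalizes boundary
  # proximity so the cheapest path rides the medial ridge
  id <- matrix(0L, nrow = nr, ncol = nc)           # row = y, col = x
  ins <- matrix(inside, nrow = nr, ncol = nc, byrow = TRUE)
  id[ins] <- seq_len(sum(ins))
  dmat <- matrix(dist, nrow = nr, ncol = nc, byrow = TRUE)
  eps <- pixel_mm / 2
  edges <- list(); wts <- list(); k <- 0L
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1L]; dc <- off[2L]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else seq(1L - dc, nc)
    a <- ins[r1, c1, drop = FALSE] & ins[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(a)) next
    ia <- id[r1, c1, drop = FALSE][a]
    ib <- id[r1 + dr, c1 + dc, drop = FALSE][a]
    davg <- (dmat[r1, c1, drop = FALSE][a] +
             dmat[r1 + dr, c1 + dc, drop = FALSE][a]) / 2
    steplen <- pixel_mm * sqrt(sum(off^2))
    k <- k + 1L
    edges[[k]] <- rbind(ia, ib)
    wts[[k]] <- steplen / (davg + eps)^2
  }
  if (k == 0L)
    pwv_abort("degenerate_geometry_error", "zero-width region: no connected interior")
  g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                          n = sum(ins), directed = FALSE)
  igraph::E(g)$weight <- unlist(wts)

  nearest_node <- function(hint) {
    dx <- px[inside] - hint[1]
    dy <- py[inside] - hint[2]
    which.min(dx * dx + dy * dy)
  }
  # map from "inside vector order" (x fastest) to node ids in `id`
  # (id was filled column-major over the (row = y, col = x) matrix)
  rows <- rep(seq_len(nr), each = nc)[inside]
  cols <- rep(seq_len(nc), times = nr)[inside]
  node_of <- id[cbind(rows, cols)]
  from <- node_of[nearest_node(hint_start)]
  to <- node_of[nearest_node(hint_end)]
  sp <- suppressWarnings(igraph::shortest_paths(g, from = from, to = to,
                                                mode = "all"))
  path <- as.integer(sp$vpath[[1L]])
  if (length(path) < 2L)
    pwv_abort("degenerate_geometry_error", "endpoint hints are not connected inside the lumen")
  # node -> coordinates
  inv <- integer(sum(ins))
  inv[node_of] <- seq_along(node_of)
  xs <- px[inside][inv[path]]
  ys <- py[inside][inv[path]]
  xs <- .moving_average(xs, smooth_window)
  ys <- .moving_average(ys, smooth_window)
  keep <- c(TRUE, diff(xs)^2 + diff(ys)^2 > 0)
  xs <- xs[keep]; ys <- ys[keep]
  # uniform arc resampling
  seglen <- sqrt(diff(xs)^2 + diff(ys)^2)
  arc <- c(0, cumsum(seglen))
  L <- arc[length(arc)]
  n_out <- max(2L, ceiling(L / spacing_mm) + 1L)
  s_out <- seq(0, L, length.out = n_out)
  pts <- cbind(stats::approx(arc, xs, xout = s_out)$y,
               stats::approx(arc, ys, xout = s_out)$y)
  centerline(pts)
}

#' Perpendicular sampling chord
#'
#' @param s_m Arc position, metres.
#' @param endpoints 2 x 2 matrix, the two chord endpoints on the lumen
#'   boundary, mm.
#' @param direction Unit centerline tangent at `s_m` (flow direction).
#' @param center Centerline point the chord passes through, mm.
#' @return An object of class `chord`.
#' @export
chord <- function(s_m, endpoints, direction, center) {
  structure(list(s_m = s_m, endpoints = endpoints, direction = direction,
                 center = center,
                 length_mm = sqrt(sum((endpoints[2L, ] - endpoints[1L, ])^2))),
            class = "chord")
}

# interpolate centerline point and (renormalized) tangent at arc s (metres)
.centerline_at <- function(cl, s_m) {
  s <- cl$arc_length_m
  x <- stats::approx(s, cl$points[, 1L], xout = s_m, rule = 2)$y
  y <- stats::approx(s, cl$points[, 2L], xout = s_m, rule = 2)$y
  tx <- stats::approx(s, cl$tangents[, 1L], xout = s_m, rule = 2)$y
  ty <- stats::approx(s, cl$tangents[, 2L], xout = s_m, rule = 2)$y
  nrm <- sqrt(tx^2 + ty^2)
  list(point = c(x, y), tangent = c(tx, ty) / nrm)
}

#' Sample equidistant perpendicular chords along a centerline
#'
#' Places `n` chords at equal arc fractions k/(n-1), k = 0..n-1 (both
#' endpoints included; `n = 1` degenerates to s = 0). Each chord is the
#' maximal segment through its centerline point, perpendicular to the local
#' tangent, clipped to the lumen polygon.
#'
#' @param cl A `centerline` lying inside `contour`.
#' @param contour A `lumen_contour`.
#' @param n Number of chords (default 200).
#' @return List of `chord`, ordered by arc position.
#' @export
sample_chords <- function(cl, contour, n = 200L) {
  stopifnot(inherits(cl, "centerline"), inherits(contour, "lumen_contour"))
  L <- max(cl$arc_length_m)
  fr <- if (n == 1L) 0 else (seq_len(n) - 1L) / (n - 1L)
  poly <- contour$poly
  m <- nrow(poly)
  ax <- poly[, 1L]; ay <- poly[, 2L]
  bx <- poly[c(2:m, 1L), 1L]; by <- poly[c(2:m, 1L), 2L]
  ex <- bx - ax; ey <- by - ay
  lapply(fr, function(f) {
    at <- .centerline_at(cl, f * L)
    p <- at$point
    u <- c(-at$tangent[2L], at$tangent[1L])   # chord direction (normal)
    # line p + t*u vs edge a + w*e: solve [u, -e] [t, w]' = a - p
    den <- u[1L] * (-ey) - u[2L] * (-ex)
    rx <- ax - p[1L]; ry <- ay - p[2L]
    ok <- abs(den) > 1e-12
    tt <- (rx * (-ey) - ry * (-ex)) / den
    ww <- (u[1L] * ry - u[2L] * rx) / den
    hit <- ok & ww >= -1e-9 & ww <= 1 + 1e-9
    tv <- sort(unique(signif(tt[hit], 10)))
    tpos <- tv[tv > 1e-9]
    tneg <- tv[tv < -1e-9]
    if (length(tpos) == 0L || length(tneg) == 0L)
      pwv_abort("degenerate_geometry_error",
                "chord does not intersect the lumen boundary on both sides")
    e1 <- p + max(tneg) * u
    e2 <- p + min(tpos) * u
    chord(f * L, rbind(e1, e2), at$tangent, p)
  })
}

#' Project AP/FH velocity components onto a direction
#'
#' Signed scalar product of the in-plane velocity vector with a unit
#' direction, by convention positive for flow from the ascending towards the
#' descending aorta. `direction` is ordered (AP, FH) to match the component
#' arguments.
#'
#' @param v_ap,v_fh Velocity components, m/s (vectors of equal length).
#' @param direction Length-2 unit vector `(d_ap, d_fh)`.
#' @param tol Allowed deviation of `|direction|` from 1.
#' @return Signed projected velocity, m/s.
#' @export
project_velocity <- function(v_ap, v_fh, direction, tol = 1e-6) {
  if (length(direction) != 2L || abs(sqrt(sum(direction^2)) - 1) > tol)
    pwv_abort("geometry_error", "direction must be a unit 2-vector")
  v_ap * direction[1L] + v_fh * direction[2L]
}

#' Velocity-encoded map series
#'
#' Per-phase 2-D velocity grids for one encoding direction. Pixel (i, j)
#' sits at planar mm position x = (j-1)*pixel_spacing_mm[2] (FH axis, along
#' columns), y = (i-1)*pixel_spacing_mm[1] (AP axis, along rows), origin at
#' the top-left pixel center.
#'
#' @param frames List of numeric matrices (m/s), one per cardiac phase, all
#'   the same shape.
#' @param component `"AP"`, `"FH"` or `"through_plane"`.
#' @param pixel_spacing_mm Length-2 `(row, col)` spacing, mm.
#' @param phase_times_s Strictly increasing per-frame times within one R-R.
#' @param venc_m_per_s Velocity-encoding limit; all |values| must be <= venc.
#' @param rr_s Cardiac cycle duration (default: phase grid span).
#' @return An object of class `velocity_map_series`.
#' @export
velocity_map_series <- function(frames, component = c("AP", "FH", "through_plane"),
                                pixel_spacing_mm, phase_times_s,
                                venc_m_per_s = 1.5, rr_s = NULL) {
  component <- match.arg(component)
  stopifnot(is.list(frames), length(frames) >= 1L)
  dm <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), dm), logical(1))))
    pwv_abort("config_error", "all frames must share one shape")
  if (length(phase_times_s) != length(frames) ||
      any(diff(phase_times_s) <= 0))
    pwv_abort("config_error", "phase_times_s must match frames and increase strictly")
  vmax <- max(vapply(frames, function(f) max(abs(f)), numeric(1)))
  if (vmax > venc_m_per_s + 1e-12)
    pwv_abort("config_error", "velocities exceed the encoding limit (venc)")
  if (is.null(rr_s)) {
    dt <- mean(diff(phase_times_s))
    rr_s <- length(frames) * dt
  }
  structure(list(frames = frames, component = component,
                 pixel_spacing_mm = pixel_spacing_mm,
                 phase_times_s = phase_times_s,
                 venc_m_per_s = venc_m_per_s, rr_s = rr_s),
            class = "velocity_map_series")
}

# bilinear sampling weights at planar mm points for a (nr x nc) grid
.bilinear_weights <- function(xp, yp, spacing, nr, nc) {
  cj <- xp / spacing[2L] + 1
  ri <- yp / spacing[1L] + 1
  if (any(cj < 1 - 1e-9 | cj > nc + 1e-9 | ri < 1 - 1e-9 | ri > nr + 1e-9))
    pwv_abort("geometry_error", "sample point outside the image extent")
  j0 <- pmin(pmax(floor(cj), 1L), nc - 1L)
  i0 <- pmin(pmax(floor(ri), 1L), nr - 1L)
  fx <- pmin(pmax(cj - j0, 0), 1)
  fy <- pmin(pmax(ri - i0, 0), 1)
  idx <- cbind(i0 + (j0 - 1L) * nr,            # (i0, j0) linear indices
               i0 + 1L + (j0 - 1L) * nr,
               i0 + j0 * nr,
               i0 + 1L + j0 * nr)
  w <- cbind((1 - fx) * (1 - fy), (1 - fx) * fy, fx * (1 - fy), fx * fy)
  list(idx = idx, w = w)
}

.sample_frame <- function(frame, bw) {
  rowSums(matrix(frame[bw$idx], ncol = 4L) * bw$w)
}

#' Per-chord maximal projected velocity-time curves
#'
#' For each chord and cardiac phase, both in-plane components are sampled by
#' bilinear interpolation at points spaced `step_mm` along the chord,
#' projected onto the chord's centerline direction, and the maximum of the
#' signed projected velocity over the chord is taken. This yields one
#' velocity-time curve per chord.
#'
#' @param maps_ap,maps_fh Congruent `velocity_map_series` (AP and FH).
#' @param chords List of `chord` (see [sample_chords()]).
#' @param step_mm Sampling step along each chord, mm.
#' @return List of velocity `sampled_waveform`, one per chord, with the
#'   chord arc positions (m) attached as attribute `"arc_positions_m"`.
#' @export
chord_velocity_curves <- function(maps_ap, maps_fh, chords, step_mm = 0.5) {
  stopifnot(inherits(maps_ap, "velocity_map_series"),
            inherits(maps_fh, "velocity_map_series"))
  if (maps_ap$component != "AP" || maps_fh$component != "FH")
    pwv_abort("config_error", "pass the AP series first and the FH series second")
  if (!identical(dim(maps_ap$frames[[1L]]), dim(maps_fh$frames[[1L]])) ||
      length(maps_ap$frames) != length(maps_fh$frames) ||
      max(abs(maps_ap$phase_times_s - maps_fh$phase_times_s)) > 1e-9)
    pwv_abort("config_error", "AP and FH series are not congruent")
  dm <- dim(maps_ap$frames[[1L]])
  nr <- dm[1L]; nc <- dm[2L]
  tps <- maps_ap$phase_times_s
  nph <- length(tps)
  dt <- mean(diff(tps))
  curves <- lapply(chords, function(ch) {
    len <- ch$length_mm
    npt <- max(2L, ceiling(len / step_mm) + 1L)
    fr <- seq(0, 1, length.out = npt)
    xp <- ch$endpoints[1L, 1L] + fr * (ch$endpoints[2L, 1L] - ch$endpoints[1L, 1L])
    yp <- ch$endpoints[1L, 2L] + fr * (ch$endpoints[2L, 2L] - ch$endpoints[1L, 2L])
    bw <- .bilinear_weights(xp, yp, maps_ap$pixel_spacing_mm, nr, nc)
    # planar tangent (x, y) = (FH, AP) components of the flow direction
    tx <- ch$direction[1L]; ty <- ch$direction[2L]
    vals <- vapply(seq_len(nph), function(p) {
      vfh <- .sample_frame(maps_fh$frames[[p]], bw)
      vap <- .sample_frame(maps_ap$frames[[p]], bw)
      max(vfh * tx + vap * ty)
    }, numeric(1))
    sampled_waveform(vals, sample_interval_s = dt, start_time_s = tps[1L],
                     kind = "velocity", rr_s = maps_ap$rr_s)
  })
  attr(curves, "arc_positions_m") <- vapply(chords, function(ch) ch$s_m,
                                            numeric(1))
  curves
}

#' Maximal velocity-time curve over a region of interest
#'
#' Per cardiac phase, the maximum through-plane velocity over the pixels
#' whose centers fall inside the contour.
#'
#' @param maps A through-plane `velocity_map_series`.
#' @param contour A `lumen_contour` (applied to all phases) or a list with
#'   one contour per phase.
#' @return A velocity `sampled_waveform`.
#' @export
roi_max_velocity_curve <- function(maps, contour) {
  stopifnot(inherits(maps, "velocity_map_series"))
  nph <- length(maps$frames)
  contours <- if (inherits(contour, "lumen_contour"))
    rep(list(contour), nph) else contour
  if (length(contours) != nph)
    pwv_abort("config_error", "need one contour per phase (or a single contour)")
  dm <- dim(maps$frames[[1L]])
  xg <- (seq_len(dm[2L]) - 1L) * maps$pixel_spacing_mm[2L]
  yg <- (seq_len(dm[1L]) - 1L) * maps$pixel_spacing_mm[1L]
  px <- rep(xg, each = dm[1L])
  py <- rep(yg, times = dm[2L])
  vals <- vapply(seq_len(nph), function(p) {
    poly <- contours[[p]]$poly
    mask <- pracma::inpolygon(px, py, poly[, 1L], poly[, 2L], boundary = TRUE)
    if (!any(mask)) pwv_abort("geometry_error", "empty contour mask")
    max(maps$frames[[p]][mask])
  }, numeric(1))
  dt <- mean(diff(maps$phase_times_s))
  sampled_waveform(vals, sample_interval_s = dt,
                   start_time_s = maps$phase_times_s[1L],
                   kind = "velocity", rr_s = maps$rr_s)
}

#' Cross-sectional lumen area series over the cardiac cycle
#'
#' Shoelace polygon area per phase, with the distension summary used by the
#' distensibility model: `delta_A = max - min` and `A_min = min`.
#'
#' @param contours List of `lumen_contour`, one per phase (>= 2).
#' @param phase_times_s Per-phase times, seconds.
#' @param rr_s Cycle duration (default: phase grid span).
#' @return List with `waveform` (area `sampled_waveform`, mm^2),
#'   `delta_A_mm2` and `A_min_mm2`.
#' @export
lumen_area_series <- function(contours, phase_times_s, rr_s = NULL) {
  stopifnot(is.list(contours))
  if (length(contours) < 2L)
    pwv_abort("config_error", "need >= 2 phases for an area series")
  areas <- vapply(contours, function(ct) {
    stopifnot(inherits(ct, "lumen_contour"))
    abs(.shoelace_area(ct$poly))
  }, numeric(1))
  dt <- mean(diff(phase_times_s))
  if (is.null(rr_s)) rr_s <- length(areas) * dt
  wf <- sampled_waveform(areas, sample_interval_s = dt,
                         start_time_s = phase_times_s[1L],
                         kind = "area", rr_s = rr_s)
  list(waveform = wf, delta_A_mm2 = max(areas) - min(areas),
       A_min_mm2 = min(areas))
}
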
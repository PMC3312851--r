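test_that("contour validation catches degenerate polygons", {
  expect_error(lumen_contour(c(0, 1), c(0, 1)),
               class = "aortapwv_degenerate_geometry_error")
  expect_error(lumen_contour(c(0, 1, 2), c(0, 0, 0)),
               class = "aortapwv_degenerate_geometry_error")
  expect_error(lumen_contour(c(0, 1, 1, 0), c(0, 1, 0, 1)),   # bow-tie
               class = "aortapwv_degenerate_geometry_error")
  ok <- lumen_contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_s3_class(ok, "lumen_contour")
})

test_that("rectangle band centerline is its midline", {
  cl <- centerline_from_contour(rect_contour(), c(0, 10), c(100, 10))
  # every centerline point on the midline, spanning the full band
  expect_lt(max(abs(cl$points[, 2] - 10)), 0.5)
  expect_lt(abs(max(cl$arc_length_m) * 1000 - 100), 0.5)
  expect_true(all(diff(cl$arc_length_m) > 0))
  expect_equal(rowSums(cl$tangents^2), rep(1, nrow(cl$points)),
               tolerance = 1e-9)
  # Hausdorff distance to the analytic midline segment
  mid_x <- seq(0, 100, by = 0.25)
  d1 <- max(apply(cl$points, 1, function(p)
    min(sqrt((mid_x - p[1])^2 + (10 - p[2])^2))))
  d2 <- max(sapply(mid_x, function(x)
    min(sqrt((cl$points[, 1] - x)^2 + (cl$points[, 2] - 10)^2))))
  expect_lt(max(d1, d2), 0.5)
})

test_that("half-ring centerline follows the medial arc", {
  cl <- centerline_from_contour(ring_contour(), c(10, 60), c(90, 60))
  r <- sqrt((cl$points[, 1] - 50)^2 + (cl$points[, 2] - 60)^2)
  expect_lt(max(abs(r - 40)), 1)
})

test_that("degenerate centerline inputs are rejected", {
  expect_error(centerline(matrix(c(0, 0, 0, 0), 2, 2)),
               class = "aortapwv_degenerate_geometry_error")
  # a region too small for the raster grid cannot carry a path
  expect_error(
    centerline_from_contour(rect_contour(1, 1), c(0, 0.5), c(1, 0.5),
                            pixel_mm = 5),
    class = "aortapwv_degenerate_geometry_error")
})

test_that("rectangle chords sit at equal arc fractions with full width", {
  ct <- rect_contour()
  cl <- centerline_from_contour(ct, c(0, 10), c(100, 10))
  ch <- sample_chords(cl, ct, 5L)
  expect_length(ch, 5L)
  s <- vapply(ch, function(c) c$s_m, numeric(1))
  L <- max(cl$arc_length_m)
  expect_equal(s / L, c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-9)
  expect_equal(vapply(ch, function(c) c$length_mm, numeric(1)),
               rep(20, 5), tolerance = 0.1)
  # chords are perpendicular to the local tangent
  for (c_ in ch) {
    u <- (c_$endpoints[2, ] - c_$endpoints[1, ]) / c_$length_mm
    expect_lt(abs(sum(u * c_$direction)), 1e-6)
  }
  # n = 1 degenerates to s = 0
  one <- sample_chords(cl, ct, 1L)
  expect_equal(one[[1]]$s_m, 0)
})

test_that("half-ring chords have the constant annulus width", {
  ct <- ring_contour()
  cl <- centerline_from_contour(ct, c(10, 60), c(90, 60))
  len <- vapply(sample_chords(cl, ct, 50L), function(c) c$length_mm,
                numeric(1))
  expect_lt(max(abs(len - 20)), 0.5)
})

test_that("chord arc spacing is uniform", {
  ct <- ring_contour()
  cl <- centerline_from_contour(ct, c(10, 60), c(90, 60))
  s <- vapply(sample_chords(cl, ct, 40L), function(c) c$s_m, numeric(1))
  L <- max(cl$arc_length_m)
  expect_lt(max(abs(diff(s) - L / 39)), 0.01 * L / 39)
})

test_that("velocity projection is the signed scalar product", {
  expect_equal(project_velocity(0, 1, c(0, 1)), 1.0)
  expect_equal(project_velocity(1, 0, c(0, 1)), 0.0)
  expect_equal(project_velocity(0.6, 0.8, c(0.6, 0.8)), 1.0)
  expect_error(project_velocity(1, 1, c(1, 1)),
               class = "aortapwv_geometry_error")
  # linearity
  set.seed(4)
  d <- c(0.6, 0.8)
  for (a in c(-2, 0.5, 3)) {
    v <- rnorm(2)
    expect_equal(project_velocity(a * v[1], a * v[2], d),
                 a * project_velocity(v[1], v[2], d), tolerance = 1e-12)
  }
})

test_that("in-package bilinear sampling matches pracma::interp2", {
  set.seed(8)
  Z <- matrix(rnorm(30 * 25), 30, 25)
  xp <- runif(50, 0, 24)   # mm at 1 mm spacing
  yp <- runif(50, 0, 29)
  bw <- aortapwv:::.bilinear_weights(xp, yp, c(1, 1), 30L, 25L)
  got <- aortapwv:::.sample_frame(Z, bw)
  ref <- pracma::interp2(x = 0:24, y = 0:29, Z = Z, xp = xp, yp = yp)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("uniform tangent-aligned flow gives constant unit chord curves", {
  ct <- rect_contour(30, 10)
  cl <- centerline_from_contour(ct, c(0, 5), c(30, 5))
  ch <- sample_chords(cl, ct, 7L)
  # tangent is +x: FH carries the flow, AP is zero
  maps <- uniform_field_maps(v_ap = 0, v_fh = 1, nr = 15, nc = 35)
  curves <- chord_velocity_curves(maps$ap, maps$fh, ch)
  for (cv in curves) expect_equal(cv$values, rep(1, 5), tolerance = 1e-9)
  expect_equal(attr(curves, "arc_positions_m"),
               vapply(ch, function(c) c$s_m, numeric(1)))
})

test_that("chord maxima recover the centerline peak of a parabolic profile", {
  # field v_x(y) = 1 - ((y - 5)/5)^2 inside a straight band
  nr <- 11; nc <- 35
  vx <- matrix(rep(1 - ((0:(nr - 1) - 5) / 5)^2, nc), nr, nc)
  tph <- (0:4) / 5
  mk <- function(m, comp) velocity_map_series(replicate(5, m, simplify = FALSE),
                                              comp, c(1, 1), tph, 1.5, 1)
  ct <- rect_contour(30, 10)
  cl <- centerline_from_contour(ct, c(0, 5), c(30, 5))
  ch <- sample_chords(cl, ct, 5L)
  curves <- chord_velocity_curves(mk(matrix(0, nr, nc), "AP"), mk(vx, "FH"), ch)
  for (cv in curves) expect_equal(cv$values, rep(1, 5), tolerance = 0.02)
})

test_that("chord curves are equivariant under rigid rotation", {
  set.seed(9)
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  # one oblique chord in a shared 60x60 grid, uniform field v = (vx, vy)
  v <- c(0.5, 0.3)
  center <- c(30, 30)
  p1 <- center + c(-8, -3); p2 <- center + c(8, 3)
  tangent <- c(-(p2 - p1)[2], (p2 - p1)[1])
  tangent <- tangent / sqrt(sum(tangent^2))
  mk_chord <- function(a, b, tg, ctr)
    chord(0.01, rbind(a, b), tg, ctr)
  mk_maps <- function(vv) {
    tph <- (0:2) / 3
    list(ap = velocity_map_series(replicate(3, matrix(vv[2], 61, 61),
                                            simplify = FALSE),
                                  "AP", c(1, 1), tph, 1.5, 1),
         fh = velocity_map_series(replicate(3, matrix(vv[1], 61, 61),
                                            simplify = FALSE),
                                  "FH", c(1, 1), tph, 1.5, 1))
  }
  rot <- function(p) as.numeric(center + R %*% (p - center))
  m0 <- mk_maps(v)
  c0 <- mk_chord(p1, p2, tangent, center)   # planar (x = FH, y = AP) frame
  cur0 <- chord_velocity_curves(m0$ap, m0$fh, list(c0))[[1]]
  vr <- as.numeric(R %*% v)
  tr_ <- as.numeric(R %*% tangent)
  cr <- mk_chord(rot(p1), rot(p2), tr_, center)
  mr <- mk_maps(vr)
  cur1 <- chord_velocity_curves(mr$ap, mr$fh, list(cr))[[1]]
  expect_equal(cur0$values, cur1$values, tolerance = 1e-6)
})

test_that("chords outside the image extent are rejected", {
  ct <- rect_contour(30, 10)
  cl <- centerline_from_contour(ct, c(0, 5), c(30, 5))
  ch <- sample_chords(cl, ct, 3L)
  small <- uniform_field_maps(0, 1, nr = 4, nc = 4)
  expect_error(chord_velocity_curves(small$ap, small$fh, ch),
               class = "aortapwv_geometry_error")
})

test_that("ROI maximal velocity curves track the through-plane maps", {
  tph <- (0:3) / 4
  frames <- lapply(1:4, function(p) matrix(1, 20, 20))
  maps <- velocity_map_series(frames, "through_plane", c(1, 1), tph, 1.5, 1)
  roi <- lumen_contour(c(3, 12, 12, 3), c(3, 3, 12, 12))
  expect_equal(roi_max_velocity_curve(maps, roi)$values, rep(1, 4))
  zero <- velocity_map_series(lapply(1:4, function(p) matrix(0, 20, 20)),
                              "through_plane", c(1, 1), tph, 1.5, 1)
  zc <- roi_max_velocity_curve(zero, roi)
  expect_equal(zc$values, rep(0, 4))
  expect_error(detect_onset_velocity(zc), class = "aortapwv_no_upslope_error")
  far <- lumen_contour(c(100, 110, 110, 100), c(100, 100, 110, 110))
  expect_error(roi_max_velocity_curve(maps, far),
               class = "aortapwv_geometry_error")
})

test_that("two-site phantom transit time yields the configured speed", {
  # two square ROIs whose velocity upstrokes are delayed by 16.6 ms over
  # 0.116 m -> 7.0 m/s, within temporal-resolution error
  rr <- 1; nph <- 50
  tph <- (0:(nph - 1)) * rr / nph
  mk_site <- function(foot) {
    vals <- waveform_template(tph / rr, onset_phase = foot / rr,
                              kind = "velocity")
    frames <- lapply(vals, function(v) matrix(v, 8, 8))
    velocity_map_series(frames, "through_plane", c(1, 1), tph, 1.5, rr)
  }
  roi <- lumen_contour(c(1, 6, 6, 1), c(1, 1, 6, 6))
  c1 <- roi_max_velocity_curve(mk_site(0.100), roi)
  c2 <- roi_max_velocity_curve(mk_site(0.100 + 0.116 / 7), roi)
  est <- two_site_pwv(site_onset(0, detect_onset_velocity(c1)),
                      site_onset(0.116, detect_onset_velocity(c2)))
  expect_lt(abs(est$pwv_m_per_s / 7 - 1), 0.05)
})

test_that("lumen areas follow the shoelace formula per phase", {
  # 64-gon of radius 10 mm approximates pi r^2 within 0.5%
  phases <- lapply(1:2, function(p) circle_contour(10, phase_id = p))
  res <- lumen_area_series(phases, c(0, 0.5))
  expect_equal(res$waveform$values[1], pi * 100, tolerance = 0.005 * pi * 100)
  expect_equal(res$delta_A_mm2, 0)
  # oscillating radii reproduce the analytic distension
  ph2 <- lapply(1:6, function(p) {
    r <- c(11.28, 11.42, 11.70, 11.97, 11.70, 11.42)[p]
    circle_contour(r, phase_id = p)
  })
  res2 <- lumen_area_series(ph2, (0:5) / 6)
  shoelace_factor <- 64 / 2 * sin(2 * pi / 64) / pi  # polygon vs circle area
  expect_equal(res2$A_min_mm2, pi * 11.28^2 * shoelace_factor,
               tolerance = 1e-6)
  expect_equal(res2$delta_A_mm2,
               pi * (11.97^2 - 11.28^2) * shoelace_factor, tolerance = 1e-6)
  expect_equal(res2$A_min_mm2, 399.7, tolerance = 0.01 * 399.7)
  expect_equal(res2$delta_A_mm2, 50.5, tolerance = 0.02 * 50.5)
  expect_error(lumen_area_series(phases[1], 0),
               class = "aortapwv_config_error")
})
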
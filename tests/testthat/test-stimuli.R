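test_that("temporal frequency is the product of spatial frequency and speed", {
  expect_equal(derive_temporal_frequency(0.016, 130), 2.08)
  expect_equal(derive_temporal_frequency(0, 500), 0)
  expect_equal(derive_temporal_frequency(0.05, 20), 1.0)
  expect_equal(derive_temporal_frequency(0.05, -20), 1.0)  # speed, not velocity
  expect_error(derive_temporal_frequency(-0.01, 10), "sf")
})

test_that("Michelson contrast matches its definition and guards its domain", {
  expect_identical(michelson_contrast(255, 0), 1)
  expect_identical(michelson_contrast(128, 128), 0)
  expect_equal(michelson_contrast(192, 64), 0.5)
  expect_identical(michelson_contrast(0, 0), 0)
  expect_error(michelson_contrast(64, 192), "l_min")
})

test_that("grating frames are two-colour, full range, and static at v = 0", {
  g <- grating_spec(0.016, 130)
  fs <- render_grating(g, screen_geometry(), 3)
  f1 <- fs$frames[[1]]
  expect_identical(range(f1), c(0L, 255L))
  expect_identical(sort(unique(as.vector(f1[, , 2]))), c(0L, 255L))
  expect_identical(michelson_contrast(max(f1), min(f1)), 1)

  static <- render_grating(grating_spec(0.016, 0), screen_geometry(), 4)
  for (k in 2:4) expect_identical(static$frames[[k]], static$frames[[1]])

  flat <- render_grating(grating_spec(0.016, 130, fg_color = c(9, 9, 9),
                                      bg_color = c(9, 9, 9)),
                         screen_geometry(), 2)
  expect_true(all(flat$frames[[1]] == 9L))
})

test_that("grating phase advances by v*sf/fps cycles per frame", {
  # 130 deg/s * 0.016 cpd / 60 fps = 0.03467 cycles/frame; at 2 px/deg the
  # bar pattern shifts 4.333 px/frame, i.e. 52 px over 12 frames
  # shifts of a periodic pattern are identifiable modulo its 125-px period
  fs <- render_grating(grating_spec(0.016, 130), screen_geometry(), 13)
  fwd <- best_circular_shift(fs$frames[[1]], fs$frames[[13]])
  expect_equal(fwd %% 125, 52)
  # mirror: negated velocity shifts the other way (-52 = 73 mod 125)
  bk <- render_grating(grating_spec(0.016, -130), screen_geometry(), 13)
  bwd <- best_circular_shift(bk$frames[[1]], bk$frames[[13]])
  expect_equal((fwd + bwd) %% 125, 0)
})

test_that("unrepresentable gratings raise a resolution error", {
  expect_error(render_grating(grating_spec(2, 10), screen_geometry()),
               "unrepresentable")
})

test_that("RDK with no dots is uniform background; same seed, same frames", {
  geo <- small_geom()
  empty <- render_rdk(rdk_spec(n_dots = 0, dot_diameter_deg = 2),
                      geo, 3, seed = 1)
  expect_true(all(vapply(empty$frames, function(f) all(f == 0L), logical(1))))

  spec <- rdk_spec(n_dots = 20, dot_diameter_deg = 2, coherence = 0.5)
  a <- render_rdk(spec, geo, 5, seed = 99)
  b <- render_rdk(spec, geo, 5, seed = 99)
  expect_identical(a$frames, b$frames)
  c <- render_rdk(spec, geo, 5, seed = 100)
  expect_false(identical(a$frames, c$frames))
})

test_that("respawn conserves the rendered dot count", {
  # 1-px dots far apart: non-background pixel count equals n_dots every
  # frame, across several lifespan expiries
  geo <- screen_geometry(200, 200, 1, 60)
  spec <- rdk_spec(n_dots = 12, dot_diameter_deg = 1, speed_dps = 40,
                   lifespan_s = 0.05, coherence = 1)
  fs <- render_rdk(spec, geo, 24, seed = 5)
  px_per_dot <- nrow(flymaze:::.dot_offsets(1, 1, "circle"))
  expect_identical(px_per_dot, 1L)
  counts <- vapply(fs$frames, function(f) sum(f[, , 2] != 0L), integer(1))
  expect_true(all(counts <= 12L))           # collisions can only merge
  expect_true(mean(counts) > 11)            # and are rare on a 200x200 field
})

test_that("coherent dots move 4.33 px/frame along the signal direction", {
  geo <- screen_geometry(400, 400, 2, 60)
  spec <- rdk_spec(n_dots = 1, dot_diameter_deg = 3, speed_dps = 130,
                   coherence = 1, direction_deg = 0, lifespan_s = 100)
  fs <- render_rdk(spec, geo, 30, seed = 8)
  cents <- t(vapply(fs$frames, frame_centroid, numeric(2)))
  dx <- diff(cents[, "x"]); dy <- diff(cents[, "y"])
  ok <- abs(dx) < 100                        # drop wrap events
  expect_equal(mean(dx[ok]), 130 * 2 / 60, tolerance = 0.15)
  expect_true(all(abs(dy[ok]) <= 1))
  # 180 degrees mirrors the displacement along the motion axis
  spec2 <- rdk_spec(n_dots = 1, dot_diameter_deg = 3, speed_dps = 130,
                    coherence = 1, direction_deg = 180, lifespan_s = 100)
  fs2 <- render_rdk(spec2, geo, 30, seed = 8)
  cents2 <- t(vapply(fs2$frames, frame_centroid, numeric(2)))
  dx2 <- diff(cents2[, "x"])
  ok2 <- abs(dx2) < 100
  expect_equal(mean(dx2[ok2]), -130 * 2 / 60, tolerance = 0.15)
})

test_that("square and circle dots rasterize to the same pixel count", {
  for (d in c(1.2, 2, 5, 13.8)) {
    circ <- flymaze:::.dot_offsets(d, 2, "circle")
    sq <- flymaze:::.dot_offsets(d, 2, "square")
    expect_identical(nrow(sq), nrow(circ))
  }
  geo <- screen_geometry(100, 100, 2, 60)
  n_px <- function(shape) {
    spec <- rdk_spec(n_dots = 1, dot_diameter_deg = 5, shape = shape,
                     speed_dps = 0)
    sum(render_rdk(spec, geo, 1, seed = 3)$frames[[1]][, , 2] != 0L)
  }
  expect_identical(n_px("square"), n_px("circle"))
})

test_that("sub-pixel dots raise a resolution error", {
  geo <- screen_geometry(64, 64, 0.2, 60)
  expect_error(render_rdk(rdk_spec(n_dots = 2, dot_diameter_deg = 1),
                          geo, 1, seed = 1), "0 pixels")
})

test_that("combined stimulus layers dots opaquely with relative direction", {
  g <- grating_spec(0.05, 20, fg_color = c(0, 255, 0))
  r <- rdk_spec(n_dots = 3, dot_diameter_deg = 3, speed_dps = 20,
                dot_color = c(0, 0, 255), lifespan_s = 100)
  expect_error(combined_spec(g, r, 30), "multiple of 45")
  for (rel in seq(0, 315, by = 45))
    expect_s3_class(combined_spec(g, r, rel), "combined_spec")

  geo <- small_geom(128, 96)
  cs <- combined_spec(g, r, 0)
  fs <- render_combined(cs, geo, 3, seed = 4)
  f1 <- fs$frames[[1]]
  expect_true(any(f1[, , 3] == 255L))       # blue dots present
  expect_true(any(f1[, , 2] == 255L))       # grating visible behind

  # dots matching a zero-contrast grating are invisible
  g0 <- grating_spec(0.05, 20, fg_color = c(0, 128, 0), bg_color = c(0, 128, 0))
  r0 <- rdk_spec(n_dots = 5, dot_diameter_deg = 3, dot_color = c(0, 128, 0))
  fs0 <- render_combined(combined_spec(g0, r0, 90), geo, 2, seed = 4)
  base <- render_grating(g0, geo, 2)
  expect_identical(fs0$frames, base$frames)
})

test_that("combined dots move parallel to the grating at 0 degrees relative", {
  geo <- screen_geometry(400, 400, 2, 60)
  g <- grating_spec(0.016, 130, fg_color = c(0, 80, 0))  # dim so dots stand out
  r <- rdk_spec(n_dots = 1, dot_diameter_deg = 3, speed_dps = 130,
                dot_color = c(255, 0, 0), lifespan_s = 100)
  fs <- render_combined(combined_spec(g, r, 0), geo, 10, seed = 21)
  cents <- t(vapply(fs$frames, function(f) {
    idx <- which(f[, , 1] == 255L, arr.ind = TRUE)
    c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
  }, numeric(2)))
  dx <- diff(cents[, "x"])
  ok <- abs(dx) < 100
  expect_true(all(dx[ok] > 0))  # rightward, like the positive-velocity grating
})

test_that("synthetic textures are deterministic and intensity-valid", {
  geo <- small_geom(64, 48)
  a <- synth_texture(geo, 2, 130, 4, seed = 17)
  b <- synth_texture(geo, 2, 130, 4, seed = 17)
  expect_identical(a$frames, b$frames)
  expect_true(all(vapply(a$frames, function(f)
    min(f) >= 0L && max(f) <= 255L, logical(1))))
  # rigid translation: frame content is a circular shift of frame 1
  px <- 130 * geo$pixels_per_degree / geo$frame_rate_hz
  s <- round(3 * px) %% 64
  expect_identical(a$frames[[4]][, , 1],
                   a$frames[[1]][, c((64 - s + 1):64, 1:(64 - s)), 1])
})

test_that("texture spectral exponent is recovered from averaged spectra", {
  geo <- small_geom(128, 64)
  slope_for <- function(expo) {
    specs <- vapply(1:100, function(s) {
      fr <- synth_texture(geo, expo, 0, 1, seed = s)$frames[[1]]
      frame_power_spectrum(to_luminance(fr))
    }, numeric(65))
    m <- rowMeans(specs)
    k <- 1:63                               # non-DC, below Nyquist
    unname(coef(lm(log(m[k + 1]) ~ log(k)))[2])
  }
  expect_equal(slope_for(0), 0, tolerance = 0.2)
  expect_equal(slope_for(2), -2, tolerance = 0.2)
})

test_that("spec constructors validate their invariants", {
  expect_error(screen_geometry(0, 480), "positive")
  expect_error(grating_spec(-1, 10), "spatial_frequency")
  expect_error(grating_spec(0.1, 10, fg_color = c(0, 300, 0)), "RGB")
  expect_error(rdk_spec(coherence = 1.2), "coherence")
  expect_error(rdk_spec(shape = "triangle"))
  expect_error(render_grating(grating_spec(0.05, 10), screen_geometry(), 0),
               "n_frames")
  expect_error(render_rdk(rdk_spec(n_dots = 1), screen_geometry(), 1),
               "seed")
})
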
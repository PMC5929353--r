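# Synthetic diffraction-frame generator.

test_that("label_from_spot_count implements the annotation rule", {
  expect_identical(as.character(label_from_spot_count(c(10, 9, 4, 3, 0))),
                   c("Hit", "Maybe", "Maybe", "Miss", "Miss"))
  expect_error(label_from_spot_count(-1), "nonnegative")
})

test_that("spot position sampling respects geometry and density", {
  prof <- flat_profile(c(256L, 256L))
  # expected count 0 -> empty
  p0 <- scene_params(mode = "random", n_spots = 0)
  set.seed(1)
  expect_identical(nrow(sample_spot_positions(p0, prof)), 0L)

  # all positions inside the resolution limit, azimuthally uniform
  pu <- scene_params(mode = "random", n_spots = 10000,
                     resolution_limit = 100)
  set.seed(2)
  pos <- sample_spot_positions(pu, prof)
  r <- sqrt((pos[, 1] - 128.5)^2 + (pos[, 2] - 128.5)^2)
  expect_true(all(r <= 100 + 1e-9))
  ang <- atan2(pos[, 2] - 128.5, pos[, 1] - 128.5)
  counts <- table(cut(ang, breaks = seq(-pi, pi, length.out = 13)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # radially decreasing surface density: inner half-annulus denser than outer
  inner <- sum(r <= 50) / (pi * 50^2)
  outer <- sum(r > 50) / (pi * (100^2 - 50^2))
  expect_gt(inner, outer)

  # lattice mode: smaller reciprocal spacing (larger unit cell) gives more
  # nodes -> crowded patterns
  n_nodes <- function(cs, seed) {
    set.seed(seed)
    mean(replicate(5, nrow(sample_spot_positions(
      scene_params(mode = "lattice", cell_scale = cs), prof))))
  }
  expect_gt(n_nodes(8, 3), n_nodes(20, 3))

  # positions on untrusted pixels are discarded
  prof_gap <- builtin_profile("cspad_like", shape = c(128L, 128L))
  mask <- profile_mask(prof_gap)
  set.seed(4)
  pg <- sample_spot_positions(scene_params(mode = "random", n_spots = 300),
                              prof_gap)
  expect_true(all(mask[cbind(round(pg[, 1]), round(pg[, 2]))]))
})

test_that("render_frame composes the stated terms", {
  prof <- flat_profile(c(48L, 48L), dark = 25)
  quiet <- scene_params(mode = "random", n_spots = 0,
                        background_photons = 0, poisson_noise = FALSE)
  set.seed(1)
  res <- render_frame(matrix(numeric(0), 0, 2), quiet, prof)
  expect_true(all(res$frame$pixels == 25))
  expect_identical(res$truth$visible_count, 0L)
  expect_identical(as.character(res$truth$label), "Miss")

  # 12 bright well-separated spots -> visible_count 12, label Hit
  p12 <- scene_params(mode = "random", n_spots = 0, background_photons = 2,
                      spot_intensity = c(median = 300, spread = 0.01),
                      b_factor = 0.1, poisson_noise = FALSE)
  pos <- as.matrix(expand.grid(row = c(10, 20, 30, 40),
                               col = c(12, 24, 36)))
  set.seed(2)
  res12 <- render_frame(pos, p12, prof)
  expect_identical(res12$truth$visible_count, 12L)
  expect_identical(as.character(res12$truth$label), "Hit")
  # peak pixels sit near the stated amplitude above background + dark
  expect_gt(max(res12$frame$pixels), 250)

  # clipping at the saturation level
  sat_prof <- detector_profile("sat", c(32L, 32L), psf_sigma = 1,
                               saturation_level = 1000, dark_mean = 0)
  psat <- scene_params(mode = "random", n_spots = 0, background_photons = 0,
                       spot_intensity = c(median = 10000, spread = 0.001),
                       b_factor = 0, poisson_noise = FALSE)
  set.seed(3)
  rsat <- render_frame(cbind(16, 16), psat, sat_prof)
  expect_identical(max(rsat$frame$pixels), 1000)

  # positions outside the frame are rejected
  expect_error(render_frame(cbind(100, 100), p12, prof), "inside the frame")
})

test_that("noise-free rendering conserves photons", {
  prof <- flat_profile(c(64L, 64L), psf = 1.5, dark = 100)
  p <- scene_params(mode = "random", n_spots = 0, background_photons = 7,
                    spot_intensity = c(median = 500, spread = 0.2),
                    b_factor = 0.3, poisson_noise = FALSE)
  pos <- cbind(c(20, 32, 44), c(20, 40, 28))  # well inside, 6-sigma margin
  set.seed(5)
  res <- render_frame(pos, p, prof)
  total <- sum(res$frame$pixels - prof$dark_mean)
  expected <- res$truth$background_integral + sum(res$truth$spot_integrals)
  expect_equal(total, expected, tolerance = 1e-6)
})

test_that("beam-off frames contain dark noise only", {
  prof <- flat_profile(c(32L, 32L), dark = 50, dark_sigma = 2)
  p <- scene_params(mode = "random", n_spots = 40, beam_off_prob = 1,
                    background_photons = 20)
  set.seed(6)
  pos <- sample_spot_positions(p, prof)
  res <- render_frame(pos, p, prof)
  expect_true(res$truth$beam_off)
  expect_identical(res$truth$visible_count, 0L)
  expect_lt(max(res$frame$pixels), 50 + 5 * 2 + 1)
})

test_that("generate_dataset is deterministic and label-consistent", {
  prof <- flat_profile(c(40L, 40L), dark = 10, dark_sigma = 1)
  mix <- demo_scene_mixture(water_amplitude = 8)
  d1 <- generate_dataset(40, mix, prof, seed = 21)
  d2 <- generate_dataset(40, mix, prof, seed = 21)
  expect_identical(lapply(d1$stack$frames, function(f) f$pixels),
                   lapply(d2$stack$frames, function(f) f$pixels))
  expect_identical(d1$annotations, d2$annotations)

  # stored labels equal the rule applied to stored ground truth
  recomputed <- label_from_spot_count(
    vapply(d1$truth, function(t) t$visible_count, integer(1)))
  expect_identical(as.character(d1$annotations$label),
                   as.character(recomputed))
  expect_true(all(d1$annotations$source == "rule"))

  # a zero-spot world yields only Miss
  d0 <- generate_dataset(10, scene_params(mode = "random", n_spots = 0),
                         prof, seed = 3)
  expect_true(all(d0$annotations$label == "Miss"))
})

test_that("brighter spots never shrink the visible-count distribution", {
  prof <- flat_profile(c(48L, 48L), psf = 1)
  mk <- function(med) scene_params(mode = "random", n_spots = 8,
                                   spot_intensity = c(median = med,
                                                      spread = 0.5))
  dim_counts <- generate_dataset(200, mk(12), prof, seed = 31)$
    annotations$spot_count
  bright_counts <- generate_dataset(200, mk(120), prof, seed = 31)$
    annotations$spot_count
  # stochastic dominance on the sorted samples (same seed, same positions)
  expect_true(all(sort(bright_counts) >= sort(dim_counts)))
  expect_gt(mean(bright_counts), mean(dim_counts))
})

test_that("point-spread scale separates spot areas across profiles", {
  measure_area <- function(psf, window, sigma) {
    prof <- detector_profile("m", c(96L, 96L), psf_sigma = psf,
                             dark_mean = 0, dark_sigma = 0,
                             saturation_level = 1e6)
    p <- scene_params(mode = "random", n_spots = 6, poisson_noise = FALSE,
                      background_photons = 0, b_factor = 0.5,
                      spot_intensity = c(median = 200, spread = 0.1))
    areas <- c()
    for (s in 1:8) {
      ds <- generate_dataset(1, p, prof, seed = s)
      cands <- find_spots(ds$stack$frames[[1]],
                          spotfinder_params(global_threshold = 20,
                                            sigma_strong = sigma,
                                            min_spot_area = 1,
                                            local_window = window))
      areas <- c(areas, vapply(cands, function(x) x$area, numeric(1)))
    }
    median(areas)
  }
  # small point spread: ~1-pixel spots; large: tens of pixels
  # (the local window must exceed the spot footprint to measure it)
  expect_lt(measure_area(0.5, 7L, 3), 10)
  expect_gte(measure_area(2.5, 21L, 2), 10)
})
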
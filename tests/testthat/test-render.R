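# image generation stack: rasterization, halo, illumination, noise, PSF

test_that("rasterizing an empty world gives constant background", {
  w <- structure(list(time = 0, agents = empty_agents(), next_id = 1L,
                      seed = 1L), class = "colony_world")
  img <- rasterize(w, small_render())
  expect_true(all(img == 0.7))
})

test_that("rasterized intensity deficit equals cell area over calibration^2", {
  w <- grow_colony(12, seed = 4)
  rc <- render_config(image_size = c(256L, 256L))
  img <- rasterize(w, rc)
  ag <- w$agents
  area <- sum(vapply(seq_len(nrow(ag)), function(i)
    polygon_area(agent_outline(ag[i, ])), numeric(1)))
  flux <- sum(rc$background_level - img)
  expect_lt(abs(flux / ((rc$background_level - rc$cell_level) *
                          area / rc$calibration^2) - 1), 0.02)
})

test_that("a cell outside the field of view leaves the frame blank", {
  ag <- cell_agent(1L, x = 100, y = 100)
  w <- structure(list(time = 0, agents = ag, next_id = 2L, seed = 1L),
                 class = "colony_world")
  img <- rasterize(w, small_render(), center = c(0, 0))
  expect_true(all(img == 0.7))
})

test_that("halo stage is the identity on constant input and makes a bright rim", {
  rc <- small_render()
  flat <- matrix(rc$background_level, 128, 128)
  expect_equal(apply_halo(flat, rc), flat)
  # single centered coccoid: radial profile dips inside, peaks above
  # background just outside the cell edge
  ag <- cell_agent(1L, kind = "coccoid", length = 2, width = 2)
  w <- structure(list(time = 0, agents = ag, next_id = 2L, seed = 1L),
                 class = "colony_world")
  img <- apply_halo(rasterize(w, rc, center = c(0, 0)), rc)
  mid <- 64L
  profile <- img[mid, ]
  r_px <- 1 / rc$calibration  # cell radius in px
  inside <- profile[(mid - r_px * 0.5):(mid + r_px * 0.5)]
  outside <- profile[(mid + r_px + 1):(mid + r_px + 12)]
  expect_lt(min(inside), rc$background_level)
  expect_gt(max(outside), rc$background_level)
  bad <- rc
  bad$halo_sigmas <- c(6, 1)
  expect_error(apply_halo(flat, bad), "sigma")
})

test_that("uneven illumination preserves the mean and stays within bounds", {
  rc <- small_render(illumination_amplitude = 0.1)
  flat <- matrix(0.5, 128, 128)
  expect_identical(apply_illumination(flat,
                                      small_render(illumination_amplitude = 0)),
                   flat)
  set.seed(3)
  out <- apply_illumination(flat, rc)
  expect_lt(abs(mean(out) / 0.5 - 1), 0.01)
  expect_gte(min(out), 0.5 * 0.9 - 1e-9)
  expect_lte(max(out), 0.5 * 1.1 + 1e-9)
  set.seed(5); a <- apply_illumination(flat, rc)
  set.seed(5); b <- apply_illumination(flat, rc)
  expect_identical(a, b)
})

test_that("pixel noise recovers its configured moments", {
  flat <- matrix(0.5, 512, 512)
  rc0 <- small_render(noise_additive_sigma = 0, noise_multiplicative_sigma = 0)
  expect_identical(apply_noise(flat, rc0), flat)
  set.seed(8)
  add <- apply_noise(flat, small_render(noise_additive_sigma = 0.02,
                                        noise_multiplicative_sigma = 0))
  expect_lt(abs(sd(add) / 0.02 - 1), 0.03)
  set.seed(9)
  mul <- apply_noise(flat, small_render(noise_additive_sigma = 0,
                                        noise_multiplicative_sigma = 0.04))
  expect_lt(abs(sd(mul) / (0.5 * 0.04) - 1), 0.03)
})

test_that("the full stack renders dark cells, reproducibly", {
  w <- grow_colony(20, seed = 6)
  rc <- render_config(image_size = c(256L, 256L))
  f1 <- render_phase_contrast(w, rc, seed = 12)
  f2 <- render_phase_contrast(w, rc, seed = 12)
  expect_identical(f1, f2)
  ann <- annotate(w, rc)
  lab <- write_masks(ann, NULL)
  inside <- mean(f1[lab > 0])
  outside <- mean(f1[lab == 0])
  expect_lt(inside, outside)
  # noiseless pipeline is already deterministic without seeding
  rc0 <- render_config(image_size = c(256L, 256L),
                       illumination_amplitude = 0,
                       noise_additive_sigma = 0,
                       noise_multiplicative_sigma = 0)
  expect_identical(render_phase_contrast(w, rc0),
                   render_phase_contrast(w, rc0))
})

test_that("gaussian blur conserves flux for interior content", {
  img <- matrix(0, 128, 128)
  img[40:90, 30:100] <- runif(51 * 71)
  rc <- small_render()
  rc$background_level <- 0
  rc$halo_weights <- c(1, 0)
  rc$halo_sigmas <- c(3, 4)
  blurred <- apply_halo(img, rc)
  expect_lt(abs(sum(blurred) / sum(img) - 1), 0.001)
})

test_that("quantization depths agree in rank order", {
  w <- grow_colony(10, seed = 12)
  rc8 <- render_config(image_size = c(192L, 192L), output_depth = 8L)
  rc16 <- render_config(image_size = c(192L, 192L), output_depth = 16L)
  f8 <- render_phase_contrast(w, rc8, seed = 3)
  f16 <- render_phase_contrast(w, rc16, seed = 3)
  expect_gte(cor(as.vector(f8), as.vector(f16), method = "spearman"), 0.999)
})

test_that("fluorescence flux is conserved under the PSF", {
  ag <- cell_agent(1L, fluorescence = 5)
  w <- structure(list(time = 0, agents = ag, next_id = 2L, seed = 1L),
                 class = "colony_world")
  rc <- small_render()
  fc <- fluorescence_config(psf_sigma = 2, background_level = 0.1)
  img <- render_fluorescence(w, fc, rc, center = c(0, 0))
  expect_lt(abs((sum(img) - 0.1 * length(img)) / 5 - 1), 0.02)
  # zero fluorescence -> constant background
  w$agents$fluorescence <- 0
  img0 <- render_fluorescence(w, fc, rc, center = c(0, 0))
  expect_true(all(img0 == 0.1))
  # peak decreases as the PSF widens
  w$agents$fluorescence <- 5
  pk <- vapply(c(1, 2, 4), function(s)
    max(render_fluorescence(w, fluorescence_config(psf_sigma = s,
                                                   background_level = 0),
                            rc, center = c(0, 0))), numeric(1))
  expect_true(all(diff(pk) < 0))
})

test_that("histogram correlation behaves as a realism metric", {
  w <- grow_colony(25, seed = 21)
  rc <- render_config(image_size = c(256L, 256L))
  f <- render_phase_contrast(w, rc, seed = 2)
  expect_equal(histogram_correlation(f, f), 1)
  inv <- (2^16 - 1) - f
  expect_lt(histogram_correlation(f, inv), 1)
  expect_error(histogram_correlation(f, f, n_bins = 1), "n_bins")
  # two colonies of similar density from different seeds look alike
  w2 <- grow_colony(25, seed = 22)
  f2 <- render_phase_contrast(w2, rc, seed = 4)
  expect_gt(histogram_correlation(f, f2), 0.9)
})

test_that("histogram correlation degrades monotonically with noise", {
  w <- grow_colony(25, seed = 23)
  mk <- function(sig) render_config(image_size = c(256L, 256L),
                                    illumination_amplitude = 0,
                                    noise_multiplicative_sigma = 0,
                                    noise_additive_sigma = sig)
  clean <- render_phase_contrast(w, mk(0))
  cors <- vapply(c(0.01, 0.05, 0.1), function(sig)
    histogram_correlation(clean, render_phase_contrast(w, mk(sig), seed = 31)),
    numeric(1))
  expect_true(all(diff(cors) < 0))
})
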
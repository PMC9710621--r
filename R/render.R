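# Synthetic microscopy: an ideal noiseless raster of the colony is degraded
# through a fixed stage stack -- phase-contrast halo (combined Gaussian
# blurs), uneven illumination, additive/multiplicative pixel noise -- and
# quantized, mimicking how a phase-contrast micrograph arises from the ideal
# scene. Images are numeric matrices in [0, 1], row = image row (origin top
# left).

#' Rendering configuration
#'
#' Pixel calibration, intensity levels and the parameters of every
#' degradation stage. Defaults give dark cells on a bright field with the
#' characteristic phase-contrast halo.
#'
#' @param image_size `(height, width)` in pixels.
#' @param calibration pixel size in µm/pixel (default 0.09).
#' @param background_level,cell_level ideal-image intensities in `[0, 1]`.
#' @param halo_sigmas `(sigma_inner, sigma_outer)` Gaussian widths in px of
#'   the two blur stages combined into the halo; `sigma_outer > sigma_inner`.
#' @param halo_weights `(w_inner, w_outer)` combination weights.
#' @param illumination_amplitude peak amplitude of the uneven-illumination
#'   field as a fraction of the local intensity (0 disables).
#' @param illumination_scale correlation length in px of the
#'   `"noise"`-type illumination field (ignored by the default smooth
#'   polynomial field).
#' @param illumination_type `"polynomial"` (random 2nd-order surface) or
#'   `"noise"` (broadly blurred white noise).
#' @param noise_additive_sigma std. dev. of additive Gaussian pixel noise.
#' @param noise_multiplicative_sigma std. dev. of multiplicative Gaussian
#'   pixel noise.
#' @param output_depth quantization depth in bits: 8 or 16.
#' @param n_vertices contour vertex count used when rasterizing cells.
#' @return A `render_config` list.
#' @export
render_config <- function(image_size = c(512L, 512L), calibration = 0.09,
                          background_level = 0.7, cell_level = 0.25,
                          halo_sigmas = c(1, 6), halo_weights = c(1, 0.4),
                          illumination_amplitude = 0.05,
                          illumination_scale = 128,
                          illumination_type = c("polynomial", "noise"),
                          noise_additive_sigma = 0.01,
                          noise_multiplicative_sigma = 0.02,
                          output_depth = 16L, n_vertices = 32L) {
  illumination_type <- match.arg(illumination_type)
  if (any(image_size < 1)) stop("image_size must be positive", call. = FALSE)
  if (calibration <= 0) stop("calibration must be > 0", call. = FALSE)
  if (background_level < 0 || background_level > 1 ||
      cell_level < 0 || cell_level > 1)
    stop("intensity levels must lie in [0, 1]", call. = FALSE)
  if (!(halo_sigmas[2L] > halo_sigmas[1L]) || halo_sigmas[1L] <= 0)
    stop("need halo sigma_outer > sigma_inner > 0", call. = FALSE)
  if (noise_additive_sigma < 0 || noise_multiplicative_sigma < 0)
    stop("noise sigmas must be >= 0", call. = FALSE)
  if (!output_depth %in% c(8L, 16L)) stop("output_depth must be 8 or 16", call. = FALSE)
  structure(list(image_size = as.integer(image_size), calibration = calibration,
                 background_level = background_level, cell_level = cell_level,
                 halo_sigmas = halo_sigmas, halo_weights = halo_weights,
                 illumination_amplitude = illumination_amplitude,
                 illumination_scale = illumination_scale,
                 illumination_type = illumination_type,
                 noise_additive_sigma = noise_additive_sigma,
                 noise_multiplicative_sigma = noise_multiplicative_sigma,
                 output_depth = as.integer(output_depth),
                 n_vertices = as.integer(n_vertices)),
            class = "render_config")
}

#' Fluorescence rendering configuration
#'
#' @param psf_sigma Gaussian point-spread-function width in px (> 0).
#' @param background_level constant background intensity added to the frame.
#' @param shot_noise apply Poisson shot noise to the photon counts.
#' @param photons_per_unit photon scale used when `shot_noise = TRUE`.
#' @return A `fluorescence_config` list.
#' @export
fluorescence_config <- function(psf_sigma = 2, background_level = 0.05,
                                shot_noise = FALSE, photons_per_unit = 1e4) {
  if (psf_sigma <= 0) stop("psf_sigma must be > 0", call. = FALSE)
  structure(list(psf_sigma = psf_sigma, background_level = background_level,
                 shot_noise = isTRUE(shot_noise),
                 photons_per_unit = photons_per_unit),
            class = "fluorescence_config")
}

# world-µm -> pixel mapping. The camera is centered on `center` (µm); pixel
# (r, c), 1-based, covers the world rectangle
# [x0 + (c-1) s, x0 + c s) x [y0 + (r-1) s, y0 + r s), s = calibration.
frame_origin <- function(center, config) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  s <- config$calibration
  c(x0 = center[1L] - w * s / 2, y0 = center[2L] - h * s / 2)
}

default_center <- function(world) {
  if (nrow(world$agents) == 0L) return(c(0, 0))
  c(mean(world$agents$x), mean(world$agents$y))
}

# per-cell pixel coverage accumulated into a h x w matrix; 4x4 subpixel
# sampling gives area-weighted anti-aliased boundary pixels
coverage_matrix <- function(world, config, center) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  s <- config$calibration
  org <- frame_origin(center, config)
  cov <- matrix(0, h, w)
  ss <- 4L
  offs <- (seq_len(ss) - 0.5) / ss
  for (i in seq_len(nrow(world$agents))) {
    poly <- as.matrix(agent_outline(world$agents[i, ], config$n_vertices))
    # to pixel units (continuous, 0-based)
    px <- (poly[, 1L] - org["x0"]) / s
    py <- (poly[, 2L] - org["y0"]) / s
    c0 <- max(1L, floor(min(px)) + 1L); c1 <- min(w, ceiling(max(px)))
    r0 <- max(1L, floor(min(py)) + 1L); r1 <- min(h, ceiling(max(py)))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    sx <- as.vector(outer(offs, cols - 1L, `+`))  # subsample x coords
    sy <- as.vector(outer(offs, rows - 1L, `+`))
    gx <- rep(sx, times = length(sy))
    gy <- rep(sy, each = length(sx))
    inside <- points_in_polygon(gx, gy, cbind(px, py))
    m <- matrix(inside, nrow = length(sx))           # subcols x subrows
    # aggregate ss x ss blocks -> per-pixel coverage fraction
    dim(m) <- c(ss, length(cols), ss, length(rows))
    frac <- apply(m, c(2L, 4L), sum) / (ss * ss)
    cov[rows, cols] <- cov[rows, cols] + t(frac)
  }
  pmin(cov, 1)
}

#' Rasterize the ideal (noiseless) image
#'
#' Background everywhere except pixels covered by a cell outline, which take
#' the cell level; boundary pixels are anti-aliased by 4x4 subpixel
#' sampling. The camera is centered on the colony centroid unless `center`
#' is given.
#'
#' @param world a `colony_world`.
#' @param config a [render_config()].
#' @param center optional camera center (x, y) in µm.
#' @return Numeric `height x width` matrix in `[0, 1]`.
#' @export
rasterize <- function(world, config = render_config(), center = NULL) {
  if (any(config$image_size < 1)) stop("zero-size image", call. = FALSE)
  if (is.null(center)) center <- default_center(world)
  cov <- coverage_matrix(world, config, center)
  config$background_level + (config$cell_level - config$background_level) * cov
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma)
}

#' Apply the phase-contrast halo stage
#'
#' Combines two Gaussian blurs of the deviation from background into a
#' difference-of-Gaussians composite:
#' `out = bg + w_inner * G(sigma_inner) * d - w_outer * G(sigma_outer) * d`
#' with `d = img - bg`. Dark cell bodies acquire the bright rim typical of
#' phase contrast. Output clipped to `[0, 1]`.
#'
#' @param img ideal image in `[0, 1]`.
#' @param config a [render_config()].
#' @return Image matrix in `[0, 1]`.
#' @export
apply_halo <- function(img, config = render_config()) {
  if (!(config$halo_sigmas[2L] > config$halo_sigmas[1L]))
    stop("need halo sigma_outer > sigma_inner", call. = FALSE)
  bg <- config$background_level
  d <- img - bg
  out <- bg + config$halo_weights[1L] * gaussian_blur(d, config$halo_sigmas[1L]) -
    config$halo_weights[2L] * gaussian_blur(d, config$halo_sigmas[2L])
  pmin(pmax(out, 0), 1)
}

# unit-amplitude smooth random surface with mean ~ 0
illumination_field <- function(config) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  if (config$illumination_type == "polynomial") {
    u <- matrix(rep(seq(-1, 1, length.out = w), each = h), h, w)
    v <- matrix(rep(seq(-1, 1, length.out = h), times = w), h, w)
    cf <- stats::rnorm(5L)
    f <- cf[1L] * u + cf[2L] * v + cf[3L] * u * v + cf[4L] * u^2 + cf[5L] * v^2
  } else {
    f <- matrix(stats::rnorm(h * w), h, w)
    f <- gaussian_blur(f, config$illumination_scale / 4)
  }
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0) f <- f / m
  f
}

#' Apply uneven illumination
#'
#' Multiplies the image by `1 + amplitude * f(x, y)` where `f` is a smooth
#' unit-amplitude random surface with approximately zero mean (a random
#' 2nd-order polynomial by default, mimicking microscope flat-field error).
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param img image in `[0, 1]`.
#' @param config a [render_config()].
#' @return Image matrix, clipped to `[0, 1]`.
#' @export
apply_illumination <- function(img, config = render_config()) {
  a <- config$illumination_amplitude
  if (a == 0) return(img)
  f <- illumination_field(config)
  pmin(pmax(img * (1 + a * f), 0), 1)
}

#' Apply pixel noise
#'
#' `out = clip(img * (1 + eps_m) + eps_a)` with independent per-pixel
#' Gaussian draws: `eps_m ~ N(0, sigma_m^2)` (multiplicative) and
#' `eps_a ~ N(0, sigma_a^2)` (additive). Uses the current RNG state.
#'
#' @param img image in `[0, 1]`.
#' @param config a [render_config()].
#' @return Image matrix, clipped to `[0, 1]`.
#' @export
apply_noise <- function(img, config = render_config()) {
  sm <- config$noise_multiplicative_sigma
  sa <- config$noise_additive_sigma
  if (sm < 0 || sa < 0) stop("noise sigmas must be >= 0", call. = FALSE)
  n <- length(img)
  out <- img
  if (sm > 0) out <- out * (1 + matrix(stats::rnorm(n, 0, sm), nrow(img)))
  if (sa > 0) out <- out + matrix(stats::rnorm(n, 0, sa), nrow(img))
  pmin(pmax(out, 0), 1)
}

quantize_image <- function(img, depth) {
  maxv <- 2L^depth - 1L
  m <- round(img * maxv)
  storage.mode(m) <- "integer"
  m
}

#' Render a realistic phase-contrast frame
#'
#' Full stage stack in fixed order: rasterize -> halo -> uneven
#' illumination -> pixel noise -> quantize to 8 or 16 bits.
#'
#' @param world a `colony_world`.
#' @param config a [render_config()].
#' @param center optional camera center (x, y) in µm.
#' @param seed optional integer seed for the illumination/noise draws; when
#'   `NULL` the current RNG state is used.
#' @return Integer matrix of quantized intensities, with attribute `depth`.
#' @export
render_phase_contrast <- function(world, config = render_config(),
                                  center = NULL, seed = NULL) {
  run <- function() {
    img <- rasterize(world, config, center)
    img <- apply_halo(img, config)
    img <- apply_illumination(img, config)
    img <- apply_noise(img, config)
    quantize_image(img, config$output_depth)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  attr(out, "depth") <- config$output_depth
  out
}

#' Render a fluorescence frame
#'
#' Each cell emits its `fluorescence` total intensity uniformly over its
#' area; the emission raster is convolved with a Gaussian point spread
#' function and a constant background added. Total flux above background is
#' conserved by the convolution (away from the image borders). Optional
#' Poisson shot noise.
#'
#' @param world a `colony_world` whose agents carry `fluorescence >= 0`.
#' @param config a [fluorescence_config()].
#' @param calib_config a [render_config()] supplying image size, pixel
#'   calibration and camera framing.
#' @param center optional camera center (x, y) in µm.
#' @param seed optional integer seed for the shot-noise draw.
#' @return Numeric image matrix (intensity units, not clipped to `[0, 1]`).
#' @export
render_fluorescence <- function(world, config = fluorescence_config(),
                                calib_config = render_config(),
                                center = NULL, seed = NULL) {
  if (config$psf_sigma <= 0) stop("psf_sigma must be > 0", call. = FALSE)
  if (any(world$agents$fluorescence < 0))
    stop("fluorescence must be >= 0", call. = FALSE)
  if (is.null(center)) center <- default_center(world)
  h <- calib_config$image_size[1L]; w <- calib_config$image_size[2L]
  emission <- matrix(0, h, w)
  cc <- calib_config
  for (i in seq_len(nrow(world$agents))) {
    if (world$agents$fluorescence[i] == 0) next
    w1 <- world
    w1$agents <- world$agents[i, , drop = FALSE]
    cov <- coverage_matrix(w1, cc, center)
    tot <- sum(cov)
    if (tot > 0)
      emission <- emission + cov * (world$agents$fluorescence[i] / tot)
  }
  img <- gaussian_blur(emission, config$psf_sigma) + config$background_level
  if (config$shot_noise) {
    s <- config$photons_per_unit
    draw <- function() matrix(stats::rpois(length(img), pmax(img, 0) * s) / s,
                              nrow(img))
    img <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  img
}

#' Correlation of two intensity histograms
#'
#' Normalizes both images to the common intensity range, bins each into
#' `n_bins` equal-width bins and returns the Pearson correlation of the two
#' count vectors. Used as a realism/quality-control comparison between
#' synthetic and reference frames.
#'
#' @param img_a,img_b numeric or integer image matrices.
#' @param n_bins number of histogram bins (>= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
histogram_correlation <- function(img_a, img_b, n_bins = 64L) {
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  a <- as.numeric(img_a); b <- as.numeric(img_b)
  lo <- min(a, b); hi <- max(a, b)
  if (hi <= lo) return(1)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  ha <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins)
  hb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins)
  stats::cor(ha, hb)
}

#' Write an image frame to disk
#'
#' Integer frames from [render_phase_contrast()] are written as 16-bit TIFF
#' or 8-bit PNG according to their depth; float images in `[0, 1]` according
#' to the file extension.
#'
#' @param img integer or numeric image matrix.
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path) {
  depth <- attr(img, "depth")
  if (is.null(depth)) depth <- if (grepl("\\.png$", path, ignore.case = TRUE)) 8L else 16L
  x <- as.matrix(img)
  if (is.integer(x)) x <- x / (2^depth - 1)
  x <- pmin(pmax(x, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(x, path)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = if (depth > 8L) 16L else 8L)
  }
  invisible(path)
}
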
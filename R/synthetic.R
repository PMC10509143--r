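#' Describe one blood sample applied to a sponge
#'
#' A sample is characterised by its hemoglobin concentration and the volume
#' pipetted onto the sponge; the hemoglobin mass follows by unit arithmetic:
#' concentration (g/L) times volume (mL) gives mass in mg, since
#' 1 g/L = 1 mg/mL.
#'
#' @param concentration Hb concentration in g/L; must be positive. The
#'   clinically relevant range emulated by the generator is 50--170 g/L.
#' @param volume applied whole-blood volume in mL; must be non-negative.
#' @return An object of class `blood_sample`: a list with `concentration`
#'   (g/L), `volume` (mL) and `hb_mass` (mg).
#' @examples
#' blood_sample(100, 1)   # 100 mg of Hb
#' blood_sample(170, 2.5) # 425 mg
#' @export
blood_sample <- function(concentration, volume) {
  stopifnot_scalar_num(concentration, "concentration")
  stopifnot_scalar_num(volume, "volume")
  if (concentration <= 0) {
    stop("`concentration` must be positive: it is a Hb concentration in g/L ",
         "(grams of hemoglobin per litre of blood)", call. = FALSE)
  }
  if (volume < 0) {
    stop("`volume` must be >= 0: it is an applied blood volume in mL",
         call. = FALSE)
  }
  structure(
    list(concentration = concentration, volume = volume,
         hb_mass = concentration * volume),
    class = "blood_sample"
  )
}

#' @export
print.blood_sample <- function(x, ...) {
  cat(sprintf("Blood sample: %.3g g/L Hb x %.3g mL = %.4g mg Hb\n",
              x$concentration, x$volume, x$hb_mass))
  invisible(x)
}

#' Scene parameters for the synthetic sponge renderer
#'
#' Describes the simulated camera scene: frame size, where the sponge lies,
#' base colours, the stain geometry and the per-channel Beer--Lambert-style
#' absorption coefficients that darken stained pixels as a function of Hb
#' surface density.
#'
#' The sponge is taken to represent `sponge_area_cm2` of physical gauze, so
#' renders are resolution independent: the same sample produces the same
#' stain colour at any frame size.
#'
#' @param image_height,image_width frame size in pixels.
#' @param sponge_box [bounding_box()] of the sponge within the frame
#'   (0-based, half-open). Default: a centred box covering most of the frame.
#' @param sponge_base_color,background_color RGB triples in `[0, 1]`. The
#'   default background is a surgical-drape teal, well separated from both
#'   gauze white and blood red.
#' @param absorption per-channel positive absorption coefficients
#'   (cm^2/mg) with `absorption[1]` (red) smallest, so stains render
#'   red-brown and darken monotonically with Hb surface density.
#' @param spread_frac_per_ml fraction of the sponge area wetted per mL of
#'   blood (constant absorbency); the stain footprint area is
#'   `volume * spread_frac_per_ml * sponge_area`, clipped to the sponge.
#' @param sponge_area_cm2 physical area the sponge box represents, cm^2.
#' @param stain_roughness amplitude of the angular irregularity of the stain
#'   boundary (0 = circle).
#' @param stain_harmonics number of random Fourier harmonics shaping the
#'   stain boundary.
#' @param stain_edge_frac width of the thin wicking rim at the stain
#'   boundary where the blood layer ramps down, as a fraction of the sponge
#'   box's smaller dimension. Blood pools deeper towards the stain centre
#'   and wicks outward into a fixed-width lighter fringe, so small stains
#'   are proportionally fringier than large ones.
#' @param stain_edge_floor relative blood depth at the very boundary of the
#'   stain (before depth renormalisation), in (0, 1].
#' @param noise_sd additive Gaussian pixel noise SD on the `[0, 1]` scale.
#' @param texture_amp amplitude of the multiplicative low-frequency sponge
#'   texture.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_height = 512L, image_width = 512L,
                         sponge_box = NULL,
                         sponge_base_color = c(0.91, 0.88, 0.82),
                         background_color = c(0.18, 0.35, 0.42),
                         absorption = c(0.06, 0.33, 0.36),
                         spread_frac_per_ml = 0.25,
                         sponge_area_cm2 = 100,
                         stain_roughness = 0.25,
                         stain_harmonics = 6L,
                         stain_edge_frac = 0.04,
                         stain_edge_floor = 0.35,
                         noise_sd = 0.008,
                         texture_amp = 0.03) {
  image_height <- as.integer(image_height)
  image_width <- as.integer(image_width)
  if (image_height < 8L || image_width < 8L) {
    stop("frame must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (is.null(sponge_box)) {
    mr <- max(1L, round(image_height * 0.1))
    mc <- max(1L, round(image_width * 0.1))
    sponge_box <- bounding_box(mr, image_height - mr, mc, image_width - mc)
  }
  validate_box_in_frame(sponge_box, image_height, image_width)
  if ((sponge_box$row_end - sponge_box$row_start) < 1 ||
      (sponge_box$col_end - sponge_box$col_start) < 1) {
    stop("`sponge_box` has zero area", call. = FALSE)
  }
  for (nm in c("sponge_base_color", "background_color")) {
    v <- get(nm)
    if (length(v) != 3L || any(v < 0) || any(v > 1)) {
      stop(sprintf("`%s` must be an RGB triple in [0, 1]", nm), call. = FALSE)
    }
  }
  if (length(absorption) != 3L || any(absorption <= 0)) {
    stop("`absorption` must be three strictly positive coefficients",
         call. = FALSE)
  }
  if (absorption[1] >= absorption[2] || absorption[1] >= absorption[3]) {
    stop("red absorption must be the smallest (blood stains stay red): ",
         "need absorption[1] < absorption[2] and absorption[1] < absorption[3]",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (spread_frac_per_ml <= 0) {
    stop("`spread_frac_per_ml` must be positive", call. = FALSE)
  }
  structure(
    list(image_height = image_height, image_width = image_width,
         sponge_box = sponge_box,
         sponge_base_color = as.numeric(sponge_base_color),
         background_color = as.numeric(background_color),
         absorption = as.numeric(absorption),
         spread_frac_per_ml = spread_frac_per_ml,
         sponge_area_cm2 = sponge_area_cm2,
         stain_roughness = stain_roughness,
         stain_harmonics = as.integer(stain_harmonics),
         stain_edge_frac = stain_edge_frac,
         stain_edge_floor = stain_edge_floor,
         noise_sd = noise_sd, texture_amp = texture_amp),
    class = "scene_params"
  )
}

# Low-frequency multiplicative texture field in [-1, 1]: a coarse random grid
# bilinearly upsampled to the requested size. Consumes RNG.
texture_field <- function(nrow, ncol, cells = 16L) {
  g <- matrix(runif(cells * cells, -1, 1), cells, cells)
  ri <- seq(1, cells, length.out = nrow)
  ci <- seq(1, cells, length.out = ncol)
  r0 <- pmin(floor(ri), cells - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), cells - 1L); cf <- ci - c0
  a <- g[cbind(rep(r0, ncol), rep(c0, each = nrow))]
  b <- g[cbind(rep(r0 + 1, ncol), rep(c0, each = nrow))]
  cc <- g[cbind(rep(r0, ncol), rep(c0 + 1, each = nrow))]
  d <- g[cbind(rep(r0 + 1, ncol), rep(c0 + 1, each = nrow))]
  w_rf <- rep(rf, ncol); w_cf <- rep(cf, each = nrow)
  v <- a * (1 - w_rf) * (1 - w_cf) + b * w_rf * (1 - w_cf) +
    cc * (1 - w_rf) * w_cf + d * w_rf * w_cf
  matrix(v, nrow, ncol)
}

# Irregular stain footprint inside the sponge box with (up to clipping) a
# prescribed pixel area. Returns a logical H x W mask. Consumes RNG.
stain_footprint <- function(scene, area_px) {
  H <- scene$image_height; W <- scene$image_width
  box <- scene$sponge_box
  mask <- matrix(FALSE, H, W)
  if (area_px < 1) return(mask)
  rows <- (box$row_start + 1L):box$row_end
  cols <- (box$col_start + 1L):box$col_end
  box_px <- length(rows) * length(cols)
  area_px <- min(area_px, box_px)
  # random centre in the middle half of the sponge
  cr <- box$row_start + (0.25 + 0.5 * runif(1)) * (box$row_end - box$row_start)
  ccol <- box$col_start + (0.25 + 0.5 * runif(1)) * (box$col_end - box$col_start)
  nh <- scene$stain_harmonics
  amp <- rnorm(nh) / seq_len(nh)
  amp <- amp / max(1, sqrt(sum(amp^2))) * scene$stain_roughness
  phase <- runif(nh, 0, 2 * pi)
  dr <- outer(rows - 0.5, rep(1, length(cols))) - cr
  dc <- outer(rep(1, length(rows)), cols - 0.5) - ccol
  dist <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  rho <- 1
  for (k in seq_len(nh)) rho <- rho + amp[k] * cos(k * theta + phase[k])
  rho <- pmax(rho, 0.2)
  # q <= R0 selects the blob; choose R0 so that exactly area_px pixels qualify
  q <- dist / rho
  r0 <- sort(as.vector(q), partial = area_px)[area_px]
  mask[rows, cols] <- q <= r0
  mask
}

#' Render a synthetic blood-soaked sponge image
#'
#' Paints the background and a textured sponge, stamps an irregular blood
#' stain whose footprint area is proportional to the applied volume, and
#' darkens stained pixels channelwise by `exp(-k_c * d)`, where `d` is the
#' Hb surface density (mg/cm^2): the sample's Hb mass divided by the physical
#' stain area. Because the footprint area is proportional to volume, `d` is
#' proportional to concentration alone, so stain colour encodes concentration
#' while stain area encodes volume. Gaussian noise is added and intensities
#' are quantised to 8 bits.
#'
#' Rendering is bit-exact reproducible: the same (sample, scene, seed) always
#' yields the same pixels.
#'
#' @param sample a [blood_sample()].
#' @param scene a [scene_params()].
#' @param seed integer RNG seed for this render.
#' @return An object of class `synthetic_image`: list with `pixels`
#'   (H x W x 3 integer array, 0--255), `sample`, `truth_sponge_box`,
#'   `truth_stain_mask` (logical H x W), `seed` and `scene`.
#' @export
render_sponge_image <- function(sample, scene = scene_params(), seed = 1L) {
  if (!inherits(sample, "blood_sample")) {
    stop("`sample` must be a blood_sample", call. = FALSE)
  }
  if (!inherits(scene, "scene_params")) {
    stop("`scene` must be scene_params", call. = FALSE)
  }
  with_seed(seed, {
    H <- scene$image_height; W <- scene$image_width
    box <- scene$sponge_box
    rows <- (box$row_start + 1L):box$row_end
    cols <- (box$col_start + 1L):box$col_end
    sponge_px <- length(rows) * length(cols)

    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) img[, , ch] <- scene$background_color[ch]

    tex <- 1 + scene$texture_amp * texture_field(length(rows), length(cols))
    for (ch in 1:3) {
      img[rows, cols, ch] <- scene$sponge_base_color[ch] * tex
    }

    mask <- matrix(FALSE, H, W)
    if (sample$volume > 0) {
      area_px <- round(sample$volume * scene$spread_frac_per_ml * sponge_px)
      mask <- stain_footprint(scene, area_px)
      stain_px <- sum(mask)
      if (stain_px > 0) {
        stain_frac <- stain_px / sponge_px
        stain_cm2 <- stain_frac * scene$sponge_area_cm2
        density <- sample$hb_mass / stain_cm2  # mean Hb density, mg/cm^2
        # Depth profile: blood wicks outward into a fixed-width lighter rim,
        # so the local blood layer ramps up over `edge_w` pixels from the
        # stain boundary and is renormalised to conserve the total Hb mass.
        edge_w <- max(1, scene$stain_edge_frac *
                        min(box$row_end - box$row_start,
                            box$col_end - box$col_start))
        dist <- EBImage::imageData(EBImage::distmap(mask))
        depth <- scene$stain_edge_floor + (1 - scene$stain_edge_floor) *
          pmin(dist[mask] / edge_w, 1)
        depth <- depth / mean(depth)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[mask] <- plane[mask] * exp(-scene$absorption[ch] * density *
                                             depth)
          img[, , ch] <- plane
        }
      }
    }

    if (scene$noise_sd > 0) {
      img <- img + rnorm(length(img), sd = scene$noise_sd)
    }
    pix <- array(as.integer(round(pmin(pmax(img, 0), 1) * 255)),
                 dim = dim(img))

    structure(
      list(pixels = pix, sample = sample, truth_sponge_box = box,
           truth_stain_mask = mask, seed = as.integer(seed), scene = scene),
      class = "synthetic_image"
    )
  })
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("Synthetic sponge image %dx%d, Hb mass %.4g mg, stain %d px, seed %d\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$sample$hb_mass,
              sum(x$truth_stain_mask), x$seed))
  invisible(x)
}

#' Simulate a batch of sponge images in memory
#'
#' Draws concentrations and volumes uniformly from the given ranges (defaults
#' emulate the clinical 50--170 g/L range of whole-blood dilutions) and
#' renders one image per sample. A single master seed fans out to per-image
#' seeds, so each image is independently reproducible.
#'
#' @param n number of images.
#' @param concentration_range,volume_range ranges (g/L, mL) sampled uniformly.
#' @param scene a [scene_params()].
#' @param seed master RNG seed.
#' @return List with `images` (list of `synthetic_image`) and `manifest`
#'   (data.frame: `filename`, `concentration_g_per_L`, `volume_mL`,
#'   `hb_mass_mg`, `seed`).
#' @export
simulate_sponges <- function(n, concentration_range = c(50, 170),
                             volume_range = c(1.0, 2.0),
                             scene = scene_params(), seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (concentration_range[1] <= 0 || diff(concentration_range) < 0) {
    stop("invalid `concentration_range` (g/L)", call. = FALSE)
  }
  if (volume_range[1] < 0 || diff(volume_range) < 0) {
    stop("invalid `volume_range` (mL)", call. = FALSE)
  }
  draws <- with_seed(seed, list(
    conc = runif(n, concentration_range[1], concentration_range[2]),
    vol = runif(n, volume_range[1], volume_range[2]),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- render_sponge_image(
      blood_sample(draws$conc[i], draws$vol[i]), scene, draws$seeds[i])
  }
  manifest <- data.frame(
    filename = sprintf("sponge_%04d.png", seq_len(n)),
    concentration_g_per_L = draws$conc,
    volume_mL = draws$vol,
    hb_mass_mg = draws$conc * draws$vol,
    seed = draws$seeds,
    stringsAsFactors = FALSE
  )
  list(images = images, manifest = manifest)
}

#' Generate a sponge image dataset on disk
#'
#' Renders `n` synthetic sponge images (see [simulate_sponges()]), writes them
#' as 8-bit RGB PNG files plus a CSV manifest
#' (`filename,concentration_g_per_L,volume_mL,hb_mass_mg,seed`), and
#' optionally a PASCAL-VOC-style XML annotation of the true sponge box per
#' image.
#'
#' @inheritParams simulate_sponges
#' @param dir output directory (created if needed).
#' @param write_xml also write a VOC XML annotation per image.
#' @return Invisibly, the manifest data.frame with an attribute `dir`.
#' @export
generate_dataset <- function(n, dir, concentration_range = c(50, 170),
                             volume_range = c(1.0, 2.0),
                             scene = scene_params(), seed = 1L,
                             write_xml = FALSE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
    }
  }
  sim <- simulate_sponges(n, concentration_range, volume_range, scene, seed)
  for (i in seq_len(n)) {
    path <- file.path(dir, sim$manifest$filename[i])
    png::writePNG(sim$images[[i]]$pixels / 255, target = path)
    if (write_xml) {
      ann <- annotation(
        image_filename = sim$manifest$filename[i],
        boxes = list(list(label = "sponge",
                          box = sim$images[[i]]$truth_sponge_box)),
        width = scene$image_width, height = scene$image_height)
      write_annotation(ann, sub("\\.png$", ".xml", path))
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(sim$manifest, manifest_path, row.names = FALSE,
                   quote = FALSE)
  attr(sim$manifest, "dir") <- dir
  invisible(sim$manifest)
}
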
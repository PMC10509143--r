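test_that("blood sample mass follows g/L x mL = mg arithmetic", {
  expect_equal(blood_sample(100, 1.0)$hb_mass, 100)
  expect_equal(blood_sample(50, 0)$hb_mass, 0)
  expect_equal(blood_sample(170, 2.5)$hb_mass, 425)
})

test_that("invalid samples are rejected with unit-explaining errors", {
  expect_error(blood_sample(0, 1), "g/L")
  expect_error(blood_sample(-50, 1), "g/L")
  expect_error(blood_sample(100, -0.1), "mL")
})

test_that("scene validation rejects degenerate and unphysical setups", {
  expect_error(scene_params(sponge_box = bounding_box(0, 600, 0, 100)),
               "exceeds")
  expect_error(scene_params(absorption = c(0.5, 0.3, 0.3)), "red absorption")
  expect_error(scene_params(absorption = c(0, 0.3, 0.3)), "positive")
  expect_error(scene_params(noise_sd = -1), "noise_sd")
})

test_that("rendering is bit-exact under a fixed seed", {
  a <- render_fixture(seed = 13)
  b <- render_fixture(seed = 13)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth_stain_mask, b$truth_stain_mask)
  c <- render_fixture(seed = 14)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("pixels are 8-bit and the stain stays inside the sponge box", {
  img <- render_fixture(volume = 3.9)  # footprint would overflow: clipped
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  box <- img$truth_sponge_box
  outside <- img$truth_stain_mask
  outside[(box$row_start + 1):box$row_end,
          (box$col_start + 1):box$col_end] <- FALSE
  expect_false(any(outside))
})

test_that("zero volume renders a stain-free sponge", {
  img0 <- render_sponge_image(blood_sample(100, 0), small_scene(), seed = 3)
  expect_false(any(img0$truth_stain_mask))
  # sponge region statistically indistinguishable from an untouched render
  ref <- render_sponge_image(blood_sample(150, 0), small_scene(), seed = 3)
  expect_identical(img0$pixels, ref$pixels)
})

test_that("stain darkness increases strictly with concentration", {
  # noise and texture off isolates the Beer-Lambert attenuation
  concs <- seq(50, 170, by = 20)
  means <- vapply(concs, function(cc) {
    img <- render_sponge_image(blood_sample(cc, 1.5),
                               small_scene(noise_sd = 0, texture_amp = 0),
                               seed = 5)
    green <- img$pixels[, , 2]
    mean(green[img$truth_stain_mask])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("stain area is proportional to applied volume", {
  sc <- small_scene(size = 128)
  sponge_px <- with(sc$sponge_box,
                    (row_end - row_start) * (col_end - col_start))
  for (v in c(0.5, 1.0, 2.0)) {
    img <- render_sponge_image(blood_sample(100, v), sc, seed = 9)
    expect_equal(sum(img$truth_stain_mask) / sponge_px,
                 v * sc$spread_frac_per_ml, tolerance = 0.01)
  }
})

test_that("simulated batches respect ranges and conserve mass", {
  sim <- simulate_sponges(25, scene = small_scene(size = 48), seed = 21)
  m <- sim$manifest
  expect_equal(nrow(m), 25)
  expect_length(sim$images, 25)
  expect_true(all(m$concentration_g_per_L >= 50 &
                    m$concentration_g_per_L <= 170))
  expect_equal(m$hb_mass_mg, m$concentration_g_per_L * m$volume_mL)
})

test_that("generate_dataset writes images, manifest and XML deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man1 <- generate_dataset(10, d1, scene = small_scene(size = 48), seed = 2,
                           write_xml = TRUE)
  generate_dataset(10, d2, scene = small_scene(size = 48), seed = 2)
  expect_length(list.files(d1, pattern = "\\.png$"), 10)
  expect_length(list.files(d1, pattern = "\\.xml$"), 10)
  expect_equal(nrow(man1), 10)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # written PNG round-trips to the rendered pixels
  px <- round(png::readPNG(file.path(d1, "sponge_0003.png")) * 255)
  img <- render_sponge_image(
    blood_sample(man1$concentration_g_per_L[3], man1$volume_mL[3]),
    small_scene(size = 48), man1$seed[3])
  expect_equal(as.vector(px), as.vector(img$pixels))
})
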
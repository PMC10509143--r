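test_that("bounding boxes enforce the half-open convention", {
  b <- bounding_box(0, 10, 5, 20)
  expect_s3_class(b, "bounding_box")
  expect_error(bounding_box(10, 10, 0, 5), "row_start")
  expect_error(bounding_box(0, 10, 7, 3), "col_start")
  expect_error(bounding_box(-1, 10, 0, 5), "non-negative")
})

test_that("box_iou matches hand-computed overlaps", {
  a <- bounding_box(0, 10, 0, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bounding_box(10, 20, 10, 20)), 0)
  # 5x10 overlap over union 100 + 100 - 50
  expect_equal(box_iou(a, bounding_box(5, 15, 0, 10)), 50 / 150)
})

test_that("detector recovers the true sponge box on synthetic scenes", {
  img <- render_fixture(seed = 31)
  box <- detect_sponge_region(img$pixels, small_scene()$background_color)
  expect_gte(box_iou(box, img$truth_sponge_box), 0.9)
})

test_that("detector fails informatively on a background-only image", {
  sc <- small_scene()
  flat <- array(rep(sc$background_color, each = 48 * 48), c(48, 48, 3))
  expect_error(detect_sponge_region(flat * 255, sc$background_color),
               "no sponge found")
})

test_that("a sponge filling the frame is detected as the full frame", {
  sc <- small_scene()
  full <- array(rep(sc$sponge_base_color, each = 40 * 40), c(40, 40, 3))
  box <- detect_sponge_region(full * 255, sc$background_color)
  expect_equal(unclass(box)[c("row_start", "row_end", "col_start", "col_end")],
               list(row_start = 0L, row_end = 40L, col_start = 0L,
                    col_end = 40L))
})

test_that("speck-sized foreground components are ignored", {
  sc <- small_scene()
  img <- array(rep(sc$background_color, each = 100 * 100), c(100, 100, 3))
  img[50:80, 40:90, ] <- rep(sc$sponge_base_color, each = 31 * 51)
  img[5, 5, ] <- c(1, 0, 0)  # single hot pixel, below the area floor
  box <- detect_sponge_region(img * 255, sc$background_color)
  expect_equal(box$row_start, 49L)
  expect_equal(box$col_start, 39L)
})

test_that("crop returns the half-open sub-array and is idempotent", {
  img <- array(seq_len(30 * 40 * 3), c(30, 40, 3))
  cr <- crop(img, bounding_box(10, 20, 30, 40))
  expect_equal(dim(cr), c(10L, 10L, 3L))
  full <- crop(img, bounding_box(0, 30, 0, 40))
  expect_identical(full, img)
  expect_identical(crop(full, bounding_box(0, 30, 0, 40)), img)
  expect_error(crop(img, bounding_box(0, 31, 0, 40)), "exceeds")
})

test_that("detect -> crop -> detect returns roughly the full crop frame", {
  img <- render_fixture(seed = 55)
  sc <- small_scene()
  box1 <- detect_sponge_region(img$pixels, sc$background_color)
  cr <- crop(img$pixels, box1)
  box2 <- detect_sponge_region(cr, sc$background_color)
  frame <- bounding_box(0, dim(cr)[1], 0, dim(cr)[2])
  expect_gte(box_iou(box2, frame), 0.95)
})

test_that("VOC XML annotations round-trip bit-exactly", {
  ann <- annotation("sponge_0001.png",
                    list(list(label = "sponge",
                              box = bounding_box(49, 450, 99, 500))),
                    width = 512L, height = 512L)
  path <- withr::local_tempfile(fileext = ".xml")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_identical(back$boxes[[1]]$box, ann$boxes[[1]]$box)
  expect_identical(back$boxes[[1]]$label, "sponge")
  expect_identical(back$image_filename, "sponge_0001.png")
  expect_identical(back$width, 512L)
})

test_that("VOC 1-based inclusive coordinates convert to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>img.png</filename>",
    "<size><width>10</width><height>10</height><depth>3</depth></size>",
    "<object><name>sponge</name>",
    "<bndbox><xmin>1</xmin><ymin>1</ymin><xmax>10</xmax><ymax>10</ymax></bndbox>",
    "</object></annotation>"), path)
  ann <- read_annotation(path)
  b <- ann$boxes[[1]]$box
  expect_equal(c(b$row_start, b$row_end, b$col_start, b$col_end),
               c(0L, 10L, 0L, 10L))
})

test_that("inverted or incomplete bndbox coordinates are parse errors", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>img.png</filename><object><name>s</name>",
    "<bndbox><xmin>10</xmin><ymin>1</ymin><xmax>5</xmax><ymax>10</ymax></bndbox>",
    "</object></annotation>"), path)
  expect_error(read_annotation(path), "xmax")
  writeLines(c(
    "<annotation><filename>img.png</filename><object><name>s</name>",
    "<bndbox><xmin>1</xmin><ymin>1</ymin><ymax>10</ymax></bndbox>",
    "</object></annotation>"), path)
  expect_error(read_annotation(path), "xmax")
})
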
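test_that("config validation and tiny preset defaults hold", {
  cfg <- regressor_config(variant = "tiny")
  expect_equal(cfg$input_size, 64L)
  expect_equal(cfg$epochs, 30L)
  full <- regressor_config()
  expect_equal(full$input_size, 224L)
  expect_equal(full$batch_size, 16L)
  expect_equal(full$learning_rate, 1e-3)
  expect_equal(full$epochs, 1000L)
  expect_equal(full$se_reduction, 8L)
  expect_error(regressor_config(input_size = 16), "input_size")
  expect_error(regressor_config(batch_size = 0), "batch_size")
  expect_error(build_regressor("vgg"), "should be one of")
})

test_that("tiny and full variants map image batches to one scalar each", {
  tiny <- build_regressor("se_resnet", regressor_config(variant = "tiny"))
  x <- array(runif(3 * 64 * 64 * 4), c(3, 64, 64, 4))
  fw <- net_forward(tiny, x)
  expect_length(fw$pred, 4)
  expect_true(all(is.finite(fw$pred)))

  full <- build_regressor("resnet", regressor_config())
  xf <- array(runif(3 * 224 * 224 * 2), c(3, 224, 224, 2))
  fwf <- net_forward(full, xf)
  expect_length(fwf$pred, 2)
  expect_true(all(is.finite(fwf$pred)))
})

test_that("SE bottleneck widths equal gated channels / 8 throughout", {
  m <- build_regressor("se_resnet",
                       regressor_config(variant = "tiny", se_reduction = 8))
  for (blk in m$arch$blocks) {
    w1 <- m$params[[paste0(blk$name, ".se.w1")]]
    expect_equal(nrow(w1), blk$cout / 8)
    expect_equal(ncol(w1), blk$cout)
  }
  mf <- build_regressor("se_resnet", regressor_config())
  w1 <- mf$params[["s4b3.se.w1"]]
  expect_equal(dim(w1), c(2048L / 8L, 2048L))
  expect_error(build_regressor("se_resnet",
                               regressor_config(variant = "tiny",
                                                se_reduction = 24)),
               "does not divide")
})

test_that("SE block squeezes, gates in (0,1), and can be forced to identity", {
  set.seed(5)
  x <- array(runif(6 * 6 * 16), c(6, 6, 16))
  res <- se_block(x, r = 8)
  expect_true(all(res$gates > 0 & res$gates < 1))
  expect_equal(res$squeeze, apply(x, 3, mean))
  expect_true(all(abs(res$output) <= abs(x)))

  # constant-per-channel input: squeeze returns those constants
  xc <- array(rep(1:16, each = 36), c(6, 6, 16))
  expect_equal(se_block(xc, r = 8)$squeeze, as.numeric(1:16))

  # zero excitation weights, zero bias -> every gate exactly 0.5
  w <- list(w1 = matrix(0, 2, 16), b1 = numeric(2),
            w2 = matrix(0, 16, 2), b2 = numeric(16))
  half <- se_block(x, r = 8, weights = w)
  expect_equal(half$gates, rep(0.5, 16))
  expect_equal(half$output, x * 0.5)

  # large positive output bias -> gates ~ 1, output ~ input
  w$b2 <- rep(40, 16)
  ident <- se_block(x, r = 8, weights = w)
  expect_equal(ident$output, x, tolerance = 1e-12)

  expect_error(se_block(x, r = 5), "not divisible")
})

test_that("analytic gradients match finite differences on a tiny net", {
  cfg <- regressor_config(variant = "tiny", input_size = 32, seed = 9)
  m <- build_regressor("se_resnet", cfg)
  set.seed(10)
  x <- array(runif(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  y <- c(0.3, 0.8)
  loss_of <- function(model) {
    fw <- net_forward(model, x, training = TRUE, keep_cache = TRUE)
    err <- fw$pred - y
    list(loss = mean(err^2) + mean(abs(err)), fw = fw, err = err)
  }
  l0 <- loss_of(m)
  dpred <- 2 * l0$err / 2 + sign(l0$err) / 2
  grads <- net_backward(m, l0$fw$caches, dpred)
  eps <- 1e-6
  for (nm in c("stem.W", "s2b1.conv1.W", "s3b1.se.w2", "s1b1.conv2.gamma",
               "head.W")) {
    idx <- sample(length(m$params[[nm]]), 3)
    for (j in idx) {
      mp <- m; mp$params[[nm]][j] <- mp$params[[nm]][j] + eps
      mm <- m; mm$params[[nm]][j] <- mm$params[[nm]][j] - eps
      g_num <- (loss_of(mp)$loss - loss_of(mm)$loss) / (2 * eps)
      g_an <- grads[[nm]][j]
      expect_lt(abs(g_an - g_num) / (abs(g_an) + abs(g_num) + 1e-6), 1e-4)
    }
  }
})

test_that("the composite loss equals MSE + lambda * L1 recomputed", {
  cfg <- regressor_config(variant = "tiny", input_size = 32, epochs = 1,
                          batch_size = 64, seed = 3)
  m <- build_regressor("resnet", cfg)
  set.seed(4)
  imgs <- lapply(1:8, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  masses <- runif(8, 50, 300)
  tr <- train_hb_cnn(m, imgs, masses)
  # single whole-dataset batch: recompute the recorded epoch loss from the
  # pre-update forward pass by replaying with the same seed stream
  m2 <- build_regressor("resnet", cfg)
  x <- hbloss:::prepare_batch(imgs, 32)
  with_seed <- hbloss:::with_seed
  pred <- with_seed(cfg$seed + 1L, {
    perm <- sample.int(8)  # same shuffle as the training loop
    fw <- hbloss:::net_forward(m2, x[, , , perm, drop = FALSE],
                               training = TRUE, keep_cache = TRUE)
    list(p = fw$pred, perm = perm)
  })
  err <- pred$p - masses[pred$perm] / cfg$target_scale
  expect_equal(tr$history$loss[1], mean(err^2) + mean(abs(err)),
               tolerance = 1e-6)
})

test_that("training reduces the loss and is seed-reproducible", {
  sc <- small_scene(size = 48, noise_sd = 0)
  sim <- simulate_sponges(40, scene = sc, seed = 31)
  crops <- lapply(sim$images, function(im) {
    crop(im$pixels, im$truth_sponge_box)
  })
  cfg <- regressor_config(variant = "tiny", input_size = 32, epochs = 6,
                          seed = 8)
  m1 <- train_hb_cnn(build_regressor("se_resnet", cfg), crops,
                     sim$manifest$hb_mass_mg)
  expect_lt(m1$history$loss[6], m1$history$loss[1])
  m2 <- train_hb_cnn(build_regressor("se_resnet", cfg), crops,
                     sim$manifest$hb_mass_mg)
  expect_identical(m1$history, m2$history)

  # inference is a pure, order-preserving function
  p1 <- predict(m1, crops[1:5])
  expect_equal(p1[3], predict(m1, crops[[3]]), tolerance = 1e-12)
  expect_equal(rev(p1), predict(m1, rev(crops[1:5])), tolerance = 1e-12)
  expect_identical(predict(m1, crops[1:5]), p1)
  expect_true(all(is.finite(p1)))
  expect_true(all(predict(m1, crops[1:5], clamp = TRUE) >= 0))

  untrained <- build_regressor("se_resnet", cfg)
  expect_error(predict(untrained, crops[[1]]), "not been trained")
  expect_error(train_hb_cnn(m1, list(), numeric(0)), "empty")
})

test_that("models survive a save/load round trip", {
  cfg <- regressor_config(variant = "tiny", input_size = 32, epochs = 2,
                          seed = 2)
  imgs <- lapply(1:6, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  m <- train_hb_cnn(build_regressor("resnet", cfg), imgs, runif(6, 50, 300))
  path <- withr::local_tempfile(fileext = ".rds")
  save_hb_cnn(m, path)
  back <- load_hb_cnn(path)
  expect_identical(predict(back, imgs), predict(m, imgs))
})
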
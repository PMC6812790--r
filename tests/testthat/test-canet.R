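test_that("branch geometry matches the published architecture arithmetic", {
  cfg <- canet_config()  # full-size: 24/24/48 kernels, N = 64
  sh <- flightcall:::canet_shapes(cfg)
  # two 4x pools downsample the 104-frame clip 16x in time:
  # 104 -> 100 (conv) -> 25 (pool) -> 21 (conv) -> 5 (pool) -> 1 (conv)
  expect_equal(sh$p1, c(25, 62))
  expect_equal(sh$p2, c(5, 29))
  expect_equal(sh$c3, c(1, 25))
  expect_equal(sh$flat, 1200)
  # auxiliary conv stage: 9 quantile positions x 8 kernels = 72 activations
  mdl <- canet_init(canet_config("at"), seed = 1)
  expect_equal(dim(mdl$params$Wa2), c(72, 64))
})

test_that("zero clips and zero slices map to zero embeddings", {
  mdl <- canet_init(tiny_config("at"), seed = 4)
  z <- forward_main(mdl, array(0, dim = c(104, 128, 1, 2)))
  expect_true(all(z == 0))  # zero-initialized biases
  za <- forward_aux(mdl, array(0, dim = c(9, 32, 2)))
  expect_true(all(za == 0))
  expect_true(all(forward_main(mdl, matrix(0.5, 104, 128)) >= 0))
  expect_error(forward_main(mdl, array(0, dim = c(50, 128, 1, 1))), "shape")
  expect_error(forward_aux(mdl, array(0, dim = c(5, 32, 1))), "slice")
})

test_that("forward passes are deterministic and functionally pure", {
  mdl <- canet_init(tiny_config("aw"), seed = 5)
  set.seed(99)
  clip <- array(rnorm(104 * 128), dim = c(104, 128, 1, 1))
  expect_identical(forward_main(mdl, clip), forward_main(mdl, clip))
  sl <- matrix(rnorm(9 * 32), 9, 32)
  expect_identical(forward_aux(mdl, sl), forward_aux(mdl, sl + 0))
})

test_that("training-path and inference-path activations agree exactly", {
  for (form in c("baseline", "moe")) {
    mdl <- canet_init(tiny_config(form), seed = 6)
    set.seed(42)
    clips <- array(rnorm(104 * 128 * 3), dim = c(104, 128, 1, 3))
    expect_equal(flightcall:::forward_main_infer(mdl, clips),
                 flightcall:::forward_main_internal(mdl, clips)$z)
  }
})

test_that("all merge formulations output 0.5 at zero parameters and inputs", {
  for (form in c("baseline", "aw", "at", "moe")) {
    mdl <- canet_init(tiny_config(form), seed = 2)
    for (nm in names(mdl$params)) mdl$params[[nm]][] <- 0
    y <- merge_output(mdl, numeric(8), numeric(8))
    expect_equal(y, 0.5)
  }
  mdl <- canet_init(tiny_config("at"), seed = 2)
  expect_error(merge_output(mdl, numeric(8)), "z_aux")
})

test_that("merge outputs lie strictly inside (0, 1)", {
  set.seed(13)
  for (form in c("baseline", "aw", "at", "moe")) {
    mdl <- canet_init(tiny_config(form), seed = 3)
    y <- merge_output(mdl, matrix(abs(rnorm(8 * 50)), 8),
                      matrix(abs(rnorm(8 * 50)), 8))
    expect_true(all(y > 0 & y < 1))
  }
})

test_that("MoE gates form a flat histogram when the aux projection is zero", {
  mdl <- canet_init(tiny_config("moe"), seed = 9)
  mdl$params$w_aux_m[] <- 0
  mdl$params$b_aux <- rep(1.3, 4)
  mf <- flightcall:::merge_forward(mdl, matrix(abs(rnorm(8 * 5)), 8),
                                   matrix(abs(rnorm(8 * 5)), 8))
  expect_equal(mf$cache$gates, matrix(0.25, 4, 5))
})

test_that("MoE gates sum to one and are permutation-equivariant in k", {
  set.seed(21)
  mdl <- canet_init(tiny_config("moe"), seed = 10)
  z <- matrix(abs(rnorm(8 * 6)), 8)
  za <- matrix(abs(rnorm(8 * 6)), 8)
  mf <- flightcall:::merge_forward(mdl, z, za)
  expect_equal(colSums(mf$cache$gates), rep(1, 6))
  # permute the experts: with K = 4, M = 2, index n = K*m + k, so expert k
  # owns code components {k+1, k+1+K}; permute params and codes coherently
  perm <- c(3, 1, 4, 2)
  reidx <- as.vector(outer(perm, c(0, 4), `+`))
  m2 <- mdl
  m2$params$w <- mdl$params$w[reidx]
  m2$params$w_aux_m <- mdl$params$w_aux_m[, perm]
  m2$params$b_aux <- mdl$params$b_aux[perm]
  mf2 <- flightcall:::merge_forward(m2, z[reidx, ], za[reidx, ])
  expect_equal(mf2$cache$gates, mf$cache$gates[perm, ])
  expect_equal(mf2$u, mf$u)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  clips <- array(rnorm(104 * 128 * 2), dim = c(104, 128, 1, 2))
  slices <- array(rnorm(9 * 32 * 2), dim = c(9, 32, 2))
  y_true <- c(1, 0)
  for (form in c("baseline", "aw", "at", "moe")) {
    mdl <- canet_init(tiny_config(form), seed = 7)
    lg <- flightcall:::canet_loss_grad(mdl, clips, slices, y_true)
    worst <- 0
    for (nm in names(mdl$params)) {
      p <- mdl$params[[nm]]
      for (ci in sample(length(p), min(4, length(p)))) {
        h <- 1e-5 * max(1, abs(p[ci]))
        m2 <- mdl
        m2$params[[nm]][ci] <- p[ci] + h
        lp <- flightcall:::canet_loss_grad(m2, clips, slices, y_true)$loss
        m2$params[[nm]][ci] <- p[ci] - h
        lm <- flightcall:::canet_loss_grad(m2, clips, slices, y_true)$loss
        fd <- (lp - lm) / (2 * h)
        an <- lg$grads[[nm]][ci]
        worst <- max(worst, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("classification accuracy uses the strict |y - y_true| < 0.5 rule", {
  expect_equal(classification_accuracy(c(0.9, 0.2, 0.6), c(1, 0, 0)), 2 / 3)
  expect_equal(classification_accuracy(c(1, 0), c(1, 0)), 1)
  expect_equal(classification_accuracy(rep(0.5, 4), c(0, 1, 0, 1)), 0)
  expect_error(classification_accuracy(c(0.1), c(0, 1)), "length")
})

test_that("a small model overfits a separable toy set", {
  set.seed(5)
  B <- 32
  clips <- array(abs(rnorm(104 * 128 * B, sd = 0.1)), dim = c(104, 128, 1, B))
  lab <- rep(c(0, 1), each = B / 2)
  for (i in which(lab == 1)) {
    clips[40:60, 50:70, 1, i] <- clips[40:60, 50:70, 1, i] + 2
  }
  db <- clip_batch(clips, lab, sensor_ids = rep("s1", B))
  cfg <- canet_config("baseline", conv_channels = c(4, 4, 8), n_hidden = 16)
  tm <- canet_train(canet_init(cfg, seed = 2), db, epochs = 30,
                    batch_size = 8, seed = 9)
  expect_gte(utils::tail(tm$history$train_acc, 1), 0.95)
})

test_that("training is reproducible and enforces the sensor-split contract", {
  set.seed(6)
  B <- 16
  clips <- array(rnorm(104 * 128 * B, sd = 0.1), dim = c(104, 128, 1, B))
  db <- clip_batch(clips, rep(0:1, B / 2), sensor_ids = rep("s1", B))
  cfg <- canet_config("baseline", conv_channels = c(3, 3, 4), n_hidden = 8)
  t1 <- canet_train(canet_init(cfg, seed = 3), db, epochs = 3, seed = 11)
  t2 <- canet_train(canet_init(cfg, seed = 3), db, epochs = 3, seed = 11)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
  db_val <- clip_batch(clips[, , , 1:4, drop = FALSE], rep(0:1, 2),
                       sensor_ids = rep("s1", 4))
  expect_error(canet_train(canet_init(cfg, seed = 3), db,
                           validation = db_val, epochs = 1),
               "intersect")
  expect_error(clip_batch(clips, rep(2, B)), "binary")
})

test_that("checkpoints round-trip through save_model / load_model", {
  mdl <- canet_init(tiny_config("at"), seed = 8,
                    frontend = list(representation = "pcen",
                                    stft = stft_config(),
                                    pcen = pcen_params("outdoor")))
  path <- tempfile(fileext = ".rds")
  save_model(mdl, path)
  back <- load_model(path)
  expect_identical(back$params, mdl$params)
  expect_equal(back$frontend$pcen$alpha, 0.8)
  unlink(path)
})
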
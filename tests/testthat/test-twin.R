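test_that("twin configuration validates its invariants", {
  expect_s3_class(twin_config(), "twin_config")
  expect_equal(twin_config("twin_nn")$batch_size, 32L)
  expect_equal(twin_config("twin_dn")$batch_size, 8L)
  expect_error(twin_config(margin = 0), "margin")
  expect_error(twin_config(embedding_dim = 0), "embedding_dim")
  expect_error(twin_config(norm_lo = 10, norm_hi = 5), "norm_hi")
})

test_that("contrastive loss matches its closed forms", {
  # matched pair at identical embeddings
  expect_equal(contrastive_loss(c(1, 2), c(1, 2), "same"), 0, tolerance = 1e-12)
  # mismatched pair beyond the margin
  y <- c(0.7, 0); expect_equal(contrastive_loss(y, c(0, 0), "different", 0.5), 0,
                               tolerance = 1e-12)
  # mismatched pair inside the margin: 0.5 * (0.5 - 0.3)^2 = 0.02
  expect_equal(contrastive_loss(c(0.3, 0), c(0, 0), "different", 0.5), 0.02,
               tolerance = 1e-12)
  # batch loss is the mean over pairs
  y1 <- rbind(c(1, 0), c(0.3, 0)); y2 <- rbind(c(1, 0), c(0, 0))
  expect_equal(contrastive_loss(y1, y2, c("same", "different"), 0.5), 0.01)
  expect_error(contrastive_loss(1:3, 1:2, "same"), "dimensions differ")
  expect_error(contrastive_loss(1:2, 1:2, "positive"), "same")
})

test_that("analytic loss gradient matches central finite differences", {
  eps <- 1e-6
  withr::with_seed(42, {
    for (rep in seq_len(50)) {
      d <- sample(2:6, 1)
      y1 <- matrix(stats::rnorm(d), 1)
      y2 <- matrix(stats::rnorm(d), 1)
      label <- sample(c("same", "different"), 1)
      g <- contrastive_loss_grad(y1, y2, label, 0.5)
      for (k in seq_len(d)) {
        up <- y1; up[k] <- up[k] + eps
        dn <- y1; dn[k] <- dn[k] - eps
        fd <- (contrastive_loss(up, y2, label, 0.5) -
                 contrastive_loss(dn, y2, label, 0.5)) / (2 * eps)
        denom <- max(abs(fd), abs(g$dy1[k]), 1e-8)
        expect_lt(abs(fd - g$dy1[k]) / denom, 1e-4)
      }
    }
  })
})

test_that("full network gradients agree with finite differences", {
  cfg <- twin_config("twin_nn", input_length = 12, hidden_widths = c(7, 5),
                     embedding_dim = 3, seed = 8)
  model <- build_twin_model(cfg)
  layers <- model$layers
  withr::with_seed(9, {
    X <- matrix(stats::rnorm(8 * 12), 8, 12)
    labels <- rep(c("same", "different"), 2)
  })
  loss_at <- function(layers) {
    fwd <- twinphen:::nn_forward(layers, X, training = TRUE)
    y1 <- fwd$out[1:4, , drop = FALSE]; y2 <- fwd$out[5:8, , drop = FALSE]
    contrastive_loss(y1, y2, labels, 0.5)
  }
  fwd <- twinphen:::nn_forward(layers, X, training = TRUE)
  g <- contrastive_loss_grad(fwd$out[1:4, , drop = FALSE],
                             fwd$out[5:8, , drop = FALSE], labels, 0.5)
  grads <- twinphen:::nn_backward(layers, fwd, X, rbind(g$dy1, g$dy2))
  eps <- 1e-5
  withr::with_seed(10, {
    for (k in seq_along(layers)) {
      for (f in intersect(c("W", "b", "gamma", "beta"), names(grads[[k]]))) {
        for (probe in 1:3) {
          idx <- sample(length(layers[[k]][[f]]), 1)
          up <- layers; up[[k]][[f]][idx] <- up[[k]][[f]][idx] + eps
          dn <- layers; dn[[k]][[f]][idx] <- dn[[k]][[f]][idx] - eps
          fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
          an <- grads[[k]][[f]][idx]
          expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-3)
        }
      }
    }
  })
})

test_that("twin_nn builds the documented layer stack", {
  # full-scale architecture shapes, computed without allocating parameters
  expect_equal(twin_layer_shapes(twin_config()),
               c(20250, 4000, 500, 250, 100, 10))
  cfg <- twin_config("twin_nn", input_length = 1000,
                     hidden_widths = c(200, 100, 50, 20), embedding_dim = 10)
  model <- build_twin_model(cfg)
  expect_length(model$layers, 5)            # five linear maps over six sizes
  dims <- vapply(model$layers, function(l) dim(l$W), integer(2))
  expect_equal(dims[1, ], c(1000, 200, 100, 50, 20))
  expect_equal(dims[2, ], c(200, 100, 50, 20, 10))
  # batch norm + ReLU everywhere except the final linear layer
  expect_true(all(vapply(model$layers[-5], `[[`, TRUE, "bn")))
  expect_false(model$layers[[5]]$bn)
  expect_false(model$layers[[5]]$relu)
})

test_that("twin_dn uses dense connectivity and ends at the embedding", {
  cfg <- twin_config("twin_dn", input_length = 300, embedding_dim = 10)
  model <- build_twin_model(cfg)
  shapes <- twin_layer_shapes(cfg)
  expect_equal(shapes$n_out[nrow(shapes)], 10)
  last <- model$layers[[length(model$layers)]]
  expect_equal(ncol(last$W), 10)
  # a dense-block layer consumes the concatenation of all previous outputs
  spec <- cfg$dense_block_spec
  b1_last <- model$layers[[1 + spec$layers_per_block]]
  expect_length(b1_last$inputs, spec$layers_per_block)
  # forward works at both batch sizes
  X <- matrix(stats::rnorm(6 * 300), 6, 300)
  out <- twinphen:::nn_forward(model$layers, X, training = TRUE)$out
  expect_equal(dim(out), c(6L, 10L))
})

test_that("training learns a well-separated screen quickly", {
  h <- tiny_model()$history
  expect_gte(max(h$val_auroc), 0.95)
  # monotone learning: the train loss ends below where it starts
  expect_lte(stats::median(utils::tail(h$train_loss, 5)),
             stats::median(utils::head(h$train_loss, 5)))
})

test_that("the learned distance is a symmetric pseudometric with zero self-distance", {
  model <- tiny_model()
  ds <- tiny_screen()$dataset
  a <- ds$traces[1, ]; b <- ds$traces[50, ]
  expect_equal(learned_distance(model, a, a), 0, tolerance = 1e-10)
  expect_equal(learned_distance(model, a, b), learned_distance(model, b, a))
  expect_gte(learned_distance(model, a, b), 0)
  # weight sharing: both branches embed identically
  expect_equal(twin_embed(model, a), twin_embed(model, b - b + a))
})

test_that("same-drug distances fall below the margin, mismatches above", {
  model <- tiny_model()
  ds <- tiny_screen()$dataset
  gt <- tiny_screen()$ground_truth
  margin <- model$config$margin
  dw <- which(ds$wells$role == "drug")
  E <- twin_embed(model, ds$traces[dw, ])
  tr <- ds$wells$treatment_id[dw]
  combos <- t(utils::combn(seq_along(dw), 2))
  d <- sqrt(rowSums((E[combos[, 1], ] - E[combos[, 2], ])^2))
  same <- tr[combos[, 1]] == tr[combos[, 2]]
  cls <- gt$class_of_drug
  diff_class <- cls[tr[combos[, 1]]] != cls[tr[combos[, 2]]]
  expect_lt(stats::median(d[same]), margin)
  expect_gt(stats::median(d[diff_class]), margin)
})

test_that("training is deterministic and checkpoints restore exactly", {
  model <- tiny_model()
  ds <- tiny_screen()$dataset
  path <- withr::local_tempfile(fileext = ".rds")
  save_twin_model(model, path)
  restored <- load_twin_model(path)
  expect_identical(learned_distance(restored, ds$traces[1, ], ds$traces[2, ]),
                   learned_distance(model, ds$traces[1, ], ds$traces[2, ]))
  expect_error(twin_embed(build_twin_model(model$config), ds$traces[1, ]),
               "untrained")
})

test_that("shuffled pair labels leave no learnable signal on the tiny screen", {
  rep <- label_shuffle_test(tiny_pairs(), tiny_screen()$dataset$traces,
                            reduced_twin_config(seed = 56, max_epochs = 20),
                            seed = 56)
  expect_lt(abs(rep$perturbed_auroc - 0.5), 0.1)
})
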
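test_that("roc_auc ranks matched pairs by small distance", {
  # perfect separation
  expect_equal(roc_auc(c(.1, .2, .8, .9), c("same", "same", "different", "different"))$auc, 1)
  # random labels hover at chance
  withr::with_seed(31, {
    d <- stats::runif(1000)
    lab <- sample(c("same", "different"), 1000, replace = TRUE)
  })
  expect_lt(abs(roc_auc(d, lab)$auc - 0.5), 0.07)
  expect_error(roc_auc(1:3, rep("same", 3)), "both")
})

test_that("roc_auc equals the brute-force comparison oracle, ties included", {
  withr::with_seed(33, {
    for (rep in seq_len(20)) {
      n <- sample(20:500, 1)
      d <- round(stats::runif(n), sample(1:3, 1))   # induce ties
      lab <- sample(c("same", "different"), n, replace = TRUE,
                    prob = c(0.4, 0.6))
      if (length(unique(lab)) < 2) lab[1:2] <- c("same", "different")
      expect_equal(roc_auc(d, lab)$auc, roc_oracle(d, lab), tolerance = 1e-12)
    }
  })
})

test_that("prc_auc integrates the step-interpolated precision-recall curve", {
  expect_equal(prc_auc(c(.1, .2, .8, .9), c("same", "same", "different", "different"))$auc, 1)
  # random scores, balanced classes: near the prevalence baseline
  withr::with_seed(35, {
    d <- stats::runif(2000)
    lab <- rep(c("same", "different"), 1000)
  })
  res <- prc_auc(d, lab)
  expect_equal(res$baseline, 0.5)
  expect_lt(abs(res$auc - 0.5), 0.07)
  # hand-computed five-positive/five-negative example:
  # distances 1..10, positives at ranks 1,2,4,6,7
  d10 <- 1:10
  lab10 <- c("same", "same", "different", "same", "different",
             "same", "same", "different", "different", "different")
  # step area: sum over positives of (1/5) * precision at that recall
  prec <- c(1 / 1, 2 / 2, 3 / 4, 4 / 6, 5 / 7)
  expect_equal(prc_auc(d10, lab10)$auc, sum(0.2 * prec))
})

test_that("kNN classification recovers reference drugs under correlation distance", {
  qc <- generate_screen(sim_config(n_drugs = 16, replicates_per_drug = 10,
                                   inactive_fraction = 0, n_phenotype_classes = 16,
                                   class_separation = 3, noise_scale = 20,
                                   rep_gain_sd = 0.1, shift_frac = 0.006,
                                   seed = 99))$dataset
  dw <- which(qc$wells$role == "drug")
  D <- pairwise_distance_matrix(qc$traces[dw, ], correlation_distance)
  res <- knn_classify(D, qc$wells$treatment_id[dw], k = 15, seed = 99)
  expect_gte(res$overall, 0.9)
  expect_length(res$per_drug, 16)
  expect_error(knn_classify(D, qc$wells$treatment_id[dw], k = 1000), "exceeds")
})

test_that("kNN at k = 1 follows the duplicated training well and ties break by distance", {
  # validation wells duplicate one training well of their own drug
  X <- rbind(c(0, 0), c(0, 0.1), c(5, 5), c(5, 5.1), c(0, 0), c(5, 5))
  labs <- c("a", "a", "b", "b", "a", "b")
  D <- pairwise_distance_matrix(X, euclidean_distance)
  res <- knn_classify(D, labs, k = 1, n_train = 2, n_val = 1, seed = 1)
  expect_equal(res$overall, 1)

  # two-way tie at k = 2: both drugs contribute one neighbor; the drug with
  # the smaller summed distance wins. Drug "a" wells are identical, so the
  # validation well sits at distance 0 from its own drug and the tied vote
  # resolves toward "a" for every split.
  D2 <- matrix(c(0, 0, 5, 9,
                 0, 0, 5, 9,
                 5, 5, 0, 9,
                 9, 9, 9, 0), 4, 4, byrow = TRUE)
  labs2 <- c("a", "a", "b", "b")
  res2 <- knn_classify(D2, labs2, k = 2, n_train = 1, n_val = 1, seed = 3)
  expect_equal(unname(res2$per_drug["a"]), 1)
})

test_that("replicate identification counts same-drug wells in the top ranks", {
  # 1 drug with 8 identical replicates among far-away distinct wells
  n <- 30
  X <- matrix(stats::rnorm(n * 4, 50, 1), n, 4)
  X[1:8, ] <- matrix(rep(c(0, 0, 0, 0), each = 8), 8)
  wells <- data.frame(well_id = paste0("w", 1:n),
                      treatment_id = c(rep("drugA", 8),
                                       paste0("drug_", 9:n)),
                      role = "drug")
  D <- pairwise_distance_matrix(X, euclidean_distance)
  curve <- replicate_identification(D, wells, top_n = 10)
  per_drug <- attr(curve, "per_drug")
  expect_equal(unname(per_drug["drugA"]), 7)   # self excluded
  # curve is non-increasing in k
  expect_true(all(diff(curve$n_drugs) <= 0))
  expect_error(replicate_identification(D, wells, top_n = n), "below")
})

test_that("mean traces per compound are element-wise means", {
  ds <- tiny_screen()$dataset
  mt <- mean_traces_by_drug(ds)
  d1 <- which(ds$wells$treatment_id == rownames(mt)[1])
  expect_equal(mt[1, ], colMeans(ds$traces[d1, ]))
})

test_that("behaviorome maps place identical compounds together", {
  X <- rbind(a = sin(1:40), b = sin(1:40), c = cos(1:40) * 3 + 2,
             d = stats::rnorm(40), e = stats::rnorm(40), f = stats::rnorm(40))
  coords <- behaviorome_map(X, metric = euclidean_distance, n_neighbors = 3)
  expect_equal(dim(coords), c(6L, 2L))
  expect_lt(sqrt(sum((coords["a", ] - coords["b", ])^2)), 1e-8)
  expect_error(behaviorome_map(X[1:3, ], n_neighbors = 5), "at least")
})

test_that("the learned metric groups replicate wells that correlation scatters", {
  r <- screen_a()
  ds <- r$dataset; gt <- r$ground_truth
  act <- names(gt$active)[gt$active]
  w <- which(ds$wells$role == "drug" & ds$wells$treatment_id %in% act)
  drug <- ds$wells$treatment_id[w]
  E <- twin_embed(screen_a_model(), ds$traces[w, ])
  rownames(E) <- ds$wells$well_id[w]
  X <- ds$traces[w, ]
  rownames(X) <- ds$wells$well_id[w]
  co_l <- behaviorome_map(E, metric = euclidean_distance, n_neighbors = 10)
  co_c <- suppressWarnings(
    behaviorome_map(X, metric = correlation_distance, n_neighbors = 10))
  sil_l <- twinphen:::silhouette_score(co_l, drug)
  sil_c <- twinphen:::silhouette_score(co_c, drug)
  expect_gt(sil_l, 0)
  expect_gt(sil_l, sil_c)
})
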
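test_that("layouts respect capacity, controls and seeded determinism", {
  expect_error(sim_config(n_drugs = 96), "capacity exceeded")

  cfg <- sim_config(n_drugs = 20, replicates_per_drug = c(7, 10), seed = 3)
  lay <- generate_layout(cfg)
  expect_equal(nrow(lay), cfg$n_plates * 96L)
  expect_false(anyDuplicated(lay[c("plate_id", "row", "col")]) > 0)
  # every plate carries the configured controls
  per_plate <- table(lay$plate_id, lay$role)
  expect_true(all(per_plate[, "lethal"] == cfg$controls_lethal))
  expect_true(all(per_plate[, "vehicle"] >= cfg$controls_vehicle))
  # replicate counts within the configured range
  reps <- table(lay$treatment_id[lay$role == "drug"])
  expect_true(all(reps >= 7 & reps <= 10))
  expect_identical(generate_layout(cfg), generate_layout(cfg))
})

test_that("fixed layouts pin each drug to one plate position", {
  cfg <- sim_config(n_drugs = 24, replicates_per_drug = 8, layout_mode = "fixed",
                    seed = 5)
  lay <- generate_layout(cfg)
  pos_per_drug <- tapply(paste(lay$row, lay$col), lay$treatment_id,
                         function(x) length(unique(x)))
  expect_true(all(pos_per_drug[grep("^drug_", names(pos_per_drug))] == 1))
})

test_that("randomized layouts permute treatments independently per plate", {
  cfg1 <- sim_config(n_drugs = 24, seed = 5)
  cfg2 <- sim_config(n_drugs = 24, seed = 6)
  expect_false(identical(generate_layout(cfg1)$treatment_id,
                         generate_layout(cfg2)$treatment_id))
  # within one seed, plates differ from each other
  lay <- generate_layout(cfg1)
  p1 <- lay$treatment_id[lay$plate_id == "P01"]
  p2 <- lay$treatment_id[lay$plate_id == "P02"]
  expect_false(identical(p1, p2))
})

test_that("randomized drug positions are uniform over wells (chi-square GOF)", {
  cfg <- sim_config(n_drugs = 60, replicates_per_drug = 8, n_plates = 10, seed = 9)
  lay <- generate_layout(cfg)
  drugs <- lay[lay$role == "drug", ]
  # pool position indices over >= 50 drugs; uniformity across the 96 slots
  slot <- drugs$row * 12 + drugs$col
  p <- suppressWarnings(stats::chisq.test(table(factor(slot, 0:95)))$p.value)
  expect_gt(p, 0.01)
})

test_that("generated screens are deterministic and within bounds", {
  cfg <- sim_config(seed = 7)
  r1 <- generate_screen(cfg)
  r2 <- generate_screen(sim_config(seed = 7))
  expect_identical(r1$dataset$traces, r2$dataset$traces)
  expect_true(all(r1$dataset$traces >= 0 & r1$dataset$traces <= cfg$max_mi))
  wells <- r1$dataset$wells
  expect_equal(nrow(wells), cfg$n_plates * 96L)
  # every drug has exactly one class; inactive drugs flagged
  gt <- r1$ground_truth
  expect_setequal(names(gt$class_of_drug), sprintf("drug_%03d", 1:24))
  expect_equal(sum(!gt$active), round(cfg$inactive_fraction * cfg$n_drugs))
})

test_that("lethal-control wells show near-zero motion", {
  r <- screen_a()
  ds <- r$dataset
  lethal_mean <- mean(ds$traces[ds$wells$role == "lethal", ])
  active_drugs <- names(r$ground_truth$active)[r$ground_truth$active]
  active_mean <- mean(ds$traces[ds$wells$treatment_id %in% active_drugs, ])
  expect_lt(lethal_mean, 0.02 * active_mean)
})

test_that("within-drug correlation distance is smaller than between-class", {
  r <- screen_a()
  ds <- r$dataset; gt <- r$ground_truth
  act <- names(gt$active)[gt$active]
  wells_by_drug <- split(seq_len(nrow(ds$wells)),
                         ds$wells$treatment_id)[act]
  withr::with_seed(17, {
    within <- replicate(200, {
      w <- sample(wells_by_drug[[sample(length(wells_by_drug), 1)]], 2)
      correlation_distance(ds$traces[w[1], ], ds$traces[w[2], ])
    })
    between <- replicate(200, {
      dd <- sample(length(wells_by_drug), 2)
      cls <- gt$class_of_drug[names(wells_by_drug)[dd]]
      while (cls[1] == cls[2]) {
        dd <- sample(length(wells_by_drug), 2)
        cls <- gt$class_of_drug[names(wells_by_drug)[dd]]
      }
      correlation_distance(ds$traces[sample(wells_by_drug[[dd[1]]], 1), ],
                           ds$traces[sample(wells_by_drug[[dd[2]]], 1), ])
    })
    expect_lt(mean(within), mean(between))
  })
})

test_that("without a planted artifact, traces are independent of position", {
  ds <- screen_a()$dataset
  keep <- ds$wells$role != "lethal"
  hf <- apply(ds$traces[keep, ], 1, hf_power)
  pos <- ds$wells[keep, c("row", "col")]
  obs <- summary(stats::lm(hf ~ row + col, data = cbind(pos, hf = hf)))$r.squared
  perm <- withr::with_seed(19, {
    replicate(1000, {
      idx <- sample(nrow(pos))
      summary(stats::lm(hf ~ row + col,
                        data = cbind(pos[idx, ], hf = hf)))$r.squared
    })
  })
  p <- (1 + sum(perm >= obs)) / (1 + length(perm))
  expect_gt(p, 0.01)
})

test_that("the planted artifact is position-keyed, removable and optional", {
  cfg <- sim_config(n_drugs = 12, replicates_per_drug = c(7, 8), seed = 13)
  ds <- generate_screen(cfg)$dataset

  # amplitude 0 is the identity, bit for bit
  expect_identical(plant_positional_artifact(ds, 0), ds)

  planted <- plant_positional_artifact(ds, 150)
  # same (row, col) on different plates receives the identical component
  # (compared where neither trace saturates at the clipping bounds)
  w <- which(ds$wells$row == 3 & ds$wells$col == 5)[1:2]
  comp <- planted$traces[w, ] - ds$traces[w, ]
  free <- planted$traces[w[1], ] > 0 & planted$traces[w[2], ] > 0 &
    planted$traces[w[1], ] < ds$config$max_mi &
    planted$traces[w[2], ] < ds$config$max_mi
  expect_gt(mean(free), 0.9)
  expect_equal(comp[1, free], comp[2, free], tolerance = 1e-8)

  # Hanning(11) removes >= 90% of the planted component's power
  x_raw <- planted$traces[w[1], ]
  raw_band <- hf_power(x_raw)
  base_band <- hf_power(ds$traces[w[1], ])
  planted_power <- mean(comp[1, ]^2)
  removed <- raw_band - base_band
  expect_gt(removed, 0.9 * planted_power)
})

test_that("class separability dial monotonically drives correlation AUROC", {
  aucs <- vapply(c(0.3, 1, 2), function(sep) {
    r <- generate_screen(sim_config(n_drugs = 16, replicates_per_drug = 8,
                                    class_separation = sep,
                                    inactive_fraction = 0, seed = 23))
    ds <- r$dataset
    dw <- which(ds$wells$role == "drug")
    dw <- withr::with_seed(23, sample(dw, 60))
    combos <- t(utils::combn(dw, 2))
    labs <- ifelse(ds$wells$treatment_id[combos[, 1]] ==
                     ds$wells$treatment_id[combos[, 2]], "same", "different")
    d <- vapply(seq_len(nrow(combos)), function(i)
      correlation_distance(ds$traces[combos[i, 1], ], ds$traces[combos[i, 2], ]), 0)
    roc_auc(d, labs)$auc
  }, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("synthetic fingerprints form tight families with optional class split", {
  gt <- screen_a()$ground_truth
  fp <- synthetic_fingerprints(gt, split_class = 1, seed = 2)
  fams <- unique(fp$family)
  expect_true(any(grepl("b$", fams)))       # the split family exists
  same_fam <- NULL; cross_fam <- NULL
  ids <- rownames(fp$fingerprints)
  for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    s <- tanimoto(fp$fingerprints[i, ], fp$fingerprints[j, ])
    if (fp$family[i] == fp$family[j]) same_fam <- c(same_fam, s)
    else cross_fam <- c(cross_fam, s)
  }
  expect_gt(min(same_fam), max(cross_fam))  # families are bit-separated
})
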
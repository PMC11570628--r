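# Shared fixtures and independent oracles for the test suite.
#
# The reference screen ("screen A": 24 pseudo-drugs x 8 replicates in 8
# phenotype classes at the default separability, randomized layout, seed 1)
# and the twin model trained on it are built lazily once per session and
# reused across test files.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- builder()
  fixture_cache[[key]]
}

reduced_twin_config <- function(seed, max_epochs = 40, ...) {
  twin_config("twin_nn", input_length = 1000,
              hidden_widths = c(200, 100, 50, 20), embedding_dim = 10,
              max_epochs = max_epochs, patience = max_epochs, seed = seed, ...)
}

screen_a <- function() memo("screen_a", function() {
  generate_screen(sim_config(n_drugs = 24, replicates_per_drug = 8, seed = 1))
})

screen_a_labels <- function() memo("screen_a_labels", function() {
  ds <- screen_a()$dataset
  model <- train_activity_classifier(ds, mode = "binary", seed = 1)
  list(model = model, labels = label_wells(model, ds))
})

screen_a_pairs <- function() memo("screen_a_pairs", function() {
  ds <- screen_a()$dataset
  drugs <- unique(ds$wells$treatment_id[ds$wells$role == "drug"])
  split <- split_by_drug(drugs, seed = 1)
  suppressWarnings(build_pairs(ds, screen_a_labels()$labels, split, seed = 1))
})

screen_a_model <- function() memo("screen_a_model", function() {
  train_twin(reduced_twin_config(seed = 1), screen_a_pairs(),
             screen_a()$dataset$traces)
})

# Held-out pair distances on screen A under a metric function of two traces.
screen_a_test_distances <- function(metric) {
  ds <- screen_a()$dataset
  test <- screen_a_pairs()
  test <- test[test$split == "test", ]
  d <- vapply(seq_len(nrow(test)), function(i)
    metric(ds$traces[test$index_a[i], ], ds$traces[test$index_b[i], ]), 0)
  list(d = d, labels = test$label)
}

# Small screen with one well-separated phenotype class per drug, and the
# twin model trained on it, for fast unit tests of the learned distance.
tiny_screen <- function() memo("tiny_screen", function() {
  generate_screen(sim_config(n_drugs = 10, n_phenotype_classes = 10,
                             replicates_per_drug = 8, inactive_fraction = 0,
                             class_separation = 3, noise_scale = 20,
                             rep_gain_sd = 0.1, amp_scale_sd = 0.1, seed = 55))
})

tiny_pairs <- function() memo("tiny_pairs", function() {
  ds <- tiny_screen()$dataset
  labels <- data.frame(well_id = ds$wells$well_id,
                       label = ifelse(ds$wells$role == "lethal", "lethal",
                                      ifelse(ds$wells$role == "vehicle",
                                             "inactive", "active")))
  drugs <- unique(ds$wells$treatment_id[ds$wells$role == "drug"])
  build_pairs(ds, labels, split_by_drug(drugs, seed = 55), seed = 55)
})

tiny_model <- function() memo("tiny_model", function() {
  train_twin(reduced_twin_config(seed = 55, max_epochs = 20), tiny_pairs(),
             tiny_screen()$dataset$traces)
})

## ---- independent oracles ----

# Per-pixel double-loop motion index.
mi_oracle <- function(frames, threshold = 10) {
  n <- dim(frames)[1L]
  out <- integer(n - 1L)
  for (t in 2:n) {
    count <- 0L
    for (i in seq_len(dim(frames)[2L])) {
      for (j in seq_len(dim(frames)[3L])) {
        if (abs(frames[t, i, j] - frames[t - 1, i, j]) >= threshold)
          count <- count + 1L
      }
    }
    out[t - 1L] <- count
  }
  out
}

# Full dynamic-programming DTW (pure R).
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- abs(a[i] - b[j]) +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  D[n + 1L, m + 1L]
}

# Brute-force Mann-Whitney comparison count (ties count 1/2).
roc_oracle <- function(distances, labels) {
  pos <- distances[labels == "same"]
  neg <- distances[labels == "different"]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p < q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# High-frequency residual power of a trace (energy removed by Hanning(11)).
hf_power <- function(x) mean((x - smooth_hanning(x, 11))^2)
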
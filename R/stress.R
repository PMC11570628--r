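new_stress_report <- function(test, baseline_auroc, perturbed_auroc, config,
                              notes = "") {
  structure(list(test = test, baseline_auroc = baseline_auroc,
                 perturbed_auroc = perturbed_auroc,
                 delta = baseline_auroc - perturbed_auroc,
                 config = config, notes = notes),
            class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat(sprintf("stress test [%s]: baseline AUROC %.3f, perturbed %.3f (delta %+.3f)\n",
              x$test, x$baseline_auroc, x$perturbed_auroc, -x$delta))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n")
  invisible(x)
}

# Held-out pair AUROC of a trained model on a given trace matrix.
pair_auroc <- function(model, pairs, traces, split = "test") {
  pairs <- pairs[pairs$split == split, ]
  X <- twin_preprocess(traces, model$config)
  evaluate_pair_split(model$layers, model$config, X, pairs)$auroc
}

#' Smoothing ablation: does the model depend on high-frequency signal?
#'
#' Compares held-out pair AUROC with and without Hanning smoothing of the
#' traces (applied *before* stride subsampling and normalization). In the
#' default `"retrain"` mode a fresh model is trained on the smoothed traces
#' and its held-out AUROC is compared with the raw-trained model's: when the
#' model's performance rests on genuine stimulus-locked behavior the two
#' hardly differ, but when it exploits high-frequency content (sensor noise
#' patterns, position-keyed artifact components) the smoothed-trained model
#' loses that channel and its AUROC drops. `"evaluate"` mode instead feeds
#' smoothed inputs to the raw-trained model, probing the trained model's
#' reliance on the high-frequency band directly.
#'
#' @param model a trained `twin_model`.
#' @param pairs a `pair_dataset`.
#' @param traces raw trace matrix.
#' @param window Hanning window length (default 11).
#' @param mode `"retrain"` (default) or `"evaluate"`.
#' @return a `stress_report` (baseline = raw AUROC, perturbed = smoothed
#'   AUROC; positive `delta` means smoothing hurt).
#' @export
smoothing_ablation <- function(model, pairs, traces, window = 11,
                               mode = c("retrain", "evaluate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "twin_model"), model$trained)
  smoothed <- smooth_hanning(as.matrix(traces), window = window)
  base <- pair_auroc(model, pairs, traces)
  pert <- if (mode == "retrain") {
    m2 <- train_twin(build_twin_model(model$config), pairs, smoothed)
    pair_auroc(m2, pairs, smoothed)
  } else {
    pair_auroc(model, pairs, smoothed)
  }
  new_stress_report("smoothing_ablation", base, pert,
                    list(window = window, mode = mode), "")
}

#' Label-shuffle soundness check (y-scrambling)
#'
#' Retrains the model from scratch after randomly permuting the pair labels
#' within each split (inputs fixed, label counts preserved — the classic
#' y-scrambling control) and reports held-out AUROC against the scrambled
#' held-out labels. Since the scrambled labels carry no relationship to the
#' inputs, any performance above chance (0.5) would indicate leakage in the
#' training machinery.
#'
#' @param pairs a `pair_dataset`.
#' @param traces raw trace matrix.
#' @param config a [twin_config()].
#' @param seed shuffle seed.
#' @return a `stress_report`; `baseline_auroc` is 0.5 (chance),
#'   `perturbed_auroc` the shuffled-label model's held-out AUROC.
#' @export
label_shuffle_test <- function(pairs, traces, config, seed = 1) {
  shuffled <- pairs
  shuffled$label <- with_seed(child_seed(seed, "shuffle"),
    unsplit(lapply(split(shuffled$label, shuffled$split), sample),
            shuffled$split))
  model <- train_twin(build_twin_model(config), shuffled, traces, selection = "final")
  auroc <- pair_auroc(model, shuffled, traces)
  new_stress_report("label_shuffle", 0.5, auroc,
                    list(seed = seed), "expected ~0.5: no learnable signal")
}

#' Input-randomization soundness check
#'
#' Replaces every trace with a uniform random vector over the observed MI
#' range (labels fixed) and retrains. The features then carry no signal, so
#' held-out AUROC should be chance; training AUROC may exceed it through
#' memorization and is reported in the notes. Held-out scoring is restricted
#' to pairs sharing no well with any training pair (control wells straddle
#' the drug-wise split, and a memorized random trace would otherwise leak
#' its trained-in position into the held-out score).
#'
#' @inheritParams label_shuffle_test
#' @return a `stress_report`.
#' @export
random_input_test <- function(pairs, traces, config, seed = 1) {
  traces <- as.matrix(traces)
  rand <- with_seed(child_seed(seed, "randinput"), {
    matrix(stats::runif(length(traces), min(traces), max(traces)),
           nrow(traces), ncol(traces))
  })
  model <- train_twin(build_twin_model(config), pairs, rand, selection = "final")
  tr <- pairs$split == "train"
  train_wells <- unique(c(pairs$index_a[tr], pairs$index_b[tr]))
  clean <- pairs[!tr & !(pairs$index_a %in% train_wells) &
                   !(pairs$index_b %in% train_wells), ]
  auroc <- pair_auroc(model, clean, rand)
  train_auroc <- pair_auroc(model, pairs, rand, split = "train")
  new_stress_report("random_input", 0.5, auroc, list(seed = seed),
                    sprintf("train AUROC %.3f (memorization possible); %d disjoint held-out pairs",
                            train_auroc, nrow(clean)))
}

#' Well-distance prediction control
#'
#' Relabels pairs by physical plate geometry instead of treatment: a pair is
#' "same" when the Euclidean distance between its wells' (row, col)
#' coordinates — in well-pitch units, ignoring plate identity — is below the
#' cutoff, and "different" otherwise. A twin model is trained on these
#' positional labels. On artifact-free data the traces carry no positional
#' information and held-out AUROC sits at chance; a planted positional
#' artifact makes well distance learnable and pushes the AUROC up,
#' diagnosing the shortcut channel directly.
#'
#' @param dataset a `screen_dataset`.
#' @param config a [twin_config()].
#' @param cutoffs numeric vector of plate-distance cutoffs (conventionally
#'   2 and 5.2 well-pitch units).
#' @param n_train_pairs,n_test_pairs balanced pair counts constructed per
#'   split; wells are partitioned 80/20 between the splits first, so no
#'   well is shared between training and held-out pairs.
#' @param seed integer seed.
#' @return a list of `stress_report`, one per cutoff.
#' @export
well_distance_test <- function(dataset, config, cutoffs = c(2, 5.2),
                               n_train_pairs = 2000, n_test_pairs = 1000,
                               seed = 1) {
  if (any(cutoffs <= 0)) stop_param("cutoffs must be > 0")
  wells <- dataset$wells
  n <- nrow(wells)
  lapply(cutoffs, function(cut) {
    pairs <- with_seed(child_seed(seed, "wd", cut), {
      train_wells <- sort(sample.int(n, round(0.8 * n)))
      test_wells <- setdiff(seq_len(n), train_wells)
      rbind(geometric_pairs(wells, train_wells, cut, n_train_pairs, "train"),
            geometric_pairs(wells, test_wells, cut, n_test_pairs, "test"))
    })
    model <- train_twin(build_twin_model(config), pairs, dataset$traces,
                        selection = "final")
    auroc <- pair_auroc(model, pairs, dataset$traces)
    new_stress_report(sprintf("well_distance(cutoff=%g)", cut), 0.5, auroc,
                      list(cutoff = cut, seed = seed),
                      sprintf("%d train / %d held-out balanced pairs",
                              sum(pairs$split == "train"),
                              sum(pairs$split == "test")))
  })
}

# Balanced geometric pair sample within one well subset: label "same" when
# the within-plate (row, col) Euclidean distance is below `cutoff`.
geometric_pairs <- function(wells, subset, cutoff, n_pairs, split_name) {
  combos <- t(utils::combn(subset, 2L))
  d_geo <- sqrt((wells$row[combos[, 1]] - wells$row[combos[, 2]])^2 +
                (wells$col[combos[, 1]] - wells$col[combos[, 2]])^2)
  same <- which(d_geo < cutoff)
  diff <- which(d_geo >= cutoff)
  if (length(same) == 0L || length(diff) == 0L)
    stop_data("cutoff ", cutoff, " yields a single geometric class; ",
              "choose a cutoff inside the plate's distance range")
  per_class <- min(length(same), length(diff), ceiling(n_pairs / 2))
  pick <- c(sample(same, per_class), sample(diff, per_class))
  data.frame(index_a = combos[pick, 1], index_b = combos[pick, 2],
             label = rep(c("same", "different"), each = per_class),
             pair_class = "well-distance", split = split_name,
             stringsAsFactors = FALSE)
}
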
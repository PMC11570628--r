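#' Balance classes by seeded undersampling
#'
#' Downsamples every class, without replacement, to the size of the minority
#' class, so a classifier trains on exactly balanced classes.
#'
#' @param class_of named factor/character vector: class per example (names
#'   or positions identify examples).
#' @param seed integer seed.
#' @return integer indices of the retained examples (equal counts per class).
#' @examples
#' cls <- rep(c("a", "b"), c(556, 900))
#' table(cls[balance_by_undersampling(cls, seed = 1)])  # 556 of each
#' @export
balance_by_undersampling <- function(class_of, seed = 1) {
  counts <- table(class_of)
  if (any(counts == 0) || length(counts) < 1L)
    stop_data("every class must be non-empty")
  m <- min(counts)
  idx <- with_seed(child_seed(seed, "undersample"), {
    unlist(lapply(split(seq_along(class_of), class_of), function(i)
      if (length(i) == m) i else sample(i, m)))
  })
  sort(unname(idx))
}

#' Train a random-forest activity classifier
#'
#' Fits a random forest on raw MI trace vectors to separate wells whose
#' treatment altered behavior from vehicle-like wells. In `binary` mode the
#' classes are treatment (`active`) versus vehicle (`inactive`); `ternary`
#' mode adds lethal-control wells as a third class (`lethal`), so the model
#' can flag toxic compounds. Labels are seeded from well roles (vehicle
#' wells are `inactive`, lethal controls `lethal`, drug wells `active` —
#' a deliberately noisy labeling, since genuinely inactive drugs look like
#' vehicle). Training classes are exactly balanced by undersampling and the
#' fit uses a drug-wise-agnostic seeded 80/20 well split; held-out accuracy
#' is reported.
#'
#' @param dataset a `screen_dataset`.
#' @param mode `"binary"` or `"ternary"`.
#' @param split_fraction training fraction of the well split.
#' @param ntree random-forest size (default 500 trees, unlimited depth).
#' @param seed integer seed.
#' @return an `activity_model` list: `forest`, `mode`, `test_accuracy`,
#'   `class_counts`, `train_idx`, `test_idx`, `seed`.
#' @export
train_activity_classifier <- function(dataset, mode = c("binary", "ternary"),
                                      split_fraction = 0.8, ntree = 500, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "screen_dataset"))
  roles <- dataset$wells$role
  if (!any(roles == "vehicle")) stop_data("dataset has no vehicle wells")
  if (mode == "ternary" && !any(roles == "lethal"))
    stop_data("ternary mode requires lethal-control wells")
  keep <- if (mode == "binary") roles %in% c("drug", "vehicle") else rep(TRUE, length(roles))
  y <- c(drug = "active", vehicle = "inactive", lethal = "lethal")[roles[keep]]
  X <- dataset$traces[keep, , drop = FALSE]

  split <- with_seed(child_seed(seed, "activity_split"), {
    n <- nrow(X)
    train <- sort(sample.int(n, round(split_fraction * n)))
    list(train = train, test = setdiff(seq_len(n), train))
  })
  bal <- balance_by_undersampling(y[split$train], seed = child_seed(seed, "activity_bal"))
  train_idx <- split$train[bal]
  forest <- with_seed(child_seed(seed, "activity_rf"), {
    randomForest::randomForest(x = X[train_idx, , drop = FALSE],
                               y = factor(y[train_idx]), ntree = ntree)
  })
  pred <- predict(forest, X[split$test, , drop = FALSE])
  structure(list(forest = forest, mode = mode,
                 test_accuracy = mean(pred == y[split$test]),
                 class_counts = table(y[train_idx]),
                 train_idx = which(keep)[train_idx],
                 test_idx = which(keep)[split$test], seed = seed),
            class = "activity_model")
}

#' Label wells with a fitted activity model
#'
#' Predicts an activity label (`active` / `inactive` / `lethal`) and class
#' probabilities for every well. Role metadata takes precedence for
#' pair-building purposes: vehicle and lethal control wells keep their
#' control designation regardless of the forest's output (the prediction is
#' still reported in the probability columns).
#'
#' When labeling the same dataset the model was trained on (`oob = TRUE`,
#' the default), wells that served as training examples are scored by their
#' out-of-bag votes rather than by running them back through the full
#' forest, which would simply return their memorized training labels.
#'
#' @param model an `activity_model`.
#' @param dataset a `screen_dataset` with the same trace length as training.
#' @param oob use out-of-bag votes for training-member wells; set to `FALSE`
#'   when labeling a dataset other than the training screen.
#' @return a data.frame: `well_id`, `predicted` (raw forest label), `label`
#'   (role-overridden label used downstream), and per-class probabilities.
#' @export
label_wells <- function(model, dataset, oob = TRUE) {
  stopifnot(inherits(model, "activity_model"))
  X <- dataset$traces
  if (ncol(X) != nrow(model$forest$importance))
    stop_shape("trace length ", ncol(X), " does not match the model's ",
               nrow(model$forest$importance), " features")
  prob <- predict(model$forest, X, type = "prob")
  if (oob) {
    votes <- model$forest$votes        # OOB class proportions, training order
    in_train <- model$train_idx[model$train_idx <= nrow(X)]
    prob[in_train, ] <- votes[seq_along(in_train), colnames(prob)]
  }
  predicted <- colnames(prob)[max.col(prob, ties.method = "first")]
  label <- predicted
  label[dataset$wells$role == "vehicle"] <- "inactive"
  label[dataset$wells$role == "lethal"] <- "lethal"
  out <- data.frame(well_id = dataset$wells$well_id, predicted = predicted,
                    label = label, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(prob))
}

#' Per-drug phenotype strength
#'
#' The forest's probability of the `active` class, averaged over a drug's
#' replicate wells — a scalar summary of how reliably the drug perturbs
#' behavior, used for coloring behaviorome maps and selecting
#' strong-phenotype compound subsets.
#'
#' @param model an `activity_model`.
#' @param dataset a `screen_dataset`.
#' @return named numeric vector, one entry per drug.
#' @export
phenotype_strength <- function(model, dataset) {
  labels <- label_wells(model, dataset)
  is_drug <- dataset$wells$role == "drug"
  tapply(labels$active[is_drug], dataset$wells$treatment_id[is_drug], mean)
}
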
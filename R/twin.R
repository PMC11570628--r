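#' Configuration for a twin (Siamese) metric-learning model
#'
#' Captures the architecture and training hyperparameters of the two
#' parameter-sharing encoder branches. The full-scale MLP encoder
#' (`twin_nn`) maps a 20,250-point input (a 101,250-frame MI trace
#' subsampled at stride 5) through hidden widths 4000, 500, 250 and 100 to a
#' 10-dimensional embedding, with batch normalization and ReLU after every
#' linear map except the last. `twin_dn` replaces the plain stack with a
#' densely connected encoder (see [build_twin_model()]).
#'
#' @param architecture `"twin_nn"` (plain MLP) or `"twin_dn"` (densely
#'   connected variant).
#' @param input_length encoder input width after stride subsampling.
#' @param hidden_widths hidden layer widths of the `twin_nn` encoder.
#' @param embedding_dim output embedding dimension.
#' @param margin contrastive-loss margin applied to mismatched pairs.
#' @param learning_rate,weight_decay Adam optimizer settings.
#' @param batch_size pairs per optimizer step; defaults to 32 for `twin_nn`
#'   and 8 for `twin_dn`.
#' @param max_epochs,patience training length and early-stopping patience
#'   (epochs without validation-loss improvement).
#' @param subsample_stride frame stride applied to raw traces before the
#'   encoder.
#' @param norm_lo,norm_hi dataset-wide min-max normalization bounds in MI
#'   units, frozen into the model (conventionally 0 and 6750).
#' @param seed integer seed controlling initialization and batch order.
#' @param dense_block_spec list with `n_blocks`, `layers_per_block`,
#'   `growth`, `initial_width` (`twin_dn` only).
#' @return a `twin_config` list.
#' @export
twin_config <- function(architecture = c("twin_nn", "twin_dn"),
                        input_length = 20250,
                        hidden_widths = c(4000, 500, 250, 100),
                        embedding_dim = 10,
                        margin = 0.5,
                        learning_rate = 5e-4,
                        weight_decay = 1e-6,
                        batch_size = NULL,
                        max_epochs = 100,
                        patience = 10,
                        subsample_stride = 5,
                        norm_lo = 0, norm_hi = 6750,
                        seed = 1,
                        dense_block_spec = list(n_blocks = 3, layers_per_block = 4,
                                                growth = 12, initial_width = 48)) {
  architecture <- match.arg(architecture)
  if (embedding_dim < 1) stop_param("embedding_dim must be >= 1")
  if (margin <= 0) stop_param("margin must be > 0")
  if (any(hidden_widths < 1)) stop_param("hidden widths must be positive")
  if (norm_hi <= norm_lo) stop_param("need norm_hi > norm_lo")
  batch_size <- batch_size %||% if (architecture == "twin_nn") 32L else 8L
  structure(list(
    architecture = architecture, input_length = as.integer(input_length),
    hidden_widths = as.integer(hidden_widths),
    embedding_dim = as.integer(embedding_dim), margin = margin,
    learning_rate = learning_rate, weight_decay = weight_decay,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), subsample_stride = as.integer(subsample_stride),
    norm_lo = norm_lo, norm_hi = norm_hi, seed = as.integer(seed),
    dense_block_spec = dense_block_spec
  ), class = "twin_config")
}

#' Contrastive loss between paired embeddings
#'
#' For embeddings `y1`, `y2` with Euclidean distance `d`, matched
#' (same-treatment) pairs incur `0.5 * d^2` and mismatched pairs
#' `0.5 * max(0, margin - d)^2`; a batch's loss is the mean over its pairs.
#' Matched pairs are thus pulled together while mismatched pairs are pushed
#' apart until they clear the margin.
#'
#' @param y1,y2 numeric embedding vectors of equal length, or matrices with
#'   one embedding per row.
#' @param label `"same"`/`"different"` per pair (recycled for matrices).
#' @param margin non-negative margin.
#' @return mean loss (non-negative scalar).
#' @examples
#' contrastive_loss(c(1, 0), c(1, 0), "same")                   # 0
#' contrastive_loss(c(0.3, 0), c(0, 0), "different", 0.5)       # 0.5 * 0.2^2
#' @export
contrastive_loss <- function(y1, y2, label, margin = 0.5) {
  if (!is.matrix(y1)) y1 <- matrix(y1, nrow = 1L)
  if (!is.matrix(y2)) y2 <- matrix(y2, nrow = 1L)
  if (!identical(dim(y1), dim(y2)))
    stop_shape("embedding dimensions differ: ", paste(dim(y1), collapse = "x"),
               " vs ", paste(dim(y2), collapse = "x"))
  if (!all(label %in% c("same", "different")))
    stop_param('labels must be "same" or "different"')
  label <- rep_len(label, nrow(y1))
  d <- sqrt(rowSums((y1 - y2)^2))
  li <- ifelse(label == "same", 0.5 * d^2, 0.5 * pmax(0, margin - d)^2)
  mean(li)
}

#' @describeIn contrastive_loss analytic gradient of the mean loss with
#'   respect to `y1` and `y2`; returned as a list of two matrices. Used by
#'   the training loop and checkable against finite differences.
#' @export
contrastive_loss_grad <- function(y1, y2, label, margin = 0.5) {
  if (!is.matrix(y1)) y1 <- matrix(y1, nrow = 1L)
  if (!is.matrix(y2)) y2 <- matrix(y2, nrow = 1L)
  label <- rep_len(label, nrow(y1))
  B <- nrow(y1)
  diff <- y1 - y2
  d <- sqrt(rowSums(diff^2))
  coef <- ifelse(label == "same", 1,
                 ifelse(d > 0 & d < margin, -(margin - d) / d, 0))
  g <- diff * (coef / B)
  list(dy1 = g, dy2 = -g)
}

#' Build an untrained twin model
#'
#' Constructs the shared-weight encoder described by a [twin_config()]. Both
#' branches of the twin are the *same* parameter set, so the resulting
#' distance is symmetric by construction.
#'
#' `twin_nn` is a plain MLP: linear maps through `hidden_widths` to
#' `embedding_dim`, batch normalization + ReLU after every linear layer
#' except the last. `twin_dn` uses DenseNet-style dense connectivity adapted
#' to fully connected layers: within a block every layer consumes the
#' concatenation of the block input and all previous layer outputs and emits
#' `growth` new features; linear transition layers halve the width between
#' blocks; a final linear layer maps to the embedding.
#'
#' @param config a [twin_config()].
#' @return a `twin_model` list with fields `config`, `layers`, `trained`.
#' @seealso [train_twin()], [twin_layer_shapes()]
#' @export
build_twin_model <- function(config) {
  stopifnot(inherits(config, "twin_config"))
  layers <- with_seed(child_seed(config$seed, "init"), {
    if (config$architecture == "twin_nn") build_mlp_layers(config)
    else build_dense_layers(config)
  })
  structure(list(config = config, layers = layers, trained = FALSE,
                 history = NULL), class = "twin_model")
}

build_mlp_layers <- function(config) {
  widths <- c(config$input_length, config$hidden_widths, config$embedding_dim)
  layers <- vector("list", length(widths) - 1L)
  for (k in seq_along(layers)) {
    last <- k == length(layers)
    layers[[k]] <- nn_init_layer(widths[k], widths[k + 1L], inputs = k - 1L,
                                 bn = !last, relu = !last)
  }
  layers
}

build_dense_layers <- function(config) {
  spec <- config$dense_block_spec
  layers <- list()
  id <- 0L
  add <- function(n_in, n_out, inputs, bn = TRUE, relu = TRUE) {
    id <<- id + 1L
    layers[[id]] <<- nn_init_layer(n_in, n_out, inputs, bn = bn, relu = relu)
    id
  }
  # stem: compress the raw input to the initial feature width
  stem <- add(config$input_length, spec$initial_width, inputs = 0L)
  width <- spec$initial_width
  block_in <- stem
  for (b in seq_len(spec$n_blocks)) {
    feats <- block_in          # ids whose outputs feed subsequent layers
    w <- width
    for (l in seq_len(spec$layers_per_block)) {
      new <- add(w, spec$growth, inputs = feats)
      feats <- c(feats, new)
      w <- w + spec$growth
    }
    if (b < spec$n_blocks) {
      block_in <- add(w, max(1L, w %/% 2L), inputs = feats)
      width <- max(1L, w %/% 2L)
    } else {
      block_in <- feats        # final block feeds the head with all features
      width <- w
    }
  }
  add(width, config$embedding_dim, inputs = block_in, bn = FALSE, relu = FALSE)
  layers
}

#' Layer shapes implied by a twin configuration
#'
#' Returns the sequence of layer sizes (input width, hidden widths,
#' embedding) without allocating any parameters — useful for validating a
#' configuration such as the full-scale encoder whose first weight matrix
#' alone holds 81 million parameters.
#'
#' @param config a [twin_config()].
#' @return for `twin_nn`, the integer vector of layer sizes; for `twin_dn`,
#'   a data.frame of per-layer input/output widths.
#' @export
twin_layer_shapes <- function(config) {
  stopifnot(inherits(config, "twin_config"))
  if (config$architecture == "twin_nn")
    return(c(config$input_length, config$hidden_widths, config$embedding_dim))
  spec <- config$dense_block_spec
  rows <- list(data.frame(layer = "stem", n_in = config$input_length,
                          n_out = spec$initial_width))
  width <- spec$initial_width
  for (b in seq_len(spec$n_blocks)) {
    w <- width
    for (l in seq_len(spec$layers_per_block)) {
      rows <- c(rows, list(data.frame(layer = sprintf("block%d.%d", b, l),
                                      n_in = w, n_out = spec$growth)))
      w <- w + spec$growth
    }
    if (b < spec$n_blocks) {
      rows <- c(rows, list(data.frame(layer = sprintf("transition%d", b),
                                      n_in = w, n_out = max(1L, w %/% 2L))))
      width <- max(1L, w %/% 2L)
    } else width <- w
  }
  rows <- c(rows, list(data.frame(layer = "head", n_in = width,
                                  n_out = config$embedding_dim)))
  do.call(rbind, rows)
}

# Preprocess a raw trace matrix exactly as the training loop does.
twin_preprocess <- function(traces, config) {
  x <- subsample_trace(as.matrix(traces), config$subsample_stride)
  if (ncol(x) != config$input_length)
    stop_shape("preprocessed trace length ", ncol(x),
               " does not match encoder input length ", config$input_length)
  normalize_trace(x, config$norm_lo, config$norm_hi)
}

#' Train a twin metric-learning model
#'
#' Runs mini-batch training with the contrastive loss and the Adam
#' optimizer. Per epoch the training pairs are shuffled and each pair's
#' member order is randomly swapped (the encoder is weight-shared, so the
#' swap is a symmetry-preserving augmentation); raw traces are stride-
#' subsampled and min-max normalized with the bounds frozen in the config.
#' Validation pairs (the `"test"` split of `pairs`) are scored every epoch
#' with the frozen running batch-norm statistics; training stops at
#' `max_epochs` or when validation loss fails to improve for `patience`
#' epochs, returning the parameters of the best validation epoch. The run
#' is fully determined by `config$seed`.
#'
#' @param model an untrained model from [build_twin_model()] (or a
#'   [twin_config()], from which one is built).
#' @param pairs a pair table from [build_pairs()] with columns `index_a`,
#'   `index_b`, `label`, `split`.
#' @param traces numeric matrix of raw traces, rows indexed by the pair
#'   table.
#' @param selection which weights to return: `"best_val"` (the epoch with
#'   the lowest validation loss, the default) or `"final"` (the last epoch;
#'   used by adversarial stress tests whose validation labels must not
#'   influence the returned model).
#' @param verbose print per-epoch progress.
#' @return the trained `twin_model`, with a `history` data.frame
#'   (per-epoch train/validation loss and validation pair AUROC).
#' @export
train_twin <- function(model, pairs, traces,
                       selection = c("best_val", "final"), verbose = FALSE) {
  selection <- match.arg(selection)
  if (inherits(model, "twin_config")) model <- build_twin_model(model)
  stopifnot(inherits(model, "twin_model"))
  config <- model$config
  pairs <- as.data.frame(pairs)
  need <- c("index_a", "index_b", "label", "split")
  if (!all(need %in% names(pairs))) stop_data("pair table lacks columns: ",
    paste(setdiff(need, names(pairs)), collapse = ", "))
  X <- twin_preprocess(traces, config)
  tr <- pairs[pairs$split == "train", ]
  va <- pairs[pairs$split == "test", ]
  if (nrow(tr) == 0L) stop_data("no training pairs")

  layers <- model$layers
  state <- adam_init(layers)
  step <- 0L
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  hist <- list()
  n_tr <- nrow(tr)

  for (epoch in seq_len(config$max_epochs)) {
    sched <- with_seed(child_seed(config$seed, "epoch", epoch), {
      list(ord = sample.int(n_tr), swap = stats::runif(n_tr) < 0.5)
    })
    ep <- tr[sched$ord, ]
    a_idx <- ifelse(sched$swap, ep$index_b, ep$index_a)
    b_idx <- ifelse(sched$swap, ep$index_a, ep$index_b)
    ep_loss <- 0
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (s in starts) {
      rows <- s:min(s + config$batch_size - 1L, n_tr)
      B <- length(rows)
      Xb <- X[c(a_idx[rows], b_idx[rows]), , drop = FALSE]
      fwd <- nn_forward(layers, Xb, training = TRUE)
      layers <- fwd$layers                  # running BN stats updated
      y1 <- fwd$out[seq_len(B), , drop = FALSE]
      y2 <- fwd$out[B + seq_len(B), , drop = FALSE]
      loss <- contrastive_loss(y1, y2, ep$label[rows], config$margin)
      if (!is.finite(loss))
        stop("non-finite training loss (lr = ", config$learning_rate,
             ", epoch ", epoch, ", batch at pair ", s, ")")
      g <- contrastive_loss_grad(y1, y2, ep$label[rows], config$margin)
      grads <- nn_backward(layers, fwd, Xb, rbind(g$dy1, g$dy2))
      step <- step + 1L
      upd <- adam_step(layers, grads, state, step,
                       config$learning_rate, config$weight_decay)
      layers <- upd$layers; state <- upd$state
      ep_loss <- ep_loss + loss * B
    }
    ep_loss <- ep_loss / n_tr
    val <- evaluate_pair_split(layers, config, X, va)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = val$loss, val_auroc = val$auroc)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  auroc %.3f",
                      epoch, ep_loss, val$loss, val$auroc))
    if (is.finite(val$loss) && val$loss < best$loss - 1e-9) {
      best <- list(loss = val$loss, layers = layers, epoch = epoch)
    } else if (selection == "best_val" && nrow(va) > 0L &&
               epoch - best$epoch >= config$patience) {
      break
    }
  }
  model$layers <- if (selection == "best_val" && nrow(va) > 0L) best$layers else layers
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model
}

evaluate_pair_split <- function(layers, config, X, pairs) {
  if (nrow(pairs) == 0L) return(list(loss = NA_real_, auroc = NA_real_))
  E <- nn_forward(layers, X[unique(c(pairs$index_a, pairs$index_b)), , drop = FALSE],
                  training = FALSE)$out
  idx <- match(c(pairs$index_a, pairs$index_b),
               unique(c(pairs$index_a, pairs$index_b)))
  n <- nrow(pairs)
  y1 <- E[idx[seq_len(n)], , drop = FALSE]
  y2 <- E[idx[n + seq_len(n)], , drop = FALSE]
  d <- sqrt(rowSums((y1 - y2)^2))
  loss <- contrastive_loss(y1, y2, pairs$label, config$margin)
  auroc <- if (length(unique(pairs$label)) == 2L) roc_auc(d, pairs$label)$auc else NA_real_
  list(loss = loss, auroc = auroc, distances = d)
}

#' Embed traces with a trained twin model
#'
#' @param model a trained `twin_model`.
#' @param traces raw trace matrix (rows = wells) or a single trace vector.
#' @return an `n x embedding_dim` matrix of embeddings (inference mode:
#'   frozen batch-norm statistics).
#' @export
twin_embed <- function(model, traces) {
  stopifnot(inherits(model, "twin_model"))
  if (!model$trained) stop("model is untrained; call train_twin() first")
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1L)
  X <- twin_preprocess(traces, model$config)
  nn_forward(model$layers, X, training = FALSE)$out
}

#' Learned phenotypic distance between two traces
#'
#' Euclidean distance between the twin-model embeddings of two raw traces,
#' each preprocessed exactly as during training. Symmetric (the branches
#' share weights) with `learned_distance(m, x, x) == 0`.
#'
#' @param model a trained `twin_model`.
#' @param a,b raw traces (vectors) or matrices of traces compared row-wise.
#' @return non-negative scalar (or vector, for matrix input).
#' @export
learned_distance <- function(model, a, b) {
  ya <- twin_embed(model, a)
  yb <- twin_embed(model, b)
  if (!identical(dim(ya), dim(yb))) stop_shape("trace sets differ in size")
  d <- sqrt(rowSums((ya - yb)^2))
  if (length(d) == 1L) as.numeric(d) else d
}

#' Save / load a trained twin model
#'
#' The checkpoint is a single `.rds` archive holding parameters, the full
#' configuration and normalization constants; reloading reproduces
#' [learned_distance()] bit-for-bit.
#'
#' @param model a `twin_model`.
#' @param path file path for the checkpoint.
#' @return `load_twin_model()` returns the restored model.
#' @export
save_twin_model <- function(model, path) {
  stopifnot(inherits(model, "twin_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_twin_model
#' @export
load_twin_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "twin_model"))
  model
}
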
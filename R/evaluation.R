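#' ROC curve and AUROC for pair distances
#'
#' Scores how well a distance separates matched (`"same"`) from mismatched
#' (`"different"`) pairs. The positive class is the matched pair and the
#' ranking score is the negated distance, so smaller distances rank first.
#' The AUROC equals the Mann-Whitney statistic: the fraction of
#' positive/negative pair comparisons won by the positive (ties count 1/2).
#'
#' @param distances numeric vector of pair distances.
#' @param labels `"same"`/`"different"` per pair.
#' @return a list with `auc` and a `curve` data.frame (`fpr`, `tpr`).
#' @examples
#' roc_auc(c(0.1, 0.2, 0.8, 0.9), c("same", "same", "different", "different"))$auc
#' @export
roc_auc <- function(distances, labels) {
  check_pair_scores(distances, labels)
  pos <- labels == "same"
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(-distances)            # high score (low distance) = high rank? no:
  # rank() gives 1 for the smallest; with score = -distance the largest score
  # (smallest distance) gets the highest rank, as the Mann-Whitney sum needs.
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  ord <- order(distances, decreasing = FALSE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  curve <- data.frame(fpr = c(0, fp / n2), tpr = c(0, tp / n1))
  list(auc = auc, curve = curve)
}

check_pair_scores <- function(distances, labels) {
  if (length(distances) != length(labels))
    stop_shape("one score per pair required")
  if (!all(labels %in% c("same", "different")))
    stop_param('labels must be "same" or "different"')
  if (length(unique(labels)) < 2L)
    stop_data("need both positive and negative pairs")
  if (!all(is.finite(distances))) stop_data("non-finite distances")
}

#' Precision-recall curve and area
#'
#' Sweeps the distance threshold from the closest pair outward, computing
#' precision and recall at each distinct distance, and integrates the curve
#' with the standard step interpolation
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}. The random-classifier baseline equals
#' the positive prevalence.
#'
#' @inheritParams roc_auc
#' @return a list with `auc`, a `curve` data.frame (`recall`, `precision`)
#'   and `baseline` (positive prevalence).
#' @export
prc_auc <- function(distances, labels) {
  check_pair_scores(distances, labels)
  pos <- labels == "same"
  ord <- order(distances)
  pos <- pos[ord]; d <- distances[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  keep <- c(d[-1] != d[-length(d)], TRUE)   # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / sum(labels == "same")
  auc <- sum(diff(c(0, recall)) * precision)
  list(auc = auc,
       curve = data.frame(recall = recall, precision = precision),
       baseline = mean(labels == "same"))
}

#' k-nearest-neighbor classification of reference drugs
#'
#' Evaluates a distance metric by a quality-control task: given a
#' high-replicate screen of reference drugs, hold out validation replicates
#' per drug and predict each validation well's drug as the majority label
#' among its `k` nearest *training* wells under the metric. Ties are broken
#' by smaller summed distance, then lexicographically by drug id. With the
#' conventional `k = 15` and 8 training replicates per drug, neighbor sets
#' necessarily pool across drugs.
#'
#' @param D symmetric well-by-well distance matrix.
#' @param drug_labels drug id per well (rows of `D`).
#' @param k neighbor count.
#' @param n_train,n_val per-drug training/validation replicate counts.
#' @param seed seed for the replicate split.
#' @return list with `overall` accuracy, `per_drug` accuracy vector, and the
#'   `predictions` data.frame.
#' @export
knn_classify <- function(D, drug_labels, k = 15, n_train = 8, n_val = 2, seed = 1) {
  stopifnot(nrow(D) == length(drug_labels))
  counts <- table(drug_labels)
  if (any(counts < n_train + n_val))
    stop_data("every drug needs >= ", n_train + n_val, " replicates; short: ",
              paste(names(counts)[counts < n_train + n_val], collapse = ", "))
  split <- with_seed(child_seed(seed, "knn_split"), {
    idx <- seq_along(drug_labels)
    train <- unlist(lapply(split(idx, drug_labels), function(i)
      sample(i, n_train)))
    val <- unlist(lapply(split(setdiff(idx, train), drug_labels[-train]),
                         function(i) sample(i, n_val)))
    list(train = train, val = val)
  })
  if (k > length(split$train)) stop_param("k exceeds training-set size")
  preds <- vapply(split$val, function(w) {
    dd <- D[w, split$train]
    nn <- split$train[order(dd)[seq_len(k)]]
    votes <- table(drug_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(dr)
        sum(D[w, intersect(nn, which(drug_labels == dr))]), 0)
      top <- top[order(sums, top)]
    }
    top[1L]
  }, "")
  truth <- drug_labels[split$val]
  per_drug <- tapply(preds == truth, truth, mean)
  list(overall = mean(preds == truth), per_drug = per_drug,
       predictions = data.frame(well = split$val, truth = truth, pred = preds))
}

#' Replicate identification curve
#'
#' For each well, ranks all other wells by distance and counts how many
#' same-drug replicates appear in the `top_n` most similar; each drug's
#' score is aggregated over its wells (`max` by default). The curve reports,
#' for each replicate count `k`, how many unique drugs had at least `k`
#' replicates identified — a cumulative count that is non-increasing in `k`.
#' Strong metrics identify many replicates for many drugs; metrics that fail
#' beyond the first replicate plateau early.
#'
#' @param D symmetric well-by-well distance matrix.
#' @param wells well records with `treatment_id` and `role` columns; only
#'   `role == "drug"` wells enter the curve.
#' @param top_n ranking depth (wells), default 50.
#' @param aggregate `"max"` (default) or `"mean"` over a drug's own wells.
#' @return a data.frame (`k`, `n_drugs`) of class `replicate_id_curve`, with
#'   the per-drug counts in attribute `per_drug`.
#' @export
replicate_identification <- function(D, wells, top_n = 50, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(D) == nrow(wells))
  if (top_n >= nrow(D)) stop_param("top_n must be below the number of wells")
  drug_wells <- which(wells$role == "drug")
  treatment <- wells$treatment_id
  found <- vapply(drug_wells, function(w) {
    ord <- order(D[w, ])
    ord <- ord[ord != w][seq_len(top_n)]
    sum(treatment[ord] == treatment[w])
  }, 0L)
  agg_fun <- if (aggregate == "max") max else mean
  per_drug <- tapply(found, treatment[drug_wells], agg_fun)
  max_k <- max(1L, max(per_drug))
  curve <- data.frame(k = seq_len(max_k),
                      n_drugs = vapply(seq_len(max_k),
                                       function(k) sum(per_drug >= k), 0L))
  structure(curve, class = c("replicate_id_curve", "data.frame"),
            per_drug = per_drug)
}

#' Mean trace per compound
#'
#' @param dataset a `screen_dataset`.
#' @param roles which well roles to include (default drug wells only).
#' @return a matrix of element-wise mean traces, rows named by treatment.
#' @export
mean_traces_by_drug <- function(dataset, roles = "drug") {
  keep <- dataset$wells$role %in% roles
  ids <- unique(dataset$wells$treatment_id[keep])
  out <- t(vapply(ids, function(id) {
    colMeans(dataset$traces[keep & dataset$wells$treatment_id == id, , drop = FALSE])
  }, numeric(ncol(dataset$traces))))
  rownames(out) <- ids
  out
}

#' Two-dimensional behaviorome map of compounds
#'
#' Computes a compound-level distance matrix from mean traces under the
#' given metric and lays the compounds out in two dimensions with a
#' pluggable embedding engine operating on the precomputed distances. The
#' default engine is classical multidimensional scaling ([stats::cmdscale]);
#' any function with signature `function(D, n_neighbors, min_dist, seed)`
#' returning an `n x 2` matrix can be substituted (e.g. a UMAP-family
#' embedding), and the `n_neighbors`/`min_dist` arguments are forwarded to
#' it.
#'
#' @param mean_traces compound-by-frame matrix (see [mean_traces_by_drug()]),
#'   or a precomputed compound distance matrix when `metric = NULL`.
#' @param metric distance function over trace rows, or `NULL`.
#' @param layout_fun the 2-D layout engine.
#' @param n_neighbors,min_dist neighborhood parameters forwarded to
#'   `layout_fun` (inert under the MDS default; conventional values are 10
#'   and 0.1 for a single dataset and `n_neighbors = 50` for joint maps of
#'   two datasets).
#' @param seed seed forwarded to `layout_fun`.
#' @return an `n x 2` coordinate matrix with compound rownames.
#' @export
behaviorome_map <- function(mean_traces, metric = correlation_distance,
                            layout_fun = layout_cmds,
                            n_neighbors = 10, min_dist = 0.1, seed = 1) {
  D <- if (is.null(metric)) as.matrix(mean_traces)
       else pairwise_distance_matrix(mean_traces, metric)
  if (nrow(D) < n_neighbors + 1)
    stop_data("need at least n_neighbors + 1 = ", n_neighbors + 1, " compounds")
  coords <- layout_fun(D, n_neighbors = n_neighbors, min_dist = min_dist, seed = seed)
  rownames(coords) <- rownames(D)
  coords
}

#' @describeIn behaviorome_map classical-MDS layout engine over a
#'   precomputed distance matrix.
#' @param D precomputed symmetric distance matrix.
#' @export
layout_cmds <- function(D, n_neighbors = NULL, min_dist = NULL, seed = NULL) {
  coords <- stats::cmdscale(stats::as.dist(D), k = 2)
  if (ncol(coords) < 2)     # degenerate input (e.g. all-zero distances)
    coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  coords
}

# Mean silhouette width of integer/character labels on 2-D coordinates.
silhouette_score <- function(coords, labels) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(D[i, labels == l]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}
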
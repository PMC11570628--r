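#' Drug-wise train/test split
#'
#' Partitions drug ids (not wells) into disjoint train and test sets, so no
#' replicate of any drug appears on both sides — the split that forces a
#' metric-learning model to generalize across compounds rather than
#' memorize them. Controls are not part of the split; both splits may draw
#' control pairs.
#'
#' @param drug_ids character vector of drug identifiers.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors (disjoint,
#'   exhaustive).
#' @export
split_by_drug <- function(drug_ids, fraction = 0.8, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop_param("fraction must be in (0, 1)")
  drug_ids <- unique(drug_ids)
  if (length(drug_ids) < 2L) stop_data("need at least 2 drugs to split")
  train <- with_seed(child_seed(seed, "drug_split"),
                     sample(drug_ids, round(fraction * length(drug_ids))))
  list(train = sort(train), test = sort(setdiff(drug_ids, train)))
}

#' Build a labeled pair dataset for metric learning
#'
#' Constructs positive (matched) and negative (mismatched) well pairs per
#' split. Candidate positives are all unordered same-drug replicate pairs in
#' which both members are labeled `active` (pairs touching an inactive or
#' lethal member are excluded — labeling replicates of an ineffective drug
#' "positive" would be misleading); drug-drug negatives are sampled from
#' cross-drug active pairs. Negatives are subsampled to match the positives
#' exactly. On top of the drug-drug pairs, 25% of the final positives are
#' drawn from control-control and tox-tox pairs (evenly) and 25% of the
#' final negatives from control-drug, control-tox and tox-drug pairs (evenly
#' up to rounding), exposing the model to the pair types a screen actually
#' contains. Vehicle wells are exempt from activity filtering and lethal
#' controls feed the tox buckets regardless of the forest's output. When a
#' quota bucket lacks candidates its shortfall is reallocated proportionally
#' to the remaining buckets, with a warning.
#'
#' @param dataset a `screen_dataset`.
#' @param labels a labels table from [label_wells()] (or any data.frame with
#'   `well_id` and `label`).
#' @param drug_split a list from [split_by_drug()].
#' @param quota_pos_ctrl,quota_neg_ctrl fraction of final positives /
#'   negatives drawn from the control/tox buckets.
#' @param seed integer seed.
#' @return a `pair_dataset` data.frame with columns `index_a`, `index_b`
#'   (row indices into `dataset$traces`), `label` (`same`/`different`),
#'   `pair_class`, `split`; provenance in attributes.
#' @export
build_pairs <- function(dataset, labels, drug_split,
                        quota_pos_ctrl = 0.25, quota_neg_ctrl = 0.25, seed = 1) {
  stopifnot(inherits(dataset, "screen_dataset"))
  wells <- dataset$wells
  lab <- labels$label[match(wells$well_id, labels$well_id)]
  if (anyNA(lab)) stop_data("labels missing for some wells")
  active_drug_well <- wells$role == "drug" & lab == "active"
  ctrl_wells <- which(wells$role == "vehicle")
  tox_wells <- which(wells$role == "lethal")

  build_split <- function(split_name, drugs, sseed) {
    dd_wells <- lapply(drugs, function(d)
      which(active_drug_well & wells$treatment_id == d))
    names(dd_wells) <- drugs
    # (i) all same-drug active pairs
    pos_dd <- do.call(rbind, lapply(drugs, function(d) {
      w <- dd_wells[[d]]
      if (length(w) < 2L) return(NULL)
      cbind(t(utils::combn(w, 2L)))
    }))
    if (is.null(pos_dd) || nrow(pos_dd) == 0L)
      stop_data("no candidate positive pairs in ", split_name, " split")
    n_dd <- nrow(pos_dd)
    # quota arithmetic: drug-drug pairs are (1 - quota) of the final total
    total_pos <- round(n_dd / (1 - quota_pos_ctrl))
    n_ctrl_pos <- total_pos - n_dd
    total_neg <- total_pos
    n_dd_neg <- total_neg - round(quota_neg_ctrl * total_neg)
    n_mixed <- total_neg - n_dd_neg

    with_seed(sseed, {
      pos_cc <- sample_pairs_within(ctrl_wells, even_split(n_ctrl_pos, 2)[1])
      pos_tt <- sample_pairs_within(tox_wells, even_split(n_ctrl_pos, 2)[2])
      short_pos <- n_ctrl_pos - nrow(pos_cc) - nrow(pos_tt)
      if (short_pos > 0) {
        warning("control/tox positive quota short by ", short_pos,
                " pairs in ", split_name, " split; reallocating to drug-drug")
        total_pos <- total_pos - short_pos
        total_neg <- total_pos
        n_dd_neg <- total_neg - round(quota_neg_ctrl * total_neg)
        n_mixed <- total_neg - n_dd_neg
      }
      all_drug <- unlist(dd_wells)
      neg_dd <- sample_pairs_across(dd_wells, n_dd_neg)
      m3 <- even_split(n_mixed, 3)
      neg_cd <- sample_pairs_between(ctrl_wells, all_drug, m3[1])
      neg_ct <- sample_pairs_between(ctrl_wells, tox_wells, m3[2])
      neg_td <- sample_pairs_between(tox_wells, all_drug, m3[3])
      short_neg <- n_mixed - nrow(neg_cd) - nrow(neg_ct) - nrow(neg_td)
      if (short_neg > 0) {
        warning("mixed negative quota short by ", short_neg,
                " pairs in ", split_name, " split; reallocating to drug-drug")
        extra <- sample_pairs_across(dd_wells, n_dd_neg + short_neg)
        neg_dd <- extra
      }
      mk <- function(m, label, cls) {
        if (is.null(m) || nrow(m) == 0L) return(NULL)
        data.frame(index_a = m[, 1], index_b = m[, 2], label = label,
                   pair_class = cls, split = split_name, stringsAsFactors = FALSE)
      }
      out <- rbind(mk(pos_dd, "same", "drug-drug+"),
                   mk(pos_cc, "same", "control-control"),
                   mk(pos_tt, "same", "tox-tox"),
                   mk(neg_dd, "different", "drug-drug-"),
                   mk(neg_cd, "different", "control-drug"),
                   mk(neg_ct, "different", "control-tox"),
                   mk(neg_td, "different", "tox-drug"))
      # enforce exact positive/negative balance after any reallocation
      n_pos <- sum(out$label == "same"); n_neg <- sum(out$label == "different")
      if (n_neg > n_pos) {
        drop <- sample(which(out$label == "different" & out$pair_class == "drug-drug-"),
                       n_neg - n_pos)
        out <- out[-drop, ]
      } else if (n_pos > n_neg) {
        drop <- sample(which(out$label == "same" & out$pair_class == "drug-drug+"),
                       n_pos - n_neg)
        out <- out[-drop, ]
      }
      out
    })
  }

  res <- rbind(build_split("train", drug_split$train, child_seed(seed, "pairs_train")),
               build_split("test", drug_split$test, child_seed(seed, "pairs_test")))
  rownames(res) <- NULL
  structure(res, class = c("pair_dataset", "data.frame"),
            provenance = list(seed = seed,
                              quota_pos_ctrl = quota_pos_ctrl,
                              quota_neg_ctrl = quota_neg_ctrl,
                              n_wells = nrow(wells)))
}

even_split <- function(n, k) {
  base <- n %/% k
  extra <- n - base * k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

# All C(n,2) pairs within a well set, subsampled to `n_want`.
sample_pairs_within <- function(wells, n_want) {
  if (n_want <= 0 || length(wells) < 2L) return(matrix(integer(), 0, 2))
  all_pairs <- t(utils::combn(wells, 2L))
  if (nrow(all_pairs) <= n_want) return(all_pairs)
  all_pairs[sample.int(nrow(all_pairs), n_want), , drop = FALSE]
}

# Cross-drug pairs: sample index pairs from different drugs without
# duplicates.
sample_pairs_across <- function(dd_wells, n_want) {
  dd_wells <- dd_wells[vapply(dd_wells, length, 0L) > 0]
  if (n_want <= 0 || length(dd_wells) < 2L) return(matrix(integer(), 0, 2))
  drug_of <- rep(seq_along(dd_wells), vapply(dd_wells, length, 0L))
  wells <- unlist(dd_wells)
  n <- length(wells)
  # enumerate when feasible, otherwise rejection-sample unique pairs
  n_cross <- (n * (n - 1)) %/% 2 - sum(vapply(dd_wells, function(w)
    length(w) * (length(w) - 1) %/% 2, 0))
  if (n_cross <= max(4 * n_want, 20000)) {
    all_pairs <- t(utils::combn(seq_len(n), 2L))
    keep <- drug_of[all_pairs[, 1]] != drug_of[all_pairs[, 2]]
    all_pairs <- all_pairs[keep, , drop = FALSE]
    sel <- if (nrow(all_pairs) <= n_want) seq_len(nrow(all_pairs))
           else sample.int(nrow(all_pairs), n_want)
    cbind(wells[all_pairs[sel, 1]], wells[all_pairs[sel, 2]])
  } else {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, n_want, 2)
    got <- 0L
    while (got < n_want) {
      i <- sample.int(n, 1L); j <- sample.int(n, 1L)
      if (drug_of[i] == drug_of[j]) next
      a <- min(wells[i], wells[j]); b <- max(wells[i], wells[j])
      key <- paste0(a, "_", b)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      out[got, ] <- c(a, b)
    }
    out
  }
}

sample_pairs_between <- function(set_a, set_b, n_want) {
  if (n_want <= 0 || length(set_a) == 0L || length(set_b) == 0L)
    return(matrix(integer(), 0, 2))
  grid <- expand.grid(a = set_a, b = set_b)
  grid <- grid[grid$a != grid$b, ]
  sel <- if (nrow(grid) <= n_want) seq_len(nrow(grid))
         else sample.int(nrow(grid), n_want)
  cbind(grid$a[sel], grid$b[sel])
}
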
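#' Stimulus schedule for a behavioral assay
#'
#' An ordered set of non-overlapping epochs covering `[0, trace_length)`
#' frames, each tagged with a stimulus kind (`dark`, `blue_light`,
#' `purple_light`, `acoustic`, `tap`). The schedule drives the simulator's
#' stimulus-locked response templates; `frame_rate` is carried as metadata
#' only.
#'
#' @param trace_length total number of frames.
#' @param frame_rate frames per second (metadata).
#' @param epochs optional data.frame with 0-based `start_frame`,
#'   (exclusive) `end_frame` and `stimulus_kind`; when omitted, a default
#'   assay block structure of alternating dark and stimulus periods is laid
#'   out proportionally over the trace.
#' @return a `stimulus_schedule` data.frame with a `frame_rate` attribute.
#' @export
stimulus_schedule <- function(trace_length, frame_rate = 120, epochs = NULL) {
  kinds <- c("dark", "blue_light", "purple_light", "acoustic", "tap")
  if (is.null(epochs)) {
    frac <- c(0, .12, .20, .28, .33, .45, .53, .60, .64, .76, .84, .90, .94, 1)
    kind <- c("dark", "blue_light", "dark", "acoustic", "dark", "purple_light",
              "dark", "tap", "dark", "blue_light", "dark", "acoustic", "dark")
    cut <- round(frac * trace_length)
    epochs <- data.frame(start_frame = cut[-length(cut)], end_frame = cut[-1],
                         stimulus_kind = kind)
  }
  epochs <- epochs[order(epochs$start_frame), ]
  with(epochs, {
    if (!all(stimulus_kind %in% kinds))
      stop_param("unknown stimulus kind(s): ",
                 paste(setdiff(stimulus_kind, kinds), collapse = ", "))
    if (any(end_frame <= start_frame)) stop_param("epochs must have end > start")
    if (epochs$start_frame[1] != 0 || utils::tail(end_frame, 1) != trace_length ||
        any(utils::head(end_frame, -1) != utils::tail(start_frame, -1)))
      stop_param("epochs must tile [0, trace_length) without gaps or overlap")
  })
  structure(epochs, class = c("stimulus_schedule", "data.frame"),
            frame_rate = frame_rate, trace_length = trace_length)
}

#' Synthetic screen configuration
#'
#' Parameterizes the seeded screen simulator. The defaults emulate the
#' structure of a high-replicate 96-well behavioral screen: 7-10 replicate
#' plates, per-plate vehicle (8 DMSO + 2 H2O, treated identically) and 2
#' lethal (eugenol) control wells, stimulus-locked response templates per
#' phenotype class, replicate-level response jitter, a fraction of inactive
#' drugs indistinguishable from vehicle, and an optional well-position-keyed
#' high-frequency artifact for shortcut-learning experiments.
#'
#' @param n_drugs number of pseudo-drugs.
#' @param n_phenotype_classes number of distinct response classes.
#' @param replicates_per_drug inclusive integer range; each drug's replicate
#'   count is drawn uniformly (seeded) from it.
#' @param n_plates number of replicate plates; defaults to
#'   `max(replicates_per_drug)`.
#' @param inactive_fraction fraction of drugs whose template equals the
#'   vehicle template.
#' @param trace_length frames per trace (desk-scale default 5000; the
#'   canonical full-resolution length is 101,250).
#' @param layout_mode `"fixed"` (every replicate of a drug at the same
#'   (row, col) on every plate, as in supplier-preset layouts) or
#'   `"randomized"` (seeded per-plate permutation of the treatments).
#' @param artifact_amplitude amplitude (MI units) of the planted positional
#'   artifact; 0 disables it.
#' @param noise_scale standard deviation (MI units) of the smooth
#'   low-frequency replicate noise.
#' @param hf_noise_sd standard deviation of the per-frame high-frequency
#'   sensor noise.
#' @param rep_gain_sd per-replicate, per-epoch response-gain jitter (sd of a
#'   multiplicative lognormal factor): replicates respond to each assay
#'   epoch with varying strength.
#' @param amp_scale_sd per-well global amplitude jitter (sd of a
#'   multiplicative lognormal factor), modeling well-to-well differences in
#'   overall vigor and fish count.
#' @param shift_frac maximum replicate time misalignment as a fraction of
#'   the trace length.
#' @param class_separation scales the between-class spread of epoch response
#'   gains and latencies; the separability dial.
#' @param controls_vehicle,controls_lethal control wells per plate.
#' @param n_targets size of the ground-truth binary target vocabulary.
#' @param max_mi saturation bound of the motion index (MI units).
#' @param frame_rate frames per second (metadata).
#' @param seed integer master seed; identical configs give bit-identical
#'   datasets.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_drugs = 24, n_phenotype_classes = 8,
                       replicates_per_drug = c(7, 10), n_plates = NULL,
                       inactive_fraction = 0.25,
                       trace_length = 5000,
                       layout_mode = c("randomized", "fixed"),
                       artifact_amplitude = 0,
                       noise_scale = 40, hf_noise_sd = 15,
                       rep_gain_sd = 0.3, amp_scale_sd = 0.2, shift_frac = 0.012,
                       class_separation = 1,
                       controls_vehicle = 10, controls_lethal = 2,
                       n_targets = 32, max_mi = 6750, frame_rate = 120,
                       seed = 1) {
  layout_mode <- match.arg(layout_mode)
  if (inactive_fraction < 0 || inactive_fraction > 1)
    stop_param("inactive_fraction must be in [0, 1]")
  if (artifact_amplitude < 0 || noise_scale < 0)
    stop_param("artifact_amplitude and noise_scale must be >= 0")
  if (length(replicates_per_drug) == 1L)
    replicates_per_drug <- rep(replicates_per_drug, 2L)
  n_plates <- as.integer(n_plates %||% max(replicates_per_drug))
  if (n_plates < max(replicates_per_drug))
    stop_param("n_plates must cover max(replicates_per_drug)")
  n_controls <- controls_vehicle + controls_lethal
  if (n_drugs + n_controls > 96)
    stop_param("capacity exceeded: ", n_drugs, " drugs + ", n_controls,
               " controls = ", n_drugs + n_controls, " wells > 96 available (",
               n_drugs + n_controls - 96, " over)")
  structure(list(
    n_drugs = as.integer(n_drugs), wells_per_plate = 96L,
    n_phenotype_classes = as.integer(n_phenotype_classes),
    replicates_per_drug = as.integer(replicates_per_drug),
    n_plates = n_plates, inactive_fraction = inactive_fraction,
    trace_length = as.integer(trace_length), layout_mode = layout_mode,
    artifact_amplitude = artifact_amplitude, noise_scale = noise_scale,
    hf_noise_sd = hf_noise_sd, rep_gain_sd = rep_gain_sd,
    amp_scale_sd = amp_scale_sd,
    shift_frac = shift_frac, class_separation = class_separation,
    controls_vehicle = as.integer(controls_vehicle),
    controls_lethal = as.integer(controls_lethal),
    n_targets = as.integer(n_targets), max_mi = max_mi,
    frame_rate = frame_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

drug_ids <- function(config) sprintf("drug_%03d", seq_len(config$n_drugs))

#' Generate plate layouts
#'
#' Assigns treatments to wells on every plate. In `fixed` mode each drug
#' occupies the same (row, col) on every plate it appears on — emulating
#' supplier-preset layouts in which all replicates of a compound share a
#' plate location. In `randomized` mode the treatment-to-well assignment is
#' an independent seeded permutation per plate. Each plate carries the
#' configured vehicle and lethal control wells; when a drug is absent from a
#' plate (it has fewer replicates than there are plates) its well reverts to
#' vehicle.
#'
#' @param config a [sim_config()].
#' @return a data.frame of well records: `well_id`, `plate_id`, 0-based
#'   `row` and `col`, `treatment_id`, `role`
#'   (`drug`/`vehicle`/`lethal`), `replicate_index`.
#' @export
generate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- drug_ids(config)
  n_rep <- with_seed(child_seed(config$seed, "replicates"), {
    r <- config$replicates_per_drug
    if (r[1] == r[2]) rep(r[1], config$n_drugs)
    else r[1] + sample.int(r[2] - r[1] + 1L, config$n_drugs, replace = TRUE) - 1L
  })
  # which plates each drug appears on
  presence <- with_seed(child_seed(config$seed, "presence"), {
    lapply(seq_len(config$n_drugs), function(d)
      sort(sample.int(config$n_plates, n_rep[d])))
  })
  controls <- c(rep("DMSO", max(0L, config$controls_vehicle - 2L)),
                rep("H2O", min(2L, config$controls_vehicle)),
                rep("EUG", config$controls_lethal))
  base_slots <- c(ids, controls,
                  rep("DMSO", 96L - config$n_drugs - length(controls)))
  rows <- list()
  rep_count <- stats::setNames(integer(config$n_drugs), ids)
  for (p in seq_len(config$n_plates)) {
    slots <- base_slots
    absent <- ids[!vapply(presence, function(x) p %in% x, TRUE)[seq_along(ids)]]
    slots[slots %in% absent] <- "DMSO"
    if (config$layout_mode == "randomized") {
      slots <- with_seed(child_seed(config$seed, "layout", p), sample(slots))
    }
    row <- (seq_len(96L) - 1L) %/% 12L
    col <- (seq_len(96L) - 1L) %% 12L
    role <- ifelse(slots %in% ids, "drug",
                   ifelse(slots == "EUG", "lethal", "vehicle"))
    rep_idx <- integer(96L)
    is_drug <- role == "drug"
    rep_count[slots[is_drug]] <- rep_count[slots[is_drug]] + 1L
    rep_idx[is_drug] <- rep_count[slots[is_drug]]
    plate_id <- sprintf("P%02d", p)
    rows[[p]] <- data.frame(
      well_id = paste0(plate_id, "_", well_name(row, col)),
      plate_id = plate_id, row = row, col = col,
      treatment_id = slots, role = role, replicate_index = rep_idx,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-class response templates, rows = classes (row 1 = vehicle, row K+1+1 =
# lethal handled separately). Returns a matrix (n_classes + 1) x L where row
# 1 is the vehicle template.
class_templates <- function(config, schedule) {
  L <- config$trace_length
  sep <- config$class_separation
  stim <- schedule[schedule$stimulus_kind != "dark", ]
  base_amp <- c(blue_light = 650, purple_light = 550, acoustic = 950, tap = 1150)
  baseline <- 150
  K <- config$n_phenotype_classes
  out <- matrix(baseline, K + 1L, L)
  for (cl in 0:K) {                       # class 0 = vehicle
    pars <- with_seed(child_seed(config$seed, "class", cl), {
      ne <- nrow(stim)
      # active classes are distinctly hypo- or hyper-responsive per epoch
      # (ineffective, vehicle-like compounds are modeled by inactive_fraction)
      dir <- sample(c(-1, 1), ne, replace = TRUE)
      list(gain = if (cl == 0) rep(1, ne) else
             pmax(0.05, 1 + sep * dir * stats::runif(ne, 0.35, 0.8)),
           latency = if (cl == 0) rep(8, ne) else
             round(8 + sep * stats::runif(ne, 0, 25)),
           tau = if (cl == 0) rep(0.15, ne) else
             0.15 * exp(sep * stats::runif(ne, -0.7, 0.7)),
           plateau = if (cl == 0) rep(0.25, ne) else
             pmin(0.9, pmax(0, 0.25 + sep * stats::runif(ne, -0.25, 0.5))),
           base_gain = if (cl == 0) 1 else pmax(0.2, 1 + sep * stats::runif(1, -0.5, 0.5)))
    })
    tpl <- rep(baseline * pars$base_gain, L)
    for (e in seq_len(nrow(stim))) {
      s <- stim$start_frame[e]; en <- stim$end_frame[e]
      epoch_len <- en - s
      t <- seq.int(s, en - 1L)
      onset <- s + pars$latency[e]
      # onset burst decaying toward a class-specific sustained plateau
      resp <- ifelse(t >= onset,
                     pars$plateau[e] + (1 - pars$plateau[e]) *
                       exp(-(t - onset) / (pars$tau[e] * epoch_len)), 0)
      amp <- base_amp[[stim$stimulus_kind[e]]] * pars$gain[e]
      tpl[t + 1L] <- tpl[t + 1L] + amp * resp
    }
    out[cl + 1L, ] <- tpl
  }
  out
}

# Smooth (low-frequency) noise of sd `scale`: iid Gaussian noise filtered
# with a wide Hanning window, rescaled to the target sd.
smooth_noise <- function(L, scale) {
  if (scale == 0) return(numeric(L))
  w <- min(51L, if (L %% 2 == 0) L - 1L else L)
  x <- smooth_hanning(stats::rnorm(L), window = w)
  x / stats::sd(x) * scale
}

#' Generate a synthetic screen
#'
#' Simulates well-level MI traces for every well of the configured layout.
#' Each drug inherits its phenotype class template (stimulus-locked response
#' bursts with class-specific gains, latencies and decay constants) with a
#' small per-drug modulation; each replicate is perturbed by a time shift, a
#' global amplitude scale, per-epoch response-gain jitter, smooth
#' low-frequency noise and per-frame high-frequency sensor noise. Vehicle
#' wells and inactive drugs follow the vehicle template; lethal wells show
#' near-zero motion. Traces are clipped to `[0, max_mi]`. If
#' `artifact_amplitude > 0` the positional artifact of
#' [plant_positional_artifact()] is applied.
#'
#' @param config a [sim_config()].
#' @return a list with components `dataset` (a `screen_dataset`: `traces`
#'   matrix wells x frames, `wells` records, `schedule`, `config`) and
#'   `ground_truth` (`class_of_drug`, `active`, `target_profile`,
#'   `artifact_field`, `class_templates`).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  wells <- generate_layout(config)
  schedule <- stimulus_schedule(config$trace_length, config$frame_rate)
  L <- config$trace_length
  ids <- drug_ids(config)
  K <- config$n_phenotype_classes

  tpl <- class_templates(config, schedule)
  truth <- with_seed(child_seed(config$seed, "truth"), {
    n_inactive <- round(config$inactive_fraction * config$n_drugs)
    inactive <- sample(ids, n_inactive)
    cls <- stats::setNames(sample(rep_len(seq_len(K), config$n_drugs)), ids)
    list(class_of_drug = cls,
         active = stats::setNames(!(ids %in% inactive), ids))
  })

  # per-drug template: class template with mild per-drug epoch-gain tweaks
  stim <- schedule[schedule$stimulus_kind != "dark", ]
  drug_tpl <- matrix(NA_real_, config$n_drugs, L, dimnames = list(ids, NULL))
  for (d in seq_along(ids)) {
    base <- if (!truth$active[d]) tpl[1L, ] else tpl[truth$class_of_drug[d] + 1L, ]
    g <- with_seed(child_seed(config$seed, "drug", d),
                   stats::rnorm(nrow(stim), 1, 0.05))
    t <- base
    if (truth$active[d]) {
      pivot <- min(base)
      for (e in seq_len(nrow(stim))) {
        idx <- (stim$start_frame[e] + 1L):stim$end_frame[e]
        t[idx] <- (t[idx] - pivot) * g[e] + pivot
      }
    }
    drug_tpl[d, ] <- t
  }

  traces <- matrix(0, nrow(wells), L)
  rownames(traces) <- wells$well_id
  stim_epochs <- lapply(seq_len(nrow(stim)), function(e)
    (stim$start_frame[e] + 1L):stim$end_frame[e])
  for (w in seq_len(nrow(wells))) {
    role <- wells$role[w]
    tr <- with_seed(child_seed(config$seed, "well", wells$well_id[w]), {
      if (role == "lethal") {
        abs(stats::rnorm(L, 0, 3))
      } else {
        base <- if (role == "vehicle") tpl[1L, ] else drug_tpl[wells$treatment_id[w], ]
        shift <- round(stats::runif(1, -1, 1) * config$shift_frac * L)
        x <- shift_trace(base, shift)
        gains <- exp(stats::rnorm(length(stim_epochs), 0, config$rep_gain_sd))
        for (e in seq_along(stim_epochs)) {
          idx <- stim_epochs[[e]]
          x[idx] <- (x[idx] - 150) * gains[e] + 150
        }
        x <- x * exp(stats::rnorm(1, 0, config$amp_scale_sd))
        x + smooth_noise(L, config$noise_scale) +
          stats::rnorm(L, 0, config$hf_noise_sd)
      }
    })
    traces[w, ] <- pmin(pmax(tr, 0), config$max_mi)
  }

  target_profile <- with_seed(child_seed(config$seed, "targets"), {
    class_targets <- lapply(seq_len(K), function(cl)
      sample.int(config$n_targets, 3L))
    prof <- matrix(0L, config$n_drugs, config$n_targets,
                   dimnames = list(ids, sprintf("T%02d", seq_len(config$n_targets))))
    for (d in seq_along(ids)) {
      tg <- if (truth$active[d]) class_targets[[truth$class_of_drug[d]]]
            else sample.int(config$n_targets, 1L)
      if (stats::runif(1) < 0.5) tg <- union(tg, sample.int(config$n_targets, 1L))
      prof[d, tg] <- 1L
    }
    prof
  })

  dataset <- structure(list(traces = traces, wells = wells, schedule = schedule,
                            config = config,
                            provenance = list(seed = config$seed, source = "twinphen simulator")),
                       class = "screen_dataset")
  field <- artifact_field()
  ground_truth <- list(class_of_drug = truth$class_of_drug, active = truth$active,
                       target_profile = target_profile,
                       artifact_field = field, class_templates = tpl)
  if (config$artifact_amplitude > 0)
    dataset <- plant_positional_artifact(dataset, config$artifact_amplitude)
  list(dataset = dataset, ground_truth = ground_truth)
}

shift_trace <- function(x, shift) {
  L <- length(x)
  if (shift == 0) return(x)
  if (shift > 0) c(rep(x[1], shift), x[seq_len(L - shift)])
  else c(x[(-shift + 1):L], rep(x[L], -shift))
}

# Deterministic smooth per-position artifact descriptor for a 96-well plate.
artifact_field <- function() {
  pos <- expand.grid(row = 0:7, col = 0:11)
  data.frame(pos,
             amp_scale = 0.6 + 0.4 * sin(pi * pos$row / 7) * cos(pi * pos$col / 11),
             phase = 2 * pi * (0.35 * pos$row / 7 + 0.65 * pos$col / 11))
}

#' Plant a well-position-keyed high-frequency artifact
#'
#' Adds a deterministic near-Nyquist sinusoid to every trace whose amplitude
#' and phase vary smoothly with the well's (row, col) position — a model of
#' position-dependent instrumentation effects (e.g. differences in distance
#' to directional light and sound sources) imprinted in the high-frequency
#' band. Two wells at the same plate position always receive the identical
#' component, which in a fixed layout makes plate position a learnable
#' shortcut for treatment identity. The default frequency (0.425 cycles per
#' frame) is far above the behavioral band, so Hanning smoothing with a
#' window of 11 removes nearly all of its power; under stride-5 subsampling
#' it aliases to a slow 0.125 cycles-per-sample oscillation, mimicking how
#' undersampled instrumentation vibrations fold into the model's input band.
#' `amplitude = 0` returns the dataset unchanged.
#'
#' @param dataset a `screen_dataset`.
#' @param amplitude artifact amplitude in MI units (scaled per position by a
#'   smooth field in `[0.2, 1]`).
#' @param frequency cycles per frame of the planted sinusoid.
#' @return the dataset with modified traces (clipped to `[0, max_mi]`).
#' @export
plant_positional_artifact <- function(dataset, amplitude, frequency = 0.425) {
  stopifnot(inherits(dataset, "screen_dataset"))
  if (amplitude < 0) stop_param("amplitude must be >= 0")
  if (amplitude == 0) return(dataset)
  field <- artifact_field()
  L <- ncol(dataset$traces)
  t <- seq_len(L) - 1L
  key <- match(paste(dataset$wells$row, dataset$wells$col),
               paste(field$row, field$col))
  for (w in seq_len(nrow(dataset$traces))) {
    comp <- amplitude * field$amp_scale[key[w]] *
      sin(2 * pi * frequency * t + field$phase[key[w]])
    dataset$traces[w, ] <- pmin(pmax(dataset$traces[w, ] + comp, 0),
                                dataset$config$max_mi)
  }
  dataset$provenance$artifact_amplitude <- amplitude
  dataset
}

#' Synthetic structural fingerprints for simulated drugs
#'
#' Generates family-structured binary fingerprints: drugs in the same
#' structural family share a set of characteristic bits (high within-family
#' Tanimoto similarity), families are bit-disjoint (low cross-family
#' similarity), and every drug carries additional random background bits. By
#' default the structural family equals the phenotype class; `split_class`
#' divides one class's drugs between two disjoint families, creating
#' ground-truth scaffold-hopping pairs (same phenotype, different
#' chemotype).
#'
#' @param ground_truth the `ground_truth` component of [generate_screen()].
#' @param n_bits fingerprint length.
#' @param bits_per_family characteristic bits per family.
#' @param split_class optional phenotype class (integer) whose drugs are
#'   split across two structural families.
#' @param seed integer seed.
#' @return a list: `fingerprints` (drugs x bits 0/1 matrix) and `family`
#'   (named vector of family labels).
#' @export
synthetic_fingerprints <- function(ground_truth, n_bits = 256,
                                   bits_per_family = 24, split_class = NULL,
                                   seed = 1) {
  cls <- ground_truth$class_of_drug
  ids <- names(cls)
  family <- paste0("fam_", cls)
  if (!is.null(split_class)) {
    members <- which(cls == split_class)
    half <- with_seed(child_seed(seed, "split"),
                      sample(members, ceiling(length(members) / 2)))
    family[half] <- paste0("fam_", split_class, "b")
  }
  names(family) <- ids
  fams <- unique(family)
  with_seed(child_seed(seed, "fp"), {
    pool <- sample.int(n_bits)
    need <- length(fams) * bits_per_family
    if (need > n_bits) stop_param("n_bits too small for ", length(fams), " families")
    fam_bits <- split(pool[seq_len(need)], rep(fams, each = bits_per_family))
    fp <- matrix(0L, length(ids), n_bits,
                 dimnames = list(ids, NULL))
    for (d in seq_along(ids)) {
      on <- fam_bits[[family[d]]][stats::runif(bits_per_family) < 0.9]
      extra <- sample(setdiff(seq_len(n_bits), unlist(fam_bits)),
                      min(6L, n_bits - need))
      fp[d, c(on, extra)] <- 1L
    }
    list(fingerprints = fp, family = family)
  })
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset:", nrow(x$traces), "wells x", ncol(x$traces), "frames;",
      x$config$n_drugs, "drugs on", x$config$n_plates, "plates (",
      x$config$layout_mode, "layout )\n")
  invisible(x)
}
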
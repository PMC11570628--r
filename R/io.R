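#' Write / read a screen dataset
#'
#' The native on-disk layout is a directory holding `wells.csv` (well
#' metadata), `schedule.csv` (stimulus epochs), `provenance.json`, and the
#' traces either as `traces.csv` (well_id + one column per frame; the
#' default, convenient for desk-scale data) or as a raw little-endian
#' float64 array `traces.bin` (`dialect = "bin"`, for full-resolution
#' screens whose rows run to 100k frames). Reading normalizes well
#' coordinates to 0-based `row`/`col`; a 1-based input dialect
#' (`coord_base = 1`) is converted with a provenance note. Round-trips are
#' lossless.
#'
#' @param dataset a `screen_dataset`.
#' @param path directory to create/read.
#' @param dialect `"csv"` or `"bin"`.
#' @param ground_truth optional simulator ground truth; written as a JSON
#'   sidecar `ground_truth.json`.
#' @return `read_screen()` returns a `screen_dataset` (with
#'   `ground_truth` attached as an attribute when the sidecar exists).
#' @export
write_screen <- function(dataset, path, dialect = c("csv", "bin"),
                         ground_truth = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "screen_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dataset$wells, file.path(path, "wells.csv"))
  sch <- as.data.frame(dataset$schedule)
  data.table::fwrite(sch, file.path(path, "schedule.csv"))
  prov <- c(dataset$provenance,
            list(dialect = dialect, coord_base = 0,
                 n_wells = nrow(dataset$traces), n_frames = ncol(dataset$traces),
                 frame_rate = attr(dataset$schedule, "frame_rate"),
                 config = unclass(dataset$config)))
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (dialect == "csv") {
    tr <- data.table::data.table(well_id = rownames(dataset$traces))
    tr <- cbind(tr, data.table::as.data.table(dataset$traces))
    data.table::fwrite(tr, file.path(path, "traces.csv"))
  } else {
    con <- file(file.path(path, "traces.bin"), "wb")
    on.exit(close(con))
    writeBin(as.vector(t(dataset$traces)), con, size = 8, endian = "little")
  }
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    gt$class_templates <- NULL
    gt$class_of_drug <- as.list(gt$class_of_drug)
    gt$active <- as.list(gt$active)
    gt$target_profile <- list(ids = rownames(ground_truth$target_profile),
                              targets = colnames(ground_truth$target_profile),
                              matrix = unname(as.matrix(ground_truth$target_profile)))
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_screen
#' @export
read_screen <- function(path) {
  prov <- jsonlite::read_json(file.path(path, "provenance.json"),
                              simplifyVector = TRUE)
  wells <- as.data.frame(data.table::fread(file.path(path, "wells.csv")))
  if (anyDuplicated(wells[c("plate_id", "row", "col")]))
    stop_data("duplicate (plate, row, col) well records in ", path)
  if (anyDuplicated(wells$well_id)) stop_data("duplicate well ids in ", path)
  if (isTRUE(prov$coord_base == 1)) {
    wells$row <- wells$row - 1L
    wells$col <- wells$col - 1L
    prov$coord_base <- 0
    prov$note <- c(prov$note, "coordinates normalized from 1-based input")
  }
  if (identical(prov$dialect, "bin")) {
    con <- file(file.path(path, "traces.bin"), "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = prov$n_wells * prov$n_frames,
                 size = 8, endian = "little")
    traces <- matrix(v, nrow = prov$n_wells, byrow = TRUE)
    rownames(traces) <- wells$well_id
  } else {
    tr <- data.table::fread(file.path(path, "traces.csv"))
    if (nrow(tr) != nrow(wells))
      stop_data("trace rows (", nrow(tr), ") != well records (", nrow(wells), ")")
    traces <- as.matrix(tr[, -1])
    rownames(traces) <- tr[[1]]
    dimnames(traces)[[2]] <- NULL
  }
  sch <- as.data.frame(data.table::fread(file.path(path, "schedule.csv")))
  schedule <- stimulus_schedule(ncol(traces), prov$frame_rate %||% 120, epochs = sch)
  config <- prov$config
  if (!is.null(config)) class(config) <- "sim_config"
  ds <- structure(list(traces = traces, wells = wells, schedule = schedule,
                       config = config, provenance = prov),
                  class = "screen_dataset")
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    if (!is.null(gt$target_profile)) {
      m <- gt$target_profile$matrix
      dimnames(m) <- list(gt$target_profile$ids, gt$target_profile$targets)
      gt$target_profile <- m
    }
    gt$class_of_drug <- unlist(gt$class_of_drug)
    gt$active <- unlist(gt$active)
    attr(ds, "ground_truth") <- gt
  }
  ds
}

#' Write / read a pair table
#'
#' Pair tables are CSV files (`index_a`, `index_b`, `label`, `pair_class`,
#' `split`) with a JSON provenance sidecar (`<file>.json`).
#'
#' @param pairs a `pair_dataset`.
#' @param path CSV file path.
#' @export
write_pairs <- function(pairs, path) {
  data.table::fwrite(as.data.frame(pairs), path)
  prov <- attr(pairs, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path))
    jsonlite::read_json(prov_path, simplifyVector = TRUE) else NULL
  structure(out, class = c("pair_dataset", "data.frame"), provenance = prov)
}

#' Run configuration
#'
#' A nested configuration for the whole pipeline (simulator, activity
#' filter, pair builder, model, evaluation, stress tests, phenosearch) with
#' the conventional defaults, serializable to YAML with a lossless
#' round-trip.
#'
#' @param ... named overrides of the default sections (partial lists are
#'   merged over the defaults).
#' @param seed global seed recorded at the top level.
#' @return a `run_config` list.
#' @export
run_config <- function(..., seed = 1) {
  defaults <- list(
    seed = seed,
    sim = unclass(sim_config(seed = seed)),
    filter = list(mode = "ternary", split_fraction = 0.8, ntree = 500),
    pairs = list(fraction = 0.8, quota_pos_ctrl = 0.25, quota_neg_ctrl = 0.25),
    model = list(architecture = "twin_nn", input_length = 1000,
                 hidden_widths = c(200, 100, 50, 20), embedding_dim = 10,
                 margin = 0.5, learning_rate = 5e-4, weight_decay = 1e-6,
                 max_epochs = 60, subsample_stride = 5,
                 norm_lo = 0, norm_hi = 6750),
    eval = list(top_n = 50, knn_k = 15),
    stress = list(window = 11, cutoffs = c(2, 5.2)),
    phenosearch = list(top_k = 500, min_shared = 1)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]]))
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    else defaults[[nm]] <- over[[nm]]
  }
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Read a frame stack from image files or an array file
#'
#' Accepts a directory of per-frame grayscale PNG/TIFF images (sorted by
#' file name) or a single `.rds` file holding a `T x H x W` array, and
#' returns the array form consumed by [motion_index()]. Image intensities
#' in `[0, 1]` are rescaled to 8-bit units so the conventional threshold of
#' 10 applies.
#'
#' @param path directory of images or an `.rds` array file.
#' @return a `T x H x W` numeric array.
#' @export
read_frame_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) stop_data("need >= 2 frame images in ", path)
    read1 <- function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
          stop("reading PNG frames requires the 'png' package")
        img <- png::readPNG(f)
      } else {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("reading TIFF frames requires the 'tiff' package")
        img <- tiff::readTIFF(f)
      }
      if (length(dim(img)) == 3L) img <- img[, , 1L]   # first channel
      if (max(img) <= 1) img <- img * 255
      img
    }
    frames <- lapply(files, read1)
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop_shape("frame images differ in size")
    aperm(simplify2array(frames), c(3, 1, 2))
  } else {
    arr <- readRDS(path)
    if (!is.array(arr) || length(dim(arr)) != 3L)
      stop_shape("array file must hold a T x H x W array")
    arr
  }
}
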
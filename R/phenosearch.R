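#' Rank a compound library against query phenotypes
#'
#' For every query trace, ranks all library traces by ascending phenotypic
#' distance under the given metric and truncates to the `top_k` closest
#' matches — the "phenosearch" screen that surfaces library compounds
#' mimicking a known drug's behavioral phenotype. Ties are broken by library
#' id.
#'
#' @param query numeric matrix of query traces (rows named by compound id).
#' @param library numeric matrix of library traces (rows named by id).
#' @param metric distance function over trace rows, or a precomputed
#'   query-by-library distance matrix.
#' @param top_k ranking depth (default 500); a smaller library returns the
#'   full ranking.
#' @return a `phenosearch_result`: named list (per query) of data.frames
#'   with `library_id`, `distance`, `rank`.
#' @export
phenosearch_rank <- function(query, library, metric = correlation_distance,
                             top_k = 500) {
  if (is.function(metric)) {
    if (nrow(as.matrix(library)) == 0L) stop_data("empty library")
    D <- pairwise_distance_matrix(query, metric, Y = library)
  } else {
    D <- as.matrix(metric)
  }
  k <- min(top_k, ncol(D))
  res <- lapply(rownames(D) %||% seq_len(nrow(D)), function(q) {
    d <- D[q, ]
    ord <- order(d, colnames(D))[seq_len(k)]
    data.frame(library_id = colnames(D)[ord], distance = unname(d[ord]),
               rank = seq_len(k), stringsAsFactors = FALSE)
  })
  names(res) <- rownames(D)
  structure(res, class = "phenosearch_result", top_k = top_k,
            library_size = ncol(D))
}

#' Target-profile (MOA) enrichment curve for a phenosearch ranking
#'
#' A ranked library compound is a "hit" for a query when its binary target
#' profile shares at least `min_shared` predicted targets with the query's
#' profile. The curve reports cumulative hits against the fraction of the
#' ranked list examined; the analytic random baseline is the hypergeometric
#' mean `m * H / L` (`m` compounds examined among `L` with `H` total hits),
#' i.e. the expectation under a uniformly random ordering of the library.
#' A bootstrap band over queries is attached when several queries are given.
#'
#' @param rankings a `phenosearch_result`.
#' @param target_profiles compound-by-target 0/1 matrix covering queries and
#'   library compounds (compounds without a profile are excluded with a
#'   warning).
#' @param fractions grid of list fractions to evaluate.
#' @param min_shared minimum shared-target count that counts as a hit.
#' @param n_boot bootstrap resamples over queries for the confidence band
#'   (0 disables).
#' @param seed bootstrap seed.
#' @return a data.frame: `fraction`, `hits` (mean cumulative hits per
#'   query), `baseline` (analytic random expectation), and bootstrap
#'   `lo`/`hi` when requested.
#' @export
moa_enrichment <- function(rankings, target_profiles,
                           fractions = seq(0.1, 1, by = 0.1),
                           min_shared = 1, n_boot = 200, seed = 1) {
  stopifnot(inherits(rankings, "phenosearch_result"))
  per_query <- lapply(names(rankings), function(q) {
    if (!q %in% rownames(target_profiles)) {
      warning("no target profile for query ", q, "; excluded")
      return(NULL)
    }
    r <- rankings[[q]]
    known <- r$library_id %in% rownames(target_profiles)
    if (!all(known)) {
      warning(sum(!known), " ranked compounds lack target profiles for query ",
              q, "; excluded")
      r <- r[known, ]
    }
    shared <- as.vector(target_profiles[r$library_id, , drop = FALSE] %*%
                          target_profiles[q, ])
    hit <- shared >= min_shared
    n <- nrow(r)
    m <- pmax(1L, floor(fractions * n))
    data.frame(fraction = fractions,
               hits = cumsum(hit)[m],
               baseline = m * sum(hit) / n)
  })
  per_query <- Filter(Negate(is.null), per_query)
  if (length(per_query) == 0L) stop_data("no queries with target profiles")
  H <- sapply(per_query, `[[`, "hits")
  B <- sapply(per_query, `[[`, "baseline")
  if (is.null(dim(H))) { H <- matrix(H, nrow = length(fractions)); B <- matrix(B, nrow = length(fractions)) }
  out <- data.frame(fraction = fractions, hits = rowMeans(H), baseline = rowMeans(B))
  if (n_boot > 0 && ncol(H) > 1) {
    bs <- with_seed(child_seed(seed, "boot"), {
      replicate(n_boot, rowMeans(H[, sample.int(ncol(H), replace = TRUE), drop = FALSE]))
    })
    out$lo <- apply(bs, 1, stats::quantile, 0.025)
    out$hi <- apply(bs, 1, stats::quantile, 0.975)
  }
  out
}

#' Negative-control contamination of a phenosearch ranking
#'
#' Counts how many vehicle (negative-control) wells appear among each
#' query's ranked matches. A metric that cannot tell weak phenotypes from
#' vehicle lets controls flood the top of the list; a good phenotypic
#' distance keeps them out.
#'
#' @param rankings a `phenosearch_result` whose library ids are well ids.
#' @param well_roles named character vector: role (`drug`/`vehicle`/
#'   `lethal`) per library id.
#' @return a named integer vector of per-query vehicle counts, with the
#'   total as attribute `total`.
#' @export
control_contamination <- function(rankings, well_roles) {
  stopifnot(inherits(rankings, "phenosearch_result"))
  counts <- vapply(rankings, function(r)
    sum(well_roles[r$library_id] == "vehicle", na.rm = TRUE), 0L)
  structure(counts, total = sum(counts))
}

#' Tanimoto similarity between binary fingerprints
#'
#' `|a AND b| / |a OR b|` over bit vectors, the standard chemical
#' similarity on circular (ECFP4-style) fingerprints.
#' `tanimoto_distance()` is its complement. Two all-zero fingerprints have
#' no defined similarity; 0 is returned with a warning.
#'
#' @param a,b equal-length 0/1 vectors (or logical).
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2/4
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop_shape("fingerprint lengths differ: ", length(a), " vs ", length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) {
    warning("both fingerprints empty; Tanimoto similarity defined as 0")
    return(0)
  }
  sum(a & b) / u
}

#' @rdname tanimoto
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto(a, b)

#' Scaffold-hopping quadrant analysis
#'
#' Annotates every unordered compound pair with three quantities: chemical
#' structure distance (Tanimoto distance on fingerprints), phenotypic
#' distance (any metric, typically the learned twin distance on mean
#' traces), and target-profile Tanimoto similarity. Pairs are assigned to
#' quadrants at the axis cuts (`pheno_cut`, `struct_cut`); scaffold-hop
#' candidates are pairs with a low phenotypic distance, a high structural
#' distance and a corroborating target-profile similarity — structurally
#' unrelated molecules acting alike — ranked by target similarity.
#'
#' @param pheno_D symmetric compound-level phenotypic distance matrix with
#'   compound ids as dimnames.
#' @param fingerprints compound-by-bit 0/1 matrix.
#' @param target_profiles compound-by-target 0/1 matrix.
#' @param pheno_max,struct_min,target_min candidate thresholds: phenotypic
#'   distance < `pheno_max` (default 0.3), structure distance >
#'   `struct_min` (default 0.5), target similarity > `target_min` (default
#'   0.2).
#' @param pheno_cut,struct_cut quadrant axis cuts (defaults 0.3 and 0.4).
#' @return a data.frame of all annotated pairs: `id_a`, `id_b`,
#'   `struct_dist`, `pheno_dist`, `target_sim`, `quadrant` (e.g.
#'   `"low-pheno/high-struct"`), `candidate`; candidates sorted first by
#'   descending target similarity.
#' @export
quadrant_analysis <- function(pheno_D, fingerprints, target_profiles,
                              pheno_max = 0.3, struct_min = 0.5, target_min = 0.2,
                              pheno_cut = 0.3, struct_cut = 0.4) {
  ids <- rownames(pheno_D)
  usable <- ids %in% rownames(fingerprints) & ids %in% rownames(target_profiles)
  if (!all(usable)) {
    warning(sum(!usable), " compounds lack a fingerprint or target profile; excluded")
    ids <- ids[usable]
  }
  if (length(ids) < 2L) stop_data("fewer than 2 annotatable compounds")
  combos <- t(utils::combn(ids, 2L))
  ann <- data.frame(id_a = combos[, 1], id_b = combos[, 2], stringsAsFactors = FALSE)
  ann$struct_dist <- apply(combos, 1L, function(p)
    tanimoto_distance(fingerprints[p[1], ], fingerprints[p[2], ]))
  ann$pheno_dist <- pheno_D[combos]
  ann$target_sim <- apply(combos, 1L, function(p)
    suppressWarnings(tanimoto(target_profiles[p[1], ], target_profiles[p[2], ])))
  ann$quadrant <- paste0(ifelse(ann$pheno_dist < pheno_cut, "low-pheno", "high-pheno"),
                         "/",
                         ifelse(ann$struct_dist > struct_cut, "high-struct", "low-struct"))
  ann$candidate <- ann$pheno_dist < pheno_max & ann$struct_dist > struct_min &
    ann$target_sim > target_min
  ann[order(-ann$candidate, -ann$target_sim), ]
}
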
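test_that("phenosearch ranks ascending by distance with id tie-breaks", {
  lib <- matrix(stats::rnorm(20 * 30), 20, 30,
                dimnames = list(sprintf("lib%02d", 1:20), NULL))
  q <- lib["lib07", , drop = FALSE]
  rownames(q) <- "query1"
  res <- phenosearch_rank(q, lib, metric = euclidean_distance, top_k = 5)
  r <- res$query1
  expect_equal(r$library_id[1], "lib07")       # exact copy ranks first
  expect_equal(r$distance[1], 0)
  expect_true(!is.unsorted(r$distance))
  expect_equal(nrow(r), 5)
  # top_k larger than the library: full ranking returned
  full <- phenosearch_rank(q, lib, euclidean_distance, top_k = 500)$query1
  expect_equal(nrow(full), 20)
  expect_error(phenosearch_rank(q, lib[0, ], euclidean_distance), "empty library")
})

test_that("tanimoto similarity counts shared and unioned bits", {
  expect_equal(tanimoto(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_warning(s <- tanimoto(c(0, 0), c(0, 0)), "empty")
  expect_equal(s, 0)
  expect_equal(tanimoto_distance(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("enrichment curves are linear for front-loaded hits and flat for none", {
  lib_ids <- c(paste0("h", 1:5), paste0("m", 1:5))
  prof <- rbind(q = c(1, 0, 0),
                matrix(rep(c(1, 1, 0), 5), 5, byrow = TRUE,
                       dimnames = list(paste0("h", 1:5))),
                matrix(rep(c(0, 0, 1), 5), 5, byrow = TRUE,
                       dimnames = list(paste0("m", 1:5))))
  ranking <- structure(list(q = data.frame(library_id = lib_ids,
                                           distance = seq(0.1, 1, 0.1),
                                           rank = 1:10)),
                       class = "phenosearch_result", top_k = 10, library_size = 10)
  enr <- moa_enrichment(ranking, prof, fractions = seq(0.2, 1, 0.2), n_boot = 0)
  # all five hits placed first: slope of one hit per compound until exhausted
  expect_equal(enr$hits, c(2, 4, 5, 5, 5))
  expect_equal(enr$baseline, c(1, 2, 3, 4, 5))
  # non-decreasing and bounded by total hits
  expect_true(!is.unsorted(enr$hits))
  expect_lte(max(enr$hits), 5)
})

test_that("random orderings track the analytic hypergeometric baseline", {
  n_lib <- 40; n_hit <- 12
  hits <- c(rep(TRUE, n_hit), rep(FALSE, n_lib - n_hit))
  fractions <- seq(0.25, 1, 0.25)
  m <- floor(fractions * n_lib)
  perm_counts <- withr::with_seed(13, {
    replicate(1000, {
      o <- sample(n_lib)
      vapply(m, function(k) sum(hits[o][1:k]), 0L)
    })
  })
  analytic <- m * n_hit / n_lib
  band <- apply(perm_counts, 1, stats::quantile, c(0.025, 0.975))
  expect_true(all(analytic >= band[1, ] & analytic <= band[2, ]))
  expect_equal(rowMeans(perm_counts), analytic, tolerance = 0.05)
})

test_that("control contamination counts vehicles and is bounded", {
  roles <- c(l1 = "drug", l2 = "vehicle", l3 = "vehicle", l4 = "drug")
  ranking <- structure(list(q = data.frame(library_id = c("l2", "l1", "l3"),
                                           distance = 1:3, rank = 1:3)),
                       class = "phenosearch_result", top_k = 3, library_size = 4)
  counts <- control_contamination(ranking, roles)
  expect_equal(unname(counts["q"]), 2L)
  expect_lte(max(counts), sum(roles == "vehicle"))
  # a library without vehicle wells contaminates nothing
  ranking2 <- structure(list(q = data.frame(library_id = c("l1", "l4"),
                                            distance = 1:2, rank = 1:2)),
                        class = "phenosearch_result", top_k = 2, library_size = 2)
  expect_equal(unname(control_contamination(ranking2, roles)["q"]), 0L)
})

test_that("quadrant thresholds gate scaffold-hop candidates", {
  fps <- rbind(A = c(1, 1, 0, 0, 0, 0), B = c(0, 0, 0, 0, 1, 1),
               C = c(1, 1, 0, 0, 0, 0))
  prof <- rbind(A = c(1, 1, 0), B = c(1, 0, 0), C = c(0, 0, 1))
  D <- matrix(c(0, 0.2, 0.9,
                0.2, 0, 0.8,
                0.9, 0.8, 0), 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  qa <- quadrant_analysis(D, fps, prof)
  ab <- qa[qa$id_a == "A" & qa$id_b == "B", ]
  # structurally disjoint, phenotypically close, shared target: a candidate
  expect_true(ab$candidate)
  expect_equal(ab$quadrant, "low-pheno/high-struct")
  ac <- qa[qa$id_a == "A" & qa$id_b == "C", ]
  # identical fingerprints fail the structure threshold
  expect_false(ac$candidate)
  expect_equal(ac$struct_dist, 0)
  # quadrant labels partition all annotated pairs
  expect_equal(nrow(qa), choose(3, 2))
  expect_true(all(table(qa$quadrant) >= 0))
})

test_that("duplicate query compounds yield duplicate annotated rows", {
  fps <- rbind(X1 = c(1, 1, 0, 0), X2 = c(1, 1, 0, 0), Y = c(0, 0, 1, 1))
  prof <- rbind(X1 = c(1, 0), X2 = c(1, 0), Y = c(1, 1))
  D <- matrix(0.2, 3, 3, dimnames = list(rownames(fps), rownames(fps)))
  diag(D) <- 0
  qa <- quadrant_analysis(D, fps, prof)
  xy <- qa[qa$id_b == "Y" | qa$id_a == "Y", ]
  # the duplicated compound pairs with Y twice, with identical annotations
  expect_equal(nrow(xy), 2)
  expect_equal(xy$struct_dist[1], xy$struct_dist[2])
  expect_equal(xy$target_sim[1], xy$target_sim[2])
})
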
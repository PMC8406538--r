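# Clustering inputs, principal-curve fitting, pseudotime and its summaries.

line_embedding <- function(n = 90, noise = 0, seed = 2) {
  set.seed(seed)
  t <- sort(runif(n, 0, 10))
  emb <- data.frame(PC1 = t + rnorm(n, 0, noise),
                    PC2 = 0.5 * t + rnorm(n, 0, noise),
                    PC3 = rnorm(n, 0, noise))
  list(emb = emb, t = t,
       cl = factor(cut(t, c(-Inf, 3.3, 6.6, Inf), labels = c("a", "b", "c"))))
}

test_that("AP bins are half-open and empty bins merge with a warning", {
  tab <- data.frame(ap_position_norm = c(0.99, 0.5, 0, 1, 0.25, 0.35, 0.55,
                                         0.75))
  f <- cluster_inputs(tab, "ap_bins", k = 6)
  expect_equal(as.integer(as.character(f))[1:4], c(6L, 4L, 1L, 6L))
  sparse <- data.frame(ap_position_norm = c(0.05, 0.08, 0.95))
  expect_warning(f2 <- cluster_inputs(sparse, "ap_bins", k = 6), "empty")
  expect_equal(length(f2), 3L)
})

test_that("k-means clustering is reproducible under a fixed seed", {
  tab <- data.frame(PC1 = rnorm(80), PC2 = rnorm(80))
  f1 <- cluster_inputs(tab, "kmeans", k = 4, seed = 5)
  f2 <- cluster_inputs(tab, "kmeans", k = 4, seed = 5)
  expect_identical(f1, f2)
})

test_that("collinear cells give the line back and rank-preserving pseudotime", {
  le <- line_embedding(noise = 0)
  tr <- infer_trajectory(le$emb, le$cl, start = "a", ends = "c")
  expect_equal(order(tr$cells$pseudotime), order(le$t))
  expect_lt(max(tr$cells$projection_dist), 1e-8)
  # MST over three collinear centres visits them in spatial order
  expect_equal(tr$curves[[1]]$path, c("a", "b", "c"))
})

test_that("pseudotime lies in [0, 1] and orients start before end", {
  le <- line_embedding(noise = 0.4)
  tr <- infer_trajectory(le$emb, le$cl, start = "a", ends = "c")
  expect_true(all(tr$cells$pseudotime >= 0 & tr$cells$pseudotime <= 1))
  expect_lt(mean(tr$cells$pseudotime[le$cl == "a"]),
            mean(tr$cells$pseudotime[le$cl == "c"]))
  # fit improves on the initial centre path
  init <- notomorph:::.project_polyline(
    as.matrix(le$emb), tr$centers[c(1, 2, 3), ])
  expect_lte(mean(tr$cells$projection_dist), mean(sqrt(init$dist2)) + 1e-9)
})

test_that("pseudotime is invariant under rigid rotation of the embedding", {
  le <- line_embedding(n = 150, noise = 0.5, seed = 8)
  tr1 <- infer_trajectory(le$emb, le$cl, start = "a", ends = "c")
  R <- rotation_matrix(c(1, 2, 3), 0.83)
  rot <- as.data.frame(as.matrix(le$emb) %*% t(R))
  names(rot) <- c("PC1", "PC2", "PC3")
  tr2 <- infer_trajectory(rot, le$cl, start = "a", ends = "c")
  expect_gte(stats::cor(tr1$cells$pseudotime, tr2$cells$pseudotime), 0.999)
})

test_that("undersized clusters and unknown labels are rejected", {
  le <- line_embedding()
  expect_error(infer_trajectory(le$emb, le$cl, start = "zz"), "start")
  tiny <- le$cl
  tiny[1:length(tiny)] <- "a"; tiny[1:2] <- "b"
  expect_error(infer_trajectory(le$emb, droplevels(tiny), start = "a"),
               "fewer than 3")
})

test_that("per-stage densities are proper and centred where the cells are", {
  pt <- c(rep(0.5, 40), runif(40))
  st <- rep(c(8, 10), each = 40)
  d <- pseudotime_density(pt, st, bw = 0.05)
  for (s in c(8, 10)) {
    sub <- d[d$stage == s, ]
    expect_equal(trapz(sub$pseudotime, sub$density), 1, tolerance = 1e-3)
  }
  d8 <- d[d$stage == 8, ]
  # all stage-8 mass sits at 0.5: the curve is the (reflected) kernel there
  expect_equal(d8$pseudotime[which.max(d8$density)], 0.5, tolerance = 0.01)
  ref <- dnorm(d8$pseudotime - 0.5, sd = 0.05) +
    dnorm(d8$pseudotime + 0.5, sd = 0.05) +
    dnorm(2 - d8$pseudotime - 0.5, sd = 0.05)
  expect_equal(d8$density, ref, tolerance = 1e-9)
  w <- testthat::capture_warnings(pseudotime_density(c(0.1, 0.5), c(1, 2)))
  expect_match(w, "fewer than 2 cells", all = TRUE)
  expect_length(w, 2)
})

test_that("stage correlation behaves for ordered, shuffled and degenerate input", {
  st <- rep(c(6, 8, 10, 12, 14), each = 100)
  pt <- (st - 6) / 8 + runif(500, 0, 0.02)
  co <- stage_pseudotime_correlation(pt, st)
  expect_gt(co$r, 0.99)
  expect_true(all(diff(co$per_stage$mean) > 0))
  set.seed(14)
  co_sh <- stage_pseudotime_correlation(pt, sample(st))
  expect_lt(abs(co_sh$r), 0.2)
  expect_error(stage_pseudotime_correlation(rep(0.5, 10), rep(c(1, 2), 5)),
               "zero variance")
  expect_error(stage_pseudotime_correlation(runif(10), rep(1, 10)),
               "2 stages")
})

test_that("spatial profiles are flat for uniform pseudotime and need 2+ bins", {
  ap <- runif(300)
  prof <- spatial_pseudotime_profile(rep(0.7, 300), ap, rep(10, 300))
  expect_equal(prof$mean_pseudotime, rep(0.7, 10), tolerance = 1e-12)
  expect_error(spatial_pseudotime_profile(runif(10), runif(10), rep(1, 10),
                                          n_bins = 1), "n_bins")
})
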
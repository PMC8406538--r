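# Redundancy screen, standardised PCA, embedding and their invariants.

test_that("the screen drops exact duplicates and keeps independent features", {
  set.seed(3)
  tab <- data.frame(f1 = rnorm(50))
  tab$f2 <- 2 * tab$f1
  tab$f3 <- rnorm(50)
  kept <- screen_redundant_features(tab, features = c("f1", "f2", "f3"))
  expect_length(kept, 2)
  expect_true(sum(c("f1", "f2") %in% kept) == 1)
  expect_true("f3" %in% kept)

  ind <- as.data.frame(matrix(rnorm(200 * 6), 200))
  names(ind) <- paste0("g", 1:6)
  expect_setequal(screen_redundant_features(ind, features = names(ind)),
                  names(ind))
})

test_that("constant features are removed with a warning", {
  tab <- data.frame(f1 = rnorm(30), f2 = rnorm(30), flat = 1)
  expect_warning(kept <- screen_redundant_features(
    tab, features = c("f1", "f2", "flat")), "flat")
  expect_false("flat" %in% kept)
})

test_that("curated descriptors are preferred over raw lengths", {
  set.seed(4)
  tab <- data.frame(ell_a = rnorm(60, 10))
  tab$l_AP <- tab$ell_a + rnorm(60, 0, 1e-4)  # near-duplicate pair
  tab$cuboidness <- runif(60)
  kept <- screen_redundant_features(tab, features = c("l_AP", "ell_a",
                                                      "cuboidness"))
  expect_true("l_AP" %in% kept)    # aabb length outranks ellipsoid axis
  expect_false("ell_a" %in% kept)
})

test_that("a rho = 0.8 feature pair yields variance fractions (0.9, 0.1)", {
  tab <- make_corr_pair(200, 0.8)
  m <- fit_morphospace(tab, n_components = 2, features = c("f1", "f2"))
  expect_equal(m$variance_fraction, c(0.9, 0.1), tolerance = 1e-9)
  expect_equal(sum(m$variance_fraction), 1, tolerance = 1e-9)
})

test_that("loadings are orthonormal and reconstruction is exact", {
  tab <- default_tab()
  m <- default_model()
  G <- t(m$loadings) %*% m$loadings
  expect_lt(max(abs(G - diag(ncol(m$loadings)))), 1e-8)
  expect_equal(colSums(m$contributions), rep(100, ncol(m$contributions)),
               ignore_attr = TRUE, tolerance = 1e-9)

  z <- scale(as.matrix(tab[stats::complete.cases(tab[, m$features]),
                           m$features]), m$center, m$scale)
  recon <- reconstruct_morphospace(m, tab)
  expect_lt(max(abs(recon - z)), 1e-8)
})

test_that("the model is invariant to cell order and embeds linearly", {
  tab <- default_tab()
  m <- default_model()
  set.seed(9)
  perm <- sample(nrow(tab))
  m2 <- fit_morphospace(tab[perm, ])
  expect_equal(m$loadings, m2$loadings, tolerance = 1e-10)
  expect_equal(m$variance_fraction, m2$variance_fraction, tolerance = 1e-12)

  emb <- embed_morphospace(m, tab)
  # training-embedding coordinate variances equal the eigenvalues
  k <- m$n_components
  v <- apply(as.matrix(emb[, paste0("PC", 1:k)]), 2, stats::var)
  n <- m$n_cells
  expect_equal(v * (n - 1) / n, m$eigenvalues[1:k] * (n - 1) / n,
               tolerance = 1e-9, ignore_attr = TRUE)
  # a mean cell embeds at the origin
  mean_cell <- as.data.frame(as.list(m$center))
  expect_lt(max(abs(embed_morphospace(m, mean_cell)[, paste0("PC", 1:k)])),
            1e-10)
  # held-out coordinates equal the explicit matrix product
  new <- tab[7:9, ]
  z <- scale(as.matrix(new[, m$features]), m$center, m$scale)
  expect_equal(as.matrix(embed_morphospace(m, new)[, paste0("PC", 1:k)]),
               z %*% m$loadings[, 1:k], ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(embed_morphospace(m, tab[, -match(m$features[1], names(tab))]),
               m$features[1])
})

test_that("significant contributors recover planted latent factors", {
  set.seed(11)
  n <- 400
  fA <- rnorm(n); fB <- rnorm(n)
  tab <- data.frame(a1 = fA + rnorm(n, 0, 0.01), a2 = -fA + rnorm(n, 0, 0.01),
                    a3 = 2 * fA + rnorm(n, 0, 0.01),
                    b1 = fB + rnorm(n, 0, 0.01), b2 = 3 * fB + rnorm(n, 0, 0.01))
  m <- fit_morphospace(tab, n_components = 2, features = names(tab),
                       screen_threshold = 1.01)
  expect_setequal(significant_contributors(m, 1), c("a1", "a2", "a3"))
  expect_setequal(significant_contributors(m, 2), c("b1", "b2"))
  # two latent factors carry essentially all variance
  expect_gt(sum(m$variance_fraction[1:2]), 0.99)
  expect_error(significant_contributors(m, 99), "unknown")
})

test_that("uniform contributions yield no significant contributors", {
  m <- structure(list(features = paste0("f", 1:10),
                      contributions = matrix(10, 10, 2,
                                             dimnames = list(paste0("f", 1:10),
                                                             NULL))),
                 class = "morphospace")
  expect_length(significant_contributors(m, 1), 0)
})

test_that("central and Muller cells separate in the first component plane", {
  tab <- default_tab()
  m <- default_model()
  emb <- embed_morphospace(m, tab)
  sil <- silhouette_width(as.matrix(emb[, c("PC1", "PC2")]), emb$layer)
  expect_gt(sil, 0.2)
})
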
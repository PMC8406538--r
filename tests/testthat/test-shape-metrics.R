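# Closed-form fixtures for the metric suite, and the bookkeeping around them.

test_that("axis-aligned box metrics match closed forms exactly", {
  mask <- fixture_superellipsoid(10, 5, 2.5, p = Inf, voxel_size = 0.5)
  cells <- extract_cells(make_volume(mask), 0.5)
  expect_length(cells, 1)
  f <- compute_derived_metrics(compute_core_metrics(cells[[1]]), cells[[1]])
  expect_equal(f$volume, 1000)
  expect_equal(c(f$l_AP, f$l_DV, f$l_ML), c(20, 10, 5))
  expect_equal(c(f$o1, f$o2, f$o3), c(20, 10, 5), tolerance = 1e-9)
  expect_equal(f$cuboidness, 1, tolerance = 1e-9)
  expect_equal(f$orientation_AP, 1, tolerance = 1e-9)
  expect_equal(f$orientation_DV, 0, tolerance = 1e-9)
  expect_equal(c(f$aspect_AP_DV, f$aspect_AP_ML, f$aspect_DV_ML), c(2, 4, 2))
  expect_equal(f$area_transverse, 50)
  expect_equal(f$AP_anisotropy, 20 / sqrt(50))
  expect_equal(f$area_bb, 50)
  # the box is a prism, so the length approximation V/A is exact
  expect_equal(ap_length_eq1(f$volume, f$area_transverse), 20)
  # centroid at the box centre to within half a voxel
  expect_lt(max(abs(cells[[1]]$centroid_um -
                      apply(cells[[1]]$voxels - 0.5, 2, mean) * 0.5)), 1e-9)
})

test_that("ball metrics match closed forms within discretisation tolerance", {
  mask <- fixture_superellipsoid(10, 10, 10, p = 2, voxel_size = 0.5)
  cells <- extract_cells(make_volume(mask), 0.5)
  f <- compute_derived_metrics(compute_core_metrics(cells[[1]]), cells[[1]])
  expect_lt(abs(f$volume / (4 / 3 * pi * 1000) - 1), 0.02)
  for (ax in c(f$ell_a, f$ell_b, f$ell_c)) expect_lt(abs(ax / 10 - 1), 0.02)
  expect_gte(f$sphericity, 0.97)
  expect_lt(abs(f$cuboidness / (pi / 6) - 1), 0.03)
  expect_true(f$flag_isotropic)
})

test_that("rotated shapes report the rotated orientation cosines", {
  rot_z90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  mask <- fixture_superellipsoid(10, 5, 2.5, p = 2, voxel_size = 0.5,
                                 rotation = rot_z90)
  cells <- extract_cells(make_volume(mask), 0.5)
  f <- compute_core_metrics(cells[[1]])
  expect_equal(f$orientation_DV, 1, tolerance = 0.01)
  expect_equal(f$orientation_AP, 0, tolerance = 0.01)

  rot45 <- rotation_matrix(c(0, 0, 1), pi / 4)
  mask45 <- fixture_superellipsoid(10, 5, 2.5, p = Inf, voxel_size = 0.5,
                                   rotation = rot45)
  f45 <- compute_core_metrics(extract_cells(make_volume(mask45), 0.5)[[1]])
  expect_equal(f45$orientation_AP, sqrt(2) / 2, tolerance = 0.02)
  expect_equal(f45$orientation_DV, sqrt(2) / 2, tolerance = 0.02)
  expect_lt(f45$orientation_ML, 0.02)
})

test_that("descriptor orderings and orientation normalisation always hold", {
  set.seed(42)
  for (i in 1:8) {
    ax <- sort(runif(3, 2, 8), decreasing = TRUE)
    R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, pi))
    mask <- fixture_superellipsoid(ax[1], ax[2], ax[3],
                                   p = stats::runif(1, 1.8, 8),
                                   voxel_size = 0.5, rotation = R)
    cl <- extract_cells(make_volume(mask), 0.5)[[1]]
    f <- compute_derived_metrics(compute_core_metrics(cl), cl)
    expect_true(f$o1 >= f$o2 && f$o2 >= f$o3)
    expect_true(f$ell_a >= f$ell_b && f$ell_b >= f$ell_c)
    expect_equal(f$orientation_AP^2 + f$orientation_DV^2 + f$orientation_ML^2,
                 1, tolerance = 1e-6)
    expect_true(f$cuboidness > 0 && f$cuboidness <= 1)
    expect_true(f$sphericity > 0 && f$sphericity <= 1)
    # the oriented bounding box always contains the cell
    expect_gte(f$o1 * f$o2 * f$o3, f$volume)
  }
})

test_that("extract_cells validates its input and flags pathology", {
  v <- array(0L, c(6, 6, 6))
  v[2:3, 2:3, 2:3] <- 1L
  v[5, 5, 5] <- 2L
  v[1, 1, 1] <- 3L  # touches the border
  cells <- extract_cells(v, 1)
  expect_length(cells, 3)
  expect_true(cells[[3]]$on_border)
  expect_false(cells[[1]]$on_border)

  bad <- v; bad[6, 6, 6] <- 1L  # disconnected piece of label 1
  expect_error(extract_cells(bad, 1), "label 1")
  expect_error(extract_cells(array(0L, c(3, 3, 3)), 1), "no labelled")
  expect_error(extract_cells(array(0.5, c(3, 3, 3)), 1), "integer")

  nuc <- data.frame(cell_id = c(1, 99), nuc_ap = c(2.4, 0), nuc_dv = c(2.6, 0),
                    nuc_ml = c(2.5, 0))
  expect_warning(cells <- extract_cells(v, 1, nuc), "99")
  expect_equal(cells[[1]]$nucleus_centroid_um, c(2.4, 2.6, 2.5))
  f <- compute_derived_metrics(compute_core_metrics(cells[[1]]), cells[[1]])
  expect_equal(c(f$nuc_dAP, f$nuc_dDV, f$nuc_dML),
               c(2.4, 2.6, 2.5) - cells[[1]]$centroid_um)
  # no nucleus: displacement missing, not zero
  f2 <- compute_derived_metrics(compute_core_metrics(cells[[2]]), cells[[2]])
  expect_true(is.na(f2$nuc_dAP))
})

test_that("degenerate cells are flagged with missing metrics", {
  v <- array(0L, c(5, 5, 5))
  v[2, 2, 2:3] <- 1L  # 2 voxels
  cells <- extract_cells(v, 1)
  f <- compute_core_metrics(cells[[1]])
  expect_true(f$flag_degenerate)
  expect_true(is.na(f$surface_area))
})

test_that("AP regions use half-open bins and layers follow DV extremes", {
  expect_equal(as.character(ap_region(c(0, 0.149, 0.15, 0.399, 0.4, 0.5,
                                        0.599, 0.6, 1))),
               c("anterior", "anterior", "pharynx", "pharynx", "trunk",
                 "trunk", "trunk", "posterior", "posterior"))
  # three-row stack: outer rows are Muller, middle row central
  ap <- rep(seq(1, 50, by = 5), 3)
  dv <- rep(c(0, 5, 10), each = 10)
  lay <- classify_dv_layer(ap, dv)
  expect_equal(lay, rep(c("muller", "central", "muller"), each = 10))
})

test_that("feature_table joins annotations and excludes unannotated cells", {
  v <- array(0L, c(14, 8, 8))
  v[2:5, 3:5, 3:5] <- 1L
  v[8:11, 3:5, 3:5] <- 2L
  cells <- extract_cells(v, 1)
  feats <- compute_features(cells)
  ann <- data.frame(cell_id = 1, embryo = "e1", stage = 8,
                    ap_position_norm = 0.5, layer = "central")
  expect_message(tab <- feature_table(feats, ann), "1 unannotated")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$region, "trunk")
})
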
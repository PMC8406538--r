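# Generator invariants: determinism, program fidelity, intercalation targets,
# the maturation gradient and proliferation labelling.

test_that("identical config and seed give identical output", {
  cfg <- generator_config(stages = c(8, 10), cells_per_stage = 15, seed = 77)
  s1 <- generate_notochord(cfg)
  s2 <- generate_notochord(cfg)
  expect_identical(s1$volumes, s2$volumes)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$nuclei, s2$nuclei)
  # a different seed changes the realisation
  s3 <- generate_notochord(generator_config(stages = c(8, 10),
                                            cells_per_stage = 15, seed = 78))
  expect_false(identical(s1$ground_truth$l_AP, s3$ground_truth$l_AP))
})

test_that("a noise-free cuboid program digitises to an exact box", {
  cfg <- generator_config(stages = 10, cells_per_stage = 1,
                          include_muller = FALSE, noise_cv = 0,
                          gradient_gamma = 0,
                          central_program = cuboid_program(10, 5, 5),
                          beta_schedule = c("10" = 1),
                          posterior_prolif_fraction = c("10" = 0), seed = 1)
  sim <- generate_notochord(cfg)
  f <- compute_features(extract_cells(sim$volumes[[1]], 0.5))
  expect_equal(f$volume, 250)
  expect_equal(f$cuboidness, 1, tolerance = 1e-9)
  expect_equal(c(f$l_AP, f$l_DV, f$l_ML), c(10, 5, 5))
})

test_that("a beta = 1 noise-free stack has group length n * l_bar exactly", {
  cfg <- generator_config(stages = 14, cells_per_stage = 20,
                          include_muller = FALSE, noise_cv = 0,
                          gradient_gamma = 0,
                          beta_schedule = c("14" = 1),
                          posterior_prolif_fraction = c("14" = 0), seed = 1)
  gt <- generate_notochord(cfg)$ground_truth
  ns <- neighborhood_series(gt, n = 10)
  expect_equal(ns$beta, 1, tolerance = 1e-12)
  expect_equal(ns$l_n, 10 * ns$l_bar, tolerance = 1e-9)
})

test_that("noise-free realised cells match their programmed geometry", {
  cfg <- generator_config(stages = c(8, 12), cells_per_stage = 12,
                          include_muller = TRUE, noise_cv = 0,
                          gradient_gamma = 0, seed = 5)
  sim <- generate_notochord(cfg)
  f <- do.call(rbind, lapply(sim$volumes, function(v)
    compute_features(extract_cells(v, 0.5))))
  m <- merge(f, sim$ground_truth, by = "cell_id")
  expect_lt(max(abs(m$volume / m$V - 1)), 0.02)
  expect_lt(max(abs(m$l_AP.x / m$l_AP.y - 1)), 0.02)
})

test_that("the intercalation schedule is recovered from the arrangement", {
  for (b in c(0.4, 0.7, 1.0)) {
    cfg <- generator_config(stages = 12, cells_per_stage = 50,
                            include_muller = FALSE,
                            beta_schedule = stats::setNames(b, "12"),
                            gradient_gamma = 0, seed = 13)
    ns <- neighborhood_series(generate_notochord(cfg)$ground_truth, n = 10)
    expect_lt(abs(ns$beta - b), 0.02)
  }
})

test_that("increasing flare raises surface area and lowers cuboidness", {
  flares <- c(0, 0.25, 0.5, 0.75)
  res <- lapply(flares, function(fl) {
    mask <- fixture_flared_cell(4, 4, 3.5, p = 12, q = 4, flare = fl)
    compute_features(extract_cells(make_volume(mask), 0.5))
  })
  area <- vapply(res, `[[`, numeric(1), "surface_area")
  cub <- vapply(res, `[[`, numeric(1), "cuboidness")
  expect_true(all(diff(area) > 0))
  expect_true(all(diff(cub) < 0))
})

test_that("maturity declines linearly from the middle towards the tips", {
  cfg <- generator_config(stages = 10, cells_per_stage = 40,
                          include_muller = FALSE, gradient_gamma = 4,
                          seed = 3)
  gt <- generate_notochord(cfg)$ground_truth
  mid <- gt$maturity[which.min(abs(gt$ap_position_norm - 0.5))]
  tip <- gt$maturity[which.min(abs(gt$ap_position_norm - 0.05))]
  expect_equal(mid - tip, 4 * 0.45, tolerance = 0.1)
  # monotone decline with |ap - 0.5|
  expect_lte(stats::cor(abs(gt$ap_position_norm - 0.5), gt$maturity), -0.99)
})

test_that("proliferation labels are confined to the posterior fraction", {
  cfg <- generator_config(stages = c(6, 12), cells_per_stage = 60,
                          include_muller = FALSE, seed = 21,
                          posterior_prolif_fraction = c("6" = 1, "12" = 0.2))
  gt <- generate_notochord(cfg)$ground_truth
  lab12 <- gt[gt$stage == 12 & gt$prolif_label != "none", ]
  expect_true(all(lab12$ap_position_norm >= 1 - 0.2 - 0.05))
  # early broad phase labels anywhere
  lab6 <- gt[gt$stage == 6 & gt$prolif_label != "none", ]
  expect_gt(nrow(lab6), 0)
  expect_lt(min(lab6$ap_position_norm), 0.5)
})

test_that("programs reject evaluation outside their domain and bad configs fail", {
  prog <- default_central_program()
  expect_error(program_eval(prog, 3), "domain")
  expect_error(program_eval(prog, 15), "domain")
  expect_error(generator_config(beta_schedule = c("6" = 1.5)), "beta")
  expect_error(generator_config(stages = c(10, 8)))
  expect_error(shape_program(data.frame(m = c(4, 14), l_AP = -1, A = 10,
                                        V = 10, dv_ml = 1, flare = 0)),
               "positive")
})

test_that("fixture table values verify against the measured fixtures", {
  fx <- generate_fixture_shapes(0.5)
  for (i in seq_len(nrow(fx$expected))) {
    e <- fx$expected[i, ]
    cl <- extract_cells(make_volume(fx$masks[[e$shape]]), 0.5)[[1]]
    f <- compute_derived_metrics(compute_core_metrics(cl), cl)
    expect_lt(abs(f$volume / e$volume - 1), e$tol_rel)
    if (!is.na(e$l_AP)) expect_lt(abs(f$l_AP / e$l_AP - 1), e$tol_rel)
    if (!is.na(e$cuboidness))
      expect_lt(abs(f$cuboidness / e$cuboidness - 1), 0.03)
    if (!is.na(e$orientation_AP))
      expect_lt(abs(f$orientation_AP - e$orientation_AP), 0.02)
  }
})
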
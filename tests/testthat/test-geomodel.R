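# The mean-cell parameterisation, length scenarios and intercalation algebra.

fake_params <- function(stages, l, V, A) {
  out <- data.frame(stage = stages, n = 10, l_AP = l, l_AP_sem = 0,
                    V = V, V_sem = 0, A = A, A_sem = 0, A_bb = A, A_bb_sem = 0)
  out$eq1_rel_error <- abs(out$l_AP - out$V / out$A) / out$l_AP
  class(out) <- c("mean_cell_params", "data.frame")
  out
}

test_that("mean cell parameters are stage means with standard errors", {
  tab <- data.frame(stage = rep(8, 3), l_AP = c(9, 10, 11),
                    volume = c(90, 100, 110), area_transverse = c(19, 20, 21),
                    area_bb = c(24, 25, 26))
  p <- mean_cell_params(tab)
  expect_equal(p$V, 100)
  expect_equal(p$V_sem, 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(p$V_sem, 5.7735, tolerance = 1e-4)
  expect_error(mean_cell_params(tab[1, ]), "fewer than 3")
  expect_error(mean_cell_params(tab, stages = c(8, 10)), "10")
})

test_that("the prism length approximation and its trivial cases", {
  expect_equal(ap_length_eq1(1000, 200), 5)
  expect_equal(ap_length_eq1(250, 50), 5)
  expect_error(ap_length_eq1(-1, 10), "positive")
  expect_error(ap_length_eq1(10, 0), "positive")
})

test_that("scenario algebra holds to 1e-12 on random parameter sets", {
  set.seed(20)
  for (i in 1:1000) {
    stages <- c(6, 10)
    l <- runif(2, 2, 15); V <- runif(2, 50, 900); A <- runif(2, 10, 150)
    p <- fake_params(stages, l, V, A)
    aniso_shape <- scenario_ap_anisotropy(p, 10)     # V0 / A(s)
    iso <- scenario_isotropic_growth(p, 10)          # l0 (V/V0)^(1/3)
    aniso_g <- scenario_anisotropic_growth(p, 10)    # l0 V/V0
    expect_equal(aniso_shape, V[1] / A[2], tolerance = 1e-12)
    expect_equal(iso, l[1] * (V[2] / V[1])^(1/3), tolerance = 1e-12)
    expect_equal(aniso_g, l[1] * V[2] / V[1], tolerance = 1e-12)
    # cross-scenario identity: aniso / iso = (V/V0)^(2/3)
    expect_equal(aniso_g / iso, (V[2] / V[1])^(2/3), tolerance = 1e-12)
    # reference stage maps to the reference values
    expect_equal(scenario_isotropic_growth(p, 6), l[1], tolerance = 1e-12)
    expect_equal(scenario_ap_anisotropy(p, 6), V[1] / A[1], tolerance = 1e-12)
    # round trip through the intercalation index
    beta <- runif(1, 0.2, 1)
    ln <- neighborhood_length_eq2(beta, 10, l[1])
    expect_equal(intercalation_index(ln, 10, l[1]), beta, tolerance = 1e-12)
  }
})

test_that("scenario predictions move the right way with A and V", {
  p <- fake_params(c(6, 8, 10), l = c(9, 7, 5), V = c(220, 300, 380),
                   A = c(35, 60, 95))
  shape <- scenario_ap_anisotropy(p, c(6, 8, 10))
  expect_true(all(diff(shape) < 0))          # A rises, constant-V length falls
  iso <- scenario_isotropic_growth(p, c(6, 8, 10))
  expect_true(all(diff(iso) > 0))            # V rises, growth length rises
  expect_true(all(scenario_anisotropic_growth(p, c(8, 10)) > iso[2:3]))
})

test_that("the intercalation index clips noise and validates input", {
  expect_equal(intercalation_index(50, 10, 5), 1)
  expect_equal(intercalation_index(40, 10, 5), 0.8)
  expect_warning(b <- intercalation_index(52, 10, 5), "clipped")
  expect_equal(b, 1)
  expect_error(intercalation_index(50, 1, 5), "at least 2")
  expect_error(neighborhood_length_eq2(1.2, 10, 5), "beta")
  expect_equal(neighborhood_length_eq2(1, 10, 5), 50)
  expect_equal(neighborhood_length_eq2(0.5, 10, 5), 25)
})

test_that("neighbourhood scenarios combine beta and length as specified", {
  p <- fake_params(c(6, 10), l = c(5, 8), V = c(200, 500), A = c(40, 62.5))
  series <- data.frame(stage = c(6, 10), beta = c(0.5, 1.0))
  ic <- scenario_neighborhood(p, series, "intercalation_only", n = 10)
  expect_equal(ic$l_n, c(0.5 * 10 * 5, 1.0 * 10 * 5))
  expect_equal(ic$pct_change, c(0, 100))
  sng <- scenario_neighborhood(p, series, "shape_no_growth", n = 10)
  expect_equal(sng$l_n, c(0.5 * 10 * 200 / 40, 1.0 * 10 * 200 / 62.5))
  ig <- scenario_neighborhood(p, series, "isotropic_growth_only", n = 10)
  expect_equal(ig$l_n, 0.5 * 10 * 5 * c(1, (500 / 200)^(1/3)))
  full <- scenario_neighborhood(p, series, "full", n = 10)
  expect_equal(full$l_n, series$beta * 10 * p$l_AP, tolerance = 1e-12)
  expect_error(scenario_neighborhood(p, series, "warp"), "arg")
})

test_that("the full scenario reproduces measured group lengths on synthetic data", {
  sim <- default_sim()
  ns <- neighborhood_series(sim$ground_truth, n = 10)
  gt <- sim$ground_truth
  cen <- gt[gt$cell_type %in% c("central", "posterior_progenitor"), ]
  params <- fake_params(ns$stage, ns$l_bar,
                        tapply(cen$V, cen$stage, mean)[as.character(ns$stage)],
                        tapply(cen$A, cen$stage, mean)[as.character(ns$stage)])
  full <- scenario_neighborhood(params, ns, "full", n = 10)
  expect_equal(full$l_n, ns$beta * 10 * ns$l_bar, tolerance = 1e-12)
  expect_equal(full$l_n, ns$l_n, tolerance = 1e-9)
  # the growth-free scenario underestimates the full elongation
  sng <- scenario_neighborhood(params, ns, "shape_no_growth", n = 10)
  last <- nrow(full)
  expect_lt(sng$pct_change[last], full$pct_change[last])
})

test_that("tissue vs neighbourhood comparison isolates the addition gap", {
  nb <- data.frame(stage = c(6, 10, 14), l_n = c(30, 45, 60))
  tis <- data.frame(stage = c(6, 10, 14), tissue_length = c(300, 450, 600))
  cmp <- elongation_comparison(nb, tis)
  expect_equal(cmp$gap, rep(0, 3))
  tis2 <- tis; tis2$tissue_length <- tis$tissue_length * c(1, 1.2, 1.5)
  cmp2 <- elongation_comparison(nb, tis2)
  expect_equal(cmp2$gap[1], 0)
  expect_true(all(cmp2$gap[2:3] > 0))
  const <- data.frame(stage = c(6, 10, 14), l_n = 30)
  cmp3 <- elongation_comparison(const, tis)
  expect_equal(cmp3$rel_neighborhood, rep(1, 3))
  expect_error(elongation_comparison(nb, tis[1:2, ]), "mismatch")
})
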
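# Synthetic notochord generator.
#
# Produces labelled 3D volumes of superellipsoid-like cells following
# parameterised shape programs, together with nucleus, annotation and
# ground-truth tables, so that every downstream stage of the pipeline can be
# exercised against known answers.
#
# A cell is modelled in its own frame as a generalised superellipsoid: the
# transverse cross-section at axial fraction u = x / (l_AP/2) is a superellipse
# with exponent q whose semi-axes are scaled by the axial profile
# (1 - |u|^p)^(1/p) and by an optional flare factor (1 + flare * |u|^kappa)
# that swells the margins near the AP faces (the "bowtie"). The profile
# exponent p is solved per cell so that the enclosed volume matches the
# programmed volume; q controls how square the cross-section is.

# --- axial profile algebra -------------------------------------------------

# J_m(p) = integral_0^1 u^m (1-u^p)^(2/p) du, closed form via the beta function
.profile_moment <- function(p, m) {
  if (!is.finite(p)) return(1 / (m + 1))
  exp(lgamma((m + 1) / p) + lgamma(2 / p + 1) -
        lgamma((m + 1) / p + 2 / p + 1)) / p
}

# fullness V / (A * l_AP) of a cell with axial exponent p and flare
.fullness <- function(p, flare, kappa) {
  .profile_moment(p, 0) + 2 * flare * .profile_moment(p, kappa) +
    flare^2 * .profile_moment(p, 2 * kappa)
}

# invert fullness -> p on [1, 64]; Inf when the target needs a full prism
.solve_axial_exponent <- function(fullness, flare, kappa) {
  lo <- .fullness(1, flare, kappa)
  hi <- .fullness(64, flare, kappa)
  hi_inf <- .fullness(Inf, flare, kappa)
  if (fullness >= hi) return(list(p = Inf, fullness = hi_inf))
  if (fullness <= lo) return(list(p = 1, fullness = lo))
  p <- stats::uniroot(function(pp) .fullness(pp, flare, kappa) - fullness,
                      c(1, 64), tol = 1e-10)$root
  list(p = p, fullness = fullness)
}

# superellipse area factor: area = 4 * b * c * SE(q)
.se_area_factor <- function(q) {
  if (!is.finite(q)) return(1)
  exp(2 * lgamma(1 + 1 / q) - lgamma(1 + 2 / q))
}

# --- shape programs --------------------------------------------------------

#' Define a piecewise-linear cell shape program
#'
#' A program maps maturity m (somite-stage units) to the target geometry of a
#' cell: AP length \code{l_AP} (um), transverse cross-sectional area \code{A}
#' (um^2), volume \code{V} (um^3), DV:ML semi-axis ratio \code{dv_ml} and the
#' margin flare amplitude \code{flare}. Values between knots are linearly
#' interpolated; evaluation outside the knot range is an error.
#'
#' @param knots Data frame with columns \code{m}, \code{l_AP}, \code{A},
#'   \code{V}, \code{dv_ml}, \code{flare}.
#' @param q Transverse superellipse exponent (2 = ellipse, larger = squarer,
#'   \code{Inf} = rectangle).
#' @param kappa Exponent of the flare profile along the AP axis.
#' @return Object of class \code{shape_program}.
#' @export
shape_program <- function(knots, q = 4, kappa = 4) {
  need <- c("m", "l_AP", "A", "V", "dv_ml", "flare")
  stopifnot(all(need %in% names(knots)), nrow(knots) >= 2)
  knots <- knots[order(knots$m), ]
  if (any(knots$l_AP <= 0) || any(knots$A <= 0) || any(knots$V <= 0) ||
      any(knots$dv_ml <= 0) || any(knots$flare < 0))
    stop("program values must be positive (flare >= 0)")
  structure(list(knots = knots, q = q, kappa = kappa), class = "shape_program")
}

#' Evaluate a shape program at given maturities
#'
#' @param prog A \code{shape_program}.
#' @param m Maturity values; must lie within the program's knot range.
#' @return Data frame with one row per maturity.
#' @export
program_eval <- function(prog, m) {
  stopifnot(inherits(prog, "shape_program"))
  k <- prog$knots
  if (any(m < min(k$m) - 1e-9 | m > max(k$m) + 1e-9))
    stop("maturity outside program domain [", min(k$m), ", ", max(k$m), "]")
  f <- function(col) stats::approx(k$m, k[[col]], xout = m, rule = 2)$y
  data.frame(m = m, l_AP = f("l_AP"), A = f("A"), V = f("V"),
             dv_ml = f("dv_ml"), flare = f("flare"))
}

#' @export
print.shape_program <- function(x, ...) {
  cat(sprintf("shape_program: %d knots over m in [%g, %g], q = %g, kappa = %g\n",
              nrow(x$knots), min(x$knots$m), max(x$knots$m), x$q, x$kappa))
  invisible(x)
}

#' Default central-cell shape program
#'
#' Encodes the two-step central-cell dynamic: an early transition from an
#' ML-elongated morphology to a transversely spread, flared (bowtie)
#' morphology with AP shortening and volume growth (maturity 6 to 10),
#' followed by AP re-elongation with flare loss and continued growth
#' (maturity 10 to 14).
#'
#' @return A \code{shape_program}.
#' @export
default_central_program <- function() {
  shape_program(data.frame(
    m     = c(4,    6,    8,    10,   12,   14),
    l_AP  = c(7,    9,    6.5,  4.5,  7,    10),
    A     = c(22,   35,   60,   95,   100,  100),
    V     = c(110,  220,  270,  320,  480,  700),
    dv_ml = c(0.40, 0.45, 0.65, 0.95, 1.15, 1.30),
    flare = c(0,    0,    0.25, 0.50, 0.20, 0)
  ), q = 4)
}

#' Default Muller-cell shape program
#'
#' Coincides with the central program at low maturity, then diverges: Muller
#' cells stay ML-flattened with modest growth and no flare, forming the
#' second branch of the shape trajectory.
#'
#' @return A \code{shape_program}.
#' @export
default_muller_program <- function() {
  shape_program(data.frame(
    m     = c(4,    6,    8,    10,   12,   14),
    l_AP  = c(7,    9,    9.5,  10,   10.5, 11),
    A     = c(22,   35,   38,   40,   42,   45),
    V     = c(110,  220,  240,  260,  290,  320),
    dv_ml = c(0.40, 0.45, 0.40, 0.35, 0.30, 0.28),
    flare = c(0,    0,    0,    0,    0,    0)
  ), q = 2)
}

#' Constant cuboid shape program
#'
#' A degenerate program useful as an analytic fixture: every cell is an
#' axis-aligned rectangular prism with AP length \code{l}, cross-section
#' \code{w_dv} x \code{w_ml}.
#'
#' @param l,w_dv,w_ml Box dimensions in micrometres.
#' @return A \code{shape_program} with \code{q = Inf} and fullness 1.
#' @export
cuboid_program <- function(l = 10, w_dv = 5, w_ml = 5) {
  A <- w_dv * w_ml
  shape_program(data.frame(
    m = c(4, 14), l_AP = l, A = A, V = A * l,
    dv_ml = w_dv / w_ml, flare = 0
  ), q = Inf)
}

# --- configuration ---------------------------------------------------------

#' Generator configuration
#'
#' Bundles all parameters of the synthetic notochord. Defaults encode the
#' study conditions emulated by the package: five somite stages, a
#' mid-to-tips maturation gradient, a rising intercalation schedule that
#' reaches the stack-of-coins limit at the last stage, and posterior-restricted
#' proliferation that narrows over time.
#'
#' @param stages Somite stages to simulate.
#' @param cells_per_stage Number of central-column cells per stage.
#' @param voxel_size_um Isotropic voxel size (um).
#' @param gradient_gamma Maturation delay per unit of |ap - 0.5| in stage
#'   units: maturity m = s - gamma * |ap - 0.5|, clamped to the program
#'   domain. 0 disables the gradient.
#' @param beta_schedule Named numeric vector mapping stage to the target
#'   intercalation index in (1/n, 1].
#' @param central_program,muller_program \code{shape_program}s for the two
#'   cell types.
#' @param include_muller Add dorsal and ventral Muller rows.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   size noise on l_AP, A and V; 0 disables all stochastic perturbation
#'   (including orientation jitter).
#' @param rotation_max_deg Maximum orientation jitter, realised as a spin
#'   about the AP axis (degrees) so that AP packing is preserved exactly.
#' @param posterior_prolif_fraction Named numeric vector mapping stage to the
#'   fraction of the AP axis (from the posterior end) that is proliferative;
#'   1 means proliferation throughout (early broad phase).
#' @param neighborhood_n Cells per neighbourhood used for the intercalation
#'   placement target.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Object of class \code{generator_config}.
#' @export
generator_config <- function(stages = c(6, 8, 10, 12, 14),
                             cells_per_stage = 100,
                             voxel_size_um = 0.5,
                             gradient_gamma = 4,
                             beta_schedule = c("6" = 0.45, "8" = 0.55,
                                               "10" = 0.75, "12" = 0.9,
                                               "14" = 1.0),
                             central_program = default_central_program(),
                             muller_program = default_muller_program(),
                             include_muller = TRUE,
                             noise_cv = 0.08,
                             rotation_max_deg = 5,
                             posterior_prolif_fraction = c("6" = 1.0, "8" = 0.4,
                                                           "10" = 0.3, "12" = 0.2,
                                                           "14" = 0.12),
                             neighborhood_n = 10,
                             seed = 1L) {
  stopifnot(length(stages) >= 1, all(diff(stages) > 0),
            cells_per_stage >= 1, voxel_size_um > 0, gradient_gamma >= 0,
            noise_cv >= 0, neighborhood_n >= 2)
  for (s in stages) {
    b <- .lookup_stage(beta_schedule, s, "beta_schedule")
    if (b <= 1 / neighborhood_n || b > 1)
      stop("beta target for stage ", s, " must be in (1/n, 1]")
    p <- .lookup_stage(posterior_prolif_fraction, s, "posterior_prolif_fraction")
    if (p < 0 || p > 1) stop("posterior fraction for stage ", s, " must be in [0, 1]")
  }
  stopifnot(inherits(central_program, "shape_program"),
            inherits(muller_program, "shape_program"))
  structure(list(stages = stages, cells_per_stage = cells_per_stage,
                 voxel_size_um = voxel_size_um, gradient_gamma = gradient_gamma,
                 beta_schedule = beta_schedule,
                 central_program = central_program,
                 muller_program = muller_program,
                 include_muller = include_muller, noise_cv = noise_cv,
                 rotation_max_deg = rotation_max_deg,
                 posterior_prolif_fraction = posterior_prolif_fraction,
                 neighborhood_n = neighborhood_n, seed = as.integer(seed)),
            class = "generator_config")
}

.lookup_stage <- function(map, stage, what) {
  v <- map[as.character(stage)]
  if (is.na(v)) stop(what, " has no entry for stage ", stage)
  unname(v)
}

# --- cell realisation ------------------------------------------------------

# resolve one cell's solid-geometry parameters from programmed targets.
# The flare term swells the margins near the AP faces; its volume
# contribution is folded into the solve for the axial profile exponent, so
# the realised volume still matches the programmed one.
.cell_geometry <- function(targ, q, kappa) {
  a <- targ$l_AP / 2
  se <- .se_area_factor(q)
  b <- sqrt(targ$A * targ$dv_ml / (4 * se))
  c_ <- b / targ$dv_ml
  sol <- .solve_axial_exponent(targ$V / (targ$A * targ$l_AP), targ$flare, kappa)
  list(a = a, b = b, c = c_, p = sol$p, q = q, kappa = kappa,
       flare = targ$flare, V = sol$fullness * targ$A * targ$l_AP)
}

#' Rasterise one cell of the generator's shape family
#'
#' Direct access to the solid-geometry family the generator places in its
#' volumes: a superellipsoid core with semi-axes \code{a, b, c}, axial
#' profile exponent \code{p}, transverse exponent \code{q}, and a margin
#' flare that multiplies the transverse semi-axes by
#' \code{1 + flare * |u|^kappa} towards the AP faces. Useful for studying
#' single parameters (for example, a flare sweep on an otherwise fixed cell).
#'
#' @param a,b,c Core semi-axes (um; AP, DV, ML).
#' @param p Axial profile exponent (\code{Inf} = prism).
#' @param q Transverse superellipse exponent.
#' @param flare Margin flare amplitude (>= 0).
#' @param kappa Flare profile exponent.
#' @param voxel_size Voxel edge (um).
#' @return 3D logical mask.
#' @export
fixture_flared_cell <- function(a, b, c, p = 12, q = 4, flare = 0, kappa = 4,
                                voxel_size = 0.5) {
  geom <- list(a = a, b = b, c = c, p = p, q = q, kappa = kappa,
               flare = flare)
  h <- c(a, b * (1 + flare), c * (1 + flare)) + 2 * voxel_size
  ctr <- (ceiling(h / voxel_size) + 2L) * voxel_size
  idx <- .rasterize_cell(geom, ctr, diag(3), voxel_size)
  d <- apply(idx, 2, max) + 2L
  m <- array(FALSE, d)
  m[idx] <- TRUE
  m
}

# rotation by `ang` radians about the AP (x) axis
.spin_matrix <- function(ang) {
  rbind(c(1, 0, 0),
        c(0, cos(ang), -sin(ang)),
        c(0, sin(ang), cos(ang)))
}

# voxel indices (global grid, origin 0, 1-based) occupied by a cell
.rasterize_cell <- function(geom, center, R, vox) {
  h <- c(geom$a, geom$b * (1 + geom$flare), geom$c * (1 + geom$flare))
  hw <- abs(R) %*% h  # world-frame half extents
  rng <- lapply(1:3, function(k) {
    lo <- ceiling((center[k] - hw[k]) / vox + 0.5)
    hi <- floor((center[k] + hw[k]) / vox + 0.5)
    seq.int(lo, hi)
  })
  gx <- (rep(rng[[1]], times = length(rng[[2]]) * length(rng[[3]])) - 0.5) * vox
  gy <- (rep(rep(rng[[2]], each = length(rng[[1]])), times = length(rng[[3]])) - 0.5) * vox
  gz <- (rep(rng[[3]], each = length(rng[[1]]) * length(rng[[2]])) - 0.5) * vox
  d <- cbind(gx - center[1], gy - center[2], gz - center[3]) %*% R  # into cell frame
  t_ <- abs(d[, 1]) / geom$a
  inside <- t_ < 1
  shrink <- if (is.finite(geom$p)) (pmax(0, 1 - t_^geom$p))^(1 / geom$p) else 1
  fl <- 1 + geom$flare * t_^geom$kappa
  rb <- geom$b * shrink * fl
  rc <- geom$c * shrink * fl
  ok <- inside & rb > 0 & rc > 0
  yy <- abs(d[, 2]) / rb
  zz <- abs(d[, 3]) / rc
  if (is.finite(geom$q)) {
    ok <- ok & (yy^geom$q + zz^geom$q) <= 1
  } else {
    ok <- ok & yy < 1 & zz < 1
  }
  cbind(rep(rng[[1]], times = length(rng[[2]]) * length(rng[[3]]))[ok],
        rep(rep(rng[[2]], each = length(rng[[1]])), times = length(rng[[3]]))[ok],
        rep(rng[[3]], each = length(rng[[1]]) * length(rng[[2]]))[ok])
}

# --- main generator --------------------------------------------------------

#' Generate a synthetic labelled notochord
#'
#' Builds one labelled volume per somite stage plus nucleus, annotation and
#' ground-truth tables. Central cells are placed in single file along the AP
#' (x) axis with centre-to-centre pitch chosen so that the span of every
#' 10-cell neighbourhood matches the stage's intercalation target
#' beta * n * mean(l_AP); for beta < 1, cells are staggered across
#' dorsoventral levels (emulating the multi-layered, pre-intercalation
#' organisation) so that AP-overlapping neighbours never collide. Optional
#' Muller rows flank the stack dorsally and ventrally. Proliferation labels
#' (EdU, PhH3) are drawn only within the stage's posterior fraction of the
#' axis.
#'
#' @param config A \code{generator_config}.
#' @return Object of class \code{notochord_sim}: list with \code{volumes}
#'   (named list of 3D integer label arrays, one per stage), \code{nuclei},
#'   \code{annotations}, \code{ground_truth} (data frames) and the
#'   \code{config}.
#' @export
generate_notochord <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  vox <- config$voxel_size_um
  n_nb <- config$neighborhood_n
  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  volumes <- list()
  gt_rows <- list(); ann_rows <- list(); nuc_rows <- list()
  next_id <- 1L

  for (s in config$stages) {
    beta <- .lookup_stage(config$beta_schedule, s, "beta_schedule")
    pfrac <- .lookup_stage(config$posterior_prolif_fraction, s,
                           "posterior_prolif_fraction")
    N <- config$cells_per_stage
    ap <- (seq_len(N) - 0.5) / N
    mdom <- range(config$central_program$knots$m)
    m <- pmin(pmax(s - config$gradient_gamma * abs(ap - 0.5), mdom[1]), mdom[2])

    targ <- program_eval(config$central_program, m)
    if (sdlog > 0) {
      targ$l_AP <- targ$l_AP * exp(stats::rnorm(N, 0, sdlog))
      targ$A <- targ$A * exp(stats::rnorm(N, 0, sdlog))
      targ$V <- targ$V * exp(stats::rnorm(N, 0, sdlog))
    }
    geoms <- lapply(seq_len(N), function(i)
      .cell_geometry(targ[i, ], config$central_program$q,
                     config$central_program$kappa))
    targ$V <- vapply(geoms, `[[`, numeric(1), "V")  # fullness-feasible volume
    l <- targ$l_AP
    lbar <- mean(l)

    spins <- if (sdlog > 0) {
      stats::runif(N, -1, 1) * config$rotation_max_deg * pi / 180
    } else rep(0, N)
    Rs <- lapply(spins, .spin_matrix)

    # AP placement: exact abutment at beta = 1 (stack of coins, spans equal
    # summed lengths); otherwise the first n-1 cells take a constant pitch
    # Pitch placement: gaps are proportional to adjacent cell lengths (local
    # adaptation under maturity gradients and noise) with a global factor
    # solved in closed form so that the MEAN n-cell window span equals
    # beta * n * mean(l_AP) -- the quantity the intercalation index measures.
    # At beta (effectively) 1 the cells abut exactly: the stack-of-coins
    # limit, where group length equals the summed cell lengths.
    beta_use <- beta
    pitch_half <- (l[-N] + l[-1]) / 2
    if (N >= n_nb) {
      csl <- cumsum(l)
      wmean <- mean(csl[n_nb:N] - c(0, csl)[seq_len(N - n_nb + 1L)]) / n_nb
      beta_use <- min(beta * lbar / wmean, 1)
    }
    if (beta_use >= 0.999) {
      x <- cumsum(c(l[1] / 2, pitch_half))
      level <- rep(0L, N)
      n_lev <- 1L
    } else {
      if (N >= n_nb) {
        # window j spans c * S_j + E_j with S_j the summed gaps and E_j the
        # end-cap half-lengths; solve c so the window mean equals the target
        cumP <- c(0, cumsum(pitch_half))
        j <- seq_len(N - n_nb + 1L)
        S <- cumP[j + n_nb - 1L] - cumP[j]
        E <- (l[j] + l[j + n_nb - 1L]) / 2
        cfac <- (beta * n_nb * lbar - mean(E)) / mean(S)
      } else {
        cfac <- (beta * n_nb - 1) / (n_nb - 1)
      }
      if (cfac <= 0)
        stop("beta target ", beta, " unreachable for n = ", n_nb)
      gaps <- cfac * pitch_half
      x <- cumsum(c(l[1] / 2, gaps))
      n_lev <- as.integer(ceiling((max(l) + 2 * vox) / min(gaps)))
      level <- (seq_len(N) - 1L) %% n_lev
    }
    dv_ext <- vapply(seq_len(N), function(i) {
      h <- c(geoms[[i]]$a, geoms[[i]]$b * (1 + geoms[[i]]$flare),
             geoms[[i]]$c * (1 + geoms[[i]]$flare))
      (abs(Rs[[i]]) %*% h)[2] * 2
    }, numeric(1))
    dy <- max(dv_ext) + 2 * vox
    y <- (level - (n_lev - 1) / 2) * dy
    z <- rep(0, N)

    type <- rep("central", N)
    if (pfrac > 0) type[ap >= 1 - pfrac] <- "posterior_progenitor"
    prolif <- rep("none", N)
    elig <- type == "posterior_progenitor"
    r <- stats::runif(N)
    prolif[elig & r < 0.5] <- "EdU"
    prolif[elig & r >= 0.5 & r < 0.62] <- "PhH3"

    cells <- data.frame(stage = s, ap = ap, m = m, type = type,
                        x = x, y = y, z = z, l_AP = l, A = targ$A, V = targ$V,
                        prolif = prolif, stringsAsFactors = FALSE)
    cell_geoms <- geoms
    cell_Rs <- Rs

    # Muller rows: single-file abutting cells spanning the same AP range
    if (config$include_muller) {
      span <- c(min(x - l / 2), max(x + l / 2))
      for (side in c(1, -1)) {
        mu_rows <- list(); xm <- span[1]
        while (TRUE) {
          apm <- min(max((xm + 1) / diff(span), 0), 1)  # provisional
          mm <- pmin(pmax(s - config$gradient_gamma * abs(apm - 0.5), mdom[1]), mdom[2])
          tg <- program_eval(config$muller_program, mm)
          if (sdlog > 0) {
            tg$l_AP <- tg$l_AP * exp(stats::rnorm(1, 0, sdlog))
            tg$A <- tg$A * exp(stats::rnorm(1, 0, sdlog))
            tg$V <- tg$V * exp(stats::rnorm(1, 0, sdlog))
          }
          if (xm + tg$l_AP > span[2]) break
          gm <- .cell_geometry(tg, config$muller_program$q,
                               config$muller_program$kappa)
          tg$V <- gm$V
          ctr_x <- xm + tg$l_AP / 2
          apm <- (ctr_x - span[1]) / diff(span)
          mu_rows[[length(mu_rows) + 1L]] <- list(tg = tg, gm = gm, x = ctr_x,
                                                  ap = apm, m = mm)
          xm <- xm + tg$l_AP
        }
        y_off <- side * (max(abs(y)) + dy / 2 +
                           max(vapply(mu_rows, function(r0)
                             r0$gm$b * (1 + r0$gm$flare), numeric(1))) + 2 * vox)
        for (r0 in mu_rows) {
          spin <- if (sdlog > 0)
            stats::runif(1, -1, 1) * config$rotation_max_deg * pi / 180 else 0
          cells <- rbind(cells, data.frame(
            stage = s, ap = r0$ap, m = r0$m,
            type = if (side > 0) "muller_dorsal" else "muller_ventral",
            x = r0$x, y = y_off, z = 0, l_AP = r0$tg$l_AP, A = r0$tg$A,
            V = r0$tg$V, prolif = "none", stringsAsFactors = FALSE))
          cell_geoms[[length(cell_geoms) + 1L]] <- r0$gm
          cell_Rs[[length(cell_Rs) + 1L]] <- .spin_matrix(spin)
        }
      }
    }

    # snap centres to the voxel lattice so noise-free prisms digitise exactly;
    # abutting placements (beta = 1 stacks, Muller rows) must keep their exact
    # face-sharing coordinates, so only pitch-placed cells are snapped in x
    if (beta_use < 0.999) {
      pitched <- !grepl("^muller", cells$type)
      face <- cells$x[pitched] - cells$l_AP[pitched] / 2
      cells$x[pitched] <- round(face / vox) * vox + cells$l_AP[pitched] / 2
    }
    cells$y <- round(cells$y / vox) * vox
    cells$z <- round(cells$z / vox) * vox

    # rasterise into a shared grid
    vox_sets <- lapply(seq_len(nrow(cells)), function(i)
      .rasterize_cell(cell_geoms[[i]], c(cells$x[i], cells$y[i], cells$z[i]),
                      cell_Rs[[i]], vox))
    all_idx <- do.call(rbind, vox_sets)
    lo <- apply(all_idx, 2, min) - 2L
    hi <- apply(all_idx, 2, max) + 2L
    volume <- array(0L, hi - lo + 1L)
    ids <- next_id - 1L + seq_len(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      vi <- sweep(vox_sets[[i]], 2, lo - 1L)
      if (any(volume[vi] != 0L)) {
        hit <- unique(volume[vi][volume[vi] != 0L])
        stop("label collision at stage ", s, ": cell ", ids[i],
             " overlaps cell(s) ", paste(hit, collapse = ", "))
      }
      volume[vi] <- ids[i]
    }
    volumes[[as.character(s)]] <- volume

    cells$cell_id <- ids
    # realised normalised AP position over the stage's full span
    span_all <- c(min(cells$x - cells$l_AP / 2), max(cells$x + cells$l_AP / 2))
    cells$ap_real <- (cells$x - span_all[1]) / diff(span_all)

    # volume-frame coordinates: local = global - (lo - 1) * vox
    off <- (lo - 1L) * vox
    nuc_sd <- 0.3
    nuc_rows[[as.character(s)]] <- data.frame(
      cell_id = ids, embryo = paste0("sim", s), stage = s,
      nuc_ap = cells$x - off[1] + stats::rnorm(nrow(cells), 0, nuc_sd),
      nuc_dv = cells$y - off[2] + stats::rnorm(nrow(cells), 0, nuc_sd),
      nuc_ml = cells$z - off[3] + stats::rnorm(nrow(cells), 0, nuc_sd))

    ann_rows[[as.character(s)]] <- data.frame(
      cell_id = ids, embryo = paste0("sim", s), stage = s,
      ap_position_norm = cells$ap_real,
      layer = ifelse(grepl("^muller", cells$type), "muller", "central"),
      stringsAsFactors = FALSE)
    gt_rows[[as.character(s)]] <- data.frame(
      cell_id = ids, stage = s, maturity = cells$m, cell_type = cells$type,
      ap_position_norm = cells$ap_real, l_AP = cells$l_AP, V = cells$V,
      A = cells$A, beta_target = beta, prolif_label = cells$prolif,
      x_center_um = cells$x - off[1], y_center_um = cells$y - off[2],
      stringsAsFactors = FALSE)
    next_id <- next_id + nrow(cells)
  }

  structure(list(volumes = volumes,
                 nuclei = do.call(rbind, c(nuc_rows, make.row.names = FALSE)),
                 annotations = do.call(rbind, c(ann_rows, make.row.names = FALSE)),
                 ground_truth = do.call(rbind, c(gt_rows, make.row.names = FALSE)),
                 config = config),
            class = "notochord_sim")
}

#' @export
print.notochord_sim <- function(x, ...) {
  gt <- x$ground_truth
  cat("notochord_sim:", nrow(gt), "cells over stages",
      paste(x$config$stages, collapse = ", "), "\n")
  print(table(stage = gt$stage, type = gt$cell_type))
  invisible(x)
}

# --- measurements on the generated arrangement -----------------------------

#' Neighbourhood lengths and intercalation index from ground truth
#'
#' Slides a window of \code{n} consecutive central-column cells (ordered by
#' AP position) along each stage and measures the neighbourhood span from the
#' anterior face of the first cell to the posterior face of the last. The
#' intercalation index is the mean span divided by \code{n} times the stage
#' mean cell length.
#'
#' @param ground_truth Ground-truth table from \code{\link{generate_notochord}}
#'   (or any data frame with \code{stage}, \code{cell_type},
#'   \code{x_center_um}, \code{l_AP}).
#' @param n Cells per neighbourhood.
#' @return Data frame per stage: \code{l_n} (mean span, um), \code{l_n_sem},
#'   \code{l_bar}, \code{beta}.
#' @export
neighborhood_series <- function(ground_truth, n = 10) {
  stopifnot(n >= 2)
  cen <- ground_truth[ground_truth$cell_type %in% c("central", "posterior_progenitor"), ]
  out <- lapply(split(cen, cen$stage), function(g) {
    g <- g[order(g$x_center_um), ]
    N <- nrow(g)
    if (N < n) return(NULL)
    spans <- vapply(seq_len(N - n + 1), function(i) {
      j <- i + n - 1
      (g$x_center_um[j] + g$l_AP[j] / 2) - (g$x_center_um[i] - g$l_AP[i] / 2)
    }, numeric(1))
    data.frame(stage = g$stage[1], l_n = mean(spans),
               l_n_sem = stats::sd(spans) / sqrt(length(spans)),
               l_bar = mean(g$l_AP), beta = mean(spans) / (n * mean(g$l_AP)))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Whole-arrangement tissue length per stage
#'
#' @param ground_truth Ground-truth table.
#' @return Data frame with \code{stage} and \code{tissue_length} (um).
#' @export
tissue_length_series <- function(ground_truth) {
  out <- lapply(split(ground_truth, ground_truth$stage), function(g) {
    data.frame(stage = g$stage[1],
               tissue_length = max(g$x_center_um + g$l_AP / 2) -
                 min(g$x_center_um - g$l_AP / 2))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

# --- analytic fixtures -----------------------------------------------------

#' Rasterise a single superellipsoid into a mask
#'
#' Analytic fixture builder: a superellipsoid with semi-axes \code{a, b, c}
#' (AP, DV, ML), shared exponent \code{p} (\code{Inf} gives an exact box,
#' 2 an ellipsoid), optionally rotated, digitised at the given voxel size.
#'
#' @param a,b,c Semi-axes in micrometres.
#' @param p Superellipsoid exponent.
#' @param voxel_size Voxel edge (um).
#' @param rotation 3x3 rotation matrix applied to the shape (cell frame to
#'   world frame).
#' @return 3D logical mask with the shape centred on the voxel lattice.
#' @export
fixture_superellipsoid <- function(a, b, c, p = 2, voxel_size = 0.5,
                                   rotation = diag(3)) {
  h <- as.vector(abs(rotation) %*% c(a, b, c)) + 2 * voxel_size
  nd <- ceiling(h / voxel_size) * 2L + 1L
  ctr <- floor(nd / 2) + 1L  # shape centre sits on a voxel-corner lattice plane
  rng <- lapply(1:3, function(k) (seq_len(nd[k]) - ctr[k] - 0.5) * voxel_size)
  gx <- rep(rng[[1]], times = nd[2] * nd[3])
  gy <- rep(rep(rng[[2]], each = nd[1]), times = nd[3])
  gz <- rep(rng[[3]], each = nd[1] * nd[2])
  d <- cbind(gx, gy, gz) %*% rotation
  inside <- if (is.finite(p)) {
    (abs(d[, 1]) / a)^p + (abs(d[, 2]) / b)^p + (abs(d[, 3]) / c)^p <= 1
  } else {
    abs(d[, 1]) < a & abs(d[, 2]) < b & abs(d[, 3]) < c
  }
  array(inside, nd)
}

#' Analytic fixture shapes with closed-form expected metrics
#'
#' Builds a set of axis-aligned and rotated primitives (box, ball, tri-axial
#' ellipsoids) at known sizes and returns, for each, a labelled volume plus a
#' table of closed-form metric values with their discretisation tolerances.
#'
#' @param voxel_size Voxel edge (um).
#' @return List with \code{masks} (named list of logical arrays) and
#'   \code{expected} (data frame of closed-form values).
#' @export
generate_fixture_shapes <- function(voxel_size = 0.5) {
  rot_z90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))   # AP -> DV
  rot_xy45 <- rbind(c(sqrt(2)/2, -sqrt(2)/2, 0),
                    c(sqrt(2)/2, sqrt(2)/2, 0), c(0, 0, 1))
  masks <- list(
    cuboid = fixture_superellipsoid(10, 5, 2.5, Inf, voxel_size),
    sphere = fixture_superellipsoid(10, 10, 10, 2, voxel_size),
    ellipsoid = fixture_superellipsoid(10, 5, 2.5, 2, voxel_size),
    ellipsoid_z90 = fixture_superellipsoid(10, 5, 2.5, 2, voxel_size,
                                           rotation = rot_z90),
    cuboid_xy45 = fixture_superellipsoid(10, 5, 2.5, Inf, voxel_size,
                                         rotation = rot_xy45)
  )
  expected <- data.frame(
    shape = names(masks),
    volume = c(1000, 4 / 3 * pi * 1000, 4 / 3 * pi * 125, 4 / 3 * pi * 125, 1000),
    surface_area = c(2 * (20 * 10 + 20 * 5 + 10 * 5), 4 * pi * 100, NA, NA, NA),
    l_AP = c(20, 20, 20, 10, NA),
    orientation_AP = c(1, NA, 1, 0, sqrt(2) / 2),
    orientation_DV = c(0, NA, 0, 1, sqrt(2) / 2),
    orientation_ML = c(0, NA, 0, 0, 0),
    aspect_AP_DV = c(2, 1, 2, 0.5, NA),
    aspect_AP_ML = c(4, 1, 4, 4, NA),
    aspect_DV_ML = c(2, 1, 2, 8, NA),
    cuboidness = c(1, pi / 6, pi / 6, pi / 6, NA),
    sphericity = c(NA, 1, NA, NA, NA),
    # the 45-degree box digitises with a larger boundary bias than the
    # lattice-aligned shapes, hence its wider tolerance
    tol_rel = c(0.02, 0.02, 0.02, 0.02, 0.05)
  )
  list(masks = masks, expected = expected)
}
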
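# Geometric model of cell and neighbourhood elongation.
#
# A mean cell at stage s is summarised by its AP length l(s), volume V(s) and
# transverse cross-sectional area A(s), linked by the prism approximation
# l ~ V / A. Counterfactual scenarios change one quantity while freezing the
# others at the reference stage s0, and the intercalation index
# beta = l_n / (n * l) extends cell-scale predictions to neighbourhoods of n
# cells via l_n = beta * n * l.

#' Per-stage mean cell parameters
#'
#' Arithmetic means and standard errors, per stage, of AP length, volume,
#' transverse cross-sectional area and bounding-box transverse area, from an
#' (already filtered) feature table. The relative error of the prism
#' approximation |l - V/A| / l is reported per stage as a model diagnostic.
#'
#' @param table Feature data frame (typically filtered to one region and the
#'   central layer) with columns \code{stage}, \code{l_AP}, \code{volume},
#'   \code{area_transverse}, \code{area_bb}.
#' @param stages Stages that must be present (default: all in the table).
#' @return Data frame of class \code{mean_cell_params}, one row per stage.
#' @export
mean_cell_params <- function(table, stages = NULL) {
  if (is.null(stages)) stages <- sort(unique(table$stage))
  missing_s <- setdiff(stages, unique(table$stage))
  if (length(missing_s))
    stop("missing stage(s): ", paste(missing_s, collapse = ", "))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(stages, function(s) {
    g <- table[table$stage == s, ]
    if (nrow(g) < 3) stop("stage ", s, " has fewer than 3 cells")
    data.frame(stage = s, n = nrow(g),
               l_AP = mean(g$l_AP), l_AP_sem = sem(g$l_AP),
               V = mean(g$volume), V_sem = sem(g$volume),
               A = mean(g$area_transverse), A_sem = sem(g$area_transverse),
               A_bb = mean(g$area_bb), A_bb_sem = sem(g$area_bb))
  }))
  out$eq1_rel_error <- abs(out$l_AP - out$V / out$A) / out$l_AP
  class(out) <- c("mean_cell_params", "data.frame")
  out
}

#' @export
print.mean_cell_params <- function(x, ...) {
  cat("mean_cell_params over stages", paste(x$stage, collapse = ", "), "\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  cat(sprintf("prism-approximation error: %.1f%% (max over stages)\n",
              100 * max(x$eq1_rel_error)))
  invisible(x)
}

#' AP length from the prism approximation
#'
#' @param V Cell volume (um^3).
#' @param A Transverse cross-sectional area (um^2).
#' @return Approximate AP length V / A (um).
#' @export
ap_length_eq1 <- function(V, A) {
  if (any(V <= 0) || any(A <= 0)) stop("V and A must be positive")
  V / A
}

.param_at <- function(params, s, what = "stage") {
  i <- match(s, params$stage)
  if (is.na(i)) stop("stage ", s, " not in parameters")
  params[i, ]
}

#' Constant-volume (AP anisotropy) scenario
#'
#' Predicted AP length when volume stays at its reference-stage value and
#' cross-sectional area follows its measured time course:
#' l(s) = V(s0) / A(s).
#'
#' @param params A \code{mean_cell_params}.
#' @param s Stage(s) of interest.
#' @param s0 Reference stage (default: first stage in \code{params}).
#' @return Predicted length(s) in um.
#' @export
scenario_ap_anisotropy <- function(params, s, s0 = params$stage[1]) {
  p0 <- .param_at(params, s0)
  vapply(s, function(si) p0$V / .param_at(params, si)$A, numeric(1))
}

#' Isotropic growth scenario
#'
#' Volume follows its measured course and scales the cell proportionally in
#' all directions: l(s) = l(s0) * (V(s) / V(s0))^(1/3).
#'
#' @inheritParams scenario_ap_anisotropy
#' @export
scenario_isotropic_growth <- function(params, s, s0 = params$stage[1]) {
  p0 <- .param_at(params, s0)
  vapply(s, function(si) p0$l_AP * (.param_at(params, si)$V / p0$V)^(1/3),
         numeric(1))
}

#' Anisotropic growth scenario
#'
#' Volume follows its measured course while the cross-section is frozen at
#' its reference value, so growth acts on AP length alone:
#' l(s) = l(s0) * V(s) / V(s0).
#'
#' @inheritParams scenario_ap_anisotropy
#' @export
scenario_anisotropic_growth <- function(params, s, s0 = params$stage[1]) {
  p0 <- .param_at(params, s0)
  vapply(s, function(si) p0$l_AP * .param_at(params, si)$V / p0$V, numeric(1))
}

#' Intercalation index of a cell neighbourhood
#'
#' beta = l_n / (n * l_bar): the measured neighbourhood length relative to the
#' maximal (stack-of-coins) extension of n cells of mean length l_bar.
#' Values slightly above 1 (measurement noise) are clipped to 1 with a
#' warning.
#'
#' @param l_n Measured neighbourhood AP length (um).
#' @param n Number of cells in the neighbourhood (>= 2).
#' @param l_bar Mean AP cell length (um).
#' @return beta in (0, 1].
#' @export
intercalation_index <- function(l_n, n, l_bar) {
  if (n < 2) stop("n must be at least 2")
  if (any(l_n <= 0) || any(l_bar <= 0)) stop("lengths must be positive")
  beta <- l_n / (n * l_bar)
  if (any(beta > 1)) {
    warning("beta > 1 clipped to 1 (measurement noise)")
    beta <- pmin(beta, 1)
  }
  beta
}

#' Neighbourhood length from the intercalation index
#'
#' l_n = beta * n * l_bar: extended AP group length from cell number, mean
#' cell length and intercalation index.
#'
#' @param beta Intercalation index in (0, 1].
#' @param n Number of cells (>= 2).
#' @param l_bar Mean AP cell length (um).
#' @return Neighbourhood length (um).
#' @export
neighborhood_length_eq2 <- function(beta, n, l_bar) {
  if (n < 2) stop("n must be at least 2")
  if (any(beta <= 0) || any(beta > 1)) stop("beta must be in (0, 1]")
  if (any(l_bar <= 0)) stop("l_bar must be positive")
  beta * n * l_bar
}

#' Neighbourhood-length scenarios over a stage course
#'
#' Predicts the length of an n-cell neighbourhood at each stage under one of
#' five scenarios: \describe{
#'   \item{intercalation_only}{measured beta(s) applied to groups of frozen
#'     reference-stage cells: l_n = beta(s) * n * l(s0).}
#'   \item{shape_no_growth}{measured beta(s) and cross-section, volume frozen:
#'     l_n = beta(s) * n * V(s0)/A(s).}
#'   \item{isotropic_growth_only}{beta frozen at beta(s0), isotropic growth:
#'     l_n = beta(s0) * n * l(s0) * (V(s)/V(s0))^(1/3).}
#'   \item{anisotropic_growth_only}{beta frozen, growth acts on length alone:
#'     l_n = beta(s0) * n * l(s0) * V(s)/V(s0).}
#'   \item{full}{measured beta(s) and measured mean length:
#'     l_n = beta(s) * n * l(s), which reproduces the measured neighbourhood
#'     lengths by construction of beta.}
#' }
#'
#' @param params A \code{mean_cell_params}.
#' @param series Data frame with \code{stage} and \code{beta} (e.g. from
#'   \code{\link{neighborhood_series}}).
#' @param scenario Scenario name (above).
#' @param n Cells per neighbourhood.
#' @param s0 Reference stage.
#' @return Data frame with \code{stage}, \code{scenario}, \code{l_n} and
#'   \code{pct_change} (percent change from s0).
#' @export
scenario_neighborhood <- function(params, series,
                                  scenario = c("intercalation_only",
                                               "shape_no_growth",
                                               "isotropic_growth_only",
                                               "anisotropic_growth_only",
                                               "full"),
                                  n = 10, s0 = params$stage[1]) {
  scenario <- match.arg(scenario)
  stages <- params$stage
  if (!all(stages %in% series$stage))
    stop("series lacks stage(s): ",
         paste(setdiff(stages, series$stage), collapse = ", "))
  beta_s <- series$beta[match(stages, series$stage)]
  beta_0 <- series$beta[match(s0, series$stage)]
  p0 <- .param_at(params, s0)
  l_used <- switch(scenario,
    intercalation_only = rep(p0$l_AP, length(stages)),
    shape_no_growth = scenario_ap_anisotropy(params, stages, s0),
    isotropic_growth_only = scenario_isotropic_growth(params, stages, s0),
    anisotropic_growth_only = scenario_anisotropic_growth(params, stages, s0),
    full = params$l_AP)
  beta_used <- if (scenario %in% c("isotropic_growth_only",
                                   "anisotropic_growth_only"))
    rep(beta_0, length(stages)) else beta_s
  l_n <- beta_used * n * l_used
  ref <- l_n[match(s0, stages)]
  data.frame(stage = stages, scenario = scenario, l_n = l_n,
             pct_change = 100 * (l_n - ref) / ref)
}

#' Cell-scale versus tissue-scale elongation
#'
#' Normalises a neighbourhood-length series and a tissue-length series to
#' their values at the first shared stage and returns the relative-change
#' curves together with their difference (the gap attributable to posterior
#' cell addition).
#'
#' @param neighborhood Data frame with \code{stage} and a length column
#'   (\code{l_n}).
#' @param tissue Data frame with \code{stage} and \code{tissue_length}.
#' @return Data frame with \code{stage}, \code{rel_neighborhood},
#'   \code{rel_tissue}, \code{gap}.
#' @export
elongation_comparison <- function(neighborhood, tissue) {
  if (!setequal(neighborhood$stage, tissue$stage))
    stop("stage mismatch between series")
  stages <- sort(unique(neighborhood$stage))
  ln <- neighborhood$l_n[match(stages, neighborhood$stage)]
  lt <- tissue$tissue_length[match(stages, tissue$stage)]
  rn <- ln / ln[1]
  rt <- lt / lt[1]
  data.frame(stage = stages, rel_neighborhood = rn, rel_tissue = rt,
             gap = rt - rn)
}
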
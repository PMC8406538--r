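# Proliferation landscapes: density of labelled nuclei along the normalised
# AP axis, pooled per stage, with the axis rescaled to the stage mean length.

#' Normalise nucleus positions along the AP axis
#'
#' Maps each labelled nucleus to p = (x - x_ant) / (x_post - x_ant) using its
#' embryo's anterior and posterior reference coordinates. Positions up to 2\%
#' outside [0, 1] are clipped with a warning; larger excursions are an error.
#'
#' @param table Data frame with columns \code{embryo}, \code{stage},
#'   \code{marker}, \code{x_um}, \code{x_anterior_um}, \code{x_posterior_um}.
#' @return The table with an added \code{ap_norm} column.
#' @export
normalize_positions <- function(table) {
  need <- c("embryo", "stage", "marker", "x_um", "x_anterior_um",
            "x_posterior_um")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(table$x_anterior_um)) || any(is.na(table$x_posterior_um)))
    stop("missing axis reference coordinates for embryo(s): ",
         paste(unique(table$embryo[is.na(table$x_anterior_um) |
                                     is.na(table$x_posterior_um)]),
               collapse = ", "))
  len <- table$x_posterior_um - table$x_anterior_um
  if (any(len <= 0)) stop("anterior reference must precede posterior")
  p <- (table$x_um - table$x_anterior_um) / len
  out_of_range <- p < 0 | p > 1
  too_far <- p < -0.02 | p > 1.02
  if (any(too_far))
    stop(sum(too_far), " nucleus position(s) more than 2% outside the axis")
  if (any(out_of_range)) {
    warning("clipping ", sum(out_of_range),
            " slightly out-of-range position(s) to [0, 1]")
    p <- pmin(pmax(p, 0), 1)
  }
  table$ap_norm <- p
  table
}

#' Build per-stage, per-marker proliferation landscapes
#'
#' Pools normalised nucleus positions per (stage, marker), rescales the axis
#' of stage s to its mean length L(s), and estimates a Gaussian kernel
#' density with reflective boundaries at 0 and L(s). Each curve is scaled so
#' that its integral equals the mean number of labelled nuclei per embryo at
#' that stage ("mean frequency" rather than probability); set
#' \code{frequency = FALSE} for unit-integral densities.
#'
#' @param table Output of \code{\link{normalize_positions}}.
#' @param stage_lengths Data frame with \code{stage} and \code{mean_length_um}.
#' @param bw Kernel bandwidth on the scaled axis (um); default Silverman's
#'   rule per curve.
#' @param n_grid Grid resolution per curve.
#' @param frequency Scale integrals to mean per-embryo counts (default TRUE).
#' @param min_nuclei Minimum labelled nuclei per (stage, marker); sparser
#'   combinations are skipped with a warning.
#' @return Data frame of class \code{prolif_landscape} with \code{stage},
#'   \code{marker}, \code{x_um} (position on the scaled axis),
#'   \code{density} and \code{mean_count}.
#' @export
build_landscape <- function(table, stage_lengths, bw = NULL, n_grid = 256,
                            frequency = TRUE, min_nuclei = 5) {
  stopifnot("ap_norm" %in% names(table))
  if (any(stage_lengths$mean_length_um <= 0))
    stop("stage mean lengths must be positive")
  out <- list()
  for (s in sort(unique(table$stage))) {
    L <- stage_lengths$mean_length_um[match(s, stage_lengths$stage)]
    if (is.na(L)) stop("no mean length for stage ", s)
    sub <- table[table$stage == s, ]
    n_embryos <- length(unique(sub$embryo))
    for (mk in sort(unique(sub$marker))) {
      x <- sub$ap_norm[sub$marker == mk] * L
      if (length(x) < min_nuclei) {
        warning("skipping stage ", s, " marker ", mk, ": only ",
                length(x), " nuclei")
        next
      }
      h <- if (is.null(bw)) stats::bw.nrd0(x) else bw
      grid <- seq(0, L, length.out = n_grid)
      dens <- vapply(grid, function(g)
        mean(stats::dnorm(g - x, sd = h) + stats::dnorm(g + x, sd = h) +
               stats::dnorm(2 * L - g - x, sd = h)), numeric(1))
      mean_count <- length(x) / n_embryos
      if (frequency) dens <- dens * mean_count
      out[[paste(s, mk)]] <- data.frame(stage = s, marker = mk, x_um = grid,
                                        density = dens,
                                        mean_count = mean_count)
    }
  }
  if (!length(out)) {
    res <- data.frame(stage = numeric(0), marker = character(0),
                      x_um = numeric(0), density = numeric(0),
                      mean_count = numeric(0))
  } else {
    res <- do.call(rbind, c(out, make.row.names = FALSE))
  }
  class(res) <- c("prolif_landscape", "data.frame")
  res
}

#' Ridgeline-style plot of a proliferation landscape
#'
#' @param x A \code{prolif_landscape}.
#' @param ... Passed to \code{plot}.
#' @export
plot.prolif_landscape <- function(x, ...) {
  stages <- sort(unique(x$stage))
  markers <- sort(unique(x$marker))
  ymax <- max(x$density)
  graphics::plot(NA, xlim = range(x$x_um), ylim = c(0, length(stages)),
                 xlab = "AP position (um, axis scaled to stage mean)",
                 ylab = "somite stage", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(stages) - 0.5, labels = stages)
  cols <- grDevices::hcl.colors(max(2L, length(markers)), "Dark 2")
  for (i in seq_along(stages)) {
    base <- i - 1
    for (j in seq_along(markers)) {
      sub <- x[x$stage == stages[i] & x$marker == markers[j], ]
      if (!nrow(sub)) next
      graphics::lines(sub$x_um, base + 0.9 * sub$density / ymax, col = cols[j])
    }
  }
  graphics::legend("topleft", legend = markers, col = cols[seq_along(markers)],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Nucleus table of labelled cells from a synthetic notochord
#'
#' Converts the generator's ground truth into the raw nucleus-position format
#' consumed by \code{\link{normalize_positions}}, using the arrangement span
#' as the embryo axis references.
#'
#' @param sim A \code{notochord_sim}.
#' @return Data frame with one row per labelled (EdU or PhH3) nucleus.
#' @export
prolif_nucleus_table <- function(sim) {
  gt <- sim$ground_truth
  rows <- list()
  for (s in unique(gt$stage)) {
    g <- gt[gt$stage == s, ]
    lab <- g[g$prolif_label != "none", ]
    if (!nrow(lab)) next
    ant <- min(g$x_center_um - g$l_AP / 2)
    post <- max(g$x_center_um + g$l_AP / 2)
    rows[[as.character(s)]] <- data.frame(
      embryo = paste0("sim", s), stage = s, marker = lab$prolif_label,
      x_um = lab$x_center_um, x_anterior_um = ant, x_posterior_um = post)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
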
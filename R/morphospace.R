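# PCA morphospace: feature screening, standardised PCA, embedding.

#' Default morphospace feature set
#'
#' The per-cell descriptors entered into the PCA by default: orientation of
#' the major ellipsoid axis, surface area, volume, the three axis-aligned
#' aspect ratios, AP anisotropy, nuclear displacement, cuboidness, sphericity
#' and flatness. Raw bounding-box and ellipsoid axis lengths, positions and
#' stage are deliberately excluded (redundant with, or extrinsic to, shape).
#'
#' @return Character vector of feature names.
#' @export
morphospace_features <- function() {
  c("orientation_AP", "orientation_DV", "orientation_ML",
    "surface_area", "volume",
    "aspect_AP_DV", "aspect_AP_ML", "aspect_DV_ML",
    "AP_anisotropy",
    "nuc_dAP", "nuc_dDV", "nuc_dML",
    "cuboidness", "sphericity", "flatness")
}

# priority order used when the redundancy screen must drop one of a pair:
# curated dimensionless descriptors first, then areas/volumes, then raw
# lengths; within a family, earlier-listed names are preferred
.feature_priority <- function(features) {
  pref <- c(morphospace_features(),
            "area_transverse", "area_bb", "prolate_ellipticity",
            "oblate_ellipticity", "l_AP", "l_DV", "l_ML",
            "o1", "o2", "o3", "ell_a", "ell_b", "ell_c")
  rank <- match(features, pref)
  rank[is.na(rank)] <- length(pref) + seq_len(sum(is.na(rank)))
  rank
}

#' Screen redundant features by pairwise correlation
#'
#' Greedy removal: while any retained pair has |Pearson r| at or above the
#' threshold, the pair with the largest |r| is found and its lower-priority
#' member dropped. Constant features (undefined r) are removed first with a
#' warning.
#'
#' @param table Data frame containing the candidate feature columns.
#' @param features Candidate feature names (default
#'   \code{\link{morphospace_features}} intersected with the table).
#' @param threshold Absolute correlation at or above which a pair is
#'   considered redundant.
#' @return Character vector of retained feature names.
#' @export
screen_redundant_features <- function(table, features = NULL, threshold = 0.95) {
  if (is.null(features))
    features <- intersect(morphospace_features(), names(table))
  stopifnot(length(features) >= 2, nrow(table) >= 3)
  x <- as.matrix(table[, features, drop = FALSE])
  sds <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE))
  const <- is.na(sds) | sds < 1e-12
  if (any(const)) {
    warning("removing constant feature(s): ",
            paste(features[const], collapse = ", "))
    features <- features[!const]
    x <- x[, features, drop = FALSE]
  }
  repeat {
    r <- abs(stats::cor(x, use = "pairwise.complete.obs"))
    diag(r) <- 0
    if (max(r, na.rm = TRUE) < threshold) break
    ij <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pr <- .feature_priority(features[ij])
    drop <- ij[which.max(pr)]
    features <- features[-drop]
    x <- x[, features, drop = FALSE]
    if (length(features) < 2) break
  }
  features
}

#' Fit a PCA morphospace
#'
#' Standardises the retained features to zero mean and unit variance across
#' all cells and performs a PCA. Component signs are fixed so that the
#' largest-|loading| feature of each component loads positively. Cells with
#' missing feature values (flagged degenerate metrics, absent nuclei) are
#' excluded listwise and counted.
#'
#' @param table Annotated feature data frame.
#' @param n_components Number of components to report (loadings for all
#'   components are retained internally for reconstruction).
#' @param features Feature names; defaults to
#'   \code{\link{screen_redundant_features}} on the default set.
#' @param screen_threshold Redundancy threshold passed to the screen.
#' @return Object of class \code{morphospace}: retained feature names,
#'   per-feature centre/scale, loading matrix, per-component variance
#'   fractions, contribution matrix (percent per feature per component) and
#'   cell counts.
#' @export
fit_morphospace <- function(table, n_components = 5, features = NULL,
                            screen_threshold = 0.95) {
  if (is.null(features))
    features <- screen_redundant_features(table, threshold = screen_threshold)
  x <- as.matrix(table[, features, drop = FALSE])
  ok <- stats::complete.cases(x)
  n_dropped <- sum(!ok)
  x <- x[ok, , drop = FALSE]
  p <- length(features)
  if (n_components > p)
    stop("n_components (", n_components, ") exceeds retained features (", p, ")")
  if (nrow(x) <= p) stop("need more complete cells than features")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl < 1e-12)) stop("constant feature after screening: ",
                             paste(features[scl < 1e-12], collapse = ", "))
  z <- scale(x, ctr, scl)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load <- pc$rotation
  # sign convention: dominant feature of each component loads positively
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  ev <- pc$sdev^2
  vf <- ev / sum(ev)
  contrib <- 100 * load^2  # loadings are unit vectors: columns sum to 100
  structure(list(features = features, center = ctr, scale = scl,
                 loadings = load, eigenvalues = ev, variance_fraction = vf,
                 contributions = contrib, n_components = n_components,
                 n_cells = nrow(x), n_dropped = n_dropped),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat("morphospace:", length(x$features), "features,", x$n_cells, "cells")
  if (x$n_dropped) cat(" (", x$n_dropped, " dropped for missing values)", sep = "")
  cat("\nvariance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(x$n_components),
                    100 * x$variance_fraction[seq_len(x$n_components)]),
            collapse = ", "),
      sprintf("| top %d total %.1f", x$n_components,
              100 * sum(x$variance_fraction[seq_len(x$n_components)])), "\n")
  invisible(x)
}

#' @export
summary.morphospace <- function(object, ...) {
  print(object)
  for (j in seq_len(object$n_components)) {
    cat(sprintf("PC%d significant contributors: %s\n", j,
                paste(significant_contributors(object, j), collapse = ", ")))
  }
  invisible(object)
}

#' Features contributing above the mean to a component
#'
#' A feature contributes significantly to a component when its contribution
#' exceeds the mean contribution over all retained features (100/p percent).
#'
#' @param model A \code{morphospace}.
#' @param component Component index.
#' @return Character vector of feature names, ordered by contribution.
#' @export
significant_contributors <- function(model, component) {
  stopifnot(inherits(model, "morphospace"))
  if (component < 1 || component > ncol(model$contributions))
    stop("unknown component: ", component)
  co <- model$contributions[, component]
  sel <- co > 100 / length(model$features)
  names(sort(co[sel], decreasing = TRUE))
}

#' Embed cells into a fitted morphospace
#'
#' Applies the stored standardisation and loadings to a feature table and
#' returns component coordinates joined to any annotation columns present.
#'
#' @param model A \code{morphospace}.
#' @param table Feature data frame containing all retained features.
#' @param annotations Annotation column names to carry through when present
#'   (default: the usual stage/layer/region identifiers).
#' @return Data frame of PC coordinates (PC1..PCk) plus annotations.
#' @export
embed_morphospace <- function(model, table,
                              annotations = c("cell_id", "embryo", "stage",
                                              "ap_position_norm", "layer",
                                              "region")) {
  stopifnot(inherits(model, "morphospace"))
  missing_f <- setdiff(model$features, names(table))
  if (length(missing_f))
    stop("table lacks retained feature(s): ", paste(missing_f, collapse = ", "))
  x <- as.matrix(table[, model$features, drop = FALSE])
  ok <- stats::complete.cases(x)
  z <- scale(x[ok, , drop = FALSE], model$center, model$scale)
  k <- model$n_components
  coords <- z %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  out <- as.data.frame(coords)
  keep <- intersect(annotations, names(table))
  if (length(keep)) out <- cbind(table[ok, keep, drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' @export
predict.morphospace <- function(object, newdata, ...) {
  embed_morphospace(object, newdata)
}

#' Reconstruct standardised features from all components
#'
#' Round-trip utility (and invariant check): projects onto all components and
#' back, which reproduces the standardised input exactly.
#'
#' @param model A \code{morphospace}.
#' @param table Feature data frame.
#' @return Matrix of reconstructed standardised feature values.
#' @export
reconstruct_morphospace <- function(model, table) {
  x <- as.matrix(table[, model$features, drop = FALSE])
  ok <- stats::complete.cases(x)
  z <- scale(x[ok, , drop = FALSE], model$center, model$scale)
  (z %*% model$loadings) %*% t(model$loadings)
}

#' Scatter of cells in a component plane
#'
#' @param x A \code{morphospace}.
#' @param table Feature table to embed.
#' @param components Pair of component indices.
#' @param colour_by Optional annotation column used to colour points.
#' @param ... Passed to \code{plot}.
#' @export
plot.morphospace <- function(x, table, components = c(1, 2),
                             colour_by = NULL, ...) {
  emb <- embed_morphospace(x, table)
  cx <- paste0("PC", components[1]); cy <- paste0("PC", components[2])
  col <- "grey30"
  if (!is.null(colour_by) && colour_by %in% names(emb)) {
    f <- factor(emb[[colour_by]])
    col <- grDevices::hcl.colors(nlevels(f), "viridis")[as.integer(f)]
  }
  graphics::plot(emb[[cx]], emb[[cy]], col = col, pch = 16, cex = 0.6,
                 xlab = sprintf("%s (%.1f%%)", cx,
                                100 * x$variance_fraction[components[1]]),
                 ylab = sprintf("%s (%.1f%%)", cy,
                                100 * x$variance_fraction[components[2]]), ...)
  invisible(emb)
}

#' Serialise a morphospace model to JSON
#'
#' @param model A \code{morphospace}.
#' @param path Output file.
#' @export
write_morphospace <- function(model, path) {
  jsonlite::write_json(list(
    features = model$features, center = model$center, scale = model$scale,
    loadings = model$loadings, eigenvalues = model$eigenvalues,
    variance_fraction = model$variance_fraction,
    n_components = model$n_components, n_cells = model$n_cells
  ), path, digits = NA, auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}
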
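# Per-cell 3D shape descriptors from labelled segmentation volumes.
#
# Axis convention throughout: anteroposterior (AP) ~ x (first array margin),
# dorsoventral (DV) ~ y (second margin), mediolateral (ML) ~ z (third margin).
# All physical quantities are in micrometres (um, um^2, um^3); voxels are
# isotropic cubes of edge voxel_size_um.

#' Extract per-cell voxel records from a labelled volume
#'
#' Splits a labelled 3D segmentation volume (background 0, one positive
#' integer label per cell) into one \code{cell_shape} record per label, with
#' centroid in physical coordinates and optional nucleus centroid joined by
#' cell id.
#'
#' @param label_volume 3D array of non-negative integer labels.
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @param nucleus_table Optional data frame with columns \code{cell_id},
#'   \code{nuc_ap}, \code{nuc_dv}, \code{nuc_ml} (micrometres).
#' @param check_connectivity Verify that every label forms a single
#'   6-connected component (error on violation, naming the label).
#' @return List of \code{cell_shape} objects. Each carries the voxel index
#'   matrix, mask offset, centroid, border flag and (optionally) nucleus
#'   centroid.
#' @export
extract_cells <- function(label_volume, voxel_size_um, nucleus_table = NULL,
                          check_connectivity = TRUE) {
  if (length(dim(label_volume)) != 3L)
    stop("label_volume must be a 3D array")
  if (voxel_size_um <= 0) stop("voxel_size_um must be positive")
  v <- as.vector(label_volume)
  if (any(v < 0) || any(v != round(v)))
    stop("labels must be non-negative integers")
  idx <- which(v > 0)
  if (!length(idx)) stop("label volume contains no labelled voxels")
  labs <- v[idx]
  d <- dim(label_volume)
  by_lab <- split(idx, labs)

  if (!is.null(nucleus_table)) {
    need <- c("cell_id", "nuc_ap", "nuc_dv", "nuc_ml")
    if (!all(need %in% names(nucleus_table)))
      stop("nucleus_table needs columns: ", paste(need, collapse = ", "))
    orphan <- setdiff(nucleus_table$cell_id, as.integer(names(by_lab)))
    if (length(orphan)) {
      warning("dropping nucleus rows without matching cell: ",
              paste(orphan, collapse = ", "))
      nucleus_table <- nucleus_table[!nucleus_table$cell_id %in% orphan, ]
    }
  }

  lapply(names(by_lab), function(nm) {
    lin <- by_lab[[nm]]
    vox <- arrayInd(lin, d)
    lab <- as.integer(nm)
    if (check_connectivity && !.is_connected(vox))
      stop("label ", lab, " is not a single connected component")
    border <- any(vox == 1L) || any(sweep(vox, 2, d, "==" ))
    centroid <- colMeans(vox - 0.5) * voxel_size_um
    nuc <- NULL
    if (!is.null(nucleus_table) && lab %in% nucleus_table$cell_id) {
      r <- nucleus_table[match(lab, nucleus_table$cell_id), ]
      nuc <- c(r$nuc_ap, r$nuc_dv, r$nuc_ml)
    }
    structure(list(cell_id = lab, voxels = vox, voxel_size_um = voxel_size_um,
                   centroid_um = centroid, nucleus_centroid_um = nuc,
                   on_border = border),
              class = "cell_shape")
  })
}

# 6-connectivity check by frontier flood fill over linear keys
.is_connected <- function(vox) {
  n <- nrow(vox)
  if (n <= 1L) return(TRUE)
  off <- sweep(vox, 2, apply(vox, 2, min) - 1L)  # 1-based, compact
  dd <- apply(off, 2, max) + 1L
  key <- function(m) (m[, 1] - 1L) + dd[1] * ((m[, 2] - 1L) + dd[2] * (m[, 3] - 1L))
  keys <- key(off)
  remaining <- new.env(hash = TRUE, size = n)
  for (k in keys) assign(as.character(k), TRUE, envir = remaining)
  steps <- c(1L, -1L, dd[1], -dd[1], dd[1] * dd[2], -dd[1] * dd[2])
  frontier <- keys[1]
  rm(list = as.character(frontier), envir = remaining)
  seen <- 1L
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, steps, "+")))
    nb <- nb[vapply(as.character(nb), exists, logical(1), envir = remaining)]
    if (length(nb)) rm(list = as.character(nb), envir = remaining)
    seen <- seen + length(nb)
    frontier <- nb
  }
  seen == n
}

#' Dense binary mask of one cell
#'
#' @param cell A \code{cell_shape}.
#' @return List with \code{mask} (3D logical array over the cell's bounding
#'   box) and \code{origin} (0-based voxel offset of the box in the volume).
#' @keywords internal
cell_mask <- function(cell) {
  vox <- cell$voxels
  lo <- apply(vox, 2, min)
  hi <- apply(vox, 2, max)
  m <- array(FALSE, hi - lo + 1L)
  m[sweep(vox, 2, lo - 1L)] <- TRUE
  list(mask = m, origin = lo - 1L)
}

#' Core geometric descriptors of one cell
#'
#' Computes volume, surface area, axis-aligned and object-oriented bounding
#' boxes, moment-ellipsoid semi-axes and the orientation of the major axis.
#'
#' The ellipsoid semi-axes come from the eigen-decomposition of the voxel
#' second-moment matrix (with the per-voxel variance \code{vox^2/12} added on
#' the diagonal so a filled box of side L has variance exactly L^2/12), scaled
#' by \code{sqrt(5 * lambda)} so that a uniformly filled ellipsoid is
#' recovered exactly. Orientations are absolute direction cosines between the
#' major eigenvector and the AP/DV/ML axes; their squares sum to one.
#'
#' @param cell A \code{cell_shape}.
#' @param area_smooth_sigma Gaussian smoothing (voxel units) applied to the
#'   occupancy field before the surface-area mesh is extracted; suppresses
#'   staircase overestimation of the area of smooth objects.
#' @return One-row data frame of core metrics; degenerate cells (< 4 voxels
#'   or rank-deficient moments) have metrics set to NA and
#'   \code{flag_degenerate = TRUE}. Near-isotropic cells (major and second
#'   eigenvalue within 2\%) are flagged \code{flag_isotropic} since their
#'   orientation is unconstrained.
#' @export
compute_core_metrics <- function(cell, area_smooth_sigma = 0.7) {
  stopifnot(inherits(cell, "cell_shape"))
  vox <- cell$voxels
  vs <- cell$voxel_size_um
  n <- nrow(vox)
  out <- data.frame(cell_id = cell$cell_id, n_voxels = n,
                    volume = n * vs^3, surface_area = NA_real_,
                    n_triangles = NA_integer_,
                    l_AP = NA_real_, l_DV = NA_real_, l_ML = NA_real_,
                    o1 = NA_real_, o2 = NA_real_, o3 = NA_real_,
                    ell_a = NA_real_, ell_b = NA_real_, ell_c = NA_real_,
                    orientation_AP = NA_real_, orientation_DV = NA_real_,
                    orientation_ML = NA_real_,
                    flag_degenerate = FALSE, flag_isotropic = FALSE,
                    flag_border = isTRUE(cell$on_border))
  if (n < 4L) {
    out$flag_degenerate <- TRUE
    out$volume <- NA_real_
    return(out)
  }
  cm <- cell_mask(cell)
  msh <- voxel_mesh(cm$mask, vs, area_smooth_sigma)
  out$surface_area <- mesh_area(msh)
  out$n_triangles <- nrow(msh$triangles)

  ext <- apply(vox, 2, max) - apply(vox, 2, min) + 1L
  out[c("l_AP", "l_DV", "l_ML")] <- as.list(ext * vs)

  ctr <- sweep(vox, 2, colMeans(vox))
  cv <- crossprod(ctr) / n + diag(1 / 12, 3)  # voxel-center covariance + cube term
  cv <- cv * vs^2
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values <= 0)) {
    out$flag_degenerate <- TRUE
    return(out)
  }
  ax <- sqrt(5 * eg$values)
  out[c("ell_a", "ell_b", "ell_c")] <- as.list(ax)
  if (ax[2] / ax[1] > 0.98) out$flag_isotropic <- TRUE

  # oriented bounding box: extents along eigenvectors of the voxel cloud,
  # plus the support of the voxel cube itself in each eigen-direction
  proj <- (vox - 0.5) %*% eg$vectors * vs
  supp <- colSums(abs(eg$vectors)) * vs / 2
  ob <- apply(proj, 2, max) - apply(proj, 2, min) + 2 * supp
  out[c("o1", "o2", "o3")] <- as.list(sort(ob, decreasing = TRUE))

  e1 <- eg$vectors[, 1]
  out[c("orientation_AP", "orientation_DV", "orientation_ML")] <- as.list(abs(e1))
  out
}

#' Derived shape descriptors
#'
#' Completes a core metric row with the dimensionless and composite
#' descriptors: transverse cross-sectional area (area of the binary projection
#' of the mask onto the DV-ML plane), bounding-box transverse area, AP
#' anisotropy \code{l_AP / sqrt(A)}, cuboidness \code{V / (o1 o2 o3)},
#' sphericity \code{pi^(1/3) (6V)^(2/3) / surface_area}, flatness \code{c/b},
#' prolate/oblate ellipticity, the three axis-aligned aspect ratios, and the
#' nuclear displacement vector (missing, not zero, when no nucleus is given).
#'
#' @param core One-row data frame from \code{\link{compute_core_metrics}}.
#' @param cell The \code{cell_shape} the core row was computed from.
#' @return One-row data frame with all shape features.
#' @export
compute_derived_metrics <- function(core, cell) {
  stopifnot(inherits(cell, "cell_shape"))
  out <- core
  vs <- cell$voxel_size_um
  out$area_transverse <- NA_real_
  out$area_bb <- NA_real_
  out$AP_anisotropy <- NA_real_
  out$cuboidness <- NA_real_
  out$sphericity <- NA_real_
  out$flatness <- NA_real_
  out$prolate_ellipticity <- NA_real_
  out$oblate_ellipticity <- NA_real_
  out$aspect_AP_DV <- NA_real_
  out$aspect_AP_ML <- NA_real_
  out$aspect_DV_ML <- NA_real_
  out$nuc_dAP <- NA_real_; out$nuc_dDV <- NA_real_; out$nuc_dML <- NA_real_
  if (isTRUE(core$flag_degenerate)) return(out)

  vox <- cell$voxels
  A <- nrow(unique(vox[, 2:3, drop = FALSE])) * vs^2
  out$area_transverse <- A
  out$area_bb <- core$l_DV * core$l_ML
  out$AP_anisotropy <- core$l_AP / sqrt(A)
  out$cuboidness <- min(1, core$volume / (core$o1 * core$o2 * core$o3))
  out$sphericity <- min(1, pi^(1/3) * (6 * core$volume)^(2/3) / core$surface_area)
  out$flatness <- core$ell_c / core$ell_b
  a <- core$ell_a; b <- core$ell_b; c <- core$ell_c
  out$prolate_ellipticity <- if (2 * a - b - c > 1e-12) 2 * (a - b) / (2 * a - b - c) else 0
  out$oblate_ellipticity <- if (a + b - 2 * c > 1e-12) 2 * (b - c) / (a + b - 2 * c) else 0
  out$aspect_AP_DV <- core$l_AP / core$l_DV
  out$aspect_AP_ML <- core$l_AP / core$l_ML
  out$aspect_DV_ML <- core$l_DV / core$l_ML
  if (!is.null(cell$nucleus_centroid_um)) {
    dlt <- cell$nucleus_centroid_um - cell$centroid_um
    out$nuc_dAP <- dlt[1]; out$nuc_dDV <- dlt[2]; out$nuc_dML <- dlt[3]
  }
  out
}

#' Full feature suite for a list of cells
#'
#' @param cells List of \code{cell_shape} objects.
#' @param area_smooth_sigma Passed to \code{\link{compute_core_metrics}}.
#' @return Data frame, one row per cell, including centroid columns
#'   \code{cx_AP}, \code{cx_DV}, \code{cx_ML}.
#' @export
compute_features <- function(cells, area_smooth_sigma = 0.7) {
  rows <- lapply(cells, function(cl) {
    r <- compute_derived_metrics(compute_core_metrics(cl, area_smooth_sigma), cl)
    r$cx_AP <- cl$centroid_um[1]; r$cx_DV <- cl$centroid_um[2]
    r$cx_ML <- cl$centroid_um[3]
    r
  })
  do.call(rbind, rows)
}

#' Anteroposterior region from normalised position
#'
#' Half-open bins over normalised AP position: anterior [0, 0.15), pharynx
#' [0.15, 0.40), trunk [0.40, 0.60), posterior [0.60, 1].
#'
#' @param ap_norm Numeric vector of normalised positions in [0, 1].
#' @return Factor with levels anterior, pharynx, trunk, posterior.
#' @export
ap_region <- function(ap_norm) {
  stopifnot(all(ap_norm >= 0 & ap_norm <= 1, na.rm = TRUE))
  cut(ap_norm, breaks = c(0, 0.15, 0.40, 0.60, 1),
      labels = c("anterior", "pharynx", "trunk", "posterior"),
      right = FALSE, include.lowest = TRUE)
}

#' Classify dorsoventral layers from cell positions
#'
#' When no layer annotation is supplied, prospective Muller cells are
#' identified as the most dorsal and most ventral cells within local AP
#' windows (regardless of morphology); all remaining cells are central.
#'
#' @param ap AP centroid positions (um).
#' @param dv DV centroid positions (um).
#' @param window AP window half-width (um); defaults to the mean AP spacing
#'   scaled by 2.
#' @return Character vector, "muller" or "central".
#' @export
classify_dv_layer <- function(ap, dv, window = NULL) {
  n <- length(ap)
  stopifnot(length(dv) == n)
  if (is.null(window)) {
    window <- if (n > 1) 2 * diff(range(ap)) / n else 1
    window <- max(window, 1e-6)
  }
  out <- rep("central", n)
  for (i in seq_len(n)) {
    nb <- which(abs(ap - ap[i]) <= window)
    if (dv[i] >= max(dv[nb]) || dv[i] <= min(dv[nb])) out[i] <- "muller"
  }
  out
}

#' Join features with annotations and positional classifications
#'
#' Merges the per-cell feature table with an annotation table (by
#' \code{cell_id}), fills in the AP region from normalised position, and, when
#' no \code{layer} column is supplied, classifies DV layers with
#' \code{\link{classify_dv_layer}}. Cells without an annotation row are
#' excluded with a message giving the count.
#'
#' @param features Data frame from \code{\link{compute_features}}.
#' @param annotations Data frame with \code{cell_id}, \code{embryo},
#'   \code{stage}, \code{ap_position_norm}, and optionally \code{layer}.
#' @return Annotated feature data frame.
#' @export
feature_table <- function(features, annotations) {
  need <- c("cell_id", "embryo", "stage", "ap_position_norm")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  miss <- setdiff(features$cell_id, annotations$cell_id)
  if (length(miss)) {
    message("excluding ", length(miss), " unannotated cell(s)")
    features <- features[!features$cell_id %in% miss, ]
  }
  tab <- merge(features, annotations, by = "cell_id", sort = TRUE)
  tab$region <- as.character(ap_region(tab$ap_position_norm))
  if (!"layer" %in% names(tab)) {
    tab$layer <- NA_character_
    for (grp in split(seq_len(nrow(tab)), paste(tab$embryo, tab$stage))) {
      tab$layer[grp] <- classify_dv_layer(tab$cx_AP[grp], tab$cx_DV[grp])
    }
  }
  tab
}
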
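# Cluster-guided principal-curve trajectory inference in morphospace.
#
# Clusters (somite stage, AP bins or k-means) anchor a minimum spanning tree
# over cluster centres; each start-to-end path through the tree seeds an
# iterated principal curve (project - order - smooth - re-parameterise), and
# pseudotime is the arc-length position of each cell's projection, scaled to
# [0, 1] per lineage.

#' Build clustering inputs for trajectory inference
#'
#' @param table Data frame with the columns needed by the chosen mode.
#' @param mode One of \code{"stage"} (use somite stage), \code{"ap_bins"}
#'   (k equal half-open bins of normalised AP position) or \code{"kmeans"}.
#' @param k Number of bins or k-means centres.
#' @param seed Seed for k-means (deterministic given seed).
#' @return Factor of cluster labels, one per row of \code{table}.
#' @export
cluster_inputs <- function(table, mode = c("stage", "ap_bins", "kmeans"),
                           k = 6, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "stage") {
    return(factor(table$stage))
  }
  if (mode == "ap_bins") {
    ap <- table$ap_position_norm
    stopifnot(all(ap >= 0 & ap <= 1))
    bin <- pmin(floor(ap * k) + 1L, k)
    f <- factor(bin, levels = seq_len(k))
    if (any(tabulate(f, k) == 0)) {
      empty <- which(tabulate(f, k) == 0)
      warning("merging empty AP bin(s) ", paste(empty, collapse = ", "),
              " into nearest neighbour")
      lev <- as.integer(levels(f))
      occupied <- lev[tabulate(f, k) > 0]
      bin <- occupied[vapply(bin, function(b) which.min(abs(occupied - b)),
                             integer(1))]
      f <- factor(bin)
    }
    return(f)
  }
  pcs <- as.matrix(table[, grep("^PC", names(table)), drop = FALSE])
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  factor(stats::kmeans(pcs, centers = k, nstart = 10, iter.max = 50)$cluster)
}

# project points onto a polyline; the first and last segments extend
# linearly beyond the curve ends so extreme cells project without clamping.
# Returns arc position (can be < 0 or > total on the extensions) and squared
# distance.
.project_polyline <- function(pts, poly, extend = TRUE) {
  n <- nrow(pts)
  seg <- diff(poly)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 1e-12
  if (!any(keep)) {
    return(list(arc = rep(0, n),
                dist2 = rowSums(sweep(pts, 2, poly[1, ])^2),
                total = 0))
  }
  seg <- seg[keep, , drop = FALSE]
  starts <- poly[-nrow(poly), , drop = FALSE][keep, , drop = FALSE]
  len <- len[keep]
  cum <- c(0, cumsum(len))
  nseg <- length(len)
  best_d2 <- rep(Inf, n); best_arc <- rep(0, n)
  for (j in seq_len(nseg)) {
    dp <- sweep(pts, 2, starts[j, ])
    t <- (dp %*% seg[j, ]) / len[j]^2
    lo <- if (extend && j == 1L) -Inf else 0
    hi <- if (extend && j == nseg) Inf else 1
    t <- pmin(pmax(t, lo), hi)
    d2 <- rowSums((dp - t %*% t(seg[j, ]))^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[j] + t[upd] * len[j]
  }
  list(arc = best_arc, dist2 = best_d2, total = cum[length(cum)])
}

# iterated principal curve seeded on a polyline through cluster centres;
# local-linear (non-robust) smoothing keeps the fit equivariant under
# rotations of the embedding
.fit_principal_curve <- function(pts, init_poly, span = 0.6, max_iter = 50,
                                 tol = 1e-4, n_vertices = 150) {
  poly <- init_poly
  best <- NULL
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pr <- .project_polyline(pts, poly)
    md <- mean(sqrt(pr$dist2))
    if (is.null(best) || md <= best$md) best <- list(poly = poly, pr = pr, md = md)
    if (is.finite(prev) && (prev - md) < tol * max(prev, 1e-12)) {
      converged <- TRUE  # improvement below tolerance; best iterate is kept
      break
    }
    prev <- md
    ord <- order(pr$arc)
    s <- pr$arc[ord]
    fit <- sapply(seq_len(ncol(pts)), function(d)
      stats::lowess(s, pts[ord, d], f = span, iter = 0)$y)
    # re-sample the smoothed curve at evenly spaced arc positions
    su <- seq(min(s), max(s), length.out = n_vertices)
    poly <- sapply(seq_len(ncol(pts)), function(d)
      stats::approx(s, fit[, d], xout = su, ties = mean)$y)
    step <- diff(poly)
    ok <- c(TRUE, sqrt(rowSums(step^2)) > 1e-9)
    poly <- poly[ok, , drop = FALSE]
    if (nrow(poly) < 2) { poly <- best$poly; break }
  }
  pr <- .project_polyline(pts, best$poly)
  list(poly = best$poly, arc = pr$arc, dist = sqrt(pr$dist2),
       total = pr$total, mean_dist = mean(sqrt(pr$dist2)),
       converged = converged, iterations = it)
}

#' Infer cluster-guided principal-curve trajectories
#'
#' Builds a Euclidean minimum spanning tree over cluster centres in the
#' embedding, extracts the path from the start cluster to each end cluster
#' (default: every leaf of the tree other than the start), and fits one
#' principal curve per path, initialised on the piecewise-linear centre
#' path. Every cell is then assigned to the lineage whose curve it projects
#' closest to (ties broken by lower branch id), with pseudotime equal to its
#' scaled arc-length position on that curve, oriented so the start cluster
#' precedes the ends.
#'
#' @param embedding Numeric matrix or data frame of component coordinates
#'   (columns PC1..; the first \code{dims} columns are used).
#' @param clusters Factor of cluster labels (see \code{\link{cluster_inputs}}).
#' @param start Label of the start cluster.
#' @param ends Labels of end clusters; default: all tree leaves except start.
#' @param dims Number of embedding dimensions to use (default 3).
#' @param span Lowess span of the curve smoother.
#' @param max_iter,tol Iteration cap and relative tolerance on the mean
#'   projection distance.
#' @return Object of class \code{notochord_trajectory}: per-cell
#'   \code{pseudotime}, \code{branch} and \code{projection_dist}; per-lineage
#'   curves (polyline, cluster path, convergence info); the MST edge list.
#' @export
infer_trajectory <- function(embedding, clusters, start, ends = NULL,
                             dims = 3, span = 0.6, max_iter = 50, tol = 1e-4) {
  emb <- as.data.frame(embedding)
  pc_cols <- grep("^PC", names(emb), value = TRUE)
  if (length(pc_cols) >= 2) emb <- emb[, pc_cols, drop = FALSE]
  pts <- as.matrix(emb[, seq_len(min(dims, ncol(emb))), drop = FALSE])
  clusters <- factor(clusters)
  if (nlevels(clusters) < 2) stop("need at least 2 clusters")
  sizes <- table(clusters)
  if (any(sizes < 3))
    stop("cluster(s) with fewer than 3 cells: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  if (!as.character(start) %in% levels(clusters))
    stop("start cluster not found: ", start)

  centers <- t(vapply(levels(clusters), function(l)
    colMeans(pts[clusters == l, , drop = FALSE]), numeric(ncol(pts))))
  D <- as.matrix(stats::dist(centers))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  start_i <- match(as.character(start), levels(clusters))
  if (is.null(ends)) {
    deg <- igraph::degree(tree)
    ends <- levels(clusters)[deg == 1 & seq_along(deg) != start_i]
    if (!length(ends)) ends <- levels(clusters)[which.max(D[start_i, ])]
  }
  ends <- as.character(ends)
  if (!all(ends %in% levels(clusters)))
    stop("end cluster(s) not found: ",
         paste(setdiff(ends, levels(clusters)), collapse = ", "))

  lineages <- lapply(ends, function(e) {
    e_i <- match(e, levels(clusters))
    path <- igraph::shortest_paths(tree, start_i, e_i)$vpath[[1]]
    as.integer(path)
  })

  curves <- vector("list", length(lineages))
  for (li in seq_along(lineages)) {
    path <- lineages[[li]]
    in_path <- clusters %in% levels(clusters)[path]
    fit <- .fit_principal_curve(pts[in_path, , drop = FALSE],
                                centers[path, , drop = FALSE],
                                span = span, max_iter = max_iter, tol = tol)
    if (!fit$converged)
      warning("principal curve for lineage ", li,
              " did not converge; returning best fit")
    # orient: start cluster must project before the end cluster
    prc <- .project_polyline(centers[path, , drop = FALSE], fit$poly)
    flip <- prc$arc[1] > prc$arc[length(path)]
    curves[[li]] <- list(poly = fit$poly, path = levels(clusters)[path],
                         total = fit$total, flip = flip,
                         arc_min = min(fit$arc),
                         arc_range = max(max(fit$arc) - min(fit$arc), 1e-12),
                         converged = fit$converged,
                         mean_dist = fit$mean_dist)
  }

  n <- nrow(pts)
  pt_mat <- matrix(NA_real_, n, length(curves))
  d_mat <- matrix(Inf, n, length(curves))
  for (li in seq_along(curves)) {
    cv <- curves[[li]]
    pr <- .project_polyline(pts, cv$poly)
    tau <- (pr$arc - cv$arc_min) / cv$arc_range
    if (cv$flip) tau <- 1 - tau
    pt_mat[, li] <- pmin(pmax(tau, 0), 1)
    d_mat[, li] <- sqrt(pr$dist2)
  }
  branch <- max.col(-d_mat, ties.method = "first")
  cells <- data.frame(
    pseudotime = pt_mat[cbind(seq_len(n), branch)],
    branch = branch,
    projection_dist = d_mat[cbind(seq_len(n), branch)],
    cluster = clusters)

  structure(list(cells = cells, curves = curves,
                 centers = centers, clusters = levels(clusters),
                 mst_edges = igraph::as_edgelist(tree),
                 start = as.character(start), ends = ends),
            class = "notochord_trajectory")
}

#' @export
print.notochord_trajectory <- function(x, ...) {
  cat("notochord_trajectory:", nrow(x$cells), "cells,",
      length(x$curves), "lineage(s) from cluster", x$start, "\n")
  for (li in seq_along(x$curves)) {
    cv <- x$curves[[li]]
    cat(sprintf("  lineage %d: %s (mean projection distance %.3f%s)\n", li,
                paste(cv$path, collapse = " -> "), cv$mean_dist,
                if (cv$converged) "" else ", not converged"))
  }
  invisible(x)
}

#' @export
plot.notochord_trajectory <- function(x, embedding, components = c(1, 2), ...) {
  emb <- as.data.frame(embedding)
  cx <- paste0("PC", components[1]); cy <- paste0("PC", components[2])
  graphics::plot(emb[[cx]], emb[[cy]], pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor(x$cells$branch + 1, 0.5),
                 xlab = cx, ylab = cy, ...)
  for (cv in x$curves)
    graphics::lines(cv$poly[, components[1]], cv$poly[, components[2]], lwd = 2)
  graphics::points(x$centers[, components[1]], x$centers[, components[2]],
                   pch = 4, cex = 1.2, lwd = 2)
  invisible(x)
}

#' Per-stage pseudotime density curves
#'
#' One Gaussian kernel density per stage over pseudotime in [0, 1], with
#' boundary reflection at 0 and 1 so each curve integrates to one.
#'
#' @param pseudotime Numeric vector in [0, 1].
#' @param stages Stage label per cell.
#' @param bw Bandwidth; default Silverman's rule per stage.
#' @param n_grid Grid resolution.
#' @return Data frame with \code{stage}, \code{pseudotime} (grid) and
#'   \code{density}; stages with fewer than 2 cells are skipped with a
#'   warning.
#' @export
pseudotime_density <- function(pseudotime, stages, bw = NULL, n_grid = 512) {
  grid <- seq(0, 1, length.out = n_grid)
  out <- list()
  for (s in sort(unique(stages))) {
    x <- pseudotime[stages == s]
    if (length(x) < 2) {
      warning("skipping stage ", s, ": fewer than 2 cells")
      next
    }
    h <- if (is.null(bw)) stats::bw.nrd0(x) else bw
    dens <- vapply(grid, function(g)
      mean(stats::dnorm(g - x, sd = h) + stats::dnorm(g + x, sd = h) +
             stats::dnorm(2 - g - x, sd = h)), numeric(1))
    out[[as.character(s)]] <- data.frame(stage = s, pseudotime = grid,
                                         density = dens)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Correlation between pseudotime and somite stage
#'
#' @param pseudotime Numeric vector.
#' @param stages Numeric stage per cell.
#' @return List with Pearson \code{r}, linear-regression \code{slope} and
#'   \code{intercept} (pseudotime on stage), and a per-stage data frame of
#'   mean and SD pseudotime.
#' @export
stage_pseudotime_correlation <- function(pseudotime, stages) {
  stages <- as.numeric(as.character(stages))
  if (length(unique(stages)) < 2) stop("need at least 2 stages")
  if (stats::sd(pseudotime) < 1e-12 || stats::sd(stages) < 1e-12)
    stop("zero variance in pseudotime or stage")
  r <- stats::cor(stages, pseudotime)
  fit <- stats::lm(pseudotime ~ stages)
  per <- do.call(rbind, lapply(split(pseudotime, stages), function(x)
    data.frame(mean = mean(x), sd = stats::sd(x), n = length(x))))
  per$stage <- as.numeric(rownames(per))
  rownames(per) <- NULL
  list(r = r, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       per_stage = per[, c("stage", "mean", "sd", "n")])
}

#' Mean pseudotime per AP bin per stage
#'
#' Bins normalised AP positions into \code{n_bins} equal half-open intervals
#' and returns the mean pseudotime per bin per stage (NA where empty).
#'
#' @param pseudotime Numeric vector.
#' @param ap Normalised AP position per cell, in [0, 1].
#' @param stages Stage per cell.
#' @param n_bins Number of bins (default 10).
#' @return Data frame with \code{stage}, \code{bin}, \code{bin_mid},
#'   \code{mean_pseudotime}, \code{n}.
#' @export
spatial_pseudotime_profile <- function(pseudotime, ap, stages, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  stopifnot(all(ap >= 0 & ap <= 1))
  bin <- pmin(floor(ap * n_bins) + 1L, n_bins)
  out <- expand.grid(stage = sort(unique(stages)), bin = seq_len(n_bins))
  out$bin_mid <- (out$bin - 0.5) / n_bins
  out$mean_pseudotime <- NA_real_
  out$n <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- stages == out$stage[i] & bin == out$bin[i]
    out$n[i] <- sum(sel)
    if (any(sel)) out$mean_pseudotime[i] <- mean(pseudotime[sel])
  }
  out[order(out$stage, out$bin), ]
}
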
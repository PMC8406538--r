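# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the reference synthetic dataset: defaults (5 stages x 100 central cells,
# Muller rows, maturation gradient, intercalation schedule), fixed seed
default_sim <- function() {
  cached("default_sim", function() generate_notochord(generator_config(seed = 101)))
}

default_tab <- function() {
  cached("default_tab", function() {
    sim <- default_sim()
    feats <- do.call(rbind, lapply(names(sim$volumes), function(s) {
      nuc <- sim$nuclei[sim$nuclei$stage == as.numeric(s), ]
      compute_features(extract_cells(sim$volumes[[s]], sim$config$voxel_size_um,
                                     nuc))
    }))
    feature_table(feats, sim$annotations)
  })
}

default_model <- function() {
  cached("default_model", function() fit_morphospace(default_tab()))
}

# trapezoid integral of a density curve
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# mean silhouette width of a two-class labelling in a coordinate matrix
silhouette_width <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  mean(vapply(seq_len(n), function(i) {
    a <- mean(D[i, labels == labels[i] & seq_len(n) != i])
    b <- mean(D[i, labels != labels[i]])
    (b - a) / max(a, b)
  }, numeric(1)))
}

# small rotation-matrix builder (axis-angle)
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# integer label volume from a logical mask
make_volume <- function(mask) {
  v <- array(0L, dim(mask))
  v[mask] <- 1L
  v
}

# two columns with sample correlation exactly rho
make_corr_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  raw <- scale(cbind(stats::rnorm(n), stats::rnorm(n)), scale = FALSE)
  q <- qr.Q(qr(raw))
  u <- q[, 1]; v <- q[, 2]
  data.frame(f1 = u, f2 = rho * u + sqrt(1 - rho^2) * v)
}
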
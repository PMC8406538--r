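# End-to-end pipeline: simulate (or load) -> shape features -> morphospace ->
# trajectory -> geometric model -> proliferation landscape, with a
# deterministic output layout and a machine-readable JSON summary.

#' Default pipeline configuration
#'
#' Returns the full nested configuration consumed by
#' \code{\link{run_pipeline}}; override any entry by passing a modified copy.
#'
#' @param seed Master seed for all stochastic steps.
#' @return Nested list of per-stage settings.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, cells_per_stage = 60),
    inputs = list(labels_dir = NULL, annotations_csv = NULL,
                  nuclei_csv = NULL),
    features = list(area_smooth_sigma = 0.7),
    morphospace = list(n_components = 5, screen_threshold = 0.95),
    trajectory = list(cluster_mode = "stage", dims = 3, span = 0.6,
                      region = "trunk", layer = "central"),
    geomodel = list(n = 10),
    proliferation = list(enabled = TRUE),
    write_volumes = FALSE
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes every enabled stage and writes a deterministic directory layout:
#' \code{features.csv}, \code{morphospace/}, \code{traj/}, \code{geo/},
#' \code{prolif/}, \code{summary.json}, \code{config.yaml} and
#' \code{pipeline.log}. Given the same configuration and seed, two runs
#' produce byte-identical CSV outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Partial configuration merged over
#'   \code{\link{pipeline_config}}, or a path to a YAML file with the same
#'   structure.
#' @return Invisibly, a list with the main in-memory results and the summary.
#' @export
run_pipeline <- function(out_dir, config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("morphospace", "traj", "geo", "prolif"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage_call <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logmsg(name, " done in ", sprintf("%.2fs", as.numeric(Sys.time() - t0,
                                                          units = "secs")))
    res
  }

  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  cfg_hash <- unname(tools::md5sum(file.path(out_dir, "config.yaml")))
  meta <- list(config_hash = cfg_hash)

  # --- inputs ---------------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- stage_call("simulate", {
      gen_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
      gen_args$seed <- cfg$seed
      gen <- do.call(generator_config, gen_args)
      generate_notochord(gen)
    })
    volumes <- sim$volumes
    annotations <- sim$annotations
    nuclei <- sim$nuclei
    if (isTRUE(cfg$write_volumes)) {
      for (s in names(volumes))
        write_label_tiff(volumes[[s]],
                         file.path(out_dir, paste0("labels_stage", s, ".tif")))
    }
  } else {
    sim <- NULL
    if (is.null(cfg$inputs$labels_dir) || !dir.exists(cfg$inputs$labels_dir))
      stop("simulate disabled and labels_dir missing or not found: ",
           if (is.null(cfg$inputs$labels_dir)) "<unset>" else cfg$inputs$labels_dir)
    if (is.null(cfg$inputs$annotations_csv) ||
        !file.exists(cfg$inputs$annotations_csv))
      stop("simulate disabled and annotations_csv missing or not found: ",
           if (is.null(cfg$inputs$annotations_csv)) "<unset>"
           else cfg$inputs$annotations_csv)
    tifs <- list.files(cfg$inputs$labels_dir, "\\.tif+$", full.names = TRUE)
    volumes <- lapply(tifs, read_label_tiff)
    names(volumes) <- sub("^labels_stage", "",
                          tools::file_path_sans_ext(basename(tifs)))
    annotations <- utils::read.csv(cfg$inputs$annotations_csv)
    nuclei <- if (!is.null(cfg$inputs$nuclei_csv) &&
                  file.exists(cfg$inputs$nuclei_csv))
      utils::read.csv(cfg$inputs$nuclei_csv) else NULL
  }

  # --- features -------------------------------------------------------------
  tab <- stage_call("features", {
    feats <- do.call(rbind, lapply(names(volumes), function(nm) {
      v <- volumes[[nm]]
      vs <- if (!is.null(sim)) sim$config$voxel_size_um else 0.5
      nuc <- nuclei
      if (!is.null(nuc) && "stage" %in% names(nuc))
        nuc <- nuc[as.character(nuc$stage) == nm, , drop = FALSE]
      cells <- extract_cells(v, vs, nuc)
      compute_features(cells, cfg$features$area_smooth_sigma)
    }))
    feature_table(feats, annotations)
  })
  write_table_csv(tab, file.path(out_dir, "features.csv"), meta)

  # --- morphospace ----------------------------------------------------------
  model <- stage_call("morphospace", fit_morphospace(
    tab, n_components = cfg$morphospace$n_components,
    screen_threshold = cfg$morphospace$screen_threshold))
  emb <- embed_morphospace(model, tab)
  write_morphospace(model, file.path(out_dir, "morphospace", "model.json"))
  write_table_csv(emb, file.path(out_dir, "morphospace", "coords.csv"), meta)

  # --- trajectory -----------------------------------------------------------
  tcfg <- cfg$trajectory
  sel <- rep(TRUE, nrow(emb))
  if (!is.null(tcfg$layer) && "layer" %in% names(emb))
    sel <- sel & emb$layer == tcfg$layer
  if (!is.null(tcfg$region) && "region" %in% names(emb))
    sel <- sel & emb$region == tcfg$region
  sub <- emb[sel, , drop = FALSE]
  traj <- stage_call("trajectory", {
    cl <- cluster_inputs(sub, tcfg$cluster_mode, seed = cfg$seed)
    start <- levels(cl)[1]
    ends <- levels(cl)[nlevels(cl)]
    infer_trajectory(sub, cl, start, ends, dims = tcfg$dims, span = tcfg$span)
  })
  pt_tab <- cbind(sub[, intersect(c("cell_id", "stage", "ap_position_norm"),
                                  names(sub)), drop = FALSE],
                  traj$cells[, c("pseudotime", "branch", "projection_dist")])
  write_table_csv(pt_tab, file.path(out_dir, "traj", "pseudotime.csv"), meta)
  jsonlite::write_json(
    lapply(traj$curves, function(cv)
      list(path = cv$path, polyline = cv$poly, converged = cv$converged)),
    file.path(out_dir, "traj", "curves.json"), digits = NA, auto_unbox = TRUE)
  corr <- stage_pseudotime_correlation(pt_tab$pseudotime, pt_tab$stage)

  # --- geometric model ------------------------------------------------------
  geo <- stage_call("geomodel", {
    ftab <- tab[tab$cell_id %in% sub$cell_id, , drop = FALSE]
    params <- mean_cell_params(ftab)
    series <- if (!is.null(sim)) {
      ns <- neighborhood_series(sim$ground_truth, n = cfg$geomodel$n)
      ns[ns$stage %in% params$stage, ]
    } else {
      data.frame(stage = params$stage,
                 beta = rep(1, nrow(params)), l_n = params$l_AP * cfg$geomodel$n)
    }
    scen <- do.call(rbind, lapply(
      c("intercalation_only", "shape_no_growth", "isotropic_growth_only",
        "anisotropic_growth_only", "full"),
      function(sc) scenario_neighborhood(params, series, sc,
                                         n = cfg$geomodel$n)))
    list(params = params, series = series, scenarios = scen)
  })
  write_table_csv(as.data.frame(geo$params), file.path(out_dir, "geo", "params.csv"),
                  meta)
  write_table_csv(geo$scenarios, file.path(out_dir, "geo", "scenarios.csv"), meta)
  write_table_csv(geo$series, file.path(out_dir, "geo", "intercalation.csv"), meta)

  # --- proliferation --------------------------------------------------------
  landscape <- NULL
  if (isTRUE(cfg$proliferation$enabled) && !is.null(sim)) {
    landscape <- stage_call("proliferation", {
      nt <- prolif_nucleus_table(sim)
      if (is.null(nt) || !nrow(nt)) return(NULL)
      nt <- normalize_positions(nt)
      lens <- tissue_length_series(sim$ground_truth)
      names(lens)[2] <- "mean_length_um"
      build_landscape(nt, lens)
    })
    if (!is.null(landscape))
      write_table_csv(as.data.frame(landscape),
                      file.path(out_dir, "prolif", "landscape.csv"), meta)
  }

  # --- summary --------------------------------------------------------------
  summary <- list(
    config_hash = cfg_hash,
    n_cells = nrow(tab),
    variance_fraction = model$variance_fraction[seq_len(model$n_components)],
    variance_top = sum(model$variance_fraction[seq_len(model$n_components)]),
    stage_pseudotime_r = corr$r,
    beta = if (!is.null(geo$series)) stats::setNames(
      as.list(geo$series$beta), geo$series$stage) else NULL,
    eq1_rel_error_max = max(geo$params$eq1_rel_error)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  logmsg("pipeline complete")
  invisible(list(features = tab, model = model, embedding = emb,
                 trajectory = traj, geomodel = geo, landscape = landscape,
                 summary = summary, sim = sim))
}
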
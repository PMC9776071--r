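#' Fill per-slice contours into 3D masks
#'
#' Rasterizes lumen and outer-wall contours slice by slice (even-odd fill at
#' pixel centres) and returns the lumen mask and the wall band (inside an
#' outer contour but outside every lumen contour).
#'
#' @param contours List of `contour`s (kinds `lumen` and `outer_wall`).
#' @param dims,spacing,origin Target grid.
#' @return List `lumen`, `wall` (logical 3D arrays).
#' @export
contours_to_masks <- function(contours, dims, spacing, origin) {
  lumen <- array(FALSE, dims)
  wall <- array(FALSE, dims)
  ax <- origin[1] + spacing[1] * (seq_len(dims[1]) - 1)
  ay <- origin[2] + spacing[2] * (seq_len(dims[2]) - 1)
  fill <- function(poly) {
    ix <- which(ax >= min(poly[, 1]) - spacing[1] &
                ax <= max(poly[, 1]) + spacing[1])
    iy <- which(ay >= min(poly[, 2]) - spacing[2] &
                ay <= max(poly[, 2]) + spacing[2])
    if (!length(ix) || !length(iy)) return(NULL)
    pts <- cbind(rep(ax[ix], length(iy)), rep(ay[iy], each = length(ix)))
    inside <- points_in_polygon(pts, poly)
    list(ix = ix, iy = iy, m = matrix(inside, length(ix), length(iy)))
  }
  for (ct in contours) {
    iz <- ct$slice_index + 1
    f <- fill(ct$vertices)
    if (is.null(f)) next
    if (ct$kind == "lumen") {
      lumen[f$ix, f$iy, iz] <- lumen[f$ix, f$iy, iz] | f$m
    } else {
      wall[f$ix, f$iy, iz] <- wall[f$ix, f$iy, iz] | f$m
    }
  }
  list(lumen = lumen, wall = wall & !lumen)
}

#' Assemble a case configuration
#'
#' Exactly one of `phantom_case_id` (1-3, see [phantom_case()]) or a custom
#' `phantom`/`plaque` pair drives the phantom stage; ingesting external
#' volumes instead is configured by `stack_prefix` + `seeds`.
#'
#' @param phantom_case_id Built-in phantom case (1, 2 or 3).
#' @param phantom Optional [phantom_config()] list (custom geometry).
#' @param plaque Optional function `geometry -> plaque_spec`.
#' @param stack_prefix Optional NIfTI prefix of externally supplied volumes.
#' @param seeds Optional list of voxel seeds `cca`, `ica`, `eca` (0-based)
#'   when ingesting external volumes.
#' @param spacing Phantom voxel spacing (mm).
#' @param noise_sd Per-channel additive noise SD.
#' @param seed Master RNG seed for the case.
#' @param q_mean,q_peak,period,n_frames Flow waveform parameters.
#' @param p_dia,p_sys Pressure scaling bounds (mmHg).
#' @param r0 Initial lumen contour radius (mm); must be smaller than the
#'   narrowest lumen so the balloon snake inflates onto the boundary.
#' @param r_max_offset Outer-wall radial search depth beyond the lumen (mm);
#'   must exceed the thickest plaque band.
#' @param snake Snake parameter list, see [snake_params()].
#' @param lumen_channel,wall_channel Channels for lumen/outer-wall
#'   detection.
#' @param wall_band_source `"segmentation"` or `"truth"` wall band for
#'   clustering.
#' @param kmeans_k,kmeans_seed,kmeans_n_init Clustering controls.
#' @param roi_length TAWSS ROI length from the apex (mm), default 17.
#' @param stress_roi_length Stress ROI window (mm), default 13.
#' @param mesh Logical: run wall meshing + material mapping.
#' @param mesh_edge Target tet edge (mm) when `mesh = TRUE`.
#' @param out_dir Optional output directory for artifacts.
#' @param cache Reuse cached stage results in `out_dir` when the
#'   configuration hash is unchanged.
#' @return A `case_config` list.
#' @export
case_config <- function(phantom_case_id = 1, phantom = NULL, plaque = NULL,
                        stack_prefix = NULL, seeds = NULL,
                        spacing = 0.3, noise_sd = 0.05, seed = 1L,
                        q_mean = 6, q_peak = 20, period = 1.0, n_frames = 40,
                        p_dia = 80, p_sys = 120,
                        r0 = 0.4, snake = snake_params(),
                        lumen_channel = "TOF", wall_channel = "PDW",
                        r_max_offset = 5,
                        wall_band_source = c("segmentation", "truth"),
                        kmeans_k = 5, kmeans_seed = 17, kmeans_n_init = 10,
                        roi_length = 17, stress_roi_length = 13,
                        mesh = FALSE, mesh_edge = 0.6,
                        out_dir = NULL, cache = FALSE) {
  wall_band_source <- match.arg(wall_band_source)
  if (!is.null(stack_prefix) && (!is.null(phantom) || !is.null(plaque)))
    stop("configure either phantom parameters or input volumes, not both")
  if (roi_length <= 0 || stress_roi_length <= 0)
    stop("ROI lengths must be positive")
  cfg <- as.list(environment())
  class(cfg) <- "case_config"
  cfg
}

# run one pipeline stage with optional caching and timing
run_stage <- function(state, name, fun) {
  cache_file <- NULL
  if (isTRUE(state$config$cache) && !is.null(state$config$out_dir)) {
    cache_file <- file.path(state$config$out_dir,
                            sprintf("cache_%s_%s.rds", state$hash, name))
    if (file.exists(cache_file)) {
      state$stages[[name]] <- readRDS(cache_file)
      state$log[[name]] <- "cached"
      return(state)
    }
  }
  t0 <- proc.time()[3]
  res <- tryCatch(fun(state), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         "; completed stages: ", paste(names(state$stages), collapse = ", "),
         call. = FALSE))
  state$stages[[name]] <- res
  state$log[[name]] <- sprintf("%.1fs", proc.time()[3] - t0)
  if (!is.null(cache_file)) saveRDS(res, cache_file)
  state
}

#' Run the full assessment pipeline for one case
#'
#' Phantom (or ingest) -> centerline -> segmentation -> clustering ->
#' morphology -> hemodynamic surrogate -> wall-stress surrogate ->
#' report. Deterministic for a fixed configuration and seed.
#'
#' @param config A [case_config()].
#' @return A `case_report` list: `morphology`, `tawss_roi`, `osi_max`,
#'   `stress_roi`, `summary` (fields consumed by [compare_patients()]),
#'   `provenance`, `warnings`, plus `stages` with the intermediate objects.
#' @export
run_pipeline <- function(config = case_config()) {
  stopifnot(inherits(config, "case_config"))
  if (!is.null(config$out_dir) &&
      !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  cfg_for_hash <- config[!names(config) %in% c("out_dir", "cache")]
  state <- list(config = config, stages = list(), log = list(),
                hash = substr(config_hash(cfg_for_hash), 1, 12))

  state <- run_stage(state, "phantom", function(st) {
    cfg <- st$config
    if (!is.null(cfg$stack_prefix)) {
      stack <- read_contrast_stack(cfg$stack_prefix)
      return(list(stack = stack, geometry = NULL, labels_truth = NULL,
                  seeds = cfg$seeds))
    }
    pc <- if (is.null(cfg$phantom)) phantom_case(cfg$phantom_case_id) else
      list(config = cfg$phantom, plaque = cfg$plaque %||%
             function(g) plaque_spec())
    geom <- make_bifurcation_geometry(pc$config)
    labels <- rasterize_labels(geom, pc$plaque(geom), grid = cfg$spacing)
    stack <- render_contrasts(labels, noise_sd = cfg$noise_sd,
                              seed = cfg$seed)
    ends <- rbind(geom$branches$cca$points[1, ],
                  geom$branches$ica$points[nrow(geom$branches$ica$points), ],
                  geom$branches$eca$points[nrow(geom$branches$eca$points), ])
    vox <- world_to_voxel(ends, labels$spacing, labels$origin,
                          dim(labels$labels))
    list(stack = stack, geometry = geom, labels_truth = labels,
         seeds = list(cca = vox[1, ], ica = vox[2, ], eca = vox[3, ]))
  })

  state <- run_stage(state, "waveforms", function(st) {
    cfg <- st$config
    flow <- make_flow_waveform(cfg$period, cfg$q_mean, cfg$q_peak,
                               cfg$n_frames, seed = cfg$seed + 1L)
    list(flow = flow,
         pressure = scale_pressure_waveform(flow, cfg$p_dia, cfg$p_sys))
  })

  state <- run_stage(state, "centerline", function(st) {
    cost <- build_cost_volume(st$stages$phantom$stack,
                              st$config$lumen_channel, medialness = TRUE,
                              sigma = 1)
    seeds <- st$stages$phantom$seeds
    cl <- extract_bifurcation_centerlines(cost, seeds$cca, seeds$ica,
                                          seeds$eca)
    cl$ica_smooth <- smooth_centerline(cl$ica, window = 7)
    cl$eca_smooth <- smooth_centerline(cl$eca, window = 7)
    cl
  })

  state <- run_stage(state, "segmentation", function(st) {
    cfg <- st$config
    stack <- st$stages$phantom$stack
    cl <- st$stages$centerline
    apex_z <- cl$apex[3]
    contours <- list()
    segment_along <- function(path, z_min) {
      inits <- init_contours_from_centerline(path, stack, r0 = cfg$r0)
      for (init in inits) {
        zw <- stack$origin[3] + stack$spacing[3] * init$slice_index
        if (zw < z_min) next
        sl_l <- get_slice(stack, cfg$lumen_channel, init$slice_index)
        lum <- tryCatch(evolve_active_contour(sl_l, init, cfg$snake),
                        error = function(e) NULL)
        if (is.null(lum)) next
        sl_w <- get_slice(stack, cfg$wall_channel, init$slice_index)
        outw <- suppressWarnings(trace_outer_wall(sl_w, lum,
          r_max_offset = cfg$r_max_offset))
        contours[[length(contours) + 1]] <<- lum
        contours[[length(contours) + 1]] <<- outw
      }
    }
    segment_along(cl$ica_smooth, z_min = -Inf)
    segment_along(cl$eca_smooth, z_min = apex_z + stack$spacing[3])
    masks <- contours_to_masks(contours, dim(stack$channels[[1]]),
                               stack$spacing, stack$origin)
    seg_labels <- array(tissue_codes[["background"]],
                        dim(stack$channels[[1]]))
    seg_labels[masks$wall] <- tissue_codes[["wall"]]
    seg_labels[masks$lumen] <- tissue_codes[["lumen"]]
    list(contours = contours, masks = masks,
         labels = label_volume(seg_labels, stack$spacing, stack$origin))
  })

  state <- run_stage(state, "clustering", function(st) {
    cfg <- st$config
    stack <- st$stages$phantom$stack
    band <- if (cfg$wall_band_source == "truth" &&
                !is.null(st$stages$phantom$labels_truth)) {
      st$stages$phantom$labels_truth$labels %in%
        tissue_codes[c("wall", "lipid", "calcification")]
    } else {
      st$stages$segmentation$masks$wall
    }
    band <- array(band, dim(stack$channels[[1]]))
    feats <- extract_wall_features(stack, band)
    km <- kmeans_cluster(feats, k = cfg$kmeans_k, seed = cfg$kmeans_seed,
                         n_init = cfg$kmeans_n_init)
    base_labels <- if (cfg$wall_band_source == "truth")
      st$stages$phantom$labels_truth else st$stages$segmentation$labels
    cls <- c("wall", "lipid", "calcification")
    if (cfg$wall_band_source == "segmentation")
      cls <- c("background", cls)
    tissue <- assign_tissue_classes(km, feats, base_labels, classes = cls)
    if (cfg$wall_band_source == "segmentation") {
      # background and calcification are both hypointense and may share a
      # cluster; split the dark voxels individually by nearest signature
      dark_cls <- c("background", "calcification")
      dark <- tissue$labels[feats$idx] %in% tissue_codes[dark_cls]
      if (any(dark)) {
        sig <- default_signatures()[dark_cls, feats$channels, drop = FALSE]
        sig_z <- sweep(sweep(sig, 2, feats$center), 2, feats$scale, `/`)
        d2 <- dist2_to_centroids(
          feats$features[dark, , drop = FALSE], sig_z)
        lab2 <- tissue$labels
        lab2[feats$idx[dark]] <-
          tissue_codes[dark_cls[max.col(-d2, ties.method = "first")]]
        tissue <- label_volume(lab2, tissue$spacing, tissue$origin)
      }
    }
    if (cfg$wall_band_source == "segmentation") {
      # single-voxel speckle from acquisition noise corrupts minimum-distance
      # morphology (cap thickness); keep only inclusion voxels supported by
      # at least two 6-neighbours of the same class
      lab3 <- tissue$labels
      for (cls in c("lipid", "calcification")) {
        m <- lab3 == tissue_codes[[cls]]
        if (!any(m)) next
        nb <- neighbor_count(m)
        drop <- m & nb < 2
        lab3[drop] <- tissue_codes[["wall"]]
      }
      tissue <- label_volume(lab3, tissue$spacing, tissue$origin)
    }
    list(features_n = nrow(feats$features), kmeans = km, labels = tissue)
  })

  state <- run_stage(state, "morphology", function(st) {
    cfg <- st$config
    cl <- st$stages$centerline
    lumen_mask <- st$stages$clustering$labels$labels == tissue_codes[["lumen"]]
    stack <- st$stages$phantom$stack
    # ICA portion of the smoothed CCA-ICA path, from the apex onward
    pts <- cl$ica_smooth$points
    d_apex <- sqrt(rowSums(sweep(pts, 2, cl$apex)^2))
    i0 <- which.min(d_apex)
    # fine resampling keeps the profile smoothing window short so the
    # sharp throat minimum is not flattened
    pts <- resample_polyline(pts[i0:nrow(pts), , drop = FALSE], 0.15)
    prof <- lumen_radius_profile(lumen_mask, stack$spacing, stack$origin,
                                 pts)
    morphology_report(st$stages$clustering$labels, prof)
  })

  state <- run_stage(state, "hemodynamics", function(st) {
    cfg <- st$config
    geom <- st$stages$phantom$geometry
    if (is.null(geom))
      stop("hemodynamic surrogate requires phantom geometry")
    flow <- st$stages$waveforms$flow
    field <- surrogate_wss_field(geom, flow)
    tw <- tawss(field)
    os <- osi(field)
    pk <- peak_systole_map(field, flow)
    roi <- roi_spec("ica", 0, cfg$roi_length)
    list(tawss_roi = roi_stats(tw, roi),
         peak_roi = roi_stats(pk, roi),
         osi_max = max(os$values, na.rm = TRUE),
         maps = list(tawss = tw, osi = os, peak = pk))
  })

  state <- run_stage(state, "wallstress", function(st) {
    geom <- st$stages$phantom$geometry
    field <- laplace_stress(geom, st$stages$waveforms$pressure)
    list(field = field,
         roi = stress_roi_stats(field, st$config$stress_roi_length))
  })

  if (isTRUE(config$mesh)) {
    state <- run_stage(state, "matmap", function(st) {
      mesh <- mesh_phantom_wall(st$stages$phantom$geometry,
                                target_edge = st$config$mesh_edge)
      mm <- map_materials_to_mesh(mesh, st$stages$clustering$labels)
      smooth_transition(mm, radius = 0.6)
    })
  }

  morph <- state$stages$morphology
  hemo <- state$stages$hemodynamics
  ws <- state$stages$wallstress
  report <- structure(list(
    morphology = morph,
    tawss_roi = hemo$tawss_roi[c("mean", "sd", "n")],
    osi_max = hemo$osi_max,
    stress_roi = ws$roi[c("mean", "sd", "max", "central_s_mm", "n")],
    summary = list(
      calcification_volume_mm3 = morph$calcification_volume_mm3,
      lipid_volume_mm3 = morph$lipid_volume_mm3,
      tawss_mean_pa = hemo$tawss_roi$mean,
      stress_max_kpa = ws$roi$max,
      stenosis_percent = morph$stenosis_percent,
      thinnest_cap_mm = morph$thinnest_cap_mm),
    units = list(volumes = "mm^3", tawss = "Pa", osi = "dimensionless",
                 stress = "kPa", stenosis = "percent", cap = "mm"),
    provenance = list(
      package_version = as.character(utils::packageVersion("plaquescan")),
      seed = config$seed, config_hash = state$hash,
      surrogate = list(wss = TRUE, stress = TRUE),
      stage_timings = state$log),
    stages = state$stages
  ), class = "case_report")

  if (!is.null(config$out_dir)) {
    json <- report[setdiff(names(report), "stages")]
    # timings vary between runs; the written report must be byte-identical
    # for identical configuration and seed
    json$provenance$stage_timings <- NULL
    jsonlite::write_json(json, file.path(config$out_dir, "case_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case report (surrogate hemodynamics/stress)\n")
  print(x$morphology)
  cat(sprintf("  TAWSS ROI: %.2f +/- %.2f Pa (n = %d)\n",
              x$tawss_roi$mean, x$tawss_roi$sd, x$tawss_roi$n))
  cat(sprintf("  stress ROI: %.1f +/- %.1f kPa, max %.1f kPa\n",
              x$stress_roi$mean, x$stress_roi$sd, x$stress_roi$max))
  invisible(x)
}

#' Run a batch of cases and compare them pairwise
#'
#' @param configs Named list of [case_config()]s.
#' @return List `reports` (per case), `comparison` (from
#'   [compare_patients()]).
#' @export
run_batch <- function(configs) {
  reports <- lapply(configs, run_pipeline)
  summaries <- lapply(reports, `[[`, "summary")
  list(reports = reports, comparison = compare_patients(summaries))
}
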
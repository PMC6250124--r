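# Standard-format I/O, configuration and the end-to-end pipeline:
# simulate/read -> detect -> segment -> trace -> stats, with all artifacts
# written to an output directory.

#' Write a time-lapse stack as a multi-page TIFF with a JSON sidecar
#'
#' Frames are written in (t, z, c) page order. `bits = 16` stores
#' scaled 16-bit samples (scale recorded in the sidecar); `bits = 32`
#' stores float samples losslessly. The sidecar (`<path>.json`) records
#' the axis order, calibration, channel labels and any scaling, and is
#' what [read_stack()] uses to canonicalise axes.
#'
#' @param stack a [papt_stack()].
#' @param path output TIFF path.
#' @param bits 16 (scaled integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "papt_stack"), bits %in% c(16L, 32L))
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  # TIFF samples live in [0, 1]: store (x - offset) / scale, recorded in
  # the sidecar so read_stack() restores the original intensities
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    i <- i + 1L
    fr <- (stack$data[t, z, ch, , ] - lo) / scale
    pages[[i]] <- if (bits == 16L) {
      pmin(pmax(round(fr * 65535), 0), 65535) / 65535
    } else fr
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "deflate", reduce = FALSE)
  meta <- list(axes = "TZCYX",
               shape = as.integer(d),
               pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               channels = stack$channels,
               bits = as.integer(bits),
               intensity_scale = scale,
               intensity_offset = lo)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a time-lapse stack from TIFF, canonicalising axes
#'
#' Axis order is taken from (in priority): the `axes` override, the JSON
#' sidecar written by [write_stack()], or — for unambiguous files — a
#' single page read as `"YX"`. A multi-page file with neither sidecar nor
#' override is ambiguous and raises an error listing the candidate
#' interpretations. Intensities stored as scaled 16-bit are mapped back to
#' their original scale; data are held as doubles.
#'
#' @param path TIFF path.
#' @param axes optional axis-order override (e.g. `"TYX"`, `"TZCYX"`).
#' @param pixel_size,frame_interval calibration overrides; otherwise read
#'   from the sidecar (defaults 1 px = 1 um, 1 s if absent).
#' @param channels optional channel labels.
#' @return a [papt_stack()] with axes `(t, z, c, y, x)`.
#' @export
read_stack <- function(path, axes = NULL, pixel_size = NULL,
                       frame_interval = NULL, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (is.null(axes)) axes <- meta$axes
  n_pages <- length(pages)
  if (is.null(axes)) {
    if (n_pages == 1L) {
      axes <- "YX"
    } else {
      stop("ambiguous axis order for ", n_pages, "-page TIFF '", path,
           "': supply `axes` (candidates: TYX, ZYX, CYX, TZCYX) or a ",
           "sidecar JSON")
    }
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  ax <- toupper(axes)
  page_axes <- strsplit(gsub("[YX]", "", ax), "")[[1]]
  if (length(page_axes) > 1L) {
    # pages are (t, z, c)-major in write order; unfold via the sidecar shape
    if (is.null(meta$shape)) {
      stop("axis order '", ax, "' needs a sidecar with the page shape")
    }
    sh <- as.integer(meta$shape)     # (t, z, c, y, x)
    if (prod(sh[1:3]) != n_pages) {
      stop("sidecar shape does not match the page count of '", path, "'")
    }
    data <- array(0, c(sh[1], sh[2], sh[3], ny, nx))
    p <- 0L
    for (t in seq_len(sh[1])) for (z in seq_len(sh[2])) {
      for (ch in seq_len(sh[3])) {
        p <- p + 1L
        data[t, z, ch, , ] <- pages[[p]]
      }
    }
    axes_full <- "TZCYX"
  } else if (n_pages == 1L && length(page_axes) == 0L) {
    data <- pages[[1]]
    axes_full <- "YX"
  } else {
    data <- array(unlist(pages, use.names = FALSE), c(ny, nx, n_pages))
    data <- aperm(data, c(3, 1, 2))
    axes_full <- paste0(if (length(page_axes)) page_axes else "T", "YX")
  }
  if (!is.null(meta$intensity_scale)) {
    data <- data * meta$intensity_scale + (meta$intensity_offset %||% 0)
  }
  px <- pixel_size %||% meta$pixel_size_um %||% 1
  fi <- frame_interval %||% meta$frame_interval_s %||% 1
  ch <- channels %||% meta$channels %||% "tracer"
  papt_stack(data, pixel_size = px, frame_interval = fi, channels = ch,
             axes = axes_full)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a label map as a 16-bit TIFF
#' @param label_map integer matrix (labels 0..65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(max(label_map) <= 65535)
  tiff::writeTIFF(label_map / 65535, path, bits.per.sample = 16L,
                  compression = "deflate")
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path TIFF path.
#' @return integer matrix.
#' @export
read_label_map <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Default pipeline configuration
#'
#' Nested list of every module's parameters with the package defaults:
#' calibration (0.4 um px, 30 s frames), the synthetic-generation study
#' conditions, detection scales and thresholds, segmentation rules,
#' kinetics windows and statistics options. Override any subset via
#' [read_config()] or `utils::modifyList()`.
#'
#' @param seed master seed; every stochastic stage derives a named
#'   sub-stream from it.
#' @return nested list of class `papt_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    calibration = list(pixel_size_um = 0.4, frame_interval_s = 30,
                       axes = "TYX"),
    channels = list(tracer = 1L),
    simulate = list(n_cells = 64, field_size = 512, cell_diameter_um = 10,
                    endothelial_fraction = 0, secretory_type = "beta",
                    n_frames = 80, baseline_rate = 3e-3,
                    heterogeneity_cv = 0.6, inactive_fraction = 0,
                    chamber_lag_s = 138, chamber_tau_s = 126,
                    psf_sigma_px = 1, tracer_amplitude = 1, puncta_peak = 1,
                    haze_fraction = 0.08, photon_scale = 40,
                    read_noise_sd = 0.1, bleach_tau_s = 7200),
    detect = list(sigma_small = 1.0, sigma_large = 1.6, k_mad = 5,
                  min_separation = 2, bulk_sigma = 6, blobness_min = 0.25,
                  bulk_response_ratio_max = 1.5),
    segment = list(border_sigma = 1, min_area = 80, max_area = 3000,
                   watershed_tolerance = 2, q_hi = 0.95, cv_max = 0.3,
                   reference = "post_washin"),
    kinetics = list(dilation_radius = 3, network_threshold = NA,
                    cumulative = TRUE, smooth_window = 5, k_sd = 2,
                    layer_width_um = 10),
    washout = list(phase = "onset")
  ), class = c("papt_config", "list"))
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, so every module block is always complete.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a `papt_config`.
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), user)
  class(cfg) <- c("papt_config", "list")
  cfg
}

# reference frame index: first frame after wash-in completes (lag + 3 tau)
reference_frame_index <- function(cfg, n_frames) {
  t_ref <- cfg$simulate$chamber_lag_s + 3 * cfg$simulate$chamber_tau_s
  min(n_frames, floor(t_ref / cfg$calibration$frame_interval_s) + 2L)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> detect -> segment -> trace -> stats and
#' writes all artifacts to `out_dir`: the movie (if simulated), detections
#' CSV, label-map TIFF, ROI CSV, per-cell trace CSV (with stimulus
#' condition labels), responder CSV, stats JSON, wash-in fit JSON and a
#' run log with the config hash and seed. Outputs are deterministic for a
#' fixed config.
#'
#' @param config a `papt_config` (or path to one).
#' @param out_dir output directory (created if needed).
#' @param input optional TIFF path; when `NULL`, a synthetic movie is
#'   generated under the config's `simulate` block.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir, input = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              seed = cfg$seed)

  truth <- NULL
  if (is.null(input)) {
    sim <- stage("simulate", {
      s <- cfg$simulate
      protocol <- default_protocol()
      geom <- generate_islet_geometry(
        s$n_cells, s$field_size, s$cell_diameter_um,
        cfg$calibration$pixel_size_um, s$endothelial_fraction,
        s$secretory_type, seed = sub_seed(cfg$seed, "geometry"))
      rates <- simulate_rates(protocol, geom$cell_types, s$baseline_rate,
                              s$heterogeneity_cv, s$inactive_fraction,
                              seed = cfg$seed)
      render_movie(geom, rates, chamber_kinetics(s$chamber_lag_s,
                                                 s$chamber_tau_s),
                   cfg$calibration$frame_interval_s, s$n_frames,
                   s$psf_sigma_px, s$tracer_amplitude, s$puncta_peak,
                   s$haze_fraction, photon_scale = s$photon_scale,
                   read_noise_sd = s$read_noise_sd,
                   bleach_tau_s = s$bleach_tau_s, seed = cfg$seed)
    })
    stk <- sim$stack
    truth <- sim$truth
    write_stack(stk, file.path(out_dir, "movie.tif"))
    write_ground_truth(truth, out_dir)
  } else {
    stk <- stage("read", read_stack(
      input, axes = cfg$calibration$axes,
      pixel_size = cfg$calibration$pixel_size_um,
      frame_interval = cfg$calibration$frame_interval_s))
  }
  nt <- n_frames(stk)
  ref_idx <- reference_frame_index(cfg, nt)
  ref <- get_frame(stk, ref_idx)

  seg <- stage("segment", {
    lab <- segment_cells(ref, cfg$segment$border_sigma, cfg$segment$min_area,
                         cfg$segment$max_area, cfg$segment$watershed_tolerance)
    flags <- flag_nonviable(stk, lab, frames = ref_idx:min(nt, ref_idx + 4L),
                            q_hi = cfg$segment$q_hi,
                            cv_max = cfg$segment$cv_max)
    rois <- cell_rois(lab, attr(lab, "hull"), flags,
                      cfg$calibration$pixel_size_um)
    list(lab = lab, flags = flags, rois = rois)
  })

  params <- scale_space_params(
    cfg$detect$sigma_small, cfg$detect$sigma_large, cfg$detect$k_mad,
    min_separation = cfg$detect$min_separation,
    bulk_sigma = cfg$detect$bulk_sigma,
    blobness_min = cfg$detect$blobness_min,
    bulk_response_ratio_max = cfg$detect$bulk_response_ratio_max)
  net_thr <- cfg$kinetics$network_threshold
  if (is.null(net_thr) || is.na(net_thr)) net_thr <- NULL
  ana <- stage("detect+trace", papt_analyze(
    stk, params, seg$lab, border_mask = attr(seg$lab, "border_mask"),
    flags = seg$flags, dilation_radius = cfg$kinetics$dilation_radius,
    network_threshold = net_thr, cumulative = cfg$kinetics$cumulative,
    smooth_window = cfg$kinetics$smooth_window))

  protocol <- default_protocol()
  traces <- ana$traces
  traces$condition <- protocol$condition[
    pmax(1, findInterval(traces$t_s, protocol$start_s))]

  resp <- stage("responders", {
    step_frame <- floor(protocol$start_s[2] /
                          cfg$calibration$frame_interval_s) + 1L
    if (step_frame > ref_idx + 2L && step_frame < nt) {
      base_w <- max(2L, ref_idx):(step_frame - 1L)
      stim_w <- step_frame:nt
      classify_responders(traces, base_w, stim_w, k_sd = cfg$kinetics$k_sd)
    } else NULL   # movie ends before the stimulus: nothing to classify
  })

  depth_prof <- stage("depth", depth_profile(traces, seg$rois,
                                             cfg$kinetics$layer_width_um))

  wfit <- stage("washout", {
    border_trace <- vapply(seq_len(nt), function(t) {
      mean(get_frame(stk, t)[attr(seg$lab, "border_mask")])
    }, numeric(1))
    fit_washout(border_trace, stk$time, phase = cfg$washout$phase)
  })

  # ---- write artifacts (CSV columns carry units in their names) ----
  det_out <- ana$detections
  det_out$frame <- det_out$frame - 1L   # external convention: 0-based
  det_out$z <- det_out$z - 1L
  det_out$y <- det_out$y - 1L
  det_out$x <- det_out$x - 1L
  names(det_out) <- c("frame_0based", "z_0based", "y_px_0based",
                      "x_px_0based", "dog_response_au", "lambda1_au",
                      "lambda2_au", "class", "cell_label")
  utils::write.csv(det_out, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  write_label_map(seg$lab, file.path(out_dir, "label_map.tif"))
  rois_out <- seg$rois
  names(rois_out) <- c("label", "centroid_y_px", "centroid_x_px", "area_px",
                       "depth_um", "endothelial_like", "viable")
  utils::write.csv(rois_out, file.path(out_dir, "rois.csv"),
                   row.names = FALSE)
  tr_out <- traces[c("cell_label", "t_s", "papt", "dpapt_dt", "condition")]
  names(tr_out) <- c("cell_label", "t_s", "papt_au", "dpapt_dt_au_per_s",
                     "condition")
  utils::write.csv(tr_out, file.path(out_dir, "traces.csv"),
                   row.names = FALSE)
  resp_cells <- if (is.null(resp)) {
    data.frame(cell_label = integer(0), active = logical(0),
               delta = numeric(0), threshold = numeric(0))
  } else resp$cells
  utils::write.csv(resp_cells, file.path(out_dir, "responders.csv"),
                   row.names = FALSE)
  utils::write.csv(depth_prof, file.path(out_dir, "depth_profile.csv"),
                   row.names = FALSE)
  stats_json <- list(
    responders = if (is.null(resp)) NULL else
      list(active_fraction = resp$active_fraction,
           inactive_fraction = resp$inactive_fraction,
           ci95 = as.list(resp$ci95), n = resp$n),
    washout = list(lag_time_s = wfit$lag_time,
                   clearance_tau_s = wfit$clearance_tau,
                   amplitude_au = wfit$amplitude,
                   residual_rms_au = wfit$residual_rms))
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  log$config_md5 <- unname(tools::md5sum(cfg_path))
  log$n_cells <- nrow(seg$rois)
  log$n_detections <- nrow(ana$detections)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(stack = stk, truth = truth, label_map = seg$lab,
                 rois = seg$rois, detections = ana$detections,
                 traces = traces, responders = resp, washout = wfit,
                 depth_profile = depth_prof, config = cfg))
}

# ground-truth CSV/TIFF/JSON artifacts for a simulated run
write_ground_truth <- function(truth, out_dir) {
  utils::write.csv(truth$puncta, file.path(out_dir, "truth_puncta.csv"),
                   row.names = FALSE)
  rates <- truth$rates
  rate_tab <- data.frame(cell_label = seq_along(rates$cell_types),
                         cell_type = rates$cell_types,
                         inactive = rates$inactive,
                         heterogeneity_factor = rates$factors)
  for (s in seq_len(nrow(rates$protocol))) {
    rate_tab[[paste0("lambda_seg", s, "_per_s")]] <- rates$lambda[, s]
  }
  utils::write.csv(rate_tab, file.path(out_dir, "truth_rates.csv"),
                   row.names = FALSE)
  write_label_map(truth$label_map, file.path(out_dir, "truth_labels.tif"))
  jsonlite::write_json(truth$params, file.path(out_dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
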
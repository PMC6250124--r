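# Synthetic islet time-lapse generator with complete ground truth.
#
# Emulates the imaging situation the analysis is built for: tightly packed
# islet cells outlined by a bright extracellular polar tracer, stimulus-
# dependent appearance of sub-resolution endocytotic puncta that persist
# once born, endothelial-like cells with high uniform uptake, chamber
# wash-in with a lag and exponential equilibration, photobleaching, and
# Poisson + Gaussian detection noise.

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generation never perturbs user randomness
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a module-specific sub-seed from the master seed (kept < 2^31)
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + sum(utf8ToInt(stream))) %% 2147483587
}

#' Stimulus protocol table
#'
#' Ordered, contiguous perifusion segments with a condition label and a
#' secretion-rate multiplier applied to the per-cell baseline rate of
#' secretory cells (endothelial-like cells ignore the protocol).
#'
#' @param start_s,end_s segment boundaries in seconds; contiguous and
#'   non-overlapping, `start_s < end_s`.
#' @param condition character condition labels (e.g. `"1 mM glucose"`).
#' @param multiplier non-negative finite rate multipliers.
#' @return a `data.frame` of class `papt_protocol`.
#' @export
stimulus_protocol <- function(start_s, end_s, condition, multiplier) {
  stopifnot(length(start_s) == length(end_s),
            length(end_s) == length(condition),
            length(condition) == length(multiplier))
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)) ||
      any(!is.finite(multiplier)) || any(multiplier < 0)) {
    stop("protocol times and multipliers must be finite, multipliers >= 0")
  }
  if (any(start_s >= end_s)) stop("each segment needs start_s < end_s")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  if (length(start_s) > 1 &&
      any(abs(start_s[-1] - end_s[-length(end_s)]) > 1e-9)) {
    stop("segments must be contiguous and non-overlapping")
  }
  structure(data.frame(start_s = start_s, end_s = end_s,
                       condition = condition[o], multiplier = multiplier[o],
                       stringsAsFactors = FALSE),
            class = c("papt_protocol", "data.frame"))
}

#' Default biphasic glucose-step protocol
#'
#' Basal low glucose for 20 min, then a glucose step rendered as a brief
#' intense first phase (1 min) followed by a sustained second phase, the
#' classic biphasic time course of stimulated insulin secretion.
#'
#' @param t_basal_s basal segment duration (s).
#' @param t_first_s first-phase duration (s).
#' @param t_total_s total protocol duration (s).
#' @param m_basal,m_first,m_second rate multipliers of the three segments.
#' @return a `papt_protocol`.
#' @export
default_protocol <- function(t_basal_s = 1200, t_first_s = 60,
                             t_total_s = 2400,
                             m_basal = 0.2, m_first = 25, m_second = 6) {
  stimulus_protocol(
    start_s = c(0, t_basal_s, t_basal_s + t_first_s),
    end_s = c(t_basal_s, t_basal_s + t_first_s, t_total_s),
    condition = c("1 mM glucose", "20 mM glucose (first phase)",
                  "20 mM glucose"),
    multiplier = c(m_basal, m_first, m_second))
}

#' Perifusion chamber kinetics
#'
#' Dead time plus single-exponential equilibration of the tracer
#' concentration in the imaging chamber. Defaults reproduce the measured
#' behaviour of the blotted microperifusion circuit: 2.3 min lag and a
#' 2.1 min characteristic clearance time.
#'
#' @param lag_time_s transport dead time in seconds (>= 0).
#' @param clearance_tau_s e-folding equilibration time in seconds (> 0).
#' @return a `papt_chamber` list.
#' @export
chamber_kinetics <- function(lag_time_s = 138, clearance_tau_s = 126) {
  stopifnot(is.finite(lag_time_s), lag_time_s >= 0,
            is.finite(clearance_tau_s), clearance_tau_s > 0)
  structure(list(lag_time = lag_time_s, clearance_tau = clearance_tau_s),
            class = "papt_chamber")
}

# chamber tracer concentration (fraction of perifusate concentration)
washin_fraction <- function(t, chamber) {
  ifelse(t < chamber$lag_time, 0,
         1 - exp(-(t - chamber$lag_time) / chamber$clearance_tau))
}

#' Generate a packed islet-like cell geometry
#'
#' Places `n_cells` centres inside a disk by minimum-separation dart
#' throwing, partitions the disk by nearest centre (a Voronoi-like packing),
#' and erodes every cell by one pixel so that neighbouring cells are
#' separated by a 1-3 px extracellular border, the "cell borders" that the
#' polar tracer outlines.
#'
#' @param n_cells number of cells (>= 1).
#' @param field_size image size in px, scalar or `c(ny, nx)`.
#' @param cell_diameter nominal cell diameter in micrometres.
#' @param pixel_size pixel size in micrometres.
#' @param endothelial_fraction fraction of cells typed `"endothelial"`;
#'   the count is `round(fraction * n_cells)`, exactly.
#' @param secretory_type cell type of the non-endothelial cells
#'   (`"beta"`, `"alpha"` or `"delta"`).
#' @param seed RNG seed; the map is bit-reproducible given the seed.
#' @return list with `label_map` (integer matrix, 0 = extracellular),
#'   `border_mask` (logical), `hull` (logical islet footprint),
#'   `cell_types` (character vector indexed by label), `centers`,
#'   `pixel_size`.
#' @export
generate_islet_geometry <- function(n_cells, field_size = 512,
                                    cell_diameter = 10, pixel_size = 0.4,
                                    endothelial_fraction = 0,
                                    secretory_type = "beta", seed = 1) {
  stopifnot(n_cells >= 1, cell_diameter > 0, pixel_size > 0,
            endothelial_fraction >= 0, endothelial_fraction <= 1)
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  ny <- field_size[1]; nx <- field_size[2]
  rc <- cell_diameter / 2 / pixel_size            # cell radius, px
  R <- rc * sqrt(n_cells)                         # islet disk radius, px
  margin <- 2
  if (2 * (R + margin) > min(ny, nx)) {
    stop(sprintf(paste0("infeasible packing: %d cells of %.3g um need an islet",
                        " of radius %.0f px, but the field is %d x %d px"),
                 n_cells, cell_diameter, R, ny, nx))
  }
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  with_seed(seed, {
    # dart-throwing with shrinking separation; deterministic given seed
    min_sep <- 1.5 * rc
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_cells) {
      tries <- tries + 1L
      if (tries > 20000L) {
        if (min_sep > 0.8 * rc) {
          min_sep <- min_sep * 0.9; tries <- 0L
        } else {
          stop("infeasible packing: could not place all cell centres")
        }
      }
      u <- sqrt(runif(1)) * max(R - 0.6 * rc, 0.1)
      a <- runif(1, 0, 2 * pi)
      p <- c(cy + u * sin(a), cx + u * cos(a))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= min_sep) {
        centers <- rbind(centers, p)
      }
    }
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    hull <- (yy - cy)^2 + (xx - cx)^2 <= R^2
    # nearest-centre partition inside the hull
    d2 <- matrix(Inf, ny, nx)
    lab <- matrix(0L, ny, nx)
    for (i in seq_len(n_cells)) {
      di <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2
      upd <- hull & di < d2
      d2[upd] <- di[upd]
      lab[upd] <- i
    }
    # 1-px erosion of every cell: a pixel stays only if its 4-neighbours
    # share its label and lie inside the hull
    same <- function(a, b) !is.na(a) & !is.na(b) & a == b
    shift <- function(m, dy, dx) {
      out <- matrix(NA_integer_, ny, nx)
      ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
      ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
      out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
      out
    }
    keep <- lab > 0 &
      same(lab, shift(lab, 1L, 0L)) & same(lab, shift(lab, -1L, 0L)) &
      same(lab, shift(lab, 0L, 1L)) & same(lab, shift(lab, 0L, -1L))
    lab[!keep] <- 0L
    border <- hull & lab == 0L
    n_endo <- round(endothelial_fraction * n_cells)
    types <- rep(secretory_type, n_cells)
    if (n_endo > 0) types[sample(n_cells, n_endo)] <- "endothelial"
    list(label_map = lab, border_mask = border, hull = hull,
         cell_types = types, centers = centers, pixel_size = pixel_size,
         seed = seed)
  })
}

#' Simulate per-cell secretion-rate functions
#'
#' Each secretory cell's punctum birth rate is piecewise constant over the
#' protocol: baseline rate x segment multiplier x a per-cell lognormal
#' heterogeneity factor (unit mean, coefficient of variation
#' `heterogeneity_cv`). An exact `round(inactive_fraction * n)` subset of the
#' cells of `inactive_type` is silenced (rate 0 in all segments).
#' Endothelial cells get no punctum rate; their constant high uniform uptake
#' is carried separately (`endothelial_uptake`, a.u. per second).
#'
#' @param protocol a `papt_protocol`.
#' @param cell_types character vector of cell types, indexed by label.
#' @param baseline_rate baseline punctum birth rate, puncta per second per
#'   cell, before multipliers.
#' @param heterogeneity_cv CV of the per-cell lognormal factor (>= 0).
#' @param inactive_fraction fraction of `inactive_type` cells silenced.
#' @param inactive_type cell type subject to silencing (default: all
#'   secretory types).
#' @param endothelial_uptake uniform uptake rate of endothelial cells,
#'   a.u. s^-1 (reached intensity ~2 a.u. over a 40 min movie by default).
#' @param seed RNG seed.
#' @return object of class `papt_rates`: list with `lambda` (cells x
#'   segments matrix, puncta/s), `protocol`, `factors`, `inactive`,
#'   `endothelial_uptake`, `cell_types`.
#' @export
simulate_rates <- function(protocol, cell_types, baseline_rate = 3e-3,
                           heterogeneity_cv = 0.6, inactive_fraction = 0,
                           inactive_type = NULL,
                           endothelial_uptake = 8.5e-4, seed = 1) {
  stopifnot(inherits(protocol, "papt_protocol"),
            inactive_fraction >= 0, inactive_fraction <= 1,
            heterogeneity_cv >= 0, baseline_rate >= 0)
  n <- length(cell_types)
  with_seed(sub_seed(seed, "rates"), {
    sdlog <- sqrt(log(1 + heterogeneity_cv^2))
    factors <- if (heterogeneity_cv > 0) {
      rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n)
    secretory <- cell_types != "endothelial"
    eligible <- if (is.null(inactive_type)) which(secretory) else
      which(cell_types == inactive_type)
    inactive <- rep(FALSE, n)
    n_off <- round(inactive_fraction * length(eligible))
    if (n_off > 0) inactive[sample(eligible, n_off)] <- TRUE
    lambda <- outer(baseline_rate * factors, protocol$multiplier)
    lambda[!secretory, ] <- 0
    lambda[inactive, ] <- 0
    structure(list(lambda = lambda, protocol = protocol, factors = factors,
                   inactive = inactive, endothelial_uptake = endothelial_uptake,
                   cell_types = cell_types, seed = seed),
              class = "papt_rates")
  })
}

# piecewise-constant rate of cell i at times t (vector), zero outside protocol
rate_at <- function(rates, i, t) {
  seg <- findInterval(t, rates$protocol$start_s,
                      rightmost.closed = FALSE, left.open = FALSE)
  out <- numeric(length(t))
  ok <- seg >= 1 & t < rates$protocol$end_s[pmin(seg, nrow(rates$protocol))]
  out[ok] <- rates$lambda[i, seg[ok]]
  out
}

# circular Gaussian stamp of a punctum at continuous position (py, px)
stamp_punctum <- function(img, py, px, peak, psf_sigma) {
  r <- ceiling(5 * psf_sigma)
  ys <- max(1, floor(py) - r):min(nrow(img), ceiling(py) + r)
  xs <- max(1, floor(px) - r):min(ncol(img), ceiling(px) + r)
  gy <- exp(-(ys - py)^2 / (2 * psf_sigma^2))
  gx <- exp(-(xs - px)^2 / (2 * psf_sigma^2))
  img[ys, xs] <- img[ys, xs] + peak * outer(gy, gx)
  img
}

#' Render a synthetic time-lapse movie with ground truth
#'
#' Combines the geometry, the per-cell rate functions and the chamber
#' kinetics into a noisy movie. The extracellular border follows the
#' wash-in curve; every cell interior carries a faint tracer haze
#' (`haze_fraction` of the border amplitude); endothelial cells accumulate
#' uniform intensity linearly once the tracer has arrived; puncta are born
#' by an inhomogeneous Poisson process with intensity
#' `lambda_i(t) * washin(t)` and persist for the rest of the movie (vesicles
#' remain detectable for hours); the whole signal is multiplied by
#' `exp(-t / bleach_tau)`; noise is `Poisson(photon_scale * signal) /
#' photon_scale + N(0, read_noise_sd)`.
#'
#' With the defaults the punctum peak-to-noise ratio is ~5.
#'
#' @param geometry output of [generate_islet_geometry()].
#' @param rates a `papt_rates` from [simulate_rates()].
#' @param chamber a `papt_chamber`.
#' @param frame_interval_s frame interval (s).
#' @param n_frames number of frames (>= 2).
#' @param psf_sigma Gaussian PSF sigma in px (> 0).
#' @param tracer_amplitude plateau intensity of the extracellular border
#'   (a.u.).
#' @param puncta_peak peak intensity of one punctum (a.u.); the integrated
#'   brightness is `puncta_peak * 2 * pi * psf_sigma^2`.
#' @param haze_fraction intracellular tracer haze, as a fraction of
#'   `tracer_amplitude`.
#' @param puncta_margin_px puncta are placed at least this far inside the
#'   cell mask, keeping sub-resolution uptake distinct from the membrane
#'   signal at the analysis scale.
#' @param puncta_min_sep_px optional minimum separation between puncta of
#'   one cell (px); 0 (default) allows optically merging events.
#' @param photon_scale photons per intensity unit for the Poisson shot-noise
#'   model; `Inf` disables shot noise.
#' @param read_noise_sd Gaussian read-noise standard deviation (a.u.);
#'   0 disables it.
#' @param bleach_tau_s photobleaching e-folding time (s); `Inf` disables.
#' @param frame_interval_s frame interval in seconds.
#' @param seed RNG seed; rendering is bit-reproducible given the seed.
#' @return list with `stack` (a [papt_stack()]) and `truth`
#'   (class `papt_truth`): label map, cell types, border/hull masks, the
#'   puncta event table, the rates object, chamber and all parameters.
#' @export
render_movie <- function(geometry, rates, chamber = chamber_kinetics(),
                         frame_interval_s = 30, n_frames = 80,
                         psf_sigma = 1, tracer_amplitude = 1,
                         puncta_peak = 1, haze_fraction = 0.08,
                         puncta_margin_px = 2, puncta_min_sep_px = 0,
                         photon_scale = 40,
                         read_noise_sd = 0.1, bleach_tau_s = 7200,
                         pixel_size = NULL, seed = 1) {
  stopifnot(n_frames >= 2, psf_sigma > 0)
  pars <- c(frame_interval_s, psf_sigma, tracer_amplitude, puncta_peak,
            haze_fraction, read_noise_sd)
  if (any(!is.finite(pars)) || !(is.finite(photon_scale) || is.infinite(photon_scale)) ||
      !(is.finite(bleach_tau_s) || is.infinite(bleach_tau_s))) {
    stop("render_movie: non-finite parameter")
  }
  if (is.null(pixel_size)) pixel_size <- geometry$pixel_size
  lab <- geometry$label_map
  ny <- nrow(lab); nx <- ncol(lab)
  n_cells <- length(geometry$cell_types)
  t_frames <- (seq_len(n_frames) - 1) * frame_interval_s

  # static structural templates, blurred once by the PSF
  border_t <- gauss_smooth(geometry$border_mask * 1.0, psf_sigma)
  interior_t <- gauss_smooth((lab > 0) * 1.0, psf_sigma)
  endo_mask <- lab %in% which(geometry$cell_types == "endothelial")
  endo_t <- if (any(endo_mask)) {
    gauss_smooth(matrix(as.numeric(endo_mask), ny, nx), psf_sigma)
  } else NULL

  # per-cell pixel pools for punctum placement (eroded interiors)
  pools <- punctum_pools(lab, puncta_margin_px)

  with_seed(sub_seed(seed, "render"), {
    movie <- array(0, c(ny, nx, n_frames))
    puncta_img <- matrix(0, ny, nx)
    events <- vector("list", n_frames)
    placed_y <- rep(list(numeric(0)), n_cells)
    placed_x <- rep(list(numeric(0)), n_cells)
    for (k in seq_len(n_frames)) {
      t0 <- t_frames[k]
      t_mid <- t0 + frame_interval_s / 2
      if (k > 1) {
        # births during (t_{k-1}, t_k]: midpoint-rate Poisson draw per cell
        tm <- t_frames[k - 1] + frame_interval_s / 2
        w <- washin_fraction(tm, chamber)
        born <- lapply(seq_len(n_cells), function(i) {
          if (length(pools[[i]]) == 0) return(NULL)
          mu <- rate_at(rates, i, tm) * w * frame_interval_s
          nb <- if (mu > 0) rpois(1, mu) else 0L
          if (nb == 0) return(NULL)
          ys <- xs <- numeric(nb)
          for (q in seq_len(nb)) {
            for (try in seq_len(40L)) {
              px_idx <- pools[[i]][sample.int(length(pools[[i]]), 1L)]
              yq <- ((px_idx - 1) %% ny) + 1 + runif(1, -0.5, 0.5)
              xq <- ((px_idx - 1) %/% ny) + 1 + runif(1, -0.5, 0.5)
              prev_y <- c(placed_y[[i]], ys[seq_len(q - 1L)])
              prev_x <- c(placed_x[[i]], xs[seq_len(q - 1L)])
              if (puncta_min_sep_px <= 0 || length(prev_y) == 0 ||
                  min((prev_y - yq)^2 + (prev_x - xq)^2) >=
                    puncta_min_sep_px^2) break
            }
            ys[q] <- yq; xs[q] <- xq
          }
          data.frame(
            cell = i,
            birth_time_s = runif(nb, t_frames[k - 1], t_frames[k]),
            y = ys, x = xs, peak = puncta_peak)
        })
        born <- do.call(rbind, born)
        if (!is.null(born) && nrow(born) > 0) {
          events[[k]] <- born
          for (j in seq_len(nrow(born))) {
            puncta_img <- stamp_punctum(puncta_img, born$y[j], born$x[j],
                                        born$peak[j], psf_sigma)
            placed_y[[born$cell[j]]] <- c(placed_y[[born$cell[j]]], born$y[j])
            placed_x[[born$cell[j]]] <- c(placed_x[[born$cell[j]]], born$x[j])
          }
        }
      }
      w_now <- washin_fraction(t0, chamber)
      clean <- tracer_amplitude * w_now * border_t +
        haze_fraction * tracer_amplitude * w_now * interior_t +
        puncta_img
      if (!is.null(endo_t)) {
        exposure <- max(0, t0 - chamber$lag_time)
        clean <- clean + rates$endothelial_uptake * exposure * endo_t
      }
      if (is.finite(bleach_tau_s)) clean <- clean * exp(-t0 / bleach_tau_s)
      frame <- clean
      if (is.finite(photon_scale)) {
        frame <- rpois(length(clean), photon_scale * pmax(clean, 0)) /
          photon_scale
        dim(frame) <- dim(clean)
      }
      if (read_noise_sd > 0) {
        frame <- frame + rnorm(length(frame), 0, read_noise_sd)
        dim(frame) <- dim(clean)
      }
      movie[, , k] <- frame
    }
    puncta <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
    if (is.null(puncta)) {
      puncta <- data.frame(cell = integer(0), birth_time_s = numeric(0),
                           y = numeric(0), x = numeric(0), peak = numeric(0))
    }
    stack <- papt_stack(aperm(movie, c(3, 1, 2)), pixel_size,
                        frame_interval_s, channels = "tracer", axes = "TYX")
    truth <- structure(list(
      label_map = lab, cell_types = geometry$cell_types,
      border_mask = geometry$border_mask, hull = geometry$hull,
      puncta = puncta, rates = rates, chamber = chamber,
      params = list(frame_interval_s = frame_interval_s, n_frames = n_frames,
                    psf_sigma = psf_sigma, tracer_amplitude = tracer_amplitude,
                    puncta_peak = puncta_peak, haze_fraction = haze_fraction,
                    puncta_margin_px = puncta_margin_px,
                    puncta_min_sep_px = puncta_min_sep_px,
                    photon_scale = photon_scale,
                    read_noise_sd = read_noise_sd, bleach_tau_s = bleach_tau_s,
                    pixel_size = pixel_size, seed = seed)),
      class = "papt_truth")
    list(stack = stack, truth = truth)
  })
}

# linear pixel indices of each cell's interior eroded by `margin` px
punctum_pools <- function(lab, margin) {
  n <- max(lab)
  if (margin > 0) {
    inner <- EBImage::erode(
      matrix(as.numeric(lab > 0), nrow(lab), ncol(lab)),
      EBImage::makeBrush(2L * as.integer(margin) + 1L, shape = "diamond"))
    lab2 <- lab
    lab2[inner < 0.5] <- 0L
  } else lab2 <- lab
  pools <- split(which(lab2 > 0), lab2[lab2 > 0])
  out <- vector("list", n)
  for (nm in names(pools)) out[[as.integer(nm)]] <- pools[[nm]]
  for (i in seq_len(n)) {
    if (is.null(out[[i]])) {
      # margin swallowed a small cell: fall back to the un-eroded mask
      out[[i]] <- which(lab == i)
    }
  }
  out
}
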
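# Per-cell PAPT kinetics: the patterned-system mask, background-corrected
# per-cell traces, their smoothed first temporal derivative (the secretion
# surrogate), responder classification, depth profiles and perifusion
# wash-in/washout fits.

# disk offsets (dy, dx) of radius r, used to stamp detection disks
disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

#' Build the per-frame patterned-system mask
#'
#' The patterned system is the union of (a) disks of `dilation_radius`
#' around punctate maxima and (b) in-cell pixels whose fine-scale DoG
#' response exceeds `network_threshold`, which captures the connected
#' endosomal network between discrete maxima. By default the mask is
#' cumulative over frames (monotone non-decreasing), reflecting vesicles
#' that persist once born; `cumulative = FALSE` gives the per-frame mask.
#'
#' @param stack a [papt_stack()].
#' @param detections data.frame from [detect_stack()]; only rows with
#'   `class == "punctate"` are used.
#' @param params the [scale_space_params()] used for detection.
#' @param cell_mask logical matrix of in-cell pixels (e.g.
#'   `label_map > 0`); network pixels outside it are ignored.
#' @param dilation_radius disk radius around each maximum, px (default 3,
#'   about three PSF sigma, capturing ~99% of a punctum's flux).
#' @param network_threshold DoG response cut for network pixels; by default
#'   the larger of 0.6 x the detection threshold (first-frame MAD units)
#'   and 10% of the running median punctate response, so the cut stays
#'   meaningful in the noise-free limit.
#' @param cumulative logical; cumulative union over frames (default).
#' @param channel channel index.
#' @return logical array `[y, x, t]`.
#' @export
build_papt_mask <- function(stack, detections, params = scale_space_params(),
                            cell_mask = NULL, dilation_radius = 3,
                            network_threshold = NULL, cumulative = TRUE,
                            channel = 1L) {
  d <- dim(stack$data)
  ny <- d[4]; nx <- d[5]; nt <- d[1]
  mask <- array(FALSE, c(ny, nx, nt))
  offs <- disk_offsets(dilation_radius)
  pk <- detections[detections$class == "punctate", , drop = FALSE]
  cur <- matrix(FALSE, ny, nx)
  thr_base <- NULL
  resp_floor <- 0
  net_space <- NULL
  for (t in seq_len(nt)) {
    if (!cumulative) cur <- matrix(FALSE, ny, nx)
    resp <- dog_filter(stack$data[t, 1, channel, , ],
                       params$sigma_small, params$sigma_large)
    if (is.null(thr_base)) {
      thr0 <- detection_threshold(resp, params)
      thr_base <- if (is.null(network_threshold)) 0.6 * thr0 else
        network_threshold
    }
    dk <- pk[pk$frame == t, , drop = FALSE]
    if (is.null(network_threshold) && nrow(dk)) {
      # floor the network cut at 10% of the typical punctum response, so a
      # (nearly) noise-free response image does not flood the mask
      resp_floor <- max(resp_floor, 0.1 * stats::median(dk$dog_response))
    }
    thr <- max(thr_base, resp_floor)
    if (is.finite(thr)) {
      net <- resp > thr
      if (!is.null(cell_mask)) {
        if (is.null(net_space)) {
          # stay 2 px clear of the cell boundary: the bright extracellular
          # border bleeds response into the first pixels of each cell
          net_space <- !dilate_mask(!cell_mask, 2L)
        }
        net <- net & net_space
      }
      cur <- cur | net
    }
    if (nrow(dk)) {
      ys <- pmin(pmax(rep(dk$y, each = nrow(offs)) + offs$dy, 1L), ny)
      xs <- pmin(pmax(rep(dk$x, each = nrow(offs)) + offs$dx, 1L), nx)
      cur[cbind(ys, xs)] <- TRUE
    }
    mask[, , t] <- cur
  }
  mask
}

#' Per-cell PAPT traces from a stack, label map and patterned-system mask
#'
#' For each cell and frame: the summed intensity over
#' `cell intersect mask(t)`, minus the occupied area times the per-cell
#' background (median intensity of the cell outside the mask at that
#' frame). Negative values are clipped to zero. Cells flagged non-viable
#' are excluded; cells whose mask is empty at every frame yield a zero
#' trace, not an error.
#'
#' @param stack a [papt_stack()].
#' @param label_map integer cell label matrix.
#' @param papt_mask logical array `[y, x, t]` from [build_papt_mask()].
#' @param flags optional data.frame from [flag_nonviable()]; non-viable
#'   cells are dropped.
#' @param smooth_window window (frames, odd) for the derivative.
#' @param channel channel index.
#' @return object of class `papt_traces`: a data.frame with `cell_label`,
#'   `frame`, `t_s`, `papt`, `dpapt_dt`, `mask_area_px`; the islet-mean
#'   trace is in `attr(, "islet")`.
#' @export
cell_trace <- function(stack, label_map, papt_mask, flags = NULL,
                       smooth_window = 5, channel = 1L) {
  d <- dim(stack$data)
  if (!identical(dim(label_map), as.integer(d[4:5]))) {
    stop("label map does not match the stack's spatial shape")
  }
  labs <- sort(unique(label_map[label_map > 0]))
  if (!is.null(flags)) {
    labs <- intersect(labs, flags$label[flags$viable])
  }
  nt <- d[1]
  papt <- area <- matrix(0, length(labs), nt)
  in_cell <- label_map > 0
  for (t in seq_len(nt)) {
    frame <- stack$data[t, 1, channel, , ]
    m <- papt_mask[, , t]
    sel_in <- in_cell & m
    sel_out <- in_cell & !m
    s_in <- rowsum_by_label(frame, label_map, sel_in, labs)
    n_in <- rowsum_by_label(NULL, label_map, sel_in, labs)
    bg <- median_by_label(frame, label_map, sel_out, labs)
    bg[is.na(bg)] <- 0
    papt[, t] <- pmax(0, s_in - n_in * bg)
    area[, t] <- n_in
  }
  t_s <- stack$time
  dp <- t(apply(papt, 1, trace_derivative, dt = stack$frame_interval,
                smooth_window = smooth_window))
  if (length(labs) == 1L) dp <- matrix(dp, 1L)
  out <- data.frame(
    cell_label = rep(labs, each = nt),
    frame = rep(seq_len(nt), length(labs)),
    t_s = rep(t_s, length(labs)),
    papt = as.vector(t(papt)),
    dpapt_dt = as.vector(t(dp)),
    mask_area_px = as.vector(t(area)))
  class(out) <- c("papt_traces", "data.frame")
  attr(out, "islet") <- data.frame(
    t_s = t_s, papt = colMeans(papt),
    dpapt_dt = trace_derivative(colMeans(papt), stack$frame_interval,
                                smooth_window))
  attr(out, "frame_interval") <- stack$frame_interval
  out
}

# sum (or count when frame is NULL) of selected pixels per label;
# labels with no selected pixels contribute 0
rowsum_by_label <- function(frame, label_map, sel, labs) {
  out <- numeric(length(labs))
  if (!any(sel)) return(out)
  l <- label_map[sel]
  v <- if (is.null(frame)) rep(1, length(l)) else frame[sel]
  s <- rowsum(v, l)
  hit <- match(as.integer(rownames(s)), labs)
  ok <- !is.na(hit)
  out[hit[ok]] <- s[ok, 1L]
  out
}

median_by_label <- function(frame, label_map, sel, labs) {
  out <- rep(NA_real_, length(labs))
  if (!any(sel)) return(out)
  sp <- split(frame[sel], factor(label_map[sel], levels = labs))
  vapply(sp, function(v) if (length(v)) stats::median(v) else NA_real_,
         numeric(1))
}

#' Smoothed first temporal derivative of a trace
#'
#' Local quadratic (Savitzky-Golay) first derivative over an odd window.
#' Interior points use the centred window; endpoints use shrunken one-sided
#' windows, so a linear ramp returns its exact slope everywhere.
#'
#' @param y numeric trace.
#' @param dt sampling interval, s.
#' @param smooth_window odd window length in samples, `>= 3`, `<= length(y)`.
#' @return numeric derivative, units of `y` per second. Linear in `y`.
#' @export
trace_derivative <- function(y, dt, smooth_window = 5) {
  n <- length(y)
  stopifnot(smooth_window %% 2 == 1, smooth_window >= 3, smooth_window <= n)
  h <- (smooth_window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    o <- (lo:hi) - i
    deg <- min(2L, length(o) - 1L)
    X <- outer(o, 0:deg, "^")
    w <- solve(crossprod(X), t(X))[2L, ]
    out[i] <- sum(w * y[lo:hi]) / dt
  }
  out
}

#' Classify cells as secretion responders
#'
#' A cell is `active` when its mean derivative over the stimulus window
#' exceeds its baseline mean by `k_sd` baseline standard deviations. If a
#' cell's baseline SD is degenerate (zero) it is floored at the median
#' baseline SD across cells (or `sd_floor`). The active fraction is
#' reported with a Wilson 95% confidence interval.
#'
#' @param traces a `papt_traces` from [cell_trace()].
#' @param baseline_frames,stimulus_frames disjoint frame-index windows;
#'   the baseline must precede the stimulus.
#' @param k_sd threshold in baseline SD units (default 2).
#' @param sd_floor optional absolute SD floor.
#' @return list with `cells` (data.frame: `cell_label`, `active`,
#'   `delta`, `threshold`), `active_fraction`, `inactive_fraction`,
#'   `ci95` (Wilson), `n`.
#' @export
classify_responders <- function(traces, baseline_frames, stimulus_frames,
                                k_sd = 2, sd_floor = NULL) {
  if (max(baseline_frames) >= min(stimulus_frames)) {
    stop("baseline window must precede the stimulus window")
  }
  labs <- unique(traces$cell_label)
  base_mean <- base_sd <- stim_mean <- numeric(length(labs))
  for (i in seq_along(labs)) {
    tr <- traces[traces$cell_label == labs[i], ]
    base_mean[i] <- mean(tr$dpapt_dt[tr$frame %in% baseline_frames])
    base_sd[i] <- stats::sd(tr$dpapt_dt[tr$frame %in% baseline_frames])
    stim_mean[i] <- mean(tr$dpapt_dt[tr$frame %in% stimulus_frames])
  }
  floor_sd <- if (is.null(sd_floor)) {
    m <- stats::median(base_sd[base_sd > 0])
    if (is.finite(m)) m else .Machine$double.eps
  } else sd_floor
  base_sd <- pmax(base_sd, floor_sd)
  thr <- base_mean + k_sd * base_sd
  active <- stim_mean > thr
  n <- length(labs); k <- sum(active)
  list(cells = data.frame(cell_label = labs, active = active,
                          delta = stim_mean - base_mean, threshold = thr),
       active_fraction = k / n,
       inactive_fraction = 1 - k / n,
       ci95 = wilson_ci(k, n),
       n = n)
}

# Wilson 95% score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Mean PAPT traces by tissue depth layer
#'
#' Bins cells into depth layers `[0, w), [w, 2w), ...` from the islet
#' surface and returns each layer's mean and standard error trace. Empty
#' layers are absent from the output (reported missing, not zero).
#'
#' @param traces a `papt_traces`.
#' @param depths data.frame with `label` and `depth_um` (from
#'   [compute_depth()]).
#' @param layer_width layer width, micrometres (> 0).
#' @return data.frame: `layer`, `depth_lo_um`, `depth_hi_um`, `t_s`,
#'   `mean_papt`, `se_papt`, `n_cells`.
#' @export
depth_profile <- function(traces, depths, layer_width = 10) {
  stopifnot(layer_width > 0)
  dmap <- stats::setNames(depths$depth_um, depths$label)
  traces$depth <- dmap[as.character(traces$cell_label)]
  traces <- traces[!is.na(traces$depth), ]
  traces$layer <- floor(traces$depth / layer_width)
  out <- list()
  for (ly in sort(unique(traces$layer))) {
    sub <- traces[traces$layer == ly, ]
    n_cells <- length(unique(sub$cell_label))
    agg_m <- tapply(sub$papt, sub$t_s, mean)
    agg_s <- tapply(sub$papt, sub$t_s, stats::sd) / sqrt(n_cells)
    out[[length(out) + 1L]] <- data.frame(
      layer = ly, depth_lo_um = ly * layer_width,
      depth_hi_um = (ly + 1) * layer_width,
      t_s = as.numeric(names(agg_m)),
      mean_papt = as.numeric(agg_m),
      se_papt = as.numeric(agg_s),
      n_cells = n_cells)
  }
  do.call(rbind, out)
}

#' Fit the delayed-exponential perifusion curve
#'
#' Least-squares fit of `f(t) = A * (1 - exp(-(t - lag) / tau))` for
#' `t > lag` (onset; zero before the lag), or its mirrored form
#' `A * exp(-(t - lag) / tau)` for washout. Initial values come from the
#' 10%-rise time (lag) and the 10%-to-63% interval (tau). The fit is by
#' Levenberg-Marquardt least squares.
#'
#' @param trace numeric intensity trace.
#' @param time time vector, s (strictly increasing, same length).
#' @param phase `"onset"` or `"washout"`.
#' @return object of class `papt_washout`: list with `lag_time`,
#'   `clearance_tau`, `amplitude`, `residual_rms`, `phase`, `fitted`.
#' @export
fit_washout <- function(trace, time, phase = c("onset", "washout")) {
  phase <- match.arg(phase)
  stopifnot(length(trace) == length(time), all(diff(time) > 0))
  y <- as.numeric(trace); t <- as.numeric(time)
  if (phase == "washout") y <- max(y) - y   # reduce to the rising form
  A0 <- stats::quantile(y, 0.95, names = FALSE)
  if (A0 <= 0) stop("trace carries no signal to fit")
  t10 <- t[which(y >= 0.10 * A0)[1]]
  t63 <- t[which(y >= 0.632 * A0)[1]]
  if (is.na(t10)) t10 <- t[1]
  if (is.na(t63) || t63 <= t10) t63 <- t10 + diff(range(t)) / 4
  dt_min <- min(diff(t))
  model <- function(par) par[1] * (1 - exp(-pmax(t - par[2], 0) /
                                             max(par[3], 1e-9)))
  sse <- function(par) {
    if (par[1] < 0 || par[2] < 0 || par[3] <= 0) return(Inf)
    sum((y - model(par))^2)
  }
  tau0 <- max(t63 - t10, dt_min)
  starts <- list(c(A0, max(t10, t[1]), tau0),
                 c(A0, max(t10, t[1]), dt_min),
                 c(A0, t[1], diff(range(t)) / 5))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (1 - exp(-pmax(t - lag, 0) / tau)),
        start = list(A = st[1], lag = st[2], tau = st[3]),
        lower = c(A = 0, lag = 0, tau = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    cand <- if (!is.null(fit)) {
      cf <- stats::coef(fit)
      c(cf["A"], cf["lag"], cf["tau"])
    } else {
      # kinked model can defeat the gradient step (e.g. a near-step
      # trace); fall back to a derivative-free simplex search
      op <- stats::optim(st, sse, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
      op$par
    }
    if (is.null(best) || sse(cand) < sse(best)) best <- cand
  }
  if (is.null(best) || !is.finite(sse(best))) {
    stop("washout fit did not converge (initial lag=", signif(t10, 3),
         " s, tau=", signif(tau0, 3), " s, residual RMS at start=",
         signif(sqrt(sse(starts[[1]]) / length(y)), 3), ")")
  }
  fitted_y <- model(best)
  if (phase == "washout") fitted_y <- max(trace) - fitted_y
  structure(list(lag_time = unname(best[2]),
                 clearance_tau = unname(best[3]),
                 amplitude = unname(best[1]),
                 residual_rms = sqrt(sse(best) / length(y)),
                 phase = phase, fitted = fitted_y),
            class = "papt_washout")
}

#' @export
print.papt_washout <- function(x, ...) {
  cat(sprintf("perifusion %s fit: lag %.3g s (%.2f min), tau %.3g s (%.2f min), amplitude %.3g, RMS %.3g\n",
              x$phase, x$lag_time, x$lag_time / 60, x$clearance_tau,
              x$clearance_tau / 60, x$amplitude, x$residual_rms))
  invisible(x)
}

#' One-pass detection + mask + trace analysis of a movie
#'
#' Streams over frames once, running the DoG detector, classifying maxima,
#' growing the (cumulative) patterned-system mask, and accumulating the
#' per-cell background-corrected PAPT sums. Produces the same traces as
#' [build_papt_mask()] followed by [cell_trace()] without holding per-frame
#' response images.
#'
#' @param stack a [papt_stack()].
#' @param params a [scale_space_params()].
#' @param label_map integer cell label matrix.
#' @param border_mask logical extracellular border mask.
#' @param flags optional viability flags from [flag_nonviable()].
#' @param dilation_radius,network_threshold,cumulative see
#'   [build_papt_mask()].
#' @param smooth_window derivative window (frames).
#' @param channel channel index.
#' @return list with `detections` (as [detect_stack()]) and `traces`
#'   (a `papt_traces`).
#' @export
papt_analyze <- function(stack, params = scale_space_params(), label_map,
                         border_mask = NULL, flags = NULL,
                         dilation_radius = 3, network_threshold = NULL,
                         cumulative = TRUE, smooth_window = 5,
                         channel = 1L) {
  d <- dim(stack$data)
  ny <- d[4]; nx <- d[5]; nt <- d[1]
  labs <- sort(unique(label_map[label_map > 0]))
  if (!is.null(flags)) labs <- intersect(labs, flags$label[flags$viable])
  in_cell <- label_map > 0
  net_space <- !dilate_mask(!in_cell, 2L)   # clear of border bleed-through
  offs <- disk_offsets(dilation_radius)
  cur <- matrix(FALSE, ny, nx)
  papt <- area <- matrix(0, length(labs), nt)
  dets <- vector("list", nt)
  thr <- NULL; net_base <- NULL
  resp_floor <- 0
  for (t in seq_len(nt)) {
    frame <- stack$data[t, 1, channel, , ]
    resp <- dog_filter(frame, params$sigma_small, params$sigma_large)
    if (is.null(thr)) {
      thr <- detection_threshold(resp, params)
      net_base <- if (is.null(network_threshold)) 0.6 * thr else
        network_threshold
    }
    det <- detect_frame(frame, params, border_mask, label_map,
                        threshold = thr, response = resp)
    if (nrow(det)) {
      det$frame <- t; det$z <- 1L
      dets[[t]] <- det
    }
    if (!cumulative) cur <- matrix(FALSE, ny, nx)
    pk <- det[det$class == "punctate", , drop = FALSE]
    if (is.null(network_threshold) && nrow(pk)) {
      resp_floor <- max(resp_floor, 0.1 * stats::median(pk$dog_response))
    }
    net_thr <- max(net_base, resp_floor)
    if (is.finite(net_thr)) cur <- cur | (resp > net_thr & net_space)
    if (nrow(pk)) {
      ys <- pmin(pmax(rep(pk$y, each = nrow(offs)) + offs$dy, 1L), ny)
      xs <- pmin(pmax(rep(pk$x, each = nrow(offs)) + offs$dx, 1L), nx)
      cur[cbind(ys, xs)] <- TRUE
    }
    sel_in <- in_cell & cur
    sel_out <- in_cell & !cur
    s_in <- rowsum_by_label(frame, label_map, sel_in, labs)
    n_in <- rowsum_by_label(NULL, label_map, sel_in, labs)
    bg <- median_by_label(frame, label_map, sel_out, labs)
    bg[is.na(bg)] <- 0
    papt[, t] <- pmax(0, s_in - n_in * bg)
    area[, t] <- n_in
  }
  detections <- do.call(rbind, dets[!vapply(dets, is.null, logical(1))])
  if (is.null(detections)) {
    detections <- data.frame(frame = integer(0), z = integer(0),
                             y = integer(0), x = integer(0),
                             dog_response = numeric(0), lambda1 = numeric(0),
                             lambda2 = numeric(0), class = character(0),
                             cell_label = integer(0))
  } else {
    detections <- detections[c("frame", "z", "y", "x", "dog_response",
                               "lambda1", "lambda2", "class", "cell_label")]
  }
  dp <- t(apply(papt, 1, trace_derivative, dt = stack$frame_interval,
                smooth_window = smooth_window))
  if (length(labs) == 1L) dp <- matrix(dp, 1L)
  traces <- data.frame(
    cell_label = rep(labs, each = nt),
    frame = rep(seq_len(nt), length(labs)),
    t_s = rep(stack$time, length(labs)),
    papt = as.vector(t(papt)),
    dpapt_dt = as.vector(t(dp)),
    mask_area_px = as.vector(t(area)))
  class(traces) <- c("papt_traces", "data.frame")
  attr(traces, "islet") <- data.frame(
    t_s = stack$time, papt = colMeans(papt),
    dpapt_dt = trace_derivative(colMeans(papt), stack$frame_interval,
                                smooth_window))
  attr(traces, "frame_interval") <- stack$frame_interval
  list(detections = detections, traces = traces)
}
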
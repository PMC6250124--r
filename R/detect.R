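# Detection of candidate endocytotic maxima: adjustable DoG band-pass,
# strict local maxima with minimum-separation suppression, and Hessian
# shape classification that discards membrane/extracellular ridges and
# coarse "bulk-uptake" structure.

#' Scale-space detection parameters
#'
#' @param sigma_small,sigma_large DoG scales in px (`0 < small < large`;
#'   defaults 1.0 / 1.6, the classic DoG ratio for diffraction-limited
#'   puncta).
#' @param k_mad response threshold in robust units: `k_mad` times the MAD of
#'   the DoG response over the first (pre-stimulus) frame.
#' @param response_floor absolute lower bound on the threshold, guarding the
#'   noise-free case where the first-frame MAD is zero.
#' @param min_separation minimum distance between reported maxima, px.
#' @param bulk_sigma coarse scale (px) probing bulk-mode (diffuse) uptake;
#'   must exceed `sigma_large`.
#' @param blobness_min minimum `lambda2 / lambda1` (eigenvalues ascending,
#'   both negative) for a maximum to count as a blob rather than a ridge.
#' @param bulk_response_ratio_max maxima whose coarse-scale DoG response
#'   exceeds this multiple of the fine-scale response are classed `bulk`.
#' @param hessian_sigma analysis scale of the Hessian (px).
#' @return list of class `papt_detect_params`.
#' @export
scale_space_params <- function(sigma_small = 1.0, sigma_large = 1.6,
                               k_mad = 5, response_floor = 1e-8,
                               min_separation = 2, bulk_sigma = 6,
                               blobness_min = 0.25,
                               bulk_response_ratio_max = 1.5,
                               hessian_sigma = sigma_large) {
  stopifnot(sigma_small > 0, sigma_large > sigma_small,
            bulk_sigma > sigma_large, min_separation >= 1,
            blobness_min >= 0, blobness_min <= 1,
            bulk_response_ratio_max > 0, k_mad > 0, response_floor >= 0)
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 k_mad = k_mad, response_floor = response_floor,
                 min_separation = min_separation, bulk_sigma = bulk_sigma,
                 blobness_min = blobness_min,
                 bulk_response_ratio_max = bulk_response_ratio_max,
                 hessian_sigma = hessian_sigma),
            class = "papt_detect_params")
}

#' Strict local maxima of a response image
#'
#' Returns strict 8-neighbour local maxima above `threshold`, then enforces
#' `min_separation` by greedy suppression: maxima are visited in order of
#' decreasing response (ties broken by lexicographically smallest (y, x))
#' and kept only if no stronger kept maximum lies closer than
#' `min_separation` (Euclidean).
#'
#' @param response numeric matrix (finite).
#' @param threshold minimum response.
#' @param min_separation suppression radius in px.
#' @return data.frame with `y`, `x` (1-based) and `response`.
#' @export
find_local_maxima <- function(response, threshold, min_separation = 1) {
  stopifnot(all(is.finite(response)))
  ny <- nrow(response); nx <- ncol(response)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- response
  ctr <- pad[2:(ny + 1L), 2:(nx + 1L)]
  is_max <- ctr > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    is_max <- is_max & (ctr > nb)
    if (!any(is_max)) break
  }
  idx <- which(is_max)
  if (length(idx) == 0) {
    return(data.frame(y = integer(0), x = integer(0), response = numeric(0)))
  }
  y <- ((idx - 1L) %% ny) + 1L
  x <- ((idx - 1L) %/% ny) + 1L
  r <- response[idx]
  o <- order(-r, y, x)
  y <- y[o]; x <- x[o]; r <- r[o]
  if (min_separation > 1 && length(y) > 1) {
    keep <- logical(length(y))
    ky <- numeric(0); kx <- numeric(0)
    for (i in seq_along(y)) {
      if (length(ky) == 0 ||
          min((ky - y[i])^2 + (kx - x[i])^2) >= min_separation^2) {
        keep[i] <- TRUE
        ky <- c(ky, y[i]); kx <- c(kx, x[i])
      }
    }
    y <- y[keep]; x <- x[keep]; r <- r[keep]
  }
  data.frame(y = y, x = x, response = r)
}

#' Classify detected maxima by Hessian shape and scale occupancy
#'
#' Implements the discard logic for membrane/extracellular maxima and for
#' bulk-mode uptake: a maximum is `extracellular` if it falls on the border
#' mask dilated by 1 px; `membrane_ridge` if any Hessian eigenvalue is
#' non-negative or the blobness `lambda2 / lambda1` falls below
#' `blobness_min`; `bulk` if the coarse-scale DoG response exceeds
#' `bulk_response_ratio_max` times the fine-scale response (the structure is
#' dominated by the coarse scale); otherwise `punctate`.
#'
#' @param eigenvalues matrix `[n, 2]`, ascending, from
#'   [hessian_eigenvalues()].
#' @param positions integer matrix `[n, 2]` of (y, x).
#' @param border_mask logical matrix of the extracellular border (or `NULL`
#'   to skip the border test).
#' @param dog_small,dog_bulk fine- and coarse-scale DoG responses at the
#'   positions (numeric vectors).
#' @param params a `papt_detect_params`.
#' @return character vector of class labels.
#' @export
classify_maximum <- function(eigenvalues, positions, border_mask,
                             dog_small, dog_bulk, params) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  n <- nrow(positions)
  cls <- rep("punctate", n)
  l1 <- eigenvalues[, 1L]; l2 <- eigenvalues[, 2L]
  ridge <- l2 >= 0 | l1 >= 0 | (l2 / l1) < params$blobness_min
  bulk <- dog_bulk / pmax(dog_small, .Machine$double.eps) >
    params$bulk_response_ratio_max & dog_bulk > 0
  cls[bulk] <- "bulk"
  cls[ridge] <- "membrane_ridge"
  if (!is.null(border_mask)) {
    bm <- dilate_mask(border_mask, 1L)
    on_border <- bm[cbind(positions[, 1L], positions[, 2L])]
    cls[on_border] <- "extracellular"
  }
  cls
}

# binary dilation by r px (diamond structuring element), pure shifts
dilate_mask <- function(mask, r = 1L) {
  out <- mask
  for (k in seq_len(r)) {
    ny <- nrow(out); nx <- ncol(out)
    d <- out
    d[-1, ] <- d[-1, ] | out[-ny, ]
    d[-ny, ] <- d[-ny, ] | out[-1, ]
    d[, -1] <- d[, -1] | out[, -nx]
    d[, -nx] <- d[, -nx] | out[, -1]
    out <- d
  }
  out
}

# robust detection threshold from the first (pre-stimulus) frame response
detection_threshold <- function(first_response, params) {
  max(params$k_mad * stats::mad(first_response), params$response_floor)
}

#' Detect and classify maxima over a whole time-lapse stack
#'
#' Per frame (and z-plane): DoG filter, strict local maxima above the
#' robust threshold (`k_mad` x MAD of the first-frame response), pointwise
#' gamma-normalised Hessian at the analysis scale, shape classification,
#' and cell assignment by lookup in `cell_label_map`. All classes are
#' retained in the output; filtering to `punctate` happens downstream.
#'
#' @param stack a [papt_stack()].
#' @param params a [scale_space_params()].
#' @param border_mask logical matrix of the extracellular border, or `NULL`.
#' @param cell_label_map integer matrix of cell labels (0 = extracellular),
#'   or `NULL` for no assignment.
#' @param channel channel index to detect on.
#' @return data.frame of detections: `frame`, `z`, `y`, `x` (1-based),
#'   `dog_response`, `lambda1`, `lambda2`, `class`, `cell_label`.
#' @export
detect_stack <- function(stack, params = scale_space_params(),
                         border_mask = NULL, cell_label_map = NULL,
                         channel = 1L) {
  stopifnot(inherits(stack, "papt_stack"))
  d <- dim(stack$data)
  spatial <- d[4:5]
  for (m in list(border_mask, cell_label_map)) {
    if (!is.null(m) && !identical(dim(m), as.integer(spatial))) {
      stop("mask shape ", paste(dim(m), collapse = "x"),
           " does not match stack spatial shape ",
           paste(spatial, collapse = "x"))
    }
  }
  out <- vector("list", d[1] * d[2])
  thr <- NULL
  for (z in seq_len(d[2])) {
    for (t in seq_len(d[1])) {
      frame <- stack$data[t, z, channel, , ]
      res <- detect_frame(frame, params, border_mask, cell_label_map, thr)
      if (is.null(thr)) thr <- attr(res, "threshold")
      if (nrow(res) > 0) {
        res$frame <- t; res$z <- z
        out[[(z - 1L) * d[1] + t]] <- res
      }
    }
    thr <- NULL  # threshold is per-plane, from that plane's first frame
  }
  dets <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(dets)) {
    dets <- data.frame(y = integer(0), x = integer(0),
                       dog_response = numeric(0), lambda1 = numeric(0),
                       lambda2 = numeric(0), class = character(0),
                       cell_label = integer(0), frame = integer(0),
                       z = integer(0))
  }
  dets[c("frame", "z", "y", "x", "dog_response", "lambda1", "lambda2",
         "class", "cell_label")]
}

# single-frame detection; returns detections plus the threshold used
detect_frame <- function(frame, params, border_mask, cell_label_map,
                         threshold = NULL, response = NULL) {
  if (is.null(response)) {
    response <- dog_filter(frame, params$sigma_small, params$sigma_large)
  }
  if (is.null(threshold)) threshold <- detection_threshold(response, params)
  mx <- find_local_maxima(response, threshold, params$min_separation)
  if (nrow(mx) == 0) {
    out <- data.frame(y = integer(0), x = integer(0),
                      dog_response = numeric(0), lambda1 = numeric(0),
                      lambda2 = numeric(0), class = character(0),
                      cell_label = integer(0))
    attr(out, "threshold") <- threshold
    return(out)
  }
  pos <- cbind(mx$y, mx$x)
  eig <- hessian_eigenvalues(frame, pos, params$hessian_sigma)
  bulk_resp <- point_dog(frame, pos, params$sigma_large, params$bulk_sigma)
  cls <- classify_maximum(eig, pos, border_mask, mx$response, bulk_resp,
                          params)
  lab <- if (is.null(cell_label_map)) 0L else cell_label_map[pos]
  out <- data.frame(y = mx$y, x = mx$x, dog_response = mx$response,
                    lambda1 = eig[, 1L], lambda2 = eig[, 2L], class = cls,
                    cell_label = as.integer(lab))
  attr(out, "threshold") <- threshold
  out
}

#' Match punctate detections against a ground-truth event table
#'
#' For every frame, punctate detections are matched one-to-one (greedily,
#' strongest response first) to true puncta already born, within
#' `radius` px. Precision is the matched fraction of all punctate
#' detections; recall is the fraction of true events matched in at least
#' one frame.
#'
#' @param detections output of [detect_stack()].
#' @param truth a `papt_truth` from [render_movie()].
#' @param radius match radius in px.
#' @return list with `precision`, `recall`, `n_true`, `n_detections`.
#' @export
evaluate_detection <- function(detections, truth, radius = 2) {
  pk <- detections[detections$class == "punctate", , drop = FALSE]
  tp <- truth$puncta
  fi <- truth$params$frame_interval_s
  if (nrow(tp) == 0) {
    return(list(precision = if (nrow(pk)) 0 else NA_real_, recall = NA_real_,
                n_true = 0L, n_detections = nrow(pk)))
  }
  matched_evt <- rep(FALSE, nrow(tp))
  n_matched_det <- 0L
  for (t in sort(unique(pk$frame))) {
    dk <- pk[pk$frame == t, , drop = FALSE]
    alive <- which(tp$birth_time_s <= (t - 1) * fi)
    used <- rep(FALSE, length(alive))
    for (i in order(-dk$dog_response)) {
      if (length(alive) == 0) break
      d2 <- (tp$y[alive] - dk$y[i])^2 + (tp$x[alive] - dk$x[i])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (length(j) && d2[j] <= radius^2) {
        used[j] <- TRUE
        matched_evt[alive[j]] <- TRUE
        n_matched_det <- n_matched_det + 1L
      }
    }
  }
  last_t <- (max(detections$frame, 1) - 1) * fi
  eligible <- tp$birth_time_s <= last_t
  list(precision = if (nrow(pk)) n_matched_det / nrow(pk) else NA_real_,
       recall = mean(matched_evt[eligible]),
       n_true = sum(eligible), n_detections = nrow(pk))
}
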
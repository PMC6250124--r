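# Tracer-guided tissue segmentation: extracellular border mask, watershed
# partition of the islet into cells, endothelial-like/non-viable flagging,
# and depth of every cell from the islet surface.

# remove connected components smaller than min_size from a logical mask
drop_small_components <- function(mask, min_size) {
  if (min_size <= 0 || !any(mask)) return(mask)
  cc <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  cc <- matrix(as.integer(cc), nrow(cc), ncol(cc))
  sizes <- tabulate(cc[cc > 0])
  ok <- cc > 0
  ok[ok] <- sizes[cc[ok]] >= min_size
  mask & ok
}

erode_binary <- function(mask, brush) {
  EBImage::erode(matrix(as.numeric(mask), nrow(mask), ncol(mask)), brush) > 0
}

# filled islet footprint: morphological closing of the tracer-bright mask,
# filled, then eroded 1 px to land on the outermost cell boundary
estimate_hull <- function(bright_mask, close_radius = 7) {
  m <- matrix(as.numeric(bright_mask), nrow(bright_mask), ncol(bright_mask))
  br <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
  closed <- EBImage::erode(EBImage::dilate(m, br), br)
  filled <- EBImage::fillHull(EBImage::bwlabel(closed)) > 0
  erode_binary(filled, EBImage::makeBrush(3L, "diamond"))
}

#' Extract the extracellular "cell borders" mask
#'
#' The polar tracer fills all extracellular space, sharply outlining each
#' cell. The reference frame (taken after wash-in) is Gaussian-smoothed and
#' thresholded at `frac` of the robust border brightness (the 0.99
#' intensity quantile), which lands near the half-maximum of the blurred
#' inter-cell clefts and keeps the mask thin; isolated components smaller
#' than `min_size` px (typically endocytotic puncta, not membrane) are
#' removed, and the 1-px rim of the islet footprint — extracellular by
#' construction — is added back, since its intensity profile falls below
#' the cleft threshold.
#'
#' @param ref_frame numeric matrix: a frame acquired after tracer wash-in.
#' @param border_sigma smoothing scale, px.
#' @param frac threshold fraction of the 0.99 intensity quantile.
#' @param hull_frac lower fraction used to estimate the islet footprint.
#' @param min_size minimum connected-component size, px.
#' @return logical matrix; attributes `"threshold"` (the cut used) and
#'   `"hull"` (the estimated islet footprint).
#' @export
extract_border_mask <- function(ref_frame, border_sigma = 1, frac = 0.85,
                                hull_frac = 0.35, min_size = 30) {
  if (max(ref_frame) <= 0 || stats::quantile(ref_frame, 0.99) <= 0) {
    stop("reference frame is dark: tracer has not washed in")
  }
  sm <- gauss_smooth(ref_frame, border_sigma)
  q_hi <- stats::quantile(sm, 0.99, names = FALSE)
  thr <- frac * q_hi
  mask <- drop_small_components(sm > thr, min_size)
  hull <- estimate_hull(sm > hull_frac * q_hi)
  ring <- hull & !erode_binary(hull, EBImage::makeBrush(3L, "diamond"))
  mask <- mask | ring
  # the extracellular net is connected and reaches the islet rim; isolated
  # bright blobs (clusters of endocytotic puncta) are not membrane
  cc <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  cc <- matrix(as.integer(cc), nrow(cc), ncol(cc))
  keep_ids <- unique(cc[ring & cc > 0])
  mask <- mask & matrix(cc %in% keep_ids, nrow(cc), ncol(cc))
  mask <- prune_blob_protrusions(mask, ref_frame, ring)
  attr(mask, "threshold") <- as.numeric(thr)
  attr(mask, "hull") <- hull
  mask
}

# Bright endocytotic puncta that touch the membrane can bridge into the
# thresholded net. They show up as blob-like (isotropic negative Hessian)
# mask pixels whose surrounding ring is mostly empty, unlike junctions of
# the net, whose arms cross the ring. Remove small disks around such cores.
prune_blob_protrusions <- function(mask, ref_frame, ring,
                                   blobness = 0.4, coverage = 0.25,
                                   sigma = 1.5) {
  idx <- which(mask & !ring, arr.ind = TRUE)
  if (nrow(idx) == 0) return(mask)
  e <- hessian_eigenvalues(ref_frame, idx, sigma)
  blob <- e[, 1] < 0 & e[, 2] < 0 & (e[, 2] / e[, 1]) > blobness
  if (!any(blob)) return(mask)
  ann <- disk_offsets(3.2)
  ann <- ann[ann$dy^2 + ann$dx^2 >= 2.5^2, ]
  ny <- nrow(mask); nx <- ncol(mask)
  cores <- idx[blob, , drop = FALSE]
  cov <- vapply(seq_len(nrow(cores)), function(i) {
    ys <- pmin(pmax(cores[i, 1] + ann$dy, 1L), ny)
    xs <- pmin(pmax(cores[i, 2] + ann$dx, 1L), nx)
    mean(mask[cbind(ys, xs)])
  }, numeric(1))
  cut <- cores[cov < coverage, , drop = FALSE]
  if (nrow(cut) == 0) return(mask)
  disk <- disk_offsets(2.5)
  ys <- pmin(pmax(rep(cut[, 1], each = nrow(disk)) + disk$dy, 1L), ny)
  xs <- pmin(pmax(rep(cut[, 2], each = nrow(disk)) + disk$dx, 1L), nx)
  mask[cbind(ys, xs)] <- FALSE
  mask
}

#' Segment the islet into individual cells
#'
#' Two-level tracer-guided segmentation: a permissive threshold
#' (`seed_frac`) yields a gap-free border net whose complement inside the
#' islet footprint gives one seed region per cell (split, where fused, by a
#' watershed on the distance transform with the given tolerance); the seeds
#' are then grown over the interior bounded by the crisp border
#' (`grow_frac` threshold) so each label recovers its full cell extent.
#' Labels outside `[min_area, max_area]` are discarded. Deterministic for
#' fixed input and parameters.
#'
#' @param ref_frame numeric matrix: post-wash-in reference frame.
#' @param border_sigma smoothing scale, px.
#' @param min_area,max_area admissible cell areas, px.
#' @param watershed_tolerance minimum catchment-basin depth (px of
#'   distance) before fused seed regions are merged.
#' @param seed_frac,grow_frac permissive / crisp threshold fractions of the
#'   0.99 intensity quantile.
#' @return integer label matrix (0 = extracellular / outside), labels
#'   `1..K`; attributes `"border_mask"` (from [extract_border_mask()]) and
#'   `"hull"`.
#' @export
segment_cells <- function(ref_frame, border_sigma = 1, min_area = 80,
                          max_area = 3000, watershed_tolerance = 2,
                          seed_frac = 0.35, grow_frac = 0.65) {
  border_mask <- extract_border_mask(ref_frame, border_sigma)
  ny <- nrow(ref_frame); nx <- ncol(ref_frame)
  sm <- gauss_smooth(ref_frame, border_sigma)
  q_hi <- stats::quantile(sm, 0.99, names = FALSE)
  fat <- drop_small_components(sm > seed_frac * q_hi, 16)
  hull <- estimate_hull(fat)
  seed_space <- hull & !fat & !border_mask
  dm <- EBImage::distmap(matrix(as.numeric(seed_space), ny, nx))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1L)
  seeds <- matrix(as.integer(ws), ny, nx)
  grow_space <- hull & !(sm > grow_frac * q_hi) & !border_mask
  lab <- EBImage::propagate(sm, seeds = seeds, mask = grow_space,
                            lambda = 1e-4)
  lab <- matrix(as.integer(lab), ny, nx)
  sizes <- tabulate(lab[lab > 0])
  bad <- which(sizes < min_area | sizes > max_area)
  if (length(bad)) lab[lab %in% bad] <- 0L
  kept <- sort(unique(lab[lab > 0]))
  if (length(kept) == 0) stop("segmentation found no cells")
  lab[] <- match(lab, kept, nomatch = 0L)
  lab[is.na(lab)] <- 0L
  storage.mode(lab) <- "integer"
  attr(lab, "border_mask") <- border_mask
  attr(lab, "hull") <- hull
  lab
}

#' Flag endothelial-like (non-viable) cells by high uniform uptake
#'
#' Cells that take up the tracer intensely and *uniformly* — vascular
#' endothelium, or non-viable cells — must be excluded from patterned-uptake
#' statistics. Over the temporal mean of `frames` (>= 3 frames after
#' wash-in), each cell's interior median intensity and spatial coefficient
#' of variation are computed. A cell is flagged when its CV is below
#' `cv_max` and its median exceeds the `q_hi` quantile of the medians of
#' the punctate-uptake (CV >= `cv_max`) cells; if every cell is uniform the
#' quantile is taken over all cells. Flags are recorded, not deleted.
#'
#' @param stack a [papt_stack()].
#' @param label_map integer cell label matrix.
#' @param frames frame indices to average (>= 3, after wash-in).
#' @param q_hi reference quantile for "high" uptake.
#' @param cv_max maximum spatial CV for "uniform" uptake.
#' @param channel channel index.
#' @return data.frame: `label`, `median_uptake`, `cv`, `endothelial_like`,
#'   `viable`.
#' @export
flag_nonviable <- function(stack, label_map, frames, q_hi = 0.95,
                           cv_max = 0.3, channel = 1L) {
  stopifnot(length(frames) >= 3)
  labs <- sort(unique(label_map[label_map > 0]))
  if (length(labs) == 0) {
    return(data.frame(label = integer(0), median_uptake = numeric(0),
                      cv = numeric(0), endothelial_like = logical(0),
                      viable = logical(0)))
  }
  d <- dim(stack$data)
  avg <- matrix(0, d[4], d[5])
  for (t in frames) avg <- avg + stack$data[t, 1, channel, , ]
  avg <- avg / length(frames)
  med <- cv <- numeric(length(labs))
  for (i in seq_along(labs)) {
    v <- avg[label_map == labs[i]]
    med[i] <- stats::median(v)
    cv[i] <- stats::sd(v) / max(mean(v), .Machine$double.eps)
  }
  uniform <- cv < cv_max
  ref <- if (any(!uniform)) med[!uniform] else med
  thr <- stats::quantile(ref, q_hi, names = FALSE)
  endo <- uniform & med > thr
  data.frame(label = labs, median_uptake = med, cv = cv,
             endothelial_like = endo, viable = !endo)
}

#' Depth of each cell from the islet surface
#'
#' Euclidean distance transform of the islet hull, evaluated at each cell
#' centroid and converted to micrometres.
#'
#' @param label_map integer cell label matrix.
#' @param hull logical islet footprint.
#' @param pixel_size pixel size, micrometres.
#' @return data.frame: `label`, `centroid_y`, `centroid_x`, `area_px`,
#'   `depth_um`.
#' @export
compute_depth <- function(label_map, hull, pixel_size) {
  stopifnot(pixel_size > 0)
  dm <- EBImage::distmap(matrix(as.numeric(hull), nrow(hull), ncol(hull)))
  labs <- sort(unique(label_map[label_map > 0]))
  out <- data.frame(label = labs, centroid_y = NA_real_,
                    centroid_x = NA_real_, area_px = NA_integer_,
                    depth_um = NA_real_)
  for (i in seq_along(labs)) {
    idx <- which(label_map == labs[i])
    ys <- ((idx - 1L) %% nrow(label_map)) + 1L
    xs <- ((idx - 1L) %/% nrow(label_map)) + 1L
    cy <- mean(ys); cx <- mean(xs)
    out$centroid_y[i] <- cy
    out$centroid_x[i] <- cx
    out$area_px[i] <- length(idx)
    out$depth_um[i] <- dm[round(cy), round(cx)] * pixel_size
  }
  out
}

#' Assemble the per-cell ROI table
#'
#' Joins segmentation, depth and viability/endothelial flags into one
#' table of cell regions of interest.
#'
#' @param label_map integer label matrix from [segment_cells()].
#' @param hull logical islet footprint.
#' @param flags data.frame from [flag_nonviable()] (or `NULL`).
#' @param pixel_size pixel size, micrometres.
#' @return data.frame: label, centroid, area, depth and flags.
#' @export
cell_rois <- function(label_map, hull, flags = NULL, pixel_size) {
  rois <- compute_depth(label_map, hull, pixel_size)
  if (!is.null(flags)) {
    rois <- merge(rois, flags[c("label", "endothelial_like", "viable")],
                  by = "label", all.x = TRUE)
  } else {
    rois$endothelial_like <- FALSE
    rois$viable <- TRUE
  }
  rois[order(rois$label), ]
}

#' Match a predicted label map against ground truth by IoU
#'
#' Greedy one-to-one matching: true cells are assigned their best-IoU
#' predicted label in decreasing IoU order.
#'
#' @param pred,truth integer label matrices (0 = background).
#' @param iou_min IoU above which a true cell counts as recovered.
#' @return list with `recovered` (fraction of true cells at
#'   `IoU >= iou_min`), `mean_iou`, `n_pred`, `n_true`, `oversegmentation`
#'   (`n_pred / n_true`) and the per-true-cell `iou` vector.
#' @export
match_segmentation <- function(pred, truth, iou_min = 0.6) {
  tl <- sort(unique(truth[truth > 0]))
  pl <- sort(unique(pred[pred > 0]))
  if (length(tl) == 0) stop("empty ground truth")
  # contingency of overlaps
  both <- truth > 0 & pred > 0
  ov <- table(factor(truth[both], levels = tl), factor(pred[both], levels = pl))
  t_area <- tabulate(truth[truth > 0], nbins = max(tl))[tl]
  p_area <- tabulate(pred[pred > 0], nbins = if (length(pl)) max(pl) else 1)[pl]
  iou_mat <- as.matrix(ov) /
    (outer(t_area, p_area, "+") - as.matrix(ov))
  best <- numeric(length(tl))
  if (length(pl)) {
    pairs <- which(iou_mat > 0, arr.ind = TRUE)
    if (nrow(pairs)) {
      o <- order(-iou_mat[pairs])
      used_t <- logical(length(tl)); used_p <- logical(length(pl))
      for (k in o) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (!used_t[i] && !used_p[j]) {
          used_t[i] <- TRUE; used_p[j] <- TRUE
          best[i] <- iou_mat[i, j]
        }
      }
    }
  }
  list(recovered = mean(best >= iou_min), mean_iou = mean(best),
       n_pred = length(pl), n_true = length(tl),
       oversegmentation = length(pl) / length(tl), iou = best)
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices.
#' @return numeric IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  sum(a & b) / max(1L, sum(a | b))
}
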
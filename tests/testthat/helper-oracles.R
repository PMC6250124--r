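# Independent brute-force oracles and small synthetic fixtures shared by
# the unit and acceptance tests. Oracles deliberately use direct
# definitional computation (dense loops), never the package's own code
# paths.

# direct dense 2-D convolution with a sampled DoG kernel, reflecting
# boundary (edge pixel repeated) - O(n^2 k^2)
oracle_dog_dense <- function(img, sigma_small, sigma_large) {
  kern1d <- function(s) {
    r <- max(1L, as.integer(ceiling(6 * s)))
    u <- seq(-r, r)
    g <- exp(-u^2 / (2 * s^2))
    g / sum(g)
  }
  ks <- kern1d(sigma_small); kl <- kern1d(sigma_large)
  pad_to <- function(k, r) {
    d <- r - (length(k) - 1L) %/% 2L
    if (d > 0) c(rep(0, d), k, rep(0, d)) else k
  }
  r <- max((length(ks) - 1L) %/% 2L, (length(kl) - 1L) %/% 2L)
  ks <- pad_to(ks, r); kl <- pad_to(kl, r)
  k2d <- outer(ks, ks) - outer(kl, kl)
  ny <- nrow(img); nx <- ncol(img)
  refl <- function(i, n) {
    m <- (i - 1L) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r) {
      acc <- acc + img[refl(y + dy, ny), refl(x + dx, nx)] *
        k2d[dy + r + 1L, dx + r + 1L]
    }
    out[y, x] <- acc
  }
  out
}

# definitional O(n^2) distance correlation (double loops, no matrix tricks)
oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j])
    b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx == 0 || dvy == 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# exhaustive strict-local-maximum scan (no suppression logic)
oracle_local_maxima <- function(img, threshold) {
  ny <- nrow(img); nx <- ncol(img)
  hits <- NULL
  for (y in 1:ny) for (x in 1:nx) {
    v <- img[y, x]
    if (v <= threshold) next
    ok <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx && img[yy, xx] >= v) {
        ok <- FALSE
      }
    }
    if (ok) hits <- rbind(hits, c(y, x))
  }
  hits
}

# analytic isotropic Gaussian blob / straight ridge images
blob_image <- function(n = 81, A = 2, s = 2) {
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  A * exp(-((yy - c0)^2 + (xx - c0)^2) / (2 * s^2))
}

ridge_image <- function(n = 81, A = 2, s = 2, angle_deg = 0) {
  c0 <- (n + 1) / 2
  th <- angle_deg * pi / 180
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  u <- (yy - c0) * cos(th) + (xx - c0) * sin(th)
  A * exp(-u^2 / (2 * s^2))
}

# small default-condition movie, cached across tests within a run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- generate_islet_geometry(16, 256, seed = 21)
      rates <- simulate_rates(default_protocol(), geom$cell_types, seed = 21)
      cache <<- c(render_movie(geom, rates, n_frames = 40, seed = 21),
                  list(geom = geom, rates = rates))
    }
    cache
  }
})

# Per-seed rate-recovery and latency metrics over the 20 default-condition
# movies (seeds 0-19); computed once and cached for the blocks that use it.
default_movie_metrics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- lapply(0:19, function(s) {
        geom <- generate_islet_geometry(64, 512, seed = s)
        rates <- simulate_rates(default_protocol(), geom$cell_types, seed = s)
        sim <- render_movie(geom, rates, n_frames = 80, seed = s)
        ana <- papt_analyze(sim$stack, scale_space_params(),
                            sim$truth$label_map,
                            border_mask = sim$truth$border_mask)
        tr <- ana$traces
        stim <- tr$frame %in% 42:80
        est <- tapply(tr$dpapt_dt[stim], tr$cell_label[stim], mean)
        rho <- cor(est, rates$lambda[as.integer(names(est)), 3],
                   method = "spearman")
        isl <- attr(tr, "islet")
        # programmed step at t = 1200 s = frame 41 (1-based)
        list(rho = rho, latency = which.max(isl$dpapt_dt) - 41L)
      })
      cache <<- list(rho = vapply(res, `[[`, numeric(1), "rho"),
                     latency = vapply(res, `[[`, numeric(1), "latency"))
    }
    cache
  }
})

# the detection benchmark movie: 64 cells, ~200 puncta expected over
# 50 frames, punctum peak-to-noise ~5
detection_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- generate_islet_geometry(64, 512, seed = 101)
      prot <- stimulus_protocol(0, 1500, "tracer on", 1)
      rates <- simulate_rates(prot, geom$cell_types,
                              baseline_rate = 2.53e-3,
                              heterogeneity_cv = 0, seed = 101)
      cache <<- render_movie(geom, rates, n_frames = 50, seed = 101)
    }
    cache
  }
})
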
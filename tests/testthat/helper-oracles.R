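# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

oracle_median3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    vals <- numeric(0)
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), H)
      jj <- min(max(j + dj, 1), W)
      vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- sort(vals)[5]
  }
  out
}

oracle_binom3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  K <- outer(c(1, 2, 1) / 4, c(1, 2, 1) / 4)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), H)
      jj <- min(max(j + dj, 1), W)
      acc <- acc + K[di + 2, dj + 2] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

oracle_gradmag <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in 2:(H - 1)) for (j in 2:(W - 1)) {
    gx <- (m[i, j + 1] - m[i, j - 1]) / 2
    gy <- (m[i + 1, j] - m[i - 1, j]) / 2
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

oracle_sharpness_sum <- function(m) sum(oracle_gradmag(oracle_binom3(m)))

# even-odd point-in-polygon by ray casting, scalar per point
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(poly, shape) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    out[i, j] <- oracle_point_in_polygon(j - 0.5, i - 0.5, poly)
  }
  out
}

# random convex polygon (convex implies simple)
random_convex_polygon <- function(shape, n = 8) {
  H <- shape[1]; W <- shape[2]
  cx <- runif(1, 0.3 * W, 0.7 * W)
  cy <- runif(1, 0.3 * H, 0.7 * H)
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, 0.1, 0.28) * min(H, W)
  cbind(pmin(pmax(cx + rad * cos(ang), 0), W),
        pmin(pmax(cy + rad * sin(ang), 0), H))
}

rand_angio <- function(H = 16, W = 16, plexus = "DCP") {
  intensity_image(matrix(runif(H * W), H, W), kind = "enface_angiogram",
                  plexus = plexus)
}

simple_roi <- function(H = 16, W = 16) {
  roi_set(vessel = rbind(c(1, 1), c(6, 1), c(6, 6), c(1, 6)),
          background = list(rbind(c(9, 9), c(14, 9), c(14, 14), c(9, 14))),
          image_shape = c(H, W))
}

# small repeated-measures table
rm_table <- function(n = 4, k = 3, fun = function(a, e, w) rnorm(1)) {
  d <- tidyr::expand_grid(animal_id = paste0("a", seq_len(n)),
                          eye = c("OD", "OS"),
                          week = seq(3, by = 3, length.out = k))
  d$value <- mapply(fun, d$animal_id, d$eye, d$week)
  d
}
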
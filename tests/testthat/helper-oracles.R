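# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's C++ kernels: plain R, exhaustive computation.

# exhaustive nearest-fibre assignment (lowest index wins ties)
bf_nearest_map <- function(lattice, grid_shape) {
  out <- matrix(NA_integer_, grid_shape[1], grid_shape[2])
  pos <- lattice$positions
  for (r in seq_len(grid_shape[1])) {
    for (c in seq_len(grid_shape[2])) {
      if ((r - lattice$fov_center[1])^2 + (c - lattice$fov_center[2])^2 >
          lattice$fov_radius^2) next
      d <- (pos[, 1] - r)^2 + (pos[, 2] - c)^2
      out[r, c] <- which(d == min(d))[1]
    }
  }
  out
}

# circumcircle of a triangle given 3x2 coordinates
circumcircle <- function(p) {
  a <- p[1, ]; b <- p[2, ]; c <- p[3, ]
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
         (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
  uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
         (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
  list(center = c(ux, uy), radius = sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

# TRUE iff every simplex's circumcircle is empty of all other fibres
bf_delaunay_ok <- function(positions, simplices, tol = 1e-9) {
  for (t in seq_len(nrow(simplices))) {
    v <- simplices[t, ]
    cc <- circumcircle(positions[v, , drop = FALSE])
    d <- sqrt((positions[, 1] - cc$center[1])^2 + (positions[, 2] - cc$center[2])^2)
    others <- setdiff(seq_len(nrow(positions)), v)
    if (any(d[others] < cc$radius - tol * max(1, cc$radius))) return(FALSE)
  }
  TRUE
}

# point-in-triangle barycentric solve over all simplices; returns the
# interpolated value or NA if outside the hull
bf_interp_at <- function(positions, simplices, values, p, tol = 1e-9) {
  for (t in seq_len(nrow(simplices))) {
    v <- simplices[t, ]
    A <- rbind(t(positions[v, , drop = FALSE]), rep(1, 3))
    lam <- tryCatch(solve(A, c(p, 1)), error = function(e) NULL)
    if (is.null(lam)) next
    if (all(lam >= -tol)) return(sum(lam * values[v]))
  }
  NA_real_
}

# exhaustive k-nearest-pixel mean (ties by lower row-major pixel index)
bf_knn_mean <- function(positions, img, k) {
  nr <- nrow(img); nc <- ncol(img)
  grid <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  rowmajor <- (grid$r - 1) * nc + (grid$c - 1)
  vapply(seq_len(nrow(positions)), function(i) {
    d2 <- (grid$r - positions[i, 1])^2 + (grid$c - positions[i, 2])^2
    ord <- order(d2, rowmajor)
    mean(img[cbind(grid$r[ord[1:k]], grid$c[ord[1:k]])])
  }, 0)
}

# textbook paired t-test
bf_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# direct (unvectorized) windowed SSIM with Gaussian weights, valid windows
bf_ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                    data_range = 1) {
  r <- (window - 1L) / 2L
  x <- seq_len(window) - (window + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  w <- outer(k, k)
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  vals <- c()
  for (i in seq.int(r + 1L, nrow(a) - r)) {
    for (j in seq.int(r + 1L, ncol(a) - r)) {
      wa <- a[(i - r):(i + r), (j - r):(j + r)]
      wb <- b[(i - r):(i + r), (j - r):(j + r)]
      mx <- sum(w * wa); my <- sum(w * wb)
      vx <- sum(w * wa^2) - mx^2; vy <- sum(w * wb^2) - my^2
      vxy <- sum(w * wa * wb) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                      ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# small deterministic random lattice fully inside the FoV disc
random_lattice <- function(n, fov_radius, seed, fov_center = c(fov_radius + 1, fov_radius + 1)) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rad <- fov_radius * 0.98 * sqrt(runif(n))
  fibre_lattice(cbind(fov_center[1] + rad * cos(th), fov_center[2] + rad * sin(th)),
                fov_center, fov_radius, seed = seed)
}
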
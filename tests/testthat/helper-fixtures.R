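# Shared fixtures and independent oracles, all built in code at test time.

water_disk <- function(n = 128, spacing = 0.25, radius = 8, offset = c(0, 0)) {
  make_elliptical_phantom(n, spacing, body_axes = c(radius, radius),
                          body_material = "water", body_center = offset)
}

fan_geometry <- function(n_cols = 220, pitch = 0.375, offset = 0,
                         angles = 0:359, sad = 100, sdd = 150) {
  scan_geometry(sad, sdd, n_cols = n_cols, pitch = pitch,
                lateral_offset = offset, angles = angles)
}

central_mask <- function(n, frac = 0.25) {
  roi_mask(roi_spec("central", "ellipse", c((n + 1) / 2, (n + 1) / 2),
                    rep(max(n * frac, 2), 2)), c(n, n))
}

# Independent dense-sampling oracle for line integrals: midpoint sampling at a
# step far below the voxel size, nearest-voxel lookup.
dense_line_integral <- function(map, p1, p2, step_frac = 1 / 400) {
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  n <- ceiling(L / (min(map$spacing) * step_frac))
  t <- (seq_len(n) - 0.5) / n
  pts <- cbind(p1[1] + t * d[1], p1[2] + t * d[2], p1[3] + t * d[3])
  lo <- map$origin - map$spacing / 2
  idx <- floor(sweep(sweep(pts, 2, lo, `-`), 2, map$spacing, `/`)) + 1
  dm <- dim(map$values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
    idx[, 2] >= 1 & idx[, 2] <= dm[2] &
    idx[, 3] >= 1 & idx[, 3] <= dm[3]
  v <- numeric(n)
  if (any(inside))
    v[inside] <- map$values[idx[inside, , drop = FALSE]]
  sum(v) * L / n
}

# Analytic chord length of a segment p1 -> p2 inside the map's bounding box.
box_chord <- function(map, p1, p2) {
  d <- p2 - p1
  lo <- map$origin - map$spacing / 2
  hi <- lo + dim(map$values) * map$spacing
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (p1[ax] < lo[ax] || p1[ax] >= hi[ax]) return(0)
    } else {
      a <- (lo[ax] - p1[ax]) / d[ax]
      b <- (hi[ax] - p1[ax]) / d[ax]
      t0 <- max(t0, min(a, b)); t1 <- min(t1, max(a, b))
    }
  }
  max(t1 - t0, 0) * sqrt(sum(d^2))
}

# random rays guaranteed to pass near the grid
random_rays <- function(n, reach = 12, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    o <- runif(3, -1.5, 1.5)
    list(p1 = o - reach * d, p2 = o + reach * d)
  })
}

# Brute-force constrained minimizer of total quanta at fixed variance
# (independent of the closed-form allocation): eliminate the last view via
# the constraint and run Nelder-Mead on the logs of the rest.
oracle_min_total <- function(A, s2) {
  P <- length(A)
  if (P == 1) return(A[1] / s2)
  obj <- function(logN) {
    N <- exp(logN)
    rest <- s2 - sum(A[-P] / N)
    if (rest <= 0) return(1e300)
    sum(N) + A[P] / rest
  }
  if (P == 2) {
    lo <- log(A[1] / s2 * (1 + 1e-9))
    hi <- log(1e4 * sum(A) / s2)
    return(optimize(obj, c(lo, hi), tol = 1e-12)$objective)
  }
  start <- log(2 * P * A[-P] / s2)
  best <- Inf
  for (sc in c(1, 0.7, 1.4)) {
    res <- optim(start + log(sc), obj, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-15))
    best <- min(best, res$value)
  }
  best
}

# scikit-image SSIM as the independent cross-implementation oracle
skimage_ssim <- function(x, y, data_range) {
  xd <- tempfile(fileext = ".csv"); yd <- tempfile(fileext = ".csv")
  on.exit(unlink(c(xd, yd)))
  write.table(x, xd, row.names = FALSE, col.names = FALSE, sep = ",")
  write.table(y, yd, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage.metrics import structural_similarity as ss\n",
    "x = np.loadtxt('%s', delimiter=','); y = np.loadtxt('%s', delimiter=',')\n",
    "print('%%.17g' %% float(ss(x, y, gaussian_weights=True, sigma=1.5, ",
    "use_sample_covariance=False, data_range=%.17g)))"), xd, yd, data_range)
  out <- system2("python", "-", input = code, stdout = TRUE)
  as.numeric(out[length(out)])
}

# nibabel as the independent NIfTI reference reader
nibabel_read <- function(path) {
  code <- sprintf(paste0(
    "import nibabel, numpy as np\n",
    "img = nibabel.load('%s')\n",
    "d = np.asanyarray(img.dataobj)\n",
    "np.savetxt('%s.out', d.reshape(-1, order='F')[:50])\n",
    "print(','.join(str(v) for v in img.header.get_zooms()))\n",
    "print(','.join(str(v) for v in d.shape))"), path, path)
  out <- system2("python", "-", input = code, stdout = TRUE)
  list(first50 = scan(paste0(path, ".out"), quiet = TRUE),
       zooms = as.numeric(strsplit(out[length(out) - 1], ",")[[1]]),
       shape = as.numeric(strsplit(out[length(out)], ",")[[1]]))
}
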
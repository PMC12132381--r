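# Internal geometry and array helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# 2x2 in-plane rotation matrix, angle in degrees (counter-clockwise).
rot2 <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# Deterministic orthonormal in-plane basis (u, v) perpendicular to `axis`,
# so that for a z-aligned axis u = x and v = y.
plane_basis <- function(axis) {
  a <- unit_vec(axis)
  e <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit_vec(e - sum(e * a) * a)
  v <- cross3(a, u)
  list(u = u, v = v, axis = a)
}

# Angle a-b-c at vertex b, degrees.
angle_deg <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  rad2deg(acos(max(-1, min(1, cosang))))
}

# Dihedral angle p1-p2-p3-p4 in degrees, signed, in (-180, 180], IUPAC
# sign convention (agrees with bio3d::torsion.xyz).
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -rad2deg(atan2(y, x))
}

# Physical coordinates (Angstrom) of voxel centers for linear indices into
# a grid. Voxel (1,1,1) sits at `origin` (voxel-center convention).
voxel_coords <- function(idx, dims, voxel_size, origin) {
  i <- (idx - 1L) %% dims[1]
  j <- ((idx - 1L) %/% dims[1]) %% dims[2]
  k <- (idx - 1L) %/% (dims[1] * dims[2])
  cbind(origin[1] + i * voxel_size[1],
        origin[2] + j * voxel_size[2],
        origin[3] + k * voxel_size[3])
}

# 26-connectivity half-neighbourhood offsets (13 of the 26, one per
# unordered pair direction).
.offsets26 <- local({
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  keep <- off$dz > 0 | (off$dz == 0 & off$dy > 0) |
    (off$dz == 0 & off$dy == 0 & off$dx > 0)
  as.matrix(off[keep, ])
})

# Label connected components of a 3D logical array (26-connectivity).
# Returns an integer array: 0 outside the mask, component id inside.
label_components <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dims)
  n <- length(idx)
  if (n == 0L) return(lab)
  pos <- integer(prod(dims))
  pos[idx] <- seq_len(n)
  edges <- vector("list", nrow(.offsets26))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  for (r in seq_len(nrow(.offsets26))) {
    o <- .offsets26[r, ]
    xr <- if (o[1] >= 0) seq_len(nx - o[1]) else seq(1 - o[1], nx)
    yr <- if (o[2] >= 0) seq_len(ny - o[2]) else seq(1 - o[2], ny)
    zr <- if (o[3] >= 0) seq_len(nz - o[3]) else seq(1 - o[3], nz)
    a <- mask[xr, yr, zr, drop = FALSE]
    b <- mask[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
    both <- which(a & b)
    if (length(both) == 0L) next
    sub <- dim(a)
    i <- (both - 1L) %% sub[1]
    j <- ((both - 1L) %/% sub[1]) %% sub[2]
    k <- (both - 1L) %/% (sub[1] * sub[2])
    lin1 <- (xr[1] + i) + (yr[1] + j - 1L) * nx + (zr[1] + k - 1L) * nx * ny
    lin2 <- lin1 + o[1] + o[2] * nx + o[3] * nx * ny
    edges[[r]] <- cbind(pos[lin1], pos[lin2])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# 2D variant (8-connectivity) for cross-section images.
label_components_2d <- function(mask) {
  m3 <- array(mask, c(dim(mask), 1L))
  lab <- label_components(m3)
  array(lab, dim(mask))
}

# Bin scalar values along a 1D coordinate into a regular profile using a
# triangular deposition kernel of half-width `kernel_hw`. A kernel at
# least as wide as the sample spacing (e.g. the voxel size) fills the
# gaps of a sub-sample bin width, avoiding lattice-comb artefacts in
# downstream autocorrelation.
bin_profile <- function(t, values, h, kernel_hw = h) {
  t0 <- min(t) - kernel_hw
  nb <- ceiling((max(t) + kernel_hw - t0) / h) + 1L
  full <- numeric(nb)
  base <- (t - t0) / h
  K <- ceiling(kernel_hw / h)
  for (o in (-K):(K + 1L)) {
    bi <- floor(base) + o + 1L
    ok <- bi >= 1L & bi <= nb
    if (!any(ok)) next
    ctr <- (bi - 1L) * h + t0
    w <- pmax(0, 1 - abs(t - ctr) / kernel_hw)
    sel <- ok & w > 0
    if (!any(sel)) next
    acc <- rowsum((values * w)[sel], bi[sel])
    full[as.integer(rownames(acc))] <- full[as.integer(rownames(acc))] +
      acc
  }
  list(profile = full, t0 = t0, h = h)
}

# Dominant periodicity of a profile: power spectrum of the demeaned,
# Hann-tapered profile evaluated on a fine frequency grid spanning the
# search window, peak = interior maximum. Sharpness is the fraction of
# the tapered profile's power concentrated at the peak frequency;
# profiles without axial structure (e.g. a uniform rod) fall below the
# prominence threshold and give an indeterminate (NA) repeat.
profile_periodicity <- function(profile, h, window = c(3, 7),
                                prominence = 0.1) {
  p <- profile - mean(profile)
  n <- length(p)
  if (n < 8L || stats::var(p) < 1e-14) {
    return(list(repeat_A = NA_real_, sharpness = NA_real_, window = window))
  }
  j <- seq_len(n)
  w <- 0.5 * (1 - cos(2 * pi * (j - 1) / (n - 1)))
  pw <- p * w
  pw <- pw - mean(pw)
  t <- (j - 1) * h
  span <- n * h
  if (span < 2 * window[1]) {
    return(list(repeat_A = NA_real_, sharpness = NA_real_, window = window))
  }
  fs <- seq(1 / window[2], 1 / window[1], by = min(1e-3, 1 / (40 * span)))
  ang <- outer(t, 2 * pi * fs)
  P <- (as.vector(crossprod(pw, cos(ang))))^2 +
    (as.vector(crossprod(pw, sin(ang))))^2
  inner <- 2:(length(fs) - 1)
  peaks <- inner[P[inner] >= P[inner - 1] & P[inner] >= P[inner + 1]]
  if (length(peaks) == 0L) {
    return(list(repeat_A = NA_real_, sharpness = 0, window = window))
  }
  best <- peaks[which.max(P[peaks])]
  # share of the profile's power at the peak (1 for a pure cosine)
  share <- P[best] / max(sum(pw^2) * n / 2, 1e-300)
  if (!is.finite(share) || share < prominence) {
    return(list(repeat_A = NA_real_, sharpness = share, window = window))
  }
  list(repeat_A = 1 / fs[best], sharpness = share, window = window)
}

# Bilinear sampling of a matrix at fractional (row, col) positions;
# returns NA outside the grid.
bilinear_sample <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  if (!any(ok)) return(out)
  r <- ri[ok]; c <- ci[ok]
  r0 <- pmin(pmax(floor(r), 1), nr - 1)
  c0 <- pmin(pmax(floor(c), 1), nc - 1)
  fr <- r - r0
  fc <- c - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]
  v11 <- img[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

# Rotate an image about a center (row, col) by theta degrees; bilinear.
rotate_image <- function(img, theta_deg, center) {
  nr <- nrow(img); nc <- ncol(img)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  t <- deg2rad(theta_deg)
  dr <- g$r - center[1]
  dc <- g$c - center[2]
  # sample source position = inverse rotation of target position
  sr <- center[1] + cos(t) * dr + sin(t) * dc
  sc <- center[2] - sin(t) * dr + cos(t) * dc
  matrix(bilinear_sample(img, sr, sc), nr, nc)
}

# Normalized cross-correlation over jointly finite pixels.
ncc_images <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) return(NA_real_)
  x <- a[ok]; y <- b[ok]
  if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14) return(NA_real_)
  stats::cor(x, y)
}

# Density-weighted centroid and covariance of a set of points.
weighted_moments <- function(coords, w) {
  w <- w / sum(w)
  ctr <- colSums(coords * w)
  d <- sweep(coords, 2, ctr)
  cov <- crossprod(d * sqrt(w))
  list(center = ctr, cov = cov)
}
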
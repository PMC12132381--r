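#' Construct a fibril frame
#'
#' The helical frame of a fibril: a unit axis direction, a point on the
#' axis, the rise (Angstrom of axial translation per protein rung) and the
#' twist (degrees of rotation per rung; `NA` when unknown). Amyloid
#' fibrils stack misfolded protein molecules at a near-universal rise of
#' about 4.8 Angstrom with a small twist.
#'
#' @param axis_direction unit 3-vector.
#' @param axis_point 3-vector, a point on the axis (Angstrom).
#' @param rise Angstrom per rung, positive.
#' @param twist degrees per rung, `NA` when not estimated.
#' @return An object of class `fibril_frame`.
#' @export
fibril_frame <- function(axis_direction, axis_point = c(0, 0, 0),
                         rise = 4.8, twist = NA_real_) {
  if (abs(vec_norm(axis_direction) - 1) > 1e-6) {
    stop("axis_direction must be a unit vector")
  }
  if (!is.finite(rise) || rise <= 0) stop("rise must be positive")
  structure(list(axis_direction = as.numeric(axis_direction),
                 axis_point = as.numeric(axis_point),
                 rise = as.numeric(rise), twist = as.numeric(twist)),
            class = "fibril_frame")
}

#' @export
print.fibril_frame <- function(x, ...) {
  cat(sprintf(
    "fibril_frame: axis (%.3f, %.3f, %.3f), rise %.3f A, twist %s deg/rung\n",
    x$axis_direction[1], x$axis_direction[2], x$axis_direction[3], x$rise,
    if (is.finite(x$twist)) sprintf("%.2f", x$twist) else "unknown"))
  invisible(x)
}

#' Estimate the helical frame of a fibril map
#'
#' The fibril axis is taken as the principal axis of the voxel cloud above
#' the contour level; the rise is the dominant peak of the axial
#' autocorrelation of the density profile, searched within `window`
#' (default 3-7 Angstrom, bracketing the universal ~4.8 Angstrom
#' stacking); the twist is estimated from the in-plane rotation between
#' cross-sections of the two ends of the fibril and may be `NA` when the
#' rotation search is inconclusive.
#'
#' @param map a [density_map()].
#' @param level contour level; defaults to the map's recommended level
#'   (or [fallback_level()]).
#' @param window numeric length-2 rise search window in Angstrom.
#' @param min_axis_ratio minimum ratio of first to second principal
#'   eigenvalue below which the cloud is considered isotropic (error).
#' @param estimate_twist logical; skip the (slower) twist search if FALSE.
#' @return A [fibril_frame()]; its `rise` may be `NA` if no axial
#'   periodicity is found.
#' @export
estimate_fibril_frame <- function(map, level = NULL, window = c(3, 7),
                                  min_axis_ratio = 1.5,
                                  estimate_twist = TRUE) {
  stopifnot(inherits(map, "density_map"))
  level <- map_level(map, level)
  idx <- which(map$grid >= level)
  if (length(idx) < 100L) {
    stop("fewer than 100 voxels above the contour level")
  }
  coords <- map_voxel_coords(map, idx)
  vals <- map$grid[idx]
  mom <- weighted_moments(coords, vals)
  eig <- eigen(mom$cov, symmetric = TRUE)
  if (eig$values[1] < min_axis_ratio * eig$values[2]) {
    stop("degenerate axis: density cloud is not elongated (eigenvalue ",
         sprintf("ratio %.2f < %.2f)", eig$values[1] / eig$values[2],
                 min_axis_ratio))
  }
  axis <- eig$vectors[, 1]
  # sign convention: largest-magnitude component positive
  axis <- axis * sign(axis[which.max(abs(axis))])
  t <- as.vector(coords %*% axis)
  h <- min(map$voxel_size) / 4
  prof <- bin_profile(t, vals, h, kernel_hw = min(map$voxel_size))
  per <- profile_periodicity(prof$profile, h, window = window)
  twist <- NA_real_
  if (estimate_twist && is.finite(per$repeat_A)) {
    twist <- .estimate_twist(coords, vals, axis, mom$center, per$repeat_A)
  }
  fr <- fibril_frame(axis, mom$center,
                     rise = if (is.finite(per$repeat_A)) per$repeat_A else 1,
                     twist = twist)
  fr$rise <- per$repeat_A
  fr$rise_sharpness <- per$sharpness
  fr$level <- level
  fr
}

# Twist from the best-aligning in-plane rotation between the two axial
# end-quarters of the above-level cloud, divided by the rung count between
# their centers.
.estimate_twist <- function(coords, vals, axis, center, rise,
                            angle_step = 0.5, max_total = 60) {
  b <- plane_basis(axis)
  d <- sweep(coords, 2, center)
  t <- as.vector(d %*% b$axis)
  u <- as.vector(d %*% b$u)
  v <- as.vector(d %*% b$v)
  tr <- range(t)
  span <- diff(tr)
  if (span < 4 * rise) return(NA_real_)
  q <- span / 4
  lo <- t <= tr[1] + q
  hi <- t >= tr[2] - q
  img_lo <- .bin_image(u[lo], v[lo], vals[lo])
  img_hi <- .bin_image(u[hi], v[hi], vals[hi], like = img_lo)
  dt <- mean(t[hi]) - mean(t[lo])
  n_rungs <- dt / rise
  angles <- seq(-max_total, max_total, by = angle_step)
  ctr_lo <- .image_centroid(img_lo)
  ctr_hi <- .image_centroid(img_hi)
  sc <- vapply(angles, function(th) {
    rot <- rotate_image(img_hi, th, ctr_hi)
    ncc_images(.recenter_image(img_lo, ctr_lo), .recenter_image(rot, ctr_hi))
  }, numeric(1))
  if (all(!is.finite(sc))) return(NA_real_)
  k <- which.max(sc)
  if (sc[k] < 0.5) return(NA_real_)
  best <- angles[k]
  if (k > 1 && k < length(angles)) {
    y1 <- sc[k - 1]; y2 <- sc[k]; y3 <- sc[k + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > 1e-12) {
      best <- best + angle_step * max(-1, min(1, 0.5 * (y1 - y3) / den))
    }
  }
  # aligning the later slab back onto the earlier one undoes the
  # accumulated twist, so the recovered angle is minus the total twist
  -best / n_rungs
}

# Bin scattered in-plane points into a regular image (1 A pixels). When
# `like` is given, reuse its pixel frame so two images are comparable.
.bin_image <- function(u, v, w, px = 1, like = NULL) {
  if (is.null(like)) {
    u0 <- min(u) - px; v0 <- min(v) - px
    nu <- ceiling((max(u) - u0) / px) + 2L
    nv <- ceiling((max(v) - v0) / px) + 2L
  } else {
    u0 <- attr(like, "u0"); v0 <- attr(like, "v0")
    px <- attr(like, "px")
    nu <- nrow(like); nv <- ncol(like)
  }
  iu <- pmin(pmax(floor((u - u0) / px) + 1L, 1L), nu)
  iv <- pmin(pmax(floor((v - v0) / px) + 1L, 1L), nv)
  img <- matrix(0, nu, nv)
  acc <- rowsum(w, (iv - 1L) * nu + iu)
  img[as.integer(rownames(acc))] <- acc
  attr(img, "u0") <- u0; attr(img, "v0") <- v0; attr(img, "px") <- px
  img
}

.image_centroid <- function(img) {
  w <- pmax(img, 0)
  s <- sum(w)
  if (s <= 0) return(c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2))
  r <- sum(row(img) * w) / s
  c <- sum(col(img) * w) / s
  c(r, c)
}

# Shift an image so its centroid sits at the matrix center (bilinear).
.recenter_image <- function(img, centroid) {
  target <- c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
  dr <- centroid[1] - target[1]
  dc <- centroid[2] - target[2]
  g <- expand.grid(r = seq_len(nrow(img)), c = seq_len(ncol(img)))
  matrix(bilinear_sample(img, g$r + dr, g$c + dc), nrow(img), ncol(img))
}
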
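#' Grade the occupancy strength of an extra density
#'
#' Strength reflects the occupancy of the extra component relative to the
#' protein and is graded against a contour ladder: `s` (strong) when a
#' single connected component spans the region's axial extent at the
#' display (authors') level; `m` (moderate) when not strong but a single
#' spanning component exists at two or more consecutive ladder levels;
#' `w` (weak) when the density is discontinuous at every ladder level but
#' resolves into bead-like per-rung units of substantially uniform size:
#' density present opposite at least 80% of spanned rungs, with the
#' per-rung volumes varying by a coefficient of variation below 0.5;
#' `none` otherwise (dust-like or absent).
#'
#' @param region an `ed_region` from [extract_extra_density()].
#' @param ladder a [make_contour_ladder()] result.
#' @param frame a [fibril_frame()] (supplies rise for rung assignment).
#' @param span_frac fraction of the region's axial extent a component
#'   must cover to count as spanning.
#' @param uniform_frac minimum fraction of rungs with density opposite
#'   them for the weak grade.
#' @param max_cv maximum coefficient of variation of unit volumes for the
#'   weak grade.
#' @return An object of class `strength_grade` with fields `grade`,
#'   `evidence` (per-level component counts and spanning flags) and
#'   `uniformity`.
#' @export
grade_strength <- function(region, ladder, frame, span_frac = 0.9,
                           uniform_frac = 0.8, max_cv = 0.5) {
  stopifnot(inherits(region, "ed_region"),
            inherits(ladder, "contour_ladder"),
            inherits(frame, "fibril_frame"))
  sub <- .region_subvolume(region, pad = 3L)
  axis <- plane_basis(if (is.null(region$frame)) frame$axis_direction
                      else region$frame$axis_direction)$axis
  t_all <- as.vector(sub$coords %*% axis)
  t_region <- as.vector(sub$coords[sub$in_region, , drop = FALSE] %*% axis)
  extent <- diff(range(t_region))
  rise <- frame$rise
  if (!is.finite(rise) || rise <= 0) rise <- 4.8
  n_rungs <- round(extent / rise) + 1L
  levels <- ladder$levels
  spanning <- logical(length(levels))
  n_comp <- integer(length(levels))
  unit_stats <- NULL
  for (li in seq_along(levels)) {
    m <- array(FALSE, sub$dims)
    m[sub$box_idx_local[sub$vals >= levels[li]]] <- TRUE
    if (!any(m)) next
    lab <- label_components(m)
    ids <- which(lab > 0)
    n_comp[li] <- max(lab)
    tt <- t_all[match(ids, sub$box_idx_local)]
    comp <- lab[ids]
    spans <- tapply(tt, comp, function(z) diff(range(z)))
    spanning[li] <- any(spans >= span_frac * extent)
    if (li == ladder$authors_index) {
      vols <- as.vector(table(comp))
      tz <- as.vector(tapply(tt, comp, mean))
      rung <- round((tz - min(t_region)) / rise)
      cnt <- tabulate(rung + 1L, nbins = n_rungs)
      rung_vol <- vapply(seq_len(n_rungs) - 1L, function(rr) {
        sum(vols[rung == rr])
      }, numeric(1))
      unit_stats <- list(
        n_units = length(vols),
        rung_coverage = mean(rung_vol > 0),
        cv = if (n_rungs > 1 && mean(rung_vol) > 0) {
          stats::sd(rung_vol) / mean(rung_vol)
        } else 0)
    }
  }
  evidence <- data.frame(level = levels, n_components = n_comp,
                         spanning = spanning)
  grade <- "none"
  if (spanning[ladder$authors_index]) {
    grade <- "s"
  } else if (any(spanning[-length(spanning)] & spanning[-1])) {
    grade <- "m"
  } else if (!is.null(unit_stats) && unit_stats$n_units > 0 &&
             unit_stats$rung_coverage >= uniform_frac &&
             unit_stats$cv < max_cv) {
    # not continuous at the display level nor at two consecutive ladder
    # levels, but resolves into uniform bead-like units: weak
    grade <- "w"
  }
  structure(list(grade = grade, evidence = evidence,
                 uniformity = unit_stats, n_rungs = n_rungs),
            class = "strength_grade")
}

#' @export
print.strength_grade <- function(x, ...) {
  cat("strength_grade:", x$grade, "\n")
  print(x$evidence, row.names = FALSE)
  invisible(x)
}

# Crop a padded bounding box of the region out of the residual grid.
# Returns local dims, local linear indices of above-nothing voxels, their
# values, world coordinates and an in-region flag.
.region_subvolume <- function(region, pad = 3L) {
  dims <- dim(region$map$grid)
  idx <- which(region$mask)
  i <- (idx - 1L) %% dims[1]
  j <- ((idx - 1L) %/% dims[1]) %% dims[2]
  k <- (idx - 1L) %/% (dims[1] * dims[2])
  lo <- pmax(c(min(i), min(j), min(k)) - pad + 1L, 1L)
  hi <- pmin(c(max(i), max(j), max(k)) + pad + 1L, dims)
  box <- region$residual[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  bdims <- dim(box)
  loc <- seq_along(box)
  li <- (loc - 1L) %% bdims[1]
  lj <- ((loc - 1L) %/% bdims[1]) %% bdims[2]
  lk <- (loc - 1L) %/% (bdims[1] * bdims[2])
  gi <- li + lo[1]; gj <- lj + lo[2]; gk <- lk + lo[3]
  glob <- gi + (gj - 1L) * dims[1] + (gk - 1L) * dims[1] * dims[2]
  coords <- cbind(region$map$origin[1] + (gi - 1L) * region$map$voxel_size[1],
                  region$map$origin[2] + (gj - 1L) * region$map$voxel_size[2],
                  region$map$origin[3] + (gk - 1L) * region$map$voxel_size[3])
  list(dims = bdims, box_idx_local = loc, vals = as.vector(box),
       coords = coords, in_region = region$mask[glob],
       global_idx = glob)
}

# Voxel cloud of a region at a (usually lower) contour level: voxels in
# the padded bounding box at or above `level` that belong to connected
# components intersecting the region mask. Keeps the low-level growth of
# the region while excluding unrelated density (e.g. protein fringes)
# that enters the box.
.region_cloud <- function(region, level, pad = 3L, max_radius = 6) {
  sub <- .region_subvolume(region, pad = pad)
  m <- array(FALSE, sub$dims)
  m[sub$box_idx_local[sub$vals >= level]] <- TRUE
  lab <- label_components(m)
  near <- .dilate_mask(array(sub$in_region, sub$dims), 2L)
  own <- unique(lab[sub$box_idx_local[as.vector(near)]])
  own <- own[own > 0]
  if (length(own)) {
    # reject adjacent foreign density (e.g. protein fringe creeping past
    # the erase zone): a component kept must center near the region
    axis <- if (is.null(region$frame)) c(0, 0, 1)
            else region$frame$axis_direction
    b <- plane_basis(axis)
    uu <- as.vector(sub$coords %*% b$u) - region$centroid_uv[1]
    vv <- as.vector(sub$coords %*% b$v) - region$centroid_uv[2]
    keep <- vapply(own, function(id) {
      sel <- lab[sub$box_idx_local] == id
      sqrt(mean(uu[sel])^2 + mean(vv[sel])^2) <= max_radius
    }, logical(1))
    own <- own[keep]
  }
  sel <- lab[sub$box_idx_local] %in% own & sub$vals >= level
  list(coords = sub$coords[sel, , drop = FALSE], vals = sub$vals[sel])
}

# Morphological dilation of a 3D logical array (26-neighbourhood).
.dilate_mask <- function(mask, iter = 1L) {
  dims <- dim(mask)
  for (it in seq_len(iter)) {
    out <- mask
    for (r in seq_len(nrow(.offsets26))) {
      for (sgn in c(1L, -1L)) {
        o <- sgn * .offsets26[r, ]
        xr <- if (o[1] >= 0) seq_len(dims[1] - o[1]) else seq(1 - o[1], dims[1])
        yr <- if (o[2] >= 0) seq_len(dims[2] - o[2]) else seq(1 - o[2], dims[2])
        zr <- if (o[3] >= 0) seq_len(dims[3] - o[3]) else seq(1 - o[3], dims[3])
        out[xr, yr, zr] <- out[xr, yr, zr] |
          mask[xr + o[1], yr + o[2], zr + o[3]]
      }
    }
    mask <- out
  }
  mask
}

#' Estimate the axial repeat distance of an extra density
#'
#' Autocorrelation of the axial density profile of the region; the repeat
#' is the lag of the dominant peak within the search window. An axially
#' uniform rod has no peak and yields an indeterminate (`NA`) repeat.
#'
#' @param region an `ed_region`.
#' @param frame a [fibril_frame()].
#' @param window search window in Angstrom.
#' @param level contour level defining the profile support (default: the
#'   region's extraction level).
#' @param prominence minimum autocorrelation peak prominence.
#' @return list with `repeat_A` (possibly `NA`), `sharpness`, `window`.
#' @export
estimate_repeat <- function(region, frame, window = c(3, 7), level = NULL,
                            prominence = 0.1) {
  stopifnot(inherits(region, "ed_region"), inherits(frame, "fibril_frame"))
  level <- level %||% region$level
  sub <- .region_subvolume(region, pad = 2L)
  sel <- sub$vals >= level
  if (!any(sel)) {
    return(list(repeat_A = NA_real_, sharpness = NA_real_, window = window))
  }
  axis <- plane_basis(frame$axis_direction)$axis
  t <- as.vector(sub$coords[sel, , drop = FALSE] %*% axis)
  if (diff(range(t)) < 5 * window[1]) {
    stop("region spans fewer than 5 candidate repeats")
  }
  h <- min(region$map$voxel_size) / 4
  prof <- bin_profile(t, sub$vals[sel], h,
                      kernel_hw = min(region$map$voxel_size))
  profile_periodicity(prof$profile, h, window = window,
                      prominence = prominence)
}

#' Averaged 2D cross-section of an extra density
#'
#' Partitions the region into axial repeat units, projects each unit onto
#' the plane normal to the fibril axis after undoing the per-unit twist,
#' and averages the unit images. The averaged image is rescaled so its
#' maximum equals the maximum 3D density of the region, which keeps
#' contour-ladder levels meaningful on the section.
#'
#' @param region an `ed_region`.
#' @param frame a [fibril_frame()].
#' @param repeat_A repeat unit length, Angstrom; default: estimated from
#'   the region, falling back to the frame rise.
#' @param twist degrees of twist per repeat unit to undo; default: the
#'   frame twist (0 when unknown).
#' @param level density level defining the projected cloud.
#' @param half half-width of the section image, Angstrom.
#' @param px pixel size of the section image, Angstrom.
#' @return object of class `lced_section`: fields `img` (matrix),
#'   `units` (per-unit images), `u`, `v` (pixel center coordinates,
#'   relative to the region's in-plane centroid), `n_units`, `max3d`.
#' @export
cross_section_profile <- function(region, frame, repeat_A = NULL,
                                  twist = NULL, level = NULL, half = 9,
                                  px = 0.5) {
  stopifnot(inherits(region, "ed_region"), inherits(frame, "fibril_frame"))
  level <- level %||% (region$level * 0.5)
  if (is.null(repeat_A)) {
    est <- tryCatch(estimate_repeat(region, frame), error = function(e) NULL)
    repeat_A <- if (!is.null(est) && is.finite(est$repeat_A)) est$repeat_A
                else frame$rise
  }
  if (!is.finite(repeat_A) || repeat_A <= 0) repeat_A <- 4.8
  twist <- twist %||% (if (is.finite(frame$twist)) frame$twist else 0)
  b <- plane_basis(frame$axis_direction)
  cloud <- .region_cloud(region, level)
  u0 <- region$centroid_uv[1]
  v0 <- region$centroid_uv[2]
  uu <- as.vector(cloud$coords %*% b$u) - u0
  vv <- as.vector(cloud$coords %*% b$v) - v0
  sel <- sqrt(uu^2 + vv^2) <= half
  if (!any(sel)) stop("no density above level near the region")
  uu <- uu[sel]; vv <- vv[sel]
  w <- cloud$vals[sel]
  t <- as.vector(cloud$coords[sel, , drop = FALSE] %*% b$axis)
  # phase-align the unit windows with the axial density so that repeat
  # units are centered on the rungs rather than cut through them
  ang <- 2 * pi * t / repeat_A
  phase <- atan2(sum(w * sin(ang)), sum(w * cos(ang)))
  t0 <- phase / (2 * pi) * repeat_A - repeat_A / 2
  t0 <- t0 - repeat_A * ceiling((t0 - min(t)) / repeat_A)
  ui <- floor((t - t0) / repeat_A)
  ui <- ui - min(ui)
  n_units <- max(ui) + 1L
  if (n_units < 3L) stop("region has fewer than 3 repeat units")
  mid <- (n_units - 1) / 2
  n_px <- 2L * as.integer(round(half / px)) + 1L
  centers <- seq(-half, half, length.out = n_px)
  g <- max(region$map$voxel_size)
  # per-unit centroids (in the untransformed in-plane frame): units are
  # de-twisted about and aligned on them, which removes the systematic
  # per-unit drift a small axis-direction error would otherwise cause
  unit_ctr <- matrix(NA_real_, n_units, 2)
  for (k in seq_len(n_units)) {
    s <- ui == (k - 1L)
    if (!any(s)) next
    unit_ctr[k, ] <- c(sum(uu[s] * w[s]), sum(vv[s] * w[s])) / sum(w[s])
  }
  tgt <- cbind(rep(centers, times = n_px), rep(centers, each = n_px))
  units <- vector("list", n_units)
  for (k in seq_len(n_units)) {
    s <- ui == (k - 1L)
    if (!any(s) || !is.finite(unit_ctr[k, 1])) {
      units[[k]] <- matrix(0, n_px, n_px)
      next
    }
    # column maximum on the unit's own voxel lattice (alias-free), ...
    x <- uu[s]; y <- vv[s]; ws <- w[s]
    ix <- as.integer(round((x - min(x)) / g))
    iy <- as.integer(round((y - min(y)) / g))
    ni <- max(ix) + 3L; nj <- max(iy) + 3L   # zero border for resampling
    M <- matrix(0, ni, nj)
    key <- (iy + 1L) * ni + ix + 2L
    ord <- order(key, -ws)
    first <- !duplicated(key[ord])
    M[key[ord][first]] <- ws[ord][first]
    # ... then resampled bilinearly into the de-twisted frame centered
    # on the unit centroid (target pixel p maps to source point
    # ck + R(twist)(p), the inverse of the de-twist about ck)
    Rinv <- rot2(twist * ((k - 1L) - mid))
    src <- tgt %*% t(Rinv)
    ri <- (src[, 1] + unit_ctr[k, 1] - min(x)) / g + 2
    ci <- (src[, 2] + unit_ctr[k, 2] - min(y)) / g + 2
    vals <- bilinear_sample(M, ri, ci)
    vals[!is.finite(vals)] <- 0
    units[[k]] <- matrix(vals, n_px, n_px)
  }
  avg <- Reduce(`+`, units) / n_units
  max3d <- max(w)
  sc <- if (max(avg) > 0) max3d / max(avg) else 1
  structure(list(img = avg * sc,
                 units = lapply(units, function(m) m * sc),
                 u = centers, v = centers, px = px,
                 n_units = n_units, repeat_A = repeat_A,
                 max3d = max3d, scale = sc,
                 center_uv = colMeans(unit_ctr, na.rm = TRUE)),
            class = "lced_section")
}

#' @export
print.lced_section <- function(x, ...) {
  cat(sprintf("lced_section: %dx%d px (%.2f A), %d repeat units of %.2f A\n",
              nrow(x$img), ncol(x$img), x$px, x$n_units, x$repeat_A))
  invisible(x)
}

# Light 3x3 box smoothing used before local-maximum detection.
.smooth3 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  p <- matrix(0, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- img
  acc <- matrix(0, n, m)
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + p[(1 + di):(n + di), (1 + dj):(m + dj)]
  }
  acc / 9
}

#' Moment-based ellipse fit of a cross-section
#'
#' Fits an ellipse to the above-level pixels of a section image via
#' second moments. Vertices (V1, V2) sit on the major axis, co-vertices
#' (CV1, CV2) on the minor axis. Near-circular sections (aspect ratio
#' below `circle_ratio`) are flagged and their vertex order is arbitrary.
#'
#' @param section an `lced_section` (or bare matrix with unit pixels).
#' @param level iso-level defining the fitted pixel set.
#' @param circle_ratio aspect ratio below which the fit is flagged
#'   circular.
#' @return object of class `lced_ellipse`: center, semi-axes, axis
#'   directions, vertices, co-vertices, aspect, `circle` flag.
#' @export
fit_ellipse <- function(section, level, circle_ratio = 1.1) {
  img <- if (inherits(section, "lced_section")) section$img else section
  uc <- if (inherits(section, "lced_section")) section$u else seq_len(nrow(img))
  vc <- if (inherits(section, "lced_section")) section$v else seq_len(ncol(img))
  sel <- which(img >= level)
  if (length(sel) < 10L) stop("fewer than 10 pixels above level")
  pu <- uc[(sel - 1L) %% nrow(img) + 1L]
  pv <- vc[(sel - 1L) %/% nrow(img) + 1L]
  ctr <- c(mean(pu), mean(pv))
  cov <- stats::cov(cbind(pu, pv)) * (length(pu) - 1) / length(pu)
  eig <- eigen(cov, symmetric = TRUE)
  a <- 2 * sqrt(max(eig$values[1], 0))
  bax <- 2 * sqrt(max(eig$values[2], 1e-12))
  e1 <- eig$vectors[, 1]
  e2 <- eig$vectors[, 2]
  aspect <- a / bax
  structure(list(center = ctr, major = a, minor = bax,
                 major_dir = e1, minor_dir = e2, aspect = aspect,
                 circle = aspect < circle_ratio,
                 vertices = rbind(V1 = ctr + a * e1, V2 = ctr - a * e1),
                 covertices = rbind(CV1 = ctr + bax * e2,
                                    CV2 = ctr - bax * e2)),
            class = "lced_ellipse")
}

#' Marker graph of a cross-section
#'
#' Places marker nodes at local maxima of the averaged section that
#' persist above the second ladder level, and joins two nodes when the
#' density along the straight segment between them stays above the lowest
#' ladder level. Edges whose segment passes close to a third node are
#' suppressed (the direct join is redundant). Degree-2 chain nodes form
#' the backbone; a degree-1 node clearly weaker than the strongest
#' terminal is a side node (a peg joined just once).
#'
#' @param section an `lced_section`.
#' @param ladder a [make_contour_ladder()] result.
#' @param merge_dist maxima closer than this (Angstrom) are merged.
#' @param node_suppress_dist edges passing within this distance of a
#'   third node are suppressed.
#' @param side_ratio a terminal with value below `side_ratio` times the
#'   strongest terminal is classed a side node.
#' @return object of class `marker_graph`: `nodes` (data.frame u, v,
#'   value, role, degree), `edges` (2-column matrix of node indices),
#'   `orientations` (admissible Y attitudes when the terminals are
#'   symmetric).
#' @export
build_marker_graph <- function(section, ladder, merge_dist = 1.0,
                               node_suppress_dist = 0.8,
                               side_ratio = 0.85) {
  stopifnot(inherits(section, "lced_section"),
            inherits(ladder, "contour_ladder"))
  img <- section$img
  # judge persistence and connectivity relative to the section's own
  # scale: a weak density's features sit below the fixed ladder, while
  # under noise the lower ladder rungs sit below the background
  node_level <- 0.35 * max(img)
  edge_level <- min(ladder$levels[1], 0.25 * max(img))
  n <- nrow(img); m <- ncol(img)
  inner_i <- 2:(n - 1); inner_j <- 2:(m - 1)
  ctrm <- img[inner_i, inner_j]
  is_max <- ctrm >= node_level
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (ctrm >= img[inner_i + di, inner_j + dj])
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) == 0L) {
    return(structure(list(nodes = data.frame(u = numeric(), v = numeric(),
                                             value = numeric(),
                                             role = character(),
                                             degree = integer()),
                          edges = matrix(integer(), 0, 2),
                          orientations = character()),
                     class = "marker_graph"))
  }
  pu <- section$u[pk[, 1] + 1L]
  pv <- section$v[pk[, 2] + 1L]
  val <- ctrm[pk]
  ord <- order(-val)
  pu <- pu[ord]; pv <- pv[ord]; val <- val[ord]
  keep <- rep(TRUE, length(val))
  for (i in seq_along(val)) {
    if (!keep[i]) next
    d <- sqrt((pu - pu[i])^2 + (pv - pv[i])^2)
    keep[d < merge_dist & seq_along(val) > i] <- FALSE
  }
  pu <- pu[keep]; pv <- pv[keep]; val <- val[keep]
  nn <- length(val)
  # node values: mean over a small disc around the maximum, which is far
  # more noise-stable than the single peak pixel
  gu <- section$u[rep(seq_along(section$u), times = length(section$v))]
  gv <- section$v[rep(seq_along(section$v), each = length(section$u))]
  for (i in seq_len(nn)) {
    disc <- (gu - pu[i])^2 + (gv - pv[i])^2 <= 1.0^2
    val[i] <- mean(img[disc])
  }
  edges <- matrix(integer(), 0, 2)
  if (nn >= 2L) {
    for (i in 1:(nn - 1)) for (j in (i + 1):nn) {
      ts <- seq(0, 1, length.out = 30)
      su <- pu[i] + ts * (pu[j] - pu[i])
      sv <- pv[i] + ts * (pv[j] - pv[i])
      ri <- (su - section$u[1]) / section$px + 1
      ci <- (sv - section$v[1]) / section$px + 1
      dens <- bilinear_sample(img, ri, ci)
      if (any(!is.finite(dens)) || min(dens) < edge_level) next
      # suppress the join if it passes through another node's territory
      others <- setdiff(seq_len(nn), c(i, j))
      blocked <- FALSE
      for (k in others) {
        dseg <- .point_segment_dist(pu[k], pv[k], pu[i], pv[i], pu[j], pv[j])
        if (dseg < node_suppress_dist) { blocked <- TRUE; break }
      }
      if (!blocked) edges <- rbind(edges, c(i, j))
    }
  }
  deg <- tabulate(as.vector(edges), nbins = nn)
  role <- rep("backbone", nn)
  term <- which(deg == 1L)
  if (length(term) >= 2L) {
    vmax <- max(val[term])
    role[term[val[term] < side_ratio * vmax]] <- "side"
  }
  orientations <- character()
  if (length(term) == 2L) {
    r <- min(val[term]) / max(val[term])
    orientations <- if (r >= side_ratio) {
      c("forward-Y", "backward-Y", "lambda", "reverse-lambda")
    } else "single-Y"
  }
  structure(list(nodes = data.frame(u = pu, v = pv, value = val,
                                    role = role, degree = deg),
                 edges = edges, orientations = orientations),
            class = "marker_graph")
}

.point_segment_dist <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax; aby <- by - ay
  len2 <- abx^2 + aby^2
  t <- if (len2 < 1e-12) 0 else ((px - ax) * abx + (py - ay) * aby) / len2
  t <- max(0, min(1, t))
  sqrt((ax + t * abx - px)^2 + (ay + t * aby - py)^2)
}

#' @export
print.marker_graph <- function(x, ...) {
  cat("marker_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) print(x$nodes, row.names = FALSE)
  invisible(x)
}

# --- morphology classification -------------------------------------------

# Connected components of a section image above an absolute level.
# Returns per-component moments for components of at least min_px pixels.
.section_components <- function(section, level, min_px = 5L) {
  img <- section$img
  lab <- label_components_2d(img >= level)
  ids <- sort(unique(lab[lab > 0]))
  comps <- list()
  for (id in ids) {
    sel <- which(lab == id)
    if (length(sel) < min_px) next
    pu <- section$u[(sel - 1L) %% nrow(img) + 1L]
    pv <- section$v[(sel - 1L) %/% nrow(img) + 1L]
    ctr <- c(mean(pu), mean(pv))
    cv <- stats::cov(cbind(pu, pv)) * (length(pu) - 1) / length(pu)
    eig <- eigen(cv, symmetric = TRUE)
    comps[[length(comps) + 1L]] <- list(
      area = length(sel), centroid = ctr,
      major = 2 * sqrt(max(eig$values[1], 1e-12)),
      minor = 2 * sqrt(max(eig$values[2], 1e-12)),
      major_dir = eig$vectors[, 1],
      aspect = sqrt(max(eig$values[1], 1e-12) /
                      max(eig$values[2], 1e-12)))
  }
  comps
}

# Duplex test on a section: two dominant elongated parallel sub-rods.
# The split level is searched over a band of fractions of the section
# maximum, since the level at which a duplex resolves into its chains
# depends on occupancy and noise.
.duplex_test <- function(section, split_frac = 0.5, min_aspect = 1.4,
                         sep_factor = 1.5) {
  for (frac in sort(unique(c(split_frac, seq(0.35, 0.7, by = 0.05))))) {
    hit <- .duplex_test_at(section, frac, min_aspect, sep_factor)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

.duplex_test_at <- function(section, split_frac, min_aspect = 1.4,
                            sep_factor = 1.5) {
  level <- split_frac * max(section$img)
  comps <- .section_components(section, level)
  if (length(comps) < 2L) return(NULL)
  ord <- order(-vapply(comps, `[[`, numeric(1), "area"))
  c1 <- comps[[ord[1]]]; c2 <- comps[[ord[2]]]
  if (c1$aspect < min_aspect || c2$aspect < min_aspect) return(NULL)
  # a duplex is two substantial chains of comparable size that together
  # dominate the section (noise sections fragment into many small
  # components instead) ...
  if (c2$area < 0.4 * c1$area || c2$area < 10L) return(NULL)
  total <- sum(vapply(comps, `[[`, numeric(1), "area"))
  if ((c1$area + c2$area) < 0.55 * total) return(NULL)
  sep <- c2$centroid - c1$centroid
  d <- vec_norm(sep)
  if (d <= sep_factor * mean(c(c1$minor, c2$minor))) return(NULL)
  # ... running parallel to each other and across the separation
  if (abs(sum(c1$major_dir * c2$major_dir)) < cos(deg2rad(45))) {
    return(NULL)
  }
  sd1 <- abs(sum(unit_vec(sep) * c1$major_dir))
  sd2 <- abs(sum(unit_vec(sep) * c2$major_dir))
  if (sd1 > cos(deg2rad(45)) || sd2 > cos(deg2rad(45))) return(NULL)
  list(chain1 = c1, chain2 = c2, separation = d)
}

# Mean correlation of the per-unit images with the averaged section: a
# repeating substructure persists across units, noise does not.
.section_persistence <- function(section) {
  nz <- Filter(function(u) max(u) > 0, section$units)
  if (length(nz) < 2L) return(0)
  r <- vapply(nz, function(u) {
    v <- suppressWarnings(stats::cor(as.vector(u),
                                     as.vector(section$img)))
    if (is.finite(v)) v else 0
  }, numeric(1))
  mean(r)
}

# Three-fold rotational symmetry score of a section about its centroid:
# the correlation is restricted to the joint support so that empty
# background does not inflate it.
.threefold_score <- function(section) {
  img <- .smooth3(section$img)
  w <- pmax(img, 0)
  s <- sum(w)
  if (s <= 0) return(0)
  cr <- sum(row(img) * w) / s
  cc <- sum(col(img) * w) / s
  floor_v <- 0.1 * max(img)
  one <- function(center) {
    sc <- vapply(c(120, 240), function(th) {
      rot <- rotate_image(img, th, center)
      sel <- is.finite(rot) & (img > floor_v | rot > floor_v)
      if (sum(sel) < 10) 0 else ncc_images(img[sel], rot[sel])
    }, numeric(1))
    min(sc)
  }
  # the score is sensitive to the rotation center; search a small
  # neighbourhood of the density centroid for the best-aligned center
  best <- -1
  for (dr in -2:2) for (dc in -2:2) {
    best <- max(best, one(c(cr + dr, cc + dc)))
  }
  best
}

#' Classify the cross-sectional morphology of a section image
#'
#' Decision cascade over an averaged cross-section: (1) a duplex of two
#' parallel elongated sub-rods is bulky (`b`); (2) a section correlating
#' with its own 120/240-degree rotations is three-fold symmetric (`t`);
#' (3) a three-node marker chain with clearly asymmetric terminals is
#' Y-shaped (`y`: hump, middle, peg); (4) with symmetric terminals it is
#' X-shaped (`x`, the superposition of alternative Y poses, reported with
#' its admissible Y attitudes); (5) a two-node chain is V-shaped (`v`,
#' a truncated Y); (6) anything else is indeterminate (`i`). Threshold
#' ties break toward the less specific code. Before the cascade, the
#' cross-section must persist across repeat units: when the mean
#' unit-to-average correlation falls below `min_persistence` the section
#' has no repeating substructure (noise rather than a polymer) and the
#' call is `i` outright.
#'
#' @param section an `lced_section`.
#' @param ladder a [make_contour_ladder()] result.
#' @param split_frac fraction of the section maximum at which the duplex
#'   split is probed.
#' @param t_threshold three-fold symmetry score threshold.
#' @param side_ratio terminal symmetry threshold separating `y` from `x`.
#' @param min_persistence minimum mean unit-to-average correlation.
#' @return object of class `morphology_call`: `code`, `features`,
#'   `confidence`, `graph`.
#' @export
classify_section <- function(section, ladder, split_frac = 0.5,
                             t_threshold = 0.8, side_ratio = 0.85,
                             min_persistence = 0.72) {
  stopifnot(inherits(section, "lced_section"))
  dup <- .duplex_test(section, split_frac)
  graph <- build_marker_graph(section, ladder, side_ratio = side_ratio)
  feats <- list(n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges),
                threefold = .threefold_score(section),
                persistence = .section_persistence(section),
                duplex_separation = if (!is.null(dup)) dup$separation
                                    else NA_real_)
  finish <- function(code, confidence) {
    structure(list(code = code, features = feats,
                   confidence = max(0, min(1, confidence)), graph = graph,
                   duplex = dup),
              class = "morphology_call")
  }
  if (length(section$units) > 2L && feats$persistence < min_persistence) {
    return(finish("i", 1 - feats$persistence))
  }
  if (!is.null(dup)) {
    return(finish("b", dup$separation /
                    (2 * mean(c(dup$chain1$minor, dup$chain2$minor))) - 0.5))
  }
  if (feats$threefold > t_threshold) {
    return(finish("t", (feats$threefold - t_threshold) / (1 - t_threshold)))
  }
  deg <- graph$nodes$degree
  nn <- length(deg)
  if (nn >= 2L && nrow(graph$edges) == nn - 1L && all(deg <= 2L) &&
      sum(deg == 1L) == 2L) {
    term <- which(deg == 1L)
    if (nn == 2L) return(finish("v", 0.5))
    r <- min(graph$nodes$value[term]) / max(graph$nodes$value[term])
    if (r < side_ratio) return(finish("y", (side_ratio - r) / side_ratio))
    return(finish("x", (r - side_ratio) / (1 - side_ratio)))
  }
  finish("i", 0.25)
}

#' @export
print.morphology_call <- function(x, ...) {
  cat(sprintf("morphology_call: %s (confidence %.2f, %d nodes, %d edges)\n",
              x$code, x$confidence, x$features$n_nodes, x$features$n_edges))
  invisible(x)
}

#' Classify the morphology of an extra-density region
#'
#' Convenience wrapper: computes the averaged cross-section of the region
#' (repeat from [estimate_repeat()], twist from the frame) and classifies
#' it with [classify_section()].
#'
#' @param region an `ed_region` graded `s`, `m` or `w`.
#' @param frame a [fibril_frame()].
#' @param ladder a [make_contour_ladder()] result.
#' @param ... passed to [classify_section()].
#' @return a `morphology_call`.
#' @export
classify_morphology <- function(region, frame, ladder, ...) {
  section <- cross_section_profile(region, frame,
                                   level = ladder$levels[1])
  call <- classify_section(section, ladder, ...)
  call$section <- section
  call
}

#' Chain directions of a bulky (duplex) extra density
#'
#' Splits a bulky extra density into its two chains (perpendicular
#' bisector between the sub-rod centroids found by the duplex test) and
#' determines each chain's axial feature polarity: the axial phase offset
#' between the peg-side and hump-side density within a repeat unit. Equal
#' polarities give a parallel duplex, opposite polarities antiparallel.
#' When a chain's cross-section is symmetric (no identifiable peg side)
#' the polarity is indeterminate and the call falls back to single-chain
#' with a warning.
#'
#' @param region an `ed_region` classified as morphology `b`.
#' @param frame a [fibril_frame()].
#' @param ladder a [make_contour_ladder()] result.
#' @param min_lag minimum axial phase lag (Angstrom) accepted as a
#'   determinate polarity.
#' @param sym_tol terminal peak ratio above which a chain profile is
#'   considered symmetric (indeterminate).
#' @return list with `status` (`"duplex_parallel"`,
#'   `"duplex_antiparallel"` or `"single"`), per-chain `lags` (Angstrom)
#'   and an optional `warning` message.
#' @export
detect_duplex_direction <- function(region, frame, ladder, min_lag = 0.3,
                                    sym_tol = 0.95, split_frac = 0.5) {
  section <- cross_section_profile(region, frame, level = ladder$levels[1])
  dup <- .duplex_test(section, split_frac)
  if (is.null(dup)) {
    return(list(status = "single", lags = c(NA_real_, NA_real_),
                warning = "region does not split into two chains"))
  }
  b <- plane_basis(frame$axis_direction)
  cloud <- .region_cloud(region, ladder$levels[1])
  uu <- as.vector(cloud$coords %*% b$u) - region$centroid_uv[1]
  vv <- as.vector(cloud$coords %*% b$v) - region$centroid_uv[2]
  tt <- as.vector(cloud$coords %*% b$axis)
  w <- cloud$vals
  rep_A <- section$repeat_A
  # chain centroids live in the section frame (centered on the mean unit
  # centroid); translate them into the region-centroid frame of the cloud
  chains <- list(dup$chain1, dup$chain2)
  for (ci in 1:2) {
    chains[[ci]]$centroid <- chains[[ci]]$centroid + section$center_uv
  }
  d1 <- sqrt((uu - chains[[1]]$centroid[1])^2 +
               (vv - chains[[1]]$centroid[2])^2)
  d2 <- sqrt((uu - chains[[2]]$centroid[1])^2 +
               (vv - chains[[2]]$centroid[2])^2)
  assign_chain <- ifelse(d1 <= d2, 1L, 2L)
  lags <- rep(NA_real_, 2L)
  for (ci in 1:2) {
    ch <- chains[[ci]]
    s <- assign_chain == ci
    if (!any(s)) next
    along <- (uu[s] - ch$centroid[1]) * ch$major_dir[1] +
      (vv[s] - ch$centroid[2]) * ch$major_dir[2]
    wts <- w[s]
    # terminal-lobe windows anchored on the outermost substantial
    # density of each side, so the middle blob's skirt does not dilute
    # the axial phase of the peg
    elig <- wts >= 0.25 * max(wts)
    if (!any(elig & along > 0) || !any(elig & along < 0)) next
    far_pos <- max(along[elig & along > 0])
    far_neg <- min(along[elig & along < 0])
    if (far_pos < 1.2 || far_neg > -1.2) next
    pos <- along > far_pos - 2 & along <= far_pos
    neg <- along < far_neg + 2 & along >= far_neg
    if (!any(pos) || !any(neg)) next
    peak_pos <- max(wts[pos]); peak_neg <- max(wts[neg])
    if (min(peak_pos, peak_neg) / max(peak_pos, peak_neg) > sym_tol) next
    peg_side <- if (peak_pos < peak_neg) pos else neg
    hump_side <- if (peak_pos < peak_neg) neg else pos
    phase <- function(side) {
      ang <- 2 * pi * tt[s][side] / rep_A
      atan2(sum(wts[side] * sin(ang)), sum(wts[side] * cos(ang)))
    }
    dphi <- phase(peg_side) - phase(hump_side)
    dphi <- atan2(sin(dphi), cos(dphi))
    lags[ci] <- dphi * rep_A / (2 * pi)
  }
  determinate <- is.finite(lags) & abs(lags) >= min_lag
  if (!all(determinate)) {
    return(list(status = "single", lags = lags,
                warning = paste("chain polarity indeterminate;",
                                "treating as single chains")))
  }
  status <- if (sign(lags[1]) == sign(lags[2])) "duplex_parallel"
            else "duplex_antiparallel"
  list(status = status, lags = lags, warning = NULL)
}

#' Binding pose of an extra density relative to its coordinating pair
#'
#' The pose is defined against the two nearest coordinating residues:
#' alignment is `horizontal` when the section's major axis makes an angle
#' below 45 degrees with the inter-residue vector, `vertical` otherwise
#' (a tie at exactly 45 degrees breaks toward vertical); the flip (`up`
#' or `down`) is the sign of the hump-to-peg vector projected on the
#' inter-residue normal, or on the inter-residue direction itself when
#' the hump-peg axis runs along the pair (a horizontal rod), so that an
#' upside-down rebinding of the same rod always reverses the flip.
#'
#' @param region an `ed_region`.
#' @param coordination a `coordination_set` (see
#'   [find_coordinating_residues()]) with at least 2 entries.
#' @param frame a [fibril_frame()].
#' @param ladder a [make_contour_ladder()] result.
#' @return object of class `pose_call`: `alignment`, `flip`,
#'   `reference_pair`, `angle` (degrees between major axis and pair).
#' @export
determine_pose <- function(region, coordination, frame, ladder) {
  stopifnot(inherits(coordination, "coordination_set"))
  ent <- coordination$entries
  if (nrow(ent) < 2L) stop("pose needs at least 2 coordinating residues")
  # select the two closest residues, then orient the pair vector
  # deterministically (by residue number) so the flip sign is stable
  ent <- ent[order(ent$min_distance), ][1:2, ]
  ent <- ent[order(ent$residue_number), ]
  p1 <- c(ent$atom_x[1], ent$atom_y[1], ent$atom_z[1])
  p2 <- c(ent$atom_x[2], ent$atom_y[2], ent$atom_z[2])
  if (vec_norm(p2 - p1) < 0.5) {
    stop("reference coordinating residues are (nearly) coincident")
  }
  b <- plane_basis(frame$axis_direction)
  pair3 <- p2 - p1
  pvec <- c(sum(pair3 * b$u), sum(pair3 * b$v))
  if (vec_norm(pvec) < 1e-6) stop("coordinating pair is purely axial")
  phat <- unit_vec(pvec)
  nhat <- c(-phat[2], phat[1])
  section <- cross_section_profile(region, frame, level = ladder$levels[1])
  ell <- fit_ellipse(section, level = ladder$levels[1])
  cosang <- abs(sum(unit_vec(ell$major_dir) * phat))
  angle <- rad2deg(acos(max(-1, min(1, cosang))))
  alignment <- if (angle < 45) "horizontal" else "vertical"
  graph <- build_marker_graph(section, ladder)
  term <- which(graph$nodes$degree == 1L)
  flip <- NA_character_
  if (length(term) >= 2L) {
    tv <- graph$nodes$value[term]
    if (min(tv) / max(tv) < 0.95) {
      hump <- term[which.max(tv)]
      peg <- term[which.min(tv)]
      v_hp <- c(graph$nodes$u[peg] - graph$nodes$u[hump],
                graph$nodes$v[peg] - graph$nodes$v[hump])
      dref <- if (abs(sum(v_hp * nhat)) >= abs(sum(v_hp * phat))) nhat
              else phat
      flip <- if (sum(v_hp * dref) >= 0) "up" else "down"
    }
  }
  structure(list(alignment = alignment, flip = flip,
                 reference_pair = ent[1:2, c("chain", "residue_number",
                                             "residue_name")],
                 angle = angle),
            class = "pose_call")
}

#' @export
print.pose_call <- function(x, ...) {
  cat(sprintf("pose_call: %s, flip %s (major axis at %.1f deg to pair)\n",
              x$alignment, x$flip, x$angle))
  invisible(x)
}
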
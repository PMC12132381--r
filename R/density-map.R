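#' Construct a density map object
#'
#' A density map is a 3D scalar grid on a regular lattice with a physical
#' voxel size and origin (both in Angstrom, voxel-center convention: voxel
#' (1,1,1) is centered at `origin`). Cryo-EM maps deposited in the EMDB
#' carry a recommended display contour level; it is kept alongside the grid
#' because strength grading and dissection are defined relative to it.
#'
#' @param grid 3D numeric array of density values (arbitrary units).
#' @param voxel_size numeric length-3, Angstrom per voxel along x, y, z.
#'   A scalar is recycled.
#' @param origin numeric length-3, Angstrom position of voxel (1,1,1).
#' @param recommended_level optional scalar display contour level.
#' @param accession_label free-text provenance label (e.g. "EMD-10650").
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                        recommended_level = NULL, accession_label = "") {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (any(dim(grid) < 2L)) stop("grid needs at least 2 voxels per axis")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size components must be positive")
  if (!is.null(recommended_level)) {
    rng <- range(grid)
    if (recommended_level < rng[1] || recommended_level > rng[2]) {
      stop("recommended_level lies outside the density range of the grid")
    }
  }
  structure(list(grid = grid,
                 voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3L),
                 recommended_level = recommended_level,
                 accession_label = accession_label),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map ",
      if (nzchar(x$accession_label)) x$accession_label else "",
      "\n  grid: ", paste(dim(x$grid), collapse = " x "),
      "  voxel: ", paste(signif(x$voxel_size, 4), collapse = ", "), " A\n",
      "  range: [", signif(min(x$grid), 4), ", ", signif(max(x$grid), 4), "]",
      if (!is.null(x$recommended_level)) {
        paste0("  recommended level: ", signif(x$recommended_level, 4))
      } else "  (no recommended level)", "\n", sep = "")
  invisible(x)
}

# Physical coordinates of given linear voxel indices of a map.
map_voxel_coords <- function(map, idx) {
  voxel_coords(idx, dim(map$grid), map$voxel_size, map$origin)
}

.mrc_level_tag <- "lcedscan_level="

#' Read an MRC/CCP4 2014 density map
#'
#' Parses the 1024-byte MRC header, reads the data block (modes 0, 1 and 2)
#' and reorders the axes to the canonical x-fast, z-slow convention using
#' the MAPC/MAPR/MAPS header words, so that identical physical volumes read
#' identically regardless of the axis order they were stored in. The origin
#' is taken from the MRC2014 ORIGIN words, falling back to
#' NXSTART/NYSTART/NZSTART times the voxel size when ORIGIN is all-zero.
#'
#' @param path file path to an MRC/CCP4 map.
#' @param recommended_level optional display contour level to attach; when
#'   absent, a level stored in the map labels by [write_map()] is used.
#' @param accession_label provenance label; defaults to the file name.
#' @return A [density_map()].
#' @export
read_map <- function(path, recommended_level = NULL, accession_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, integer(), n = 10L, size = 4L, endian = "little")
  if (any(!is.finite(ints1))) stop("malformed MRC header")
  nc <- ints1[1]; nr <- ints1[2]; ns <- ints1[3]
  mode <- ints1[4]
  nstart <- ints1[5:7]
  m <- ints1[8:10]
  cella <- readBin(con, numeric(), n = 3L, size = 4L, endian = "little")
  readBin(con, numeric(), n = 3L, size = 4L, endian = "little")  # cellb
  crs <- readBin(con, integer(), n = 3L, size = 4L, endian = "little")
  readBin(con, numeric(), n = 3L, size = 4L, endian = "little")  # dmin/max/mean
  readBin(con, integer(), n = 2L, size = 4L, endian = "little")  # ispg, nsymbt
  readBin(con, raw(), n = 100L)                                   # extra
  orig <- readBin(con, numeric(), n = 3L, size = 4L, endian = "little")
  mapchr <- rawToChar(readBin(con, raw(), n = 4L))
  readBin(con, raw(), n = 4L)                                     # machst
  readBin(con, numeric(), n = 1L, size = 4L, endian = "little")   # rms
  readBin(con, integer(), n = 1L, size = 4L, endian = "little")   # nlabl
  labels_raw <- readBin(con, raw(), n = 800L)
  if (!identical(substr(mapchr, 1, 3), "MAP")) {
    stop("malformed MRC header: missing MAP signature")
  }
  if (nc < 1 || nr < 1 || ns < 1) stop("unsupported: non-3D MRC data")
  if (!all(crs %in% 1:3) || anyDuplicated(crs)) {
    stop("malformed MRC header: bad axis order words")
  }
  nvox <- as.numeric(nc) * nr * ns
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, integer(), n = nvox, size = 1L,
                             signed = TRUE)),
    "1" = as.numeric(readBin(con, integer(), n = nvox, size = 2L,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, numeric(), n = nvox, size = 4L, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(data) != nvox) stop("malformed MRC file: truncated data block")
  d <- array(data, c(nc, nr, ns))
  perm <- match(1:3, crs)
  grid <- aperm(d, perm)
  m[m == 0] <- dim(grid)[m == 0]
  voxel_size <- cella / m
  voxel_size[!is.finite(voxel_size) | voxel_size <= 0] <- 1
  origin <- orig
  if (all(origin == 0) && any(nstart != 0)) {
    origin <- nstart[perm] * voxel_size
  }
  labtxt <- rawToChar(labels_raw[labels_raw != as.raw(0)])
  if (is.null(recommended_level) && grepl(.mrc_level_tag, labtxt, fixed = TRUE)) {
    lv <- sub(paste0(".*", .mrc_level_tag, "([-0-9.eE+]+).*"), "\\1", labtxt)
    lv <- suppressWarnings(as.numeric(lv))
    if (is.finite(lv)) recommended_level <- lv
  }
  if (!is.null(recommended_level) &&
      (recommended_level < min(grid) || recommended_level > max(grid))) {
    recommended_level <- NULL
  }
  density_map(grid, voxel_size, origin, recommended_level,
              accession_label %||% basename(path))
}

#' Write a density map to an MRC 2014 file
#'
#' Writes mode-2 (float32) MRC. The recommended contour level, if present,
#' is stored in a map label so that [read_map()] round-trips it.
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @param axis_order integer permutation of 1:3 giving the physical axis
#'   stored fastest, medium, slowest (header words MAPC/MAPR/MAPS). The
#'   default stores x fastest; other orders are useful to exercise readers.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, axis_order = c(1L, 2L, 3L)) {
  stopifnot(inherits(map, "density_map"))
  axis_order <- as.integer(axis_order)
  if (!all(sort(axis_order) == 1:3)) stop("axis_order must permute 1:3")
  g <- map$grid
  d <- aperm(g, axis_order)
  dims <- dim(d)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dims, 2L, 0L, 0L, 0L, dim(g))), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(c(dim(g) * map$voxel_size, 90, 90, 90)), con,
           size = 4L, endian = "little")
  writeBin(as.integer(axis_order), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(g), max(g), mean(g))), con, size = 4L,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4L, endian = "little")
  writeBin(raw(100L), con)
  writeBin(as.numeric(map$origin), con, size = 4L, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  writeBin(as.numeric(stats::sd(g)), con, size = 4L, endian = "little")
  nlabl <- 0L
  lab <- raw(800L)
  if (!is.null(map$recommended_level)) {
    txt <- sprintf("%s%.8g", .mrc_level_tag, map$recommended_level)
    lab[seq_len(nchar(txt))] <- charToRaw(txt)
    nlabl <- 1L
  }
  writeBin(nlabl, con, size = 4L, endian = "little")
  writeBin(lab, con)
  writeBin(as.numeric(as.vector(d)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Fallback display contour level for maps without a deposited one
#'
#' Returns the density value enclosing the top `top_frac` fraction of
#' voxels. Intended for maps whose deposition lacks a recommended level;
#' the result carries a `"fallback"` attribute so downstream reports can
#' flag it.
#'
#' @param map a [density_map()].
#' @param top_frac fraction of voxels above the returned level.
#' @return scalar level with attribute `fallback = TRUE`.
#' @export
fallback_level <- function(map, top_frac = 0.01) {
  stopifnot(top_frac > 0, top_frac < 1)
  lv <- as.numeric(stats::quantile(map$grid, 1 - top_frac, names = FALSE))
  attr(lv, "fallback") <- TRUE
  lv
}

# Resolve the working contour level of a map.
map_level <- function(map, level = NULL) {
  lv <- level %||% map$recommended_level %||% fallback_level(map)
  as.numeric(lv)
}

#' Build a contour ladder around a display level
#'
#' A contour ladder is an ordered set of iso-levels spanning
#' `authors_level * (1 - spread)` to `authors_level * (1 + spread)`, evenly
#' spaced and always containing the display level itself. Probing density
#' persistence across the ladder is the basis of strength grading and
#' marker placement.
#'
#' @param map a [density_map()] with a recommended level, or `NULL` when
#'   `level` is given directly.
#' @param n_levels odd integer >= 3, number of rungs in the ladder.
#' @param spread fraction in (0, 1) giving the relative half-range.
#' @param level explicit display level overriding the map's.
#' @return An object of class `contour_ladder` with fields `levels` and
#'   `authors_index`.
#' @export
make_contour_ladder <- function(map = NULL, n_levels = 5L, spread = 0.5,
                                level = NULL) {
  authors <- level %||% (if (!is.null(map)) map$recommended_level else NULL)
  if (is.null(authors)) {
    stop("no recommended level available; supply one (see fallback_level())")
  }
  if (authors == 0) stop("a zero contour level is not a usable iso-surface")
  n_levels <- as.integer(n_levels)
  if (n_levels < 3L || n_levels %% 2L == 0L) {
    stop("n_levels must be an odd integer >= 3")
  }
  if (spread <= 0 || spread >= 1) stop("spread must be in (0, 1)")
  fac <- seq(1 - spread, 1 + spread, length.out = n_levels)
  levels <- authors * fac
  if (authors < 0) levels <- rev(levels)
  structure(list(levels = levels,
                 authors_index = which.min(abs(levels - authors))),
            class = "contour_ladder")
}

#' @export
print.contour_ladder <- function(x, ...) {
  marks <- rep("", length(x$levels))
  marks[x$authors_index] <- " (authors')"
  cat("contour_ladder:\n",
      paste0("  ", signif(x$levels, 5), marks, collapse = "\n"), "\n",
      sep = "")
  invisible(x)
}
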
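#' Construct a point cloud
#'
#' @param points numeric matrix (or data.frame) with columns `x`, `y`, `z`
#'   in metres; all coordinates must be finite.
#' @param scanner_origin optional `(x, y, z)` of the scanner.
#' @param plot_id optional plot identifier.
#' @return A list of class `"point_cloud"` with elements `points` (Nx3
#'   matrix), `scanner_origin`, `plot_id`.
#' @export
point_cloud <- function(points, scanner_origin = NULL, plot_id = NULL) {
  p <- as.matrix(points)
  if (length(p) == 0L) p <- matrix(numeric(0), 0L, 3L)
  if (ncol(p) != 3L) stop("points must have 3 columns (x, y, z)")
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  storage.mode(p) <- "double"
  dimnames(p) <- list(NULL, c("x", "y", "z"))
  structure(list(points = p, scanner_origin = scanner_origin,
                 plot_id = plot_id), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("Point cloud", if (!is.null(x$plot_id)) paste0("[", x$plot_id, "]"),
      ":", nrow(x$points), "points\n")
  if (nrow(x$points)) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  x: [%.2f, %.2f]  y: [%.2f, %.2f]  z: [%.2f, %.2f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  if (!is.null(x$scanner_origin))
    cat(sprintf("  scanner at (%.2f, %.2f, %.2f)\n", x$scanner_origin[1],
                x$scanner_origin[2], x$scanner_origin[3]))
  invisible(x)
}

#' @export
plot.point_cloud <- function(x, which = c("side", "top"), cex = 0.2, ...) {
  which <- match.arg(which)
  p <- x$points
  if (which == "side")
    graphics::plot(p[, "x"], p[, "z"], pch = ".", cex = cex,
                   xlab = "x (m)", ylab = "z (m)", ...)
  else
    graphics::plot(p[, "x"], p[, "y"], pch = ".", cex = cex,
                   xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  invisible(x)
}

#' Read and write plot point clouds
#'
#' XYZ files are whitespace-delimited `x y z` lines; blank lines and lines
#' starting with `#` are ignored; any other malformed line raises an error
#' naming its line number. PLY files use the standard vertex-only element
#' and are written as `binary_little_endian` doubles by default (exact
#' round-trip) or as ASCII.
#'
#' @param path file path.
#' @param format `"xyz"` or `"ply"`; guessed from the file extension when
#'   missing.
#' @param cloud a [point_cloud()].
#' @param binary for PLY writing: binary (default) or ASCII body.
#' @param digits decimal digits written in XYZ text (round-trip is then
#'   exact to `10^-digits` m).
#' @return `read_cloud()` a [point_cloud()]; `write_cloud()` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' write_cloud(point_cloud(matrix(runif(30), 10)), f)
#' cl <- read_cloud(f)
#' @export
read_cloud <- function(path, format = c("auto", "xyz", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") read_xyz(path) else read_ply(path)
}

#' @rdname read_cloud
#' @export
write_cloud <- function(cloud, path, format = c("auto", "xyz", "ply"),
                        binary = TRUE, digits = 7L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (format == "xyz") write_xyz(cloud, path, digits) else
    write_ply(cloud, path, binary)
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    warning("empty point-cloud file: ", path)
    return(point_cloud(matrix(numeric(0), 0L, 3L)))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("parse error in ", path, " at line ", idx[which(nf < 3L)[1L]],
         ": expected 3 numeric fields")
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[1:3]), numeric(3L)))
  if (anyNA(vals))
    stop("parse error in ", path, " at line ",
         idx[which(colSums(is.na(vals)) > 0)[1L]], ": non-numeric field")
  point_cloud(t(vals))
}

write_xyz <- function(cloud, path, digits = 7L) {
  fmt <- sprintf("%%.%df %%.%df %%.%df", digits, digits, digits)
  p <- cloud$points
  writeLines(sprintf(fmt, p[, 1], p[, 2], p[, 3]), path)
}

write_ply <- function(cloud, path, binary = TRUE) {
  p <- cloud$points
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", nrow(p)),
              "property double x", "property double y", "property double z",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) writeBin(as.vector(t(p)), con, size = 8L, endian = "little")
  else writeLines(sprintf("%.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]), con,
                  sep = "\n")
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  marker <- charToRaw("end_header\n")
  hlen <- length(marker)
  pos <- NA_integer_
  limit <- min(length(raw), 65536L)
  for (i in seq_len(limit - hlen + 1L)) {
    if (raw[i] == marker[1L] && identical(raw[i:(i + hlen - 1L)], marker)) {
      pos <- i + hlen - 1L
      break
    }
  }
  if (is.na(pos)) stop("not a PLY file (no end_header): ", path)
  header <- strsplit(rawToChar(raw[seq_len(pos)]), "\n")[[1L]]
  if (header[1L] != "ply") stop("not a PLY file: ", path)
  fmt <- strsplit(grep("^format ", header, value = TRUE)[1L], " ")[[1L]][2L]
  nv <- as.integer(strsplit(grep("^element vertex", header, value = TRUE)[1L],
                            " ")[[1L]][3L])
  props <- grep("^property ", header, value = TRUE)
  ptypes <- vapply(strsplit(props, " "), `[`, "", 2L)
  if (length(props) != 3L || length(unique(ptypes)) != 1L)
    stop("only vertex-only PLY with three same-type properties is supported")
  size <- switch(ptypes[1L], double = 8L, float64 = 8L, float = 4L,
                 float32 = 4L, stop("unsupported PLY property type: ", ptypes[1L]))
  body <- raw[-seq_len(pos)]
  vals <- if (fmt == "ascii") {
    scan(text = rawToChar(body), quiet = TRUE)
  } else if (fmt == "binary_little_endian") {
    readBin(body, "double", n = 3L * nv, size = size, endian = "little")
  } else stop("unsupported PLY format: ", fmt)
  if (length(vals) < 3L * nv) stop("truncated PLY body: ", path)
  point_cloud(matrix(vals[seq_len(3L * nv)], ncol = 3L, byrow = TRUE))
}

#' Clip a point cloud to a horizontal rectangle
#'
#' Retains points whose `(x, y)` fall inside `bounds` under a
#' closed-left/open-right convention on both axes: `xmin <= x < xmax`,
#' `ymin <= y < ymax`. Points exactly on a maximum edge are excluded.
#'
#' @param cloud a [point_cloud()].
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)`.
#' @return The clipped [point_cloud()].
#' @export
clip_to_plot <- function(cloud, bounds = plot_bounds()) {
  p <- cloud$points
  keep <- p[, 1] >= bounds[1] & p[, 1] < bounds[2] &
          p[, 2] >= bounds[3] & p[, 2] < bounds[4]
  point_cloud(p[keep, , drop = FALSE], cloud$scanner_origin, cloud$plot_id)
}

#' Remove the soil-surface layer of a cloud
#'
#' Drops all points with `z <= min(z) + soil_height`, with `min(z)` taken
#' from the cloud itself. With `soil_height = 0` only the points at exactly
#' the minimum height are removed.
#'
#' @param cloud a [point_cloud()].
#' @param soil_height thickness (m) of the removed layer; default 0.10.
#' @return The cleaned [point_cloud()]; a warning is raised if nothing
#'   remains.
#' @export
remove_soil_layer <- function(cloud, soil_height = 0.10) {
  if (soil_height < 0) stop("soil_height must be >= 0")
  p <- cloud$points
  if (nrow(p) == 0L) return(cloud)
  zmin <- min(p[, 3])
  keep <- p[, 3] > zmin + soil_height
  if (!any(keep)) warning("soil removal left an empty cloud")
  point_cloud(p[keep, , drop = FALSE], cloud$scanner_origin, cloud$plot_id)
}

#' Voxelize a point cloud into a 5 cm occupancy grid
#'
#' Converts the cloud to a cubic-voxel occupancy grid anchored at the
#' cloud's minimum corner, with half-open voxel intervals
#' `[origin + i*s, origin + (i+1)*s)`. A voxel is filled if it contains at
#' least one point. The grid extent is the cloud's axis-aligned bounding
#' box.
#'
#' @param cloud a nonempty [point_cloud()].
#' @param voxel_size edge length (m) of a voxel; default 0.05.
#' @return An object of class `"voxel_grid"`: `voxel_size`, `origin`,
#'   `dims`, `voxels` (matrix of filled `(i, j, k)` indices, 0-based),
#'   `n_filled`, `n_total`, `fill_ratio`.
#' @examples
#' g <- voxelize(point_cloud(matrix(runif(300), 100)), voxel_size = 0.1)
#' g$fill_ratio
#' @export
voxelize <- function(cloud, voxel_size = 0.05) {
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  p <- cloud$points
  if (nrow(p) == 0L) stop("cannot voxelize an empty cloud")
  origin <- c(min(p[, 1]), min(p[, 2]), min(p[, 3]))
  idx <- floor(sweep(p, 2, origin) / voxel_size)
  dims <- apply(idx, 2, max) + 1
  key <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  ukey <- sort(unique(key))
  k <- ukey %/% (dims[1] * dims[2])
  rem <- ukey %% (dims[1] * dims[2])
  vox <- cbind(i = rem %% dims[1], j = rem %/% dims[1], k = k)
  n_total <- prod(dims)
  structure(list(voxel_size = voxel_size, origin = origin, dims = dims,
                 voxels = vox, n_filled = nrow(vox), n_total = n_total,
                 fill_ratio = nrow(vox) / n_total, plot_id = cloud$plot_id),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "Voxel grid: %d x %d x %d voxels of %.3g m; %d filled (fill ratio %.4g)\n",
    x$dims[1], x$dims[2], x$dims[3], x$voxel_size, x$n_filled, x$fill_ratio))
  invisible(x)
}
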
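#' Point cloud objects
#'
#' A point cloud is the raw representation of a scanned skeletal segment: an
#' ordered set of 3D coordinates in metres. Duplicated points are permitted
#' (scanners produce them); every coordinate must be finite.
#'
#' @param points numeric matrix with 3 columns (x, y, z in metres) or an
#'   object coercible to one.
#' @param label free-text label carried through reports.
#' @return An object of class `pointcloud`: a list with elements `points`
#'   (n x 3 matrix) and `label`.
#' @examples
#' pc <- pointcloud(matrix(runif(30), ncol = 3), label = "demo")
#' npoints(pc)
#' @export
pointcloud <- function(points, label = "") {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have exactly 3 columns (x, y, z)")
  if (nrow(points) < 1L)
    stop("a point cloud needs at least one point")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("all coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, label = as.character(label)[1]),
            class = "pointcloud")
}

#' @rdname pointcloud
#' @param x a `pointcloud`.
#' @export
npoints <- function(x) {
  stopifnot(inherits(x, "pointcloud"))
  nrow(x$points)
}

#' @export
print.pointcloud <- function(x, ...) {
  cat(sprintf("<pointcloud> %d points%s\n", npoints(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Read a point cloud from an OBJ or PLY file
#'
#' Reads the vertex list of a Wavefront OBJ file (only `v x y z` records are
#' consumed; faces, normals and texture coordinates are ignored) or a PLY
#' file (ASCII or binary little-endian). Coordinates are returned exactly as
#' stored: no unit conversion or rescaling is ever applied, so files written
#' in metres stay in metres.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension, falling back to content sniffing),
#'   `"obj"` or `"ply"`.
#' @param label label for the returned cloud; defaults to the file name.
#' @return A [pointcloud].
#' @seealso [write_pointcloud()]
#' @export
read_pointcloud <- function(path, format = c("auto", "obj", "ply"),
                            label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("obj", "ply")) ext else {
      head_bytes <- readBin(path, "raw", 3L)
      if (identical(rawToChar(head_bytes), "ply")) "ply" else "obj"
    }
  }
  pts <- if (format == "obj") .read_obj(path) else .read_ply(path)
  if (nrow(pts) == 0L) stop("no vertices found in ", path)
  pointcloud(pts, label = label)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_v <- grepl("^v[ \t]", lines)
  vlines <- lines[is_v]
  if (length(vlines) == 0L) return(matrix(numeric(0), ncol = 3))
  toks <- strsplit(trimws(sub("^v", "", vlines)), "[ \t]+")
  out <- matrix(NA_real_, nrow = length(toks), ncol = 3)
  lineno <- which(is_v)
  for (i in seq_along(toks)) {
    xyz <- suppressWarnings(as.numeric(toks[[i]][1:3]))
    if (length(toks[[i]]) < 3L || anyNA(xyz))
      stop(sprintf("malformed vertex record at line %d of %s: '%s'",
                   lineno[i], path, vlines[i]))
    out[i, ] <- xyz
  }
  out
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) stop("unterminated PLY header in ", path)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
  }
  if (!identical(trimws(header[1]), "ply")) stop(path, " is not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop("missing PLY format line in ", path)
  fmt <- strsplit(trimws(fmt_line), "[ \t]+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' (ascii and binary_little_endian only)")

  # element/property layout; only the vertex element is consumed
  elems <- list()
  cur <- NULL
  for (ln in trimws(header)) {
    tk <- strsplit(ln, "[ \t]+")[[1]]
    if (tk[1] == "element") {
      cur <- tk[2]
      elems[[cur]] <- list(n = as.integer(tk[3]), props = character(0),
                           types = character(0))
    } else if (tk[1] == "property" && !is.null(cur)) {
      if (tk[2] == "list")
        stop("PLY list properties are not supported for vertex data")
      elems[[cur]]$types <- c(elems[[cur]]$types, tk[2])
      elems[[cur]]$props <- c(elems[[cur]]$props, tk[3])
    }
  }
  if (is.null(elems$vertex)) stop("PLY file has no vertex element: ", path)
  if (names(elems)[1] != "vertex")
    stop("PLY files with elements preceding 'vertex' are not supported")
  v <- elems$vertex
  ixyz <- match(c("x", "y", "z"), v$props)
  if (anyNA(ixyz)) stop("PLY vertex element lacks x/y/z properties")

  if (fmt == "ascii") {
    rows <- readLines(con, n = v$n, warn = FALSE)
    if (length(rows) < v$n) stop("truncated PLY vertex data in ", path)
    toks <- strsplit(trimws(rows), "[ \t]+")
    out <- t(vapply(toks, function(tk) {
      xyz <- suppressWarnings(as.numeric(tk[ixyz]))
      if (anyNA(xyz)) stop("malformed PLY vertex row in ", path)
      xyz
    }, numeric(3)))
    return(out)
  }

  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  sz <- sizes[v$types]
  if (anyNA(sz)) stop("unsupported PLY property type in ", path)
  stride <- sum(sz)
  raw <- readBin(con, "raw", n = stride * v$n)
  if (length(raw) < stride * v$n) stop("truncated PLY vertex data in ", path)
  offs <- cumsum(c(0L, sz))[seq_along(sz)]
  out <- matrix(NA_real_, nrow = v$n, ncol = 3)
  for (k in 1:3) {
    j <- ixyz[k]
    type <- v$types[j]
    bytes <- sz[j]
    idx <- as.vector(outer(seq_len(bytes), (seq_len(v$n) - 1L) * stride + offs[j], "+"))
    col_raw <- raw[idx]
    out[, k] <- if (type %in% c("float", "float32", "double", "float64")) {
      readBin(col_raw, "double", n = v$n, size = bytes, endian = "little")
    } else {
      readBin(col_raw, "integer", n = v$n, size = bytes, endian = "little",
              signed = !startsWith(type, "u"))
    }
  }
  out
}

#' Write a point cloud to OBJ or PLY
#'
#' Coordinates are written at full double precision (OBJ: `%.17g`; PLY:
#' `double` properties), so write/read round trips are lossless well beyond
#' the 6 decimal places scanners deliver.
#'
#' @param cloud a [pointcloud].
#' @param path output path.
#' @param format `"obj"` or `"ply"`.
#' @param binary for PLY, write binary little-endian instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(cloud, path, format = c("obj", "ply"),
                             binary = FALSE) {
  stopifnot(inherits(cloud, "pointcloud"))
  format <- match.arg(format)
  p <- cloud$points
  if (format == "obj") {
    writeLines(sprintf("v %.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]), path)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", nrow(p)),
           "property double x", "property double y", "property double z",
           "end_header")
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.vector(t(p)), con, size = 8L, endian = "little")
  } else {
    writeLines(sprintf("%.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}
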
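#' Triangle mesh in template correspondence
#'
#' A minimal triangle-mesh container: vertex coordinates in millimetres, a
#' face index matrix, and optional per-vertex RGB colors. Meshes used with a
#' [shape_model()] must all share the same template topology so that vertex
#' `i` denotes the same anatomical location across meshes.
#'
#' @param vertices numeric V x 3 matrix of coordinates (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param vertex_colors optional numeric V x 3 matrix with values in `[0, 1]`.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, vertex_colors = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (nrow(vertices) < 3L) stop("a mesh needs at least 3 vertices")
  if (nrow(faces) < 1L) stop("a mesh needs at least 1 face")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range [1, V]")
  if (!is.null(vertex_colors)) {
    vertex_colors <- as.matrix(vertex_colors)
    if (!all(dim(vertex_colors) == c(nrow(vertices), 3L)))
      stop("vertex_colors must be V x 3")
    vertex_colors <- pmin(pmax(vertex_colors, 0), 1)
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_colors = vertex_colors),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$vertex_colors)) "" else ", per-vertex color"))
  ext <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Read a triangle mesh from OBJ or PLY
#'
#' Supports Wavefront OBJ (`v` lines with optional RGB color extension,
#' `f` lines; polygons are fan-triangulated) and PLY in ASCII or
#' little/big-endian binary form. Coordinates are taken as millimetres.
#'
#' @param path file path ending in `.obj` or `.ply`.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stop("unsupported mesh format: ", ext))
}

#' Write a triangle mesh to OBJ or PLY (ASCII)
#'
#' @param mesh a [tri_mesh()].
#' @param path output path ending in `.obj` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: ", ext))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  vtok <- strsplit(trimws(sub("^v ", "", vlines)), "\\s+")
  vmat <- do.call(rbind, lapply(vtok, function(t) as.numeric(t)))
  cols <- NULL
  if (ncol(vmat) >= 6L) {
    cols <- vmat[, 4:6, drop = FALSE]
    vmat <- vmat[, 1:3, drop = FALSE]
  } else vmat <- vmat[, 1:3, drop = FALSE]
  ftok <- strsplit(trimws(sub("^f ", "", flines)), "\\s+")
  tri <- list()
  for (t in ftok) {
    idx <- as.integer(vapply(strsplit(t, "/"), `[`, "", 1L))
    for (j in seq_len(length(idx) - 2L))            # fan triangulation
      tri[[length(tri) + 1L]] <- idx[c(1L, j + 1L, j + 2L)]
  }
  tri_mesh(vmat, do.call(rbind, tri), vertex_colors = cols)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  if (!is.null(mesh$vertex_colors)) {
    vl <- sprintf("v %.8g %.8g %.8g %.6g %.6g %.6g",
                  v[, 1], v[, 2], v[, 3],
                  mesh$vertex_colors[, 1], mesh$vertex_colors[, 2],
                  mesh$vertex_colors[, 3])
  } else {
    vl <- sprintf("v %.8g %.8g %.8g", v[, 1], v[, 2], v[, 3])
  }
  f <- mesh$faces
  fl <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(vl, fl), path)
}

# PLY: ASCII plus the common binary layouts (float32 vertex properties,
# uchar colors, uchar-counted int32 face index lists).
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readBinLine(con)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 200L) stop("malformed PLY header")
  }
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  el <- grep("^element ", header)
  elements <- list()
  for (i in seq_along(el)) {
    tok <- strsplit(header[el[i]], "\\s+")[[1]]
    to <- if (i < length(el)) el[i + 1] - 1L else length(header) - 1L
    props <- header[(el[i] + 1L):to]
    props <- props[startsWith(props, "property")]
    elements[[tok[2]]] <- list(count = as.integer(tok[3]), props = props)
  }
  vel <- elements[["vertex"]]
  fel <- elements[["face"]]
  if (is.null(vel) || is.null(fel)) stop("PLY lacks vertex or face element")
  pnames <- vapply(strsplit(vel$props, "\\s+"), function(t) t[length(t)], "")
  ptypes <- vapply(strsplit(vel$props, "\\s+"), `[`, "", 2L)
  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    vtxt <- txt[seq_len(vel$count)]
    ftxt <- txt[vel$count + seq_len(fel$count)]
    vmat <- do.call(rbind, lapply(strsplit(trimws(vtxt), "\\s+"), as.numeric))
    colnames(vmat) <- pnames
    fl <- lapply(strsplit(trimws(ftxt), "\\s+"), as.integer)
    tri <- do.call(rbind, lapply(fl, function(r) r[2:4] + 1L))
  } else {
    endian <- if (grepl("little", fmt)) "little" else "big"
    vmat <- matrix(NA_real_, vel$count, length(pnames))
    colnames(vmat) <- pnames
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    read_one <- function(type) {
      sz <- sizes[[type]]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(con, "double", 1L, size = sz, endian = endian)
      else
        readBin(con, "integer", 1L, size = sz, endian = endian,
                signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    for (i in seq_len(vel$count))
      for (j in seq_along(pnames)) vmat[i, j] <- read_one(ptypes[j])
    ftok <- strsplit(fel$props[1], "\\s+")[[1]]
    cnt_type <- ftok[3]; idx_type <- ftok[4]
    tri <- matrix(0L, fel$count, 3L)
    for (i in seq_len(fel$count)) {
      k <- read_one(cnt_type)
      idx <- vapply(seq_len(k), function(j) read_one(idx_type), 0)
      if (k != 3L) stop("only triangular PLY faces are supported")
      tri[i, ] <- as.integer(idx) + 1L
    }
  }
  cols <- NULL
  if (all(c("red", "green", "blue") %in% pnames)) {
    cols <- vmat[, c("red", "green", "blue"), drop = FALSE]
    if (max(cols) > 1) cols <- cols / 255
  }
  tri_mesh(vmat[, c("x", "y", "z"), drop = FALSE], tri, vertex_colors = cols)
}

readBinLine <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L || b == as.raw(10L)) break
    out <- c(out, b)
  }
  trimws(rawToChar(out))
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  has_col <- !is.null(mesh$vertex_colors)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (has_col)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  if (has_col) {
    cc <- round(mesh$vertex_colors * 255)
    vl <- sprintf("%.8g %.8g %.8g %d %d %d", v[, 1], v[, 2], v[, 3],
                  cc[, 1], cc[, 2], cc[, 3])
  } else {
    vl <- sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3])
  }
  f <- mesh$faces - 1L
  fl <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(hdr, vl, fl), path)
}

# Flatten V x 3 vertices to the stacked 3V coordinate vector used by the
# shape model (x1, y1, z1, x2, ...).
flatten_vertices <- function(v) as.numeric(t(v))

unflatten_vertices <- function(x) matrix(x, ncol = 3L, byrow = TRUE)
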
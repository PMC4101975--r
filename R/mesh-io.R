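# Surface-mesh file I/O: STL (ASCII + binary little-endian), PLY (ASCII +
# binary little-endian read, ASCII write) and OBJ (vertices/faces only).
# Units are taken as millimetres verbatim; no rescaling is performed.
# These readers are deliberately minimal triangle-soup parsers: segmented
# labyrinth surfaces are exported as plain geometry, and no mesh I/O package
# is available in the R dependency stack used here.

#' Read a triangulated surface mesh
#'
#' Supports STL (ASCII and binary), PLY (ASCII and binary little-endian) and
#' OBJ (`v`/`f` records only; polygonal faces are fan-triangulated).
#' Coordinates are interpreted as millimetres with no rescaling. STL triangle
#' soup is welded: vertices that agree to 1e-9 mm are merged so shared edges
#' are represented once.
#'
#' @param path input file path.
#' @param format `"auto"` (from the file extension), `"stl"`, `"ply"` or
#'   `"obj"`.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj")) {
      stop(sprintf("cannot infer mesh format from extension '.%s'; pass format=", ext))
    }
    format <- ext
  }
  switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path))
}

#' Write a triangulated surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"auto"` (from the extension), `"stl"`, `"ply"` or `"obj"`.
#' @param binary write binary STL instead of ASCII (STL only; binary STL
#'   stores single-precision coordinates).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj")) {
      stop(sprintf("cannot infer mesh format from extension '.%s'; pass format=", ext))
    }
    format <- ext
  }
  switch(format,
    stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
    ply = write_ply_ascii(mesh, path),
    obj = write_obj(mesh, path))
  invisible(path)
}

## ---- STL ----

# Binary STL is 84 + 50 * ntriangles bytes; use that to disambiguate files
# whose header happens to start with "solid".
stl_is_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  !is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)
}

read_stl <- function(path) {
  if (stl_is_binary(path)) return(read_stl_binary(path))
  con <- file(path, "rb")
  head5 <- rawToChar(readBin(con, "raw", 5L))
  close(con)
  # files that neither pass the binary size check nor start with "solid"
  # are (possibly truncated) binary STL; let the binary reader report the
  # byte offset
  if (identical(head5, "solid")) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines)
  if (length(vlines) == 0L) stop(sprintf("'%s': no STL vertex records found", path))
  if (length(vlines) %% 3L != 0L) {
    stop(sprintf("'%s': truncated ASCII STL, vertex count %d is not a multiple of 3 (last vertex at line %d)",
                 path, length(vlines), vlines[length(vlines)]))
  }
  if (!any(grepl("^\\s*endsolid", lines))) {
    stop(sprintf("'%s': truncated ASCII STL, missing 'endsolid' (file ends at line %d)",
                 path, length(lines)))
  }
  toks <- strsplit(trimws(lines[vlines]), "\\s+")
  coords <- vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))
  if (any(is.na(coords))) {
    bad <- vlines[which(colSums(is.na(coords)) > 0)[1L]]
    stop(sprintf("'%s': unparseable vertex at line %d", path, bad))
  }
  weld_triangle_soup(t(coords), provenance = sprintf("stl-ascii:%s", basename(path)))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (ntri <= 0L) stop(sprintf("'%s': binary STL declares %d triangles", path, ntri))
  rec <- readBin(con, "raw", 50L * ntri)
  if (length(rec) < 50L * ntri) {
    stop(sprintf("'%s': truncated binary STL at byte offset %d (expected %d bytes of triangles)",
                 path, 84L + length(rec), 50L * ntri))
  }
  idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L + rep(seq_len(48L), times = ntri)
  floats <- readBin(rec[idx], "numeric", n = 12L * ntri, size = 4L, endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)  # normal xyz + 3 vertices
  verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE], m[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
  weld_triangle_soup(verts[ord, , drop = FALSE],
                     provenance = sprintf("stl-binary:%s", basename(path)))
}

# Triangle soup -> indexed mesh, merging vertices identical to 1e-9 mm.
weld_triangle_soup <- function(soup, provenance) {
  key <- paste(round(soup[, 1L], 9L), round(soup[, 2L], 9L), round(soup[, 3L], 9L))
  first <- !duplicated(key)
  vid <- match(key, key[first])
  vertices <- soup[first, , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  surface_mesh(vertices, faces, provenance = provenance)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  n <- cbind(
    (v[f[, 2L], 2L] - a[, 2L]) * (v[f[, 3L], 3L] - a[, 3L]) -
      (v[f[, 2L], 3L] - a[, 3L]) * (v[f[, 3L], 2L] - a[, 2L]),
    (v[f[, 2L], 3L] - a[, 3L]) * (v[f[, 3L], 1L] - a[, 1L]) -
      (v[f[, 2L], 1L] - a[, 1L]) * (v[f[, 3L], 3L] - a[, 3L]),
    (v[f[, 2L], 1L] - a[, 1L]) * (v[f[, 3L], 2L] - a[, 2L]) -
      (v[f[, 2L], 2L] - a[, 2L]) * (v[f[, 3L], 1L] - a[, 1L]))
  len <- pmax(row_norms(n), .Machine$double.eps)
  n <- n / len
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid cochleoplan", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[i, 1L], n[i, 2L], n[i, 3L]),
      "    outer loop",
      sprintf("      vertex %.17g %.17g %.17g",
              v[f[i, ], 1L], v[f[i, ], 2L], v[f[i, ], 3L]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid cochleoplan", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb"); on.exit(close(con))
  header <- charToRaw(formatC("cochleoplan binary STL", width = -80))
  writeBin(header[seq_len(80L)], con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  zero16 <- as.raw(c(0L, 0L))
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- cross3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
    nl <- vec_norm(n); if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, t(tri))), con, size = 4L, endian = "little")
    writeBin(zero16, con)
  }
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- character()
  repeat {
    line <- readBinLine(con, path)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000L) stop(sprintf("'%s': PLY header not terminated", path))
  }
  if (!identical(trimws(header[1L]), "ply")) stop(sprintf("'%s': not a PLY file", path))
  fmt_line <- grep("^format ", trimws(header), value = TRUE)
  if (length(fmt_line) != 1L) stop(sprintf("'%s': PLY format line missing", path))
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("'%s': unsupported PLY format '%s'", path, fmt))
  }

  elements <- parse_ply_header(header, path)
  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    parse_ply_ascii(txt, elements, path)
  } else {
    parse_ply_binary(con, elements, path)
  }
}

readBinLine <- function(con, path) {
  bytes <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop(sprintf("'%s': unexpected end of file in header", path))
    if (b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  sub("\r$", "", rawToChar(bytes))
}

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

parse_ply_header <- function(header, path) {
  elements <- list()
  cur <- NULL
  for (line in trimws(header)) {
    tk <- strsplit(line, "\\s+")[[1L]]
    if (tk[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tk[2L], count = as.integer(tk[3L]), props = list())
    } else if (tk[1L] == "property") {
      if (is.null(cur)) stop(sprintf("'%s': PLY property before element", path))
      if (tk[2L] == "list") {
        cur$props[[tk[5L]]] <- list(list = TRUE, count_type = tk[3L], type = tk[4L])
      } else {
        cur$props[[tk[3L]]] <- list(list = FALSE, type = tk[2L])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop(sprintf("'%s': PLY file lacks vertex/face elements", path))
  }
  elements
}

parse_ply_ascii <- function(txt, elements, path) {
  txt <- txt[nzchar(trimws(txt))]
  pos <- 0L
  vertices <- NULL; faces <- NULL
  for (el in elements) {
    if (pos + el$count > length(txt)) {
      stop(sprintf("'%s': truncated PLY, element '%s' ends at line %d of %d data lines",
                   path, el$name, length(txt), pos + el$count))
    }
    chunk <- txt[pos + seq_len(el$count)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pn <- names(el$props)
      vals <- t(vapply(strsplit(trimws(chunk), "\\s+"),
                       function(tk) as.numeric(tk[seq_along(pn)]),
                       numeric(length(pn))))
      colnames(vals) <- pn
      vertices <- vals[, c("x", "y", "z"), drop = FALSE]
    } else if (el$name == "face") {
      faces <- do.call(rbind, lapply(strsplit(trimws(chunk), "\\s+"), function(tk) {
        n <- as.integer(tk[1L])
        idx <- as.integer(tk[1L + seq_len(n)])
        fan_triangulate(idx)
      }))
    }
  }
  surface_mesh(vertices, faces + 1L, provenance = sprintf("ply-ascii:%s", path_base(path)))
}

parse_ply_binary <- function(con, elements, path) {
  read_scalar <- function(type, n = 1L) {
    sz <- ply_type_size[[type]]
    if (is.null(sz)) stop(sprintf("'%s': unsupported PLY type '%s'", path, type))
    what <- if (type %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
    out <- readBin(con, what, n = n, size = sz, endian = "little",
                   signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    if (length(out) < n) stop(sprintf("'%s': truncated binary PLY", path))
    out
  }
  vertices <- NULL; faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      pn <- names(el$props)
      types <- vapply(el$props, function(p) p$type, character(1))
      if (length(unique(types)) == 1L && all(!vapply(el$props, `[[`, logical(1), "list"))) {
        vals <- matrix(read_scalar(types[1L], el$count * length(pn)),
                       ncol = length(pn), byrow = TRUE)
      } else {
        vals <- matrix(0, nrow = el$count, ncol = length(pn))
        for (i in seq_len(el$count)) {
          for (j in seq_along(pn)) vals[i, j] <- read_scalar(types[j])
        }
      }
      colnames(vals) <- pn
      vertices <- vals[, c("x", "y", "z"), drop = FALSE]
    } else if (el$name == "face") {
      lp <- el$props[[1L]]
      if (!isTRUE(lp$list)) stop(sprintf("'%s': PLY face element is not a list property", path))
      flist <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        n <- read_scalar(lp$count_type)
        flist[[i]] <- fan_triangulate(read_scalar(lp$type, n))
      }
      faces <- do.call(rbind, flist)
    } else {
      # skip unknown scalar-only elements
      types <- vapply(el$props, function(p) p$type, character(1))
      for (i in seq_len(el$count)) for (type in types) read_scalar(type)
    }
  }
  surface_mesh(vertices, faces + 1L, provenance = sprintf("ply-binary:%s", path_base(path)))
}

path_base <- function(path) basename(path)

# 0-based polygon index vector -> rows of 0-based triangles.
fan_triangulate <- function(idx) {
  if (length(idx) < 3L) stop("face with fewer than 3 vertices")
  if (length(idx) == 3L) return(matrix(idx, nrow = 1L))
  cbind(idx[1L], idx[seq(2L, length(idx) - 1L)], idx[seq(3L, length(idx))])
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment cochleoplan surface mesh (mm)",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines)
  flines <- grep("^f\\s", lines)
  if (length(vlines) == 0L || length(flines) == 0L) {
    stop(sprintf("'%s': OBJ file has no vertices or no faces", path))
  }
  verts <- t(vapply(strsplit(trimws(lines[vlines]), "\\s+"),
                    function(tk) as.numeric(tk[2:4]), numeric(3)))
  faces <- do.call(rbind, lapply(strsplit(trimws(lines[flines]), "\\s+"), function(tk) {
    idx <- as.integer(sub("/.*$", "", tk[-1L]))
    if (any(is.na(idx)) || any(idx < 0L)) {
      stop(sprintf("'%s': unsupported OBJ face record '%s'", path, paste(tk, collapse = " ")))
    }
    fan_triangulate(idx - 1L)
  }))
  surface_mesh(verts, faces + 1L, provenance = sprintf("obj:%s", basename(path)))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# cochleoplan surface mesh (mm)", con)
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
}
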
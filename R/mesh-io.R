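#' Construct a TriangleMesh
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param faces matrix of 1-based vertex index triples.
#' @param vertexIndex optional parent-mesh vertex indices.
#' @return a \linkS4class{TriangleMesh}.
#' @examples
#' m <- TriangleMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(1:3))
#' nFaces(m)
#' @export
TriangleMesh <- function(vertices, faces, vertexIndex = integer(0)) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, dimnames = NULL)
  new("TriangleMesh", vertices = vertices, faces = faces,
      vertexIndex = as.integer(vertexIndex))
}

.format_error <- function(fmt, ...) {
  stop(sprintf(paste0("mesh format error: ", fmt), ...), call. = FALSE)
}

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary-little-endian PLY with float/double vertex
#' coordinates (extra scalar vertex properties are skipped) and Wavefront OBJ
#' \code{v}/\code{f} records. Polygonal faces are fan-triangulated from their
#' first vertex. Coordinates are interpreted as millimetres; vertex order is
#' preserved.
#'
#' @param path file path.
#' @param format "ply", "obj" or "auto" (by file extension, falling back to
#'   content sniffing).
#' @return a \linkS4class{TriangleMesh}.
#' @seealso [writeMesh()]
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) .format_error("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "obj") "obj"
              else if (ext == "ply") "ply"
              else {
                head <- readBin(path, "raw", n = 3L)
                if (identical(rawToChar(head), "ply")) "ply" else "obj"
              }
  }
  mesh <- if (format == "ply") .read_ply(path) else .read_obj(path)
  if (nrow(mesh@faces) == 0L) .format_error("no faces in %s", path)
  mesh
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # ---- header ----
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) .format_error("missing 'ply' magic")
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) .format_error("unterminated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) .format_error("property before element")
      if (tok[2] == "list") {
        p <- list(name = tok[5], list = TRUE, count_type = tok[3],
                  item_type = tok[4])
      } else {
        p <- list(name = tok[3], list = FALSE, type = tok[2])
      }
      elements[[cur]]$props <- c(elements[[cur]]$props, list(p))
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt)) .format_error("PLY header has no format line")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    .format_error("unsupported PLY format '%s'", fmt)
  if (is.null(elements$vertex) || is.null(elements$face))
    .format_error("PLY must declare vertex and face elements")

  if (fmt == "ascii") {
    body <- readLines(con)
    out <- .parse_ply_ascii(body, elements)
  } else {
    out <- .parse_ply_binary(con, elements)
  }
  v <- out$vertices
  f <- out$faces
  if (nrow(f) > 0 && (min(f) < 0L || max(f) >= nrow(v)))
    .format_error("face references vertex %d but only %d vertices exist",
                  if (nrow(f) > 0) max(f) else -1L, nrow(v))
  TriangleMesh(v, f + 1L)
}

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type) {
  sz <- .ply_type_size[[type]]
  if (is.null(sz)) .format_error("unknown PLY type '%s'", type)
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", n = 1L, size = sz, endian = "little",
            signed = !(sz < 4L && grepl("^u", type)))
}

.parse_ply_binary <- function(con, elements) {
  vertices <- NULL; facelist <- NULL
  for (el_name in names(elements)) {
    el <- elements[[el_name]]
    props <- el$props
    if (el_name == "vertex") {
      want <- match(c("x", "y", "z"), vapply(props, `[[`, "", "name"))
      if (anyNA(want)) .format_error("vertex element lacks x/y/z")
      # fast path: contiguous non-list properties, read as one block
      if (!any(vapply(props, `[[`, TRUE, "list"))) {
        sizes <- vapply(props, function(p) .ply_type_size[[p$type]], 1L)
        stride <- sum(sizes)
        raw <- readBin(con, "raw", n = el$count * stride)
        if (length(raw) < el$count * stride)
          .format_error("truncated vertex data")
        vertices <- matrix(0, el$count, 3)
        offs <- c(0L, cumsum(sizes))
        for (k in 1:3) {
          p <- props[[want[k]]]
          sz <- .ply_type_size[[p$type]]
          sel <- as.vector(outer(seq_len(sz), stride * (seq_len(el$count) - 1L)
                                 + offs[want[k]], `+`))
          col_raw <- raw[sel]
          vertices[, k] <- if (p$type %in% c("float", "float32"))
            readBin(col_raw, "double", n = el$count, size = 4L,
                    endian = "little")
          else if (p$type %in% c("double", "float64"))
            readBin(col_raw, "double", n = el$count, size = 8L,
                    endian = "little")
          else readBin(col_raw, "integer", n = el$count, size = sz,
                       endian = "little")
        }
      } else .format_error("list-typed vertex properties are not supported")
    } else if (el_name == "face") {
      facelist <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        row <- NULL
        for (p in props) {
          if (p$list) {
            cnt <- .ply_read_scalar(con, p$count_type)
            items <- vapply(seq_len(cnt), function(j)
              .ply_read_scalar(con, p$item_type), 0)
            if (p$name %in% c("vertex_indices", "vertex_index")) row <- items
          } else .ply_read_scalar(con, p$type)
        }
        if (is.null(row) || length(row) < 3L)
          .format_error("face record %d has fewer than 3 indices", i)
        facelist[[i]] <- row
      }
    } else {
      # skip unknown fixed-size elements
      if (any(vapply(props, `[[`, TRUE, "list")))
        .format_error("cannot skip list element '%s'", el_name)
      stride <- sum(vapply(props, function(p) .ply_type_size[[p$type]], 1L))
      readBin(con, "raw", n = el$count * stride)
    }
  }
  list(vertices = vertices, faces = .fan_triangulate(facelist))
}

.parse_ply_ascii <- function(body, elements) {
  body <- body[nzchar(trimws(body))]
  pos <- 0L
  vertices <- NULL; facelist <- NULL
  for (el_name in names(elements)) {
    el <- elements[[el_name]]
    lines <- body[pos + seq_len(el$count)]
    if (anyNA(lines)) .format_error("truncated element '%s'", el_name)
    pos <- pos + el$count
    toks <- strsplit(trimws(lines), "\\s+")
    if (el_name == "vertex") {
      nm <- vapply(el$props, `[[`, "", "name")
      want <- match(c("x", "y", "z"), nm)
      if (anyNA(want)) .format_error("vertex element lacks x/y/z")
      num <- vapply(toks, function(t) as.numeric(t[want]), numeric(3))
      vertices <- t(num)
    } else if (el_name == "face") {
      facelist <- lapply(seq_along(toks), function(i) {
        t <- suppressWarnings(as.numeric(toks[[i]]))
        cnt <- t[1]
        if (is.na(cnt) || length(t) < cnt + 1 || cnt < 3)
          .format_error("face record %d is malformed", i)
        t[1 + seq_len(cnt)]
      })
    }
  }
  list(vertices = vertices, faces = .fan_triangulate(facelist))
}

# fan-triangulate polygonal records (0-based index vectors) into an m x 3
# integer matrix of 0-based triangles
.fan_triangulate <- function(facelist) {
  if (is.null(facelist) || length(facelist) == 0L)
    return(matrix(integer(0), 0, 3))
  tri <- lapply(facelist, function(row) {
    k <- length(row)
    cbind(row[1], row[2:(k - 1)], row[3:k])
  })
  out <- do.call(rbind, tri)
  storage.mode(out) <- "integer"
  out
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) .format_error("OBJ has no vertex records")
  vtok <- strsplit(vlines, "\\s+")
  v <- t(vapply(vtok, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(v)) .format_error("unparseable OBJ vertex record")
  facelist <- lapply(seq_along(flines), function(i) {
    t <- strsplit(flines[[i]], "\\s+")[[1]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", t)))
    if (anyNA(idx) || length(idx) < 3L)
      .format_error("unparseable OBJ face record %d: '%s'", i, flines[[i]])
    neg <- idx < 0L
    idx[neg] <- nrow(v) + 1L + idx[neg]
    if (any(idx < 1L | idx > nrow(v)))
      .format_error("OBJ face record %d references vertex %d but only %d vertices exist",
                    i, max(idx), nrow(v))
    idx - 1L
  })
  TriangleMesh(v, .fan_triangulate(facelist) + 1L)
}

#' Write a triangle mesh to PLY or OBJ
#'
#' PLY is written as ASCII with full double precision; OBJ uses \code{v} and
#' \code{f} records.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output file path.
#' @param format "ply", "obj" or "auto" (by extension).
#' @return \code{path}, invisibly.
#' @seealso [readMesh()]
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj")) {
  stopifnot(is(mesh, "TriangleMesh"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "obj") "obj" else "ply"
  v <- mesh@vertices
  f <- mesh@faces
  if (format == "ply") {
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property double x", "property double y", "property double z",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    vlines <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    flines <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(header, vlines, flines), path)
  } else {
    vlines <- sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    flines <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c(vlines, flines), path)
  }
  invisible(path)
}
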
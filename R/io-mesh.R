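#' Read a tooth mesh from PLY, OBJ or STL
#'
#' Supports ASCII and binary (little/big endian) PLY, ASCII OBJ
#' (polygonal faces are fan-triangulated) and ASCII or binary STL.
#' STL files carry no shared-vertex topology, so identical vertex
#' records are merged on read.  Coordinates are taken as-is from the
#' file and assumed to be millimeters; no unit inference is performed.
#'
#' @param path path to a `.ply`, `.obj` or `.stl` file.
#' @param name tooth name; defaults to the file name without extension.
#' @param label integer segment label for the resulting mesh.
#' @return a [tooth_mesh()].
#' @export
read_mesh <- function(path, name = NULL, label = 1L) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  vf <- tryCatch(
    switch(ext,
           ply = read_ply(path),
           obj = read_obj(path),
           stl = read_stl(path),
           stop(sprintf("unsupported mesh format '.%s': %s", ext, path))),
    error = function(e) stop(sprintf("failed to read mesh %s: %s",
                                     path, conditionMessage(e)), call. = FALSE))
  tooth_mesh(vf$vertices, vf$faces, name = name, label = label)
}

#' Write a tooth mesh to PLY, OBJ or STL
#'
#' The format is chosen from the file extension: `.ply` is written as
#' ASCII PLY, `.obj` as ASCII OBJ, `.stl` as binary (little-endian) STL.
#'
#' @param mesh a [tooth_mesh()].
#' @param path output path ending in `.ply`, `.obj` or `.stl`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  validate_tooth_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stl = write_stl_binary(mesh, path),
         stop(sprintf("unsupported mesh format '.%s': %s", ext, path)))
  invisible(path)
}

## ---- PLY ------------------------------------------------------------------

ply_type_info <- function(type) {
  switch(type,
         char = , int8 = list(size = 1L, what = "integer", signed = TRUE),
         uchar = , uint8 = list(size = 1L, what = "integer", signed = FALSE),
         short = , int16 = list(size = 2L, what = "integer", signed = TRUE),
         ushort = , uint16 = list(size = 2L, what = "integer", signed = FALSE),
         int = , int32 = list(size = 4L, what = "integer", signed = TRUE),
         uint = , uint32 = list(size = 4L, what = "integer", signed = TRUE),
         float = , float32 = list(size = 4L, what = "double", signed = TRUE),
         double = , float64 = list(size = 8L, what = "double", signed = TRUE),
         stop(sprintf("unsupported PLY property type '%s'", type)))
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # locate the end_header line on raw bytes (the body may contain NULs)
  m <- grepRaw("end_header", raw, fixed = TRUE)
  if (!length(m)) stop("not a PLY file (no end_header)")
  nl <- m[1] + 9L + which(raw[(m[1] + 10L):min(length(raw), m[1] + 12L)] == as.raw(10L))[1]
  if (is.na(nl)) stop("malformed PLY header")
  hdr_len <- nl
  header <- strsplit(rawToChar(raw[seq_len(hdr_len)]), "\r?\n")[[1]]
  if (!identical(trimws(header[1]), "ply")) stop("not a PLY file (missing magic)")

  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("PLY header has no format line")
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  endian <- if (fmt == "binary_big_endian") "big" else "little"

  # parse element/property declarations in order
  elements <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3], value_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex or face element")

  if (fmt == "ascii") {
    body <- rawToChar(raw[(hdr_len + 1L):length(raw)])
    lines <- strsplit(body, "\r?\n")[[1]]
    lines <- lines[nzchar(trimws(lines))]
    ptr <- 0L
    verts <- NULL; faces <- NULL
    for (el in elements) {
      chunk <- lines[ptr + seq_len(el$n)]
      ptr <- ptr + el$n
      if (el$name == "vertex") {
        pn <- names(el$props)
        vals <- matrix(as.numeric(unlist(strsplit(trimws(chunk), "\\s+"))),
                       nrow = el$n, byrow = TRUE)
        verts <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(chunk, function(ln) {
          v <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
          idx <- v[2:(1 + v[1])] + 1L
          fan_triangulate(idx)
        }))
      }
    }
  } else {
    off <- hdr_len  # 0-based offset of first body byte
    verts <- NULL; faces <- NULL
    for (el in elements) {
      is_list <- vapply(el$props, function(p) p$list, logical(1))
      if (!any(is_list)) {
        sizes <- vapply(names(el$props), function(nm) ply_type_info(el$props[[nm]]$type)$size, integer(1))
        stride <- sum(sizes)
        offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
        block <- raw[off + seq_len(el$n * stride)]
        if (el$name == "vertex") {
          getcol <- function(nm) {
            j <- match(nm, names(el$props))
            ti <- ply_type_info(el$props[[nm]]$type)
            idx <- as.vector(outer(seq_len(ti$size), (0:(el$n - 1L)) * stride + offs[j], `+`))
            readBin(block[idx], ti$what, n = el$n, size = ti$size,
                    endian = endian, signed = ti$signed)
          }
          verts <- cbind(getcol("x"), getcol("y"), getcol("z"))
        }
        off <- off + el$n * stride
      } else {
        # element with a list property: walk records (face element)
        if (length(el$props) != 1L)
          stop("PLY list elements with extra properties are not supported")
        p <- el$props[[1]]
        ct <- ply_type_info(p$count_type); vt <- ply_type_info(p$value_type)
        fl <- vector("list", el$n)
        for (i in seq_len(el$n)) {
          cnt <- readBin(raw[off + seq_len(ct$size)], ct$what, n = 1L,
                         size = ct$size, endian = endian, signed = ct$signed)
          off <- off + ct$size
          idx <- readBin(raw[off + seq_len(cnt * vt$size)], vt$what, n = cnt,
                         size = vt$size, endian = endian, signed = vt$signed)
          off <- off + cnt * vt$size
          fl[[i]] <- fan_triangulate(as.integer(idx) + 1L)
        }
        if (el$name == "face") faces <- do.call(rbind, fl)
      }
    }
  }
  list(vertices = verts, faces = faces)
}

# fan-triangulate a polygon given as a vector of vertex indices
fan_triangulate <- function(idx) {
  n <- length(idx)
  if (n < 3L) stop("face with fewer than 3 vertices")
  if (n == 3L) return(matrix(idx, 1L, 3L))
  cbind(idx[1], idx[2:(n - 1L)], idx[3:n])
}

write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment tooth '%s' label %d", mesh$name, mesh$label),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

## ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[grepl("^v\\s", lines)]
  flines <- lines[grepl("^f\\s", lines)]
  if (!length(vlines)) stop("OBJ file has no vertices")
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(tok) {
    idx <- as.integer(sub("/.*$", "", tok[-1]))
    if (any(is.na(idx)) || any(idx < 0)) stop("unsupported OBJ face indexing")
    fan_triangulate(idx)
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("# tooth '%s' label %d", mesh$name, mesh$label), con)
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

## ---- STL ------------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(raw[81:84], "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && 84 + 50 * ntri == sz) is_binary <- TRUE
  }
  if (is_binary) {
    ntri <- readBin(raw[81:84], "integer", n = 1L, size = 4L, endian = "little")
    # vertex bytes of triangle i: 84 + (i-1)*50 + 12 .. + 48
    idx <- as.vector(outer(seq_len(36L), 84L + (0:(ntri - 1L)) * 50L + 12L, `+`))
    vals <- readBin(raw[idx], "double", n = 9L * ntri, size = 4L, endian = "little")
    tri_verts <- matrix(vals, ncol = 3L, byrow = TRUE)
  } else {
    txt <- rawToChar(raw)
    lines <- strsplit(txt, "\r?\n")[[1]]
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vlines) || length(vlines) %% 3L != 0L)
      stop("malformed ASCII STL")
    tri_verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(tok)
      as.numeric(tok[2:4])))
  }
  # merge duplicated vertex records (STL stores them per triangle)
  key <- paste(tri_verts[, 1], tri_verts[, 2], tri_verts[, 3])
  ids <- match(key, unique(key))
  verts <- tri_verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(ids, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  nrm <- cross_mm(b - a, c_ - a)
  len <- sqrt(rowSums(nrm * nrm))
  len[len < .Machine$double.eps] <- 1
  nrm <- nrm / len
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", sprintf("dentition tooth '%s'", mesh$name)))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], c_[i, ])), con,
             size = 4L, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}
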
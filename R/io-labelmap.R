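#' Read a labelled segmentation volume as one mesh per tooth
#'
#' Reads an integer labelmap (NRRD or NIfTI) in which every nonzero
#' label marks one tooth, and extracts one closed triangle surface per
#' label.  Extraction is exact voxel-boundary ("cuberille")
#' triangulation of the binary mask at threshold 0.5, with no smoothing,
#' so results are fully deterministic; vertices are emitted in physical
#' (mm) coordinates using the volume's spacing, origin and direction.
#'
#' @param path path to a `.nrrd`/`.nhdr` or `.nii`/`.nii.gz` volume.
#' @param spacing_override optional numeric length-3 vector of voxel
#'   spacings (mm) replacing the file's direction matrix (origin kept).
#' @return a list of [tooth_mesh()] objects, one per nonzero label in
#'   increasing label order, named `tooth_<label>`.
#' @export
read_labelmap <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop(sprintf("labelmap file not found: %s", path))
  lower <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", lower)) {
    lv <- read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vol <- as.array(img)
    if (length(dim(vol)) != 3) stop("labelmap must be a 3D volume")
    lv <- list(vol = vol, affine = structure(RNifti::xform(img), class = NULL))
  } else {
    stop(sprintf("unsupported labelmap format: %s", path))
  }
  vol <- lv$vol
  affine <- lv$affine  # 4x4; world = affine %*% c(i,j,k,1), 0-based indices
  if (!is.null(spacing_override)) {
    spacing_override <- as.numeric(spacing_override)
    if (length(spacing_override) != 3 || any(!is.finite(spacing_override)) ||
        any(spacing_override <= 0))
      stop("spacing_override must be 3 positive numbers (mm)")
    affine[1:3, 1:3] <- diag(spacing_override)
  }
  if (any(!is.finite(vol)) || any(vol != round(vol)) || any(vol < 0))
    stop("labelmap must contain non-negative integer labels only")
  labels <- sort(unique(as.vector(vol[vol > 0])))
  out <- list()
  for (lab in labels) {
    mesh <- tryCatch(
      label_surface(vol == lab, affine, label = as.integer(lab)),
      error = function(e) {
        warning(sprintf("label %d produced no usable surface (%s); skipped",
                        as.integer(lab), conditionMessage(e)))
        NULL
      })
    if (!is.null(mesh)) out[[sprintf("tooth_%d", as.integer(lab))]] <- mesh
  }
  out
}

# shift a logical 3D array by one voxel along axis a (s = +1/-1),
# filling the vacated slice with FALSE: result[i] = m[i + s] along a.
shift_along <- function(m, a, s) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (s > 0) { dst[[a]] <- seq_len(d[a] - 1L); src[[a]] <- 2:d[a] }
  else       { dst[[a]] <- 2:d[a];             src[[a]] <- seq_len(d[a] - 1L) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

# exact boundary surface of a voxel mask, in world coordinates
label_surface <- function(mask, affine, label = 1L) {
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  quads <- list()  # each: n x 3 matrix of doubled half-integer corner coords
  for (a in 1:3) {
    for (s in c(1L, -1L)) {
      exposed <- mask & !shift_along(mask, a, s)
      if (!any(exposed)) next
      ijk <- which(exposed, arr.ind = TRUE) - 1L  # 0-based voxel centers
      b <- (a %% 3L) + 1L
      c_ <- (b %% 3L) + 1L
      # quad corners at center + s*0.5*e_a +/- 0.5*e_b +/- 0.5*e_c,
      # stored doubled so all coordinates are integers (exact dedup)
      base2 <- 2L * ijk
      base2[, a] <- base2[, a] + s
      mk <- function(db, dc) {
        q <- base2; q[, b] <- q[, b] + db; q[, c_] <- q[, c_] + dc; q
      }
      # wind corners consistently (outward for s=+1, reversed for s=-1)
      if (s > 0) corner_order <- list(mk(-1L, -1L), mk(1L, -1L), mk(1L, 1L), mk(-1L, 1L))
      else       corner_order <- list(mk(-1L, -1L), mk(-1L, 1L), mk(1L, 1L), mk(1L, -1L))
      quads[[length(quads) + 1L]] <- corner_order
    }
  }
  if (!length(quads)) stop("mask has no boundary faces")
  # flatten: corners matrix (4*nq x 3), quad i occupies rows (i-1)*4 + 1:4
  corners <- do.call(rbind, lapply(quads, function(co) {
    nq <- nrow(co[[1]])
    m <- matrix(0L, 4L * nq, 3L)
    for (j in 1:4) m[seq(j, by = 4L, length.out = nq), ] <- co[[j]]
    m
  }))
  key <- paste(corners[, 1], corners[, 2], corners[, 3])
  ids <- match(key, unique(key))
  uniq <- corners[!duplicated(key), , drop = FALSE]
  nq <- nrow(corners) / 4L
  i1 <- ids[seq(1L, by = 4L, length.out = nq)]
  i2 <- ids[seq(2L, by = 4L, length.out = nq)]
  i3 <- ids[seq(3L, by = 4L, length.out = nq)]
  i4 <- ids[seq(4L, by = 4L, length.out = nq)]
  faces <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
  # doubled index coords -> continuous index -> world
  idxc <- uniq / 2
  world <- t(affine[1:3, 1:3] %*% t(idxc)) +
    matrix(affine[1:3, 4], nrow(idxc), 3, byrow = TRUE)
  tooth_mesh(world, faces, name = sprintf("tooth_%d", label), label = label)
}

## ---- minimal NRRD reader --------------------------------------------------

nrrd_type_info <- function(type) {
  switch(tolower(type),
         "signed char" = , "int8" = , "int8_t" = list(size = 1L, what = "integer", signed = TRUE),
         "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" = list(size = 1L, what = "integer", signed = FALSE),
         "short" = , "signed short" = , "int16" = , "int16_t" = list(size = 2L, what = "integer", signed = TRUE),
         "ushort" = , "unsigned short" = , "uint16" = , "uint16_t" = list(size = 2L, what = "integer", signed = FALSE),
         "int" = , "signed int" = , "int32" = , "int32_t" = list(size = 4L, what = "integer", signed = TRUE),
         "uint" = , "unsigned int" = , "uint32" = , "uint32_t" = list(size = 4L, what = "integer", signed = TRUE),
         "float" = list(size = 4L, what = "double", signed = TRUE),
         "double" = list(size = 8L, what = "double", signed = TRUE),
         stop(sprintf("unsupported NRRD type '%s'", type)))
}

parse_nrrd_vectors <- function(s) {
  # "(a,b,c) (d,e,f) ..." with possible "none" entries
  toks <- regmatches(s, gregexpr("\\(([^)]*)\\)|none", s))[[1]]
  lapply(toks, function(t) {
    if (t == "none") return(NULL)
    as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]])
  })
}

# Reads a 3D NRRD volume (attached data; raw, gzip or text encodings).
# Returns list(vol, affine) with world = affine %*% c(i,j,k,1), 0-based.
read_nrrd <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # header is text up to the first blank line
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    line_len <- p - prev - 1L
    if (line_len == 0L || (line_len == 1L && raw[prev + 1L] == as.raw(13L))) {
      hdr_end <- p; break
    }
    prev <- p
  }
  if (is.na(hdr_end)) stop("not a valid NRRD file (no blank line after header)")
  header <- strsplit(rawToChar(raw[seq_len(hdr_end - 1L)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", header[1])) stop("not a NRRD file (missing magic)")
  fields <- list()
  for (line in header[-1]) {
    if (grepl("^#", line) || !nzchar(trimws(line))) next
    pos <- regexpr(":=?", line)
    key <- tolower(trimws(substr(line, 1L, pos - 1L)))
    val <- trimws(substr(line, pos + attr(pos, "match.length"), nchar(line)))
    fields[[key]] <- val
  }
  if (!is.null(fields[["data file"]]) || !is.null(fields[["datafile"]]))
    stop("detached NRRD data files are not supported")
  dimn <- as.integer(fields$dimension %||% stop("NRRD header missing dimension"))
  if (dimn != 3L) stop("only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  ti <- nrrd_type_info(fields$type %||% stop("NRRD header missing type"))
  endian <- if (identical(tolower(fields$endian %||% "little"), "big")) "big" else "little"
  enc <- tolower(fields$encoding %||% "raw")
  n <- prod(sizes)
  # hdr_end points at the blank line's newline; data starts right after it
  payload <- raw[(hdr_end + 1L):length(raw)]
  vals <- switch(enc,
    raw = readBin(payload, ti$what, n = n, size = ti$size,
                  endian = endian, signed = ti$signed),
    gzip = , gz = readBin(memDecompress(payload, type = "gzip"), ti$what, n = n,
                          size = ti$size, endian = endian, signed = ti$signed),
    ascii = , text = , txt = as.numeric(scan(text = rawToChar(payload),
                                             what = character(), quiet = TRUE)),
    stop(sprintf("unsupported NRRD encoding '%s'", enc)))
  if (length(vals) < n) stop("NRRD data shorter than promised by sizes")
  vol <- array(vals[seq_len(n)], dim = sizes)  # first axis fastest, as in NRRD
  D <- diag(3)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    vecs <- Filter(Negate(is.null), vecs)
    if (length(vecs) == 3L) D <- do.call(cbind, vecs)
  } else if (!is.null(fields$spacings)) {
    D <- diag(as.numeric(strsplit(fields$spacings, "\\s+")[[1]])[1:3])
  }
  if (!is.null(fields[["space origin"]])) {
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  }
  affine <- rbind(cbind(D, origin), c(0, 0, 0, 1))
  dimnames(affine) <- NULL
  list(vol = vol, affine = affine)
}
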
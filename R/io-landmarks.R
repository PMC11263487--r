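#' Read jaw landmarks from FCSV or JSON
#'
#' FCSV is the 3D Slicer markups fiducial format: comma-separated rows
#' with a `# columns = id,x,y,z,...` header.  The coordinate-system
#' header (`# CoordinateSystem = LPS|RAS`, or the numeric codes 0 = RAS,
#' 1 = LPS) is honored and points are converted to the package's single
#' internal right-handed convention (RAS): LPS coordinates have their
#' first two axes negated.  When the header is absent, LPS is assumed
#' (the default of recent Slicer versions).  JSON files are a plain
#' object mapping landmark labels to `[x, y, z]` and are taken to be in
#' the internal convention already.
#'
#' Landmark labels must be drawn from `jaw_joint`, `jaw_tip`,
#' `insertion_1..3`, `origin_1..3`.
#'
#' @param path path to a `.fcsv` or `.json` file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  points <- switch(ext,
                   fcsv = read_fcsv(path),
                   json = {
                     obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
                     lapply(obj, as.numeric)
                   },
                   stop(sprintf("unsupported landmark format '.%s': %s", ext, path)))
  landmark_set(points)
}

read_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^#", lines, value = TRUE)
  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) stop(sprintf("FCSV file has no data rows: %s", path))
  cs <- "LPS"  # Slicer default when no header is present
  cs_line <- grep("CoordinateSystem", comments, value = TRUE)
  if (length(cs_line)) {
    val <- trimws(sub(".*=", "", cs_line[1]))
    cs <- switch(val, "0" = "RAS", "1" = "LPS", toupper(val))
  }
  if (!cs %in% c("RAS", "LPS"))
    stop(sprintf("unsupported FCSV coordinate system '%s'", cs))
  col_line <- grep("columns\\s*=", comments, value = TRUE)
  cols <- if (length(col_line)) {
    strsplit(trimws(sub(".*=", "", col_line[1])), ",")[[1]]
  } else {
    c("id", "x", "y", "z", "ow", "ox", "oy", "oz", "vis", "sel", "lock",
      "label", "desc", "associatedNodeID")
  }
  df <- read.csv(text = paste(data_lines, collapse = "\n"), header = FALSE,
                 col.names = trimws(cols), stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "label")
  if (!all(need %in% names(df)))
    stop("FCSV columns must include x, y, z and label")
  pts <- lapply(seq_len(nrow(df)), function(i) {
    p <- as.numeric(df[i, c("x", "y", "z")])
    if (cs == "LPS") p[1:2] <- -p[1:2]  # LPS -> RAS
    p
  })
  names(pts) <- trimws(as.character(df$label))
  pts
}

#' Write jaw landmarks to FCSV or JSON
#'
#' The FCSV writer emits a Slicer markups fiducial file declaring LPS
#' coordinates (converting from the internal convention); the JSON
#' writer emits the internal coordinates directly.  A read of the
#' written file reproduces the landmark set exactly.
#'
#' @param landmarks a [landmark_set()].
#' @param path output path ending in `.fcsv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  if (!inherits(landmarks, "landmark_set"))
    landmarks <- landmark_set(landmarks)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lapply(landmarks, as.numeric), path,
                         auto_unbox = FALSE, digits = NA)
  } else if (ext == "fcsv") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("# Markups fiducial file version = 4.11",
                 "# CoordinateSystem = LPS",
                 "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID"),
               con)
    nm <- names(landmarks)
    for (i in seq_along(landmarks)) {
      p <- landmarks[[i]]
      writeLines(sprintf("vtkMRMLMarkupsFiducialNode_%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,,",
                         i - 1L, -p[1], -p[2], p[3], nm[i]), con)
    }
  } else {
    stop(sprintf("unsupported landmark format '.%s': %s", ext, path))
  }
  invisible(path)
}
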
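#' Column order of the trait table
#'
#' Returns the documented, stable column order used by
#' [write_traits_table()].  Per-muscle columns (`in_lever_k`,
#' `insertion_angle_k`, `mechanical_advantage_k`) are interleaved after
#' the geometric traits for `n_muscles` muscles.
#'
#' @param n_muscles number of closing muscles in the model.
#' @return character vector of column names.
#' @export
traits_columns <- function(n_muscles = 1L) {
  per_muscle <- as.vector(t(outer(c("in_lever_", "insertion_angle_", "mechanical_advantage_"),
                                  seq_len(n_muscles), paste0)))
  c("tooth", "label", "ok", "jaw_id", "side",
    "jaw_length", "position", "out_lever",
    "height", "width", "aspect_ratio", "surface_area",
    per_muscle, "force", "stress",
    "tip_x", "tip_y", "tip_z", "base_x", "base_y", "base_z", "note")
}

#' Write a per-tooth trait table to CSV
#'
#' One row per tooth, one column per trait, in the stable order given by
#' [traits_columns()]; jaw-level fields (jaw length, in-levers) are
#' repeated on every row.  UTF-8, comma-delimited, `.` decimal, header
#' row always present; names containing commas are quoted per the CSV
#' standard.
#'
#' @param traits a trait data.frame from [compute_dentition()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits_table <- function(traits, path) {
  if (!is.data.frame(traits) || nrow(traits) == 0)
    stop("trait table must be a non-empty data.frame")
  nm <- sum(grepl("^in_lever_", names(traits)))
  want <- traits_columns(max(nm, 1L))
  cols <- c(intersect(want, names(traits)), setdiff(names(traits), want))
  write.csv(traits[, cols, drop = FALSE], path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-tooth trait table written by [write_traits_table()]
#'
#' @param path CSV path.
#' @return a data.frame; numeric columns are restored at full precision.
#' @export
read_traits_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("trait table not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
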
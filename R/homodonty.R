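#' Residual stresses of a dentition
#'
#' Each tooth's stress divided by the jaw's median stress, a
#' dimensionless ratio.  The ratio (rather than a difference) makes the
#' residuals invariant to any common rescaling of the stresses.
#'
#' @param stresses numeric vector of per-tooth stresses (N/mm^2), all
#'   positive, length >= 2.
#' @return numeric vector of residuals with median 1.
#' @export
residual_stress <- function(stresses) {
  stresses <- as.numeric(stresses)
  if (length(stresses) < 2) stop("need at least 2 stresses")
  if (any(!is.finite(stresses)) || any(stresses <= 0))
    stop("all stresses must be positive and finite")
  stresses / median(stresses)
}

#' Bootstrap null distribution of residual stresses
#'
#' Each replicate draws half the teeth (floor(n/2)) without replacement
#' and normalizes the subsample by its own median; all subsampled
#' residuals are pooled.  The pool approximates the distribution of
#' residuals expected from sampling variation alone, against which the
#' observed residuals are thresholded.
#'
#' @param stresses numeric vector of per-tooth stresses (> 0), n >= 4.
#' @param reps number of bootstrap replicates (default 10000).
#' @param seed optional integer seed; the caller's RNG state is left
#'   untouched.
#' @return numeric vector of pooled residuals, length `reps * floor(n/2)`.
#' @export
bootstrap_null <- function(stresses, reps = 10000, seed = NULL) {
  stresses <- as.numeric(stresses)
  n <- length(stresses)
  if (n < 4) stop("bootstrap null needs at least 4 teeth (half-subsample degenerate)")
  if (any(!is.finite(stresses)) || any(stresses <= 0))
    stop("all stresses must be positive and finite")
  if (reps < 1) stop("reps must be >= 1")
  m <- n %/% 2L
  with_local_seed(seed, {
    pool <- numeric(reps * m)
    for (r in seq_len(reps)) {
      sub <- stresses[sample.int(n, m)]
      pool[((r - 1L) * m + 1L):(r * m)] <- sub / median(sub)
    }
    pool
  })
}

# exact optimal 2-medoids of a 1-D sample.
# In one dimension an optimal k-medoids partition is contiguous in sorted
# order, and the optimal medoid of a contiguous run is its (lower) median
# element; scanning all n-1 split points therefore finds the global
# optimum in O(n log n), with the smallest split as deterministic
# tie-break.  Returns the two medoid values, sorted.
medoids2_1d <- function(x) {
  s <- sort(as.numeric(x))
  n <- length(s)
  if (n < 2) stop("need at least 2 points for 2-medoids")
  cs <- cumsum(s)
  p <- seq_len(n - 1L)                 # split: left = 1..p, right = (p+1)..n
  m1 <- (1L + p) %/% 2L
  m2 <- (p + 1L + n) %/% 2L
  cost1 <- s[m1] * m1 - cs[m1] + (cs[p] - cs[m1]) - s[m1] * (p - m1)
  cost2 <- s[m2] * (m2 - p) - (cs[m2] - cs[p]) + (cs[n] - cs[m2]) - s[m2] * (n - m2)
  best <- which.min(cost1 + cost2)
  c(s[m1[best]], s[m2[best]])
}

#' Heterodonty threshold by 1-D k-medoids clustering
#'
#' For each repeat, a subsample of the bootstrap pool is partitioned
#' into two clusters by exact one-dimensional 2-medoids (global
#' optimum, no PAM seed sensitivity); the repeat's threshold is the
#' mean of the two medoids, and the upper threshold is the mean over
#' repeats.  The lower threshold depends on `two_sided`:
#' `"reciprocal"` (default) runs the identical procedure on the
#' reciprocals of the pool and inverts the result
#' (`lower = 1/upper_of_reciprocals`); `"mirror_log"` mirrors the upper
#' threshold in log space (`lower = 1/upper`); `"off"` sets the lower
#' threshold to 0 (one-sided classification).
#'
#' An all-identical pool is degenerate: both thresholds are set to the
#' common value and the result is flagged, so every tooth classifies as
#' homodont.
#'
#' @param pool numeric vector of pooled residuals from
#'   [bootstrap_null()].
#' @param subsample residuals drawn (without replacement) per repeat,
#'   clipped to the pool size.  Default 5000.
#' @param repeats number of clustering repeats (default 100).
#' @param k number of clusters; only 2 is supported.
#' @param seed optional integer seed.
#' @param two_sided `"reciprocal"`, `"mirror_log"` or `"off"`.
#' @return list with `upper_threshold`, `lower_threshold`, `degenerate`.
#' @export
kmedoids_threshold <- function(pool, subsample = 5000, repeats = 100, k = 2,
                               seed = NULL, two_sided = c("reciprocal", "mirror_log", "off")) {
  two_sided <- match.arg(two_sided)
  pool <- as.numeric(pool)
  if (k != 2) stop("only k = 2 clusters are supported")
  if (length(pool) < 2) stop("pool too small")
  if (max(pool) == min(pool)) {
    return(list(upper_threshold = pool[1], lower_threshold = pool[1],
                degenerate = TRUE))
  }
  ss <- min(subsample, length(pool))
  run_side <- function(values) {
    mean(vapply(seq_len(repeats), function(r) {
      sub <- if (ss == length(values)) values else values[sample.int(length(values), ss)]
      mean(medoids2_1d(sub))
    }, numeric(1)))
  }
  with_local_seed(seed, {
    upper <- run_side(pool)
    lower <- switch(two_sided,
                    reciprocal = 1 / run_side(1 / pool),
                    mirror_log = 1 / upper,
                    off = 0)
    list(upper_threshold = upper, lower_threshold = lower, degenerate = FALSE)
  })
}

#' Classify teeth as functionally homodont or heterodont
#'
#' A tooth is heterodont when its residual stress lies outside the
#' (lower, upper) threshold band.  Two dentition-level summaries are
#' returned: the average squared residual (degree of functional
#' divergence; optionally centered at 1) and the proportion of
#' heterodont teeth (few unique teeth vs regionalization).
#'
#' @param residuals numeric vector from [residual_stress()].
#' @param upper,lower thresholds from [kmedoids_threshold()].
#' @param center `"none"` for mean(residual^2) (default) or `"one"` for
#'   mean((residual - 1)^2).
#' @return list with `class` (character vector, `"homodont"` /
#'   `"heterodont"`), `avg_squared_residual`, `proportion_heterodont`.
#' @export
classify <- function(residuals, upper, lower, center = c("none", "one")) {
  center <- match.arg(center)
  residuals <- as.numeric(residuals)
  het <- residuals > upper | residuals < lower
  list(class = ifelse(het, "heterodont", "homodont"),
       avg_squared_residual = if (center == "none") mean(residuals^2)
                              else mean((residuals - 1)^2),
       proportion_heterodont = sum(het) / length(residuals))
}

#' Functional-homodonty analysis of a trait table
#'
#' Full pipeline per jaw side: residual stresses, bootstrap null
#' distribution, k-medoids thresholds and per-tooth classification.
#' Rows are grouped by the `jaw_id` and `side` columns when present
#' (left and right sides are analyzed separately); a group with fewer
#' than 4 teeth is skipped with a warning.  Each group's RNG substream
#' is derived deterministically from the master seed and the group
#' identifier, so adding a jaw never perturbs the others' results.
#'
#' @param traits data.frame with a positive `stress` column (and
#'   optionally `tooth`, `jaw_id`, `side`); rows with `ok == FALSE` are
#'   dropped first.
#' @param reps bootstrap replicates (default 10000).
#' @param subsample,repeats k-medoids parameters (defaults 5000, 100).
#' @param seed master integer seed (optional).
#' @param two_sided,center see [kmedoids_threshold()] and [classify()].
#' @return an object of class `homodonty_set`: a named list with one
#'   `homodonty_result` per analyzed group, each holding `tooth`,
#'   `residuals`, `class`, `upper_threshold`, `lower_threshold`,
#'   `degenerate`, `avg_squared_residual`, `proportion_heterodont`,
#'   `pool`, `seed` and `params`.
#' @examples
#' jaw <- make_jaw(jaw_spec(n_teeth = 8))
#' traits <- compute_dentition(jaw$meshes, jaw$landmarks)
#' res <- run_homodonty(traits, reps = 200, subsample = 500, repeats = 10,
#'                      seed = 1)
#' summary(res)
#' @export
run_homodonty <- function(traits, reps = 10000, subsample = 5000,
                          repeats = 100, seed = NULL,
                          two_sided = c("reciprocal", "mirror_log", "off"),
                          center = c("none", "one")) {
  two_sided <- match.arg(two_sided)
  center <- match.arg(center)
  if (!is.data.frame(traits) || !"stress" %in% names(traits))
    stop("trait table must contain a 'stress' column")
  if ("ok" %in% names(traits)) traits <- traits[is.na(traits$ok) | traits$ok, , drop = FALSE]
  group <- if (all(c("jaw_id", "side") %in% names(traits))) {
    paste(traits$jaw_id, traits$side, sep = "/")
  } else if ("jaw_id" %in% names(traits)) {
    as.character(traits$jaw_id)
  } else rep("jaw", nrow(traits))
  results <- list()
  for (g in unique(group)) {
    rows <- traits[group == g, , drop = FALSE]
    if (nrow(rows) < 4) {
      warning(sprintf("group '%s' has %d teeth (< 4); skipped", g, nrow(rows)))
      next
    }
    sub_seed <- if (is.null(seed)) NULL else (as.integer(seed) + hash_string(g)) %% 2147483647L
    res <- residual_stress(rows$stress)
    pool <- bootstrap_null(rows$stress, reps = reps, seed = sub_seed)
    thr <- kmedoids_threshold(pool, subsample = subsample, repeats = repeats,
                              seed = if (is.null(sub_seed)) NULL else sub_seed + 1L,
                              two_sided = two_sided)
    cl <- classify(res, thr$upper_threshold, thr$lower_threshold, center = center)
    results[[g]] <- structure(list(
      group = g,
      tooth = if ("tooth" %in% names(rows)) rows$tooth else as.character(seq_len(nrow(rows))),
      residuals = res,
      class = cl$class,
      upper_threshold = thr$upper_threshold,
      lower_threshold = thr$lower_threshold,
      degenerate = thr$degenerate,
      avg_squared_residual = cl$avg_squared_residual,
      proportion_heterodont = cl$proportion_heterodont,
      pool = pool,
      seed = sub_seed,
      params = list(reps = reps, subsample = subsample, repeats = repeats,
                    master_seed = seed, two_sided = two_sided, center = center)),
      class = "homodonty_result")
  }
  if (!length(results)) stop("no group had enough teeth to analyze")
  structure(results, class = "homodonty_set")
}

#' @export
print.homodonty_result <- function(x, ...) {
  cat(sprintf("homodonty_result '%s': %d teeth, thresholds (%.4g, %.4g)%s\n",
              x$group, length(x$residuals), x$lower_threshold, x$upper_threshold,
              if (x$degenerate) " [degenerate pool]" else ""))
  cat(sprintf("  avg squared residual %.4g; proportion heterodont %.3g (%d teeth)\n",
              x$avg_squared_residual, x$proportion_heterodont,
              sum(x$class == "heterodont")))
  invisible(x)
}

#' @export
print.homodonty_set <- function(x, ...) {
  cat(sprintf("homodonty_set with %d group(s):\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}

#' Per-tooth classification table of a homodonty analysis
#'
#' @param x a `homodonty_set` from [run_homodonty()].
#' @return data.frame with columns `group`, `tooth`, `residual`, `class`.
#' @export
homodonty_table <- function(x) {
  if (inherits(x, "homodonty_result")) x <- structure(list(x), class = "homodonty_set")
  do.call(rbind, lapply(unclass(x), function(r)
    data.frame(group = r$group, tooth = r$tooth, residual = r$residuals,
               class = r$class, stringsAsFactors = FALSE)))
}

#' @export
summary.homodonty_set <- function(object, ...) {
  do.call(rbind, lapply(unclass(object), function(r)
    data.frame(group = r$group, n_teeth = length(r$residuals),
               lower_threshold = r$lower_threshold,
               upper_threshold = r$upper_threshold,
               avg_squared_residual = r$avg_squared_residual,
               proportion_heterodont = r$proportion_heterodont,
               degenerate = r$degenerate,
               seed = if (is.null(r$seed)) NA_integer_ else r$seed,
               stringsAsFactors = FALSE)))
}
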
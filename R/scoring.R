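#' Visual Response of one maze
#'
#' The weighted mean tube index of the counted flies,
#' `VR = sum_N N * count_N / sum_N count_N` with N = -4..+4, sign-corrected
#' by the stimulus direction so that following the stimulus is positive.
#'
#' @param record A `tube_counts` record with at least one counted fly.
#' @return The VR, a real number in \[-4, +4\].
#' @examples
#' rec <- tube_counts(c(0, 0, 5, 10, 20, 25, 20, 15, 5), n_loaded = 100)
#' visual_response(rec)  # 0.75
#' @export
visual_response <- function(record) {
  stopifnot(inherits(record, "tube_counts"))
  n <- sum(record$counts)
  if (n < 1L)
    stop("zero counted flies: maze cannot be scored", call. = FALSE)
  sum(record$counts * (-4:4)) / n * record$stimulus_direction
}

#' Pooled Visual Response across mazes
#'
#' Direction-corrected per-maze VRs with their mean and s.e.m. The maze —
#' not the fly — is the statistical unit: the s.e.m. is the sample standard
#' deviation of per-maze VRs divided by sqrt(number of scored mazes).
#' Mazes with zero counted flies are excluded (with a message), never
#' scored as 0.
#'
#' @param records List of at least 2 `tube_counts`.
#' @return A `vr_result` with `vr_mean`, `vr_sem`, `per_maze_vr`, `n_mazes`,
#'   `n_flies`, `strain`.
#' @export
pooled_vr <- function(records) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "tube_counts")))
  if (length(records) < 2L)
    stop("at least 2 maze records are required", call. = FALSE)
  counted <- vapply(records, function(r) sum(r$counts), integer(1))
  if (all(counted == 0L)) stop("all maze records are empty", call. = FALSE)
  if (any(counted == 0L)) {
    message(sum(counted == 0L), " empty maze record(s) excluded from scoring")
    records <- records[counted > 0L]
  }
  vrs <- vapply(records, visual_response, numeric(1))
  strains <- unique(vapply(records, `[[`, character(1), "strain"))
  structure(
    list(vr_mean = mean(vrs),
         vr_sem = if (length(vrs) > 1) stats::sd(vrs) / sqrt(length(vrs)) else 0,
         per_maze_vr = vrs, n_mazes = length(vrs),
         n_flies = sum(counted),
         strain = paste(strains, collapse = "+")),
    class = "vr_result"
  )
}

#' @export
print.vr_result <- function(x, ...) {
  cat(sprintf("<vr_result> %s: VR = %.3f +/- %.3f s.e.m. (N = %d mazes, %d flies)\n",
              x$strain, x$vr_mean, x$vr_sem, x$n_mazes, x$n_flies))
  invisible(x)
}

#' Per-tube proportions of flies across mazes
#'
#' Direction-corrected mean proportion of counted flies per tube (-4..+4)
#' across mazes, with the s.e.m. over mazes. Proportions within each maze
#' sum to 1; empty mazes are skipped with a message.
#'
#' @param records List of `tube_counts`, at least one with counted flies.
#' @return A data frame with columns `tube`, `proportion`, `sem`.
#' @export
tube_proportions <- function(records) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "tube_counts")))
  counted <- vapply(records, function(r) sum(r$counts), integer(1))
  if (all(counted == 0L)) stop("no counted flies in any record", call. = FALSE)
  if (any(counted == 0L))
    message(sum(counted == 0L), " empty maze record(s) skipped")
  records <- records[counted > 0L]
  props <- vapply(records, function(r) {
    p <- r$counts / sum(r$counts)
    if (r$stimulus_direction < 0L) rev(p) else p
  }, numeric(9))
  props <- matrix(props, nrow = 9L)
  n <- ncol(props)
  data.frame(
    tube = -4:4,
    proportion = rowMeans(props),
    sem = if (n > 1) apply(props, 1, stats::sd) / sqrt(n) else rep(0, 9)
  )
}
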
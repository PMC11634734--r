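#' Construct an activity record
#'
#' An `activity_record` holds binned wheel-running counts for one animal as a
#' days-by-bins matrix together with the bin width and a per-day light
#' schedule. It is the input type for all actigraphy operations.
#'
#' @param counts Numeric matrix of non-negative counts, one row per day, one
#'   column per within-day bin. `ncol(counts) * bin_minutes` must equal 1440.
#' @param bin_minutes Width of one bin in minutes; must divide 60.
#' @param schedule Tibble with one row per day and columns `day`, `phase`
#'   (one of `"LD"`, `"advance"`, `"DD"`), `lights_on_h`, `lights_off_h`
#'   (clock hours, `NA` for DD days) and logical `stress`.
#' @param start_clock_minutes Clock time (minutes after midnight) at which the
#'   first bin of each day starts. Defaults to 0 (midnight-aligned days).
#' @return An object of class `activity_record`.
#' @seealso [simulate_activity()], [circadian_metrics()]
#' @export
activity_record <- function(counts, bin_minutes, schedule,
                            start_clock_minutes = 0) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0)) {
    abort("`counts` must be a numeric matrix of non-negative values")
  }
  assert_scalar_number(bin_minutes, "bin_minutes", 1, 1440)
  if (60 %% bin_minutes != 0) {
    abort("`bin_minutes` must divide 60")
  }
  if (ncol(counts) * bin_minutes != 1440) {
    abort("bins per day times `bin_minutes` must equal 1440")
  }
  schedule <- as_tibble(schedule)
  required <- c("day", "phase", "lights_on_h", "lights_off_h", "stress")
  missing_cols <- setdiff(required, names(schedule))
  if (length(missing_cols)) {
    abort(paste0("schedule is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(schedule) != nrow(counts)) {
    abort("schedule must have one row per day of `counts`")
  }
  if (!all(schedule$phase %in% c("LD", "advance", "DD"))) {
    abort("schedule `phase` must be one of 'LD', 'advance', 'DD'")
  }
  structure(
    list(counts = counts, bin_minutes = bin_minutes,
         start_clock_minutes = start_clock_minutes, schedule = schedule),
    class = "activity_record"
  )
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf(
    "<activity_record> %d days x %d bins (%d-min bins)\n",
    nrow(x$counts), ncol(x$counts), x$bin_minutes
  ))
  ph <- table(x$schedule$phase)
  cat("phases:", paste(sprintf("%s=%d", names(ph), as.integer(ph)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.activity_record <- function(x) dim(x$counts)

#' Flatten an activity record to a long tibble
#'
#' @param x An `activity_record`.
#' @param ... Unused.
#' @return Tibble with columns `day`, `bin`, `clock_time_minutes`, `counts`.
#' @export
as_tibble.activity_record <- function(x, ...) {
  nd <- nrow(x$counts)
  nb <- ncol(x$counts)
  tibble(
    day = rep(seq_len(nd), each = nb),
    bin = rep(seq_len(nb), times = nd),
    clock_time_minutes =
      (x$start_clock_minutes + rep(seq_len(nb) - 1, times = nd) *
         x$bin_minutes) %% 1440,
    counts = as.vector(t(x$counts))
  )
}

# concatenated bin counts in time order
record_series <- function(rec) as.vector(t(rec$counts))

#' Write / read an activity record as TSV plus a JSON schedule sidecar
#'
#' The TSV has columns `day_index`, `bin_index`, `clock_time_minutes`,
#' `counts`; the sidecar holds bin width, start time and the per-day schedule.
#'
#' @param rec An `activity_record`.
#' @param tsv,json File paths.
#' @return `write_activity_record()` returns `rec` invisibly;
#'   `read_activity_record()` returns an `activity_record`.
#' @export
write_activity_record <- function(rec, tsv, json) {
  stopifnot(inherits(rec, "activity_record"))
  long <- as_tibble(rec)
  names(long) <- c("day_index", "bin_index", "clock_time_minutes", "counts")
  readr::write_tsv(long, tsv)
  side <- list(
    bin_minutes = rec$bin_minutes,
    start_clock_minutes = rec$start_clock_minutes,
    schedule = rec$schedule
  )
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(rec)
}

#' @rdname write_activity_record
#' @export
read_activity_record <- function(tsv, json) {
  long <- readr::read_tsv(tsv, show_col_types = FALSE)
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  sched <- as_tibble(side$schedule)
  sched$lights_on_h <- as.numeric(sched$lights_on_h)
  sched$lights_off_h <- as.numeric(sched$lights_off_h)
  nd <- max(long$day_index)
  nb <- 1440 %/% side$bin_minutes
  counts <- matrix(0, nd, nb)
  counts[cbind(long$day_index, long$bin_index)] <- long$counts
  activity_record(counts, side$bin_minutes, sched,
                  start_clock_minutes = side$start_clock_minutes)
}
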
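#' Inlet volume flow-rate profile
#'
#' Time-varying inlet flow rate Q(t) defined by anchor points in normalised
#' time, interpolated with a shape-preserving monotone cubic (exact at every
#' anchor, bounded between neighbouring anchor values on each segment).  The
#' default anchors are the measured phrase-level record: Q rises from
#' 280 cm^3/s at the frication onset (t/t_s = 0) to a maximum of 313 cm^3/s
#' at t/t_s = 0.314, then falls to 184 cm^3/s at the offset (t/t_s = 1).
#'
#' Before the first anchor the profile holds the first anchor value by
#' default (the preceding vowel still carries flow); a linear `"ramp"` from
#' zero over `pre_ramp` is available.  After the last anchor the flow decays
#' linearly to zero over `post_decay` units of `t_s`.
#'
#' @param anchors Data frame with columns `t` (units of `t_s`, strictly
#'   increasing) and `Q` (cm^3/s, nonnegative).
#' @param method `"monotone"` (shape-preserving piecewise-cubic Hermite,
#'   default) or `"linear"` for bit-exact piecewise-linear tests.
#' @param pre_onset `"hold"` (default) or `"ramp"` behaviour before the first
#'   anchor.
#' @param pre_ramp Ramp-up duration for `pre_onset = "ramp"`, units of `t_s`.
#' @param post_offset `"decay"` (default) or `"hold"` behaviour after the
#'   last anchor.
#' @param post_decay Linear decay-to-zero duration for
#'   `post_offset = "decay"`, units of `t_s`.
#' @param sample_rate Sampling rate of discretised records, Hz.  Default 100
#'   (the mass-flow-meter rate).
#' @param t_s Normalisation duration, ms.  Default 175.
#' @return An object of class `"flow_profile"`.
#' @export
flow_profile <- function(anchors = data.frame(t = c(0, 0.314, 1),
                                              Q = c(280, 313, 184)),
                         method = c("monotone", "linear"),
                         pre_onset = c("hold", "ramp"),
                         pre_ramp = 0.3,
                         post_offset = c("decay", "hold"),
                         post_decay = 0.3,
                         sample_rate = 100,
                         t_s = 175) {
  method <- match.arg(method)
  pre_onset <- match.arg(pre_onset)
  post_offset <- match.arg(post_offset)
  if (!is.data.frame(anchors) || !all(c("t", "Q") %in% names(anchors)) ||
      nrow(anchors) < 1L)
    stop_invalid("`anchors` must be a data frame with columns t and Q")
  if (is.unsorted(anchors$t, strictly = TRUE))
    stop_invalid("anchor times must be strictly increasing")
  if (any(anchors$Q < 0))
    stop_invalid("anchor flow rates must be nonnegative")
  if (sample_rate <= 0) stop_invalid("`sample_rate` must be positive")
  if (post_decay < 0 || pre_ramp < 0)
    stop_invalid("`pre_ramp` and `post_decay` must be nonnegative")
  interp <- if (nrow(anchors) == 1L) {
    function(t) rep(anchors$Q, length(t))
  } else if (method == "linear" || nrow(anchors) == 2L) {
    # two anchors: linear is the shape-preserving interpolant
    function(t) approx(anchors$t, anchors$Q, xout = t, rule = 2)$y
  } else {
    # shape-preserving Hermite (pchip): monotone between anchors, zero
    # slope at interior extrema, so no overshoot past any anchor
    function(t) pracma::pchip(anchors$t, anchors$Q, t)
  }
  structure(
    list(anchors = anchors, method = method, pre_onset = pre_onset,
         pre_ramp = pre_ramp, post_offset = post_offset,
         post_decay = post_decay,
         sample_rate = sample_rate, t_s = t_s, interp = interp),
    class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("Flow profile: %d anchor(s), %s interpolation, t_s = %g ms\n",
              nrow(x$anchors), x$method, x$t_s))
  print(x$anchors)
  invisible(x)
}

#' Flow rate at normalised time
#'
#' @param t Time(s) in units of `t_s` (vectorised).
#' @param profile A [flow_profile()].
#' @return Flow rate(s), cm^3/s.
#' @export
flow_rate <- function(t, profile = flow_profile()) {
  stopifnot(inherits(profile, "flow_profile"))
  a <- profile$anchors
  t0 <- a$t[1L]
  t1 <- a$t[nrow(a)]
  Q0 <- a$Q[1L]
  Q1 <- a$Q[nrow(a)]
  q <- numeric(length(t))
  pre <- t < t0
  if (profile$pre_onset == "hold") {
    q[pre] <- Q0
  } else {
    q[pre] <- Q0 * pmax(0, 1 - (t0 - t[pre]) / profile$pre_ramp)
  }
  mid <- t >= t0 & t <= t1
  q[mid] <- profile$interp(t[mid])
  post <- t > t1
  if (profile$post_offset == "hold") {
    q[post] <- Q1
  } else if (profile$post_decay > 0) {
    q[post] <- Q1 * pmax(0, 1 - (t[post] - t1) / profile$post_decay)
  }
  pmax(q, 0)
}

#' Discretise a flow profile to a uniform record
#'
#' Samples the profile at `profile$sample_rate` from `t_start` to `t_end`
#' inclusive of the start and of every full sample period that fits (the
#' default profile over `[0, 1]` at 100 Hz with `t_s` = 175 ms yields 18
#' samples).
#'
#' @param profile A [flow_profile()].
#' @param t_start,t_end Interval bounds, units of `t_s`; `t_start < t_end`.
#' @return Data frame with `time` (seconds, `t = 0` at `t/t_s = 0`) and
#'   `value` (cm^3/s).
#' @export
discretize_flow <- function(profile, t_start, t_end) {
  stopifnot(inherits(profile, "flow_profile"))
  if (!(t_start < t_end)) stop_invalid("`t_start` must be below `t_end`")
  ts_sec <- profile$t_s / 1000
  fs <- profile$sample_rate
  n <- floor((t_end - t_start) * ts_sec * fs + 1e-9) + 1L
  time <- t_start * ts_sec + (seq_len(n) - 1L) / fs
  data.frame(time = time, value = flow_rate(time / ts_sec, profile))
}

#' Read a two-column time/value record
#'
#' Parses the plain-text format of the deposited flow-meter and hot-wire
#' records: two numeric columns (time in seconds, then value), separated by
#' whitespace or commas; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Data frame with columns `time` and `value`.
#' @export
read_flow_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop_invalid("empty record: no data rows in '%s'", path)
  fields <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  parse_row <- function(f, line_no) {
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 2L || anyNA(v))
      stop_invalid("malformed record row at line %d of '%s': '%s'", line_no,
                   path, trimws(lines[line_no]))
    v
  }
  m <- t(mapply(parse_row, fields, idx))
  data.frame(time = m[, 1L], value = m[, 2L])
}

#' Write a two-column time/value record
#'
#' Writes full double precision so that [read_flow_record()] round-trips
#' losslessly.
#'
#' @param series Data frame with columns `time` and `value`.
#' @param path File path.
#' @param comment Optional header comment (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_flow_record <- function(series, path, comment = NULL) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  lines <- sprintf("%.17g\t%.17g", series$time, series$value)
  if (!is.null(comment)) lines <- c(paste0("# ", comment), lines)
  writeLines(lines, path)
  invisible(path)
}
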
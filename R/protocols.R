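# Acquisition protocol descriptions and their (de)serialization.

#' MOLLI acquisition protocol
#'
#' Complete timing and flip-angle description of one ECG-gated MOLLI
#' acquisition. Defaults reproduce the common 3T implementation: a 3-3-5
#' scheme with three inversions, TI1 = 100 ms, dTI = 80 ms, TE/TR =
#' 1.25/2.5 ms, nominal flip angle 35 deg, 3 R-R rest periods between
#' blocks, and a 60 bpm (1000 ms R-R) simulated heart rate. Each single-shot
#' b-SSFP readout consists of 5 preparation pulses (alpha/6, -alpha/3,
#' alpha/2, -2 alpha/3, 5 alpha/6) separated by TR followed by a 69-pulse
#' +/-alpha train; with linear ordering and 75% partial Fourier the k-space
#' centre falls near line 23 of the train.
#'
#' @param ti1 First inversion time in ms (inversion to centre line of the
#'   first image of block 1).
#' @param delta_ti TI increment between blocks in ms; block b uses
#'   `ti1 + (b-1) * delta_ti`.
#' @param tr,te Repetition and echo time of the b-SSFP readout in ms.
#' @param alpha_nominal Nominal excitation flip angle in degrees.
#' @param scheme Integer vector of images per block (default `c(3, 3, 5)`).
#' @param rest_periods Integer R-R counts of free recovery before each
#'   re-inversion (length `length(scheme) - 1`).
#' @param rr_interval R-R interval in ms (constant; no ECG jitter).
#' @param n_readout_pulses Number of +/-alpha pulses per image readout.
#' @param n_prep_pulses Number of ramp preparation pulses.
#' @param prep_scale_factors Signed fractions of alpha for the ramp pulses.
#' @param center_line_index 1-based index of the k-space centre line within
#'   the +/-alpha train; the echo of this pulse defines the image TI.
#' @return An object of class `molli_protocol`.
#' @examples
#' p <- molli_protocol()
#' molli_ti_schedule(p)$ti
#' @export
molli_protocol <- function(ti1 = 100, delta_ti = 80, tr = 2.5, te = 1.25,
                           alpha_nominal = 35, scheme = c(3, 3, 5),
                           rest_periods = c(3, 3), rr_interval = 1000,
                           n_readout_pulses = 69, n_prep_pulses = 5,
                           prep_scale_factors = c(1/6, -1/3, 1/2, -2/3, 5/6),
                           center_line_index = 23) {
  stopifnot(ti1 > 0, delta_ti >= 0, tr > 0, te > 0, te < tr,
            rr_interval > 0, n_readout_pulses >= 1,
            center_line_index >= 1, center_line_index <= n_readout_pulses,
            length(prep_scale_factors) == n_prep_pulses)
  scheme <- as.integer(scheme)
  if (any(scheme < 1)) stop("scheme must contain positive block sizes")
  rest_periods <- as.integer(rest_periods)
  if (length(rest_periods) != length(scheme) - 1L)
    stop("rest_periods must have one entry per gap between blocks")
  if (any(rest_periods < 0)) stop("rest_periods must be non-negative")
  structure(list(ti1 = ti1, delta_ti = delta_ti, tr = tr, te = te,
                 alpha_nominal = alpha_nominal, scheme = scheme,
                 rest_periods = rest_periods, rr_interval = rr_interval,
                 n_readout_pulses = as.integer(n_readout_pulses),
                 n_prep_pulses = as.integer(n_prep_pulses),
                 prep_scale_factors = prep_scale_factors,
                 center_line_index = as.integer(center_line_index)),
            class = "molli_protocol")
}

#' @export
print.molli_protocol <- function(x, ...) {
  cat(sprintf(
    "<molli_protocol> %s scheme, TI1 = %g ms, dTI = %g ms, TE/TR = %g/%g ms,\n",
    paste(x$scheme, collapse = "-"), x$ti1, x$delta_ti, x$te, x$tr))
  cat(sprintf("  alpha = %g deg, rest = %s R-R, R-R = %g ms\n",
              x$alpha_nominal, paste(x$rest_periods, collapse = "/"),
              x$rr_interval))
  invisible(x)
}

# Time from readout start (first prep pulse) to the centre-line echo,
# and total readout duration, in ms.
readout_center_offset <- function(p)
  (p$n_prep_pulses + p$center_line_index - 1) * p$tr + p$te

readout_duration <- function(p) (p$n_prep_pulses + p$n_readout_pulses) * p$tr

#' Inversion-time schedule of a MOLLI protocol
#'
#' Lays the acquisition out on the R-R beat grid. Image centre lines fall on
#' consecutive beats within a block; block b is inverted `ti1 +
#' (b-1)*delta_ti` ms before its first centre line; rest periods insert
#' whole R-R intervals of free recovery before re-inversion.
#'
#' @param protocol A [molli_protocol()].
#' @return A data.frame with one row per image in acquisition order:
#'   `index`, `block`, `beat` (0-based beat of the centre line), `ti` (ms),
#'   `t_center` (absolute centre-line time, ms, block-1 inversion at 0) and
#'   `t_inversion` (absolute time of that image's block inversion).
#' @export
molli_ti_schedule <- function(protocol) {
  p <- protocol
  nblock <- length(p$scheme)
  start_beat <- integer(nblock)
  for (b in seq_len(nblock)[-1])
    start_beat[b] <- start_beat[b - 1] + p$scheme[b - 1] + p$rest_periods[b - 1]
  rows <- list()
  idx <- 0L
  for (b in seq_len(nblock)) {
    ti_b <- p$ti1 + (b - 1) * p$delta_ti
    for (k in seq_len(p$scheme[b]) - 1L) {
      idx <- idx + 1L
      beat <- start_beat[b] + k
      t_center <- p$ti1 + beat * p$rr_interval
      rows[[idx]] <- data.frame(
        index = idx, block = b, beat = beat,
        ti = ti_b + k * p$rr_interval,
        t_center = t_center,
        t_inversion = (p$ti1 + start_beat[b] * p$rr_interval) - ti_b)
    }
  }
  do.call(rbind, rows)
}

#' T2-prepared b-SSFP protocol
#'
#' Single-shot b-SSFP images preceded by T2 preparations of increasing
#' duration, each followed by a recovery period, used for in vivo T2
#' mapping. Defaults follow the common 3T cardiac implementation
#' (TE/TR = 1.3/2.6 ms, preparations of 0/25/75 ms, 3 R-R recovery).
#'
#' @param prep_times T2-preparation durations in ms (non-negative, strictly
#'   increasing).
#' @param tr,te Readout repetition and echo time in ms.
#' @param alpha Readout flip angle in degrees.
#' @param rest_rr R-R cycles of recovery after each image.
#' @param rr_interval R-R interval in ms.
#' @param n_readout_pulses,n_prep_pulses,prep_scale_factors,center_line_index
#'   Readout train structure as in [molli_protocol()].
#' @return An object of class `t2prep_protocol`.
#' @export
t2prep_protocol <- function(prep_times = c(0, 25, 75), tr = 2.6, te = 1.3,
                            alpha = 35, rest_rr = 3, rr_interval = 1000,
                            n_readout_pulses = 69, n_prep_pulses = 5,
                            prep_scale_factors = c(1/6, -1/3, 1/2, -2/3, 5/6),
                            center_line_index = 23) {
  stopifnot(all(prep_times >= 0), !is.unsorted(prep_times, strictly = TRUE),
            tr > 0, te > 0, te < tr, rest_rr >= 0, rr_interval > 0)
  structure(list(prep_times = prep_times, tr = tr, te = te, alpha = alpha,
                 rest_rr = as.integer(rest_rr), rr_interval = rr_interval,
                 n_readout_pulses = as.integer(n_readout_pulses),
                 n_prep_pulses = as.integer(n_prep_pulses),
                 prep_scale_factors = prep_scale_factors,
                 center_line_index = as.integer(center_line_index)),
            class = "t2prep_protocol")
}

# --- Serialization --------------------------------------------------------

protocol_class_tag <- function(p) class(p)[1]

#' Write a protocol to JSON or YAML
#'
#' Field names, units (ms, degrees) and structure follow the protocol
#' constructors exactly, so files round-trip through [read_protocol()].
#'
#' @param protocol A `molli_protocol` or `t2prep_protocol`.
#' @param path Output file; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  x <- unclass(protocol)
  x$.type <- protocol_class_tag(protocol)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a protocol written by [write_protocol()]
#' @param path JSON or YAML file.
#' @return The reconstructed protocol object.
#' @export
read_protocol <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  type <- x$.type %||% "molli_protocol"
  x$.type <- NULL
  do.call(type, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
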
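# Count engine: open emulation of the accelerometer count digitization
# chain -- band-pass filter, 12-bit digitizer, rectification, dead-band,
# amplitude quantization, per-second summation -- plus vector magnitude
# and epoch aggregation. The commercial count algorithm is proprietary;
# this engine reproduces its documented structure and its qualitative
# contracts (zero input -> zero counts, monotonicity in signal amplitude),
# not its bit-exact output.

#' Tri-axial acceleration signal
#'
#' Container for a fixed-rate tri-axial acceleration recording in g units.
#' Axes follow the usual body-frame labelling: vertical,
#' anterior--posterior and medio-lateral.
#'
#' @param vertical,ap,ml Numeric vectors of equal length: acceleration in g
#'   on the vertical, anterior--posterior and medio-lateral axes.
#' @param sampling_rate_hz Sampling rate in Hz. Default 30, the rate used
#'   for count-based activity monitoring.
#' @param t0_s Time of the first sample in seconds.
#' @return An object of class `accel_signal` with elements `axes` (a named
#'   list of the three series), `sampling_rate_hz` and `t0_s`.
#' @examples
#' t <- seq(0, 10, by = 1 / 30)
#' sig <- accel_signal(1 + 0.3 * sin(2 * pi * t), 0 * t, 0 * t)
#' @export
accel_signal <- function(vertical, ap, ml, sampling_rate_hz = 30, t0_s = 0) {
  axes <- list(vertical = as.numeric(vertical),
               ap = as.numeric(ap),
               ml = as.numeric(ml))
  n <- lengths(axes)
  if (length(unique(n)) != 1L || n[[1L]] < 1L)
    stop_speedcuts("all three axes must have equal, positive length",
                   "invalid_argument")
  if (!all(vapply(axes, function(x) all(is.finite(x)), logical(1))))
    stop_speedcuts("acceleration values must be finite", "invalid_argument")
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 0,
                      strict_lower = TRUE)
  structure(list(axes = axes, sampling_rate_hz = sampling_rate_hz,
                 t0_s = t0_s),
            class = "accel_signal")
}

#' @export
print.accel_signal <- function(x, ...) {
  n <- length(x$axes$vertical)
  cat(sprintf("<accel_signal> %d samples @ %g Hz (%.1f s)\n",
              n, x$sampling_rate_hz, n / x$sampling_rate_hz))
  invisible(x)
}

#' Band-pass filter specification
#'
#' The activity-count passband. In `"default"` mode the band is
#' 0.25--2.5 Hz, the documented band used to extract body movement and
#' attenuate artifacts. `"lfe"` selects a low-frequency-extension variant
#' that lowers the low cut to 0.05 Hz, increasing sensitivity to slow
#' movement; the exact passband of the commercial low-frequency extension
#' is not public, so only the mode's contract (strictly more counts for
#' slow supra-dead-band motion) is guaranteed.
#'
#' @param mode `"default"` or `"lfe"`.
#' @param low_cut_hz,high_cut_hz Band edges in Hz; `low_cut_hz` defaults to
#'   0.25 (`"default"`) or 0.05 (`"lfe"`).
#' @param order Overall Butterworth band-pass order (even; default 4).
#'   Applied forward--backward for zero phase.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(mode = c("default", "lfe"), low_cut_hz = NULL,
                        high_cut_hz = 2.5, order = 4) {
  mode <- match.arg(mode)
  if (is.null(low_cut_hz)) low_cut_hz <- if (mode == "lfe") 0.05 else 0.25
  check_scalar_number(low_cut_hz, "low_cut_hz", lower = 0, strict_lower = TRUE)
  check_scalar_number(high_cut_hz, "high_cut_hz", lower = 0, strict_lower = TRUE)
  if (low_cut_hz >= high_cut_hz)
    stop_speedcuts("low_cut_hz must be below high_cut_hz", "invalid_argument")
  check_scalar_number(order, "order", lower = 2)
  if (order %% 2 != 0)
    stop_speedcuts("`order` must be even (band-pass sections come in pairs)",
                   "invalid_argument")
  structure(list(mode = mode, low_cut_hz = low_cut_hz,
                 high_cut_hz = high_cut_hz, order = order),
            class = "filter_spec")
}

#' Zero-phase band-pass filtering of an acceleration signal
#'
#' Applies the activity-count passband per axis with a Butterworth design
#' run forward and backward (zero phase). Output length equals input
#' length.
#'
#' @param signal An [accel_signal()].
#' @param spec A [filter_spec()].
#' @return A filtered [accel_signal()].
#' @export
bandpass <- function(signal, spec = filter_spec()) {
  if (!inherits(signal, "accel_signal"))
    stop_speedcuts("`signal` must be an accel_signal", "invalid_argument")
  if (!inherits(spec, "filter_spec"))
    stop_speedcuts("`spec` must be a filter_spec", "invalid_argument")
  fs <- signal$sampling_rate_hz
  if (fs <= 2 * spec$high_cut_hz)
    stop_speedcuts(sprintf(
      "sampling rate %g Hz violates the Nyquist bound for a %g Hz high cut",
      fs, spec$high_cut_hz), "invalid_argument")
  bf <- signal::butter(spec$order / 2,
                       c(spec$low_cut_hz, spec$high_cut_hz) / (fs / 2),
                       type = "pass")
  out <- lapply(signal$axes, function(x) signal::filtfilt(bf, x))
  accel_signal(out$vertical, out$ap, out$ml, fs, signal$t0_s)
}

#' 12-bit digitizer levels for an acceleration value
#'
#' Maps acceleration in g onto the integer levels of a 12-bit
#' analog-to-digital converter spanning `±range_g`. Zero acceleration sits
#' at mid-scale: level 4096 / 2 = 2048.
#'
#' @param accel_g Numeric vector, acceleration in g.
#' @param n_bits ADC resolution in bits (default 12, i.e. 4096 levels).
#' @param range_g Half-range of the converter in g (default 6).
#' @return Integer-valued vector of levels in `[0, 2^n_bits - 1]`.
#' @examples
#' adc_digitize(0)  # mid-scale, 2048
#' @export
adc_digitize <- function(accel_g, n_bits = 12, range_g = 6) {
  n_levels <- 2^n_bits
  lv <- floor((accel_g + range_g) / (2 * range_g) * n_levels)
  pmin(pmax(lv, 0), n_levels - 1)
}

adc_dequantize <- function(level, n_bits = 12, range_g = 6) {
  (level - 2^n_bits / 2) * (2 * range_g) / 2^n_bits
}

#' Convert a band-pass-filtered signal to per-second activity counts
#'
#' Emulates the count accumulation stage: the filtered signal is passed
#' through a 12-bit digitizer, rectified, clipped at `ceiling_g`, zeroed
#' below the dead-band, quantized in steps of `quantum_g`, and the
#' quantized levels are summed over non-overlapping 1-second windows per
#' axis. Counts are non-negative integers and are monotone in the
#' amplitude of the in-band signal.
#'
#' @param filtered A band-pass-filtered [accel_signal()] with an integer
#'   sampling rate.
#' @param deadband_g Amplitude below which a sample contributes zero
#'   counts (default 0.05 g).
#' @param ceiling_g Saturation amplitude (default 2.13 g).
#' @param quantum_g Count quantum in g (default 1/128 g).
#' @param placement,filter_mode Metadata labels carried on the result.
#' @return A [count_series()] at a 1-second base epoch; any trailing
#'   partial second is discarded.
#' @export
accel_to_counts <- function(filtered, deadband_g = 0.05, ceiling_g = 2.13,
                            quantum_g = 1 / 128, placement = "waist",
                            filter_mode = "default") {
  if (!inherits(filtered, "accel_signal"))
    stop_speedcuts("`filtered` must be an accel_signal", "invalid_argument")
  check_scalar_number(quantum_g, "quantum_g", lower = 0, strict_lower = TRUE)
  check_scalar_number(ceiling_g, "ceiling_g", lower = 0, strict_lower = TRUE)
  check_scalar_number(deadband_g, "deadband_g", lower = 0)
  if (deadband_g >= ceiling_g)
    stop_speedcuts("deadband_g must be below ceiling_g", "invalid_argument")
  fs <- filtered$sampling_rate_hz
  if (fs != round(fs))
    stop_speedcuts("per-second accumulation needs an integer sampling rate",
                   "invalid_argument")
  per_second <- function(x) {
    a <- pmin(abs(adc_dequantize(adc_digitize(x))), ceiling_g)
    a[a < deadband_g] <- 0
    q <- floor(a / quantum_g)
    n_sec <- length(q) %/% fs
    if (n_sec == 0L) return(integer(0))
    as.integer(colSums(matrix(q[seq_len(n_sec * fs)], nrow = fs)))
  }
  cs <- lapply(filtered$axes, per_second)
  count_series(cs$vertical, cs$ap, cs$ml, placement = placement,
               filter_mode = filter_mode)
}

#' Per-epoch activity count series
#'
#' @param counts_v,counts_ap,counts_ml Equal-length vectors of
#'   non-negative integer counts per base epoch (vertical,
#'   anterior--posterior, medio-lateral).
#' @param placement Sensor placement label, `"waist"` or `"ankle"`.
#' @param filter_mode Filter mode the counts were derived under.
#' @param base_epoch_s Base epoch length in seconds (1 s internally).
#' @return An object of class `count_series`.
#' @export
count_series <- function(counts_v, counts_ap, counts_ml,
                         placement = "waist", filter_mode = "default",
                         base_epoch_s = 1) {
  axes <- list(counts_v = counts_v, counts_ap = counts_ap,
               counts_ml = counts_ml)
  n <- lengths(axes)
  if (length(unique(n)) != 1L)
    stop_speedcuts("axis count series must have equal length",
                   "invalid_argument")
  if (!all(vapply(axes, is_count_vector, logical(1))))
    stop_speedcuts("counts must be finite non-negative integers",
                   "invalid_argument")
  check_scalar_number(base_epoch_s, "base_epoch_s", lower = 0,
                      strict_lower = TRUE)
  structure(list(counts_v = as.integer(counts_v),
                 counts_ap = as.integer(counts_ap),
                 counts_ml = as.integer(counts_ml),
                 placement = placement, filter_mode = filter_mode,
                 base_epoch_s = base_epoch_s),
            class = "count_series")
}

#' @export
length.count_series <- function(x) length(x$counts_v)

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %s/%s: %d x %g s epochs\n",
              x$placement, x$filter_mode, length(x), x$base_epoch_s))
  invisible(x)
}

#' Vector magnitude of tri-axial counts
#'
#' Combines the three axis counts into a single value. The conventional
#' definition is the Euclidean norm rounded to the nearest integer
#' (`method = "euclidean"`, the default used throughout the cut-point
#' literature); an arithmetic sum across axes is available as
#' `method = "sum"`.
#'
#' @param count_v,count_ap,count_ml Non-negative integer counts
#'   (vectorized).
#' @param method `"euclidean"` or `"sum"`.
#' @return Non-negative integer vector; always at least the per-axis
#'   maximum, and zero only when all three inputs are zero.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(count_v, count_ap, count_ml,
                             method = c("euclidean", "sum")) {
  method <- match.arg(method)
  if (!is_count_vector(count_v) || !is_count_vector(count_ap) ||
      !is_count_vector(count_ml))
    stop_speedcuts("axis counts must be non-negative integers",
                   "invalid_argument")
  if (method == "euclidean")
    as.integer(round(sqrt(count_v^2 + count_ap^2 + count_ml^2)))
  else
    as.integer(count_v + count_ap + count_ml)
}

#' Aggregate a count series into 15-second or 1-minute epochs
#'
#' Sums the 1-second base counts into consecutive epochs of
#' `epoch_length_s` seconds, starting at the first base epoch; any
#' trailing partial epoch is discarded. The vector magnitude is computed
#' from the aggregated per-axis epoch sums.
#'
#' @param series A [count_series()].
#' @param epoch_length_s Epoch length in seconds; 15 or 60 unless
#'   `allow_nonstandard = TRUE`.
#' @param vm_method Vector-magnitude method, see [vector_magnitude()].
#' @param allow_nonstandard Permit epoch lengths other than 15/60 s.
#' @return A data frame with columns `placement`, `filter_mode`,
#'   `epoch_index`, `epoch_length_s`, `count_v`, `count_ap`, `count_ml`,
#'   `count_vm`.
#' @export
aggregate_epochs <- function(series, epoch_length_s,
                             vm_method = c("euclidean", "sum"),
                             allow_nonstandard = FALSE) {
  vm_method <- match.arg(vm_method)
  if (!inherits(series, "count_series"))
    stop_speedcuts("`series` must be a count_series", "invalid_argument")
  check_scalar_number(epoch_length_s, "epoch_length_s", lower = 0,
                      strict_lower = TRUE)
  if (!allow_nonstandard && !epoch_length_s %in% c(15, 60))
    stop_speedcuts(
      "epoch_length_s must be 15 or 60 (use allow_nonstandard to override)",
      "invalid_argument")
  k <- epoch_length_s / series$base_epoch_s
  if (k != round(k) || k < 1)
    stop_speedcuts("epoch length must be a whole multiple of the base epoch",
                   "invalid_argument")
  n_ep <- length(series) %/% k
  sum_axis <- function(x) {
    if (n_ep == 0L) return(integer(0))
    as.integer(colSums(matrix(x[seq_len(n_ep * k)], nrow = k)))
  }
  v <- sum_axis(series$counts_v)
  ap <- sum_axis(series$counts_ap)
  ml <- sum_axis(series$counts_ml)
  data.frame(placement = rep(series$placement, n_ep),
             filter_mode = rep(series$filter_mode, n_ep),
             epoch_index = seq_len(n_ep),
             epoch_length_s = rep(epoch_length_s, n_ep),
             count_v = v, count_ap = ap, count_ml = ml,
             count_vm = vector_magnitude(v, ap, ml, method = vm_method),
             stringsAsFactors = FALSE)
}

#' Full raw-signal-to-counts conversion
#'
#' Convenience wrapper: [bandpass()] followed by [accel_to_counts()],
#' carrying the filter mode from `spec` onto the result.
#'
#' @inheritParams bandpass
#' @inheritParams accel_to_counts
#' @return A [count_series()] at a 1-second base epoch.
#' @export
signal_to_counts <- function(signal, spec = filter_spec(),
                             placement = "waist", deadband_g = 0.05,
                             ceiling_g = 2.13, quantum_g = 1 / 128) {
  accel_to_counts(bandpass(signal, spec), deadband_g = deadband_g,
                  ceiling_g = ceiling_g, quantum_g = quantum_g,
                  placement = placement, filter_mode = spec$mode)
}
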
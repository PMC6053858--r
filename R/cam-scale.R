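# ERB_N-number (Cam) scale and audiogram handling.
#
# All frequency warping in the package happens on the Cam scale, the
# ERB_N-number scale for normal hearing: one Cam step corresponds to one
# equivalent rectangular bandwidth (ERB_N) of the normal auditory filter.

#' Convert frequency in Hz to ERB_N-number (Cams)
#'
#' Uses the standard conversion Cam = 21.4 * log10(4.37 * F + 1) with F in
#' kHz. The scale is 0 at 0 Hz and strictly increasing.
#'
#' @param f Frequency in Hz (vectorised, must be non-negative).
#' @return ERB_N-number in Cams.
#' @seealso [hz_from_cam()], [erb_n_hz()]
#' @export
#' @examples
#' cam_from_hz(c(520, 900, 1000))
cam_from_hz <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  21.4 * log10(4.37 * f / 1000 + 1)
}

#' Convert ERB_N-number (Cams) to frequency in Hz
#'
#' Exact inverse of [cam_from_hz()].
#'
#' @param cam ERB_N-number in Cams (vectorised, must be non-negative).
#' @return Frequency in Hz.
#' @export
hz_from_cam <- function(cam) {
  if (any(cam < 0)) stop("Cam value must be non-negative")
  (10^(cam / 21.4) - 1) / 4.37 * 1000
}

#' Equivalent rectangular bandwidth of the normal auditory filter
#'
#' ERB_N(F) = 24.7 * (4.37 * F + 1) Hz, F in kHz.
#'
#' @param f Centre frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb_n_hz <- function(f) {
  24.7 * (4.37 * f / 1000 + 1)
}

#' Construct an audiogram
#'
#' An audiogram is the fixed, known part of the hearing model: total
#' hearing loss (HL_total, dB HL) tabulated at increasing frequencies for
#' one ear. Between tabulated points the package interpolates linearly on
#' the (Cam, dB HL) plane.
#'
#' @param frequency_hz Strictly increasing positive frequencies (>= 2).
#' @param hl_db Hearing levels in dB HL, within \[-10, 120\].
#' @param ear Free-text ear label.
#' @return An object of class `"audiogram"`.
#' @export
#' @examples
#' a <- audiogram(c(500, 1000, 2000, 4000), c(20, 40, 80, 95), ear = "sim L")
#' interpolate_hl(a, 1500)
audiogram <- function(frequency_hz, hl_db, ear = "") {
  frequency_hz <- as.numeric(frequency_hz)
  hl_db <- as.numeric(hl_db)
  if (length(frequency_hz) != length(hl_db))
    stop("frequency_hz and hl_db must have the same length")
  if (length(frequency_hz) < 2)
    stop("an audiogram needs at least 2 points")
  if (any(frequency_hz <= 0))
    stop("audiogram frequencies must be positive")
  if (any(diff(frequency_hz) <= 0))
    stop("audiogram frequencies must be strictly increasing")
  if (any(hl_db < -10 | hl_db > 120))
    stop("hearing levels must lie within [-10, 120] dB HL")
  structure(
    list(frequency_hz = frequency_hz, hl_db = hl_db,
         cam = cam_from_hz(frequency_hz), ear = ear),
    class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram", if (nzchar(x$ear)) paste0("(", x$ear, ")"), "-",
      length(x$frequency_hz), "points,",
      sprintf("%.0f-%.0f Hz, HL %.0f-%.0f dB\n",
              min(x$frequency_hz), max(x$frequency_hz),
              min(x$hl_db), max(x$hl_db)))
  invisible(x)
}

#' Read an audiogram from CSV
#'
#' Expects a header with columns `frequency_hz` and `hl_total_db`,
#' comma-separated with '.' decimals.
#'
#' @param path File path.
#' @param ear Optional ear label.
#' @return An `"audiogram"` object.
#' @export
read_audiogram <- function(path, ear = "") {
  d <- utils::read.csv(path)
  need <- c("frequency_hz", "hl_total_db")
  if (!all(need %in% names(d)))
    stop("audiogram CSV must have columns: ", paste(need, collapse = ", "))
  audiogram(d$frequency_hz, d$hl_total_db, ear = ear)
}

#' Write an audiogram to CSV
#'
#' @param a An `"audiogram"`.
#' @param path File path.
#' @export
write_audiogram <- function(a, path) {
  utils::write.csv(
    data.frame(frequency_hz = a$frequency_hz, hl_total_db = a$hl_db),
    path, row.names = FALSE)
  invisible(path)
}

#' Interpolate total hearing loss at a frequency
#'
#' Piecewise-linear interpolation on the (Cam, dB HL) plane; exact at
#' tabulated frequencies. Frequencies outside the tabulated range are an
#' error (no silent clamping).
#'
#' @param a An `"audiogram"`.
#' @param f Frequency in Hz (vectorised).
#' @return HL_total in dB HL.
#' @export
interpolate_hl <- function(a, f) {
  stopifnot(inherits(a, "audiogram"))
  if (any(f < min(a$frequency_hz) | f > max(a$frequency_hz)))
    stop(sprintf("frequency outside audiogram range [%g, %g] Hz",
                 min(a$frequency_hz), max(a$frequency_hz)))
  stats::approx(a$cam, a$hl_db, xout = cam_from_hz(f), ties = "ordered")$y
}

#' Lowest frequency at which the audiogram reaches a criterion level
#'
#' Scans the piecewise-linear (Cam, dB HL) audiogram from low to high
#' frequency and returns the first frequency at which the interpolated
#' HL_total equals `criterion`. Used to extract the probe candidates
#' f_65, f_70 and f_75 for the screening cascade. Targeting the lowest
#' crossing suits the low-frequency edge of a high-frequency loss.
#'
#' @param a An `"audiogram"`.
#' @param criterion Criterion level in dB HL, within \[0, 120\].
#' @return Frequency in Hz, or `NA_real_` if the criterion is never reached.
#' @export
find_freq_at_hl <- function(a, criterion) {
  stopifnot(inherits(a, "audiogram"))
  if (criterion < 0 || criterion > 120)
    stop("criterion must lie within [0, 120] dB HL")
  cam <- a$cam
  hl <- a$hl_db
  for (i in seq_len(length(cam) - 1L)) {
    h1 <- hl[i]
    h2 <- hl[i + 1L]
    if ((criterion - h1) * (criterion - h2) <= 0) {
      if (h1 == criterion) return(hz_from_cam(cam[i]))
      if (h1 == h2) next  # flat segment not at criterion
      cmx <- cam[i] + (criterion - h1) * (cam[i + 1L] - cam[i]) / (h2 - h1)
      return(hz_from_cam(cmx))
    }
  }
  NA_real_
}

#' Signal (probe tone) specification
#'
#' @param f_sig Probe frequency in Hz.
#' @param l_sig Probe level in dB HL (10 dB SL when produced by
#'   [quick_ten_protocol()]).
#' @return A list of class `"signal_spec"`.
#' @export
signal_spec <- function(f_sig, l_sig) {
  stopifnot(f_sig > 0, is.finite(l_sig))
  structure(list(f_sig = f_sig, l_sig = l_sig), class = "signal_spec")
}

#' Masker stimulus
#'
#' @param f_mask Masker centre frequency in Hz.
#' @param l_mask Masker overall level in dB HL.
#' @return A list of class `"stimulus"`.
#' @export
stimulus <- function(f_mask, l_mask) {
  stopifnot(f_mask > 0, is.finite(l_mask))
  structure(list(f_mask = f_mask, l_mask = l_mask), class = "stimulus")
}
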
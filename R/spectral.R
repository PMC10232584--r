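#' Frequency band scheme
#'
#' The canonical band partition used throughout the pipeline: theta 4-8 Hz,
#' alpha 8-13 Hz, beta 13-30 Hz, with relative power always taken with
#' respect to the total 1-40 Hz range.
#'
#' @param theta,alpha,beta,total length-2 numeric band edges in Hz.
#' @return a named list of bands with class `band_scheme`.
#' @export
band_scheme <- function(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
                        total = c(1, 40)) {
  b <- list(theta = theta, alpha = alpha, beta = beta, total = total)
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2 || b[[nm]][1] >= b[[nm]][2]) {
      stop("band `", nm, "` must have increasing edges")
    }
  }
  for (nm in c("theta", "alpha", "beta")) {
    if (b[[nm]][1] < total[1] || b[[nm]][2] > total[2]) {
      stop("band `", nm, "` must lie inside the total band")
    }
  }
  structure(b, class = "band_scheme")
}

#' Welch power spectral density
#'
#' Welch's averaged-periodogram estimate: the signal is split into
#' Hann-tapered segments with 50% overlap, and one-sided periodograms are
#' averaged over segments (and over epochs when `x` is a matrix). Default
#' segment length is 2 s, giving 0.5 Hz resolution.
#'
#' @param x numeric vector (one epoch) or matrix `epoch x sample`.
#' @param fs sampling rate in Hz.
#' @param window_s segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power density, unit^2/Hz).
#' @export
psd_welch <- function(x, fs, window_s = 2, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nper <- round(window_s * fs)
  if (ncol(x) < nper) {
    stop("epoch (", ncol(x), " samples) shorter than one Welch window (", nper, " samples)")
  }
  step <- max(1L, round(nper * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / nper) # Hann (periodic)
  u <- sum(w^2)
  nfreq <- nper %/% 2 + 1
  acc <- numeric(nfreq)
  nseg <- 0L
  for (e in seq_len(nrow(x))) {
    starts <- seq.int(1L, ncol(x) - nper + 1L, by = step)
    for (s in starts) {
      seg <- x[e, s:(s + nper - 1L)]
      seg <- (seg - mean(seg)) * w
      p <- Mod(fft(seg)[seq_len(nfreq)])^2 / (fs * u)
      p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)] # one-sided
      acc <- acc + p
      nseg <- nseg + 1L
    }
  }
  list(freq = seq(0, fs / 2, length.out = nfreq), psd = acc / nseg)
}

#' 1/f spectral correction
#'
#' Compensates the 1/f background of neural power spectra by multiplying
#' the density by `f^exponent` (exponent 1 by default): a pure 1/f spectrum
#' becomes flat, and band power ratios are no longer dominated by the lowest
#' frequencies.
#'
#' @param psd power density values.
#' @param freq matching frequency grid in Hz.
#' @param exponent correction exponent (default 1; 0 is the identity).
#' @return corrected density vector.
#' @export
one_over_f_correct <- function(psd, freq, exponent = 1) {
  stopifnot(length(psd) == length(freq))
  psd * freq^exponent
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Relative band power
#'
#' Power inside `band` divided by power inside `total_band`, both computed
#' from the same (optionally 1/f-corrected) density by trapezoidal
#' integration over the closed band interval on the discrete grid.
#' Because trapezoidal integrals are additive across shared edges, bands
#' that tile the total band have fractions that sum to exactly 1.
#'
#' @param psd density values (use the corrected density if a 1/f correction
#'   is wanted; numerator and denominator always share the same density).
#' @param freq frequency grid in Hz.
#' @param band length-2 band edges in Hz; must lie inside `total_band`.
#' @param total_band length-2 edges of the normalizing range (default 1-40 Hz).
#' @return a fraction in `[0, 1]`.
#' @export
relative_band_power <- function(psd, freq, band, total_band = c(1, 40)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] < total_band[1] || band[2] > total_band[2]) {
    stop("band must lie inside the total band")
  }
  band_idx <- freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9
  tot_idx <- freq >= total_band[1] - 1e-9 & freq <= total_band[2] + 1e-9
  if (sum(band_idx) < 2 || sum(tot_idx) < 2) stop("frequency grid too coarse for the requested band")
  total <- trapz(freq[tot_idx], psd[tot_idx])
  if (total <= 0) stop("total power is zero; relative power undefined")
  max(0, min(1, trapz(freq[band_idx], psd[band_idx]) / total))
}

#' Relative band power table for a set of epoch sets
#'
#' For every epoch set and channel: per-epoch Welch spectra are averaged
#' into one mean spectrum, the 1/f correction is applied, and the relative
#' power of each band is computed. Output is the tidy long-format table
#' consumed by the statistics layer.
#'
#' @param epoch_sets list of [epoch_set()] objects.
#' @param bands a [band_scheme()].
#' @param exponent 1/f correction exponent (default 1).
#' @param window_s Welch segment length in seconds.
#' @return data.frame with columns `participant`, `condition`, `region`,
#'   `band`, `relative_power`.
#' @export
power_table <- function(epoch_sets, bands = band_scheme(), exponent = 1,
                        window_s = 2) {
  if (inherits(epoch_sets, "epoch_set")) epoch_sets <- list(epoch_sets)
  band_names <- setdiff(names(bands), "total")
  rows <- list()
  for (es in epoch_sets) {
    stopifnot(inherits(es, "epoch_set"))
    for (ch in seq_along(es$channel_labels)) {
      sp <- psd_welch(es$data[, ch, , drop = TRUE], es$fs, window_s = window_s)
      cor_psd <- one_over_f_correct(sp$psd, sp$freq, exponent)
      for (bn in band_names) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = es$participant, condition = es$condition,
          region = es$channel_labels[ch], band = bn,
          relative_power = relative_band_power(cor_psd, sp$freq, bands[[bn]], bands$total),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Average frontal-channel power
#'
#' Collapses per-channel relative power over the six frontal electrodes
#' into one frontal mean per participant, condition and band.
#'
#' @param pt a [power_table()] whose `region` column holds channel names.
#' @param channels the frontal montage (default F7, F3, Fz, FPz, F4, F8).
#' @return data.frame like `pt` with `region = "frontal"`.
#' @export
frontal_average <- function(pt, channels = c("F7", "F3", "Fz", "FPz", "F4", "F8")) {
  missing_ch <- setdiff(channels, unique(pt$region))
  if (length(missing_ch) > 0) {
    stop("frontal channels missing from the power table: ",
         paste(missing_ch, collapse = ", "))
  }
  sub <- pt[pt$region %in% channels, ]
  out <- aggregate(relative_power ~ participant + condition + band, data = sub, FUN = mean)
  out$region <- "frontal"
  out[, c("participant", "condition", "region", "band", "relative_power")]
}
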
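#' Simulation configuration
#'
#' Describes the synthetic two-condition study world: participants,
#' feedback-locked 6.2-s epochs at 512 Hz, band-limited oscillations with
#' log-normal amplitude envelopes, controlled inter-regional envelope
#' coupling, linear channel mixing (spatial-leakage stand-in),
#' condition-dependent cardiac acceleration and gamma-distributed
#' questionnaire scores.
#'
#' Condition effects are stated the way the statistics layer will see them:
#' `band_effects` gives the standardized effect size (contrast divided by
#' the residual coefficient-of-variation scale of the gamma family) of the
#' relative-power change per `"region.band"`, and the generator converts it
#' into a log-amplitude shift via a first-order calibration so the realized
#' SES matches the request in expectation. `coupling_effects` gives the
#' condition difference in latent envelope correlation per
#' `"regionA|regionB.band"`.
#'
#' @param n_participants number of participants (default 73).
#' @param n_epochs_per_condition epochs per participant and condition
#'   (default 30; at least 15 are needed to pass the inclusion rule).
#' @param epoch_duration_s epoch length in seconds (default 6.2); the
#'   sample count is `floor(epoch_duration_s * fs)`.
#' @param fs sampling rate in Hz (default 512).
#' @param band_effects named numeric, `"region.band"` -> standardized
#'   condition effect on relative power (positive = larger in the negative
#'   condition). Defaults: alpha increases in left/right precuneus and
#'   right PCC with SES 0.07/0.11/0.10.
#' @param coupling_effects named numeric, `"regionA|regionB.band"` ->
#'   condition difference in envelope correlation (default: +0.017 for the
#'   left-right precuneus pair in alpha).
#' @param baseline_coupling named numeric like `coupling_effects`: envelope
#'   correlation shared by both conditions (default 0.1 for the
#'   homologous precuneus and PCC pairs in alpha).
#' @param mixing_matrix channels x regions weight matrix (rows named with
#'   channel labels); must have full column rank. Default:
#'   [default_mixing_matrix()], a 16-channel montage including the six
#'   frontal electrodes.
#' @param ibi_effect_ms per-beat shortening (ms) applied to IBI indices
#'   2..7 after each event in the negative condition (default 30).
#' @param random_seed integer master seed; per-participant substreams are
#'   derived from it so any participant subset is reproducible.
#' @param amp_base named per-band baseline oscillation amplitudes (uV).
#' @param amp_participant_sd,amp_cond_sd,amp_epoch_sd log-amplitude SDs of
#'   the participant intercept, the within-participant condition-level
#'   jitter (the residual scale the SES calibration standardizes against)
#'   and the epoch-level jitter.
#' @param env_sigma log-normal depth of the amplitude envelopes.
#' @param env_cutoff_hz low-pass cutoff of the envelope modulators (<= 1 Hz
#'   so the envelopes are slow compared to the carriers).
#' @param bg_sd SD (uV) of the 1-40 Hz band-limited background activity per
#'   region.
#' @param sensor_noise_sd SD (uV) of white sensor noise added per channel.
#' @param ibi_mean_ms,ibi_sd_ms,ibi_participant_sd_ms baseline inter-beat
#'   interval mean, beat-to-beat SD and between-participant SD (ms).
#' @param n_events,event_spacing_s feedback events per condition and their
#'   spacing (must exceed 12 mean IBIs).
#' @param score_mean,score_sd,score_participant_sd gamma questionnaire
#'   score mean, within-participant SD and participant-intercept SD.
#' @param score_shifts named numeric condition shifts per scale (defaults:
#'   valence -1.0, arousal -0.4; direction is configurable, not hard-coded).
#' @param n_sam_per_condition questionnaire administrations per condition.
#' @param likert if `TRUE` (default) scores are rounded and clamped to the
#'   1-9 Likert range.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 73,
                              n_epochs_per_condition = 30,
                              epoch_duration_s = 6.2,
                              fs = 512,
                              band_effects = c("precuneus_L.alpha" = 0.07,
                                               "precuneus_R.alpha" = 0.11,
                                               "PCC_R.alpha" = 0.10),
                              coupling_effects = c("precuneus_L|precuneus_R.alpha" = 0.017),
                              baseline_coupling = c("precuneus_L|precuneus_R.alpha" = 0.10,
                                                    "PCC_L|PCC_R.alpha" = 0.10),
                              mixing_matrix = default_mixing_matrix(),
                              ibi_effect_ms = 30,
                              random_seed = 1L,
                              amp_base = c(theta = 10, alpha = 8, beta = 12),
                              amp_participant_sd = 0.15,
                              amp_cond_sd = 0.04,
                              amp_epoch_sd = 0.15,
                              env_sigma = 0.5,
                              env_cutoff_hz = 1,
                              bg_sd = 6,
                              sensor_noise_sd = 0.5,
                              ibi_mean_ms = 850,
                              ibi_sd_ms = 40,
                              ibi_participant_sd_ms = 60,
                              n_events = 33,
                              event_spacing_s = 15,
                              score_mean = 5,
                              score_sd = 1.2,
                              score_participant_sd = 0.8,
                              score_shifts = c(valence = -1.0, arousal = -0.4),
                              n_sam_per_condition = 3,
                              likert = TRUE) {
  cfg <- as.list(environment())
  if (floor(epoch_duration_s * fs) < 1) stop("epoch_duration_s * fs must round to a positive sample count")
  regions <- names(roi_catalog())
  bands <- names(band_scheme())
  for (nm in names(band_effects)) {
    pr <- parse_measure_name(nm)
    if (!pr$unit %in% regions || !pr$band %in% bands) stop("unknown band effect key: ", nm)
  }
  all_coupling <- c(coupling_effects, baseline_coupling)
  for (nm in names(all_coupling)) {
    pr <- parse_measure_name(nm)
    rr <- strsplit(pr$unit, "|", fixed = TRUE)[[1]]
    if (length(rr) != 2 || !all(rr %in% regions) || !pr$band %in% bands) {
      stop("unknown coupling key: ", nm)
    }
  }
  for (cond in c("control", "negative")) {
    for (bn in setdiff(bands, "total")) {
      rho <- coupling_matrix(cfg, bn, cond, regions)[upper.tri(diag(length(regions)))]
      if (any(rho < 0 | rho >= 1)) stop("envelope correlations must lie in [0, 1)")
      C <- latent_coupling_matrix(cfg, bn, cond, regions)
      if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
        bad <- names(all_coupling)[vapply(names(all_coupling), function(x) parse_measure_name(x)$band == bn, logical(1))]
        stop("requested envelope correlation structure for band ", bn,
             " is not positive semi-definite; offending pairs: ", paste(bad, collapse = ", "))
      }
    }
  }
  if (is.null(rownames(mixing_matrix))) stop("mixing_matrix must have channel row names")
  if (ncol(mixing_matrix) != length(regions)) stop("mixing_matrix must have one column per region")
  if (qr(mixing_matrix)$rank < ncol(mixing_matrix)) stop("mixing_matrix must have full column rank")
  if (event_spacing_s * 1000 <= 12 * ibi_mean_ms) stop("event spacing must exceed 12 mean IBIs")
  structure(cfg, class = "simulation_config")
}

parse_measure_name <- function(x) {
  band <- sub("^.*\\.", "", x)
  unit <- sub("\\.[^.]+$", "", x)
  list(unit = unit, band = band)
}

coupling_matrix <- function(cfg, band, condition, regions) {
  R <- length(regions)
  C <- diag(R)
  dimnames(C) <- list(regions, regions)
  add <- function(spec, mat) {
    for (nm in names(spec)) {
      pr <- parse_measure_name(nm)
      if (pr$band != band) next
      rr <- strsplit(pr$unit, "|", fixed = TRUE)[[1]]
      mat[rr[1], rr[2]] <- mat[rr[1], rr[2]] + spec[[nm]]
      mat[rr[2], rr[1]] <- mat[rr[1], rr[2]]
    }
    mat
  }
  C <- add(cfg$baseline_coupling, C)
  if (condition == "negative") C <- add(cfg$coupling_effects, C)
  C
}

# exponentiating a Gaussian attenuates correlations; invert the log-normal
# correlation map so the requested value is realized on the envelope scale
latent_coupling_matrix <- function(cfg, band, condition, regions) {
  C <- coupling_matrix(cfg, band, condition, regions)
  s2 <- cfg$env_sigma^2
  off <- upper.tri(C) | lower.tri(C)
  C[off] <- log(1 + C[off] * (exp(s2) - 1)) / s2
  C
}

#' Default channel mixing matrix
#'
#' A fixed 16-channel leadfield-like weight matrix projecting the 10
#' regions into channel space (including the six frontal electrodes used by
#' the sensor-level analysis). Deliberately coarse - its only job is to
#' produce instantaneous linear mixing with full column rank so leakage
#' behaviour is testable.
#'
#' @return 16 x 10 numeric matrix with channel row names and region column
#'   names.
#' @export
default_mixing_matrix <- function() {
  channels <- c("F7", "F3", "Fz", "FPz", "F4", "F8", "C3", "Cz", "C4",
                "T7", "T8", "P3", "Pz", "P4", "POz", "Oz")
  regions <- c("anterior_insula_L", "anterior_insula_R", "ACC_L", "ACC_R",
               "PCC_L", "PCC_R", "precuneus_L", "precuneus_R", "OFC_L", "OFC_R")
  M <- matrix(0, length(channels), length(regions), dimnames = list(channels, regions))
  w <- list(
    anterior_insula_L = c(T7 = 0.8, F7 = 0.5, C3 = 0.3),
    anterior_insula_R = c(T8 = 0.8, F8 = 0.5, C4 = 0.3),
    ACC_L = c(Fz = 0.7, FPz = 0.5, F3 = 0.3, Cz = 0.2),
    ACC_R = c(Fz = 0.7, FPz = 0.5, F4 = 0.3, Cz = 0.2),
    PCC_L = c(Pz = 0.7, P3 = 0.5, C3 = 0.2, Cz = 0.2),
    PCC_R = c(Pz = 0.7, P4 = 0.5, C4 = 0.2, Cz = 0.2),
    precuneus_L = c(POz = 0.7, Pz = 0.5, P3 = 0.3, Oz = 0.2),
    precuneus_R = c(POz = 0.7, Pz = 0.5, P4 = 0.3, Oz = 0.2),
    OFC_L = c(FPz = 0.7, F3 = 0.4, F7 = 0.3),
    OFC_R = c(FPz = 0.7, F4 = 0.4, F8 = 0.3)
  )
  for (r in names(w)) M[names(w[[r]]), r] <- w[[r]]
  M
}

# counter-based substream derivation: every (participant, purpose) pair maps
# to its own 31-bit seed so subsets of participants reproduce exactly
derive_seed <- function(seed, participant_idx, tag) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    participant_idx * 104729 + tag * 7919
  as.integer(s %% 2147483629) + 1L
}

participant_ids <- function(cfg) sprintf("P%03d", seq_len(cfg$n_participants))

#' Participant metadata
#'
#' Deterministic per-participant attributes (currently sex, drawn with the
#' study's observed 47/73 female proportion).
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `participant`, `sex`.
#' @export
participant_info <- function(config) {
  ids <- participant_ids(config)
  sex <- vapply(seq_along(ids), function(i) {
    set.seed(derive_seed(config$random_seed, i, 9L))
    if (runif(1) < 47 / 73) "F" else "M"
  }, character(1))
  data.frame(participant = ids, sex = sex, stringsAsFactors = FALSE)
}

# brick-wall FFT band-limitation of white noise columns, standardized to
# unit variance; shape = "flat" keeps a white in-band spectrum, "pink"
# imposes a 1/f power density (flat after the exponent-1 correction)
bandlimited_noise <- function(n, ncol_, fs, lo, hi, shape = "flat") {
  z <- matrix(rnorm(n * ncol_), n, ncol_)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  keep <- f >= lo & f <= hi
  zf <- stats::mvfft(z)
  zf[!keep, ] <- 0
  if (shape == "pink") zf[keep, ] <- zf[keep, ] / sqrt(pmax(f[keep], 1e-6))
  out <- Re(stats::mvfft(zf, inverse = TRUE)) / n
  scale_ <- sqrt(colMeans(out^2))
  sweep(out, 2, pmax(scale_, 1e-12), "/")
}

# slow Gaussian modulators: white noise low-passed below `cutoff`,
# synthesized on a decimated grid (the modulators carry no energy above
# cutoff, so a ~8x-cutoff rate loses nothing) and linearly interpolated to
# the signal rate; columns standardized to unit variance
slow_modulators <- function(ns, fs, cutoff, ncol_) {
  fs_dec <- max(8 * cutoff, 8)
  nd <- ceiling(ns * fs_dec / fs) + 2L
  g <- bandlimited_noise(nd, ncol_, fs_dec, 0, cutoff)
  tt <- (seq_len(ns) - 1) * fs_dec / fs # in decimated-sample units
  lo <- pmin(floor(tt) + 1L, nd - 1L)
  w <- tt - (lo - 1L)
  out <- g[lo, , drop = FALSE] * (1 - w) + g[lo + 1L, , drop = FALSE] * w
  sc <- sqrt(pmax(colMeans(out^2) - colMeans(out)^2, 0))
  sweep(out, 2, pmax(sc, 1e-12), "/")
}

# expected relative band power of the baseline world (1/f-corrected scale),
# used to convert standardized effects into log-amplitude shifts. The pink
# background has corrected density K = bg_sd^2 / log(hi/lo), flat in f.
expected_rel_power <- function(cfg) {
  bands <- band_scheme()
  band_names <- setdiff(names(bands), "total")
  centers <- vapply(band_names, function(b) mean(bands[[b]]), numeric(1))
  sig <- cfg$amp_base[band_names]^2 / 2 * centers
  k <- cfg$bg_sd^2 / log(bands$total[2] / bands$total[1])
  bg <- vapply(band_names, function(b) k * diff(bands[[b]]), numeric(1))
  total <- sum(sig) + k * diff(bands$total)
  (sig + bg) / total
}

#' Generate synthetic epoched recordings
#'
#' Per participant and condition, each region's signal is a sum over bands
#' of constant-modulus in-band carriers (random frequency and phase per
#' epoch) multiplied by slow log-normal amplitude envelopes, plus 1-40 Hz
#' band-limited background activity; channel data are
#' `mixing_matrix %*% regions + sensor noise`. Requested envelope couplings
#' are induced by shared latent components
#' (`sqrt(rho) * common + sqrt(1 - rho) * private` on the Gaussian scale),
#' and the realized ground truths (relative band power; envelope
#' correlations) are returned alongside the data so every downstream
#' estimator can be scored against them.
#'
#' @param config a [simulation_config()].
#' @param participants integer indices of the participants to generate
#'   (default: all). Thanks to per-participant substreams the output for a
#'   subset is bit-identical to the corresponding slice of the full run.
#' @param keep_roi also return the region-space (pre-mixing, noise-free)
#'   epoch sets (`roi_sets`); memory-hungry at full scale.
#' @param keep_envelopes also return the concatenated ground-truth envelope
#'   time series per band and region (`envelopes`); for oracle tests.
#' @return list of class `synthetic_epochs` with elements `sets` (named
#'   list of channel-space [epoch_set()]s, `"<participant>.<condition>"`),
#'   `roi_sets` (optional), `power_truth`, `coupling_truth` (data.frames),
#'   `envelopes` (optional) and `config`.
#' @export
generate_epochs <- function(config, participants = NULL, keep_roi = FALSE,
                            keep_envelopes = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  regions <- names(roi_catalog())
  bands <- band_scheme()
  band_names <- setdiff(names(bands), "total")
  if (is.null(participants)) participants <- seq_len(config$n_participants)
  ids <- participant_ids(config)
  ns <- floor(config$epoch_duration_s * config$fs)
  nep <- config$n_epochs_per_condition
  tvec <- (seq_len(ns) - 1) / config$fs
  p_expect <- expected_rel_power(config)
  sigma_eff <- sqrt(config$amp_cond_sd^2 + config$amp_epoch_sd^2 / nep)
  M <- config$mixing_matrix
  chol_by <- list()
  for (cond in c("control", "negative")) {
    for (bn in band_names) {
      C <- latent_coupling_matrix(config, bn, cond, regions)
      ev <- eigen(C, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
      chol_by[[paste(cond, bn)]] <- L
    }
  }
  wanted_pairs <- unique(names(c(config$baseline_coupling, config$coupling_effects)))

  sets <- list()
  roi_sets <- list()
  pow_rows <- list()
  coup_rows <- list()
  env_store <- list()
  for (i in participants) {
    pid <- ids[i]
    set.seed(derive_seed(config$random_seed, i, 0L))
    u <- matrix(rnorm(length(regions) * length(band_names), sd = config$amp_participant_sd),
                length(regions), length(band_names),
                dimnames = list(regions, band_names))
    for (cond in c("control", "negative")) {
      set.seed(derive_seed(config$random_seed, i, if (cond == "control") 1L else 2L))
      eta <- matrix(rnorm(length(regions) * length(band_names), sd = config$amp_cond_sd),
                    length(regions), length(band_names),
                    dimnames = list(regions, band_names))
      delta <- matrix(0, length(regions), length(band_names),
                      dimnames = list(regions, band_names))
      if (cond == "negative") {
        for (nm in names(config$band_effects)) {
          pr <- parse_measure_name(nm)
          delta[pr$unit, pr$band] <- config$band_effects[[nm]] * sigma_eff / p_expect[[pr$band]]
        }
      }
      roi <- array(0, dim = c(nep, length(regions), ns))
      band_power_acc <- matrix(0, length(regions), length(band_names),
                               dimnames = list(regions, band_names))
      pair_corr_acc <- setNames(numeric(length(wanted_pairs)), wanted_pairs)
      env_keep <- if (keep_envelopes) {
        setNames(lapply(band_names, function(b) matrix(0, nep * ns, length(regions))), band_names)
      }
      for (e in seq_len(nep)) {
        acc <- matrix(0, ns, length(regions))
        for (bi in seq_along(band_names)) {
          bn <- band_names[bi]
          edges <- bands[[bn]]
          margin <- config$env_cutoff_hz + 0.5
          g <- slow_modulators(ns, config$fs, config$env_cutoff_hz, length(regions))
          g <- g %*% chol_by[[paste(cond, bn)]]
          env <- exp(config$env_sigma * g - config$env_sigma^2) # E[env^2] = 1
          fc <- runif(length(regions), edges[1] + margin, edges[2] - margin)
          ph <- runif(length(regions), 0, 2 * pi)
          eps <- rnorm(length(regions), sd = config$amp_epoch_sd)
          A <- config$amp_base[[bn]] * exp(u[, bi] + eta[, bi] + delta[, bi] + eps)
          carr <- cos(tvec %o% (2 * pi * fc) + matrix(ph, ns, length(regions), byrow = TRUE))
          acc <- acc + sweep(env * carr, 2, A, "*")
          band_power_acc[, bi] <- band_power_acc[, bi] + A^2 * colMeans(env^2) / 2 * fc / nep
          for (nm in wanted_pairs) {
            pr <- parse_measure_name(nm)
            if (pr$band != bn) next
            rr <- strsplit(pr$unit, "|", fixed = TRUE)[[1]]
            idx <- match(rr, regions)
            pair_corr_acc[[nm]] <- pair_corr_acc[[nm]] + cor(env[, idx[1]], env[, idx[2]]) / nep
          }
          if (keep_envelopes) env_keep[[bn]][((e - 1) * ns + 1):(e * ns), ] <- env
        }
        bg <- bandlimited_noise(ns, length(regions), config$fs, bands$total[1],
                                bands$total[2], shape = "pink") * config$bg_sd
        roi[e, , ] <- t(acc + bg)
      }
      # channel-space data
      chan <- array(0, dim = c(nep, nrow(M), ns))
      for (e in seq_len(nep)) {
        chan[e, , ] <- M %*% roi[e, , ] +
          matrix(rnorm(nrow(M) * ns, sd = config$sensor_noise_sd), nrow(M), ns)
      }
      key <- paste(pid, cond, sep = ".")
      sets[[key]] <- epoch_set(chan, config$fs, rownames(M), pid, cond)
      if (keep_roi) roi_sets[[key]] <- epoch_set(roi, config$fs, regions, pid, cond)
      # ground truth: relative band power on the 1/f-corrected scale
      k_bg <- config$bg_sd^2 / log(bands$total[2] / bands$total[1])
      bg_band <- vapply(band_names, function(b) k_bg * diff(bands[[b]]), numeric(1))
      for (r in seq_along(regions)) {
        tot <- sum(band_power_acc[r, ]) + k_bg * diff(bands$total)
        for (bi in seq_along(band_names)) {
          pow_rows[[length(pow_rows) + 1L]] <- data.frame(
            participant = pid, condition = cond, region = regions[r],
            band = band_names[bi],
            rel_power_truth = (band_power_acc[r, bi] + bg_band[bi]) / tot,
            stringsAsFactors = FALSE)
        }
      }
      # ground truth: realized envelope correlation per coupled pair,
      # epoch-wise (the aggregation level the AEC estimator targets)
      for (nm in wanted_pairs) {
        pr <- parse_measure_name(nm)
        rr <- strsplit(pr$unit, "|", fixed = TRUE)[[1]]
        coup_rows[[length(coup_rows) + 1L]] <- data.frame(
          participant = pid, condition = cond,
          pair = canonical_pair(rr[1], rr[2]), band = pr$band,
          env_corr_truth = pair_corr_acc[[nm]], stringsAsFactors = FALSE)
      }
      if (keep_envelopes) env_store[[key]] <- env_keep
    }
  }
  structure(list(sets = sets,
                 roi_sets = if (keep_roi) roi_sets,
                 power_truth = do.call(rbind, pow_rows),
                 coupling_truth = do.call(rbind, coup_rows),
                 envelopes = if (keep_envelopes) env_store,
                 config = config),
            class = "synthetic_epochs")
}

#' @export
print.synthetic_epochs <- function(x, ...) {
  cat(sprintf("<synthetic_epochs> %d epoch sets (%d participants x 2 conditions)\n",
              length(x$sets), length(x$sets) / 2))
  invisible(x)
}

#' Recover region time series from channel data
#'
#' The toy counterpart of source reconstruction: applies the Moore-Penrose
#' pseudoinverse of the mixing matrix to every sample. With identity mixing
#' and no sensor noise this is exact.
#'
#' @param x a channel-space [epoch_set()].
#' @param mixing the mixing matrix used in generation (channels x regions).
#' @return an [epoch_set()] of region time series.
#' @export
unmix_epochs <- function(x, mixing) {
  stopifnot(inherits(x, "epoch_set"))
  idx <- match(rownames(mixing), x$channel_labels)
  if (anyNA(idx)) stop("epoch set lacks channels required by the mixing matrix")
  pinv <- solve(crossprod(mixing), t(mixing))
  d <- dim(x$data)
  out <- array(0, dim = c(d[1], ncol(mixing), d[3]))
  for (e in seq_len(d[1])) {
    out[e, , ] <- pinv %*% x$data[e, idx, , drop = TRUE]
  }
  epoch_set(out, x$fs, colnames(mixing), x$participant, x$condition, x$onset)
}

#' Epoch counts per participant and condition
#'
#' @param sets named list of [epoch_set()]s (e.g. `generate_epochs()$sets`).
#' @return data.frame with `participant`, `condition`, `n_epochs` - the
#'   input of [inclusion_filter()].
#' @export
epoch_counts <- function(sets) {
  do.call(rbind, lapply(unname(sets), function(es) {
    data.frame(participant = es$participant, condition = es$condition,
               n_epochs = dim(es$data)[1], stringsAsFactors = FALSE)
  }))
}

#' Generate R-peak timestamp trains
#'
#' Baseline inter-beat intervals are drawn as independent Gaussians around
#' a participant-specific mean; in the negative condition the six intervals
#' mapping to IBI indices 2..7 after each event are shortened by
#' `ibi_effect_ms`. Events too close to the edge of the train are dropped
#' with a warning.
#'
#' @param config a [simulation_config()].
#' @param event_times event onsets in seconds.
#' @param condition `"control"` or `"negative"`.
#' @param participant_idx participant index (drives the substream and the
#'   participant-level baseline IBI).
#' @return strictly increasing numeric vector of R-peak times in seconds.
#' @export
generate_rpeaks <- function(config, event_times, condition = "control",
                            participant_idx = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(event_times) > 1 && min(diff(sort(event_times))) * 1000 <= 12 * config$ibi_mean_ms) {
    stop("event spacing must exceed 12 mean IBIs")
  }
  set.seed(derive_seed(config$random_seed, participant_idx, 3L))
  base_mean <- config$ibi_mean_ms + rnorm(1, sd = config$ibi_participant_sd_ms)
  set.seed(derive_seed(config$random_seed, participant_idx,
                       if (condition == "control") 4L else 5L))
  t_end <- max(event_times) + 15
  n_beats <- ceiling(t_end * 1000 / max(base_mean - 5 * config$ibi_sd_ms, 300)) + 16L
  ibis <- pmax(rnorm(n_beats, base_mean, config$ibi_sd_ms), 250) / 1000
  peaks <- cumsum(ibis)
  if (condition == "negative" && config$ibi_effect_ms != 0) {
    for (ev in sort(event_times)) {
      i <- which.min(abs(peaks - ev))
      if (i + 7 > length(ibis) || i - 4 < 1) {
        warning(sprintf("event at %.3f s too close to the series edge; no effect applied", ev))
        next
      }
      idx <- (i + 2):(i + 7)
      ibis[idx] <- pmax(ibis[idx] - config$ibi_effect_ms / 1000, 0.25)
      peaks <- cumsum(ibis)
    }
  }
  peaks
}

#' Generate the cardiac dataset for all participants
#'
#' Convenience wrapper pairing [generate_rpeaks()] trains with an event
#' table, ready for [ibi_table()].
#'
#' @param config a [simulation_config()].
#' @param participants participant indices (default: all).
#' @return list with `rpeaks` (named list participant -> condition ->
#'   timestamps) and `events` (data.frame `participant`, `condition`,
#'   `time`).
#' @export
generate_cardiac <- function(config, participants = NULL) {
  if (is.null(participants)) participants <- seq_len(config$n_participants)
  ids <- participant_ids(config)
  event_times <- 20 + (seq_len(config$n_events) - 1) * config$event_spacing_s
  rpeaks <- list()
  ev_rows <- list()
  for (i in participants) {
    pid <- ids[i]
    rpeaks[[pid]] <- list(
      control = generate_rpeaks(config, event_times, "control", i),
      negative = generate_rpeaks(config, event_times, "negative", i))
    for (cond in c("control", "negative")) {
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        participant = pid, condition = cond, time = event_times,
        stringsAsFactors = FALSE)
    }
  }
  list(rpeaks = rpeaks, events = do.call(rbind, ev_rows))
}

#' Generate questionnaire scores
#'
#' Gamma-distributed positive scores with a participant random intercept
#' and a configurable condition shift; optionally rounded and clamped to
#' the 1-9 Likert range.
#'
#' @param config a [simulation_config()].
#' @param scale scale name; must appear in `config$score_shifts`.
#' @param participants participant indices (default: all).
#' @param likert overrides `config$likert`.
#' @return data.frame with `participant`, `sex`, `condition`, `scale`,
#'   `value`.
#' @export
generate_scores <- function(config, scale = "valence", participants = NULL,
                            likert = config$likert) {
  stopifnot(inherits(config, "simulation_config"))
  if (!scale %in% names(config$score_shifts)) {
    stop("unknown scale `", scale, "`; configure it in score_shifts")
  }
  if (is.null(participants)) participants <- seq_len(config$n_participants)
  ids <- participant_ids(config)
  info <- participant_info(config)
  shift <- config$score_shifts[[scale]]
  tag_base <- 10L + 2L * match(scale, names(config$score_shifts))
  rows <- list()
  for (i in participants) {
    pid <- ids[i]
    set.seed(derive_seed(config$random_seed, i, tag_base))
    b <- rnorm(1, sd = config$score_participant_sd)
    set.seed(derive_seed(config$random_seed, i, tag_base + 1L))
    for (cond in c("control", "negative")) {
      mu <- config$score_mean + b + if (cond == "negative") shift else 0
      if (mu <= 0) stop("requested score mean is non-positive (gamma support); participant ", pid)
      shape <- (mu / config$score_sd)^2
      v <- rgamma(config$n_sam_per_condition, shape = shape, rate = shape / mu)
      if (likert) v <- pmin(pmax(round(v), 1), 9)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, sex = info$sex[info$participant == pid],
        condition = cond, scale = scale, value = v, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
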
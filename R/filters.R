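#' Butterworth filter design
#'
#' Designs digital Butterworth filters via the analog prototype and the
#' bilinear transform. The returned object carries both the transfer
#' function (`b`, `a`) and a second-order-sections factorization (`sos`);
#' all filtering in the package runs through the sections, which stay
#' numerically stable even for high orders with band edges close to DC
#' (where the expanded polynomial form blows up).
#'
#' @param order filter order of the analog prototype (a band-pass of order
#'   `n` has `2n` poles).
#' @param w critical frequency (low-pass) or length-2 band edges (band-pass),
#'   normalized to the Nyquist frequency, i.e. in (0, 1).
#' @param type `"pass"` or `"low"`.
#' @return list of class `butter_filter` with `b`, `a` (descending powers of
#'   z) and `sos` (one row per biquad: b0 b1 b2 a0 a1 a2).
#' @examples
#' f <- butter_filter(4, c(8, 13) / (512 / 2), "pass")
#' length(f$a)  # 9 coefficients: 8 poles
#' @export
butter_filter <- function(order, w, type = c("pass", "low")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) {
    stop("normalized frequencies must lie strictly inside (0, 1)")
  }
  k <- seq_len(order)
  # analog low-pass prototype poles on the unit circle, unit gain, no zeros
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 # internal sampling rate of the bilinear transform
  warped <- 2 * fs2 * tan(pi * w / 2)
  if (type == "low") {
    sp <- p * warped
    sz <- complex(0)
    gain <- warped^order
  } else {
    if (length(w) != 2 || w[1] >= w[2]) stop("band-pass needs increasing band edges")
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    ph <- p * bw / 2
    sp <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
    sz <- rep(0 + 0i, order)
    gain <- bw^order
  }
  # bilinear transform s -> z
  zp <- (2 * fs2 + sp) / (2 * fs2 - sp)
  zz <- (2 * fs2 + sz) / (2 * fs2 - sz)
  zz <- c(zz, rep(-1 + 0i, length(sp) - length(sz)))
  gain <- gain * Re(prod(2 * fs2 - sz) / prod(2 * fs2 - sp))
  structure(list(b = Re(gain * poly_from_roots(zz)),
                 a = Re(poly_from_roots(zp)),
                 sos = sos_from_zpk(zz, zp, gain)),
            class = "butter_filter")
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# factor a zero/pole/gain design into second-order sections: conjugate pole
# pairs (unit-circle-nearest first) each matched with a spread of zeros,
# the gain distributed evenly across sections
sos_from_zpk <- function(z, p, k) {
  split_pairs <- function(r) {
    cplx <- r[Im(r) > 1e-9]
    cplx <- cplx[order(-Mod(cplx))]
    pairs <- lapply(cplx, function(x) c(x, Conj(x)))
    re <- Re(r[abs(Im(r)) <= 1e-9])
    re <- re[order(-abs(re))]
    while (length(re) >= 2) {
      pairs[[length(pairs) + 1]] <- c(re[1], re[length(re)]) # spread extremes
      re <- re[-c(1, length(re))]
    }
    if (length(re) == 1) pairs[[length(pairs) + 1]] <- re[1]
    pairs
  }
  pp <- split_pairs(p)
  zp <- split_pairs(z)
  nsec <- length(pp)
  while (length(zp) < nsec) zp[[length(zp) + 1]] <- numeric(0)
  g <- abs(k)^(1 / nsec) * ifelse(k < 0, 1, 1)
  sos <- matrix(0, nsec, 6)
  for (j in seq_len(nsec)) {
    bj <- Re(poly_from_roots(zp[[j]])) * g
    if (j == 1 && k < 0) bj <- -bj
    aj <- Re(poly_from_roots(pp[[j]]))
    sos[j, ] <- c(c(bj, numeric(3 - length(bj))), c(aj, numeric(3 - length(aj))))
  }
  sos
}

# steady-state state vector of one biquad for a unit-step input
biquad_zi <- function(b, a) {
  A <- diag(2)
  A[, 1] <- A[, 1] + a[2:3]
  A[1, 2] <- A[1, 2] - 1
  solve(A, b[2:3] - a[2:3] * b[1])
}

sosfilt <- function(sos, x, x0) {
  scale <- 1
  for (j in seq_len(nrow(sos))) {
    b <- sos[j, 1:3]
    a <- sos[j, 4:6]
    zi <- biquad_zi(b, a) * x0 * scale
    x <- iir_filter_cpp(b, a, x, zi)
    scale <- scale * sum(b) / sum(a) # DC gain feeding the next section
  }
  x
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forwards and backwards through its second-order
#' sections so the net phase response is zero, with odd-reflection padding
#' and steady-state initial conditions at both ends to suppress start-up
#' transients.
#'
#' @param filt a [butter_filter()].
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(filt, x) {
  sos <- filt$sos
  # pad until the slowest pole's transient has decayed to ~1e-6, capped at
  # the signal length (filters with edges near DC ring for seconds)
  pmax_ <- sqrt(max(sos[, 6]))
  pad <- 3 * (2 * nrow(sos) + 1)
  if (pmax_ < 1) pad <- max(pad, ceiling(log(1e-6) / log(pmax_)))
  pad <- min(pad, length(x) - 1L)
  if (length(x) <= 3 * (2 * nrow(sos) + 1)) {
    stop("signal too short for zero-phase filtering (need > ",
         3 * (2 * nrow(sos) + 1), " samples)")
  }
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
  y <- sosfilt(sos, xe, xe[1])
  y <- rev(y)
  y <- sosfilt(sos, y, y[1])
  y <- rev(y)
  y[(pad + 1):(pad + length(x))]
}

#' Analytic signal and amplitude envelope
#'
#' The analytic signal is obtained in the frequency domain (negative
#' frequencies zeroed, positive doubled); its pointwise magnitude is the
#' amplitude envelope used for envelope-correlation connectivity.
#'
#' @param x real-valued numeric vector.
#' @return `analytic_signal`: complex vector; `envelope`: non-negative
#'   numeric vector of the same length.
#' @examples
#' t <- seq(0, 1, length.out = 512)
#' e <- envelope(3 * cos(2 * pi * 40 * t))
#' round(median(e), 2)  # ~3
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' @rdname analytic_signal
#' @export
envelope <- function(x) Mod(analytic_signal(x))
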
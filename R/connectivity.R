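#' Region-of-interest catalog
#'
#' Reads the catalog mapping each of the 10 cortical regions of interest
#' (anterior insula, anterior/posterior cingulate cortex, precuneus,
#' orbitofrontal cortex; left and right) to its constituent atlas scouts.
#' The catalog ships as an editable YAML file under `inst/extdata`.
#'
#' @param path path to a YAML catalog; defaults to the packaged catalog.
#' @return named list: region -> character vector of scout labels.
#' @export
roi_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "roi_catalog.yaml", package = "stressfc")
  }
  if (!file.exists(path)) stop("ROI catalog not found: ", path)
  cat_ <- yaml::read_yaml(path)
  if (any(lengths(cat_) == 0)) stop("every region must list at least one scout")
  scouts <- unlist(cat_, use.names = FALSE)
  if (anyDuplicated(scouts)) {
    stop("scout lists must be disjoint across regions; duplicated: ",
         paste(unique(scouts[duplicated(scouts)]), collapse = ", "))
  }
  cat_
}

#' Combine scout time series into one region time series
#'
#' Composite regions span several atlas scouts; their representative signal
#' is the first principal component across the scout time series. A single
#' scout is returned unchanged. The component sign is fixed so that its
#' correlation with the scout mean is non-negative; when the scout mean
#' (nearly) cancels, the dominant loading is made positive instead, keeping
#' the sign deterministic.
#'
#' @param x numeric matrix `sample x scout` (or a list of equal-length
#'   vectors).
#' @return numeric vector, one sample per row of `x`.
#' @export
combine_scouts_pca <- function(x) {
  if (is.list(x)) {
    if (length(unique(lengths(x))) != 1) stop("scout time series have unequal lengths")
    x <- do.call(cbind, x)
  }
  if (is.null(dim(x))) return(as.numeric(x))
  if (ncol(x) == 1) return(x[, 1])
  dec <- prcomp(x, center = TRUE, scale. = FALSE)
  pc <- dec$x[, 1]
  ref <- rowMeans(x)
  r <- if (sd(ref) > 0) cor(pc, ref) else 0
  if (abs(r) > 0.1) {
    if (r < 0) pc <- -pc
  } else {
    # scout mean (nearly) cancels - e.g. anti-phase scouts; fall back to
    # making the dominant loading positive so the sign stays deterministic
    load <- dec$rotation[, 1]
    if (load[which.max(abs(load))] < 0) pc <- -pc
  }
  pc
}

#' Gram-Schmidt orthogonalization of one signal against another
#'
#' Removes from `y` its least-squares projection onto `x`, so the returned
#' series has (numerically) zero inner product with `x`. Zero-lag shared
#' components - the signature of spatial leakage - are thereby eliminated.
#' The operation is asymmetric: `orthogonalize(x, y)` differs from
#' `orthogonalize(y, x)`, which is why [aec_pair()] averages both orders.
#'
#' @param x reference signal (must not be identically zero).
#' @param y signal to orthogonalize.
#' @return `y` minus its projection on `x`; if the residual is numerically
#'   zero (collinear inputs) it carries attribute `collinear = TRUE` and a
#'   warning is raised, since a downstream envelope correlation on it is
#'   undefined.
#' @export
orthogonalize <- function(x, y) {
  stopifnot(length(x) == length(y))
  xx <- sum(x * x)
  if (xx == 0) stop("reference signal is identically zero; cannot orthogonalize")
  r <- y - x * (sum(x * y) / xx)
  if (sqrt(sum(r * r)) <= 1e-10 * max(sqrt(sum(y * y)), 1e-300)) {
    warning("signals are collinear: orthogonalized residual is numerically zero")
    attr(r, "collinear") <- TRUE
  }
  r
}

#' Orthogonalized amplitude envelope correlation of a signal pair
#'
#' The functional-connectivity estimator of the pipeline. Per epoch, both
#' signals are band-pass filtered, pairwise orthogonalized in both orders,
#' and Hilbert amplitude envelopes are correlated:
#' `corr(env(x), env(y_orth_x))` and `corr(env(y), env(x_orth_y))` are
#' averaged (making the result exactly symmetric in the pair), and epoch
#' values are averaged into one AEC in `[-1, 1]`. The first and last
#' `trim_s` seconds of each epoch are discarded before the correlation to
#' avoid filter and Hilbert edge artifacts.
#'
#' @param x,y numeric matrices `epoch x sample` (broadband signals).
#' @param fs sampling rate in Hz.
#' @param band length-2 band edges in Hz.
#' @param order Butterworth prototype order for the band-pass.
#' @param trim_s edge trim per epoch side, in seconds (default 0.25).
#' @return one AEC value; attribute `n_epochs_used` counts contributing
#'   epochs. Epochs with a zero-variance envelope are skipped with a
#'   warning; if all epochs are skipped the value is `NA`.
#' @export
aec_pair <- function(x, y, fs, band, order = 4, trim_s = 0.25) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  stopifnot(all(dim(x) == dim(y)), length(band) == 2, band[1] < band[2])
  f <- butter_filter(order, band / (fs / 2), "pass")
  trim <- round(trim_s * fs)
  ns <- ncol(x)
  if (ns - 2 * trim < 8) stop("epochs too short for the requested edge trim")
  keep <- (trim + 1):(ns - trim)
  vals <- numeric(0)
  skipped <- 0L
  for (e in seq_len(nrow(x))) {
    bx <- filtfilt_zero_phase(f, x[e, ])
    by <- filtfilt_zero_phase(f, y[e, ])
    v <- aec_epoch(bx, by, keep)
    if (is.na(v)) skipped <- skipped + 1L else vals <- c(vals, v)
  }
  if (skipped > 0) {
    warning(skipped, " epoch(s) skipped (zero-variance envelope or collinear pair)")
  }
  out <- if (length(vals) == 0) NA_real_ else mean(vals)
  attr(out, "n_epochs_used") <- length(vals)
  out
}

# one epoch of band-passed data; keep = indices surviving the edge trim
aec_epoch <- function(bx, by, keep) {
  ex <- envelope(bx)[keep]
  ey <- envelope(by)[keep]
  ryx <- suppressWarnings(orthogonalize(bx, by))
  rxy <- suppressWarnings(orthogonalize(by, bx))
  if (isTRUE(attr(ryx, "collinear")) || isTRUE(attr(rxy, "collinear"))) return(NA_real_)
  eyx <- envelope(ryx)[keep]
  exy <- envelope(rxy)[keep]
  if (sd(ex) == 0 || sd(ey) == 0 || sd(eyx) == 0 || sd(exy) == 0) return(NA_real_)
  (cor(ex, eyx) + cor(ey, exy)) / 2
}

#' Plain (non-orthogonalized) envelope correlation
#'
#' Reference estimator without leakage correction: band-pass, Hilbert
#' envelope, Pearson correlation, averaged over epochs. Used to demonstrate
#' how instantaneous linear mixing inflates connectivity when
#' orthogonalization is omitted.
#'
#' @inheritParams aec_pair
#' @return mean envelope correlation across epochs.
#' @export
env_correlation_raw <- function(x, y, fs, band, order = 4, trim_s = 0.25) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  f <- butter_filter(order, band / (fs / 2), "pass")
  trim <- round(trim_s * fs)
  keep <- (trim + 1):(ncol(x) - trim)
  vals <- vapply(seq_len(nrow(x)), function(e) {
    ex <- envelope(filtfilt_zero_phase(f, x[e, ]))[keep]
    ey <- envelope(filtfilt_zero_phase(f, y[e, ]))[keep]
    if (sd(ex) == 0 || sd(ey) == 0) NA_real_ else cor(ex, ey)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

canonical_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Enumerate the connection space
#'
#' All unordered region pairs crossed with the requested frequency bands,
#' optionally restricted to pairs touching an anchor set (e.g. the left and
#' right precuneus). Pairs are stored canonically (alphabetically sorted)
#' so no reversed duplicates occur.
#'
#' @param regions character vector of region names (default: the 10 regions
#'   of [roi_catalog()]).
#' @param bands character vector of band names.
#' @param anchor optional character vector; keep only pairs with at least
#'   one member in this set.
#' @return data.frame with columns `region_a`, `region_b`, `pair`, `band`.
#' @examples
#' nrow(enumerate_connections(bands = c("theta", "alpha", "beta")))  # 135
#' @export
enumerate_connections <- function(regions = names(roi_catalog()),
                                  bands = c("alpha", "beta"), anchor = NULL) {
  regions <- sort(unique(regions))
  if (length(regions) < 2) {
    return(data.frame(region_a = character(0), region_b = character(0),
                      pair = character(0), band = character(0)))
  }
  idx <- utils::combn(length(regions), 2)
  pairs <- data.frame(region_a = regions[idx[1, ]], region_b = regions[idx[2, ]],
                      stringsAsFactors = FALSE)
  if (!is.null(anchor)) {
    pairs <- pairs[pairs$region_a %in% anchor | pairs$region_b %in% anchor, ]
  }
  out <- merge(pairs, data.frame(band = bands), by = NULL)
  out$pair <- canonical_pair(out$region_a, out$region_b)
  out <- out[order(out$band, out$pair), c("region_a", "region_b", "pair", "band")]
  rownames(out) <- NULL
  out
}

#' Connectivity table for a set of region-space epoch sets
#'
#' Computes [aec_pair()] for every requested connection and band, per
#' participant and condition: the tidy long-format table consumed by the
#' statistics layer.
#'
#' @param epoch_sets list of [epoch_set()] objects holding region time
#'   series (channel labels = region names).
#' @param connections data.frame from [enumerate_connections()].
#' @param bands a [band_scheme()] translating band names to edges.
#' @param ... passed to [aec_pair()].
#' @return data.frame with columns `participant`, `condition`, `pair`,
#'   `band`, `aec`.
#' @export
connectivity_table <- function(epoch_sets, connections = enumerate_connections(),
                               bands = band_scheme(), ...) {
  rows <- list()
  for (es in epoch_sets) {
    stopifnot(inherits(es, "epoch_set"))
    for (k in seq_len(nrow(connections))) {
      ra <- connections$region_a[k]
      rb <- connections$region_b[k]
      bn <- connections$band[k]
      ia <- match(ra, es$channel_labels)
      ib <- match(rb, es$channel_labels)
      if (is.na(ia) || is.na(ib)) stop("region not present in epoch set: ", ra, " / ", rb)
      v <- aec_pair(es$data[, ia, , drop = TRUE], es$data[, ib, , drop = TRUE],
                    es$fs, bands[[bn]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = es$participant, condition = es$condition,
        pair = canonical_pair(ra, rb), band = bn, aec = as.numeric(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
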
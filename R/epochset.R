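#' Epoched multichannel recording
#'
#' The central container of the pipeline: a fixed-length collection of
#' epochs from one participant in one condition. `data` is a 3-D array
#' with dimensions `epoch x channel x sample` (voltages in microvolt for
#' channel-space data; arbitrary units for region time series).
#'
#' @param data 3-D numeric array, `epoch x channel x sample`.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per channel.
#' @param participant participant identifier.
#' @param condition condition label, e.g. `"control"` or `"negative"`.
#' @param onset epoch onset relative to the trigger, in seconds
#'   (default -0.2: epochs start 200 ms before the feedback trigger).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channel_labels, participant = NA_character_,
                      condition = NA_character_, onset = -0.2) {
  if (length(dim(data)) != 3) stop("`data` must be a 3-D array (epoch x channel x sample)")
  if (dim(data)[2] != length(channel_labels)) {
    stop("number of channel labels (", length(channel_labels),
         ") does not match dim(data)[2] (", dim(data)[2], ")")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         participant = as.character(participant), condition = as.character(condition),
         onset = onset),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> participant %s, condition %s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$participant, x$condition, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_epochs <- function(x) dim(x$data)[1]

#' Write / read an epoch set as plain delimited text
#'
#' One tab-separated matrix of `(epoch * channel)` rows by `sample` columns,
#' with a JSON sidecar (`<path>.json`) holding the sampling rate, labels and
#' axis order, so the files are self-describing. This is the portable
#' exchange format of the package (EDF export is not provided).
#'
#' @param x an [epoch_set()].
#' @param path file path for the matrix; the sidecar is written next to it.
#' @return `write_epoch_set`: `path`, invisibly. `read_epoch_set`: an
#'   [epoch_set()].
#' @export
write_epoch_set <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  write.table(flat, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(fs = x$fs, channel_labels = x$channel_labels,
               participant = x$participant, condition = x$condition,
               onset = x$onset, n_epochs = d[1], n_channels = d[2],
               n_samples = d[3],
               axis_order = "rows are epoch-major then channel; columns are samples")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(read.table(path, sep = "\t"))
  data <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels, meta$n_epochs)),
                c(3, 2, 1))
  epoch_set(data, meta$fs, meta$channel_labels, meta$participant,
            meta$condition, meta$onset)
}
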
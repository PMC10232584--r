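#' Event-locked inter-beat intervals
#'
#' For one event: the R-peak closest to the event onset is the anchor
#' (ties broken toward the earlier peak); `IBI_0` is the interval from the
#' previous peak to the anchor, `IBI_k = t[i+k] - t[i+k-1]` extends the
#' indexing three beats back (`IBI_-3`) and eight beats forward (`IBI_8`).
#' All intervals are re-referenced to `IBI_-2`, giving difference scores in
#' which a negative value means a shorter interval, i.e. heart-rate
#' acceleration relative to the pre-event reference.
#'
#' @param rpeaks strictly increasing R-peak timestamps in seconds.
#' @param event_time event (feedback) onset in seconds.
#' @return data.frame with columns `index` (-3..8), `ibi` (ms) and
#'   `ibi_diff` (ms, `ibi - ibi[index == -2]`), or `NULL` with a warning
#'   when fewer than 4 peaks precede or 8 follow the anchor.
#' @export
align_ibis <- function(rpeaks, event_time) {
  stopifnot(length(event_time) == 1)
  if (is.unsorted(rpeaks, strictly = TRUE)) stop("R-peak timestamps must be strictly increasing")
  i <- which.min(abs(rpeaks - event_time)) # ties resolve to the earlier peak
  ks <- -3:8
  if (i - 4 < 1 || i + 8 > length(rpeaks)) {
    warning(sprintf("event at %.3f s dropped: insufficient R-peaks around the anchor", event_time))
    return(NULL)
  }
  ibi <- (rpeaks[i + ks] - rpeaks[i + ks - 1]) * 1000
  if (any(ibi <= 0)) stop("non-positive inter-beat interval encountered")
  data.frame(index = ks, ibi = ibi, ibi_diff = ibi - ibi[ks == -2])
}

#' Event-locked IBI table across participants
#'
#' Applies [align_ibis()] to every event of every participant and stacks
#' the result into the tidy long-format table consumed by the statistics
#' layer.
#'
#' @param rpeaks_by_participant named list: participant -> list with one
#'   numeric R-peak vector per condition (e.g.
#'   `list(control = ..., negative = ...)`).
#' @param events data.frame with columns `participant`, `condition`,
#'   `time` (seconds).
#' @return data.frame with columns `participant`, `condition`, `event`,
#'   `index`, `ibi`, `ibi_diff`.
#' @export
ibi_table <- function(rpeaks_by_participant, events) {
  stopifnot(all(c("participant", "condition", "time") %in% names(events)))
  rows <- list()
  for (k in seq_len(nrow(events))) {
    p <- as.character(events$participant[k])
    cond <- as.character(events$condition[k])
    rp <- rpeaks_by_participant[[p]][[cond]]
    if (is.null(rp)) stop("no R-peak series for participant ", p, ", condition ", cond)
    al <- align_ibis(rp, events$time[k])
    if (is.null(al)) next
    al$participant <- p
    al$condition <- cond
    al$event <- k
    rows[[length(rows) + 1L]] <- al
  }
  out <- do.call(rbind, rows)
  out[, c("participant", "condition", "event", "index", "ibi", "ibi_diff")]
}

#' Condition contrast of IBI-difference scores
#'
#' Per IBI index, fits the linear mixed model
#' `ibi_diff ~ condition + (1 | participant)` (always linear: difference
#' scores can be negative, which rules out a gamma family) and extracts the
#' negative-vs-control contrast. Event-level rows are first averaged per
#' participant and condition.
#'
#' @param tbl an [ibi_table()].
#' @param conditions length-2 character: reference and treatment level.
#' @return data.frame, one row per index: `index`, `mean_control`,
#'   `mean_negative`, `estimate`, `se`, `t`, `p`.
#' @export
condition_contrast_ibi <- function(tbl, conditions = c("control", "negative")) {
  if (length(unique(tbl$participant)) < 2) {
    stop("only one participant: the random-intercept model is degenerate; ",
         "fit a fixed-effects (paired) model instead")
  }
  agg <- aggregate(ibi_diff ~ participant + condition + index, data = tbl, FUN = mean)
  out <- lapply(sort(unique(agg$index)), function(k) {
    d <- agg[agg$index == k, ]
    d$condition <- factor(d$condition, levels = conditions)
    d$value <- d$ibi_diff
    fit <- fit_condition_model(d, allow_gamma = FALSE)
    data.frame(index = k,
               mean_control = mean(d$value[d$condition == conditions[1]]),
               mean_negative = mean(d$value[d$condition == conditions[2]]),
               estimate = fit$beta, se = fit$se, t = fit$t, p = fit$p_raw)
  })
  do.call(rbind, out)
}
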
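# Fatigue-state ground truth from reaction times.
#
# Reaction times to rudder orders are clustered on the 1-D RT axis into
# three groups (k-means); clusters are relabeled by ascending center so
# that 1 = alert (fastest), 2 = middle, 3 = fatigue (slowest). The
# alert/middle/fatigue EEG sections of a session are the 180 s spans
# around the orders with the minimum, median and maximum RT.

#' Cluster reaction times into three fatigue states
#'
#' 1-D k-means (50 random restarts) on the pooled RT values; clusters are
#' relabeled by ascending center, which makes the output invariant to
#' initialization whenever the same partition is reached. Decision
#' boundaries are the midpoints between adjacent centers.
#'
#' @param rts numeric reaction times in seconds, or a data frame with an
#'   `rt_s` column (e.g. from [read_rt_log()]).
#' @param k number of states (default 3).
#' @param seed RNG seed for the restarts.
#' @return object of class `state_partition`: `centers` (ascending),
#'   `boundaries` (k-1 cut points), `assignments` (state per input).
#' @export
cluster_rts <- function(rts, k = 3, seed = 1) {
  if (is.data.frame(rts)) rts <- rts$rt_s
  rts <- as.numeric(rts)
  if (length(unique(rts)) < k)
    stop("degenerate clustering: fewer than ", k, " distinct RT values")
  set.seed(seed)
  fit <- stats::kmeans(rts, centers = k, nstart = 50, iter.max = 100)
  ord <- order(fit$centers)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  centers <- sort(as.numeric(fit$centers))
  structure(list(
    centers = centers,
    boundaries = (centers[-k] + centers[-1]) / 2,
    assignments = relabel[fit$cluster]
  ), class = "state_partition")
}

#' Label a reaction time with its fatigue state
#'
#' Nearest-center assignment under a fitted [cluster_rts()] partition;
#' deterministic and monotone (a larger RT never maps to a lower state).
#'
#' @param rt reaction time(s) in seconds.
#' @param partition a `state_partition`.
#' @return integer state(s) in 1..k.
#' @export
label_rt <- function(rt, partition) {
  stopifnot(inherits(partition, "state_partition"))
  vapply(rt, function(r) which.min(abs(partition$centers - r)), integer(1))
}

#' Select the alert/middle/fatigue EEG sections of a session
#'
#' Returns three `section_s`-second spans centered on the order times of
#' the minimum-RT, median-RT and maximum-RT records (ties broken by the
#' earliest occurrence; even counts use the lower median), clipped to the
#' recording bounds.
#'
#' @param recording an [eeg_recording()] covering the RT timestamps.
#' @param rt_log data frame with `order_time_s` and `rt_s`.
#' @param section_s section length in seconds (default 180).
#' @return named list `alert`, `middle`, `fatigue` of `c(start, end)`
#'   spans in seconds.
#' @export
select_state_sections <- function(recording, rt_log, section_s = 180) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(rt_log) < 3) stop("need at least 3 RT records")
  dur <- recording_duration(recording)
  if (dur < section_s)
    stop("recording (", dur, " s) shorter than one ", section_s, " s section")
  rt <- rt_log$rt_s
  t_ord <- rt_log$order_time_s
  pick <- function(target_rt) t_ord[which(rt == target_rt)[1L]]
  lower_median <- sort(rt)[ceiling(length(rt) / 2)]
  anchors <- c(alert = pick(min(rt)), middle = pick(lower_median),
               fatigue = pick(max(rt)))
  lapply(anchors, function(tc) {
    start <- tc - section_s / 2
    start <- min(max(start, 0), dur - section_s)
    c(start = start, end = start + section_s)
  })
}
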
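# Session-level behavioural variables: windowed counts, per-contact-period
# emission rates and the play asymmetry score.

#' Count detections with onset inside a half-open window
#'
#' A detection is counted if its onset lies in `[start_s, end_s)`; half-open
#' windows prevent double counting at shared boundaries, and assignment by
#' onset means a call beginning inside a period counts there even if it ends
#' later.
#'
#' @param dets Detections tibble with an `onset_s` column.
#' @param start_s,end_s Window bounds in seconds.
#' @return Integer count.
#' @export
count_in_window <- function(dets, start_s, end_s) {
  if (end_s <= start_s) abort("window must satisfy start_s < end_s")
  sum(dets$onset_s >= start_s & dets$onset_s < end_s)
}

#' Per-contact-period emission rates
#'
#' Assigns each detection to the contact period containing its onset
#' (half-open `[start, end)` intervals), then sums counts and durations per
#' period type and reports the emission rate count / summed duration. A
#' detection whose onset falls outside every period raises a warning and is
#' counted under the `none` (no-contact) type.
#'
#' @param dets Detections tibble.
#' @param periods Periods tibble (`period_type`, `start_s`, `end_s`), e.g.
#'   from [make_contact_schedule()]; periods must not overlap.
#' @return A rates tibble, one row per period type present in `periods`:
#'   `period_type`, `total_duration_s`, `count`, `rate_per_s`.
#' @examples
#' periods <- make_contact_schedule(60)
#' dets <- tibble::tibble(onset_s = c(2, 16, 17, 40))
#' emission_rates(dets, periods)
#' @export
emission_rates <- function(dets, periods) {
  stopifnot(all(periods$end_s > periods$start_s))
  o <- order(periods$start_s)
  ps <- periods[o, ]
  if (nrow(ps) > 1 && any(ps$start_s[-1] < ps$end_s[-nrow(ps)])) {
    abort("periods must not overlap")
  }
  idx <- rep(NA_integer_, nrow(dets))
  for (i in seq_len(nrow(ps))) {
    inside <- dets$onset_s >= ps$start_s[i] & dets$onset_s < ps$end_s[i]
    idx[inside] <- i
  }
  type_of_det <- ps$period_type[idx]
  if (anyNA(idx) && nrow(dets) > 0) {
    warn(sprintf("%d detection(s) fall outside all periods; counted as 'none'",
                 sum(is.na(idx))))
    type_of_det[is.na(idx)] <- "none"
  }
  ps |>
    mutate(dur = .data$end_s - .data$start_s) |>
    group_by(.data$period_type) |>
    summarise(total_duration_s = sum(.data$dur), .groups = "drop") |>
    left_join(
      tibble(period_type = type_of_det) |>
        dplyr::count(.data$period_type, name = "count"),
      by = "period_type"
    ) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           rate_per_s = .data$count / .data$total_duration_s)
}

#' Play asymmetry score
#'
#' `(delivered - received) / (delivered + received)`: -1 when a rat only
#' received pinnings, +1 when it only delivered them, 0 for equal numbers.
#' Undefined (returned as `NA` with a warning) when both counts are zero, as
#' for rats whose play arena prevented pinning altogether.
#'
#' @param delivered,received Non-negative pinning counts (vectorised).
#' @return Numeric score(s) in `[-1, 1]`, `NA` where both counts are zero.
#' @examples
#' asymmetry_score(10, 0)   #  1
#' asymmetry_score(5, 5)    #  0
#' asymmetry_score(0, 7)    # -1
#' @export
asymmetry_score <- function(delivered, received) {
  if (any(delivered < 0) || any(received < 0)) abort("counts must be non-negative")
  tot <- delivered + received
  if (any(tot == 0)) {
    warn("undefined score: delivered + received = 0; returning NA")
  }
  ifelse(tot == 0, NA_real_, (delivered - received) / tot)
}

#' Add the asymmetry score to a play table
#'
#' @param play Play tibble with `pinnings_delivered` and `pinnings_received`.
#' @return The table with an `asymmetry` column ([asymmetry_score()]).
#' @export
add_asymmetry <- function(play) {
  mutate(play, asymmetry = suppressWarnings(
    asymmetry_score(.data$pinnings_delivered, .data$pinnings_received)))
}
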
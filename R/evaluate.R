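# Detection-vs-truth matching and accuracy summaries.

interval_iou <- function(a_on, a_off, b_on, b_off) {
  inter <- pmax(0, pmin(a_off, b_off) - pmax(a_on, b_on))
  union <- pmax(a_off, b_off) - pmin(a_on, b_on)
  ifelse(union > 0, inter / union, 0)
}

#' Match detections to ground-truth annotations
#'
#' One-to-one greedy matching by descending temporal intersection-over-union
#' (IoU). A detection/truth pair is matchable if its IoU is at least
#' `iou_min` or its onsets differ by at most `onset_tol_ms`. Recall is
#' matched/truth and precision matched/detected; with no detections,
#' precision is 1 by convention (no false alarms), and with no truth calls
#' recall is 1.
#'
#' @param dets Detections tibble ([detect_recording()] output).
#' @param truth Truth annotations tibble with `onset_s`, `offset_s` (e.g.
#'   from [synth_recording()]).
#' @param iou_min Minimum temporal IoU for a match.
#' @param onset_tol_ms Alternative onset-difference tolerance in ms.
#' @return A list of class `usv_eval`: counts `n_truth`, `n_detected`,
#'   `n_matched`, rates `recall`, `precision`, `f1`, and a `pairs` tibble of
#'   matched indices with their IoU.
#' @examples
#' truth <- tibble::tibble(onset_s = c(0.1, 0.5), offset_s = c(0.15, 0.56))
#' evaluate_detections(truth, truth)   # perfect detector
#' @export
evaluate_detections <- function(dets, truth, iou_min = 0.3, onset_tol_ms = 5) {
  n_d <- nrow(dets)
  n_t <- nrow(truth)
  pairs <- tibble(det = integer(), truth = integer(), iou = numeric())
  if (n_d > 0 && n_t > 0) {
    cand <- tidyr::expand_grid(det = seq_len(n_d), truth = seq_len(n_t))
    cand$iou <- interval_iou(dets$onset_s[cand$det], dets$offset_s[cand$det],
                             truth$onset_s[cand$truth], truth$offset_s[cand$truth])
    cand$d_on <- abs(dets$onset_s[cand$det] - truth$onset_s[cand$truth])
    cand <- cand |>
      filter(.data$iou >= iou_min | .data$d_on <= onset_tol_ms / 1000) |>
      arrange(dplyr::desc(.data$iou))
    used_d <- logical(n_d)
    used_t <- logical(n_t)
    for (i in seq_len(nrow(cand))) {
      di <- cand$det[i]; ti <- cand$truth[i]
      if (!used_d[di] && !used_t[ti]) {
        used_d[di] <- TRUE
        used_t[ti] <- TRUE
        pairs <- bind_rows(pairs, tibble(det = di, truth = ti, iou = cand$iou[i]))
      }
    }
  }
  n_m <- nrow(pairs)
  recall <- if (n_t == 0) 1 else n_m / n_t
  precision <- if (n_d == 0) 1 else n_m / n_d
  f1 <- if (recall + precision == 0) 0 else 2 * recall * precision / (recall + precision)
  structure(list(n_truth = n_t, n_detected = n_d, n_matched = n_m,
                 recall = recall, precision = precision, f1 = f1,
                 pairs = pairs),
            class = "usv_eval")
}

#' @export
print.usv_eval <- function(x, ...) {
  cat(sprintf(
    "<usv_eval: %d truth, %d detected, %d matched | recall %.3f, precision %.3f, F1 %.3f>\n",
    x$n_truth, x$n_detected, x$n_matched, x$recall, x$precision, x$f1))
  invisible(x)
}

#' @method tidy usv_eval
#' @export
tidy.usv_eval <- function(x, ...) {
  tibble(n_truth = x$n_truth, n_detected = x$n_detected,
         n_matched = x$n_matched, recall = x$recall,
         precision = x$precision, f1 = x$f1)
}
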
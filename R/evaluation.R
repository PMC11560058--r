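#' Confusion counts for whale detection
#'
#' @param tp,fp,fn nonnegative counts: true positives (objects confirmed by
#'   the observer), false positives (overcount) and false negatives
#'   (undercount).
#' @param identified observer-verified whale count; must equal `tp + fn`.
#' @param total_count the algorithm's detection-object count (default
#'   `tp + fp`).
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, identified = tp + fn,
                             total_count = tp + fp) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  if (any(c(tp, fp, fn) < 0)) stop("counts must be nonnegative")
  if (tp + fn != identified)
    stop("tp + fn must equal the identified whale count")
  structure(list(tp = tp, fp = fp, fn = fn,
                 identified = as.integer(identified),
                 total_count = as.integer(total_count)),
            class = "confusion_counts")
}

# minimum distance (m) from a world point to a detection object's footprint
# (0 when inside); measured to the union of member pixel squares
point_object_distance <- function(px, py, obj) {
  ps <- obj$pixel_size
  cx <- obj$origin[1] + (obj$pixels[, 2] - 0.5) * ps
  cy <- obj$origin[2] - (obj$pixels[, 1] - 0.5) * ps
  dx <- pmax(abs(px - cx) - ps / 2, 0)
  dy <- pmax(abs(py - cy) - ps / 2, 0)
  sqrt(min(dx^2 + dy^2))
}

#' Match detection objects against ground-truth points
#'
#' A ground-truth point is covered when it lies inside, or within
#' `buffer_m` meters of, any detection object's footprint. True positives
#' are the covered points, false negatives the uncovered points, and false
#' positives the detection objects covering no point; a single object
#' covering several points yields several true positives and no false
#' positive. The default buffer (1 m) is smaller than the minimum whale
#' length, so distinct whales cannot alias.
#'
#' @param objects list of [detection_object()].
#' @param gt a [ground_truth_set()] in the same coordinate frame.
#' @param buffer_m matching tolerance in meters (>= 0).
#' @param min_confidence optionally restrict matching to points with at
#'   least this confidence rating (default 1 = use all points).
#' @return a [confusion_counts()].
#' @export
match_detections <- function(objects, gt, buffer_m = 1.0,
                             min_confidence = 1L) {
  stopifnot(inherits(gt, "ground_truth_set"), buffer_m >= 0)
  pts <- gt$points[gt$confidence >= min_confidence, , drop = FALSE]
  n_pts <- nrow(pts)
  n_obj <- length(objects)
  covered_pt <- rep(FALSE, n_pts)
  covering_obj <- rep(FALSE, n_obj)
  if (n_pts && n_obj) {
    for (i in seq_len(n_pts)) {
      for (j in seq_len(n_obj)) {
        if (point_object_distance(pts[i, 1], pts[i, 2], objects[[j]]) <= buffer_m) {
          covered_pt[i] <- TRUE
          covering_obj[j] <- TRUE
        }
      }
    }
  }
  confusion_counts(tp = sum(covered_pt), fp = sum(!covering_obj),
                   fn = sum(!covered_pt), identified = n_pts,
                   total_count = n_obj)
}

check_identified <- function(counts) {
  if (counts$identified <= 0)
    stop("metric undefined: no observer-identified whales")
}

#' False negative rate (missed rate)
#'
#' `100 * FN / identified`, the direct measure of the undercount, reported
#' rounded half-up to 2 decimals.
#'
#' @param counts a [confusion_counts()] with `identified > 0`.
#' @return percentage in \[0, 100\].
#' @export
fnr <- function(counts) {
  check_identified(counts)
  round_half_up(100 * counts$fn / counts$identified)
}

#' False positive rate
#'
#' `100 * FP / identified`, the measure of overcount, rounded half-up to 2
#' decimals. Exceeds 100 only if the algorithm overcounts more objects than
#' whales exist.
#'
#' @inheritParams fnr
#' @return percentage >= 0.
#' @export
fpr <- function(counts) {
  check_identified(counts)
  round_half_up(100 * counts$fp / counts$identified)
}

#' Automated count deviation
#'
#' `100 * (FP + FN) / identified`: the combined accuracy-and-reliability
#' measure, equal to FNR + FPR before rounding. Rounded half-up to 2
#' decimals.
#'
#' @inheritParams fnr
#' @return percentage >= 0.
#' @export
acd <- function(counts) {
  check_identified(counts)
  round_half_up(100 * (counts$fp + counts$fn) / counts$identified)
}

#' Full accuracy report for one algorithm on one tile
#'
#' Matches detections to ground truth and assembles the accuracy-matrix row
#' (total count, TP, FP, FN, FNR, FPR, ACD).
#'
#' @inheritParams match_detections
#' @param algorithm_id,tile_id labels recorded in the report.
#' @return one-row data.frame with columns algorithm_id, tile_id,
#'   total_count, tp, fp, fn, fnr_pct, fpr_pct, acd_pct.
#' @export
metrics_report <- function(objects, gt, algorithm_id = NA_character_,
                           tile_id = NA_character_, buffer_m = 1.0,
                           min_confidence = 1L) {
  counts <- match_detections(objects, gt, buffer_m, min_confidence)
  data.frame(algorithm_id = algorithm_id, tile_id = tile_id,
             total_count = counts$total_count, tp = counts$tp,
             fp = counts$fp, fn = counts$fn,
             fnr_pct = fnr(counts), fpr_pct = fpr(counts),
             acd_pct = acd(counts))
}

#' Recompute accuracy rates from printed count tables
#'
#' Replays rows of (total_count, fp, fn, identified) counts through the
#' rate definitions, e.g. to reproduce a published accuracy-assessment
#' matrix from its printed counts.
#'
#' @param df data.frame with columns `fp`, `fn`, `identified` (extra
#'   columns are carried through).
#' @return `df` with recomputed `fnr_pct`, `fpr_pct`, `acd_pct` columns.
#' @export
replay_count_table <- function(df) {
  stopifnot(all(c("fp", "fn", "identified") %in% names(df)))
  res <- t(vapply(seq_len(nrow(df)), function(i) {
    cc <- confusion_counts(tp = df$identified[i] - df$fn[i], fp = df$fp[i],
                           fn = df$fn[i])
    c(fnr(cc), fpr(cc), acd(cc))
  }, numeric(3)))
  df$fnr_pct <- res[, 1]
  df$fpr_pct <- res[, 2]
  df$acd_pct <- res[, 3]
  df
}

#' Consensus ground truth from two observers
#'
#' Whales identified by both observers are the verifiable truth: a point of
#' observer 1 is kept when observer 2 placed a point within `buffer_m`
#' meters (the same tolerance rule used for algorithm matching).
#'
#' @param gt1,gt2 [ground_truth_set()]s from the two observers.
#' @param buffer_m agreement tolerance in meters.
#' @return a `ground_truth_set` of the agreed points (coordinates from
#'   observer 1).
#' @export
consensus_truth <- function(gt1, gt2, buffer_m = 1.0) {
  if (nrow(gt1$points) == 0 || nrow(gt2$points) == 0)
    return(ground_truth_set(source_label = "consensus"))
  keep <- vapply(seq_len(nrow(gt1$points)), function(i) {
    d <- sqrt((gt2$points[, 1] - gt1$points[i, 1])^2 +
              (gt2$points[, 2] - gt1$points[i, 2])^2)
    any(d <= buffer_m)
  }, TRUE)
  ground_truth_set(gt1$points[keep, , drop = FALSE], gt1$confidence[keep],
                   source_label = "consensus")
}
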
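# Event-based scoring: maximum bipartite matching of predicted against
# reference timestamps at a 500 ms tolerance, precision / recall / F1,
# AUPRC over a threshold sweep, and recall-over-time/band diagnostics.

#' Match estimated events against reference events
#'
#' Builds the bipartite graph whose edges join reference and estimated
#' events within `tolerance` seconds of each other and computes a
#' maximum-cardinality matching (each event used at most once). The
#' precision / recall metrics depend only on the matching cardinality, so
#' any maximum matching is acceptable.
#'
#' @param ref,est [event_list()]s (time-sorted).
#' @param tolerance Matching tolerance in seconds (default 0.5).
#' @return List with `tp`, `fp`, `fn` counts and `pairs`, a two-column
#'   matrix of matched (ref index, est index).
#' @examples
#' match_events(event_list(c(1, 2)), event_list(c(1.4, 2.6)))
#' @export
match_events <- function(ref, est, tolerance = 0.5) {
  if (tolerance < 0) stop("tolerance must be nonnegative")
  nr <- nrow(ref); ne <- nrow(est)
  if (nr == 0L || ne == 0L) {
    return(list(tp = 0L, fp = ne, fn = nr,
                pairs = matrix(integer(), ncol = 2,
                               dimnames = list(NULL, c("ref", "est")))))
  }
  d <- abs(outer(ref$time_s, est$time_s, `-`))
  hit <- which(d <= tolerance, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(list(tp = 0L, fp = ne, fn = nr,
                pairs = matrix(integer(), ncol = 2,
                               dimnames = list(NULL, c("ref", "est")))))
  }
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, ne)),
    edges = as.vector(t(cbind(hit[, 1], nr + hit[, 2])))
  )
  mm <- igraph::max_bipartite_match(g)
  mref <- mm$matching[seq_len(nr)]
  matched <- which(!is.na(mref))
  pairs <- cbind(ref = matched, est = as.integer(mref[matched]) - nr)
  tp <- nrow(pairs)
  list(tp = tp, fp = ne - tp, fn = nr - tp, pairs = pairs)
}

#' Precision-recall curve of an event detection function
#'
#' For each threshold: extract peaks ([pick_peaks()]), match them against
#' the reference ([match_events()]), and compute precision
#' `TP / (TP + FP)` (1 when nothing is detected) and recall
#' `TP / (TP + FN)`. AUPRC is the trapezoidal integral over the recall
#' axis after sorting by recall, with the curve extended to recall 0 at
#' the precision of its lowest-recall point.
#'
#' @param edf An `edf` object.
#' @param ref Reference [event_list()] (must be non-empty: recall is
#'   undefined otherwise).
#' @param thresholds Threshold grid within (0, 1); default 100 evenly
#'   spaced values.
#' @param min_spacing Peak spacing constraint in ms (see [pick_peaks()]).
#' @param tolerance Matching tolerance in seconds.
#' @return An object of class `pr_curve`: list with `curve` (data frame
#'   `threshold`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`), `auprc`,
#'   and `best` (the maximal-F1 operating point).
#' @export
pr_curve <- function(edf, ref, thresholds = seq_len(100) / 101,
                     min_spacing = 0, tolerance = 0.5) {
  stopifnot(inherits(edf, "edf"))
  if (nrow(ref) == 0L) stop("undefined recall: empty reference list")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly in (0, 1)")
  }
  rows <- lapply(thresholds, function(tau) {
    est <- pick_peaks(edf, tau, min_spacing)
    m <- match_events(ref, est, tolerance)
    p <- if (m$tp + m$fp == 0L) 1 else m$tp / (m$tp + m$fp)
    r <- m$tp / (m$tp + m$fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(threshold = tau, tp = m$tp, fp = m$fp, fn = m$fn,
               precision = p, recall = r, f1 = f1)
  })
  curve <- do.call(rbind, rows)
  structure(list(curve = curve, auprc = auprc_trapezoid(curve),
                 best = curve[which.max(curve$f1), ]),
            class = "pr_curve")
}

# Trapezoidal AUPRC over the swept curve, extended to recall 0 holding
# the precision of the lowest-recall operating point.
auprc_trapezoid <- function(curve) {
  o <- order(curve$recall, curve$precision)
  r <- curve$recall[o]
  p <- curve$precision[o]
  r <- c(0, r)
  p <- c(p[1], p)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUPRC %.4f, best F1 %.3f @ tau=%.3f\n",
              nrow(x$curve), x$auprc, x$best$f1, x$best$threshold))
  invisible(x)
}

#' Write a PR curve to CSV plus a JSON summary
#'
#' @param pr A `pr_curve`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return `pr`, invisibly.
#' @export
write_pr_curve <- function(pr, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(pr, "pr_curve"))
  if (!is.null(csv_path)) utils::write.csv(pr$curve, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(auprc = pr$auprc,
                              best_f1 = pr$best$f1,
                              best_threshold = pr$best$threshold,
                              best_precision = pr$best$precision,
                              best_recall = pr$best$recall),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(pr)
}

#' Recall per temporal segment and frequency band
#'
#' One global matching between reference and estimates, then recall of
#' the reference events falling in each (segment, band) cell. Reference
#' events must carry band labels; `band_split` only documents the
#' low/high boundary used when labeling.
#'
#' @param ref Reference [event_list()] with `band_label` set.
#' @param est Estimated [event_list()].
#' @param segment Segment duration in seconds (default 1800).
#' @param band_split Hz boundary between `"low"` and `"high"` (metadata).
#' @param tolerance Matching tolerance in seconds.
#' @return Data frame with `segment`, `segment_start`, `band`, `n_ref`,
#'   `n_matched`, `recall`.
#' @export
segmented_recall <- function(ref, est, segment = 1800, band_split = 5000,
                             tolerance = 0.5) {
  if (nrow(ref) == 0L) stop("empty reference list")
  if (any(is.na(ref$band_label))) stop("reference events must carry band labels")
  m <- match_events(ref, est, tolerance)
  matched <- logical(nrow(ref))
  matched[m$pairs[, "ref"]] <- TRUE
  seg <- floor(ref$time_s / segment)
  cells <- expand.grid(segment = sort(unique(seg)),
                       band = c("low", "high"), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- seg == cells$segment[i] & ref$band_label == cells$band[i]
    n <- sum(sel)
    data.frame(segment = cells$segment[i],
               segment_start = cells$segment[i] * segment,
               band = cells$band[i], n_ref = n,
               n_matched = sum(matched[sel]),
               recall = if (n > 0) sum(matched[sel]) / n else NA_real_)
  }))
  out[order(out$segment, out$band), ]
}
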
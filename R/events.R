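#' Construct an event list
#'
#' An `event_list` is a data frame of event center timestamps, optional
#' detector scores and optional frequency-band labels (`"low"` for the
#' thrush range below the band split, `"high"` for warblers and sparrows
#' above it). Timestamps are strictly increasing.
#'
#' @param time_s Event center times in seconds.
#' @param score Optional scores in (0, 1) (EDF value at the peak).
#' @param band_label Optional `"low"` / `"high"` labels.
#' @return A data frame of class `event_list` with columns `time_s`,
#'   `score`, `band_label`.
#' @export
event_list <- function(time_s = numeric(), score = NULL, band_label = NULL) {
  n <- length(time_s)
  if (is.null(score)) score <- rep(NA_real_, n)
  if (is.null(band_label)) band_label <- rep(NA_character_, n)
  if (length(score) != n || length(band_label) != n) {
    stop("score and band_label must match time_s in length")
  }
  o <- order(time_s)
  time_s <- time_s[o]; score <- score[o]; band_label <- band_label[o]
  if (n > 1 && any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (any(!is.na(score) & (score <= 0 | score >= 1))) {
    stop("scores must lie strictly in (0, 1)")
  }
  structure(data.frame(time_s = as.numeric(time_s), score = score,
                       band_label = band_label,
                       stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

#' Read / write event lists as CSV
#'
#' @param path CSV path with columns `time_s` and optionally `score`,
#'   `band_label`.
#' @return An [event_list()].
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("CSV must have a time_s column")
  event_list(df$time_s,
             if ("score" %in% names(df)) df$score else NULL,
             if ("band_label" %in% names(df)) df$band_label else NULL)
}

#' @rdname read_events
#' @param events An [event_list()].
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
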
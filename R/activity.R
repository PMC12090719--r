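# Promoter-activity reporter data: validation and replicate means.

#' Validate a promoter-activity table
#'
#' @param df Data frame with columns `cohort` ("PvPs", "Pv" or "Ps"),
#'   `boxes` (box-subset label), `time_h`, `replicate`, `activity`
#'   (Miller-like reporter units, >= 0).
#' @return The validated data frame (labels canonicalized), classed
#'   `activity_dataset`.
#' @export
activity_dataset <- function(df) {
  need <- c("cohort", "boxes", "time_h", "replicate", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(df$cohort %in% COHORTS)) {
    stop("cohort must be one of ", paste(COHORTS, collapse = ", "),
         call. = FALSE)
  }
  df$boxes <- normalize_label(df$boxes)
  if (!is.numeric(df$time_h) || any(!is.finite(df$time_h))) {
    stop("time_h must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(df$activity) || any(!is.finite(df$activity)) ||
      any(df$activity < 0)) {
    stop("activity must be finite and >= 0", call. = FALSE)
  }
  key <- paste(df$cohort, df$boxes, df$time_h, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (cohort, boxes, time_h, replicate) rows", call. = FALSE)
  }
  class(df) <- c("activity_dataset", "data.frame")
  df
}

# Canonical strain row order: cohorts PvPs, Pv, Ps crossed with the 8 labels.
strain_index <- function() {
  data.frame(cohort = rep(COHORTS, each = 8),
             boxes = rep(BOX_LABELS, 3))
}

#' Replicate-mean activity matrix
#'
#' Averages replicates into a strain-by-timepoint matrix in the canonical
#' panel order (cohorts PvPs, Pv, Ps; labels none..123).
#'
#' @param data An [activity_dataset()] or a tidy prediction frame with a
#'   `veff` column in place of `activity`/`replicate`.
#' @param timepoints Expected hour grid; defaults to 2..9.
#' @return 24 x T numeric matrix, rows named "cohort:boxes".
#' @export
activity_means <- function(data, timepoints = TIME_GRID) {
  value <- if ("activity" %in% names(data)) "activity" else "veff"
  idx <- strain_index()
  m <- matrix(NA_real_, nrow(idx), length(timepoints),
              dimnames = list(paste(idx$cohort, idx$boxes, sep = ":"),
                              timepoints))
  for (r in seq_len(nrow(idx))) {
    for (ti in seq_along(timepoints)) {
      sel <- data$cohort == idx$cohort[r] & data$boxes == idx$boxes[r] &
        data$time_h == timepoints[ti]
      if (any(sel)) m[r, ti] <- mean(data[[value]][sel])
    }
  }
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    stop("data does not cover every (strain, timepoint); first gap: ",
         rownames(m)[gaps[1, 1]], " at t=", timepoints[gaps[1, 2]], " h",
         call. = FALSE)
  }
  m
}
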
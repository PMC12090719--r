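# Bookkeeping for 0A boxes, binding configurations and the strain panel.
#
# A configuration is a 3-character binary string; digits left to right
# correspond to the 0A1, 0A2 and 0A3 boxes, "1" = bound. Strains are labelled
# by the subset of intact boxes ("none", "1", ..., "123") and belong to one
# of three promoter cohorts: both promoters present ("PvPs"), the vegetative
# promoter alone ("Pv") or the sporulation promoter alone ("Ps").

BOXES <- c("0A1", "0A2", "0A3")
BOX_LABELS <- c("none", "1", "2", "3", "12", "13", "23", "123")
COHORTS <- c("PvPs", "Pv", "Ps")
PROMOTERS <- c("Pv", "Ps")
EPS_PAIRS <- c("12", "13", "23")
TIME_GRID <- 2:9

#' Binding configuration identifiers
#'
#' All eight bound/unbound states of the three 0A boxes, as 3-character
#' binary strings whose digits (left to right) give the state of 0A1, 0A2
#' and 0A3 ("1" = bound).
#'
#' @return Character vector of length 8, ordered `"000"` to `"111"` by the
#'   integer value of the bit string.
#' @export
config_ids <- function() {
  c("000", "001", "010", "011", "100", "101", "110", "111")
}

# 8 x 3 0/1 matrix of box states, rows named by configuration id.
config_matrix <- function() {
  ids <- config_ids()
  m <- t(vapply(strsplit(ids, "", fixed = TRUE),
                function(x) as.integer(x), integer(3)))
  dimnames(m) <- list(ids, BOXES)
  m
}

#' Canonicalize a box-subset label
#'
#' Strain labels name the intact 0A boxes by their indices; the canonical
#' form is the sorted concatenation of unique digits ("31" becomes "13"),
#' with "none" for the empty subset.
#'
#' @param label Character vector of labels (digits drawn from 1-3, or
#'   "none"/"" for no boxes).
#' @return Character vector of canonical labels.
#' @export
normalize_label <- function(label) {
  vapply(as.character(label), function(l) {
    if (is.na(l) || l %in% c("", "none", "0")) {
      return("none")
    }
    ch <- sort(unique(strsplit(l, "", fixed = TRUE)[[1]]))
    if (!all(ch %in% c("1", "2", "3"))) {
      stop("invalid box-subset label: '", l, "'", call. = FALSE)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Boxes named by a subset label
#'
#' @param label A single box-subset label (e.g. "13" or "none").
#' @return Character vector of box names, e.g. `c("0A1", "0A3")`.
#' @export
label_to_boxes <- function(label) {
  label <- normalize_label(label)
  if (label == "none") {
    return(character(0))
  }
  BOXES[as.integer(strsplit(label, "", fixed = TRUE)[[1]])]
}

boxes_to_label <- function(boxes) {
  if (length(boxes) == 0) {
    return("none")
  }
  stopifnot(all(boxes %in% BOXES))
  paste(sort(match(boxes, BOXES)), collapse = "")
}

# Configuration with exactly the boxes of `label` bound, e.g. "13" -> "101".
label_to_config <- function(label) {
  paste(as.integer(BOXES %in% label_to_boxes(label)), collapse = "")
}

#' Specify a reporter strain
#'
#' A strain is a promoter cohort plus the subset of 0A boxes left intact;
#' the full panel is 3 cohorts x 8 subsets = 24 strains.
#'
#' @param cohort One of "PvPs", "Pv", "Ps".
#' @param label Box-subset label ("none", "1", ..., "123"); any digit order
#'   is accepted and canonicalized.
#' @return An object of class `strain_spec` with fields `cohort`, `label`
#'   and `boxes`.
#' @export
strain_spec <- function(cohort, label) {
  cohort <- match.arg(cohort, COHORTS)
  label <- normalize_label(label)
  structure(list(cohort = cohort, label = label,
                 boxes = label_to_boxes(label)),
            class = "strain_spec")
}

#' @export
print.strain_spec <- function(x, ...) {
  cat("<strain> cohort=", x$cohort, " boxes=", x$label, "\n", sep = "")
  invisible(x)
}

#' Enumerate the full 24-strain panel
#'
#' @return List of 24 [strain_spec()] objects, cohorts in the order
#'   PvPs, Pv, Ps and labels in the order none, 1, 2, 3, 12, 13, 23, 123.
#' @export
all_strains <- function() {
  out <- list()
  for (coh in COHORTS) {
    for (lab in BOX_LABELS) {
      out[[length(out) + 1L]] <- strain_spec(coh, lab)
    }
  }
  out
}
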
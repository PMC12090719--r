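# EMSA titration data: validation, replicate-uncertainty augmentation,
# half-saturation estimation and cooperativity selection.

#' Validate an EMSA titration table
#'
#' @param df Data frame with columns `box_subset` (label such as "1" or
#'   "23"), `conc_uM` (>= 0), `replicate` (integer) and `frac_bound`
#'   (in \[0, 1\]).
#' @return The validated data frame (labels canonicalized), classed
#'   `emsa_dataset`.
#' @export
emsa_dataset <- function(df) {
  need <- c("box_subset", "conc_uM", "replicate", "frac_bound")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df$box_subset <- normalize_label(df$box_subset)
  if (any(df$box_subset == "none")) {
    stop("box_subset must name at least one box", call. = FALSE)
  }
  if (!is.numeric(df$conc_uM) || any(!is.finite(df$conc_uM)) ||
      any(df$conc_uM < 0)) {
    stop("conc_uM must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(df$frac_bound) || any(!is.finite(df$frac_bound)) ||
      any(df$frac_bound < 0 | df$frac_bound > 1)) {
    stop("frac_bound must lie in [0, 1]", call. = FALSE)
  }
  class(df) <- c("emsa_dataset", "data.frame")
  df
}

# Per-(subset, conc) replicate mean and sd.
emsa_summary <- function(data) {
  key <- interaction(data$box_subset, data$conc_uM, drop = TRUE)
  agg <- data.frame(
    box_subset = tapply(data$box_subset, key, `[`, 1),
    conc_uM = tapply(data$conc_uM, key, `[`, 1),
    mean = tapply(data$frac_bound, key, mean),
    sd = tapply(data$frac_bound, key, sd),
    n_rep = tapply(data$frac_bound, key, length),
    row.names = NULL
  )
  agg[order(agg$box_subset, agg$conc_uM), , drop = FALSE]
}

# Truncated-normal draw on [0, 1] via inverse-CDF; sd = 0 returns the mean.
rtrunc01 <- function(n, mean, sd) {
  if (sd <= 0) {
    return(rep(mean, n))
  }
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Augment an EMSA dataset by parametric resampling
#'
#' Produces pseudo-datasets for bootstrap confidence intervals: each
#' augmented dataset redraws `frac_bound` for every (subset, concentration)
#' point from a normal law with the replicate mean and standard deviation,
#' truncated to \[0, 1\]. Points with a single replicate (undefined SD) fall
#' back to `fallback_rel_sd * mean`.
#'
#' @param data An [emsa_dataset()].
#' @param n_augment Number of augmented datasets (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param fallback_rel_sd Relative SD used when a point has one replicate.
#' @return List of `n_augment` data frames with one pseudo-replicate per
#'   (subset, concentration) point.
#' @export
augment_dataset <- function(data, n_augment, seed = 1,
                            fallback_rel_sd = 0.05) {
  data <- emsa_dataset(data)
  if (n_augment < 1) {
    stop("n_augment must be >= 1", call. = FALSE)
  }
  agg <- emsa_summary(data)
  sdv <- agg$sd
  fall <- is.na(sdv)
  sdv[fall] <- fallback_rel_sd * agg$mean[fall]
  set.seed(seed)
  draws <- matrix(NA_real_, nrow(agg), n_augment)
  for (i in seq_len(nrow(agg))) {
    draws[i, ] <- rtrunc01(n_augment, agg$mean[i], sdv[i])
  }
  lapply(seq_len(n_augment), function(j) {
    emsa_dataset(data.frame(
      box_subset = agg$box_subset,
      conc_uM = agg$conc_uM,
      replicate = 1L,
      frac_bound = draws[, j]
    ))
  })
}

# Least-squares Kh for one titration curve (conc, y), fixed n. 1-D bounded
# search on log10(kh); returns kh and the summed squared error.
fit_kh_curve <- function(conc, y, n, interval = c(-4, 2)) {
  sse <- function(lkh) {
    sum((fraction_bound_single(conc, 10^lkh, n) - y)^2)
  }
  opt <- optimize(sse, interval = interval, tol = 1e-12)
  list(kh = 10^opt$minimum, sse = opt$objective,
       at_bound = min(abs(opt$minimum - interval)) < 1e-6)
}

#' Estimate per-box half-saturation constants with bootstrap CIs
#'
#' Fits the single-box occupancy curve to the replicate means of every
#' single-box titration in `data` by least squares (untransformed
#' fractions), then repeats the fit on `n_augment` augmented datasets and
#' reports 2.5/97.5 percentile confidence intervals.
#'
#' @param data An [emsa_dataset()] containing single-box subsets.
#' @param n Stoichiometric coefficient used in the fits.
#' @param n_augment Number of augmented-data fits for the CI; 0 skips the
#'   bootstrap and returns point estimates only.
#' @param seed Integer seed for the augmentation.
#' @param fallback_rel_sd Passed to [augment_dataset()].
#' @return Object of class `kh_fit`: per-box estimates `kh`, 95% CI bounds,
#'   per-box and total summed squared error, and a `warning` field set when
#'   more than 10% of augmented fits ran to the search boundary.
#' @export
fit_kh <- function(data, n, n_augment = 1000, seed = 1,
                   fallback_rel_sd = 0.05) {
  data <- emsa_dataset(data)
  single <- data[data$box_subset %in% c("1", "2", "3"), , drop = FALSE]
  if (nrow(single) == 0) {
    stop("data contains no single-box subsets", call. = FALSE)
  }
  labs <- sort(unique(single$box_subset))
  boxes <- BOXES[as.integer(labs)]
  agg <- emsa_summary(single)

  point <- lapply(labs, function(l) {
    a <- agg[agg$box_subset == l, ]
    fit_kh_curve(a$conc_uM, a$mean, n)
  })
  kh <- setNames(vapply(point, `[[`, numeric(1), "kh"), boxes)
  sse_box <- setNames(vapply(point, `[[`, numeric(1), "sse"), boxes)

  ci <- matrix(NA_real_, length(boxes), 2,
               dimnames = list(boxes, c("ci95_low", "ci95_high")))
  warn <- NULL
  if (n_augment > 0) {
    aug <- augment_dataset(single, n_augment, seed = seed,
                           fallback_rel_sd = fallback_rel_sd)
    boot <- matrix(NA_real_, n_augment, length(boxes))
    n_bound <- 0L
    for (j in seq_len(n_augment)) {
      dj <- aug[[j]]
      for (b in seq_along(labs)) {
        dd <- dj[dj$box_subset == labs[b], ]
        f <- fit_kh_curve(dd$conc_uM, dd$frac_bound, n)
        boot[j, b] <- f$kh
        if (f$at_bound) n_bound <- n_bound + 1L
      }
    }
    ci[, 1] <- apply(boot, 2, quantile, probs = 0.025)
    ci[, 2] <- apply(boot, 2, quantile, probs = 0.975)
    if (n_bound > 0.1 * n_augment * length(boxes)) {
      warn <- sprintf("%d of %d augmented fits ran to the search boundary",
                      n_bound, n_augment * length(boxes))
    }
  }
  structure(list(kh = kh, ci = ci, n = as.integer(n), sse_box = sse_box,
                 sse = sum(sse_box), n_augment = n_augment, seed = seed,
                 warning = warn),
            class = "kh_fit")
}

#' @export
print.kh_fit <- function(x, ...) {
  cat("<kh_fit> N=", x$n, "  total SSE=", signif(x$sse, 4), "\n", sep = "")
  for (b in names(x$kh)) {
    cat(sprintf("  %s: Kh = %.4g uM  [%.4g, %.4g]\n", b, x$kh[[b]],
                x$ci[b, 1], x$ci[b, 2]))
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Select the 0A~P binding stoichiometry
#'
#' Refits the single-box half-saturation model for each candidate
#' stoichiometric coefficient and picks the one with the lowest summed
#' squared error; ties break toward the smaller candidate.
#'
#' @param data An [emsa_dataset()] with single-box subsets.
#' @param candidates Integer candidates for N (non-empty).
#' @return List with `best_n`, the named per-candidate `errors`, and the
#'   per-candidate `fits` (point estimates only).
#' @export
select_cooperativity <- function(data, candidates = 1:6) {
  if (length(candidates) == 0) {
    stop("candidates must be non-empty", call. = FALSE)
  }
  candidates <- sort(unique(as.integer(candidates)))
  fits <- lapply(candidates, function(nn) fit_kh(data, nn, n_augment = 0))
  errors <- setNames(vapply(fits, `[[`, numeric(1), "sse"),
                     as.character(candidates))
  best <- candidates[which.min(errors)]  # which.min takes the first tie
  list(best_n = best, errors = errors,
       fits = setNames(fits, as.character(candidates)))
}
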
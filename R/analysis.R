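# Derived regulatory statistics: data collapses, repression/activation
# strength, box-saturation timing, RNAP-dynamics decomposition, and the
# shared-sigma joint fit of box-free promoter pairs.

value_column <- function(df) {
  if ("activity" %in% names(df)) "activity" else "veff"
}

# Replicate-mean tidy frame (cohort, boxes, time_h, value).
tidy_means <- function(df) {
  v <- value_column(df)
  key <- interaction(df$cohort, df$boxes, df$time_h, drop = TRUE)
  out <- data.frame(
    cohort = tapply(df$cohort, key, `[`, 1),
    boxes = tapply(df$boxes, key, `[`, 1),
    time_h = tapply(df$time_h, key, `[`, 1),
    value = as.numeric(tapply(df[[v]], key, mean)),
    row.names = NULL
  )
  out[order(out$cohort, out$boxes, out$time_h), , drop = FALSE]
}

#' Dual-promoter additivity ratio
#'
#' For every box-subset label present in all three cohorts and every
#' timepoint, the ratio of the summed single-promoter activities to the
#' dual-promoter activity,
#' `(Pv_MS(t) + Ps_MS(t)) / PvPs_MS(t)`.
#' Purely kinetic control makes this exactly 1; thermodynamic coupling
#' through shared 0A~P-RNAP interactions makes it deviate.
#'
#' @param df Tidy measurements or predictions with columns `cohort`,
#'   `boxes`, `time_h` and `activity` (replicates averaged) or `veff`.
#' @return Data frame `boxes`, `time_h`, `ratio`; rows with a zero
#'   dual-promoter denominator carry `NA` and are counted in the
#'   `n_undefined` attribute.
#' @export
additivity_ratio <- function(df) {
  m <- tidy_means(df)
  labs <- Reduce(intersect, lapply(COHORTS, function(ch) {
    unique(m$boxes[m$cohort == ch])
  }))
  out <- NULL
  for (lab in labs) {
    sub <- m[m$boxes == lab, ]
    times <- Reduce(intersect, lapply(COHORTS, function(ch) {
      sub$time_h[sub$cohort == ch]
    }))
    for (t in times) {
      num <- sub$value[sub$cohort == "Pv" & sub$time_h == t] +
        sub$value[sub$cohort == "Ps" & sub$time_h == t]
      den <- sub$value[sub$cohort == "PvPs" & sub$time_h == t]
      out <- rbind(out, data.frame(
        boxes = lab, time_h = t,
        ratio = if (den == 0) NA_real_ else num / den))
    }
  }
  structure(out, n_undefined = sum(is.na(out$ratio)))
}

#' Endpoint/none-strain normalization collapse
#'
#' Normalizes each strain's curve by its last timepoint and then by the
#' identically normalized box-free ("none") strain of the same cohort:
#' `y_norm(l,t) = [y(l,t)/y(l,T)] / [y(none,t)/y(none,T)]`.
#' When a shared RNAP-activity rise is the only time-varying driver and the
#' boxes are saturated, every strain collapses onto 1.
#'
#' @inheritParams additivity_ratio
#' @return Data frame `cohort`, `boxes`, `time_h`, `norm`; undefined values
#'   (zero reference) are `NA`, counted in the `n_undefined` attribute.
#' @export
normalize_collapse <- function(df) {
  m <- tidy_means(df)
  t_last <- max(m$time_h)
  out <- NULL
  for (ch in unique(m$cohort)) {
    sub <- m[m$cohort == ch, ]
    ref <- sub[sub$boxes == "none", ]
    if (nrow(ref) == 0) {
      stop("cohort ", ch, " has no 'none' strain to normalize by",
           call. = FALSE)
    }
    ref_end <- ref$value[ref$time_h == t_last]
    for (lab in unique(sub$boxes)) {
      sl <- sub[sub$boxes == lab, ]
      end <- sl$value[sl$time_h == t_last]
      for (i in seq_len(nrow(sl))) {
        t <- sl$time_h[i]
        refv <- ref$value[ref$time_h == t]
        den <- end * refv
        out <- rbind(out, data.frame(
          cohort = ch, boxes = lab, time_h = t,
          norm = if (den == 0 || ref_end == 0) NA_real_ else
            (sl$value[i] / end) / (refv / ref_end)))
      }
    }
  }
  structure(out, n_undefined = sum(is.na(out$norm)))
}

# A scenario_params with the RNAP activity frozen at its value at t_freeze.
freeze_rnap <- function(params, t_freeze = 2) {
  fi <- match(t_freeze, params$timepoints)
  if (is.na(fi)) {
    stop("t_freeze must lie on the parameter grid", call. = FALSE)
  }
  params$A[, ] <- params$A[, fi]
  params
}

fit_params <- function(fit) {
  if (inherits(fit, "scenario_fit")) fit$params else fit
}

#' Repression/activation strength of each box subset
#'
#' Percent change of each strain's effective transcription rate relative to
#' the box-free strain of its cohort at the reference time, with the RNAP
#' activity frozen at its `t_freeze` value so that only the time-dependent
#' 0A~P concentration drives regulation:
#' `strength = 100 * (veff_strain(t_ref) - veff_none(t_ref)) / veff_none(t_ref)`.
#' Negative values are repression, positive activation. At full box
#' saturation the strength of a single-promoter strain equals
#' `100 * (rho(bound configuration) - 1)`.
#'
#' @param fit A `scenario_fit` or [scenario_params()].
#' @param sig A [signal_0ap()].
#' @param t_ref Reference time in hours (default 9).
#' @param t_freeze Time whose RNAP activity is held throughout (default 2).
#' @return Data frame `cohort`, `boxes`, `strength_pct`, with the "none"
#'   rows identically 0.
#' @export
regulation_strength <- function(fit, sig, t_ref = 9, t_freeze = 2) {
  params <- freeze_rnap(fit_params(fit), t_freeze)
  conc <- signal_conc_at(sig, t_ref)
  out <- strain_index()
  out$strength_pct <- NA_real_
  for (ch in COHORTS) {
    fun <- if (ch == "PvPs") veff_dual else veff_single
    v_none <- fun(strain_spec(ch, "none"), params, conc, t_ref)
    for (lab in BOX_LABELS) {
      v <- fun(strain_spec(ch, lab), params, conc, t_ref)
      out$strength_pct[out$cohort == ch & out$boxes == lab] <-
        100 * (v - v_none) / v_none
    }
  }
  out
}

#' First saturation time of each 0A box
#'
#' Scans the hourly grid for the earliest time at which the marginal bound
#' probability of each present box reaches `threshold`, under the fitted
#' in-vivo binding parameters and the 0A~P signal.
#'
#' @param fit A `scenario_fit` or [scenario_params()].
#' @param strain A [strain_spec()] (its absent boxes are reported as `NA`).
#' @param sig A [signal_0ap()].
#' @param threshold Occupancy threshold defining saturation (default 0.99).
#' @return Named numeric vector over the strain's boxes: the saturation time
#'   in hours, or `NA` if not reached on the grid.
#' @export
saturation_time <- function(fit, strain, sig, threshold = 0.99) {
  params <- fit_params(fit)
  if (length(strain$boxes) == 0) {
    return(setNames(numeric(0), character(0)))
  }
  times <- params$timepoints
  conc <- signal_conc_at(sig, times)
  sat <- setNames(rep(NA_real_, length(strain$boxes)), strain$boxes)
  for (ti in seq_along(times)) {
    marg <- box_marginals(conc[ti], params$binding, strain$boxes)
    for (b in strain$boxes) {
      if (is.na(sat[[b]]) && marg[[b]] >= threshold) sat[[b]] <- times[ti]
    }
  }
  sat
}

#' Decompose the RNAP-dynamics contribution to a strain's expression
#'
#' Predicts the strain's time course twice: with the fitted time-dependent
#' RNAP activity, and with the activity frozen at its `t_freeze` value (so
#' only 0A~P binding varies). The per-timepoint ratio isolates how much of
#' the expression rise is driven by RNAP holoenzyme dynamics.
#'
#' @inheritParams regulation_strength
#' @param strain A [strain_spec()].
#' @return Data frame `time_h`, `veff_dynamic`, `veff_frozen`, `ratio`.
#' @export
rnap_contribution <- function(fit, strain, sig, t_freeze = 2) {
  params <- fit_params(fit)
  dyn <- predict_timecourse(strain, params, sig)
  frz <- predict_timecourse(strain, freeze_rnap(params, t_freeze), sig)
  data.frame(time_h = dyn$time_h, veff_dynamic = dyn$veff,
             veff_frozen = frz$veff, ratio = dyn$veff / frz$veff)
}

#' Joint fit of two box-free promoters sharing one RNAP dynamic
#'
#' Fits `y_p(t) = c_p * g(t)` to two activity curves measured on the same
#' grid, with one shared nonparametric shape `g` (normalized to `g = 1` at
#' the first timepoint) and a per-promoter affinity scale `c_p`, by least
#' squares (best rank-1 approximation). A small residual supports the two
#' promoters reading the same sigma-factor-RNAP pool through different
#' binding affinities.
#'
#' @param y1,y2 Activity curves (equal length, not all zero).
#' @param time_h Common time grid.
#' @return List with `shape` (data frame `time_h`, `g`), `scales` (length-2
#'   vector `c1`, `c2`), `sse` (residual sum of squares) and `fitted`
#'   (2 x T matrix).
#' @export
joint_shared_sigma_fit <- function(y1, y2, time_h = TIME_GRID) {
  if (length(y1) != length(time_h) || length(y2) != length(time_h)) {
    stop("curves and time grid must have equal length", call. = FALSE)
  }
  if (all(y1 == 0) || all(y2 == 0)) {
    stop("degenerate all-zero curve", call. = FALSE)
  }
  Y <- rbind(y1, y2)
  sv <- svd(Y)
  g_raw <- sv$v[, 1]
  u1 <- sv$u[, 1]
  if (sum(g_raw) < 0) {
    g_raw <- -g_raw
    u1 <- -u1
  }
  if (abs(g_raw[1]) < 1e-12) {
    stop("shape is zero at the first timepoint; cannot normalize",
         call. = FALSE)
  }
  g <- g_raw / g_raw[1]
  scales <- sv$d[1] * u1 * g_raw[1]
  fitted <- scales %o% g
  dimnames(fitted) <- list(c("c1", "c2"), time_h)
  list(shape = data.frame(time_h = time_h, g = g),
       scales = setNames(scales, c("c1", "c2")),
       sse = sum((Y - fitted)^2),
       fitted = fitted)
}
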
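# Reference implementation by exhaustive joint-state enumeration. Used as
# the independent check on the closed-form rate functions: it loops over
# every (box configuration, RNAP state) pair with no algebraic shortcuts.

#' Effective transcription rate by exhaustive enumeration
#'
#' Computes the same quantity as [veff_single()] / [veff_dual()] by explicit
#' enumeration of every joint state: all admissible box configurations
#' crossed with the bound/unbound state of each thermodynamically controlled
#' RNAP. Kinetically controlled promoters carry their occupancy-weighted
#' `A * rho` contribution in every state. Intended as a test oracle; the
#' closed-form functions must agree with it to near machine precision.
#'
#' @inheritParams veff_single
#' @param strain Any [strain_spec()] (single- or dual-promoter cohort).
#' @return Rate in reporter units/h.
#' @export
veff_enumerate <- function(strain, params, conc, t) {
  stopifnot(inherits(strain, "strain_spec"), inherits(params, "scenario_params"))
  ti <- match(t, params$timepoints)
  if (is.na(ti)) {
    stop("timepoint ", t, " h is outside the parameter grid", call. = FALSE)
  }
  proms <- if (strain$cohort == "PvPs") PROMOTERS else strain$cohort
  thermo <- proms[vapply(proms, function(p) {
    promoter_control(params, p) == "T"
  }, logical(1))]
  S <- config_matrix()
  pres <- as.integer(BOXES %in% strain$boxes)
  bnd <- params$binding
  nr <- length(thermo)
  rstates <- if (nr == 0) {
    matrix(0L, 1, 0)
  } else {
    as.matrix(expand.grid(rep(list(0:1), nr)))
  }
  total_w <- 0
  total_rate_w <- 0
  for (ci in seq_len(8)) {
    s <- S[ci, ]
    if (any(s > pres)) next
    for (ri in seq_len(nrow(rstates))) {
      r <- rstates[ri, ]
      w <- 1
      for (i in 1:3) {
        if (s[i] == 1) w <- w * (conc / bnd$kh[[BOXES[i]]])^bnd$n0a
      }
      for (i in 1:2) {
        for (j in (i + 1):3) {
          if (s[i] == 1 && s[j] == 1) w <- w * exp(-eps_pair(bnd, i, j))
        }
      }
      rate <- 0
      for (p in proms) {
        if (p %in% thermo) {
          if (r[[match(p, thermo)]] == 1) {
            fac <- 1
            for (i in 1:3) {
              if (s[i] == 1) fac <- fac * exp(-params$eta[[p]][[BOXES[i]]])
            }
            w <- w * params$A[p, ti] * fac
            rate <- rate + params$vmax_scale[[p]]
          }
        } else {
          rate <- rate + params$A[p, ti] * params$rho[[p]][[ci]]
        }
      }
      total_w <- total_w + w
      total_rate_w <- total_rate_w + w * rate
    }
  }
  total_rate_w / total_w
}
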
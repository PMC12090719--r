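# Fit objective: mean squared relative residuals per promoter cohort, and
# the Bayesian information criterion for nested interaction-energy models.

#' Relative squared-error objective with per-cohort breakdown
#'
#' For each cohort i the error term is
#' `E_i = 1/(L_i T_i) * sum_{l,t} (veff_{l,t} - X_{l,t})^2 / X_{l,t}^2`
#' where X are the replicate-mean measured activities, and the total is
#' `E = Ev + Es + Evs`. Relative residuals make the objective invariant to
#' a common rescaling of predictions and data.
#'
#' @param pred Tidy prediction frame (`cohort`, `boxes`, `time_h`, `veff`)
#'   covering every measured (strain, timepoint).
#' @param data An [activity_dataset()] (replicates are averaged), or a
#'   matching mean matrix from [activity_means()].
#' @return Object of class `objective_breakdown`: `E`, `Ev`, `Es`, `Evs`,
#'   and the per-cohort strain/timepoint counts `L`, `T`.
#' @export
objective <- function(pred, data) {
  X <- if (is.matrix(data)) data else activity_means(data)
  V <- activity_means(pred, timepoints = as.numeric(colnames(X)))
  if (any(X == 0)) {
    stop("mean activity of zero: relative residual undefined", call. = FALSE)
  }
  rel2 <- ((V - X) / X)^2
  idx <- strain_index()
  terms <- vapply(COHORTS, function(coh) {
    mean(rel2[idx$cohort == coh, , drop = FALSE])
  }, numeric(1))
  structure(list(E = sum(terms),
                 Ev = terms[["Pv"]], Es = terms[["Ps"]],
                 Evs = terms[["PvPs"]],
                 L = setNames(rep(8L, 3), COHORTS),
                 T = setNames(rep(ncol(X), 3), COHORTS)),
            class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat(sprintf("<objective> E=%.6g (Evs=%.4g, Ev=%.4g, Es=%.4g)\n",
              x$E, x$Evs, x$Ev, x$Es))
  invisible(x)
}

# Total summed squared relative residuals implied by a breakdown.
ssr_rel <- function(obj) {
  sum(c(obj$Evs, obj$Ev, obj$Es) * obj$L * obj$T)
}

#' Bayesian information criterion for a fitted scenario
#'
#' Under a Gaussian relative-error likelihood,
#' `BIC = n_obs * ln(SSR_rel / n_obs) + k * ln(n_obs)` with `SSR_rel` the
#' summed squared relative residuals. Used to test whether freeing box-box
#' interaction energies is justified by the data.
#'
#' @param result A `scenario_fit` from [fit_scenario()], an
#'   `objective_breakdown`, or the scalar `SSR_rel`.
#' @param n_obs Number of fitted observations (24 strains x 8 timepoints =
#'   192 for the full panel).
#' @param k Number of free (unpinned) parameters; taken from a
#'   `scenario_fit` when omitted.
#' @return The BIC value; `-Inf` with attribute `perfect_fit = TRUE` when
#'   `SSR_rel` is 0.
#' @export
bic <- function(result, n_obs = NULL, k = NULL) {
  if (inherits(result, "scenario_fit")) {
    ssr <- ssr_rel(result$objective)
    if (is.null(k)) k <- result$k
    if (is.null(n_obs)) n_obs <- sum(result$objective$L * result$objective$T)
  } else if (inherits(result, "objective_breakdown")) {
    ssr <- ssr_rel(result)
    if (is.null(n_obs)) n_obs <- sum(result$L * result$T)
  } else {
    ssr <- result
  }
  if (is.null(n_obs) || is.null(k)) {
    stop("n_obs and k are required", call. = FALSE)
  }
  if (ssr <= 0) {
    return(structure(-Inf, perfect_fit = TRUE))
  }
  n_obs * log(ssr / n_obs) + k * log(n_obs)
}
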
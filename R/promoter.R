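# Statistical-mechanical promoter model: configuration weights, box
# occupancy, and the effective transcription rate for single and dual
# promoters under kinetic or thermodynamic control.
#
# Scenario tags are two letters, first for Pv and second for Ps: "K" means
# kinetic control (0A~P binding rescales the maximum initiation rate through
# per-configuration ratios rho, with the identifiable product of RNAP-bound
# probability and basal vmax carried by a per-timepoint activity scale A)
# and "T" means thermodynamic control (0A~P modulates the RNAP binding
# probability through box-RNAP interaction energies eta, with A carrying the
# RNAP occupancy ratio R(t) = [RNAP]/K_P and a separate vmax scale).

SCENARIOS <- c("KK", "TT", "TK", "KT")

#' A time series of 0A~P concentration
#'
#' @param time_h Timepoints in hours.
#' @param conc 0A~P concentration in uM at each timepoint (>= 0).
#' @return Object of class `signal_0ap`.
#' @export
signal_0ap <- function(time_h, conc) {
  if (length(time_h) != length(conc)) {
    stop("time_h and conc must have equal length", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("conc must be finite and >= 0", call. = FALSE)
  }
  structure(list(time_h = as.numeric(time_h), conc = as.numeric(conc)),
            class = "signal_0ap")
}

signal_conc_at <- function(sig, t) {
  i <- match(t, sig$time_h)
  if (anyNA(i)) {
    stop("signal does not cover timepoint(s): ",
         paste(t[is.na(i)], collapse = ", "), call. = FALSE)
  }
  sig$conc[i]
}

#' Scenario parameters for the dual-promoter model
#'
#' @param scenario Two-letter control tag among `r paste(SCENARIOS, collapse=", ")`;
#'   first letter = Pv, second = Ps, "K" kinetic / "T" thermodynamic.
#' @param binding [binding_params()] with the in-vivo half-saturation
#'   constants (already reconciled via the lambda scale), in-vivo exponent
#'   `n0a`, and fitted box-box interaction energies `eps`.
#' @param A Numeric 2 x T matrix (rownames "Pv","Ps") of per-timepoint
#'   effective RNAP activities: for a kinetic promoter the activity scale
#'   (reporter units/h), for a thermodynamic promoter the occupancy ratio
#'   R(t). All entries >= 0.
#' @param rho Named list (`Pv`, `Ps`) of per-configuration maximum-initiation
#'   rate ratios, each a named vector over all 8 configuration ids with
#'   `rho["000"] == 1`. Forced to 1 for thermodynamically controlled
#'   promoters; may be omitted for them.
#' @param eta Named list (`Pv`, `Ps`) of box-RNAP interaction energies (kT),
#'   each named over the boxes. Forced to 0 for kinetic promoters.
#' @param vmax_scale Named vector (`Pv`, `Ps`) of maximum-rate scales for
#'   thermodynamic promoters (ignored for kinetic ones).
#' @param timepoints Hour grid; defaults to 2..9.
#' @return Object of class `scenario_params`.
#' @export
scenario_params <- function(scenario, binding, A, rho = NULL, eta = NULL,
                            vmax_scale = NULL, timepoints = TIME_GRID) {
  scenario <- match.arg(scenario, SCENARIOS)
  stopifnot(inherits(binding, "binding_params"))
  if (!is.matrix(A) || nrow(A) != 2 || ncol(A) != length(timepoints)) {
    stop("A must be a 2 x ", length(timepoints), " matrix", call. = FALSE)
  }
  if (is.null(rownames(A))) rownames(A) <- PROMOTERS
  if (!setequal(rownames(A), PROMOTERS)) {
    stop("A must have rownames Pv, Ps", call. = FALSE)
  }
  A <- A[PROMOTERS, , drop = FALSE]
  colnames(A) <- timepoints
  if (any(!is.finite(A)) || any(A < 0)) {
    stop("A must be finite and >= 0", call. = FALSE)
  }
  ids <- config_ids()
  ctrl <- c(Pv = substr(scenario, 1, 1), Ps = substr(scenario, 2, 2))
  rho_out <- eta_out <- list()
  vs_out <- setNames(rep(NA_real_, 2), PROMOTERS)
  for (p in PROMOTERS) {
    if (ctrl[[p]] == "K") {
      r <- rho[[p]]
      if (is.null(r)) {
        stop("rho$", p, " required for kinetic promoter", call. = FALSE)
      }
      if (!setequal(names(r), ids)) {
        stop("rho$", p, " must be named over all 8 configuration ids",
             call. = FALSE)
      }
      r <- r[ids]
      if (abs(r[["000"]] - 1) > 1e-12) {
        stop("rho$", p, "['000'] must equal 1", call. = FALSE)
      }
      if (any(!is.finite(r)) || any(r < 0)) {
        stop("rho$", p, " must be finite and >= 0", call. = FALSE)
      }
      rho_out[[p]] <- r
      eta_out[[p]] <- setNames(numeric(3), BOXES)
    } else {
      rho_out[[p]] <- setNames(rep(1, 8), ids)
      e <- eta[[p]]
      if (is.null(e)) e <- setNames(numeric(3), BOXES)
      if (!setequal(names(e), BOXES)) {
        stop("eta$", p, " must be named over the boxes", call. = FALSE)
      }
      eta_out[[p]] <- e[BOXES]
      v <- vmax_scale[[p]]
      if (is.null(v) || !is.finite(v) || v < 0) {
        stop("vmax_scale$", p, " required (>= 0) for thermodynamic promoter",
             call. = FALSE)
      }
      vs_out[[p]] <- v
    }
  }
  structure(list(scenario = scenario, binding = binding, A = A,
                 rho = rho_out, eta = eta_out, vmax_scale = vs_out,
                 timepoints = as.numeric(timepoints)),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params> scenario=", x$scenario, " (Pv=",
      substr(x$scenario, 1, 1), ", Ps=", substr(x$scenario, 2, 2), ")\n",
      sep = "")
  cat("  timepoints:", paste(x$timepoints, collapse = " "), "h\n")
  print(x$binding)
  invisible(x)
}

promoter_control <- function(params, promoter) {
  substr(params$scenario, match(promoter, PROMOTERS), match(promoter, PROMOTERS))
}

#' Statistical weight of a box configuration
#'
#' `W(s) = prod_i (conc/kh_i)^(n0a * s_i) * prod_{i<j} exp(-eps_ij)^(s_i s_j)`
#' relative to the all-unbound reference, so `W("000") == 1`.
#'
#' @param config Configuration id, e.g. "011".
#' @param conc 0A~P concentration in uM (scalar >= 0).
#' @param binding [binding_params()]; uses the in-vivo exponent `n0a`.
#' @return Non-negative weight.
#' @export
config_weight <- function(config, conc, binding) {
  stopifnot(inherits(binding, "binding_params"))
  if (!config %in% config_ids()) {
    stop("invalid configuration id: ", config, call. = FALSE)
  }
  if (length(conc) != 1 || conc < 0) {
    stop("conc must be a single value >= 0", call. = FALSE)
  }
  s <- as.integer(strsplit(config, "", fixed = TRUE)[[1]])
  w <- 1
  for (i in 1:3) {
    if (s[i] == 1) w <- w * (conc / binding$kh[[BOXES[i]]])^binding$n0a
  }
  for (i in 1:2) {
    for (j in (i + 1):3) {
      if (s[i] == 1 && s[j] == 1) w <- w * exp(-eps_pair(binding, i, j))
    }
  }
  w
}

# Vector of weights over the 8 configurations, 0 for configurations binding
# an absent box.
config_weights_vec <- function(conc, binding, present_boxes) {
  S <- config_matrix()
  pres <- as.integer(BOXES %in% present_boxes)
  w <- setNames(numeric(8), rownames(S))
  for (ci in seq_len(8)) {
    s <- S[ci, ]
    if (any(s > pres)) next
    wi <- 1
    for (i in 1:3) {
      if (s[i] == 1) wi <- wi * (conc / binding$kh[[BOXES[i]]])^binding$n0a
    }
    for (i in 1:2) {
      for (j in (i + 1):3) {
        if (s[i] == 1 && s[j] == 1) wi <- wi * exp(-eps_pair(binding, i, j))
      }
    }
    w[ci] <- wi
  }
  w
}

#' Box-configuration occupancy probabilities
#'
#' Normalized Boltzmann probabilities `P(s) = W(s) / sum W(s')` over the
#' configurations consistent with the present boxes (absent boxes are forced
#' unbound and their configurations get probability 0).
#'
#' @param conc 0A~P concentration in uM (scalar).
#' @param binding [binding_params()].
#' @param present Boxes present in the strain: box names or subset label;
#'   defaults to all three.
#' @return Named probability vector over all 8 configuration ids, summing
#'   to 1.
#' @export
box_occupancy <- function(conc, binding, present = BOXES) {
  boxes <- if (length(present) == 0) {
    character(0)
  } else if (length(present) == 1 && !present[1] %in% BOXES) {
    label_to_boxes(present)
  } else {
    present
  }
  w <- config_weights_vec(conc, binding, boxes)
  w / sum(w)
}

# Marginal bound probability per box, from box_occupancy.
box_marginals <- function(conc, binding, present = BOXES) {
  p <- box_occupancy(conc, binding, present)
  S <- config_matrix()
  setNames(as.numeric(crossprod(S, p)), BOXES)
}

# eta interaction factors F(s) = exp(-sum_i eta_i s_i) per configuration.
eta_factors <- function(eta_vec) {
  exp(-as.numeric(config_matrix() %*% eta_vec))
}

#' Effective transcription rate of a single-promoter strain
#'
#' For a kinetically controlled promoter,
#' `veff = A(p, t) * sum_s P(s) rho(p, s)`; for a thermodynamically
#' controlled promoter the RNAP-bound probability comes from the joint
#' partition function over (box configuration, RNAP state) with weights
#' `W(s) * (R(p, t) * prod_i exp(-eta_i)^{s_i})^r`, and
#' `veff = vmax_scale * P(RNAP bound)`.
#'
#' @param strain A [strain_spec()] with cohort "Pv" or "Ps".
#' @param params A [scenario_params()].
#' @param conc 0A~P concentration in uM (scalar).
#' @param t Timepoint in hours; must lie on the parameter grid.
#' @return Rate in reporter units/h.
#' @export
veff_single <- function(strain, params, conc, t) {
  stopifnot(inherits(strain, "strain_spec"), inherits(params, "scenario_params"))
  if (!strain$cohort %in% PROMOTERS) {
    stop("veff_single requires a Pv or Ps strain", call. = FALSE)
  }
  ti <- match(t, params$timepoints)
  if (is.na(ti)) {
    stop("timepoint ", t, " h is outside the parameter grid", call. = FALSE)
  }
  p <- strain$cohort
  w <- config_weights_vec(conc, params$binding, strain$boxes)
  if (promoter_control(params, p) == "K") {
    occ <- w / sum(w)
    params$A[p, ti] * sum(occ * params$rho[[p]])
  } else {
    g <- params$A[p, ti] * eta_factors(params$eta[[p]])
    params$vmax_scale[[p]] * sum(w * g) / sum(w * (1 + g))
  }
}

#' Effective transcription rate of a dual-promoter strain
#'
#' Joint partition function over the box configuration and the RNAP state of
#' each thermodynamically controlled promoter (no RNAP-RNAP interaction
#' term); each bound RNAP couples to bound boxes through its own eta
#' energies. Kinetically controlled promoters contribute
#' `A(p, t) * rho(p, s)` in every joint state, so under the purely kinetic
#' scenario the dual rate is exactly the sum of the two single-promoter
#' rates.
#'
#' @inheritParams veff_single
#' @param strain A [strain_spec()] with cohort "PvPs".
#' @return Rate in reporter units/h.
#' @export
veff_dual <- function(strain, params, conc, t) {
  stopifnot(inherits(strain, "strain_spec"), inherits(params, "scenario_params"))
  if (strain$cohort != "PvPs") {
    stop("veff_dual requires a PvPs strain", call. = FALSE)
  }
  ti <- match(t, params$timepoints)
  if (is.na(ti)) {
    stop("timepoint ", t, " h is outside the parameter grid", call. = FALSE)
  }
  w <- config_weights_vec(conc, params$binding, strain$boxes)
  g <- f <- list()
  for (p in PROMOTERS) {
    if (promoter_control(params, p) == "T") {
      g[[p]] <- params$A[p, ti] * eta_factors(params$eta[[p]])
      f[[p]] <- 1 + g[[p]]
    } else {
      g[[p]] <- NULL
      f[[p]] <- rep(1, 8)
    }
  }
  z <- sum(w * f$Pv * f$Ps)
  v <- 0
  for (p in PROMOTERS) {
    other <- setdiff(PROMOTERS, p)
    if (promoter_control(params, p) == "K") {
      v <- v + params$A[p, ti] *
        sum(w * f$Pv * f$Ps * params$rho[[p]]) / z
    } else {
      v <- v + params$vmax_scale[[p]] * sum(w * g[[p]] * f[[other]]) / z
    }
  }
  v
}

#' Predicted activity time course of a strain
#'
#' Evaluates [veff_single()] or [veff_dual()] at every timepoint of the
#' parameter grid using the 0A~P signal.
#'
#' @param strain A [strain_spec()].
#' @param params A [scenario_params()].
#' @param sig A [signal_0ap()] covering the parameter time grid.
#' @return Data frame with columns `time_h` and `veff`.
#' @export
predict_timecourse <- function(strain, params, sig) {
  conc <- signal_conc_at(sig, params$timepoints)
  fun <- if (strain$cohort == "PvPs") veff_dual else veff_single
  veff <- vapply(seq_along(params$timepoints), function(i) {
    fun(strain, params, conc[i], params$timepoints[i])
  }, numeric(1))
  data.frame(time_h = params$timepoints, veff = veff)
}

#' Predicted activity of the full strain panel
#'
#' @inheritParams predict_timecourse
#' @param strains List of [strain_spec()]s; defaults to the 24-strain panel.
#' @return Tidy data frame with columns `cohort`, `boxes`, `time_h`, `veff`.
#' @export
predict_panel <- function(params, sig, strains = all_strains()) {
  out <- lapply(strains, function(st) {
    tc <- predict_timecourse(st, params, sig)
    data.frame(cohort = st$cohort, boxes = st$label,
               time_h = tc$time_h, veff = tc$veff)
  })
  do.call(rbind, out)
}
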
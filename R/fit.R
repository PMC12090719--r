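# Multi-strain scenario fitting: EMSA-derived constraints with the in-vivo
# reconciliation scale, multi-start bounded optimization of the compiled
# objective, scenario ranking, and constrained (nested) interaction fits.

#' Reconcile in-vitro half-saturation constants with in-vivo conditions
#'
#' A single global scale lambda maps the EMSA-derived constants onto the
#' in-vivo model, `Kh_vivo,i = lambda * Kh_vitro,i`, preserving the relative
#' box affinities. lambda is fitted alongside the other promoter-model
#' parameters.
#'
#' @param kh_vitro Named per-box Kh in uM.
#' @param lambda Positive scale factor.
#' @return Named in-vivo Kh vector.
#' @export
reconcile_kh <- function(kh_vitro, lambda) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0) {
    stop("lambda must be a single value > 0", call. = FALSE)
  }
  lambda * kh_vitro
}

# Parameter-vector layout for a scenario; bounds follow the optimizer
# defaults (rho in [0,5], eps in [-10,5], lambda in [0.01,100], A in
# [0, 5*max data], eta in [-10,5], log R in [-9,9]).
theta_layout <- function(scenario, max_data, timepoints = TIME_GRID,
                         eps_zero = character()) {
  scenario <- match.arg(scenario, SCENARIOS)
  bad <- setdiff(eps_zero, EPS_PAIRS)
  if (length(bad) > 0) {
    stop("unknown eps pair(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  T <- length(timepoints)
  nm <- paste0("eps", EPS_PAIRS)
  lo <- rep(-10, 3)
  hi <- rep(5, 3)
  pin <- EPS_PAIRS %in% eps_zero
  lo[pin] <- 0
  hi[pin] <- 0
  nm <- c(nm, "log_lambda")
  lo <- c(lo, log(0.01))
  hi <- c(hi, log(100))
  for (p in PROMOTERS) {
    ctrl <- substr(scenario, match(p, PROMOTERS), match(p, PROMOTERS))
    if (ctrl == "K") {
      nm <- c(nm, paste0(p, ".A.t", timepoints),
              paste0(p, ".rho.", config_ids()[-1]))
      lo <- c(lo, rep(0, T), rep(0, 7))
      hi <- c(hi, rep(5 * max_data, T), rep(5, 7))
    } else {
      nm <- c(nm, paste0(p, ".logR.t", timepoints),
              paste0(p, ".logvmax"), paste0(p, ".eta.", BOXES))
      lo <- c(lo, rep(-9, T), log(1e-3 * max_data), rep(-10, 3))
      hi <- c(hi, rep(9, T), log(20 * max_data), rep(5, 3))
    }
  }
  list(scenario = scenario, names = nm, lower = lo, upper = hi,
       timepoints = timepoints, eps_zero = eps_zero,
       k = as.integer(length(nm) - length(eps_zero)))
}

# Data/constraint bundle handed to the compiled objective.
build_fit_spec <- function(X, kh_vitro, n0a, scenario, conc, layout) {
  idx <- strain_index()
  present <- t(vapply(idx$boxes, function(l) {
    as.integer(BOXES %in% label_to_boxes(l))
  }, integer(3)))
  list(conc = as.numeric(conc), kh = as.numeric(kh_vitro[BOXES]),
       n0a = as.numeric(n0a),
       ctrl_v = as.integer(substr(scenario, 1, 1) == "T"),
       ctrl_s = as.integer(substr(scenario, 2, 2) == "T"),
       cohort = match(idx$cohort, COHORTS) - 1L,
       present = present, X = X,
       lower = layout$lower, upper = layout$upper)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Data-informed starting point: A (or R) from the cohort's box-free strain,
# rho from late-time activity ratios. `jitter = 0` gives the plain heuristic.
init_theta <- function(layout, X, jitter = 0) {
  T <- length(layout$timepoints)
  none <- list(Pv = X["Pv:none", ], Ps = X["Ps:none", ])
  jit <- function(x, lo, hi) {
    if (jitter > 0) x <- x * exp(runif(length(x), -jitter, jitter))
    clamp(x, lo, hi)
  }
  th <- numeric(0)
  eps0 <- ifelse(EPS_PAIRS %in% layout$eps_zero, 0,
                 if (jitter > 0) runif(3, -3, 1) else rep(-1, 3))
  th <- c(th, eps0)
  th <- c(th, if (jitter > 0) runif(1, log(0.2), log(5)) else 0)
  for (p in PROMOTERS) {
    ctrl <- substr(layout$scenario, match(p, PROMOTERS), match(p, PROMOTERS))
    y <- none[[p]]
    if (ctrl == "K") {
      A0 <- jit(y, 0, 5 * max(X))
      ratio <- vapply(config_ids()[-1], function(cfg) {
        lab <- boxes_to_label(BOXES[strsplit(cfg, "")[[1]] == "1"])
        X[paste0(p, ":", lab), T] / y[T]
      }, numeric(1))
      rho0 <- jit(ratio, 0.02, 4.98)
      th <- c(th, A0, rho0)
    } else {
      vmax <- 2 * max(y) * (if (jitter > 0) exp(runif(1, -0.5, 0.5)) else 1)
      R <- clamp(y / pmax(vmax - y, 1e-8 * vmax), 1e-4, 1e4)
      logR <- jit(log(R) + 0, -9, 9)
      eta0 <- if (jitter > 0) runif(3, -3, 1) else rep(0, 3)
      th <- c(th, clamp(logR, -9, 9), clamp(log(vmax), log(1e-3 * max(X)),
                                            log(20 * max(X))), eta0)
    }
  }
  names(th) <- layout$names
  clamp(th, layout$lower, layout$upper)
}

# Rebuild scenario_params (with in-vivo binding) from an optimizer vector.
params_from_theta <- function(theta, layout, kh_vitro, n, n0a) {
  T <- length(layout$timepoints)
  eps <- setNames(theta[1:3], EPS_PAIRS)
  lambda <- exp(theta[[4]])
  binding <- binding_params(n = n, kh = reconcile_kh(kh_vitro, lambda),
                            eps = eps, n0a = n0a)
  off <- 4
  A <- matrix(0, 2, T, dimnames = list(PROMOTERS, layout$timepoints))
  rho <- list()
  eta <- list()
  vmax <- setNames(rep(NA_real_, 2), PROMOTERS)
  for (p in PROMOTERS) {
    ctrl <- substr(layout$scenario, match(p, PROMOTERS), match(p, PROMOTERS))
    if (ctrl == "K") {
      A[p, ] <- theta[(off + 1):(off + T)]
      rho[[p]] <- setNames(c(1, theta[(off + T + 1):(off + T + 7)]),
                           config_ids())
      off <- off + T + 7
    } else {
      A[p, ] <- exp(theta[(off + 1):(off + T)])
      vmax[[p]] <- exp(theta[[off + T + 1]])
      eta[[p]] <- setNames(theta[(off + T + 2):(off + T + 4)], BOXES)
      off <- off + T + 4
    }
  }
  list(params = scenario_params(layout$scenario, binding, A, rho = rho,
                                eta = eta, vmax_scale = vmax,
                                timepoints = layout$timepoints),
       lambda = lambda)
}

# Inverse of params_from_theta, used to start a fit from known parameters.
theta_from_params <- function(params, layout, kh_vitro) {
  T <- length(layout$timepoints)
  lambda <- params$binding$kh[[BOXES[1]]] / kh_vitro[[BOXES[1]]]
  th <- c(params$binding$eps[EPS_PAIRS], log(lambda))
  for (p in PROMOTERS) {
    ctrl <- substr(layout$scenario, match(p, PROMOTERS), match(p, PROMOTERS))
    if (ctrl == "K") {
      th <- c(th, params$A[p, ], params$rho[[p]][config_ids()[-1]])
    } else {
      th <- c(th, log(params$A[p, ]), log(params$vmax_scale[[p]]),
              params$eta[[p]][BOXES])
    }
  }
  names(th) <- layout$names
  clamp(th, layout$lower, layout$upper)
}

#' Fit one regulatory scenario to the 24-strain panel
#'
#' Minimizes the per-cohort relative squared-error objective over the free
#' parameters of the scenario (per-timepoint RNAP activities, initiation
#' -rate ratios rho or box-RNAP energies eta, box-box interaction energies
#' eps, and the EMSA reconciliation scale lambda), constrained by the
#' EMSA-derived half-saturation constants and stoichiometry. Optimization
#' is multi-start bounded quasi-Newton (L-BFGS-B) with one data-informed
#' start plus seeded random restarts; the best restart is reported.
#'
#' @param data An [activity_dataset()] covering all 24 strains on the hour
#'   grid.
#' @param emsa EMSA constraints: a [fit_kh()] result, or a list with `kh`
#'   (named per-box, all three boxes) and `n`.
#' @param sig A [signal_0ap()] giving the 0A~P concentration over the grid.
#' @param scenario Control scenario ("KK", "TT", "TK", "KT").
#' @param n_restarts Number of independent starts (default 20).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param eps_zero Interaction-energy pairs (among "12","13","23") pinned to
#'   zero, for nested-model tests.
#' @param maxit L-BFGS-B iteration cap for the polishing stage.
#' @param maxit_explore Iteration cap for the exploration stage run from
#'   every start; the best `n_polish` exploration results are then polished
#'   to convergence.
#' @param n_polish Number of exploration results polished (default 3).
#' @param n0a In-vivo cooperativity exponent; defaults to the EMSA `n`.
#' @param init Optional [scenario_params()] used as the first start.
#' @return Object of class `scenario_fit`: fitted `params`
#'   ([scenario_params()] with in-vivo binding), `lambda`, `objective`
#'   breakdown, `E`, `bic`, `k`, per-restart errors, convergence codes,
#'   flagged bound-hitting parameters, and the seed.
#' @export
fit_scenario <- function(data, emsa, sig, scenario = "KK", n_restarts = 20,
                         seed = 1, eps_zero = character(), maxit = 500,
                         maxit_explore = 80, n_polish = 3,
                         n0a = NULL, init = NULL) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  if (inherits(emsa, "kh_fit")) {
    emsa <- list(kh = emsa$kh, n = emsa$n)
  }
  kh_vitro <- emsa$kh[BOXES]
  if (anyNA(kh_vitro)) {
    stop("emsa constraints must provide Kh for all three boxes",
         call. = FALSE)
  }
  n <- emsa$n
  if (is.null(n0a)) n0a <- n
  X <- activity_means(data)
  if (any(X == 0)) {
    stop("zero mean activity: relative objective undefined", call. = FALSE)
  }
  conc <- signal_conc_at(sig, TIME_GRID)
  layout <- theta_layout(scenario, max(X), eps_zero = eps_zero)
  cspec <- build_fit_spec(X, kh_vitro, n0a, scenario, conc, layout)

  set.seed(seed)
  starts <- vector("list", n_restarts)
  if (!is.null(init)) {
    starts[[1]] <- theta_from_params(init, layout, kh_vitro)
  } else {
    starts[[1]] <- init_theta(layout, X, jitter = 0)
  }
  if (n_restarts > 1) {
    for (i in 2:n_restarts) {
      starts[[i]] <- init_theta(layout, X, jitter = 0.5)
    }
  }

  # Pinned parameters (eps_zero) are held out of the optimizer vector and
  # re-embedded on every evaluation.
  free_idx <- which(!layout$names %in% paste0("eps", layout$eps_zero))
  template <- numeric(length(layout$names))
  embed <- function(par) {
    template[free_idx] <- par
    template
  }
  run_lbfgsb <- function(par, iters, factr) {
    res <- tryCatch(
      optim(par[free_idx],
            fn = function(p) panel_objective_cpp(embed(p), cspec),
            method = "L-BFGS-B",
            lower = layout$lower[free_idx], upper = layout$upper[free_idx],
            control = list(maxit = iters, factr = factr)),
      error = function(e) NULL)
    if (!is.null(res)) {
      res$par <- setNames(embed(res$par), layout$names)
    }
    res
  }

  # Stage 1: short exploration from every start; stage 2: polish the best
  # few exploration results to convergence.
  values <- rep(NA_real_, n_restarts)
  conv <- rep(NA_integer_, n_restarts)
  stage1 <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    res <- run_lbfgsb(starts[[i]], maxit_explore, 1e9)
    if (is.null(res)) next
    stage1[[i]] <- res
    values[i] <- res$value
    conv[i] <- res$convergence
  }
  if (all(is.na(values))) {
    stop("optimizer failed on every restart", call. = FALSE)
  }
  top <- order(values)[seq_len(min(n_polish, sum(!is.na(values))))]
  best <- NULL
  for (i in top) {
    res <- run_lbfgsb(stage1[[i]]$par, maxit, 1e7)
    if (is.null(res)) next
    if (res$value < values[i]) {
      values[i] <- res$value
      conv[i] <- res$convergence
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) best <- stage1[[which.min(values)]]

  pf <- params_from_theta(best$par, layout, kh_vitro, n, n0a)
  pred <- predict_panel(pf$params, sig)
  obj <- objective(pred, X)
  free <- !layout$names %in% paste0("eps", eps_zero)
  hits <- layout$names[free &
    (abs(best$par - layout$lower) < 1e-8 | abs(best$par - layout$upper) < 1e-8)]
  fit <- structure(list(
    scenario = scenario, params = pf$params, lambda = pf$lambda,
    kh_vitro = kh_vitro, n = n, n0a = n0a,
    objective = obj, E = obj$E, k = layout$k,
    eps_zero = eps_zero, theta = best$par, layout = layout,
    restart_errors = values, convergence = conv,
    n_restarts = n_restarts, seed = seed, bound_hits = hits), class = "scenario_fit")
  fit$bic <- bic(fit)
  fit
}

#' @export
print.scenario_fit <- function(x, ...) {
  cat(sprintf("<scenario_fit> %s: E=%.6g (BIC=%.2f, k=%d, %d restarts)\n",
              x$scenario, x$E, x$bic, x$k, x$n_restarts))
  cat(sprintf("  lambda=%.4g; eps: %s\n", x$lambda,
              paste(EPS_PAIRS, signif(x$params$binding$eps, 3), sep = "=",
                    collapse = "  ")))
  if (length(x$bound_hits) > 0) {
    cat("  at bounds:", paste(x$bound_hits, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit with selected interaction energies pinned to zero
#'
#' Nested-model variant of [fit_scenario()] used to test whether each
#' box-box interaction energy is required: the listed pairs are constrained
#' to zero and excluded from the free-parameter count.
#'
#' @inheritParams fit_scenario
#' @param zero_set Pairs (among "12","13","23") to pin at zero; empty set
#'   reproduces [fit_scenario()].
#' @return A `scenario_fit`.
#' @export
fit_constrained_interactions <- function(data, emsa, sig, zero_set,
                                         scenario = "KK", ...) {
  fit_scenario(data, emsa, sig, scenario = scenario, eps_zero = zero_set, ...)
}

#' Rank fitted scenarios by optimization error
#'
#' Sorts scenario fits by total error E ascending, breaking ties by fewer
#' effective parameters and then by the tag order KK, KT, TK, TT.
#'
#' @param results List of `scenario_fit` objects fitted on the same data.
#' @return List with `ranking` (data frame of scenario, E, k, BIC in rank
#'   order) and `best` (the winning scenario tag).
#' @export
compare_scenarios <- function(results) {
  df <- data.frame(
    scenario = vapply(results, `[[`, character(1), "scenario"),
    E = vapply(results, `[[`, numeric(1), "E"),
    k = vapply(results, `[[`, integer(1), "k"),
    bic = vapply(results, function(r) as.numeric(r$bic), numeric(1))
  )
  ord <- order(df$E, df$k, match(df$scenario, c("KK", "KT", "TK", "TT")))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  list(ranking = df, best = df$scenario[1])
}
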
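# Synthetic-data generator: a ground-truth parameter set with the
# qualitative structure of the spo0A system, a logistic 0A~P stand-in
# signal, EMSA titrations for all seven box subsets, and the 24-strain
# activity panel with replicate noise.

#' Logistic 0A~P concentration stand-in
#'
#' A configurable stand-in for the wild-type 0A~P rise after the onset of
#' starvation: `c(t) = c_max / (1 + exp(-k (t - t0)))` sampled on the hour
#' grid, monotone non-decreasing for `k >= 0`.
#'
#' @param c_max Plateau concentration in uM (> 0); default 1.
#' @param t0 Midpoint in hours; default 4.
#' @param k Rise rate in 1/h; default 1.
#' @param timepoints Hour grid; default 2..9.
#' @return A [signal_0ap()].
#' @export
gen_0ap_signal <- function(c_max = 1, t0 = 4, k = 1,
                           timepoints = TIME_GRID) {
  if (!is.finite(c_max) || c_max <= 0) {
    stop("c_max must be > 0", call. = FALSE)
  }
  signal_0ap(timepoints, c_max / (1 + exp(-k * (timepoints - t0))))
}

#' Default ground truth for the synthetic study
#'
#' The generator's fixed study conditions: tetrameric binding (N = N0A = 4)
#' with affinity ordering Kh(0A3) < Kh(0A1) < Kh(0A2); a purely kinetic
#' (KK) scenario whose initiation-rate ratios make the 0A boxes mostly
#' repressive on Pv while 0A3 activates and 0A2 represses Ps (with the
#' 2+3 combination overriding the 0A3 activation); attractive in-vivo
#' box-box interactions, strongest between 0A2 and 0A3; RNAP activities
#' rising ~1.4-fold (Pv) and ~10.8-fold (Ps) over 2-9 h; a unit EMSA
#' reconciliation scale; and the logistic 0A~P signal. The in-vitro binding
#' model carries no interaction energies.
#'
#' @param scenario Generating control scenario (default "KK").
#' @return List with `binding_vitro` ([binding_params()], eps = 0),
#'   `params` ([scenario_params()] with the in-vivo binding),
#'   `sig` ([signal_0ap()]), `kh_vitro`, `lambda`, `n`.
#' @export
default_truth <- function(scenario = "KK") {
  kh_vitro <- c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2)
  n <- 4L
  lambda <- 1
  eps_vivo <- c("12" = -1.0, "13" = -1.5, "23" = -2.5)
  binding_vitro <- binding_params(n, kh_vitro)
  binding_vivo <- binding_params(n, reconcile_kh(kh_vitro, lambda),
                                 eps = eps_vivo)
  t <- TIME_GRID
  A <- rbind(Pv = 100 * (1 + 0.4 * (t - 2) / 7),
             Ps = 20 * 10.8^((t - 2) / 7))
  rho <- list(
    Pv = c("000" = 1, "001" = 0.90, "010" = 0.80, "011" = 0.75,
           "100" = 0.45, "101" = 0.42, "110" = 0.40, "111" = 0.35),
    Ps = c("000" = 1, "001" = 1.50, "010" = 0.55, "011" = 0.50,
           "100" = 1.20, "101" = 1.60, "110" = 0.65, "111" = 0.284)
  )
  params <- scenario_params(scenario, binding_vivo, A, rho = rho)
  list(binding_vitro = binding_vitro, params = params,
       sig = gen_0ap_signal(), kh_vitro = kh_vitro, lambda = lambda, n = n)
}

#' Generate a synthetic EMSA titration table
#'
#' Evaluates the in-vitro multi-box bound fraction for all seven non-empty
#' box subsets on a concentration grid and adds truncated-Gaussian noise
#' per replicate.
#'
#' @param truth Ground truth from [default_truth()] (uses `binding_vitro`).
#' @param conc Concentration grid in uM; default 8 points spanning 0-2 uM.
#' @param replicates Replicates per point (default 2, as in duplicate gels).
#' @param sd Additive noise SD on the bound fraction (default 0.02).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An [emsa_dataset()].
#' @export
gen_emsa_dataset <- function(truth = default_truth(),
                             conc = c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1.2, 2),
                             replicates = 2, sd = 0.02, seed = 1) {
  set.seed(seed)
  labs <- setdiff(BOX_LABELS, "none")
  rows <- expand.grid(replicate = seq_len(replicates), conc_uM = conc,
                      box_subset = labs, stringsAsFactors = FALSE)
  rows <- rows[, c("box_subset", "conc_uM", "replicate")]
  mu <- unlist(lapply(labs, function(l) {
    rep(fraction_bound_multi(l, truth$binding_vitro, conc),
        each = replicates)
  }))
  y <- vapply(mu, function(m) rtrunc01(1, m, sd), numeric(1))
  rows$frac_bound <- y
  rows <- rows[order(rows$box_subset, rows$conc_uM, rows$replicate), ]
  rownames(rows) <- NULL
  emsa_dataset(rows)
}

#' Generate the synthetic 24-strain activity panel
#'
#' Enumerates all 3 cohorts x 8 box subsets, takes the noise-free means
#' from [predict_timecourse()] under the ground-truth scenario, and applies
#' multiplicative log-normal replicate noise (reporter noise scales with
#' signal).
#'
#' @param truth Ground truth from [default_truth()].
#' @param cv Coefficient of variation of the replicate noise (default 5%).
#' @param replicates Replicates per strain and timepoint (default 3).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An [activity_dataset()].
#' @export
gen_activity_panel <- function(truth = default_truth(), cv = 0.05,
                               replicates = 3, seed = 1) {
  set.seed(seed)
  means <- predict_panel(truth$params, truth$sig)
  sdlog <- sqrt(log(1 + cv^2))
  out <- means[rep(seq_len(nrow(means)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), nrow(means))
  noise <- if (cv > 0) exp(rnorm(nrow(out), -sdlog^2 / 2, sdlog)) else 1
  out$activity <- out$veff * noise
  out$veff <- NULL
  rownames(out) <- NULL
  activity_dataset(out)
}
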
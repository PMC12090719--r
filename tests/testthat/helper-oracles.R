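# Independent loop-based oracles, deliberately free of the package's
# vectorized code paths.

# P(at least one box of `boxes` bound): explicit sum over all 2^k states.
oracle_frac_bound <- function(boxes, kh, n, eps_mat, conc) {
  idx <- match(boxes, c("0A1", "0A2", "0A3"))
  k <- length(idx)
  z <- 0
  p_none <- 0
  for (code in 0:(2^k - 1)) {
    s <- as.integer(intToBits(code))[seq_len(k)]
    w <- 1
    for (b in seq_len(k)) {
      if (s[b] == 1) w <- w * (conc / kh[[boxes[b]]])^n
    }
    if (k > 1) {
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) {
          if (s[a] == 1 && s[b] == 1) {
            w <- w * exp(-eps_mat[idx[a], idx[b]])
          }
        }
      }
    }
    z <- z + w
    if (sum(s) == 0) p_none <- p_none + w
  }
  1 - p_none / z
}

# Symmetric 3x3 eps matrix from a binding_params object.
eps_matrix <- function(binding) {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- binding$eps[["12"]]
  m[1, 3] <- m[3, 1] <- binding$eps[["13"]]
  m[2, 3] <- m[3, 2] <- binding$eps[["23"]]
  m
}

# Configuration probabilities by explicit enumeration over all 8 states.
oracle_occupancy <- function(conc, binding, present_boxes) {
  boxes <- c("0A1", "0A2", "0A3")
  pres <- as.integer(boxes %in% present_boxes)
  em <- eps_matrix(binding)
  w <- setNames(numeric(8), config_ids())
  i <- 0
  for (s1 in 0:1) for (s2 in 0:1) for (s3 in 0:1) {
    i <- i + 1
    id <- paste0(s1, s2, s3)
    s <- c(s1, s2, s3)
    if (any(s > pres)) {
      w[[id]] <- 0
      next
    }
    wi <- 1
    for (b in 1:3) {
      if (s[b] == 1) wi <- wi * (conc / binding$kh[[boxes[b]]])^binding$n0a
    }
    for (a in 1:2) for (b in (a + 1):3) {
      if (s[a] == 1 && s[b] == 1) wi <- wi * exp(-em[a, b])
    }
    w[[id]] <- wi
  }
  w / sum(w)
}

# Eq. 5-8 objective re-implemented with plain accumulation loops.
oracle_objective <- function(pred, data) {
  v <- if ("activity" %in% names(data)) "activity" else "veff"
  terms <- setNames(numeric(3), c("PvPs", "Pv", "Ps"))
  for (coh in names(terms)) {
    tot <- 0
    cnt <- 0
    for (lab in c("none", "1", "2", "3", "12", "13", "23", "123")) {
      for (t in 2:9) {
        x <- mean(data[[v]][data$cohort == coh & data$boxes == lab &
                              data$time_h == t])
        p <- mean(pred$veff[pred$cohort == coh & pred$boxes == lab &
                              pred$time_h == t])
        tot <- tot + (p - x)^2 / x^2
        cnt <- cnt + 1
      }
    }
    terms[[coh]] <- tot / cnt
  }
  list(E = sum(terms), Evs = terms[["PvPs"]], Ev = terms[["Pv"]],
       Es = terms[["Ps"]])
}

# Random scenario parameters for property tests. Draws a full parameter set
# with the requested control scenario over the 2..9 h grid.
random_scenario <- function(scenario = "KK") {
  kh <- setNames(runif(3, 0.1, 1), c("0A1", "0A2", "0A3"))
  eps <- setNames(runif(3, -4, 2), c("12", "13", "23"))
  binding <- binding_params(sample(1:4, 1), kh, eps = eps)
  A <- matrix(runif(16, 0.05, 5), 2, 8, dimnames = list(c("Pv", "Ps"), 2:9))
  rho <- lapply(c(Pv = 1, Ps = 2), function(i) {
    setNames(c(1, runif(7, 0, 3)), config_ids())
  })
  eta <- lapply(c(Pv = 1, Ps = 2), function(i) {
    setNames(runif(3, -3, 2), c("0A1", "0A2", "0A3"))
  })
  scenario_params(scenario, binding, A, rho = rho, eta = eta,
                  vmax_scale = c(Pv = runif(1, 10, 200),
                                 Ps = runif(1, 10, 200)))
}

random_strain <- function(cohorts = c("PvPs", "Pv", "Ps")) {
  strain_spec(sample(cohorts, 1),
              sample(c("none", "1", "2", "3", "12", "13", "23", "123"), 1))
}
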
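# In-vitro binding model: cooperative occupancy of 0A boxes by 0A~P.

#' Binding-model parameters
#'
#' Parameters of the cooperative 0A~P binding model: the stoichiometric
#' coefficient N (number of 0A~P molecules binding a box as one event), the
#' per-box half-saturation concentration Kh (uM), optional pairwise box-box
#' interaction energies (kT units, negative = attractive, entering
#' statistical weights as `exp(-eps)`), and the in-vivo cooperativity
#' exponent `n0a` (defaults to N).
#'
#' Under in-vitro conditions interactions between 0A~P molecules bound at
#' different boxes are taken as negligible, so `eps` defaults to zero; the
#' in-vivo promoter model fits them.
#'
#' @param n Integer stoichiometric coefficient, >= 1.
#' @param kh Named numeric vector of half-saturation concentrations in uM,
#'   names among `c("0A1","0A2","0A3")`, all > 0.
#' @param eps Named numeric vector of pair interaction energies with names
#'   among `c("12","13","23")`; missing pairs default to 0.
#' @param n0a In-vivo cooperativity exponent; defaults to `n`.
#' @return Object of class `binding_params`.
#' @export
binding_params <- function(n, kh, eps = NULL, n0a = n) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  if (is.null(names(kh)) || !all(names(kh) %in% BOXES)) {
    stop("kh must be named with box identifiers ", paste(BOXES, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(kh)) || any(kh <= 0)) {
    stop("all kh must be finite and > 0", call. = FALSE)
  }
  e <- setNames(numeric(3), EPS_PAIRS)
  if (!is.null(eps)) {
    if (is.null(names(eps)) || !all(names(eps) %in% EPS_PAIRS)) {
      stop("eps must be named with pair identifiers ",
           paste(EPS_PAIRS, collapse = ", "), call. = FALSE)
    }
    e[names(eps)] <- eps
  }
  if (!is.finite(n0a) || n0a < 1) {
    stop("n0a must be >= 1", call. = FALSE)
  }
  structure(list(n = as.integer(n), kh = kh[order(names(kh))], eps = e,
                 n0a = n0a),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat("<binding_params> N=", x$n, " N0A=", x$n0a, "\n", sep = "")
  cat("  Kh (uM):", paste(names(x$kh), signif(x$kh, 4), sep = "=",
                          collapse = "  "), "\n")
  cat("  eps (kT):", paste(names(x$eps), signif(x$eps, 4), sep = "=",
                           collapse = "  "), "\n")
  invisible(x)
}

# eps value for an unordered pair of box indices i < j (1-based).
eps_pair <- function(params, i, j) {
  key <- paste0(min(i, j), max(i, j))
  params$eps[[key]]
}

#' Single-box bound fraction
#'
#' Mass-action equilibrium occupancy of one 0A box by N molecules of 0A~P:
#' `conc^n / (kh^n + conc^n)`. At `conc == kh` the box is occupied with 50%
#' probability; the curve is strictly increasing in `conc` and tends to 1.
#'
#' @param conc 0A~P concentration in uM (vectorized, >= 0).
#' @param kh Half-saturation concentration in uM (> 0).
#' @param n Stoichiometric coefficient (integer >= 1).
#' @return Bound fraction in \[0, 1\], same length as `conc`.
#' @export
fraction_bound_single <- function(conc, kh, n) {
  if (length(kh) != 1 || !is.finite(kh) || kh <= 0) {
    stop("kh must be a single finite value > 0", call. = FALSE)
  }
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  if (any(conc < 0)) {
    stop("conc must be >= 0", call. = FALSE)
  }
  r <- (conc / kh)^n
  r / (1 + r)
}

#' Multi-box bound fraction (band-shift observable)
#'
#' Probability that at least one box of `subset` is bound, from the
#' statistical-thermodynamic partition function over all bound/unbound
#' states of the subset, with per-box weights `(conc/kh_i)^(n * s_i)` and
#' pair factors `exp(-eps_ij)^(s_i s_j)`. Any occupied state shifts an EMSA
#' band, so this is the assay observable. With `eps == 0` it reduces to
#' `1 - prod_i (1 - fraction_bound_single(conc, kh_i, n))`.
#'
#' @param subset Boxes present on the DNA fragment: box names
#'   (e.g. `c("0A1","0A3")`) or a subset label (e.g. "13"). Must be
#'   non-empty.
#' @param params A [binding_params()] object (its `n`, not `n0a`, is the
#'   in-vitro exponent used here).
#' @param conc 0A~P concentration in uM (vectorized).
#' @return Probability that at least one subset box is bound.
#' @export
fraction_bound_multi <- function(subset, params, conc) {
  stopifnot(inherits(params, "binding_params"))
  boxes <- if (length(subset) == 1 && !subset %in% BOXES) {
    label_to_boxes(subset)
  } else {
    subset
  }
  if (length(boxes) == 0) {
    stop("subset must contain at least one box", call. = FALSE)
  }
  if (!all(boxes %in% BOXES) || anyDuplicated(boxes)) {
    stop("subset must be distinct boxes among ", paste(BOXES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(boxes %in% names(params$kh))) {
    stop("params$kh missing entries for: ",
         paste(setdiff(boxes, names(params$kh)), collapse = ", "),
         call. = FALSE)
  }
  if (any(conc < 0)) {
    stop("conc must be >= 0", call. = FALSE)
  }
  idx <- match(boxes, BOXES)
  k <- length(boxes)
  states <- as.matrix(expand.grid(rep(list(0:1), k)))
  # Z per concentration; the empty state has weight 1, so P(none bound) = 1/Z.
  z <- rep(0, length(conc))
  for (si in seq_len(nrow(states))) {
    s <- states[si, ]
    w <- rep(1, length(conc))
    for (b in seq_len(k)) {
      if (s[b] == 1) {
        w <- w * (conc / params$kh[[boxes[b]]])^params$n
      }
    }
    if (k > 1) {
      for (a in seq_len(k - 1)) {
        for (b in seq((a + 1), k)) {
          if (s[a] == 1 && s[b] == 1) {
            w <- w * exp(-eps_pair(params, idx[a], idx[b]))
          }
        }
      }
    }
    z <- z + w
  }
  1 - 1 / z
}
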
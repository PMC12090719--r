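# Readers and writers: tidy CSV for measurement tables, JSON for fitted
# parameters. Readers validate and reject malformed rows with their line
# numbers; writers are deterministic with stable key order.

JSON_VERSION <- "spo0Areg/1"

#' Read a promoter-activity CSV
#'
#' Expects columns `cohort`, `boxes`, `time_h`, `replicate`, `activity`.
#' Box labels are validated and canonicalized ("31" becomes "13"); rows
#' with unknown labels or non-numeric fields are rejected with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return An [activity_dataset()].
#' @export
read_activity_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cohort", "boxes", "time_h", "replicate", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_coh <- which(!df$cohort %in% COHORTS)
  if (length(bad_coh) > 0) {
    stop("unknown cohort in row(s) ", paste(bad_coh, collapse = ", "),
         call. = FALSE)
  }
  lab <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(normalize_label(df$boxes[i]), error = function(e) NA_character_)
  }, character(1))
  if (anyNA(lab)) {
    stop("invalid box label in row(s) ",
         paste(which(is.na(lab)), collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric ", col, " in row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
    v
  }
  activity_dataset(data.frame(
    cohort = df$cohort, boxes = lab, time_h = num("time_h"),
    replicate = as.integer(num("replicate")), activity = num("activity")))
}

#' Write a promoter-activity CSV
#'
#' @param data An [activity_dataset()].
#' @param path Output path.
#' @export
write_activity_csv <- function(data, path) {
  write.csv(activity_dataset(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EMSA titration CSV
#'
#' Expects columns `box_subset`, `conc_uM`, `replicate`, `frac_bound`;
#' malformed rows are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return An [emsa_dataset()].
#' @export
read_emsa_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("box_subset", "conc_uM", "replicate", "frac_bound")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric ", col, " in row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
    v
  }
  emsa_dataset(data.frame(
    box_subset = df$box_subset, conc_uM = num("conc_uM"),
    replicate = as.integer(num("replicate")),
    frac_bound = num("frac_bound")))
}

#' Write an EMSA titration CSV
#'
#' @param data An [emsa_dataset()].
#' @param path Output path.
#' @export
write_emsa_csv <- function(data, path) {
  write.csv(emsa_dataset(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an EMSA binding-model fit to JSON
#'
#' Serializes per-box Kh with 95% CI bounds, the chosen stoichiometry and
#' per-candidate errors, and the seed.
#'
#' @param kh_fit A [fit_kh()] result.
#' @param path Output path.
#' @param selection Optional [select_cooperativity()] result.
#' @export
write_emsa_fit_json <- function(kh_fit, path, selection = NULL) {
  stopifnot(inherits(kh_fit, "kh_fit"))
  boxes <- lapply(names(kh_fit$kh), function(b) {
    list(kh_uM = kh_fit$kh[[b]], ci95_low = kh_fit$ci[b, 1],
         ci95_high = kh_fit$ci[b, 2])
  })
  names(boxes) <- names(kh_fit$kh)
  obj <- list(version = JSON_VERSION, type = "emsa_fit",
              n = kh_fit$n, boxes = boxes, sse = kh_fit$sse,
              n_augment = kh_fit$n_augment, seed = kh_fit$seed)
  if (!is.null(kh_fit$warning)) obj$warning <- kh_fit$warning
  if (!is.null(selection)) {
    obj$selection <- list(best_n = selection$best_n,
                          errors = as.list(selection$errors))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

serialize_scenario_params <- function(params) {
  list(
    scenario = params$scenario,
    timepoints = params$timepoints,
    binding = list(n = params$binding$n, n0a = params$binding$n0a,
                   kh = as.list(params$binding$kh),
                   eps = as.list(params$binding$eps)),
    A = list(Pv = unname(params$A["Pv", ]), Ps = unname(params$A["Ps", ])),
    rho = lapply(params$rho, as.list),
    eta = lapply(params$eta, as.list),
    vmax_scale = as.list(params$vmax_scale)
  )
}

deserialize_scenario_params <- function(x) {
  binding <- binding_params(n = x$binding$n,
                            kh = unlist(x$binding$kh),
                            eps = unlist(x$binding$eps),
                            n0a = x$binding$n0a)
  A <- rbind(Pv = unlist(x$A$Pv), Ps = unlist(x$A$Ps))
  scenario_params(x$scenario, binding, A,
                  rho = lapply(x$rho, unlist),
                  eta = lapply(x$eta, unlist),
                  vmax_scale = unlist(x$vmax_scale),
                  timepoints = unlist(x$timepoints))
}

#' Write a scenario fit to JSON
#'
#' Full-precision serialization of a `scenario_fit`: the scenario tag,
#' fitted parameters with explicit configuration keys "000".."111", the
#' reconciliation scale, objective breakdown, BIC, per-restart error trace
#' and the seed.
#'
#' @param fit A `scenario_fit` from [fit_scenario()].
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "scenario_fit"))
  obj <- list(
    version = JSON_VERSION, type = "scenario_fit",
    scenario = fit$scenario,
    params = serialize_scenario_params(fit$params),
    lambda = fit$lambda,
    kh_vitro = as.list(fit$kh_vitro), n = fit$n, n0a = fit$n0a,
    objective = list(E = fit$E, Ev = fit$objective$Ev,
                     Es = fit$objective$Es, Evs = fit$objective$Evs),
    bic = as.numeric(fit$bic), k = fit$k,
    eps_zero = as.list(fit$eps_zero),
    restart_errors = fit$restart_errors,
    convergence = fit$convergence,
    n_restarts = fit$n_restarts, seed = fit$seed,
    bound_hits = as.list(fit$bound_hits)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scenario fit from JSON
#'
#' Inverse of [write_fit_json()]; rejects files whose version tag does not
#' match.
#'
#' @param path JSON file path.
#' @return A `scenario_fit` (without the optimizer layout internals).
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$version) || x$version != JSON_VERSION) {
    stop("version tag mismatch in ", path, " (expected ", JSON_VERSION, ")",
         call. = FALSE)
  }
  params <- deserialize_scenario_params(x$params)
  obj <- structure(list(E = x$objective$E, Ev = x$objective$Ev,
                        Es = x$objective$Es, Evs = x$objective$Evs,
                        L = setNames(rep(8L, 3), COHORTS),
                        T = setNames(rep(length(params$timepoints), 3),
                                     COHORTS)),
                   class = "objective_breakdown")
  structure(list(
    scenario = x$scenario, params = params, lambda = x$lambda,
    kh_vitro = unlist(x$kh_vitro), n = x$n, n0a = x$n0a,
    objective = obj, E = x$objective$E, k = as.integer(x$k),
    eps_zero = as.character(unlist(x$eps_zero)),
    restart_errors = as.numeric(unlist(x$restart_errors)),
    convergence = as.integer(unlist(x$convergence)),
    n_restarts = x$n_restarts, seed = x$seed,
    bound_hits = as.character(unlist(x$bound_hits)),
    bic = as.numeric(x$bic)), class = "scenario_fit")
}
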
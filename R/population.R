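# Log-normal population sampling of body parameters, ensemble summaries and
# one-at-a-time sensitivity scans.

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# One mean-matched log-normal draw per entry of x (vectorized).
.lnorm_draw <- function(x, sigma, mean_match) {
  if (sigma == 0) return(x)
  z <- stats::rnorm(length(x))
  if (identical(mean_match, "arithmetic")) x * exp(sigma * z - sigma^2 / 2)
  else x * exp(sigma * z)
}

#' Sample a population of physiologies
#'
#' Draws `n` parameter sets around a base physiology by independent
#' log-normal variation of the body parameters (compartment volumes, tissue
#' blood flows, cardiac output, respiratory water flow and body mass;
#' chemical parameters are never varied). By default each parameter's
#' arithmetic mean equals its base value (`mu_log = ln(base) - sigma^2/2`,
#' `sigma = ln(gsd)`); geometric mean-matching is available. After sampling,
#' tissue flows are rescaled so they sum exactly to the drawn cardiac output,
#' keeping every draw a valid physiology.
#'
#' @param base A [physiology_parameter_set()].
#' @param gsd Geometric standard deviation, >= 1 (1 gives degenerate draws
#'   equal to the base). Default `sqrt(2)`: draws rarely exceed two-fold.
#' @param n Number of draws, >= 1.
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @param mean_match `"arithmetic"` (default) or `"geometric"`.
#' @param vary Character vector naming what varies; any subset of
#'   `c("volumes", "flows", "Qc", "Qw", "body_mass")`.
#' @return A `parameter_ensemble`: `draws` (list of physiologies), `n`,
#'   `seed`, `gsd`, `base`.
#' @export
sample_physiology <- function(base, gsd = sqrt(2), n = 1000, seed = 1,
                              mean_match = c("arithmetic", "geometric"),
                              vary = c("volumes", "flows", "Qc", "Qw", "body_mass")) {
  mean_match <- match.arg(mean_match)
  stopifnot(inherits(base, "physiology"))
  if (gsd < 1) stop("gsd must be >= 1", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  sigma <- log(gsd)
  draws <- .with_seed(seed, lapply(seq_len(n), function(i) {
    cmp <- base$compartments
    if ("volumes" %in% vary) cmp$volume_mL <- .lnorm_draw(cmp$volume_mL, sigma, mean_match)
    has_flow <- !is.na(cmp$flow_mL_per_s)
    if ("flows" %in% vary)
      cmp$flow_mL_per_s[has_flow] <- .lnorm_draw(cmp$flow_mL_per_s[has_flow], sigma, mean_match)
    Qc <- base$Qc
    if (!is.na(Qc) && "Qc" %in% vary) Qc <- .lnorm_draw(Qc, sigma, mean_match)
    if (!is.na(Qc) && any(has_flow))  # re-balance: sum of tissue flows = Qc
      cmp$flow_mL_per_s[has_flow] <- cmp$flow_mL_per_s[has_flow] *
        (Qc / sum(cmp$flow_mL_per_s[has_flow]))
    Qw <- if ("Qw" %in% vary) .lnorm_draw(base$Qw, sigma, mean_match) else base$Qw
    bm <- if ("body_mass" %in% vary) .lnorm_draw(base$body_mass_g, sigma, mean_match) else base$body_mass_g
    physiology_parameter_set(base$model_id, cmp, body_mass_g = bm, Qc = Qc,
                             Qw = Qw,
                             assimilation_factor = base$assimilation_factor,
                             provenance = sprintf("draw %d (seed %d, gsd %.4g)", i, seed, gsd))
  }))
  structure(list(draws = draws, n = n, seed = seed, gsd = gsd, base = base),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat(sprintf("<parameter_ensemble> %d draws of %s physiology (gsd = %.4g, seed = %d)\n",
              x$n, x$base$model_id, x$gsd, x$seed))
  invisible(x)
}

#' Ensemble time series under constant exposure
#'
#' Integrates each draw of a physiology ensemble from a clean (all-zero)
#' state under constant exposure and summarizes the per-compartment and
#' whole-body concentrations pointwise (mean and standard deviation across
#' draws). First-order kinetics uses the exact linear propagator; draws whose
#' rate matrix fails to solve are excluded and counted.
#'
#' @param model_id One of the five structure identifiers.
#' @param chem A [chemical_descriptor()].
#' @param c_env Constant water concentration (uM).
#' @param ensemble A [sample_physiology()] ensemble.
#' @param t_grid Strictly increasing output times (s).
#' @return An `ensemble_summary`: `times`, `mean` and `sd` (time by
#'   compartment matrices including a `whole_body` column), `n_used`,
#'   `n_failed`.
#' @export
ensemble_timeseries <- function(model_id, chem, c_env, ensemble, t_grid) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  acc <- list(); n_failed <- 0L
  for (d in ensemble$draws) {
    res <- tryCatch({
      m <- build_model(model_id, d)
      sm <- system_matrices(m, chem)
      conc <- .linear_profile(sm$A, sm$b, c_env, numeric(length(sm$b)), t_grid)
      cbind(conc, whole_body = whole_body(conc, m))
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else acc[[length(acc) + 1L]] <- res
  }
  if (!length(acc)) stop("all ensemble draws failed", call. = FALSE)
  arr <- simplify2array(acc)  # time x comp x draw
  mu <- apply(arr, c(1, 2), mean)
  sd_ <- if (dim(arr)[3] > 1) apply(arr, c(1, 2), stats::sd) else mu * 0
  structure(list(times = t_grid, mean = mu, sd = sd_,
                 n_used = length(acc), n_failed = n_failed,
                 model_id = model_id),
            class = "ensemble_summary")
}

#' One-at-a-time parameter sensitivity scan
#'
#' Multiplies a single named body parameter by each factor in `fold_grid` and
#' reports the first-order steady state. Semantics of the perturbation:
#' `Qw` and `assimilation_factor` scale directly; `Qc` scales cardiac output
#' and all tissue flows proportionally; `body_mass` scales the mass and every
#' compartment volume; `V_<comp>` / `Q_<comp>` scale a single volume or flow
#' (cardiac output is recomputed as the flow sum so the draw stays balanced).
#'
#' @param model_id Structure identifier.
#' @param chem A [chemical_descriptor()].
#' @param c_env Water concentration (uM).
#' @param parameter_name See above.
#' @param fold_grid Positive multiplicative factors.
#' @param physiology Base physiology (default [default_physiology()]).
#' @return Tidy data frame: `fold`, `parameter`, `compartment` (including
#'   `whole_body`), `concentration_uM`, `response_coefficient` (the
#'   exposure-independent ratio `C_ss / C_env`).
#' @export
sensitivity_scan <- function(model_id, chem, c_env, parameter_name, fold_grid,
                             physiology = NULL) {
  if (any(fold_grid <= 0)) stop("folds must be > 0", call. = FALSE)
  base <- physiology %||% default_physiology(
    if (model_id %in% c("6C_collapsed", "6C_rewired")) "6C" else model_id)
  out <- lapply(fold_grid, function(f) {
    phys <- .perturb_physiology(base, parameter_name, f)
    m <- build_model(model_id, phys)
    s <- response_coefficients(m, chem)
    vals <- c(s, whole_body = attr(s, "whole_body"))
    data.frame(fold = f, parameter = parameter_name,
               compartment = names(vals),
               concentration_uM = as.numeric(vals) * c_env,
               response_coefficient = as.numeric(vals))
  })
  do.call(rbind, out)
}

.perturb_physiology <- function(base, parameter_name, fold) {
  cmp <- base$compartments
  Qc <- base$Qc; Qw <- base$Qw; bm <- base$body_mass_g
  af <- base$assimilation_factor
  if (identical(parameter_name, "Qw")) {
    Qw <- Qw * fold
  } else if (identical(parameter_name, "Qc")) {
    if (is.na(Qc)) stop("model has no cardiac output parameter", call. = FALSE)
    Qc <- Qc * fold
    cmp$flow_mL_per_s <- cmp$flow_mL_per_s * fold
  } else if (identical(parameter_name, "body_mass")) {
    bm <- bm * fold
    cmp$volume_mL <- cmp$volume_mL * fold
  } else if (identical(parameter_name, "assimilation_factor")) {
    if (is.null(af))
      stop("assimilation_factor is not a parameter of the ", base$model_id,
           " model", call. = FALSE)
    af <- af * fold
    if (af > 1) stop("perturbed assimilation factor exceeds 1", call. = FALSE)
  } else if (grepl("^V_", parameter_name)) {
    comp <- sub("^V_", "", parameter_name)
    i <- match(comp, cmp$compartment)
    if (is.na(i)) stop("unknown compartment: ", comp, call. = FALSE)
    cmp$volume_mL[i] <- cmp$volume_mL[i] * fold
  } else if (grepl("^Q_", parameter_name)) {
    comp <- sub("^Q_", "", parameter_name)
    i <- match(comp, cmp$compartment)
    if (is.na(i) || is.na(cmp$flow_mL_per_s[i]))
      stop("unknown or flowless compartment: ", comp, call. = FALSE)
    cmp$flow_mL_per_s[i] <- cmp$flow_mL_per_s[i] * fold
    Qc <- sum(cmp$flow_mL_per_s, na.rm = TRUE)  # keep the draw balanced
  } else {
    stop("unknown parameter: ", parameter_name, call. = FALSE)
  }
  physiology_parameter_set(base$model_id, cmp, body_mass_g = bm, Qc = Qc,
                           Qw = Qw, assimilation_factor = af,
                           provenance = sprintf("%s x %.4g", parameter_name, fold))
}
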
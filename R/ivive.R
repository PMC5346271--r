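# IVIVE comparison layer: AC10 -> PEC mapping, exact binomial under-prediction
# tests, PEC/LOEC ratio statistics and model-vs-model prediction-ratio grids.

#' Response fraction at the tangent-based point of departure
#'
#' For a logistic concentration-response curve on the semi-log scale, the
#' tangent at the inflection point (response 1/2, slope 1/4 per log unit)
#' meets the lower asymptote two log-units below the inflection; the logistic
#' response there is `1 / (1 + e^2)`, about 11.9% — the concentration at
#' which activity crosses from the control regime into the power-law regime.
#' This motivates treating an AC10-like concentration as a screening-level
#' point of departure (approximately 12% response).
#'
#' @return The dimensionless fraction `1 / (1 + exp(2))`.
#' @examples
#' round(100 * pod_response_fraction())  # ~12 percent
#' @export
pod_response_fraction <- function() 1 / (1 + exp(2))

#' Reconstruct exposure concentrations for a chemical assay table
#'
#' Treats each chemical's in vitro activity concentration (AC10) as a
#' steady-state internal concentration — whole-body, or a named tissue such
#' as the gonads — and inverts the chosen rTK model for the predicted
#' exposure concentration (PEC).
#'
#' @param model_id Structure identifier.
#' @param records Data frame with columns `name`, `ac10`, `log_kow`, `loec`,
#'   `k_met` (a [generate_chemical_table()] output qualifies).
#' @param observable `"whole_body"` (default) or `"tissue:<name>"`.
#' @param physiology Optional physiology override.
#' @return Data frame: `chemical`, `model`, `observable`, `pec_uM`,
#'   `response_coefficient`, `ac10_uM`, `loec_uM`.
#' @export
reconstruct_exposures <- function(model_id, records, observable = "whole_body",
                                  physiology = NULL) {
  req <- c("name", "ac10", "log_kow", "loec", "k_met")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(records$ac10 <= 0) || any(records$loec <= 0))
    stop("ac10 and loec must be strictly positive", call. = FALSE)
  phys <- physiology %||% default_physiology(
    if (model_id %in% c("6C_collapsed", "6C_rewired")) "6C" else model_id)
  model <- build_model(model_id, phys)
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    chem <- chemical_descriptor(r$name, log_kow = r$log_kow, k_met = r$k_met)
    p <- predict_exposure(model, chem, observable, r$ac10)
    data.frame(chemical = r$name, model = model_id, observable = observable,
               pec_uM = p$pec, response_coefficient = p$response_coefficient,
               ac10_uM = r$ac10, loec_uM = r$loec)
  })
  do.call(rbind, out)
}

#' Exact binomial test for under-prediction of effect thresholds
#'
#' Counts how many predicted exposure concentrations fall below their
#' matched LOECs and tests the count against a fair-coin null with the exact
#' two-sided binomial test (tail enumeration, no normal approximation). Ties
#' (`pec == loec`) count as not-below and are reported.
#'
#' @param pecs,loecs Equal-length positive vectors (uM).
#' @return List: `k` (count below), `n`, `p_two_sided`, `n_ties`.
#' @examples
#' # 21 of 36 predictions below threshold is consistent with chance:
#' binomial_underprediction(rep(c(0.5, 2), c(21, 15)), rep(1, 36))$p_two_sided
#' @export
binomial_underprediction <- function(pecs, loecs) {
  if (length(pecs) != length(loecs))
    stop("pecs and loecs must have equal length", call. = FALSE)
  n <- length(pecs)
  if (n == 0) stop("n = 0: nothing to test", call. = FALSE)
  if (any(pecs <= 0) || any(loecs <= 0))
    stop("pecs and loecs must be strictly positive", call. = FALSE)
  k <- sum(pecs < loecs)
  list(k = k, n = n,
       p_two_sided = stats::binom.test(k, n, p = 0.5)$p.value,
       n_ties = sum(pecs == loecs))
}

#' PEC/LOEC ratio statistics across models
#'
#' For each model's predictions, forms the log10 ratios of predicted exposure
#' concentration to the matched LOEC, then compares models pairwise with
#' two-sample t-tests (Welch by default; the classic pooled test via
#' `var_equal = TRUE`) and returns Gaussian kernel density estimates of the
#' log10 ratios (Silverman-type default bandwidth) plus each model's exact
#' binomial under-prediction summary.
#'
#' @param pecs_by_model Named list of PEC vectors (uM), one per model, each
#'   matched to `loecs`.
#' @param loecs Positive LOEC vector (uM).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param log_ratios Test log10 ratios (default) or raw ratios.
#' @return A `comparison_result`: `ratios` (long data frame of log10
#'   ratios), `binomial` (per-model data frame), `t_tests` (pairwise data
#'   frame), `kde` (named list of `stats::density` objects).
#' @export
ratio_statistics <- function(pecs_by_model, loecs, var_equal = FALSE,
                             log_ratios = TRUE) {
  stopifnot(is.list(pecs_by_model), !is.null(names(pecs_by_model)))
  if (length(loecs) < 2) stop("need at least 2 observations", call. = FALSE)
  models <- names(pecs_by_model)
  rat <- lapply(pecs_by_model, function(p) {
    if (length(p) != length(loecs)) stop("length mismatch", call. = FALSE)
    r <- p / loecs
    if (log_ratios) log10(r) else r
  })
  ratios <- do.call(rbind, lapply(models, function(m)
    data.frame(model = m, chemical_index = seq_along(loecs), ratio = rat[[m]])))
  binom <- do.call(rbind, lapply(models, function(m) {
    b <- binomial_underprediction(pecs_by_model[[m]], loecs)
    data.frame(model = m, k = b$k, n = b$n, p_two_sided = b$p_two_sided,
               n_ties = b$n_ties)
  }))
  pairs <- if (length(models) > 1) utils::combn(models, 2, simplify = FALSE) else list()
  t_tests <- if (length(pairs)) do.call(rbind, lapply(pairs, function(pr) {
    x <- rat[[pr[1]]]; y <- rat[[pr[2]]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate samples: no variance to test against
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      data.frame(model_a = pr[1], model_b = pr[2],
                 statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                 df = NA_real_, p_value = if (eq) 1 else 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(model_a = pr[1], model_b = pr[2],
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
    }
  })) else data.frame()
  kde <- lapply(rat, function(r) stats::density(r, bw = "nrd0"))
  structure(list(ratios = ratios, binomial = binom, t_tests = t_tests,
                 kde = kde, log_ratios = log_ratios),
            class = "comparison_result")
}

#' Model-vs-model prediction-ratio grid
#'
#' For every `(k_met, K_ow)` grid cell, builds both models for a chemical
#' with those properties (hepatic-only clearance), inverts the same observed
#' whole-body concentration through both, and stores
#' `log10(PEC_a / PEC_b)`. Because the inversion is linear, the grid is
#' independent of the observed concentration; this is asserted internally.
#'
#' @param model_a,model_b Structure identifiers.
#' @param log10_kmet_grid,log10_kow_grid Grid axes (default 50 points over
#'   log10 k_met in \[-7, -1\] (1/s) and log10 K_ow in \[0, 8\]).
#' @param c_body Observed whole-body concentration (uM), > 0; default 10.
#' @param physiology_a,physiology_b Optional physiology overrides.
#' @return A `ratio_grid`: `log10_kmet`, `log10_kow`, `log10_ratio` (matrix,
#'   k_met rows by K_ow columns), `model_a`, `model_b`.
#' @export
prediction_ratio_grid <- function(model_a, model_b,
                                  log10_kmet_grid = seq(-7, -1, length.out = 50),
                                  log10_kow_grid = seq(0, 8, length.out = 50),
                                  c_body = 10,
                                  physiology_a = NULL, physiology_b = NULL) {
  if (!all(is.finite(log10_kmet_grid)) || !all(is.finite(log10_kow_grid)))
    stop("grids must be finite", call. = FALSE)
  if (c_body <= 0) stop("c_body must be > 0", call. = FALSE)
  phys_a <- physiology_a %||% default_physiology(
    if (model_a %in% c("6C_collapsed", "6C_rewired")) "6C" else model_a)
  phys_b <- physiology_b %||% default_physiology(
    if (model_b %in% c("6C_collapsed", "6C_rewired")) "6C" else model_b)
  ma <- build_model(model_a, phys_a)  # structures are chemical-independent
  mb <- build_model(model_b, phys_b)
  grid <- matrix(NA_real_, length(log10_kmet_grid), length(log10_kow_grid))
  for (i in seq_along(log10_kmet_grid)) {
    for (j in seq_along(log10_kow_grid)) {
      chem <- chemical_descriptor("grid", log_kow = log10_kow_grid[j],
                                  k_met = 10^log10_kmet_grid[i])
      pa <- predict_exposure(ma, chem, "whole_body", c_body)$pec
      pb <- predict_exposure(mb, chem, "whole_body", c_body)$pec
      grid[i, j] <- log10(pa / pb)
    }
  }
  # linearity check: the ratio must not depend on the observed concentration
  chem0 <- chemical_descriptor("grid", log_kow = log10_kow_grid[1],
                               k_met = 10^log10_kmet_grid[1])
  r1 <- predict_exposure(ma, chem0, "whole_body", 1)$pec /
    predict_exposure(mb, chem0, "whole_body", 1)$pec
  stopifnot(abs(log10(r1) - grid[1, 1]) < 1e-9 * max(1, abs(grid[1, 1])))
  structure(list(log10_kmet = log10_kmet_grid, log10_kow = log10_kow_grid,
                 log10_ratio = grid, model_a = model_a, model_b = model_b,
                 c_body = c_body),
            class = "ratio_grid")
}

#' @export
print.ratio_grid <- function(x, ...) {
  cat(sprintf("<ratio_grid> log10(PEC_%s / PEC_%s): %d x %d cells, range [%.3g, %.3g]\n",
              x$model_a, x$model_b, nrow(x$log10_ratio), ncol(x$log10_ratio),
              min(x$log10_ratio), max(x$log10_ratio)))
  invisible(x)
}
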
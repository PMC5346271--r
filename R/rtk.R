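# Exact steady-state inversion: linear response coefficients and exposure
# reconstruction.

#' Steady-state response coefficients
#'
#' The dimensionless coefficients `s_i = C_i,ss / C_env = (-A^{-1} b)_i`
#' linking each compartment's steady-state concentration to the exposure
#' concentration under first-order kinetics. They are independent of the
#' exposure level; the whole-body coefficient is their volume-weighted mean.
#' With no metabolism or excretion every tissue equilibrates thermodynamically
#' with the water and `s_i = P_i`.
#'
#' @param model A `model_structure` (or model id).
#' @param chem A [chemical_descriptor()].
#' @return Named vector of per-compartment coefficients with attribute
#'   `whole_body`.
#' @export
response_coefficients <- function(model, chem) {
  model <- .as_model(model)
  sm <- system_matrices(model, chem)
  s <- tryCatch(solve(sm$A, -sm$b),
                error = function(e) stop("singular system: ",
                                         conditionMessage(e), call. = FALSE))
  s <- stats::setNames(as.numeric(s), model$compartments)
  attr(s, "whole_body") <- whole_body(s, model)
  s
}

#' Reconstruct the exposure concentration from an internal concentration
#'
#' Exact (non-probabilistic) reverse-toxicokinetic inversion: the predicted
#' exposure concentration (PEC) is the observed concentration divided by the
#' observable's response coefficient.
#'
#' @param model A `model_structure` (or model id).
#' @param chem A [chemical_descriptor()].
#' @param observable `"whole_body"` or `"tissue:<name>"` (a bare compartment
#'   name is also accepted).
#' @param concentration Observed steady-state concentration (uM), >= 0.
#' @return An `exposure_prediction`: `pec` (uM), `model_id`, `observable`,
#'   `response_coefficient`.
#' @examples
#' predict_exposure("1C", preset_chemical("diazinon"), "whole_body", 1.0)
#' @export
predict_exposure <- function(model, chem, observable, concentration) {
  model <- .as_model(model)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  s <- response_coefficients(model, chem)
  s_obs <- if (identical(observable, "whole_body")) {
    attr(s, "whole_body")
  } else {
    comp <- sub("^tissue:", "", observable)
    if (!comp %in% model$compartments)
      stop("observable '", observable, "' not in model ", model$model_id,
           call. = FALSE)
    s[[comp]]
  }
  if (!is.finite(s_obs) || s_obs <= 0)
    stop("ill-posed observable: response coefficient is ", s_obs, call. = FALSE)
  structure(list(pec = concentration / s_obs, model_id = model$model_id,
                 observable = observable, response_coefficient = s_obs),
            class = "exposure_prediction")
}

#' @export
print.exposure_prediction <- function(x, ...) {
  cat(sprintf("<exposure_prediction> %s/%s: PEC = %.6g uM (s = %.6g)\n",
              x$model_id, x$observable, x$pec, x$response_coefficient))
  invisible(x)
}

#' Steady-state differences between structural variants
#'
#' Signed differences of the per-compartment response coefficients
#' `s_i(variant_a) - s_i(variant_b)` for compartments shared by both
#' structures. Being differences of response coefficients they are
#' exposure-independent; multiply by an exposure concentration to obtain
#' concentration differences.
#'
#' @param variant_a,variant_b `model_structure` objects (or model ids).
#' @param chem A [chemical_descriptor()].
#' @param compartments Compartment names to compare; default is the shared
#'   set.
#' @return Named vector of signed coefficient differences.
#' @export
steady_state_difference <- function(variant_a, variant_b, chem,
                                    compartments = NULL) {
  variant_a <- .as_model(variant_a); variant_b <- .as_model(variant_b)
  shared <- intersect(variant_a$compartments, variant_b$compartments)
  compartments <- compartments %||% shared
  if (!all(compartments %in% shared))
    stop("compartments not shared by both variants: ",
         paste(setdiff(compartments, shared), collapse = ", "), call. = FALSE)
  s_a <- response_coefficients(variant_a, chem)
  s_b <- response_coefficients(variant_b, chem)
  s_a[compartments] - s_b[compartments]
}
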
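# Shared fixtures and generators for the test suite.

all_structures <- c("7C", "6C", "1C", "6C_collapsed", "6C_rewired")

base_physiology <- function(model_id) {
  default_physiology(if (grepl("^6C_", model_id)) "6C" else model_id)
}

build_default <- function(model_id) {
  build_model(model_id, base_physiology(model_id))
}

# Random chemical with hepatic-only clearance (the rTK parameterization).
random_chemical <- function(k_exc = 0) {
  chemical_descriptor(
    name = "rand",
    log_kow = stats::runif(1, 0, 6),
    k_met = 10^stats::runif(1, -7, -2),
    k_exc = k_exc)
}

# Random strictly positive 6C physiology (log-uniform around the default).
random_6c_physiology <- function() {
  base <- default_physiology("6C")
  cmp <- base$compartments
  cmp$volume_mL <- cmp$volume_mL * 10^stats::runif(nrow(cmp), -0.5, 0.5)
  has_flow <- !is.na(cmp$flow_mL_per_s)
  cmp$flow_mL_per_s[has_flow] <-
    cmp$flow_mL_per_s[has_flow] * 10^stats::runif(sum(has_flow), -0.5, 0.5)
  physiology_parameter_set(
    "6C", cmp, body_mass_g = base$body_mass_g,
    Qc = sum(cmp$flow_mL_per_s[has_flow]),
    Qw = base$Qw * 10^stats::runif(1, -0.5, 0.5),
    provenance = "random test draw")
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  scale <- pmax(abs(expected), .Machine$double.xmin)
  expect_lt(max(abs(actual - expected) / scale), rel_tol)
}
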
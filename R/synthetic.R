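# Synthetic chemical assay tables: a reproducible stand-in emulating the
# structure of a high-throughput estrogenic-activity dataset (per-chemical
# AC10, lipophilicity, clearance) matched to whole-organism LOECs.

#' Specification for a synthetic chemical assay table
#'
#' Defaults emulate a cohort of 36 endocrine-active chemicals: AC10s
#' log-uniform over four orders of magnitude, lipophilicities uniform over a
#' typical screening range, hepatic clearances log-uniform, and LOECs loosely
#' correlated with the AC10s through a log-normal offset
#' `loec = ac10 * 10^eta`, `eta ~ N(mu_offset, sigma_offset)` (defaults 1
#' and 1: LOECs typically an order of magnitude above the AC10s, scattered
#' over roughly two more).
#'
#' @param n_chemicals Number of chemicals (default 36).
#' @param ac10_range AC10 range (uM), log-uniform.
#' @param log_kow_range log10 Kow range, uniform.
#' @param k_met_range Hepatic clearance range (1/s), log-uniform.
#' @param loec_mu_offset,loec_sigma_offset Offset model parameters (log10
#'   units).
#' @param seed Integer seed.
#' @return A `synthetic_table_spec` list.
#' @export
synthetic_table_spec <- function(n_chemicals = 36,
                                 ac10_range = c(1e-3, 10),
                                 log_kow_range = c(0.5, 6),
                                 k_met_range = c(1e-6, 1e-3),
                                 loec_mu_offset = 1, loec_sigma_offset = 1,
                                 seed = 1) {
  if (n_chemicals < 1) stop("n_chemicals must be >= 1", call. = FALSE)
  for (rng in list(ac10_range, k_met_range)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2])
      stop("ranges must be positive and ordered", call. = FALSE)
  }
  if (length(log_kow_range) != 2 || log_kow_range[1] > log_kow_range[2])
    stop("log_kow_range must be ordered", call. = FALSE)
  if (loec_sigma_offset < 0) stop("loec_sigma_offset must be >= 0", call. = FALSE)
  structure(list(n_chemicals = n_chemicals, ac10_range = ac10_range,
                 log_kow_range = log_kow_range, k_met_range = k_met_range,
                 loec_mu_offset = loec_mu_offset,
                 loec_sigma_offset = loec_sigma_offset, seed = seed),
            class = "synthetic_table_spec")
}

#' Generate a synthetic chemical assay table
#'
#' @param spec A [synthetic_table_spec()].
#' @return Data frame with columns `name`, `ac10` (uM), `log_kow`, `loec`
#'   (uM), `k_met` (1/s); reproducible for a fixed seed, all concentrations
#'   strictly positive.
#' @examples
#' tab <- generate_chemical_table(synthetic_table_spec(seed = 42))
#' nrow(tab)
#' @export
generate_chemical_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_table_spec"))
  n <- spec$n_chemicals
  .with_seed(spec$seed, {
    ac10 <- 10^stats::runif(n, log10(spec$ac10_range[1]), log10(spec$ac10_range[2]))
    log_kow <- stats::runif(n, spec$log_kow_range[1], spec$log_kow_range[2])
    k_met <- 10^stats::runif(n, log10(spec$k_met_range[1]), log10(spec$k_met_range[2]))
    eta <- stats::rnorm(n, spec$loec_mu_offset, spec$loec_sigma_offset)
    data.frame(name = sprintf("chem_%03d", seq_len(n)),
               ac10 = ac10, log_kow = log_kow,
               loec = ac10 * 10^eta, k_met = k_met)
  })
}
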
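#' Chemical descriptor
#'
#' Bundles the chemical-dependent inputs of the PBTK/rTK models: lipophilicity
#' (log10 octanol-water partition ratio), the first-order hepatic
#' metabolism/excretion rate `k_met`, an optional distributed excretion rate
#' `k_exc` acting in the six-compartment model's "other" tissue, optional
#' Michaelis parameters for saturable clearance, and optional assay anchors
#' (AC10, LOEC). `kd_plasma` is carried for completeness but inert under the
#' default assumption that blood does not accumulate chemical.
#'
#' @param name Chemical name.
#' @param log_kow log10 octanol-water partition ratio (dimensionless).
#' @param k_met First-order hepatic metabolism/excretion rate (1/s).
#' @param k_exc First-order excretion rate for the 6C "other" compartment (1/s).
#' @param vmax Optional Michaelis maximal clearance rate (uM/s).
#' @param km Optional Michaelis constant (uM); required with `vmax`.
#' @param kd_plasma Optional plasma-protein dissociation constant (uM); unused
#'   under the no-blood-accumulation assumption.
#' @param ac10 Optional in vitro activity concentration (uM).
#' @param loec Optional whole-organism lowest observed effect concentration (uM).
#' @return An object of class `chemical_descriptor`.
#' @examples
#' chemical_descriptor("diazinon", log_kow = 3.81, k_met = 1e-4)
#' @export
chemical_descriptor <- function(name, log_kow, k_met = 0, k_exc = 0,
                                vmax = NULL, km = NULL, kd_plasma = NULL,
                                ac10 = NULL, loec = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_scalar(log_kow, "log_kow")
  .check_scalar(k_met, "k_met")
  .check_scalar(k_exc, "k_exc")
  if (k_met < 0) stop("k_met must be >= 0", call. = FALSE)
  if (k_exc < 0) stop("k_exc must be >= 0", call. = FALSE)
  if (!is.null(vmax) || !is.null(km)) {
    if (is.null(vmax) || is.null(km))
      stop("Michaelis kinetics needs both vmax and km", call. = FALSE)
    .check_scalar(vmax, "vmax"); .check_scalar(km, "km")
    if (vmax < 0) stop("vmax must be >= 0", call. = FALSE)
    if (km <= 0) stop("km must be > 0", call. = FALSE)
  }
  for (nm in c("kd_plasma", "ac10", "loec")) {
    v <- get(nm)
    if (!is.null(v)) {
      .check_scalar(v, nm)
      if (v <= 0) stop(nm, " must be > 0 when set", call. = FALSE)
    }
  }
  structure(
    list(name = name, log_kow = log_kow, k_met = k_met, k_exc = k_exc,
         vmax = vmax, km = km, kd_plasma = kd_plasma, ac10 = ac10, loec = loec),
    class = "chemical_descriptor")
}

.check_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a finite numeric scalar", call. = FALSE)
  invisible(x)
}

#' @export
print.chemical_descriptor <- function(x, ...) {
  cat(sprintf("<chemical_descriptor> %s: log Kow = %.3g, k_met = %.3g /s, k_exc = %.3g /s\n",
              x$name, x$log_kow, x$k_met, x$k_exc))
  if (!is.null(x$vmax))
    cat(sprintf("  Michaelis: vmax = %.3g uM/s, km = %.3g uM\n", x$vmax, x$km))
  if (!is.null(x$ac10)) cat(sprintf("  AC10 = %.3g uM\n", x$ac10))
  if (!is.null(x$loec)) cat(sprintf("  LOEC = %.3g uM\n", x$loec))
  invisible(x)
}

#' Preset chemicals used in the worked comparisons
#'
#' Two reference chemicals spanning a lipophilicity contrast: diazinon
#' (log Kow = 3.81) and 1,2-dichloroethane (log Kow = 1.48). The default
#' metabolism/excretion rate `k_met = 1e-4` per second is an assumed mid-range
#' hepatic clearance (the midpoint of the default log10 k_met grid, flagged
#' as such rather than measured), identical for both presets so that
#' comparisons between them isolate the effect of lipophilicity.
#'
#' @param name One of `"diazinon"`, `"dichloroethane_12"`.
#' @return A [chemical_descriptor()].
#' @examples
#' preset_chemical("diazinon")$log_kow
#' @export
preset_chemical <- function(name) {
  presets <- list(
    diazinon          = list(log_kow = 3.81, k_met = 1e-4),
    dichloroethane_12 = list(log_kow = 1.48, k_met = 1e-4))
  if (!name %in% names(presets))
    stop("unknown preset chemical: ", name, call. = FALSE)
  p <- presets[[name]]
  chemical_descriptor(name, log_kow = p$log_kow, k_met = p$k_met, k_exc = 0)
}

#' Read / write chemical descriptor tables
#'
#' CSV schema: `name, log_kow, k_met_per_s, k_exc_per_s, vmax_uM_per_s, km_uM,
#' ac10_uM, loec_uM` (optional columns may be absent or NA).
#'
#' @param path CSV file path.
#' @return `read_chemicals()`: a list of [chemical_descriptor()] objects.
#' @export
read_chemicals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "log_kow")
  if (!all(req %in% names(df)))
    stop("chemical CSV must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  get_opt <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- row[[col]]
    if (is.na(v)) NULL else v
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    chemical_descriptor(
      name = row$name, log_kow = row$log_kow,
      k_met = if ("k_met_per_s" %in% names(df) && !is.na(row$k_met_per_s)) row$k_met_per_s else 0,
      k_exc = if ("k_exc_per_s" %in% names(df) && !is.na(row$k_exc_per_s)) row$k_exc_per_s else 0,
      vmax = get_opt(row, "vmax_uM_per_s"), km = get_opt(row, "km_uM"),
      ac10 = get_opt(row, "ac10_uM"), loec = get_opt(row, "loec_uM"))
  })
}

#' @rdname read_chemicals
#' @param chems List of [chemical_descriptor()] objects.
#' @return `write_chemicals()`: the path, invisibly.
#' @export
write_chemicals <- function(chems, path) {
  df <- do.call(rbind, lapply(chems, function(ch) {
    data.frame(name = ch$name, log_kow = ch$log_kow,
               k_met_per_s = ch$k_met, k_exc_per_s = ch$k_exc,
               vmax_uM_per_s = ch$vmax %||% NA_real_, km_uM = ch$km %||% NA_real_,
               ac10_uM = ch$ac10 %||% NA_real_, loec_uM = ch$loec %||% NA_real_)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
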
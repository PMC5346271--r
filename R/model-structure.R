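#' Lipid/water tissue-water partition coefficient
#'
#' Linear mixing rule `P = f_lipid * 10^log_kow + f_water`, using the
#' octanol-water ratio as a surrogate for the tissue lipid phase. Blood
#' compartments are parameterized with `f_lipid = 0, f_water = 1`, giving
#' `P = 1` (no accumulation in blood).
#'
#' @param chem A [chemical_descriptor()].
#' @param f_lipid,f_water Volume fractions in \[0, 1\].
#' @return Dimensionless tissue:water partition ratio (vectorized over the
#'   fraction arguments).
#' @examples
#' partition_coefficient(preset_chemical("diazinon"), f_lipid = 0.05, f_water = 0.8)
#' @export
partition_coefficient <- function(chem, f_lipid, f_water) {
  stopifnot(inherits(chem, "chemical_descriptor"))
  if (any(f_lipid < 0) || any(f_water < 0))
    stop("lipid/water fractions must be non-negative", call. = FALSE)
  if (any(f_lipid > 1) || any(f_water > 1) || any(f_lipid + f_water > 1 + 1e-12))
    stop("lipid/water fractions must lie in [0, 1] with f_lipid + f_water <= 1",
         call. = FALSE)
  f_lipid * 10^chem$log_kow + f_water
}

.known_models <- c("7C", "6C", "1C", "6C_collapsed", "6C_rewired")

#' Build a PBTK model structure
#'
#' Assembles a compartment graph for one of the five supported architectures:
#' \describe{
#'   \item{7C}{arterial/venous blood, brain, gonads, liver, poorly (ppt) and
#'     richly (rpt) perfused tissues. Gonad and rpt effluents drain into the
#'     liver; brain, liver and ppt effluents enter the venous blood. The liver
#'     is the sole metabolizing compartment. The gill interface carries the
#'     assimilation factor.}
#'   \item{6C}{arterial/venous blood, brain, gonads, liver and "other"
#'     tissues, all draining to the venous blood; the liver metabolizes
#'     (`k_met`) and the "other" tissue excretes (`k_exc`).}
#'   \item{1C}{a single well-mixed body compartment exchanging with the water
#'     at the respiratory flow; metabolism acts on the whole body.}
#'   \item{6C_collapsed / 6C_rewired}{structural variants derived from a 6C
#'     structure via [collapse_gonads_other()] / [rewire_gonads_to_liver()].}
#' }
#' Gill exchange is modeled as an instantaneous-equilibrium interface on the
#' venous-to-arterial pass: an effective water-equilibrating flow
#' `Q_ex = phi * min(Qw, Qc)` (with `phi` the assimilation factor, 1 unless
#' 7C) takes up `Q_ex * C_env` and eliminates `Q_ex * C_venous`, so uptake can
#' never exceed what the respiratory water delivers. The 1C model exchanges
#' directly at `Qw` against its free (water-phase) concentration.
#'
#' @param model_id One of `"7C"`, `"6C"`, `"1C"`, `"6C_collapsed"`,
#'   `"6C_rewired"`.
#' @param physiology A [physiology_parameter_set()] consistent with
#'   `model_id` (the variants accept 6C physiology).
#' @param composition Optional data frame (`compartment`, `f_lipid`,
#'   `f_water`) overriding the composition columns of `physiology`.
#' @return An object of class `model_structure` with fields `model_id`,
#'   `compartments`, `volumes`, `composition`, `edges` (directed blood-flow
#'   edges with flows in mL/s), `gill_exchange`, `metabolizing`, `excreting`.
#' @export
build_model <- function(model_id, physiology, composition = NULL) {
  if (!model_id %in% .known_models)
    stop("unknown model_id: ", model_id, call. = FALSE)
  if (model_id %in% c("6C_collapsed", "6C_rewired")) {
    base <- build_model("6C", physiology, composition)
    return(if (model_id == "6C_collapsed") collapse_gonads_other(base)
           else rewire_gonads_to_liver(base))
  }
  validate_physiology(physiology)
  cmp <- physiology$compartments
  if (!is.null(composition)) {
    idx <- match(cmp$compartment, composition$compartment)
    if (anyNA(idx)) stop("composition table must cover every compartment", call. = FALSE)
    cmp$f_lipid <- composition$f_lipid[idx]
    cmp$f_water <- composition$f_water[idx]
  }

  expected <- switch(model_id,
    "7C" = c("arterial", "venous", "brain", "gonads", "liver", "ppt", "rpt"),
    "6C" = c("arterial", "venous", "brain", "gonads", "liver", "other"),
    "1C" = "body")
  if (!setequal(cmp$compartment, expected))
    stop("physiology compartments do not match ", model_id, " (expected: ",
         paste(expected, collapse = ", "), ")", call. = FALSE)
  cmp <- cmp[match(expected, cmp$compartment), ]

  if (identical(model_id, "7C") && is.null(physiology$assimilation_factor))
    stop("the 7C model requires an assimilation factor", call. = FALSE)

  vol <- stats::setNames(cmp$volume_mL, cmp$compartment)
  q <- stats::setNames(cmp$flow_mL_per_s, cmp$compartment)
  Qc <- physiology$Qc

  if (identical(model_id, "1C")) {
    structure(list(
      model_id = "1C", compartments = "body", volumes = vol,
      composition = cmp[, c("compartment", "f_lipid", "f_water")],
      edges = data.frame(from = character(), to = character(),
                         flow_mL_per_s = numeric()),
      gill_exchange = list(uptake_into = "body", eliminate_from = "body",
                           q_ex = physiology$Qw, phi = 1,
                           Qw = physiology$Qw, free_phase = TRUE),
      metabolizing = "body", excreting = character(),
      Qc = NA_real_, physiology = physiology),
      class = "model_structure") -> m
    return(validate_structure(m))
  }

  phi <- physiology$assimilation_factor %||% 1
  tissues <- setdiff(expected, c("arterial", "venous"))
  edges <- data.frame(from = "arterial", to = tissues,
                      flow_mL_per_s = unname(q[tissues]))
  if (identical(model_id, "7C")) {
    to_liver <- c("gonads", "rpt")
    to_ven <- setdiff(tissues, c(to_liver, "liver"))
    edges <- rbind(
      edges,
      data.frame(from = to_liver, to = "liver", flow_mL_per_s = unname(q[to_liver])),
      data.frame(from = to_ven, to = "venous", flow_mL_per_s = unname(q[to_ven])),
      data.frame(from = "liver", to = "venous",
                 flow_mL_per_s = unname(q["liver"] + sum(q[to_liver]))))
    metabolizing <- "liver"; excreting <- character()
  } else {
    edges <- rbind(edges,
                   data.frame(from = tissues, to = "venous",
                              flow_mL_per_s = unname(q[tissues])))
    metabolizing <- "liver"; excreting <- "other"
  }
  edges <- rbind(edges, data.frame(from = "venous", to = "arterial",
                                   flow_mL_per_s = Qc))
  m <- structure(list(
    model_id = model_id, compartments = expected, volumes = vol,
    composition = cmp[, c("compartment", "f_lipid", "f_water")],
    edges = edges,
    gill_exchange = list(uptake_into = "arterial", eliminate_from = "venous",
                         q_ex = phi * min(physiology$Qw, Qc), phi = phi,
                         Qw = physiology$Qw, free_phase = FALSE),
    metabolizing = metabolizing, excreting = excreting,
    Qc = Qc, physiology = physiology),
    class = "model_structure")
  validate_structure(m)
}

#' Validate a model structure
#'
#' Asserts exact flow conservation at every node (inflow equals outflow), a
#' single gill-exchange interface, and reachability of every compartment from
#' the environment.
#'
#' @param model A `model_structure`.
#' @return `model`, invisibly (returned visibly for chaining convenience).
#' @export
validate_structure <- function(model) {
  stopifnot(inherits(model, "model_structure"))
  e <- model$edges
  for (cn in model$compartments) {
    inflow <- sum(e$flow_mL_per_s[e$to == cn]) +
      if (identical(model$gill_exchange$uptake_into, cn) &&
          model$gill_exchange$free_phase) model$gill_exchange$q_ex else 0
    outflow <- sum(e$flow_mL_per_s[e$from == cn]) +
      if (identical(model$gill_exchange$eliminate_from, cn) &&
          model$gill_exchange$free_phase) model$gill_exchange$q_ex else 0
    if (nrow(e) > 0 || model$gill_exchange$free_phase) {
      tol <- 1e-12 * max(inflow, outflow, 1e-300)
      if (abs(inflow - outflow) > tol)
        stop("flow balance violated at compartment '", cn, "' (in ", inflow,
             " vs out ", outflow, ")", call. = FALSE)
    }
  }
  # reachability from the environment through the gill interface
  reach <- model$gill_exchange$uptake_into
  repeat {
    nxt <- unique(c(reach, e$to[e$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!all(model$compartments %in% reach))
    stop("compartments unreachable from the environment: ",
         paste(setdiff(model$compartments, reach), collapse = ", "), call. = FALSE)
  model
}

#' @export
print.model_structure <- function(x, ...) {
  cat(sprintf("<model_structure> %s: %d compartments (%s)\n", x$model_id,
              length(x$compartments), paste(x$compartments, collapse = ", ")))
  cat(sprintf("  gill: uptake -> %s, elimination <- %s, Q_ex = %.3g mL/s (phi = %.3g)\n",
              x$gill_exchange$uptake_into, x$gill_exchange$eliminate_from,
              x$gill_exchange$q_ex, x$gill_exchange$phi))
  cat(sprintf("  metabolizing: %s; excreting: %s\n",
              paste(x$metabolizing, collapse = ", "),
              if (length(x$excreting)) paste(x$excreting, collapse = ", ") else "-"))
  invisible(x)
}

#' Collapse the gonads and "other" compartments of a 6C model
#'
#' Merges gonads and "other" into a single "other" compartment whose volume
#' and arterial inflow are the sums of the originals and whose composition is
#' the volume-weighted mixture; everything else is unchanged (the merged
#' compartment keeps the excretory assignment). Total body volume and cardiac
#' output are preserved.
#'
#' @param model A 6C `model_structure`.
#' @return A `model_structure` with `model_id = "6C_collapsed"`.
#' @export
collapse_gonads_other <- function(model) {
  stopifnot(inherits(model, "model_structure"))
  if (!identical(model$model_id, "6C"))
    stop("collapse_gonads_other() requires a 6C model, got ", model$model_id,
         call. = FALSE)
  vol <- model$volumes
  v_new <- vol[["gonads"]] + vol[["other"]]
  comp <- model$composition
  w <- vol[c("gonads", "other")]
  mix <- function(col) sum(w * comp[[col]][match(c("gonads", "other"), comp$compartment)]) / sum(w)
  keep <- setdiff(model$compartments, "gonads")
  volumes <- vol[keep]; volumes[["other"]] <- v_new
  composition <- comp[comp$compartment %in% keep, ]
  composition$f_lipid[composition$compartment == "other"] <- mix("f_lipid")
  composition$f_water[composition$compartment == "other"] <- mix("f_water")

  e <- model$edges
  q_g <- e$flow_mL_per_s[e$from == "arterial" & e$to == "gonads"]
  e <- e[!(e$from == "gonads" | e$to == "gonads"), ]
  e$flow_mL_per_s[e$from == "arterial" & e$to == "other"] <-
    e$flow_mL_per_s[e$from == "arterial" & e$to == "other"] + q_g
  e$flow_mL_per_s[e$from == "other" & e$to == "venous"] <-
    e$flow_mL_per_s[e$from == "other" & e$to == "venous"] + q_g

  out <- model
  out$model_id <- "6C_collapsed"
  out$compartments <- keep
  out$volumes <- volumes
  out$composition <- composition
  out$edges <- e
  validate_structure(out)
}

#' Rewire the 6C gonads to drain into the liver
#'
#' Redirects the gonads' effluent from the venous blood to the liver (the
#' routing used by the 7C architecture); all flow magnitudes are preserved
#' and the liver's venous outflow grows by the gonadal flow, keeping flow
#' conservation exact at every node.
#'
#' @param model A 6C `model_structure`.
#' @return A `model_structure` with `model_id = "6C_rewired"`.
#' @export
rewire_gonads_to_liver <- function(model) {
  stopifnot(inherits(model, "model_structure"))
  if (!identical(model$model_id, "6C"))
    stop("rewire_gonads_to_liver() requires a 6C model, got ", model$model_id,
         call. = FALSE)
  e <- model$edges
  i <- which(e$from == "gonads" & e$to == "venous")
  if (length(i) != 1L) stop("gonads -> venous edge not found", call. = FALSE)
  q_g <- e$flow_mL_per_s[i]
  e$to[i] <- "liver"
  j <- which(e$from == "liver" & e$to == "venous")
  e$flow_mL_per_s[j] <- e$flow_mL_per_s[j] + q_g
  out <- model
  out$model_id <- "6C_rewired"
  out$edges <- e
  validate_structure(out)
}

# Resolve a model argument that may be an id string or a built structure.
.as_model <- function(model, physiology = NULL, composition = NULL) {
  if (inherits(model, "model_structure")) return(model)
  if (is.character(model) && length(model) == 1L) {
    phys <- physiology %||% default_physiology(
      if (model %in% c("6C_collapsed", "6C_rewired")) "6C" else model)
    return(build_model(model, phys, composition))
  }
  stop("model must be a model_structure or a model id string", call. = FALSE)
}

# Per-compartment partition coefficients for a chemical (named vector).
.partitions <- function(model, chem) {
  comp <- model$composition
  stats::setNames(partition_coefficient(chem, comp$f_lipid, comp$f_water),
                  comp$compartment)[model$compartments]
}
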
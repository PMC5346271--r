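# ODE right-hand sides, system matrices, stiff integration and steady states.

# Assemble the linear circulation operator: A0 (flows, gill exchange and the
# always-first-order excretion sink), uptake vector b, and the metabolizing
# compartment indices. dC/dt = A0 C + b C_env - (metabolic loss).
.assemble <- function(model, chem) {
  n <- length(model$compartments)
  V <- model$volumes[model$compartments]
  P <- .partitions(model, chem)
  A <- matrix(0, n, n, dimnames = list(model$compartments, model$compartments))
  b <- stats::setNames(numeric(n), model$compartments)
  g <- model$gill_exchange
  e <- model$edges
  for (k in seq_len(nrow(e))) {
    f <- e$from[k]; t <- e$to[k]; q <- e$flow_mL_per_s[k]
    is_gill <- !g$free_phase && identical(f, g$eliminate_from) &&
      identical(t, g$uptake_into)
    A[f, f] <- A[f, f] - q / (V[[f]] * P[[f]])
    qin <- if (is_gill) q - g$q_ex else q
    A[t, f] <- A[t, f] + qin / (V[[t]] * P[[f]])
    if (is_gill) b[[t]] <- b[[t]] + g$q_ex / V[[t]]
  }
  if (g$free_phase) {
    cn <- g$uptake_into
    A[cn, cn] <- A[cn, cn] - g$q_ex / (V[[cn]] * P[[cn]])
    b[[cn]] <- b[[cn]] + g$q_ex / V[[cn]]
  }
  for (cn in model$excreting) A[cn, cn] <- A[cn, cn] - chem$k_exc
  list(A0 = A, b = b, met = match(model$metabolizing, model$compartments),
       V = V, P = P)
}

#' Linear system matrices of a PBTK model
#'
#' Returns the rate matrix `A` (1/s) and uptake vector `b` (1/s) such that
#' `dC/dt = A C + b C_env` under first-order kinetics. Michaelis kinetics is
#' nonlinear and cannot be expressed this way.
#'
#' @param model A `model_structure` (or model id, built with default
#'   physiology).
#' @param chem A [chemical_descriptor()].
#' @param kinetics `"first_order"` (the only admissible value here).
#' @return List with `A` (matrix) and `b` (named vector).
#' @export
system_matrices <- function(model, chem, kinetics = "first_order") {
  if (!identical(kinetics, "first_order"))
    stop("Michaelis kinetics is nonlinear and has no (A, b) representation",
         call. = FALSE)
  model <- .as_model(model)
  parts <- .assemble(model, chem)
  A <- parts$A0
  for (i in parts$met) A[i, i] <- A[i, i] - chem$k_met
  list(A = A, b = parts$b)
}

# Internal unvalidated right-hand side, written as explicit flux bookkeeping
# (independently of the matrix assembly, which tests cross-check against it).
.dstate <- function(model, chem, state, c_env, kinetics, parts = NULL) {
  V <- model$volumes[model$compartments]
  P <- if (is.null(parts)) .partitions(model, chem) else parts$P
  g <- model$gill_exchange
  flux <- stats::setNames(numeric(length(state)), model$compartments)
  e <- model$edges
  eff <- state / P  # effluent (blood-side) concentration leaving each compartment
  for (k in seq_len(nrow(e))) {
    f <- e$from[k]; t <- e$to[k]; q <- e$flow_mL_per_s[k]
    is_gill <- !g$free_phase && identical(f, g$eliminate_from) &&
      identical(t, g$uptake_into)
    flux[[f]] <- flux[[f]] - q * eff[[f]]
    flux[[t]] <- flux[[t]] + (if (is_gill) (q - g$q_ex) else q) * eff[[f]]
    if (is_gill) flux[[t]] <- flux[[t]] + g$q_ex * c_env
  }
  if (g$free_phase) {
    cn <- g$uptake_into
    flux[[cn]] <- flux[[cn]] + g$q_ex * (c_env - eff[[cn]])
  }
  for (cn in model$excreting)
    flux[[cn]] <- flux[[cn]] - chem$k_exc * V[[cn]] * state[[cn]]
  for (cn in model$metabolizing) {
    loss <- if (identical(kinetics, "michaelis")) {
      c_pos <- max(state[[cn]], 0)
      V[[cn]] * chem$vmax * c_pos / (chem$km + c_pos)
    } else {
      V[[cn]] * chem$k_met * state[[cn]]
    }
    flux[[cn]] <- flux[[cn]] - loss
  }
  flux / V
}

#' Time derivatives of the compartment concentrations
#'
#' Explicit flux-bookkeeping right-hand side of the model ODEs: flow-limited
#' tissue exchange `Q_i (C_arterial - C_i / P_i)`, gill uptake/elimination,
#' and first-order or Michaelis metabolic/excretory loss. The volume-weighted
#' sum of the returned rates equals gill uptake minus gill elimination minus
#' total sink loss (whole-body mass balance).
#'
#' @param model A `model_structure` (or model id).
#' @param chem A [chemical_descriptor()].
#' @param state Named or ordered per-compartment concentrations (uM),
#'   non-negative.
#' @param c_env Environmental water concentration (uM), non-negative.
#' @param kinetics `"first_order"` or `"michaelis"`.
#' @return Per-compartment d(concentration)/dt (uM/s).
#' @export
derivatives <- function(model, chem, state, c_env,
                        kinetics = c("first_order", "michaelis")) {
  kinetics <- match.arg(kinetics)
  model <- .as_model(model)
  if (length(state) != length(model$compartments))
    stop("state length does not match the model's compartments", call. = FALSE)
  if (any(state < 0)) stop("state entries must be non-negative", call. = FALSE)
  if (c_env < 0) stop("c_env must be non-negative", call. = FALSE)
  if (identical(kinetics, "michaelis") && (is.null(chem$vmax) || is.null(chem$km)))
    stop("michaelis kinetics requested without vmax/km", call. = FALSE)
  if (!is.null(names(state))) state <- state[model$compartments]
  state <- stats::setNames(as.numeric(state), model$compartments)
  .dstate(model, chem, state, c_env, kinetics)
}

# Log-spaced output grid covering [t0, t1] with >= ppd points per decade.
.log_grid <- function(t0, t1, ppd = 200) {
  lo <- max(t0, t1 * 1e-8, 1e-3)
  n_dec <- log10(t1) - log10(lo)
  pts <- 10^seq(log10(lo), log10(t1), length.out = max(2L, ceiling(ppd * n_dec) + 1L))
  unique(sort(c(t0, pts, t1)))
}

#' Integrate a PBTK model over time
#'
#' Stiff-capable numerical integration (deSolve's `lsoda`, switching to BDF
#' where the system is stiff) with tight tolerances (default relative 1e-8,
#' absolute 1e-12) and dense log-spaced output suited to half-life
#' interpolation over dynamics spanning many decades of time.
#'
#' @param model A `model_structure` (or model id).
#' @param chem A [chemical_descriptor()].
#' @param exposure Constant exposure (uM scalar) or a piecewise-constant
#'   non-negative function of time returning uM.
#' @param t_span Two positive times (s), `t_span[1] < t_span[2]`
#'   (`t_span[1] = 0` allowed).
#' @param initial_state Initial concentrations (uM); default all-zero.
#' @param kinetics `"first_order"` or `"michaelis"`.
#' @param rtol,atol Solver tolerances.
#' @param points_per_decade Output density on the log-time grid.
#' @param method deSolve method (default `"lsoda"`).
#' @return A `concentration_profile`: `times` (s), `concentrations`
#'   (time-by-compartment matrix, uM), `exposure_trace` (uM), `model_id`.
#' @export
integrate_model <- function(model, chem, exposure, t_span,
                            initial_state = NULL,
                            kinetics = c("first_order", "michaelis"),
                            rtol = 1e-8, atol = 1e-12,
                            points_per_decade = 200, method = "lsoda") {
  kinetics <- match.arg(kinetics)
  model <- .as_model(model)
  stopifnot(length(t_span) == 2L, t_span[1] >= 0, t_span[2] > t_span[1])
  exp_fn <- if (is.function(exposure)) exposure else function(t) exposure
  n <- length(model$compartments)
  y0 <- if (is.null(initial_state)) numeric(n) else {
    stopifnot(length(initial_state) == n)
    if (!is.null(names(initial_state))) initial_state <- initial_state[model$compartments]
    as.numeric(initial_state)
  }
  if (identical(kinetics, "michaelis") && (is.null(chem$vmax) || is.null(chem$km)))
    stop("michaelis kinetics requested without vmax/km", call. = FALSE)
  times <- .log_grid(t_span[1], t_span[2], points_per_decade)
  e_trace <- vapply(times, exp_fn, numeric(1))
  if (any(e_trace < 0)) stop("exposure must be non-negative", call. = FALSE)

  parts <- .assemble(model, chem)
  if (identical(kinetics, "first_order")) {
    A <- parts$A0
    for (i in parts$met) A[i, i] <- A[i, i] - chem$k_met
    rhs <- function(t, y, p) list(as.numeric(A %*% y + parts$b * exp_fn(t)))
  } else {
    A0 <- parts$A0; b <- parts$b; met <- parts$met
    Vm <- parts$V[met]
    rhs <- function(t, y, p) {
      dy <- as.numeric(A0 %*% y + b * exp_fn(t))
      cp <- pmax(y[met], 0)
      dy[met] <- dy[met] - chem$vmax * cp / (chem$km + cp) # uM/s in-compartment
      list(dy)
    }
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 1e5)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to converge", call. = FALSE)
  conc <- unname(sol[, -1, drop = FALSE])
  colnames(conc) <- model$compartments
  structure(list(times = times, concentrations = conc,
                 exposure_trace = e_trace, model_id = model$model_id,
                 kinetics = kinetics, volumes = model$volumes),
            class = "concentration_profile")
}

# Exact solution of dC/dt = A C + b c_env from y0, evaluated at `times`,
# via the eigendecomposition of A (first-order kinetics only).
.linear_profile <- function(A, b, c_env, y0, times) {
  ss <- solve(A, -b * c_env)
  eg <- eigen(A)
  if (any(Re(eg$values) >= 0))
    stop("rate matrix is not strictly stable", call. = FALSE)
  w <- solve(eg$vectors, y0 - ss)
  out <- vapply(times, function(t)
    as.numeric(Re(eg$vectors %*% (exp(eg$values * t) * w))) + as.numeric(ss),
    numeric(length(y0)))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(y0))
  conc <- t(out)
  colnames(conc) <- names(b)
  conc
}

#' Steady state of a PBTK model under constant exposure
#'
#' Either the exact linear solve `C_ss = -A^{-1} b C_env` (first-order
#' kinetics) or integration until the maximum relative change of every
#' compartment over a sliding window of one simulated hour falls below 1e-8
#' (required for Michaelis kinetics; an explicit, reproducible criterion).
#'
#' @param model A `model_structure` (or model id).
#' @param chem A [chemical_descriptor()].
#' @param c_env Water concentration (uM), non-negative.
#' @param method `"linear_solve"` or `"integration"`.
#' @param kinetics `"first_order"` or `"michaelis"` (integration only).
#' @param window_s Convergence window (s).
#' @param max_time Integration-time cap (s).
#' @return A `steady_state_result`: `c_ss` (named, uM), `whole_body` (uM),
#'   `method`, `converged`, `time_to_ss` (s; NA for the linear solve).
#' @export
steady_state <- function(model, chem, c_env,
                         method = c("linear_solve", "integration"),
                         kinetics = c("first_order", "michaelis"),
                         window_s = 3600, max_time = 1e9) {
  method <- match.arg(method); kinetics <- match.arg(kinetics)
  model <- .as_model(model)
  if (c_env < 0) stop("c_env must be non-negative", call. = FALSE)
  if (identical(method, "linear_solve")) {
    if (!identical(kinetics, "first_order"))
      stop("linear_solve requires first-order kinetics", call. = FALSE)
    sm <- system_matrices(model, chem)
    c_ss <- tryCatch(solve(sm$A, -sm$b * c_env),
                     error = function(e) stop("singular rate matrix: ",
                                              conditionMessage(e), call. = FALSE))
    c_ss <- stats::setNames(as.numeric(c_ss), model$compartments)
    return(structure(list(c_ss = c_ss, whole_body = whole_body(c_ss, model),
                          method = method, converged = TRUE,
                          time_to_ss = NA_real_, model_id = model$model_id),
                     class = "steady_state_result"))
  }
  n <- length(model$compartments)
  zero <- stats::setNames(numeric(n), model$compartments)
  if (c_env == 0) {
    return(structure(list(c_ss = zero, whole_body = 0, method = method,
                          converged = TRUE, time_to_ss = 0,
                          model_id = model$model_id),
                     class = "steady_state_result"))
  }
  H <- 16 * window_s
  repeat {
    prof <- integrate_model(model, chem, c_env, c(0, H), kinetics = kinetics,
                            points_per_decade = 60)
    t_chk <- H - window_s
    c_end <- prof$concentrations[nrow(prof$concentrations), ]
    c_prev <- vapply(seq_len(n), function(j)
      stats::approx(prof$times, prof$concentrations[, j], xout = t_chk)$y,
      numeric(1))
    scale <- pmax(abs(c_end), 1e-30)
    if (max(abs(c_end - c_prev) / scale) < 1e-8) {
      c_ss <- stats::setNames(as.numeric(c_end), model$compartments)
      return(structure(list(c_ss = c_ss, whole_body = whole_body(c_ss, model),
                            method = method, converged = TRUE, time_to_ss = H,
                            model_id = model$model_id),
                       class = "steady_state_result"))
    }
    H <- H * 4
    if (H > max_time)
      stop("steady state not reached within time cap (", max_time, " s)",
           call. = FALSE)
  }
}

#' Whole-body concentration
#'
#' Volume-weighted mean concentration over all compartments, blood included:
#' total amount divided by total body volume.
#'
#' @param x A `steady_state_result`, a `concentration_profile`, a named
#'   per-compartment vector, or a time-by-compartment matrix.
#' @param model The `model_structure` the concentrations belong to (not
#'   needed for profiles/steady-state results, which carry their volumes).
#' @return A scalar (uM) or a per-time vector for profiles/matrices.
#' @export
whole_body <- function(x, model = NULL) {
  if (inherits(x, "steady_state_result")) return(x$whole_body)
  if (inherits(x, "concentration_profile")) {
    V <- x$volumes[colnames(x$concentrations)]
    return(as.numeric(x$concentrations %*% V) / sum(V))
  }
  if (is.null(model)) stop("model is required for raw concentrations", call. = FALSE)
  model <- .as_model(model)
  V <- model$volumes[model$compartments]
  if (is.matrix(x)) {
    if (ncol(x) != length(V)) stop("dimension mismatch", call. = FALSE)
    cols <- if (!is.null(colnames(x))) colnames(x) else model$compartments
    return(as.numeric(x[, model$compartments, drop = FALSE] %*% V) / sum(V))
  }
  if (length(x) != length(V)) stop("dimension mismatch", call. = FALSE)
  if (!is.null(names(x))) x <- x[model$compartments]
  sum(V * x) / sum(V)
}

#' Export a concentration profile as a tidy data frame
#'
#' @param profile A `concentration_profile`.
#' @return Data frame with columns `time_s`, `compartment`,
#'   `concentration_uM`.
#' @export
profile_as_data_frame <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  comps <- colnames(profile$concentrations)
  data.frame(
    time_s = rep(profile$times, times = length(comps)),
    compartment = rep(comps, each = length(profile$times)),
    concentration_uM = as.numeric(profile$concentrations))
}
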
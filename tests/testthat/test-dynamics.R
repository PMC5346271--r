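# Forward simulation: derivatives, matrices, integration, steady states.

test_that("the 1C system matrices match the hand-derived balance", {
  phys <- default_physiology("1C")
  chem <- preset_chemical("diazinon")
  m <- build_model("1C", phys)
  sm <- system_matrices(m, chem)
  V <- phys$compartments$volume_mL
  P <- partition_coefficient(chem, phys$compartments$f_lipid,
                             phys$compartments$f_water)
  # A = -(gill elimination + metabolism), b = uptake rate
  expect_equal(sm$A[1, 1], -(phys$Qw / (V * P) + chem$k_met), tolerance = 1e-12)
  expect_equal(unname(sm$b[1]), phys$Qw / V, tolerance = 1e-12)
  expect_error(system_matrices(m, chem, kinetics = "michaelis"), "nonlinear")
})

test_that("derivatives and system matrices agree for first-order kinetics", {
  set.seed(11)
  for (mid in all_structures) {
    m <- build_default(mid)
    chem <- random_chemical()
    for (rep in 1:5) {
      state <- stats::runif(length(m$compartments), 0, 50)
      c_env <- stats::runif(1, 0, 20)
      sm <- system_matrices(m, chem)
      expect_rel_equal(derivatives(m, chem, state, c_env),
                       as.numeric(sm$A %*% state + sm$b * c_env), 1e-12)
    }
  }
})

test_that("whole-body mass balance holds for random states and parameters", {
  # volume-weighted sum of rates == gill uptake - gill elimination - sinks
  set.seed(21)
  n_cases <- 0
  for (rep in 1:25) {
    for (mid in all_structures) {
      m <- if (identical(mid, "6C")) build_model("6C", random_6c_physiology())
           else build_default(mid)
      for (kin in c("first_order", "michaelis")) {
        chem <- random_chemical(k_exc = stats::runif(1, 0, 1e-4))
        if (kin == "michaelis") {
          chem$km <- 10^stats::runif(1, 0, 3)
          chem$vmax <- chem$k_met * chem$km
        }
        state <- stats::setNames(stats::runif(length(m$compartments), 0, 30),
                                 m$compartments)
        c_env <- stats::runif(1, 0, 20)
        V <- m$volumes[m$compartments]
        P <- stats::setNames(
          partition_coefficient(chem, m$composition$f_lipid, m$composition$f_water),
          m$composition$compartment)[m$compartments]
        g <- m$gill_exchange
        elim_comp <- g$eliminate_from
        uptake <- g$q_ex * c_env
        elim <- g$q_ex * state[[elim_comp]] / P[[elim_comp]]
        sinks <- 0
        for (cn in m$metabolizing) {
          sinks <- sinks + if (kin == "michaelis")
            V[[cn]] * chem$vmax * state[[cn]] / (chem$km + state[[cn]])
          else V[[cn]] * chem$k_met * state[[cn]]
        }
        for (cn in m$excreting) sinks <- sinks + V[[cn]] * chem$k_exc * state[[cn]]
        lhs <- sum(V * derivatives(m, chem, state, c_env, kin))
        rhs <- uptake - elim - sinks
        scale <- max(abs(uptake), abs(elim), abs(sinks), 1e-30)
        expect_lt(abs(lhs - rhs) / scale, 1e-12)
        n_cases <- n_cases + 1
      }
    }
  }
  expect_gte(n_cases, 250)
})

test_that("derivatives vanish at zero and at the steady state", {
  chem <- preset_chemical("diazinon")
  for (mid in c("7C", "6C", "1C")) {
    m <- build_default(mid)
    expect_equal(unname(derivatives(m, chem, numeric(length(m$compartments)), 0)),
                 numeric(length(m$compartments)))
    ss <- steady_state(m, chem, c_env = 5)$c_ss
    d <- derivatives(m, chem, ss, c_env = 5)
    expect_lt(max(abs(d)) / max(ss), 1e-9)
  }
  expect_error(derivatives(build_default("1C"), chem, -1, 0), "non-negative")
  expect_error(derivatives(build_default("1C"), chem, 1, 0, "michaelis"),
               "vmax/km")
})

test_that("all eigenvalues of the rate matrix are strictly stable", {
  set.seed(31)
  for (mid in all_structures) {
    m <- build_default(mid)
    for (rep in 1:10) {
      sm <- system_matrices(m, random_chemical())
      expect_true(all(Re(eigen(sm$A, only.values = TRUE)$values) < 0))
      expect_true(all(sm$b >= 0))
    }
  }
})

test_that("Michaelis kinetics approaches first order as km grows", {
  m <- build_default("7C")
  chem_fo <- preset_chemical("diazinon")
  state <- stats::setNames(seq(1, 7), m$compartments)
  for (km in c(1e4, 1e6)) {
    chem_mm <- chemical_descriptor("dz_mm", log_kow = 3.81, k_met = chem_fo$k_met,
                                   vmax = chem_fo$k_met * km, km = km)
    d_fo <- derivatives(m, chem_fo, state, 10, "first_order")
    d_mm <- derivatives(m, chem_mm, state, 10, "michaelis")
    expect_rel_equal(d_mm, d_fo, if (km >= 1e6) 1e-6 else 1e-3)
  }
})

test_that("integration of zero exposure from a clean state stays at zero", {
  prof <- integrate_model("6C", preset_chemical("diazinon"), 0, c(0, 1e4))
  expect_true(all(prof$concentrations == 0))
})

test_that("long-horizon integration reaches the analytic steady state", {
  chem <- preset_chemical("diazinon")
  m <- build_default("7C")
  prof <- integrate_model(m, chem, 10, c(0, 4e7), points_per_decade = 40)
  terminal <- prof$concentrations[nrow(prof$concentrations), ]
  ss <- steady_state(m, chem, 10)$c_ss
  expect_rel_equal(terminal, ss, 1e-3)
  # accumulation from a clean state under constant exposure is monotone
  wb <- whole_body(prof)
  expect_true(all(diff(wb) > -1e-9 * max(wb)))
})

test_that("integrated and linear-solve steady states agree", {
  chem <- preset_chemical("diazinon")
  for (mid in c("6C", "1C")) {
    ss_int <- steady_state(mid, chem, 10, method = "integration")
    ss_lin <- steady_state(mid, chem, 10, method = "linear_solve")
    expect_true(ss_int$converged)
    expect_rel_equal(ss_int$c_ss, ss_lin$c_ss, 1e-6)
  }
})

test_that("first-order steady states are homogeneous in the exposure", {
  set.seed(41)
  for (mid in all_structures) {
    chem <- random_chemical()
    s1 <- steady_state(mid, chem, 3)$c_ss
    s2 <- steady_state(mid, chem, 6)$c_ss
    expect_rel_equal(s2, 2 * s1, 1e-12)
  }
  expect_equal(max(steady_state("6C", preset_chemical("diazinon"), 0)$c_ss), 0)
})

test_that("the exact linear propagator matches stiff numerical integration", {
  chem <- preset_chemical("diazinon")
  m <- build_default("6C")
  sm <- system_matrices(m, chem)
  times <- 10^seq(0, 6, length.out = 40)
  exact <- fishrtk:::.linear_profile(sm$A, sm$b, 10, numeric(6), times)
  prof <- integrate_model(m, chem, 10, c(0, 1e6), points_per_decade = 50)
  num <- vapply(seq_len(6), function(j)
    stats::approx(prof$times, prof$concentrations[, j], xout = times)$y,
    numeric(length(times)))
  expect_rel_equal(num[times > 10, ], exact[times > 10, ], 5e-3)
})

test_that("whole-body concentration is the volume-weighted mean", {
  m1 <- build_default("1C")
  expect_equal(whole_body(c(body = 3.2), m1), 3.2)
  # equal-volume compartments at 1 and 3 uM average to 2 uM
  m6 <- build_default("6C")
  expect_equal(whole_body(stats::setNames(c(2, 2, 1, 2, 3, 2), m6$compartments), m6),
               whole_body(stats::setNames(c(2, 2, 3, 2, 1, 2), m6$compartments), m6))
  # brain and liver share a volume, so swapping their values changes nothing
  V <- m6$volumes
  x <- stats::setNames(rep(2, 6), m6$compartments)
  x[["brain"]] <- 1; x[["gonads"]] <- 3
  wb <- whole_body(x, m6)
  expect_equal(wb, sum(V * x) / sum(V))
  V2 <- V; V2[["gonads"]] <- 2 * V2[["gonads"]]
  m6b <- m6; m6b$volumes <- V2
  expect_gt(whole_body(x, m6b), wb)  # weight moved toward the 3 uM compartment
  expect_error(whole_body(1:3, m6), "dimension mismatch")
})
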
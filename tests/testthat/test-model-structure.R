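# Model architectures, partitioning and structural variants.

test_that("chemical descriptors validate their inputs", {
  expect_error(chemical_descriptor("x", log_kow = 2, k_met = -1), "k_met")
  expect_error(chemical_descriptor("x", log_kow = 2, vmax = 1), "vmax and km")
  expect_error(chemical_descriptor("x", log_kow = 2, vmax = 1, km = 0), "km")
  expect_error(chemical_descriptor("x", log_kow = 2, ac10 = -1), "ac10")
  expect_s3_class(chemical_descriptor("x", log_kow = 2, vmax = 1, km = 5),
                  "chemical_descriptor")
})

test_that("preset chemicals carry the published lipophilicities", {
  expect_equal(preset_chemical("diazinon")$log_kow, 3.81)
  expect_equal(preset_chemical("dichloroethane_12")$log_kow, 1.48)
  expect_error(preset_chemical("atrazine"), "unknown preset")
})

test_that("chemical tables round-trip through CSV", {
  chems <- list(preset_chemical("diazinon"),
                chemical_descriptor("m", log_kow = 2.5, k_met = 1e-5,
                                    vmax = 0.2, km = 30, ac10 = 0.7, loec = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chemicals(chems, path)
  back <- read_chemicals(path)
  expect_equal(back[[2]]$km, 30)
  expect_equal(back[[2]]$ac10, 0.7)
  expect_equal(back[[1]]$log_kow, 3.81)
  expect_null(back[[1]]$vmax)
})

test_that("partition coefficient follows the lipid/water mixing rule", {
  any_chem <- chemical_descriptor("x", log_kow = 4.2)
  expect_equal(partition_coefficient(any_chem, f_lipid = 0, f_water = 1), 1)
  # direct arithmetic: 0.05 * 10^3.81 + 0.8
  dz <- chemical_descriptor("dz", log_kow = 3.81)
  expect_equal(partition_coefficient(dz, 0.05, 0.8), 323.63, tolerance = 1e-4)
  expect_error(partition_coefficient(dz, -0.1, 0.8), "non-negative")
})

test_that("partition coefficient is monotone in log_kow and lipid fraction", {
  kows <- seq(-1, 7, by = 0.5)
  p <- vapply(kows, function(k)
    partition_coefficient(chemical_descriptor("x", log_kow = k), 0.05, 0.8),
    numeric(1))
  expect_true(all(diff(p) > 0))
  fls <- seq(0, 0.2, by = 0.02)
  p2 <- partition_coefficient(chemical_descriptor("x", log_kow = 3), fls, 0.7)
  expect_true(all(diff(p2) > 0))
  expect_true(all(p2 >= 0.7))
})

test_that("build_model produces the expected architectures", {
  m7 <- build_default("7C")
  expect_setequal(m7$compartments,
                  c("arterial", "venous", "brain", "gonads", "liver", "ppt", "rpt"))
  # gonads and richly perfused effluent route to the liver
  expect_true(any(m7$edges$from == "gonads" & m7$edges$to == "liver"))
  expect_true(any(m7$edges$from == "rpt" & m7$edges$to == "liver"))
  expect_identical(m7$metabolizing, "liver")
  expect_length(m7$excreting, 0)

  m6 <- build_default("6C")
  expect_true(any(m6$edges$from == "gonads" & m6$edges$to == "venous"))
  expect_identical(m6$metabolizing, "liver")
  expect_identical(m6$excreting, "other")

  m1 <- build_default("1C")
  expect_identical(m1$compartments, "body")
  expect_identical(m1$metabolizing, "body")

  expect_error(build_model("9C", default_physiology("7C")), "unknown model_id")
})

test_that("the 7C model demands an assimilation factor", {
  phys <- default_physiology("7C")
  phys$assimilation_factor <- NULL
  expect_error(build_model("7C", phys), "assimilation factor")
})

test_that("flow is conserved at every node of every structure", {
  for (mid in all_structures) {
    m <- build_default(mid)
    expect_silent(validate_structure(m))
    e <- m$edges
    for (cn in m$compartments) {
      inflow <- sum(e$flow_mL_per_s[e$to == cn])
      outflow <- sum(e$flow_mL_per_s[e$from == cn])
      if (nrow(e)) expect_equal(inflow, outflow, tolerance = 1e-12)
    }
  }
})

test_that("physiology validation enforces flow balance and positivity", {
  phys <- default_physiology("6C")
  bad <- phys
  bad$compartments$flow_mL_per_s[3] <- bad$compartments$flow_mL_per_s[3] * 2
  expect_error(validate_physiology(bad), "sum to cardiac output")
  bad2 <- phys
  bad2$compartments$volume_mL[1] <- -1
  expect_error(validate_physiology(bad2), "positive")
  bad3 <- phys
  bad3$compartments$f_lipid[3] <- 0.9  # f_lipid + f_water > 1
  expect_error(validate_physiology(bad3), "exceed 1")
})

test_that("physiology fixtures round-trip through CSV", {
  phys <- default_physiology("7C")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_physiology(phys, f1, f2)
  back <- read_physiology("7C", f1, f2)
  expect_equal(back$compartments$volume_mL, phys$compartments$volume_mL)
  expect_equal(back$assimilation_factor, 0.5)
  expect_equal(back$Qc, phys$Qc)
})

test_that("collapsing gonads and other merges volumes and flows additively", {
  m6 <- build_default("6C")
  mc <- collapse_gonads_other(m6)
  expect_identical(mc$model_id, "6C_collapsed")
  expect_equal(mc$volumes[["other"]],
               m6$volumes[["gonads"]] + m6$volumes[["other"]])
  q_in <- function(m, comp) sum(m$edges$flow_mL_per_s[m$edges$to == comp])
  expect_equal(q_in(mc, "other"), q_in(m6, "gonads") + q_in(m6, "other"))
  expect_length(mc$compartments, length(m6$compartments) - 1L)
  # total body volume and cardiac output unchanged
  expect_equal(sum(mc$volumes), sum(m6$volumes))
  expect_equal(mc$Qc, m6$Qc)
  expect_error(collapse_gonads_other(build_default("7C")), "requires a 6C")
})

test_that("rewiring sends the gonads' effluent to the liver, conserving flow", {
  m6 <- build_default("6C")
  mr <- rewire_gonads_to_liver(m6)
  expect_false(any(mr$edges$from == "gonads" & mr$edges$to == "venous"))
  expect_true(any(mr$edges$from == "gonads" & mr$edges$to == "liver"))
  liver_in <- sum(mr$edges$flow_mL_per_s[mr$edges$to == "liver"])
  liver_out <- sum(mr$edges$flow_mL_per_s[mr$edges$from == "liver"])
  expect_equal(liver_in, liver_out, tolerance = 1e-12)
  expect_equal(sum(mr$volumes), sum(m6$volumes))
  expect_equal(mr$Qc, m6$Qc)
  expect_error(rewire_gonads_to_liver(build_default("1C")), "requires a 6C")
})

test_that("the shipped CSV fixtures reproduce the in-code defaults", {
  for (mid in c("7C", "6C", "1C")) {
    cmp_csv <- system.file("extdata",
                           sprintf("physiology_%s_compartments.csv", mid),
                           package = "fishrtk")
    sc_csv <- system.file("extdata",
                          sprintf("physiology_%s_scalars.csv", mid),
                          package = "fishrtk")
    phys <- read_physiology(mid, cmp_csv, sc_csv)
    def <- default_physiology(mid)
    expect_equal(phys$compartments, def$compartments, tolerance = 1e-12)
    expect_equal(phys$Qw, def$Qw)
    expect_s3_class(build_model(mid, phys), "model_structure")
  }
})
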
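test_that("reference statistics load with all cohort variables", {
  tab <- reference_group_stats()
  expect_equal(nrow(tab), 14)
  expect_true(all(descriptor_names() %in% tab$parameter))
  expect_true(all(tab$control_sd > 0) && all(tab$fracture_sd > 0))
})

test_that("group specs validate their correlation structure", {
  expect_error(group_spec("control", 10, c(a = 1, b = 2), c(1, 1),
                          matrix(c(1, 2, 2, 1), 2)), "positive-definite")
  expect_error(group_spec("control", 10, c(a = 1, b = 2), c(1, 1),
                          matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
  sp <- reference_group_spec("control", 64)
  expect_s3_class(sp, "group_spec")
  ev <- eigen(sp$correlation, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("descriptor cohorts are seeded, sized, positive and calibrated", {
  ctrl <- reference_group_spec("control", 64)
  frac <- reference_group_spec("fracture", 64)
  a <- sample_descriptor_cohort(ctrl, frac, seed = 5)
  b <- sample_descriptor_cohort(ctrl, frac, seed = 5)
  expect_identical(a, b)
  expect_equal(table(a$group), table(rep(c("control", "fracture"), 64)),
               ignore_attr = TRUE)
  num <- a[, setdiff(names(a), c("subject_id", "group"))]
  expect_true(all(num > 0))

  # long-run group mean matches the configured mean within 3 SE
  reps <- 40
  m <- vapply(seq_len(reps), function(r)
    mean(sample_descriptor_cohort(ctrl, frac, seed = r)$F0_N[1:64]),
    numeric(1))
  se <- ctrl$sds[["F0_N"]] / sqrt(64 * reps)
  expect_lt(abs(mean(m) - ctrl$means[["F0_N"]]), 3 * se)
})

test_that("identical group specs carry no discriminative signal", {
  ctrl <- reference_group_spec("control", 5000)
  same <- reference_group_spec("control", 5000)
  same$label <- "fracture"
  co <- sample_descriptor_cohort(ctrl, same, seed = 9)
  expect_lt(abs(auroc(co$F0_N, co$group) - 0.5), 0.02)
})

test_that("independent specs sample near-zero correlation", {
  sp <- group_spec("control", 10000, c(x = 10, y = 20), c(1, 2), diag(2))
  set.seed(3)
  draw <- femofall:::rmvn_positive(sp$n, sp$means, sp$sds, sp$correlation)
  expect_lt(abs(cor(draw[, 1], draw[, 2])), 0.1)
})

test_that("curve-level cohorts honour the descriptor identities and the
           calibrated means", {
  sp <- reference_group_spec("control", 400,
                             parameters = c("F0_N", "D0_mm", "D1_mm", "D3_mm"),
                             correlation = curve_param_correlation())
  cc <- sample_curve_cohort(sp, seed = 21)
  dsc <- extract_cohort_descriptors(cc)
  expect_equal(nrow(dsc), 400)
  expect_true(all(dsc$F0_N >= dsc$F1_N - 1e-9))
  expect_true(all(dsc$D0_mm >= dsc$D1_mm - 1e-9))
  expect_equal(dsc$D2_mm, dsc$D0_mm - dsc$D1_mm)
  expect_equal(dsc$E_res_Nmm, dsc$E_nl_Nmm - dsc$E_dis_Nmm)
  expect_true(all(dsc$D3_mm <= dsc$D0_mm + 1e-9))
  expect_true(all(dsc$E_dis_Nmm >= 0))
  # extracted strength is the drawn strength (monotone curve)
  expect_equal(dsc$F0_N, cc$params$F0_N, tolerance = 1e-9)
  # moment calibration: mean extracted F0 within 2% of the configured mean
  expect_lt(abs(mean(dsc$F0_N) - sp$means[["F0_N"]]) / sp$means[["F0_N"]],
            0.02)
})

test_that("curve- and descriptor-level cohorts agree on the univariate
           discrimination they induce", {
  n <- 4000
  vars <- c("F0_N", "D0_mm", "D1_mm", "D3_mm")
  Rc <- curve_param_correlation()
  dsc <- list(); lab <- rep(c(0, 1), each = n)
  for (g in c("control", "fracture")) {
    sp <- reference_group_spec(g, n, parameters = vars, correlation = Rc)
    cc <- sample_curve_cohort(sp, seed = 31 + (g == "fracture"),
                              n_points = 40)
    dsc[[g]] <- extract_cohort_descriptors(cc, grid_resolution = 30)
  }
  curve_tab <- rbind(dsc$control, dsc$fracture)
  ctrl <- reference_group_spec("control", n)
  frac <- reference_group_spec("fracture", n)
  desc_tab <- sample_descriptor_cohort(ctrl, frac, seed = 77)
  for (v in c("F0_N", "D0_mm", "D3_mm")) {
    a_curve <- auroc(curve_tab[[v]], lab)
    a_desc <- auroc(desc_tab[[v]], desc_tab$group)
    expect_lt(abs(a_curve - a_desc), 0.02)
  }
})

test_that("phantom construction counts, labels and uniform mapping", {
  ph <- make_phantom(phantom_spec("graded_beam", nx = 4, ny = 4, nz = 20,
                                  length_mm = 100, width_mm = 20,
                                  shell_mm = 5), seed = 2)
  expect_equal(nrow(ph$mesh$elements), 4 * 4 * 20)
  # outer ring cortical, inner 2x2 core trabecular
  expect_equal(sum(ph$mesh$compartment == "trabecular"), 4 * 20)
  expect_error(phantom_spec("graded_beam", nx = 4, width_mm = 20,
                            shell_mm = 2), "thinner")

  # uniform density image gives identical material points per compartment
  mat <- map_density_field(ph$mesh, 0.4)
  expect_equal(length(unique(mat$E[ph$mesh$compartment == "cortical"])), 1)
  expect_equal(length(unique(mat$E[ph$mesh$compartment == "trabecular"])), 1)
})

test_that("femur-like phantom fails under the default sideways fall", {
  ph <- make_phantom(phantom_spec("femur_like", nx = 4, nz = 10,
                                  length_mm = 90, width_mm = 26), seed = 1)
  mat <- map_density_field(ph$mesh, ph$element_rho)
  sim <- run_side_fall(ph$mesh, mat,
                       program = load_program(increment = 0.1,
                                              max_displacement = 6))
  expect_true(sim$failed)
  expect_lt(sim$D0, 6)
  expect_gt(sim$F0, 0)
})

test_that("density summaries aggregate compartments correctly", {
  ph <- make_phantom(phantom_spec("graded_beam", nx = 4, ny = 4, nz = 6,
                                  length_mm = 30, width_mm = 20,
                                  shell_mm = 5), seed = 1)
  # uniform 200 mg/cm^3 everywhere
  s <- density_summaries(ph$mesh, rep(0.2, nrow(ph$mesh$elements)))
  expect_equal(s$integral_vBMD, 200)
  expect_equal(s$trab_vBMD, 200)
  expect_equal(s$cortical_vBMD, 200)

  # cortical 800 mg/cm^3 at 0.18 cm thickness: sBMD = 144 mg/cm^2
  rho <- ifelse(ph$mesh$compartment == "cortical", 0.8, 0.15)
  s2 <- density_summaries(ph$mesh, rho, cortical_thickness_cm = 0.18)
  expect_equal(s2$cortical_sBMD, 144)

  # halving the densities halves every summary
  s3 <- density_summaries(ph$mesh, rho / 2, cortical_thickness_cm = 0.18)
  expect_equal(s3$integral_vBMD, s2$integral_vBMD / 2)
  expect_equal(s3$cortical_sBMD, s2$cortical_sBMD / 2)

  # geometric thickness estimate is close to the built 5 mm shell
  expect_equal(s2$cortical_thickness_cm, 0.18)
  s4 <- density_summaries(ph$mesh, rho)
  expect_gt(s4$cortical_thickness_cm, 0.2)  # volume/area of a closed ring
  expect_error(density_summaries(
    hex_mesh(ph$mesh$nodes, ph$mesh$elements, "cortical"), rho),
    "both cortical and trabecular")
})
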
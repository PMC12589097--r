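test_that("assembled stiffness of a free cube is symmetric PSD with six
           rigid-body modes", {
  bm <- femofall:::brick_mesh(1, 1, 1, 1, 1, 1)
  mesh <- hex_mesh(bm$nodes, bm$elements)
  model <- fe_model(mesh, data.frame(E = 1000, nu = 0.3,
                                     sigma_yc = 1e9, sigma_yt = 1e9))
  resp <- femofall:::fe_response(mesh$nodes, mesh$elements, 1000, 0.3,
                                 1e9, 1e9, numeric(24),
                                 matrix(0, 6, 8), matrix(0, 6, 8), TRUE)
  K <- matrix(0, 24, 24)
  K[cbind(as.numeric(resp$Ki), as.numeric(resp$Kj))] <- 0  # init pattern
  for (t in seq_along(resp$Kx))
    K[resp$Ki[t], resp$Kj[t]] <- K[resp$Ki[t], resp$Kj[t]] + resp$Kx[t]
  expect_equal(K, t(K), tolerance = 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_true(all(ev > -1e-8 * max(ev)))
})

test_that("two stacked cubes couple through their shared face", {
  bm <- femofall:::brick_mesh(1, 1, 2, 1, 1, 2)
  mesh <- hex_mesh(bm$nodes, bm$elements)
  resp <- femofall:::fe_response(mesh$nodes, mesh$elements, rep(1000, 2),
                                 rep(0.3, 2), rep(1e9, 2), rep(1e9, 2),
                                 numeric(36), matrix(0, 6, 16),
                                 matrix(0, 6, 16), TRUE)
  K <- Matrix::sparseMatrix(i = as.numeric(resp$Ki), j = as.numeric(resp$Kj),
                            x = as.numeric(resp$Kx), dims = c(36, 36))
  shared <- 5:8                       # middle-plane nodes
  bottom <- 1:4; top <- 9:12
  dof <- function(n) rep(3 * (n - 1), each = 3) + 1:3
  # shared nodes couple to both layers; outer layers do not couple directly
  expect_true(sum(abs(K[dof(shared), dof(bottom)])) > 0)
  expect_true(sum(abs(K[dof(shared), dof(top)])) > 0)
  expect_equal(sum(abs(K[dof(bottom), dof(top)])), 0)
})

test_that("distorted-mesh patch test reproduces a linear field exactly", {
  set.seed(42)
  bm <- femofall:::brick_mesh(2, 2, 2, 2, 2, 2)
  nodes <- bm$nodes + matrix(runif(length(bm$nodes), -0.12, 0.12), ncol = 3)
  mesh <- hex_mesh(nodes, bm$elements)
  model <- fe_model(mesh, data.frame(E = rep(1000, 8), nu = 0.3,
                                     sigma_yc = 1e9, sigma_yt = 1e9))
  A <- matrix(c(1e-3, 4e-4, -2e-4, 3e-4, -5e-4, 6e-4, 2e-4, 1e-4, 8e-4),
              3, 3, byrow = TRUE)
  uex <- nodes %*% t(A)
  idx <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
  bnd <- which(idx$i %in% c(0, 2) | idx$j %in% c(0, 2) | idx$k %in% c(0, 2))
  pres <- do.call(rbind, lapply(bnd, function(n) cbind(n, 1:3, uex[n, ])))
  con <- dirichlet_constraints(mesh, prescribed = pres)
  st <- femofall:::advance_to(model, con, femofall:::fresh_state(model), 1)
  expect_lt(max(abs(st$u - as.vector(t(uex)))), 1e-10)
})

test_that("fall direction honours the adduction/rotation convention", {
  expect_equal(fall_direction(0, 0), c(1, 0, 0))
  expect_equal(fall_direction(30, 0),
               c(cos(pi / 6), 0, -sin(pi / 6)))
  d <- fall_direction(17, 23)
  expect_equal(sum(d^2), 1)
  expect_error(fall_direction(31, 0), "0, 30")
  expect_error(fall_direction(0, -1), "0, 30")
})

test_that("side-fall constraints remove the documented number of dofs", {
  ph <- make_phantom(phantom_spec(nx = 4, ny = 4, nz = 6, length_mm = 30),
                     seed = 1)
  mesh <- ph$mesh
  con <- side_fall_constraints(mesh)
  S <- length(mesh$node_sets$shaft_end)
  T_ <- length(mesh$node_sets$trochanter_surface)
  H <- length(mesh$node_sets$head_surface)
  expect_equal(con$n_constrained, 3 * S + T_ + 3 * H - 3)
  # free dofs: everything minus the coupled/fixed dofs minus the prescribed
  # reference-point axis
  expect_equal(ncol(con$C), 3 * nrow(mesh$nodes) - con$n_constrained - 1)
  expect_error(side_fall_constraints(
    hex_mesh(mesh$nodes, mesh$elements, mesh$compartment,
             node_sets = mesh$node_sets[c("shaft_end", "head_surface")])),
    "empty")
})

test_that("uniaxial bar reproduces the closed-form elastic-plastic cycle", {
  bar <- make_bar(E = 1000, sy = 10, L = 10)
  run <- bar_march(bar, c(0.05, 0.1, 0.15, 0.2))
  # elastic branch F = EA d / L, plateau F = sy A
  expect_equal(run$curve$f, c(0, 5, 10, 10, 10), tolerance = 1e-6)
  st <- run$state
  expect_equal(st$W_ext, 1.5, tolerance = 1e-6)
  expect_equal(st$E_el, 0.5, tolerance = 1e-6)
  expect_equal(st$E_dis, 1.0, tolerance = 1e-6)
  un <- run_unload(bar$model, bar$con, st,
                   load_program(increment = 0.05))
  expect_equal(un$D3, 0.1, tolerance = 1e-6)
  expect_equal(un$E_dissipated, 1.0, tolerance = 1e-6)
  expect_equal(un$E_residual, 0.5, tolerance = 1e-6)
  # unloading tangent equals the elastic tangent within 2%
  k_un <- diff(un$curve$force_N[1:2]) / diff(un$curve$displacement_mm[1:2])
  expect_equal(k_un, 100, tolerance = 0.02)
})

test_that("purely elastic cycle leaves no residual displacement", {
  bar <- make_bar(E = 1000, sy = 1e6, L = 10)
  run <- bar_march(bar, c(0.1, 0.2))
  un <- run_unload(bar$model, bar$con, run$state,
                   load_program(increment = 0.05))
  expect_equal(un$D3, 0, tolerance = 1e-9)
  expect_equal(un$E_dissipated, 0, tolerance = 1e-9)
})

test_that("two-material series bar matches the series-spring solution", {
  # two stacked elements, nu = 0 so the 3D model decouples into springs
  L <- 10
  bm <- femofall:::brick_mesh(1, 1, 2, 1, 1, L)
  mesh <- hex_mesh(bm$nodes, bm$elements)
  E <- c(1000, 2000); sy <- c(10, 40)
  mat <- data.frame(E = E, nu = 0, sigma_yc = sy, sigma_yt = sy)
  model <- fe_model(mesh, mat)
  bot <- which(mesh$nodes[, 3] < 1e-9)
  top <- which(mesh$nodes[, 3] > L - 1e-9)
  fixed <- rbind(cbind(bot, 3), c(bot[1], 1), c(bot[1], 2), c(bot[2], 2))
  con <- dirichlet_constraints(mesh, fixed, cbind(top, 3))
  k1 <- E[1] / (L / 2); k2 <- E[2] / (L / 2)
  ks <- 1 / (1 / k1 + 1 / k2)
  d_yield <- sy[1] / ks                # weaker element yields first
  closed_form <- function(d) pmin(ks * d, sy[1])
  st <- femofall:::fresh_state(model)
  for (d in c(0.02, 0.05, 0.08, 0.12)) {
    st <- femofall:::advance_to(model, con, st, d)
    expect_equal(st$reaction, closed_form(d), tolerance = 1e-3)
  }
})

test_that("denser phantoms are stronger", {
  s1 <- beam_sim(seed = 2, density_scale = 1)
  s2 <- beam_sim(seed = 2, density_scale = 1.1)
  expect_gt(s2$F0, s1$F0)
})

test_that("rigid rotation of mesh and fall axis leaves the response
           unchanged", {
  ph <- make_phantom(phantom_spec("graded_beam", nx = 4, ny = 4, nz = 8,
                                  length_mm = 40, width_mm = 20,
                                  shell_mm = 5, density_cv = 0), seed = 1)
  mat <- map_density_field(ph$mesh, ph$element_rho)
  prog <- load_program(increment = 0.2, max_displacement = 1)
  s1 <- suppressWarnings(run_side_fall(ph$mesh, mat, program = prog))
  th <- 25 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mesh2 <- hex_mesh(ph$mesh$nodes %*% t(Rz), ph$mesh$elements,
                    ph$mesh$compartment, ph$mesh$node_sets)
  s2 <- suppressWarnings(run_loading(
    fe_model(mesh2, mat),
    side_fall_constraints(mesh2, as.numeric(Rz %*% c(1, 0, 0))), prog))
  expect_equal(s2$curve$force_N, s1$curve$force_N,
               tolerance = 1e-5)
})

test_that("dissipation accumulates monotonically during loading", {
  bar <- make_bar(E = 1000, sy = 10, L = 10)
  st <- femofall:::fresh_state(bar$model)
  prev <- 0
  for (d in seq(0.05, 0.4, by = 0.05)) {
    st <- femofall:::advance_to(bar$model, bar$con, st, d)
    expect_gte(st$E_dis, prev - 1e-12)
    prev <- st$E_dis
  }
})

test_that("refinement of the bending phantom contracts the strength
           estimate", {
  # uniform refinement with the cortical shell held at 5 mm; the pair is
  # kept small so the suite stays fast -- the vignette reports the longer
  # converged sequence
  f0 <- vapply(c(4, 8), function(nx) {
    ph <- make_phantom(phantom_spec("graded_beam", nx = nx, ny = nx,
                                    nz = nx, length_mm = 30, width_mm = 20,
                                    shell_mm = 5, density_cv = 0), seed = 1)
    mesh <- ph$mesh
    model <- fe_model(mesh, map_density_field(mesh, ph$element_rho))
    fixed <- do.call(rbind, lapply(mesh$node_sets$shaft_end,
                                   function(n) cbind(n, 1:3)))
    con <- dirichlet_constraints(mesh, fixed,
                                 cbind(mesh$node_sets$head_surface, 1))
    suppressWarnings(run_loading(model, con,
                                 load_program(increment = 0.25,
                                              max_displacement = 1))$F0)
  }, numeric(1))
  expect_lt(abs(diff(f0)) / f0[2], 0.10)
})
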
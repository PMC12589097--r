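# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately naive: direct formulas and pair
# loops, no shared code with the implementation paths they check.

# trilinear interpolation on a unit-spaced grid, one point at a time
oracle_trilinear <- function(values, origin, spacing, p) {
  f <- (p - origin) / spacing
  i <- pmin(pmax(floor(f), 0), dim(values) - 2)
  t <- f - i
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
      (if (dy) t[2] else 1 - t[2]) *
      (if (dz) t[3] else 1 - t[3])
    acc <- acc + w * values[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
  }
  acc
}

# exhaustive origin-anchored bilinear fit over all sample breakpoints
oracle_bilinear <- function(d, f) {
  best <- list(sse = Inf)
  for (b in d[2:(length(d) - 1)]) {
    x1 <- pmin(d, b); x2 <- pmax(d - b, 0)
    a11 <- sum(x1^2); a12 <- sum(x1 * x2); a22 <- sum(x2^2)
    det <- a11 * a22 - a12^2
    if (det <= 1e-12 * a11 * max(a22, 1)) next
    k1 <- (a22 * sum(x1 * f) - a12 * sum(x2 * f)) / det
    k2 <- (a11 * sum(x2 * f) - a12 * sum(x1 * f)) / det
    sse <- sum((f - k1 * x1 - k2 * x2)^2)
    if (sse < best$sse) best <- list(sse = sse, D1 = b, k1 = k1, k2 = k2)
  }
  best
}

# AUROC by explicit pair counting
oracle_auroc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Mann-Whitney U for y over x by pair counting
oracle_u <- function(x, y) {
  u <- 0
  for (b in y) for (a in x) u <- u + (b > a) + 0.5 * (a == b)
  u
}

# single-element uniaxial bar along z: L mm long, 1 mm^2 section.
# bottom face held axially (plus minimal rigid-body constraints), top face
# prescribed along z; lateral contraction free so the stress state is
# exactly uniaxial.
make_bar <- function(E = 1000, sy = 10, L = 10, nu = 0.3, nel = 1) {
  bm <- femofall:::brick_mesh(1, 1, nel, 1, 1, L)
  mesh <- hex_mesh(bm$nodes, bm$elements, rep("trabecular", nel), list())
  mat <- data.frame(E = rep(E, nel), nu = nu, sigma_yc = sy, sigma_yt = sy)
  model <- fe_model(mesh, mat)
  bot <- which(mesh$nodes[, 3] < 1e-9)
  top <- which(mesh$nodes[, 3] > L - 1e-9)
  fixed <- rbind(cbind(bot, 3),
                 c(bot[1], 1), c(bot[1], 2), c(bot[2], 2))
  con <- dirichlet_constraints(mesh, fixed = fixed,
                               prescribed = cbind(top, 3))
  list(model = model, con = con, mesh = mesh)
}

bar_march <- function(bar, d_targets) {
  st <- femofall:::fresh_state(bar$model)
  out <- data.frame(d = 0, f = 0)
  for (d in d_targets) {
    st <- femofall:::advance_to(bar$model, bar$con, st, d)
    out <- rbind(out, data.frame(d = d, f = st$reaction))
  }
  list(state = st, curve = out)
}

# small graded-beam side-fall run shared by several tests
beam_sim <- function(seed = 1, density_scale = 1, increment = 0.25,
                     max_displacement = 3, unload = FALSE, nx = 4, nz = 8,
                     density_cv = 0.05) {
  ph <- make_phantom(phantom_spec("graded_beam", nx = nx, ny = nx, nz = nz,
                                  length_mm = 40, width_mm = 20,
                                  shell_mm = 5, density_cv = density_cv),
                     seed = seed)
  mat <- map_density_field(ph$mesh, ph$element_rho * density_scale)
  suppressWarnings(run_side_fall(
    ph$mesh, mat,
    program = load_program(increment = increment,
                           max_displacement = max_displacement,
                           unload = unload)))
}
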
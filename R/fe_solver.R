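# ---------------------------------------------------------------------------
# Displacement-controlled elastic-perfectly-plastic FE driver.
#
# Constraints are handled by a sparse transformation u = C q + d * g:
#   C  maps the free generalised dofs q to full nodal dofs,
#   g  is the unit prescribed-displacement pattern scaled by the load d.
# Skew constraints (a node fixed only along a direction) and the rigid
# head-to-reference-point coupling are columns/patterns of C and g, so the
# reduced system C' K C stays symmetric and the conjugate reaction to d is
# simply g' f_int.
# ---------------------------------------------------------------------------

#' Assemble an FE model from a mesh and element material properties
#'
#' @param mesh A [hex_mesh()].
#' @param materials Data.frame with one row per element containing at least
#'   `E`, `nu`, `sigma_yc`, `sigma_yt` (e.g. from [map_density_field()]).
#' @return An object of class `fe_model` holding mesh, materials and state
#'   dimensions.
#' @export
fe_model <- function(mesh, materials) {
  stopifnot(inherits(mesh, "hex_mesh"),
            nrow(materials) == nrow(mesh$elements),
            all(c("E", "nu", "sigma_yc", "sigma_yt") %in% names(materials)))
  if (any(materials$E <= 0)) stop("non-positive elastic modulus")
  structure(list(mesh = mesh, materials = materials,
                 ndof = 3L * nrow(mesh$nodes),
                 ngp = 8L * nrow(mesh$elements)),
            class = "fe_model")
}

fresh_state <- function(model) {
  list(u = numeric(model$ndof),
       eps_p = matrix(0, 6, model$ngp),
       stress = matrix(0, 6, model$ngp),
       d = 0, reaction = 0,
       E_el = 0, E_dis = 0, W_ext = 0,
       max_eps_p = 0)
}

# orthonormal basis completing a unit vector n
tangent_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  cbind(t1, t2)
}

#' Fall direction from adduction and internal-rotation angles
#'
#' The canonical fall axis (both angles zero) is the model +x axis; the
#' shaft runs along +z. Adduction tilts the axis in the frontal (x-z) plane
#' by rotating about y; internal rotation then rotates about the shaft (z)
#' axis. Both angles must lie in the simulated 0--30 degree range.
#'
#' @param adduction_deg,rotation_deg Angles in degrees, within [0, 30].
#' @return Unit direction vector, length 3.
#' @export
fall_direction <- function(adduction_deg = 0, rotation_deg = 0) {
  if (adduction_deg < 0 || adduction_deg > 30 ||
      rotation_deg < 0 || rotation_deg > 30)
    stop("fall-direction angles must lie in [0, 30] degrees")
  a <- adduction_deg * pi / 180
  r <- rotation_deg * pi / 180
  v <- c(cos(a), 0, -sin(a))                       # tilt in frontal plane
  Rz <- matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
  as.numeric(Rz %*% v)
}

#' Sideways-fall boundary conditions as a constraint transformation
#'
#' Implements the lateral-fall experimental configuration: the distal shaft
#' cross-section is fully fixed, the greater-trochanter surface is supported
#' only along the fall direction, and the femoral-head surface nodes are
#' rigidly coupled (translations) to a reference point whose displacement
#' along the fall direction is the prescribed load; the reference point's
#' transverse translations remain free.
#'
#' @param mesh A [hex_mesh()] with non-empty `shaft_end`,
#'   `trochanter_surface` and `head_surface` node sets.
#' @param direction Unit fall-direction vector (see [fall_direction()]).
#' @return A constraint object (list with sparse `C`, pattern `g`, and
#'   bookkeeping), class `fe_constraints`.
#' @export
side_fall_constraints <- function(mesh, direction = fall_direction(0, 0)) {
  for (nm in c("shaft_end", "trochanter_surface", "head_surface"))
    if (!length(mesh$node_sets[[nm]])) stop("node set '", nm, "' is empty")
  n <- nrow(mesh$nodes)
  dirn <- direction / sqrt(sum(direction^2))
  tb <- tangent_basis(dirn)
  shaft <- mesh$node_sets$shaft_end
  troch <- setdiff(mesh$node_sets$trochanter_surface, shaft)
  head <- setdiff(mesh$node_sets$head_surface, shaft)
  other <- setdiff(seq_len(n), c(shaft, troch, head))

  ti <- tj <- tx <- list()
  qn <- 0L
  add <- function(rows, cols, vals) {
    k <- length(ti) + 1L
    ti[[k]] <<- rows; tj[[k]] <<- cols; tx[[k]] <<- vals
  }
  # unconstrained nodes: identity block
  if (length(other)) {
    rows <- as.vector(vapply(other, function(nd) 3 * nd - c(2, 1, 0),
                             numeric(3)))
    cols <- qn + seq_along(rows)
    add(rows, cols, rep(1, length(rows)))
    qn <- qn + length(rows)
  }
  # trochanter nodes: two tangential dofs each
  for (nd in troch) {
    rows <- rep(3 * nd - c(2, 1, 0), 2)
    cols <- qn + rep(1:2, each = 3)
    add(rows, cols, c(tb[, 1], tb[, 2]))
    qn <- qn + 2L
  }
  # head nodes: all coupled to the two transverse reference-point dofs
  qa <- qn + 1L; qb <- qn + 2L
  qn <- qn + 2L
  for (nd in head) {
    rows <- rep(3 * nd - c(2, 1, 0), 2)
    add(rows, c(qa, qa, qa, qb, qb, qb), c(tb[, 1], tb[, 2]))
  }
  C <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(3L * n, qn))
  g <- numeric(3L * n)
  for (nd in head) g[3 * nd - c(2, 1, 0)] <- dirn
  structure(list(C = C, g = g, direction = dirn,
                 n_constrained = 3L * length(shaft) + length(troch) +
                   3L * length(head) - 3L),
            class = "fe_constraints")
}

#' Generic Dirichlet constraints (fixed and prescribed dofs)
#'
#' @param mesh A [hex_mesh()].
#' @param fixed Two-column matrix `(node, dof)` of dofs held at zero
#'   (dof in 1:3).
#' @param prescribed Two- or three-column matrix `(node, dof[, weight])` of
#'   dofs following the load parameter `d` (weight defaults to 1).
#' @return An `fe_constraints` object.
#' @export
dirichlet_constraints <- function(mesh, fixed = NULL, prescribed = NULL) {
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  dof_id <- function(m) 3L * (as.integer(m[, 1]) - 1L) + as.integer(m[, 2])
  fixed_dofs <- if (!is.null(fixed)) dof_id(rbind(fixed)) else integer()
  g <- numeric(ndof)
  pres_dofs <- integer()
  if (!is.null(prescribed)) {
    prescribed <- rbind(prescribed)
    pres_dofs <- dof_id(prescribed)
    w <- if (ncol(prescribed) >= 3) prescribed[, 3] else rep(1, nrow(prescribed))
    g[pres_dofs] <- w
  }
  free <- setdiff(seq_len(ndof), c(fixed_dofs, pres_dofs))
  C <- Matrix::sparseMatrix(i = free, j = seq_along(free), x = 1,
                            dims = c(ndof, length(free)))
  structure(list(C = C, g = g, direction = NULL,
                 n_constrained = length(fixed_dofs) + length(pres_dofs)),
            class = "fe_constraints")
}

# one converged equilibrium solve at load level d, Newton with tangent
# from the committed state; returns updated (uncommitted) response
newton_solve <- function(model, con, state, d, tol = 1e-6, max_iter = 100) {
  mesh <- model$mesh; mat <- model$materials
  # C'C is diagonal by construction (identity blocks, orthonormal pairs,
  # shared head columns), so the projection is a cheap diagonal solve
  cc <- Matrix::colSums(con$C^2)
  q <- as.numeric(Matrix::crossprod(con$C, state$u - state$d * con$g)) / cc
  respond <- function(q, want_matrix) {
    u <- as.numeric(con$C %*% q) + d * con$g
    resp <- fe_response(mesh$nodes, mesh$elements, mat$E, mat$nu,
                        mat$sigma_yc, mat$sigma_yt, u,
                        state$eps_p, state$stress, want_matrix)
    list(u = u, resp = resp,
         r = as.numeric(Matrix::crossprod(con$C, resp$fint)))
  }
  cur <- respond(q, TRUE)
  for (it in seq_len(max_iter)) {
    reaction <- sum(con$g * cur$resp$fint)
    rn <- sqrt(sum(cur$r^2))
    if (rn <= tol * max(abs(reaction), 1e-3)) {
      return(list(converged = TRUE, u = cur$u, resp = cur$resp,
                  reaction = reaction, iter = it))
    }
    K <- Matrix::sparseMatrix(i = as.numeric(cur$resp$Ki),
                              j = as.numeric(cur$resp$Kj),
                              x = as.numeric(cur$resp$Kx),
                              dims = c(model$ndof, model$ndof))
    Kr <- Matrix::forceSymmetric(Matrix::crossprod(con$C, K %*% con$C))
    dq <- tryCatch(
      as.numeric(Matrix::solve(Kr, -cur$r)),
      error = function(e) {
        reg <- Kr + Matrix::Diagonal(nrow(Kr)) * (1e-8 * max(abs(Kr@x)))
        as.numeric(Matrix::solve(reg, -cur$r))
      })
    # backtracking line search on the residual norm (the sharp elastic-
    # plastic transition makes full Newton steps overshoot); trials are
    # matrix-free, the tangent is only assembled at the accepted point
    trial <- respond(q + dq, TRUE)
    if (sqrt(sum(trial$r^2)) < rn) {
      q <- q + dq
      cur <- trial
    } else {
      alpha <- 0.5
      repeat {
        trial <- respond(q + alpha * dq, FALSE)
        if (sqrt(sum(trial$r^2)) < rn || alpha <= 1 / 64) break
        alpha <- alpha / 2
      }
      q <- q + alpha * dq
      cur <- respond(q, TRUE)
    }
  }
  list(converged = FALSE)
}

# advance state from state$d to d_target, halving the increment on
# non-convergence (up to max_halvings); commits plastic state and energies
advance_to <- function(model, con, state, d_target, tol = 1e-6,
                       max_halvings = 4) {
  d0 <- state$d
  step <- d_target - d0
  halv <- 0
  while (abs(state$d - d_target) > 1e-12) {
    d_try <- if (step > 0) min(state$d + step, d_target) else
      max(state$d + step, d_target)
    sol <- newton_solve(model, con, state, d_try, tol = tol)
    if (!sol$converged) {
      halv <- halv + 1
      if (halv > max_halvings)
        stop("Newton failed to converge after ", max_halvings,
             " increment halvings at d = ", signif(d_try, 6))
      step <- step / 2
      next
    }
    # trapezoidal external work: 0.5*(F_n + F_{n+1}) * (d_{n+1} - d_n)
    state$W_ext <- state$W_ext +
      0.5 * (state$reaction + sol$reaction) * (d_try - state$d)
    state$u <- sol$u
    state$eps_p <- sol$resp$eps_p
    state$stress <- sol$resp$stress
    state$E_el <- sol$resp$E_el
    state$E_dis <- state$E_dis + sol$resp$D_inc
    state$max_eps_p <- sol$resp$max_eps_p
    state$d <- d_try
    state$reaction <- sol$reaction
  }
  state
}

#' Load program for displacement-controlled runs
#'
#' @param increment Head-displacement step, mm (> 0).
#' @param max_displacement Maximum prescribed displacement, mm.
#' @param unload Run the unloading pass after failure.
#' @param drop_fraction Failure is declared at the first increment whose
#'   reaction falls below `drop_fraction` times the running maximum.
#' @param tol Relative Newton tolerance (residual norm / reaction).
#' @return A list of class `load_program`.
#' @export
load_program <- function(increment = 0.05, max_displacement = 6,
                         unload = FALSE, drop_fraction = 0.999,
                         tol = 1e-6) {
  stopifnot(increment > 0, max_displacement >= increment,
            drop_fraction > 0, drop_fraction <= 1)
  structure(list(increment = increment, max_displacement = max_displacement,
                 unload = unload, drop_fraction = drop_fraction, tol = tol),
            class = "load_program")
}

#' Run a displacement-controlled loading pass
#'
#' Marches the prescribed displacement in fixed increments, recording the
#' reaction force, until either the reaction drops below
#' `drop_fraction * running max` (declared mechanical failure) or
#' `max_displacement` is reached (warning; failure flag `FALSE`).
#'
#' @param model An [fe_model()].
#' @param constraints An `fe_constraints` object (e.g.
#'   [side_fall_constraints()]).
#' @param program A [load_program()].
#' @return List with `curve` (data.frame `displacement_mm`, `force_N`,
#'   `phase`), `F0` (N), `D0` (mm), `failed` (logical), `state` (solver
#'   state at the last converged increment), and `state_at_peak`.
#' @export
run_loading <- function(model, constraints, program = load_program()) {
  state <- fresh_state(model)
  d <- 0; fmax <- 0
  ds <- 0; fs <- 0
  state_peak <- state
  failed <- FALSE
  while (d < program$max_displacement - 1e-12) {
    d <- min(d + program$increment, program$max_displacement)
    state <- advance_to(model, constraints, state, d, tol = program$tol)
    ds <- c(ds, d); fs <- c(fs, state$reaction)
    if (state$reaction >= fmax) {
      fmax <- state$reaction
      state_peak <- state
    } else if (state$reaction < program$drop_fraction * fmax) {
      failed <- TRUE
      break
    }
  }
  if (!failed)
    warning("reaction force never dropped before max_displacement = ",
            program$max_displacement, " mm; failure not reached")
  i0 <- which.max(fs)
  curve <- data.frame(displacement_mm = ds, force_N = fs, phase = "loading")
  list(curve = curve, F0 = fs[i0], D0 = ds[i0], failed = failed,
       state = state, state_at_peak = state_peak)
}

#' Sideways-fall simulation of a femur model
#'
#' Convenience wrapper: builds the side-fall constraints for the given fall
#' angles and runs the displacement-controlled loading pass (and optionally
#' the unloading pass from the force peak).
#'
#' @param mesh A [hex_mesh()] with the three side-fall node sets.
#' @param materials Per-element material table (see [fe_model()]).
#' @param adduction_deg,rotation_deg Fall-direction angles, degrees, [0,30].
#' @param program A [load_program()].
#' @return As [run_loading()], plus `unload` (the [run_unload()] result)
#'   when `program$unload` is `TRUE`, and `direction`.
#' @export
run_side_fall <- function(mesh, materials, adduction_deg = 0,
                          rotation_deg = 0, program = load_program()) {
  model <- fe_model(mesh, materials)
  con <- side_fall_constraints(mesh,
                               fall_direction(adduction_deg, rotation_deg))
  out <- run_loading(model, con, program)
  out$direction <- con$direction
  if (isTRUE(program$unload)) {
    out$unload <- run_unload(model, con, out$state_at_peak, program)
  }
  out
}

#' Unloading pass from a converged loaded state
#'
#' Reverses the prescribed displacement until the reaction force crosses
#' zero, then locates the residual displacement D3 by linear interpolation
#' between the bracketing increments. The dissipated energy is the area
#' between the loading and unloading force-displacement curves; the
#' residual energy is the loading (nonlinear) energy minus the dissipated
#' energy.
#'
#' @param model An [fe_model()].
#' @param constraints The constraint object used for loading.
#' @param state A converged solver state (typically at the force peak).
#' @param program A [load_program()]; its increment and tolerance are
#'   reused for the unloading march.
#' @return List with `curve` (unloading phase), `D3` (mm),
#'   `E_dissipated`, `E_residual`, `E_nonlinear` (N.mm).
#' @export
run_unload <- function(model, constraints, state, program = load_program()) {
  D0 <- state$d; F0 <- state$reaction
  W_load <- state$W_ext
  ds <- D0; fs <- F0
  d <- D0
  while (d > 1e-12 && state$reaction > 0) {
    d <- max(d - program$increment, 0)
    state <- advance_to(model, constraints, state, d, tol = program$tol)
    ds <- c(ds, d); fs <- c(fs, state$reaction)
  }
  k <- length(fs)
  if (fs[k] > 1e-6 * max(F0, 1))
    stop("unloading reached zero displacement with positive reaction; ",
         "zero-force crossing not bracketed")
  if (fs[k] < 0) {
    D3 <- ds[k - 1] + (ds[k] - ds[k - 1]) * (0 - fs[k - 1]) /
      (fs[k] - fs[k - 1])
    dsz <- c(ds[1:(k - 1)], D3); fsz <- c(fs[1:(k - 1)], 0)
  } else {
    # fully recovered within numerical tolerance (elastic cycle)
    D3 <- ds[k]
    dsz <- ds; fsz <- fs
  }
  # recovered area from the unloading curve, truncated at zero force
  W_rec <- -sum(0.5 * (fsz[-1] + fsz[-length(fsz)]) * diff(dsz))
  curve <- data.frame(displacement_mm = ds, force_N = fs, phase = "unloading")
  E_dis <- W_load - W_rec
  list(curve = curve, D3 = D3, E_dissipated = E_dis,
       E_residual = W_load - E_dis, E_nonlinear = W_load,
       state = state)
}
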
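# ---------------------------------------------------------------------------
# Phantom meshes: desk-scale stand-ins for reconstructed femoral anatomy.
# Two families: a prismatic graded beam (cortical shell + trabecular core)
# whose density comes from a rectilinear image, and a swept femur-like
# shape (elliptical cross-sections, narrowed neck, widened head) with
# per-element densities.
# ---------------------------------------------------------------------------

#' Phantom specification
#'
#' @param geometry `"graded_beam"` or `"femur_like"`.
#' @param nx,ny,nz Element counts (beam: per axis; femur-like: `nx` = cells
#'   per cross-section axis, `nz` = element layers along the sweep).
#' @param length_mm Overall length along the sweep/beam axis, mm.
#' @param width_mm Transverse size (beam) or shaft diameter (femur), mm.
#' @param shell_mm Cortical shell thickness, mm (>= one element layer); the
#'   shell is the set of elements whose centroid lies within `shell_mm` of
#'   the lateral surface, so the labelled geometry is stable under mesh
#'   refinement.
#' @param cortical_density,trabecular_density Mean volumetric density per
#'   compartment, mg/cm^3.
#' @param density_cv Coefficient of variation of the stochastic density
#'   field in each compartment.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("graded_beam", "femur_like"),
                         nx = 4, ny = 4, nz = 20,
                         length_mm = 100, width_mm = 20,
                         shell_mm = width_mm / nx,
                         cortical_density = 850, trabecular_density = 150,
                         density_cv = 0.05) {
  geometry <- match.arg(geometry)
  stopifnot(cortical_density > 0, trabecular_density > 0, density_cv >= 0)
  el_w <- width_mm / max(nx, ny)
  if (shell_mm < el_w - 1e-9)
    stop("cortical shell (", shell_mm, " mm) is thinner than one element ",
         "layer (", signif(el_w, 4), " mm)")
  if (geometry == "graded_beam" && 2 * shell_mm >= width_mm)
    stop("cortical shell leaves no trabecular core")
  structure(list(geometry = geometry, nx = nx, ny = ny, nz = nz,
                 length_mm = length_mm, width_mm = width_mm,
                 shell_mm = shell_mm,
                 cortical_density = cortical_density,
                 trabecular_density = trabecular_density,
                 density_cv = density_cv),
            class = "phantom_spec")
}

#' Build a phantom mesh with compartments, node sets, and densities
#'
#' The graded beam is a prismatic hex mesh along +z with a cortical outer
#' ring and trabecular core; its density field is returned as a rectilinear
#' [density_image()] (mg/cm^3 converted to g/cm^3) covering the mesh, with
#' compartment-mean values plus lognormal-free Gaussian noise. The
#' femur-like phantom sweeps elliptical cross-sections along a curved path
#' (straight shaft, bent neck, widened head); densities are per-element.
#' Node sets `shaft_end` (z = 0 face), `head_surface` (final face) and
#' `trochanter_surface` (lateral patch on the canonical-fall side of the
#' proximal shaft) are defined for the sideways-fall boundary conditions.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the stochastic density field.
#' @return List with `mesh` (a [hex_mesh()]), `image` (a [density_image()]
#'   for the beam, `NULL` for the femur-like phantom), and `element_rho`
#'   (per-element density, g/cm^3).
#' @export
make_phantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  if (spec$geometry == "graded_beam") make_graded_beam(spec)
  else make_femur_like(spec)
}

make_graded_beam <- function(spec) {
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  W <- spec$width_mm; L <- spec$length_mm
  bm <- brick_mesh(nx, ny, nz, W, W, L)
  # compartment by centroid distance to the lateral surface
  eid <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  cx <- (eid$i - 0.5) * W / nx
  cy <- (eid$j - 0.5) * W / ny
  edge <- pmin(cx, W - cx, cy, W - cy)
  comp <- ifelse(edge < spec$shell_mm, "cortical", "trabecular")
  z <- bm$nodes[, 3]
  node_sets <- list(
    shaft_end = which(z < 1e-9),
    head_surface = which(z > L - 1e-9),
    trochanter_surface = which(bm$nodes[, 1] < 1e-9 &
                                 z > 0.45 * L & z < 0.8 * L))
  mesh <- hex_mesh(bm$nodes, bm$elements, comp, node_sets)
  # density image on a grid twice as fine as the mesh so that centroid
  # interpolation stays inside the right compartment
  gx <- 2 * nx + 1; gy <- 2 * ny + 1; gz <- 2 * nz + 1
  sp <- c(W / (gx - 1), W / (gy - 1), L / (gz - 1))
  co <- expand.grid(x = seq(0, W, length.out = gx),
                    y = seq(0, W, length.out = gy),
                    z = seq(0, L, length.out = gz))
  shell_w <- spec$shell_mm
  in_cort <- co$x < shell_w | co$x > W - shell_w |
    co$y < shell_w | co$y > W - shell_w
  base <- ifelse(in_cort, spec$cortical_density, spec$trabecular_density)
  noise <- stats::rnorm(length(base), 0, spec$density_cv) * base
  vals <- array(pmax(base + noise, 1), dim = c(gx, gy, gz))
  img <- density_image(vals, origin = c(0, 0, 0), spacing = sp,
                       units = "mg/cm3")
  corner <- array(t(mesh$nodes[t(mesh$elements), ]),
                  dim = c(3, 8, nrow(mesh$elements)))
  rho <- interp_density(img, t(apply(corner, c(1, 3), mean)))
  list(mesh = mesh, image = img, element_rho = rho)
}

# square -> ellipse disc mapping, preserves the structured grid topology
square_to_ellipse <- function(u, v, a, b) {
  x <- u * sqrt(pmax(1 - v^2 / 2, 0))
  y <- v * sqrt(pmax(1 - u^2 / 2, 0))
  cbind(a * x, b * y)
}

make_femur_like <- function(spec) {
  nc <- spec$nx                     # cells per cross-section axis
  nl <- spec$nz                     # element layers along the sweep
  L <- spec$length_mm
  r_shaft <- spec$width_mm / 2
  ns <- nl + 1                      # sections
  s <- seq(0, 1, length.out = ns)
  # sweep path: straight shaft for s < 0.55, then circular bend of ~55
  # degrees towards +x (the canonical fall axis), mimicking the neck-head
  # axis of a proximal femur
  bend <- 55 * pi / 180
  s0 <- 0.55
  Ls <- s0 * L                       # shaft length
  Rb <- (1 - s0) * L / bend          # bend radius
  centers <- matrix(0, ns, 3)
  axes <- matrix(0, ns, 3)           # section normal (sweep tangent)
  for (i in seq_len(ns)) {
    if (s[i] <= s0) {
      centers[i, ] <- c(0, 0, s[i] * L)
      axes[i, ] <- c(0, 0, 1)
    } else {
      th <- (s[i] - s0) / (1 - s0) * bend
      centers[i, ] <- c(Rb * (1 - cos(th)), 0, Ls + Rb * sin(th))
      axes[i, ] <- c(sin(th), 0, cos(th))
    }
  }
  # section radii: shaft -> narrow neck (s ~ 0.55-0.85) -> widened head
  rad <- numeric(ns)
  for (i in seq_len(ns)) {
    si <- s[i]
    rad[i] <- if (si < 0.5) r_shaft
    else if (si < 0.85) r_shaft * (1 - 0.35 * sin((si - 0.5) / 0.35 * pi))
    else r_shaft * (1 + 0.5 * (si - 0.85) / 0.15)
  }
  # cross-section grid on [-1,1]^2
  g <- seq(-1, 1, length.out = nc + 1)
  uv <- as.matrix(expand.grid(u = g, v = g))
  npts <- nrow(uv)                   # (nc+1)^2 per section
  nodes <- matrix(0, ns * npts, 3)
  for (i in seq_len(ns)) {
    xy <- square_to_ellipse(uv[, 1], uv[, 2], rad[i], 0.85 * rad[i])
    n <- axes[i, ]
    tb <- tangent_basis(n)           # two in-plane axes
    pts <- outer(xy[, 1], tb[, 1]) + outer(xy[, 2], tb[, 2])
    nodes[(i - 1) * npts + seq_len(npts), ] <-
      sweep(pts, 2, centers[i, ], "+")
  }
  # connectivity
  nid <- function(sec, iu, iv) (sec - 1) * npts + (iv - 1) * (nc + 1) + iu
  el <- matrix(0L, nl * nc * nc, 8)
  comp <- character(nl * nc * nc)
  e <- 0L
  # shell depth in rings of the cross-section grid
  sl <- max(1L, round(spec$shell_mm / (r_shaft * 2 / nc)))
  for (k in seq_len(nl)) for (jv in seq_len(nc)) for (iu in seq_len(nc)) {
    e <- e + 1L
    el[e, ] <- c(nid(k, iu, jv), nid(k, iu + 1, jv), nid(k, iu + 1, jv + 1),
                 nid(k, iu, jv + 1), nid(k + 1, iu, jv),
                 nid(k + 1, iu + 1, jv), nid(k + 1, iu + 1, jv + 1),
                 nid(k + 1, iu, jv + 1))
    ring <- iu <= sl || iu > nc - sl || jv <= sl || jv > nc - sl
    comp[e] <- if (ring) "cortical" else "trabecular"
  }
  if (all(comp == "cortical"))
    stop("cortical shell leaves no trabecular core; reduce shell_layers")
  z <- nodes[, 3]
  # trochanter: lateral -x surface nodes around the shaft/neck junction
  xmin_band <- nodes[, 1] < -0.75 * r_shaft
  troch <- which(xmin_band & z > 0.40 * L & z < 0.62 * L)
  node_sets <- list(
    shaft_end = seq_len(npts),
    head_surface = (ns - 1) * npts + seq_len(npts),
    trochanter_surface = troch)
  mesh <- hex_mesh(nodes, el, comp, node_sets)
  base <- ifelse(comp == "cortical", spec$cortical_density,
                 spec$trabecular_density)
  rho_mg <- pmax(base * (1 + stats::rnorm(length(base), 0, spec$density_cv)),
                 1)
  list(mesh = mesh, image = NULL, element_rho = rho_mg / 1000)
}

#' Compartmental density summaries of a labelled mesh
#'
#' Volume-weighted densitometric summaries: integral vBMD (both
#' compartments), trabecular and cortical vBMD, mean cortical thickness,
#' and cortical surface BMD computed as mean cortical vBMD (mg/cm^3) times
#' mean cortical thickness (cm). Cortical thickness is estimated as the
#' cortical compartment volume divided by the exterior surface area of the
#' cortical elements (end caps excluded when `cap_sets` are present).
#'
#' @param mesh A [hex_mesh()] with both compartments present.
#' @param rho Per-element density, g/cm^3 (e.g. `element_rho` from
#'   [make_phantom()]), or a [density_image()] sampled at centroids.
#' @param cortical_thickness_cm Optional known thickness overriding the
#'   geometric estimate.
#' @return List with `integral_vBMD`, `trab_vBMD`, `cortical_vBMD`
#'   (mg/cm^3), `cortical_thickness_cm`, `cortical_sBMD` (mg/cm^2).
#' @export
density_summaries <- function(mesh, rho, cortical_thickness_cm = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (inherits(rho, "density_image")) {
    corner <- array(t(mesh$nodes[t(mesh$elements), ]),
                    dim = c(3, 8, nrow(mesh$elements)))
    rho <- interp_density(rho, t(apply(corner, c(1, 3), mean)))
  }
  stopifnot(length(rho) == nrow(mesh$elements))
  vols <- hex_volumes(mesh)
  comp <- mesh$compartment
  if (!all(c("cortical", "trabecular") %in% comp))
    stop("mesh must contain both cortical and trabecular elements")
  wmean <- function(sel) sum(rho[sel] * vols[sel]) / sum(vols[sel])
  integral <- wmean(rep(TRUE, length(rho))) * 1000      # mg/cm^3
  trab <- wmean(comp == "trabecular") * 1000
  cort <- wmean(comp == "cortical") * 1000
  if (is.null(cortical_thickness_cm)) {
    area <- cortical_exterior_area(mesh)                 # mm^2
    vol_c <- sum(vols[comp == "cortical"])               # mm^3
    cortical_thickness_cm <- vol_c / area / 10           # mm -> cm
  }
  list(integral_vBMD = integral, trab_vBMD = trab, cortical_vBMD = cort,
       cortical_thickness_cm = cortical_thickness_cm,
       cortical_sBMD = cort * cortical_thickness_cm)
}

# exterior (boundary, non-shared) face area of cortical elements, mm^2
cortical_exterior_area <- function(mesh) {
  faces_idx <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                     c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  el <- mesh$elements
  ne <- nrow(el)
  fl <- vector("list", 6)
  for (f in 1:6) fl[[f]] <- el[, faces_idx[f, ], drop = FALSE]
  faces <- do.call(rbind, fl)
  owner <- rep(seq_len(ne), 6)
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  cnt <- table(key)
  ext <- cnt[key] == 1
  sel <- ext & mesh$compartment[owner] == "cortical"
  if (!any(sel)) stop("cortical compartment has no exterior faces")
  quad_area <- function(q) {
    p <- mesh$nodes[q, ]
    tri <- function(a, b, c) {
      v1 <- b - a; v2 <- c - a
      0.5 * sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2],
                       v1[3] * v2[1] - v1[1] * v2[3],
                       v1[1] * v2[2] - v1[2] * v2[1])^2))
    }
    tri(p[1, ], p[2, ], p[3, ]) + tri(p[1, ], p[3, ], p[4, ])
  }
  sum(apply(faces[sel, , drop = FALSE], 1, quad_area))
}
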
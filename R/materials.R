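#' @useDynLib femofall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# ---------------------------------------------------------------------------
# Density conversions and density-elasticity / density-yield power laws.
#
# Unit conventions (strict):
#   rho_qct, rho_ash          g/cm^3
#   rho_app (trabecular E)    kg/m^3   (= g/cm^3 * 1000)
#   rho_app (trabecular yield) g/cm^3  (Morgan-type coefficients)
#   E, yield stresses         MPa
# ---------------------------------------------------------------------------

#' Ash density from radiological (QCT-equivalent) density
#'
#' Linear calibration from radiological density to ash density,
#' \eqn{\rho_{ash} = 0.87\,\rho_{QCT} + 0.079} (both in g/cm\eqn{^3}).
#'
#' @param rho_qct Radiological density in g/cm^3; non-negative, vectorised.
#' @return Ash density in g/cm^3.
#' @examples
#' ash_density(1.0)   # 0.949
#' @export
ash_density <- function(rho_qct) {
  if (any(!is.finite(rho_qct)) || any(rho_qct < 0))
    stop("rho_qct must be finite and >= 0 (g/cm^3)")
  0.87 * rho_qct + 0.079
}

#' Apparent density from ash density
#'
#' Divides ash density by the assumed ash/apparent mass ratio. The ratio
#' defaults to 0.6; published measurements place it in 0.55--0.63, and values
#' outside that range raise a warning.
#'
#' @param rho_ash Ash density in g/cm^3; non-negative, vectorised.
#' @param ratio Ash-to-apparent density ratio (dimensionless), default 0.6.
#' @return Apparent density in g/cm^3.
#' @export
apparent_density <- function(rho_ash, ratio = 0.6) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("ash/apparent ratio must be a positive scalar")
  if (ratio < 0.55 || ratio > 0.63)
    warning("ash/apparent ratio ", ratio,
            " outside the physiological range [0.55, 0.63]")
  if (any(!is.finite(rho_ash)) || any(rho_ash < 0))
    stop("rho_ash must be finite and >= 0 (g/cm^3)")
  rho_ash / ratio
}

#' Convert apparent density from g/cm^3 to kg/m^3
#' @param rho_app_gcc Apparent density in g/cm^3.
#' @return Apparent density in kg/m^3.
#' @export
app_density_kgm3 <- function(rho_app_gcc) rho_app_gcc * 1000

#' Elastic modulus from density, per tissue compartment
#'
#' Compartment-specific density--elasticity power laws:
#' trabecular \eqn{E = 0.003715\,\rho_{app}^{1.96}} with \eqn{\rho_{app}}
#' in kg/m\eqn{^3}; cortical \eqn{E = 10200\,\rho_{ash}^{2.01}} with
#' \eqn{\rho_{ash}} in g/cm\eqn{^3}. E in MPa in both branches.
#'
#' @param rho Density in the units of the selected branch: apparent density
#'   in kg/m^3 for `"trabecular"`, ash density in g/cm^3 for `"cortical"`.
#' @param compartment `"trabecular"` or `"cortical"` (scalar or per-element).
#' @return Elastic modulus in MPa.
#' @export
elastic_modulus <- function(rho, compartment) {
  compartment <- match_compartment(compartment, length(rho))
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("density must be finite and >= 0")
  trab <- compartment == "trabecular"
  # kg/m^3 magnitudes: anything positive but < 10 in the trabecular branch is
  # almost certainly a g/cm^3 value passed by mistake
  if (any(trab & rho > 0 & rho < 10))
    stop("trabecular elastic_modulus expects rho_app in kg/m^3; ",
         "values < 10 look like g/cm^3")
  out <- numeric(length(rho))
  out[trab]  <- 0.003715 * rho[trab]^1.96
  out[!trab] <- 10200 * rho[!trab]^2.01
  out
}

#' Compressive and tensile yield stresses from density, per compartment
#'
#' Trabecular bone: \eqn{\sigma_{yc} = 38.5\,\rho_{app}^{1.48}},
#' \eqn{\sigma_{yt} = 22.6\,\rho_{app}^{1.26}} with \eqn{\rho_{app}} in
#' g/cm^3. Cortical bone: linear functions of the elastic modulus,
#' \eqn{\sigma_{yc} = -0.41 + 0.0062 E} (default sign reading; set
#' `cortical_syc_positive_intercept = TRUE` for the \eqn{+0.41} reading) and
#' \eqn{\sigma_{yt} = 0.33 + 0.0039 E}. Non-positive results are clamped to
#' `floor_mpa` with a warning.
#'
#' @param rho_app Apparent density in g/cm^3 (used by the trabecular branch).
#' @param compartment `"trabecular"` or `"cortical"`.
#' @param E Elastic modulus in MPa (used by the cortical branch).
#' @param cortical_syc_positive_intercept Use +0.41 instead of -0.41 in the
#'   cortical compressive yield law.
#' @param floor_mpa Positivity floor for yield stresses, MPa.
#' @return A list with vectors `sigma_yc` and `sigma_yt`, MPa.
#' @export
yield_stresses <- function(rho_app, compartment, E = NULL,
                           cortical_syc_positive_intercept = FALSE,
                           floor_mpa = 0.01) {
  n <- max(length(rho_app), length(E))
  compartment <- match_compartment(compartment, n)
  trab <- compartment == "trabecular"
  if (any(trab) && (any(!is.finite(rho_app[trab])) || any(rho_app[trab] < 0)))
    stop("rho_app must be finite and >= 0 (g/cm^3)")
  if (any(!trab)) {
    if (is.null(E)) stop("cortical yield stresses require E")
    if (any(!is.finite(E[!trab])) || any(E[!trab] < 0))
      stop("E must be finite and >= 0 for the cortical branch")
  }
  syc <- syt <- numeric(n)
  rho_app <- rep_len(rho_app, n)
  if (!is.null(E)) E <- rep_len(E, n)
  syc[trab] <- 38.5 * rho_app[trab]^1.48
  syt[trab] <- 22.6 * rho_app[trab]^1.26
  a <- if (cortical_syc_positive_intercept) 0.41 else -0.41
  syc[!trab] <- a + 0.0062 * E[!trab]
  syt[!trab] <- 0.33 + 0.0039 * E[!trab]
  low <- (syc < floor_mpa) | (syt < floor_mpa)
  if (any(low)) {
    warning(sum(low), " yield stresses below ", floor_mpa,
            " MPa clamped to the floor")
    syc <- pmax(syc, floor_mpa)
    syt <- pmax(syt, floor_mpa)
  }
  list(sigma_yc = syc, sigma_yt = syt)
}

match_compartment <- function(compartment, n) {
  compartment <- as.character(compartment)
  bad <- !compartment %in% c("cortical", "trabecular")
  if (any(bad))
    stop("unknown tissue compartment: ",
         paste(unique(compartment[bad]), collapse = ", "))
  rep_len(compartment, n)
}

#' Material properties for one density sample
#'
#' Runs the full conversion chain for a radiological density:
#' ash density, apparent density, compartment-specific elastic modulus and
#' yield stresses. Poisson's ratio is fixed at 0.3.
#'
#' @param rho_qct Radiological density, g/cm^3 (vectorised).
#' @param compartment `"trabecular"` or `"cortical"`, recycled.
#' @param ash_app_ratio Ash/apparent density ratio, default 0.6.
#' @param ... Passed to [yield_stresses()].
#' @return A data.frame with columns `compartment`, `rho_qct`, `rho_ash`,
#'   `rho_app` (g/cm^3), `E` (MPa), `nu`, `sigma_yc`, `sigma_yt` (MPa).
#' @export
material_point <- function(rho_qct, compartment, ash_app_ratio = 0.6, ...) {
  n <- length(rho_qct)
  compartment <- match_compartment(compartment, n)
  rho_ash <- ash_density(rho_qct)
  rho_app <- apparent_density(rho_ash, ash_app_ratio)
  trab <- compartment == "trabecular"
  E <- numeric(n)
  if (any(trab))
    E[trab] <- elastic_modulus(app_density_kgm3(rho_app[trab]), "trabecular")
  if (any(!trab))
    E[!trab] <- elastic_modulus(rho_ash[!trab], "cortical")
  ys <- yield_stresses(rho_app, compartment, E, ...)
  data.frame(compartment = compartment, rho_qct = rho_qct,
             rho_ash = rho_ash, rho_app = rho_app, E = E, nu = 0.3,
             sigma_yc = ys$sigma_yc, sigma_yt = ys$sigma_yt)
}

# ---------------------------------------------------------------------------
# Density-image mapping
# ---------------------------------------------------------------------------

#' Rectilinear density image
#'
#' A scalar volumetric-density field sampled on a regular 3D grid, used to
#' assign densities to mesh elements by trilinear interpolation.
#'
#' @param values 3D array of densities, dimension `(nx, ny, nz)`.
#' @param origin Coordinates of the first grid node, length 3, mm.
#' @param spacing Grid spacing per axis, length 3, mm.
#' @param units `"g/cm3"` or `"mg/cm3"`. Images in mg/cm^3 (the volumetric
#'   BMD convention) are converted to g/cm^3 on construction.
#' @return An object of class `density_image`.
#' @export
density_image <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                          units = c("g/cm3", "mg/cm3")) {
  units <- match.arg(units)
  stopifnot(is.array(values), length(dim(values)) == 3,
            length(origin) == 3, length(spacing) == 3, all(spacing > 0))
  if (units == "mg/cm3") {
    values <- values / 1000  # to g/cm^3
  }
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "density_image")
}

#' Trilinear interpolation of a density image
#'
#' @param img A [density_image()].
#' @param points Numeric matrix `n x 3` of query coordinates, mm.
#' @return Interpolated densities, g/cm^3.
#' @export
interp_density <- function(img, points) {
  stopifnot(inherits(img, "density_image"))
  points <- rbind(points)
  dm <- dim(img$values)
  # fractional voxel coordinates (0-based)
  fc <- sweep(sweep(points, 2, img$origin, "-"), 2, img$spacing, "/")
  eps <- 1e-9
  for (k in 1:3) {
    out <- fc[, k] < -eps | fc[, k] > dm[k] - 1 + eps
    if (any(out))
      stop("point(s) ", paste(which(out), collapse = ", "),
           " outside the density-image domain on axis ", k)
    fc[, k] <- pmin(pmax(fc[, k], 0), dm[k] - 1)
  }
  i0 <- pmin(floor(fc), matrix(rep(dm - 2, each = nrow(fc)), ncol = 3))
  i0 <- pmax(i0, 0)
  t <- fc - i0
  v <- img$values
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  c00 <- idx(0, 0, 0) * (1 - t[, 1]) + idx(1, 0, 0) * t[, 1]
  c10 <- idx(0, 1, 0) * (1 - t[, 1]) + idx(1, 1, 0) * t[, 1]
  c01 <- idx(0, 0, 1) * (1 - t[, 1]) + idx(1, 0, 1) * t[, 1]
  c11 <- idx(0, 1, 1) * (1 - t[, 1]) + idx(1, 1, 1) * t[, 1]
  c0 <- c00 * (1 - t[, 2]) + c10 * t[, 2]
  c1 <- c01 * (1 - t[, 2]) + c11 * t[, 2]
  c0 * (1 - t[, 3]) + c1 * t[, 3]
}

#' Map a density field onto mesh elements as material properties
#'
#' Samples the density image at each element centroid (default) or averages
#' it over the 2x2x2 Gauss points, then applies the conversion chain of
#' [material_point()] with the element's tissue-compartment label.
#'
#' @param mesh A [hex_mesh()] with per-element `compartment` labels.
#' @param img A [density_image()] (g/cm^3 after construction), a single
#'   number for a uniform field, or a numeric vector with one density per
#'   element (g/cm^3).
#' @param locus `"centroid"` or `"gauss"`.
#' @param ... Passed to [material_point()].
#' @return Data.frame of element material properties (one row per element)
#'   with an `element_id` column prepended; suitable for CSV export.
#' @export
map_density_field <- function(mesh, img, locus = c("centroid", "gauss"), ...) {
  locus <- match.arg(locus)
  stopifnot(inherits(mesh, "hex_mesh"))
  ne <- nrow(mesh$elements)
  if (is.numeric(img) && length(img) == 1) {
    rho <- rep(img, ne)
  } else if (is.numeric(img)) {
    if (length(img) != ne)
      stop("per-element density vector must have one value per element")
    rho <- img
  } else {
    corner <- array(t(mesh$nodes[t(mesh$elements), ]), dim = c(3, 8, ne))
    if (locus == "centroid") {
      pts <- t(apply(corner, c(1, 3), mean))
      rho <- interp_density(img, pts)
    } else {
      g <- 1 / sqrt(3)
      gp <- as.matrix(expand.grid(x = c(-g, g), y = c(-g, g), z = c(-g, g)))
      rho <- numeric(ne)
      sh <- vapply(seq_len(nrow(gp)), function(i) hex8_shape(gp[i, ]),
                   numeric(8))
      for (q in seq_len(nrow(gp))) {
        pts <- t(apply(corner, 3, function(cc) cc %*% sh[, q]))
        rho <- rho + interp_density(img, pts) / nrow(gp)
      }
    }
  }
  mat <- material_point(rho, mesh$compartment, ...)
  cbind(element_id = seq_len(ne), mat)
}

# trilinear shape functions on [-1,1]^3, standard hex8 corner ordering
hex8_shape <- function(xi) {
  s <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
              ncol = 3, byrow = TRUE)
  (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2]) * (1 + s[, 3] * xi[3]) / 8
}
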
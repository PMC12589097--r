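# ---------------------------------------------------------------------------
# Descriptor extraction from force-displacement curves: strength, the
# origin-anchored continuous bilinear decomposition, and the elastic/plastic
# displacement and energy descriptors.
# ---------------------------------------------------------------------------

check_curve <- function(d, f, strict_monotone = TRUE) {
  if (length(d) != length(f) || length(d) < 2)
    stop("curve needs matching d/f vectors of length >= 2")
  if (any(!is.finite(d)) || any(!is.finite(f))) stop("non-finite curve values")
  if (strict_monotone && any(diff(d) <= 0))
    stop("displacement must be strictly increasing within a phase")
  invisible(TRUE)
}

#' Strength and failure displacement from a loading curve
#'
#' Strength `F0` is the maximum reaction force; `D0` is the displacement at
#' which it occurs (first index on ties).
#'
#' @param d Displacement, mm, strictly increasing.
#' @param f Reaction force, N.
#' @return List with `F0` (N) and `D0` (mm).
#' @export
extract_strength <- function(d, f) {
  check_curve(d, f)
  i <- which.max(f)
  list(F0 = f[i], D0 = d[i])
}

# closed-form SSE of the continuous origin-anchored two-segment fit for a
# fixed breakpoint b: f ~ k1*min(d,b) + k2*max(d-b,0), linear in (k1,k2)
bilinear_sse_at <- function(d, f, b) {
  x1 <- pmin(d, b)
  x2 <- pmax(d - b, 0)
  a11 <- sum(x1 * x1); a12 <- sum(x1 * x2); a22 <- sum(x2 * x2)
  b1 <- sum(x1 * f); b2 <- sum(x2 * f)
  det <- a11 * a22 - a12 * a12
  if (a22 < 1e-12 * a11 || det <= 1e-12 * a11 * a22) {
    k1 <- b1 / a11; k2 <- k1                   # degenerate: single line
  } else {
    k1 <- (a22 * b1 - a12 * b2) / det
    k2 <- (a11 * b2 - a12 * b1) / det
  }
  r <- f - k1 * x1 - k2 * x2
  list(sse = sum(r * r), k1 = k1, k2 = k2)
}

#' Origin-anchored continuous bilinear fit of a loading curve
#'
#' Fits a continuous two-segment piecewise-linear model whose first segment
#' passes through the origin, by least squares: for each candidate
#' breakpoint the two slopes have a closed-form solution, and the breakpoint
#' minimising the total SSE is located on a grid of candidate positions
#' between the 2nd and penultimate samples, then refined by a bracketed
#' 1-D optimisation.
#'
#' @param d Displacement, mm, strictly increasing, truncated at `D0`.
#' @param f Reaction force, N.
#' @param grid_resolution Number of candidate breakpoints, default 100.
#' @return List of class `bilinear_fit`: `k1`, `k2` (N/mm), `D1`, `F1`
#'   (breakpoint), `sse` (N^2), `degenerate` (logical).
#' @export
fit_bilinear <- function(d, f, grid_resolution = 100) {
  check_curve(d, f)
  n <- length(d)
  if (n < 4) {
    k1 <- sum(d * f) / sum(d * d)
    return(structure(list(k1 = k1, k2 = k1, D1 = d[n], F1 = k1 * d[n],
                          sse = sum((f - k1 * d)^2), degenerate = TRUE),
                     class = "bilinear_fit"))
  }
  lo <- d[2]; hi <- d[n - 1]
  bs <- seq(lo, hi, length.out = max(grid_resolution, 3))
  sses <- vapply(bs, function(b) bilinear_sse_at(d, f, b)$sse, numeric(1))
  i <- which.min(sses)
  blo <- bs[max(i - 1, 1)]; bhi <- bs[min(i + 1, length(bs))]
  opt <- stats::optimize(function(b) bilinear_sse_at(d, f, b)$sse,
                         c(blo, bhi), tol = 1e-10 * (hi - lo) + 1e-12)
  b <- if (opt$objective <= sses[i]) opt$minimum else bs[i]
  sol <- bilinear_sse_at(d, f, b)
  degen <- abs(sol$k2 - sol$k1) <= 1e-8 * max(abs(sol$k1), 1)
  if (degen) { b <- d[n]; sol$k2 <- sol$k1 }
  structure(list(k1 = sol$k1, k2 = sol$k2, D1 = b, F1 = sol$k1 * b,
                 sse = sol$sse, degenerate = degen),
            class = "bilinear_fit")
}

#' Nonlinear energy: trapezoidal area under the loading curve
#'
#' @param d Displacement, mm, strictly increasing, truncated at `D0`.
#' @param f Reaction force, N.
#' @return Energy in N.mm.
#' @export
nonlinear_energy <- function(d, f) {
  check_curve(d, f)
  sum(0.5 * (f[-1] + f[-length(f)]) * diff(d))
}

#' Linear-elastic force, displacement and energy from a bilinear fit
#'
#' The linear-elastic energy is the triangle area under the first segment,
#' \eqn{E_{lin} = F_1 D_1 / 2}.
#'
#' @param fit A `bilinear_fit` from [fit_bilinear()].
#' @return List with `F1` (N), `D1` (mm), `E_linear` (N.mm).
#' @export
linear_elastic_quantities <- function(fit) {
  stopifnot(inherits(fit, "bilinear_fit"))
  list(F1 = fit$F1, D1 = fit$D1, E_linear = 0.5 * fit$F1 * fit$D1)
}

#' Nonlinear (post-yield) deformation
#'
#' @param D0 Failure displacement, mm.
#' @param D1 Linear-elastic displacement, mm; must not exceed `D0`.
#' @return `D2 = D0 - D1`, mm.
#' @export
nonlinear_deformation <- function(D0, D1) {
  if (any(D1 > D0 + 1e-12)) stop("D1 exceeds D0")
  D0 - D1
}

#' Residual displacement and dissipated/residual energies
#'
#' With an unloading curve: `D3` is the zero-force intercept of the
#' unloading branch (linear interpolation between the bracketing samples),
#' the dissipated energy is the area between loading and unloading curves,
#' and the residual energy follows from the identity
#' `E_residual = E_nonlinear - E_dissipated`.
#' Without an unloading curve the elastic-slope fallback is used:
#' `D3 = D0 - F0/k1`, with the recovered energy taken as the elastic
#' triangle `F0 (D0 - D3) / 2`.
#'
#' @param d,f Loading curve truncated at `D0` (strictly increasing `d`).
#' @param d_un,f_un Optional unloading curve from `D0` down to (or across)
#'   zero force, with strictly decreasing `d_un`.
#' @param k1 Elastic slope (N/mm) for the fallback path.
#' @return List with `D3` (mm), `E_dissipated`, `E_residual`,
#'   `E_nonlinear` (N.mm).
#' @export
residual_quantities <- function(d, f, d_un = NULL, f_un = NULL, k1 = NULL) {
  check_curve(d, f)
  E_nl <- nonlinear_energy(d, f)
  n <- length(d)
  F0 <- f[n]; D0 <- d[n]
  if (is.null(d_un)) {
    if (is.null(k1)) stop("need an unloading curve or an elastic slope k1")
    if (k1 <= 0) stop("k1 must be positive")
    D3 <- max(D0 - F0 / k1, 0)
    E_rec <- 0.5 * F0 * (D0 - D3)
    E_dis <- E_nl - E_rec
    return(list(D3 = D3, E_dissipated = E_dis, E_residual = E_rec,
                E_nonlinear = E_nl))
  }
  if (length(d_un) != length(f_un) || length(d_un) < 2)
    stop("invalid unloading curve")
  if (any(diff(d_un) >= 0))
    stop("unloading displacement must be strictly decreasing")
  if (min(f_un) > 0)
    stop("unloading curve does not reach zero force; cannot bracket D3")
  k <- which(f_un <= 0)[1]
  if (k == 1) stop("unloading curve starts at non-positive force")
  D3 <- d_un[k - 1] + (d_un[k] - d_un[k - 1]) *
    (0 - f_un[k - 1]) / (f_un[k] - f_un[k - 1])
  du <- c(d_un[seq_len(k - 1)], D3)
  fu <- c(f_un[seq_len(k - 1)], 0)
  E_rec <- -sum(0.5 * (fu[-1] + fu[-length(fu)]) * diff(du))
  E_dis <- E_nl - E_rec
  list(D3 = D3, E_dissipated = E_dis, E_residual = E_nl - E_dis,
       E_nonlinear = E_nl)
}

#' Canonical descriptor column names
#'
#' Fixed column order of the ten mechanical descriptors used throughout the
#' package and in exported CSV files.
#' @return Character vector of length 10.
#' @export
descriptor_names <- function() {
  c("F0_N", "D0_mm", "E_nl_Nmm", "F1_N", "D1_mm", "E_lin_Nmm",
    "D2_mm", "D3_mm", "E_dis_Nmm", "E_res_Nmm")
}

#' Extract the full descriptor set from force-displacement curves
#'
#' Runs strength extraction, truncation at the force peak, the bilinear
#' decomposition, the energy integrals, and the residual quantities (from
#' the unloading curve when given, otherwise the elastic-slope fallback).
#'
#' @param d,f Loading curve (strictly increasing `d`, starting at 0).
#' @param d_un,f_un Optional unloading curve.
#' @param grid_resolution Breakpoint grid for [fit_bilinear()].
#' @return One-row data.frame with the columns of [descriptor_names()].
#' @export
extract_descriptors <- function(d, f, d_un = NULL, f_un = NULL,
                                grid_resolution = 100) {
  s <- extract_strength(d, f)
  keep <- d <= s$D0 + 1e-12
  dl <- d[keep]; fl <- f[keep]
  fit <- fit_bilinear(dl, fl, grid_resolution)
  lin <- linear_elastic_quantities(fit)
  D2 <- nonlinear_deformation(s$D0, lin$D1)
  res <- residual_quantities(dl, fl, d_un, f_un, k1 = fit$k1)
  data.frame(F0_N = s$F0, D0_mm = s$D0, E_nl_Nmm = res$E_nonlinear,
             F1_N = lin$F1, D1_mm = lin$D1, E_lin_Nmm = lin$E_linear,
             D2_mm = D2, D3_mm = res$D3, E_dis_Nmm = res$E_dissipated,
             E_res_Nmm = res$E_residual)
}

#' Read / write force-displacement curve CSV files
#'
#' Curves use the fixed header `displacement_mm,force_N,phase`.
#' @param path CSV path.
#' @param curve Data.frame with those columns.
#' @return `read_curve_csv` returns the data.frame; `write_curve_csv`
#'   returns `path` invisibly.
#' @export
read_curve_csv <- function(path) {
  cv <- utils::read.csv(path)
  need <- c("displacement_mm", "force_N")
  if (!all(need %in% names(cv)))
    stop("curve CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(cv$phase)) cv$phase <- "loading"
  cv
}

#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
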
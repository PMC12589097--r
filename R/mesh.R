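# ---------------------------------------------------------------------------
# Hexahedral mesh container, validation, and VTK legacy ASCII I/O.
# Node sets are the three boundary groups the sideways-fall model needs:
# shaft_end, trochanter_surface, head_surface.
# ---------------------------------------------------------------------------

#' Hexahedral mesh with tissue compartments and boundary node sets
#'
#' @param nodes Numeric matrix `n x 3`, node coordinates in mm.
#' @param elements Integer matrix `ne x 8`, 1-based connectivity in standard
#'   hex8 corner order (bottom face counter-clockwise, then top face).
#' @param compartment Character vector length `ne`, `"cortical"` or
#'   `"trabecular"` per element.
#' @param node_sets Named list of integer node-index vectors; the sideways
#'   fall model requires `shaft_end`, `trochanter_surface`, `head_surface`.
#' @param validate Check connectivity, Jacobians, and node-set disjointness.
#' @return An object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, elements, compartment = NULL, node_sets = list(),
                     validate = TRUE) {
  nodes <- as.matrix(nodes)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elements) == 8)
  if (is.null(compartment)) compartment <- rep("trabecular", nrow(elements))
  compartment <- match_compartment(compartment, nrow(elements))
  m <- structure(list(nodes = nodes, elements = elements,
                      compartment = compartment, node_sets = node_sets),
                 class = "hex_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("hex_mesh:", nrow(x$nodes), "nodes,", nrow(x$elements), "hex8 elements\n")
  cat("  compartments:",
      paste(names(table(x$compartment)), table(x$compartment),
            collapse = ", "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets),
                              lengths(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

validate_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (any(mesh$elements < 1L) || any(mesh$elements > n))
    stop("element connectivity references nodes outside 1..", n)
  vols <- hex_volumes(mesh)
  if (any(vols <= 0))
    stop("non-positive Jacobian in element(s) ",
         paste(utils::head(which(vols <= 0), 5), collapse = ", "))
  req <- intersect(names(mesh$node_sets),
                   c("shaft_end", "trochanter_surface", "head_surface"))
  for (nm in req) {
    s <- mesh$node_sets[[nm]]
    if (length(s) == 0) stop("node set '", nm, "' is empty")
    if (any(s < 1L | s > n)) stop("node set '", nm, "' out of range")
  }
  if (length(req) > 1) {
    for (i in seq_along(req)[-1]) for (j in seq_len(i - 1)) {
      if (length(intersect(mesh$node_sets[[req[i]]],
                           mesh$node_sets[[req[j]]])))
        stop("node sets '", req[i], "' and '", req[j], "' overlap")
    }
  }
  invisible(TRUE)
}

#' Element volumes (mm^3) by 2x2x2 Gauss quadrature
#' @param mesh A [hex_mesh()].
#' @return Numeric vector of element volumes.
#' @export
hex_volumes <- function(mesh) {
  as.numeric(fe_hex_volumes(mesh$nodes, mesh$elements))
}

# ---------------------------------------------------------------------------
# VTK legacy ASCII unstructured grid I/O. Node sets are encoded as an
# integer POINT_DATA field (bit flags), compartment as CELL_DATA.
# ---------------------------------------------------------------------------

#' Write a hex mesh (plus optional element density) to legacy VTK ASCII
#'
#' @param mesh A [hex_mesh()].
#' @param path Output file path.
#' @param element_density Optional per-element density (g/cm^3) written as a
#'   CELL_DATA scalar field `density`.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, element_density = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("femofall hex mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS ", nrow(mesh$nodes), " double")
  writeLines(apply(format(mesh$nodes, digits = 10, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  ne <- nrow(mesh$elements)
  w("CELLS ", ne, " ", ne * 9)
  writeLines(apply(cbind(8L, mesh$elements - 1L), 1, paste, collapse = " "),
             con)
  w("CELL_TYPES ", ne)
  writeLines(rep("12", ne), con)  # VTK_HEXAHEDRON
  # point data: node-set bit flags (1 shaft, 2 trochanter, 4 head)
  flags <- integer(nrow(mesh$nodes))
  bits <- c(shaft_end = 1L, trochanter_surface = 2L, head_surface = 4L)
  for (nm in names(bits))
    if (!is.null(mesh$node_sets[[nm]]))
      flags[mesh$node_sets[[nm]]] <- flags[mesh$node_sets[[nm]]] + bits[[nm]]
  w("POINT_DATA ", nrow(mesh$nodes))
  w("SCALARS node_set_flags int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(flags), con)
  w("CELL_DATA ", ne)
  w("SCALARS compartment int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(ifelse(mesh$compartment == "cortical", 1L, 0L)), con)
  if (!is.null(element_density)) {
    stopifnot(length(element_density) == ne)
    w("SCALARS density double 1")
    w("LOOKUP_TABLE default")
    writeLines(format(element_density, digits = 10, trim = TRUE), con)
  }
  invisible(path)
}

#' Read a hex mesh written by [write_vtk_mesh()]
#'
#' Minimal legacy VTK ASCII reader for unstructured grids whose cells are all
#' hexahedra, recovering node sets and compartments from the flag fields.
#'
#' @param path Path to a legacy VTK ASCII file.
#' @return A list with `mesh` (a [hex_mesh()]) and `element_density`
#'   (numeric or NULL).
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  toks <- function(l) strsplit(trimws(l), "\\s+")[[1]]
  i <- grep("^POINTS", lines)[1]
  np <- as.integer(toks(lines[i])[2])
  vals <- scan(text = lines[(i + 1):length(lines)], what = double(),
               n = np * 3, quiet = TRUE)
  nodes <- matrix(vals, ncol = 3, byrow = TRUE)
  i <- grep("^CELLS", lines)[1]
  ne <- as.integer(toks(lines[i])[2])
  cv <- scan(text = lines[(i + 1):length(lines)], what = integer(),
             n = ne * 9, quiet = TRUE)
  cv <- matrix(cv, ncol = 9, byrow = TRUE)
  if (any(cv[, 1] != 8L)) stop("non-hexahedral cell in VTK file")
  elements <- cv[, -1, drop = FALSE] + 1L
  read_scalar <- function(name, n, what = double()) {
    j <- grep(paste0("^SCALARS ", name, " "), lines)
    if (!length(j)) return(NULL)
    scan(text = lines[(j[1] + 2):length(lines)], what = what, n = n,
         quiet = TRUE)
  }
  flags <- read_scalar("node_set_flags", np, integer())
  node_sets <- list()
  if (!is.null(flags)) {
    bits <- c(shaft_end = 1L, trochanter_surface = 2L, head_surface = 4L)
    for (nm in names(bits)) {
      s <- which(bitwAnd(flags, bits[[nm]]) > 0L)
      if (length(s)) node_sets[[nm]] <- s
    }
  }
  comp <- read_scalar("compartment", ne, integer())
  compartment <- if (is.null(comp)) NULL else
    ifelse(comp == 1L, "cortical", "trabecular")
  dens <- read_scalar("density", ne)
  list(mesh = hex_mesh(nodes, elements, compartment, node_sets),
       element_density = dens)
}

# structured brick mesh helper: nx x ny x nz elements on [0,Lx]x[0,Ly]x[0,Lz]
brick_mesh <- function(nx, ny, nz, Lx, Ly, Lz) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  zs <- seq(0, Lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k) i + (nx + 1) * (j - 1) + (nx + 1) * (ny + 1) * (k - 1)
  el <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    el[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                 nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                 nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  list(nodes = nodes, elements = el, dims = c(nx, ny, nz))
}
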
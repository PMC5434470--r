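# Quasi-static extracellular potential over tissue + blood + catheter:
# div((sigma_i + sigma_e) grad phi_e) = -div(sigma_i grad Vm), with
# homogeneous Neumann boundaries and the zero-mean uniqueness constraint
# int_Omega phi_e dOmega = 0.

#' Assemble the extracellular (elliptic) operator
#'
#' Seven-point finite-volume discretization of
#' -div((sigma_i + sigma_e) grad .) over the full domain with
#' face-harmonic conductivity averaging and homogeneous Neumann outer
#' boundaries. The operator is symmetric positive semidefinite with
#' nullspace equal to the constants; the companion intracellular operator
#' -div(sigma_i grad .) used for the right-hand side is assembled
#' alongside.
#'
#' The mini-electrode insulation is physically much thinner (about
#' 0.1-0.2 mm) than a voxel, so it is discretized as a sub-voxel film:
#' the insulation collar voxels are filled with electrode metal in the
#' operator, and the faces between each ME and its collar carry zero
#' conductance. This keeps the aperture in the surrounding metal shield
#' at the true 1 mm ME diameter instead of growing it by a full voxel of
#' insulator on either side (which at coarse `h` would exaggerate how
#' much of the field the ME sees and inflate ME-vs-distal electrogram
#' differences). The stored per-voxel `sigma_e` of the grid is not
#' modified.
#'
#' @param grid A `labeled_grid`.
#' @return An `egm_operator` object holding the face conductances.
#' @export
assemble_operator <- function(grid) {
  stopifnot(inherits(grid, "labeled_grid"))
  labs <- egm_labels()
  se <- grid$sigma_e
  iso <- grid$label == labs[["isolation"]]
  se[iso] <- 7000
  st <- grid$sigma_i + se
  if (any(!is.finite(st)) || any(st <= 0))
    stop("every voxel needs positive total conductivity")
  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  h <- grid$h
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  me <- grid$label %in% c(labs[["electrode_me1"]], labs[["electrode_me2"]],
                          labs[["electrode_me3"]])
  me <- array(me, grid$dims)
  film <- function(a_me, a_iso, b_me, b_iso) (a_me & b_iso) | (b_me & a_iso)
  face <- function(s, insulate) {
    fx <- harm(s[-nx, , , drop = FALSE], s[-1, , , drop = FALSE])
    fy <- harm(s[, -ny, , drop = FALSE], s[, -1, , drop = FALSE])
    fz <- harm(s[, , -nz, drop = FALSE], s[, , -1, drop = FALSE])
    if (insulate) {
      fx[film(me[-nx, , ], iso[-nx, , ], me[-1, , ], iso[-1, , ])] <- 0
      fy[film(me[, -ny, ], iso[, -ny, ], me[, -1, ], iso[, -1, ])] <- 0
      fz[film(me[, , -nz], iso[, , -nz], me[, , -1], iso[, , -1])] <- 0
    }
    list(gx = as.vector(fx) * h, gy = as.vector(fy) * h,
         gz = as.vector(fz) * h)
  }
  structure(c(list(dims = grid$dims, h = h), face(st, TRUE),
              stats::setNames(face(grid$sigma_i, FALSE),
                              c("gxi", "gyi", "gzi"))),
            class = "egm_operator")
}

#' Apply the extracellular operator
#'
#' @param op An `egm_operator`.
#' @param x Numeric vector over the full domain.
#' @param which `"total"` applies -div((sigma_i+sigma_e) grad .),
#'   `"intra"` applies -div(sigma_i grad .).
#' @return The matrix-vector product as a numeric vector.
#' @export
apply_operator <- function(op, x, which = c("total", "intra")) {
  which <- match.arg(which)
  if (which == "total")
    cpp_stencil_apply(op$dims, op$gx, op$gy, op$gz, x)
  else
    cpp_stencil_apply(op$dims, op$gxi, op$gyi, op$gzi, x)
}

# embed a tissue-box Vm vector into the full domain (rest elsewhere)
embed_vm <- function(op, grid, vm_tissue, rest = -86.9) {
  full <- array(rest, op$dims)
  full[, , grid$k_tissue] <- vm_tissue
  as.vector(full)
}

#' Solve for the extracellular potential at one instant
#'
#' Solves the pure-Neumann elliptic problem with the transmembrane
#' voltage as bidomain source, using conjugate gradients with constants
#' deflated out of the right-hand side and iterates (which enforces the
#' zero-mean uniqueness constraint).
#'
#' @param op An `egm_operator` from [assemble_operator()].
#' @param grid The `labeled_grid` the operator was assembled from.
#' @param vm Transmembrane voltage over the tissue box (vector or 3-d
#'   array), mV.
#' @param tol Relative residual tolerance.
#' @param maxit Iteration cap.
#' @return An `extracellular_field`: `phi` (3-d array, mV, zero mean),
#'   `relres`, `iters`.
#' @export
solve_phie <- function(op, grid, vm, tol = 1e-9, maxit = 10000) {
  b <- -apply_operator(op, embed_vm(op, grid, vm), "intra")
  sol <- cpp_pcg_neumann(op$dims, op$gx, op$gy, op$gz, b, tol, maxit,
                         numeric(0))
  if (sol$relres > 1e-6)
    stop(sprintf("extracellular solve did not converge (relres = %.2e)",
                 sol$relres))
  structure(list(phi = array(sol$x, op$dims), relres = sol$relres,
                 iters = sol$iters, dims = op$dims, h = op$h),
            class = "extracellular_field")
}

# indicator (as weights summing to 1) of an electrode label
label_weights <- function(grid, label) {
  code <- egm_labels()[[label]]
  if (is.null(code)) stop("unknown label: ", label)
  m <- as.vector(grid$label == code)
  if (!any(m)) stop("label '", label, "' is absent from the grid")
  m / sum(m)
}

# weights of the reference: blood voxels in the top 1 mm of the domain
# (catheter voxels are excluded by construction since they are not blood)
reference_weights <- function(grid, layer_mm = 1) {
  labs <- egm_labels()
  zs <- axis_centers(grid$dims[3], grid$h)
  top <- zs > grid$dims[3] * grid$h - layer_mm
  m <- grid$label == labs[["blood"]]
  m[, , !top] <- FALSE
  m <- as.vector(m)
  if (!any(m)) stop("empty reference blood layer")
  m / sum(m)
}

#' Lead-field weight vector of an electrode
#'
#' By reciprocity, the referenced unipolar electrogram
#' phi_e(electrode) - phi_e(reference) equals w' Vm for a weight vector w
#' obtained from one adjoint elliptic solve: A z = c with c the electrode
#' minus reference averaging vector, then w = -A_i z restricted to the
#' tissue box. This turns per-sample field solves into a dot product and
#' is exact up to solver tolerance.
#'
#' @param op An `egm_operator`.
#' @param grid The corresponding `labeled_grid`.
#' @param electrode_label Label name, e.g. `"electrode_distal"`.
#' @param tol,maxit Solver controls.
#' @param warm_start Optional initial guess for the adjoint solution
#'   (e.g. the solution for a neighbouring pose).
#' @return List with `w` (weights over the tissue box), `z` (adjoint
#'   solution over the full domain) and solver diagnostics.
#' @export
lead_vector <- function(op, grid, electrode_label, tol = 1e-9,
                        maxit = 20000, warm_start = NULL) {
  cvec <- label_weights(grid, electrode_label) - reference_weights(grid)
  sol <- cpp_pcg_neumann(op$dims, op$gx, op$gy, op$gz, cvec, tol, maxit,
                         warm_start %||% numeric(0))
  if (sol$relres > 1e-6)
    stop(sprintf("lead-field solve did not converge (relres = %.2e)",
                 sol$relres))
  w_full <- -apply_operator(op, sol$x, "intra")
  w <- array(w_full, op$dims)[, , grid$k_tissue]
  list(w = as.vector(w), z = sol$x, iters = sol$iters,
       relres = sol$relres)
}

#' Electrode equipotentiality
#'
#' Spread (max - min) of the extracellular potential across the voxels of
#' one electrode. The 7000 S/m electrode conductivity keeps this spread
#' far below the signal amplitude.
#'
#' @param field An `extracellular_field`.
#' @param grid The corresponding `labeled_grid`.
#' @param electrode_label Label name.
#' @return Potential spread in mV.
#' @export
electrode_equipotentiality <- function(field, grid, electrode_label) {
  code <- egm_labels()[[electrode_label]]
  if (is.null(code)) stop("unknown label: ", electrode_label)
  m <- as.vector(grid$label == code)
  if (!any(m)) stop("label '", electrode_label, "' absent from grid")
  ph <- as.vector(field$phi)[m]
  max(ph) - min(ph)
}

#' Materialize the operator as a sparse matrix
#'
#' Intended for small grids (tests, inspection); the solvers never form
#' the matrix.
#'
#' @param op An `egm_operator`.
#' @param which `"total"` or `"intra"`.
#' @return A `Matrix::sparseMatrix`.
#' @export
operator_matrix <- function(op, which = c("total", "intra")) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("the Matrix package is required")
  which <- match.arg(which)
  nx <- op$dims[1]; ny <- op$dims[2]; nz <- op$dims[3]
  n <- nx * ny * nz
  gx <- if (which == "total") op$gx else op$gxi
  gy <- if (which == "total") op$gy else op$gyi
  gz <- if (which == "total") op$gz else op$gzi
  idx <- function(i, j, k) ((k - 1) * ny + (j - 1)) * nx + i
  ex <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny), k = seq_len(nz))
  ey <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1), k = seq_len(nz))
  ez <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz - 1))
  ia <- c(idx(ex$i, ex$j, ex$k), idx(ey$i, ey$j, ey$k), idx(ez$i, ez$j, ez$k))
  ib <- c(idx(ex$i + 1, ex$j, ex$k), idx(ey$i, ey$j + 1, ey$k),
          idx(ez$i, ez$j, ez$k + 1))
  g <- c(gx, gy, gz)
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = -c(g, g),
                            dims = c(n, n))
  Matrix::Diagonal(n, -Matrix::rowSums(A)) + A
}
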
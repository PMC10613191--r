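#' Alignment of the orthotropy axes with the principal strain directions
#'
#' Trajectorial-theory diagnostic.  At every quadrature point the raw
#' difference between the orientation angle and the major principal strain
#' angle is folded modulo pi/2 (the two orthotropy axes and the two
#' eigendirections are unordered orthogonal line pairs, so a pi/2 offset
#' is the same alignment with the labels swapped) and mapped to
#' `Delta in [0, pi/4]`.  Points with near-degenerate strain eigenvalues
#' (no well-defined eigenframe) are masked.  Fractions are quadrature-area
#' weighted.
#'
#' @param mesh a [build_mesh()] object.
#' @param psi_qp orientation angles at quadrature points (rad).
#' @param e_qp Voigt strains at quadrature points (3 x nqp), e.g. from an
#'   equilibrium solution.
#' @param align_tol alignment tolerance in rad (default 10 degrees).
#' @param mask_rel eigenvalue-gap masking threshold relative to the
#'   field-wide maximum eigenvalue magnitude.
#' @return Object of class `alignment_report`: `Delta` (rad, `NA` where
#'   masked), `aligned_fraction`, `misaligned_fraction`, `masked_fraction`
#'   (summing to one), and the thresholds used.
#' @export
angle_difference_field <- function(mesh, psi_qp, e_qp,
                                   align_tol = 10 * pi / 180,
                                   mask_rel = 1e-2) {
  pr <- .principal_angle_qp(e_qp)
  masked <- pr$gap < mask_rel * max(pr$lam_max)
  delta <- (psi_qp - pr$angle) %% (pi / 2)
  delta <- ifelse(delta > pi / 4, delta - pi / 2, delta)   # (-pi/4, pi/4]
  Delta <- abs(delta)
  Delta[masked] <- NA_real_
  w <- mesh$w
  wtot <- sum(w)
  wm <- sum(w[masked])
  wa <- sum(w[!masked & Delta < align_tol], na.rm = TRUE)
  rep <- list(Delta = Delta,
              aligned_fraction = wa / max(wtot - wm, 1e-300),
              misaligned_fraction = 1 - wa / max(wtot - wm, 1e-300),
              masked_fraction = wm / wtot,
              align_tol = align_tol, mask_rel = mask_rel)
  class(rep) <- "alignment_report"
  rep
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(paste0("<alignment_report> aligned %.1f%% | misaligned ",
                     "%.1f%% of unmasked area (tol %.1f deg); masked %.1f%%\n"),
              100 * x$aligned_fraction, 100 * x$misaligned_fraction,
              x$align_tol * 180 / pi, 100 * x$masked_fraction))
  invisible(x)
}

# L2-project a quadrature-point scalar onto the spline basis.
.project_qp <- function(mesh, f_qp) {
  M <- Matrix::crossprod(mesh$N, mesh$w * mesh$N)
  rhs <- as.vector(Matrix::crossprod(mesh$N, mesh$w * f_qp))
  as.vector(Matrix::solve(M, rhs))
}

#' Continuous direction-field evaluator from quadrature-point angles
#'
#' Angles defined modulo pi cannot be interpolated directly; the doubled
#' director components `cos(2 psi)`, `sin(2 psi)` are L2-projected onto the
#' spline basis and the angle is recovered as `atan2 / 2`.
#'
#' @param mesh a [build_mesh()] object.
#' @param angle_qp line-field angles at quadrature points (rad, mod pi).
#' @return Function `(x, y) -> angle` (vectorized over points).
#' @export
direction_field <- function(mesh, angle_qp) {
  c2 <- .project_qp(mesh, cos(2 * angle_qp))
  s2 <- .project_qp(mesh, sin(2 * angle_qp))
  function(x, y) {
    E <- .eval_matrix(mesh, x, y)
    0.5 * atan2(as.vector(E %*% s2), as.vector(E %*% c2))
  }
}

#' Streamlines of a line field
#'
#' Integrates curves tangent to a direction field defined modulo pi
#' (orientation axes, isostatic lines).  At every step the branch of the
#' +/- direction closest to the previous step is taken, so the line field
#' needs no global orientation; integration runs both ways from the seed
#' and stops at the domain boundary.
#'
#' @param mesh a [build_mesh()] object.
#' @param field function `(x, y) -> angle` (see [direction_field()]).
#' @param seeds matrix or data.frame with columns `x`, `y` (inside the
#'   domain).
#' @param step arc-length step in m.
#' @param max_steps per-direction step budget.
#' @return List of polylines (two-column matrices), one per seed.
#' @export
field_streamlines <- function(mesh, field, seeds, step = NULL,
                              max_steps = 2000L) {
  seeds <- as.matrix(seeds)
  if (is.null(step)) step <- min(mesh$Lx / mesh$nx, mesh$Ly / mesh$ny) / 2
  inside <- function(p) p[1] >= 0 && p[1] <= mesh$Lx &&
    p[2] >= 0 && p[2] <= mesh$Ly
  # shorten the segment p -> q so it ends on the domain boundary
  clip_to_boundary <- function(p, q) {
    t <- 1
    if (q[1] < 0) t <- min(t, (0 - p[1]) / (q[1] - p[1]))
    if (q[1] > mesh$Lx) t <- min(t, (mesh$Lx - p[1]) / (q[1] - p[1]))
    if (q[2] < 0) t <- min(t, (0 - p[2]) / (q[2] - p[2]))
    if (q[2] > mesh$Ly) t <- min(t, (mesh$Ly - p[2]) / (q[2] - p[2]))
    p + t * (q - p)
  }
  trace_one <- function(p0, sgn) {
    pts <- list()
    p <- p0
    dir_prev <- NULL
    for (k in seq_len(max_steps)) {
      a <- field(p[1], p[2])
      v <- c(cos(a), sin(a))
      if (is.null(dir_prev)) v <- sgn * v
      else if (sum(v * dir_prev) < 0) v <- -v
      # Heun step with sign-consistent midpoint direction
      pm <- p + step * v
      if (!inside(pm)) { pts[[k]] <- clip_to_boundary(p, pm); break }
      am <- field(pm[1], pm[2])
      vm <- c(cos(am), sin(am))
      if (sum(vm * v) < 0) vm <- -vm
      pn <- p + step * (v + vm) / 2
      if (!inside(pn)) { pts[[k]] <- clip_to_boundary(p, pn); break }
      pts[[k]] <- pn
      dir_prev <- (v + vm) / 2
      p <- pn
    }
    if (length(pts) == 0L) matrix(numeric(0), 0, 2)
    else do.call(rbind, pts)
  }
  out <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    p0 <- as.numeric(seeds[i, 1:2])
    if (!inside(p0)) stop("seed outside domain")
    fwd <- trace_one(p0, +1)
    bwd <- trace_one(p0, -1)
    out[[i]] <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                      matrix(p0, 1, 2), fwd)
  }
  out
}

# Sample all state fields on a regular (nx+1) x (ny+1) corner lattice.
.sample_lattice <- function(mesh, state, p) {
  xs <- seq(0, mesh$Lx, length.out = mesh$nx + 1)
  ys <- seq(0, mesh$Ly, length.out = mesh$ny + 1)
  X <- rep(xs, times = length(ys))
  Y <- rep(ys, each = length(xs))
  Ev <- .eval_matrix(mesh, X, Y)
  ncp <- mesh$ncp
  val <- function(qp_field) as.vector(Ev %*% .project_qp(mesh, qp_field))
  f <- .qp_fields(mesh, state$d)
  gamma <- .wrap_half(f$theta - state$psi)
  sh <- .shares_qp(f$e, state$psi, state$mu, state$beta1, state$beta2)
  al <- angle_difference_field(mesh, state$psi, f$e)
  Delta_fill <- ifelse(is.na(al$Delta), 0, al$Delta)
  list(x = X, y = Y, nx = length(xs), ny = length(ys),
       fields = list(
         u1 = as.vector(Ev %*% state$d[seq_len(ncp)]),
         u2 = as.vector(Ev %*% state$d[ncp + seq_len(ncp)]),
         psi = val(state$psi), gamma = val(gamma),
         mu = val(state$mu), beta1 = val(state$beta1),
         beta2 = val(state$beta2),
         S_mu = as.vector(Ev %*% state$S$mu),
         S_beta1 = as.vector(Ev %*% state$S$beta1),
         S_beta2 = as.vector(Ev %*% state$S$beta2),
         U_mu = val(sh$mu), U_beta1 = val(sh$beta1), U_beta2 = val(sh$beta2),
         Delta = val(Delta_fill)))
}

#' Export a snapshot to a VTK file plus CSV summary
#'
#' Writes a legacy-ASCII VTK unstructured grid (quad cells on the element
#' corner lattice) with all state fields as point data, and appends one row
#' of summary statistics (time, energy, alignment fractions, field extrema)
#' to a CSV file.
#'
#' @param mesh a [build_mesh()] object.
#' @param state a simulation state or trajectory snapshot holding `d`,
#'   `psi`, `mu`, `beta1`, `beta2`, `S` and `time`.
#' @param p the scenario's [moduli_set()].
#' @param path output VTK file path.
#' @param csv_path optional CSV summary path (created with a header if
#'   absent).
#' @return Invisibly, the VTK path.
#' @export
export_fields <- function(mesh, state, p, path, csv_path = NULL) {
  sm <- .sample_lattice(mesh, state, p)
  npts <- length(sm$x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("osteoadapt snapshot t=%.8g", state$time %||% NA),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", npts)), con)
  writeLines(sprintf("%.10g %.10g 0", sm$x, sm$y), con)
  nxl <- sm$nx; nyl <- sm$ny
  ncell <- (nxl - 1) * (nyl - 1)
  writeLines(sprintf("CELLS %d %d", ncell, 5 * ncell), con)
  for (j in seq_len(nyl - 1)) {
    i0 <- (j - 1) * nxl + seq_len(nxl - 1) - 1     # 0-based
    writeLines(sprintf("4 %d %d %d %d", i0, i0 + 1, i0 + 1 + nxl, i0 + nxl),
               con)
  }
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(rep("9", ncell), con)                  # VTK_QUAD
  writeLines(sprintf("POINT_DATA %d", npts), con)
  for (nm in names(sm$fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", sm$fields[[nm]]), con)
  }
  if (!is.null(csv_path)) {
    f <- .qp_fields(mesh, state$d)
    al <- angle_difference_field(mesh, state$psi, f$e)
    en <- stored_energy(mesh, state$d, state$psi, p, state$mu, state$beta1,
                        state$beta2)
    row <- data.frame(time = state$time %||% NA_real_, energy = en,
                      aligned_fraction = al$aligned_fraction,
                      masked_fraction = al$masked_fraction,
                      mu_min = min(state$mu), mu_max = max(state$mu),
                      beta1_min = min(state$beta1),
                      beta1_max = max(state$beta1),
                      beta2_min = min(state$beta2),
                      beta2_max = max(state$beta2),
                      S_mu_max = max(state$S$mu),
                      S_beta1_max = max(state$S$beta1),
                      S_beta2_max = max(state$S$beta2))
    utils::write.table(row, csv_path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(csv_path),
                       append = file.exists(csv_path))
  }
  invisible(path)
}

#' Read point-data arrays back from an exported VTK file
#'
#' Minimal reader for the files written by [export_fields()] (round-trip
#' checks and downstream scripting).
#'
#' @param path VTK file from [export_fields()].
#' @return List with `points` (n x 2) and `fields` (named list of numeric
#'   vectors).
#' @export
read_vtk_fields <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)
  npts <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + npts)], function(s)
    as.numeric(strsplit(trimws(s), " +")[[1]])))[, 1:2, drop = FALSE]
  fields <- list()
  isc <- grep("^SCALARS", ln)
  for (k in isc) {
    nm <- strsplit(ln[k], " ")[[1]][2]
    fields[[nm]] <- as.numeric(ln[(k + 2):(k + 1 + npts)])
  }
  list(points = pts, fields = fields)
}
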
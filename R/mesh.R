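#' C1-continuous structured B-spline mesh of a rectangle
#'
#' Tensor-product B-spline discretization of `[0, Lx] x [0, Ly]` with open
#' uniform knot vectors.  Degree >= 2 gives global C^(degree-1) continuity,
#' so second derivatives of the displacement are square integrable as the
#' strain-gradient energy requires.  The constructor precomputes sparse
#' evaluation operators (values, gradients, Hessians) at tensor-product
#' Gauss points, the strain and Hessian interpolation matrices used by the
#' equilibrium assembly, and edge quadrature tables for tractions, double
#' forces and pin contact.
#'
#' @param Lx,Ly domain lengths in m.
#' @param nx,ny element counts per direction.
#' @param degree spline degree (>= 1; >= 2 needed for second-gradient terms).
#' @param nq 1D Gauss points per element per direction (2, 3 or 4).
#' @return Object of class `bone_mesh`.
#' @export
build_mesh <- function(Lx, Ly, nx, ny, degree = 2, nq = 3) {
  stopifnot(Lx > 0, Ly > 0, nx >= 1, ny >= 1, degree >= 1, nq %in% 2:4)
  gl <- switch(as.character(nq),
               "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
               "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                          w = c(5, 8, 5) / 9),
               "4" = list(x = c(-0.8611363115940526, -0.3399810435848563,
                                0.3399810435848563, 0.8611363115940526),
                          w = c(0.3478548451374538, 0.6521451548625461,
                                0.6521451548625461, 0.3478548451374538)))
  dir1d <- function(L, nel) {
    brk <- seq(0, L, length.out = nel + 1)
    knots <- c(rep(0, degree), brk, rep(L, degree))
    ncp <- nel + degree
    hw <- diff(brk) / 2
    xq <- as.vector(vapply(seq_len(nel), function(e)
      (brk[e] + brk[e + 1]) / 2 + hw[e] * gl$x, numeric(nq)))
    wq <- as.vector(vapply(seq_len(nel), function(e) hw[e] * gl$w,
                           numeric(nq)))
    tab <- function(d) {
      M <- splines::splineDesign(knots, xq, ord = degree + 1,
                                 derivs = rep(d, length(xq)))
      methods::as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix")
    }
    atpt <- function(x, d) {
      splines::splineDesign(knots, x, ord = degree + 1,
                            derivs = rep(d, length(x)), outer.ok = FALSE)
    }
    grev <- vapply(seq_len(ncp), function(i)
      mean(knots[(i + 1):(i + degree)]), numeric(1))
    list(knots = knots, ncp = ncp, xq = xq, wq = wq,
         B0 = tab(0), B1 = tab(1), B2 = if (degree >= 2) tab(2) else NULL,
         atpt = atpt, grev = grev)
  }
  dx <- dir1d(Lx, nx)
  dy <- dir1d(Ly, ny)
  ncp <- dx$ncp * dy$ncp
  kr <- function(A, B) methods::as(Matrix::kronecker(A, B), "CsparseMatrix")
  N   <- kr(dy$B0, dx$B0)
  Dx  <- kr(dy$B0, dx$B1)
  Dy  <- kr(dy$B1, dx$B0)
  second <- degree >= 2
  Dxx <- if (second) kr(dy$B0, dx$B2) else NULL
  Dyy <- if (second) kr(dy$B2, dx$B0) else NULL
  Dxy <- if (second) kr(dy$B1, dx$B1) else NULL
  w  <- as.vector(kronecker(dy$wq, dx$wq))    # qp index: x fastest
  xq <- rep(dx$xq, times = length(dy$xq))
  yq <- rep(dy$xq, each = length(dx$xq))
  nqp <- length(w)
  Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nqp, ncp))
  interleave <- function(blocks) {
    nb <- length(blocks)
    S <- do.call(rbind, blocks)
    perm <- as.vector(t(matrix(seq_len(nb * nqp), nqp, nb)))
    S[perm, , drop = FALSE]
  }
  B1g <- interleave(list(cbind(Dx, Z), cbind(Z, Dy), cbind(Dy, Dx)))
  B2g <- if (second)
    interleave(list(cbind(Dxx, Z), cbind(Dyy, Z), cbind(Dxy, Z),
                    cbind(Z, Dxx), cbind(Z, Dyy), cbind(Z, Dxy)))
  else NULL
  blk_idx <- function(nb) {
    q <- rep(seq_len(nqp), each = nb * nb)
    a <- rep(rep(seq_len(nb), each = nb), times = nqp)
    b <- rep(rep(seq_len(nb), times = nb), times = nqp)
    list(i = nb * (q - 1L) + a, j = nb * (q - 1L) + b)
  }
  edge <- function(which) {
    horiz <- which %in% c("bottom", "top")
    d_run <- if (horiz) dx else dy
    d_fix <- if (horiz) dy else dx
    xfix <- switch(which, bottom = 0, top = Ly, left = 0, right = Lx)
    Brun0 <- methods::as(Matrix::Matrix(d_run$atpt(d_run$xq, 0),
                                        sparse = TRUE), "generalMatrix")
    Bfix0 <- Matrix::Matrix(matrix(d_fix$atpt(xfix, 0), 1), sparse = TRUE)
    Bfix1 <- Matrix::Matrix(matrix(d_fix$atpt(xfix, 1), 1), sparse = TRUE)
    if (horiz) {
      Ne <- kr(Bfix0, Brun0)
      Dn <- kr(Bfix1, Brun0)       # d/dy at the edge
      x <- d_run$xq; y <- rep(xfix, length(x))
    } else {
      Ne <- kr(Brun0, Bfix0)
      Dn <- kr(Brun0, Bfix1)       # d/dx at the edge
      y <- d_run$xq; x <- rep(xfix, length(y))
    }
    nrm <- switch(which, bottom = c(0, -1), top = c(0, 1),
                  left = c(-1, 0), right = c(1, 0))
    if (which %in% c("bottom", "left")) Dn <- -Dn   # outward normal deriv
    list(N = Ne, Dn = Dn, w = d_run$wq, x = x, y = y, normal = nrm)
  }
  edges <- list(bottom = edge("bottom"), top = edge("top"),
                left = edge("left"), right = edge("right"))
  cp_ix <- rep(seq_len(dx$ncp), times = dy$ncp)
  cp_iy <- rep(seq_len(dy$ncp), each = dx$ncp)
  m <- list(Lx = Lx, Ly = Ly, nx = nx, ny = ny, degree = degree, nq = nq,
            ncpx = dx$ncp, ncpy = dy$ncp, ncp = ncp, ndof = 2L * ncp,
            nqp = nqp, w = w, xq = xq, yq = yq,
            N = N, Dx = Dx, Dy = Dy, Dxx = Dxx, Dyy = Dyy, Dxy = Dxy,
            B1g = B1g, B2g = B2g,
            idx3 = blk_idx(3L), idx6 = if (second) blk_idx(6L) else NULL,
            edges = edges,
            cp_ix = cp_ix, cp_iy = cp_iy,
            grev_x = dx$grev, grev_y = dy$grev,
            knots_x = dx$knots, knots_y = dy$knots)
  class(m) <- "bone_mesh"
  m
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf(
    "<bone_mesh> %.3g x %.3g m, %d x %d elements, degree %d (C%d), %d dofs\n",
    x$Lx, x$Ly, x$nx, x$ny, x$degree, x$degree - 1L, x$ndof))
  invisible(x)
}

# Control-point (coefficient) indices lying on a named edge.
.edge_cps <- function(mesh, which) {
  switch(which,
         left = which(mesh$cp_ix == 1L),
         right = which(mesh$cp_ix == mesh$ncpx),
         bottom = which(mesh$cp_iy == 1L),
         top = which(mesh$cp_iy == mesh$ncpy),
         stop("unknown edge: ", which))
}

# Evaluate spline basis (value) at arbitrary points -> sparse matrix
# (npts x ncp).  Points must lie inside the domain.
.eval_matrix <- function(mesh, x, y, dxo = 0L, dyo = 0L) {
  ordx <- mesh$degree + 1L
  Bx <- splines::splineDesign(mesh$knots_x, pmin(pmax(x, 0), mesh$Lx),
                              ord = ordx, derivs = rep(dxo, length(x)))
  By <- splines::splineDesign(mesh$knots_y, pmin(pmax(y, 0), mesh$Ly),
                              ord = ordx, derivs = rep(dyo, length(y)))
  n <- length(x)
  ii <- jj <- vv <- vector("list", n)
  ncpx <- mesh$ncpx
  for (k in seq_len(n)) {
    cx <- which(Bx[k, ] != 0); cy <- which(By[k, ] != 0)
    cols <- as.vector(outer(cx, (cy - 1L) * ncpx, "+"))
    vals <- as.vector(outer(Bx[k, cx], By[k, cy]))
    ii[[k]] <- rep(k, length(cols)); jj[[k]] <- cols; vv[[k]] <- vals
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, mesh$ncp))
}

# Coefficient vector reproducing a bivariate polynomial exactly (for
# degree-2 splines): uses the polar (blossom) form per direction, exact for
# total degree <= 2 per direction.  f is a function(x, y); implemented for
# the monomials via numeric blossoming on the Greville grid.
.poly_coeffs <- function(mesh, f) {
  stopifnot(mesh$degree == 2L)
  kx <- mesh$knots_x; ky <- mesh$knots_y
  nx <- mesh$ncpx; ny <- mesh$ncpy
  # 1D polar form of degree-2 polynomial g: g[(s,t)] =
  #   g((s+t)/2) adjusted so that blossom of x^2 is s*t:
  # write g(x) = a + b x + c x^2 -> blossom = a + b (s+t)/2 + c s t.
  blos2 <- function(g, s, t) {
    a <- g(0); b <- (g(1) - g(-1)) / 2; c <- (g(1) + g(-1)) / 2 - a
    a + b * (s + t) / 2 + c * s * t
  }
  coef <- numeric(mesh$ncp)
  for (iy in seq_len(ny)) {
    sy <- ky[iy + 1]; ty <- ky[iy + 2]
    for (ix in seq_len(nx)) {
      sx <- kx[ix + 1]; tx <- kx[ix + 2]
      # bivariate blossom: blossom in x of (blossom in y of f)
      gy <- function(xv) blos2(function(yv) f(xv, yv), sy, ty)
      coef[(iy - 1L) * nx + ix] <- blos2(gy, sx, tx)
    }
  }
  coef
}
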
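# Full-domain scattering operator: lossy free-space Green kernel, piston
# source incident field, the volume integral-equation operator on the
# total pressure, its Hermitian adjoint, and the conjugate-gradient
# solution of O[p_tot] = p_inc.

#' Lossy free-space Green's function
#'
#' `G(r) = exp(-gamma0 |r|) / (4 pi |r|)` with `gamma0 = alpha + i beta`
#' the background complex propagation coefficient. The kernel is
#' symmetric in its argument.
#'
#' @param displacement n x 3 matrix (or length-3 vector) of displacement
#'   vectors in metres; none may be the zero vector (the singular
#'   self-term is regularised by the operator assembly, not here).
#' @param gamma0 Complex background propagation coefficient (1/m).
#' @return Complex vector of kernel values.
#' @export
greens_function <- function(displacement, gamma0) {
  displacement <- rbind(displacement, deparse.level = 0)
  r <- unname(sqrt(rowSums(displacement^2)))
  if (any(r == 0)) stop("zero displacement: Green kernel singularity")
  exp(-gamma0 * r) / (4 * pi * r)
}

# Regularised self-term: exact mean of the lossy kernel over the sphere
# with the cell's volume (radius r_eq = h (3/(4 pi))^(1/3)):
# (1 - e^{-g a}(1 + g a)) / (V g^2); series for small |g a| to avoid
# cancellation. Reduces to 3/(8 pi r_eq) in the lossless limit.
.greens_self <- function(h, gamma0) {
  a <- h * (3 / (4 * pi))^(1 / 3)
  V <- (4 / 3) * pi * a^3
  x <- gamma0 * a
  small <- Mod(x) < 1e-4
  out <- complex(length.out = length(a))
  out[small] <- (a[small]^2 / 2) * (1 - 2 * x[small] / 3) / V[small]
  ns <- !small
  out[ns] <- (1 - exp(-x[ns]) * (1 + x[ns])) / (V[ns] * gamma0^2)
  out
}

# Smoothing factor of the cell-averaged kernel: the mean of
# exp(-g|r - r'|)/(4 pi |r - r'|) over r' in the equivalent sphere of
# radius a (observation point outside) equals the point kernel times
# f(g a) = 3 (x cosh x - sinh x) / x^3. For |beta| h >> 1 this carries
# the intra-cell phase cancellation that keeps the discrete operator in
# the Born regime on meshes coarser than the wavelength.
.greens_smoothing <- function(x) {
  out <- complex(length.out = length(x))
  small <- Mod(x) < 1e-3
  out[small] <- 1 + x[small]^2 / 10
  ns <- !small
  out[ns] <- 3 * (x[ns] * cosh(x[ns]) - sinh(x[ns])) / x[ns]^3
  out
}

#' Discretised circular piston source
#'
#' Surface points on a regular raster covering the source disk, each
#' carrying a uniform strength and the raster patch area `dS`.
#'
#' @param center Disk centre (m).
#' @param normal Unit normal of the source plane (beam direction).
#' @param radius Disk radius in metres (default 5 mm).
#' @param spacing Point spacing in metres (default `radius / 8`).
#' @param strength Uniform source strength per point (default 1).
#' @return A `us_source` with `points` (n x 3), `s` (strengths), `dS`,
#'   `center`, `normal`, `radius`.
#' @export
source_transducer <- function(center, normal, radius = 0.005,
                              spacing = radius / 8, strength = 1) {
  normal <- normal / sqrt(sum(normal^2))
  frame <- .axis_frame(normal)
  u <- seq(-radius + spacing / 2, radius, by = spacing)
  gg <- as.matrix(expand.grid(u = u, v = u))
  gg <- gg[gg[, 1]^2 + gg[, 2]^2 <= radius^2, , drop = FALSE]
  pts <- sweep(gg[, 1] %o% frame$e1 + gg[, 2] %o% frame$e2, 2, center, `+`)
  src <- list(points = pts, s = rep(strength, nrow(pts)), dS = spacing^2,
              center = center, normal = normal, radius = radius)
  class(src) <- "us_source"
  src
}

#' Incident pressure field of a piston source in the background medium
#'
#' `p_inc(r) = i omega rho0 sum_k G(r - r_k) s(r_k) dS` over the
#' discretised source points; evaluated once per scenario. A field cell
#' coincident with a source point takes the regularised self-term.
#'
#' @param grid A `us_grid` (or an n x 3 matrix of evaluation points, in
#'   which case `h` supplies the regularisation scale).
#' @param source A `us_source`.
#' @param rho0 Background density (kg/m^3).
#' @param gamma0 Background complex propagation coefficient (1/m).
#' @param frequency Hz.
#' @param h Regularisation scale for matrix input (default the source
#'   spacing).
#' @return A `us_field` (complex per-cell pressure, variant "incident"),
#'   or a bare complex vector for matrix input.
#' @export
incident_field <- function(grid, source, rho0, gamma0, frequency, h = NULL) {
  omega <- 2 * pi * frequency
  if (inherits(grid, "us_grid")) {
    pts <- cell_barycenters(grid)
    hv <- cell_h(grid)
  } else {
    pts <- rbind(grid)
    hv <- rep(if (is.null(h)) sqrt(source$dS) else h, nrow(pts))
  }
  acc <- complex(length.out = nrow(pts))
  for (k in seq_len(nrow(source$points))) {
    d <- sweep(pts, 2, source$points[k, ], `-`)
    r <- sqrt(rowSums(d^2))
    g <- complex(length.out = length(r))
    sing <- r < 1e-12
    if (any(sing)) g[sing] <- .greens_self(hv[sing], gamma0)
    g[!sing] <- exp(-gamma0 * r[!sing]) / (4 * pi * r[!sing])
    acc <- acc + g * source$s[k]
  }
  p <- 1i * omega * rho0 * acc * source$dS
  if (!inherits(grid, "us_grid")) return(p)
  structure(list(p = p, variant = "incident", frequency = frequency),
            class = "us_field")
}

#' @export
print.us_field <- function(x, ...) {
  cat(sprintf("<us_field> %s, %d cells, max |p| = %.4g\n",
              x$variant, length(x$p), max(Mod(x$p))))
  invisible(x)
}

#' Assemble the scattering operator for a scene at one frequency
#'
#' Precomputes the dense Green kernel between all cell pairs (with the
#' regularised diagonal), the contrast maps and the scaled
#' divergence/gradient matrices, and returns closures for the forward
#' operator `O[p] = p - G[dgamma p V] - G[div(drho grad p) V]` and its
#' Hermitian adjoint.
#'
#' @param scene A `us_scene`.
#' @param frequency Hz.
#' @return A `us_operator`: functions `apply_fwd(p)`, `apply_adj(y)`,
#'   `dense()` (the assembled matrix), plus `contrasts`, `gamma0`, `n`.
#' @export
scattering_operator <- function(scene, frequency) {
  grid <- scene$grid
  n <- grid$n_cells
  sg <- scene_gamma(scene, frequency)
  ct <- contrast_maps(scene$rho, sg$gamma, scene$background$rho0, sg$gamma0)
  V <- cell_volumes(grid)
  bc <- cell_barycenters(grid)
  h <- cell_h(grid)
  # dense symmetric Green kernel between barycenters
  dx <- outer(bc[, 1], bc[, 1], `-`)
  dy <- outer(bc[, 2], bc[, 2], `-`)
  dz <- outer(bc[, 3], bc[, 3], `-`)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  rm(dx, dy, dz)
  diag(r) <- 1  # placeholder, replaced below
  # cell-averaged kernel: point kernel times the source-cell smoothing
  # factor (column-wise), exact sphere mean on the diagonal
  a_eq <- h * (3 / (4 * pi))^(1 / 3)
  G <- exp(-sg$gamma0 * r) / (4 * pi * r) *
    rep(.greens_smoothing(sg$gamma0 * a_eq), each = n)
  rm(r)
  diag(G) <- .greens_self(h, sg$gamma0)
  nbrs <- neighbor_matrices(grid)
  ops <- differential_operators(grid, nbrs)
  Drho <- Matrix::Diagonal(n, ct$delta_rho)
  L <- ops$sdiv_x %*% Drho %*% ops$sgrad_x +
    ops$sdiv_y %*% Drho %*% ops$sgrad_y +
    ops$sdiv_z %*% Drho %*% ops$sgrad_z
  Lh <- Matrix::t(L)  # real matrix: conjugate transpose = transpose
  dgV <- ct$delta_gamma * V
  apply_fwd <- function(p) {
    w <- dgV * p + V * .sp_cmult(L, p)
    p - as.vector(G %*% w)
  }
  # O^H y = y - conj(Dg V) G^H y - L^T (V * (G^H y)); G^H y computed as
  # Conj(t(G) %*% Conj(y)) since G is not symmetric on multi-level grids
  apply_adj <- function(y) {
    gy <- as.vector(Conj(crossprod(G, Conj(y))))
    y - Conj(dgV) * gy - .sp_cmult(Lh, V * gy)
  }
  dense <- function() {
    M <- -G * rep(dgV, each = n)          # -G %*% diag(dgV)
    M <- M - G %*% (V * as.matrix(L))     # -G diag(V) L
    diag(M) <- diag(M) + 1
    M
  }
  op <- list(apply_fwd = apply_fwd, apply_adj = apply_adj, dense = dense,
             contrasts = ct, gamma0 = sg$gamma0, n = n, V = V,
             frequency = frequency)
  class(op) <- "us_operator"
  op
}

# Real sparse matrix times complex vector: Matrix has no complex method,
# so multiply the real and imaginary parts separately.
.sp_cmult <- function(M, z) {
  complex(real = as.numeric(M %*% Re(z)), imaginary = as.numeric(M %*% Im(z)))
}

#' Apply the forward scattering operator to a pressure field
#'
#' @param op A `us_operator` from [scattering_operator()].
#' @param p Complex per-cell pressure vector (or `us_field`).
#' @return Complex vector `O[p]`.
#' @export
scattering_apply <- function(op, p) {
  if (inherits(p, "us_field")) p <- p$p
  if (length(p) != op$n) stop("field length does not match operator grid")
  op$apply_fwd(p)
}

#' Apply the Hermitian adjoint of the scattering operator
#'
#' @param op A `us_operator`.
#' @param y Complex per-cell vector.
#' @return Complex vector `O^H[y]`.
#' @export
scattering_adjoint <- function(op, y) {
  if (inherits(y, "us_field")) y <- y$p
  if (length(y) != op$n) stop("field length does not match operator grid")
  op$apply_adj(y)
}

#' Solve the scattering integral equation by conjugate gradients
#'
#' Starting from a zero total-field estimate, iterates the update scheme
#' with search directions built from the Hermitian adjoint of the
#' operator and step size equal to the ratio of the adjoint-residual and
#' mapped-direction norms, stopping when the relative residual
#' `||r||_2 / ||p_inc||_2` falls below `tol` or after `max_iter`
#' iterations. The default `"cgnr"` variant uses squared-norm ratios for
#' the direction weight and step (conjugate gradients on the normal
#' equations, which is monotone in the residual); `"norm"` uses plain
#' norm ratios and is retained for comparison only -- its step size is
#' wrongly scaled and it diverges on all but trivial scenes.
#'
#' @param scene A `us_scene`.
#' @param source A `us_source`.
#' @param frequency Hz.
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative residual tolerance (default 0.10).
#' @param variant `"cgnr"` (default) or `"norm"`.
#' @param op Optional pre-assembled `us_operator` (rebuilt otherwise).
#' @param p_inc Optional precomputed incident `us_field`.
#' @return A `us_solution`: fields `total`, `incident`, `scattered`
#'   (`us_field`s), `history` data frame (iteration, error, theta),
#'   `converged`, `iterations`.
#' @export
cg_solve <- function(scene, source, frequency, max_iter = 100, tol = 0.10,
                     variant = c("cgnr", "norm"), op = NULL, p_inc = NULL) {
  variant <- match.arg(variant)
  if (is.null(op)) op <- scattering_operator(scene, frequency)
  if (is.null(p_inc)) {
    p_inc <- incident_field(scene$grid, source, scene$background$rho0,
                            op$gamma0, frequency)
  }
  b <- p_inc$p
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) stop("incident field is identically zero")
  p <- complex(length.out = op$n)
  Op <- complex(length.out = op$n)  # O[p], tracked incrementally
  xi <- NULL
  prev_w <- NA_real_
  hist_err <- numeric(0)
  hist_theta <- numeric(0)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- b - Op
    err <- sqrt(sum(Mod(r)^2)) / nb
    if (!is.finite(err)) stop("non-finite residual at iteration ", it)
    hist_err <- c(hist_err, err)
    iters <- it
    if (err <= tol) { converged <- TRUE; break }
    g <- op$apply_adj(r)
    w <- sqrt(sum(Mod(g)^2))
    if (w == 0) { converged <- TRUE; break }  # stationary: residual in null space
    beta <- if (is.null(xi)) 0 else {
      if (variant == "norm") w / prev_w else (w / prev_w)^2
    }
    xi <- if (is.null(xi)) g else g + beta * xi
    Oxi <- op$apply_fwd(xi)
    nOxi <- sqrt(sum(Mod(Oxi)^2))
    theta <- if (variant == "norm") w / nOxi else (w / nOxi)^2
    if (!is.finite(theta)) stop("non-finite step size at iteration ", it)
    hist_theta <- c(hist_theta, theta)
    p <- p + theta * xi
    Op <- Op + theta * Oxi
    prev_w <- w
  }
  total <- structure(list(p = p, variant = "total", frequency = frequency),
                     class = "us_field")
  scattered <- structure(list(p = p - b, variant = "scattered",
                              frequency = frequency), class = "us_field")
  sol <- list(total = total, incident = p_inc, scattered = scattered,
              history = data.frame(
                iteration = seq_along(hist_err),
                error = hist_err,
                theta = c(hist_theta, rep(NA_real_,
                                          length(hist_err) - length(hist_theta)))),
              converged = converged, iterations = iters, variant = variant)
  class(sol) <- "us_solution"
  sol
}

#' @export
print.us_solution <- function(x, ...) {
  cat(sprintf(
    "<us_solution> %d iterations, final error %.4g%% (%sconverged)\n",
    x$iterations, 100 * utils::tail(x$history$error, 1),
    if (x$converged) "" else "not "))
  invisible(x)
}

#' Write a complex pressure field as plain text
#'
#' One row per cell: barycenter, cell size, real and imaginary pressure
#' and magnitude.
#'
#' @param field A `us_field`.
#' @param grid The `us_grid` the field lives on.
#' @param file Output CSV path.
#' @return Invisibly, the path.
#' @export
write_field <- function(field, grid, file) {
  bc <- cell_barycenters(grid)
  utils::write.csv(data.frame(
    x = bc[, 1], y = bc[, 2], z = bc[, 3], h = cell_h(grid),
    re = Re(field$p), im = Im(field$p), mag = Mod(field$p)),
    file, row.names = FALSE)
  invisible(file)
}
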
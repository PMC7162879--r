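# Graded multi-resolution orthogonal cell-complex grid.
#
# Cells are axis-aligned cubes stored in integer units of the finest
# admissible resolution (base_h / 2^max_level), which makes face adjacency
# exact. Three refinement levels are supported (edge h, h/2, h/4), and
# face-adjacent cells never differ by more than one level.

.MAX_LEVEL <- 2L

#' Build a uniform level-0 grid over an axis-aligned box
#'
#' @param extent Box edge lengths in metres: length-3 vector (or a single
#'   number for a cube). Each must be a positive multiple of `base_h`
#'   (1e-9 relative tolerance).
#' @param base_h Coarsest cell edge length in metres.
#' @param origin Coordinates of the box corner (default `c(0,0,0)`).
#' @return A `us_grid` object. Cell values are understood as cell-centred
#'   (pressure at the barycenter); cells are half-open `[x_i, x_{i+1})`.
#' @export
#' @examples
#' g <- build_grid(0.1, 0.01)
#' g$n_cells  # 1000
build_grid <- function(extent, base_h, origin = c(0, 0, 0)) {
  if (length(extent) == 1L) extent <- rep(extent, 3L)
  stopifnot(length(extent) == 3L, length(origin) == 3L, base_h > 0)
  n_base <- extent / base_h
  for (ax in 1:3) {
    if (abs(n_base[ax] - round(n_base[ax])) > 1e-9 * max(1, n_base[ax])) {
      stop("extent along axis ", c("x", "y", "z")[ax],
           " (", extent[ax], " m) is not a multiple of base_h = ", base_h)
    }
  }
  n_base <- as.integer(round(n_base))
  if (any(n_base < 1L)) stop("extent must be positive along every axis")
  s <- 2L^.MAX_LEVEL  # base cell size in finest units
  ijk <- as.matrix(expand.grid(i = seq_len(n_base[1]) - 1L,
                               j = seq_len(n_base[2]) - 1L,
                               k = seq_len(n_base[3]) - 1L))
  grid <- list(origin = as.numeric(origin), base_h = base_h,
               unit = base_h / s, max_level = .MAX_LEVEL,
               n_base = n_base, extent = n_base * base_h,
               lo = ijk * s,
               size = rep(s, nrow(ijk)),
               level = rep(0L, nrow(ijk)))
  grid$n_cells <- nrow(grid$lo)
  class(grid) <- "us_grid"
  .grid_finalize(grid)
}

#' @export
print.us_grid <- function(x, ...) {
  cat(sprintf("<us_grid> %d cells, extent %s m, base h = %g m, levels %s\n",
              x$n_cells, paste(signif(x$extent, 4), collapse = " x "),
              x$base_h, paste(sort(unique(x$level)), collapse = "/")))
  invisible(x)
}

# Re-sort cells lexicographically (x fastest), recompute the unit-lookup
# index and cached geometry.
.grid_finalize <- function(grid) {
  ord <- order(grid$lo[, 3], grid$lo[, 2], grid$lo[, 1])
  grid$lo <- grid$lo[ord, , drop = FALSE]
  grid$size <- grid$size[ord]
  grid$level <- grid$level[ord]
  grid$n_cells <- nrow(grid$lo)
  dimnames(grid$lo) <- NULL
  nu <- grid$n_base * 2L^grid$max_level
  idx <- array(0L, dim = nu)
  for (l in seq_len(grid$n_cells)) {
    s <- grid$size[l]
    idx[grid$lo[l, 1] + seq_len(s), grid$lo[l, 2] + seq_len(s),
        grid$lo[l, 3] + seq_len(s)] <- l
  }
  grid$index <- idx
  grid
}

#' Cell edge lengths in metres
#' @param grid A `us_grid`.
#' @return Numeric vector of per-cell `h`.
#' @export
cell_h <- function(grid) grid$size * grid$unit

#' Cell barycenters
#' @param grid A `us_grid`.
#' @return n_cells x 3 matrix of barycenter coordinates (m).
#' @export
cell_barycenters <- function(grid) {
  ctr <- (grid$lo + grid$size / 2) * grid$unit
  sweep(ctr, 2, grid$origin, `+`)
}

#' Cell volumes h^3 in m^3
#' @param grid A `us_grid`.
#' @return Numeric vector of per-cell volumes.
#' @export
cell_volumes <- function(grid) cell_h(grid)^3

#' Locate the cells containing a set of points
#'
#' @param grid A `us_grid`.
#' @param points n x 3 matrix of coordinates (m).
#' @return Integer vector of cell indices; `NA` for points outside the
#'   domain. Cells are half-open, so a point on a shared face belongs to
#'   the cell on its positive side.
#' @export
locate_cells <- function(grid, points) {
  points <- rbind(points)
  u <- sweep(points, 2, grid$origin, `-`) / grid$unit
  u <- floor(u + 1e-9)
  nu <- dim(grid$index)
  ok <- u[, 1] >= 0 & u[, 1] < nu[1] & u[, 2] >= 0 & u[, 2] < nu[2] &
    u[, 3] >= 0 & u[, 3] < nu[3]
  out <- rep(NA_integer_, nrow(points))
  if (any(ok)) {
    out[ok] <- grid$index[cbind(u[ok, 1, drop = TRUE] + 1L,
                                u[ok, 2, drop = TRUE] + 1L,
                                u[ok, 3, drop = TRUE] + 1L)]
  }
  out
}

# Face-adjacency lists: for every cell, the indices of cells sharing a
# face on the given side. axis in 1:3, positive = TRUE for the + side.
.face_neighbors <- function(grid, axis, positive) {
  lo <- grid$lo[, axis]
  hi <- lo + grid$size
  oa <- setdiff(1:3, axis)
  a_lo <- grid$lo[, oa[1]]; a_hi <- a_lo + grid$size
  b_lo <- grid$lo[, oa[2]]; b_hi <- b_lo + grid$size
  # a cell's +face plane must equal the neighbor's -face plane
  grp <- split(seq_len(grid$n_cells), if (positive) lo else hi)
  face <- if (positive) hi else lo
  out <- vector("list", grid$n_cells)
  for (l in seq_len(grid$n_cells)) {
    cand <- grp[[as.character(face[l])]]
    if (is.null(cand)) next
    keep <- cand[a_lo[cand] < a_hi[l] & a_hi[cand] > a_lo[l] &
                   b_lo[cand] < b_hi[l] & b_hi[cand] > b_lo[l]]
    if (length(keep) > 0L) out[[l]] <- keep
  }
  out
}

.all_adjacency <- function(grid) {
  out <- vector("list", 6L)
  n <- 0L
  for (axis in 1:3) for (pos in c(TRUE, FALSE)) {
    n <- n + 1L
    out[[n]] <- .face_neighbors(grid, axis, pos)
  }
  names(out) <- c("xp", "xm", "yp", "ym", "zp", "zm")
  out
}

#' Check the one-level grading constraint
#' @param grid A `us_grid`.
#' @return TRUE if no face-adjacent pair differs by more than one level.
#' @export
is_graded <- function(grid) {
  adj <- .all_adjacency(grid)
  for (d in adj) {
    for (l in seq_along(d)) {
      nb <- d[[l]]
      if (length(nb) > 0L &&
          any(abs(grid$level[nb] - grid$level[l]) > 1L)) return(FALSE)
    }
  }
  TRUE
}

# Split the given cells into octants (8 children each).
.split_cells <- function(grid, which_cells) {
  if (length(which_cells) == 0L) return(grid)
  if (any(grid$level[which_cells] >= grid$max_level)) {
    stop("cannot refine beyond level ", grid$max_level)
  }
  oct <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  kid_lo <- vector("list", length(which_cells))
  for (n in seq_along(which_cells)) {
    l <- which_cells[n]
    half <- grid$size[l] %/% 2L
    kid_lo[[n]] <- sweep(oct * half, 2, grid$lo[l, ], `+`)
  }
  kid_lo <- do.call(rbind, kid_lo)
  kid_size <- rep(grid$size[which_cells] %/% 2L, each = 8L)
  kid_level <- rep(grid$level[which_cells] + 1L, each = 8L)
  keep <- setdiff(seq_len(grid$n_cells), which_cells)
  grid$lo <- rbind(grid$lo[keep, , drop = FALSE], kid_lo)
  grid$size <- c(grid$size[keep], kid_size)
  grid$level <- c(grid$level[keep], kid_level)
  grid$n_cells <- nrow(grid$lo)
  grid
}

#' Refine a grid inside a region, with one-level grading
#'
#' Every cell intersecting the region is split by successive octant
#' subdivisions until it reaches `target_level`; refinement then
#' propagates through shared faces (not edges or corners) so that no
#' face-adjacent pair differs by more than one level.
#'
#' @param grid A `us_grid`.
#' @param region Either a box `list(min = c(x,y,z), max = c(x,y,z))` in
#'   metres, or a predicate `function(barycenters)` returning a logical
#'   vector over cells.
#' @param target_level Integer refinement level in 0..2.
#' @return The refined, graded `us_grid`.
#' @export
refine <- function(grid, region, target_level) {
  target_level <- as.integer(target_level)
  if (target_level < 0L || target_level > grid$max_level) {
    stop("target_level must be between 0 and ", grid$max_level)
  }
  in_region <- function(g) {
    if (is.function(region)) {
      as.logical(region(cell_barycenters(g)))
    } else {
      lo_m <- sweep(g$lo * g$unit, 2, g$origin, `+`)
      hi_m <- lo_m + g$size * g$unit
      tol <- 1e-12
      lo_m[, 1] < region$max[1] - tol & hi_m[, 1] > region$min[1] + tol &
        lo_m[, 2] < region$max[2] - tol & hi_m[, 2] > region$min[2] + tol &
        lo_m[, 3] < region$max[3] - tol & hi_m[, 3] > region$min[3] + tol
    }
  }
  repeat {
    todo <- which(in_region(grid) & grid$level < target_level)
    if (length(todo) == 0L) break
    grid <- .split_cells(grid, todo)
    # grading: any cell more than one level coarser than a face neighbor
    repeat {
      adj <- .all_adjacency(grid)
      bad <- integer(0)
      for (d in adj) {
        for (l in seq_along(d)) {
          nb <- d[[l]]
          if (length(nb) > 0L && any(grid$level[nb] > grid$level[l] + 1L)) {
            bad <- c(bad, l)
          }
        }
      }
      bad <- unique(bad)
      if (length(bad) == 0L) break
      grid <- .split_cells(grid, bad)
    }
  }
  .grid_finalize(grid)
}

#' Neighbor sparse matrices for the six face directions
#'
#' Six `n_cells x n_cells` sparse matrices (`xp, xm, yp, ym, zp, zm`). A
#' same-level (or coarser) neighbor contributes a single unit entry; a
#' coarse cell facing `k` finer cells holds equal interpolation weights
#' `1/k` (k at most 4) so each non-boundary row sums to one; rows of cells
#' whose face lies on the domain boundary are zero.
#'
#' @param grid A graded `us_grid`.
#' @return List of class `us_neighbors` with sparse matrices `xp, xm, yp,
#'   ym, zp, zm` and the adjacency lists in `adjacency`.
#' @export
neighbor_matrices <- function(grid) {
  if (!is_graded(grid)) stop("grid is not graded; refine() enforces grading")
  adj <- .all_adjacency(grid)
  n <- grid$n_cells
  mats <- lapply(adj, function(d) {
    ii <- jj <- ww <- vector("list", n)
    for (l in seq_len(n)) {
      nb <- d[[l]]
      k <- length(nb)
      if (k == 0L) next
      if (any(grid$size[nb] >= grid$size[l])) {
        # same level or coarser: the single covering neighbor
        nb <- nb[which.max(grid$size[nb])]
        k <- 1L
      }
      ii[[l]] <- rep(l, k); jj[[l]] <- nb; ww[[l]] <- rep(1 / k, k)
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                         dims = c(n, n))
  })
  names(mats) <- names(adj)
  mats$adjacency <- adj
  class(mats) <- "us_neighbors"
  mats
}

#' Discrete divergence and gradient operators
#'
#' Returns both the unscaled topological operators
#' `div = 3D - Nxx+ - Nyy+ - Nzz+` and `grad_c = D - Ncc-` (with `D` the
#' identity-pattern diagonal), and a physically scaled variant that
#' divides each row by the barycenter distance to the face neighbor and
#' orients the divergence as a forward difference, so that the
#' composition `sdiv . sgrad` reproduces the 7-point Laplacian on uniform
#' interiors. Scaled rows without a neighbor (domain boundary) are zero.
#'
#' @param grid A `us_grid`.
#' @param nbrs Result of [neighbor_matrices()] for the same grid.
#' @return List of class `us_operators`: unscaled `div`, `grad_x/y/z`,
#'   `D`; scaled per-component `sdiv_x/y/z`, `sgrad_x/y/z`.
#' @export
differential_operators <- function(grid, nbrs) {
  n <- grid$n_cells
  if (nrow(nbrs$xp) != n) stop("neighbor matrices do not match grid size")
  D <- Matrix::Diagonal(n)
  h <- cell_h(grid)
  bc <- cell_barycenters(grid)
  # per-row distance to the face neighbors along the given axis;
  # 0 marks a boundary row (no neighbor), which the scaled forms zero out
  row_dist <- function(M, axis) {
    has_nb <- abs(Matrix::rowSums(M)) > 0.5
    d <- abs(as.numeric(M %*% bc[, axis]) - bc[, axis])
    ifelse(has_nb, d, 0)
  }
  scale_rows <- function(M, dist) {
    s <- ifelse(dist > 0, 1 / dist, 0)
    Matrix::Diagonal(n, s) %*% M
  }
  ops <- list(
    div = 3 * D - nbrs$xp - nbrs$yp - nbrs$zp,
    grad_x = D - nbrs$xm, grad_y = D - nbrs$ym, grad_z = D - nbrs$zm,
    D = D)
  for (ax in 1:3) {
    nm <- c("x", "y", "z")[ax]
    Np <- nbrs[[paste0(nm, "p")]]
    Nm <- nbrs[[paste0(nm, "m")]]
    dp <- row_dist(Np, ax)
    dm <- row_dist(Nm, ax)
    ops[[paste0("sdiv_", nm)]] <- scale_rows(Np - D, dp)   # forward difference
    ops[[paste0("sgrad_", nm)]] <- scale_rows(D - Nm, dm)  # backward difference
  }
  class(ops) <- "us_operators"
  ops
}

#' Serialize a grid to a directory of plain-text files
#'
#' Writes `cells.csv` (barycenter, h, level), the six neighbor matrices in
#' MatrixMarket coordinate format and a `meta.json` with the grid
#' parameters.
#'
#' @param grid A `us_grid`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bc <- cell_barycenters(grid)
  utils::write.csv(data.frame(x = bc[, 1], y = bc[, 2], z = bc[, 3],
                              h = cell_h(grid), level = grid$level),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  nb <- neighbor_matrices(grid)
  for (nm in c("xp", "xm", "yp", "ym", "zp", "zm")) {
    Matrix::writeMM(nb[[nm]], file.path(dir, paste0("N_", nm, ".mtx")))
  }
  jsonlite::write_json(list(origin = grid$origin, base_h = grid$base_h,
                            n_base = grid$n_base, n_cells = grid$n_cells),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
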
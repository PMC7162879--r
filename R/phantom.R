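# Acoustic scene construction: grey-level segmentation of slice stacks,
# boundary surfaces with normals, material assignment onto a grid, and
# synthetic scenes (water tank, layered breast analog, homogeneous box).

#' Labelled tissue volume
#'
#' Constructor for the integer-labelled voxel volume used throughout the
#' phantom stage. Labels are a contiguous set `0..k-1`, with 0 the
#' background.
#'
#' @param labels 3D integer array of tissue labels.
#' @param spacing Voxel spacing in metres (scalar or length 3).
#' @param origin Volume corner coordinates (m).
#' @return A `us_volume`.
#' @export
labeled_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  lab <- sort(unique(as.integer(labels)))
  if (!all(lab == seq_along(lab) - 1L)) {
    stop("labels must form a contiguous set 0..k-1; found: ",
         paste(lab, collapse = ", "))
  }
  v <- list(labels = array(as.integer(labels), dim = dim(labels)),
            spacing = as.numeric(spacing), origin = as.numeric(origin),
            dims = dim(labels), n_labels = length(lab))
  class(v) <- "us_volume"
  v
}

#' @export
print.us_volume <- function(x, ...) {
  cat(sprintf("<us_volume> %s voxels, spacing %s m, %d labels\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "/"), x$n_labels))
  invisible(x)
}

# 5x5 Gaussian mask, sigma in pixels.
.gaussian_mask5 <- function(sigma = 1) {
  g <- exp(-((-2):2)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 2D convolution with reflection padding, via 25 shifted additions.
.smooth_slice <- function(mat, kernel) {
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- c(2:1, 1:nr, nr:(nr - 1))  # reflected row index, pad 2
  ci <- c(2:1, 1:nc, nc:(nc - 1))
  pad <- mat[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (di in 1:5) for (dj in 1:5) {
    out <- out + kernel[di, dj] * pad[(di - 1) + 1:nr, (dj - 1) + 1:nc]
  }
  out
}

# Reassign single-voxel islands (no face neighbor shares the label) to the
# majority label among their up-to-6 face neighbors; ties to the smaller label.
.despeckle <- function(lab) {
  d <- dim(lab)
  pad <- array(NA_integer_, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nbr <- lapply(shifts, function(s) {
    pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2], 2:(d[3] + 1) + s[3]]
  })
  same <- array(0L, d)
  for (nb in nbr) same <- same + (!is.na(nb) & nb == lab)
  iso <- which(same == 0L)
  for (v in iso) {
    votes <- vapply(nbr, function(nb) nb[v], integer(1))
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0L) next
    tab <- table(votes)
    best <- as.integer(names(tab)[tab == max(tab)])
    lab[v] <- min(best)  # tie -> smaller label
  }
  lab
}

#' Smooth a grey-level slice stack and segment it into tissues
#'
#' Each slice is convolved with a 5x5 Gaussian mask (reflection padding),
#' the smoothed grey levels are clustered into `n_tissues` groups by
#' k-means on intensity (deterministically seeded by quantile-spread
#' initial centres; clusters relabelled so lower mean intensity gets the
#' lower label), and isolated single-voxel islands are reassigned to the
#' majority label of their face neighbours.
#'
#' @param slices 3D numeric array (x, y, slice) or list of equal-shape
#'   matrices of grey levels.
#' @param n_tissues Number of tissue classes (>= 1).
#' @param spacing Voxel spacing in metres (scalar or length 3).
#' @param sigma Gaussian mask standard deviation in pixels (default 1).
#' @return A `us_volume` of labels `0..n_tissues-1`.
#' @export
smooth_and_segment <- function(slices, n_tissues, spacing = 1e-3, sigma = 1) {
  if (is.list(slices)) {
    shapes <- unique(lapply(slices, dim))
    if (length(slices) == 0L) stop("empty slice stack")
    if (length(shapes) != 1L) stop("all slices must have the same shape")
    slices <- array(unlist(slices), dim = c(shapes[[1]], length(slices)))
  }
  stopifnot(length(dim(slices)) == 3L)
  if (n_tissues < 1L) stop("n_tissues must be >= 1")
  k5 <- .gaussian_mask5(sigma)
  sm <- slices
  for (s in seq_len(dim(slices)[3])) {
    sm[, , s] <- .smooth_slice(slices[, , s, drop = TRUE], k5)
  }
  vals <- as.numeric(sm)
  uniq <- sort(unique(vals))
  if (n_tissues > length(uniq)) {
    stop("n_tissues (", n_tissues, ") exceeds the ", length(uniq),
         " distinct grey levels after smoothing")
  }
  if (n_tissues == 1L) {
    lab <- array(0L, dim(sm))
  } else {
    centers <- uniq[round(seq(1, length(uniq), length.out = n_tissues))]
    km <- stats::kmeans(vals, centers = matrix(centers, ncol = 1),
                        iter.max = 100)
    relabel <- integer(n_tissues)
    relabel[order(km$centers[, 1])] <- seq_len(n_tissues) - 1L
    lab <- array(relabel[km$cluster], dim(sm))
    lab <- .despeckle(lab)
    # despeckling can in principle drop a class; recompact labels
    present <- sort(unique(as.integer(lab)))
    lab <- array(match(lab, present) - 1L, dim(lab))
  }
  labeled_volume(lab, spacing)
}

# Near-uniform unit directions on the sphere (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Voxel label at arbitrary coordinates; NA outside the volume.
.volume_label_at <- function(volume, pts) {
  pts <- rbind(pts)
  ijk <- floor(sweep(sweep(pts, 2, volume$origin, `-`), 2,
                     volume$spacing, `/`)) + 1
  d <- volume$dims
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- rep(NA_integer_, nrow(pts))
  if (any(ok)) out[ok] <- volume$labels[ijk[ok, , drop = FALSE]]
  out
}

#' Extract the boundary surface of one tissue by radial marching
#'
#' Line segments spread radially from the tissue's geometric centre along
#' near-uniform sphere directions; each is marched in half-voxel steps
#' until the label changes, and the transition point becomes a boundary
#' sample whose outward normal is the radial direction of the segment.
#'
#' @param volume A `us_volume`.
#' @param tissue Label to extract (must be present).
#' @param n_directions Number of radial directions (default 2048).
#' @return A `us_surface`: `points` (n x 3, m), `normals` (n x 3, unit),
#'   `centroid`, `tissue`.
#' @export
extract_boundary <- function(volume, tissue, n_directions = 2048) {
  vox <- which(volume$labels == tissue, arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("tissue label ", tissue, " not present in volume")
  centers <- sweep((vox - 0.5) %*% diag(volume$spacing), 2, volume$origin, `+`)
  centroid <- colMeans(centers)
  if (nrow(vox) == 1L) {
    # degenerate single voxel: its 6 face centres, axis-aligned normals
    h <- volume$spacing / 2
    normals <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    pts <- sweep(normals %*% diag(h), 2, centroid, `+`)
    return(structure(list(tissue = tissue, points = pts, normals = normals,
                          centroid = centroid), class = "us_surface"))
  }
  if (!isTRUE(.volume_label_at(volume, rbind(centroid)) == tissue)) {
    warning("tissue ", tissue, " centroid falls outside the tissue ",
            "(non-star-convex); marching from the nearest tissue voxel")
    near <- which.min(colSums((t(centers) - centroid)^2))
    centroid <- centers[near, ]
  }
  dirs <- .fibonacci_sphere(n_directions)
  step <- min(volume$spacing) / 2
  max_dist <- sqrt(sum((volume$dims * volume$spacing)^2))
  ts <- seq(step, max_dist, by = step)
  pts <- matrix(NA_real_, n_directions, 3)
  for (d in seq_len(n_directions)) {
    pos <- outer(ts, dirs[d, ]) + rep(centroid, each = length(ts))
    lab <- .volume_label_at(volume, pos)
    hit <- which(is.na(lab) | lab != tissue)[1]
    if (is.na(hit)) next
    t_hit <- if (hit == 1L) ts[1] / 2 else (ts[hit - 1L] + ts[hit]) / 2
    pts[d, ] <- centroid + t_hit * dirs[d, ]
  }
  keep <- !is.na(pts[, 1])
  structure(list(tissue = tissue, points = pts[keep, , drop = FALSE],
                 normals = dirs[keep, , drop = FALSE], centroid = centroid),
            class = "us_surface")
}

#' Assign acoustic material properties onto a grid
#'
#' Each grid cell receives the properties of the majority tissue label
#' among the voxels whose centres it covers (exact ties to the smaller
#' label); cells finer than the voxel raster sample the voxel containing
#' their barycenter. Materials missing an attenuation law (the piezo
#' rows) are treated as lossless (`a = 0, y = 1`).
#'
#' @param volume A `us_volume`.
#' @param materials Named list mapping each label (as character, e.g.
#'   `"0"`) to a material name or `us_material`.
#' @param grid A `us_grid` covering (part of) the volume.
#' @param background Background medium material (name or `us_material`),
#'   default `"Water"`; defines `rho0` and `gamma0` downstream.
#' @param surfaces Optional list of `us_surface` objects to attach.
#' @return A `us_scene` with per-cell maps `rho`, `v`, `a`, `y`, `label`.
#' @export
assign_properties <- function(volume, materials, grid,
                              background = "Water", surfaces = list()) {
  labs_present <- sort(unique(as.integer(volume$labels)))
  missing <- setdiff(as.character(labs_present), names(materials))
  if (length(missing) > 0L) {
    stop("unmapped tissue labels: ", paste(missing, collapse = ", "))
  }
  mat_of <- function(m) if (inherits(m, "us_material")) m else get_material(m)
  mats <- lapply(materials, mat_of)
  bg <- mat_of(background)

  # voxel-centre majority vote per cell
  d <- volume$dims
  vox_ctr <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
                   rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                   rep(seq_len(d[3]), each = d[1] * d[2]))
  vox_ctr <- sweep((vox_ctr - 0.5) %*% diag(volume$spacing), 2,
                   volume$origin, `+`)
  cell_of <- locate_cells(grid, vox_ctr)
  vlab <- as.integer(volume$labels)
  inside <- !is.na(cell_of)
  label <- rep(NA_integer_, grid$n_cells)
  if (any(inside)) {
    maj <- tapply(vlab[inside], cell_of[inside], function(x) {
      tab <- table(x)
      as.integer(min(as.integer(names(tab)[tab == max(tab)])))
    })
    label[as.integer(names(maj))] <- as.integer(maj)
  }
  # cells without a covered voxel centre: sample at the barycenter
  empty <- which(is.na(label))
  if (length(empty) > 0L) {
    bl <- .volume_label_at(volume, cell_barycenters(grid)[empty, , drop = FALSE])
    label[empty] <- bl
  }
  # cells outside the volume entirely: background
  label[is.na(label)] <- -1L

  pick <- function(field, default) {
    out <- rep(default, grid$n_cells)
    for (lv in labs_present) {
      m <- mats[[as.character(lv)]]
      val <- m[[field]]
      if (is.null(val) || !is.finite(val)) {
        val <- if (field == "a") 0 else if (field == "y") 1 else
          stop("material '", m$name, "' lacks required field ", field)
      }
      out[label == lv] <- val
    }
    out
  }
  bg_a <- if (is.finite(bg$a)) bg$a else 0
  bg_y <- if (is.finite(bg$y)) bg$y else 1
  scene <- list(grid = grid, label = label,
                rho = pick("rho", bg$rho), v = pick("v", bg$v),
                a = pick("a", bg_a), y = pick("y", bg_y),
                surfaces = surfaces,
                background = list(material = bg, rho0 = bg$rho),
                volume = volume, materials = mats, implants = list())
  class(scene) <- "us_scene"
  scene
}

#' @export
print.us_scene <- function(x, ...) {
  cat(sprintf("<us_scene> %d cells, %d surface(s), background %s\n",
              x$grid$n_cells, length(x$surfaces), x$background$material$name))
  invisible(x)
}

#' Per-cell complex propagation coefficient of a scene at a frequency
#'
#' @param scene A `us_scene`.
#' @param frequency Hz.
#' @return List with per-cell `gamma` (complex vector) and background
#'   `gamma0`.
#' @export
scene_gamma <- function(scene, frequency) {
  pc <- propagation_coefficient_vec(scene$v, scene$a, scene$y, frequency)
  bg <- scene$background$material
  bg_a <- if (is.finite(bg$a)) bg$a else 0
  bg_y <- if (is.finite(bg$y)) bg$y else 1
  pc0 <- propagation_coefficient_vec(bg$v, bg_a, bg_y, frequency)
  list(gamma = pc$gamma, gamma0 = pc0$gamma)
}

#' Generate a synthetic acoustic scene
#'
#' Three built-in study scenes requiring no external imaging data:
#' \describe{
#'   \item{`water_tank`}{Homogeneous water box, 0.30 m x 0.25 m x 0.25 m
#'     by default, with the source plane on the x = 0 wall.}
#'   \item{`layered_breast`}{Hemispherical breast analog (concentric
#'     skin/fat/breast shells) mounted on a muscle chest-wall slab in a
#'     water bath; skin is mapped to the fat-like PDMS row.}
#'   \item{`homogeneous`}{Single-material box.}
#' }
#'
#' @param kind One of `"water_tank"`, `"layered_breast"`, `"homogeneous"`.
#' @param params Named list overriding geometry defaults (see Details in
#'   the package vignette): `dims`, `voxel`, `base_h`, and for the breast
#'   `radius`, `t_skin`, `t_fat`, `t_wall`; `material` for homogeneous;
#'   `refine_box`/`refine_level` to pre-refine the grid; `n_directions`
#'   for boundary extraction; `surfaces` logical.
#' @param seed Integer seed (the built-in scenes are deterministic, but
#'   the seed is honoured so user extensions with stochastic texture stay
#'   reproducible).
#' @return List with `volume` (a `us_volume`) and `scene` (a `us_scene`).
#' @export
synthetic_scene <- function(kind = c("water_tank", "layered_breast",
                                     "homogeneous"),
                            params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default

  if (kind == "water_tank") {
    dims <- p("dims", c(0.30, 0.25, 0.25))
    voxel <- p("voxel", 0.005)
    base_h <- p("base_h", 0.01)
    nd <- round(dims / voxel)
    lab <- array(0L, nd)
    vol <- labeled_volume(lab, voxel)
    grid <- build_grid(dims, base_h)
    scene <- assign_properties(vol, list(`0` = "Water"), grid)
    scene$source_center <- c(0, dims[2] / 2, dims[3] / 2)
    scene$source_normal <- c(1, 0, 0)
  } else if (kind == "homogeneous") {
    dims <- p("dims", c(0.04, 0.04, 0.04))
    voxel <- p("voxel", 0.002)
    base_h <- p("base_h", 0.01)
    material <- p("material", "Water")
    nd <- round(dims / voxel)
    vol <- labeled_volume(array(0L, nd), voxel)
    grid <- build_grid(dims, base_h)
    scene <- assign_properties(vol, list(`0` = material), grid,
                               background = material)
    scene$source_center <- c(0, dims[2] / 2, dims[3] / 2)
    scene$source_normal <- c(1, 0, 0)
  } else { # layered_breast
    dims <- p("dims", c(0.06, 0.06, 0.06))
    voxel <- p("voxel", 0.002)
    base_h <- p("base_h", 0.01)
    radius <- p("radius", 0.025)
    t_skin <- p("t_skin", 0.002)
    t_fat <- p("t_fat", 0.010)
    t_wall <- p("t_wall", 0.010)
    nd <- round(dims / voxel)
    # voxel centres
    ax <- lapply(1:3, function(i) (seq_len(nd[i]) - 0.5) * voxel)
    ctr <- c(dims[1] - t_wall, dims[2] / 2, dims[3] / 2)  # hemisphere pole plane
    X <- array(rep(ax[[1]], times = nd[2] * nd[3]), nd)
    Y <- array(rep(rep(ax[[2]], each = nd[1]), times = nd[3]), nd)
    Z <- array(rep(ax[[3]], each = nd[1] * nd[2]), nd)
    r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
    lab <- array(0L, nd)
    hemi <- X <= ctr[1]  # breast bulges toward the source at x = 0
    lab[hemi & r < radius] <- 1L                       # skin
    lab[hemi & r < radius - t_skin] <- 2L              # fat
    lab[hemi & r < radius - t_skin - t_fat] <- 3L      # breast
    lab[X > ctr[1]] <- 4L                              # chest wall (muscle)
    vol <- labeled_volume(lab, voxel)
    grid <- build_grid(dims, base_h)
    if (!is.null(params$refine_box)) {
      grid <- refine(grid, params$refine_box, p("refine_level", 2L))
    }
    mats <- list(`0` = "Water", `1` = "PDMS", `2` = "Fat",
                 `3` = "Breast", `4` = "Muscle")
    surfs <- list()
    if (isTRUE(p("surfaces", TRUE))) {
      ndir <- p("n_directions", 512L)
      surfs <- lapply(1:4, function(tl) {
        suppressWarnings(extract_boundary(vol, tl, n_directions = ndir))
      })
    }
    scene <- assign_properties(vol, mats, grid, surfaces = surfs)
    scene$source_center <- c(0, dims[2] / 2, dims[3] / 2)
    scene$source_normal <- c(1, 0, 0)
  }
  list(volume = vol, scene = scene)
}

#' Read a stack of raster slices as a grey-level array
#'
#' One file per slice in lexicographic order; PNG and TIFF are supported.
#' Colour images are averaged to grey.
#'
#' @param files Character vector of file paths (sorted internally).
#' @return 3D numeric array (rows, cols, slices) with values in the
#'   file's native intensity scale.
#' @export
read_slice_stack <- function(files) {
  files <- sort(files)
  if (length(files) == 0L) stop("empty slice stack")
  read1 <- function(f) {
    ext <- tolower(tools::file_ext(f))
    img <- switch(ext,
                  png = png::readPNG(f),
                  tif = , tiff = tiff::readTIFF(f),
                  stop("unsupported slice format: ", ext))
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    img
  }
  slices <- lapply(files, read1)
  shapes <- unique(lapply(slices, dim))
  if (length(shapes) != 1L) stop("all slices must have the same shape")
  array(unlist(slices), dim = c(shapes[[1]], length(slices)))
}

#' Write a labelled volume as plain text
#'
#' Writes `meta.json` (dims, spacing, origin) and `labels.txt` (one slice
#' per block, rows of space-separated integers) under `dir`.
#'
#' @param volume A `us_volume`.
#' @param dir Output directory.
#' @return Invisibly, the directory path.
#' @export
write_volume <- function(volume, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(dims = volume$dims, spacing = volume$spacing,
                            origin = volume$origin),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(dir, "labels.txt"), "w")
  on.exit(close(con))
  for (s in seq_len(volume$dims[3])) {
    utils::write.table(volume$labels[, , s], con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}
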
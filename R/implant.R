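# Lens/disk/cone implants as nested layered solids: a bio-compatible PDMS
# shell around two piezoelectric layers (outer and inner), each carrying a
# sampled surface with outward and inward unit normals.

.ALLOWED_PAIRS <- list(c("PZN-PT", "LiNbO3"), c("PZN-PT", "BaTiO3"),
                       c("PZN-PT", "PVDF"), c("PZT-5A", "LiNbO3"),
                       c("PZT-5A", "BaTiO3"), c("PZT-5A", "PVDF"))
.ALLOWED_THICKNESS <- list(c(0.5, 1), c(1, 2), c(1.5, 3), c(2, 4), c(2.5, 5))

#' Specify a double-piezo-layer implant
#'
#' @param shape `"lens"` (semi-paraboloid cap facing the orientation
#'   axis), `"disk"` (right cylinder) or `"cone"` (right cone, apex along
#'   the axis).
#' @param materials Character pair `c(inner, outer)`; one of the six
#'   allowed compositions (PZN-PT or PZT-5A inner with LiNbO3, BaTiO3 or
#'   PVDF outer).
#' @param thickness_mm Numeric pair `c(inner, outer)` in mm; one of
#'   0.5/1, 1/2, 1.5/3, 2/4, 2.5/5.
#' @param bounding Outer bounding dimensions in metres
#'   `c(width, depth, height)`; default 1 cm x 1 cm x 0.5 cm. Width and
#'   depth must agree (circular footprint); `height` is the extent along
#'   the axis.
#' @param position Centre of the implant base in metres.
#' @param axis Unit orientation axis (the face presented to the source);
#'   default `c(-1, 0, 0)`.
#' @param pdms_mm PDMS shell thickness in mm (default 0.5).
#' @return A validated `us_implant_spec`.
#' @export
implant_spec <- function(shape = c("lens", "disk", "cone"),
                         materials = c("PZT-5A", "LiNbO3"),
                         thickness_mm = c(1, 2),
                         bounding = c(0.01, 0.01, 0.005),
                         position = c(0, 0, 0),
                         axis = c(-1, 0, 0),
                         pdms_mm = 0.5) {
  shape <- match.arg(shape)
  ok_pair <- any(vapply(.ALLOWED_PAIRS, function(p) all(p == materials),
                        logical(1)))
  if (!ok_pair) {
    stop("material pair ", paste(materials, collapse = "/"),
         " is not one of the six allowed inner/outer compositions")
  }
  ok_t <- any(vapply(.ALLOWED_THICKNESS,
                     function(t) isTRUE(all.equal(t, thickness_mm)),
                     logical(1)))
  if (!ok_t) {
    stop("thickness pair ", paste(thickness_mm, collapse = "/"),
         " mm is not one of 0.5/1, 1/2, 1.5/3, 2/4, 2.5/5")
  }
  if (abs(bounding[1] - bounding[2]) > 1e-12) {
    stop("bounding width and depth must agree (circular footprint)")
  }
  # the innermost layer surface sits pdms + outer-thickness inside the
  # bounding surface; the core it encloses must not collapse
  delta_in <- (pdms_mm + thickness_mm[2]) * 1e-3
  if (delta_in >= bounding[3] || delta_in >= bounding[1] / 2) {
    stop("layer thicknesses (PDMS ", pdms_mm, " mm + outer ",
         thickness_mm[2], " mm) exceed the bounding dimensions")
  }
  axis <- axis / sqrt(sum(axis^2))
  spec <- list(shape = shape, materials = materials,
               thickness_mm = thickness_mm, bounding = bounding,
               position = as.numeric(position), axis = axis,
               pdms_mm = pdms_mm)
  class(spec) <- "us_implant_spec"
  spec
}

# Orthonormal frame (e1, e2, axis) for a unit axis.
.axis_frame <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = axis)
}

# Sample one shape surface in local coordinates (axis = +z, base at z=0,
# extending to z = H, footprint radius R). Returns points and outward
# normals (local frame). `ds` is the target sample spacing in metres.
.shape_surface_local <- function(shape, R, H, ds) {
  pts <- list(); nrm <- list()
  add <- function(p, n) { pts[[length(pts) + 1]] <<- p; nrm[[length(nrm) + 1]] <<- n }
  disk_face <- function(z, nz) {
    nr <- max(2L, ceiling(R / ds))
    for (ri in seq_len(nr)) {
      rr <- (ri - 0.5) * R / nr
      na <- max(6L, ceiling(2 * pi * rr / ds))
      th <- (seq_len(na) - 0.5) * 2 * pi / na
      add(cbind(rr * cos(th), rr * sin(th), z),
          cbind(0 * th, 0 * th, 0 * th + nz))
    }
  }
  if (shape == "disk") {
    disk_face(H, 1); disk_face(0, -1)
    nz <- max(2L, ceiling(H / ds))
    for (zi in seq_len(nz)) {
      zz <- (zi - 0.5) * H / nz
      na <- max(6L, ceiling(2 * pi * R / ds))
      th <- (seq_len(na) - 0.5) * 2 * pi / na
      add(cbind(R * cos(th), R * sin(th), zz),
          cbind(cos(th), sin(th), 0 * th))
    }
  } else if (shape == "lens") {
    # plano-convex: cylinder base for z in [0, H/2], paraboloid cap of
    # height H/2 above: z = H/2 + (H/2)(1 - s^2/R^2)
    disk_face(0, -1)
    Hc <- H / 2
    nz <- max(2L, ceiling(Hc / ds))
    for (zi in seq_len(nz)) {
      zz <- (zi - 0.5) * Hc / nz
      na <- max(6L, ceiling(2 * pi * R / ds))
      th <- (seq_len(na) - 0.5) * 2 * pi / na
      add(cbind(R * cos(th), R * sin(th), zz),
          cbind(cos(th), sin(th), 0 * th))
    }
    nr <- max(3L, ceiling(sqrt(R^2 + Hc^2) / ds))
    for (ri in seq_len(nr)) {
      ss <- (ri - 0.5) * R / nr
      zz <- Hc + Hc * (1 - ss^2 / R^2)
      na <- max(6L, ceiling(2 * pi * max(ss, ds) / ds))
      th <- (seq_len(na) - 0.5) * 2 * pi / na
      # gradient of z - Hc - Hc(1 - s^2/R^2): (2 Hc x/R^2, 2 Hc y/R^2, 1)
      gx <- 2 * Hc * ss * cos(th) / R^2
      gy <- 2 * Hc * ss * sin(th) / R^2
      gn <- sqrt(gx^2 + gy^2 + 1)
      add(cbind(ss * cos(th), ss * sin(th), zz),
          cbind(gx / gn, gy / gn, 1 / gn))
    }
    # apex sample (normal along the axis)
    add(cbind(0, 0, H), cbind(0, 0, 1))
  } else { # cone: base radius R at z = 0, apex at z = H
    disk_face(0, -1)
    slant <- sqrt(R^2 + H^2)
    nr <- max(3L, ceiling(slant / ds))
    for (ri in seq_len(nr)) {
      frac <- (ri - 0.5) / nr          # 0 at base, 1 at apex
      ss <- R * (1 - frac)
      zz <- H * frac
      na <- max(6L, ceiling(2 * pi * max(ss, ds) / ds))
      th <- (seq_len(na) - 0.5) * 2 * pi / na
      # lateral normal: (cos th * H, sin th * H, R)/slant
      add(cbind(ss * cos(th), ss * sin(th), zz),
          cbind(cos(th) * H / slant, sin(th) * H / slant,
                0 * th + R / slant))
    }
  }
  list(points = do.call(rbind, pts), normals = do.call(rbind, nrm))
}

# Point-in-shape test in local coordinates.
.shape_inside_local <- function(shape, pts, R, H) {
  s2 <- pts[, 1]^2 + pts[, 2]^2
  z <- pts[, 3]
  if (shape == "disk") {
    s2 <= R^2 & z >= 0 & z <= H
  } else if (shape == "lens") {
    Hc <- H / 2
    z >= 0 & s2 <= R^2 & z <= Hc + Hc * (1 - s2 / R^2)
  } else {
    z >= 0 & z <= H & sqrt(s2) <= R * (1 - z / H)
  }
}

#' Build a layered implant solid from its specification
#'
#' The PDMS shell occupies the nominal bounding shape; the outer piezo
#' layer is the same shape shrunk inward by the shell thickness, and the
#' inner piezo is shrunk further by the outer layer thickness (parametric
#' inward offset: radius and height reduced together). Every layer
#' carries a sampled surface with outward normals; inward normals are the
#' exact negatives. Default sampling keeps adjacent samples closer than a
#' quarter wavelength at 10 MHz in soft tissue.
#'
#' @param spec A `us_implant_spec`.
#' @param max_spacing Surface sample spacing in metres (default
#'   `1540 / 10e6 / 4`).
#' @return A `us_implant`: list of 3 layers (outermost first), each with
#'   `material`, `points`, `normals_out`, `normals_in`, local shape
#'   parameters, plus the spec.
#' @export
build_implant <- function(spec, max_spacing = 1540 / 10e6 / 4) {
  stopifnot(inherits(spec, "us_implant_spec"))
  R0 <- spec$bounding[1] / 2
  H0 <- spec$bounding[3]
  offs <- c(0, spec$pdms_mm, spec$pdms_mm + spec$thickness_mm[2]) * 1e-3
  mats <- c("PDMS", spec$materials[2], spec$materials[1])
  frame <- .axis_frame(spec$axis)
  B <- rbind(frame$e1, frame$e2, frame$e3)  # local -> world rotation rows
  layers <- vector("list", 3L)
  for (li in 1:3) {
    # anisotropic inward offset: radius shrinks by the full offset, the
    # height by the same amount split between base and top, which keeps
    # every allowed thickness pair realisable inside the default envelope
    R <- R0 - offs[li]
    H <- H0 - offs[li]
    if (R <= 0 || H <= 0) stop("layer ", li, " collapses: thicknesses too large")
    surf <- .shape_surface_local(spec$shape, R, H, max_spacing)
    zoff <- offs[li] / 2
    local_pts <- surf$points
    local_pts[, 3] <- local_pts[, 3] + zoff
    world_pts <- local_pts %*% B
    world_pts <- sweep(world_pts, 2, spec$position, `+`)
    world_nrm <- surf$normals %*% B
    layers[[li]] <- list(material = get_material(mats[li]),
                         points = world_pts,
                         normals_out = world_nrm,
                         normals_in = -world_nrm,
                         shape = spec$shape, R = R, H = H, z_offset = zoff)
  }
  solid <- list(layers = layers, spec = spec)
  class(solid) <- "us_implant"
  solid
}

#' @export
print.us_implant <- function(x, ...) {
  cat(sprintf("<us_implant> %s, layers %s, %d surface samples\n",
              x$spec$shape,
              paste(vapply(x$layers, function(l) l$material$name,
                           character(1)), collapse = "/"),
              sum(vapply(x$layers, function(l) nrow(l$points), integer(1)))))
  invisible(x)
}

# Which of the given world points fall inside layer `li` of the solid
# (inside its outer surface, regardless of deeper layers).
implant_layer_inside <- function(solid, li, pts) {
  spec <- solid$spec
  lay <- solid$layers[[li]]
  frame <- .axis_frame(spec$axis)
  B <- rbind(frame$e1, frame$e2, frame$e3)
  local <- sweep(rbind(pts), 2, spec$position, `-`) %*% t(B)
  local[, 3] <- local[, 3] - lay$z_offset
  .shape_inside_local(lay$shape, local, lay$R, lay$H)
}

#' Embed an implant into an acoustic scene
#'
#' Cells whose barycenter lies inside a layer take that layer's material
#' (innermost wins); the layer surfaces are appended to the scene surface
#' list. Optionally the grid is refined to the finest level over the
#' implant bounding box extended toward the source (the source-implant
#' corridor), in which case all scene maps are re-derived from the stored
#' labelled volume before the override.
#'
#' @param scene A `us_scene`.
#' @param solid A `us_implant`.
#' @param refine_corridor If `TRUE` (default), refine to `refine_level`
#'   over the implant box plus the corridor to `scene$source_center`.
#' @param refine_level Target refinement level (default 2).
#' @param margin Extra margin around the refinement box in metres.
#' @return The modified `us_scene`; the pre-override property maps are
#'   kept in `scene$pristine` so [unembed()] can restore them.
#' @export
embed_implant <- function(scene, solid, refine_corridor = TRUE,
                          refine_level = 2L, margin = 0.005) {
  stopifnot(inherits(scene, "us_scene"), inherits(solid, "us_implant"))
  pts <- do.call(rbind, lapply(solid$layers, function(l) l$points))
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  dom_lo <- scene$grid$origin
  dom_hi <- scene$grid$origin + scene$grid$extent
  if (any(lo < dom_lo) || any(hi > dom_hi)) {
    stop("implant extends outside the scene domain")
  }
  if (!is.null(scene$source_center)) {
    d2 <- sum((scene$source_center - solid$spec$position)^2)
    if (d2 < sum((hi - lo)^2) / 16) stop("implant overlaps the source")
  }
  if (refine_corridor) {
    box_lo <- pmax(lo - margin, dom_lo)
    box_hi <- pmin(hi + margin, dom_hi)
    if (!is.null(scene$source_center)) {
      box_lo <- pmax(pmin(box_lo, scene$source_center - margin), dom_lo)
      box_hi <- pmin(pmax(box_hi, scene$source_center + margin), dom_hi)
    }
    grid <- refine(scene$grid, list(min = box_lo, max = box_hi), refine_level)
    src <- scene$source_center; srcn <- scene$source_normal
    scene <- assign_properties(scene$volume, scene$materials, grid,
                               background = scene$background$material,
                               surfaces = scene$surfaces)
    scene$source_center <- src; scene$source_normal <- srcn
  }
  scene$pristine <- scene[c("rho", "v", "a", "y", "label")]
  bc <- cell_barycenters(scene$grid)
  for (li in 1:3) {  # outermost first; inner layers overwrite
    inside <- implant_layer_inside(solid, li, bc)
    m <- solid$layers[[li]]$material
    scene$rho[inside] <- m$rho
    scene$v[inside] <- m$v
    scene$a[inside] <- if (is.finite(m$a)) m$a else 0
    scene$y[inside] <- if (is.finite(m$y)) m$y else 1
    scene$label[inside] <- 100L + 10L * length(scene$implants) + li
  }
  for (li in 1:3) {
    lay <- solid$layers[[li]]
    scene$surfaces[[length(scene$surfaces) + 1]] <-
      structure(list(tissue = 100L + 10L * length(scene$implants) + li,
                     points = lay$points, normals = lay$normals_out,
                     centroid = colMeans(lay$points)),
                class = "us_surface")
  }
  scene$implants[[length(scene$implants) + 1]] <- solid
  scene
}

#' Restore a scene's property maps to their pre-embedding state
#'
#' @param scene A `us_scene` previously passed through [embed_implant()].
#' @return The scene with the stored pristine property maps, implant
#'   surfaces and implant list removed.
#' @export
unembed <- function(scene) {
  if (is.null(scene$pristine)) return(scene)
  scene[c("rho", "v", "a", "y", "label")] <- scene$pristine
  scene$surfaces <- Filter(function(s) s$tissue < 100L, scene$surfaces)
  scene$implants <- list()
  scene$pristine <- NULL
  scene
}
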
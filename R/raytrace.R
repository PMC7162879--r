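# Ray-tracing operator: emission from the source disk, straight-segment
# propagation between interfaces, Snell refraction with the 3D direction
# update, impedance-based amplitude splitting, power-law attenuation and
# phase-delay accumulation, and aperture detection.

#' Snell's law
#'
#' @param n1,n2 Refraction indices of the incident and transmitting media.
#' @param theta_in Incidence angle in radians, in `[0, pi/2]`.
#' @return Refraction angle in radians, or `NA` on total internal
#'   reflection.
#' @export
snell <- function(n1, n2, theta_in) {
  stopifnot(n1 > 0, n2 > 0, theta_in >= 0, theta_in <= pi / 2 + 1e-12)
  s <- n1 * sin(theta_in) / n2
  if (s > 1) return(NA_real_)
  asin(s)
}

#' Refracted ray direction at an interface
#'
#' Vector form of Snell's law:
#' `r' = (n1/n2) [N x (-N x r)] - N sqrt(1 - (n1/n2)^2 (N x r).(N x r))`
#' with `N` the unit interface normal oriented against the incident ray
#' (`r . N < 0`) and `r` the unit incident direction.
#'
#' @param r_hat Unit incident direction.
#' @param n_hat Unit normal, oriented so `sum(r_hat * n_hat) < 0`.
#' @param n1,n2 Refraction indices.
#' @return Unit refracted direction, or `NULL` on total internal
#'   reflection (including the degenerate grazing case).
#' @export
refract_direction <- function(r_hat, n_hat, n1, n2) {
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  eta <- n1 / n2
  nxr <- cx(n_hat, r_hat)
  rad <- 1 - eta^2 * sum(nxr * nxr)
  if (rad < 0) return(NULL)
  out <- eta * cx(n_hat, -nxr) - n_hat * sqrt(rad)
  nn <- sqrt(sum(out^2))
  if (!is.finite(nn) || nn == 0) return(NULL)
  out / nn
}

#' Split a ray amplitude at an impedance interface
#'
#' Reflected amplitude `R * amp` with `R = (z2 - z1)/(z2 + z1)`; the
#' transmitted amplitude is `(1 - R) * amp` so that the two parts sum
#' exactly to the incident amplitude (the framework's stated conservation
#' rule). The physically standard pressure transmission `T = 1 + R`
#' violates that conservation and is available as `mode = "pressure"`.
#'
#' @param amp Incident amplitude.
#' @param z1,z2 Impedances on the incident and transmitting sides.
#' @param mode `"conservation"` (default) or `"pressure"`.
#' @return List with `transmitted` and `reflected` amplitudes.
#' @export
split_amplitude <- function(amp, z1, z2, mode = c("conservation", "pressure")) {
  mode <- match.arg(mode)
  R <- reflection_coefficient(z1, z2)
  refl <- R * amp
  trans <- if (mode == "conservation") amp - refl else amp + refl
  list(transmitted = trans, reflected = refl)
}

# Spatial bucket index over all scene surface samples for nearest-normal
# queries at interface hits.
.surface_index <- function(scene, cellsize) {
  pts <- lapply(scene$surfaces, function(s) s$points)
  nrm <- lapply(scene$surfaces, function(s) s$normals)
  if (length(pts) == 0L) return(NULL)
  P <- do.call(rbind, pts)
  N <- do.call(rbind, nrm)
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = "_")
  ijk <- floor(P / cellsize)
  buckets <- split(seq_len(nrow(P)), key(ijk))
  list(P = P, N = N, buckets = buckets, cellsize = cellsize)
}

# Nearest surface sample within `maxdist` of a point; NULL if none.
.nearest_surface_normal <- function(sidx, pt, maxdist) {
  if (is.null(sidx)) return(NULL)
  c0 <- floor(pt / sidx$cellsize)
  cand <- integer(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    b <- sidx$buckets[[paste(c0[1] + di, c0[2] + dj, c0[3] + dk, sep = "_")]]
    if (!is.null(b)) cand <- c(cand, b)
  }
  if (length(cand) == 0L) return(NULL)
  d2 <- (sidx$P[cand, 1] - pt[1])^2 + (sidx$P[cand, 2] - pt[2])^2 +
    (sidx$P[cand, 3] - pt[3])^2
  best <- which.min(d2)
  if (d2[best] > maxdist^2) return(NULL)
  list(point = sidx$P[cand[best], ], normal = sidx$N[cand[best], ])
}

#' Trace acoustic rays through a scene
#'
#' Rays are emitted from uniformly sampled points of the source disk into
#' a forward cone, advance in straight segments between label changes of
#' the per-cell material map, and at each interface spawn a transmitted
#' ray (direction from the vector Snell update, amplitude `(1-R)`) and a
#' reflected ray (specular direction, amplitude `R`), using the nearest
#' sampled surface normal within the intersection tolerance sphere of
#' radius `0.5 * 4500 / frequency` (4500 m/s being the average
#' propagation velocity of the tissues and piezos modelled). Per-segment
#' attenuation multiplies `exp(-alpha_i * L)` and the delay accumulates
#' `L / v_i`. Rays terminate on domain exit, after `max_wavelengths`
#' accumulated wavelengths, when the carried amplitude falls below
#' `min_amplitude`, or at `max_generation` interface events.
#'
#' @param scene A `us_scene` (its surfaces supply interface normals; a
#'   scene without surfaces propagates rays in straight lines).
#' @param source A `us_source`.
#' @param frequency Hz.
#' @param n_rays Number of emitted rays (default 128).
#' @param amplitude Total source amplitude, split evenly over rays
#'   (default 10, the excitation pulse amplitude).
#' @param cone_half_angle Emission cone half-angle in radians (default 30
#'   degrees).
#' @param limits List overriding `max_wavelengths` (1000),
#'   `min_amplitude` (1e-5), `max_generation` (6), `max_rays` (20000).
#' @param seed RNG seed for emission sampling (default 1).
#' @param split_mode Amplitude split rule, see [split_amplitude()].
#' @return A `us_rays` object: `rays` data frame (one row per terminated
#'   ray: terminal segment endpoints and direction, amplitude, cumulative
#'   attenuation and delay at the segment start, medium properties,
#'   generation, termination reason), `segments` data frame of all
#'   traversed segments, and the trace parameters.
#' @export
trace_rays <- function(scene, source, frequency, n_rays = 128,
                       amplitude = 10, cone_half_angle = pi / 6,
                       limits = list(), seed = 1,
                       split_mode = c("conservation", "pressure")) {
  split_mode <- match.arg(split_mode)
  lim <- utils::modifyList(list(max_wavelengths = 1000, min_amplitude = 1e-5,
                                max_generation = 6L, max_rays = 20000L),
                           limits)
  set.seed(as.integer(seed))
  grid <- scene$grid
  tol_r <- 0.5 * 4500 / frequency
  step <- tol_r
  eps <- step / 20
  alpha_cell <- propagation_coefficient_vec(scene$v, scene$a, scene$y,
                                            frequency)$alpha
  sidx <- .surface_index(scene, cellsize = max(tol_r, min(cell_h(grid))))

  # emission: uniform points on the source disk, cone directions
  frame <- .axis_frame(source$normal)
  rr <- source$radius * sqrt(stats::runif(n_rays))
  th <- 2 * pi * stats::runif(n_rays)
  origins <- sweep((rr * cos(th)) %o% frame$e1 + (rr * sin(th)) %o% frame$e2,
                   2, source$center, `+`)
  cosa <- 1 - stats::runif(n_rays) * (1 - cos(cone_half_angle))
  sina <- sqrt(1 - cosa^2)
  phi <- 2 * pi * stats::runif(n_rays)
  dirs <- cosa %o% source$normal +
    (sina * cos(phi)) %o% frame$e1 + (sina * sin(phi)) %o% frame$e2
  dirs <- dirs / sqrt(rowSums(dirs^2))

  queue <- vector("list", n_rays)
  for (i in seq_len(n_rays)) {
    queue[[i]] <- list(origin = origins[i, ] + eps * dirs[i, ],
                       dir = dirs[i, ], amp = amplitude / n_rays,
                       atten = 1, delay = 0, wl = 0, gen = 0L)
  }
  done <- list()
  segs <- list()
  n_spawned <- n_rays
  while (length(queue) > 0L) {
    ray <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    cell0 <- locate_cells(grid, rbind(ray$origin))
    if (is.na(cell0)) {  # born outside: record as immediately exited
      done[[length(done) + 1]] <- c(ray, list(to = ray$origin, reason = "exit",
                                              v = NA_real_, alpha = NA_real_))
      next
    }
    lab0 <- scene$label[cell0]
    v0 <- scene$v[cell0]; al0 <- alpha_cell[cell0]
    lambda <- v0 / frequency
    max_d <- (lim$max_wavelengths - ray$wl) * lambda
    ts <- seq(step, max(max_d, step), by = step)
    pos <- outer(ts, ray$dir) + rep(ray$origin, each = length(ts))
    cells <- locate_cells(grid, pos)
    labs <- ifelse(is.na(cells), NA_integer_, scene$label[cells])
    change <- which(is.na(labs) | labs != lab0)[1]
    if (is.na(change)) {
      # wavelength budget exhausted inside the medium
      L <- max_d
      endp <- ray$origin + L * ray$dir
      segs[[length(segs) + 1]] <- c(ray$origin, endp, lab0, ray$amp)
      done[[length(done) + 1]] <- c(ray, list(to = endp, reason = "wavelengths",
                                              v = v0, alpha = al0))
      next
    }
    # bisect the hit between the last same-label and first different sample
    t_lo <- if (change == 1L) 0 else ts[change - 1L]
    t_hi <- ts[change]
    for (b in 1:25) {
      t_mid <- (t_lo + t_hi) / 2
      cm <- locate_cells(grid, rbind(ray$origin + t_mid * ray$dir))
      lm <- if (is.na(cm)) NA_integer_ else scene$label[cm]
      if (!is.na(lm) && lm == lab0) t_lo <- t_mid else t_hi <- t_mid
    }
    t_hit <- (t_lo + t_hi) / 2
    hit <- ray$origin + t_hit * ray$dir
    segs[[length(segs) + 1]] <- c(ray$origin, hit, lab0, ray$amp)
    atten_hit <- ray$atten * exp(-al0 * t_hit)
    delay_hit <- ray$delay + t_hit / v0
    wl_hit <- ray$wl + t_hit / lambda
    exiting <- is.na(labs[change])
    if (exiting) {
      done[[length(done) + 1]] <- c(ray, list(to = hit, reason = "exit",
                                              v = v0, alpha = al0))
      next
    }
    if (ray$gen >= lim$max_generation) {
      done[[length(done) + 1]] <- c(ray, list(to = hit, reason = "generation",
                                              v = v0, alpha = al0))
      next
    }
    cell2 <- cells[change]
    v2 <- scene$v[cell2]
    z1 <- scene$rho[cell0] * v0
    z2 <- scene$rho[cell2] * v2
    n1 <- scene$background$material$v / v0
    n2 <- scene$background$material$v / v2
    nrm <- .nearest_surface_normal(sidx, hit, tol_r)
    n_hat <- if (is.null(nrm)) -ray$dir else nrm$normal
    if (sum(n_hat * ray$dir) > 0) n_hat <- -n_hat
    sp <- split_amplitude(ray$amp, z1, z2, mode = split_mode)
    t_dir <- refract_direction(ray$dir, n_hat, n1, n2)
    if (is.null(t_dir)) {  # total internal reflection: all energy reflects
      sp$reflected <- ray$amp
      sp$transmitted <- 0
    }
    r_dir <- ray$dir - 2 * sum(ray$dir * n_hat) * n_hat
    spawn <- function(origin, dir, amp) {
      if (abs(amp) * atten_hit < lim$min_amplitude) return()
      if (n_spawned >= lim$max_rays) return()
      n_spawned <<- n_spawned + 1L
      queue[[length(queue) + 1L]] <<- list(origin = origin, dir = dir,
                                           amp = amp, atten = atten_hit,
                                           delay = delay_hit, wl = wl_hit,
                                           gen = ray$gen + 1L)
    }
    if (!is.null(t_dir) && sp$transmitted != 0) {
      spawn(hit + eps * t_dir, t_dir, sp$transmitted)
    }
    if (sp$reflected != 0) spawn(hit + eps * r_dir, r_dir, sp$reflected)
    done[[length(done) + 1]] <- c(ray, list(to = hit, reason = "interface",
                                            v = v0, alpha = al0))
  }
  rays <- do.call(rbind, lapply(done, function(d) {
    data.frame(x0 = d$origin[1], y0 = d$origin[2], z0 = d$origin[3],
               x1 = d$to[1], y1 = d$to[2], z1 = d$to[3],
               dx = d$dir[1], dy = d$dir[2], dz = d$dir[3],
               amp = d$amp, atten = d$atten, delay = d$delay,
               wavelengths = d$wl, generation = d$gen,
               v = d$v, alpha = d$alpha, reason = d$reason)
  }))
  segments <- if (length(segs) > 0) {
    m <- do.call(rbind, segs)
    data.frame(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3], x1 = m[, 4],
               y1 = m[, 5], z1 = m[, 6], label = m[, 7], amp = m[, 8])
  } else data.frame()
  out <- list(rays = rays, segments = segments, frequency = frequency,
              tol_r = tol_r, n_emitted = n_rays, n_spawned = n_spawned)
  class(out) <- "us_rays"
  out
}

#' @export
print.us_rays <- function(x, ...) {
  cat(sprintf("<us_rays> %d emitted, %d total, %d terminal records\n",
              x$n_emitted, x$n_spawned, nrow(x$rays)))
  invisible(x)
}

#' Apply the detection threshold and record cap to echo records
#'
#' Records with `|amplitude|` below `threshold` are dropped; at most
#' `cap` records are kept, preferring the largest amplitudes.
#'
#' @param records Data frame with columns `time`, `amplitude` (and
#'   optionally others).
#' @param threshold Amplitude threshold (default 1e-5, the 10 uV
#'   equivalent).
#' @param cap Maximum number of records (default 1200).
#' @return The filtered data frame, ordered by arrival time.
#' @export
filter_echo_records <- function(records, threshold = 1e-5, cap = 1200L) {
  if (nrow(records) == 0L) return(records)
  keep <- records[abs(records$amplitude) >= threshold, , drop = FALSE]
  if (nrow(keep) > cap) {
    ord <- order(abs(keep$amplitude), decreasing = TRUE)
    keep <- keep[ord[seq_len(cap)], , drop = FALSE]
  }
  keep[order(keep$time), , drop = FALSE]
}

#' Collect echoes arriving on a detector aperture
#'
#' A traced ray contributes when its terminal segment crosses the
#' detector disk; the arrival amplitude is the carried amplitude times
#' the attenuation accumulated up to the crossing, and the arrival time
#' is the accumulated delay. The 10 uV threshold and the 1200-record cap
#' are then applied via [filter_echo_records()].
#'
#' @param rays A `us_rays` result.
#' @param detector_center Disk centre (m).
#' @param aperture_diameter Aperture diameter in metres (nominal sweep
#'   range 0.01 to 0.07 m).
#' @param frequency Hz (recorded alongside).
#' @param detector_normal Unit disk normal (default +x).
#' @param threshold,cap See [filter_echo_records()].
#' @return Data frame of echo records: `time`, `amplitude`, `aperture`,
#'   `generation`.
#' @export
collect_echo <- function(rays, detector_center, aperture_diameter, frequency,
                         detector_normal = c(1, 0, 0), threshold = 1e-5,
                         cap = 1200L) {
  rr <- rays$rays
  if (is.null(rr) || nrow(rr) == 0L) {
    return(data.frame(time = numeric(0), amplitude = numeric(0),
                      aperture = numeric(0), generation = integer(0)))
  }
  n <- detector_normal / sqrt(sum(detector_normal^2))
  p0 <- cbind(rr$x0, rr$y0, rr$z0)
  p1 <- cbind(rr$x1, rr$y1, rr$z1)
  seg <- p1 - p0
  seg_len <- sqrt(rowSums(seg^2))
  denom <- seg %*% n
  num <- -(sweep(p0, 2, detector_center, `-`) %*% n)
  t_par <- ifelse(abs(denom) < 1e-300, NA_real_, num / denom)
  frac <- as.numeric(t_par)
  # small slack: terminal points sit on the domain boundary only to the
  # bisection precision of the tracer
  ok <- !is.na(frac) & frac > 0 & frac <= 1 + 1e-6 & seg_len > 0
  cross <- p0 + seg * frac
  radial <- sweep(cross, 2, detector_center, `-`)
  radial <- radial - (radial %*% n) %*% t(n)
  rdist <- sqrt(rowSums(radial^2))
  ok <- ok & rdist <= aperture_diameter / 2
  if (!any(ok)) {
    return(data.frame(time = numeric(0), amplitude = numeric(0),
                      aperture = numeric(0), generation = integer(0)))
  }
  d_cross <- seg_len[ok] * frac[ok]
  amp <- rr$amp[ok] * rr$atten[ok] * exp(-rr$alpha[ok] * d_cross)
  tim <- rr$delay[ok] + d_cross / rr$v[ok]
  rec <- data.frame(time = tim, amplitude = amp,
                    aperture = aperture_diameter,
                    generation = rr$generation[ok])
  filter_echo_records(rec, threshold = threshold, cap = cap)
}
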
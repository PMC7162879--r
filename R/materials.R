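# Acoustic material properties and pointwise acoustic quantities:
# power-law attenuation, complex propagation coefficient, contrast
# functions, impedance and interface reflection.

# dB per neper for amplitude quantities: 20*log10(e) = 8.6859...
.DB_PER_NP <- 20 / log(10)

#' Built-in acoustic material table
#'
#' Longitudinal velocity `v` (m/s), density `rho` (kg/m^3), power-law
#' attenuation constant `a` (dB MHz^-y cm^-1) and exponent `y` for soft
#' tissues and water, plus elastic moduli (`E`, `G` in GPa, Poisson ratio
#' `eta`) for the piezoelectric ceramics and polymers used in implant
#' layers. The water density is the standard 1000 kg/m^3. The `PDMS` row
#' is a synthetic entry carrying fat-like acoustic properties (PDMS has an
#' acoustic impedance close to fat); it is not a measured characterisation
#' of PDMS.
#'
#' @param file Optional path to a user table in the same tab-separated
#'   layout (columns `name, class, v, rho, a, y, E, eta, G`); defaults to
#'   the table shipped with the package.
#' @return A data frame, one row per material.
#' @export
#' @examples
#' mt <- material_table()
#' mt[mt$name == "Liver", ]
material_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "materials.tsv", package = "usforward")
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  needed <- c("name", "v", "rho", "a", "y")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop("material table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$name)) stop("duplicated material names in table")
  tab
}

#' Look up one material as a `us_material` object
#'
#' @param name Material name as it appears in the table (case-insensitive).
#' @param table Material table; defaults to [material_table()].
#' @return A list of class `us_material` with fields `name, v, rho, a, y`
#'   and, when present, `E, eta, G`.
#' @export
get_material <- function(name, table = material_table()) {
  hit <- which(tolower(table$name) == tolower(name))
  if (length(hit) != 1L) {
    stop("unknown material '", name, "'; table has: ",
         paste(table$name, collapse = ", "))
  }
  row <- as.list(table[hit, , drop = FALSE])
  row <- lapply(row, function(x) if (is.factor(x)) as.character(x) else x)
  m <- list(name = row$name, class = row$class,
            v = as.numeric(row$v), rho = as.numeric(row$rho),
            a = as.numeric(row$a), y = as.numeric(row$y),
            E = as.numeric(row$E), eta = as.numeric(row$eta),
            G = as.numeric(row$G))
  if (!is.finite(m$v) || m$v <= 0) stop("material '", name, "': v must be > 0")
  if (!is.finite(m$rho) || m$rho <= 0) stop("material '", name, "': rho must be > 0")
  class(m) <- "us_material"
  m
}

#' @export
print.us_material <- function(x, ...) {
  cat(sprintf("<us_material> %s: v = %g m/s, rho = %g kg/m^3", x$name, x$v, x$rho))
  if (is.finite(x$a)) cat(sprintf(", a = %g dB MHz^-y cm^-1, y = %g", x$a, x$y))
  cat("\n")
  invisible(x)
}

#' Complex propagation coefficient under the tissue power law
#'
#' Attenuation follows `alpha = a * f^y` with `f` in MHz and `a` in
#' dB MHz^-y cm^-1, converted to Np/m; the phase constant is
#' `beta = omega/v` plus the power-law dispersion correction
#' `a * tan(pi*y/2) * f^y` (same unit conversion). The dispersion factor
#' diverges for `y = 1`; for exponents within 1e-9 of 1 the correction is
#' taken as zero.
#'
#' @param material A `us_material` (or any list with `v`, `a`, `y`).
#' @param frequency Excitation frequency in Hz (> 0).
#' @return A list of class `us_propagation` with `alpha` (Np/m), `beta`
#'   (rad/m) and `gamma = alpha + 1i*beta` (1/m).
#' @export
#' @examples
#' propagation_coefficient(get_material("Breast"), 5e6)
propagation_coefficient <- function(material, frequency) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0) {
    stop("frequency must be a single positive number (Hz)")
  }
  nm <- if (!is.null(material$name)) material$name else "<unnamed>"
  if (is.null(material$a) || !is.finite(material$a) ||
      is.null(material$y) || !is.finite(material$y)) {
    stop("material '", nm, "' has no attenuation law (a, y); ",
         "cannot form its propagation coefficient")
  }
  pc <- propagation_coefficient_vec(material$v, material$a, material$y, frequency)
  out <- list(alpha = pc$alpha, beta = pc$beta, gamma = pc$gamma,
              frequency = frequency)
  class(out) <- "us_propagation"
  out
}

# Vectorised propagation coefficient over per-cell (v, a, y) maps.
# a in dB MHz^-y cm^-1, frequency in Hz; returns alpha (Np/m), beta (rad/m).
propagation_coefficient_vec <- function(v, a, y, frequency) {
  f_mhz <- frequency / 1e6
  omega <- 2 * pi * frequency
  alpha_db_cm <- a * f_mhz^y
  alpha <- alpha_db_cm * 100 / .DB_PER_NP
  disp <- ifelse(abs(y - 1) < 1e-9, 0, tan(pi * y / 2))
  beta <- omega / v + a * disp * f_mhz^y * 100 / .DB_PER_NP
  list(alpha = alpha, beta = beta, gamma = complex(real = alpha, imaginary = beta))
}

#' Density and propagation-coefficient contrast maps
#'
#' Per-cell deviation of the medium from the homogeneous background:
#' `delta_rho = (rho0 - rho)/rho` and
#' `delta_gamma = gamma0^2 - (rho0/rho) * gamma^2`. Cells whose properties
#' equal the background have both contrasts identically zero.
#'
#' @param rho Per-cell density (kg/m^3), all > 0.
#' @param gamma Per-cell complex propagation coefficient (1/m).
#' @param rho0 Background density (kg/m^3).
#' @param gamma0 Background complex propagation coefficient (1/m).
#' @return List of class `us_contrasts` with `delta_rho` (real vector),
#'   `delta_gamma` (complex vector), `rho0`, `gamma0`.
#' @export
contrast_maps <- function(rho, gamma, rho0, gamma0) {
  if (length(rho) != length(gamma)) stop("rho and gamma must have equal length")
  bad <- which(!is.finite(rho) | rho <= 0)
  if (length(bad) > 0L) {
    stop("non-positive or non-finite density at cell(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(!is.finite(Re(gamma)) | !is.finite(Im(gamma)))) {
    stop("non-finite propagation coefficient in gamma map")
  }
  out <- list(delta_rho = (rho0 - rho) / rho,
              delta_gamma = gamma0^2 - (rho0 / rho) * gamma^2,
              rho0 = rho0, gamma0 = gamma0)
  class(out) <- "us_contrasts"
  out
}

#' Characteristic acoustic impedance Z = rho * v
#'
#' @param material A `us_material` (or list with `v`, `rho`).
#' @return Impedance in MRayls (1e6 kg m^-2 s^-1).
#' @export
#' @examples
#' acoustic_impedance(get_material("LiNbO3"))  # 34.15 MRayls
acoustic_impedance <- function(material) {
  if (is.null(material$v) || is.null(material$rho)) {
    stop("material must carry v and rho")
  }
  material$rho * material$v / 1e6
}

#' One-dimensional pressure reflection coefficient at an interface
#'
#' `R = (z2 - z1)/(z2 + z1)` for a wave travelling from medium 1 into
#' medium 2; positive when `z2 > z1`.
#'
#' @param z1,z2 Characteristic impedances of the incident and transmitting
#'   media (any common unit, e.g. MRayls), both > 0.
#' @return Dimensionless reflection coefficient in (-1, 1).
#' @export
reflection_coefficient <- function(z1, z2) {
  if (any(!is.finite(z1) | z1 <= 0) || any(!is.finite(z2) | z2 <= 0)) {
    stop("impedances must be positive and finite")
  }
  (z2 - z1) / (z2 + z1)
}
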
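#' Patch probe geometry
#'
#' Describes the optical layout of one wearable NIRS patch: the
#' source-detector separations, the laser wavelengths and the sampling rate.
#' Defaults match a four-wavelength (670/780/808/850 nm) patch with
#' photodiodes at 25 mm and 32 mm sampled at 2.24 Hz.
#'
#' @param source_detector_distances_mm Strictly increasing positive distances
#'   between the source column and each detector, in mm.
#' @param wavelengths_nm Laser diode wavelengths, in nm.
#' @param sampling_rate_hz Acquisition rate shared by all channels, in Hz.
#' @return An object of class `patch_geometry`.
#' @examples
#' patch_geometry()
#' @export
patch_geometry <- function(source_detector_distances_mm = c(25, 32),
                           wavelengths_nm = c(670, 780, 808, 850),
                           sampling_rate_hz = 2.24) {
  rho <- as.numeric(source_detector_distances_mm)
  wl <- as.numeric(wavelengths_nm)
  if (length(rho) < 1 || any(rho <= 0) || is.unsorted(rho, strictly = TRUE)) {
    stop("source-detector distances must be positive and strictly increasing", call. = FALSE)
  }
  if (length(wl) < 1 || any(wl <= 0)) stop("need at least one positive wavelength", call. = FALSE)
  if (length(sampling_rate_hz) != 1 || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive scalar", call. = FALSE)
  }
  structure(
    list(
      source_detector_distances_mm = rho,
      wavelengths_nm = wl,
      sampling_rate_hz = as.numeric(sampling_rate_hz)
    ),
    class = "patch_geometry"
  )
}

#' Bulk tissue optical properties at one wavelength
#'
#' @param mu_a Absorption coefficient, 1/mm.
#' @param mu_s_prime Reduced scattering coefficient, 1/mm.
#' @param A Dimensionless internal-reflection boundary constant (>= 1);
#'   2.95 is a common tissue-air value for refractive index ~1.4.
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s_prime, A = 2.95) {
  if (any(mu_a <= 0) || any(mu_s_prime <= 0)) {
    stop("mu_a and mu_s_prime must be positive", call. = FALSE)
  }
  if (any(A < 1)) stop("boundary constant A must be >= 1", call. = FALSE)
  if (any(mu_a / mu_s_prime > 0.1)) {
    warning("mu_a/mu_s_prime > 0.1: diffusion approximation is questionable", call. = FALSE)
  }
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, A = A),
            class = "optical_properties")
}

#' Continuous-wave diffuse reflectance of a semi-infinite medium
#'
#' Extrapolated-boundary dipole solution of the diffusion approximation for a
#' pencil beam on a homogeneous semi-infinite medium. Relative units: an
#' overall instrument gain is unconstrained, so only ratios and log-changes of
#' the returned value are meaningful downstream.
#'
#' The isotropic source sits at depth `z0 = 1/(mu_a + mu_s')`; the negative
#' image source at `-(z0 + 2*zb)` with `zb = 2*A*D`, `D = 1/(3*(mu_a + mu_s'))`,
#' and `mu_eff = sqrt(3*mu_a*(mu_a + mu_s'))`.
#'
#' @param mu_a Absorption coefficient, 1/mm (vectorised).
#' @param mu_s_prime Reduced scattering coefficient, 1/mm.
#' @param rho_mm Source-detector distance, mm.
#' @param A Boundary constant, see [optical_properties()].
#' @return Diffuse reflectance (relative intensity), same length as the
#'   recycled arguments; strictly decreasing in both `rho_mm` and `mu_a`.
#' @examples
#' diffuse_reflectance(0.01, 1.0, 25) / diffuse_reflectance(0.01, 1.0, 32)
#' @export
diffuse_reflectance <- function(mu_a, mu_s_prime, rho_mm, A = 2.95) {
  if (any(mu_a <= 0) || any(mu_s_prime <= 0) || any(rho_mm <= 0)) {
    stop("mu_a, mu_s_prime and rho_mm must all be positive", call. = FALSE)
  }
  mut <- mu_a + mu_s_prime
  z0 <- 1 / mut
  zb <- 2 * A / (3 * mut)
  z2 <- z0 + 2 * zb
  mueff <- sqrt(3 * mu_a * mut)
  r1 <- sqrt(rho_mm^2 + z0^2)
  r2 <- sqrt(rho_mm^2 + z2^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     z2 * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

#' Differential pathlength factor
#'
#' DPF = (1/rho) * d(-ln R)/d(mu_a), evaluated analytically from the dipole
#' reflectance model. It is the factor by which the mean photon path exceeds
#' the source-detector chord, and is the scaling used in the modified
#' Beer-Lambert law `dOD ~ DPF * rho * d(mu_a)`.
#'
#' @inheritParams diffuse_reflectance
#' @return Dimensionless DPF (> 1), decreasing in `mu_a`.
#' @export
differential_pathlength_factor <- function(mu_a, mu_s_prime, rho_mm, A = 2.95) {
  if (any(mu_a <= 0) || any(mu_s_prime <= 0) || any(rho_mm <= 0)) {
    stop("mu_a, mu_s_prime and rho_mm must all be positive", call. = FALSE)
  }
  mut <- mu_a + mu_s_prime
  z0 <- 1 / mut
  k2 <- 1 + 4 * A / 3          # z2 = k2 / mut
  z2 <- k2 / mut
  mueff <- sqrt(3 * mu_a * mut)
  r1 <- sqrt(rho_mm^2 + z0^2)
  r2 <- sqrt(rho_mm^2 + z2^2)

  f <- function(r) (mueff + 1 / r) * exp(-mueff * r) / r^2
  # partials of f(r; mueff)
  df_dmueff <- function(r) -mueff * exp(-mueff * r) / r
  df_dr <- function(r) {
    exp(-mueff * r) * (-1 / r^4 - (mueff + 1 / r) * (mueff / r^2 + 2 / r^3))
  }
  dz0 <- -1 / mut^2
  dz2 <- -k2 / mut^2
  dmueff <- 3 * (2 * mu_a + mu_s_prime) / (2 * mueff)
  dr1 <- z0 * dz0 / r1
  dr2 <- z2 * dz2 / r2

  R <- z0 * f(r1) + z2 * f(r2)
  dR <- dz0 * f(r1) + z0 * (df_dmueff(r1) * dmueff + df_dr(r1) * dr1) +
    dz2 * f(r2) + z2 * (df_dmueff(r2) * dmueff + df_dr(r2) * dr2)
  -(dR / R) / rho_mm
}

#' Hemoglobin extinction spectra
#'
#' Molar extinction coefficients (decadic, 1/(cm M)) of oxyhemoglobin and
#' deoxyhemoglobin at the patch wavelengths, transcribed from the standard
#' compiled literature values. Below the ~800 nm isosbestic point Hb absorbs
#' more strongly than HbO2; above it the order reverses.
#'
#' @return Tibble with columns `wavelength_nm`, `chromophore`,
#'   `epsilon_per_cm_per_M`.
#' @export
hb_extinction <- function() {
  if (is.null(.optics_cache$extinction)) {
    path <- system.file("extdata", "hb_extinction_molar.csv", package = "carotidnirs")
    .optics_cache$extinction <- readr::read_csv(path, show_col_types = FALSE)
  }
  .optics_cache$extinction
}

.optics_cache <- new.env(parent = emptyenv())

#' Chromophore spectra bundle
#'
#' Packages the extinction table together with a per-wavelength background
#' absorption (water + other chromophores) for use by the forward model and
#' the spectral unmixing.
#'
#' @param extinction Extinction tibble as returned by [hb_extinction()].
#' @param background_mu_a Named numeric vector of baseline absorption (1/mm),
#'   names = wavelengths in nm.
#' @return An object of class `chromophore_spectra`.
#' @export
chromophore_spectra <- function(extinction = hb_extinction(),
                                background_mu_a = c(
                                  "670" = 0.0035, "780" = 0.0040,
                                  "808" = 0.0045, "850" = 0.0055
                                )) {
  stopifnot(all(c("wavelength_nm", "chromophore", "epsilon_per_cm_per_M") %in%
                  names(extinction)))
  if (any(extinction$epsilon_per_cm_per_M <= 0)) {
    stop("all extinction coefficients must be positive", call. = FALSE)
  }
  eps <- function(chrom, wl) {
    v <- extinction$epsilon_per_cm_per_M[
      extinction$chromophore == chrom & extinction$wavelength_nm == wl
    ]
    if (length(v) != 1) NA_real_ else v
  }
  wls <- sort(unique(extinction$wavelength_nm))
  if (min(wls) < 800 &&
      eps("Hb", min(wls)) <= eps("HbO2", min(wls))) {
    stop("expected Hb to dominate below the isosbestic point", call. = FALSE)
  }
  if (max(wls) > 800 &&
      eps("HbO2", max(wls)) <= eps("Hb", max(wls))) {
    stop("expected HbO2 to dominate above the isosbestic point", call. = FALSE)
  }
  if (any(background_mu_a < 0)) stop("background_mu_a must be >= 0", call. = FALSE)
  structure(list(extinction = extinction, background_mu_a = background_mu_a),
            class = "chromophore_spectra")
}

#' Extinction matrix in working units
#'
#' Rows = wavelengths, columns = c(HbO2, Hb); units 1/(mm mM), i.e. the CSV's
#' decadic 1/(cm M) values scaled by 1e-4. The natural-log factor ln(10) is
#' applied by the callers, not here.
#'
#' @param spectra A [chromophore_spectra()] object.
#' @param wavelengths_nm Wavelengths to extract, nm.
#' @return Numeric matrix `length(wavelengths_nm)` x 2.
#' @export
extinction_matrix <- function(spectra, wavelengths_nm) {
  ext <- spectra$extinction
  out <- vapply(wavelengths_nm, function(wl) {
    row <- c(
      ext$epsilon_per_cm_per_M[ext$chromophore == "HbO2" & ext$wavelength_nm == wl],
      ext$epsilon_per_cm_per_M[ext$chromophore == "Hb" & ext$wavelength_nm == wl]
    )
    if (length(row) != 2) {
      stop("extinction spectra undefined at ", wl, " nm", call. = FALSE)
    }
    row
  }, numeric(2))
  m <- t(out) * 1e-4
  dimnames(m) <- list(as.character(wavelengths_nm), c("HbO2", "Hb"))
  m
}

#' Absorption coefficient from chromophore concentrations
#'
#' `mu_a(lambda) = ln(10) * (eps_HbO2 * C_HbO2 + eps_Hb * C_Hb) + mu_a,bg(lambda)`
#' with concentrations in mM and extinction in decadic 1/(mm mM).
#'
#' @param c_hbo2_mM,c_hb_mM Chromophore concentrations, mM (vectorised).
#' @param wavelength_nm Single wavelength present in `spectra`.
#' @param spectra A [chromophore_spectra()] object.
#' @return Absorption coefficient, 1/mm.
#' @export
mua_from_chromophores <- function(c_hbo2_mM, c_hb_mM, wavelength_nm, spectra) {
  if (any(c_hbo2_mM < 0) || any(c_hb_mM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  E <- extinction_matrix(spectra, wavelength_nm)
  bg <- background_mua(spectra, wavelength_nm)
  log(10) * (E[1, "HbO2"] * c_hbo2_mM + E[1, "Hb"] * c_hb_mM) + bg
}

background_mua <- function(spectra, wavelength_nm) {
  key <- as.character(wavelength_nm)
  bg <- spectra$background_mu_a[key]
  if (any(is.na(bg))) {
    stop("background absorption undefined at ", wavelength_nm, " nm", call. = FALSE)
  }
  unname(bg)
}

#' Reduced scattering prior
#'
#' Power-law Mie-type spectrum `mu_s'(lambda) = a * (lambda/800)^(-b)`, the
#' usual soft-tissue prior needed to turn a two-distance attenuation slope
#' into an absolute absorption estimate.
#'
#' @param wavelengths_nm Wavelengths, nm.
#' @param a Reduced scattering at 800 nm, 1/mm.
#' @param b Scatter power.
#' @return Named numeric vector of `mu_s'` values, 1/mm.
#' @export
scattering_prior <- function(wavelengths_nm, a = 0.9, b = 1.2) {
  if (a <= 0 || b < 0) stop("invalid scattering prior parameters", call. = FALSE)
  out <- a * (wavelengths_nm / 800)^(-b)
  names(out) <- as.character(wavelengths_nm)
  out
}
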
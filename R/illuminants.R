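#' Construct an illuminant
#'
#' An illuminant is a relative spectral irradiance, interpreted throughout as
#' photon flux (quantal units). Quantum catches are invariant to its overall
#' scale because of von Kries normalization, so only the spectral shape
#' matters.
#'
#' @param wl wavelengths, nm.
#' @param irradiance relative photon flux, positive.
#' @param name label.
#' @export
illuminant <- function(wl, irradiance, name = "custom") {
  wl <- as.numeric(wl); irradiance <- as.numeric(irradiance)
  if (length(wl) != length(irradiance)) stop("length mismatch in illuminant")
  if (any(diff(wl) <= 0)) stop("non-monotone wavelengths in illuminant")
  if (any(irradiance <= 0)) stop("illuminant must be positive everywhere")
  structure(list(wl = wl, irradiance = irradiance, name = name),
            class = "illuminant")
}

#' Load a bundled or user illuminant
#'
#' `"D65"` is a nominal CIE daylight D65 table bundled at 10-nm resolution
#' over 300-700 nm. `"sunset"` is a synthetic low-colour-temperature stand-in
#' (2500 K blackbody photon flux) for the reddish ambient light at dusk, when
#' nocturnal hawkmoths begin foraging; measured twilight spectra can be
#' supplied instead via a file path. Tables are linearly interpolated to the
#' requested grid.
#'
#' @param name "D65", "sunset", or a path to a CSV with columns
#'   `wl,irradiance`.
#' @param grid wavelength grid (nm) to resample onto.
#' @export
load_illuminant <- function(name = "D65", grid = 300:700) {
  path <- switch(name,
                 D65 = system.file("extdata", "illum_d65.csv",
                                   package = "pollicolor"),
                 sunset = system.file("extdata", "illum_sunset_synthetic.csv",
                                      package = "pollicolor"),
                 name)
  if (!nzchar(path) || !file.exists(path))
    stop("illuminant not found: ", name)
  df <- utils::read.csv(path)
  if (min(df$wl) > min(grid) || max(df$wl) < max(grid))
    stop("illuminant table does not cover requested grid")
  illuminant(grid, stats::approx(df$wl, df$irradiance, xout = grid)$y,
             name = if (name %in% c("D65", "sunset")) name else "custom")
}

#' Convert an energy-unit irradiance to photon flux
#'
#' Photoreceptors count photons; an irradiance measured in energy units
#' (W m^-2 nm^-1) is converted to relative photon flux by multiplying by
#' wavelength (E = hc/lambda). Off by default in the pipeline: bundled tables
#' are already treated as quantal.
#'
#' @param illum an [illuminant()] in energy units.
#' @export
energy_to_photon_flux <- function(illum) {
  stopifnot(inherits(illum, "illuminant"))
  illuminant(illum$wl, illum$irradiance * illum$wl,
             name = paste0(illum$name, "_quantal"))
}
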
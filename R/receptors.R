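#' Visual-pigment absorbance template
#'
#' Alpha-band absorbance of an A1 visual pigment from the Govardovskii et al.
#' (2000) nomogram, parameterized only by the wavelength of peak sensitivity.
#' The curve is evaluated on the supplied grid and peak-normalized to 1.
#' Published sensitivity curves can be substituted wherever a `receptor_set`
#' accepts explicit `sensitivities`.
#'
#' @param lambda_max wavelength of peak sensitivity, nm (300-700).
#' @param grid wavelength grid, nm.
#' @return numeric sensitivity curve on `grid`, peak 1.
#' @export
receptor_template <- function(lambda_max, grid = 300:700) {
  if (lambda_max < 300 || lambda_max > 700)
    stop("lambda_max outside 300-700 nm")
  if (lambda_max < min(grid) || lambda_max > max(grid))
    stop("lambda_max outside grid coverage")
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  x <- lambda_max / grid
  s <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  s / max(s)
}

#' Construct a receptor set
#'
#' Named photoreceptor spectral sensitivities for one viewer, with relative
#' receptor densities (used only by the noise model). Sensitivities default to
#' nomogram curves generated from `lambda_max`.
#'
#' @param viewer viewer label ("hawkmoth", "blowfly", "hoverfly", ...).
#' @param names receptor names, ordered by increasing lambda_max by
#'   convention.
#' @param lambda_max peak wavelengths, nm, one per receptor.
#' @param densities relative receptor abundances (positive), one per receptor.
#' @param grid wavelength grid.
#' @param sensitivities optional matrix (length(grid) x n receptors) of
#'   measured sensitivity curves, overriding the nomogram; each column is
#'   peak-normalized.
#' @export
receptor_set <- function(viewer, names, lambda_max, densities,
                         grid = 300:700, sensitivities = NULL) {
  k <- length(names)
  stopifnot(length(lambda_max) == k, length(densities) == k)
  if (any(densities <= 0)) stop("receptor densities must be positive")
  if (is.null(sensitivities)) {
    sensitivities <- vapply(lambda_max, receptor_template, numeric(length(grid)),
                            grid = grid)
  } else {
    sensitivities <- as.matrix(sensitivities)
    stopifnot(nrow(sensitivities) == length(grid), ncol(sensitivities) == k)
    if (any(sensitivities < 0)) stop("sensitivities must be non-negative")
    sensitivities <- sweep(sensitivities, 2, apply(sensitivities, 2, max), "/")
  }
  colnames(sensitivities) <- names
  structure(list(viewer = viewer, names = names,
                 lambda_max = stats::setNames(lambda_max, names),
                 densities = stats::setNames(densities, names),
                 grid = grid, sensitivities = sensitivities),
            class = "receptor_set")
}

#' Bundled default receptor sets
#'
#' The hawkmoth set is the Manduca sexta trichromat: UV (357 nm), blue
#' (450 nm) and green (520 nm) receptors with relative densities
#' 0.1 / 0.23 / 0.67 from the ventral compound eye. Fly sets carry the two
#' pale (R7p/R8p) and two yellow (R7y/R8y) ommatidial receptors used by the
#' categorical colour model; their peak wavelengths are nomogram stand-ins for
#' the published (but not tabulated) blowfly and hoverfly curves and can be
#' overridden by supplying measured curves to [receptor_set()]. Definitions
#' are read from the bundled `receptors.csv`.
#'
#' @param viewer "hawkmoth", "blowfly" or "hoverfly".
#' @param grid wavelength grid.
#' @export
default_receptor_set <- function(viewer = c("hawkmoth", "blowfly", "hoverfly"),
                                 grid = 300:700) {
  viewer <- match.arg(viewer)
  path <- system.file("extdata", "receptors.csv", package = "pollicolor")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$viewer == viewer, , drop = FALSE]
  if (!nrow(df)) stop("no bundled receptor set for viewer ", viewer)
  receptor_set(viewer, df$receptor, df$lambda_max, df$density, grid = grid)
}
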
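# trapezoidal quadrature on an arbitrary grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Receptor-noise model
#'
#' Per-receptor noise for the receptor-noise-limited (RNL) discrimination
#' model, derived from relative receptor densities ("neural" noise):
#' `e_i = weber * sqrt(max(density) / density_i)`, so the most abundant
#' receptor class has noise equal to the Weber fraction.
#'
#' @param recs a [receptor_set()], or a named numeric vector of densities.
#' @param weber Weber fraction of the most abundant receptor class
#'   (default 0.1).
#' @return object of class `noise_model` with per-receptor noise `e`.
#' @export
noise_model <- function(recs, weber = 0.1) {
  d <- if (inherits(recs, "receptor_set")) recs$densities else recs
  if (any(d <= 0)) stop("densities must be positive")
  structure(list(weber = weber, mode = "neural",
                 e = weber * sqrt(max(d) / d)),
            class = "noise_model")
}

#' Quantum catches and colour locus of a spectrum
#'
#' The raw catch of receptor i is the trapezoid-rule integral of reflectance
#' (as a proportion) times receptor sensitivity times illuminant photon flux.
#' Catches are then von Kries adapted: divided by the catch of the background
#' (e.g. the mean leaf spectrum), so the background itself maps to q = 1 in
#' every receptor. Relative catches r normalize q to sum 1.
#'
#' @param spec stimulus `refl_spectrum` (percent reflectance).
#' @param recs a [receptor_set()].
#' @param illum an [illuminant()].
#' @param background background `refl_spectrum` (percent reflectance).
#' @return object of class `color_locus` with fields `Q`, `q`, `r`, receptor
#'   names and metadata.
#' @export
quantum_catch <- function(spec, recs, illum, background) {
  stopifnot(inherits(spec, "refl_spectrum"), inherits(recs, "receptor_set"),
            inherits(illum, "illuminant"),
            inherits(background, "refl_spectrum"))
  grid <- recs$grid
  refl <- stats::approx(spec$wl, spec$reflectance, xout = grid)$y / 100
  bkg <- stats::approx(background$wl, background$reflectance,
                       xout = grid)$y / 100
  irr <- stats::approx(illum$wl, illum$irradiance, xout = grid)$y
  if (anyNA(refl) || anyNA(bkg) || anyNA(irr))
    stop("stimulus, background and illuminant must cover the receptor grid")
  Q <- vapply(seq_along(recs$names), function(i)
    trapz(grid, refl * recs$sensitivities[, i] * irr), numeric(1))
  Qb <- vapply(seq_along(recs$names), function(i)
    trapz(grid, bkg * recs$sensitivities[, i] * irr), numeric(1))
  if (any(Qb <= 0))
    stop("background quantum catch is zero in at least one receptor")
  q <- Q / Qb
  names(Q) <- names(q) <- recs$names
  structure(list(viewer = recs$viewer, receptors = recs$names,
                 lambda_max = recs$lambda_max, Q = Q, q = q, r = q / sum(q),
                 species = spec$species, individual = spec$individual,
                 morph = spec$morph, illuminant = illum$name),
            class = "color_locus")
}

#' Construct a colour locus from adapted catches
#'
#' Low-level constructor for workflows where von Kries adapted catches are
#' already available (e.g. from another visual-modeling tool). [quantum_catch()]
#' is the usual entry point.
#'
#' @param q named vector of von Kries adapted catches (names = receptors,
#'   ordered by increasing peak wavelength).
#' @param viewer viewer label.
#' @param lambda_max optional peak wavelengths (defaults to the rank order of
#'   `q`).
#' @param species,individual,morph sample metadata.
#' @export
color_locus <- function(q, viewer = "hawkmoth", lambda_max = NULL,
                        species = "unknown", individual = "unknown",
                        morph = NA_character_) {
  if (is.null(names(q))) stop("catches must be named by receptor")
  if (is.null(lambda_max))
    lambda_max <- stats::setNames(seq_along(q), names(q))
  structure(list(viewer = viewer, receptors = names(q),
                 lambda_max = lambda_max, Q = q, q = q, r = q / sum(q),
                 species = species, individual = individual, morph = morph,
                 illuminant = "none"),
            class = "color_locus")
}

#' @export
print.color_locus <- function(x, ...) {
  cat(sprintf("<color_locus> %s | %s/%s | q = %s\n", x$viewer, x$species,
              x$individual, paste(sprintf("%.3f", x$q), collapse = ", ")))
  invisible(x)
}

#' Maxwell-triangle coordinates of a trichromat locus
#'
#' Projects relative catches r = (r1, r2, r3), ordered by increasing receptor
#' peak wavelength (UV, B, G for the hawkmoth), into the Maxwell triangle:
#' `x = (r3 - r1)/sqrt(2)`, `y = sqrt(2/3) * (r2 - (r1 + r3)/2)`. The centre
#' (0,0) is equal excitation of the three receptors (the adaptation
#' background); vertices are pure single-receptor colours at distance
#' sqrt(2/3) from the centre.
#'
#' @param locus a trichromat `color_locus`.
#' @return numeric `c(x, y)`.
#' @export
maxwell_locus <- function(locus) {
  stopifnot(inherits(locus, "color_locus"))
  if (length(locus$r) != 3)
    stop("maxwell_locus requires a trichromat locus (3 receptors)")
  r <- locus$r
  c(x = (r[[3]] - r[[1]]) / sqrt(2),
    y = sqrt(2 / 3) * (r[[2]] - (r[[1]] + r[[3]]) / 2))
}

fly_uv <- function(locus) {
  need <- c("R7p", "R8p", "R7y", "R8y")
  if (length(locus$q) != 4 || !all(need %in% names(locus$q)))
    stop("fly locus requires receptors R7p, R8p, R7y, R8y")
  q <- locus$q[need]
  if (q[["R7p"]] + q[["R8p"]] <= 0 || q[["R7y"]] + q[["R8y"]] <= 0)
    stop("non-positive opponency denominator")
  c(u = (q[["R7p"]] - q[["R8p"]]) / (q[["R7p"]] + q[["R8p"]]),
    v = (q[["R7y"]] - q[["R8y"]]) / (q[["R7y"]] + q[["R8y"]]))
}

#' Categorical fly colour locus
#'
#' Flies are modeled as categorical colour discriminators: two opponent
#' signals are computed from the pale (R7p vs R8p) and yellow (R7y vs R8y)
#' ommatidial pairs, `u = (q_R7p - q_R8p)/(q_R7p + q_R8p)` and
#' `v = (q_R7y - q_R8y)/(q_R7y + q_R8y)`, and the sign pair assigns one of
#' four categories: fly-UV (p+, y+), fly-blue (p-, y+), fly-yellow (p-, y-),
#' fly-purple (p+, y-). Loci within `tie_tol` of an axis are labelled
#' "boundary" (the model is undefined at the adaptation point).
#'
#' @param locus a fly `color_locus` (receptors R7p, R8p, R7y, R8y).
#' @param tie_tol tolerance below which |u| or |v| counts as a tie.
#' @return list with `category` and opponency `coord = c(u, v)`.
#' @export
fly_locus <- function(locus, tie_tol = 1e-9) {
  stopifnot(inherits(locus, "color_locus"))
  uv <- fly_uv(locus)
  category <- if (abs(uv[["u"]]) < tie_tol || abs(uv[["v"]]) < tie_tol) {
    "boundary"
  } else if (uv[["u"]] > 0) {
    if (uv[["v"]] > 0) "fly-UV" else "fly-purple"
  } else {
    if (uv[["v"]] > 0) "fly-blue" else "fly-yellow"
  }
  structure(list(category = category, coord = uv, species = locus$species,
                 individual = locus$individual, morph = locus$morph,
                 viewer = locus$viewer),
            class = "fly_locus")
}

#' Euclidean conspicuousness distance between fly loci
#'
#' Distance between two loci in the fly opponency plane (u, v); used as a
#' graded conspicuousness measure within the categorical model.
#'
#' @param a,b fly `color_locus` objects from the same viewer.
#' @export
fly_distance <- function(a, b) {
  stopifnot(inherits(a, "color_locus"), inherits(b, "color_locus"))
  if (!identical(a$viewer, b$viewer))
    stop("mixed viewers in fly_distance")
  sqrt(sum((fly_uv(a) - fly_uv(b))^2))
}

#' Receptor-noise-limited chromatic distance
#'
#' Chromatic distance between two trichromat loci under the receptor-noise-
#' limited model, in just-noticeable-difference (JND) units; 1 JND is the
#' theoretical discrimination threshold. Contrasts are log catch ratios
#' `df_i = ln(q_i^a / q_i^b)` and
#' `dS = sqrt((e1^2 (df3-df2)^2 + e2^2 (df3-df1)^2 + e3^2 (df2-df1)^2) /
#' ((e1 e2)^2 + (e1 e3)^2 + (e2 e3)^2))`. Any uniform (achromatic) scaling of
#' the catches cancels.
#'
#' @param a,b trichromat `color_locus` objects sharing background and
#'   illuminant.
#' @param noise a [noise_model()] with three receptor noises.
#' @export
rnl_distance <- function(a, b, noise) {
  stopifnot(inherits(a, "color_locus"), inherits(b, "color_locus"),
            inherits(noise, "noise_model"))
  if (length(a$q) != 3 || length(b$q) != 3)
    stop("rnl_distance requires trichromat loci")
  if (any(a$q <= 0) || any(b$q <= 0))
    stop("non-positive quantum catch")
  rnl_from_df(log(a$q) - log(b$q), noise$e)
}

# dS from a vector of 3 receptor log-contrasts
rnl_from_df <- function(df, e) {
  num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
    e[3]^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  unname(sqrt(num / den))
}

#' Achromatic contrast in the long-wavelength receptor
#'
#' Luminance contrast between a stimulus and the background, carried by the
#' receptor with the longest peak wavelength (the hawkmoth green receptor).
#' Two forms: `"michelson"` (default), `|q_a - q_b| / (q_a + q_b)`, and
#' `"log_jnd"`, `|ln(q_a / q_b)| / e_L` in JND units.
#'
#' @param a stimulus `color_locus`.
#' @param background background `color_locus` (q = 1 everywhere if the locus
#'   was adapted to itself).
#' @param noise a [noise_model()]; needed for the log_jnd form.
#' @param form "michelson" or "log_jnd".
#' @export
achromatic_contrast <- function(a, background, noise = NULL,
                                form = c("michelson", "log_jnd")) {
  form <- match.arg(form)
  stopifnot(inherits(a, "color_locus"), inherits(background, "color_locus"))
  iL <- which.max(a$lambda_max)
  qa <- a$q[[iL]]; qb <- background$q[[iL]]
  if (qa <= 0 || qb <= 0) stop("non-positive quantum catch")
  val <- if (form == "michelson") {
    abs(qa - qb) / (qa + qb)
  } else {
    if (is.null(noise)) stop("log_jnd form requires a noise model")
    abs(log(qa / qb)) / noise$e[[iL]]
  }
  structure(val, form = form)
}

#' Per-sample locus table
#'
#' Convenience wrapper: computes the colour locus of every spectrum in a
#' collection against one background and illuminant and returns a tidy data
#' frame (plus the locus list in attribute `loci`).
#'
#' @param coll a `spectrum_collection`.
#' @param recs a [receptor_set()].
#' @param illum an [illuminant()].
#' @param background background `refl_spectrum`.
#' @export
locus_table <- function(coll, recs, illum, background) {
  stopifnot(inherits(coll, "spectrum_collection"))
  loci <- lapply(coll$spectra, quantum_catch, recs = recs, illum = illum,
                 background = background)
  base <- data.frame(
    species = vapply(loci, function(l) l$species, character(1)),
    morph = vapply(loci, function(l) l$morph, character(1)),
    individual = vapply(loci, function(l) l$individual, character(1)),
    viewer = recs$viewer, row.names = NULL)
  qm <- t(vapply(loci, function(l) l$q, numeric(length(recs$names))))
  colnames(qm) <- paste0("q_", recs$names)
  out <- cbind(base, qm)
  if (length(recs$names) == 3) {
    xy <- t(vapply(loci, maxwell_locus, numeric(2)))
    out$x <- xy[, 1]; out$y <- xy[, 2]
  } else if (all(c("R7p", "R8p", "R7y", "R8y") %in% recs$names)) {
    fl <- lapply(loci, fly_locus)
    out$u <- vapply(fl, function(f) f$coord[["u"]], numeric(1))
    out$v <- vapply(fl, function(f) f$coord[["v"]], numeric(1))
    out$category <- vapply(fl, function(f) f$category, character(1))
  }
  attr(out, "loci") <- loci
  out
}
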
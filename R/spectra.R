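#' Construct a reflectance spectrum
#'
#' A reflectance spectrum is a wavelength grid (nm, strictly increasing) with
#' percent reflectance relative to a white standard (0-100; small negative
#' measurement noise is tolerated on input and clipped during processing),
#' plus the sample metadata needed downstream: species, individual, optional
#' colour morph, and tissue (corolla or leaf).
#'
#' @param wl numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance numeric vector, percent of white standard.
#' @param species species label.
#' @param individual individual label.
#' @param morph optional colour-morph label (e.g. "green" vs "maroon").
#' @param tissue one of "corolla" or "leaf".
#' @param replicate optional replicate label.
#' @return an object of class `refl_spectrum`.
#' @export
reflectance_spectrum <- function(wl, reflectance, species = "unknown",
                                 individual = "unknown", morph = NA_character_,
                                 tissue = c("corolla", "leaf"),
                                 replicate = NA_character_) {
  tissue <- match.arg(tissue)
  wl <- as.numeric(wl)
  reflectance <- as.numeric(reflectance)
  if (length(wl) != length(reflectance))
    stop("wavelength and reflectance vectors differ in length")
  if (any(!is.finite(wl)) || any(!is.finite(reflectance)))
    stop("non-finite values in spectrum")
  if (any(diff(wl) <= 0))
    stop("non-monotone wavelengths: grid must be strictly increasing")
  structure(
    list(wl = wl, reflectance = reflectance, species = as.character(species),
         individual = as.character(individual), morph = as.character(morph),
         tissue = tissue, replicate = as.character(replicate)),
    class = "refl_spectrum")
}

#' @export
print.refl_spectrum <- function(x, ...) {
  cat(sprintf("<refl_spectrum> %s / %s%s [%s] %g-%g nm (%d pts), R in [%.1f, %.1f]%%\n",
              x$species, x$individual,
              if (!is.na(x$morph)) paste0(" (", x$morph, ")") else "",
              x$tissue, min(x$wl), max(x$wl), length(x$wl),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

sample_id <- function(s) {
  paste(na.omit(c(s$species, s$morph, s$individual, s$replicate)),
        collapse = ":")
}

#' Bundle spectra into a collection on a common grid
#'
#' All member spectra are linearly resampled onto a shared 1-nm grid spanning
#' the intersection of their wavelength ranges. The grouping hierarchy is
#' species -> morph -> individual -> replicate.
#'
#' @param spectra list of [reflectance_spectrum()] objects.
#' @param step grid step in nm for the common grid (default 1).
#' @return an object of class `spectrum_collection`.
#' @export
spectrum_collection <- function(spectra, step = 1) {
  if (!length(spectra)) stop("empty spectrum collection")
  stopifnot(all(vapply(spectra, inherits, logical(1), "refl_spectrum")))
  lo <- max(vapply(spectra, function(s) min(s$wl), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wl), numeric(1)))
  if (lo >= hi) stop("spectra share no common wavelength range")
  grid <- seq(ceiling(lo), floor(hi), by = step)
  spectra <- lapply(spectra, function(s) {
    s$reflectance <- stats::approx(s$wl, s$reflectance, xout = grid)$y
    s$wl <- grid
    s
  })
  names(spectra) <- vapply(spectra, sample_id, character(1))
  structure(list(spectra = spectra, grid = grid),
            class = "spectrum_collection")
}

#' @export
print.spectrum_collection <- function(x, ...) {
  cat(sprintf("<spectrum_collection> %d spectra, grid %g-%g nm (step %g)\n",
              length(x$spectra), min(x$grid), max(x$grid),
              x$grid[2] - x$grid[1]))
  invisible(x)
}

#' @export
length.spectrum_collection <- function(x) length(x$spectra)

#' Turn a collection into a long data frame
#' @param x a `spectrum_collection`.
#' @param row.names,optional,... unused, for generic consistency.
#' @export
as.data.frame.spectrum_collection <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  do.call(rbind, lapply(x$spectra, function(s) {
    data.frame(wl = s$wl, reflectance = s$reflectance, species = s$species,
               individual = s$individual, morph = s$morph, tissue = s$tissue,
               replicate = s$replicate, row.names = NULL)
  }))
}

#' Read reflectance spectra from tabular text
#'
#' Two layouts are supported. `"long"` expects columns
#' `wl, reflectance, species, individual, tissue` and optionally `morph` and
#' `replicate`. `"wide"` expects a first column `wl` and one column per
#' sample; sample metadata is then taken from `metadata` (a data frame with a
#' `sample` column matching the spectrum column names plus `species`,
#' `individual`, and optionally `tissue`, `morph`); without `metadata` the
#' column name is used as both species and individual label and tissue
#' defaults to corolla.
#'
#' All spectra are resampled to a common 1-nm grid covering the intersection
#' of the input ranges.
#'
#' @param path CSV/TSV file (delimiter sniffed from the header line).
#' @param layout "wide" or "long".
#' @param metadata optional sidecar metadata data frame for wide files.
#' @return a [spectrum_collection()].
#' @export
read_spectra <- function(path, layout = c("wide", "long"), metadata = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"wl" %in% names(df)) stop("missing metadata: no 'wl' column")
  if (layout == "long") {
    need <- c("reflectance", "species", "individual", "tissue")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing metadata: column(s) ", paste(miss, collapse = ", "))
    if (!"morph" %in% names(df)) df$morph <- NA_character_
    if (!"replicate" %in% names(df)) df$replicate <- NA_character_
    nz <- function(v) ifelse(is.na(v), "", as.character(v))
    key <- paste(nz(df$species), nz(df$morph), nz(df$individual),
                 nz(df$replicate), nz(df$tissue), sep = "\r")
    specs <- lapply(split(df, key), function(d) {
      d <- d[order(d$wl), , drop = FALSE]
      if (any(duplicated(d$wl)))
        stop("non-monotone wavelengths: duplicated wl within one sample")
      reflectance_spectrum(d$wl, d$reflectance, d$species[1], d$individual[1],
                           d$morph[1], d$tissue[1], d$replicate[1])
    })
  } else {
    if (any(diff(df$wl) <= 0)) stop("non-monotone wavelengths")
    cols <- setdiff(names(df), "wl")
    if (!length(cols)) stop("wide file has no sample columns")
    specs <- lapply(cols, function(cn) {
      sp <- cn; ind <- cn; tis <- "corolla"; mor <- NA_character_
      if (!is.null(metadata)) {
        row <- metadata[metadata$sample == cn, , drop = FALSE]
        if (nrow(row) != 1)
          stop("missing metadata: no metadata row for sample '", cn, "'")
        sp <- row$species[1]; ind <- row$individual[1]
        if ("tissue" %in% names(row)) tis <- row$tissue[1]
        if ("morph" %in% names(row)) mor <- row$morph[1]
      }
      reflectance_spectrum(df$wl, df[[cn]], sp, ind, mor, tis)
    })
  }
  spectrum_collection(unname(specs))
}

#' Write a collection as long-format CSV
#' @param coll a `spectrum_collection`.
#' @param path output file.
#' @export
write_spectra <- function(coll, path) {
  utils::write.csv(as.data.frame(coll), path, row.names = FALSE)
  invisible(path)
}

#' Trim a spectrum to a wavelength window
#'
#' Insect colour vision spans roughly 300-700 nm; spectra are trimmed to that
#' window (or any requested sub-window of the measured range) before visual
#' modeling. If the window edges fall between grid points the edge values are
#' obtained by linear interpolation so the returned grid spans exactly
#' `[lo, hi]`.
#'
#' @param spec a `refl_spectrum` or `spectrum_collection`.
#' @param lo,hi window bounds in nm (default 300-700).
#' @export
trim_spectrum <- function(spec, lo = 300, hi = 700) {
  if (inherits(spec, "spectrum_collection")) {
    return(spectrum_collection(lapply(spec$spectra, trim_spectrum, lo, hi)))
  }
  if (lo >= hi) stop("invalid trim window: lo must be < hi")
  if (lo < min(spec$wl) || hi > max(spec$wl))
    stop(sprintf("trim window [%g, %g] outside measured range [%g, %g]",
                 lo, hi, min(spec$wl), max(spec$wl)))
  keep <- spec$wl >= lo & spec$wl <= hi
  wl <- spec$wl[keep]
  r <- spec$reflectance[keep]
  if (length(wl) == 0 || wl[1] > lo) {
    wl <- c(lo, wl)
    r <- c(stats::approx(spec$wl, spec$reflectance, lo)$y, r)
  }
  if (wl[length(wl)] < hi) {
    wl <- c(wl, hi)
    r <- c(r, stats::approx(spec$wl, spec$reflectance, hi)$y)
  }
  out <- spec
  out$wl <- wl
  out$reflectance <- r
  out
}

#' Smooth a spectrum by local regression
#'
#' Local polynomial regression (degree-2, tricube weights; the default LOESS
#' family) evaluated back on the original grid. The span is the fraction of
#' points entering each local fit; 0.25 removes instrument noise while
#' preserving spectral shape. Negative fitted values are clipped to zero,
#' reflectance being physically non-negative.
#'
#' @param spec a `refl_spectrum` or `spectrum_collection`.
#' @param span local-regression span in (0, 1].
#' @param degree local polynomial degree (default 2).
#' @export
smooth_spectrum <- function(spec, span = 0.25, degree = 2) {
  if (inherits(spec, "spectrum_collection")) {
    return(spectrum_collection(
      lapply(spec$spectra, smooth_spectrum, span, degree)))
  }
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (length(spec$wl) < 10)
    stop("too few points to smooth (need >= 10)")
  fit <- stats::loess(r ~ w, data = data.frame(w = spec$wl,
                                               r = spec$reflectance),
                      span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  out <- spec
  out$reflectance <- unname(pmax(stats::predict(fit, newdata =
                                                  data.frame(w = spec$wl)),
                                 0))
  out
}

group_key <- function(s, level) {
  morph <- if (is.na(s$morph)) "" else s$morph
  switch(level,
         individual = paste(s$species, morph, s$individual, s$tissue,
                            sep = "\r"),
         species = paste(s$species, morph, s$tissue, sep = "\r"))
}

#' Average spectra within groups
#'
#' Pointwise arithmetic mean per group. `level = "individual"` averages
#' replicates within individuals; `level = "species"` averages individuals
#' within species. Colour morphs of polymorphic species are always kept
#' separate, so the species level is in effect species-by-morph. Group sizes
#' are recorded in the `n` attribute of the returned collection.
#'
#' @param coll a `spectrum_collection` on a common grid.
#' @param level "individual" or "species".
#' @export
aggregate_spectra <- function(coll, level = c("individual", "species")) {
  level <- match.arg(level)
  stopifnot(inherits(coll, "spectrum_collection"))
  keys <- vapply(coll$spectra, group_key, character(1), level = level)
  groups <- split(coll$spectra, keys)
  if (any(!lengths(groups))) stop("empty group in aggregation")
  out <- lapply(groups, function(g) {
    m <- rowMeans(vapply(g, function(s) s$reflectance,
                         numeric(length(coll$grid))))
    s <- g[[1]]
    s$reflectance <- m
    s$replicate <- NA_character_
    if (level == "species") s$individual <- "mean"
    s
  })
  res <- spectrum_collection(unname(out))
  attr(res, "n") <- lengths(groups)
  res
}

#' Center a spectrum and average into wavelength bins
#'
#' The spectrum's own mean reflectance is subtracted (removing total
#' reflectance as a variable, so only spectral shape remains) and the centered
#' values are averaged within `n_bins` contiguous, equal-width wavelength
#' intervals across 300-700 nm. The default 10 bins give 40-nm intervals.
#' Intervals are right-open except the last, which is closed.
#'
#' @param spec a `refl_spectrum` whose grid spans exactly 300-700 nm.
#' @param n_bins number of equal-width bins (default 10).
#' @return numeric vector of bin means with bin edges in attribute `edges`.
#' @export
center_and_bin <- function(spec, n_bins = 10) {
  stopifnot(inherits(spec, "refl_spectrum"))
  if (abs(min(spec$wl) - 300) > 1e-9 || abs(max(spec$wl) - 700) > 1e-9)
    stop("grid must span exactly 300-700 nm (trim first)")
  edges <- seq(300, 700, length.out = n_bins + 1)
  centered <- spec$reflectance - mean(spec$reflectance)
  idx <- findInterval(spec$wl, edges, rightmost.closed = TRUE)
  v <- vapply(seq_len(n_bins), function(b) mean(centered[idx == b]),
              numeric(1))
  names(v) <- sprintf("bin_%g_%g", edges[-length(edges)], edges[-1])
  attr(v, "edges") <- edges
  v
}

#' Binned-shape matrix for a collection
#'
#' Applies [center_and_bin()] to every spectrum and stacks the results into a
#' sample-by-bin matrix suitable for PCA.
#'
#' @param coll a `spectrum_collection` spanning 300-700 nm.
#' @param n_bins number of bins (default 10).
#' @export
binned_matrix <- function(coll, n_bins = 10) {
  stopifnot(inherits(coll, "spectrum_collection"))
  rows <- t(vapply(coll$spectra, center_and_bin, numeric(n_bins),
                   n_bins = n_bins))
  attr(rows, "edges") <- seq(300, 700, length.out = n_bins + 1)
  attr(rows, "species") <- vapply(coll$spectra, function(s) s$species,
                                  character(1))
  attr(rows, "morph") <- vapply(coll$spectra, function(s) s$morph,
                                character(1))
  rows
}
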
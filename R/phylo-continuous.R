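# Phylogenetic correlation structures. Ta is the matrix of shared root-to-MRCA
# path lengths (BM covariance under unit rate); D the patristic distance
# matrix. All return the covariance up to the sigma^2 factor, which is
# profiled out of the likelihood.
corr_bm <- function(Ta, D) Ta

corr_ou <- function(Ta, D, alpha) {
  # OU conditioned on the root state: sigma^2/(2a) e^(-a d_ij)(1 - e^(-2a t_a));
  # -expm1 keeps the alpha -> 0 limit (= Ta) numerically exact
  exp(-alpha * D) * (-expm1(-2 * alpha * Ta)) / (2 * alpha)
}

corr_eb <- function(Ta, D, r) {
  # early burst: rates decay as e^(rt), r < 0; integral over shared history
  if (abs(r) < 1e-12) return(Ta)
  expm1(r * Ta) / r
}

# profiled Gaussian log-likelihood: given unit-rate covariance Cstar, the GLS
# root and ML rate have closed forms. Returns loglik, z0, sigma2.
profile_bm_ll <- function(Cstar, x) {
  n <- length(x)
  L <- chol(Cstar)
  logdet <- 2 * sum(log(diag(L)))
  tx <- backsolve(L, x, transpose = TRUE)
  to <- backsolve(L, rep(1, n), transpose = TRUE)
  z0 <- sum(to * tx) / sum(to * to)
  s2 <- sum((tx - z0 * to)^2) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
  list(ll = ll, z0 = z0, sigma2 = s2)
}

#' Fit a continuous-trait evolutionary model by maximum likelihood
#'
#' Fits Brownian motion (BM), single-optimum Ornstein-Uhlenbeck (OU) or early
#' burst (EB) to a tip trait vector by maximizing the multivariate-normal
#' phylogenetic likelihood `N(x | z0 1, sigma^2 C_model)`. The root state and
#' rate are profiled analytically; the remaining parameter (OU pull `alpha` or
#' EB decay `r`) is optimized by bounded quasi-Newton on a log scale from five
#' starts. Models are compared by small-sample AICc.
#'
#' @param tree rooted `phylo` with branch lengths (ultrametric expected for
#'   OU).
#' @param x named tip trait vector.
#' @param model "BM", "OU" or "EB".
#' @return object of class `continuous_fit`: model, `sigma2`, `z0`, `alpha`
#'   (OU) or `r` (EB), `logLik`, `k`, `AICc`, `n`, `degenerate` flag.
#' @export
fit_continuous <- function(tree, x, model = c("BM", "OU", "EB")) {
  model <- match.arg(model)
  x <- align_trait(tree, x)
  n <- length(x)
  if (model == "OU" && !is_ultrametric(tree))
    warning("OU fit assumes an ultrametric tree")
  out <- list(model = model, n = n, tip_labels = tree$tip.label,
              alpha = NA_real_, r = NA_real_, degenerate = FALSE)
  if (stats::sd(x) < 1e-12) {
    # zero-variance trait: sigma^2 pinned at its lower bound, flagged
    out <- c(out[-match(c("degenerate"), names(out))],
             list(sigma2 = 1e-8, z0 = x[[1]], logLik = NA_real_,
                  k = if (model == "BM") 2L else 3L, AICc = NA_real_,
                  degenerate = TRUE))
    return(structure(out, class = "continuous_fit"))
  }
  Ta <- ape::vcv(tree)
  depth <- diag(Ta)
  D <- outer(depth, depth, "+") - 2 * Ta
  if (model == "BM") {
    p <- profile_bm_ll(corr_bm(Ta, D), x)
    k <- 2L
  } else if (model == "OU") {
    f <- function(la) -profile_bm_ll(corr_ou(Ta, D, exp(la)), x)$ll
    opt <- multistart_1d(f, log(c(1e-6, 1e-2, 0.1, 1, 10)),
                         lower = log(1e-8), upper = log(1e3))
    out$alpha <- exp(opt$par)
    p <- profile_bm_ll(corr_ou(Ta, D, out$alpha), x)
    k <- 3L
  } else {
    h <- tree_height(tree)
    f <- function(lr) -profile_bm_ll(corr_eb(Ta, D, -exp(lr)), x)$ll
    opt <- multistart_1d(f, log(c(1e-6, 1e-3, 0.1, 0.5, 2) / h),
                         lower = log(1e-9), upper = log(30 / h))
    out$r <- -exp(opt$par)
    p <- profile_bm_ll(corr_eb(Ta, D, out$r), x)
    k <- 3L
  }
  if (!is.finite(p$ll)) stop("non-finite optimum in continuous fit")
  out$sigma2 <- p$sigma2
  out$z0 <- p$z0
  out$logLik <- p$ll
  out$k <- k
  out$AICc <- -2 * p$ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(out, class = "continuous_fit")
}

multistart_1d <- function(f, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, f, method = "L-BFGS-B", lower = lower,
                               upper = upper),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimizer failed from all starts")
  best
}

#' @export
print.continuous_fit <- function(x, ...) {
  extra <- if (x$model == "OU") sprintf(", alpha = %.4g", x$alpha)
  else if (x$model == "EB") sprintf(", r = %.4g", x$r) else ""
  cat(sprintf("<continuous_fit> %s: sigma2 = %.4g, z0 = %.4g%s, logLik = %.3f, AICc = %.3f%s\n",
              x$model, x$sigma2, x$z0, extra,
              if (is.na(x$logLik)) NA else x$logLik,
              if (is.na(x$AICc)) NA else x$AICc,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Compare BM, OU and EB fits by AICc
#' @param tree rooted `phylo`.
#' @param x named tip trait vector.
#' @return data frame of fits sorted by AICc, with the fitted objects in
#'   attribute `fits`.
#' @export
compare_continuous <- function(tree, x) {
  fits <- lapply(c("BM", "OU", "EB"), function(m) fit_continuous(tree, x, m))
  df <- data.frame(model = vapply(fits, function(f) f$model, character(1)),
                   sigma2 = vapply(fits, function(f) f$sigma2, numeric(1)),
                   logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                   k = vapply(fits, function(f) f$k, integer(1)),
                   AICc = vapply(fits, function(f) f$AICc, numeric(1)))
  df <- df[order(df$AICc), ]
  attr(df, "fits") <- fits
  df
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML estimates of internal-node states: under BM these satisfy a
#' weighted-average condition at every internal node (weights are inverse
#' branch lengths), giving a sparse linear system that is solved exactly. The
#' root estimate coincides with the GLS root of the BM fit.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param x named tip trait vector.
#' @param fit optional `continuous_fit` (must be a BM fit on the same tips).
#' @return named numeric vector of internal-node states (`node_<id>`, ids as
#'   in `tree$edge`).
#' @export
anc_ml <- function(tree, x, fit = NULL) {
  x <- align_trait(tree, x)
  if (!is.null(fit)) {
    if (fit$model != "BM") stop("ancestral states require a BM fit")
    if (!identical(sort(fit$tip_labels), sort(tree$tip.label)))
      stop("fit and tree disagree in tip labels")
  }
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1] - ntip
    ch <- tree$edge[i, 2]
    w <- 1 / max(tree$edge.length[i], 1e-12)
    A[p, p] <- A[p, p] + w
    if (ch > ntip) {
      cc <- ch - ntip
      A[p, cc] <- A[p, cc] - w
      A[cc, cc] <- A[cc, cc] + w
      A[cc, p] <- A[cc, p] - w
    } else {
      b[p] <- b[p] + w * x[[ch]]
    }
  }
  est <- solve(A, b)
  names(est) <- paste0("node_", ntip + seq_len(m))
  est
}

#' Phylogenetic GLS correlation between two traits
#'
#' Joint maximum likelihood of a bivariate trait under BM or OU phylogenetic
#' covariance (`Sigma = R (x) C`): the 2x2 trait rate matrix R is estimated
#' from GLS residuals, the evolutionary correlation is
#' `r = R12 / sqrt(R11 R22)`, and `r = 0` is tested by a likelihood-ratio test
#' against the diagonal-R model (chi-squared, 1 df). For OU the pull alpha is
#' optimized separately under the full and null models.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param x,y named tip trait vectors (e.g. environmental liability and
#'   perceptual colour vector).
#' @param model "BM" or "OU".
#' @return object of class `pgls_fit`: `r`, `slope` (y on x), `R`, `logLik`,
#'   `AIC`, `p_value`, `alpha` (OU).
#' @export
pgls_corr <- function(tree, x, y, model = c("BM", "OU")) {
  model <- match.arg(model)
  x <- align_trait(tree, x, "x")
  y <- align_trait(tree, y, "y")
  n <- length(x)
  Ta <- ape::vcv(tree)
  depth <- diag(Ta)
  D <- outer(depth, depth, "+") - 2 * Ta
  biv_ll <- function(Cstar, diag_only = FALSE) {
    L <- chol(Cstar)
    logdet <- 2 * sum(log(diag(L)))
    tx <- backsolve(L, cbind(x, y), transpose = TRUE)
    to <- backsolve(L, rep(1, n), transpose = TRUE)
    z <- colSums(to * tx) / sum(to * to)
    E <- tx - outer(to, z)
    R <- crossprod(E) / n
    ldR <- if (diag_only) log(R[1, 1]) + log(R[2, 2])
    else determinant(R)$modulus[1]
    ll <- -0.5 * (2 * n * log(2 * pi) + n * ldR + 2 * logdet + 2 * n)
    list(ll = ll, R = R, z = z)
  }
  if (model == "BM") {
    full <- biv_ll(Ta)
    null <- biv_ll(Ta, diag_only = TRUE)
    alpha <- NA_real_
    k <- 5L
  } else {
    opt_f <- multistart_1d(function(la)
      -biv_ll(corr_ou(Ta, D, exp(la)))$ll,
      log(c(1e-6, 1e-2, 0.1, 1, 10)), log(1e-8), log(1e3))
    alpha <- exp(opt_f$par)
    full <- biv_ll(corr_ou(Ta, D, alpha))
    opt_0 <- multistart_1d(function(la)
      -biv_ll(corr_ou(Ta, D, exp(la)), diag_only = TRUE)$ll,
      log(c(1e-6, 1e-2, 0.1, 1, 10)), log(1e-8), log(1e3))
    null <- biv_ll(corr_ou(Ta, D, exp(opt_0$par)), diag_only = TRUE)
    k <- 6L
  }
  if (full$R[1, 1] <= 0 || full$R[2, 2] <= 0)
    stop("singular covariance in PGLS")
  r <- full$R[1, 2] / sqrt(full$R[1, 1] * full$R[2, 2])
  lrt <- max(0, 2 * (full$ll - null$ll))
  structure(list(model = model, r = r, slope = full$R[1, 2] / full$R[1, 1],
                 R = full$R, intercepts = full$z, alpha = alpha,
                 logLik = full$ll, logLik_null = null$ll, k = k,
                 AIC = -2 * full$ll + 2 * k, lrt = lrt,
                 p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> %s: r = %.3f, slope = %.3f, logLik = %.3f, AIC = %.2f, LRT p = %.4g%s\n",
              x$model, x$r, x$slope, x$logLik, x$AIC, x$p_value,
              if (!is.na(x$alpha)) sprintf(" (alpha = %.3g)", x$alpha) else ""))
  invisible(x)
}

#' Perceptual colour vector of species
#'
#' Collapses per-species colour loci to a single axis for comparative
#' analysis. For the hawkmoth, a PCA of the species-by-receptor matrix of von
#' Kries adapted catches q; for flies, a PCA of the species-by-species matrix
#' of pairwise opponency-plane Euclidean distances. PC1 scores are returned
#' with the deterministic sign convention of [standardized_pca()].
#'
#' @param loci named list (one aggregated `color_locus` per species/morph).
#' @param viewer "hawkmoth" or "fly".
#' @return named numeric vector of PC1 scores; attributes `var_explained` and
#'   `degenerate`.
#' @export
color_vector <- function(loci, viewer = c("hawkmoth", "fly")) {
  viewer <- match.arg(viewer)
  if (length(loci) < 3) stop("color_vector needs at least 3 species")
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, function(l)
      if (is.na(l$morph)) l$species else paste(l$species, l$morph, sep = ":"),
      character(1))
  M <- if (viewer == "hawkmoth") {
    t(vapply(loci, function(l) l$q, numeric(3)))
  } else {
    uv <- t(vapply(loci, fly_uv, numeric(2)))
    as.matrix(stats::dist(uv))
  }
  degenerate <- all(apply(M, 2, stats::sd) < 1e-12)
  if (degenerate) {
    warning("zero variance among species loci; colour vector is degenerate")
    out <- stats::setNames(rep(0, length(loci)), names(loci))
    attr(out, "var_explained") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  v <- p$rotation[, 1]
  if (v[which.max(abs(v))] < 0) p$x[, 1] <- -p$x[, 1]
  out <- stats::setNames(p$x[, 1], names(loci))
  attr(out, "var_explained") <- p$sdev[1]^2 / sum(p$sdev^2)
  attr(out, "degenerate") <- FALSE
  out
}
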
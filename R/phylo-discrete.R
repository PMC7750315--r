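# build an Mk rate matrix from a parameter vector under a model constraint
mk_index_matrix <- function(k, model) {
  M <- matrix(0L, k, k)
  if (model == "ER") {
    M[row(M) != col(M)] <- 1L
  } else if (model == "SYM") {
    idx <- 0L
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      idx <- idx + 1L
      M[i, j] <- M[j, i] <- idx
    }
  } else {
    idx <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) { idx <- idx + 1L; M[i, j] <- idx }
    }
  }
  M
}

mk_build_q <- function(rates, M) {
  Q <- matrix(0, nrow(M), ncol(M))
  Q[M > 0] <- rates[M[M > 0]]
  diag(Q) <- -rowSums(Q)
  Q
}

# tip state vector -> likelihood matrix rows; NA/"?" means unknown (all ones)
mk_tip_matrix <- function(states, levels) {
  L <- matrix(0, length(states), length(levels))
  for (i in seq_along(states)) {
    if (is.na(states[i]) || states[i] %in% c("?", "unknown")) {
      L[i, ] <- 1
    } else {
      j <- match(states[i], levels)
      if (is.na(j)) stop("state '", states[i], "' absent from alphabet")
      L[i, j] <- 1
    }
  }
  L
}

# Felsenstein pruning. Returns the log-likelihood and, if keep = TRUE, the
# per-node scaled partial likelihoods and per-edge transition matrices (used
# by stochastic mapping).
mk_prune <- function(tree, tipL, Q, root_prior = NULL, keep = FALSE) {
  k <- ncol(Q)
  ntip <- nrow(tipL)
  nn <- ntip + tree$Nnode
  L <- matrix(1, nn, k)
  L[seq_len(ntip), ] <- tipL
  po <- reorder(tree, "postorder")
  P <- vector("list", nrow(po$edge))
  logscale <- 0
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    Pt <- ape::matexpo(Q * po$edge.length[i])
    Pt[Pt < 0] <- 0
    P[[i]] <- Pt
    v <- Pt %*% L[ch, ]
    L[p, ] <- L[p, ] * v
    s <- max(L[p, ])
    if (s <= 0) return(list(loglik = -Inf))
    L[p, ] <- L[p, ] / s
    logscale <- logscale + log(s)
  }
  root <- ntip + 1L
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  loglik <- log(sum(root_prior * L[root, ])) + logscale
  if (!keep) return(list(loglik = loglik))
  list(loglik = loglik, L = L, P = P, edge = po$edge,
       edge.length = po$edge.length, root_prior = root_prior)
}

#' Mk model log-likelihood for a given rate matrix
#'
#' Felsenstein-pruning likelihood of tip states under a continuous-time Markov
#' model with rate matrix `Q`, with a uniform prior over root states. Exposed
#' so fitted models can be checked against independent computations.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states named character vector of tip states (NA = unknown).
#' @param Q rate matrix with dimnames giving the state alphabet (rows sum
#'   to 0).
#' @export
mk_loglik <- function(tree, states, Q) {
  states <- align_trait(tree, states, "states")
  levels <- colnames(Q)
  if (is.null(levels)) stop("Q must carry state names as dimnames")
  mk_prune(tree, mk_tip_matrix(states, levels), Q)$loglik
}

#' Fit an Mk discrete-trait model by maximum likelihood
#'
#' Continuous-time Markov model of a discrete character with equal (ER),
#' symmetric (SYM) or all-rates-different (ARD) rate constraints. The
#' likelihood is computed by Felsenstein pruning with a uniform root prior and
#' maximized by bounded quasi-Newton on log rates from several starts.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states named character vector of tip states; NA or "?" marks an
#'   unknown tip.
#' @param model "ER", "SYM" or "ARD".
#' @param levels optional state alphabet (default: sorted observed states).
#' @return object of class `mk_fit`: `Q`, `rates`, `logLik`, `k_params`,
#'   `AIC`, `levels`, `degenerate` flag (single observed state: rate pinned
#'   at 0).
#' @export
fit_mk <- function(tree, states, model = c("ER", "SYM", "ARD"),
                   levels = NULL) {
  model <- match.arg(model)
  states <- align_trait(tree, states, "states")
  obs <- states[!is.na(states) & !states %in% c("?", "unknown")]
  if (is.null(levels)) levels <- sort(unique(obs))
  if (length(levels) < 2) stop("need an alphabet of >= 2 states")
  bad <- setdiff(obs, levels)
  if (length(bad))
    stop("state '", bad[1], "' absent from alphabet")
  k <- length(levels)
  M <- mk_index_matrix(k, model)
  npar <- max(M)
  tipL <- mk_tip_matrix(states, levels)
  if (length(unique(obs)) < 2) {
    Q <- matrix(0, k, k, dimnames = list(levels, levels))
    return(structure(list(model = model, Q = Q, rates = rep(0, npar),
                          logLik = log(1 / k), k_params = npar,
                          AIC = NA_real_, levels = levels, states = states,
                          tip_labels = tree$tip.label, degenerate = TRUE),
                     class = "mk_fit"))
  }
  nll <- function(lr) {
    ll <- mk_prune(tree, tipL, mk_build_q(exp(lr), M))$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  r0 <- length(levels) / sum(tree$edge.length)
  best <- NULL
  for (s in log(r0 * c(0.1, 1, 10))) {
    o <- tryCatch(stats::optim(rep(s, npar), nll, method = "L-BFGS-B",
                               lower = log(1e-9), upper = log(1e3)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("Mk optimizer failed from all starts")
  rates <- exp(best$par)
  Q <- mk_build_q(rates, M)
  dimnames(Q) <- list(levels, levels)
  structure(list(model = model, Q = Q, rates = rates, logLik = -best$value,
                 k_params = npar, AIC = 2 * best$value + 2 * npar,
                 levels = levels, states = states,
                 tip_labels = tree$tip.label, degenerate = FALSE),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> %s over {%s}: logLik = %.3f, AIC = %s%s\n",
              x$model, paste(x$levels, collapse = ", "), x$logLik,
              if (is.na(x$AIC)) "NA" else sprintf("%.2f", x$AIC),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Compare ER, SYM and ARD Mk models
#'
#' Likelihood-ratio tests of the nested pairs and AIC for all three models.
#' The default selection rule prefers the model with fewest parameters that is
#' not significantly worse than ARD at the 5% level.
#'
#' @param tree rooted `phylo`.
#' @param states named tip state vector.
#' @return data frame (model, k, logLik, AIC, LRT p vs ARD) with the chosen
#'   model in attribute `chosen` and fits in attribute `fits`.
#' @export
compare_mk <- function(tree, states) {
  fits <- lapply(c("ER", "SYM", "ARD"), function(m) fit_mk(tree, states, m))
  names(fits) <- c("ER", "SYM", "ARD")
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  kp <- vapply(fits, function(f) f$k_params, numeric(1))
  p_ard <- vapply(seq_along(fits), function(i) {
    df <- kp["ARD"] - kp[i]
    if (df <= 0) return(NA_real_)
    stats::pchisq(max(0, 2 * (ll["ARD"] - ll[i])), df, lower.tail = FALSE)
  }, numeric(1))
  df <- data.frame(model = names(fits), k = kp, logLik = ll,
                   AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                   p_vs_ARD = p_ard, row.names = NULL)
  ok <- which(is.na(p_ard) | p_ard >= 0.05)
  chosen <- names(fits)[ok[which.min(kp[ok])]]
  attr(df, "chosen") <- chosen
  attr(df, "fits") <- fits
  df
}

# sample a CTMC path conditional on endpoints: rejection sampling with a retry
# cap, then exact uniformization as fallback. Returns a data.frame of events
# (time from the parent end, from, to), possibly empty.
sample_branch_history <- function(Q, a, b, t, levels, max_retry = 1000) {
  k <- nrow(Q)
  for (try in seq_len(max_retry)) {
    s <- a; tm <- 0; ev <- list()
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      tm <- tm + stats::rexp(1, rate)
      if (tm >= t) break
      nxt <- sample.int(k, 1, prob = pmax(Q[s, ], 0))
      ev[[length(ev) + 1]] <- c(tm, s, nxt)
      s <- nxt
    }
    if (s == b) {
      if (!length(ev)) return(NULL)
      m <- do.call(rbind, ev)
      return(data.frame(time = m[, 1], from = levels[m[, 2]],
                        to = levels[m[, 3]]))
    }
  }
  # uniformization: condition the number of Poisson jumps on the endpoints,
  # then bridge-sample the jump chain and drop virtual (self) jumps
  mu <- max(-diag(Q))
  R <- diag(k) + Q / mu
  Pt <- ape::matexpo(Q * t)
  Rpow <- list(diag(k))
  w <- numeric(0)
  nmax <- 0
  repeat {
    nmax <- nmax + 1
    Rpow[[nmax + 1]] <- Rpow[[nmax]] %*% R
    w[nmax] <- stats::dpois(nmax, mu * t) * Rpow[[nmax + 1]][a, b] / Pt[a, b]
    if (nmax >= 2 && sum(w) > 1 - 1e-10) break
    if (nmax > 500) break
  }
  w0 <- stats::dpois(0, mu * t) * (a == b) / Pt[a, b]
  probs <- c(w0, w)
  N <- sample.int(length(probs), 1, prob = pmax(probs, 0)) - 1L
  if (N == 0) return(NULL)
  s <- a
  path <- integer(N)
  for (i in seq_len(N)) {
    pr <- R[s, ] * Rpow[[N - i + 1]][, b]
    path[i] <- sample.int(k, 1, prob = pmax(pr, 0))
    s <- path[i]
  }
  times <- sort(stats::runif(N, 0, t))
  states <- c(a, path)
  real <- which(diff(states) != 0)
  if (!length(real)) return(NULL)
  data.frame(time = times[real], from = levels[states[real]],
             to = levels[states[real + 1]])
}

#' Stochastic character mapping
#'
#' Samples full character histories conditional on tip states and a fitted Mk
#' model: node states are drawn from their conditional distributions (pruning
#' partials + backward sampling from the root), then substitution histories
#' along each branch are sampled conditional on the endpoint states (rejection
#' sampling with a retry cap, uniformization fallback). Node posterior
#' probabilities are the state frequencies across maps. Deterministic given
#' `seed`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states named tip state vector (NA = unknown).
#' @param fit an [fit_mk()] result.
#' @param n_maps number of maps (default 100).
#' @param seed integer seed (required).
#' @return object of class `simmap_ensemble`: `node_posterior` (node x state),
#'   `node_states` (map x node), `events` (map, edge, time, from, to),
#'   `n_changes` per map.
#' @export
stochastic_map <- function(tree, states, fit, n_maps = 100, seed) {
  stopifnot(inherits(fit, "mk_fit"))
  states <- align_trait(tree, states, "states")
  levels <- fit$levels
  k <- length(levels)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  pr <- mk_prune(tree, mk_tip_matrix(states, levels), fit$Q, keep = TRUE)
  if (!is.finite(pr$loglik)) stop("zero likelihood under supplied fit")
  set.seed(seed)
  node_states <- matrix(NA_integer_, n_maps, nn)
  events <- vector("list", n_maps)
  root <- ntip + 1L
  nedge <- nrow(pr$edge)
  for (m in seq_len(n_maps)) {
    st <- integer(nn)
    st[root] <- sample.int(k, 1, prob = pr$root_prior * pr$L[root, ])
    ev <- list()
    for (i in rev(seq_len(nedge))) {   # preorder
      p <- pr$edge[i, 1]; ch <- pr$edge[i, 2]
      w <- pr$P[[i]][st[p], ] * pr$L[ch, ]
      st[ch] <- sample.int(k, 1, prob = w)
      h <- sample_branch_history(fit$Q, st[p], st[ch], pr$edge.length[i],
                                 levels)
      if (!is.null(h)) {
        h$edge <- i
        h$map <- m
        ev[[length(ev) + 1]] <- h
      }
    }
    node_states[m, ] <- st
    events[[m]] <- if (length(ev)) do.call(rbind, ev) else NULL
  }
  post <- t(vapply(seq(ntip + 1, nn), function(j)
    tabulate(node_states[, j], k) / n_maps, numeric(k)))
  dimnames(post) <- list(paste0("node_", seq(ntip + 1, nn)), levels)
  ev_all <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  structure(list(node_posterior = post,
                 node_states = matrix(levels[node_states], n_maps, nn),
                 events = ev_all,
                 n_changes = vapply(events, function(e)
                   if (is.null(e)) 0L else nrow(e), integer(1)),
                 n_maps = n_maps, seed = seed, levels = levels),
            class = "simmap_ensemble")
}

#' @export
print.simmap_ensemble <- function(x, ...) {
  cat(sprintf("<simmap_ensemble> %d maps over {%s}; mean changes/map = %.2f\n",
              x$n_maps, paste(x$levels, collapse = ", "),
              mean(x$n_changes)))
  invisible(x)
}
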
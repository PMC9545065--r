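## Binary elevational regimes: threshold assignment, 2-state Markov (Mk)
## likelihoods by the pruning algorithm, ML rate estimation (ER/ARD), and
## stochastic character maps conditional on tip states.

REGIME_LEVELS <- c("low", "high")

#' Assign binary elevational regimes from median elevations
#'
#' Species at or below the threshold are classed "low", above it "high".
#' The closed-low boundary convention (exactly 1500 m is "low") is
#' deterministic and affects only species sitting exactly on the cutoff.
#'
#' @param elevations Named numeric vector: median elevation (m a.s.l.) per
#'   species.
#' @param threshold Elevation cutoff in metres (default 1500, splitting
#'   foothill/hill species from sub-alpine/alpine ones).
#' @param species Optional character vector (e.g. tree tip labels); an error
#'   lists any species without an elevation.
#' @return A named character vector of `"low"`/`"high"` states with class
#'   `"regimes"` and attribute `threshold_m`.
#' @export
assign_regimes <- function(elevations, threshold = 1500, species = NULL) {
  if (is.null(names(elevations)) || any(!nzchar(names(elevations))))
    stop("'elevations' must be a named vector")
  if (!is.null(species)) {
    missing <- setdiff(species, names(elevations))
    if (length(missing))
      stop("no elevation for species: ", paste(missing, collapse = ", "))
    elevations <- elevations[species]
  }
  if (anyNA(elevations)) {
    bad <- names(elevations)[is.na(elevations)]
    stop("missing elevation for species: ", paste(bad, collapse = ", "))
  }
  st <- ifelse(elevations <= threshold, "low", "high")
  structure(st, names = names(elevations), class = "regimes",
            threshold_m = threshold)
}

#' @export
print.regimes <- function(x, ...) {
  cat("Elevational regimes (threshold ", attr(x, "threshold_m"), " m): ",
      sum(x == "low"), " low, ", sum(x == "high"), " high, ",
      length(x), " species\n", sep = "")
  invisible(x)
}

## 2x2 transition probability matrix for rates a = q_low->high, b = q_high->low
mk_pmat <- function(a, b, t) {
  s <- a + b
  if (s <= 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c(b + a * e, b - b * e,    # column 1: to "low"
           a - a * e, a + b * e) / s, 2L, 2L)
}

## states as integer vector 1 = low, 2 = high, named by tip label
regime_int <- function(states, tip_labels) {
  if (inherits(states, "regimes") || is.character(states)) {
    missing <- setdiff(tip_labels, names(states))
    if (length(missing))
      stop("no regime state for tips: ", paste(missing, collapse = ", "))
    s <- match(unclass(states)[tip_labels], REGIME_LEVELS)
    if (anyNA(s)) stop("regime states must be 'low' or 'high'")
    names(s) <- tip_labels
    return(s)
  }
  stop("'states' must be a regimes object or named character vector")
}

## Pruning pass: per-node downward partial likelihoods (conditional on data
## below each node), rescaled per node; returns list(L, logscale, pmats, po).
mk_prune <- function(tree, s_int, a, b) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, ntip + nnode, 2L)
  L[cbind(seq_len(ntip), 3L - s_int[tree$tip.label])] <- 0
  logscale <- 0
  pmats <- vector("list", nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; chd <- po$edge[k, 2L]
    P <- mk_pmat(a, b, po$edge.length[k])
    pmats[[k]] <- P
    L[par, ] <- L[par, ] * as.vector(P %*% L[chd, ])
    if (k == nrow(po$edge) || po$edge[k + 1L, 1L] != par) {
      m <- sum(L[par, ])
      if (m > 0) { L[par, ] <- L[par, ] / m; logscale <- logscale + log(m) }
    }
  }
  list(L = L, logscale = logscale, pmats = pmats, po = po)
}

#' Mk log-likelihood of binary regimes on a phylogeny
#'
#' Felsenstein pruning with per-branch matrix exponentials of the 2x2 rate
#' matrix and a flat (1/2, 1/2) root prior. Rates are in events per mya.
#'
#' @param tree A rooted `"phylo"` object.
#' @param states A [assign_regimes()] result or named `"low"`/`"high"` vector.
#' @param q_lh,q_hl Transition rates low-to-high and high-to-low (>= 0).
#' @return Log-likelihood (scalar); `-Inf` for data impossible under the rates.
#' @export
mk_loglik <- function(tree, states, q_lh, q_hl) {
  if (q_lh < 0 || q_hl < 0) stop("transition rates must be non-negative")
  s_int <- regime_int(states, tree$tip.label)
  pr <- mk_prune(tree, s_int, q_lh, q_hl)
  root <- ape::Ntip(tree) + 1L
  lik <- sum(0.5 * pr$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Fit a 2-state Markov model of regime switching by maximum likelihood
#'
#' `model = "ER"` constrains the two rates to be equal (1 free parameter);
#' `"ARD"` lets forward and backward rates differ (2 parameters). Rates are
#' searched on the log scale within \[1e-6, 100\] per mya with a multi-start
#' grid, so boundary solutions (e.g. all tips in one state) converge to the
#' lower bound.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` or `"ARD"`.
#' @return An object of class `"mk_fit"`: rates, logLik, k, AIC.
#' @export
fit_mk <- function(tree, states, model = c("ARD", "ER")) {
  model <- match.arg(model)
  s_int <- regime_int(states, tree$tip.label)
  lb <- log(1e-6); ub <- log(100)
  if (model == "ER") {
    nll <- function(lq) -mk_loglik(tree, states, exp(lq), exp(lq))
    op <- stats::optimize(nll, c(lb, ub))
    grid <- exp(seq(lb, ub, length.out = 25))
    gv <- vapply(log(grid), nll, 0)
    if (min(gv) < op$objective) {  # guard against a missed basin
      op2 <- stats::optimize(nll, log(grid[pmax(1, which.min(gv) + c(-1, 1))]))
      if (op2$objective < op$objective) op <- op2
    }
    rates <- rep(exp(op$minimum), 2L)
    ll <- -op$objective
    k <- 1L
  } else {
    starts <- as.matrix(expand.grid(lq1 = log(c(0.01, 0.1, 1, 10)),
                                    lq2 = log(c(0.03, 3))))
    nll <- function(p) {
      v <- -mk_loglik(tree, states, exp(p[1]), exp(p[2]))
      if (!is.finite(v)) 1e10 else v
    }
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      op <- tryCatch(
        stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                     lower = lb, upper = ub),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) stop("Mk ML optimisation failed from every start")
    rates <- exp(best$par)
    ll <- -best$value
    k <- 2L
  }
  names(rates) <- c("q_low_high", "q_high_low")
  structure(list(model = model, rates = rates, logLik = ll, k = k,
                 AIC = -2 * ll + 2 * k, n_tips = ape::Ntip(tree)),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk (", x$model, ") regime-switch model, ", x$n_tips, " tips\n",
      "  q low->high = ", signif(x$rates[1], 3),
      ",  q high->low = ", signif(x$rates[2], 3), " per mya\n",
      "  logLik = ", round(x$logLik, 3), ",  AIC = ", round(x$AIC, 2),
      "\n", sep = "")
  invisible(x)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' Marginal posterior state probabilities at internal nodes
#'
#' Pruning (inside) pass combined with an outside pass; used as the analytic
#' reference for stochastic-map node-state frequencies.
#'
#' @inheritParams mk_loglik
#' @return Matrix (nodes x 2) of posterior probabilities, rows ordered as
#'   node numbers (tips first), columns `low`/`high`.
#' @export
mk_marginals <- function(tree, states, q_lh, q_hl) {
  s_int <- regime_int(states, tree$tip.label)
  pr <- mk_prune(tree, s_int, q_lh, q_hl)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  up <- matrix(NA_real_, nn, 2L)
  up[root, ] <- c(0.5, 0.5)
  edge <- pr$po$edge
  ## children contributions P_k %*% L_child per edge
  contrib <- lapply(seq_len(nrow(edge)), function(k)
    as.vector(pr$pmats[[k]] %*% pr$L[edge[k, 2L], ]))
  ## preorder = reverse postorder
  for (k in rev(seq_len(nrow(edge)))) {
    par <- edge[k, 1L]; chd <- edge[k, 2L]
    sib <- which(edge[, 1L] == par & edge[, 2L] != chd)
    m <- up[par, ]
    for (j in sib) m <- m * contrib[[j]]
    up[chd, ] <- as.vector(m %*% pr$pmats[[k]])
  }
  post <- up * pr$L
  post <- post / rowSums(post)
  colnames(post) <- REGIME_LEVELS
  post
}

## --- stochastic maps -------------------------------------------------------

## forward-simulate the chain from state i over duration t; returns list of
## (times of jumps, states after each jump)
mk_forward <- function(i, t, rates_out) {
  times <- numeric(0); st <- integer(0)
  cur <- i; now <- 0
  repeat {
    r <- rates_out[cur]
    if (r <= 0) break
    now <- now + stats::rexp(1L, r)
    if (now >= t) break
    cur <- 3L - cur
    times <- c(times, now); st <- c(st, cur)
  }
  list(times = times, states = st)
}

## sample a path on one branch conditional on endpoint states (Nielsen-style
## rejection with forced first jump when i != j; uniformization fallback)
mk_branch_path <- function(i, j, t, a, b, max_attempts = 1000L) {
  rates_out <- c(a, b)
  if (t <= 0) {
    if (i != j) stop("zero-length branch with differing endpoint states")
    return(list(times = numeric(0), states = integer(0)))
  }
  for (att in seq_len(max_attempts)) {
    if (i == j) {
      p <- mk_forward(i, t, rates_out)
    } else {
      r <- rates_out[i]
      if (r <= 0) break   # change required but impossible by simulation
      u <- stats::runif(1L)
      tau <- -log(1 - u * (1 - exp(-r * t))) / r   # first jump, truncated exp
      cont <- mk_forward(3L - i, t - tau, rates_out)
      p <- list(times = c(tau, tau + cont$times), states = c(3L - i, cont$states))
    }
    end <- if (length(p$states)) p$states[length(p$states)] else i
    if (end == j) return(p)
  }
  mk_uniformization_path(i, j, t, a, b)
}

## uniformization bridge: exact sampling of the conditioned path
mk_uniformization_path <- function(i, j, t, a, b) {
  om <- max(a, b)
  if (om <= 0) {
    if (i != j) stop("no valid history: both rates zero with differing endpoints")
    return(list(times = numeric(0), states = integer(0)))
  }
  Q <- matrix(c(-a, b, a, -b), 2L, 2L)
  R <- diag(2) + Q / om
  Pij <- mk_pmat(a, b, t)[i, j]
  ## sample number of virtual jumps N | endpoints
  u <- stats::runif(1L)
  cum <- 0; n <- -1L
  Rpow <- diag(2)          # R^0
  Rlist <- list(Rpow)
  repeat {
    n <- n + 1L
    if (n > 0L) { Rpow <- Rpow %*% R; Rlist[[n + 1L]] <- Rpow }
    cum <- cum + stats::dpois(n, om * t) * Rlist[[n + 1L]][i, j] / Pij
    if (u <= cum || n > 10000L) break
  }
  if (n == 0L) return(list(times = numeric(0), states = integer(0)))
  jump_t <- sort(stats::runif(n, 0, t))
  v <- integer(n + 1L); v[1L] <- i; v[n + 1L] <- j
  if (n > 1L) for (k in 2L:n) {
    w <- R[v[k - 1L], ] * Rlist[[n + 2L - k]][, j]
    v[k] <- sample.int(2L, 1L, prob = w)
  }
  keep <- which(v[-1L] != v[-(n + 1L)])   # drop virtual (self) jumps
  list(times = jump_t[keep], states = v[keep + 1L])
}

#' Sample stochastic character maps of regime history
#'
#' Draws full regime histories along every branch, consistent with the tip
#' states: internal node states are sampled from their joint conditional
#' distribution (pruning partials, root-to-tip sampling), and within-branch
#' histories conditional on endpoint states by rejection sampling with a
#' uniformization fallback after 1000 attempts.
#'
#' @inheritParams mk_loglik
#' @param fit An [fit_mk()] result (its rates are used), or `NULL` to pass
#'   rates directly via `q_lh`/`q_hl`.
#' @param n_maps Number of independent maps.
#' @param seed Optional integer seed.
#' @return A list of `"regime_map"` objects. Each has `edge_maps` (per edge of
#'   `tree$edge`, a matrix with columns `duration`, `state` (1 = low,
#'   2 = high), ordered from the parent end), `node_states`, `tip_states`,
#'   and the rates used.
#' @export
sample_stochastic_maps <- function(tree, states, fit = NULL, n_maps = 100L,
                                   seed = NULL, q_lh = NULL, q_hl = NULL) {
  if (!is.null(fit)) {
    if (!inherits(fit, "mk_fit")) stop("'fit' must be an mk_fit object")
    if (!is.finite(fit$logLik)) stop("'fit' has non-finite log-likelihood")
    a <- fit$rates[[1]]; b <- fit$rates[[2]]
  } else {
    if (is.null(q_lh) || is.null(q_hl)) stop("supply 'fit' or both rates")
    a <- q_lh; b <- q_hl
  }
  s_int <- regime_int(states, tree$tip.label)
  if (a <= 0 && b <= 0 && length(unique(s_int)) > 1L)
    stop("no valid history: both rates are zero but tip states differ")
  if (!is.null(seed)) set.seed(seed)
  pr <- mk_prune(tree, s_int, a, b)
  if (sum(pr$L[ape::Ntip(tree) + 1L, ]) <= 0)
    stop("tip data impossible under the supplied rates")
  edge <- pr$po$edge
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  ## map postorder edge index -> original edge index of tree$edge
  orig_idx <- match(paste(edge[, 1], edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  lapply(seq_len(n_maps), function(m) {
    ns <- integer(ntip + tree$Nnode)
    w <- 0.5 * pr$L[root, ]
    ns[root] <- sample.int(2L, 1L, prob = w)
    edge_maps <- vector("list", nrow(edge))
    for (k in rev(seq_len(nrow(edge)))) {       # preorder
      par <- edge[k, 1L]; chd <- edge[k, 2L]
      w <- pr$pmats[[k]][ns[par], ] * pr$L[chd, ]
      ns[chd] <- sample.int(2L, 1L, prob = w)
      p <- mk_branch_path(ns[par], ns[chd], pr$po$edge.length[k], a, b)
      bounds <- c(0, p$times, pr$po$edge.length[k])
      seg_states <- c(ns[par], p$states)
      edge_maps[[orig_idx[k]]] <- cbind(duration = diff(bounds),
                                        state = seg_states)
    }
    structure(list(edge_maps = edge_maps,
                   node_states = ns,
                   tip_states = s_int,
                   rates = c(q_low_high = a, q_high_low = b)),
              class = "regime_map")
  })
}

#' Convert a true simulated history or single map to summaries
#'
#' `map_state_times()` gives per-edge time spent in each state;
#' `map_node_path_times()` the cumulative time in each state from the root to
#' every node; `map_tip_segments()` the ordered (start, end, state) segments
#' along each root-to-tip lineage in absolute time.
#'
#' @param tree A `"phylo"` object (the one the map was built on).
#' @param map A `"regime_map"` object.
#' @return See details.
#' @export
map_state_times <- function(tree, map) {
  t(vapply(map$edge_maps, function(m)
    c(low = sum(m[m[, 2] == 1, 1]), high = sum(m[m[, 2] == 2, 1])),
    numeric(2)))
}

#' @rdname map_state_times
#' @export
map_node_path_times <- function(tree, map) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  out <- matrix(0, nn, 2L, dimnames = list(NULL, REGIME_LEVELS))
  st <- map_state_times(tree, map)
  po <- ape::reorder.phylo(tree, "postorder")
  orig_idx <- match(paste(po$edge[, 1], po$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in rev(seq_len(nrow(po$edge))))        # preorder
    out[po$edge[k, 2L], ] <- out[po$edge[k, 1L], ] + st[orig_idx[k], ]
  out
}

#' @rdname map_state_times
#' @export
map_tip_segments <- function(tree, map) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  segs <- vector("list", nn)
  segs[[ape::Ntip(tree) + 1L]] <-
    matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("start", "end", "state")))
  po <- ape::reorder.phylo(tree, "postorder")
  orig_idx <- match(paste(po$edge[, 1], po$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in rev(seq_len(nrow(po$edge)))) {      # preorder
    par <- po$edge[k, 1L]; chd <- po$edge[k, 2L]
    base <- segs[[par]]
    t0 <- if (nrow(base)) base[nrow(base), 2L] else 0
    em <- map$edge_maps[[orig_idx[k]]]
    ends <- t0 + cumsum(em[, 1L])
    starts <- c(t0, ends[-length(ends)])
    segs[[chd]] <- rbind(base, cbind(start = starts, end = ends,
                                     state = em[, 2L]))
  }
  out <- segs[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}
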
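# Independent oracles used across the suite. Each deliberately avoids the
# package's own computational path.

# dense multivariate-normal log density via solve()/determinant()
dense_mvn_loglik <- function(y, mu, V) {
  d <- y - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + drop(t(d) %*% solve(V, d)))
}

# Mk likelihood by full enumeration over internal-node state assignments
enum_mk_loglik <- function(tree, states, a, b) {
  ntip <- ape::Ntip(tree)
  P <- function(t) {
    s <- a + b
    if (s <= 0) return(diag(2))
    e <- exp(-s * t)
    matrix(c(b + a * e, b - b * e, a - a * e, a + b * e) / s, 2L, 2L)
  }
  sint <- match(unclass(states)[tree$tip.label], c("low", "high"))
  assigns <- as.matrix(expand.grid(rep(list(1:2), tree$Nnode)))
  tot <- 0
  for (r in seq_len(nrow(assigns))) {
    full <- c(sint, assigns[r, ])
    pr <- 0.5
    for (k in seq_len(nrow(tree$edge)))
      pr <- pr * P(tree$edge.length[k])[full[tree$edge[k, 1L]],
                                        full[tree$edge[k, 2L]]]
    tot <- tot + pr
  }
  if (tot <= 0) -Inf else log(tot)
}

# phylogenetic covariance by per-pair intersection of root-to-tip edge paths
brute_vcv <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  path_edges <- function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root) {
      k <- which(tree$edge[, 2L] == node)
      out <- c(out, k)
      node <- tree$edge[k, 1L]
    }
    out
  }
  paths <- lapply(seq_len(ntip), path_edges)
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in i:ntip) {
    C[i, j] <- C[j, i] <- sum(tree$edge.length[intersect(paths[[i]],
                                                         paths[[j]])])
  }
  C
}

# random binary regimes with both states present
rand_regimes <- function(tree) {
  n <- ape::Ntip(tree)
  repeat {
    s <- sample(c("low", "high"), n, replace = TRUE)
    if (length(unique(s)) == 2L) break
  }
  structure(s, names = tree$tip.label, class = "regimes", threshold_m = NA_real_)
}

# exact-transition OU path simulation along the mapped tree (vectorized over
# replicates); independent of the closed-form covariance assembly
simulate_ou_paths <- function(tree, map, alpha, sigma2, theta, n_paths) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  orig_idx <- match(paste(po$edge[, 1], po$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  x <- matrix(NA_real_, ntip + tree$Nnode, n_paths)
  root <- ntip + 1L
  root_state <- map$edge_maps[[orig_idx[length(orig_idx)]]][1L, 2L]
  x[root, ] <- theta[root_state]
  for (k in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[k, 1L]; chd <- po$edge[k, 2L]
    v <- x[par, ]
    em <- map$edge_maps[[orig_idx[k]]]
    for (s in seq_len(nrow(em))) {
      d <- em[s, 1L]; th <- theta[em[s, 2L]]
      e <- exp(-alpha * d)
      v <- v * e + th * (1 - e) +
        stats::rnorm(n_paths, 0, sqrt(sigma2 * (1 - e^2) / (2 * alpha)))
    }
    x[chd, ] <- v
  }
  out <- t(x[seq_len(ntip), , drop = FALSE])
  colnames(out) <- tree$tip.label
  out
}

# quick species-level long table for phylogenetic mixed-model tests
make_lmm_data <- function(tree, elev, beta_heat_elev = 0, sd_phylo = 0.4,
                          sd_round = 0.1, sd_resid = 0.3) {
  d <- expand.grid(species = tree$tip.label,
                   treatment = c("Mild", "Frost", "Heat"),
                   round = c("S1", "S2"), stringsAsFactors = FALSE)
  d$elevation <- elev[d$species]
  ec <- d$elevation - mean(tapply(d$elevation, d$species, mean))
  C <- phylo_covariance(tree); C <- C / max(C)
  a <- drop(t(chol(C)) %*% stats::rnorm(ape::Ntip(tree))) * sd_phylo
  re_round <- stats::setNames(stats::rnorm(2, 0, sd_round), c("S1", "S2"))
  d$value <- 2 + a[match(d$species, tree$tip.label)] + re_round[d$round] +
    beta_heat_elev * ec * (d$treatment == "Heat") +
    stats::rnorm(nrow(d), 0, sd_resid)
  d
}
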
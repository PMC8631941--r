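# Shared fixtures, cached across test files within a session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tb_truth <- function() fixture("tb_truth", function() {
  make_ground_truth(7, "three_basin", 1)
})

# 1e5 i.i.d. samples from the packaged model and the refitted model
tb_series <- function() fixture("tb_series", function() {
  sample_binary_series(tb_truth(), 1e5, persistence = 0, seed = 11)
})

tb_fit <- function() fixture("tb_fit", function() {
  fit_pairwise_mem(tb_series())
})

tb_fit_landscape <- function() fixture("tb_fit_landscape", function() {
  energy_landscape(tb_fit()$params)
})

tb_fit_map <- function() fixture("tb_fit_map", function() {
  coarse_grain(tb_fit_landscape())
})

# small deterministic random models for property tests
random_params <- function(n_roi, seed, scale = 0.5) {
  withr::with_seed(seed, {
    h <- stats::runif(n_roi, -scale, scale)
    J <- matrix(stats::rnorm(n_roi^2, 0, scale / sqrt(n_roi)), n_roi)
    J <- (J + t(J)) / 2
    diag(J) <- 0
    mem_params(h, J)
  })
}

# ferromagnetic two-spin toy model used by several hand-value tests
ferro2 <- function() mem_params(c(0, 0), matrix(c(0, 1, 1, 0), 2))

# independent saddle-energy oracle: for each minima pair, the lowest
# level t (over the multiset of node energies) such that both minima lie
# in one connected component of the subgraph {E <= t}, connectivity via
# igraph. Exact for small N.
saddle_oracle <- function(landscape) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  e <- landscape$energies
  n_roi <- landscape$n_roi
  nb <- neighbour_table(n_roi)
  edges <- cbind(rep(seq_len(nrow(nb)), n_roi), as.vector(nb))
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  mins <- landscape$minima
  k <- length(mins)
  out <- matrix(NA_real_, k, k)
  diag(out) <- e[mins]
  levels <- sort(unique(e))
  for (t in levels) {
    alive <- which(e <= t)
    sub <- edges[edges[, 1] %in% alive & edges[, 2] %in% alive, ,
                 drop = FALSE]
    g <- igraph::graph_from_edgelist(matrix(as.character(sub), ncol = 2),
                                     directed = FALSE)
    comp <- igraph::components(g)$membership
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (!is.na(out[a, b])) next
      ca <- comp[as.character(mins[a])]
      cb <- comp[as.character(mins[b])]
      if (!is.na(ca) && !is.na(cb) && ca == cb) {
        out[a, b] <- out[b, a] <- t
      }
    }
    if (!anyNA(out)) break
  }
  dimnames(out) <- list(mins, mins)
  out
}

# direct numerical maximum-likelihood fit (independent of the package's
# gradient ascent): optimise the exact log-likelihood over (h, J) with
# optim/BFGS. Oracle for N <= 3.
ml_oracle <- function(freq, n_roi) {
  pats <- all_patterns(n_roi)
  if (!is.matrix(pats)) pats <- matrix(pats, ncol = n_roi)
  n_off <- n_roi * (n_roi - 1) / 2
  unpack <- function(theta) {
    h <- theta[seq_len(n_roi)]
    J <- matrix(0, n_roi, n_roi)
    J[upper.tri(J)] <- theta[-seq_len(n_roi)]
    J <- J + t(J)
    list(h = h, J = J)
  }
  nll <- function(theta) {
    p <- unpack(theta)
    e <- -(pats %*% p$h) - rowSums((pats %*% p$J) * pats) / 2
    logz <- max(-e) + log(sum(exp(-e - max(-e))))
    -sum(freq * (-e - logz))
  }
  fit <- stats::optim(rep(0, n_roi + n_off), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  p <- unpack(fit$par)
  mem_params(p$h, p$J)
}
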
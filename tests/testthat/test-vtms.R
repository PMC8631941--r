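# brute-force oracle: landscape quantities computed on the explicit
# restricted pattern set by enumeration (independent of the package's
# embedding-based route)
restricted_oracle <- function(params, target) {
  n <- params$n_roi
  full <- all_patterns(n)
  keep_pat <- full[full[, target] == -1, , drop = FALSE]
  e <- pattern_energy(params, keep_pat)
  # adjacency: single flip among non-target ROIs
  n_sub <- nrow(keep_pat)
  adj <- matrix(FALSE, n_sub, n_sub)
  for (i in seq_len(n_sub)) for (j in seq_len(n_sub)) {
    adj[i, j] <- sum(keep_pat[i, ] != keep_pat[j, ]) == 1
  }
  minima <- which(vapply(seq_len(n_sub), function(i) {
    all(e[i] < e[adj[i, ]])
  }, logical(1)))
  list(patterns = keep_pat, energies = e, minima = minima, adj = adj)
}

test_that("restriction keeps the energies of surviving patterns exactly", {
  p2 <- mem_params(c(0.3, -0.2), matrix(c(0, 0.4, 0.4, 0), 2))
  r <- restrict_landscape(p2, 1)
  expect_equal(length(r$energies), 2L)
  expect_equal(r$energies,
               pattern_energy(p2, rbind(c(-1, -1), c(-1, 1))))
  truth <- tb_truth()
  r7 <- restrict_landscape(truth$params, "DLPFC")
  expect_equal(length(r7$energies), 64L)
  keep <- r7$roi_subset
  sub <- all_patterns(6)
  full <- matrix(-1, 64, 7)
  full[, keep] <- sub
  expect_equal(r7$energies, pattern_energy(truth$params, full))
  expect_error(restrict_landscape(truth$params, 9), "invalid")
})

test_that("restricted minima and saddles agree with brute force at N <= 4", {
  for (seed in c(1, 4, 7)) {
    p <- random_params(4, seed, scale = 0.9)
    for (target in 1:4) {
      r <- restrict_landscape(p, target)
      o <- restricted_oracle(p, target)
      expect_equal(sort(r$energies), sort(o$energies))
      expect_setequal(r$minima, o$minima)
      if (length(r$minima) >= 2) {
        skip_if_not_installed("igraph")
        expect_equal(unclass(r$saddle), unclass(saddle_oracle(r)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("order of repeated restriction does not matter", {
  p <- random_params(5, seed = 3, scale = 0.6)
  # restricting i then j equals restricting {i, j}: compare energies over
  # the patterns with both ROIs inactive
  r_i <- restrict_landscape(p, 2)
  # build params on the 4 remaining ROIs with sigma_2 fixed at -1
  keep <- r_i$roi_subset
  h_eff <- p$h[keep] - p$J[keep, 2]
  p_i <- mem_params(h_eff, p$J[keep, keep])
  r_ij <- restrict_landscape(p_i, which(keep == 4))
  r_ji <- restrict_landscape(
    mem_params(p$h[setdiff(1:5, 4)] - p$J[setdiff(1:5, 4), 4],
               p$J[setdiff(1:5, 4), setdiff(1:5, 4)]),
    which(setdiff(1:5, 4) == 2))
  expect_equal(sort(r_ij$energies - min(r_ij$energies)),
               sort(r_ji$energies - min(r_ji$energies)), tolerance = 1e-12)
})

test_that("major states are remapped by the neighbouring-vector rule", {
  truth <- tb_truth()
  # no major minimum has a parietal ROI active: restricting aSPL keeps
  # every representative pattern and its label
  r_par <- restrict_landscape(truth$params, "aSPL")
  m_par <- remap_major_states(truth$map, r_par)
  keep <- r_par$roi_subset
  for (s in c("F", "Int", "V")) {
    pat <- index_to_pattern(truth$map$representative_minima[[s]], 7)
    ridx <- pattern_to_index(pat[keep])
    expect_equal(unname(m_par$label_of[ridx]), s)
  }
  # DLPFC is active in the F minimum. On the heterogeneous-frontal
  # template the F state survives its removal: the remapped F basin must
  # contain the neighbour with DLPFC switched off, and 3 states survive
  het <- fixture("het_truth", function() {
    make_ground_truth(7, "three_basin_het", 1)
  })
  r_dlpfc <- restrict_landscape(het$params, "DLPFC")
  m_dlpfc <- remap_major_states(het$map, r_dlpfc)
  expect_equal(sort(unique(m_dlpfc$label_of[m_dlpfc$label_of != "Other"])),
               c("F", "Int", "V"))
  patF <- index_to_pattern(het$map$representative_minima[["F"]], 7)
  patF[2] <- -1
  ridxF <- pattern_to_index(patF[r_dlpfc$roi_subset])
  expect_equal(unname(m_dlpfc$label_of[ridxF]), "F")
})

test_that("barrier changes match hand enumeration on a three-spin model", {
  # three spins: two coupled ferromagnetically, the third antagonistic
  J <- matrix(c(0, 1.2, -0.4,
                1.2, 0, -0.4,
                -0.4, -0.4, 0), 3, 3)
  p <- mem_params(c(0.05, 0.02, 0.4), J)
  ls <- energy_landscape(p)
  r <- restrict_landscape(p, 3)
  o <- restricted_oracle(p, 3)
  expect_setequal(r$minima, o$minima)
  # barriers on the restricted two-spin landscape by hand: with sigma_3
  # = -1 the effective model is h' = (0.45, 0.42), J12 = 1.2
  h_eff <- c(0.05 + 0.4, 0.02 + 0.4)
  e_hand <- function(s) -sum(h_eff * s) - 1.2 * s[1] * s[2] +
    (-0.4 + (-0.4 * -1 * -1) * 0)   # constant offset from sigma_3 terms
  # compare energy differences (offsets cancel)
  stopifnot(length(r$minima) == 2)
  d_pkg <- diff(r$energies[r$minima])
  d_hand <- e_hand(c(1, 1)) - e_hand(c(-1, -1))
  expect_equal(abs(d_pkg), abs(d_hand), tolerance = 1e-12)
})

test_that("virtual stimulation reports deltas and propagates degeneracy", {
  het <- fixture("het_truth", function() {
    make_ground_truth(7, "three_basin_het", 1)
  })
  vs <- virtual_stimulation(het$params, het$map, het$landscape, "DLPFC")
  expect_s3_class(vs, "restriction_result")
  expect_named(vs$barrier_deltas,
               c("F->Int", "Int->F", "Int->V", "V->Int"))
  expect_true(all(is.finite(vs$barrier_deltas)))
  # visual-side barriers are untouched by this frontal restriction
  expect_equal(unname(vs$barrier_deltas["Int->V"]), 0, tolerance = 1e-9)
  tab <- barrier_change_stats(vs)
  expect_equal(tab$delta, unname(vs$barrier_deltas))
  # a restriction that destroys the frontal remnant raises the
  # documented degeneracy error instead of mislabelling: on the
  # heterogeneous template the FEF-IFC pair defines F, so removing FEF
  # (and on the uniform template any frontal site) merges F into Int
  expect_error(virtual_stimulation(het$params, het$map, het$landscape,
                                   "FEF"),
               "collapsed")
  truth <- tb_truth()
  expect_error(virtual_stimulation(truth$params, truth$map,
                                   truth$landscape, "DLPFC"),
               "collapsed")
})

test_that("barrier manipulations move dwell times and transition shares together", {
  # family of landscapes: scaling the frontal fields raises the depth of
  # F and with it the F -> Int barrier; F dwell in the walk must rise
  truth <- tb_truth()
  bumps <- seq(-0.16, 0.16, length.out = 5)
  bars <- numeric(length(bumps))
  dwells <- matrix(NA_real_, length(bumps), 10)
  for (i in seq_along(bumps)) {
    h <- truth$params$h
    h[1:3] <- h[1:3] + bumps[i]
    p <- mem_params(h, truth$params$J)
    ls <- energy_landscape(p)
    mp <- coarse_grain(ls)
    bars[i] <- major_barriers(ls, mp)["F->Int"]
    for (s in 1:10) {
      w <- metropolis_walk(p, 2e4, 100, seed = 100 + s)
      sm <- smooth_states(label_states(w, mp))
      dwells[i, s] <- dynamics_summary(sm)$dwell["F"]
    }
  }
  rho <- stats::cor(bars, rowMeans(dwells), method = "spearman")
  expect_gt(rho, 0)
})
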
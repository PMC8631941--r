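test_that("local minima follow the strict single-flip rule", {
  flat <- enumerate_landscape(mem_params(c(0, 0), matrix(0, 2, 2)))
  expect_length(flat$minima, 0)
  f <- enumerate_landscape(ferro2())
  expect_setequal(f$minima, c(pattern_to_index(c(1, 1)),
                              pattern_to_index(c(-1, -1))))
  single <- enumerate_landscape(mem_params(c(2, 2), matrix(0, 2, 2)))
  expect_equal(single$minima, pattern_to_index(c(1, 1)))
})

test_that("two-spin ferromagnet has saddle +1 and symmetric barriers 2", {
  ls <- build_disconnectivity(enumerate_landscape(ferro2()))
  m <- as.character(c(pattern_to_index(c(1, 1)), pattern_to_index(c(-1, -1))))
  expect_equal(ls$saddle[m[1], m[2]], 1)
  expect_equal(ls$barriers[m[1], m[2]], 2)
  expect_equal(ls$barriers[m[2], m[1]], 2)
})

test_that("steepest descent uses the lowest-index tie rule and sizes sum to 1", {
  ls <- assign_basins(enumerate_landscape(ferro2()))
  # (+1, -1) has equal-energy descent targets (+1,+1) and (-1,-1);
  # the lowest pattern index is (-1,-1) = 1
  expect_equal(ls$basin_of[pattern_to_index(c(1, -1))],
               pattern_to_index(c(-1, -1)))
  expect_equal(sum(ls$basin_sizes), 1)
  single <- assign_basins(enumerate_landscape(
    mem_params(c(2, 2), matrix(0, 2, 2))))
  expect_equal(unname(single$basin_sizes), 1)
})

test_that("saddle energies match the igraph threshold oracle (N = 4)", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 5, 9)) {
    p <- random_params(4, seed, scale = 0.8)
    ls <- build_disconnectivity(enumerate_landscape(p))
    if (length(ls$minima) < 2) next
    expect_equal(unclass(ls$saddle), unclass(saddle_oracle(ls)),
                 tolerance = 1e-12)
  }
})

test_that("saddle matrix is ultrametric and barriers satisfy the depth identity", {
  for (seed in 1:6) {
    p <- random_params(5, seed, scale = 0.7)
    ls <- build_disconnectivity(enumerate_landscape(p))
    k <- length(ls$minima)
    if (k < 2) next
    e_min <- ls$energies[ls$minima]
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b) next
      expect_gte(ls$barriers[a, b], 0)
      expect_equal(ls$barriers[a, b] - ls$barriers[b, a],
                   e_min[b] - e_min[a], tolerance = 1e-12)
      for (cc in seq_len(k)) {
        if (cc == a || cc == b) next
        expect_lte(ls$saddle[a, b],
                   max(ls$saddle[a, cc], ls$saddle[cc, b]) + 1e-12)
      }
    }
  }
})

test_that("coarse-graining absorbs shallow minima by the threshold rule", {
  # two minima with a sub-threshold directional barrier: higher one merges
  p <- mem_params(c(0.25, 0), matrix(c(0, 0.6, 0.6, 0), 2))
  ls <- energy_landscape(p)
  expect_length(ls$minima, 2)
  bar <- ls$barriers
  e_min <- ls$energies[ls$minima]
  hi <- which.max(e_min)
  lo <- which.min(e_min)
  expect_lt(bar[hi, lo], 1)
  mg <- statescape:::merge_minima(ls, 1)
  expect_false(mg$alive[hi])
  expect_equal(mg$final[hi], lo)
  # with deep mutual barriers nothing merges
  p2 <- mem_params(c(0.1, 0.1), matrix(c(0, 1.6, 1.6, 0), 2))
  ls2 <- energy_landscape(p2)
  mg2 <- statescape:::merge_minima(ls2, 1)
  expect_true(all(mg2$alive))
})

test_that("the merged map is independent of the qualifying-merge order", {
  random_order_merge <- function(ls, threshold, seed) {
    mins <- ls$minima
    e_min <- ls$energies[mins]
    alive <- rep(TRUE, length(mins))
    into <- rep(NA_integer_, length(mins))
    withr::with_seed(seed, repeat {
      idx <- which(alive)
      quals <- list()
      for (l in idx) for (m in idx) {
        if (l != m && ls$saddle[l, m] - e_min[l] < threshold &&
            e_min[l] > e_min[m]) {
          quals[[length(quals) + 1]] <- c(l, m)
        }
      }
      if (!length(quals)) break
      pick <- quals[[sample.int(length(quals), 1)]]
      alive[pick[1]] <- FALSE
      into[pick[1]] <- pick[2]
    })
    final <- seq_along(mins)
    for (j in seq_along(mins)) {
      f <- j
      while (!alive[f]) f <- into[f]
      final[j] <- f
    }
    final
  }
  # the packaged landscape, pushed to merge with higher thresholds:
  # randomised qualifying-merge orders give the same final map
  tb <- tb_truth()$landscape
  for (th in c(1.5, 2.5)) {
    ref <- statescape:::merge_minima(tb, th)$final
    for (os in 1:4) expect_equal(random_order_merge(tb, th, os), ref)
  }
  # on arbitrary landscapes order independence can genuinely fail (a
  # minimum may have several qualifying absorbers); the contract is then
  # that the documented lowest-barrier-first order defines the output
  # deterministically
  n_checked <- 0
  for (seed in 1:10) {
    p <- random_params(6, seed + 20, scale = 1.2)
    ls <- energy_landscape(p)
    if (length(ls$minima) < 3) next
    n_checked <- n_checked + 1
    ref <- statescape:::merge_minima(ls, 1)$final
    expect_identical(statescape:::merge_minima(ls, 1)$final, ref)
    # every randomised-order result still maps each absorbed minimum to
    # a deeper surviving one (the rule itself is respected)
    for (os in 1:2) {
      alt <- random_order_merge(ls, 1, os)
      e_min <- ls$energies[ls$minima]
      moved <- which(alt != seq_along(alt))
      expect_true(all(e_min[alt[moved]] < e_min[moved]))
    }
  }
  expect_gte(n_checked, 1)
})

test_that("the packaged three-basin model coarse-grains to its designated states", {
  truth <- tb_truth()
  mp <- truth$map
  expect_s3_class(mp, "major_state_map")
  expect_equal(sort(unique(mp$label_of)), sort(c("F", "Int", "V")))
  expect_equal(unname(mp$representative_minima["F"]),
               pattern_to_index(c(1, 1, 1, -1, -1, -1, -1)))
  expect_equal(unname(mp$representative_minima["Int"]),
               pattern_to_index(rep(-1, 7)))
  expect_equal(unname(mp$representative_minima["V"]),
               pattern_to_index(c(-1, -1, -1, -1, -1, 1, 1)))
  # the three states are mutually separated by barriers above threshold
  bar <- major_barriers(truth$landscape, mp)
  expect_true(all(bar[c("F->Int", "Int->F", "Int->V", "V->Int")] > 1))
  # F and V lie at Hamming distance >= 3; Int sits between them in the tree
  expect_gte(sum(index_to_pattern(mp$representative_minima[["F"]], 7) !=
                 index_to_pattern(mp$representative_minima[["V"]], 7)), 3)
  # Int between F and V in the disconnectivity tree: the F-V branch point
  # is the higher of the F-Int and Int-V branch points
  pos <- stats::setNames(match(mp$representative_minima,
                               truth$landscape$minima),
                         names(mp$representative_minima))
  sad <- truth$landscape$saddle
  expect_equal(sad[pos[["F"]], pos[["V"]]],
               max(sad[pos[["F"]], pos[["Int"]]],
                   sad[pos[["Int"]], pos[["V"]]]),
               tolerance = 1e-9)
})
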
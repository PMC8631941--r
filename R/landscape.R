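#' Enumerate the energy landscape of a pairwise model
#'
#' The landscape is the hypercube graph over all 2^N activity patterns
#' (two patterns adjacent iff they differ at exactly one ROI) together
#' with the model energy of every pattern. Local minima are patterns whose
#' energy is strictly below that of all N neighbours.
#'
#' @param params a [mem_params()] object (N <= 20).
#' @return an object of class `energy_landscape` with `energies`
#'   (length 2^N), `minima` (pattern indices), `n_roi`, and the generating
#'   `params`. Restricted landscapes (see [restrict_landscape()])
#'   additionally carry `roi_subset`/`fixed` describing their embedding.
#' @export
enumerate_landscape <- function(params) {
  stopifnot(inherits(params, "mem_params"))
  e <- pattern_energy(params, all_patterns(params$n_roi))
  new_landscape(e, params$n_roi, params = params)
}

new_landscape <- function(energies, n_roi, params = NULL,
                          roi_subset = NULL, fixed = NULL) {
  nb <- neighbour_table(n_roi)
  nb_min <- apply(matrix(energies[nb], ncol = n_roi), 1, min)
  minima <- which(energies < nb_min)
  structure(list(energies = energies, minima = minima, n_roi = n_roi,
                 params = params, roi_subset = roi_subset, fixed = fixed),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape: %d patterns (N = %d), %d local minima\n",
              2^x$n_roi, x$n_roi, length(x$minima)))
  if (!is.null(x$basin_sizes)) {
    cat("  basin sizes:", signif(x$basin_sizes, 3), "\n")
  }
  invisible(x)
}

#' Disconnectivity structure: saddle energies, tree, barriers
#'
#' For every pair of local minima (l, m) the connecting threshold E*_lm is
#' the lowest energy level at which the two minima are still connected
#' when all patterns at or above the level are removed from the hypercube
#' -- equivalently, the minimum over connecting paths of the maximum node
#' energy along the path. The directional barrier is
#' barrier(l -> m) = E*_lm - E(min l). The disconnectivity tree is the
#' single-linkage ultrametric of E*.
#'
#' Implemented as one ascending-energy sweep with union-find: patterns are
#' activated from low to high energy, each activation unions the pattern
#' with its already-active neighbours, and the activation energy at which
#' two minima first share a component is their E*.
#'
#' @param landscape an `energy_landscape`.
#' @return the landscape augmented with `saddle` (symmetric E* matrix over
#'   minima, `Inf`-free), `barriers` (directional matrix, rows = from) and
#'   `tree` (an [stats::hclust] object, `NULL` for a single minimum).
#' @export
build_disconnectivity <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  mins <- landscape$minima
  k <- length(mins)
  if (k < 1) stop("landscape has no local minima")
  e <- landscape$energies
  n_pat <- length(e)
  nb <- neighbour_table(landscape$n_roi)
  ord <- order(e, seq_len(n_pat))

  parent <- seq_len(n_pat)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # minima carried by each component root (indices into mins)
  comp_mins <- vector("list", n_pat)
  for (j in seq_len(k)) comp_mins[[mins[j]]] <- j
  active <- logical(n_pat)
  saddle <- matrix(NA_real_, k, k)
  n_found <- 0L

  for (v in ord) {
    active[v] <- TRUE
    for (w in nb[v, ]) {
      if (!active[w]) next
      rv <- find(v)
      rw <- find(w)
      if (rv == rw) next
      mv <- comp_mins[[rv]]
      mw <- comp_mins[[rw]]
      if (length(mv) && length(mw)) {
        for (a in mv) for (b in mw) {
          if (is.na(saddle[a, b])) {
            saddle[a, b] <- saddle[b, a] <- e[v]
            n_found <- n_found + 1L
          }
        }
      }
      parent[rw] <- rv
      comp_mins[[rv]] <- c(mv, mw)
      comp_mins[rw] <- list(NULL)
    }
    if (n_found == k * (k - 1) / 2) break
  }
  if (k > 1 && anyNA(saddle[upper.tri(saddle)])) {
    stop("internal error: minima remained disconnected on the hypercube")
  }
  diag(saddle) <- e[mins]
  dimnames(saddle) <- list(mins, mins)

  barriers <- saddle - e[mins]   # rows = from-minimum
  diag(barriers) <- 0
  dimnames(barriers) <- dimnames(saddle)

  tree <- NULL
  if (k > 1) {
    d <- stats::as.dist(saddle)
    tree <- stats::hclust(d, method = "single")
    tree$labels <- as.character(mins)
  }
  landscape$saddle <- saddle
  landscape$barriers <- barriers
  landscape$tree <- tree
  landscape
}

#' Basin assignment by steepest descent
#'
#' From every pattern, repeatedly move to the neighbour with the smallest
#' energy while some neighbour is strictly lower; the pattern is assigned
#' to the basin of the local minimum finally reached. Ties among equally
#' lowest neighbours are broken towards the lowest pattern index
#' (deterministic rule). Basin size is the fraction of the 2^N patterns
#' draining to each minimum.
#'
#' @param landscape an `energy_landscape`.
#' @return the landscape augmented with `basin_of` (length 2^N, minimum
#'   pattern index per pattern) and `basin_sizes` (named fractions,
#'   summing to 1).
#' @export
assign_basins <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (length(landscape$minima) < 1) stop("landscape has no local minima")
  e <- landscape$energies
  n_pat <- length(e)
  nb <- neighbour_table(landscape$n_roi)
  basin <- integer(n_pat)
  ord <- order(e, seq_len(n_pat))
  for (v in ord) {
    nbe <- e[nb[v, ]]
    lo <- min(nbe)
    if (lo >= e[v]) {
      if (!(v %in% landscape$minima)) {
        stop("steepest descent stalled on an equal-energy plateau; ",
             "degenerate (tied) energies are not supported")
      }
      basin[v] <- v
    } else {
      tgt <- nb[v, which(nbe == lo)]
      basin[v] <- basin[min(tgt)]   # target is lower in energy: already done
    }
  }
  sizes <- table(factor(basin, levels = landscape$minima)) / n_pat
  landscape$basin_of <- basin
  landscape$basin_sizes <- stats::setNames(as.numeric(sizes),
                                           names(sizes))
  landscape
}

#' Full landscape construction
#'
#' Convenience wrapper: enumerate energies and minima, assign basins and
#' build the disconnectivity structure in one call.
#'
#' @param params a [mem_params()] object.
#' @return a fully populated `energy_landscape`.
#' @export
energy_landscape <- function(params) {
  build_disconnectivity(assign_basins(enumerate_landscape(params)))
}

# Iteratively absorb shallow minima: a minimum l (and its basin) joins the
# basin of minimum m when barrier(l -> m) < threshold and E(l) > E(m).
# Merges are applied lowest-qualifying-barrier first and re-evaluated
# after each merge. Saddle energies are fixed by the landscape, so a merge
# only removes l from the surviving set.
merge_minima <- function(landscape, barrier_threshold = 1) {
  stopifnot(!is.null(landscape$saddle))
  mins <- landscape$minima
  e_min <- landscape$energies[mins]
  alive <- rep(TRUE, length(mins))
  absorbed_into <- rep(NA_integer_, length(mins))
  trace <- list()
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    best <- NULL
    for (l in idx) for (m in idx) {
      if (l == m) next
      bar <- landscape$saddle[l, m] - e_min[l]
      if (bar < barrier_threshold && e_min[l] > e_min[m]) {
        cand <- c(bar, e_min[m], l, m)
        if (is.null(best) || bar < best[1] ||
            (bar == best[1] && e_min[m] < best[2])) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    l <- best[3]; m <- best[4]
    alive[l] <- FALSE
    absorbed_into[l] <- m
    trace[[length(trace) + 1L]] <- c(absorbed = mins[l], absorbing = mins[m])
  }
  # resolve chains l -> m -> ... -> survivor
  final <- seq_along(mins)
  for (j in seq_along(mins)) {
    f <- j
    while (!alive[f]) f <- absorbed_into[f]
    final[j] <- f
  }
  list(alive = alive, final = final, trace = trace)
}

#' Coarse-grain the landscape into major brain states
#'
#' Local minima separated from a deeper minimum by a directional barrier
#' below `barrier_threshold` are absorbed, together with their basins,
#' into the deeper minimum's basin; the rule is applied repeatedly
#' (lowest qualifying barrier first) until no merge applies. The three
#' surviving basins with the largest pattern counts are the major brain
#' states and are named by the activity profile of their minima: F has the
#' frontal ROIs (FEF, DLPFC, IFC) active, V the visual ROIs (LOC, V5),
#' Int is the remaining one. Patterns in any other surviving basin are
#' labelled Other.
#'
#' @param landscape a fully built `energy_landscape` (see
#'   [energy_landscape()]).
#' @param barrier_threshold energy-unit threshold below which a basin is
#'   absorbed (default 1).
#' @param strict_three raise an error unless exactly three basins survive.
#' @param rois optional list with `frontal` and `visual` index vectors
#'   used for naming (defaults to the packaged 7-ROI layout).
#' @return an object of class `major_state_map`: `label_of` (length 2^N
#'   character, one of "F", "Int", "V", "Other"), `representative_minima`
#'   (named pattern indices), `merge_trace`, `survivors`, `n_roi`,
#'   `threshold`.
#' @export
coarse_grain <- function(landscape, barrier_threshold = 1,
                         strict_three = FALSE, rois = NULL) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (is.null(landscape$basin_of) || is.null(landscape$saddle)) {
    landscape <- build_disconnectivity(assign_basins(landscape))
  }
  mg <- merge_minima(landscape, barrier_threshold)
  mins <- landscape$minima
  survivors <- mins[mg$alive]
  if (strict_three && length(survivors) != 3) {
    stop(sprintf("coarse-graining left %d basins, not 3 (strict_three)",
                 length(survivors)))
  }
  if (length(survivors) < 3) {
    stop(sprintf(
      "only %d basin(s) survive coarse-graining; cannot name F/Int/V",
      length(survivors)))
  }
  # coarse basin of each pattern = surviving minimum after the merges
  surv_of_min <- mins[mg$final]
  names(surv_of_min) <- as.character(mins)
  coarse <- surv_of_min[as.character(landscape$basin_of)]
  counts <- table(factor(coarse, levels = survivors))
  majors <- survivors[order(-as.numeric(counts), survivors)][1:3]

  patterns <- landscape_patterns(landscape)
  if (is.null(rois)) rois <- list(frontal = frontal_rois(),
                                  visual = visual_rois())
  score <- vapply(majors, function(m) {
    p <- patterns[match(m, seq_len(nrow(patterns))), ]
    sum(p[rois$frontal]) - sum(p[rois$visual])
  }, numeric(1))
  lab <- character(3)
  lab[which.max(score)] <- "F"
  lab[which.min(score)] <- "V"
  lab[lab == ""] <- "Int"
  rep_min <- stats::setNames(majors[match(c("F", "Int", "V"), lab)],
                             c("F", "Int", "V"))

  label_of <- rep("Other", length(landscape$energies))
  for (s in c("F", "Int", "V")) label_of[coarse == rep_min[[s]]] <- s
  structure(list(label_of = label_of,
                 representative_minima = rep_min,
                 survivors = survivors,
                 merge_trace = mg$trace,
                 n_roi = landscape$n_roi,
                 threshold = barrier_threshold),
            class = "major_state_map")
}

# patterns of a landscape in index order, embedded into the full ROI
# space for restricted landscapes
landscape_patterns <- function(landscape) {
  p <- all_patterns(landscape$n_roi)
  if (!is.matrix(p)) p <- matrix(p, ncol = landscape$n_roi)
  if (is.null(landscape$roi_subset)) return(p)
  n_full <- length(landscape$roi_subset) + length(landscape$fixed$roi)
  full <- matrix(NA_real_, nrow(p), n_full)
  full[, landscape$roi_subset] <- p
  full[, landscape$fixed$roi] <- landscape$fixed$value
  full
}

#' @export
print.major_state_map <- function(x, ...) {
  tab <- table(factor(x$label_of, levels = c("F", "Int", "V", "Other")))
  cat(sprintf("Major-state map (threshold %g): %d/%d minima survive\n",
              x$threshold, length(x$survivors),
              length(x$survivors) + length(x$merge_trace)))
  cat("  pattern counts:",
      paste(names(tab), as.numeric(tab), sep = "=", collapse = ", "), "\n")
  cat("  representative minima:",
      paste(names(x$representative_minima), x$representative_minima,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Directional barriers between the major states
#'
#' Extracts the four barrier heights the virtual-stimulation analysis
#' tracks (F->Int, Int->F, Int->V, V->Int) plus F<->V, from a landscape
#' and its major-state map.
#'
#' @param landscape a built `energy_landscape`.
#' @param map a `major_state_map` whose representative minima exist in the
#'   landscape.
#' @return named numeric vector of barriers in energy units.
#' @export
major_barriers <- function(landscape, map) {
  stopifnot(!is.null(landscape$saddle))
  mins <- landscape$minima
  pos <- match(map$representative_minima, mins)
  if (anyNA(pos)) stop("representative minima are not minima of this landscape")
  names(pos) <- names(map$representative_minima)
  b <- function(a, z) landscape$saddle[pos[[a]], pos[[z]]] -
    landscape$energies[mins[pos[[a]]]]
  c("F->Int" = b("F", "Int"), "Int->F" = b("Int", "F"),
    "Int->V" = b("Int", "V"), "V->Int" = b("V", "Int"),
    "F->V" = b("F", "V"), "V->F" = b("V", "F"))
}
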
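#' Restrict the landscape to patterns with an ROI silenced
#'
#' Models complete regional inhibition as state-space restriction: every
#' pattern with sigma_target = +1 is removed, leaving a hypercube of
#' dimension N-1 over the remaining ROIs. Energies of the surviving
#' patterns are exactly their energies under the full model (same h, J),
#' and all landscape machinery (minima, basins, disconnectivity,
#' coarse-graining) is reused on the restricted space.
#'
#' @param params the fitted [mem_params()].
#' @param target_roi index (or [roi_names()] name) of the silenced ROI.
#' @return an `energy_landscape` over 2^(N-1) patterns, fully built, with
#'   `roi_subset` (surviving ROI indices) and `fixed` (target, value -1)
#'   describing the embedding.
#' @export
restrict_landscape <- function(params, target_roi) {
  stopifnot(inherits(params, "mem_params"))
  if (is.character(target_roi)) {
    target_roi <- match(target_roi, roi_names())
  }
  n <- params$n_roi
  if (is.na(target_roi) || target_roi < 1 || target_roi > n) {
    stop("invalid target ROI")
  }
  keep <- setdiff(seq_len(n), target_roi)
  sub <- all_patterns(n - 1)
  if (!is.matrix(sub)) sub <- matrix(sub, ncol = n - 1)
  full <- matrix(-1, nrow(sub), n)
  full[, keep] <- sub
  e <- pattern_energy(params, full)
  ls <- new_landscape(e, n - 1, params = params, roi_subset = keep,
                      fixed = list(roi = target_roi, value = -1))
  build_disconnectivity(assign_basins(ls))
}

#' Remap the major states onto a restricted landscape
#'
#' The restricted landscape is coarse-grained with the same barrier
#' threshold; each pre-stimulation major state is then located in it. A
#' representative minimum whose pattern survives the restriction keeps
#' its label. If it was removed (its target ROI was +1), the state is
#' represented by the neighbouring pattern differing only at the target
#' ROI, and the label attaches to the restricted coarse basin containing
#' that neighbour. An error is raised if two major labels collapse onto
#' the same restricted basin.
#'
#' @param pre_map the pre-stimulation `major_state_map` (full space).
#' @param restricted a [restrict_landscape()] result.
#' @param barrier_threshold coarse-graining threshold (default 1).
#' @return a `major_state_map` over the restricted pattern space.
#' @export
remap_major_states <- function(pre_map, restricted, barrier_threshold = 1) {
  stopifnot(inherits(pre_map, "major_state_map"),
            inherits(restricted, "energy_landscape"),
            !is.null(restricted$roi_subset))
  n_full <- pre_map$n_roi
  keep <- restricted$roi_subset
  target <- restricted$fixed$roi
  mg <- merge_minima(restricted, barrier_threshold)
  mins <- restricted$minima
  surv_of_min <- mins[mg$final]
  names(surv_of_min) <- as.character(mins)
  coarse <- surv_of_min[as.character(restricted$basin_of)]

  reps <- integer(0)
  for (s in c("F", "Int", "V")) {
    pat <- index_to_pattern(pre_map$representative_minima[[s]], n_full)
    pat[target] <- -1   # neighbouring-vector rule when the minimum is removed
    ridx <- pattern_to_index(pat[keep])
    reps[[s]] <- coarse[[ridx]]   # basin that contains it (or its neighbour)
  }
  if (anyDuplicated(reps)) {
    stop("major states collapsed onto one basin after restriction")
  }
  label_of <- rep("Other", length(restricted$energies))
  for (s in c("F", "Int", "V")) label_of[coarse == reps[[s]]] <- s
  structure(list(label_of = label_of,
                 representative_minima = stats::setNames(reps,
                                                         c("F", "Int", "V")),
                 survivors = mins[mg$alive],
                 merge_trace = mg$trace,
                 n_roi = restricted$n_roi,
                 threshold = barrier_threshold),
            class = "major_state_map")
}

#' Virtual inhibitory stimulation of one ROI
#'
#' Full pipeline: restrict the landscape, remap the major states, and
#' quantify the structural change as the four directional barrier
#' differences (F->Int, Int->F, Int->V, V->Int; post minus pre) and the
#' change in the Int->F / Int->V barrier ratio.
#'
#' @param params fitted [mem_params()].
#' @param pre_map pre-stimulation `major_state_map`.
#' @param pre_landscape pre-stimulation `energy_landscape` (built).
#' @param target_roi ROI index or name.
#' @param barrier_threshold coarse-graining threshold (default 1).
#' @return an object of class `restriction_result`: `target_roi`,
#'   `restricted` (landscape), `map` (remapped states),
#'   `barriers_pre`, `barriers_post`, `barrier_deltas`,
#'   `ratio_pre`, `ratio_post`, `ratio_delta`. Undefined barriers
#'   (merged states) propagate as NA, never as silent zeros.
#' @export
virtual_stimulation <- function(params, pre_map, pre_landscape,
                                target_roi, barrier_threshold = 1) {
  restricted <- restrict_landscape(params, target_roi)
  map_post <- remap_major_states(pre_map, restricted, barrier_threshold)
  pre <- major_barriers(pre_landscape, pre_map)
  post <- major_barriers(restricted, map_post)
  keys <- c("F->Int", "Int->F", "Int->V", "V->Int")
  deltas <- post[keys] - pre[keys]
  ratio_pre <- unname(pre["Int->F"] / pre["Int->V"])
  ratio_post <- unname(post["Int->F"] / post["Int->V"])
  structure(list(target_roi = target_roi, restricted = restricted,
                 map = map_post, barriers_pre = pre, barriers_post = post,
                 barrier_deltas = deltas, ratio_pre = ratio_pre,
                 ratio_post = ratio_post,
                 ratio_delta = ratio_post - ratio_pre),
            class = "restriction_result")
}

#' @export
print.restriction_result <- function(x, ...) {
  cat("Virtual stimulation: ROI", x$target_roi, "silenced\n")
  cat("  barrier deltas (post - pre):\n")
  print(round(x$barrier_deltas, 4))
  cat(sprintf("  Int->F / Int->V ratio: %.3f -> %.3f (delta %+.3f)\n",
              x$ratio_pre, x$ratio_post, x$ratio_delta))
  invisible(x)
}

#' @rdname virtual_stimulation
#' @param pre,post a built pre-stimulation landscape+map pair and a
#'   `restriction_result`; convenience accessor returning the barrier
#'   change table.
#' @export
barrier_change_stats <- function(post) {
  stopifnot(inherits(post, "restriction_result"))
  data.frame(barrier = names(post$barrier_deltas),
             pre = as.numeric(post$barriers_pre[names(post$barrier_deltas)]),
             post = as.numeric(post$barriers_post[names(post$barrier_deltas)]),
             delta = as.numeric(post$barrier_deltas),
             row.names = NULL)
}
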
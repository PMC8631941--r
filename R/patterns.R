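#' Pattern indexing for binary activity vectors
#'
#' The whole landscape machinery works on the 2^N activity patterns of N
#' regions of interest (ROIs), each region being active (+1) or inactive
#' (-1). Patterns are indexed 1..2^N with the convention that ROI 1 is the
#' least significant bit of `index - 1` and a bit value of 1 means sigma =
#' +1. Every module (model fitting, landscape, dynamics, virtual
#' stimulation) shares this convention.
#'
#' @param pattern integer vector of +1/-1 activities, or a matrix with one
#'   pattern per row.
#' @return `pattern_to_index` returns 1-based integer indices;
#'   `index_to_pattern` returns a +1/-1 vector (or matrix for several
#'   indices); `all_patterns` returns the full 2^N x N matrix in index
#'   order.
#' @examples
#' pattern_to_index(c(1, -1, -1))   # 2
#' index_to_pattern(2, 3)           # c(1, -1, -1)
#' @export
pattern_to_index <- function(pattern) {
  if (is.matrix(pattern)) {
    check_pm1(pattern)
    n <- ncol(pattern)
    as.integer(((pattern + 1) / 2) %*% 2^(0:(n - 1))) + 1L
  } else {
    check_pm1(pattern)
    n <- length(pattern)
    as.integer(sum(((pattern + 1) / 2) * 2^(0:(n - 1)))) + 1L
  }
}

#' @rdname pattern_to_index
#' @param index 1-based pattern index (vectorised).
#' @param n_roi number of ROIs.
#' @export
index_to_pattern <- function(index, n_roi) {
  stopifnot(all(index >= 1L), all(index <= 2^n_roi))
  bits <- outer(index - 1L, 2^(0:(n_roi - 1)), function(k, b) bitwAnd(k, b) > 0)
  out <- matrix(ifelse(bits, 1, -1), nrow = length(index))
  if (length(index) == 1L) drop(out) else out
}

#' @rdname pattern_to_index
#' @export
all_patterns <- function(n_roi) {
  stopifnot(n_roi >= 1, n_roi <= 20)
  index_to_pattern(seq_len(2^n_roi), n_roi)
}

#' Hamming-1 neighbour table
#'
#' Row k lists the indices of the N patterns that differ from pattern k at
#' exactly one ROI (the adjacency used by the landscape and the random
#' walk).
#'
#' @param n_roi number of ROIs.
#' @return integer matrix, 2^n_roi rows by n_roi columns.
#' @export
neighbour_table <- function(n_roi) {
  k <- 0:(2^n_roi - 1)
  nb <- vapply(0:(n_roi - 1), function(b) bitwXor(k, 2^b), numeric(2^n_roi))
  matrix(as.integer(nb) + 1L, ncol = n_roi)
}

check_pm1 <- function(x) {
  if (!all(x == 1 | x == -1)) {
    stop("activity patterns must contain only +1 and -1", call. = FALSE)
  }
  invisible(x)
}

#' Canonical ROI names
#'
#' The seven regions tracked by the study design this package models, in
#' the fixed order used throughout: three frontal (FEF, DLPFC, IFC), two
#' parietal (aSPL, pSPL) and two visual (LOC, V5) areas.
#' @export
roi_names <- function() c("FEF", "DLPFC", "IFC", "aSPL", "pSPL", "LOC", "V5")

#' @rdname roi_names
#' @export
frontal_rois <- function() 1:3

#' @rdname roi_names
#' @export
visual_rois <- function() 6:7
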
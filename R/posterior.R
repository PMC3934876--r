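# Stage I: pairwise posterior probability matrices.
#
# For a sequence pair (x, y) a posterior matrix holds, at cell (i, j) of
# the (l_x + 1) x (l_y + 1) grid (row/column 0 being the DP boundary), the
# probability that residue x_i aligns with y_j in the true alignment. Two
# independent models are decoded -- a five-state pair HMM and a
# Boltzmann-weighted partition function over affine-gap global alignments
# -- and combined entrywise as root mean squares.

check_pair <- function(x, y) {
  if (!nzchar(x) || !nzchar(y)) stop("empty sequence", call. = FALSE)
}

#' Pair-HMM posterior probability matrix
#'
#' Forward-backward decoding of the five-state pair HMM (match plus
#' short/long insert states in either sequence), in log space so that
#' sequences of several thousand residues do not underflow. Entry (i, j)
#' is forward(i, j, match) * backward(i, j, match) / total.
#'
#' @param x,y Residue strings.
#' @param params [default_hmm_params()]-shaped parameter list.
#' @return Dense `(l_x + 1) x (l_y + 1)` posterior matrix.
#' @export
hmm_posterior <- function(x, y, params = default_hmm_params()) {
  check_pair(x, y)
  xi <- encode_residues(x, params$alphabet)
  yi <- encode_residues(y, params$alphabet)
  hmm_posterior_cpp(xi, yi, params$init, params$trans,
                    params$match_emit, params$ins_emit)
}

#' Partition-function posterior probability matrix
#'
#' Boltzmann-weighted ensemble of all affine-gap global alignments: entry
#' (i, j) is `Zf(i-1, j-1) * exp(beta * s(x_i, y_j)) * Zr(i, j) / Z`,
#' where `Zf`/`Zr` accumulate prefix/suffix ensembles in log space. At
#' `beta -> 0` every alignment weighs 1 and the entry tends to the
#' fraction of global alignments containing the pair (i, j).
#'
#' @param x,y Residue strings.
#' @param params [default_partition_params()]-shaped parameter list.
#' @return Dense `(l_x + 1) x (l_y + 1)` posterior matrix.
#' @export
pf_posterior <- function(x, y, params = default_partition_params()) {
  check_pair(x, y)
  if (params$beta <= 0) stop("beta must be > 0", call. = FALSE)
  xi <- encode_residues(x, params$alphabet)
  yi <- encode_residues(y, params$alphabet)
  pf_posterior_cpp(xi, yi, params$score, params$beta,
                   params$gap_open, params$gap_ext)
}

#' Root-mean-square combination of two posterior matrices
#'
#' Entrywise `sqrt((p_hmm^2 + p_pf^2) / 2)`.
#'
#' @param p_hmm,p_pf Equal-shaped posterior matrices.
#' @return Combined posterior matrix.
#' @export
combine_rms <- function(p_hmm, p_pf) {
  if (!identical(dim(p_hmm), dim(p_pf)))
    stop("posterior matrices differ in shape", call. = FALSE)
  sqrt((p_hmm^2 + p_pf^2) / 2)
}

#' Maximum expected accuracy score of a posterior matrix
#'
#' The maximum, over all monotone matchings (global alignments) of the two
#' sequences, of the sum of matched posterior entries; a Needleman-Wunsch
#' recursion with zero gap cost.
#'
#' @param p Dense posterior matrix with zero boundary row/column.
#' @return Non-negative score.
#' @export
mea_score <- function(p) {
  mea_score_cpp(p)
}

#' Posterior-based distance between two sequences
#'
#' `1 - mea_score(p) / min(l_x, l_y)`, clamped to `[0, 1]`: identical,
#' confidently aligned sequences score near 0.
#'
#' @param p Dense posterior matrix for the pair.
#' @param l_x,l_y Sequence lengths consistent with `dim(p) - 1`.
#' @return Distance in `[0, 1]`.
#' @export
pair_distance <- function(p, l_x = nrow(p) - 1L, l_y = ncol(p) - 1L) {
  stopifnot(l_x >= 1, l_y >= 1, nrow(p) == l_x + 1L, ncol(p) == l_y + 1L)
  min(1, max(0, 1 - mea_score(p) / min(l_x, l_y)))
}

#' Full posterior task for one sequence pair
#'
#' Runs both posterior models, combines them as root mean squares,
#' computes the pair distance, and converts the combined matrix (and its
#' transpose, so both orientations are available to the consistency
#' stage) to sparse form. In adaptive (accurate) mode the per-matrix
#' fraction filter replaces the static threshold.
#'
#' @param x,y Residue strings.
#' @param hmm,pf Model parameter lists.
#' @param tau Static sparsification threshold.
#' @param filter `"static"` or `"adaptive"`.
#' @param f Retained fraction for the adaptive filter.
#' @return List with `s_xy`, `s_yx` (`sparse_posterior`) and `distance`.
#' @export
posterior_task <- function(x, y, hmm = default_hmm_params(),
                           pf = default_partition_params(),
                           tau = 0.01, filter = c("static", "adaptive"),
                           f = 0.15) {
  filter <- match.arg(filter)
  p <- combine_rms(hmm_posterior(x, y, hmm), pf_posterior(x, y, pf))
  d <- pair_distance(p)
  s <- if (filter == "adaptive") {
    filter_adaptive(sparsify(p, tau = 0), f)
  } else {
    sparsify(p, tau = tau)
  }
  list(s_xy = s, s_yx = sparse_transpose(s), distance = d)
}
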
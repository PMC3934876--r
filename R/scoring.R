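# Sum-of-pairs (SP) and total-column (TC) accuracy against a reference
# alignment.
#
# SP counts aligned residue pairs of the reference that the test
# alignment reproduces; TC counts reference columns whose full residue
# content reappears as a single test column. Gap-residue and gap-gap
# pairs are never counted, and the TC denominator is restricted to
# reference columns holding at least two residues.

alignment_resmap <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  resmap <- matrix(0L, nrow(mat), ncol(mat))
  for (k in seq_len(nrow(mat))) {
    ng <- mat[k, ] != "-"
    resmap[k, ] <- as.integer(cumsum(ng) * ng)
  }
  resmap
}

#' Score a test alignment against a reference
#'
#' @param test,ref `Alignment` objects over the same identifiers and the
#'   same underlying (degapped) sequences; row order may differ.
#' @param core_columns Optional mask over reference columns (logical
#'   vector of length `ref$width`, or integer column indices): scoring is
#'   restricted to these annotated core columns.
#' @return Object of class `score_report`: list with `sp` and `tc`
#'   percentages in `[0, 100]`, plus the counted `ref_pairs`,
#'   `matched_pairs`, `ref_columns`, `matched_columns`.
#' @export
score_alignment <- function(test, ref, core_columns = NULL) {
  stopifnot(inherits(test, "Alignment"), inherits(ref, "Alignment"))
  if (!setequal(test$ids, ref$ids))
    stop("test and reference hold different identifiers", call. = FALSE)
  ord <- match(ref$ids, test$ids)
  test_rows <- test$rows[ord]
  if (!identical(gsub("-", "", test_rows, fixed = TRUE),
                 gsub("-", "", ref$rows, fixed = TRUE)))
    stop("test and reference disagree on the underlying sequences",
         call. = FALSE)

  n <- length(ref$ids)
  rmap <- alignment_resmap(ref)
  tmap <- alignment_resmap(new_alignment(ref$ids, test_rows, ref$alphabet))

  core <- rep(TRUE, ref$width)
  if (!is.null(core_columns)) {
    if (is.logical(core_columns)) {
      stopifnot(length(core_columns) == ref$width)
      core <- core_columns
    } else {
      core <- seq_len(ref$width) %in% as.integer(core_columns)
    }
  }

  # SP over ordered pairs x < y
  ref_pairs <- 0L
  matched <- 0L
  for (x in seq_len(n - 1L)) {
    lx <- max(rmap[x, ])
    for (y in (x + 1L):n) {
      both_ref <- which(rmap[x, ] > 0L & rmap[y, ] > 0L & core)
      if (!length(both_ref)) next
      ref_pairs <- ref_pairs + length(both_ref)
      # partner of each residue of x in the test alignment
      partner <- rep(NA_integer_, lx)
      both_test <- which(tmap[x, ] > 0L & tmap[y, ] > 0L)
      partner[tmap[x, both_test]] <- tmap[y, both_test]
      matched <- matched +
        sum(partner[rmap[x, both_ref]] == rmap[y, both_ref], na.rm = TRUE)
    }
  }

  # TC: reference columns (>= 2 residues, within the mask) reproduced
  # exactly -- same member set and residue indices -- by some test column
  signature <- function(m, j) {
    rows <- which(m[, j] > 0L)
    paste(rows, m[rows, j], sep = ":", collapse = ",")
  }
  ref_cols <- which(colSums(rmap > 0L) >= 2L & core)
  test_sigs <- vapply(seq_len(ncol(tmap)), function(j) signature(tmap, j), "")
  matched_cols <- sum(vapply(ref_cols, function(j) signature(rmap, j), "")
                      %in% test_sigs)

  structure(list(
    sp = if (ref_pairs > 0) 100 * matched / ref_pairs else NA_real_,
    tc = if (length(ref_cols) > 0) 100 * matched_cols / length(ref_cols)
         else NA_real_,
    ref_pairs = ref_pairs, matched_pairs = matched,
    ref_columns = length(ref_cols), matched_columns = matched_cols),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("SP %.2f%% (%d/%d pairs), TC %.2f%% (%d/%d columns)\n",
              x$sp, x$matched_pairs, x$ref_pairs,
              x$tc, x$matched_columns, x$ref_columns))
  invisible(x)
}
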
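# Alphabets, residue encoding, and model parameters.
#
# Residues are encoded as 1-based integer codes; the last code of each
# alphabet is the wildcard (X for amino acids, N for nucleotides) to which
# all ambiguity letters are mapped.

AMINO_LETTERS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
NUC_LETTERS <- c("A", "C", "G", "T", "N")

AMINO_AMBIGUITY <- c(B = "X", Z = "X", J = "X", U = "X", O = "X")
NUC_AMBIGUITY <- c(U = "T", R = "N", Y = "N", S = "N", W = "N", K = "N",
                   M = "N", B = "N", D = "N", H = "N", V = "N")

#' Residue letters of an alphabet
#'
#' @param alphabet `"amino"` or `"nucleotide"`.
#' @return Character vector of canonical letters; the final letter is the
#'   wildcard ambiguity code.
#' @export
alphabet_letters <- function(alphabet = c("amino", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "amino") AMINO_LETTERS else NUC_LETTERS
}

# Map a residue string to integer codes; ambiguity letters collapse to the
# wildcard. Unknown letters raise an error naming the offender.
encode_residues <- function(s, alphabet) {
  letters_ <- alphabet_letters(alphabet)
  amb <- if (alphabet == "amino") AMINO_AMBIGUITY else NUC_AMBIGUITY
  chars <- strsplit(toupper(s), "")[[1]]
  hit <- match(chars, names(amb))
  chars[!is.na(hit)] <- amb[hit[!is.na(hit)]]
  codes <- match(chars, letters_)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("illegal residue character(s) for ", alphabet, " alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  codes
}

decode_residues <- function(codes, alphabet) {
  paste(alphabet_letters(alphabet)[codes], collapse = "")
}

# Substitution score table over the encoded alphabet (wildcard included),
# in half-bit units. Amino acids use BLOSUM62; nucleotides a +5/-4
# match/mismatch table with neutral wildcard.
substitution_table <- function(alphabet) {
  letters_ <- alphabet_letters(alphabet)
  if (alphabet == "amino") {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    s <- env$BLOSUM62[letters_, letters_]
  } else {
    s <- matrix(-4, 5, 5, dimnames = list(letters_, letters_))
    diag(s) <- 5
    s["N", ] <- 0
    s[, "N"] <- 0
  }
  unname(as.matrix(s))
}

# Joint match-emission distribution: the Boltzmann transform of the
# half-bit score table, t(a,b) ~ q_a q_b 2^(s(a,b)/2), with background q
# taken at the self-consistent fixed point (q equals the marginal of t).
boltzmann_emissions <- function(score, n_iter = 200) {
  k <- nrow(score)
  w <- 2^(score / 2)
  q <- rep(1 / k, k)
  for (it in seq_len(n_iter)) {
    t_ <- outer(q, q) * w
    t_ <- t_ / sum(t_)
    q_new <- rowSums(t_)
    if (max(abs(q_new - q)) < 1e-14) { q <- q_new; break }
    q <- q_new
  }
  t_ <- outer(q, q) * w
  t_ <- t_ / sum(t_)
  list(match = t_, single = rowSums(t_))
}

#' Default five-state pair-HMM parameters
#'
#' The hidden model has one match state and two insert-state pairs (short
#' and long gaps in either sequence), the architecture used throughout the
#' ProbCons family of aligners. Match emissions are the Boltzmann transform
#' of the substitution table (BLOSUM62 for proteins) at its half-bit scale
#' with a self-consistent background; insert states emit the background.
#' Transition scalars follow the same family's conventions and can be
#' overridden through a parameter file (see [read_params_file()]).
#'
#' @param alphabet `"amino"` or `"nucleotide"`.
#' @param overrides Named list of scalar overrides (keys
#'   `hmm_init_match`, `hmm_init_short`, `hmm_init_long`,
#'   `hmm_gap_open_short`, `hmm_gap_open_long`, `hmm_gap_ext_short`,
#'   `hmm_gap_ext_long`).
#' @return List with elements `init` (length 5), `trans` (5 x 5
#'   row-stochastic), `match_emit` (K x K), `ins_emit` (length K), where
#'   state order is match, short-x, short-y, long-x, long-y.
#' @export
default_hmm_params <- function(alphabet = c("amino", "nucleotide"),
                               overrides = list()) {
  alphabet <- match.arg(alphabet)
  p <- list(hmm_init_match = 0.6814757, hmm_init_short = 0.1291759622,
            hmm_init_long = 0.0302861878,
            hmm_gap_open_short = 0.0119511066, hmm_gap_open_long = 0.008008334786,
            hmm_gap_ext_short = 0.3965826333, hmm_gap_ext_long = 0.8988758326)
  for (k in names(overrides)) if (k %in% names(p)) p[[k]] <- overrides[[k]]

  init <- c(p$hmm_init_match, p$hmm_init_short, p$hmm_init_short,
            p$hmm_init_long, p$hmm_init_long)
  init <- init / sum(init)
  go1 <- p$hmm_gap_open_short; go2 <- p$hmm_gap_open_long
  ge1 <- p$hmm_gap_ext_short; ge2 <- p$hmm_gap_ext_long
  trans <- rbind(
    c(1 - 2 * go1 - 2 * go2, go1, go1, go2, go2),
    c(1 - ge1, ge1, 0, 0, 0),
    c(1 - ge1, 0, ge1, 0, 0),
    c(1 - ge2, 0, 0, ge2, 0),
    c(1 - ge2, 0, 0, 0, ge2))
  em <- boltzmann_emissions(substitution_table(alphabet))
  structure(list(init = init, trans = trans,
                 match_emit = em$match, ins_emit = em$single,
                 alphabet = alphabet),
            class = "hmm_params")
}

#' Default partition-function parameters
#'
#' The alignment ensemble is Boltzmann-weighted with inverse temperature
#' `beta` over substitution scores (half-bit BLOSUM62 for proteins) and
#' affine gap penalties: a gap run of length L costs
#' `gap_open + (L - 1) * gap_ext`, terminal gaps included.
#'
#' @inheritParams default_hmm_params
#' @param overrides Named list with any of `pf_beta`, `pf_gap_open`,
#'   `pf_gap_ext`.
#' @return List with elements `score` (K x K), `gap_open`, `gap_ext`,
#'   `beta`.
#' @export
default_partition_params <- function(alphabet = c("amino", "nucleotide"),
                                     overrides = list()) {
  alphabet <- match.arg(alphabet)
  p <- list(pf_beta = 1.0, pf_gap_open = -4.5, pf_gap_ext = -0.25)
  for (k in names(overrides)) if (k %in% names(p)) p[[k]] <- overrides[[k]]
  if (p$pf_beta <= 0) stop("pf_beta must be > 0", call. = FALSE)
  structure(list(score = substitution_table(alphabet),
                 gap_open = p$pf_gap_open, gap_ext = p$pf_gap_ext,
                 beta = p$pf_beta, alphabet = alphabet),
            class = "partition_params")
}

#' Read a plain-text key/value parameter file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognised keys
#' are the scalar overrides of [default_hmm_params()] and
#' [default_partition_params()].
#'
#' @param path File path.
#' @return Named list of numeric values.
#' @export
read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed parameter line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric parameter value in line: ", ln, call. = FALSE)
    out[[key]] <- val
  }
  out
}
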
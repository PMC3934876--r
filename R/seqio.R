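# Sequence sets, alignments, and FASTA/CLUSTAL input-output.
#
# Unaligned residues live in a SequenceSet; gapped rows of equal width in
# an Alignment. Residues are 1-based within posterior matrices (index 0 is
# the DP boundary), alignment columns are addressed 1..width.

#' Construct a validated sequence set
#'
#' @param ids Character vector of unique, non-empty identifiers.
#' @param seqs Character vector of residue strings (upper-cased on
#'   construction), one per identifier.
#' @param alphabet `"amino"` or `"nucleotide"`.
#' @return Object of class `SequenceSet` with fields `ids`, `seqs`,
#'   `alphabet`.
#' @export
new_sequence_set <- function(ids, seqs, alphabet = c("amino", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs differ in length", call. = FALSE)
  if (any(!nzchar(ids))) stop("empty sequence identifier", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1], call. = FALSE)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for identifier: ", ids[!nzchar(seqs)][1], call. = FALSE)
  }
  for (k in seq_along(seqs)) encode_residues(seqs[k], alphabet)  # alphabet check
  structure(list(ids = ids, seqs = seqs, alphabet = alphabet),
            class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat("SequenceSet of", length(x$ids), x$alphabet, "sequences, lengths",
      paste(range(nchar(x$seqs)), collapse = "-"), "\n")
  invisible(x)
}

#' Construct a validated alignment
#'
#' @param ids Character vector of unique identifiers.
#' @param rows Character vector of gapped rows (`-` as gap), all the same
#'   width.
#' @param alphabet `"amino"` or `"nucleotide"`.
#' @return Object of class `Alignment` with fields `ids`, `rows`,
#'   `alphabet`, `width`.
#' @export
new_alignment <- function(ids, rows, alphabet = c("amino", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows))
    stop("ids and rows differ in length", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate identifier in alignment", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1)
    stop("alignment rows differ in width", call. = FALSE)
  if (widths[1] == 0) stop("alignment of width zero", call. = FALSE)
  for (k in seq_along(rows)) encode_residues(gsub("-", "", rows[k]), alphabet)
  structure(list(ids = ids, rows = rows, alphabet = alphabet,
                 width = widths[1]),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat("Alignment of", length(x$ids), "sequences, width", x$width, "\n")
  invisible(x)
}

#' Remove gaps from alignment rows
#'
#' @param aln An `Alignment`.
#' @return `SequenceSet` of the degapped rows, in row order.
#' @export
degap <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  new_sequence_set(aln$ids, gsub("-", "", aln$rows, fixed = TRUE), aln$alphabet)
}

# Scan raw FASTA lines for structural problems; returns NULL or an error
# message naming the offending line.
fasta_diagnose <- function(lines, alphabet = NULL) {
  if (!is.null(alphabet)) {
    amb <- if (alphabet == "amino") AMINO_AMBIGUITY else NUC_AMBIGUITY
    ok <- c(alphabet_letters(alphabet), names(amb), "-", ".", "*")
    body_lines <- which(!startsWith(trimws(lines), ">") & nzchar(trimws(lines)))
    for (ln in body_lines) {
      chars <- setdiff(strsplit(toupper(trimws(lines[ln])), "")[[1]], ok)
      if (length(chars))
        return(sprintf("line %d: illegal residue character(s) %s", ln,
                       paste(chars, collapse = ", ")))
    }
  }
  fasta_diagnose_structure(lines)
}

fasta_diagnose_structure <- function(lines) {
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first)) return("empty FASTA file")
  if (!startsWith(trimws(lines[first]), ">"))
    return(sprintf("line %d: expected '>' header before sequence data", first))
  hdr <- which(startsWith(trimws(lines), ">"))
  ids <- sub("^>\\s*", "", trimws(lines[hdr]))
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    return(sprintf("line %d: empty FASTA header", hdr[!nzchar(ids)][1]))
  dup <- duplicated(ids)
  if (any(dup))
    return(sprintf("line %d: duplicate FASTA header '%s'", hdr[dup][1], ids[dup][1]))
  ends <- c(hdr[-1] - 1, length(lines))
  for (k in seq_along(hdr)) {
    body <- if (hdr[k] < ends[k]) lines[(hdr[k] + 1):ends[k]] else character(0)
    if (!any(nzchar(gsub("[-.*[:space:]]", "", body))))
      return(sprintf("line %d: record '%s' has no residues", hdr[k], ids[k]))
  }
  NULL
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; records are then
#' canonicalised (upper case, `*` and whitespace stripped) and validated.
#' In unaligned mode gap characters `-` and `.` are stripped; in alignment
#' mode they are preserved (`.` rewritten to `-`) and an [new_alignment()]
#' is returned instead.
#'
#' @param path FASTA file path.
#' @param alphabet `"amino"` or `"nucleotide"`.
#' @param aligned If `TRUE` return an `Alignment` keeping gaps.
#' @return A `SequenceSet`, or an `Alignment` when `aligned = TRUE`.
#' @export
read_fasta <- function(path, alphabet = c("amino", "nucleotide"),
                       aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  diag_ <- fasta_diagnose(lines, alphabet)
  if (!is.null(diag_)) stop("malformed FASTA (", path, "): ", diag_, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[*[:space:]]", "", seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (aligned) {
    new_alignment(ids, seqs, alphabet)
  } else {
    new_sequence_set(ids, gsub("-", "", seqs, fixed = TRUE), alphabet)
  }
}

#' Write a sequence set or alignment as FASTA
#'
#' Records are written in input order with 60-column line wrapping via
#' [Biostrings::writeXStringSet()].
#'
#' @param x A `SequenceSet` or `Alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "SequenceSet")) {
    ss <- Biostrings::BStringSet(stats::setNames(x$seqs, x$ids))
  } else if (inherits(x, "Alignment")) {
    if (x$width == 0) stop("refusing to write zero-width alignment", call. = FALSE)
    ss <- Biostrings::BStringSet(stats::setNames(x$rows, x$ids))
  } else {
    stop("x must be a SequenceSet or Alignment", call. = FALSE)
  }
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Write an alignment in CLUSTAL format
#'
#' @param aln An `Alignment`.
#' @param path Output path.
#' @param block Residues per interleaved block line.
#' @return Invisibly, `path`.
#' @export
write_clustal <- function(aln, path, block = 60L) {
  stopifnot(inherits(aln, "Alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL multiple sequence alignment\n", con)
  namew <- max(nchar(aln$ids)) + 3L
  starts <- seq(1L, aln$width, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, aln$width)
    for (k in seq_along(aln$ids)) {
      writeLines(sprintf("%-*s%s", namew, aln$ids[k],
                         substr(aln$rows[k], s, e)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
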
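#' Alignment scoring parameters
#'
#' Defaults mirror the EDNAFULL/Needle convention for DNA: match +5,
#' mismatch -4, gap opening 10, gap extension 0.5.  A gap run of length k is
#' penalized `gap_open + (k - 1) * gap_extend`.
#'
#' @param match score for an identical base pair.
#' @param mismatch score for a mismatching pair (N against anything is a
#'   mismatch and never counts as identical).
#' @param gap_open penalty charged for the first column of a gap run.
#' @param gap_extend penalty per additional gap column.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = 10, gap_extend = 0.5) {
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  if (!(match > mismatch)) stop("need match > mismatch", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under the Gotoh three-state affine-gap
#' model, with a deterministic traceback (ties prefer the diagonal, then a
#' gap in `b`, then a gap in `a`).  Identity is the number of identical
#' non-gap, non-N columns divided by the total number of alignment columns,
#' gap columns included — the convention of the classical global pairwise
#' tools.
#'
#' @param a,b sequences ([annotated_sequence()] or plain strings).
#' @param params an [alignment_params()].
#' @param end_gaps_free if `TRUE`, leading and trailing gap runs are not
#'   penalized (overlap mode), appropriate when locating a short element
#'   inside a longer genomic region.  Default `FALSE`: true global mode with
#'   terminal gaps penalized.
#' @return Object of class `pairwise_alignment`: `gapped_a`, `gapped_b`,
#'   `score`, `n_columns`, `n_identical`, `identity` (fraction).
#' @examples
#' aln <- global_align("ACGT", "ACGA")
#' aln$identity  # 0.75
#' @export
global_align <- function(a, b, params = alignment_params(),
                         end_gaps_free = FALSE) {
  sa <- as_dna_string(a)
  sb <- as_dna_string(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  raw <- .gotoh_align(sa, sb, params$match, params$mismatch,
                      params$gap_open, params$gap_extend, end_gaps_free)
  ca <- strsplit(raw$gapped_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(raw$gapped_b, "", fixed = TRUE)[[1L]]
  ident <- ca == cb & ca != "-" & ca != "N"
  structure(list(gapped_a = raw$gapped_a, gapped_b = raw$gapped_b,
                 score = raw$score, n_columns = length(ca),
                 n_identical = sum(ident),
                 identity = sum(ident) / length(ca),
                 params = params, end_gaps_free = end_gaps_free),
            class = "pairwise_alignment")
}

#' Percent identity of a pairwise alignment
#'
#' `100 * n_identical / n_columns`, reported to 0.1%.  The denominator is the
#' full alignment length including gap columns.
#'
#' @param aln a [global_align()] result.
#' @return Percent identity, rounded to one decimal.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  round(100 * aln$n_identical / aln$n_columns, 1L)
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, %d identical (%.1f%%), score %.1f%s\n",
              x$n_columns, x$n_identical, 100 * x$identity, x$score,
              if (x$end_gaps_free) ", free end gaps" else ""))
  ca <- strsplit(x$gapped_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(x$gapped_b, "", fixed = TRUE)[[1L]]
  marks <- ifelse(ca == cb & ca != "-" & ca != "N", "|", " ")
  for (s in seq(1L, x$n_columns, by = width)) {
    e <- min(s + width - 1L, x$n_columns)
    cat("  ", substr(x$gapped_a, s, e), "\n", sep = "")
    cat("  ", paste(marks[s:e], collapse = ""), "\n", sep = "")
    cat("  ", substr(x$gapped_b, s, e), "\n", sep = "")
  }
  invisible(x)
}
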
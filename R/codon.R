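#' Codon-position overlay of an element
#'
#' Partitions every base of an element into one of five classes given the
#' reading frame: `pre_orf` (before the first codon), `codon_pos1`,
#' `codon_pos2`, `wobble` (third codon position), and `post_orf` (1-2
#' trailing bases that do not complete a codon).  First/second codon
#' positions are where base changes usually alter the encoded amino acid, so
#' bases there are held fixed by selection on the overlapping protein; wobble
#' positions are largely free to drift.
#'
#' @param seq an [annotated_sequence()] (or string).
#' @param frame_start 1-based position of the first base of the first codon;
#'   defaults to the sequence's own `frame_start` when present.
#' @return Object of class `codon_overlay` with fields `element_length`,
#'   `frame_start`, `per_position` (character vector of classes),
#'   `codon_index` (per-position codon number, `NA` outside the ORF),
#'   `n_codons` and `peptide` (with `'*'` for a stop codon).
#' @examples
#' ov <- overlay_frame(load_element("exonic_silencer"))
#' table(ov$per_position)
#' ov$peptide
#' @export
overlay_frame <- function(seq, frame_start = NULL) {
  seq <- as_annotated(seq)
  if (is.null(frame_start)) frame_start <- seq$frame_start
  len <- seq_length(seq)
  if (is.na(frame_start) || frame_start < 1L || frame_start > len)
    stop("frame_start must lie within the element (1..", len, ")",
         call. = FALSE)
  frame_start <- as.integer(frame_start)
  n_codons <- (len - frame_start + 1L) %/% 3L
  classes <- rep("post_orf", len)
  if (frame_start > 1L) classes[seq_len(frame_start - 1L)] <- "pre_orf"
  codon_index <- rep(NA_integer_, len)
  if (n_codons > 0L) {
    orf <- frame_start:(frame_start + 3L * n_codons - 1L)
    classes[orf] <- rep(c("codon_pos1", "codon_pos2", "wobble"), n_codons)
    codon_index[orf] <- rep(seq_len(n_codons), each = 3L)
  }
  structure(list(element_length = len, frame_start = frame_start,
                 per_position = classes, codon_index = codon_index,
                 n_codons = n_codons,
                 peptide = if (n_codons >= 1L)
                   translate_region(seq, frame_start) else ""),
            class = "codon_overlay")
}

#' @export
print.codon_overlay <- function(x, ...) {
  counts <- table(factor(x$per_position,
                         levels = c("pre_orf", "codon_pos1", "codon_pos2",
                                    "wobble", "post_orf")))
  cat(sprintf("<codon_overlay> %d bp, frame start %d, %d codons\n",
              x$element_length, x$frame_start, x$n_codons))
  print(counts)
  if (nzchar(x$peptide)) cat("peptide:", x$peptide, "\n")
  invisible(x)
}

# standard genetic code, one codon -> one aa letter ('*' = stop)
codon_table <- function() Biostrings::GENETIC_CODE

#' Translate the in-frame region of an element
#'
#' Standard genetic code; stop codons are reported as `'*'` and any codon
#' containing an `N` as `'X'`.
#'
#' @inheritParams overlay_frame
#' @return Peptide string, one letter per complete codon.
#' @examples
#' translate_region("ATGAAATGA", 1)  # "MK*"
#' @export
translate_region <- function(seq, frame_start = NULL) {
  seq <- as_annotated(seq)
  if (is.null(frame_start)) frame_start <- seq$frame_start
  len <- seq_length(seq)
  if (is.na(frame_start) || frame_start < 1L || frame_start > len)
    stop("frame_start must lie within the element", call. = FALSE)
  n_codons <- (len - frame_start + 1L) %/% 3L
  if (n_codons < 1L)
    stop("fewer than 3 in-frame bases: nothing to translate", call. = FALSE)
  starts <- frame_start + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(as_dna_string(seq), starts, starts + 2L)
  aa <- unname(codon_table()[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Effect of a single-base substitution on the encoded peptide
#'
#' Recomputes the translation before and after replacing one base; a change
#' is synonymous when the two peptides are equal (substitutions outside the
#' ORF are synonymous by location).
#'
#' @inheritParams overlay_frame
#' @param position 1-based position of the substituted base.
#' @param new_base replacement base, one of A/C/G/T, different from the
#'   current base.
#' @return List of class `mutation_effect`: `position`, `old_base`,
#'   `new_base`, `codon_index`, `codon_position_class`, `old_peptide`,
#'   `new_peptide`, `synonymous`.
#' @examples
#' # the G6 -> C change in the exonic silencer alters codon 2 (GAC -> CAC)
#' mutation_effect(load_element("exonic_silencer"), position = 6,
#'                 new_base = "C")$new_peptide
#' @export
mutation_effect <- function(seq, position, new_base, frame_start = NULL) {
  seq <- as_annotated(seq)
  if (is.null(frame_start)) frame_start <- seq$frame_start
  len <- seq_length(seq)
  position <- as.integer(position)
  if (position < 1L || position > len)
    stop("position outside the element", call. = FALSE)
  new_base <- toupper(new_base)
  if (!new_base %in% c("A", "C", "G", "T"))
    stop("new_base must be one of A/C/G/T", call. = FALSE)
  chars <- seq_chars(seq)
  old_base <- chars[position]
  if (new_base == old_base)
    stop("new_base equals the current base at position ", position,
         call. = FALSE)
  ov <- overlay_frame(seq, frame_start)
  chars[position] <- new_base
  mutated <- annotated_sequence(paste(chars, collapse = ""),
                                id = paste0(seq$id, "_mut"))
  old_pep <- ov$peptide
  new_pep <- if (ov$n_codons >= 1L) translate_region(mutated, frame_start)
             else ""
  structure(list(position = position, old_base = old_base,
                 new_base = new_base,
                 codon_index = ov$codon_index[position],
                 codon_position_class = ov$per_position[position],
                 old_peptide = old_pep, new_peptide = new_pep,
                 synonymous = identical(old_pep, new_pep)),
            class = "mutation_effect")
}

#' @export
print.mutation_effect <- function(x, ...) {
  cat(sprintf("<mutation_effect> %s%d -> %s (%s%s): %s\n",
              x$old_base, x$position, x$new_base, x$codon_position_class,
              if (!is.na(x$codon_index))
                paste0(", codon ", x$codon_index) else "",
              if (x$synonymous) "synonymous" else "non-synonymous"))
  cat("  ", x$old_peptide, " -> ", x$new_peptide, "\n", sep = "")
  invisible(x)
}

#' Is a codon base forced by the encoded amino acid?
#'
#' A base is "forced" when no alternative base at that codon position
#' preserves the amino acid (zero degeneracy at that position).  Used by the
#' `exclude_forced` policy of [neighbor_bias_table()]: neighbors whose
#' identity is already pinned by selection on the protein carry no
#' information about mutational bias.
#'
#' @param codon three-letter codon string.
#' @param pos codon position, 1-3.
#' @return `TRUE` if every alternative base at `pos` changes the amino acid.
#' @export
is_forced_base <- function(codon, pos) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L, pos %in% 1:3)
  tab <- codon_table()
  if (grepl("N", codon, fixed = TRUE)) return(FALSE)
  aa <- tab[[codon]]
  for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
    trial <- codon
    substr(trial, pos, pos) <- alt
    if (tab[[trial]] == aa) return(FALSE)
  }
  TRUE
}
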
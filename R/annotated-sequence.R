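#' Construct an annotated DNA sequence
#'
#' The basic container used throughout the package: a DNA string over
#' `{A,C,G,T,N}` with an identifier, an optional reading-frame anchor and a
#' role label.  Input is case-normalized to uppercase.  Coordinates are
#' 1-based and inclusive everywhere in this package, so "G6" means "the base
#' at position 6, which is G".
#'
#' @param residues single string of DNA residues (case-insensitive;
#'   `N` is accepted and treated as "unknown": it never matches in identity or
#'   invariance comparisons and is excluded from GC/CpG denominators).
#' @param id text label for the sequence.
#' @param frame_start optional 1-based position of the first base of the
#'   first codon, when the element overlaps an ORF.
#' @param role one of `"exonic_silencer"`, `"silencer_b"`, `"full_silencer"`,
#'   `"enhancer"`, `"embedded_silencer"`, `"generic"`.
#' @return An object of class `annotated_sequence`.
#' @examples
#' x <- annotated_sequence("tgcgcgacaac", id = "demo")
#' seq_length(x)
#' @export
annotated_sequence <- function(residues, id = "seq", frame_start = NA_integer_,
                               role = "generic") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("sequence '", id, "' is empty", call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("illegal residue '%s' at position %d of record '%s'",
                 chars[bad[1L]], bad[1L], id), call. = FALSE)
  role <- match.arg(role, c("generic", "exonic_silencer", "silencer_b",
                            "full_silencer", "enhancer", "embedded_silencer"))
  if (!is.na(frame_start)) {
    frame_start <- as.integer(frame_start)
    if (frame_start < 1L || frame_start > length(chars))
      stop("frame_start must lie within the sequence (1..", length(chars), ")",
           call. = FALSE)
  }
  structure(list(id = id, residues = residues,
                 frame_start = if (is.na(frame_start)) NA_integer_ else frame_start,
                 role = role),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  n <- seq_length(x)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<annotated_sequence> %s (%d bp, role %s%s)\n", x$id, n, x$role,
              if (!is.na(x$frame_start))
                paste0(", frame start ", x$frame_start) else ""))
  cat(" ", head, if (n > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.annotated_sequence <- function(x, ...) x$residues

#' Sequence length in bases
#' @param x an `annotated_sequence`.
#' @return Integer length.
#' @export
seq_length <- function(x) nchar(as_dna_string(x))

# Accept annotated_sequence or plain string; returns the residue string.
as_dna_string <- function(x) {
  if (inherits(x, "annotated_sequence")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected an annotated_sequence or a single DNA string")
}

# Residues as a character vector, one element per base.
seq_chars <- function(x) strsplit(as_dna_string(x), "", fixed = TRUE)[[1L]]

# Coerce anything sequence-like to annotated_sequence.
as_annotated <- function(x, id = "seq") {
  if (inherits(x, "annotated_sequence")) x else annotated_sequence(x, id = id)
}

# Resolve a `source` argument (path, or text with records) to a file path.
source_to_path <- function(source) {
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE) &&
      file.exists(source))
    return(list(path = source, temp = FALSE))
  path <- tempfile(fileext = ".txt")
  writeLines(unlist(strsplit(source, "\n", fixed = TRUE)), path)
  list(path = path, temp = TRUE)
}

#' Read a (multi-record) FASTA file
#'
#' Wrapped or unwrapped FASTA is accepted; the full description line is kept
#' as the sequence id and residues are uppercased.  Records containing
#' characters outside `{A,C,G,T,N}` after normalization are rejected with the
#' record and offending position named.
#'
#' @param source path to a FASTA file, or FASTA text itself.
#' @return A list of [annotated_sequence()] objects, input order preserved.
#' @examples
#' read_fasta(">x\nacgt")
#' @export
read_fasta <- function(source) {
  src <- source_to_path(source)
  if (src$temp) on.exit(unlink(src$path))
  set <- tryCatch(Biostrings::readBStringSet(src$path),
                  error = function(e) stop("FASTA parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in input", call. = FALSE)
  mapply(function(s, nm) annotated_sequence(s, id = nm),
         as.character(set), names(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs an `annotated_sequence` or list of them.
#' @param path output file path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "annotated_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    res <- s$residues
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))),
               con)
  }
  invisible(path)
}

#' Species record and ladder table
#'
#' Reads a two-column TSV of species name and divergence age (million years
#' ago, relative to the reference lineage).  A header row naming the columns
#' `species_name` and `divergence_age_mya` is recognized; otherwise the first
#' two columns are used positionally.
#'
#' @param source path to the TSV, or its text.
#' @return `data.frame` with columns `name` and `divergence_age`, sorted by
#'   ascending age.
#' @export
read_species_ladder <- function(source) {
  src <- source_to_path(source)
  if (src$temp) on.exit(unlink(src$path))
  first <- readLines(src$path, n = 1L)
  has_header <- grepl("species_name", first, fixed = TRUE)
  tab <- utils::read.delim(src$path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("species ladder needs two columns", call. = FALSE)
  out <- data.frame(name = as.character(tab[[1L]]),
                    divergence_age = as.numeric(tab[[2L]]),
                    stringsAsFactors = FALSE)
  validate_ladder_table(out)
  out[order(out$divergence_age), , drop = FALSE]
}

validate_ladder_table <- function(tab) {
  if (anyNA(tab$divergence_age) || any(tab$divergence_age < 0))
    stop("divergence ages must be numeric and >= 0", call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicate species name in ladder: ",
         tab$name[duplicated(tab$name)][1L], call. = FALSE)
  invisible(tab)
}

#' Ortholog ladder: species-ordered homologs with divergence ages
#'
#' Couples a reference element with orthologous sequences from other species,
#' ordered by ascending divergence age.  The reference lineage has age 0.
#' A member may be `NULL` to record a species in which no ortholog could be
#' located (treated as "no data", not as absence, by downstream dating).
#'
#' @param reference the reference [annotated_sequence()].
#' @param seqs named list of `annotated_sequence` (or `NULL`) per species.
#' @param ages numeric vector of divergence ages (Mya), named like `seqs`, or
#'   a ladder `data.frame` as returned by [read_species_ladder()].
#' @return An object of class `ortholog_ladder`.
#' @export
ortholog_ladder <- function(reference, seqs, ages) {
  reference <- as_annotated(reference, id = "reference")
  if (is.data.frame(ages)) {
    a <- ages$divergence_age
    names(a) <- ages$name
    ages <- a
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("ladder members must be named by species", call. = FALSE)
  if (!all(names(seqs) %in% names(ages)))
    stop("every member needs a divergence age", call. = FALSE)
  tab <- data.frame(name = names(seqs),
                    divergence_age = as.numeric(ages[names(seqs)]),
                    stringsAsFactors = FALSE)
  validate_ladder_table(tab)
  ord <- order(tab$divergence_age)
  structure(list(reference = reference,
                 members = tab[ord, , drop = FALSE],
                 seqs = lapply(seqs[ord], function(s)
                   if (is.null(s)) NULL else as_annotated(s))),
            class = "ortholog_ladder")
}

#' @export
print.ortholog_ladder <- function(x, ...) {
  cat(sprintf("<ortholog_ladder> reference %s (%d bp), %d members\n",
              x$reference$id, seq_length(x$reference), nrow(x$members)))
  for (i in seq_len(nrow(x$members))) {
    s <- x$seqs[[i]]
    cat(sprintf("  %-25s %7.1f Mya  %s\n", x$members$name[i],
                x$members$divergence_age[i],
                if (is.null(s)) "(no data)" else paste0(seq_length(s), " bp")))
  }
  invisible(x)
}

#' Multiple alignment container
#'
#' @param labels row labels.
#' @param rows gapped strings over `{A,C,G,T,N,-}`, all the same length.
#' @return Object of class `multiple_alignment` with fields `labels`, `rows`
#'   and `n_columns`.
#' @export
multiple_alignment <- function(labels, rows) {
  stopifnot(length(labels) == length(rows), length(rows) >= 1L)
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: rows differ in gapped length", call. = FALSE)
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% c("A", "C", "G", "T", "N", "-"))
    if (length(bad))
      stop(sprintf("illegal character '%s' at column %d of row '%s'",
                   chars[bad[1L]], bad[1L], labels[i]), call. = FALSE)
    ungapped <- gsub("-", "", rows[i], fixed = TRUE)
    if (!nzchar(ungapped))
      stop("row '", labels[i], "' is all gaps", call. = FALSE)
  }
  structure(list(labels = as.character(labels), rows = unname(rows),
                 n_columns = unname(widths[1L])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d rows x %d columns\n",
              length(x$rows), x$n_columns))
  for (i in seq_along(x$rows))
    cat(sprintf("  %-20s %s%s\n", x$labels[i], substr(x$rows[i], 1L, 50L),
                if (x$n_columns > 50L) "..." else ""))
  invisible(x)
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA and Clustal (the `CLUSTAL` header line is tolerated
#' with any version suffix; conservation lines are ignored).
#'
#' @param source path or text of the alignment.
#' @param dialect `"aligned_fasta"` or `"clustal"`.
#' @return A [multiple_alignment()].
#' @export
read_alignment <- function(source, dialect = c("aligned_fasta", "clustal")) {
  dialect <- match.arg(dialect)
  src <- source_to_path(source)
  if (src$temp) on.exit(unlink(src$path))
  if (dialect == "aligned_fasta") {
    set <- Biostrings::readBStringSet(src$path)
    if (length(set) == 0L) stop("no records in alignment", call. = FALSE)
    multiple_alignment(names(set), as.character(set))
  } else {
    aln <- tryCatch(
      Biostrings::readDNAMultipleAlignment(src$path, format = "clustal"),
      error = function(e) stop("Clustal parse error: ",
                               conditionMessage(e), call. = FALSE))
    rows <- as.character(aln)
    multiple_alignment(names(rows), unname(rows))
  }
}

# Ungap one alignment row into an annotated_sequence.
ungap_row <- function(maln, i) {
  annotated_sequence(gsub("-", "", maln$rows[i], fixed = TRUE),
                     id = maln$labels[i])
}
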
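#' Load a packaged SMIM45 element sequence
#'
#' The package ships the element sequences of the human SMIM45 locus: the
#' 230-bp silencer (an ATAC-STARR-seq lymphoblastoid silent region), its two
#' segments — the 38-bp exonic silencer overlapping the C-terminal end of the
#' 68-aa ORF and the 192-bp silencer b in the promoter region — the three
#' enhancers, and the 60-bp silencer embedded in enhancer 2.  The full
#' silencer is the exact concatenation of the exonic silencer and silencer b.
#' The exonic silencer's reading frame starts at base 3 (first codon CGC),
#' and the loader records that.
#'
#' @param name one of `"full_silencer"`, `"exonic_silencer"`, `"silencer_b"`,
#'   `"enhancer1"`, `"enhancer2"`, `"embedded_silencer"`, `"enhancer3"`.
#' @return An [annotated_sequence()].
#' @examples
#' seq_length(load_element("exonic_silencer"))  # 38
#' @export
load_element <- function(name) {
  meta <- list(
    full_silencer     = list(role = "full_silencer",     frame = 3L),
    exonic_silencer   = list(role = "exonic_silencer",   frame = 3L),
    silencer_b        = list(role = "silencer_b",        frame = NA_integer_),
    enhancer1         = list(role = "enhancer",          frame = NA_integer_),
    enhancer2         = list(role = "enhancer",          frame = NA_integer_),
    embedded_silencer = list(role = "embedded_silencer", frame = NA_integer_),
    enhancer3         = list(role = "enhancer",          frame = NA_integer_))
  if (!name %in% names(meta))
    stop("unknown element fixture '", name, "'; available: ",
         paste(names(meta), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", "smim45_elements.fa", package = "elemevo",
                      mustWork = TRUE)
  seqs <- read_fasta(path)
  ids <- vapply(seqs, function(s) s$id, "")
  s <- seqs[[match(name, ids)]]
  annotated_sequence(s$residues, id = name, frame_start = meta[[name]]$frame,
                     role = meta[[name]]$role)
}

#' The printed nearest-neighbor table of the exonic silencer
#'
#' Returns the published 13-row table of nearest-neighbor bases flanking
#' invariant bases of the exonic silencer, exactly as printed (labels like
#' `"G2"` meaning base G at 1-based position 2).  One printed entry (the 3'
#' neighbor of G22, printed as T23) disagrees with the extant base at
#' position 23 of the 38-mer (C); [evaluate_printed_neighbors()] reports and
#' flags this rather than silently overriding the published row.
#'
#' @return `data.frame` with columns `invariant_label`, `side`,
#'   `neighbor_label`.
#' @export
printed_neighbor_table <- function() {
  path <- system.file("extdata", "neighbor_table_printed.tsv",
                      package = "elemevo", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Split a label like "G22" into base and 1-based position.
parse_base_label <- function(label) {
  stopifnot(grepl("^[ACGTN][0-9]+$", label))
  list(base = substr(label, 1L, 1L),
       position = as.integer(substring(label, 2L)))
}

#' Evaluate a printed neighbor table against an element sequence
#'
#' For each printed row the neighbor base is taken from the published label
#' and scored for G/C membership (this reproduces the published 12/13
#' summary); the extant base at the same position is also read from the
#' sequence and any disagreement with the printed label is flagged.
#'
#' @param tbl a table as returned by [printed_neighbor_table()].
#' @param seq the element the labels refer to (default: the packaged exonic
#'   silencer).
#' @return The table with columns `printed_base`, `neighbor_position`,
#'   `printed_is_gc`, `extant_base`, `matches_extant` added; attributes
#'   `n_gc` and `n_rows` hold the G/C summary over the printed rows.
#' @export
evaluate_printed_neighbors <- function(tbl = printed_neighbor_table(),
                                       seq = load_element("exonic_silencer")) {
  chars <- seq_chars(seq)
  parsed <- lapply(tbl$neighbor_label, parse_base_label)
  tbl$printed_base <- vapply(parsed, `[[`, "", "base")
  tbl$neighbor_position <- vapply(parsed, `[[`, 0L, "position")
  if (any(tbl$neighbor_position > length(chars)))
    stop("neighbor position outside the element", call. = FALSE)
  tbl$printed_is_gc <- tbl$printed_base %in% c("G", "C")
  tbl$extant_base <- chars[tbl$neighbor_position]
  tbl$matches_extant <- tbl$printed_base == tbl$extant_base
  structure(tbl, n_gc = sum(tbl$printed_is_gc), n_rows = nrow(tbl))
}
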
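#' Recompute every desk-scale published check on the packaged fixtures
#'
#' Runs the full battery of in-locus computations on the packaged element
#' sequences — fixture lengths, segment concatenation, the codon overlay and
#' translation of the exonic silencer, the G6 substitution effect, CpG counts
#' and the junction-additivity identity, the printed nearest-neighbor table
#' evaluation, the proto-silencer run location, the NANOG motif and Alu
#' target-site scans, and the GC-rich tandem repeat — and compares each
#' computed value with the published one.
#'
#' @param json_path optional path; when given (and jsonlite is installed) a
#'   machine-readable twin of the table is written there.
#' @return `data.frame` of class `repro_report` with columns `check`,
#'   `computed`, `expected`, `status`; attribute `pass` is `TRUE` only if
#'   every row passes.  Use it as a process exit status: any failure means
#'   the packaged fixtures or the code no longer reproduce the published
#'   values.
#' @examples
#' rep <- reproduce_printed_checks()
#' all(rep$status == "pass")
#' @export
reproduce_printed_checks <- function(json_path = NULL) {
  checks <- list()
  add <- function(check, computed, expected) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, computed = as.character(computed),
      expected = as.character(expected),
      status = if (identical(as.character(computed), as.character(expected)))
        "pass" else "FAIL",
      stringsAsFactors = FALSE)
  }

  els <- c(full_silencer = 230L, exonic_silencer = 38L, silencer_b = 192L,
           enhancer1 = 210L, enhancer2 = 628L, embedded_silencer = 60L,
           enhancer3 = 512L)
  seqs <- lapply(names(els), load_element)
  names(seqs) <- names(els)
  for (nm in names(els))
    add(paste0("length ", nm), seq_length(seqs[[nm]]), els[[nm]])
  add("full = exonic + silencer_b",
      identical(paste0(seqs$exonic_silencer$residues,
                       seqs$silencer_b$residues),
                seqs$full_silencer$residues), TRUE)
  add("embedded silencer inside enhancer 2",
      grepl(seqs$embedded_silencer$residues, seqs$enhancer2$residues,
            fixed = TRUE), TRUE)

  ov <- overlay_frame(seqs$exonic_silencer)
  add("exonic silencer codons", ov$n_codons, 12L)
  add("exonic silencer wobble positions",
      sum(ov$per_position == "wobble"), 12L)
  add("exonic silencer codon-pos-1/2 bases",
      sum(ov$per_position %in% c("codon_pos1", "codon_pos2")), 24L)
  add("exonic silencer pre-ORF bases", sum(ov$per_position == "pre_orf"), 2L)
  add("exonic silencer peptide", ov$peptide, "RDNLAFGGPEV*")
  g6 <- mutation_effect(seqs$exonic_silencer, position = 6, new_base = "C")
  add("G6->C peptide", g6$new_peptide, "RHNLAFGGPEV*")
  add("G6->C non-synonymous", !g6$synonymous, TRUE)

  add("CpG count exonic silencer", composition(seqs$exonic_silencer)$n_cpg, 5L)
  add("CpG count silencer b", composition(seqs$silencer_b)$n_cpg, 13L)
  add("CpG count full silencer", composition(seqs$full_silencer)$n_cpg, 18L)
  add("CpG junction additivity",
      composition(seqs$full_silencer)$n_cpg ==
        composition(seqs$exonic_silencer)$n_cpg +
        composition(seqs$silencer_b)$n_cpg +
        as.integer(substring(seqs$exonic_silencer$residues, 38L) == "C" &&
                   substring(seqs$silencer_b$residues, 1L, 1L) == "G"), TRUE)
  add("GC count exonic silencer", composition(seqs$exonic_silencer)$n_gc, 27L)

  nb <- evaluate_printed_neighbors()
  add("printed neighbor rows", attr(nb, "n_rows"), 13L)
  add("printed neighbors that are G/C", attr(nb, "n_gc"), 12L)
  add("printed 5' neighbor bases match the 38-mer",
      all(nb$matches_extant[nb$side == "five_prime"]), TRUE)

  run <- motif_scan(seqs$silencer_b, "CCTCTGCAGCC")
  add("proto-silencer 11-mer at position",
      if (nrow(run) == 1L) run$start else NA, 121L)

  nanog <- motif_scan(seqs$enhancer3, "TAATTTTGT")
  add("NANOG motif hits in enhancer 3", nrow(nanog), 1L)
  add("Alu target-site motif TTTTA in enhancer 3",
      nrow(motif_scan(seqs$enhancer3, "TTTTA")) >= 1L, TRUE)

  tr <- tandem_repeat_scan(seqs$silencer_b, min_unit = 8L,
                           max_mismatches_per_copy = 1L)
  region <- regexpr("GCCCGCCCCGCCCGCCC", seqs$silencer_b$residues,
                    fixed = TRUE)
  covered <- nrow(tr) > 0L &&
    any(tr$start <= region[1L] &
        tr$end >= region[1L] + attr(region, "match.length") - 1L)
  add("tandem array covers the GC-rich repeat of silencer b", covered, TRUE)

  out <- do.call(rbind, checks)
  class(out) <- c("repro_report", "data.frame")
  attr(out, "pass") <- all(out$status == "pass")
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is needed to write JSON output", call. = FALSE)
    jsonlite::write_json(out, json_path, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.repro_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<repro_report> %d checks, %d pass\n", nrow(df),
              sum(df$status == "pass")))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
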
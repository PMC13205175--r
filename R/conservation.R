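#' Cross-species invariance profile of a reference element
#'
#' Marks every reference position as invariant when all compared homologs
#' carry the identical base at the homologous column: a gap or an `N` in any
#' compared row (or in the reference) breaks invariance.  Homologs may be
#' supplied pre-aligned as a [multiple_alignment()] (reference row named or
#' first), or as an [ortholog_ladder()], in which case each member is aligned
#' to the reference by [global_align()] with free end gaps.
#'
#' @param x a `multiple_alignment` or `ortholog_ladder`.
#' @param subset optional character vector of row labels / species names to
#'   compare against the reference (default: all of them).
#' @param reference label of the reference row (alignment input only;
#'   default: the first row).
#' @param params [alignment_params()] used when members must be aligned.
#' @return A `conservation_profile`: a `data.frame` with one row per
#'   reference position (`position`, `base`, `invariant`), attributes
#'   `reference` and `n_compared`.
#' @export
column_invariance <- function(x, subset = NULL, reference = NULL,
                              params = alignment_params()) {
  UseMethod("column_invariance")
}

new_profile <- function(position, base, invariant, reference, n_compared) {
  structure(data.frame(position = position, base = base,
                       invariant = invariant, stringsAsFactors = FALSE),
            reference = reference, n_compared = n_compared,
            class = c("conservation_profile", "data.frame"))
}

#' @export
column_invariance.multiple_alignment <- function(x, subset = NULL,
                                                 reference = NULL,
                                                 params = alignment_params()) {
  if (is.null(reference)) reference <- x$labels[1L]
  ri <- match(reference, x$labels)
  if (is.na(ri)) stop("reference row '", reference, "' not in alignment",
                      call. = FALSE)
  others <- setdiff(x$labels, reference)
  if (!is.null(subset)) {
    missing <- setdiff(subset, x$labels)
    if (length(missing)) stop("unknown rows: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    others <- setdiff(subset, reference)
  }
  if (length(others) == 0L) stop("empty species subset", call. = FALSE)
  mat <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  ref <- mat[ri, ]
  keep <- ref != "-"
  cmp <- mat[match(others, x$labels), keep, drop = FALSE]
  refk <- ref[keep]
  # invariant: every compared base equals the reference base, gap/N excluded
  inv <- vapply(seq_along(refk), function(k) {
    b <- refk[k]
    b != "N" && all(cmp[, k] == b) && !any(cmp[, k] %in% c("-", "N"))
  }, logical(1L))
  new_profile(seq_along(refk), refk, inv, reference, length(others))
}

#' @export
column_invariance.ortholog_ladder <- function(x, subset = NULL,
                                              reference = NULL,
                                              params = alignment_params()) {
  names_all <- x$members$name[!vapply(x$seqs, is.null, TRUE)]
  use <- if (is.null(subset)) names_all else {
    missing <- setdiff(subset, x$members$name)
    if (length(missing)) stop("unknown species: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    intersect(subset, names_all)
  }
  if (length(use) == 0L) stop("empty species subset", call. = FALSE)
  ref_chars <- seq_chars(x$reference)
  n <- length(ref_chars)
  # per member, the base aligned to each reference position ("-" if gapped)
  aligned <- vapply(use, function(nm) {
    s <- x$seqs[[match(nm, x$members$name)]]
    aln <- global_align(x$reference, s, params, end_gaps_free = TRUE)
    ga <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1L]]
    gb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1L]]
    gb[ga != "-"]
  }, character(n))
  aligned <- matrix(aligned, nrow = n)
  inv <- vapply(seq_len(n), function(k) {
    b <- ref_chars[k]
    b != "N" && all(aligned[k, ] == b)
  }, logical(1L))
  new_profile(seq_len(n), ref_chars, inv, x$reference$id, length(use))
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %s, %d positions, %d invariant (vs %d homologs)\n",
              attr(x, "reference"), nrow(x), sum(x$invariant),
              attr(x, "n_compared")))
  invisible(x)
}

#' Tripartite base classification of an element
#'
#' Combines an invariance profile with the codon overlay to partition every
#' base into `codon_fixed_invariant` (invariant and at codon position 1 or
#' 2 — conservation explainable by selection on the overlapping protein),
#' `wobble_invariant` (invariant at a third codon position — conservation NOT
#' required by the protein, the signature of a constraint on the element
#' itself), `pre_orf_invariant` / `post_orf_invariant` (invariant outside the
#' ORF), or `variable`.
#'
#' @param profile a [column_invariance()] result.
#' @param overlay the matching [overlay_frame()] result.
#' @return List of class `base_classification`: `per_position` data.frame
#'   (position, base, invariant, overlay_class, tri_class), `counts` (named
#'   integer, classes partition the element), and `wobble_invariant_positions`.
#' @export
classify_bases <- function(profile, overlay) {
  stopifnot(inherits(profile, "conservation_profile"),
            inherits(overlay, "codon_overlay"))
  if (nrow(profile) != overlay$element_length)
    stop("profile and overlay lengths differ (", nrow(profile), " vs ",
         overlay$element_length, ")", call. = FALSE)
  oc <- overlay$per_position
  tri <- ifelse(!profile$invariant, "variable",
         ifelse(oc %in% c("codon_pos1", "codon_pos2"), "codon_fixed_invariant",
         ifelse(oc == "wobble", "wobble_invariant",
         ifelse(oc == "pre_orf", "pre_orf_invariant", "post_orf_invariant"))))
  per <- data.frame(position = profile$position, base = profile$base,
                    invariant = profile$invariant, overlay_class = oc,
                    tri_class = tri, stringsAsFactors = FALSE)
  lev <- c("codon_fixed_invariant", "wobble_invariant", "pre_orf_invariant",
           "post_orf_invariant", "variable")
  counts <- table(factor(tri, levels = lev))
  structure(list(per_position = per,
                 counts = stats::setNames(as.integer(counts), lev),
                 wobble_invariant_positions =
                   per$position[per$tri_class == "wobble_invariant"]),
            class = "base_classification")
}

#' @export
print.base_classification <- function(x, ...) {
  cat("<base_classification>\n")
  print(x$counts)
  if (length(x$wobble_invariant_positions))
    cat("wobble-invariant positions:",
        paste(x$wobble_invariant_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Nearest-neighbor base table around invariant positions
#'
#' Lists, for every invariant position, the extant base immediately 5' and 3'
#' of it, and summarizes how many of those neighbors are G or C.  Neighbors
#' that are themselves invariant are omitted (their identity is constrained,
#' not informative about mutation).  Under `policy = "exclude_forced"`,
#' neighbors sitting at codon position 1 or 2 of a codon whose amino acid
#' admits no alternative base there (see [is_forced_base()]) are flagged
#' excluded and left out of the G/C summary; the default policy `"all"`
#' keeps every row, matching how the published table treats first-position
#' bases in degenerate codons.
#'
#' @param seq the element.
#' @param invariant_positions integer vector of invariant positions (1-based).
#' @param overlay optional [overlay_frame()] result; required for
#'   `exclude_forced`.
#' @param policy `"all"` or `"exclude_forced"`.
#' @return `data.frame` of class `neighbor_bias_table` with columns
#'   `invariant_position`, `side` (`five_prime`/`three_prime`),
#'   `neighbor_position`, `neighbor_base`, `is_gc`, `excluded`, `reason`;
#'   attributes `n_considered`, `n_gc`, `gc_fraction` summarize the
#'   non-excluded rows.
#' @export
neighbor_bias_table <- function(seq, invariant_positions, overlay = NULL,
                                policy = c("all", "exclude_forced")) {
  policy <- match.arg(policy)
  seq <- as_annotated(seq)
  chars <- seq_chars(seq)
  invariant_positions <- as.integer(invariant_positions)
  if (length(invariant_positions) &&
      (min(invariant_positions) < 1L ||
       max(invariant_positions) > length(chars)))
    stop("invariant position outside the element", call. = FALSE)
  if (policy == "exclude_forced" && is.null(overlay))
    stop("policy 'exclude_forced' needs a codon overlay", call. = FALSE)
  rows <- list()
  for (p in sort(invariant_positions)) {
    for (side in c("five_prime", "three_prime")) {
      q <- if (side == "five_prime") p - 1L else p + 1L
      if (q < 1L || q > length(chars)) next
      if (q %in% invariant_positions) next
      excluded <- FALSE
      reason <- ""
      if (policy == "exclude_forced" &&
          overlay$per_position[q] %in% c("codon_pos1", "codon_pos2")) {
        ci <- overlay$codon_index[q]
        cstart <- overlay$frame_start + 3L * (ci - 1L)
        codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
        cpos <- q - cstart + 1L
        if (is_forced_base(codon, cpos)) {
          excluded <- TRUE
          reason <- sprintf("codon %d position %d forced by %s", ci, cpos,
                            codon_table()[[codon]])
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(invariant_position = p, side = side,
                   neighbor_position = q, neighbor_base = chars[q],
                   is_gc = chars[q] %in% c("G", "C"),
                   excluded = excluded, reason = reason,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(invariant_position = integer(), side = character(),
               neighbor_position = integer(), neighbor_base = character(),
               is_gc = logical(), excluded = logical(), reason = character(),
               stringsAsFactors = FALSE)
  keep <- !tab$excluded
  structure(tab, n_considered = sum(keep), n_gc = sum(tab$is_gc[keep]),
            gc_fraction = if (sum(keep)) sum(tab$is_gc[keep]) / sum(keep)
                          else NA_real_,
            class = c("neighbor_bias_table", "data.frame"))
}

#' Maximal invariant runs (proto-element candidates)
#'
#' Finds all maximal runs of consecutive invariant positions — deeply
#' conserved stretches that are candidates for the nucleation sequence from
#' which a regulatory element matured.
#'
#' @param profile a [column_invariance()] result.
#' @param min_length shortest run to report.
#' @return `data.frame` with `start`, `end` (1-based inclusive element
#'   coordinates), `length` and `sequence`, sorted by decreasing length,
#'   ties broken by the 5'-most start.
#' @export
longest_invariant_runs <- function(profile, min_length = 1L) {
  stopifnot(inherits(profile, "conservation_profile"))
  r <- rle(profile$invariant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep], stringsAsFactors = FALSE)
  out$sequence <- vapply(seq_len(nrow(out)), function(i)
    paste(profile$base[out$start[i]:out$end[i]], collapse = ""), "")
  out[order(-out$length, out$start), , drop = FALSE]
}

#' Point and indel differences between two alignable sequences
#'
#' Aligns the two sequences globally with free end gaps, then counts
#' substitution columns individually (`N` against a base counts as a
#' difference: it is never identical) and each maximal gap run — terminal
#' runs included — as one indel event.
#'
#' @param ref,other the sequences.
#' @param params [alignment_params()].
#' @return Named numeric vector `c(n_point_differences, n_indel_events)`.
#' @examples
#' count_differences("ACGTACGT", "ACGAACG")  # one substitution, one indel
#' @export
count_differences <- function(ref, other, params = alignment_params()) {
  aln <- global_align(ref, other, params, end_gaps_free = TRUE)
  ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1L]]
  subs <- sum(ca != "-" & cb != "-" & ca != cb)
  gap_runs <- function(v) { r <- rle(v == "-"); sum(r$values) }
  c(n_point_differences = subs,
    n_indel_events = gap_runs(ca) + gap_runs(cb))
}

#' Completion species of an element
#'
#' For each ladder member, counts point and indel differences against the
#' reference over the element span (the alignment columns covered by the
#' reference; flanking sequence carried by a member is ignored).  The
#' completion species is the most anciently diverged member whose element is
#' identical to the reference; when no member is identical the element is
#' reference-lineage specific (human-specific, for a human reference).
#'
#' @param ladder an [ortholog_ladder()] with at least one non-reference
#'   member.
#' @param params [alignment_params()].
#' @return List of class `completion_call`: `per_member` data.frame (`name`,
#'   `divergence_age`, `n_point_differences`, `n_indel_events`, `identical`),
#'   `completion_species`, `completion_age`, `human_specific`.
#' @export
completion_call <- function(ladder, params = alignment_params()) {
  stopifnot(inherits(ladder, "ortholog_ladder"))
  if (nrow(ladder$members) == 0L) stop("empty ladder", call. = FALSE)
  n <- nrow(ladder$members)
  pm <- data.frame(name = ladder$members$name,
                   divergence_age = ladder$members$divergence_age,
                   n_point_differences = NA_integer_,
                   n_indel_events = NA_integer_,
                   identical = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- ladder$seqs[[i]]
    if (is.null(s)) next
    aln <- global_align(ladder$reference, s, params, end_gaps_free = TRUE)
    ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1L]]
    span <- range(which(ca != "-"))
    idx <- span[1L]:span[2L]
    ca <- ca[idx]; cb <- cb[idx]
    subs <- sum(ca != "-" & cb != "-" & ca != cb)
    r <- rle(ca == "-"); r2 <- rle(cb == "-")
    indels <- sum(r$values) + sum(r2$values)
    pm$n_point_differences[i] <- subs
    pm$n_indel_events[i] <- indels
    pm$identical[i] <- subs == 0L && indels == 0L
  }
  complete <- which(pm$identical %in% TRUE)
  if (length(complete)) {
    best <- complete[which.max(pm$divergence_age[complete])]
    comp_sp <- pm$name[best]
    comp_age <- pm$divergence_age[best]
    hs <- FALSE
  } else {
    comp_sp <- NA_character_; comp_age <- NA_real_; hs <- TRUE
  }
  structure(list(per_member = pm, completion_species = comp_sp,
                 completion_age = comp_age, human_specific = hs),
            class = "completion_call")
}

#' @export
print.completion_call <- function(x, ...) {
  cat("<completion_call>",
      if (x$human_specific) "element is reference-lineage specific\n"
      else sprintf("completed in %s (~%g Mya)\n", x$completion_species,
                   x$completion_age))
  print(x$per_member, row.names = FALSE)
  invisible(x)
}
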
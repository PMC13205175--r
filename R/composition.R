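#' GC and CpG composition of a sequence
#'
#' CpG counting is overlapping, single-strand, on the sequence as given: a
#' CpG is a position `p` with `C` at `p` and `G` at `p + 1`.  `N` bases are
#' excluded from both numerator and denominator of the GC fraction and never
#' take part in a CpG.
#'
#' @param seq an [annotated_sequence()] or string.
#' @return Object of class `composition_report`: `length`, `n_N`, `n_gc`,
#'   `gc_fraction`, `n_cpg`, `cpg_positions` (1-based start positions).
#' @examples
#' composition(load_element("exonic_silencer"))$n_cpg  # 5
#' @export
composition <- function(seq) {
  seq <- as_annotated(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  n_N <- sum(chars == "N")
  n_gc <- sum(chars %in% c("G", "C"))
  cpg <- if (n >= 2L)
    which(chars[-n] == "C" & chars[-1L] == "G") else integer()
  structure(list(id = seq$id, length = n, n_N = n_N, n_gc = n_gc,
                 gc_fraction = n_gc / (n - n_N),
                 n_cpg = length(cpg), cpg_positions = cpg),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %s: %d bp, GC %d/%d (%.1f%%), %d CpG\n",
              x$id, x$length, x$n_gc, x$length - x$n_N,
              100 * x$gc_fraction, x$n_cpg))
  invisible(x)
}

#' CpG cluster enrichment probability
#'
#' How surprising is the observed CpG count under a null in which the
#' dinucleotide carries no signal beyond mononucleotide composition?  Two
#' models are provided.  `binomial_tail`: the number of CpG-bearing adjacent
#' pairs is modelled as Binomial(length - 1, p) with `p = freq(C) * freq(G)`
#' estimated from the sequence itself, and the p-value is the upper tail
#' P(X >= k_observed).  `shuffle_null`: the exact mononucleotide composition
#' is preserved by permuting the residues, and the p-value is the fraction of
#' shuffles whose CpG count reaches the observed one.  The two nulls are
#' close but not identical (the permutation fixes the base counts; the
#' binomial does not), so small systematic differences between their
#' p-values are expected.
#'
#' @param seq the sequence (length >= 2).
#' @param model `"binomial_tail"` or `"shuffle_null"`.
#' @param n_shuffles number of permutations for the shuffle model.
#' @param seed integer seed, required for the shuffle model so results are
#'   reproducible.
#' @return Object of class `cluster_enrichment`: `k_observed`, `model`,
#'   `p_hat`, `p_value`, plus `n_shuffles` and `seed` for the shuffle model.
#' @examples
#' cpg_cluster_pvalue("CGCGCGCG")$p_value
#' @export
cpg_cluster_pvalue <- function(seq, model = c("binomial_tail", "shuffle_null"),
                               n_shuffles = 10000L, seed = NULL) {
  model <- match.arg(model)
  seq <- as_annotated(seq)
  chars <- seq_chars(seq)
  if (length(chars) < 2L) stop("sequence shorter than 2 bases", call. = FALSE)
  comp <- composition(seq)
  k <- comp$n_cpg
  informative <- chars[chars != "N"]
  p_hat <- mean(informative == "C") * mean(informative == "G")
  if (model == "binomial_tail") {
    p <- stats::pbinom(k - 1L, size = length(chars) - 1L, prob = p_hat,
                       lower.tail = FALSE)
    out <- list(k_observed = k, model = model, p_hat = p_hat, p_value = p,
                n_shuffles = NA_integer_, seed = NA_integer_)
  } else {
    if (is.null(seed)) stop("shuffle_null requires a seed", call. = FALSE)
    n_shuffles <- as.integer(n_shuffles)
    if (n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
    cpg_count <- function(v) sum(v[-length(v)] == "C" & v[-1L] == "G")
    hits <- withr_seed(seed, {
      sum(vapply(seq_len(n_shuffles),
                 function(i) cpg_count(sample(chars)) >= k, logical(1L)))
    })
    out <- list(k_observed = k, model = model, p_hat = p_hat,
                p_value = hits / n_shuffles, n_shuffles = n_shuffles,
                seed = as.integer(seed))
  }
  structure(out, class = "cluster_enrichment")
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.cluster_enrichment <- function(x, ...) {
  cat(sprintf("<cluster_enrichment> k = %d CpG, model %s, p_hat %.4f, p = %.4g\n",
              x$k_observed, x$model, x$p_hat, x$p_value))
  invisible(x)
}

# translate the motif mini-language (fixed letters + bounded repeats like
# "T{2,6}") into an anchored regular expression; spaces are cosmetic
motif_to_regex <- function(pattern) {
  pat <- gsub(" ", "", toupper(pattern), fixed = TRUE)
  if (!nzchar(pat)) stop("empty motif pattern", call. = FALSE)
  token <- "[ACGTN](\\{[0-9]+(,[0-9]+)?\\})?"
  if (!grepl(paste0("^(", token, ")+$"), pat))
    stop("malformed motif pattern '", pattern,
         "': only A/C/G/T/N and bounded repeats like T{2,6} are allowed",
         call. = FALSE)
  pat
}

#' Scan a sequence for a motif
#'
#' The pattern language is deliberately small: fixed bases `A/C/G/T/N` and
#' bounded repeats written `X{min,max}` (for example the NANOG core binding
#' motif family `TAAT T{2,6} GT`).  All hits are reported, overlapping ones
#' included; at each start position the longest match is taken.
#'
#' @param seq the sequence.
#' @param pattern motif pattern (literal string or bounded-repeat pattern).
#' @param pattern_id label carried into the result (defaults to the pattern).
#' @return `data.frame` with `pattern_id`, `start`, `end`, `matched_text`,
#'   in ascending start order.
#' @examples
#' motif_scan(load_element("enhancer3"), "TAATTTTGT")
#' @export
motif_scan <- function(seq, pattern, pattern_id = pattern) {
  seq <- as_annotated(seq)
  rx <- paste0("^(", motif_to_regex(pattern), ")")
  s <- as_dna_string(seq)
  n <- nchar(s)
  hits <- list()
  for (i in seq_len(n)) {
    m <- regmatches(substring(s, i), regexpr(rx, substring(s, i)))
    if (length(m)) {
      hits[[length(hits) + 1L]] <-
        data.frame(pattern_id = pattern_id, start = i,
                   end = i + nchar(m) - 1L, matched_text = m,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(pattern_id = character(), start = integer(), end = integer(),
               matched_text = character(), stringsAsFactors = FALSE)
}

#' Detect tandem repeats
#'
#' Finds maximal arrays of two or more adjacent copies of a repeat unit,
#' allowing up to `max_mismatches_per_copy` mismatches of each copy against
#' the first copy (the first copy is the fixed comparator, which keeps the
#' scan deterministic).  Only whole copies extend an array.
#'
#' @param seq the sequence.
#' @param min_unit smallest repeat-unit length considered (>= 4).
#' @param max_mismatches_per_copy mismatch budget per copy.
#' @param max_unit largest unit length considered; scanning very long units
#'   is quadratic, so the default caps at 20 bp (or half the sequence).
#' @return `data.frame` with `start`, `end`, `unit`, `unit_length`,
#'   `n_copies`, sorted by start position.
#' @examples
#' tandem_repeat_scan("ACGTACGT", min_unit = 4)
#' @export
tandem_repeat_scan <- function(seq, min_unit = 4L, max_mismatches_per_copy = 0L,
                               max_unit = 20L) {
  seq <- as_annotated(seq)
  if (min_unit < 4L) stop("min_unit must be >= 4", call. = FALSE)
  chars <- seq_chars(seq)
  n <- length(chars)
  max_unit <- min(max_unit, n %/% 2L)
  cand <- list()
  mism <- function(i, j, u) sum(chars[i:(i + u - 1L)] != chars[j:(j + u - 1L)])
  for (u in seq.int(min_unit, length.out = max(0L, max_unit - min_unit + 1L))) {
    s <- 1L
    while (s + 2L * u - 1L <= n) {
      k <- 1L
      while (s + (k + 1L) * u - 1L <= n &&
             mism(s, s + k * u, u) <= max_mismatches_per_copy)
        k <- k + 1L
      if (k >= 2L) {
        cand[[length(cand) + 1L]] <-
          data.frame(start = s, end = s + k * u - 1L,
                     unit = paste(chars[s:(s + u - 1L)], collapse = ""),
                     unit_length = u, n_copies = k, stringsAsFactors = FALSE)
        s <- s + 1L
      } else s <- s + 1L
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_length = integer(), n_copies = integer(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, cand)
  # maximality: drop arrays strictly contained in another array of the same
  # unit length
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    same <- which(tab$unit_length == tab$unit_length[i])
    for (j in same) {
      if (j != i && tab$start[j] <= tab$start[i] && tab$end[j] >= tab$end[i] &&
          (tab$start[j] < tab$start[i] || tab$end[j] > tab$end[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$start, tab$unit_length), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
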
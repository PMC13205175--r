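#' Configuration for the ortholog-ladder forward simulator
#'
#' The simulator emulates the generative picture behind constraint-overlay
#' analyses of regulatory elements: an ancestral element evolves
#' independently along each branch of a star phylogeny (one branch per
#' species, length = divergence age), with three per-position constraint
#' classes — frozen anchor bases that never change, codon positions 1/2 under
#' purifying selection when the element overlaps an ORF, and free positions —
#' plus a GC-biased substitution kernel at the immediate neighbors of frozen
#' positions.
#'
#' `neighbor_gc_bias` (beta) is the probability that an accepted substitution
#' at a frozen-neighbor site produces a G or C: the result base is drawn
#' uniformly from `{G,C}` minus the current base with probability beta, and
#' uniformly from the remaining non-G/C alternatives otherwise, so the G/C
#' indicator of every accepted frozen-neighbor change is exactly
#' Bernoulli(beta) and beta is identifiable by [recover_beta()].  At all
#' other sites the result is uniform over the three alternative bases.
#'
#' @param ladder `data.frame` with `name` and `divergence_age` (Mya) per
#'   species (see [read_species_ladder()]).
#' @param seed integer seed; mandatory, there is no hidden global randomness.
#' @param ancestral_sequence DNA string for the ancestor; alternatively give
#'   `length` (and `gc`) to generate one.
#' @param length,gc length and GC fraction of a generated ancestor.
#' @param frame_start 1-based first codon base, or `NA` when the element does
#'   not overlap an ORF.
#' @param mu substitution rate, events per site per million years.
#' @param frozen_positions integer positions that never mutate.
#' @param purifying if `TRUE` (requires `frame_start`), proposed changes at
#'   codon positions 1/2 that alter the encoded amino acid are rejected.
#' @param neighbor_gc_bias beta, in `[0, 1]`.  Default 0.92 — a strong bias,
#'   of the size suggested by observed neighbor tables (12/13 G/C).
#' @param indel_rate indel events per site per million years (default 0).
#' @param indel_max_len longest insertion/deletion, bases.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(ladder, seed, ancestral_sequence = NULL,
                              length = NULL, gc = 0.5, frame_start = NA,
                              mu = 0.002, frozen_positions = integer(),
                              purifying = FALSE, neighbor_gc_bias = 0.92,
                              indel_rate = 0, indel_max_len = 3L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.data.frame(ladder)) validate_ladder_table(ladder)
  else stop("ladder must be a data.frame of name/divergence_age",
            call. = FALSE)
  if (is.null(ancestral_sequence) && is.null(length))
    stop("give ancestral_sequence or length", call. = FALSE)
  if (!is.null(ancestral_sequence)) {
    ancestral_sequence <- toupper(ancestral_sequence)
    length <- nchar(ancestral_sequence)
  }
  if (mu < 0 || indel_rate < 0) stop("rates must be >= 0", call. = FALSE)
  if (neighbor_gc_bias < 0 || neighbor_gc_bias > 1)
    stop("neighbor_gc_bias must be in [0, 1]", call. = FALSE)
  frozen_positions <- sort(unique(as.integer(frozen_positions)))
  if (base::length(frozen_positions) &&
      (min(frozen_positions) < 1L || max(frozen_positions) > length))
    stop("frozen position out of range", call. = FALSE)
  if (purifying && is.na(frame_start))
    stop("purifying selection needs a frame_start", call. = FALSE)
  structure(list(ladder = ladder[order(ladder$divergence_age), , drop = FALSE],
                 seed = as.integer(seed),
                 ancestral_sequence = ancestral_sequence,
                 length = as.integer(length), gc = gc,
                 frame_start = if (is.na(frame_start)) NA_integer_
                               else as.integer(frame_start),
                 mu = mu, frozen_positions = frozen_positions,
                 purifying = purifying,
                 neighbor_gc_bias = neighbor_gc_bias,
                 indel_rate = indel_rate,
                 indel_max_len = as.integer(indel_max_len)),
            class = "simulation_config")
}

# draw a replacement base for a substitution event
propose_base <- function(current, frozen_neighbor, beta) {
  if (frozen_neighbor) {
    if (stats::runif(1L) < beta) {
      pool <- setdiff(c("G", "C"), current)
    } else {
      pool <- setdiff(c("A", "T"), current)
    }
  } else {
    pool <- setdiff(c("A", "C", "G", "T"), current)
  }
  pool[sample.int(length(pool), 1L)]
}

#' Simulate an ortholog ladder with known ground truth
#'
#' Evolves the ancestral element independently along each species branch:
#' every non-frozen site receives a Poisson(mu * divergence_age) number of
#' substitution events, applied sequentially with the kernel described in
#' [simulation_config()]; with `purifying = TRUE`, events at codon positions
#' 1/2 whose result would change the encoded amino acid are rejected.
#' Optional indels (never touching frozen positions, and kept out of the ORF
#' under purifying selection) are recorded together with the true alignment
#' to the ancestor.  Fully reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @return Object of class `simulated_ladder`: `ladder` (an
#'   [ortholog_ladder()] whose reference is the ancestor, age 0), `truth`
#'   with `classes` (per-position `"frozen"`, `"codon_constrained"` or
#'   `"free"`), `frozen_neighbors`, `substitutions` (data.frame: species,
#'   position in ancestral coordinates, from, to, frozen_neighbor,
#'   overlay_class), `alignments` (per species, gapped ancestor/member pair),
#'   and the `config`.
#' @export
simulate_ladder <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$length
  anc_chars <- if (!is.null(config$ancestral_sequence))
    strsplit(config$ancestral_sequence, "", fixed = TRUE)[[1L]]
  else sample(c("G", "C", "A", "T"), L, replace = TRUE,
              prob = c(config$gc / 2, config$gc / 2,
                       (1 - config$gc) / 2, (1 - config$gc) / 2))
  ancestor <- annotated_sequence(paste(anc_chars, collapse = ""),
                                 id = "ancestor",
                                 frame_start = config$frame_start)
  frozen <- config$frozen_positions
  fr_nb <- setdiff(unique(c(frozen - 1L, frozen + 1L)), frozen)
  fr_nb <- fr_nb[fr_nb >= 1L & fr_nb <= L]
  overlay <- if (!is.na(config$frame_start))
    overlay_frame(ancestor, config$frame_start) else NULL
  classes <- rep("free", L)
  if (config$purifying)
    classes[overlay$per_position %in% c("codon_pos1", "codon_pos2")] <-
      "codon_constrained"
  classes[frozen] <- "frozen"

  subs <- list()
  seqs <- list()
  alignments <- list()
  orf_span <- if (config$purifying)
    config$frame_start:(config$frame_start + 3L * overlay$n_codons - 1L)
  else integer()

  for (i in seq_len(nrow(config$ladder))) {
    sp <- config$ladder$name[i]
    t_branch <- config$ladder$divergence_age[i]
    cur <- anc_chars
    n_events <- stats::rpois(L, config$mu * t_branch)
    n_events[frozen] <- 0L
    for (pos in which(n_events > 0L)) {
      for (e in seq_len(n_events[pos])) {
        new <- propose_base(cur[pos], pos %in% fr_nb, config$neighbor_gc_bias)
        if (config$purifying && classes[pos] == "codon_constrained") {
          ci <- overlay$codon_index[pos]
          cstart <- config$frame_start + 3L * (ci - 1L)
          codon <- cur[cstart:(cstart + 2L)]
          trial <- codon
          trial[pos - cstart + 1L] <- new
          if (codon_table()[[paste(codon, collapse = "")]] !=
              codon_table()[[paste(trial, collapse = "")]])
            next  # rejected by purifying selection
        }
        subs[[length(subs) + 1L]] <-
          data.frame(species = sp, position = pos, from = cur[pos], to = new,
                     frozen_neighbor = pos %in% fr_nb,
                     overlay_class = classes[pos], stringsAsFactors = FALSE)
        cur[pos] <- new
      }
    }
    # indels: per-ancestral-position piece strings ("" = deleted,
    # extra characters = insertion after that base)
    pieces <- cur
    if (config$indel_rate > 0) {
      n_indels <- stats::rpois(1L, config$indel_rate * t_branch * L)
      protected <- unique(c(frozen, orf_span))
      for (e in seq_len(n_indels)) {
        len <- sample.int(config$indel_max_len, 1L)
        if (stats::runif(1L) < 0.5) {  # deletion
          cand <- setdiff(seq_len(L), protected)
          if (!length(cand)) next
          s0 <- cand[sample.int(length(cand), 1L)]
          del <- setdiff(s0:min(L, s0 + len - 1L), protected)
          pieces[del] <- ""
        } else {                        # insertion after a position
          s0 <- sample.int(L, 1L)
          ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
          pieces[s0] <- paste0(pieces[s0], ins)
        }
      }
    }
    member <- paste(pieces, collapse = "")
    if (!nzchar(member)) member <- cur[1L]  # degenerate: keep one base
    seqs[[sp]] <- annotated_sequence(member, id = sp)
    # true alignment in ancestral coordinates
    ga <- character(0L); gb <- character(0L)
    for (p in seq_len(L)) {
      piece <- strsplit(pieces[p], "", fixed = TRUE)[[1L]]
      if (length(piece) == 0L) {        # deleted
        ga <- c(ga, anc_chars[p]); gb <- c(gb, "-")
      } else {
        ga <- c(ga, anc_chars[p], rep("-", length(piece) - 1L))
        gb <- c(gb, piece)
      }
    }
    alignments[[sp]] <- list(ancestor = paste(ga, collapse = ""),
                             member = paste(gb, collapse = ""))
  }

  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(species = character(), position = integer(),
               from = character(), to = character(),
               frozen_neighbor = logical(), overlay_class = character(),
               stringsAsFactors = FALSE)
  ladder <- ortholog_ladder(ancestor, seqs,
                            stats::setNames(config$ladder$divergence_age,
                                            config$ladder$name))
  structure(list(ladder = ladder,
                 truth = list(classes = classes,
                              frozen_neighbors = fr_nb,
                              substitutions = subs,
                              alignments = alignments),
                 config = config),
            class = "simulated_ladder")
}

#' @export
print.simulated_ladder <- function(x, ...) {
  cat(sprintf("<simulated_ladder> %d bp ancestor, %d species, %d substitutions recorded\n",
              x$config$length, nrow(x$config$ladder),
              nrow(x$truth$substitutions)))
  invisible(x)
}

#' Ground-truth multiple alignment of a simulated ladder
#'
#' Projects every simulated member onto ancestral coordinates using the
#' simulator's own records (insertions relative to the ancestor are dropped,
#' deletions appear as gaps), yielding a gap-free-reference alignment that
#' lets the conservation stages be exercised without alignment inference.
#'
#' @param simulated a [simulate_ladder()] result.
#' @return A [multiple_alignment()] whose first row is the ancestor.
#' @export
truth_alignment <- function(simulated) {
  stopifnot(inherits(simulated, "simulated_ladder"))
  anc <- simulated$ladder$reference$residues
  rows <- vapply(names(simulated$truth$alignments), function(sp) {
    al <- simulated$truth$alignments[[sp]]
    ga <- strsplit(al$ancestor, "", fixed = TRUE)[[1L]]
    gb <- strsplit(al$member, "", fixed = TRUE)[[1L]]
    paste(gb[ga != "-"], collapse = "")
  }, character(1L))
  multiple_alignment(c("ancestor", names(rows)), c(anc, unname(rows)))
}

#' Recover the neighbor GC bias from a simulated ladder
#'
#' Pools all accepted substitutions at frozen-neighbor sites across branches
#' and estimates beta as the fraction that produced a G or C, with an exact
#' (Clopper-Pearson) binomial confidence interval.
#'
#' @param simulated a [simulate_ladder()] result.
#' @param conf_level confidence level for the interval.
#' @return List: `beta_hat`, `ci` (length 2), `n_gc`, `n` (qualifying
#'   substitutions).
#' @export
recover_beta <- function(simulated, conf_level = 0.95) {
  stopifnot(inherits(simulated, "simulated_ladder"))
  subs <- simulated$truth$substitutions
  qual <- subs[subs$frozen_neighbor, , drop = FALSE]
  if (nrow(qual) == 0L)
    stop("no accepted substitutions at frozen-neighbor sites", call. = FALSE)
  x <- sum(qual$to %in% c("G", "C"))
  n <- nrow(qual)
  bt <- stats::binom.test(x, n, conf.level = conf_level)
  list(beta_hat = x / n, ci = as.numeric(bt$conf.int), n_gc = x, n = n)
}
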
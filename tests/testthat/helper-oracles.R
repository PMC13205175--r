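# Independent oracles used across the suite.  All of them are deliberately
# naive: they re-derive the quantity by direct definition, never by calling
# the code paths they are checking.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Affine-gap global alignment score by memoized three-state recursion over
# (i, j, state).  Gap run of length k costs go + (k - 1) * ge.
oracle_align_score <- function(a, b, match = 5, mismatch = -4,
                               go = 10, ge = 0.5, free_ends = FALSE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  sub <- function(x, y)
    if (x == "N" || y == "N") mismatch else if (x == y) match else mismatch
  E <- function(i, j, s) {
    if (i == 0 && j == 0) return(if (s == "M") 0 else -Inf)
    key <- paste0(i, ",", j, ",", s)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- -Inf
    if (s == "M" && i > 0 && j > 0)
      v <- sub(av[i], bv[j]) +
        max(E(i - 1, j - 1, "M"), E(i - 1, j - 1, "X"), E(i - 1, j - 1, "Y"))
    if (s == "X" && i > 0) {
      open <- if (free_ends && j == 0) 0 else go
      ext <- if (free_ends && j == 0) 0 else ge
      v <- max(E(i - 1, j, "M") - open, E(i - 1, j, "X") - ext,
               E(i - 1, j, "Y") - open)
    }
    if (s == "Y" && j > 0) {
      open <- if (free_ends && i == 0) 0 else go
      ext <- if (free_ends && i == 0) 0 else ge
      v <- max(E(i, j - 1, "M") - open, E(i, j - 1, "X") - open,
               E(i, j - 1, "Y") - ext)
    }
    memo[[key]] <- v
    v
  }
  if (!free_ends)
    return(max(E(n, m, "M"), E(n, m, "X"), E(n, m, "Y")))
  # free trailing gaps: best over the last row / column, at least one
  # aligned column
  best <- -Inf
  for (i in 1:n) best <- max(best, E(i, m, "M"), E(i, m, "X"), E(i, m, "Y"))
  for (j in 1:m) best <- max(best, E(n, j, "M"), E(n, j, "X"), E(n, j, "Y"))
  best
}

# Pure recursive enumeration of every global alignment path (no memo):
# the textbook brute force, feasible only for short pairs.
enum_align_score <- function(a, b, match = 5, mismatch = -4,
                             go = 10, ge = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sub <- function(x, y)
    if (x == "N" || y == "N") mismatch else if (x == y) match else mismatch
  E <- function(i, j, s) {
    if (i == 0 && j == 0) return(if (s == "M") 0 else -Inf)
    v <- -Inf
    if (s == "M" && i > 0 && j > 0)
      v <- sub(av[i], bv[j]) +
        max(E(i - 1, j - 1, "M"), E(i - 1, j - 1, "X"), E(i - 1, j - 1, "Y"))
    if (s == "X" && i > 0)
      v <- max(E(i - 1, j, "M") - go, E(i - 1, j, "X") - ge,
               E(i - 1, j, "Y") - go)
    if (s == "Y" && j > 0)
      v <- max(E(i, j - 1, "M") - go, E(i, j - 1, "X") - go,
               E(i, j - 1, "Y") - ge)
    v
  }
  max(E(length(av), length(bv), "M"), E(length(av), length(bv), "X"),
      E(length(av), length(bv), "Y"))
}

# direct-definition CpG count
naive_cpg <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  if (length(v) < 2) return(0L)
  sum(v[-length(v)] == "C" & v[-1] == "G")
}

# exhaustive tandem-repeat search over all (start, unit) pairs
brute_tandem <- function(s, min_unit, max_mm) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  hits <- list()
  for (u in seq.int(min_unit, length.out = max(0L, n %/% 2L - min_unit + 1L))) {
    for (st in 1:(n - 2 * u + 1)) {
      k <- 1
      while (st + (k + 1) * u - 1 <= n &&
             sum(v[st:(st + u - 1)] !=
                 v[(st + k * u):(st + (k + 1) * u - 1)]) <= max_mm)
        k <- k + 1
      if (k >= 2)
        hits[[length(hits) + 1]] <- data.frame(
          start = st, end = st + k * u - 1,
          unit = paste(v[st:(st + u - 1)], collapse = ""),
          unit_length = u, n_copies = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(NULL)
  tab <- do.call(rbind, hits)
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(nrow(tab)))
      if (j != i && tab$unit_length[j] == tab$unit_length[i] &&
          tab$start[j] <= tab$start[i] && tab$end[j] >= tab$end[i] &&
          (tab$start[j] < tab$start[i] || tab$end[j] > tab$end[i])) {
        keep[i] <- FALSE
        break
      }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$start, tab$unit_length), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# a small simulated ladder used by several tests
demo_ladder <- function(seed = 1, ...) {
  lad <- data.frame(name = paste0("sp", 1:4),
                    divergence_age = c(10, 40, 80, 160))
  simulate_ladder(simulation_config(ladder = lad, seed = seed, ...))
}
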
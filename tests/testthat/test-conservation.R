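exonic <- load_element("exonic_silencer")

test_that("column invariance matches a direct column scan", {
  m <- multiple_alignment(c("r", "s"), c("ACGT", "ACGT"))
  expect_true(all(column_invariance(m)$invariant))

  set.seed(31)
  for (r in 1:60) {
    n <- sample(2:10, 1)
    a <- rand_seq(n, c("A", "C", "G", "T", "N"))
    b <- rand_seq(n, c("A", "C", "G", "T", "N", "-"))
    if (!grepl("[ACGT]", b)) next
    m <- multiple_alignment(c("ref", "oth"), c(a, b))
    prof <- column_invariance(m)
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    expect_equal(prof$invariant,
                 av == bv & av != "N" & bv != "N" & bv != "-",
                 info = paste(a, b))
  }
  expect_error(column_invariance(m, reference = "nope"), "not in alignment")
  expect_error(column_invariance(m, subset = "ref"), "empty species subset")
})

test_that("gaps in the reference are skipped; profile is in element coordinates", {
  m <- multiple_alignment(c("ref", "oth"), c("AC-GT", "ACCGA"))
  prof <- column_invariance(m)
  expect_equal(nrow(prof), 4L)
  expect_equal(prof$base, c("A", "C", "G", "T"))
  expect_equal(prof$invariant, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("ladder-based invariance aligns members to the reference", {
  ref <- annotated_sequence("ACGTACGTAC", "ref")
  lad <- ortholog_ladder(ref,
                         list(near = "ACGTACGTAC", far = "ACGAACGTAC"),
                         c(near = 5, far = 50))
  prof <- column_invariance(lad)
  expect_equal(sum(!prof$invariant), 1L)
  expect_equal(prof$position[!prof$invariant], 4L)
})

test_that("tripartite classification partitions the element", {
  ov <- overlay_frame(exonic, 3)
  # saturated case: everything invariant
  m <- multiple_alignment(c("a", "b"),
                          c(exonic$residues, exonic$residues))
  cls <- classify_bases(column_invariance(m), ov)
  expect_equal(unname(cls$counts["codon_fixed_invariant"]), 24L)
  expect_equal(unname(cls$counts["wobble_invariant"]), 12L)
  expect_equal(unname(cls$counts["pre_orf_invariant"]), 2L)
  expect_equal(sum(cls$counts), 38L)

  set.seed(32)
  for (r in 1:20) {
    n <- sample(6:40, 1)
    a <- rand_seq(n)
    b <- rand_seq(n)
    m <- multiple_alignment(c("a", "b"), c(a, b))
    prof <- column_invariance(m)
    cls <- classify_bases(prof, overlay_frame(a, sample(1:n, 1)))
    expect_equal(sum(cls$counts), n)
    expect_equal(unname(cls$counts["variable"]), sum(!prof$invariant))
  }
  expect_error(classify_bases(column_invariance(m), overlay_frame(exonic, 3)),
               "lengths differ")
})

test_that("classification recovers simulated frozen wobble sites exactly", {
  # freeze only wobble positions; saturating rates mutate everything else
  frozen <- seq(3, 90, by = 9)  # a subset of wobble positions under frame 1
  lad <- data.frame(name = paste0("sp", 1:8),
                    divergence_age = seq(100, 800, by = 100))
  cfg <- simulation_config(ladder = lad, seed = 33, length = 90,
                           frame_start = 1, mu = 0.05,
                           frozen_positions = frozen)
  sim <- simulate_ladder(cfg)
  prof <- column_invariance(truth_alignment(sim), reference = "ancestor")
  cls <- classify_bases(prof, overlay_frame(sim$ladder$reference, 1))
  expect_equal(cls$wobble_invariant_positions, frozen)
  expect_equal(unname(cls$counts["wobble_invariant"]), length(frozen))
})

test_that("neighbor tables list extant flanks of invariant bases", {
  inv <- c(3, 6, 9, 10, 13, 15, 18, 20, 22, 26, 28, 31, 34)
  tab <- neighbor_bias_table(exonic, inv)
  five <- tab[tab$side == "five_prime", ]
  # the published table lists one side per invariant base; its 5' column
  # (G2, C5, C8, C12, C17, G25, G33) must appear among our 5' rows verbatim
  expect_true(all(c("G2", "C5", "C8", "C12", "C17", "G25", "G33") %in%
                    paste0(five$neighbor_base, five$neighbor_position)))
  expect_true(all(tab$neighbor_position %in% c(inv - 1, inv + 1)))
  expect_false(any(tab$neighbor_position %in% inv))
  expect_equal(attr(tab, "n_gc"), sum(tab$is_gc))

  empty <- neighbor_bias_table(exonic, integer())
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_considered"), 0L)

  gc_only <- neighbor_bias_table("GCGCGCGC", c(3, 6))
  expect_equal(attr(gc_only, "gc_fraction"), 1)
  expect_error(neighbor_bias_table(exonic, 99), "outside")
})

test_that("exclude_forced drops neighbors pinned by the amino acid", {
  # TGG ATG GCA: codon 2 (ATG, methionine) is fully forced; mark position 5
  # (its middle base) invariant so both neighbors 4 and 6 are candidates
  s <- annotated_sequence("TGGATGGCA", "toy", frame_start = 1)
  ov <- overlay_frame(s, 1)
  all_rows <- neighbor_bias_table(s, 5, ov, policy = "all")
  expect_equal(nrow(all_rows), 2L)
  expect_false(any(all_rows$excluded))
  strict <- neighbor_bias_table(s, 5, ov, policy = "exclude_forced")
  # position 4 (first base of ATG) is pinned by methionine and excluded;
  # position 6 is a wobble base, which the policy never excludes
  expect_equal(strict$excluded, c(TRUE, FALSE))
  expect_equal(attr(strict, "n_considered"), 1L)
  expect_match(strict$reason[1], "forced by M")
  expect_error(neighbor_bias_table(s, 5, policy = "exclude_forced"),
               "overlay")
})

test_that("invariant runs are maximal, sorted, and match a brute-force scan", {
  set.seed(34)
  for (r in 1:60) {
    n <- sample(1:20, 1)
    inv <- sample(c(TRUE, FALSE), n, replace = TRUE)
    base <- strsplit(rand_seq(n), "")[[1]]
    prof <- structure(data.frame(position = 1:n, base = base,
                                 invariant = inv),
                      reference = "x", n_compared = 1,
                      class = c("conservation_profile", "data.frame"))
    runs <- longest_invariant_runs(prof)
    # oracle: all maximal invariant substrings by direct scan
    expected <- list()
    i <- 1
    while (i <= n) {
      if (inv[i]) {
        j <- i
        while (j < n && inv[j + 1]) j <- j + 1
        expected[[length(expected) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    expect_equal(nrow(runs), length(expected))
    if (length(expected)) {
      got <- runs[order(runs$start), c("start", "end")]
      expect_equal(unname(as.matrix(got)),
                   do.call(rbind, expected), info = paste(inv, collapse = ""))
      # sorted by length desc, ties by 5'-most start
      lens <- runs$end - runs$start + 1
      expect_true(all(diff(lens) <= 0))
      ties <- split(runs$start, lens)
      expect_true(all(vapply(ties, function(s) !is.unsorted(rev(s)) ||
                               !is.unsorted(s), TRUE)))
    }
  }
  # explicit tie: two runs of equal length, 5'-most first
  prof <- structure(data.frame(position = 1:7,
                               base = strsplit("ACGTACG", "")[[1]],
                               invariant = c(TRUE, TRUE, FALSE, FALSE,
                                             TRUE, TRUE, FALSE)),
                    reference = "x", n_compared = 1,
                    class = c("conservation_profile", "data.frame"))
  runs <- longest_invariant_runs(prof)
  expect_equal(runs$start, c(1, 5))
})

test_that("difference counts separate substitutions from indel events", {
  expect_equal(unname(count_differences("ACGTT", "ACGTT")), c(0, 0))
  expect_equal(unname(count_differences("ACGTACGT", "ACGAACG")), c(1, 1))

  # modest divergence: enough substitutions to count, few enough that the
  # optimal alignment stays gapless
  set.seed(35)
  for (r in 1:25) {
    sim <- demo_ladder(seed = 400 + r, length = 60, mu = 0.0006)
    anc <- sim$ladder$reference
    for (i in seq_along(sim$ladder$seqs)) {
      # substitution-only members differ at exactly the changed positions
      member <- sim$ladder$seqs[[i]]
      av <- strsplit(anc$residues, "")[[1]]
      bv <- strsplit(member$residues, "")[[1]]
      expect_equal(unname(count_differences(anc, member)),
                   c(sum(av != bv), 0))
    }
  }
})

test_that("completion calls find the oldest identical ortholog", {
  ref <- load_element("embedded_silencer")
  chars <- strsplit(ref$residues, "")[[1]]
  mutate <- function(v, k) {
    idx <- sample(seq_along(v), k)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  set.seed(36)
  lad <- ortholog_ladder(ref,
                         list(chimp = ref$residues,
                              gorilla = mutate(chars, 4)),
                         c(chimp = 6, gorilla = 9))
  call <- completion_call(lad)
  expect_equal(call$completion_species, "chimp")
  expect_false(call$human_specific)
  expect_equal(call$per_member$n_point_differences[
    call$per_member$name == "gorilla"], 4)

  all_diff <- ortholog_ladder(ref, list(chimp = mutate(chars, 3),
                                        gorilla = mutate(chars, 5)),
                              c(chimp = 6, gorilla = 9))
  expect_true(completion_call(all_diff)$human_specific)

  all_same <- ortholog_ladder(ref, list(chimp = ref$residues,
                                        gorilla = ref$residues),
                              c(chimp = 6, gorilla = 9))
  expect_equal(completion_call(all_same)$completion_species, "gorilla")
})

test_that("completion is monotone under added substitutions", {
  ref <- annotated_sequence("ACGTACGTACGTACGTACGT", "ref")
  chars <- strsplit(ref$residues, "")[[1]]
  one <- chars; one[7] <- "A"
  lad0 <- ortholog_ladder(ref, list(a = ref$residues, b = ref$residues),
                          c(a = 10, b = 50))
  lad1 <- ortholog_ladder(ref, list(a = ref$residues,
                                    b = paste(one, collapse = "")),
                          c(a = 10, b = 50))
  expect_equal(completion_call(lad0)$completion_age, 50)
  expect_equal(completion_call(lad1)$completion_age, 10)
})
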
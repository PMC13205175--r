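test_that("zero mutation rate reproduces the ancestor everywhere", {
  sim <- demo_ladder(seed = 1, length = 50, mu = 0)
  anc <- sim$ladder$reference$residues
  for (s in sim$ladder$seqs) expect_equal(s$residues, anc)
  expect_equal(nrow(sim$truth$substitutions), 0L)
})

test_that("identical config and seed give byte-identical ladders", {
  a <- demo_ladder(seed = 9, length = 80, mu = 0.01,
                   frozen_positions = c(10, 20, 30))
  b <- demo_ladder(seed = 9, length = 80, mu = 0.01,
                   frozen_positions = c(10, 20, 30))
  expect_identical(lapply(a$ladder$seqs, `[[`, "residues"),
                   lapply(b$ladder$seqs, `[[`, "residues"))
  expect_identical(a$truth$substitutions, b$truth$substitutions)
  c <- demo_ladder(seed = 10, length = 80, mu = 0.01,
                   frozen_positions = c(10, 20, 30))
  expect_false(identical(lapply(a$ladder$seqs, `[[`, "residues"),
                         lapply(c$ladder$seqs, `[[`, "residues")))
})

test_that("frozen positions never change", {
  sim <- demo_ladder(seed = 2, length = 60, mu = 0.05,
                     frozen_positions = seq(5, 55, by = 5))
  anc <- strsplit(sim$ladder$reference$residues, "")[[1]]
  for (s in sim$ladder$seqs) {
    v <- strsplit(s$residues, "")[[1]]
    expect_equal(v[seq(5, 55, by = 5)], anc[seq(5, 55, by = 5)])
  }
  expect_false(any(sim$truth$substitutions$position %in% seq(5, 55, by = 5)))
})

test_that("full GC bias saturates frozen-neighbor sites", {
  sim <- demo_ladder(seed = 3, length = 60, mu = 0.2,
                     frozen_positions = seq(3, 57, by = 3),
                     neighbor_gc_bias = 1)
  nb <- sim$truth$frozen_neighbors
  oldest <- sim$ladder$seqs[[which.max(sim$ladder$members$divergence_age)]]
  v <- strsplit(oldest$residues, "")[[1]]
  hit <- unique(sim$truth$substitutions$position[
    sim$truth$substitutions$species == oldest$id &
      sim$truth$substitutions$frozen_neighbor])
  expect_gt(length(hit), 0L)
  expect_true(all(v[hit] %in% c("G", "C")))
  expect_equal(recover_beta(sim)$beta_hat, 1)
})

test_that("substitution counts follow the Poisson expectation", {
  # recorded accepted events at unconstrained sites are Poisson(mu * age)
  # per site; compare the pooled count to its analytic expectation
  lad <- data.frame(name = paste0("sp", 1:10),
                    divergence_age = rep(100, 10))
  cfg <- simulation_config(ladder = lad, seed = 4, length = 300, mu = 0.002)
  sim <- simulate_ladder(cfg)
  n_events <- nrow(sim$truth$substitutions)
  expected <- 10 * 300 * 0.002 * 100   # branches * sites * mu * t = 600
  expect_lt(abs(n_events - expected), 4 * sqrt(expected))
})

test_that("purifying selection admits only synonymous coding changes", {
  lad <- data.frame(name = paste0("sp", 1:5),
                    divergence_age = seq(40, 200, by = 40))
  cfg <- simulation_config(ladder = lad, seed = 5, length = 120,
                           frame_start = 1, mu = 0.02, purifying = TRUE)
  sim <- simulate_ladder(cfg)
  # replay each branch: every accepted change at codon positions 1/2 must
  # preserve the amino acid of its codon at the moment it is applied
  # (wobble changes are free and may legitimately alter the peptide)
  code <- Biostrings::GENETIC_CODE
  n_constrained <- 0L
  for (sp in sim$ladder$members$name) {
    cur <- strsplit(sim$ladder$reference$residues, "")[[1]]
    subs <- sim$truth$substitutions[sim$truth$substitutions$species == sp, ]
    for (k in seq_len(nrow(subs))) {
      pos <- subs$position[k]
      expect_equal(cur[pos], subs$from[k])
      if (subs$overlay_class[k] == "codon_constrained") {
        cstart <- pos - (pos - 1L) %% 3L
        old_codon <- paste(cur[cstart:(cstart + 2L)], collapse = "")
        trial <- cur
        trial[pos] <- subs$to[k]
        new_codon <- paste(trial[cstart:(cstart + 2L)], collapse = "")
        expect_equal(code[[new_codon]], code[[old_codon]],
                     info = paste(sp, pos))
        n_constrained <- n_constrained + 1L
      }
      cur[pos] <- subs$to[k]
    }
    expect_equal(paste(cur, collapse = ""),
                 sim$ladder$seqs[[sp]]$residues)
  }
  expect_gt(n_constrained, 0L)
})

test_that("recovered beta tracks the simulated bias", {
  sim <- demo_ladder(seed = 6, length = 120, mu = 0.03,
                     frozen_positions = seq(2, 119, by = 3),
                     neighbor_gc_bias = 0.9)
  rb <- recover_beta(sim)
  expect_gte(rb$n, 50L)
  expect_true(rb$ci[1] <= 0.9 && 0.9 <= rb$ci[2] ||
                abs(rb$beta_hat - 0.9) < 0.1)

  # an unbiased kernel is clearly distinguishable from strong bias
  flat <- demo_ladder(seed = 7, length = 120, mu = 0.03,
                      frozen_positions = seq(2, 119, by = 3),
                      neighbor_gc_bias = 1 / 3)
  rb_flat <- recover_beta(flat)
  expect_lt(rb_flat$ci[2], 0.9)

  none <- demo_ladder(seed = 8, length = 30, mu = 0)
  expect_error(recover_beta(none), "no accepted")
})

test_that("ground-truth alignments are exact without indels", {
  sim <- demo_ladder(seed = 11, length = 70, mu = 0.02,
                     frozen_positions = c(7, 14, 21))
  msa <- truth_alignment(sim)
  expect_equal(msa$labels[1], "ancestor")
  expect_equal(msa$n_columns, 70L)
  for (i in 2:length(msa$rows))
    expect_equal(msa$rows[i],
                 sim$ladder$seqs[[msa$labels[i]]]$residues)
})

test_that("indels respect frozen positions and the truth alignment", {
  lad <- data.frame(name = c("x", "y"), divergence_age = c(50, 150))
  cfg <- simulation_config(ladder = lad, seed = 12, length = 80, mu = 0.01,
                           frozen_positions = seq(10, 70, by = 10),
                           indel_rate = 2e-4, indel_max_len = 3L)
  sim <- simulate_ladder(cfg)
  msa <- truth_alignment(sim)
  expect_equal(msa$n_columns, 80L)
  anc <- strsplit(sim$ladder$reference$residues, "")[[1]]
  for (i in 2:length(msa$rows)) {
    v <- strsplit(msa$rows[i], "")[[1]]
    expect_equal(v[seq(10, 70, by = 10)], anc[seq(10, 70, by = 10)])
    # projected member re-derives the member sequence minus insertions
    al <- sim$truth$alignments[[msa$labels[i]]]
    ga <- strsplit(al$ancestor, "")[[1]]
    gb <- strsplit(al$member, "")[[1]]
    expect_false(any(ga == "-" & gb == "-"))
    expect_equal(paste(gb[gb != "-"], collapse = ""),
                 sim$ladder$seqs[[msa$labels[i]]]$residues)
  }
})

test_that("configs are validated", {
  lad <- data.frame(name = "a", divergence_age = 10)
  expect_error(simulation_config(ladder = lad, seed = 1), "ancestral_sequence")
  expect_error(simulation_config(ladder = lad, seed = 1, length = 10,
                                 mu = -1), "rates")
  expect_error(simulation_config(ladder = lad, seed = 1, length = 10,
                                 neighbor_gc_bias = 1.5), "neighbor_gc_bias")
  expect_error(simulation_config(ladder = lad, seed = 1, length = 10,
                                 frozen_positions = 99), "out of range")
  expect_error(simulation_config(ladder = lad, seed = 1, length = 10,
                                 purifying = TRUE), "frame_start")
  expect_error(simulation_config(ladder = lad, seed = NULL, length = 10),
               "seed")
})
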
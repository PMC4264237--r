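test_that("amplicon read proportions follow a_i * r_i when delta = 1", {
  ref <- tiny_reference()
  comm <- ref$community
  st <- primer_strategy("beta", ref, mismatch_penalty = 1, chimera_prob = 0,
                        run_efficiency_sd = 0, species_efficiency_sd = 0)
  n <- 20000
  sim <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = n, seed = 3,
                                     error = no_errors())
  m <- comm$members
  p <- m$true_copies_per_ul * m$rrn_copies
  p <- p / sum(p)
  counts <- table(factor(sim$truth$species, levels = m$name))
  # multinomial oracle: every species within 4 sigma
  expect_true(all(abs(counts - n * p) <= 4 * sqrt(n * p * (1 - p)) + 1))
  expect_equal(nrow(sim$reads), n)
  expect_false(any(sim$truth$is_chimera))
})

test_that("mismatch penalty suppresses species by the closed-form weight", {
  ref <- tiny_reference()
  m <- ref$community$members
  st <- primer_strategy("alpha", ref, e_max = 0.2, mismatch_penalty = 0.5,
                        chimera_prob = 0, run_efficiency_sd = 0,
                        species_efficiency_sd = 0)
  sim <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 1, seed = 1)
  # deterministic weights: a * r * (1 + E * delta^m)^35
  delta_m <- 0.5^ifelse(m$subgroup == "gram_positive", 2, 0)
  expected <- m$true_copies_per_ul * m$rrn_copies * (1 + 0.2 * delta_m)^35
  expect_equal(unname(sim$weights), expected, tolerance = 1e-12)
  # relative suppression of mismatched species matches ((1+E/4)/(1+E))^35
  w1 <- simulate_pcr_amplicon_reads(
    ref, strategy = primer_strategy("alpha", ref, e_max = 0.2,
                                    mismatch_penalty = 1, chimera_prob = 0,
                                    run_efficiency_sd = 0,
                                    species_efficiency_sd = 0),
    n_reads = 1, seed = 1)$weights
  gp <- m$subgroup == "gram_positive"
  expect_equal(unname(sim$weights[gp] / w1[gp]),
               rep(((1 + 0.2 * 0.25) / (1 + 0.2))^35, sum(gp)),
               tolerance = 1e-12)
})

test_that("chimeras are emitted at the configured rate with two parents", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0.2)
  sim <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 2000,
                                     seed = 8, error = no_errors())
  tr <- sim$truth
  expect_equal(nrow(tr), 2000)  # truth accounts for every read
  n_chim <- sum(tr$is_chimera)
  expect_gt(n_chim, 2000 * 0.2 - 4 * sqrt(2000 * 0.2 * 0.8))
  expect_lt(n_chim, 2000 * 0.2 + 4 * sqrt(2000 * 0.2 * 0.8))
  expect_true(all(!is.na(tr$parent_a[tr$is_chimera])))
  expect_true(all(tr$parent_a[tr$is_chimera] != tr$parent_b[tr$is_chimera]))
  expect_true(all(is.na(tr$species[tr$is_chimera])))
  expect_true(all(!is.na(tr$species[!tr$is_chimera])))
})

test_that("amplicon simulation is reproducible and conserves read count", {
  ref <- tiny_reference()
  st <- primer_strategy("gamma", ref)
  a <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 500, seed = 9,
                                   error = no_errors())
  b <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 500, seed = 9,
                                   error = no_errors())
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$reads), 500)
  # non-chimeric reads carry the strategy's primer bases at their 5' end
  pre <- substr(a$reads$bases[!a$truth$is_chimera], 1,
                nchar(st$forward_primers[1]))
  expect_true(all(pre %in% st$forward_primers))
})

test_that("error-free WGS reads are exact genome substrings, pairs oriented", {
  ref <- tiny_reference()
  sim <- simulate_wgs_reads(ref, n_read_pairs = 200, error = no_errors(),
                            seed = 4)
  expect_equal(nrow(sim$reads), 400)
  r1 <- sim$reads[sim$reads$pairing == "pair_1", ]
  r2 <- sim$reads[sim$reads$pairing == "pair_2", ]
  sp <- setNames(sim$truth$species, sim$truth$pair_id)
  for (i in seq_len(20)) {
    g <- ref$genomes[[sp[r1$pair_id[i]]]]
    expect_true(grepl(r1$bases[i], g, fixed = TRUE))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(r2$bases[i])))
    expect_true(grepl(rc, g, fixed = TRUE))
  }
})

test_that("WGS species proportions follow a_i * g_i", {
  ref <- tiny_reference()
  m <- ref$community$members
  n <- 20000
  sim <- simulate_wgs_reads(ref, n_read_pairs = n, error = no_errors(),
                            seed = 12)
  p <- m$true_copies_per_ul * m$genome_length
  p <- p / sum(p)
  counts <- table(factor(sim$truth$species, levels = m$name))
  expect_true(all(abs(counts - n * p) <= 4 * sqrt(n * p * (1 - p)) + 1))
})

test_that("the 454-like error model introduces indels at homopolymers", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0)
  err <- error_params(substitution_rate = 0, homopolymer_rate = 0.05,
                      homopolymer_cap = 0.5)
  sim <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 400,
                                     error = err, seed = 21)
  lens <- nchar(sim$reads$bases)
  expect_gt(sum(lens != 337), 0)  # some reads gained/lost bases
  expect_equal(nrow(sim$reads), 400)
  expect_true(all(nchar(sim$reads$bases) == nchar(sim$reads$quals)))
})
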
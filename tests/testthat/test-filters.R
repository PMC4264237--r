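test_that("primer matching applies the 2-mismatch boundary", {
  primer <- "ACGTACGTAC"
  read0 <- paste0(primer, "GGGGG")
  expect_true(match_primer(read0, primer)$match)
  expect_equal(match_primer(read0, primer)$mismatches, 0L)
  mutate_at <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[substr(s, p, p)]
    s
  }
  read2 <- mutate_at(read0, c(2, 5))
  expect_true(match_primer(read2, primer)$match)
  expect_equal(match_primer(read2, primer)$mismatches, 2L)
  read3 <- mutate_at(read0, c(2, 5, 8))
  expect_false(match_primer(read3, primer)$match)
  # N counts as mismatch; over-long primer is a no-match, not an error
  readN <- read0
  substr(readN, 1, 3) <- "NNN"
  expect_equal(match_primer(readN, primer)$mismatches, 3L)
  expect_false(match_primer("ACG", primer)$match)
})

test_that("quality-window trimming matches the exhaustive oracle", {
  # the documented example: good bases then a quality cliff
  bases <- strrep("A", 300)
  quals <- intToUtf8(c(rep(40L, 250), rep(10L, 50)) + 33L)
  tr <- trim_quality_window(bases, quals, window = 50, threshold = 35)
  expect_equal(nchar(tr$bases), trim_oracle(quals, 50, 35))
  # property: random reads, windows, thresholds
  set.seed(99)
  for (i in 1:60) {
    L <- sample(5:300, 1)
    w <- sample(3:60, 1)
    thr <- sample(10:38, 1)
    q <- intToUtf8(sample(2:40, L, replace = TRUE) + 33L)
    b <- random_read(L)
    tr <- trim_quality_window(b, q, window = w, threshold = thr)
    expect_equal(nchar(tr$bases), trim_oracle(q, w, thr))
    expect_equal(tr$bases, substr(b, 1, nchar(tr$bases)))
  }
  # all high quality: unchanged; all low: trimmed to nothing
  expect_equal(nchar(trim_quality_window(bases, const_quals(300, 40))$bases), 300)
  expect_equal(nchar(trim_quality_window(bases, const_quals(300, 2))$bases), 0)
})

test_that("bimera detection flags split reads and spares clean copies", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0)
  parents <- strategy_amplicons(ref, st)
  clean <- detect_bimera(parents[[1]], parents)
  expect_false(clean$is_bimera)
  L <- nchar(parents[[1]])
  chim <- paste0(substr(parents[[1]], 1, L %/% 2),
                 substr(parents[[2]], L %/% 2 + 1, L))
  hit <- detect_bimera(chim, parents)
  expect_true(hit$is_bimera)
  expect_setequal(hit$parents, names(parents)[1:2])
  # two identical candidate parents can never produce a flag
  twins <- c(a = parents[[1]], b = parents[[1]])
  expect_false(detect_bimera(chim, twins)$is_bimera)
})

test_that("the hand-constructed 10-read fixture yields exact per-rule counts", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0)
  parents <- strategy_amplicons(ref, st)
  A <- parents[[1]]; B <- parents[[2]]; C <- parents[[3]]
  L <- nchar(A)  # 337
  q40 <- const_quals(L)
  mutate_at <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[substr(s, p, p)]
    s
  }
  set.seed(1)
  reads <- data.frame(
    id = paste0("fx", 1:10),
    bases = c(
      A,                                               # survivor
      mutate_at(A, c(3, 7, 11)),                       # 3 primer mismatches
      paste0(substr(A, 1, 168), substr(B, 169, L)),    # bimera
      A,                                               # trimmed below 200
      paste0(A, random_read(44)),                      # 381 > 1.1 * 337
      sub("^(.{99})(.)", "\\1N", A),                   # ambiguous base
      paste0(substr(A, 1, 190), "C", strrep("A", 9), "C",
             substr(A, 202, L)),                       # 9-base homopolymer
      B,                                               # survivor
      C,                                               # survivor
      paste0(substr(A, 1, 190), "C", strrep("A", 8), "C",
             substr(A, 201, L))                        # exactly 8: kept
    ),
    quals = c(q40, q40,
              q40,
              intToUtf8(c(rep(40L, 150), rep(10L, L - 150)) + 33L),
              const_quals(L + 44), q40, q40, q40, q40, q40),
    stringsAsFactors = FALSE)
  # guard: the homopolymer constructions really contain runs of 9 and 8
  expect_true(grepl("([ACGT])\\1{8,}", reads$bases[7]))
  expect_false(grepl("([ACGT])\\1{8,}", reads$bases[10]))

  cfg <- amplicon_filter_config(forward_primers = st$forward_primers,
                                expected_amplicon_length = L)
  res <- run_amplicon_filter(reads, cfg, parents = parents)
  expect_equal(unname(res$report$removed),
               c(1L, 1L, 1L, 1L, 1L, 1L))  # one read per failure mode
  expect_equal(res$report$removed[["primer"]], 1L)
  expect_equal(res$report$removed[["chimera"]], 1L)
  expect_equal(res$report$removed[["too_long"]], 1L)
  expect_equal(res$report$removed[["too_short"]], 1L)
  expect_equal(res$report$removed[["ambiguous"]], 1L)
  expect_equal(res$report$removed[["homopolymer"]], 1L)
  expect_equal(res$report$surviving, 4L)
  expect_equal(res$reasons$reason,
               c(NA, "primer", "chimera", "too_short", "too_long",
                 "ambiguous", "homopolymer", NA, NA, NA))
  # attrition conservation and survivor order
  expect_equal(res$report$input,
               res$report$surviving + sum(res$report$removed))
  expect_equal(res$reads$id, c("fx1", "fx8", "fx9", "fx10"))
})

test_that("amplicon filtering conserves attrition and is idempotent", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0.05)
  parents <- strategy_amplicons(ref, st)
  sim <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 600,
                                     error = error_params(), seed = 31)
  cfg <- amplicon_filter_config(forward_primers = st$forward_primers,
                                expected_amplicon_length = 337)
  res <- run_amplicon_filter(sim$reads, cfg, parents = parents)
  expect_equal(res$report$input,
               res$report$surviving + sum(res$report$removed))
  # filtering the survivors again removes nothing
  res2 <- run_amplicon_filter(res$reads, cfg, parents = parents)
  expect_equal(res2$report$surviving, res$report$surviving)
  expect_equal(sum(res2$report$removed), 0L)
  # error-free, chimera-free reads survive in full
  clean <- simulate_pcr_amplicon_reads(
    ref, strategy = primer_strategy("beta", ref, chimera_prob = 0),
    n_reads = 300, error = no_errors(), seed = 5)
  resc <- run_amplicon_filter(clean$reads, cfg, parents = parents)
  expect_equal(resc$report$surviving, 300L)
  # empty input
  empty <- run_amplicon_filter(sim$reads[0, ], cfg, parents = parents)
  expect_equal(empty$report$input, 0L)
  expect_equal(empty$report$surviving, 0L)
})

test_that("WGS filter applies the 30-base and 90% Q30 rules with pair bookkeeping", {
  mk <- function(id, q, pairing = "unpaired", pair_id = id) {
    data.frame(id = id, bases = strrep("A", length(q)),
               quals = intToUtf8(q + 33L), pairing = pairing,
               pair_id = pair_id, stringsAsFactors = FALSE)
  }
  # all Q35: kept
  expect_true(filter_wgs_read(list(bases = strrep("A", 100),
                                   quals = const_quals(100, 35)))$keep)
  # 89/100 bases >= Q30: dropped (below the 90% boundary); 90/100 kept
  r89 <- filter_wgs_read(list(bases = strrep("A", 100),
                              quals = intToUtf8(c(rep(35L, 89), rep(25L, 11)) + 33L)))
  expect_false(r89$keep)
  expect_equal(r89$reason, "low_quality")
  r90 <- filter_wgs_read(list(bases = strrep("A", 100),
                              quals = intToUtf8(c(rep(35L, 90), rep(25L, 10)) + 33L)))
  expect_true(r90$keep)
  # end-trimming below Q20 then too short
  short <- filter_wgs_read(list(bases = strrep("A", 100),
                                quals = intToUtf8(c(rep(35L, 20), rep(5L, 80)) + 33L)))
  expect_false(short$keep)
  expect_equal(short$reason, "too_short")

  # a dropped mate reroutes its partner to the unpaired stream
  reads <- rbind(
    mk("p1/1", rep(35L, 100), "pair_1", "p1"),
    mk("p1/2", rep(5L, 100), "pair_2", "p1"),
    mk("p2/1", rep(35L, 100), "pair_1", "p2"),
    mk("p2/2", rep(35L, 100), "pair_2", "p2"))
  res <- filter_wgs_reads(reads)
  expect_equal(res$report$input, 4L)
  expect_equal(res$report$surviving, 3L)
  expect_equal(res$rerouted_unpaired, 1L)
  expect_equal(res$reads$pairing[res$reads$id == "p1/1"], "unpaired")
  expect_equal(res$reads$pairing[res$reads$id == "p2/1"], "pair_1")
  expect_equal(res$report$input,
               res$report$surviving + sum(res$report$removed))
})
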
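test_that("normalisation divides by copy number or genome size", {
  comm <- community_definition(data.frame(
    name = c("A", "B"), genus = c("gA", "gB"), family = c("fA", "fB"),
    order = c("oA", "oB"), subgroup = c("gram_negative", "gram_positive"),
    genome_length = c(6e6, 2e6), rrn_copies = c(8L, 4L),
    gc_fraction = c(0.5, 0.4), true_copies_per_ul = c(100, 100)))
  # amplicon: counts {800, 400} with r = {8, 4} -> 50/50
  p <- normalize_counts(c(A = 800, B = 400), comm, mode = "rrn_copy_number")
  expect_equal(p$percent, c(50, 50))
  expect_equal(p$normalized, c(100, 100))
  # WGS: counts {600, 200} with g = {6 Mb, 2 Mb} -> 50/50
  p2 <- normalize_counts(c(A = 600, B = 200), comm, mode = "genome_size")
  expect_equal(p2$percent, c(50, 50))
  # mode "none" leaves proportions raw
  p3 <- normalize_counts(c(A = 600, B = 200), comm, mode = "none")
  expect_equal(p3$percent, c(75, 25))
  expect_equal(sum(p3$percent), 100, tolerance = 1e-9)
  # identical copy numbers cancel
  comm2 <- comm; comm2$members$rrn_copies <- c(4L, 4L)
  p4 <- normalize_counts(c(A = 300, B = 100), comm2, mode = "rrn_copy_number")
  expect_equal(p4$percent, c(75, 25))
  # absent species appear with explicit zeros
  p5 <- normalize_counts(c(A = 10), comm, mode = "none")
  expect_equal(p5$percent[p5$species == "B"], 0)
  expect_error(normalize_counts(c(A = 1, Zed = 2), comm, mode = "none"),
               "Zed")
  expect_error(normalize_counts(c(A = 0, B = 0), comm, mode = "none"),
               "all counts are zero")
})

test_that("profiles always sum to 100 percent", {
  comm <- tiny_community()
  set.seed(3)
  for (i in 1:20) {
    counts <- setNames(rpois(nrow(comm$members), 50) + c(1, rep(0, 3)),
                       comm$members$name)
    for (mode in c("rrn_copy_number", "genome_size", "none")) {
      expect_equal(sum(normalize_counts(counts, comm, mode)$percent), 100,
                   tolerance = 1e-9)
    }
  }
})

test_that("plasmid hits are excluded before normalisation", {
  counts <- data.frame(
    reference = c("chrA", "plasA", "chrB", "plasC"),
    species = c("A", "A", "B", "C"),
    type = c("chromosome", "plasmid", "chromosome", "plasmid"),
    count = c(100, 40, 70, 9))
  out <- exclude_plasmid_hits(counts)
  expect_equal(out[["A"]], 100)
  expect_equal(out[["B"]], 70)
  expect_equal(out[["C"]], 0)  # all hits plasmid: present with count 0
  expect_equal(attr(out, "excluded_plasmid_hits"), 49)
  # unlabeled references are chromosome, with a warning
  counts$type[3] <- NA
  expect_warning(out2 <- exclude_plasmid_hits(counts), "unlabelled")
  expect_equal(out2[["B"]], 70)
  # no plasmids: identity
  clean <- counts[c(1, 3), ]; clean$type <- "chromosome"
  expect_equal(unname(exclude_plasmid_hits(clean)[c("A", "B")]), c(100, 70))
})

test_that("Poisson correction converts positive partitions to molecules", {
  panel <- list(positive = 385L, n_partitions = 770L,
                partition_volume_nl = 0.84, dilution_factor = 4 / 1.2)
  est <- dpcr_estimate(panel)
  expect_equal(est$lambda, log(2), tolerance = 1e-12)
  expect_equal(est$molecules, -770 * log(0.5), tolerance = 1e-12)
  expect_equal(est$molecules, 533.72332903115785, tolerance = 1e-10)
  # concentration bookkeeping: molecules / (N * Vp) * D
  expect_equal(est$concentration,
               est$molecules / (770 * 0.84e-3) * (4 / 1.2), tolerance = 1e-12)
  expect_true(est$molecules_ci[1] <= est$molecules &&
                est$molecules <= est$molecules_ci[2])
  # k = 0 and saturation
  panel0 <- panel; panel0$positive <- 0L
  expect_equal(dpcr_estimate(panel0)$molecules, 0)
  sat <- panel; sat$positive <- 770L
  expect_error(dpcr_estimate(sat), "saturated")
  over <- panel; over$positive <- 771L
  expect_error(dpcr_estimate(over), "exceeds")
  # monotone increasing in k
  mols <- vapply(c(10L, 100L, 385L, 700L), function(k) {
    p <- panel; p$positive <- k; dpcr_estimate(p)$molecules
  }, numeric(1))
  expect_true(all(diff(mols) > 0))
})

test_that("replicate dPCR aggregation uses the t interval", {
  res <- lapply(c(90, 100, 110), function(x) list(concentration = x))
  agg <- aggregate_dpcr(res)
  expect_equal(agg$mean_concentration, 100)
  expect_equal(agg$ci, 100 + c(-1, 1) * 24.841377117503299, tolerance = 1e-10)
  # identical replicates: zero-width interval
  same <- aggregate_dpcr(lapply(rep(50, 3), function(x) list(concentration = x)))
  expect_equal(same$ci, c(50, 50))
  # single replicate: point estimate only
  one <- aggregate_dpcr(list(list(concentration = 42)))
  expect_false(one$ci_available)
  expect_equal(one$mean_concentration, 42)
})
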
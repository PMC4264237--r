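test_that("k-mer scoring matches the naive set-intersection oracle", {
  set.seed(17)
  ref <- random_read(2000)
  for (i in 1:20) {
    read <- random_read(300)
    expect_equal(score_read(read, ref, k = 12),
                 max(kmer_score_oracle(read, ref, 12),
                     kmer_score_oracle(mcmbench:::revcomp(read), ref, 12)))
  }
  # a read lifted from the reference scores maximally
  sub <- substr(ref, 101, 400)
  expect_equal(score_read(sub, ref, k = 12), 300 - 12 + 1)
  # and so does its reverse complement
  expect_equal(score_read(mcmbench:::revcomp(sub), ref, k = 12), 289)
  # disjoint sequences score 0; short reads score 0
  expect_equal(score_read(strrep("A", 50), strrep("C", 500), k = 12), 0)
  expect_equal(score_read("ACGT", ref, k = 12), 0L)
})

test_that("top-hit retention keeps scores within 1% of the maximum", {
  hits <- data.frame(ref = c("a", "b", "c"), score = c(100, 99.5, 98))
  kept <- retain_top_hits(hits, top_fraction = 0.01)
  expect_equal(kept$ref, c("a", "b"))
  expect_equal(nrow(retain_top_hits(hits[1, , drop = FALSE])), 1)
  ties <- data.frame(ref = letters[1:4], score = rep(7, 4))
  expect_equal(nrow(retain_top_hits(ties)), 4)
  expect_equal(nrow(retain_top_hits(hits[0, , drop = FALSE])), 0)
})

test_that("LCA agrees with the ancestor-path-intersection oracle", {
  ref <- tiny_reference()
  tax <- ref$taxonomy
  # two congeneric species resolve to their genus
  sp <- ref$record_nodes[c("Species_a", "Species_b")]
  genus <- tax$node_id[tax$rank == "genus" & tax$name == "GenusA"]
  expect_equal(lca(unname(sp), tax), genus)
  expect_equal(lca(unname(sp[1]), tax), unname(sp[1]))
  # random node sets over random trees
  for (s in 1:40) {
    rt <- random_taxonomy(20, seed = s)
    set.seed(s + 1000)
    nodes <- sample(rt$node_id, sample(2:6, 1))
    expect_equal(lca(nodes, rt), lca_oracle(nodes, rt))
  }
  expect_error(lca(c(1, 999), tax), "not in taxonomy")
})

test_that("error-free reads are assigned to their source species exactly", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0)
  sim <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 400,
                                     error = no_errors(), seed = 6)
  asg <- assign_reads(sim$reads, ref, db = "genes", min_support = 1)
  merged <- merge(asg$per_read, sim$truth, by = "read_id")
  expect_equal(merged$taxon, merged$species)
  expect_equal(asg$n_unassigned, 0L)
})

test_that("minimum support gates taxon calls at the boundary", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0)
  amp <- strategy_amplicons(ref, st)
  # 20 reads of species a, exactly 5 of b, exactly 4 of c
  bases <- c(rep(amp[["Species_a"]], 20), rep(amp[["Species_b"]], 5),
             rep(amp[["Species_c"]], 4))
  asg <- assign_reads(bases, ref, db = "genes", min_support = 5)
  called <- called_counts(asg)
  expect_true("Species_b" %in% names(called))   # exactly 5: called
  expect_false("Species_c" %in% names(called))  # exactly 4: suppressed
  # suppressed reads are unassigned at the reporting rank
  expect_equal(sum(is.na(asg$per_read$taxon)), 4)
  # lowering min_support never decreases the number of called taxa
  n_called <- vapply(c(10, 5, 4, 1), function(ms) {
    sum(assign_reads(bases, ref, db = "genes", min_support = ms)$counts$called)
  }, integer(1))
  expect_true(all(diff(n_called) >= 0))
})

test_that("taxon counts respect the rank hierarchy", {
  ref <- tiny_reference()
  st <- primer_strategy("beta", ref, chimera_prob = 0.1)
  sim <- simulate_pcr_amplicon_reads(ref, strategy = st, n_reads = 500,
                                     error = error_params(), seed = 44)
  asg <- assign_reads(sim$reads, ref, db = "genes", min_support = 1)
  tax <- ref$taxonomy
  # reads assigned at or below a node, counted via ancestor paths
  count_at <- function(node) {
    sum(vapply(asg$per_read$node_id, function(nd) {
      !is.na(nd) && node %in% ancestor_path_for_test(nd, tax)
    }, logical(1)))
  }
  for (node in tax$node_id[tax$rank %in% c("genus", "family")]) {
    kids <- tax$node_id[!is.na(tax$parent_id) & tax$parent_id == node]
    if (!length(kids)) next
    expect_gte(count_at(node), sum(vapply(kids, count_at, numeric(1))))
  }
})

test_that("WGS reads resolve to species; shared 16S regions go up the tree", {
  ref <- tiny_reference()
  sim <- simulate_wgs_reads(ref, n_read_pairs = 300, error = no_errors(),
                            seed = 15)
  asg <- assign_reads(sim$reads, ref, db = "genomes", min_support = 1)
  asg$per_read$pair_id <- sub("/[12]$", "", asg$per_read$read_id)
  merged <- merge(asg$per_read, sim$truth, by = "pair_id")
  sp_level <- !is.na(merged$taxon)
  # species-level assignments are always correct
  expect_true(all(merged$taxon[sp_level] == merged$species[sp_level]))
  # and nearly all reads are species-level (only reads wholly inside a
  # conserved 16S stretch can float upward)
  expect_gt(mean(sp_level), 0.98)
})
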
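# Shared fixtures: a small synthetic community for fast unit tests and a
# cached desk-scale MCM-like reference for pipeline tests.

tiny_community <- function(n = 4) {
  genera <- c("GenusA", "GenusA", "GenusB", "GenusC", "GenusD", "GenusE")
  families <- c("FamilyA", "FamilyA", "FamilyA", "FamilyC", "FamilyD", "FamilyE")
  orders <- c("OrderA", "OrderA", "OrderA", "OrderA", "OrderD", "OrderE")
  members <- data.frame(
    name = paste0("Species_", head(letters, n)),
    genus = head(genera, n), family = head(families, n),
    order = head(orders, n),
    subgroup = rep(c("gram_negative", "gram_positive"), length.out = n),
    genome_length = seq(20000, 20000 + 5000 * (n - 1), by = 5000),
    rrn_copies = rep(c(4L, 7L, 5L, 8L, 6L, 4L), length.out = n),
    gc_fraction = rep(c(0.45, 0.55, 0.35, 0.6, 0.5, 0.4), length.out = n),
    true_copies_per_ul = rep(c(10000, 3000, 800, 200, 5000, 1500),
                             length.out = n),
    stringsAsFactors = FALSE)
  community_definition(members, name = "tiny", version = "test")
}

tiny_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reference(tiny_community(), seed = 42)
    cache
  }
})

# Desk-scale MCM-like community: genomes at 1% of full size, which leaves
# every relative abundance unchanged.
scaled_mcm <- function() mcm_community(genome_scale = 0.01)

mcm_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reference(scaled_mcm(), seed = 101)
    cache
  }
})

ancestor_path_for_test <- function(node, taxonomy) {
  path <- integer(0)
  while (!is.na(node)) {
    path <- c(node, path)
    node <- taxonomy$parent_id[match(node, taxonomy$node_id)]
  }
  path
}

# Brute-force LCA oracle: intersect full ancestor sets, return the deepest
# common one.
lca_oracle <- function(nodes, taxonomy) {
  anc_set <- function(n) {
    out <- integer(0)
    while (!is.na(n)) {
      out <- c(out, n)
      n <- taxonomy$parent_id[match(n, taxonomy$node_id)]
    }
    out
  }
  common <- Reduce(intersect, lapply(unique(nodes), anc_set))
  depths <- vapply(common, function(n) length(anc_set(n)), integer(1))
  common[which.max(depths)]
}

# Random rooted tree as a taxonomy table (node 1 is the root).
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  parent <- c(NA_integer_,
              vapply(2:n_nodes, function(i) sample.int(i - 1, 1), integer(1)))
  data.frame(node_id = seq_len(n_nodes), parent_id = parent,
             rank = c("root", rep("clade", n_nodes - 1)),
             name = paste0("n", seq_len(n_nodes)), stringsAsFactors = FALSE)
}

# Exhaustive sliding-window trim oracle: first window (1-base steps) whose
# mean quality is strictly below the threshold.
trim_oracle <- function(quals, window, threshold) {
  q <- utf8ToInt(quals) - 33L
  L <- length(q)
  if (L == 0) return(0L)
  if (L < window) return(if (mean(q) < threshold) 0L else L)
  for (i in 1:(L - window + 1)) {
    if (mean(q[i:(i + window - 1)]) < threshold) return(i - 1L)
  }
  L
}

# Naive distinct-shared-k-mer score oracle (forward orientation only).
kmer_score_oracle <- function(read, ref, k) {
  rk <- unique(substring(read, 1:(nchar(read) - k + 1), k:nchar(read)))
  fk <- unique(substring(ref, 1:(nchar(ref) - k + 1), k:nchar(ref)))
  sum(rk %in% fk)
}

random_read <- function(length, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

const_quals <- function(n, q = 40) {
  intToUtf8(rep(q + 33L, n))
}
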
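# Read simulators.
#
# Amplicon reads follow a deterministic exponential PCR-bias model: species i
# is amplified with per-cycle efficiency E (jittered per run and per species)
# attenuated by delta^m_i for m_i primer mismatches, so over C cycles its
# amplification weight is
#
#     w_i = a_i * r_i * (1 + E_i * delta^m_i)^C
#
# (a_i genome copies/uL, r_i rrn copies per genome). Reads are drawn
# multinomially with probabilities w_i / sum(w_j); chimeric (bimera) reads
# are formed with probability pi_chim by joining the prefix of one parent
# amplicon to the suffix of another at a uniform interior breakpoint.
# WGS read pairs are drawn from species proportional to a_i * g_i with
# uniform genome positions, mate 2 reverse-complemented.

#' Sequencing error model parameters
#'
#' The pyrosequencing-like amplicon model applies a constant per-base
#' substitution rate plus homopolymer-length-dependent indels with
#' probability `min(homopolymer_rate * (L - 1), homopolymer_cap)` for a run
#' of length L (longer runs are more error-prone, the classic 454 failure
#' mode). Per-base qualities decay linearly from `quality_start` to
#' `quality_end` with per-read level jitter (`read_quality_sd`) and
#' per-base noise (`base_quality_sd`), so simulated reads genuinely
#' exercise the sliding-window quality filters.
#'
#' @param substitution_rate Per-base substitution probability.
#' @param homopolymer_rate Per-run indel rate slope (per unit run length).
#' @param homopolymer_cap Upper bound on the per-run indel probability.
#' @param quality_start,quality_end Mean Phred quality at read start/end.
#' @param read_quality_sd SD of the per-read quality offset.
#' @param base_quality_sd SD of per-base quality noise.
#' @return A list of class `error_params`.
#' @export
error_params <- function(substitution_rate = 0.004, homopolymer_rate = 0.003,
                         homopolymer_cap = 0.03, quality_start = 40,
                         quality_end = 36, read_quality_sd = 2,
                         base_quality_sd = 3) {
  stopifnot(substitution_rate >= 0, homopolymer_rate >= 0)
  structure(list(substitution_rate = substitution_rate,
                 homopolymer_rate = homopolymer_rate,
                 homopolymer_cap = homopolymer_cap,
                 quality_start = quality_start, quality_end = quality_end,
                 read_quality_sd = read_quality_sd,
                 base_quality_sd = base_quality_sd),
            class = "error_params")
}

#' Error-free, noise-free error model
#' @return An `error_params` object with all rates and noise set to zero.
#' @export
no_errors <- function() {
  error_params(substitution_rate = 0, homopolymer_rate = 0,
               quality_start = 40, quality_end = 40,
               read_quality_sd = 0, base_quality_sd = 0)
}

#' Define a primer strategy
#'
#' The four strategies are modelled by their mismatch structure against the
#' two Gram subgroups, not by literal primer sequences:
#' \describe{
#'   \item{alpha}{single V1-V2 primer pair perfectly matching the
#'     Gram-negative conserved regions; `mismatches` mismatches (default 2)
#'     against Gram-positive templates. All products carry the
#'     Gram-negative primer bases.}
#'   \item{beta}{mix of subgroup-specific V1-V2 primers; zero mismatches for
#'     every species, products carry their own subgroup's primer variant.}
#'   \item{gamma}{degenerate V4-V6 primers covering both subgroup variants;
#'     zero mismatches, products carry their own variant.}
#'   \item{delta}{single cross-priming V4-V6 primer pair (T:G wobble);
#'     zero effective mismatches, all products carry the same primer bases.}
#' }
#'
#' @param label One of `"alpha"`, `"beta"`, `"gamma"`, `"delta"`.
#' @param ref A [build_reference()] result supplying the conserved-region
#'   sequences the primers bind.
#' @param e_max Maximum per-cycle amplification efficiency in (0, 1].
#'   Because the deterministic weight `(1 + E * delta^m)^C` applies one
#'   fixed efficiency across all `cycles` cycles, `e_max` is an effective
#'   whole-reaction average (plateau phase included) rather than an
#'   early-cycle efficiency; the default 0.12 keeps mismatched species
#'   detectable (~7-fold depressed at 2 mismatches) while making their
#'   share strongly sensitive to run-to-run efficiency jitter, the
#'   mechanism behind the alpha strategy's excess replicate variance.
#' @param mismatch_penalty Efficiency attenuation per mismatch, `delta` in
#'   (0, 1]; effective efficiency is `e * delta^m_i`.
#' @param cycles Number of PCR cycles (default 35).
#' @param chimera_prob Per-read probability of emitting a bimera.
#' @param mismatches Mismatch count for the alpha strategy on Gram-positive
#'   templates (default 2).
#' @param run_efficiency_sd SD of the per-replicate-run efficiency jitter
#'   shared by all species (drives the alpha strategy's excess
#'   run-to-run variance on mismatched species).
#' @param species_efficiency_sd SD of independent per-species, per-run
#'   efficiency jitter (generic PCR stochasticity affecting every
#'   strategy).
#' @return A list of class `primer_strategy`.
#' @export
primer_strategy <- function(label = c("alpha", "beta", "gamma", "delta"),
                            ref, e_max = 0.12, mismatch_penalty = 0.7,
                            cycles = 35, chimera_prob = 0.01, mismatches = 2,
                            run_efficiency_sd = 0.03,
                            species_efficiency_sd = 0.005) {
  label <- match.arg(label)
  stopifnot(inherits(ref, "reference_set"), e_max > 0, e_max <= 1,
            mismatch_penalty > 0, mismatch_penalty <= 1, cycles >= 1,
            chimera_prob >= 0, chimera_prob < 1)
  members <- ref$community$members
  region <- if (label %in% c("alpha", "beta")) "V12" else "V456"
  m <- setNames(rep(0L, nrow(members)), members$name)
  if (label == "alpha") {
    m[members$subgroup == "gram_positive"] <- as.integer(mismatches)
  }
  flank <- if (region == "V12") c("C1", "C2") else c("C3", "C4")
  # which conserved variant each species' PCR product carries at its ends
  product_subgroup <- switch(label,
    alpha = setNames(rep("gram_negative", nrow(members)), members$name),
    delta = setNames(rep("gram_negative", nrow(members)), members$name),
    beta = setNames(members$subgroup, members$name),
    gamma = setNames(members$subgroup, members$name))
  variants <- unique(product_subgroup)
  forward_primers <- vapply(variants, function(sg) ref$conserved[[sg]][flank[1]], "")
  reverse_primers <- vapply(variants, function(sg) revcomp(ref$conserved[[sg]][flank[2]]), "")
  structure(list(label = label, region = region, mismatches = m,
                 e_max = e_max, mismatch_penalty = mismatch_penalty,
                 cycles = cycles, chimera_prob = chimera_prob,
                 run_efficiency_sd = run_efficiency_sd,
                 species_efficiency_sd = species_efficiency_sd,
                 product_subgroup = product_subgroup,
                 forward_primers = unname(forward_primers),
                 reverse_primers = unname(reverse_primers),
                 flank = flank,
                 expected_amplicon_length = unname(ref$amplicon_lengths[region])),
            class = "primer_strategy")
}

#' PCR product sequences of a strategy
#'
#' The per-species amplicon a strategy produces: the strategy's primer
#' bases flanking the species' own variable region.
#'
#' @param ref A [build_reference()] result.
#' @param strategy A [primer_strategy()].
#' @return Named character vector, one amplicon per species.
#' @export
strategy_amplicons <- function(ref, strategy) {
  members <- ref$community$members
  vapply(members$name, function(sp) {
    sg <- strategy$product_subgroup[sp]
    paste0(ref$conserved[[sg]][strategy$flank[1]],
           ref$variable[[strategy$region]][sp],
           ref$conserved[[sg]][strategy$flank[2]])
  }, "")
}

#' Simulate amplicon sequencing reads under a primer strategy
#'
#' @param ref A [build_reference()] result.
#' @param community A [community_definition()]; defaults to the one inside
#'   `ref`.
#' @param strategy A [primer_strategy()].
#' @param n_reads Number of reads to emit (all are emitted; filtering is a
#'   downstream concern).
#' @param error An [error_params()] model.
#' @param seed Integer seed.
#' @return A list with `reads` (data.frame: id, bases, quals, pairing),
#'   `truth` (data.frame: read_id, species, is_chimera, parent_a,
#'   parent_b), `weights` (realised amplification weights) and `params`.
#' @export
simulate_pcr_amplicon_reads <- function(ref, community = ref$community,
                                        strategy, n_reads,
                                        error = error_params(), seed = 1) {
  stopifnot(inherits(strategy, "primer_strategy"), n_reads > 0)
  members <- community$members
  if (nrow(members) == 0) stop("empty community", call. = FALSE)
  set.seed(seed)

  amplicons <- strategy_amplicons(ref, strategy)
  e_run <- strategy$e_max + rnorm(1, 0, strategy$run_efficiency_sd)
  e_i <- e_run + rnorm(nrow(members), 0, strategy$species_efficiency_sd)
  e_i <- pmin(pmax(e_i, 0.01), 1)
  delta_m <- strategy$mismatch_penalty^strategy$mismatches[members$name]
  w <- members$true_copies_per_ul * members$rrn_copies *
    (1 + e_i * delta_m)^strategy$cycles
  prob <- w / sum(w)

  is_chim <- runif(n_reads) < strategy$chimera_prob
  n_chim <- sum(is_chim)
  species <- rep(NA_character_, n_reads)
  species[!is_chim] <- sample(members$name, n_reads - n_chim, replace = TRUE,
                              prob = prob)
  bases <- character(n_reads)
  bases[!is_chim] <- amplicons[species[!is_chim]]
  parent_a <- parent_b <- rep(NA_character_, n_reads)
  if (n_chim > 0) {
    L <- strategy$expected_amplicon_length
    for (j in which(is_chim)) {
      par <- sample(members$name, 2, replace = FALSE, prob = prob)
      b <- sample(seq(25, L - 25), 1)  # uniform over the amplicon interior
      bases[j] <- paste0(substr(amplicons[par[1]], 1, b),
                         substr(amplicons[par[2]], b + 1, L))
      parent_a[j] <- par[1]; parent_b[j] <- par[2]
    }
  }

  bases <- apply_sequencing_errors(bases, error)
  quals <- simulate_qualities(nchar(bases), error)
  ids <- sprintf("amp_%06d", seq_len(n_reads))
  list(
    reads = data.frame(id = ids, bases = bases, quals = quals,
                       pairing = "unpaired", stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, species = species,
                       is_chimera = is_chim, parent_a = parent_a,
                       parent_b = parent_b, stringsAsFactors = FALSE),
    weights = setNames(w, members$name),
    params = list(strategy = strategy$label, n_reads = n_reads, seed = seed,
                  efficiencies = setNames(e_i, members$name))
  )
}

#' Simulate paired-end whole-genome shotgun reads
#'
#' Read pairs are drawn from species with probability proportional to
#' `a_i * g_i` (copies x genome length), fragment positions uniform over
#' the genome, mate 2 reverse-complemented from the fragment end.
#'
#' @param ref A [build_reference()] result.
#' @param community A [community_definition()]; defaults to the one in `ref`.
#' @param n_read_pairs Number of pairs (2 reads each).
#' @param read_length Read length in bp (default 100).
#' @param insert_mean,insert_sd Fragment-length distribution; inserts are
#'   clamped to `[2 * read_length + 10, genome length]`.
#' @param error An [error_params()] model (defaults to an Illumina-like
#'   substitution-only model).
#' @param seed Integer seed.
#' @return A list with `reads` (data.frame: id, bases, quals, pairing,
#'   pair_id; mates interleaved), `truth` (pair_id, species) and `params`.
#' @export
simulate_wgs_reads <- function(ref, community = ref$community, n_read_pairs,
                               read_length = 100, insert_mean = 300,
                               insert_sd = 30,
                               error = error_params(substitution_rate = 0.001,
                                                    homopolymer_rate = 0,
                                                    quality_start = 38,
                                                    quality_end = 34,
                                                    read_quality_sd = 2.5,
                                                    base_quality_sd = 2),
                               seed = 1) {
  stopifnot(n_read_pairs > 0, read_length >= 20)
  members <- community$members
  if (any(read_length > members$genome_length)) {
    stop("read_length exceeds a genome length", call. = FALSE)
  }
  set.seed(seed)
  w <- members$true_copies_per_ul * members$genome_length
  species <- sample(members$name, n_read_pairs, replace = TRUE, prob = w / sum(w))
  g_len <- setNames(members$genome_length, members$name)[species]
  ins <- pmin(pmax(round(rnorm(n_read_pairs, insert_mean, insert_sd)),
                   2 * read_length + 10), g_len)
  start <- floor(runif(n_read_pairs, 1, g_len - ins + 2))
  genome <- setNames(ref$genomes, members$name)
  r1 <- r2 <- character(n_read_pairs)
  for (sp in unique(species)) {
    m <- species == sp
    r1[m] <- substring(genome[sp], start[m], start[m] + read_length - 1)
    r2[m] <- revcomp(substring(genome[sp], start[m] + ins[m] - read_length,
                               start[m] + ins[m] - 1))
  }
  r1 <- apply_sequencing_errors(r1, error)
  r2 <- apply_sequencing_errors(r2, error)
  q1 <- simulate_qualities(nchar(r1), error)
  q2 <- simulate_qualities(nchar(r2), error)
  pair_id <- sprintf("wgs_%06d", seq_len(n_read_pairs))
  reads <- data.frame(
    id = as.vector(rbind(paste0(pair_id, "/1"), paste0(pair_id, "/2"))),
    bases = as.vector(rbind(r1, r2)),
    quals = as.vector(rbind(q1, q2)),
    pairing = rep(c("pair_1", "pair_2"), n_read_pairs),
    pair_id = rep(pair_id, each = 2),
    stringsAsFactors = FALSE)
  list(reads = reads,
       truth = data.frame(pair_id = pair_id, species = species,
                          stringsAsFactors = FALSE),
       params = list(n_read_pairs = n_read_pairs, read_length = read_length,
                     seed = seed))
}

# Apply substitutions and homopolymer-scaling indels to a character vector
# of sequences. Assumes the RNG is already seeded by the caller.
apply_sequencing_errors <- function(seqs, error) {
  n_sub <- if (error$substitution_rate > 0) {
    rbinom(length(seqs), nchar(seqs), error$substitution_rate)
  } else {
    integer(length(seqs))
  }
  for (j in which(n_sub > 0)) {
    ch <- strsplit(seqs[j], "")[[1]]
    pos <- sample(length(ch), n_sub[j])
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    seqs[j] <- paste(ch, collapse = "")
  }
  if (error$homopolymer_rate > 0) {
    # run structure is shared by identical sequences; compute it once each
    uniq <- unique(seqs)
    idx <- match(seqs, uniq)
    runs <- lapply(uniq, function(s) {
      r <- rle(strsplit(s, "")[[1]])
      ends <- cumsum(r$lengths)
      keep <- r$lengths >= 2
      list(start = (ends - r$lengths + 1)[keep], len = r$lengths[keep],
           base = r$values[keep],
           p = pmin(error$homopolymer_rate * (r$lengths[keep] - 1),
                    error$homopolymer_cap))
    })
    for (j in seq_along(seqs)) {
      ri <- runs[[idx[j]]]
      if (!length(ri$p)) next
      hit <- which(runif(length(ri$p)) < ri$p)
      if (!length(hit)) next
      ch <- strsplit(seqs[j], "")[[1]]
      for (h in rev(hit)) {  # right-to-left so positions stay valid
        if (runif(1) < 0.5) {
          ch <- append(ch, ri$base[h], after = ri$start[h])   # insertion
        } else {
          ch <- ch[-ri$start[h]]                              # deletion
        }
      }
      seqs[j] <- paste(ch, collapse = "")
    }
  }
  seqs
}

# Per-read Phred quality strings: linear decay + read-level and base-level
# noise, clamped to [2, 40].
simulate_qualities <- function(lengths, error) {
  vapply(lengths, function(L) {
    if (L == 0) return("")
    prof <- seq(error$quality_start, error$quality_end, length.out = L)
    shift <- rnorm(1, 0, error$read_quality_sd)
    q <- round(prof + shift + rnorm(L, 0, error$base_quality_sd))
    int_to_quals(as.integer(pmin(pmax(q, 2), 40)))
  }, "")
}
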
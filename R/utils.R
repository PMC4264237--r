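# Shared internal helpers: constants, DNA string utilities, seed derivation.

AVOGADRO <- 6.02214076e23
BP_MOLAR_MASS <- 650  # g/mol per double-stranded base pair, standard average

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA string with a given expected GC fraction.
random_dna <- function(length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

# Random DNA whose single-base runs never exceed max_run. Used for gene
# regions so that true reference sequences cannot trip homopolymer-based
# artifact filters: runs are capped at 4 per region, so even a run
# spanning a region boundary cannot exceed 8.
random_dna_norun <- function(length, gc = 0.5, max_run = 4) {
  ch <- strsplit(random_dna(length, gc), "")[[1]]
  repeat {
    r <- rle(ch)
    bad <- which(r$lengths > max_run)
    if (!length(bad)) break
    ends <- cumsum(r$lengths)
    for (b in bad) {
      start <- ends[b] - r$lengths[b] + 1
      fix <- seq(start + max_run, ends[b], by = max_run + 1)
      for (p in fix) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    }
  }
  paste(ch, collapse = "")
}

# Reverse complement of one or more DNA strings (IUPAC-aware via Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages of the package draw their own seed from the master
#' seed plus a stage/replicate index path through this linear-congruential
#' mix, so that every simulated artefact is reproducible and independent
#' stages do not share random streams. The result is always a positive
#' 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param ... Integer indices identifying the stage (e.g. strategy number,
#'   replicate number).
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483563
  for (i in seq_along(idx)) {
    h <- (h * 69069 + as.double(idx[i]) * 40014 + i) %% 2147483563
  }
  as.integer(h) + 1L
}

quals_to_int <- function(q) utf8ToInt(q) - 33L

int_to_quals <- function(q) intToUtf8(pmin(pmax(q, 0L), 60L) + 33L)

# Distinct k-mers of a single sequence.
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Small stable fingerprint of an R object (for run manifests).
param_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
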
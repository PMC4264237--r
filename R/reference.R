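# Synthetic reference set: per species a 16S-like gene (conserved regions
# interleaved with two variable-region blocks) and a genome with the gene
# embedded rrn_copies times, plus a rooted rank taxonomy for LCA assignment.
#
# Gene layout (coordinates fixed across species):
#   C1 | V12 | C2 | linker | C3 | V456 | C4
# The C1+V12+C2 block is the short amplicon (default 337 bp, emulating the
# V1-V2 product) and C3+V456+C4 the long amplicon (default 564 bp, V4-V6).
# Conserved regions are identical within a Gram subgroup and differ between
# subgroups at a fixed number of sites (the primer-mismatch structure that
# the alpha primer strategy exploits).

RANKS <- c("root", "order", "family", "genus", "species")

#' Build a synthetic reference set for a community
#'
#' Generates, deterministically for a given seed, one 16S-like gene and one
#' genome per species, and the rank taxonomy (root/order/family/genus/
#' species) implied by the community's taxonomic labels. Variable regions
#' are drawn independently per species and re-drawn until every pair of
#' species differs by at least `d_min` substitutions in each variable
#' region.
#'
#' @param community A [community_definition()].
#' @param seed Integer seed; the same seed reproduces the reference
#'   byte-for-byte.
#' @param d_min Minimum pairwise Hamming distance between the variable
#'   regions of any two species (default 10).
#' @param conserved_length Length of each conserved region C1..C4 (default
#'   64 bp). The default is chosen so the shared-k-mer score floor between
#'   a read and any same-subgroup reference (2 x (64 - k + 1) = 106 at
#'   k = 12) exceeds 99, which keeps the 1% top-score retention window
#'   wider than one score unit: a single chance k-mer collision can then
#'   never isolate a wrong top hit.
#' @param v12_length,v456_length Variable-region lengths; the defaults give
#'   amplicons of 337 bp (C1+V12+C2) and 564 bp (C3+V456+C4).
#' @param linker_length Length of the spacer between the two amplicon
#'   blocks (default 50 bp).
#' @param subgroup_divergence Number of substitutions separating the
#'   Gram-positive from the Gram-negative variant of each conserved region
#'   (default 2, the mismatch count of the alpha strategy on Gram-positive
#'   templates).
#' @param max_attempts Re-draw attempts before giving up on `d_min`.
#' @return An object of class `reference_set`: a list with `genes`,
#'   `genomes` (named character vectors), `variable` (per-region named
#'   vectors), `conserved` (per-subgroup region sequences), `taxonomy`
#'   (data.frame: node_id, parent_id, rank, name), `record_nodes` (named
#'   map from reference record to taxonomy node), and the generation
#'   parameters.
#' @export
build_reference <- function(community, seed = 1, d_min = 10,
                            conserved_length = 64, v12_length = 209,
                            v456_length = 436, linker_length = 50,
                            subgroup_divergence = 2, max_attempts = 20) {
  stopifnot(inherits(community, "community_definition"), d_min >= 1)
  members <- community$members
  gene_length <- 4 * conserved_length + v12_length + v456_length + linker_length
  short <- members$genome_length < members$rrn_copies * gene_length
  if (any(short)) {
    stop("genome of '", members$name[short][1],
         "' is too short to embed its rrn copies (needs >= ",
         members$rrn_copies[short][1] * gene_length, " bp)", call. = FALSE)
  }

  set.seed(seed)
  conserved <- list(gram_negative = lapply(1:4, function(i) random_dna_norun(conserved_length, 0.5)))
  names(conserved$gram_negative) <- paste0("C", 1:4)
  conserved$gram_positive <- lapply(conserved$gram_negative, function(s) {
    pos <- sample(2:(nchar(s) - 1), subgroup_divergence)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) {
      # avoid the neighbours too, so the edit cannot extend a base run
      ch[p] <- sample(setdiff(DNA_BASES, ch[c(p - 1, p, p + 1)]), 1)
    }
    paste(ch, collapse = "")
  })

  draw_regions <- function(len) {
    for (attempt in seq_len(max_attempts)) {
      v <- vapply(members$gc_fraction, function(gc) random_dna_norun(len, gc), "")
      names(v) <- members$name
      if (min_pairwise_hamming(v) >= d_min) return(v)
    }
    stop("could not generate variable regions with pairwise distance >= ",
         d_min, " in ", max_attempts,
         " attempts; use longer variable regions", call. = FALSE)
  }
  variable <- list(V12 = draw_regions(v12_length), V456 = draw_regions(v456_length))

  genes <- vapply(seq_len(nrow(members)), function(i) {
    cc <- conserved[[members$subgroup[i]]]
    paste0(cc$C1, variable$V12[i], cc$C2,
           random_dna_norun(linker_length, members$gc_fraction[i]),
           cc$C3, variable$V456[i], cc$C4)
  }, "")
  names(genes) <- members$name

  genomes <- vapply(seq_len(nrow(members)), function(i) {
    g_len <- members$genome_length[i]
    r <- members$rrn_copies[i]
    backbone <- random_dna(g_len - r * gene_length, members$gc_fraction[i])
    # spread the rrn operons evenly through the backbone
    cut <- floor(seq_len(r) * nchar(backbone) / (r + 1))
    parts <- character(2 * r + 1)
    prev <- 0
    for (j in seq_len(r)) {
      parts[2 * j - 1] <- substr(backbone, prev + 1, cut[j])
      parts[2 * j] <- genes[i]
      prev <- cut[j]
    }
    parts[2 * r + 1] <- substr(backbone, prev + 1, nchar(backbone))
    paste(parts, collapse = "")
  }, "")
  names(genomes) <- members$name

  taxonomy <- build_taxonomy(members)
  species_nodes <- taxonomy$node_id[match(members$name, taxonomy$name)]
  names(species_nodes) <- members$name

  structure(list(
    genes = genes, genomes = genomes, variable = variable,
    conserved = lapply(conserved, function(x) vapply(x, identity, "")),
    taxonomy = taxonomy, record_nodes = species_nodes,
    community = community, d_min = d_min, seed = seed,
    gene_length = gene_length, conserved_length = conserved_length,
    amplicon_lengths = c(V12 = 2 * conserved_length + v12_length,
                         V456 = 2 * conserved_length + v456_length)
  ), class = "reference_set")
}

min_pairwise_hamming <- function(seqs) {
  if (length(seqs) < 2) return(Inf)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  dmin <- Inf
  for (i in 1:(nrow(mat) - 1)) {
    for (j in (i + 1):nrow(mat)) {
      dmin <- min(dmin, sum(mat[i, ] != mat[j, ]))
    }
  }
  dmin
}

build_taxonomy <- function(members) {
  tax <- data.frame(node_id = 1L, parent_id = NA_integer_, rank = "root",
                    name = "root", stringsAsFactors = FALSE)
  add_node <- function(rank, name, parent_id) {
    hit <- tax$rank == rank & tax$name == name & tax$parent_id %in% parent_id
    if (any(hit)) return(tax$node_id[hit][1])
    id <- nrow(tax) + 1L
    tax[id, ] <<- list(id, parent_id, rank, name)
    id
  }
  for (i in seq_len(nrow(members))) {
    o <- add_node("order", members$order[i], 1L)
    f <- add_node("family", members$family[i], o)
    g <- add_node("genus", members$genus[i], f)
    add_node("species", members$name[i], g)
  }
  tax
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d species; gene %d bp; amplicons %d/%d bp; %d taxonomy nodes; seed %d\n",
              length(x$genes), x$gene_length, x$amplicon_lengths["V12"],
              x$amplicon_lengths["V456"], nrow(x$taxonomy), x$seed))
  invisible(x)
}

#' Corrupt a reference set (database-composition effects)
#'
#' Emulates working against an imperfect public database: taxa can be
#' dropped entirely (their sequences and taxonomy nodes disappear) or
#' mislabelled (a species' sequences keep their bases but are re-annotated
#' with another species' taxonomy path). A provenance log of the edits is
#' attached as the `"corruptions"` attribute.
#'
#' @param ref A [build_reference()] result.
#' @param drop Character vector of taxon names (species or higher ranks) to
#'   remove.
#' @param mislabel Named character vector: `c("A" = "B")` relabels species
#'   A's sequences as species B.
#' @param seed Unused randomness hook kept for interface symmetry.
#' @return A modified `reference_set`.
#' @export
corrupt_reference <- function(ref, drop = character(), mislabel = character(),
                              seed = 1) {
  stopifnot(inherits(ref, "reference_set"))
  log <- data.frame(action = character(), taxon = character(),
                    detail = character(), stringsAsFactors = FALSE)
  out <- ref

  if (length(drop)) {
    unknown <- setdiff(drop, out$taxonomy$name)
    if (length(unknown)) {
      stop("unknown taxon name: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    drop_ids <- out$taxonomy$node_id[out$taxonomy$name %in% drop]
    doomed <- out$taxonomy$node_id[vapply(out$taxonomy$node_id, function(n) {
      any(ancestor_path(n, out$taxonomy) %in% drop_ids)
    }, logical(1))]
    gone_species <- names(out$record_nodes)[out$record_nodes %in% doomed]
    out$genes <- out$genes[setdiff(names(out$genes), gone_species)]
    out$genomes <- out$genomes[setdiff(names(out$genomes), gone_species)]
    out$record_nodes <- out$record_nodes[setdiff(names(out$record_nodes), gone_species)]
    keep <- !(out$taxonomy$node_id %in% doomed)
    # prune internal nodes left without any species below them
    repeat {
      used <- unique(c(out$record_nodes,
                       out$taxonomy$parent_id[keep & !is.na(out$taxonomy$parent_id)]))
      drop_more <- keep & out$taxonomy$rank != "root" &
        !(out$taxonomy$node_id %in% used)
      if (!any(drop_more)) break
      keep <- keep & !drop_more
    }
    out$taxonomy <- out$taxonomy[keep, , drop = FALSE]
    log <- rbind(log, data.frame(action = "drop", taxon = drop,
                                 detail = sprintf("removed %d species record(s)",
                                                  length(gone_species)),
                                 stringsAsFactors = FALSE))
  }

  if (length(mislabel)) {
    for (a in names(mislabel)) {
      b <- mislabel[[a]]
      if (!a %in% names(out$record_nodes)) {
        stop("unknown taxon name: ", a, call. = FALSE)
      }
      if (!b %in% out$taxonomy$name[out$taxonomy$rank == "species"]) {
        stop("unknown taxon name: ", b, call. = FALSE)
      }
      out$record_nodes[a] <-
        out$taxonomy$node_id[out$taxonomy$name == b & out$taxonomy$rank == "species"]
      log <- rbind(log, data.frame(action = "mislabel", taxon = a,
                                   detail = paste("relabelled as", b),
                                   stringsAsFactors = FALSE))
    }
  }

  attr(out, "corruptions") <- log
  out
}
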
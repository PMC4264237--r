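# Read-to-reference scoring, top-score retention, lowest-common-ancestor
# (LCA) taxonomic assignment and minimum-support taxon calling: the roles a
# BLAST search plus an LCA classifier play in the published pipeline,
# re-implemented with deterministic shared-k-mer scoring.

#' Score a read against one reference sequence
#'
#' The score is the number of the read's distinct k-mers that also occur in
#' the reference, with the reverse-complement orientation taken as the
#' maximum of the two. Deterministic; bounded by `nchar(read) - k + 1`.
#' Reads shorter than `k` score 0.
#'
#' @param read Read bases.
#' @param reference Reference bases.
#' @param k k-mer size (default 12).
#' @return Non-negative integer score.
#' @export
score_read <- function(read, reference, k = 12) {
  if (nchar(read) < k) return(0L)
  ref_k <- seq_kmers(reference, k)
  max(sum(seq_kmers(read, k) %in% ref_k),
      sum(seq_kmers(revcomp(read), k) %in% ref_k))
}

# Vectorised scoring: reads (character vector) against every reference,
# returning an n_reads x n_refs integer matrix. Duplicate read sequences are
# scored once; k-mer membership is resolved with one hashed lookup per
# reference and orientation over the pooled k-mers of a chunk of reads.
score_reads <- function(bases, refs, k = 12, chunk_size = 20000L) {
  ub <- unique(bases)
  ref_kmers <- lapply(refs, seq_kmers, k = k)
  su <- matrix(0L, length(ub), length(refs),
               dimnames = list(NULL, names(refs)))
  for (lo in seq(1, length(ub), by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, length(ub))
    rows <- lo:hi
    for (orient in 1:2) {
      seqs <- if (orient == 1) ub[rows] else revcomp(ub[rows])
      kl <- lapply(seqs, seq_kmers, k = k)
      idx <- rep(seq_along(kl), lengths(kl))
      X <- unlist(kl, use.names = FALSE)
      if (!length(X)) next
      for (j in seq_along(refs)) {
        hit <- X %in% ref_kmers[[j]]
        sc <- tabulate(idx[hit], nbins = length(rows))
        su[rows, j] <- pmax(su[rows, j], sc)
      }
    }
  }
  su[match(bases, ub), , drop = FALSE]
}

#' Retain hits within a fraction of the top score
#'
#' Keeps hit h iff `score(h) >= (1 - top_fraction) * max(score)`; with the
#' default `top_fraction = 0.01` this is the "within 1% of the top score"
#' rule. Ties for the top all qualify by construction.
#'
#' @param hits Data frame with at least a `score` column (one row per hit).
#' @param top_fraction Retention window as a fraction of the top score
#'   (default 0.01).
#' @return The qualifying rows of `hits` (empty data frame for empty
#'   input).
#' @export
retain_top_hits <- function(hits, top_fraction = 0.01) {
  if (nrow(hits) == 0) return(hits)
  hits[hits$score >= (1 - top_fraction) * max(hits$score), , drop = FALSE]
}

# Root-to-node path of taxonomy node ids.
ancestor_path <- function(node, taxonomy) {
  path <- integer(0)
  cur <- node
  while (!is.na(cur)) {
    path <- c(cur, path)
    row <- match(cur, taxonomy$node_id)
    if (is.na(row)) stop("node ", cur, " not in taxonomy", call. = FALSE)
    cur <- taxonomy$parent_id[row]
  }
  path
}

#' Lowest common ancestor of a set of taxonomy nodes
#'
#' Returns the deepest node that is an ancestor-or-self of every input
#' node in a rooted taxonomy tree.
#'
#' @param nodes Vector of taxonomy node ids.
#' @param taxonomy Data frame with columns `node_id`, `parent_id`, `rank`,
#'   `name` describing a single rooted tree.
#' @return A single node id.
#' @export
lca <- function(nodes, taxonomy) {
  nodes <- unique(nodes)
  if (!all(nodes %in% taxonomy$node_id)) {
    stop("node not in taxonomy: ",
         paste(setdiff(nodes, taxonomy$node_id), collapse = ", "),
         call. = FALSE)
  }
  paths <- lapply(nodes, ancestor_path, taxonomy = taxonomy)
  depth <- min(lengths(paths))
  common <- 0L
  for (d in seq_len(depth)) {
    ids <- vapply(paths, `[`, integer(1), d)
    if (all(ids == ids[1])) common <- d else break
  }
  paths[[1]][common]
}

# Ancestor-or-self of `node` at `rank`, or NA if the node sits above that
# rank.
node_at_rank <- function(node, rank, taxonomy) {
  path <- ancestor_path(node, taxonomy)
  ranks <- taxonomy$rank[match(path, taxonomy$node_id)]
  hit <- which(ranks == rank)
  if (length(hit)) path[hit[1]] else NA_integer_
}

#' Assign reads to taxonomy nodes and call taxa at a reporting rank
#'
#' For every read: score against all reference records, retain hits within
#' `top_fraction` of the top score, and assign the read to the lowest
#' common ancestor of the qualifying records' taxonomy nodes (reads with no
#' scoring hit stay unassigned). At the reporting rank, taxa supported by
#' fewer than `min_support` reads are suppressed and their reads counted as
#' unassigned-at-rank.
#'
#' @param reads Data frame with `id` and `bases` columns (or a character
#'   vector of bases).
#' @param ref A [build_reference()] result (possibly corrupted via
#'   [corrupt_reference()]).
#' @param db Which reference records to score against: `"genes"` (16S, for
#'   amplicon reads) or `"genomes"` (for WGS reads).
#' @param top_fraction Top-score retention window (default 0.01).
#' @param min_support Minimum reads supporting a taxon for it to be called
#'   (default 5).
#' @param rank Reporting rank (default `"species"`).
#' @param k k-mer size for scoring (default 12).
#' @return An object of class `assignment_result`: list with `per_read`
#'   (read_id, node_id, node_rank, node_name, taxon: name at the reporting
#'   rank or `NA`), `counts` (taxon, node_id, count, called), `n_reads`,
#'   `n_unassigned`, and the parameters used.
#' @export
assign_reads <- function(reads, ref, db = c("genes", "genomes"),
                         top_fraction = 0.01, min_support = 5,
                         rank = "species", k = 12) {
  db <- match.arg(db)
  if (is.character(reads)) {
    reads <- data.frame(id = sprintf("read_%06d", seq_along(reads)),
                        bases = reads, stringsAsFactors = FALSE)
  }
  refs <- ref[[db]]
  if (!length(refs)) stop("reference set has no '", db, "' records",
                          call. = FALSE)
  taxonomy <- ref$taxonomy
  sc <- score_reads(reads$bases, refs, k = k)
  rmax <- do.call(pmax, as.data.frame(sc))
  qual <- sc >= (1 - top_fraction) * rmax & rmax > 0

  # identical qualifying-hit patterns share one LCA computation
  pattern <- if (ncol(qual) <= 30) {
    as.integer(qual %*% 2^(seq_len(ncol(qual)) - 1))
  } else {
    match(apply(qual, 1, paste, collapse = ""), unique(apply(qual, 1, paste, collapse = "")))
  }
  node <- rep(NA_integer_, nrow(reads))
  for (p in unique(pattern)) {
    sel <- pattern == p
    recs <- names(refs)[qual[which(sel)[1], ]]
    if (!length(recs)) next
    node[sel] <- lca(unname(ref$record_nodes[recs]), taxonomy)
  }

  tax_row <- match(node, taxonomy$node_id)
  unode <- unique(node[!is.na(node)])
  urank <- vapply(unode, node_at_rank, integer(1), rank = rank,
                  taxonomy = taxonomy)
  rank_node <- urank[match(node, unode)]
  rank_name <- taxonomy$name[match(rank_node, taxonomy$node_id)]

  tab <- table(rank_name)
  counts <- data.frame(taxon = names(tab),
                       node_id = taxonomy$node_id[match(names(tab), taxonomy$name)],
                       count = as.integer(tab), stringsAsFactors = FALSE)
  counts$called <- counts$count >= min_support
  suppressed <- counts$taxon[!counts$called]
  rank_name[rank_name %in% suppressed] <- NA_character_

  structure(list(
    per_read = data.frame(read_id = reads$id, node_id = node,
                          node_rank = taxonomy$rank[tax_row],
                          node_name = taxonomy$name[tax_row],
                          taxon = rank_name, stringsAsFactors = FALSE),
    counts = counts[order(-counts$count), , drop = FALSE],
    n_reads = nrow(reads),
    n_unassigned = sum(is.na(node)),
    params = list(db = db, top_fraction = top_fraction,
                  min_support = min_support, rank = rank, k = k)
  ), class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> %d reads, %d unassigned; %d/%d %s-level taxa called (min support %d)\n",
              x$n_reads, x$n_unassigned, sum(x$counts$called),
              nrow(x$counts), x$params$rank, x$params$min_support))
  invisible(x)
}

#' Called-taxon read counts of an assignment
#'
#' @param assignment An [assign_reads()] result.
#' @return Named integer vector of read counts for the taxa called at the
#'   reporting rank.
#' @export
called_counts <- function(assignment) {
  called <- assignment$counts[assignment$counts$called, , drop = FALSE]
  setNames(called$count, called$taxon)
}
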
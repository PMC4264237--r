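# High-stringency amplicon read filter and WGS quality filter, each with
# per-rule attrition accounting. Amplicon rules, applied in a fixed order so
# each dropped read has exactly one (first-failing) reason:
#   primer -> chimera -> quality trim -> length bounds -> ambiguity ->
#   homopolymer.

#' Amplicon filter configuration
#'
#' Defaults are the published high-stringency settings: at most 2 primer
#' mismatches, 50 bp sliding window trimmed where mean quality falls below
#' 35, reads dropped if longer than 10% over the expected amplicon length
#' (pre-trim) or shorter than 200 bases after trimming, and reads with any
#' ambiguous base or a homopolymer run longer than 8 removed.
#'
#' @param forward_primers Character vector of acceptable forward primer
#'   sequences (a read matches if its prefix is within
#'   `max_primer_mismatches` of any variant).
#' @param expected_amplicon_length Expected amplicon length in bp.
#' @param max_primer_mismatches Maximum primer mismatches (default 2).
#' @param window Sliding-window width in bp (default 50).
#' @param window_quality Mean-quality threshold below which the window
#'   fails (default 35, strict `<`).
#' @param min_length Minimum post-trim read length (default 200).
#' @param max_length_factor Reads longer than this multiple of the expected
#'   amplicon length are dropped (default 1.10), assessed on the raw
#'   (pre-trim) length.
#' @param max_homopolymer Longest tolerated single-base run (default 8;
#'   runs strictly longer are dropped).
#' @param check_chimeras Whether to run the bimera detector (requires
#'   candidate parent amplicons at filter time).
#' @param chimera_id_min,chimera_id_full Identity thresholds of
#'   [detect_bimera()].
#' @return A list of class `amplicon_filter_config`.
#' @export
amplicon_filter_config <- function(forward_primers, expected_amplicon_length,
                                   max_primer_mismatches = 2, window = 50,
                                   window_quality = 35, min_length = 200,
                                   max_length_factor = 1.10,
                                   max_homopolymer = 8, check_chimeras = TRUE,
                                   chimera_id_min = 0.9,
                                   chimera_id_full = 0.9) {
  stopifnot(length(forward_primers) >= 1, expected_amplicon_length > 0,
            max_primer_mismatches >= 0, window >= 1, window_quality > 0,
            min_length > 0, max_length_factor > 1, max_homopolymer >= 1)
  structure(list(forward_primers = forward_primers,
                 expected_amplicon_length = expected_amplicon_length,
                 max_primer_mismatches = max_primer_mismatches,
                 window = window, window_quality = window_quality,
                 min_length = min_length, max_length_factor = max_length_factor,
                 max_homopolymer = max_homopolymer,
                 check_chimeras = check_chimeras,
                 chimera_id_min = chimera_id_min,
                 chimera_id_full = chimera_id_full),
            class = "amplicon_filter_config")
}

#' WGS filter configuration
#'
#' Published settings: after end-trimming low-quality bases, reads with
#' fewer than 30 bases remaining are removed, as are reads with less than
#' 90% of bases at quality 30 or greater. The end-trim threshold (not
#' parameterised in the published text) defaults to Q20.
#'
#' @param min_length Minimum post-trim length (default 30).
#' @param min_q30_fraction Minimum fraction of bases at or above
#'   `q30_threshold` (default 0.90).
#' @param q30_threshold Quality defining a "high-quality" base (default 30).
#' @param trim_quality End-trim threshold (default 20): leading/trailing
#'   bases below it are removed.
#' @return A list of class `wgs_filter_config`.
#' @export
wgs_filter_config <- function(min_length = 30, min_q30_fraction = 0.90,
                              q30_threshold = 30, trim_quality = 20) {
  stopifnot(min_length >= 1, min_q30_fraction > 0, min_q30_fraction <= 1)
  structure(list(min_length = min_length,
                 min_q30_fraction = min_q30_fraction,
                 q30_threshold = q30_threshold, trim_quality = trim_quality),
            class = "wgs_filter_config")
}

#' Match a primer against a read prefix
#'
#' Ungapped position-by-position comparison of the primer to the read
#' prefix (for a reverse primer, pass the reverse-complemented read and
#' primer orientation of your convention). `N` counts as a mismatch. A
#' primer longer than the read is a no-match, not an error.
#'
#' @param read Read bases.
#' @param primer Primer bases.
#' @param max_mismatches Maximum tolerated Hamming mismatches (default 2).
#' @return A list with `match` (logical) and `mismatches` (integer; `NA`
#'   when the primer is longer than the read).
#' @export
match_primer <- function(read, primer, max_mismatches = 2) {
  if (nchar(primer) > nchar(read)) {
    return(list(match = FALSE, mismatches = NA_integer_))
  }
  mm <- primer_mismatches(read, primer)
  list(match = mm <= max_mismatches, mismatches = mm)
}

# Vectorised over reads: Hamming mismatches of `primer` vs each read prefix.
# Reads shorter than the primer get NA.
primer_mismatches <- function(reads, primer) {
  pl <- nchar(primer)
  pc <- strsplit(primer, "")[[1]]
  ok <- nchar(reads) >= pl
  mm <- rep(NA_integer_, length(reads))
  if (any(ok)) {
    pre <- substr(reads[ok], 1, pl)
    mat <- matrix(unlist(strsplit(pre, ""), use.names = FALSE), nrow = pl)
    mm[ok] <- as.integer(colSums(mat != pc))
  }
  mm
}

#' Trim a read at the first failing sliding quality window
#'
#' Scans 5' to 3' with a window of `window` bases advancing one base at a
#' time and truncates the read immediately before the first window whose
#' mean Phred quality is strictly below `threshold`. Reads shorter than the
#' window are evaluated as a single window spanning the whole read.
#'
#' @param bases Read bases (single string).
#' @param quals Phred+33 quality string of the same length.
#' @param window Window width (default 50).
#' @param threshold Mean-quality threshold (default 35).
#' @return A list with trimmed `bases` and `quals` (possibly empty
#'   strings).
#' @export
trim_quality_window <- function(bases, quals, window = 50, threshold = 35) {
  stopifnot(window >= 1, nchar(bases) == nchar(quals))
  q <- quals_to_int(quals)
  L <- length(q)
  if (L == 0) return(list(bases = "", quals = ""))
  if (L < window) {
    cut <- if (mean(q) < threshold) 0L else L
  } else {
    cs <- cumsum(q)
    wmean <- (cs[window:L] - c(0, cs[seq_len(L - window)])) / window
    bad <- which(wmean < threshold)
    cut <- if (length(bad)) bad[1] - 1L else L
  }
  list(bases = substr(bases, 1, cut), quals = substr(quals, 1, cut))
}

#' Detect a bimera against candidate parent amplicons
#'
#' Flags a read as a two-parent chimera if some split point gives a
#' left-segment identity to one parent and a right-segment identity to a
#' different parent both at least `id_min`, while the full-length identity
#' to every single parent is below `id_full`. Identities are ungapped,
#' computed position-by-position from the read start; split points at
#' least `min_segment` bases from either end are considered.
#'
#' @param bases Read bases.
#' @param parents Named character vector of candidate parent amplicons (at
#'   least 2).
#' @param id_min Minimum segment identity for a chimeric parent (default
#'   0.9).
#' @param id_full Full-length identity at or above which the read is
#'   considered a clean copy of a parent (default 0.9).
#' @param min_segment Minimum segment length flanking a split (default 20).
#' @return A list with `is_bimera` (logical), `parents` (the flagged pair
#'   or `NULL`) and `split` (breakpoint position or `NA`).
#' @export
detect_bimera <- function(bases, parents, id_min = 0.9, id_full = 0.9,
                          min_segment = 20) {
  stopifnot(length(parents) >= 2)
  rc <- strsplit(bases, "")[[1]]
  L <- length(rc)
  if (L < 2 * min_segment + 1) {
    return(list(is_bimera = FALSE, parents = NULL, split = NA_integer_))
  }
  pnames <- names(parents)
  # cumulative matches of the read against each parent, padded to L
  M <- vapply(parents, function(p) {
    pc <- strsplit(p, "")[[1]]
    Lp <- min(L, length(pc))
    cs <- cumsum(rc[seq_len(Lp)] == pc[seq_len(Lp)])
    c(cs, rep(cs[Lp], L - Lp))
  }, numeric(L))
  full_id <- M[L, ] / L
  if (any(full_id >= id_full)) {
    return(list(is_bimera = FALSE, parents = NULL, split = NA_integer_))
  }
  splits <- seq(min_segment, L - min_segment)
  left_id <- sweep(M, 1, seq_len(L), "/")                 # L x P
  right_id <- sweep(-M, 2, M[L, ], "+") / (L - seq_len(L))
  for (s in splits) {
    lok <- which(left_id[s, ] >= id_min)
    rok <- which(right_id[s, ] >= id_min)
    if (!length(lok) || !length(rok)) next
    if (length(lok) == 1 && length(rok) == 1 && lok == rok) next
    p1 <- lok[which.max(left_id[s, lok])]
    p2 <- rok[which.max(right_id[s, rok])]
    if (p1 == p2) p2 <- setdiff(if (length(rok) > 1) rok else lok, p1)[1]
    return(list(is_bimera = TRUE, parents = pnames[c(p1, p2)], split = s))
  }
  list(is_bimera = FALSE, parents = NULL, split = NA_integer_)
}

#' Filter a single amplicon read
#'
#' Convenience wrapper around [run_amplicon_filter()] for one read.
#'
#' @param read A list or one-row data.frame with `bases` and `quals`.
#' @param cfg An [amplicon_filter_config()].
#' @param parents Optional candidate parent amplicons for chimera
#'   detection.
#' @return A list with `keep`, `reason` (`NA` if kept) and the possibly
#'   trimmed `bases`/`quals`.
#' @export
filter_amplicon_read <- function(read, cfg, parents = NULL) {
  df <- data.frame(id = "read", bases = read$bases, quals = read$quals,
                   stringsAsFactors = FALSE)
  res <- run_amplicon_filter(df, cfg, parents = parents)
  list(keep = nrow(res$reads) == 1,
       reason = res$reasons$reason[1],
       bases = if (nrow(res$reads)) res$reads$bases[1] else "",
       quals = if (nrow(res$reads)) res$reads$quals[1] else "")
}

#' Run the amplicon filter over a read set
#'
#' Applies the rules in order (primer, chimera, quality trim + length
#' bounds, ambiguity, homopolymer); each removed read is charged to the
#' first rule it fails, so the per-rule counts plus survivors always sum to
#' the input count. Survivors are returned quality-trimmed, in input order.
#'
#' @param reads Data frame with columns `id`, `bases`, `quals`.
#' @param cfg An [amplicon_filter_config()].
#' @param parents Named character vector of candidate parent amplicons for
#'   bimera detection; when `NULL` (or `cfg$check_chimeras` is `FALSE`) the
#'   chimera rule is skipped and its removal count is zero.
#' @return A list with `reads` (surviving, trimmed), `report` (a
#'   `filter_report`) and `reasons` (per-read id/kept/reason).
#' @export
run_amplicon_filter <- function(reads, cfg, parents = NULL) {
  stopifnot(inherits(cfg, "amplicon_filter_config"),
            all(c("id", "bases", "quals") %in% names(reads)))
  if (any(nchar(reads$bases) != nchar(reads$quals))) {
    stop("malformed read record: bases/quality length mismatch at record ",
         which(nchar(reads$bases) != nchar(reads$quals))[1], call. = FALSE)
  }
  n <- nrow(reads)
  rule_names <- c("primer", "chimera", "too_long", "too_short", "ambiguous",
                  "homopolymer")
  reason <- rep(NA_character_, n)
  bases <- reads$bases
  quals <- reads$quals

  if (n > 0) {
    # 1. primer grouping: prefix within max mismatches of any forward variant
    mm <- vapply(cfg$forward_primers, function(p) primer_mismatches(bases, p),
                 numeric(n))
    mm <- matrix(mm, nrow = n)
    mm[is.na(mm)] <- Inf
    best <- apply(mm, 1, min)
    reason[best > cfg$max_primer_mismatches] <- "primer"

    # quality trim first (the trim is idempotent, and running the bimera
    # detector on the trimmed sequence keeps the whole filter idempotent);
    # the over-length rule still judges the raw, pre-trim length
    raw_length <- nchar(bases)
    for (i in which(is.na(reason))) {
      tr <- trim_quality_window(bases[i], quals[i], cfg$window,
                                cfg$window_quality)
      bases[i] <- tr$bases
      quals[i] <- tr$quals
    }

    # 2. chimera removal (on the trimmed sequence)
    if (isTRUE(cfg$check_chimeras) && !is.null(parents)) {
      idx <- which(is.na(reason))
      exact <- bases[idx] %in% parents  # identical copies can never be flagged
      for (i in idx[!exact]) {
        hit <- detect_bimera(bases[i], parents, cfg$chimera_id_min,
                             cfg$chimera_id_full)
        if (hit$is_bimera) reason[i] <- "chimera"
      }
    }

    # 3. over-length on the raw (pre-trim) read
    too_long <- is.na(reason) &
      raw_length > cfg$max_length_factor * cfg$expected_amplicon_length
    reason[too_long] <- "too_long"

    # 4. minimum post-trim length
    reason[is.na(reason) & nchar(bases) < cfg$min_length] <- "too_short"

    # 5. ambiguous bases
    reason[is.na(reason) & grepl("N", bases, fixed = TRUE)] <- "ambiguous"

    # 6. homopolymer runs longer than max_homopolymer
    hp <- sprintf("([ACGT])\\1{%d,}", cfg$max_homopolymer)
    reason[is.na(reason) & grepl(hp, bases)] <- "homopolymer"
  }

  keep <- is.na(reason)
  removed <- vapply(rule_names, function(r) sum(reason == r, na.rm = TRUE), 0L)
  report <- filter_report(n, removed, sum(keep))
  out <- reads[keep, , drop = FALSE]
  out$bases <- bases[keep]
  out$quals <- quals[keep]
  list(reads = out, report = report,
       reasons = data.frame(id = reads$id, kept = keep, reason = reason,
                            stringsAsFactors = FALSE))
}

filter_report <- function(input, removed, surviving) {
  stopifnot(input == surviving + sum(removed))
  structure(list(input = as.integer(input),
                 removed = vapply(removed, as.integer, 0L),
                 surviving = as.integer(surviving),
                 surviving_fraction = if (input > 0) surviving / input else NA_real_),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d reads in, %d surviving (%.1f%%)\n",
              x$input, x$surviving, 100 * x$surviving_fraction))
  rem <- x$removed[x$removed > 0]
  if (length(rem)) {
    cat("  removed:", paste(sprintf("%s=%d", names(rem), rem), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Convert a filter report to a one-row data frame
#' @param report A `filter_report`.
#' @return A one-row data.frame: input, one column per rule, surviving,
#'   surviving_fraction.
#' @export
filter_report_row <- function(report) {
  cbind(data.frame(input = report$input),
        as.data.frame(as.list(report$removed)),
        data.frame(surviving = report$surviving,
                   surviving_fraction = report$surviving_fraction))
}

#' Filter whole-genome shotgun reads
#'
#' End-trims low-quality bases (below `trim_quality`) from both read ends,
#' then removes reads shorter than `min_length` or with less than
#' `min_q30_fraction` of bases at quality `q30_threshold` or above.
#' Surviving reads whose mate was removed are rerouted to the unpaired
#' stream (`pairing = "unpaired"`), keeping the pair streams synchronised.
#'
#' @param reads Data frame with `id`, `bases`, `quals`, `pairing` and
#'   (for paired reads) `pair_id`.
#' @param cfg A [wgs_filter_config()].
#' @return A list with `reads` (survivors, trimmed, mate-aware pairing),
#'   `report` (a `filter_report` with rules `too_short` and `low_quality`)
#'   and `rerouted_unpaired` (count of surviving mates rerouted).
#' @export
filter_wgs_reads <- function(reads, cfg = wgs_filter_config()) {
  stopifnot(inherits(cfg, "wgs_filter_config"))
  n <- nrow(reads)
  qs <- lapply(reads$quals, quals_to_int)
  start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    good <- which(qs[[i]] >= cfg$trim_quality)
    if (!length(good)) { start[i] <- 1L; end[i] <- 0L }
    else { start[i] <- good[1]; end[i] <- good[length(good)] }
  }
  len <- pmax(end - start + 1L, 0L)
  q30ok <- logical(n)
  for (i in seq_len(n)) {
    if (len[i] > 0) {
      q30ok[i] <- mean(qs[[i]][start[i]:end[i]] >= cfg$q30_threshold) >=
        cfg$min_q30_fraction
    }
  }
  reason <- rep(NA_character_, n)
  reason[len < cfg$min_length] <- "too_short"
  reason[is.na(reason) & !q30ok] <- "low_quality"
  keep <- is.na(reason)

  out <- reads[keep, , drop = FALSE]
  out$bases <- substr(reads$bases[keep], start[keep], end[keep])
  out$quals <- substr(reads$quals[keep], start[keep], end[keep])

  rerouted <- 0L
  if ("pair_id" %in% names(reads)) {
    surv_by_pair <- table(out$pair_id[out$pairing %in% c("pair_1", "pair_2")])
    widowed <- names(surv_by_pair)[surv_by_pair == 1]
    sel <- out$pair_id %in% widowed & out$pairing %in% c("pair_1", "pair_2")
    rerouted <- sum(sel)
    out$pairing[sel] <- "unpaired"
  }
  removed <- c(too_short = sum(reason == "too_short", na.rm = TRUE),
               low_quality = sum(reason == "low_quality", na.rm = TRUE))
  list(reads = out, report = filter_report(n, removed, sum(keep)),
       rerouted_unpaired = rerouted)
}

#' Filter a single WGS read
#'
#' @param read A list with `bases` and `quals`.
#' @param cfg A [wgs_filter_config()].
#' @return A list with `keep`, `reason` and the trimmed `bases`/`quals`.
#' @export
filter_wgs_read <- function(read, cfg = wgs_filter_config()) {
  df <- data.frame(id = "read", bases = read$bases, quals = read$quals,
                   pairing = "unpaired", stringsAsFactors = FALSE)
  res <- filter_wgs_reads(df, cfg)
  kept <- nrow(res$reads) == 1
  rem <- res$report$removed
  list(keep = kept,
       reason = if (kept) NA_character_ else names(rem)[rem > 0][1],
       bases = if (kept) res$reads$bases[1] else "",
       quals = if (kept) res$reads$quals[1] else "")
}
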
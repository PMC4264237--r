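# Orchestration: single-run pipelines (simulate -> filter -> assign ->
# normalise), the replicate %CV study contrasting primer strategies with
# WGS, and the full in-silico experiment with its report.

#' Run one amplicon sequencing replicate end to end
#'
#' Simulates reads under a primer strategy, applies the high-stringency
#' amplicon filter (primer grouping, bimera removal when the strategy can
#' produce chimeras, quality-window trimming, length/ambiguity/homopolymer
#' rules), assigns survivors by k-mer scoring + LCA against the 16S gene
#' records, and normalises species-level counts by rrn copy number.
#'
#' @param ref A [build_reference()] result.
#' @param strategy A [primer_strategy()].
#' @param n_reads Reads to simulate.
#' @param error An [error_params()] model.
#' @param seed Integer seed.
#' @param community A [community_definition()] (defaults to the one in
#'   `ref`).
#' @param min_support,top_fraction,k Assignment parameters.
#' @param normalization Normalisation mode (default `"rrn_copy_number"`).
#' @return A list with `profile` (an `abundance_profile`), `report`
#'   (filter report), `assignment`, `truth` and `simulation`.
#' @export
run_amplicon_pipeline <- function(ref, strategy, n_reads,
                                  error = error_params(), seed = 1,
                                  community = ref$community,
                                  min_support = 5, top_fraction = 0.01,
                                  k = 12,
                                  normalization = "rrn_copy_number") {
  sim <- simulate_pcr_amplicon_reads(ref, community, strategy, n_reads,
                                     error = error, seed = seed)
  cfg <- amplicon_filter_config(
    forward_primers = strategy$forward_primers,
    expected_amplicon_length = strategy$expected_amplicon_length,
    check_chimeras = strategy$chimera_prob > 0)
  parents <- if (cfg$check_chimeras) strategy_amplicons(ref, strategy) else NULL
  flt <- run_amplicon_filter(sim$reads, cfg, parents = parents)
  asg <- assign_reads(flt$reads, ref, db = "genes",
                      top_fraction = top_fraction,
                      min_support = min_support, rank = "species", k = k)
  profile <- normalize_counts(called_counts(asg), community,
                              mode = normalization)
  list(profile = profile, report = flt$report, assignment = asg,
       truth = sim$truth, simulation = sim)
}

#' Run one WGS sequencing replicate end to end
#'
#' Simulates paired-end reads, applies the WGS quality filter with pair
#' bookkeeping, assigns survivors against the genome records, and
#' normalises species-level counts by genome size. The WGS pipeline
#' reports raw alignment counts, so no minimum-support suppression is
#' applied by default.
#'
#' @param ref A [build_reference()] result.
#' @param n_read_pairs Read pairs to simulate.
#' @param error An [error_params()] model (see [simulate_wgs_reads()] for
#'   the Illumina-like default).
#' @param seed Integer seed.
#' @param community A [community_definition()].
#' @param min_support,top_fraction,k Assignment parameters.
#' @return A list with `profile`, `report`, `assignment`, `truth`,
#'   `filtered_reads` and `simulation`.
#' @export
run_wgs_pipeline <- function(ref, n_read_pairs,
                             error = NULL, seed = 1,
                             community = ref$community, min_support = 1,
                             top_fraction = 0.01, k = 12) {
  sim <- if (is.null(error)) {
    simulate_wgs_reads(ref, community, n_read_pairs, seed = seed)
  } else {
    simulate_wgs_reads(ref, community, n_read_pairs, error = error,
                       seed = seed)
  }
  flt <- filter_wgs_reads(sim$reads, wgs_filter_config())
  asg <- assign_reads(flt$reads, ref, db = "genomes",
                      top_fraction = top_fraction,
                      min_support = min_support, rank = "species", k = k)
  profile <- normalize_counts(called_counts(asg), community,
                              mode = "genome_size")
  list(profile = profile, report = flt$report, assignment = asg,
       truth = sim$truth, filtered_reads = flt$reads, simulation = sim)
}

#' Replicate %CV study across measurement strategies
#'
#' Runs `n_triplets` independent replicate triplets for each requested
#' strategy (the four primer strategies and/or WGS) at matched read depth
#' and returns the per-species %CV of the resulting abundance profiles,
#' averaged over triplets. This is the machinery behind the
#' strategy-precision contrast: the alpha strategy's run-to-run efficiency
#' jitter is amplified on its mismatched (Gram-positive) species, the
#' mixed-primer strategies carry only generic PCR jitter, and WGS carries
#' no PCR noise at all.
#'
#' @param ref A [build_reference()] result.
#' @param strategies Character subset of
#'   `c("alpha", "beta", "gamma", "delta", "wgs")`.
#' @param depth Reads (amplicon) / read pairs x 2 (WGS) per replicate; WGS
#'   simulates `depth / 2` pairs so total read counts match.
#' @param n_triplets Number of independent triplets (default 20).
#' @param replicates Replicates per triplet (default 3).
#' @param error Amplicon error model (default [no_errors()]: the contrast
#'   isolates PCR-efficiency variation).
#' @param chimera_prob Amplicon chimera rate (default 0 for the same
#'   reason).
#' @param seed Master seed.
#' @param min_support Assignment support threshold for amplicon runs.
#' @return A list with `cv` (species x strategy matrix, mean %CV over
#'   triplets, NA cells dropped), `average` (per-strategy mean over
#'   species) and `per_triplet` (list of `precision_report`s).
#' @export
precision_study <- function(ref, strategies = c("alpha", "beta", "gamma",
                                                "delta", "wgs"),
                            depth = 3000, n_triplets = 20, replicates = 3,
                            error = no_errors(), chimera_prob = 0, seed = 1,
                            min_support = 5) {
  community <- ref$community
  members <- community$members
  strat_objs <- list()
  for (s in setdiff(strategies, "wgs")) {
    strat_objs[[s]] <- primer_strategy(s, ref, chimera_prob = chimera_prob)
  }
  per_triplet <- vector("list", n_triplets)
  cv_sum <- matrix(0, nrow(members), length(strategies),
                   dimnames = list(members$name, strategies))
  cv_n <- cv_sum
  for (t in seq_len(n_triplets)) {
    profiles <- list()
    for (si in seq_along(strategies)) {
      s <- strategies[si]
      profiles[[s]] <- lapply(seq_len(replicates), function(r) {
        sd <- derive_seed(seed, t, si, r)
        if (s == "wgs") {
          run_wgs_pipeline(ref, n_read_pairs = max(1, round(depth / 2)),
                           seed = sd)$profile
        } else {
          run_amplicon_pipeline(ref, strat_objs[[s]], n_reads = depth,
                                error = error, seed = sd,
                                min_support = min_support)$profile
        }
      })
    }
    pr <- precision_report(profiles, community)
    per_triplet[[t]] <- pr
    ok <- !is.na(pr$cv)
    cv_sum[ok] <- cv_sum[ok] + pr$cv[ok]
    cv_n[ok] <- cv_n[ok] + 1
  }
  cv <- cv_sum / cv_n
  list(cv = cv, average = colMeans(cv, na.rm = TRUE),
       per_triplet = per_triplet,
       subgroup = setNames(members$subgroup, members$name))
}

#' Experiment configuration
#'
#' @param community A [community_definition()] (default: the bundled
#'   MCM-like community with genomes scaled to 1% of full size, which
#'   leaves all relative abundances unchanged while keeping simulation
#'   tractable).
#' @param strategies Strategies to run (default all four primer strategies
#'   plus WGS).
#' @param replicates Replicate runs per strategy (default 3).
#' @param amplicon_depth Reads per amplicon replicate (default 5000).
#' @param wgs_depth Read pairs per WGS replicate (default 50000).
#' @param bootstrap_sizes,bootstrap_B Bootstrap ladder for the WGS depth
#'   study (defaults 500...30000 and 1000).
#' @param error Amplicon error model.
#' @param chimera_prob Amplicon chimera rate (default 0.01).
#' @param qubit_bias Named fluorometry bias factors (default: 3-fold
#'   overestimate for Pseudomonas aeruginosa, the known discordant
#'   member, when present; 1 otherwise).
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(community = mcm_community(genome_scale = 0.01),
                              strategies = c("alpha", "beta", "gamma",
                                             "delta", "wgs"),
                              replicates = 3, amplicon_depth = 5000,
                              wgs_depth = 50000,
                              bootstrap_sizes = c(500, 1000, 2500, 5000,
                                                  10000, 30000),
                              bootstrap_B = 1000,
                              error = error_params(), chimera_prob = 0.01,
                              qubit_bias = NULL, seed = 1) {
  stopifnot(replicates >= 1)
  if (is.null(qubit_bias)) {
    qubit_bias <- if ("Pseudomonas aeruginosa" %in% community$members$name) {
      c("Pseudomonas aeruginosa" = 3)
    } else {
      1
    }
  }
  structure(list(community = community, strategies = strategies,
                 replicates = replicates, amplicon_depth = amplicon_depth,
                 wgs_depth = wgs_depth, bootstrap_sizes = bootstrap_sizes,
                 bootstrap_B = bootstrap_B, error = error,
                 chimera_prob = chimera_prob, qubit_bias = qubit_bias,
                 seed = seed),
            class = "experiment_config")
}

#' Run the full in-silico profiling experiment
#'
#' For each strategy and replicate: simulate, filter, assign and quantify;
#' then summarise precision across replicates (when `replicates >= 2`),
#' simulate fluorometric and triplicate dPCR quantification of every
#' species and compare them (per-species Welch t-tests with Bonferroni
#' correction plus the slope test of log10 copy numbers), and run the
#' bootstrap depth study on the first WGS replicate. Rerunning with the
#' same configuration reproduces every number.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory; when given, profiles, filter
#'   reports, the CV matrix, comparison tables, the bootstrap table, the
#'   reference FASTA/taxonomy and a manifest (seed + parameter
#'   fingerprint) are written there.
#' @return An object of class `mcm_experiment`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  community <- config$community
  seed <- config$seed
  ref <- build_reference(community, seed = derive_seed(seed, 1))

  profiles <- list()
  filter_reports <- list()
  wgs_runs <- list()
  for (si in seq_along(config$strategies)) {
    s <- config$strategies[si]
    profiles[[s]] <- list()
    for (r in seq_len(config$replicates)) {
      sd <- derive_seed(seed, 10 + si, r)
      if (s == "wgs") {
        run <- run_wgs_pipeline(ref, n_read_pairs = config$wgs_depth,
                                seed = sd)
        wgs_runs[[r]] <- run
      } else {
        strat <- primer_strategy(s, ref, chimera_prob = config$chimera_prob)
        run <- run_amplicon_pipeline(ref, strat,
                                     n_reads = config$amplicon_depth,
                                     error = config$error, seed = sd)
      }
      profiles[[s]][[r]] <- run$profile
      filter_reports[[paste(s, r, sep = "_rep")]] <- run$report
    }
  }

  precision <- NULL
  precision_note <- NULL
  if (config$replicates >= 2) {
    precision <- precision_report(profiles, community)
  } else {
    precision_note <- "precision report suppressed: %CV needs >= 2 replicates"
  }

  fluor <- simulate_fluorometry(community, bias_factor = config$qubit_bias,
                                cv_noise = 0.05, n_replicates = 3,
                                seed = derive_seed(seed, 2))
  dpcr <- dpcr_quantify_community(community, n_replicates = 3,
                                  seed = derive_seed(seed, 3))
  members <- community$members
  qubit_log <- log10(mass_to_copies(fluor$readings,
                                    members$genome_length))
  rownames(qubit_log) <- members$name
  comparison <- compare_methods(qubit_log, dpcr$log10_replicates)
  slope <- slope_test(rowMeans(qubit_log), rowMeans(dpcr$log10_replicates))

  bootstrap <- NULL
  if ("wgs" %in% config$strategies) {
    reads <- wgs_runs[[1]]$filtered_reads
    sizes <- config$bootstrap_sizes[config$bootstrap_sizes <= nrow(reads)]
    bootstrap <- bootstrap_precision_curve(reads, ref, community,
                                           sizes = sizes,
                                           B = config$bootstrap_B,
                                           seed = derive_seed(seed, 4))
  }

  result <- structure(list(
    config = config, reference = ref, profiles = profiles,
    filter_reports = filter_reports, precision = precision,
    precision_note = precision_note, fluorometry = fluor, dpcr = dpcr,
    comparison = comparison, slope = slope, bootstrap = bootstrap,
    fingerprint = param_fingerprint(list(seed = seed,
                                         strategies = config$strategies,
                                         replicates = config$replicates,
                                         amplicon_depth = config$amplicon_depth,
                                         wgs_depth = config$wgs_depth))
  ), class = "mcm_experiment")

  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(x$reference$genes, file.path(out_dir, "reference_16s.fasta"))
  write_taxonomy(x$reference$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  for (s in names(x$profiles)) {
    for (r in seq_along(x$profiles[[s]])) {
      write_tsv(x$profiles[[s]][[r]],
                file.path(out_dir, sprintf("profile_%s_rep%d.tsv", s, r)))
    }
  }
  rows <- lapply(names(x$filter_reports), function(nm) {
    cbind(data.frame(run = nm), filter_report_row(x$filter_reports[[nm]]))
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  fr <- do.call(rbind, rows)
  write_tsv(fr, file.path(out_dir, "filter_reports.tsv"))
  if (!is.null(x$precision)) {
    cv <- data.frame(species = rownames(x$precision$cv), x$precision$cv,
                     check.names = FALSE)
    avg <- data.frame(species = "Average", as.list(x$precision$average),
                      check.names = FALSE)
    write_tsv(rbind(cv, avg), file.path(out_dir, "precision_cv.tsv"))
  }
  write_tsv(as.data.frame(x$comparison),
            file.path(out_dir, "method_comparison.tsv"))
  if (!is.null(x$bootstrap)) {
    write_tsv(x$bootstrap$table, file.path(out_dir, "bootstrap_precision.tsv"))
  }
  write_tsv(x$dpcr$estimates, file.path(out_dir, "dpcr_estimates.tsv"))
  jsonlite::write_json(list(seed = x$config$seed,
                            fingerprint = x$fingerprint,
                            slope = x$slope,
                            precision_note = x$precision_note),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mcm_experiment <- function(x, ...) {
  cat(sprintf("<mcm_experiment> %d strategies x %d replicates; fingerprint %s\n",
              length(x$config$strategies), x$config$replicates, x$fingerprint))
  invisible(x)
}

#' Render a human-readable experiment summary
#'
#' Three sections: the precision (%CV) matrix, truth vs dPCR vs sequencing
#' abundance tables with flags for estimates more than `flag_fold`-fold
#' from truth, and the fluorometry-vs-dPCR comparison with slope tests.
#'
#' @param experiment A [run_experiment()] result.
#' @param flag_fold Fold-discrepancy threshold for flagging (default 2).
#' @return Character vector of report lines, invisibly; also printed.
#' @export
make_report <- function(experiment, flag_fold = 2) {
  x <- experiment
  members <- x$config$community$members
  lines <- c("== Precision: %CV across replicates ==")
  if (!is.null(x$precision)) {
    tab <- rbind(round(x$precision$cv, 1), Average = round(x$precision$average, 1))
    lines <- c(lines, utils::capture.output(print(tab)))
  } else {
    lines <- c(lines, x$precision_note)
  }

  lines <- c(lines, "", "== Relative abundance vs truth (percent) ==")
  truth_pct <- 100 * members$true_copies_per_ul / sum(members$true_copies_per_ul)
  abund <- data.frame(species = members$name, truth = round(truth_pct, 3))
  dpcr_pct <- 100 * x$dpcr$estimates$mean_copies_per_ul /
    sum(x$dpcr$estimates$mean_copies_per_ul)
  abund$dpcr <- round(dpcr_pct, 3)
  for (s in names(x$profiles)) {
    est <- rowMeans(vapply(x$profiles[[s]],
                           function(p) p$percent[match(members$name, p$species)],
                           numeric(nrow(members))))
    abund[[s]] <- round(est, 3)
    fold <- ifelse(truth_pct > 0 & est > 0,
                   pmax(est / truth_pct, truth_pct / est), Inf)
    abund[[paste0(s, "_flag")]] <- ifelse(fold >= flag_fold, "*", "")
  }
  lines <- c(lines, utils::capture.output(print(abund, row.names = FALSE)))

  lines <- c(lines, "", "== Method comparison: fluorometry vs dPCR ==",
             utils::capture.output(print(as.data.frame(x$comparison),
                                         row.names = FALSE)),
             sprintf("slope %.3f (se %.3f); p(slope=0) %.3g; p(slope=1) %.3g",
                     x$slope$slope, x$slope$se, x$slope$p_zero, x$slope$p_one))
  cat(lines, sep = "\n")
  invisible(lines)
}
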
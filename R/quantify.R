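# Conversion of assigned read counts into relative abundances (16S copy
# number or genome size normalisation) and of dPCR panel counts into
# absolute copy estimates with Poisson statistics.

#' Normalise read counts into a relative abundance profile
#'
#' Amplicon counts are divided by each species' rrn copy number
#' (`mode = "rrn_copy_number"`, since a genome with more 16S copies yields
#' proportionally more amplicon reads), WGS counts by genome size
#' (`mode = "genome_size"`); `mode = "none"` leaves counts untouched.
#' Percentages are the normalised quantities rescaled to sum to 100.
#' Species present in the community but absent from `counts` are reported
#' with explicit zeros so profiles are comparable across replicates.
#'
#' @param counts Named numeric vector of per-species read counts.
#' @param community A [community_definition()] containing every counted
#'   species.
#' @param mode Normalisation mode: `"rrn_copy_number"`, `"genome_size"` or
#'   `"none"`.
#' @return An object of class `abundance_profile`: a data.frame with
#'   columns `species`, `raw_count`, `normalized`, `percent` (summing to
#'   100), with the mode in attribute `"mode"`.
#' @export
normalize_counts <- function(counts, community,
                             mode = c("rrn_copy_number", "genome_size", "none")) {
  mode <- match.arg(mode)
  members <- community$members
  unknown <- setdiff(names(counts), members$name)
  if (length(unknown)) {
    stop("species missing from community definition: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  c_i <- setNames(rep(0, nrow(members)), members$name)
  c_i[names(counts)] <- counts
  if (sum(c_i) == 0) stop("all counts are zero", call. = FALSE)
  q_i <- switch(mode,
                rrn_copy_number = c_i / members$rrn_copies,
                genome_size = c_i / members$genome_length,
                none = c_i)
  p_i <- 100 * q_i / sum(q_i)
  structure(data.frame(species = members$name, raw_count = unname(c_i),
                       normalized = unname(q_i), percent = unname(p_i),
                       stringsAsFactors = FALSE),
            mode = mode, community = community$name,
            class = c("abundance_profile", "data.frame"))
}

#' Collapse per-reference counts to species, excluding plasmid hits
#'
#' Reference records labelled `"plasmid"` are excluded before
#' normalisation, because plasmid copy number per genome is unknown;
#' unlabelled records are treated as chromosome with a warning.
#'
#' @param counts Data frame with columns `reference`, `species`, `type`
#'   (`"chromosome"` or `"plasmid"`) and `count`.
#' @return Named numeric vector of per-species chromosome-hit counts
#'   (species whose hits were all plasmid appear with count 0). The number
#'   of excluded hits is attached as attribute `"excluded_plasmid_hits"`.
#' @export
exclude_plasmid_hits <- function(counts) {
  stopifnot(all(c("species", "type", "count") %in% names(counts)))
  type <- counts$type
  if (any(is.na(type) | type == "")) {
    warning("unlabelled reference(s) treated as chromosome")
    type[is.na(type) | type == ""] <- "chromosome"
  }
  keep <- type != "plasmid"
  out <- tapply(counts$count * keep, counts$species, sum)
  res <- setNames(as.numeric(out), names(out))
  attr(res, "excluded_plasmid_hits") <- sum(counts$count[!keep])
  res
}

#' Estimate molecule count and concentration from a dPCR panel
#'
#' With k of N partitions positive, the mean molecules per partition is
#' `lambda = -ln(1 - k/N)` (Poisson correction for partitions holding more
#' than one molecule), the molecule count `M = N * lambda`, and the sample
#' concentration `M / (N * V_p) * D` for partition volume `V_p` and
#' sample-in-reaction dilution factor `D`. The 95% confidence interval
#' propagates the binomial standard error of k/N through the log transform
#' (delta method), truncated at zero.
#'
#' @param panel A [simulate_dpcr_panel()] result, or any list with
#'   `positive`, `n_partitions`, `partition_volume_nl`, `dilution_factor`.
#' @return An object of class `dpcr_result`: list with `lambda`,
#'   `molecules`, `molecules_ci`, `concentration` (copies/uL of the
#'   original sample), `concentration_ci`, and the panel geometry.
#' @export
dpcr_estimate <- function(panel) {
  k <- panel$positive
  n <- panel$n_partitions
  if (k > n) stop("positive count exceeds partition count", call. = FALSE)
  if (k < 0) stop("positive count must be >= 0", call. = FALSE)
  if (k == n) {
    stop("saturated panel (all partitions positive): lambda is unbounded; ",
         "dilute the sample", call. = FALSE)
  }
  p <- k / n
  lambda <- -log(1 - p)
  molecules <- n * lambda
  se_lambda <- if (k == 0) 0 else sqrt(p / (n * (1 - p)))
  ci <- pmax(n * (lambda + c(-1, 1) * 1.96 * se_lambda), 0)
  panel_volume_ul <- n * panel$partition_volume_nl * 1e-3
  scale <- panel$dilution_factor / panel_volume_ul
  structure(list(n_partitions = n, positive = k, lambda = lambda,
                 molecules = molecules, molecules_ci = ci,
                 concentration = molecules * scale,
                 concentration_ci = ci * scale,
                 partition_volume_nl = panel$partition_volume_nl,
                 dilution_factor = panel$dilution_factor),
            class = "dpcr_result")
}

#' @export
print.dpcr_result <- function(x, ...) {
  cat(sprintf("<dpcr_result> k=%d/%d, lambda=%.4f, molecules=%.1f [%.1f, %.1f], %.1f copies/uL\n",
              x$positive, x$n_partitions, x$lambda, x$molecules,
              x$molecules_ci[1], x$molecules_ci[2], x$concentration))
  invisible(x)
}

#' Aggregate replicate dPCR estimates
#'
#' @param results List of [dpcr_estimate()] results (replicate panels of
#'   the same sample).
#' @param conf_level Confidence level of the t-based interval (default
#'   0.95).
#' @return A list with `mean_concentration`, `ci` (t interval across
#'   replicates; `NA` with `ci_available = FALSE` for a single replicate),
#'   `n_replicates` and the per-replicate concentrations.
#' @export
aggregate_dpcr <- function(results, conf_level = 0.95) {
  conc <- vapply(results, function(r) r$concentration, numeric(1))
  n <- length(conc)
  if (n >= 2) {
    half <- qt(1 - (1 - conf_level) / 2, n - 1) * sd(conc) / sqrt(n)
    ci <- mean(conc) + c(-1, 1) * half
    avail <- TRUE
  } else {
    ci <- c(NA_real_, NA_real_)
    avail <- FALSE
  }
  list(mean_concentration = mean(conc), ci = ci, ci_available = avail,
       n_replicates = n, concentrations = conc)
}

#' Simulate triplicate dPCR quantification of every community member
#'
#' Emulates the wet-lab workflow: each species' assay is pre-diluted so the
#' panel sits in the quantifiable occupancy range (the loaded molecule
#' count targets `target_molecules` and is Poisson-distributed around the
#' diluted expectation), measured on a partition panel in `n_replicates`
#' replicates, Poisson-corrected, and scaled back through the pre-dilution
#' and the sample-in-reaction dilution to copies/uL of the original
#' material.
#'
#' @param community A [community_definition()].
#' @param n_replicates Replicate panels per species (default 3).
#' @param target_molecules Target loaded molecules per panel (default 385,
#'   i.e. mean occupancy ~0.5 on a 770-partition chip).
#' @param n_partitions,partition_volume_nl,dilution_factor Panel geometry,
#'   see [simulate_dpcr_panel()].
#' @param seed Integer seed.
#' @return A list with `estimates` (data.frame: species,
#'   true_copies_per_ul, mean_copies_per_ul, ci_low, ci_high),
#'   `log10_replicates` (species x replicate matrix of log10 copies/uL) and
#'   `replicates` (same, linear scale).
#' @export
dpcr_quantify_community <- function(community, n_replicates = 3,
                                    target_molecules = 385,
                                    n_partitions = 770,
                                    partition_volume_nl = 0.84,
                                    dilution_factor = 4 / 1.2, seed = 1) {
  members <- community$members
  panel_volume_ul <- n_partitions * partition_volume_nl * 1e-3
  est <- matrix(NA_real_, nrow(members), n_replicates,
                dimnames = list(members$name, paste0("rep", seq_len(n_replicates))))
  for (i in seq_len(nrow(members))) {
    conc_reaction <- members$true_copies_per_ul[i] / dilution_factor
    expected_loaded <- conc_reaction * panel_volume_ul
    predilution <- max(1, expected_loaded / target_molecules)
    for (r in seq_len(n_replicates)) {
      s <- derive_seed(seed, 900, i, r)
      set.seed(s)
      loaded <- rpois(1, expected_loaded / predilution)
      panel <- simulate_dpcr_panel(loaded, n_partitions, partition_volume_nl,
                                   dilution_factor, seed = derive_seed(s, 1))
      est[i, r] <- dpcr_estimate(panel)$concentration * predilution
    }
  }
  agg <- t(apply(est, 1, function(x) {
    a <- aggregate_dpcr(lapply(x, function(v) list(concentration = v)))
    c(a$mean_concentration, a$ci)
  }))
  list(estimates = data.frame(species = members$name,
                              true_copies_per_ul = members$true_copies_per_ul,
                              mean_copies_per_ul = agg[, 1],
                              ci_low = agg[, 2], ci_high = agg[, 3],
                              stringsAsFactors = FALSE, row.names = NULL),
       log10_replicates = log10(est), replicates = est)
}
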
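# Non-sequencing measurement simulators: microfluidic digital PCR panels
# (770 x 0.84 nL partitions) and fluorometric mass readings.

#' Simulate a digital PCR panel
#'
#' Each loaded target molecule falls into one of `n_partitions` partitions
#' uniformly and independently; a partition is positive if it holds at
#' least one molecule (a partition may hold several, which is what the
#' downstream Poisson correction accounts for).
#'
#' @param true_molecules_loaded Number of target molecules loaded (>= 0).
#' @param n_partitions Number of partitions (default 770).
#' @param partition_volume_nl Partition volume in nanolitres (default
#'   0.84).
#' @param dilution_factor Sample-in-reaction dilution factor carried along
#'   for concentration bookkeeping (default 4/1.2: 1.2 uL of sample in a
#'   4 uL reaction).
#' @param seed Integer seed.
#' @return An object of class `dpcr_panel`: list with `n_partitions`,
#'   `partition_volume_nl`, `positive` (count k of positive partitions) and
#'   `dilution_factor`.
#' @export
simulate_dpcr_panel <- function(true_molecules_loaded, n_partitions = 770,
                                partition_volume_nl = 0.84,
                                dilution_factor = 4 / 1.2, seed = 1) {
  stopifnot(true_molecules_loaded >= 0, n_partitions > 0,
            partition_volume_nl > 0)
  set.seed(seed)
  k <- if (true_molecules_loaded == 0) {
    0L
  } else {
    length(unique(sample.int(n_partitions, true_molecules_loaded,
                             replace = TRUE)))
  }
  structure(list(n_partitions = as.integer(n_partitions),
                 partition_volume_nl = partition_volume_nl,
                 positive = as.integer(k),
                 dilution_factor = dilution_factor),
            class = "dpcr_panel")
}

#' @export
print.dpcr_panel <- function(x, ...) {
  cat(sprintf("<dpcr_panel> %d/%d positive partitions (%.2f nL each)\n",
              x$positive, x$n_partitions, x$partition_volume_nl))
  invisible(x)
}

#' Simulate fluorometric quantification of a community
#'
#' Each species' true mass concentration (ng/uL, derived from its true
#' genome copies via [copies_to_mass()]) is observed through a
#' multiplicative species-specific bias factor and mean-one lognormal
#' measurement noise, in triplicate, with the replicate mean reported.
#' A bias factor of 3 emulates the ~3-fold fluorometry/dPCR discordance
#' observed for one community member.
#'
#' @param community A [community_definition()].
#' @param bias_factor Multiplicative bias per species; scalar or named
#'   vector over species (default 1 = unbiased).
#' @param cv_noise Coefficient of variation of the lognormal measurement
#'   noise (default 0.05).
#' @param n_replicates Replicate measurements per species (default 3).
#' @param seed Integer seed.
#' @return A list of class `fluorometry_result` with `readings` (species x
#'   replicate matrix, ng/uL), `mean_ng_per_ul`, `copies_per_ul` (copies
#'   recovered from the mean reading) and `true_mass_ng_per_ul`.
#' @export
simulate_fluorometry <- function(community, bias_factor = 1, cv_noise = 0.05,
                                 n_replicates = 3, seed = 1) {
  stopifnot(all(bias_factor > 0), cv_noise >= 0, n_replicates >= 1)
  members <- community$members
  bias <- rep(1, nrow(members))
  names(bias) <- members$name
  if (!is.null(names(bias_factor))) {
    unknown <- setdiff(names(bias_factor), members$name)
    if (length(unknown)) stop("unknown species: ", unknown[1], call. = FALSE)
    bias[names(bias_factor)] <- bias_factor
  } else {
    bias[] <- bias_factor
  }
  set.seed(seed)
  true_mass <- copies_to_mass(members$true_copies_per_ul, members$genome_length)
  sdlog <- sqrt(log(1 + cv_noise^2))
  noise <- matrix(exp(rnorm(nrow(members) * n_replicates, -sdlog^2 / 2, sdlog)),
                  nrow = nrow(members))
  readings <- true_mass * bias * noise
  dimnames(readings) <- list(members$name, paste0("rep", seq_len(n_replicates)))
  mean_ng <- rowMeans(readings)
  structure(list(readings = readings, mean_ng_per_ul = mean_ng,
                 copies_per_ul = mass_to_copies(mean_ng, members$genome_length),
                 true_mass_ng_per_ul = setNames(true_mass, members$name)),
            class = "fluorometry_result")
}
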
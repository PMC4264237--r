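# Precision and method-comparison statistics: percent coefficient of
# variation across replicates, bootstrap subsampling precision curves, and
# fluorometry-vs-dPCR style method comparisons (Welch t-tests with
# Bonferroni correction; OLS slope tests against 0 and 1).

#' Percent coefficient of variation
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation. With triplicates the n-1 choice matters and is deliberate.
#'
#' @param values At least two replicate measurements with non-zero mean.
#' @return The %CV (numeric scalar).
#' @export
percent_cv <- function(values) {
  if (length(values) < 2) stop("percent_cv needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("percent_cv undefined for zero mean", call. = FALSE)
  100 * sd(values) / m
}

#' Draw a bootstrap subsample of reads
#'
#' Samples exactly `n` reads with replacement, uniformly over the read set;
#' expected draws from the pair-1/pair-2/unpaired streams are thereby
#' proportional to the stream sizes.
#'
#' @param reads Data frame of reads (any columns; rows are resampled).
#' @param n Subsample size (>= 1).
#' @param seed Integer seed.
#' @return A data frame of `n` resampled rows.
#' @export
bootstrap_subsample <- function(reads, n, seed = 1) {
  if (nrow(reads) == 0) stop("empty read set", call. = FALSE)
  stopifnot(n >= 1)
  set.seed(seed)
  reads[sample.int(nrow(reads), n, replace = TRUE), , drop = FALSE]
}

#' Bootstrap subsampling precision curve
#'
#' Measures how abundance-estimate precision depends on sequencing depth:
#' filtered reads are assigned once (assignment is deterministic per read,
#' so resampling reads and re-running assignment is equivalent to
#' resampling the per-read assignments), then for each subsample size `n`,
#' `B` bootstrap subsamples are drawn with replacement, normalised, and
#' summarised per species by mean abundance and %CV. Per-(n, b) seeds are
#' derived from the master seed by a counter scheme, so the curve is fully
#' reproducible.
#'
#' @param reads Filtered reads (data frame with `id`, `bases`).
#' @param ref A [build_reference()] result.
#' @param community A [community_definition()].
#' @param sizes Subsample sizes (default the published ladder 500, 1000,
#'   2500, 5000, 10000, 30000).
#' @param B Subsamples per size (default 1000).
#' @param db Reference records to assign against (default `"genomes"`).
#' @param normalization Normalisation mode (default `"genome_size"`).
#' @param min_support Minimum support for the full-data assignment
#'   (default 1: the WGS pipeline reports raw alignment counts).
#' @param top_fraction,k Assignment parameters, see [assign_reads()].
#' @param seed Master integer seed.
#' @return An object of class `bootstrap_report`: list with `table`
#'   (data.frame: n, species, mean_percent, cv_percent, full_percent),
#'   `full_profile` (the full-data [normalize_counts()] profile), `B`,
#'   `sizes` and `assignment` (the full-data per-read assignment).
#' @export
bootstrap_precision_curve <- function(reads, ref, community,
                                      sizes = c(500, 1000, 2500, 5000, 10000, 30000),
                                      B = 1000, db = "genomes",
                                      normalization = "genome_size",
                                      min_support = 1, top_fraction = 0.01,
                                      k = 12, seed = 1) {
  stopifnot(all(sizes >= 1), B >= 2, nrow(reads) > 0)
  asg <- assign_reads(reads, ref, db = db, top_fraction = top_fraction,
                      min_support = min_support, rank = "species", k = k)
  members <- community$members
  labels <- match(asg$per_read$taxon, members$name)  # NA = not species-level
  norm_div <- switch(normalization,
                     rrn_copy_number = members$rrn_copies,
                     genome_size = members$genome_length,
                     none = rep(1, nrow(members)))
  full_counts <- tabulate(labels, nbins = nrow(members))
  full_profile <- normalize_counts(setNames(full_counts, members$name),
                                   community, mode = normalization)

  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    pct <- matrix(NA_real_, B, nrow(members))
    for (b in seq_len(B)) {
      set.seed(derive_seed(seed, 700, si, b))
      idx <- sample.int(length(labels), n, replace = TRUE)
      counts <- tabulate(labels[idx], nbins = nrow(members))
      q <- counts / norm_div
      pct[b, ] <- 100 * q / sum(q)
    }
    rows[[si]] <- data.frame(
      n = n, species = members$name,
      mean_percent = colMeans(pct),
      sd_percent = apply(pct, 2, sd),
      cv_percent = ifelse(colMeans(pct) > 0,
                          100 * apply(pct, 2, sd) / colMeans(pct), NA_real_),
      full_percent = full_profile$percent, stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), full_profile = full_profile,
                 B = B, sizes = sizes, assignment = asg, seed = seed),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report> %d sizes (%s), B=%d\n", length(x$sizes),
              paste(x$sizes, collapse = ", "), x$B))
  invisible(x)
}

#' Compare two quantification methods per species
#'
#' Per species, a Welch two-sample t-test on replicate log10 copy numbers,
#' with Bonferroni-adjusted significance calls (adjusted alpha =
#' `alpha / n_species`) and the fold-difference `10^(mean_a - mean_b)`.
#'
#' @param method_a,method_b Species x replicate matrices of log10 copy
#'   numbers with matching row names (replicate counts may differ).
#' @param alpha Family-wise significance level (default 0.05).
#' @return An object of class `comparison_report`: data.frame with
#'   `species`, `mean_a`, `mean_b`, `fold_difference`, `p_value`,
#'   `significant`, `testable`; attributes `alpha` and `bonferroni_alpha`.
#' @export
compare_methods <- function(method_a, method_b, alpha = 0.05) {
  stopifnot(identical(rownames(method_a), rownames(method_b)))
  species <- rownames(method_a)
  n_species <- length(species)
  adj_alpha <- alpha / n_species
  res <- lapply(species, function(sp) {
    a <- method_a[sp, ]; b <- method_b[sp, ]
    testable <- sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2
    p <- NA_real_
    if (testable) {
      degenerate <- isTRUE(all.equal(var(a), 0)) && isTRUE(all.equal(var(b), 0))
      p <- if (degenerate) {
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        t.test(a, b)$p.value
      }
    }
    data.frame(species = sp, mean_a = mean(a), mean_b = mean(b),
               fold_difference = 10^(mean(a) - mean(b)), p_value = p,
               significant = !is.na(p) & p < adj_alpha, testable = testable,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res), alpha = alpha, bonferroni_alpha = adj_alpha,
            class = c("comparison_report", "data.frame"))
}

#' Test an OLS slope against 0 and against 1
#'
#' Ordinary least-squares regression of `y` on `x` with t-tests of the
#' slope against 0 and against 1 on n-2 degrees of freedom (the Figure-1
#' style check that two quantification methods agree: the slope should
#' differ from 0 but not from 1).
#'
#' @param x,y Paired per-species values (e.g. log10 mean copy numbers by
#'   two methods); at least 3 points, `x` non-constant.
#' @return A list with `slope`, `intercept`, `se`, `p_zero` (H0: slope =
#'   0), `p_one` (H0: slope = 1) and `df`.
#' @export
slope_test <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) {
    stop("slope_test needs >= 3 paired points", call. = FALSE)
  }
  if (var(x) == 0) stop("slope_test undefined for constant x", call. = FALSE)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  se <- sqrt(sum(fit$residuals^2) / fit$df.residual / sum((x - mean(x))^2))
  # an exact linear fit leaves se at floating-point dust: treat it as zero
  degenerate <- se <= 1e-10 * (abs(slope) + 1)
  p_vs <- function(target) {
    if (degenerate) {
      if (isTRUE(all.equal(slope, target))) 1 else 0
    } else {
      2 * pt(-abs((slope - target) / se), fit$df.residual)
    }
  }
  p_zero <- p_vs(0)
  p_one <- p_vs(1)
  list(slope = slope, intercept = unname(coef(fit)[1]), se = se,
       p_zero = p_zero, p_one = p_one, df = fit$df.residual)
}

#' Per-species %CV matrix across replicate abundance profiles
#'
#' The Table-1-shaped precision summary: rows are species (Gram-negative
#' then Gram-positive, by decreasing abundance), columns are strategies,
#' with a final per-strategy average row (arithmetic mean of the
#' per-species CVs, NA cells dropped).
#'
#' @param profiles Named list (one element per strategy) of lists of
#'   [normalize_counts()] profiles (one per replicate, >= 2).
#' @param community A [community_definition()].
#' @return An object of class `precision_report`: list with `cv` (species
#'   x strategy matrix of %CV), `average` (named per-strategy mean %CV)
#'   and `n_replicates`.
#' @export
precision_report <- function(profiles, community) {
  members <- community$members
  strategies <- names(profiles)
  cv <- matrix(NA_real_, nrow(members), length(strategies),
               dimnames = list(members$name, strategies))
  for (s in strategies) {
    reps <- profiles[[s]]
    if (length(reps) < 2) {
      stop("precision_report needs >= 2 replicate profiles for strategy '",
           s, "'", call. = FALSE)
    }
    mat <- vapply(reps, function(p) p$percent[match(members$name, p$species)],
                  numeric(nrow(members)))
    cv[, s] <- apply(mat, 1, function(v) {
      if (mean(v) == 0) NA_real_ else 100 * sd(v) / mean(v)
    })
  }
  structure(list(cv = cv,
                 average = apply(cv, 2, mean, na.rm = TRUE),
                 n_replicates = lengths(profiles)),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report> %CV across replicates\n")
  print(round(rbind(x$cv, Average = x$average), 1))
  invisible(x)
}
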
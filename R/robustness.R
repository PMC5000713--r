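# Replicate-based assay robustness: per-population coefficient of variation
# across independently processed replicates, the <100-event validity filter,
# and the CV-distribution summary.

#' Coefficient of variation of replicate measurements
#'
#' `CV (%) = sample standard deviation / mean x 100`, using the n-1
#' denominator.
#'
#' @param values numeric vector of replicate measurements (>= 2 values,
#'   non-zero mean).
#' @return CV in percent.
#' @export
cv <- function(values) {
  if (length(values) < 2L)
    stop("cv() needs at least 2 replicate values")
  m <- mean(values)
  if (m == 0) stop("cv() undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Validity filter on replicate event counts
#'
#' A population is excluded from interpretation when it consists of fewer
#' than `min_events` events; with several replicates the default (strictest)
#' rule invalidates a population if *any* replicate falls below the
#' threshold, the alternative rule uses the replicate mean.
#'
#' @param counts numeric vector (one population) or matrix/data.frame
#'   (populations x replicates) of event counts.
#' @param min_events inclusion threshold; counts of exactly `min_events`
#'   are valid ("less than 100" excludes only < 100).
#' @param rule `"any"` or `"mean"`.
#' @return logical vector, `TRUE` = valid.
#' @export
validity_filter <- function(counts, min_events = 100, rule = c("any", "mean")) {
  rule <- match.arg(rule)
  m <- as.matrix(counts)
  if (is.vector(counts)) m <- matrix(counts, nrow = 1)
  if (rule == "any") apply(m, 1, function(x) all(x >= min_events))
  else rowMeans(m) >= min_events
}

#' Bin the CV distribution of valid populations
#'
#' Fractions of populations with CV below 5%, below 10% (cumulative),
#' in `[10, 15)` and at or above 15%. Boundary values fall into the upper
#' band (a CV of exactly 5 is not "below 5").
#'
#' @param cvs numeric vector of CVs (percent) of the valid populations.
#' @return named list: `pct_lt5`, `pct_lt10` (both cumulative percentages),
#'   `n_10_15`, `n_ge15` (population counts), `n` (total).
#' @export
cv_summary <- function(cvs) {
  if (length(cvs) == 0L) stop("cv_summary() needs at least one valid population")
  list(pct_lt5 = 100 * mean(cvs < 5),
       pct_lt10 = 100 * mean(cvs < 10),
       n_10_15 = sum(cvs >= 10 & cvs < 15),
       n_ge15 = sum(cvs >= 15),
       n = length(cvs))
}

#' Closed-form counting-noise CV
#'
#' Expected CV (percent) of a population fraction `p` estimated from `n`
#' events under pure multinomial counting noise:
#' `100 x sqrt((1 - p) / (p x n))`.
#'
#' @param p population fraction of the denominator.
#' @param n denominator event count.
#' @return expected CV in percent.
#' @export
binomial_cv <- function(p, n) 100 * sqrt((1 - p) / (p * n))

#' Replicate simulation experiment
#'
#' Simulates `n_replicates` independent acquisitions of all selected panels
#' from one donor profile, runs the full pipeline on each replicate, and
#' summarizes per-population CVs — the synthetic analogue of a processing-
#' robustness experiment. Between replicates the leaf-population
#' frequencies are jittered by a lognormal factor (`freq_sdlog = 0` gives
#' pure counting noise); each replicate uses an independent random
#' substream derived from `seed`.
#'
#' CVs are computed on each population's percent-of-All-Cells value
#' (populations are matched across replicates by panel and name; the bead
#' population uses its mean effective count).
#'
#' @param profile donor profile.
#' @param n_replicates number of replicates.
#' @param n_events events per panel acquisition.
#' @param freq_sdlog lognormal sd of the inter-replicate frequency jitter.
#' @param seed master seed.
#' @param replicate_seeds optional explicit per-replicate seeds (length
#'   `n_replicates`); giving every replicate the same seed reproduces the
#'   identical acquisition, so all CVs collapse to zero.
#' @param schemas panel schemas to run (default all 12).
#' @param config a [diob_config()].
#' @param min_events validity threshold.
#' @return list of class `robustness_summary`: `populations` (data.frame
#'   with per-replicate values, mean, CV, min event count, validity),
#'   `summary` (the [cv_summary()] bins over valid populations), and counts
#'   `n_total`, `n_excluded`, `n_valid`.
#' @export
replicate_experiment <- function(profile = build_default_profile(),
                                 n_replicates = 3, n_events = 50000,
                                 freq_sdlog = 0.02, seed = 1L,
                                 replicate_seeds = NULL,
                                 schemas = build_diob_schema(),
                                 config = diob_config(), min_events = 100) {
  stopifnot(n_replicates >= 2)
  if (!is.null(replicate_seeds))
    stopifnot(length(replicate_seeds) == n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    prof_r <- profile
    rep_seed <- if (!is.null(replicate_seeds)) as.integer(replicate_seeds[r])
                else (as.integer(seed) * 131L + r * 7919L) %% 2147483647L
    if (freq_sdlog > 0) {
      set.seed(rep_seed)
      f <- population_frequencies(profile)
      f <- f * exp(stats::rnorm(length(f), 0, freq_sdlog))
      f <- f / sum(f)
      for (nm in names(f)) prof_r$populations[[nm]]$freq <- f[[nm]]
    }
    run <- run_pipeline(run_config(panels = names(schemas), profile = prof_r,
                                   seed = rep_seed, n_events = n_events,
                                   schemas = schemas, config = config))
    reps[[r]] <- run$populations
  }

  key <- paste(reps[[1]]$panel, reps[[1]]$population, sep = " | ")
  vals <- sapply(reps, function(df) {
    stopifnot(identical(paste(df$panel, df$population, sep = " | "), key))
    ifelse(df$source == "beads", df$n_events, df$pct_all)
  })
  counts <- sapply(reps, `[[`, "n_events")
  min_counts <- apply(counts, 1, min)
  valid <- validity_filter(counts, min_events = min_events)
  cvs <- apply(vals, 1, function(v) {
    if (mean(v) == 0) NA_real_ else cv(v)
  })
  valid <- valid & !is.na(cvs)

  populations <- data.frame(
    panel = reps[[1]]$panel, population = reps[[1]]$population,
    source = reps[[1]]$source, stringsAsFactors = FALSE)
  for (r in seq_len(n_replicates)) populations[[paste0("rep", r)]] <- vals[, r]
  populations$mean <- rowMeans(vals)
  populations$cv <- cvs
  populations$min_events <- min_counts
  populations$valid <- valid

  structure(list(populations = populations,
                 summary = cv_summary(cvs[valid]),
                 n_total = nrow(populations),
                 n_excluded = sum(!valid),
                 n_valid = sum(valid)),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("robustness_summary: %d populations, %d valid (>= threshold events)\n",
              x$n_total, x$n_valid))
  cat(sprintf("  CV < 5%%: %.1f%%   CV < 10%%: %.1f%%   10-15%%: %d   >= 15%%: %d\n",
              s$pct_lt5, s$pct_lt10, s$n_10_15, s$n_ge15))
  invisible(x)
}
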
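#' Pseudo-colony resampling of behavioural variation
#'
#' Sampling-effect control for group-size comparisons of within-colony
#' variation: in each iteration, a pseudo-colony of `subsample_size` members
#' is drawn without replacement from every size-`source_size` colony, the
#' sample SD of each pseudo-colony's scores is computed, and the SDs are
#' averaged across pseudo-colonies. The 95% confidence interval is the
#' (2.5th, 97.5th) percentile pair of the iteration means (closed interval).
#'
#' When the number of distinct subsets per colony is modest (up to
#' `choose(8, 4) = 70` in the default design) all subset SDs are enumerated
#' once and iterations draw uniformly among them, which is distributionally
#' identical to re-sampling members and much faster.
#'
#' @param records defence-record tibble ([defence_records()]).
#' @param design design tibble with `colony_id`, `group_size`.
#' @param source_size size of the colonies resampled from (default 8).
#' @param subsample_size pseudo-colony size (default 4).
#' @param n_iterations number of resampling iterations (default 1000).
#' @param trial which score stratum to resample (default `"pooled"`, the
#'   across-trials scores).
#' @param seed optional integer; when given, results are reproducible.
#' @return An object of class `antdol_resample`: a list with
#'   `iteration_means`, `ci_low`, `ci_high`, `n_iterations`,
#'   `subsample_size`, `source_size`, `n_colonies`, `trial`.
#' @export
resample_variation <- function(records, design, source_size = 8,
                               subsample_size = 4, n_iterations = 1000,
                               trial = "pooled", seed = NULL) {
  stopifnot(subsample_size >= 2, subsample_size < source_size,
            n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  large <- design$colony_id[design$group_size == source_size]
  if (length(large) == 0) {
    stop("no colonies of size ", source_size, " in the design", call. = FALSE)
  }
  sel <- records[records$trial == trial & records$colony_id %in% large, ]
  scores <- split(sel$score, sel$colony_id)
  sizes <- vapply(scores, length, integer(1))
  if (any(sizes != source_size)) {
    stop("colony with ", paste(unique(sizes[sizes != source_size]),
                               collapse = ", "),
         " member scores; expected exactly ", source_size, call. = FALSE)
  }
  n_subsets <- choose(source_size, subsample_size)
  if (n_subsets <= 1e5) {
    combos <- combn(source_size, subsample_size)
    subset_sds <- vapply(scores, function(s) {
      apply(combos, 2, function(idx) sd(s[idx]))
    }, numeric(ncol(combos)))          # n_subsets x n_colonies
    subset_sds <- matrix(subset_sds, nrow = ncol(combos))
    picks <- matrix(
      sample.int(ncol(combos), n_iterations * length(scores), replace = TRUE),
      nrow = length(scores)
    )
    per_colony <- matrix(
      subset_sds[cbind(as.vector(picks),
                       rep(seq_along(scores), n_iterations))],
      nrow = length(scores)
    )
    iteration_means <- colMeans(per_colony)
  } else {
    iteration_means <- vapply(seq_len(n_iterations), function(i) {
      mean(vapply(scores, function(s) {
        sd(s[sample.int(source_size, subsample_size)])
      }, numeric(1)))
    }, numeric(1))
  }
  ci <- unname(quantile(iteration_means, c(0.025, 0.975)))
  structure(
    list(
      iteration_means = iteration_means,
      ci_low = ci[1], ci_high = ci[2],
      n_iterations = n_iterations,
      subsample_size = subsample_size,
      source_size = source_size,
      n_colonies = length(scores),
      trial = trial
    ),
    class = "antdol_resample"
  )
}

#' @export
print.antdol_resample <- function(x, ...) {
  cat(sprintf(
    "<antdol_resample> %d iterations, %d colonies of %d -> pseudo-colonies of %d\n",
    x$n_iterations, x$n_colonies, x$source_size, x$subsample_size))
  cat(sprintf("  95%% CI of mean variation: (%.4f, %.4f)\n",
              x$ci_low, x$ci_high))
  if (!is.null(x$observed_small_mean)) {
    cat(sprintf("  observed small-colony mean: %.4f (%s CI)\n",
                x$observed_small_mean,
                if (x$flag) "outside" else "inside"))
  }
  invisible(x)
}

#' Compare observed small-colony variation with the resampling CI
#'
#' Computes the mean behavioural variation of the observed small colonies
#' (same trial stratum as the resampling) and flags whether it falls outside
#' the closed resampling confidence interval — evidence that the group-size
#' difference in variation is not a sampling artefact.
#'
#' @param result an `antdol_resample` from [resample_variation()].
#' @param records defence-record tibble.
#' @param design design tibble.
#' @param small_size observed small-colony size (defaults to the result's
#'   `subsample_size`).
#' @return The `antdol_resample` with added `observed_small_mean`, `flag`
#'   (`TRUE` when the observed mean lies outside `[ci_low, ci_high]`) and
#'   `n_small_colonies`.
#' @export
compare_observed <- function(result, records, design, small_size = NULL) {
  stopifnot(inherits(result, "antdol_resample"))
  if (is.null(small_size)) small_size <- result$subsample_size
  small <- design$colony_id[design$group_size == small_size]
  if (length(small) == 0) {
    stop("no colonies of size ", small_size, " in the design", call. = FALSE)
  }
  sel <- records[records$trial == result$trial &
                   records$colony_id %in% small, ]
  vars <- vapply(split(sel$score, sel$colony_id), sd, numeric(1))
  observed <- mean(vars)
  result$observed_small_mean <- observed
  result$n_small_colonies <- length(vars)
  result$flag <- observed < result$ci_low || observed > result$ci_high
  result
}
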
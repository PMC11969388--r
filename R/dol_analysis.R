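#' Rank scores within a colony, ties sharing the lowest rank
#'
#' Ascending 1-based ranks with the "min" tie method: every member of a tie
#' group receives the smallest rank of the group, as used when displaying
#' and pooling within-colony defence ranks.
#'
#' @param score numeric scores of one colony-trial.
#' @return Integer ranks.
#' @examples
#' rank_scores(c(0, 0, 1.2, 3.4))  # 1 1 3 4
#' @export
rank_scores <- function(score) {
  rank(score, ties.method = "min")
}

#' Spearman rank correlation with a tie-corrected coefficient
#'
#' The coefficient is the Pearson correlation of average ranks (the standard
#' tie correction). The two-sided p-value uses the t-distribution
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom; for small samples an exact permutation p-value is available
#' (`p_method = "exact"`, feasible for `n <= 8`).
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param p_method `"t"` (default) or `"exact"`.
#' @return A list with `rho`, `p` and `n`. When either vector has zero
#'   variance the coefficient is undefined and both are `NA`.
#' @export
spearman_rank_test <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman requires at least 3 paired observations",
                  call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  if (p_method == "exact") {
    if (n > 8) stop("exact permutation p only supported for n <= 8",
                    call. = FALSE)
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: sorted ascending,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in input order.
#' `NA` entries are preserved and excluded from the family size.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Inter-trial consistency of defence behaviour
#'
#' Quantifies within-individual consistency: defence scores are ranked
#' within each colony in each trial (ties sharing the lowest rank), ranks
#' are pooled across the colonies of each stratum (group size, or brood
#' treatment), and a Spearman rank correlation is computed between each pair
#' of successive trials. Colonies that showed no defence behaviour (zero
#' sting events colony-wide) in both trials of a pair are excluded from that
#' pair. The family of p-values produced by one call (all trial pairs x
#' strata of one stratification) is adjusted with Benjamini-Hochberg.
#'
#' @param records defence-record tibble ([defence_records()]); only
#'   per-trial rows are used.
#' @param design design tibble (`colony_id`, `group_size`, `brood`).
#' @param stratify_by `"group_size"` or `"brood"`.
#' @param pool_ranks pool within-colony min-ranks (default, matching the
#'   displayed ranks) or raw scores before correlating.
#' @param p_method passed to [spearman_rank_test()] (`"exact"` requires
#'   every stratum-pair to have at most 8 ants, so the default t
#'   approximation is the practical choice).
#' @return A tibble with one row per stratum x trial pair: `stratum_var`,
#'   `stratum`, `trial_pair`, `rho`, `p`, `p_adj`, `n` (ants used),
#'   `n_colonies`, `computable`.
#' @export
consistency_analysis <- function(records, design,
                                 stratify_by = c("group_size", "brood"),
                                 pool_ranks = TRUE,
                                 p_method = "t") {
  stratify_by <- match.arg(stratify_by)
  per_trial <- records |>
    dplyr::filter(.data$trial != "pooled") |>
    dplyr::mutate(trial = as.integer(.data$trial))
  trials <- sort(unique(per_trial$trial))
  if (length(trials) < 2) stop("need at least two trials", call. = FALSE)
  ranked <- per_trial |>
    dplyr::group_by(.data$colony_id, .data$trial) |>
    dplyr::mutate(rank = rank_scores(.data$score)) |>
    dplyr::ungroup() |>
    dplyr::left_join(design[, c("colony_id", "group_size", "brood")],
                     by = "colony_id")
  if (anyNA(ranked$group_size)) {
    stop("record colony missing from design", call. = FALSE)
  }
  colony_stings <- per_trial |>
    dplyr::group_by(.data$colony_id, .data$trial) |>
    dplyr::summarise(stings = sum(.data$n_stings), .groups = "drop")
  strata <- sort(unique(ranked[[stratify_by]]))
  rows <- list()
  for (s in strata) {
    for (t1 in trials[-length(trials)]) {
      t2 <- t1 + 1L
      if (!t2 %in% trials) next
      in_stratum <- unique(ranked$colony_id[ranked[[stratify_by]] == s])
      active <- colony_stings |>
        dplyr::filter(.data$colony_id %in% in_stratum,
                      .data$trial %in% c(t1, t2)) |>
        dplyr::group_by(.data$colony_id) |>
        dplyr::summarise(defended = sum(.data$stings) > 0, .groups = "drop")
      keep <- active$colony_id[active$defended]
      value_col <- if (pool_ranks) "rank" else "score"
      a <- ranked |>
        dplyr::filter(.data$colony_id %in% keep, .data$trial == t1) |>
        dplyr::arrange(.data$colony_id, .data$ant_id)
      b <- ranked |>
        dplyr::filter(.data$colony_id %in% keep, .data$trial == t2) |>
        dplyr::arrange(.data$colony_id, .data$ant_id)
      stopifnot(identical(a$ant_id, b$ant_id))
      n <- nrow(a)
      if (n >= 3) {
        st <- spearman_rank_test(a[[value_col]], b[[value_col]],
                                 p_method = p_method)
        rho <- st$rho
        p <- st$p
        computable <- !is.na(rho)
      } else {
        rho <- NA_real_
        p <- NA_real_
        computable <- FALSE
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum_var = stratify_by,
        stratum = as.character(s),
        trial_pair = sprintf("%d-%d", t1, t2),
        rho = rho, p = p, n = n,
        n_colonies = length(keep),
        computable = computable
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  dplyr::select(out, "stratum_var", "stratum", "trial_pair", "rho", "p",
                "p_adj", "n", "n_colonies", "computable")
}

#' Within-colony behavioural variation
#'
#' The sample standard deviation (n - 1 denominator) of member defence
#' scores within each colony, for each trial stratum present in the records
#' (per-trial and `"pooled"`), together with the colony mean score.
#'
#' @param records defence-record tibble ([defence_records()]).
#' @return A tibble of `colony_id`, `trial`, `variation`, `mean_score`,
#'   `n_ants`; `variation` is `NA` for colonies of a single ant.
#' @export
behavioural_variation <- function(records) {
  records |>
    dplyr::group_by(.data$colony_id, .data$trial) |>
    dplyr::summarise(
      variation = if (dplyr::n() >= 2) sd(.data$score) else NA_real_,
      mean_score = mean(.data$score),
      n_ants = dplyr::n(),
      .groups = "drop"
    )
}

#' Tidy tables for external mixed-model fitting
#'
#' Assembles the model-ready exports: a colony-trial table (behavioural
#' variation, mean score, group size, brood, trial) for variation models,
#' and a per-ant table (baseline entropy and activity metrics, trial-1
#' encounters and score, pooled score) for syndrome analyses. Fitting
#' itself (GLMM/LM, model reduction, post hoc tests) is left to standard
#' tools on these tables.
#'
#' @param metrics baseline metrics tibble ([baseline_metrics()]), or `NULL`
#'   to omit baseline columns.
#' @param records defence-record tibble ([defence_records()]).
#' @param design design tibble.
#' @return A list of tibbles `colony_trial` and `ants`.
#' @export
assemble_model_tables <- function(metrics, records, design) {
  summaries <- behavioural_variation(records) |>
    dplyr::filter(.data$trial != "pooled")
  colony_trial <- summaries |>
    dplyr::left_join(design, by = "colony_id")
  if (anyNA(colony_trial$group_size)) {
    stop("summary colony missing from design", call. = FALSE)
  }
  t1 <- records |>
    dplyr::filter(.data$trial == "1") |>
    dplyr::select("colony_id", "ant_id",
                  encounters_t1 = "n_encounters", score_t1 = "score")
  pooled <- records |>
    dplyr::filter(.data$trial == "pooled") |>
    dplyr::select("colony_id", "ant_id", score_pooled = "score")
  ants <- dplyr::full_join(t1, pooled, by = c("colony_id", "ant_id"))
  if (!is.null(metrics)) {
    ants <- dplyr::full_join(
      ants,
      metrics[, c("colony_id", "ant_id", "H", "prop_active", "mean_bout")],
      by = c("colony_id", "ant_id")
    )
    if (anyNA(ants$score_t1) || anyNA(ants$H)) {
      stop("unmatched ant ids between metrics and records", call. = FALSE)
    }
  }
  ants <- dplyr::left_join(ants, design, by = "colony_id")
  if (anyNA(ants$group_size)) {
    stop("ant colony missing from design", call. = FALSE)
  }
  list(colony_trial = colony_trial, ants = ants)
}
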
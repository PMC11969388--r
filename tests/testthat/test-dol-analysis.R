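test_that("within-colony ranking gives ties the lowest rank", {
  expect_equal(rank_scores(c(0, 0, 1.2, 3.4)), c(1, 1, 3, 4))
  expect_equal(rank_scores(c(0, 0, 0, 0)), c(1, 1, 1, 1))
  expect_equal(rank_scores(c(5, 2, 9)), c(2, 1, 3))
})

test_that("spearman coefficient matches its closed-form examples", {
  expect_equal(spearman_rank_test(1:6, 2 * (1:6))$rho, 1)
  expect_equal(spearman_rank_test(1:6, 6:1)$rho, -1)
  st <- spearman_rank_test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(st$rho, 0.8, tolerance = 1e-12)
  # zero variance: undefined
  expect_true(is.na(spearman_rank_test(rep(1, 5), 1:5)$rho))
  expect_error(spearman_rank_test(1:2, 1:2), "at least 3")
})

test_that("spearman equals the brute-force oracle on random vectors", {
  set.seed(99)
  max_delta <- 0
  for (i in 1:1000) {
    n <- sample(3:10, 1)
    x <- sample(0:4, n, replace = TRUE) + runif(n) * sample(0:1, 1)
    y <- sample(0:4, n, replace = TRUE) + runif(n) * sample(0:1, 1)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    max_delta <- max(max_delta,
                     abs(spearman_rank_test(x, y)$rho - oracle_spearman(x, y)))
  }
  expect_lt(max_delta, 1e-12)
})

test_that("spearman agrees with the reference implementation", {
  set.seed(17)
  x <- rnorm(20)
  y <- rnorm(20)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  st <- spearman_rank_test(x, y)
  expect_equal(st$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("exact permutation p-value is consistent with the t approximation", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  ex <- spearman_rank_test(x, y, p_method = "exact")
  tt <- spearman_rank_test(x, y, p_method = "t")
  expect_equal(ex$rho, tt$rho)
  expect_gt(ex$p, 0)
  expect_lt(abs(ex$p - tt$p), 0.1)
  expect_error(spearman_rank_test(rnorm(9), rnorm(9), p_method = "exact"),
               "n <= 8")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(123)
  for (i in 1:500) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("BH output is order-invariant, monotone and bounded", {
  set.seed(5)
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  o <- sample(20)
  expect_equal(bh_adjust(p[o]), q[o])
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("behavioural variation is the sample SD of member scores", {
  rec <- tibble::tibble(
    colony_id = rep(c("C1", "C2"), each = 2), trial = "pooled",
    ant_id = paste0("A", 1:4), score = c(1.5, 1.5, 0, 2)
  )
  v <- behavioural_variation(rec)
  expect_equal(v$variation[v$colony_id == "C1"], 0)
  expect_equal(v$variation[v$colony_id == "C2"], sqrt(2))
  # brute-force definitional check on random colonies
  set.seed(7)
  for (i in 1:100) {
    s <- rnorm(sample(2:8, 1))
    rec_i <- tibble::tibble(colony_id = "C", trial = "1",
                            ant_id = as.character(seq_along(s)), score = s)
    expect_equal(behavioural_variation(rec_i)$variation,
                 sqrt(sum((s - mean(s))^2) / (length(s) - 1)),
                 tolerance = 1e-12)
  }
})

# small two-colony fixture with controllable scores per trial
fixture_records <- function(scores) {
  # scores: named list colony -> matrix [ant x trial]
  rows <- list()
  for (cid in names(scores)) {
    m <- scores[[cid]]
    for (tr in seq_len(ncol(m))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        colony_id = cid, trial = as.character(tr),
        ant_id = paste0(cid, "_A", seq_len(nrow(m))),
        n_encounters = 10L,
        n_stings = as.integer(round(pmax(m[, tr], 0))),
        sting_seconds = pmax(m[, tr], 0) * 10,
        score = m[, tr],
        norm_sting_rate = pmax(m[, tr], 0) / 10
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("perfectly consistent colonies yield rho 1", {
  m <- matrix(rep(c(0, 1, 2, 3), 3), ncol = 3)
  rec <- fixture_records(list(C1 = m, C2 = m + 1))
  design <- tibble::tibble(colony_id = c("C1", "C2"), group_size = 4L,
                           brood = "none")
  out <- consistency_analysis(rec, design, stratify_by = "group_size")
  expect_equal(out$rho, c(1, 1))
  expect_equal(out$p_adj, out$p)
  expect_equal(out$n, c(8L, 8L))
})

test_that("colonies with no defence in both trials of a pair are excluded", {
  active <- matrix(c(0, 1, 2, 3), nrow = 4, ncol = 3)
  silent <- matrix(0, nrow = 4, ncol = 3)
  silent[, 3] <- c(0, 1, 0, 2)  # defends only in trial 3
  rec <- fixture_records(list(C1 = active, C2 = silent))
  design <- tibble::tibble(colony_id = c("C1", "C2"), group_size = 4L,
                           brood = "none")
  out <- consistency_analysis(rec, design, stratify_by = "group_size")
  # pair 1-2: only C1 contributes; pair 2-3: both colonies
  expect_equal(out$n_colonies[out$trial_pair == "1-2"], 1L)
  expect_equal(out$n_colonies[out$trial_pair == "2-3"], 2L)
  expect_equal(out$n[out$trial_pair == "1-2"], 4L)
})

test_that("a fully defenceless stratum yields no computable result", {
  silent <- matrix(0, nrow = 4, ncol = 3)
  rec <- fixture_records(list(C1 = silent, C2 = silent))
  design <- tibble::tibble(colony_id = c("C1", "C2"), group_size = 4L,
                           brood = "none")
  out <- consistency_analysis(rec, design, stratify_by = "group_size")
  expect_false(any(out$computable))
  expect_true(all(is.na(out$rho)))
  expect_equal(out$n_colonies, c(0L, 0L))
})

test_that("stratification by brood produces one family of adjusted p", {
  sc <- event_scenario(seed = 19)
  ex <- simulate_experiment(sc, include_baseline = FALSE)
  rec <- defence_records(ex$events, ex$individuals[, c("colony_id", "ant_id")])
  out <- consistency_analysis(rec, ex$design, stratify_by = "brood")
  expect_equal(nrow(out), 3 * 2)  # 3 brood levels x 2 successive pairs
  expect_equal(out$p_adj, bh_adjust(out$p))
  expect_true(all(out$p_adj >= out$p, na.rm = TRUE))
})

test_that("model tables are complete and dimensioned by the design", {
  sc <- sim_scenario(n_colonies_per_treatment = 1, baseline_duration = 20,
                     seed = 23)
  ex <- simulate_experiment(sc)
  roster <- ex$individuals[, c("colony_id", "ant_id")]
  rec <- defence_records(ex$events, roster)
  m <- baseline_metrics(ex$trajectories, fps = sc$fps)
  tabs <- assemble_model_tables(m, rec, ex$design)
  expect_equal(nrow(tabs$colony_trial), nrow(ex$design) * 3)
  expect_equal(nrow(tabs$ants), nrow(roster))
  expect_true(all(c("variation", "mean_score", "group_size", "brood",
                    "trial") %in% names(tabs$colony_trial)))
  expect_true(all(c("H", "prop_active", "mean_bout", "encounters_t1",
                    "score_t1", "score_pooled") %in% names(tabs$ants)))
  expect_false(anyNA(tabs$ants$H))
  # unmatched ids are a hard error
  expect_error(assemble_model_tables(m[-1, ], rec, ex$design), "unmatched")
})
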
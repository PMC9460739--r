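# Stage binning, two-way ANOVAs against a brute-force sum-of-squares
# oracle, Tukey contrasts against a permutation oracle, stage profiles.

test_that("stage assignment bins presentation order into thirds", {
  expect_equal(as.character(assign_stage(c(1, 4, 5, 8, 9, 12))),
               c("first", "first", "middle", "middle", "last", "last"))
  expect_equal(levels(assign_stage(1)), c("first", "middle", "last"))
  expect_error(assign_stage(0), class = "eegdwt_bad_trial_index")
  expect_error(assign_stage(13), class = "eegdwt_bad_trial_index")
  expect_error(assign_stage(1, n_trials = 10), class = "eegdwt_bad_trial_index")
  # generalizes to other multiples of 3
  expect_equal(as.character(assign_stage(c(1, 2, 3), n_trials = 3)),
               c("first", "middle", "last"))
})

test_that("two-way ANOVA F statistics match the brute-force SS oracle", {
  set.seed(21)
  for (i in 1:20) {
    n_cell <- sample(2:6, 1)
    tab <- synthetic_stage_table(n_cell,
                                 mean_fun = function(cond, stage) runif(1, -1, 1))
    an <- anova_stage_condition(tab, "rel_alpha")
    oracle <- ss_anova_oracle(tab$rel_alpha,
                              factor(tab$stage, c("first", "middle", "last")),
                              tab$condition)
    expect_equal(an$terms$statistic, oracle$F, tolerance = 1e-10)
    expect_equal(an$terms$df, oracle$df)
    expect_equal(an$residual_df, oracle$df_e)
    expect_equal(an$terms$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("returned dfs follow the balanced a x b design structure", {
  set.seed(5)
  tab <- synthetic_stage_table(7)
  an <- anova_stage_condition(tab, "tbr")
  N <- 2 * 3 * 7
  expect_equal(an$terms$df, c(3 - 1, 2 - 1, (3 - 1) * (2 - 1)))
  expect_equal(an$residual_df, N - 6)
  expect_equal(an$n, N)
})

test_that("condition x band ANOVA uses the 3 x 3 long layout", {
  set.seed(31)
  cfg <- tiny_config(seed = 31, n_participants = 1)
  ft <- cohort_features(cfg)
  ft <- ft[!ft$degenerate, ]
  an <- anova_condition_band(ft)
  expect_equal(an$terms$df[an$terms$term == "condition:band"], 4)
  expect_equal(an$terms$df[an$terms$term == "condition"], 2)
  expect_equal(an$terms$df[an$terms$term == "band"], 2)
  n_obs <- 3 * sum(!ft$degenerate)
  expect_equal(an$residual_df, n_obs - 9)

  # oracle agreement on the same long table
  long_y <- c(ft$rel_theta, ft$rel_alpha, ft$rel_beta)
  long_A <- rep(ft$condition, 3)
  long_B <- rep(c("theta", "alpha", "beta"), each = nrow(ft))
  oracle <- ss_anova_oracle(long_y, long_A, long_B)
  expect_equal(sort(an$terms$statistic), sort(oracle$F), tolerance = 1e-8)

  expect_error(anova_condition_band(ft[ft$condition == "rest", ]),
               class = "eegdwt_missing_level")
})

test_that("all-equal observations give a flagged degenerate ANOVA, not a crash", {
  tab <- synthetic_stage_table(3, sd = 0)
  tab$rel_alpha <- 0.5
  an <- anova_stage_condition(tab, "rel_alpha")
  expect_true(an$degenerate)
  expect_true(all(is.na(an$terms$statistic)))
  expect_equal(an$residual_df, nrow(tab) - 6)
})

test_that("Tukey contrasts flag exactly the separated pairs, matching a permutation oracle", {
  set.seed(77)
  # three conditions: two overlapping, one 10 pooled SDs away
  mk <- function(cond, mu, n = 30) {
    data.frame(participant_id = 1L, condition = cond, trial_index = NA,
               stage = NA, rel_theta = rnorm(n, mu, 1), degenerate = FALSE)
  }
  ft <- rbind(mk("rest", 0), mk("picking", 0.2), mk("coordination", 10))
  tk <- tukey_posthoc(ft, "theta")
  expect_equal(nrow(tk), 3)
  flagged <- tk$contrast[tk$significant]
  expect_true(all(grepl("coordination", flagged)))
  expect_equal(length(flagged), 2)

  # permutation oracle agrees on direction and significance per pair
  groups <- split(ft$rel_theta, ft$condition)
  for (i in seq_len(nrow(tk))) {
    pair <- strsplit(tk$contrast[i], "-")[[1]]
    p_perm <- perm_test(groups[[pair[1]]], groups[[pair[2]]])
    expect_equal(unname(tk$significant[i]), p_perm < 0.05 / 3)
    expect_equal(sign(tk$diff[i]),
                 sign(mean(groups[[pair[1]]]) - mean(groups[[pair[2]]])))
  }

  # identical group means -> nothing flagged, adjusted p near 1
  set.seed(8)
  ft0 <- rbind(mk("rest", 0, 50), mk("picking", 0, 50), mk("coordination", 0, 50))
  tk0 <- tukey_posthoc(ft0, "theta")
  expect_true(all(!tk0$significant))

  expect_error(tukey_posthoc(ft[ft$condition == "rest", ], "theta"),
               class = "eegdwt_missing_level")
  expect_error(tukey_posthoc(ft, "gamma"), class = "eegdwt_bad_tag")
})

test_that("stage profiles summarize 2 x 3 cell means and reject empty cells", {
  set.seed(14)
  tab <- synthetic_stage_table(10,
                               mean_fun = function(cond, stage) {
                                 if (cond == "coordination" && stage == "last") 2 else 0
                               }, sd = 0.5)
  prof <- stage_profile(tab, "rel_alpha")
  expect_equal(nrow(prof), 6)
  expect_equal(prof$n, rep(10, 6))
  co_last <- prof$mean[prof$condition == "coordination" & prof$stage == "last"]
  co_first <- prof$mean[prof$condition == "coordination" & prof$stage == "first"]
  expect_gt(co_last, co_first)

  expect_error(stage_profile(tab[!(tab$condition == "picking" & tab$stage == "last"), ],
                             "rel_alpha"),
               class = "eegdwt_empty_cell")
})

test_that("participant-aggregated variant collapses to one observation per cell", {
  set.seed(9)
  tab <- do.call(rbind, lapply(1:4, function(p) {
    t <- synthetic_stage_table(6)
    t$participant_id <- p
    t
  }))
  an <- anova_stage_condition(tab, "rel_alpha", aggregate_by_participant = TRUE)
  expect_equal(an$n, 4 * 6)
  expect_equal(an$residual_df, 4 * 6 - 6)
})
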
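test_that("mixed ANOVA matches the aov Error-strata partition on random balanced data", {
  set.seed(12)
  for (i in 1:20) {
    d <- random_anova_dataset(n_per_group = sample(3:6, 1))
    mine <- mixed_anova(d, "dv", "participant", "stopping", "value_level",
                        "knowledge")
    fa <- aov_oracle_f(d)
    for (j in seq_len(nrow(mine))) {
      rel <- min(abs(fa - mine$F[j])) / mine$F[j]
      expect_lt(rel, 1e-8)
    }
    expect_equal(nrow(mine), 7L)
  }
})

test_that("single-group within ANOVA matches aov as well", {
  set.seed(13)
  d <- random_anova_dataset(n_per_group = 8)
  d$knowledge <- NULL
  mine <- within_anova_2x4(transform(d, mean_bid_level = dv),
                           dv = "dv")
  fa <- aov_oracle_f(d, between = FALSE)
  for (j in seq_len(nrow(mine))) {
    expect_lt(min(abs(fa - mine$F[j])) / mine$F[j], 1e-8)
  }
  # 16 subjects in a single group: error df = (N - 1)(s - 1) = 15
  expect_equal(mine$df2[mine$effect == "stopping"], 15)
})

test_that("degrees of freedom follow the mixed-design pattern at n = 59", {
  set.seed(14)
  n1 <- 22
  d <- expand.grid(participant = sprintf("s%02d", 1:59),
                   stopping = c("go", "stop"), value_level = 1:4,
                   stringsAsFactors = FALSE)
  idx <- as.integer(sub("s", "", d$participant))
  d$knowledge <- ifelse(idx <= n1, "explicit", "implicit")
  d$dv <- rnorm(nrow(d))
  tab <- mixed_anova(d, "dv", "participant", "stopping", "value_level",
                     "knowledge")
  expect_equal(tab$df1[tab$effect == "value_level"], 3)
  expect_equal(tab$df2[tab$effect == "value_level"], 171)
  expect_equal(tab$df1[tab$effect == "stopping"], 1)
  expect_equal(tab$df2[tab$effect == "stopping"], 57)
  expect_equal(tab$df2[tab$effect == "knowledge"], 57)
  expect_equal(tab$df2[tab$effect == "knowledge:stopping:value_level"], 171)
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
})

test_that("adding a constant to every observation leaves all F values unchanged", {
  set.seed(16)
  d <- random_anova_dataset(n_per_group = 5)
  t1 <- mixed_anova(d, "dv", "participant", "stopping", "value_level",
                    "knowledge")
  d$dv <- d$dv + 100
  t2 <- mixed_anova(d, "dv", "participant", "stopping", "value_level",
                    "knowledge")
  expect_equal(t2$F, t1$F, tolerance = 1e-8)
  expect_equal(t2$p, t1$p, tolerance = 1e-8)
})

test_that("missing cells are refused", {
  d <- random_anova_dataset(n_per_group = 3)
  expect_error(
    mixed_anova(d[-1, ], "dv", "participant", "stopping", "value_level",
                "knowledge"),
    "exactly one observation"
  )
})

test_that("parametric p for the stopping effect agrees with a permutation oracle", {
  # 6 participants, one group; permute the within-subject stopping labels
  set.seed(17)
  d <- expand.grid(participant = sprintf("s%d", 1:6),
                   stopping = c("go", "stop"), value_level = 1:4,
                   stringsAsFactors = FALSE)
  d$dv <- rnorm(nrow(d)) + 0.8 * (d$stopping == "stop")
  stat_of <- function(dd) {
    tab <- mixed_anova(dd, "dv", "participant", "stopping", "value_level")
    tab$F[tab$effect == "stopping"]
  }
  f_obs <- stat_of(d)
  p_obs <- {
    tab <- mixed_anova(d, "dv", "participant", "stopping", "value_level")
    tab$p[tab$effect == "stopping"]
  }
  # permutation: independently swap the go/stop labels within participant
  # x value cell (the exchangeable units under the null)
  perms <- replicate(2000, {
    dd <- d
    for (s in unique(d$participant)) for (v in 1:4) {
      if (runif(1) < 0.5) {
        idx <- which(dd$participant == s & dd$value_level == v)
        dd$stopping[idx] <- rev(dd$stopping[idx])
      }
    }
    stat_of(dd)
  })
  p_perm <- mean(perms >= f_obs)
  expect_lt(abs(p_perm - p_obs), 0.05)
})
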
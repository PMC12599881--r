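test_that("per-animal aggregation fixes the object -> animal -> group order", {
  df <- data.frame(animal_id = c("a", "a", "b"), v = c(1, 3, 5))
  gm <- per_animal_aggregate(df, "v")
  expect_equal(sort(gm$per_animal$value), c(2, 5))
  expect_equal(gm$group$mean, 3.5)
  # unbalanced animals: pooling objects first would give a different answer
  expect_false(isTRUE(all.equal(gm$group$mean, mean(df$v))))
  # single animal: SEM undefined
  g1 <- per_animal_aggregate(data.frame(animal_id = "a", v = c(1, 2)), "v")
  expect_true(is.na(g1$group$sem))
  # SEM across 6 animals matches the direct formula
  set.seed(61)
  d6 <- data.frame(animal_id = rep(1:6, each = 20), v = rnorm(120))
  g6 <- per_animal_aggregate(d6, "v")
  per <- tapply(d6$v, d6$animal_id, mean)
  expect_equal(g6$group$sem, sd(per) / sqrt(6))
  expect_warning(
    per_animal_aggregate(data.frame(animal_id = c("a", "b"),
                                    v = c(1, NA)), "v"), "excluded")
})

test_that("group comparisons behave at the null and under a large shift", {
  set.seed(62)
  same <- data.frame(group = rep(c("a", "b"), each = 6),
                     value = rep(rnorm(6), 2))
  cr <- compare_groups(same, "ttest", group = "group")
  expect_gt(cr$p_value, 0.99)
  expect_equal(tidy(cr)$stars, "ns")
  shift <- data.frame(group = rep(c("a", "b"), each = 6),
                      value = c(rnorm(6), rnorm(6) + 10))
  cr2 <- compare_groups(shift, "ttest", group = "group")
  expect_lt(cr2$p_value, 0.001)
  expect_equal(tidy(cr2)$stars, "***")
})

test_that("one- and two-way designs produce adjusted Tukey comparisons", {
  set.seed(63)
  d <- data.frame(group = rep(c("a", "b", "c"), each = 6),
                  value = c(rnorm(6), rnorm(6) + 4, rnorm(6)))
  cr <- compare_groups(d, "anova1_tukey", group = "group")
  expect_equal(nrow(tidy(cr)), 3)
  expect_true(all(tidy(cr)$p_adj >= 0 & tidy(cr)$p_adj <= 1))
  d2 <- expand.grid(group = c("wt", "mut"),
                    cls = c("stationary", "anterograde", "retrograde"),
                    rep = 1:5)
  d2$value <- rnorm(nrow(d2)) + ifelse(d2$group == "mut" &
                                         d2$cls == "stationary", 5, 0)
  cr2 <- compare_groups(d2, "anova2_tukey", group = "group", factor2 = "cls")
  tk <- tidy(cr2)
  # adjustment spans all class x group contrasts; only the stationary
  # between-group contrast is highlighted
  expect_equal(nrow(tk), choose(6, 2))
  hi <- tk[tk$highlight, ]
  expect_equal(nrow(hi), 1)
  expect_match(hi$contrast, "stationary")
  expect_lt(hi$p_adj, 0.01)
  # empty cells are named in the error
  d3 <- d2[!(d2$group == "mut" & d2$cls == "retrograde"), ]
  expect_error(compare_groups(d3, "anova2_tukey", group = "group",
                              factor2 = "cls"), "mut x retrograde")
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(significance_stars(c(0.04, 0.009, 0.0009, 0.2)),
               c("*", "**", "***", "ns"))
})

test_that("type-I error of the default test is calibrated near alpha", {
  set.seed(64)
  rej <- mean(replicate(400, {
    d <- data.frame(group = rep(c("a", "b"), each = 6), value = rnorm(12))
    compare_groups(d, "ttest", group = "group")$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
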
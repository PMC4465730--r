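test_that("population margins are reproduced at the study size", {
  pop <- generate_population(547, seed = 31)
  expect_equal(nrow(pop), 547L)
  expect_lt(abs(mean(pop$physician) - 0.67), 0.05)
  expect_lt(abs(mean(pop$female) - 0.31), 0.05)
  expect_lt(abs(mean(pop$area == "us") - 0.37), 0.06)
  expect_true(all(rowSums(pop[, c("physician", "policy_maker", "executive",
                                  "researcher")]) >= 1L))
  expect_true(all(pop$age >= pop$seniority))
  expect_true(all(pop$seniority >= 0))
  expect_equal(sort(unique(pop$block)), 1:3)
  expect_lt(abs(mean(pop$age) - 50), 2)
  expect_lt(abs(mean(pop$seniority) - 23), 2)
})

test_that("degenerate margins and edge sizes behave", {
  one <- generate_population(1, seed = 4)
  expect_equal(nrow(one), 1L)
  expect_gte(sum(one[, c("physician", "policy_maker", "executive",
                         "researcher")]), 1L)
  m <- study_margins()
  m$area <- c(canada = 0, eastern_europe = 0, western_europe = 0,
              oceania = 0, us = 1)
  all_us <- generate_population(50, margins = m, seed = 4)
  expect_true(all(all_us$area == "us"))
  expect_true(all(all_us$area_us == 1L))
  m$female <- 1.5
  expect_error(generate_population(10, margins = m), "\\[0, 1\\]")
})

test_that("simulated datasets satisfy the structural invariants", {
  fx <- toy_fit_fixture()
  truth <- truth_spec(fx$base, completion = 0.8)
  for (seed in c(1L, 2L, 3L)) {
    ds <- simulate_choices(fx$design, fx$population, truth, seed = seed)
    obs <- ds$observations
    key <- paste(obs$respondent_id, obs$set_id)
    tab <- table(key)
    expect_true(all(tab == 2L))
    chosen <- tapply(obs$chosen, key, sum)
    expect_true(all(chosen == 1L))
  }
})

test_that("null preferences give symmetric choice shares", {
  fx <- toy_fit_fixture()
  truth0 <- truth_spec(setNames(rep(0, 8), names(fx$base)), completion = 1)
  pop <- generate_population(400, seed = 5, n_blocks = 1)
  ds <- simulate_choices(fx$design, pop, truth0, seed = 6)
  share <- mean(ds$observations$chosen[ds$observations$alt == 1L])
  n <- nrow(ds$observations) / 2
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / n))
})

test_that("completion thinning matches the target rate", {
  ds <- study_dataset_t()
  cs <- completion_summary(ds, 18L)
  expect_equal(cs$shown, 9846)
  expected <- 0.87 * 9846
  expect_lt(abs(cs$answered - expected), 3 * sqrt(9846 * 0.87 * 0.13))
})

test_that("a large utility gap forces the preferred alternative", {
  sch <- toy_schema(2)
  pr <- build_ordered_prior(sch, draws = 8L, seed = 1L)
  des <- optimize_design(sch, pr, 4, 2, restarts = 1, seed = 3, draws = 8)
  # craft a truth with utility difference +10 for alternative 1 of set 1
  d <- ppdce:::design_diff_matrix(des)[1L, ]
  base <- setNames(as.numeric(10 * d / sum(d * d)), coding_map(sch)$column)
  truth <- truth_spec(base, completion = 1)
  pop <- generate_population(1, seed = 1, n_blocks = 1)
  picks <- vapply(1:300, function(s) {
    ds <- simulate_choices(des, pop, truth, seed = s)
    obs <- ds$observations
    obs$chosen[obs$set_id == des$sets[[1L]]$id & obs$alt == 1L]
  }, integer(1))
  # P(alt 1) = logistic(10) = 0.99995...; allow at most one miss in 300
  expect_gte(sum(picks), 299L)
})

test_that("choice shares converge to the truth probabilities per set", {
  sch <- toy_schema(2)
  pr <- build_ordered_prior(sch, draws = 8L, seed = 1L)
  des <- optimize_design(sch, pr, 4, 2, restarts = 1, seed = 2, draws = 8)
  base <- setNames(c(0.8, 0.1, -0.4, 0.2), coding_map(sch)$column)
  truth <- truth_spec(base, completion = 1)
  pop <- generate_population(10000, seed = 9, n_blocks = 1)
  ds <- simulate_choices(des, pop, truth, seed = 10)
  D <- ppdce:::design_diff_matrix(des)
  p_true <- stats::plogis(drop(D %*% base))
  obs <- ds$observations
  for (i in 1:3) {
    sel <- obs$set_id == des$sets[[i]]$id & obs$alt == 1L
    share <- mean(obs$chosen[sel])
    expect_lt(abs(share - p_true[i]),
              4 * sqrt(p_true[i] * (1 - p_true[i]) / sum(sel)))
  }
})

test_that("the default study truth carries the reported sign structure", {
  sch <- build_schema()
  truth <- study_truth_t()
  tab <- t(vapply(schema_ids_t(sch), function(a)
    level_utilities(sch, truth$base, a), numeric(3)))
  expect_true(all(tab[, 1] > 0))
  expect_true(all(abs(tab[, 2]) <= 0.15))
  expect_true(all(tab[, 3] < 0))
  # deterioration in effectiveness is the dominant coefficient
  expect_equal(unname(tab["effectiveness_safety", 3]), -1)
  expect_equal(max(abs(tab)), abs(tab[["effectiveness_safety", 3]]))
  # avoidance outweighs improvement except long-term cost and gaming
  for (a in rownames(tab)) {
    if (a %in% c("long_term_cost", "gaming")) {
      expect_gt(tab[a, 1], abs(tab[a, 3]))
    } else {
      expect_gte(abs(tab[a, 3]), tab[a, 1])
    }
  }
  expect_equal(truth$completion, 0.87)
})

test_that("choice data round-trips through CSV with label normalization", {
  fx <- toy_fit_fixture()
  ds <- fx$dataset
  rp <- tempfile(fileext = ".csv"); cp <- tempfile(fileext = ".csv")
  write_choice_data(ds, rp, cp)
  back <- read_choice_data(rp, cp, fx$schema)
  expect_equal(back$observations[, names(ds$observations)], ds$observations)
  expect_equal(back$respondents$id, ds$respondents$id)
  # dialect tolerance: trailing blanks and case differences normalize
  raw <- read.csv(cp, stringsAsFactors = FALSE)
  raw$a1[1] <- paste0(raw$a1[1], " ")
  raw$a2[2] <- toupper(raw$a2[2])
  write.csv(raw, cp, row.names = FALSE)
  again <- read_choice_data(rp, cp, fx$schema)
  expect_equal(again$observations$a1, back$observations$a1)
  expect_equal(again$observations$a2, back$observations$a2)
})
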
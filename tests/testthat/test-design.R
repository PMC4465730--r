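test_that("attribute balance plans hit the equal-constancy quotas", {
  # exact divisibility: 3 attributes, 3 sets, 1 constant per set
  p1 <- plan_attribute_balance(toy_schema(3), 3, 2, seed = 1)
  expect_equal(unname(p1$counts), c(1L, 1L, 1L))
  # study geometry: 54 sets, 6 constants per set, 11 attributes
  p2 <- plan_attribute_balance(build_schema(), 54, 5, seed = 1)
  expect_true(all(p2$counts %in% c(29L, 30L)))
  expect_equal(sum(p2$counts), 54L * 6L)
  lens <- lengths(p2$assignment)
  expect_true(all(lens == 6L))
  expect_error(plan_attribute_balance(toy_schema(3), 10, 4), "exceeds")
})

test_that("pair-count penalty spreads co-constancy evenly", {
  # 4 attributes, 6 sets, 2 constants each: all 6 unordered pairs once
  p <- plan_attribute_balance(toy_schema(4), 6, 2, seed = 1)
  off <- p$pair_counts[upper.tri(p$pair_counts)]
  expect_equal(sort(off), rep(1L, 6L))
  expect_equal(p$pair_range, 0L)
})

test_that("information matrix matches closed forms and a brute-force oracle", {
  fx <- toy_fit_fixture()
  des <- fx$design
  # beta = 0: probabilities 1/2, M = 1/4 sum of outer products of diffs
  M0 <- mnl_information_matrix(des, rep(0, 8))
  D <- ppdce:::design_diff_matrix(des)
  expect_equal(unname(M0), unname(0.25 * t(D) %*% D), tolerance = 1e-12)
  # identical profiles contribute nothing
  sch2 <- toy_schema(2)
  prof <- c(a1 = "positive", a2 = "negative")
  one <- ppdce:::new_choice_design(
    sch2, list(choice_set(1, prof, prof, sch2)), c("1" = 1L), 2L)
  expect_equal(unname(mnl_information_matrix(one, c(0.3, 0, -0.2, 0.1))),
               matrix(0, 4, 4), tolerance = 1e-15)
  # general beta against an independent straight-loop oracle
  beta <- c(0.5, 0, -0.5, 0, 0.25, -0.1, 0.3, 0.2)
  expect_equal(unname(mnl_information_matrix(des, beta)),
               info_matrix_oracle(des, beta), tolerance = 1e-10)
})

test_that("Bayesian criterion averages log-determinants and flags singularity", {
  fx <- toy_fit_fixture()
  des <- fx$design
  B0 <- matrix(0, 1, 8)
  D <- ppdce:::design_diff_matrix(des)
  expect_equal(bayesian_d_criterion(des, B0),
               determinant(0.25 * t(D) %*% D, logarithm = TRUE)$modulus[[1]],
               tolerance = 1e-10)
  # an attribute constant everywhere makes the matrix singular
  sch2 <- toy_schema(2)
  sets <- list(
    choice_set(1, c(a1 = "positive", a2 = "no_change"),
               c(a1 = "negative", a2 = "no_change"), sch2),
    choice_set(2, c(a1 = "positive", a2 = "no_change"),
               c(a1 = "no_change", a2 = "no_change"), sch2),
    choice_set(3, c(a1 = "no_change", a2 = "no_change"),
               c(a1 = "negative", a2 = "no_change"), sch2),
    choice_set(4, c(a1 = "positive", a2 = "no_change"),
               c(a1 = "negative", a2 = "no_change"), sch2))
  sing <- ppdce:::new_choice_design(sch2, sets,
                                    setNames(rep(1L, 4), 1:4), 2L)
  expect_identical(bayesian_d_criterion(sing, matrix(0, 2, 4)), -Inf)
  expect_error(bayesian_d_criterion(des, matrix(0, 1, 5)), "columns")
})

test_that("criterion at few draws agrees with a high-resolution estimate", {
  fx <- toy_fit_fixture()
  pr <- fx$prior
  c256 <- bayesian_d_criterion(fx$design, sample_prior(pr, 256))
  c10k <- bayesian_d_criterion(fx$design, sample_prior(pr, 10000))
  # Monte-Carlo error of the 256-draw mean, from its own draw spread
  B <- sample_prior(pr, 256)
  per_draw <- apply(B, 1L, function(b)
    determinant(mnl_information_matrix(fx$design, b),
                logarithm = TRUE)$modulus[[1]])
  se <- stats::sd(per_draw) / sqrt(256)
  expect_lt(abs(c256 - c10k), 5 * se)
})

test_that("criterion is invariant to profile swaps and set permutation", {
  fx <- toy_fit_fixture()
  des <- fx$design
  B <- sample_prior(fx$prior, 64)
  base <- bayesian_d_criterion(des, B)
  swapped <- des
  swapped$sets <- lapply(des$sets, function(s) {
    s$profiles <- rev(s$profiles); s
  })
  expect_equal(bayesian_d_criterion(swapped, B), base, tolerance = 1e-10)
  perm <- des
  perm$sets <- des$sets[sample(seq_along(des$sets))]
  expect_equal(bayesian_d_criterion(perm, B), base, tolerance = 1e-10)
})

test_that("every attribute carries positive conditional information", {
  # the information attributable to one attribute given all others is the
  # Schur complement of its coding block; in a full-rank optimized design
  # it must be positive definite for every attribute
  fx <- toy_fit_fixture()
  M <- mnl_information_matrix(fx$design, fx$prior$mean)
  for (k in 1:4) {
    own <- c(2 * k - 1, 2 * k)
    rest <- setdiff(1:8, own)
    schur <- M[own, own] - M[own, rest] %*%
      solve(M[rest, rest], M[rest, own])
    expect_true(all(eigen(schur, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("coordinate exchange attains the exhaustive optimum on a toy", {
  sch <- toy_schema(2)
  pr <- build_ordered_prior(sch, draws = 1L, sd = 1e-6, seed = 1L)
  pr$covariance[] <- 0  # point mass at the ordered prior mean
  B <- sample_prior(pr)
  scores <- ppdce:::prior_level_scores(sch, pr$mean)
  lvs <- c("positive", "no_change", "negative")
  grid <- expand.grid(a1 = lvs, a2 = lvs, stringsAsFactors = FALSE)
  codes <- ppdce:::effects_code_matrix(sch, grid)
  idx <- expand.grid(i = 1:9, j = 1:9)
  feasible <- sapply(seq_len(nrow(idx)), function(r) {
    i1 <- c((idx$i[r] - 1) %% 3 + 1, (idx$i[r] - 1) %/% 3 + 1)
    i2 <- c((idx$j[r] - 1) %% 3 + 1, (idx$j[r] - 1) %/% 3 + 1)
    !all(i1 == i2) && !ppdce:::dominated_idx(i1, i2, scores)
  })
  Df <- unique(codes[idx$i, ][feasible, ] - codes[idx$j, ][feasible, ])
  n <- nrow(Df)
  ms <- t(utils::combn(n + 3L, 4L))
  ms <- ms - matrix(rep(0:3, each = nrow(ms)), ncol = 4L)
  best <- -Inf
  for (r in seq_len(nrow(ms))) {
    v <- ppdce:::cpp_bayes_logdet(Df[ms[r, ], , drop = FALSE], B)
    if (v > best) best <- v
  }
  des <- optimize_design(sch, pr, n_sets = 4, n_varying_max = 2,
                         restarts = 5, seed = 5, draws = 1)
  expect_equal(des$criterion_value, best, tolerance = 1e-8)
})

test_that("more restarts never worsen the optimized criterion", {
  sch <- toy_schema(3)
  pr <- build_ordered_prior(sch, draws = 32L, seed = 2L)
  c1 <- optimize_design(sch, pr, 8, 2, restarts = 1, seed = 9)$criterion_value
  c8 <- optimize_design(sch, pr, 8, 2, restarts = 8, seed = 9)$criterion_value
  expect_gte(c8, c1)
})

test_that("optimized designs respect structure, dominance and blocking", {
  fx <- toy_fit_fixture()
  des <- fx$design
  expect_length(des$sets, 10L)
  expect_true(all(vapply(des$sets, ppdce:::n_varying, 1L) <= 3L))
  rep <- design_report(des)
  expect_length(rep$dominated_sets, 0L)
  for (s in des$sets) {
    expect_length(s$balanced_constant_ids, 1L)
    for (a in c(s$balanced_constant_ids, s$incidental_constant_ids)) {
      expect_equal(s$profiles[[1L]][[a]], s$profiles[[2L]][[a]])
    }
  }
  expect_equal(des$criterion_value,
               bayesian_d_criterion(des, sample_prior(fx$prior)),
               tolerance = 1e-9)
})

test_that("designs round-trip through CSV", {
  fx <- toy_fit_fixture()
  path <- tempfile(fileext = ".csv")
  write_design_csv(fx$design, path)
  back <- read_design_csv(path, fx$schema)
  expect_length(back$sets, length(fx$design$sets))
  for (i in seq_along(back$sets)) {
    expect_equal(back$sets[[i]]$profiles, fx$design$sets[[i]]$profiles)
    expect_equal(back$sets[[i]]$balanced_constant_ids,
                 fx$design$sets[[i]]$balanced_constant_ids)
    expect_equal(back$sets[[i]]$incidental_constant_ids,
                 fx$design$sets[[i]]$incidental_constant_ids)
  }
  expect_equal(unname(back$blocks[as.character(1:10)]),
               unname(fx$design$blocks[as.character(1:10)]))
})
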
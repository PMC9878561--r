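test_that("invest_probability implements the logistic policy", {
    a0 <- agent_params("exp2", beta_intercept = 0, beta_p_lose = 0,
                       beta_responsible = 0, beta_optimal_assigned = 0,
                       beta_preference = 0, sd_participant = 0)
    expect_equal(invest_probability(a0, list(p_lose = 0.5,
                                             condition = "responsible",
                                             preference = 1)), 0.5)

    # fitted exp2 coefficients: responsible trial, preference, p_lose = 0
    a <- agent_params("exp2")
    expect_equal(invest_probability(a, list(p_lose = 0,
                                            condition = "responsible",
                                            preference = 1)),
                 plogis(1.39 + 1.77 + 1.24))
    # random-assignment baseline at p_lose = 0 is the intercept alone
    expect_equal(invest_probability(a, list(p_lose = 0,
                                            condition = "random_assigned",
                                            preference = 0)),
                 plogis(1.39))
    expect_error(agent_params("exp2", beta_bogus = 1), "unknown agent")
})

test_that("decision draws match the logistic probability empirically", {
    a <- agent_params("exp2")
    feats <- data.frame(p_lose = rep(0.4, 1e5), condition = "responsible",
                        preference = 1)
    p_true <- invest_probability(a, feats[1, ])
    set.seed(301)
    draws <- decide_invest(a, feats, u = 0)
    se <- sqrt(p_true * (1 - p_true) / 1e5)
    expect_lt(abs(mean(draws) - p_true), 3 * se)
})

test_that("preference elicitation follows the stage-one policy", {
    a <- agent_params("exp2")
    # empirical preference rate matches the stage-one logistic value
    set.seed(302)
    p_true <- plogis(1.39 - 3.18 * 0.95)
    pref_bad <- elicit_preference(a, rep(0.95, 5000), u = 0)
    expect_lt(abs(mean(pref_bad) - p_true),
              3 * sqrt(p_true * (1 - p_true) / 5000))
    # a steep policy makes preference vanish on near-certain losses
    steep <- agent_params("exp2", beta_p_lose = -20)
    set.seed(303)
    expect_lt(mean(elicit_preference(steep, rep(0.95, 2000))), 0.005)
    # a (near) deterministic agent's preference is the sign of the predictor
    ad <- agent_params("exp2", beta_intercept = 50, beta_p_lose = -100)
    expect_equal(elicit_preference(ad, 0, u = 0), 1L)
    expect_equal(elicit_preference(ad, 1, u = 0), 0L)
    # mean preference decreases in p_lose
    set.seed(304)
    grid <- seq(0.05, 0.95, by = 0.1)
    rates <- vapply(grid, function(pl) mean(elicit_preference(a, rep(pl, 4000))),
                    numeric(1))
    expect_true(all(diff(rates) < 0))
})

test_that("simulate_experiment produces the declared decision-log structure", {
    d <- simulate_experiment("exp2", n_participants = 3, seed = 7)
    # assigned trials always yield an analyzed row; responsible rows are
    # missing only when the agent itself opted out at stage one
    expect_equal(sum(d$condition == "random_assigned"), 3 * 50)
    expect_equal(sum(d$condition == "optimal_assigned"), 3 * 50)
    expect_lte(sum(d$condition == "responsible"), 3 * 50)
    expect_true(all(d$stage == 2))
    expect_true(all(d$prior_investments == 1))
    expect_true(all(d$decision %in% 0:1))
    expect_true(all(d$preference %in% 0:1))
    expect_equal(sort(unique(d$responsibility_code)),
                 c("assigned", "responsible"))
    # optimal-advisor trials were screened at p_lose <= 1/2 at stage one,
    # which cannot be seen at stage two directly, but their payout fields
    # must satisfy the exp2 point rules
    expect_true(all(d$payout[d$decision == 0] == 100))
    expect_true(all(d$payout[d$decision == 1] %in% c(0, 150, 300)))

    # byte-identical determinism
    d2 <- simulate_experiment("exp2", n_participants = 3, seed = 7)
    expect_identical(d, d2)
})

test_that("participant heterogeneity comes from the random intercept alone", {
    d <- simulate_experiment("exp2", n_participants = 2, seed = 9,
                             agent = agent_params("exp2", sd_participant = 0))
    expect_equal(attr(d, "u"), c(0, 0))
})

test_that("invest rates fall with p_lose and order by condition", {
    d <- simulate_experiment("exp2", n_participants = 6, seed = 10)
    bins <- cut(d$p_lose, breaks = c(0, 0.25, 0.5, 0.75, 1),
                include.lowest = TRUE)
    rates <- tapply(d$decision, bins, mean)
    expect_true(all(diff(rates) < 0))
    cond_rates <- tapply(d$decision, d$condition, mean)
    expect_gt(cond_rates[["responsible"]], cond_rates[["random_assigned"]])
})

test_that("exp1 and exp3 sessions honor their designs", {
    d1 <- simulate_experiment("exp1", n_participants = 2, n_trials = 10,
                              seed = 11, exact_cap = 2000, mc_samples = 500)
    expect_true(all(d1$responsibility_code %in% c("responsible", "assigned")))
    expect_true(all(d1$stage >= 2 | d1$responsibility_code == "assigned"))
    expect_true(all(is.na(d1$preference)))

    d3 <- simulate_experiment("exp3", n_participants = 4, n_trials = 12,
                              seed = 12)
    expect_equal(sort(unique(d3$framing)), c("gain", "loss"))
    s <- attr(d3, "session")
    expect_equal(nrow(s), 4)
    # framing allocation is balanced by default
    expect_equal(sum(s$framing == "gain"), 2)
    expect_error(simulate_experiment("exp2", n_trials = 100, seed = 1),
                 "divisible")
})
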
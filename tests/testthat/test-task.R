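test_that("cost schedules match the task variants", {
    s1 <- cost_schedule("exp1")
    expect_equal(s1$endowment, 310)
    expect_equal(s1$stage_costs, c(10, 20, 40, 80, 160))
    expect_equal(sum(s1$stage_costs), s1$endowment)
    s2 <- cost_schedule("exp2")
    expect_equal(s2$endowment, 150)
    expect_equal(s2$stage_costs, c(50, 100))
})

test_that("generate_trial is reproducible and condition-appropriate", {
    set.seed(201)
    t1 <- generate_trial("exp2", "responsible")
    set.seed(201)
    t2 <- generate_trial("exp2", "responsible")
    expect_identical(t1, t2)
    expect_equal(t1$revealed_at_start, 3L)
    expect_equal(length(t1$board), 5L)
    expect_equal(anyDuplicated(c(t1$player_hole, t1$opp_hole, t1$board)), 0L)

    set.seed(202)
    for (i in 1:25) {
        ta <- generate_trial("exp1", "random_assigned")
        expect_true(ta$start_stage %in% 2:5)
        k <- ta$revealed_at_start
        expect_true(k %in% 1:4)
        expect_equal(ta$pre_invested,
                     sum(cost_schedule("exp1")$stage_costs[seq_len(k)]))
    }
    tf <- generate_trial("exp1", "responsible")
    expect_equal(tf$revealed_at_start, 0L)
    expect_equal(tf$pre_invested, 0)
    expect_error(generate_trial("exp1", "optimal_assigned"), "optimal")
})

test_that("the random advisor is a fair, card-independent coin", {
    set.seed(203)
    draws <- replicate(10000, advisor_random())
    frac <- mean(draws == "invest")
    expect_lt(abs(frac - 0.5), 0.015)  # 3 binomial SEs
    set.seed(42)
    a <- advisor_random()
    set.seed(42)
    expect_identical(a, advisor_random())
})

test_that("the optimal advisor follows the expected-value rule", {
    expect_equal(advisor_optimal(list(p_win = 0.6, p_tie = 0.1, p_lose = 0.3)),
                 "invest")
    expect_equal(advisor_optimal(list(p_win = 0.2, p_tie = 0.1, p_lose = 0.7)),
                 "opt_out")
    # boundary: equal chances resolve toward investing
    expect_equal(advisor_optimal(list(p_win = 0.25, p_tie = 0.25, p_lose = 0.5)),
                 "invest")
})

test_that("payout accounting matches the task rules", {
    # exp1: invest all five stages and win the showdown -> 310 in, 620 out
    r <- play_trial(sure_win_trial("exp1"), always_invest)
    expect_equal(r$invested, 310)
    expect_equal(r$outcome, "win")
    expect_equal(r$payout, 620)

    # exp1: opt out after investing 10 + 20
    n_dec <- 0
    two_then_out <- function(f) {
        n_dec <<- n_dec + 1
        if (n_dec <= 2) "invest" else "opt_out"
    }
    r2 <- play_trial(fixed_trial("exp1", "responsible", c("As", "Ks"),
                                 c("2d", "7h"), c("Qs", "Js", "Ts", "3c", "4d")),
                     two_then_out)
    expect_equal(r2$invested, 30)
    expect_equal(r2$payout, 280)
    expect_equal(r2$outcome, "opted_out")

    # exp2: invest then opt out banks 100 points
    n_dec <- 0
    one_then_out <- function(f) {
        n_dec <<- n_dec + 1
        if (n_dec <= 1) "invest" else "opt_out"
    }
    r3 <- play_trial(sure_win_trial("exp2"), one_then_out)
    expect_equal(r3$payout, 150 - 50)
    expect_equal(r3$outcome, "opted_out")

    # exp2: invest twice and win -> 300
    r4 <- play_trial(sure_win_trial("exp2"), always_invest)
    expect_equal(r4$invested, 150)
    expect_equal(r4$payout, 300)

    expect_error(play_trial(sure_win_trial("exp2"), function(f) "maybe"),
                 "invest")
})

test_that("points are conserved under random policies", {
    set.seed(204)
    for (i in 1:40) {
        variant <- sample(c("exp1", "exp2"), 1)
        condition <- if (variant == "exp1") {
            sample(c("responsible", "random_assigned"), 1)
        } else "responsible"
        trial <- generate_trial(variant, condition)
        res <- play_trial(trial, function(f) {
            if (runif(1) < 0.6) "invest" else "opt_out"
        }, exact_cap = 2000, mc_samples = 500)
        sched <- cost_schedule(variant)
        mult <- switch(res$outcome, win = 2, tie = 1, lose = 0, opted_out = 0)
        inv_back <- if (res$outcome == "opted_out") 0 else mult * res$invested
        expect_equal(res$payout,
                     sched$endowment - res$invested + inv_back)
    }
})

test_that("responsibility coding excludes fresh first stages", {
    # fresh exp1 trial, three participant decisions: stage 1 excluded,
    # stages 2-3 responsible
    n_dec <- 0
    three_then_out <- function(f) {
        n_dec <<- n_dec + 1
        if (n_dec <= 3) "invest" else "opt_out"
    }
    r <- play_trial(fixed_trial("exp1", "responsible", c("As", "Ks"),
                                c("2d", "7h"), c("Qs", "Js", "Ts", "3c", "4d")),
                    three_then_out)
    d <- code_responsibility(r)
    expect_equal(d$stage, c(2, 3, 4))
    expect_equal(d$responsibility_code[1:2], c("responsible", "responsible"))
    expect_equal(d$prior_investments, c(1, 2, 3))

    # assigned exp1 trial starting at stage 3: first decision assigned with
    # two prior (computer) investments, later ones responsible
    r2 <- play_trial(fixed_trial("exp1", "random_assigned", c("As", "Ks"),
                                 c("2d", "7h"), c("Qs", "Js", "Ts", "3c", "4d"),
                                 start_stage = 3L),
                     always_invest)
    d2 <- code_responsibility(r2)
    expect_equal(d2$responsibility_code, c("assigned", "responsible", "responsible"))
    expect_equal(d2$prior_investments[1], 2)

    # exp2 responsible trial: the stage-2 decision is responsible
    r3 <- play_trial(sure_win_trial("exp2"), always_invest)
    d3 <- code_responsibility(r3)
    expect_equal(d3$stage, 2)
    expect_equal(d3$responsibility_code, "responsible")
})

test_that("advisor opt-outs mark the trial as discarded", {
    set.seed(205)
    found <- FALSE
    for (i in 1:30) {
        r <- play_trial(generate_trial("exp2", "random_assigned"),
                        always_invest)
        if (r$outcome == "advisor_opted_out") {
            found <- TRUE
            expect_true(r$discarded)
            expect_true(is.na(r$payout))
        }
    }
    expect_true(found)  # a fair coin opts out within 30 trials
})

test_that("gain and loss framings are payout-equivalent displays", {
    for (g in c(0, 100, 300)) {
        gv <- frame_display(g, "gain")
        lv <- frame_display(g, "loss")
        expect_equal(gv$trial_start_display, 0)
        expect_equal(gv$displayed_change, g)
        expect_equal(lv$trial_start_display, 300)
        expect_equal(lv$displayed_change, -(300 - g))
        expect_equal(gv$displayed_change + abs(lv$displayed_change), 300)
    }
    expect_equal(frame_display(0, "gain")$session_start_display, 0)
    expect_equal(frame_display(0, "loss")$session_start_display, 27000)
    expect_error(frame_display(301, "gain"), "\\[0, 300\\]")

    # identical seed and policy give identical payouts whatever the display
    set.seed(206)
    t1 <- generate_trial("exp3", "responsible")
    r_gain <- play_trial(t1, always_invest, framing = "gain")
    r_loss <- play_trial(t1, always_invest, framing = "loss")
    expect_identical(r_gain$payout, r_loss$payout)
})

test_that("bonus conversion uses 5000 points per GBP with half-up rounding", {
    expect_equal(convert_bonus(27000), 5.4)
    expect_equal(convert_bonus(0), 0)
    expect_equal(convert_bonus(2525), 0.51)  # 0.505 rounds up
    expect_error(convert_bonus(1000, variant = "exp1"), "exp3")
})
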
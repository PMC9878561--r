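# small random-intercept logistic dataset generator used across tests
make_ri_data <- function(n_groups, n_per, b0, b1, sd_u, seed) {
    set.seed(seed)
    id <- factor(rep(seq_len(n_groups), each = n_per))
    x <- rep(rep(0:1, length.out = n_per), n_groups)
    u <- rnorm(n_groups, 0, sd_u)
    y <- rbinom(length(x), 1, plogis(b0 + b1 * x + u[as.integer(id)]))
    data.frame(y = y, x = x, participant_id = id)
}

test_that("zero participant variance reduces to a plain logistic fit", {
    d <- make_ri_data(20, 40, 0.4, 0.8, 0, seed = 401)
    fit <- fit_logistic_ri(y ~ x + (1 | participant_id), d, nAGQ = 15)
    ref <- glm(y ~ x, data = d, family = binomial())
    expect_true(fit$converged)
    expect_lt(max(abs(fit$coefficients$estimate - coef(ref))), 1e-3)
    expect_lt(fit$s2[["participant_id"]], 1e-4)
})

test_that("marginal log-likelihood matches fine-grid numerical integration", {
    # tiny instance: 3 groups x 8 rows with visibly different base rates
    d <- data.frame(
        y = c(1, 1, 1, 1, 1, 1, 1, 0,
              1, 1, 1, 0, 1, 0, 0, 1,
              1, 0, 0, 0, 0, 0, 1, 0),
        x = rep(rep(0:1, each = 4), 3),
        participant_id = factor(rep(1:3, each = 8)))
    fit <- fit_logistic_ri(y ~ x + (1 | participant_id), d, nAGQ = 25)
    beta <- lme4::fixef(fit$model)
    sd_u <- sqrt(fit$s2[["participant_id"]])
    expect_gt(sd_u, 0.05)

    # independent oracle: trapezoid integration of the marginal likelihood
    # over the random intercept on a fine grid
    grid <- seq(-10 * sd_u, 10 * sd_u, length.out = 4001)
    h <- grid[2] - grid[1]
    ll <- 0
    for (g in levels(d$participant_id)) {
        dg <- d[d$participant_id == g, ]
        eta <- beta[1] + beta[2] * dg$x
        lik_u <- vapply(grid, function(u) {
            p <- plogis(eta + u)
            prod(ifelse(dg$y == 1, p, 1 - p)) * dnorm(u, 0, sd_u)
        }, numeric(1))
        ll <- ll + log(sum(lik_u) * h)
    }
    expect_lt(abs(ll - fit$logLik), 1e-4)
})

test_that("separation and missing random terms are raised explicitly", {
    d <- make_ri_data(6, 10, 0, 0.5, 0.3, seed = 402)
    d$sep <- as.numeric(d$y == 1)  # perfectly separating covariate
    expect_warning(fit_logistic_ri(y ~ sep + (1 | participant_id), d),
                   "separation")
    expect_error(fit_logistic_ri(y ~ x, d), "random-intercept")
})

test_that("linear fits match OLS and closed-form ANOVA benchmarks", {
    # zero-variance grouping: fixed effects equal ordinary least squares
    set.seed(403)
    d <- data.frame(participant_id = factor(rep(1:12, each = 10)),
                    x = rnorm(120))
    d$yv <- 1 + 0.5 * d$x + rnorm(120)
    fit <- fit_linear_ri(yv ~ x + (1 | participant_id), d)
    ols <- lm(yv ~ x, data = d)
    expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-2)

    # balanced one-way layout: REML variance components equal the
    # closed-form moment estimators (MSB - MSW)/m and MSW
    set.seed(404)
    g <- 15; m <- 8
    id <- factor(rep(seq_len(g), each = m))
    yv <- 2 + rnorm(g, 0, 1.5)[as.integer(id)] + rnorm(g * m, 0, 1)
    d2 <- data.frame(yv = yv, participant_id = id)
    fit2 <- fit_linear_ri(yv ~ 1 + (1 | participant_id), d2)
    aov_tab <- anova(lm(yv ~ id))
    msb <- aov_tab["id", "Mean Sq"]
    msw <- aov_tab["Residuals", "Mean Sq"]
    expect_lt(abs(fit2$s2[["participant_id"]] - (msb - msw) / m), 1e-6)
    expect_lt(abs(fit2$s2[["Residual"]] - msw), 1e-6)
    # t statistics carry Satterthwaite df
    expect_true("df" %in% names(fit2$coefficients))
})

test_that("predicted probabilities invert the fixed-effect predictor", {
    d <- make_ri_data(25, 40, 0.5, -1, 0.4, seed = 405)
    fit <- fit_logistic_ri(y ~ x + (1 | participant_id), d)
    grid <- data.frame(x = c(0, 1))
    pp <- predicted_probabilities(fit, grid)
    beta <- lme4::fixef(fit$model)
    V <- as.matrix(vcov(fit$model))
    # manual delta-method check at x = 1
    eta <- beta[1] + beta[2]
    se <- sqrt(V[1, 1] + V[2, 2] + 2 * V[1, 2])
    expect_equal(pp$prob[2], unname(plogis(eta)))
    expect_equal(pp$lower[2], unname(plogis(eta - qnorm(0.975) * se)))
    expect_equal(pp$upper[2], unname(plogis(eta + qnorm(0.975) * se)))
    expect_true(all(pp$lower < pp$prob & pp$prob < pp$upper))
    # interval width shrinks toward zero with the standard errors
    expect_equal(unname(pp$se_logit[2]), se)
})

test_that("baseline relabeling leaves Wald p values invariant", {
    d <- simulate_experiment("exp2", n_participants = 4, n_trials = 30,
                             seed = 406)
    f1 <- fit_logistic_ri(decision ~ p_lose + condition + (1 | participant_id),
                          d, nAGQ = 5)
    d2 <- prepare_decision_table(d)
    d2$condition <- stats::relevel(d2$condition, "responsible")
    f2 <- fit_logistic_ri(decision ~ p_lose + condition + (1 | participant_id),
                          d2, nAGQ = 5)
    # p_lose is shared between parameterizations; contrasts reparameterize
    p1 <- f1$coefficients$p[f1$coefficients$term == "p_lose"]
    p2 <- f2$coefficients$p[f2$coefficients$term == "p_lose"]
    expect_equal(p1, p2, tolerance = 1e-4)
    # responsible-vs-random contrast equals minus the random-vs-responsible
    b1 <- f1$coefficients$estimate[f1$coefficients$term == "conditionresponsible"]
    b2 <- f2$coefficients$estimate[f2$coefficients$term == "conditionrandom_assigned"]
    expect_equal(b1, -b2, tolerance = 1e-3)
})

test_that("estimated variance rises with the generating variance", {
    sds <- c(0.1, 0.6, 1.2)
    est <- vapply(seq_along(sds), function(i) {
        d <- make_ri_data(40, 40, 0.3, 0.5, sds[i], seed = 410 + i)
        fit <- fit_logistic_ri(y ~ x + (1 | participant_id), d, nAGQ = 5)
        fit$s2[["participant_id"]]
    }, numeric(1))
    expect_true(all(diff(est) > 0))
    expect_true(all(est >= 0))
})

test_that("power simulation is calibrated at the null and saturates", {
    # null: rejection rate within 3 Monte-Carlo SEs of alpha
    p0 <- simulate_power(effect_or = 1, n_participants = 25, n_trials = 40,
                         n_sim = 100, seed = 420)
    expect_lt(abs(p0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
    # a huge effect is detected essentially always
    p1 <- simulate_power(effect_or = 20, n_participants = 25, n_trials = 40,
                         n_sim = 30, seed = 421)
    expect_gte(p1$power, 1 - 1e-9)
    expect_equal(p1$n_nonconverged, 0)
    expect_true(p0$ci[1] <= p0$power && p0$power <= p0$ci[2])
    expect_error(simulate_power(n_sim = 10), "seed")
})
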
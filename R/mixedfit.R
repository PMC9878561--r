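## Random-intercept logistic and linear model estimation with Wald
## inference, predicted-probability grids, and simulation-based power.
## Estimation is by maximum marginal likelihood: adaptive Gauss-Hermite
## quadrature (default 15 nodes, via lme4) for a single grouping factor,
## the Laplace approximation when random intercepts are crossed (e.g.
## participants and trials). Inference is Wald: z = B / SE, two-sided p.

#' Default fixed-effect model formula of each experiment's decision model
#'
#' exp1: probability of losing x personal responsibility x prior
#' investments, with crossed participant and trial random intercepts.
#' exp2: probability of losing x trial type x preference with a
#' participant random intercept. exp3: probability of losing x trial type
#' x framing plus preference, numeracy and risk covariates. `"linear"`
#' gives the expected-value model (trial type x preference).
#'
#' @param variant Task variant.
#' @param type `"logistic"` (decision model) or `"linear"` (expected-value
#'   model).
#' @return A model formula in lme4 notation.
#' @export
default_model_formula <- function(variant = c("exp2", "exp1", "exp3"),
                                  type = c("logistic", "linear")) {
    variant <- match.arg(variant)
    type <- match.arg(type)
    if (type == "linear") {
        return(ev ~ condition * preference + (1 | participant_id))
    }
    switch(variant,
           exp1 = decision ~ p_lose * responsible * prior_investments +
               (1 | participant_id) + (1 | trial_id),
           exp2 = decision ~ p_lose * condition * preference +
               (1 | participant_id),
           exp3 = decision ~ p_lose * condition * framing + preference +
               numeracy + risk + (1 | participant_id))
}

#' Prepare a decision table for model fitting
#'
#' Sets the dummy coding the models assume: `condition` becomes a factor
#' with `random_assigned` as the baseline level, `framing` a factor with
#' `gain` as the baseline, `responsible` (exp1) a 0/1 dummy, and
#' `participant_id`/`trial_id` factors.
#'
#' @param data A decision table from [simulate_experiment()] or
#'   [read_decision_log()].
#' @return The data frame with coded columns.
#' @export
prepare_decision_table <- function(data) {
    d <- as.data.frame(data)
    if (!is.null(d$condition) && !is.factor(d$condition)) {
        d$condition <- factor(d$condition,
                              levels = c("random_assigned",
                                         "optimal_assigned", "responsible"))
        d$condition <- droplevels(d$condition)
    }
    if (!is.null(d$framing) && !is.factor(d$framing) &&
        !all(is.na(d$framing))) {
        d$framing <- factor(d$framing, levels = c("gain", "loss"))
    }
    if (!is.null(d$responsibility_code)) {
        d$responsible <- as.integer(d$responsibility_code == "responsible")
    }
    if (!is.null(d$participant_id)) d$participant_id <- factor(d$participant_id)
    if (!is.null(d$trial_id)) d$trial_id <- factor(d$trial_id)
    d
}

# shared: detect complete/quasi separation in the fixed design by fitting
# the fixed-effects-only GLM and looking for the classic symptoms
check_separation <- function(formula, data) {
    fixed <- lme4::nobars(formula)
    sep <- FALSE
    withCallingHandlers(
        g <- glm(fixed, data = data, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w))) sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (!sep && any(abs(coef(g)) > 15, na.rm = TRUE)) sep <- TRUE
    sep
}

new_vip_fit <- function(model, family) {
    is_binom <- family == "binomial"
    cc <- as.data.frame(coef(summary(model)))
    if (is_binom) {
        tab <- data.frame(term = rownames(cc), or = exp(cc[["Estimate"]]),
                          estimate = cc[["Estimate"]],
                          se = cc[["Std. Error"]],
                          z = cc[["z value"]], p = cc[["Pr(>|z|)"]],
                          stringsAsFactors = FALSE)
    } else {
        tab <- data.frame(term = rownames(cc), or = NA_real_,
                          estimate = cc[["Estimate"]],
                          se = cc[["Std. Error"]], df = cc[["df"]],
                          z = cc[["t value"]], p = cc[["Pr(>|t|)"]],
                          stringsAsFactors = FALSE)
    }
    rownames(tab) <- NULL
    vc <- as.data.frame(lme4::VarCorr(model))
    vc <- vc[is.na(vc$var2), ]
    s2 <- setNames(vc$vcov, ifelse(is.na(vc$var1), vc$grp,
                                   paste0(vc$grp)))
    msgs <- model@optinfo$conv$lme4$messages
    # a boundary (singular) fit is a legitimate variance estimate of 0,
    # not a convergence failure
    real_msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
    converged <- model@optinfo$conv$opt == 0 && length(real_msgs) == 0
    structure(list(coefficients = tab, s2 = s2,
                   logLik = as.numeric(logLik(model)),
                   converged = converged,
                   singular = lme4::isSingular(model),
                   messages = msgs, family = family, model = model),
              class = "vip_fit")
}

#' Fit a random-intercept logistic regression
#'
#' Maximum marginal likelihood estimation of a mixed-effects logistic
#' model, by adaptive Gauss-Hermite quadrature for one grouping factor and
#' by the Laplace approximation (with a message) when random intercepts
#' are crossed. Separation in the fixed design is detected via a
#' fixed-effects-only fit and raised as a warning; non-convergence is
#' flagged in the result, never silently dropped.
#'
#' @param formula Model formula in lme4 notation, e.g.
#'   `decision ~ p_lose * condition * preference + (1 | participant_id)`;
#'   see [default_model_formula()].
#' @param data Decision table; passed through [prepare_decision_table()].
#' @param nAGQ Number of quadrature nodes (default 15); forced to 1
#'   (Laplace) with more than one grouping factor.
#' @return An object of class `vip_fit`: a coefficient table with columns
#'   `term`, `or` (`exp(B)`), `estimate` (B), `se`, `z`, `p`, plus `s2`
#'   (random-intercept variances), `logLik`, a `converged` flag, and the
#'   underlying lme4 `model`.
#' @export
fit_logistic_ri <- function(formula, data, nAGQ = 15L) {
    d <- prepare_decision_table(data)
    n_groups <- length(lme4::findbars(formula))
    if (n_groups == 0L) stop("formula has no random-intercept term")
    if (n_groups > 1L && nAGQ > 1L) {
        message("crossed random intercepts: using the Laplace approximation (nAGQ = 1)")
        nAGQ <- 1L
    }
    if (check_separation(formula, d)) {
        warning("possible separation in the fixed design; estimates may diverge")
    }
    model <- lme4::glmer(formula, data = d, family = binomial(),
                         nAGQ = nAGQ,
                         control = lme4::glmerControl(optimizer = "bobyqa",
                                                      calc.derivs = FALSE))
    new_vip_fit(model, "binomial")
}

#' Fit a random-intercept linear model
#'
#' REML estimation of a mixed linear model with t statistics on
#' Satterthwaite degrees of freedom.
#'
#' @inheritParams fit_logistic_ri
#' @return A `vip_fit` (see [fit_logistic_ri()]); the coefficient table's
#'   `z` column holds the t statistic and a `df` column is added, `or` is
#'   `NA`. `s2` includes the residual variance.
#' @export
fit_linear_ri <- function(formula, data) {
    d <- prepare_decision_table(data)
    if (length(lme4::findbars(formula)) == 0L) {
        stop("formula has no random-intercept term")
    }
    model <- lmerTest::lmer(formula, data = d)
    new_vip_fit(model, "gaussian")
}

#' @export
print.vip_fit <- function(x, digits = 3, ...) {
    cat("<vip_fit> ", if (x$family == "binomial") "random-intercept logistic"
        else "random-intercept linear",
        if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
    tab <- x$coefficients
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits)
    print(tab, row.names = FALSE)
    cat("Random effects (s^2): ",
        paste(sprintf("%s %.3g", names(x$s2), x$s2), collapse = ", "),
        "\n", sep = "")
    invisible(x)
}

#' @export
as.data.frame.vip_fit <- function(x, ...) x$coefficients

#' Predicted probabilities over a feature grid
#'
#' Inverse-logit of the fixed-effect linear predictor at a random
#' intercept of 0, with a delta-method 95% confidence band (computed on
#' the logit scale from the fixed-effect covariance and transformed).
#'
#' @param fit A converged binomial [fit_logistic_ri()] result.
#' @param newdata Data frame of feature combinations (factor columns must
#'   use the fitted levels; see [prepare_decision_table()]).
#' @param level Confidence level (default 0.95).
#' @return `newdata` with columns `prob`, `lower`, `upper`, and
#'   `se_logit`.
#' @export
predicted_probabilities <- function(fit, newdata, level = 0.95) {
    stopifnot(inherits(fit, "vip_fit"), fit$family == "binomial")
    if (!fit$converged) warning("predictions from a non-converged fit")
    tt <- delete.response(terms(formula(fit$model, fixed.only = TRUE)))
    X <- model.matrix(tt, data = newdata)
    beta <- lme4::fixef(fit$model)
    V <- as.matrix(vcov(fit$model))
    eta <- drop(X %*% beta)
    se <- sqrt(rowSums((X %*% V) * X))
    zq <- qnorm(1 - (1 - level) / 2)
    out <- newdata
    out$prob <- plogis(eta)
    out$lower <- plogis(eta - zq * se)
    out$upper <- plogis(eta + zq * se)
    out$se_logit <- se
    out
}

#' Simulation-based power for a within-participant effect
#'
#' Estimates the power of the Wald test for a balanced within-participant
#' binary factor in a random-intercept logistic regression, in the style
#' of simr: each replicate simulates responses directly from the
#' generating model `logit P(invest) = b0 + log(OR) x + u_i`,
#' `u_i ~ Normal(0, sd_participant^2)`, fits
#' `y ~ x + (1 | participant)`, and tests the factor at `alpha`. Defaults
#' match the exp2 design (49 participants x 150 trials) with a
#' random-intercept variance of 0.25 and the exp2 baseline invest rate
#' (`plogis(1.39)`).
#'
#' @param effect_or Odds ratio of the tested factor (e.g. 1.4).
#' @param n_participants,n_trials Design size per replicate.
#' @param alpha Significance level of the Wald test.
#' @param n_sim Number of replicates (at least 100 recommended).
#' @param seed Integer seed.
#' @param sd_participant Random-intercept standard deviation
#'   (default `sqrt(0.25)`).
#' @param baseline_logit Intercept of the generating model (default 1.39).
#' @param nAGQ Quadrature nodes per replicate fit (default 1, Laplace).
#' @return An object of class `vip_power`: `power` (rejection fraction
#'   over all replicates), a Monte-Carlo binomial `ci`, `n_sim`, `alpha`,
#'   `effect_or`, and `n_nonconverged` (replicates with a convergence
#'   flag, reported separately, never dropped).
#' @export
simulate_power <- function(effect_or = 1.4, n_participants = 49L,
                           n_trials = 150L, alpha = 0.05, n_sim = 200L,
                           seed, sd_participant = sqrt(0.25),
                           baseline_logit = 1.39, nAGQ = 1L) {
    if (missing(seed)) stop("simulate_power() requires a seed")
    stopifnot(effect_or > 0, n_sim >= 1)
    set.seed(seed)
    b1 <- log(effect_or)
    id <- factor(rep(seq_len(n_participants), each = n_trials))
    x <- rep(rep(0:1, length.out = n_trials), n_participants)
    n <- length(x)
    rejected <- 0L
    nonconverged <- 0L
    for (s in seq_len(n_sim)) {
        u <- rnorm(n_participants, 0, sd_participant)
        eta <- baseline_logit + b1 * x + u[as.integer(id)]
        y <- rbinom(n, 1L, plogis(eta))
        dat <- data.frame(y = y, x = x, id = id)
        model <- suppressMessages(lme4::glmer(
            y ~ x + (1 | id), data = dat, family = binomial(),
            nAGQ = nAGQ,
            control = lme4::glmerControl(optimizer = "bobyqa",
                                         calc.derivs = FALSE)))
        msgs <- model@optinfo$conv$lme4$messages
        msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
        if (model@optinfo$conv$opt != 0 || length(msgs) > 0) {
            nonconverged <- nonconverged + 1L
        }
        p <- coef(summary(model))["x", "Pr(>|z|)"]
        if (is.finite(p) && p < alpha) rejected <- rejected + 1L
    }
    ci <- binom.test(rejected, n_sim)$conf.int
    structure(list(power = rejected / n_sim,
                   ci = c(lower = ci[1], upper = ci[2]),
                   n_sim = n_sim, alpha = alpha, effect_or = effect_or,
                   n_participants = n_participants, n_trials = n_trials,
                   n_nonconverged = nonconverged),
              class = "vip_power")
}

#' @export
print.vip_power <- function(x, ...) {
    cat(sprintf("<vip_power> OR %.3g, %d x %d design: power %.3f (95%% MC CI %.3f-%.3f, n_sim %d, %d non-converged)\n",
                x$effect_or, x$n_participants, x$n_trials, x$power,
                x$ci[1], x$ci[2], x$n_sim, x$n_nonconverged))
    invisible(x)
}
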
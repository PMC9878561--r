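## Synthetic participants: parametric agents whose invest/opt-out choices
## follow the logistic random-intercept structure the analysis models
## assume. The default generating coefficients are the fitted point
## estimates of the corresponding experiment's decision model, so the
## published tables double as canonical fixtures for every downstream
## stage (model fitting, power, expected-value scoring).

#' Coefficients of a synthetic participant's decision policy
#'
#' The agent invests with probability `plogis(lp + u_i)` where `u_i` is a
#' participant random intercept drawn once per participant from
#' `Normal(0, sd_participant^2)` and `lp` is a linear predictor in the
#' decision features. For exp2/exp3 the features are the probability of
#' losing, trial-type dummies (random assignment as the baseline), the
#' dichotomous pre-task preference, and (exp3) a loss-framing dummy plus
#' optional numeracy/risk covariate terms. For exp1 the features are the
#' probability of losing, a personal-responsibility dummy, the number of
#' prior investments, and their interactions. Interaction coefficients for
#' exp2/exp3 default to 0.
#'
#' @param variant Task variant the defaults are taken from.
#' @param ... Named coefficient overrides (see the fields of the returned
#'   object), e.g. `beta_preference = 0` or `sd_participant = 0`.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params("exp2")
#' agent_params("exp2", sd_participant = 0)
#' @export
agent_params <- function(variant = c("exp2", "exp1", "exp3"), ...) {
    variant <- match.arg(variant)
    p <- switch(variant,
        exp1 = list(
            beta_intercept = 6.20, beta_p_lose = -5.90,
            beta_responsible = 2.32, beta_prior_investments = -0.69,
            beta_p_lose_x_responsible = -2.07,
            beta_p_lose_x_prior = 0.42,
            beta_responsible_x_prior = -0.36,
            beta_p_lose_x_responsible_x_prior = 0.48,
            beta_optimal_assigned = 0, beta_preference = 0,
            beta_framing_loss = 0, beta_numeracy = 0, beta_risk = 0,
            sd_participant = sqrt(0.35)),
        exp2 = list(
            beta_intercept = 1.39, beta_p_lose = -3.18,
            beta_responsible = 1.77, beta_optimal_assigned = 0.51,
            beta_preference = 1.24,
            beta_prior_investments = 0,
            beta_p_lose_x_responsible = 0, beta_p_lose_x_prior = 0,
            beta_responsible_x_prior = 0,
            beta_p_lose_x_responsible_x_prior = 0,
            beta_framing_loss = 0, beta_numeracy = 0, beta_risk = 0,
            sd_participant = sqrt(0.25)),
        exp3 = list(
            beta_intercept = 2.40, beta_p_lose = -2.78,
            beta_responsible = 0.99, beta_optimal_assigned = 0.37,
            beta_preference = 0.74, beta_framing_loss = 0.54,
            beta_numeracy = -0.06, beta_risk = -0.06,
            beta_prior_investments = 0,
            beta_p_lose_x_responsible = 0, beta_p_lose_x_prior = 0,
            beta_responsible_x_prior = 0,
            beta_p_lose_x_responsible_x_prior = 0,
            sd_participant = sqrt(0.25)))
    p$variant <- variant
    dots <- list(...)
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown agent parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
    stopifnot(p$sd_participant >= 0, all(is.finite(unlist(p[startsWith(names(p), "beta")]))))
    structure(p, class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
    b <- unlist(x[startsWith(names(x), "beta")])
    b <- b[b != 0 | names(b) == "beta_intercept"]
    cat("<agent_params ", x$variant, "> ",
        paste(sprintf("%s=%.3g", sub("^beta_", "", names(b)), b),
              collapse = ", "),
        "; sd_participant=", format(x$sd_participant), "\n", sep = "")
    invisible(x)
}

# vectorized linear predictor over decision-feature rows. `features` is a
# data frame (or list of equal-length vectors) with p_lose and, as needed,
# condition, preference, framing, prior_investments, responsible, numeracy,
# risk.
agent_linear_predictor <- function(agent, features) {
    f <- as.data.frame(features, stringsAsFactors = FALSE)
    n <- nrow(f)
    num <- function(x) if (is.null(x)) rep(0, n) else ifelse(is.na(x), 0, x)
    p_lose <- f$p_lose
    stopifnot(all(p_lose >= 0 & p_lose <= 1))
    if (agent$variant == "exp1") {
        resp <- as.numeric(num(f$responsible))
        prior <- num(f$prior_investments)
        agent$beta_intercept +
            agent$beta_p_lose * p_lose +
            agent$beta_responsible * resp +
            agent$beta_prior_investments * prior +
            agent$beta_p_lose_x_responsible * p_lose * resp +
            agent$beta_p_lose_x_prior * p_lose * prior +
            agent$beta_responsible_x_prior * resp * prior +
            agent$beta_p_lose_x_responsible_x_prior * p_lose * resp * prior
    } else {
        cond <- if (is.null(f$condition)) rep("random_assigned", n) else f$condition
        responsible <- as.numeric(cond == "responsible")
        optimal <- as.numeric(cond == "optimal_assigned")
        loss <- if (is.null(f$framing)) rep(0, n) else as.numeric(!is.na(f$framing) & f$framing == "loss")
        agent$beta_intercept +
            agent$beta_p_lose * p_lose +
            agent$beta_responsible * responsible +
            agent$beta_optimal_assigned * optimal +
            agent$beta_preference * num(f$preference) +
            agent$beta_framing_loss * loss +
            agent$beta_numeracy * num(f$numeracy) +
            agent$beta_risk * num(f$risk) +
            agent$beta_p_lose_x_responsible * p_lose * responsible
    }
}

#' Investment probability of an agent at given features
#'
#' Deterministic counterpart of [decide_invest()]: the logistic probability
#' `plogis(lp + u)` of investing.
#'
#' @param agent An [agent_params()] object.
#' @param features Data frame (or list) of decision features; see
#'   [agent_params()] for the feature set of each variant.
#' @param u Participant random-intercept value(s) on the logit scale.
#' @return Numeric vector of invest probabilities.
#' @examples
#' a <- agent_params("exp2")
#' invest_probability(a, list(p_lose = 0, condition = "responsible",
#'                            preference = 1))  # plogis(1.39 + 1.77 + 1.24)
#' @export
invest_probability <- function(agent, features, u = 0) {
    stopifnot(inherits(agent, "agent_params"))
    plogis(agent_linear_predictor(agent, features) + u)
}

#' Draw an agent's invest/opt-out decision
#'
#' Bernoulli draw (using the current RNG state) with the probability given
#' by [invest_probability()].
#'
#' @inheritParams invest_probability
#' @return Integer vector of decisions, 1 = invest, 0 = opt out.
#' @export
decide_invest <- function(agent, features, u = 0) {
    p <- invest_probability(agent, features, u)
    rbinom(length(p), 1L, p)
}

#' Elicit an agent's dichotomous pre-task preference
#'
#' The preference for a trial's initial configuration (three shared cards
#' revealed, before any investment) is generated from the agent's stage-one
#' policy: a Bernoulli draw with logit
#' `beta_intercept + beta_p_lose * p_lose + u`. The same policy governs the
#' agent's stage-one play decision in personally responsible trials, so
#' preference and play are linked only through shared coefficients and the
#' random intercept.
#'
#' @param agent An [agent_params()] object.
#' @param p_lose Probability of losing at the initial configuration.
#' @param u Participant random intercept.
#' @return Integer vector, 1 = would invest, 0 = would not.
#' @export
elicit_preference <- function(agent, p_lose, u = 0) {
    stopifnot(inherits(agent, "agent_params"),
              all(p_lose >= 0 & p_lose <= 1))
    p <- plogis(agent$beta_intercept + agent$beta_p_lose * p_lose + u)
    rbinom(length(p), 1L, p)
}

# stage-one play probability (responsible trials / fresh exp1 stages):
# intercept + p_lose slope + random intercept only
stage1_invest_prob <- function(agent, p_lose, u) {
    plogis(agent$beta_intercept + agent$beta_p_lose * p_lose + u)
}

default_design <- function(variant) {
    switch(variant,
           exp1 = list(n_participants = 51L, n_trials = 100L,
                       conditions = c("responsible", "random_assigned")),
           exp2 = list(n_participants = 49L, n_trials = 150L,
                       conditions = CONDITIONS),
           exp3 = list(n_participants = 80L, n_trials = 90L,
                       conditions = CONDITIONS))
}

#' Simulate a full experiment of synthetic participants
#'
#' Generates the complete decision log of one experiment: per participant a
#' random intercept is drawn once, trials are generated and shuffled across
#' conditions, assigned trials whose advisor opts out are regenerated (they
#' count neither toward the payout nor as trials played), preferences are
#' elicited for every analyzed trial (exp2/exp3), and each reachable
#' reinvestment decision is drawn from the agent's logistic policy.
#'
#' Defaults reproduce the study designs: exp1 = 51 participants, 100
#' trials (half responsible, half computer-assigned); exp2 = 49
#' participants, 150 trials (50 per condition); exp3 = 80 participants, 90
#' trials (30 per condition) with a balanced between-participant gain/loss
#' framing allocation.
#'
#' @param variant Task variant.
#' @param n_participants,n_trials Design size; `NULL` means the variant's
#'   study default. `n_trials` must be divisible by the number of
#'   conditions.
#' @param agent An [agent_params()] object (default: the variant's fitted
#'   coefficients).
#' @param framing_allocation exp3 only: character vector of `"gain"`/
#'   `"loss"` per participant (default alternating, i.e. balanced).
#' @param seed Integer seed governing all randomness of the session.
#' @param exact_cap,mc_samples Outcome-probability settings (see
#'   [outcome_probabilities()]).
#' @return A data frame with one row per analyzed reinvestment decision and
#'   columns `participant_id`, `trial_id`, `variant`, `condition`,
#'   `framing`, `stage`, `prior_investments`, `responsibility_code`,
#'   `p_win`, `p_tie`, `p_lose`, `preference`, `numeracy`, `risk`,
#'   `decision` (1 = invest), `invested`, `payout`. Per-participant random
#'   intercepts are in `attr(, "u")`; per-participant session totals in
#'   `attr(, "session")`.
#' @examples
#' \donttest{
#' d <- simulate_experiment("exp2", n_participants = 2, seed = 1)
#' head(d)
#' }
#' @export
simulate_experiment <- function(variant = c("exp2", "exp1", "exp3"),
                                n_participants = NULL, n_trials = NULL,
                                agent = NULL, framing_allocation = NULL,
                                seed, exact_cap = 250000,
                                mc_samples = 20000L) {
    variant <- match.arg(variant)
    if (missing(seed)) stop("simulate_experiment() requires a seed")
    des <- default_design(variant)
    if (is.null(n_participants)) n_participants <- des$n_participants
    if (is.null(n_trials)) n_trials <- des$n_trials
    if (is.null(agent)) agent <- agent_params(variant)
    stopifnot(inherits(agent, "agent_params"))
    if (agent$variant != variant) {
        stop("agent parameters are for ", agent$variant,
             " but the requested variant is ", variant)
    }
    k <- length(des$conditions)
    if (n_trials %% k != 0L) {
        stop("n_trials must be divisible by ", k, " (conditions: ",
             paste(des$conditions, collapse = ", "), ")")
    }
    if (variant == "exp3") {
        if (is.null(framing_allocation)) {
            framing_allocation <- rep(c("gain", "loss"),
                                      length.out = n_participants)
        }
        stopifnot(length(framing_allocation) == n_participants,
                  all(framing_allocation %in% c("gain", "loss")))
    }

    set.seed(seed)
    u <- rnorm(n_participants, 0, agent$sd_participant)
    rows <- vector("list", n_participants)
    session <- vector("list", n_participants)

    for (p in seq_len(n_participants)) {
        framing <- if (variant == "exp3") framing_allocation[p] else NA_character_
        numeracy <- if (variant == "exp3") rnorm(1) else NA_real_
        risk <- if (variant == "exp3") rnorm(1) else NA_real_
        conds <- sample(rep(des$conditions, each = n_trials / k))
        prows <- vector("list", n_trials)
        total_payout <- 0
        for (i in seq_len(n_trials)) {
            if (variant == "exp1") {
                res <- sim_trial_exp1(agent, conds[i], i, u[p],
                                      exact_cap, mc_samples)
            } else {
                res <- sim_trial_reinvest(variant, agent, conds[i], i, u[p],
                                          framing, numeracy, risk,
                                          exact_cap, mc_samples)
            }
            total_payout <- total_payout + res$payout
            if (!is.null(res$rows)) prows[[i]] <- res$rows
        }
        prow <- do.call(rbind, prows)
        if (!is.null(prow) && nrow(prow)) {
            prow$participant_id <- p
            prow$framing <- framing
            prow$numeracy <- numeracy
            prow$risk <- risk
            rows[[p]] <- prow
        }
        session[[p]] <- data.frame(participant_id = p, framing = framing,
                                   total_payout = total_payout,
                                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[, c("participant_id", "trial_id", "variant", "condition",
                   "framing", "stage", "prior_investments",
                   "responsibility_code", "p_win", "p_tie", "p_lose",
                   "preference", "numeracy", "risk", "decision",
                   "invested", "payout")]
    rownames(out) <- NULL
    attr(out, "u") <- u
    attr(out, "session") <- do.call(rbind, session)
    attr(out, "agent") <- agent
    attr(out, "seed") <- seed
    out
}

# one exp2/exp3 trial: regenerate while the advisor opts out, elicit the
# preference, then play stage 1 (agent or advisor) and, if invested, draw
# the analyzed stage-2 reinvestment decision
sim_trial_reinvest <- function(variant, agent, condition, trial_id, u,
                               framing, numeracy, risk,
                               exact_cap, mc_samples) {
    repeat {
        trial <- generate_trial(variant, condition, trial_id)
        probs1 <- probs_in_stream(trial_state_at(trial, 3L),
                                  exact_cap, mc_samples)
        if (condition == "random_assigned") {
            d1 <- advisor_random()
        } else if (condition == "optimal_assigned") {
            d1 <- advisor_optimal(probs1)
        } else {
            d1 <- NA_character_
        }
        if (is.na(d1) || d1 == "invest") break
        # advisor opted out: trial does not count, regenerate
    }
    pref <- elicit_preference(agent, probs1$p_lose, u)
    if (condition == "responsible") {
        invest1 <- rbinom(1L, 1L, stage1_invest_prob(agent, probs1$p_lose, u))
        if (invest1 == 0L) {
            return(list(payout = cost_schedule(variant)$endowment, rows = NULL))
        }
    }
    probs2 <- probs_in_stream(trial_state_at(trial, 4L),
                              exact_cap, mc_samples)
    feats <- list(p_lose = probs2$p_lose, condition = condition,
                  preference = pref, framing = framing,
                  numeracy = numeracy, risk = risk)
    d2 <- decide_invest(agent, feats, u)
    sched <- cost_schedule(variant)
    if (d2 == 1L) {
        outc <- showdown(trial$player_hole, trial$opp_hole, trial$board)
        invested <- sum(sched$stage_costs)
        payout <- switch(outc,
                         win = 2 * invested, tie = invested, lose = 0)
    } else {
        invested <- sched$stage_costs[1]
        payout <- sched$endowment - invested
    }
    rows <- data.frame(trial_id = trial_id, variant = variant,
                       condition = condition, stage = 2L,
                       prior_investments = 1L,
                       responsibility_code = if (condition == "responsible")
                           "responsible" else "assigned",
                       p_win = probs2$p_win, p_tie = probs2$p_tie,
                       p_lose = probs2$p_lose, preference = pref,
                       decision = d2, invested = invested, payout = payout,
                       stringsAsFactors = FALSE)
    list(payout = payout, rows = rows)
}

# one exp1 trial: stagewise decisions from the agent's policy; fresh
# stage-1 decisions are played but excluded from the analysis rows
sim_trial_exp1 <- function(agent, condition, trial_id, u,
                           exact_cap, mc_samples) {
    trial <- generate_trial("exp1", condition, trial_id)
    agent_policy <- function(f) {
        p <- if (f$responsibility_code == "none") {
            stage1_invest_prob(agent, f$p_lose, u)
        } else {
            invest_probability(agent,
                list(p_lose = f$p_lose,
                     responsible = f$responsibility_code == "responsible",
                     prior_investments = f$prior_investments), u)
        }
        if (rbinom(1L, 1L, p) == 1L) "invest" else "opt_out"
    }
    res <- play_trial(trial, agent_policy,
                      exact_cap = exact_cap, mc_samples = mc_samples)
    d <- code_responsibility(res)
    rows <- NULL
    if (nrow(d)) {
        rows <- data.frame(trial_id = trial_id, variant = "exp1",
                           condition = condition, stage = d$stage,
                           prior_investments = d$prior_investments,
                           responsibility_code = d$responsibility_code,
                           p_win = d$p_win, p_tie = d$p_tie,
                           p_lose = d$p_lose, preference = NA_integer_,
                           decision = as.integer(d$decision == "invest"),
                           invested = res$invested, payout = res$payout,
                           stringsAsFactors = FALSE)
    }
    list(payout = res$payout, rows = rows)
}
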
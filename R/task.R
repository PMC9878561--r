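## Stagewise invest/opt-out task engine: trial generation, cost schedules,
## advisors, payouts, responsibility coding, and gain/loss framing.
##
## Three variants are supported:
##   exp1 - up to five investment stages from a 310-point endowment
##          (costs 10/20/40/80/160); half the trials start mid-sequence with
##          computer-made prior investments.
##   exp2 - trials start with three shared cards revealed; two decisions
##          (invest 50, then reinvest 100) from a 150-point endowment;
##          responsible / random-advisor / optimal-advisor conditions.
##   exp3 - the exp2 structure with a between-participant gain/loss framing
##          of the (payout-identical) outcomes.

VARIANTS <- c("exp1", "exp2", "exp3")
CONDITIONS <- c("responsible", "random_assigned", "optimal_assigned")

#' Endowment and stage costs of a task variant
#'
#' @param variant `"exp1"`, `"exp2"`, or `"exp3"`.
#' @return List with `endowment` (points available at trial start) and
#'   `stage_costs` (cost of each successive investment).
#' @examples
#' cost_schedule("exp1")  # 310 points, costs 10/20/40/80/160
#' @export
cost_schedule <- function(variant = VARIANTS) {
    variant <- match.arg(variant)
    if (variant == "exp1") {
        list(endowment = 310, stage_costs = c(10, 20, 40, 80, 160))
    } else {
        list(endowment = 150, stage_costs = c(50, 100))
    }
}

#' Generate a random trial
#'
#' Draws nine distinct cards (two holes each, five shared) uniformly from
#' the deck using the current RNG state, with a condition-appropriate start
#' state: exp2/exp3 trials start with exactly three shared cards revealed;
#' exp1 assigned trials start with 1-4 cards revealed and the cumulative
#' stage costs already invested by the computer.
#'
#' @param variant Task variant.
#' @param condition `"responsible"`, `"random_assigned"`, or
#'   `"optimal_assigned"` (exp1 uses `"responsible"` and
#'   `"random_assigned"` only).
#' @param trial_id Identifier carried into logs.
#' @return An object of class `vip_trial`.
#' @examples
#' set.seed(1)
#' generate_trial("exp2", "responsible")
#' @export
generate_trial <- function(variant = VARIANTS, condition = CONDITIONS,
                           trial_id = 1L) {
    variant <- match.arg(variant)
    condition <- match.arg(condition)
    if (variant == "exp1" && condition == "optimal_assigned") {
        stop("exp1 has no optimal-assignment condition")
    }
    ids <- sample.int(52L, 9L) - 1L
    sched <- cost_schedule(variant)
    if (variant == "exp1") {
        if (condition == "responsible") {
            revealed <- 0L
        } else {
            revealed <- sample(1:4, 1L)
        }
        pre_invested <- if (revealed > 0L) sum(sched$stage_costs[seq_len(revealed)]) else 0
        start_stage <- revealed + 1L
    } else {
        revealed <- 3L
        pre_invested <- 0
        start_stage <- 1L
    }
    structure(list(trial_id = trial_id, variant = variant,
                   condition = condition,
                   player_hole = card_code(ids[1:2]),
                   opp_hole = card_code(ids[3:4]),
                   board = card_code(ids[5:9]),
                   revealed_at_start = revealed,
                   pre_invested = pre_invested,
                   start_stage = start_stage),
              class = "vip_trial")
}

#' @export
print.vip_trial <- function(x, ...) {
    cat(sprintf("<vip_trial %s> %s/%s hole %s vs %s board %s (%d revealed)\n",
                format(x$trial_id), x$variant, x$condition,
                paste(x$player_hole, collapse = " "),
                paste(x$opp_hole, collapse = " "),
                paste(x$board, collapse = " "), x$revealed_at_start))
    invisible(x)
}

#' Random advisor: a fair coin, independent of the cards
#'
#' @return `"invest"` or `"opt_out"`, each with probability 0.5, drawn from
#'   the current RNG state.
#' @export
advisor_random <- function() {
    if (runif(1) < 0.5) "invest" else "opt_out"
}

#' Optimal advisor: invest when winning or tying is more likely than losing
#'
#' Invests if `p_win + p_tie >= p_lose` and opts out if losing is strictly
#' more likely; the (measure-zero) equality case is resolved toward
#' investing, matching the advisor's maximizing role.
#'
#' @param probs An [outcome_probabilities()] result (or any list with
#'   `p_win`, `p_tie`, `p_lose`).
#' @return `"invest"` or `"opt_out"` (deterministic).
#' @export
advisor_optimal <- function(probs) {
    if (probs$p_win + probs$p_tie >= probs$p_lose) "invest" else "opt_out"
}

# state visible at decision stage `stage` (1-based): stage - 1 + initial
# reveals for exp1; 3 or 4 revealed for exp2/exp3
trial_state_at <- function(trial, n_revealed,
                           visibility = "opponent_known") {
    game_state(trial$player_hole, trial$opp_hole,
               trial$board[seq_len(n_revealed)], visibility = visibility)
}

#' Play one trial under a decision policy
#'
#' Runs the stagewise protocol: at each stage the deciding actor (the
#' participant's `policy`, or an advisor at stage one of assigned exp2/exp3
#' trials) chooses to invest (revealing the next shared card at the next
#' stage cost) or to opt out (banking the remaining endowment). If all
#' shared cards are revealed the showdown decides the payout: the remaining
#' endowment plus twice the invested points after a win, plus the invested
#' points after a tie, plus nothing after a loss.
#'
#' Assigned exp2/exp3 trials in which the advisor opts out are returned
#' with `outcome = "advisor_opted_out"` and `discarded = TRUE`; callers
#' (see [simulate_experiment()]) regenerate such trials, so they never
#' count as trials played.
#'
#' @param trial A [generate_trial()] result.
#' @param policy Function of one argument (a feature list with `variant`,
#'   `condition`, `stage`, `prior_investments`, `responsibility_code`,
#'   `p_win`, `p_tie`, `p_lose`, `preference`, `framing`) returning
#'   `"invest"` or `"opt_out"`.
#' @param preference Dichotomous pre-task preference (0/1) carried into the
#'   policy features, or `NA`.
#' @param framing `"gain"`, `"loss"`, or `NA`; presentation only, carried
#'   into the policy features (payouts are framing-invariant).
#' @param exact_cap,mc_samples Passed to the outcome-probability
#'   computation at each stage; Monte Carlo sub-seeds are drawn from the
#'   current RNG stream.
#' @return An object of class `vip_trial_result`: the trial, a data frame
#'   of per-stage decisions (with outcome probabilities, responsibility
#'   codes, and the deciding actor), the `outcome` (`"win"`, `"tie"`,
#'   `"lose"`, `"opted_out"`, or `"advisor_opted_out"`), total `invested`
#'   points, and the `payout`.
#' @export
play_trial <- function(trial, policy, preference = NA, framing = NA,
                       exact_cap = 250000, mc_samples = 20000L) {
    stopifnot(inherits(trial, "vip_trial"), is.function(policy))
    sched <- cost_schedule(trial$variant)
    n_stages <- length(sched$stage_costs)
    invested <- trial$pre_invested
    revealed <- trial$revealed_at_start
    decisions <- list()
    outcome <- NULL

    for (stage in trial$start_stage:n_stages) {
        probs <- probs_in_stream(trial_state_at(trial, revealed),
                                 exact_cap, mc_samples)
        prior <- stage - 1L
        if (trial$variant == "exp1") {
            resp <- if (stage == 1L) "none"
                    else if (stage == trial$start_stage) "assigned"
                    else "responsible"
            decided_by <- "participant"
        } else {
            advisor_turn <- stage == 1L && trial$condition != "responsible"
            resp <- if (stage == 1L) {
                if (trial$condition == "responsible") "none" else "advisor"
            } else {
                if (trial$condition == "responsible") "responsible" else "assigned"
            }
            decided_by <- if (advisor_turn) "advisor" else "participant"
        }

        if (decided_by == "advisor") {
            decision <- if (trial$condition == "random_assigned") {
                advisor_random()
            } else {
                advisor_optimal(probs)
            }
        } else {
            decision <- policy(list(variant = trial$variant,
                                    condition = trial$condition,
                                    stage = stage,
                                    prior_investments = prior,
                                    responsibility_code = resp,
                                    p_win = probs$p_win, p_tie = probs$p_tie,
                                    p_lose = probs$p_lose,
                                    preference = preference,
                                    framing = framing))
            if (!decision %in% c("invest", "opt_out")) {
                stop("policy must return \"invest\" or \"opt_out\", got: ",
                     deparse(decision))
            }
        }
        decisions[[length(decisions) + 1L]] <-
            data.frame(stage = stage, prior_investments = prior,
                       responsibility_code = resp, decided_by = decided_by,
                       p_win = probs$p_win, p_tie = probs$p_tie,
                       p_lose = probs$p_lose, decision = decision,
                       cost = sched$stage_costs[stage],
                       stringsAsFactors = FALSE)

        if (decision == "opt_out") {
            if (decided_by == "advisor") {
                outcome <- "advisor_opted_out"
            } else {
                outcome <- "opted_out"
            }
            break
        }
        invested <- invested + sched$stage_costs[stage]
        revealed <- revealed + 1L
    }

    if (is.null(outcome)) {
        outcome <- showdown(trial$player_hole, trial$opp_hole, trial$board)
    }
    remaining <- sched$endowment - invested
    payout <- switch(outcome,
                     win = remaining + 2 * invested,
                     tie = remaining + invested,
                     lose = remaining,
                     opted_out = remaining,
                     advisor_opted_out = NA_real_)
    structure(list(trial = trial,
                   decisions = do.call(rbind, decisions),
                   outcome = outcome, invested = invested, payout = payout,
                   discarded = outcome == "advisor_opted_out"),
              class = "vip_trial_result")
}

#' @export
print.vip_trial_result <- function(x, ...) {
    cat(sprintf("<vip_trial_result> %s: invested %g, payout %s (%d decision stage%s)\n",
                x$outcome, x$invested,
                if (is.na(x$payout)) "-" else format(x$payout),
                nrow(x$decisions), if (nrow(x$decisions) == 1) "" else "s"))
    invisible(x)
}

#' Responsibility coding of the analyzed decisions of a trial
#'
#' Extracts the participant's decision stages with their responsibility
#' codes and prior-investment counts: a stage after at least one of the
#' participant's own investments is `responsible`; the stage directly
#' following computer-made investments is `assigned`; the first stage of a
#' fresh trial is excluded (no prior investment exists there), as are
#' advisor decisions.
#'
#' @param trial_result A [play_trial()] result.
#' @return Data frame of analyzed decision rows (possibly zero rows).
#' @export
code_responsibility <- function(trial_result) {
    stopifnot(inherits(trial_result, "vip_trial_result"))
    d <- trial_result$decisions
    d[d$decided_by == "participant" & d$responsibility_code %in%
          c("responsible", "assigned"), , drop = FALSE]
}

#' Gain- versus loss-framed display of a trial outcome
#'
#' The two framings are payout-equivalent presentations: the gain frame
#' shows points accumulating from a 0 start (`+g`), the loss frame shows
#' points lost from a 300-point trial stake (`-(300 - g)`), so the gain and
#' the absolute framed loss always sum to 300. Session-level displays start
#' at 0 (gain) versus 27000 (loss) points.
#'
#' @param trial_points_gained Points credited for the trial (0 to 300).
#' @param framing `"gain"` or `"loss"`.
#' @return List with `framing`, `trial_start_display`, `displayed_change`,
#'   and `session_start_display`.
#' @examples
#' frame_display(100, "loss")  # shown as -200 from a 300-point trial stake
#' @export
frame_display <- function(trial_points_gained, framing = c("gain", "loss")) {
    framing <- match.arg(framing)
    g <- trial_points_gained
    if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0 || g > 300) {
        stop("trial_points_gained must be a single value in [0, 300]")
    }
    if (framing == "gain") {
        list(framing = "gain", trial_start_display = 0,
             displayed_change = g, session_start_display = 0)
    } else {
        list(framing = "loss", trial_start_display = 300,
             displayed_change = -(300 - g), session_start_display = 27000)
    }
}

#' Convert session points to the monetary bonus
#'
#' Five thousand points are worth 1 GBP, rounded half-up ("mathematically")
#' to one penny. Only the exp3 variant states a conversion rate; requesting
#' a conversion for exp1/exp2 is an error rather than a guess.
#'
#' @param points Non-negative session points.
#' @param variant Task variant (must be `"exp3"`).
#' @return Bonus in GBP, e.g. `convert_bonus(27000)` is 5.4.
#' @export
convert_bonus <- function(points, variant = "exp3") {
    if (!identical(variant, "exp3")) {
        stop("points-to-currency rate is only defined for exp3 ",
             "(5000 points = 1 GBP)")
    }
    stopifnot(is.numeric(points), all(points >= 0))
    floor(points / 5000 * 100 + 0.5) / 100
}
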
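## Expected-value scoring of reinvestment decisions, the optimal benchmark
## policy, and the classification of decision errors as escalation of
## commitment versus premature opt-out. Applies to the single-reinvestment
## variants (exp2/exp3): opting out is worth a sure 100 points and
## investing is worth 300 * (1 - p_lose), so the expected values cross at
## p_lose = 2/3. The multi-stage exp1 variant admits no fair per-decision
## expected value (it depends on future decisions) and is rejected.

normalize_decision <- function(decision) {
    if (is.numeric(decision)) {
        stopifnot(all(decision %in% c(0, 1)))
        ifelse(decision == 1, "invest", "opt_out")
    } else {
        stopifnot(all(decision %in% c("invest", "opt_out")))
        decision
    }
}

#' Expected value of a reinvestment decision
#'
#' Opt-out yields a sure 100 points; investing yields
#' `300 * (1 - p_lose)`. This is the task's nominal formula, which grants
#' a tie the win payout; see [score_decisions()] for an exact-tie variant.
#'
#' @param decision `"invest"`/`"opt_out"` (or 1/0), vectorized.
#' @param p_lose Probability of losing at the decision, in `[0, 1]`.
#' @param variant `"exp2"` or `"exp3"`; exp1 is rejected.
#' @return Expected value in points.
#' @examples
#' expected_value("opt_out", 0.9)  # 100
#' expected_value("invest", 2/3)   # 100: the break-even point
#' @export
expected_value <- function(decision, p_lose, variant = "exp2") {
    if (!variant %in% c("exp2", "exp3")) {
        stop("per-decision expected value is only defined for the ",
             "single-reinvestment variants (exp2, exp3)")
    }
    decision <- normalize_decision(decision)
    stopifnot(all(p_lose >= 0 & p_lose <= 1))
    ifelse(decision == "invest", 300 * (1 - p_lose), 100)
}

#' Expected-value-optimal reinvestment policy
#'
#' Invest while the probability of losing is below the 2/3 break-even
#' point; at or above it, opt out (indifference is resolved toward the
#' sure payout, where both actions' expected values are equal).
#'
#' @param p_lose Probability of losing, vectorized.
#' @return `"invest"` or `"opt_out"` per element.
#' @export
optimal_policy <- function(p_lose) {
    stopifnot(all(p_lose >= 0 & p_lose <= 1))
    ifelse(p_lose < 2 / 3, "invest", "opt_out")
}

#' Classify a decision against the optimal policy
#'
#' Investing when losing is more likely than the 2/3 break-even point is
#' escalation of commitment; opting out below it is a premature opt-out;
#' everything else (including either action exactly at the indifference
#' point, where the expected values are equal) is optimal.
#'
#' @inheritParams expected_value
#' @return `"optimal"`, `"escalation"`, or `"premature_opt_out"` per
#'   element.
#' @examples
#' classify_decision("invest", 0.8)   # escalation
#' classify_decision("opt_out", 0.2)  # premature_opt_out
#' @export
classify_decision <- function(decision, p_lose) {
    decision <- normalize_decision(decision)
    stopifnot(all(p_lose >= 0 & p_lose <= 1))
    ifelse(decision == "invest" & p_lose > 2 / 3, "escalation",
           ifelse(decision == "opt_out" & p_lose < 2 / 3,
                  "premature_opt_out", "optimal"))
}

#' Score a decision table against the optimal policy
#'
#' Adds per-row expected values (`ev`), the optimal attainable expected
#' value (`optimal_ev`, the larger of the two actions'), and the error
#' `classification`. `ev_method = "exact"` replaces the nominal invest
#' formula by `300 * p_win + 150 * p_tie`, which pays ties their actual
#' payout, for sensitivity checks; the classification always uses the
#' nominal 2/3 rule.
#'
#' @param data Decision table with columns `decision`, `p_lose` (and
#'   `p_win`, `p_tie` for the exact method); exp2/exp3 rows only.
#' @param ev_method `"nominal"` (the task's formula) or `"exact"`.
#' @return The table with `ev`, `optimal_ev`, `classification` columns.
#' @export
score_decisions <- function(data, ev_method = c("nominal", "exact")) {
    ev_method <- match.arg(ev_method)
    d <- as.data.frame(data)
    if (!is.null(d$variant) && any(d$variant == "exp1")) {
        stop("expected-value scoring is not defined for exp1 rows")
    }
    dec <- normalize_decision(d$decision)
    if (ev_method == "nominal") {
        ev_invest <- 300 * (1 - d$p_lose)
    } else {
        ev_invest <- 300 * d$p_win + 150 * d$p_tie
    }
    d$ev <- ifelse(dec == "invest", ev_invest, 100)
    d$optimal_ev <- pmax(ev_invest, 100)
    d$classification <- classify_decision(dec, d$p_lose)
    d
}

#' Per-condition summary of scored decisions
#'
#' Aggregates a scored decision table by condition (and framing, when
#' present): group counts, invest rate, mean expected value, mean optimal
#' expected value, the expected-value shortfall
#' `mean(optimal_ev - ev) >= 0`, and the three classification rates.
#'
#' @param scored A [score_decisions()] result.
#' @return Data frame with one row per group.
#' @export
session_summary <- function(scored) {
    d <- as.data.frame(scored)
    stopifnot(all(c("ev", "optimal_ev", "classification") %in% names(d)))
    by_cols <- "condition"
    if (!is.null(d$framing) && !all(is.na(d$framing))) {
        by_cols <- c("condition", "framing")
    }
    groups <- unique(d[by_cols])
    rows <- lapply(seq_len(nrow(groups)), function(i) {
        sel <- rep(TRUE, nrow(d))
        for (bc in by_cols) sel <- sel & d[[bc]] == groups[[bc]][i]
        g <- d[sel, ]
        data.frame(groups[i, , drop = FALSE],
                   n = nrow(g),
                   invest_rate = mean(normalize_decision(g$decision) == "invest"),
                   mean_ev = mean(g$ev),
                   mean_optimal_ev = mean(g$optimal_ev),
                   ev_shortfall = mean(g$optimal_ev - g$ev),
                   rate_optimal = mean(g$classification == "optimal"),
                   rate_escalation = mean(g$classification == "escalation"),
                   rate_premature = mean(g$classification == "premature_opt_out"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$condition), , drop = FALSE]
}
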
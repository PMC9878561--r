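## Outcome probabilities for a partially revealed trial: the probability of
## winning / tying / losing the showdown if the trial is played to the end,
## averaged over all equally likely completions of the hidden cards.

#' Describe a partially revealed trial state
#'
#' @param player_hole,opp_hole Character vectors of 2 card codes each.
#' @param board Character vector of 0 to 5 revealed shared-card codes.
#' @param visibility `"opponent_known"` (both holes on the table, the
#'   default for this task: only board cards are hidden) or
#'   `"opponent_hidden"` (probabilities are computed as if the opponent's
#'   hole cards were also unknown, i.e. from the player's information set).
#' @return An object of class `game_state`.
#' @examples
#' game_state(c("Ah", "Ad"), c("Kh", "Kd"), c("2c", "4d", "7s"))
#' @export
game_state <- function(player_hole, opp_hole, board = character(),
                       visibility = c("opponent_known", "opponent_hidden")) {
    visibility <- match.arg(visibility)
    stopifnot(length(player_hole) == 2L, length(opp_hole) == 2L)
    if (length(board) > 5L) stop("at most 5 shared cards can be revealed")
    check_distinct(card_id(c(player_hole, opp_hole, board)))
    structure(list(player_hole = player_hole, opp_hole = opp_hole,
                   board = board, visibility = visibility),
              class = "game_state")
}

#' Number of hidden-card completions of a game state
#'
#' Counts the distinct, equally likely completions the exact method
#' enumerates: all ways to fill the hidden board cards from the unseen deck
#' and, when `visibility = "opponent_hidden"`, all opponent hole-card pairs.
#'
#' @param state A [game_state()].
#' @return A single number, e.g. `choose(45, 2) = 990` for a state with
#'   three revealed shared cards and a known opponent.
#' @export
completion_count <- function(state) {
    stopifnot(inherits(state, "game_state"))
    hidden <- 5L - length(state$board)
    known_opp <- state$visibility == "opponent_known"
    unseen <- 52L - 2L - (if (known_opp) 2L else 0L) - length(state$board)
    n <- choose(unseen, hidden)
    if (!known_opp) n <- n * choose(unseen - hidden, 2L)
    n
}

#' Win/tie/lose probabilities of a partially revealed trial
#'
#' Computes the probability that the player wins, ties, or loses the
#' showdown if the trial is played to the end, over all equally likely
#' completions of the hidden cards. The exact method enumerates every
#' completion; the Monte Carlo method samples completions uniformly.
#'
#' @param state A [game_state()].
#' @param method `"auto"` (exact when [completion_count()] is at most
#'   `exact_cap`, Monte Carlo otherwise), `"exact"`, or `"monte_carlo"`.
#'   Requesting `"exact"` above the cap is an error, never a silent
#'   fallback.
#' @param n_samples Number of Monte Carlo samples (default 20000).
#' @param seed Integer seed, required whenever Monte Carlo sampling is used.
#' @param exact_cap Largest completion count the exact method will
#'   enumerate (default 250000, which covers every state of the task
#'   variants with a known opponent and at least one revealed shared card).
#' @return An object of class `outcome_probs`: a list with `p_win`,
#'   `p_tie`, `p_lose` (summing to 1 exactly for the exact method), the
#'   `method` used, and `n` (completions enumerated or samples drawn).
#' @examples
#' st <- game_state(c("Ah", "Ad"), c("Kh", "Kd"), c("2c", "4d", "7s"))
#' outcome_probabilities(st)
#' @export
outcome_probabilities <- function(state,
                                  method = c("auto", "exact", "monte_carlo"),
                                  n_samples = 20000L, seed = NULL,
                                  exact_cap = 250000) {
    stopifnot(inherits(state, "game_state"))
    method <- match.arg(method)
    n_exact <- completion_count(state)
    if (method == "auto") {
        method <- if (n_exact <= exact_cap) "exact" else "monte_carlo"
    }
    opp_known <- state$visibility == "opponent_known"
    p_ids <- card_id(state$player_hole)
    o_ids <- card_id(state$opp_hole)
    b_ids <- if (length(state$board)) card_id(state$board) else integer()

    if (method == "exact") {
        if (n_exact > exact_cap) {
            stop("exact enumeration would require ", format(n_exact),
                 " completions (cap ", format(exact_cap),
                 "); use method = \"monte_carlo\"")
        }
        cnt <- cpp_outcome_counts(p_ids, o_ids, b_ids, opp_known)
        n_used <- sum(cnt)
        stopifnot(n_used == n_exact)
    } else {
        if (is.null(seed)) {
            stop("monte_carlo method requires an explicit seed")
        }
        stopifnot(n_samples >= 1L)
        set.seed(seed)
        cnt <- cpp_outcome_counts_mc(p_ids, o_ids, b_ids, opp_known,
                                     as.integer(n_samples))
        n_used <- n_samples
    }
    structure(list(p_win = cnt[1] / sum(cnt),
                   p_tie = cnt[2] / sum(cnt),
                   p_lose = cnt[3] / sum(cnt),
                   method = method, n = n_used),
              class = "outcome_probs")
}

#' @export
print.outcome_probs <- function(x, ...) {
    cat(sprintf("<outcome_probs> win %.4f / tie %.4f / lose %.4f (%s, n = %s)\n",
                x$p_win, x$p_tie, x$p_lose, x$method, format(x$n)))
    invisible(x)
}

# internal: probabilities inside a seeded simulation stream. Monte Carlo
# sub-seeds are drawn from the current RNG stream so one session seed
# governs everything while outcome_probabilities() keeps its mandatory-seed
# contract.
probs_in_stream <- function(state, exact_cap, mc_samples) {
    if (completion_count(state) <= exact_cap) {
        outcome_probabilities(state, method = "exact", exact_cap = exact_cap)
    } else {
        sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        outcome_probabilities(state, method = "monte_carlo",
                              n_samples = mc_samples, seed = sub_seed)
    }
}
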
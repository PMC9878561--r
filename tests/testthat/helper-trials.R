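# deterministic trial with chosen cards (bypasses the random draw)
fixed_trial <- function(variant, condition, player, opp, board,
                        start_stage = NULL) {
    sched <- cost_schedule(variant)
    if (variant == "exp1") {
        if (is.null(start_stage)) start_stage <- 1L
        revealed <- start_stage - 1L
        pre <- if (revealed > 0) sum(sched$stage_costs[seq_len(revealed)]) else 0
    } else {
        start_stage <- 1L
        revealed <- 3L
        pre <- 0
    }
    structure(list(trial_id = 1L, variant = variant, condition = condition,
                   player_hole = player, opp_hole = opp, board = board,
                   revealed_at_start = revealed, pre_invested = pre,
                   start_stage = start_stage),
              class = "vip_trial")
}

always_invest <- function(f) "invest"
always_opt_out <- function(f) "opt_out"

# a trial the player is certain to win (royal flush vs nothing)
sure_win_trial <- function(variant = "exp2", condition = "responsible") {
    fixed_trial(variant, condition, c("As", "Ks"), c("2d", "7h"),
                c("Qs", "Js", "Ts", "3c", "4d"))
}
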
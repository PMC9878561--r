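## Five-card hand ranking, best-of-seven evaluation, and showdowns under
## standard (Texas hold'em) poker rules. The ace plays high and low
## (A-2-3-4-5 is a five-high straight); suits never break ties, so ties are
## possible and meaningful.

HAND_CATEGORIES <- c("high_card", "pair", "two_pair", "three_of_a_kind",
                     "straight", "flush", "full_house", "four_of_a_kind",
                     "straight_flush")

# integer hand code -> hand_rank object
new_hand_rank <- function(code) {
    cat_i <- code %/% 2L^20L
    nib <- integer(5)
    rest <- code %% 2L^20L
    for (i in 5:1) {
        nib[i] <- rest %% 16L
        rest <- rest %/% 16L
    }
    structure(list(category = HAND_CATEGORIES[cat_i + 1L],
                   tiebreak = nib[nib > 0L],
                   code = code),
              class = "hand_rank")
}

#' Rank a five-card poker hand
#'
#' Assigns a hand its category (high card up to straight flush) and the
#' category-specific kicker sequence that breaks ties within a category.
#' Comparison of two hand ranks is a total order: equal category and equal
#' tiebreak sequence is a genuine tie (suits are never compared).
#'
#' @param cards Character vector of exactly 5 distinct card codes
#'   (see [full_deck()]).
#' @return An object of class `hand_rank` with elements `category`
#'   (character), `tiebreak` (integer vector of ranks, 14 = ace), and `code`
#'   (a single integer whose numeric order is the hand order). Comparison
#'   operators (`<`, `==`, ...) are defined between `hand_rank` objects.
#' @examples
#' rank_five(c("As", "Ks", "Qs", "Js", "Ts"))  # royal flush
#' rank_five(c("Ac", "2d", "3h", "4s", "5c"))  # ace-low straight, five high
#' @export
rank_five <- function(cards) {
    if (length(cards) != 5L) stop("rank_five() requires exactly 5 cards")
    ids <- check_distinct(card_id(cards))
    new_hand_rank(cpp_eval5(ids))
}

#' Best five-card hand out of seven cards
#'
#' Evaluates the strongest five-card hand obtainable from two hole cards and
#' five shared cards; equals the maximum of [rank_five()] over all 21
#' five-card subsets.
#'
#' @param cards Character vector of exactly 7 distinct card codes.
#' @return A `hand_rank` object (see [rank_five()]).
#' @examples
#' best_of_seven(c("As", "Ks", "Qs", "Js", "Ts", "2h", "3d"))
#' @export
best_of_seven <- function(cards) {
    if (length(cards) != 7L) stop("best_of_seven() requires exactly 7 cards")
    ids <- check_distinct(card_id(cards))
    new_hand_rank(cpp_eval7(ids))
}

#' Compare both players' best hands at showdown
#'
#' @param player_hole,opp_hole Character vectors of 2 card codes each.
#' @param board Character vector of 5 card codes (the fully revealed shared
#'   cards). All 9 cards must be distinct.
#' @return `"win"`, `"tie"`, or `"lose"`, from the player's perspective.
#' @examples
#' showdown(c("Ah", "Ad"), c("Kh", "Kd"), c("2c", "4d", "7s", "9c", "Qh"))
#' @export
showdown <- function(player_hole, opp_hole, board) {
    stopifnot(length(player_hole) == 2L, length(opp_hole) == 2L,
              length(board) == 5L)
    ids <- check_distinct(card_id(c(player_hole, opp_hole, board)))
    p <- cpp_eval7(ids[c(1:2, 5:9)])
    o <- cpp_eval7(ids[c(3:4, 5:9)])
    if (p > o) "win" else if (p == o) "tie" else "lose"
}

#' @export
print.hand_rank <- function(x, ...) {
    cat("<hand_rank> ", x$category, " (",
        paste(x$tiebreak, collapse = ","), ")\n", sep = "")
    invisible(x)
}

#' @export
Ops.hand_rank <- function(e1, e2) {
    if (!.Generic %in% c("<", ">", "<=", ">=", "==", "!=")) {
        stop("operation '", .Generic, "' not defined for hand_rank objects")
    }
    get(.Generic)(e1$code, e2$code)
}
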
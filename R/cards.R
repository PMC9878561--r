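## Card representation
##
## Public card codes are two- or three-character strings: a rank symbol
## ("2".."9", "T" or "10", "J", "Q", "K", "A") followed by a suit letter
## ("c", "d", "h", "s"). Reading is case-insensitive; the canonical written
## form is e.g. "Th", "As". Internally cards are integers 0..51 with
## rank = id %/% 4 + 2 and suit = id %% 4 (suits ordered c, d, h, s).

RANK_CHARS <- c("2", "3", "4", "5", "6", "7", "8", "9", "T", "J", "Q", "K", "A")
SUIT_CHARS <- c("c", "d", "h", "s")

#' All 52 card codes of a standard deck
#'
#' @return Character vector of length 52, e.g. `"2c"`, `"Th"`, `"As"`.
#' @examples
#' length(full_deck())
#' @export
full_deck <- function() {
    as.vector(t(outer(RANK_CHARS, SUIT_CHARS, paste0)))
}

# character codes -> integer ids 0..51 (errors on anything malformed)
card_id <- function(codes) {
    if (!is.character(codes)) stop("card codes must be character strings")
    x <- tolower(trimws(codes))
    x <- sub("^10", "t", x)
    rank_ch <- substr(x, 1, 1)
    suit_ch <- substr(x, 2, 2)
    r <- match(rank_ch, tolower(RANK_CHARS))
    s <- match(suit_ch, SUIT_CHARS)
    bad <- is.na(r) | is.na(s) | nchar(x) != 2
    if (any(bad)) {
        stop("invalid card code(s): ", paste(codes[bad], collapse = ", "))
    }
    as.integer((r - 1L) * 4L + (s - 1L))
}

# integer ids 0..51 -> character codes
card_code <- function(ids) {
    stopifnot(all(ids >= 0L & ids <= 51L))
    paste0(RANK_CHARS[ids %/% 4L + 1L], SUIT_CHARS[ids %% 4L + 1L])
}

# numeric rank 2..14 of each card code
card_rank <- function(codes) card_id(codes) %/% 4L + 2L

check_distinct <- function(ids, what = "cards") {
    if (anyDuplicated(ids)) {
        stop("duplicate ", what, ": ",
             paste(card_code(ids[duplicated(ids)]), collapse = ", "))
    }
    invisible(ids)
}
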
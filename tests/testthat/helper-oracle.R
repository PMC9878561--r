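# Independent pure-R five-card hand oracle, written against the standard
# rules from scratch (table()-based, no shared code with the package).
# Returns a length-6 numeric vector (category, five tiebreak slots) that
# compares lexicographically.

ORACLE_CATS <- c("high_card", "pair", "two_pair", "three_of_a_kind",
                 "straight", "flush", "full_house", "four_of_a_kind",
                 "straight_flush")

oracle_rank5 <- function(cards) {
    lookup <- c(`2` = 2, `3` = 3, `4` = 4, `5` = 5, `6` = 6, `7` = 7,
                `8` = 8, `9` = 9, t = 10, j = 11, q = 12, k = 13, a = 14)
    x <- tolower(cards)
    r <- unname(lookup[substr(x, 1, 1)])
    s <- substr(x, 2, 2)
    stopifnot(!anyNA(r), length(cards) == 5)
    counts <- table(r)
    cnt <- as.integer(counts)
    rk <- as.integer(names(counts))
    ord <- order(-cnt, -rk)
    cnt <- cnt[ord]
    rk <- rk[ord]
    flush <- length(unique(s)) == 1
    u <- sort(unique(r))
    straight <- FALSE
    high <- 0
    if (length(u) == 5) {
        if (max(u) - min(u) == 4) {
            straight <- TRUE
            high <- max(u)
        } else if (setequal(u, c(2, 3, 4, 5, 14))) {
            straight <- TRUE
            high <- 5
        }
    }
    pattern <- paste(cnt, collapse = "")
    cat_i <- if (straight && flush) 8
             else if (pattern == "41") 7
             else if (pattern == "32") 6
             else if (flush) 5
             else if (straight) 4
             else if (pattern == "311") 3
             else if (pattern == "221") 2
             else if (pattern == "2111") 1
             else 0
    tb <- if (straight) high else rk
    c(cat_i, tb, rep(0, 5 - length(tb)))
}

# lexicographic comparison of two oracle vectors: -1 / 0 / 1
oracle_compare <- function(a, b) {
    d <- a - b
    nz <- which(d != 0)
    if (length(nz) == 0) 0 else sign(d[nz[1]])
}

# package hand_rank -> the oracle's vector layout
hand_rank_vec <- function(hr) {
    c(match(hr$category, ORACLE_CATS) - 1L, hr$tiebreak,
      rep(0, 5 - length(hr$tiebreak)))
}

# best-of-seven oracle: exhaustive max over all 21 five-card subsets of the
# independent five-card oracle
oracle_best7 <- function(cards) {
    stopifnot(length(cards) == 7)
    best <- NULL
    for (drop2 in utils::combn(7, 2, simplify = FALSE)) {
        v <- oracle_rank5(cards[-drop2])
        if (is.null(best) || oracle_compare(v, best) > 0) best <- v
    }
    best
}

random_cards <- function(n) sample(full_deck(), n)
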
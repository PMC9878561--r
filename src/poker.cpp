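#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Card ids are 0..51: rank = id / 4 + 2 (2..14, 14 = ace), suit = id % 4.
// A five-card hand is encoded as a single comparable integer:
//   (category << 20) | t1 << 16 | t2 << 12 | t3 << 8 | t4 << 4 | t5
// where category is 0 (high card) .. 8 (straight flush) and t1..t5 is the
// category-specific kicker sequence (ranks 2..14 fit in a nibble). Suits
// never enter the code, so equal codes mean a genuine tie.

static inline int eval5(const int r[5], const int s[5]) {
    int cnt[15];
    for (int v = 0; v < 15; ++v) cnt[v] = 0;
    for (int i = 0; i < 5; ++i) cnt[r[i]]++;
    bool flush = s[0] == s[1] && s[1] == s[2] && s[2] == s[3] && s[3] == s[4];

    int ndist = 0, hi = 0, lo = 15;
    for (int v = 2; v <= 14; ++v) {
        if (cnt[v]) { ndist++; if (v > hi) hi = v; if (v < lo) lo = v; }
    }
    int straight_high = 0;
    if (ndist == 5) {
        if (hi - lo == 4) straight_high = hi;
        // ace-low wheel A-2-3-4-5 ranks as a five-high straight
        else if (hi == 14 && cnt[2] && cnt[3] && cnt[4] && cnt[5]) straight_high = 5;
    }

    int cat = 0, tb[5] = {0, 0, 0, 0, 0};
    if (straight_high) {
        cat = flush ? 8 : 4;
        tb[0] = straight_high;
    } else if (flush) {
        cat = 5;
        int k = 0;
        for (int v = 14; v >= 2; --v) if (cnt[v]) tb[k++] = v;
    } else {
        int quad = 0, trip = 0, p1 = 0, p2 = 0;
        for (int v = 14; v >= 2; --v) {
            if (cnt[v] == 4) quad = v;
            else if (cnt[v] == 3) trip = v;
            else if (cnt[v] == 2) { if (!p1) p1 = v; else p2 = v; }
        }
        if (quad) {
            cat = 7; tb[0] = quad;
            for (int v = 14; v >= 2; --v) if (cnt[v] == 1) tb[1] = v;
        } else if (trip && p1) {
            cat = 6; tb[0] = trip; tb[1] = p1;
        } else if (trip) {
            cat = 3; tb[0] = trip;
            int k = 1;
            for (int v = 14; v >= 2; --v) if (cnt[v] == 1) tb[k++] = v;
        } else if (p1 && p2) {
            cat = 2; tb[0] = p1; tb[1] = p2;
            for (int v = 14; v >= 2; --v) if (cnt[v] == 1) tb[2] = v;
        } else if (p1) {
            cat = 1; tb[0] = p1;
            int k = 1;
            for (int v = 14; v >= 2; --v) if (cnt[v] == 1) tb[k++] = v;
        } else {
            cat = 0;
            int k = 0;
            for (int v = 14; v >= 2; --v) if (cnt[v]) tb[k++] = v;
        }
    }
    int code = cat;
    for (int i = 0; i < 5; ++i) code = (code << 4) | tb[i];
    return code;
}

static inline int eval5_ids(const int ids[5]) {
    int r[5], s[5];
    for (int i = 0; i < 5; ++i) { r[i] = ids[i] / 4 + 2; s[i] = ids[i] % 4; }
    return eval5(r, s);
}

// high card of the best straight in a rank bitmask (bits 2..14), or 0;
// an ace also plays low (A-2-3-4-5)
static inline int straight_high_of(int m) {
    if (m & (1 << 14)) m |= (1 << 1);
    for (int hi = 14; hi >= 5; --hi) {
        int need = 0x1F << (hi - 4);
        if ((m & need) == need) return hi;
    }
    return 0;
}

// direct evaluation of the best five-card hand out of seven cards;
// equivalent to the subset maximum (see cpp_eval7_subsets), but O(1)
static inline int eval7_ids(const int ids[7]) {
    int cnt[15], suitc[4], suitmask[4], mask = 0;
    for (int v = 0; v < 15; ++v) cnt[v] = 0;
    for (int s = 0; s < 4; ++s) { suitc[s] = 0; suitmask[s] = 0; }
    for (int i = 0; i < 7; ++i) {
        int r = ids[i] / 4 + 2, s = ids[i] % 4;
        cnt[r]++;
        suitc[s]++;
        suitmask[s] |= 1 << r;
        mask |= 1 << r;
    }
    int fs = -1;
    for (int s = 0; s < 4; ++s) if (suitc[s] >= 5) fs = s;
    if (fs >= 0) {
        int sh = straight_high_of(suitmask[fs]);
        if (sh) return (8 << 20) | (sh << 16);
    }
    int quad = 0, trips[2] = {0, 0}, nt = 0, pairs[3] = {0, 0, 0}, np = 0;
    for (int v = 14; v >= 2; --v) {
        if (cnt[v] == 4) quad = v;
        else if (cnt[v] == 3) { if (nt < 2) trips[nt++] = v; }
        else if (cnt[v] == 2) { if (np < 3) pairs[np++] = v; }
    }
    if (quad) {
        int kick = 0;
        for (int v = 14; v >= 2 && !kick; --v)
            if (v != quad && cnt[v] > 0) kick = v;
        return (7 << 20) | (quad << 16) | (kick << 12);
    }
    if (nt >= 1 && (nt == 2 || np >= 1)) {
        int trip = trips[0];
        int pr = nt == 2 ? trips[1] : pairs[0];
        if (nt == 2 && np >= 1 && pairs[0] > pr) pr = pairs[0];
        return (6 << 20) | (trip << 16) | (pr << 12);
    }
    if (fs >= 0) {
        int code = 5 << 20, got = 0;
        for (int v = 14; v >= 2 && got < 5; --v) {
            if (suitmask[fs] & (1 << v)) {
                code |= v << (16 - 4 * got);
                ++got;
            }
        }
        return code;
    }
    int sh = straight_high_of(mask);
    if (sh) return (4 << 20) | (sh << 16);
    if (nt == 1) {
        int code = (3 << 20) | (trips[0] << 16), got = 0;
        for (int v = 14; v >= 2 && got < 2; --v) {
            if (v != trips[0] && cnt[v] > 0) {
                code |= v << (12 - 4 * got);
                ++got;
            }
        }
        return code;
    }
    if (np >= 2) {
        int kick = 0;
        for (int v = 14; v >= 2 && !kick; --v)
            if (v != pairs[0] && v != pairs[1] && cnt[v] > 0) kick = v;
        return (2 << 20) | (pairs[0] << 16) | (pairs[1] << 12) | (kick << 8);
    }
    if (np == 1) {
        int code = (1 << 20) | (pairs[0] << 16), got = 0;
        for (int v = 14; v >= 2 && got < 3; --v) {
            if (v != pairs[0] && cnt[v] > 0) {
                code |= v << (12 - 4 * got);
                ++got;
            }
        }
        return code;
    }
    int code = 0, got = 0;
    for (int v = 14; v >= 2 && got < 5; --v) {
        if (cnt[v] > 0) {
            code |= v << (16 - 4 * got);
            ++got;
        }
    }
    return code;
}

// best five of seven as the explicit max over all C(7,5) = 21 subsets;
// the reference route eval7_ids is checked against
static inline int eval7_subsets(const int ids[7]) {
    int best = -1;
    int r[5], s[5];
    for (int i = 0; i < 6; ++i) {
        for (int j = i + 1; j < 7; ++j) {
            int k = 0;
            for (int t = 0; t < 7; ++t) {
                if (t == i || t == j) continue;
                r[k] = ids[t] / 4 + 2;
                s[k] = ids[t] % 4;
                ++k;
            }
            int c = eval5(r, s);
            if (c > best) best = c;
        }
    }
    return best;
}

// [[Rcpp::export]]
int cpp_eval5(IntegerVector ids) {
    int a[5];
    for (int i = 0; i < 5; ++i) a[i] = ids[i];
    return eval5_ids(a);
}

// [[Rcpp::export]]
int cpp_eval7(IntegerVector ids) {
    int a[7];
    for (int i = 0; i < 7; ++i) a[i] = ids[i];
    return eval7_ids(a);
}

// [[Rcpp::export]]
int cpp_eval7_subsets(IntegerVector ids) {
    int a[7];
    for (int i = 0; i < 7; ++i) a[i] = ids[i];
    return eval7_subsets(a);
}

// [[Rcpp::export]]
IntegerVector cpp_eval5_batch(IntegerMatrix ids) {
    int n = ids.nrow();
    IntegerVector out(n);
    int a[5];
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < 5; ++j) a[j] = ids(i, j);
        out[i] = eval5_ids(a);
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_eval7_batch(IntegerMatrix ids) {
    int n = ids.nrow();
    IntegerVector out(n);
    int a[7];
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < 7; ++j) a[j] = ids(i, j);
        out[i] = eval7_ids(a);
    }
    return out;
}

static inline void tally(const int ph[2], const int oh[2], const int board[5],
                         double cnt[3]) {
    int a[7] = {ph[0], ph[1], board[0], board[1], board[2], board[3], board[4]};
    int b[7] = {oh[0], oh[1], board[0], board[1], board[2], board[3], board[4]};
    int ca = eval7_ids(a), cb = eval7_ids(b);
    if (ca > cb) cnt[0] += 1.0;
    else if (ca == cb) cnt[1] += 1.0;
    else cnt[2] += 1.0;
}

// recursive enumeration of the hidden board cards; at the leaf either use
// the known opponent hole or enumerate all opponent two-card combinations
static void enum_rec(const std::vector<int> &unseen, std::vector<char> &used,
                     int start, int need, int board[5], int pos,
                     const int ph[2], const int oh[2], bool opp_known,
                     double cnt[3]) {
    if (need == 0) {
        if (opp_known) {
            tally(ph, oh, board, cnt);
        } else {
            int n = (int)unseen.size();
            int o[2];
            for (int i = 0; i < n - 1; ++i) {
                if (used[i]) continue;
                for (int j = i + 1; j < n; ++j) {
                    if (used[j]) continue;
                    o[0] = unseen[i];
                    o[1] = unseen[j];
                    tally(ph, o, board, cnt);
                }
            }
        }
        return;
    }
    int n = (int)unseen.size();
    for (int i = start; i <= n - need; ++i) {
        board[pos] = unseen[i];
        used[i] = 1;
        enum_rec(unseen, used, i + 1, need - 1, board, pos + 1, ph, oh,
                 opp_known, cnt);
        used[i] = 0;
    }
}

static std::vector<int> unseen_cards(const int ph[2], const int oh[2],
                                     bool opp_known,
                                     const IntegerVector &board_revealed) {
    std::vector<char> seen(52, 0);
    seen[ph[0]] = seen[ph[1]] = 1;
    if (opp_known) { seen[oh[0]] = seen[oh[1]] = 1; }
    for (int i = 0; i < board_revealed.size(); ++i) seen[board_revealed[i]] = 1;
    std::vector<int> u;
    u.reserve(52);
    for (int c = 0; c < 52; ++c) if (!seen[c]) u.push_back(c);
    return u;
}

// Exact win/tie/lose counts over all equally likely completions of the
// hidden board cards (and the opponent's hole cards when opp_known = false).
// [[Rcpp::export]]
NumericVector cpp_outcome_counts(IntegerVector player, IntegerVector opp,
                                 IntegerVector board_revealed, bool opp_known) {
    int ph[2] = {player[0], player[1]};
    int oh[2] = {0, 0};
    if (opp.size() == 2) { oh[0] = opp[0]; oh[1] = opp[1]; }
    std::vector<int> unseen = unseen_cards(ph, oh, opp_known, board_revealed);
    std::vector<char> used(unseen.size(), 0);

    int board[5];
    int nrev = board_revealed.size();
    for (int i = 0; i < nrev; ++i) board[i] = board_revealed[i];
    int need = 5 - nrev;

    double cnt[3] = {0.0, 0.0, 0.0};
    enum_rec(unseen, used, 0, need, board, nrev, ph, oh, opp_known, cnt);
    return NumericVector::create(cnt[0], cnt[1], cnt[2]);
}

// Monte Carlo win/tie/lose counts; draws use R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_outcome_counts_mc(IntegerVector player, IntegerVector opp,
                                    IntegerVector board_revealed,
                                    bool opp_known, int n) {
    int ph[2] = {player[0], player[1]};
    int oh[2] = {0, 0};
    if (opp.size() == 2) { oh[0] = opp[0]; oh[1] = opp[1]; }
    std::vector<int> unseen = unseen_cards(ph, oh, opp_known, board_revealed);

    int board[5];
    int nrev = board_revealed.size();
    for (int i = 0; i < nrev; ++i) board[i] = board_revealed[i];
    int need = 5 - nrev;
    int k = need + (opp_known ? 0 : 2);

    int m = (int)unseen.size();
    std::vector<int> pool(unseen);
    double cnt[3] = {0.0, 0.0, 0.0};
    int o[2];
    for (int it = 0; it < n; ++it) {
        // partial Fisher-Yates: first k entries of pool become the draw
        for (int i = 0; i < k; ++i) {
            int j = i + (int)(unif_rand() * (m - i));
            if (j >= m) j = m - 1;
            int tmp = pool[i];
            pool[i] = pool[j];
            pool[j] = tmp;
        }
        for (int i = 0; i < need; ++i) board[nrev + i] = pool[i];
        if (opp_known) {
            tally(ph, oh, board, cnt);
        } else {
            o[0] = pool[need];
            o[1] = pool[need + 1];
            tally(ph, o, board, cnt);
        }
    }
    return NumericVector::create(cnt[0], cnt[1], cnt[2]);
}
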
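# Exclusive maximum-affinity cow pairs per pen, built stepwise: greedy
# top-partner assignment when exclusivity is not required; Irving's
# stable-roommates algorithm for exclusive stable pairs; maximum-weight
# matching as the fallback when no stable matching exists.  Zero-score
# pairs are excluded throughout.

#' Preference table from an affinity network
#'
#' Each cow's potential partners ordered by descending score, ties broken by
#' ascending cow id; zero-score partners are omitted.
#'
#' @param network an `affinity_network`.
#' @return named list of character vectors (class `preference_table`).
#' @export
build_preferences <- function(network) {
  w <- network$weights
  prefs <- lapply(network$cows, function(cw) {
    s <- w[cw, ]
    s <- s[names(s) != cw & s > 0]
    if (!length(s)) return(character())
    names(s)[order(-s, names(s), method = "radix")]
  })
  structure(stats::setNames(prefs, network$cows), class = "preference_table")
}

#' Greedy top-partner assignment
#'
#' Assigns every cow its top-scoring partner without an exclusivity
#' constraint, so assignments may be asymmetric (A's best is B while B's
#' best is C).  Cows whose scores are all zero stay unassigned.
#'
#' @param network an `affinity_network`.
#' @return `data.table` with `cow_id, partner, score, symmetric` (TRUE when
#'   the two cows pick each other).
#' @export
greedy_pairs <- function(network) {
  prefs <- build_preferences(network)
  top <- vapply(prefs, function(p) if (length(p)) p[1] else NA_character_, "")
  out <- data.table(cow_id = network$cows, partner = unname(top[network$cows]))
  out <- out[!is.na(partner)]
  out[, score := network$weights[cbind(cow_id, partner)]]
  out[, symmetric := top[partner] == cow_id]
  setorder(out, cow_id)
  out[]
}

rank_lookup <- function(prefs) {
  lapply(prefs, function(p) stats::setNames(seq_along(p), p))
}

# Blocking pair check over expressed preferences: (a, b) blocks a matching
# when each lists the other and each is unmatched or prefers the other to
# its assigned mate.
find_blocking_pairs <- function(prefs, mate) {
  rk <- rank_lookup(prefs)
  rank_of <- function(a, x) {
    r <- rk[[a]][x]
    if (is.na(r)) Inf else unname(r)
  }
  cur <- function(a) if (is.na(mate[a])) Inf else rank_of(a, mate[a])
  blocks <- list()
  for (a in names(prefs)) {
    for (b in prefs[[a]]) {
      if (b <= a || is.na(rk[[b]][a])) next
      if (rank_of(a, b) < cur(a) && rank_of(b, a) < cur(b))
        blocks[[length(blocks) + 1L]] <- c(a, b)
    }
  }
  blocks
}

#' Irving's stable-roommates matching
#'
#' Runs the two-phase stable-roommates algorithm on a (possibly incomplete)
#' preference table.  A matching is stable when no two cows not matched to
#' each other both prefer each other over their assigned mates; with
#' incomplete lists, stability is defined over expressed preferences only
#' and cows may remain unmatched.  When the instance admits no stable
#' matching the function returns `stable = FALSE` rather than raising, so
#' the stepwise procedure can fall back to maximum-weight matching.
#'
#' @param preferences a [build_preferences()] table, or a named list of
#'   partner vectors (mutual listing is enforced by intersection).
#' @return list with `stable` (logical), `matching` (named character vector,
#'   `NA` for unmatched cows) and `unmatched` (character vector).
#' @export
stable_roommates <- function(preferences) {
  agents <- names(preferences)
  n <- length(agents)
  prefs <- lapply(agents, function(a)
    preferences[[a]][vapply(preferences[[a]],
                            function(b) a %in% preferences[[b]], TRUE)])
  names(prefs) <- agents
  fail <- list(stable = FALSE,
               matching = stats::setNames(rep(NA_character_, n), agents),
               unmatched = agents)
  if (n == 0L)
    return(list(stable = TRUE, matching = stats::setNames(character(), NULL),
                unmatched = character()))

  rk <- rank_lookup(prefs)
  alive <- lapply(prefs, function(p) rep(TRUE, length(p)))  # pair not deleted

  del_pair <- function(a, b) {
    ia <- rk[[a]][b]; ib <- rk[[b]][a]
    if (!is.na(ia)) alive[[a]][ia] <<- FALSE
    if (!is.na(ib)) alive[[b]][ib] <<- FALSE
  }
  active <- function(a) prefs[[a]][alive[[a]]]

  # Phase 1: proposal round.  held[b] = proposer b currently holds.
  held <- stats::setNames(rep(NA_character_, n), agents)
  nxt <- stats::setNames(rep(1L, n), agents)
  stack <- agents
  while (length(stack)) {
    a <- stack[length(stack)]; stack <- stack[-length(stack)]
    repeat {
      if (nxt[a] > length(prefs[[a]])) break       # exhausted: a unmatched
      if (!alive[[a]][nxt[a]]) { nxt[a] <- nxt[a] + 1L; next }
      b <- prefs[[a]][nxt[a]]
      if (is.na(held[b])) { held[b] <- a; break }
      if (rk[[b]][a] < rk[[b]][held[b]]) {
        old <- held[b]; held[b] <- a
        del_pair(b, old)
        stack <- c(stack, old)
        break
      }
      del_pair(a, b)
      nxt[a] <- nxt[a] + 1L
    }
  }
  # Reduction: b deletes everyone it likes less than the proposer it holds.
  for (b in agents) {
    if (is.na(held[b])) next
    r <- rk[[b]][held[b]]
    worse <- prefs[[b]][alive[[b]] & seq_along(prefs[[b]]) > r]
    for (x in worse) del_pair(b, x)
  }

  # Phase 2: rotation elimination until all lists have length <= 1.
  repeat {
    lens <- vapply(agents, function(a) sum(alive[[a]]), 0L)
    cand <- agents[lens >= 2L]
    if (!length(cand)) break
    p <- cand[1L]
    p_seq <- character(0)
    q_seq <- character(0)
    pos <- integer(0)
    repeat {
      la <- active(p)
      if (length(la) < 2L) return(fail)
      q <- la[2L]
      lb <- active(q)
      if (!length(lb)) return(fail)
      hit <- match(p, p_seq)
      if (!is.na(hit)) { start <- hit; break }
      p_seq <- c(p_seq, p)
      q_seq <- c(q_seq, q)
      p <- lb[length(lb)]
    }
    # The rotation is (p_i, q_i) for i = start..end; eliminate it: each q_i
    # rejects everyone it likes less than p_i (dropping p_{i+1} in
    # particular).
    idx <- seq(start, length(p_seq))
    for (i in idx) {
      qi <- q_seq[i]
      pi <- p_seq[i]
      r <- rk[[qi]][pi]
      worse <- prefs[[qi]][alive[[qi]] & seq_along(prefs[[qi]]) > r]
      for (x in worse) del_pair(qi, x)
      if (!any(alive[[qi]])) return(fail)
      if (!any(alive[[pi]])) return(fail)
    }
  }

  matching <- stats::setNames(rep(NA_character_, n), agents)
  for (a in agents) {
    la <- active(a)
    if (length(la) == 1L) matching[a] <- la
  }
  # Consistency + stability self-check; any violation means no stable
  # matching is reported (triggering the caller's fallback).
  for (a in agents) {
    m <- matching[a]
    if (!is.na(m) && (is.na(matching[m]) || matching[m] != a)) return(fail)
  }
  if (length(find_blocking_pairs(prefs, matching))) return(fail)
  list(stable = TRUE, matching = matching,
       unmatched = agents[is.na(matching)])
}

#' Maximum-weight exclusive matching
#'
#' Finds a matching of the affinity network maximising the total score of
#' matched pairs (weighted blossom matching on the general graph).  Among
#' maximum-weight matchings, ties are broken toward the lexicographically
#' smallest pair set (by cow id) via an edge-fixing refinement.
#'
#' @param network an `affinity_network`.
#' @param lex_refine break optimum ties toward the lexicographically
#'   smallest pair set (requires extra matching solves; disable for speed).
#' @return `data.table` with `cow_a, cow_b, score`, `cow_a < cow_b`.
#' @export
max_weight_pairs <- function(network, lex_refine = TRUE) {
  W <- network$weights
  cows <- network$cows
  mate <- blossom_mates(W)
  total <- total_mate_weight(W, mate)
  if (lex_refine && any(mate > 0)) {
    # Greedy edge fixing in lexicographic pair order: fix an edge whenever
    # some maximum-weight matching contains it together with all edges fixed
    # so far; the fixed set ends up being the lexicographically smallest
    # maximum-weight matching.
    edges <- network_edges(network)   # already sorted cow_a, cow_b
    fixed <- integer(0)               # interleaved vertex indices
    fixed_w <- 0
    tol <- 1e-9 * max(1, total)
    for (r in seq_len(nrow(edges))) {
      if (fixed_w >= total - tol) break
      a <- match(edges$cow_a[r], cows)
      b <- match(edges$cow_b[r], cows)
      if (a %in% fixed || b %in% fixed) next
      drop <- c(fixed, a, b)
      Wr <- W[-drop, -drop, drop = FALSE]
      rest <- if (nrow(Wr) > 1) total_mate_weight(Wr, blossom_mates(Wr))
              else 0
      if (fixed_w + W[a, b] + rest >= total - tol) {
        fixed <- c(fixed, a, b)
        fixed_w <- fixed_w + W[a, b]
      }
    }
    mate <- rep(0L, length(cows))
    if (length(fixed)) {
      fa <- fixed[seq(1, length(fixed), by = 2)]
      fb <- fixed[seq(2, length(fixed), by = 2)]
      mate[fa] <- fb
      mate[fb] <- fa
    }
  }
  i <- which(mate > 0 & seq_along(mate) < mate)
  cp <- canonical_pairs(cows[i], cows[mate[i]])
  out <- data.table(cow_a = cp$cow_a, cow_b = cp$cow_b,
                    score = W[cbind(cp$cow_a, cp$cow_b)])
  setorder(out, cow_a)
  out[]
}

total_mate_weight <- function(W, mate) {
  i <- which(mate > 0 & seq_along(mate) < mate)
  sum(W[cbind(i, mate[i])])
}

#' Stepwise maximum-affinity pair matching
#'
#' The pair-generation procedure applied per pen: with
#' `mode = "non_exclusive"`, each cow simply gets its top-scoring partner
#' (greedy); with `mode = "exclusive"` (default), Irving's stable-roommates
#' algorithm is attempted first and, when no stable matching exists,
#' maximum-weight blossom matching is used instead.  Zero-score pairs are
#' excluded; each returned pair records the algorithm that produced it.
#'
#' Preferences derived from a symmetric score matrix with deterministic
#' tie-breaking always admit a stable matching (the globally heaviest edge
#' is mutually most-preferred, and induction on the remaining cows does the
#' rest), so with network-derived preferences the fallback never fires; it
#' exists for preference tables supplied from elsewhere.
#'
#' @param network an `affinity_network`.
#' @param mode `"exclusive"` or `"non_exclusive"`.
#' @param preferences optional `preference_table` overriding
#'   [build_preferences()] of the network.
#' @return `data.table` with `pen_id, cow_a, cow_b, score, algorithm`.  For
#'   the greedy mode only mutual (symmetric) assignments are emitted as
#'   pairs; the full assignment table is attached as attribute
#'   `"assignments"`.
#' @export
stepwise_match <- function(network, mode = c("exclusive", "non_exclusive"),
                           preferences = NULL) {
  mode <- match.arg(mode)
  empty <- data.table(pen_id = character(), cow_a = character(),
                      cow_b = character(), score = numeric(),
                      algorithm = character())
  if (mode == "non_exclusive") {
    g <- greedy_pairs(network)
    sym <- g[symmetric == TRUE & cow_id < partner]
    if (!nrow(sym)) return(empty)
    out <- data.table(pen_id = network$pen_id, cow_a = sym$cow_id,
                      cow_b = sym$partner, score = sym$score,
                      algorithm = "greedy")
    setattr(out, "assignments", g)
    return(out[])
  }
  sr <- stable_roommates(preferences %||% build_preferences(network))
  if (sr$stable) {
    m <- sr$matching
    a <- names(m)[!is.na(m) & names(m) < m]
    if (!length(a)) return(empty)
    out <- data.table(pen_id = network$pen_id, cow_a = a, cow_b = m[a],
                      score = network$weights[cbind(a, m[a])],
                      algorithm = "stable_roommates")
  } else {
    mw <- max_weight_pairs(network)
    if (!nrow(mw)) return(empty)
    out <- data.table(pen_id = network$pen_id, cow_a = mw$cow_a,
                      cow_b = mw$cow_b, score = mw$score,
                      algorithm = "max_weight")
  }
  setorder(out, cow_a)
  out[]
}

#' Match every pen of a scored herd
#'
#' @param networks named list of `affinity_network` objects (one per pen),
#'   as returned by [score_affinity()].
#' @param mode passed to [stepwise_match()].
#' @return combined `data.table` of matched pairs across pens.
#' @export
match_pairs <- function(networks, mode = c("exclusive", "non_exclusive")) {
  mode <- match.arg(mode)
  rbindlist(lapply(networks, stepwise_match, mode = mode))
}
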
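#' 2x2 co-occurrence table for a token pair
#'
#' Counts participants over their duplicate-collapsed token sets: `n11` mention
#' both tokens, `n10` only the first, `n01` only the second, `n00` neither.
#'
#' @param corpus A [coop_corpus].
#' @param token_i,token_j Distinct tokens present in the corpus lexicon.
#' @return A one-row tibble `n11, n10, n01, n00, N`.
#' @export
pair_table <- function(corpus, token_i, token_j) {
  stopifnot(inherits(corpus, "coop_corpus"))
  if (n_participants(corpus) == 0) {
    abort("Corpus has no participants.", class = "coop_degenerate_error")
  }
  if (identical(token_i, token_j)) {
    abort("Self-pairs are undefined.", class = "coop_lookup_error")
  }
  lex <- lexicon(corpus)
  missing <- setdiff(c(token_i, token_j), lex$token)
  if (length(missing)) {
    abort(paste0("Unknown token(s): ", paste(missing, collapse = ", ")),
          class = "coop_lookup_error")
  }
  sets <- corpus$mentions %>% distinct(.data$participant_id, .data$token)
  has_i <- unique(sets$participant_id[sets$token == token_i])
  has_j <- unique(sets$participant_id[sets$token == token_j])
  N <- n_participants(corpus)
  n11 <- length(intersect(has_i, has_j))
  tibble(
    n11 = n11,
    n10 = length(has_i) - n11,
    n01 = length(has_j) - n11,
    n00 = N - length(has_i) - length(has_j) + n11,
    N = N
  )
}

# vectorized G statistic core; callers guarantee nonzero margins
g_stat_core <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  r1 <- n11 + n10
  r0 <- n01 + n00
  c1 <- n11 + n01
  c0 <- n10 + n00
  term <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  g <- 2 * (term(n11, r1 * c1 / N) + term(n10, r1 * c0 / N) +
              term(n01, r0 * c1 / N) + term(n00, r0 * c0 / N))
  pmax(g, 0) # clamp numerical negatives at independence
}

check_pair_margins <- function(t) {
  r1 <- t$n11 + t$n10
  r0 <- t$n01 + t$n00
  c1 <- t$n11 + t$n01
  c0 <- t$n10 + t$n00
  if (any(c(r1, r0, c1, c0) == 0)) {
    abort(
      "G statistic undefined: a token is mentioned by nobody or by everybody.",
      class = "coop_degenerate_error"
    )
  }
}

#' Log-likelihood ratio (G) statistic of a 2x2 co-occurrence table
#'
#' `G = 2 * sum O * ln(O / E)` over the four cells, with `E` the independence
#' expectation from the margins and `0 * ln(0/E) = 0`; equivalently twice the
#' gap between the saturated and the independence multinomial log-likelihood.
#' Both margins must be nonzero.
#'
#' @param t A pair table as returned by [pair_table()] (any list with fields
#'   `n11, n10, n01, n00`).
#' @return Non-negative scalar G.
#' @export
loglikelihood_ratio <- function(t) {
  check_pair_margins(t)
  unname(g_stat_core(t$n11, t$n10, t$n01, t$n00))
}

#' Signed co-occurrence weight
#'
#' The G statistic signed by the direction of the deviation: positive
#' (attractive) when the pair co-occurs more often than expected under
#' independence, negative (repulsive) when less often, zero exactly at the
#' expectation.
#'
#' @inheritParams loglikelihood_ratio
#' @return Signed real weight.
#' @export
signed_weight <- function(t) {
  check_pair_margins(t)
  g <- g_stat_core(t$n11, t$n10, t$n01, t$n00)
  N <- t$n11 + t$n10 + t$n01 + t$n00
  e11 <- (t$n11 + t$n10) * (t$n11 + t$n01) / N
  unname(sign(t$n11 - e11) * g)
}

#' Build the signed co-occurrence network
#'
#' Every unordered pair of lexicon tokens is scored by [signed_weight()];
#' nonzero weights become edges (attractive or repulsive), tokens are nodes
#' carrying their participant frequency. Pairs involving a token mentioned by
#' every participant have an undefined statistic and are skipped with a
#' warning. Isolated nodes are kept.
#'
#' @param corpus A preprocessed [coop_corpus] with at least two tokens.
#' @return A `coop_network`: list with `nodes` (tibble `token`,
#'   `n_participants`), `edges` (tibble `from`, `to`, `weight`) and
#'   `n_participants` (total N).
#' @export
build_network <- function(corpus) {
  stopifnot(inherits(corpus, "coop_corpus"))
  lex <- lexicon(corpus)
  if (nrow(lex) < 2) {
    abort("Need at least 2 tokens to build a network.", class = "coop_degenerate_error")
  }
  sets <- corpus$mentions %>% distinct(.data$participant_id, .data$token)
  N <- n_participants(corpus)
  tokens <- lex$token
  inc <- table(factor(sets$participant_id), factor(sets$token, levels = tokens))
  inc <- matrix(as.numeric(inc > 0), nrow = nrow(inc), dimnames = dimnames(inc))
  both <- crossprod(inc) # n11 for every ordered pair
  counts <- diag(both)

  ut <- which(upper.tri(both), arr.ind = TRUE)
  n11 <- both[ut]
  ci <- counts[ut[, 1]]
  cj <- counts[ut[, 2]]
  n10 <- ci - n11
  n01 <- cj - n11
  n00 <- N - ci - cj + n11

  degenerate <- ci == N | cj == N | ci == 0 | cj == 0
  if (any(degenerate)) {
    warn(sprintf(
      "%d pair(s) skipped: token mentioned by all %d participants (G undefined).",
      sum(degenerate), N
    ))
  }
  e11 <- ci * cj / N
  w <- rep(NA_real_, length(n11))
  ok <- !degenerate
  w[ok] <- sign(n11[ok] - e11[ok]) *
    g_stat_core(n11[ok], n10[ok], n01[ok], n00[ok])

  keep <- ok & w != 0
  edges <- tibble(
    from = tokens[ut[keep, 1]],
    to = tokens[ut[keep, 2]],
    weight = w[keep]
  )
  structure(
    list(
      nodes = tibble(token = tokens, n_participants = as.integer(counts)),
      edges = edges,
      n_participants = N
    ),
    class = "coop_network"
  )
}

#' @export
print.coop_network <- function(x, ...) {
  cat("<coop_network>\n")
  cat("  nodes:", nrow(x$nodes), "\n")
  cat(sprintf(
    "  edges: %d (%d attractive, %d repulsive)\n",
    nrow(x$edges), sum(x$edges$weight > 0), sum(x$edges$weight < 0)
  ))
  tot <- network_totals(x)
  cat(sprintf("  total weight: v+ = %.3f, v- = %.3f\n", tot$v_pos, tot$v_neg))
  invisible(x)
}

#' Signed adjacency matrix of a network
#'
#' @param net A `coop_network`.
#' @return Dense symmetric matrix with zero diagonal, rows/columns ordered and
#'   named as `net$nodes$token`.
#' @export
as_adjacency <- function(net) {
  stopifnot(inherits(net, "coop_network"))
  tokens <- net$nodes$token
  n <- length(tokens)
  W <- matrix(0, n, n, dimnames = list(tokens, tokens))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, tokens)
    j <- match(net$edges$to, tokens)
    W[cbind(i, j)] <- net$edges$weight
    W[cbind(j, i)] <- net$edges$weight
  }
  W
}

#' Per-node positive and negative strengths
#'
#' @param net A `coop_network`.
#' @return Tibble `token`, `s_pos`, `s_neg` (both non-negative; `s_neg` is the
#'   summed magnitude of repulsive weights).
#' @export
network_strengths <- function(net) {
  W <- as_adjacency(net)
  tibble(
    token = net$nodes$token,
    s_pos = unname(rowSums(pmax(W, 0))),
    s_neg = unname(rowSums(pmax(-W, 0)))
  )
}

#' Total positive and negative weight
#'
#' Each undirected edge counted once.
#'
#' @param net A `coop_network`.
#' @return List with `v_pos` and `v_neg`.
#' @export
network_totals <- function(net) {
  stopifnot(inherits(net, "coop_network"))
  list(
    v_pos = sum(net$edges$weight[net$edges$weight > 0]),
    v_neg = sum(-net$edges$weight[net$edges$weight < 0])
  )
}

#' Chance-expected co-occurrence weight under the signed configuration model
#'
#' Within each sign layer the null model preserves node strengths:
#' `e_ij = s_i * s_j / (2 v)` with `s` the layer strengths and `v` the layer's
#' total (undirected) weight; zero when the layer is empty. Summed over all
#' ordered pairs (self-pairs included) the expectations reproduce `2 v`.
#'
#' @param net A `coop_network`.
#' @param token_i,token_j Tokens in the network (may coincide: self-pair
#'   expectations enter the null-model bookkeeping).
#' @param sign `"positive"` or `"negative"` layer.
#' @return Scalar expected weight.
#' @export
expected_weight <- function(net, token_i, token_j, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  s <- network_strengths(net)
  if (!all(c(token_i, token_j) %in% s$token)) {
    abort("Unknown token(s).", class = "coop_lookup_error")
  }
  tot <- network_totals(net)
  v <- if (sign == "positive") tot$v_pos else tot$v_neg
  if (v == 0) {
    return(0)
  }
  col <- if (sign == "positive") "s_pos" else "s_neg"
  si <- s[[col]][s$token == token_i]
  sj <- s[[col]][s$token == token_j]
  si * sj / (2 * v)
}

# construct a coop_network directly from a signed adjacency matrix (used by
# tests and the consensus machinery)
network_from_matrix <- function(W, tokens = NULL, n_participants = NA_integer_) {
  n <- nrow(W)
  tokens <- tokens %||% rownames(W) %||% paste0("v", seq_len(n))
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  structure(
    list(
      nodes = tibble(token = tokens, n_participants = n_participants),
      edges = tibble(
        from = tokens[ut[, 1]],
        to = tokens[ut[, 2]],
        weight = W[ut]
      ),
      n_participants = n_participants
    ),
    class = "coop_network"
  )
}
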
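# fixtures are built in code; nothing is read from disk

# wide response table: `assoc` is a list of character(5) token vectors, one
# per participant; labels are assigned deterministically from the PANAS list
make_responses <- function(assoc, category = "alcohol", intensity = 4,
                           ids = NULL, labels = panas_labels()) {
  n <- length(assoc)
  ids <- ids %||% sprintf("p%02d", seq_len(n))
  category <- rep_len(category, n)
  intensity <- rep_len(intensity, n)
  out <- tibble::tibble(participant_id = ids)
  for (k in 1:5) {
    out[[paste0("assoc_", k)]] <- vapply(assoc, `[[`, "", k)
    out[[paste0("emo_", k, "a")]] <- labels[((k - 1) * 2) %% 20 + 1]
    out[[paste0("emo_", k, "b")]] <- labels[((k - 1) * 2 + 1) %% 20 + 1]
  }
  out$category <- category
  out$intensity <- intensity
  out
}

make_corpus <- function(assoc, ...) {
  as_corpus(make_responses(assoc, ...), pipeline_config())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random symmetric weight matrix; sign_frac = fraction of negative edges
random_signed_matrix <- function(n, density = 0.3, sign_frac = 0, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    m <- max(3L, rbinom(1, length(ut), density))
    pick <- sample(ut, m)
    w <- runif(m, 0.1, 2)
    neg <- runif(m) < sign_frac
    A[pick] <- ifelse(neg, -w, w)
    A + t(A)
  })
}

# independent double-loop Newman-Girvan modularity oracle (positive weights)
newman_oracle <- function(A, memb) {
  k <- rowSums(A)
  two_m <- sum(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + A[i, j] - k[i] * k[j] / two_m
      }
    }
  }
  q / two_m
}

# independence / saturated multinomial log-likelihood oracle for the G test
g_oracle <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  p1 <- (n11 + n10) / N
  q1 <- (n11 + n01) / N
  tm <- function(o, pr) ifelse(o == 0, 0, o * log(pr))
  l_sat <- tm(n11, n11 / N) + tm(n10, n10 / N) + tm(n01, n01 / N) + tm(n00, n00 / N)
  l_ind <- tm(n11, p1 * q1) + tm(n10, p1 * (1 - q1)) +
    tm(n01, (1 - p1) * q1) + tm(n00, (1 - p1) * (1 - q1))
  2 * (l_sat - l_ind)
}

# label marginal induced by drawing 2 distinct labels with weights p
induced_label_marginal <- function(p) {
  q <- p * (1 + vapply(seq_along(p), function(l) sum(p[-l] / (1 - p[-l])), 0))
  100 * q / sum(q)
}
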
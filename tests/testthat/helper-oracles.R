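# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (per-character loops, double sums) and share no code
# with the implementation paths they check.

# strip lowercase insertions / '.' with a character loop
oracle_match_chars <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ch[!(ch %in% letters) & ch != "."]
}

oracle_match_matrix <- function(m) {
  ab <- alphabet22()
  out <- matrix(NA_integer_, m$N, m$L)
  for (n in seq_len(m$N)) {
    ch <- oracle_match_chars(m$seq[n])
    for (i in seq_along(ch)) {
      out[n, i] <- if (ch[i] %in% names(ab)) ab[[ch[i]]] else 20L
    }
  }
  out
}

oracle_identity <- function(m, a, b) {
  x <- oracle_match_chars(m$seq[a])
  y <- oracle_match_chars(m$seq[b])
  num <- 0L; den <- 0L
  for (i in seq_along(x)) {
    if (x[i] != "-" && y[i] != "-") {
      den <- den + 1L
      if (x[i] == y[i]) num <- num + 1L
    }
  }
  if (den == 0L) 0 else num / den
}

oracle_neff <- function(m, thr = 0.8) {
  total <- 0
  for (n in seq_len(m$N)) {
    red <- 0L
    for (k in seq_len(m$N)) {
      if (k != n && oracle_identity(m, n, k) >= thr) red <- red + 1L
    }
    total <- total + 1 / (1 + red)
  }
  total / sqrt(m$L)
}

oracle_coverage <- function(m) {
  covs <- numeric(0)
  for (n in 2:m$N) {
    ch <- oracle_match_chars(m$seq[n])
    covs <- c(covs, sum(ch != "-") / m$L)
  }
  mean(covs)
}

oracle_depth <- function(m) {
  d <- integer(m$L)
  for (n in seq_len(m$N)[-1]) {
    ch <- oracle_match_chars(m$seq[n])
    for (i in seq_len(m$L)) if (ch[i] != "-") d[i] <- d[i] + 1L
  }
  d
}

# counting-loop frequencies and direct double-sum mutual information
oracle_frequencies <- function(mat) {
  N <- nrow(mat); L <- ncol(mat); Q <- 22
  f1 <- matrix(0, L, Q)
  for (n in seq_len(N)) {
    for (i in seq_len(L)) f1[i, mat[n, i] + 1] <- f1[i, mat[n, i] + 1] + 1
  }
  f1 <- f1 / N
  f2 <- array(0, dim = c(L, L, Q, Q))
  for (n in seq_len(N)) {
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        k <- mat[n, i] + 1; l <- mat[n, j] + 1
        f2[i, j, k, l] <- f2[i, j, k, l] + 1
      }
    }
  }
  list(f1 = f1, f2 = f2 / N)
}

oracle_mi_summed <- function(mat) {
  fr <- oracle_frequencies(mat)
  L <- ncol(mat); Q <- 22
  out <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      s <- 0
      for (k in seq_len(Q)) {
        for (l in seq_len(Q)) {
          fij <- fr$f2[i, j, k, l]
          if (fij > 0) s <- s + fij * log(fij / (fr$f1[i, k] * fr$f1[j, l]))
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# sort-all-pairs contact selection
oracle_top_contacts <- function(scores, count, min_sep) {
  L <- nrow(scores)
  rows <- list()
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j > i && j - i >= min_sep) {
        rows[[length(rows) + 1]] <- data.frame(i = i, j = j,
                                               score = scores[i, j])
      }
    }
  }
  d <- do.call(rbind, rows)
  d <- d[order(-d$score, d$i, d$j), , drop = FALSE]
  head(d, count)
}
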
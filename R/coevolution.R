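# MSA-derived coevolution features: column frequencies, mutual information,
# the pseudolikelihood-maximized 22-state Potts model (fields h and couplings
# P with L2 regularization), Frobenius/APC contact scores, distance-bin
# midpoints and the top-5L long-range mean absolute distance error.

Q_STATES <- 22L

#' Empirical single- and pair-column frequencies
#'
#' Plug-in frequencies over the 22-state alphabet: `f1[i, k]` is the
#' frequency of state k at column i, and `f2[i, j, k, l]` the co-occurrence
#' frequency of states (k, l) at columns (i, j). Every `f1` row and every
#' `f2` block sums to 1. An optional pseudocount is added to every cell
#' before normalization.
#'
#' @param m integer state matrix (N x L, entries 0..21) from
#'   [to_match_matrix()], or an [msa].
#' @param pseudocount nonnegative pseudocount added per cell (default 0).
#' @return List with `f1` (L x Q) and `f2` (L x L x Q x Q).
#' @export
column_frequencies <- function(m, pseudocount = 0) {
  if (is_msa(m)) m <- to_match_matrix(m)
  stopifnot(is.matrix(m), pseudocount >= 0)
  N <- nrow(m); L <- ncol(m); Q <- Q_STATES
  if (N == 0L) usage_error("cannot compute frequencies of an empty MSA")
  if (any(m < 0L | m > Q - 1L)) usage_error("states must lie in 0..21")
  f1 <- matrix(0, L, Q)
  for (i in seq_len(L)) {
    cnt <- tabulate(m[, i] + 1L, nbins = Q) + pseudocount
    f1[i, ] <- cnt / sum(cnt)
  }
  f2 <- array(0, dim = c(L, L, Q, Q))
  for (i in seq_len(L)) {
    for (j in i:L) {
      cnt <- tabulate(m[, i] * Q + m[, j] + 1L, nbins = Q * Q) + pseudocount
      blk <- matrix(cnt / sum(cnt), Q, Q, byrow = TRUE)
      f2[i, j, , ] <- blk
      if (j != i) f2[j, i, , ] <- t(blk)
    }
  }
  list(f1 = f1, f2 = f2)
}

#' Mutual information between alignment columns
#'
#' For columns i and j and states (k, l):
#' \deqn{M_{i,j}(k,l) = f_{i,j}(k,l)\,\ln\frac{f_{i,j}(k,l)}{f_i(k) f_j(l)}}
#' with the convention \eqn{0 \ln 0 = 0} and the natural logarithm (nats).
#' The summed L x L matrix \eqn{\sum_{k,l} M_{i,j}(k,l)} is symmetric and
#' nonnegative; its diagonal is the column self-information, flagged as such.
#' By default the gap and unknown states participate as ordinary states; set
#' `exclude_gaps = TRUE` to drop the gap state from the sums.
#'
#' @param x an [msa] or an integer state matrix.
#' @param pseudocount passed to [column_frequencies()].
#' @param exclude_gaps drop gap-state terms from the summation (default
#'   FALSE).
#' @param keep_tensor retain the full L x L x Q x Q per-pair tensor; defaults
#'   to `TRUE` for L <= 50 (the tensor grows as L^2 Q^2).
#' @return An object of class `mi_result` with `summed` (L x L) and,
#'   optionally, `tensor`.
#' @export
mutual_information <- function(x, pseudocount = 0, exclude_gaps = FALSE,
                               keep_tensor = NULL) {
  m <- if (is_msa(x)) to_match_matrix(x) else x
  L <- ncol(m)
  if (is.null(keep_tensor)) keep_tensor <- L <= 50L
  fr <- column_frequencies(m, pseudocount)
  Q <- Q_STATES
  keep <- if (exclude_gaps) seq_len(Q - 1L) else seq_len(Q)
  summed <- matrix(0, L, L)
  tensor <- if (keep_tensor) array(0, dim = c(L, L, Q, Q)) else NULL
  for (i in seq_len(L)) {
    for (j in i:L) {
      fij <- fr$f2[i, j, , ]
      denom <- outer(fr$f1[i, ], fr$f1[j, ])
      mm <- matrix(0, Q, Q)
      pos <- fij > 0 & denom > 0
      mm[pos] <- fij[pos] * log(fij[pos] / denom[pos])
      if (keep_tensor) {
        tensor[i, j, , ] <- mm
        if (j != i) tensor[j, i, , ] <- t(mm)
      }
      s <- sum(mm[keep, keep])
      summed[i, j] <- s
      summed[j, i] <- s
    }
  }
  structure(list(summed = summed, tensor = tensor, Q = Q,
                 exclude_gaps = exclude_gaps),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  L <- ncol(x$summed)
  off <- x$summed[upper.tri(x$summed)]
  cat(sprintf(
    "mutual information over %d columns (nats)%s\n  off-diagonal: min %.4f, max %.4f\n  (diagonal entries are column self-information)\n",
    L, if (x$exclude_gaps) ", gap state excluded" else "",
    min(off), max(off)))
  invisible(x)
}

#' Construct a Potts model container
#'
#' Fields `h` (L x Q) and couplings `P` (L x L x Q x Q, zero diagonal
#' blocks), with the default regularization constants `lambda_single = 1`
#' and `lambda_pair = 0.2 * (L - 1)`.
#'
#' @param h L x Q field matrix.
#' @param P L x L x Q x Q coupling array.
#' @param lambda_single,lambda_pair L2 regularization coefficients.
#' @return An object of class `potts_model`.
#' @export
potts_model <- function(h, P, lambda_single = 1,
                        lambda_pair = 0.2 * (nrow(h) - 1)) {
  stopifnot(is.matrix(h), length(dim(P)) == 4L,
            ncol(h) == Q_STATES, dim(P)[3] == Q_STATES,
            dim(P)[1] == nrow(h), dim(P)[2] == nrow(h))
  structure(list(h = h, P = P, Q = Q_STATES,
                 lambda_single = lambda_single, lambda_pair = lambda_pair,
                 converged = NA, niter = NA_integer_, loss = NA_real_),
            class = "potts_model")
}

zero_potts_model <- function(L, lambda_single = 1,
                             lambda_pair = 0.2 * (L - 1)) {
  potts_model(matrix(0, L, Q_STATES),
              array(0, dim = c(L, L, Q_STATES, Q_STATES)),
              lambda_single, lambda_pair)
}

#' @export
print.potts_model <- function(x, ...) {
  L <- nrow(x$h)
  cat(sprintf(
    "Potts model: L = %d, Q = %d, lambda_single = %g, lambda_pair = %g\n",
    L, x$Q, x$lambda_single, x$lambda_pair))
  if (!is.na(x$loss)) {
    cat(sprintf("  fitted: loss = %.4f, converged = %s\n", x$loss,
                x$converged))
  }
  invisible(x)
}

# couplings array (L,L,Q,Q) <-> block matrix W (LQ x LQ); block (i,j) = P_ij
couplings_to_block <- function(P) {
  d <- dim(P)
  matrix(aperm(P, c(3, 1, 4, 2)), d[1] * d[3], d[2] * d[4])
}
block_to_couplings <- function(W, L, Q) {
  aperm(array(W, dim = c(Q, L, Q, L)), c(2, 4, 1, 3))
}
zero_diag_blocks <- function(W, L, Q) {
  for (i in seq_len(L)) {
    idx <- ((i - 1L) * Q + 1L):(i * Q)
    W[idx, idx] <- 0
  }
  W
}

# core negative log-pseudolikelihood + L2 penalties and its exact gradient,
# parameterized by (h vector LQ, block matrix W LQ x LQ with zero diagonal
# blocks). Returns list(loss, gh, gW).
plm_objective <- function(hvec, W, m, lambda_single, lambda_pair) {
  N <- nrow(m); L <- ncol(m); Q <- Q_STATES
  idx <- m + 1L                       # states 1..Q
  colpos <- rep((seq_len(L) - 1L) * Q, each = N) + as.vector(idx)
  X <- matrix(0, N, L * Q)
  X[cbind(rep(seq_len(N), L), colpos)] <- 1
  tX <- t(X)
  G <- W %*% tX + hvec                # LQ x N (hvec recycled down columns)
  dim(G) <- c(Q, L * N)               # columns indexed by (i, n), i fastest
  mx <- G[1, ]
  for (q in 2:Q) mx <- pmax(mx, G[q, ])
  E <- exp(G - rep(mx, each = Q))
  Z <- colSums(E)
  logZ <- log(Z) + mx
  true_rows <- as.vector(t(idx))      # (i, n) order matching columns of G
  gt <- G[cbind(true_rows, seq_len(L * N))]
  nll <- sum(logZ - gt)
  loss <- nll + lambda_single * sum(hvec^2) + lambda_pair * sum(W^2)
  PI <- E / rep(Z, each = Q)
  dim(PI) <- c(L * Q, N)
  D <- PI - tX
  gW <- D %*% X
  gW <- zero_diag_blocks(gW, L, Q) + 2 * lambda_pair * W
  gh <- rowSums(D) + 2 * lambda_single * hvec
  list(loss = loss, gh = gh, gW = gW)
}

#' Pseudolikelihood loss and gradient of a Potts model
#'
#' Evaluates the negative log-pseudolikelihood of the 22-state Potts model
#' over all sites and sequences,
#' \deqn{\mathcal{L} = -\sum_{i=1}^{L}\sum_{n=1}^{N} \ln
#'   \frac{\exp(h_i(\sigma^i_n) + \sum_{j \ne i} P_{ij}(\sigma^i_n, \sigma^j_n))}
#'        {\sum_q \exp(h_i(q) + \sum_{j \ne i} P_{ij}(q, \sigma^j_n))}
#'   + \lambda_{single} \lVert h \rVert_2^2
#'   + \lambda_{pair} \sum_{i \ne j} \lVert P_{ij} \rVert_2^2}
#' together with its exact gradient (matching the model shapes). For the
#' zero model the loss is `N * L * log(22)` plus zero regularization.
#'
#' @param model a `potts_model`.
#' @param m integer state matrix (N x L, entries 0..21) or an [msa].
#' @return List with `loss` (scalar), `grad_h` (L x Q) and `grad_P`
#'   (L x L x Q x Q, zero diagonal blocks).
#' @export
plm_loss_grad <- function(model, m) {
  stopifnot(inherits(model, "potts_model"))
  if (is_msa(m)) m <- to_match_matrix(m)
  L <- nrow(model$h); Q <- model$Q
  stopifnot(ncol(m) == L)
  W <- zero_diag_blocks(couplings_to_block(model$P), L, Q)
  obj <- plm_objective(as.vector(t(model$h)), W, m,
                       model$lambda_single, model$lambda_pair)
  list(loss = obj$loss,
       grad_h = matrix(obj$gh, L, Q, byrow = TRUE),
       grad_P = block_to_couplings(obj$gW, L, Q))
}

#' Fit a Potts model by pseudolikelihood maximization
#'
#' Minimizes the regularized negative log-pseudolikelihood with L-BFGS-B
#' starting from the zero model (deterministic). The pseudolikelihood
#' objective is convex, so the reached optimum is unique up to the
#' optimizer's tolerance. The asymmetric couplings are symmetrized after
#' optimization as \eqn{(P_{ij} + P_{ji}^T)/2}.
#'
#' @param x an [msa] or integer state matrix.
#' @param lambda_single L2 coefficient on the fields (default 1).
#' @param lambda_pair L2 coefficient on the couplings (default
#'   `0.2 * (L - 1)`).
#' @param maxit iteration cap for L-BFGS-B (default 100).
#' @param pgtol projected-gradient tolerance (default 1e-4).
#' @return A fitted `potts_model` with `converged`, `niter` and `loss`
#'   filled in (`converged = FALSE` when the iteration budget was exhausted;
#'   the model reached so far is still returned).
#' @export
plm_fit <- function(x, lambda_single = 1, lambda_pair = NULL, maxit = 100,
                    pgtol = 1e-4) {
  m <- if (is_msa(x)) to_match_matrix(x) else x
  N <- nrow(m); L <- ncol(m); Q <- Q_STATES
  if (is.null(lambda_pair)) lambda_pair <- 0.2 * (L - 1)
  nh <- L * Q
  nW <- (L * Q)^2
  # cache: optim asks for fn and gr at the same parameters consecutively
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$obj)
    W <- zero_diag_blocks(matrix(par[(nh + 1L):(nh + nW)], L * Q, L * Q),
                          L, Q)
    obj <- plm_objective(par[seq_len(nh)], W, m, lambda_single, lambda_pair)
    cache$par <- par
    cache$obj <- obj
    obj
  }
  fn <- function(par) evaluate(par)$loss
  gr <- function(par) {
    obj <- evaluate(par)
    c(obj$gh, as.vector(obj$gW))
  }
  res <- optim(rep(0, nh + nW), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = pgtol))
  W <- zero_diag_blocks(matrix(res$par[(nh + 1L):(nh + nW)], L * Q, L * Q),
                        L, Q)
  P <- block_to_couplings(W, L, Q)
  # post-hoc symmetrization of the asymmetric pseudolikelihood couplings
  Psym <- P
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      Psym[i, j, , ] <- (P[i, j, , ] + t(P[j, i, , ])) / 2
    }
  }
  model <- potts_model(matrix(res$par[seq_len(nh)], L, Q, byrow = TRUE),
                       Psym, lambda_single, lambda_pair)
  model$converged <- res$convergence == 0L
  model$niter <- res$counts[["function"]]
  model$loss <- res$value
  model
}

#' Average product correction of a score matrix
#'
#' Subtracts the background term `rowmean_i * rowmean_j / mean` from each
#' entry. Means are taken over the full matrix (diagonal included), which
#' makes the correction exact for rank-one matrices.
#'
#' @param s symmetric numeric matrix.
#' @return The corrected matrix.
#' @export
apc_correct <- function(s) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  mu <- mean(s)
  if (mu == 0) return(s)
  s - outer(rowMeans(s), colMeans(s)) / mu
}

#' Contact scores from fitted Potts couplings
#'
#' The score of a residue pair (i, j) is the Frobenius norm of its coupling
#' block over the 21 non-gap states, optionally followed by the average
#' product correction. The result is symmetric with a zero diagonal.
#'
#' @param model a fitted `potts_model`.
#' @param apc apply the average product correction (default TRUE).
#' @param exclude_gap restrict the norm to the 21 non-gap states (default
#'   TRUE).
#' @return L x L numeric score matrix.
#' @export
coupling_scores <- function(model, apc = TRUE, exclude_gap = TRUE) {
  stopifnot(inherits(model, "potts_model"))
  L <- nrow(model$h); Q <- model$Q
  keep <- if (exclude_gap) seq_len(Q - 1L) else seq_len(Q)
  s <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      s[i, j] <- sqrt(sum(model$P[i, j, keep, keep]^2))
    }
  }
  s <- (s + t(s)) / 2
  if (apc) {
    s <- apc_correct(s)
    diag(s) <- 0
  }
  s
}

#' Top-scoring residue pairs at a minimum sequence separation
#'
#' Returns the `count` highest-scoring pairs (i < j) with
#' `|i - j| >= min_separation`, in descending score order with a
#' deterministic (i, j) tie-break. Fewer eligible pairs than `count` returns
#' all of them.
#'
#' @param scores symmetric L x L score matrix.
#' @param count number of pairs requested.
#' @param min_separation minimum sequence separation (default 24, the
#'   long-range convention).
#' @return Data frame with columns `i`, `j` (1-based) and `score`.
#' @export
top_contacts <- function(scores, count, min_separation = 24) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores), count >= 0)
  L <- nrow(scores)
  pairs <- which(upper.tri(scores), arr.ind = TRUE)
  sep_ok <- (pairs[, 2] - pairs[, 1]) >= min_separation
  pairs <- pairs[sep_ok, , drop = FALSE]
  sc <- scores[pairs]
  ord <- order(-sc, pairs[, 1], pairs[, 2])
  take <- head(ord, count)
  data.frame(i = pairs[take, 1], j = pairs[take, 2], score = sc[take],
             row.names = NULL)
}

#' Default distance-bin scheme
#'
#' 36 equal-width bins of 0.5 Angstrom spanning 2 to 20 Angstrom, plus an
#' open final bin starting at 20 whose nominal midpoint is its lower edge
#' plus half the previous bin width.
#'
#' @return Data frame with columns `lower` and `upper` (Angstrom; the final
#'   `upper` is `Inf`).
#' @export
default_bin_scheme <- function() {
  lower <- seq(2, 19.5, by = 0.5)
  data.frame(lower = c(lower, 20), upper = c(lower + 0.5, Inf))
}

#' Distance estimate from bin probabilities
#'
#' The predicted distance is the midpoint of the highest-probability bin
#' (first-argmax tie-break). For an open final bin the midpoint is its lower
#' edge plus half the previous bin's width.
#'
#' @param bin_probs numeric vector of bin probabilities (should sum to ~1).
#' @param bin_scheme data frame with `lower` and `upper` columns; defaults to
#'   [default_bin_scheme()].
#' @return Distance in Angstrom.
#' @export
bin_midpoint_estimate <- function(bin_probs, bin_scheme = default_bin_scheme()) {
  stopifnot(length(bin_probs) == nrow(bin_scheme))
  if (abs(sum(bin_probs) - 1) > 0.01) {
    warning("bin probabilities do not sum to 1; using them as given")
  }
  k <- which.max(bin_probs)   # first argmax
  lo <- bin_scheme$lower[k]
  up <- bin_scheme$upper[k]
  if (is.finite(up)) return((lo + up) / 2)
  prev_width <- if (k > 1L) {
    bin_scheme$upper[k - 1L] - bin_scheme$lower[k - 1L]
  } else 1
  lo + prev_width / 2
}

#' Construct a residue-pair distance set
#'
#' @param i,j residue indices (1-based; pairs are normalized to i < j).
#' @param value distances in Angstrom (> 0).
#' @param kind `"predicted"` or `"experimental"`.
#' @return Data frame of class `distance_set` with columns `i`, `j`,
#'   `value`.
#' @export
distance_set <- function(i, j, value, kind = c("predicted", "experimental")) {
  kind <- match.arg(kind)
  stopifnot(length(i) == length(j), length(i) == length(value))
  if (any(value <= 0)) usage_error("distances must be positive")
  if (any(i == j)) usage_error("self-pairs are not allowed in a distance set")
  ii <- pmin(i, j); jj <- pmax(i, j)
  structure(data.frame(i = as.integer(ii), j = as.integer(jj),
                       value = as.numeric(value)),
            kind = kind, class = c("distance_set", "data.frame"))
}

#' Mean absolute error of the top 5L long-range predicted distances
#'
#' Selects the `multiplier * L` long-range (`|i - j| >= min_separation`)
#' predicted pairs by the caller-supplied confidence ranking and averages
#' `|d_pred - d_exp|` over them. Pairs without an experimental distance are
#' excluded and the divisor reduced accordingly.
#'
#' @param pred a `distance_set` of predicted distances.
#' @param exp_set a `distance_set` of experimental distances on the same
#'   residue numbering.
#' @param L protein length in residues.
#' @param multiplier pairs selected per residue (default 5, i.e. top 5L).
#' @param min_separation long-range cutoff (default 24).
#' @param confidence optional numeric vector (one per `pred` row); pairs are
#'   ranked by it, descending. Defaults to the order in which the predictor
#'   supplied the pairs.
#' @return The MAE in Angstrom.
#' @export
mae_top_long_range <- function(pred, exp_set, L, multiplier = 5,
                               min_separation = 24, confidence = NULL) {
  stopifnot(inherits(pred, "distance_set"), inherits(exp_set, "distance_set"),
            L >= 1)
  if (is.null(confidence)) confidence <- rev(seq_len(nrow(pred)))
  stopifnot(length(confidence) == nrow(pred))
  lr <- (pred$j - pred$i) >= min_separation
  p <- pred[lr, , drop = FALSE]
  conf <- confidence[lr]
  if (!nrow(p)) undefined_error("no eligible long-range predicted pairs")
  ord <- order(-conf, p$i, p$j)
  p <- p[head(ord, ceiling(multiplier * L)), , drop = FALSE]
  key <- paste(p$i, p$j)
  ekey <- paste(exp_set$i, exp_set$j)
  hit <- match(key, ekey)
  ok <- !is.na(hit)
  if (!any(ok)) undefined_error("no selected pair has an experimental distance")
  mean(abs(p$value[ok] - exp_set$value[hit[ok]]))
}
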
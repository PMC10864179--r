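test_that("column frequencies are normalized and match the counting oracle", {
  # single-row MSA: one-hot frequencies
  one <- to_match_matrix(msa("q", "ACD"))
  fr <- column_frequencies(one)
  expect_equal(fr$f1[1, 1], 1)          # A at column 1
  expect_equal(rowSums(fr$f1), rep(1, 3))
  # 50/50 column
  half <- to_match_matrix(msa(c("q", "a", "b", "c"), c("A", "A", "C", "C")))
  fr2 <- column_frequencies(half)
  expect_equal(fr2$f1[1, c(1, 2)], c(0.5, 0.5))
  # random fixture vs the counting-loop oracle
  m <- to_match_matrix(make_msa(L = 6, N = 8,
                                identity_levels = c(0.5, 2 / 3), seed = 3))
  fr3 <- column_frequencies(m)
  orc <- oracle_frequencies(m)
  expect_equal(fr3$f1, orc$f1)
  expect_equal(fr3$f2, orc$f2)
  # every f2 block sums to 1
  expect_equal(apply(fr3$f2, c(1, 2), sum), matrix(1, 6, 6))
  expect_error(column_frequencies(matrix(integer(), 0, 3)), "empty")
})

test_that("mutual information matches closed forms and the double-sum oracle", {
  # two perfectly covarying 50/50 binary columns -> ln 2
  cov2 <- msa(c("q", "a", "b", "c"), c("AC", "AC", "GT", "GT"))
  mi <- mutual_information(cov2)
  expect_equal(mi$summed[1, 2], log(2))
  # a constant column has zero MI with every other column
  const <- msa(c("q", "a", "b", "c"), c("AA", "CA", "GA", "TA"))
  expect_equal(mutual_information(const)$summed[1, 2], 0)
  # fixture vs oracle; symmetry and nonnegativity
  fx <- make_msa(L = 8, N = 10, identity_levels = c(0.5, 0.75), seed = 9)
  r <- mutual_information(fx)
  expect_equal(r$summed, oracle_mi_summed(to_match_matrix(fx)))
  expect_equal(r$summed, t(r$summed))
  expect_true(all(r$summed >= -1e-12))
  # the per-pair tensor sums to the summed matrix
  expect_equal(apply(r$tensor, c(1, 2), sum), r$summed)
})

test_that("the PLM loss matches its zero-model closed form and penalty behavior", {
  fx <- make_msa(L = 5, N = 4, identity_levels = 0.6, seed = 1)
  m <- to_match_matrix(fx)
  zero <- msaforge:::zero_potts_model(5)
  lg <- plm_loss_grad(zero, m)
  expect_equal(lg$loss, 4 * 5 * log(22))
  # adding L2 terms strictly increases the loss of any nonzero model
  nz <- msaforge:::zero_potts_model(5)
  nz$h[2, 3] <- 0.5
  nz$P[1, 4, 2, 2] <- 0.3; nz$P[4, 1, 2, 2] <- 0.3
  with_pen <- plm_loss_grad(nz, m)$loss
  nopen <- potts_model(nz$h, nz$P, lambda_single = 0, lambda_pair = 0)
  expect_gt(with_pen, plm_loss_grad(nopen, m)$loss)
})

test_that("the PLM gradient matches central finite differences", {
  L <- 3; Q <- 22
  m <- with_seed(11, matrix(sample(0:21, 4 * L, replace = TRUE), 4, L))
  model <- with_seed(12, {
    h <- matrix(rnorm(L * Q, sd = 0.3), L, Q)
    P <- array(rnorm(L * L * Q * Q, sd = 0.2), dim = c(L, L, Q, Q))
    for (i in seq_len(L)) P[i, i, , ] <- 0
    potts_model(h, P)
  })
  lg <- plm_loss_grad(model, m)
  loss_at <- function(h, P) {
    plm_loss_grad(potts_model(h, P, model$lambda_single, model$lambda_pair),
                  m)$loss
  }
  eps <- 1e-5
  coords <- with_seed(13, data.frame(
    i = sample(L, 30, replace = TRUE),
    j = sample(L, 30, replace = TRUE),
    q1 = sample(Q, 30, replace = TRUE),
    q2 = sample(Q, 30, replace = TRUE)))
  for (t in seq_len(nrow(coords))) {
    i <- coords$i[t]; q1 <- coords$q1[t]
    hp <- model$h; hp[i, q1] <- hp[i, q1] + eps
    hm <- model$h; hm[i, q1] <- hm[i, q1] - eps
    fd <- (loss_at(hp, model$P) - loss_at(hm, model$P)) / (2 * eps)
    expect_equal(lg$grad_h[i, q1], fd, tolerance = 1e-5)
    j <- coords$j[t]; q2 <- coords$q2[t]
    if (i != j) {
      Pp <- model$P; Pp[i, j, q1, q2] <- Pp[i, j, q1, q2] + eps
      Pm <- model$P; Pm[i, j, q1, q2] <- Pm[i, j, q1, q2] - eps
      fd <- (loss_at(model$h, Pp) - loss_at(model$h, Pm)) / (2 * eps)
      expect_equal(lg$grad_P[i, j, q1, q2], fd, tolerance = 1e-5)
    }
  }
})

test_that("plm_fit yields symmetric couplings, small couplings on identical rows, and a monotone regularization path", {
  # identical rows: no covariation signal; couplings stay small while the
  # planted fixture below reaches scores an order of magnitude larger
  ident <- make_msa(L = 10, N = 8, identity_levels = 1.0, seed = 4)
  fit0 <- plm_fit(ident)
  expect_true(fit0$converged)
  s0 <- coupling_scores(fit0, apc = FALSE)
  expect_lt(max(s0), 1)
  # symmetry of the fitted couplings
  P <- fit0$P
  for (i in 1:10) {
    for (j in 1:10) {
      if (i != j) expect_equal(P[i, j, , ], t(P[j, i, , ]))
    }
  }
  # planted-pair fixture: the planted pair attains the top coupling score
  fx <- make_potts_msa(L = 10, N = 400,
                       planted_pairs = cbind(2L, 9L), seed = 31)
  fit1 <- plm_fit(fx$msa)
  sc <- coupling_scores(fit1)
  top <- top_contacts(sc, 1, min_separation = 0)
  expect_equal(c(top$i, top$j), c(2L, 9L))
  expect_gt(top$score, 5 * max(s0))
  # doubling lambda_pair never increases the coupling norm
  norm1 <- sqrt(sum(fit1$P^2))
  fit2 <- plm_fit(fx$msa, lambda_pair = 2 * 0.2 * (10 - 1))
  expect_lte(sqrt(sum(fit2$P^2)), norm1 + 1e-6)
})

test_that("coupling scores are symmetric, zero-diagonal, and APC cancels rank-one structure", {
  zero <- msaforge:::zero_potts_model(6)
  expect_equal(coupling_scores(zero), matrix(0, 6, 6))
  fx <- make_potts_msa(L = 10, N = 200, planted_pairs = cbind(1L, 8L),
                       seed = 5)
  sc <- coupling_scores(plm_fit(fx$msa, maxit = 40))
  expect_equal(sc, t(sc))
  expect_equal(diag(sc), rep(0, 10))
  # APC of a rank-one score matrix is ~0 (exact up to floating point)
  v <- with_seed(6, runif(12, 0.5, 2))
  expect_equal(apc_correct(outer(v, v)), matrix(0, 12, 12),
               tolerance = 1e-12)
})

test_that("top_contacts respects separation filters and matches the sort oracle", {
  L <- 30
  sc <- with_seed(8, {
    s <- matrix(runif(L * L), L, L)
    s <- (s + t(s)) / 2
    diag(s) <- 0
    s
  })
  tc <- top_contacts(sc, 10, min_separation = 24)
  expect_true(all(tc$j - tc$i >= 24))
  expect_equal(tc, oracle_top_contacts(sc, 10, 24),
               ignore_attr = TRUE)
  # only pairs with j - i >= 24 are eligible at L = 30: at most 21 pairs
  expect_lte(nrow(top_contacts(sc, 100, min_separation = 24)), 21)
  # count = 1 returns the global eligible argmax
  t1 <- top_contacts(sc, 1, min_separation = 24)
  elig <- oracle_top_contacts(sc, 1000, 24)
  expect_equal(t1$score, max(elig$score))
  # deterministic tie-break by (i, j)
  tie <- matrix(0, 30, 30); tie[1, 26] <- 1; tie[2, 27] <- 1
  tie <- tie + t(tie)
  tt <- top_contacts(tie, 1, min_separation = 24)
  expect_equal(c(tt$i, tt$j), c(1, 26))
})

test_that("bin midpoints follow the argmax bin with a first-bin tie rule", {
  scheme <- default_bin_scheme()
  expect_equal(nrow(scheme), 37L)
  # argmax bin [4.0, 4.5) -> 4.25
  p <- rep(0, 37); p[which(scheme$lower == 4.0)] <- 1
  expect_equal(bin_midpoint_estimate(p, scheme), 4.25)
  # uniform probabilities -> first bin midpoint
  expect_equal(bin_midpoint_estimate(rep(1 / 37, 37), scheme), 2.25)
  # one-hot on the open last bin -> lower edge + half the previous width
  p2 <- rep(0, 37); p2[37] <- 1
  expect_equal(bin_midpoint_estimate(p2, scheme), 20.25)
})

test_that("the top-5L long-range MAE handles selection, missing truth and translation", {
  # identical sets -> 0
  pred <- distance_set(c(1, 2, 3), c(30, 40, 50), c(8, 10, 12))
  expect_equal(mae_top_long_range(pred, distance_set(c(1, 2, 3), c(30, 40, 50),
                                                     c(8, 10, 12),
                                                     "experimental"),
                                  L = 1, multiplier = 3), 0)
  # two pairs with errors 1 and 3 Angstrom, selecting two pairs -> 2.0
  p2 <- distance_set(c(1, 2), c(30, 40), c(8, 10))
  e2 <- distance_set(c(1, 2), c(30, 40), c(9, 13), "experimental")
  expect_equal(mae_top_long_range(p2, e2, L = 2, multiplier = 1), 2.0)
  # a pair without experimental truth is dropped and the divisor reduced
  p3 <- distance_set(c(1, 2, 3), c(30, 40, 50), c(8, 10, 12))
  e3 <- distance_set(c(1, 2), c(30, 40), c(9, 13), "experimental")
  expect_equal(mae_top_long_range(p3, e3, L = 3, multiplier = 1), 2.0)
  # translation invariance; constant shift of pred alone moves MAE by |c|
  shift <- function(ds, c) distance_set(ds$i, ds$j, ds$value + c,
                                        attr(ds, "kind"))
  expect_equal(mae_top_long_range(shift(p2, 2), shift(e2, 2), L = 2,
                                  multiplier = 1), 2.0)
  expect_equal(mae_top_long_range(shift(p2, 5), e2, L = 2, multiplier = 1),
               abs(2.0 - 5))
  # separation filter: nothing eligible -> undefined signal
  near <- distance_set(1, 5, 7)
  expect_error(mae_top_long_range(near, e2, L = 1), "no eligible")
  # confidence ranking picks the top pairs
  p4 <- distance_set(c(1, 2), c(30, 40), c(8, 10))
  e4 <- distance_set(c(1, 2), c(30, 40), c(9, 20), "experimental")
  expect_equal(mae_top_long_range(p4, e4, L = 1, multiplier = 1,
                                  confidence = c(1, 0)), 1.0)
  expect_equal(mae_top_long_range(p4, e4, L = 1, multiplier = 1,
                                  confidence = c(0, 1)), 10.0)
})
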
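test_that("stoichiometry strings parse, format and round-trip", {
  st <- parse_stoichiometry("A2B2C1")
  expect_equal(st$n_distinct, 3L)
  expect_equal(unname(st$copies), c(2L, 2L, 1L))
  expect_false(st$is_homomer)

  oct <- parse_stoichiometry("A8")
  expect_true(oct$is_homomer)
  expect_equal(unname(oct$copies), 8L)

  expect_error(parse_stoichiometry("2A"), "position 1")
  expect_error(parse_stoichiometry("A2B"), "position 3")
  expect_error(parse_stoichiometry("A2A3"), "duplicate")
  expect_error(parse_stoichiometry("A0"), ">= 1")

  # parse -> format -> parse round trip
  for (s in c("A2B2C1", "A8", "A1B1C1D1E1", "A3B1")) {
    expect_identical(format(parse_stoichiometry(s)), s)
    expect_identical(parse_stoichiometry(format(parse_stoichiometry(s)))$copies,
                     parse_stoichiometry(s)$copies)
  }
})

test_that("pairing depth maximizes M under M^N <= budget, capped by availability", {
  expect_identical(pairing_depth(3), 4L)   # 4^3 = 64 <= 100
  expect_identical(pairing_depth(2), 10L)  # 10^2 = 100, also the cap
  expect_identical(pairing_depth(7), 1L)   # 2^7 = 128 > 100
  expect_identical(pairing_depth(1), 10L)  # capped by available
  expect_identical(pairing_depth(2, available = 3), 3L)
  # brute-force check over a range of N and budgets
  for (N in 1:6) {
    for (budget in c(10, 100, 500)) {
      brute <- max(which(vapply(1:50, function(m) m^N <= budget, logical(1))))
      expect_identical(pairing_depth(N, budget = budget, available = 50),
                       as.integer(brute))
    }
  }
  # accepts a stoichiometry directly
  expect_identical(pairing_depth(parse_stoichiometry("A2B2C1")), 4L)
})

test_that("pairing enumeration yields exactly M^N lexicographic tuples", {
  fx <- make_complex_fixture("A2B2C1", n_candidates = 5, seed = 13)
  M <- pairing_depth(fx$stoich)
  tuples <- enumerate_pairings(fx$chain_set, M)
  expect_equal(nrow(tuples), 64L)
  expect_equal(colnames(tuples), c("A", "B", "C"))
  expect_equal(unname(tuples[1, ]), c(1L, 1L, 1L))
  expect_equal(unname(tuples[2, ]), c(1L, 1L, 2L))  # last chain varies fastest
  expect_equal(unname(tuples[64, ]), c(4L, 4L, 4L))
  expect_false(anyDuplicated(tuples) > 0)

  # single-chain degenerate case: M tuples; M = 1: one tuple
  one <- make_complex_fixture("A1", n_candidates = 6, seed = 2)
  expect_equal(nrow(enumerate_pairings(one$chain_set, 4L)), 4L)
  expect_equal(nrow(enumerate_pairings(fx$chain_set, 1L)), 1L)

  # fewer available candidates than M lowers M and records it
  small <- make_complex_fixture("A1B1", n_candidates = 3, seed = 3)
  t2 <- enumerate_pairings(small$chain_set, 10L)
  expect_equal(attr(t2, "M_used"), 3L)
  expect_equal(nrow(t2), 9L)
})

test_that("heteromer linking groups by species, ranks by identity and pads gaps", {
  # minimal link: one shared species, one member each
  mini <- make_complex_fixture("A1B1",
                               species_table = list(s1 = c(A = 1, B = 1)),
                               n_extra = 0, seed = 21)
  pm <- link_heteromer(lapply(mini$chain_set, function(x) x[[1]]$msa),
                       mini$stoich)
  expect_equal(pm$linked_rows, 1L)
  expect_equal(pm$msa$N, 2L)  # query + 1 linked row

  # no shared species: zero linked rows, all homologs padded below
  disj <- make_complex_fixture("A1B1",
                               species_table = list(s1 = c(A = 1),
                                                    s2 = c(B = 1)),
                               n_extra = 0, seed = 22)
  pm0 <- link_heteromer(lapply(disj$chain_set, function(x) x[[1]]$msa),
                        disj$stoich)
  expect_equal(pm0$linked_rows, 0L)
  expect_equal(pm0$msa$N, 3L)  # query + 2 unlinked

  # hand-enumerated fixture: s1 {2 in A, 1 in B}, s2 {1 in A}
  hand <- make_complex_fixture("A1B1",
                               species_table = list(s1 = c(A = 2, B = 1),
                                                    s2 = c(A = 1)),
                               n_extra = 0, seed = 23)
  chains <- lapply(hand$chain_set, function(x) x[[1]]$msa)
  pmh <- link_heteromer(chains, hand$stoich)
  expect_equal(pmh$linked_rows, 1L)            # only s1 rank-1 pair links
  expect_equal(pmh$msa$N, 1L + 1L + 2L)        # query + linked + 2 unlinked
  # the linked row pairs the highest-identity s1 member of A
  a <- chains$A
  s1_rows <- which(a$species == "s1")
  best <- s1_rows[which.max(vapply(s1_rows, function(r) seq_identity(a, 1, r),
                                   numeric(1)))]
  la <- substr(pmh$msa$seq[2], 1, a$L)
  expect_equal(la, msaforge:::match_seq(a$seq[best]))

  # N = 3 with one species absent from one chain: that chain is gap-padded
  pad <- make_complex_fixture("A1B1C1",
                              species_table = list(s1 = c(A = 1, B = 1)),
                              n_extra = 0, seed = 24)
  chains3 <- lapply(pad$chain_set, function(x) x[[1]]$msa)
  pm3 <- link_heteromer(chains3, pad$stoich)
  expect_equal(pm3$linked_rows, 1L)
  lc <- substring(pm3$msa$seq[2],
                  chains3$A$L + chains3$B$L + 1,
                  chains3$A$L + chains3$B$L + chains3$C$L)
  expect_equal(lc, strrep("-", chains3$C$L))

  # chain set / stoichiometry mismatch is an error
  expect_error(link_heteromer(chains, pad$stoich), "do not match")
})

test_that("linking conserves rows and keeps row lengths constant", {
  tables <- list(
    list(s1 = c(A = 2, B = 1), s2 = c(A = 1, B = 2), s3 = c(B = 1)),
    list(s1 = c(A = 1, B = 1, C = 1), s2 = c(A = 2, C = 1)),
    list(s1 = c(A = 3), s2 = c(B = 2))
  )
  stoichs <- c("A1B1", "A2B1C1", "A1B2")
  for (k in seq_along(tables)) {
    fx <- make_complex_fixture(stoichs[k], species_table = tables[[k]],
                               n_extra = 1, seed = 30 + k)
    chains <- lapply(fx$chain_set, function(x) x[[1]]$msa)
    pm <- link_heteromer(chains, fx$stoich)
    expect_equal(pm$linked_rows, fx$expected_linked_rows)
    # conservation: every homolog appears exactly once (linked or padded);
    # count consumed members via non-gap chain blocks (each chain block is
    # repeated copies times, so divide by the copy count)
    n_hom <- sum(vapply(fx$stoich$chains,
                        function(ch) chains[[ch]]$N - 1L, integer(1)))
    spans <- pm$spans
    linked_seqs <- pm$msa$seq[1 + seq_len(pm$linked_rows)]
    consumed_in_linked <- sum(vapply(linked_seqs, function(s) {
      sum(vapply(seq_len(nrow(spans)), function(r) {
        seg <- substring(s, spans$start[r] + 1, spans$end[r])
        seg != strrep("-", nchar(seg))
      }, logical(1)) / fx$stoich$copies[spans$chain])
    }, numeric(1)))
    n_unlinked <- pm$msa$N - 1L - pm$linked_rows
    expect_equal(consumed_in_linked + n_unlinked, n_hom)
    # constant total row length, gap padding never alters residues
    expect_true(all(nchar(pm$msa$seq) ==
                      sum(fx$stoich$copies *
                            vapply(fx$stoich$chains,
                                   function(ch) chains[[ch]]$L, integer(1)))))
  }
})

test_that("homomer self-concatenation repeats rows side by side", {
  m <- make_msa(L = 50, N = 6, identity_levels = 0.7, seed = 40)
  pm <- concat_homomer(m, 3)
  expect_equal(pm$msa$L, 150L)
  expect_equal(pm$msa$N, 6L)
  expect_equal(pm$msa$id[1], m$id[1])
  # slicing block k recovers the original match columns
  for (k in 1:3) {
    block <- substring(pm$msa$seq, (k - 1) * 50 + 1, k * 50)
    expect_equal(block, unname(vapply(m$seq, msaforge:::match_seq,
                                      character(1))))
  }
})

test_that("the M-score combines Neff with copy-weighted chain confidences", {
  st <- parse_stoichiometry("A2B1")
  fx <- make_complex_fixture("A2B1", n_extra = 0, seed = 41)
  pm <- link_heteromer(lapply(fx$chain_set, function(x) x[[1]]$msa), st)
  pm$neff <- 2
  expect_equal(m_score(pm, c(A = 0.8, B = 0.5), st), 1.4)
  # all pLDDT = 1 -> M-score equals Neff; all zero -> zero
  expect_equal(m_score(pm, c(A = 1, B = 1), st), 2)
  expect_equal(m_score(pm, c(A = 0, B = 0), st), 0)
  # monotone nondecreasing in each pLDDT, linear in Neff
  base <- m_score(pm, c(A = 0.5, B = 0.5), st)
  expect_gte(m_score(pm, c(A = 0.6, B = 0.5), st), base)
  pm2 <- pm; pm2$neff <- 4
  expect_equal(m_score(pm2, c(A = 0.5, B = 0.5), st), 2 * base)
  expect_error(m_score(pm, c(A = 0.5), st), "every chain")
})

test_that("paired-MSA selection keeps the top 25 heteromers and all homomers", {
  fx <- make_complex_fixture("A2B2C1", n_candidates = 4, n_extra = 2,
                             seed = 42)
  M <- pairing_depth(fx$stoich)
  tuples <- enumerate_pairings(fx$chain_set, M)
  paired <- lapply(seq_len(nrow(tuples)), function(t) {
    choice <- lapply(fx$stoich$chains, function(ch) {
      fx$chain_set[[ch]][[tuples[t, ch]]]$msa
    })
    names(choice) <- fx$stoich$chains
    pm <- link_heteromer(choice, fx$stoich, component_choice = tuples[t, ])
    pm$neff <- neff(pm$msa)
    plddts <- vapply(fx$stoich$chains, function(ch) {
      fx$chain_set[[ch]][[tuples[t, ch]]]$rank_score
    }, numeric(1))
    pm$m_score <- m_score(pm, plddts, fx$stoich)
    pm
  })
  sel <- select_paired(paired, fx$stoich)
  expect_length(sel, 25L)
  scores <- vapply(sel, `[[`, numeric(1), "m_score")
  expect_true(all(diff(scores) <= 1e-12))  # sorted descending
  expect_equal(max(scores),
               max(vapply(paired, `[[`, numeric(1), "m_score")))
  # permuting the input never changes the selected set
  perm <- with_seed(7, sample(seq_along(paired)))
  sel2 <- select_paired(paired[perm], fx$stoich)
  expect_equal(vapply(sel2, msaforge:::choice_key, character(1)),
               vapply(sel, msaforge:::choice_key, character(1)))
  # fewer candidates than k: all survive
  expect_length(select_paired(paired[1:20], fx$stoich), 20L)
  # homomer: unfiltered
  hom <- parse_stoichiometry("A2")
  expect_length(select_paired(paired[1:10], hom), 10L)
})

test_that("run_multimer generates 625 heteromer / 250 homomer models and keeps five", {
  het <- make_complex_fixture("A1B1", n_candidates = 10, seed = 11)
  res <- run_multimer(het$chain_set, het$stoich, mock_predictor)
  expect_equal(res$n_generated, 625L)
  expect_equal(res$n_msas_used, 25L)
  expect_equal(nrow(res$models), 5L)
  expect_true(all(diff(res$models$ptm) <= 0))

  hom <- make_complex_fixture("A3", n_candidates = 10, seed = 12)
  rh <- run_multimer(hom$chain_set, hom$stoich, mock_predictor)
  expect_equal(rh$n_generated, 250L)
  expect_equal(rh$n_msas_used, 10L)

  # final_k larger than generated: everything is returned
  tiny <- run_multimer(hom$chain_set, hom$stoich, mock_predictor,
                       models_per_msa = 2, final_k = 100)
  expect_equal(nrow(tiny$models), tiny$n_generated)

  # predictor failure on one MSA: skipped with a diagnostic
  flaky <- local({
    calls <- 0
    function(paired, count) {
      calls <<- calls + 1
      if (calls == 2) stop("GPU on fire")
      mock_predictor(paired, count)
    }
  })
  rf <- run_multimer(hom$chain_set, hom$stoich, flaky)
  expect_equal(rf$n_generated, 225L)
  expect_match(rf$diagnostics, "paired MSA 2")
})
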
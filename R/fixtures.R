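# Deterministic synthetic-data generators: mutated-query MSAs with species
# labels, fully diverse random MSAs, planted-coupling Potts alignments
# sampled by Gibbs sweeps, complex chain sets with controlled species
# sharing, and the mock scorer / predictor / search backends that stand in
# for the out-of-scope structure predictors and search tools. All generators
# are pure functions of their arguments (seed included) and never touch the
# caller's RNG state.

random_aa_seq <- function(L) paste0(sample(AA20, L, replace = TRUE),
                                    collapse = "")

#' Generate a mutated-query MSA fixture
#'
#' Builds a random query of length `L` and `N - 1` homologs, each derived
#' from the query by point mutations placed to hit its requested identity
#' level within 0.02. Homolog r substitutes its mutated positions with the
#' query residue shifted by `((r - 1) mod 19) + 1` places in the amino-acid
#' alphabet, so that for up to 19 homologs any two rows disagree at every
#' position either of them mutated; with all identity levels below ~0.79 and
#' `N <= 20` every pairwise identity is then provably below 0.8 and
#' `neff(msa)` equals the closed form `N / sqrt(L)` exactly. Species labels
#' from `species_pool` are assigned round-robin to the first
#' `round(fraction_annotated * (N - 1))` homologs.
#'
#' @param L query length.
#' @param N total number of rows including the query.
#' @param identity_levels target identities in \[0, 1\], recycled over the
#'   homologs.
#' @param species_pool character vector of species keys (may be empty).
#' @param fraction_annotated fraction of homologs receiving a species label.
#' @param seed RNG seed; identical arguments give byte-identical output.
#' @return An [msa] with species keys set and `OS=` annotations in the
#'   headers.
#' @export
make_msa <- function(L, N, identity_levels = 0.6, species_pool = character(),
                     fraction_annotated = 0, seed = 1) {
  stopifnot(L >= 1, N >= 1, all(identity_levels >= 0 & identity_levels <= 1),
            fraction_annotated >= 0, fraction_annotated <= 1)
  with_seed(seed, {
    qchars <- sample(AA20, L, replace = TRUE)
    n_hom <- N - 1L
    levels <- rep_len(identity_levels, max(n_hom, 1L))
    seqs <- character(n_hom)
    for (r in seq_len(n_hom)) {
      lvl <- levels[r]
      k <- round((1 - lvl) * L)
      achieved <- 1 - k / L
      if (abs(achieved - lvl) > 0.02 || (lvl < 1 && k == 0L)) {
        usage_error(sprintf(
          "identity level %.4f is infeasible at L = %d (achievable %.4f)",
          lvl, L, achieved))
      }
      chars <- qchars
      if (k > 0L) {
        pos <- sample.int(L, k)
        shift <- ((r - 1L) %% 19L) + 1L
        from <- match(qchars[pos], AA20)
        chars[pos] <- AA20[((from - 1L + shift) %% 20L) + 1L]
      }
      seqs[r] <- paste0(chars, collapse = "")
    }
    n_annot <- round(fraction_annotated * n_hom)
    species <- rep(NA_character_, n_hom)
    if (n_annot > 0L && length(species_pool)) {
      species[seq_len(n_annot)] <-
        species_pool[((seq_len(n_annot) - 1L) %% length(species_pool)) + 1L]
    }
    ids <- c("query", sprintf("hom%04d", seq_len(n_hom)))
    desc <- c("query",
              ifelse(is.na(species), ids[-1],
                     paste0(ids[-1], " OS=", species)))
    msa(ids, c(paste0(qchars, collapse = ""), seqs), desc = desc,
        species = c(NA_character_, species))
  })
}

#' Generate a fully diverse random MSA
#'
#' All rows are independent uniform random sequences, so every pairwise
#' identity is far below the 0.8 redundancy threshold (with overwhelming
#' probability at the lengths used) and `neff` equals `n / sqrt(L)`. Used to
#' emulate deep, diverse search results at a controlled Neff.
#'
#' @param n number of rows (query included).
#' @param L sequence length.
#' @param seed RNG seed.
#' @return An [msa].
#' @export
make_diverse_msa <- function(n, L, seed = 1) {
  stopifnot(n >= 1, L >= 1)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) random_aa_seq(L), character(1))
    msa(c("query", sprintf("div%04d", seq_len(n - 1L)))[seq_len(n)], seqs)
  })
}

#' Default planted coupling pairs
#'
#' `n_pairs` site-disjoint pairs at the largest separation the length allows
#' (pair p is `(p, L - n_pairs + p)`, separation `L - n_pairs`). The
#' long-range convention |i - j| >= 24 is enforced whenever `L` permits it.
#'
#' @param L alignment length (must allow `n_pairs` disjoint pairs).
#' @param n_pairs number of planted pairs (default 3).
#' @return Two-column integer matrix of (i, j) pairs.
#' @export
default_planted_pairs <- function(L, n_pairs = 3) {
  stopifnot(L >= 2 * n_pairs + 2)
  i <- seq_len(n_pairs)
  j <- L - n_pairs + i
  cbind(i = i, j = as.integer(j))
}

#' Sample a planted-coupling Potts alignment
#'
#' Sequences are sampled from a 22-state Potts model with zero fields and
#' couplings only on the planted pairs (`strength` on the same-state
#' diagonal), by Gibbs sweeps run in parallel over `N` independent chains:
#' `burnin` full sweeps followed by `thin` additional sweeps before the
#' single recorded state per chain. Sampled gap states in the query row are
#' replaced by random residues so the query stays gapless; all chain
#' settings are recorded for reproducibility.
#'
#' @param L alignment length.
#' @param N number of sequences.
#' @param planted_pairs two-column matrix of coupled site pairs (defaults to
#'   [default_planted_pairs()]).
#' @param strength same-state coupling strength (log-odds units; default 3,
#'   a strong, clearly recoverable signal).
#' @param seed RNG seed.
#' @param burnin burn-in sweeps (default 100).
#' @param thin additional sweeps before recording (default 10).
#' @return An object of class `potts_fixture`: `msa`, `planted_pairs`,
#'   `strength` and the `sampler` settings.
#' @export
make_potts_msa <- function(L, N, planted_pairs = default_planted_pairs(L),
                           strength = 3, seed = 1, burnin = 100, thin = 10) {
  pp <- as.matrix(planted_pairs)[, 1:2, drop = FALSE]
  stopifnot(all(pp >= 1), all(pp <= L), all(pp[, 1] < pp[, 2]))
  Q <- Q_STATES
  partner <- rep(NA_integer_, L)
  for (r in seq_len(nrow(pp))) {
    if (!is.na(partner[pp[r, 1]]) || !is.na(partner[pp[r, 2]])) {
      usage_error("planted pairs must be site-disjoint")
    }
    partner[pp[r, 1]] <- pp[r, 2]
    partner[pp[r, 2]] <- pp[r, 1]
  }
  out <- with_seed(seed, {
    states <- matrix(sample.int(Q, N * L, replace = TRUE), N, L)
    for (sweep in seq_len(burnin + thin)) {
      for (i in seq_len(L)) {
        if (is.na(partner[i])) {
          # no couplings and zero fields: conditional is uniform
          states[, i] <- sample.int(Q, N, replace = TRUE)
        } else {
          logits <- matrix(0, N, Q)
          logits[cbind(seq_len(N), states[, partner[i]])] <- strength
          gumbel <- -log(-log(runif(N * Q)))
          states[, i] <- max.col(logits + gumbel, ties.method = "first")
        }
      }
    }
    chars <- matrix(states_to_chars(states - 1L), N, L)
    gap_in_q <- chars[1, ] == "-"
    if (any(gap_in_q)) {
      chars[1, gap_in_q] <- sample(AA20, sum(gap_in_q), replace = TRUE)
    }
    seqs <- apply(chars, 1, paste0, collapse = "")
    msa(c("query", sprintf("smp%04d", seq_len(N - 1L)))[seq_len(N)], seqs)
  })
  structure(
    list(msa = out, planted_pairs = pp, strength = strength,
         sampler = list(seed = seed, burnin = burnin, thin = thin, Q = Q)),
    class = "potts_fixture")
}

#' Build a complex chain set with controlled species sharing
#'
#' Emits, for every distinct chain of the stoichiometry, `n_candidates`
#' candidate MSAs whose homologs realize the requested per-species chain
#' membership, plus `n_extra` unannotated homologs per chain. Homolog r of a
#' chain carries `r + 1` mutations, so identity-to-query strictly decreases
#' with row order and the rank-matched linking rule is hand-enumerable. The
#' expected number of linked rows under that rule (sum over species present
#' in >= 2 chains of the smallest per-chain member count) is returned
#' alongside. Candidate k receives `n_candidates - k` additional diverse
#' rows, so Neff - and with it the mock rank score - strictly decreases down
#' the candidate list.
#'
#' @param stoich a `stoichiometry` or a stoichiometry string.
#' @param species_table named list: species key to named integer vector of
#'   per-chain homolog counts, e.g. `list(s1 = c(A = 2, B = 1))`. `NULL`
#'   gives three species shared by all chains with one member each.
#' @param n_candidates candidate MSAs per chain (default 1).
#' @param L chain query length (default 12).
#' @param n_extra unannotated homologs per chain (default 1).
#' @param seed RNG seed.
#' @return List with `chain_set` (named list of [candidate_msa] lists, rank
#'   scores populated, best first), `stoich` and `expected_linked_rows`.
#' @export
make_complex_fixture <- function(stoich, species_table = NULL,
                                 n_candidates = 1, L = 12, n_extra = 1,
                                 seed = 1) {
  if (is.character(stoich)) stoich <- parse_stoichiometry(stoich)
  stopifnot(inherits(stoich, "stoichiometry"))
  chains <- stoich$chains
  if (is.null(species_table)) {
    species_table <- lapply(sprintf("species %d", 1:3), function(sp) {
      setNames(rep(1L, length(chains)), chains)
    })
    names(species_table) <- sprintf("species %d", 1:3)
  }
  counts <- function(sp, ch) {
    v <- species_table[[sp]]
    if (ch %in% names(v)) as.integer(v[[ch]]) else 0L
  }
  sp_names <- names(species_table)
  carriers <- vapply(sp_names, function(sp) {
    sum(vapply(chains, function(ch) counts(sp, ch) > 0L, logical(1)))
  }, integer(1))
  expected_linked <- sum(vapply(sp_names[carriers >= 2L], function(sp) {
    pres <- chains[vapply(chains, function(ch) counts(sp, ch) > 0L,
                          logical(1))]
    min(vapply(pres, function(ch) counts(sp, ch), integer(1)))
  }, integer(1)))

  chain_set <- with_seed(seed, {
    out <- lapply(seq_along(chains), function(ci) {
      ch <- chains[ci]
      qchars <- sample(AA20, L, replace = TRUE)
      lapply(seq_len(n_candidates), function(k) {
        species <- unlist(lapply(sp_names, function(sp) {
          rep(sp, counts(sp, ch))
        }), use.names = FALSE)
        n_div <- n_extra + (n_candidates - k)
        species <- c(species, rep(NA_character_, n_div))
        seqs <- vapply(seq_along(species), function(r) {
          if (r > length(species) - n_div) {
            return(random_aa_seq(L))
          }
          chars <- qchars
          pos <- sample.int(L, min(r + 1L, L - 1L))
          from <- match(qchars[pos], AA20)
          chars[pos] <- AA20[(from %% 20L) + 1L]
          paste0(chars, collapse = "")
        }, character(1))
        ids <- c(sprintf("%s_query", ch),
                 sprintf("%s_c%d_h%02d", ch, k, seq_along(species)))
        desc <- c(ids[1],
                  ifelse(is.na(species), ids[-1],
                         paste0(ids[-1], " OS=", species)))
        m <- msa(ids, c(paste0(qchars, collapse = ""), seqs), desc = desc,
                 species = c(NA_character_, species))
        candidate_msa(m, "qMSA", 1L, rank_score = max(mock_scorer(m)))
      })
    })
    names(out) <- chains
    out
  })
  list(chain_set = chain_set, stoich = stoich,
       expected_linked_rows = if (stoich$n_distinct >= 2L) expected_linked
                              else NA_integer_)
}

#' Mock structure scorer
#'
#' Deterministic stand-in for the rapid single-chain structure predictor:
#' returns five pLDDT values computed as a fixed saturating function of the
#' alignment's Neff, `p = Neff / (Neff + 8)`, scaled by the factors
#' (1, 0.98, 0.96, 0.94, 0.92). Higher Neff never scores lower, and the best
#' of the five equals `p` exactly, so ranking tests are closed-form.
#'
#' @param x an [msa].
#' @return Numeric vector of five confidences in \[0, 1\].
#' @export
mock_scorer <- function(x) {
  nf <- neff(x)
  p <- nf / (nf + 8)
  p * c(1, 0.98, 0.96, 0.94, 0.92)
}

#' Mock complex structure predictor
#'
#' Deterministic stand-in for the complex predictor: emits `count`
#' (model, predicted TM-score) pairs whose scores are a saturating function
#' of the paired MSA's Neff, decreasing slightly with model index.
#'
#' @param paired a `paired_msa`.
#' @param count number of models to emit.
#' @return Data frame with columns `model` and `ptm`.
#' @export
mock_predictor <- function(paired, count) {
  stopifnot(inherits(paired, "paired_msa"), count >= 1)
  nf <- paired$neff
  if (is.na(nf)) nf <- neff(paired$msa)
  base <- nf / (nf + 8)
  k <- seq_len(count)
  data.frame(model = sprintf("model_%03d", k),
             ptm = base * (1 - (k - 1) / (2 * count)))
}

#' Build a deterministic mock backend set
#'
#' Constructs dMSA/qMSA/mMSA stage backends whose alignments hit the
#' requested Neff values: each stage emits a fully diverse random MSA
#' ([make_diverse_msa()]) with `round(target * sqrt(L))` rows, so its Neff
#' equals the target. Stages beyond the first follow the
#' `list(search=, build=)` contract, emitting `n_raw` raw hit sequences that
#' the orchestrator may truncate before `build` is called.
#'
#' @param neff_targets list with numeric vectors `dmsa` (up to 3), `qmsa`
#'   (up to 4) and `mmsa` (up to 3) of per-stage Neff values.
#' @param L alignment length used by the mock MSAs (default 16).
#' @param n_raw number of raw hits emitted by stage >= 2 searches (default
#'   100).
#' @param seed RNG seed.
#' @return Backend set usable with [generate_candidates()].
#' @export
make_mock_backends <- function(neff_targets = list(dmsa = c(20, 40, 60),
                                                   qmsa = c(20, 40, 60, 80),
                                                   mmsa = c(30, 50, 70)),
                               L = 16, n_raw = 100, seed = 1) {
  stage_msa <- function(target, salt) {
    make_diverse_msa(max(1L, round(target * sqrt(L))), L,
                     seed = seed + salt)
  }
  stage_backend <- function(target, salt, first) {
    if (first) {
      function(query, prev) stage_msa(target, salt)
    } else {
      list(
        search = function(query, prev) {
          vapply(seq_len(n_raw), function(i) {
            with_seed(seed + salt * 1000L + i, random_aa_seq(L))
          }, character(1))
        },
        build = function(hits, prev) stage_msa(target, salt))
    }
  }
  dmsa <- lapply(seq_along(neff_targets$dmsa), function(k) {
    stage_backend(neff_targets$dmsa[k], k, k == 1L)
  })
  qmsa <- lapply(seq_along(neff_targets$qmsa), function(k) {
    stage_backend(neff_targets$qmsa[k], 10L + k, k == 1L)
  })
  mmsa_targets <- neff_targets$mmsa %||% numeric()
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  mmsa <- if (length(mmsa_targets)) {
    list(
      build_db = function(probe) list(probe_L = probe$L),
      search = function(seed_msa, db) {
        counter$k <- counter$k + 1L
        k <- ((counter$k - 1L) %% length(mmsa_targets)) + 1L
        stage_msa(mmsa_targets[k], 20L + k)
      })
  } else {
    NULL
  }
  list(dmsa = dmsa, qmsa = qmsa, mmsa = mmsa)
}
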
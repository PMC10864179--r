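# Multimeric MSA construction: stoichiometry parsing, the M^N <= 100 pairing
# budget, species-grouped sequence linking with gap padding, homomer
# self-concatenation, M-score ranking and model-count bookkeeping with a
# pluggable complex predictor.

#' Parse a stoichiometry string
#'
#' A stoichiometry string such as `"A2B2C1"` lists each distinct protein
#' chain as a letter followed by its copy number.
#'
#' @param s stoichiometry string.
#' @return An object of class `stoichiometry` with fields `chains`
#'   (character), `copies` (integer), `n_distinct` and `is_homomer`
#'   (one distinct chain with at least two copies).
#' @export
#' @examples
#' parse_stoichiometry("A2B2C1")
#' parse_stoichiometry("A8")
parse_stoichiometry <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- trimws(s)
  if (!nzchar(s)) format_error("empty stoichiometry string")
  chains <- character()
  copies <- integer()
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    frag <- substring(s, pos)
    m <- regmatches(frag, regexpr("^[A-Za-z][0-9]+", frag))
    if (!length(m)) {
      format_error(sprintf(
        "stoichiometry parse error at position %d of '%s' (expected letter+digits)",
        pos, s))
    }
    chains <- c(chains, substr(m, 1, 1))
    copies <- c(copies, as.integer(substr(m, 2, nchar(m))))
    pos <- pos + nchar(m)
  }
  if (anyDuplicated(chains)) {
    format_error(sprintf("duplicate chain id '%s' in '%s'",
                         chains[anyDuplicated(chains)], s))
  }
  if (any(copies < 1L)) {
    format_error("chain copy numbers must be >= 1")
  }
  structure(
    list(chains = chains, copies = setNames(copies, chains),
         n_distinct = length(chains),
         is_homomer = length(chains) == 1L && copies[1] >= 2L),
    class = "stoichiometry")
}

#' @export
format.stoichiometry <- function(x, ...) {
  paste0(x$chains, x$copies[x$chains], collapse = "")
}

#' @export
print.stoichiometry <- function(x, ...) {
  kind <- if (x$is_homomer) "homomer" else if (x$n_distinct == 1L) {
    "monomer"
  } else "heteromer"
  cat(sprintf("stoichiometry %s (%s, %d distinct chain(s), %d total)\n",
              format(x), kind, x$n_distinct, sum(x$copies)))
  invisible(x)
}

#' Pairing depth under the M^N budget
#'
#' The number `M` of top-ranked monomer MSAs retained per distinct chain is
#' the largest value with `M^N <= budget`, additionally capped by the number
#' of available MSAs per chain, and never below 1. For `N = 3` and the
#' default budget 100 this gives `M = 4` (64 paired MSAs).
#'
#' @param n_chains number of distinct chains, or a `stoichiometry`.
#' @param budget maximum number of paired MSAs (default 100).
#' @param available MSAs available per chain (default 10).
#' @return Integer `M >= 1`.
#' @export
#' @examples
#' pairing_depth(3)
#' pairing_depth(2)
pairing_depth <- function(n_chains, budget = 100, available = 10) {
  if (inherits(n_chains, "stoichiometry")) n_chains <- n_chains$n_distinct
  stopifnot(n_chains >= 1, budget >= 1, available >= 1)
  m <- 1
  while ((m + 1)^n_chains <= budget) m <- m + 1
  as.integer(max(1, min(m, available)))
}

chain_candidates <- function(chain_set, ch) {
  x <- chain_set[[ch]]
  if (is.null(x)) usage_error(sprintf("no candidate MSAs for chain '%s'", ch))
  if (inherits(x, "candidate_msa")) x <- list(x)
  x
}

#' Enumerate per-chain MSA combinations
#'
#' Produces the `M^N` component choices (one monomer-MSA rank index per
#' distinct chain) in lexicographic order over the per-chain rank indices.
#' When a chain offers fewer than `M` candidates, `M` is lowered to the
#' minimum available and the reduction is recorded in the `M_used`
#' attribute.
#'
#' @param chain_set named list: chain id to list of [candidate_msa] (sorted
#'   by rank score, best first).
#' @param M pairing depth, typically from [pairing_depth()].
#' @return Integer matrix with `M^N` rows and one column per chain; attribute
#'   `M_used` records the effective depth.
#' @export
enumerate_pairings <- function(chain_set, M) {
  stopifnot(length(chain_set) >= 1, M >= 1)
  chains <- names(chain_set)
  if (is.null(chains) || any(!nzchar(chains))) {
    usage_error("chain_set must be a named list keyed by chain id")
  }
  avail <- vapply(chains, function(ch) length(chain_candidates(chain_set, ch)),
                  integer(1))
  M_used <- as.integer(min(M, min(avail)))
  # lexicographic: first chain varies slowest, last chain fastest
  g <- do.call(expand.grid, rev(lapply(chains, function(ch) seq_len(M_used))))
  g <- as.matrix(g)[, rev(seq_along(chains)), drop = FALSE]
  colnames(g) <- chains
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  structure(g, M_used = M_used)
}

gap_string <- function(L) strrep("-", L)

paired_msa_obj <- function(msa_obj, component_choice, linked_rows, spans,
                           neff_value = NA_real_, m_score = NA_real_) {
  structure(
    list(msa = msa_obj, component_choice = component_choice,
         linked_rows = linked_rows, spans = spans,
         neff = neff_value, m_score = m_score),
    class = "paired_msa")
}

#' @export
print.paired_msa <- function(x, ...) {
  cat(sprintf(
    "paired MSA: N = %d rows, L = %d columns, %s linked row(s)%s%s\n",
    x$msa$N, x$msa$L,
    if (is.na(x$linked_rows)) "NA" else x$linked_rows,
    if (is.na(x$neff)) "" else sprintf(", Neff = %.3f", x$neff),
    if (is.na(x$m_score)) "" else sprintf(", M-score = %.3f", x$m_score)))
  invisible(x)
}

# column spans (0-based half-open) of each chain copy in the concatenated
# coordinate system
chain_spans <- function(stoich, Ls) {
  spans <- list()
  offset <- 0L
  for (ch in stoich$chains) {
    for (cp in seq_len(stoich$copies[[ch]])) {
      spans[[length(spans) + 1L]] <-
        data.frame(chain = ch, copy = cp, start = offset,
                   end = offset + Ls[[ch]])
      offset <- offset + Ls[[ch]]
    }
  }
  do.call(rbind, spans)
}

#' Link monomeric MSAs into a heteromeric paired MSA
#'
#' Builds a concatenated multichain MSA from one monomer MSA per distinct
#' chain. Homologs are grouped by species key and, within each group, ordered
#' by sequence identity to the chain query (descending). For every species
#' present in at least two chains, the rank-r members of the group across
#' chains are concatenated side by side for r = 1..(smallest group size among
#' the chains carrying that species); chains lacking the species contribute a
#' gap block. The concatenated query is row 1; all remaining (unlinked)
#' homologs are appended below, each padded with gaps in every other chain's
#' columns. Each distinct chain's block is repeated according to its copy
#' number. Rows without a species annotation are never linked. Only the
#' match columns of each monomer MSA enter the concatenated coordinate
#' system.
#'
#' @param choice named list mapping each distinct chain id to its chosen
#'   monomer [msa] (or [candidate_msa]).
#' @param stoich a `stoichiometry`.
#' @param link_depth maximum linked rank per species (default `Inf` =
#'   rank-matched down to the smallest group; `1` links only the top
#'   sequences).
#' @param component_choice optional integer vector recording which rank index
#'   was chosen per chain (provenance).
#' @return A `paired_msa`: the concatenated [msa], the component choice, the
#'   number of linked rows, per-chain column spans (0-based half-open), and
#'   slots for Neff and M-score.
#' @export
link_heteromer <- function(choice, stoich, link_depth = Inf,
                           component_choice = NULL) {
  stopifnot(inherits(stoich, "stoichiometry"))
  chains <- stoich$chains
  if (!setequal(names(choice), chains)) {
    usage_error(sprintf(
      "choice chains {%s} do not match stoichiometry chains {%s}",
      paste(sort(names(choice)), collapse = ","),
      paste(sort(chains), collapse = ",")))
  }
  mono <- lapply(chains, function(ch) {
    x <- choice[[ch]]
    if (inherits(x, "candidate_msa")) x <- x$msa
    if (!is_msa(x)) usage_error(sprintf("choice for chain '%s' is not an msa", ch))
    x
  })
  names(mono) <- chains
  Ls <- lapply(mono, `[[`, "L")

  # per chain: homolog bookkeeping in identity-descending order
  hom <- lapply(chains, function(ch) {
    m <- mono[[ch]]
    if (m$N < 2L) {
      return(data.frame(row = integer(), species = character(),
                        ident = numeric(), seq = character(),
                        id = character(), stringsAsFactors = FALSE))
    }
    rows <- 2:m$N
    ident <- vapply(rows, function(r) seq_identity(m, 1L, r), numeric(1))
    d <- data.frame(row = rows, species = m$species[rows], ident = ident,
                    seq = vapply(m$seq[rows], match_seq, character(1),
                                 USE.NAMES = FALSE),
                    id = m$id[rows], stringsAsFactors = FALSE)
    d$species <- ifelse(is.na(d$species), NA_character_, trimws(d$species))
    d[order(-d$ident, d$row), , drop = FALSE]
  })
  names(hom) <- chains

  # species -> chains carrying it
  sp_chain <- lapply(chains, function(ch) unique(stats::na.omit(hom[[ch]]$species)))
  names(sp_chain) <- chains
  all_sp <- sort(unique(unlist(sp_chain, use.names = FALSE)))
  carriers <- lapply(all_sp, function(sp) {
    chains[vapply(chains, function(ch) sp %in% sp_chain[[ch]], logical(1))]
  })
  names(carriers) <- all_sp
  eligible <- all_sp[lengths(carriers) >= 2L]

  consumed <- lapply(hom, function(d) rep(FALSE, nrow(d)))
  linked_segments <- list()  # each: named list chain -> segment string
  linked_ids <- character()
  linked_sp <- character()
  for (sp in eligible) {
    pres <- carriers[[sp]]
    sizes <- vapply(pres, function(ch) sum(hom[[ch]]$species %in% sp),
                    integer(1))
    depth <- min(min(sizes), link_depth)
    for (r in seq_len(depth)) {
      segs <- setNames(vector("list", length(chains)), chains)
      for (ch in chains) {
        if (ch %in% pres) {
          idx <- which(hom[[ch]]$species %in% sp)[r]
          segs[[ch]] <- hom[[ch]]$seq[idx]
          consumed[[ch]][idx] <- TRUE
        } else {
          segs[[ch]] <- gap_string(Ls[[ch]])
        }
      }
      linked_segments[[length(linked_segments) + 1L]] <- segs
      linked_ids <- c(linked_ids, sprintf("linked|%s|%d", sp, r))
      linked_sp <- c(linked_sp, sp)
    }
  }

  # unlinked homologs, chain by chain in stoichiometry order, identity order
  unlinked_segments <- list()
  unlinked_ids <- character()
  unlinked_sp <- character()
  for (ch in chains) {
    left <- which(!consumed[[ch]])
    for (idx in left) {
      segs <- setNames(as.list(vapply(chains, function(c2) gap_string(Ls[[c2]]),
                                      character(1))), chains)
      segs[[ch]] <- hom[[ch]]$seq[idx]
      unlinked_segments[[length(unlinked_segments) + 1L]] <- segs
      unlinked_ids <- c(unlinked_ids, sprintf("%s|%s", ch, hom[[ch]]$id[idx]))
      unlinked_sp <- c(unlinked_sp, hom[[ch]]$species[idx])
    }
  }

  assemble <- function(segs) {
    paste0(vapply(chains, function(ch) strrep(segs[[ch]], stoich$copies[[ch]]),
                  character(1)),
           collapse = "")
  }
  qsegs <- setNames(lapply(chains, function(ch) match_seq(mono[[ch]]$seq[1])),
                    chains)
  rows <- c(list(qsegs), linked_segments, unlinked_segments)
  seqs <- vapply(rows, assemble, character(1))
  ids <- c("query", linked_ids, unlinked_ids)
  species <- c(NA_character_, linked_sp, unlinked_sp)
  # expand spans to repeated chain copies
  Ls_rep <- lapply(chains, function(ch) Ls[[ch]])
  names(Ls_rep) <- chains
  out <- msa(ids, seqs, species = species)
  paired_msa_obj(out, component_choice, linked_rows = length(linked_segments),
                 spans = chain_spans(stoich, Ls_rep))
}

#' Self-concatenate a monomer MSA for a homomeric complex
#'
#' Every row's match-column sequence is repeated `copies` times side by side:
#' the row count is unchanged and the alignment length is multiplied by the
#' copy number.
#'
#' @param x monomer [msa] (or [candidate_msa]).
#' @param copies number of chain copies (>= 2).
#' @return A `paired_msa` (no linking is involved; `linked_rows` is `NA`).
#' @export
concat_homomer <- function(x, copies) {
  if (inherits(x, "candidate_msa")) x <- x$msa
  stopifnot(is_msa(x), copies >= 2)
  copies <- as.integer(copies)
  seqs <- strrep(vapply(x$seq, match_seq, character(1), USE.NAMES = FALSE),
                 copies)
  out <- msa(x$id, seqs, desc = x$desc, species = x$species)
  spans <- data.frame(chain = "A", copy = seq_len(copies),
                      start = (seq_len(copies) - 1L) * x$L,
                      end = seq_len(copies) * x$L)
  paired_msa_obj(out, component_choice = NULL, linked_rows = NA_integer_,
                 spans = spans)
}

#' M-score of a paired MSA
#'
#' Combines the diversity of the concatenated alignment with the
#' copy-number-weighted mean of the per-chain model confidences:
#' \deqn{M = Neff \times \frac{\sum_i n_i\, pLDDT_i}{\sum_i n_i}}
#' where `n_i` is the copy number of chain i and `pLDDT_i` the rank score of
#' the monomer MSA chosen for that chain. Neff is computed over the full
#' concatenated MSA (linked plus padded rows).
#'
#' @param paired a `paired_msa`; its `neff` slot is used when present,
#'   otherwise Neff is computed from the concatenated MSA.
#' @param chain_plddts named numeric vector of per-chain pLDDTs in \[0, 1\].
#' @param stoich the complex `stoichiometry`.
#' @return The M-score (numeric scalar).
#' @export
m_score <- function(paired, chain_plddts, stoich) {
  stopifnot(inherits(paired, "paired_msa"), inherits(stoich, "stoichiometry"))
  p <- chain_plddts[stoich$chains]
  if (any(is.na(p))) usage_error("chain_plddts must cover every chain")
  if (any(p < 0 | p > 1)) usage_error("pLDDT values must lie in [0, 1]")
  nf <- paired$neff
  if (is.na(nf)) nf <- neff(paired$msa)
  w <- stoich$copies[stoich$chains]
  nf * sum(w * p) / sum(w)
}

choice_key <- function(p) {
  if (is.null(p$component_choice)) return("")
  paste(sprintf("%06d", p$component_choice), collapse = "|")
}

#' Select the paired MSAs forwarded to structure prediction
#'
#' Heteromers: the top `k_het` paired MSAs by M-score (descending; exact ties
#' broken by lexicographic component choice). Homomers: all self-concatenated
#' MSAs are returned unfiltered.
#'
#' @param paired_list list of `paired_msa` (heteromers must carry `m_score`).
#' @param stoich the complex `stoichiometry`.
#' @param k_het number of heteromer MSAs to keep (default 25).
#' @return List of `paired_msa`, sorted by M-score for heteromers.
#' @export
select_paired <- function(paired_list, stoich, k_het = 25) {
  stopifnot(inherits(stoich, "stoichiometry"))
  if (stoich$is_homomer || stoich$n_distinct == 1L) return(paired_list)
  scores <- vapply(paired_list, `[[`, numeric(1), "m_score")
  if (any(is.na(scores))) {
    usage_error("heteromer selection requires m_score on every paired MSA")
  }
  keys <- vapply(paired_list, choice_key, character(1))
  ord <- order(-scores, keys)
  paired_list[ord[seq_len(min(k_het, length(paired_list)))]]
}

#' Run the multimeric MSA + model bookkeeping pipeline
#'
#' For a heteromer: chooses the pairing depth M under the `M^N <= budget`
#' rule, enumerates all component choices, links each into a paired MSA,
#' scores them with the M-score and keeps the top `k_het` (default 25). For a
#' homomer: self-concatenates each of the available monomer MSAs (up to 10)
#' and keeps them all. Each selected MSA is then passed to the pluggable
#' complex predictor, which returns `models_per_msa` (model, predicted
#' TM-score) pairs; all generated models are ranked by predicted TM-score and
#' the top `final_k` are returned with provenance. With the defaults this
#' generates 25 x 25 = 625 models for a heteromer and 10 x 25 = 250 for a
#' homomer before selecting the top five.
#'
#' @param chain_set named list: chain id to list of [candidate_msa] with rank
#'   scores populated, best first.
#' @param stoich the complex `stoichiometry`.
#' @param predictor function `(paired_msa, count)` returning a data frame
#'   with columns `model` and `ptm` (`count` rows).
#' @param models_per_msa models generated per paired MSA (default 25).
#' @param final_k models returned after ranking (default 5).
#' @param k_het paired MSAs kept for heteromers (default 25).
#' @param budget,available passed to [pairing_depth()].
#' @param link_depth passed to [link_heteromer()].
#' @return An object of class `multimer_result`: `models` (top `final_k`
#'   with provenance), `n_generated`, `n_msas_used`, `paired` (the selected
#'   paired MSAs), `stoich` and `diagnostics`.
#' @export
run_multimer <- function(chain_set, stoich, predictor, models_per_msa = 25,
                         final_k = 5, k_het = 25, budget = 100,
                         available = 10, link_depth = Inf) {
  stopifnot(inherits(stoich, "stoichiometry"), is.function(predictor))
  sort_cands <- function(cands) {
    rs <- vapply(cands, `[[`, numeric(1), "rank_score")
    if (any(is.na(rs))) usage_error("chain candidates need rank_score set")
    cands[order(-rs)]
  }
  if (stoich$n_distinct == 1L) {
    cands <- sort_cands(chain_candidates(chain_set, stoich$chains[1]))
    cands <- cands[seq_len(min(length(cands), available))]
    paired <- lapply(cands, function(cand) {
      pm <- concat_homomer(cand$msa, stoich$copies[1])
      pm$neff <- neff(pm$msa)
      pm$m_score <- m_score(pm, setNames(cand$rank_score, stoich$chains[1]),
                            stoich)
      pm
    })
    selected <- select_paired(paired, stoich, k_het)
  } else {
    per_chain <- lapply(stoich$chains, function(ch) {
      sort_cands(chain_candidates(chain_set, ch))
    })
    names(per_chain) <- stoich$chains
    M <- pairing_depth(stoich$n_distinct, budget, available)
    tuples <- enumerate_pairings(per_chain, M)
    paired <- lapply(seq_len(nrow(tuples)), function(t) {
      choice <- lapply(stoich$chains, function(ch) {
        per_chain[[ch]][[tuples[t, ch]]]$msa
      })
      names(choice) <- stoich$chains
      pm <- link_heteromer(choice, stoich, link_depth = link_depth,
                           component_choice = tuples[t, ])
      pm$neff <- neff(pm$msa)
      plddts <- vapply(stoich$chains, function(ch) {
        per_chain[[ch]][[tuples[t, ch]]]$rank_score
      }, numeric(1))
      pm$m_score <- m_score(pm, plddts, stoich)
      pm
    })
    selected <- select_paired(paired, stoich, k_het)
  }

  rows <- list()
  diagnostics <- character()
  n_generated <- 0L
  for (s in seq_along(selected)) {
    preds <- tryCatch(predictor(selected[[s]], models_per_msa),
                      error = function(e) e)
    if (inherits(preds, "error")) {
      diagnostics <- c(diagnostics, sprintf(
        "predictor failed on paired MSA %d: %s", s, conditionMessage(preds)))
      next
    }
    if (!is.data.frame(preds) || is.null(preds$ptm)) {
      diagnostics <- c(diagnostics, sprintf(
        "predictor returned an invalid result for paired MSA %d; skipped", s))
      next
    }
    n_generated <- n_generated + nrow(preds)
    rows[[length(rows) + 1L]] <- data.frame(
      msa_index = s,
      model = if (is.null(preds$model)) paste0("model_", seq_len(nrow(preds)))
              else as.character(preds$model),
      ptm = preds$ptm,
      stringsAsFactors = FALSE)
  }
  all_models <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(msa_index = integer(), model = character(), ptm = numeric())
  }
  ord <- order(-all_models$ptm, all_models$msa_index, all_models$model)
  top <- all_models[head(ord, final_k), , drop = FALSE]
  rownames(top) <- NULL
  structure(
    list(models = top, n_generated = n_generated,
         n_msas_used = length(selected), paired = selected,
         stoich = stoich, diagnostics = diagnostics),
    class = "multimer_result")
}

#' @export
print.multimer_result <- function(x, ...) {
  cat(sprintf(
    "multimer run (%s): %d paired MSA(s), %d models generated, top %d kept\n",
    format(x$stoich), x$n_msas_used, x$n_generated, nrow(x$models)))
  print(x$models)
  invisible(x)
}
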
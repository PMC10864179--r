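# Staged monomeric MSA construction: the three-stage dMSA block, the
# four-stage qMSA block and the three-seed mMSA block run over pluggable
# search backends, with the Neff > 128 early stop, the 30,000-hit filter
# before custom-database construction, and model-confidence ranking of the
# candidate MSAs.
#
# Backend contracts (all deterministic in test/mock implementations):
#   * stage-1 backend:      function(query_msa, prev_msa) -> msa (or NULL)
#   * stage >= 2 backend:   either the same function form, or a list
#     `list(search = function(query_msa, prev_msa) -> character vector of raw
#     hit sequences, build = function(hits, prev_msa) -> msa)`. The
#     orchestrator truncates the raw hits to `blast_keep` before `build` is
#     called (the e-value-ranked BLAST filter ahead of clustering and
#     profile-database construction).
#   * mMSA backend:         list(build_db = function(probe_msa) -> opaque db,
#     search = function(seed_msa, db) -> msa).
#   * structure scorer:     function(msa) -> exactly five model confidence
#     values (pLDDT) in [0, 1].

#' Construct a candidate MSA record
#'
#' Wraps an [msa] with its provenance (pipeline block and stage), its Neff
#' and an optional model-based rank score (best pLDDT of five models).
#'
#' @param x an [msa] object.
#' @param block one of `"dMSA"`, `"qMSA"`, `"mMSA"`.
#' @param stage stage index within the block.
#' @param neff_value precomputed Neff; computed from `x` when omitted.
#' @param rank_score optional rank score in \[0, 1\].
#' @return An object of class `candidate_msa`.
#' @export
candidate_msa <- function(x, block, stage, neff_value = neff(x),
                          rank_score = NA_real_) {
  stopifnot(is_msa(x), block %in% c("dMSA", "qMSA", "mMSA"),
            stage >= 1)
  max_stage <- c(dMSA = 3L, qMSA = 4L, mMSA = 3L)[[block]]
  if (stage > max_stage) {
    usage_error(sprintf("block %s has at most %d stages", block, max_stage))
  }
  if (!is.na(rank_score) && (rank_score < 0 || rank_score > 1)) {
    usage_error("rank_score must lie in [0, 1]")
  }
  structure(
    list(msa = x, block = block, stage = as.integer(stage),
         neff = neff_value, rank_score = rank_score),
    class = "candidate_msa")
}

#' @export
print.candidate_msa <- function(x, ...) {
  cat(sprintf("candidate MSA [%s stage %d]: N = %d, L = %d, Neff = %.3f%s\n",
              x$block, x$stage, x$msa$N, x$msa$L, x$neff,
              if (is.na(x$rank_score)) ""
              else sprintf(", rank score = %.3f", x$rank_score)))
  invisible(x)
}

as_query_msa <- function(query) {
  if (is_msa(query)) {
    return(msa(query$id[1], match_seq(query$seq[1]), query$desc[1]))
  }
  stopifnot(is.character(query), length(query) == 1L)
  id <- names(query) %||% "query"
  msa(id, toupper(query))
}

call_stage_backend <- function(backend, query_msa, prev_msa, blast_keep) {
  if (is.function(backend)) return(backend(query_msa, prev_msa))
  if (is.list(backend) && is.function(backend$search) &&
      is.function(backend$build)) {
    hits <- backend$search(query_msa, prev_msa)
    if (length(hits) > blast_keep) hits <- hits[seq_len(blast_keep)]
    return(backend$build(hits, prev_msa))
  }
  usage_error("a stage backend must be a function or list(search=, build=)")
}

run_block <- function(query_msa, stages, block, neff_stop, blast_keep) {
  cands <- list()
  prev <- NULL
  diagnostics <- character()
  stopped_stage <- NA_integer_
  for (k in seq_along(stages)) {
    res <- tryCatch(
      call_stage_backend(stages[[k]], query_msa, prev, blast_keep),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, sprintf(
        "%s stage %d backend failed: %s", block, k, conditionMessage(res)))
      break
    }
    if (is.null(res)) {
      if (k == 1L) {
        res <- query_msa  # empty stage-1 search: query-only candidate
      } else {
        diagnostics <- c(diagnostics, sprintf(
          "%s stage %d produced no alignment; block ended", block, k))
        break
      }
    }
    cand <- candidate_msa(res, block, k)
    cands[[length(cands) + 1L]] <- cand
    prev <- res
    if (cand$neff > neff_stop) {   # strictly greater, as specified
      stopped_stage <- k
      break
    }
  }
  structure(cands, stopped_stage = stopped_stage, diagnostics = diagnostics)
}

#' Run the three-stage dMSA block
#'
#' Iterates the block's stage backends in order, stopping after the first
#' stage whose alignment has `Neff > neff_stop` (strict comparison). For
#' stages implemented as `list(search=, build=)`, raw hits are truncated to
#' `blast_keep` by the backend-supplied ranking before the clustering /
#' custom-database step receives them.
#'
#' @param query query sequence (character) or an [msa] whose first row is
#'   used.
#' @param backends backend set; `backends$dmsa` must be a list of up to three
#'   stage backends.
#' @param neff_stop early-stop threshold (default 128).
#' @param blast_keep maximum number of raw hits forwarded to the enrichment
#'   step (default 30000).
#' @return List of [candidate_msa] in stage order (1 to 3 entries), with
#'   attributes `stopped_stage` (NA when no early stop) and `diagnostics`.
#' @export
run_dmsa <- function(query, backends, neff_stop = 128, blast_keep = 30000) {
  stages <- backends$dmsa %||% usage_error("backends$dmsa is missing")
  if (length(stages) > 3L) usage_error("dMSA has at most 3 stages")
  run_block(as_query_msa(query), stages, "dMSA", neff_stop, blast_keep)
}

#' Run the four-stage qMSA block
#'
#' @inheritParams run_dmsa
#' @return List of [candidate_msa] (1 to 4 entries) with the same attributes
#'   as [run_dmsa()].
#' @export
run_qmsa <- function(query, backends, neff_stop = 128, blast_keep = 30000) {
  stages <- backends$qmsa %||% usage_error("backends$qmsa is missing")
  if (length(stages) > 4L) usage_error("qMSA has at most 4 stages")
  run_block(as_query_msa(query), stages, "qMSA", neff_stop, blast_keep)
}

#' Run the mMSA block over a metagenomic backend
#'
#' A probe alignment is used to build a search database once; each available
#' seed alignment (dMSA stage 2, qMSA stage 2, qMSA stage 3) is then searched
#' against it, yielding up to three candidates. Absent seeds are skipped.
#'
#' @param seeds named list with elements `dmsa2`, `qmsa2`, `qmsa3` ([msa] or
#'   `NULL`).
#' @param probe probe [msa] used to build the database.
#' @param backend list with functions `build_db(probe)` and
#'   `search(seed, db)`.
#' @return List of [candidate_msa] (at most 3) with a `diagnostics`
#'   attribute.
#' @export
run_mmsa <- function(seeds, probe, backend) {
  stopifnot(is.list(backend), is.function(backend$build_db),
            is.function(backend$search))
  seed_order <- c("dmsa2", "qmsa2", "qmsa3")
  avail <- seed_order[vapply(seed_order, function(s) !is.null(seeds[[s]]),
                             logical(1))]
  if (!length(avail) || is.null(probe)) {
    return(structure(list(), diagnostics = "mMSA: no seeds or probe available"))
  }
  db <- backend$build_db(probe)
  cands <- list()
  diagnostics <- character()
  for (k in seq_along(avail)) {
    res <- tryCatch(backend$search(seeds[[avail[k]]], db),
                    error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, sprintf(
        "mMSA seed '%s' backend failed: %s", avail[k], conditionMessage(res)))
      next
    }
    if (is.null(res)) next
    cands[[length(cands) + 1L]] <- candidate_msa(res, "mMSA",
                                                 length(cands) + 1L)
  }
  structure(cands, diagnostics = diagnostics)
}

block_msa <- function(block_result, stage) {
  if (length(block_result) >= stage) block_result[[stage]]$msa else NULL
}

#' Generate the full set of candidate MSAs for a query
#'
#' Runs the dMSA (up to 3 MSAs) and qMSA (up to 4) blocks, then the mMSA
#' block (up to 3) seeded by the dMSA stage-2 and qMSA stage-2/3 alignments.
#' The mMSA block is skipped when both dMSA and qMSA early-stopped at stage 1
#' (the genomic databases alone were sufficient). At most ten candidates are
#' returned.
#'
#' @param query query sequence or [msa].
#' @param backends backend set with elements `dmsa`, `qmsa` and optionally
#'   `mmsa`.
#' @param config list of options: `neff_stop` (default 128) and `blast_keep`
#'   (default 30000).
#' @return List of [candidate_msa] (at most 10) with a `diagnostics`
#'   attribute.
#' @export
generate_candidates <- function(query, backends, config = list()) {
  neff_stop <- config$neff_stop %||% 128
  blast_keep <- config$blast_keep %||% 30000
  d <- run_dmsa(query, backends, neff_stop, blast_keep)
  q <- run_qmsa(query, backends, neff_stop, blast_keep)
  diagnostics <- c(attr(d, "diagnostics"), attr(q, "diagnostics"))
  m <- list()
  d_stop1 <- identical(attr(d, "stopped_stage"), 1L)
  q_stop1 <- identical(attr(q, "stopped_stage"), 1L)
  if (!(d_stop1 && q_stop1) && !is.null(backends$mmsa)) {
    seeds <- list(dmsa2 = block_msa(d, 2L),
                  qmsa2 = block_msa(q, 2L),
                  qmsa3 = block_msa(q, 3L))
    # probe is the qMSA stage-3 alignment; fall back to the deepest qMSA MSA
    probe <- block_msa(q, 3L) %||%
      (if (length(q)) q[[length(q)]]$msa else NULL)
    m <- run_mmsa(seeds, probe, backends$mmsa)
    diagnostics <- c(diagnostics, attr(m, "diagnostics"))
  }
  out <- c(unclass(d)[], unclass(q)[], unclass(m)[])
  attributes(out) <- list(diagnostics = diagnostics)
  out
}

#' Score and select the final MSA
#'
#' Each candidate is scored by the pluggable structure scorer, which returns
#' five model confidences (pLDDT); the best of the five becomes the
#' candidate's rank score. The candidate with the highest rank score is
#' selected; exact ties are broken by higher Neff, then by block order
#' (dMSA < qMSA < mMSA) and stage index, so selection is deterministic.
#'
#' @param candidates non-empty list of [candidate_msa].
#' @param scorer function taking an [msa] and returning exactly five numeric
#'   confidences in \[0, 1\].
#' @return The selected [candidate_msa] (rank score filled in), with a
#'   `ranking` attribute holding the full scored table.
#' @export
rank_and_select <- function(candidates, scorer) {
  if (!length(candidates)) usage_error("no candidate MSAs to rank")
  stopifnot(is.function(scorer))
  block_rank <- c(dMSA = 1L, qMSA = 2L, mMSA = 3L)
  scored <- lapply(candidates, function(cand) {
    s <- scorer(cand$msa)
    if (length(s) != 5L || !is.numeric(s)) {
      usage_error("the structure scorer must return exactly 5 numeric values")
    }
    if (any(s < 0 | s > 1)) usage_error("pLDDT scores must lie in [0, 1]")
    cand$rank_score <- max(s)
    cand
  })
  tbl <- data.frame(
    block = vapply(scored, `[[`, character(1), "block"),
    stage = vapply(scored, `[[`, integer(1), "stage"),
    neff = vapply(scored, `[[`, numeric(1), "neff"),
    rank_score = vapply(scored, `[[`, numeric(1), "rank_score"))
  ord <- order(-tbl$rank_score, -tbl$neff, block_rank[tbl$block], tbl$stage)
  selected <- scored[[ord[1]]]
  attr(selected, "ranking") <- tbl[ord, , drop = FALSE]
  selected
}
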
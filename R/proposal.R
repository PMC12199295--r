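# The ligand-generation step: similarity-ranked fragment sampling into
# reaction containers, candidate enumeration, and similarity-weighted
# candidate selection.
#
# Fragments are ranked once per reference molecule by Tversky substructure
# similarity (reference weight 0.1, fragment weight 0.9); the geometric rank
# sampler then routes fragments -- drawn without replacement -- into every
# compatible reaction component sub-container. After each batch all currently
# formable products are enumerated; the loop stops when the candidate limit
# is reached or the fragment list is exhausted. Candidates are then ranked by
# Tanimoto similarity to the reference and one is drawn with the same
# geometric rank sampler.

#' Proposal-step configuration
#'
#' @param candidate_limit Stop filling containers once at least this many
#'   candidate products exist (default 30).
#' @param fragment_batch Fragments sampled per filling step before products
#'   are re-enumerated (default 20); a cost bound, not a semantic knob.
#' @param tversky_alpha,tversky_beta Tversky weights for fragment ranking
#'   (defaults 0.1 / 0.9: reference / fragment).
#' @return A list of class `rx_proposal_config`.
#' @export
proposal_config <- function(candidate_limit = 30L, fragment_batch = 20L,
                            tversky_alpha = 0.1, tversky_beta = 0.9) {
  stopifnot(candidate_limit >= 1L, fragment_batch >= 1L)
  structure(list(candidate_limit = as.integer(candidate_limit),
                 fragment_batch = as.integer(fragment_batch),
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta),
            class = "rx_proposal_config")
}

#' Rank library fragments by similarity to a reference molecule
#'
#' @param lib An `rx_library`.
#' @param ref Reference molecule ([rx_mol] or SMILES).
#' @param alpha,beta Tversky weights (defaults 0.1 / 0.9).
#' @return A data frame with columns `smiles`, `similarity`, `rank`
#'   (1 = most similar), sorted by decreasing similarity with stable ties.
#' @export
rank_fragments <- function(lib, ref, alpha = 0.1, beta = 0.9) {
  stopifnot(inherits(lib, "rx_library"))
  ref <- rx_mol(ref)
  sim <- tversky_vec(rx_fingerprint(ref), lib$frag_fp, alpha, beta)
  ord <- order(-sim)   # stable: ties keep library order
  data.frame(smiles = lib$fragments[ord], similarity = sim[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Propose candidate products by similarity-guided fragment sampling
#'
#' @param lib An `rx_library`.
#' @param ref Reference molecule.
#' @param x Sampling ratio for the geometric rank sampler.
#' @param cfg An [proposal_config()].
#' @return A list of candidate [rx_mol] products (deduplicated, possibly
#'   fewer than `candidate_limit`, empty if nothing is formable), each with
#'   a provenance attribute.
#' @export
propose_candidates <- function(lib, ref, x, cfg = proposal_config()) {
  stopifnot(inherits(lib, "rx_library"))
  ranked <- rank_fragments(lib, ref, cfg$tversky_alpha, cfg$tversky_beta)
  remaining <- ranked$smiles
  containers <- lapply(lib$reactions, function(rxn)
    lapply(seq_len(rxn$n_components), function(i) character()))
  candidates <- list()
  seen <- character()
  while (length(remaining) > 0L && length(candidates) < cfg$candidate_limit) {
    take <- min(cfg$fragment_batch, length(remaining))
    for (b in seq_len(take)) {
      w <- geometric_weights(x, length(remaining))
      k <- sample_rank(w)
      frag <- remaining[k]
      remaining <- remaining[-k]
      for (mem in lib$membership[[frag]]) {
        rid <- mem[["reaction"]]; ci <- as.integer(mem[["component"]])
        containers[[rid]][[ci]] <- c(containers[[rid]][[ci]], frag)
      }
      if (!length(remaining)) break
    }
    for (rid in names(containers)) {
      subs <- containers[[rid]]
      if (any(vapply(subs, length, integer(1)) == 0L)) next
      prods <- enumerate_products(
        list(reaction = lib$reactions[[rid]], sub_containers = subs),
        limit = cfg$candidate_limit)
      for (p in prods) {
        if (p$smiles %in% seen) next
        seen <- c(seen, p$smiles)
        candidates[[length(candidates) + 1L]] <- p
      }
    }
  }
  candidates
}

#' Select one candidate by Tanimoto-ranked geometric sampling
#'
#' @param cands Non-empty list of candidate [rx_mol]s.
#' @param ref Reference molecule.
#' @param x Sampling ratio.
#' @return The chosen [rx_mol] (provenance attribute preserved).
#' @export
select_candidate <- function(cands, ref, x) {
  if (!length(cands)) stop("no candidates to select from", call. = FALSE)
  if (length(cands) == 1L) return(cands[[1L]])
  ref_fp <- rx_fingerprint(rx_mol(ref))
  smi <- vapply(cands, `[[`, character(1), "smiles")
  sim <- tanimoto_vec(ref_fp, fp_matrix(smi))
  ord <- order(-sim)
  w <- geometric_weights(x, length(cands))
  cands[[ord[sample_rank(w)]]]
}
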
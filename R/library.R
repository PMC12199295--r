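# Combinatorial reaction/synthon libraries.
#
# A library couples reactions (SMARTS transformations of arity >= 1) with
# per-reaction, per-component synthon lists. On construction every synthon is
# canonicalised, deduplicated, checked against its component's reactant
# template (non-matching synthons are dropped with a warning), and its
# fingerprint precomputed. A global table of unique fragments with their
# component memberships supports similarity ranking and container routing.

.validate_component <- function(rxn, comp, smiles_vec) {
  can <- canonical_smiles(smiles_vec)
  bad <- is.na(can)
  if (any(bad)) {
    warning("reaction ", rxn$reaction_id, " component ", comp, ": dropped ",
            sum(bad), " unparseable synthon(s)", call. = FALSE)
  }
  can <- unique(can[!bad])
  ok <- vapply(can, function(s) {
    g <- mol_graph_smiles(s)
    !is.null(g) && graph_valence_ok(g) &&
      length(match_smarts(rxn$reactants[[comp]], g, max_matches = 1L)) > 0L
  }, logical(1))
  if (any(!ok)) {
    warning("reaction ", rxn$reaction_id, " component ", comp, ": dropped ",
            sum(!ok), " synthon(s) not matching the component template",
            call. = FALSE)
  }
  can[ok]
}

#' Build a combinatorial library from reactions and synthon lists
#'
#' @param reactions List of [rx_reaction] objects.
#' @param synthons Nested list: `synthons[[reaction_id]][[component]]` is a
#'   character vector of synthon SMILES (components are 1-based here;
#'   the file format of [load_library()] uses 0-based component indices).
#' @return An object of class `rx_library`.
#' @export
combinatorial_library <- function(reactions, synthons) {
  stopifnot(length(reactions) >= 1L)
  names(reactions) <- vapply(reactions, `[[`, character(1), "reaction_id")
  validated <- list()
  for (rid in names(reactions)) {
    rxn <- reactions[[rid]]
    comps <- synthons[[rid]]
    if (is.null(comps) || length(comps) != rxn$n_components) {
      stop("reaction '", rid, "': expected synthon lists for ",
           rxn$n_components, " components", call. = FALSE)
    }
    validated[[rid]] <- lapply(seq_len(rxn$n_components), function(ci) {
      v <- .validate_component(rxn, ci, comps[[ci]])
      if (!length(v)) {
        stop("reaction '", rid, "' component ", ci,
             ": no valid synthons remain", call. = FALSE)
      }
      v
    })
  }
  # global unique-fragment table with component membership
  frag <- unique(unlist(validated, use.names = FALSE))
  membership <- vector("list", length(frag))
  names(membership) <- frag
  for (rid in names(validated)) {
    for (ci in seq_along(validated[[rid]])) {
      for (s in validated[[rid]][[ci]]) {
        membership[[s]] <- c(membership[[s]],
                             list(c(reaction = rid, component = ci)))
      }
    }
  }
  lib <- structure(list(
    reactions = reactions,
    synthons = validated,
    fragments = frag,
    membership = membership,
    frag_fp = fp_matrix(frag)), class = "rx_library")
  lib
}

#' @export
print.rx_library <- function(x, ...) {
  cat("<rx_library> ", length(x$reactions), " reactions, ",
      length(x$fragments), " unique synthons\n", sep = "")
  for (rid in names(x$reactions)) {
    sizes <- vapply(x$synthons[[rid]], length, integer(1))
    cat("  ", rid, ": ", paste(sizes, collapse = " x "), " synthons\n",
        sep = "")
  }
  invisible(x)
}

#' Load a combinatorial library from TSV files
#'
#' `reactions_path`: header-less TSV `reaction_id<TAB>n_components<TAB>smarts`.
#' `synthons_path`: header-less TSV `reaction_id<TAB>component_index<TAB>smiles`
#' with 0-based component indices. Synthons failing their component template
#' are dropped with a warning; a malformed SMARTS or an empty component after
#' validation is an error.
#'
#' @param reactions_path,synthons_path File paths.
#' @return An `rx_library`.
#' @seealso [save_library()], [make_fixture_library()]
#' @export
load_library <- function(reactions_path, synthons_path) {
  rtab <- utils::read.delim(reactions_path, header = FALSE,
                            col.names = c("reaction_id", "n_components",
                                          "smarts"),
                            colClasses = c("character", "integer",
                                           "character"))
  stab <- utils::read.delim(synthons_path, header = FALSE,
                            col.names = c("reaction_id", "component_index",
                                          "smiles"),
                            colClasses = c("character", "integer",
                                           "character"))
  reactions <- lapply(seq_len(nrow(rtab)), function(i) {
    rxn <- rx_reaction(rtab$reaction_id[i], rtab$smarts[i])
    if (rxn$n_components != rtab$n_components[i]) {
      stop("reaction '", rtab$reaction_id[i], "': declared arity ",
           rtab$n_components[i], " but SMARTS has ", rxn$n_components,
           " reactant templates", call. = FALSE)
    }
    rxn
  })
  synthons <- list()
  for (i in seq_len(nrow(rtab))) {
    rid <- rtab$reaction_id[i]
    rows <- stab[stab$reaction_id == rid, , drop = FALSE]
    synthons[[rid]] <- lapply(seq_len(rtab$n_components[i]) - 1L,
                              function(ci) rows$smiles[rows$component_index == ci])
  }
  combinatorial_library(reactions, synthons)
}

#' Save a combinatorial library to TSV files
#'
#' Writes the two-file TSV representation read by [load_library()].
#'
#' @param lib An `rx_library`.
#' @param reactions_path,synthons_path Output file paths.
#' @return Invisibly, `lib`.
#' @export
save_library <- function(lib, reactions_path, synthons_path) {
  stopifnot(inherits(lib, "rx_library"))
  rtab <- data.frame(
    reaction_id = names(lib$reactions),
    n_components = vapply(lib$reactions, `[[`, integer(1), "n_components"),
    smarts = vapply(lib$reactions, `[[`, character(1), "smarts"))
  utils::write.table(rtab, reactions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  srows <- do.call(rbind, lapply(names(lib$synthons), function(rid) {
    do.call(rbind, lapply(seq_along(lib$synthons[[rid]]), function(ci) {
      data.frame(reaction_id = rid, component_index = ci - 1L,
                 smiles = lib$synthons[[rid]][[ci]])
    }))
  }))
  utils::write.table(srows, synthons_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(lib)
}

#' Enumerate products of a reaction container
#'
#' Takes the cross-product of the per-component fragment lists, runs the
#' reaction on each combination (later components varying fastest), skips
#' failures, deduplicates by canonical SMILES, and stops at `limit` products.
#'
#' @param container List with `reaction` (an [rx_reaction]) and
#'   `sub_containers` (list of character vectors of fragment SMILES, one per
#'   component).
#' @param limit Maximum number of products (default `Inf`).
#' @return List of [rx_mol] products (possibly empty), each carrying a
#'   `provenance` attribute naming its reaction and synthons.
#' @export
enumerate_products <- function(container, limit = Inf) {
  stopifnot(limit >= 1)
  rxn <- container$reaction
  subs <- container$sub_containers
  stopifnot(length(subs) == rxn$n_components)
  if (any(vapply(subs, length, integer(1)) == 0L)) return(list())
  counts <- vapply(subs, length, integer(1))
  idx <- rep(1L, length(counts))
  out <- list()
  seen <- character()
  repeat {
    frags <- vapply(seq_along(idx), function(i) subs[[i]][idx[i]],
                    character(1))
    prod <- run_reaction_cached(rxn, as.list(frags))
    if (!is.null(prod) && !(prod$smiles %in% seen)) {
      seen <- c(seen, prod$smiles)
      out[[length(out) + 1L]] <- prod
      if (length(out) >= limit) break
    }
    pos <- length(idx)
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= counts[pos]) break
      idx[pos] <- 1L
      pos <- pos - 1L
      if (pos == 0L) break
    }
    if (pos == 0L) break
  }
  out
}

#' Draw random products from a library
#'
#' The random-baseline construction: reactions are drawn uniformly with
#' replacement; within each reaction component, synthons are drawn without
#' replacement across that reaction's repeated uses until the component pool
#' is exhausted, at which point it is replenished (with a message). Failed
#' reaction applications are redrawn.
#'
#' @param lib An `rx_library`.
#' @param n Number of products wanted (>= 0).
#' @param max_tries Bound on total draw attempts (default `50 * n`).
#' @return List of `n` [rx_mol] products with provenance attributes.
#' @export
random_products <- function(lib, n, max_tries = 50L * n) {
  stopifnot(inherits(lib, "rx_library"), n >= 0L)
  if (n == 0L) return(list())
  rids <- names(lib$reactions)
  pools <- lapply(lib$synthons, function(comps) lapply(comps, sample))
  out <- list()
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("library too small: could not draw ", n, " random products in ",
           max_tries, " attempts", call. = FALSE)
    }
    rid <- rids[sample.int(length(rids), 1L)]
    rxn <- lib$reactions[[rid]]
    frags <- character(rxn$n_components)
    for (ci in seq_len(rxn$n_components)) {
      if (!length(pools[[rid]][[ci]])) {
        message("replenishing exhausted component ", ci, " of reaction ", rid)
        pools[[rid]][[ci]] <- sample(lib$synthons[[rid]][[ci]])
      }
      frags[ci] <- pools[[rid]][[ci]][1L]
      pools[[rid]][[ci]] <- pools[[rid]][[ci]][-1L]
    }
    prod <- run_reaction_cached(rxn, as.list(frags))
    if (!is.null(prod)) out[[length(out) + 1L]] <- prod
  }
  out
}

# ---- synthetic fixture library ---------------------------------------------

# substituent pool for fixture synthons: each entry is a SMILES prefix whose
# final atom carries the attachment point when concatenated with a suffix
.fixture_r_groups <- function() {
  chains <- c("C", "CC", "CCC", "CCCC", "CC(C)", "CC(C)C", "CCCCC",
              "C(C)(C)C", "CCC(C)", "CCOC", "CCCOC", "CC(F)(F)")
  rings <- c("C1CCC1", "C1CCCC1", "C1CCCCC1", "c1ccccc1", "c1ccncc1",
             "c1ccsc1", "c1ccoc1", "Cc1ccccc1", "CCc1ccccc1", "COc1ccccc1",
             "Fc1ccccc1", "Clc1ccccc1", "Cc1ccncc1", "CC1CCCCC1",
             "c1cccnc1", "CSc1ccccc1")
  # only ring-first groups can safely take a chain prefix
  ring_first <- c("C1CCC1", "C1CCCC1", "C1CCCCC1", "c1ccccc1", "c1ccncc1",
                  "c1ccsc1", "c1ccoc1", "c1cccnc1")
  linked <- as.vector(outer(c("C", "CC", "CCO"), ring_first, paste0))
  unique(c(chains, rings, linked))
}

#' Generate a deterministic synthetic fixture library
#'
#' Builds a desk-scale stand-in for a make-on-demand combinatorial library:
#' simple, chemically valid reactions (amide coupling, sulfonamide formation,
#' Williamson ether synthesis, and -- for three or more reactions -- a
#' three-component double acylation) with randomised but valid substituent
#' sets. Deterministic for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param n_reactions Number of reactions (1--4; >= 3 includes a
#'   three-component reaction). Default 3.
#' @param synthons_per_component Synthons per reaction component (default 12,
#'   giving on the order of 10^2 products per two-component reaction).
#' @param seed Integer seed.
#' @return An `rx_library`.
#' @export
make_fixture_library <- function(n_reactions = 3L, synthons_per_component = 12L,
                                 seed = 1L) {
  stopifnot(n_reactions >= 1L, n_reactions <= 4L,
            synthons_per_component >= 1L)
  defs <- list(
    list(id = "amide",
         smarts = "[C:1](=[O:2])[OX2H1].[NX3;H2,H1:3]>>[C:1](=[O:2])[N:3]",
         suffixes = list("C(=O)O", "N")),
    list(id = "sulfonamide",
         smarts = "[S:1](=[O:2])(=[O:3])Cl.[NX3;H2,H1:4]>>[S:1](=[O:2])(=[O:3])[N:4]",
         suffixes = list("S(=O)(=O)Cl", "N")),
    list(id = "diacylamine",
         smarts = "[C:1](=[O:2])[OX2H1].[NX3;H2:3].[C:4](=[O:5])[OX2H1]>>[C:1](=[O:2])[N:3][C:4]=[O:5]",
         suffixes = list("C(=O)O", "N", "C(=O)O")),
    list(id = "ether",
         smarts = "[CX4:1][Br].[OX2H1:2][CX4,c:3]>>[C:1][O:2][*:3]",
         suffixes = list("Br", "O")))
  # a 3-component reaction must be present once n_reactions >= 3
  pick <- if (n_reactions >= 3L) c(1L, 2L, 3L, 4L)[seq_len(n_reactions)]
          else seq_len(n_reactions)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  pool <- .fixture_r_groups()
  reactions <- list()
  synthons <- list()
  for (d in defs[pick]) {
    rxn <- rx_reaction(d$id, d$smarts)
    comps <- lapply(seq_along(d$suffixes), function(ci) {
      rg <- sample(pool)
      keep <- character()
      for (cand in paste0(rg, d$suffixes[[ci]])) {
        can <- canonical_smiles(cand)
        if (is.na(can)) next
        g <- mol_graph_smiles(can)
        if (is.null(g) || !graph_valence_ok(g) ||
            !length(match_smarts(rxn$reactants[[ci]], g, 1L))) next
        keep <- c(keep, cand)
        if (length(keep) >= synthons_per_component) break
      }
      keep
    })
    reactions[[length(reactions) + 1L]] <- rxn
    synthons[[d$id]] <- comps
  }
  suppressWarnings(combinatorial_library(reactions, synthons))
}
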
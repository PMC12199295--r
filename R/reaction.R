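# Reaction SMARTS transformations.
#
# A reaction is written as reactant templates separated by '.', then '>>',
# then a single product template, with atom maps (:n) tying product atoms to
# reactant atoms -- the convention used by combinatorial make-on-demand
# libraries. Application semantics:
#   * each reactant template is matched (monomorphism) into its fragment;
#   * matched atoms whose map number appears in the product survive;
#   * matched atoms absent from the product template (leaving groups) are
#     deleted;
#   * bonds between matched atoms that the reactant templates declare are
#     removed, then the product template's bonds are installed (a template
#     bond with no explicit order keeps the pre-existing order, else single);
#   * unmapped product-template atoms are created fresh;
#   * implicit hydrogens are recomputed from standard valences, the edited
#     graph is sanitised (valence check + canonicalisation round trip).
# Application fails softly (NULL) when no match combination yields a valid
# single-component product.

# split at top level (depth 0 wrt both () and []) on a single character
.split_top <- function(s, sep) {
  depth <- 0L
  out <- character()
  cur <- character()
  for (ch in strsplit(s, "", fixed = TRUE)[[1]]) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == sep && depth == 0L) {
      out <- c(out, paste(cur, collapse = ""))
      cur <- character()
    } else cur <- c(cur, ch)
  }
  c(out, paste(cur, collapse = ""))
}

#' Define a reaction from reaction SMARTS
#'
#' @param reaction_id Identifier string.
#' @param smarts Reaction SMARTS `reactant1.reactant2...>>product` with atom
#'   maps. Any number of components (>= 1) is supported.
#' @return An object of class `rx_reaction` with fields `reaction_id`,
#'   `smarts`, `n_components`, and parsed templates.
#' @examples
#' amide <- rx_reaction("amide",
#'   "[C:1](=[O:2])[OX2H1].[NX3;H2,H1:3]>>[C:1](=[O:2])[N:3]")
#' amide$n_components
#' @export
rx_reaction <- function(reaction_id, smarts) {
  sides <- strsplit(smarts, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("reaction '", reaction_id, "': SMARTS must contain exactly one '>>': ",
         smarts, call. = FALSE)
  }
  r_parts <- .split_top(sides[1], ".")
  p_parts <- .split_top(sides[2], ".")
  if (length(p_parts) != 1L) {
    stop("reaction '", reaction_id,
         "': exactly one product template is supported", call. = FALSE)
  }
  reactants <- lapply(r_parts, function(p) {
    tryCatch(parse_smarts(p), error = function(e)
      stop("reaction '", reaction_id, "': bad reactant SMARTS '", p, "': ",
           conditionMessage(e), call. = FALSE))
  })
  product <- tryCatch(parse_smarts(p_parts), error = function(e)
    stop("reaction '", reaction_id, "': bad product SMARTS '", p_parts, "': ",
         conditionMessage(e), call. = FALSE))
  rmaps <- unlist(lapply(reactants, function(t) t$maps))
  rmaps <- rmaps[!is.na(rmaps)]
  if (anyDuplicated(rmaps)) {
    stop("reaction '", reaction_id, "': duplicate atom map numbers",
         call. = FALSE)
  }
  pmaps <- product$maps[!is.na(product$maps)]
  if (!all(pmaps %in% rmaps)) {
    stop("reaction '", reaction_id,
         "': product maps atoms absent from reactants", call. = FALSE)
  }
  structure(list(reaction_id = reaction_id, smarts = smarts,
                 n_components = length(reactants),
                 reactants = reactants, product = product),
            class = "rx_reaction")
}

#' @export
print.rx_reaction <- function(x, ...) {
  cat("<rx_reaction> ", x$reaction_id, " (", x$n_components,
      " components)\n  ", x$smarts, "\n", sep = "")
  invisible(x)
}

# element (and charge) demanded by a product-template atom expression
.expr_new_atom <- function(expr) {
  elem <- NA_character_; arom <- FALSE; charge <- 0L
  for (group in expr) {
    for (alt in group[1]) {
      for (prim in alt) {
        if (prim$neg) next
        if (prim$kind == "elem") elem <- prim$val
        if (prim$kind == "aelem") { elem <- prim$val; arom <- TRUE }
        if (prim$kind == "z") elem <- names(.ELEM_Z)[match(prim$val, .ELEM_Z)]
        if (prim$kind == "charge") charge <- prim$val
      }
    }
  }
  if (is.na(elem)) {
    stop("product template atom without a definite element", call. = FALSE)
  }
  list(elem = elem, arom = arom, charge = charge)
}

.expr_charge <- function(expr) {
  for (group in expr) for (alt in group[1]) for (prim in alt) {
    if (!prim$neg && prim$kind == "charge") return(prim$val)
  }
  NA_integer_
}

# apply one concrete match combination; returns canonical SMILES or NULL
.apply_reaction_once <- function(rxn, frag_graphs, combo_matches) {
  atoms <- do.call(rbind, lapply(frag_graphs, function(g)
    g$atoms[, c("elem", "charge")]))
  rownames(atoms) <- NULL
  offs <- cumsum(c(0L, vapply(frag_graphs, function(g) nrow(g$atoms),
                              integer(1))))
  bonds <- do.call(rbind, lapply(seq_along(frag_graphs), function(i) {
    b <- frag_graphs[[i]]$bonds[, c("a1", "a2", "order"), drop = FALSE]
    b$a1 <- b$a1 + offs[i]; b$a2 <- b$a2 + offs[i]
    b
  }))
  rownames(bonds) <- NULL

  gmap <- integer()                    # map number -> global atom index
  matched_global <- vector("list", length(frag_graphs))
  for (i in seq_along(frag_graphs)) {
    m <- combo_matches[[i]] + offs[i]
    matched_global[[i]] <- m
    tmpl <- rxn$reactants[[i]]
    for (p in seq_along(tmpl$maps)) {
      if (!is.na(tmpl$maps[p])) gmap[as.character(tmpl$maps[p])] <- m[p]
    }
  }

  bond_key <- function(i, j) paste(min(i, j), max(i, j))
  bkeys <- if (nrow(bonds)) mapply(bond_key, bonds$a1, bonds$a2)
           else character()

  # remove reactant-template bonds between matched atoms
  drop_keys <- character()
  for (i in seq_along(frag_graphs)) {
    tmpl <- rxn$reactants[[i]]
    m <- matched_global[[i]]
    if (nrow(tmpl$bonds)) {
      for (k in seq_len(nrow(tmpl$bonds))) {
        drop_keys <- c(drop_keys, bond_key(m[tmpl$bonds$a1[k]],
                                           m[tmpl$bonds$a2[k]]))
      }
    }
  }
  removed_order <- bonds$order[bkeys %in% drop_keys]
  names(removed_order) <- bkeys[bkeys %in% drop_keys]
  bonds <- bonds[!(bkeys %in% drop_keys), , drop = FALSE]

  # product atoms: mapped survive (charge possibly reset), unmapped created
  prod <- rxn$product
  prod_global <- integer(length(prod$atoms))
  for (p in seq_along(prod$atoms)) {
    mp <- prod$maps[p]
    if (!is.na(mp)) {
      gi <- gmap[[as.character(mp)]]
      prod_global[p] <- gi
      ch <- .expr_charge(prod$atoms[[p]])
      if (!is.na(ch)) atoms$charge[gi] <- ch
    } else {
      spec <- .expr_new_atom(prod$atoms[[p]])
      atoms <- rbind(atoms, data.frame(elem = spec$elem,
                                       charge = spec$charge))
      prod_global[p] <- nrow(atoms)
    }
  }

  # install product-template bonds
  if (nrow(prod$bonds)) {
    for (k in seq_len(nrow(prod$bonds))) {
      ga <- prod_global[prod$bonds$a1[k]]
      gb <- prod_global[prod$bonds$a2[k]]
      sym <- prod$bonds$sym[k]
      ord <- switch(sym,
        "-" = 1L, "=" = 2L, "#" = 3L,
        "default" = {
          prev <- removed_order[bond_key(ga, gb)]
          if (!is.na(prev)) unname(prev) else 1L
        },
        stop("unsupported product bond type '", sym, "'", call. = FALSE))
      # replace any existing bond between the pair
      if (nrow(bonds)) {
        bk <- mapply(bond_key, bonds$a1, bonds$a2)
        bonds <- bonds[!(bk %in% bond_key(ga, gb)), , drop = FALSE]
      }
      bonds <- rbind(bonds, data.frame(a1 = ga, a2 = gb, order = ord))
    }
  }

  # delete matched-but-unmapped atoms (leaving groups)
  survivors_by_map <- prod_global[!is.na(prod$maps)]
  deleted <- integer()
  for (i in seq_along(frag_graphs)) {
    m <- matched_global[[i]]
    tmpl <- rxn$reactants[[i]]
    gone <- m[is.na(tmpl$maps) | !(m %in% survivors_by_map)]
    deleted <- c(deleted, gone)
  }
  deleted <- setdiff(unique(deleted), prod_global)
  keep <- setdiff(seq_len(nrow(atoms)), deleted)
  remap <- match(seq_len(nrow(atoms)), keep)
  bonds <- bonds[!(bonds$a1 %in% deleted | bonds$a2 %in% deleted), ,
                 drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- rownames(bonds) <- NULL
  prod_global <- remap[prod_global]

  if (!nrow(atoms)) return(NULL)
  g <- finish_graph(atoms, bonds)
  comp <- graph_components(g)
  pc <- unique(comp[prod_global])
  if (length(pc) != 1L) return(NULL)    # product atoms not connected
  if (any(comp != pc)) {
    keep <- which(comp == pc)
    remap <- match(seq_len(nrow(g$atoms)), keep)
    b <- g$bonds[g$bonds$a1 %in% keep & g$bonds$a2 %in% keep,
                 c("a1", "a2", "order"), drop = FALSE]
    b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
    a <- g$atoms[keep, c("elem", "charge"), drop = FALSE]
    rownames(a) <- rownames(b) <- NULL
    g <- finish_graph(a, b)
  }
  if (!graph_valence_ok(g)) return(NULL)
  smi <- molblock_to_smiles(write_molblock(g))
  if (is.na(smi) || grepl(".", smi, fixed = TRUE)) return(NULL)
  smi
}

#' Run a reaction on one fragment per component
#'
#' Matches each reactant template into its fragment, applies the
#' transformation, and returns the first sanitised product under a
#' deterministic enumeration order of match combinations (matches of later
#' components vary fastest). Failure to produce a valid product is signalled
#' by returning `NULL`, not an error.
#'
#' @param rxn An [rx_reaction].
#' @param fragments List (or character vector) of fragments, one per
#'   component, as [rx_mol] or SMILES.
#' @param max_matches Match combinations explored per component (default 5).
#' @return An [rx_mol] product, or `NULL` if no valid product forms.
#' @examples
#' amide <- rx_reaction("amide",
#'   "[C:1](=[O:2])[OX2H1].[NX3;H2,H1:3]>>[C:1](=[O:2])[N:3]")
#' run_reaction(amide, c("CC(=O)O", "CN"))$smiles   # N-methylacetamide
#' @export
run_reaction <- function(rxn, fragments, max_matches = 5L) {
  stopifnot(inherits(rxn, "rx_reaction"))
  fragments <- as.list(fragments)
  if (length(fragments) != rxn$n_components) {
    stop("reaction '", rxn$reaction_id, "' needs ", rxn$n_components,
         " fragments, got ", length(fragments), call. = FALSE)
  }
  mols <- lapply(fragments, rx_mol)
  graphs <- lapply(mols, mol_graph)
  match_sets <- lapply(seq_along(graphs), function(i)
    match_smarts(rxn$reactants[[i]], graphs[[i]], max_matches = max_matches))
  if (any(vapply(match_sets, length, integer(1)) == 0L)) return(NULL)
  # deterministic order: later components vary fastest
  counts <- vapply(match_sets, length, integer(1))
  idx <- rep(1L, length(counts))
  repeat {
    combo <- lapply(seq_along(idx), function(i) match_sets[[i]][[idx[i]]])
    smi <- .apply_reaction_once(rxn, graphs, combo)
    if (!is.null(smi)) {
      out <- rx_mol(smi)
      attr(out, "provenance") <- list(
        reaction_id = rxn$reaction_id,
        synthons = vapply(mols, function(m) m$smiles, character(1)))
      return(out)
    }
    pos <- length(idx)
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= counts[pos]) break
      idx[pos] <- 1L
      pos <- pos - 1L
      if (pos == 0L) return(NULL)
    }
  }
}

# memoised product for library fragments (key: reaction id + synthon SMILES)
run_reaction_cached <- function(rxn, fragments) {
  frag_smiles <- vapply(lapply(fragments, rx_mol), `[[`, character(1),
                        "smiles")
  key <- paste(rxn$reaction_id, paste(frag_smiles, collapse = "|"), sep = "::")
  hit <- .cache_get("product", key)
  if (!is.null(hit)) {
    if (identical(hit, FALSE)) return(NULL)
    return(hit)
  }
  prod <- run_reaction(rxn, fragments)
  .cache_set("product", key, if (is.null(prod)) FALSE else prod)
  prod
}
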
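# Molecule representation and per-session caches.

.rx_cache <- new.env(parent = emptyenv())

.cache_get <- function(store, key) {
  env <- .rx_cache[[store]]
  if (is.null(env)) return(NULL)
  env[[key]]
}

.cache_set <- function(store, key, value) {
  env <- .rx_cache[[store]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    assign(store, env, envir = .rx_cache)
  }
  assign(key, value, envir = env)
  value
}

#' Clear the internal molecule/fingerprint/product caches
#'
#' The package memoises canonical SMILES, molecular graphs, fingerprints,
#' computed properties and reaction products for the duration of a session.
#' Caches only store deterministic derived values, so clearing them never
#' changes results; this exists mainly to bound memory in long sessions.
#'
#' @return Invisibly, `NULL`.
#' @export
rx_clear_cache <- function() {
  rm(list = ls(.rx_cache), envir = .rx_cache)
  invisible(NULL)
}

#' Create a molecule from a SMILES string
#'
#' Molecules are stored as canonical SMILES (OpenBabel canonicalisation, so
#' `rx_mol(rx_mol(s)$smiles)` is idempotent) together with the heavy-atom
#' count. Properties are computed lazily by [physchem()].
#'
#' @param smiles A SMILES string (any valid spelling; it is canonicalised).
#' @return An object of class `rx_mol` with fields `smiles` (canonical),
#'   `n_heavy` and `props` (`NULL` until computed).
#' @examples
#' m <- rx_mol("OCC")           # ethanol, any spelling
#' m$smiles                     # canonical form
#' m$n_heavy                    # 3
#' @export
rx_mol <- function(smiles) {
  if (inherits(smiles, "rx_mol")) return(smiles)
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- .cache_get("canon", smiles)
  if (is.null(can)) can <- .cache_set("canon", smiles, ob_canon(smiles))
  if (is.na(can)) {
    stop("invalid molecule: SMILES does not parse: ", smiles,
         call. = FALSE)
  }
  g <- mol_graph_smiles(can)
  if (is.null(g) || nrow(g$atoms) < 1L) {
    stop("invalid molecule: SMILES does not parse: ", smiles, call. = FALSE)
  }
  structure(list(smiles = can, n_heavy = nrow(g$atoms), props = NULL),
            class = "rx_mol")
}

#' @export
print.rx_mol <- function(x, ...) {
  cat("<rx_mol> ", x$smiles, "  (", x$n_heavy, " heavy atoms)\n", sep = "")
  if (!is.null(x$props)) {
    cat("  ", paste(names(x$props), signif(unlist(x$props), 4),
                    sep = "=", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

# cached annotated graph for a canonical SMILES
mol_graph_smiles <- function(can_smiles) {
  g <- .cache_get("graph", can_smiles)
  if (is.null(g)) {
    g <- smiles_to_graph(can_smiles)
    if (!is.null(g)) .cache_set("graph", can_smiles, g)
  }
  g
}

mol_graph <- function(mol) {
  mol <- rx_mol(mol)
  mol_graph_smiles(mol$smiles)
}

#' Canonicalise a SMILES string
#'
#' @param smiles SMILES string.
#' @return The canonical SMILES, or `NA` if the input does not parse.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    can <- .cache_get("canon", s)
    if (is.null(can)) can <- .cache_set("canon", s, ob_canon(s))
    can
  }, character(1), USE.NAMES = FALSE)
}
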
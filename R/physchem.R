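# Scaffolds and physicochemical properties.

#' Bemis-Murcko scaffold of a molecule
#'
#' The ring systems plus the linkers connecting them, with side chains
#' removed; atoms double-bonded directly to the framework (e.g. carbonyl
#' oxygens in a linker) are retained. Acyclic molecules map to the empty
#' scaffold `""` and thus share one scaffold class.
#'
#' @param mol An [rx_mol] or SMILES string.
#' @return Canonical scaffold SMILES (`""` for acyclic molecules).
#' @examples
#' murcko_scaffold("Cc1ccccc1")    # toluene -> benzene
#' murcko_scaffold("CCCCCC")       # acyclic -> ""
#' @export
murcko_scaffold <- function(mol) {
  mol <- rx_mol(mol)
  hit <- .cache_get("scaffold", mol$smiles)
  if (!is.null(hit)) return(hit)
  g <- mol_graph(mol)
  if (!length(g$rings)) return(.cache_set("scaffold", mol$smiles, ""))
  # iteratively strip terminal atoms: what remains is rings + linkers
  keep <- rep(TRUE, nrow(g$atoms))
  bonds <- g$bonds
  repeat {
    deg <- integer(nrow(g$atoms))
    live <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
    if (nrow(live)) {
      tb <- table(c(live$a1, live$a2))
      deg[as.integer(names(tb))] <- as.integer(tb)
    }
    term <- which(keep & deg <= 1L & !g$atoms$in_ring)
    if (!length(term)) break
    keep[term] <- FALSE
  }
  core <- which(keep)
  # re-attach atoms double-bonded directly to the framework
  extra <- unique(unlist(lapply(seq_len(nrow(bonds)), function(k) {
    if (bonds$order[k] < 2L) return(integer())
    a <- bonds$a1[k]; b <- bonds$a2[k]
    if (keep[a] && !keep[b]) return(b)
    if (keep[b] && !keep[a]) return(a)
    integer()
  })))
  sel <- sort(c(core, extra))
  remap <- match(seq_len(nrow(g$atoms)), sel)
  b <- bonds[bonds$a1 %in% sel & bonds$a2 %in% sel,
             c("a1", "a2", "order"), drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  a <- g$atoms[sel, c("elem", "charge"), drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  sg <- finish_graph(a, b)
  smi <- molblock_to_smiles(write_molblock(sg))
  if (is.na(smi)) smi <- ""
  .cache_set("scaffold", mol$smiles, smi)
}

#' Scaffold diversity of a set of molecules
#'
#' @param mols List/vector of molecules ([rx_mol] or SMILES), non-empty.
#' @return Percentage of unique Bemis-Murcko scaffolds:
#'   `100 * n_distinct_scaffolds / n_molecules`.
#' @export
scaffold_diversity <- function(mols) {
  mols <- as.list(mols)
  if (!length(mols)) stop("empty molecule set", call. = FALSE)
  scaff <- vapply(mols, murcko_scaffold, character(1))
  100 * length(unique(scaff)) / length(mols)
}

# rotatable bonds: acyclic single bonds between non-terminal heavy atoms,
# excluding bonds adjacent to a triple bond
.n_rotatable <- function(g) {
  if (!nrow(g$bonds)) return(0L)
  deg <- integer(nrow(g$atoms))
  tb <- table(c(g$bonds$a1, g$bonds$a2))
  deg[as.integer(names(tb))] <- as.integer(tb)
  triple <- unique(c(g$bonds$a1[g$bonds$order == 3L],
                     g$bonds$a2[g$bonds$order == 3L]))
  sum(g$bonds$order == 1L & !g$bonds$in_ring &
        deg[g$bonds$a1] > 1L & deg[g$bonds$a2] > 1L &
        !(g$bonds$a1 %in% triple) & !(g$bonds$a2 %in% triple))
}

#' Synthetic-accessibility estimate
#'
#' A monotone complexity score on the 1 (easy) to 10 (hard) scale, built
#' from structural-complexity terms (molecule size, ring fusion, quaternary
#' centres, heteroatom load, formal charges). It is this package's own
#' estimator honouring the provider contract -- it tracks the usual
#' fragment-based synthetic-accessibility scores in trend, not in value.
#'
#' @param mol An [rx_mol] or SMILES string.
#' @return Score in `[1, 10]`.
#' @export
sa_score <- function(mol) {
  g <- mol_graph(rx_mol(mol))
  n <- nrow(g$atoms)
  deg <- integer(n)
  if (nrow(g$bonds)) {
    tb <- table(c(g$bonds$a1, g$bonds$a2))
    deg[as.integer(names(tb))] <- as.integer(tb)
  }
  size_pen <- max(0, n - 20) * 0.08
  # bonds shared by two or more small rings indicate fused systems
  fused <- 0L
  if (length(g$rings) > 1L && nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      inr <- sum(vapply(g$rings, function(r)
        g$bonds$a1[k] %in% r && g$bonds$a2[k] %in% r, logical(1)))
      if (inr >= 2L) fused <- fused + 1L
    }
  }
  ring_pen <- 0.3 * fused + 0.2 * max(0L, length(g$rings) - 2L)
  quat_pen <- 0.4 * sum(deg >= 4L)
  frac_het <- mean(g$atoms$elem != "C")
  het_pen <- max(0, frac_het - 0.3) * 3
  chg_pen <- 0.2 * sum(g$atoms$charge != 0L)
  min(10, max(1, 1 + size_pen + ring_pen + quat_pen + het_pen + chg_pen))
}

#' Physicochemical properties of a molecule
#'
#' Fills the property map: molecular weight (Da), hydrogen-bond acceptor and
#' donor counts, log P (Crippen-type atom contributions via OpenBabel),
#' rotatable-bond count, and a synthetic-accessibility estimate. The log P
#' and synthetic-accessibility providers can be overridden.
#'
#' @param mol An [rx_mol] or SMILES string.
#' @param logp_fn,sascore_fn Optional provider overrides: functions taking an
#'   `rx_mol` and returning a number.
#' @return The `rx_mol` with `props` filled (`mol_weight`, `hba`, `hbd`,
#'   `logp`, `n_rotatable`, `sascore`).
#' @export
physchem <- function(mol, logp_fn = NULL, sascore_fn = NULL) {
  mol <- rx_mol(mol)
  default <- is.null(logp_fn) && is.null(sascore_fn)
  if (default) {
    hit <- .cache_get("props", mol$smiles)
    if (!is.null(hit)) { mol$props <- hit; return(mol) }
  }
  ob <- ChemmineOB::forEachMol("SMILES", mol$smiles, function(m)
    ChemmineOB::prop_OB(list(m)))[[1]]
  g <- mol_graph(mol)
  props <- list(
    mol_weight = ob$MW,
    hba = as.integer(ob$HBA1),
    hbd = as.integer(ob$HBD),
    logp = if (is.null(logp_fn)) ob$logP else logp_fn(mol),
    n_rotatable = .n_rotatable(g),
    sascore = if (is.null(sascore_fn)) sa_score(mol) else sascore_fn(mol))
  if (default) .cache_set("props", mol$smiles, props)
  mol$props <- props
  mol
}

#' Property table for a set of molecules
#'
#' @param mols List/vector of molecules.
#' @param mol_id Optional identifiers (default `mol_1`, `mol_2`, ...).
#' @return Data frame with columns `mol_id`, `smiles`, `mol_weight`, `hba`,
#'   `hbd`, `logp`, `n_rotatable`, `sascore`.
#' @export
property_table <- function(mols, mol_id = NULL) {
  mols <- lapply(as.list(mols), physchem)
  if (is.null(mol_id)) mol_id <- paste0("mol_", seq_along(mols))
  data.frame(
    mol_id = mol_id,
    smiles = vapply(mols, `[[`, character(1), "smiles"),
    mol_weight = vapply(mols, function(m) m$props$mol_weight, numeric(1)),
    hba = vapply(mols, function(m) m$props$hba, integer(1)),
    hbd = vapply(mols, function(m) m$props$hbd, integer(1)),
    logp = vapply(mols, function(m) m$props$logp, numeric(1)),
    n_rotatable = vapply(mols, function(m) m$props$n_rotatable, integer(1)),
    sascore = vapply(mols, function(m) m$props$sascore, numeric(1)),
    stringsAsFactors = FALSE)
}
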
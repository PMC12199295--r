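# Internal molecular-graph layer.
#
# Molecules cross the OpenBabel boundary (via ChemmineOB) as SMILES strings or
# V2000 molblocks. Everything graph-topological in the hot path -- SMARTS
# matching, reaction editing, scaffold pruning, common-substructure search --
# works on the lightweight graph representation built here: a list with
#   atoms: data.frame(elem, charge, arom, nH, in_ring, x, y, z)
#   bonds: data.frame(a1, a2, order, arom, in_ring)   (a1 < a2)
#   rings: list of integer vectors (atom indices of small rings, size <= 8)
# Graphs are heavy-atom only; explicit hydrogens from input are folded into nH.
# Bond orders are kekulized (as OpenBabel writes molblocks); aromaticity is
# re-perceived with a per-ring Hueckel rule.

.ELEM_Z <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L,
             P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L)

.ELEM_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
                Br = 79.904, I = 126.904)

# smallest standard valences consistent with a bond-order sum, charge-adjusted
.allowed_valence <- function(elem, charge) {
  base <- switch(elem,
    C = 4L, B = 3L, N = 3L, O = 2L, F = 1L, Cl = 1L, Br = 1L, I = 1L,
    P = c(3L, 5L), S = c(2L, 4L, 6L), Si = 4L, H = 1L, 0L)
  if (elem %in% c("N", "P", "O", "S")) base + charge
  else if (charge != 0) pmax(base - abs(charge), 0L)
  else base
}

ob_canon <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(out)) return(NA_character_)
  out
}

ob_molblock <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) "")
  if (!nzchar(trimws(out))) return(NA_character_)
  out
}

molblock_to_smiles <- function(molblock) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", molblock)),
    error = function(e) "")
  out <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(out)) return(NA_character_)
  out
}

# -- V2000 codec --------------------------------------------------------------

parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) return(NULL)
  atom_lines <- lines[seq_len(na) + 4]
  atoms <- data.frame(
    elem = trimws(substr(atom_lines, 32, 34)),
    charge = 0L,
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    stringsAsFactors = FALSE)
  # old-style charge column (codes 1..7), superseded by M CHG when present
  ccode <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  ccode[is.na(ccode)] <- 0L
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  hit <- ccode %in% as.integer(names(code_map))
  atoms$charge[hit] <- code_map[as.character(ccode[hit])]
  if (nb > 0) {
    bond_lines <- lines[seq_len(nb) + 4 + na]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)))
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    atoms$charge[] <- 0L
    for (ln in chg) {
      flds <- scan(text = substr(ln, 7, nchar(ln)), what = integer(),
                   quiet = TRUE)
      n <- flds[1]
      for (k in seq_len(n)) {
        atoms$charge[flds[2 * k]] <- flds[2 * k + 1]
      }
    }
  }
  list(atoms = atoms, bonds = bonds)
}

write_molblock <- function(g, title = "") {
  atoms <- g$atoms
  bonds <- g$bonds
  na <- nrow(atoms); nb <- nrow(bonds)
  x <- if (!is.null(atoms$x)) atoms$x else rep(0, na)
  y <- if (!is.null(atoms$y)) atoms$y else rep(0, na)
  z <- if (!is.null(atoms$z)) atoms$z else rep(0, na)
  x[is.na(x)] <- 0; y[is.na(y)] <- 0; z[is.na(z)] <- 0
  header <- c(title, "  rxnmc", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        x, y, z, atoms$elem)
  bond_lines <- if (nb > 0)
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  else character()
  chg_idx <- which(atoms$charge != 0L)
  chg_lines <- if (length(chg_idx)) {
    vapply(split(chg_idx, ceiling(seq_along(chg_idx) / 8)), function(ii) {
      paste0(sprintf("M  CHG%3d", length(ii)),
             paste0(sprintf("%4d%4d", ii, atoms$charge[ii]), collapse = ""))
    }, character(1))
  } else character()
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

# -- graph construction -------------------------------------------------------

.adjacency <- function(natoms, bonds) {
  adj <- vector("list", natoms)
  for (i in seq_len(natoms)) adj[[i]] <- integer()
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
      adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
    }
  }
  adj
}

# smallest ring through each bond (BFS with the bond removed), size <= max_size
.find_rings <- function(atoms, bonds, max_size = 8L) {
  n <- nrow(atoms)
  rings <- list()
  seen <- character()
  if (!nrow(bonds)) return(rings)
  adj <- .adjacency(n, bonds)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    # BFS from a to b avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[a] <- 0L
    queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (dist[v] >= max_size - 1L) next
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          if (w == b) { queue <- integer(); break }
          queue <- c(queue, w)
        }
      }
      if (!is.na(dist[b])) break
    }
    if (is.na(dist[b])) next
    path <- b
    while (path[1] != a) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# simplified per-ring Hueckel perception on kekulized 5/6-rings
.perceive_aromaticity <- function(atoms, bonds, rings) {
  n <- nrow(atoms)
  arom_atom <- rep(FALSE, n)
  arom_bond <- rep(FALSE, nrow(bonds))
  if (!length(rings)) return(list(atom = arom_atom, bond = arom_bond))
  bkey <- paste(bonds$a1, bonds$a2)
  bond_idx <- function(i, j) match(paste(min(i, j), max(i, j)), bkey)
  for (ring in rings) {
    sz <- length(ring)
    if (sz < 5L || sz > 6L) next
    if (!all(atoms$elem[ring] %in% c("C", "N", "O", "S"))) next
    pi_e <- 0L
    ok <- TRUE
    for (v in ring) {
      inc <- which(bonds$a1 == v | bonds$a2 == v)
      dbl_in_ring <- any(bonds$order[inc] == 2L &
        ifelse(bonds$a1[inc] == v, bonds$a2[inc], bonds$a1[inc]) %in% ring)
      dbl_exo <- any(bonds$order[inc] >= 2L &
        !(ifelse(bonds$a1[inc] == v, bonds$a2[inc], bonds$a1[inc]) %in% ring))
      if (dbl_in_ring) {
        pi_e <- pi_e + 1L
      } else if (dbl_exo) {
        pi_e <- pi_e + 0L           # sp2, empty/withdrawn p orbital
      } else if (atoms$elem[v] %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L           # lone pair donated
      } else if (atoms$elem[v] == "C" && atoms$charge[v] < 0L) {
        pi_e <- pi_e + 2L
      } else {
        ok <- FALSE                  # saturated carbon breaks conjugation
        break
      }
    }
    if (ok && pi_e == 6L) {
      arom_atom[ring] <- TRUE
      for (i in seq_len(sz)) {
        j <- if (i == sz) 1L else i + 1L
        bi <- bond_idx(ring[i], ring[j])
        if (!is.na(bi)) arom_bond[bi] <- TRUE
      }
    }
  }
  list(atom = arom_atom, bond = arom_bond)
}

.implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- rep(0L, n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
    }
  }
  nh <- integer(n)
  for (i in seq_len(n)) {
    av <- .allowed_valence(atoms$elem[i], atoms$charge[i])
    fit <- av[av >= bsum[i]]
    nh[i] <- if (length(fit)) min(fit) - bsum[i] else 0L
  }
  nh
}

# bond-order sum per atom (kekulized orders)
.bond_order_sum <- function(atoms, bonds) {
  bsum <- rep(0L, nrow(atoms))
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
    }
  }
  bsum
}

# assemble the annotated graph from raw atoms/bonds (heavy atoms only)
finish_graph <- function(atoms, bonds) {
  if (nrow(bonds)) {
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  rings <- .find_rings(atoms, bonds)
  arom <- .perceive_aromaticity(atoms, bonds, rings)
  atoms$arom <- arom$atom
  bonds$arom <- if (nrow(bonds)) arom$bond else logical()
  in_ring <- rep(FALSE, nrow(atoms))
  for (r in rings) in_ring[r] <- TRUE
  atoms$in_ring <- in_ring
  if (nrow(bonds)) {
    bonds$in_ring <- vapply(seq_len(nrow(bonds)), function(k) {
      any(vapply(rings, function(r)
        bonds$a1[k] %in% r && bonds$a2[k] %in% r, logical(1)))
    }, logical(1))
  } else bonds$in_ring <- logical()
  atoms$nH <- .implicit_h(atoms, bonds)
  list(atoms = atoms, bonds = bonds, rings = rings)
}

# drop explicit hydrogens, folding them into the heavy neighbour's nH later
.strip_hydrogens <- function(atoms, bonds) {
  hyd <- which(atoms$elem == "H")
  if (!length(hyd)) return(list(atoms = atoms, bonds = bonds))
  keep <- setdiff(seq_len(nrow(atoms)), hyd)
  remap <- match(seq_len(nrow(atoms)), keep)
  bonds <- bonds[!(bonds$a1 %in% hyd | bonds$a2 %in% hyd), , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds)
}

# SMILES -> annotated heavy-atom graph (NULL if unparseable)
smiles_to_graph <- function(smiles) {
  mb <- ob_molblock(smiles)
  if (is.na(mb)) return(NULL)
  raw <- parse_molblock(mb)
  if (is.null(raw) || nrow(raw$atoms) == 0) return(NULL)
  raw <- .strip_hydrogens(raw$atoms, raw$bonds)
  finish_graph(raw$atoms, raw$bonds)
}

graph_valence_ok <- function(g) {
  bsum <- .bond_order_sum(g$atoms, g$bonds)
  all(vapply(seq_len(nrow(g$atoms)), function(i) {
    av <- .allowed_valence(g$atoms$elem[i], g$atoms$charge[i])
    any(av >= bsum[i])
  }, logical(1)))
}

# connected components of a graph; returns membership vector
graph_components <- function(g) {
  n <- nrow(g$atoms)
  comp <- rep(NA_integer_, n)
  adj <- .adjacency(n, g$bonds)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}
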
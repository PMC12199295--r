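# Ligand pose placement: common-substructure atom mapping, rigid
# superposition, conformer selection, and the pocket-location filter.
# Geometry only -- no force field.

#' Construct a ligand pose
#'
#' @param mol The molecule ([rx_mol] or SMILES).
#' @param coords Numeric matrix (n x 3, Angstrom), one row per atom of
#'   `elements`.
#' @param elements Element symbols, one per row of `coords`. Defaults to the
#'   heavy atoms of `mol` in graph order (coords must then match that order).
#' @return An object of class `rx_pose`.
#' @export
rx_pose <- function(mol, coords, elements = NULL) {
  mol <- rx_mol(mol)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  if (is.null(elements)) {
    g <- mol_graph(mol)
    stopifnot(nrow(coords) == nrow(g$atoms))
    elements <- g$atoms$elem
  }
  stopifnot(length(elements) == nrow(coords))
  structure(list(mol = mol, coords = coords, elements = elements),
            class = "rx_pose")
}

#' @export
print.rx_pose <- function(x, ...) {
  cat("<rx_pose> ", x$mol$smiles, "  (", nrow(x$coords), " atoms placed)\n",
      sep = "")
  invisible(x)
}

# indices of heavy atoms within a pose's coordinate rows
.pose_heavy_idx <- function(pose) which(pose$elements != "H")

#' Binding-pocket definition
#'
#' @param center Numeric length-3 centre (Angstrom).
#' @param radius Allowed radius for the ligand centre of mass (Angstrom,
#'   > 0; 7.5 is a typical choice).
#' @return An object of class `rx_pocket`.
#' @export
rx_pocket <- function(center, radius = 7.5) {
  stopifnot(length(center) == 3L, is.finite(radius), radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "rx_pocket")
}

# ---- maximum-common-substructure atom mapping -------------------------------

#' Map atoms between two molecules via a common substructure
#'
#' Finds a large connected common substructure (matching element, aromatic
#' flag and compatible bonds) by bounded backtracking and returns the
#' one-to-one atom correspondence. The search is budgeted, so for large
#' molecules the mapping is a maximal common substructure found within the
#' budget rather than a certified maximum; in scope (drug-sized molecules)
#' it is exhaustive. Dissimilar molecules may map 0 or 1 atoms.
#'
#' @param prev,new Molecules ([rx_mol] or SMILES).
#' @param budget Backtracking step budget (default 200000).
#' @return Integer matrix with columns `prev`, `new` (heavy-atom indices in
#'   each molecule's graph order); zero rows if no common substructure.
#' @export
map_atoms <- function(prev, new, budget = 200000L) {
  g1 <- mol_graph(rx_mol(prev))
  g2 <- mol_graph(rx_mol(new))
  n1 <- nrow(g1$atoms); n2 <- nrow(g2$atoms)
  adj1 <- .adjacency(n1, g1$bonds); adj2 <- .adjacency(n2, g2$bonds)
  bk1 <- paste(g1$bonds$a1, g1$bonds$a2); bk2 <- paste(g2$bonds$a1, g2$bonds$a2)
  bond1 <- function(i, j) match(paste(min(i, j), max(i, j)), bk1)
  bond2 <- function(i, j) match(paste(min(i, j), max(i, j)), bk2)
  atom_ok <- function(i, j) {
    g1$atoms$elem[i] == g2$atoms$elem[j] &&
      g1$atoms$arom[i] == g2$atoms$arom[j]
  }
  bond_ok <- function(r1, r2) {
    (g1$bonds$order[r1] == g2$bonds$order[r2]) ||
      (g1$bonds$arom[r1] && g2$bonds$arom[r2])
  }
  best <- matrix(integer(), ncol = 2L)
  steps <- 0L
  map12 <- rep(NA_integer_, n1)
  used2 <- rep(FALSE, n2)
  extend <- function(size) {
    if (steps > budget) return()
    steps <<- steps + 1L
    if (size > nrow(best)) {
      best <<- cbind(which(!is.na(map12)), map12[!is.na(map12)])
    }
    if (size + 0L >= min(n1, n2)) return()   # cannot grow further
    # frontier: unmapped atoms of g1 adjacent to the mapped core (any atom
    # when the core is empty)
    mapped1 <- which(!is.na(map12))
    cand1 <- if (!length(mapped1)) seq_len(n1) else {
      setdiff(unique(unlist(adj1[mapped1])), mapped1)
    }
    for (i in cand1) {
      nb1 <- intersect(adj1[[i]], mapped1)
      cand2 <- if (!length(mapped1)) seq_len(n2) else {
        Reduce(intersect, lapply(nb1, function(p) adj2[[map12[p]]]))
      }
      for (j in cand2) {
        if (used2[j]) next
        if (!atom_ok(i, j)) next
        # all bonds between i and the mapped core must correspond, both ways
        ok <- TRUE
        for (p in nb1) {
          r1 <- bond1(i, p); r2 <- bond2(j, map12[p])
          if (is.na(r2) || !bond_ok(r1, r2)) { ok <- FALSE; break }
        }
        if (ok) {
          mapped2 <- map12[mapped1]
          for (q in intersect(adj2[[j]], mapped2)) {
            p <- mapped1[match(q, mapped2)]
            if (!(p %in% nb1)) { ok <- FALSE; break }  # induced both ways
          }
        }
        if (!ok) next
        map12[i] <<- j
        used2[j] <<- TRUE
        extend(size + 1L)
        map12[i] <<- NA_integer_
        used2[j] <<- FALSE
        if (steps > budget) return()
      }
    }
  }
  extend(0L)
  colnames(best) <- c("prev", "new")
  best
}

# ---- rigid superposition ----------------------------------------------------

# optimal rotation (Kabsch, via SVD) of B onto A; rows are points
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = ca - as.vector(cb %*% t(R)))
}

#' Superpose a mobile pose onto a reference pose over mapped atoms
#'
#' Finds the rigid transform (rotation + translation) minimising the RMSD
#' over the mapped atom pairs and applies it to every atom of the mobile
#' pose. With fewer than 3 mapped pairs the rotation is underdetermined; a
#' translation-only alignment of the mapped centroids is returned with a
#' warning.
#'
#' @param ref_pose,mobile_pose [rx_pose] objects.
#' @param mapping Two-column matrix (`prev` = atom row in `ref_pose`,
#'   `new` = atom row in `mobile_pose`), e.g. from [map_atoms()]. Indices
#'   refer to heavy atoms in graph order.
#' @return List with `pose` (transformed mobile pose) and `rmsd` (Angstrom,
#'   over the mapped pairs).
#' @export
superpose <- function(ref_pose, mobile_pose, mapping) {
  stopifnot(inherits(ref_pose, "rx_pose"), inherits(mobile_pose, "rx_pose"))
  mapping <- as.matrix(mapping)
  if (!nrow(mapping)) stop("empty atom mapping", call. = FALSE)
  href <- .pose_heavy_idx(ref_pose)
  hmob <- .pose_heavy_idx(mobile_pose)
  A <- ref_pose$coords[href[mapping[, 1]], , drop = FALSE]
  B <- mobile_pose$coords[hmob[mapping[, 2]], , drop = FALSE]
  if (nrow(mapping) < 3L) {
    warning("fewer than 3 mapped atoms: translation-only alignment",
            call. = FALSE)
    shift <- colMeans(A) - colMeans(B)
    newc <- sweep(mobile_pose$coords, 2, shift, `+`)
  } else {
    k <- .kabsch(A, B)
    newc <- mobile_pose$coords %*% t(k$R)
    newc <- sweep(newc, 2, k$t, `+`)
  }
  Bt <- newc[hmob[mapping[, 2]], , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
  out <- mobile_pose
  out$coords <- newc
  list(pose = out, rmsd = rmsd)
}

# ---- conformer generation ---------------------------------------------------

# base 3-D geometry (with explicit hydrogens appended) via OpenBabel
.base_geometry <- function(mol) {
  mol <- rx_mol(mol)
  hit <- .cache_get("geom3d", mol$smiles)
  if (!is.null(hit)) return(hit)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(mol$smiles, "m"))
  sdf3 <- ChemmineOB::convertFormat(
    "SDF", "SDF", paste(as(sdf[[1]], "character"), collapse = "\n"),
    options = data.frame(names = "gen3d", args = ""))
  raw <- parse_molblock(sdf3)
  if (is.null(raw)) stop("3-D embedding failed for ", mol$smiles,
                         call. = FALSE)
  pose <- rx_pose(mol, as.matrix(raw$atoms[, c("x", "y", "z")]),
                  raw$atoms$elem)
  .cache_set("geom3d", mol$smiles, pose)
}

# rotate points around the axis through p0 with direction u by angle theta
.rotate_about <- function(coords, p0, u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(sweep(coords, 2, p0) %*% t(R), 2, p0, `+`)
}

#' Generate conformers of a molecule by torsion sampling
#'
#' Starts from a single embedded 3-D geometry and produces `k` conformers by
#' rotating each rotatable bond by a random torsion angle (the first
#' conformer is always the unperturbed base geometry). A lightweight,
#' seeded, pluggable default for the conformer-provider contract.
#'
#' @param mol Molecule ([rx_mol] or SMILES).
#' @param k Number of conformers (default 10).
#' @return List of [rx_pose] objects (hydrogens included).
#' @export
generate_conformers <- function(mol, k = 10L) {
  mol <- rx_mol(mol)
  base <- .base_geometry(mol)
  g <- mol_graph(mol)
  heavy <- .pose_heavy_idx(base)
  if (k <= 1L || !nrow(g$bonds)) return(list(base))
  deg <- integer(nrow(g$atoms))
  tb <- table(c(g$bonds$a1, g$bonds$a2))
  deg[as.integer(names(tb))] <- as.integer(tb)
  rot <- which(g$bonds$order == 1L & !g$bonds$in_ring &
                 deg[g$bonds$a1] > 1L & deg[g$bonds$a2] > 1L)
  out <- list(base)
  if (!length(rot)) return(out)   # rigid molecule: one conformer
  # full-atom adjacency (hydrogens follow their heavy atom)
  n_all <- nrow(base$coords)
  hmap <- integer(0)
  # assign each explicit H to its nearest heavy atom in the base geometry
  hyd <- setdiff(seq_len(n_all), heavy)
  h_owner <- vapply(hyd, function(h) {
    d <- rowSums(sweep(base$coords[heavy, , drop = FALSE], 2,
                       base$coords[h, ])^2)
    which.min(d)
  }, integer(1))
  side_atoms <- function(bond_row) {
    # heavy atoms on the a2 side when the bond is cut
    a1 <- g$bonds$a1[bond_row]; a2 <- g$bonds$a2[bond_row]
    adj <- .adjacency(nrow(g$atoms), g$bonds)
    seen <- rep(FALSE, nrow(g$atoms))
    seen[a1] <- TRUE
    queue <- a2; seen[a2] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen[a1] <- FALSE
    which(seen)
  }
  sides <- lapply(rot, side_atoms)
  for (ci in seq_len(k - 1L)) {
    coords <- base$coords
    for (ri in seq_along(rot)) {
      a1 <- g$bonds$a1[rot[ri]]; a2 <- g$bonds$a2[rot[ri]]
      theta <- stats::runif(1, 0, 2 * pi)
      moving_heavy <- sides[[ri]]
      moving <- c(heavy[moving_heavy], hyd[h_owner %in% moving_heavy])
      p0 <- coords[heavy[a1], ]
      u <- coords[heavy[a2], ] - p0
      coords[moving, ] <- .rotate_about(coords[moving, , drop = FALSE],
                                        p0, u, theta)
    }
    pose <- base
    pose$coords <- coords
    out[[length(out) + 1L]] <- pose
  }
  out
}

#' Select the conformer closest to a previous pose
#'
#' Superposes each of up to `k` conformers onto the previous pose via the
#' atom mapping and returns the transformed pose with the lowest RMSD
#' (ties: first).
#'
#' @param conformers Non-empty list of [rx_pose].
#' @param prev_pose Reference [rx_pose].
#' @param mapping Mapping matrix (`prev` = atom in `prev_pose`'s molecule,
#'   `new` = atom in the conformers' molecule).
#' @param k Maximum conformers considered (default 200).
#' @return List with `pose` (best transformed pose) and `rmsd`.
#' @export
select_pose <- function(conformers, prev_pose, mapping, k = 200L) {
  if (!length(conformers)) stop("empty conformer list", call. = FALSE)
  conformers <- utils::head(conformers, k)
  fits <- lapply(conformers, function(cf) superpose(prev_pose, cf, mapping))
  rmsds <- vapply(fits, `[[`, numeric(1), "rmsd")
  fits[[which.min(rmsds)]]
}

#' Pocket-location filter: is the ligand centre of mass inside the pocket?
#'
#' @param pose An [rx_pose].
#' @param pocket An [rx_pocket].
#' @return `TRUE` iff the mass-weighted centre of mass lies within
#'   `pocket$radius` of the centre (boundary inclusive).
#' @export
com_in_pocket <- function(pose, pocket) {
  stopifnot(inherits(pose, "rx_pose"), inherits(pocket, "rx_pocket"))
  mass <- .ELEM_MASS[pose$elements]
  mass[is.na(mass)] <- 12
  com <- colSums(pose$coords * mass) / sum(mass)
  sqrt(sum((com - pocket$center)^2)) <= pocket$radius
}

# ---- SDF pose I/O -----------------------------------------------------------

#' Write poses to an SDF (V2000) file
#'
#' @param poses List of [rx_pose].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_poses <- function(poses, path) {
  blocks <- vapply(poses, function(p) {
    g <- mol_graph(p$mol)
    heavy <- .pose_heavy_idx(p)
    stopifnot(length(heavy) == nrow(g$atoms))
    bonds <- g$bonds[, c("a1", "a2", "order"), drop = FALSE]
    bonds$a1 <- heavy[bonds$a1]; bonds$a2 <- heavy[bonds$a2]
    hyd <- setdiff(seq_len(nrow(p$coords)), heavy)
    if (length(hyd)) {
      owner <- vapply(hyd, function(h) {
        d <- rowSums(sweep(p$coords[heavy, , drop = FALSE], 2, p$coords[h, ])^2)
        heavy[which.min(d)]
      }, integer(1))
      bonds <- rbind(bonds, data.frame(a1 = owner, a2 = hyd, order = 1L))
    }
    charge <- integer(nrow(p$coords))
    charge[heavy] <- g$atoms$charge
    full <- list(atoms = data.frame(elem = p$elements,
                                    charge = charge,
                                    x = p$coords[, 1], y = p$coords[, 2],
                                    z = p$coords[, 3]),
                 bonds = bonds)
    write_molblock(full, title = p$mol$smiles)
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

#' Read poses from an SDF (V2000) file
#'
#' Molecules are re-derived from the title line (canonical SMILES written by
#' [write_poses()]); coordinates round-trip to 4 decimals.
#'
#' @param path SDF file path.
#' @return List of [rx_pose].
#' @export
read_poses <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n")[[1]]
    while (length(lines) && !nzchar(trimws(lines[1]))) lines <- lines[-1]
    smi <- trimws(lines[1])
    raw <- parse_molblock(paste(lines, collapse = "\n"))
    if (is.null(raw)) stop("malformed SDF block in ", path, call. = FALSE)
    rx_pose(rx_mol(smi), as.matrix(raw$atoms[, c("x", "y", "z")]),
            raw$atoms$elem)
  })
}
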
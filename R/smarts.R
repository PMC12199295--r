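# Restricted SMARTS pattern engine.
#
# No installed R package exposes SMARTS match *atom indices* or reaction
# transformations, so a focused subset of SMARTS is implemented here, enough
# for combinatorial-library reaction templates:
#   atoms:  bare organic-subset symbols (C N O S P F Cl Br I B, aromatic
#           c n o s p), *, and bracket atoms with primitives
#           element / #n / a / A / * / Dn / Xn / Hn / R / R0 / Rn / rn /
#           charge (+, -, +n, -n), negation (!), AND (& and ;), OR (,),
#           and atom maps (:n)
#   bonds:  - = # : ~ and the default single-or-aromatic bond
#   plus branches ( ), ring closures 1-9 / %nn
# Recursive SMARTS ($(...)) and stereo are not supported (hard error).
# Matching is plain subgraph monomorphism by backtracking; molecules and
# templates in scope are small, so no index structures are needed.

.SMARTS_ELEMS <- c("Cl", "Br", "Si", "C", "N", "O", "S", "P", "F", "I", "B")
.SMARTS_AROM <- c("c", "n", "o", "s", "p")

# ---- parsing ----------------------------------------------------------------

.parse_bracket <- function(body) {
  map <- NA_integer_
  mm <- regmatches(body, regexec(":([0-9]+)$", body))[[1]]
  if (length(mm)) {
    map <- as.integer(mm[2])
    body <- sub(":[0-9]+$", "", body)
  }
  if (grepl("$", body, fixed = TRUE)) {
    stop("unsupported SMARTS feature (recursive SMARTS) in [", body, "]",
         call. = FALSE)
  }
  ors <- lapply(strsplit(body, ";", fixed = TRUE)[[1]], function(part) {
    alts <- strsplit(part, ",", fixed = TRUE)[[1]]
    lapply(alts, .parse_prim_seq)
  })
  # structure: list of AND-groups; each group = list of OR-alternatives;
  # each alternative = list of primitives (implicit AND)
  list(groups = ors, map = map)
}

.parse_prim_seq <- function(s) {
  prims <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    neg <- FALSE
    ch <- substr(s, i, i)
    if (ch == "&") { i <- i + 1L; next }
    if (ch == "!") { neg <- TRUE; i <- i + 1L; ch <- substr(s, i, i) }
    two <- substr(s, i, i + 1L)
    take_num <- function(j) {
      k <- j
      while (k <= n && grepl("[0-9]", substr(s, k, k))) k <- k + 1L
      list(num = if (k > j) as.integer(substr(s, j, k - 1L)) else NA_integer_,
           next_i = k)
    }
    if (two %in% c("Cl", "Br", "Si")) {
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "elem", val = two)
      i <- i + 2L
    } else if (ch == "#") {
      tn <- take_num(i + 1L)
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "z", val = tn$num)
      i <- tn$next_i
    } else if (ch == "*") {
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "any", val = NA)
      i <- i + 1L
    } else if (ch == "a") {
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "arom", val = TRUE)
      i <- i + 1L
    } else if (ch == "A") {
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "arom", val = FALSE)
      i <- i + 1L
    } else if (ch %in% c("D", "X", "H", "v")) {
      tn <- take_num(i + 1L)
      num <- if (is.na(tn$num)) 1L else tn$num
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = ch, val = num)
      i <- tn$next_i
    } else if (ch == "R") {
      tn <- take_num(i + 1L)
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "R", val = tn$num)
      i <- tn$next_i
    } else if (ch == "r") {
      tn <- take_num(i + 1L)
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "r", val = tn$num)
      i <- tn$next_i
    } else if (ch %in% c("+", "-")) {
      tn <- take_num(i + 1L)
      num <- if (is.na(tn$num)) 1L else tn$num
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "charge",
                                          val = if (ch == "+") num else -num)
      i <- tn$next_i
    } else if (ch %in% .SMARTS_AROM) {
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "aelem",
                                          val = toupper(ch))
      i <- i + 1L
    } else if (grepl("[A-Z]", ch)) {
      prims[[length(prims) + 1L]] <- list(neg = neg, kind = "elem", val = ch)
      i <- i + 1L
    } else {
      stop("unsupported SMARTS primitive at '", substr(s, i, n), "'",
           call. = FALSE)
    }
  }
  prims
}

# parse one connected SMARTS component into a pattern graph
parse_smarts <- function(s) {
  atoms <- list()
  bonds <- list()
  maps <- integer()
  prev_stack <- integer()
  prev <- NA_integer_
  pending_bond <- NA_character_
  ring_open <- list()
  i <- 1L
  n <- nchar(s)
  add_atom <- function(expr, map) {
    atoms[[length(atoms) + 1L]] <<- expr
    maps[length(atoms)] <<- if (is.na(map)) NA_integer_ else map
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(
        a1 = prev, a2 = idx,
        sym = if (is.na(pending_bond)) "default" else pending_bond)
    }
    prev <<- idx
    pending_bond <<- NA_character_
    idx
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    two <- substr(s, i, i + 1L)
    if (ch == "(") {
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- "-"
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        lab <- substr(s, i + 1L, i + 2L); i <- i + 3L
      } else {
        lab <- ch; i <- i + 1L
      }
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (!is.na(pending_bond)) pending_bond
               else if (!is.na(op$sym)) op$sym else "default"
        bonds[[length(bonds) + 1L]] <- list(a1 = op$atom, a2 = prev, sym = sym)
        ring_open[[lab]] <- NULL
        pending_bond <- NA_character_
      } else {
        ring_open[[lab]] <- list(atom = prev, sym = pending_bond)
        pending_bond <- NA_character_
      }
    } else if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        cj <- substr(s, j, j)
        if (cj == "[") depth <- depth + 1L
        if (cj == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("unbalanced [ in SMARTS: ", s, call. = FALSE)
      body <- substr(s, i + 1L, j - 2L)
      pb <- .parse_bracket(body)
      add_atom(pb$groups, pb$map)
      i <- j
    } else if (two %in% c("Cl", "Br")) {
      add_atom(list(list(list(list(neg = FALSE, kind = "elem", val = two)))),
               NA_integer_)
      i <- i + 2L
    } else if (ch %in% c("C", "N", "O", "S", "P", "F", "I", "B")) {
      add_atom(list(list(list(list(neg = FALSE, kind = "elem", val = ch)))),
               NA_integer_)
      i <- i + 1L
    } else if (ch %in% .SMARTS_AROM) {
      add_atom(list(list(list(list(neg = FALSE, kind = "aelem",
                                   val = toupper(ch))))),
               NA_integer_)
      i <- i + 1L
    } else if (ch == "*") {
      add_atom(list(list(list(list(neg = FALSE, kind = "any", val = NA)))),
               NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("@", ".")) {
      stop("unsupported SMARTS feature '", ch, "' in: ", s, call. = FALSE)
    } else {
      stop("cannot parse SMARTS at '", substr(s, i, n), "'", call. = FALSE)
    }
  }
  if (!length(atoms)) stop("empty SMARTS pattern", call. = FALSE)
  bdf <- if (length(bonds)) {
    data.frame(a1 = vapply(bonds, `[[`, integer(1), "a1"),
               a2 = vapply(bonds, `[[`, integer(1), "a2"),
               sym = vapply(bonds, `[[`, character(1), "sym"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a1 = integer(), a2 = integer(), sym = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(atoms = atoms, bonds = bdf, maps = maps, smarts = s),
            class = "rx_smarts")
}

# ---- evaluation -------------------------------------------------------------

.eval_prim <- function(prim, g, ai, deg, ring_sizes) {
  at <- g$atoms[ai, ]
  val <- switch(prim$kind,
    elem = at$elem == prim$val && !at$arom,
    aelem = at$elem == prim$val && at$arom,
    z = identical(unname(.ELEM_Z[at$elem]), prim$val),
    any = TRUE,
    arom = at$arom == prim$val,
    D = deg[ai] == prim$val,
    X = (deg[ai] + at$nH) == prim$val,
    H = at$nH == prim$val,
    v = {
      bsum <- sum(g$bonds$order[g$bonds$a1 == ai | g$bonds$a2 == ai])
      (bsum + at$nH) == prim$val
    },
    R = if (is.na(prim$val)) at$in_ring
        else if (prim$val == 0L) !at$in_ring else at$in_ring,
    r = prim$val %in% ring_sizes[[ai]],
    charge = at$charge == prim$val,
    stop("unknown primitive kind ", prim$kind))
  if (prim$neg) !val else val
}

.eval_atom_expr <- function(expr, g, ai, deg, ring_sizes) {
  all(vapply(expr, function(group) {
    any(vapply(group, function(alt) {
      all(vapply(alt, .eval_prim, logical(1), g = g, ai = ai, deg = deg,
                 ring_sizes = ring_sizes))
    }, logical(1)))
  }, logical(1)))
}

.eval_bond_sym <- function(sym, order, arom) {
  switch(sym,
    "-" = order == 1L && !arom,
    "=" = order == 2L && !arom,
    "#" = order == 3L,
    ":" = arom,
    "~" = TRUE,
    "default" = (order == 1L && !arom) || arom,
    stop("unknown bond symbol ", sym))
}

# ---- matching ---------------------------------------------------------------

# Subgraph monomorphism of `pattern` into graph `g` by backtracking over a
# connectivity-first atom order. Returns a list of integer vectors (pattern
# atom i -> graph atom match[i]), at most `max_matches`, in deterministic
# order. Patterns must be connected.
match_smarts <- function(pattern, g, max_matches = 1L) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  np <- length(pattern$atoms)
  ng <- nrow(g$atoms)
  if (np > ng) return(list())   # cannot match injectively
  deg <- integer(ng)
  if (nrow(g$bonds)) {
    tb <- table(c(g$bonds$a1, g$bonds$a2))
    deg[as.integer(names(tb))] <- as.integer(tb)
  }
  ring_sizes <- lapply(seq_len(ng), function(i)
    unique(vapply(Filter(function(r) i %in% r, g$rings), length, integer(1))))
  # order pattern atoms so each (after the first) touches an earlier one
  order_idx <- 1L
  placed <- c(1L)
  while (length(placed) < np) {
    nxt <- NA_integer_
    for (k in seq_len(nrow(pattern$bonds))) {
      a1 <- pattern$bonds$a1[k]; a2 <- pattern$bonds$a2[k]
      if (a1 %in% placed && !(a2 %in% placed)) { nxt <- a2; break }
      if (a2 %in% placed && !(a1 %in% placed)) { nxt <- a1; break }
    }
    if (is.na(nxt)) {
      stop("disconnected SMARTS pattern not supported: ", pattern$smarts,
           call. = FALSE)
    }
    placed <- c(placed, nxt)
  }
  # pre-tabulate, for each placement step, the pattern bonds to earlier atoms
  back_bonds <- lapply(seq_len(np), function(step) {
    pi <- placed[step]
    earlier <- placed[seq_len(step - 1L)]
    sel <- which((pattern$bonds$a1 == pi & pattern$bonds$a2 %in% earlier) |
                 (pattern$bonds$a2 == pi & pattern$bonds$a1 %in% earlier))
    lapply(sel, function(k) {
      other <- if (pattern$bonds$a1[k] == pi) pattern$bonds$a2[k]
               else pattern$bonds$a1[k]
      list(other = other, sym = pattern$bonds$sym[k])
    })
  })
  adj <- .adjacency(ng, g$bonds)
  bkey <- paste(g$bonds$a1, g$bonds$a2)
  bond_row <- function(i, j) match(paste(min(i, j), max(i, j)), bkey)
  matches <- list()
  assign_map <- rep(NA_integer_, np)   # pattern idx -> graph idx
  used <- rep(FALSE, ng)
  recurse <- function(step) {
    if (length(matches) >= max_matches) return()
    if (step > np) {
      matches[[length(matches) + 1L]] <<- assign_map
      return()
    }
    pi <- placed[step]
    bb <- back_bonds[[step]]
    cand <- if (step == 1L) seq_len(ng) else {
      anchor <- assign_map[bb[[1L]]$other]
      adj[[anchor]]
    }
    for (gi in cand) {
      if (used[gi]) next
      if (!.eval_atom_expr(pattern$atoms[[pi]], g, gi, deg, ring_sizes)) next
      ok <- TRUE
      for (b in bb) {
        gj <- assign_map[b$other]
        br <- bond_row(gi, gj)
        if (is.na(br) ||
            !.eval_bond_sym(b$sym, g$bonds$order[br], g$bonds$arom[br])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_map[pi] <<- gi
      used[gi] <<- TRUE
      recurse(step + 1L)
      assign_map[pi] <<- NA_integer_
      used[gi] <<- FALSE
      if (length(matches) >= max_matches) return()
    }
  }
  recurse(1L)
  matches
}

# does the pattern match anywhere in the molecule?
has_substructure <- function(pattern, mol) {
  g <- mol_graph(mol)
  length(match_smarts(pattern, g, max_matches = 1L)) > 0L
}
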
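# Design score, Metropolis acceptance, ligand filters, and the scorer
# contract with a deterministic surrogate.
#
# The design score is the size-normalised ligand efficiency
#   LE2 = E / N_HA^2   (REU per squared heavy-atom count)
# where E is the interface energy reported by the active scorer (lower is
# better). Scorers are pluggable: any function taking (mol, pose) and
# returning a finite interface energy in REU satisfies the contract. The
# shipped surrogate scores a molecule by its fingerprint overlap with a
# hidden target, giving a smooth, deterministic landscape on which the full
# optimisation loop can run and be tested without a docking engine.

#' Size-normalised ligand-efficiency design score
#'
#' @param energy Interface energy in REU (lower is better).
#' @param n_heavy Heavy-atom count (>= 1).
#' @return `energy / n_heavy^2`.
#' @examples
#' le2(-15, 10)   # -0.15
#' @export
le2 <- function(energy, n_heavy) {
  if (any(n_heavy < 1)) stop("n_heavy must be >= 1", call. = FALSE)
  energy / n_heavy^2
}

#' Metropolis acceptance decision
#'
#' A proposal with a better (lower) design score is always accepted; a worse
#' one is accepted with probability `exp(-delta / kT)`.
#'
#' @param delta Score difference, new minus current (in LE2 units).
#' @param kT Temperature factor (> 0).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
metropolis_accept <- function(delta, kT) {
  if (!is.numeric(kT) || kT <= 0) stop("kT must be > 0", call. = FALSE)
  if (delta <= 0) return(TRUE)
  stats::runif(1) < exp(-delta / kT)
}

#' Ligand filter set
#'
#' The log P bandpass penalises molecules outside `[logp_min, logp_max]` and
#' rejects them outright outside `[logp_reject_min, logp_reject_max]`;
#' overly complex molecules (synthetic-accessibility estimate above
#' `sascore_max`) are rejected before scoring. Optional molecular-weight and
#' rotatable-bond bounds reject when violated.
#'
#' @param logp_min,logp_max Penalty band (defaults 0 and 5).
#' @param logp_reject_min,logp_reject_max Hard bounds (defaults -1 and 8).
#' @param sascore_max Maximum synthetic-accessibility estimate (default 6).
#' @param penalty Score penalty in LE2 units added for in-bounds but
#'   out-of-band log P (default 0.5).
#' @param mol_weight_max,n_rotatable_max Optional hard bounds (`NULL` = off).
#' @return A list of class `rx_filters`.
#' @export
filter_set <- function(logp_min = 0, logp_max = 5,
                       logp_reject_min = -1, logp_reject_max = 8,
                       sascore_max = 6, penalty = 0.5,
                       mol_weight_max = NULL, n_rotatable_max = NULL) {
  stopifnot(logp_reject_min <= logp_min, logp_max <= logp_reject_max)
  structure(list(logp_min = logp_min, logp_max = logp_max,
                 logp_reject_min = logp_reject_min,
                 logp_reject_max = logp_reject_max,
                 sascore_max = sascore_max, penalty = penalty,
                 mol_weight_max = mol_weight_max,
                 n_rotatable_max = n_rotatable_max),
            class = "rx_filters")
}

#' Apply ligand filters to a molecule
#'
#' @param mol Molecule ([rx_mol] or SMILES).
#' @param filters An [filter_set()].
#' @param logp_fn,sascore_fn Optional property-provider overrides, passed to
#'   [physchem()].
#' @return A list with `status` (`"pass"`, `"penalize"` or `"reject"`),
#'   `penalty` (LE2 units, 0 unless penalised) and `reason`.
#' @export
apply_filters <- function(mol, filters = filter_set(), logp_fn = NULL,
                          sascore_fn = NULL) {
  stopifnot(inherits(filters, "rx_filters"))
  mol <- tryCatch(physchem(mol, logp_fn, sascore_fn),
                  error = function(e) NULL)
  if (is.null(mol)) {
    return(list(status = "reject", penalty = 0,
                reason = "property computation failed"))
  }
  p <- mol$props
  if (p$logp < filters$logp_reject_min || p$logp > filters$logp_reject_max) {
    return(list(status = "reject", penalty = 0,
                reason = sprintf("logP %.2f outside [%g, %g]", p$logp,
                                 filters$logp_reject_min,
                                 filters$logp_reject_max)))
  }
  if (p$sascore > filters$sascore_max) {
    return(list(status = "reject", penalty = 0,
                reason = sprintf("SA estimate %.2f > %g", p$sascore,
                                 filters$sascore_max)))
  }
  if (!is.null(filters$mol_weight_max) &&
      p$mol_weight > filters$mol_weight_max) {
    return(list(status = "reject", penalty = 0,
                reason = sprintf("mol weight %.1f > %g", p$mol_weight,
                                 filters$mol_weight_max)))
  }
  if (!is.null(filters$n_rotatable_max) &&
      p$n_rotatable > filters$n_rotatable_max) {
    return(list(status = "reject", penalty = 0,
                reason = sprintf("%d rotatable bonds > %g", p$n_rotatable,
                                 filters$n_rotatable_max)))
  }
  if (p$logp < filters$logp_min || p$logp > filters$logp_max) {
    return(list(status = "penalize", penalty = filters$penalty,
                reason = sprintf("logP %.2f outside band [%g, %g]", p$logp,
                                 filters$logp_min, filters$logp_max)))
  }
  list(status = "pass", penalty = 0, reason = "")
}

# ---- scorer contract --------------------------------------------------------

.scorer_registry <- new.env(parent = emptyenv())

#' Register a scorer factory
#'
#' A scorer is a function `function(mol, pose = NULL)` returning a finite
#' interface energy in REU (lower = better binding). Factories take
#' name-specific arguments and return such a function.
#'
#' @param name Registry key.
#' @param factory Function returning a scorer.
#' @return Invisibly, `name`.
#' @export
register_scorer <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(name, factory, envir = .scorer_registry)
  invisible(name)
}

#' Resolve a scorer by name
#'
#' @param name Registry key (e.g. `"surrogate"`).
#' @param ... Arguments passed to the registered factory.
#' @return A scorer function.
#' @export
get_scorer <- function(name, ...) {
  factory <- get0(name, envir = .scorer_registry)
  if (is.null(factory)) {
    stop("no scorer registered under '", name, "'", call. = FALSE)
  }
  factory(...)
}

#' Deterministic fingerprint-overlap surrogate scorer
#'
#' Scores a molecule as `-scale * |fp(mol) intersect fp(target)|`: the more
#' path-fingerprint features it shares with a hidden target molecule, the
#' lower (better) its interface energy. Deterministic, smooth in structural
#' similarity, and minimised by the target itself -- a stand-in landscape
#' that lets the optimiser run end-to-end without a docking engine.
#'
#' @param target Hidden target molecule ([rx_mol] or SMILES).
#' @param scale REU per shared bit (default 1).
#' @return A scorer function `function(mol, pose = NULL)`.
#' @export
make_surrogate_scorer <- function(target, scale = 1) {
  target_fp <- rx_fingerprint(rx_mol(target))
  force(scale)
  function(mol, pose = NULL) {
    fp <- rx_fingerprint(rx_mol(mol))
    -scale * length(intersect(fp$bits, target_fp$bits))
  }
}

# default registry entries
register_scorer("surrogate", make_surrogate_scorer)
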
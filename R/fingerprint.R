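# Fingerprints and set-overlap similarity metrics.
#
# Fingerprints are OpenBabel FP2: path-based ("Daylight-like") hashed
# fingerprints over linear fragments of 1-7 atoms, folded to 1024 bits.
# They are represented sparsely as the sorted vector of on-bit indices.

.FP_NBITS <- 1024L

#' Path-based hashed fingerprint of a molecule
#'
#' Computes the OpenBabel FP2 fingerprint (linear paths of 1--7 atoms hashed
#' into a 1024-bit space) of the canonicalised molecule. Deterministic: the
#' same canonical SMILES always yields the identical bit set.
#'
#' @param mol An [rx_mol] or SMILES string.
#' @return An object of class `rx_fp`: list with `bits` (sorted 1-based
#'   indices of on bits) and `n_bits`.
#' @examples
#' fp <- rx_fingerprint("c1ccccc1O")
#' length(fp$bits)
#' @export
rx_fingerprint <- function(mol) {
  mol <- rx_mol(mol)
  fp <- .cache_get("fp", mol$smiles)
  if (is.null(fp)) {
    vec <- ChemmineOB::forEachMol("SMILES", mol$smiles, function(m)
      ChemmineOB::fingerprint_OB(list(m), "FP2"))[[1]]
    fp <- structure(list(bits = which(vec != 0), n_bits = .FP_NBITS),
                    class = "rx_fp")
    .cache_set("fp", mol$smiles, fp)
  }
  fp
}

#' @export
print.rx_fp <- function(x, ...) {
  cat("<rx_fp> ", length(x$bits), "/", x$n_bits, " bits on\n", sep = "")
  invisible(x)
}

as_rx_fp <- function(x) {
  if (inherits(x, "rx_fp")) return(x)
  rx_fingerprint(x)
}

.check_same_space <- function(a, b) {
  if (a$n_bits != b$n_bits) {
    stop("fingerprints live in different bit spaces (", a$n_bits, " vs ",
         b$n_bits, ")", call. = FALSE)
  }
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`. Two all-zero fingerprints count as
#' identical (similarity 1), which avoids a 0/0 for featureless inputs.
#'
#' @param a,b `rx_fp` fingerprints (or molecules/SMILES, converted on the fly).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as_rx_fp(a); b <- as_rx_fp(b)
  .check_same_space(a, b)
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(a$bits) + length(b$bits) - ni
  if (nu == 0L) return(1)
  ni / nu
}

#' Tversky similarity between a reference and a fragment fingerprint
#'
#' The asymmetric index `c / (c + alpha * a_only + beta * b_only)` where `c`
#' is the shared bit count, `a_only` the bits unique to the reference and
#' `b_only` the bits unique to the fragment. The default weights (0.1 on the
#' reference, 0.9 on the fragment) make the index behave like a substructure
#' similarity: a fragment fully contained in the reference scores close to 1.
#' With `alpha = beta = 1` the index reduces to Tanimoto.
#'
#' @param ref Reference fingerprint (or molecule/SMILES).
#' @param frag Fragment fingerprint (or molecule/SMILES).
#' @param alpha Weight on reference-only bits (default 0.1).
#' @param beta Weight on fragment-only bits (default 0.9).
#' @return Similarity in `[0, 1]`; two all-zero fingerprints give 1.
#' @export
tversky <- function(ref, frag, alpha = 0.1, beta = 0.9) {
  stopifnot(alpha >= 0, beta >= 0)
  ref <- as_rx_fp(ref); frag <- as_rx_fp(frag)
  .check_same_space(ref, frag)
  ni <- length(intersect(ref$bits, frag$bits))
  a_only <- length(ref$bits) - ni
  b_only <- length(frag$bits) - ni
  denom <- ni + alpha * a_only + beta * b_only
  if (denom == 0) return(1)
  ni / denom
}

# dense logical fingerprint matrix for a character vector of canonical SMILES
fp_matrix <- function(smiles) {
  m <- matrix(FALSE, nrow = length(smiles), ncol = .FP_NBITS)
  for (i in seq_along(smiles)) m[i, rx_fingerprint(smiles[i])$bits] <- TRUE
  m
}

# vectorised Tversky of one reference fp against the rows of a fp matrix
tversky_vec <- function(ref_fp, mat, alpha = 0.1, beta = 0.9) {
  ref <- logical(ncol(mat)); ref[ref_fp$bits] <- TRUE
  ni <- as.vector(mat %*% ref)
  a_only <- sum(ref) - ni
  b_only <- rowSums(mat) - ni
  denom <- ni + alpha * a_only + beta * b_only
  out <- ifelse(denom == 0, 1, ni / denom)
  out
}

# vectorised Tanimoto of one reference fp against the rows of a fp matrix
tanimoto_vec <- function(ref_fp, mat) {
  ref <- logical(ncol(mat)); ref[ref_fp$bits] <- TRUE
  ni <- as.vector(mat %*% ref)
  nu <- sum(ref) + rowSums(mat) - ni
  ifelse(nu == 0, 1, ni / nu)
}
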
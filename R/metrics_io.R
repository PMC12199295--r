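# Diagnostic metrics (step size, output diversity, novelty, property
# distributions) and file I/O for designs, trajectories and properties.

#' Mean step size of a design route
#'
#' The step size of a route is measured as the Tanimoto similarity between
#' consecutive accepted ligands (larger similarity = smaller step); this
#' returns the route average.
#'
#' @param record An `rx_route` (or a data frame with a `smiles` column of
#'   accepted states in order).
#' @return Mean consecutive-pair Tanimoto similarity, or `NA` when fewer
#'   than two accepted states exist.
#' @export
mean_step_size <- function(record) {
  smi <- if (inherits(record, "rx_route")) record$accepted$smiles
         else record$smiles
  if (length(smi) < 2L) return(NA_real_)
  mean(vapply(seq_len(length(smi) - 1L), function(i)
    tanimoto(rx_fingerprint(smi[i]), rx_fingerprint(smi[i + 1L])),
    numeric(1)))
}

#' Output diversity: per-molecule maximum similarity to the rest of the set
#'
#' @param mols List/vector of >= 2 molecules.
#' @return Numeric vector: for each molecule, the maximum Tanimoto
#'   similarity to any other molecule of the set (values near 0 = diverse).
#' @export
output_diversity <- function(mols) {
  smi <- vapply(lapply(as.list(mols), rx_mol), `[[`, character(1), "smiles")
  if (length(smi) < 2L) stop("need at least two molecules", call. = FALSE)
  fpm <- fp_matrix(smi)
  vapply(seq_along(smi), function(i) {
    s <- tanimoto_vec(rx_fingerprint(smi[i]), fpm)
    max(s[-i])
  }, numeric(1))
}

#' Novelty: per-design maximum similarity to a reference set
#'
#' @param designs Non-empty list/vector of design molecules.
#' @param references Non-empty list/vector of reference molecules (e.g.
#'   known actives).
#' @return Numeric vector: for each design, the highest Tanimoto similarity
#'   to any reference.
#' @export
novelty_vs_reference <- function(designs, references) {
  dsmi <- vapply(lapply(as.list(designs), rx_mol), `[[`, character(1),
                 "smiles")
  rsmi <- vapply(lapply(as.list(references), rx_mol), `[[`, character(1),
                 "smiles")
  if (!length(dsmi) || !length(rsmi)) {
    stop("both design and reference sets must be non-empty", call. = FALSE)
  }
  rfp <- fp_matrix(rsmi)
  vapply(dsmi, function(s) max(tanimoto_vec(rx_fingerprint(s), rfp)),
         numeric(1), USE.NAMES = FALSE)
}

# ---- file I/O ---------------------------------------------------------------

#' Write final designs to CSV
#'
#' Columns: `route_id`, `smiles`, `le2`, `n_heavy`, `scaffold`.
#'
#' @param designs Data frame as returned by [campaign_designs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_designs <- function(designs, path) {
  need <- c("route_id", "smiles", "le2", "n_heavy", "scaffold")
  stopifnot(all(need %in% names(designs)))
  utils::write.csv(designs[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a designs CSV written by [write_designs()]
#'
#' @param path File path.
#' @return Data frame with the design columns.
#' @export
read_designs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(route_id = "integer",
                                       smiles = "character",
                                       le2 = "numeric", n_heavy = "integer",
                                       scaffold = "character"))
  need <- c("route_id", "smiles", "le2", "n_heavy", "scaffold")
  if (!all(need %in% names(df))) {
    stop("malformed designs file ", path, ": expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a route trajectory as JSON lines
#'
#' One JSON object per proposal: iteration, proposal SMILES, verdict, score
#' difference, sampling ratio, acceptance flag.
#'
#' @param record An `rx_route`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(record, path) {
  stopifnot(inherits(record, "rx_route"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(record$trajectory))) {
    writeLines(jsonlite::toJSON(as.list(record$trajectory[i, ]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' Read a JSONL trajectory
#'
#' @param path File path.
#' @return Data frame with the trajectory columns.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop("malformed trajectory line ", i, " in ", path, ": ",
           conditionMessage(e), call. = FALSE))
    rec[vapply(rec, is.null, logical(1))] <- NA
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Accepted states recoverable from a trajectory log
#'
#' Replays a persisted trajectory and returns the accepted proposal SMILES
#' in order (excluding the initial state, which the log does not contain).
#'
#' @param trajectory Data frame from [read_trajectory()].
#' @return Character vector of accepted SMILES.
#' @export
replay_accepted <- function(trajectory) {
  trajectory$proposal[which(trajectory$accepted)]
}

#' Write a property table to CSV
#'
#' Header: `mol_id,smiles,mol_weight,hba,hbd,logp,n_rotatable,sascore`.
#'
#' @param mols List/vector of molecules, or a data frame from
#'   [property_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_properties <- function(mols, path) {
  df <- if (is.data.frame(mols)) mols else property_table(mols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write molecules as a SMILES list file (one `smiles<TAB>id` per line)
#'
#' @param mols List/vector of molecules.
#' @param path Output path.
#' @param ids Optional identifiers.
#' @return Invisibly, `path`.
#' @export
write_smiles <- function(mols, path, ids = NULL) {
  smi <- vapply(lapply(as.list(mols), rx_mol), `[[`, character(1), "smiles")
  if (is.null(ids)) ids <- paste0("mol_", seq_along(smi))
  writeLines(paste(smi, ids, sep = "\t"), path)
  invisible(path)
}
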
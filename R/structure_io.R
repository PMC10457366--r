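# Residue-level structure and sequence I/O.
#
# Structures are reduced to ordered per-chain Calpha records: the geometric
# substrate for residue-level graphs. PDB parsing stands on bio3d; the rules
# applied on top (model selection, altloc resolution, MSE handling, dropping
# residues without a Calpha) are fixed here so downstream graphs are
# deterministic.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

aa_one <- function(resid3) {
  out <- unname(AA3TO1[resid3])
  out[is.na(out)] <- "X"
  out
}

#' Read a PDB structure into ordered Calpha residue records
#'
#' Parses ATOM records of one model into per-chain, file-ordered residue
#' records carrying the Calpha coordinate and a one-letter residue code.
#' Alternate locations are resolved to the highest-occupancy altloc
#' (ties: alphabetically first id); residues without a Calpha atom are
#' dropped with a warning; HETATM records are ignored except MSE
#' (selenomethionine), which is kept as a residue with code \code{"X"}.
#'
#' @param path path to a PDB file (wwPDB v3.3 ATOM/HETATM/MODEL records).
#' @param model_index 1-based model to read (default 1; NMR-style multi-model
#'   files carry one conformer per MODEL block).
#' @return An object of class \code{structure_model}: a list with
#'   \code{chains} (named list, one data.frame per chain with columns
#'   \code{res_seq}, \code{icode}, \code{aa}, \code{x}, \code{y}, \code{z},
#'   in file order) and \code{source_id}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_ca_pdb("AGK", cbind(0:2 * 3.8, 0, 0), pdb)
#' mod <- read_structure(pdb)
#' derive_sequence(mod, "A")$seq
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stopf("cannot parse PDB file '%s': %s", path,
                              conditionMessage(e)))
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models)
    stopf("model_index %d out of range: '%s' has %d model(s)",
          model_index, path, n_models)

  at <- pdb$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep, , drop = FALSE]
  rows <- which(keep)
  if (nrow(at) == 0L) stopf("no ATOM records in '%s'", path)

  icode <- ifelse(is.na(at$insert), "", at$insert)
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  reskey <- paste(chain, at$resno, icode, sep = "\r")

  is_ca <- at$elety == "CA"
  missing_ca <- setdiff(unique(reskey), unique(reskey[is_ca]))
  if (length(missing_ca) > 0L)
    warnf("dropped %d residue(s) without a CA atom in '%s'",
          length(missing_ca), path)

  ca <- which(is_ca)
  if (length(ca) == 0L) stopf("no CA atoms in '%s'", path)

  # altloc resolution: highest occupancy wins, ties to the alphabetically
  # first altloc id; NA occupancy treated as 1.0, blank altloc sorts first
  occ <- ifelse(is.na(at$o[ca]), 1, at$o[ca])
  alt <- ifelse(is.na(at$alt[ca]), "", at$alt[ca])
  ord <- order(match(reskey[ca], unique(reskey[ca])), -occ, alt)
  ca <- ca[ord]
  ca <- ca[!duplicated(reskey[ca])]
  ca <- sort(ca)                      # restore file order

  xyz_row <- pdb$xyz[model_index, ]
  gi <- rows[ca]                      # index into the full atom table
  coords <- cbind(xyz_row[3 * gi - 2], xyz_row[3 * gi - 1], xyz_row[3 * gi])
  if (any(!is.finite(coords)))
    stopf("non-finite CA coordinate in '%s' (model %d)", path, model_index)

  df <- data.frame(
    res_seq = at$resno[ca],
    icode   = icode[ca],
    aa      = aa_one(at$resid[ca]),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE)
  chains <- split(df, factor(chain[ca], levels = unique(chain[ca])))

  structure(list(chains = chains, source_id = basename(path)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", x$source_id, "\n")
  for (cid in names(x$chains))
    cat("  chain ", cid, ": ", nrow(x$chains[[cid]]), " residues\n", sep = "")
  invisible(x)
}

#' Calpha coordinates of one chain
#'
#' @param model a \code{structure_model}.
#' @param chain_id chain identifier.
#' @return N x 3 coordinate matrix in Angstrom, record order.
#' @export
chain_coords <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stopf("chain '%s' not found", chain_id)
  as.matrix(ch[, c("x", "y", "z")])
}

#' Derive the structure-observed sequence of a chain
#'
#' One-letter codes in record order; non-standard residues (including MSE)
#' appear as \code{"X"}. This is the "fragmentary" sequence that may lack
#' residues unresolved in the crystal.
#'
#' @inheritParams chain_coords
#' @return A \code{sequence_record}: list with \code{id} and \code{seq}.
#' @export
derive_sequence <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stopf("chain '%s' not found", chain_id)
  if (nrow(ch) == 0L) stopf("chain '%s' has no residues", chain_id)
  sequence_record(paste0(model$source_id, "_", chain_id),
                  paste(ch$aa, collapse = ""))
}

#' Construct a sequence record
#'
#' @param id free-text identifier.
#' @param seq amino-acid string; uppercased on construction.
#' @export
sequence_record <- function(id, seq) {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (nchar(seq) == 0L) stopf("empty sequence for record '%s'", id)
  structure(list(id = id, seq = seq), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(">", x$id, " (", nchar(x$seq), " aa)\n", sep = "")
  cat(x$seq, "\n")
  invisible(x)
}

#' Read FASTA sequences
#'
#' @param path FASTA file.
#' @return list of \code{sequence_record}, file order, uppercased.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("cannot parse FASTA '%s': %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0L) stopf("no FASTA records in '%s'", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set),
         function(i) sequence_record(ids[i], as.character(set[[i]])))
}

#' Write FASTA sequences
#'
#' @param records a \code{sequence_record} or list of them.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a Calpha-only PDB file
#'
#' Emits one ATOM CA record per residue, standard three-letter names
#' (\code{"X"} becomes UNK). Used to materialise synthetic chains as
#' structures and to build parsing fixtures.
#'
#' @param seq one-letter amino-acid string (length N).
#' @param coords N x 3 matrix, Angstrom.
#' @param path output file.
#' @param chain_id one-character chain id.
#' @export
write_ca_pdb <- function(seq, coords, path, chain_id = "A") {
  letters1 <- strsplit(toupper(seq), "")[[1]]
  if (length(letters1) != nrow(coords))
    stopf("sequence length %d != coordinate rows %d",
          length(letters1), nrow(coords))
  rev3 <- names(AA3TO1)[match(letters1, AA3TO1)]
  rev3[is.na(rev3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(letters1), rev3, chain_id, seq_along(letters1),
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
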
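# Per-residue embedding providers and their integration into node features.
#
# A provider maps a sequence of length N to an N x psi_PLM matrix of
# per-residue representations h'. The packaged provider is a deterministic
# mock (seeded hash of residue letter and position expanded to
# pseudo-random values) so pipelines run and are testable without any
# model weights; a real protein-language-model provider plugs in behind
# the same interface. Default width psi_PLM = 1280.

#' Deterministic mock per-residue embedding
#'
#' Row i is a pure function of (seed, residue letter, position i): a
#' sub-seed hashed from the triple drives a private RNG stream expanded to
#' \code{width} values. The matrix therefore encodes both residue identity
#' and sequence position, and repeated calls are bitwise identical.
#'
#' @param seq sequence (string or \code{sequence_record}), non-empty.
#' @param width embedding width psi_PLM (default 1280).
#' @param seed integer seed.
#' @return class \code{embedding_matrix}: an N x width numeric matrix with
#'   attributes \code{provider_id} and \code{psi_plm}.
#' @examples
#' e <- mock_embed("AGK", width = 8, seed = 0)
#' dim(e)
#' @export
mock_embed <- function(seq, width = 1280L, seed = 0L) {
  s <- as_seq_string(seq)
  width <- as.integer(width)
  if (width < 1L) stopf("width must be >= 1")
  letters1 <- strsplit(s, "")[[1]]
  n <- length(letters1)
  vals <- matrix(0, n, width)
  for (i in seq_len(n)) {
    sub <- (as.integer(seed) * 1000003 + i * 7919 +
              utf8ToInt(letters1[i]) * 104729) %% (2^31 - 1)
    vals[i, ] <- with_private_rng(sub, stats::rnorm(width))
  }
  embedding_matrix(vals, provider_id = sprintf("mock-%d", as.integer(seed)))
}

#' Construct an embedding matrix
#'
#' @param values N x psi_PLM numeric matrix, finite.
#' @param provider_id free-text provider identifier.
#' @export
embedding_matrix <- function(values, provider_id = "unknown") {
  values <- as.matrix(values)
  assert_finite_matrix(values, "embedding values")
  structure(values, provider_id = provider_id, psi_plm = ncol(values),
            class = c("embedding_matrix", class(values)))
}

#' Embedding provider interface
#'
#' Bundles an id, a width and a deterministic \code{embed(seq)} closure.
#' \code{mock_provider()} is the packaged implementation; providers backed
#' by real protein language models (e.g. a 1280-wide transformer) satisfy
#' the same contract: identical sequence in, identical matrix out, one row
#' per residue.
#'
#' @param width embedding width.
#' @param seed provider seed.
#' @return class \code{embedding_provider}: list with \code{id},
#'   \code{width}, \code{embed}.
#' @export
mock_provider <- function(width = 1280L, seed = 0L) {
  force(width); force(seed)
  structure(list(
    id = sprintf("mock-%d", as.integer(seed)),
    width = as.integer(width),
    embed = function(seq) mock_embed(seq, width = width, seed = seed)),
    class = "embedding_provider")
}

#' Integrate embeddings into node features
#'
#' \code{replace} (default for residue-level graphs): h' verbatim becomes
#' the node features. \code{concat}: h columns followed by h' columns.
#' \code{add}: elementwise sum, requiring psi_h == psi_PLM.
#'
#' @param h N x psi_h node feature matrix.
#' @param h_prime N x psi_PLM \code{embedding_matrix} (or plain matrix).
#' @param mode \code{"replace"}, \code{"concat"} or \code{"add"}.
#' @return N x psi_out numeric matrix.
#' @export
integrate_features <- function(h, h_prime,
                               mode = c("replace", "concat", "add")) {
  mode <- match.arg(mode)
  h <- as.matrix(h); hp <- unclass(as.matrix(h_prime))
  attr(hp, "provider_id") <- NULL; attr(hp, "psi_plm") <- NULL
  if (nrow(h) != nrow(hp))
    stopf(paste("row mismatch: features have %d rows, embeddings %d;",
                "reconcile sequence and structure first (see reconcile()",
                "and project_embedding())"), nrow(h), nrow(hp))
  switch(mode,
         replace = hp,
         concat = cbind(h, hp),
         add = {
           if (ncol(h) != ncol(hp))
             stopf("add requires psi_h == psi_PLM (got %d vs %d)",
                   ncol(h), ncol(hp))
           h + hp
         })
}

#' Project full-sequence embeddings onto structure residues
#'
#' Selects the embedding rows at the mapped full-sequence positions,
#' ordered by structure position, so the result is aligned 1:1 with the
#' graph nodes (residues absent from the structure are abandoned).
#'
#' @param h_prime embedding matrix over the full sequence.
#' @param mapping a \code{seq_struct_mapping} from \code{reconcile()}.
#' @return \code{embedding_matrix} with one row per mapped structure
#'   residue.
#' @export
project_embedding <- function(h_prime, mapping) {
  stopifnot(inherits(mapping, "seq_struct_mapping"))
  pairs <- mapping$pairs
  hp <- as.matrix(h_prime)
  if (nrow(pairs) > 0L && max(pairs[, "full_seq_pos"]) > nrow(hp))
    stopf("mapping references position %d beyond the %d embedding rows",
          max(pairs[, "full_seq_pos"]), nrow(hp))
  out <- hp[pairs[order(pairs[, "struct_pos"]), "full_seq_pos"], ,
            drop = FALSE]
  embedding_matrix(out,
                   provider_id = attr(h_prime, "provider_id") %||% "unknown")
}

#' Cache an embedding matrix as TSV + JSON header
#'
#' Stored as a plain-text matrix next to a JSON header keyed by
#' (provider id, md5 of the embedded sequence), enabling reuse without
#' recomputation.
#'
#' @param emb an \code{embedding_matrix}.
#' @param prefix path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @param seq the embedded sequence (for the integrity hash); optional.
#' @export
write_embedding <- function(emb, prefix, seq = NULL) {
  utils::write.table(unclass(as.matrix(emb)), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hdr <- list(provider_id = attr(emb, "provider_id") %||% "unknown",
              n_residues = nrow(emb), width = ncol(emb))
  if (!is.null(seq)) {
    tf <- tempfile(); writeLines(as_seq_string(seq), tf)
    hdr$sequence_md5 <- unname(tools::md5sum(tf)); unlink(tf)
  }
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(prefix)
}

#' Read a cached embedding matrix
#'
#' @param prefix path prefix used by \code{write_embedding}.
#' @export
read_embedding <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"))
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != hdr$n_residues || ncol(m) != hdr$width)
    stopf("embedding cache '%s' does not match its header", prefix)
  embedding_matrix(m, provider_id = hdr$provider_id)
}
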
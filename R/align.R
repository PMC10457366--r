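# Sequence-structure reconciliation.
#
# Crystal structures are usually incomplete, so the structure-derived
# sequence is a fragment of the deposited full-length sequence. Two
# strategies are supported: embed the fragment as-is ("fragment", the
# default), or globally align the full sequence to the fragment and drop
# residues absent from the structure ("align"). Both yield a 1-based
# position mapping consumed by project_embedding().

#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Optimal global alignment under a (match, mismatch, gap) scoring triple.
#' Among co-optimal alignments the traceback deterministically prefers
#' diagonal over up (gap in \code{b}) over left (gap in \code{a}).
#'
#' @param a,b sequences: strings or \code{sequence_record}s, non-empty.
#' @param match,mismatch,gap scoring triple (defaults 1, -1, -2).
#' @return class \code{alignment}: list with \code{aligned_a},
#'   \code{aligned_b} (equal-length gapped strings, gap = \code{"-"}) and
#'   \code{score}.
#' @examples
#' global_align("AGKV", "AKV")
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as_seq_string(a); b <- as_seq_string(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)

  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    prev <- S[i, ]
    cur <- numeric(m + 1L)
    cur[1L] <- gap * i
    # rowwise recurrence; the left-dependency forces the inner loop
    diag_up <- pmax(prev[1:m] + sub, prev[2:(m + 1L)] + gap)
    for (j in seq_len(m)) cur[j + 1L] <- max(diag_up[j], cur[j] + gap)
    S[i + 1L, ] <- cur
  }

  # traceback, diagonal > up > left
  i <- n; j <- m; ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] +
          (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }

  structure(list(aligned_a = paste(ra, collapse = ""),
                 aligned_b = paste(rb, collapse = ""),
                 score = S[n + 1L, m + 1L]),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", "score: ", x$score, "\n", sep = "")
  invisible(x)
}

as_seq_string <- function(s) {
  if (inherits(s, "sequence_record")) s <- s$seq
  if (!is.character(s) || length(s) != 1L || nchar(s) == 0L)
    stopf("sequence must be a non-empty string")
  toupper(s)
}

#' Map full-length sequence positions onto structure positions
#'
#' \code{mode = "fragment"}: the fragmentary structure sequence stands in
#' for the full sequence; the mapping is the identity on structure
#' positions and \code{full_seq} is ignored downstream.
#' \code{mode = "align"}: the full sequence is globally aligned to the
#' structure sequence; aligned (match or mismatch) columns become mapping
#' pairs and full-sequence residues aligned to gaps are abandoned.
#'
#' @param full_seq full-length sequence (record or string).
#' @param struct_seq structure-derived sequence (record or string).
#' @param mode \code{"fragment"} (default) or \code{"align"}.
#' @param match,mismatch,gap scoring for \code{mode = "align"}.
#' @return class \code{seq_struct_mapping}: list with \code{pairs}
#'   (2-column integer matrix, 1-based \code{full_seq_pos},
#'   \code{struct_pos}, both strictly increasing) and \code{mode}.
#' @examples
#' reconcile("AGKV", "AKV", mode = "align")$pairs
#' @export
reconcile <- function(full_seq, struct_seq, mode = c("fragment", "align"),
                      match = 1, mismatch = -1, gap = -2) {
  if (length(mode) == 1L && !mode %in% c("fragment", "align"))
    stopf("unknown reconcile mode '%s' (use 'fragment' or 'align')", mode)
  mode <- match.arg(mode)
  ss <- as_seq_string(struct_seq)
  if (mode == "fragment") {
    n <- nchar(ss)
    pairs <- cbind(full_seq_pos = seq_len(n), struct_pos = seq_len(n))
  } else {
    fs <- as_seq_string(full_seq)
    al <- global_align(fs, ss, match = match, mismatch = mismatch, gap = gap)
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    pa <- cumsum(ca != "-"); pb <- cumsum(cb != "-")
    both <- ca != "-" & cb != "-"
    pairs <- cbind(full_seq_pos = pa[both], struct_pos = pb[both])
  }
  structure(list(pairs = pairs, mode = mode), class = "seq_struct_mapping")
}

#' @export
print.seq_struct_mapping <- function(x, ...) {
  cat("seq_struct_mapping (", x$mode, "): ", nrow(x$pairs),
      " mapped positions\n", sep = "")
  invisible(x)
}

#' Write a mapping as 2-column 1-based TSV
#'
#' @param mapping a \code{seq_struct_mapping}.
#' @param path output file.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.table(mapping$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("full_seq_pos",
                                                      "struct_pos"))
  invisible(path)
}
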
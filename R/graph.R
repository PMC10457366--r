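# Residue-level 3D graph construction.
#
# A protein is a graph G = (V, E) whose N nodes carry 3D Calpha coordinates
# x (N x 3, Angstrom) and rotation/translation-invariant scalar features h
# (N x psi_h). Three connectivity schemes are supported:
#   knn   - each node gets directed edges to its K nearest neighbours
#           (default K = 10); not symmetrised unless requested
#   rball - all pairs with Euclidean distance strictly below a cutoff
#           (default 8 Angstrom), stored in both directions
#   fc    - all ordered pairs, N(N-1) edges
# Edges are stored 1-based in R objects; file exports are 0-based.

#' Build a residue-level protein graph
#'
#' @param coords N x 3 numeric matrix of Calpha coordinates (Angstrom),
#'   N >= 2, finite.
#' @param scheme \code{"knn"}, \code{"rball"} or \code{"fc"}.
#' @param k neighbours per node for \code{knn} (default 10); each node
#'   links to its \code{min(k, N-1)} nearest neighbours, distance ties
#'   broken by smaller node index.
#' @param cutoff radius for \code{rball}, Angstrom (default 8); strict
#'   \code{<} comparison.
#' @param symmetrize for \code{knn}: also add every reverse edge
#'   (union closure). Default \code{FALSE}.
#' @param node_feats optional N x psi_h feature matrix.
#' @return class \code{protein_graph}: list with \code{coords},
#'   \code{node_feats} (possibly zero-width), \code{edges} (M x 2 integer
#'   matrix of 1-based directed pairs source, target), \code{scheme},
#'   \code{params}.
#' @examples
#' g <- build_graph(cbind(c(0, 5, 11), 0, 0), "rball", cutoff = 8)
#' g$edges
#' @export
build_graph <- function(coords, scheme = c("knn", "rball", "fc"),
                        k = 10L, cutoff = 8.0, symmetrize = FALSE,
                        node_feats = NULL) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  assert_finite_matrix(coords, "coords")
  n <- nrow(coords)
  if (n < 2L) stopf("need at least 2 nodes, got %d", n)
  if (ncol(coords) != 3L) stopf("coords must be N x 3")

  if (scheme == "fc") {
    idx <- expand.grid(src = seq_len(n), dst = seq_len(n))
    idx <- idx[idx$src != idx$dst, ]
    edges <- cbind(src = idx$src, dst = idx$dst)
    params <- list()
  } else {
    D <- as.matrix(stats::dist(coords))
    if (scheme == "knn") {
      k <- as.integer(k)
      if (k < 1L) stopf("knn requires k >= 1")
      kk <- min(k, n - 1L)
      nb <- lapply(seq_len(n), function(i) {
        o <- order(D[i, -i], seq_len(n)[-i])  # ties to smaller index
        (seq_len(n)[-i])[o][seq_len(kk)]
      })
      edges <- cbind(src = rep(seq_len(n), each = kk), dst = unlist(nb))
      if (symmetrize) {
        rev <- edges[, c(2, 1)]
        colnames(rev) <- c("src", "dst")
        edges <- unique(rbind(edges, rev))
      }
      params <- list(k = k, symmetrize = symmetrize)
    } else {
      if (!is.numeric(cutoff) || cutoff <= 0) stopf("rball requires cutoff > 0")
      hit <- which(D < cutoff & upper.tri(D), arr.ind = TRUE)
      edges <- cbind(src = c(hit[, 1], hit[, 2]),
                     dst = c(hit[, 2], hit[, 1]))
      params <- list(cutoff = cutoff)
    }
  }
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("src", "dst")))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]

  g <- structure(list(coords = coords,
                      node_feats = matrix(0, n, 0L),
                      edges = edges, scheme = scheme, params = params),
                 class = "protein_graph")
  if (!is.null(node_feats)) g <- attach_features(g, node_feats)
  g
}

#' Attach node features to a graph
#'
#' Replaces the node feature matrix; coordinates and edges are untouched.
#' A zero-width matrix is allowed (features may come entirely from
#' embeddings later).
#'
#' @param g a \code{protein_graph}.
#' @param feats numeric matrix with exactly N rows.
#' @export
attach_features <- function(g, feats) {
  stopifnot(inherits(g, "protein_graph"))
  feats <- as.matrix(feats)
  n <- nrow(g$coords)
  if (nrow(feats) != n)
    stopf("feature rows (%d) must equal node count (%d)", nrow(feats), n)
  if (ncol(feats) > 0L) assert_finite_matrix(feats, "feats")
  g$node_feats <- feats
  g
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph: ", nrow(x$coords), " nodes, ", nrow(x$edges),
      " directed edges, scheme=", x$scheme, sep = "")
  if (length(x$params))
    cat(" (", paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "), ")", sep = "")
  cat("\n  node features: ", ncol(x$node_feats), "-dim\n", sep = "")
  invisible(x)
}

#' One-hot residue-class node features
#'
#' 21 classes: the 20 standard amino acids plus \code{"X"} for anything
#' else. These are the invariant scalar features h of a residue-level
#' graph before any embedding is injected.
#'
#' @param seq one-letter amino-acid string.
#' @return nchar(seq) x 21 binary matrix, columns named by residue letter.
#' @export
residue_onehot <- function(seq) {
  classes <- c(sort(unname(AA3TO1)), "X")
  letters1 <- strsplit(toupper(as_seq_string(seq)), "")[[1]]
  j <- match(letters1, classes)
  j[is.na(j)] <- length(classes)
  m <- matrix(0, length(letters1), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(j), j)] <- 1
  m
}

#' Write a graph edge list as 0-based TSV plus JSON sidecar
#'
#' @param g a \code{protein_graph}.
#' @param path edge-list TSV path; a \code{.json} sidecar with N, scheme
#'   and parameters is written next to it.
#' @export
write_edgelist <- function(g, path) {
  utils::write.table(g$edges - 1L, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("src", "dst"))
  side <- list(n_nodes = nrow(g$coords), n_edges = nrow(g$edges),
               scheme = g$scheme, params = g$params, index_base = 0L)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
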
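# Minimal invariant message-passing network (reference backbone).
#
# The only geometric input is the squared inter-node distance on each edge
# (expanded over a radial basis), so every output is invariant to
# translations, rotations and reflections by construction, and permutation
# equivariance follows from symmetric aggregation. The message on a
# directed edge (i, j) is a linear function of the source features h_i and
# the distance expansion; the receiving node's own features h_j enter
# through the update, which keeps the per-edge work inside node-sized
# matrix multiplies:
#
#   m_j     = agg over in-edges (i, j) of  W_msg [h_i, rbf(||x_i - x_j||^2)]
#   h_j'    = relu(W_self h_j + m_j + b)
#   output  = W_out [h_L, h_0] + b_out          (input-skip head)
#
# Heads: per-node classification (masked softmax over C classes; classes
# beyond a chain's length are excluded from both loss and argmax) or
# per-node regression (mean squared error). Training is full-batch Adam
# with a fixed seed; identical data and config reproduce identical fits.

#' Configuration for the reference message-passing network
#'
#' @param layers number of message-passing layers (>= 1).
#' @param hidden hidden width (>= 1).
#' @param aggregation \code{"mean"} (default) or \code{"sum"} over
#'   in-edges.
#' @param head \code{"classify"} (per-node C-way softmax) or
#'   \code{"regress"} (per-node scalar).
#' @param classes number of classes for the classify head.
#' @param head_skip give the output head the raw input features alongside
#'   the last hidden layer (default \code{TRUE}).
#' @param rbf_centers,rbf_max radial-basis expansion of edge distances:
#'   number of Gaussian centers, evenly spaced on [0, rbf_max] Angstrom.
#' @param epochs,lr full-batch Adam epochs and learning rate.
#' @param seed seed for parameter initialisation.
#' @return list of class \code{mpnn_config}.
#' @export
mpnn_config <- function(layers = 1L, hidden = 64L,
                        aggregation = c("mean", "sum"),
                        head = c("classify", "regress"), classes = NULL,
                        head_skip = TRUE, rbf_centers = 8L, rbf_max = 12,
                        epochs = 150L, lr = 0.02, seed = 1L) {
  aggregation <- match.arg(aggregation)
  head <- match.arg(head)
  if (layers < 1L) stopf("layers must be >= 1")
  if (hidden < 1L) stopf("hidden must be >= 1")
  if (head == "classify" && (is.null(classes) || classes < 2L))
    stopf("classify head needs classes >= 2")
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 aggregation = aggregation, head = head,
                 classes = if (is.null(classes)) NULL else as.integer(classes),
                 head_skip = isTRUE(head_skip),
                 rbf_centers = as.integer(rbf_centers), rbf_max = rbf_max,
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "mpnn_config")
}

# ---- graph packing ---------------------------------------------------------

# concatenate a list of protein_graphs into one block-diagonal graph
pack_graphs <- function(graphs) {
  if (inherits(graphs, "protein_graph")) graphs <- list(graphs)
  sizes <- vapply(graphs, function(g) nrow(g$coords), 0L)
  offs <- c(0L, cumsum(sizes))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_feats"))
  coords <- do.call(rbind, lapply(graphs, `[[`, "coords"))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i)
    graphs[[i]]$edges + offs[i]))
  list(X = X, coords = coords, edges = edges,
       chain = rep(seq_along(graphs), sizes), sizes = sizes,
       n = sum(sizes))
}

rbf_expand <- function(d, centers, rmax) {
  mu <- seq(0, rmax, length.out = centers)
  sg <- if (centers > 1L) mu[2] - mu[1] else rmax
  exp(-(outer(d, mu, "-")^2) / (2 * sg^2))
}

rowsum_full <- function(m, group, n) {
  out <- matrix(0, n, ncol(m))
  rs <- rowsum(m, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---- parameters ------------------------------------------------------------

mpnn_init <- function(cfg, in_width) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  with_private_rng(cfg$seed, {
    params <- list()
    fin <- in_width
    for (l in seq_len(cfg$layers)) {
      params[[paste0("W_self", l)]] <- he(fin, cfg$hidden)
      params[[paste0("W_msg", l)]] <- he(fin + cfg$rbf_centers, cfg$hidden)
      params[[paste0("b", l)]] <- numeric(cfg$hidden)
      fin <- cfg$hidden
    }
    hw <- cfg$hidden + if (cfg$head_skip) in_width else 0L
    outw <- if (cfg$head == "classify") cfg$classes else 1L
    params$W_out <- he(hw, outw) * 0.1
    params$b_out <- numeric(outw)
    params
  })
}

# ---- forward / backward ----------------------------------------------------

mpnn_forward_packed <- function(params, pk, cfg, keep_cache = FALSE) {
  src <- pk$edges[, 1]; dst <- pk$edges[, 2]
  d <- sqrt(rowSums((pk$coords[src, , drop = FALSE] -
                       pk$coords[dst, , drop = FALSE])^2))
  RBF <- rbf_expand(d, cfg$rbf_centers, cfg$rbf_max)
  indeg <- tabulate(dst, pk$n)
  wdeg <- if (cfg$aggregation == "mean") pmax(indeg, 1L) else rep(1L, pk$n)

  H <- pk$X
  cache <- list(RBF = RBF, wdeg = wdeg, H0 = H, Hs = list(), Ps = list(),
                Zs = list())
  for (l in seq_len(cfg$layers)) {
    U <- cbind(H[src, , drop = FALSE], RBF)
    P <- rowsum_full(U, dst, pk$n) / wdeg
    Z <- H %*% params[[paste0("W_self", l)]] +
      P %*% params[[paste0("W_msg", l)]] +
      rep(params[[paste0("b", l)]], each = pk$n)
    Hn <- pmax(Z, 0)
    if (keep_cache) {
      cache$Hs[[l]] <- H; cache$Ps[[l]] <- P; cache$Zs[[l]] <- Z
    }
    H <- Hn
  }
  Hh <- if (cfg$head_skip) cbind(H, pk$X) else H
  out <- Hh %*% params$W_out + rep(params$b_out, each = pk$n)
  if (keep_cache) {
    cache$Hh <- Hh
    list(out = out, cache = cache)
  } else list(out = out)
}

mpnn_backward_packed <- function(params, pk, cfg, cache, dout) {
  src <- pk$edges[, 1]; dst <- pk$edges[, 2]
  grads <- list()
  grads$W_out <- crossprod(cache$Hh, dout)
  grads$b_out <- colSums(dout)
  dHh <- dout %*% t(params$W_out)
  L <- cfg$layers
  hidden <- cfg$hidden
  dH <- dHh[, seq_len(hidden), drop = FALSE]   # skip-path grad to X unused
  for (l in rev(seq_len(L))) {
    dZ <- dH * (cache$Zs[[l]] > 0)
    grads[[paste0("W_self", l)]] <- crossprod(cache$Hs[[l]], dZ)
    grads[[paste0("W_msg", l)]] <- crossprod(cache$Ps[[l]], dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dHprev <- dZ %*% t(params[[paste0("W_self", l)]])
      dP <- (dZ %*% t(params[[paste0("W_msg", l)]])) / cache$wdeg
      fin <- ncol(cache$Hs[[l]])
      dU_h <- dP[dst, seq_len(fin), drop = FALSE]
      dHprev <- dHprev + rowsum_full(dU_h, src, pk$n)
      dH <- dHprev
    }
  }
  grads
}

# ---- losses ----------------------------------------------------------------

class_mask <- function(pk, classes) {
  # class c allowed for a node iff c <= its chain's length
  len <- pk$sizes[pk$chain]
  outer(len, seq_len(classes), ">=")
}

masked_softmax <- function(logits, mask) {
  logits[!mask] <- -Inf
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e[!mask] <- 0
  e / rowSums(e)
}

loss_grad <- function(out, labels, cfg, mask = NULL) {
  n <- nrow(out)
  if (cfg$head == "classify") {
    p <- masked_softmax(out, mask)
    picked <- p[cbind(seq_len(n), labels)]
    loss <- -mean(log(pmax(picked, 1e-12)))
    dout <- p
    dout[cbind(seq_len(n), labels)] <- dout[cbind(seq_len(n), labels)] - 1
    list(loss = loss, dout = dout / n)
  } else {
    r <- out[, 1] - labels
    list(loss = mean(r^2), dout = matrix(2 * r / n, ncol = 1L))
  }
}

# ---- fit -------------------------------------------------------------------

#' Fit the reference message-passing network
#'
#' Full-batch Adam on a list of featurised graphs with per-node labels.
#' With a \code{classify} head, labels are 1-based class indices and
#' classes beyond each graph's node count are masked out of the softmax;
#' with a \code{regress} head labels are numeric.
#'
#' @param graphs list of \code{protein_graph}s with node features attached.
#' @param labels list of per-node label vectors, matching \code{graphs}.
#' @param cfg an \code{mpnn_config}.
#' @param eval_graphs,eval_labels optional held-out split evaluated after
#'   training (accuracy for classify, RMSE for regress).
#' @return class \code{mpnn}: list with \code{params}, \code{cfg},
#'   \code{in_width} and \code{report} (final train loss, eval metric,
#'   epochs, seed).
#' @export
mpnn <- function(graphs, labels, cfg, eval_graphs = NULL,
                 eval_labels = NULL) {
  stopifnot(inherits(cfg, "mpnn_config"))
  if (length(graphs) == 0L) stopf("empty training set")
  if (length(graphs) != length(labels))
    stopf("graphs and labels differ in length")
  pk <- pack_graphs(graphs)
  y <- unlist(labels)
  if (length(y) != pk$n) stopf("label count does not match node count")
  if (ncol(pk$X) == 0L) stopf("graphs carry no node features")
  mask <- if (cfg$head == "classify") {
    if (max(y) > cfg$classes)
      stopf("label %d exceeds classes = %d", max(y), cfg$classes)
    class_mask(pk, cfg$classes)
  }
  # regression targets are standardised for optimisation and unscaled at
  # prediction time; the reported loss stays on the standardised scale
  y_mu <- 0; y_sd <- 1
  if (cfg$head == "regress") {
    y_mu <- mean(y); y_sd <- stats::sd(y)
    if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
    y <- (y - y_mu) / y_sd
  }

  params <- mpnn_init(cfg, ncol(pk$X))
  mstate <- lapply(params, function(p) p * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss <- NA_real_
  for (ep in seq_len(cfg$epochs)) {
    fw <- mpnn_forward_packed(params, pk, cfg, keep_cache = TRUE)
    lg <- loss_grad(fw$out, y, cfg, mask)
    loss <- lg$loss
    if (!is.finite(loss))
      stopf("training diverged (non-finite loss) at epoch %d", ep)
    grads <- mpnn_backward_packed(params, pk, cfg, fw$cache, lg$dout)
    for (nm in names(params)) {
      g <- grads[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
      mh <- mstate[[nm]] / (1 - b1^ep)
      vh <- vstate[[nm]] / (1 - b2^ep)
      params[[nm]] <- params[[nm]] - cfg$lr * mh / (sqrt(vh) + eps)
    }
  }

  fit <- structure(list(params = params, cfg = cfg, in_width = ncol(pk$X),
                        y_mu = y_mu, y_sd = y_sd),
                   class = "mpnn")
  eval_metric <- NA_real_
  if (!is.null(eval_graphs)) {
    pred <- predict(fit, eval_graphs)
    ey <- unlist(eval_labels)
    eval_metric <- if (cfg$head == "classify") mean(unlist(pred) == ey)
      else sqrt(mean((unlist(pred) - ey)^2))
  }
  fit$report <- list(final_train_loss = loss, eval_metric = eval_metric,
                     metric_name = if (cfg$head == "classify") "accuracy"
                                   else "rmse",
                     epochs = cfg$epochs, seed = cfg$seed)
  fit
}

#' @export
print.mpnn <- function(x, ...) {
  cat("mpnn: ", x$cfg$layers, " layer(s), hidden=", x$cfg$hidden,
      ", head=", x$cfg$head, ", in_width=", x$in_width, "\n", sep = "")
  cat("  final train loss: ", format(x$report$final_train_loss), "\n",
      sep = "")
  if (is.finite(x$report$eval_metric))
    cat("  eval ", x$report$metric_name, ": ",
        format(x$report$eval_metric), "\n", sep = "")
  invisible(x)
}

#' Per-node predictions from a fitted network
#'
#' @param object an \code{mpnn} fit.
#' @param graphs a \code{protein_graph} or list of them.
#' @param ... unused.
#' @return list of per-node predictions per graph: 1-based class indices
#'   (classify, argmax over the masked softmax) or numeric values
#'   (regress).
#' @export
predict.mpnn <- function(object, graphs, ...) {
  if (inherits(graphs, "protein_graph")) graphs <- list(graphs)
  pk <- pack_graphs(graphs)
  out <- mpnn_forward_packed(object$params, pk, object$cfg)$out
  pred <- if (object$cfg$head == "classify") {
    mask <- class_mask(pk, object$cfg$classes)
    p <- out; p[!mask] <- -Inf
    max.col(p, ties.method = "first")
  } else out[, 1] * (object$y_sd %||% 1) + (object$y_mu %||% 0)
  split(pred, pk$chain)
}

#' Raw per-node network outputs for one or more graphs
#'
#' The forward pass only: logits (classify) or scalars (regress) before
#' any masking or argmax. Outputs depend on node features, edge structure
#' and inter-node distances alone, so they are invariant under any rigid
#' motion or reflection of the coordinates.
#'
#' @param g a \code{protein_graph} or list of them.
#' @param cfg an \code{mpnn_config}.
#' @param params a parameter list shaped per \code{cfg} (as produced
#'   inside \code{mpnn()}), or an \code{mpnn} fit.
#' @return matrix of per-node outputs (rows follow node order).
#' @export
mpnn_forward <- function(g, cfg, params) {
  if (inherits(params, "mpnn")) {
    cfg <- params$cfg; params <- params$params
  }
  pk <- pack_graphs(g)
  if (ncol(pk$X) != nrow(params$W_self1))
    stopf("feature width %d does not match parameters (expect %d)",
          ncol(pk$X), nrow(params$W_self1))
  mpnn_forward_packed(params, pk, cfg)$out
}
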
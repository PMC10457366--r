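# Evaluation statistics for structure-based model assessment.
#
# Ranking metrics follow the model-quality-assessment convention: "global"
# statistics pool every (prediction, truth) row; "mean" statistics are
# computed within each target and averaged across targets. Kendall is the
# tie-corrected tau-b, Spearman is Pearson on average ranks. Docking RMSDs
# default to the fixed-receptor convention: predicted and true complexes
# are compared in the frame where the receptors coincide, with no Kabsch
# superposition of the compared point sets; the Kabsch convention is
# available for cross-checks. All coordinates in Angstrom.

#' Assemble a ranking table
#'
#' @param target_id,model_id identifiers; (target, model) pairs unique.
#' @param pred_score,true_score numeric scores (e.g. predicted and true
#'   GDT-TS).
#' @return class \code{ranking_table} (a data.frame).
#' @export
ranking_table <- function(target_id, model_id, pred_score, true_score) {
  df <- data.frame(target_id = as.character(target_id),
                   model_id = as.character(model_id),
                   pred_score = pred_score, true_score = true_score,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("target_id", "model_id")]))
    stopf("(target_id, model_id) pairs must be unique")
  class(df) <- c("ranking_table", "data.frame")
  df
}

#' Per-target (mean) and pooled (global) ranking correlations
#'
#' Spearman, Pearson and Kendall (tau-b) correlations between predicted
#' and true scores: \code{global_*} on all rows pooled, \code{mean_*}
#' averaged over per-target values. Targets with a single model are
#' excluded from the mean with a warning; targets where either score is
#' constant contribute 0 with a warning.
#'
#' @param t a \code{ranking_table} (or data.frame with the same columns).
#' @return named list: \code{mean_RS}, \code{global_RS}, \code{mean_RP},
#'   \code{global_RP}, \code{mean_KR}, \code{global_KR}.
#' @export
rank_correlations <- function(t) {
  if (nrow(t) < 2L) stopf("need at least 2 rows for global correlations")
  cor3 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warnf("constant scores: correlations set to 0")
      return(c(RS = 0, RP = 0, KR = 0))
    }
    c(RS = stats::cor(x, y, method = "spearman"),
      RP = stats::cor(x, y, method = "pearson"),
      KR = stats::cor(x, y, method = "kendall"))
  }
  g <- cor3(t$pred_score, t$true_score)
  per <- lapply(split(t, t$target_id), function(d) {
    if (nrow(d) < 2L) {
      warnf("target '%s' has a single model: excluded from mean correlations",
            d$target_id[1])
      return(NULL)
    }
    cor3(d$pred_score, d$true_score)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, TRUE)])
  if (is.null(per)) stopf("no target with >= 2 models")
  m <- colMeans(per)
  list(mean_RS = unname(m["RS"]), global_RS = unname(g["RS"]),
       mean_RP = unname(m["RP"]), global_RP = unname(g["RP"]),
       mean_KR = unname(m["KR"]), global_KR = unname(g["KR"]))
}

#' First rank loss
#'
#' For each target, the difference between the true score of the truly
#' best model and the true score of the model ranked first by the
#' predictions (prediction ties broken by smaller model id), averaged
#' over targets. Zero iff the predicted top model attains the target's
#' best true score everywhere.
#'
#' @param t a \code{ranking_table}.
#' @export
first_rank_loss <- function(t) {
  if (nrow(t) == 0L) stopf("empty ranking table")
  losses <- vapply(split(t, t$target_id), function(d) {
    top <- d[order(-d$pred_score, d$model_id), ][1L, ]
    max(d$true_score) - top$true_score
  }, 0)
  mean(losses)
}

#' Area under the ROC curve
#'
#' Mann-Whitney pair-counting definition: the probability that a random
#' positive outranks a random negative, score ties counted one half
#' (equivalently the tie-corrected rank-sum statistic).
#'
#' @param labels binary labels (0/1 or logical), both classes present.
#' @param scores numeric scores, higher = more positive.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores)) stopf("labels/scores length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("AUROC undefined: both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binding affinity to pK
#'
#' pK = -log10(K) with K the binding affinity in Molar units; strictly
#' decreasing in K.
#'
#' @param K binding affinity, Molar, > 0.
#' @export
pk_from_affinity <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stopf("affinity K must be positive and finite (Molar units)")
  -log10(K)
}

#' Root mean squared error
#'
#' @param pred,true equal-length numeric vectors.
#' @export
rmse <- function(pred, true) {
  if (length(pred) != length(true) || length(pred) == 0L)
    stopf("pred and true must have equal positive length")
  sqrt(mean((pred - true)^2))
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation of P onto Q
#' (SVD solution, rotation determinant forced to +1) and the resulting
#' RMSD. Row vectors: the superposed copy of P is
#' \code{P \%*\% rotation + translation} (each row offset).
#'
#' @param P,Q N x 3 matrices, N >= 3, paired rows.
#' @return list with \code{rotation} (3 x 3, det +1),
#'   \code{translation} (length 3) and \code{rmsd}.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stopf("P and Q must be equal-shape N x 3 matrices")
  if (nrow(P) < 3L) stopf("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  C <- crossprod(Pc, Qc)
  sv <- svd(C)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    warnf("degenerate (collinear) point set: superposition not unique")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  rmsd_val <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - cp %*% R),
       rmsd = rmsd_val)
}

#' Interface residues of a complex
#'
#' Indices (1-based) of receptor and ligand residues participating in any
#' cross-molecule Calpha pair strictly closer than the cutoff, computed
#' on the ground-truth complex.
#'
#' @param rec,lig N x 3 Calpha coordinate matrices.
#' @param cutoff Angstrom (default 8, strict \code{<}).
#' @return list with \code{rec} and \code{lig} index vectors (possibly
#'   empty).
#' @export
interface_residues <- function(rec, lig, cutoff = 8.0) {
  rec <- as.matrix(rec); lig <- as.matrix(lig)
  if (nrow(rec) == 0L || nrow(lig) == 0L) stopf("empty coordinate set")
  D <- cross_dist(rec, lig)
  hit <- D < cutoff
  list(rec = which(rowSums(hit) > 0), lig = which(colSums(hit) > 0))
}

#' Bundle a docking complex for evaluation
#'
#' @param receptor N_r x 3 receptor Calpha coordinates (shared frame:
#'   the receptor is fixed during evaluation).
#' @param ligand_true,ligand_pred N_l x 3 true and predicted ligand
#'   coordinates, identical node ordering.
#' @return class \code{complex_pair}.
#' @export
complex_pair <- function(receptor, ligand_true, ligand_pred) {
  receptor <- as.matrix(receptor)
  ligand_true <- as.matrix(ligand_true)
  ligand_pred <- as.matrix(ligand_pred)
  if (!all(dim(ligand_true) == dim(ligand_pred)))
    stopf("predicted and true ligand must match in node count and order")
  structure(list(receptor = receptor, ligand_true = ligand_true,
                 ligand_pred = ligand_pred), class = "complex_pair")
}

#' Docking RMSD family
#'
#' \code{fixed_receptor} (default): the receptor frame is shared, so
#' ligand, complex and interface RMSDs are computed directly, with no
#' superposition of the compared point sets. \code{kabsch}: each compared
#' point set is optimally superposed first (the protocol used for
#' cross-checking). Interface residues come from
#' \code{\link{interface_residues}} on the ground-truth complex.
#'
#' @param c a \code{complex_pair}.
#' @param convention \code{"fixed_receptor"} or \code{"kabsch"}.
#' @param cutoff interface cutoff, Angstrom.
#' @return list with \code{complex_rmsd}, \code{ligand_rmsd},
#'   \code{interface_rmsd}.
#' @export
docking_rmsds <- function(c, convention = c("fixed_receptor", "kabsch"),
                          cutoff = 8.0) {
  stopifnot(inherits(c, "complex_pair"))
  convention <- match.arg(convention)
  iface <- interface_residues(c$receptor, c$ligand_true, cutoff)

  true_cplx <- rbind(c$receptor, c$ligand_true)
  pred_cplx <- rbind(c$receptor, c$ligand_pred)
  iface_true <- rbind(c$receptor[iface$rec, , drop = FALSE],
                      c$ligand_true[iface$lig, , drop = FALSE])
  iface_pred <- rbind(c$receptor[iface$rec, , drop = FALSE],
                      c$ligand_pred[iface$lig, , drop = FALSE])

  pair_rmsd <- function(A, B) {
    if (nrow(A) == 0L) return(NA_real_)
    if (convention == "kabsch" && nrow(A) >= 3L) kabsch(A, B)$rmsd
    else sqrt(mean(rowSums((A - B)^2)))
  }
  list(complex_rmsd = pair_rmsd(pred_cplx, true_cplx),
       ligand_rmsd = pair_rmsd(c$ligand_pred, c$ligand_true),
       interface_rmsd = pair_rmsd(iface_pred, iface_true))
}
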
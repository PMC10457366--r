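toy_table <- function(targets, models_per_target, seed = 1) {
  set.seed(seed)
  tid <- rep(paste0("T", seq_len(targets)), each = models_per_target)
  mid <- rep(sprintf("m%02d", seq_len(models_per_target)), targets)
  ranking_table(tid, mid, pred_score = round(runif(length(tid)), 2),
                true_score = round(runif(length(tid)), 2))
}

test_that("perfect and inverted predictions give the boundary correlations", {
  t <- ranking_table(rep("T1", 4), paste0("m", 1:4),
                     pred_score = c(0.1, 0.4, 0.7, 0.9),
                     true_score = c(0.1, 0.4, 0.7, 0.9))
  res <- rank_correlations(t)
  expect_equal(unlist(res), rep(1, 6), ignore_attr = TRUE)
  t$pred_score <- -t$true_score
  res <- rank_correlations(t)
  expect_equal(res$global_RS, -1)
  expect_equal(res$mean_KR, -1)
})

test_that("Kendall matches brute-force tau-b on all short permutations", {
  for (n in 2:5) {
    ref <- seq_len(n)
    for (p in all_perms(n)) {
      t <- ranking_table(rep("T", n), sprintf("m%d", ref),
                         pred_score = as.numeric(p), true_score = ref)
      expect_equal(rank_correlations(t)$global_KR, kendall_brute(p, ref),
                   tolerance = 1e-12)
    }
  }
  # with ties
  set.seed(8)
  for (i in 1:25) {
    x <- sample(1:3, 6, TRUE); y <- sample(1:3, 6, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    t <- ranking_table(rep("T", 6), sprintf("m%d", 1:6), x, y)
    expect_equal(rank_correlations(t)$global_KR, kendall_brute(x, y),
                 tolerance = 1e-12)
    expect_equal(rank_correlations(t)$global_RS, spearman_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("mean correlations average per-target values, global pools rows", {
  t <- ranking_table(rep(c("T1", "T2"), each = 3),
                     rep(paste0("m", 1:3), 2),
                     pred_score = c(1, 2, 3, 3, 2, 1),
                     true_score = c(1, 2, 3, 1, 2, 3))
  res <- rank_correlations(t)
  expect_equal(res$mean_RS, 0)            # (+1 - 1) / 2
  # pooled: perfect and inverted halves cancel
  expect_equal(res$global_RS, spearman_brute(c(1, 2, 3, 3, 2, 1),
                                             c(1, 2, 3, 1, 2, 3)),
               tolerance = 1e-12)
})

test_that("degenerate targets warn: constant scores 0, singletons excluded", {
  t <- ranking_table(c("T1", "T1", "T2", "T2", "T3"),
                     c("a", "b", "a", "b", "a"),
                     pred_score = c(1, 2, 5, 5, 1),
                     true_score = c(1, 2, 1, 2, 1))
  w <- capture_warnings(res <- rank_correlations(t))
  expect_true(any(grepl("constant", w)))
  expect_true(any(grepl("single", w)))
  # T1 contributes 1, T2 (constant preds) contributes 0, T3 is excluded
  expect_equal(suppressWarnings(rank_correlations(t))$mean_RS, 0.5)
})

test_that("first rank loss follows its definition", {
  t <- ranking_table(rep("T1", 2), c("m1", "m2"),
                     pred_score = c(0.1, 0.9), true_score = c(0.9, 0.5))
  expect_equal(first_rank_loss(t), 0.4)
  # predicted top is the true best everywhere -> 0
  t2 <- toy_table(4, 5, seed = 2)
  t2$pred_score <- t2$true_score
  expect_equal(first_rank_loss(t2), 0)
  for (seed in 1:10) {
    t3 <- toy_table(sample(2:4, 1), sample(2:6, 1), seed = seed)
    expect_equal(first_rank_loss(t3), frl_brute(t3))
    expect_gte(first_rank_loss(t3), 0)
  }
  expect_error(first_rank_loss(t[0, ]), "empty")
})

test_that("prediction ties in first rank loss break to the smaller model id", {
  t <- ranking_table(rep("T1", 3), c("m1", "m2", "m3"),
                     pred_score = c(0.5, 0.5, 0.1),
                     true_score = c(0.2, 0.9, 0.9))
  # m1 and m2 tie on pred; m1 (smaller id) is chosen -> loss 0.9 - 0.2
  expect_equal(first_rank_loss(t), 0.7)
})

test_that("AUROC equals exhaustive pair counting, ties counted half", {
  expect_equal(auroc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(2, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(1, 2)), "both classes")
  set.seed(14)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(1:4, n, TRUE)       # heavy ties
    expect_equal(auroc(labels, scores), auroc_brute(labels, scores),
                 tolerance = 1e-12)
    if (!any(duplicated(scores)))
      expect_equal(auroc(labels, scores) + auroc(labels, -scores), 1)
  }
})

test_that("pK transform is exact and strictly decreasing", {
  expect_identical(pk_from_affinity(1e-9), 9)
  expect_identical(pk_from_affinity(1), 0)
  K <- sort(10^runif(20, -12, 0))
  expect_true(all(diff(pk_from_affinity(K)) < 0))
  expect_error(pk_from_affinity(0), "positive")
  expect_error(pk_from_affinity(-2), "positive")
})

test_that("rmse matches its definition", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5 + 2, 1:5), 2)
  set.seed(4)
  for (i in 1:10) {
    p <- rnorm(sample(2:10, 1)); t <- rnorm(length(p))
    expect_equal(rmse(p, t), sqrt(sum((p - t)^2) / length(p)),
                 tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "equal")
})

test_that("Kabsch recovers rigid transforms to numerical precision", {
  set.seed(31)
  for (i in 1:10) {
    P <- random_coords(sample(4:10, 1))
    Q <- rigid_transform(P)
    kb <- kabsch(P, Q)
    expect_lt(kb$rmsd, 1e-6)
    expect_equal(det(kb$rotation), 1, tolerance = 1e-9)
    expect_equal(sweep(P %*% kb$rotation, 2, -kb$translation), Q,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  kb0 <- kabsch(P, P)
  expect_equal(kb0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(kb0$translation, rep(0, 3), tolerance = 1e-9)
  expect_lt(kb0$rmsd, 1e-12)
})

test_that("the rotation stays proper even against reflected targets", {
  set.seed(32)
  P <- random_coords(8)
  Q <- P; Q[, 1] <- -Q[, 1]              # improper image
  kb <- kabsch(P, Q)
  expect_equal(det(kb$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD lower-bounds any rigid superposition", {
  set.seed(33)
  P <- random_coords(8); Q <- random_coords(8)
  best <- kabsch(P, Q)$rmsd
  for (i in 1:1000) {
    Pt <- rigid_transform(P)
    expect_gte(sqrt(mean(rowSums((Pt - Q)^2))) + 1e-9, best)
  }
})

test_that("collinear points warn but still return a solution", {
  P <- cbind(1:5, 0, 0)
  Q <- cbind(1:5 * 2, 0, 0)
  expect_warning(kb <- kabsch(P, Q), "collinear|degenerate")
  expect_true(is.finite(kb$rmsd))
})

test_that("Kabsch RMSD agrees with the bio3d fitted RMSD", {
  set.seed(34)
  P <- random_coords(10); Q <- random_coords(10)
  ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(kabsch(P, Q)$rmsd, ref, tolerance = 1e-3)
})

test_that("interface extraction is a strict-< cross-distance filter", {
  rec <- rbind(c(0, 0, 0), c(50, 0, 0))
  lig <- rbind(c(7.9, 0, 0), c(100, 0, 0))
  ifc <- interface_residues(rec, lig, cutoff = 8)
  expect_equal(ifc$rec, 1); expect_equal(ifc$lig, 1)
  lig2 <- rbind(c(8.0, 0, 0), c(100, 0, 0))
  ifc2 <- interface_residues(rec, lig2, cutoff = 8)
  expect_length(ifc2$rec, 0); expect_length(ifc2$lig, 0)
  set.seed(41)
  for (i in 1:10) {
    r <- random_coords(sample(3:15, 1), 15)
    l <- random_coords(sample(3:15, 1), 15)
    expect_equal(lapply(interface_residues(r, l, 8), as.integer),
                 interface_brute(r, l, 8))
  }
})

test_that("docking RMSDs follow the fixed-receptor convention", {
  set.seed(51)
  rec <- random_coords(12, 20)
  lig <- sweep(random_coords(10, 8), 2, c(12, 0, 0), "+")
  cp0 <- complex_pair(rec, lig, lig)
  r0 <- docking_rmsds(cp0)
  expect_equal(unlist(r0), c(0, 0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unlist(docking_rmsds(cp0, "kabsch")), c(0, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-7)

  tvec <- c(1.5, -2, 0.5)
  cp <- complex_pair(rec, lig, sweep(lig, 2, tvec, "+"))
  r <- docking_rmsds(cp, "fixed_receptor")
  expect_equal(r$ligand_rmsd, sqrt(sum(tvec^2)), tolerance = 1e-9)
  rk <- docking_rmsds(cp, "kabsch")
  expect_lt(rk$ligand_rmsd, 1e-7)        # translation is superposed away
  expect_error(complex_pair(rec, lig, lig[1:5, ]), "match")
})

test_that("fixed-receptor RMSDs dominate Kabsch RMSDs", {
  set.seed(52)
  for (i in 1:10) {
    rec <- random_coords(8, 15)
    lig <- sweep(random_coords(6, 6), 2, c(10, 0, 0), "+")
    pred <- lig + matrix(rnorm(18, sd = 2), 6, 3)
    cp <- complex_pair(rec, lig, pred)
    rf <- docking_rmsds(cp, "fixed_receptor")
    rk <- docking_rmsds(cp, "kabsch")
    for (k in names(rf))
      if (is.finite(rf[[k]]) && is.finite(rk[[k]]))
        expect_gte(rf[[k]] + 1e-9, rk[[k]])
  }
})

test_that("interface RMSD ignores perturbations of non-interface residues", {
  rec <- rbind(c(0, 0, 0), c(4, 0, 0), c(60, 0, 0))
  lig <- rbind(c(7, 0, 0), c(70, 0, 0))
  cp <- complex_pair(rec, lig, lig)
  base <- docking_rmsds(cp)$interface_rmsd
  pred <- lig; pred[2, ] <- pred[2, ] + 25      # far from the interface
  cp2 <- complex_pair(rec, lig, pred)
  expect_equal(docking_rmsds(cp2)$interface_rmsd, base)
  expect_gt(docking_rmsds(cp2)$ligand_rmsd, 0)
})
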
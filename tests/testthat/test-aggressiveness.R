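test_that("classifier gene selection follows the three-stage chain", {
  tab <- data.frame(cluster = "T00", gene = paste0("gene", 1:5),
                    log_fc = c(1.0, 0.8, 0.7, 0.9, 2.0),
                    p_value = c(.001, .004, .001, .02, .0001),
                    adj_p = c(.01, .04, .01, .2, .001),
                    pct_in = 1, pct_out = 0.2)
  bulk_genes <- paste0("gene", 1:4)  # bulk misses gene5
  sel <- select_classifier_genes(tab, bulk_genes)
  expect_equal(sel$selection_log$tested, 5L)
  expect_equal(sel$selection_log$passing_filter, 3L)
  expect_equal(sel$selection_log$bulk_detected, 2L)
  expect_setequal(sel$genes, c("gene1", "gene2"))
  expect_equal(sel$selection_log$min_log_fc, 0.75)
  expect_equal(sel$selection_log$max_adj_p, 0.05)

  # bulk covering everything makes stage 3 a no-op
  sel2 <- select_classifier_genes(tab, tab$gene)
  expect_equal(sel2$selection_log$bulk_detected, sel2$selection_log$passing_filter)

  expect_error(select_classifier_genes(tab[0, ], bulk_genes), "no rows")
  strict <- tab; strict$adj_p <- 0.9
  expect_error(select_classifier_genes(strict, bulk_genes), "filter")
})

test_that("quantile normalization equalizes sample distributions exactly", {
  x <- rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  colnames(x) <- paste0("g", 1:3)
  qn <- quantile_normalize(x)
  expect_equal(unname(qn[1, ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[2, ]), c(2.5, 3.5, 4.5))

  set.seed(12)
  y <- matrix(rnorm(8 * 40), 8, 40)
  qy <- quantile_normalize(y)
  ref <- sort(qy[1, ])
  for (i in 2:8) expect_equal(sort(qy[i, ]), ref, tolerance = 1e-12)
})

test_that("KNN imputation recovers masked entries of replicated-profile matrices", {
  # constant matrix: a masked entry comes back as the constant
  const <- matrix(5, 6, 15, dimnames = list(paste0("s", 1:6), paste0("g", 1:15)))
  const[2, 3] <- NA
  expect_equal(impute_knn(const, k = 10)[2, 3], 5)

  # noiseless rank-1 matrix with replicated gene profiles: exact recovery
  vals <- replicated_rank1(seed = 33)
  set.seed(34)
  mask <- matrix(runif(length(vals)) < 0.05, nrow(vals))
  masked <- vals
  masked[mask] <- NA
  imp <- impute_knn(masked, k = 10)
  expect_lt(max(abs(imp[mask] - vals[mask])), 1e-6)
  expect_false(anyNA(imp))

  allna <- vals; allna[, 1] <- NA
  expect_error(impute_knn(allna), "missing in all samples")
})

test_that("bulk and single-cell harmonization deliver matched z-score scales", {
  v <- rbind(c(1, 2, 3), c(4, 4, 4))
  nm <- make_nm(v, genes = c("gA", "gB"), cells = c("c1", "c2", "c3"))
  z <- harmonize_sc(nm, c("gA", "gB"))
  expect_equal(unname(z[, "gA"]), c(-1, 0, 1))
  expect_equal(unname(z[, "gB"]), c(0, 0, 0))  # constant gene -> zero column

  set.seed(44)
  vals <- matrix(rlnorm(10 * 30), 10, 30,
                 dimnames = list(sprintf("s%02d", 1:10), sprintf("g%02d", 1:30)))
  vals[1, 2] <- NA
  cohort <- bulk_cohort(vals, rownames(vals), colnames(vals))
  z2 <- harmonize_bulk(cohort, colnames(vals)[1:5], k_impute = 5)
  expect_lt(max(abs(colMeans(z2))), 1e-8)
  expect_lt(max(abs(apply(z2, 2, sd) - 1)), 1e-8)
  expect_equal(colnames(z2), colnames(vals)[1:5])
  expect_error(harmonize_bulk(cohort, "nonexistent"), "absent")
})

test_that("the ensemble separates separable classes and stays symmetric on nulls", {
  set.seed(50)
  x <- matrix(c(rnorm(60, 3), rnorm(140, -3)), ncol = 1)
  colnames(x) <- "feat"
  labels <- c(rep("aggressive", 60), rep("non_aggressive", 140))
  model <- train_classifier(x, labels, n_trees = 200, n_pos = 50, n_neg = 50,
                            seed = 1)
  xb <- matrix(c(3, -3), ncol = 1, dimnames = list(c("hot", "cold"), "feat"))
  pred <- predict_aggressiveness(model, xb)
  expect_gt(pred$p_aggressive[pred$sample_id == "hot"], 0.9)
  expect_lt(pred$p_aggressive[pred$sample_id == "cold"], 0.1)
  expect_equal(pred$p_aggressive + pred$p_non_aggressive, rep(1, 2))
  expect_equal(pred$rank[order(-pred$p_aggressive)], 1:2)

  # shuffled labels carry no signal: out-of-sample AUC near 0.5
  set.seed(51)
  xn <- matrix(rnorm(300 * 4), 300, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    lab <- sample(rep(c("aggressive", "non_aggressive"), each = 150))
    fit <- train_classifier(xn[1:200, ], lab[1:200], n_trees = 100,
                            n_pos = 50, n_neg = 50, seed = s)
    newx <- xn[201:300, ]
    rownames(newx) <- paste0("s", 1:100)
    p <- predict_aggressiveness(fit, newx)$p_aggressive
    pos <- lab[201:300] == "aggressive"
    (sum(rank(p)[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)

  expect_error(train_classifier(x, rep("aggressive", 200)), "both classes")
  wrong <- xb; colnames(wrong) <- "other"
  expect_error(predict_aggressiveness(model, wrong), "feature order")
})

test_that("training is seed-deterministic and permutation-consistent", {
  set.seed(60)
  x <- matrix(rnorm(150 * 6), 150, 6, dimnames = list(NULL, paste0("f", 1:6)))
  labels <- rep(c("aggressive", "non_aggressive"), times = c(50, 100))
  m1 <- train_classifier(x, labels, n_trees = 100, n_pos = 40, n_neg = 40, seed = 9)
  m2 <- train_classifier(x, labels, n_trees = 100, n_pos = 40, n_neg = 40, seed = 9)
  newx <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(paste0("s", 1:10), paste0("f", 1:6)))
  expect_identical(predict_aggressiveness(m1, newx)$p_aggressive,
                   predict_aggressiveness(m2, newx)$p_aggressive)

  # a consistent feature-column permutation of training and prediction data
  # leaves the learned decision intact (separable problem)
  set.seed(61)
  xs <- cbind(sig = c(rnorm(50, 3), rnorm(100, -3)),
              matrix(rnorm(150 * 5), 150, 5,
                     dimnames = list(NULL, paste0("n", 1:5))))
  labs <- rep(c("aggressive", "non_aggressive"), times = c(50, 100))
  newxs <- matrix(c(3, -3, rep(0, 10)), 2, 6,
                  dimnames = list(c("hot", "cold"), colnames(xs)))
  perm <- c(4, 2, 6, 1, 3, 5)
  mo <- train_classifier(xs, labs, n_trees = 200, n_pos = 40, n_neg = 40, seed = 9)
  mp <- train_classifier(xs[, perm], labs, n_trees = 200, n_pos = 40,
                         n_neg = 40, seed = 9)
  po <- predict_aggressiveness(mo, newxs)
  pp <- predict_aggressiveness(mp, newxs[, perm])
  expect_equal(pp$p_aggressive, po$p_aggressive, tolerance = 0.1)
  expect_identical(order(-pp$p_aggressive), order(-po$p_aggressive))
})
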
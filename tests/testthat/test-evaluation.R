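test_that("confusion counts partition the records and use the >= tie rule", {
  set.seed(10)
  for (rep in 1:10) {
    preds <- random_preds(sample(20:100, 1), seed = rep)
    cc <- confusion(preds)
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, nrow(preds))
  }
  perfect <- data.frame(score = c(1, 1, 0, 0), label = c(1L, 1L, 0L, 0L))
  cc <- confusion(perfect)
  expect_equal(cc$fp, 0L); expect_equal(cc$fn, 0L)
  # all scores exactly at the threshold predict positive
  ties <- data.frame(score = rep(0.5, 6), label = rep(0:1, 3))
  cc <- confusion(ties)
  expect_equal(cc$tn + cc$fn, 0L)
  expect_equal(cc$tp + cc$fp, 6L)
})

test_that("metrics implement the five defining equations exactly", {
  cc <- structure(list(tp = 7L, fp = 3L, tn = 5L, fn = 5L), class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 0.60)
  expect_equal(m$precision, 0.70)
  expect_equal(m$sensitivity, 7 / 12, tolerance = 1e-12)
  expect_equal(m$specificity, 0.625)
  expect_equal(m$f1, 2 * 0.7 * (7 / 12) / (0.7 + 7 / 12), tolerance = 1e-12)
  expect_equal(round(m$sensitivity, 4), 0.5833)
  expect_equal(round(m$f1, 4), 0.6364)
  perfect <- classification_metrics(
    structure(list(tp = 50L, fp = 0L, tn = 50L, fn = 0L), class = "confusion_counts"))
  for (k in c("accuracy", "precision", "sensitivity", "specificity", "f1"))
    expect_equal(perfect[[k]], 1.0)
})

test_that("metric identities hold on random confusion counts", {
  set.seed(22)
  for (rep in 1:20) {
    cc <- structure(as.list(stats::setNames(sample(1:200, 4, replace = TRUE),
                                            c("tp", "fp", "tn", "fn"))),
                    class = "confusion_counts")
    m <- classification_metrics(cc)
    total <- cc$tp + cc$fp + cc$tn + cc$fn
    expect_equal(m$accuracy * total, cc$tp + cc$tn, tolerance = 1e-12)
    # F1 is the harmonic mean of precision and sensitivity
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$sensitivity), tolerance = 1e-12)
  }
})

test_that("undefined metrics are flagged, never silent zeros", {
  cc <- structure(list(tp = 0L, fp = 0L, tn = 10L, fn = 5L), class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_true(is.na(m$precision))
  expect_true("precision" %in% m$undefined)
  expect_false("accuracy" %in% m$undefined)
  expect_error(classification_metrics(
    structure(list(tp = 0L, fp = 0L, tn = 0L, fn = 0L), class = "confusion_counts")),
    "zero")
})

test_that("auroc matches its definition on worked examples", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1L, 0L, 1L, 0L)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(1L, 1L, 0L, 0L)), 1.0)
  expect_equal(auroc(rep(0.4, 10), rep(0:1, 5)), 0.5)
  expect_error(auroc(c(0.1, 0.9), c(1L, 1L)), "both classes")
})

test_that("auroc equals the O(n^2) pair-counting oracle on random instances", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(4:200, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(auroc(scores, labels), auc_pair_count(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auroc agrees with pROC on a reference case", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- sample(0:1, 80, replace = TRUE)
  scores <- runif(80) + 0.4 * labels
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("DeLong test degenerates and symmetrises correctly", {
  preds <- random_preds(40, seed = 1, score_fn = function(l) runif(length(l)) + 0.3 * l)
  self <- delong_test(preds, preds)
  expect_equal(self$p_value, 1)
  other <- random_preds(40, seed = 1)
  other$score <- runif(40)
  ab <- delong_test(preds, other)
  ba <- delong_test(other, preds)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_true(ab$p_value >= 0 && ab$p_value <= 1)
})

test_that("DeLong agrees with pROC's implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  preds_a <- random_preds(120, seed = 9,
                          score_fn = function(l) (runif(length(l)) + 0.5 * l) / 1.5)
  preds_b <- preds_a
  preds_b$score <- (runif(120) + 0.2 * preds_a$label) / 1.2
  ours <- delong_test(preds_a, preds_b)
  ref <- pROC::roc.test(
    pROC::roc(preds_a$label, preds_a$score, quiet = TRUE),
    pROC::roc(preds_b$label, preds_b$score, quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(ours$statistic), abs(unname(ref$statistic)), tolerance = 1e-9)
})

test_that("DeLong p is close to a label-preserving bootstrap on a small fixture", {
  # n = 30 fixture with a clear AUC difference, where the normal
  # approximation and the bootstrap are both in their agreement regime
  preds_a <- random_preds(30, seed = 30,
                          score_fn = function(l) 0.15 * runif(length(l)) + 0.75 * l)
  preds_b <- preds_a
  set.seed(31)
  preds_b$score <- runif(30)
  ours <- delong_test(preds_a, preds_b)
  boot <- bootstrap_auc_diff_p(preds_a$score, preds_b$score, preds_a$label,
                               reps = 2e4, seed = 7)
  expect_lt(abs(ours$p_value - boot), 0.02)
})

test_that("unpairable or label-inconsistent predictions are rejected by name", {
  a <- random_preds(10, seed = 2)
  b <- a; b$tile_id[3] <- "zzz"
  expect_error(delong_test(a, b), "t003|zzz")
  b2 <- a; b2$label[4] <- 1L - b2$label[4]
  expect_error(mcnemar_test(a, b2), "labels")
})

test_that("McNemar exact p matches binomial tail enumeration", {
  a <- random_preds(4, seed = 3)
  # direct worked example: b = 3, c = 1
  expect_equal(hawkshead:::mcnemar_exact_p(3, 1), 0.625)
  expect_equal(hawkshead:::mcnemar_exact_p(0, 0), 1)
  for (b in 0:10) for (cc in 0:10) {
    if (b + cc > 20) next
    expect_equal(hawkshead:::mcnemar_exact_p(b, cc), mcnemar_enum_p(b, cc),
                 tolerance = 1e-12, info = paste(b, cc))
  }
})

test_that("McNemar counts discordant pairs and is symmetric under model swap", {
  labels <- rep(c(0L, 1L), each = 10)
  a <- data.frame(tile_id = sprintf("t%02d", 1:20), score = ifelse(labels == 1, 0.9, 0.1),
                  label = labels, stringsAsFactors = FALSE)
  b <- a
  a$score[1:4] <- 0.9   # model A wrong on 4 negatives that B gets right
  b$score[11:12] <- 0.1 # model B wrong on 2 positives that A gets right
  ab <- mcnemar_test(a, b)
  expect_equal(ab$b, 4L)
  expect_equal(ab$c, 2L)
  ba <- mcnemar_test(b, a)
  expect_equal(ba$b, 2L)
  expect_equal(ba$c, 4L)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  # identical models have no discordant pairs
  self <- mcnemar_test(a, a)
  expect_equal(self$b + self$c, 0L)
  expect_equal(self$p_value, 1)
})

test_that("the large-count case from the comparison table is highly significant", {
  expect_lt(hawkshead:::mcnemar_exact_p(954, 630), 0.001)
})

test_that("the chi-square variant approximates the exact test for large counts", {
  a <- random_preds(10, seed = 4)
  chi <- function(b, c) {
    labels <- rep(c(0L, 1L), each = b + c)
    n <- 2 * (b + c)
    pa <- data.frame(tile_id = sprintf("t%04d", 1:n),
                     score = ifelse(labels == 1, 0.9, 0.1), label = labels,
                     stringsAsFactors = FALSE)
    pb <- pa
    pa$score[seq_len(b)] <- 0.9
    pb$score[b + seq_len(c)] <- 0.9
    mcnemar_test(pa, pb, method = "chisq")
  }
  res <- chi(120, 80)
  expect_equal(res$b, 120L)
  expect_equal(res$c, 80L)
  exact <- hawkshead:::mcnemar_exact_p(120, 80)
  expect_lt(abs(res$p_value - exact) / exact, 0.15)
})
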
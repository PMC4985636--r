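test_that("dG = RT ln Kd with the stated gas constant", {
  expect_equal(delta_g_from_kd(1, 300), 0)
  expect_equal(delta_g_from_kd(1e-6, 300), -8.234, tolerance = 0.01 / 8.234)
  # halving Kd lowers dG by exactly RT ln 2
  t <- 310
  expect_equal(delta_g_from_kd(5e-7, t) - delta_g_from_kd(1e-6, t),
               -1.987204e-3 * t * log(2))
  expect_error(delta_g_from_kd(0), class = "ptb_error_domain")
  expect_error(delta_g_from_kd(-1e-6), class = "ptb_error_domain")
})

test_that("pearson matches cor.test and handles exact linearity", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -3 * x + 2)$r, -1)
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(8 + i)
    b <- 0.5 * a + rnorm(8 + i)
    ct <- cor.test(a, b)
    p <- pearson(a, b)
    expect_equal(p$r, unname(ct$estimate))
    expect_equal(p$p_value, ct$p.value, tolerance = 1e-12)
    expect_equal(tidy(p)$p.value, ct$p.value, tolerance = 1e-12)
  }
  expect_error(pearson(1:5, rep(2, 5)), class = "ptb_error_degenerate")
  expect_error(pearson(1:4, 1:5), class = "ptb_error_contract")
})

test_that("the printed affinity panel reproduces the published correlations", {
  t1 <- table1_panel()
  mm <- pearson(t1$delta_g, t1$pbtot)
  pp <- pearson(t1$delta_g, t1$pp_score)
  expect_equal(round(mm$r, 2), 0.63)
  expect_equal(round(pp$r, 2), 0.85)
  expect_equal(pp$p_value, 0.03, tolerance = 0.005 / 0.03)
  expect_equal(pp$n, 6)
})

test_that("confusion counts use a strict threshold and conserve marginals", {
  sc <- tibble::tibble(score = c(-2, 1), label = c("binder", "nonbinder"))
  cm <- confusion_at(sc, 0)
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 0, tn = 1, fn = 0))

  # threshold below every score: nothing predicted positive
  set.seed(11)
  sc4 <- tibble::tibble(score = c(-1.5, -0.5, -0.5, 2),
                        label = c("binder", "nonbinder", "binder",
                                  "nonbinder"))
  low <- confusion_at(sc4, min(sc4$score) - 1)
  expect_equal(low$tp + low$fp, 0)
  expect_equal(low$fn, 2)
  expect_equal(low$tn, 2)

  # sweep at each observed score matches exhaustive tabulation, with
  # marginals conserved (ties at the threshold predicted non-binder)
  for (th in unique(sc4$score)) {
    cm <- confusion_at(sc4, th)
    expect_equal(cm$tp, sum(sc4$score < th & sc4$label == "binder"))
    expect_equal(cm$fp, sum(sc4$score < th & sc4$label == "nonbinder"))
    expect_equal(cm$tp + cm$fn, 2)
    expect_equal(cm$fp + cm$tn, 2)
  }
})

test_that("ROC endpoints, known areas, and tie handling are correct", {
  roc1 <- roc_curve(tibble::tibble(score = c(-3, -2, 1, 2),
                                   label = rep(c("binder", "nonbinder"),
                                               each = 2)))
  expect_equal(roc1$auc, 1)
  expect_equal(roc1$points$fpr[1], 0)
  expect_equal(roc1$points$tpr[1], 0)
  expect_equal(tail(roc1$points$fpr, 1), 1)
  expect_equal(tail(roc1$points$tpr, 1), 1)
  expect_false(is.unsorted(roc1$points$tpr))

  # 3 concordant of 4 binder/non-binder pairs
  roc2 <- roc_curve(tibble::tibble(score = c(-2, 0, -1, 1),
                                   label = c("binder", "binder",
                                             "nonbinder", "nonbinder")))
  expect_equal(roc2$auc, 0.75)

  # all scores equal: half credit, AUC exactly 0.5
  roc3 <- roc_curve(tibble::tibble(score = rep(2, 6),
                                   label = rep(c("binder", "nonbinder"), 3)))
  expect_equal(roc3$auc, 0.5)

  expect_error(roc_curve(tibble::tibble(score = 1:3,
                                        label = rep("binder", 3))),
               class = "ptb_error_degenerate")
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(123)
  for (i in 1:100) {
    n1 <- sample(2:50, 1)
    n2 <- sample(2:50, 1)
    scores <- tibble::tibble(
      # integer scores force plenty of cross-class ties
      score = c(round(rnorm(n1, -1), 0), round(rnorm(n2, 0), 0)),
      label = rep(c("binder", "nonbinder"), c(n1, n2)))
    expect_equal(roc_curve(scores)$auc, mann_whitney_auc(scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- tibble::tibble(score = rnorm(40),
                           label = sample(c("binder", "nonbinder"), 40,
                                          replace = TRUE, prob = c(.5, .5)))
  r0 <- roc_curve(scores)
  for (f in list(function(x) 3 * x + 2, function(x) exp(x),
                 function(x) x^3)) {
    rt <- roc_curve(dplyr::mutate(scores, score = f(score)))
    expect_equal(rt$auc, r0$auc, tolerance = 1e-12)
    expect_equal(rt$points[c("fpr", "tpr")], r0$points[c("fpr", "tpr")])
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- tibble::tibble(score = rnorm(60),
                           label = rep(c("binder", "nonbinder"), 30))
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = scores$label, predictor = scores$score,
    levels = c("nonbinder", "binder"), direction = ">")))
  expect_equal(roc_curve(scores)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("benchmark reports join labels and affinities and flag mismatches", {
  t1 <- table1_panel()
  rep_pp <- benchmark_report(
    tibble::tibble(peptide_id = t1$peptide_id, score = t1$pp_score),
    affinities = tibble::tibble(peptide_id = t1$peptide_id,
                                delta_g = t1$delta_g))
  expect_equal(rep_pp$correlation$r,
               pearson(t1$delta_g, t1$pp_score)$r)
  rep_mm <- benchmark_report(
    tibble::tibble(peptide_id = t1$peptide_id, score = t1$pbtot),
    affinities = tibble::tibble(peptide_id = t1$peptide_id,
                                delta_g = t1$delta_g))
  expect_equal(round(rep_mm$correlation$r, 2), 0.63)

  # labels-only input: no correlation block, per-class ranges present
  lab <- tibble::tibble(peptide_id = t1$peptide_id,
                        label = rep(c("binder", "nonbinder"), 3))
  rep_lab <- benchmark_report(
    tibble::tibble(peptide_id = t1$peptide_id, score = t1$pp_score),
    labels = lab)
  expect_null(rep_lab$correlation)
  expect_equal(sort(rep_lab$score_ranges$label), c("binder", "nonbinder"))
  expect_equal(glance(rep_lab)$auc, rep_lab$roc$auc)

  # disjoint ids: an error that lists the unmatched ids
  expect_error(
    benchmark_report(
      tibble::tibble(peptide_id = "pepX", score = 1),
      labels = tibble::tibble(peptide_id = c("a", "b"),
                              label = c("binder", "nonbinder"))),
    "a, b", class = "ptb_error_join")

  # kd input converts through delta_g_from_kd at the given temperature
  kdtab <- tibble::tibble(peptide_id = t1$peptide_id,
                          kd = exp(t1$delta_g / (1.987204e-3 * 300)))
  rep_kd <- benchmark_report(
    tibble::tibble(peptide_id = t1$peptide_id, score = t1$pp_score),
    affinities = kdtab, temperature = 300)
  expect_equal(rep_kd$correlation$r, rep_pp$correlation$r, tolerance = 1e-9)

  # serialization writes a JSON report and a per-peptide table
  dir <- withr::local_tempdir()
  write_benchmark_report(rep_lab, dir)
  doc <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(doc$roc$auc, rep_lab$roc$auc)
  expect_true(file.exists(file.path(dir, "per_peptide.tsv")))
})
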
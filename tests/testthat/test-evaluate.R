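test_that("ranking is descending in dG with id tie-breaks", {
  scores <- tibble::tibble(variant_id = c("A", "B", "C"),
                           dg = c(-10, -5, -7))
  labels <- tibble::tibble(variant_id = c("A", "B", "C"),
                           label = c("S", "R", "R"))
  r <- rank_panel(scores, labels)
  expect_equal(r$variant_id, c("B", "C", "A"))
  # ties resolve alphabetically and the result ignores input order
  tied <- tibble::tibble(variant_id = c("Z", "M", "A"), dg = c(-5, -5, -9))
  lab <- tibble::tibble(variant_id = c("Z", "M", "A"),
                        label = c("R", "R", "S"))
  r1 <- rank_panel(tied, lab)
  expect_equal(r1$variant_id, c("M", "Z", "A"))
  r2 <- rank_panel(tied[c(3, 1, 2), ], lab)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_error(rank_panel(tied, lab[1:2, ]), "missing label")
})

test_that("confusion counts, accuracy and EF match the worked examples", {
  # perfect ranking of 25 R above 4 S
  perfect <- ranked_from_labels(c(rep("R", 25), rep("S", 4)))
  cm <- classification_metrics(perfect, ef_n = 10)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$ef, 29 / 25)
  expect_equal(round(cm$ef, 2), 1.16)
  expect_equal(cm$tr, 25); expect_equal(cm$fr, 0)

  # one resistant variant ranked below the cut
  one_off <- ranked_from_labels(c(rep("R", 24), "S", "R", rep("S", 3)))
  cm1 <- classification_metrics(one_off, ef_n = 10)
  expect_equal(cm1$accuracy, 27 / 29)
  expect_equal(round(cm1$accuracy, 2), 0.93)

  # all four susceptible variants inside the top ten
  worst_top <- ranked_from_labels(c(rep("S", 4), rep("R", 25)))
  cm2 <- classification_metrics(worst_top, ef_n = 10)
  expect_equal(cm2$ef, (6 / 10) / (25 / 29))

  expect_error(classification_metrics(perfect, ef_n = 30), "exceeds")
})

test_that("confusion identities hold on randomized panels", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(6:30, 1)
      lab <- sample(c("R", "S"), n, replace = TRUE, prob = c(0.7, 0.3))
    })
    if (length(unique(lab)) < 2) next
    ranked <- ranked_from_labels(lab)
    for (cut in c(1, sum(lab == "R"), n - 1)) {
      cm <- classification_metrics(ranked, ef_n = min(10, n), cut = cut)
      expect_equal(cm$tr + cm$fr, cut)
      expect_equal(cm$tr + cm$fs, cm$n_resistant)
      expect_equal(cm$ts + cm$fr, cm$n_total - cm$n_resistant)
      expect_gte(cm$ef, 0)
      expect_lte(cm$ef, cm$n_total / cm$n_resistant + 1e-12)
    }
  }
})

test_that("ROC endpoints and the interleaved worked case are exact", {
  perfect <- ranked_from_labels(c(rep("R", 5), rep("S", 3)))
  expect_equal(roc_auc(perfect)$auc, 1)
  reversed <- ranked_from_labels(c(rep("S", 3), rep("R", 5)))
  expect_equal(roc_auc(reversed)$auc, 0)
  inter <- ranked_from_labels(c("R", "S", "R", "S"))
  expect_equal(roc_auc(inter)$auc, 0.75)
  expect_error(roc_auc(ranked_from_labels(rep("R", 4))), "both classes")
})

test_that("trapezoid AUC equals exhaustive pair counting, ties included", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      n <- sample(4:12, 1)
      dg <- sample(seq(-12, -2, by = 0.5), n, replace = TRUE) # forces ties
      lab <- sample(c("R", "S"), n, replace = TRUE)
    })
    if (length(unique(lab)) < 2) next
    scores <- tibble::tibble(variant_id = sprintf("V%02d", seq_len(n)),
                             dg = dg)
    labels <- tibble::tibble(variant_id = scores$variant_id, label = lab)
    got <- roc_auc(rank_panel(scores, labels))$auc
    expect_equal(got, pair_count_auc(dg, lab), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(42, {
    dg <- rnorm(40); lab <- sample(c("R", "S"), 40, replace = TRUE)
  })
  scores <- tibble::tibble(variant_id = sprintf("V%02d", 1:40), dg = dg)
  labels <- tibble::tibble(variant_id = scores$variant_id, label = lab)
  got <- roc_auc(rank_panel(scores, labels))$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = dg, levels = c("S", "R"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the paired t-test matches the closed form and its symmetries", {
  got <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(got$t, -2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(got$t, -3.464, tolerance = 1e-3)
  expect_equal(got$df, 2)
  expect_equal(got$p, 0.0742, tolerance = 1e-3)
  # decided degenerate case
  same <- paired_t_test(c(1, 2), c(1, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # antisymmetry
  fwd <- paired_t_test(c(1, 5, 2), c(0, 3, 3))
  rev <- paired_t_test(c(0, 3, 3), c(1, 5, 2))
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:2), "equal length")
})

test_that("evaluate_panel bundles metrics with tidy/glance accessors", {
  tab <- gen_affinity_table(n_R = 6, n_S = 2, delta = 6, sigma = 0.5,
                            seed = 3)
  ev <- evaluate_panel(tab$scores, tab$labels)
  g <- glance(ev)
  expect_equal(g$accuracy, 1)
  expect_equal(g$auc, 1)
  td <- tidy(ev)
  expect_equal(nrow(td), 9)
  expect_setequal(unique(td$call), c("TR", "TS"))
})

test_that("evaluate_grid separates a signal method from a noise method", {
  tab_sig <- gen_affinity_table(n_R = 20, n_S = 4, delta = 5, sigma = 0.5,
                                n_methods = 4, seed = 7)
  tab_noise <- gen_affinity_table(n_R = 20, n_S = 4, delta = 0, sigma = 0.5,
                                  n_methods = 4, seed = 8)
  scores <- dplyr::bind_rows(
    dplyr::mutate(tab_sig$scores, family = "signal"),
    dplyr::mutate(tab_noise$scores, family = "noise")
  )
  ge <- evaluate_grid(scores, tab_sig$labels,
                      cell_vars = c("family", "method"),
                      compare_var = "family")
  s <- tidy(ge, "summary")
  auc_mean <- s$mean[s$metric == "auc"]
  names(auc_mean) <- s$family[s$metric == "auc"]
  expect_gt(auc_mean[["signal"]], auc_mean[["noise"]])
  comp <- tidy(ge, "comparisons")
  expect_equal(nrow(comp), 3)  # three metrics, one level pair
  expect_true(all(comp$df == 3))
})

test_that("identical cells compare with t = 0, p = 1 and unpaired cells error", {
  tab <- gen_affinity_table(n_R = 10, n_S = 3, delta = 3, n_methods = 3,
                            seed = 5)
  scores <- dplyr::bind_rows(
    dplyr::mutate(tab$scores, sampling = "single_structure"),
    dplyr::mutate(tab$scores, sampling = "ensemble")
  )
  ge <- evaluate_grid(scores, tab$labels,
                      cell_vars = c("sampling", "method"),
                      compare_var = "sampling")
  comp <- tidy(ge, "comparisons")
  expect_true(all(comp$t == 0))
  expect_true(all(comp$p == 1))
  # single cell: metrics only, no comparisons
  ge1 <- evaluate_grid(tab$scores, tab$labels,
                       cell_vars = c("sampling", "method"),
                       compare_var = "sampling")
  expect_error(tidy(ge1, "comparisons"), "no comparisons")
  # drop one cell from one level -> unpaired
  broken <- scores[!(scores$sampling == "ensemble" &
                       scores$method == "M01"), ]
  expect_error(evaluate_grid(broken, tab$labels,
                             cell_vars = c("sampling", "method"),
                             compare_var = "sampling"), "unpaired")
})
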
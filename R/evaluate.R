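#' Rank a panel from weak to strong binding
#'
#' Sorts variants by binding free energy in descending order (largest,
#' i.e. weakest-binding, first), the order in which resistance calls are
#' made: resistance manifests as less negative `dG`, so resistant
#' variants should populate the top of the ranking. Ties are broken
#' deterministically by `variant_id` (ascending), so the result is
#' invariant to the input row order.
#'
#' @param scores tibble with `variant_id` and `dg` columns.
#' @param labels tibble with `variant_id` and `label` (`"R"`/`"S"`)
#'   columns; may be omitted if `scores` carries a `label` column.
#' @return tibble of class `ranked_panel` with a `rank` column.
#' @export
rank_panel <- function(scores, labels = NULL) {
  if (!all(c("variant_id", "dg") %in% names(scores))) {
    abort("scores need columns `variant_id` and `dg`")
  }
  if (!is.null(labels)) {
    scores <- left_join(scores[setdiff(names(scores), "label")],
                        labels[, c("variant_id", "label")],
                        by = "variant_id")
  }
  if (!"label" %in% names(scores)) abort("no labels supplied")
  if (anyNA(scores$label)) {
    abort(sprintf("missing label for: %s",
                  paste(scores$variant_id[is.na(scores$label)],
                        collapse = ", ")))
  }
  if (!all(scores$label %in% c("R", "S"))) {
    abort("labels must be 'R' or 'S'")
  }
  out <- scores %>%
    arrange(dplyr::desc(.data$dg), .data$variant_id) %>%
    mutate(rank = row_number())
  class(out) <- c("ranked_panel", class(out))
  out
}

#' Confusion counts, accuracy and enrichment factor of a ranking
#'
#' Variants in the top `cut` ranks are called resistant, the remainder
#' susceptible. With `A` resistant labels among `N` variants the
#' default cut is `A`: a resistant variant ranked below `A` is a false
#' susceptibility, a susceptible variant inside the top `A` a false
#' resistance. Accuracy is `(TR + TS) / N` at that cut; the enrichment
#' factor is `(a / ef_n) / (A / N)` with `a` the number of resistant
#' variants in the top `ef_n` (default 10).
#'
#' @param ranked a [rank_panel()] result (or any tibble with `rank` and
#'   `label` columns).
#' @param ef_n depth of the enrichment-factor window; must not exceed
#'   the panel size.
#' @param cut resistance-call cut; defaults to the number of resistant
#'   labels.
#' @return one-row tibble: `n_total`, `n_resistant`, `cut`, `tr`, `fr`,
#'   `ts`, `fs`, `ef_n`, `top_resistant`, `accuracy`, `ef`.
#' @export
classification_metrics <- function(ranked, ef_n = 10, cut = NULL) {
  if (!all(c("rank", "label") %in% names(ranked))) {
    abort("`ranked` must come from rank_panel()")
  }
  N <- nrow(ranked)
  A <- sum(ranked$label == "R")
  if (A < 1) abort("panel has no resistant labels")
  if (ef_n > N) abort("ef_n exceeds the panel size")
  cut <- cut %||% A
  top <- ranked$label[ranked$rank <= cut]
  bottom <- ranked$label[ranked$rank > cut]
  tr <- sum(top == "R"); fr <- sum(top == "S")
  ts <- sum(bottom == "S"); fs <- sum(bottom == "R")
  a <- sum(ranked$label[ranked$rank <= ef_n] == "R")
  tibble(n_total = N, n_resistant = A, cut = cut, tr = tr, fr = fr,
         ts = ts, fs = fs, ef_n = ef_n, top_resistant = a,
         accuracy = (tr + ts) / N, ef = (a / ef_n) / (A / N))
}

#' ROC curve and AUC of a resistance ranking
#'
#' Sweeps the call cut `n` from 0 to the panel size, plotting the true
#' resistance rate `TR / (TR + FS)` against the false resistance rate
#' `FR / (FR + TS)`, and integrates by the trapezoid rule. The AUC
#' equals the probability that a resistant variant outranks (binds more
#' weakly than) a susceptible one, with tied cross-class pairs given
#' half credit.
#'
#' @inheritParams classification_metrics
#' @return list with `points` (tibble of `n`, `tpr`, `fpr`) and `auc`.
#' @export
roc_auc <- function(ranked) {
  if (!all(c("rank", "label") %in% names(ranked))) {
    abort("`ranked` must come from rank_panel()")
  }
  A <- sum(ranked$label == "R")
  S <- sum(ranked$label == "S")
  if (A == 0 || S == 0) abort("both classes must be present for a ROC")
  ord <- order(ranked$rank)
  lab <- ranked$label[ord]
  tpr <- c(0, cumsum(lab == "R") / A)
  fpr <- c(0, cumsum(lab == "S") / S)
  # AUC by trapezoid over tie blocks: variants sharing a dG value advance
  # the curve as one diagonal segment, giving tied cross-class pairs half
  # credit (identical to Mann-Whitney pair counting)
  if ("dg" %in% names(ranked)) {
    block_end <- c(which(diff(ranked$dg[ord]) != 0), length(lab))
  } else {
    block_end <- seq_along(lab)
  }
  bt <- c(0, tpr[block_end + 1])
  bf <- c(0, fpr[block_end + 1])
  auc <- sum(diff(bf) * (head(bt, -1) + bt[-1]) / 2)
  list(points = tibble(n = 0:length(lab), tpr = tpr, fpr = fpr), auc = auc)
}

#' Paired t-test between two metric vectors
#'
#' Two-sided paired t-test (`t = mean(d) / (sd(d) / sqrt(n))`,
#' `df = n - 1`). The degenerate all-equal case returns `t = 0, p = 1`
#' rather than `NaN`; a constant nonzero difference returns an infinite
#' statistic with `p = 0`.
#'
#' @param x,y numeric vectors of equal length (>= 2), paired
#'   elementwise.
#' @return one-row tibble: `estimate` (mean difference), `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(estimate = 0, t = 0, df = length(d) - 1, p = 1))
    }
    return(tibble(estimate = mean(d), t = sign(mean(d)) * Inf,
                  df = length(d) - 1, p = 0))
  }
  ht <- t.test(x, y, paired = TRUE)
  tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value)
}

#' Evaluate one score table against labels
#'
#' Convenience wrapper that ranks, computes the confusion counts,
#' accuracy, enrichment factor and ROC-AUC in one object with
#' [tidy()]/[glance()]/[autoplot()] methods.
#'
#' @inheritParams rank_panel
#' @inheritParams classification_metrics
#' @param ef_n enrichment window; defaults to 10, clipped to the panel
#'   size for small panels.
#' @return object of class `resistance_eval`.
#' @export
evaluate_panel <- function(scores, labels = NULL, ef_n = NULL, cut = NULL) {
  ranked <- rank_panel(scores, labels)
  ef_n <- ef_n %||% min(10L, nrow(ranked))
  cm <- classification_metrics(ranked, ef_n = ef_n, cut = cut)
  roc <- roc_auc(ranked)
  structure(list(ranked = ranked, confusion = cm, roc = roc$points,
                 metrics = tibble(accuracy = cm$accuracy, ef = cm$ef,
                                  auc = roc$auc)),
            class = "resistance_eval")
}

#' Metric grid over methods and sampling strategies, with paired tests
#'
#' Computes accuracy, enrichment factor and AUC for every cell of a
#' scoring grid (e.g. polar method crossed with sampling strategy and
#' herbicide), summarises each level of a grouping factor as mean and
#' standard deviation, and compares the levels pairwise with paired
#' t-tests, pairing cells on the remaining factors. Cells missing from
#' a pairing are an error: a paired comparison needs the full cross.
#'
#' @param scores long tibble of scores: `variant_id`, `dg`, plus the
#'   factor columns in `cell_vars`.
#' @param labels tibble with `variant_id`, `label`.
#' @param cell_vars columns identifying one scored panel per cell.
#' @param compare_var the factor whose levels are compared.
#' @param ef_n,cut forwarded to [classification_metrics()].
#' @return object of class `grid_eval`: `$metrics` per cell, `$summary`
#'   mean and SD per level, `$comparisons` paired t-tests per metric and
#'   level pair.
#' @export
evaluate_grid <- function(scores, labels,
                          cell_vars = c("polar_method", "sampling"),
                          compare_var = "sampling", ef_n = NULL,
                          cut = NULL) {
  miss <- setdiff(c(cell_vars, "variant_id", "dg"), names(scores))
  if (length(miss) > 0) {
    abort(sprintf("scores missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (!compare_var %in% cell_vars) {
    abort("`compare_var` must be one of `cell_vars`")
  }
  pair_vars <- setdiff(cell_vars, compare_var)

  metrics <- scores %>%
    group_by(across(all_of(cell_vars))) %>%
    dplyr::group_modify(function(df, key) {
      ev <- evaluate_panel(df, labels, ef_n = ef_n, cut = cut)
      ev$metrics
    }) %>%
    ungroup()

  metric_names <- c("accuracy", "ef", "auc")
  summary <- metrics %>%
    tidyr::pivot_longer(all_of(metric_names), names_to = "metric") %>%
    group_by(across(all_of(c(compare_var, "metric")))) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_cells = dplyr::n(), .groups = "drop")

  lev <- unique(metrics[[compare_var]])
  comparisons <- NULL
  if (length(lev) > 1 && length(pair_vars) > 0) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(pr) {
      a <- metrics[metrics[[compare_var]] == pr[1], , drop = FALSE]
      b <- metrics[metrics[[compare_var]] == pr[2], , drop = FALSE]
      joined <- dplyr::inner_join(a, b, by = pair_vars,
                                  suffix = c("_1", "_2"))
      if (nrow(joined) < nrow(a) || nrow(joined) < nrow(b)) {
        abort(sprintf("unpaired cells between %s levels '%s' and '%s'",
                      compare_var, pr[1], pr[2]))
      }
      purrr::map_dfr(metric_names, function(mn) {
        tt <- paired_t_test(joined[[paste0(mn, "_1")]],
                            joined[[paste0(mn, "_2")]])
        dplyr::bind_cols(tibble(level_1 = as.character(pr[1]),
                                level_2 = as.character(pr[2]),
                                metric = mn), tt)
      })
    })
  }
  structure(list(metrics = metrics, summary = summary,
                 comparisons = comparisons, compare_var = compare_var,
                 cell_vars = cell_vars),
            class = "grid_eval")
}

#' Sensitivity of accuracy to class imbalance by resampling
#'
#' Re-evaluates prediction accuracy on reduced panels formed by drawing
#' unique random subsets of `k` resistant variants (for each `k` from
#' `k_min` to `k_max`) together with all susceptible-labelled variants,
#' re-cutting the resistance call at the reduced resistant count `k`.
#' The number of subsets per `k` is capped at the number of
#' non-redundant combinations `choose(A, k)`; when the cap is at or
#' below `draws` the subsets are enumerated exhaustively, otherwise
#' unique subsets are rejection-sampled. A single seed makes the whole
#' resampling reproducible.
#'
#' @param scores tibble with `variant_id` and `dg`.
#' @param labels tibble with `variant_id` and `label`.
#' @param k_min,k_max range of resistant-subset sizes.
#' @param draws requested subsets per `k`.
#' @param seed integer seed for the resampling generator.
#' @return object of class `imbalance_resample`; `$summary` has one row
#'   per `k` with `n_subsets`, `mean_accuracy`, `sd_accuracy`.
#' @export
imbalance_resample <- function(scores, labels, k_min = 4, k_max = 24,
                               draws = 1000, seed = 1) {
  ranked_all <- rank_panel(scores, labels)   # validates labels
  if (draws < 1) abort("draws must be >= 1")
  r_ids <- sort(ranked_all$variant_id[ranked_all$label == "R"])
  s_ids <- ranked_all$variant_id[ranked_all$label == "S"]
  A <- length(r_ids)
  if (k_max > A) abort(sprintf("k_max (%d) exceeds resistant pool (%d)",
                               k_max, A))
  if (k_min < 1 || k_min > k_max) abort("need 1 <= k_min <= k_max")

  dg <- setNames(ranked_all$dg, ranked_all$variant_id)
  n_s <- length(s_ids)
  acc_of <- function(sub_ids) {
    ids <- c(sub_ids, s_ids)
    ord <- order(-dg[ids], ids)
    k <- length(sub_ids)
    top <- ids[ord][seq_len(k)]
    tr <- sum(top %in% sub_ids)
    (tr + (n_s - (k - tr))) / (k + n_s)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  rows <- purrr::map_dfr(k_min:k_max, function(k) {
    total <- choose(A, k)
    if (total <= draws) {
      subsets <- combn(A, k, simplify = FALSE)
    } else {
      seen <- new.env(parent = emptyenv(), hash = TRUE)
      subsets <- vector("list", draws)
      got <- 0L
      while (got < draws) {
        cand <- sort(sample.int(A, k))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          subsets[[got]] <- cand
        }
      }
    }
    acc <- vapply(subsets, function(ix) acc_of(r_ids[ix]), numeric(1))
    tibble(k = k, n_subsets = length(subsets), mean_accuracy = mean(acc),
           sd_accuracy = sd(acc))
  })
  structure(list(summary = rows, seed = seed, draws = draws,
                 n_resistant = A, n_susceptible = n_s),
            class = "imbalance_resample")
}
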
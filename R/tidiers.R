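#' Tidy a panel evaluation
#'
#' One row per variant in rank order, with the resistance call each
#' variant received at the evaluation cut: `TR`/`FR` inside the top
#' ranks, `TS`/`FS` below.
#'
#' @param x a [evaluate_panel()] result.
#' @param ... unused.
#' @return tibble with `variant_id`, `dg`, `label`, `rank`, `call`.
#' @export
tidy.resistance_eval <- function(x, ...) {
  cut <- x$confusion$cut
  x$ranked %>%
    mutate(call = dplyr::case_when(
      .data$rank <= cut & .data$label == "R" ~ "TR",
      .data$rank <= cut & .data$label == "S" ~ "FR",
      .data$rank > cut & .data$label == "S" ~ "TS",
      TRUE ~ "FS"
    )) %>%
    select(dplyr::any_of(c("variant_id", "dg", "label", "rank", "call"))) %>%
    as_tibble()
}

#' @describeIn tidy.resistance_eval one-row summary with the panel
#'   composition, accuracy, enrichment factor and AUC.
#' @export
glance.resistance_eval <- function(x, ...) {
  dplyr::bind_cols(
    x$confusion[, c("n_total", "n_resistant", "cut")],
    x$metrics
  )
}

#' Tidy an imbalance resampling
#'
#' @param x an [imbalance_resample()] result.
#' @param ... unused.
#' @return per-`k` tibble of subset counts and accuracy mean/SD.
#' @export
tidy.imbalance_resample <- function(x, ...) x$summary

#' @describeIn tidy.imbalance_resample one-row summary of the
#'   resampling design.
#' @export
glance.imbalance_resample <- function(x, ...) {
  tibble(k_min = min(x$summary$k), k_max = max(x$summary$k),
         draws = x$draws, n_resistant = x$n_resistant,
         n_susceptible = x$n_susceptible, seed = x$seed)
}

#' Tidy a metric grid evaluation
#'
#' @param x an [evaluate_grid()] result.
#' @param type `"metrics"` (per cell), `"summary"` (mean and SD per
#'   compared level) or `"comparisons"` (paired t-tests).
#' @param ... unused.
#' @return the requested tibble.
#' @export
tidy.grid_eval <- function(x, type = c("metrics", "summary",
                                       "comparisons"), ...) {
  type <- match.arg(type)
  out <- x[[type]]
  if (is.null(out)) {
    abort("no comparisons in this grid (single level)")
  }
  out
}

#' @describeIn tidy.grid_eval one-row description of the grid layout.
#' @export
glance.grid_eval <- function(x, ...) {
  tibble(n_cells = nrow(x$metrics), compare_var = x$compare_var,
         n_levels = length(unique(x$metrics[[x$compare_var]])),
         n_comparisons = if (is.null(x$comparisons)) 0L
                         else nrow(x$comparisons))
}

#' @export
print.resistance_eval <- function(x, ...) {
  cat("<resistance_eval>\n")
  cat(sprintf("  panel: %d variants (%d R / %d S), cut %d\n",
              x$confusion$n_total, x$confusion$n_resistant,
              x$confusion$n_total - x$confusion$n_resistant,
              x$confusion$cut))
  cat(sprintf("  accuracy %.3f | EF@%d %.3f | AUC %.3f\n",
              x$metrics$accuracy, x$confusion$ef_n, x$metrics$ef,
              x$metrics$auc))
  invisible(x)
}

#' @export
print.imbalance_resample <- function(x, ...) {
  cat("<imbalance_resample>\n")
  cat(sprintf("  %d resistant, %d susceptible; %d draws requested, seed %d\n",
              x$n_resistant, x$n_susceptible, x$draws, x$seed))
  print(x$summary, n = 5)
  invisible(x)
}

#' @export
print.grid_eval <- function(x, ...) {
  cat("<grid_eval>\n")
  print(x$summary)
  invisible(x)
}
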
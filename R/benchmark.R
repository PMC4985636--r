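#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = RT \ln K_d} with R = 1.987204e-3 kcal/(mol K). Negative
#' for sub-molar Kd; tighter binding (smaller Kd) gives a more negative
#' free energy.
#'
#' @param kd Dissociation constant(s) in molar; must be positive.
#' @param temperature Temperature in kelvin (default 300).
#' @return Free energy in kcal/mol.
#' @export
#' @examples
#' delta_g_from_kd(1e-6, 300) # ~ -8.23 kcal/mol
delta_g_from_kd <- function(kd, temperature = 300) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    abort("kd must be positive and finite", class = "ptb_error_domain")
  }
  if (any(temperature <= 0)) {
    abort("temperature must be positive", class = "ptb_error_domain")
  }
  R_KCAL * temperature * log(kd)
}

#' Pearson correlation with a t-based two-tailed p-value
#'
#' Sample Pearson r with significance from the exact t distribution:
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n-2 degrees of freedom,
#' two-tailed.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with non-zero
#'   variance.
#' @return A `ptb_cor`: list with `r`, `n`, `t`, `df`, `p_value`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "ptb_error_contract")
  }
  if (length(x) < 3) {
    abort("need at least 3 observations", class = "ptb_error_contract")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("missing values not allowed", class = "ptb_error_contract")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance input", class = "ptb_error_degenerate")
  }
  r <- cor(x, y)
  n <- length(x)
  df <- n - 2
  t <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t), df)
  structure(list(r = r, n = n, t = t, df = df, p_value = min(p, 1)),
            class = "ptb_cor")
}

#' @export
print.ptb_cor <- function(x, ...) {
  cat("<ptb_cor> r = ", round(x$r, 3), " (n = ", x$n, ", two-tailed p = ",
      signif(x$p_value, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname pearson
#' @param x A `ptb_cor`.
#' @param ... Unused.
#' @method tidy ptb_cor
#' @export
tidy.ptb_cor <- function(x, ...) {
  tibble(estimate = x$r, statistic = x$t, p.value = x$p_value,
         parameter = x$df, n = x$n)
}

#' @rdname pearson
#' @method glance ptb_cor
#' @export
glance.ptb_cor <- function(x, ...) tidy(x)

check_labels <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("score", "label") %in% names(scores)))
  bad <- setdiff(unique(scores$label), c("binder", "nonbinder"))
  if (length(bad) > 0) {
    abort(paste0("labels must be 'binder'/'nonbinder'; got: ",
                 paste(bad, collapse = ", ")), class = "ptb_error_contract")
  }
  if (length(unique(scores$label)) < 2) {
    abort("both binder and non-binder labels are required",
          class = "ptb_error_degenerate")
  }
  invisible(scores)
}

#' Confusion counts at a score threshold
#'
#' A peptide is predicted a binder when its score is strictly below the
#' threshold (lower score = more favorable), non-binder otherwise; counts
#' are tallied against the true labels.
#'
#' @param scores Tibble with columns `score` and `label`
#'   (`"binder"`/`"nonbinder"`); both labels must be present.
#' @param threshold Score cutoff.
#' @return One-row tibble: threshold, tp, fp, tn, fn, tpr, fpr.
#' @export
confusion_at <- function(scores, threshold) {
  check_labels(scores)
  pred_binder <- scores$score < threshold
  truth_binder <- scores$label == "binder"
  tp <- sum(pred_binder & truth_binder)
  fp <- sum(pred_binder & !truth_binder)
  fn <- sum(!pred_binder & truth_binder)
  tn <- sum(!pred_binder & !truth_binder)
  tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         tpr = tp / (tp + fn), fpr = fp / (fp + tn))
}

#' ROC curve and AUC by threshold sweep over observed scores
#'
#' Sweeps the binder-prediction threshold over every observed score (plus
#' sentinels that pin the curve at (0,0) and (1,1)), computing TPR =
#' TP/(TP+FN) and FPR = FP/(FP+TN) at each cutoff, and integrates the
#' area under the curve by the trapezoidal rule. With tied scores across
#' classes the trapezoid awards half credit, so the AUC equals the
#' tie-corrected Mann-Whitney statistic U/(n1*n2): the probability that a
#' random binder scores below a random non-binder.
#'
#' @param scores Tibble with `score` and `label` columns; both labels
#'   required.
#' @return A `ptb_roc`: list with `points` (tibble: threshold, fpr, tpr,
#'   sorted along the curve), `auc`, `n_binder`, `n_nonbinder`.
#' @export
roc_curve <- function(scores) {
  check_labels(scores)
  thresholds <- c(-Inf, sort(unique(scores$score)), Inf)
  pts <- map(thresholds, function(th) confusion_at(scores, th)) |>
    list_rbind() |>
    select("threshold", "fpr", "tpr") |>
    arrange(.data$fpr, .data$tpr)
  auc <- trapezoid_auc(pts$fpr, pts$tpr)
  structure(list(points = pts, auc = auc,
                 n_binder = sum(scores$label == "binder"),
                 n_nonbinder = sum(scores$label == "nonbinder")),
            class = "ptb_roc")
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' @export
print.ptb_roc <- function(x, ...) {
  cat("<ptb_roc> AUC = ", round(x$auc, 3), " (", x$n_binder, " binders vs ",
      x$n_nonbinder, " non-binders, ", nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' @rdname roc_curve
#' @param x A `ptb_roc`.
#' @param ... Unused.
#' @method tidy ptb_roc
#' @export
tidy.ptb_roc <- function(x, ...) x$points

#' @rdname roc_curve
#' @method glance ptb_roc
#' @export
glance.ptb_roc <- function(x, ...) {
  tibble(auc = x$auc, n_binder = x$n_binder, n_nonbinder = x$n_nonbinder)
}

#' Joint benchmark report: ROC block and/or correlation block
#'
#' Joins a score table with binder/non-binder labels and/or experimental
#' affinities on `peptide_id` and assembles the evaluation outputs the
#' screen is judged by: ROC points + AUC and per-class score ranges when
#' labels are present; Pearson correlation between computational score and
#' experimental free energy when affinities are present (`delta_g` used
#' directly, otherwise derived from `kd` at `temperature`). Unmatched ids
#' are listed, not fatal.
#'
#' @param score_table Tibble with `peptide_id` (or `id`) and `score`.
#' @param labels Optional tibble: `peptide_id`, `label`.
#' @param affinities Optional tibble: `peptide_id` plus `delta_g` (kcal/mol)
#'   and/or `kd` (molar).
#' @param temperature Kelvin, for Kd conversion (default 300).
#' @return A `ptb_benchmark`: list with `per_peptide`, `roc` (or NULL),
#'   `score_ranges`, `correlation` (or NULL), `unmatched`.
#' @export
benchmark_report <- function(score_table, labels = NULL, affinities = NULL,
                             temperature = 300) {
  tab <- as_tibble(score_table)
  if ("id" %in% names(tab) && !"peptide_id" %in% names(tab)) {
    tab <- rename(tab, peptide_id = "id")
  }
  stopifnot(all(c("peptide_id", "score") %in% names(tab)))
  ## truth columns come from the label/affinity tables, never the score side
  tab <- select(tab, -dplyr::any_of(c("label", "delta_g")))
  unmatched <- tibble(peptide_id = character(), source = character())

  roc <- NULL
  ranges <- NULL
  if (!is.null(labels)) {
    labels <- as_tibble(labels)
    if ("id" %in% names(labels)) labels <- rename(labels, peptide_id = "id")
    joined <- inner_join(tab, select(labels, "peptide_id", "label"),
                         by = "peptide_id")
    unmatched <- bind_rows(
      unmatched,
      tibble(peptide_id = setdiff(labels$peptide_id, tab$peptide_id),
             source = "labels"))
    if (nrow(joined) == 0) {
      abort(paste0("no peptide ids in common with the label table; ",
                   "unmatched: ",
                   paste(head(unmatched$peptide_id, 10), collapse = ", ")),
            class = "ptb_error_join")
    }
    roc <- roc_curve(joined)
    ranges <- joined |>
      group_by(.data$label) |>
      summarise(n = n(), min_score = min(.data$score),
                max_score = max(.data$score), .groups = "drop")
    tab <- left_join(tab, select(labels, "peptide_id", "label"),
                     by = "peptide_id")
  }

  correlation <- NULL
  if (!is.null(affinities)) {
    affinities <- as_tibble(affinities)
    if ("id" %in% names(affinities)) {
      affinities <- rename(affinities, peptide_id = "id")
    }
    if (!"delta_g" %in% names(affinities)) {
      affinities$delta_g <- delta_g_from_kd(affinities$kd, temperature)
    }
    joined <- inner_join(tab, select(affinities, "peptide_id", "delta_g"),
                         by = "peptide_id")
    unmatched <- bind_rows(
      unmatched,
      tibble(peptide_id = setdiff(affinities$peptide_id, tab$peptide_id),
             source = "affinities"))
    if (nrow(joined) == 0) {
      abort(paste0("no peptide ids in common with the affinity table; ",
                   "unmatched: ",
                   paste(head(unmatched$peptide_id, 10), collapse = ", ")),
            class = "ptb_error_join")
    }
    correlation <- pearson(joined$delta_g, joined$score)
    tab <- left_join(tab, select(affinities, "peptide_id", "delta_g"),
                     by = "peptide_id")
  }

  structure(list(per_peptide = tab, roc = roc, score_ranges = ranges,
                 correlation = correlation, unmatched = unmatched,
                 temperature = temperature),
            class = "ptb_benchmark")
}

#' @export
print.ptb_benchmark <- function(x, ...) {
  cat("<ptb_benchmark> ", nrow(x$per_peptide), " peptides\n", sep = "")
  if (!is.null(x$roc)) cat("  AUC = ", round(x$roc$auc, 3), "\n", sep = "")
  if (!is.null(x$correlation)) {
    cat("  Pearson r(score, dG) = ", round(x$correlation$r, 3),
        " (p = ", signif(x$correlation$p_value, 2), ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname benchmark_report
#' @param x A `ptb_benchmark`.
#' @param ... Unused.
#' @method glance ptb_benchmark
#' @export
glance.ptb_benchmark <- function(x, ...) {
  tibble(
    n = nrow(x$per_peptide),
    auc = if (is.null(x$roc)) NA_real_ else x$roc$auc,
    r = if (is.null(x$correlation)) NA_real_ else x$correlation$r,
    p_value = if (is.null(x$correlation)) NA_real_ else x$correlation$p_value
  )
}

#' @rdname benchmark_report
#' @method tidy ptb_benchmark
#' @export
tidy.ptb_benchmark <- function(x, ...) x$per_peptide

#' Serialize a benchmark report
#'
#' Writes `report.json` (ROC points, AUC, per-class score ranges,
#' correlation block, unmatched ids) and `per_peptide.tsv` into `dir`.
#'
#' @param report A `ptb_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- list(
    n_peptides = nrow(report$per_peptide),
    temperature_K = report$temperature,
    unmatched = report$unmatched
  )
  if (!is.null(report$roc)) {
    doc$roc <- list(auc = report$roc$auc, n_binder = report$roc$n_binder,
                    n_nonbinder = report$roc$n_nonbinder,
                    points = report$roc$points)
    doc$score_ranges <- report$score_ranges
  }
  if (!is.null(report$correlation)) {
    doc$correlation <- tidy(report$correlation)
  }
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_tsv(report$per_peptide, file.path(dir, "per_peptide.tsv"))
  invisible(dir)
}
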
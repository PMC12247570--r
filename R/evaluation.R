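#' Two-class labels from estimated excitabilities
#'
#' A region is labelled `EZ_PZ` when its estimated excitability is strictly
#' larger than the threshold, `NIZ` otherwise.  EZ and PZ are pooled into one
#' positive class because no fixed excitability boundary separates
#' propagation from non-involved regions.
#'
#' @param medians Estimated excitability per region (posterior medians).
#' @param threshold Classification threshold.
#' @return Character vector of `"EZ_PZ"` / `"NIZ"`.
#' @export
classify_regions <- function(medians, threshold) {
  ifelse(medians > threshold, "EZ_PZ", "NIZ")
}

# counts + metrics at one threshold; truth_pos is a logical vector
classification_metrics <- function(medians, truth_pos, threshold) {
  pred <- medians > threshold
  tp <- sum(pred & truth_pos)
  fp <- sum(pred & !truth_pos)
  fn <- sum(!pred & truth_pos)
  tn <- sum(!pred & !truth_pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (!is.na(precision) && !is.na(recall)) 0 else NA_real_
  list(threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1)
}

#' Precision-maximizing threshold sweep
#'
#' Evaluates classification thresholds from -5 to -1 in steps of 0.01 (401
#' values).  Among thresholds with at least one predicted positive, the one
#' with maximal precision is selected; ties are broken by larger recall, then
#' by larger threshold.  Maximizing precision is the conservative clinical
#' choice (estimated positives are resection candidates); the bias against
#' recall is reflected in the reported F1.
#'
#' @param medians Estimated excitability per region.
#' @param truth_positive Logical (or integer ids) of the true `EZ_PZ`
#'   regions.
#' @param thresholds Threshold grid.
#' @return A `classification_report`: chosen `threshold`, `labels`, counts,
#'   `precision`, `recall`, `f1`.
#' @export
sweep_threshold <- function(medians, truth_positive,
                            thresholds = seq(-5, -1, by = 0.01)) {
  if (!is.logical(truth_positive)) {
    truth_positive <- seq_along(medians) %in% truth_positive
  }
  best <- NULL
  for (th in thresholds) {
    m <- classification_metrics(medians, truth_positive, th)
    if (m$tp + m$fp == 0) next
    if (is.null(best) ||
        m$precision > best$precision + 1e-15 ||
        (abs(m$precision - best$precision) <= 1e-15 &&
         (m$recall > best$recall + 1e-15 ||
          (abs(m$recall - best$recall) <= 1e-15 &&
           m$threshold > best$threshold)))) {
      best <- m
    }
  }
  if (is.null(best)) {
    # no threshold yields a positive prediction: report the largest
    # threshold with its (empty-positive) counts
    best <- classification_metrics(medians, truth_positive,
                                   thresholds[length(thresholds)])
  }
  best$labels <- classify_regions(medians, best$threshold)
  structure(best, class = "classification_report")
}

#' Group-level statistics across the configuration catalogue
#'
#' Per configuration type and metric: the median over simulations in each
#' condition, a Kruskal-Wallis test across the four conditions, and paired
#' Wilcoxon signed-rank tests of the control condition against each field
#' condition over matched configurations.  Degenerate (all-identical)
#' samples are flagged and their tests skipped.
#'
#' @param reports Data frame with columns `config_id`, `config_type`,
#'   `condition`, and metric columns (`gof`, `precision`, `recall`, `f1`).
#' @param metrics Metric column names to analyse.
#' @param control Condition treated as control (`"lc_none"`).
#' @return List per config type: `medians` (condition x metric),
#'   `kruskal_p` (per metric), `wilcoxon_p` (condition x metric vs control).
#' @export
group_stats <- function(reports, metrics = c("gof", "precision", "recall",
                                             "f1"),
                        control = "lc_none") {
  out <- list()
  for (ct in unique(reports$config_type)) {
    sub <- reports[reports$config_type == ct, ]
    conds <- sort(unique(sub$condition))
    med <- sapply(metrics, function(m)
      sapply(conds, function(cc) median(sub[[m]][sub$condition == cc])))
    kw <- sapply(metrics, function(m) {
      groups <- split(sub[[m]], sub$condition)
      if (length(groups) < 2 || length(unique(unlist(groups))) == 1) {
        return(NA_real_)
      }
      kruskal.test(groups)$p.value
    })
    others <- setdiff(conds, control)
    wil <- sapply(metrics, function(m) {
      sapply(others, function(cc) {
        a <- sub[sub$condition == control, ]
        b <- sub[sub$condition == cc, ]
        common <- intersect(a$config_id, b$config_id)
        if (length(common) < 5) return(NA_real_)
        d <- a[[m]][match(common, a$config_id)] -
          b[[m]][match(common, b$config_id)]
        if (all(d == 0)) return(NA_real_)
        suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
      })
    })
    if (is.null(dim(wil))) wil <- matrix(wil, nrow = length(others),
                                         dimnames = list(others, metrics))
    out[[ct]] <- list(medians = med, kruskal_p = kw, wilcoxon_p = wil,
                      conditions = conds)
  }
  out
}

#' Gain-similarity analysis
#'
#' Bins per-simulation records (gain correlation of the EZ region vs the four
#' evaluation metrics) into correlation intervals of width 0.1 and reports
#' bin means plus the Spearman rank correlation between gain similarity and
#' each metric.  Empty bins are carried as missing.
#'
#' @param records Data frame with columns `r` (gain correlation) and metric
#'   columns.
#' @param metrics Metric column names.
#' @return List `bins` (data frame of bin means), `spearman` (per metric).
#' @export
correlation_analysis <- function(records, metrics = c("gof", "precision",
                                                      "recall", "f1")) {
  if (nrow(records) < 1) stop("no records")
  edges <- seq(-1, 1, by = 0.1)
  bin <- cut(records$r, breaks = edges, include.lowest = TRUE)
  bins <- data.frame(bin = levels(bin),
                     mid = (head(edges, -1) + tail(edges, -1)) / 2)
  for (m in metrics) {
    bins[[m]] <- as.numeric(tapply(records[[m]], bin, mean))[
      match(bins$bin, levels(bin))]
  }
  spearman <- sapply(metrics, function(m) {
    if (sd(records[[m]]) == 0 || sd(records$r) == 0) return(0)
    suppressWarnings(cor(records$r, records[[m]], method = "spearman"))
  })
  list(bins = bins, spearman = spearman)
}
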
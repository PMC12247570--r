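# exhaustive-threshold oracle used to validate the sweep
brute_force_sweep <- function(medians, truth_pos,
                              thresholds = seq(-5, -1, by = 0.01)) {
  best <- NULL
  for (th in thresholds) {
    pred <- medians > th
    tp <- sum(pred & truth_pos); fp <- sum(pred & !truth_pos)
    fn <- sum(!pred & truth_pos)
    if (tp + fp == 0) next
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    cand <- list(threshold = th, precision = prec, recall = rec)
    if (is.null(best) || prec > best$precision + 1e-15 ||
        (abs(prec - best$precision) <= 1e-15 &&
         (rec > best$recall + 1e-15 ||
          (abs(rec - best$recall) <= 1e-15 && th > best$threshold)))) {
      best <- cand
    }
  }
  best
}
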
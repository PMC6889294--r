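#' Confusion-matrix performance report
#'
#' The full binary performance suite for the copy-number surrogate: accuracy
#' with an exact (Clopper-Pearson) binomial 95% confidence interval, the
#' no-information rate (largest class fraction), Cohen's kappa, an exact
#' two-sided McNemar test on the discordant pairs (binomial, capped at 1),
#' sensitivity, specificity, predictive values, prevalence, detection rate,
#' detection prevalence and balanced accuracy, all computed against the
#' declared positive class.
#'
#' @param truth,predicted Equal-length label vectors over `{"CNL", "CNH"}`
#'   (or the two levels of `levels`).
#' @param positive The positive class (default `"CNH"`).
#' @param levels The two permitted labels.
#' @return An `ec_performance` object: a one-row tibble of all metrics, with
#'   the 2x2 confusion matrix in attribute `"confusion"`.
#' @examples
#' performance_metrics(rep(c("CNH", "CNL"), c(3, 5)),
#'                     rep(c("CNH", "CNL"), c(3, 5)))
#' @export
performance_metrics <- function(truth, predicted, positive = "CNH",
                                levels = c("CNL", "CNH")) {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    abort("`truth` and `predicted` must be equal-length, non-empty.")
  }
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad) > 0) {
    abort(sprintf("Label(s) outside {%s}: %s", paste(levels, collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  negative <- setdiff(levels, positive)
  n <- length(truth)
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted == negative)
  fp <- sum(truth == negative & predicted == positive)
  tn <- sum(truth == negative & predicted == negative)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(predicted = c(positive, negative),
                                      truth = c(positive, negative)))
  accuracy <- (tp + tn) / n
  ci <- stats::binom.test(tp + tn, n)$conf.int
  nir <- max(tp + fn, fp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (pe == 1) 0 else (accuracy - pe) / (1 - pe)
  disc <- fn + fp
  mcnemar_p <- if (disc == 0) 1 else min(1, stats::binom.test(fn, disc, 0.5)$p.value)
  sensitivity <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  out <- tibble(
    n = n, tp = tp, fn = fn, fp = fp, tn = tn,
    accuracy = accuracy, ci_lower = ci[1], ci_upper = ci[2],
    no_information_rate = nir, kappa = kappa, mcnemar_p = mcnemar_p,
    sensitivity = sensitivity, specificity = specificity,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    prevalence = (tp + fn) / n,
    detection_rate = tp / n,
    detection_prevalence = (tp + fp) / n,
    balanced_accuracy = (sensitivity + specificity) / 2,
    positive = positive
  )
  structure(out, confusion = confusion,
            class = c("ec_performance", class(out)))
}

#' @rdname performance_metrics
#' @param x An `ec_performance` object.
#' @export
confusion_matrix <- function(x) attr(x, "confusion")

#' @rdname performance_metrics
#' @param ... Unused.
#' @return For `tidy()`: a long tibble `metric`, `value`.
#' @export
tidy.ec_performance <- function(x, ...) {
  tibble(metric = setdiff(names(x), "positive"),
         value = as.numeric(x[1, setdiff(names(x), "positive")]))
}

#' @rdname performance_metrics
#' @export
glance.ec_performance <- function(x, ...) {
  as_tibble(x)[, c("accuracy", "ci_lower", "ci_upper", "no_information_rate",
                   "kappa", "mcnemar_p", "balanced_accuracy")]
}

#' @export
print.ec_performance <- function(x, ...) {
  cm <- confusion_matrix(x)
  cat("<ec_performance> positive class:", x$positive, "\n")
  print(cm)
  cat(sprintf("Accuracy (95%% CI): %.4f (%.4f-%.4f)  NIR: %.4f\n",
              x$accuracy, x$ci_lower, x$ci_upper, x$no_information_rate))
  cat(sprintf("Kappa: %.4f  McNemar p: %.4g\n", x$kappa, x$mcnemar_p))
  cat(sprintf("Sens: %.4f  Spec: %.4f  PPV: %.4f  NPV: %.4f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  cat(sprintf("Prevalence: %.4f  Detection rate: %.4f  Detection prev: %.4f\n",
              x$prevalence, x$detection_rate, x$detection_prevalence))
  cat(sprintf("Balanced accuracy: %.4f\n", x$balanced_accuracy))
  invisible(x)
}
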
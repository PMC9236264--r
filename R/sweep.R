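# Chromosome-length sweep: sensitivity of performance and feature stability
# to the number of selected features (the study explored lengths 1-20 around
# its default of 8).

#' Sweep the chromosome length
#'
#' Runs [run_nested_cv()] once per requested chromosome length and collects
#' per-length performance (with 95% CI across repeats) and selection
#' frequencies.
#'
#' @param table A [feature_table()].
#' @param labels Aligned `outcome_labels`.
#' @param classifier `"lsld"`, `"svm-linear"` or `"svm-rbf"`.
#' @param lengths Integer vector of chromosome lengths (study: 1..20).
#' @param ga_config Base [ga_config()]; its `chromosome_length` and
#'   `population_size` are overridden per length (population stays at
#'   10 x L unless an explicit `population_size` was set).
#' @param spec Optional [svm_spec()].
#' @param repeats,k,seed As in [run_nested_cv()]; the same master seed is
#'   reused per length so lengths differ only in L.
#' @return A list of class `chromosome_sweep`: `summary` (one row per
#'   length: mean balanced accuracy and 95% CI, sensitivity, specificity,
#'   AUC) and `frequency` (named list of per-length frequency tables).
#' @export
chromosome_sweep <- function(table, labels,
                             classifier = c("lsld", "svm-linear", "svm-rbf"),
                             lengths = 1:20, ga_config = NULL, spec = NULL,
                             repeats = 100, k = 5, seed = 1) {
  classifier <- match.arg(classifier)
  ga_config <- ga_config %||% ganest::ga_config()
  d <- length(table$schema$feature_names)
  if (max(lengths) > d) {
    stop_ganest("max chromosome length exceeds feature count ", d)
  }
  fixed_pop <- !is.null(ga_config$population_size_fixed) &&
    ga_config$population_size_fixed
  rows <- vector("list", length(lengths))
  freqs <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    L <- as.integer(lengths[i])
    gc_l <- ga_config
    gc_l$chromosome_length <- L
    if (!fixed_pop) gc_l$population_size <- 10L * L
    rep_l <- run_nested_cv(table, labels, classifier = classifier,
                           ga_config = gc_l, spec = spec,
                           repeats = repeats, k = k, seed = seed)
    o <- rep_l$overall
    rows[[i]] <- data.frame(
      length = L,
      balanced_accuracy = o$balanced_accuracy$mean,
      ci_lower = o$balanced_accuracy$ci95[1],
      ci_upper = o$balanced_accuracy$ci95[2],
      sensitivity = o$sensitivity$mean,
      specificity = o$specificity$mean,
      auc = o$auc$mean)
    freqs[[i]] <- rep_l$frequency
  }
  names(freqs) <- paste0("L", lengths)
  structure(list(summary = do.call(rbind, rows), frequency = freqs,
                 classifier = classifier, repeats = repeats, k = k,
                 seed = seed),
            class = "chromosome_sweep")
}

#' @export
print.chromosome_sweep <- function(x, ...) {
  cat(sprintf("<chromosome_sweep> %s over lengths %s (%d repeats)\n",
              x$classifier,
              paste(range(x$summary$length), collapse = "-"), x$repeats))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
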
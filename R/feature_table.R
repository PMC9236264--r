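# Subject-by-feature tables: construction, validation, delimited-text IO.

#' Construct a feature table
#'
#' Bundles a numeric subjects-by-features matrix with its schema and subject
#' identifiers, validating shape, column order and completeness. This is the
#' container every downstream stage (selection, classification, reporting)
#' consumes.
#'
#' @param values Numeric matrix, one row per subject, columns in schema order
#'   (a column-named matrix in any order is reordered to the schema).
#' @param schema A [build_schema()] object.
#' @param subject_ids Character vector of unique subject identifiers.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, schema, subject_ids) {
  stopifnot(inherits(schema, "feature_schema"))
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_ganest("feature values must be numeric")
  if (nrow(values) < 1) stop_ganest("feature table has no subjects")
  if (!is.null(colnames(values))) {
    missing <- setdiff(schema$feature_names, colnames(values))
    if (length(missing)) {
      stop_ganest("missing schema column(s): ", paste(missing, collapse = ", "))
    }
    values <- values[, schema$feature_names, drop = FALSE]
  } else if (ncol(values) != length(schema$feature_names)) {
    stop_ganest("unnamed value matrix must have exactly ",
                length(schema$feature_names), " columns")
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values)) {
    stop_ganest("subject_ids length does not match row count")
  }
  if (anyDuplicated(subject_ids)) {
    stop_ganest("duplicate subject ids: ",
                paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  if (anyNA(values)) stop_ganest("feature table contains missing values")
  dimnames(values) <- list(subject_ids, schema$feature_names)
  structure(list(schema = schema, subject_ids = subject_ids, values = values),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d %s features\n",
              nrow(x$values), ncol(x$values), x$schema$modality))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a feature table from delimited text
#'
#' Reads a header-ed delimited file (comma by default, tab via `sep`) with a
#' `subject_id` column and one column per schema feature, validates it
#' against the schema and normalizes column order. Extra non-schema columns
#' are tolerated and dropped with a warning; missing schema columns,
#' non-numeric cells and duplicate subject ids are errors. Missing values are
#' an error unless `drop_incomplete = TRUE`, in which case incomplete
#' subjects are dropped with a message naming them.
#'
#' @param path File path.
#' @param schema A [build_schema()] object.
#' @param sep Field separator (`","` default, `"\t"` accepted).
#' @param id_col Name of the subject-id column.
#' @param drop_incomplete Drop subjects with missing values instead of
#'   erroring.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, schema, sep = ",",
                               id_col = "subject_id",
                               drop_incomplete = FALSE) {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = id_col),
                          data.table = FALSE, showProgress = FALSE)
  if (!id_col %in% names(dt)) {
    stop_ganest("no '", id_col, "' column in ", path)
  }
  missing <- setdiff(schema$feature_names, names(dt))
  if (length(missing)) {
    stop_ganest("missing schema column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(dt), c(id_col, schema$feature_names))
  if (length(extra)) {
    warning("ignoring non-schema column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  ids <- dt[[id_col]]
  if (anyDuplicated(ids)) {
    stop_ganest("duplicate subject ids in ", path)
  }
  vals <- dt[, schema$feature_names, drop = FALSE]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num)) {
    stop_ganest("non-numeric cells in column(s): ",
                paste(non_num, collapse = ", "))
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    if (!drop_incomplete) {
      stop_ganest("missing values in ", path,
                  " (use drop_incomplete = TRUE to drop those subjects)")
    }
    bad <- rowSums(is.na(m)) > 0
    message("dropping ", sum(bad), " incomplete subject(s): ",
            paste(ids[bad], collapse = ", "))
    m <- m[!bad, , drop = FALSE]
    ids <- ids[!bad]
    if (!length(ids)) stop_ganest("no complete subjects remain")
  }
  feature_table(m, schema, ids)
}

#' Write a feature table to delimited text
#'
#' Values are serialized at full double precision (shortest round-trippable
#' decimal form), so that [read_feature_table()] reproduces the table
#' exactly.
#'
#' @param table A [feature_table()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  # serialize doubles at 17 significant digits so the decimal form
  # round-trips to the identical binary value
  chr <- apply(table$values, 2, function(col) sprintf("%.17g", col))
  if (nrow(table$values) == 1) chr <- matrix(chr, nrow = 1)
  df <- data.frame(subject_id = table$subject_ids,
                   chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("subject_id", colnames(table$values))
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read a two-score fatigue file
#'
#' Expects columns `subject_id`, `cfs_baseline`, `cfs_followup`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A data.frame with the three columns.
#' @export
read_fatigue_scores <- function(path, sep = ",") {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  need <- c("subject_id", "cfs_baseline", "cfs_followup")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stop_ganest("missing column(s): ", paste(missing, collapse = ", "))
  }
  dt[need]
}

#' Derive improver/non-improver outcome labels from fatigue scores
#'
#' The change score is `delta_cfs = cfs_baseline - cfs_followup` (improvement
#' on the Chalder Fatigue Scale means a lower score), and a subject is an
#' improver when `delta_cfs >= threshold`; the study's clinically relevant
#' cut-off is 2 points.
#'
#' @param cfs_baseline,cfs_followup Integer score vectors of equal length.
#' @param threshold Improvement cut-off in points (default 2).
#' @param subject_ids Optional subject identifiers (default `"s1"`, ...).
#' @param bounds Plausible score range of the instrument, used for input
#'   validation (Chalder Fatigue Scale bimodal scoring spans 0-11).
#' @return An object of class `outcome_labels`: `subject_ids`,
#'   `cfs_baseline`, `cfs_followup`, `delta_cfs`, logical `improver`, and the
#'   per-class counts in `n_improver` / `n_nonimprover`.
#' @examples
#' label_improvement(c(20, 20, 20), c(18, 19, 20), bounds = c(0, 33))$improver
#' @export
label_improvement <- function(cfs_baseline, cfs_followup, threshold = 2,
                              subject_ids = NULL, bounds = c(0, 11)) {
  if (length(cfs_baseline) != length(cfs_followup)) {
    stop_ganest("baseline and follow-up score lists differ in length")
  }
  if (!is_count(threshold, min = 1)) stop_ganest("threshold must be >= 1")
  scores <- c(cfs_baseline, cfs_followup)
  if (any(scores < bounds[1] | scores > bounds[2])) {
    stop_ganest("scores outside plausible range [",
                bounds[1], ", ", bounds[2], "]")
  }
  n <- length(cfs_baseline)
  subject_ids <- as.character(subject_ids %||% paste0("s", seq_len(n)))
  delta <- cfs_baseline - cfs_followup
  improver <- delta >= threshold
  structure(list(subject_ids = subject_ids,
                 cfs_baseline = cfs_baseline,
                 cfs_followup = cfs_followup,
                 delta_cfs = delta,
                 improver = improver,
                 n_improver = sum(improver),
                 n_nonimprover = sum(!improver),
                 threshold = threshold),
            class = "outcome_labels")
}

#' @export
print.outcome_labels <- function(x, ...) {
  cat(sprintf(
    "<outcome_labels> %d subjects: %d improvers / %d non-improvers (dCFS >= %d)\n",
    length(x$improver), x$n_improver, x$n_nonimprover, x$threshold))
  invisible(x)
}

# +1 = improver, -1 = non-improver: the signed target of the least-squares fit
labels_pm1 <- function(labels) {
  stopifnot(inherits(labels, "outcome_labels"))
  ifelse(labels$improver, 1, -1)
}
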
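#' Error (confusion) matrix
#'
#' Square class-by-class count table in the orientation used throughout:
#' rows are the classified (predicted) data, columns are the reference
#' (validation) data. All accuracy formulas and serializations assume this
#' orientation; it is stored in the object to prevent transposition bugs.
#'
#' @param counts square integer matrix, `counts[predicted, reference]`.
#' @param classes character class labels (defaults to the 4-class legend).
#' @return object of class `error_matrix`.
#' @export
error_matrix <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("error matrix must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(classes)) {
    classes <- if (!is.null(rownames(counts))) rownames(counts)
    else if (nrow(counts) == 4) habitat_classes()$label
    else as.character(seq_len(nrow(counts)))
  }
  dimnames(counts) <- list(predicted = classes, reference = classes)
  structure(list(counts = counts, classes = classes,
                 n_total = sum(counts), orientation = "rows=predicted"),
            class = "error_matrix")
}

#' Build an error matrix from a habitat map and validation points
#'
#' `counts[p, r]` = number of reference points of class `r` that the map
#' labels as class `p`. Points on masked (code 0) or out-of-grid pixels are
#' dropped, with the count in attribute `n_dropped`.
#'
#' @param predicted a [habitat_map()].
#' @param reference data.frame with columns `x`, `y`, `class`.
#' @return an [error_matrix()].
#' @export
build_error_matrix <- function(predicted, reference) {
  if (nrow(reference) == 0) stop("empty reference point set")
  rc <- lookup_cells(predicted$grid, reference$x, reference$y)
  ok <- !is.na(rc[, 1])
  pred <- rep(NA_integer_, nrow(reference))
  pred[ok] <- predicted$values[rc[ok, , drop = FALSE]]
  ok <- ok & !is.na(pred) & pred != 0L
  if (!any(ok)) stop("no reference points fall on classified pixels")
  codes <- predicted$classes$code
  m <- matrix(0L, length(codes), length(codes))
  for (i in which(ok)) {
    p <- match(pred[i], codes); r <- match(reference$class[i], codes)
    m[p, r] <- m[p, r] + 1L
  }
  out <- error_matrix(m, classes = predicted$classes$label)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Overall accuracy (percent)
#'
#' Ratio of correctly classified validation samples to all validation
#' samples: `100 * trace / n_total`.
#' @param m an [error_matrix()].
#' @return percentage in `[0, 100]`.
#' @export
overall_accuracy <- function(m) {
  if (m$n_total == 0) stop("empty error matrix")
  100 * sum(diag(m$counts)) / m$n_total
}

#' Producer and user accuracy per class (percent)
#'
#' Producer accuracy = diagonal / column (reference) total: the fraction of
#' reference samples of a class that were classified correctly (omission
#' complement). User accuracy = diagonal / row (predicted) total: the
#' fraction of pixels given a class label that truly are that class
#' (commission complement). Classes with a zero marginal get `NaN`
#' (undefined, not an error).
#'
#' @param m an [error_matrix()].
#' @return data.frame with `class`, `producer_pct`, `user_pct`.
#' @export
producer_user_accuracy <- function(m) {
  d <- diag(m$counts)
  col_tot <- colSums(m$counts)
  row_tot <- rowSums(m$counts)
  data.frame(class = m$classes,
             producer_pct = 100 * d / col_tot,
             user_pct = 100 * d / row_tot,
             row.names = NULL)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/n` and expected agreement
#' `p_e = sum(row_i * col_i) / n^2`. Degenerate `p_e = 1` yields `NaN`
#' (undefined), reported rather than thrown.
#'
#' @param m an [error_matrix()].
#' @return kappa in `[-1, 1]` (or `NaN` when undefined).
#' @export
kappa_statistic <- function(m) {
  if (m$n_total == 0) stop("empty error matrix")
  n <- m$n_total
  p_o <- sum(diag(m$counts)) / n
  p_e <- sum(rowSums(m$counts) * colSums(m$counts)) / n^2
  if (p_e >= 1) return(NaN)
  (p_o - p_e) / (1 - p_e)
}

#' Full accuracy report
#'
#' @param m an [error_matrix()].
#' @return list of class `accuracy_report`: `overall_pct`, `per_class`
#'   (producer/user), `kappa`, and the matrix itself.
#' @export
accuracy_report <- function(m) {
  structure(list(overall_pct = overall_accuracy(m),
                 per_class = producer_user_accuracy(m),
                 kappa = kappa_statistic(m),
                 matrix = m),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%%   kappa: %.3f\n", x$overall_pct, x$kappa))
  pc <- x$per_class
  pc$producer_pct <- round(pc$producer_pct, 1)
  pc$user_pct <- round(pc$user_pct, 1)
  print(pc)
  invisible(x)
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("<error_matrix> rows = predicted, columns = reference\n")
  print(x$counts)
  invisible(x)
}

#' Serialize an accuracy report to JSON
#' @param report an [accuracy_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  out <- list(overall_pct = report$overall_pct,
              kappa = report$kappa,
              per_class = report$per_class,
              counts = report$matrix$counts,
              orientation = report$matrix$orientation)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
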
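# Validation scoring: hard labels, confusion matrix with row percentages
# on actual-class sums, overall accuracy, Hinton-diagram weight export and
# the per-feature relevance (alpha) report.

# 2-decimal half-up rounding, matching how confusion percentages are
# conventionally printed (e.g. 439/441 -> 99.55).
round2_half_up <- function(x) floor(x * 100 + 0.5) / 100

#' Hard labels from network outputs
#'
#' Label 1 (target class) iff `p(t = 1 | x) >= threshold`; an output
#' exactly at the threshold goes to class 1 (deterministic tie rule).
#'
#' @param model An `"mlp_ard"`.
#' @param features `N x n` matrix, already standardized with the training
#'   parameters.
#' @param threshold Decision threshold, default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(model, features, threshold = 0.5) {
  as.integer(mlp_forward(model, features) >= threshold)
}

#' Confusion matrix with row percentages
#'
#' 2x2 counts (rows = actual, columns = predicted; target class first) plus
#' row percentages computed on actual-class sums, reported half-up to two
#' decimals, and the overall accuracy both exact and rounded.
#'
#' @param actual,predicted Equal-length 0/1 vectors (1 = target class).
#' @return A `"confusion_result"`: list with `counts`, `row_percent`,
#'   `accuracy` (2-dec), `accuracy_exact`, `support`, `n`.
#' @export
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  actual <- as.integer(actual)
  predicted <- as.integer(predicted)
  stopifnot(all(actual %in% c(0L, 1L)), all(predicted %in% c(0L, 1L)))
  lv <- c("target", "other")
  counts <- matrix(c(sum(actual == 1L & predicted == 1L),
                     sum(actual == 1L & predicted == 0L),
                     sum(actual == 0L & predicted == 1L),
                     sum(actual == 0L & predicted == 0L)),
                   2, 2, byrow = TRUE,
                   dimnames = list(actual = lv, predicted = lv))
  rs <- rowSums(counts)
  pct <- counts
  for (i in 1:2) {
    pct[i, ] <- if (rs[i] > 0) round2_half_up(100 * counts[i, ] / rs[i]) else 0
  }
  n <- length(actual)
  acc_exact <- 100 * sum(diag(counts)) / n
  structure(list(counts = counts, row_percent = pct,
                 accuracy = round2_half_up(acc_exact),
                 accuracy_exact = acc_exact,
                 support = stats::setNames(rs, lv), n = n),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted;",
      "percentages on actual-class sums)\n")
  lv <- rownames(x$counts)
  cat(sprintf("  %-8s %18s %18s\n", "", lv[1], lv[2]))
  for (i in 1:2) {
    cat(sprintf("  %-8s %8d (%6.2f%%) %8d (%6.2f%%)\n", lv[i],
                x$counts[i, 1], x$row_percent[i, 1],
                x$counts[i, 2], x$row_percent[i, 2]))
  }
  cat(sprintf("  overall accuracy: %.2f%% (%d/%d = %.6f%%)\n",
              x$accuracy, sum(diag(x$counts)), x$n, x$accuracy_exact))
  invisible(x)
}

#' Overall accuracy in percent
#'
#' `100 * (TP + TN) / N`, reported half-up to two decimals; the exact
#' fraction is kept in the confusion object (`accuracy_exact`).
#'
#' @param confusion A `"confusion_result"`.
#' @return Scalar percentage.
#' @export
overall_accuracy <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_result"))
  confusion$accuracy
}

#' Signed first-layer weight table (Hinton diagram data)
#'
#' Rows are input features (display order texture, NIR, red, green when the
#' features are the canonical four), columns are hidden neurons; each cell
#' is the signed first-layer weight. The companion [hinton_text()] renders
#' magnitude (symbol size class) and sign, the way a Hinton diagram uses
#' square size and white/black.
#'
#' @param model A trained `"mlp_ard"`.
#' @return Numeric matrix of shape n x hidden_count with feature rownames,
#'   class `"hinton_table"`.
#' @export
hinton_export <- function(model) {
  stopifnot(inherits(model, "mlp_ard"))
  tab <- t(model$W1) # n x hidden, storage feature order
  rownames(tab) <- model$features
  colnames(tab) <- paste0("h", seq_len(model$hidden_count))
  tab <- tab[feature_display_order(model$features), , drop = FALSE]
  class(tab) <- c("hinton_table", class(tab))
  tab
}

#' Text rendering of a Hinton table
#'
#' Each cell shows the weight's sign (`+`/`-`) and a magnitude class
#' relative to the largest absolute weight (`.` `o` `O` `#` for quartiles).
#'
#' @param table A `"hinton_table"` from [hinton_export()].
#' @return Character vector of lines (also printed invisibly's worth:
#'   returned, not printed).
#' @export
hinton_text <- function(table) {
  m <- unclass(table)
  mx <- max(abs(m))
  size_chars <- c(".", "o", "O", "#")
  lines <- character(nrow(m) + 1L)
  lines[1] <- sprintf("%-10s %s", "feature",
                      paste(sprintf("%3s", colnames(m)), collapse = " "))
  for (i in seq_len(nrow(m))) {
    cells <- vapply(m[i, ], function(wv) {
      if (mx == 0 || wv == 0) return(" 0 ")
      lvl <- min(4L, 1L + as.integer(floor(4 * abs(wv) / mx - 1e-12)))
      paste0(" ", if (wv > 0) "+" else "-", size_chars[lvl])
    }, character(1))
    lines[i + 1L] <- sprintf("%-10s %s", rownames(m)[i],
                             paste(cells, collapse = " "))
  }
  lines
}

#' Per-feature relevance report
#'
#' For each input-feature weight group: the final hyperparameter alpha_k,
#' the group weight norm `sqrt(2 E_w(k))`, and the rank by ascending alpha
#' (rank 1 = most relevant; ties broken by display order). Small alpha
#' means weakly constrained, hence relevant, weights — the inverse
#' alpha-norm relation of the evidence framework.
#'
#' @param model A trained `"mlp_ard"`.
#' @param alphas Named per-group hyperparameters (feature groups are looked
#'   up by feature name; extra bias-group entries are ignored).
#' @return A `"relevance_report"` data.frame with columns `feature`,
#'   `alpha`, `weight_norm`, `rank`, ordered by display order.
#' @export
relevance_report <- function(model, alphas) {
  stopifnot(inherits(model, "mlp_ard"))
  if (inherits(alphas, "hyperparameter_set")) alphas <- alphas$alphas
  stopifnot(all(model$features %in% names(alphas)))
  groups <- weight_groups(model$n, model$hidden_count, model$features)
  disp <- feature_display_order(model$features)
  a <- as.numeric(alphas[disp])
  norms <- vapply(disp, function(f) {
    sqrt(2 * group_penalty(model, groups, f))
  }, numeric(1))
  # rank by ascending alpha; ties resolved by display position
  rk <- integer(length(disp))
  rk[order(a, seq_along(a))] <- seq_along(a)
  out <- data.frame(feature = disp, alpha = a, weight_norm = norms,
                    rank = rk, row.names = NULL)
  class(out) <- c("relevance_report", "data.frame")
  out
}

write_confusion_csv <- function(confusion, path) {
  df <- data.frame(actual = rep(rownames(confusion$counts), each = 2),
                   predicted = rep(colnames(confusion$counts), 2),
                   count = as.integer(t(confusion$counts)),
                   row_percent = as.numeric(t(confusion$row_percent)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_confusion_csv <- function(path) {
  df <- read.csv(path)
  counts <- matrix(df$count, 2, 2, byrow = TRUE,
                   dimnames = list(actual = c("target", "other"),
                                   predicted = c("target", "other")))
  counts
}
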
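# Plain-text model serialization. Numbers are printed with "%.17g", which
# round-trips IEEE doubles exactly, so save -> load -> forward is
# bit-identical. Layout (one record per line, space-separated):
#
#   mlpard-model 1
#   n <int>                      input feature count
#   hidden_count <int>
#   features <name> ...          storage-order feature names
#   group <name> <size>          n+3 lines, the ARD partition sizes
#   W1 <hidden*n values>         column-major (by input feature)
#   b1 <hidden values>
#   w2 <hidden values>
#   b2 <value>
#   alphas <n+3 values>          per-group hyperparameters (or absent)
#   gammas <n+3 values>          (or absent)
#   center <n values>            standardization (or absent)
#   scale <n values>
#   seed <int>
#   config <key> <value>         echo of the training configuration

#' Save a fitted model (or bare model) to a plain-text file
#'
#' @param fit An `"mlp_ard_fit"` or `"mlp_ard"`.
#' @param path Output path.
#' @param standardization Optional `"standardization_params"` to embed so
#'   the model file is self-contained for deployment.
#' @return `path`, invisibly.
#' @export
save_mlp_ard <- function(fit, path, standardization = NULL) {
  if (inherits(fit, "mlp_ard_fit")) {
    model <- fit$model
    alphas <- fit$alphas
    gammas <- fit$gammas
    config <- fit$config
  } else if (inherits(fit, "mlp_ard")) {
    model <- fit
    alphas <- NULL
    gammas <- NULL
    config <- NULL
  } else {
    stop("expected an mlp_ard_fit or mlp_ard object", call. = FALSE)
  }
  groups <- weight_groups(model$n, model$hidden_count, model$features)
  lines <- c("mlpard-model 1",
             paste("n", model$n),
             paste("hidden_count", model$hidden_count),
             paste("features", paste(model$features, collapse = " ")),
             vapply(names(groups), function(nm) {
               paste("group", nm, length(groups[[nm]]))
             }, character(1)),
             paste("W1", paste(fmt_num(as.numeric(model$W1)),
                               collapse = " ")),
             paste("b1", paste(fmt_num(model$b1), collapse = " ")),
             paste("w2", paste(fmt_num(model$w2), collapse = " ")),
             paste("b2", fmt_num(model$b2)))
  if (!is.null(alphas)) {
    lines <- c(lines,
               paste("alphas", paste(fmt_num(as.numeric(alphas)),
                                     collapse = " ")),
               paste("gammas", paste(fmt_num(as.numeric(gammas)),
                                     collapse = " ")))
  }
  if (!is.null(standardization)) {
    stopifnot(inherits(standardization, "standardization_params"))
    lines <- c(lines,
               paste("center", paste(fmt_num(standardization$center),
                                     collapse = " ")),
               paste("scale", paste(fmt_num(standardization$scale),
                                    collapse = " ")))
  }
  if (!is.null(config)) {
    lines <- c(lines, paste("seed", config$seed),
               vapply(setdiff(names(config), "seed"), function(k) {
                 paste("config", k, fmt_num(config[[k]]))
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a model saved by [save_mlp_ard()]
#'
#' @param path Path to the model file.
#' @return A list with `model` (`"mlp_ard"`), and if present in the file
#'   `alphas`, `gammas`, `standardization`, `seed`, `config` (a plain
#'   named list echo).
#' @export
load_mlp_ard <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "mlpard-model 1") {
    stop("not an mlpard model file: ", path, call. = FALSE)
  }
  fields <- strsplit(lines[-1], " ", fixed = TRUE)
  keys <- vapply(fields, `[[`, character(1), 1)
  get_field <- function(key) {
    i <- which(keys == key)
    if (length(i) == 0) return(NULL)
    fields[[i[1]]][-1]
  }
  n <- as.integer(get_field("n"))
  hidden <- as.integer(get_field("hidden_count"))
  features <- get_field("features")
  W1 <- matrix(as.numeric(get_field("W1")), hidden, n)
  b1 <- as.numeric(get_field("b1"))
  w2 <- as.numeric(get_field("w2"))
  b2 <- as.numeric(get_field("b2"))
  model <- new_mlp(W1, b1, w2, b2, features)
  out <- list(model = model)
  group_names <- c(features, "hidden_bias", "hidden_to_output",
                   "output_bias")
  av <- get_field("alphas")
  if (!is.null(av)) {
    out$alphas <- stats::setNames(as.numeric(av), group_names)
    out$gammas <- stats::setNames(as.numeric(get_field("gammas")),
                                  group_names)
  }
  cv <- get_field("center")
  if (!is.null(cv)) {
    out$standardization <- structure(
      list(center = stats::setNames(as.numeric(cv), features),
           scale = stats::setNames(as.numeric(get_field("scale")),
                                   features)),
      class = "standardization_params")
  }
  sv <- get_field("seed")
  if (!is.null(sv)) out$seed <- as.integer(sv)
  cfg_rows <- which(keys == "config")
  if (length(cfg_rows) > 0) {
    out$config <- stats::setNames(
      lapply(cfg_rows, function(i) as.numeric(fields[[i]][3])),
      vapply(cfg_rows, function(i) fields[[i]][2], character(1)))
  }
  out
}
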
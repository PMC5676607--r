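# One-hidden-layer MLP with tanh hidden units and a logistic output,
# regularised by group-wise weight decay (automatic relevance
# determination). The weight vector omega concatenates, in this fixed
# order: the first-layer weights column-by-input-feature, the hidden
# biases, the hidden-to-output weights, and the output bias. Groups
# k = 1..n pick out each input feature's fan-out to the hidden layer;
# groups n+1, n+2, n+3 are the hidden biases, the hidden-to-output
# weights, and the output bias (n + 3 groups in total).

#' Training configuration for the ARD-regularised MLP
#'
#' @param hidden_count Hidden-layer size; default 8.
#' @param inner_iterations Iteration budget of each inner (weight)
#'   optimization; default 100.
#' @param outer_cycles Maximum number of evidence re-estimation cycles;
#'   default 10.
#' @param alpha_init Initial weight-decay hyperparameter for every group.
#' @param alpha_max Upper clamp for re-estimated hyperparameters.
#' @param alpha_tol Outer-loop convergence: stop when the maximum relative
#'   change of any alpha falls below this.
#' @param saturation_tol Outer-loop saturation stop: once the mean training
#'   cross-entropy per sample falls below this, the likelihood is flat at
#'   the minimum and evidence re-estimation is uninformative, so the loop
#'   stops with the current hyperparameters.
#' @param f_tol,grad_tol Inner optimizer convergence tolerances on the
#'   objective decrease and gradient norm.
#' @param seed Integer seed for weight initialization.
#' @return A `"train_config"` list.
#' @export
train_config <- function(hidden_count = 8L, inner_iterations = 100L,
                         outer_cycles = 10L, alpha_init = 0.01,
                         alpha_max = 1e6, alpha_tol = 1e-3,
                         saturation_tol = 1e-4, f_tol = 1e-10,
                         grad_tol = 1e-6, seed = 0L) {
  stopifnot(hidden_count >= 1, inner_iterations >= 1, outer_cycles >= 1,
            alpha_init > 0, alpha_max > 0, alpha_tol > 0,
            saturation_tol > 0, f_tol > 0, grad_tol > 0)
  structure(list(hidden_count = as.integer(hidden_count),
                 inner_iterations = as.integer(inner_iterations),
                 outer_cycles = as.integer(outer_cycles),
                 alpha_init = alpha_init, alpha_max = alpha_max,
                 alpha_tol = alpha_tol, saturation_tol = saturation_tol,
                 f_tol = f_tol, grad_tol = grad_tol,
                 seed = as.integer(seed)),
            class = "train_config")
}

new_mlp <- function(W1, b1, w2, b2, features) {
  stopifnot(is.matrix(W1), length(b1) == nrow(W1),
            length(w2) == nrow(W1), length(b2) == 1L)
  structure(list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2), n = ncol(W1),
                 hidden_count = nrow(W1), features = features),
            class = "mlp_ard")
}

#' Initialise an MLP with seeded small random weights
#'
#' Biases start at zero; weights are uniform on `(-r, r)` with
#' `r = 1/sqrt(fan-in)` of the receiving layer.
#'
#' @param n Number of input features.
#' @param hidden_count Hidden-layer size.
#' @param seed Integer master seed (child stream label `"init"`).
#' @param features Optional feature names (length `n`).
#' @return An `"mlp_ard"` model.
#' @export
mlp_init <- function(n, hidden_count = 8L, seed = 0L, features = NULL) {
  stopifnot(n >= 1, hidden_count >= 1)
  if (is.null(features)) features <- paste0("x", seq_len(n))
  stopifnot(length(features) == n)
  r1 <- 1 / sqrt(n)
  r2 <- 1 / sqrt(hidden_count)
  with_seed(derive_seed(seed, "init"), {
    W1 <- matrix(runif(hidden_count * n, -r1, r1), hidden_count, n)
    w2 <- runif(hidden_count, -r2, r2)
    new_mlp(W1, rep(0, hidden_count), w2, 0, features)
  })
}

#' @export
print.mlp_ard <- function(x, ...) {
  cat(sprintf("mlp_ard model: %d inputs (%s) -> %d tanh hidden -> logistic\n",
              x$n, paste(x$features, collapse = ", "), x$hidden_count))
  cat(sprintf("  %d weights in %d ARD groups\n",
              x$hidden_count * x$n + x$hidden_count + x$hidden_count + 1L,
              x$n + 3L))
  invisible(x)
}

# ---- weight vector packing and groups ---------------------------------------

pack_weights <- function(model) {
  c(as.numeric(model$W1), model$b1, model$w2, model$b2)
}

unpack_weights <- function(model, omega) {
  n <- model$n
  h <- model$hidden_count
  stopifnot(length(omega) == h * n + 2L * h + 1L)
  model$W1 <- matrix(omega[seq_len(h * n)], h, n)
  model$b1 <- omega[h * n + seq_len(h)]
  model$w2 <- omega[h * n + h + seq_len(h)]
  model$b2 <- omega[h * n + 2L * h + 1L]
  model
}

#' Partition of the weight vector into ARD groups
#'
#' Returns the `n + 3` disjoint index sets that cover the packed weight
#' vector exactly once: one group per input feature (that feature's
#' connections to all hidden neurons), then the hidden biases, the
#' hidden-to-output weights, and the output bias.
#'
#' @param n Number of input features.
#' @param hidden_count Hidden-layer size.
#' @param features Optional feature names for the first `n` groups.
#' @return Named list of integer index vectors into the packed weight
#'   vector.
#' @export
weight_groups <- function(n, hidden_count, features = NULL) {
  stopifnot(n >= 1, hidden_count >= 1)
  if (is.null(features)) features <- paste0("x", seq_len(n))
  stopifnot(length(features) == n)
  h <- hidden_count
  groups <- lapply(seq_len(n), function(k) (k - 1L) * h + seq_len(h))
  groups <- c(groups,
              list(n * h + seq_len(h)),            # hidden biases
              list(n * h + h + seq_len(h)),        # hidden -> output
              list(n * h + 2L * h + 1L))           # output bias
  names(groups) <- c(features, "hidden_bias", "hidden_to_output",
                     "output_bias")
  groups
}

# Per-weight decay vector alpha_j from per-group alphas.
expand_alphas <- function(groups, alphas) {
  total <- max(unlist(groups))
  out <- numeric(total)
  for (k in seq_along(groups)) out[groups[[k]]] <- alphas[[k]]
  out
}

check_alphas <- function(groups, alphas, allow_zero = FALSE) {
  if (length(alphas) != length(groups)) {
    stop("need one alpha per weight group (", length(groups), ")",
         call. = FALSE)
  }
  if (any(!is.finite(alphas)) || any(alphas < 0) ||
      (!allow_zero && any(alphas == 0))) {
    stop("alphas must be positive and finite", call. = FALSE)
  }
  invisible(alphas)
}

# ---- forward pass and objective ---------------------------------------------

# Hidden activations for an N x n input matrix.
hidden_activations <- function(model, X) {
  tanh(tcrossprod(X, model$W1) + rep(model$b1, each = nrow(X)))
}

as_input_matrix <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != model$n) {
      stop("input has ", length(x), " components; model expects ", model$n,
           call. = FALSE)
    }
    x <- matrix(x, 1L)
  }
  if (ncol(x) != model$n) {
    stop("input has ", ncol(x), " feature columns; model expects ", model$n,
         call. = FALSE)
  }
  if (!all(is.finite(x))) stop("inputs must be finite", call. = FALSE)
  x
}

#' Network output p(t = 1 | x)
#'
#' Hidden activations are `tanh(W1 x + b1)`; the output is
#' `logistic(w2 . hidden + b2)`, interpreted as the posterior probability
#' of the target class.
#'
#' @param model An `"mlp_ard"`.
#' @param x Numeric vector of length `n` or an `N x n` matrix.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
mlp_forward <- function(model, x) {
  X <- as_input_matrix(model, x)
  Z <- hidden_activations(model, X)
  as.numeric(plogis(Z %*% model$w2 + model$b2))
}

#' @export
predict.mlp_ard <- function(object, newdata, type = c("prob", "label"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  y <- mlp_forward(object, newdata)
  if (type == "prob") y else as.integer(y >= threshold)
}

# Clip predicted probabilities away from 0/1 before taking logs.
CLIP_EPS <- 1e-12

ce_terms <- function(y, t) {
  y <- pmin(pmax(y, CLIP_EPS), 1 - CLIP_EPS)
  -(t * log(y) + (1 - t) * log(1 - y))
}

#' Cross-entropy data term G
#'
#' `G = -sum_i [t_i log y_i + (1 - t_i) log(1 - y_i)]`, the negative
#' Bernoulli log-likelihood of the labels under the network output, with
#' predictions clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param model An `"mlp_ard"`.
#' @param dataset A `"pixel_dataset"` (binary labels).
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(model, dataset) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  y <- mlp_forward(model, dataset$features)
  sum(ce_terms(y, dataset$labels))
}

#' Group weight penalty E_w(k)
#'
#' Half the sum of squared weights in group `k` of the ARD partition.
#'
#' @param model An `"mlp_ard"`.
#' @param groups Output of [weight_groups()] for this model's shape.
#' @param k Group index or name.
#' @return Non-negative scalar.
#' @export
group_penalty <- function(model, groups, k) {
  if (is.character(k)) {
    if (!k %in% names(groups)) stop("unknown group '", k, "'", call. = FALSE)
  } else if (k < 1 || k > length(groups)) {
    stop("group index ", k, " out of range 1..", length(groups),
         call. = FALSE)
  }
  omega <- pack_weights(model)
  0.5 * sum(omega[groups[[k]]]^2)
}

all_group_penalties <- function(model, groups) {
  omega <- pack_weights(model)
  vapply(groups, function(idx) 0.5 * sum(omega[idx]^2), numeric(1))
}

#' Regularised objective F = G + sum_k alpha_k E_w(k)
#'
#' @param model An `"mlp_ard"`.
#' @param groups Output of [weight_groups()].
#' @param alphas Positive per-group hyperparameters (zero allowed only with
#'   `allow_zero_alpha = TRUE`, for diagnostics).
#' @param dataset A `"pixel_dataset"`.
#' @param allow_zero_alpha Permit alpha = 0 (then F = G).
#' @return Scalar, always >= the cross-entropy term.
#' @export
ard_objective <- function(model, groups, alphas, dataset,
                          allow_zero_alpha = FALSE) {
  check_alphas(groups, alphas, allow_zero = allow_zero_alpha)
  cross_entropy(model, dataset) +
    sum(as.numeric(alphas) * all_group_penalties(model, groups))
}

# Gradient of the data term G alone, as a packed vector. Standard
# backpropagation: for a logistic output under cross-entropy the output
# pre-activation error is (y - t).
gradient_data_term <- function(model, X, t) {
  Z <- hidden_activations(model, X)
  y <- as.numeric(plogis(Z %*% model$w2 + model$b2))
  d_out <- y - t
  g_b2 <- sum(d_out)
  g_w2 <- as.numeric(crossprod(Z, d_out))
  D <- (d_out %o% model$w2) * (1 - Z * Z)
  g_b1 <- colSums(D)
  g_W1 <- crossprod(D, X) # hidden x n
  c(as.numeric(g_W1), g_b1, g_w2, g_b2)
}

#' Analytic gradient of the regularised objective
#'
#' Backpropagation of the cross-entropy term plus the per-weight decay
#' `alpha_k * omega_j`, returned in packed weight order.
#'
#' @inheritParams ard_objective
#' @return Numeric vector, one element per weight/bias.
#' @export
ard_gradient <- function(model, groups, alphas, dataset,
                         allow_zero_alpha = FALSE) {
  check_alphas(groups, alphas, allow_zero = allow_zero_alpha)
  X <- as_input_matrix(model, dataset$features)
  g <- gradient_data_term(model, X, dataset$labels)
  g + expand_alphas(groups, as.numeric(alphas)) * pack_weights(model)
}
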
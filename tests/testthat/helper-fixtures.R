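# Fixtures and independent oracles used across the suite. Everything is
# generated in code at test time; no stored data.

# Loop-based moving-window population variance with reflect padding:
# the independent oracle for local_variance().
oracle_local_variance <- function(band, window_size = 7) {
  r <- (window_size - 1) / 2
  h <- nrow(band)
  w <- ncol(band)
  mirror <- function(n) c(rev(seq_len(r) + 1), seq_len(n), n - seq_len(r))
  pad <- band[mirror(h), mirror(w)]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      win <- as.numeric(pad[i:(i + 2 * r), j:(j + 2 * r)])
      m <- sum(win) / length(win)
      out[i, j] <- sum((win - m)^2) / length(win)
    }
  }
  out
}

# Small class map + scene for module tests (fast; patches still much
# larger than the texture window).
small_class_map <- function(seed = 1, height = 80, width = 80,
                            patch_scale = 10, coverage = 0.4) {
  generate_class_map(height, width, patch_scale = patch_scale,
                     coverage_fraction = coverage, seed = seed)
}

small_scene_params <- function(seed = 1, ...) {
  scene_params(patch_scale = 10, seed = seed, ...)
}

# Two-class Gaussian-blob dataset with named feature columns; only the
# first `n_informative` features carry signal.
blob_dataset <- function(n_per_class = 50, n_features = 4,
                         n_informative = 2, separation = 3, seed = 1) {
  set.seed(seed)
  shift <- c(rep(separation, n_informative),
             rep(0, n_features - n_informative))
  x1 <- matrix(rnorm(n_per_class * n_features), n_per_class)
  x0 <- matrix(rnorm(n_per_class * n_features), n_per_class)
  x1 <- sweep(x1, 2, shift, "+")
  feats <- rbind(x1, x0)
  colnames(feats) <- paste0("f", seq_len(n_features))
  pixel_dataset(feats, rep(c(1L, 0L), each = n_per_class))
}

# A hand-set model whose output is driven by the third feature only
# (y > 0.5 iff standardized nir > 0); no training involved.
nir_gate_model <- function() {
  W1 <- matrix(0, 1, 4)
  W1[1, 3] <- 1
  mlpard:::new_mlp(W1, b1 = 0, w2 = 10, b2 = 0,
                   features = c("green", "red", "nir", "texture"))
}

random_small_model <- function(n = 4, hidden = 2, seed = 1) {
  m <- mlp_init(n, hidden, seed = seed)
  # perturb biases too, so no structural zeros survive
  set.seed(seed + 1000)
  mlpard:::unpack_weights(m, mlpard:::pack_weights(m) +
                            rnorm(n * hidden + 2 * hidden + 1, sd = 0.3))
}

random_dataset <- function(n_rows = 10, n_features = 4, seed = 1) {
  set.seed(seed)
  feats <- matrix(rnorm(n_rows * n_features), n_rows)
  colnames(feats) <- paste0("f", seq_len(n_features))
  pixel_dataset(feats, sample(c(0L, 1L), n_rows, replace = TRUE))
}

# Central finite differences of the objective: gradient oracle.
fd_gradient <- function(model, groups, alphas, dataset, h = 1e-6) {
  omega <- mlpard:::pack_weights(model)
  vapply(seq_along(omega), function(j) {
    wp <- omega
    wp[j] <- omega[j] + h
    wm <- omega
    wm[j] <- omega[j] - h
    (ard_objective(mlpard:::unpack_weights(model, wp), groups, alphas,
                   dataset) -
       ard_objective(mlpard:::unpack_weights(model, wm), groups, alphas,
                     dataset)) / (2 * h)
  }, numeric(1))
}
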
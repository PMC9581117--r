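# Fixtures are generated in code; nothing is stored on disk.

# two Gaussian blobs, one per class, optionally fully separable
make_blobs <- function(n_per_class = 30, d = 5, sep = 3, seed = 1,
                       labels = c("neg", "pos")) {
  trgb:::with_seed(seed, {
    x0 <- matrix(rnorm(n_per_class * d), ncol = d)
    x1 <- matrix(rnorm(n_per_class * d), ncol = d)
    x1[, 1] <- x1[, 1] + sep
    df <- as.data.frame(rbind(x0, x1))
    colnames(df) <- paste0("f", seq_len(d))
    df$label <- factor(rep(labels, each = n_per_class), levels = labels)
    df
  })
}

# three collinear Gaussian blobs for multiclass checks
make_blobs3 <- function(n_per_class = 25, d = 4, sep = 4, seed = 1,
                        labels = c("CN", "MCI", "AD")) {
  trgb:::with_seed(seed, {
    blocks <- lapply(seq_along(labels), function(k) {
      x <- matrix(rnorm(n_per_class * d), ncol = d)
      x[, 1] <- x[, 1] + (k - 1) * sep
      x
    })
    df <- as.data.frame(do.call(rbind, blocks))
    colnames(df) <- paste0("f", seq_len(d))
    df$label <- factor(rep(labels, each = n_per_class), levels = labels)
    df
  })
}

# a small, quickly learnable-but-noisy logistic fixture
make_logistic_fixture <- function(n = 200, d = 5, seed = 42) {
  trgb:::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    colnames(x) <- paste0("f", seq_len(d))
    beta <- c(1.5, -1, 0.5, rep(0, d - 3))
    y <- as.integer(runif(n) < plogis(x %*% beta))
    df <- as.data.frame(x)
    df$label <- factor(c("a", "b")[y + 1], levels = c("a", "b"))
    df
  })
}

fast_config <- function(...) trgb_config(n_iterations = 15, ...)
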
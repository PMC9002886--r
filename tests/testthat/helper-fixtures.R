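# Shared fixtures and independent oracles, built in code at test time.

# a small valid sequence with deterministic coordinates
make_toy_sequence <- function(n_frames = 4, subject = "S01", sequence = "walk1") {
  nb <- 20L
  dat <- expand.grid(joint = seq_len(nb), frame = seq_len(n_frames) - 1L)
  dat <- dat[, c("frame", "joint")]
  dat$x <- sin(dat$frame + dat$joint / 7)
  dat$y <- 1 + cos(dat$frame * 0.3 + dat$joint / 5)
  dat$z <- 0.04 * dat$frame + dat$joint / 100
  skeleton_sequence(dat, subject, sequence)
}

# naive direct convolution (triple loop over output pixels and kernel taps):
# the independent oracle for the GEMM-based implementation. x: (H, W, C_in),
# w: (K, K, C_in, C_out), zero "same" padding, single sample.
naive_conv <- function(x, w, stride = 1L) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(w)[1]; cout <- dim(w)[4]
  ho <- ceiling(h / stride); wo <- ceiling(wd / stride)
  pth <- max((ho - 1) * stride + k - h, 0); pbh <- pth %/% 2
  ptw <- max((wo - 1) * stride + k - wd, 0); pbw <- ptw %/% 2
  out <- array(0, c(ho, wo, cout))
  for (i in seq_len(ho)) for (j in seq_len(wo)) for (co in seq_len(cout)) {
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      ii <- (i - 1) * stride + a - pbh
      jj <- (j - 1) * stride + b - pbw
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= wd) {
        acc <- acc + sum(x[ii, jj, ] * w[a, b, , co])
      }
    }
    out[i, j, co] <- acc
  }
  out
}

# brute-force macro one-vs-rest ROC: sweep every distinct score as a
# threshold, trapezoidal area per class, unweighted mean over classes
oracle_macro_auc <- function(scores, labels) {
  p <- ncol(scores)
  aucs <- c()
  for (cl in seq_len(p) - 1) {
    s <- scores[, cl + 1]
    truth <- labels == cl
    if (!any(truth) || all(truth)) next
    thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
    fpr <- vapply(thr, function(t) mean(s[!truth] >= t), numeric(1))
    tpr <- vapply(thr, function(t) mean(s[truth] >= t), numeric(1))
    aucs <- c(aucs, sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2))
  }
  mean(aucs)
}

# EER by dense sampling of a piecewise-linear ROC polyline
oracle_eer <- function(fpr, tpr, n = 1e5) {
  g <- seq(0, 1, length.out = n)
  ti <- approx(fpr, tpr, xout = g, ties = max, rule = 2)$y
  i <- which.min(abs(g - (1 - ti)))
  (g[i] + (1 - ti[i])) / 2
}

# rigid rotation matrix about an arbitrary fixed axis
fixed_rotation <- function() {
  ang <- 0.7
  ax <- c(1, 2, 3) / sqrt(14)
  kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(ang) * kx + (1 - cos(ang)) * kx %*% kx
}

apply_rigid <- function(seq, rot, shift = c(0.3, -0.1, 2)) {
  m <- as.matrix(as.data.frame(seq)[, c("x", "y", "z")]) %*% t(rot)
  out <- as.data.frame(seq)
  out$x <- m[, 1] + shift[1]
  out$y <- m[, 2] + shift[2]
  out$z <- m[, 3] + shift[3]
  skeleton_sequence(out, attr(seq, "subject_id"), attr(seq, "sequence_id"),
                    fps = attr(seq, "fps"), schema = attr(seq, "schema"))
}

# small, fast model configuration for training smoke tests
tiny_config <- function(classes, pooling = "gap") {
  model_config(classes = classes,
               stem = list(kernel = 3, filters = 4),
               blocks = list(block_spec(3, 4, 1), block_spec(3, 6, 2),
                             block_spec(3, 6, 1), block_spec(3, 8, 2),
                             block_spec(3, 8, 1)),
               pooling = pooling, spp_levels = c(1, 2))
}
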
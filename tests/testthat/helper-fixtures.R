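# Shared fixtures: small deterministic masks and reduced-size phantom
# configurations that keep the unit tests fast. The full-size default
# phantom is exercised only in test-acceptance.R.

square_mask <- function(size = 32L, r0 = 5L, r1 = 20L, c0 = 5L, c1 = 20L) {
  m <- matrix(0L, size, size)
  m[r0:r1, c0:c1] <- 1L
  m
}

# small phantom: same kinematic world as the default, scaled down
small_phantom_config <- function(n_frames = 50L, size = 384L, seed = 1L, ...) {
  phantom_config(n_frames = n_frames, image_size = c(size, size),
                 seed = seed, ...)
}

# random blob pair for metric property tests
random_mask_pair <- function(seed, size = 32L) {
  set.seed(seed)
  mk <- function() {
    m <- matrix(0L, size, size)
    cx <- runif(1, 8, size - 8); cy <- runif(1, 8, size - 8)
    rx <- runif(1, 3, 8); ry <- runif(1, 3, 8)
    xs <- matrix(rep(1:size, each = size), size)
    ys <- matrix(rep(1:size, times = size), size)
    m[((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1] <- 1L
    m
  }
  list(a = mk(), b = mk())
}

# brute-force all-pairs HD95 oracle (independent of the EDT route)
hd95_bruteforce <- function(a, b) {
  bnd <- function(m) {
    # 4-neighbour-outside boundary, image border counts as outside
    p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
    p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    inb <- p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] == 1L
    nb <- p[1:nrow(m), 2:(ncol(m) + 1L)] & p[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)] &
          p[2:(nrow(m) + 1L), 1:ncol(m)] & p[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)]
    which(inb & !nb, arr.ind = TRUE)
  }
  pa <- bnd(a); pb <- bnd(b)
  dists <- function(p, q) {
    # for each row of p, distance to nearest row of q
    apply(p, 1, function(pt)
      sqrt(min((q[, 1] - pt[1])^2 + (q[, 2] - pt[2])^2)))
  }
  p95 <- function(x) as.numeric(quantile(x, 0.95, type = 7, names = FALSE))
  max(p95(dists(pa, pb)), p95(dists(pb, pa)))
}

# brute-force two-way ANOVA ICC(3,1) oracle via stats::aov
icc31_aov_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ target + rater, data = d))[[1]][, "Mean Sq"]
  ms_r <- ms[1]; ms_e <- ms[3]
  (ms_r - ms_e) / (ms_r + ms_e)
}
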
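# Independent brute-force oracles and tiny fixtures. Each oracle is a direct,
# loop-level transcription of the definition it checks, sharing no code with
# the implementation.

# all-pairs Euclidean distance matrix by double loop
bf_dist_matrix <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  d
}

# element-wise mutual threshold filter + upper-triangle subtraction
bf_difference_map <- function(a, b, threshold) {
  n <- nrow(a)
  u <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ai <- a[i, j]
      bi <- b[i, j]
      if (ai > threshold || bi > threshold) {
        ai <- 0
        bi <- 0
      }
      u[i, j] <- if (i < j) ai - bi else 0
    }
  }
  u
}

# KS D by scanning |F1 - F2| on a dense grid spanning the pooled range
# (augmented with the pooled points themselves, where the ECDFs jump)
bf_ks_d <- function(x, y, grid_n = 2000) {
  lo <- min(x, y) - 1
  hi <- max(x, y) + 1
  grid <- sort(c(seq(lo, hi, length.out = grid_n), x, y))
  f1 <- vapply(grid, function(g) mean(x <= g), numeric(1))
  f2 <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(f1 - f2))
}

# population skewness, direct transcription of the printed formula
bf_skewness <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  num <- sum((x - xb)^3) / n
  den <- (sum((x - xb)^2) / n)^(3 / 2)
  num / den
}

# Pearson correlation from the covariance / sigma*sigma definition
bf_pcc <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

# ranking loss by enumerating the definition
bf_ranking_loss <- function(true, pred, ids = paste0("m", seq_along(true))) {
  top <- which(pred == max(pred))
  top <- top[order(ids[top])][1]
  abs(max(true) - true[top])
}

# distance-agreement quality by independent pair loop
bf_quality <- function(native, decoy, threshold = 16,
                       cutoffs = c(1, 2, 4, 8)) {
  dn <- bf_dist_matrix(native)
  dd <- bf_dist_matrix(decoy)
  n <- nrow(dn)
  fracs <- numeric(length(cutoffs))
  for (k in seq_along(cutoffs)) {
    hit <- 0L
    tot <- 0L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (dn[i, j] <= threshold) {
          tot <- tot + 1L
          if (abs(dd[i, j] - dn[i, j]) < cutoffs[k]) hit <- hit + 1L
        }
      }
    }
    fracs[k] <- hit / tot
  }
  mean(fracs)
}

# random symmetric distance-map-like matrix with zero diagonal
random_sym_map <- function(L, max_d = 30) {
  m <- matrix(stats::runif(L * L, 0, max_d), L, L)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

# records with random difference maps, for batching/prediction tests
random_records <- function(n, lengths, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    L <- lengths[sample.int(length(lengths), 1)]
    u <- matrix(0, L, L)
    u[upper.tri(u)] <- stats::rnorm(sum(upper.tri(u)))
    model_record(sprintf("T%02d", (i %% 5) + 1), sprintf("m%03d", i),
                 structure(list(values = u, length = L),
                           class = "dmqa_diffmap"),
                 true_gdtts = stats::runif(1))
  })
}

# small network configuration so unit tests stay fast
tiny_net_config <- function(seed = 1) {
  network_config(conv_channels = c(4L, 4L, 8L, 8L), se_ratio = 2L,
                 dense_sizes = c(8L, 4L, 2L, 1L), seed = seed)
}

# write a PDB with one CA (and optional CB) per residue
write_test_pdb <- function(path, ca, cb = NULL, resid = NULL, resno = NULL) {
  L <- nrow(ca)
  if (is.null(resid)) resid <- rep("ALA", L)
  if (is.null(resno)) resno <- seq_len(L)
  xyz <- c()
  rn <- c()
  rs <- c()
  el <- c()
  for (i in seq_len(L)) {
    xyz <- c(xyz, ca[i, ])
    rn <- c(rn, resno[i])
    rs <- c(rs, resid[i])
    el <- c(el, "CA")
    if (!is.null(cb) && resid[i] != "GLY") {
      xyz <- c(xyz, cb[i, ])
      rn <- c(rn, resno[i])
      rs <- c(rs, resid[i])
      el <- c(el, "CB")
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = rn, resid = rs,
                   elety = el, chain = rep("A", length(rn)))
  path
}

write_map_file <- function(path, m) {
  write.table(format(m, digits = 8, trim = TRUE, scientific = FALSE),
              path, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# small end-to-end CLI configuration
tiny_run_config <- function(out, seed = 5) {
  cfg <- default_run_config(out = out, seed = seed)
  cfg$n_targets <- 4L
  cfg$length_min <- 18L
  cfg$length_max <- 24L
  cfg$decoys_per_target <- 6L
  cfg$epochs <- 3L
  cfg$verbose <- FALSE
  cfg
}
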
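# Independent oracles, kept deliberately separate from the package's code
# paths: plain-arithmetic distance, lm-based R^2, and an exhaustive grid
# search. Used to pin expected values rather than re-deriving them from the
# implementation under test.

# Ra as the Euclidean norm of the rescaled difference (2*dd, dp, dhb)
oracle_ra <- function(a, b) {
  d <- (as.numeric(a) - as.numeric(b)) * c(2, 1, 1)
  sqrt(sum(d^2))
}

# signed R^2 through stats::lm / stats::cor
oracle_signed_r2 <- function(candidate, swelling, solvent_tab) {
  ra <- vapply(seq_len(nrow(solvent_tab)), function(i) {
    oracle_ra(candidate, c(solvent_tab$delta_d[i], solvent_tab$delta_p[i],
                           solvent_tab$delta_hb[i]))
  }, numeric(1))
  r2 <- summary(stats::lm(ra ~ swelling))$r.squared
  if (stats::cor(ra, swelling) < 0) r2 else -r2
}

# exhaustive grid search at a fixed step over [lower, upper]^3, chunked over
# delta_hb slices to bound memory; lexicographic tie-break like the package
oracle_grid_search <- function(swelling, solvent_tab, lower, upper, step) {
  ax <- seq(lower, upper, by = step)
  sm <- cbind(solvent_tab$delta_d, solvent_tab$delta_p, solvent_tab$delta_hb)
  sc <- swelling - mean(swelling)
  best_score <- -Inf
  best <- NULL
  for (h in ax) {
    g <- as.matrix(expand.grid(delta_d = ax, delta_p = ax, delta_hb = h,
                               KEEP.OUT.ATTRS = FALSE))
    R <- matrix(0, nrow(g), nrow(sm))
    for (j in seq_len(nrow(sm))) {
      R[, j] <- sqrt(4 * (g[, 1] - sm[j, 1])^2 + (g[, 2] - sm[j, 2])^2 +
                       (g[, 3] - sm[j, 3])^2)
    }
    Rc <- R - rowMeans(R)
    r <- as.vector(Rc %*% sc) / (sqrt(rowSums(Rc^2)) * sqrt(sum(sc^2)))
    s <- ifelse(r < 0, r^2, -r^2)
    m <- max(s)
    if (m > best_score + 1e-15) {
      best_score <- m
      top <- g[s >= m, , drop = FALSE]
      best <- top[order(top[, 1], top[, 2], top[, 3])[1], ]
    }
  }
  list(hsp = unname(best), score = best_score)
}

# small fixed solvent designs used across estimation tests
toy_solvents <- function() {
  data.frame(name = c("s_low", "s_mid", "s_high"),
             delta_d = c(15, 17, 19),
             delta_p = c(2, 8, 14),
             delta_hb = c(4, 10, 6),
             source = "toy", stringsAsFactors = FALSE)
}

make_dataset <- function(solvent, percent, replicate = 1, exclude = character()) {
  swelling_dataset(data.frame(solvent = solvent, replicate = replicate,
                              percent_swelling = percent),
                   exclude = exclude)
}

random_hsp_triple <- function() {
  c(runif(1, 0, 30), runif(1, 0, 30), runif(1, 0, 30))
}
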
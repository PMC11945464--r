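# Independent oracles and small fixture builders shared across tests.

# Forward SPGR steady-state signal, written out directly (kept independent
# of the package's own forward model).
oracle_spgr <- function(r1, m0, flip_deg, tr_ms) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / 1000 * r1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

# Closed-form normal-equations OLS, solved voxel by voxel.
oracle_ols <- function(y, ages, ref_age) {
  a <- ages - ref_age
  X <- cbind(1, a, a^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(beta = unname(drop(beta)), rmse = sqrt(sum(res^2) / (length(y) - 3)))
}

# Brute-force flood fill (breadth-first) connected-component labeling.
oracle_label <- function(mask, connectivity) {
  mask <- mask > 0
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dist <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = dist == 1,
                      "18" = dist >= 1 & dist <= 2,
                      "26" = dist >= 1), , drop = FALSE]
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- cc + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Do two labelings describe the same partition (up to label permutation)?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 1]) &&
    !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 2])
}

# Small phantom spec used by most tests.
tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L, 24L), seed = 11L, ...)
}

# A cuboid analysis mask on a small grid.
box_mask <- function(shape, margin = 4L) {
  m <- array(0, dim = shape)
  idx <- lapply(shape, function(n) (margin + 1L):(n - margin))
  m[idx[[1]], idx[[2]], idx[[3]]] <- 1
  as_analysis_mask(volume_grid(m))
}

# Cohort of volumes with per-voxel values generated from a known quadratic
# age law plus optional iid noise, directly (independent of the phantom
# generator).
law_cohort <- function(shape, ages, beta, noise_sd = 0, seed = 1) {
  ref <- mean(ages)
  set.seed(seed)
  lapply(ages, function(ag) {
    a <- ag - ref
    base <- beta[1] + beta[2] * a + beta[3] * a^2
    volume_grid(array(base + stats::rnorm(prod(shape), 0, noise_sd),
                      dim = shape))
  })
}
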
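# Independent oracles kept deliberately naive.

# boundary = body pixels with at least one non-body 4-neighbour
bruteforce_boundary <- function(body) {
  d <- dim(body)
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!body[i, j]) next
    nb <- c(if (i > 1) body[i - 1, j] else FALSE,
            if (i < d[1]) body[i + 1, j] else FALSE,
            if (j > 1) body[i, j - 1] else FALSE,
            if (j < d[2]) body[i, j + 1] else FALSE)
    out[i, j] <- !all(nb)
  }
  out
}

# O(n^2) nearest-neighbour with lowest-index tie-break
bruteforce_nn <- function(moving, target) {
  idx <- integer(nrow(moving)); dist <- numeric(nrow(moving))
  for (i in seq_len(nrow(moving))) {
    d2 <- colSums((t(target) - moving[i, ])^2)
    idx[i] <- which.min(d2)          # which.min takes the first minimum
    dist[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dist)
}

# exhaustive search over an Euler-angle grid for the best rigid fit
bruteforce_rigid <- function(moving, target, step = 3) {
  angles <- seq(-180, 180 - step, by = step)
  best <- Inf; best_R <- diag(3)
  for (a in angles) for (b in seq(-90, 90, by = step)) for (c in angles) {
    R <- euler_rotation(a, b, c)
    mv <- t(R %*% (t(moving) - colMeans(moving))) # rotate about centroid
    tv <- sweep(target, 2, colMeans(target))
    ss <- sum((mv - tv)^2)
    if (ss < best) { best <- ss; best_R <- R }
  }
  list(R = best_R, ss = best)
}
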
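# Shared fixtures and independent oracles, all built in code at test time.

# minimal hand-built topology: n CA-only atoms on one chain
toy_topology <- function(n, chain = "A") {
  tibble::tibble(
    serial = seq_len(n),
    atom_name = "CA",
    residue_name = "GLY",
    chain_id = chain,
    residue_number = seq_len(n),
    element = "C",
    record_class = "polymer"
  )
}

toy_ensemble <- function(coords_list, chain = "A") {
  a <- nrow(coords_list[[1]])
  arr <- array(NA_real_, dim = c(length(coords_list), a, 3L))
  for (i in seq_along(coords_list)) arr[i, , ] <- coords_list[[i]]
  ensemble(toy_topology(a, chain), arr)
}

# rotation matrices (row-vector convention: x %*% R)
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
euler_rot <- function(a, b, c) rot_z(a) %*% rot_y(b) %*% rot_x(c)

# Independent rigid-motion RMSD minimizer: for any fixed rotation the
# optimal translation matches centroids, so minimize over Euler angles by
# multi-start Nelder-Mead. Never touches SVD.
oracle_min_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    r <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((p %*% r - q)^2)))
  }
  starts <- expand.grid(a = c(0, 90, 180, 270), b = c(-60, 0, 60), c = c(0, 120, 240))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), obj,
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-14)
    )
    best <- min(best, fit$value)
  }
  best
}

# accuracy of a clustering against true labels, over all label permutations
best_label_accuracy <- function(assigned, truth) {
  lv_a <- sort(unique(assigned))
  lv_t <- sort(unique(truth))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(lv_t)) {
    mapped <- p[match(assigned, lv_a)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

jitter_region <- function(start, end, sigma, chain = "A") {
  r <- region_set(tibble::tibble(
    region = paste0("r", start), chain_id = chain,
    start = as.integer(start), end = as.integer(end)
  ))
  r$sigma <- sigma
  r
}
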
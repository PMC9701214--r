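# Global conformational landscape: backbone phi/psi dihedrals per frame,
# standard scaling on the pooled conditions, PCA into a shared 2-D latent
# space, Boltzmann-inverted free-energy surface from histogram density, and
# K-Means state assignment with per-condition occupancies.

#' Backbone phi/psi dihedral matrix of an ensemble
#'
#' phi(i) = torsion(C(i-1), N(i), CA(i), C(i)); psi(i) = torsion(N(i),
#' CA(i), C(i), N(i+1)), in the IUPAC sign convention (cis = 0 degrees),
#' degrees in (-180, 180]. Terminal angles (phi of the first residue, psi
#' of the last) are undefined and omitted, so a chain of R residues yields
#' D = 2R - 2 columns.
#'
#' @param x An [ensemble()].
#' @param chain Chain identifier to analyse.
#' @param condition Label attached to the matrix (used when pooling
#'   conditions into one landscape).
#' @return A `dihedral_matrix`: list with `values` (F x D matrix, degrees),
#'   `column_labels` (tibble of `residue_number`, `angle`), `condition`.
#' @export
phi_psi_matrix <- function(x, chain = "A", condition = "condition") {
  stopifnot(inherits(x, "ensemble"))
  top <- x$topology
  in_chain <- top$chain_id == chain & top$record_class == "polymer"
  if (!any(in_chain)) stop("no polymer atoms in chain ", chain, call. = FALSE)
  resnums <- sort(unique(as.integer(top$residue_number[in_chain])))
  if (length(resnums) > 1 && any(diff(resnums) != 1L)) {
    gap <- resnums[which(diff(resnums) != 1L)[1]]
    stop("chain break in chain ", chain, " after residue ", gap, call. = FALSE)
  }
  r <- length(resnums)
  if (r < 2) stop("need at least 2 residues for dihedrals", call. = FALSE)

  atom_idx <- function(resnum, name) {
    i <- which(in_chain & top$residue_number == resnum & top$atom_name == name)
    if (length(i) != 1) {
      stop("missing backbone atom ", name, " in residue ", resnum,
        " of chain ", chain,
        call. = FALSE
      )
    }
    i
  }
  n_i <- vapply(resnums, atom_idx, integer(1), name = "N")
  ca_i <- vapply(resnums, atom_idx, integer(1), name = "CA")
  c_i <- vapply(resnums, atom_idx, integer(1), name = "C")

  f <- n_frames(x)
  at <- function(i) matrix(x$coords[, i, ], ncol = 3L)
  phi <- matrix(NA_real_, f, r) # phi[ ,1] undefined
  psi <- matrix(NA_real_, f, r) # psi[ ,r] undefined
  for (k in 2:r) {
    phi[, k] <- torsion_angle(at(c_i[k - 1]), at(n_i[k]), at(ca_i[k]), at(c_i[k]))
  }
  for (k in 1:(r - 1)) {
    psi[, k] <- torsion_angle(at(n_i[k]), at(ca_i[k]), at(c_i[k]), at(n_i[k + 1]))
  }

  labels <- tibble::tibble(
    residue_number = c(resnums[-1], resnums[-r]),
    angle = rep(c("phi", "psi"), c(r - 1, r - 1))
  )
  values <- cbind(phi[, -1, drop = FALSE], psi[, -r, drop = FALSE])
  colnames(values) <- paste0(labels$angle, "_", labels$residue_number)
  structure(
    list(values = values, column_labels = labels, condition = condition),
    class = "dihedral_matrix"
  )
}

#' @export
print.dihedral_matrix <- function(x, ...) {
  cat(
    "<dihedral_matrix> '", x$condition, "': ", nrow(x$values), " frames x ",
    ncol(x$values), " angles\n",
    sep = ""
  )
  invisible(x)
}

#' Fit the shared dihedral-PCA landscape over pooled conditions
#'
#' Row-concatenates all condition matrices, standard-scales each column to
#' zero mean and unit variance (population standard deviation) on the
#' pooled data, fits PCA by SVD of the scaled pooled matrix, and projects
#' every condition with the shared scaling and basis, so all conditions
#' live in one comparable latent space. Component signs are fixed by
#' forcing the largest-magnitude loading of each component positive.
#'
#' An optional `mode = "sincos"` replaces each angle by its (sin, cos) pair
#' before scaling (classical dihedral PCA), avoiding distortion near the
#' +/-180 degree periodic seam; the default feeds raw angles to PCA.
#'
#' @param matrices A `dihedral_matrix` or list of them; all must share
#'   column labels.
#' @param n_components Number of latent components retained (default 2).
#' @param mode `"raw"` (default) or `"sincos"`.
#' @return A `landscape_model`: scaling parameters, `components`
#'   (n_components x D, orthonormal rows), `explained_variance`,
#'   `all_eigenvalues`, per-condition `projections` (F x n_components
#'   matrices), `mode`.
#' @export
fit_landscape <- function(matrices, n_components = 2, mode = c("raw", "sincos")) {
  mode <- match.arg(mode)
  if (inherits(matrices, "dihedral_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  labels <- matrices[[1]]$column_labels
  for (m in matrices[-1]) {
    if (!identical(m$column_labels, labels)) {
      stop("dihedral matrices must share identical column labels", call. = FALSE)
    }
  }
  conds <- vapply(matrices, function(m) m$condition, character(1))
  if (anyDuplicated(conds)) stop("condition labels must be unique", call. = FALSE)

  feats <- lapply(matrices, function(m) landscape_features(m$values, mode))
  pooled <- do.call(rbind, feats)
  n <- nrow(pooled)
  mu <- colMeans(pooled)
  sd_pop <- sqrt(colMeans(sweep(pooled, 2, mu)^2))
  zero_var <- which(sd_pop < 1e-12)
  if (length(zero_var) > 0) {
    stop("zero-variance column(s): ",
      paste(colnames(pooled)[zero_var], collapse = ", "),
      " (add noise to the input)",
      call. = FALSE
    )
  }
  z <- sweep(sweep(pooled, 2, mu), 2, sd_pop, `/`)
  s <- svd(z)
  eigenvalues <- s$d^2 / n # population variance along each component
  comp <- t(s$v[, seq_len(n_components), drop = FALSE])
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[k, ]))
    if (comp[k, j] < 0) comp[k, ] <- -comp[k, ]
  }
  colnames(comp) <- colnames(pooled)

  project <- function(feat) {
    zi <- sweep(sweep(feat, 2, mu), 2, sd_pop, `/`)
    pr <- zi %*% t(comp)
    colnames(pr) <- paste0("pc", seq_len(ncol(pr)))
    pr
  }
  projections <- lapply(feats, project)
  names(projections) <- conds

  structure(
    list(
      scaling = list(mean = mu, sd = sd_pop),
      components = comp,
      explained_variance = eigenvalues[seq_len(n_components)],
      all_eigenvalues = eigenvalues,
      projections = projections,
      column_labels = labels,
      mode = mode,
      n_pooled = n
    ),
    class = "landscape_model"
  )
}

landscape_features <- function(values, mode) {
  if (mode == "raw") {
    return(values)
  }
  rad <- values * pi / 180
  out <- cbind(sin(rad), cos(rad))
  colnames(out) <- c(
    paste0("sin_", colnames(values)),
    paste0("cos_", colnames(values))
  )
  out
}

#' Project new dihedral data with a fitted landscape
#'
#' @param model A `landscape_model`.
#' @param matrix A `dihedral_matrix` with the model's column labels.
#' @return F x n_components projection matrix.
#' @export
project_landscape <- function(model, matrix) {
  stopifnot(inherits(model, "landscape_model"), inherits(matrix, "dihedral_matrix"))
  if (!identical(matrix$column_labels, model$column_labels)) {
    stop("column labels do not match the fitted model", call. = FALSE)
  }
  feat <- landscape_features(matrix$values, model$mode)
  zi <- sweep(sweep(feat, 2, model$scaling$mean), 2, model$scaling$sd, `/`)
  pr <- zi %*% t(model$components)
  colnames(pr) <- paste0("pc", seq_len(ncol(pr)))
  pr
}

#' @export
print.landscape_model <- function(x, ...) {
  total <- sum(x$all_eigenvalues)
  cat(sprintf(
    "<landscape_model> %d conditions, %d pooled frames, %d angles (%s mode)\n",
    length(x$projections), x$n_pooled, ncol(x$components), x$mode
  ))
  cat(sprintf(
    "  PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
    100 * x$explained_variance[1] / total,
    100 * x$explained_variance[2] / total
  ))
  invisible(x)
}

#' @export
tidy.landscape_model <- function(x, ...) {
  purrr::map_dfr(names(x$projections), function(cond) {
    pr <- x$projections[[cond]]
    out <- tibble::as_tibble(pr)
    out$condition <- cond
    out$frame <- seq_len(nrow(pr))
    out[, c("condition", "frame", setdiff(names(out), c("condition", "frame")))]
  })
}

#' @export
glance.landscape_model <- function(x, ...) {
  total <- sum(x$all_eigenvalues)
  tibble::tibble(
    n_conditions = length(x$projections),
    n_pooled_frames = x$n_pooled,
    n_features = ncol(x$components),
    var_explained_pc1 = x$explained_variance[1] / total,
    var_explained_pc2 = x$explained_variance[2] / total,
    mode = x$mode
  )
}

#' Free-energy surface from 2-D sample density
#'
#' Bins the projection over its bounding box, converts bin probabilities to
#' free energies F = -ln p shifted so the minimum over occupied bins is
#' zero (kT units; no temperature factor is applied). Empty bins are masked
#' as `NA`.
#'
#' @param projection Numeric F x 2 matrix (e.g. one entry of a
#'   `landscape_model`'s `projections`, or all of them pooled).
#' @param bins Bins per axis (default 60).
#' @param limits Optional list with `x` and `y` ranges `c(lo, hi)`; default
#'   is the projection's bounding box.
#' @return A `free_energy_surface`: list with `x_edges`, `y_edges`,
#'   `energy` (bins x bins matrix, kT, `NA` where empty), `counts`.
#' @export
free_energy_surface <- function(projection, bins = 60, limits = NULL) {
  projection <- as.matrix(projection)
  stopifnot(ncol(projection) == 2, nrow(projection) >= 1, bins >= 2)
  xr <- if (is.null(limits)) range(projection[, 1]) else limits$x
  yr <- if (is.null(limits)) range(projection[, 2]) else limits$y
  if (diff(xr) <= 0 || diff(yr) <= 0) {
    stop("degenerate extent: all points identical along an axis", call. = FALSE)
  }
  x_edges <- seq(xr[1], xr[2], length.out = bins + 1)
  y_edges <- seq(yr[1], yr[2], length.out = bins + 1)
  ix <- findInterval(projection[, 1], x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(projection[, 2], y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)), factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  p <- counts / nrow(projection)
  energy <- -log(p)
  energy[counts == 0L] <- NA_real_
  energy <- energy - min(energy, na.rm = TRUE)
  structure(
    list(x_edges = x_edges, y_edges = y_edges, energy = energy, counts = counts),
    class = "free_energy_surface"
  )
}

#' @export
print.free_energy_surface <- function(x, ...) {
  occ <- sum(!is.na(x$energy))
  cat(sprintf(
    "<free_energy_surface> %dx%d bins, %d occupied, max %.2f kT\n",
    nrow(x$energy), ncol(x$energy), occ, max(x$energy, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
tidy.free_energy_surface <- function(x, ...) {
  bins <- nrow(x$energy)
  xc <- (x$x_edges[-1] + x$x_edges[-(bins + 1)]) / 2
  yc <- (x$y_edges[-1] + x$y_edges[-(bins + 1)]) / 2
  tibble::tibble(
    pc1 = rep(xc, times = bins),
    pc2 = rep(yc, each = bins),
    count = as.integer(x$counts),
    energy = as.numeric(x$energy)
  )
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, the
# rest D^2-weighted.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    probs <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' K-Means conformational states on the pooled latent space
#'
#' Runs K-Means (k-means++ seeding, 10 restarts, Lloyd iterations,
#' squared-Euclidean objective) on the pooled 2-D projections of all
#' conditions, relabels clusters `A`, `B`, `C`, ... by ascending PC1
#' coordinate of their centers, and reports each condition's occupancy of
#' each state.
#'
#' @param model A `landscape_model`.
#' @param k Number of states (default 3).
#' @param seed Integer seed for initialization (default 0).
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return A `state_assignment`: list with `centers` (k x 2, rows ordered
#'   A, B, ...), `labels` (per-condition factor vectors), `occupancy`
#'   (tibble of `condition`, `state`, `occupancy`), `tot_withinss`.
#' @export
kmeans_states <- function(model, k = 3, seed = 0, n_restarts = 10) {
  stopifnot(inherits(model, "landscape_model"))
  pooled <- do.call(rbind, model$projections)
  if (nrow(unique(pooled)) < k) {
    stop("k exceeds the number of distinct projected points", call. = FALSE)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(pooled, k)
      fit <- suppressWarnings(
        stats::kmeans(pooled, centers = init, iter.max = 100, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  ord <- order(best$centers[, 1])
  letters_k <- LETTERS[seq_len(k)]
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- letters_k

  sizes <- vapply(model$projections, nrow, integer(1))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1
  labels <- purrr::map(seq_along(sizes), function(i) {
    factor(letters_k[relabel[best$cluster[starts[i]:stops[i]]]], levels = letters_k)
  })
  names(labels) <- names(model$projections)

  occupancy <- purrr::map_dfr(names(labels), function(cond) {
    tab <- table(labels[[cond]]) / length(labels[[cond]])
    tibble::tibble(
      condition = cond,
      state = letters_k,
      occupancy = as.numeric(tab[letters_k])
    )
  })

  structure(
    list(
      centers = centers, labels = labels, occupancy = occupancy,
      tot_withinss = best$tot.withinss, k = k
    ),
    class = "state_assignment"
  )
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("<state_assignment> ", x$k, " states at PC1-ordered centers:\n", sep = "")
  print(round(x$centers, 3))
  print(tidyr::pivot_wider(x$occupancy,
    names_from = "state", values_from = "occupancy"
  ))
  invisible(x)
}

#' @export
tidy.state_assignment <- function(x, ...) x$occupancy
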
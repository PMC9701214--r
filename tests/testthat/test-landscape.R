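# Dihedral extraction, shared PCA, free-energy surface, K-Means states.

test_that("torsion angles follow the IUPAC sign convention", {
  # planar anti (trans) arrangement
  expect_equal(
    torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
    180
  )
  # hand-evaluated quarter turn, sign flips under mirroring
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))
  expect_equal(torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]]), -90)
  m <- lapply(p, function(v) v * c(1, 1, -1))
  expect_equal(torsion_angle(m[[1]], m[[2]], m[[3]], m[[4]]), 90)
})

test_that("measured phi/psi equal the generator's prescribed basin angles", {
  spec <- synthetic_spec(
    n_residues = 9, n_frames = 3, seed = 12,
    basins = matrix(c(-60, -45), 1), dihedral_noise_deg = 0
  )
  e <- simulate_ensemble(spec)$ensemble
  dm <- phi_psi_matrix(e, chain = "A")
  phis <- dm$values[, dm$column_labels$angle == "phi"]
  psis <- dm$values[, dm$column_labels$angle == "psi"]
  expect_equal(as.numeric(phis), rep(-60, length(phis)), tolerance = 1e-6)
  expect_equal(as.numeric(psis), rep(-45, length(psis)), tolerance = 1e-6)
  expect_equal(ncol(dm$values), 2 * 9 - 2)
})

test_that("torsions agree with an independent structural library", {
  skip_if_not_installed("bio3d")
  spec <- synthetic_spec(n_residues = 7, n_frames = 1, seed = 3, dihedral_noise_deg = 20)
  e <- simulate_ensemble(spec)$ensemble
  dm <- phi_psi_matrix(e, chain = "A")
  xyz <- frame_coords(e, 1)
  # psi of residue 1: N1, CA1, C1, N2 (atoms 1, 2, 3, 4 in topology order)
  expect_equal(
    as.numeric(dm$values[1, "psi_1"]),
    bio3d::torsion.xyz(as.numeric(t(xyz[c(1, 2, 3, 4), ]))),
    tolerance = 1e-6, ignore_attr = TRUE
  )
})

test_that("dihedral extraction validates the chain", {
  e <- build_reference(8)
  expect_error(phi_psi_matrix(e, chain = "B"), "no polymer atoms")
  gap <- e
  gap$topology$residue_number[gap$topology$residue_number >= 5 &
    gap$topology$record_class == "polymer"] <-
    gap$topology$residue_number[gap$topology$residue_number >= 5 &
      gap$topology$record_class == "polymer"] + 1L
  expect_error(phi_psi_matrix(gap, chain = "A"), "chain break")
  drop <- e
  keep <- !(drop$topology$atom_name == "CA" & drop$topology$residue_number == 3)
  drop$topology <- drop$topology[keep, ]
  drop$coords <- drop$coords[, keep, , drop = FALSE]
  expect_error(phi_psi_matrix(drop, chain = "A"), "missing backbone atom CA in residue 3")
})

test_that("PCA matches the eigendecomposition of the scaled covariance", {
  set.seed(8)
  vals <- matrix(stats::rnorm(50 * 6, sd = 20), 50, 6)
  dm <- structure(
    list(
      values = vals,
      column_labels = tibble::tibble(
        residue_number = rep(2:4, 2), angle = rep(c("phi", "psi"), each = 3)
      ),
      condition = "x"
    ),
    class = "dihedral_matrix"
  )
  model <- fit_landscape(dm)
  mu <- colMeans(vals)
  z <- sweep(vals, 2, mu)
  z <- sweep(z, 2, sqrt(colMeans(z^2)), `/`)
  ed <- eigen(crossprod(z) / nrow(z), symmetric = TRUE)
  expect_equal(model$explained_variance, ed$values[1:2], tolerance = 1e-8)
  for (k in 1:2) {
    expect_equal(abs(model$components[k, ]), abs(ed$vectors[, k]),
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
  # orthonormal rows, non-increasing variances, total-variance identity
  expect_equal(model$components %*% t(model$components), diag(2), tolerance = 1e-10)
  expect_true(diff(model$explained_variance) <= 0)
  # total variance of the scaled pooled data equals the eigenvalue sum
  expect_equal(sum(model$all_eigenvalues), sum(colMeans(z^2)), tolerance = 1e-8)
})

test_that("a line embedded in many dimensions loads entirely on PC1", {
  set.seed(3)
  t_par <- stats::rnorm(80)
  dirn <- c(1, -2, 0.5, 3, -1, 2)
  vals <- outer(t_par, dirn) + matrix(stats::rnorm(80 * 6, sd = 1e-6), 80, 6)
  dm <- structure(
    list(
      values = vals,
      column_labels = tibble::tibble(
        residue_number = rep(2:4, 2), angle = rep(c("phi", "psi"), each = 3)
      ),
      condition = "line"
    ),
    class = "dihedral_matrix"
  )
  model <- fit_landscape(dm)
  expect_gt(model$explained_variance[1] / sum(model$all_eigenvalues), 0.999)
})

test_that("fitting is reproducible and shared across conditions", {
  specs <- lapply(c(5, 6), function(s) {
    synthetic_spec(n_residues = 8, n_frames = 60, seed = s, dihedral_noise_deg = 10)
  })
  dms <- lapply(seq_along(specs), function(i) {
    phi_psi_matrix(simulate_ensemble(specs[[i]])$ensemble,
      chain = "A", condition = paste0("c", i)
    )
  })
  m1 <- fit_landscape(dms)
  m2 <- fit_landscape(dms)
  expect_identical(m1$projections, m2$projections)
  # projecting a condition manually reproduces the stored projection
  expect_equal(project_landscape(m1, dms[[2]]), m1$projections$c2, tolerance = 1e-12)
  # zero-variance column is named in the error
  flat <- dms
  flat[[1]]$values[, 3] <- 7
  flat[[2]]$values[, 3] <- 7
  expect_error(fit_landscape(flat), colnames(dms[[1]]$values)[3])
})

test_that("two separated basins are resolved along PC1 with the true labels", {
  spec <- synthetic_spec(
    n_residues = 8, n_frames = 1200, seed = 31,
    basins = rbind(c(-135, 135), c(-15, 15)),
    transition_matrix = rbind(c(0.9, 0.1), c(0.1, 0.9)),
    dihedral_noise_deg = 10
  )
  sim <- simulate_ensemble(spec)
  dm <- phi_psi_matrix(sim$ensemble, chain = "A")
  model <- fit_landscape(dm)
  pc1 <- model$projections[[1]][, 1]
  truth <- ground_truth(spec, sim)$state_sequence
  # PC1 alone separates the generator's states almost perfectly
  split <- mean(c(mean(pc1[truth == 1]), mean(pc1[truth == 2])))
  acc <- best_label_accuracy(as.integer(pc1 > split) + 1L, truth)
  expect_gte(acc, 0.99)
})

test_that("free energies follow the Boltzmann inversion closed forms", {
  # exactly uniform counts: 2x2 grid with one point per bin
  pts <- rbind(c(0.25, 0.25), c(0.75, 0.25), c(0.25, 0.75), c(0.75, 0.75))
  f <- free_energy_surface(pts, bins = 2, limits = list(x = c(0, 1), y = c(0, 1)))
  expect_equal(as.numeric(f$energy), rep(0, 4))

  # 75/25 split over two occupied bins: energies 0 and ln 3
  pts2 <- cbind(c(rep(0.25, 75), rep(0.75, 25)), 0.5)
  f2 <- free_energy_surface(pts2, bins = 2, limits = list(x = c(0, 1), y = c(0, 1)))
  vals <- sort(f2$energy[f2$counts > 0])
  expect_equal(vals, c(0, log(3)), tolerance = 1e-12)
  expect_true(all(is.na(f2$energy[f2$counts == 0])))

  # normalization identity: sum over occupied bins of exp(-F), times the
  # max bin probability, is exactly 1
  set.seed(2)
  f3 <- free_energy_surface(matrix(stats::rnorm(2000), ncol = 2), bins = 20)
  p_max <- max(f3$counts) / 1000
  expect_equal(sum(exp(-f3$energy), na.rm = TRUE) * p_max, 1, tolerance = 1e-12)
  expect_equal(min(f3$energy, na.rm = TRUE), 0)

  expect_error(free_energy_surface(matrix(1, 5, 2)), "degenerate extent")
})

test_that("an isotropic Gaussian yields the quadratic radial free-energy profile", {
  set.seed(99)
  pts <- matrix(stats::rnorm(2e5), ncol = 2)
  f <- free_energy_surface(pts, bins = 60)
  df <- tidy(f)
  df <- df[df$count >= 100, ]
  df$r2 <- df$pc1^2 + df$pc2^2
  # reference the analytic profile to the same zero as the surface
  r2_min <- df$r2[which.min(df$energy)]
  df$predicted <- (df$r2 - min(df$r2)) / 2
  observed <- df$energy - df$energy[which.min(df$r2)]
  # azimuthal averaging: pool bins in thin radial shells
  shell <- round(sqrt(df$r2) / 0.25)
  prof_obs <- tapply(observed, shell, mean)
  prof_pred <- tapply(df$predicted, shell, mean)
  expect_lt(max(abs(prof_obs - prof_pred)), 0.15)
})

test_that("K-Means states recover point masses and well-separated clouds", {
  mk_model <- function(pts_by_cond) {
    structure(
      list(
        projections = lapply(pts_by_cond, function(p) {
          colnames(p) <- c("pc1", "pc2")
          p
        }),
        column_labels = NULL, mode = "raw"
      ),
      class = "landscape_model"
    )
  }
  pts <- rbind(
    matrix(rep(c(-10, 0), each = 30), ncol = 2),
    matrix(rep(c(0, 0), each = 30), ncol = 2),
    matrix(rep(c(10, 0), each = 30), ncol = 2)
  )
  model <- mk_model(list(all = pts))
  st <- kmeans_states(model, k = 3, seed = 0)
  expect_equal(unname(st$centers[, 1]), c(-10, 0, 10))
  expect_equal(st$occupancy$occupancy, rep(1 / 3, 3))

  set.seed(17)
  truth <- sample(1:3, 600, replace = TRUE)
  centers <- rbind(c(-10, 0), c(0, 7), c(10, -3))
  clouds <- centers[truth, ] + matrix(stats::rnorm(1200, sd = 0.5), ncol = 2)
  st2 <- kmeans_states(mk_model(list(all = clouds)), k = 3, seed = 42)
  lab <- as.integer(st2$labels$all)
  expect_equal(best_label_accuracy(lab, truth), 1) # ARI = 1
  # occupancies sum to one; labels stable under frame permutation
  expect_equal(sum(st2$occupancy$occupancy), 1, tolerance = 1e-12)
  perm <- sample(600)
  st3 <- kmeans_states(mk_model(list(all = clouds[perm, ])), k = 3, seed = 42)
  expect_equal(
    as.character(st3$labels$all),
    as.character(st2$labels$all[perm])
  )
  expect_error(kmeans_states(mk_model(list(all = clouds[1:2, ])), k = 3), "distinct")
})

test_that("sin/cos mode handles basins straddling the periodic seam", {
  spec <- synthetic_spec(
    n_residues = 8, n_frames = 300, seed = 77,
    basins = rbind(c(175, 175), c(-60, -45)),
    transition_matrix = rbind(c(0.9, 0.1), c(0.1, 0.9)),
    dihedral_noise_deg = 10
  )
  sim <- simulate_ensemble(spec)
  dm <- phi_psi_matrix(sim$ensemble, chain = "A")
  model <- fit_landscape(dm, mode = "sincos")
  truth <- ground_truth(spec, sim)$state_sequence
  st <- kmeans_states(model, k = 2, seed = 0)
  acc <- best_label_accuracy(as.integer(st$labels[[1]]), truth)
  expect_gte(acc, 0.99)
})
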
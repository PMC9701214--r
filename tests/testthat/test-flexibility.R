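# Kabsch superposition and loop-RMSD series.

test_that("kabsch recovers exact rigid motions", {
  set.seed(41)
  p <- matrix(rnorm(30), 10, 3)
  self <- kabsch_superpose(p, p)
  expect_equal(self$fit_rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  moved <- sweep(p %*% rot_z(90), 2, c(5, 0, 0), `+`)
  fit <- kabsch_superpose(moved, p)
  expect_equal(fit$fit_rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  back <- sweep(moved %*% fit$rotation, 2, fit$translation, `+`)
  expect_equal(back, p, tolerance = 1e-8)
})

test_that("kabsch matches an independent rigid-motion minimizer on small cases", {
  set.seed(7)
  for (rep in 1:4) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    q <- sweep(p %*% euler_rot(35, -20, 60), 2, c(1, -2, 3), `+`) +
      matrix(rnorm(12, sd = 0.3), 4, 3)
    k <- kabsch_superpose(p, q)
    expect_lt(abs(k$fit_rmsd - oracle_min_rmsd(p, q)), 1e-3)
  }
})

test_that("kabsch corrects reflections and rejects degenerate geometry", {
  set.seed(5)
  p <- matrix(rnorm(15), 5, 3)
  mirrored <- p %*% diag(c(1, 1, -1))
  fit <- kabsch_superpose(mirrored, p)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$fit_rmsd, 0) # a reflection is not attainable

  expect_error(kabsch_superpose(p[1:2, ], p[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|rank")
})

test_that("region RMSD is zero for identical frames and exact for a unit displacement", {
  ref <- build_reference(30)
  e <- ensemble(ref$topology, ref$coords[rep(1, 3), , , drop = FALSE])
  fit_sel <- select_atoms(e, chain = "A", atom_names = "CA")
  reg_sel <- select_atoms(e, chain = "A", atom_names = "CA", resnum_ranges = c(10, 15))
  r0 <- region_rmsd_series(e, ref, fit_sel, reg_sel)
  expect_equal(r0$per_frame$rmsd, rep(0, 3), tolerance = 1e-8)
  expect_equal(r0$mean, 0, tolerance = 1e-8)

  # single region atom displaced 1.0 A perpendicular to the backbone plane,
  # region atom excluded from the fit set so the fit stays exact
  e2 <- e
  reg_one <- select_atoms(e2, chain = "A", atom_names = "CA", resnum_ranges = c(12, 12))
  fit_rest <- select_atoms(e2, chain = "A", atom_names = "CA", resnum_ranges = c(1, 11))
  i <- reg_one$indices
  e2$coords[2, i, 3] <- e2$coords[2, i, 3] + 1.0
  r1 <- region_rmsd_series(e2, ref, fit_rest, reg_one)
  expect_equal(r1$per_frame$rmsd, c(0, 1, 0), tolerance = 1e-8)
})

test_that("jitter recovery: mean loop RMSD approaches sigma * sqrt(3)", {
  sigma <- 0.5
  spec <- synthetic_spec(
    n_residues = 60, n_frames = 800, seed = 21,
    jitter_regions = jitter_region(20, 29, sigma)
  )
  sim <- simulate_ensemble(spec)
  ref <- build_reference(60)
  fit_sel <- select_atoms(sim$ensemble, chain = "A", atom_names = "CA")
  reg_sel <- select_atoms(sim$ensemble,
    chain = "A", atom_names = "CA",
    resnum_ranges = c(20, 29)
  )
  fr <- region_rmsd_series(sim$ensemble, ref, fit_sel, reg_sel)
  expect_lt(abs(fr$mean - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.05)
  truth <- ground_truth(spec, sim)
  expect_equal(truth$expected_region_rmsd$expected_mean_rmsd, sigma * sqrt(3))
})

test_that("mean loop RMSD increases strictly with the jitter sigma", {
  means <- vapply(c(0.2, 0.5, 1.0), function(sigma) {
    spec <- synthetic_spec(
      n_residues = 40, n_frames = 400, seed = 33,
      jitter_regions = jitter_region(10, 19, sigma)
    )
    sim <- simulate_ensemble(spec)
    ref <- build_reference(40)
    fit_sel <- select_atoms(sim$ensemble, chain = "A", atom_names = "CA")
    reg_sel <- select_atoms(sim$ensemble,
      chain = "A", atom_names = "CA",
      resnum_ranges = c(10, 19)
    )
    region_rmsd_series(sim$ensemble, ref, fit_sel, reg_sel)$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("loop RMSD is invariant to one global rigid motion of all frames", {
  spec <- synthetic_spec(
    n_residues = 20, n_frames = 10, seed = 9,
    jitter_regions = jitter_region(5, 10, 0.4)
  )
  e <- simulate_ensemble(spec)$ensemble
  ref <- build_reference(20)
  fit_sel <- select_atoms(e, chain = "A", atom_names = "CA")
  reg_sel <- select_atoms(e, chain = "A", atom_names = "CA", resnum_ranges = c(5, 10))
  base <- region_rmsd_series(e, ref, fit_sel, reg_sel)

  r <- euler_rot(17, -40, 120)
  shift <- c(4, -7, 2)
  moved <- e
  for (i in seq_len(n_frames(e))) {
    moved$coords[i, , ] <- sweep(frame_coords(e, i) %*% r, 2, shift, `+`)
  }
  again <- region_rmsd_series(moved, ref, fit_sel, reg_sel)
  expect_equal(again$per_frame$rmsd, base$per_frame$rmsd, tolerance = 1e-8)
})

test_that("summary statistics match direct recomputation from the per-frame series", {
  spec <- synthetic_spec(
    n_residues = 20, n_frames = 50, seed = 2,
    jitter_regions = jitter_region(5, 10, 0.3)
  )
  e <- simulate_ensemble(spec)$ensemble
  ref <- build_reference(20)
  fr <- region_rmsd_series(
    e, ref,
    select_atoms(e, chain = "A", atom_names = "CA"),
    select_atoms(e, chain = "A", atom_names = "CA", resnum_ranges = c(5, 10))
  )
  expect_equal(fr$mean, mean(fr$per_frame$rmsd), tolerance = 1e-12)
  expect_equal(fr$sd, stats::sd(fr$per_frame$rmsd), tolerance = 1e-12)
  expect_true(fr$mean >= min(fr$per_frame$rmsd) && fr$mean <= max(fr$per_frame$rmsd))
  expect_equal(sum(fr$histogram$counts), fr$n_frames)
  g <- glance(fr)
  expect_equal(g$mean_rmsd, fr$mean)
})

test_that("frame sampling is deterministic, ordered, and seed-sensitive", {
  spec <- synthetic_spec(n_residues = 10, n_frames = 200, seed = 4, dihedral_noise_deg = 3)
  e <- simulate_ensemble(spec)$ensemble
  all_frames <- sample_frames(e, 200, seed = 1)
  expect_equal(all_frames$coords, e$coords)

  s1 <- sample_frames(e, 40, seed = 123)
  s2 <- sample_frames(e, 40, seed = 123)
  expect_equal(s1$coords, s2$coords)
  s3 <- sample_frames(e, 40, seed = 124)
  expect_false(isTRUE(all.equal(s1$coords, s3$coords)))
  expect_error(sample_frames(e, 201, seed = 1), "cannot sample")

  # aligned sampling leaves fit atoms superposed on the reference
  ref <- build_reference(10)
  fit_sel <- select_atoms(e, chain = "A", atom_names = "CA")
  sa <- sample_frames(e, 5, seed = 3, reference = ref, fit_sel)
  expect_equal(n_frames(sa), 5)
})
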
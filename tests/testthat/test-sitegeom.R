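rand_cloud <- function(n = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(3 * n, sd = 4), ncol = 3)
}

test_that("Kabsch recovers identity, translations and rotations exactly", {
  x <- rand_cloud(10, seed = 1)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$R, diag(3), tolerance = 1e-9)
  ## pure translation
  fit <- kabsch_superpose(x, sweep(x, 2, c(3, -2, 7), "+"))
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$t, c(3, -2, 7), tolerance = 1e-9)
  ## random rigid motions
  set.seed(2)
  for (i in 1:20) {
    R <- random_rotation()
    tv <- rnorm(3, sd = 5)
    y <- sweep(x %*% t(R), 2, tv, "+")
    fit <- kabsch_superpose(x, y)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)  # proper rotation
  }
})

test_that("Kabsch matches an exhaustive rotation-grid oracle on 4-point toys", {
  set.seed(3)
  x <- rand_cloud(4)
  y <- rand_cloud(4)
  ## center both; grid over Euler angles at 15-degree resolution
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  th <- seq(0, 2 * pi - 1e-9, by = pi / 12)
  rotm <- function(a, b, c) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rz2
  }
  best <- Inf
  for (a in th) for (b in th[th <= pi]) for (c in th) {
    r <- sqrt(mean(rowSums((xc %*% t(rotm(a, b, c)) - yc)^2)))
    if (r < best) best <- r
  }
  fit <- kabsch_superpose(x, y)
  expect_lte(fit$rmsd, best + 1e-9)           # never worse than the grid
  expect_lt(best - fit$rmsd, 0.35 * best + 1) # grid approaches the optimum
})

test_that("Kabsch beats 1000 random rigid transforms", {
  set.seed(4)
  x <- rand_cloud(8)
  y <- rand_cloud(8)
  fit <- kabsch_superpose(x, y)
  for (i in 1:1000) {
    R <- random_rotation(); tv <- rnorm(3, sd = 3)
    r <- sqrt(mean(rowSums((sweep(x %*% t(R), 2, tv, "+") - y)^2)))
    expect_gte(r, fit$rmsd - 1e-12)
  }
})

test_that("Kabsch agrees with the bio3d superposition on random pairs", {
  set.seed(5)
  x <- rand_cloud(12)
  y <- x %*% t(random_rotation()) + matrix(rnorm(36, sd = 0.3), ncol = 3)
  fit <- kabsch_superpose(x, y)
  xv <- as.numeric(t(x)); yv <- as.numeric(t(y))
  xyz <- bio3d::fit.xyz(fixed = yv, mobile = matrix(xv, nrow = 1),
                        fixed.inds = 1:36, mobile.inds = 1:36)
  rmsd_b3d <- sqrt(mean(colSums((matrix(xyz, nrow = 3) -
                                 matrix(yv, nrow = 3))^2)))
  expect_equal(fit$rmsd, rmsd_b3d, tolerance = 1e-6)
})

test_that("collinear point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

site_test_system <- function(depth = 8, n_frames = 30, seed = 6,
                             cls = "lipid_PC") {
  params <- sim_params(
    n_frames = n_frames, save_stride = 5, dt = 0.25, seed = seed,
    well_depths = list(
      outer = setNames(c(depth, depth, depth), lipidsite:::LIPID_CLASSES),
      inner = c(lipid_PC = 0, lipid_PG = 0, lipid_TAP = 0)),
    site_lipid_class = cls)
  sys <- build_membrane_system(membrane_spec(n_lipids_per_leaflet = 0),
                               protein_placeholder(), params)
  list(sys = sys, params = params)
}

ring6 <- c("CG", "CD1", "NE1", "CE2", "CD2", "CE3")

test_that("site RMSD is zero at the reference and exact for rigid shifts", {
  st <- site_test_system()
  sys <- st$sys
  map <- symmetry_map(sys$topology)
  sd1 <- site_definition(1, map, lipid_id = sys$site_lipid_ids[1],
                         ring_names = ring6)
  f0 <- sys$frame0
  traj0 <- trajectory_memory(list(f0))
  expect_equal(site_rmsd_series(traj0, sys$topology, sd1, reference = f0)[1],
               0, tolerance = 1e-12)
  ## displace the site lipid rigidly by 3 A with the protein fixed
  rows <- lipidsite:::site_lipid_rows(sys$topology, sd1)
  f1 <- f0
  f1$xyz[rows, 1] <- f1$xyz[rows, 1] + 3
  traj1 <- trajectory_memory(list(f1))
  expect_equal(site_rmsd_series(traj1, sys$topology, sd1, reference = f0)[1],
               3, tolerance = 1e-9)
})

test_that("site RMSD is invariant under per-frame global rigid motion", {
  st <- site_test_system(n_frames = 10)
  traj <- simulate_membrane(st$sys, st$params)
  map <- symmetry_map(st$sys$topology)
  sd1 <- site_definition(1, map, lipid_id = st$sys$site_lipid_ids[1],
                         ring_names = ring6)
  ref <- st$sys$frame0
  base <- site_rmsd_series(traj, st$sys$topology, sd1, reference = ref)
  set.seed(8)
  moved <- trajectory_memory(lapply(seq_len(n_frames(traj)), function(i) {
    f <- get_frame(traj, i)
    R <- random_rotation()
    f$xyz <- sweep(f$xyz %*% t(R), 2, rnorm(3, sd = 10), "+")
    f
  }))
  rot <- site_rmsd_series(moved, st$sys$topology, sd1, reference = ref)
  expect_equal(rot, base, tolerance = 1e-7)
})

test_that("cation-centroid distances match constructed geometries", {
  ## ring hexagon in the xy plane around the origin + cation on the normal
  df <- data.frame(name = c(ring6, "NC3"),
                   resid = c(rep(206, 6), 1000),
                   resname = c(rep("TRP", 6), "POPC"),
                   chain = c(rep("A", 6), "U"),
                   mol_class = c(rep("protein", 6), "lipid_PC"))
  ang <- (0:5) * pi / 3
  ring_xyz <- cbind(1.4 * cos(ang) + 25, 1.4 * sin(ang) + 25, 25)
  make <- function(cation) {
    xyz <- rbind(ring_xyz, cation)
    list(top = toy_topology(df, xyz, box = c(50, 50, 50)),
         traj = one_frame_traj(xyz, c(50, 50, 50)))
  }
  map5 <- structure(list(chains = c("A", "B", "C", "D", "E")),
                    class = "symmetry_map")
  sd1 <- site_definition(1, map5, chain = "A", lipid_id = 1,
                         ring_names = ring6)
  s <- make(c(25, 25, 29.5))   # 4.5 A above the centroid
  expect_equal(cation_pi_series(s$traj, s$top, sd1, reference =
                                  get_frame(s$traj, 1))[1], 4.5)
  s0 <- make(c(25, 25, 25))    # at the centroid
  d0 <- cation_pi_series(s0$traj, s0$top, sd1,
                         reference = get_frame(s0$traj, 1))
  expect_equal(d0[1], 0)
  expect_equal(attr(d0, "frac_le_4.5"), 1)
  ## random geometry equals a hand recomputation
  set.seed(12)
  for (i in 1:10) {
    cat_pos <- runif(3, 0, 50)
    s <- make(cat_pos)
    got <- cation_pi_series(s$traj, s$top, sd1,
                            reference = get_frame(s$traj, 1))[1]
    cen <- colMeans(ring_xyz)
    expect_equal(got, min_image_distance(cat_pos, cen, c(50, 50, 50)),
                 tolerance = 1e-12)
  }
})

test_that("pooled distribution summaries follow the stated conventions", {
  s <- pool_and_summarize(rep(3.25, 40))
  expect_equal(s$median, 3.25)
  expect_equal(s$q1, 3.25)
  expect_equal(s$q3, 3.25)
  ## two series {0}*n, {10}*n pool to median 5 (midpoint convention)
  s2 <- pool_and_summarize(list(rep(0, 25), rep(10, 25)))
  expect_equal(s2$median, 5)
  expect_equal(s2$n, 50)
  ## pooling equals summarizing the explicit concatenation
  set.seed(13)
  parts <- lapply(1:4, function(i) rnorm(30, mean = i))
  a <- pool_and_summarize(parts)
  b <- pool_and_summarize(unlist(parts))
  for (f in c("median", "q1", "q3", "whisker_lo", "whisker_hi", "n"))
    expect_equal(a[[f]], b[[f]])
  expect_error(pool_and_summarize(list()), "at least one")
})

test_that("deeper wells keep the tracked lipid closer to the aromatic ring", {
  medians <- vapply(c(0, 4, 8), function(depth) {
    st <- site_test_system(depth = depth, n_frames = 60, seed = 31)
    traj <- simulate_membrane(st$sys, st$params)
    map <- symmetry_map(st$sys$topology)
    pooled <- unlist(lapply(1:5, function(s) {
      sd_s <- site_definition(s, map, lipid_id = st$sys$site_lipid_ids[s],
                              ring_names = ring6)
      as.numeric(cation_pi_series(traj, st$sys$topology, sd_s,
                                  reference = st$sys$frame0))
    }))
    median(pooled)
  }, 0)
  expect_true(all(diff(medians) < 0))
})
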
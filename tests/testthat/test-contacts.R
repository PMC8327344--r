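## one protein residue (single bead) + one PC lipid head at distance d
two_particle_system <- function(d, box = c(50, 50, 50)) {
  df <- data.frame(name = c("CA", "CB", "NC3"),
                   resid = c(10, 11, 1000),
                   resname = c("ALA", "ALA", "POPC"),
                   chain = c("A", "A", "U"),
                   mol_class = c("protein", "protein", "lipid_PC"))
  xyz <- rbind(c(10, 10, 10), c(30, 30, 30), c(10 + d, 10, 10))
  list(top = toy_topology(df, xyz, box),
       traj = one_frame_traj(xyz, box))
}

test_that("the contact threshold is inclusive and sharp", {
  pars <- contact_params("cg", threshold = 5.5, lipid_class = "lipid_PC",
                         window = analysis_window(0))
  s <- two_particle_system(5.4)
  prof <- compute_contact_profile(s$traj, s$top, pars)
  expect_equal(prof$frequency[prof$resid == 10], 1.0)
  expect_equal(prof$frequency[prof$resid == 11], 0.0)
  s <- two_particle_system(5.5)   # exactly at threshold: inclusive
  prof <- compute_contact_profile(s$traj, s$top, pars)
  expect_equal(prof$frequency[prof$resid == 10], 1.0)
  s <- two_particle_system(5.6)
  prof <- compute_contact_profile(s$traj, s$top, pars)
  expect_equal(prof$frequency, c(0, 0))
})

test_that("profiles equal the brute-force all-pairs oracle exactly", {
  head_sel <- selection_spec("pc_head", atom_names = "NC3",
                             mol_class = "lipid_PC")
  for (seed in 1:30) {
    s <- random_contact_system(seed)
    traj <- random_frames(s$top, n = 5, seed = seed + 100)
    thr <- runif(1, 2, 12)
    pars <- contact_params("cg", threshold = thr, lipid_class = "lipid_PC",
                           headgroup = head_sel,
                           window = analysis_window(0))
    prof <- compute_contact_profile(traj, s$top, pars)
    oracle <- oracle_contact_profile(traj, s$top, head_sel, thr)
    got <- setNames(prof$frequency, paste(prof$chain, prof$resid))
    expect_identical(unname(got[names(oracle)]), unname(oracle))
  }
})

test_that("enlarging the threshold never decreases any frequency", {
  s <- random_contact_system(7, n_prot_res = 6, n_lip = 10)
  traj <- random_frames(s$top, n = 10, seed = 7)
  prev <- NULL
  for (thr in c(3, 5, 8, 12)) {
    pars <- contact_params("cg", threshold = thr, lipid_class = "lipid_PC",
                           window = analysis_window(0))
    prof <- compute_contact_profile(traj, s$top, pars)
    if (!is.null(prev)) expect_true(all(prof$frequency >= prev - 1e-15))
    prev <- prof$frequency
    expect_true(all(prof$frequency >= 0 & prof$frequency <= 1))
  }
})

test_that("profiles are invariant under particle reordering", {
  s <- random_contact_system(11, n_prot_res = 5, n_lip = 8)
  f <- random_frames(s$top, 4, seed = 11)
  set.seed(99)
  perm <- sample(n_particles(s$top))
  top_p <- toy_topology(s$top$particles[perm, 1:6], s$top$xyz[perm, ],
                        s$top$box)
  traj_p <- trajectory_memory(lapply(seq_len(4), function(i) {
    fr <- get_frame(f, i); fr$xyz <- fr$xyz[perm, ]; fr
  }))
  pars <- contact_params("cg", threshold = 6, lipid_class = "lipid_PC",
                         window = analysis_window(0))
  a <- compute_contact_profile(f, s$top, pars)
  b <- compute_contact_profile(traj_p, top_p, pars)
  key <- function(x) paste(x$chain, x$resid)
  expect_identical(b$frequency[match(key(a), key(b))], a$frequency)
})

test_that("subunit averaging is the exact arithmetic mean of five chains", {
  df <- data.frame(name = "CA", resid = rep(206, 5), resname = "TRP",
                   chain = LETTERS[1:5], mol_class = "protein")
  df <- rbind(df, data.frame(name = "NC3", resid = 1000, resname = "POPC",
                             chain = "U", mol_class = "lipid_PC"))
  ## lipid within 5.5 A of chain A's bead only
  xyz <- rbind(c(10, 10, 10), c(30, 10, 10), c(50, 10, 10),
               c(70, 10, 10), c(90, 10, 10), c(12, 10, 10))
  top <- toy_topology(df, xyz, box = c(200, 200, 50))
  traj <- one_frame_traj(xyz, c(200, 200, 50))
  pars <- contact_params("cg", lipid_class = "lipid_PC",
                         window = analysis_window(0))
  prof <- compute_contact_profile(traj, top, pars)
  map <- symmetry_map(top)
  avg <- average_over_subunits(prof, map)
  expect_equal(avg$frequency[avg$resid == 206], 0.2)  # one of five chains
  ## identical chains: averaging leaves values unchanged
  prof$frequency <- rep(0.4, 5)
  expect_equal(average_over_subunits(prof, map)$frequency, 0.4)
  ## random profiles: equals independent mean
  set.seed(3)
  prof$frequency <- runif(5)
  expect_equal(average_over_subunits(prof, map)$frequency,
               mean(prof$frequency))
  ## missing chain is an error
  expect_error(average_over_subunits(prof[1:4, ], map), "lacks chain")
})

test_that("hot-residue classification uses strict inequality", {
  prof <- data.frame(resid = c(1, 2, 3), frequency = c(0.32, 0.33, 0.34))
  expect_equal(classify_hot_residues(prof, 0.33), 3)
  expect_equal(classify_hot_residues(data.frame(resid = 1:3,
                                                frequency = rep(0, 3))),
               integer(0))
  expect_equal(classify_hot_residues(prof, 0), c(1, 2, 3))
})

test_that("empty selections and empty windows are errors", {
  s <- two_particle_system(5)
  pars <- contact_params("cg", lipid_class = "lipid_PG",
                         window = analysis_window(0))
  expect_error(compute_contact_profile(s$traj, s$top, pars),
               "no particles")
  pars2 <- contact_params("cg", lipid_class = "lipid_PC",
                          window = analysis_window(t_start = 99))
  expect_error(compute_contact_profile(s$traj, s$top, pars2),
               "zero frames")
})

test_that("atomistic mode ignores hydrogens on the protein side", {
  df <- data.frame(name = c("CA", "HA", "N"),
                   resid = c(10, 10, 1000),
                   resname = c("ALA", "ALA", "POPC"),
                   chain = c("A", "A", "U"),
                   is_hydrogen = c(FALSE, TRUE, FALSE),
                   mol_class = c("protein", "protein", "lipid_PC"))
  ## only the hydrogen is within 3.2 A of the lipid atom
  xyz <- rbind(c(10, 10, 10), c(14, 10, 10), c(16, 10, 10))
  top <- toy_topology(df, xyz)
  traj <- one_frame_traj(xyz, c(50, 50, 50))
  head_sel <- selection_spec("aa_head", atom_names = "N",
                             mol_class = "lipid_PC")
  pars <- contact_params("atomistic", lipid_class = "lipid_PC",
                         headgroup = head_sel, window = analysis_window(0))
  prof <- compute_contact_profile(traj, top, pars)
  expect_equal(prof$frequency, 0)   # CA is 6 A away; HA doesn't count
  pars_cg <- contact_params("cg", threshold = 3.2, lipid_class = "lipid_PC",
                            headgroup = head_sel,
                            window = analysis_window(0))
  prof_cg <- compute_contact_profile(traj, top, pars_cg)
  expect_equal(prof_cg$frequency, 1)  # cg mode counts any bead
})
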
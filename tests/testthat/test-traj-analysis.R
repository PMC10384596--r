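test_that("Kabsch superposition matches the quaternion oracle and is rigid-motion invariant", {
  set.seed(21)
  x <- matrix(rnorm(30), 10)
  # identical coordinates
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-10)
  # arbitrary rigid motions leave rmsd at 0 and det(R) at +1
  for (rep in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, 3)
    y <- x %*% (Rz %*% Rx) + matrix(runif(3, -9, 9), 10, 3, byrow = TRUE)
    fit <- superpose(y, x)
    expect_equal(fit$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }
  # displaced atom: agree with the quaternion-based oracle
  y2 <- x; y2[4, ] <- y2[4, ] + c(1, 0, 0)
  expect_equal(superpose(y2, x)$rmsd, quaternion_rmsd(y2, x),
               tolerance = 1e-10)
  # random deformations: Kabsch == quaternion, and superposed <= unsuperposed
  for (rep in 1:5) {
    y3 <- x + matrix(rnorm(30, sd = 0.6), 10)
    expect_equal(superpose(y3, x)$rmsd, quaternion_rmsd(y3, x),
                 tolerance = 1e-9)
    expect_lte(superpose(y3, x)$rmsd, sqrt(mean(rowSums((y3 - x)^2))) + 1e-12)
  }
  expect_error(superpose(x[1:5, ], x), "congruent")
})

test_that("RMSD time courses use the fixed starting structure as reference", {
  m <- make_ideal_fragment("helix", 8)
  base <- coords(m)
  frames <- list(base, base, base)
  tr <- trajectory_segment(m, frames, "RT")
  s <- rmsd_timecourse(tr, selection = "protein")
  expect_equal(s$value, rep(0, 3), tolerance = 1e-10)
  # rigid motion of a frame still gives 0
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr2 <- trajectory_segment(m, list(base, base %*% Rz + 5), "RT")
  expect_equal(rmsd_timecourse(tr2, "protein")$value[2], 0, tolerance = 1e-8)
  # two-frame toy with a known displacement: one atom moved by 1 A out of n
  moved <- base; moved[1, ] <- moved[1, ] + c(1, 0, 0)
  tr3 <- trajectory_segment(m, list(base, moved), "RT")
  expect_equal(rmsd_timecourse(tr3, "protein")$value[2],
               quaternion_rmsd(moved, base), tolerance = 1e-9)
  expect_error(rmsd_timecourse(list()), "empty")
})

test_that("radius of gyration matches closed forms and the direct-sum oracle", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1)), 0)
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(radius_of_gyration(two), 5)
  set.seed(31)
  cloud <- matrix(rnorm(150, sd = 4), 50)
  mass <- runif(50, 1, 16)
  com <- colSums(cloud * mass) / sum(mass)
  oracle <- sqrt(sum(mass * rowSums(sweep(cloud, 2, com)^2)) / sum(mass))
  expect_equal(radius_of_gyration(cloud, mass), oracle, tolerance = 1e-12)
  expect_error(radius_of_gyration(cloud, rep(-1, 50)), "> 0")
})

test_that("Shrake-Rupley SASA matches sphere closed forms and the two-sphere oracle", {
  iso <- structure_model(data.frame(element = "C", name = "C",
                                    residue_index = 1L, residue_name = "GLY",
                                    chain_id = "A", x = 0, y = 0, z = 0,
                                    role = "protein"))
  # isolated atom: exact sphere area 4 pi (r + probe)^2
  expect_equal(sum(sasa(iso, 1.4, 960)), 4 * pi * (1.7 + 1.4)^2,
               tolerance = 1e-6)
  # two far-apart atoms: additivity
  pair <- structure_model(data.frame(element = c("C", "O"),
                                     name = c("C", "O"),
                                     residue_index = 1:2, residue_name = "GLY",
                                     chain_id = "A", x = c(0, 50), y = 0,
                                     z = 0, role = "protein"))
  expect_equal(sum(sasa(pair, 1.4, 480)),
               4 * pi * ((1.7 + 1.4)^2 + (1.52 + 1.4)^2), tolerance = 1e-6)
  # overlapping diatomic: within 2% of the analytic two-sphere area
  for (d in c(1.2, 2.0, 2.8)) {
    dia <- structure_model(data.frame(element = c("C", "O"),
                                      name = c("C", "O"), residue_index = 1:2,
                                      residue_name = "GLY", chain_id = "A",
                                      x = c(0, d), y = 0, z = 0,
                                      role = "protein"))
    exact <- two_sphere_sasa(1.7, 1.52, d, 1.4)
    expect_lt(abs(sum(sasa(dia, 1.4, 960)) - exact) / exact, 0.02)
  }
  # convergence: doubling the sphere points changes the total by < 1%
  m <- make_ideal_fragment("helix", 8)
  a1 <- sum(sasa(m, 1.4, 240)); a2 <- sum(sasa(m, 1.4, 480))
  expect_lt(abs(a2 - a1) / a2, 0.01)
  unk <- iso; unk$atoms$element <- "XX"
  expect_error(sasa(unk), "radius")
})

test_that("non-polar SASA ratio classifies C/S as non-polar with H inheritance", {
  allc <- structure_model(data.frame(element = "C", name = paste0("C", 1:3),
                                     residue_index = 1L, residue_name = "GLY",
                                     chain_id = "A", x = c(0, 2, 4), y = 0,
                                     z = 0, role = "protein"))
  expect_equal(nonpolar_sasa_ratio(allc), 1.0)
  allo <- allc; allo$atoms$element <- "O"; allo$atoms$name <- paste0("O", 1:3)
  expect_equal(nonpolar_sasa_ratio(allo), 0.0)
  # mixed toy with hydrogens: equals the per-atom classification oracle
  mix <- structure_model(data.frame(
    element = c("C", "H", "O", "H"), name = c("C1", "H1", "O1", "H2"),
    residue_index = 1L, residue_name = "GLY", chain_id = "A",
    x = c(0, 1.1, 3.0, 3.9), y = 0, z = 0, role = "protein"))
  areas <- sasa(mix, 1.4, 480)
  # H1 attaches to C1 (non-polar), H2 to O1 (polar)
  oracle <- (areas[1] + areas[2]) / sum(areas)
  expect_equal(nonpolar_sasa_ratio(mix, areas), oracle, tolerance = 1e-12)
})

test_that("beta content separates ideal hairpins from helices", {
  expect_equal(beta_sheet_content(make_ideal_fragment("helix", 12)), 0)
  hp <- make_ideal_fragment("hairpin", 12)
  expect_gt(beta_sheet_content(hp), 0)
  # strand residues, not the connector, carry the assignment
  one <- structure_model(hp$atoms[hp$atoms$residue_index == 1, ])
  expect_equal(beta_sheet_content(one), 0)
  # determinism
  expect_identical(beta_sheet_content(hp), beta_sheet_content(hp))
})

test_that("geometric H-bond criterion applies distance and angle cutoffs", {
  mk <- function(ox, oy = 0) structure_model(data.frame(
    element = c("N", "H", "O"), name = c("N", "H", "O"),
    residue_index = c(1L, 1L, 2L), residue_name = "ALA", chain_id = "A",
    x = c(0, 1.0, ox), y = c(0, 0, oy), z = 0, role = "protein"))
  expect_equal(hbond_count(mk(2.9)), 1L)          # collinear at 2.9 A
  expect_equal(hbond_count(mk(4.2)), 0L)          # beyond 3.5 A
  expect_equal(hbond_count(mk(1.0, 2.9)), 0L)     # 90 deg off the N-H axis
  # deviation just inside 30 degrees still counts
  ang <- 20 * pi / 180
  expect_equal(hbond_count(mk(1 + 1.9 * cos(ang), 1.9 * sin(ang))), 1L)
})

test_that("domain separation reports COM and minimum distances symmetrically", {
  atoms <- data.frame(element = "C", name = "CA",
                      residue_index = c(1L, 2L),
                      residue_name = "GLY", chain_id = "A",
                      x = c(0, 30), y = 0, z = 0, role = "protein")
  m <- structure_model(atoms)
  d <- domain_definition(kringle2 = 1, catalytic = 2)
  out <- domain_separation(m, d)
  expect_equal(out$com_distance, 30)
  expect_equal(out$min_distance, 30)
  # label swap symmetry
  d2 <- domain_definition(kringle2 = 2, catalytic = 1)
  expect_equal(domain_separation(m, d2)$com_distance, 30)
  # collapse: translating one domain into contact shrinks the separation
  m2 <- m; m2$atoms$x[2] <- 4
  expect_lt(domain_separation(m2, d)$com_distance, out$com_distance)
  expect_error(domain_definition(kringle2 = 1:3, catalytic = 3:5), "overlap")
})

test_that("stage concatenation preserves point counts and order", {
  m <- make_ideal_fragment("helix", 6)
  segs <- lapply(c("RT", "F", "1D", "2D", "REC"), function(st)
    make_jitter_trajectory(m, st, n_frames = 3, seed = match(st, c("RT", "F", "1D", "2D", "REC"))))
  full <- concat_segments(segs)
  s <- rmsd_timecourse(full, selection = "protein")
  expect_equal(nrow(s), 15)
  expect_equal(unique(s$stage), c("RT", "F", "1D", "2D", "REC"))
  expect_equal(sum(vapply(segs, n_frames, 1L)), nrow(s))
  expect_error(concat_segments(segs[[3]], segs[[1]]), "order")
  # rg series aligns with the same stage structure
  rg <- rg_timecourse(full)
  expect_equal(rg$stage, s$stage)
  expect_true(all(rg$value > 0))
})
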
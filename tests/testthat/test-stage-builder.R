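test_that("box definition gives the requested protein-to-face margin", {
  one <- tiny_monomer(1)
  one$atoms <- one$atoms[1, ]; one$atoms$x <- 0
  b <- define_box(one, 15, cubic = TRUE)
  expect_equal(b$lengths, rep(30, 3))
  one$box <- b
  expect_equal(box_margin(one), 15)

  # synthetic protein with extents 40 x 30 x 20
  grid <- expand.grid(x = c(0, 40), y = c(0, 30), z = c(0, 20))
  atoms <- data.frame(element = "C", name = "C1",
                      residue_index = seq_len(nrow(grid)),
                      residue_name = "GLY", chain_id = "A",
                      x = grid$x, y = grid$y, z = grid$z, role = "protein")
  m <- structure_model(atoms)
  expect_equal(define_box(m, 15, cubic = TRUE)$lengths, rep(70, 3))
  m$box <- define_box(m, 15, cubic = TRUE)
  expect_equal(box_margin(m), 15)
  # non-cubic margins hold on every axis
  b2 <- define_box(m, 7.5, cubic = FALSE)
  expect_equal(b2$lengths, c(55, 45, 35))
  # empty protein selection fails
  w <- structure_model(data.frame(element = "O", name = "O",
                                  residue_index = 1L, residue_name = "HOH",
                                  chain_id = "W", x = 0, y = 0, z = 0,
                                  role = "water"))
  expect_error(define_box(w, 15), "no protein")
})

test_that("monomer replication spaces centres of mass exactly and rigidly", {
  mono <- make_ideal_fragment("helix", 6)
  multi <- replicate_monomers(mono, c(2, 2, 2), spacing = 85)
  expect_equal(length(unique(multi$atoms$chain_id)), 8)
  coms <- t(sapply(sort(unique(multi$atoms$chain_id)), function(ch)
    colMeans(coords(multi, atom_mask(multi, chain = ch)))))
  d <- as.matrix(dist(coms))
  diag(d) <- Inf
  expect_equal(min(d), 85, tolerance = 1e-10)
  # intra-monomer distances preserved to machine precision
  ch1 <- coords(multi, atom_mask(multi, chain = sort(unique(multi$atoms$chain_id))[2]))
  expect_equal(as.matrix(dist(ch1)), as.matrix(dist(coords(mono))),
               tolerance = 1e-12, ignore_attr = TRUE)

  # 1x1x1 grid is identity up to chain relabel
  same <- replicate_monomers(mono, c(1, 1, 1))
  expect_equal(coords(same), coords(mono), ignore_attr = TRUE)

  # 2x1x1 with spacing 10 displaces along x only
  two <- replicate_monomers(mono, c(2, 1, 1), spacing = 10)
  ids <- sort(unique(two$atoms$chain_id))
  shift <- colMeans(coords(two, atom_mask(two, chain = ids[2]))) -
    colMeans(coords(two, atom_mask(two, chain = ids[1])))
  expect_equal(shift, c(x = 10, y = 0, z = 0), tolerance = 1e-12)

  expect_error(replicate_monomers(mono, c(0, 2, 2)), ">= 1")
})

test_that("molar excipient counts follow N = C V N_A and the formulation table", {
  b0 <- simulation_box(rep(10, 3))
  expect_equal(count_excipients_molar(b0, 0), 0L)
  # volume 1.6605e-21 L at 10 mM -> 10 molecules
  side <- (1.6605e6)^(1/3)
  expect_equal(count_excipients_molar(simulation_box(rep(side, 3)), 10), 10L)
  # invert the 100 mM -> 51 row; the same box must give 5 at 10 mM
  vol_A3 <- 51 / (0.1 * 6.02214076e23) * 1e27
  bx <- simulation_box(rep(vol_A3^(1/3), 3))
  expect_equal(count_excipients_molar(bx, 100), 51L)
  expect_equal(count_excipients_molar(bx, 10), 5L)
  # homogeneity and monotonicity
  for (conc in c(1, 5, 20, 80)) {
    expect_equal(count_excipients_molar(bx, 2 * conc),
                 as.integer(round(2 * conc * 1e-3 * prod(bx$lengths) *
                                    1e-27 * 6.02214076e23)))
    expect_gte(count_excipients_molar(bx, conc + 1),
               count_excipients_molar(bx, conc))
  }
})

test_that("mass-fraction excipient counts use the excipient/(excipient+water) basis", {
  arg <- excipient_spec("ARG", mass_fraction = 0.10)
  expect_equal(count_excipients_ww(1000, arg, 0), 0L)
  expect_equal(count_excipients_ww(1000, arg, 0.10), 11L)   # round(11.49)
  same_mm <- excipient_spec("X", molar_mass = 18.015, net_charge = 0,
                            mass_fraction = 0.5)
  expect_equal(count_excipients_ww(100, same_mm, 0.5), 100L)
  expect_error(count_excipients_ww(100, arg, 1), "fraction")
})

test_that("neutralization reproduces the formulation-table ion inventories", {
  # protein -1 plus 284 ARG(+1) -> 283 Cl-
  ions <- neutralize(-1 + 284)
  expect_equal(ions$n_cl, 283L); expect_equal(ions$n_na, 0L)
  # protein -1 alone -> 1 Na+
  ions2 <- neutralize(-1)
  expect_equal(ions2$n_na, 1L); expect_equal(ions2$n_cl, 0L)
  expect_equal(neutralize(0)$n_na + neutralize(0)$n_cl, 0L)
  # 51 ARG -> 50 Cl-; 5 ARG -> 4 Cl-
  expect_equal(neutralize(-1 + 51)$n_cl, 50L)
  expect_equal(neutralize(-1 + 5)$n_cl, 4L)
  expect_error(neutralize(0.5), "integer")
  # property: inventory always cancels the input charge, never mixes species
  for (q in c(-100, -3, -1, 0, 1, 7, 283)) {
    inv <- neutralize(q)
    expect_equal(inv$n_na - inv$n_cl + q, 0)
    expect_true(inv$n_na == 0 || inv$n_cl == 0)
  }
})

test_that("ice blocks sit on the ice-Ih lattice", {
  blk <- build_ice_block(1, 1, 1)
  expect_equal(nrow(blk$atoms), 12)            # 4 molecules x 3 atoms
  expect_true(all(blk$atoms$role == "ice"))
  big <- build_ice_block(3, 3, 2)
  o <- coords(big, atom_mask(big, name = "O"))
  d <- as.matrix(dist(o)); diag(d) <- Inf
  expect_equal(min(d), 2.75, tolerance = 0.01)  # nearest O-O ~2.75 A
  # tiling doubles the molecule count
  expect_equal(nrow(build_ice_block(2, 1, 1)$atoms),
               2 * nrow(build_ice_block(1, 1, 1)$atoms))
  expect_error(build_ice_block(0, 1, 1), ">= 1")
})

test_that("ice slabs cover the positive faces without steric clashes", {
  set.seed(11)
  mono <- tiny_monomer(3)
  mono$box <- simulation_box(rep(12, 3))
  # put the solute near the +x face to force pruning
  mono <- set_coords(mono, sweep(coords(mono), 2, c(10.5, 6, 6), "+"))
  iced <- place_ice_blocks(mono, clash_cutoff = 2.4)
  ice_idx <- which(iced$atoms$role == "ice")
  expect_gt(length(ice_idx), 0)
  # brute-force: no ice atom within the clash cutoff of the solute
  d2 <- outer(rowSums(coords(iced, ice_idx)^2),
              rowSums(coords(mono)^2), "+") -
    2 * coords(iced, ice_idx) %*% t(coords(mono))
  expect_gte(sqrt(min(d2)), 2.4)
  # pruning is monotone: slab molecule count never exceeds the free tiling
  empty <- structure_model(mono$atoms[0, ], box = mono$box)
  free <- place_ice_blocks(empty, clash_cutoff = 2.4)
  expect_lte(sum(iced$atoms$role == "ice"), sum(free$atoms$role == "ice"))
  # three disjoint slabs on an empty box
  expect_equal(length(unique(free$atoms$chain_id[free$atoms$role == "ice"])), 3)
  expect_error(place_ice_blocks(tiny_monomer(2)), "no box")
})

test_that("bulk-water stripping keeps exactly the hydration shell", {
  prot <- tiny_monomer(3)
  fix <- make_solvated_fixture(prot, list(c(2.0, 6), c(5.0, 7)), seed = 4)
  expect_equal(length(water_oxygens(fix)), 13)
  stripped <- strip_bulk_water(fix, cutoff = 3)
  expect_equal(length(water_oxygens(stripped)), 6)
  # every survivor within 3 A of protein; non-water untouched
  pr <- coords(stripped, atom_mask(stripped, role = "protein"))
  wo <- water_oxygens(stripped)
  dmin <- apply(sqrt(outer(rowSums(coords(stripped, wo)^2), rowSums(pr^2), "+") -
                       2 * coords(stripped, wo) %*% t(pr)), 1, min)
  expect_true(all(dmin <= 3 + 1e-9))
  expect_equal(sum(stripped$atoms$role == "protein"),
               sum(fix$atoms$role == "protein"))
  # no waters: unchanged; all waters far: none retained
  expect_equal(nrow(strip_bulk_water(prot, 3)$atoms), nrow(prot$atoms))
  far <- make_solvated_fixture(prot, list(c(6.0, 5)), seed = 5)
  expect_equal(length(water_oxygens(strip_bulk_water(far, 3))), 0)
})

test_that("residual-water selection matches crystal-water sites", {
  prot <- tiny_monomer(3)
  fix <- make_solvated_fixture(prot, list(c(2.5, 4)), seed = 6)
  wo <- water_oxygens(fix)
  sites <- coords(fix, wo[1:2])
  kept <- select_residual_waters(fix, sites, match_cutoff = 1.5)
  expect_equal(length(water_oxygens(kept)), 2)
  # displaced by 0.5 A still matches at 1.5 A cutoff
  kept2 <- select_residual_waters(fix, sites + 0.5 / sqrt(3), 1.5)
  expect_equal(length(water_oxygens(kept2)), 2)
  # empty crystal list removes everything, with a warning
  expect_warning(none <- select_residual_waters(fix, NULL), "crystal")
  expect_equal(length(water_oxygens(none)), 0)
})

test_that("re-solvation fills the box at grid density outside the clash zone", {
  # empty solute, pure grid count: floor(L/spacing)^3
  empty <- structure_model(tiny_monomer(1)$atoms[0, ],
                           box = simulation_box(rep(12.4, 3)))
  solv <- resolvate(empty, grid_spacing = 3.1)
  expect_equal(length(water_oxygens(solv)), floor(12.4 / 3.1)^3)
  # with solute: margin 15 and no water within the clash cutoff
  prot <- tiny_monomer(3)
  solv2 <- resolvate(prot, margin = 15, grid_spacing = 3.1)
  expect_equal(box_margin(solv2), 15, tolerance = 1e-9)
  wo <- water_oxygens(solv2)
  pr <- coords(solv2, atom_mask(solv2, role = "protein"))
  d2 <- outer(rowSums(coords(solv2, wo)^2), rowSums(pr^2), "+") -
    2 * coords(solv2, wo) %*% t(pr)
  expect_gte(sqrt(min(d2)), 2.4)
  expect_error(resolvate(prot, grid_spacing = -1), "grid_spacing")
})

test_that("the five-stage pipeline runs end to end, each stage consuming the last", {
  prot <- make_ideal_fragment("hairpin", 12)
  stages <- run_fd_pipeline(prot, excipients = excipient_spec("ARG", conc_mM = 100),
                            protein_net_charge = -1, seed = 7)
  expect_named(stages, c("RT", "F", "1D", "2D", "REC"))
  expect_equal(box_margin(stages$RT), 15, tolerance = 1e-9)
  expect_true(any(stages$F$atoms$role == "ice"))
  expect_equal(box_margin(stages$`1D`), 50, tolerance = 1e-9)
  expect_lte(length(water_oxygens(stages$`2D`)),
             length(water_oxygens(stages$`1D`)))
  expect_equal(box_margin(stages$REC), 15, tolerance = 1e-9)
  expect_gt(length(water_oxygens(stages$REC)),
            length(water_oxygens(stages$`2D`)))
  # system is neutral after ion addition
  n_na <- sum(stages$RT$atoms$element == "NA")
  n_cl <- sum(stages$RT$atoms$element == "CL")
  expect_equal((n_na - n_cl) + stages$RT$net_charge, 0)
})

test_that("stage configs validate their numeric rules", {
  expect_equal(stage_config("RT")$box_margin, 15)
  expect_equal(stage_config("CG")$box_margin, 7.5)
  expect_equal(stage_config("1D")$box_margin, 50)
  expect_equal(stage_config("REC")$box_margin, 15)
  expect_error(stage_config("RT", box_margin = -1), "> 0")
  expect_error(stage_config("RT", heatmap_filter = 1.2), "heatmap_filter")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("RT:", "  box_margin: 12", "CG:", "  cg_spacing: 40"), f)
  cfgs <- read_stage_config(f)
  expect_equal(cfgs$RT$box_margin, 12)
  expect_equal(cfgs$CG$cg_spacing, 40)
  expect_equal(cfgs$CG$box_margin, 7.5)
})
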
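# Pose bundle I/O, reference sites, best-pose selection.

test_that("a 2-compound x 16-pose bundle round-trips through PDB + CSV", {
  spec <- pose_set_spec(n_active_compounds = 2, poses_per_compound = 16,
                        seed = 3)
  ps <- gen_pose_set(spec)
  expect_equal(nrow(ps$poses), 32)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pose_bundle(ps$poses, pdb, csv)
  back <- read_pose_bundle(pdb, csv)
  expect_equal(nrow(back), 32)
  expect_equal(back$compound_id, ps$poses$compound_id)
  expect_equal(back$ee, ps$poses$ee, tolerance = 1e-9)
  expect_equal(back$docked_energy, ps$poses$docked_energy, tolerance = 1e-9)
  # coordinates survive at PDB precision (3 decimals)
  expect_equal(back$atoms[[1]]$x, ps$poses$atoms[[1]]$x, tolerance = 1e-3)
  expect_equal(back$atoms[[5]]$is_polar_heavy,
               ps$poses$atoms[[5]]$element %in% c("N", "O"))
})

test_that("energy rows without a matching model are dropped with a warning", {
  spec <- pose_set_spec(n_active_compounds = 2, poses_per_compound = 2,
                        seed = 4)
  ps <- gen_pose_set(spec)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pose_bundle(ps$poses, pdb, csv)
  extra <- readr::read_csv(csv, show_col_types = FALSE)
  extra <- dplyr::bind_rows(extra,
                            tibble::tibble(compound_id = "ghost",
                                           pose_rank = 1, ee = -2,
                                           docked_energy = -7))
  readr::write_csv(extra, csv)
  expect_warning(back <- read_pose_bundle(pdb, csv), "without a matching model")
  expect_equal(nrow(back), 4)
  expect_false("ghost" %in% back$compound_id)
})

test_that("empty MODEL blocks and untagged count mismatches are fatal", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("MODEL        1", "ENDMDL", "END"), pdb)
  readr::write_csv(tibble::tibble(compound_id = "c1", pose_rank = 1,
                                  ee = -1, docked_energy = -5), csv)
  expect_error(read_pose_bundle(pdb, csv), "no atoms")

  writeLines(c(
    "MODEL        1",
    "HETATM    1  N1  LIG A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ENDMDL",
    "MODEL        2",
    "HETATM    1  N1  LIG A   1       1.000   0.000   0.000  1.00  0.00           N",
    "ENDMDL", "END"
  ), pdb)
  expect_error(read_pose_bundle(pdb, csv), "2 model")
})

test_that("non-numeric energies are skipped with a warning", {
  spec <- pose_set_spec(n_active_compounds = 1, poses_per_compound = 3,
                        seed = 5)
  ps <- gen_pose_set(spec)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pose_bundle(ps$poses, pdb, csv)
  lines <- readLines(csv)
  lines[2] <- sub("^([^,]*,[^,]*,)[^,]*", "\\1not_a_number", lines[2])
  writeLines(lines, csv)
  # the bad row is skipped, which also leaves its model without an energy row
  expect_warning(
    expect_warning(back <- read_pose_bundle(pdb, csv), "non-numeric"),
    "no energy row"
  )
  expect_equal(nrow(back), 2)
  expect_length(attr(back, "errors"), 1)
})

test_that("best pose selection minimizes docked energy with rank tie-break", {
  atoms <- list(atoms_at_distances(3, 3))
  poses <- make_poses(
    ids = rep("c1", 3), ranks = c(1L, 2L, 3L),
    ee = c(-1, -5, -2), docked = c(-6, -8, -7),
    atoms_list = rep(atoms, 3)
  )
  best <- best_pose_per_compound(poses)
  expect_equal(nrow(best), 1)
  expect_equal(best$pose_rank, 2L)

  tied <- make_poses(
    ids = rep("c1", 2), ranks = c(2L, 1L),
    ee = c(-1, -2), docked = c(-8, -8),
    atoms_list = rep(atoms, 2)
  )
  expect_equal(best_pose_per_compound(tied)$pose_rank, 1L)

  single <- make_poses("c2", ee = -1, docked = -3, atoms_list = atoms)
  expect_equal(best_pose_per_compound(single), single)
})

test_that("reference sites are read from a receptor PDB via chain and residue", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_fixture(pdb)
  cfg <- list("D3.32" = list(chain = "A", resid = 94),
              "E5.46" = list(chain = "A", resid = 182))
  site <- read_reference_site(pdb, cfg)
  expect_s3_class(site, "reference_site")
  expect_equal(nrow(site[["D3.32"]]), 2)   # OD1 + OD2 only, carbons excluded
  expect_equal(site[["D3.32"]][1, ], c(0, 0, 0))
  expect_equal(site[["E5.46"]][2, ], c(8.9, 1.3, 0.6))
  # JSON configuration path
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, js, auto_unbox = TRUE)
  site2 <- read_reference_site(pdb, js)
  expect_equal(site2[["E5.46"]], site[["E5.46"]])
  expect_error(
    read_reference_site(pdb, list("D3.32" = list(chain = "B", resid = 94),
                                  "E5.46" = list(chain = "A", resid = 182))),
    "No carboxylate")
})
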
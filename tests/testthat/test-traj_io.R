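# Trajectory and annotation I/O.

test_that("multi-model PDB: model count, unit conversion, metadata", {
  pdb <- c(
    "MODEL     1",
    "ATOM      1  N   ALA A   1      10.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.500   2.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       0.000   0.000   3.000  1.00  0.00",
    "ATOM      4  CA  GLY A   2       5.000   5.000   5.000  1.00  0.00",
    "ATOM      5  CA  SER B   3      -1.000  -2.000  -3.000  1.00  0.00",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  N   ALA A   1      11.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.500   2.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       0.000   0.000   3.000  1.00  0.00",
    "ATOM      4  CA  GLY A   2       5.000   5.000   5.000  1.00  0.00",
    "ATOM      5  CA  SER B   3      -1.000  -2.000  -3.000  1.00  0.00",
    "ENDMDL",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  tr <- read_multimodel_pdb(f)
  expect_equal(n_frames(tr), 2)
  expect_equal(n_atoms(tr), 5)
  expect_equal(tr$coords[1, 1, 1], 1.0) # 10 A -> 1 nm
  expect_equal(tr$atoms$atom_name, c("N", "CA", "C", "CA", "CA"))
  # continuous residue numbering spans chains
  expect_equal(tr$atoms$residue_number, c(1L, 1L, 1L, 2L, 3L))
  expect_equal(tr$atoms$residue_id, c(1L, 1L, 1L, 2L, 3L))
})

test_that("multi-model PDB rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".pdb")
  # inconsistent atom counts across models
  writeLines(c("MODEL     1",
               "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
               "ENDMDL",
               "MODEL     2",
               "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
               "ATOM      2  CA  ALA A   2       1.000   0.000   0.000  1.00  0.00",
               "ENDMDL"), f)
  expect_error(read_multimodel_pdb(f), class = "srd_format_error")
  # zero models / no atoms
  writeLines(c("REMARK empty", "END"), f)
  expect_error(read_multimodel_pdb(f), "empty input", class = "srd_usage_error")
  # altloc rejected
  writeLines(c("MODEL     1",
               "ATOM      1  CA AALA A   1       0.000   0.000   0.000  1.00  0.00",
               "ENDMDL"), f)
  expect_error(read_multimodel_pdb(f), class = "srd_format_error")
})

test_that("PDB round trip preserves coordinates to format precision", {
  withr::local_seed(11)
  tr <- rand_traj(4, 12, sd = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f)
  back <- read_multimodel_pdb(f)
  expect_equal(n_frames(back), 4)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3) # PDB %8.3f A = 1e-4 nm
  expect_equal(back$dt_frame, tr$dt_frame)
  expect_equal(back$atoms$residue_number, tr$atoms$residue_number)
})

test_that("GRO round trip preserves coordinates and frame times", {
  withr::local_seed(12)
  tr <- rand_traj(10, 7, sd = 1.5, dt = 40)
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro_trajectory(tr, f)
  back <- read_gro_trajectory(f)
  expect_equal(n_frames(back), 10)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3)
  expect_equal(back$dt_frame, 40) # from t= stamps, not the default
  # empty file -> empty-input error
  f2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(character(0), f2)
  expect_error(read_gro_trajectory(f2), class = "srd_usage_error")
})

test_that("trim_frames obeys the floor formula and edge cases", {
  withr::local_seed(13)
  tr <- rand_traj(10, 3, dt = 20)
  expect_identical(trim_frames(tr, 0), tr)
  out <- trim_frames(tr, 100) # frames at t = 0..80 dropped
  expect_equal(n_frames(out), 5)
  expect_equal(out$coords[1, , ], tr$coords[6, , ])
  expect_equal(out$time0, 100)
  expect_error(trim_frames(tr, 200), class = "srd_usage_error")
  expect_error(trim_frames(tr, 1000), class = "srd_usage_error")
  # floor formula on a non-multiple discard
  out2 <- trim_frames(tr, 50) # keeps t >= 50: frames 4..10
  expect_equal(n_frames(out2), floor((10 * 20 - 50) / 20))
})

test_that("select_atoms and the backbone fit selection", {
  withr::local_seed(14)
  # 3 residues x backbone(N, CA, C) + one O atom
  nat <- 10
  atoms <- data.frame(
    atom_index = 1:nat,
    atom_name = c(rep(c("N", "CA", "C"), 3), "O"),
    residue_number = c(rep(1:3, each = 3), 3L),
    residue_id = c(rep(1:3, each = 3), 3L),
    chain_id = "A", residue_name = "ALA")
  tr <- srd_trajectory(array(0, c(2, nat, 3)), 20, atoms)
  expect_equal(select_calpha(tr), c(2, 5, 8))
  ss <- ss_table(data.frame(domain = c("s1", "l1"),
                            res_start = c(1, 3), res_end = c(2, 3),
                            kind = c("strand", "loop")))
  expect_equal(fit_selection(tr, ss), 1:6) # backbone of the 2-residue strand
  expect_error(select_atoms(tr, function(a) a$atom_name == "ZZ"),
               class = "srd_usage_error")
})

test_that("packaged secondary-structure fixtures are contiguous and well-typed", {
  ss <- read_ss_table(path_ss_fixtures())
  expect_s3_class(ss, "srd_sstable")
  expect_true(all(ss$kind %in% c("strand", "helix", "loop")))
  covered <- unlist(mapply(seq, ss$res_start, ss$res_end, SIMPLIFY = FALSE))
  expect_equal(sort(covered), 1:240)
  # overlapping or gapped tables are rejected
  bad <- data.frame(domain = c("a", "b"), res_start = c(1, 3),
                    res_end = c(3, 5), kind = "loop")
  expect_error(ss_table(bad), class = "srd_format_error")
})
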
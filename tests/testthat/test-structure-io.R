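test_that("a minimal PDB round-trips into a C-alpha model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, mini_pdb_lines())
  m <- read_structure(f)
  expect_s3_class(m, "calpha_model")
  expect_equal(nrow(m), 3)
  expect_equal(model_subunits(m), "A")
  expect_equal(m$aa, c("A", "L", "G"))
  expect_equal(m$seq_num, 1:3)
  expect_equal(m[, c("x", "y", "z")] |> as.matrix() |> unname(),
               rbind(c(1, 0, 0), c(3, 1, 0), c(4, 2, 1)))
  # determinism: same file, same options -> identical model
  expect_identical(as.data.frame(read_structure(f)), as.data.frame(m))
})

test_that("residues without a C-alpha are skipped with a message", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- mini_pdb_lines()
  write_mini_pdb(f, lines[-4])   # drop LEU 2's CA, keep its N
  expect_message(m <- read_structure(f), "without a C-alpha")
  expect_equal(nrow(m), 2)
  expect_equal(m$seq_num, c(1, 3))
})

test_that("altlocs resolve to the highest occupancy, ties to file order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(
    pdb_atom_line(1, "ALA", "A", 1, 1, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "ALA", "A", 1, 9, 0, 0, occ = 0.6, alt = "B"),
    pdb_atom_line(3, "GLY", "A", 2, 5, 0, 0, occ = 0.5, alt = "A"),
    pdb_atom_line(4, "GLY", "A", 2, 7, 0, 0, occ = 0.5, alt = "B")))
  m <- read_structure(f)
  expect_equal(m$x, c(9, 5))   # B wins res 1; tie -> first listed wins res 2
})

test_that("hetero C-alpha of a known modified residue is kept as its parent", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
             sub("^ATOM  ", "HETATM", pdb_atom_line(2, "MSE", "A", 2, 3, 0, 0)))
  write_mini_pdb(f, lines)
  m <- read_structure(f)
  expect_equal(m$aa, c("A", "M"))
})

test_that("error contracts: missing file, empty model, unknown assembly", {
  expect_error(read_structure(tempfile()), "not found",
               class = "capsidprof_input_error")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, pdb_atom_line(1, "HOH", "A", 1, 0, 0, 0, elety = " O  "))
  expect_error(read_structure(f), "no C-alpha",
               class = "capsidprof_input_error")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f2, mini_pdb_lines(), header = biomt_block(c(0, 180)))
  expect_error(read_structure(f2, assembly = 7), "unknown assembly",
               class = "capsidprof_input_error")
})

test_that("BIOMT assembly expansion yields chains x operators copies", {
  f <- withr::local_tempfile(fileext = ".pdb")
  n_ops <- 60
  X <- cbind(20 + seq_len(10), 0, seq_len(10))
  lines <- pdb_atom_line(1:10, "ALA", "A", 1:10, X[, 1], X[, 2], X[, 3])
  write_mini_pdb(f, lines, header = biomt_block(seq(0, 354, by = 6)))
  m <- read_structure(f, assembly = 1)
  expect_equal(nrow(m), 10 * n_ops)
  expect_equal(length(model_subunits(m)), n_ops)
  # transform-major ordering: first copy first, named chain.k
  expect_equal(m$subunit[1], "A.1")
  expect_equal(m$subunit[nrow(m)], paste0("A.", n_ops))
})

test_that("expand_assembly: identity, symmetry and rigid-motion contracts", {
  m <- toy_model(rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3)))
  ident <- list(list(rotation = diag(3), translation = c(0, 0, 0)))
  e <- expand_assembly(m, ident)
  expect_identical(coord_unname(e), coord_unname(m))
  expect_equal(model_subunits(e), model_subunits(m))

  rot180z <- list(rotation = diag(c(-1, -1, 1)), translation = c(0, 0, 0))
  p <- expand_assembly(toy_model(matrix(c(1, 0, 0), 1)), list(rot180z))
  expect_equal(c(p$x, p$y, p$z), c(-1, 0, 0))

  set.seed(42)
  tfs <- replicate(4, random_rigid(), simplify = FALSE)
  e2 <- expand_assembly(m, tfs)
  expect_equal(nrow(e2), 4 * nrow(m))
  d0 <- dist(coord_unname(m))
  for (k in 1:4) {
    copy <- e2[e2$subunit == paste0("A.", k), ]
    expect_lt(max(abs(dist(coord_unname(copy)) - d0)), 1e-9)
  }
  # inverse transforms recover the original coordinates
  inv <- lapply(tfs, function(tf) list(
    rotation = t(tf$rotation),
    translation = -as.vector(t(tf$rotation) %*% tf$translation)))
  for (k in 1:4) {
    back <- expand_assembly(
      as_calpha_model(e2[e2$subunit == paste0("A.", k), ]), inv[k])
    expect_lt(max(abs(coord_unname(back) - coord_unname(m))), 1e-9)
  }
})

test_that("expand_assembly rejects improper rotations", {
  m <- toy_model(rbind(c(1, 0, 0), c(0, 2, 0)))
  reflect <- list(list(rotation = diag(c(-1, 1, 1)), translation = c(0, 0, 0)))
  expect_error(expand_assembly(m, reflect), "orthonormal",
               class = "capsidprof_input_error")
  skew <- list(list(rotation = matrix(c(1, 0.1, 0, 0, 1, 0, 0, 0, 1), 3),
                    translation = c(0, 0, 0)))
  expect_error(expand_assembly(m, skew), class = "capsidprof_input_error")
})

test_that("external operator files are read and applied", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# identity then z-flip",
               "1 0 0 0 1 0 0 0 1 0 0 0",
               "-1 0 0 0 -1 0 0 0 1 0 0 10"), f)
  tfs <- read_transforms(f)
  expect_length(tfs, 2)
  m <- toy_model(matrix(c(1, 0, 0), 1))
  e <- expand_assembly(m, tfs)
  expect_equal(c(e$x[2], e$y[2], e$z[2]), c(-1, 0, 10))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 0 0", bad)
  expect_error(read_transforms(bad), "12 numbers",
               class = "capsidprof_input_error")
})

test_that("mmCIF assembly operators are parsed from oper_list/assembly_gen", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "loop_",
    "_pdbx_struct_oper_list.id",
    "_pdbx_struct_oper_list.matrix[1][1]",
    "_pdbx_struct_oper_list.matrix[1][2]",
    "_pdbx_struct_oper_list.matrix[1][3]",
    "_pdbx_struct_oper_list.vector[1]",
    "_pdbx_struct_oper_list.matrix[2][1]",
    "_pdbx_struct_oper_list.matrix[2][2]",
    "_pdbx_struct_oper_list.matrix[2][3]",
    "_pdbx_struct_oper_list.vector[2]",
    "_pdbx_struct_oper_list.matrix[3][1]",
    "_pdbx_struct_oper_list.matrix[3][2]",
    "_pdbx_struct_oper_list.matrix[3][3]",
    "_pdbx_struct_oper_list.vector[3]",
    "1 1 0 0 0  0 1 0 0  0 0 1 0",
    "2 -1 0 0 0  0 -1 0 0  0 0 1 5",
    "loop_",
    "_pdbx_struct_assembly_gen.assembly_id",
    "_pdbx_struct_assembly_gen.oper_expression",
    "_pdbx_struct_assembly_gen.asym_id_list",
    "1 '(1-2)' A",
    "2 1 A"), f)
  tfs <- capsidprof:::mmcif_transforms(f, 1)
  expect_length(tfs, 2)
  expect_equal(tfs[[2]]$rotation, diag(c(-1, -1, 1)))
  expect_equal(tfs[[2]]$translation, c(0, 0, 5))
  expect_length(capsidprof:::mmcif_transforms(f, 2), 1)
  expect_error(capsidprof:::mmcif_transforms(f, 9), "unknown assembly",
               class = "capsidprof_input_error")
})

test_that("colored-PDB write/read round-trips values at B-factor precision", {
  m <- toy_model(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0)))
  prof <- wcn_profile(m)
  prof$value <- c(-1.5, 0, 2.25)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_colored_structure(m, prof, f, mode = "pdb_bfactor")
  back <- bio3d::read.pdb(f)
  expect_equal(back$atom$b, c(-1.5, 0, 2.25))

  # arbitrary values round-trip to the 0.01 quantization
  prof$value <- c(0.123456, -3.98765, 10.005)
  write_colored_structure(m, prof, f, mode = "pdb_bfactor")
  back <- bio3d::read.pdb(f)
  expect_true(all(abs(back$atom$b - prof$value) <= 0.005 + 1e-9))

  # constant profile
  prof$value <- rep(1, 3)
  write_colored_structure(m, prof, f, mode = "pdb_bfactor")
  expect_equal(bio3d::read.pdb(f)$atom$b, rep(1, 3))
})

test_that("colored-structure export logs gaps, clamps, and errors on strangers", {
  m <- toy_model(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0)))
  prof <- wcn_profile(m)

  stranger <- prof
  stranger$seq_num <- stranger$seq_num + 100
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_colored_structure(m, stranger, f),
               class = "capsidprof_input_error")

  partial <- prof[1:2, ]
  expect_message(write_colored_structure(m, partial, f, mode = "pdb_bfactor"),
                 "no profile value")
  expect_equal(bio3d::read.pdb(f)$atom$b[3], 0)

  big <- prof
  big$value <- c(1e5, -1e5, 1)
  expect_message(write_colored_structure(m, big, f, mode = "pdb_bfactor"),
                 "clamped")
  b <- bio3d::read.pdb(f)$atom$b
  expect_equal(b, c(999.99, -99.99, 1))
})

test_that("attribute_table mode writes a per-residue TSV", {
  m <- toy_model(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0)))
  prof <- normalize_profile(wcn_profile(m))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_colored_structure(m, prof, f, mode = "attribute_table")
  tb <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(tb), 3)
  expect_true(all(c("subunit", "seq_num", "value") %in% names(tb)))
  expect_equal(tb$value, prof$value, tolerance = 1e-12)
})
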
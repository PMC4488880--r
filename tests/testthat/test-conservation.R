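test_that("grades files round-trip in both dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(grades_lines(1:3, c("M", "K", "L"), c(-0.8, 0.1, 1.2)), f)
  cons <- parse_rate4site(f)
  expect_equal(cons$pos, 1:3)
  expect_equal(cons$aa, c("M", "K", "L"))
  expect_equal(cons$score, c(-0.8, 0.1, 1.2))
  expect_false(isTRUE(attr(cons, "normalized")))

  # interleaved comment lines change nothing
  f2 <- withr::local_tempfile(fileext = ".txt")
  base <- grades_lines(1:3, c("M", "K", "L"), c(-0.8, 0.1, 1.2))
  writeLines(c(base[1:3], "# interleaved comment", base[4], "", base[5]), f2)
  expect_equal(as.data.frame(parse_rate4site(f2)), as.data.frame(cons),
               ignore_attr = TRUE)

  # plain two-column table, no residue letters
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("5\t-1.25", "6\t0.5"), f3)
  c3 <- parse_rate4site(f3)
  expect_equal(c3$pos, 5:6)
  expect_true(all(is.na(c3$aa)))
  expect_equal(c3$score, c(-1.25, 0.5))

  # classic rows with trailing columns: score stays the third field
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 M -0.83 [-1.2,-0.4] 0.31 45/50", f4)
  expect_equal(parse_rate4site(f4)$score, -0.83)
})

test_that("grades parser error contracts", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only", "# comments"), f)
  expect_error(parse_rate4site(f), "no data rows",
               class = "capsidprof_input_error")
  writeLines(grades_lines(c(1, 3, 2), c("M", "K", "L"), c(1, 2, 3)), f)
  expect_error(parse_rate4site(f), "strictly increasing",
               class = "capsidprof_input_error")
  writeLines(c("1 M -0.8", "2 K not_a_number"), f)
  expect_error(parse_rate4site(f), "line 2",
               class = "capsidprof_input_error")
})

test_that("write_grades is the exact inverse of parse_rate4site", {
  set.seed(4)
  cons <- capsidprof:::new_conservation(1:50, rep("A", 50), rnorm(50))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_grades(cons, f)
  back <- parse_rate4site(f)
  expect_identical(back$score, cons$score)
  expect_identical(back$pos, cons$pos)
})

test_that("column entropy scores behave analytically", {
  msa <- list(s1 = strsplit("AAGA-", "")[[1]],
              s2 = strsplit("AAGC-", "")[[1]],
              s3 = strsplit("A-GG-", "")[[1]],
              s4 = strsplit("A-GTA", "")[[1]])
  cons <- entropy_conservation(msa, "s1")
  # query s1 has residues in columns 1-4; column 5 is a query gap: skipped
  expect_equal(cons$pos, 1:4)
  expect_equal(cons$score[1], 0)                     # all A
  expect_equal(cons$score[2], 0)                     # gaps excluded: A,A
  expect_equal(cons$score[3], 0)                     # all G
  expect_equal(cons$score[4], 2)                     # uniform over 4 letters
  # 50/50 split is exactly 1 bit; uniform over 20 letters log2(20)
  msa2 <- list(q = rep("A", 2), o = rep("G", 2))
  expect_equal(entropy_conservation(msa2, "q")$score, c(1, 1))
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  msa20 <- stats::setNames(lapply(aa20, function(a) c(a, "A")), paste0("s", 1:20))
  expect_equal(entropy_conservation(msa20, "s1")$score[1], log2(20),
               tolerance = 1e-12)
})

test_that("entropy scorer validates input and ignores sequence order", {
  msa <- list(a = c("A", "C"), b = c("A", "C", "G"))
  expect_error(entropy_conservation(msa, "a"), "ragged",
               class = "capsidprof_input_error")
  expect_error(entropy_conservation(list(a = c("A", "C")), "zz"),
               class = "capsidprof_input_error")
  msa3 <- list(a = c("A", "C"), b = c("A", "G"), c = c("C", "G"))
  expect_equal(entropy_conservation(msa3, "a")$score,
               entropy_conservation(rev(msa3), "a")$score)
})

test_that("aligned FASTA files feed the entropy scorer", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "MKL-", ">h1", "MKI-", ">h2", "MRLA"), f)
  cons <- entropy_conservation(f, "q")
  expect_equal(cons$pos, 1:3)
  expect_equal(cons$aa, c("M", "K", "L"))
  # col 1 is unanimous; cols 2 and 3 split 2:1, H = log2(3) - 2/3
  expect_equal(cons$score, c(0, 0.9182958, 0.9182958), tolerance = 1e-6)
})

test_that("site mapping pairs by residue number with an offset", {
  m <- toy_model(cbind(1:3, 0, 0), aa = c("M", "K", "L"))
  cons <- capsidprof:::new_conservation(1:3, c("M", "K", "L"), c(-1, 0, 1))
  sm <- map_to_structure(cons, m, "A")
  expect_equal(nrow(sm$pairs), 3)
  expect_equal(nrow(sm$mismatches), 0)
  expect_equal(sm$pairs$score, c(-1, 0, 1))

  m2 <- toy_model(cbind(1:3, 0, 0), seq_num = 11:13, aa = c("M", "K", "L"))
  sm2 <- map_to_structure(cons, m2, "A", offset = 10)
  expect_equal(nrow(sm2$pairs), 3)
  expect_equal(sm2$pairs$seq_num, 11:13)

  # mapping twice gives the identical map
  sm2b <- map_to_structure(cons, m2, "A", offset = 10)
  expect_identical(sm2$pairs, sm2b$pairs)
})

test_that("site mapping records leftovers and rejects letter disagreement", {
  m <- toy_model(cbind(1:4, 0, 0), aa = c("M", "K", "L", "W"))
  cons <- capsidprof:::new_conservation(2:6, c("K", "L", "W", "A", "A"),
                                        seq(-1, 1, length.out = 5))
  sm <- map_to_structure(cons, m, "A")
  expect_equal(sm$pairs$pos, 2:4)
  expect_equal(sm$unmapped_structure$seq_num, 1)
  expect_equal(sm$unmapped_sites$pos, c(5, 6))

  wrong <- capsidprof:::new_conservation(1:4, c("A", "A", "A", "A"), 1:4)
  expect_error(map_to_structure(wrong, m, "A"), "mismatch",
               class = "capsidprof_mapping_error")
  sm_forced <- map_to_structure(wrong, m, "A", force = TRUE)
  expect_equal(nrow(sm_forced$mismatches), 4)
  expect_error(map_to_structure(wrong, m, "A", offset = 1000),
               class = "capsidprof_input_error")
})

test_that("insertion-coded residues stay unmapped", {
  df <- tibble::tibble(subunit = "A", chain = "A", seq_num = c(1, 2, 2, 3),
                       icode = c("", "", "A", ""), aa = c("M", "K", "G", "L"),
                       x = 1:4, y = 0, z = 0)
  m <- as_calpha_model(df)
  cons <- capsidprof:::new_conservation(1:3, c("M", "K", "L"), c(-1, 0, 1))
  sm <- map_to_structure(cons, m, "A")
  expect_equal(nrow(sm$pairs), 3)
  expect_true(any(sm$unmapped_structure$icode == "A"))
})

test_that("conservation normalization matches the shared population-sd contract", {
  cons <- capsidprof:::new_conservation(1:3, c("M", "K", "L"), c(1, 2, 3))
  z <- normalize_conservation(cons)
  expect_equal(z$score, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_true(attr(z, "normalized"))
  expect_equal(normalize_conservation(z)$score, z$score, tolerance = 1e-10)
  flat <- capsidprof:::new_conservation(1:3, c("M", "K", "L"), c(2, 2, 2))
  expect_error(normalize_conservation(flat),
               class = "capsidprof_degenerate_error")
  # smoothing never reorders sites
  sm <- smooth_profile(cons, 3)
  expect_identical(sm$pos, cons$pos)
})
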
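test_that("FASTA reading preserves order and normalizes case and T->U", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">h1", "acgt", ">h2 some description", "GGGAAACCC"), f)
  seqs <- read_hairpin_fasta(f)
  expect_identical(names(seqs), c("h1", "h2"))
  expect_identical(unname(seqs[1]), "ACGU")
  expect_identical(unname(seqs[2]), "GGGAAACCC")

  single <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">h1", "ACGU"), single)
  expect_identical(unname(read_hairpin_fasta(single)), "ACGU")
})

test_that("FASTA reading rejects empty and malformed files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_hairpin_fasta(f), "no records")
  g <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hx", "ACGJQZ"), g)
  expect_error(read_hairpin_fasta(g), "outside A/C/G/U")
  expect_error(read_hairpin_fasta(tempfile()), "not found")
})

test_that("Vienna structure blocks parse and strip the energy token", {
  f <- withr::local_tempfile(fileext = ".vienna")
  writeLines(c(">h1", "GGGAAACCC", "(((...))) ( -1.20)",
               ">h2", "AAAA", "...."), f)
  st <- read_structures(f)
  expect_identical(st[["h1"]], "(((...)))")
  expect_identical(st[["h2"]], "....")
})

test_that("structure file errors name the offending record", {
  bad_len <- withr::local_tempfile()
  writeLines(c(">h1", "GGGAAACCC", "((...))"), bad_len)
  expect_error(read_structures(bad_len), "h1")

  unbalanced <- withr::local_tempfile()
  writeLines(c(">h2", "GGAACC", "(((..)"), unbalanced)
  expect_error(read_structures(unbalanced), "unbalanced")

  missing_line <- withr::local_tempfile()
  writeLines(c(">h3", "GGAACC"), missing_line)
  expect_error(read_structures(missing_line), "missing a structure line")
})

test_that("mature TSV parses 1-based starts and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("h1\t17\t22", "h2\t5\t21"), f)
  ann <- read_mature_tsv(f)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$mature_start[ann$id == "h1"], 17L)
  expect_equal(ann$mature_len[ann$id == "h2"], 21L)

  zero <- withr::local_tempfile()
  writeLines("h1\t0\t22", zero)
  expect_error(read_mature_tsv(zero), "start < 1")

  dup <- withr::local_tempfile()
  writeLines(c("h1\t17\t22", "h1\t18\t22"), dup)
  expect_error(read_mature_tsv(dup), "duplicate")

  hdr <- withr::local_tempfile()
  writeLines(c("id\tstart\tlen", "h1\t17\t22"), hdr)
  expect_equal(read_mature_tsv(hdr)$mature_start, 17L)
})

test_that("hairpin ingest enforces structure/sequence consistency", {
  hp <- perfect_hairpin()
  expect_s3_class(hp, "hairpin")
  expect_error(hairpin("bad", strrep("A", 50), strrep(".", 49)),
               "length")
  expect_error(hairpin("bad", strrep("A", 50),
                       paste0("((", strrep(".", 48))), "unbalanced")
  expect_error(hairpin("short", "ACGU", "...."), "40-200")
  expect_error(hairpin("bad", strrep("A", 50), strrep(".", 50),
                       mature_start = 40, mature_len = 22), "outside")
})

test_that("model save/load round-trips predictions exactly", {
  model <- fit_tiny_model(n = 25, rounds = 1)
  hp <- simulate_hairpins(2, seed = 99)
  path <- withr::local_tempfile(fileext = ".rds")
  save_mirstart(model, path)
  loaded <- load_mirstart(path)
  expect_identical(score_candidates(loaded, hp[[1]]),
                   score_candidates(model, hp[[1]]))
})

test_that("model loading refuses corrupted or inconsistent bundles", {
  model <- fit_tiny_model(n = 25, rounds = 1)
  path <- withr::local_tempfile(fileext = ".rds")

  writeLines("not a model", path)
  expect_error(load_mirstart(path), "corrupted")

  bad <- model
  bad$normalization$min <- bad$normalization$min[1:109]
  saveRDS(bad, path)
  expect_error(load_mirstart(path), "110")

  stale <- model
  stale$codebook_version <- "mirstart-codebook-0"
  saveRDS(stale, path)
  expect_error(load_mirstart(path), "codebook")
  expect_error(score_candidates(stale, simulate_hairpins(1, seed = 1)[[1]]),
               "codebook")
})
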
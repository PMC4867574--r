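test_that("pair_table builds a symmetric partner array", {
  expect_identical(pair_table("((..))"), c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_identical(pair_table("......"), integer(6))
  expect_error(pair_table("((.)"), "unbalanced")
  expect_error(pair_table("(x)"), "invalid")

  pt <- pair_table("((..((...))))")
  paired <- which(pt > 0L)
  expect_identical(pt[pt[paired]], paired)
})

test_that("pair_table and dot-bracket rendering are mutually inverse", {
  for (h in simulate_hairpins(5, seed = 21, bulge_rate = 0.15)) {
    expect_identical(render_dot_bracket(pair_table(h$structure)),
                     h$structure)
  }
})

test_that("terminal loop starts after the innermost 5'-arm pair", {
  expect_equal(terminal_loop_start(pair_table("(((...)))")), 4L)
  expect_equal(terminal_loop_start(pair_table("((..((...))))")), 7L)
  expect_error(terminal_loop_start(pair_table("......")), "no stem")
})

test_that("a perfect stem window aligns fully paired with N padding", {
  hp <- perfect_hairpin(flank5 = 10, stem = 14)
  d <- build_duplex(hp, start = 11, window_len = 10)
  expect_length(d$top, 25L)
  expect_true(all(d$paired[1:10]))
  expect_true(all(d$top[11:25] == "N" & d$bottom[11:25] == "N"))
  expect_false(any(d$paired[11:25]))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  expect_identical(d$bottom[1:10], unname(comp[d$top[1:10]]))
})

test_that("a top-strand bulge aligns as a single gapped column", {
  hp <- bulged_hairpin(flank5 = 10, before = 3, after = 10)
  d <- build_duplex(hp, start = 11, window_len = 10)
  gap_cols <- which(d$bottom == "-")
  expect_identical(gap_cols, 4L)
  expect_true(all(d$paired[c(1:3, 5:10)]))
  expect_false(d$paired[4])
})

test_that("a symmetric 2x2 internal loop yields two gapless unpaired columns", {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  p <- c("G", "C", "A", "U"); q <- c("C", "G", "U", "A")
  revcomp <- function(x) rev(unname(comp[x]))
  seq <- paste(c(rep("A", 10), p, c("A", "A"), q, rep("C", 6),
                 revcomp(q), c("G", "G"), revcomp(p), rep("A", 10)),
               collapse = "")
  str <- paste(c(rep(".", 10), rep("(", 4), "..", rep("(", 4),
                 rep(".", 6), rep(")", 4), "..", rep(")", 4),
                 rep(".", 10)), collapse = "")
  hp <- hairpin("iloop", seq, str)
  d <- build_duplex(hp, start = 11, window_len = 10)
  # brute-force walk of the hand-built pair table: columns 5 and 6 carry
  # the internal loop on both strands, everything else pairs
  expect_true(all(d$paired[c(1:4, 7:10)]))
  expect_false(any(d$paired[5:6]))
  expect_false(any(d$top[1:10] == "-"))
  expect_false(any(d$bottom[1:10] == "-"))
  expect_identical(d$top[5:6], c("A", "A"))
  expect_identical(d$bottom[5:6], c("G", "G"))
})

test_that("windows with no pairing partner align against gaps", {
  hp <- perfect_hairpin(flank5 = 12, stem = 14)
  d <- build_duplex(hp, start = 1, window_len = 10)  # inside the 5' flank
  expect_true(all(d$bottom[1:10] == "-"))
  expect_false(any(d$paired))
})

test_that("stack table is complete and negative", {
  tab <- load_stack_table()
  expect_length(tab, 36L)
  expect_true(all(tab < 0))
  wc <- expand.grid(c("AU", "UA", "CG", "GC"), c("AU", "UA", "CG", "GC"))
  keys <- paste0(substr(wc[[1]], 1, 1), substr(wc[[2]], 1, 1), "/",
                 substr(wc[[1]], 2, 2), substr(wc[[2]], 2, 2))
  expect_true(all(keys %in% names(tab)))
})

test_that("region energy is a stack-table sum over adjacent paired columns", {
  tab <- load_stack_table()
  d <- structure(list(top = c("G", "C", rep("N", 23)),
                      bottom = c("C", "G", rep("N", 23)),
                      paired = c(TRUE, TRUE, rep(FALSE, 23))),
                 class = "duplex")
  expect_equal(region_energy(d, c(1, 2), tab), tab[["GC/CG"]])
  expect_equal(region_energy(d, c(2, 25), tab), 0)   # single paired column
  expect_equal(region_energy(d, c(3, 25), tab), 0)   # none

  hp <- perfect_hairpin(flank5 = 10, stem = 14, seed = 5)
  dd <- build_duplex(hp, start = 11, window_len = 12)
  whole <- region_energy(dd, c(1, 25), tab)
  # shared-boundary split
  expect_equal(region_energy(dd, c(1, 5), tab) +
                 region_energy(dd, c(5, 25), tab), whole)
  # disjoint split plus the boundary stack
  boundary <- paste0(dd$top[5], dd$top[6], "/", dd$bottom[5], dd$bottom[6])
  expect_equal(region_energy(dd, c(1, 5), tab) +
                 region_energy(dd, c(6, 25), tab) + tab[[boundary]], whole)
})

test_that("region energy decreases monotonically as the range grows", {
  hp <- perfect_hairpin(flank5 = 10, stem = 14, seed = 8)
  d <- build_duplex(hp, start = 11, window_len = 14)
  e <- vapply(2:25, function(k) region_energy(d, c(1, k)), 0)
  expect_true(all(diff(e) <= 1e-12))
})
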
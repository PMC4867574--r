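# Hand-built hairpin fixtures used across tests.

# Perfect stem-loop: flank5 + stem + loop + revcomp(stem) + flank3,
# structure exact by construction.
perfect_hairpin <- function(id = "perfect", flank5 = 10L, stem = 14L,
                            loop = 6L, flank3 = 10L, mature_start = NULL,
                            seed = 42L) {
  set.seed(seed)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  arm <- sample(names(comp), stem, replace = TRUE)
  seq <- paste(c(sample(names(comp), flank5, TRUE), arm,
                 sample(names(comp), loop, TRUE),
                 rev(unname(comp[arm])),
                 sample(names(comp), flank3, TRUE)), collapse = "")
  str <- paste(c(rep(".", flank5), rep("(", stem), rep(".", loop),
                 rep(")", stem), rep(".", flank3)), collapse = "")
  hairpin(id, seq, str, mature_start = mature_start,
          mature_len = min(22L, stem))
}

# Stem with a single-nt bulge on the 5' arm after `before` pairs:
# flank5 + pairs + bulge + pairs + loop + revcomp pairs + flank3.
bulged_hairpin <- function(id = "bulged", flank5 = 10L, before = 3L,
                           after = 10L, loop = 6L, flank3 = 10L,
                           seed = 7L) {
  set.seed(seed)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  arm1 <- sample(names(comp), before, TRUE)
  arm2 <- sample(names(comp), after, TRUE)
  bulge <- sample(names(comp), 1L)
  seq <- paste(c(sample(names(comp), flank5, TRUE),
                 arm1, bulge, arm2,
                 sample(names(comp), loop, TRUE),
                 rev(unname(comp[arm2])), rev(unname(comp[arm1])),
                 sample(names(comp), flank3, TRUE)), collapse = "")
  str <- paste(c(rep(".", flank5), rep("(", before), ".", rep("(", after),
                 rep(".", loop), rep(")", after + before),
                 rep(".", flank3)), collapse = "")
  hairpin(id, seq, str)
}

truth_frame <- function(hairpins) {
  data.frame(id = vapply(hairpins, `[[`, "", "id"),
             mature_start = vapply(hairpins, `[[`, 0L, "mature_start"),
             stringsAsFactors = FALSE)
}

fit_tiny_model <- function(n = 30L, rounds = 2L, seed = 3L, ...) {
  hp <- simulate_hairpins(n, seed = seed)
  suppressWarnings(mirstart(hp, rounds = rounds, seed = seed, ...))
}
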
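.rna_comp <- c(A = "U", C = "G", G = "C", U = "A")

# one synthetic stem-loop; deterministic in (seed, index)
.make_hairpin <- function(index, flank5_len, flank3_len, stem_len, loop_len,
                          mature_len, bulge_rate, signal_strength, seed) {
  set.seed((as.integer(seed) * 10007L + as.integer(index)) %% 2147483647L)
  # per-hairpin length jitter so the planted start varies in position
  f5 <- max(3L, flank5_len + sample(-4:4, 1L))
  f3 <- max(3L, flank3_len + sample(-4:4, 1L))
  stem <- max(mature_len - 3L, stem_len + sample(-3:3, 1L))
  loop <- max(4L, loop_len + sample(-2:2, 1L))
  signature <- stats::runif(1L) < signal_strength

  top_seq <- character(0); top_str <- character(0)
  bot_seq <- character(0); bot_str <- character(0)  # 3'->5' order
  for (k in seq_len(stem)) {
    b <- if (k == 1L && signature) "U" else sample(names(.rna_comp), 1L)
    top_seq <- c(top_seq, b); top_str <- c(top_str, "(")
    bot_seq <- c(bot_seq, .rna_comp[[b]]); bot_str <- c(bot_str, ")")
    protected <- signature && k < 9L  # keep first 9 duplex columns paired
    if (k < stem && !protected && stats::runif(1L) < bulge_rate) {
      defect <- sample(c("mismatch", "bulge_top", "bulge_bottom"), 1L)
      if (defect == "mismatch") {
        x <- sample(names(.rna_comp), 1L)
        y <- sample(setdiff(names(.rna_comp), .rna_comp[[x]]), 1L)
        top_seq <- c(top_seq, x); top_str <- c(top_str, ".")
        bot_seq <- c(bot_seq, y); bot_str <- c(bot_str, ".")
      } else if (defect == "bulge_top") {
        top_seq <- c(top_seq, sample(names(.rna_comp), 1L))
        top_str <- c(top_str, ".")
      } else {
        bot_seq <- c(bot_seq, sample(names(.rna_comp), 1L))
        bot_str <- c(bot_str, ".")
      }
    }
  }
  rand_nt <- function(n) sample(names(.rna_comp), n, replace = TRUE)
  seq <- paste(c(rand_nt(f5), top_seq, rand_nt(loop), rev(bot_seq),
                 rand_nt(f3)), collapse = "")
  str <- paste(c(rep(".", f5), top_str, rep(".", loop), rev(bot_str),
                 rep(".", f3)), collapse = "")
  hairpin(sprintf("synth%04d", index), seq, str,
          mature_start = f5 + 1L, mature_len = mature_len)
}

#' Simulate stem-loop hairpins with a planted mature start
#'
#' Generates structurally exact synthetic pre-miRNA-like hairpins: a random
#' 5' flank, a stem whose 3' arm is the reverse complement of the 5' arm
#' apart from seeded bulges and mismatches, a terminal loop and a 3'
#' flank. The dot-bracket structure is emitted by construction, so it is
#' exactly consistent with the sequence and independent of any folding
#' energy model. The planted mature start is the first stem position; with
#' probability `signal_strength` a hairpin carries the learnable start
#' signature (5' U at the start and a fully paired first 9 duplex columns).
#' Flank, stem and loop lengths are jittered by a few nt per hairpin so the
#' start position itself carries no constant-position shortcut.
#'
#' @param n_hairpins Number of hairpins.
#' @param flank5_len,flank3_len Central flank lengths in nt.
#' @param stem_len Central number of base pairs in the stem (must be at
#'   least `mature_len - 3`).
#' @param loop_len Central terminal-loop length in nt.
#' @param mature_len Planted mature length in nt.
#' @param bulge_rate Per-stem-position probability of a bulge or mismatch.
#' @param signal_strength Probability that the start signature is enforced.
#' @param seed Integer seed; hairpin `i` depends only on `(seed, i)`.
#' @return Named list of annotated [hairpin()] objects.
#' @examples
#' hp <- simulate_hairpins(3, seed = 1)
#' hp[[1]]
#' @export
simulate_hairpins <- function(n_hairpins, flank5_len = 12L, flank3_len = 12L,
                              stem_len = 28L, loop_len = 8L,
                              mature_len = 22L, bulge_rate = 0.05,
                              signal_strength = 0.9, seed = 1L) {
  stopifnot(n_hairpins >= 1L, stem_len >= mature_len - 3L,
            bulge_rate >= 0, bulge_rate <= 1,
            signal_strength >= 0, signal_strength <= 1)
  out <- lapply(seq_len(n_hairpins), .make_hairpin,
                flank5_len = flank5_len, flank3_len = flank3_len,
                stem_len = stem_len, loop_len = loop_len,
                mature_len = mature_len, bulge_rate = bulge_rate,
                signal_strength = signal_strength, seed = seed)
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write hairpins to the pipeline's three input files
#'
#' Emits a FASTA file, a Vienna-style dot-bracket file and the 3-column
#' mature-annotation TSV, all consumable by [hairpins_from_files()].
#'
#' @param hairpins List of annotated [hairpin()] objects.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default `"hairpins"`).
#' @return Named character vector of the three paths.
#' @export
write_hairpin_files <- function(hairpins, dir, prefix = "hairpins") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fa"))
  vienna <- file.path(dir, paste0(prefix, ".vienna"))
  tsv <- file.path(dir, paste0(prefix, "_mature.tsv"))
  fa <- unlist(lapply(hairpins, function(h) c(paste0(">", h$id), h$sequence)))
  writeLines(fa, fasta)
  vn <- unlist(lapply(hairpins, function(h)
    c(paste0(">", h$id), h$sequence, h$structure)))
  writeLines(vn, vienna)
  ann <- do.call(rbind, lapply(hairpins, function(h) {
    if (is.null(h$mature_start)) return(NULL)
    data.frame(id = h$id, mature_start = h$mature_start,
               mature_len = h$mature_len)
  }))
  utils::write.table(ann, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  c(fasta = fasta, structures = vienna, mature = tsv)
}

#' Simulate a train/test dataset of synthetic hairpins
#'
#' Generates hairpins with [simulate_hairpins()], shuffles them with the
#' seed and splits ~90/10 into training and test sets. With `dir` given,
#' writes the three input files per split plus a manifest recording the
#' generator configuration.
#'
#' @param n_hairpins Total number of hairpins (>= 10).
#' @param dir Optional output directory.
#' @param test_frac Test fraction (default 0.1).
#' @param seed Integer seed.
#' @param ... Generator parameters passed to [simulate_hairpins()].
#' @return List with `train` and `test` hairpin lists (and `files` when
#'   `dir` is given).
#' @export
simulate_dataset <- function(n_hairpins, dir = NULL, test_frac = 0.1,
                             seed = 1L, ...) {
  if (n_hairpins < 10L) stop("need at least 10 hairpins to split")
  hp <- simulate_hairpins(n_hairpins, seed = seed, ...)
  set.seed(as.integer(seed))
  perm <- sample(n_hairpins)
  n_test <- max(1L, round(n_hairpins * test_frac))
  test <- hp[perm[seq_len(n_test)]]
  train <- hp[perm[-seq_len(n_test)]]
  out <- list(train = train, test = test)
  if (!is.null(dir)) {
    f_train <- write_hairpin_files(train, dir, "train")
    f_test <- write_hairpin_files(test, dir, "test")
    manifest <- file.path(dir, "manifest.tsv")
    cfg <- c(list(n_hairpins = n_hairpins, test_frac = test_frac,
                  seed = seed), list(...))
    utils::write.table(
      data.frame(key = names(cfg), value = unlist(cfg)),
      manifest, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- c(train = f_train, test = f_test, manifest = manifest)
  }
  out
}
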
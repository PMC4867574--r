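# Feature codebooks. Version string is persisted with trained models so a
# model trained under one encoding refuses to score under another.
CODEBOOK_VERSION <- "mirstart-codebook-1"

.pair_codebook <- c("NN", "AA", "AC", "AG", "AU", "CA", "CC", "CG", "CU",
                    "GA", "GC", "GG", "GU", "UA", "UC", "UG", "UU",
                    "-A", "-C", "-G", "-U", "A-", "C-", "G-", "U-", "--")

.ntstate_codebook <- c("N.", "A(", "C(", "G(", "U(", "A.", "C.", "G.", "U.",
                       "-.")

#' Encode a duplex column as a paired-nucleotides type
#'
#' Maps the (top, bottom) nucleotide pair of one duplex alignment column to
#' its ordinal code 0-25, in the fixed codebook order NN, AA, AC, AG, AU,
#' CA, ..., UU, -A, -C, -G, -U, A-, C-, G-, U-, --.
#'
#' @param top,bottom Characters in `A/C/G/U/-/N`.
#' @return Integer code 0-25.
#' @export
encode_pair_type <- function(top, bottom) {
  key <- paste0(top, bottom)
  code <- match(key, .pair_codebook)
  if (anyNA(code))
    stop("no paired-nucleotides code for: ",
         paste(unique(key[is.na(code)]), collapse = ", "))
  code - 1L
}

#' Decode a paired-nucleotides type code
#' @param code Integer 0-25.
#' @return Two-character string, e.g. `"AU"`.
#' @export
decode_pair_type <- function(code) {
  stopifnot(all(code >= 0L & code <= 25L))
  .pair_codebook[code + 1L]
}

#' Encode a nucleotide together with its pairing state
#'
#' Maps (nucleotide, paired flag) to the ordinal code 0-9 in the fixed
#' order N., A(, C(, G(, U(, A., C., G., U., -. — a paired base always
#' uses its "(" class regardless of which arm it sits on.
#'
#' @param nt Character in `A/C/G/U/-/N`.
#' @param paired Logical pairing flag.
#' @return Integer code 0-9.
#' @export
encode_nt_pairstate <- function(nt, paired) {
  key <- paste0(nt, ifelse(paired, "(", "."))
  code <- match(key, .ntstate_codebook)
  if (anyNA(code))
    stop("no nucleotide/pair-state code for: ",
         paste(unique(key[is.na(code)]), collapse = ", "))
  code - 1L
}

#' Decode a nucleotide/pair-state code
#' @param code Integer 0-9.
#' @return Two-character string, e.g. `"G("`.
#' @export
decode_nt_pairstate <- function(code) {
  stopifnot(all(code >= 0L & code <= 9L))
  .ntstate_codebook[code + 1L]
}

#' Names of the 110 features, in vector order
#' @return Character vector of length 110.
#' @export
feature_names <- function() {
  c(paste0("pn", 1:25), paste0("ss", 1:50), paste0("fl", 1:18),
    paste0("fr", 1:6), paste0("MFE", 1:5), "length", paste0("Num", 1:3),
    "fn", "pair")
}

# (nt, paired) codes for hairpin position p and its partner; positions
# outside 1..L encode as ('N', unpaired) on both strands
.flank_codes <- function(bases, pt, positions) {
  L <- length(bases)
  top <- integer(length(positions)); bot <- integer(length(positions))
  for (k in seq_along(positions)) {
    p <- positions[k]
    if (p < 1L || p > L) {
      top[k] <- encode_nt_pairstate("N", FALSE)
      bot[k] <- encode_nt_pairstate("N", FALSE)
    } else if (pt[p] > 0L) {
      top[k] <- encode_nt_pairstate(bases[p], TRUE)
      bot[k] <- encode_nt_pairstate(bases[pt[p]], TRUE)
    } else {
      top[k] <- encode_nt_pairstate(bases[p], FALSE)
      bot[k] <- encode_nt_pairstate("N", FALSE)
    }
  }
  c(top, bot)
}

#' Extract the 110-dimensional feature vector of a candidate window
#'
#' Encodes one candidate mature start as the fixed feature vector:
#' \describe{
#'   \item{pn1-25}{paired-nucleotides type (0-25) of each duplex column}
#'   \item{ss1-50}{nucleotide/pair-state codes (0-9) of the 25 top-strand
#'     then 25 bottom-strand duplex positions}
#'   \item{fl1-18}{codes of the 9 hairpin positions immediately 5' of the
#'     window and their partners (lower-stem flank)}
#'   \item{fr1-6}{codes of the 3 positions immediately 3' of the window and
#'     their partners}
#'   \item{MFE1-5}{stacking energies of the whole duplex and of its left
#'     3/5/9-column and right 3-column sub-regions (kcal/mol)}
#'   \item{length}{distance from the window start to the terminal loop}
#'   \item{Num1-3}{gap (`-`) counts over duplex columns 2-5, 3-8 and 9-12,
#'     both strands}
#'   \item{fn}{first window nucleotide, A=0, C=1, G=2, U=3}
#'   \item{pair}{0 if the first duplex column is paired, else 1}
#' }
#'
#' @param h A [hairpin()] object.
#' @param start 1-based window start.
#' @param window_len Window length in nt.
#' @param table Stack-energy table from [load_stack_table()].
#' @return Named numeric vector of length 110.
#' @export
extract_features <- function(h, start, window_len = 22L,
                             table = load_stack_table()) {
  d <- build_duplex(h, start, window_len)
  pt <- pair_table(h$structure)
  bases <- strsplit(h$sequence, "")[[1]]
  start <- as.integer(start)

  pn <- encode_pair_type(d$top, d$bottom)
  # pad columns are ('N','N') and unpaired; 'N' paired never occurs
  ss <- c(encode_nt_pairstate(d$top, d$paired),
          encode_nt_pairstate(d$bottom, d$paired))
  fl <- .flank_codes(bases, pt, seq(start - 9L, start - 1L))
  fr <- .flank_codes(bases, pt, seq(start + window_len,
                                    start + window_len + 2L))

  npad <- sum(d$top == "N")
  ncols <- 25L - npad
  right3 <- if (ncols >= 3L) c(ncols - 2L, ncols) else c(1L, max(ncols, 1L))
  mfe <- c(region_energy(d, c(1L, 25L), table),
           region_energy(d, c(1L, 3L), table),
           region_energy(d, c(1L, 5L), table),
           region_energy(d, c(1L, 9L), table),
           region_energy(d, right3, table))

  loop_start <- terminal_loop_start(pt)
  len_feat <- loop_start - start

  gap_count <- function(a, b)
    sum(d$top[a:b] == "-") + sum(d$bottom[a:b] == "-")
  num <- c(gap_count(2L, 5L), gap_count(3L, 8L), gap_count(9L, 12L))

  fn <- match(bases[start], c("A", "C", "G", "U")) - 1L
  pair_feat <- if (d$paired[1L]) 0L else 1L

  stats::setNames(
    as.numeric(c(pn, ss, fl, fr, mfe, len_feat, num, fn, pair_feat)),
    feature_names())
}

#' Feature matrix for a set of candidate windows
#'
#' @param hairpins Named list of [hairpin()] objects.
#' @param windows Data frame with `hairpin_id`, `start`, `window_len`
#'   columns (from [generate_windows()], possibly row-bound and labeled).
#' @param table Stack-energy table.
#' @return Numeric matrix, one row per window, 110 named columns; row names
#'   are `"<hairpin_id>:<start>"` sample keys.
#' @export
feature_matrix <- function(hairpins, windows, table = load_stack_table()) {
  stopifnot(is.data.frame(windows))
  n <- nrow(windows)
  m <- matrix(NA_real_, nrow = n, ncol = 110L,
              dimnames = list(paste0(windows$hairpin_id, ":", windows$start),
                              feature_names()))
  pts <- lapply(hairpins, function(h) pair_table(h$structure))
  for (i in seq_len(n)) {
    h <- hairpins[[windows$hairpin_id[i]]]
    if (is.null(h)) stop("unknown hairpin id: ", windows$hairpin_id[i])
    m[i, ] <- extract_features(h, windows$start[i], windows$window_len[i],
                               table)
  }
  m
}

#' Fit min-max normalization parameters
#'
#' Records the per-feature minimum and maximum of a training feature
#' matrix, for affine mapping onto `[-1, 1]`.
#'
#' @param m Numeric matrix with 110 columns.
#' @return Object of class `"mirstart_norm"`: list with numeric vectors
#'   `min` and `max`.
#' @export
fit_normalization <- function(m) {
  if (ncol(m) != 110L) stop("feature matrix must have 110 columns, has ",
                            ncol(m))
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max)),
            class = "mirstart_norm")
}

#' Apply min-max normalization
#'
#' Maps each feature affinely to `[-1, 1]` using training min/max.
#' Constant training features map to 0; out-of-range test values are
#' clipped to `[-1, 1]`.
#'
#' @param m Numeric matrix with 110 columns.
#' @param params From [fit_normalization()].
#' @return Normalized matrix of the same shape.
#' @export
apply_normalization <- function(m, params) {
  stopifnot(inherits(params, "mirstart_norm"))
  if (ncol(m) != 110L) stop("feature matrix must have 110 columns, has ",
                            ncol(m))
  lo <- params$min; hi <- params$max
  rng <- hi - lo
  out <- m
  for (j in seq_len(ncol(m))) {
    if (rng[j] == 0) out[, j] <- 0
    else out[, j] <- pmin(1, pmax(-1, 2 * (m[, j] - lo[j]) / rng[j] - 1))
  }
  out
}
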
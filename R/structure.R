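#' Pair table from a dot-bracket structure
#'
#' Converts a pseudoknot-free dot-bracket string into a partner vector:
#' `pt[i] == j` if positions i and j are base-paired, `0` if i is unpaired.
#'
#' @param structure Dot-bracket string over `(`, `)`, `.`.
#' @return Integer vector of length `nchar(structure)`.
#' @examples
#' pair_table("((..))")  # 6 5 0 0 2 1
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  L <- length(chars)
  pt <- integer(L)
  stack <- integer(0)
  for (i in seq_len(L)) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, i)
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stop("unbalanced structure: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch != ".") {
      stop("invalid structure character '", ch, "' at position ", i)
    }
  }
  if (length(stack) > 0L)
    stop("unbalanced structure: unmatched '(' at position ", stack[1])
  pt
}

#' Render a pair table back to dot-bracket
#'
#' Inverse of [pair_table()] for pseudoknot-free structures.
#'
#' @param pt Integer partner vector.
#' @return Dot-bracket string.
#' @export
render_dot_bracket <- function(pt) {
  chars <- rep(".", length(pt))
  paired <- which(pt > 0L)
  chars[paired[pt[paired] > paired]] <- "("
  chars[paired[pt[paired] < paired]] <- ")"
  paste(chars, collapse = "")
}

#' First position of the terminal loop
#'
#' The terminal loop begins one position after the innermost paired base on
#' the 5' arm, i.e. `1 + max{ i : pt[i] > i }`.
#'
#' @param pt Pair table from [pair_table()].
#' @return 1-based position of the first loop base.
#' @examples
#' terminal_loop_start(pair_table("(((...)))"))  # 4
#' @export
terminal_loop_start <- function(pt) {
  open5 <- which(pt > seq_along(pt))
  if (length(open5) == 0L) stop("no stem: structure has no base pairs")
  max(open5) + 1L
}

#' Build the gapped miRNA:miRNA* duplex alignment for a candidate window
#'
#' The top strand is the candidate window read 5'->3'; the bottom strand is
#' the pairing partner region read along decreasing partner coordinates
#' (3'->5'). Between consecutive paired anchors the larger of the two
#' unpaired runs determines the number of inserted columns; the shorter run
#' is left-justified and padded with `-`. Window positions past the last
#' anchor (e.g. inside the terminal loop) get `-` on the bottom. The
#' alignment is truncated or right-padded with `("N","N")` columns to
#' exactly 25 columns.
#'
#' @param h A [hairpin()] object.
#' @param start 1-based window start.
#' @param window_len Window length in nt (default 22).
#' @return An object of class `"duplex"`: a list with character vectors
#'   `top`, `bottom` (length 25, alphabet `A/C/G/U/-/N`) and logical
#'   `paired`.
#' @export
build_duplex <- function(h, start, window_len = 22L) {
  stopifnot(inherits(h, "hairpin"))
  L <- nchar(h$sequence)
  start <- as.integer(start); window_len <- as.integer(window_len)
  if (start < 1L || start + window_len - 1L > L)
    stop("window [", start, ", ", start + window_len - 1L,
         "] outside hairpin of length ", L)
  pt <- pair_table(h$structure)
  bases <- strsplit(h$sequence, "")[[1]]
  win <- seq(start, length.out = window_len)

  # anchors: window positions paired to somewhere 3' of the window end;
  # absent pseudoknots their partners strictly decrease with position
  anchors <- win[pt[win] > (start + window_len - 1L)]

  top <- character(0); bottom <- character(0); paired <- logical(0)
  emit <- function(t, b, p) {
    top <<- c(top, t); bottom <<- c(bottom, b); paired <<- c(paired, p)
  }
  if (length(anchors) == 0L) {
    for (i in win) emit(bases[i], "-", FALSE)
  } else {
    # leading window positions before the first anchor: no partner region
    i1 <- anchors[1]
    if (i1 > start) for (i in seq(start, i1 - 1L)) emit(bases[i], "-", FALSE)
    emit(bases[i1], bases[pt[i1]], TRUE)
    if (length(anchors) > 1L) {
      for (a in seq(2L, length(anchors))) {
        ia <- anchors[a - 1L]; ib <- anchors[a]
        ja <- pt[ia]; jb <- pt[ib]
        g_top <- ib - ia - 1L
        g_bot <- ja - jb - 1L
        g <- max(g_top, g_bot)
        if (g > 0L) {
          tops <- if (g_top > 0L) bases[seq(ia + 1L, ib - 1L)] else character(0)
          bots <- if (g_bot > 0L) bases[seq(ja - 1L, jb + 1L)] else character(0)
          tops <- c(tops, rep("-", g - length(tops)))
          bots <- c(bots, rep("-", g - length(bots)))
          for (k in seq_len(g)) emit(tops[k], bots[k], FALSE)
        }
        emit(bases[ib], bases[jb], TRUE)
      }
    }
    last <- anchors[length(anchors)]
    if (last < start + window_len - 1L)
      for (i in seq(last + 1L, start + window_len - 1L))
        emit(bases[i], "-", FALSE)
  }

  n <- length(top)
  if (n > 25L) {
    top <- top[1:25]; bottom <- bottom[1:25]; paired <- paired[1:25]
  } else if (n < 25L) {
    pad <- 25L - n
    top <- c(top, rep("N", pad)); bottom <- c(bottom, rep("N", pad))
    paired <- c(paired, rep(FALSE, pad))
  }
  structure(list(top = top, bottom = bottom, paired = paired),
            class = "duplex")
}

#' @export
print.duplex <- function(x, ...) {
  cat("5' ", paste(x$top, collapse = ""), " 3'\n", sep = "")
  cat("   ", paste(ifelse(x$paired, "|", " "), collapse = ""), "\n", sep = "")
  cat("3' ", paste(x$bottom, collapse = ""), " 5'\n", sep = "")
  invisible(x)
}

# package-level cache for the stacking table
.stack_env <- new.env(parent = emptyenv())

#' Load the nearest-neighbor stacking-energy table
#'
#' Reads the packaged plain-text table of helix stacking free energies
#' (kcal/mol at 37 C). Keys are two adjacent base pairs written
#' `XY/ZW`: pair X-Z followed 3'-ward on the top strand by pair Y-W.
#' Watson-Crick values follow the standard nearest-neighbor parameter set;
#' wobble-pair entries are mildly negative simplifications (see the package
#' vignette).
#'
#' @param path Optional path to an alternative table (two tab-separated
#'   columns: key, energy).
#' @return Named numeric vector of stack energies.
#' @export
load_stack_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.stack_env$table)) return(.stack_env$table)
    path <- system.file("extdata", "stack_energies.tsv", package = "mirstart")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  energies <- stats::setNames(as.numeric(tab$energy), tab$stack)
  if (any(!is.finite(energies)) || any(energies >= 0))
    stop("stack table must contain finite negative energies")
  if (cache) .stack_env$table <- energies
  energies
}

#' Stacking free energy of a duplex sub-region
#'
#' Sums nearest-neighbor stack energies over consecutive paired columns
#' inside an inclusive column range of a [build_duplex()] alignment.
#' Regions with fewer than two paired columns score 0. Only immediately
#' adjacent paired columns stack; columns separated by an internal loop or
#' bulge contribute no stacking term.
#'
#' @param d A `duplex` object.
#' @param cols Inclusive column range, within 1..25.
#' @param table Stack-energy table from [load_stack_table()].
#' @return Free energy in kcal/mol (<= 0).
#' @export
region_energy <- function(d, cols, table = load_stack_table()) {
  stopifnot(inherits(d, "duplex"))
  cols <- as.integer(cols)
  if (min(cols) < 1L || max(cols) > 25L) stop("column range outside 1..25")
  cols <- seq(min(cols), max(cols))
  e <- 0
  for (i in cols[-length(cols)]) {
    if (d$paired[i] && d$paired[i + 1L]) {
      key <- paste0(d$top[i], d$top[i + 1L], "/", d$bottom[i], d$bottom[i + 1L])
      val <- table[[key]]
      if (is.null(val)) next  # non-canonical pair annotated as paired
      e <- e + val
    }
  }
  e
}
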
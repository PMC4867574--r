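#' Construct a pre-miRNA hairpin record
#'
#' A hairpin bundles an RNA sequence with its secondary structure in
#' dot-bracket notation and, optionally, the annotated 1-based start of the
#' 5' mature miRNA. Sequences are uppercased and DNA-style `T` is mapped to
#' `U`; any other letter outside `A/C/G/U` is rejected. The structure must
#' have the same length as the sequence and balanced brackets.
#'
#' @param id Character identifier.
#' @param sequence RNA (or DNA) string, 40-200 nt.
#' @param structure Dot-bracket string over `(`, `)`, `.` of equal length.
#' @param mature_start Optional 1-based position of the annotated 5' mature
#'   start. Must lie in `[1, L - mature_len + 1]`.
#' @param mature_len Mature miRNA length in nt (default 22).
#' @return An object of class `"hairpin"`: a list with elements `id`,
#'   `sequence`, `structure`, `mature_start`, `mature_len`.
#' @examples
#' hp <- hairpin("h1", strrep("ACGU", 15),
#'               paste0(strrep("(", 25), strrep(".", 10), strrep(")", 25)))
#' hp
#' @export
hairpin <- function(id, sequence, structure, mature_start = NULL,
                    mature_len = 22L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  if (L < 40L || L > 200L)
    stop("hairpin '", id, "': sequence length ", L, " outside 40-200 nt")
  if (!is.character(structure) || length(structure) != 1L)
    stop("hairpin '", id, "': structure must be a single string")
  if (nchar(structure) != L)
    stop("hairpin '", id, "': structure length ", nchar(structure),
         " != sequence length ", L)
  if (grepl("[^().]", structure))
    stop("hairpin '", id, "': structure contains characters outside (, ), .")
  pair_table(structure)  # errors on unbalanced brackets
  if (!is.null(mature_start)) {
    mature_start <- as.integer(mature_start)
    mature_len <- as.integer(mature_len)
    if (mature_len < 1L) stop("hairpin '", id, "': mature_len must be >= 1")
    if (mature_start < 1L || mature_start > L - mature_len + 1L)
      stop("hairpin '", id, "': mature_start ", mature_start,
           " outside [1, ", L - mature_len + 1L, "]")
  }
  structure(list(id = id, sequence = sequence, structure = structure,
                 mature_start = mature_start,
                 mature_len = as.integer(mature_len)),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat("<hairpin ", x$id, ">  ", nchar(x$sequence), " nt",
      if (!is.null(x$mature_start))
        paste0(", mature start ", x$mature_start, " (len ", x$mature_len, ")"),
      "\n", sep = "")
  cat(" ", x$sequence, "\n ", x$structure, "\n", sep = "")
  invisible(x)
}

# Uppercase, T->U, validate alphabet.
normalize_rna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s))
    stop("sequence contains letters outside A/C/G/U/T: ",
         paste(unique(strsplit(gsub("[ACGU]", "", s), "")[[1]]), collapse = ", "))
  s
}

#' Read hairpin sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file of pre-miRNA sequences, preserving record
#' order. Sequences are uppercased and `T` mapped to `U`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences (names = record ids,
#'   first whitespace-delimited token of each header).
#' @export
read_hairpin_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  vapply(seqs, normalize_rna, "", USE.NAMES = TRUE)
}

#' Read dot-bracket structures from a Vienna-style file
#'
#' Parses the block format emitted by RNAfold: a `>id` header line, the
#' sequence line, then the structure line with an optional trailing
#' free-energy token such as `( -23.40)`, which is stripped.
#'
#' @param path Path to an RNAfold-style output file.
#' @return Named character vector of dot-bracket strings.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in structure file: ", path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L)
    stop("structure file '", path, "' has no '>' headers")
  out <- character(0)
  bounds <- c(hdr, length(lines) + 1L)
  for (b in seq_along(hdr)) {
    id <- sub("^>\\s*", "", lines[hdr[b]])
    id <- strsplit(id, "[ \t]")[[1]][1]
    body <- lines[seq(hdr[b] + 1L, length.out = bounds[b + 1L] - hdr[b] - 1L)]
    if (length(body) < 2L)
      stop("structure block for '", id, "' is missing a structure line")
    seq_line <- gsub("\\s", "", body[1])
    struct_line <- body[2]
    # strip trailing energy "( -x.y)" or "(-x.y)"
    struct <- sub("\\s*\\(\\s*-?[0-9]+(\\.[0-9]+)?\\s*\\)\\s*$", "",
                  struct_line)
    struct <- gsub("\\s", "", struct)
    if (grepl("[^().]", struct))
      stop("structure for '", id, "' contains characters outside (, ), .")
    if (nchar(struct) != nchar(seq_line))
      stop("structure length ", nchar(struct), " != sequence length ",
           nchar(seq_line), " for '", id, "'")
    pair_table(struct)  # unbalanced -> error
    out[id] <- struct
  }
  out
}

#' Read mature-start annotations from a 3-column TSV
#'
#' Columns: hairpin id, 1-based 5' mature start, mature length. A header
#' row is detected (non-numeric second column) and skipped.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id`, `mature_start`, `mature_len`,
#'   one row per hairpin.
#' @export
read_mature_tsv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L)
    stop("annotation file '", path, "' must have 3 tab-separated columns")
  if (nrow(tab) > 0L && is.na(suppressWarnings(as.integer(tab[1, 2]))))
    tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no records in annotation file: ", path)
  ids <- tab[[1]]
  starts <- suppressWarnings(as.integer(tab[[2]]))
  lens <- suppressWarnings(as.integer(tab[[3]]))
  if (anyNA(starts) || anyNA(lens))
    stop("non-integer start/length in annotation file: ", path)
  if (any(starts < 1L))
    stop("mature start < 1 for id(s): ",
         paste(ids[starts < 1L], collapse = ", "))
  if (any(lens < 1L))
    stop("mature length < 1 for id(s): ", paste(ids[lens < 1L], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate id(s) in annotation file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, mature_start = starts, mature_len = lens,
             stringsAsFactors = FALSE)
}

#' Assemble hairpin objects from the three input files
#'
#' Joins a FASTA file, a structure file and (optionally) a mature-start
#' annotation TSV into a list of [hairpin()] objects. Hairpins without a
#' structure are an error; with `annotations` given, hairpins missing an
#' annotation are kept unannotated with a warning.
#'
#' @param fasta,structures Paths to the FASTA and dot-bracket files.
#' @param mature Optional path to the annotation TSV.
#' @return List of `hairpin` objects, FASTA order.
#' @export
hairpins_from_files <- function(fasta, structures, mature = NULL) {
  seqs <- read_hairpin_fasta(fasta)
  structs <- read_structures(structures)
  ann <- if (!is.null(mature)) read_mature_tsv(mature) else NULL
  missing_struct <- setdiff(names(seqs), names(structs))
  if (length(missing_struct))
    stop("no structure for hairpin id(s): ",
         paste(missing_struct, collapse = ", "))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    ms <- NULL; ml <- 22L
    if (!is.null(ann)) {
      j <- match(id, ann$id)
      if (is.na(j)) {
        warning("no mature annotation for hairpin '", id,
                "'; kept unannotated")
      } else {
        ms <- ann$mature_start[j]; ml <- ann$mature_len[j]
      }
    }
    out[[i]] <- hairpin(id, seqs[[i]], structs[[id]],
                        mature_start = ms, mature_len = ml)
  }
  names(out) <- names(seqs)
  out
}

#' Optionally fold sequences with an external command
#'
#' Pipes a FASTA file through an external secondary-structure folder (for
#' example `RNAfold --noPS`) and parses its Vienna-style output. Used when
#' no precomputed structure file is available.
#'
#' @param fasta Path to a FASTA file.
#' @param fold_cmd Command line that reads FASTA on stdin and writes
#'   RNAfold-style blocks on stdout.
#' @return Named character vector of dot-bracket strings.
#' @export
fold_with_command <- function(fasta, fold_cmd) {
  out <- system(paste(fold_cmd, "<", shQuote(fasta)), intern = TRUE)
  tmp <- tempfile(fileext = ".vienna")
  on.exit(unlink(tmp))
  writeLines(out, tmp)
  read_structures(tmp)
}
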
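#' Construct a protein multiple sequence alignment object
#'
#' An `Alignment` is an ordered set of equal-length gapped amino-acid
#' sequences with unique identifiers. It is the object the conservation
#' classifier consumes. Residues are restricted to the 20 amino-acid
#' letters, the ambiguity letter `X`, and the gap character `-`; lowercase
#' input is uppercased.
#'
#' @param ids character vector of unique, non-empty sequence identifiers.
#' @param seqs character vector of gapped residue strings, same length as
#'   `ids`.
#' @return An object of class `Alignment` with elements `ids`, `seqs`
#'   (named by `ids`) and `length` (number of columns).
#' @examples
#' aln <- alignment(c("a", "b"), c("MK-V", "MKAV"))
#' aln$length
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have the same length")
  }
  if (length(ids) > 0) {
    if (anyNA(ids) || any(!nzchar(ids))) stop("sequence ids must be non-empty")
    if (anyDuplicated(ids)) {
      stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
    }
    widths <- nchar(seqs)
    if (length(unique(widths)) > 1L) {
      ref <- widths[1L]
      bad <- ids[widths != ref][1L]
      stop("ragged alignment: sequence '", bad, "' has ",
           widths[ids == bad][1L], " columns, expected ", ref)
    }
    ok <- grepl(sprintf("^[%s]*$", paste0(AA_ALPHABET_CHARS, collapse = "")),
                seqs)
    if (!all(ok)) {
      stop("sequence '", ids[!ok][1L],
           "' contains letters outside the amino-acid alphabet")
    }
  }
  names(seqs) <- ids
  structure(
    list(ids = ids, seqs = seqs,
         length = if (length(seqs)) nchar(seqs[[1L]]) else 0L),
    class = "Alignment"
  )
}

# amino acids + ambiguity X + gap; X participates in occupancy but no group
AA_ALPHABET_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], "-")

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequence(s) x %d column(s)\n",
              length(x$ids), x$length))
  show <- utils::head(x$ids, 6L)
  for (id in show) {
    s <- x$seqs[[id]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", id, s))
  }
  if (length(x$ids) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read a CLUSTAL ALN multiple sequence alignment
#'
#' Parses the interleaved CLUSTAL format (the default ClustalW output): a
#' `CLUSTAL` header line, then sequence blocks separated by blank lines.
#' Conservation-mark lines (`*`, `:`, `.`) are ignored, per-block segments
#' are concatenated per identifier in first-seen order, and a trailing
#' all-digit token on a sequence line (cumulative residue coordinates
#' emitted by some CLUSTAL builds) is dropped.
#'
#' @param input path to a file, or a character vector of lines.
#' @return An [alignment()] object.
#' @examples
#' txt <- c("CLUSTAL W (1.83) multiple sequence alignment", "",
#'          "s1   MKV-", "s2   MKVA")
#' read_clustal(txt)
#' @export
read_clustal <- function(input) {
  lines <- read_input_lines(input)
  if (length(lines) == 0 || !grepl("^(CLUSTAL|MUSCLE|PROBCONS)", lines[[1]])) {
    stop("not a CLUSTAL file: missing CLUSTAL header line")
  }
  body <- lines[-1L]
  ids <- character(0)
  segs <- list()
  block_seen <- character(0)
  for (ln in body) {
    if (!nzchar(trimws(ln))) {
      block_seen <- character(0)
      next
    }
    # conservation-mark line: only spaces and * : .
    if (grepl("^[ \t.:*]+$", ln)) next
    toks <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(toks) < 2L) {
      stop("malformed CLUSTAL sequence line: '", ln, "'")
    }
    id <- toks[[1]]
    rest <- toks[-1L]
    # drop trailing cumulative coordinate, if present
    if (length(rest) > 1L && grepl("^[0-9]+$", rest[[length(rest)]])) {
      rest <- rest[-length(rest)]
    }
    seg <- paste0(rest, collapse = "")
    if (id %in% block_seen) {
      stop("duplicate id within a CLUSTAL block: '", id, "'")
    }
    block_seen <- c(block_seen, id)
    if (!id %in% ids) {
      ids <- c(ids, id)
      segs[[id]] <- character(0)
    }
    segs[[id]] <- c(segs[[id]], seg)
  }
  if (length(ids) == 0) stop("CLUSTAL file contains no sequences")
  alignment(ids, vapply(segs[ids], paste0, "", collapse = ""))
}

#' Read an aligned FASTA file as an Alignment
#'
#' All records must have identical gapped length; record order is
#' preserved.
#'
#' @param input path to a file, or a character vector of lines.
#' @return An [alignment()] object.
#' @export
read_fasta_alignment <- function(input) {
  lines <- read_input_lines(input)
  txt <- paste0(lines, collapse = "\n")
  if (!nzchar(trimws(txt))) stop("empty FASTA input")
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  aas <- Biostrings::readAAStringSet(tmp, format = "fasta")
  if (length(aas) == 0) stop("empty FASTA input")
  ids <- sub("[ \t].*$", "", names(aas))
  alignment(ids, as.character(aas))
}

read_input_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  # split embedded newlines while preserving blank lines (block separators)
  unlist(lapply(as.character(input), function(x) {
    if (!grepl("\n", x, fixed = TRUE)) x
    else strsplit(paste0(x, "\n"), "\n", fixed = TRUE)[[1]]
  }), use.names = FALSE)
}

#' Write an Alignment in CLUSTAL format
#'
#' @param aln an [alignment()] object.
#' @param path optional output file; when `NULL` the lines are returned.
#' @param width residues per block line.
#' @return Invisibly (or visibly when `path` is `NULL`), the character
#'   vector of output lines.
#' @export
write_clustal <- function(aln, path = NULL, width = 60L) {
  stopifnot(inherits(aln, "Alignment"))
  out <- c("CLUSTAL W multiple sequence alignment", "")
  if (aln$length > 0 && length(aln$ids) > 0) {
    idw <- max(nchar(aln$ids)) + 3L
    starts <- seq(1L, aln$length, by = width)
    for (s in starts) {
      e <- min(s + width - 1L, aln$length)
      for (id in aln$ids) {
        out <- c(out, sprintf("%-*s%s", idw, id, substr(aln$seqs[[id]], s, e)))
      }
      out <- c(out, "")
    }
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Write an Alignment as aligned FASTA
#'
#' @inheritParams write_clustal
#' @return Invisibly (or visibly when `path` is `NULL`), the output lines.
#' @export
write_fasta_alignment <- function(aln, path = NULL) {
  stopifnot(inherits(aln, "Alignment"))
  out <- as.vector(rbind(paste0(">", aln$ids), unname(aln$seqs)))
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Write per-column conservation annotations as TSV
#'
#' One row per alignment column: 1-based index, category, driving
#' percentage, color band, majority residue and majority group. Output is
#' bit-stable for a fixed input.
#'
#' @param annotations a list of column annotations from
#'   [colorfy_alignment()].
#' @param path optional output file; when `NULL` lines are returned.
#' @return The TSV lines (invisibly when written to `path`).
#' @export
write_annotation_tsv <- function(annotations, path = NULL) {
  header <- paste(c("column", "category", "percent", "band",
                    "majority_residue", "majority_group"), collapse = "\t")
  rows <- vapply(annotations, function(a) {
    paste(c(a$column_index, a$category,
            sprintf("%.10g", a$driving_percent),
            a$band %||% "none",
            a$majority_residue %||% "none",
            a$majority_group %||% "none"), collapse = "\t")
  }, "")
  out <- c(header, rows)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Read back a column-annotation TSV
#'
#' Inverse of [write_annotation_tsv()] for the tabular fields (shade
#' vectors are not serialized to TSV).
#'
#' @param input path or character lines.
#' @return A data.frame with one row per column.
#' @export
read_annotation_tsv <- function(input) {
  lines <- read_input_lines(input)
  df <- utils::read.delim(text = paste0(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "numeric",
                                         "character", "character", "character"))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
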
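#' Describe a CDS variant
#'
#' Variants use HGVS-like `c.` numbering: 1-based positions on the coding
#' sequence only (no 5' UTR). Supported kinds are single-nucleotide
#' `substitution`, `deletion` of one or more bases (`alt` empty), and
#' `multi_substitution` (a length-preserving multi-base replacement, e.g.
#' the TCC→ATT triple substitution).
#'
#' @param kind `"substitution"`, `"deletion"` or `"multi_substitution"`.
#' @param cds_position 1-based coding-nucleotide index of the first edited
#'   base.
#' @param ref reference base(s) at that position.
#' @param alt replacement base(s); empty string for a deletion.
#' @return An object of class `GeneVariant`.
#' @examples
#' gene_variant("substitution", 1376, "C", "T")
#' @export
gene_variant <- function(kind = c("substitution", "deletion",
                                  "multi_substitution"),
                         cds_position, ref, alt = "") {
  kind <- match.arg(kind)
  cds_position <- as.integer(cds_position)
  ref <- toupper(ref); alt <- toupper(alt)
  if (is.na(cds_position) || cds_position < 1L) {
    stop("cds_position must be a positive integer")
  }
  if (!grepl("^[ACGT]+$", ref)) stop("ref must be a DNA string")
  if (kind == "deletion") {
    if (nzchar(alt)) stop("deletion must have empty alt")
  } else if (!grepl("^[ACGT]+$", alt)) {
    stop("alt must be a DNA string")
  }
  if (kind == "substitution" && (nchar(ref) != 1L || nchar(alt) != 1L)) {
    stop("substitution edits exactly one base")
  }
  if (kind == "multi_substitution" &&
      (nchar(ref) != nchar(alt) || nchar(ref) < 2L)) {
    stop("multi_substitution requires |ref| == |alt| > 1")
  }
  structure(list(kind = kind, cds_position = cds_position,
                 ref = ref, alt = alt),
            class = "GeneVariant")
}

#' Codon number of a coding-nucleotide position
#'
#' Positions 3k-2..3k map to codon k, so c.1376 falls in codon 459 and
#' c.559 in codon 187 — the arithmetic behind naming a missense change by
#' its residue number.
#'
#' @param cds_position 1-based coding-nucleotide position(s).
#' @return Integer codon number(s), `ceiling(position / 3)`.
#' @examples
#' codon_index(1376)  # 459
#' codon_index(559)   # 187
#' @export
codon_index <- function(cds_position) {
  cds_position <- as.integer(cds_position)
  if (any(is.na(cds_position)) || any(cds_position < 1L)) {
    stop("cds_position must be >= 1")
  }
  as.integer(ceiling(cds_position / 3))
}

#' Apply a variant to a coding sequence
#'
#' The reference allele is checked against the sequence; a mismatch is an
#' error that reports the expected and found bases.
#'
#' @param cds DNA string (coding sequence).
#' @param variant a [gene_variant()].
#' @return The edited DNA string.
#' @examples
#' apply_variant("ATGTCCTAA", gene_variant("multi_substitution", 4, "TCC", "ATT"))
#' @export
apply_variant <- function(cds, variant) {
  stopifnot(inherits(variant, "GeneVariant"))
  cds <- toupper(cds)
  p <- variant$cds_position
  w <- nchar(variant$ref)
  if (p + w - 1L > nchar(cds)) {
    stop("variant at position ", p, " (width ", w,
         ") runs past the end of the CDS (length ", nchar(cds), ")")
  }
  found <- substr(cds, p, p + w - 1L)
  if (found != variant$ref) {
    stop("reference mismatch at position ", p, ": expected '",
         variant$ref, "', found '", found, "'")
  }
  before <- substr(cds, 1L, p - 1L)
  after <- substr(cds, p + w, nchar(cds))
  paste0(before, if (variant$kind == "deletion") "" else variant$alt, after)
}

#' Translate a codon with the standard genetic code
#'
#' @param codon 3-letter DNA string.
#' @return One amino-acid letter (`"*"` for a stop codon).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("not a DNA codon: '", codon, "'")
  unname(Biostrings::GENETIC_CODE[[codon]])
}

translate_cds <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return(character(0))
  starts <- 3L * seq_len(n) - 2L
  vapply(starts, function(s) translate_codon(substr(dna, s, s + 2L)), "")
}

#' Protein consequences of CDS variants
#'
#' Translates the wild-type and mutant coding sequences with the standard
#' genetic code. Length-preserving edits give one consequence per changed
#' codon (`synonymous`, `missense` or `nonsense`); a deletion whose length
#' is not a multiple of 3 gives a `frameshift` consequence at the first
#' affected codon, with a scan for the first downstream in-frame stop in
#' the mutant sequence (a frameshifted CDS lacking any in-frame stop is
#' flagged `no_stop_found`). The scan runs to the end of the provided CDS
#' only.
#'
#' @param cds wild-type coding DNA, starting with ATG.
#' @param variants a [gene_variant()] or a list of non-overlapping ones.
#' @return A list of `Consequence` objects, each with `kind`,
#'   `residue_index`, `wt_aa`, `mut_aa`, `stop_codon_index` (codon number
#'   in the mutant, or `NA`) and `no_stop_found`.
#' @examples
#' call_consequence("ATGTCCTAA", gene_variant("substitution", 5, "C", "T"))
#' @export
call_consequence <- function(cds, variants) {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds)) stop("CDS contains non-DNA letters")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must start with ATG")
  if (inherits(variants, "GeneVariant")) variants <- list(variants)
  stopifnot(all(vapply(variants, inherits, TRUE, "GeneVariant")))
  if (length(variants) == 0L) return(list())

  # overlap check
  iv <- t(vapply(variants, function(v) {
    c(v$cds_position, v$cds_position + nchar(v$ref) - 1L)
  }, integer(2)))
  ord <- order(iv[, 1L])
  iv <- iv[ord, , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
    stop("variants overlap")
  }

  shifts <- vapply(variants, function(v) {
    if (v$kind == "deletion") nchar(v$ref) else 0L
  }, integer(1))
  fs <- which(shifts %% 3L != 0L)
  if (length(fs) > 1L) stop("at most one frameshifting deletion is supported")
  if (any(shifts > 0L & shifts %% 3L == 0L)) {
    stop("in-frame deletions are not supported")
  }

  mutant <- cds
  # apply right-to-left so earlier positions stay valid
  for (v in variants[order(vapply(variants, `[[`, 1L, "cds_position"),
                           decreasing = TRUE)]) {
    mutant <- apply_variant(mutant, v)
  }

  wt_aa <- translate_cds(cds)
  mut_aa <- translate_cds(mutant)

  out <- list()
  if (length(fs) == 1L) {
    v <- variants[[fs]]
    first_codon <- codon_index(v$cds_position)
    stop_idx <- NA_integer_
    no_stop <- TRUE
    for (k in seq(first_codon, length(mut_aa))) {
      if (mut_aa[[k]] == "*") {
        stop_idx <- k; no_stop <- FALSE; break
      }
    }
    out[[length(out) + 1L]] <- consequence(
      "frameshift", first_codon, wt_aa[[first_codon]],
      if (first_codon <= length(mut_aa)) mut_aa[[first_codon]] else NA_character_,
      stop_idx, no_stop)
  }
  # per-codon calls for length-preserving edits
  subs <- variants[shifts == 0L]
  hit_codons <- sort(unique(unlist(lapply(subs, function(v) {
    codon_index(seq(v$cds_position, v$cds_position + nchar(v$ref) - 1L))
  }))))
  for (k in hit_codons) {
    wt <- wt_aa[[k]]; mu <- mut_aa[[k]]
    kind <- if (wt == mu) "synonymous"
            else if (mu == "*") "nonsense"
            else "missense"
    out[[length(out) + 1L]] <- consequence(
      kind, k, wt, mu, if (kind == "nonsense") k else NA_integer_, FALSE)
  }
  out[order(vapply(out, `[[`, 1L, "residue_index"))]
}

consequence <- function(kind, residue_index, wt_aa, mut_aa,
                        stop_codon_index, no_stop_found) {
  structure(list(kind = kind, residue_index = as.integer(residue_index),
                 wt_aa = wt_aa, mut_aa = mut_aa,
                 stop_codon_index = as.integer(stop_codon_index),
                 no_stop_found = no_stop_found),
            class = "Consequence")
}

#' @export
#' @method format Consequence
format.Consequence <- function(x, ...) {
  base <- switch(x$kind,
                 synonymous = sprintf("%s%d%s (synonymous)",
                                      x$wt_aa, x$residue_index, x$wt_aa),
                 missense = sprintf("%s%d%s", x$wt_aa, x$residue_index, x$mut_aa),
                 nonsense = sprintf("%s%d*", x$wt_aa, x$residue_index),
                 frameshift = sprintf("%s%dfs", x$wt_aa, x$residue_index))
  if (x$kind == "frameshift") {
    base <- if (x$no_stop_found) paste0(base, " (no stop found)")
            else sprintf("%s*%d", base, x$stop_codon_index)
  }
  base
}

#' @export
print.Consequence <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Enumerate single-base edits of a codon reaching a target amino acid
#'
#' Lists the 9 single-base neighbors of `codon` and keeps those that
#' translate to `target_aa` — the computation behind designing a one-base
#' reversion (e.g. ATT (Ile) → AGT (Ser) at position 2).
#'
#' @param codon 3-letter DNA codon.
#' @param target_aa target amino-acid letter, or `"*"` for stop.
#' @return A data.frame with columns `position` (1-3 within the codon),
#'   `base`, and `codon`; sorted by position then base. When the input
#'   codon already encodes `target_aa`, the result is empty and carries
#'   `attr(, "already_encodes") = TRUE`.
#' @examples
#' design_single_base_reversion("ATT", "S")
#' @export
design_single_base_reversion <- function(codon, target_aa) {
  codon <- toupper(codon); target_aa <- toupper(target_aa)
  if (!grepl("^[ACGT]{3}$", codon)) stop("not a DNA codon: '", codon, "'")
  if (!target_aa %in% c(unique(Biostrings::GENETIC_CODE), "*")) {
    stop("unknown amino acid: '", target_aa, "'")
  }
  empty <- data.frame(position = integer(0), base = character(0),
                      codon = character(0), stringsAsFactors = FALSE)
  if (translate_codon(codon) == target_aa) {
    message("codon ", codon, " already encodes ", target_aa)
    attr(empty, "already_encodes") <- TRUE
    return(empty)
  }
  bases <- c("A", "C", "G", "T")
  rows <- empty
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      cand <- codon
      substr(cand, pos, pos) <- b
      if (translate_codon(cand) == target_aa) {
        rows <- rbind(rows, data.frame(position = pos, base = b, codon = cand,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  rows[order(rows$position, rows$base), , drop = FALSE]
}

#' Bundled restriction enzymes
#'
#' Reads the small enzyme table shipped with the package (name to IUPAC
#' recognition pattern), including SfcI = CTRYAG used to genotype the
#' Ile-to-Ser reversion.
#'
#' @return Named character vector, pattern by enzyme name.
#' @export
restriction_enzymes <- function() {
  path <- system.file("extdata", "enzymes.json", package = "nadkit",
                      mustWork = TRUE)
  unlist(jsonlite::read_json(path))
}

#' Scan DNA for a degenerate restriction site
#'
#' Matches an IUPAC recognition pattern against a DNA sequence. With
#' `both_strands = TRUE`, matches on the reverse complement are reported
#' in forward coordinates, and duplicate hits from palindromic patterns
#' (such as SfcI's CTRYAG) are collapsed.
#'
#' @param seq DNA string over A/C/G/T.
#' @param enzyme either an enzyme name present in [restriction_enzymes()],
#'   or a list/vector with `name` and `pattern`.
#' @param both_strands scan the reverse strand as well (default `TRUE`).
#' @return A data.frame with columns `start` (1-based, forward
#'   coordinates) and `strand` (`"+"` or `"-"`), sorted by start.
#' @examples
#' scan_restriction_sites("TTCTACAGTA", "SfcI")
#' @export
scan_restriction_sites <- function(seq, enzyme, both_strands = TRUE) {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]*$", seq)) stop("sequence must be over A/C/G/T")
  if (is.character(enzyme) && length(enzyme) == 1L && !grepl("[^A-Za-z0-9]", enzyme) &&
      enzyme %in% names(restriction_enzymes())) {
    pattern <- restriction_enzymes()[[enzyme]]
  } else if (!is.null(enzyme$pattern)) {
    pattern <- enzyme$pattern
  } else {
    stop("unknown enzyme: provide a bundled name or a list with $pattern")
  }
  pattern <- toupper(pattern)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(strsplit(pattern, "")[[1]] %in% iupac)) {
    stop("pattern contains a letter outside the IUPAC DNA alphabet")
  }
  empty <- data.frame(start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < nchar(pattern)) return(empty)
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(pattern)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject,
                                                    fixed = FALSE))
  hits <- if (length(fwd)) {
    data.frame(start = fwd, strand = "+", stringsAsFactors = FALSE)
  } else empty
  if (both_strands) {
    rc <- Biostrings::matchPattern(pat, Biostrings::reverseComplement(subject),
                                   fixed = FALSE)
    if (length(rc)) {
      # forward-coordinate start of a reverse-strand hit
      rstart <- nchar(seq) - Biostrings::end(rc) + 1L
      rev_hits <- data.frame(start = rstart, strand = "-",
                             stringsAsFactors = FALSE)
      rev_hits <- rev_hits[!rev_hits$start %in% hits$start, , drop = FALSE]
      hits <- rbind(hits, rev_hits)
    }
  }
  hits[order(hits$start), , drop = FALSE]
}
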
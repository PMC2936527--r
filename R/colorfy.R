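#' Colorfy configuration: conservation groups, thresholds, and color bands
#'
#' The classifier partitions the twenty amino acids into eight conservation
#' groups — \{G,A\}, \{V,L,I\}, \{F,Y,W\}, \{C,M\}, \{K,R,H\}, \{D,E,N,Q\},
#' \{S,T\}, \{P\} — and scores each alignment column by percentage
#' composition over its non-gap residues. A column is *Majority Identity*
#' when at least `identity_threshold` percent of its amino acids are
#' identical; it is *Conserved Minority* when at least
#' `minority_group_threshold` percent belong to one conservation group while
#' no single amino acid exceeds `minority_identity_cap` percent; otherwise
#' it is *Insufficient Conservation*. Majority Identity takes precedence
#' when both definitions are satisfied. The driving percentage selects a
#' color band (defaults: Blue 61–70, Green 71–80, Gold 81–90, Red 91–100),
#' each band carrying a dark and a light shade.
#'
#' @param groups named list partitioning the 20 amino-acid letters.
#' @param identity_threshold minimum identity percentage for a Majority
#'   Identity call (default 61).
#' @param minority_group_threshold minimum same-group percentage for a
#'   Conserved Minority call (default 61).
#' @param minority_identity_cap maximum single-residue percentage allowed
#'   in a Conserved Minority column (default 60).
#' @param bands data.frame with columns `name`, `lower`, `upper` giving
#'   contiguous ascending percentage bands.
#' @param palette named list, per band a `c(dark =, light =)` hex pair.
#' @return An object of class `ColorfyConfig`.
#' @export
colorfy_config <- function(groups = default_conservation_groups(),
                           identity_threshold = 61,
                           minority_group_threshold = 61,
                           minority_identity_cap = 60,
                           bands = default_bands(),
                           palette = default_palette()) {
  all_aa <- sort(unlist(groups, use.names = FALSE))
  if (!identical(all_aa, sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))) {
    stop("groups must partition exactly the 20 amino-acid letters")
  }
  stopifnot(is.data.frame(bands),
            all(c("name", "lower", "upper") %in% names(bands)))
  if (is.unsorted(bands$lower, strictly = TRUE) ||
      any(bands$upper[-nrow(bands)] + 1 != bands$lower[-1L])) {
    stop("bands must be contiguous, non-overlapping, and ascending")
  }
  aa2group <- character(0)
  for (g in names(groups)) {
    aa2group[groups[[g]]] <- g
  }
  structure(
    list(groups = groups, aa2group = aa2group,
         identity_threshold = identity_threshold,
         minority_group_threshold = minority_group_threshold,
         minority_identity_cap = minority_identity_cap,
         bands = bands, palette = palette),
    class = "ColorfyConfig"
  )
}

#' @rdname colorfy_config
#' @export
default_conservation_groups <- function() {
  list(
    GA   = c("G", "A"),
    VLI  = c("V", "L", "I"),
    FYW  = c("F", "Y", "W"),
    CM   = c("C", "M"),
    KRH  = c("K", "R", "H"),
    DENQ = c("D", "E", "N", "Q"),
    ST   = c("S", "T"),
    P    = "P"
  )
}

#' @rdname colorfy_config
#' @export
default_bands <- function() {
  data.frame(name  = c("Blue", "Green", "Gold", "Red"),
             lower = c(61, 71, 81, 91),
             upper = c(70, 80, 90, 100),
             stringsAsFactors = FALSE)
}

#' @rdname colorfy_config
#' @export
default_palette <- function() {
  list(Blue  = c(dark = "#1f4e9c", light = "#9ab8e8"),
       Green = c(dark = "#1e7a1e", light = "#9cd89c"),
       Gold  = c(dark = "#b8860b", light = "#ecd27a"),
       Red   = c(dark = "#b22222", light = "#eda3a3"))
}

#' Per-column residue and group composition
#'
#' Percentages downstream are computed over the column's *occupancy* — the
#' number of non-gap residues — so gaps never dilute a conservation call.
#'
#' @param aln an [alignment()] object.
#' @param column 1-based column index.
#' @param config a [colorfy_config()].
#' @return A list of class `CompositionProfile`: `column_index`,
#'   `residues` (the column's characters, per sequence), `residue_counts`,
#'   `group_counts`, `occupancy`, `gap_count`.
#' @export
column_composition <- function(aln, column, config = colorfy_config()) {
  stopifnot(inherits(aln, "Alignment"))
  column <- as.integer(column)
  if (column < 1L || column > aln$length) {
    stop("column ", column, " out of range 1..", aln$length)
  }
  chars <- substr(aln$seqs, column, column)
  res <- chars[chars != "-"]
  rc <- table(factor(res, levels = unique(res)))
  residue_counts <- stats::setNames(as.integer(rc), names(rc))
  grp <- config$aa2group[res]
  grp <- grp[!is.na(grp)]  # X and friends belong to no group
  gc <- table(factor(grp, levels = unique(grp)))
  group_counts <- stats::setNames(as.integer(gc), names(gc))
  structure(
    list(column_index = column, residues = chars,
         residue_counts = residue_counts, group_counts = group_counts,
         occupancy = length(res), gap_count = sum(chars == "-")),
    class = "CompositionProfile"
  )
}

#' Map a conservation percentage to a color band
#'
#' Bands are half-open on the real line — \[61, 71), \[71, 81), \[81, 91),
#' \[91, 100\] by default — so non-integer percentages fall into exactly
#' one band; values below the first band's lower edge get no band.
#'
#' @param percent a percentage in \[0, 100\].
#' @param config a [colorfy_config()].
#' @return The band name, or `NULL` when the percentage is below the first
#'   band.
#' @export
percent_band <- function(percent, config = colorfy_config()) {
  if (is.na(percent) || percent < 0 || percent > 100) {
    stop("percent must lie in [0, 100]")
  }
  b <- config$bands
  if (percent < b$lower[1L]) return(NULL)
  for (i in seq_len(nrow(b))) {
    hi <- if (i == nrow(b)) b$upper[i] else b$lower[i + 1L]
    if (percent >= b$lower[i] &&
        (percent < hi || (i == nrow(b) && percent <= hi))) {
      return(b$name[i])
    }
  }
  NULL
}

#' Classify one alignment column
#'
#' Applies the three-way categorization with Majority Identity precedence
#' (see [colorfy_config()]). Shades: in a Majority Identity column the
#' positions holding the majority residue are dark and other members of its
#' conservation group are light; a Conserved Minority column is entirely
#' light over its majority group; Insufficient Conservation columns are
#' uncolored. Ties for the majority residue or group are broken
#' alphabetically (a tie can never change the category, only the label).
#'
#' @param profile a [column_composition()] result.
#' @param config a [colorfy_config()].
#' @return A list of class `ColumnAnnotation`: `column_index`, `category`
#'   (`"MajorityIdentity"`, `"ConservedMinority"` or
#'   `"InsufficientConservation"`), `driving_percent`, `band`,
#'   `majority_residue`, `majority_group`, `residue_shades` (per sequence:
#'   `"dark"`, `"light"` or `"uncolored"`).
#' @export
classify_column <- function(profile, config = colorfy_config()) {
  stopifnot(inherits(profile, "CompositionProfile"))
  n <- profile$occupancy
  chars <- profile$residues
  uncol <- rep("uncolored", length(chars))

  if (n == 0L) {
    warning("column ", profile$column_index,
            " contains only gaps; classified as InsufficientConservation")
    return(column_annotation(profile$column_index, "InsufficientConservation",
                             0, NULL, NULL, NULL, uncol))
  }

  rc <- profile$residue_counts
  # exclude ambiguity letters from majority-residue candidacy
  cand <- rc[names(rc) %in% names(config$aa2group)]
  max_res_pct <- if (length(rc)) 100 * max(rc) / n else 0
  top_res <- if (length(cand)) {
    nm <- names(cand)[cand == max(cand)]
    sort(nm)[1L]
  } else NULL
  top_res_pct <- if (!is.null(top_res)) 100 * cand[[top_res]] / n else 0

  gc <- profile$group_counts
  top_grp <- if (length(gc)) {
    nm <- names(gc)[gc == max(gc)]
    sort(nm)[1L]
  } else NULL
  top_grp_pct <- if (!is.null(top_grp)) 100 * gc[[top_grp]] / n else 0

  if (!is.null(top_res) && top_res_pct >= config$identity_threshold) {
    grp_of <- unname(config$aa2group[top_res])
    shades <- uncol
    shades[chars == top_res] <- "dark"
    in_grp <- chars %in% config$groups[[grp_of]] & chars != top_res
    shades[in_grp] <- "light"
    return(column_annotation(profile$column_index, "MajorityIdentity",
                             top_res_pct, percent_band(top_res_pct, config),
                             top_res, grp_of, shades))
  }

  if (!is.null(top_grp) &&
      top_grp_pct >= config$minority_group_threshold &&
      max_res_pct <= config$minority_identity_cap) {
    shades <- uncol
    shades[chars %in% config$groups[[top_grp]]] <- "light"
    return(column_annotation(profile$column_index, "ConservedMinority",
                             top_grp_pct, percent_band(top_grp_pct, config),
                             NULL, top_grp, shades))
  }

  column_annotation(profile$column_index, "InsufficientConservation",
                    max(max_res_pct, top_grp_pct), NULL, NULL, NULL, uncol)
}

column_annotation <- function(column_index, category, driving_percent,
                              band, majority_residue, majority_group,
                              residue_shades) {
  structure(
    list(column_index = column_index, category = category,
         driving_percent = driving_percent, band = band,
         majority_residue = majority_residue,
         majority_group = majority_group,
         residue_shades = residue_shades),
    class = "ColumnAnnotation"
  )
}

#' Classify every column of an alignment
#'
#' @param aln an [alignment()] object.
#' @param config a [colorfy_config()].
#' @return A list with one [classify_column()] annotation per column.
#' @examples
#' aln <- alignment(c("a", "b", "c"), c("AAA", "AAA", "AAV"))
#' anns <- colorfy_alignment(aln)
#' sapply(anns, `[[`, "category")
#' @export
colorfy_alignment <- function(aln, config = colorfy_config()) {
  stopifnot(inherits(aln, "Alignment"))
  lapply(seq_len(aln$length), function(j) {
    classify_column(column_composition(aln, j, config), config)
  })
}

#' Annotate a mutation point on the alignment
#'
#' Maps an ungapped residue position of one sequence to its alignment
#' column (skipping gaps) and attaches that column's conservation
#' annotation together with the wild-type and mutant codons and their
#' translations — the "box" drawn alongside the alignment insets.
#'
#' @param aln an [alignment()] object.
#' @param annotations result of [colorfy_alignment()] on `aln`.
#' @param seq_id identifier of the sequence carrying the mutation.
#' @param residue_position 1-based position in the *ungapped* sequence.
#' @param wt_codon,mut_codon 3-letter DNA codons.
#' @return A list of class `MutationBox`: `seq_id`, `residue_position`,
#'   `column`, `category`, `band`, `wt_codon`, `mut_codon`, `wt_aa`,
#'   `mut_aa`.
#' @export
annotate_mutation_box <- function(aln, annotations, seq_id, residue_position,
                                  wt_codon, mut_codon) {
  stopifnot(inherits(aln, "Alignment"))
  if (!seq_id %in% aln$ids) stop("unknown sequence id: '", seq_id, "'")
  wt_codon <- toupper(wt_codon); mut_codon <- toupper(mut_codon)
  for (cd in c(wt_codon, mut_codon)) {
    if (!grepl("^[ACGT]{3}$", cd)) stop("not a DNA codon: '", cd, "'")
  }
  chars <- strsplit(aln$seqs[[seq_id]], "")[[1]]
  ungapped_cols <- which(chars != "-")
  if (residue_position < 1L || residue_position > length(ungapped_cols)) {
    stop("residue position ", residue_position, " beyond ungapped length ",
         length(ungapped_cols), " of '", seq_id, "'")
  }
  col <- ungapped_cols[[residue_position]]
  ann <- annotations[[col]]
  structure(
    list(seq_id = seq_id, residue_position = residue_position,
         column = col, category = ann$category, band = ann$band,
         wt_codon = wt_codon, mut_codon = mut_codon,
         wt_aa = translate_codon(wt_codon), mut_aa = translate_codon(mut_codon)),
    class = "MutationBox"
  )
}

#' Render a classified alignment
#'
#' @param aln an [alignment()] object.
#' @param annotations result of [colorfy_alignment()].
#' @param boxes optional list of [annotate_mutation_box()] results.
#' @param format `"html"`, `"ansi"` or `"tsv"`.
#' @param config the [colorfy_config()] whose palette to use.
#' @return A character vector of output lines; byte-identical for fixed
#'   input.
#' @export
render_colorfy <- function(aln, annotations, boxes = list(),
                           format = c("html", "ansi", "tsv"),
                           config = colorfy_config()) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "Alignment"))
  if (length(annotations) != aln$length) {
    stop("need one annotation per column")
  }
  switch(format,
         tsv  = write_annotation_tsv(annotations),
         html = render_html(aln, annotations, boxes, config),
         ansi = render_ansi(aln, annotations, config))
}

render_html <- function(aln, annotations, boxes, config) {
  css <- unlist(lapply(names(config$palette), function(b) {
    p <- config$palette[[b]]
    c(sprintf(".%s-dark{background:%s;color:#fff;}", tolower(b), p[["dark"]]),
      sprintf(".%s-light{background:%s;}", tolower(b), p[["light"]]))
  }))
  out <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/><style>",
           "body{font-family:monospace;}", "span.res{padding:0 1px;}",
           css, "</style></head><body>")
  out <- c(out, "<table class=\"legend\"><tr><th>Band</th><th>Range</th></tr>")
  for (i in seq_len(nrow(config$bands))) {
    out <- c(out, sprintf("<tr><td>%s</td><td>%d&ndash;%d</td></tr>",
                          config$bands$name[i], config$bands$lower[i],
                          config$bands$upper[i]))
  }
  out <- c(out, "</table>")
  for (si in seq_along(aln$ids)) {
    id <- aln$ids[[si]]
    chars <- strsplit(aln$seqs[[id]], "")[[1]]
    spans <- vapply(seq_along(chars), function(j) {
      ann <- annotations[[j]]
      shade <- ann$residue_shades[[si]]
      if (shade == "uncolored" || is.null(ann$band)) {
        sprintf("<span class=\"res\">%s</span>", chars[[j]])
      } else {
        sprintf("<span class=\"res %s-%s\">%s</span>",
                tolower(ann$band), shade, chars[[j]])
      }
    }, "")
    out <- c(out, sprintf("<div class=\"seq\"><b>%s</b> %s</div>",
                          id, paste0(spans, collapse = "")))
  }
  for (bx in boxes) {
    out <- c(out, sprintf(
      "<div class=\"box\">%s position %d (column %d): %s/%s &rarr; %s/%s [%s, %s]</div>",
      bx$seq_id, bx$residue_position, bx$column, bx$wt_codon, bx$wt_aa,
      bx$mut_codon, bx$mut_aa, bx$category, bx$band %||% "no band"))
  }
  c(out, "</body></html>")
}

# 8-color terminal approximation of the band palette
ANSI_CODES <- list(Blue = c(dark = "44;97", light = "104;30"),
                   Green = c(dark = "42;97", light = "102;30"),
                   Gold = c(dark = "43;30", light = "103;30"),
                   Red = c(dark = "41;97", light = "101;30"))

render_ansi <- function(aln, annotations, config) {
  vapply(seq_along(aln$ids), function(si) {
    id <- aln$ids[[si]]
    chars <- strsplit(aln$seqs[[id]], "")[[1]]
    cells <- vapply(seq_along(chars), function(j) {
      ann <- annotations[[j]]
      shade <- ann$residue_shades[[si]]
      if (shade == "uncolored" || is.null(ann$band)) return(chars[[j]])
      sprintf("\033[%sm%s\033[0m", ANSI_CODES[[ann$band]][[shade]], chars[[j]])
    }, "")
    sprintf("%-12s %s", id, paste0(cells, collapse = ""))
  }, "")
}
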
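#' Read a meiotic progeny genotype table
#'
#' Expects TSV columns `cross`, `medium`, `genotype_class`, `count` — the
#' layout of the packaged cross-results fixture ([progeny_fixture()]), in
#' which each (cross, medium) block tallies the four two-locus genotype
#' classes of a dihybrid cross.
#'
#' @param input path or character lines.
#' @return A validated data.frame of class `ProgenyTable`.
#' @export
read_progeny_table <- function(input) {
  lines <- read_input_lines(input)
  df <- utils::read.delim(text = paste0(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("cross", "medium", "genotype_class", "count")
  if (!all(need %in% names(df))) {
    stop("progeny table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(is.na(df$count)) || any(df$count < 0)) {
    stop("progeny counts must be non-negative integers")
  }
  dup <- duplicated(df[, c("cross", "medium", "genotype_class")])
  if (any(dup)) stop("duplicate (cross, medium, genotype_class) row")
  class(df) <- c("ProgenyTable", class(df))
  df
}

#' Path to the packaged cross-results fixture
#'
#' Progeny tallies from the four crosses between the NAMPT-insertion
#' mutant and each nicotinamide-requiring mutant, scored on NAM and on NMN
#' medium; the double-mutant class is zero in every block.
#'
#' @return File path of the bundled TSV.
#' @export
progeny_fixture <- function() {
  system.file("extdata", "progeny_table2.tsv", package = "nadkit",
              mustWork = TRUE)
}

#' Tally viable progeny per cross
#'
#' @param table a [read_progeny_table()] result (or a path, which is read
#'   first).
#' @param medium optional medium filter (e.g. `"R+NAM"`).
#' @return A list with `per_cross` (named integer vector), `per_class`
#'   (named integer vector) and `total`.
#' @examples
#' tally_progeny(progeny_fixture(), medium = "R+NAM")$total  # 198
#' @export
tally_progeny <- function(table, medium = NULL) {
  if (is.character(table)) table <- read_progeny_table(table)
  stopifnot(inherits(table, "ProgenyTable"))
  if (!is.null(medium)) {
    table <- table[table$medium == medium, , drop = FALSE]
    if (nrow(table) == 0L) stop("no rows for medium '", medium, "'")
  }
  per_cross <- vapply(split(table$count, table$cross), sum, 0)
  per_class <- vapply(split(table$count, table$genotype_class), sum, 0)
  list(per_cross = per_cross[unique(table$cross)],
       per_class = per_class,
       total = sum(table$count))
}

#' Exact probability that a genotype class is empty
#'
#' Under Mendelian segregation of two unlinked loci, each viable progeny
#' falls in a given two-locus class with probability `p` (1/4 for a
#' 1:1:1:1 dihybrid cross). The probability that none of `n` independent
#' viable progeny belong to the class is `(1 - p)^n` — the exact tail
#' evidence that an unrecovered class (here the double mutant) is
#' synthetically lethal rather than missing by chance. A chi-square test
#' is deliberately avoided: an expected count of zero in the missing class
#' invalidates its asymptotics.
#'
#' @param n_viable number of viable progeny scored.
#' @param expected_fraction the class probability `p`, default 1/4.
#' @return The probability of observing zero members of the class.
#' @examples
#' missing_class_test(198)  # ~ 2.2e-25
#' @export
missing_class_test <- function(n_viable, expected_fraction = 0.25) {
  n_viable <- as.integer(n_viable)
  if (is.na(n_viable) || n_viable < 0L) stop("n_viable must be >= 0")
  p <- expected_fraction
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    stop("expected_fraction must lie strictly between 0 and 1")
  }
  (1 - p)^n_viable
}

#' Percent increase of a quantity over a baseline
#'
#' `100 * (new - base) / base`; the replicative-capacity headline
#' (38-40 versus 48-50 completed cell cycles) is a 25 percent increase on
#' the ranges' upper bounds.
#'
#' @param base baseline value, strictly positive.
#' @param new new value.
#' @return Percent change (negative for a decrease).
#' @examples
#' percent_increase(40, 50)  # 25
#' @export
percent_increase <- function(base, new) {
  if (!is.numeric(base) || any(base <= 0)) stop("base must be > 0")
  100 * (new - base) / base
}

#' Lifespan contrast between two generation ranges
#'
#' Summarizes the percent increase between two ranges of completed cell
#' cycles at their lower bounds, upper bounds, and midpoints.
#'
#' @param base_range,new_range length-2 numeric vectors `c(lo, hi)`.
#' @return A named numeric vector with elements `lower`, `upper`,
#'   `midpoint`.
#' @examples
#' lifespan_contrast(c(38, 40), c(48, 50))
#' @export
lifespan_contrast <- function(base_range, new_range) {
  stopifnot(length(base_range) == 2L, length(new_range) == 2L)
  c(lower = percent_increase(base_range[1L], new_range[1L]),
    upper = percent_increase(base_range[2L], new_range[2L]),
    midpoint = percent_increase(mean(base_range), mean(new_range)))
}
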
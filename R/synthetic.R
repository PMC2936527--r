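#' Generate an alignment with planted per-column conservation categories
#'
#' Builds a gapless protein alignment column by column so that
#' [classify_column()] provably recovers each planted label: a
#' MajorityIdentity column places exactly `percent` identical residues and
#' fills the remainder with distinct residues from distinct other
#' conservation groups; a ConservedMinority column spreads `percent`
#' same-group residues as evenly as possible over the group (so no single
#' residue exceeds the 60 percent identity cap) and fills the rest from
#' other groups; an InsufficientConservation column cycles residues over
#' different groups so neither threshold is met. Row order is shuffled per
#' column. A percentage that does not correspond to a whole number of
#' sequences, or a plan unachievable at the given depth, is an error.
#'
#' @param n_seqs number of sequences.
#' @param column_plan data.frame with columns `category`
#'   (`"MajorityIdentity"`, `"ConservedMinority"`,
#'   `"InsufficientConservation"`) and `percent` (target driving
#'   percentage; ignored for InsufficientConservation).
#' @param seed RNG seed.
#' @return A list with `alignment` (an [alignment()]) and `truth` (the
#'   plan, with the realized driving percent).
#' @examples
#' plan <- data.frame(category = c("MajorityIdentity", "ConservedMinority"),
#'                    percent = c(70, 100))
#' gen_alignment(10, plan, seed = 1)$truth
#' @export
gen_alignment <- function(n_seqs, column_plan, seed = 1L) {
  stopifnot(n_seqs >= 2L, is.data.frame(column_plan),
            all(c("category", "percent") %in% names(column_plan)))
  set.seed(as.integer(seed))
  groups <- default_conservation_groups()
  cols <- vector("list", nrow(column_plan))
  for (i in seq_len(nrow(column_plan))) {
    cat_i <- column_plan$category[i]
    pct <- column_plan$percent[i]
    cols[[i]] <- switch(
      cat_i,
      MajorityIdentity = plant_majority_column(n_seqs, pct, groups),
      ConservedMinority = plant_minority_column(n_seqs, pct, groups),
      InsufficientConservation = plant_unconserved_column(n_seqs, groups),
      stop("unknown category: '", cat_i, "'"))
    cols[[i]] <- sample(cols[[i]])  # shuffle rows within the column
  }
  mat <- do.call(cbind, cols)
  seqs <- apply(mat, 1L, paste0, collapse = "")
  list(alignment = alignment(sprintf("s%d", seq_len(n_seqs)), seqs),
       truth = column_plan)
}

count_for_percent <- function(n, pct) {
  k <- n * pct / 100
  if (abs(k - round(k)) > 1e-9) {
    stop(pct, "% of ", n, " sequences is not a whole number of residues")
  }
  as.integer(round(k))
}

plant_majority_column <- function(n, pct, groups) {
  if (pct < 61) stop("MajorityIdentity needs percent >= 61, got ", pct)
  k <- count_for_percent(n, pct)
  gi <- sample(length(groups), 1L)
  res <- sample(groups[[gi]], 1L)
  fillers <- vapply(groups[-gi], `[`, "", 1L)
  fill <- rep(sample(fillers), length.out = n - k)
  # fillers must each stay rarer than the majority residue (k >= 0.61 n)
  if (n - k > 0L && max(table(fill)) >= k) {
    stop("cannot fill ", n - k, " minority residues below a majority of ", k)
  }
  c(rep(res, k), fill)
}

plant_minority_column <- function(n, pct, groups) {
  if (pct < 61) stop("ConservedMinority needs percent >= 61, got ", pct)
  g <- count_for_percent(n, pct)
  multi <- groups[vapply(groups, length, 0L) >= 2L]
  gi <- sample(length(multi), 1L)
  members <- multi[[gi]]
  base <- g %/% length(members)
  extra <- g %% length(members)
  counts <- rep(base, length(members)) + c(rep(1L, extra),
                                           rep(0L, length(members) - extra))
  if (max(counts) / n > 0.60 + 1e-9) {
    stop("cannot spread ", g, " group residues below the 60% identity cap ",
         "at depth ", n)
  }
  other <- setdiff(names(groups), names(multi)[gi])
  fillers <- vapply(groups[other], `[`, "", 1L)
  fill <- rep(sample(fillers), length.out = n - g)
  col <- c(rep(members, counts), fill)
  # filler groups must stay below the planted group
  if (n - g > 0L && max(table(fill)) >= g) {
    stop("minority plan unachievable: fillers would rival the planted group")
  }
  col
}

plant_unconserved_column <- function(n, groups) {
  if (n < 2L) stop("InsufficientConservation needs >= 2 sequences")
  fillers <- vapply(groups, `[`, "", 1L)
  col <- rep(sample(fillers), length.out = n)
  if (max(table(col)) / n >= 0.61) {
    stop("cannot build an unconserved column at depth ", n)
  }
  col
}

# codons by translation, excluding stops
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0(c("ATG", body, sample(stops, 1L)), collapse = "")
}

#' Generate a CDS with a planted variant of known consequence
#'
#' Builds a random coding sequence (ATG start, random sense codons, one
#' stop) and plants a variant whose protein-level consequence is known by
#' construction: for `missense`, `synonymous` and `nonsense` a single-base
#' substitution is chosen from the 9 neighbors of a random internal codon;
#' for `frameshift` one base of an internal codon is deleted, and the
#' expected downstream stop is located by naive translation of the mutant
#' sequence inside the generator.
#'
#' @param n_codons total codons including start and stop (>= 3).
#' @param variant_kind `"missense"`, `"synonymous"`, `"nonsense"` or
#'   `"frameshift"`.
#' @param seed RNG seed.
#' @return A list with `cds`, `variant` (a [gene_variant()]) and
#'   `expected` (a consequence list with `kind`, `residue_index`, `wt_aa`,
#'   `mut_aa`, `stop_codon_index`, `no_stop_found`).
#' @export
gen_gene_with_variant <- function(n_codons, variant_kind = c("missense",
                                                             "synonymous",
                                                             "nonsense",
                                                             "frameshift"),
                                  seed = 1L) {
  variant_kind <- match.arg(variant_kind)
  stopifnot(n_codons >= 3L)
  set.seed(as.integer(seed))
  gc <- Biostrings::GENETIC_CODE

  repeat {
    cds <- random_cds(n_codons)
    # internal codons only (not start, not stop)
    cand <- sample(seq(2L, n_codons - 1L))
    hit <- NULL
    for (k in cand) {
      codon <- substr(cds, 3L * k - 2L, 3L * k)
      if (variant_kind == "frameshift") {
        off <- sample(0:2, 1L)
        pos <- 3L * k - 2L + off
        ref <- substr(cds, pos, pos)
        variant <- gene_variant("deletion", pos, ref)
        mutant <- apply_variant(cds, variant)
        aa <- naive_translate(mutant)
        stop_rel <- which(aa[seq(k, length(aa))] == "*")
        hit <- list(variant = variant, expected = list(
          kind = "frameshift", residue_index = k,
          wt_aa = unname(gc[[codon]]),
          stop_codon_index = if (length(stop_rel)) k + stop_rel[1L] - 1L
                             else NA_integer_,
          no_stop_found = length(stop_rel) == 0L))
        break
      }
      nb <- codon_neighbors(codon)
      want <- switch(variant_kind,
                     synonymous = nb$aa == gc[[codon]],
                     missense = nb$aa != gc[[codon]] & nb$aa != "*",
                     nonsense = nb$aa == "*")
      if (!any(want)) next
      pick <- nb[want, , drop = FALSE]
      pick <- pick[sample(nrow(pick), 1L), , drop = FALSE]
      pos <- 3L * k - 3L + pick$position
      variant <- gene_variant("substitution", pos,
                              substr(codon, pick$position, pick$position),
                              pick$base)
      hit <- list(variant = variant, expected = list(
        kind = variant_kind, residue_index = k,
        wt_aa = unname(gc[[codon]]), mut_aa = unname(pick$aa),
        stop_codon_index = if (variant_kind == "nonsense") k else NA_integer_,
        no_stop_found = FALSE))
      break
    }
    if (!is.null(hit)) {
      return(c(list(cds = cds), hit))
    }
  }
}

codon_neighbors <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      cand <- codon
      substr(cand, pos, pos) <- b
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, base = b, codon = cand, aa = unname(gc[[cand]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# straightforward frame-0 translation used as generator-side truth
naive_translate <- function(dna) {
  n <- nchar(dna) %/% 3L
  gc <- Biostrings::GENETIC_CODE
  vapply(seq_len(n), function(k) {
    unname(gc[[substr(dna, 3L * k - 2L, 3L * k)]])
  }, "")
}

#' Generate a meiotic progeny table with an optional lethal class
#'
#' Draws multinomial counts over the four two-locus genotype classes at
#' Mendelian 1:1:1:1 proportions; when `lethal_class` is given, that class
#' is fixed at zero and the `n_per_cross` viable progeny are drawn over
#' the remaining three classes (the conditional distribution of viable
#' progeny when one class dies before scoring).
#'
#' @param crosses character vector of cross names.
#' @param n_per_cross viable progeny per cross.
#' @param lethal_class optional genotype class forced to zero.
#' @param medium medium label for the table.
#' @param seed RNG seed.
#' @return A `ProgenyTable` data.frame.
#' @export
gen_progeny_table <- function(crosses, n_per_cross,
                              lethal_class = NULL, medium = "R+NAM",
                              seed = 1L) {
  classes <- c("NIC;NPT1", "NIC;npt1", "nic;NPT1", "nic;npt1")
  if (!is.null(lethal_class) && !lethal_class %in% classes) {
    stop("lethal_class must be one of: ", paste(classes, collapse = ", "))
  }
  set.seed(as.integer(seed))
  rows <- do.call(rbind, lapply(crosses, function(cr) {
    live <- if (is.null(lethal_class)) classes else setdiff(classes,
                                                            lethal_class)
    cnt <- as.integer(stats::rmultinom(1L, n_per_cross,
                                       rep(1 / length(live), length(live))))
    df <- data.frame(cross = cr, medium = medium, genotype_class = live,
                     count = cnt, stringsAsFactors = FALSE)
    if (!is.null(lethal_class)) {
      df <- rbind(df, data.frame(cross = cr, medium = medium,
                                 genotype_class = lethal_class, count = 0L,
                                 stringsAsFactors = FALSE))
    }
    df[match(classes, df$genotype_class), , drop = FALSE]
  }))
  rownames(rows) <- NULL
  class(rows) <- c("ProgenyTable", class(rows))
  rows
}

#' Generate a Ct table with planted relative-expression truth
#'
#' Each strain's replicate delta-Ct is the wild-type baseline plus the
#' offset `-log2(percent / 100)` that encodes its true expression level,
#' plus Gaussian measurement noise on the offset. The wild-type rows carry
#' the baseline exactly: planted truth is defined relative to the measured
#' wild-type calibration, so noise models the per-replicate ΔΔCt
#' measurement error of each mutant strain against that anchor.
#'
#' @param true_percent named numeric vector of true percent-of-wild-type
#'   values; must contain the wild-type strain at exactly 100. The first
#'   strain with value 100 is taken as wild type.
#' @param noise_sd Gaussian noise standard deviation in cycles (default
#'   0.2).
#' @param n_reps replicates per strain (default 2, as in the assay
#'   design).
#' @param gene gene label.
#' @param seed RNG seed.
#' @return A `CtTable` data.frame with an attribute `wild_type` naming the
#'   anchor strain.
#' @examples
#' gen_ct_table(c(wt = 100, mut = 250), noise_sd = 0, seed = 1)
#' @export
gen_ct_table <- function(true_percent, noise_sd = 0.2, n_reps = 2L,
                         gene = "G1", seed = 1L) {
  if (is.null(names(true_percent)) || any(!nzchar(names(true_percent)))) {
    stop("true_percent must be a named vector of strains")
  }
  if (any(true_percent <= 0)) stop("true percents must be positive")
  wt_idx <- which(abs(true_percent - 100) < 1e-12)[1L]
  if (is.na(wt_idx)) stop("one strain must sit at exactly 100 (wild type)")
  set.seed(as.integer(seed))
  base_dct <- 3  # arbitrary wild-type target-minus-reference baseline
  ct_ref <- 20
  rows <- do.call(rbind, lapply(seq_along(true_percent), function(i) {
    strain <- names(true_percent)[i]
    offset <- -log2(true_percent[[i]] / 100)
    noise <- if (i == wt_idx) rep(0, n_reps) else
      stats::rnorm(n_reps, 0, noise_sd)
    data.frame(strain = strain, gene = gene, replicate = seq_len(n_reps),
               ct_target = ct_ref + base_dct + offset + noise,
               ct_ref = ct_ref, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("CtTable", class(rows))
  attr(rows, "wild_type") <- names(true_percent)[wt_idx]
  rows
}
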
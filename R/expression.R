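#' Read a qRT-PCR Ct table
#'
#' TSV columns: `strain`, `gene`, `replicate`, `ct_target`, `ct_ref` —
#' one row per replicate measurement, with `ct_ref` the cycle threshold of
#' the internal control gene (CRY1, encoding ribosomal protein S14).
#'
#' @param input path or character lines.
#' @return A validated data.frame of class `CtTable`.
#' @export
read_ct_table <- function(input) {
  lines <- read_input_lines(input)
  df <- utils::read.delim(text = paste0(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("strain", "gene", "replicate", "ct_target", "ct_ref")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$ct_target)) || any(!is.finite(df$ct_ref))) {
    stop("Ct values must be finite")
  }
  class(df) <- c("CtTable", class(df))
  df
}

#' Relative expression by the comparative Ct method
#'
#' For each replicate, delta-Ct = `ct_target - ct_ref`; replicates are
#' averaged on the delta-Ct scale, and each strain's expression is
#' `100 * efficiency^-(meanDeltaCt_strain - meanDeltaCt_wildtype)` percent
#' of wild type, so the wild-type strain maps to exactly 100. Per-strain
#' standard errors are computed on the percent scale from per-replicate
#' delta-delta-Ct values.
#'
#' @param records a `CtTable` (or path) for a single gene, or for several
#'   genes (each normalized independently).
#' @param wild_type_strain name of the reference strain.
#' @param efficiency amplification efficiency (default 2, perfect
#'   doubling).
#' @return A data.frame: `gene`, `strain`, `percent`, `se` (`NA` for a
#'   single replicate), `n_reps`, `call` (see [fold_change_call()]).
#' @examples
#' tab <- gen_ct_table(c(wt = 100, mut = 250), noise_sd = 0, seed = 1)
#' relative_expression(tab, "wt")
#' @export
relative_expression <- function(records, wild_type_strain, efficiency = 2) {
  if (is.character(records)) records <- read_ct_table(records)
  stopifnot(is.data.frame(records))
  if (!wild_type_strain %in% records$strain) {
    stop("wild-type strain '", wild_type_strain, "' not in table")
  }
  records$dct <- records$ct_target - records$ct_ref
  out <- do.call(rbind, lapply(split(records, records$gene), function(g) {
    wt <- g[g$strain == wild_type_strain, , drop = FALSE]
    if (nrow(wt) == 0L) {
      stop("gene '", g$gene[1L], "' lacks wild-type measurements")
    }
    wt_mean <- mean(wt$dct)
    do.call(rbind, lapply(split(g, g$strain), function(s) {
      ddct <- s$dct - wt_mean
      pct <- 100 * efficiency^-mean(ddct)
      per_rep <- 100 * efficiency^-ddct
      se <- if (length(ddct) >= 2L) {
        stats::sd(per_rep) / sqrt(length(per_rep))
      } else NA_real_
      data.frame(gene = s$gene[1L], strain = s$strain[1L],
                 percent = pct, se = se, n_reps = length(ddct),
                 call = fold_change_call(pct),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Two-fold significance rule for relative expression
#'
#' Only changes beyond two-fold in either direction count: above 200
#' percent of wild type is `significant_up`, below 50 percent is
#' `significant_down`, anything between is `not_significant`.
#'
#' @param percent percent-of-wild-type value(s), non-negative.
#' @return Character vector of calls.
#' @examples
#' fold_change_call(c(250, 150, 40))
#' @export
fold_change_call <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0)) {
    stop("percent must be non-negative and finite")
  }
  ifelse(percent > 200, "significant_up",
         ifelse(percent < 50, "significant_down", "not_significant"))
}

#' Mean and standard error of replicate measurements
#'
#' Standard error is the sample standard deviation over the square root of
#' the replicate count; with two replicates it reduces to half the
#' absolute difference.
#'
#' @param values numeric vector, at least two values.
#' @return Named vector `c(mean, se)`.
#' @examples
#' summarize_replicates(c(80, 120))  # mean 100, se 20
#' @export
summarize_replicates <- function(values) {
  if (length(values) < 2L) stop("need at least 2 replicate values")
  c(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}
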
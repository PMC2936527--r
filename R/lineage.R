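#' A cell in the flagellar-number pedigree
#'
#' In the delta-tubulin pedigree system, flagellar number reports lineage
#' age: a uniflagellate or biflagellate cell divides into one aflagellate
#' and one biflagellate daughter, while an aflagellate cell never produces
#' a biflagellate daughter directly — its daughters are one aflagellate
#' and one uniflagellate, so a biflagellate descendant of an aflagellate
#' founder takes at least two divisions to appear. Biflagellate cells swim
#' and mark the oldest lineage in a culture.
#'
#' @param flagella 0, 1 or 2.
#' @param age completed divisions of the lineage (>= 0).
#' @param lifespan_limit maximum divisions this lineage can complete; the
#'   cell is senescent once `age >= lifespan_limit`.
#' @return A list of class `CellState`.
#' @export
cell_state <- function(flagella, age = 0L, lifespan_limit = 40L) {
  flagella <- as.integer(flagella)
  if (!flagella %in% 0:2) stop("flagella must be 0, 1 or 2")
  age <- as.integer(age)
  if (age < 0L) stop("age must be >= 0")
  structure(list(flagella = flagella, age = age,
                 lifespan_limit = as.integer(lifespan_limit),
                 senescent = age >= lifespan_limit),
            class = "CellState")
}

#' Divide a cell under the flagellar-number pedigree rules
#'
#' @param cell a [cell_state()].
#' @return A list of the two daughter `CellState`s, each one division
#'   older. Dividing a senescent cell is an error.
#' @examples
#' divide_cell(cell_state(2, age = 5))
#' @export
divide_cell <- function(cell) {
  stopifnot(inherits(cell, "CellState"))
  if (cell$senescent) {
    stop("cannot divide a senescent cell (age ", cell$age, " >= limit ",
         cell$lifespan_limit, ")")
  }
  daughters <- if (cell$flagella >= 1L) c(0L, 2L) else c(0L, 1L)
  lapply(daughters, function(f) {
    cell_state(f, age = cell$age + 1L, lifespan_limit = cell$lifespan_limit)
  })
}

#' Parameters of the transfer-and-plate aging assay
#'
#' The assay propagates swimming (biflagellate) cells: every 12 hours the
#' top of the culture is transferred to fresh medium, and about 100 cells
#' are plated to score the fraction that still forms colonies. Division
#' number per 12-h transfer defaults to 2. The replicative limit is drawn
#' per founder lineage uniformly from `lifespan_range`, reflecting the
#' spread of completed cell cycles between lineages.
#'
#' @param lifespan_range length-2 integer range of the per-lineage
#'   division limit.
#' @param divisions_per_transfer divisions completed between transfers.
#' @param cells_plated cells plated per transfer.
#' @param n_founders biflagellate founder cells.
#' @param seed RNG seed for lifespan sampling and plating.
#' @return A list of class `LineageParams`.
#' @export
lineage_params <- function(lifespan_range = c(38L, 40L),
                           divisions_per_transfer = 2L,
                           cells_plated = 100L,
                           n_founders = 100L,
                           seed = 1L) {
  stopifnot(length(lifespan_range) == 2L, all(lifespan_range >= 1L),
            lifespan_range[1L] <= lifespan_range[2L],
            divisions_per_transfer >= 1L, cells_plated >= 1L,
            n_founders >= 1L)
  structure(list(lifespan_range = as.integer(lifespan_range),
                 divisions_per_transfer = as.integer(divisions_per_transfer),
                 cells_plated = as.integer(cells_plated),
                 n_founders = as.integer(n_founders),
                 seed = as.integer(seed)),
            class = "LineageParams")
}

# vectorized one-division step on a population matrix
# columns: flagella, age, limit; senescent cells persist undivided
step_population <- function(pop) {
  senescent <- pop[, "age"] >= pop[, "limit"]
  keep <- pop[senescent, , drop = FALSE]
  div <- pop[!senescent, , drop = FALSE]
  if (nrow(div) == 0L) return(keep)
  d1 <- div; d2 <- div
  d1[, "flagella"] <- 0L
  d2[, "flagella"] <- ifelse(div[, "flagella"] >= 1L, 2L, 1L)
  d1[, "age"] <- d1[, "age"] + 1L
  d2[, "age"] <- d2[, "age"] + 1L
  rbind(keep, d1, d2)
}

#' Simulate the transfer-and-plate aging assay
#'
#' Each transfer selects the biflagellate (swimming) cells, lets the
#' culture complete `divisions_per_transfer` divisions, then plates
#' `cells_plated` sampled cells and scores the fraction able to complete
#' at least one further division (non-senescent cells). Trajectories are
#' bit-identical for a fixed seed.
#'
#' @param params a [lineage_params()].
#' @param n_transfers number of transfers to simulate.
#' @return A data.frame with columns `transfer`, `generation` (divisions
#'   completed by the transferred lineage) and `fraction` (colony-forming
#'   fraction of plated cells).
#' @examples
#' tr <- simulate_transfers(lineage_params(seed = 7), n_transfers = 25)
#' estimate_lifespan(tr)
#' @export
simulate_transfers <- function(params, n_transfers) {
  stopifnot(inherits(params, "LineageParams"), n_transfers >= 1L)
  set.seed(params$seed)
  vals <- seq(params$lifespan_range[1L], params$lifespan_range[2L])
  limits <- vals[sample.int(length(vals), params$n_founders, replace = TRUE)]
  pop <- cbind(flagella = rep(2L, params$n_founders),
               age = 0L, limit = as.integer(limits))
  out <- data.frame(transfer = integer(0), generation = integer(0),
                    fraction = numeric(0))
  for (t in seq_len(n_transfers)) {
    swimmers <- pop[pop[, "flagella"] == 2L, , drop = FALSE]
    gen <- t * params$divisions_per_transfer
    if (nrow(swimmers) == 0L) {
      out <- rbind(out, data.frame(transfer = t, generation = gen,
                                   fraction = 0))
      next
    }
    tube <- swimmers
    for (d in seq_len(params$divisions_per_transfer)) {
      tube <- step_population(tube)
    }
    idx <- if (nrow(tube) <= params$cells_plated) seq_len(nrow(tube))
           else sample.int(nrow(tube), params$cells_plated)
    plated <- tube[idx, , drop = FALSE]
    frac <- mean(plated[, "age"] < plated[, "limit"])
    out <- rbind(out, data.frame(transfer = t, generation = gen,
                                 fraction = frac))
    pop <- tube
  }
  out
}

#' Generation interval at which colony formation is lost
#'
#' @param trajectory a [simulate_transfers()] result.
#' @return A list with `last_positive` (last generation with fraction >
#'   0; 0 if never positive), `first_zero` (first generation with fraction
#'   0; `NA` when the fraction never reaches 0, an open-ended interval).
#' @export
estimate_lifespan <- function(trajectory) {
  stopifnot(all(c("generation", "fraction") %in% names(trajectory)))
  pos <- trajectory$generation[trajectory$fraction > 0]
  zero <- trajectory$generation[trajectory$fraction == 0]
  list(last_positive = if (length(pos)) max(pos) else 0L,
       first_zero = if (length(zero)) min(zero) else NA_integer_)
}
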
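#' The default NAD+ biosynthesis network
#'
#' Builds the metabolite/reaction graph of NAD+ biosynthesis as studied in
#' Chlamydomonas: the aspartate de novo route (ASO, QS, QPT, NMNAT, NS),
#' the six-enzyme tryptophan de novo route (TDO/IDO as alternative first
#' steps, then AFMID, KMO, KYNU, 3HAO, converging on quinolinate), the
#' 4-step salvage route (NAMase, NAPRT, NMNAT, NS) and the 2-step salvage
#' route (NAMPT, NMNAT). NMNAT carries two reactions (NaMN to NaAD and NMN
#' to NAD), and the sirtuin SIRT consumes NAD+ back to nicotinamide.
#'
#' @return A list of class `PathwayNetwork` with elements `metabolites`,
#'   `reactions` (data.frame: substrate, product, enzyme), `enzymes`, and
#'   `routes` (named list of slot lists; a slot is a character vector whose
#'   members are alternatives).
#' @examples
#' net <- build_default_network()
#' length(net$routes$aspartate_de_novo)  # 5 enzyme slots
#' @export
build_default_network <- function() {
  reactions <- data.frame(
    substrate = c("Asp", "iminoaspartate",
                  "Trp", "Trp", "NFK", "kynurenine", "3HK", "3HA",
                  "QA", "NaMN", "NaAD",
                  "NAM", "NA", "NAM", "NMN", "NAD"),
    product = c("iminoaspartate", "QA",
                "NFK", "NFK", "kynurenine", "3HK", "3HA", "QA",
                "NaMN", "NaAD", "NAD",
                "NA", "NaMN", "NMN", "NAD", "NAM"),
    enzyme = c("ASO", "QS",
               "TDO", "IDO", "AFMID", "KMO", "KYNU", "3HAO",
               "QPT", "NMNAT", "NS",
               "NAMase", "NAPRT", "NAMPT", "NMNAT", "SIRT"),
    stringsAsFactors = FALSE
  )
  routes <- list(
    aspartate_de_novo = list("ASO", "QS", "QPT", "NMNAT", "NS"),
    # six enzymes; TDO and IDO are alternatives for the first step
    tryptophan = list(c("TDO", "IDO"), "AFMID", "KMO", "KYNU", "3HAO"),
    salvage_4step = list("NAMase", "NAPRT", "NMNAT", "NS"),
    salvage_2step = list("NAMPT", "NMNAT")
  )
  structure(
    list(metabolites = unique(c(reactions$substrate, reactions$product)),
         reactions = reactions,
         enzymes = unique(reactions$enzyme),
         routes = routes,
         # amino-acid precursors every cell synthesizes internally
         internal_sources = c("Asp", "Trp")),
    class = "PathwayNetwork"
  )
}

#' Enzyme presence/absence profile of an organism
#'
#' @param organism organism name.
#' @param presence named logical vector covering every enzyme of the
#'   network.
#' @param transport named character vector mapping supplementable
#'   metabolites to `"yes"`, `"weak"` or `"no"` uptake. Defaults reflect
#'   the observed rescue pattern: NAM and NMN are taken up, nicotinic acid
#'   only weakly, NaAD and 3-hydroxyanthranilate not at all.
#' @param network the [build_default_network()] the profile refers to.
#' @return An object of class `OrganismProfile`.
#' @export
organism_profile <- function(organism, presence,
                             transport = default_transport(),
                             network = build_default_network()) {
  presence <- unlist(presence)
  missing_enz <- setdiff(network$enzymes, names(presence))
  if (length(missing_enz)) {
    stop("profile does not cover enzyme(s): ",
         paste(missing_enz, collapse = ", "))
  }
  unknown <- setdiff(names(presence), network$enzymes)
  if (length(unknown)) {
    stop("unknown enzyme(s) in profile: ", paste(unknown, collapse = ", "))
  }
  structure(list(organism = organism,
                 presence = as.logical(presence)[order(names(presence))] |>
                   stats::setNames(sort(names(presence))),
                 transport = unlist(transport)),
            class = "OrganismProfile")
}

#' @rdname organism_profile
#' @export
default_transport <- function() {
  c(NAM = "yes", NMN = "yes", "NA" = "weak", NaAD = "no", "3HA" = "no")
}

#' Bundled organism enzyme profiles
#'
#' Loads the presence/absence profiles shipped with the package
#' (Chlamydomonas, Volvox, the two Ostreococcus species, Monosiga,
#' Arabidopsis, human). The Chlamydomonas profile records IDO, KMO and
#' NAMase as present but TDO, AFMID, KYNU, 3HAO and NAPRT as absent.
#'
#' @param organism optional name; when given, that single
#'   [organism_profile()] is returned, otherwise a named list of all of
#'   them.
#' @return An `OrganismProfile` or a named list of them.
#' @export
bundled_profiles <- function(organism = NULL) {
  path <- system.file("extdata", "organism_profiles.json",
                      package = "nadkit", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  profs <- lapply(names(raw), function(nm) {
    organism_profile(nm, raw[[nm]])
  })
  names(profs) <- names(raw)
  if (is.null(organism)) return(profs)
  if (!organism %in% names(profs)) {
    stop("no bundled profile for '", organism, "'")
  }
  profs[[organism]]
}

#' Route completeness of an enzyme profile
#'
#' A route is complete when every slot is satisfied; a slot with
#' alternative members (TDO/IDO) needs at least one present. The `missing`
#' set lists every absent enzyme belonging to the route, counting
#' alternatives separately — so Chlamydomonas is missing four of the six
#' tryptophan-route enzymes even though the first slot is satisfied by
#' IDO.
#'
#' @param network a [build_default_network()].
#' @param profile an [organism_profile()].
#' @return A named list, per route: `complete` (logical) and `missing`
#'   (character vector of absent enzymes).
#' @examples
#' ev <- evaluate_profile(build_default_network(),
#'                        bundled_profiles("Chlamydomonas"))
#' ev$tryptophan$missing
#' @export
evaluate_profile <- function(network, profile) {
  stopifnot(inherits(network, "PathwayNetwork"),
            inherits(profile, "OrganismProfile"))
  pres <- profile$presence
  lapply(network$routes, function(slots) {
    enzymes <- unlist(slots)
    complete <- all(vapply(slots, function(slot) any(pres[slot]), TRUE))
    list(complete = complete,
         missing = enzymes[!pres[enzymes]])
  })
}

# metabolites reachable from `sources` using reactions whose enzyme is active
reachable_metabolites <- function(network, active_enzymes, sources) {
  rx <- network$reactions[network$reactions$enzyme %in% active_enzymes, ,
                          drop = FALSE]
  sources <- intersect(sources, network$metabolites)
  if (nrow(rx) == 0L || length(sources) == 0L) return(sources)
  g <- igraph::graph_from_data_frame(rx[, c("substrate", "product")],
                                     directed = TRUE,
                                     vertices = network$metabolites)
  reach <- unique(unlist(lapply(sources, function(s) {
    names(igraph::subcomponent(g, s, mode = "out"))
  })))
  reach
}

#' Predict viability of a lesioned strain on a given medium
#'
#' A strain is predicted viable when NAD+ is reachable from its internal
#' precursors (aspartate and tryptophan) plus an optional transported
#' supplement, using only reactions whose enzyme is present in the profile
#' and not lesioned. Transport is taken from the profile: a supplement
#' with `"no"` uptake contributes nothing, `"weak"` uptake yields a
#' rescue flagged as weak.
#'
#' @param network a [build_default_network()].
#' @param profile an [organism_profile()].
#' @param lesions character vector of lesioned (inactivated) enzymes.
#' @param supplement a metabolite name, or `NULL` for unsupplemented
#'   medium.
#' @return A list with `viable` (logical), `rescue` (`"none"`, `"full"` or
#'   `"weak"`: whether viability depended on the supplement and how well
#'   it is transported), and `reachable` (metabolite set).
#' @examples
#' net <- build_default_network()
#' chl <- bundled_profiles("Chlamydomonas")
#' predict_rescue(net, chl, lesions = "QPT", supplement = "NAM")$viable
#' @export
predict_rescue <- function(network, profile, lesions = character(0),
                           supplement = NULL) {
  stopifnot(inherits(network, "PathwayNetwork"),
            inherits(profile, "OrganismProfile"))
  lesions <- as.character(lesions)
  unknown <- setdiff(lesions, network$enzymes)
  if (length(unknown)) {
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(supplement) && !supplement %in% network$metabolites) {
    stop("unknown metabolite: '", supplement, "'")
  }
  active <- names(profile$presence)[profile$presence]
  active <- setdiff(active, lesions)

  base_reach <- reachable_metabolites(network, active,
                                      network$internal_sources)
  if ("NAD" %in% base_reach) {
    return(list(viable = TRUE, rescue = "none", reachable = base_reach))
  }
  if (is.null(supplement)) {
    return(list(viable = FALSE, rescue = "none", reachable = base_reach))
  }
  uptake <- profile$transport[supplement]
  if (is.na(uptake)) uptake <- "yes"  # unlisted metabolites: assume uptake
  if (uptake == "no") {
    return(list(viable = FALSE, rescue = "none", reachable = base_reach))
  }
  supp_reach <- reachable_metabolites(network, active,
                                      c(network$internal_sources, supplement))
  viable <- "NAD" %in% supp_reach
  list(viable = viable && uptake == "yes",
       rescue = if (!viable) "none" else if (uptake == "weak") "weak" else "full",
       reachable = supp_reach)
}

#' Predict double-mutant viability
#'
#' Convenience wrapper around [predict_rescue()] for two lesions — the
#' synthetic-lethality question for `nic; npt1` double mutants. Note the
#' pure reachability model predicts NMN medium rescues an NAMPT+NS double
#' mutant via NMNAT, whereas no such double mutants were recovered in
#' crosses; the discrepancy (NMN hydrolysis, uptake, or meiotic expression
#' differences) is flagged, not resolved, by this model.
#'
#' @param network a [build_default_network()].
#' @param profile an [organism_profile()].
#' @param lesion1,lesion2 the two lesioned enzymes.
#' @param supplement optional metabolite.
#' @return As [predict_rescue()].
#' @export
predict_double_mutant_viability <- function(network, profile, lesion1,
                                            lesion2, supplement = NULL) {
  predict_rescue(network, profile, lesions = c(lesion1, lesion2),
                 supplement = supplement)
}

#' The characterized Chlamydomonas NAD+ pathway mutants
#'
#' Maps each mutant allele to its lesioned enzyme. The `leaky` flag marks
#' alleles retaining partial activity: the NMNAT nonsense allele nic1-1
#' must be partially functional (a null would disconnect every route to
#' NAD+, yet the strain is rescued by nicotinamide), so in reachability
#' terms a leaky lesion does not block its reactions.
#'
#' @return A data.frame with columns `mutant`, `enzyme`, `leaky`.
#' @export
chlamy_mutants <- function() {
  data.frame(
    mutant = c("nic15-1", "nic7-1", "nic2-1", "nic1-1", "nic13-1", "npt1-1"),
    enzyme = c("ASO", "QS", "QPT", "NMNAT", "NS", "NAMPT"),
    leaky = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Effective lesion set of a mutant genotype
#'
#' Expands mutant allele names to the enzymes they inactivate, dropping
#' leaky alleles (which retain enough activity to pass flux).
#'
#' @param mutants character vector of allele names from
#'   [chlamy_mutants()].
#' @return Character vector of fully inactivated enzymes.
#' @export
mutant_lesions <- function(mutants) {
  tab <- chlamy_mutants()
  unknown <- setdiff(mutants, tab$mutant)
  if (length(unknown)) {
    stop("unknown mutant(s): ", paste(unknown, collapse = ", "))
  }
  sel <- tab[tab$mutant %in% mutants & !tab$leaky, , drop = FALSE]
  sel$enzyme
}
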
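#' @useDynLib rhoswitch, .registration = TRUE
#' @importFrom stats median qnorm rlnorm runif sd setNames wilcox.test
#' @importFrom utils head tail
#' @importFrom mclust Mclust mclustBIC
NULL

#' Species of the Rac1-RhoA-PAK network
#'
#' The model tracks 14 molecular species (all concentrations in nM):
#' the GDP- and GTP-bound forms of Rac1 and RhoA; PAK in its inactive
#' (`iPAK`), Rac1-GTP-bound (`cPAK`), autophosphorylated active (`pPAK`)
#' and inhibitor-bound (`iPAK_I`) forms; GEF-H1 in its active (`GEFH1`),
#' phosphorylated (`pGEFH1`) and 14-3-3-sequestered (`pGEFH1_1433`) forms;
#' free 14-3-3 (`F1433`); and the Rac GAP in inactive (`GAPi`) and
#' RhoA-activated (`GAPa`) forms. This order is fixed and used for all
#' state vectors, trajectory columns and CSV output.
#'
#' @return Character vector of the 14 species names, in canonical order.
#' @export
#' @examples
#' species_names()
species_names <- function() {
  c("Rac1_GDP", "Rac1_GTP", "RhoA_GDP", "RhoA_GTP",
    "iPAK", "cPAK", "pPAK", "iPAK_I",
    "GEFH1", "pGEFH1", "pGEFH1_1433", "F1433",
    "GAPi", "GAPa")
}

#' Conserved moieties and their member species
#'
#' Each protein is conserved across its bound/modified forms. Note that
#' `cPAK` (the Rac1-GTP:PAK complex) carries one copy of Rac1 and one of
#' PAK, so it appears in both moieties.
#'
#' @return Named list mapping moiety name (matching [abundances()] fields)
#'   to the member species names.
#' @export
moiety_members <- function() {
  list(
    rac1_tot   = c("Rac1_GDP", "Rac1_GTP", "cPAK"),
    rhoa_tot   = c("RhoA_GDP", "RhoA_GTP"),
    pak_tot    = c("iPAK", "cPAK", "pPAK", "iPAK_I"),
    gefh1_tot  = c("GEFH1", "pGEFH1", "pGEFH1_1433"),
    s1433_tot  = c("F1433", "pGEFH1_1433"),
    racgap_tot = c("GAPi", "GAPa")
  )
}

#' Reaction names of the network
#'
#' The 14 reactions, in the order used for the stoichiometry matrix
#' columns. `PAK_BIND` and `SEQ_BIND` are reversible mass-action binding
#' steps (their rate is the net forward flux); inhibitor binding and
#' unbinding are kept as separate irreversible columns because the free
#' inhibitor is an external forcing, not a state variable.
#'
#' @return Character vector of 14 reaction identifiers.
#' @export
reaction_names <- function() {
  c("RAC_ACT", "RAC_DEACT", "RHO_ACT", "RHO_DEACT",
    "PAK_BIND", "PAK_AUTOPH", "PAK_DEPH",
    "GEF_PHOS", "GEF_DEPH", "SEQ_BIND",
    "GAP_ACT", "GAP_DEACT", "INH_BIND", "INH_UNBIND")
}

# stoichiometry matrix: 14 species x 14 reactions
.stoichiometry <- function() {
  sp <- species_names()
  rx <- reaction_names()
  S <- matrix(0, length(sp), length(rx), dimnames = list(sp, rx))
  S["Rac1_GDP", "RAC_ACT"] <- -1; S["Rac1_GTP", "RAC_ACT"] <- 1
  S["Rac1_GTP", "RAC_DEACT"] <- -1; S["Rac1_GDP", "RAC_DEACT"] <- 1
  S["RhoA_GDP", "RHO_ACT"] <- -1; S["RhoA_GTP", "RHO_ACT"] <- 1
  S["RhoA_GTP", "RHO_DEACT"] <- -1; S["RhoA_GDP", "RHO_DEACT"] <- 1
  S["Rac1_GTP", "PAK_BIND"] <- -1; S["iPAK", "PAK_BIND"] <- -1
  S["cPAK", "PAK_BIND"] <- 1
  S["cPAK", "PAK_AUTOPH"] <- -1; S["pPAK", "PAK_AUTOPH"] <- 1
  S["Rac1_GTP", "PAK_AUTOPH"] <- 1
  S["pPAK", "PAK_DEPH"] <- -1; S["iPAK", "PAK_DEPH"] <- 1
  S["GEFH1", "GEF_PHOS"] <- -1; S["pGEFH1", "GEF_PHOS"] <- 1
  S["pGEFH1", "GEF_DEPH"] <- -1; S["GEFH1", "GEF_DEPH"] <- 1
  S["pGEFH1", "SEQ_BIND"] <- -1; S["F1433", "SEQ_BIND"] <- -1
  S["pGEFH1_1433", "SEQ_BIND"] <- 1
  S["GAPi", "GAP_ACT"] <- -1; S["GAPa", "GAP_ACT"] <- 1
  S["GAPa", "GAP_DEACT"] <- -1; S["GAPi", "GAP_DEACT"] <- 1
  S["iPAK", "INH_BIND"] <- -1; S["iPAK_I", "INH_BIND"] <- 1
  S["iPAK_I", "INH_UNBIND"] <- -1; S["iPAK", "INH_UNBIND"] <- 1
  S
}
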
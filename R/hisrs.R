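## Published per-residue DTSS reference values for histidyl-tRNA
## synthetase (HisRS), the enzyme family the catalytic-field methodology
## was demonstrated on. Shipped as package data so the barrier arithmetic
## (sums of per-residue contributions, B0 + sum(DTSS)) can be reproduced
## and used as worked examples.

#' Reference per-residue DTSS values for the HisRS reactions
#'
#' MULTISCAN DTSS contributions (kcal/mol) of the nine charged residues
#' conserved across twelve HisRS structures, for the ATP-aminoacylation
#' transition state (TS0) and the four tRNA-charging mechanism variants
#' (TS1-TS4); `dtss_crystal` holds the values for crystallographic
#' side-chain conformations scored without inter-residue interactions.
#'
#' @param pathway optional pathway filter (`"TS0"` ... `"TS4"`).
#' @return tibble with columns `residue`, `pathway`, `dtss`,
#'   `dtss_crystal`.
#' @export
hisrs_reference_dtss <- function(pathway = NULL) {
  path <- system.file("extdata", "hisrs_dtss_reference.tsv", package = "catfield")
  tab <- as_tibble(utils::read.delim(path, check.names = FALSE))
  if (!is.null(pathway)) {
    pathway <- match.arg(pathway, unique(tab$pathway))
    tab <- tab[tab$pathway == pathway, ]
  }
  tab
}

#' Reference bare barriers for the HisRS reactions
#'
#' Bare activation barriers `B0 = E_TS - E_RS` (kcal/mol) of the isolated
#' reactant models per pathway, with the published DTSS sums and
#' `B0 + sum(DTSS)` footers for comparison. Note the published TS0 and
#' TS2 footers are not the exact sums of the published per-residue
#' values; [hisrs_barrier_estimate()] always recomputes the sum.
#'
#' @return tibble with `pathway`, `reaction`, `b0`, `sum_dtss_printed`,
#'   `total_printed`.
#' @export
hisrs_reference_barriers <- function() {
  path <- system.file("extdata", "hisrs_barriers_reference.tsv", package = "catfield")
  as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Barrier estimate for a HisRS pathway from the reference table
#'
#' Convenience wrapper: [barrier_estimate()] on the reference per-residue
#' DTSS contributions of one pathway.
#'
#' @param pathway `"TS0"`, `"TS1"`, `"TS2"`, `"TS3"` or `"TS4"`.
#' @param crystal use the crystallographic-conformation DTSS values
#'   instead of the MULTISCAN ones?
#' @return a [barrier_estimate()].
#' @examples
#' hisrs_barrier_estimate("TS3")  # B0 18.95, sum(DTSS) -6.58, total 12.37
#' @export
hisrs_barrier_estimate <- function(pathway, crystal = FALSE) {
  contrib <- hisrs_reference_dtss(pathway)
  if (crystal) contrib$dtss <- contrib$dtss_crystal
  b0 <- hisrs_reference_barriers()
  b0 <- b0$b0[b0$pathway == contrib$pathway[1]]
  barrier_estimate(b0, contrib[, c("residue", "dtss", "dtss_crystal")])
}
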
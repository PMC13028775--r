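#' The five-variant statin pharmacogene panel
#'
#' Returns the variant panel the burden score is built from: the two
#' SLCO1B1 sites that define the *1/*37/*5/*15 haplotypes (c.521T>C
#' rs4149056 and c.388A>G rs2306283), the ABCG2 efflux variant c.421C>A
#' (rs2231142), and the two CYP2C9 reduced-function alleles (*2 and *3).
#' Coordinates are GRCh38. Dosages throughout the package count the listed
#' `alt` allele (the functionally relevant minor allele at each site).
#'
#' The CYP2C9*3 locus is keyed internally as `CYP2C9_star3`; its rsID is
#' configurable because published panels disagree on the identifier, and
#' genotype files are matched by rsID with a chrom:pos:ref:alt fallback.
#'
#' @param cyp2c9_star3_rsid rsID used to match the CYP2C9*3 locus in
#'   genotype inputs.
#' @return A data.frame with columns `locus`, `rsid`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @examples
#' pgx_panel()
#' @export
pgx_panel <- function(cyp2c9_star3_rsid = "rs4986893") {
  data.frame(
    locus = c("SLCO1B1_521", "SLCO1B1_388", "ABCG2_421",
              "CYP2C9_star2", "CYP2C9_star3"),
    rsid  = c("rs4149056", "rs2306283", "rs2231142",
              "rs1799853", cyp2c9_star3_rsid),
    chrom = c("12", "12", "4", "10", "10"),
    pos   = c(21331549L, 21329738L, 89052323L, 96702047L, 96540410L),
    ref   = c("T", "A", "G", "C", "A"),
    alt   = c("C", "G", "T", "T", "C"),
    stringsAsFactors = FALSE
  )
}

# canonical column order of a wide genotype table, derived from a panel
panel_rsids <- function(panel = pgx_panel()) panel$rsid

# map rsid -> locus for a given panel
panel_locus <- function(rsid, panel = pgx_panel()) {
  panel$locus[match(rsid, panel$rsid)]
}
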
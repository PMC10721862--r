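#' Atlas region labels for the 44-region bihemispheric parcellation
#'
#' The parcellation used throughout the pipeline: 44 bihemispheric
#' gray-matter regions derived from the SIGMA rat brain atlas (cerebellum
#' and olfactory bulb excluded). Labels follow the standard rodent
#' abbreviations (PL prelimbic, IL infralimbic, RS retrosplenial, DRN
#' dorsal raphe nucleus, HypR hypothalamus region, and so on).
#'
#' @return Character vector of 44 region labels, fixed order.
#' @seealso [dmn_regions()] for the default-mode-network subset.
#' @export
#' @examples
#' length(region_labels())
region_labels <- function() {
  c("BF", "FrA", "OF", "PL", "IL", "Cing1", "Cing2", "aIns", "dyIns",
    "pIns", "Sept", "PreTe", "Amyg", "BNST", "Acb", "dStr", "M1", "M2",
    "S1", "S2", "Ect", "Ent", "Peri", "ParA", "TempA", "V1", "V2",
    "Aud1", "Aud2", "RS", "HypR", "CA1", "CA2", "CA3", "DG", "Sub",
    "Th", "Hb", "VTA", "IC", "SC", "PAG", "SN", "DRN")
}

#' Default mode network region subset
#'
#' The 12-region rodent DMN: orbitofrontal, pre-/infralimbic, cingulate,
#' retrosplenial, temporal and parietal association, auditory, primary
#' visual and hippocampal CA1 regions.
#'
#' @return Character vector of 12 region labels, all members of
#'   [region_labels()].
#' @export
dmn_regions <- function() {
  c("OF", "PL", "IL", "Cing1", "Cing2", "RS", "TempA", "ParA",
    "Aud1", "Aud2", "V1", "CA1")
}

# Community assignment used by the synthetic generator's latent-factor
# model: 1 = DMN/cortical-associative, 2 = sensory-motor, 3 = subcortical.
region_communities <- function() {
  labs <- region_labels()
  comm <- integer(length(labs))
  names(comm) <- labs
  cortical <- c("OF", "PL", "IL", "Cing1", "Cing2", "RS", "TempA", "ParA",
                "CA1", "FrA", "Ect", "Ent", "Peri", "Sub", "CA2", "CA3", "DG")
  sensory <- c("M1", "M2", "S1", "S2", "V1", "V2", "Aud1", "Aud2",
               "aIns", "dyIns", "pIns", "IC", "SC")
  comm[labs %in% cortical] <- 1L
  comm[labs %in% sensory] <- 2L
  comm[comm == 0L] <- 3L
  comm
}
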
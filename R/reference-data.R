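#' Reference panel of 22 Juncus effusus populations
#'
#' Published metadata for the central-German population panel that
#' motivates this package: population acronyms and site names, decimal
#' coordinates, the number of seed families and total offspring raised per
#' nitrogen treatment (T0 / T70 / T150; `NA` where a population could not
#' be raised in a treatment), the three-cluster admixture proportions, and
#' per-population expected heterozygosity at 16 microsatellite loci.  The
#' SF site hosts two co-occurring lineages and is split into two
#' populations (SF1, SF2) sharing one set of site coordinates.
#'
#' @return data frame with one row per population and columns
#'   `population_id`, `site`, `latitude`, `longitude`,
#'   `fam_T0`, `ind_T0`, `fam_T70`, `ind_T70`, `fam_T150`, `ind_T150`,
#'   `Q_Eff1`, `Q_Eff2`, `Q_Eff3`, `He`.
#' @examples
#' ref <- reference_populations()
#' sum(ref$fam_T0)        # 111 maternal seed families at T0
#' @export
reference_populations <- function() {
  d <- data.frame(
    population_id = c("BB", "DB", "EB", "ES", "ET", "GF", "GR", "JAM",
                      "JEM", "MS", "OH", "PWA", "PWI", "RB", "RO", "SC",
                      "SF1", "SF2", "WD", "WL", "ZM", "ZR"),
    site = c("Brandberge", "Druebeck", "Ettersberg", "Esperstedt",
             "Elendstal", "Graefenroda", "Gross Rosenburg",
             "Jaevenitzer Moor", "Jemmeritzer Moor", "Massanei", "Oberhof",
             "Pressel (forest)", "Pressel (meadow)", "Rappbodetalsperre",
             "Roesa", "Schierke", "Siptenfelde", "Siptenfelde",
             "Wermsdorf", "Woerlitz", "Zella Mehlis", "Ziegelroda"),
    latitude = c(51.5117, 51.8531, 51.0320, 51.4192, 51.7475, 50.7438,
                 51.9124, 52.5029, 52.6365, 51.0587, 50.7150, 51.5739,
                 51.5655, 51.7407, 51.6114, 51.7732, 51.6605, 51.6605,
                 51.3017, 51.8336, 50.6722, 51.3455),
    longitude = c(11.9263, 10.7057, 11.2638, 11.6676, 10.6810, 10.7914,
                  11.9178, 11.4720, 11.2620, 13.0458, 10.7769, 12.7381,
                  12.7322, 10.8875, 12.4493, 10.6388, 11.0484, 11.0484,
                  12.9030, 12.4348, 10.6739, 11.4931),
    fam_T0  = c(4, 5, 5, 6, 6, 6, 5, 5, 6, 5, 5, 5, 5, 5, 5, 6, 4, 5, 4,
                5, 5, 4),
    ind_T0  = c(16, 14, 20, 24, 24, 24, 14, 19, 24, 20, 17, 20, 20, 16,
                20, 22, 16, 20, 15, 20, 20, 14),
    fam_T70 = c(NA, NA, 4, 4, 4, 4, NA, 4, 4, NA, NA, 4, 4, NA, 4, NA,
                NA, NA, NA, 4, 4, 4),
    ind_T70 = c(NA, NA, 11, 12, 12, 12, NA, 12, 12, NA, NA, 12, 12, NA,
                12, NA, NA, NA, NA, 12, 12, 12),
    fam_T150 = c(4, NA, 4, 4, 4, 4, NA, 4, 4, 4, 4, 4, 4, NA, 4, NA, NA,
                 NA, 4, 4, 4, 4),
    ind_T150 = c(12, NA, 12, 12, 12, 12, NA, 12, 11, 12, 12, 12, 12, NA,
                 12, NA, NA, NA, 12, 12, 12, 12),
    Q_Eff1 = c(0.975, 0.116, 0.001, 0.001, 0.001, 0.997, 0.002, 0.986,
               0.989, 0.005, 0.993, 0.924, 0.021, 0.002, 0.003, 0.002,
               0.996, 0.002, 0.001, 0.024, 0.997, 0.002),
    Q_Eff2 = c(0.023, 0.877, 0.996, 0.998, 0.002, 0.002, 0.994, 0.003,
               0.009, 0.989, 0.005, 0.022, 0.941, 0.002, 0.981, 0.002,
               0.002, 0.997, 0.988, 0.967, 0.001, 0.996),
    Q_Eff3 = c(0.003, 0.007, 0.003, 0.001, 0.997, 0.001, 0.004, 0.011,
               0.002, 0.006, 0.002, 0.055, 0.038, 0.996, 0.017, 0.996,
               0.002, 0.001, 0.011, 0.010, 0.002, 0.002),
    He = c(0.359, 0.356, 0.181, 0.042, 0.133, 0.256, 0.144, 0.275, 0.302,
           0.075, 0.197, 0.341, 0.194, 0.027, 0.203, 0.250, 0.188, 0.050,
           0.144, 0.181, 0.000, 0.198),
    stringsAsFactors = FALSE)
  d
}

#' Deterministic reference-shaped test fixture
#'
#' Bundles everything the pipeline consumes, built from the reference
#' panel metadata plus seeded simulation: the population table (ids,
#' coordinates, Q-matrix, seed-family counts, gene diversities), island-
#' model genotypes at the panel's differentiation level, a nested trait
#' table that respects the panel's population x treatment unbalance and
#' family counts, and a correlated soil table.  Genotypes, traits and soil
#' are synthetic stand-ins with the panel's statistical structure, not
#' observed data.
#'
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param reference use the 22-population reference metadata (currently
#'   the only option).
#' @return list with `populations`, `q_matrix`, `genotypes`, `traits`,
#'   `soil`, `design`.
#' @export
make_fixture <- function(seed = 1, reference = TRUE) {
  stopifnot(isTRUE(reference))
  ref <- reference_populations()
  n_pop <- nrow(ref)
  q <- ref[c("population_id", "Q_Eff1", "Q_Eff2", "Q_Eff3")]
  names(q) <- c("population_id", "Eff1", "Eff2", "Eff3")
  assign <- assign_lineages(q[-1], population = q$population_id)
  lineage <- attr(assign, "population_assignment")$lineage
  mask <- cbind(!is.na(ref$fam_T0), !is.na(ref$fam_T70),
                !is.na(ref$fam_T150))
  ord <- order(factor(lineage, levels = c("Eff1", "Eff2", "Eff3")))
  design <- sim_design(n_pop = n_pop,
                       lineage_sizes = as.vector(table(lineage)[
                         c("Eff1", "Eff2", "Eff3")]),
                       treatment_mask = mask[ord, , drop = FALSE],
                       seed = seed)
  gt <- simulate_genotypes(design, seed = seed)
  traits <- simulate_phenotypes(design, seed = seed + 1)
  soil_sim <- simulate_soil(design, seed = seed + 2)
  # re-label simulated populations with the panel ids (lineage-ordered)
  relabel <- stats::setNames(ref$population_id[ord], pop_ids(design))
  gt$population_id <- unname(relabel[gt$population_id])
  gt$individual_id <- paste0(gt$population_id, "_",
                             sub("^P\\d+_", "", gt$individual_id))
  rownames(gt$alleles) <- gt$individual_id
  old_pop <- traits$population_id
  traits$population_id <- unname(relabel[old_pop])
  traits$seed_family_id <- paste0(traits$population_id,
                                  sub("^P\\d+", "", traits$seed_family_id))
  soil <- soil_sim$soil
  soil$population_id <- unname(relabel[soil$population_id])
  pops <- ref
  pops$lineage <- lineage
  list(populations = pops, q_matrix = q, genotypes = gt, traits = traits,
       soil = soil, design = design)
}
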
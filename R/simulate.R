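#' Simulation design for the synthetic common-garden study
#'
#' Bundles every parameter of the synthetic-data generators.  Defaults
#' mirror the reference study design: 22 populations in three lineages
#' (8/11/3), 4-6 seed families per population, three nitrogen treatments
#' with an unbalanced population x treatment mask (all populations at T0,
#' 12 at T70, 16 at T150), 4 offspring per family and treatment, strong
#' neutral differentiation (target F_ST 0.66) under high selfing, 16
#' microsatellite-like loci, and a nested phenotypic variance structure.
#'
#' @param n_pop number of populations.
#' @param lineage_sizes integer partition of `n_pop` into lineages.
#' @param families_range inclusive range the per-population seed-family
#'   count is drawn from.
#' @param offspring_per_family offspring per family per treatment cell.
#' @param treatments treatment labels.
#' @param treatment_mask logical `n_pop x length(treatments)` matrix saying
#'   which populations appear in which treatment; default keeps all
#'   populations in the first treatment, the first 12 in the second and the
#'   first 16 in the third (reference-like unbalance).
#' @param n_genotyped individuals genotyped per population.
#' @param n_loci,n_alleles loci and (maximum) alleles per locus.
#' @param f_st target neutral differentiation of the island model.
#' @param selfing selfing rate; enters genotypes via the equilibrium
#'   inbreeding coefficient `F_IS = s / (2 - s)`.
#' @param grand_mean,treatment_effects fixed part of the phenotype model
#'   (one effect per treatment, first usually 0).
#' @param v_ap,v_wp,v_fxt,v_res among-population, seed-family,
#'   family x treatment, and residual variances of the phenotype model.
#' @param pc1_slope clinal effect of the latent soil gradient on the
#'   population trait mean (0 = no cline).
#' @param seed integer RNG seed recorded with the design.
#' @return a list of class `sim_design`.
#' @export
sim_design <- function(n_pop = 22, lineage_sizes = c(8, 11, 3),
                       families_range = c(4, 6), offspring_per_family = 4,
                       treatments = c("T0", "T70", "T150"),
                       treatment_mask = NULL,
                       n_genotyped = 10, n_loci = 16, n_alleles = 5,
                       f_st = 0.66, selfing = 0.95,
                       grand_mean = 10, treatment_effects = c(0, 1, 2),
                       v_ap = 1, v_wp = 1, v_fxt = 0.25, v_res = 1,
                       pc1_slope = 0, seed = 1) {
  if (sum(lineage_sizes) != n_pop) {
    lineage_sizes <- if (length(lineage_sizes) == 1) n_pop else
      stop("lineage_sizes must sum to n_pop")
  }
  if (is.null(treatment_mask)) {
    treatment_mask <- matrix(TRUE, n_pop, length(treatments))
    if (length(treatments) >= 2)
      treatment_mask[, 2] <- seq_len(n_pop) <= min(12, n_pop)
    if (length(treatments) >= 3)
      treatment_mask[, 3] <- seq_len(n_pop) <= min(16, n_pop)
  }
  stopifnot(nrow(treatment_mask) == n_pop,
            ncol(treatment_mask) == length(treatments),
            length(treatment_effects) == length(treatments),
            selfing >= 0, selfing <= 1, f_st >= 0, f_st < 1,
            v_ap >= 0, v_wp >= 0, v_fxt >= 0, v_res >= 0)
  structure(list(n_pop = n_pop, lineage_sizes = lineage_sizes,
                 families_range = families_range,
                 offspring_per_family = offspring_per_family,
                 treatments = treatments, treatment_mask = treatment_mask,
                 n_genotyped = n_genotyped, n_loci = n_loci,
                 n_alleles = n_alleles, f_st = f_st, selfing = selfing,
                 grand_mean = grand_mean,
                 treatment_effects = treatment_effects,
                 v_ap = v_ap, v_wp = v_wp, v_fxt = v_fxt, v_res = v_res,
                 pc1_slope = pc1_slope, seed = seed),
            class = "sim_design")
}

pop_ids <- function(design)
  sprintf("P%02d", seq_len(design$n_pop))

lineage_of <- function(design)
  rep(paste0("Eff", seq_along(design$lineage_sizes)), design$lineage_sizes)

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate island-model genotypes under partial selfing
#'
#' Population allele frequencies follow the Dirichlet island model: for
#' each locus, base frequencies `p` are drawn once, and each population's
#' frequencies come from `Dirichlet(p * (1 - F_ST) / F_ST)`, whose
#' among-population variance `p * (1 - p) * F_ST` matches the target
#' differentiation in expectation.  Genotypes are drawn with the
#' equilibrium inbreeding coefficient `F_IS = s / (2 - s)`: with
#' probability `F_IS` an individual is autozygous (one frequency draw),
#' otherwise its two alleles are independent.  `F_ST = 0` degenerates to
#' identical frequencies everywhere.
#'
#' @param design a [sim_design()].
#' @param seed overrides the design seed.
#' @return a [genotype_table()] with `design$n_genotyped` individuals per
#'   population; parameters and seed are attached as attribute
#'   `"provenance"`.
#' @export
simulate_genotypes <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  ids <- pop_ids(design)
  n_i <- design$n_genotyped
  n <- design$n_pop * n_i
  fis <- design$selfing / (2 - design$selfing)
  al <- matrix(NA_integer_, n, 2L * design$n_loci)
  pop <- rep(ids, each = n_i)
  for (l in seq_len(design$n_loci)) {
    base <- rdirichlet1(rep(1, design$n_alleles))
    codes <- 100L + 2L * seq_len(design$n_alleles)   # fragment-length style
    for (pi in seq_len(design$n_pop)) {
      p <- if (design$f_st == 0) base else
        rdirichlet1(base * (1 - design$f_st) / design$f_st)
      rows <- which(pop == ids[pi])
      auto <- stats::runif(n_i) < fis
      a1 <- sample(codes, n_i, replace = TRUE, prob = p)
      a2 <- ifelse(auto, a1, sample(codes, n_i, replace = TRUE, prob = p))
      al[rows, 2L * l - 1L] <- a1
      al[rows, 2L * l] <- a2
    }
  }
  gt <- genotype_table(al, paste(pop, rep(seq_len(n_i), design$n_pop),
                                 sep = "_"),
                       pop, paste0("loc", seq_len(design$n_loci)))
  attr(gt, "provenance") <- list(generator = "simulate_genotypes",
                                 seed = seed, f_st = design$f_st,
                                 selfing = design$selfing)
  gt
}

#' Simulate nested common-garden phenotypes
#'
#' `y = mu + treatment effect + pop effect + family effect +
#' family x treatment effect + residual`, with independent Gaussian
#' effects at the variances in the design, respecting the population x
#' treatment unbalance mask.  With `neutral = TRUE` the among-population
#' variance is set to the neutral expectation
#' `F_ST * 2 * V_WP / (1 - F_ST)` implied by the design's (or the given)
#' F_ST.  An optional clinal term adds `pc1_slope * gradient` to the
#' population means (`gradient` standard-normal per population unless
#' supplied).
#'
#' @param design a [sim_design()].
#' @param neutral generate under the neutral null relation.
#' @param f_st differentiation used for the neutral relation (defaults to
#'   the design target).
#' @param gradient optional numeric vector (length `n_pop`) of an
#'   environmental axis driving the cline.
#' @param seed overrides the design seed.
#' @return data frame with `individual_id`, `population_id`,
#'   `seed_family_id`, `treatment`, `lineage`, and the response `y`;
#'   attribute `"truth"` records the generating parameters and realized
#'   population effects.
#' @export
simulate_phenotypes <- function(design, neutral = FALSE, f_st = design$f_st,
                                gradient = NULL, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  ids <- pop_ids(design)
  lin <- lineage_of(design)
  v_ap <- if (neutral) f_st * 2 * design$v_wp / (1 - f_st) else design$v_ap
  if (is.null(gradient)) gradient <- stats::rnorm(design$n_pop)
  nf <- if (diff(design$families_range) == 0) rep(design$families_range[1],
                                                  design$n_pop) else
    sample(seq(design$families_range[1], design$families_range[2]),
           design$n_pop, replace = TRUE)
  pop_eff <- stats::rnorm(design$n_pop, 0, sqrt(v_ap)) +
    design$pc1_slope * gradient
  rows <- list()
  for (pi in seq_len(design$n_pop)) {
    fams <- sprintf("%s_F%d", ids[pi], seq_len(nf[pi]))
    fam_eff <- stats::rnorm(nf[pi], 0, sqrt(design$v_wp))
    for (ti in seq_along(design$treatments)) {
      if (!design$treatment_mask[pi, ti]) next
      fxt <- stats::rnorm(nf[pi], 0, sqrt(design$v_fxt))
      for (fi in seq_len(nf[pi])) {
        k <- design$offspring_per_family
        y <- design$grand_mean + design$treatment_effects[ti] +
          pop_eff[pi] + fam_eff[fi] + fxt[fi] +
          stats::rnorm(k, 0, sqrt(design$v_res))
        rows[[length(rows) + 1L]] <- data.frame(
          population_id = ids[pi], seed_family_id = fams[fi],
          treatment = design$treatments[ti], lineage = lin[pi], y = y,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$individual_id <- sprintf("ind%05d", seq_len(nrow(out)))
  out$treatment <- factor(out$treatment, levels = design$treatments)
  out <- out[c("individual_id", "population_id", "seed_family_id",
               "treatment", "lineage", "y")]
  attr(out, "truth") <- list(v_ap = v_ap, v_wp = design$v_wp,
                             v_fxt = design$v_fxt, v_res = design$v_res,
                             pop_effects = stats::setNames(pop_eff, ids),
                             gradient = stats::setNames(gradient, ids),
                             neutral = neutral, f_st = f_st, seed = seed)
  out
}

#' Simulate correlated soil variables and population coordinates
#'
#' Eleven soil variables (texture fractions, coarse fragments, pH, organic
#' carbon, carbonate, P, N, K, cation exchange capacity) are driven by a
#' shared latent gradient plus independent noise, giving a configurable
#' leading principal component; coordinates fall in a regional
#' (central-German-scale) bounding box.
#'
#' @param design a [sim_design()].
#' @param gradient_weight strength of the shared gradient (0 = independent
#'   variables, flat eigenvalue spectrum).
#' @param seed overrides the design seed.
#' @return list with `soil` (data frame, one row per population),
#'   `meta` (`population_id`, `latitude`, `longitude`), and the latent
#'   `gradient` vector.
#' @export
simulate_soil <- function(design, gradient_weight = 1, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  ids <- pop_ids(design)
  np <- design$n_pop
  g <- stats::rnorm(np)
  vars <- c("clay", "silt", "sand", "coarse_fragments", "pH",
            "organic_carbon", "carbonate", "P", "N", "K", "CEC")
  load <- c(0.8, 0.5, -0.9, -0.3, 0.7, 0.6, 0.4, 0.5, 0.6, 0.5, 0.9)
  soil <- data.frame(population_id = ids, stringsAsFactors = FALSE)
  for (j in seq_along(vars))
    soil[[vars[j]]] <- gradient_weight * load[j] * g + stats::rnorm(np)
  meta <- data.frame(population_id = ids,
                     latitude = stats::runif(np, 50.6, 52.7),
                     longitude = stats::runif(np, 10.6, 13.1),
                     stringsAsFactors = FALSE)
  list(soil = soil, meta = meta, gradient = stats::setNames(g, ids))
}
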
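#' Run the full adaptive-divergence pipeline
#'
#' Orchestrates the analysis stages over one dataset bundle: molecular
#' diversity and differentiation, posterior Q_ST per trait, the
#' Q_ST - neutral-Q_ST difference tests, soil PCA with the
#' He-environment correlation, and MMRR of pairwise trait differentiation
#' on environmental and molecular distance.  Writes `he.csv`, `fst.json`,
#' `qst.csv`, `qstfst_tests.csv`, `pca_scores.csv`, `mmrr.csv` and a
#' `run.log` (package version, config, seeds) to the output directory.
#'
#' @param config either a path to a YAML file or an equivalent named list
#'   with entries: `genotypes` (path) and `genotype_format`, or a
#'   `genotype_table` under `data$genotypes`; `traits` (path to CSV with
#'   the trait table) or `data$traits`; optional `soil` (path/data frame)
#'   and `q_matrix`; `traits_to_test` (character); `modes`;
#'   numeric settings `lineage_threshold` (0.7), `n_sim` (1000), `n_perm`
#'   (9999), `soil_radius_km` (15), chain settings `n_iter`, `burn_in`,
#'   `thin`, and `seed`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a named list of the result objects.
#' @export
run_pipeline <- function(config, out_dir = "qstkit-run") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(lineage_threshold = 0.7, n_sim = 1000, n_perm = 9999,
                   soil_radius_km = 15, n_iter = 13000, burn_in = 3000,
                   thin = 10, seed = 1, modes = "across",
                   genotype_format = "genalex")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  num <- c("lineage_threshold", "n_sim", "n_perm", "soil_radius_km",
           "n_iter", "burn_in", "thin")
  bad <- num[vapply(num, function(nm) cfg[[nm]] <= 0, logical(1))]
  if (length(bad)) stop("non-positive setting(s): ",
                        paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gt <- cfg[["data"]][["genotypes"]]
  if (is.null(gt)) gt <- read_genotypes(cfg[["genotypes"]],
                                        cfg[["genotype_format"]])
  traits <- cfg[["data"]][["traits"]]
  if (is.null(traits)) traits <- utils::read.csv(cfg[["traits"]],
                                                 stringsAsFactors = FALSE)
  orphans <- setdiff(unique(traits$population_id), populations(gt))
  if (length(orphans))
    stop("trait populations absent from the genotype table: ",
         paste(orphans, collapse = ", "))
  traits_to_test <- cfg[["traits_to_test"]] %||%
    setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
            c("latitude", "longitude"))

  results <- list()
  div <- expected_heterozygosity(gt)
  utils::write.csv(div$he, file.path(out_dir, "he.csv"), row.names = FALSE)
  results$he <- div

  global <- fst(gt, scope = "global")
  fst_out <- list(global = global$value, per_locus_sd = global$sd,
                  n_loci = global$n_loci)
  qm <- cfg[["data"]][["q_matrix"]] %||% cfg[["q_matrix"]]
  lineage_tab <- NULL
  if (!is.null(qm)) {
    if (is.character(qm)) qm <- utils::read.csv(qm, stringsAsFactors = FALSE)
    asg <- assign_lineages(qm[setdiff(names(qm), "population_id")],
                           threshold = cfg[["lineage_threshold"]],
                           population = qm$population_id)
    lineage_tab <- attr(asg, "population_assignment")[
      c("population_id", "lineage")]
    ind_lineage <- lineage_tab$lineage[match(gt$population_id,
                                             lineage_tab$population_id)]
    keep <- !is.na(ind_lineage) & ind_lineage != "admixed"
    if (length(unique(ind_lineage[keep])) >= 2)
      fst_out$between_lineages_pooled <-
        fst(subset_populations(gt, unique(gt$population_id[keep])),
            group = ind_lineage[keep], scope = "lineages")$value
    for (ln in setdiff(unique(stats::na.omit(lineage_tab$lineage)),
                       "admixed")) {
      pops_ln <- lineage_tab$population_id[lineage_tab$lineage == ln]
      if (length(pops_ln) >= 2)
        fst_out[[paste0("within_", ln)]] <-
          tryCatch(fst(subset_populations(gt, pops_ln), scope = ln)$value,
                   error = function(e) NA_real_)
    }
    if (!"lineage" %in% names(traits))
      traits$lineage <- lineage_tab$lineage[
        match(traits$population_id, lineage_tab$population_id)]
  }
  jsonlite::write_json(fst_out, file.path(out_dir, "fst.json"),
                       auto_unbox = TRUE, digits = NA)
  results$fst <- fst_out

  tests <- run_qstfst_suite(traits, gt, traits_to_test = traits_to_test,
                            modes = cfg[["modes"]], n_sim = cfg[["n_sim"]],
                            seed = cfg[["seed"]], n_iter = cfg[["n_iter"]],
                            burn_in = cfg[["burn_in"]], thin = cfg[["thin"]])
  utils::write.csv(tests[c("trait", "mode", "subset", "qst_median",
                           "f_st", "n_pop")],
                   file.path(out_dir, "qst.csv"), row.names = FALSE)
  utils::write.csv(tests, file.path(out_dir, "qstfst_tests.csv"),
                   row.names = FALSE)
  results$qstfst <- tests

  soil <- cfg[["data"]][["soil"]] %||% cfg[["soil"]]
  if (!is.null(soil)) {
    if (is.character(soil)) soil <- utils::read.csv(soil,
                                                    stringsAsFactors = FALSE)
    pca <- soil_pca(soil)
    sc <- data.frame(population_id = rownames(pca$scores), pca$scores,
                     row.names = NULL)
    utils::write.csv(sc, file.path(out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    results$soil_pca <- pca
    he_v <- div$he$He[match(rownames(pca$scores), div$he$population_id)]
    results$he_pc1 <- tryCatch(
      he_env_correlation(he_v, pca$scores[, 1]), error = function(e) NULL)
    # MMRR of pairwise trait differentiation on env + molecular distance
    env_d <- environmental_distance(soil)
    fst_m <- pairwise_fst(gt)
    common <- Reduce(intersect, list(rownames(env_d), rownames(fst_m),
                                     unique(traits$population_id)))
    mm_rows <- list()
    if (length(common) >= 4) {
      for (tr in traits_to_test) {
        qm_tr <- tryCatch(pairwise_qst(traits, tr), error = function(e) NULL)
        if (is.null(qm_tr)) next
        use <- intersect(common, rownames(qm_tr))
        if (length(use) < 4) next
        res <- mmrr(qm_tr[use, use],
                    list(env = env_d[use, use], fst = fst_m[use, use]),
                    n_perm = cfg[["n_perm"]], seed = cfg[["seed"]])
        mm_rows[[tr]] <- data.frame(trait = tr, res$coefficients,
                                    r_squared = res$r_squared,
                                    stringsAsFactors = FALSE)
      }
    }
    if (length(mm_rows)) {
      mm <- do.call(rbind, mm_rows)
      utils::write.csv(mm, file.path(out_dir, "mmrr.csv"),
                       row.names = FALSE)
      results$mmrr <- mm
    }
  }

  log_lines <- c(
    paste0("qstkit ", as.character(utils::packageVersion("qstkit"))),
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", cfg[["seed"]]),
    paste0("config sha: ", substr(digest_config(cfg), 1, 16)),
    paste0("settings: n_sim=", cfg[["n_sim"]], " n_perm=", cfg[["n_perm"]],
           " chain=", cfg[["n_iter"]], "/", cfg[["burn_in"]], "/",
           cfg[["thin"]],
           " lineage_threshold=", cfg[["lineage_threshold"]]))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(results)
}

# stable hash of the numeric/character config entries (no external deps)
digest_config <- function(cfg) {
  flat <- unlist(cfg[vapply(cfg, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))])
  txt <- paste(names(flat), flat, sep = "=", collapse = ";")
  sprintf("%08x%08x",
          sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            .Machine$integer.max,
          nchar(txt))
}
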
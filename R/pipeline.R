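#' Build a run configuration
#'
#' Collects every input path (or simulation preset), analysis parameter
#' and seed of a full analysis run.  All seeds are explicit after
#' resolution; the resolved configuration is serialised alongside the
#' outputs so a run can be reproduced byte-for-byte.
#'
#' @param counts,metadata,taxonomy input TSV paths (`taxonomy` optional),
#'   or `NULL` when simulating.
#' @param simulate simulation preset name (`"study_mimic"`) or a list
#'   `list(meta = , design = )`; ignored when `counts` is given.
#' @param outdir output directory.
#' @param depth rarefaction depth; `NULL` = smallest sample total.
#' @param group_var metadata column defining the two environments.
#' @param term_formula PERMANOVA design (Type-I order as written).
#' @param n_perm_niche,n_perm_indval,n_perm_permanova,n_perm_varpart,n_null
#'   permutation/null-ensemble sizes (defaults follow the study
#'   protocol: 1000 niche permutations, 999 IndVal and PERMANOVA
#'   permutations, 9999 varpart permutations, 1000 null assemblies).
#' @param alpha niche-classification significance level.
#' @param indval_min,p_max indicator-selection gates.
#' @param indval_rank taxonomy rank for the indicator analysis, or
#'   `NULL` to run at the taxon (ASV) level.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts = NULL, metadata = NULL, taxonomy = NULL,
                       simulate = "study_mimic", outdir = "sandassembly_run",
                       depth = NULL, group_var = "environment",
                       term_formula = ~ environment * site,
                       n_perm_niche = 1000, n_perm_indval = 999,
                       n_perm_permanova = 999, n_perm_varpart = 9999,
                       n_null = 1000, alpha = 0.05,
                       indval_min = 0.75, p_max = 0.01,
                       indval_rank = NULL, seed = 1) {
  cfg <- list(counts = counts, metadata = metadata, taxonomy = taxonomy,
              simulate = simulate, outdir = outdir, depth = depth,
              group_var = group_var,
              term_formula = paste(deparse(term_formula), collapse = ""),
              n_perm_niche = n_perm_niche, n_perm_indval = n_perm_indval,
              n_perm_permanova = n_perm_permanova,
              n_perm_varpart = n_perm_varpart, n_null = n_null,
              alpha = alpha, indval_min = indval_min, p_max = p_max,
              indval_rank = indval_rank, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @param seed optional master-seed override.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$term_formula)) y$term_formula <- stats::as.formula(y$term_formula)
  if (!is.null(seed)) y$seed <- seed
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, log_con, expr) {
  msg <- sprintf("[stage %s] start", name)
  message(msg); writeLines(c(paste(format(Sys.time()), msg)), log_con)
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  msg <- sprintf("[stage %s] done", name)
  message(msg); writeLines(c(paste(format(Sys.time()), msg)), log_con)
  res
}

#' Run the full community-assembly analysis
#'
#' One-command orchestration of the whole analysis graph on supplied or
#' simulated data: rarefaction, generalist/specialist classification,
#' indicator analysis, PERMANOVA and ANOSIM on the whole community and
#' the generalist/specialist strata, VIF screening, PCNM spatial
#' eigenvectors, forward selection, db-RDA variation partitioning per
#' stratum, beta-null deviations per stratum and environment, per-
#' environment neutral-model fits, and the cross-partition of neutral
#' prediction by niche class.  Strata subset the taxon columns of the
#' one rarefied table without re-rarefying.  Every intermediate table is
#' written as TSV, the machine-readable report as JSON, and a log with
#' package version and all seeds; the report itself contains no
#' timestamps, so identical configurations give byte-identical reports.
#'
#' @param config a `run_config`.
#' @return the report, invisibly; written to
#'   `file.path(config$outdir, "report.json")`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  writeLines(sprintf("sandassembly %s | master seed %d",
                     as.character(utils::packageVersion("sandassembly")),
                     config$seed), log_con)
  cfg_ser <- config; class(cfg_ser) <- NULL
  if (is.list(cfg_ser$simulate)) {
    des <- cfg_ser$simulate$design
    class(des) <- NULL
    cfg_ser$simulate <- list(custom = TRUE,
                             n_taxa = length(cfg_ser$simulate$meta$rel_abund),
                             design = des)
  }
  jsonlite::write_json(cfg_ser, file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  report <- list(package_version =
                   as.character(utils::packageVersion("sandassembly")),
                 seed = config$seed)

  ## stage 1: inputs
  inp <- run_stage("input", log_con, {
    if (!is.null(config$counts)) {
      table <- read_community_table(config$counts, quiet = TRUE)
      metadata <- align_metadata(table, read_sample_metadata(config$metadata))
      truth <- NULL
    } else if (identical(config$simulate, "study_mimic")) {
      sim <- study_mimic_simulation(seed = derive_seed(config$seed, 1))
      table <- sim$table; metadata <- sim$metadata; truth <- sim$truth
      write_simulation(sim, file.path(config$outdir, "simulation"))
    } else if (is.list(config$simulate)) {
      sim <- simulate_community(config$simulate$meta, config$simulate$design)
      table <- sim$table; metadata <- sim$metadata; truth <- sim$truth
      write_simulation(sim, file.path(config$outdir, "simulation"))
    } else stop("no input counts and no recognised simulation preset")
    list(table = table, metadata = metadata, truth = truth)
  })
  rar <- run_stage("rarefy", log_con, {
    depth <- config$depth %||% min(rowSums(inp$table))
    rarefy(inp$table, depth = depth, seed = derive_seed(config$seed, 2),
           quiet = TRUE)
  })
  write_community_table(rar, file.path(config$outdir, "rarefied_counts.tsv"))
  meta_df <- inp$metadata
  groups <- factor(meta_df[[config$group_var]])
  report$input <- list(n_samples = nrow(rar), n_taxa = ncol(rar),
                       depth = unname(min(rowSums(rar))),
                       groups = as.list(table(groups)))

  ## stage 2: niche classification
  cls <- run_stage("niche", log_con,
    classify_generalists_specialists(rar, n_perm = config$n_perm_niche,
                                     alpha = config$alpha,
                                     seed = derive_seed(config$seed, 3)))
  write_niche_classification(cls, file.path(config$outdir, "niche.tsv"))
  strata <- list(
    whole = rar,
    generalists = rar[, cls$label == "generalist", drop = FALSE],
    specialists = rar[, cls$label == "specialist", drop = FALSE])
  # a stratum is only analysable if every sample retains reads in it
  usable <- vapply(strata, function(tab)
    ncol(tab) >= 5 && all(rowSums(tab) > 0), TRUE)
  if (!all(usable))
    message("strata skipped (too few taxa or empty samples): ",
            paste(names(strata)[!usable], collapse = ", "))
  strata <- strata[usable]
  rel_total <- colSums(rar) / sum(rar)
  report$niche <- list(
    n_generalist = sum(cls$label == "generalist"),
    n_specialist = sum(cls$label == "specialist"),
    n_non_significant = sum(cls$label == "non_significant"),
    generalist_seq_fraction =
      sum(rel_total[cls$label == "generalist"]),
    specialist_seq_fraction =
      sum(rel_total[cls$label == "specialist"]),
    n_perm = config$n_perm_niche, alpha = config$alpha)

  ## stage 3: indicator taxa
  iv <- run_stage("indval", log_con, {
    tab_iv <- rar
    if (!is.null(config$indval_rank) && !is.null(config$taxonomy)) {
      tax <- read_taxonomy_table(config$taxonomy)
      tab_iv <- aggregate_by_rank(rar, tax, config$indval_rank,
                                  missing = "pool")
    }
    indval_analysis(tab_iv, groups, n_perm = config$n_perm_indval,
                    seed = derive_seed(config$seed, 4), exact = FALSE,
                    indval_min = config$indval_min, p_max = config$p_max)
  })
  write_tsv(iv, file.path(config$outdir, "indval.tsv"))
  report$indval <- list(
    n_tested = nrow(iv), n_selected = sum(iv$selected),
    selected_by_group = as.list(table(iv$group[iv$selected])),
    gates = list(indval_min = config$indval_min, p_max = config$p_max))

  ## stage 4: PERMANOVA / ANOSIM per stratum
  mv <- run_stage("multivariate_tests", log_con, {
    lapply(strata, function(tab) {
      dm <- bray_curtis(tab)
      pv <- permanova(dm, meta_df,
                      stats::as.formula(config$term_formula),
                      n_perm = config$n_perm_permanova,
                      seed = derive_seed(config$seed, 5))
      an <- anosim_test(dm, groups, n_perm = config$n_perm_permanova,
                        seed = derive_seed(config$seed, 6))
      list(permanova = pv, anosim = an)
    })
  })
  report$multivariate_tests <- lapply(mv, function(z) list(
    permanova = lapply(seq_len(nrow(z$permanova)), function(i)
      as.list(z$permanova[i, ])),
    anosim = list(R = z$anosim$statistic, p = z$anosim$p)))
  for (s in names(mv))
    write_tsv(mv[[s]]$permanova,
              file.path(config$outdir, paste0("permanova_", s, ".tsv")))

  ## stage 5: environmental and spatial predictors
  envsel <- run_stage("environment_selection", log_con, {
    env_cols <- setdiff(names(meta_df),
                        c("sample_id", "environment", "site", "x", "y"))
    env <- meta_df[, env_cols, drop = FALSE]
    vf <- if (ncol(env) >= 2) vif_filter(env) else
      list(retained = names(env), vif = NULL,
           dropped = data.frame(variable = character(0), vif = numeric(0)))
    pc <- pcnm_vectors(meta_df[, c("x", "y")])
    dmw <- bray_curtis(strata$whole)
    fwd_env <- forward_select(dmw, env[, vf$retained, drop = FALSE],
                              seed = derive_seed(config$seed, 7))
    fwd_spat <- forward_select(dmw, as.data.frame(pc),
                               seed = derive_seed(config$seed, 8))
    list(vif = vf, pcnm = pc, fwd_env = fwd_env, fwd_spat = fwd_spat,
         env = env)
  })
  report$environment_selection <- list(
    vif_retained = as.list(envsel$vif$retained),
    vif_dropped = as.list(envsel$vif$dropped$variable),
    n_pcnm = ncol(envsel$pcnm),
    forward_selected_env = as.list(envsel$fwd_env$selected),
    forward_selected_spat = as.list(envsel$fwd_spat$selected))

  ## stage 6: variation partitioning per stratum
  vps <- run_stage("variation_partitioning", log_con, {
    env_use <- envsel$env[, envsel$vif$retained, drop = FALSE]
    spat_use <- as.data.frame(envsel$pcnm)
    lapply(strata, function(tab)
      dbrda_varpart(bray_curtis(tab), env_use, spat_use,
                    n_perm = config$n_perm_varpart,
                    seed = derive_seed(config$seed, 9)))
  })
  report$variation_partitioning <- lapply(vps, function(v)
    list(adjR2 = as.list(v$adjR2), p = as.list(v$p),
         sqrt_dist = v$sqrt_dist))

  ## stage 7: beta-null deviations per stratum x environment
  bnull <- run_stage("beta_null", log_con, {
    res <- list()
    for (s in names(strata)) {
      for (g in levels(groups)) {
        sub <- strata[[s]][groups == g, , drop = FALSE]
        sub <- sub[, colSums(sub) > 0, drop = FALSE]
        bn <- suppressWarnings(
          beta_null_deviation(community_table(sub, quiet = TRUE),
                              n_null = config$n_null,
                              seed = derive_seed(config$seed,
                                                 10 + length(res))))
        res[[paste(s, g, sep = ".")]] <- bn
      }
    }
    res
  })
  for (nm in names(bnull))
    write_tsv(bnull[[nm]]$pairs,
              file.path(config$outdir, paste0("beta_null_", nm, ".tsv")))
  report$beta_null <- lapply(bnull, function(b) list(
    mean_deviation = b$summary$mean_deviation[1],
    sd_deviation = b$summary$sd_deviation[1],
    n_pairs = b$summary$n_pairs[1], n_null = b$n_null))

  ## stage 8: neutral model per environment
  ncm <- run_stage("neutral_model", log_con, {
    res <- list()
    for (g in levels(groups)) {
      sub <- rar[groups == g, , drop = FALSE]
      sub <- community_table(sub[, colSums(sub) > 0, drop = FALSE],
                             quiet = TRUE)
      res[[g]] <- fit_neutral_model(sub)
    }
    res
  })
  for (g in names(ncm)) {
    write_tsv(ncm[[g]]$taxa,
              file.path(config$outdir, paste0("ncm_", g, ".tsv")))
    fitsum <- ncm[[g]][c("m", "N", "d", "R2")]
    fitsum$n_over <- sum(ncm[[g]]$taxa$partition == "over")
    fitsum$n_neutral <- sum(ncm[[g]]$taxa$partition == "neutral")
    fitsum$n_under <- sum(ncm[[g]]$taxa$partition == "under")
    jsonlite::write_json(fitsum,
                         file.path(config$outdir, paste0("ncm_", g, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  report$neutral_model <- lapply(ncm, function(f) list(
    m = f$m, N = f$N, d = f$d, R2 = f$R2, at_bound = f$at_bound,
    partition = as.list(table(f$taxa$partition))))

  ## stage 9: cross-partition of neutral prediction by niche class
  cross <- run_stage("cross_partition", log_con, {
    lapply(ncm, function(f) {
      sub_cls <- cls[cls$taxon_id %in% f$taxa$taxon_id, , drop = FALSE]
      partition_by_neutral_prediction(f, sub_cls)
    })
  })
  report$cross_partition <- lapply(cross, function(cp) {
    lbl <- as.vector(outer(rownames(cp$counts), colnames(cp$counts),
                           paste, sep = "_"))
    sane <- function(v) as.list(ifelse(is.finite(v), v, NA))
    list(counts = as.list(stats::setNames(as.vector(cp$counts), lbl)),
         richness_ratio = sane(cp$richness_ratio),
         abundance_ratio = sane(cp$abundance_ratio))
  })

  ## qualitative ordering flags mirroring the study's headline claims
  dev_by <- function(s) {
    v <- vapply(names(bnull)[startsWith(names(bnull), paste0(s, "."))],
                function(nm) report$beta_null[[nm]]$mean_deviation, 0)
    mean(v)
  }
  report$flags <- list(
    specialist_dev_gt_generalist =
      dev_by("specialists") > dev_by("generalists"),
    specialist_nonneutral_ratio_gt_generalist = all(vapply(cross,
      function(cp) cp$richness_ratio["specialist"] >=
        cp$richness_ratio["generalist"], TRUE)))

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

#' Validate an analysis report against the shipped schema
#'
#' Structural validation: every section and field required by the schema
#' (`inst/schema/report_schema.json`) must be present with the right
#' JSON type.
#'
#' @param report report list (from [run_full_analysis()]) or path to a
#'   report JSON.
#' @return `TRUE`, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "sandassembly"))
  check <- function(node, spec, path) {
    for (key in names(spec$required)) {
      if (is.null(node[[key]]))
        stop("report missing required field: ", path, key)
      want <- spec$required[[key]]
      if (is.character(want)) {
        ok <- switch(want,
                     number = is.numeric(node[[key]]) ||
                       is.numeric(unlist(node[[key]])),
                     string = is.character(node[[key]]),
                     object = is.list(node[[key]]),
                     boolean = is.logical(node[[key]]),
                     TRUE)
        if (!ok) stop("report field has wrong type: ", path, key)
      } else {
        check(node[[key]], list(required = want), paste0(path, key, "."))
      }
    }
    TRUE
  }
  check(report, schema, "")
}
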
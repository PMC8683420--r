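# Configuration-driven orchestration of the full analysis grid:
# trees -> dataset variants -> alpha, beta, within-clade, ED, chi-square.

#' Build a run configuration
#'
#' Either `tree_path`/`matrix_path`/`taxonomy_path` or a `scenario` must be
#' supplied. Defaults mirror the standard analysis grid: full and
#' congeneric dataset variants at species and genus grain.
#'
#' @param tree_path Newick file (single or multi-tree, one per line).
#' @param matrix_path benefit-matrix CSV (wide format).
#' @param taxonomy_path taxonomy CSV (`tip,genus,family`).
#' @param scenario a [scenario_spec()] used instead of input files.
#' @param datasets subset of `c("full", "congeneric")`.
#' @param levels subset of `c("species", "genus")`.
#' @param n_null null-model draws (>= 99).
#' @param trees_subsample trees to analyse per base distribution (NULL =
#'   all).
#' @param thresholds multi-beneficial thresholds for the ED battery.
#' @param alphas nominal significance levels.
#' @param run_beta_pairs run the (quadratic) pairwise turnover SES matrix?
#' @param seed root seed recorded in every output.
#' @param out_dir output directory.
#' @return a validated `run_config` list.
#' @export
run_config <- function(tree_path = NULL, matrix_path = NULL,
                       taxonomy_path = NULL, scenario = NULL,
                       datasets = c("full", "congeneric"),
                       levels = c("species", "genus"),
                       n_null = 999, trees_subsample = NULL,
                       thresholds = 3:8, alphas = c(0.05, 0.01, 0.001),
                       run_beta_pairs = TRUE, seed = 1L, out_dir = "results") {
  if (n_null < 99) stopf("'n_null' must be >= 99")
  datasets <- match.arg(datasets, c("full", "congeneric"), several.ok = TRUE)
  levels <- match.arg(levels, c("species", "genus"), several.ok = TRUE)
  if (is.null(scenario) &&
      (is.null(tree_path) || is.null(matrix_path) || is.null(taxonomy_path))) {
    stopf("provide either input paths (tree, matrix, taxonomy) or a scenario")
  }
  structure(list(tree_path = tree_path, matrix_path = matrix_path,
                 taxonomy_path = taxonomy_path, scenario = scenario,
                 datasets = datasets, levels = levels, n_null = n_null,
                 trees_subsample = trees_subsample, thresholds = thresholds,
                 alphas = alphas, run_beta_pairs = run_beta_pairs,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$scenario)) {
    vals$scenario <- do.call(scenario_spec, vals$scenario)
  }
  do.call(run_config, vals)
}

genus_level_tree <- function(tree, taxonomy) {
  gen <- clade_of(taxonomy, tree$tip.label, "genus")
  reps <- tapply(tree$tip.label, gen, function(x) sort(x)[1])
  gt <- prune_to_tips(tree, unname(reps))
  gt$tip.label <- names(reps)[match(gt$tip.label, reps)]
  gt
}

write_output <- function(df, dir, name, files) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  c(files, path)
}

#' Run the full analysis pipeline
#'
#' Emits per-analysis CSV outputs plus a JSON manifest (seed, counts,
#' skipped items, file checksums). Re-running with the same configuration
#' reproduces every output bit-exactly; failure of one analysis stage is
#' logged and the remaining stages still run.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log <<- c(log, msg)
  }
  seeds <- derive_seeds(config$seed, 8)

  if (!is.null(config$scenario)) {
    sc <- generate_scenario(config$scenario, seed = seeds[[1]])
    trees <- tree_distribution(list(sc$tree))
    matrix_full <- sc$matrix
    taxonomy <- sc$taxonomy
    note("generated synthetic scenario: %d tips, %d beneficial species",
         length(sc$tree$tip.label), nrow(matrix_full))
  } else {
    lines <- readLines(config$tree_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    trees <- tree_distribution(lapply(lines, parse_newick))
    matrix_full <- read_benefit_matrix(config$matrix_path)
    taxonomy <- read_taxonomy_csv(config$taxonomy_path)
  }
  if (!is.null(config$trees_subsample) &&
      config$trees_subsample < length(trees)) {
    trees <- subsample_trees(trees, config$trees_subsample, seed = seeds[[2]])
  }
  reconcile_taxa(matrix_full, trees[[1]])

  variants <- list()
  for (ds in config$datasets) {
    if (ds == "full") {
      msp <- matrix_full
    } else {
      msp <- tryCatch(congeneric_subset(matrix_full, taxonomy),
                      warning = function(w) {
                        note("congeneric variant skipped: %s", conditionMessage(w))
                        NULL
                      })
      if (is.null(msp) || nrow(msp) == 0) next
    }
    for (lv in config$levels) {
      if (lv == "species") {
        variants[[paste(ds, lv, sep = "_")]] <-
          list(matrix = msp, trees = trees, dataset = ds, level = lv)
      } else {
        gtrees <- tree_distribution(
          lapply(trees$trees, genus_level_tree, taxonomy = taxonomy))
        variants[[paste(ds, lv, sep = "_")]] <-
          list(matrix = collapse_to_genus(msp, taxonomy), trees = gtrees,
               dataset = ds, level = lv)
      }
    }
  }

  files <- character(0)
  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      note("stage '%s' failed: %s", label, conditionMessage(e))
      NULL
    })
  }

  alpha_rows <- list()
  beta_rows <- list()
  multisite_rows <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    run_stage(paste0("alpha/", vn), {
      whole <- ses_pd_whole_set(v$trees, v$matrix, n_null = config$n_null,
                                seed = seeds[[3]], alphas = config$alphas)
      per <- ses_pd_per_benefit(v$trees, v$matrix, n_null = config$n_null,
                                seed = seeds[[3]], alphas = config$alphas)
      alpha_rows[[vn]] <- rbind(
        data.frame(benefit = "(all)", n_taxa = nrow(v$matrix),
                   mean_ses = whole$mean, ci_low = whole$ci_low,
                   ci_high = whole$ci_high, call = unname(whole$calls[1]),
                   dataset = v$dataset, level = v$level,
                   stringsAsFactors = FALSE),
        cbind(per, dataset = v$dataset, level = v$level))
    })
    run_stage(paste0("multisite/", vn), {
      sites <- lapply(colnames(v$matrix), function(b) {
        rownames(v$matrix)[unclass(v$matrix)[, b] == 1]
      })
      names(sites) <- colnames(v$matrix)
      sites <- sites[lengths(sites) > 0]
      per_tree <- lapply(v$trees$trees, function(tr) {
        multisite_partition(sites, "phylogenetic", tree = tr)
      })
      multisite_rows[[vn]] <- data.frame(
        dataset = v$dataset, level = v$level, n_trees = length(per_tree),
        pbsor = mean(vapply(per_tree, `[[`, numeric(1), "beta_sor")),
        pbsim = mean(vapply(per_tree, `[[`, numeric(1), "beta_sim")),
        pbnes = mean(vapply(per_tree, `[[`, numeric(1), "beta_nes")),
        stringsAsFactors = FALSE)
    })
    if (config$run_beta_pairs) {
      run_stage(paste0("beta_pairs/", vn), {
        bp <- ses_pbsim_matrix(v$trees, v$matrix, n_null = config$n_null,
                               seed = seeds[[4]], alphas = config$alphas)
        beta_rows[[vn]] <- cbind(bp, dataset = v$dataset, level = v$level)
      })
    }
  }
  if (length(alpha_rows)) {
    files <- write_output(do.call(rbind, alpha_rows), config$out_dir,
                          "alpha_ses_pd.csv", files)
  }
  if (length(multisite_rows)) {
    files <- write_output(do.call(rbind, multisite_rows), config$out_dir,
                          "beta_multisite.csv", files)
  }
  if (length(beta_rows)) {
    files <- write_output(do.call(rbind, beta_rows), config$out_dir,
                          "beta_pairwise_ses.csv", files)
  }

  run_stage("within_clades", {
    wc <- rbind(within_clade_es(matrix_full, taxonomy, "genus",
                                n_null = config$n_null, seed = seeds[[5]]),
                within_clade_es(matrix_full, taxonomy, "family",
                                n_null = config$n_null, seed = seeds[[5]]))
    if (nrow(wc)) {
      files <- write_output(wc, config$out_dir, "within_clade_es.csv", files)
    } else {
      note("within-clade analysis skipped: no clade has two beneficial members")
    }
  })

  run_stage("ed_battery", {
    ed <- run_ed_battery(trees, matrix_full, thresholds = config$thresholds,
                         n_null = config$n_null, seed = seeds[[6]],
                         alphas = config$alphas)
    if (nrow(ed)) {
      files <- write_output(ed, config$out_dir, "ed_battery.csv", files)
    }
    for (sk in names(attr(ed, "skipped") %||% character(0))) {
      note("ED battery: %s skipped (%s)", sk, attr(ed, "skipped")[[sk]])
    }
  })

  run_stage("chisq", {
    rows <- list()
    for (k in config$thresholds) {
      subset <- multibeneficial_subset(matrix_full, k)
      if (length(subset) == 0 || length(subset) == nrow(matrix_full)) next
      rows[[as.character(k)]] <- cbind(threshold = k,
        benefit_contribution_chisq(matrix_full, subset))
    }
    if (length(rows)) {
      files <- write_output(do.call(rbind, rows), config$out_dir,
                             "benefit_contribution_chisq.csv", files)
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("phylobenefit")),
    seed = config$seed,
    n_null = config$n_null,
    n_trees = length(trees),
    n_species = nrow(matrix_full),
    n_benefits = ncol(matrix_full),
    variants = names(variants),
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    log = log
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(manifest)
}
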
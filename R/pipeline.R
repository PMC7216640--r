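#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates every stage behind a single configuration (a YAML file or
#' an equivalent named list): load or simulate the inputs, fit
#' \code{\link{triad_bias}}, optionally filter DEGs, score gene-set
#' enrichment and solute changes, and write all tabular outputs plus a
#' machine-readable summary and a run manifest into \code{outdir}.
#'
#' Configuration keys: either \code{simulate} (a list of
#' \code{\link{sim_config}} arguments, \code{seed} included) or the paths
#' \code{expr}, \code{triads}, \code{samples}; optional paths \code{de},
#' \code{gene_sets}, \code{solutes}; \code{tissue}; thresholds
#' \code{min_total_tpm}, \code{fold_threshold}, \code{alpha},
#' \code{min_abs_log2fc}; \code{outdir}.
#'
#' Outputs: \code{rev.tsv}, \code{hebc.tsv}, \code{shifts.tsv},
#' \code{hebc_changes.tsv}, and when inputs allow \code{degs.tsv},
#' \code{enrichment.tsv}, \code{solute_calls.tsv}, \code{truth.tsv};
#' \code{summary.json} holds the headline numbers (all recomputable from
#' the TSVs) and \code{manifest.json} the config hash and versions. Every
#' stage failure aborts with the stage name.
#'
#' @param config Path to a YAML file, or a named list.
#' @param outdir Output directory (overrides \code{config$outdir}).
#' @return Invisibly, a list with the fitted \code{triad_bias} object, the
#'   summary list and the output paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("stage 'config': config must be a YAML path or a list")
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) stop("stage 'config': no output directory given")

  # validate before any computation
  simulate <- !is.null(cfg$simulate)
  if (!simulate) {
    for (key in c("expr", "triads", "samples")) {
      if (is.null(cfg[[key]])) stop("stage 'config': missing input path '", key, "'")
      if (!file.exists(cfg[[key]])) {
        stop("stage 'config': input file not found: ", cfg[[key]])
      }
    }
  }
  for (key in c("de", "gene_sets", "solutes")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("stage 'config': input file not found: ", cfg[[key]])
    }
  }
  min_total_tpm <- cfg$min_total_tpm %||% 0.5
  fold_threshold <- cfg$fold_threshold %||% 1.2
  alpha <- cfg$alpha %||% 0.05
  min_abs_log2fc <- cfg$min_abs_log2fc %||% 1
  if (fold_threshold <= 1) stop("stage 'config': fold_threshold must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("stage 'config': alpha must be in (0, 1)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- NULL
  de <- NULL
  if (simulate) {
    inputs <- stage("simulate", {
      sim <- simulate_dataset(do.call(sim_config, cfg$simulate))
      list(expr = sim$tpm, triads = sim$triads, samples = sim$sheet,
           tissue = cfg$tissue %||% sim$config$tissue)
    })
    de <- stage("naive_de",
                naive_de(sim$counts, sim$sheet, tissue = inputs$tissue))
  } else {
    inputs <- stage("load", list(
      expr = read_expression_matrix(cfg$expr, unit = "TPM"),
      triads = read_triad_table(cfg$triads),
      samples = read_sample_sheet(cfg$samples),
      tissue = cfg$tissue %||% stop("tissue is required")))
  }
  if (!is.null(cfg$de)) de <- stage("read_de", read_de_table(cfg$de))

  fit <- stage("triad_bias",
               triad_bias(inputs$expr, inputs$triads, inputs$samples,
                          tissue = inputs$tissue,
                          min_total_tpm = min_total_tpm,
                          fold_threshold = fold_threshold))

  paths <- list()
  emit <- function(obj, name) {
    p <- file.path(outdir, name)
    write_tsv(obj, p)
    paths[[name]] <<- p
  }
  stage("write_tables", {
    emit(fit$rev[c("triad_id", "condition", "a_pct", "b_pct", "d_pct",
                   "total_tpm")], "rev.tsv")
    hebc <- fit$rev[c("triad_id", "condition", "category", "distance", "x", "y")]
    hebc$category <- as.character(hebc$category)
    emit(hebc, "hebc.tsv")
    emit(fit$shifts, "shifts.tsv")
    ch <- fit$changes
    ch$category_control <- as.character(ch$category_control)
    ch$category_stress <- as.character(ch$category_stress)
    emit(ch, "hebc_changes.tsv")
  })

  summary <- list(
    tissue = inputs$tissue,
    n_triads_input = fit$n_input,
    n_triads_detected = fit$n_detected,
    fraction_hebc_changed = attr(fit$changes, "fraction_changed"),
    category_percent = list(
      control = stats::setNames(as.list(fit$category_summary$control$percent),
                                fit$category_summary$control$category),
      stress = stats::setNames(as.list(fit$category_summary$stress$percent),
                               fit$category_summary$stress$category)),
    shift_frac_below_threshold = stats::setNames(
      as.list(fit$shift_summary$frac_below_threshold),
      fit$shift_summary$homeolog),
    shift_frac_significant = stats::setNames(
      as.list(fit$shift_summary$frac_significant),
      fit$shift_summary$homeolog),
    thresholds = list(min_total_tpm = min_total_tpm,
                      fold_threshold = fold_threshold,
                      alpha = alpha, min_abs_log2fc = min_abs_log2fc))

  sets <- NULL
  if (!is.null(cfg$gene_sets)) {
    sets <- stage("gene_sets", read_gene_sets(cfg$gene_sets))
  }
  if (!is.null(de)) {
    stage("degs", {
      degs <- filter_degs(de, alpha = alpha, min_abs_log2fc = min_abs_log2fc)
      emit(degs$table, "degs.tsv")
      summary$n_degs <- length(degs$degs)
      summary$n_degs_up <- length(degs$up)
      summary$n_degs_down <- length(degs$down)
      if (!is.null(sets)) {
        enr <- hypergeometric_enrichment(degs$degs, de$gene_id, sets)
        emit(enr, "enrichment.tsv")
      }
    })
  }
  if (!is.null(sets)) {
    stage("set_hebc_changes", {
      frac <- lapply(sets, function(members) {
        tr <- inputs$triads
        in_set <- tr$gene_a %in% members | tr$gene_b %in% members |
          tr$gene_d %in% members
        ch <- fit$changes[fit$changes$triad_id %in% tr$triad_id[in_set], ]
        if (nrow(ch) == 0L) NA_real_ else mean(ch$changed)
      })
      summary$fraction_hebc_changed_by_set <- frac
    })
  }
  if (!is.null(cfg$solutes)) {
    stage("solutes", {
      prof <- read_solute_table(cfg$solutes)
      calls <- significant_solute_change(prof)
      pc_c <- percent_contribution(prof, "control")
      pc_s <- percent_contribution(prof, "stress")
      calls$percent_contribution_control <-
        pc_c$percent_contribution[match(calls$solute, pc_c$solute)]
      calls$percent_contribution_stress <-
        pc_s$percent_contribution[match(calls$solute, pc_s$solute)]
      emit(calls, "solute_calls.tsv")
    })
  }
  if (simulate) {
    stage("truth", {
      emit(sim$truth, "truth.tsv")
      ctl <- fit$rev[fit$rev$condition == "control", ]
      rep <- truth_report(sim$truth, assignments = ctl, changes = fit$changes,
                          shifts = fit$shifts[fit$shifts$homeolog == "D", ],
                          fold_threshold = fold_threshold)
      summary$truth <- list(category_recovery = rep$category_recovery,
                             change_sensitivity = rep$change_sensitivity,
                             change_specificity = rep$change_specificity,
                             change_fpr = rep$change_fpr,
                             shift_sensitivity = rep$shift_sensitivity,
                             shift_specificity = rep$shift_specificity)
    })
  }

  stage("summary", {
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    paths[["summary.json"]] <- file.path(outdir, "summary.json")
    manifest <- list(
      package = "triadbias",
      version = as.character(utils::packageVersion("triadbias")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config_md5 = config_hash(cfg),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
  })

  invisible(list(fit = fit, summary = summary, paths = paths, sim = sim))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the canonical (yaml) serialization of the config
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
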
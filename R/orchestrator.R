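#' Experiment configuration
#'
#' A serializable description of a full stability experiment: study-design
#' preset, cohort-generator parameters, perturbation grid, hypothesis list,
#' model settings, output directory and global seed. Round-trips through
#' YAML ([save_config()] / [load_config()]).
#'
#' @param preset study-design preset name (see [design_preset()]).
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir output directory for [run_experiment()].
#' @param ... overrides of the default fields (e.g. `n_nodes`, `t`,
#'   `modes`, `pipelines`, `n_sims`, `sigma_session`, `n_perm`,
#'   `k_folds`, `n_repeats`).
#' @return an object of class `cs_config` (a named list).
#' @export
experiment_config <- function(preset = "smoke", seed = 1L,
                              out_dir = tempfile("connstab-"), ...) {
  base <- list(
    preset = preset,
    n_nodes = if (preset == "smoke") 8L else 40L,
    sigma_subject = 1.0, sigma_session = 0.3, sigma_subsample = 0.1,
    assoc = 1.5,
    t = 52L, mca_mode = "rr",
    pipelines = c("det", "prob"), modes = c("dense", "sparse"),
    n_sims = if (preset == "smoke") 2L else 20L,
    hypotheses = c("H1", "H2", "H3"),
    n_perm = if (preset == "smoke") 50L else 1000L,
    k_folds = 5L, n_repeats = if (preset == "smoke") 3L else 20L,
    lambda = 1.0, variance_threshold = 0.9,
    community_seed = 42L,
    out_dir = out_dir, seed = as.integer(seed))
  cfg <- utils::modifyList(base, list(...))
  for (f in intersect(config_int_fields, names(cfg))) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  structure(cfg, class = c("cs_config", "list"))
}

config_int_fields <- c("n_nodes", "t", "n_sims", "n_perm", "k_folds",
                       "n_repeats", "community_seed", "seed")

#' @rdname experiment_config
#' @param config a `cs_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in intersect(config_int_fields, names(cfg))) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  structure(cfg, class = c("cs_config", "list"))
}

config_hash <- function(config) {
  fnv1a(yaml::as.yaml(unclass(config)))
}

#' Total executions of a study design
#'
#' `n_subjects * n_sessions * n_subsamples * n_pipelines * n_modes *
#' (n_sims + 1)`: every sample is reconstructed once per pipeline and
#' instrumentation mode without perturbation (reference) plus `n_sims`
#' perturbed simulations. Both built-in study presets yield 8,400.
#'
#' @param design a [study_design()].
#' @return integer execution count.
#' @export
count_executions <- function(design) {
  stopifnot(inherits(design, "cs_design"))
  n_samples(design) * length(design$pipelines) * length(design$modes) *
    (design$n_sims + 1L)
}

#' Default hypothesis-comparison grid
#'
#' The full class-based evaluation grid: per hypothesis, the observation
#' levels compared on MCA-perturbed executions, and the comparisons that
#' can also run on reference executions (H3 requires perturbed executions).
#'
#' @return list with `mca` and `reference` comparison lists.
#' @export
default_test_grid <- function() {
  list(
    mca = list(H1 = c("session", "subsample", "mca"),
               H2 = c("subsample", "mca"),
               H3 = "mca"),
    reference = list(H1 = c("session", "subsample"),
                     H2 = "subsample")
  )
}

#' Number of distinct discriminability tests in a grid
#'
#' MCA comparison settings run per pipeline and per instrumentation mode;
#' reference comparison settings run per pipeline only (the reference
#' execution is mode-independent). The default grid on two pipelines and
#' two modes yields 6 x 2 x 2 + 3 x 2 = 30 distinct tests.
#'
#' @param mca_comparisons list (or vector) of comparison settings evaluated
#'   on perturbed executions.
#' @param ref_comparisons list (or vector) evaluated on reference
#'   executions.
#' @param n_pipelines,n_modes grid dimensions.
#' @return integer test count.
#' @export
count_tests <- function(mca_comparisons = default_test_grid()$mca,
                        ref_comparisons = default_test_grid()$reference,
                        n_pipelines = 2L, n_modes = 2L) {
  length(unlist(mca_comparisons)) * n_pipelines * n_modes +
    length(unlist(ref_comparisons)) * n_pipelines
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  invisible(msg)
}

#' Run a full stability experiment
#'
#' Executes the end-to-end pipeline described by a configuration: cohort
#' generation, reference + perturbed reconstruction of the execution grid,
#' grouped stability metrics, the discriminability test grid,
#' graph-feature moment stability, and the resampled phenotype model. All
#' outputs (CSV/JSON, plus the config and a run log) are written under
#' `config$out_dir`; every output file name carries the config hash. A
#' failing stage is logged and skipped, and downstream stages that depend
#' on it are marked unavailable.
#'
#' @param config an [experiment_config()].
#' @param until last stage to run, in the order `cohort`, `connectomes`,
#'   `stability`, `discriminability`, `features`, `model`; later stages are
#'   skipped.
#' @return invisibly, a list with the stage results (`cohort`, `connectomes`,
#'   `stability`, `discriminability`, `features`, `model`), stage `status`,
#'   and the output directory.
#' @export
run_experiment <- function(config = experiment_config(), until = "model") {
  stage_order <- c("cohort", "connectomes", "stability", "discriminability",
                   "features", "model")
  until <- match.arg(until, stage_order)
  run_upto <- match(until, stage_order)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  tag <- function(name) file.path(config$out_dir, paste0(name, "-", hash))
  logf <- file(file.path(config$out_dir, paste0("run-", hash, ".log")), "w")
  on.exit(close(logf))
  status <- list()
  res <- list(out_dir = config$out_dir, hash = hash)
  save_config(config, file.path(config$out_dir, paste0("config-", hash, ".yaml")))

  stage <- function(name, depends, fun) {
    if (match(name, stage_order) > run_upto) {
      status[[name]] <<- NA
      return(invisible(NULL))
    }
    if (length(depends) &&
        !all(vapply(depends, function(d) isTRUE(status[[d]]), logical(1)))) {
      log_line(logf, name, ": unavailable (failed dependency)")
      status[[name]] <<- NA
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      log_line(logf, name, ": FAILED - ", conditionMessage(e))
      NULL
    })
    if (!is.null(out)) {
      status[[name]] <<- TRUE
      res[[name]] <<- out
      log_line(logf, sprintf("%s: done in %.2fs", name,
                             as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    } else if (is.null(status[[name]])) {
      status[[name]] <<- FALSE
    }
    invisible(out)
  }

  log_line(logf, "config hash ", hash, ", seed ", config$seed)

  stage("cohort", character(0), function() {
    design <- design_preset(config$preset)
    if (!is.null(config$n_sims)) design$n_sims <- config$n_sims
    design$pipelines <- config$pipelines
    design$modes <- config$modes
    cohort <- generate_cohort(design, n_nodes = config$n_nodes,
                              sigma_subject = config$sigma_subject,
                              sigma_session = config$sigma_session,
                              sigma_subsample = config$sigma_subsample,
                              assoc = config$assoc,
                              seed = derive_seed(config$seed, 1L))
    write_manifest(cohort$samples, paste0(tag("manifest"), ".csv"))
    cohort
  })

  stage("connectomes", "cohort", function() {
    set <- reconstruct_cohort(res$cohort, t = config$t,
                              base_seed = derive_seed(config$seed, 2L))
    cdir <- paste0(tag("connectomes"))
    dir.create(cdir, showWarnings = FALSE)
    refs <- which(set$index$sim == 0)
    for (i in refs) {
      k <- set$index[i, ]
      write_connectome_tsv(
        set$connectomes[[i]],
        file.path(cdir, sprintf("ref_s%02d_e%d_u%d_%s_%s.tsv", k$subject,
                                k$session, k$subsample, k$pipeline, k$mode)))
    }
    write_manifest(set$index, paste0(tag("executions"), ".csv"))
    set
  })

  stage("stability", "connectomes", function() {
    classes <- c("mca", if (res$cohort$design$n_subsamples > 1) "subsample",
                 if (res$cohort$design$n_sessions > 1) "session",
                 if (res$cohort$design$n_subjects > 1) "subject")
    reports <- lapply(classes, function(cl) group_stability(res$connectomes, cl))
    names(reports) <- classes
    smry <- do.call(rbind, lapply(reports, function(r) {
      data.frame(class = r$class, n_pairs = nrow(r$pairs),
                 median_pdev = stats::median(r$pairs$pdev),
                 mean_edge_digits = mean(r$digits$digits, na.rm = TRUE))
    }))
    utils::write.csv(smry, paste0(tag("stability"), ".csv"), row.names = FALSE)
    reports
  })

  stage("discriminability", "connectomes", function() {
    grid <- default_test_grid()
    rows <- list()
    add <- function(hyp, cmp, pl, mode, use_ref) {
      r <- tryCatch(
        run_hypothesis(res$connectomes, hyp, pipeline = pl, mode = mode,
                       comparison = cmp, use_reference = use_ref,
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, 3L)),
        error = function(e) NULL)
      if (is.null(r)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        hypothesis = hyp, comparison = cmp, pipeline = pl, mode = mode,
        reference = use_ref, chance = r$chance,
        chance_empirical = r$chance_empirical, statistic = r$statistic,
        scaled = r$scaled, p_value = r$p_value)
    }
    for (hyp in intersect(config$hypotheses, names(grid$mca))) {
      for (cmp in grid$mca[[hyp]]) {
        for (pl in config$pipelines) {
          for (mode in config$modes) add(hyp, cmp, pl, mode, FALSE)
        }
      }
    }
    for (hyp in intersect(config$hypotheses, names(grid$reference))) {
      for (cmp in grid$reference[[hyp]]) {
        for (pl in config$pipelines) add(hyp, cmp, pl, config$modes[1], TRUE)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, paste0(tag("discriminability"), ".csv"),
                     row.names = FALSE)
    tab
  })

  stage("features", "connectomes", function() {
    idx <- res$connectomes$index
    out <- list()
    for (mode in config$modes) {
      pl <- config$pipelines[1]
      sel <- which(idx$pipeline == pl & idx$mode == mode & idx$sim > 0 &
                     idx$session == 1 & idx$subsample == 1)
      by_subj <- split(sel, idx$subject[sel])
      vals <- lapply(by_subj, function(ii) {
        do.call(rbind, lapply(ii, function(i) {
          compute_features(res$connectomes$connectomes[[i]],
                           sets = "nodewise",
                           community_seed = config$community_seed)$nodewise$degree
        }))
      })
      out[[mode]] <- multivariate_stability(vals)
    }
    smry <- do.call(rbind, lapply(names(out), function(m) {
      data.frame(mode = m, moment = names(out[[m]]$digit_summary),
                 median_digits = as.numeric(out[[m]]$digit_summary))
    }))
    utils::write.csv(smry, paste0(tag("feature-moments"), ".csv"),
                     row.names = FALSE)
    out
  })

  stage("model", "connectomes", function() {
    idx <- res$connectomes$index
    labels <- cohort_labels(res$cohort)
    pl <- config$pipelines[1]; mode <- config$modes[1]
    subj_ids <- sort(unique(idx$subject))
    pick <- function(s, sims) which(idx$subject == s & idx$session == 1 &
                                      idx$subsample == 1 & idx$pipeline == pl &
                                      idx$mode == mode &
                                      (if (sims) idx$sim > 0 else idx$sim == 0))
    x_ref <- t(vapply(subj_ids, function(s) {
      upper_triangle(res$connectomes$connectomes[[pick(s, FALSE)[1]]]$weights)
    }, numeric(res$cohort$n_nodes * (res$cohort$n_nodes - 1) / 2)))
    x_by_subject <- lapply(subj_ids, function(s) {
      do.call(rbind, lapply(pick(s, TRUE), function(i) {
        upper_triangle(res$connectomes$connectomes[[i]]$weights)
      }))
    })
    perf <- resampled_performance(x_by_subject, x_ref, labels[subj_ids],
                                  k = min(config$k_folds, length(subj_ids)),
                                  n_repeats = config$n_repeats,
                                  seed = derive_seed(config$seed, 4L),
                                  lambda = config$lambda,
                                  threshold = config$variance_threshold)
    utils::write.csv(perf$runs, paste0(tag("model-runs"), ".csv"),
                     row.names = FALSE)
    jsonlite::write_json(perf$summary, paste0(tag("model-summary"), ".json"),
                         auto_unbox = TRUE, digits = NA)
    perf
  })

  res$status <- status
  invisible(res)
}

#' Command-line interface
#'
#' Subcommands: `generate`, `perturb`, `stability`, `discrim`, `features`,
#' `model`, `all`. Each accepts `--config` (YAML experiment config),
#' `--preset`, `--seed` and `--out`; `all` runs the full pipeline, the
#' stage subcommands run the pipeline up to (and including) that stage.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
cs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("generate", "perturb", "stability", "discrim", "features",
            "model", "all")
  if (!length(args) || !args[1] %in% cmds) {
    cat("usage: connstab <", paste(cmds, collapse = "|"),
        "> [--config FILE] [--preset NAME] [--seed N] [--out DIR]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--preset", type = "character", default = "smoke"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = NULL)))
  opt <- optparse::parse_args(parser, args = args[-1])
  cfg <- if (!is.null(opt$config)) load_config(opt$config) else
    experiment_config(preset = opt$preset, seed = opt$seed)
  cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  until <- switch(cmd,
    generate = "cohort", perturb = "connectomes", stability = "stability",
    discrim = "discriminability", features = "features", model = "model",
    all = "model")
  res <- run_experiment(cfg, until = until)
  cat("outputs written to ", res$out_dir, "\n", sep = "")
  invisible(if (isTRUE(res$status[[until]])) 0L else 1L)
}
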
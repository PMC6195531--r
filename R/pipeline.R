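#' Validate and normalise a pipeline configuration
#'
#' A pipeline run is reproducible from the configuration, the inputs and
#' the seed alone. The configuration is a plain list (or a YAML/JSON file
#' holding one) with fields:
#' \describe{
#'   \item{out_dir}{output directory (required)}
#'   \item{seed}{global seed propagated to all stochastic stages
#'     (default 1)}
#'   \item{alpha}{KS significance level (default 0.05)}
#'   \item{dataset_label}{label of the comparison (default
#'     \code{"dataset"})}
#'   \item{simulate}{list with \code{n_pairs}, \code{gene_length},
#'     optional \code{biases} (list of \code{list(codon =, delta =)}
#'     applied to the extremophile profile) and \code{include_stop} —
#'     generates the input dataset}
#'   \item{fasta, manifest}{alternatively, paths to a CDS FASTA (both
#'     classes) and a pair manifest TSV}
#'   \item{ml}{list with \code{models} (default \code{c("knn", "tree")}),
#'     \code{k}, \code{criterion}, \code{train_frac}}
#' }
#'
#' @param config List, or path to a YAML or JSON file.
#' @return Normalised configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  defaults <- list(seed = 1L, alpha = 0.05, dataset_label = "dataset",
                   ml = list())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  ml_defaults <- list(models = c("knn", "tree"), k = 10,
                      criterion = "infogain", train_frac = 0.7)
  for (nm in names(ml_defaults)) {
    if (is.null(config$ml[[nm]])) config$ml[[nm]] <- ml_defaults[[nm]]
  }
  has_sim <- !is.null(config$simulate)
  has_files <- !is.null(config$fasta) && !is.null(config$manifest)
  if (!has_sim && !has_files) {
    stop("config needs either 'simulate' or 'fasta' + 'manifest'",
         call. = FALSE)
  }
  structure(config, class = c("pipeline_config", "list"))
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full codon-preference analysis end-to-end
#'
#' Executes, in order: input assembly (synthetic generation or
#' FASTA/manifest loading), KS significance filtering, relative abundance,
#' 1-9 ranking with extreme-codon identification, composition summary of
#' the positive contributors, data-point series for the extreme codons,
#' attribute weighting with support counts, supervised classification, and
#' decision-rule extraction from the tree model. Every stage's table is
#' written under \code{out_dir} and indexed in a top-level
#' \code{manifest.json}, so any downstream stage can be resumed from the
#' files alone. An empty significant set stops the pipeline after the
#' significance stage with a clear message.
#'
#' @param config A \code{\link{pipeline_config}} (or anything it accepts).
#' @return Invisibly, a list with all in-memory stage results and
#'   \code{artifacts} (named file paths).
#' @export
run_all <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- c()
  add <- function(name, path) {
    art[[name]] <<- path
    path
  }

  paired <- .stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      prof_e <- class_codon_profile()
      if (!is.null(sim$biases)) {
        specs <- lapply(sim$biases, function(b) bias_spec(b$codon, b$delta))
        prof_e <- make_profiles(prof_e, specs)
      }
      sc <- synth_config(
        n_pairs = sim$n_pairs,
        gene_length = if (is.null(sim$gene_length)) 300 else sim$gene_length,
        profile_e = prof_e,
        include_stop = if (is.null(sim$include_stop)) TRUE else sim$include_stop,
        seed = cfg$seed
      )
      ds <- generate_dataset(sc, dataset_label = cfg$dataset_label)
      write_dataset(ds, file.path(cfg$out_dir, "input"))
      as_paired_dataset(ds)
    } else {
      recs <- read_cds_fasta(cfg$fasta)
      man <- load_manifest(cfg$manifest, recs,
                           dataset_label = cfg$dataset_label)
      build_paired_dataset(man, recs)
    }
  })

  sigset <- .stage("significance", {
    s <- filter_significant(paired, alpha = cfg$alpha)
    write_tsv(as.data.frame(s), add("significance", file.path(cfg$out_dir, "significance.tsv")))
    s
  })
  if (attr(sigset, "n_significant") == 0) {
    jsonlite::write_json(as.list(art), file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    stop(sprintf("no codon significant at alpha = %g in dataset '%s'; pipeline stopped after the significance stage",
                 cfg$alpha, cfg$dataset_label), call. = FALSE)
  }

  abundance <- .stage("abundance", {
    a <- relative_abundance(paired, sigset)
    write_tsv(as.data.frame(a), add("abundance", file.path(cfg$out_dir, "abundance.tsv")))
    a
  })

  ranks <- .stage("ranking", {
    r <- rank_codons(abundance)
    write_tsv(as.data.frame(r), add("ranks", file.path(cfg$out_dir, "ranks.tsv")))
    r
  })
  extremes <- extreme_codons(ranks)
  jsonlite::write_json(extremes, add("extreme_codons", file.path(cfg$out_dir, "extreme_codons.json")),
                       auto_unbox = TRUE)

  composition <- .stage("composition", {
    pos <- positive_contributors(abundance)
    cs <- composition_summary(pos)
    jsonlite::write_json(unclass(cs), add("composition", file.path(cfg$out_dir, "composition.json")),
                         auto_unbox = TRUE, digits = NA)
    cs
  })

  .stage("datapoints", {
    for (cod in unique(unlist(extremes))) {
      dp <- datapoint_series(paired, cod)
      write_tsv(as.data.frame(dp),
                add(paste0("datapoints_", cod),
                    file.path(cfg$out_dir, sprintf("datapoints_%s.tsv", cod))))
    }
  })

  ft <- feature_table(paired, sigset)
  weights <- .stage("weighting", {
    wm <- attribute_weights(ft)
    wdf <- data.frame(codon = rownames(wm), unclass(wm),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(wdf, add("weights", file.path(cfg$out_dir, "weights.tsv")))
    write_tsv(support_counts(wm), add("support_counts", file.path(cfg$out_dir, "support_counts.tsv")))
    wm
  })

  reports <- .stage("classification", {
    lapply(cfg$ml$models, function(m) {
      train_eval(ft, model = m, criterion = cfg$ml$criterion,
                 k = cfg$ml$k, train_frac = cfg$ml$train_frac,
                 seed = cfg$seed)
    })
  })
  names(reports) <- cfg$ml$models
  jsonlite::write_json(
    lapply(reports, function(r) r[c("model", "hyperparameters", "split", "accuracy")]),
    add("classifier_reports", file.path(cfg$out_dir, "classifier_reports.json")),
    auto_unbox = TRUE, digits = NA)

  rules <- NULL
  if ("tree" %in% names(reports)) {
    rules <- .stage("rules", {
      rl <- extract_rules(reports[["tree"]]$fitted)
      writeLines(render_rules(rl), add("rules", file.path(cfg$out_dir, "rules.txt")))
      rl
    })
  }

  jsonlite::write_json(as.list(art), file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(paired = paired, sigset = sigset, abundance = abundance,
                 ranks = ranks, extremes = extremes,
                 composition = composition, weights = weights,
                 reports = reports, rules = rules,
                 artifacts = as.list(art)))
}

#' Pool per-class analyses into a codon-harmony table
#'
#' Convenience wrapper for multi-class runs: takes one
#' \code{abundance_result} per extremophile class, extracts each class's
#' positive contributors, and builds the 64-codon harmony table.
#'
#' @param abundance_by_class Named list (class name ->
#'   \code{abundance_result}).
#' @param out_path Optional TSV path for the harmony matrix.
#' @return A \code{\link{harmony_table}}.
#' @export
pool_harmony <- function(abundance_by_class, out_path = NULL) {
  preferred <- lapply(abundance_by_class, positive_contributors)
  ht <- harmony_table(preferred)
  if (!is.null(out_path)) write_tsv(as.data.frame(ht), out_path)
  ht
}
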
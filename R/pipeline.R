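#' End-to-end pipeline configuration
#'
#' One serializable object drives a full run: dataset source (a directory
#' of class folders or a synthetic spec), descriptor configuration, SMOTE
#' and split settings, classifier roster, optional stress conditions, and
#' the root seed every stochastic stage derives from.
#'
#' @param root dataset directory (ignored when `synthetic` is given).
#' @param synthetic optional [synthetic_dataset_spec()]; the dataset is
#'   generated under the output directory.
#' @param cfg a [descriptor_config()].
#' @param classifiers character vector of classifier names.
#' @param smote_mode `"guarded"`, `"paper_order"` or `"off"`.
#' @param smote_k SMOTE neighbour count.
#' @param folds cross-validation fold count.
#' @param fractions train/val/test fractions (for the stress split).
#' @param stress optional condition string (e.g. `"noise:10,rot:180"`).
#' @param seed root seed.
#' @param out_dir run output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(root = NULL, synthetic = NULL,
                            cfg = descriptor_config(),
                            classifiers = c("RandomForest", "GradientBoost",
                                            "SVM", "SoftVote"),
                            smote_mode = "guarded", smote_k = 5L,
                            folds = 5L, fractions = c(0.7, 0.15, 0.15),
                            stress = NULL, seed = 42L, out_dir = tempfile()) {
  if (is.null(root) && is.null(synthetic))
    lf_abort("either a dataset root or a synthetic spec is required")
  structure(list(root = root, synthetic = synthetic, cfg = cfg,
                 classifiers = classifiers, smote_mode = smote_mode,
                 smote_k = as.integer(smote_k), folds = as.integer(folds),
                 fractions = fractions, stress = stress,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# config echo with everything needed to reproduce the run
config_as_list <- function(cfg) {
  lst <- unclass(cfg)
  lst$cfg <- unclass(lst$cfg)
  if (!is.null(lst$synthetic)) {
    lst$synthetic <- unclass(lst$synthetic)
    lst$synthetic$class_specs <- lapply(lst$synthetic$class_specs, unclass)
  }
  lst
}

#' Run the full pipeline
#'
#' Executes extract, balance, cross-validated evaluation, inter-class
#' similarity and (optionally) stress testing, and writes all artifacts
#' into the run directory: `features.csv`, `report.json`, `report.md`,
#' `similarity.csv`, `similarity.png`, `stress.csv` (when requested),
#' `config.json` and `run.log`.
#'
#' @param cfg a [pipeline_config()].
#' @return the run directory path, invisibly; the parsed artifacts are
#'   attached as attributes `report`, `similarity`, `stress`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", sep = "", file = logf, append = TRUE)
  stage <- "init"
  tryCatch({
    stage <- "dataset"
    dataset <- if (!is.null(cfg$synthetic)) {
      log_line("generating synthetic dataset")
      generate_dataset(cfg$synthetic, file.path(cfg$out_dir, "images"))
    } else load_dataset(cfg$root)
    log_line("dataset: ", nrow(dataset$records), " images, ",
             length(dataset$label_map), " classes")

    stage <- "extract"
    fm <- extract_features(dataset, cfg$cfg)
    feat <- data.frame(path = dataset$records$path, label = fm$y,
                       fm$X, check.names = FALSE)
    utils::write.csv(feat, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(segments = fm$segments, config = unclass(cfg$cfg)),
      file.path(cfg$out_dir, "features_meta.json"),
      auto_unbox = TRUE, digits = NA)
    log_line("extracted ", ncol(fm$X), "-dim fused features")

    stage <- "evaluate"
    report <- kfold_evaluate(fm, as.list(cfg$classifiers), k = cfg$folds,
                             seed = cfg$seed, smote_mode = cfg$smote_mode,
                             smote_k = cfg$smote_k)
    log_line("evaluation done")

    stage <- "similarity"
    tr <- smote_resample(fm, cfg$smote_k, seed = derive_seed(cfg$seed, 7))
    std <- standardize(tr)
    S <- interclass_similarity(class_mean_vectors(std$train))
    utils::write.csv(as.data.frame(unclass(S)),
                     file.path(cfg$out_dir, "similarity.csv"))
    write_similarity_heatmap(S, file.path(cfg$out_dir, "similarity.png"))

    stress_tab <- NULL
    if (!is.null(cfg$stress)) {
      stage <- "stress"
      fit <- fit_pipeline(dataset, cfg$classifiers[1], cfg$cfg,
                          cfg$fractions, seed = cfg$seed)
      stress_tab <- stress_suite(fit, cfg$stress)
      utils::write.csv(stress_tab, file.path(cfg$out_dir, "stress.csv"),
                       row.names = FALSE)
      log_line("stress testing done")
    }

    stage <- "report"
    write_report(report, S, cfg$out_dir)
    jsonlite::write_json(config_as_list(cfg),
                         file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log_line("run complete")
    out <- cfg$out_dir
    attr(out, "report") <- report
    attr(out, "similarity") <- S
    attr(out, "stress") <- stress_tab
    invisible(out)
  }, error = function(e) {
    log_line("FAILED at stage '", stage, "': ", conditionMessage(e))
    lf_abort("pipeline failed at stage '", stage, "': ",
             conditionMessage(e))
  })
}

#' Serialize an evaluation report
#'
#' Writes `report.json` (machine-readable: per-classifier, per-fold
#' confusion matrices and metrics plus CV aggregates) and `report.md`
#' (a human summary with one row per classifier and a per-class metric
#' block).
#'
#' @param report an `evaluation_report` from [kfold_evaluate()].
#' @param similarity a `similarity_matrix` (or `NULL`).
#' @param out output directory.
#' @return invisible vector of the files written.
#' @export
write_report <- function(report, similarity, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  js <- list(k = report$k, seed = report$seed,
             smote_mode = report$smote_mode,
             class_names = report$class_names,
             classifiers = lapply(report$classifiers, function(r) list(
               name = r$spec$name, hyper = r$spec$hyper,
               seed = r$spec$seed,
               cv = r$cv,
               folds = lapply(r$folds, function(f) list(
                 CM = f$CM, n_test = f$n_test, accuracy = f$accuracy,
                 precision = f$precision, recall = f$recall, f1 = f$f1)))))
  jf <- file.path(out, "report.json")
  jsonlite::write_json(js, jf, auto_unbox = TRUE, digits = NA)

  md <- c("# Evaluation report", "",
          sprintf("%d-fold cross-validation, SMOTE mode `%s`, seed %d.",
                  report$k, report$smote_mode, report$seed), "",
          "| Classifier | Accuracy | Macro P | Macro R | Macro F1 |",
          "|---|---|---|---|---|")
  for (nm in names(report$classifiers)) {
    cv <- report$classifiers[[nm]]$cv
    md <- c(md, sprintf("| %s | %.4f | %.4f | %.4f | %.4f |", nm,
                        cv$accuracy, cv$macro_precision, cv$macro_recall,
                        cv$macro_f1))
  }
  md <- c(md, "", "## Per-class metrics (fold means)", "")
  for (nm in names(report$classifiers)) {
    r <- report$classifiers[[nm]]
    P <- rowMeans(sapply(r$folds, `[[`, "precision"))
    R <- rowMeans(sapply(r$folds, `[[`, "recall"))
    F1 <- rowMeans(sapply(r$folds, `[[`, "f1"))
    md <- c(md, paste0("### ", nm), "",
            "| Class | Precision | Recall | F1 |", "|---|---|---|---|",
            sprintf("| %s | %.4f | %.4f | %.4f |",
                    report$class_names, P, R, F1), "")
  }
  if (!is.null(similarity)) {
    md <- c(md, "## Most confusable class pairs", "",
            "| Class A | Class B | Similarity |", "|---|---|---|")
    tp <- top_confusable_pairs(similarity, top_n = 5)
    md <- c(md, sprintf("| %s | %s | %.4f |", tp$class_a, tp$class_b,
                        tp$similarity))
  }
  mf <- file.path(out, "report.md")
  writeLines(md, mf)
  invisible(c(jf, mf))
}

#' Command-line entry point
#'
#' Subcommands: `generate-fixtures`, `extract`, `evaluate`, `similarity`,
#' `stress`, `run`.  Installed as `inst/cli/leaffusion`; run
#' `Rscript <path>/leaffusion <subcommand> --help`-style invocations via
#' this function.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
leaffusion_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: leaffusion <command> [options]",
    "  generate-fixtures --out <dir> [--classes k] [--images n] [--seed s]",
    "  extract   --root <dir> --out <features.csv> [--resize n]",
    "  evaluate  --features <csv> [--classifiers a,b] [--folds k] [--seed s] --out <dir>",
    "  similarity --features <csv> --out <sim.csv> [--heatmap <png>]",
    "  stress    --root <dir> [--classifier name] --conditions <spec> --out <csv>",
    "  run       --root <dir> --out <dir> [--classifiers a,b] [--seed s] [--stress spec]",
    sep = "\n")
  known <- c("generate-fixtures", "extract", "evaluate", "similarity",
             "stress", "run")
  if (length(args) == 0 || !args[1] %in% known) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0) default else args[i + 1]
  }
  status <- tryCatch({
    switch(cmd,
      "generate-fixtures" = {
        k <- as.integer(opt("classes", "5"))
        spec <- synthetic_dataset_spec(
          demo_class_specs(k),
          images_per_class = as.integer(opt("images", "40")),
          seed = as.integer(opt("seed", "1")))
        generate_dataset(spec, opt("out", "fixtures"))
      },
      "extract" = {
        cfg <- descriptor_config(
          resize = rep(as.integer(opt("resize", "128")), 2))
        fm <- extract_features(load_dataset(opt("root")), cfg)
        utils::write.csv(data.frame(label = fm$y, fm$X, check.names = FALSE),
                         opt("out", "features.csv"), row.names = FALSE)
      },
      "evaluate" = {
        fm <- read_features_csv(opt("features"))
        rep_ <- kfold_evaluate(
          fm, as.list(strsplit(opt("classifiers", "RandomForest"), ",")[[1]]),
          k = as.integer(opt("folds", "5")),
          seed = as.integer(opt("seed", "42")))
        write_report(rep_, NULL, opt("out", "."))
        print(rep_)
      },
      "similarity" = {
        fm <- read_features_csv(opt("features"))
        S <- interclass_similarity(class_mean_vectors(standardize(fm)$train))
        utils::write.csv(as.data.frame(unclass(S)), opt("out", "sim.csv"))
        hm <- opt("heatmap")
        if (!is.null(hm)) write_similarity_heatmap(S, hm)
      },
      "stress" = {
        fit <- fit_pipeline(load_dataset(opt("root")),
                            opt("classifier", "RandomForest"),
                            seed = as.integer(opt("seed", "42")))
        tab <- stress_suite(fit, opt("conditions", ""))
        utils::write.csv(tab, opt("out", "stress.csv"), row.names = FALSE)
      },
      "run" = {
        cfg <- pipeline_config(
          root = opt("root"),
          classifiers = strsplit(
            opt("classifiers", "RandomForest,GradientBoost,SVM,SoftVote"),
            ",")[[1]],
          seed = as.integer(opt("seed", "42")),
          stress = opt("stress"),
          out_dir = opt("out", "leaffusion_run"))
        run_pipeline(cfg)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# read a features CSV written by `extract` back into a feature_matrix
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  drop <- intersect(c("path", "label"), names(df))
  X <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  y <- as.integer(df$label)
  feature_matrix(X, y, as.character(sort(unique(y))))
}
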
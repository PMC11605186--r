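#' Configuration of an end-to-end run
#'
#' A single configuration object with per-stage blocks. Every stage draws
#' its randomness from a seed derived deterministically from the global
#' seed and the stage name ([stage_seed()]), so runs are reproducible and
#' stages are independently re-runnable.
#'
#' @param outdir output directory for all artifacts.
#' @param seed global integer seed.
#' @param generator a [generator_params()] block (its own seed is
#'   overridden by the derived stage seed).
#' @param min_studies study-support threshold of the high-confidence
#'   filter (1 disables it).
#' @param lor_cut,q_cut pan-cancer selection thresholds.
#' @param dcn optional [dcn_config()] overrides (list of fields).
#' @param cnn optional [cnn_config()] overrides (list of fields).
#' @param interpret_n_permutations,interpret_background,interpret_samples
#'   attribution budget.
#' @param stages named logical toggles: simulate, select, encode, train,
#'   evaluate, interpret.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L,
                       generator = generator_params(),
                       min_studies = 2L, lor_cut = 2, q_cut = 0.05,
                       dcn = list(), cnn = list(),
                       interpret_n_permutations = 20L,
                       interpret_background = 50L,
                       interpret_samples = 100L,
                       stages = list()) {
  st <- utils::modifyList(list(simulate = TRUE, select = TRUE, encode = TRUE,
                               train = TRUE, evaluate = TRUE,
                               interpret = TRUE), stages)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 generator = generator, min_studies = as.integer(min_studies),
                 lor_cut = lor_cut, q_cut = q_cut, dcn = dcn, cnn = cnn,
                 interpret_n_permutations = as.integer(interpret_n_permutations),
                 interpret_background = as.integer(interpret_background),
                 interpret_samples = as.integer(interpret_samples),
                 stages = st),
            class = "run_config")
}

# append one structured JSONL event to the run log
.log_event <- function(logfile, stage, level, message, ...) {
  rec <- c(list(stage = stage, level = level, message = message), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = logfile, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> select -> encode -> train (sequence baseline,
#' genomic-only and integrated deep cross networks) -> evaluate ->
#' interpret, writing every declared artifact under `config$outdir` plus a
#' JSONL event log and a manifest of file digests. Idempotent under an
#' identical config and seed. Stages toggled off are skipped along with
#' their outputs; downstream stages requiring them abort with the stage
#' name.
#'
#' @param config a [run_config()].
#' @return list(manifest, results): `results` holds the catalog,
#'   selection, dataset, trained models, test AUROCs and the attribution
#'   report; `manifest` the config snapshot, schema hash, file digests and
#'   session metadata.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "log.jsonl")
  if (file.exists(logfile)) unlink(logfile)
  st <- config$stages
  res <- list()
  run_stage <- function(name, enabled, fn) {
    if (!enabled) {
      .log_event(logfile, name, "info", "stage skipped")
      return(NULL)
    }
    .log_event(logfile, name, "info", "stage started")
    out <- tryCatch(fn(), error = function(e) {
      .log_event(logfile, name, "error", conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    .log_event(logfile, name, "info", "stage finished")
    out
  }
  schema <- feature_schema()

  res$simulate <- run_stage("simulate", st$simulate, function() {
    gp <- config$generator
    gp$seed <- stage_seed(config$seed, "simulate")
    catalog <- generate_catalog(gp)
    features <- generate_features(catalog, gp, schema)
    write_fixture(catalog, features, file.path(config$outdir, "fixture"), gp)
    list(catalog = catalog, features = features, params = gp)
  })

  res$select <- run_stage("select", st$select, function() {
    if (is.null(res$simulate)) stop("requires the simulate stage")
    catalog <- filter_high_confidence(res$simulate$catalog,
                                      config$min_studies)
    assoc <- catalog_association(catalog)
    labeled <- select_pan_cancer(assoc, config$lor_cut, config$q_cut)
    balanced <- balance_sample(labeled,
                               seed = stage_seed(config$seed, "select"))
    assoc$label <- ifelse(assoc$site_id %in% balanced$positives, "positive",
                   ifelse(assoc$site_id %in% balanced$negatives, "negative",
                          "unlabeled"))
    write_selection(assoc, file.path(config$outdir, "selection.tsv"))
    .log_event(logfile, "select", "info", "selection sizes",
               n_positive = length(balanced$positives),
               n_negative = length(balanced$negatives))
    list(catalog = catalog, association = assoc, labeled = balanced)
  })

  res$encode <- run_stage("encode", st$encode, function() {
    if (is.null(res$select)) stop("requires the select stage")
    encode_labeled_dataset(res$select$catalog, res$simulate$features,
                           res$select$labeled,
                           seed = stage_seed(config$seed, "encode"))
  })

  res$train <- run_stage("train", st$train, function() {
    if (is.null(res$encode)) stop("requires the encode stage")
    ds <- res$encode
    tseed <- stage_seed(config$seed, "train")
    fits <- list()
    for (mode in c("sequence_cnn", "genomic_only", "integrated")) {
      cfg <- if (mode == "sequence_cnn") {
        do.call(cnn_config, utils::modifyList(list(seed = tseed), config$cnn))
      } else {
        base <- list(input_dim = if (mode == "genomic_only")
          ncol(ds$genomic) else ncol(ds$one_hot) + ncol(ds$genomic),
          seed = tseed)
        do.call(dcn_config, utils::modifyList(base, config$dcn))
      }
      fits[[mode]] <- train_model(ds, mode = mode, config = cfg)
      hist <- fits[[mode]]$history
      for (r in seq_len(nrow(hist)))
        .log_event(logfile, "train", "metric", mode,
                   epoch = hist$epoch[r], train_loss = hist$train_loss[r],
                   val_loss = hist$val_loss[r])
    }
    fits
  })

  res$evaluate <- run_stage("evaluate", st$evaluate, function() {
    if (is.null(res$train)) stop("requires the train stage")
    aucs <- vapply(res$train, function(fit) {
      pr <- predict_split(fit, res$encode, "test")
      auroc(pr$scores, pr$labels)
    }, numeric(1))
    jsonlite::write_json(as.list(aucs),
                         file.path(config$outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    aucs
  })

  res$interpret <- run_stage("interpret", st$interpret, function() {
    if (is.null(res$train)) stop("requires the train stage")
    rep <- attribute_model(res$train$integrated, res$encode,
                           mode = "sampled",
                           n_permutations = config$interpret_n_permutations,
                           background_size = config$interpret_background,
                           n_samples = config$interpret_samples,
                           seed = stage_seed(config$seed, "interpret"))
    phi_df <- cbind(site_id = rep$site_ids,
                    as.data.frame(rep$phi, check.names = FALSE))
    utils::write.table(phi_df, file.path(config$outdir, "attribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- data.frame(feature = names(rep$mean_abs),
                       mean_abs = unname(rep$mean_abs),
                       rank = match(names(rep$mean_abs), rep$ranking),
                       sign_cor = rep$sign_summary$sign_cor)
    utils::write.table(summ,
                       file.path(config$outdir, "attribution_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$outdir, "manifest.json"))
  strip_class <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_class) else x
  }
  manifest <- list(
    config = strip_class(config),
    schema_hash = schema_hash(schema),
    digests = as.list(tools::md5sum(files)),
    version = as.character(utils::packageVersion("epicrossnet"))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, results = res)
}
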
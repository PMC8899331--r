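#' Pipeline run configuration
#'
#' Defaults follow the reference workflow: MDS variance threshold 0.96
#' capped at 50 dimensions, t-SNE perplexity 20 with 1,500 iterations and 10
#' restarts, k = 8 sub-categories, reference group AD.
#'
#' @param vectors path to a word2vec file (text or binary), or `NULL` with
#'   `simulate = TRUE`.
#' @param transcripts path to the long-format transcript CSV, or `NULL`
#'   with `simulate = TRUE`.
#' @param manual_labels optional TSV path; overrides k-means labeling.
#' @param vector_format `"text"` or `"binary"`.
#' @param simulate generate inputs with [default_paper_like_scenario].
#' @param out_dir output directory (created if needed).
#' @param variance_threshold,max_dims MDS controls.
#' @param perplexity,n_iter,n_restarts t-SNE controls.
#' @param k number of k-means sub-categories.
#' @param reference reference diagnostic group.
#' @param seed master seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(vectors = NULL, transcripts = NULL,
                       manual_labels = NULL,
                       vector_format = c("text", "binary"),
                       simulate = FALSE, out_dir = "fluenspace-out",
                       variance_threshold = 0.96, max_dims = 50L,
                       perplexity = 20, n_iter = 1500L, n_restarts = 10L,
                       k = 8L, reference = "AD", seed = 0L) {
  vector_format <- match.arg(vector_format)
  if (!simulate) {
    if (is.null(vectors)) stop("vectors path required unless simulate = TRUE")
    if (is.null(transcripts))
      stop("transcripts path required unless simulate = TRUE")
  }
  structure(list(vectors = vectors, transcripts = transcripts,
                 manual_labels = manual_labels,
                 vector_format = vector_format, simulate = simulate,
                 out_dir = out_dir, variance_threshold = variance_threshold,
                 max_dims = as.integer(max_dims), perplexity = perplexity,
                 n_iter = as.integer(n_iter),
                 n_restarts = as.integer(n_restarts), k = as.integer(k),
                 reference = reference, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: build-space (cosine distances) -> MDS -> t-SNE map -> labeling
#' (k-means or manual) -> per-participant metrics -> group analysis
#' (correlations, ANOVA/MANOVA, the four-model multinomial suite). All
#' artifacts are written under `cfg$out_dir` along with a JSON manifest
#' (package version, seeds, parameters, restart KL table, timestamps)
#' sufficient to re-run the seeded stages bit-identically. A stage failure
#' aborts with the stage name; artifacts of completed stages remain on disk.
#'
#' @param cfg a [run_config].
#' @return invisibly, a list with all in-memory stage results
#'   (`distances`, `mds`, `map`, `labeling`, `metrics`, `correlations`,
#'   `group_report`, `models`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "fluenspace",
                   version = as.character(utils::packageVersion("fluenspace")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   parameters = unclass(cfg), stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), tic, units = "secs")))
    res
  }

  inputs <- stage("inputs", {
    if (cfg$simulate) {
      scen <- default_paper_like_scenario(cfg$seed)
      write_word_vectors(scen$space$vectors,
                         file.path(cfg$out_dir, "vectors.txt"))
      write_transcripts(scen$records,
                        file.path(cfg$out_dir, "transcripts.csv"))
      write_labels_tsv(scen$labeling,
                       file.path(cfg$out_dir, "true_labels.tsv"))
      list(vectors = scen$space$vectors, records = scen$records)
    } else {
      list(vectors = load_word_vectors(cfg$vectors, cfg$vector_format),
           records = read_transcripts(cfg$transcripts))
    }
  })

  D <- stage("build-space", {
    D <- cosine_distance_matrix(inputs$vectors)
    write_distance_csv(D, file.path(cfg$out_dir, "distances.csv"))
    D
  })
  mds <- stage("mds", classical_mds(D, cfg$variance_threshold, cfg$max_dims))
  map <- stage("map", {
    map <- embed_tsne(mds, perplexity = cfg$perplexity, n_iter = cfg$n_iter,
                      n_restarts = cfg$n_restarts, seed = cfg$seed)
    write_map_csv(map, file.path(cfg$out_dir, "map.csv"))
    map
  })
  manifest$mds <- list(k_selected = mds$k_selected,
                       variance_explained = mds$variance_explained)
  manifest$tsne <- list(kl_divergence = map$kl_divergence,
                        winning_seed = map$seed,
                        restart_log = map$restart_log)
  labeling <- stage("label", {
    lab <- if (!is.null(cfg$manual_labels))
      load_manual_labels(cfg$manual_labels, map$items)
    else cluster_kmeans(map, k = cfg$k, seed = cfg$seed)
    write_labels_tsv(lab, file.path(cfg$out_dir, "labels.tsv"))
    lab
  })
  metrics <- stage("metrics", {
    m <- cohort_metrics_table(inputs$records, labeling)
    utils::write.csv(m, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    m
  })
  analysis <- stage("analyze", {
    corr <- spearman_table(metrics)
    utils::write.csv(corr$rho, file.path(cfg$out_dir, "correlations.csv"))
    rep <- group_difference_report(metrics)
    suite <- model_suite(metrics, reference = cfg$reference)
    utils::write.csv(suite$comparison,
                     file.path(cfg$out_dir, "models.csv"), row.names = FALSE)
    utils::write.csv(
      do.call(rbind, lapply(suite$models, `[[`, "coefficients")),
      file.path(cfg$out_dir, "coefficients.csv"), row.names = FALSE)
    for (id in names(suite$confusions))
      utils::write.csv(suite$confusions[[id]]$counts,
                       file.path(cfg$out_dir, paste0("confusion_", id, ".csv")))
    anova_json <- lapply(rep$anova, function(a)
      list(F = a$statistic, df = unname(a$df), p = a$p_value,
           partial_eta_sq = a$partial_eta_sq))
    jsonlite::write_json(
      list(anova = anova_json,
           manova = list(F = rep$manova$statistic,
                         df = unname(rep$manova$df),
                         p = rep$manova$p_value,
                         wilks_lambda = rep$manova$wilks_lambda,
                         partial_eta_sq = rep$manova$partial_eta_sq,
                         dependents = rep$manova_dependents)),
      file.path(cfg$out_dir, "group_tests.json"),
      auto_unbox = TRUE, digits = NA)
    list(correlations = corr, group_report = rep, models = suite)
  })
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(distances = D, mds = mds, map = map, labeling = labeling,
                 metrics = metrics, correlations = analysis$correlations,
                 group_report = analysis$group_report,
                 models = analysis$models, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `build-space`, `map`, `label`, `stability`, `metrics`,
#' `analyze`, `simulate`, `run`. Run `fluenspace_main(c("run", "--help"))`
#' for per-command options. The installed `exec/fluenspace` script forwards
#' `commandArgs(trailingOnly = TRUE)` here.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
fluenspace_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fluenspace <command> [options]",
    "commands: build-space | map | label | stability | metrics | analyze | simulate | run",
    "          --version", sep = "\n")
  if (length(argv) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- argv[1]; rest <- argv[-1]
  if (cmd %in% c("--version", "version")) {
    cat("fluenspace", as.character(utils::packageVersion("fluenspace")), "\n")
    return(invisible(0L))
  }
  status <- tryCatch({
    switch(cmd,
      "build-space" = cli_build_space(rest),
      "map" = cli_map(rest),
      "label" = cli_label(rest),
      "stability" = cli_stability(rest),
      "metrics" = cli_metrics(rest),
      "analyze" = cli_analyze(rest),
      "simulate" = cli_simulate(rest),
      "run" = cli_run(rest),
      { message("unknown command: ", cmd, "\n", usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(as.integer(status %||% 0L))
}

cli_parse <- function(spec, args) {
  parser <- optparse::OptionParser(option_list = spec)
  optparse::parse_args(parser, args = args)
}

cli_build_space <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--vectors", type = "character"),
    optparse::make_option("--items", type = "character", default = NULL),
    optparse::make_option("--format", type = "character", default = "text"),
    optparse::make_option("--skip-missing", action = "store_true",
                          default = FALSE, dest = "skip_missing"),
    optparse::make_option("--out", type = "character",
                          default = "distances.csv")), args)
  items <- if (!is.null(o$items)) readLines(o$items) else NULL
  vs <- load_word_vectors(o$vectors, o$format, items = items,
                          skip_missing = o$skip_missing)
  write_distance_csv(cosine_distance_matrix(vs), o$out)
  message("wrote ", o$out, " (", length(vs$items), " items)")
  0L
}

cli_map <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--distances", type = "character"),
    optparse::make_option("--threshold", type = "double", default = 0.96),
    optparse::make_option("--max-dims", type = "integer", default = 50L,
                          dest = "max_dims"),
    optparse::make_option("--perplexity", type = "double", default = 20),
    optparse::make_option("--iters", type = "integer", default = 1500L),
    optparse::make_option("--restarts", type = "integer", default = 10L),
    optparse::make_option("--seed", type = "integer", default = 0L),
    optparse::make_option("--out", type = "character", default = "map.csv")),
    args)
  D <- read_distance_csv(o$distances)
  mds <- classical_mds(D, o$threshold, o$max_dims)
  map <- embed_tsne(mds, o$perplexity, o$iters, o$restarts, o$seed)
  write_map_csv(map, o$out)
  message(sprintf("wrote %s (KL = %.4f, MDS k = %d)", o$out,
                  map$kl_divergence, mds$k_selected))
  0L
}

cli_label <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--map", type = "character"),
    optparse::make_option("--k", type = "integer", default = 8L),
    optparse::make_option("--manual", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 0L),
    optparse::make_option("--out", type = "character",
                          default = "labels.tsv")), args)
  df <- utils::read.csv(o$map)
  map <- structure(list(items = df$item,
                        coords2d = as.matrix(df[, c("x", "y")])),
                   class = "semantic_map")
  rownames(map$coords2d) <- df$item
  lab <- if (!is.null(o$manual)) load_manual_labels(o$manual, df$item)
  else cluster_kmeans(map, k = o$k, seed = o$seed)
  write_labels_tsv(lab, o$out)
  message("wrote ", o$out, " (", length(lab$labels), " sub-categories)")
  0L
}

cli_stability <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--distances", type = "character"),
    optparse::make_option("--perplexities", type = "character",
                          default = "5,20,35,50"),
    optparse::make_option("--seeds", type = "character", default = "0,1,2"),
    optparse::make_option("--k", type = "integer", default = 8L),
    optparse::make_option("--iters", type = "integer", default = 1500L),
    optparse::make_option("--threshold", type = "double", default = 0.96),
    optparse::make_option("--out", type = "character",
                          default = "stability.csv")), args)
  D <- read_distance_csv(o$distances)
  mds <- classical_mds(D, o$threshold)
  rep <- stability_analysis(mds,
                            as.numeric(strsplit(o$perplexities, ",")[[1]]),
                            as.integer(strsplit(o$seeds, ",")[[1]]),
                            k = o$k, n_iter = o$iters)
  utils::write.csv(rep$ari_matrix, o$out)
  print(rep)
  0L
}

cli_metrics <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--transcripts", type = "character"),
    optparse::make_option("--labels", type = "character"),
    optparse::make_option("--collapse-repetitions", action = "store_true",
                          default = FALSE, dest = "collapse"),
    optparse::make_option("--skip-unlabeled", action = "store_true",
                          default = FALSE, dest = "skip"),
    optparse::make_option("--out", type = "character",
                          default = "metrics.csv")), args)
  records <- read_transcripts(o$transcripts)
  df <- utils::read.table(o$labels, sep = "\t",
                          col.names = c("item", "label"),
                          colClasses = "character")
  lab <- subcategory_labeling(df$item, df$label, source = "manual")
  m <- cohort_metrics_table(records, lab, skip_unlabeled = o$skip,
                            collapse_repetitions = o$collapse)
  utils::write.csv(m, o$out, row.names = FALSE)
  message("wrote ", o$out, " (", nrow(m), " participants)")
  0L
}

cli_analyze <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--metrics", type = "character"),
    optparse::make_option("--reference", type = "character", default = "AD"),
    optparse::make_option("--out", type = "character", default = "report")),
    args)
  metrics <- utils::read.csv(o$metrics)
  metrics$group <- factor(metrics$group, levels = fluency_groups())
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  corr <- spearman_table(metrics)
  utils::write.csv(corr$rho, file.path(o$out, "correlations.csv"))
  suite <- model_suite(metrics, reference = o$reference)
  utils::write.csv(suite$comparison, file.path(o$out, "models.csv"),
                   row.names = FALSE)
  for (id in names(suite$confusions))
    utils::write.csv(suite$confusions[[id]]$counts,
                     file.path(o$out, paste0("confusion_", id, ".csv")))
  print(suite)
  0L
}

cli_simulate <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--scenario", type = "character",
                          default = "paper-like"),
    optparse::make_option("--seed", type = "integer", default = 0L),
    optparse::make_option("--out", type = "character", default = "data")),
    args)
  if (!identical(o$scenario, "paper-like"))
    stop("unknown scenario: ", o$scenario)
  scen <- default_paper_like_scenario(o$seed)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  write_word_vectors(scen$space$vectors, file.path(o$out, "vectors.txt"))
  write_transcripts(scen$records, file.path(o$out, "transcripts.csv"))
  write_labels_tsv(scen$labeling, file.path(o$out, "true_labels.tsv"))
  message("wrote simulated inputs to ", o$out)
  0L
}

cli_run <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--vectors", type = "character", default = NULL),
    optparse::make_option("--transcripts", type = "character", default = NULL),
    optparse::make_option("--manual-labels", type = "character",
                          default = NULL, dest = "manual_labels"),
    optparse::make_option("--format", type = "character", default = "text"),
    optparse::make_option("--simulate", action = "store_true",
                          default = FALSE),
    optparse::make_option("--threshold", type = "double", default = 0.96),
    optparse::make_option("--perplexity", type = "double", default = 20),
    optparse::make_option("--iters", type = "integer", default = 1500L),
    optparse::make_option("--restarts", type = "integer", default = 10L),
    optparse::make_option("--k", type = "integer", default = 8L),
    optparse::make_option("--reference", type = "character", default = "AD"),
    optparse::make_option("--seed", type = "integer", default = 0L),
    optparse::make_option("--out", type = "character",
                          default = "fluenspace-out")), args)
  cfg <- run_config(vectors = o$vectors, transcripts = o$transcripts,
                    manual_labels = o$manual_labels, vector_format = o$format,
                    simulate = o$simulate, out_dir = o$out,
                    variance_threshold = o$threshold,
                    perplexity = o$perplexity, n_iter = o$iters,
                    n_restarts = o$restarts, k = o$k,
                    reference = o$reference, seed = o$seed)
  res <- run_pipeline(cfg)
  message("pipeline complete; report in ", o$out)
  print(res$models)
  0L
}
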
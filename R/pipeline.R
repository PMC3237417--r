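# End-to-end pipeline: synthesize (or load) a bundle, classify origins,
# detect synteny blocks, compute the feature panel, and run the
# relationship statistics, writing one report directory.

#' Default pipeline configuration
#'
#' Single nested schema holding every tunable threshold with the source
#' analyses' values as defaults; serialisable to/from YAML.
#'
#' @param seed master seed; stage seeds are derived from it
#' @param reps Monte Carlo repetitions for the intersection matrix
#' @return nested list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, reps = 100000L) {
  cfg <- list(
    seed = as.integer(seed),
    synth = unclass(synth_config(seed = seed)),
    classify = unclass(classify_config()),
    stats = list(reps = as.integer(reps), folds = 5L,
                 min_set_size = 10L),
    bundle_dir = NULL)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file
#' @return `pipeline_config` list (missing entries filled with defaults)
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  for (sec in c("synth", "classify", "stats")) {
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  if (!is.null(user$bundle_dir)) cfg$bundle_dir <- user$bundle_dir
  if (!is.null(user$reps)) cfg$stats$reps <- user$reps
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: synthesize (or load `bundle_dir`), classify, chain synteny
#' blocks, compute features, build comparison tables, and test the
#' pairwise relationships of the origin-mode sets. Writes calls.tsv,
#' blocks.tsv, features.tsv, fig1_counts.tsv, fig2A.tsv, fig2B.tsv,
#' table1.tsv, table2.tsv and manifest.json into `out_dir`. Deterministic
#' for a fixed config.
#'
#' @param config a [pipeline_config()], or path to a YAML file
#' @param out_dir report directory (created if needed)
#' @return invisibly, a list with the in-memory results
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  bundle <- if (!is.null(config$bundle_dir)) {
    read_bundle(config$bundle_dir)
  } else {
    scfg <- do.call(synth_config, config$synth)
    generate_genome(scfg, file.path(out_dir, "bundle"))
  }
  ccfg <- do.call(classify_config, config$classify)

  result <- classify_bundle(bundle, ccfg)
  features <- compute_features(bundle, result, ccfg)
  tables <- build_tables(bundle, result, features, ccfg)

  # Fig 2A-style intersection matrix over the five non-OT label sets
  m <- label_matrix(result$calls)
  labs <- c("TR", "PR", "ID", "TD", "SD")
  fig2a <- list()
  fig2b <- list()
  pair_seed <- config$seed
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      s1 <- m[, labs[i]]; s2 <- m[, labs[j]]
      M <- nrow(m)
      if (M == 0 || sum(s1) == 0 || sum(s2) == 0) next
      pair_seed <- (pair_seed + 7L) %% 2147483647L
      it <- monte_carlo_intersection(M, sum(s1), sum(s2), sum(s1 & s2),
                                     reps = config$stats$reps,
                                     seed = pair_seed)
      fig2a[[length(fig2a) + 1L]] <- data.frame(
        set1 = labs[i], set2 = labs[j], M = M, m = it$m, n = it$n,
        N = it$N, expected = it$expected, p_empirical = it$p_empirical,
        p_analytic = it$p_analytic, direction = it$direction)
      min_cv <- max(config$stats$min_set_size, config$stats$folds)
      if (sum(s1) >= min_cv && sum(s2) >= min_cv) {
        f1 <- features[match(result$calls$mirna_id[s1],
                             features$mirna_id),
                       setdiff(names(features), "mirna_id")]
        f2 <- features[match(result$calls$mirna_id[s2],
                             features$mirna_id),
                       setdiff(names(features), "mirna_id")]
        f1 <- f1[, vapply(f1, is.numeric, TRUE) |
                     vapply(f1, is.logical, TRUE), drop = FALSE]
        f2 <- f2[, names(f1), drop = FALSE]
        cv <- cv_similarity(f1, f2, seed = pair_seed,
                            folds = config$stats$folds)
        fig2b[[length(fig2b) + 1L]] <- data.frame(
          set1 = labs[i], set2 = labs[j], n1 = sum(s1), n2 = sum(s2),
          mean_accuracy = cv$mean_accuracy,
          t(cv$accuracy_per_classifier))
      }
    }
  }
  fig2a <- if (length(fig2a)) do.call(rbind, fig2a) else data.frame()
  fig2b <- if (length(fig2b)) do.call(rbind, fig2b) else data.frame()

  blocks <- if (length(result$chains)) {
    do.call(rbind, lapply(seq_along(result$chains), function(ci) {
      a <- result$chains[[ci]]$anchors
      data.frame(chain = ci, gene_a = a$gene_a, gene_b = a$gene_b,
                 pos_a = a$pos_a, pos_b = a$pos_b, score = a$score)
    }))
  } else {
    data.frame(chain = integer(0), gene_a = character(0),
               gene_b = character(0), pos_a = numeric(0),
               pos_b = numeric(0), score = numeric(0))
  }

  write_tsv(result$calls, file.path(out_dir, "calls.tsv"))
  write_tsv(blocks, file.path(out_dir, "blocks.tsv"))
  write_tsv(features, file.path(out_dir, "features.tsv"))
  write_tsv(result$counts, file.path(out_dir, "fig1_counts.tsv"))
  write_tsv(fig2a, file.path(out_dir, "fig2A.tsv"))
  write_tsv(fig2b, file.path(out_dir, "fig2B.tsv"))
  write_tsv(tables$table1, file.path(out_dir, "table1.tsv"))
  write_tsv(tables$table2, file.path(out_dir, "table2.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirorigin")),
    config_hash = digest::digest(config),
    seed = config$seed,
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.tsv$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  recovery <- if (!is.null(bundle$truth) && nrow(bundle$truth) > 0) {
    evaluate_recovery(result$calls, bundle$truth)
  } else NULL

  invisible(list(bundle = bundle, result = result, features = features,
                 tables = tables, fig2a = fig2a, fig2b = fig2b,
                 recovery = recovery, out_dir = out_dir))
}
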
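# End-to-end orchestration: synth/preprocess -> adversarial training ->
# generation -> similarity evaluation -> compressed-sensing benchmark,
# driven by a YAML (or list) configuration, with a JSON manifest so runs
# are reproducible.

pipeline_sections <- c("seed", "synthetic", "preprocess", "generator",
                       "critic", "train", "generate", "metrics", "cs")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown configuration key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

call_with <- function(fn, args, where) {
  check_keys(args, names(formals(fn)), where)
  do.call(fn, args)
}

#' Run the full workflow from a configuration
#'
#' Executes the enabled stages in order — `synthetic` (surrogate frames),
#' `preprocess` (normalize + split), `train` (adversarial training),
#' `generate`, `metrics` (similarity report) and `cs` (augmentation
#' benchmark) — writing artifacts and a run manifest to `out_dir`.
#' Sections absent from the configuration are skipped; unknown keys are
#' errors. Every random draw derives from the top-level `seed`.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, pipeline_sections, "top level")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "eeggan",
                   version = as.character(utils::packageVersion("eeggan")),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   seed = seed, config = config, stages = list())
  t_stage <- function(name, fun) {
    t0 <- Sys.time()
    outs <- fun()
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      outputs = outs)
  }
  frames <- NULL; train_fs <- NULL; test_fs <- NULL
  trained <- NULL; generated <- NULL

  if (!is.null(config$synthetic)) {
    t_stage("synthetic", function() {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- sub_seed(seed, 1L)
      if (!is.null(args$bands)) args$bands <- do.call(rbind, args$bands)
      cfg <- call_with(synthetic_config, args, "synthetic")
      frames <<- generate_frames(cfg)
      f <- file.path(out_dir, "frames.csv")
      write_frames_csv(frames, f)
      f
    })
  }
  if (!is.null(config$preprocess)) {
    if (is.null(frames)) stop("stage preprocess: no frames available")
    t_stage("preprocess", function() {
      args <- config$preprocess
      check_keys(args, c("train_fraction", "frame_len"), "preprocess")
      if (!is.null(args$frame_len)) {
        frames <<- segment_frames(as.numeric(t(frames$frames)),
                                  args$frame_len)
      }
      frames <<- normalize_frames(frames)
      sp <- split_frames(frames,
                         train_fraction = args$train_fraction %||% 0.7,
                         seed = sub_seed(seed, 2L))
      train_fs <<- sp$train; test_fs <<- sp$test
      character(0)
    })
  }
  if (!is.null(config$train)) {
    if (is.null(train_fs)) stop("stage train: no training frames (enable preprocess)")
    t_stage("train", function() {
      gspec <- call_with(generator_spec, config$generator %||% list(),
                         "generator")
      cspec <- call_with(critic_spec, config$critic %||% list(), "critic")
      targs <- config$train
      if (is.null(targs$seed)) targs$seed <- sub_seed(seed, 3L)
      tcfg <- call_with(train_config, targs, "train")
      trained <<- train_gan(build_generator(gspec, sub_seed(seed, 4L)),
                            build_critic(cspec, sub_seed(seed, 5L)),
                            train_fs, tcfg)
      f <- file.path(out_dir, "loss_history.csv")
      utils::write.csv(trained$history, f, row.names = FALSE)
      f
    })
  }
  if (!is.null(config$generate)) {
    if (is.null(trained)) stop("stage generate: no trained generator")
    t_stage("generate", function() {
      args <- config$generate
      check_keys(args, c("n_frames", "distribution"), "generate")
      z <- noise_batch(args$n_frames %||% nrow(test_fs$frames),
                       trained$generator$spec$noise_dim,
                       args$distribution %||% "uniform01",
                       seed = sub_seed(seed, 6L))
      generated <<- gan_generate(trained$generator, z)
      f <- file.path(out_dir, "generated.csv")
      write_frames_csv(generated, f)
      f
    })
  }
  if (!is.null(config$metrics)) {
    t_stage("metrics", function() {
      args <- config$metrics
      check_keys(args, c("aggregation"), "metrics")
      ref <- test_fs %||% frames
      if (is.null(ref)) stop("stage metrics: no reference frames")
      gen <- generated
      if (is.null(gen)) {
        # without a trained generator, self-comparison smoke report
        gen <- ref
      }
      agg <- args$aggregation %||%
        if (nrow(gen$frames) == nrow(ref$frames)) "paired_mean"
        else "nearest_real_mean"
      rep <- compare_sets(ref, gen, agg)
      f <- file.path(out_dir, "report.json")
      jsonlite::write_json(unclass(rep), f, auto_unbox = TRUE, digits = NA)
      f
    })
  }
  if (!is.null(config$cs)) {
    if (is.null(train_fs) || is.null(test_fs)) {
      stop("stage cs: needs preprocessed train/test frames")
    }
    t_stage("cs", function() {
      args <- config$cs
      check_keys(args, c("cr_grid", "fractions", "epochs", "batch_size",
                         "lr", "ones_per_column", "blocks"), "cs")
      gen <- generated %||% train_fs
      spec <- cs_resnet_spec(input_len = train_fs$frame_len,
                             blocks = args$blocks %||% 2L)
      tb <- augmentation_benchmark(
        train_fs, gen, test_fs,
        fractions = unlist(args$fractions) %||% c(0, 25, 50, 75, 100),
        cr_grid = unlist(args$cr_grid) %||% 30,
        spec = spec,
        ones_per_column = args$ones_per_column %||% 4L,
        epochs = args$epochs %||% 30L,
        batch_size = args$batch_size %||% 32L,
        lr = args$lr %||% 0.001,
        seed = sub_seed(seed, 7L))
      f1 <- file.path(out_dir, "prd_table.csv")
      utils::write.csv(tb$prd, f1)
      f2 <- file.path(out_dir, "prd_deltas.csv")
      utils::write.csv(tb$deltas, f2)
      c(f1, f2)
    })
  }
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a Markdown summary of a pipeline run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file output file (default `report.md` inside `run_dir`).
#' @return path to the rendered file.
#' @export
render_report <- function(run_dir, file = file.path(run_dir, "report.md")) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", run_dir)
  manifest <- jsonlite::read_json(mf)
  lines <- c("# eeggan run report", "",
             sprintf("- created: %s", manifest$created),
             sprintf("- seed: %s", manifest$seed),
             sprintf("- stages: %s",
                     paste(names(manifest$stages), collapse = ", ")), "")
  missing <- character(0)
  rj <- file.path(run_dir, "report.json")
  if (file.exists(rj)) {
    r <- jsonlite::read_json(rj)
    lines <- c(lines, "## Similarity metrics", "",
               "| metric | value |", "|---|---|",
               sprintf("| RMSE | %.4f |", as.numeric(r$rmse)),
               sprintf("| Frechet distance | %.4f |", as.numeric(r$fd)),
               sprintf("| DTW | %.4f |", as.numeric(r$dtw)),
               sprintf("| pairs (%s) | %d |", r$aggregation,
                       as.integer(r$n_pairs)), "")
  } else missing <- c(missing, "report.json")
  lh <- file.path(run_dir, "loss_history.csv")
  if (file.exists(lh)) {
    h <- utils::read.csv(lh)
    lines <- c(lines, "## Training", "",
               sprintf("- epochs: %d; final d_loss %.4f; final g_loss %.4f",
                       nrow(h), h$d_loss[nrow(h)], h$g_loss[nrow(h)]),
               sprintf("- critic:generator updates %d:%d",
                       h$critic_updates[nrow(h)], h$gen_updates[nrow(h)]), "")
  }
  pt <- file.path(run_dir, "prd_table.csv")
  if (file.exists(pt)) {
    tab <- utils::read.csv(pt, check.names = FALSE)
    hdr <- paste0("| ", paste(colnames(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    rows <- apply(tab, 1L, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    lines <- c(lines, "## Compressed-sensing PRD grid (%)", "",
               hdr, sep, rows, "")
  }
  if (length(missing)) {
    lines <- c(lines, "## Missing artifacts", "",
               paste0("- ", missing), "")
  }
  writeLines(lines, file)
  file
}
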
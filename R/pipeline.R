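#' Declarative run configuration
#'
#' One configuration object drives every command: data source (an ImageFolder
#' root or the synthetic generator), architecture overrides, training
#' hyperparameters, the pruning schedule and the profiling convention. All
#' randomness funnels through the stage seeds derived from `seed`, which are
#' recorded in every artifact so a run is replayable.
#'
#' @param data_root ImageFolder directory, or `NULL` to use the synthetic
#'   generator.
#' @param out_dir Directory for artifacts (`NULL` = don't write).
#' @param classes Class labels (synthetic generator classes by default).
#' @param image_size Input resolution in pixels.
#' @param n_per_class Synthetic images per class.
#' @param stage_widths,blocks_per_stage,stem_channels Architecture overrides.
#' @param epochs,retrain_epochs Training / post-pruning retraining epochs.
#' @param batch_size,weight_decay,learning_rate,momentum SGD settings (see
#'   [hyperparams()]).
#' @param schedule Local compression-ratio schedule (one entry per block).
#' @param norm_kind `"l1"` or `"l2"` channel importance.
#' @param convention FLOPs convention, `"mac"` or `"paper"`.
#' @param amplify Apply rotation/flip amplification to the training split?
#' @param seed Master seed.
#' @return A `cacp_config` list.
#' @export
run_config <- function(data_root = NULL, out_dir = NULL,
                       classes = c("HL", "SD", "RD", "SD+RD", "LSD"),
                       image_size = 64L, n_per_class = 200L,
                       stage_widths = c(64L, 128L, 256L, 512L),
                       blocks_per_stage = c(2L, 2L, 2L, 2L),
                       stem_channels = stage_widths[1],
                       epochs = 10L, retrain_epochs = 5L,
                       batch_size = 32L, weight_decay = 1e-3,
                       learning_rate = 5e-4, momentum = 0.9,
                       schedule = default_schedule(),
                       norm_kind = "l1", convention = "mac",
                       amplify = FALSE, seed = 1L) {
  structure(list(
    data_root = data_root, out_dir = out_dir, classes = classes,
    image_size = as.integer(image_size), n_per_class = as.integer(n_per_class),
    stage_widths = as.integer(stage_widths),
    blocks_per_stage = as.integer(blocks_per_stage),
    stem_channels = as.integer(stem_channels),
    epochs = as.integer(epochs), retrain_epochs = as.integer(retrain_epochs),
    batch_size = as.integer(batch_size), weight_decay = weight_decay,
    learning_rate = learning_rate, momentum = momentum,
    schedule = as.numeric(schedule), norm_kind = norm_kind,
    convention = convention, amplify = isTRUE(amplify),
    seed = as.integer(seed)
  ), class = "cacp_config")
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_config()]; `overrides` (e.g. parsed CLI
#' flags) take precedence over the file, which takes precedence over defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list of final overrides.
#' @return A `cacp_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

config_spec <- function(config, attention_enabled = FALSE) {
  arch_spec(stem_channels = config$stem_channels,
            stage_widths = config$stage_widths,
            blocks_per_stage = config$blocks_per_stage,
            num_classes = length(config$classes),
            input_size = config$image_size,
            attention_enabled = attention_enabled)
}

config_hp <- function(config, epochs, seed) {
  hyperparams(batch_size = config$batch_size,
              weight_decay = config$weight_decay,
              learning_rate = config$learning_rate,
              momentum = config$momentum, epochs = epochs, seed = seed)
}

# stage seeds derived from the master seed (kept below 2^31)
stage_seed <- function(config, stage) {
  (config$seed * 1000L + stage) %% 2147483647L
}

#' Generate (and optionally write) a synthetic dataset per a run config
#'
#' @param config A [run_config()].
#' @return The generated `leaf_image_set`; written as an ImageFolder plus
#'   manifest under `out_dir/dataset` when `out_dir` is set.
#' @export
cmd_synth <- function(config) {
  cfg <- synth_config(classes = config$classes,
                      n_per_class = config$n_per_class,
                      image_size = config$image_size,
                      seed = stage_seed(config, 1L))
  set <- generate_synthetic_dataset(cfg)
  if (!is.null(config$out_dir)) {
    write_dataset(set, file.path(config$out_dir, "dataset"))
  }
  set
}

#' Profile a spec or checkpoint path
#'
#' @param x A `cacp_spec`, `cacp_net`, or path to a checkpoint / spec JSON.
#' @param input_size Input resolution (default: the spec's own).
#' @param convention `"mac"` or `"paper"`.
#' @return A `cacp_complexity`, printed at 3 decimals.
#' @export
cmd_profile <- function(x, input_size = NULL, convention = "mac") {
  if (is.character(x)) {
    if (grepl("\\.json$", x)) {
      x <- read_spec(x)
    } else {
      sidecar <- paste0(x, ".json")
      if (!file.exists(sidecar)) {
        stop("no architecture sidecar found for '", x,
             "'; supply the spec JSON written next to the checkpoint",
             call. = FALSE)
      }
      x <- read_spec(sidecar)
    }
  }
  rep <- profile_model(x, input_size = input_size, convention = convention)
  print(rep)
  invisible(rep)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full attend, train, prune, retrain pipeline
#'
#' Orchestrates the complete procedure: build the backbone, attach the
#' channel-attention module, train, rank channels and build the pruning plan
#' from the compression-ratio schedule, apply it, retrain the pruned model,
#' profile complexity before and after, and evaluate on the held-out test
#' split. The summary reports achieved FLOPs/parameter/size totals and their
#' percentage reductions alongside the published reference totals (see
#' [reference_complexity()]).
#'
#' @param config A [run_config()].
#' @param verbose Print per-epoch progress?
#' @return A `cacp_pipeline` list: `net` (attended, trained), `pruned`
#'   (retrained pruned net), `plan`, `before`/`after` complexity reports,
#'   `reduction`, `reference`, `eval_before`, `eval` (pruned model), training
#'   histories, and the resolved `config`. Artifacts (checkpoints with spec
#'   sidecars, plan JSON, reports, summary JSON) are written under `out_dir`
#'   when set.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data <- pipeline_stage("data", {
    full <- if (is.null(config$data_root)) {
      cmd_synth(config)
    } else {
      load_image_folder(config$data_root)
    }
    full$images <- lapply(full$images, resize_image,
                          size = config$image_size)
    sp <- split_dataset(full, seed = stage_seed(config, 2L))
    train_set <- if (config$amplify) amplify(sp$train) else sp$train
    stats <- channel_stats(train_set)
    list(train = standardize(train_set, stats),
         test = standardize(sp$test, stats), stats = stats)
  })
  net <- pipeline_stage("attach_attention", {
    base <- build_model(config_spec(config, FALSE),
                        seed = stage_seed(config, 3L))
    attach_attention(base, seed = stage_seed(config, 4L))
  })
  fit <- pipeline_stage("train", {
    train(net, data$train,
          config_hp(config, config$epochs, stage_seed(config, 5L)),
          verbose = verbose)
  })
  before <- profile_model(net, convention = config$convention)
  eval_before <- pipeline_stage("evaluate", evaluate(net, data$test))
  if (!is.null(out)) {
    save_checkpoint(net, file.path(out, "attended.rds"))
    write_complexity(before, file.path(out, "complexity_before.json"),
                     file.path(out, "complexity_before.csv"))
  }
  plan <- pipeline_stage("prune", {
    make_pruning_plan(net, config$schedule, config$norm_kind)
  })
  pruned <- pipeline_stage("apply_plan", {
    apply_plan(net, plan, seed = stage_seed(config, 6L))
  })
  if (!is.null(out)) {
    writeLines(serialize_pruning_plan(plan), file.path(out, "plan.json"))
  }
  refit <- pipeline_stage("retrain", {
    train(pruned, data$train,
          config_hp(config, config$retrain_epochs, stage_seed(config, 7L)),
          verbose = verbose)
  })
  after <- profile_model(pruned, convention = config$convention)
  eval_after <- pipeline_stage("evaluate", evaluate(pruned, data$test))
  reduction <- complexity_reduction(before, after)
  result <- structure(list(
    net = net, pruned = pruned, plan = plan,
    before = before, after = after, reduction = reduction,
    reference = reference_complexity(),
    eval_before = eval_before, eval = eval_after,
    history = fit$history, retrain_history = refit$history,
    stats = data$stats, config = config
  ), class = "cacp_pipeline")
  if (!is.null(out)) {
    save_checkpoint(pruned, file.path(out, "pruned.rds"))
    write_complexity(after, file.path(out, "complexity_after.json"),
                     file.path(out, "complexity_after.csv"))
    write_eval(eval_after, file.path(out, "eval.json"),
               file.path(out, "eval.csv"))
    jsonlite::write_json(pipeline_summary(result),
                         file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                             logical(1))],
                     file.path(out, "config.yaml"))
  }
  result
}

#' Machine-readable pipeline summary
#'
#' @param result A `cacp_pipeline`.
#' @return A list with achieved before/after complexity, percentage
#'   reductions, the published reference totals, and test accuracies.
#' @export
pipeline_summary <- function(result) {
  list(
    achieved = list(
      before = list(gflops = result$before$gflops,
                    mparams = result$before$mparams,
                    size_mib = result$before$size_mib),
      after = list(gflops = result$after$gflops,
                   mparams = result$after$mparams,
                   size_mib = result$after$size_mib),
      reduction_pct = stats::setNames(as.list(result$reduction$reduction_pct),
                                      result$reduction$metric)
    ),
    reference = result$reference,
    accuracy = list(attended = result$eval_before$accuracy,
                    pruned = result$eval$accuracy),
    macro_f1 = list(attended = result$eval_before$macro_f1,
                    pruned = result$eval$macro_f1),
    pruned_widths = result$plan$spec_after$stage_widths,
    seed = result$config$seed
  )
}

#' @export
print.cacp_pipeline <- function(x, ...) {
  cat("<cacp_pipeline>\n")
  cat(sprintf("  complexity: %.3f -> %.3f GFLOPs | %.3f -> %.3f M params | %.1f -> %.1f MiB\n",
              x$before$gflops, x$after$gflops, x$before$mparams,
              x$after$mparams, x$before$size_mib, x$after$size_mib))
  cat(sprintf("  reductions: %s\n",
              paste(sprintf("%s %.2f%%", x$reduction$metric,
                            x$reduction$reduction_pct), collapse = ", ")))
  cat(sprintf("  test accuracy: attended %.3f | pruned+retrained %.3f\n",
              x$eval_before$accuracy, x$eval$accuracy))
  invisible(x)
}
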
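# Shared fixtures. Everything is generated in code; the expensive desk-scale
# pipeline run is built once per session and reused across test files.

toy_spec <- function(attention = FALSE, widths = c(6L, 8L, 10L, 12L),
                     stem = widths[1], classes = 3L, input = 32L,
                     blocks = c(2L, 2L, 2L, 2L)) {
  arch_spec(stem_channels = stem, stage_widths = widths,
            blocks_per_stage = blocks, num_classes = classes,
            input_size = input, attention_enabled = attention)
}

random_images <- function(n, size = 32L, seed = 1L) {
  cacpnet:::with_seed(seed, {
    lapply(seq_len(n), function(i) array(stats::rnorm(size * size * 3),
                                         c(size, size, 3)))
  })
}

# independent per-layer parameter enumeration: explicit arithmetic over the
# architecture, written without reference to the profiler
enumerate_params <- function(spec) {
  bn <- function(c) 2 * c
  total <- spec$stem_channels * 3 * 49 + bn(spec$stem_channels)
  att_k <- function(C) {
    if (!spec$attention_enabled) return(0)
    kernel_size_from_channels(C, spec$attention_gamma, spec$attention_b)
  }
  total <- total + att_k(spec$stem_channels)
  in_ch <- spec$stem_channels
  for (s in 1:4) {
    w <- spec$stage_widths[s]
    inner <- if (is.null(spec$block_inner_widths)) {
      rep(w, spec$blocks_per_stage[s])
    } else {
      spec$block_inner_widths[[s]]
    }
    for (b in seq_len(spec$blocks_per_stage[s])) {
      stride <- if (b == 1) spec$stage_strides[s] else 1
      total <- total + inner[b] * in_ch * 9 + bn(inner[b]) + att_k(inner[b]) +
        w * inner[b] * 9 + bn(w) + att_k(w)
      if (stride != 1 || in_ch != w) {
        total <- total + w * in_ch + bn(w)
      }
      in_ch <- w
    }
  }
  total + spec$stage_widths[4] * spec$num_classes + spec$num_classes
}

# desk-scale end-to-end run (synthetic 5-class set at 64 px, 200 per class;
# attend -> train -> prune -> retrain), memoised for the whole test session
.smoke <- new.env(parent = emptyenv())
smoke_run <- function() {
  if (!is.null(.smoke$result)) return(.smoke$result)
  cfg <- run_config(image_size = 64L, n_per_class = 200L,
                    stage_widths = c(16L, 32L, 64L, 128L),
                    epochs = 4L, retrain_epochs = 3L,
                    learning_rate = 0.01, seed = 101L,
                    out_dir = file.path(tempdir(), "cacpnet-smoke"))
  .smoke$elapsed <- system.time(
    .smoke$result <- run_pipeline(cfg)
  )[["elapsed"]]
  .smoke$result
}
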
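test_that("channel importance matches direct arithmetic and a brute-force oracle", {
  w <- array(c(1, -2), c(1, 2, 1, 1))
  expect_equal(as.numeric(channel_importance(w, "l1")), 3)
  expect_equal(as.numeric(channel_importance(w, "l2")), sqrt(5))
  expect_equal(as.numeric(channel_importance(array(0, c(3, 2, 3, 3)))),
               rep(0, 3))
  set.seed(8)
  for (i in 1:5) {
    w <- array(stats::rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3))
    # brute force: loop every output channel
    l1 <- vapply(1:4, function(c) sum(abs(w[c, , , ])), numeric(1))
    l2 <- vapply(1:4, function(c) sqrt(sum(w[c, , , ]^2)), numeric(1))
    expect_equal(as.numeric(channel_importance(w, "l1")), l1)
    expect_equal(as.numeric(channel_importance(w, "l2")), l2)
    expect_equal(order(channel_importance(w, "l1")), order(l1))
  }
  expect_error(channel_importance(array(0, c(2, 2, 2))), "4D|matrix")
})

test_that("prune_count implements floor(R * n) with a one-survivor cap", {
  expect_identical(prune_count(0.3, 512), 153)
  expect_identical(prune_count(0, 640), 0)
  expect_identical(prune_count(0.1, 128), 12)
  expect_identical(prune_count(0.99, 4), 3)   # capped at n-1
  expect_error(prune_count(1, 10), "\\[0, 1\\)")
  expect_error(prune_count(-0.1, 10), "\\[0, 1\\)")
  # monotone nondecreasing in R and n, always leaves a survivor
  for (n in c(1, 7, 64, 512)) {
    prev <- -1
    for (R in seq(0, 0.95, by = 0.05)) {
      p <- prune_count(R, n)
      expect_gte(p, prev)
      expect_lte(p, n - 1)
      prev <- p
    }
  }
  expect_gte(prune_count(0.5, 128), prune_count(0.5, 64))
})

test_that("residual shortcut pruning removes exactly the width difference", {
  expect_equal(residual_prune_count(512, 359), 153)
  expect_equal(residual_prune_count(64, 64), 0)
  expect_equal(residual_prune_count(256, 205), 51)
  expect_error(residual_prune_count(100, 128), "exceeds")
})

test_that("the published schedule rewrites the default widths to 64,116,205,359", {
  net <- build_model(spec_peanut(attention_enabled = TRUE), seed = 1)
  plan <- make_pruning_plan(net, default_schedule())
  expect_equal(plan$spec_after$stage_widths, c(64L, 116L, 205L, 359L))
  expect_equal(plan$spec_after$stem_channels, 64L)
  # paired-equal ratios: block-internal widths equal the stage widths (the
  # spec normalizes that to its NULL default)
  expect_null(plan$spec_after$block_inner_widths)
  expect_equal(cacpnet:::block_inner(plan$spec_after, 4), c(359L, 359L))
  expect_equal(vapply(plan$inner_sets[[4]], length, integer(1)),
               c(359L, 359L))
  # surviving sets are sorted, in range, and sized by the schedule
  for (s in 1:4) {
    set <- plan$stage_sets[[s]]
    expect_true(all(diff(set) > 0))
    expect_true(all(set >= 1 & set <= net$spec$stage_widths[s]))
  }
  expect_error(make_pruning_plan(net, c(0, 0.1)), "schedule length")
})

test_that("an all-zero schedule is the identity: same spec, identical outputs", {
  spec <- toy_spec(attention = TRUE)
  net <- build_model(spec, seed = 2)
  plan <- make_pruning_plan(net, rep(0, 8))
  expect_equal(plan$spec_after, spec)
  pruned <- apply_plan(net, plan)
  imgs <- random_images(3, seed = 5)
  expect_equal(predict_batch(pruned, imgs), predict_batch(net, imgs))
  # idempotence: a zero-schedule plan of the pruned net is again the identity
  plan2 <- make_pruning_plan(pruned, rep(0, 8))
  expect_equal(plan2$spec_after, pruned$spec)
})

test_that("surviving sets equal the brute-force importance ranking on a toy net", {
  spec <- toy_spec(widths = c(6L, 8L, 8L, 8L), blocks = c(1L, 1L, 1L, 1L))
  net <- build_model(spec, seed = 7)
  sched <- c(0.2, 0.25, 0.5, 0.375)
  plan <- make_pruning_plan(net, sched, "l1")
  for (s in 1:4) {
    blk <- net$stages[[s]][[1]]
    # brute force: recompute summed |w| per output channel by explicit loops
    score <- numeric(spec$stage_widths[s])
    for (src in c(list(blk$conv2), if (!is.null(blk$down_conv))
      list(blk$down_conv))) {
      for (ch in seq_along(score)) {
        score[ch] <- score[ch] + sum(abs(src$W[ch, ]))
      }
    }
    if (s == 1) {
      for (ch in seq_along(score)) {
        score[ch] <- score[ch] + sum(abs(net$stem$conv$W[ch, ]))
      }
    }
    keep <- spec$stage_widths[s] - prune_count(sched[s], spec$stage_widths[s])
    expect_equal(plan$stage_sets[[s]],
                 sort(order(-score)[seq_len(keep)]))
  }
})

test_that("pruning channels that are zero everywhere leaves outputs unchanged", {
  # attention disabled: the 1D attention kernel mixes neighbouring channels,
  # so index compaction is output-preserving only for attention-free nets
  spec <- toy_spec(widths = c(6L, 8L, 8L, 8L), stem = 6L)
  net <- build_model(spec, seed = 10)
  # run a forward in training mode so BN statistics are realistic
  fm <- cacpnet:::images_to_fmap(random_images(8, seed = 2))
  invisible(cacpnet:::net_forward(net, fm, training = TRUE, cache = FALSE))
  drop_per_stage <- list(c(2L, 5L), c(1L, 8L), c(3L, 4L), c(6L, 7L))
  zero_rows <- function(conv, rows) conv$W[rows, ] <- 0
  zero_cols <- function(conv, chans) {
    conv$W[, cacpnet:::conv_col_index(chans, conv$in_ch, conv$k)] <- 0
  }
  zero_bn <- function(bn, chans) {
    bn$gamma[chans] <- 0; bn$beta[chans] <- 0
  }
  for (s in 1:4) {
    drop <- drop_per_stage[[s]]
    for (b in seq_along(net$stages[[s]])) {
      blk <- net$stages[[s]][[b]]
      # stage-output channels: conv2 rows, its BN, and all consumers
      zero_rows(blk$conv2, drop)
      zero_bn(blk$bn2, drop)
      if (b > 1) zero_cols(blk$conv1, drop)
      # block-internal channels: conv1 rows, its BN, conv2 input columns
      zero_rows(blk$conv1, drop)
      zero_bn(blk$bn1, drop)
      zero_cols(blk$conv2, drop)
      if (!is.null(blk$down_conv)) {
        zero_rows(blk$down_conv, drop)
        zero_bn(blk$down_bn, drop)
        zero_cols(blk$down_conv, drop_per_stage[[s - 1]])
        zero_cols(blk$conv1, drop_per_stage[[s - 1]])
      }
    }
    if (s == 1) {
      zero_rows(net$stem$conv, drop)
      zero_bn(net$stem$bn, drop)
      # stage-1 identity shortcut couples the stem: block1 conv1 input too
      zero_cols(net$stages[[1]][[1]]$conv1, drop)
    }
    if (s < 4) {
      nxt <- net$stages[[s + 1]][[1]]
      zero_cols(nxt$conv1, drop)
      if (!is.null(nxt$down_conv)) zero_cols(nxt$down_conv, drop)
    } else {
      net$head$W[, drop] <- 0
    }
  }
  # schedule prunes exactly two channels per block (stage outputs and the
  # block-internal convs alike)
  n_drop <- 2L
  sched <- rep(n_drop / spec$stage_widths + 1e-9, each = 2)
  plan <- make_pruning_plan(net, sched)
  # zeroed channels have importance 0, ties break low-index: they are removed
  for (s in 1:4) {
    expect_equal(plan$stage_sets[[s]],
                 setdiff(seq_len(spec$stage_widths[s]), drop_per_stage[[s]]))
    for (b in 1:2) {
      expect_equal(plan$inner_sets[[s]][[b]],
                   setdiff(seq_len(spec$stage_widths[s]), drop_per_stage[[s]]))
    }
  }
  pruned <- apply_plan(net, plan)
  imgs <- random_images(4, seed = 3)
  expect_equal(predict_batch(pruned, imgs, type = "logit"),
               predict_batch(net, imgs, type = "logit"), tolerance = 1e-10)
})

test_that("pruned weights are index-selected slices and counts match the closed form", {
  spec <- toy_spec(attention = TRUE, widths = c(6L, 8L, 10L, 12L))
  net <- build_model(spec, seed = 4)
  plan <- make_pruning_plan(net, c(0, 0.2, 0.25, 0.25, 0.3, 0.3, 0.4, 0.4))
  pruned <- apply_plan(net, plan)
  expect_equal(count_parameters(pruned),
               profile_model(plan$spec_after)$params)
  expect_equal(count_parameters(pruned), enumerate_params(plan$spec_after))
  # spot-check a slice: stage 3 block 2 conv2
  sset <- plan$stage_sets[[3]]
  iset <- plan$inner_sets[[3]][[2]]
  src <- net$stages[[3]][[2]]$conv2
  expect_equal(pruned$stages[[3]][[2]]$conv2$W,
               src$W[sset, cacpnet:::conv_col_index(iset, src$in_ch, 3L)])
  expect_equal(pruned$head$W, net$head$W[, plan$stage_sets[[4]]])
  # monotonicity: pruning never increases cost, strictly reduces it here
  before <- profile_model(net)
  after <- profile_model(pruned)
  expect_lt(after$flops, before$flops)
  expect_lt(after$params, before$params)
})

test_that("pruning plans round-trip through JSON", {
  net <- build_model(toy_spec(attention = TRUE), seed = 6)
  plan <- make_pruning_plan(net, c(0, 0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3))
  back <- parse_pruning_plan(serialize_pruning_plan(plan))
  expect_equal(back$stage_sets, plan$stage_sets)
  expect_equal(back$inner_sets, plan$inner_sets)
  expect_equal(back$schedule, plan$schedule)
  expect_equal(back$spec_after, plan$spec_after)
  pruned <- apply_plan(net, back)
  expect_equal(pruned$spec, plan$spec_after)
})
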
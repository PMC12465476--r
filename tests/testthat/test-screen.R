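test_that("score_block computes margins and criteria from group means", {
  spec <- toy_spec()
  cfg <- screen_config()

  # perfect marker: fully methylated in target, zero elsewhere
  s <- score_block(toy_summary("blk", c(1, 1), 0, c(0, 0)), "blk", spec, cfg)
  expect_equal(s$margin, 1)
  expect_true(s$pass)
  expect_equal(s$direction, "hyper")

  # hand-computed: target min 0.9, background max 0.05, blood max 0.02
  s <- score_block(toy_summary("blk", c(0.9, 0.95), 0.05, c(0.02, 0.01)),
                   "blk", spec, cfg)
  expect_equal(s$target_min_beta, 0.9)
  expect_equal(s$background_max_beta, 0.05)
  expect_equal(s$blood_max_beta, 0.02)
  expect_equal(s$margin, 0.85)
  expect_true(s$pass)

  # blood contamination alone sinks a marker
  s <- score_block(toy_summary("blk", c(0.9, 0.95), 0.05, c(0.2, 0.01)),
                   "blk", spec, cfg)
  expect_false(s$pass_blood)
  expect_true(s$pass_target && s$pass_background && s$pass_margin)
  expect_false(s$pass)

  expect_error(score_block(toy_summary("blk", c(1, 1), 0, c(0, 0)),
                           "other_blk", spec, cfg), "absent")
})

test_that("a block with an unobserved target group is not evaluable", {
  spec <- toy_spec()
  su <- toy_summary("blk", c(0.9, 0.95), 0.05, c(0.01, 0.01))
  su$mean_beta[su$group == "kid_b"] <- NA
  su$n_replicates_observed[su$group == "kid_b"] <- 0L
  su$missing[su$group == "kid_b"] <- TRUE
  s <- score_block(su, "blk", spec, screen_config())
  expect_false(s$evaluable)
  expect_false(s$pass)
})

test_that("screen recovers exactly the planted markers, ranked by margin", {
  sim <- gen_atlas(atlas_gen_spec(seed = 11))
  atlas <- filter_blocks_by_replication(sim$atlas, 2)
  specs <- default_target_specs()
  for (comp in names(specs)) {
    hits <- screen_markers(atlas, specs[[comp]])
    planted <- sim$truth$block_id[sim$truth$compartment == comp]
    expect_setequal(hits$block_id, planted)
    expect_equal(hits$rank, seq_len(nrow(hits)))
    expect_equal(order(-hits$margin, hits$block_id), seq_len(nrow(hits)))
  }
})

test_that("screen pass set equals brute-force re-evaluation of the predicate", {
  sim <- gen_atlas(atlas_gen_spec(n_null_blocks = 400, seed = 3))
  atlas <- filter_blocks_by_replication(sim$atlas, 2)
  spec <- default_target_specs()$endothelial
  cfg <- screen_config()
  hits <- screen_markers(atlas, spec, cfg)
  roster <- default_group_roster()
  bg_nonblood <- setdiff(atlas_groups(atlas),
                         c(spec$target_groups, roster$blood))
  s <- aggregate_by_group(atlas)
  brute <- vapply(atlas$blocks$block_id, function(b) {
    m <- s[s$block_id == b, ]
    mb <- function(gs) m$mean_beta[match(gs, m$group)]
    tmin <- min(mb(spec$target_groups))
    bmax <- max(mb(bg_nonblood), na.rm = TRUE)
    blmax <- max(mb(roster$blood), na.rm = TRUE)
    !anyNA(mb(spec$target_groups)) &&
      tmin >= cfg$tau_target && bmax <= cfg$tau_background &&
      blmax <= cfg$tau_blood && (tmin - bmax) >= cfg$min_margin
  }, logical(1))
  expect_setequal(hits$block_id, atlas$blocks$block_id[brute])
})

test_that("screen output is invariant to block and sample ordering", {
  sim <- gen_atlas(atlas_gen_spec(n_null_blocks = 200, seed = 9))
  a <- sim$atlas
  set.seed(42)
  bperm <- sample(nrow(a$blocks))
  sperm <- sample(ncol(a$beta))
  ap <- atlas_matrix(a$blocks[bperm, ], a$samples[sperm, ],
                     a$beta[bperm, sperm])
  spec <- default_target_specs()$pan_renal
  h1 <- screen_markers(a, spec)
  h2 <- screen_markers(ap, spec)
  expect_equal(as.data.frame(h1), as.data.frame(h2), ignore_attr = TRUE)
})

test_that("tightening any threshold never grows the passing set", {
  sim <- gen_atlas(atlas_gen_spec(n_null_blocks = 300, seed = 13,
                                  beta_background = c(4, 30)))
  a <- sim$atlas
  spec <- default_target_specs()$pan_renal
  base <- screen_markers(a, spec, screen_config())$block_id
  tighter <- list(
    screen_config(tau_target = 0.8),
    screen_config(tau_background = 0.08),
    screen_config(tau_blood = 0.02),
    screen_config(min_margin = 0.6)
  )
  for (cfg in tighter) {
    expect_true(all(screen_markers(a, spec, cfg)$block_id %in% base))
  }
})

test_that("no passing block yields an empty, error-free result", {
  sim <- gen_atlas(atlas_gen_spec(n_null_blocks = 100,
                                  n_planted = c(pan_renal = 0,
                                                endothelial = 0,
                                                epithelial = 0),
                                  seed = 4))
  hits <- screen_markers(sim$atlas, default_target_specs()$pan_renal)
  expect_equal(nrow(hits), 0L)
})

test_that("screening an absent group is a hard error", {
  sim <- gen_atlas(atlas_gen_spec(n_null_blocks = 20, seed = 1))
  spec <- target_spec("custom", "martian_tissue")
  expect_error(screen_markers(sim$atlas, spec), "martian_tissue")
})

test_that("select_panel assembles the 10-target panel with one control", {
  sim <- gen_atlas(atlas_gen_spec(seed = 11))
  atlas <- filter_blocks_by_replication(sim$atlas, 2)
  screens <- lapply(default_target_specs(),
                    function(sp) screen_markers(atlas, sp))
  panel <- select_panel(screens)
  expect_s3_class(panel, "panel_definition")
  expect_equal(nrow(panel), 10L)
  expect_equal(sum(panel$role == "internal_control"), 1L)
  expect_equal(panel$channel_id, 1:10)
  expect_false(anyDuplicated(panel$assay_name) > 0)
  expect_false(anyDuplicated(na.omit(panel$block_id)) > 0)
  # the selected blocks are exactly the planted truth, per compartment
  for (comp in c("pan_renal", "endothelial", "epithelial")) {
    expect_setequal(panel$block_id[panel$role == comp],
                    sim$truth$block_id[sim$truth$compartment == comp])
  }
})

test_that("a block topping two screens is assigned to its better compartment", {
  mk <- function(block_id, margin, comp) {
    data.frame(block_id = block_id, margin = margin, compartment = comp,
               stringsAsFactors = FALSE)
  }
  screens <- list(
    pan_renal = mk("shared", 0.5, "pan_renal"),
    endothelial = mk(c("shared", paste0("e", 1:6)), c(0.8, seq(0.7, 0.2, by = -0.1)),
                     "endothelial"),
    epithelial = mk(c("p1", "p2"), c(0.6, 0.5), "epithelial")
  )
  # 'shared' is better as endothelial, so pan_renal comes up short
  expect_error(select_panel(screens), "pan_renal.*1 short")
  # with margins tied, the tie goes to pan_renal; endothelial still has 6
  screens$endothelial$margin[1] <- 0.5
  panel <- select_panel(screens)
  expect_equal(panel$block_id[panel$role == "pan_renal"], "shared")
  expect_false("shared" %in% panel$block_id[panel$role == "endothelial"])
})

test_that("panel definitions round-trip through YAML", {
  sim <- gen_atlas(atlas_gen_spec(seed = 11))
  atlas <- filter_blocks_by_replication(sim$atlas, 2)
  screens <- lapply(default_target_specs(),
                    function(sp) screen_markers(atlas, sp))
  panel <- select_panel(screens)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_panel(panel, p)
  back <- read_panel(p)
  expect_equal(as.data.frame(back), as.data.frame(panel))
})

test_that("screen report TSV carries scores and ranks for every block", {
  sim <- gen_atlas(atlas_gen_spec(n_null_blocks = 50, seed = 2))
  hits <- screen_markers(sim$atlas, default_target_specs()$endothelial)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_screen_report(hits, p)
  rep <- read.delim(p)
  expect_equal(nrow(rep), nrow(sim$atlas$blocks))
  expect_equal(sum(!is.na(rep$rank)), nrow(hits))
})
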
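# Small in-code fixtures shared across test files.

tiny_atlas <- function() {
  blocks <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 1000L, 0L),
    end = c(500L, 1500L, 500L),
    block_id = c("b1", "b2", "b3"),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = c("k1", "k2", "bl1", "bl2"),
    group = c("kidney", "kidney", "blood", "blood"),
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  beta <- matrix(c(0.9, 0.95, 0.02, 0.01,
                   0.5, NA, 0.4, 0.45,
                   0.1, 0.2, 0.15, NA),
                 nrow = 3, byrow = TRUE)
  atlas_matrix(blocks, samples, beta)
}

# group summary rows for one synthetic block, built directly
summary_row <- function(block_id, group, mean_beta) {
  data.frame(block_id = block_id, group = group,
             n_replicates_observed = 3L, mean_beta = mean_beta,
             min_beta = mean_beta, max_beta = mean_beta, missing = FALSE,
             stringsAsFactors = FALSE)
}

# a 5-group toy world: 2 kidney targets, 2 blood, 1 other
toy_spec <- function() {
  target_spec("toy", c("kid_a", "kid_b"),
              blood_groups = c("blood_a", "blood_b"))
}

toy_summary <- function(block_id, target, background, blood) {
  rbind(summary_row(block_id, "kid_a", target[1]),
        summary_row(block_id, "kid_b", target[2]),
        summary_row(block_id, "other", background),
        summary_row(block_id, "blood_a", blood[1]),
        summary_row(block_id, "blood_b", blood[2]))
}

# deterministic plate row construction: positives implied by true copies
plate_rows <- function(sample_id, assays, copies, N = 20000, v = 0.91,
                       control_type = "sample",
                       reaction_id = paste0("rx_", sample_id)) {
  k <- round(N * (1 - exp(-copies / N)))
  data.frame(reaction_id = reaction_id, sample_id = sample_id,
             control_type = control_type, assay_name = assays,
             positives = k, total_partitions = N, partition_volume_nl = v,
             stringsAsFactors = FALSE)
}

make_2x2_cohort <- function(a, b, c, d) {
  # a: exposed events, b: exposed non-events, c: unexposed events,
  # d: unexposed non-events
  n <- a + b + c + d
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    tube_type = "EDTA", biopsy_context = "indication",
    rejection = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    rejection_subtype = c(rep("ABMR", a), rep("none", b), rep("TCMR", c),
                          rep("none", d)),
    any_banff_lesion = 0, egfr = 50,
    dsa = c(rep(1, a + b), rep(0, c + d)),
    stringsAsFactors = FALSE
  )
}
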
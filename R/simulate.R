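#' Default reference-atlas group roster
#'
#' Twenty-one anatomical groups mirroring a multi-tissue methylation atlas
#' sampled in triplicate: five kidney subcompartments (tubular and glomerular
#' epithelium, podocytes, peritubular and glomerular endothelium), five blood
#' cell groups (the dominant contaminants of plasma cfDNA), and eleven other
#' organs. Membership of the roles (`kidney_epithelial`,
#' `kidney_endothelial`, `blood`, `other`) is declared here, never inferred
#' from group names.
#'
#' @return named list of character vectors: `kidney_epithelial`,
#'   `kidney_endothelial`, `blood`, `other`; plus `kidney` (the union).
#' @export
default_group_roster <- function() {
  kidney_epithelial <- c("kidney_tubular_epithelium",
                         "kidney_glomerular_epithelium",
                         "kidney_podocyte")
  kidney_endothelial <- c("kidney_peritubular_endothelium",
                          "kidney_glomerular_endothelium")
  blood <- c("blood_granulocytes", "blood_monocytes", "blood_t_cells",
             "blood_b_cells", "blood_nk_cells")
  other <- c("liver", "lung", "heart", "brain_neuron", "colon_epithelium",
             "pancreas_acinar", "skin_keratinocyte", "skeletal_muscle",
             "adipocyte", "breast_epithelium", "prostate_epithelium")
  list(kidney_epithelial = kidney_epithelial,
       kidney_endothelial = kidney_endothelial,
       blood = blood,
       other = other,
       kidney = c(kidney_epithelial, kidney_endothelial))
}

#' Default per-compartment target specs for the kidney marker screen
#'
#' @param roster a group roster (see [default_group_roster()]).
#' @return named list of [target_spec()] objects: `pan_renal`,
#'   `endothelial`, `epithelial`.
#' @export
default_target_specs <- function(roster = default_group_roster()) {
  list(
    pan_renal = target_spec("pan_renal", roster$kidney,
                            blood_groups = roster$blood),
    endothelial = target_spec("endothelial", roster$kidney_endothelial,
                              blood_groups = roster$blood),
    epithelial = target_spec("epithelial", roster$kidney_epithelial,
                             blood_groups = roster$blood)
  )
}

#' Specification for the synthetic methylation atlas
#'
#' The generator plants compartment-specific hypermethylated marker blocks
#' (high beta in every target group, low elsewhere, near-zero in blood —
#' blood negativity being a property the real marker discovery selects for)
#' among null blocks whose methylation level is shared across all groups.
#'
#' @param roster group roster; see [default_group_roster()].
#' @param n_replicates replicates per group (default 3).
#' @param n_null_blocks number of non-specific blocks (default 2000).
#' @param n_planted named integer vector of planted markers per compartment;
#'   default `c(pan_renal = 1, endothelial = 6, epithelial = 2)` mirrors the
#'   1 + 6 + 2 panel structure.
#' @param beta_target shape parameters of the Beta distribution for planted
#'   blocks in their target groups (default `c(50, 2)`, mean ~0.96).
#' @param beta_background shapes for planted blocks in non-blood background
#'   groups (default `c(2, 50)`, mean ~0.04).
#' @param beta_blood shapes for planted blocks in blood groups (default
#'   `c(1, 99)`, mean 0.01).
#' @param null_concentration Beta concentration of null blocks around their
#'   per-block mean (default 30).
#' @param missing_rate fraction of entries masked missing uniformly at
#'   random (default 0.05).
#' @param seed RNG seed.
#' @return list of class `atlas_gen_spec`.
#' @export
atlas_gen_spec <- function(roster = default_group_roster(),
                           n_replicates = 3,
                           n_null_blocks = 2000,
                           n_planted = c(pan_renal = 1, endothelial = 6,
                                         epithelial = 2),
                           beta_target = c(50, 2),
                           beta_background = c(2, 50),
                           beta_blood = c(1, 99),
                           null_concentration = 30,
                           missing_rate = 0.05,
                           seed = 1L) {
  stopifnot(n_replicates >= 1, n_null_blocks >= 0, missing_rate >= 0,
            missing_rate < 1,
            all(names(n_planted) %in% c("pan_renal", "endothelial",
                                        "epithelial")))
  structure(as.list(environment()), class = "atlas_gen_spec")
}

planted_target_groups <- function(compartment, roster) {
  switch(compartment,
         pan_renal = roster$kidney,
         endothelial = roster$kidney_endothelial,
         epithelial = roster$kidney_epithelial,
         stop("unknown compartment: ", compartment))
}

#' Generate a synthetic methylation atlas with a planted-marker truth table
#'
#' Deterministic given `spec$seed`. Planted blocks draw their target-group
#' betas from `Beta(beta_target)`, blood betas from `Beta(beta_blood)` and
#' remaining background from `Beta(beta_background)`; null blocks draw a
#' per-block mean from `Beta(2, 2)` shared by all samples. Missingness is
#' applied uniformly at random at `missing_rate` to null blocks; planted
#' blocks are emitted fully observed so the truth table always describes
#' discoverable markers.
#'
#' @param spec an [atlas_gen_spec()].
#' @return list with `atlas` (an `atlas_matrix`) and `truth` (data.frame
#'   `block_id`, `compartment`, ordered by block position); the spec is
#'   attached as attribute `"spec"` of the truth.
#' @export
gen_atlas <- function(spec = atlas_gen_spec()) {
  stopifnot(inherits(spec, "atlas_gen_spec"))
  set.seed(spec$seed)
  roster <- spec$roster
  groups <- c(roster$kidney_epithelial, roster$kidney_endothelial,
              roster$blood, roster$other)
  samples <- data.frame(
    sample_id = paste(rep(groups, each = spec$n_replicates),
                      rep(seq_len(spec$n_replicates), length(groups)),
                      sep = "_rep"),
    group = rep(groups, each = spec$n_replicates),
    replicate = rep(seq_len(spec$n_replicates), length(groups)),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(samples)
  n_planted_tot <- sum(spec$n_planted)
  n_blk <- spec$n_null_blocks + n_planted_tot
  compartments <- rep(names(spec$n_planted), spec$n_planted)

  beta <- matrix(NA_real_, nrow = n_blk, ncol = n_samp)
  # planted blocks scattered among the nulls
  planted_pos <- sort(sample.int(n_blk, n_planted_tot))
  null_pos <- setdiff(seq_len(n_blk), planted_pos)
  for (i in seq_along(planted_pos)) {
    tg <- planted_target_groups(compartments[i], roster)
    in_target <- samples$group %in% tg
    in_blood <- samples$group %in% roster$blood
    row <- numeric(n_samp)
    row[in_target] <- stats::rbeta(sum(in_target), spec$beta_target[1],
                                   spec$beta_target[2])
    row[!in_target & in_blood] <- stats::rbeta(sum(!in_target & in_blood),
                                               spec$beta_blood[1],
                                               spec$beta_blood[2])
    rest <- !in_target & !in_blood
    row[rest] <- stats::rbeta(sum(rest), spec$beta_background[1],
                              spec$beta_background[2])
    beta[planted_pos[i], ] <- row
  }
  if (length(null_pos)) {
    mu <- stats::rbeta(length(null_pos), 2, 2)
    kc <- spec$null_concentration
    beta[null_pos, ] <- stats::rbeta(length(null_pos) * n_samp,
                                     rep(mu * kc, n_samp),
                                     rep((1 - mu) * kc, n_samp))
  }
  if (spec$missing_rate > 0 && length(null_pos)) {
    # missingness hits null blocks only: the truth table's contract is that
    # every planted marker is discoverable (available in all replicates),
    # mirroring a screen that only ever selects among fully replicated blocks
    mask <- matrix(FALSE, n_blk, n_samp)
    mask[null_pos, ] <- stats::runif(length(null_pos) * n_samp) <
      spec$missing_rate
    beta[mask] <- NA_real_
  }
  blocks <- data.frame(
    chrom = paste0("chr", (seq_len(n_blk) - 1) %% 22 + 1),
    start = (seq_len(n_blk) - 1) * 1000L,
    end = (seq_len(n_blk) - 1) * 1000L + 500L,
    block_id = sprintf("blk%06d", seq_len(n_blk)),
    stringsAsFactors = FALSE
  )
  atlas <- atlas_matrix(blocks, samples, beta)
  truth <- data.frame(block_id = blocks$block_id[planted_pos],
                      compartment = compartments,
                      stringsAsFactors = FALSE)
  attr(truth, "spec") <- spec
  list(atlas = atlas, truth = truth)
}

#' Simulate a digital PCR plate from true copy numbers
#'
#' Molecules distribute over `N` partitions approximately Poisson, so each
#' assay's positive-partition count is drawn
#' `Binomial(N, 1 - exp(-copies/N))`. Optionally appends a methylated and an
#' unmethylated control well.
#'
#' @param true_copies data.frame with columns `sample_id`, `assay_name`,
#'   `copies` (>= 0), one row per sample-assay; every sample must include the
#'   panel's internal control assay.
#' @param panel a `panel_definition`.
#' @param n_partitions partitions per reaction (default 20000).
#' @param partition_volume_nl partition volume (default 0.91 nl).
#' @param seed RNG seed.
#' @param controls if `TRUE`, append one methylated control well (marker
#'   copies = `control_ratio` x control genomes) and one all-zero
#'   unmethylated control well.
#' @param control_genomes albumin copies in control wells (default 3000).
#' @param control_ratio true methylated fraction of control markers
#'   (default 0.75).
#' @return list with `plate` (long data.frame as read by [read_plate()]) and
#'   `truth` (the input copies, controls included).
#' @export
gen_dpcr_plate <- function(true_copies, panel = default_panel(),
                           n_partitions = 20000, partition_volume_nl = 0.91,
                           seed = 1L, controls = FALSE,
                           control_genomes = 3000, control_ratio = 0.75) {
  stopifnot(all(c("sample_id", "assay_name", "copies") %in%
                  names(true_copies)),
            all(true_copies$copies >= 0))
  set.seed(seed)
  ctrl_assay <- panel$assay_name[panel$role == "internal_control"]
  truth <- true_copies[, c("sample_id", "assay_name", "copies")]
  truth$control_type <- "sample"
  if (controls) {
    mk <- panel_markers(panel)
    meth <- data.frame(sample_id = "methylated_control",
                       assay_name = c(mk, ctrl_assay),
                       copies = c(rep(control_ratio * control_genomes,
                                      length(mk)), control_genomes),
                       control_type = "methylated",
                       stringsAsFactors = FALSE)
    unmeth <- data.frame(sample_id = "unmethylated_control",
                         assay_name = c(mk, ctrl_assay),
                         copies = c(rep(0, length(mk)), control_genomes),
                         control_type = "unmethylated",
                         stringsAsFactors = FALSE)
    truth <- rbind(truth, meth, unmeth)
  }
  p <- 1 - exp(-truth$copies / n_partitions)
  positives <- stats::rbinom(nrow(truth), n_partitions, p)
  plate <- data.frame(
    reaction_id = paste0("rx_", as.integer(factor(truth$sample_id,
                                                  levels = unique(truth$sample_id)))),
    sample_id = truth$sample_id,
    control_type = truth$control_type,
    assay_name = truth$assay_name,
    positives = positives,
    total_partitions = n_partitions,
    partition_volume_nl = partition_volume_nl,
    stringsAsFactors = FALSE
  )
  list(plate = plate, truth = truth)
}

#' Specification for the synthetic transplant cohort
#'
#' Defaults emulate a development cohort of 170 pre-biopsy plasmas with 44
#' rejections (24 antibody-mediated, 13 T-cell-mediated, 7 mixed; 34 from 89
#' indication biopsies and 10 from 76 surveillance biopsies, leaving 5
#' records without a recorded context). Marker levels are baseline
#' log-normal albumin ratios multiplied by planted fold-changes: endothelial
#' markers are elevated in ABMR/mixed rejection, the pan-renal marker in any
#' rejection, and all markers mildly in non-rejection Banff lesions. eGFR is
#' shifted down under rejection; DSA prevalence is raised in ABMR/mixed.
#'
#' @param n cohort size.
#' @param subtype_split named counts of rejection subtypes.
#' @param context_split named counts of biopsy contexts (remainder of `n` is
#'   context-unlabeled).
#' @param rejection_by_context named counts of rejections per context (must
#'   sum to the total rejection count).
#' @param panel assay panel; markers are its non-control assays.
#' @param endothelial_fold fold-change of endothelial markers in ABMR/mixed.
#' @param pan_renal_fold fold-change of the pan-renal marker in any
#'   rejection.
#' @param lesion_fold fold-change of all markers in non-rejection lesions.
#' @param lesion_rate_nonrejection probability a non-rejection biopsy shows
#'   some Banff lesion.
#' @param egfr_mean,egfr_sd baseline eGFR distribution (mL/min/1.73m^2).
#' @param egfr_shift_rejection additive eGFR shift under rejection.
#' @param dsa_rate_abmr,dsa_rate_other DSA prevalence in ABMR/mixed vs the
#'   rest.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline of marker
#'   ratios (percent of albumin).
#' @param counting_noise if `TRUE`, pass levels through a simulated dPCR
#'   plate so measurements carry partition counting noise.
#' @param n_partitions,albumin_copies plate settings used when
#'   `counting_noise` is on.
#' @param seed RNG seed.
#' @return list of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n = 170,
                            subtype_split = c(ABMR = 24, TCMR = 13,
                                              mixed = 7),
                            context_split = c(indication = 89,
                                              surveillance = 76),
                            rejection_by_context = c(indication = 34,
                                                     surveillance = 10),
                            panel = default_panel(),
                            endothelial_fold = 3,
                            pan_renal_fold = 2,
                            lesion_fold = 1.5,
                            lesion_rate_nonrejection = 0.25,
                            egfr_mean = 55, egfr_sd = 15,
                            egfr_shift_rejection = -12,
                            dsa_rate_abmr = 0.6, dsa_rate_other = 0.15,
                            baseline_meanlog = log(0.5),
                            baseline_sdlog = 0.8,
                            counting_noise = FALSE,
                            n_partitions = 20000,
                            albumin_copies = 2000,
                            seed = 1L) {
  n_rejection <- sum(subtype_split)
  if (n_rejection > n) stop("rejection count exceeds cohort size")
  if (sum(context_split) > n) stop("context counts exceed cohort size")
  if (sum(rejection_by_context) != n_rejection) {
    stop("rejection_by_context must sum to the total rejection count (",
         n_rejection, ")")
  }
  if (any(rejection_by_context > context_split[names(rejection_by_context)])) {
    stop("more rejections than biopsies in a context")
  }
  structure(as.list(environment()), class = "cohort_gen_spec")
}

#' Generate a synthetic transplant cohort with its truth table
#'
#' Deterministic given `spec$seed`; subtype, context and rejection counts
#' are enforced exactly (not sampled). See [cohort_gen_spec()] for the
#' planted-effect structure.
#'
#' @param spec a [cohort_gen_spec()].
#' @return list with `records` (cohort data.frame, marker levels as
#'   albumin-ratio percentages) and `truth` (list of the planted
#'   parameters, per-record latent expected levels, and marker roles).
#' @export
gen_cohort <- function(spec = cohort_gen_spec()) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  set.seed(spec$seed)
  n <- spec$n
  panel <- spec$panel
  markers <- panel_markers(panel)
  roles <- panel$role[match(markers, panel$assay_name)]
  names(roles) <- markers

  subtype <- rep("none", n)
  rej_idx <- sample.int(n, spec$n_rejection)
  subtype[rej_idx] <- sample(rep(names(spec$subtype_split),
                                 spec$subtype_split))
  rejection <- as.integer(subtype != "none")

  # biopsy context: exact rejection counts per context, remainder unlabeled
  context <- rep(NA_character_, n)
  rej_pool <- sample(which(rejection == 1))
  non_pool <- sample(which(rejection == 0))
  taken_r <- 0L
  taken_n <- 0L
  for (cx in names(spec$context_split)) {
    n_rej_cx <- spec$rejection_by_context[[cx]]
    n_non_cx <- spec$context_split[[cx]] - n_rej_cx
    context[rej_pool[taken_r + seq_len(n_rej_cx)]] <- cx
    context[non_pool[taken_n + seq_len(n_non_cx)]] <- cx
    taken_r <- taken_r + n_rej_cx
    taken_n <- taken_n + n_non_cx
  }

  abmr_like <- subtype %in% c("ABMR", "mixed")
  dsa <- stats::rbinom(n, 1, ifelse(abmr_like, spec$dsa_rate_abmr,
                                    spec$dsa_rate_other))
  egfr <- stats::rnorm(n, spec$egfr_mean + spec$egfr_shift_rejection *
                         rejection, spec$egfr_sd)
  egfr <- pmax(egfr, 5)
  lesion <- ifelse(rejection == 1, 1L,
                   stats::rbinom(n, 1, spec$lesion_rate_nonrejection))

  fold <- matrix(1, nrow = n, ncol = length(markers),
                 dimnames = list(NULL, markers))
  endo <- markers[roles == "endothelial"]
  pan <- markers[roles == "pan_renal"]
  fold[abmr_like, endo] <- spec$endothelial_fold
  fold[rejection == 1, pan] <- spec$pan_renal_fold
  nonrej_lesion <- rejection == 0 & lesion == 1
  fold[nonrej_lesion, ] <- spec$lesion_fold

  base <- matrix(stats::rlnorm(n * length(markers), spec$baseline_meanlog,
                               spec$baseline_sdlog),
                 nrow = n, dimnames = list(NULL, markers))
  levels <- base * fold

  measured <- levels
  if (spec$counting_noise) {
    # push each record through a simulated reaction: ratio -> copies ->
    # positives -> re-estimated ratio
    alb <- spec$albumin_copies
    for (j in seq_along(markers)) {
      copies <- levels[, j] / 100 * alb
      pos <- stats::rbinom(n, spec$n_partitions,
                           1 - exp(-copies / spec$n_partitions))
      alb_pos <- stats::rbinom(n, spec$n_partitions,
                               1 - exp(-alb / spec$n_partitions))
      est <- -log1p(-pos / spec$n_partitions) * spec$n_partitions
      est_alb <- -log1p(-alb_pos / spec$n_partitions) * spec$n_partitions
      measured[, j] <- 100 * est / est_alb
    }
  }

  records <- data.frame(
    patient_id = sprintf("pt%03d", seq_len(n)),
    tube_type = sample(c("EDTA", "PAXgene"), n, replace = TRUE),
    biopsy_context = context,
    rejection = rejection,
    rejection_subtype = subtype,
    any_banff_lesion = lesion,
    egfr = egfr,
    dsa = dsa,
    stringsAsFactors = FALSE
  )
  records <- cbind(records, as.data.frame(measured))
  names(records) <- c(names(records)[1:8], markers)
  validate_cohort(records)
  truth <- list(
    spec = spec[setdiff(names(spec), "panel")],
    marker_roles = as.list(roles),
    latent_levels = levels
  )
  list(records = records, truth = truth)
}

#' Generate a cohort directly from a logistic outcome model
#'
#' Companion generator for coefficient-recovery testing: predictors are drawn
#' first (eGFR ~ Normal, DSA ~ Bernoulli, one continuous marker score ~
#' Normal) and the binary outcome from `Bernoulli(plogis(eta))` with
#' `eta = b0 + b_egfr*egfr + b_dsa*dsa + b_marker*marker_score`, so the
#' planted coefficients are exactly the logistic truth.
#'
#' @param n records to generate.
#' @param beta named coefficients: `intercept`, `egfr`, `dsa`,
#'   `marker_score`.
#' @param egfr_mean,egfr_sd eGFR distribution.
#' @param dsa_rate DSA prevalence.
#' @param seed RNG seed.
#' @return list with `records` (columns `egfr`, `dsa`, `marker_score`,
#'   `outcome`) and `truth` (the coefficients).
#' @export
gen_logistic_cohort <- function(n = 170,
                                beta = c(intercept = 1.0, egfr = -0.05,
                                         dsa = 1.0, marker_score = 0.9),
                                egfr_mean = 55, egfr_sd = 15,
                                dsa_rate = 0.3, seed = 1L) {
  set.seed(seed)
  egfr <- pmax(stats::rnorm(n, egfr_mean, egfr_sd), 5)
  dsa <- stats::rbinom(n, 1, dsa_rate)
  marker_score <- stats::rnorm(n)
  eta <- beta[["intercept"]] + beta[["egfr"]] * egfr + beta[["dsa"]] * dsa +
    beta[["marker_score"]] * marker_score
  outcome <- stats::rbinom(n, 1, stats::plogis(eta))
  list(records = data.frame(egfr = egfr, dsa = dsa,
                            marker_score = marker_score, outcome = outcome),
       truth = list(beta = beta))
}

#' Write a generator truth table as YAML
#'
#' @param truth a truth object emitted by a generator.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  as_plain <- function(x) {
    if (is.matrix(x)) {
      apply(x, 1, as.list, simplify = FALSE)
    } else if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
    } else if (inherits(x, c("atlas_gen_spec", "cohort_gen_spec")) ||
               is.list(x)) {
      lapply(unclass(x), as_plain)
    } else {
      x
    }
  }
  obj <- as_plain(if (is.data.frame(truth)) {
    list(planted = truth, spec = attr(truth, "spec"))
  } else truth)
  yaml::write_yaml(obj, path)
  invisible(path)
}
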
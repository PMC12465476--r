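#' Poisson concentration estimate for a digital PCR reaction
#'
#' In digital PCR the reaction is split into `N` partitions and target
#' molecules distribute approximately Poisson, so the mean copies per
#' partition is `lambda = -ln(1 - k/N)` where `k` partitions are positive.
#' Copies per reaction are `lambda * N`; concentration is `lambda / v` with
#' `v` the partition volume. The 95% confidence interval is a Wilson score
#' interval on the positive fraction transformed through `-ln(1 - p)`, which
#' remains well-behaved at `k = 0`.
#'
#' @param k number of positive partitions (vectorised).
#' @param N total partitions.
#' @param v_nl partition volume in nanolitres.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `k`, `N`, `p_hat`, `lambda`,
#'   `copies_per_reaction`, `copies_per_ul`, `ci_low`, `ci_high` (bounds on
#'   copies per reaction).
#' @export
poisson_concentration <- function(k, N, v_nl = 0.91, conf = 0.95) {
  if (any(k > N)) stop("positives exceed total partitions (k > N)")
  if (any(k < 0)) stop("negative positive-partition count")
  if (any(k == N)) {
    stop("all ", N, " partitions positive: reaction saturated, ",
         "concentration not estimable (dilute and re-run)")
  }
  p_hat <- k / N
  lambda <- -log1p(-p_hat)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (p_hat + z^2 / (2 * N)) / (1 + z^2 / N)
  hw <- z / (1 + z^2 / N) * sqrt(p_hat * (1 - p_hat) / N + z^2 / (4 * N^2))
  p_lo <- pmax(0, centre - hw)
  p_hi <- pmin(1 - 1e-12, centre + hw)
  data.frame(k = k, N = N, p_hat = p_hat, lambda = lambda,
             copies_per_reaction = lambda * N,
             copies_per_ul = lambda / (v_nl * 1e-3),
             ci_low = -log1p(-p_lo) * N,
             ci_high = -log1p(-p_hi) * N)
}

#' Albumin-normalised relative quantification
#'
#' Marker levels are reported relative to the number of genomes in the
#' sample, represented by the albumin internal control: 100 x marker copies /
#' albumin copies. Values above 100% are possible (e.g. amplification or
#' copy-number effects) and are returned unclipped; callers may flag them.
#'
#' @param marker_copies marker copies per reaction (vectorised).
#' @param albumin_copies albumin copies per reaction (> 0).
#' @return percentage ratio(s).
#' @export
ratio_to_albumin <- function(marker_copies, albumin_copies) {
  if (any(albumin_copies <= 0)) {
    stop("albumin copies must be > 0 to define the ratio")
  }
  100 * marker_copies / albumin_copies
}

#' Read a digital PCR plate file
#'
#' Long-format CSV with columns `reaction_id, sample_id, control_type,
#' assay_name, positives, total_partitions, partition_volume_nl` and
#' optionally `input_mass_ng, plasma_volume_ml`. `control_type` is `"sample"`
#' for study samples, else `"methylated"` / `"unmethylated"`.
#'
#' @param path CSV path.
#' @return validated plate data.frame.
#' @export
read_plate <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "sample_id", "control_type", "assay_name",
            "positives", "total_partitions", "partition_volume_nl")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate file missing column: ", miss[1])
  if (any(plate$positives > plate$total_partitions)) {
    bad <- which(plate$positives > plate$total_partitions)[1]
    stop("positives > total_partitions in reaction ", plate$reaction_id[bad])
  }
  plate
}

#' Write a plate data.frame as CSV
#'
#' @param plate plate data.frame (see [read_plate()] for columns).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quantify every reaction of a plate
#'
#' Applies [poisson_concentration()] per (reaction, assay) and computes each
#' marker's albumin-normalised ratio within its reaction. The panel supplies
#' the assay roster and identifies the internal control.
#'
#' @param plate plate data.frame (see [read_plate()]).
#' @param panel a `panel_definition`.
#' @return data.frame with one row per (reaction, assay): the
#'   `poisson_concentration` columns plus `ratio_to_albumin_pct` (NA for the
#'   control itself or when albumin is 0) and `ratio_over_100` flag.
#' @export
quantify_reactions <- function(plate, panel) {
  ctrl <- panel$assay_name[panel$role == "internal_control"]
  if (length(ctrl) != 1) stop("panel must have exactly one internal control")
  unknown <- setdiff(plate$assay_name, panel$assay_name)
  if (length(unknown)) stop("assay not in panel: ", unknown[1])
  q <- poisson_concentration(plate$positives, plate$total_partitions,
                             plate$partition_volume_nl)
  out <- cbind(plate[c("reaction_id", "sample_id", "control_type",
                       "assay_name")], q)
  # per-reaction albumin copies
  alb <- out[out$assay_name == ctrl, c("reaction_id", "copies_per_reaction")]
  if (anyDuplicated(alb$reaction_id)) {
    stop("multiple albumin entries for reaction ",
         alb$reaction_id[duplicated(alb$reaction_id)][1])
  }
  no_ctrl <- setdiff(out$reaction_id, alb$reaction_id)
  if (length(no_ctrl)) {
    stop("reaction ", no_ctrl[1], " has no ", ctrl, " internal control entry")
  }
  alb_copies <- alb$copies_per_reaction[match(out$reaction_id,
                                              alb$reaction_id)]
  is_marker <- out$assay_name != ctrl
  ratio <- rep(NA_real_, nrow(out))
  ok <- is_marker & alb_copies > 0
  ratio[ok] <- 100 * out$copies_per_reaction[ok] / alb_copies[ok]
  out$ratio_to_albumin_pct <- ratio
  out$ratio_over_100 <- !is.na(ratio) & ratio > 100
  out
}

#' Acceptance bands for assay control wells
#'
#' Methylated controls must show a methylation rate (operationalised as the
#' albumin ratio) between 58% and 98%; unmethylated controls must show no
#' signal beyond a small false-positive partition allowance.
#'
#' @param methylated_band numeric length-2, acceptance band (percent).
#' @param unmethylated_allowance maximum positive partitions tolerated per
#'   marker assay in an unmethylated control (default 0).
#' @return object of class `control_expectation`.
#' @export
control_expectation <- function(methylated_band = c(58, 98),
                                unmethylated_allowance = 0) {
  stopifnot(length(methylated_band) == 2,
            methylated_band[1] < methylated_band[2],
            unmethylated_allowance >= 0)
  structure(list(methylated_band = methylated_band,
                 unmethylated_allowance = unmethylated_allowance),
            class = "control_expectation")
}

#' Validate methylated / unmethylated control wells
#'
#' @param plate plate data.frame containing reactions with `control_type`
#'   `"methylated"` or `"unmethylated"`.
#' @param panel a `panel_definition`.
#' @param expectation a [control_expectation()].
#' @return data.frame with one row per (control reaction, marker assay):
#'   measured quantity (`ratio_pct` or `positives`), the applied band and a
#'   `pass` flag.
#' @export
validate_controls <- function(plate, panel,
                              expectation = control_expectation()) {
  ctrl_assay <- panel$assay_name[panel$role == "internal_control"]
  wells <- plate[plate$control_type %in% c("methylated", "unmethylated"), ,
                 drop = FALSE]
  if (nrow(wells) == 0) stop("no control reactions in plate")
  has_alb <- tapply(wells$assay_name == ctrl_assay, wells$reaction_id, any)
  if (any(!has_alb)) {
    stop("control reaction ", names(has_alb)[!has_alb][1],
         " is missing its albumin entry")
  }
  q <- quantify_reactions(wells, panel)
  q <- q[q$assay_name != ctrl_assay, , drop = FALSE]
  band <- expectation$methylated_band
  meth <- q$control_type == "methylated"
  pass <- logical(nrow(q))
  pass[meth] <- !is.na(q$ratio_to_albumin_pct[meth]) &
    q$ratio_to_albumin_pct[meth] >= band[1] &
    q$ratio_to_albumin_pct[meth] <= band[2]
  pass[!meth] <- q$k[!meth] <= expectation$unmethylated_allowance
  data.frame(reaction_id = q$reaction_id,
             assay_name = q$assay_name,
             control_type = q$control_type,
             ratio_pct = q$ratio_to_albumin_pct,
             positives = q$k,
             pass = pass,
             stringsAsFactors = FALSE)
}

#' Replicate reproducibility of albumin-normalised ratios
#'
#' Sample standard deviation of repeated ratio measurements per assay, and
#' the mean SD across assays, in percentage-point units of the ratio.
#'
#' @param ratios numeric matrix, replicates x assays (a vector is treated as
#'   one assay), in percent.
#' @return list with `per_assay_sd` (named numeric) and `mean_sd`.
#' @export
replicate_sd <- function(ratios) {
  if (is.null(dim(ratios))) ratios <- matrix(ratios, ncol = 1)
  if (nrow(ratios) < 2) stop("need >= 2 replicates to compute an SD")
  per <- apply(ratios, 2, stats::sd)
  list(per_assay_sd = per, mean_sd = mean(per))
}

#' Genome-equivalent copies from a DNA mass
#'
#' One haploid human genome weighs about 3.3 pg, so `mass_ng * 1000 / 3.3`
#' gives the number of haploid genome equivalents — the maximum copy number
#' any single-locus assay can see in that input.
#'
#' @param mass_ng DNA mass in nanograms (vectorised, >= 0).
#' @param haploid_genome_pg haploid genome mass in picograms.
#' @return continuous genome-equivalent copy number.
#' @export
copies_from_mass <- function(mass_ng, haploid_genome_pg = 3.3) {
  if (any(mass_ng < 0)) stop("mass must be non-negative")
  mass_ng * 1000 / haploid_genome_pg
}

#' Bisulfite conversion loss model
#'
#' Bisulfite treatment degrades a large fraction of the input DNA (67-80% in
#' this assay's validation range); only a retention fraction `r = 1 - loss`
#' of input copies survives to be counted.
#'
#' @param loss_fraction fraction of input DNA destroyed, in `[0, 1)`.
#' @return object of class `bisulfite_loss` with fields `loss` and
#'   `retention`.
#' @export
bisulfite_loss <- function(loss_fraction) {
  if (any(loss_fraction < 0 | loss_fraction >= 1)) {
    stop("loss_fraction must be in [0, 1)")
  }
  structure(list(loss = loss_fraction, retention = 1 - loss_fraction),
            class = "bisulfite_loss")
}

#' Probability of detecting at least one copy after conversion loss
#'
#' Each of `n0` input copies independently survives bisulfite conversion with
#' probability `r` and, if surviving, is detected with probability `q`
#' (binomial thinning), so `P(detect) = 1 - (1 - r*q)^n0`. The expected
#' number of surviving, detectable copies `n0 * r * q` is returned alongside.
#'
#' @param n0 input copies (non-negative integer, vectorised).
#' @param loss a [bisulfite_loss()].
#' @param q per-surviving-copy detection probability, in `(0, 1]`.
#' @return data.frame with columns `n0`, `probability`,
#'   `expected_surviving`.
#' @export
detection_probability <- function(n0, loss, q = 1) {
  stopifnot(inherits(loss, "bisulfite_loss"))
  if (any(n0 < 0) || any(n0 != floor(n0))) {
    stop("n0 must be a non-negative integer")
  }
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  r <- loss$retention
  data.frame(n0 = n0,
             probability = 1 - (1 - r * q)^n0,
             expected_surviving = n0 * r * q)
}

#' Limit of detection under bisulfite conversion loss
#'
#' Smallest integer input copy number whose detection probability reaches
#' `target_probability`, by analytic inversion of the thinning model:
#' `n0 = ceil(ln(1 - target) / ln(1 - r*q))`. Optionally cross-validated by a
#' Monte-Carlo dilution series (binomial survival draws per trial), reported
#' as the smallest `n0` whose empirical detection frequency reaches the
#' target.
#'
#' @param loss a [bisulfite_loss()].
#' @param q per-copy detection probability.
#' @param target_probability required detection probability, in `(0, 1)`.
#' @param mc_trials Monte-Carlo trials per candidate `n0` (0 = closed form
#'   only).
#' @return list with `n0` (closed form), and when `mc_trials > 0`:
#'   `mc_n0` and `mc_detection_freq` (named vector over the scanned grid).
#' @export
estimate_lod <- function(loss, q = 1, target_probability = 0.95,
                         mc_trials = 0) {
  stopifnot(inherits(loss, "bisulfite_loss"))
  if (target_probability <= 0 || target_probability >= 1) {
    stop("target_probability must be in (0, 1)")
  }
  rq <- loss$retention * q
  n0 <- if (rq >= 1) 1L else {
    as.integer(ceiling(log(1 - target_probability) / log(1 - rq)))
  }
  out <- list(n0 = n0)
  if (mc_trials > 0) {
    grid <- seq_len(max(2L * n0, n0 + 3L))
    freq <- vapply(grid, function(n) {
      mean(stats::rbinom(mc_trials, n, rq) > 0)
    }, numeric(1))
    names(freq) <- grid
    hit <- which(freq >= target_probability)
    out$mc_n0 <- if (length(hit)) grid[min(hit)] else NA_integer_
    out$mc_detection_freq <- freq
  }
  out
}
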
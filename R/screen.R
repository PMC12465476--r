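#' Define a screening target compartment
#'
#' A target spec names the compartment being screened for (e.g. pan-renal =
#' all kidney subcompartments, renal endothelial, renal epithelial), the
#' atlas groups that constitute it, the background groups the marker must be
#' unmethylated in, and which background groups are blood. Blood is singled
#' out because leukocyte DNA is the dominant background of plasma cfDNA, so
#' markers must be held to a stricter negativity cap there.
#'
#' @param name compartment label (e.g. `"pan_renal"`, `"renal_endothelial"`,
#'   `"renal_epithelial"`, or any custom label).
#' @param target_groups non-empty character vector of atlas groups forming
#'   the target compartment.
#' @param background_groups groups the marker must be negative in; `NULL`
#'   (default) means "all atlas groups not in the target", resolved at screen
#'   time.
#' @param blood_groups subset of the background flagged as
#'   contaminant-critical blood cell groups.
#' @return an object of class `target_spec`.
#' @export
target_spec <- function(name, target_groups, background_groups = NULL,
                        blood_groups = character()) {
  if (length(target_groups) == 0) stop("target_groups must be non-empty")
  if (!is.null(background_groups) &&
      length(intersect(target_groups, background_groups))) {
    stop("target and background groups must be disjoint: ",
         intersect(target_groups, background_groups)[1])
  }
  if (!is.null(background_groups) &&
      length(setdiff(blood_groups, background_groups))) {
    stop("blood_groups must be a subset of background_groups")
  }
  structure(list(name = name,
                 target_groups = unique(target_groups),
                 background_groups = background_groups,
                 blood_groups = unique(blood_groups)),
            class = "target_spec")
}

#' Screening thresholds
#'
#' Numeric criteria for a block to qualify as a compartment-specific
#' hypermethylated marker. All thresholds are on per-group mean beta.
#' Because the downstream dPCR probes count methylated alleles, a usable
#' marker must be strongly methylated in every target group and near zero
#' everywhere else, most strictly in blood.
#'
#' @param tau_target minimum mean beta required in every target group.
#' @param tau_background maximum mean beta allowed in any background group.
#' @param tau_blood stricter cap applied to blood groups.
#' @param min_margin minimum specificity margin (worst-case target mean minus
#'   worst-case background mean).
#' @param top_k truncate the ranked passing list to this many markers
#'   (`Inf` = keep all).
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(tau_target = 0.5, tau_background = 0.15,
                          tau_blood = 0.05, min_margin = 0.3, top_k = Inf) {
  if (!(0 <= tau_blood && tau_blood <= tau_background &&
        tau_background < tau_target && tau_target <= 1)) {
    stop("need 0 <= tau_blood <= tau_background < tau_target <= 1")
  }
  if (min_margin < 0 || min_margin > 1) stop("min_margin must be in [0,1]")
  structure(list(tau_target = tau_target, tau_background = tau_background,
                 tau_blood = tau_blood, min_margin = min_margin,
                 top_k = top_k),
            class = "screen_config")
}

resolve_background <- function(spec, groups) {
  bg <- spec$background_groups
  if (is.null(bg)) bg <- setdiff(groups, spec$target_groups)
  if (length(intersect(bg, spec$target_groups))) {
    stop("target and background groups must be disjoint")
  }
  blood <- spec$blood_groups
  if (length(setdiff(blood, bg))) {
    stop("blood_groups must be a subset of the background groups")
  }
  list(background = bg, blood = blood)
}

# Vectorised scoring core: takes a blocks x groups matrix of per-group mean
# betas (NA = group unobserved) and returns the score table.
score_mean_matrix <- function(mean_mat, spec, config, groups) {
  res <- resolve_background(spec, groups)
  tg <- spec$target_groups
  bg <- res$background
  blood <- res$blood
  missing_groups <- setdiff(c(tg, bg), colnames(mean_mat))
  if (length(missing_groups)) {
    stop("group absent from atlas: ", missing_groups[1])
  }
  row_min <- function(m) {
    cl <- lapply(seq_len(ncol(m)), function(j) m[, j])
    suppressWarnings(do.call(pmin, c(cl, list(na.rm = TRUE))))
  }
  row_max <- function(m) {
    cl <- lapply(seq_len(ncol(m)), function(j) m[, j])
    suppressWarnings(do.call(pmax, c(cl, list(na.rm = TRUE))))
  }
  bg_nonblood <- setdiff(bg, blood)
  if (length(bg_nonblood) == 0) stop("background cannot be all blood groups")
  tmat <- mean_mat[, tg, drop = FALSE]
  bmat <- mean_mat[, bg_nonblood, drop = FALSE]
  target_min <- row_min(tmat)
  background_max <- row_max(bmat)
  blood_max <- if (length(blood)) {
    row_max(mean_mat[, blood, drop = FALSE])
  } else {
    rep(NA_real_, nrow(mean_mat))
  }
  # evaluable: every target group observed, >=1 background group observed
  evaluable <- rowSums(is.na(tmat)) == 0 & rowSums(!is.na(bmat)) > 0
  margin <- target_min - background_max
  pass_target <- !is.na(target_min) & target_min >= config$tau_target
  pass_background <- !is.na(background_max) &
    background_max <= config$tau_background
  # no blood group declared or none observed: no evidence against the block
  pass_blood <- is.na(blood_max) | blood_max <= config$tau_blood
  pass_margin <- !is.na(margin) & margin >= config$min_margin
  pass <- evaluable & pass_target & pass_background & pass_blood & pass_margin
  direction <- ifelse(is.na(margin), NA_character_,
                      ifelse(margin > 0, "hyper",
                             ifelse(margin < 0, "hypo", "flat")))
  out <- data.frame(block_id = rownames(mean_mat),
                    compartment = spec$name,
                    target_min_beta = target_min,
                    background_max_beta = background_max,
                    blood_max_beta = blood_max,
                    margin = margin,
                    direction = direction,
                    evaluable = evaluable,
                    pass_target = pass_target,
                    pass_background = pass_background,
                    pass_blood = pass_blood,
                    pass_margin = pass_margin,
                    pass = pass,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

summary_to_mean_matrix <- function(summary) {
  groups <- unique(summary$group)
  blocks <- unique(summary$block_id)
  mat <- matrix(NA_real_, nrow = length(blocks), ncol = length(groups),
                dimnames = list(blocks, groups))
  mat[cbind(match(summary$block_id, blocks),
            match(summary$group, groups))] <- summary$mean_beta
  mat
}

#' Score a single block against a compartment spec
#'
#' Computes, from the group summary rows of one block, the worst-case target
#' methylation (`target_min_beta`), the worst-case non-blood background
#' methylation (`background_max_beta`), the blood maximum
#' (`blood_max_beta`, held to its own stricter cap) and the specificity
#' margin `target_min_beta - background_max_beta`, and evaluates the pass
#' criteria of `config`. A block whose target groups are not all observed is
#' returned with `evaluable = FALSE` and `pass = FALSE`.
#'
#' @param summary a `group_summary` (output of [aggregate_by_group()]),
#'   or its subset of rows for the block.
#' @param block_id the block to score.
#' @param spec a [target_spec()].
#' @param config a [screen_config()].
#' @return one-row data.frame of per-criterion quantities and pass flags.
#' @export
score_block <- function(summary, block_id, spec, config = screen_config()) {
  rows <- summary[summary$block_id == block_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("block absent from summary: ", block_id)
  mat <- summary_to_mean_matrix(rows)
  score_mean_matrix(mat, spec, config, groups = unique(summary$group))
}

#' Screen every atlas block for compartment-specific methylation
#'
#' Scores all evaluable blocks via [score_block()]'s criteria, then returns
#' the passing blocks ranked by specificity margin (descending, ties broken
#' by `block_id` ascending), truncated to `config$top_k`. The full score
#' table for every evaluable block is attached as attribute `"scores"`. The
#' atlas should already have passed [filter_blocks_by_replication()].
#'
#' @param atlas an `atlas_matrix`.
#' @param spec a [target_spec()].
#' @param config a [screen_config()].
#' @return data.frame of passing blocks with a `rank` column; attribute
#'   `"scores"` holds all block scores.
#' @export
screen_markers <- function(atlas, spec, config = screen_config()) {
  groups <- atlas_groups(atlas)
  unknown <- setdiff(spec$target_groups, groups)
  if (length(unknown)) stop("target group absent from atlas: ", unknown[1])
  summary <- aggregate_by_group(atlas)
  mat <- summary_to_mean_matrix(summary)
  scores <- score_mean_matrix(mat, spec, config, groups = groups)
  passing <- scores[scores$pass, , drop = FALSE]
  ord <- order(-passing$margin, passing$block_id)
  passing <- passing[ord, , drop = FALSE]
  if (is.finite(config$top_k) && nrow(passing) > config$top_k) {
    passing <- passing[seq_len(config$top_k), , drop = FALSE]
  }
  passing$rank <- seq_len(nrow(passing))
  rownames(passing) <- NULL
  attr(passing, "scores") <- scores
  passing
}

default_assay_names <- list(
  pan_renal = "CTDP1",
  endothelial = c("ARID3A", "GATA2", "LOC124903692", "RHBDF2",
                  "SEPT5-GP1BB", "TNS2-AS1"),
  epithelial = c("PAX2", "ACSL5")
)

#' The canonical 10-target assay panel
#'
#' Nine kidney-specific methylation assays (one pan-renal, six renal
#' endothelial, two renal epithelial) plus the albumin (ALB) internal
#' control, which counts total genome copies regardless of methylation.
#'
#' @param block_ids optional named character vector mapping assay names to
#'   atlas block ids.
#' @return data.frame of class `panel_definition` with columns `assay_name`,
#'   `block_id`, `role`, `channel_id`.
#' @export
default_panel <- function(block_ids = NULL) {
  entries <- data.frame(
    assay_name = c(default_assay_names$pan_renal,
                   default_assay_names$endothelial,
                   default_assay_names$epithelial, "ALB"),
    block_id = NA_character_,
    role = c("pan_renal", rep("endothelial", 6), rep("epithelial", 2),
             "internal_control"),
    stringsAsFactors = FALSE
  )
  entries$channel_id <- seq_len(nrow(entries))
  if (!is.null(block_ids)) {
    idx <- match(names(block_ids), entries$assay_name)
    if (anyNA(idx)) stop("unknown assay name: ", names(block_ids)[is.na(idx)][1])
    entries$block_id[idx] <- unname(block_ids)
  }
  class(entries) <- c("panel_definition", "data.frame")
  entries
}

#' Marker assay names of a panel (internal control excluded)
#'
#' @param panel a `panel_definition`.
#' @return character vector of marker assay names.
#' @export
panel_markers <- function(panel) {
  panel$assay_name[panel$role != "internal_control"]
}

#' Assemble the assay panel from per-compartment screens
#'
#' Takes the top-`quota` passing markers of each compartment screen and
#' appends the albumin internal control, assigning channel ids in declaration
#' order. A block passing two screens is assigned once, to the compartment
#' where its margin is larger (tie goes to `pan_renal`).
#'
#' @param screens named list of [screen_markers()] outputs, one per
#'   compartment; names are the compartment labels.
#' @param quota named integer vector, markers to take per compartment.
#'   Default `c(pan_renal = 1, endothelial = 6, epithelial = 2)`.
#' @return a `panel_definition` (see [default_panel()]) with `block_id`
#'   filled in from the screens.
#' @export
select_panel <- function(screens,
                         quota = c(pan_renal = 1, endothelial = 6,
                                   epithelial = 2)) {
  comps <- names(quota)
  missing_comp <- setdiff(comps, names(screens))
  if (length(missing_comp)) stop("no screen supplied for compartment: ",
                                 missing_comp[1])
  cand <- do.call(rbind, lapply(comps, function(cp) {
    s <- screens[[cp]]
    if (nrow(s) == 0) return(NULL)
    data.frame(compartment = cp, block_id = s$block_id, margin = s$margin,
               stringsAsFactors = FALSE)
  }))
  # dedup: keep each block in its best compartment; tie -> pan_renal
  if (!is.null(cand) && nrow(cand)) {
    pref <- ifelse(cand$compartment == "pan_renal", 1L, 0L)
    ord <- order(cand$block_id, -cand$margin, -pref)
    cand <- cand[ord, , drop = FALSE]
    cand <- cand[!duplicated(cand$block_id), , drop = FALSE]
  }
  rows <- list()
  for (cp in comps) {
    sub <- cand[cand$compartment == cp, , drop = FALSE]
    sub <- sub[order(-sub$margin, sub$block_id), , drop = FALSE]
    k <- quota[[cp]]
    if (nrow(sub) < k) {
      stop("compartment '", cp, "' has only ", nrow(sub),
           " passing markers, ", k - nrow(sub), " short of its quota of ", k)
    }
    sub <- sub[seq_len(k), , drop = FALSE]
    nm <- default_assay_names[[cp]]
    if (is.null(nm) || length(nm) != k) {
      nm <- paste(cp, seq_len(k), sep = "_")
    }
    rows[[cp]] <- data.frame(assay_name = nm, block_id = sub$block_id,
                             role = cp, stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  entries <- rbind(entries,
                   data.frame(assay_name = "ALB", block_id = NA_character_,
                              role = "internal_control",
                              stringsAsFactors = FALSE))
  entries$channel_id <- seq_len(nrow(entries))
  rownames(entries) <- NULL
  class(entries) <- c("panel_definition", "data.frame")
  entries
}

#' Write a screen report as TSV
#'
#' @param screen output of [screen_markers()].
#' @param path output path.
#' @param all_scores if `TRUE` (default) write every evaluated block; the
#'   passing rank is `NA` for non-passing blocks.
#' @return invisibly, `path`.
#' @export
write_screen_report <- function(screen, path, all_scores = TRUE) {
  if (all_scores && !is.null(attr(screen, "scores"))) {
    tab <- attr(screen, "scores")
    tab$rank <- screen$rank[match(tab$block_id, screen$block_id)]
  } else {
    tab <- as.data.frame(screen)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a panel definition as YAML
#'
#' @param panel a `panel_definition`.
#' @param path file path.
#' @return `write_panel`: invisibly, `path`; `read_panel`: the panel.
#' @export
write_panel <- function(panel, path) {
  entries <- lapply(seq_len(nrow(panel)), function(i) {
    list(assay_name = panel$assay_name[i],
         block_id = if (is.na(panel$block_id[i])) NULL else panel$block_id[i],
         role = panel$role[i],
         channel_id = panel$channel_id[i])
  })
  yaml::write_yaml(list(panel = entries), path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  raw <- yaml::read_yaml(path)$panel
  entries <- data.frame(
    assay_name = vapply(raw, `[[`, "", "assay_name"),
    block_id = vapply(raw, function(e)
      if (is.null(e$block_id)) NA_character_ else e$block_id, ""),
    role = vapply(raw, `[[`, "", "role"),
    channel_id = vapply(raw, function(e) as.integer(e$channel_id), 1L),
    stringsAsFactors = FALSE
  )
  if (sum(entries$role == "internal_control") != 1) {
    stop("panel must have exactly one internal control")
  }
  if (anyDuplicated(entries$assay_name)) stop("duplicate assay_name in panel")
  class(entries) <- c("panel_definition", "data.frame")
  entries
}
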
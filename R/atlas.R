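#' Construct a block-level methylation atlas
#'
#' An atlas holds per-block methylation fractions (beta values) for a set of
#' reference samples, each sample belonging to an anatomical group (tissue or
#' purified cell type) with a replicate index. It is the substrate of the
#' compartment-specific marker screen.
#'
#' @param blocks data.frame with columns `chrom`, `start`, `end`, `block_id`.
#'   Coordinates are 0-based half-open (BED convention). `block_id` must be
#'   unique.
#' @param samples data.frame with columns `sample_id`, `group`, `replicate`.
#'   `(group, replicate)` pairs must be unique.
#' @param beta numeric matrix, blocks x samples, values in \[0, 1\] or `NA`
#'   for missing. A beta of 0 is data (fully unmethylated), never missing.
#' @param coverage optional matrix of non-negative read counts, same shape.
#'
#' @return An object of class `atlas_matrix`: a list with elements `blocks`,
#'   `samples`, `beta` (rownames = block ids, colnames = sample ids) and
#'   optionally `coverage`.
#' @export
atlas_matrix <- function(blocks, samples, beta, coverage = NULL) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  rownames(beta) <- blocks$block_id
  colnames(beta) <- samples$sample_id
  x <- structure(
    list(blocks = blocks, samples = samples, beta = beta, coverage = coverage),
    class = "atlas_matrix"
  )
  validate_atlas(x)
  x
}

#' Validate an atlas_matrix
#'
#' Checks structural invariants: column presence, unique block ids, unique
#' (group, replicate) pairs, matching matrix dimensions, betas in \[0, 1\].
#'
#' @param x an `atlas_matrix`.
#' @return `x`, invisibly. Throws an informative error on the first violation.
#' @export
validate_atlas <- function(x) {
  stopifnot(inherits(x, "atlas_matrix"))
  need_b <- c("chrom", "start", "end", "block_id")
  if (!all(need_b %in% names(x$blocks))) {
    stop("blocks must have columns: ", paste(need_b, collapse = ", "))
  }
  need_s <- c("sample_id", "group", "replicate")
  if (!all(need_s %in% names(x$samples))) {
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  }
  if (anyDuplicated(x$blocks$block_id)) {
    dup <- x$blocks$block_id[duplicated(x$blocks$block_id)][1]
    stop("duplicate block_id: ", dup)
  }
  if (nrow(x$blocks) > 0) {
    if (any(is.na(x$blocks$chrom)) || any(!nzchar(x$blocks$chrom))) {
      stop("chrom must be non-empty")
    }
    bad <- which(!(x$blocks$start < x$blocks$end))
    if (length(bad)) {
      stop("block ", x$blocks$block_id[bad[1]], " has start >= end")
    }
  }
  if (anyDuplicated(x$samples$sample_id)) {
    stop("duplicate sample_id: ",
         x$samples$sample_id[duplicated(x$samples$sample_id)][1])
  }
  key <- paste(x$samples$group, x$samples$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (group, replicate) pair in sample sheet: ",
         gsub("\r", "/", key[duplicated(key)][1]))
  }
  if (!identical(dim(x$beta), c(nrow(x$blocks), nrow(x$samples)))) {
    stop("beta matrix must be |blocks| x |samples| (",
         nrow(x$blocks), " x ", nrow(x$samples), "), got ",
         nrow(x$beta), " x ", ncol(x$beta))
  }
  bad <- which(!is.na(x$beta) & (x$beta < 0 | x$beta > 1))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(x$beta))
    stop("beta out of [0,1] at block '", rownames(x$beta)[ij[1]],
         "', sample '", colnames(x$beta)[ij[2]], "': ", x$beta[bad[1]])
  }
  if (!is.null(x$coverage)) {
    if (!identical(dim(x$coverage), dim(x$beta))) {
      stop("coverage must have the same shape as beta")
    }
    if (any(!is.na(x$coverage) & x$coverage < 0)) {
      stop("coverage must be non-negative")
    }
  }
  invisible(x)
}

#' @export
print.atlas_matrix <- function(x, ...) {
  cat("Methylation atlas:", nrow(x$blocks), "blocks x",
      nrow(x$samples), "samples\n")
  cat("Groups (", length(unique(x$samples$group)), "): ",
      paste(utils::head(sort(unique(x$samples$group)), 6), collapse = ", "),
      if (length(unique(x$samples$group)) > 6) ", ..." else "", "\n", sep = "")
  cat("Missing beta entries:", sum(is.na(x$beta)), "\n")
  invisible(x)
}

#' Group labels present in an atlas
#'
#' @param atlas an `atlas_matrix`.
#' @return character vector of unique group labels, in sample-sheet order.
#' @export
atlas_groups <- function(atlas) {
  unique(atlas$samples$group)
}

#' Read a methylation atlas from a beta table and sample sheet
#'
#' The beta table is TSV with columns `chrom start end block_id` followed by
#' one numeric column per sample (BED-compatible first three columns);
#' missing betas are encoded `NA`. The sample sheet is TSV with columns
#' `sample_id group replicate`. Every beta column must be matched by a sample
#' sheet row and vice versa.
#'
#' @param beta_table_path path to the beta TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return a validated `atlas_matrix`.
#' @export
read_atlas <- function(beta_table_path, sample_sheet_path) {
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE,
                             colClasses = c(sample_id = "character",
                                            group = "character"))
  need_s <- c("sample_id", "group", "replicate")
  if (!all(need_s %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need_s, collapse = ", "))
  }
  tab <- utils::read.delim(beta_table_path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = c(chrom = "character",
                                          block_id = "character"))
  need_b <- c("chrom", "start", "end", "block_id")
  if (!all(need_b %in% names(tab))) {
    stop("beta table must start with columns: ",
         paste(need_b, collapse = ", "))
  }
  beta_cols <- setdiff(names(tab), need_b)
  unmatched <- setdiff(beta_cols, sheet$sample_id)
  if (length(unmatched)) {
    stop("beta table column '", unmatched[1],
         "' has no sample sheet entry")
  }
  missing_cols <- setdiff(sheet$sample_id, beta_cols)
  if (length(missing_cols)) {
    stop("sample '", missing_cols[1], "' has no column in the beta table")
  }
  beta <- as.matrix(tab[, sheet$sample_id, drop = FALSE])
  atlas_matrix(blocks = tab[, need_b, drop = FALSE],
               samples = sheet,
               beta = beta)
}

#' Write a methylation atlas to a beta table and sample sheet
#'
#' Betas are printed with fixed 6-decimal precision and missing values as
#' `NA`, so that `read_atlas()` reproduces the matrix bit-for-bit at that
#' precision and write-read-write is byte-idempotent.
#'
#' @param atlas an `atlas_matrix`.
#' @param beta_table_path output path for the beta TSV.
#' @param sample_sheet_path output path for the sample sheet TSV.
#' @return invisibly, the two paths.
#' @export
write_atlas <- function(atlas, beta_table_path, sample_sheet_path) {
  validate_atlas(atlas)
  sheet <- atlas$samples[, c("sample_id", "group", "replicate")]
  utils::write.table(sheet, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fmt <- atlas$beta
  txt <- matrix(sprintf("%.6f", fmt), nrow = nrow(fmt), ncol = ncol(fmt))
  txt[is.na(fmt)] <- "NA"
  out <- cbind(atlas$blocks[, c("chrom", "start", "end", "block_id")],
               as.data.frame(txt, stringsAsFactors = FALSE))
  names(out) <- c("chrom", "start", "end", "block_id", colnames(atlas$beta))
  utils::write.table(out, beta_table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(beta_table_path, sample_sheet_path))
}

#' Keep blocks observed in enough replicates of every required group
#'
#' Mirrors the atlas-wide replication filter applied before marker screening:
#' a block is retained iff it has a non-missing beta in at least
#' `min_replicates` samples of every group in `required_groups`.
#'
#' @param atlas an `atlas_matrix`.
#' @param min_replicates minimum non-missing replicates per group (>= 1).
#' @param required_groups groups that must all meet the threshold; defaults
#'   to every group in the atlas.
#' @return a new `atlas_matrix` with the surviving blocks, sample set and
#'   block order unchanged.
#' @export
filter_blocks_by_replication <- function(atlas, min_replicates = 2,
                                         required_groups = atlas_groups(atlas)) {
  validate_atlas(atlas)
  if (min_replicates < 1) stop("min_replicates must be >= 1")
  unknown <- setdiff(required_groups, atlas_groups(atlas))
  if (length(unknown)) {
    stop("unknown group in required_groups: ", unknown[1])
  }
  keep <- rep(TRUE, nrow(atlas$blocks))
  for (g in required_groups) {
    cols <- which(atlas$samples$group == g)
    n_obs <- rowSums(!is.na(atlas$beta[, cols, drop = FALSE]))
    keep <- keep & (n_obs >= min_replicates)
  }
  atlas_matrix(blocks = atlas$blocks[keep, , drop = FALSE],
               samples = atlas$samples,
               beta = atlas$beta[keep, , drop = FALSE],
               coverage = if (!is.null(atlas$coverage))
                 atlas$coverage[keep, , drop = FALSE])
}

#' Summarise betas per block and group
#'
#' Aggregates replicate betas into per-(block, group) summaries used by the
#' marker screen. Groups with zero non-missing observations for a block are
#' flagged missing (`missing = TRUE`, statistics `NA`), never reported as 0.
#'
#' @param atlas an `atlas_matrix`.
#' @return data.frame of class `group_summary` with columns `block_id`,
#'   `group`, `n_replicates_observed`, `mean_beta`, `min_beta`, `max_beta`,
#'   `missing`.
#' @export
aggregate_by_group <- function(atlas) {
  validate_atlas(atlas)
  groups <- atlas_groups(atlas)
  n_blk <- nrow(atlas$blocks)
  pieces <- lapply(groups, function(g) {
    cols <- which(atlas$samples$group == g)
    sub <- atlas$beta[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    mean_b <- rowMeans(sub, na.rm = TRUE)
    col_list <- lapply(seq_len(ncol(sub)), function(j) sub[, j])
    min_b <- do.call(pmin, c(col_list, list(na.rm = TRUE)))
    max_b <- do.call(pmax, c(col_list, list(na.rm = TRUE)))
    none <- n_obs == 0
    mean_b[none] <- NA_real_
    min_b[none] <- NA_real_
    max_b[none] <- NA_real_
    data.frame(block_id = atlas$blocks$block_id,
               group = rep(g, n_blk),
               n_replicates_observed = n_obs,
               mean_beta = mean_b,
               min_beta = min_b,
               max_beta = max_b,
               missing = none,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Export blocks as a BED file
#'
#' Writes the (0-based half-open) coordinates of selected blocks as a
#' four-column BED file (`chrom start end name`).
#'
#' @param atlas an `atlas_matrix`.
#' @param block_ids blocks to export; defaults to all.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_blocks_bed <- function(atlas, path, block_ids = atlas$blocks$block_id) {
  missing_ids <- setdiff(block_ids, atlas$blocks$block_id)
  if (length(missing_ids)) {
    stop("block not in atlas: ", missing_ids[1])
  }
  sel <- atlas$blocks[match(block_ids, atlas$blocks$block_id), ]
  utils::write.table(sel[, c("chrom", "start", "end", "block_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
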
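#' Read / write a patient cohort table
#'
#' One row per patient-biopsy pair. Required columns: `patient_id`,
#' `tube_type` (EDTA/PAXgene), `biopsy_context` (indication/surveillance, may
#' be NA), `rejection` (0/1), `rejection_subtype` (ABMR/TCMR/mixed/none),
#' `any_banff_lesion` (0/1), `egfr` (mL/min/1.73m^2), `dsa` (0/1), plus one
#' numeric column per marker assay holding its albumin-normalised level.
#'
#' @param path CSV path.
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  validate_cohort(records)
  records
}

#' @rdname read_cohort
#' @param records cohort data.frame.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate cohort invariants
#'
#' @param records cohort data.frame.
#' @return `records`, invisibly.
#' @export
validate_cohort <- function(records) {
  need <- c("patient_id", "tube_type", "biopsy_context", "rejection",
            "rejection_subtype", "any_banff_lesion", "egfr", "dsa")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("cohort missing column: ", miss[1])
  rej <- as.logical(records$rejection)
  sub_none <- records$rejection_subtype == "none"
  if (any(rej & sub_none)) {
    stop("rejection record without subtype: ",
         records$patient_id[rej & sub_none][1])
  }
  if (any(!rej & !sub_none)) {
    stop("non-rejection record with subtype: ",
         records$patient_id[!rej & !sub_none][1])
  }
  if (any(records$egfr <= 0)) {
    stop("egfr must be positive: ", records$patient_id[records$egfr <= 0][1])
  }
  invisible(records)
}

# log10(x + delta) transform for right-skewed, zero-containing marker
# levels; delta defaults to half the smallest nonzero level of that marker.
marker_delta <- function(x) {
  nz <- x[!is.na(x) & x > 0]
  if (length(nz) == 0) return(0.5)   # all-zero marker: any constant works
  min(nz) / 2
}

build_model_frame <- function(records, outcome, predictors, markers,
                              delta = NULL) {
  miss <- setdiff(c(outcome, predictors), names(records))
  if (length(miss)) stop("column not in cohort: ", miss[1])
  y <- as.numeric(records[[outcome]])
  if (!all(stats::na.omit(y) %in% c(0, 1))) {
    stop("outcome '", outcome, "' must be binary 0/1")
  }
  mf <- data.frame(.y = y)
  deltas <- numeric(0)
  for (p in predictors) {
    x <- records[[p]]
    if (p %in% markers) {
      d <- if (!is.null(delta) && p %in% names(delta)) delta[[p]] else
        marker_delta(x)
      x <- log10(x + d)
      deltas[p] <- d
    } else if (is.character(x) || is.logical(x)) {
      x <- as.numeric(as.factor(x)) - 1
    } else {
      x <- as.numeric(x)
    }
    mf[[p]] <- x
  }
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  attr(mf, "deltas") <- deltas
  mf
}

#' Fit a logistic regression diagnostic model
#'
#' Maximum-likelihood logistic regression (binomial GLM, iteratively
#' reweighted least squares; convergence tolerance 1e-8, at most 100
#' iterations). Marker predictors are transformed `log10(x + delta)` with
#' `delta` = half the smallest nonzero level of that marker (overridable);
#' other predictors enter untransformed. Reports per-coefficient Wald
#' statistics, odds ratios with 95% CIs, and — for `egfr` — the OR per
#' 10-unit change alongside the per-unit OR. Complete separation (a
#' coefficient diverging beyond 15 on the transformed scale) is flagged and
#' its CI suppressed.
#'
#' @param records cohort data.frame.
#' @param outcome binary outcome column name (e.g. `"rejection"`,
#'   `"any_banff_lesion"`).
#' @param predictors character vector of predictor column names.
#' @param markers which predictors are marker levels (get the log
#'   transform); default none.
#' @param delta optional named numeric of per-marker offsets.
#' @return object of class `logistic_fit`: list with `table` (term,
#'   estimate, se, or, or_low, or_high, p), `loglik`, `converged`,
#'   `separation`, `n_used`, `deltas`, `outcome`, and the underlying `glm`
#'   fit in `model`.
#' @export
fit_logistic <- function(records, outcome, predictors, markers = character(),
                         delta = NULL) {
  mf <- build_model_frame(records, outcome, predictors, markers, delta)
  if (nrow(mf) == 0) stop("no complete cases")
  if (sum(mf$.y == 1) < 1 || sum(mf$.y == 0) < 1) {
    stop("outcome '", outcome, "' needs at least one event and one non-event")
  }
  for (p in predictors) {
    if (length(unique(mf[[p]])) < 2) {
      stop("constant predictor: ", p)
    }
  }
  fit <- stats::glm(.y ~ ., data = mf, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  co <- summary(fit)$coefficients
  # glm backticks non-syntactic assay names (e.g. SEPT5-GP1BB); strip them
  rownames(co) <- gsub("`", "", rownames(co), fixed = TRUE)
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  separation <- any(abs(est[-1]) > 15)
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = rownames(co),
                    estimate = est,
                    se = se,
                    or = exp(est),
                    or_low = exp(est - z * se),
                    or_high = exp(est + z * se),
                    p = co[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  tab$or_per_10 <- NA_real_
  i <- tab$term == "egfr"
  tab$or_per_10[i] <- exp(10 * tab$estimate[i])
  if (separation) {
    tab$or_low <- NA_real_
    tab$or_high <- NA_real_
  }
  rownames(tab) <- NULL
  structure(list(table = tab,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged && !separation,
                 separation = separation,
                 n_used = nrow(mf),
                 deltas = attr(mf, "deltas"),
                 outcome = outcome,
                 predictors = predictors,
                 markers = intersect(predictors, markers),
                 model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit: ", x$outcome, " ~ ",
      paste(x$predictors, collapse = " + "),
      "  (n = ", x$n_used, ")\n", sep = "")
  if (!x$converged) cat("WARNING: fit flagged unreliable",
                        if (x$separation) " (complete separation)", "\n",
                        sep = "")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v)
    if (is.numeric(v)) signif(v, 4) else v)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Linear predictor of a fitted model on (new) records
#'
#' @param fit a `logistic_fit`.
#' @param records cohort data.frame.
#' @return numeric score per record (log-odds scale), NA for incomplete
#'   rows.
#' @export
predict_score <- function(fit, records) {
  # score every row, complete or not, to keep alignment with records
  full <- data.frame(.y = as.numeric(records[[fit$outcome]]))
  for (p in fit$predictors) {
    x <- records[[p]]
    if (p %in% fit$markers) {
      x <- log10(x + fit$deltas[[p]])
    } else if (is.character(x) || is.logical(x)) {
      x <- as.numeric(as.factor(x)) - 1
    }
    full[[p]] <- as.numeric(x)
  }
  as.numeric(stats::predict(fit$model, newdata = full, type = "link"))
}

#' Univariate association screen
#'
#' One single-predictor logistic fit per candidate; the table reports the
#' odds ratio, 95% CI and Wald p per predictor, sorted by p ascending. No
#' multiple-testing correction is applied — rows are raw per-predictor
#' p-values. Per-predictor failures (e.g. a constant predictor) are recorded
#' in the `error` column rather than aborting the screen.
#'
#' @param records cohort data.frame.
#' @param outcome binary outcome column name.
#' @param predictors candidate predictor columns.
#' @param markers which candidates are marker levels.
#' @return data.frame with one row per candidate: `term`, `n`, `estimate`,
#'   `or`, `or_low`, `or_high`, `p`, `error`.
#' @export
univariate_screen <- function(records, outcome, predictors,
                              markers = character()) {
  rows <- lapply(predictors, function(p) {
    res <- tryCatch(fit_logistic(records, outcome, p, markers = markers),
                    error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(term = p, n = NA_integer_, estimate = NA_real_,
                        or = NA_real_, or_low = NA_real_, or_high = NA_real_,
                        p = NA_real_, error = conditionMessage(res),
                        stringsAsFactors = FALSE))
    }
    tr <- res$table[res$table$term == p, , drop = FALSE]
    data.frame(term = p, n = res$n_used, estimate = tr$estimate, or = tr$or,
               or_low = tr$or_low, or_high = tr$or_high, p = tr$p,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$p), out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the epigenetic signature
#'
#' The signature is the linear predictor of one joint logistic fit of the
#' markers that are univariately associated with the outcome at level
#' `alpha` (raw p-values, no multiplicity correction). Each patient's
#' signature score is `intercept + sum(coef * log10(level + delta))`.
#'
#' @param records cohort data.frame.
#' @param outcome binary outcome column name.
#' @param markers candidate marker columns.
#' @param alpha univariate inclusion threshold (default 0.05).
#' @return object of class `signature_model`: `members`, the joint
#'   `logistic_fit` in `fit`, the univariate screen in `screen`, and the
#'   per-record `scores`.
#' @export
build_signature <- function(records, outcome, markers, alpha = 0.05) {
  screen <- univariate_screen(records, outcome, markers, markers = markers)
  members <- screen$term[!is.na(screen$p) & screen$p < alpha]
  if (length(members) == 0) {
    stop("no marker is univariately associated with '", outcome,
         "' at alpha = ", alpha,
         "; consider models without an epigenetic signature")
  }
  members <- markers[markers %in% members]   # restore panel order
  fit <- fit_logistic(records, outcome, members, markers = members)
  structure(list(members = members, fit = fit, screen = screen,
                 alpha = alpha, outcome = outcome,
                 scores = predict_score(fit, records)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Epigenetic signature for '", x$outcome, "': ",
      length(x$members), " markers (univariate p < ", x$alpha, ")\n",
      "  members: ", paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score (new) records with a signature
#'
#' @param signature a `signature_model`.
#' @param records cohort data.frame containing the member marker columns.
#' @return numeric signature score per record (log-odds scale).
#' @export
signature_score <- function(signature, records) {
  predict_score(signature$fit, records)
}

#' ROC curve and AUC
#'
#' AUC by Mann-Whitney pair counting (ties count 1/2, computed via
#' midranks); the operating-point curve by a threshold sweep over the unique
#' scores (predict positive when score >= threshold). The trapezoidal area
#' of the stored curve equals the pair-counting AUC to 1e-12 and both are
#' returned.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return object of class `roc_result`: `curve` (threshold, sensitivity,
#'   specificity), `auc` (pair counting), `auc_trapezoid`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n_neg,
                 numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec)
  fpr <- 1 - curve$specificity
  auc_trap <- sum(diff(fpr) * (utils::head(curve$sensitivity, -1) +
                                 utils::tail(curve$sensitivity, -1)) / 2)
  structure(list(curve = curve, auc = auc, auc_trapezoid = auc_trap,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC = ", format(round(x$auc, 4)),
      " (", x$n_pos, " positives, ", x$n_neg, " negatives, ",
      nrow(x$curve), " operating points)\n", sep = "")
  invisible(x)
}

#' Compare diagnostic predictor combinations by apparent AUC
#'
#' Fits, on the full cohort, (a) the combined model eGFR + DSA + epigenetic
#' signature, (b) the clinical model eGFR + DSA, and (c) the signature
#' alone; for the any-Banff-lesion outcome additionally (d) all markers
#' jointly and (e) DSA alone. All AUCs are apparent (in-sample), matching
#' a development-cohort presentation; optional k-fold cross-validation
#' reports out-of-fold AUCs alongside.
#'
#' @param records cohort data.frame.
#' @param outcome binary outcome column (`"rejection"` or
#'   `"any_banff_lesion"`).
#' @param markers marker columns (default: the canonical 9-marker panel).
#' @param alpha signature inclusion threshold.
#' @param cv_folds if a positive integer, also compute stratified k-fold
#'   cross-validated AUC per model (default `NULL` = off).
#' @param seed RNG seed for the CV fold assignment.
#' @return object of class `model_comparison`: `auc_table` (model, auc, and
#'   `cv_auc` when requested), `rocs`, `fits`, `signature`.
#' @export
compare_models <- function(records, outcome, markers = panel_markers(default_panel()),
                           alpha = 0.05, cv_folds = NULL, seed = 1L) {
  validate_cohort(records)
  signature <- build_signature(records, outcome, markers, alpha)
  records$signature_score <- signature$scores
  specs <- list(
    combined = list(predictors = c("egfr", "dsa", "signature_score"),
                    markers = character()),
    clinical = list(predictors = c("egfr", "dsa"), markers = character()),
    signature = list(predictors = "signature_score", markers = character())
  )
  if (outcome == "any_banff_lesion") {
    specs$markers_only <- list(predictors = markers, markers = markers)
    specs$dsa_only <- list(predictors = "dsa", markers = character())
  }
  fits <- list()
  rocs <- list()
  auc <- numeric(0)
  for (nm in names(specs)) {
    f <- fit_logistic(records, outcome, specs[[nm]]$predictors,
                      markers = specs[[nm]]$markers)
    r <- roc_auc(predict_score(f, records), records[[outcome]])
    fits[[nm]] <- f
    rocs[[nm]] <- r
    auc[nm] <- r$auc
  }
  tab <- data.frame(model = names(auc), auc = unname(auc),
                    stringsAsFactors = FALSE)
  if (!is.null(cv_folds) && cv_folds > 1) {
    tab$cv_auc <- vapply(names(specs), function(nm) {
      cv_auc(records, outcome, specs[[nm]]$predictors, specs[[nm]]$markers,
             k = cv_folds, seed = seed)
    }, numeric(1))
  }
  structure(list(auc_table = tab, rocs = rocs, fits = fits,
                 signature = signature, outcome = outcome),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Apparent AUC, outcome '", x$outcome, "':\n", sep = "")
  tab <- x$auc_table
  tab$auc <- round(tab$auc, 3)
  if (!is.null(tab$cv_auc)) tab$cv_auc <- round(tab$cv_auc, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# stratified k-fold CV AUC for one predictor set
cv_auc <- function(records, outcome, predictors, markers, k = 5, seed = 1L) {
  set.seed(seed)
  y <- as.numeric(records[[outcome]])
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  scores <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    train <- records[fold != f, , drop = FALSE]
    fit <- fit_logistic(train, outcome, predictors, markers = markers)
    scores[fold == f] <- predict_score(fit, records[fold == f, ,
                                                    drop = FALSE])
  }
  roc_auc(scores, y)$auc
}

#' Export a model comparison's ROC points and OR tables as CSV
#'
#' @param comparison a `model_comparison`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_model_report <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "auc_table.csv")
  utils::write.csv(comparison$auc_table, p, row.names = FALSE)
  paths <- c(paths, p)
  or_tab <- do.call(rbind, lapply(names(comparison$fits), function(nm) {
    tab <- comparison$fits[[nm]]$table
    cbind(model = nm, tab)
  }))
  p <- file.path(dir, "odds_ratios.csv")
  utils::write.csv(or_tab, p, row.names = FALSE)
  paths <- c(paths, p)
  roc_tab <- do.call(rbind, lapply(names(comparison$rocs), function(nm) {
    cbind(model = nm, comparison$rocs[[nm]]$curve)
  }))
  p <- file.path(dir, "roc_points.csv")
  utils::write.csv(roc_tab, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
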
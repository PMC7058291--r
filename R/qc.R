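#' Phenotype QC configuration
#'
#' @param iqr_multiplier IQR multiple beyond the quartiles flagging a value
#'   as an outlier (default 3).
#' @param sd_multiplier SD multiple beyond the mean flagging a value as an
#'   outlier (default 4). A subject is excluded if either rule fires for any
#'   trait.
#' @param corr_threshold Pearson correlation above which a trait pair is
#'   considered redundant (default 0.6).
#' @param use_abs_corr apply the threshold to |r| (default) or to signed r.
#' @param loading_pcs principal components whose loadings decide which member
#'   of a redundant pair is dropped (default PC1-PC2).
#' @param strata stratification columns for imputation (default age band and
#'   sex).
#' @param age_band_width width of the age bands in years (default 10).
#' @param min_stratum_size minimum observed values for a stratum median;
#'   smaller strata fall back to the overall trait median (default 5).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(iqr_multiplier = 3, sd_multiplier = 4,
                      corr_threshold = 0.6, use_abs_corr = TRUE,
                      loading_pcs = 1:2, strata = c("age_band", "sex"),
                      age_band_width = 10, min_stratum_size = 5L) {
  stopifnot(iqr_multiplier > 0, sd_multiplier > 0,
            corr_threshold > 0, corr_threshold < 1)
  structure(list(iqr_multiplier = iqr_multiplier,
                 sd_multiplier = sd_multiplier,
                 corr_threshold = corr_threshold,
                 use_abs_corr = use_abs_corr, loading_pcs = loading_pcs,
                 strata = strata, age_band_width = age_band_width,
                 min_stratum_size = as.integer(min_stratum_size)),
            class = "qc_config")
}

new_qc_report <- function(n_input = 0L, n_excluded_outlier = 0L,
                          removed_traits = NULL, imputed_cells = 0L,
                          skipped_traits = character()) {
  removed_traits <- removed_traits %||%
    data.frame(trait = character(), partner_trait = character(),
               correlation = numeric(), loading_kept = numeric(),
               loading_removed = numeric(), stringsAsFactors = FALSE)
  structure(list(n_input = n_input, n_excluded_outlier = n_excluded_outlier,
                 n_after = n_input - n_excluded_outlier,
                 removed_traits = removed_traits,
                 imputed_cells = imputed_cells,
                 skipped_traits = skipped_traits),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d in, %d excluded, %d kept; %d cells imputed; %d traits pruned\n",
              x$n_input, x$n_excluded_outlier, x$n_after, x$imputed_cells,
              nrow(x$removed_traits)))
  invisible(x)
}

#' Serialize a QC report to YAML
#' @param report a `qc_report`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  yaml::write_yaml(list(
    n_input = report$n_input, n_excluded_outlier = report$n_excluded_outlier,
    n_after = report$n_after, imputed_cells = report$imputed_cells,
    skipped_traits = report$skipped_traits,
    removed_traits = lapply(seq_len(nrow(report$removed_traits)), function(i)
      as.list(report$removed_traits[i, ]))), path)
  invisible(path)
}

require_stage <- function(cohort, allowed, op) {
  st <- cohort_stage(cohort)
  if (!st %in% allowed)
    stop(sprintf("%s expects a cohort at stage %s, got '%s' (pipeline order is filter -> impute -> normalize -> prune)",
                 op, paste(sQuote(allowed), collapse = "/"), st), call. = FALSE)
  invisible(st)
}

set_stage <- function(cohort, stage) {
  attr(cohort, "qc_stage") <- stage
  cohort
}

#' Exclude subjects with extreme trait values
#'
#' A subject is excluded iff any of their trait values lies outside
#' `[Q1 - m_iqr*IQR, Q3 + m_iqr*IQR]` or beyond `mean +/- m_sd*SD`, with
#' quartiles and moments computed per trait on the input table (type-7
#' quartiles). Missing values never trigger exclusion. A constant trait
#' (zero IQR and zero SD) is skipped with a warning rather than used as an
#' exclusion criterion.
#'
#' @param cohort a raw `cohort_table`.
#' @param config a [qc_config()].
#' @return list(cohort, report): the filtered table (stage "filtered") and a
#'   `qc_report`.
#' @export
filter_outliers <- function(cohort, config = qc_config()) {
  require_stage(cohort, c("raw", "filtered"), "filter_outliers")
  traits <- cohort_traits(cohort)
  n <- nrow(cohort)
  if (n == 0L || !length(traits)) {
    return(list(cohort = set_stage(cohort, "filtered"),
                report = new_qc_report(n_input = n)))
  }
  out <- rep(FALSE, n)
  skipped <- character()
  for (tr in traits) {
    x <- cohort[[tr]]
    if (all(is.na(x))) {
      skipped <- c(skipped, tr)
      warning(sprintf("trait '%s' has no observed values; skipped as outlier criterion",
                      tr), call. = FALSE)
      next
    }
    q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if ((iqr == 0 && (is.na(s) || s == 0))) {
      skipped <- c(skipped, tr)
      warning(sprintf("trait '%s' is constant; skipped as outlier criterion", tr),
              call. = FALSE)
      next
    }
    bad <- (x < q[1] - config$iqr_multiplier * iqr) |
      (x > q[2] + config$iqr_multiplier * iqr) |
      (x < mu - config$sd_multiplier * s) |
      (x > mu + config$sd_multiplier * s)
    out <- out | (!is.na(bad) & bad)
  }
  kept <- set_stage(cohort[!out, , drop = FALSE], "filtered")
  attr(kept, "traits") <- traits
  attr(kept, "diseases") <- cohort_diseases(cohort)
  class(kept) <- class(cohort)
  list(cohort = kept,
       report = new_qc_report(n_input = n, n_excluded_outlier = sum(out),
                              skipped_traits = skipped))
}

age_band <- function(age, width) (floor(age / width) * width)

#' Impute missing trait values by stratified medians
#'
#' Each missing trait value is replaced by the median of its (age-band x sex)
#' stratum; strata with fewer than `min_stratum_size` observed values fall
#' back to the overall trait median.
#'
#' @param cohort a filtered `cohort_table` (complete `age` and `sex`).
#' @param config a [qc_config()].
#' @return list(cohort, report) with stage "imputed" and the number of
#'   imputed cells in the report.
#' @export
impute_missing <- function(cohort, config = qc_config()) {
  require_stage(cohort, "filtered", "impute_missing")
  traits <- cohort_traits(cohort)
  if (anyNA(cohort$age) || anyNA(cohort$sex))
    stop("strata columns (age, sex) must be complete", call. = FALSE)
  strat <- interaction(age_band(cohort$age, config$age_band_width),
                       cohort$sex, drop = TRUE)
  df <- as.data.frame(cohort)
  n_imputed <- 0L
  for (tr in traits) {
    x <- df[[tr]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    if (length(miss) == length(x))
      stop(sprintf("trait '%s' is entirely missing; cannot impute", tr),
           call. = FALSE)
    overall <- median(x, na.rm = TRUE)
    for (g in unique(strat[miss])) {
      idx <- miss[strat[miss] == g]
      obs <- x[strat == g & !is.na(x)]
      x[idx] <- if (length(obs) >= config$min_stratum_size) median(obs) else overall
    }
    n_imputed <- n_imputed + length(miss)
    df[[tr]] <- x
  }
  out <- new_cohort_table(df, traits, cohort_diseases(cohort), stage = "imputed")
  list(cohort = out, report = new_qc_report(n_input = nrow(df),
                                            imputed_cells = n_imputed))
}

#' Age/sex-adjusted standardization of traits
#'
#' Each trait is regressed on age and sex (linear model, sex as a two-level
#' factor); the residuals are scaled to zero mean and unit SD over the full
#' sample, so that cluster analysis operates on comparable, demographics-
#' adjusted axes. The fitted coefficients and scaling parameters are stored
#' in the `"normalization"` attribute for reuse on new data.
#'
#' @param cohort an imputed `cohort_table`.
#' @return A `cohort_table` at stage "normalized".
#' @export
stratified_normalize <- function(cohort) {
  require_stage(cohort, "imputed", "stratified_normalize")
  traits <- cohort_traits(cohort)
  df <- as.data.frame(cohort)
  params <- list()
  sexf <- factor(df$sex)
  for (tr in traits) {
    fit <- lm(df[[tr]] ~ df$age + sexf)
    r <- residuals(fit)
    s <- sd(r)
    if (!is.finite(s) || s < 1e-12)
      stop(sprintf("trait '%s' has zero residual variance after age/sex adjustment",
                   tr), call. = FALSE)
    m <- mean(r)
    df[[tr]] <- (r - m) / s
    params[[tr]] <- list(coef = coef(fit), center = m, scale = s)
  }
  out <- new_cohort_table(df, traits, cohort_diseases(cohort),
                          stage = "normalized")
  attr(out, "normalization") <- params
  out
}

#' Prune redundant (highly correlated) traits
#'
#' Runs PCA on the normalized trait matrix, then walks every trait pair whose
#' Pearson correlation exceeds the threshold in descending |r| order; for
#' each pair whose members both survive so far, the member with the smaller
#' loading magnitude (Euclidean norm of its biplot loadings on the configured
#' PCs, default PC1-PC2) is dropped. Ties keep the earlier column.
#'
#' @param cohort a normalized `cohort_table`.
#' @param config a [qc_config()].
#' @return list(cohort, report): pruned table (stage "pruned") and a
#'   `qc_report` whose `removed_traits` lists each removal with both
#'   loadings.
#' @export
prune_redundant_traits <- function(cohort, config = qc_config()) {
  require_stage(cohort, "normalized", "prune_redundant_traits")
  traits <- cohort_traits(cohort)
  if (length(traits) < 2L)
    return(list(cohort = set_stage(cohort, "pruned"),
                report = new_qc_report(n_input = nrow(cohort))))
  X <- trait_matrix(cohort)
  C <- cor(X, method = "pearson")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  pcs <- intersect(config$loading_pcs, seq_len(ncol(pc$rotation)))
  load <- pc$rotation[, pcs, drop = FALSE] %*% diag(pc$sdev[pcs], length(pcs))
  load_norm <- sqrt(rowSums(load^2))
  names(load_norm) <- traits

  cval <- if (config$use_abs_corr) abs(C) else C
  pairs <- which(upper.tri(C) & cval > config$corr_threshold, arr.ind = TRUE)
  removed <- new_qc_report()$removed_traits
  if (nrow(pairs)) {
    ord <- order(cval[pairs], decreasing = TRUE)
    pairs <- pairs[ord, , drop = FALSE]
    dropped <- character()
    for (i in seq_len(nrow(pairs))) {
      a <- traits[pairs[i, 1]]
      b <- traits[pairs[i, 2]]
      if (a %in% dropped || b %in% dropped) next
      # ties broken by column order: the earlier column is kept
      drop_b <- load_norm[b] <= load_norm[a]
      victim <- if (drop_b) b else a
      keeper <- if (drop_b) a else b
      dropped <- c(dropped, victim)
      removed <- rbind(removed, data.frame(
        trait = victim, partner_trait = keeper,
        correlation = C[pairs[i, 1], pairs[i, 2]],
        loading_kept = unname(load_norm[keeper]),
        loading_removed = unname(load_norm[victim]),
        stringsAsFactors = FALSE))
    }
    traits_kept <- setdiff(traits, dropped)
    df <- as.data.frame(cohort)
    df <- df[, setdiff(names(df), dropped), drop = FALSE]
    cohort <- new_cohort_table(df, traits_kept, cohort_diseases(cohort),
                               stage = "pruned")
  } else {
    cohort <- set_stage(cohort, "pruned")
  }
  list(cohort = cohort,
       report = new_qc_report(n_input = nrow(cohort),
                              removed_traits = removed))
}

#' Run the full phenotype QC pipeline
#'
#' Convenience wrapper applying, in fixed order: outlier exclusion, stratified
#' median imputation, age/sex-adjusted standardization and redundancy
#' pruning.
#'
#' @param cohort a raw `cohort_table`.
#' @param config a [qc_config()].
#' @return list(cohort, reports) where `reports` holds the per-stage
#'   `qc_report`s.
#' @export
run_phenotype_qc <- function(cohort, config = qc_config()) {
  f <- filter_outliers(cohort, config)
  i <- impute_missing(f$cohort, config)
  n <- stratified_normalize(i$cohort)
  p <- prune_redundant_traits(n, config)
  list(cohort = p$cohort,
       reports = list(outliers = f$report, imputation = i$report,
                      pruning = p$report))
}
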
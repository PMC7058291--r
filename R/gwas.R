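#' Per-sample genotype quality control
#'
#' Drops subjects whose genotype call rate is below `call_rate_min` and
#' subjects whose heterozygosity rate (fraction of non-missing genotypes
#' equal to 1) lies more than `het_sd` standard deviations from the sample
#' mean. If the heterozygosity SD is zero (all subjects identical) that
#' filter is disabled and a message logged.
#'
#' @param g a `genotype_matrix`.
#' @param call_rate_min minimum per-subject call rate (default 0.95).
#' @param het_sd SD multiple for the heterozygosity filter (default 5).
#' @return list(genotypes, report): the filtered matrix and a data.frame of
#'   dropped subject IDs with reasons.
#' @export
qc_samples <- function(g, call_rate_min = 0.95, het_sd = 5) {
  validate_genotype_matrix(g)
  if (length(g$subjects) < 2L) stop("need >= 2 subjects", call. = FALSE)
  called <- !is.na(g$dosage)
  call_rate <- rowMeans(called)
  het <- rowSums(g$dosage == 1L, na.rm = TRUE) / pmax(rowSums(called), 1L)
  het_mu <- mean(het)
  het_s <- sd(het)
  drop_call <- call_rate < call_rate_min
  if (is.na(het_s) || het_s == 0) {
    message("heterozygosity SD is zero; heterozygosity filter disabled")
    drop_het <- rep(FALSE, length(het))
  } else {
    drop_het <- abs(het - het_mu) > het_sd * het_s
  }
  drop <- drop_call | drop_het
  if (all(drop)) stop("sample QC would drop every subject", call. = FALSE)
  report <- data.frame(
    subject_id = g$subjects[drop],
    reason = ifelse(drop_call[drop] & drop_het[drop], "call_rate+heterozygosity",
                    ifelse(drop_call[drop], "call_rate", "heterozygosity")),
    call_rate = call_rate[drop], heterozygosity = het[drop],
    stringsAsFactors = FALSE)
  out <- new_genotype_matrix(g$dosage[!drop, , drop = FALSE], g$annotations)
  list(genotypes = out, report = report)
}

#' Per-SNP genotype quality control
#'
#' Removes SNPs with call rate < `call_rate_min`, minor allele frequency <
#' `maf_min`, or Hardy-Weinberg exact-test p < `hwe_p_min` (any filter
#' suffices). The minor allele is recomputed from the post-sample-QC data.
#'
#' @param g a `genotype_matrix` (after [qc_samples()]).
#' @param call_rate_min minimum per-SNP call rate (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_p_min minimum HWE exact p (default 1e-5).
#' @return list(genotypes, report): filtered matrix and per-filter counts
#'   plus the per-SNP statistics.
#' @export
qc_snps <- function(g, call_rate_min = 0.95, maf_min = 0.05,
                    hwe_p_min = 1e-5) {
  validate_genotype_matrix(g)
  called <- !is.na(g$dosage)
  call_rate <- colMeans(called)
  p_alt <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- vapply(seq_along(g$snp_ids), function(j) {
    d <- g$dosage[, j]
    hwe_exact_test(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                   sum(d == 2L, na.rm = TRUE))
  }, numeric(1))
  fail_call <- call_rate < call_rate_min
  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_call | fail_maf | fail_hwe)
  stats <- data.frame(snp_id = g$snp_ids, call_rate = call_rate, maf = maf,
                      hwe_p = hwe_p, kept = keep, stringsAsFactors = FALSE)
  out <- new_genotype_matrix(g$dosage[, keep, drop = FALSE],
                             g$annotations[keep, , drop = FALSE])
  list(genotypes = out,
       report = list(n_fail_call_rate = sum(fail_call),
                     n_fail_maf = sum(fail_maf), n_fail_hwe = sum(fail_hwe),
                     n_removed = sum(!keep), snp_stats = stats))
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability under Hardy-Weinberg equilibrium does not exceed that of the
#' observed count. Monomorphic tables return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1).
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  log_prob <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) + lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + lfactorial(n_rare) +
      lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- prob[hets == n_Aa]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# Genotype principal components from the centered, MAF-scaled dosage matrix
# (missing dosages mean-imputed before scaling).
genotype_pcs <- function(dosage, n_pcs = 8L) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  X <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- mu[j]
    X[, j] <- (x - mu[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1L)
  sv <- svd(X, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  pcs
}

#' Additive logistic association scan
#'
#' Per SNP, fits `outcome ~ intercept + dosage + covariates` by iteratively
#' reweighted least squares (relative tolerance 1e-8, at most 50 iterations)
#' on the subjects with a non-missing genotype at that SNP, and reports the
#' Wald two-sided p of the allele-dosage coefficient. Genotype principal
#' components (computed internally from the centered, MAF-scaled dosage
#' matrix) can be added as covariates to absorb population structure.
#' Constant-dosage SNPs and non-converged / separated fits are flagged with
#' missing estimates, never silently dropped.
#'
#' @param g a `genotype_matrix` (after QC).
#' @param outcome logical or 0/1 vector over subjects (both classes present).
#' @param covariates optional numeric data.frame/matrix of per-subject
#'   covariates (complete cases required).
#' @param n_pcs number of genotype principal components to add (default 0;
#'   the reference analysis used 8).
#' @param p_adjust_method multiplicity adjustment for `p_adj`
#'   (default Bonferroni, matching fixed genome-wide thresholds).
#' @return An `association_result` data.frame: feature_id, chrom, pos, gene,
#'   n_used, beta, se, p, p_adj, status.
#' @export
logistic_assoc <- function(g, outcome, covariates = NULL, n_pcs = 0L,
                           p_adjust_method = "bonferroni") {
  validate_genotype_matrix(g)
  y <- as.numeric(outcome)
  stopifnot(length(y) == length(g$subjects))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("outcome must contain both classes", call. = FALSE)
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (anyNA(C)) stop("covariates must be complete", call. = FALSE)
  }
  if (n_pcs > 0L) C <- cbind(C, genotype_pcs(g$dosage, n_pcs))
  ctrl <- glm.control(epsilon = 1e-8, maxit = 50L)
  res <- lapply(seq_along(g$snp_ids), function(j) {
    d <- g$dosage[, j]
    ok <- !is.na(d) & !is.na(y)
    n_used <- sum(ok)
    row <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = n_used, status = "ok")
    if (var(d[ok]) == 0) {
      row$status <- "non_estimable"
      return(row)
    }
    X <- cbind(`(Intercept)` = 1, dosage = d[ok],
               if (!is.null(C)) C[ok, , drop = FALSE])
    fit <- suppressWarnings(glm.fit(X, y[ok], family = binomial(),
                                    control = ctrl))
    rk <- fit$rank
    if (rk < ncol(X)) {
      row$status <- "non_estimable"
      return(row)
    }
    covmat <- try(chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk), drop = FALSE]),
                  silent = TRUE)
    se <- if (inherits(covmat, "try-error")) NA_real_ else sqrt(covmat[2, 2])
    beta <- fit$coefficients[["dosage"]]
    if (!fit$converged || !is.finite(se) || se > 1e3 || is.na(beta)) {
      row$status <- "not_converged"
      return(row)
    }
    row$beta <- beta
    row$se <- se
    row$p <- 2 * pnorm(-abs(beta / se))
    row
  })
  out <- data.frame(
    feature_id = g$snp_ids,
    chrom = g$annotations$chrom, pos = g$annotations$pos,
    gene = g$annotations$gene,
    n_used = vapply(res, `[[`, integer(1), "n_used"),
    beta = vapply(res, `[[`, numeric(1), "beta"),
    se = vapply(res, `[[`, numeric(1), "se"),
    p = vapply(res, `[[`, numeric(1), "p"),
    status = vapply(res, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = p_adjust_method, n = nrow(out))
  class(out) <- c("association_result", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' lambda = median of the chi-square(1) quantiles of the observed p-values
#' divided by the null median 0.4549364; lambda near 1 indicates calibrated
#' tests.
#'
#' @param results an `association_result` (or numeric p-value vector).
#' @param min_tests minimum number of valid p-values required (default 100).
#' @return scalar lambda.
#' @export
genomic_inflation <- function(results, min_tests = 100L) {
  p <- if (is.data.frame(results)) results$p else results
  p <- p[!is.na(p)]
  if (length(p) < min_tests)
    stop(sprintf("need >= %d valid p-values to estimate inflation", min_tests),
         call. = FALSE)
  chisq <- qchisq(1 - p, df = 1)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Tiered significance report (Manhattan table)
#'
#' Flags associations at the genome-wide (default 5e-8) and relaxed (default
#' 5e-6) tiers, joins gene annotations, and emits a table ready for
#' Manhattan-style plotting.
#'
#' @param results an `association_result`.
#' @param genomewide,relaxed tier thresholds.
#' @return the results with `neg_log10_p` and `tier` columns, ordered by
#'   chrom/pos, with fixed column order snp_id, chrom, pos, gene, n_used,
#'   beta, se, p, tier, neg_log10_p.
#' @export
significance_report <- function(results, genomewide = 5e-8, relaxed = 5e-6) {
  stopifnot(nrow(results) > 0)
  tier <- rep("", nrow(results))
  tier[!is.na(results$p) & results$p < relaxed] <- "relaxed"
  tier[!is.na(results$p) & results$p < genomewide] <- "genome-wide"
  out <- data.frame(snp_id = results$feature_id, chrom = results$chrom,
                    pos = results$pos, gene = results$gene,
                    n_used = results$n_used, beta = results$beta,
                    se = results$se, p = results$p, tier = tier,
                    neg_log10_p = -log10(results$p),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
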
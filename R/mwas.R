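#' Remove the water region from a spectrum set
#'
#' Deletes every point with `lower <= ppm <= upper` (default 4-5 ppm, the
#' residual-water band of plasma 1H spectra) from the axis and the intensity
#' matrix; subject order is unchanged. Idempotent.
#'
#' @param s a `spectrum_set`.
#' @param lower,upper band edges in ppm.
#' @return the trimmed `spectrum_set`.
#' @export
remove_water_region <- function(s, lower = 4, upper = 5) {
  keep <- s$ppm < lower | s$ppm > upper
  if (!any(keep))
    stop("no points remain after water-region removal", call. = FALSE)
  out <- new_spectrum_set(s$ppm[keep], s$intensity[, keep, drop = FALSE],
                          s$meta)
  attr(out, "baseline") <- attr(s, "baseline")[keep]
  out
}

# Adaptive iteratively reweighted penalized least squares for one spectrum.
# Returns the estimated baseline z minimizing
#   sum_i w_i (y_i - z_i)^2 + lambda * sum (second difference of z)^2
# with weights re-estimated each iteration to down-weight points above the
# current baseline (peaks), and the first/last points anchored.
airpls_one <- function(y, DtD, lambda, max_iter, tol) {
  m <- length(y)
  w <- rep(1, m)
  abs_y <- sum(abs(y))
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(x = w)
    z <- as.numeric(Matrix::solve(W + lambda * DtD, w * y))
    d <- y - z
    neg <- d < 0
    dssn <- abs(sum(d[neg]))
    if (dssn < tol * abs_y) break
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / dssn)
    w[1] <- exp(it * max(d[neg]) / dssn)
    w[m] <- w[1]
  }
  z
}

#' Baseline correction by adaptive iteratively reweighted penalized least squares
#'
#' Per spectrum, estimates a smooth baseline z minimizing
#' `sum w_i (y_i - z_i)^2 + lambda * sum (Delta^2 z)^2`, re-estimating the
#' weights each iteration so that points above the baseline (resonance peaks)
#' are progressively excluded while points below pull the baseline down.
#' Iteration stops when the weighted negative residual falls below `tol`
#' (0.1%) of the total absolute intensity or after `max_iter` iterations.
#'
#' @param s a `spectrum_set` (>= 10 points per spectrum).
#' @param lambda smoothness penalty (> 0); larger values give stiffer
#'   baselines. Default 1e5.
#' @param max_iter maximum reweighting iterations (default 15).
#' @param tol relative stopping tolerance (default 1e-3).
#' @return list(corrected, baselines): the baseline-subtracted
#'   `spectrum_set` and the subjects x points baseline matrix.
#' @export
airpls_baseline <- function(s, lambda = 1e5, max_iter = 15L, tol = 1e-3) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  m <- length(s$ppm)
  if (m < 10L) stop("need >= 10 points per spectrum", call. = FALSE)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2, diagonals = list(rep(1, m - 2L),
                                                    rep(-2, m - 2L),
                                                    rep(1, m - 2L)))
  DtD <- Matrix::crossprod(D)
  baselines <- t(apply(s$intensity, 1, airpls_one, DtD = DtD, lambda = lambda,
                       max_iter = max_iter, tol = tol))
  corrected <- new_spectrum_set(s$ppm, s$intensity - baselines, s$meta)
  list(corrected = corrected, baselines = baselines)
}

#' Rigid cross-correlation alignment of spectra
#'
#' Shifts each spectrum by an integer number of grid points (at most
#' `max_shift_ppm`) to maximize its cross-correlation with the reference
#' spectrum (the pointwise median spectrum by default); ties prefer the
#' smallest shift magnitude. Edges are padded with the spectrum's edge
#' value. A rigid registration standing in for peak-alignment of
#' baseline-corrected spectra.
#'
#' @param s a baseline-corrected `spectrum_set`.
#' @param reference "median" or the index of a reference subject.
#' @param max_shift_ppm maximum allowed shift in ppm (default 0.02).
#' @return the aligned `spectrum_set` with the per-subject shifts (grid
#'   points, positive = moved right) in the `"shifts"` attribute.
#' @export
align_spectra <- function(s, reference = "median", max_shift_ppm = 0.02) {
  step <- abs(stats::median(diff(s$ppm)))
  L <- max(0L, floor(max_shift_ppm / step))
  ref <- if (identical(reference, "median"))
    apply(s$intensity, 2, median) else s$intensity[reference, ]
  m <- length(ref)
  shifts <- integer(nrow(s$intensity))
  out <- s$intensity
  if (L > 0L) {
    cand <- seq.int(-L, L)
    cand <- cand[order(abs(cand), cand)]  # prefer small |shift| on ties
    for (i in seq_len(nrow(out))) {
      y <- s$intensity[i, ]
      scores <- vapply(cand, function(sh) {
        if (sh >= 0) sum(y[seq_len(m - sh)] * ref[seq_len(m - sh) + sh])
        else sum(y[seq_len(m + sh) - sh] * ref[seq_len(m + sh)])
      }, numeric(1))
      best <- cand[which.max(scores)]
      shifts[i] <- best
      if (best != 0L) out[i, ] <- shift_vector(y, best)
    }
  }
  res <- new_spectrum_set(s$ppm, out, s$meta)
  attr(res, "shifts") <- shifts
  res
}

# shift a vector right (k > 0) or left (k < 0), padding with the edge value
shift_vector <- function(y, k) {
  m <- length(y)
  if (k == 0) return(y)
  if (k > 0) c(rep(y[1], k), y[seq_len(m - k)])
  else c(y[seq_len(m + k) - k], rep(y[m], -k))
}

fit_point_logistic <- function(X, y, ctrl) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial(), control = ctrl))
  rk <- fit$rank
  if (rk < ncol(X)) return(NULL)
  covmat <- try(chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk), drop = FALSE]),
                silent = TRUE)
  if (inherits(covmat, "try-error")) return(NULL)
  se <- sqrt(covmat[2, 2])
  beta <- fit$coefficients[[2]]
  if (!fit$converged || !is.finite(se) || se > 1e3) return(NULL)
  c(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
}

new_mwas_result <- function(df, fdr_threshold, adjustment) {
  structure(df, fdr_threshold = fdr_threshold, adjustment = adjustment,
            class = c("mwas_result", "data.frame"))
}

#' Metabolome-wide logistic association with cluster membership
#'
#' Per ppm point, fits a logistic regression of case status (membership in
#' the low-prevalence cluster) on the spectral intensity with age and sex
#' (two-level factor) as confounders, then applies the Benjamini-Yekutieli
#' adjustment over all tested points (the total point count m stays fixed
#' even when some fits fail; failed points carry missing p). Points with
#' adjusted p below `fdr_threshold` form the significance mask.
#'
#' @param s a preprocessed `spectrum_set` whose `meta` has `cluster_label`,
#'   `age` and `sex`.
#' @param case_cluster the cluster label treated as the case class.
#' @param fdr_threshold Benjamini-Yekutieli FDR threshold (default 1e-3).
#' @param min_class_size minimum subjects per class (default 20).
#' @return An `mwas_result` data.frame: ppm, beta, se, p, p_adj, sign, mask,
#'   status; suitable for FDR plots via (ppm, -log10 p_adj, sign).
#' @export
mwas_logistic <- function(s, case_cluster, fdr_threshold = 1e-3,
                          min_class_size = 20L) {
  meta <- s$meta
  if (is.null(meta$cluster_label))
    stop("spectrum metadata lacks cluster_label", call. = FALSE)
  y <- as.numeric(meta$cluster_label == case_cluster)
  if (min(sum(y), sum(1 - y)) < min_class_size)
    stop(sprintf("both classes need >= %d subjects", min_class_size),
         call. = FALSE)
  sex2 <- as.numeric(factor(meta$sex)) - 1
  ctrl <- glm.control(epsilon = 1e-8, maxit = 50L)
  m <- length(s$ppm)
  est <- matrix(NA_real_, m, 3, dimnames = list(NULL, c("beta", "se", "p")))
  status <- rep("ok", m)
  for (j in seq_len(m)) {
    X <- cbind(1, s$intensity[, j], meta$age, sex2)
    r <- fit_point_logistic(X, y, ctrl)
    if (is.null(r)) status[j] <- "not_converged" else est[j, ] <- r
  }
  p_adj <- p.adjust(est[, "p"], method = "BY", n = m)
  df <- data.frame(ppm = s$ppm, beta = est[, "beta"], se = est[, "se"],
                   p = est[, "p"], p_adj = p_adj,
                   sign = sign(est[, "beta"]),
                   mask = !is.na(p_adj) & p_adj < fdr_threshold,
                   status = status, stringsAsFactors = FALSE)
  new_mwas_result(df, fdr_threshold, "BY")
}

#' Metabolome-wide linear association with allele dosage
#'
#' Per ppm point, fits a linear regression of the spectral intensity on the
#' minor-allele count (0/1/2) with age and sex as confounders, and reports
#' the raw two-sided p of the allele term. No multiplicity adjustment is
#' applied (`p_adj = p`), matching an exploratory allele-dosage scan read
#' alongside the FDR-controlled cluster scan.
#'
#' @param s a preprocessed `spectrum_set` whose `meta` has the allele-count
#'   column, `age` and `sex`.
#' @param allele_col name of the allele-count metadata column (default
#'   `"rs651821_C_count"`).
#' @return An `mwas_result` data.frame (mask uses the raw p at the 1e-3
#'   level purely for plotting symmetry).
#' @export
mwas_linear_allele <- function(s, allele_col = "rs651821_C_count") {
  meta <- s$meta
  if (is.null(meta[[allele_col]]))
    stop(sprintf("spectrum metadata lacks '%s'", allele_col), call. = FALSE)
  g <- as.numeric(meta[[allele_col]])
  sex2 <- as.numeric(factor(meta$sex)) - 1
  m <- length(s$ppm)
  est <- matrix(NA_real_, m, 3, dimnames = list(NULL, c("beta", "se", "p")))
  status <- rep("ok", m)
  X <- cbind(1, g, meta$age, sex2)
  XtXi <- try(solve(crossprod(X)), silent = TRUE)
  if (inherits(XtXi, "try-error"))
    stop("allele/age/sex design matrix is singular", call. = FALSE)
  dfres <- nrow(X) - ncol(X)
  for (j in seq_len(m)) {
    fit <- lm.fit(X, s$intensity[, j])
    sigma2 <- sum(fit$residuals^2) / dfres
    se <- sqrt(sigma2 * XtXi[2, 2])
    beta <- fit$coefficients[[2]]
    if (!is.finite(se) || se == 0) {
      if (beta == 0 || !is.finite(beta)) {
        status[j] <- "not_converged"
        next
      }
      # exact linear relation: p underflows; keep it strictly positive
      est[j, ] <- c(beta, 0, .Machine$double.xmin)
      next
    }
    est[j, ] <- c(beta, se, 2 * pt(-abs(beta / se), dfres))
  }
  df <- data.frame(ppm = s$ppm, beta = est[, "beta"], se = est[, "se"],
                   p = est[, "p"], p_adj = est[, "p"],
                   sign = sign(est[, "beta"]),
                   mask = !is.na(est[, "p"]) & est[, "p"] < 1e-3,
                   status = status, stringsAsFactors = FALSE)
  new_mwas_result(df, NA_real_, "none")
}

#' Annotate ppm positions with candidate metabolite assignments
#'
#' Joins a static ppm -> metabolite lookup (shipped with the package; plasma
#' 1H resonances commonly reported in the literature) to significant points,
#' for labeling output tables only.
#'
#' @param ppm numeric vector of chemical shifts to annotate.
#' @param tol_ppm match tolerance (default 0.03 ppm).
#' @return character vector of metabolite names ("" when unmatched).
#' @export
annotate_ppm <- function(ppm, tol_ppm = 0.03) {
  path <- system.file("extdata", "nmr_peak_annotations.tsv",
                      package = "phenoclust")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  vapply(ppm, function(x) {
    d <- abs(tab$ppm - x)
    if (min(d) <= tol_ppm) tab$metabolite[which.min(d)] else ""
  }, character(1))
}
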
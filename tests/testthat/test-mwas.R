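test_that("water-region excision removes exactly the in-band points", {
  ppm <- seq(0.5, 9.5, by = 0.01)
  withr::with_seed(72, s <- toy_spectra(matrix(rnorm(5 * length(ppm)), 5), ppm))
  out <- remove_water_region(s)
  in_band <- sum(ppm >= 4 & ppm <= 5)
  expect_equal(length(out$ppm), length(ppm) - in_band)
  expect_false(any(out$ppm >= 4 & out$ppm <= 5))
  expect_identical(rownames(out$intensity), rownames(s$intensity))
  # idempotence
  twice <- remove_water_region(out)
  expect_identical(twice$ppm, out$ppm)
  expect_identical(twice$intensity, out$intensity)
  # axis entirely inside the band
  ppm_w <- seq(4.1, 4.9, by = 0.01)
  sw <- toy_spectra(matrix(1, 2, length(ppm_w)), ppm_w)
  expect_error(remove_water_region(sw), "no points remain")
})

test_that("baseline estimation reproduces flat and known synthetic baselines", {
  ppm <- seq(0.5, 4.5, by = 0.004)
  m <- length(ppm)
  flat <- toy_spectra(matrix(7, 3, m), ppm)
  res <- airpls_baseline(flat, lambda = 1e5)
  expect_lt(max(abs(res$baselines - 7)), 1e-6)
  expect_lt(max(abs(res$corrected$intensity)), 1e-6)
  expect_error(airpls_baseline(flat, lambda = 0), "positive")

  # known quadratic baseline + isolated peaks: recover within 2% RMS in
  # signal-free regions
  true_base <- 5 + 2 * (ppm - 2.5)^2
  peaks <- 30 * exp(-(ppm - 1.2)^2 / (2 * 0.02^2)) +
    20 * exp(-(ppm - 3.3)^2 / (2 * 0.03^2))
  withr::with_seed(73, {
    Y <- matrix(rep(true_base + peaks, 4), 4, m, byrow = TRUE) +
      matrix(rnorm(4 * m, 0, 0.02), 4, m)
  })
  res2 <- airpls_baseline(toy_spectra(Y, ppm), lambda = 1e6)
  free <- abs(ppm - 1.2) > 0.15 & abs(ppm - 3.3) > 0.2
  rms_err <- sqrt(mean((res2$baselines[, free] -
                          matrix(true_base[free], 4, sum(free),
                                 byrow = TRUE))^2))
  expect_lt(rms_err / sqrt(mean(true_base[free]^2)), 0.02)
})

test_that("a very stiff penalty drives the baseline to the straight-line fit", {
  ppm <- seq(0.5, 4.5, by = 0.004)
  m <- length(ppm)
  sloped <- 2 + 3 * ppm
  peak <- 40 * exp(-(ppm - 2.0)^2 / (2 * 0.02^2))
  s <- toy_spectra(matrix(sloped + peak, 1, m, byrow = TRUE), ppm)
  res <- airpls_baseline(s, lambda = 1e12)
  # compare against the least-squares line on the points away from the peak
  mask <- abs(ppm - 2.0) > 0.15
  line <- lm(y ~ x, data = data.frame(x = ppm[mask], y = sloped[mask]))
  pred <- predict(line, newdata = data.frame(x = ppm[mask]))
  expect_lt(sqrt(mean((res$baselines[1, mask] - pred)^2)), 0.05 * mean(pred))
})

test_that("cross-correlation alignment recovers known rigid shifts", {
  ppm <- seq(0.5, 4.5, by = 0.002)
  m <- length(ppm)
  base <- 10 * exp(-(ppm - 2.0)^2 / (2 * 0.03^2)) +
    6 * exp(-(ppm - 1.3)^2 / (2 * 0.02^2))
  Y <- rbind(base, base, base)
  s0 <- toy_spectra(Y, ppm)
  aligned <- align_spectra(s0)
  expect_identical(attr(aligned, "shifts"), c(0L, 0L, 0L))
  expect_equal(aligned$intensity, s0$intensity)

  # shift one spectrum right by 3 points; alignment shifts it back by -3
  Y2 <- Y
  Y2[2, ] <- phenoclust:::shift_vector(base, 3L)
  al2 <- align_spectra(toy_spectra(Y2, ppm), reference = 1)
  expect_equal(attr(al2, "shifts")[2], -3L)
  mid <- 100:(m - 100)
  expect_lt(max(abs(al2$intensity[2, mid] - base[mid])), 1e-10)

  # pure noise: shifts bounded, no failure
  withr::with_seed(74, noise <- matrix(rnorm(4 * m), 4, m))
  al3 <- align_spectra(toy_spectra(noise, ppm), max_shift_ppm = 0.02)
  expect_true(all(abs(attr(al3, "shifts")) <= floor(0.02 / 0.002)))
})

test_that("preprocessing commutes with subject reordering", {
  s <- mwas_cohort(n = 30, n_case = 15, seed = 75)
  perm <- rev(seq_len(30))
  s_perm <- phenoclust:::new_spectrum_set(s$ppm, s$intensity[perm, ],
                                          s$meta[perm, ])
  a <- airpls_baseline(remove_water_region(s), lambda = 1e5)
  b <- airpls_baseline(remove_water_region(s_perm), lambda = 1e5)
  expect_equal(unname(b$corrected$intensity),
               unname(a$corrected$intensity[perm, ]), tolerance = 1e-10)
})

test_that("Benjamini-Yekutieli adjustment matches the hand formula", {
  # m = 3, p = (.01, .02, .03): c(3) = 11/6, all adjusted to 0.055
  p3 <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(p3, method = "BY"), rep(0.055, 3), tolerance = 1e-12)
  expect_equal(by_bruteforce(p3), rep(0.055, 3), tolerance = 1e-12)
  withr::with_seed(76, {
    for (m in 2:5) {
      p <- runif(m)
      expect_equal(p.adjust(p, method = "BY"), by_bruteforce(p),
                   tolerance = 1e-12)
      # permutation invariance and monotonicity
      perm <- sample(m)
      expect_equal(p.adjust(p[perm], method = "BY"), by_bruteforce(p)[perm])
      adj <- p.adjust(p, method = "BY")
      expect_true(all(adj >= p))
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
})

test_that("cluster-membership MWAS detects the planted GlycA depression", {
  s <- mwas_cohort(n = 217, n_case = 144, seed = 77)
  s <- remove_water_region(s)
  res <- mwas_logistic(s, case_cluster = 1)
  expect_s3_class(res, "mwas_result")
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  hits <- res$ppm[res$mask]
  expect_gt(length(hits), 0)
  glyca_hits <- hits[abs(hits - 2.04) <= 0.05]
  expect_gt(length(glyca_hits), 0)
  # intensity lower in the case class at GlycA: negative association sign
  expect_true(all(res$sign[res$mask & abs(res$ppm - 2.04) <= 0.02] == -1))
})

test_that("MWAS class-size and metadata contracts are enforced", {
  s <- mwas_cohort(n = 30, n_case = 25, seed = 78)
  expect_error(mwas_logistic(s, case_cluster = 1), ">= 20")
  s2 <- mwas_cohort(n = 25, n_case = 12, seed = 79)
  s2$meta$cluster_label <- NULL
  expect_error(mwas_logistic(s2, case_cluster = 1), "cluster_label")
  expect_error(mwas_linear_allele(s2), "rs651821_C_count")
})

test_that("null spectra produce no false discoveries at the stated FDR", {
  masked <- integer(8)
  for (r in seq_len(8)) {
    s <- mwas_cohort(n = 120, n_case = 60, seed = 800 + r,
                     null_spectra = TRUE)
    res <- mwas_logistic(remove_water_region(s), case_cluster = 1)
    masked[r] <- sum(res$mask, na.rm = TRUE)
  }
  expect_gte(mean(masked == 0), 0.95)
})

test_that("allele-dosage MWAS recovers an exact linear relation", {
  ppm <- seq(0.5, 4.5, by = 0.01)
  m <- length(ppm)
  withr::with_seed(80, {
    g <- sample(0:2, 60, replace = TRUE)
    age <- runif(60, 30, 70)
  })
  Y <- matrix(rep(2 * g, m), 60, m)
  meta <- data.frame(subject_id = sprintf("A%03d", 1:60), age = age,
                     sex = rep(c(1L, 2L), 30), rs651821_C_count = g)
  s <- toy_spectra(Y, ppm, meta)
  res <- mwas_linear_allele(s)
  expect_equal(res$beta, rep(2, m), tolerance = 1e-10)
  expect_true(all(res$p < 1e-100))
  expect_identical(res$p_adj, res$p)  # no multiplicity adjustment
})

test_that("permuted allele labels give uniform allele-MWAS p-values", {
  # independent-point fixture (pure noise spectra), since neighbouring points
  # of peaked spectra share amplitude draws and are not independent tests
  ppm <- seq(0.5, 4.5, by = 0.005)
  withr::with_seed(82, {
    Y <- matrix(rnorm(150 * length(ppm)), 150)
    g <- sample(0:2, 150, replace = TRUE, prob = c(0.49, 0.42, 0.09))
    meta <- data.frame(subject_id = sprintf("P%03d", 1:150),
                       age = runif(150, 30, 70),
                       sex = rep(c(1L, 2L), 75), rs651821_C_count = g)
  })
  res <- mwas_linear_allele(toy_spectra(Y, ppm, meta))
  ks <- ks.test(res$p[res$status == "ok"], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster and allele FDR profiles correlate when effects share loci", {
  # allele count coupled to cluster membership so both scans see the same loci
  s <- mwas_cohort(n = 217, n_case = 144, seed = 83)
  withr::with_seed(84, {
    p_case <- 0.15
    p_ctrl <- 0.35
    pr <- ifelse(s$meta$cluster_label == 1, p_case, p_ctrl)
    s$meta$rs651821_C_count <- rbinom(nrow(s$meta), 2, pr)
  })
  s <- remove_water_region(s)
  res_cl <- mwas_logistic(s, case_cluster = 1)
  res_al <- mwas_linear_allele(s)
  ok <- res_cl$status == "ok" & res_al$status == "ok"
  rho <- cor(-log10(res_cl$p[ok]), -log10(res_al$p[ok]), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("ppm annotation labels the canonical plasma resonances", {
  expect_equal(annotate_ppm(c(2.04, 0.95, 7.5)),
               c("GlycA", "leucine", ""))
})
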
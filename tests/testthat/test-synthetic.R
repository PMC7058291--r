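test_that("generation is fully deterministic given the config seed", {
  cfg <- synthetic_config(n_subjects = 200, seed = 42L)
  a <- generate_phenotypes(cfg)
  b <- generate_phenotypes(cfg)
  expect_identical(a, b)
  ga <- generate_genotypes(a, n_null_snps = 5, seed = 7)
  gb <- generate_genotypes(b, n_null_snps = 5, seed = 7)
  expect_identical(ga$dosage, gb$dosage)
  sa <- generate_spectra(a, cfg)
  sb <- generate_spectra(b, cfg)
  expect_identical(sa$intensity, sb$intensity)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(cluster_weights = c(0.5, 0.5, 0.1, 0.1)),
               "sum to 1")
  bad_panel <- default_snp_panel()
  bad_panel$maf[[1]] <- c(0, 0.2, 0.3, 0.4)
  expect_error(synthetic_config(snp_panel = bad_panel), "\\(0, 0.5\\]")
  R <- default_trait_panel()$cor
  R[1, 2] <- R[2, 1] <- 2
  expect_error(synthetic_config(trait_cor = R), "positive semi-definite")
})

test_that("zero-variance single-cluster config reproduces the means exactly", {
  panel <- default_trait_panel()
  cfg <- synthetic_config(n_subjects = 25, n_clusters = 1, cluster_weights = 1,
                          trait_means = panel$means[1, , drop = FALSE],
                          trait_sds = 0 * panel$sds[1, , drop = FALSE],
                          missing_rate = 0)
  co <- generate_phenotypes(cfg)
  for (tr in colnames(panel$means))
    expect_equal(unname(co[[tr]]), rep(unname(panel$means[1, tr]), 25),
                 tolerance = 1e-12)
})

test_that("empirical cluster trait means converge to configured values", {
  cfg <- synthetic_config(n_subjects = 100000,
                          cluster_weights = rep(0.25, 4), missing_rate = 0)
  co <- generate_phenotypes(cfg)
  for (k in 1:4) {
    idx <- co$cluster_truth == k
    n_k <- sum(idx)
    for (tr in c("TG", "BMI", "HDL_C")) {
      se <- cfg$trait_sds[k, tr] / sqrt(n_k)
      expect_lt(abs(mean(co[[tr]][idx]) - cfg$trait_means[k, tr]), 3 * se)
    }
  }
})

test_that("a cohort at published triglyceride scale realizes the printed cluster means", {
  panel <- default_trait_panel()
  cfg <- synthetic_config(n_subjects = 150000, trait_means = panel$means,
                          trait_sds = panel$sds,
                          cluster_weights = rep(0.25, 4), missing_rate = 0)
  co <- generate_phenotypes(cfg)
  tg2 <- mean(co$TG[co$cluster_truth == 2])
  tg4 <- mean(co$TG[co$cluster_truth == 4])
  expect_lt(abs(tg2 - 64.6), 1)
  expect_lt(abs(tg4 - 152), 1)
})

test_that("disease status follows the logistic model", {
  cfg <- synthetic_config(n_subjects = 20000, missing_rate = 0)
  co <- generate_phenotypes(cfg)
  null_mod <- list(flat = list(intercept = 0, coef = c(TG = 0)))
  flat <- generate_disease_status(co, null_mod, seed = 5)
  prev <- mean(flat$flat)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / nrow(co)))  # binomial CI
  sat <- generate_disease_status(co, list(none = list(intercept = -50,
                                                      coef = c(TG = 0))),
                                 seed = 5)
  expect_equal(sum(sat$none), 0)
  expect_error(generate_disease_status(co, list(x = list(intercept = 0,
                                                         coef = c(NOPE = 1)))),
               "unknown trait")
})

test_that("default models order prevalence healthy stratum < high-risk stratum", {
  cfg <- synthetic_config(n_subjects = 50000)
  co <- generate_disease_status(generate_phenotypes(cfg), seed = 11)
  for (dz in c("dyslipidemia", "hypertension", "diabetes")) {
    prev <- tapply(co[[dz]], co$cluster_truth, mean)
    expect_lt(prev[["2"]], prev[["4"]])
    expect_true(prev[["2"]] == min(prev))
  }
  expect_false(anyNA(as.data.frame(co)[c("dyslipidemia", "hypertension",
                                         "diabetes")]))
})

test_that("genotype dosages match configured minor allele frequencies", {
  cfg <- synthetic_config(n_subjects = 10000, missing_rate = 0)
  co <- generate_phenotypes(cfg)
  panel <- data.frame(snp_id = "flat", chrom = "1", pos = 1L, gene = "",
                      maf = I(list(rep(0.5, 4))), stringsAsFactors = FALSE)
  g <- generate_genotypes(co, panel, seed = 3)
  se <- sqrt(2 * 0.5 * 0.5 / nrow(co))
  expect_lt(abs(mean(g$dosage[, 1]) - 1.0), 3 * se)
})

test_that("per-cluster MAFs of the planted variant are realized", {
  cfg <- synthetic_config(n_subjects = 20000, cluster_weights = rep(0.25, 4),
                          missing_rate = 0)
  co <- generate_phenotypes(cfg)
  g <- generate_genotypes(co, default_snp_panel(), seed = 9)
  target <- default_snp_panel()$maf[[1]]
  for (k in 1:4) {
    realized <- mean(g$dosage[co$cluster_truth == k, 1]) / 2
    expect_lt(abs(realized - target[k]), 0.01)
  }
})

test_that("monomorphic SNPs are rejected before output", {
  cfg <- synthetic_config(n_subjects = 100, missing_rate = 0)
  co <- generate_phenotypes(cfg)
  panel <- data.frame(snp_id = "mono", chrom = "1", pos = 1L, gene = "",
                      maf = I(list(rep(0, 4))), stringsAsFactors = FALSE)
  expect_error(generate_genotypes(co, panel), "monomorphic")
  g <- generate_genotypes(co, n_null_snps = 50, seed = 2,
                          null_maf_range = c(0.05, 0.5))
  mono <- apply(g$dosage, 2, function(x) length(unique(x[!is.na(x)])) < 2)
  expect_false(any(mono))
})

test_that("noise-free single-peak spectra equal the analytic line shape", {
  cfg <- synthetic_config(
    n_subjects = 3, n_clusters = 1, cluster_weights = 1,
    trait_means = default_trait_panel()$means[1, , drop = FALSE],
    trait_sds = 0 * default_trait_panel()$sds[1, , drop = FALSE],
    spectrum_peaks = data.frame(name = "p", center = 2.0, width = 0.05,
                                amp1 = 1.0),
    baseline_amplitude = 0, noise_sd = 0, amplitude_cv = 0, missing_rate = 0)
  co <- generate_phenotypes(cfg)
  s <- generate_spectra(co, cfg)
  analytic <- exp(-(s$ppm - 2.0)^2 / (2 * 0.05^2))
  for (i in 1:3) expect_equal(unname(s$intensity[i, ]), analytic,
                              tolerance = 1e-12)
  # lorentzian option
  cfgL <- synthetic_config(
    n_subjects = 1, n_clusters = 1, cluster_weights = 1,
    trait_means = default_trait_panel()$means[1, , drop = FALSE],
    trait_sds = 0 * default_trait_panel()$sds[1, , drop = FALSE],
    spectrum_peaks = data.frame(name = "p", center = 2.0, width = 0.05,
                                amp1 = 1.0),
    peak_shape = "lorentzian",
    baseline_amplitude = 0, noise_sd = 0, amplitude_cv = 0, missing_rate = 0)
  sL <- generate_spectra(generate_phenotypes(cfgL), cfgL)
  expect_equal(unname(sL$intensity[1, ]),
               0.05^2 / ((sL$ppm - 2.0)^2 + 0.05^2), tolerance = 1e-12)
})

test_that("cluster-2 GlycA depression is detectable in generated spectra", {
  cfg <- synthetic_config(n_subjects = 200, cluster_weights = rep(0.25, 4))
  co <- generate_phenotypes(cfg)
  s <- generate_spectra(co, cfg)
  j <- which.min(abs(s$ppm - 2.04))
  glyca <- s$intensity[, j]
  tt <- t.test(glyca[co$cluster_truth == 2], glyca[co$cluster_truth != 2])
  expect_lt(tt$p.value, 0.01)
  expect_lt(tt$estimate[1], tt$estimate[2])
})

test_that("generated spectra are finite with a non-negative baseline", {
  cfg <- synthetic_config(n_subjects = 20, noise_sd = 0)
  co <- generate_phenotypes(cfg)
  s <- generate_spectra(co, cfg)
  expect_false(anyNA(s$intensity))
  expect_true(all(is.finite(s$intensity)))
  # signal-free region: far from every configured peak
  free <- s$ppm > 2.6 & s$ppm < 2.9
  expect_true(all(s$intensity[, free] >= 0))
  expect_true(all(attr(s, "baseline") >= 0))
})

test_that("peak centers outside the axis are rejected", {
  cfg <- synthetic_config(n_subjects = 5)
  cfg$spectrum_peaks <- data.frame(name = "bad", center = 9.0, width = 0.01,
                                   amp1 = 1, amp2 = 1, amp3 = 1, amp4 = 1)
  co <- generate_phenotypes(synthetic_config(n_subjects = 5))
  expect_error(generate_spectra(co, cfg), "outside the ppm axis")
})
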
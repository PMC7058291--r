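# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A minimal raw cohort table with explicit trait values.
toy_cohort <- function(traits, age = NULL, sex = NULL, diseases = list()) {
  n <- length(traits[[1]])
  df <- data.frame(subject_id = sprintf("T%03d", seq_len(n)),
                   age = age %||% rep(50, n),
                   sex = sex %||% rep(c(1L, 2L), length.out = n),
                   stringsAsFactors = FALSE)
  for (tr in names(traits)) df[[tr]] <- traits[[tr]]
  for (dz in names(diseases)) df[[dz]] <- diseases[[dz]]
  phenoclust:::new_cohort_table(df, names(traits), names(diseases))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Advance a raw toy cohort to a given QC stage without altering values
# (for unit tests that target one stage in isolation).
at_stage <- function(cohort, stage) {
  attr(cohort, "qc_stage") <- stage
  cohort
}

# Well-separated Gaussian blobs in `p` dimensions.
blob_matrix <- function(n_per = 50, k = 4, p = 2, sep = 10, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * p), k, p)
    centers <- sep * centers / sqrt(rowSums(centers^2))
    X <- do.call(rbind, lapply(seq_len(k), function(i)
      matrix(rnorm(n_per * p, sd = sd), n_per, p) +
        matrix(centers[i, ], n_per, p, byrow = TRUE)))
    list(X = X, labels = rep(seq_len(k), each = n_per))
  })
}

# Genotype matrix from an explicit dosage matrix.
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL, gene = NULL) {
  n_snp <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("snp%03d", seq_len(n_snp))
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("G%04d", seq_len(nrow(dosage)))
  ann <- data.frame(snp_id = colnames(dosage),
                    chrom = chrom %||% rep("1", n_snp),
                    pos = pos %||% seq_len(n_snp) * 100L,
                    gene = gene %||% rep("", n_snp),
                    stringsAsFactors = FALSE)
  phenoclust:::new_genotype_matrix(dosage, ann)
}

# Spectrum set from an explicit intensity matrix over a given axis.
toy_spectra <- function(intensity, ppm, meta = NULL) {
  if (is.null(meta))
    meta <- data.frame(subject_id = sprintf("N%03d", seq_len(nrow(intensity))),
                       age = rep(50, nrow(intensity)),
                       sex = rep(c(1L, 2L), length.out = nrow(intensity)),
                       stringsAsFactors = FALSE)
  phenoclust:::new_spectrum_set(ppm, intensity, meta)
}

# Brute-force HWE exact test by enumerating every heterozygote count
# compatible with the observed allele counts (independent oracle).
hwe_bruteforce <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- sapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    # multinomial count of genotype configurations x allele-shuffle weight
    exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)) *
      2^h / exp(lfactorial(2 * n) - lfactorial(n_rare) - lfactorial(2 * n - n_rare))
  })
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Hand evaluation of the Benjamini-Yekutieli adjustment (independent oracle).
by_bruteforce <- function(p, m = length(p)) {
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ranked <- p[ord]
  adj <- m * cm * ranked / seq_along(ranked)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(length(p))
  out[ord] <- pmin(adj, 1)
  out
}

# Brute-force greedy maximum-Jaccard matching (independent oracle).
jaccard_bruteforce <- function(ref, new) {
  rid <- sort(unique(ref)); nid <- sort(unique(new))
  J <- outer(rid, nid, Vectorize(function(a, b) {
    A <- ref == a; B <- new == b
    sum(A & B) / sum(A | B)
  }))
  res <- setNames(rep(0, length(rid)), rid)
  used_r <- used_n <- c()
  repeat {
    Jm <- J
    if (length(used_r)) Jm[used_r, ] <- -1
    if (length(used_n)) Jm[, used_n] <- -1
    if (all(Jm < 0)) break
    ij <- which(Jm == max(Jm), arr.ind = TRUE)[1, ]
    res[ij[1]] <- J[ij[1], ij[2]]
    used_r <- c(used_r, ij[1]); used_n <- c(used_n, ij[2])
    if (length(used_r) == length(rid) || length(used_n) == length(nid)) break
  }
  res
}

mwas_cohort <- function(n = 217, n_case = 144, seed = 71, glyca_case = 8,
                        glyca_ctrl = 10, noise_sd = 0.05,
                        null_spectra = FALSE) {
  # two-group spectrum set: cluster 2 (cases) vs pooled controls; with
  # null_spectra = TRUE the two classes share every peak amplitude
  cfg <- synthetic_config(
    n_subjects = n, n_clusters = 2, cluster_weights = c(n_case, n - n_case) / n,
    trait_means = default_trait_panel()$means[c(2, 4), ],
    trait_sds = default_trait_panel()$sds[c(2, 4), ] * 0.15,
    spectrum_peaks = {
      p <- default_spectrum_peaks()
      p$amp1 <- p$amp2
      p$amp2 <- if (null_spectra) p$amp1 else p$amp4
      if (!null_spectra)
        p[p$name == "GlycA", c("amp1", "amp2")] <- c(glyca_case, glyca_ctrl)
      p[, c("name", "center", "width", "amp1", "amp2")]
    },
    noise_sd = noise_sd, missing_rate = 0, seed = seed)
  co <- generate_phenotypes(cfg)
  generate_spectra(co, cfg, seed = seed + 1)
}
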
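#' Read and write cohort phenotype tables
#'
#' Tab-delimited, header row, "NA" sentinel for missing values. Trait and
#' disease columns are recorded in a `#traits:` / `#diseases:` comment header
#' so a round trip preserves the table's semantics.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#traits: ", paste(cohort_traits(cohort), collapse = "\t")),
               paste0("#diseases: ", paste(cohort_diseases(cohort), collapse = "\t")),
               paste0("#stage: ", cohort_stage(cohort))), con)
  utils::write.table(as.data.frame(cohort), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  hdr <- readLines(path, n = 3L)
  parse_hdr <- function(tag) {
    line <- hdr[startsWith(hdr, tag)]
    if (!length(line)) return(character(0))
    val <- sub(tag, "", line, fixed = TRUE)
    if (!nzchar(trimws(val))) character(0) else strsplit(trimws(val), "\t")[[1]]
  }
  traits <- parse_hdr("#traits: ")
  diseases <- parse_hdr("#diseases: ")
  stage <- parse_hdr("#stage: ") %||% "raw"
  if (!length(stage)) stage <- "raw"
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          na.strings = "NA", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (dz in diseases) df[[dz]] <- as.logical(df[[dz]])
  new_cohort_table(df, traits, diseases, stage = stage)
}

#' Read and write genotype dosage matrices
#'
#' The dosage matrix is tab-delimited with subjects in rows (first column
#' `subject_id`) and SNP IDs in columns; values 0/1/2/NA. The SNP annotation
#' table (snp_id, chrom, pos, gene) is written alongside.
#'
#' @param g a `genotype_matrix`.
#' @param path dosage file path; annotations go to `<path>.annot`.
#' @return `read_genotypes` returns a `genotype_matrix`.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(subject_id = g$subjects, g$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  utils::write.table(g$annotations, paste0(path, ".annot"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  dosage <- as.matrix(df[, -1, drop = FALSE])
  rownames(dosage) <- df$subject_id
  ann <- utils::read.table(paste0(path, ".annot"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer",
                                          "character"), na.strings = NULL)
  validate_genotype_matrix(new_genotype_matrix(dosage, ann))
}

#' Read and write spectrum sets
#'
#' Tab-delimited: first column `ppm`, one column per subject. Subject
#' metadata (age, sex, cluster label, optional allele count) is written to
#' `<path>.meta`.
#'
#' @param s a `spectrum_set`.
#' @param path file path.
#' @return `read_spectra` returns a `spectrum_set`.
#' @export
write_spectra <- function(s, path) {
  df <- data.frame(ppm = s$ppm, t(s$intensity), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s$meta, paste0(path, ".meta"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- utils::read.table(paste0(path, ".meta"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  intensity <- t(as.matrix(df[, -1, drop = FALSE]))
  rownames(intensity) <- meta$subject_id
  new_spectrum_set(df$ppm, intensity, meta)
}

#' Serialize a synthetic configuration to YAML
#'
#' Matrices are stored with explicit dimnames so the round trip is lossless
#' up to numeric printing precision.
#'
#' @param config a [synthetic_config()].
#' @param path YAML file path.
#' @return `read_synthetic_config` returns a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  ser <- list(
    n_subjects = config$n_subjects, n_clusters = config$n_clusters,
    cluster_weights = config$cluster_weights,
    traits = colnames(config$trait_means),
    trait_means = apply(config$trait_means, 1, as.list, simplify = FALSE),
    trait_sds = apply(config$trait_sds, 1, as.list, simplify = FALSE),
    trait_cor = apply(config$trait_cor, 1, as.list, simplify = FALSE),
    disease_models = lapply(config$disease_models, function(m)
      list(intercept = m$intercept, coef = as.list(m$coef))),
    snp_panel = lapply(seq_len(nrow(config$snp_panel)), function(i)
      list(snp_id = config$snp_panel$snp_id[i],
           chrom = as.character(config$snp_panel$chrom[i]),
           pos = config$snp_panel$pos[i],
           gene = config$snp_panel$gene[i],
           maf = config$snp_panel$maf[[i]])),
    null_maf_range = config$null_maf_range,
    spectrum_peaks = lapply(seq_len(nrow(config$spectrum_peaks)), function(i)
      as.list(config$spectrum_peaks[i, ])),
    ppm_range = config$ppm_range, ppm_step = config$ppm_step,
    peak_shape = config$peak_shape, amplitude_cv = config$amplitude_cv,
    baseline_amplitude = config$baseline_amplitude, noise_sd = config$noise_sd,
    missing_rate = config$missing_rate,
    geno_missing_rate = config$geno_missing_rate,
    age_mean = config$age_mean, age_sd = config$age_sd, seed = config$seed)
  # 17 significant digits make the decimal round trip of doubles exact; the
  # generator needs bit-identical covariance input for bit-identical output
  # (the trait correlation matrix has degenerate eigenvalues, so even 1e-15
  # perturbations rotate the sampling eigenbasis)
  yaml::write_yaml(ser, path, precision = 17L)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  traits <- unlist(y$traits)
  as_mat <- function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
    colnames(m) <- traits
    m
  }
  snp_panel <- do.call(rbind, lapply(y$snp_panel, function(s)
    data.frame(snp_id = s$snp_id, chrom = s$chrom, pos = as.integer(s$pos),
               gene = s$gene, maf = I(list(unlist(s$maf))),
               stringsAsFactors = FALSE)))
  peaks <- do.call(rbind, lapply(y$spectrum_peaks, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  synthetic_config(
    n_subjects = y$n_subjects, n_clusters = y$n_clusters,
    cluster_weights = unlist(y$cluster_weights),
    trait_means = as_mat(y$trait_means), trait_sds = as_mat(y$trait_sds),
    trait_cor = as_mat(y$trait_cor),
    disease_models = lapply(y$disease_models, function(m)
      list(intercept = m$intercept, coef = unlist(m$coef))),
    snp_panel = snp_panel, null_maf_range = unlist(y$null_maf_range),
    spectrum_peaks = peaks, ppm_range = unlist(y$ppm_range),
    ppm_step = y$ppm_step, peak_shape = y$peak_shape,
    amplitude_cv = y$amplitude_cv, baseline_amplitude = y$baseline_amplitude,
    noise_sd = y$noise_sd, missing_rate = y$missing_rate,
    geno_missing_rate = y$geno_missing_rate,
    age_mean = y$age_mean, age_sd = y$age_sd, seed = y$seed)
}

#' Convert a genotype matrix to and from minimal VCF
#'
#' Writes a minimal VCFv4.2 with a GT FORMAT field only; REF/ALT are
#' placeholder alleles (A/C) since the dosage representation does not carry
#' them. Dosage d is encoded as 0/0, 0/1 or 1/1 (ALT = minor allele);
#' missing as ./. . Reading goes through the vcfR parser.
#'
#' @param g a `genotype_matrix`.
#' @param path VCF file path (uncompressed).
#' @return `vcf_to_genotypes` returns a `genotype_matrix` (gene annotations
#'   are not representable in minimal VCF and come back empty).
#' @export
genotypes_to_vcf <- function(g, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  ann <- g$annotations
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$subjects), collapse = "\t"))
  body <- vapply(seq_along(g$snp_ids), function(j) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(ann$chrom[j], ann$pos[j], ann$snp_id[j], "A", "C", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname genotypes_to_vcf
#' @export
vcf_to_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcfR is required to read VCF files", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a)
             sum(a == "1"), integer(1)))
  }
  dosage <- matrix(as.integer(count_alt(as.character(gt))), nrow = nrow(gt),
                   dimnames = dimnames(gt))
  fix <- vcfR::getFIX(v)
  ann <- data.frame(snp_id = unname(fix[, "ID"]),
                    chrom = unname(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]), gene = "",
                    stringsAsFactors = FALSE)
  validate_genotype_matrix(new_genotype_matrix(t(dosage), ann))
}
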
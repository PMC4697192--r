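### VCF and TSV input/output for the regional pipeline.

#' Read a regional genotype matrix from a VCF
#'
#' Dosages are taken from the `DS` FORMAT field when present, otherwise from
#' `GT` allele counts (phased or unphased; `./.` is missing). Multi-allelic
#' records are skipped with a warning. Variants are returned sorted by
#' position, with the ALT allele as the effect allele by default.
#'
#' @param path VCF v4.2 file (plain text or bgzipped).
#' @param effect_allele `"alt"` (default) or `"ref"`.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, effect_allele = c("alt", "ref")) {
  effect_allele <- match.arg(effect_allele)
  if (!file.exists(path)) stop("no such file: ", path)
  ## light pre-scan so header/ID problems are reported with line numbers
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1)
    stop("malformed VCF header: expected exactly one #CHROM line (found ",
         length(hdr), ")")
  if (length(strsplit(lines[hdr], "\t")[[1]]) < 9)
    stop("malformed VCF header at line ", hdr, ": fewer than 9 columns")
  body <- lines[(hdr + 1):length(lines)]
  body <- body[nzchar(body)]
  ids <- vapply(strsplit(body, "\t"), `[`, character(1), 3)
  dup <- ids[duplicated(ids) & ids != "."]
  if (length(dup))
    stop("duplicate variant ID(s) '", paste(unique(dup), collapse = "', '"),
         "' at line(s) ",
         paste(hdr + which(ids %in% dup), collapse = ", "))

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  multi <- grepl(",", fx[, "ALT"])
  if (any(multi)) {
    warning("skipping ", sum(multi), " multi-allelic record(s)")
    v <- v[!multi, ]
    fx <- fx[!multi, , drop = FALSE]
  }
  if (nrow(fx) == 0) stop("no usable biallelic records in ", path)
  fmt_keys <- unique(unlist(lapply(strsplit(v@gt[, "FORMAT"], ":"), identity)))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count <- function(g) {
      g[g %in% c("./.", ".|.", ".")] <- NA
      vapply(strsplit(g, "[/|]"),
             function(z) if (length(z) == 0 || anyNA(z) || any(z == "."))
               NA_real_ else sum(z == "1"),
             numeric(1))
    }
    dos <- t(matrix(count(c(gt)), nrow = nrow(gt), dimnames = dimnames(gt)))
  }
  rng <- range(dos, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosage outside [0, 2] in ", path, ": range ", rng[1], " to ", rng[2])
  vt <- data.frame(id = fx[, "ID"], position = as.integer(fx[, "POS"]),
                   ref = fx[, "REF"], alt = fx[, "ALT"],
                   effect_allele = effect_allele,
                   effect_freq = NA_real_, stringsAsFactors = FALSE)
  vt$id[vt$id == "." | is.na(vt$id)] <-
    paste0("chr", fx[vt$id == "." | is.na(vt$id), "CHROM"], "_",
           vt$position[vt$id == "." | is.na(vt$id)])
  ord <- order(vt$position)
  vt <- vt[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  if (effect_allele == "ref") dos <- 2 - dos
  vt$effect_freq <- colMeans(dos, na.rm = TRUE) / 2
  geno_matrix(dos, vt, rownames(dos))
}

#' Write a genotype matrix as VCF v4.2
#'
#' Hard calls (all dosages integral and no `dosage_field` request) are
#' written as `GT`; otherwise dosages are written in a `DS` field rounded to
#' 3 decimals (with a best-guess `GT` alongside).
#'
#' @param genotypes a [geno_matrix()].
#' @param path output path.
#' @param chrom chromosome label, default `"15"`.
#' @param dosage_field force writing `DS` even for integral dosages.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, chrom = "15", dosage_field = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  integral <- all(is.na(d) | abs(d - round(d)) < 1e-9)
  use_ds <- isTRUE(dosage_field) || !integral
  vt <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=regmr ", as.character(utils::packageVersion("regmr"))),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (use_ds)
                 '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Effect allele dosage">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$samples), collapse = "\t")),
             con)
  gt_of <- function(x) {
    out <- rep("./.", length(x))
    r <- round(x)
    out[!is.na(x)] <- c("0/0", "0/1", "1/1")[pmin(pmax(r[!is.na(x)], 0), 2) + 1]
    out
  }
  for (j in seq_len(nrow(vt))) {
    x <- d[, j]
    cells <- if (use_ds) {
      ds <- ifelse(is.na(x), ".", formatC(x, format = "f", digits = 3))
      paste(gt_of(x), ds, sep = ":")
    } else gt_of(x)
    writeLines(paste(c(chrom, vt$position[j], vt$id[j], vt$ref[j], vt$alt[j],
                       ".", "PASS", ".", if (use_ds) "GT:DS" else "GT", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

numeric_pheno_cols <- c("age", "bmi", "log_e2", "log_t", "log_e2t")

#' Read a phenotype/covariate table
#'
#' Tab-separated with a header; `sample_id` is mandatory and must be unique.
#' Recognized columns follow the generator's schema (`status`, `log_e2`,
#' `log_t`, `log_e2t`, `age`, `bmi`, `hrt`, `menopause`, `study`, `batch`,
#' `cluster_id`); unknown columns are carried through as extra covariates.
#' `hrt` given as `yes`/`no` is recoded to 1/0, and `log_e2t` is filled in
#' as `log_e2 - log_t` where both hormones are present.
#'
#' @param path TSV file.
#' @return phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ph <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(ph)) stop("phenotype table needs a sample_id column")
  ph$sample_id <- as.character(ph$sample_id)
  dup <- unique(ph$sample_id[duplicated(ph$sample_id)])
  if (length(dup)) stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  if ("hrt" %in% names(ph) && is.character(ph$hrt)) {
    low <- tolower(ph$hrt)
    bad <- !is.na(low) & !low %in% c("yes", "no", "0", "1")
    if (any(bad)) stop("unrecognized hrt value at row ", which(bad)[1])
    ph$hrt <- ifelse(is.na(low), NA_integer_, as.integer(low %in% c("yes", "1")))
  }
  for (cn in intersect(numeric_pheno_cols, names(ph))) {
    if (is.character(ph[[cn]])) {
      suppressWarnings(num <- as.numeric(ph[[cn]]))
      bad <- !is.na(ph[[cn]]) & is.na(num)
      if (any(bad))
        stop("non-numeric value '", ph[[cn]][which(bad)[1]], "' in column '",
             cn, "' at row ", which(bad)[1])
      ph[[cn]] <- num
    }
  }
  if (all(c("log_e2", "log_t") %in% names(ph))) {
    fill <- !is.na(ph$log_e2) & !is.na(ph$log_t)
    if (!"log_e2t" %in% names(ph)) ph$log_e2t <- NA_real_
    ph$log_e2t[fill] <- ph$log_e2[fill] - ph$log_t[fill]
  }
  ph
}

#' Write a phenotype table as TSV
#' @param phenotypes phenotype data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Align a genotype matrix and phenotype table on shared samples
#'
#' Intersects the two sample sets (order taken from the genotypes) and
#' reports how many samples were kept and dropped from each side.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes phenotype data.frame.
#' @return list with aligned `genotypes` and `phenotypes`.
#' @export
align_samples <- function(genotypes, phenotypes) {
  shared <- intersect(genotypes$samples, phenotypes$sample_id)
  if (length(shared) == 0) stop("no samples shared between genotypes and phenotypes")
  dg <- length(genotypes$samples) - length(shared)
  dp <- length(unique(phenotypes$sample_id)) - length(shared)
  message("align_samples: kept ", length(shared), " samples (dropped ",
          dg, " genotype-only, ", dp, " phenotype-only)")
  list(genotypes = subset_geno(genotypes, shared),
       phenotypes = phenotypes[match(shared, phenotypes$sample_id), , drop = FALSE])
}

#' Write the region-wide summary table
#'
#' One row per variant, ordered by position, with the meta-analysis,
#' conditional and candidate-set annotations: `variant_id`, `position`,
#' `effect_allele`, `freq_case`, `freq_ctrl`, `beta`, `se`, `or`,
#' `ci_lower`, `ci_upper`, `p`, `q`, `i2`, `p_het`, `excluded_het`,
#' `conditional_p`, `lr_vs_lead`, `r2_with_lead`, `in_candidate_set`.
#' P values are written in scientific notation with 3 significant digits.
#'
#' @param meta_results data.frame from [meta_scan()].
#' @param path output TSV path.
#' @param genotypes optional [geno_matrix()] supplying effect-allele labels.
#' @param conditional optional [conditional_scan()] result.
#' @param candidates optional [candidate_set()] result.
#' @return the assembled data.frame, invisibly.
#' @export
write_summary <- function(meta_results, path, genotypes = NULL,
                          conditional = NULL, candidates = NULL) {
  cols <- c("variant_id", "position", "effect_allele", "freq_case",
            "freq_ctrl", "beta", "se", "or", "ci_lower", "ci_upper", "p",
            "q", "i2", "p_het", "excluded_het", "conditional_p",
            "lr_vs_lead", "r2_with_lead", "in_candidate_set")
  d <- meta_results
  if (is.null(d) || nrow(d) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    utils::write.table(empty, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(empty))
  }
  out <- data.frame(variant_id = d$variant_id, position = d$position,
                    effect_allele = NA_character_,
                    freq_case = d$freq_case, freq_ctrl = d$freq_ctrl,
                    beta = d$beta, se = d$se, or = exp(d$beta),
                    ci_lower = exp(d$beta - 1.96 * d$se),
                    ci_upper = exp(d$beta + 1.96 * d$se),
                    p = d$p, q = d$q_stat, i2 = d$i2, p_het = d$p_het,
                    excluded_het = d$excluded_het,
                    conditional_p = NA_real_, lr_vs_lead = NA_real_,
                    r2_with_lead = NA_real_, in_candidate_set = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(genotypes)) {
    vt <- genotypes$variants
    i <- match(out$variant_id, vt$id)
    out$effect_allele <- ifelse(vt$effect_allele[i] == "alt",
                                vt$alt[i], vt$ref[i])
  }
  if (!is.null(conditional))
    out$conditional_p <- conditional$p[match(out$variant_id,
                                             conditional$variant_id)]
  if (!is.null(candidates)) {
    m <- candidates$members
    i <- match(out$variant_id, m$variant_id)
    out$lr_vs_lead <- m$lr[i]
    out$r2_with_lead <- m$r2[i]
    out$in_candidate_set <- !is.na(i)
  }
  out <- out[order(out$position), , drop = FALSE]
  fmt <- out
  for (cn in c("p", "p_het", "conditional_p"))
    fmt[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                        formatC(out[[cn]], format = "e", digits = 3))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
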
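#' Construct a genotype matrix
#'
#' Container for a samples-by-variants effect-allele dosage matrix plus variant
#' metadata, the common currency of all association operations. Missing
#' genotypes are encoded as `NA` in the dosage matrix.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns; all
#'   non-missing entries must lie in `[0, 2]` (fractional, imputed-style
#'   dosages are allowed).
#' @param variants data.frame with one row per variant and columns `id`,
#'   `position` (1-based bp, strictly increasing), `ref`, `alt`,
#'   `effect_allele` (one of `"ref"`/`"alt"`) and `effect_freq`.
#' @param samples character vector of unique sample identifiers.
#'
#' @return An object of class `"geno_matrix"`: a list with elements `dosage`,
#'   `variants` and `samples`.
#' @export
geno_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(samples))
    stop("dosage has ", nrow(dosage), " rows but ", length(samples), " samples")
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(variants), " variants")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages outside [0, 2]: range ", rng[1], " to ", rng[2])
  if (is.unsorted(variants$position, strictly = TRUE))
    stop("variant positions must be strictly increasing")
  rownames(dosage) <- samples
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix: ", length(x$samples), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  positions ", min(x$variants$position), "-",
      max(x$variants$position), "\n", sep = "")
  nm <- sum(is.na(x$dosage))
  if (nm > 0) cat("  ", nm, " missing dosages\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Extract a dosage vector for one variant
#' @param genotypes a [geno_matrix()].
#' @param variant variant id (character) or column index.
#' @return numeric dosage vector named by sample.
#' @export
dosage_of <- function(genotypes, variant) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (is.character(variant) && !variant %in% genotypes$variants$id)
    stop("variant '", variant, "' not found")
  genotypes$dosage[, variant]
}

#' Effect-allele frequency per variant
#'
#' Frequency is `sum(dosage) / (2 * n_nonmissing)` over the requested samples.
#'
#' @param genotypes a [geno_matrix()].
#' @param samples optional character vector restricting the computation to a
#'   sample subset (default: all samples).
#' @return named numeric vector of frequencies; variants with no non-missing
#'   dosage get `NA` with a warning.
#' @export
allele_freq <- function(genotypes, samples = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, genotypes$samples)
    if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "))
    d <- d[samples, , drop = FALSE]
  }
  n_ok <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n_ok)
  if (any(n_ok == 0)) {
    warning("variant(s) with all dosages missing: ",
            paste(colnames(d)[n_ok == 0], collapse = ", "))
    f[n_ok == 0] <- NA_real_
  }
  f
}
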
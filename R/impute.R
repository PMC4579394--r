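#' Impute a pre-phased study panel from a reference panel
#'
#' The top-level imputation driver.  The study panel carries the typed
#' (array-like) sites only; every study site must exist in the reference
#' legend (allele-swapped records are resolved by flipping the study
#' allele codes and counted).  Imputation proceeds per buffered chunk:
#' reference selection and the copying HMM run on the typed sites of the
#' buffered interval, and only the core interval's results are kept.
#'
#' @param study \code{haplotype_panel} of pre-phased study haplotypes at
#'   the typed sites.
#' @param ref reference \code{haplotype_panel}.
#' @param map a \code{genetic_map} covering the reference sites.
#' @param params an \code{\link{hmm_params}}.
#' @param spec a \code{\link{selection_spec}}.
#' @param chunk_bp core chunk size in bp; \code{NULL} (default) imputes
#'   the whole region as a single chunk.
#' @param buffer_bp flanking buffer in bp (used when chunking).
#' @return an object of class \code{imputation}: list with \code{legend}
#'   (reference legend), \code{dosage} (samples x sites), \code{p0},
#'   \code{p2} (genotype-probability matrices; \code{p1} is their
#'   complement), \code{hap_post} (haplotypes x sites P(ALT)),
#'   \code{info} (per-site info score), \code{maf_ref},
#'   \code{maf_imputed}, \code{typed_mask}, \code{n_swapped}.
#' @export
impute_panel <- function(study, ref, map, params = hmm_params(),
                         spec = selection_spec(), chunk_bp = NULL,
                         buffer_bp = 250e3) {
  stopifnot(inherits(study, "haplotype_panel"), inherits(ref, "haplotype_panel"))
  m <- match(study$legend$pos, ref$legend$pos)
  if (anyNA(m)) {
    miss <- study$legend$pos[is.na(m)][1]
    stop_("study typed site at position %d absent from reference legend", miss)
  }
  # resolve REF/ALT swaps between study and reference legends
  swap <- study$legend$ref == ref$legend$alt[m] &
          study$legend$alt == ref$legend$ref[m]
  same <- study$legend$ref == ref$legend$ref[m] &
          study$legend$alt == ref$legend$alt[m]
  if (any(!swap & !same))
    stop_("allele mismatch between study and reference at position %d",
          study$legend$pos[which(!swap & !same)[1]])
  study_alleles <- study$alleles
  if (any(swap))
    study_alleles[, swap] <- 1L - study_alleles[, swap]
  S <- n_site(ref)
  typed_mask <- rep(FALSE, S)
  typed_mask[m] <- TRUE
  H <- n_hap(study)
  hap_post <- matrix(NA_real_, nrow = H, ncol = S)

  pos <- ref$legend$pos
  if (is.null(chunk_bp)) {
    chunks <- data.frame(start = min(pos), end = max(pos) + 1,
                         bstart = min(pos), bend = max(pos) + 1)
  } else {
    chunks <- plan_chunks(min(pos), max(pos) + 1, chunk_bp, buffer_bp)
  }
  for (ci in seq_len(nrow(chunks))) {
    in_buf <- pos >= chunks$bstart[ci] & pos < chunks$bend[ci]
    in_core <- pos >= chunks$start[ci] & pos < chunks$end[ci]
    if (!any(in_core)) next
    sub_ref <- restrict_sites(ref, in_buf)
    sub_typed <- typed_mask[in_buf]
    if (!any(sub_typed))
      stop_("chunk [%g, %g) contains no typed sites",
            chunks$bstart[ci], chunks$bend[ci])
    study_cols <- match(which(typed_mask & in_buf), which(typed_mask))
    core_in_buf <- in_core[in_buf]
    panel_typed <- sub_ref$alleles[, which(sub_typed), drop = FALSE]
    for (h in seq_len(H)) {
      sv <- study_alleles[h, study_cols]
      sel <- select_references(sv, panel_typed, spec)
      p <- impute_haploid(sv, sub_ref, sub_typed, map, params, sel$indices)
      hap_post[h, in_core] <- p[core_in_buf]
    }
  }
  odd <- seq(1L, H, by = 2L)
  if (H %% 2L == 0L) {
    a <- hap_post[odd, , drop = FALSE]
    b <- hap_post[odd + 1L, , drop = FALSE]
    p2 <- a * b
    p0 <- (1 - a) * (1 - b)
    dosage <- a + b
    rownames(dosage) <- sample_names(study)
    info <- info_score_matrix(p0, 1 - p0 - p2, p2)
  } else {
    p0 <- p2 <- dosage <- NULL
    info <- rep(NA_real_, S)
  }
  structure(list(legend = ref$legend, dosage = dosage, p0 = p0, p2 = p2,
                 hap_post = hap_post, info = info,
                 maf_ref = panel_maf(ref),
                 maf_imputed = if (is.null(dosage)) NULL else {
                   f <- colMeans(dosage) / 2; pmin(f, 1 - f)
                 },
                 typed_mask = typed_mask, n_swapped = sum(swap),
                 params = params, spec = spec),
            class = "imputation")
}

#' @export
print.imputation <- function(x, ...) {
  cat(sprintf("imputation: %d samples x %d sites (%d typed)\n",
              if (is.null(x$dosage)) NA_integer_ else nrow(x$dosage),
              nrow(x$legend), sum(x$typed_mask)))
  cat(sprintf("  strategy=%s k=%d Ne=%g\n", x$spec$strategy, x$spec$k,
              x$params$Ne))
  if (!all(is.na(x$info)))
    cat(sprintf("  mean info %.3f; %d sites with info > 0.8\n",
                mean(x$info, na.rm = TRUE), sum(x$info > 0.8, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.imputation <- function(object, maf_bins = c(0.001, 0.005, 0.01,
                                                    0.02, 0.05, 0.5), ...) {
  maf <- object$maf_ref
  bin <- cut(maf, breaks = c(0, maf_bins), include.lowest = FALSE)
  out <- data.frame(
    maf_bin = levels(bin),
    n_sites = as.integer(table(bin)),
    mean_info = as.numeric(tapply(object$info, bin, mean, na.rm = TRUE)),
    n_info_gt_0.8 = as.integer(tapply(object$info > 0.8, bin, sum,
                                      na.rm = TRUE)))
  out$n_info_gt_0.8[is.na(out$n_info_gt_0.8)] <- 0L
  out
}
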
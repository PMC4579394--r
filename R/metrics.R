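#' IMPUTE-style info score (expected r2)
#'
#' A panel-free confidence metric estimating the squared correlation
#' between imputed dosage and the true genotype, computed from the
#' genotype-probability uncertainty over N samples.  With
#' \eqn{e_i = p_{1i} + 2 p_{2i}}, \eqn{f_i = p_{1i} + 4 p_{2i}} and
#' \eqn{\hat\theta = \sum e_i / 2N}:
#' \deqn{info = 1 - \frac{\sum_i (f_i - e_i^2)}{2N \hat\theta (1-\hat\theta)}}
#' defined as 1 when \eqn{\hat\theta \in \{0, 1\}} and clamped to [0, 1].
#'
#' @param calls data.frame or matrix with columns \code{p0, p1, p2} (one
#'   row per sample), e.g. from \code{\link{impute_diploid}}.
#' @return scalar info score in [0, 1].
#' @export
info_score <- function(calls) {
  calls <- as.matrix(calls)
  if (!all(c("p0", "p1", "p2") %in% colnames(calls)))
    stop_("calls must have columns p0, p1, p2")
  p0 <- calls[, "p0"]; p1 <- calls[, "p1"]; p2 <- calls[, "p2"]
  if (any(p0 < -1e-9 | p1 < -1e-9 | p2 < -1e-9) ||
      any(abs(p0 + p1 + p2 - 1) > 1e-6))
    stop_("malformed genotype-probability triples")
  n <- length(p0)
  e <- p1 + 2 * p2
  f <- p1 + 4 * p2
  th <- sum(e) / (2 * n)
  if (th <= 0 || th >= 1) return(1)
  info <- 1 - sum(f - e^2) / (2 * n * th * (1 - th))
  min(max(info, 0), 1)
}

# vectorised info over sites: p0, p1, p2 are samples x sites matrices
info_score_matrix <- function(p0, p1, p2) {
  n <- nrow(p0)
  e <- p1 + 2 * p2
  f <- p1 + 4 * p2
  th <- colSums(e) / (2 * n)
  num <- colSums(f - e^2)
  info <- ifelse(th <= 0 | th >= 1, 1, 1 - num / (2 * n * th * (1 - th)))
  pmin(pmax(info, 0), 1)
}

#' Squared correlation between imputed dosages and truth genotypes
#'
#' @param dosages numeric vector in [0, 2].
#' @param truth integer genotypes in \{0, 1, 2\}.
#' @return squared Pearson correlation, or \code{NA} (undefined) when
#'   either vector is constant.
#' @export
true_r2 <- function(dosages, truth) {
  if (length(dosages) != length(truth)) stop_("length mismatch")
  if (length(dosages) < 2L) stop_("need at least two samples")
  if (var(dosages) == 0 || var(truth) == 0) return(NA_real_)
  cor(dosages, truth)^2
}

#' Minor allele frequency of an allele or genotype vector
#'
#' @param x 0/1 haplotype alleles (\code{ploidy = 1}) or 0/1/2 diploid
#'   genotypes (\code{ploidy = 2}).
#' @param ploidy per-entry chromosome count.
#' @return \code{min(f, 1-f)} for ALT frequency f.
#' @export
maf_of <- function(x, ploidy = 1) {
  if (!length(x)) stop_("empty input")
  f <- mean(x) / ploidy
  min(f, 1 - f)
}

#' Build an evaluation report from per-site metrics
#'
#' Rolls per-site MAF / info / true-r2 values into non-overlapping MAF
#' bins: mean true r2 per bin (sites with undefined r2 are counted but
#' excluded from means), site counts per MAF x info bin, and
#' high-confidence (info > 0.8) counts per MAF bin.
#'
#' @param sites data.frame with columns \code{pos}, \code{maf},
#'   \code{info}, \code{true_r2} (NA where undefined).
#' @param maf_bins upper bin edges over (0, 0.5].
#' @param info_bins upper info-bin edges over [0, 1].
#' @return an object of class \code{eval_report}.
#' @export
eval_report <- function(sites, maf_bins = c(0.001, 0.005, 0.01, 0.02,
                                            0.05, 0.5),
                        info_bins = c(0.4, 0.8, 1)) {
  stopifnot(all(c("pos", "maf", "info", "true_r2") %in% names(sites)))
  poly <- sites[sites$maf > 0, , drop = FALSE]
  bin <- cut(poly$maf, breaks = c(0, maf_bins), include.lowest = FALSE)
  ibin <- cut(poly$info, breaks = c(-1e-9, info_bins))
  mean_r2 <- tapply(poly$true_r2, bin, mean, na.rm = TRUE)
  counts <- table(maf_bin = bin, info_bin = ibin)
  high <- tapply(poly$info > 0.8, bin, sum)
  high[is.na(high)] <- 0L
  undef <- tapply(is.na(poly$true_r2), bin, sum)
  undef[is.na(undef)] <- 0L
  structure(list(sites = sites,
                 maf_bins = maf_bins, info_bins = info_bins,
                 bin_labels = levels(bin),
                 n_sites = as.integer(table(bin)),
                 mean_true_r2 = as.numeric(mean_r2),
                 counts = unclass(counts),
                 n_high_confidence = as.integer(high),
                 n_undefined_r2 = as.integer(undef),
                 n_monomorphic = nrow(sites) - nrow(poly)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d polymorphic sites (+%d monomorphic)\n",
              sum(x$n_sites), x$n_monomorphic))
  df <- data.frame(maf_bin = x$bin_labels, n = x$n_sites,
                   mean_true_r2 = round(x$mean_true_r2, 4),
                   n_info_gt_0.8 = x$n_high_confidence,
                   n_r2_undefined = x$n_undefined_r2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  mids <- (c(0, head(x$maf_bins, -1)) + x$maf_bins) / 2
  plot(mids, x$mean_true_r2, type = "b", log = "x", ylim = c(0, 1),
       xlab = "MAF bin midpoint", ylab = "mean true r2", ...)
  invisible(x)
}

#' Mean true r2 among sites below a MAF threshold
#'
#' @param report an \code{eval_report}.
#' @param maf_max upper MAF bound (exclusive).
#' @param metric \code{"true_r2"} or \code{"info"}.
#' @return mean of the metric over polymorphic sites with
#'   \code{0 < maf < maf_max} (undefined r2 excluded).
#' @export
mean_metric_below <- function(report, maf_max = 0.05,
                              metric = c("true_r2", "info")) {
  metric <- match.arg(metric)
  s <- report$sites
  sel <- s$maf > 0 & s$maf < maf_max
  mean(s[[metric]][sel], na.rm = TRUE)
}

#' Leave-one-out imputation accuracy over a reference panel
#'
#' For each evaluated sample: its two haplotypes are removed from the
#' panel, its typed-site genotypes are exposed, all other sites are
#' imputed from the remaining panel, and the dosages are scored against
#' the held-out truth.  Per-site metrics are aggregated into an
#' \code{\link{eval_report}}.
#'
#' @param panel a diploid \code{haplotype_panel} (>= 3 samples).
#' @param typed_mask logical mask over panel sites marking the pseudo-array
#'   (typed) sites.
#' @param map a \code{genetic_map}.
#' @param params an \code{hmm_params}.
#' @param spec a \code{selection_spec}.
#' @param n_samples optional number of samples to evaluate (a seeded
#'   random subsample for speed); default all.
#' @param seed RNG seed for the subsample.
#' @param maf_bins,info_bins passed to \code{\link{eval_report}}.
#' @return an \code{eval_report}.
#' @export
leave_one_out_eval <- function(panel, typed_mask, map,
                               params = hmm_params(),
                               spec = selection_spec(),
                               n_samples = NULL, seed = 1,
                               maf_bins = c(0.001, 0.005, 0.01, 0.02,
                                            0.05, 0.5),
                               info_bins = c(0.4, 0.8, 1)) {
  H <- n_hap(panel)
  if (H %% 2L != 0L || H < 6L) stop_("panel must hold >= 3 diploid samples")
  if (is.logical(typed_mask)) typed_idx <- which(typed_mask)
  else typed_idx <- as.integer(typed_mask)
  if (!length(typed_idx)) stop_("typed_mask is empty")
  ns <- H %/% 2L
  eval_samples <- seq_len(ns)
  if (!is.null(n_samples)) {
    if (n_samples < 1) stop_("must evaluate at least one sample")
    if (n_samples < ns) {
      set.seed(seed)
      eval_samples <- sort(sample.int(ns, n_samples))
    }
  }
  S <- n_site(panel)
  ne <- length(eval_samples)
  dosage <- matrix(NA_real_, ne, S)
  p0 <- matrix(NA_real_, ne, S)
  p2 <- matrix(NA_real_, ne, S)
  truth <- diploid_genotypes(panel)[eval_samples, , drop = FALSE]
  for (i in seq_len(ne)) {
    s <- eval_samples[i]
    rows <- c(2L * s - 1L, 2L * s)
    ref <- keep_haplotypes(panel, setdiff(seq_len(H), rows))
    panel_typed <- ref$alleles[, typed_idx, drop = FALSE]
    post <- matrix(NA_real_, 2L, S)
    for (j in 1:2) {
      sv <- panel$alleles[rows[j], typed_idx]
      sel <- select_references(sv, panel_typed, spec)
      post[j, ] <- impute_haploid(sv, ref, typed_idx, map, params,
                                  sel$indices)
    }
    dosage[i, ] <- post[1L, ] + post[2L, ]
    p0[i, ] <- (1 - post[1L, ]) * (1 - post[2L, ])
    p2[i, ] <- post[1L, ] * post[2L, ]
  }
  info <- info_score_matrix(p0, 1 - p0 - p2, p2)
  r2 <- vapply(seq_len(S), function(j) true_r2(dosage[, j], truth[, j]),
               numeric(1))
  maf <- vapply(seq_len(S), function(j) maf_of(truth[, j], ploidy = 2),
                numeric(1))
  eval_report(data.frame(pos = panel$legend$pos, maf = maf, info = info,
                         true_r2 = r2),
              maf_bins = maf_bins, info_bins = info_bins)
}

#' Pseudo-GWAS imputation accuracy against full-sequence truth
#'
#' Reduces the study panel to its typed (array-like) sites, imputes all
#' reference sites, and scores dosages against the withheld truth
#' genotypes wherever the study truth covers a reference site; every
#' imputed site receives an info score.
#'
#' @param study a diploid \code{haplotype_panel} holding the full truth
#'   haplotypes.
#' @param typed_mask logical mask over the study sites defining the
#'   pseudo-array.
#' @param ref the reference \code{haplotype_panel}; every typed study
#'   site must exist in its legend.
#' @param map a \code{genetic_map}.
#' @param params an \code{hmm_params}.
#' @param spec a \code{selection_spec}.
#' @param maf_source MAF used for binning: from the study truth
#'   genotypes (default, accuracy curves) or from the imputed dosages
#'   (count tables).
#' @param maf_bins,info_bins passed to \code{\link{eval_report}}.
#' @param chunk_bp,buffer_bp optional chunking, as in
#'   \code{\link{impute_panel}}.
#' @return an \code{eval_report}; the underlying \code{imputation}
#'   object is attached as attribute \code{"imputation"}.
#' @export
pseudo_gwas_eval <- function(study, typed_mask, ref, map,
                             params = hmm_params(),
                             spec = selection_spec(),
                             maf_source = c("truth", "imputed"),
                             maf_bins = c(0.001, 0.005, 0.01, 0.02,
                                          0.05, 0.5),
                             info_bins = c(0.4, 0.8, 1),
                             chunk_bp = NULL, buffer_bp = 250e3) {
  maf_source <- match.arg(maf_source)
  if (is.logical(typed_mask)) typed_idx <- which(typed_mask)
  else typed_idx <- as.integer(typed_mask)
  if (!length(typed_idx)) stop_("typed_mask is empty")
  gwas <- restrict_sites(study, typed_idx)
  imp <- impute_panel(gwas, ref, map, params, spec,
                      chunk_bp = chunk_bp, buffer_bp = buffer_bp)
  S <- n_site(ref)
  truth_all <- diploid_genotypes(study)
  m <- match(ref$legend$pos, study$legend$pos)
  r2 <- rep(NA_real_, S)
  maf_truth <- rep(NA_real_, S)
  have <- !is.na(m)
  for (j in which(have)) {
    r2[j] <- true_r2(imp$dosage[, j], truth_all[, m[j]])
    maf_truth[j] <- maf_of(truth_all[, m[j]], ploidy = 2)
  }
  maf <- switch(maf_source,
                truth = ifelse(have, maf_truth, imp$maf_ref),
                imputed = imp$maf_imputed)
  rep_ <- eval_report(data.frame(pos = ref$legend$pos, maf = maf,
                                 info = imp$info, true_r2 = r2),
                      maf_bins = maf_bins, info_bins = info_bins)
  attr(rep_, "imputation") <- imp
  rep_
}

#' Compare imputation configurations on one scenario
#'
#' Runs \code{\link{pseudo_gwas_eval}} for each configuration on
#' identical study inputs and collects accuracy-by-MAF and count tables.
#'
#' @param scenario a scenario from \code{\link{make_scenario}}, or a list
#'   with \code{study_truth}, \code{typed_mask}, \code{map}.
#' @param configs named list; each element is a list with elements
#'   \code{ref} (a \code{haplotype_panel}) and \code{spec} (a
#'   \code{selection_spec}).
#' @param params an \code{hmm_params}.
#' @param ... passed to \code{pseudo_gwas_eval}.
#' @return an object of class \code{config_comparison}: list of
#'   \code{reports}, a \code{r2_table} (MAF bin x config mean true r2)
#'   and a \code{high_conf_table} (MAF bin x config info > 0.8 counts).
#' @export
compare_configs <- function(scenario, configs, params = hmm_params(), ...) {
  if (length(configs) < 2L) stop_("need at least two configurations")
  if (is.null(names(configs)) || any(names(configs) == ""))
    stop_("configs must be a named list")
  reports <- lapply(configs, function(cf) {
    pseudo_gwas_eval(scenario$study_truth, scenario$typed_mask, cf$ref,
                     scenario$map, params, cf$spec, ...)
  })
  r2_table <- sapply(reports, function(r) r$mean_true_r2)
  rownames(r2_table) <- reports[[1]]$bin_labels
  hc_table <- sapply(reports, function(r) r$n_high_confidence)
  rownames(hc_table) <- reports[[1]]$bin_labels
  structure(list(reports = reports, r2_table = r2_table,
                 high_conf_table = hc_table),
            class = "config_comparison")
}

#' @export
print.config_comparison <- function(x, ...) {
  cat("config_comparison: mean true r2 by MAF bin\n")
  print(round(x$r2_table, 4))
  cat("sites with info > 0.8 by MAF bin\n")
  print(x$high_conf_table)
  invisible(x)
}
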
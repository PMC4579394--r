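#' Reference-haplotype selection strategy
#'
#' Specifies how the conditioning reference haplotypes for the copying HMM
#' are chosen per study haplotype and imputation chunk: the full panel
#' (\code{"all"}), the k references closest in region-wide Hamming
#' distance over the chunk's typed sites (\code{"hamming"}, the classical
#' k_hap approximation), or a local tract-sharing rule (\code{"tracts"})
#' that ranks references by the length of the exact-match segment around
#' each of several anchor sites.
#'
#' @param strategy one of \code{"all"}, \code{"hamming"}, \code{"tracts"}.
#' @param k target number of reference haplotypes (>= 2); clipped to the
#'   panel size at run time.  Default 10000, the chromosome-scale k_hap
#'   default.
#' @param anchors number of evenly spaced typed anchor sites for tract
#'   scoring (tracts only; default 16).
#' @return an object of class \code{selection_spec}.
#' @export
selection_spec <- function(strategy = c("hamming", "all", "tracts"),
                           k = 10000, anchors = 16) {
  strategy <- match.arg(strategy)
  if (k < 2) stop_("k must be >= 2")
  if (anchors < 1) stop_("anchors must be >= 1")
  structure(list(strategy = strategy, k = as.integer(k),
                 anchors = as.integer(anchors)),
            class = "selection_spec")
}

#' Select every reference haplotype
#'
#' @param panel_size number of reference haplotypes (>= 2).
#' @return list with \code{indices} (1..panel_size) and \code{scores}
#'   (zeros).
#' @export
select_all <- function(panel_size) {
  if (panel_size < 2) stop_("need at least two reference haplotypes")
  list(indices = seq_len(panel_size), scores = rep(0, panel_size))
}

#' Select references by region-wide Hamming distance
#'
#' The k references with the fewest allele mismatches to the study
#' haplotype across all typed sites of the (buffered) chunk; ties broken
#' by lower reference index.  Indices are returned sorted, so selection at
#' k = panel size reproduces \code{\link{select_all}} exactly.
#'
#' @param study_typed 0/1 study alleles at the typed sites.
#' @param panel_typed K x T matrix of reference alleles at the same sites.
#' @param k number of references to keep (>= 2, clipped to K).
#' @return list with \code{indices} (sorted) and \code{scores} (the
#'   Hamming distances of the chosen references, in index order).
#' @export
select_hamming <- function(study_typed, panel_typed, k) {
  if (k < 2) stop_("k must be >= 2")
  panel_typed <- as.matrix(panel_typed)
  K <- nrow(panel_typed)
  d <- hamming_distances(study_typed, panel_typed)
  k <- min(k, K)
  ord <- order(d, seq_len(K))[seq_len(k)]
  idx <- sort(ord)
  list(indices = idx, scores = d[idx])
}

hamming_distances <- function(study_typed, panel_typed) {
  as.integer(rowSums(panel_typed != matrix(as.integer(study_typed),
                                           nrow = nrow(panel_typed),
                                           ncol = ncol(panel_typed),
                                           byrow = TRUE)))
}

#' Shared-tract length around a typed site
#'
#' Length (in typed sites) of the maximal run of consecutive typed sites
#' containing \code{site_idx} on which study and reference agree; 0 if
#' they differ at \code{site_idx} itself.
#'
#' @param study_typed,ref_typed 0/1 allele vectors over the typed sites.
#' @param site_idx 1-based typed-site index.
#' @return integer tract length.
#' @export
shared_tract_length <- function(study_typed, ref_typed, site_idx) {
  T_ <- length(study_typed)
  if (length(ref_typed) != T_) stop_("vectors differ in length")
  if (site_idx < 1 || site_idx > T_) stop_("site index out of range")
  if (study_typed[site_idx] != ref_typed[site_idx]) return(0L)
  lo <- site_idx
  while (lo > 1L && study_typed[lo - 1L] == ref_typed[lo - 1L]) lo <- lo - 1L
  hi <- site_idx
  while (hi < T_ && study_typed[hi + 1L] == ref_typed[hi + 1L]) hi <- hi + 1L
  hi - lo + 1L
}

#' Select references by local tract sharing
#'
#' Places \code{spec$anchors} evenly spaced anchor sites over the typed
#' sites of the chunk; at each anchor, references are ranked by
#' \code{\link{shared_tract_length}} and the top \code{ceiling(k/anchors)}
#' are taken; the per-anchor sets are unioned.  If the union exceeds k,
#' the references with the largest maximum-over-anchors tract length are
#' kept (ties broken by lower index); if it falls short, the next-best
#' region-wide Hamming candidates fill the remainder.
#'
#' @param study_typed 0/1 study alleles at the typed sites.
#' @param panel_typed K x T reference allele matrix at the same sites.
#' @param spec a \code{\link{selection_spec}} with strategy
#'   \code{"tracts"}.
#' @return list with \code{indices} (sorted) and \code{scores} (maximum
#'   tract length over anchors for each chosen reference).
#' @export
select_tracts <- function(study_typed, panel_typed, spec) {
  if (!inherits(spec, "selection_spec")) stop_("spec must be a selection_spec")
  panel_typed <- as.matrix(panel_typed)
  storage.mode(panel_typed) <- "integer"
  K <- nrow(panel_typed); T_ <- ncol(panel_typed)
  if (spec$anchors > T_)
    stop_("more anchors (%d) than typed sites (%d)", spec$anchors, T_)
  k <- min(spec$k, K)
  if (k == K) {
    return(list(indices = seq_len(K),
                scores = rep(NA_integer_, K)))
  }
  anchor_idx <- unique(round(seq(1, T_, length.out = spec$anchors)))
  L <- ls_tract_lengths(as.integer(study_typed), panel_typed,
                        as.integer(anchor_idx))
  quota <- ceiling(k / length(anchor_idx))
  chosen <- integer(0)
  for (a in seq_along(anchor_idx)) {
    top <- order(-L[, a], seq_len(K))[seq_len(min(quota, K))]
    chosen <- union(chosen, top)
  }
  maxL <- apply(L, 1L, max)
  if (length(chosen) > k) {
    keep <- chosen[order(-maxL[chosen], chosen)][seq_len(k)]
    chosen <- keep
  } else if (length(chosen) < k) {
    d <- hamming_distances(study_typed, panel_typed)
    pool <- setdiff(order(d, seq_len(K)), chosen)
    chosen <- c(chosen, pool[seq_len(k - length(chosen))])
  }
  idx <- sort(chosen)
  list(indices = idx, scores = maxL[idx])
}

#' Dispatch reference selection for one study haplotype
#'
#' @param study_typed 0/1 study alleles at the chunk's typed sites.
#' @param panel_typed K x T reference allele matrix at the same sites.
#' @param spec a \code{\link{selection_spec}}.
#' @return list with \code{indices} and \code{scores}; selection is fully
#'   deterministic.
#' @export
select_references <- function(study_typed, panel_typed, spec) {
  switch(spec$strategy,
         all = select_all(nrow(as.matrix(panel_typed))),
         hamming = select_hamming(study_typed, panel_typed, spec$k),
         tracts = select_tracts(study_typed, panel_typed, spec))
}
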
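#' Harmonize two phased panels' site sets
#'
#' Applies the standard pre-merge filters to a pair of phased panels on
#' the same chromosome: positions carrying duplicate records within a
#' panel are treated as multi-allelic and removed; sites present at the
#' same position in both panels with exchanged REF/ALT alleles are
#' resolved by flipping one panel's allele codes; same-position sites
#' whose allele pairs genuinely differ are removed from both panels; and
#' sites private to one panel whose minor-allele count there is exactly 1
#' (cross-panel singletons) are removed.  Every exclusion is counted once
#' per site in the returned report.
#'
#' @param panel_a,panel_b \code{haplotype_panel}s with position-sorted
#'   legends.
#' @return list with the filtered \code{panel_a}, \code{panel_b} and a
#'   \code{report} of class \code{filter_report} with fields
#'   \code{n_input_a/b}, \code{n_multiallelic_a/b}, \code{n_mismatch},
#'   \code{n_swapped}, \code{n_private_singletons_a/b},
#'   \code{n_kept_a/b}.
#' @export
harmonize <- function(panel_a, panel_b) {
  stopifnot(inherits(panel_a, "haplotype_panel"),
            inherits(panel_b, "haplotype_panel"))
  n_in_a <- n_site(panel_a); n_in_b <- n_site(panel_b)

  drop_dups <- function(p) {
    dup_pos <- unique(p$legend$pos[duplicated(p$legend$pos)])
    keep <- !(p$legend$pos %in% dup_pos)
    list(panel = if (all(keep)) p else
           haplotype_panel(p$legend[keep, , drop = FALSE],
                           p$alleles[, keep, drop = FALSE], p$hap_ids),
         n = length(dup_pos))
  }
  # duplicate same-position records cannot pass the strict legend check,
  # so tolerate them here by bypassing the constructor when subsetting
  split_dups <- function(p) {
    dup_pos <- unique(p$legend$pos[duplicated(p$legend$pos)])
    keep <- !(p$legend$pos %in% dup_pos)
    p$legend <- p$legend[keep, , drop = FALSE]
    rownames(p$legend) <- NULL
    p$alleles <- p$alleles[, keep, drop = FALSE]
    list(panel = p, n = length(dup_pos))
  }
  da <- split_dups(panel_a); db <- split_dups(panel_b)
  pa <- da$panel; pb <- db$panel
  if (is.unsorted(pa$legend$pos, strictly = TRUE) ||
      is.unsorted(pb$legend$pos, strictly = TRUE))
    stop_("legends must be position-sorted")

  m <- match(pa$legend$pos, pb$legend$pos)
  shared_a <- which(!is.na(m))
  shared_b <- m[shared_a]
  swap <- pa$legend$ref[shared_a] == pb$legend$alt[shared_b] &
          pa$legend$alt[shared_a] == pb$legend$ref[shared_b]
  same <- pa$legend$ref[shared_a] == pb$legend$ref[shared_b] &
          pa$legend$alt[shared_a] == pb$legend$alt[shared_b]
  if (any(swap)) {
    cols <- shared_b[swap]
    pb$alleles[, cols] <- 1L - pb$alleles[, cols]
    tmp <- pb$legend$ref[cols]
    pb$legend$ref[cols] <- pb$legend$alt[cols]
    pb$legend$alt[cols] <- tmp
  }
  mismatch <- !(same | swap)
  n_mismatch <- sum(mismatch)
  drop_a <- shared_a[mismatch]
  drop_b <- shared_b[mismatch]

  # cross-panel singletons among private sites
  minor_count <- function(p) {
    ac <- colSums(p$alleles)
    pmin(ac, n_hap(p) - ac)
  }
  priv_a <- setdiff(seq_len(n_site(pa)), shared_a)
  priv_b <- setdiff(seq_len(n_site(pb)), shared_b)
  sing_a <- priv_a[minor_count(pa)[priv_a] == 1L]
  sing_b <- priv_b[minor_count(pb)[priv_b] == 1L]

  keep_a <- setdiff(seq_len(n_site(pa)), c(drop_a, sing_a))
  keep_b <- setdiff(seq_len(n_site(pb)), c(drop_b, sing_b))
  out_a <- restrict_sites(pa, keep_a)
  out_b <- restrict_sites(pb, keep_b)

  report <- structure(list(
    n_input_a = n_in_a, n_input_b = n_in_b,
    n_multiallelic_a = da$n, n_multiallelic_b = db$n,
    n_mismatch = n_mismatch, n_swapped = sum(swap),
    n_private_singletons_a = length(sing_a),
    n_private_singletons_b = length(sing_b),
    n_kept_a = length(keep_a), n_kept_b = length(keep_b)),
    class = "filter_report")
  # accounting identity: kept = input - exclusions (duplicates count the
  # records removed at each flagged position)
  n_dup_rec_a <- n_in_a - n_site(pa)
  n_dup_rec_b <- n_in_b - n_site(pb)
  stopifnot(report$n_kept_a ==
              n_in_a - n_dup_rec_a - n_mismatch - length(sing_a),
            report$n_kept_b ==
              n_in_b - n_dup_rec_b - n_mismatch - length(sing_b))
  list(panel_a = out_a, panel_b = out_b, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  cat(sprintf("  panel A: %d in, %d multi-allelic, %d mismatched, %d private singletons -> %d kept\n",
              x$n_input_a, x$n_multiallelic_a, x$n_mismatch,
              x$n_private_singletons_a, x$n_kept_a))
  cat(sprintf("  panel B: %d in, %d multi-allelic, %d mismatched, %d private singletons -> %d kept\n",
              x$n_input_b, x$n_multiallelic_b, x$n_mismatch,
              x$n_private_singletons_b, x$n_kept_b))
  if (x$n_swapped)
    cat(sprintf("  %d REF/ALT-swapped sites resolved by allele-code flip\n",
                x$n_swapped))
  invisible(x)
}

#' Sites retained after exclusion filters
#'
#' Worked-example arithmetic of the site-filtering accounting: the number
#' of sites kept is the input count minus the sum of the per-category
#' exclusion counts (each site excluded exactly once).
#'
#' @param n_input total input site count.
#' @param exclusions numeric vector of per-category exclusion counts.
#' @return integer kept-site count.
#' @examples
#' sites_after_filtering(45492035, c(18180633, 1064168, 214631))
#' @export
sites_after_filtering <- function(n_input, exclusions) {
  if (any(exclusions < 0) || sum(exclusions) > n_input)
    stop_("exclusions exceed input sites")
  as.integer(n_input - sum(exclusions))
}

#' Union site count of two panels
#'
#' @param n_a,n_b per-panel site counts after filtering.
#' @param n_overlap count of sites present in both.
#' @return \code{n_a + n_b - n_overlap}.
#' @examples
#' union_count(26032603, 32449428, 16122337)
#' @export
union_count <- function(n_a, n_b, n_overlap) {
  if (n_overlap > min(n_a, n_b) || n_overlap < 0)
    stop_("overlap exceeds panel site counts")
  n_a + n_b - n_overlap
}

#' Impute one panel's private sites into another panel
#'
#' Treats each target haplotype as a pre-phased haploid study sequence
#' typed at the sites shared with the donor, runs the copying HMM against
#' the donor panel, and appends best-guess alleles at the requested
#' donor-private sites.  Optionally chunked with buffers.
#'
#' @param target \code{haplotype_panel} receiving new sites.
#' @param donor \code{haplotype_panel} providing them.
#' @param sites_to_add bp positions, a subset of the donor legend and
#'   disjoint from the target legend.
#' @param map a \code{genetic_map}.
#' @param params an \code{hmm_params}.
#' @param spec a \code{selection_spec}.
#' @param chunk_bp,buffer_bp optional chunking of the donor region.
#' @return a \code{haplotype_panel} over the position-sorted union of the
#'   target legend and \code{sites_to_add}; original target alleles are
#'   preserved exactly.
#' @export
cross_impute <- function(target, donor, sites_to_add, map,
                         params = hmm_params(), spec = selection_spec(),
                         chunk_bp = NULL, buffer_bp = 250e3) {
  if (!length(sites_to_add)) return(target)
  if (!all(sites_to_add %in% donor$legend$pos))
    stop_("sites_to_add must be a subset of the donor legend")
  if (any(sites_to_add %in% target$legend$pos))
    stop_("sites_to_add overlap the target legend")
  shared <- intersect(target$legend$pos, donor$legend$pos)
  if (!length(shared))
    stop_("panels share no sites after harmonization")

  donor_keep <- donor$legend$pos %in% c(shared, sites_to_add)
  dsub <- restrict_sites(donor, donor_keep)
  typed_mask <- dsub$legend$pos %in% shared
  tcols <- match(dsub$legend$pos[typed_mask], target$legend$pos)
  H <- n_hap(target)
  Sd <- n_site(dsub)
  add_mask <- dsub$legend$pos %in% sites_to_add
  new_alleles <- matrix(0L, nrow = H, ncol = sum(add_mask))

  pos <- dsub$legend$pos
  if (is.null(chunk_bp)) {
    chunks <- data.frame(start = min(pos), end = max(pos) + 1,
                         bstart = min(pos), bend = max(pos) + 1)
  } else {
    chunks <- plan_chunks(min(pos), max(pos) + 1, chunk_bp, buffer_bp)
  }
  for (ci in seq_len(nrow(chunks))) {
    in_buf <- pos >= chunks$bstart[ci] & pos < chunks$bend[ci]
    core_add <- add_mask & pos >= chunks$start[ci] & pos < chunks$end[ci]
    if (!any(core_add)) next
    csub <- restrict_sites(dsub, in_buf)
    ctyped <- typed_mask[in_buf]
    if (!any(ctyped))
      stop_("chunk [%g, %g) shares no sites with the target",
            chunks$bstart[ci], chunks$bend[ci])
    tcols_chunk <- tcols[match(which(typed_mask & in_buf),
                               which(typed_mask))]
    panel_typed <- csub$alleles[, which(ctyped), drop = FALSE]
    out_cols <- match(which(core_add), which(add_mask))
    core_in_buf <- which(core_add[in_buf])
    for (h in seq_len(H)) {
      sv <- target$alleles[h, tcols_chunk]
      sel <- select_references(sv, panel_typed, spec)
      p <- impute_haploid(sv, csub, ctyped, map, params, sel$indices)
      new_alleles[h, out_cols] <- best_guess(p[core_in_buf])
    }
  }
  new_legend <- rbind(target$legend,
                      dsub$legend[add_mask, , drop = FALSE])
  ord <- order(new_legend$pos)
  all_alleles <- cbind(target$alleles, new_alleles)
  haplotype_panel(new_legend[ord, , drop = FALSE],
                  all_alleles[, ord, drop = FALSE], target$hap_ids)
}

#' Merge two phased panels by reciprocal imputation
#'
#' Harmonizes the panels (unless told they already are), imputes panel
#' B's private sites into panel A and vice versa, then stacks the
#' haplotypes over the position-sorted union legend.  Observed alleles
#' are never altered; only panel-private sites receive imputed best-guess
#' alleles.  The returned report's inclusion-exclusion identities are
#' checked on every run.
#'
#' @param panel_a,panel_b \code{haplotype_panel}s.
#' @param map a \code{genetic_map}.
#' @param params an \code{hmm_params}.
#' @param spec a \code{selection_spec}.
#' @param harmonized set \code{TRUE} if the panels already went through
#'   \code{\link{harmonize}}.
#' @param chunk_bp,buffer_bp optional chunking for the reciprocal
#'   imputation.
#' @return list with the merged \code{panel}, a \code{merge_report}
#'   (site-set accounting with SNP/INDEL breakdown) and the
#'   \code{filter_report} from harmonization (\code{NULL} when
#'   \code{harmonized = TRUE}).
#' @export
merge_panels <- function(panel_a, panel_b, map, params = hmm_params(),
                         spec = selection_spec(), harmonized = FALSE,
                         chunk_bp = NULL, buffer_bp = 250e3) {
  filt <- NULL
  if (!harmonized) {
    h <- harmonize(panel_a, panel_b)
    panel_a <- h$panel_a; panel_b <- h$panel_b; filt <- h$report
  }
  pos_a <- panel_a$legend$pos; pos_b <- panel_b$legend$pos
  shared <- intersect(pos_a, pos_b)
  if (!length(shared)) stop_("panels share no sites after harmonization")
  a_only <- setdiff(pos_a, pos_b)
  b_only <- setdiff(pos_b, pos_a)

  a_full <- if (length(b_only))
    cross_impute(panel_a, panel_b, b_only, map, params, spec,
                 chunk_bp, buffer_bp) else panel_a
  b_full <- if (length(a_only))
    cross_impute(panel_b, panel_a, a_only, map, params, spec,
                 chunk_bp, buffer_bp) else panel_b
  stopifnot(identical(a_full$legend$pos, b_full$legend$pos))

  merged <- haplotype_panel(a_full$legend,
                            rbind(a_full$alleles, b_full$alleles),
                            c(paste0("A_", a_full$hap_ids),
                              paste0("B_", b_full$hap_ids)))
  vc <- merged$legend$vclass
  in_a_only <- merged$legend$pos %in% a_only
  in_b_only <- merged$legend$pos %in% b_only
  in_shared <- merged$legend$pos %in% shared
  by_class <- function(mask) c(SNP = sum(mask & vc == "SNP"),
                               INDEL = sum(mask & vc == "INDEL"))
  report <- structure(list(
    n_a_only = length(a_only), n_b_only = length(b_only),
    n_shared = length(shared),
    n_union = length(a_only) + length(b_only) + length(shared),
    n_kept_a = length(pos_a), n_kept_b = length(pos_b),
    class_breakdown = rbind(a_only = by_class(in_a_only),
                            b_only = by_class(in_b_only),
                            shared = by_class(in_shared),
                            union = by_class(rep(TRUE, length(vc))))),
    class = "merge_report")
  stopifnot(report$n_union == n_site(merged),
            report$n_union == report$n_kept_a + report$n_kept_b -
              report$n_shared)
  # observed alleles preserved exactly
  ia <- match(pos_a, merged$legend$pos)
  stopifnot(identical(merged$alleles[seq_len(n_hap(panel_a)), ia],
                      panel_a$alleles))
  ib <- match(pos_b, merged$legend$pos)
  stopifnot(identical(merged$alleles[n_hap(panel_a) + seq_len(n_hap(panel_b)), ib],
                      panel_b$alleles))
  list(panel = merged, report = report, filter_report = filt)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("merge_report: union %d = a_only %d + b_only %d + shared %d\n",
              x$n_union, x$n_a_only, x$n_b_only, x$n_shared))
  print(x$class_breakdown)
  invisible(x)
}
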
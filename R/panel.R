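#' Phased haplotype panel
#'
#' The universal carrier for reference, study and merged panels: an ordered
#' biallelic site legend plus a binary allele matrix with one row per
#' haplotype and one column per site.  Two consecutive rows (2i-1, 2i) form
#' the phased diploid genotype of sample i when the panel represents diploid
#' samples.
#'
#' @param legend data.frame with columns \code{chrom}, \code{pos} (1-based
#'   bp, strictly increasing within a chromosome), \code{id}, \code{ref},
#'   \code{alt}.  A \code{vclass} column (\code{"SNP"}/\code{"INDEL"}) is
#'   derived from the allele lengths if absent.
#' @param alleles integer matrix of 0 (REF) / 1 (ALT); haplotypes in rows,
#'   sites in columns.  Column count must equal \code{nrow(legend)}.
#' @param hap_ids optional character vector of haplotype identifiers; the
#'   default labels pairs of rows \code{S<i>_A}, \code{S<i>_B}.
#' @return An object of class \code{haplotype_panel}: a list with elements
#'   \code{legend}, \code{alleles}, \code{hap_ids}.
#' @examples
#' leg <- data.frame(chrom = "20", pos = c(100L, 200L), id = c("s1", "s2"),
#'                   ref = c("A", "G"), alt = c("C", "T"))
#' haplotype_panel(leg, matrix(c(0L, 1L, 1L, 0L), nrow = 2))
#' @export
haplotype_panel <- function(legend, alleles, hap_ids = NULL) {
  if (!is.data.frame(legend))
    stop_("legend must be a data.frame")
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, names(legend))
  if (length(miss))
    stop_("legend is missing column(s): %s", paste(miss, collapse = ", "))
  legend$chrom <- as.character(legend$chrom)
  legend$pos <- as.integer(legend$pos)
  legend$id <- as.character(legend$id)
  legend$ref <- as.character(legend$ref)
  legend$alt <- as.character(legend$alt)
  if (is.null(legend$vclass))
    legend$vclass <- site_class(legend$ref, legend$alt)
  if (any(legend$pos < 1L)) stop_("legend positions must be >= 1")
  if (any(legend$ref == legend$alt)) stop_("legend has ref == alt at some site")
  for (ch in unique(legend$chrom)) {
    p <- legend$pos[legend$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop_("legend positions must be strictly increasing within chromosome %s", ch)
  }
  if (!is.matrix(alleles)) alleles <- matrix(as.integer(alleles), nrow = 1L)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != nrow(legend))
    stop_("alleles has %d columns but legend has %d sites",
          ncol(alleles), nrow(legend))
  if (nrow(alleles) && !all(alleles %in% 0:1))
    stop_("allele matrix entries must all be 0 or 1")
  if (is.null(hap_ids)) {
    n <- nrow(alleles)
    hap_ids <- if (n %% 2L == 0L)
      paste0("S", rep(seq_len(n / 2L), each = 2L), c("_A", "_B"))
    else paste0("H", seq_len(n))
  }
  if (length(hap_ids) != nrow(alleles))
    stop_("hap_ids length does not match haplotype count")
  dimnames(alleles) <- NULL
  rownames(legend) <- NULL
  structure(list(legend = legend, alleles = alleles,
                 hap_ids = as.character(hap_ids)),
            class = "haplotype_panel")
}

#' Classify sites as SNP or INDEL from allele strings
#'
#' @param ref,alt character vectors of REF/ALT alleles.
#' @return character vector, \code{"SNP"} where both alleles are single
#'   bases, \code{"INDEL"} otherwise.
#' @export
site_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites (%s)\n",
              n_hap(x), n_site(x),
              paste(unique(x$legend$chrom), collapse = ",")))
  tab <- table(x$legend$vclass)
  cat("  sites:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (n_site(x))
    cat(sprintf("  span: %d-%d bp\n", min(x$legend$pos), max(x$legend$pos)))
  invisible(x)
}

#' Panel dimensions and allele frequencies
#'
#' @param panel a \code{haplotype_panel}.
#' @return \code{n_hap}/\code{n_site}: integer counts. \code{alt_freq}: ALT
#'   allele frequency per site.  \code{panel_maf}: per-site minor allele
#'   frequency.
#' @export
n_hap <- function(panel) nrow(panel$alleles)

#' @rdname n_hap
#' @export
n_site <- function(panel) ncol(panel$alleles)

#' @rdname n_hap
#' @export
alt_freq <- function(panel) {
  if (n_hap(panel) == 0L) return(rep(NA_real_, n_site(panel)))
  colMeans(panel$alleles)
}

#' @rdname n_hap
#' @export
panel_maf <- function(panel) {
  f <- alt_freq(panel)
  pmin(f, 1 - f)
}

#' Subset a panel by site index or haplotype row
#'
#' @param panel a \code{haplotype_panel}.
#' @param idx site column indices (or logical mask) to keep, in order.
#' @param rows haplotype row indices (or logical mask).
#' @return a new \code{haplotype_panel}.
#' @export
restrict_sites <- function(panel, idx) {
  if (is.logical(idx)) idx <- which(idx)
  haplotype_panel(panel$legend[idx, , drop = FALSE],
                  panel$alleles[, idx, drop = FALSE],
                  panel$hap_ids)
}

#' @rdname restrict_sites
#' @export
keep_haplotypes <- function(panel, rows) {
  if (is.logical(rows)) rows <- which(rows)
  haplotype_panel(panel$legend,
                  panel$alleles[rows, , drop = FALSE],
                  panel$hap_ids[rows])
}

# sample names for a diploid panel: hap_ids "X_A"/"X_B" collapse to "X",
# otherwise synthesised as sample1..sampleN
sample_names <- function(panel) {
  n <- n_hap(panel)
  if (n %% 2L != 0L)
    stop_("panel has an odd number of haplotypes; not diploid samples")
  ids <- panel$hap_ids
  odd <- ids[seq(1L, n, by = 2L)]
  even <- ids[seq(2L, n, by = 2L)]
  base_o <- sub("_[AB]$", "", odd)
  base_e <- sub("_[AB]$", "", even)
  if (all(base_o == base_e) && !anyDuplicated(base_o)) base_o
  else paste0("sample", seq_len(n / 2L))
}

# truth diploid genotypes (0/1/2), samples x sites
diploid_genotypes <- function(panel) {
  n <- n_hap(panel)
  if (n %% 2L != 0L) stop_("panel has an odd number of haplotypes")
  odd <- seq(1L, n, by = 2L)
  panel$alleles[odd, , drop = FALSE] + panel$alleles[odd + 1L, , drop = FALSE]
}
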
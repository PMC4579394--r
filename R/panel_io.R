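#' Read phased haplotypes from a VCF file
#'
#' Reads a VCF 4.x file with phased GT fields into a
#' \code{\link{haplotype_panel}} with two haplotype rows per sample
#' (0 = REF, 1 = ALT), legend ordered by position.  Records must be
#' biallelic and every genotype phased; an unphased or missing genotype is
#' a hard error naming the offending record.
#'
#' @param path VCF file path (plain text or gzip).
#' @param region optional \code{c(start, end)} half-open bp interval; only
#'   records with \code{start <= POS < end} are kept.
#' @param drop_multiallelic if \code{TRUE}, multi-allelic records are
#'   skipped and counted (reported in the \code{"n_multiallelic"}
#'   attribute of the result) instead of raising an error.
#' @return a \code{haplotype_panel}.
#' @export
read_haplotypes_vcf <- function(path, region = NULL, drop_multiallelic = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx)))  # single-record VCFs come back as a bare vector
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_("VCF %s contains no records", path)
  fix$POS <- as.integer(fix$POS)
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) stop_("VCF %s has no genotype columns", path)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region))
    keep <- fix$POS >= region[1] & fix$POS < region[2]
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  n_multi <- sum(multi & keep)
  if (n_multi > 0L && !drop_multiallelic)
    stop_("multi-allelic or invalid ALT at %s:%s; set drop_multiallelic=TRUE to skip",
          fix$CHROM[multi & keep][1], fix$POS[multi & keep][1])
  keep <- keep & !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, -1L, drop = FALSE]
  if (nrow(fix) == 0L) stop_("no usable records in %s", path)
  # strip any trailing FORMAT fields, keep the GT token (grepl and friends
  # drop dim attributes, so restore them for arr.ind lookups)
  gtok <- sub(":.*$", "", gt)
  dim(gtok) <- dim(gt)
  colnames(gtok) <- colnames(gt)
  bad <- grepl("/", gtok)
  dim(bad) <- dim(gtok)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_("unphased genotype %s at %s:%d (sample %s)",
          gtok[bad][1], fix$CHROM[w[1]], fix$POS[w[1]], colnames(gt)[w[2]])
  }
  ok <- gtok %in% c("0|0", "0|1", "1|0", "1|1")
  dim(ok) <- dim(gtok)
  if (!all(ok)) {
    w <- which(!ok, arr.ind = TRUE)[1, ]
    stop_("missing or non-binary allele in genotype '%s' at %s:%d",
          gtok[!ok][1], fix$CHROM[w[1]], fix$POS[w[1]])
  }
  a1 <- matrix(as.integer(substr(gtok, 1L, 1L)), nrow = nrow(gtok))
  a2 <- matrix(as.integer(substr(gtok, 3L, 3L)), nrow = nrow(gtok))
  nsam <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * nsam, ncol = nrow(fix))
  alleles[seq(1L, 2L * nsam, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * nsam, by = 2L), ] <- t(a2)
  legend <- data.frame(chrom = fix$CHROM, pos = fix$POS,
                       id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                   paste0(fix$CHROM, ":", fix$POS), fix$ID),
                       ref = fix$REF, alt = fix$ALT,
                       stringsAsFactors = FALSE)
  ord <- order(legend$chrom, legend$pos)
  panel <- haplotype_panel(legend[ord, , drop = FALSE],
                           alleles[, ord, drop = FALSE],
                           paste0(rep(colnames(gt), each = 2L), c("_A", "_B")))
  attr(panel, "n_multiallelic") <- n_multi
  panel
}

#' Write a panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 file with one phased GT column per diploid
#' sample.  The panel must have an even number of haplotype rows.
#'
#' @param panel a \code{haplotype_panel}.
#' @param path output path; a \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
write_haplotypes_vcf <- function(panel, path) {
  sams <- sample_names(panel)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hapimpute",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sams), collapse = "\t")), con)
  n <- n_hap(panel)
  odd <- seq(1L, n, by = 2L)
  gt <- matrix(paste(panel$alleles[odd, , drop = FALSE],
                     panel$alleles[odd + 1L, , drop = FALSE], sep = "|"),
               nrow = length(odd))
  lg <- panel$legend
  left <- paste(lg$chrom, lg$pos, lg$id, lg$ref, lg$alt, ".", ".", ".", "GT",
                sep = "\t")
  body <- paste(left, apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read/write IMPUTE-style hap/legend/sample triplets
#'
#' The hap file is whitespace-separated 0/1 with one row per site and one
#' column per haplotype (site-major); the legend has a header line and
#' columns \code{id position a0 a1}; the sample file has the usual two
#' header lines followed by one row per sample.
#'
#' @param hap_path,legend_path paths to the hap and legend files (gzip ok).
#' @param sample_path optional sample file; if absent, samples are
#'   labelled \code{sample1..N}.
#' @param chrom chromosome label to attach (legend files carry none).
#' @return \code{read_hap_legend}: a \code{haplotype_panel}.
#' @export
read_hap_legend <- function(hap_path, legend_path, sample_path = NULL,
                            chrom = "20") {
  leg <- read.table(legend_path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(leg) < 4L)
    stop_("legend file needs at least 4 columns (id position a0 a1)")
  names(leg)[1:4] <- c("id", "position", "a0", "a1")
  hap <- as.matrix(read.table(hap_path, header = FALSE))
  if (nrow(hap) != nrow(leg))
    stop_("hap file has %d rows but legend has %d sites", nrow(hap), nrow(leg))
  if (!all(hap %in% 0:1))
    stop_("non-binary allele token in hap file")
  ids <- NULL
  if (!is.null(sample_path)) {
    sm <- read.table(sample_path, header = FALSE, stringsAsFactors = FALSE,
                     skip = 2L)
    if (nrow(sm) * 2L != ncol(hap))
      stop_("sample file lists %d samples but hap file has %d haplotype columns",
            nrow(sm), ncol(hap))
    ids <- paste0(rep(sm[[1L]], each = 2L), c("_A", "_B"))
  }
  legend <- data.frame(chrom = chrom, pos = as.integer(leg$position),
                       id = as.character(leg$id), ref = as.character(leg$a0),
                       alt = as.character(leg$a1), stringsAsFactors = FALSE)
  haplotype_panel(legend, t(hap), ids)
}

#' @rdname read_hap_legend
#' @param panel a \code{haplotype_panel} to write.
#' @param prefix output path prefix; files \code{<prefix>.hap},
#'   \code{<prefix>.legend}, \code{<prefix>.samples} are produced.
#' @return \code{write_hap_legend}: the three paths, invisibly.
#' @export
write_hap_legend <- function(panel, prefix) {
  hap_path <- paste0(prefix, ".hap")
  leg_path <- paste0(prefix, ".legend")
  sam_path <- paste0(prefix, ".samples")
  write.table(t(panel$alleles), hap_path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  leg <- data.frame(id = panel$legend$id, position = panel$legend$pos,
                    a0 = panel$legend$ref, a1 = panel$legend$alt)
  write.table(leg, leg_path, row.names = FALSE, quote = FALSE)
  sams <- sample_names(panel)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(sams, sams, "0")), sam_path)
  invisible(c(hap = hap_path, legend = leg_path, sample = sam_path))
}

#' Genetic map: monotone bp-to-cM mapping
#'
#' @param pos bp positions, strictly increasing.
#' @param cm cumulative genetic distance in cM, non-decreasing; at least
#'   two points.
#' @return an object of class \code{genetic_map}.
#' @export
genetic_map <- function(pos, cm) {
  pos <- as.numeric(pos); cm <- as.numeric(cm)
  if (length(pos) != length(cm) || length(pos) < 2L)
    stop_("genetic map needs at least 2 (pos, cM) points")
  if (any(diff(pos) <= 0)) stop_("map positions must be strictly increasing")
  if (any(diff(cm) < 0)) stop_("cumulative cM must be non-decreasing")
  structure(list(pos = pos, cm = cm), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d points, %g-%g bp, %.4g cM total\n",
              length(x$pos), min(x$pos), max(x$pos), max(x$cm) - min(x$cm)))
  invisible(x)
}

#' Read a 3-column genetic map file
#'
#' Expects a single header line and columns
#' \code{position rate(cM/Mb) cumulative_cM}; only columns 1 and 3 are
#' used.
#'
#' @param path map file path (gzip ok).
#' @return a \code{genetic_map}.
#' @export
read_genetic_map <- function(path) {
  m <- read.table(path, header = TRUE)
  if (ncol(m) < 3L) stop_("genetic map file needs 3 columns")
  genetic_map(m[[1L]], m[[3L]])
}

#' Uniform-rate genetic map over an interval
#'
#' @param start,end bp bounds.
#' @param rate recombination rate in cM/Mb (default 1).
#' @return a \code{genetic_map} with two points.
#' @export
uniform_map <- function(start, end, rate = 1) {
  genetic_map(c(start, end), c(0, (end - start) / 1e6 * rate))
}

#' Interpolate cumulative genetic distance at a position
#'
#' Linear interpolation between flanking map points; outside the mapped
#' range the nearest endpoint's cM is used (constant extrapolation, i.e.
#' local rate 0).
#'
#' @param map a \code{genetic_map}.
#' @param bp bp position(s).
#' @return cumulative cM, same length as \code{bp}.
#' @export
cm_at <- function(map, bp) {
  stopifnot(inherits(map, "genetic_map"))
  approx(map$pos, map$cm, xout = bp, rule = 2)$y
}

#' Plan buffered imputation chunks over a region
#'
#' Core intervals tile the half-open region \code{[start, end)} left to
#' right (the last core may be short); each buffered interval is the core
#' extended by \code{buffer} bp on both sides, clipped to the region
#' bounds.  Defaults follow the 3 Mb / 250 kb chunking used for
#' chromosome-scale imputation.
#'
#' @param start,end region bounds in bp, half-open.
#' @param chunk_size core chunk size in bp.
#' @param buffer flanking buffer in bp.
#' @return data.frame with columns \code{start,end,bstart,bend}, class
#'   \code{chunk_plan}.
#' @export
plan_chunks <- function(start, end, chunk_size = 3e6, buffer = 250e3) {
  if (end <= start) stop_("empty region [%g, %g)", start, end)
  if (chunk_size <= 0) stop_("chunk_size must be > 0")
  if (buffer < 0) stop_("buffer must be >= 0")
  s <- seq(start, end - 1, by = chunk_size)
  e <- pmin(s + chunk_size, end)
  out <- data.frame(start = s, end = e,
                    bstart = pmax(s - buffer, start),
                    bend = pmin(e + buffer, end))
  class(out) <- c("chunk_plan", "data.frame")
  out
}
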
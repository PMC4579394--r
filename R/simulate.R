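#' Configuration for the synthetic-panel generator
#'
#' Defaults define the package's standard experimental scenario: a 5 Mb
#' region with 5,000 segregating sites, a 400-haplotype primary reference
#' panel, a 200-haplotype secondary panel, 100 study haplotypes (50
#' diploid samples), and a pseudo-array typing ~12% of sites biased
#' towards MAF >= 5%, mimicking the common-variant content of genotyping
#' chips.  Haplotypes are copying mosaics of a founder pool, which
#' creates the linkage-disequilibrium structure the copying HMM exploits
#' without requiring a coalescent simulator.
#'
#' @param n_founders founder haplotype count.
#' @param n_sites number of variant sites.
#' @param region_bp region length in bp.
#' @param n_ref_a,n_ref_b,n_study haplotype counts of the two reference
#'   panels and the study truth set.
#' @param switch_rate expected template switches per cM in the mosaic
#'   copying process.
#' @param mut_rate per-site per-haplotype allele-flip probability.
#' @param typed_fraction fraction of sites placed on the pseudo-array.
#' @param typed_maf_floor preferred minimum MAF for typed sites.
#' @param private_fraction fraction of segregating sites made private to
#'   each reference panel (removed from the other panel's legend,
#'   disjointly).
#' @param n_singletons singletons planted per reference panel (at sites
#'   otherwise monomorphic) so that cross-panel singleton filtering is
#'   exercised.
#' @param map_rate genetic-map rate in cM/Mb (uniform map).
#' @param seed integer RNG seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_founders = 80, n_sites = 5000, region_bp = 5e6,
                       n_ref_a = 400, n_ref_b = 200, n_study = 100,
                       switch_rate = 1.0, mut_rate = 2e-4,
                       typed_fraction = 0.12, typed_maf_floor = 0.05,
                       private_fraction = 0.15, n_singletons = 5,
                       map_rate = 1, seed = 1) {
  cfg <- list(n_founders = n_founders, n_sites = n_sites,
              region_bp = region_bp, n_ref_a = n_ref_a, n_ref_b = n_ref_b,
              n_study = n_study, switch_rate = switch_rate,
              mut_rate = mut_rate, typed_fraction = typed_fraction,
              typed_maf_floor = typed_maf_floor,
              private_fraction = private_fraction,
              n_singletons = n_singletons, map_rate = map_rate, seed = seed)
  with(cfg, {
    stopifnot(n_founders >= 1, n_sites >= 1, region_bp >= 1,
              n_ref_a >= 1, n_ref_b >= 1, n_study >= 1,
              mut_rate >= 0, mut_rate <= 1, switch_rate >= 0,
              typed_fraction > 0, typed_fraction <= 1,
              private_fraction >= 0, private_fraction < 0.5)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a founder haplotype pool
#'
#' Sites are placed at uniform-random distinct positions; each site's
#' derived-allele frequency is drawn from a neutral-like spectrum with
#' density proportional to 1/f truncated to
#' [1/(2 n_founders), 0.5], and founder alleles are sampled independently
#' at that frequency.  Deterministic given the seed.
#'
#' @param n_founders number of founder haplotypes.
#' @param n_sites number of sites.
#' @param region_bp region length in bp.
#' @param seed RNG seed.
#' @param chrom chromosome label.
#' @return a \code{haplotype_panel}.
#' @export
simulate_founders <- function(n_founders, n_sites, region_bp, seed = 1,
                              chrom = "20") {
  if (n_sites > region_bp)
    stop_("cannot place %d distinct positions in %g bp", n_sites, region_bp)
  set.seed(seed)
  pos <- sort(sample.int(region_bp, n_sites))
  fmin <- 1 / (2 * n_founders)
  u <- runif(n_sites)
  f <- fmin * (0.5 / fmin)^u   # inverse-CDF sample of density 1/f on [fmin, .5]
  alleles <- matrix(rbinom(n_founders * n_sites, 1L, rep(f, each = n_founders)),
                    nrow = n_founders)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  legend <- data.frame(chrom = chrom, pos = pos,
                       id = paste0("var", seq_len(n_sites)),
                       ref = ref, alt = alt, stringsAsFactors = FALSE)
  haplotype_panel(legend, alleles, paste0("F", seq_len(n_founders)))
}

#' Simulate recombinant haplotypes as founder mosaics
#'
#' Each output haplotype copies a founder template; between consecutive
#' sites separated by \eqn{d} cM the template switches with probability
#' \eqn{1 - \exp(-switch\_rate \cdot d)} to a uniformly drawn founder,
#' and every emitted allele is flipped with probability \code{mut_rate}.
#' Deterministic given the seed.
#'
#' @param founders founder \code{haplotype_panel}.
#' @param n_haps number of mosaic haplotypes to generate.
#' @param switch_rate expected switches per cM.
#' @param mut_rate per-site flip probability.
#' @param map a \code{genetic_map} (default uniform 1 cM/Mb over the
#'   founder region).
#' @param seed RNG seed.
#' @param hap_ids optional haplotype identifiers.
#' @return a \code{haplotype_panel} sharing the founder legend.
#' @export
simulate_mosaic <- function(founders, n_haps, switch_rate = 1,
                            mut_rate = 0, map = NULL, seed = 1,
                            hap_ids = NULL) {
  if (n_hap(founders) < 1L) stop_("founder panel is empty")
  set.seed(seed)
  S <- n_site(founders)
  if (is.null(map))
    map <- uniform_map(1, max(founders$legend$pos) + 1)
  cm <- cm_at(map, founders$legend$pos)
  p_switch <- 1 - exp(-switch_rate * diff(cm))
  nf <- n_hap(founders)
  out <- matrix(0L, nrow = n_haps, ncol = S)
  for (h in seq_len(n_haps)) {
    sw <- c(TRUE, runif(S - 1) < p_switch)
    seg <- cumsum(sw)
    tpl <- sample.int(nf, max(seg), replace = TRUE)[seg]
    hap <- founders$alleles[cbind(tpl, seq_len(S))]
    if (mut_rate > 0) {
      flip <- runif(S) < mut_rate
      hap[flip] <- 1L - hap[flip]
    }
    out[h, ] <- hap
  }
  haplotype_panel(founders$legend, out, hap_ids)
}

#' Generate a full two-panel imputation scenario
#'
#' Builds founder haplotypes, derives two reference panels and a study
#' truth panel as independent mosaic sets, restricts all panels to sites
#' segregating in the combined references, plants per-panel singletons,
#' removes disjoint fractions of sites from each reference legend to
#' create panel-private variants, and draws an array-like typed mask
#' biased towards common shared variants.  Everything is a pure function
#' of the configuration (bit-identical reruns).
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{sim_scenario}: list with
#'   \code{ref_a}, \code{ref_b}, \code{study_truth}
#'   (\code{haplotype_panel}s), \code{typed_mask} (logical over study
#'   sites), \code{map}, \code{site_sets} (positions private to a,
#'   private to b, shared), and \code{config}.
#' @export
make_scenario <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 5L)
  founders <- simulate_founders(config$n_founders, config$n_sites,
                                config$region_bp, seed = seeds[1])
  map <- uniform_map(1, config$region_bp, rate = config$map_rate)
  ref_a <- simulate_mosaic(founders, config$n_ref_a, config$switch_rate,
                           config$mut_rate, map, seed = seeds[2])
  ref_b <- simulate_mosaic(founders, config$n_ref_b, config$switch_rate,
                           config$mut_rate, map, seed = seeds[3])
  study <- simulate_mosaic(founders, config$n_study, config$switch_rate,
                           config$mut_rate, map, seed = seeds[4])
  set.seed(seeds[5])

  # plant singletons at sites monomorphic in the combined references
  comb_af <- (colSums(ref_a$alleles) + colSums(ref_b$alleles)) /
             (n_hap(ref_a) + n_hap(ref_b))
  mono <- which(comb_af == 0 | comb_af == 1)
  sample_vec <- function(x, n) x[sample.int(length(x), n)]
  planted_a <- planted_b <- integer(0)
  ns <- config$n_singletons
  if (ns > 0 && length(mono) >= 2 * ns) {
    pick <- sample_vec(mono, 2L * as.integer(ns))
    planted_a <- pick[seq_len(ns)]
    planted_b <- pick[ns + seq_len(ns)]
    for (j in planted_a) {
      h <- sample.int(n_hap(ref_a), 1L)
      ref_a$alleles[h, j] <- 1L - ref_a$alleles[h, j]
    }
    for (j in planted_b) {
      h <- sample.int(n_hap(ref_b), 1L)
      ref_b$alleles[h, j] <- 1L - ref_b$alleles[h, j]
    }
  }

  # keep only sites segregating in the combined reference material
  comb_af <- (colSums(ref_a$alleles) + colSums(ref_b$alleles)) /
             (n_hap(ref_a) + n_hap(ref_b))
  seg <- which(comb_af > 0 & comb_af < 1)
  ref_a <- restrict_sites(ref_a, seg)
  ref_b <- restrict_sites(ref_b, seg)
  study <- restrict_sites(study, seg)
  remap <- function(i) match(i, seg)
  planted_a <- remap(planted_a); planted_a <- planted_a[!is.na(planted_a)]
  planted_b <- remap(planted_b); planted_b <- planted_b[!is.na(planted_b)]
  n_seg <- length(seg)

  # carve disjoint private site sets; planted singletons stay private to
  # their own panel
  n_priv <- round(config$private_fraction * n_seg)
  if (2 * n_priv >= n_seg)
    stop_("private_fraction leaves no shared sites")
  drop_from_b <- drop_from_a <- integer(0)
  if (n_priv > 0) {
    pool <- setdiff(seq_len(n_seg), c(planted_a, planted_b))
    extra_b <- sample_vec(pool, max(0L, n_priv - length(planted_a)))
    drop_from_b <- sort(c(planted_a, extra_b))          # a-private sites
    pool2 <- setdiff(pool, extra_b)
    extra_a <- sample_vec(setdiff(pool2, planted_b),
                          max(0L, n_priv - length(planted_b)))
    drop_from_a <- sort(c(planted_b, extra_a))          # b-private sites
  }  # private_fraction = 0: both legends keep every segregating site
  keep_a <- setdiff(seq_len(n_seg), drop_from_a)
  keep_b <- setdiff(seq_len(n_seg), drop_from_b)
  pos <- study$legend$pos
  site_sets <- list(a_only = pos[drop_from_b], b_only = pos[drop_from_a],
                    shared = pos[intersect(keep_a, keep_b)])
  ref_a_out <- restrict_sites(ref_a, keep_a)
  ref_b_out <- restrict_sites(ref_b, keep_b)

  # pseudo-array: typed sites drawn from shared, preferring MAF >= floor
  shared_idx <- intersect(keep_a, keep_b)
  study_maf <- panel_maf(study)
  n_typed <- max(1L, round(config$typed_fraction * n_seg))
  common <- shared_idx[study_maf[shared_idx] >= config$typed_maf_floor]
  if (length(common) >= n_typed) {
    typed <- sample_vec(common, n_typed)
  } else {
    rest <- setdiff(shared_idx, common)
    typed <- c(common, sample_vec(rest, min(length(rest),
                                            n_typed - length(common))))
  }
  typed_mask <- rep(FALSE, n_seg)
  typed_mask[typed] <- TRUE

  structure(list(ref_a = ref_a_out, ref_b = ref_b_out, study_truth = study,
                 typed_mask = typed_mask, map = map, site_sets = site_sets,
                 config = config),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario: %d segregating sites, %d typed\n",
              n_site(x$study_truth), sum(x$typed_mask)))
  cat(sprintf("  ref_a %d haps x %d sites; ref_b %d x %d; study %d x %d\n",
              n_hap(x$ref_a), n_site(x$ref_a), n_hap(x$ref_b),
              n_site(x$ref_b), n_hap(x$study_truth), n_site(x$study_truth)))
  cat(sprintf("  private: a_only=%d b_only=%d shared=%d\n",
              length(x$site_sets$a_only), length(x$site_sets$b_only),
              length(x$site_sets$shared)))
  invisible(x)
}
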
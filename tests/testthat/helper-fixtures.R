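# Shared fixtures and independent oracles for the test suite.

# small deterministic panel: n_haps x n_sites with seeded random alleles
toy_panel <- function(n_haps = 6, n_sites = 10, seed = 1, chrom = "20",
                      start = 100L, step = 100L) {
  set.seed(seed)
  pos <- start + step * (seq_len(n_sites) - 1L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  legend <- data.frame(chrom = chrom, pos = pos,
                       id = paste0("rs", seq_len(n_sites)),
                       ref = ref, alt = alt, stringsAsFactors = FALSE)
  alleles <- matrix(rbinom(n_haps * n_sites, 1L, 0.4), nrow = n_haps)
  haplotype_panel(legend, alleles)
}

# exhaustive-path oracle for the copying-HMM posterior: sums the joint
# probability of every one of the K^T copying paths.  Independent of the
# forward-backward implementation.
brute_force_gamma <- function(obs, refs, dists, Ne, eps) {
  K <- nrow(refs); T_ <- ncol(refs)
  rho <- 4 * Ne * dists / 100
  stay <- exp(-rho / K)
  sw <- (1 - stay) / K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  g <- matrix(0, T_, K)
  for (i in seq_len(nrow(paths))) {
    pth <- paths[i, ]
    pr <- 1 / K
    if (T_ > 1)
      for (t in 2:T_)
        pr <- pr * (if (pth[t] == pth[t - 1]) stay[t - 1] + sw[t - 1]
                    else sw[t - 1])
    for (t in seq_len(T_))
      pr <- pr * (if (refs[pth[t], t] == obs[t]) 1 - eps else eps)
    for (t in seq_len(T_))
      g[t, pth[t]] <- g[t, pth[t]] + pr
  }
  g / rowSums(g)
}

# oracle P(ALT) at every panel site from the brute-force posterior plus the
# documented interpolation/emission rules, written independently of
# impute_haploid
brute_force_impute <- function(study_typed, panel, typed_idx, map, Ne, eps,
                               selection) {
  refs <- panel$alleles[selection, , drop = FALSE]
  cm <- cm_at(map, panel$legend$pos)
  g <- brute_force_gamma(study_typed, refs[, typed_idx, drop = FALSE],
                         diff(cm[typed_idx]), Ne, eps)
  T_ <- length(typed_idx)
  sapply(seq_len(n_site(panel)), function(s) {
    if (s %in% typed_idx) {
      row <- g[match(s, typed_idx), ]
    } else if (s < typed_idx[1]) {
      row <- g[1, ]
    } else if (s > typed_idx[T_]) {
      row <- g[T_, ]
    } else {
      lo <- max(which(typed_idx < s))
      hi <- lo + 1
      c0 <- cm[typed_idx[lo]]; c1 <- cm[typed_idx[hi]]
      w <- if (c1 > c0) (cm[s] - c0) / (c1 - c0) else 0.5
      row <- (1 - w) * g[lo, ] + w * g[hi, ]
    }
    a <- refs[, s]
    sum(row * ((1 - eps) * a + eps * (1 - a)))
  })
}

# write a VCF fixture from raw lines
write_vcf_lines <- function(records, samples, path) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}

quick_scenario <- function(seed = 5, ...) {
  make_scenario(sim_config(n_sites = 800, region_bp = 8e5, n_ref_a = 60,
                           n_ref_b = 40, n_study = 24, seed = seed, ...))
}
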
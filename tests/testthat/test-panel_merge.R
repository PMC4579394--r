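make_raw_panel <- function(pos, ref, alt, alleles, chrom = "20") {
  legend <- data.frame(chrom = chrom, pos = as.integer(pos),
                       id = paste0("v", seq_along(pos)), ref = ref,
                       alt = alt, stringsAsFactors = FALSE)
  haplotype_panel(legend, alleles)
}

test_that("harmonize accounts for singletons, duplicates and mismatches", {
  # panel A: site 10 shared, site 20 a private singleton, site 30 a
  # duplicated (multi-allelic) position
  pa <- make_raw_panel(c(10, 20), c("A", "A"), c("C", "T"),
                       rbind(c(0L, 1L), c(1L, 0L), c(0L, 0L), c(1L, 0L)))
  dup <- data.frame(chrom = "20", pos = 30L, id = "v3", ref = "A",
                    alt = "G", vclass = "SNP", stringsAsFactors = FALSE)
  pa$legend <- rbind(pa$legend, dup, dup)
  pa$alleles <- cbind(pa$alleles, 0L, 1L)
  # panel B: site 10 shared, site 40 private with minor count 2 (kept)
  pb <- make_raw_panel(c(10, 40), c("A", "G"), c("C", "T"),
                       rbind(c(0L, 1L), c(1L, 1L), c(0L, 0L), c(1L, 0L)))
  h <- harmonize(pa, pb)
  expect_equal(h$panel_a$legend$pos, 10L)
  expect_equal(h$panel_b$legend$pos, c(10L, 40L))
  r <- h$report
  expect_equal(r$n_input_a, 4L)
  expect_equal(r$n_multiallelic_a, 1L)
  expect_equal(r$n_private_singletons_a, 1L)
  expect_equal(r$n_mismatch, 0L)
  expect_equal(r$n_kept_a, 1L)
  expect_equal(r$n_kept_b, 2L)
})

test_that("identical panels pass harmonization untouched", {
  p <- toy_panel(6, 12, seed = 2)
  h <- harmonize(p, p)
  expect_identical(h$panel_a$alleles, p$alleles)
  expect_identical(h$panel_b$alleles, p$alleles)
  expect_equal(h$report$n_kept_a, 12L)
  expect_equal(h$report$n_mismatch, 0L)
})

test_that("allele swaps are resolved by flipping, mismatches removed", {
  pa <- make_raw_panel(c(10, 20), c("A", "C"), c("C", "G"),
                       rbind(c(0L, 1L), c(1L, 0L)))
  pb <- make_raw_panel(c(10, 20), c("C", "C"), c("A", "T"),
                       rbind(c(1L, 1L), c(0L, 0L)))
  h <- harmonize(pa, pb)
  # site 10: REF/ALT exchanged in B; codes flipped, site retained
  expect_equal(h$report$n_swapped, 1L)
  expect_equal(h$report$n_mismatch, 1L)
  expect_equal(h$panel_a$legend$pos, 10L)
  expect_equal(h$panel_b$legend$pos, 10L)
  expect_equal(h$panel_b$legend$ref, "A")
  expect_equal(as.vector(h$panel_b$alleles), c(0L, 1L))
})

test_that("site-count arithmetic reproduces panel accounting worked examples", {
  expect_identical(sites_after_filtering(45492035,
                                         c(18180633, 1064168, 214631)),
                   26032603L)
  expect_equal(union_count(26032603, 32449428, 16122337), 42359694)
  expect_equal(union_count(0, 0, 0), 0)
  expect_equal(union_count(5, 7, 0), 12)
  expect_error(union_count(5, 7, 6), "overlap")
  expect_error(sites_after_filtering(10, c(7, 5)), "exceed")
})

test_that("cross-imputation copies a perfectly matching donor haplotype", {
  donor <- toy_panel(8, 40, seed = 12)
  add_idx <- c(5L, 13L, 22L, 31L)
  shared_idx <- setdiff(seq_len(40), add_idx)
  # build a 2-haplotype target from donor haplotypes restricted to shared
  target <- restrict_sites(keep_haplotypes(donor, 1:2), shared_idx)
  add <- donor$legend$pos[add_idx]
  map <- uniform_map(1, 5000)
  out <- cross_impute(target, donor, add, map,
                      hmm_params(epsilon = 1e-6),
                      selection_spec("all"))
  expect_equal(sort(out$legend$pos), out$legend$pos)
  madd <- match(add, out$legend$pos)
  dadd <- match(add, donor$legend$pos)
  expect_equal(out$alleles[1, madd], donor$alleles[1, dadd])
  expect_equal(out$alleles[2, madd], donor$alleles[2, dadd])
  # observed alleles preserved
  expect_identical(out$alleles[, match(target$legend$pos, out$legend$pos)],
                   target$alleles)
  # empty site list is the identity
  expect_identical(cross_impute(target, donor, integer(0), map), target)
})

test_that("cross-imputation equals the brute-force HMM oracle", {
  # 3-haplotype donor over 6 sites, 2-haplotype target on 4 shared sites
  donor <- toy_panel(3, 6, seed = 33)
  shared_idx <- c(1L, 3L, 4L, 6L)
  private_idx <- c(2L, 5L)
  target <- restrict_sites(donor, shared_idx)
  target <- keep_haplotypes(target, 1:2)
  target$alleles[1, 2] <- 1L - target$alleles[1, 2]
  map <- uniform_map(1, 1000)
  eps <- 0.05
  out <- cross_impute(target, donor, donor$legend$pos[private_idx], map,
                      hmm_params(Ne = 5000, epsilon = eps),
                      selection_spec("all"))
  for (h in 1:2) {
    want <- brute_force_impute(target$alleles[h, ], donor, shared_idx,
                               map, 5000, eps, 1:3)
    af <- alt_freq(donor)
    want[af == 0] <- 0; want[af == 1] <- 1
    got <- out$alleles[h, match(donor$legend$pos[private_idx],
                                out$legend$pos)]
    expect_identical(got, as.integer(want[private_idx] > 0.5))
  }
})

test_that("self-merge duplicates haplotypes and leaves the legend fixed", {
  p <- toy_panel(6, 15, seed = 14)
  m <- merge_panels(p, p, uniform_map(1, 2000))
  expect_equal(m$report$n_a_only, 0L)
  expect_equal(m$report$n_b_only, 0L)
  expect_equal(m$report$n_shared, 15L)
  expect_equal(n_hap(m$panel), 12L)
  expect_identical(m$panel$legend$pos, p$legend$pos)
  expect_identical(m$panel$alleles[1:6, ], p$alleles)
  expect_identical(m$panel$alleles[7:12, ], p$alleles)
})

test_that("panels without shared sites cannot be merged", {
  pa <- make_raw_panel(c(10, 20), c("A", "A"), c("C", "C"),
                       matrix(c(0L, 1L, 1L, 0L), 2))
  pb <- make_raw_panel(c(30, 40), c("A", "A"), c("C", "C"),
                       matrix(c(0L, 1L, 1L, 0L), 2))
  expect_error(merge_panels(pa, pb, uniform_map(1, 100)), "no sites")
})

test_that("merging a scenario preserves both panels exactly", {
  sc <- quick_scenario(seed = 15)
  m <- merge_panels(sc$ref_a, sc$ref_b, sc$map,
                    spec = selection_spec("hamming", k = 30))
  merged <- m$panel
  r <- m$report
  expect_equal(r$n_union, r$n_a_only + r$n_b_only + r$n_shared)
  expect_equal(r$n_union, r$n_kept_a + r$n_kept_b - r$n_shared)
  expect_equal(r$n_union, n_site(merged))
  # restriction oracle: panel A's rows and sites are bit-identical
  ha <- harmonize(sc$ref_a, sc$ref_b)
  ia <- match(ha$panel_a$legend$pos, merged$legend$pos)
  expect_identical(merged$alleles[seq_len(n_hap(sc$ref_a)), ia],
                   ha$panel_a$alleles)
  ib <- match(ha$panel_b$legend$pos, merged$legend$pos)
  expect_identical(merged$alleles[n_hap(sc$ref_a) + seq_len(n_hap(sc$ref_b)), ib],
                   ha$panel_b$alleles)
  # class breakdown sums to the union
  expect_equal(sum(m$report$class_breakdown["union", ]), r$n_union)
})
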
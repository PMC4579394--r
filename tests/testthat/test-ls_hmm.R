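test_that("Watterson theta and derived emission error match closed forms", {
  expect_equal(theta_watterson(2), 1)
  expect_equal(theta_watterson(3), 2 / 3)
  expect_error(theta_watterson(1), "at least two")
  expect_equal(emission_epsilon(2), 1 / 6)
  expect_equal(emission_epsilon(3), 1 / 11)
  eps <- vapply(2:1000, emission_epsilon, numeric(1))
  expect_true(all(diff(eps) < 0))
  expect_true(all(eps > 0 & eps < 0.5))
})

test_that("transition probabilities follow the exp(-rho/K) form", {
  t0 <- transition(0, 20000, 50)
  expect_equal(t0$p_norecomb, 1)
  expect_equal(t0$p_switch_each, 0)
  tr <- transition(0.01, 20000, 100)
  expect_equal(tr$p_norecomb, exp(-0.08), tolerance = 1e-12)
  expect_equal(100 * tr$p_switch_each, 1 - exp(-0.08), tolerance = 1e-12)
  # stationary limit: switching mass approaches uniform
  tbig <- transition(1e6, 20000, 10)
  expect_equal(tbig$p_switch_each, 1 / 10, tolerance = 1e-9)
  expect_error(transition(-1, 20000, 10), "non-negative")
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(101)
  worst <- 0
  for (r in 1:40) {
    K <- sample(2:3, 1); T_ <- sample(1:4, 1)
    refs <- matrix(rbinom(K * T_, 1, 0.5), K, T_)
    obs <- rbinom(T_, 1, 0.5)
    dists <- if (T_ > 1) runif(T_ - 1, 0.001, 0.3) else numeric(0)
    eps <- runif(1, 0.01, 0.4)
    g <- forward_backward(obs, refs, dists,
                          hmm_params(Ne = 20000, epsilon = eps))
    g0 <- brute_force_gamma(obs, refs, dists, 20000, eps)
    worst <- max(worst, max(abs(g - g0)))
    expect_equal(rowSums(g), rep(1, T_), tolerance = 1e-9)
    expect_true(all(g >= 0))
  }
  expect_lt(worst, 1e-10)
})

test_that("posterior mass concentrates on the matching reference", {
  refs <- rbind(c(0, 1, 1), c(1, 0, 0))
  g <- forward_backward(c(0, 1, 1), refs, c(0.05, 0.05), hmm_params())
  expect_true(all(g[, 1] > 0.5))
})

test_that("uninformative emissions give a uniform posterior", {
  refs <- matrix(rbinom(12, 1, 0.5), 3, 4)
  g <- forward_backward(c(1, 0, 1, 0), refs, rep(0.1, 3),
                        hmm_params(epsilon = 0.5))
  expect_equal(g, matrix(1 / 3, 4, 3), tolerance = 1e-12)
})

test_that("site-reversed problems give reversed posteriors", {
  set.seed(55)
  for (r in 1:10) {
    K <- sample(2:6, 1); T_ <- sample(3:12, 1)
    refs <- matrix(rbinom(K * T_, 1, 0.5), K, T_)
    obs <- rbinom(T_, 1, 0.5)
    dists <- runif(T_ - 1, 0.001, 0.5)
    g <- forward_backward(obs, refs, dists, hmm_params())
    gr <- forward_backward(rev(obs), refs[, T_:1, drop = FALSE],
                           rev(dists), hmm_params())
    expect_equal(gr, g[T_:1, , drop = FALSE], tolerance = 1e-9)
  }
})

test_that("impute_haploid matches the brute-force oracle end to end", {
  p <- toy_panel(3, 6, seed = 21)   # 3 references
  map <- uniform_map(1, 1000)
  typed_idx <- c(2L, 4L, 5L)
  study <- p$alleles[1, typed_idx]
  study[2] <- 1L - study[2]
  params <- hmm_params(Ne = 5000, epsilon = 0.05)
  got <- impute_haploid(study, p, typed_idx, map, params, 1:3)
  want <- brute_force_impute(study, p, typed_idx, map, 5000, 0.05, 1:3)
  af <- alt_freq(p)
  want[af == 0] <- 0; want[af == 1] <- 1   # monomorphic bypass
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("a perfect copy of a reference is reproduced at untyped sites", {
  panel <- toy_panel(12, 60, seed = 6)
  typed_idx <- seq(1L, 60L, by = 2L)
  study <- panel$alleles[5, typed_idx]
  # the typed profile of haplotype 5 is unique in this panel, so the
  # posterior must concentrate on it
  matches <- apply(panel$alleles[, typed_idx], 1, function(h)
    all(h == study))
  expect_equal(which(matches), 5L)
  # tight linkage (small Ne) so recombinant copying paths are negligible
  # and the copy limit is clean
  params <- hmm_params(Ne = 100, epsilon = 1e-6)
  p <- impute_haploid(study, panel, typed_idx, uniform_map(1, 7000),
                      params, seq_len(n_hap(panel)))
  expect_true(all(abs(p - panel$alleles[5, ]) < 1e-3))
})

test_that("unanimous ALT among selected references yields 1 - epsilon", {
  leg <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                    id = c("a", "b", "c"), ref = "A", alt = "C")
  # site 2 is untyped; selected refs 1-2 both carry ALT there, ref 3 does
  # not (so the panel is polymorphic and no bypass applies)
  alleles <- rbind(c(0L, 1L, 1L), c(1L, 1L, 0L), c(0L, 0L, 1L))
  p <- haplotype_panel(leg, alleles, paste0("H", 1:3))
  eps <- 0.01
  post <- impute_haploid(c(0L, 1L), p, c(1L, 3L), uniform_map(1, 400),
                         hmm_params(epsilon = eps), selection = 1:2)
  expect_equal(post[2], 1 - eps, tolerance = 1e-12)
})

test_that("more typed mismatches cannot increase untyped accuracy", {
  # study = reference haplotype with 1 vs 2 flipped typed alleles: the
  # average probability of the correct allele at untyped sites must not
  # increase with the extra error
  set.seed(77)
  diffs <- replicate(50, {
    f <- simulate_founders(6, 60, 6e4, seed = sample.int(1e6, 1))
    panel <- simulate_mosaic(f, 8, switch_rate = 1, mut_rate = 0,
                             seed = sample.int(1e6, 1))
    map <- uniform_map(1, 6e4)
    typed_idx <- sort(sample(seq_len(60), 20))
    untyped <- setdiff(seq_len(60), typed_idx)
    base <- panel$alleles[1, ]
    flips <- sample(seq_along(typed_idx), 2)
    s1 <- base[typed_idx]; s1[flips[1]] <- 1L - s1[flips[1]]
    s2 <- s1; s2[flips[2]] <- 1L - s2[flips[2]]
    params <- hmm_params()
    p1 <- impute_haploid(s1, panel, typed_idx, map, params)
    p2 <- impute_haploid(s2, panel, typed_idx, map, params)
    acc <- function(p) mean(ifelse(base[untyped] == 1, p[untyped],
                                   1 - p[untyped]))
    acc(p1) - acc(p2)
  })
  expect_gte(mean(diffs), 0)
})

test_that("diploid combination and best-guess follow their closed forms", {
  d <- impute_diploid(c(0, 0.5, 0.1), c(0, 0.5, 0.7))
  expect_equal(d$p0, c(1, 0.25, 0.27))
  expect_equal(d$p1, c(0, 0.5, 0.66))
  expect_equal(d$p2, c(0, 0.25, 0.07))
  expect_equal(d$dosage, c(0, 1, 0.8))
  expect_equal(d$p0 + d$p1 + d$p2, rep(1, 3), tolerance = 1e-12)
  expect_error(impute_diploid(c(0, 1.2), c(0, 0)), "0, 1")
  expect_error(impute_diploid(c(0, 1), c(0)), "length")
  expect_identical(best_guess(c(0.9, 0.1, 0.5, 0.500001)),
                   c(1L, 0L, 0L, 1L))
})
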
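#' Li-Stephens HMM parameters
#'
#' Parameters of the haplotype-copying model.  The recombination intensity
#' over a gap of \eqn{d} cM between typed sites is
#' \eqn{\rho = 4 N_e d / 100}, and the probability of staying on the
#' current template is \eqn{\exp(-\rho/K)} for \eqn{K} conditioning
#' haplotypes; otherwise the template switches to a uniformly chosen one.
#' The copying-error (emission) probability \eqn{\epsilon} is derived from
#' the Watterson mutation parameter for the \emph{selected} K unless
#' overridden.
#'
#' @param Ne effective population size (default 20000, the value used for
#'   chromosome-scale human imputation).
#' @param epsilon optional fixed copying-error probability in [0, 0.5];
#'   \code{NULL} derives it from K at run time via
#'   \code{\link{emission_epsilon}} (0.5 makes emissions uninformative and
#'   is only useful for degenerate checks).
#' @return an object of class \code{hmm_params}.
#' @export
hmm_params <- function(Ne = 20000, epsilon = NULL) {
  if (Ne <= 0) stop_("Ne must be positive")
  if (!is.null(epsilon) && (epsilon < 0 || epsilon > 0.5))
    stop_("epsilon must be in [0, 0.5]")
  structure(list(Ne = Ne, epsilon = epsilon), class = "hmm_params")
}

#' Watterson mutation parameter and derived emission error
#'
#' \code{theta_watterson(K)} returns
#' \eqn{\theta = 1 / \sum_{i=1}^{K-1} 1/i}; \code{emission_epsilon(K)}
#' returns the per-site copying-error probability
#' \eqn{\epsilon = \theta / (2(\theta + K))}, so that the emitted allele
#' equals the copied allele with probability \eqn{1-\epsilon}.
#'
#' @param K number of conditioning reference haplotypes (>= 2).
#' @return a scalar.
#' @examples
#' theta_watterson(2)   # 1
#' emission_epsilon(2)  # 1/6
#' @export
theta_watterson <- function(K) {
  if (K < 2) stop_("need at least two reference haplotypes")
  1 / sum(1 / seq_len(K - 1))
}

#' @rdname theta_watterson
#' @export
emission_epsilon <- function(K) {
  th <- theta_watterson(K)
  th / (2 * (th + K))
}

#' Copying-template transition probabilities over a genetic distance
#'
#' @param d_cM genetic distance(s) in cM, >= 0.
#' @param Ne effective population size.
#' @param K number of conditioning haplotypes.
#' @return list with \code{p_norecomb} (probability of keeping the current
#'   template) and \code{p_switch_each} (probability of switching to one
#'   specific other template); the full transition to state j adds
#'   \code{p_norecomb} when j is the current state.
#' @export
transition <- function(d_cM, Ne, K) {
  if (any(d_cM < 0)) stop_("genetic distance must be non-negative")
  rho <- 4 * Ne * (d_cM / 100)
  p_norecomb <- exp(-rho / K)
  list(p_norecomb = p_norecomb, p_switch_each = (1 - p_norecomb) / K)
}

#' Posterior copying probabilities at typed sites
#'
#' Exact forward-backward posteriors of the copying template under the
#' Li-Stephens HMM, numerically stabilised by per-site normalisation.
#'
#' @param obs 0/1 study alleles at the T typed sites.
#' @param refs K x T 0/1 reference alleles at the same sites.
#' @param dists length T-1 genetic gaps between consecutive typed sites,
#'   in cM.
#' @param params an \code{\link{hmm_params}} object.
#' @return T x K matrix of posterior copying probabilities (rows sum to 1).
#' @export
forward_backward <- function(obs, refs, dists, params = hmm_params()) {
  refs <- as.matrix(refs)
  storage.mode(refs) <- "integer"
  K <- nrow(refs); T_ <- ncol(refs)
  if (K < 2) stop_("need at least two reference haplotypes")
  if (length(obs) != T_) stop_("obs length %d does not match %d typed sites",
                               length(obs), T_)
  if (length(dists) != T_ - 1) stop_("dists must have length T-1")
  if (any(dists < 0)) stop_("genetic distances must be non-negative")
  eps <- params$epsilon %||% emission_epsilon(K)
  ls_forward_backward(as.integer(obs), refs, 4 * params$Ne * (dists / 100), eps)
}

#' Impute one phased haplotype at all panel sites
#'
#' Runs the copying HMM on the typed sites and returns \eqn{P(ALT)} at
#' every site of the reference panel.  At a typed site the posterior
#' copying probabilities are mixed with the reference alleles through the
#' emission model; at an untyped site the state probabilities are linearly
#' interpolated on genetic distance between the flanking typed sites
#' (nearest row beyond the first/last typed site).  Sites monomorphic in
#' the full reference panel bypass the HMM and take the panel allele
#' frequency (0 or 1).
#'
#' @param study_typed 0/1 study alleles at the typed sites, in panel order.
#' @param panel reference \code{haplotype_panel}.
#' @param typed_mask logical mask over panel sites marking the typed ones.
#' @param map a \code{genetic_map}.
#' @param params an \code{hmm_params}.
#' @param selection integer indices of the conditioning reference
#'   haplotypes (e.g. from \code{\link{select_references}}); default all.
#' @return numeric vector of \eqn{P(ALT)} over all panel sites.
#' @export
impute_haploid <- function(study_typed, panel, typed_mask, map,
                           params = hmm_params(),
                           selection = seq_len(n_hap(panel))) {
  if (is.logical(typed_mask)) {
    if (length(typed_mask) != n_site(panel))
      stop_("typed_mask length does not match panel sites")
    typed_idx <- which(typed_mask)
  } else typed_idx <- as.integer(typed_mask)
  if (length(typed_idx) == 0L) stop_("no typed sites")
  if (length(study_typed) != length(typed_idx))
    stop_("study haplotype has %d alleles but %d typed sites",
          length(study_typed), length(typed_idx))
  if (length(selection) < 2L) stop_("need at least two reference haplotypes")
  refs <- panel$alleles[selection, , drop = FALSE]
  K <- nrow(refs)
  eps <- params$epsilon %||% emission_epsilon(K)
  cm <- cm_at(map, panel$legend$pos)
  dists <- diff(cm[typed_idx])
  gamma <- ls_forward_backward(as.integer(study_typed),
                               refs[, typed_idx, drop = FALSE],
                               4 * params$Ne * (dists / 100), eps)
  p <- ls_impute_alleles(gamma, refs, as.integer(typed_idx), cm, eps)
  af <- alt_freq(panel)
  p[af == 0] <- 0
  p[af == 1] <- 1
  p
}

#' Combine two haploid posteriors into diploid genotype calls
#'
#' With \eqn{a = P(ALT)} on the first haplotype and \eqn{b} on the second
#' (pre-phased, treated independently): \eqn{p_2 = ab},
#' \eqn{p_0 = (1-a)(1-b)}, \eqn{p_1 = 1 - p_0 - p_2}; the dosage is
#' \eqn{a + b}.
#'
#' @param hapA_post,hapB_post numeric vectors of \eqn{P(ALT)} in [0, 1].
#' @return data.frame with columns \code{p0, p1, p2, dosage}.
#' @export
impute_diploid <- function(hapA_post, hapB_post) {
  if (length(hapA_post) != length(hapB_post))
    stop_("haploid posterior vectors differ in length")
  if (any(hapA_post < 0 | hapA_post > 1 | hapB_post < 0 | hapB_post > 1))
    stop_("posteriors must lie in [0, 1]")
  p2 <- hapA_post * hapB_post
  p0 <- (1 - hapA_post) * (1 - hapB_post)
  p1 <- 1 - p0 - p2
  data.frame(p0 = p0, p1 = p1, p2 = p2, dosage = hapA_post + hapB_post)
}

#' Best-guess allele from a haploid posterior
#'
#' @param posterior \eqn{P(ALT)} value(s) in [0, 1].
#' @return 0/1 integer vector; a posterior of exactly 0.5 resolves to the
#'   reference allele (0).
#' @export
best_guess <- function(posterior) {
  if (any(posterior < 0 | posterior > 1)) stop_("posterior outside [0, 1]")
  as.integer(posterior > 0.5)
}
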
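# Nucleotide-model likelihood engine: GTR exchangeabilities, discrete-
# gamma rate variation (mean-of-quantile discretization) and site
# log-likelihoods by pruning.

#' GTR instantaneous rate matrix
#'
#' @param rates exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (all > 0; GT is conventionally the reference)
#' @param pi base frequencies (A, C, G, T), summing to 1
#' @param normalize scale to 1 expected substitution per site per unit time
#' @return 4 x 4 rate matrix
#' @export
gtr_rate_matrix <- function(rates = rep(1, 6), pi = rep(0.25, 4),
                            normalize = TRUE) {
  if (length(rates) != 6L || any(rates <= 0))
    stop("rates must be 6 positive exchangeabilities")
  if (length(pi) != 4L || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be 4 frequencies summing to 1")
  Q <- matrix(0, 4L, 4L, dimnames = list(.NUC, .NUC))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    Q[i, j] <- rates[k] * pi[j]
    Q[j, i] <- rates[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

#' Discrete-gamma rate categories (mean of quantile bins)
#'
#' Equal-probability categories whose rates are the within-bin means of a
#' Gamma(alpha, alpha) distribution (mean 1).
#'
#' @param alpha gamma shape (> 0)
#' @param ncat number of categories
#' @return numeric vector of category rates (mean 1)
#' @export
discrete_gamma <- function(alpha, ncat = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (ncat == 1L) return(1)
  edges <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha,
                  rate = alpha)
  # E[X | bin] * P(bin) = F_{alpha+1}(hi) - F_{alpha+1}(lo) for mean-1 gamma
  cdf1 <- pgamma(edges, shape = alpha + 1, rate = alpha)
  ncat * diff(cdf1)
}

# integer states for aligned nucleotide rows; NA for gaps/N
.nt_states_matrix <- function(aln) {
  taxa <- names(aln)
  mat <- do.call(rbind, strsplit(toupper(unlist(aln)), "", fixed = TRUE))
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows differ in length")
  st <- matrix(match(mat, .NUC), nrow = length(taxa))
  rownames(st) <- taxa
  st
}

#' GTR+Gamma log-likelihood with per-site values
#'
#' Felsenstein pruning over 4 nucleotide states with `ncat` discrete gamma
#' categories of equal weight (category rates by mean-of-quantile
#' discretization).  Gaps and `N` are treated as missing data.
#'
#' @param aln named character vector of equal-length aligned sequences
#' @param tree [ape::phylo] with branch lengths; its leaves must all occur
#'   in `aln`
#' @param params list: `rates` (6 GTR exchangeabilities), `pi` (4 base
#'   frequencies; `"empirical"` to estimate from the data), `alpha` (gamma
#'   shape; `Inf` disables rate variation), `ncat` (default 4)
#' @return list of class `site_likelihoods`: `lnL`, `site_lnl` (per
#'   alignment column), `params`, `n_sites`
#' @export
gtr_gamma_lnL <- function(aln, tree, params = list()) {
  params <- .gtr_params(aln, params)
  miss <- setdiff(tree$tip.label, names(aln))
  if (length(miss)) stop("leaf missing from alignment: ", miss[1L])
  st <- .nt_states_matrix(aln[tree$tip.label])
  cp <- .compress_patterns(st)
  site_pat <- .gtr_pattern_lnl(tree, cp$patt, params)
  lnL <- sum(site_pat * cp$w)
  structure(list(lnL = lnL, site_lnl = site_pat[cp$index],
                 params = params, n_sites = ncol(st)),
            class = "site_likelihoods")
}

.gtr_params <- function(aln, params) {
  if (is.null(params$rates)) params$rates <- rep(1, 6)
  if (is.null(params$pi) || identical(params$pi, "empirical")) {
    ch <- strsplit(paste(unlist(aln), collapse = ""), "", fixed = TRUE)[[1L]]
    tab <- table(factor(ch, levels = .NUC))
    params$pi <- pmax(as.numeric(tab) / sum(tab), 1e-6)
    params$pi <- params$pi / sum(params$pi)
  }
  if (is.null(params$alpha)) params$alpha <- Inf
  if (is.null(params$ncat)) params$ncat <- 4L
  if (any(params$rates <= 0)) stop("exchangeabilities must be > 0")
  if (!is.infinite(params$alpha) && params$alpha <= 0)
    stop("alpha must be > 0")
  params
}

# per-pattern log-likelihood for GTR(+Gamma)
.gtr_pattern_lnl <- function(tree, patt, params) {
  Q <- gtr_rate_matrix(params$rates, params$pi)
  eig <- .rev_eigen(Q, params$pi)
  cat_rates <- if (is.infinite(params$alpha)) 1
    else discrete_gamma(params$alpha, params$ncat)
  percat <- vapply(cat_rates, function(r) {
    P_edge <- lapply(tree$edge.length, function(t) .pmat(eig, t * r))
    .prune_loglik(tree, P_edge, patt, params$pi)
  }, numeric(ncol(patt)))
  percat <- matrix(percat, ncol = length(cat_rates))
  if (length(cat_rates) == 1L) return(drop(percat))
  m <- apply(percat, 1L, max)
  m + log(rowMeans(exp(percat - m)))
}
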
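# RELL-based topology tests (KH, SH, AU) and the horizontal-transfer
# screen that combines a divergence anomaly with rejection of the
# vertical-constraint topology.

#' RELL topology tests: KH, SH and approximately unbiased (AU) p-values
#'
#' Per-site log-likelihood vectors are resampled (RELL: no re-estimation).
#' KH uses the normal approximation on the centred resampled lnL
#' difference to the best topology; SH applies the usual max-correction
#' over topologies; AU fits the signed distance / curvature pair (d, c)
#' to multiscale bootstrap probabilities by weighted least squares over
#' the scale factors and reports `1 - pnorm(d - c)`.
#'
#' @param site_lnls matrix: one column of per-site log-likelihoods per
#'   topology (columns named)
#' @param B bootstrap replicates per scale (default 10,000; below 1,000 a
#'   warning flag is set)
#' @param scales relative resampling sizes for the multiscale bootstrap
#' @param seed RNG seed
#' @return data.frame of class `topology_test`: topology, lnL, delta_lnL,
#'   p_KH, p_SH, p_AU, plus attributes `B`, `scales`, `seed`,
#'   `low_B_warning`
#' @export
rell_topology_tests <- function(site_lnls, B = 10000L,
                                scales = seq(0.5, 1.4, by = 0.1),
                                seed = 1L) {
  site_lnls <- as.matrix(site_lnls)
  Tn <- ncol(site_lnls)
  if (Tn < 2L) stop("need at least 2 topologies")
  if (length(scales) < 2L) stop("AU needs at least 2 scale factors")
  n <- nrow(site_lnls)
  if (is.null(colnames(site_lnls)))
    colnames(site_lnls) <- paste0("topo", seq_len(Tn))
  low_B <- B < 1000L
  if (low_B) warning("B < 1000: bootstrap p-values will be noisy")
  set.seed(seed)
  lnL <- colSums(site_lnls)
  best <- which.max(lnL)
  # resampled totals per scale; scale 1.0 (or the nearest) is reused for
  # KH/SH
  i1 <- which.min(abs(scales - 1))
  rl <- cpp_rell(site_lnls, as.integer(B), scales, as.integer(i1))
  bp <- rl$wins / B
  S1 <- rl$S1
  # KH: normal approximation on centred resampled delta vs the ML
  # topology (the best topology is compared to the runner-up)
  d_obs <- lnL[best] - lnL
  second <- order(lnL, decreasing = TRUE)[2L]
  p_kh <- vapply(seq_len(Tn), function(t) {
    comp <- if (t == best) second else best
    dd <- S1[, comp] - S1[, t]
    s <- sd(dd)
    if (s < 1e-12) return(0.5)
    if (t == best) pnorm(d_obs[second] / s)
    else 1 - pnorm(d_obs[t] / s)
  }, 0)
  # SH: max-corrected bootstrap of centred totals
  Sc <- sweep(S1, 2L, colMeans(S1))
  mx <- apply(Sc, 1L, max)
  p_sh <- vapply(seq_len(Tn), function(t)
    mean(mx - Sc[, t] >= d_obs[t]), 0)
  # AU: fit the signed distance / curvature pair in
  # bp(r) = Phi(-(d*sqrt(r) + c/sqrt(r))) to the per-scale win counts by
  # binomial maximum likelihood (initialized from weighted least squares
  # on the informative scales).  The count likelihood stays well-behaved
  # in the sparse regime where most scales record zero wins, where a
  # least-squares fit on clamped z-values is ill-conditioned.
  p_au <- vapply(seq_len(Tn), function(t) {
    k <- round(bp[, t] * B)
    if (all(k >= B - 1L)) return(1)
    if (all(k == 0L)) return(0)
    sq <- sqrt(scales)
    lo <- 2 / B; hi <- 1 - 2 / B
    inf_sc <- bp[, t] > lo & bp[, t] < hi
    init <- c(d = 0, c = 0)
    if (sum(inf_sc) >= 2L) {
      z <- qnorm(1 - bp[inf_sc, t])
      w <- B * dnorm(z)^2 / (bp[inf_sc, t] * (1 - bp[inf_sc, t]))
      X <- cbind(sq[inf_sc], 1 / sq[inf_sc])
      fit <- tryCatch(lm.wfit(X, z, w)$coefficients,
                      error = function(e) NULL)
      if (!is.null(fit) && !anyNA(fit)) init <- fit
    } else {
      init <- c(qnorm(1 - min(max(mean(bp[, t]), 1 / B), 1 - 1 / B)), 0)
    }
    obj <- function(par) {
      p <- pnorm(-(par[1L] * sq + par[2L] / sq))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(k * log(p) + (B - k) * log(1 - p))
    }
    fit <- tryCatch(nlminb(init, obj, lower = c(-40, -40),
                           upper = c(40, 40)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    min(max(1 - pnorm(fit$par[1L] - fit$par[2L]), 0), 1)
  }, 0)
  out <- data.frame(topology = colnames(site_lnls), lnL = lnL,
                    delta_lnL = lnL[best] - lnL, p_KH = p_kh, p_SH = p_sh,
                    p_AU = p_au, stringsAsFactors = FALSE)
  attr(out, "B") <- B
  attr(out, "scales") <- scales
  attr(out, "seed") <- seed
  attr(out, "low_B_warning") <- low_B
  class(out) <- c("topology_test", "data.frame")
  out
}

# smallest species-tree clade containing the focal taxon plus at least one
# other taxon present in `taxa`
.vertical_constraint <- function(species_tree, focal, taxa) {
  rt <- species_tree
  if (!ape::is.rooted(rt)) {
    out <- setdiff(rt$tip.label, focal)
    rt <- ape::root(rt, outgroup = out[length(out)], resolve.root = TRUE)
  }
  ntip <- length(rt$tip.label)
  node <- which(rt$tip.label == focal)
  if (!length(node)) stop("focal taxon not in species tree")
  repeat {
    parent <- rt$edge[rt$edge[, 2L] == node, 1L]
    if (!length(parent)) return(NULL)
    desc <- ape::extract.clade(rt, parent)$tip.label
    present <- intersect(desc, taxa)
    if (length(present) >= 2L && length(present) < length(taxa))
      return(present)
    node <- parent
  }
}

#' Screen genes for horizontal transfer
#'
#' A gene is an HGT candidate only if BOTH (i) its divergence statistic is
#' anomalous on the low-divergence side (leave-one-out z-score of the
#' focal-vs-reference percent identity at or above `z_threshold`), and
#' (ii) the vertical-constraint topology (focal taxon with its closest
#' sampled relatives, read off the species tree) is rejected by the AU
#' test at `alpha`.  Genes failing (i) are `vertical`; genes passing (i)
#' but not (ii) are `inconclusive`.
#'
#' @param gene_alignments named list; per gene, a named character vector
#'   of ALIGNED nucleotide sequences including the focal taxon
#' @param species_tree [ape::phylo] giving vertical relationships
#' @param focal focal taxon name
#' @param reference reference taxon used for the divergence statistic
#' @param divergence optional named numeric vector of precomputed
#'   focal-vs-reference percent identities (otherwise computed from the
#'   alignments, gap columns excluded)
#' @param alpha AU rejection level
#' @param z_threshold anomaly threshold on the leave-one-out z-score
#' @param B,seed RELL settings
#' @param n_starts starting trees for the unconstrained search
#' @return data.frame of class `hgt_report`: gene, identity, z, anomalous,
#'   p_AU (NA when the topology test was not needed), verdict
#' @export
flag_hgt_candidates <- function(gene_alignments, species_tree, focal,
                                reference, divergence = NULL, alpha = 0.05,
                                z_threshold = 2.5, B = 2000L, seed = 1L,
                                n_starts = 2L) {
  genes <- names(gene_alignments)
  if (length(genes) < 5L)
    stop("need >= 5 genes for the genome-wide divergence distribution")
  if (is.null(divergence)) {
    divergence <- vapply(gene_alignments, function(a) {
      if (!all(c(focal, reference) %in% names(a))) return(NA_real_)
      percent_identity(a[[focal]], a[[reference]])
    }, 0)
    names(divergence) <- genes
  }
  x <- divergence[genes]
  z <- vapply(seq_along(x), function(i) {
    if (is.na(x[i])) return(NA_real_)
    oth <- x[-i]
    oth <- oth[!is.na(oth)]
    (x[i] - mean(oth)) / max(sd(oth), 1e-8)
  }, 0)
  anomalous <- !is.na(z) & z >= z_threshold
  p_au <- rep(NA_real_, length(genes))
  verdict <- ifelse(anomalous, "inconclusive", "vertical")
  for (i in which(anomalous)) {
    a <- gene_alignments[[i]]
    taxa <- names(a)
    if (length(taxa) < 4L) next
    clade <- .vertical_constraint(species_tree, focal, taxa)
    if (is.null(clade)) next
    # estimate the gamma shape once, then search with it fixed
    set.seed(seed + i)
    pre <- optimize_branch_lengths(a, .random_constrained_topology(taxa, NULL),
                                   fit_alpha = TRUE, tol = 1e-3)
    mp <- list(alpha = pre$params$alpha)
    unc <- search_ml_tree(a, params = mp, constraint = NULL,
                          n_starts = n_starts, seed = seed + i)
    con <- search_ml_tree(a, params = mp, constraint = list(clade),
                          n_starts = n_starts, seed = seed + i)
    tt <- rell_topology_tests(cbind(unconstrained = unc$site_lnl,
                                    vertical = con$site_lnl),
                              B = B, seed = seed + i)
    p_au[i] <- tt$p_AU[tt$topology == "vertical"]
    if (!is.na(p_au[i]) && p_au[i] < alpha) verdict[i] <- "hgt_candidate"
  }
  out <- data.frame(gene = genes, identity = as.numeric(x), z = z,
                    anomalous = anomalous, p_AU = p_au, verdict = verdict,
                    stringsAsFactors = FALSE)
  class(out) <- c("hgt_report", "data.frame")
  out
}
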
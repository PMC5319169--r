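# Branch-length optimization on a fixed topology and small-scale ML
# topology search (exhaustive below 6 taxa, NNI hill-climbing above).

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Under GTR+Gamma.  The default `method = "joint"` optimizes all branch
#' lengths (plus, optionally, the gamma shape and exchangeabilities) with
#' a bounded quasi-Newton run; `method = "sweeps"` performs coordinate-wise
#' Brent passes over branches, which guarantees a monotone likelihood
#' trace at slightly higher cost.
#'
#' @param aln named character vector of aligned sequences
#' @param topology [ape::phylo]; branch lengths, if present, are the
#'   starting point
#' @param params model parameters as in [gtr_gamma_lnL()]
#' @param fit_alpha,fit_rates also estimate the gamma shape /
#'   exchangeabilities?
#' @param method `"joint"` or `"sweeps"`
#' @param tol convergence tolerance on lnL
#' @param iter_max iteration cap for the joint optimizer
#' @param max_sweeps maximum coordinate passes for `method = "sweeps"`
#' @return list: `tree` (with ML branch lengths), `lnL`, `params`,
#'   `site_lnl`, `trace` (lnL after each sweep, sweeps method only)
#' @export
optimize_branch_lengths <- function(aln, topology, params = list(),
                                    fit_alpha = FALSE, fit_rates = FALSE,
                                    method = c("joint", "sweeps"),
                                    tol = 1e-6, iter_max = 500L,
                                    max_sweeps = 30L) {
  method <- match.arg(method)
  if (length(topology$tip.label) < 2L) stop("need >= 2 taxa")
  params <- .gtr_params(aln, params)
  if (fit_alpha && is.infinite(params$alpha)) params$alpha <- 1
  st <- .nt_states_matrix(aln[topology$tip.label])
  cp <- .compress_patterns(st)
  tr <- topology
  if (is.null(tr$edge.length))
    tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  nb <- length(tr$edge.length)
  lnl_of <- function(bl, pars) {
    tr$edge.length <- bl
    sum(.gtr_pattern_lnl(tr, cp$patt, pars) * cp$w)
  }
  trace <- numeric()
  if (method == "joint") {
    nr <- if (fit_rates) 5L else 0L
    na <- if (fit_alpha) 1L else 0L
    unpack <- function(x) {
      bl <- exp(x[seq_len(nb)])
      pars <- params
      if (nr) pars$rates <- c(exp(x[nb + seq_len(nr)]), 1)
      if (na) pars$alpha <- exp(x[nb + nr + 1L])
      list(bl = bl, pars = pars)
    }
    obj <- function(x) {
      u <- unpack(x)
      -lnl_of(u$bl, u$pars)
    }
    x0 <- c(log(tr$edge.length),
            if (nr) log(pmax(params$rates[1:5], 1e-3)),
            if (na) log(params$alpha))
    fit <- nlminb(x0, obj, lower = c(rep(log(1e-7), nb),
                                     rep(log(1e-3), nr),
                                     if (na) log(0.02)),
                  upper = c(rep(log(20), nb), rep(log(1e3), nr),
                            if (na) log(100)),
                  control = list(rel.tol = tol * 1e-2,
                                 iter.max = as.integer(iter_max)))
    u <- unpack(fit$par)
    tr$edge.length <- u$bl
    params <- u$pars
    lnL <- -fit$objective
  } else {
    cur <- lnl_of(tr$edge.length, params)
    for (sw in seq_len(max_sweeps)) {
      for (b in seq_len(nb)) {
        bl <- tr$edge.length
        f <- function(t) { bl[b] <- t; -lnl_of(bl, params) }
        op <- optimize(f, interval = c(1e-7, 20))
        if (-op$objective >= cur) {
          tr$edge.length[b] <- op$minimum
          cur <- -op$objective
        }
      }
      if (fit_alpha) {
        fa <- function(a) {
          p2 <- params; p2$alpha <- a
          -lnl_of(tr$edge.length, p2)
        }
        op <- optimize(fa, interval = c(0.02, 100))
        if (-op$objective >= cur) {
          params$alpha <- op$minimum
          cur <- -op$objective
        }
      }
      trace <- c(trace, cur)
      if (sw > 1L && trace[sw] - trace[sw - 1L] < tol) break
    }
    if (length(trace) == max_sweeps &&
        (length(trace) < 2L ||
         trace[max_sweeps] - trace[max_sweeps - 1L] >= tol * 100))
      warning("branch-length optimization did not fully converge; ",
              "returning best-so-far")
    lnL <- cur
  }
  site_pat <- .gtr_pattern_lnl(tr, cp$patt, params)
  list(tree = tr, lnL = lnL, params = params,
       site_lnl = site_pat[cp$index], trace = trace)
}

# is every constraint clade a bipartition of (unrooted) tree?
.satisfies_constraint <- function(tree, constraint) {
  if (is.null(constraint) || !length(constraint)) return(TRUE)
  tips <- tree$tip.label
  all(vapply(constraint, function(clade) {
    clade <- intersect(clade, tips)
    if (length(clade) <= 1L || length(clade) >= length(tips) - 1L)
      return(TRUE)
    out <- setdiff(tips, clade)
    rt <- ape::root(tree, outgroup = out[1L], resolve.root = TRUE)
    ape::is.monophyletic(rt, clade)
  }, logical(1L)))
}

# random topology honouring (disjoint or nested) constraint clades
.random_constrained_topology <- function(tips, constraint) {
  rand_top <- function(lab) {
    if (length(lab) == 1L) return(lab)
    tr <- ape::rtree(length(lab), tip.label = sample(lab), br = NULL)
    ape::unroot(tr)
  }
  if (is.null(constraint) || !length(constraint)) return(rand_top(tips))
  for (i in seq_len(200L)) {
    tr <- rand_top(tips)
    if (.satisfies_constraint(tr, constraint)) return(tr)
  }
  # direct construction for a single clade
  clade <- intersect(constraint[[1L]], tips)
  rest <- setdiff(tips, clade)
  sub <- if (length(clade) > 1L)
    ape::rtree(length(clade), tip.label = sample(clade), br = NULL)
  else NULL
  base <- ape::rtree(length(rest) + 1L, tip.label = c(sample(rest), "zzCLADE"),
                     br = NULL)
  tr <- if (is.null(sub)) {
    base$tip.label[base$tip.label == "zzCLADE"] <- clade
    base
  } else ape::bind.tree(base, sub, where = which(base$tip.label == "zzCLADE"))
  tr <- ape::unroot(tr)
  if (!.satisfies_constraint(tr, constraint))
    stop("constraint unsatisfiable")
  tr
}

#' Small-scale ML topology search
#'
#' Exhaustive over all unrooted topologies below 6 taxa; for 6-12 taxa,
#' NNI hill-climbing from `n_starts` starting trees (a neighbour-joining
#' tree plus random topologies).  Moves violating the constraint (a list
#' of taxon sets that must each form a clade) are rejected.
#'
#' @param aln named character vector of aligned sequences
#' @param params model parameters as in [gtr_gamma_lnL()]
#' @param constraint list of character vectors (clades), or NULL
#' @param n_starts number of starting trees for the NNI search
#' @param seed RNG seed for the random starts
#' @param fit_alpha estimate the gamma shape during scoring?
#' @return list: `tree`, `lnL`, `params`, `site_lnl`
#' @export
search_ml_tree <- function(aln, params = list(), constraint = NULL,
                           n_starts = 10L, seed = 1L, fit_alpha = FALSE) {
  taxa <- names(aln)
  n <- length(taxa)
  if (n > 12L) stop("topology search is capped at 12 taxa")
  if (n < 4L) {
    tr <- .random_constrained_topology(taxa, constraint)
    return(optimize_branch_lengths(aln, tr, params, fit_alpha = fit_alpha))
  }
  score <- function(top) optimize_branch_lengths(aln, top, params,
                                                 fit_alpha = fit_alpha)
  coarse <- function(top) optimize_branch_lengths(aln, top, params,
                                                  fit_alpha = fit_alpha,
                                                  tol = 1e-2,
                                                  iter_max = 12L)
  if (n < 6L) {
    cand <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    cand <- Filter(function(tr) .satisfies_constraint(tr, constraint),
                   as.list(cand))
    if (!length(cand)) stop("constraint unsatisfiable")
    # coarse screen, then full optimization of the top candidates
    rough <- vapply(cand, function(t0) coarse(t0)$lnL, 0)
    keep <- order(rough, decreasing = TRUE)[seq_len(min(2L, length(cand)))]
    fits <- lapply(cand[keep], score)
    return(fits[[which.max(vapply(fits, `[[`, 0, "lnL"))]])
  }
  set.seed(seed)
  starts <- list()
  nj <- tryCatch({
    d <- ape::dist.dna(ape::as.DNAbin(strsplit(toupper(unlist(aln)), "")),
                       model = "JC69", pairwise.deletion = TRUE)
    tr <- ape::unroot(ape::nj(d))
    tr$edge.length <- NULL
    if (.satisfies_constraint(tr, constraint)) tr else NULL
  }, error = function(e) NULL)
  if (!is.null(nj)) starts <- c(starts, list(nj))
  while (length(starts) < n_starts)
    starts <- c(starts, list(.random_constrained_topology(taxa, constraint)))
  best <- NULL
  for (tr0 in starts) {
    fit <- score(tr0)
    repeat {
      nbrs <- tryCatch(phangorn::nni(fit$tree), error = function(e) NULL)
      if (is.null(nbrs)) break
      nbrs <- Filter(function(tr) .satisfies_constraint(tr, constraint),
                     as.list(nbrs))
      if (!length(nbrs)) break
      nfits <- lapply(nbrs, score)
      lnls <- vapply(nfits, `[[`, 0, "lnL")
      if (max(lnls) > fit$lnL + 1e-6) fit <- nfits[[which.max(lnls)]]
      else break
    }
    if (is.null(best) || fit$lnL > best$lnL) best <- fit
  }
  best
}
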
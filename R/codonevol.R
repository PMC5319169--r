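# Codon alignments with RNA-editing masks, dN/dS by counting (NG86) and
# by maximum likelihood under GY94 (pairwise and branch-class), and the
# branch-model selection-relaxation likelihood-ratio test.

#' Construct a codon alignment
#'
#' @param seqs named character vector of ALIGNED, in-frame nucleotide
#'   sequences (equal lengths, multiples of 3; gaps only as whole `---`
#'   codons)
#' @param mask integer vector of excluded codon columns
#' @return list of class `codon_alignment`: `codons` (taxa x columns
#'   character matrix), `mask`, `taxa`
#' @export
codon_alignment <- function(seqs, mask = integer()) {
  if (is.null(names(seqs))) stop("sequences must be named")
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("alignment rows differ in length")
  if (n %% 3L != 0L) stop("alignment length not a multiple of 3")
  codons <- matrix(vapply(seqs, split_codons, character(n / 3L)),
                   nrow = n / 3L)
  codons <- t(codons)
  rownames(codons) <- names(seqs)
  bad <- !(codons %in% c(sense_codons(), "---"))
  bad_mat <- matrix(bad, nrow = nrow(codons))
  mask <- sort(unique(as.integer(mask)))
  if (any(mask > ncol(codons))) stop("mask index beyond alignment")
  chk <- bad_mat
  if (length(mask)) chk[, mask] <- FALSE
  if (any(chk)) {
    w <- which(chk, arr.ind = TRUE)[1L, ]
    stop("non-sense codon '", codons[w[1L], w[2L]], "' for taxon ",
         rownames(codons)[w[1L]], " at codon column ", w[2L],
         " (stop codons must be masked)")
  }
  structure(list(codons = codons, mask = mask, taxa = rownames(codons)),
            class = "codon_alignment")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Codon columns mirror the protein columns; protein gaps expand to
#' `---`.  Each coding sequence must translate exactly to its
#' (ungapped) protein row.
#'
#' @param protein_alignment named character vector of aligned amino-acid
#'   sequences
#' @param cds_per_taxon named character vector of unaligned CDSs
#' @return a [codon_alignment()]
#' @export
backtranslate_alignment <- function(protein_alignment, cds_per_taxon) {
  out <- character(length(protein_alignment))
  names(out) <- names(protein_alignment)
  for (tx in names(protein_alignment)) {
    prot <- strsplit(protein_alignment[[tx]], "", fixed = TRUE)[[1L]]
    cds <- cds_per_taxon[[tx]]
    if (is.null(cds)) stop("no CDS for taxon ", tx)
    cods <- split_codons(cds)
    aa <- codon_aa(cods)
    core <- prot[prot != "-"]
    if (length(core) != length(cods))
      stop("translation mismatch for taxon ", tx, ": protein has ",
           length(core), " residues, CDS has ", length(cods), " codons")
    mism <- which(core != aa)
    if (length(mism))
      stop("translation mismatch for taxon ", tx, " at position ",
           mism[1L], " (", core[mism[1L]], " vs ", aa[mism[1L]], ")")
    row <- character(length(prot))
    j <- 0L
    for (i in seq_along(prot)) {
      if (prot[i] == "-") row[i] <- "---"
      else { j <- j + 1L; row[i] <- cods[j] }
    }
    out[[tx]] <- paste(row, collapse = "")
  }
  codon_alignment(out)
}

#' Mask RNA-edited codons in an alignment
#'
#' Edited codon indices are given in the reference taxon's frame and are
#' mapped to alignment columns through that row's non-gap codons; the
#' union of empirical, predicted and `extra` sites is added to the mask.
#' Masked columns are ignored by every downstream estimator.
#'
#' @param aln a [codon_alignment()]
#' @param table an `editing_table` (or NULL)
#' @param gene gene name to look up in the table
#' @param reference reference taxon (default: first row)
#' @param extra additional codon indices (reference frame)
#' @return the alignment with an extended mask
#' @export
mask_edited_codons <- function(aln, table = NULL, gene = NULL,
                               reference = aln$taxa[1L], extra = integer()) {
  idx <- sort(unique(c(
    if (!is.null(table) && !is.null(gene)) edited_codons_for(table, gene),
    as.integer(extra))))
  if (!length(idx)) return(aln)
  refrow <- aln$codons[reference, ]
  colmap <- which(refrow != "---")
  if (any(idx > length(colmap)))
    stop("editing codon index ", max(idx), " beyond reference length ",
         length(colmap))
  aln$mask <- sort(unique(c(aln$mask, colmap[idx])))
  # re-validate now that stop-looking codons may be masked
  codon_alignment(setNames(apply(aln$codons, 1L, paste, collapse = ""),
                           aln$taxa), aln$mask)
}

# usable columns: unmasked and gap-free in all rows
.usable_columns <- function(aln) {
  ok <- colSums(aln$codons == "---") == 0L
  if (length(aln$mask)) ok[aln$mask] <- FALSE
  which(ok)
}

# ---- NG86 ----------------------------------------------------------------

# per-codon synonymous site counts (stop-codon mutations disregarded)
.ng86_sites <- function() {
  if (!is.null(.mr_cache$ng86_sites)) return(.mr_cache$ng86_sites)
  cods <- sense_codons()
  S <- vapply(cods, function(codon) {
    tot <- 0
    for (p in 1:3) {
      nsyn <- 0L; nmut <- 0L
      for (b in setdiff(.NUC, substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- b
        if (mut %in% .STOPS) next
        nmut <- nmut + 1L
        if (codon_aa(mut) == codon_aa(codon)) nsyn <- nsyn + 1L
      }
      if (nmut > 0L) tot <- tot + nsyn / nmut
    }
    tot
  }, 0)
  .mr_cache$ng86_sites <- setNames(S, cods)
  S
}

# syn/nonsyn difference counts for a codon pair, averaging over all
# mutational paths that avoid stop codons (all paths if every one is
# blocked)
.ng86_pair <- function(c1, c2) {
  key <- paste(c1, c2)
  memo <- .mr_cache$ng86_pairs
  if (is.null(memo)) memo <- .mr_cache$ng86_pairs <- new.env()
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  diffs <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  paths <- if (length(diffs) <= 1L) list(diffs)
    else asplit(do.call(rbind, .permutations(diffs)), 1L)
  tally <- NULL
  for (ord in paths) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% .STOPS) { blocked <- TRUE; break }
      if (codon_aa(nxt) == codon_aa(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    tally <- rbind(tally, c(sd, nd, blocked))
  }
  ok <- tally[, 3L] == 0
  use <- if (any(ok)) tally[ok, , drop = FALSE] else {
    # all paths pass through a stop: count steps ignoring the block
    t2 <- NULL
    for (ord in paths) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        aa1 <- codon_aa(cur); aa2 <- codon_aa(nxt)
        if (!is.na(aa1) && !is.na(aa2) && aa1 == aa2) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      t2 <- rbind(t2, c(sd, nd, 0))
    }
    t2
  }
  res <- c(Sd = mean(use[, 1L]), Nd = mean(use[, 2L]))
  memo[[key]] <- res
  res
}

.permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Site counting disregards mutations to stop codons; multi-difference
#' codons average over all stop-free mutational pathways; proportions are
#' Jukes-Cantor corrected.  When the correction is undefined (proportion
#' >= 3/4) for only one of pS/pN, the corresponding rate is reported as
#' NA with a saturation flag; when both are undefined the call errors.
#'
#' @param aln a two-taxon [codon_alignment()]
#' @return data.frame of class `rate_estimates`: scope, dN, dS, omega,
#'   plus site/difference counts and saturation flags
#' @export
ng86_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$codons) != 2L) stop("NG86 is pairwise: need exactly 2 taxa")
  use <- .usable_columns(aln)
  if (!length(use)) stop("no usable (unmasked, gap-free) columns")
  Stab <- .ng86_sites()
  r1 <- aln$codons[1L, use]; r2 <- aln$codons[2L, use]
  S <- (sum(Stab[r1]) + sum(Stab[r2])) / 2
  N <- 3 * length(use) - S
  dif <- which(r1 != r2)
  Sd <- 0; Nd <- 0
  for (k in dif) {
    p <- .ng86_pair(r1[k], r2[k])
    Sd <- Sd + p[["Sd"]]; Nd <- Nd + p[["Nd"]]
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  if (is.na(dS) && is.na(dN))
    stop("saturation: both pS and pN >= 3/4, distances undefined")
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  out <- data.frame(scope = "pair", method = "NG86", dN = dN, dS = dS,
                    omega = omega, S = S, N = N, Sd = Sd, Nd = Nd,
                    pS = pS, pN = pN, n_codons = length(use),
                    saturated_dS = is.na(dS), saturated_dN = is.na(dN),
                    stringsAsFactors = FALSE)
  class(out) <- c("rate_estimates", "data.frame")
  out
}

# ---- GY94 maximum likelihood --------------------------------------------

# postorder edge ordering + missing-state recoding for the C++ kernel
.codon_tree_prep <- function(tree, patt) {
  post <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(post$edge[, 1L], post$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  p <- patt
  p[is.na(p)] <- 0L
  storage.mode(p) <- "integer"
  list(edge = post$edge, ord = ord, patt = p,
       ntip = length(tree$tip.label))
}

# per-pattern codon log-likelihood; edge_omega may be a vector (one
# model) or an ne x K matrix (K omega categories); returns a vector or
# an npat x K matrix accordingly
.codon_pattern_lnl <- function(tree, patt, bl, kappa, edge_omega, pi,
                               prep = NULL, cache = NULL) {
  if (is.null(prep)) prep <- .codon_tree_prep(tree, patt)
  eo <- if (is.matrix(edge_omega)) edge_omega
    else matrix(edge_omega, ncol = 1L)
  out <- cpp_codon_lnl(prep$patt, prep$edge, bl[prep$ord], prep$ntip,
                       .codon_pairs(), kappa, pi,
                       eo[prep$ord, , drop = FALSE], cache)
  if (ncol(out) == 1L) drop(out) else out
}

.resolve_pi <- function(pi, aln, use) {
  if (is.numeric(pi)) return(pi)
  if (identical(pi, "uniform")) return(rep(1 / 61, 61))
  f3x4_frequencies(aln$codons[, use, drop = FALSE])
}

#' Pairwise dN/dS by maximum likelihood under GY94
#'
#' Optimizes (t, kappa, omega) for the Goldman-Yang rate matrix
#' (single-nucleotide steps, kappa for transitions, omega for
#' nonsynonymous changes, target-codon frequencies) by bounded
#' quasi-Newton with random restarts; dN and dS follow from the standard
#' flux decomposition of t into per-site rates ([gy94_flux()]).
#'
#' @param aln a two-taxon [codon_alignment()]
#' @param init list with starting `t`, `kappa`, `omega`
#' @param pi `"f3x4"` (default), `"uniform"`, or a 61-vector
#' @param n_restarts additional randomized optimizer starts
#' @param se also compute curvature-based standard errors?
#' @return data.frame of class `rate_estimates` with `dN`, `dS`, `omega`,
#'   `t`, `kappa`, `lnL` (and `se_omega`, `se_t` when `se = TRUE`)
#' @export
fit_pairwise_gy94 <- function(aln, init = NULL, pi = "f3x4",
                              n_restarts = 1L, se = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$codons) != 2L) stop("need exactly 2 taxa")
  use <- .usable_columns(aln)
  if (length(use) < 10L) stop("need >= 10 unmasked gap-free codon columns")
  pi <- .resolve_pi(pi, aln, use)
  st1 <- match(aln$codons[1L, use], sense_codons())
  st2 <- match(aln$codons[2L, use], sense_codons())
  counts <- table(factor(st1, 1:61), factor(st2, 1:61))
  nz <- which(counts > 0, arr.ind = TRUE)
  cnt <- as.numeric(counts[nz])
  if (is.null(init)) {
    # moment-style start: codon p-distance roughly equals 1 - exp(-t)
    p <- min(mean(st1 != st2), 0.95)
    init <- list(t = max(0.02, -log(1 - p)), kappa = 2, omega = 0.5)
  }
  obj <- function(x) {
    t <- exp(x[1L]); k <- exp(x[2L]); w <- exp(x[3L])
    P <- cpp_gy94_pmat(.codon_pairs(), k, w, pi, t)
    ll <- log(pmax(pi[nz[, 1L]] * P[nz], 1e-300))
    -sum(cnt * ll)
  }
  lower <- log(c(1e-8, 0.05, 1e-5)); upper <- log(c(30, 100, 50))
  best <- nlminb(log(c(init$t, init$kappa, init$omega)), obj,
                 lower = lower, upper = upper,
                 control = list(rel.tol = 1e-10, iter.max = 400L))
  if (n_restarts > 0L) {
    set.seed(sum(cnt) + length(cnt))
    for (r in seq_len(n_restarts)) {
      # restart from a jittered copy of the incumbent optimum
      fit <- nlminb(best$par + rnorm(3L, 0, 0.4), obj,
                    lower = lower, upper = upper,
                    control = list(rel.tol = 1e-10, iter.max = 400L))
      if (fit$objective < best$objective) best <- fit
    }
  }
  t <- exp(best$par[1L]); kappa <- exp(best$par[2L])
  omega <- exp(best$par[3L])
  dd <- .dnds_from_t(t, kappa, omega, pi)
  out <- data.frame(scope = "pair", method = "GY94", dN = dd$dN,
                    dS = dd$dS,
                    omega = if (dd$dS > 0) omega else NA_real_,
                    omega_mle = omega, t = t, kappa = kappa,
                    lnL = -best$objective, n_codons = length(use),
                    stringsAsFactors = FALSE)
  if (se) {
    H <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        # delta method from log scale
        out$se_t <- sqrt(V[1L, 1L]) * t
        out$se_omega <- sqrt(V[3L, 3L]) * omega
      }
    }
  }
  class(out) <- c("rate_estimates", "data.frame")
  out
}

#' Branch-class dN/dS under GY94
#'
#' One omega per branch class (for instance the seven-set layout: each
#' focal lineage, the focal ancestral branch, other fast lineages, and
#' the background), shared kappa and frequencies, branch lengths
#' estimated jointly by ML through pruning over the 61 codon states.
#'
#' @param aln a [codon_alignment()] (>= 2 taxa)
#' @param tree [ape::phylo]; starting branch lengths used if present
#' @param classes integer vector over `tree$edge` rows assigning every
#'   branch to a class `1..K`
#' @param init list with starting `kappa` and `omega` (recycled over
#'   classes)
#' @param pi `"f3x4"`, `"uniform"`, or a 61-vector
#' @return list of class `branch_class_fit`: `omega` (per class), `tree`
#'   (ML branch lengths), `kappa`, `lnL`, `per_branch` (data.frame with
#'   class, t, dN, dS)
#' @export
fit_branch_class_gy94 <- function(aln, tree, classes,
                                  init = list(kappa = 2, omega = 0.3),
                                  pi = "f3x4") {
  stopifnot(inherits(aln, "codon_alignment"))
  ne <- nrow(tree$edge)
  if (length(classes) != ne || anyNA(classes))
    stop("every branch needs exactly one class")
  K <- max(classes)
  if (!setequal(unique(classes), seq_len(K)))
    stop("branch classes must cover 1..K with no empty class")
  if (!all(tree$tip.label %in% aln$taxa))
    stop("tree leaf missing from alignment")
  use <- .usable_columns(aln)
  pi <- .resolve_pi(pi, aln, use)
  st <- .codon_states_matrix(aln$codons[tree$tip.label, use, drop = FALSE])
  cp <- .compress_patterns(st)
  om0 <- rep(init$omega, length.out = K)
  bl0 <- if (!is.null(tree$edge.length)) pmax(tree$edge.length, 1e-4)
    else rep(0.1, ne)
  prep <- .codon_tree_prep(tree, cp$patt)
  obj <- function(x) {
    bl <- exp(x[seq_len(ne)])
    k <- exp(x[ne + 1L])
    om <- exp(x[ne + 1L + seq_len(K)])
    ll <- .codon_pattern_lnl(tree, cp$patt, bl, k, om[classes], pi,
                             prep = prep)
    -sum(ll * cp$w)
  }
  x0 <- c(log(bl0), log(init$kappa), log(om0))
  fit <- nlminb(x0, obj,
                lower = c(rep(log(1e-7), ne), log(0.05), rep(log(1e-5), K)),
                upper = c(rep(log(30), ne), log(100), rep(log(50), K)),
                control = list(rel.tol = 1e-10, iter.max = 1000L))
  bl <- exp(fit$par[seq_len(ne)])
  kappa <- exp(fit$par[ne + 1L])
  omega <- exp(fit$par[ne + 1L + seq_len(K)])
  tr <- tree; tr$edge.length <- bl
  per_branch <- do.call(rbind, lapply(seq_len(ne), function(e) {
    dd <- .dnds_from_t(bl[e], kappa, omega[classes[e]], pi)
    data.frame(edge = e, class = classes[e], t = bl[e],
               omega = omega[classes[e]], dN = dd$dN, dS = dd$dS)
  }))
  structure(list(omega = omega, tree = tr, kappa = kappa,
                 lnL = -fit$objective, per_branch = per_branch,
                 convergence = fit$convergence),
            class = "branch_class_fit")
}

#' Branch-model test for relaxed (or intensified) selection
#'
#' Reference branches share `K` discrete omega categories (values and
#' proportions estimated); test branches use the same categories raised
#' to a selection intensity `k` (`omega_i^k`).  The null fixes `k = 1`,
#' the alternative frees it; the LRT is referred to chi-square with 1
#' degree of freedom.  `k < 1` with a significant LRT indicates
#' relaxation.  Branch lengths (up to a single jointly estimated scale)
#' and kappa are estimated in a single-omega first stage and then held
#' fixed, which keeps the test at desk scale.
#'
#' @param aln a [codon_alignment()]
#' @param tree [ape::phylo] with (relative) branch lengths
#' @param test_edges integer indices into `tree$edge` rows: the test
#'   branch set (non-empty proper subset)
#' @param K number of omega categories (default 3)
#' @param pi `"f3x4"`, `"uniform"`, or a 61-vector
#' @param control optimizer settings: `rel.tol`, `iter.max`
#' @return list of class `relaxation_result`: `k`, `lnL_null`, `lnL_alt`,
#'   `LRT`, `p_value`, `omega_categories`, `proportions`, `kappa`,
#'   `collapsed` (TRUE when categories merged and the fit was redone with
#'   K-1)
#' @export
relaxation_test <- function(aln, tree, test_edges, K = 3L, pi = "f3x4",
                            control = list()) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (K < 1L) stop("K must be >= 1")
  ne <- nrow(tree$edge)
  test_edges <- as.integer(test_edges)
  if (!length(test_edges) || length(test_edges) >= ne ||
      any(test_edges < 1L | test_edges > ne))
    stop("test set must be a non-empty proper subset of branches")
  if (!all(tree$tip.label %in% aln$taxa))
    stop("tree leaf missing from alignment")
  ctl <- modifyList(list(rel.tol = 1e-9, iter.max = 300L), control)
  use <- .usable_columns(aln)
  pi <- .resolve_pi(pi, aln, use)
  st <- .codon_states_matrix(aln$codons[tree$tip.label, use, drop = FALSE])
  cp <- .compress_patterns(st)
  bl_rel <- if (!is.null(tree$edge.length)) pmax(tree$edge.length, 1e-6)
    else rep(0.1, ne)
  prep <- .codon_tree_prep(tree, cp$patt)
  # stage 1: single-omega fit of tree scale, kappa, omega
  obj0 <- function(x) {
    s <- exp(x[1L]); k <- exp(x[2L]); w <- exp(x[3L])
    -sum(.codon_pattern_lnl(tree, cp$patt, bl_rel * s, k,
                            rep(w, ne), pi, prep = prep) * cp$w)
  }
  f0 <- nlminb(log(c(1, 2, 0.3)), obj0,
               lower = log(c(1e-4, 0.05, 1e-5)),
               upper = log(c(1e3, 100, 50)),
               control = list(rel.tol = 1e-8, iter.max = 200L))
  bl <- bl_rel * exp(f0$par[1L])
  kappa <- exp(f0$par[2L])
  eig_cache <- new.env(parent = emptyenv())
  mix_lnl <- function(om_ref, om_test, props) {
    eo <- matrix(om_ref, ne, length(om_ref), byrow = TRUE)
    eo[test_edges, ] <- matrix(om_test, length(test_edges),
                               length(om_test), byrow = TRUE)
    percat <- .codon_pattern_lnl(tree, cp$patt, bl, kappa, eo, pi,
                                 prep = prep, cache = eig_cache)
    percat <- matrix(percat, ncol = length(om_ref))
    m <- apply(percat, 1L, max)
    sum((m + log(pmax(exp(percat - m) %*% props, 1e-300))) * cp$w)
  }
  # parameters: log omegas (K, unordered -- the likelihood is invariant
  # to category labels and independent coordinates let the eigen cache
  # work during gradient steps), logits (K-1), [log k]
  unpack <- function(x, free_k) {
    om <- exp(x[seq_len(K)])
    if (K > 1L) {
      lg <- x[K + seq_len(K - 1L)]
      p <- exp(c(lg, 0)); p <- p / sum(p)
    } else p <- 1
    kk <- if (free_k) exp(x[length(x)]) else 1
    list(om = om, p = p, k = kk)
  }
  objm <- function(x, free_k) {
    u <- unpack(x, free_k)
    -mix_lnl(u$om, u$om^u$k, u$p)
  }
  w0 <- exp(f0$par[3L])
  spread <- c(0.2, 0.9, 4)[seq_len(min(K, 3L))]
  if (K > 3L) spread <- c(spread, rep(8, K - 3L))
  x0 <- c(log(pmax(w0 * spread, 1e-4)),
          if (K > 1L) rep(0, K - 1L))
  low <- c(rep(log(1e-5), K), if (K > 1L) rep(-7, K - 1L))
  upp <- c(rep(log(30), K), if (K > 1L) rep(7, K - 1L))
  fit0 <- nlminb(x0, objm, free_k = FALSE, lower = low, upper = upp,
                 control = ctl)
  fit1 <- nlminb(c(fit0$par, 0), objm, free_k = TRUE,
                 lower = c(low, log(0.02)), upper = c(upp, log(50)),
                 control = ctl)
  lnL0 <- -fit0$objective
  lnL1 <- max(-fit1$objective, lnL0)   # alt nests the null
  u <- unpack(fit1$par, TRUE)
  ord <- order(u$om)
  u$om <- u$om[ord]
  if (K > 1L) u$p <- u$p[ord]
  collapsed <- K > 1L && any(diff(log(u$om)) < 0.02)
  if (collapsed && K > 2L) {
    res <- relaxation_test(aln, tree, test_edges, K = K - 1L, pi = pi,
                           control = control)
    res$collapsed <- TRUE
    return(res)
  }
  LRT <- max(0, 2 * (lnL1 - lnL0))
  structure(list(k = u$k, lnL_null = lnL0, lnL_alt = lnL1, LRT = LRT,
                 p_value = pchisq(LRT, df = 1L, lower.tail = FALSE),
                 omega_categories = u$om, proportions = u$p,
                 kappa = kappa, K = K, collapsed = collapsed),
            class = "relaxation_result")
}
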
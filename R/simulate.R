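# Synthetic mitogenome generator: continuous-time GY94 codon evolution
# with branch-specific rate multipliers and omega (exact Gillespie jumps,
# so realized substitution counts are part of the ground truth),
# pseudogenization events, compensatory rRNA evolution, and genome
# assembly with spacers, exon splits and optional origin wraparound.

#' Simulation configuration
#'
#' @param tree [ape::phylo] with branch lengths in expected substitutions
#'   per codon per unit rate
#' @param kappa transition/transversion rate ratio
#' @param pi codon frequencies: `"uniform"` or a 61-vector
#' @param omega per-edge dN/dS: a single value, a vector over
#'   `tree$edge` rows, or `list(background =, range = c(lo, hi),
#'   edges = <edge indices>)` to draw the focal edges' omega per gene
#' @param rate_mult per-edge rate multipliers (recycled; the elevated-rate
#'   lineage of the default scenario uses 20)
#' @param gene_lengths named integer vector of gene lengths in codons
#' @param seed mandatory RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(tree, kappa = 2, pi = "uniform", omega = 0.2,
                       rate_mult = 1, gene_lengths = c(gene1 = 300L),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(tree$tip.label) < 2L) stop("tree needs >= 2 leaves")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (identical(pi, "uniform")) pi <- rep(1 / 61, 61)
  if (kappa <= 0) stop("kappa must be > 0")
  ne <- nrow(tree$edge)
  rate_mult <- rep(rate_mult, length.out = ne)
  if (any(rate_mult < 0)) stop("rates must be >= 0")
  if (is.numeric(omega)) {
    if (any(omega < 0)) stop("omega must be >= 0")
    omega <- rep(omega, length.out = ne)
  } else if (is.list(omega)) {
    if (is.null(omega$background) || is.null(omega$range) ||
        is.null(omega$edges))
      stop("omega list needs background, range, edges")
    if (any(unlist(omega[c("background", "range")]) < 0))
      stop("omega must be >= 0")
  } else stop("invalid omega specification")
  structure(list(tree = tree, kappa = kappa, pi = pi, omega = omega,
                 rate_mult = rate_mult,
                 gene_lengths = gene_lengths, seed = as.integer(seed)),
            class = "sim_config")
}

# jump-chain tables for a rate matrix: exit rates + neighbour samplers
.sim_tables <- function(Q) {
  n <- nrow(Q)
  exit <- -diag(Q)
  nbr <- vector("list", n)
  prob <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(Q[i, ] > 0)
    nbr[[i]] <- js
    prob[[i]] <- Q[i, js] / exit[i]
  }
  list(exit = exit, nbr = nbr, prob = prob)
}

# Gillespie simulation of one branch; returns final states + event log
.sim_branch <- function(states, tabs, t_total, syn_lookup) {
  events <- list()
  ne <- 0L
  for (s in seq_along(states)) {
    t <- 0
    cur <- states[s]
    repeat {
      r <- tabs$exit[cur]
      if (r <= 0) break
      t <- t + rexp(1L, r)
      if (t > t_total) break
      nxt <- tabs$nbr[[cur]][sample.int(length(tabs$nbr[[cur]]), 1L,
                                        prob = tabs$prob[[cur]])]
      ne <- ne + 1L
      events[[ne]] <- c(s, cur, nxt)
      cur <- nxt
    }
    states[s] <- cur
  }
  if (ne) {
    ev <- do.call(rbind, events)
    ev <- data.frame(site = ev[, 1L], from = ev[, 2L], to = ev[, 3L])
    ev$synonymous <- syn_lookup[cbind(ev$from, ev$to)]
  } else {
    ev <- data.frame(site = integer(), from = integer(), to = integer(),
                     synonymous = logical())
  }
  list(states = states, events = ev)
}

# 61 x 61 logical lookup: is i -> j synonymous?
.syn_lookup <- function() {
  if (is.null(.mr_cache$syn_lookup)) {
    aa <- codon_aa(sense_codons())
    .mr_cache$syn_lookup <- outer(aa, aa, "==")
  }
  .mr_cache$syn_lookup
}

# resolve per-edge omega for one gene (drawing focal edges if configured)
.edge_omegas <- function(config) {
  om <- config$omega
  ne <- nrow(config$tree$edge)
  if (is.numeric(om)) return(om)
  out <- rep(om$background, ne)
  out[om$edges] <- runif(length(om$edges), om$range[1L], om$range[2L])
  out
}

#' Simulate a codon-aligned gene family on a tree
#'
#' Continuous-time GY94 evolution, one exact jump process per codon site
#' per branch, with branch-specific rate multipliers and omega.  Because
#' the state space is the 61 sense codons, generated coding sequences
#' never contain internal stops.  The returned truth records realized
#' synonymous/nonsynonymous substitution counts per branch and the full
#' per-branch event logs (replaying them reproduces every sequence).
#'
#' @param config a [sim_config()]
#' @param gene gene name; its length in codons is looked up in
#'   `config$gene_lengths` (a bare integer is also accepted)
#' @param tree optional replacement tree (same config otherwise), used for
#'   horizontally transferred copies simulated on a donor topology
#' @return list of class `gene_family_sim`: `cds` (named character,
#'   leaf coding sequences), `codons` (leaf x site codon matrix), `truth`
#'   (per-edge realized counts + drawn omega), `events` (per-edge logs),
#'   `root` (root codon states), `tree`
#' @export
simulate_gene_family <- function(config, gene, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.numeric(gene)) {
    L <- as.integer(gene); gene <- "gene"
  } else {
    L <- config$gene_lengths[[gene]]
    if (is.null(L)) stop("unknown gene: ", gene)
  }
  if (L < 30L) stop("gene length must be >= 30 codons")
  tr <- if (is.null(tree)) config$tree else tree
  idx <- if (!is.null(names(config$gene_lengths)))
    match(gene, names(config$gene_lengths)) else 1L
  if (is.na(idx)) idx <- 1L
  set.seed(config$seed + 7919L * idx)
  ne <- nrow(tr$edge)
  omg <- .edge_omegas(config)[seq_len(ne)]
  mult <- rep(config$rate_mult, length.out = ne)
  syn <- .syn_lookup()
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tr$Nnode)
  states[[root]] <- sample.int(61L, L, replace = TRUE, prob = config$pi)
  pre <- ape::reorder.phylo(tr, "cladewise")
  ord <- match(paste(pre$edge[, 1L], pre$edge[, 2L]),
               paste(tr$edge[, 1L], tr$edge[, 2L]))
  events <- vector("list", ne)
  truth <- data.frame(edge = seq_len(ne), parent = tr$edge[, 1L],
                      child = tr$edge[, 2L],
                      t_eff = tr$edge.length * mult, omega = omg,
                      syn_count = 0L, nonsyn_count = 0L)
  for (k in seq_len(ne)) {
    e <- ord[k]
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    Q <- gy94_rate_matrix(config$kappa, omg[e], config$pi)
    tabs <- .sim_tables(Q)
    sim <- .sim_branch(states[[p]], tabs, truth$t_eff[e], syn)
    states[[ch]] <- sim$states
    events[[e]] <- sim$events
    truth$syn_count[e] <- sum(sim$events$synonymous)
    truth$nonsyn_count[e] <- sum(!sim$events$synonymous)
  }
  cods <- sense_codons()
  codons <- t(vapply(seq_len(ntip), function(i) cods[states[[i]]],
                     character(L)))
  rownames(codons) <- tr$tip.label
  cds <- setNames(apply(codons, 1L, paste, collapse = ""), tr$tip.label)
  structure(list(gene = gene, cds = cds, codons = codons, truth = truth,
                 events = events, root = states[[root]], tree = tr),
            class = "gene_family_sim")
}

#' Replay a simulation's event log from the root
#'
#' Truth/emission consistency check: applying the recorded substitution
#' events along each branch must reproduce every leaf sequence exactly.
#'
#' @param sim a `gene_family_sim`
#' @return named character vector of reconstructed leaf sequences
#' @export
replay_sim <- function(sim) {
  tr <- sim$tree
  ntip <- length(tr$tip.label)
  states <- vector("list", ntip + tr$Nnode)
  states[[ntip + 1L]] <- sim$root
  pre <- ape::reorder.phylo(tr, "cladewise")
  ord <- match(paste(pre$edge[, 1L], pre$edge[, 2L]),
               paste(tr$edge[, 1L], tr$edge[, 2L]))
  for (k in seq_len(nrow(tr$edge))) {
    e <- ord[k]
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    st <- states[[p]]
    ev <- sim$events[[e]]
    if (nrow(ev)) for (r in seq_len(nrow(ev))) {
      stopifnot(st[ev$site[r]] == ev$from[r])
      st[ev$site[r]] <- ev$to[r]
    }
    states[[ch]] <- st
  }
  cods <- sense_codons()
  setNames(vapply(seq_len(ntip),
                  function(i) paste(cods[states[[i]]], collapse = ""),
                  ""), tr$tip.label)
}

#' Inject pseudogenization events into a coding sequence
#'
#' Event kinds: `frameshift` (single-base deletion at nucleotide `pos`, or
#' insertion of a random base when `insert = TRUE`), `nonsense` (codon at
#' codon-index `pos` replaced by TAA) and `truncation` (sequence cut to
#' `len` nucleotides).
#'
#' @param cds coding sequence
#' @param events list of lists: `list(type =, pos = / len =, insert =)`
#' @param seed RNG seed (inserted bases)
#' @return list: `seq` (mutated sequence), `truth` (data.frame of applied
#'   events with their final positions)
#' @export
inject_pseudogenization <- function(cds, events, seed = 1L) {
  set.seed(seed)
  cds <- toupper(cds)
  truth <- NULL
  # apply from 3' to 5' so earlier positions stay valid
  pos_of <- function(ev) switch(ev$type,
    frameshift = ev$pos,
    nonsense = 3L * ev$pos - 2L,
    truncation = ev$len,
    stop("unknown event type: ", ev$type))
  if (length(events)) {
    events <- events[order(-vapply(events, pos_of, 0))]
    for (ev in events) {
      n <- nchar(cds)
      if (ev$type == "frameshift") {
        if (ev$pos < 1L || ev$pos > n) stop("frameshift position beyond length")
        if (isTRUE(ev$insert)) {
          cds <- paste0(substr(cds, 1L, ev$pos), sample(.NUC, 1L),
                        substr(cds, ev$pos + 1L, n))
        } else {
          cds <- paste0(substr(cds, 1L, ev$pos - 1L),
                        substr(cds, ev$pos + 1L, n))
        }
        truth <- rbind(truth, data.frame(type = "frameshift", pos = ev$pos,
                                         detail = if (isTRUE(ev$insert))
                                           "insertion" else "deletion"))
      } else if (ev$type == "nonsense") {
        if (3L * ev$pos > n) stop("nonsense codon beyond length")
        cds <- paste0(substr(cds, 1L, 3L * ev$pos - 3L), "TAA",
                      substr(cds, 3L * ev$pos + 1L, n))
        truth <- rbind(truth, data.frame(type = "nonsense", pos = ev$pos,
                                         detail = "TAA"))
      } else if (ev$type == "truncation") {
        if (ev$len > n) stop("truncation length beyond sequence")
        cds <- substr(cds, 1L, ev$len)
        truth <- rbind(truth, data.frame(type = "truncation", pos = ev$len,
                                         detail = "3prime"))
      }
    }
  }
  list(seq = cds, truth = truth)
}

.PAIRING <- c("AT", "TA", "GC", "CG", "GT", "TG")

#' Evolve an rRNA sequence on a fixed secondary structure
#'
#' `n_subs` change events are placed at distinct positions.  Of the events
#' hitting paired positions, `floor(f_cbc * n)` are applied as full
#' compensatory double substitutions (both partners change, Watson-Crick
#' or GU pairing retained); the rest are disruptive single changes that
#' break the pairing.  Events at unpaired positions are ordinary
#' substitutions.
#'
#' @param struct a `secondary_structure` (see [parse_dotbracket()]); its
#'   `seq` is the ancestral sequence
#' @param n_subs number of change events (<= sequence length)
#' @param f_cbc fraction of paired-position changes made compensatory
#' @param seed RNG seed
#' @return list: `seq` (derived sequence, DNA alphabet), `truth`
#'   (data.frame: pos_i, pos_j, type in {compensatory, disruptive,
#'   unpaired}, ref_i, ref_j, new_i, new_j)
#' @export
simulate_rrna <- function(struct, n_subs, f_cbc, seed = 1L) {
  stopifnot(inherits(struct, "secondary_structure"))
  L <- nchar(struct$seq)
  if (n_subs > L) stop("n_subs exceeds sequence length")
  if (f_cbc < 0 || f_cbc > 1) stop("f_cbc must be in [0, 1]")
  set.seed(seed)
  s <- strsplit(struct$seq, "", fixed = TRUE)[[1L]]
  partner <- rep(NA_integer_, L)
  if (nrow(struct$pairs)) {
    partner[struct$pairs[, 1L]] <- struct$pairs[, 2L]
    partner[struct$pairs[, 2L]] <- struct$pairs[, 1L]
  }
  pool <- sample.int(L)
  chosen <- integer()
  for (p in pool) {
    if (length(chosen) >= n_subs) break
    if (p %in% chosen) next
    if (!is.na(partner[p]) && partner[p] %in% chosen) next
    chosen <- c(chosen, p)
  }
  paired <- chosen[!is.na(partner[chosen])]
  unpaired <- setdiff(chosen, paired)
  n_comp <- floor(f_cbc * length(paired))
  comp <- if (n_comp) paired[seq_len(n_comp)] else integer()
  disr <- setdiff(paired, comp)
  truth <- NULL
  other_base <- function(b) sample(setdiff(.NUC, b), 1L)
  for (p in comp) {
    q <- partner[p]
    i <- min(p, q); j <- max(p, q)
    cand <- .PAIRING[substr(.PAIRING, 1L, 1L) != s[i] &
                     substr(.PAIRING, 2L, 2L) != s[j]]
    new <- sample(cand, 1L)
    truth <- rbind(truth, data.frame(pos_i = i, pos_j = j,
                                     type = "compensatory",
                                     ref_i = s[i], ref_j = s[j],
                                     new_i = substr(new, 1L, 1L),
                                     new_j = substr(new, 2L, 2L)))
    s[i] <- substr(new, 1L, 1L); s[j] <- substr(new, 2L, 2L)
  }
  for (p in disr) {
    q <- partner[p]
    i <- min(p, q); j <- max(p, q)
    # change position p to a base that breaks pairing with the partner
    keepb <- s[if (p == i) j else i]
    cand <- setdiff(.NUC, s[p])
    bad <- vapply(cand, function(b) {
      pr <- if (p == i) paste0(b, keepb) else paste0(keepb, b)
      pr %in% .PAIRING
    }, logical(1L))
    cand <- if (all(bad)) cand else cand[!bad]
    new <- sample(cand, 1L)
    truth <- rbind(truth, data.frame(pos_i = i, pos_j = j,
                                     type = "disruptive",
                                     ref_i = s[i], ref_j = s[j],
                                     new_i = if (p == i) new else s[i],
                                     new_j = if (p == j) new else s[j]))
    s[p] <- new
  }
  for (p in unpaired) {
    new <- other_base(s[p])
    truth <- rbind(truth, data.frame(pos_i = p, pos_j = NA_integer_,
                                     type = "unpaired",
                                     ref_i = s[p], ref_j = NA_character_,
                                     new_i = new, new_j = NA_character_))
    s[p] <- new
  }
  if (is.null(truth))
    truth <- data.frame(pos_i = integer(), pos_j = integer(),
                        type = character(), ref_i = character(),
                        ref_j = character(), new_i = character(),
                        new_j = character())
  list(seq = paste(s, collapse = ""), truth = truth)
}

#' Generate a random helix-based secondary structure with its sequence
#'
#' Desk-scale stand-in for a reference rRNA: non-crossing helices of
#' Watson-Crick pairs embedded in unpaired sequence.
#'
#' @param len sequence length
#' @param n_helices number of helices
#' @param helix_len paired positions per helix side
#' @param seed RNG seed
#' @return a `secondary_structure`
#' @export
random_secondary_structure <- function(len = 240L, n_helices = 6L,
                                       helix_len = 5L, seed = 1L) {
  set.seed(seed)
  s <- sample(.NUC, len, replace = TRUE)
  need <- n_helices * (2L * helix_len + 6L)
  if (need > len) stop("structure does not fit the sequence length")
  db <- rep(".", len)
  pairs <- NULL
  # lay helices side by side (hairpins), non-crossing by construction
  slot <- floor(len / n_helices)
  for (h in seq_len(n_helices)) {
    off <- (h - 1L) * slot
    a <- off + sample.int(max(1L, slot - 2L * helix_len - 6L), 1L)
    for (k in seq_len(helix_len)) {
      i <- a + k - 1L
      j <- a + 2L * helix_len + 4L - k + 1L
      wc <- c(A = "T", C = "G", G = "C", T = "A")
      s[j] <- wc[[s[i]]]
      pairs <- rbind(pairs, c(i, j))
    }
  }
  db[pairs[, 1L]] <- "("
  db[pairs[, 2L]] <- ")"
  parse_dotbracket(paste(s, collapse = ""), paste(db, collapse = ""))
}

#' Assemble a mitogenome from gene sequences
#'
#' Genes are embedded in random spacer sequence on random strands, in a
#' shuffled order; selected genes are split into exons separated by
#' random intron sequence.  The record is circular; optionally the genome
#' is rotated so that one gene wraps the origin.
#'
#' @param gene_seqs named character vector of coding sequences
#' @param spacer `list(mean, sd, min)` for spacer lengths (nt)
#' @param split named list: gene -> number of exons (2 or 3)
#' @param intron_range intron length range (nt)
#' @param wrap_gene gene to place across the origin, or NULL
#' @param seq_id id for the assembled record
#' @param seed RNG seed
#' @return list: `genome` (named character of length 1, attribute
#'   `circular = TRUE`), `features` (truth [feature_table()]), `length`
#' @export
assemble_mitogenome <- function(gene_seqs, spacer = list(mean = 400, sd = 120,
                                                         min = 50),
                                split = list(), intron_range = c(200L, 600L),
                                wrap_gene = NULL, seq_id = "mitogenome",
                                seed = 1L) {
  if (!length(gene_seqs)) stop("gene set is empty")
  set.seed(seed)
  rand_seq <- function(n) paste(sample(.NUC, n, replace = TRUE),
                                collapse = "")
  spacer_len <- function() {
    n <- round(rnorm(1L, spacer$mean, spacer$sd))
    if (n < spacer$min) spacer$min else n
  }
  order_genes <- sample(names(gene_seqs))
  genome <- ""
  rows <- NULL
  for (g in order_genes) {
    genome <- paste0(genome, rand_seq(spacer_len()))
    cds <- gene_seqs[[g]]
    nex <- if (!is.null(split[[g]])) split[[g]] else 1L
    strand <- sample(c("+", "-"), 1L)
    # cassette = coding-strand sequence with introns; record exon intervals
    if (nex > 1L) {
      n <- nchar(cds)
      cuts <- sort(sample(seq(30L, n - 30L), nex - 1L))
      pieces <- substring(cds, c(1L, cuts + 1L), c(cuts, n))
      cass <- pieces[1L]
      ivs <- rbind(c(1L, nchar(pieces[1L])))
      for (k in 2L:nex) {
        intr <- rand_seq(sample(seq(intron_range[1L], intron_range[2L]), 1L))
        a <- nchar(cass) + nchar(intr) + 1L
        cass <- paste0(cass, intr, pieces[k])
        ivs <- rbind(ivs, c(a, a + nchar(pieces[k]) - 1L))
      }
    } else {
      cass <- cds
      ivs <- rbind(c(1L, nchar(cds)))
    }
    M <- nchar(cass)
    off <- nchar(genome)  # cassette occupies off+1 .. off+M
    if (strand == "+") {
      genome <- paste0(genome, cass)
      st <- off + ivs[, 1L]; en <- off + ivs[, 2L]
      rk <- seq_len(nrow(ivs))
    } else {
      genome <- paste0(genome, revcomp(cass))
      st <- off + M - ivs[, 2L] + 1L
      en <- off + M - ivs[, 1L] + 1L
      rk <- seq_len(nrow(ivs))  # rank 1 = 5' exon, highest genomic coords
    }
    rows <- rbind(rows, data.frame(gene = g, strand = strand, start = st,
                                   end = en, exon_rank = rk))
  }
  genome <- paste0(genome, rand_seq(spacer_len()))
  L <- nchar(genome)
  if (!is.null(wrap_gene)) {
    gx <- rows[rows$gene == wrap_gene, ]
    if (!nrow(gx)) stop("wrap_gene not in gene set")
    mid <- floor((min(gx$start) + max(gx$end)) / 2)
    # rotate so position mid+1 becomes position 1
    genome <- paste0(substr(genome, mid + 1L, L), substr(genome, 1L, mid))
    sh <- function(p) ((p - mid - 1L) %% L) + 1L
    ns <- sh(rows$start); ne <- sh(rows$end)
    wraps <- ne < ns
    ne[wraps] <- ne[wraps] + L
    rows$start <- ns; rows$end <- ne
  }
  ft <- feature_table(seq_id = seq_id,
                      feature_id = paste0(rows$gene, "_t"),
                      gene = rows$gene, type = "gene",
                      strand = rows$strand, start = rows$start,
                      end = rows$end, exon_rank = rows$exon_rank)
  out <- setNames(genome, seq_id)
  attr(out, "circular") <- setNames(TRUE, seq_id)
  list(genome = out, features = ft, length = L)
}

#' Extract a feature's spliced sequence from a genome
#'
#' Exons are spliced in `exon_rank` order; minus-strand exons are
#' reverse-complemented.  Intervals with `end` beyond the sequence length
#' wrap around the origin (circular records).
#'
#' @param genome named character vector (or plain string)
#' @param features a [feature_table()]
#' @param feature_id feature to extract
#' @return nucleotide string
#' @export
extract_feature <- function(genome, features, feature_id) {
  g <- genome[[1L]]
  L <- nchar(g)
  fx <- features[features$feature_id == feature_id, , drop = FALSE]
  if (!nrow(fx)) stop("no such feature: ", feature_id)
  fx <- fx[order(fx$exon_rank), , drop = FALSE]
  piece <- function(s, e) {
    if (e <= L) substr(g, s, e)
    else paste0(substr(g, s, L), substr(g, 1L, e - L))
  }
  out <- vapply(seq_len(nrow(fx)), function(k) {
    p <- piece(fx$start[k], fx$end[k])
    if (fx$strand[k] == "-") revcomp(p) else p
  }, "")
  paste(out, collapse = "")
}

#' Simulate a codon alignment under the selection-relaxation regime
#'
#' Sites fall into discrete omega categories; reference branches use the
#' category omega, test branches use it raised to the selection
#' intensity `k` (`k = 1` is the null of equal selective strength;
#' `k < 1` flattens omega towards 1, i.e. relaxation).
#'
#' @param tree [ape::phylo] with branch lengths (substitutions/codon)
#' @param n_codons alignment length
#' @param omega_cats category omega values (reference branches)
#' @param props category proportions (sum to 1)
#' @param k selection intensity on the test branches
#' @param test_edges integer indices into `tree$edge` rows
#' @param kappa transition/transversion ratio
#' @param seed RNG seed
#' @return named character vector of aligned coding sequences
#' @export
simulate_relax_alignment <- function(tree, n_codons,
                                     omega_cats = c(0.05, 0.5, 1.5),
                                     props = c(0.4, 0.4, 0.2), k = 1,
                                     test_edges = integer(), kappa = 2,
                                     seed = 1L) {
  stopifnot(abs(sum(props) - 1) < 1e-8, k > 0)
  set.seed(seed)
  ncat <- as.vector(stats::rmultinom(1L, n_codons, props))
  ne <- nrow(tree$edge)
  out <- NULL
  for (c0 in seq_along(omega_cats)) {
    if (ncat[c0] == 0L) next
    eo <- rep(omega_cats[c0], ne)
    eo[test_edges] <- omega_cats[c0]^k
    L <- max(30L, ncat[c0])
    cfg <- sim_config(tree, kappa = kappa, omega = eo,
                      gene_lengths = setNames(L, "blk"),
                      seed = seed + 101L * c0)
    sim <- simulate_gene_family(cfg, "blk")
    blk <- substring(sim$cds, 1L, 3L * ncat[c0])
    out <- if (is.null(out)) blk else paste0(out, blk)
  }
  names(out) <- tree$tip.label
  out
}

#' Simulate a nucleotide alignment under GTR+Gamma
#'
#' Companion simulator for the phylogenetic engine tests.
#'
#' @param tree [ape::phylo] with branch lengths (substitutions/site)
#' @param nsites alignment length
#' @param params model list as in [gtr_gamma_lnL()]
#' @param seed RNG seed
#' @return named character vector of aligned sequences
#' @export
simulate_gtr_alignment <- function(tree, nsites, params = list(), seed = 1L) {
  set.seed(seed)
  params <- .gtr_params(list(), c(params,
                                  if (is.null(params$pi))
                                    list(pi = rep(0.25, 4))))
  Q <- gtr_rate_matrix(params$rates, params$pi)
  eig <- .rev_eigen(Q, params$pi)
  cat_rates <- if (is.infinite(params$alpha)) 1
    else discrete_gamma(params$alpha, params$ncat)
  site_cat <- sample.int(length(cat_rates), nsites, replace = TRUE)
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- sample.int(4L, nsites, replace = TRUE,
                                    prob = params$pi)
  pre <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(pre$edge[, 1L], pre$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (k in seq_len(nrow(tree$edge))) {
    e <- ord[k]
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    child <- integer(nsites)
    for (ci in seq_along(cat_rates)) {
      P <- .pmat(eig, tree$edge.length[e] * cat_rates[ci])
      for (s0 in 1:4) {
        idx <- which(site_cat == ci & states[[p]] == s0)
        if (length(idx))
          child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                   prob = P[s0, ])
      }
    }
    states[[ch]] <- child
  }
  setNames(vapply(seq_len(ntip),
                  function(i) paste(.NUC[states[[i]]], collapse = ""), ""),
           tree$tip.label)
}
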
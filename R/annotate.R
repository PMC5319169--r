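# From HSPs to gene models and gene-status calls: colinear chaining,
# splice-aware classification with RNA-editing-aware stop detection, and
# the ORF-persistence probability used to argue that long ORFs in a
# hypermutating genome are maintained by selection, not chance.

#' Chain HSPs into gene-model candidates
#'
#' Dynamic programming over colinear HSPs (same query, same strand,
#' consistent query and subject order, genomic gap at most `max_gap`).
#' Chain score is the sum of member HSP scores minus a per-nucleotide
#' penalty on genomic gaps and query overlaps.  Consecutive chained HSPs
#' separated by less than `min_intron` on the genome are merged into one
#' exon; larger gaps become introns.  Ties are broken by leftmost genomic
#' start.
#'
#' @param hsps HSP data.frame (see [seeded_local_search()]); may mix
#'   queries and strands
#' @param gene gene name to label the models with
#' @param genome_length subject length (needed for minus-strand chains)
#' @param max_gap maximum genomic gap within a chain (nt)
#' @param gap_cost per-nucleotide chain gap penalty
#' @param overlap_slop maximum tolerated query overlap (nt)
#' @param min_intron genomic gaps at or above this become introns
#' @return list of `gene_model` objects sorted by decreasing chain score;
#'   each has `gene`, `query_id`, `strand`, `score`, `exons` (data.frame
#'   start/end/exon_rank, genomic plus-strand coordinates), `hsps`
#'   (member rows in 5'->3' query order) and `source`
#' @export
chain_hsps <- function(hsps, gene, genome_length, max_gap = 5000L,
                       gap_cost = 0.2, overlap_slop = 40L,
                       min_intron = 30L) {
  if (is.null(hsps) || !nrow(hsps)) return(list())
  models <- list()
  for (qid in unique(hsps$query_id)) for (strand in c("+", "-")) {
    hx <- hsps[hsps$query_id == qid & hsps$strand == strand, , drop = FALSE]
    if (!nrow(hx)) next
    # transformed subject coordinates: colinear with the query on both
    # strands (minus-strand HSPs flipped through the reverse complement)
    if (strand == "+") {
      hx$ts <- hx$s_start; hx$te <- hx$s_end
    } else {
      hx$ts <- genome_length - hx$s_end + 1L
      hx$te <- genome_length - hx$s_start + 1L
    }
    hx <- hx[order(hx$q_start, hx$ts), , drop = FALSE]
    n <- nrow(hx)
    best <- as.numeric(hx$score)
    prev <- rep(NA_integer_, n)
    if (n > 1L) for (j in 2:n) {
      i <- seq_len(j - 1L)
      qgap <- hx$q_start[j] - hx$q_end[i] - 1L
      sgap <- hx$ts[j] - hx$te[i] - 1L
      ok <- qgap >= -overlap_slop & sgap >= -overlap_slop & sgap <= max_gap
      if (!any(ok)) next
      pen <- gap_cost * pmax(0L, sgap[ok]) + 2 * pmax(0L, -qgap[ok]) +
        2 * pmax(0L, -sgap[ok])
      cand <- best[i][ok] + hx$score[j] - pen
      w <- which.max(cand)
      if (cand[w] > best[j]) {
        best[j] <- cand[w]
        prev[j] <- i[ok][w]
      }
    }
    end <- which.max(best)
    chain <- end
    while (!is.na(prev[chain[1L]])) chain <- c(prev[chain[1L]], chain)
    cx <- hx[chain, , drop = FALSE]
    # merge near-adjacent subject intervals into exons
    ex_s <- cx$ts[1L]; ex_e <- cx$te[1L]
    starts <- integer(); ends <- integer()
    if (nrow(cx) > 1L) for (k in 2L:nrow(cx)) {
      if (cx$ts[k] - ex_e - 1L < min_intron) {
        ex_e <- max(ex_e, cx$te[k])
      } else {
        starts <- c(starts, ex_s); ends <- c(ends, ex_e)
        ex_s <- cx$ts[k]; ex_e <- cx$te[k]
      }
    }
    starts <- c(starts, ex_s); ends <- c(ends, ex_e)
    # back-transform to genomic plus-strand coordinates
    if (strand == "+") {
      gs <- starts; ge <- ends; rank <- seq_along(starts)
    } else {
      gs <- genome_length - ends + 1L
      ge <- genome_length - starts + 1L
      rank <- seq_along(starts)  # rank 1 = 5' exon (highest coordinates)
    }
    models[[length(models) + 1L]] <- structure(
      list(gene = gene, query_id = qid, strand = strand,
           score = best[end],
           exons = data.frame(start = gs, end = ge, exon_rank = rank),
           hsps = cx[, setdiff(names(cx), c("ts", "te"))],
           source = if (!is.null(cx$strategy)) cx$strategy[1L] else NA),
      class = "gene_model")
  }
  models[order(-vapply(models, `[[`, 0, "score"),
               vapply(models, function(m) min(m$exons$start), 0))]
}

# stitch the chain's HSP alignments into one query-anchored alignment:
# query gaps between HSPs are filled with N against the query sequence
# (frame-neutral), query overlaps trim the downstream HSP
.model_alignment <- function(model) {
  hx <- model$hsps
  qa <- character(); sa <- character()
  qpos <- hx$q_start[1L]
  for (k in seq_len(nrow(hx))) {
    q <- strsplit(hx$q_aln[k], "", fixed = TRUE)[[1L]]
    s <- strsplit(hx$s_aln[k], "", fixed = TRUE)[[1L]]
    skip <- qpos - hx$q_start[k]   # >0: query overlap to trim
    if (skip > 0L) {
      adv <- cumsum(q != "-")
      cut <- which(adv == skip)[1L]
      if (is.na(cut) || cut >= length(q)) next
      q <- q[-seq_len(cut)]; s <- s[-seq_len(cut)]
    } else if (skip < 0L) {
      # unaligned query stretch between exons: pad with frame-neutral N
      qa <- c(qa, rep("?", -skip))
      sa <- c(sa, rep("N", -skip))
    }
    qa <- c(qa, q); sa <- c(sa, s)
    qpos <- max(qpos, hx$q_end[k] + 1L)
  }
  list(q = qa, s = sa, q_start = hx$q_start[1L], q_end = qpos - 1L)
}

#' Classify a gene model as intact, truncated, pseudogene or absent
#'
#' The chained HSP alignments are stitched into a query-anchored
#' alignment (inter-exon query gaps padded with `N`, which can never look
#' like a stop).  The subject is then read codon-by-codon in the
#' reference frame: any within-exon gap run whose length is not a
#' multiple of 3 is a frameshift; any subject stop codon aligned to a
#' non-terminal reference codon is a premature stop, unless that codon is
#' listed in the RNA-editing table (edited codons are skipped for stop
#' detection).  Disruption-free models are `intact` when the aligned
#' fraction of the reference is at least `thresholds$full` (default
#' 0.80), `truncated_intact` in `[thresholds$trunc, full)` (default 0.60,
#' the sdh3 regime), and `pseudogene` with reason `below_length_fraction`
#' below that.  A missing or sub-threshold model is `absent`.
#'
#' @param model a `gene_model` from [chain_hsps()], or NULL
#' @param reference_cds coding sequence of the reference/query gene
#'   (defines length and the codon frame)
#' @param genome genome string (used to report the spliced gene length)
#' @param editing optional `editing_table`
#' @param thresholds list: `full`, `trunc`, `min_chain_score`,
#'   `min_coverage`
#' @return list of class `gene_status`: `gene`, `status`, `reasons`
#'   (character vector like `premature_stop(12)`), `length_fraction`,
#'   `length_nt`, `ref_length_nt`, `pct_id`
#' @export
classify_gene_status <- function(model, reference_cds, genome = NULL,
                                 editing = NULL,
                                 thresholds = list()) {
  th <- modifyList(list(full = 0.80, trunc = 0.60, min_chain_score = 150,
                        min_coverage = 0.30), thresholds)
  refN <- nchar(reference_cds)
  gene <- if (!is.null(model)) model$gene else NA_character_
  absent <- function() structure(
    list(gene = gene, status = "absent", reasons = "no_hsp",
         length_fraction = 0, length_nt = 0L, ref_length_nt = refN,
         pct_id = NA_real_), class = "gene_status")
  if (is.null(model)) return(absent())
  aln <- .model_alignment(model)
  covered <- sum(aln$q != "-" & aln$s != "-" & aln$s != "N")
  if (model$score < th$min_chain_score || covered / refN < th$min_coverage)
    return(absent())
  edited <- edited_codons_for(editing, model$gene)
  if (length(edited) && any(3L * edited > refN))
    stop("editing index beyond reference gene ", model$gene)
  reasons <- character()
  qnum <- cumsum(aln$q != "-")          # query position per column
  # frameshifts: gap runs are grouped when separated by fewer than 30
  # aligned columns, and a group is a frameshift only when its NET indel
  # length is not a multiple of 3 -- a compensating gap pair introduced
  # by the aligner in a noisy region nets to zero and is not a real
  # disruption, whereas a genuine single-base indel shifts the frame
  # permanently
  delta <- ifelse(aln$s == "-", -1L, ifelse(aln$q == "-", 1L, 0L))
  idx <- which(delta != 0L)
  if (length(idx)) {
    grp <- cumsum(c(1L, diff(idx) > 30L))
    for (g in unique(grp)) {
      cols <- idx[grp == g]
      net <- sum(delta[cols])
      if (net %% 3L != 0L) {
        qp <- aln$q_start + max(qnum[cols[1L]], 1L) - 1L
        reasons <- c(reasons, paste0("frameshift(", qp, ")"))
      }
    }
  }
  # premature stops, reading the subject in the reference codon frame;
  # codons inside frame-shifted alignment windows (cumulative net indel
  # offset not 0 mod 3) are skipped -- their subject triplet is not in
  # the reference frame
  qglob <- ifelse(aln$q == "-", NA, qnum + aln$q_start - 1L)
  off_col <- cumsum(delta)
  ref_codons <- refN %/% 3L
  first_c <- ceiling(aln$q_start / 3) + (aln$q_start %% 3L != 1L)
  last_full <- (aln$q_end) %/% 3L
  # column index of each query position (qglob is non-decreasing over
  # the non-gap columns, so a single match() pass suffices)
  colpos <- match(seq_len(refN), qglob)
  stops_at <- integer()
  for (cc in seq_len(ref_codons)) {
    if (cc < first_c || cc > last_full) next
    if (cc %in% edited) next
    if (cc >= ref_codons) next                    # terminal codon
    cols <- colpos[(3L * cc - 2L):(3L * cc)]
    if (anyNA(cols) || cols[3L] != cols[1L] + 2L) next
    if (any(off_col[cols] %% 3L != 0L)) next
    sub <- paste(aln$s[cols], collapse = "")
    if (sub %in% .STOPS && cc < last_full)
      stops_at <- c(stops_at, cc)
  }
  if (length(stops_at))
    reasons <- c(reasons, paste0("premature_stop(", stops_at, ")"))
  frac <- covered / refN
  pid <- {
    keep <- aln$q != "-" & aln$s != "-" & aln$s != "N"
    if (any(keep)) 100 * sum(aln$q[keep] == aln$s[keep]) / sum(keep)
    else NA_real_
  }
  length_nt <- sum(model$exons$end - model$exons$start + 1L)
  status <- if (length(reasons)) "pseudogene"
    else if (frac >= th$full) "intact"
    else if (frac >= th$trunc) "truncated_intact"
    else {
      reasons <- paste0("below_length_fraction(", round(frac, 2), ")")
      "pseudogene"
    }
  structure(list(gene = model$gene, status = status, reasons = reasons,
                 length_fraction = frac, length_nt = length_nt,
                 ref_length_nt = refN, pct_id = pid),
            class = "gene_status")
}

#' Probability that an ORF survives random substitution
#'
#' Probability that `n_subs` substitutions, each uniform over the `3 * L`
#' positions and the 3 alternative bases, leave a reading frame free of
#' internal stops.  Analytic mode treats each codon as an absorbing
#' Markov chain over the 64 codon states (stops absorbing), with the
#' number of hits per codon binomial -- exact within codons, independent
#' across codons; `method = "mc"` simulates the full process.
#'
#' @param L_codons ORF length in codons (ignored when `sequence` given)
#' @param n_subs number of substitutions
#' @param base_composition frequencies of A, C, G, T (sum to 1)
#' @param sequence optional explicit in-frame sequence
#' @param method `"analytic"` or `"mc"`
#' @param n_rep Monte-Carlo replicates
#' @param seed RNG seed for `"mc"`
#' @return probability in `[0, 1]`
#' @export
orf_persistence_probability <- function(L_codons, n_subs,
                                        base_composition = rep(0.25, 4),
                                        sequence = NULL,
                                        method = c("analytic", "mc"),
                                        n_rep = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (abs(sum(base_composition) - 1) > 1e-8)
    stop("base composition must sum to 1")
  if (n_subs < 0) stop("n_subs must be >= 0")
  if (n_subs == 0) return(1)
  if (!is.null(sequence)) L_codons <- nchar(sequence) %/% 3L
  if (L_codons < 1) stop("L_codons must be >= 1")
  if (method == "analytic") {
    cods <- all_codons()
    sense <- !(cods %in% .STOPS)
    # single-substitution transition matrix over codons: each of the 9
    # neighbours with probability 1/9; transitions INTO a stop are lost
    # (absorbing), so row sums of the sense-state sub-matrix give the
    # per-hit survival
    S <- matrix(0, 64L, 64L, dimnames = list(cods, cods))
    for (ci in seq_along(cods)) {
      for (p in 1:3) for (b in setdiff(.NUC, substr(cods[ci], p, p))) {
        mut <- cods[ci]
        substr(mut, p, p) <- b
        S[ci, mut] <- S[ci, mut] + 1 / 9
      }
    }
    # the ORF is "maintained" when the FINAL codon is not a stop (a
    # codon may pass through a stop state and mutate away again)
    mmax <- min(n_subs, qbinom(1 - 1e-12, n_subs, 1 / L_codons) + 2L)
    surv <- matrix(0, sum(sense), mmax + 1L)
    v <- diag(64L)
    surv[, 1L] <- 1
    for (m in seq_len(mmax)) {
      v <- v %*% S
      surv[, m + 1L] <- 1 - rowSums(v[sense, !sense, drop = FALSE])
    }
    wts <- dbinom(0:mmax, n_subs, 1 / L_codons)
    wts <- wts / sum(wts)
    per_state <- as.vector(surv %*% wts)
    names(per_state) <- cods[sense]
    if (!is.null(sequence)) {
      start <- split_codons(sequence)
      if (any(start %in% .STOPS)) stop("sequence already contains a stop")
      return(prod(per_state[start]))
    }
    pc <- apply(do.call(rbind, strsplit(cods, "", fixed = TRUE)), 1L,
                function(v0) prod(base_composition[match(v0, .NUC)]))
    pc <- pc[sense] / sum(pc[sense])
    return(sum(pc * per_state)^L_codons)
  }
  # Monte Carlo
  set.seed(seed)
  ok <- 0L
  for (r in seq_len(n_rep)) {
    cods <- if (!is.null(sequence)) split_codons(sequence)
      else {
        repeat {
          cv <- paste0(sample(.NUC, L_codons, TRUE, base_composition),
                       sample(.NUC, L_codons, TRUE, base_composition),
                       sample(.NUC, L_codons, TRUE, base_composition))
          if (!any(cv %in% .STOPS)) break
        }
        cv
      }
    seqv <- strsplit(paste(cods, collapse = ""), "", fixed = TRUE)[[1L]]
    pos <- sample.int(3L * L_codons, n_subs, replace = TRUE)
    for (p in pos) seqv[p] <- sample(setdiff(.NUC, seqv[p]), 1L)
    cods2 <- substring(paste(seqv, collapse = ""),
                       seq(1L, 3L * L_codons, 3L), seq(3L, 3L * L_codons, 3L))
    if (!any(cods2 %in% .STOPS)) ok <- ok + 1L
  }
  ok / n_rep
}

#' Annotate a genome against a reference panel and a close relative
#'
#' Runs the dual-strategy search, chains HSPs per gene, and classifies
#' every panel gene.  Classification uses the close-relative gene as the
#' reference frame when available (it is far closer), falling back to the
#' panel copy.
#'
#' @param genome named character vector of length 1 (the genome)
#' @param panel named character vector, names `taxon|gene` or `gene`
#' @param relative_genes named character vector, names `gene`
#' @param editing optional `editing_table`
#' @param thresholds classification thresholds (see
#'   [classify_gene_status()])
#' @param circular is the genome circular?
#' @param max_gap,min_intron chaining parameters
#' @return list of class `annotation`: `status` (data.frame: gene,
#'   status, length_nt, ref_length_nt, pct_id_vs_panel,
#'   pct_id_vs_relative, reasons), `models` (best model per gene),
#'   `features` ([feature_table()] of non-absent genes), `hsps`
#' @export
annotate_genome <- function(genome, panel, relative_genes = NULL,
                            editing = NULL, thresholds = list(),
                            circular = TRUE, max_gap = 5000L,
                            min_intron = 30L) {
  hsps <- dual_strategy_search(genome, panel, relative_genes,
                               circular = circular)
  glen <- nchar(genome[[1L]])
  gene_of <- function(id) sub("^[^|]*\\|", "", id)
  genes <- sort(unique(gene_of(c(names(panel), names(relative_genes)))))
  status <- NULL
  models <- list()
  feats <- NULL
  cover_of <- function(m, refN) {
    a <- .model_alignment(m)
    sum(a$q != "-" & a$s != "-" & a$s != "N") / refN
  }
  for (g in genes) {
    hx <- hsps[hsps$gene == g, , drop = FALSE]
    mods <- chain_hsps(hx, g, glen, max_gap = max_gap,
                       min_intron = min_intron)
    # chain scores from the two scoring schemes are not comparable;
    # prefer the close-relative model (far less alignment noise) unless
    # the panel model covers substantially more of the gene
    model <- if (length(mods)) {
      src <- vapply(mods, `[[`, "", "source")
      rel <- mods[src == "close_relative"]
      pan <- mods[src == "distant_panel"]
      refN <- if (g %in% names(relative_genes))
        nchar(relative_genes[[g]])
      else nchar(panel[[which(gene_of(names(panel)) == g)[1L]]])
      if (length(rel) && length(pan)) {
        if (cover_of(rel[[1L]], refN) >= cover_of(pan[[1L]], refN) - 0.15)
          rel[[1L]] else pan[[1L]]
      } else if (length(rel)) rel[[1L]] else pan[[1L]]
    } else NULL
    ref <- if (!is.null(relative_genes) && g %in% names(relative_genes) &&
               !is.null(model) && model$source == "close_relative")
      relative_genes[[g]]
    else {
      pid <- names(panel)[gene_of(names(panel)) == g][1L]
      if (!is.na(pid)) panel[[pid]] else relative_genes[[g]]
    }
    call <- classify_gene_status(model, ref, genome, editing, thresholds)
    # identity of the top-scoring HSP per strategy (high-identity random
    # micro-HSPs must not win over the long homology HSP)
    top_pid <- function(tag) {
      sel <- hx$strategy == tag
      if (!any(sel)) return(NA_real_)
      hx$pident[sel][which.max(hx$score[sel])]
    }
    pid_panel <- top_pid("distant_panel")
    pid_rel <- top_pid("close_relative")
    status <- rbind(status, data.frame(
      gene = g, status = call$status, length_nt = call$length_nt,
      ref_length_nt = call$ref_length_nt,
      length_fraction = call$length_fraction,
      pct_id_vs_panel = pid_panel, pct_id_vs_relative = pid_rel,
      reasons = paste(call$reasons, collapse = ";"),
      stringsAsFactors = FALSE))
    if (call$status != "absent" && !is.null(model)) {
      models[[g]] <- model
      feats <- rbind(feats, feature_table(
        seq_id = names(genome)[1L], feature_id = g, gene = g,
        type = "gene", strand = model$strand,
        start = model$exons$start, end = model$exons$end,
        exon_rank = model$exons$exon_rank))
    }
  }
  if (!is.null(feats)) class(feats) <- c("feature_table", "data.frame")
  structure(list(status = status, models = models, features = feats,
                 hsps = hsps), class = "annotation")
}
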
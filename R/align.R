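# Homology search: scoring schemes, the exact local-alignment oracle and
# the seeded (BLAST-style) search used for genome annotation.

#' Construct a nucleotide scoring scheme
#'
#' A gap of length k costs `gap_open + k * gap_extend` (BLAST convention),
#' so published BLASTN settings are directly usable.
#'
#' @param word_size exact-match seed length (>= 4)
#' @param reward match reward (> 0)
#' @param penalty mismatch penalty (< 0)
#' @param gap_open,gap_extend affine gap costs (>= 0)
#' @param xdrop X-drop threshold for seed extension (raw score)
#' @param min_score minimum HSP raw score reported
#' @param min_pident minimum HSP percent identity reported
#' @return list of class `scoring_scheme`
#' @export
scoring_scheme <- function(word_size = 11L, reward = 2L, penalty = -3L,
                           gap_open = 5L, gap_extend = 2L, xdrop = 40L,
                           min_score = 30L, min_pident = 0,
                           trigger = min_score) {
  stopifnot(word_size >= 4L, reward > 0L, penalty < 0L,
            gap_open >= 0L, gap_extend >= 0L)
  structure(list(word_size = as.integer(word_size),
                 reward = as.integer(reward), penalty = as.integer(penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop = as.integer(xdrop),
                 min_score = as.integer(min_score),
                 min_pident = as.numeric(min_pident),
                 trigger = as.integer(trigger)),
            class = "scoring_scheme")
}

#' Sensitive scoring scheme for highly divergent homologs
#'
#' Word size 7, reward 5, penalty -4, gap open 8, gap extend 6, with a
#' 20% identity floor: the settings that recover gene remnants at 40%+
#' nucleotide divergence where default parameters return nothing.
#'
#' @param min_score minimum HSP raw score (raw-score filtering is used
#'   instead of E-values)
#' @return a [scoring_scheme()]
#' @export
sensitive_scheme <- function(min_score = 50L) {
  scoring_scheme(word_size = 7L, reward = 5L, penalty = -4L, gap_open = 8L,
                 gap_extend = 6L, xdrop = 40L, min_score = min_score,
                 min_pident = 20, trigger = 60L)
}

#' Default (close-relative) scoring scheme
#'
#' Standard BLASTN-like parameters (word size 11, reward 2, penalty -3,
#' gap open 5, gap extend 2) for queries from a close relative.
#'
#' @return a [scoring_scheme()]
#' @export
default_scheme <- function() scoring_scheme()

.check_nt <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop(what, " must be a non-empty nucleotide string")
  if (grepl("[^ACGTNacgtn]", x)) stop(what, " contains non-ACGTN characters")
  toupper(x)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact dynamic programming over the full DP matrix; serves as the oracle
#' that bounds every score reported by [seeded_local_search()].
#'
#' @param a,b nucleotide strings (query, subject)
#' @param scheme a [scoring_scheme()]; only its reward/penalty/gap costs
#'   are used
#' @return list with `score`, 1-based `q_start`, `q_end`, `s_start`,
#'   `s_end`, and aligned strings `q_aln`, `s_aln`.  A score of 0 means no
#'   positive-scoring local alignment exists (empty alignment).
#' @export
smith_waterman <- function(a, b, scheme = sensitive_scheme()) {
  a <- .check_nt(a, "a"); b <- .check_nt(b, "b")
  cpp_smith_waterman(a, b, scheme$reward, scheme$penalty,
                     scheme$gap_open, scheme$gap_extend)
}

#' Seeded local similarity search
#'
#' Every maximal exact word match of length `word_size` seeds an ungapped
#' X-drop extension; extensions reaching `ungapped_trigger` enter a gapped
#' stage (optimal local DP in an adaptively re-expanded window around the
#' ungapped HSP).  Both strands are searched; minus-strand HSPs carry
#' forward query coordinates and subject coordinates on the plus strand.
#' On a circular subject the first `wrap` bases are virtually appended so
#' HSPs may cross the origin (`s_end` then exceeds the subject length).
#'
#' @param query,subject nucleotide strings
#' @param scheme a [scoring_scheme()]
#' @param both_strands search the reverse complement of the query too?
#' @param circular treat the subject as circular?
#' @param query_id,subject_id ids recorded in the result
#' @param ungapped_trigger minimum ungapped score to attempt the gapped
#'   stage (a speed heuristic; homologies whose every ungapped segment
#'   scores below this are missed)
#' @param pad initial window padding for the gapped stage (nt)
#' @return data.frame of HSPs: query/subject ids and 1-based intervals,
#'   `strand`, raw `score`, `pident` (matches / alignment columns), and
#'   the aligned strings
#' @export
seeded_local_search <- function(query, subject, scheme = sensitive_scheme(),
                                both_strands = TRUE, circular = FALSE,
                                query_id = "query", subject_id = "subject",
                                ungapped_trigger = NULL, pad = 100L) {
  query <- .check_nt(query, "query"); subject <- .check_nt(subject, "subject")
  if (is.null(ungapped_trigger))
    ungapped_trigger <- if (!is.null(scheme$trigger)) scheme$trigger
      else min(scheme$min_score, 50L)
  L <- nchar(subject)
  wrap <- 0L
  if (circular && L > scheme$word_size) {
    wrap <- min(L - 1L, 3000L)
    subject <- paste0(subject, substr(subject, 1L, wrap))
  }
  run1 <- function(q, strand) {
    h <- cpp_seed_extend(q, subject, scheme$word_size, scheme$reward,
                         scheme$penalty, scheme$gap_open, scheme$gap_extend,
                         scheme$xdrop, scheme$min_score, scheme$min_pident,
                         as.integer(ungapped_trigger), as.integer(pad))
    if (!nrow(h)) return(NULL)
    if (strand == "-") {
      # map back to forward-query coordinates and flip the aligned
      # strings, so q_aln always ascends along the forward query and
      # s_aln is the subject's reverse complement (the gene's coding
      # strand)
      n <- nchar(q)
      qs <- n - h$q_end + 1L
      qe <- n - h$q_start + 1L
      h$q_start <- qs; h$q_end <- qe
      h$q_aln <- vapply(h$q_aln, revcomp, "")
      h$s_aln <- vapply(h$s_aln, revcomp, "")
    }
    h$strand <- strand
    h
  }
  out <- run1(query, "+")
  if (both_strands) out <- rbind(out, run1(revcomp(query), "-"))
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(query_id = character(), subject_id = character(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), score = integer(),
                      pident = numeric(), q_aln = character(),
                      s_aln = character(), stringsAsFactors = FALSE)
    return(out)
  }
  if (wrap > 0L) {
    # drop HSPs living entirely in the appended copy (reported already at
    # their original location)
    out <- out[out$s_start <= L, , drop = FALSE]
  }
  out$query_id <- query_id
  out$subject_id <- subject_id
  out <- out[order(-out$score), c("query_id", "subject_id", "q_start",
                                  "q_end", "s_start", "s_end", "strand",
                                  "score", "pident", "q_aln", "s_aln")]
  rownames(out) <- NULL
  out
}

#' Dual-strategy homology search
#'
#' Runs the sensitive scheme with a panel of divergent reference genes and
#' the default scheme with genes from a close relative, and merges the HSP
#' sets with a `strategy` provenance tag.  Both strategies are needed:
#' close-relative queries are far more effective for a fast-evolving
#' genome, but alone would miss genes absent from the relative.
#'
#' @param genome subject genome (single nucleotide string, or a
#'   one-element named vector from [read_fasta()])
#' @param distant_panel named character vector of panel gene sequences
#'   (names `gene` or `taxon|gene`)
#' @param close_relative_genes named character vector of close-relative
#'   gene sequences
#' @param panel_scheme,relative_scheme scoring schemes for the two passes
#' @param circular is the genome circular?
#' @return HSP data.frame (see [seeded_local_search()]) with extra columns
#'   `gene` and `strategy` (`distant_panel` / `close_relative`)
#' @export
dual_strategy_search <- function(genome, distant_panel = NULL,
                                 close_relative_genes = NULL,
                                 panel_scheme = sensitive_scheme(),
                                 relative_scheme = default_scheme(),
                                 circular = FALSE) {
  if ((is.null(distant_panel) || !length(distant_panel)) &&
      (is.null(close_relative_genes) || !length(close_relative_genes)))
    stop("both query sets are empty")
  subject_id <- if (!is.null(names(genome)) && length(genome) == 1L)
    names(genome) else "genome"
  genome <- genome[[1L]]
  gene_of <- function(id) sub("^[^|]*\\|", "", id)
  run_set <- function(queries, scheme, tag) {
    out <- NULL
    for (id in names(queries)) {
      h <- seeded_local_search(queries[[id]], genome, scheme,
                               circular = circular, query_id = id,
                               subject_id = subject_id)
      if (nrow(h)) {
        h$gene <- gene_of(id)
        h$strategy <- tag
        out <- rbind(out, h)
      }
    }
    out
  }
  out <- rbind(run_set(distant_panel, panel_scheme, "distant_panel"),
               run_set(close_relative_genes, relative_scheme,
                       "close_relative"))
  if (is.null(out))
    out <- data.frame(query_id = character(), subject_id = character(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), score = integer(),
                      pident = numeric(), q_aln = character(),
                      s_aln = character(), gene = character(),
                      strategy = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percent identity of an aligned pair, excluding gap columns
#'
#' The Table-1 convention: columns containing a gap in either sequence are
#' excluded from both numerator and denominator.
#'
#' @param a,b equal-length aligned strings (gaps as `-`)
#' @return percent identity in `[0, 100]`
#' @export
percent_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned strings differ in length")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  keep <- av != "-" & bv != "-"
  if (!any(keep)) stop("no gap-free columns: identity undefined")
  100 * sum(av[keep] == bv[keep]) / sum(keep)
}
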
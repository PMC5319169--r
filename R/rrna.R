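# Superposition of divergent rRNA sequences onto reference secondary
# structures: mapping base pairs through a pairwise alignment, counting
# compensatory vs disruptive changes, and conserved-core identity.

#' Map reference structure pairs through a pairwise alignment
#'
#' @param ref reference sequence (must equal the structure's sequence)
#' @param struct a `secondary_structure` (see [parse_dotbracket()])
#' @param alignment named character vector of TWO aligned rows: the
#'   reference (named like `ref_id`) and the query; rows are identified
#'   by name, so order does not matter
#' @param ref_id,query_id row names in `alignment`
#' @return data.frame of class `pair_map`: ref_i, ref_j, query_i,
#'   query_j (NA where the query has a deletion), plus the aligned
#'   column indices
#' @export
map_structure <- function(ref, struct, alignment, ref_id = "ref",
                          query_id = "query") {
  stopifnot(inherits(struct, "secondary_structure"))
  ref <- gsub("U", "T", toupper(ref), fixed = TRUE)
  if (nchar(ref) != nchar(struct$seq))
    stop("structure length (", nchar(struct$seq),
         ") does not match reference length (", nchar(ref), ")")
  if (!all(c(ref_id, query_id) %in% names(alignment)))
    stop("alignment must contain rows named '", ref_id, "' and '",
         query_id, "'")
  ra <- strsplit(gsub("U", "T", toupper(alignment[[ref_id]])), "")[[1L]]
  qa <- strsplit(gsub("U", "T", toupper(alignment[[query_id]])), "")[[1L]]
  if (length(ra) != length(qa)) stop("alignment rows differ in length")
  if (paste(ra[ra != "-"], collapse = "") != ref)
    stop("alignment row '", ref_id, "' does not spell the reference ",
         "sequence; are the rows swapped?")
  ref_pos <- cumsum(ra != "-")
  q_pos <- cumsum(qa != "-")
  col_of_ref <- match(seq_len(nchar(ref)), ref_pos)
  qpos_at <- function(i) {
    cl <- col_of_ref[i]
    if (qa[cl] == "-") NA_integer_ else q_pos[cl]
  }
  pr <- struct$pairs
  out <- data.frame(
    ref_i = pr[, 1L], ref_j = pr[, 2L],
    query_i = vapply(pr[, 1L], qpos_at, 0L),
    query_j = vapply(pr[, 2L], qpos_at, 0L),
    col_i = col_of_ref[pr[, 1L]], col_j = col_of_ref[pr[, 2L]])
  attr(out, "ref_id") <- ref_id
  attr(out, "query_id") <- query_id
  class(out) <- c("pair_map", "data.frame")
  out
}

.pairs_ok <- function(a, b) paste0(a, b) %in% .PAIRING

#' Classify base-pair changes as compensatory, half or disruptive
#'
#' For each mapped reference pair, the query nucleotides are compared to
#' the reference: pairing is retained when the query pair is one of
#' AU/UA, GC/CG, GU/UG.  Changed pairs partition into fully compensatory
#' (both partners changed, pairing retained), half (one partner changed,
#' pairing retained, e.g. GC to GU wobble) and disruptive (pairing
#' lost); pairs with a deleted partner are counted separately.
#'
#' @param map a `pair_map` from [map_structure()]
#' @param ref_seq,query_seq ungapped sequences (DNA or RNA alphabet)
#' @return list of class `cbc_report` with counts `n_paired_positions`,
#'   `n_unchanged`, `n_fully_compensatory`, `n_half`, `n_disruptive`,
#'   `n_pair_deleted` and a per-pair `detail` data.frame
#' @export
classify_paired_changes <- function(map, ref_seq, query_seq) {
  ref <- strsplit(gsub("U", "T", toupper(ref_seq)), "")[[1L]]
  qry <- strsplit(gsub("U", "T", toupper(query_seq)), "")[[1L]]
  n <- nrow(map)
  cls <- character(n)
  for (k in seq_len(n)) {
    ri <- ref[map$ref_i[k]]; rj <- ref[map$ref_j[k]]
    if (is.na(map$query_i[k]) || is.na(map$query_j[k])) {
      cls[k] <- "pair_deleted"; next
    }
    qi <- qry[map$query_i[k]]; qj <- qry[map$query_j[k]]
    changed <- (qi != ri) + (qj != rj)
    if (changed == 0L) cls[k] <- "unchanged"
    else if (!.pairs_ok(qi, qj)) cls[k] <- "disruptive"
    else if (changed == 2L) cls[k] <- "compensatory"
    else cls[k] <- "half"
  }
  detail <- cbind(map, class = cls)
  structure(list(n_paired_positions = 2L * n,
                 n_pairs = n,
                 n_unchanged = sum(cls == "unchanged"),
                 n_fully_compensatory = sum(cls == "compensatory"),
                 n_half = sum(cls == "half"),
                 n_disruptive = sum(cls == "disruptive"),
                 n_pair_deleted = sum(cls == "pair_deleted"),
                 detail = detail),
            class = "cbc_report")
}

#' Percent identity inside and outside a conserved core
#'
#' Gap-excluded identity (the [percent_identity()] rule) computed
#' separately for alignment columns whose reference position falls
#' inside / outside the core mask.
#'
#' @param alignment named character vector of two aligned rows (reference
#'   first, or give `ref_id`)
#' @param core_mask integer vector of reference positions forming the
#'   conserved core (non-empty)
#' @param ref_id name of the reference row (default: first)
#' @return list: `core`, `non_core` (percent identities; NA when a
#'   partition has no gap-free columns)
#' @export
conserved_core_identity <- function(alignment, core_mask,
                                    ref_id = names(alignment)[1L]) {
  if (!length(core_mask)) stop("empty core mask")
  other <- setdiff(names(alignment), ref_id)[1L]
  ra <- strsplit(gsub("U", "T", toupper(alignment[[ref_id]])), "")[[1L]]
  qa <- strsplit(gsub("U", "T", toupper(alignment[[other]])), "")[[1L]]
  ref_pos <- cumsum(ra != "-")
  in_core <- ra != "-" & ref_pos %in% core_mask
  pid <- function(sel) {
    keep <- sel & ra != "-" & qa != "-"
    if (!any(keep)) return(NA_real_)
    100 * sum(ra[keep] == qa[keep]) / sum(keep)
  }
  list(core = pid(in_core), non_core = pid(!in_core & ra != "-"))
}

#' Align a query rRNA to a reference (global, affine gaps)
#'
#' Convenience wrapper producing the two-row alignment consumed by
#' [map_structure()], using Needleman-Wunsch with free end gaps via
#' Biostrings.
#'
#' @param ref,query nucleotide strings
#' @param ref_id,query_id row names for the result
#' @return named character vector of two aligned rows
#' @export
align_rrna <- function(ref, query, ref_id = "ref", query_id = "query") {
  ref <- gsub("U", "T", toupper(ref), fixed = TRUE)
  query <- gsub("U", "T", toupper(query), fixed = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(query),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = TRUE),
    gapOpening = 6, gapExtension = 1)
  setNames(c(as.character(Biostrings::alignedPattern(pa)),
             as.character(Biostrings::alignedSubject(pa))),
           c(ref_id, query_id))
}
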
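# Readers and writers for the interchange formats used throughout the
# package: FASTA, GFF3, newick, dot-bracket secondary structures and
# RNA-editing site tables.  All internal coordinates are 1-based inclusive,
# the same convention GFF3 uses on output.

#' Read a (multi-)FASTA file
#'
#' Residues are upper-cased; for nucleotide input `U` is mapped to `T` and
#' any character outside `A,C,G,T,N` is rejected.  Duplicate ids and
#' header-only (empty) records are errors.
#'
#' @param path path to a FASTA file
#' @param moltype `"nt"` (default) or `"aa"`
#' @return named character vector of sequences, with a `descriptions`
#'   attribute carrying the full header lines and a `circular` attribute
#'   (all `FALSE` on read; see [assemble_mitogenome()])
#' @export
read_fasta <- function(path, moltype = c("nt", "aa")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", dup[1L])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("header-only FASTA record with no residues: ",
         ids[which(nchar(seqs) == 0L)[1L]])
  if (moltype == "nt") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      ch <- regmatches(seqs[bad][1L], regexpr("[^ACGTN]", seqs[bad][1L]))
      stop("invalid nucleotide character '", ch, "' in record ",
           ids[bad][1L])
    }
  } else {
    bad <- grepl("[^A-Z*]", seqs)
    if (any(bad)) stop("invalid amino-acid character in record ", ids[bad][1L])
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- setNames(headers, ids)
  attr(seqs, "moltype") <- moltype
  attr(seqs, "circular") <- setNames(rep(FALSE, length(seqs)), ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    writeLines(paste0(">", id), con)
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Construct a feature table
#'
#' One row per exon.  A feature on a circular sequence may wrap the origin;
#' its wrapping exon is stored with `end > ` sequence length and is split
#' into two GFF3 location lines on output.
#'
#' @param seq_id,feature_id,gene,type,strand,start,end,exon_rank vectors,
#'   recycled to common length; `strand` is `"+"` or `"-"`
#' @return data.frame of class `feature_table`
#' @export
feature_table <- function(seq_id, feature_id, gene = feature_id,
                          type = "gene", strand = "+",
                          start, end, exon_rank = 1L) {
  ft <- data.frame(seq_id = seq_id, feature_id = feature_id, gene = gene,
                   type = type, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   exon_rank = as.integer(exon_rank),
                   stringsAsFactors = FALSE)
  if (any(ft$start < 1L) || any(ft$end < ft$start))
    stop("invalid exon interval (1-based inclusive, start <= end required)")
  if (!all(ft$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Write a feature table as GFF3
#'
#' Emits the `##gff-version 3` pragma; multi-exon features are written as a
#' parent `gene` line plus `exon` lines sharing a `Parent` attribute.  A
#' feature wrapping the origin of a circular sequence is written as two
#' location lines sharing one `ID`.
#'
#' @param features a [feature_table()]
#' @param path output path
#' @param seqinfo named list: for each seq_id, `list(length =, circular =)`
#' @export
write_gff3 <- function(features, path, seqinfo) {
  stopifnot(inherits(features, "feature_table"))
  lines <- "##gff-version 3"
  esc <- function(x) gsub("[;=,\t]", "_", x)
  for (fid in unique(features$feature_id)) {
    fx <- features[features$feature_id == fid, , drop = FALSE]
    fx <- fx[order(fx$exon_rank), , drop = FALSE]
    sid <- fx$seq_id[1L]
    si <- seqinfo[[sid]]
    if (is.null(si)) stop("no seqinfo for sequence ", sid)
    L <- si$length
    circ <- isTRUE(si$circular)
    segs <- NULL
    for (k in seq_len(nrow(fx))) {
      s <- fx$start[k]; e <- fx$end[k]
      if (e > L) {
        if (!circ)
          stop("feature ", fid, " interval [", s, ",", e,
               "] exceeds linear sequence length ", L)
        if (s > L || e - L > L)
          stop("feature ", fid, " wraps more than once")
        segs <- rbind(segs, c(s, L), c(1L, e - L))
      } else segs <- rbind(segs, c(s, e))
    }
    gene_attr <- paste0("ID=", esc(fid), ";Name=", esc(fx$gene[1L]))
    for (r in seq_len(nrow(segs)))
      lines <- c(lines, paste(sid, "mitorescue", fx$type[1L], segs[r, 1L],
                              segs[r, 2L], ".", fx$strand[1L], ".",
                              gene_attr, sep = "\t"))
    if (nrow(fx) > 1L) {
      for (k in seq_len(nrow(fx))) {
        s <- fx$start[k]; e <- min(fx$end[k], L)
        lines <- c(lines, paste(sid, "mitorescue", "exon", s, e, ".",
                                fx$strand[1L], ".",
                                paste0("Parent=", esc(fid)), sep = "\t"))
        if (fx$end[k] > L)
          lines <- c(lines, paste(sid, "mitorescue", "exon", 1L,
                                  fx$end[k] - L, ".", fx$strand[1L], ".",
                                  paste0("Parent=", esc(fid)), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' Multi-line features sharing an `ID` (wraparound segments) are re-joined;
#' `exon` lines are attached to their `Parent`.
#'
#' @param path GFF3 path
#' @param seqinfo same structure as for [write_gff3()]; needed to re-join
#'   wraparound segments
#' @return a [feature_table()]
#' @export
read_gff3 <- function(path, seqinfo = list()) {
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(raw)]
  if (!length(raw)) stop("no feature lines in ", path)
  f <- read.delim(text = paste(raw, collapse = "\n"), header = FALSE,
                  stringsAsFactors = FALSE)
  names(f) <- c("seq_id", "source", "type", "start", "end", "score",
                "strand", "phase", "attr")
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  f$ID <- vapply(f$attr, get_attr, "", key = "ID")
  f$Name <- vapply(f$attr, get_attr, "", key = "Name")
  f$Parent <- vapply(f$attr, get_attr, "", key = "Parent")
  out <- NULL
  for (fid in unique(stats::na.omit(f$ID))) {
    main <- f[!is.na(f$ID) & f$ID == fid, , drop = FALSE]
    ex <- f[!is.na(f$Parent) & f$Parent == fid, , drop = FALSE]
    sid <- main$seq_id[1L]
    L <- if (!is.null(seqinfo[[sid]])) seqinfo[[sid]]$length else NA
    join_wrap <- function(df) {
      # a trailing [x,L] segment followed by [1,y] is a wraparound pair
      if (nrow(df) >= 2L && !is.na(L)) {
        for (k in seq_len(nrow(df) - 1L)) {
          if (df$end[k] == L && df$start[k + 1L] == 1L) {
            df$end[k] <- L + df$end[k + 1L]
            df <- df[-(k + 1L), , drop = FALSE]
            break
          }
        }
      }
      df
    }
    if (nrow(ex) == 0L) {
      main <- join_wrap(main)
      rows <- feature_table(sid, fid, gene = main$Name[1L],
                            type = main$type[1L], strand = main$strand[1L],
                            start = main$start, end = main$end,
                            exon_rank = seq_len(nrow(main)))
    } else {
      ex <- join_wrap(ex)
      rows <- feature_table(sid, fid, gene = main$Name[1L],
                            type = main$type[1L], strand = main$strand[1L],
                            start = ex$start, end = ex$end,
                            exon_rank = seq_len(nrow(ex)))
    }
    out <- rbind(out, rows)
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Read a newick tree
#'
#' Thin wrapper around [ape::read.tree()] with an explicit bracket-balance
#' check so unbalanced input is reported with its character position.
#'
#' @param path newick file path
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  .check_balanced(txt, "()")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse failure: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse failure in ", path)
  if (!is.null(tr$edge.length) && any(!is.finite(tr$edge.length) |
                                      tr$edge.length < 0))
    stop("branch length parse failure: non-finite or negative length")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' Write a tree in newick format
#' @param tree an [ape::phylo] tree
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

.check_balanced <- function(txt, pairs) {
  open <- c("(" = ")", "[" = "]", "{" = "}")
  ch <- strsplit(txt, "", fixed = TRUE)[[1L]]
  stack <- character()
  pos <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] %in% names(open)) {
      stack <- c(stack, open[[ch[i]]]); pos <- c(pos, i)
    } else if (ch[i] %in% open) {
      if (!length(stack) || tail(stack, 1L) != ch[i])
        stop("unbalanced bracket '", ch[i], "' at position ", i)
      stack <- head(stack, -1L); pos <- head(pos, -1L)
    }
  }
  if (length(stack))
    stop("unbalanced bracket opened at position ", pos[length(pos)])
  invisible(TRUE)
}

#' Parse a dot-bracket secondary structure
#'
#' Accepts the bracket alphabets `()`, `[]` and `{}`; pairs opened with
#' `[]` or `{}` (or any pair crossing another) are flagged as pseudoknots.
#'
#' @param seq reference sequence (same length as `structure`); `U` allowed
#' @param structure dot-bracket string
#' @return list of class `secondary_structure` with elements `seq`
#'   (internal DNA alphabet), `pairs` (two-column matrix, i < j) and
#'   `pseudoknot` (logical per pair)
#' @export
parse_dotbracket <- function(seq, structure) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  if (nchar(seq) != nchar(structure))
    stop("sequence length (", nchar(seq), ") != structure length (",
         nchar(structure), ")")
  ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
  ok <- ch %in% c("(", ")", "[", "]", "{", "}", ".")
  if (!all(ok)) stop("invalid structure character '", ch[!ok][1L],
                     "' at position ", which(!ok)[1L])
  .check_balanced(structure, "all")
  openers <- c("(" = ")", "[" = "]", "{" = "}")
  stacks <- list("(" = integer(), "[" = integer(), "{" = integer())
  pairs <- NULL
  knot_type <- logical()
  for (i in seq_along(ch)) {
    c0 <- ch[i]
    if (c0 %in% names(openers)) {
      stacks[[c0]] <- c(stacks[[c0]], i)
    } else if (c0 %in% openers) {
      b <- names(openers)[openers == c0]
      j <- tail(stacks[[b]], 1L)
      stacks[[b]] <- head(stacks[[b]], -1L)
      pairs <- rbind(pairs, c(j, i))
      knot_type <- c(knot_type, b != "(")
    }
  }
  if (is.null(pairs)) {
    pairs <- matrix(integer(), ncol = 2L)
    knot <- logical()
  } else {
    o <- order(pairs[, 1L])
    pairs <- pairs[o, , drop = FALSE]
    knot_type <- knot_type[o]
    # crossing test: pair (i,j) crosses (k,l) when i < k < j < l
    n <- nrow(pairs)
    crossing <- rep(FALSE, n)
    if (n > 1L) for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      if (pairs[a, 1L] < pairs[b, 1L] && pairs[b, 1L] < pairs[a, 2L] &&
          pairs[a, 2L] < pairs[b, 2L])
        crossing[a] <- crossing[b] <- TRUE
    }
    knot <- knot_type | crossing
  }
  colnames(pairs) <- c("i", "j")
  structure(list(seq = seq, pairs = pairs, pseudoknot = knot),
            class = "secondary_structure")
}

#' Read a dot-bracket structure file
#'
#' Expected layout (Vienna style): an optional `>id` header line, one
#' sequence line, one structure line.
#'
#' @param path file path
#' @return a `secondary_structure` (see [parse_dotbracket()])
#' @export
read_dotbracket <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (grepl("^>", ln[1L])) ln <- ln[-1L]
  if (length(ln) < 2L) stop("dot-bracket file needs sequence + structure lines")
  parse_dotbracket(ln[1L], ln[2L])
}

#' Write a dot-bracket structure file
#' @param struct a `secondary_structure`
#' @param path output path
#' @param id header id
#' @export
write_dotbracket <- function(struct, path, id = "structure") {
  db <- rep(".", nchar(struct$seq))
  if (nrow(struct$pairs)) {
    db[struct$pairs[, 1L]] <- ifelse(struct$pseudoknot, "[", "(")
    db[struct$pairs[, 2L]] <- ifelse(struct$pseudoknot, "]", ")")
  }
  writeLines(c(paste0(">", id), struct$seq, paste(db, collapse = "")), path)
  invisible(path)
}

#' Read an RNA-editing site table
#'
#' Tab-separated columns `gene`, `codon_index` (1-based, reference frame)
#' and `source` (`empirical` or `predicted`).
#'
#' @param path TSV path
#' @param genes optional vector of known gene names; unknown genes error
#' @return data.frame of class `editing_table`
#' @export
read_editing_table <- function(path, genes = NULL) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "codon_index", "source")
  if (!all(need %in% names(tb)))
    stop("editing table must have columns: ", paste(need, collapse = ", "))
  tb$codon_index <- as.integer(tb$codon_index)
  if (any(tb$codon_index < 1L)) stop("codon indices must be positive")
  if (!all(tb$source %in% c("empirical", "predicted")))
    stop("source must be 'empirical' or 'predicted'")
  if (!is.null(genes)) {
    bad <- setdiff(unique(tb$gene), genes)
    if (length(bad)) stop("editing table names unknown gene: ", bad[1L])
  }
  class(tb) <- c("editing_table", "data.frame")
  tb
}

#' Write an RNA-editing site table
#' @param tb an `editing_table` data.frame
#' @param path output path
#' @export
write_editing_table <- function(tb, path) {
  write.table(tb[, c("gene", "codon_index", "source")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Editing-table lookup for one gene
#' @param tb editing table (or NULL)
#' @param gene gene name
#' @return integer vector of edited codon indices
#' @keywords internal
edited_codons_for <- function(tb, gene) {
  if (is.null(tb) || !nrow(tb)) return(integer())
  sort(unique(tb$codon_index[tb$gene == gene]))
}
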
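# End-to-end orchestration: annotation -> codon-level divergence ->
# rRNA structure analysis -> HGT screen, plus the inventory summary
# arithmetic used for the headline aggregates.

#' Build a pairwise codon alignment from an annotated gene model
#'
#' The model's stitched HSP alignment is projected onto the reference
#' frame: for every reference codon fully and cleanly aligned, the
#' genomic (subject) codon enters the focal row; everything else becomes
#' a gap codon.  RNA-edited codons are masked.
#'
#' @param model a `gene_model`
#' @param reference_cds the query gene the model was built from
#' @param ref_name,focal_name row names for the result
#' @param editing optional `editing_table`
#' @param gene gene name for the editing lookup
#' @return a [codon_alignment()]
#' @export
codon_alignment_from_model <- function(model, reference_cds,
                                       ref_name = "reference",
                                       focal_name = "focal",
                                       editing = NULL, gene = model$gene) {
  aln <- .model_alignment(model)
  refN <- nchar(reference_cds)
  nref <- refN %/% 3L
  qnum <- cumsum(aln$q != "-")
  qglob <- ifelse(aln$q == "-", NA, qnum + aln$q_start - 1L)
  colpos <- match(seq_len(3L * nref), qglob)
  focal <- rep("---", nref)
  for (cc in seq_len(nref)) {
    cols <- colpos[(3L * cc - 2L):(3L * cc)]
    if (anyNA(cols) || cols[3L] != cols[1L] + 2L) next  # gap or insertion
    cod <- paste(aln$s[cols], collapse = "")
    if (grepl("[^ACGT]", cod)) next
    focal[cc] <- cod
  }
  ref_row <- paste(split_codons(substr(reference_cds, 1L, 3L * nref)),
                   collapse = "")
  mask <- integer()
  ed <- edited_codons_for(editing, gene)
  ed <- ed[ed <= nref]
  if (length(ed)) mask <- ed
  # any residual stop-looking codon in the focal row cannot enter the
  # 61-state analyses; mask it (it is what the editing table should have
  # covered, or a boundary artefact)
  stops <- which(focal %in% .STOPS)
  mask <- sort(unique(c(mask, stops)))
  codon_alignment(setNames(c(ref_row, paste(focal, collapse = "")),
                           c(ref_name, focal_name)), mask = mask)
}

#' Summary statistics over a gene inventory
#'
#' Mean of per-gene omega over genes with nonzero, non-saturated dS;
#' counts of genes whose identity exceeds the given thresholds; and
#' concatenate lengths as per-taxon sums of gene lengths.
#'
#' @param rows data.frame with at least an omega column and a dS column
#' @param omega_col,ds_col,identity_col column names
#' @param length_cols named character vector: summary name -> column of
#'   per-gene lengths to sum
#' @param identity_thresholds identity cutoffs (percent)
#' @param digits rounding applied to the reported mean omega (2 = the
#'   table convention); the raw mean is also returned
#' @return list: `mean_omega`, `mean_omega_raw`, `n_omega_used`,
#'   `identity_counts`, `concat_lengths`, `n_genes`
#' @export
summarize_inventory <- function(rows, omega_col = "omega", ds_col = "dS",
                                identity_col = "pct_id_vs_relative",
                                length_cols = NULL,
                                identity_thresholds = c(96, 98),
                                digits = 2L) {
  if (!nrow(rows)) stop("empty inventory")
  om <- rows[[omega_col]]
  ds <- rows[[ds_col]]
  used <- !is.na(om) & !is.na(ds) & ds > 0
  if (!any(used)) stop("all rows excluded from the omega summary")
  idc <- NULL
  if (!is.null(identity_col) && identity_col %in% names(rows)) {
    idv <- rows[[identity_col]]
    idc <- vapply(identity_thresholds,
                  function(th) sum(!is.na(idv) & idv > th), 0L)
    names(idc) <- paste0("gt", identity_thresholds)
  }
  cl <- NULL
  if (!is.null(length_cols))
    cl <- vapply(length_cols, function(cn) sum(rows[[cn]], na.rm = TRUE), 0)
  list(mean_omega = round(mean(om[used]), digits),
       mean_omega_raw = mean(om[used]),
       n_omega_used = sum(used),
       identity_counts = idc,
       concat_lengths = cl,
       n_genes = nrow(rows))
}

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (as produced by [simulate_study()]) or
#' file paths (FASTA / newick / TSV), which are read eagerly so that
#' unresolvable paths fail before any stage runs.
#'
#' @param genome genome (named character vector or FASTA path)
#' @param panel reference panel (named vector `taxon|gene`, or FASTA)
#' @param relative_genes close-relative genes (named vector or FASTA)
#' @param editing `editing_table` or TSV path (optional)
#' @param homologs per-gene homolog sets for the HGT screen (optional)
#' @param species_tree [ape::phylo] or newick path (optional)
#' @param rrna list per rRNA: `struct` (secondary_structure or
#'   dot-bracket path) and `query` (string) (optional)
#' @param focal,reference taxon names for the HGT screen
#' @param stages stages to run, in order
#' @param thresholds classification thresholds
#' @param alpha,z_threshold,B HGT screen settings
#' @param out_dir output directory (optional)
#' @param seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genome, panel, relative_genes = NULL,
                            editing = NULL, homologs = NULL,
                            species_tree = NULL, rrna = NULL,
                            focal = "focal", reference = "reference",
                            stages = c("annotate", "dnds", "rrna", "hgt"),
                            thresholds = list(), alpha = 0.05,
                            z_threshold = 2.5, B = 2000L,
                            out_dir = NULL, seed = 1L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(panel) && length(panel) == 1L && file.exists(panel))
    panel <- read_fasta(panel)
  if (is.character(relative_genes) && length(relative_genes) == 1L &&
      file.exists(relative_genes))
    relative_genes <- read_fasta(relative_genes)
  if (is.character(editing)) editing <- read_editing_table(editing)
  if (is.character(species_tree)) species_tree <- read_newick(species_tree)
  stages <- match.arg(stages, c("annotate", "dnds", "rrna", "hgt"),
                      several.ok = TRUE)
  structure(list(genome = genome, panel = panel,
                 relative_genes = relative_genes, editing = editing,
                 homologs = homologs, species_tree = species_tree,
                 rrna = rrna, focal = focal, reference = reference,
                 stages = stages, thresholds = thresholds, alpha = alpha,
                 z_threshold = z_threshold, B = as.integer(B),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Stages run in order annotate -> dnds -> rrna -> hgt; any stage error
#' aborts with the stage name after writing the outputs produced so far
#' (when `out_dir` is set).  Reruns with the same configuration and seed
#' are byte-identical.
#'
#' @param config a [pipeline_config()] (a `study_data` object from
#'   [simulate_study()] is also accepted and converted)
#' @param ... overrides passed to [pipeline_config()] when `config` is a
#'   `study_data`
#' @return list of class `pipeline_result`: `annotation`, `inventory`,
#'   `rrna_report`, `hgt_report`, `summary`, `config`
#' @export
run_pipeline <- function(config, ...) {
  if (inherits(config, "study_data"))
    config <- pipeline_config(genome = config$genome, panel = config$panel,
                              relative_genes = config$relative_genes,
                              editing = config$editing,
                              homologs = config$homologs,
                              species_tree = config$species_tree,
                              rrna = config$rrna, ...)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  res <- list(config = config)
  outputs <- function() {
    if (is.null(config$out_dir)) return(invisible())
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    if (!is.null(res$annotation)) {
      write.table(res$annotation$status, file.path(od, "gene_status.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(res$annotation$features)) {
        L <- nchar(config$genome[[1L]])
        si <- setNames(list(list(length = L, circular = TRUE)),
                       names(config$genome)[1L])
        write_gff3(res$annotation$features,
                   file.path(od, "annotation.gff3"), si)
      }
    }
    if (!is.null(res$inventory))
      write.table(res$inventory, file.path(od, "inventory.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$rrna_report))
      write.table(res$rrna_report, file.path(od, "rrna_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$hgt_report))
      write.table(res$hgt_report, file.path(od, "hgt_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    invisible()
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      outputs()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gene_of <- function(id) sub("^[^|]*\\|", "", id)

  if ("annotate" %in% config$stages) {
    res$annotation <- stage("annotate",
      annotate_genome(config$genome, config$panel, config$relative_genes,
                      editing = config$editing,
                      thresholds = config$thresholds))
  }
  if ("dnds" %in% config$stages && !is.null(res$annotation)) {
    res$inventory <- stage("dnds", {
      st <- res$annotation$status
      rows <- NULL
      for (g in st$gene[st$status %in% c("intact", "truncated_intact")]) {
        model <- res$annotation$models[[g]]
        if (is.null(model)) next
        ref <- if (model$source == "close_relative" &&
                   g %in% names(config$relative_genes))
          config$relative_genes[[g]]
        else config$panel[[which(gene_of(names(config$panel)) == g)[1L]]]
        ca <- codon_alignment_from_model(model, ref, editing = config$editing,
                                         gene = g)
        est <- tryCatch(fit_pairwise_gy94(ca, n_restarts = 1L),
                        error = function(e) NULL)
        ng <- tryCatch(ng86_dnds(ca), error = function(e) NULL)
        srow <- st[st$gene == g, ]
        rows <- rbind(rows, data.frame(
          gene = g, status = srow$status, length_nt = srow$length_nt,
          ref_length_nt = srow$ref_length_nt,
          pct_id_vs_panel = round(srow$pct_id_vs_panel, 1),
          pct_id_vs_relative = round(srow$pct_id_vs_relative, 1),
          dN = if (!is.null(est)) round(est$dN, 3) else NA_real_,
          dS = if (!is.null(est)) round(est$dS, 3) else NA_real_,
          # ratio recomputable from the printed dN and dS columns
          omega = if (!is.null(est) && round(est$dS, 3) > 0)
            round(round(est$dN, 3) / round(est$dS, 3), 2) else NA_real_,
          dN_ng86 = if (!is.null(ng)) round(ng$dN, 3) else NA_real_,
          dS_ng86 = if (!is.null(ng)) round(ng$dS, 3) else NA_real_,
          stringsAsFactors = FALSE))
      }
      rows
    })
  }
  if ("rrna" %in% config$stages && !is.null(config$rrna)) {
    res$rrna_report <- stage("rrna", {
      rows <- NULL
      for (nm in names(config$rrna)) {
        rr <- config$rrna[[nm]]
        struct <- if (is.character(rr$struct)) read_dotbracket(rr$struct)
          else rr$struct
        alnr <- align_rrna(struct$seq, rr$query)
        pm <- map_structure(struct$seq, struct, alnr)
        rep0 <- classify_paired_changes(pm, struct$seq,
                                        gsub("-", "", alnr[["query"]]))
        core <- if (!is.null(rr$core_mask)) rr$core_mask
          else sort(unique(as.vector(struct$pairs)))
        ci <- conserved_core_identity(alnr, core, ref_id = "ref")
        rows <- rbind(rows, data.frame(
          rrna = nm, n_pairs = rep0$n_pairs,
          n_compensatory = rep0$n_fully_compensatory,
          n_half = rep0$n_half, n_disruptive = rep0$n_disruptive,
          n_pair_deleted = rep0$n_pair_deleted,
          core_identity = round(ci$core, 1),
          non_core_identity = round(ci$non_core, 1),
          stringsAsFactors = FALSE))
      }
      rows
    })
  }
  if ("hgt" %in% config$stages && !is.null(config$homologs) &&
      !is.null(res$annotation)) {
    res$hgt_report <- stage("hgt", {
      st <- res$annotation$status
      genes <- intersect(names(config$homologs),
                         st$gene[st$status %in% c("intact",
                                                  "truncated_intact")])
      if (length(genes) < 5L)
        stop("need >= 5 intact genes for the divergence distribution")
      alns <- list()
      for (g in genes) {
        model <- res$annotation$models[[g]]
        ref <- if (model$source == "close_relative" &&
                   g %in% names(config$relative_genes))
          config$relative_genes[[g]]
        else config$panel[[which(gene_of(names(config$panel)) == g)[1L]]]
        ca <- codon_alignment_from_model(model, ref,
                                         focal_name = config$focal,
                                         editing = config$editing, gene = g)
        focal_nt <- gsub("---", paste(rep("-", 3), collapse = ""),
                         paste(ca$codons[config$focal, ], collapse = ""))
        hom <- config$homologs[[g]]
        if (unique(nchar(hom)) != nchar(focal_nt)) next
        alns[[g]] <- c(hom, setNames(focal_nt, config$focal))
      }
      div <- setNames(st$pct_id_vs_panel[match(names(alns), st$gene)],
                      names(alns))
      flag_hgt_candidates(alns, config$species_tree, config$focal,
                          config$reference, divergence = div,
                          alpha = config$alpha,
                          z_threshold = config$z_threshold,
                          B = config$B, seed = config$seed)
    })
  }
  res$summary <- stage("summary", {
    s <- list(seed = config$seed)
    if (!is.null(res$annotation)) {
      tab <- table(factor(res$annotation$status$status,
                          levels = c("intact", "truncated_intact",
                                     "pseudogene", "absent")))
      s$n_intact <- unname(tab[["intact"]])
      s$n_truncated_intact <- unname(tab[["truncated_intact"]])
      s$n_pseudogene <- unname(tab[["pseudogene"]])
      s$n_absent <- unname(tab[["absent"]])
      s$n_functional <- s$n_intact + s$n_truncated_intact
    }
    if (!is.null(res$inventory) && nrow(res$inventory)) {
      sm <- tryCatch(summarize_inventory(
        res$inventory,
        length_cols = c(focal_concat_nt = "length_nt",
                        ref_concat_nt = "ref_length_nt")),
        error = function(e) NULL)
      if (!is.null(sm)) {
        s$mean_pairwise_omega <- sm$mean_omega
        s$n_omega_used <- sm$n_omega_used
        s$identity_counts <- sm$identity_counts
        s$concat_lengths <- sm$concat_lengths
      }
    }
    if (!is.null(res$hgt_report)) {
      s$hgt_candidates <-
        res$hgt_report$gene[res$hgt_report$verdict == "hgt_candidate"]
      s$n_functional_excluding_hgt <-
        if (!is.null(s$n_functional))
          s$n_functional - length(s$hgt_candidates) else NULL
    }
    s
  })
  outputs()
  structure(res, class = "pipeline_result")
}
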
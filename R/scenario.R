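# The default closed-loop study scenario: one hemiparasite-like lineage
# with a strongly elevated synonymous rate and relaxed selection, nine
# pseudogenized nad-like genes, two genes absent from the focal genome,
# one recently transferred (HGT) gene with anomalously low divergence,
# and rRNAs evolving with mostly compensatory paired-position changes.

.SCN_TREE <- paste0(
  "(((focal:0.0025,sister:0.0025):0.06,relative:0.05):0.02,",
  "(reference:0.05,donor:0.05):0.01,outgroup:0.08);")
# HGT gene: the focal copy descends from the donor lineage (sister keeps
# its full effective length; the focal graft is recent and short)
.SCN_HGT_TREE <- paste0(
  "((sister:1.25,relative:0.05):0.02,",
  "(reference:0.05,(donor:0.03,focal:0.015):0.02):0.01,outgroup:0.08);")

.SCN_GENES <- list(
  intact = c(atp1 = 509L, atp4 = 186L, atp6 = 240L, atp8 = 158L,
             atp9 = 75L, cob = 393L, ccmB = 206L, cox1 = 524L,
             cox2 = 254L, cox3 = 265L, ccmC = 233L, ccmFc = 442L,
             ccmFn = 561L, mttB = 240L, rpl16 = 144L, rps3 = 518L,
             rps4 = 345L, sdh3 = 94L),
  hgt = c(matR = 650L),
  absent = c(rps10 = 119L, rps14 = 100L),
  pseudo = c(nad1 = 325L, nad2 = 489L, nad3 = 118L, nad4 = 495L,
             nad4L = 100L, nad5 = 670L, nad6 = 205L, nad7 = 393L,
             nad9 = 190L))

#' Default elevated-rate mistletoe-like scenario
#'
#' Six taxa; the focal + sister clade carries a 20x rate multiplier with
#' per-gene omega drawn uniformly in [0.2, 0.85] on its branches
#' (background omega 0.1); 19 intact genes (one of them a recent
#' horizontal transfer from the donor lineage, hence anomalously
#' low-divergence), 9 pseudogenized nad-like genes (one nonsense + one
#' frameshift each), 2 genes absent from the focal genome, one edited
#' genomic stop codon in `cob`, and two rRNAs with 80% compensatory
#' paired-position changes.
#'
#' @param seed scenario seed
#' @return list of class `study_scenario`
#' @export
viscum_scenario <- function(seed = 1L) {
  tree <- ape::read.tree(text = .SCN_TREE)
  ntip <- length(tree$tip.label)
  mrca <- ape::getMRCA(tree, c("focal", "sister"))
  viscum_edges <- which(
    tree$edge[, 2L] %in% c(which(tree$tip.label %in% c("focal", "sister")),
                           mrca))
  rate_mult <- rep(1, nrow(tree$edge))
  rate_mult[viscum_edges] <- 20
  gl <- unlist(.SCN_GENES)
  names(gl) <- sub("^(intact|hgt|absent|pseudo)\\.", "", names(gl))
  structure(list(
    seed = as.integer(seed),
    tree = tree,
    hgt_tree = ape::read.tree(text = .SCN_HGT_TREE),
    viscum_edges = viscum_edges,
    rate_mult = rate_mult,
    omega = list(background = 0.1, range = c(0.2, 0.85),
                 edges = viscum_edges),
    kappa = 2,
    gene_lengths = gl,
    gene_groups = lapply(.SCN_GENES, names),
    hgt_gene = names(.SCN_GENES$hgt),
    edited_stop_gene = "cob",
    editing_rate = 0.02,
    splits = list(cox2 = 2L, rps3 = 2L, nad4 = 2L),
    spacer = list(mean = 400, sd = 120, min = 60),
    rrna = list(
      rrnS = list(len = 240L, helices = 6L, n_subs = 30L, f_cbc = 0.8),
      rrnL = list(len = 360L, helices = 8L, n_subs = 45L, f_cbc = 0.8)),
    focal = "focal", sister = "sister", reference = "reference",
    donor = "donor"),
    class = "study_scenario")
}

#' Simulate a full study data set with ground truth
#'
#' Runs the generator for every gene family, applies pseudogenization and
#' the HGT replacement, assembles the focal mitogenome, generates the
#' RNA-editing table and the rRNA pairs, and returns every input the
#' pipeline needs together with the complete truth.
#'
#' @param scenario a [viscum_scenario()] (or compatible list)
#' @return list of class `study_data`: `genome`, `features_truth`,
#'   `panel`, `relative_genes`, `homologs` (per-gene cross-taxon CDS
#'   sets, focal excluded), `editing`, `rrna` (per rRNA: `struct`,
#'   `query`, `truth`), `truth` (per-gene status data.frame), `families`,
#'   `species_tree`, `scenario`
#' @export
simulate_study <- function(scenario = viscum_scenario(1L)) {
  scn <- scenario
  base_cfg <- sim_config(scn$tree, kappa = scn$kappa, omega = scn$omega,
                         rate_mult = scn$rate_mult,
                         gene_lengths = scn$gene_lengths, seed = scn$seed)
  hgt_cfg <- sim_config(scn$hgt_tree, kappa = scn$kappa,
                        omega = scn$omega$background, rate_mult = 1,
                        gene_lengths = scn$gene_lengths,
                        seed = scn$seed + 1000L)
  genes <- names(scn$gene_lengths)
  families <- list()
  for (g in genes) {
    families[[g]] <- if (g %in% scn$gene_groups$hgt)
      simulate_gene_family(hgt_cfg, g)
    else simulate_gene_family(base_cfg, g)
  }
  # RNA-editing table over intact genes (empirical source)
  set.seed(scn$seed + 11L)
  intact_all <- c(scn$gene_groups$intact, scn$gene_groups$hgt)
  ed <- NULL
  for (g in intact_all) {
    L <- scn$gene_lengths[[g]]
    n <- max(1L, round(scn$editing_rate * L))
    idx <- sort(sample(seq(2L, L - 1L), n))
    ed <- rbind(ed, data.frame(gene = g, codon_index = idx,
                               source = "empirical"))
  }
  class(ed) <- c("editing_table", "data.frame")
  # focal gene set: intact + HGT copy, with one edited genomic stop
  focal_seqs <- character()
  truth_status <- NULL
  for (g in intact_all) {
    cds <- families[[g]]$cds[[scn$focal]]
    if (identical(g, scn$edited_stop_gene)) {
      cc <- ed$codon_index[ed$gene == g][1L]
      substr(cds, 3L * cc - 2L, 3L * cc) <- "TAA"
    }
    focal_seqs[[g]] <- cds
    truth_status <- rbind(truth_status, data.frame(
      gene = g, true_status = "intact",
      is_hgt = g %in% scn$gene_groups$hgt))
  }
  set.seed(scn$seed + 23L)
  pseudo_truth <- list()
  for (g in scn$gene_groups$pseudo) {
    L <- scn$gene_lengths[[g]]
    nons <- sample(seq(round(0.25 * L), round(0.55 * L)), 1L)
    fs <- sample(seq(round(0.60 * 3L * L), round(0.85 * 3L * L)), 1L)
    inj <- inject_pseudogenization(
      families[[g]]$cds[[scn$focal]],
      list(list(type = "nonsense", pos = nons),
           list(type = "frameshift", pos = fs)),
      seed = scn$seed + 29L)
    focal_seqs[[g]] <- inj$seq
    pseudo_truth[[g]] <- inj$truth
    truth_status <- rbind(truth_status, data.frame(
      gene = g, true_status = "pseudogene", is_hgt = FALSE))
  }
  for (g in scn$gene_groups$absent)
    truth_status <- rbind(truth_status, data.frame(
      gene = g, true_status = "absent", is_hgt = FALSE))
  asm <- assemble_mitogenome(focal_seqs, spacer = scn$spacer,
                             split = scn$splits,
                             seq_id = "focal_mito",
                             seed = scn$seed + 37L)
  # panel: reference-taxon copies of every gene (incl. absent ones)
  panel <- setNames(
    vapply(genes, function(g) families[[g]]$cds[[scn$reference]], ""),
    paste0(scn$reference, "|", genes))
  # close relative: the sister taxon, which lost the nad genes and never
  # had the HGT gene
  rel_genes <- setdiff(genes,
                       c(scn$gene_groups$pseudo, scn$gene_groups$hgt))
  relative_genes <- setNames(
    vapply(rel_genes, function(g) families[[g]]$cds[[scn$sister]], ""),
    rel_genes)
  # per-gene homolog sets (focal excluded) for the phylogenetic screen;
  # the sister taxon lost the transferred gene, so its simulated copy is
  # not part of that gene's observable homolog set
  homologs <- lapply(intact_all, function(g) {
    cds <- families[[g]]$cds
    drop <- scn$focal
    if (g %in% scn$gene_groups$hgt) drop <- c(drop, scn$sister)
    cds[setdiff(names(cds), drop)]
  })
  names(homologs) <- intact_all
  # rRNAs
  rrna <- list()
  for (i in seq_along(scn$rrna)) {
    nm <- names(scn$rrna)[i]
    sp <- scn$rrna[[i]]
    struct <- random_secondary_structure(sp$len, sp$helices,
                                         seed = scn$seed + 41L + i)
    ev <- simulate_rrna(struct, sp$n_subs, sp$f_cbc,
                        seed = scn$seed + 47L + i)
    rrna[[nm]] <- list(struct = struct, query = ev$seq, truth = ev$truth)
  }
  structure(list(genome = asm$genome, features_truth = asm$features,
                 genome_length = asm$length, panel = panel,
                 relative_genes = relative_genes, homologs = homologs,
                 editing = ed, rrna = rrna, truth = truth_status,
                 pseudo_truth = pseudo_truth, families = families,
                 species_tree = scn$tree, scenario = scn),
            class = "study_data")
}
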
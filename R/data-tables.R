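# Published per-gene divergence values for the Viscum album vs
# V. scurruloideum comparison (with Liriodendron as the slow reference),
# shipped as plain text so the summary arithmetic can be exercised on the
# real study's numbers without any sequence data.

#' Published Viscum gene-divergence table
#'
#' Per-gene coding lengths, pairwise nucleotide identities (gap
#' positions excluded), and pairwise dN, dS and dN/dS for the 19 shared
#' protein genes of the two Viscum mitogenomes; two genes have no
#' synonymous differences (dS = 0, ratio undefined).
#'
#' @return data.frame with columns gene, length_lir_nt, length_va_nt,
#'   length_vs_nt, pct_id_va_lir, pct_id_va_vs, dN, dS, omega
#' @export
viscum_gene_table <- function() {
  read.delim(system.file("extdata", "viscum_album_gene_table.tsv",
                         package = "mitorescue"),
             stringsAsFactors = FALSE)
}

#' Published Viscum mitogenome sizes
#'
#' @return data.frame with columns taxon, genome_size_kb
#' @export
viscum_genome_sizes <- function() {
  read.delim(system.file("extdata", "viscum_genome_sizes.tsv",
                         package = "mitorescue"),
             stringsAsFactors = FALSE)
}
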
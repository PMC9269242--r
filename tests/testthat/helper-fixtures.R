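# Fixtures are generated in code so the repository stays text-only.

# deterministic random DNA
fix_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

gene_row <- function(gene_id, chrom, strand, tx_start, tx_end, cds_start,
                     cds_end, phase = 0L) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                 phase = as.integer(phase),
                 cds = list(tibble::tibble(start = as.integer(cds_start),
                                           end = as.integer(cds_end))))
}

# 600 bp contig with a single plus-strand, two-exon gene:
#   tx 201..440, CDS 201..290 and 351..440 (two 90 bp exons, 180 bp coding)
toy_contig_1 <- function(seed = 11) {
  genome <- Biostrings::DNAStringSet(c(tig = fix_dna(600, seed)))
  genes <- gene_row("g1", "tig", "+", 201, 440, c(201, 351), c(290, 440))
  list(genome = genome, genes = genes)
}

# 2 kb contig with three genes, exercising every region type:
#   gA: + strand, single-exon,  tx 301..600,  CDS 341..580 (UTR-like ends)
#   gB: - strand, three exons,  tx 800..1300, CDS {800..910, 1001..1120, 1201..1299}
#   gC: + strand, two exons,    tx 1500..1900, CDS 1500..1649, 1710..1898
# gaps: intergenic < 301 minus the upstream flank, 601..799 (joint up/down
# zone between gA and gB), > 1900 plus flanks; coding lengths are multiples
# of three so every CDS base sits in a complete codon
toy_contig_3 <- function(seed = 12) {
  genome <- Biostrings::DNAStringSet(c(tig = fix_dna(2000, seed)))
  genes <- dplyr::bind_rows(
    gene_row("gA", "tig", "+", 301, 600, 341, 580),
    gene_row("gB", "tig", "-", 800, 1300, c(800, 1001, 1201), c(910, 1120, 1299)),
    gene_row("gC", "tig", "+", 1500, 1900, c(1500, 1710), c(1649, 1898)))
  list(genome = genome, genes = genes)
}

# small pooled-variant table with explicit read counts
pooled_variant <- function(chrom, pos, ref = "A", alt = "T", vclass = "SNP",
                           multiallelic = FALSE, ad_high = c(20L, 20L),
                           ad_low = c(20L, 20L)) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 vclass = vclass, multiallelic = multiallelic,
                 ad_high_ref = ad_high[1], ad_high_alt = ad_high[2],
                 ad_low_ref = ad_low[1], ad_low_alt = ad_low[2])
}

# the six-variant filter fixture: one victim per rule, two survivors
filter_fixture <- function() {
  dplyr::bind_rows(
    pooled_variant("c1", 100, alt = "G,T", multiallelic = TRUE),
    pooled_variant("c1", 200, ad_high = c(2L, 1L), ad_low = c(20L, 20L)),   # depth 3
    pooled_variant("c1", 300, ad_high = c(32L, 8L), ad_low = c(36L, 4L)),   # idx .2/.1
    pooled_variant("c1", 400, ad_high = c(2L, 38L), ad_low = c(1L, 39L)),   # idx .95/.975
    pooled_variant("c1", 500, ad_high = c(8L, 32L), ad_low = c(32L, 8L)),   # keep
    pooled_variant("c1", 600, ad_high = c(26L, 14L), ad_low = c(28L, 12L))  # keep
  )
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", "VE-High", "VE-Low", sep = "\t"))
  writeLines(c(hdr, lines), path)
  path
}
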
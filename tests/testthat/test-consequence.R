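test_that("region categories follow the documented definitions on a toy gene", {
  fx <- toy_contig_1()
  cases <- tibble::tribble(
    ~pos, ~expected,
    250L, "exonic",      # inside CDS exon 1
    291L, "splicing",    # intron base 1 from the donor junction
    292L, "splicing",    # intron base 2
    293L, "intronic",    # intron interior
    349L, "splicing",    # 2 bp before the acceptor junction
    100L, "upstream",    # 101 bp 5' of the TSS, within the 1 kb flank
    500L, "downstream",  # 60 bp 3' of the transcription end (tx ends 440)
    599L, "downstream",
    50L,  "upstream"
  )
  v <- tibble::tibble(chrom = "tig", pos = cases$pos,
                      ref = vapply(cases$pos, function(p)
                        as.character(Biostrings::subseq(fx$genome[["tig"]], p, p)),
                        character(1)))
  v$alt <- vapply(v$ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                  character(1))
  v$vclass <- "SNP"
  eff <- classify_variants(v, fx$genes, fx$genome)
  expect_equal(eff$category, cases$expected)
})

test_that("codon-aware SNV subtypes: synonymous, stop-loss, stop-gain", {
  # hand-built gene ATG GAA TAA at positions 101..109, flanked by neutral Cs
  seq <- paste0(strrep("C", 100), "ATGGAATAA", strrep("C", 91))
  genome <- Biostrings::DNAStringSet(c(tig = seq))
  genes <- gene_row("g", "tig", "+", 101, 109, 101, 109)

  eff <- classify_variants(
    tibble::tibble(chrom = "tig", pos = c(106L, 107L, 105L),
                   ref = c("A", "T", "A"), alt = c("G", "C", "T"),
                   vclass = "SNP"),
    genes, genome)
  # GAA->GAG is E->E; TAA->CAA destroys the stop; GAA->GTA is E->V
  expect_equal(eff$exonic_subtype, c("synonymous", "stop-loss", "non-synonymous"))
  expect_equal(eff$aa_ref, c("E", "*", "E"))
  expect_equal(eff$aa_alt, c("E", "Q", "V"))
  expect_equal(eff$codon_index, c(2L, 3L, 2L))

  # stop-gain: GAA -> TAA
  eff2 <- classify_variants(
    tibble::tibble(chrom = "tig", pos = 104L, ref = "G", alt = "T",
                   vclass = "SNP"), genes, genome)
  expect_equal(eff2$exonic_subtype, "stop-gain")

  # same gene on the minus strand of the reverse-complemented contig
  rc <- Biostrings::DNAStringSet(c(tig = as.character(
    Biostrings::reverseComplement(genome[[1]]))))
  L <- 200L
  genes_rc <- gene_row("g", "tig", "-", L - 109 + 1, L - 101 + 1,
                       L - 109 + 1, L - 101 + 1)
  eff3 <- classify_variants(
    tibble::tibble(chrom = "tig", pos = L - 106L + 1L, ref = "T", alt = "C",
                   vclass = "SNP"), genes_rc, rc)
  expect_equal(eff3$exonic_subtype, "synonymous")
})

test_that("coding indels: frameshift by net length mod 3, with stop checks", {
  fx <- toy_contig_1()
  g <- fx$genome[["tig"]]
  ref5 <- as.character(Biostrings::subseq(g, 220, 224))
  v <- tibble::tibble(
    chrom = "tig", pos = c(220L, 220L, 219L),
    ref = c(ref5, as.character(Biostrings::subseq(g, 220, 222)),
            as.character(Biostrings::subseq(g, 219, 219))),
    alt = c("-", "-",
            paste0(as.character(Biostrings::subseq(g, 219, 219)), "AT")),
    vclass = "InDel")
  eff <- classify_variants(v, fx$genes, fx$genome)
  expect_equal(eff$category, rep("exonic", 3))
  expect_equal(eff$exonic_subtype[1], "frameshift-deletion")   # 5 bases out
  expect_match(eff$exonic_subtype[2], "^(non-frameshift-deletion|stop-gain|stop-loss)$")
  expect_equal(eff$exonic_subtype[3], "frameshift-insertion")  # +2 bases

  # in-frame insertion of a stop codon (plus strand, codon-aligned)
  # CDS starts at 201 with phase 0, so an insertion after position 203
  # sits between codons
  anchor <- as.character(Biostrings::subseq(g, 203, 203))
  eff2 <- classify_variants(
    tibble::tibble(chrom = "tig", pos = 203L, ref = anchor,
                   alt = paste0(anchor, "TAA"), vclass = "InDel"),
    fx$genes, fx$genome)
  expect_equal(eff2$exonic_subtype, "stop-gain")
})

test_that("REF mismatches and off-chromosome positions are fatal", {
  fx <- toy_contig_1()
  base <- as.character(Biostrings::subseq(fx$genome[["tig"]], 100, 100))
  wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
  expect_error(
    classify_variants(tibble::tibble(chrom = "tig", pos = 100L, ref = wrong,
                                     alt = base, vclass = "SNP"),
                      fx$genes, fx$genome),
    "REF allele mismatch")
  expect_error(
    classify_variants(tibble::tibble(chrom = "tig", pos = 5000L, ref = "A",
                                     alt = "T", vclass = "SNP"),
                      fx$genes, fx$genome),
    "beyond chromosome length")
})

test_that("classifier matches the brute-force oracle at every position and substitution", {
  fx <- toy_contig_3()
  chrom_seq <- as.character(fx$genome[["tig"]])
  pos <- rep(seq_len(2000L), each = 3)
  ref <- vapply(pos, function(p) substr(chrom_seq, p, p), character(1))
  alt <- unlist(lapply(seq_len(2000L), function(p) {
    setdiff(c("A", "C", "G", "T"), substr(chrom_seq, p, p))
  }))
  v <- tibble::tibble(chrom = "tig", pos = pos, ref = ref, alt = alt,
                      vclass = "SNP")
  eff <- classify_variants(v, fx$genes, fx$genome)

  # oracle over unique positions (category is substitution-independent)
  orc_cat <- vapply(seq_len(2000L), function(p)
    oracle_classify_snv(p, "A", fx$genes, fx$genome)$category, character(1))
  expect_equal(eff$category, orc_cat[pos])

  # oracle subtype at every exonic position x substitution
  exonic <- which(eff$category == "exonic")
  orc_sub <- vapply(exonic, function(i)
    oracle_classify_snv(v$pos[i], v$alt[i], fx$genes, fx$genome)$subtype,
    character(1))
  expect_equal(eff$exonic_subtype[exonic], orc_sub)

  # partition: exactly one category each, subtype present iff exonic
  expect_true(all(eff$category %in% c(
    "intergenic", "upstream", "downstream", "upstream/downstream",
    "intronic", "splicing", "exonic")))
  expect_true(all((eff$exonic_subtype != "none") == (eff$category == "exonic")))
})

test_that("effects are invariant under reverse-complementing the contig", {
  fx <- toy_contig_3()
  L <- 2000L
  rc_genome <- Biostrings::DNAStringSet(c(tig = as.character(
    Biostrings::reverseComplement(fx$genome[[1]]))))
  flip_gene <- function(g) {
    cds <- g$cds[[1]]
    gene_row(g$gene_id, "tig", if (g$strand == "+") "-" else "+",
             L - g$tx_end + 1L, L - g$tx_start + 1L,
             rev(L - cds$end + 1L), rev(L - cds$start + 1L), g$phase)
  }
  rc_genes <- dplyr::bind_rows(lapply(seq_len(nrow(fx$genes)), function(i)
    flip_gene(fx$genes[i, ])))

  set.seed(42)
  pos <- sample.int(L, 300L)
  chrom_seq <- as.character(fx$genome[["tig"]])
  ref <- vapply(pos, function(p) substr(chrom_seq, p, p), character(1))
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  v <- tibble::tibble(chrom = "tig", pos = pos, ref = ref, alt = alt,
                      vclass = "SNP")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_rc <- tibble::tibble(chrom = "tig", pos = L - pos + 1L,
                         ref = unname(comp[ref]), alt = unname(comp[alt]),
                         vclass = "SNP")
  eff <- classify_variants(v, fx$genes, fx$genome)
  eff_rc <- classify_variants(v_rc, rc_genes, rc_genome)
  expect_equal(eff$category, eff_rc$category)
  expect_equal(eff$exonic_subtype, eff_rc$exonic_subtype)
})

test_that("tabulate_effects partitions counts and books transitions + transversions", {
  fx <- toy_contig_3()
  set.seed(3)
  pos <- sample.int(2000L, 400L, replace = FALSE)
  chrom_seq <- as.character(fx$genome[["tig"]])
  ref <- vapply(pos, function(p) substr(chrom_seq, p, p), character(1))
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  v <- tibble::tibble(chrom = "tig", pos = pos, ref = ref, alt = alt,
                      vclass = "SNP")
  eff <- classify_variants(v, fx$genes, fx$genome)
  tab <- tabulate_effects(eff)
  total <- tab$SNP[tab$category == "total"]
  expect_equal(total, 400)
  expect_equal(tab$SNP[tab$category == "transitions"] +
                 tab$SNP[tab$category == "transversions"], total)
  # category rows (excluding bookkeeping) sum to the total
  cat_rows <- !tab$category %in% c("transitions", "transversions", "total")
  expect_equal(sum(tab$SNP[cat_rows], na.rm = TRUE), 400)
  # empty input gives all-zero counts
  tab0 <- tabulate_effects(eff[0, ])
  expect_true(all(tab0$SNP %in% c(0, NA)))
})
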
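# Independent brute-force oracles. These implement the region definitions
# literally (explicit position sets, full-protein retranslation of a mutated
# chromosome) and share no code path with the package classifier.

oracle_region_sets <- function(gene, flank = 1000L) {
  cds <- gene$cds[[1]]
  cds_pos <- unlist(Map(seq.int, cds$start, cds$end))
  splice <- integer(0)
  if (nrow(cds) >= 2L) {
    for (i in seq_len(nrow(cds) - 1L)) {
      a <- cds$end[i] + 1L; b <- cds$start[i + 1L] - 1L
      if (b < a) next
      intron <- seq.int(a, b)
      splice <- c(splice, intron[intron <= a + 1L], intron[intron >= b - 1L])
    }
  }
  genic <- seq.int(gene$tx_start, gene$tx_end)
  if (gene$strand == "+") {
    up <- seq.int(gene$tx_start - flank, gene$tx_start - 1L)
    down <- seq.int(gene$tx_end + 1L, gene$tx_end + flank)
  } else {
    up <- seq.int(gene$tx_end + 1L, gene$tx_end + flank)
    down <- seq.int(gene$tx_start - flank, gene$tx_start - 1L)
  }
  list(cds = cds_pos, splice = unique(splice), genic = genic, up = up,
       down = down)
}

# protein of one gene read off an arbitrary chromosome string
oracle_protein <- function(chrom_seq, gene) {
  cds <- gene$cds[[1]]
  pieces <- vapply(seq_len(nrow(cds)),
                   function(i) substr(chrom_seq, cds$start[i], cds$end[i]),
                   character(1))
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  ph <- gene$phase
  if (ph > 0L) s <- substr(s, ph + 1L, nchar(s))
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  if (nchar(s) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s)))
}

# category + subtype of an SNV by literal set membership and full
# retranslation of the mutated chromosome
oracle_classify_snv <- function(pos, alt, genes, genome, flank = 1000L) {
  chrom_seq <- as.character(genome[[1]])
  per_gene <- character(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    sets <- oracle_region_sets(genes[g, ], flank)
    per_gene[g] <-
      if (pos %in% sets$cds) "exonic"
      else if (pos %in% sets$splice) "splicing"
      else if (pos %in% sets$genic) "intronic"
      else if (pos %in% sets$up) "upstream"
      else if (pos %in% sets$down) "downstream"
      else "intergenic"
  }
  category <-
    if (any(per_gene == "exonic")) "exonic"
    else if (any(per_gene == "splicing")) "splicing"
    else if (any(per_gene == "intronic")) "intronic"
    else if (any(per_gene == "upstream") && any(per_gene == "downstream"))
      "upstream/downstream"
    else if (any(per_gene == "upstream")) "upstream"
    else if (any(per_gene == "downstream")) "downstream"
    else "intergenic"

  subtype <- "none"
  if (category == "exonic") {
    mutated <- chrom_seq
    substr(mutated, pos, pos) <- alt
    subs <- character(0)
    for (g in which(per_gene == "exonic")) {
      old <- oracle_protein(chrom_seq, genes[g, ])
      new <- oracle_protein(mutated, genes[g, ])
      if (old == new) { subs <- c(subs, "synonymous"); next }
      d <- which(strsplit(old, "")[[1]] != strsplit(new, "")[[1]])[1]
      oa <- substr(old, d, d); na <- substr(new, d, d)
      subs <- c(subs,
                if (na == "*" && oa != "*") "stop-gain"
                else if (oa == "*" && na != "*") "stop-loss"
                else "non-synonymous")
    }
    sev <- c("stop-gain" = 1, "stop-loss" = 2, "non-synonymous" = 4,
             "synonymous" = 6)
    subtype <- names(sort(sev[subs]))[1]
  }
  list(category = category, subtype = subtype)
}

# O(n * w) rescan of window means
oracle_window_means <- function(windows, variants) {
  out <- windows
  out$n <- 0L; out$mean_delta <- NA_real_
  out$mean_index_high <- NA_real_; out$mean_index_low <- NA_real_
  for (i in seq_len(nrow(windows))) {
    m <- variants$chrom == windows$chrom[i] &
      variants$pos >= windows$start[i] & variants$pos <= windows$end[i]
    out$n[i] <- sum(m)
    if (any(m)) {
      out$mean_delta[i] <- mean(variants$delta[m])
      out$mean_index_high[i] <- mean(variants$index_high[m])
      out$mean_index_low[i] <- mean(variants$index_low[m])
    }
  }
  out
}
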
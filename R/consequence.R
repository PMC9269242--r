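
# -- allele normalisation ----------------------------------------------------
# Accepts VCF-anchored alleles (REF "AGCAGT" / ALT "A") and dash notation
# (REF "GCAGT" / ALT "-"). Returns the minimal edit and the genomic interval
# it touches; a pure insertion is located at its anchor base.
normalize_allele <- function(pos, ref, alt) {
  if (ref == alt) abort("ref and alt alleles are identical")
  if (alt == "-" || alt == "") {
    return(list(start = pos, end = pos + nchar(ref) - 1L, ref = ref, alt = "",
                type = "del"))
  }
  if (ref == "-" || ref == "") {
    return(list(start = pos, end = pos, ref = "", alt = alt, type = "ins",
                anchor = pos))
  }
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  # strip common suffix, then common prefix; ref != alt guarantees the two
  # can never both empty out
  while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)] &&
         !(length(r) == 1L && length(a) == 1L)) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  k <- 0L
  while (k < min(length(r), length(a)) && r[k + 1L] == a[k + 1L]) {
    k <- k + 1L
  }
  r0 <- if (k < length(r)) r[(k + 1L):length(r)] else character(0)
  a0 <- if (k < length(a)) a[(k + 1L):length(a)] else character(0)
  p0 <- pos + k
  ref0 <- paste(r0, collapse = ""); alt0 <- paste(a0, collapse = "")
  if (nchar(ref0) == 0L) {
    return(list(start = p0 - 1L, end = p0 - 1L, ref = "", alt = alt0,
                type = "ins", anchor = p0 - 1L))
  }
  if (nchar(alt0) == 0L) {
    return(list(start = p0, end = p0 + nchar(ref0) - 1L, ref = ref0, alt = "",
                type = "del"))
  }
  type <- if (nchar(ref0) == 1L && nchar(alt0) == 1L) "snv"
          else if (nchar(ref0) == nchar(alt0)) "mnv" else "delins"
  list(start = p0, end = p0 + nchar(ref0) - 1L, ref = ref0, alt = alt0,
       type = type)
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(s) {
  if (nchar(s) == 0L) return(s)
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}

# genomic positions of coding bases, transcription order, phase trimmed
coding_positions <- function(gene) {
  cds <- gene$cds[[1]]
  pos <- unlist(Map(seq.int, cds$start, cds$end), use.names = FALSE)
  if (gene$strand == "-") pos <- rev(pos)
  ph <- gene$phase %||% 0L
  if (ph > 0L) pos <- pos[-seq_len(ph)]
  pos
}

coding_seq_of <- function(genome, gene, cpos) {
  bases <- vapply(cpos, function(p)
    as.character(Biostrings::subseq(genome[[gene$chrom[1]]], p, p)), character(1))
  if (gene$strand == "-") bases <- unname(COMP[bases])
  paste(bases, collapse = "")
}

# region overlap helpers (all 1-based inclusive)
olap <- function(vs, ve, s, e) vs <= e && ve >= s

# severity order used when one variant hits the CDS of several transcripts
SUBTYPE_SEVERITY <- c("stop-gain" = 1, "stop-loss" = 2,
                      "frameshift-insertion" = 3, "frameshift-deletion" = 3,
                      "non-synonymous" = 4,
                      "non-frameshift-insertion" = 5,
                      "non-frameshift-deletion" = 5,
                      "synonymous" = 6, "unknown" = 7)

# classify one variant against one gene; returns gene-level category
gene_region <- function(vs, ve, gene, flank = 1000L) {
  cds <- gene$cds[[1]]
  if (any(vapply(seq_len(nrow(cds)),
                 function(i) olap(vs, ve, cds$start[i], cds$end[i]), logical(1)))) {
    return("exonic")
  }
  if (nrow(cds) >= 2L) {
    for (i in seq_len(nrow(cds) - 1L)) {
      is <- cds$end[i] + 1L; ie <- cds$start[i + 1L] - 1L
      if (ie < is) next
      jn <- unique(c(seq.int(is, min(is + 1L, ie)), seq.int(max(ie - 1L, is), ie)))
      if (any(vs <= jn & ve >= jn)) return("splicing")
    }
  }
  if (olap(vs, ve, gene$tx_start, gene$tx_end)) return("intronic")
  up <- if (gene$strand == "+") c(gene$tx_start - flank, gene$tx_start - 1L)
        else c(gene$tx_end + 1L, gene$tx_end + flank)
  dn <- if (gene$strand == "+") c(gene$tx_end + 1L, gene$tx_end + flank)
        else c(gene$tx_start - flank, gene$tx_start - 1L)
  if (olap(vs, ve, up[1], up[2])) return("upstream")
  if (olap(vs, ve, dn[1], dn[2])) return("downstream")
  "intergenic"
}

# exonic subtype of one variant within one gene's CDS
exonic_subtype_for <- function(nv, gene, genome) {
  cpos <- coding_positions(gene)
  minus <- gene$strand == "-"
  if (nv$type == "snv") {
    i <- match(nv$start, cpos)
    if (is.na(i)) return(list(subtype = "unknown", aa = NULL))  # phase-trimmed base
    ci <- (i - 1L) %/% 3L
    idx <- ci * 3L + 1:3
    if (idx[3] > length(cpos)) return(list(subtype = "unknown", aa = NULL))
    codon_pos <- cpos[idx]
    bases <- vapply(codon_pos, function(p)
      as.character(Biostrings::subseq(genome[[gene$chrom[1]]], p, p)), character(1))
    if (minus) bases <- unname(COMP[bases])
    ref_codon <- paste(bases, collapse = "")
    alt_base <- if (minus) unname(COMP[nv$alt]) else nv$alt
    bases[match(nv$start, codon_pos)] <- alt_base
    alt_codon <- paste(bases, collapse = "")
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
    subtype <-
      if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop-gain"
      else if (ref_aa == "*") "stop-loss"
      else "non-synonymous"
    return(list(subtype = subtype,
                aa = list(ref_aa = ref_aa, codon_index = ci + 1L, alt_aa = alt_aa)))
  }

  # indel / mnv / delins: length rule first, then stop checks for in-frame
  # edits fully contained in the coding sequence
  net <- nchar(nv$alt) - nchar(nv$ref)
  if (net %% 3L != 0L) {
    return(list(subtype = if (net > 0L) "frameshift-insertion" else "frameshift-deletion",
                aa = NULL))
  }
  fallback <- if (net > 0L) "non-frameshift-insertion"
              else if (net < 0L) "non-frameshift-deletion"
              else "non-synonymous"

  old <- coding_seq_of(genome, gene, cpos)
  if (nv$type == "ins") {
    a <- nv$anchor
    i_aft <- if (minus) match(a + 1L, cpos) else match(a, cpos)
    if (is.na(i_aft)) return(list(subtype = fallback, aa = NULL))
    insert <- if (minus) revcomp_chr(nv$alt) else nv$alt
    new <- paste0(substr(old, 1L, i_aft), insert,
                  substr(old, i_aft + 1L, nchar(old)))
    c1 <- (i_aft - 1L) %/% 3L + 1L
    c2_old <- min((i_aft + 2L) %/% 3L + 1L, nchar(old) %/% 3L)
  } else {
    span <- seq.int(nv$start, nv$end)
    ii <- match(span, cpos)
    if (anyNA(ii)) return(list(subtype = fallback, aa = NULL))  # spans CDS edge
    i1 <- min(ii); i2 <- max(ii)
    repl <- if (minus) revcomp_chr(nv$alt) else nv$alt
    new <- paste0(substr(old, 1L, i1 - 1L), repl,
                  substr(old, i2 + 1L, nchar(old)))
    c1 <- (i1 - 1L) %/% 3L + 1L
    c2_old <- (i2 - 1L) %/% 3L + 1L
  }
  old_aa <- translate_codons(old)
  new_aa <- translate_codons(new)
  c2_new <- min(c2_old + net %/% 3L, length(new_aa))
  old_win <- old_aa[seq.int(c1, min(c2_old, length(old_aa)))]
  new_win <- if (c1 <= c2_new) new_aa[seq.int(c1, c2_new)] else character(0)
  subtype <-
    if (any(new_win == "*") && !any(old_win == "*")) "stop-gain"
    else if (any(old_win == "*") && !any(new_win == "*")) "stop-loss"
    else fallback
  list(subtype = subtype, aa = NULL)
}

#' Classify variants against gene models
#'
#' Assigns every variant exactly one region category — `exonic`, `splicing`,
#' `intronic`, `upstream/downstream`, `upstream`, `downstream` or
#' `intergenic` — using the standard BSA-seq annotation conventions:
#' `upstream`/`downstream` mean within 1 kb of the transcription start/end
#' (strand-aware); `splicing` means within 2 bp of an exon/intron junction
#' on the intron side; the joint `upstream/downstream` category applies when
#' a variant is upstream of one gene and downstream of another at the same
#' time. Precedence when several regions are touched: exonic > splicing >
#' intronic > upstream/downstream > upstream > downstream > intergenic.
#'
#' Exonic SNVs are translated codon-by-codon on the coding strand with the
#' standard nuclear genetic code to give `synonymous`, `non-synonymous`,
#' `stop-gain` or `stop-loss`; coding indels are `frameshift-*` when the net
#' inserted/deleted length is not a multiple of three, otherwise
#' `non-frameshift-*` with an immediate stop-codon creation/elimination
#' check. Indels spanning a CDS boundary are assigned `exonic` with the
#' length rule only and flagged. Genic positions outside the annotated CDS
#' intervals and their introns (UTR-like stretches) are reported `intronic`,
#' since the taxonomy carries no UTR class.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` (and optionally
#'   `vclass`). Dash alleles (`"-"`) and VCF-anchored indels are both
#'   understood.
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param flank Width of the upstream/downstream flanks in bases
#'   (default 1000).
#'
#' @return The input tibble with columns `category`, `exonic_subtype`
#'   (`"none"` unless exonic), `gene_id` (comma-joined when several genes
#'   back the call), `aa_ref`, `codon_index`, `aa_alt` (exonic SNVs only),
#'   `cds_boundary` flag and `substitution` (`"transition"`,
#'   `"transversion"` or `NA`).
#' @export
classify_variants <- function(variants, genes, genome, flank = 1000L) {
  assert_cols(variants, c("chrom", "pos", "ref", "alt"), "variants")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  n <- nrow(variants)
  category <- character(n); subtype <- character(n); gene_id <- character(n)
  aa_ref <- character(n); aa_alt <- character(n); codon_index <- integer(n)
  boundary <- logical(n)

  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  gene_rows <- split(seq_len(nrow(genes)), genes$chrom)

  for (v in seq_len(n)) {
    chrom <- variants$chrom[v]; pos <- variants$pos[v]
    if (!chrom %in% names(genome)) {
      abort(sprintf("chromosome '%s' not in genome", chrom))
    }
    ref <- variants$ref[v]; alt <- sub(",.*$", "", variants$alt[v])
    if (pos > chrom_len[[chrom]]) {
      abort(sprintf("position %s:%d beyond chromosome length %d",
                    chrom, pos, chrom_len[[chrom]]))
    }
    if (ref != "-" && ref != "") {
      ref_end <- min(pos + nchar(ref) - 1L, chrom_len[[chrom]])
      have <- as.character(Biostrings::subseq(genome[[chrom]], pos, ref_end))
      if (!identical(have, ref)) {
        abort(sprintf("REF allele mismatch at %s:%d (VCF '%s', genome '%s')",
                      chrom, pos, ref, have))
      }
    }
    nv <- normalize_allele(pos, ref, alt)

    g_idx <- gene_rows[[chrom]] %||% integer(0)
    cats <- character(0)
    for (gi in g_idx) {
      g <- genes[gi, , drop = FALSE]
      cats <- c(cats, setNames(gene_region(nv$start, nv$end, g, flank), g$gene_id))
    }

    pick <- function(what) names(cats)[cats == what]
    if (any(cats == "exonic")) {
      ex_genes <- pick("exonic")
      subs <- list(); flagged <- FALSE
      for (gid in ex_genes) {
        g <- genes[g_idx[genes$gene_id[g_idx] == gid], , drop = FALSE]
        st <- exonic_subtype_for(nv, g, genome)
        # boundary-spanning deletions keep the length rule only
        if (nv$type %in% c("del", "delins", "mnv")) {
          span_in <- all(seq.int(nv$start, nv$end) %in% coding_positions(g))
          if (!span_in) flagged <- TRUE
        }
        subs[[gid]] <- st
      }
      sev <- vapply(subs, function(s) SUBTYPE_SEVERITY[[s$subtype]], numeric(1))
      best <- names(which.min(sev))
      category[v] <- "exonic"
      subtype[v] <- subs[[best]]$subtype
      gene_id[v] <- paste(ex_genes, collapse = ",")
      boundary[v] <- flagged
      aa <- subs[[best]]$aa
      if (!is.null(aa)) {
        aa_ref[v] <- aa$ref_aa; aa_alt[v] <- aa$alt_aa
        codon_index[v] <- aa$codon_index
      } else {
        aa_ref[v] <- NA_character_; aa_alt[v] <- NA_character_
        codon_index[v] <- NA_integer_
      }
    } else {
      aa_ref[v] <- NA_character_; aa_alt[v] <- NA_character_
      codon_index[v] <- NA_integer_
      subtype[v] <- "none"
      if (any(cats == "splicing")) {
        category[v] <- "splicing"; gene_id[v] <- paste(pick("splicing"), collapse = ",")
      } else if (any(cats == "intronic")) {
        category[v] <- "intronic"; gene_id[v] <- paste(pick("intronic"), collapse = ",")
      } else if (any(cats == "upstream") && any(cats == "downstream")) {
        category[v] <- "upstream/downstream"
        gene_id[v] <- paste(c(pick("upstream"), pick("downstream")), collapse = ",")
      } else if (any(cats == "upstream")) {
        category[v] <- "upstream"; gene_id[v] <- paste(pick("upstream"), collapse = ",")
      } else if (any(cats == "downstream")) {
        category[v] <- "downstream"; gene_id[v] <- paste(pick("downstream"), collapse = ",")
      } else {
        category[v] <- "intergenic"; gene_id[v] <- NA_character_
      }
    }
  }

  first_alt <- sub(",.*$", "", variants$alt)
  is_snv <- nchar(variants$ref) == 1L & nchar(first_alt) == 1L &
    variants$ref != "-" & first_alt != "-"
  ts_pairs <- c("AG", "GA", "CT", "TC")
  substitution <- ifelse(is_snv,
                         ifelse(paste0(variants$ref, first_alt) %in% ts_pairs,
                                "transition", "transversion"),
                         NA_character_)

  variants |>
    mutate(category = category, exonic_subtype = subtype, gene_id = gene_id,
           aa_ref = aa_ref, codon_index = codon_index, aa_alt = aa_alt,
           cds_boundary = boundary, substitution = substitution)
}

#' Tabulate classified variants into an effect table
#'
#' Counts variants per category — with the exonic class split by subtype —
#' separately for SNPs and InDels, the layout of a standard BSA-seq
#' annotation summary. Categories impossible for a class (e.g. frameshift
#' for an SNV) are reported as `NA` rather than zero; transition and
#' transversion counts and the total are appended for the SNP class.
#'
#' @param effects Output of [classify_variants()] (needs `vclass`).
#' @return A tibble with columns `category`, `SNP`, `InDel`.
#' @export
tabulate_effects <- function(effects) {
  assert_cols(effects, c("category", "exonic_subtype", "vclass"), "effects")
  lab <- ifelse(effects$category == "exonic", effects$exonic_subtype,
                effects$category)
  indel_only <- c("frameshift-insertion", "frameshift-deletion",
                  "non-frameshift-insertion", "non-frameshift-deletion")
  cats <- c("intergenic", "upstream", "downstream", "upstream/downstream",
            "intronic", "stop-gain", "stop-loss",
            "frameshift-deletion", "frameshift-insertion",
            "non-frameshift-deletion", "non-frameshift-insertion",
            "synonymous", "non-synonymous", "splicing", "unknown")
  count_for <- function(class) {
    x <- lab[effects$vclass == class]
    vapply(cats, function(cc) sum(x == cc), integer(1))
  }
  snp <- count_for("SNP"); indel <- count_for("InDel")
  out <- tibble(category = cats, SNP = as.numeric(snp), InDel = as.numeric(indel))
  out$SNP[out$category %in% indel_only] <- NA_real_
  out$InDel[out$category %in% c("synonymous", "non-synonymous")] <- NA_real_
  is_snv <- effects$vclass == "SNP"
  out <- bind_rows(
    out,
    tibble(category = c("transitions", "transversions", "total"),
           SNP = c(sum(effects$substitution[is_snv] == "transition", na.rm = TRUE),
                   sum(effects$substitution[is_snv] == "transversion", na.rm = TRUE),
                   sum(is_snv)),
           InDel = c(NA, NA, sum(effects$vclass == "InDel")))
  )
  out
}

#' Write an effect table in candidate-gene column order
#'
#' Column order follows the conventional candidate-variant report: position,
#' chromosome, REF, ALT, effect, gene, plus optional ortholog/description
#' pass-through columns.
#'
#' @param effects Output of [classify_variants()].
#' @param path Output TSV path.
#' @param annotations Optional tibble with `gene_id`, `ortholog`,
#'   `description` pass-through columns.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(effects, path, annotations = NULL) {
  eff <- effects |>
    mutate(effect = ifelse(.data$category == "exonic",
                           .data$exonic_subtype, .data$category)) |>
    select("pos", "chrom", "ref", "alt", "effect", "gene_id")
  names(eff) <- c("position", "chromosome", "ref", "alt", "effect", "gene_id")
  if (!is.null(annotations)) {
    eff <- left_join(eff, annotations, by = "gene_id")
  }
  readr::write_tsv(eff, path, progress = FALSE)
  invisible(path)
}
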
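#' Read a two-pool VCF into a pooled-variant table
#'
#' Parses a VCF containing the two bulk samples of a BSA-seq experiment and
#' extracts, for every record, the per-pool allele depths (the `AD` FORMAT
#' field) from which the SNP/InDel index is later computed. Multi-allelic
#' records are kept and flagged so the filter stage can count them; they are
#' never silently dropped.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param high_sample,low_sample Sample names of the high- and low-phenotype
#'   pools. Defaults match the bulks of a vitamin-E tocopherol experiment
#'   (`"VE-High"`, `"VE-Low"`) but any pair present in the VCF works.
#'
#' @return A tibble with one row per VCF record, columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (comma-joined for multi-allelic records),
#'   `vclass` (`"SNP"` or `"InDel"`), `multiallelic`, and the four read
#'   counts `ad_high_ref`, `ad_high_alt`, `ad_low_ref`, `ad_low_alt`
#'   (for multi-allelic records the first ALT's depth). Rows are sorted by
#'   `(chrom, pos)`.
#'
#' @examples
#' \dontrun{
#' variants <- read_pooled_vcf("pools.vcf", "VE-High", "VE-Low")
#' }
#' @export
read_pooled_vcf <- function(path, high_sample = "VE-High", low_sample = "VE-Low") {
  vcf <- VariantAnnotation::readVcf(path)
  smp <- colnames(vcf)
  for (s in c(high_sample, low_sample)) {
    if (!s %in% smp) {
      abort(sprintf("sample '%s' not found in VCF (samples present: %s)",
                    s, paste(smp, collapse = ", ")))
    }
  }
  n <- nrow(vcf)
  if (n == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), vclass = character(),
                  multiallelic = logical(),
                  ad_high_ref = integer(), ad_high_alt = integer(),
                  ad_low_ref = integer(), ad_low_alt = integer()))
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) {
    abort(sprintf("VCF '%s' has no per-sample AD (allele depth) FORMAT field; the index is defined on read counts", path))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt <- vapply(as.list(alt_list), function(a) paste(as.character(a), collapse = ","), character(1))

  get_ad <- function(sample) {
    col <- ad[, sample]
    refs <- vapply(col, function(v) as.integer(v[1]), integer(1),
                   USE.NAMES = FALSE)
    alts <- vapply(col, function(v)
      if (length(v) >= 2) as.integer(v[2]) else NA_integer_, integer(1),
      USE.NAMES = FALSE)
    list(ref = unname(refs), alt = unname(alts))
  }
  hi <- get_ad(high_sample)
  lo <- get_ad(low_sample)
  bad <- which(is.na(hi$ref) | is.na(hi$alt) | is.na(lo$ref) | is.na(lo$alt))
  if (length(bad) > 0L) {
    abort(sprintf("missing allele depths at %s",
                  paste(sprintf("%s:%d", chrom[bad[1]], pos[bad[1]]), collapse = ", ")))
  }

  out <- tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    multiallelic = n_alt > 1L,
    ad_high_ref = hi$ref, ad_high_alt = hi$alt,
    ad_low_ref = lo$ref, ad_low_alt = lo$alt
  )
  first_alt <- sub(",.*$", "", out$alt)
  out$vclass <- ifelse(nchar(out$ref) == 1L & nchar(first_alt) == 1L &
                         !out$multiallelic, "SNP", "InDel")
  out <- dplyr::relocate(out, "vclass", .after = "alt")
  arrange(out, .data$chrom, .data$pos)
}

#' Read gene models from a GFF3 file
#'
#' Builds one gene model per mRNA feature: strand, transcription bounds, and
#' the ordered coding (CDS) intervals used by the consequence classifier.
#' Coordinates are kept 1-based inclusive exactly as in the GFF3.
#'
#' @param path Path to a GFF3 file with `gene`/`mRNA`/`CDS` features.
#'
#' @return A tibble with one row per mRNA: `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `phase` (frame offset of the first coding base in
#'   transcription order), and a list-column `cds` of tibbles
#'   (`start`, `end`), sorted ascending regardless of strand.
#'
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  mrna <- gr[type == "mRNA"]
  cds <- gr[type == "CDS"]
  if (length(mrna) == 0L) abort(sprintf("no mRNA features in '%s'", path))
  cds_parent <- vapply(as.list(cds$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }, character(1))
  if (anyNA(cds_parent)) abort("CDS feature without a Parent mRNA")
  mrna_ids <- as.character(mrna$ID)
  orphan <- setdiff(unique(cds_parent), mrna_ids)
  if (length(orphan) > 0L) {
    abort(sprintf("CDS with unknown parent(s): %s", paste(orphan, collapse = ", ")))
  }

  models <- purrr::map(seq_along(mrna), function(i) {
    id <- mrna_ids[i]
    kid <- cds[cds_parent == id]
    if (length(kid) == 0L) return(NULL)   # non-coding transcript: skipped
    o <- order(GenomicRanges::start(kid))
    kid <- kid[o]
    s <- GenomicRanges::start(kid); e <- GenomicRanges::end(kid)
    if (length(s) > 1L && any(s[-1] <= e[-length(e)])) {
      abort(sprintf("overlapping CDS intervals in transcript '%s'", id))
    }
    strand <- as.character(GenomicRanges::strand(mrna[i]))
    if (!strand %in% c("+", "-")) abort(sprintf("transcript '%s' has no strand", id))
    tx_s <- GenomicRanges::start(mrna[i]); tx_e <- GenomicRanges::end(mrna[i])
    if (s[1] < tx_s || e[length(e)] > tx_e) {
      abort(sprintf("CDS outside transcript bounds for '%s'", id))
    }
    if (sum(e - s + 1L) < 3L) abort(sprintf("total CDS length < 3 for '%s'", id))
    ph <- as.integer(kid$phase)
    ph1 <- if (strand == "+") ph[1] else ph[length(ph)]
    tibble(gene_id = id,
           chrom = as.character(GenomicRanges::seqnames(mrna[i])),
           strand = strand,
           tx_start = as.integer(tx_s), tx_end = as.integer(tx_e),
           phase = ifelse(is.na(ph1), 0L, ph1),
           cds = list(tibble(start = as.integer(s), end = as.integer(e))))
  })
  out <- bind_rows(models)
  arrange(out, .data$chrom, .data$tx_start)
}

#' Read a gene-to-GO annotation table
#'
#' @param path TSV with header columns `gene_id`, `go_id`, `ontology`, `term`.
#' @return A tibble with those columns.
#' @export
read_annotation_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(x, c("gene_id", "go_id", "ontology", "term"), "annotation table")
  as_tibble(x)
}

#' Read an accession phenotype/genotype table
#'
#' One row per accession x environment with the phenotype value (total
#' tocopherol in a vitamin-E experiment, in micrograms per gram) and the
#' allele call at the query site.
#'
#' @param path TSV with header columns `accession_id`, `accession_type`
#'   (`cultivar`/`landrace`), `environment`, `phenotype`, `allele`
#'   (`REF`, `ALT`, `HET` or `missing`).
#' @return A tibble with those columns.
#' @export
read_phenotype_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(x, c("accession_id", "accession_type", "environment",
                   "phenotype", "allele"), "phenotype table")
  if (any(!is.finite(x$phenotype))) abort("non-finite phenotype values")
  if (anyDuplicated(x[c("accession_id", "environment")]) > 0L) {
    abort("duplicated accession x environment rows")
  }
  as_tibble(x)
}

#' Write candidate regions as BED3
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' an interval `[s, e]` is emitted as `(s - 1, e)`.
#'
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  if (nrow(regions) > 0L && any(regions$end < regions$start)) {
    abort("region with end < start")
  }
  lines <- sprintf("%s\t%d\t%d", regions$chrom,
                   as.integer(regions$start) - 1L, as.integer(regions$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 file back into 1-based inclusive regions
#'
#' @param path BED3 path.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(chrom = map_chr(parts, 1),
         start = as.integer(map_chr(parts, 2)) + 1L,
         end = as.integer(map_chr(parts, 3)))
}

#' Write / read the internal variant table as TSV
#'
#' Plain tab-separated round-trip of the pooled-variant (or indexed-variant)
#' table; all columns are preserved exactly.
#'
#' @param variants A variant tibble.
#' @param path File path.
#' @return `write_variants_tsv()` returns `path` invisibly;
#'   `read_variants_tsv()` returns the tibble.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(chrom = "c", ref = "c", alt = "c"))
}
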
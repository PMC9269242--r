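#' Configuration of the synthetic extreme-pool experiment
#'
#' The generator emulates a BSA-seq design on a natural population: a panel
#' of accessions (default 1525, mixed cultivars and landraces) with a
#' quantitative phenotype driven by one causal biallelic locus plus Gaussian
#' noise, measured in several location-year environments; the top and bottom
#' `n_pool` accessions (default 49 each) are bulked and sequenced at ~40x
#' mean depth. Defaults are anchored to the tocopherol experiment the
#' package emulates: baseline 230 ug/g, additive effect 40 ug/g at allele
#' frequency 0.4 with residual sd 35 ug/g (narrow-sense h2 ~ 0.39 within an
#' environment), environments named after location-year codes.
#'
#' @param n_accessions Panel size (default 1525).
#' @param n_pool Accessions per extreme pool (default 49).
#' @param n_chromosomes,chrom_length Genome shape (default 20 x 5 Mb — a
#'   desk-scale stand-in for the ~1 Gb soybean genome).
#' @param n_variants Total segregating sites (default 12000, ~120 per Mb).
#' @param indel_fraction Fraction of sites that are 1-bp indels
#'   (default 0.15, the genome-wide InDel:SNP proportion of a typical
#'   resequencing experiment).
#' @param causal_sites Data frame with columns `chrom`, `pos`, `effect`
#'   (additive effect in phenotype units per ALT allele) and `freq`.
#'   Default: one site mid-chromosome `Chr05` with effect 40 at frequency
#'   0.4.
#' @param mu Phenotype baseline (default 230).
#' @param sigma_e Residual phenotype sd per environment (default 35).
#' @param env_sd Sd of the per-environment offsets (default 10).
#' @param freq_range Allele-frequency law for neutral sites: uniform on this
#'   interval (default `c(0.05, 0.5)`).
#' @param mean_depth Poisson mean sequencing depth per pool per site
#'   (default 40).
#' @param seq_error Symmetric per-read sequencing error (default 0.001).
#' @param environments Environment codes (default location-year codes
#'   `A17, B17, B18, H17, H18`).
#' @param cultivar_fraction Fraction of accessions labelled cultivar
#'   (default 0.5).
#' @param ld Block-LD mode: flanking sites copy the causal genotype so the
#'   delta peak has realistic width (default FALSE — independent sites).
#' @param ld_r Per-accession copy probability inside the LD block
#'   (default 0.95, long-haplotype linkage typical of a selfing crop).
#' @param ld_halfwidth Half-width of the LD block in bases (default 1.5e6).
#' @param rng_seed Seed applied by the generator functions.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_accessions = 1525, n_pool = 49,
                       n_chromosomes = 20, chrom_length = 5e6,
                       n_variants = 12000, indel_fraction = 0.15,
                       causal_sites = NULL,
                       mu = 230, sigma_e = 35, env_sd = 10,
                       freq_range = c(0.05, 0.5),
                       mean_depth = 40, seq_error = 0.001,
                       environments = c("A17", "B17", "B18", "H17", "H18"),
                       cultivar_fraction = 0.5,
                       ld = FALSE, ld_r = 0.95, ld_halfwidth = 1.5e6,
                       rng_seed = NULL) {
  if (2 * n_pool > n_accessions) abort("2 * n_pool must not exceed n_accessions")
  if (is.null(causal_sites)) {
    chrom5 <- sprintf("Chr%02d", min(5, n_chromosomes))
    causal_sites <- tibble(chrom = chrom5,
                           pos = as.integer(chrom_length / 2),
                           effect = 40, freq = 0.4)
  }
  causal_sites <- as_tibble(causal_sites)
  assert_cols(causal_sites, c("chrom", "pos", "effect", "freq"), "causal_sites")
  structure(list(
    n_accessions = as.integer(n_accessions), n_pool = as.integer(n_pool),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_variants = as.integer(n_variants), indel_fraction = indel_fraction,
    causal_sites = causal_sites, mu = mu, sigma_e = sigma_e, env_sd = env_sd,
    freq_range = freq_range, mean_depth = mean_depth, seq_error = seq_error,
    environments = environments, cultivar_fraction = cultivar_fraction,
    ld = isTRUE(ld), ld_r = ld_r, ld_halfwidth = ld_halfwidth,
    rng_seed = rng_seed), class = "sim_config")
}

#' Chromosome lengths of a simulation configuration
#' @param config A [sim_config()].
#' @return Named integer vector.
#' @export
sim_chrom_lengths <- function(config) {
  setNames(rep(config$chrom_length, config$n_chromosomes),
           sprintf("Chr%02d", seq_len(config$n_chromosomes)))
}

random_dna <- function(n) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)])
}

pick_other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a genotyped, phenotyped accession panel
#'
#' Sites are placed uniformly over the genome with allele frequencies drawn
#' from the configured law; genotypes are drawn site-wise under
#' Hardy-Weinberg. The phenotype of accession `i` in environment `e` is
#' `mu + sum(effect * dosage) + offset_e + N(0, sigma_e)`, with one offset
#' per environment drawn once per cohort. With `ld = TRUE`, sites within
#' `ld_halfwidth` of a causal site copy that accession's causal genotype
#' with probability `ld_r`, giving the delta peak its width.
#'
#' @param config A [sim_config()].
#' @param genome Optional named `DNAStringSet`; when supplied, REF alleles
#'   are read from it (and ALT alleles chosen to differ) so that downstream
#'   consequence classification is consistent.
#' @return An object of class `"synthetic_cohort"`: list with `accessions`
#'   (id, type), `sites` (chrom, pos, ref, alt, vclass, freq, causal,
#'   effect), `genotypes` (accessions x sites dosage matrix), `phenotypes`
#'   (accessions x environments), `env_offsets`, `config`.
#' @export
sim_cohort <- function(config = sim_config(), genome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  lens <- sim_chrom_lengths(config)
  n_site <- config$n_variants
  n_acc <- config$n_accessions

  chrom <- sample(names(lens), n_site, replace = TRUE)
  pos <- vapply(chrom, function(ch) sample.int(lens[[ch]] - 2L, 1L) + 1L,
                integer(1), USE.NAMES = FALSE)
  sites <- dplyr::distinct(tibble(chrom = chrom, pos = pos))
  is_indel <- stats::runif(nrow(sites)) < config$indel_fraction
  sites$vclass <- ifelse(is_indel, "InDel", "SNP")
  sites$freq <- stats::runif(nrow(sites), config$freq_range[1], config$freq_range[2])
  sites$causal <- FALSE
  sites$effect <- 0

  cs <- config$causal_sites
  sites <- sites[!(paste(sites$chrom, sites$pos) %in% paste(cs$chrom, cs$pos)), ]
  sites <- bind_rows(sites,
                     tibble(chrom = cs$chrom, pos = as.integer(cs$pos),
                            vclass = "SNP", freq = cs$freq, causal = TRUE,
                            effect = cs$effect))
  sites <- arrange(sites, .data$chrom, .data$pos)

  # alleles
  if (is.null(genome)) {
    ref1 <- sample(c("A", "C", "G", "T"), nrow(sites), replace = TRUE)
  } else {
    ref1 <- vapply(seq_len(nrow(sites)), function(i)
      as.character(Biostrings::subseq(genome[[sites$chrom[i]]],
                                      sites$pos[i], sites$pos[i])), character(1))
  }
  alt1 <- pick_other_base(ref1)
  second <- if (is.null(genome)) {
    sample(c("A", "C", "G", "T"), nrow(sites), replace = TRUE)
  } else {
    vapply(seq_len(nrow(sites)), function(i)
      as.character(Biostrings::subseq(genome[[sites$chrom[i]]],
                                      sites$pos[i] + 1L, sites$pos[i] + 1L)),
      character(1))
  }
  ins_base <- sample(c("A", "C", "G", "T"), nrow(sites), replace = TRUE)
  del <- sites$vclass == "InDel" & stats::runif(nrow(sites)) < 0.5
  ins <- sites$vclass == "InDel" & !del
  sites$ref <- ref1
  sites$alt <- alt1
  sites$ref[del] <- paste0(ref1[del], second[del])   # 1-bp anchored deletion
  sites$alt[del] <- ref1[del]
  sites$ref[ins] <- ref1[ins]
  sites$alt[ins] <- paste0(ref1[ins], ins_base[ins]) # 1-bp anchored insertion

  # genotypes under Hardy-Weinberg
  m <- nrow(sites)
  g <- matrix(rbinom(n_acc * m, 2L, rep(sites$freq, each = n_acc)),
              nrow = n_acc)

  # block LD around causal sites
  if (config$ld) {
    for (ci in which(sites$causal)) {
      near <- which(sites$chrom == sites$chrom[ci] &
                      abs(sites$pos - sites$pos[ci]) <= config$ld_halfwidth &
                      seq_len(m) != ci)
      for (j in near) {
        copy <- stats::runif(n_acc) < config$ld_r
        g[copy, j] <- g[copy, ci]
      }
    }
  }

  env <- config$environments
  offsets <- setNames(rnorm(length(env), 0, config$env_sd), env)
  gv <- as.vector(g[, sites$causal, drop = FALSE] %*% sites$effect[sites$causal])
  pheno <- vapply(env, function(e)
    config$mu + gv + offsets[[e]] + rnorm(n_acc, 0, config$sigma_e),
    numeric(n_acc))
  acc_ids <- sprintf("ACC%04d", seq_len(n_acc))
  rownames(pheno) <- acc_ids

  accessions <- tibble(
    accession_id = acc_ids,
    type = ifelse(stats::runif(n_acc) < config$cultivar_fraction,
                  "cultivar", "landrace"))

  structure(list(accessions = accessions, sites = sites, genotypes = g,
                 phenotypes = pheno, env_offsets = offsets, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d accessions, %d sites (%d causal), %d environments\n",
              nrow(x$accessions), nrow(x$sites), sum(x$sites$causal),
              ncol(x$phenotypes)))
  invisible(x)
}

#' Select the extreme-phenotype pools
#'
#' Picks the top and bottom `n_pool` accessions by phenotype — the mean
#' across environments by default, or one environment's value. Ties are
#' broken by accession id, which makes the split deterministic.
#'
#' @param cohort A [sim_cohort()] result.
#' @param environment Environment code, or `NULL` (default) for the
#'   across-environment mean.
#' @param n_pool Pool size (default from the cohort's config).
#' @return List with character vectors `high` and `low` of accession ids
#'   (disjoint by construction).
#' @export
select_pools <- function(cohort, environment = NULL, n_pool = NULL) {
  n_pool <- n_pool %||% cohort$config$n_pool
  score <- if (is.null(environment)) {
    rowMeans(cohort$phenotypes)
  } else {
    if (!environment %in% colnames(cohort$phenotypes)) {
      abort(sprintf("unknown environment '%s'", environment))
    }
    cohort$phenotypes[, environment]
  }
  ids <- cohort$accessions$accession_id
  # one total order (score, then id) so tied phenotypes still give
  # deterministic, disjoint pools
  ord <- ids[order(score, ids)]
  lo <- ord[seq_len(n_pool)]
  hi <- rev(ord)[seq_len(n_pool)]
  list(high = hi, low = lo)
}

#' Simulate pooled sequencing reads over the two bulks
#'
#' For each site and pool, the true pool ALT frequency is the mean dosage
#' over the pooled accessions divided by two (equal DNA contribution per
#' accession); the read depth is Poisson with the configured mean, and ALT
#' read counts are binomial at the error-adjusted frequency
#' `q(1-e) + (1-q)e`.
#'
#' @param cohort A [sim_cohort()] result.
#' @param pools Pool membership from [select_pools()].
#' @param vcf_path Optional path: write the two-sample VCF (samples
#'   `VE-High`, `VE-Low` with AD fields).
#' @return List with `variants` (pooled-variant tibble in the layout of
#'   [read_pooled_vcf()]) and `truth` (per-site true pool frequencies
#'   `q_high`, `q_low` and causal flags).
#' @export
sim_pooled_reads <- function(cohort, pools, vcf_path = NULL) {
  cfg <- cohort$config
  idx_h <- match(pools$high, cohort$accessions$accession_id)
  idx_l <- match(pools$low, cohort$accessions$accession_id)
  if (length(intersect(idx_h, idx_l)) > 0L) abort("pools are not disjoint")
  q_h <- colMeans(cohort$genotypes[idx_h, , drop = FALSE]) / 2
  q_l <- colMeans(cohort$genotypes[idx_l, , drop = FALSE]) / 2
  m <- nrow(cohort$sites)
  d_h <- rpois(m, cfg$mean_depth)
  d_l <- rpois(m, cfg$mean_depth)
  e <- cfg$seq_error
  a_h <- rbinom(m, d_h, q_h * (1 - e) + (1 - q_h) * e)
  a_l <- rbinom(m, d_l, q_l * (1 - e) + (1 - q_l) * e)

  variants <- cohort$sites |>
    select("chrom", "pos", "ref", "alt", "vclass") |>
    mutate(multiallelic = FALSE,
           ad_high_ref = d_h - a_h, ad_high_alt = a_h,
           ad_low_ref = d_l - a_l, ad_low_alt = a_l)
  truth <- cohort$sites |>
    select("chrom", "pos", "vclass", "causal", "effect") |>
    mutate(q_high = q_h, q_low = q_l, delta_true = q_h - q_l)
  if (!is.null(vcf_path)) write_pooled_vcf(variants, vcf_path)
  list(variants = variants, truth = truth)
}

#' Write a two-sample pooled VCF
#'
#' Minimal VCF 4.2 emitter with per-sample allele depths (`AD`), readable
#' back by [read_pooled_vcf()].
#'
#' @param variants Pooled-variant tibble.
#' @param path Output path.
#' @param high_sample,low_sample Sample names.
#' @return `path`, invisibly.
#' @export
write_pooled_vcf <- function(variants, path,
                             high_sample = "VE-High", low_sample = "VE-Low") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsascan synthetic pooled-read generator",
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", high_sample, low_sample, sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  variants$ad_high_ref, variants$ad_high_alt,
                  variants$ad_low_ref, variants$ad_low_alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# gene-model construction helpers -------------------------------------------

toy_gene <- function(gene_id, chrom, start, strand = "+") {
  # 6 kb gene: CDS 1..1800, intron 1801..2400, CDS 2401..6000 (total 5400, %3 == 0)
  cds_start <- as.integer(c(start, start + 2400L))
  cds_end <- as.integer(c(start + 1799L, start + 5999L))
  tibble(gene_id = gene_id, chrom = chrom, strand = strand,
         tx_start = as.integer(start), tx_end = as.integer(start + 5999L),
         phase = 0L,
         cds = list(tibble(start = cds_start, end = cds_end)))
}

#' Emit the toy genome, gene models and GO annotation
#'
#' Builds random-base chromosomes matching the configured genome shape and
#' places gene models on them: six genes inside a designated 100 kb
#' candidate region centred on the first causal site — one of which carries
#' the causal SNV inside its CDS at a codon chosen so the substitution is
#' non-synonymous — plus two background genes per remaining chromosome. The
#' GO table assigns a target term to the candidate-region genes so that the
#' causal neighbourhood is enriched for it against the background.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named `DNAStringSet`), `genes` (gene-model
#'   tibble as from [read_gene_models()]), `go` (annotation tibble),
#'   `region` (the designated candidate interval) and `causal_gene`.
#' @export
emit_toy_genome <- function(config = sim_config()) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  lens <- sim_chrom_lengths(config)
  genome <- Biostrings::DNAStringSet(vapply(lens, random_dna, character(1)))
  names(genome) <- names(lens)

  cs <- config$causal_sites[1, ]
  cpos <- as.integer(cs$pos)
  region <- tibble(chrom = cs$chrom,
                   start = cpos - 50000L + 1L, end = cpos + 50000L)

  # causal gene: + strand, causal position at codon position 2 of its CDS
  causal_gene <- toy_gene("GeneC01", cs$chrom, cpos - 1000L)
  offs <- c(-45000L, -30000L, -15000L, 15000L, 30000L)
  region_genes <- bind_rows(
    causal_gene,
    bind_rows(lapply(seq_along(offs), function(i)
      toy_gene(sprintf("GeneC%02d", i + 1L), cs$chrom, cpos + offs[i],
               strand = if (i %% 2 == 0) "-" else "+"))))

  bg <- list()
  for (ch in setdiff(names(lens), cs$chrom)) {
    bg[[ch]] <- bind_rows(
      toy_gene(sprintf("GeneB_%s_1", ch), ch, 100000L),
      toy_gene(sprintf("GeneB_%s_2", ch), ch, 200000L, strand = "-"))
  }
  genes <- arrange(bind_rows(region_genes, bind_rows(bg)),
                   .data$chrom, .data$tx_start)

  # force the causal codon to GCT so that C>A at its middle base gives
  # GCT (Ala) -> GAT (Asp): non-synonymous
  seqs <- as.character(genome)
  s <- seqs[[cs$chrom]]
  substr(s, cpos - 1L, cpos + 1L) <- "GCT"
  seqs[[cs$chrom]] <- s
  genome <- Biostrings::DNAStringSet(seqs)

  target_genes <- c("GeneC01", "GeneC02", "GeneC03", "GeneC04")
  bg_ids <- unlist(lapply(bg, function(x) x$gene_id), use.names = FALSE)
  go <- bind_rows(
    tibble(gene_id = target_genes, go_id = "GO:TOY0001",
           ontology = "BP", term = "response to lipid-like stimulus"),
    tibble(gene_id = c("GeneC02", "GeneC03", "GeneC04"), go_id = "GO:TOY0002",
           ontology = "BP", term = "response to abscisic acid-like stimulus"),
    tibble(gene_id = bg_ids, go_id = sprintf("GO:TOY%04d", 100 + seq_along(bg_ids) %% 8),
           ontology = "BP", term = sprintf("background process %d", seq_along(bg_ids) %% 8)),
    tibble(gene_id = c(genes$gene_id),
           go_id = "GO:TOY0099", ontology = "BP", term = "cellular process"))

  list(genome = genome, genes = genes, go = go, region = region,
       causal_gene = "GeneC01",
       causal_variant = tibble(chrom = cs$chrom, pos = cpos, ref = "C", alt = "A"))
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
      sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
              g$chrom, g$tx_start, g$tx_end, g$strand, g$gene_id),
      sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s",
              g$chrom, g$tx_start, g$tx_end, g$strand, g$gene_id, g$gene_id))
    cds <- g$cds[[1]]
    # phase in transcription order
    ph <- integer(nrow(cds))
    lens <- cds$end - cds$start + 1L
    ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    acc <- g$phase
    for (k in ord) { ph[k] <- acc %% 3L; acc <- (3L - ((lens[k] - acc) %% 3L)) %% 3L }
    for (k in seq_len(nrow(cds))) {
      lines <- c(lines,
        sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t%d\tID=CDS:%s.%d;Parent=%s",
                g$chrom, cds$start[k], cds$end[k], g$strand, ph[k],
                g$gene_id, k, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Long phenotype/genotype table of a cohort at one site
#'
#' Builds the accession x environment phenotype table with the allele call
#' at a query site (`REF` for dosage 0, `HET` for 1, `ALT` for 2), the
#' input expected by [haplotype_compare()].
#'
#' @param cohort A [sim_cohort()] result.
#' @param chrom,pos Site coordinates.
#' @return Long tibble with `accession_id`, `accession_type`, `environment`,
#'   `phenotype`, `allele`.
#' @export
cohort_phenotype_table <- function(cohort, chrom, pos) {
  j <- which(cohort$sites$chrom == chrom & cohort$sites$pos == pos)
  if (length(j) != 1L) abort(sprintf("site %s:%d not found in cohort", chrom, pos))
  dos <- cohort$genotypes[, j]
  allele <- c("REF", "HET", "ALT")[dos + 1L]
  ph <- as_tibble(cohort$phenotypes)
  ph$accession_id <- cohort$accessions$accession_id
  ph$accession_type <- cohort$accessions$type
  ph$allele <- allele
  tidyr::pivot_longer(ph, cols = all_of(colnames(cohort$phenotypes)),
                      names_to = "environment", values_to = "phenotype")
}
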
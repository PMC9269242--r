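
RANK_LEVELS <- c("frameshift/stop", "non-synonymous", "other-genic",
                 "regulatory", "none")

rank_class_of <- function(category, subtype) {
  if (is.na(category)) return("none")
  if (category == "exonic") {
    if (subtype %in% c("frameshift-insertion", "frameshift-deletion",
                       "stop-gain", "stop-loss")) return("frameshift/stop")
    if (subtype == "non-synonymous") return("non-synonymous")
    return("other-genic")
  }
  if (category %in% c("splicing", "intronic")) return("other-genic")
  if (category %in% c("upstream", "downstream", "upstream/downstream")) {
    return("regulatory")
  }
  "none"
}

#' Prioritise genes inside candidate regions by effect severity
#'
#' Genes carrying exonic non-synonymous, stop-gain/stop-loss or frameshift
#' variants are preferred as candidates; the ordering is frameshift/stop >
#' non-synonymous > other genic (synonymous, intronic, splicing,
#' non-frameshift) > regulatory (up/downstream), ties broken by position.
#' The top gene of each region is its headline candidate.
#'
#' @param regions Region tibble from [call_regions()] (needs the `genes`
#'   list-column).
#' @param effects Classified variants from [classify_variants()].
#' @return Tibble with one row per (region, gene): `chrom`, `region_start`,
#'   `region_end`, `gene_id`, `rank_class`, `best_effect`, `n_variants`,
#'   `first_pos`, ordered by severity within region.
#' @export
prioritize_genes <- function(regions, effects) {
  if (nrow(regions) == 0L) {
    return(tibble(chrom = character(), region_start = integer(),
                  region_end = integer(), gene_id = character(),
                  rank_class = character(), best_effect = character(),
                  n_variants = integer(), first_pos = integer()))
  }
  eff_genes <- strsplit(ifelse(is.na(effects$gene_id), "", effects$gene_id), ",")
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    for (g in regions$genes[[r]]) {
      hit <- which(map_lgl(eff_genes, function(x) g %in% x))
      hit <- hit[effects$chrom[hit] == regions$chrom[r]]
      if (length(hit) == 0L) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = regions$chrom[r], region_start = regions$start[r],
          region_end = regions$end[r], gene_id = g, rank_class = "none",
          best_effect = NA_character_, n_variants = 0L,
          first_pos = NA_integer_)
        next
      }
      rc <- vapply(hit, function(i)
        rank_class_of(effects$category[i], effects$exonic_subtype[i]),
        character(1))
      best <- hit[which.min(match(rc, RANK_LEVELS))]
      lab <- if (effects$category[best] == "exonic")
        effects$exonic_subtype[best] else effects$category[best]
      rows[[length(rows) + 1L]] <- tibble(
        chrom = regions$chrom[r], region_start = regions$start[r],
        region_end = regions$end[r], gene_id = g,
        rank_class = RANK_LEVELS[min(match(rc, RANK_LEVELS))],
        best_effect = lab, n_variants = length(hit),
        first_pos = min(effects$pos[hit]))
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out |>
    mutate(.rank = match(.data$rank_class, RANK_LEVELS)) |>
    arrange(.data$chrom, .data$region_start, .data$.rank,
            .data$first_pos, .data$gene_id) |>
    select(-".rank")
}

#' Haplotype-phenotype comparison at a candidate site
#'
#' Splits accessions into reference- and alternate-allele carriers at a
#' candidate variant and compares the phenotype between the two groups in
#' every environment with Welch's unequal-variance two-sample test.
#' Heterozygous accessions are excluded by default. The REF-allele fraction
#' per accession type (cultivar/landrace) is also reported.
#'
#' @param phenotypes Long tibble (see [read_phenotype_table()]) with columns
#'   `accession_id`, `accession_type`, `environment`, `phenotype`, `allele`.
#' @param include_het Score heterozygous accessions as a third group to be
#'   kept out (`FALSE`, default) or pooled with ALT carriers (`TRUE`).
#' @return An object of class `"bsa_haplotype"` with components `tests`
#'   (per-environment tibble: group sizes, means, Welch statistic and
#'   p-value; untested environments flagged), `ref_fraction` (per accession
#'   type) and `data`. Supports [tidy()], [glance()], [autoplot()].
#' @export
haplotype_compare <- function(phenotypes, include_het = FALSE) {
  assert_cols(phenotypes, c("accession_id", "accession_type", "environment",
                            "phenotype", "allele"), "phenotypes")
  x <- phenotypes
  x$allele <- toupper(as.character(x$allele))
  if (include_het) x$allele[x$allele == "HET"] <- "ALT"
  x <- x[x$allele %in% c("REF", "ALT"), , drop = FALSE]
  if (nrow(x) == 0L) {
    return(structure(list(tests = tibble(), ref_fraction = tibble(),
                          data = x), class = "bsa_haplotype"))
  }

  tests <- x |>
    group_by(.data$environment) |>
    summarise(
      n_ref = sum(.data$allele == "REF"),
      n_alt = sum(.data$allele == "ALT"),
      mean_ref = mean(.data$phenotype[.data$allele == "REF"]),
      mean_alt = mean(.data$phenotype[.data$allele == "ALT"]),
      .groups = "drop"
    )
  wt <- purrr::map(tests$environment, function(e) {
    sub <- x[x$environment == e, ]
    ok <- sum(sub$allele == "REF") >= 2 && sum(sub$allele == "ALT") >= 2 &&
      (stats::sd(sub$phenotype[sub$allele == "REF"]) > 0 ||
         stats::sd(sub$phenotype[sub$allele == "ALT"]) > 0)
    if (!ok) return(list(statistic = NA_real_, p_value = NA_real_, tested = FALSE))
    tt <- t.test(phenotype ~ allele, data = sub)  # Welch by default
    # t.test orders groups ALT, REF alphabetically; sign as high-vs-low REF
    list(statistic = unname(tt$statistic), p_value = tt$p.value, tested = TRUE)
  })
  tests$statistic <- map_dbl(wt, "statistic")
  tests$p_value <- map_dbl(wt, "p_value")
  tests$tested <- map_lgl(wt, "tested")

  acc <- dplyr::distinct(x, .data$accession_id, .data$accession_type,
                         .data$allele)
  ref_fraction <- acc |>
    group_by(.data$accession_type) |>
    summarise(n = dplyr::n(),
              ref_fraction = mean(.data$allele == "REF"), .groups = "drop")

  structure(list(tests = tests, ref_fraction = ref_fraction, data = x),
            class = "bsa_haplotype")
}

#' Permutation cross-check of the haplotype comparison
#'
#' Two-sided permutation test of the difference in group means, used as an
#' independent check on the Welch test for small groups.
#'
#' @param phenotype Numeric phenotype vector.
#' @param allele Character vector of `"REF"`/`"ALT"` calls.
#' @param n_perm Number of permutations (default 10000).
#' @return Permutation p-value.
#' @export
permutation_test <- function(phenotype, allele, n_perm = 10000) {
  is_ref <- allele == "REF"
  obs <- mean(phenotype[is_ref]) - mean(phenotype[!is_ref])
  perm <- replicate(n_perm, {
    s <- sample(is_ref)
    mean(phenotype[s]) - mean(phenotype[!s])
  })
  (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
}

#' @export
print.bsa_haplotype <- function(x, ...) {
  cat("<bsa_haplotype>\n")
  print(x$tests)
  print(x$ref_fraction)
  invisible(x)
}
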
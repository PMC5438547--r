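#' Read and write FASTA sequence files
#'
#' Thin tidy wrappers around Biostrings.
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble with columns `name`, `seq`.
#' @export
read_fasta <- function(path) {
  rlang::check_installed("Biostrings")
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), seq = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param sequences Tibble with columns `name`, `seq`.
#' @export
write_fasta <- function(sequences, path) {
  rlang::check_installed("Biostrings")
  x <- Biostrings::DNAStringSet(setNames(sequences$seq, sequences$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write BED interval files
#'
#' Minimal BED3+name support; intervals are 0-based half-open.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `start`, `end` and, if present,
#'   `name`.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(
    path, col_names = FALSE, show_col_types = FALSE, comment = "#"
  )
  names(tbl)[1:3] <- c("chrom", "start", "end")
  if (ncol(tbl) >= 4) names(tbl)[4] <- "name"
  if (any(tbl$end <= tbl$start)) {
    abort("BED intervals must satisfy end > start",
          class = "tstv_error_table_format")
  }
  select(tbl, dplyr::any_of(c("chrom", "start", "end", "name")))
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end`, optionally `name`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' Read biallelic SNVs from a VCF file
#'
#' Uses vcfR to parse the file and keeps only biallelic single-nucleotide
#' records over A/C/G/T.
#'
#' @param path VCF file path.
#' @return Tibble with `chrom`, `pos` (1-based), `id`, `ref`, `alt`,
#'   `klass`.
#' @export
read_snv_vcf <- function(path) {
  rlang::check_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tbl <- tibble(
    chrom = fx$CHROM, pos = as.integer(fx$POS),
    id = fx$ID, ref = toupper(fx$REF), alt = toupper(fx$ALT)
  )
  tbl <- filter(tbl, .data$ref %in% DNA_BASES & .data$alt %in% DNA_BASES)
  mutate(tbl, klass = classify_substitution(.data$ref, .data$alt))
}

#' Write biallelic SNVs as a minimal VCFv4.2 file
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and optional
#'   `id`.
#' @param path Output path.
#' @export
write_snv_vcf <- function(variants, path) {
  id <- if ("id" %in% names(variants)) variants$id else "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tstvreg",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$chrom, as.integer(variants$pos), id,
                  toupper(variants$ref), toupper(variants$alt))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a haplotype effects table
#'
#' TSV with one row per assayed haplotype: `haplotype_id`, `amplicon_id`,
#' `effect_size` (positive activity ratio), `effect_p`.
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_haplotype_effects <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("haplotype_id", "amplicon_id", "effect_size", "effect_p")
  if (!all(need %in% names(tbl))) {
    abort(paste0("haplotype effects table needs columns: ",
                 paste(need, collapse = ", ")),
          class = "tstv_error_table_format")
  }
  if (any(tbl$effect_size <= 0)) {
    abort("effect sizes must be positive", class = "tstv_error_data")
  }
  as_tibble(tbl)
}
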
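# metadata header lines stamped into every pipeline artifact
pipeline_meta <- function(subcommand, config) {
  ver <- as.character(utils::packageVersion("tstvreg"))
  c(
    paste0("# tstvreg ", ver),
    paste0("# subcommand: ", subcommand),
    paste0("# seed: ", config$seed %||% NA),
    paste0("# config_digest: ", rlang::hash(config))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_meta <- function(tbl, path, meta) {
  writeLines(meta, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_json_meta <- function(x, path, meta, subcommand, config) {
  out <- list(
    meta = list(
      package = "tstvreg",
      version = as.character(utils::packageVersion("tstvreg")),
      subcommand = subcommand,
      seed = config$seed %||% NA,
      config_digest = rlang::hash(config)
    ),
    result = x
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

check_input_files <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")),
          class = "tstv_error_usage")
  }
  invisible(paths)
}

#' Run one arm of the Ts/Tv analysis pipeline
#'
#' Orchestrates the package's analyses as named subcommands producing
#' deterministic artifact files. Every TSV artifact carries a commented
#' metadata header (package version, seed, config digest) and every
#' statistical result is additionally written as JSON.
#'
#' Subcommands and their `config` entries:
#' * `"simulate"`: `seed`, `scenario` plus any [sim_config()] scale
#'   parameter; writes a full synthetic dataset (shape table, motif
#'   library, ASB table, haplotype files, saturation table).
#' * `"shape-sim"`: `n_sequences`, `length`, `seed`, `shape_table`
#'   (path); writes shape-effect records and the class comparison.
#' * `"motif-scan"`: `motifs` (JASPAR path), `pseudocount`; writes
#'   mutation scores and the position/IC stratified tests.
#' * `"asb-test"`: `asb_table` (TSV path), `pooling`; writes the
#'   enrichment result.
#' * `"haplo-reg"`: `effects`, `dhs` (paths), `alleles` (TSV path with
#'   haplotype_id/pos/base) or `sequences` (FASTA) + `amplicons` (BED),
#'   `seed`, `alpha`; writes contrasts and the three regression models.
#' * `"satmut-reg"`: `satmut` (TSV path); writes pooled and per-element
#'   fits.
#'
#' @param subcommand One of `"simulate"`, `"shape-sim"`, `"motif-scan"`,
#'   `"asb-test"`, `"haplo-reg"`, `"satmut-reg"`.
#' @param config Named list of parameters for the subcommand.
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of artifact paths.
#' @export
run_pipeline <- function(subcommand, config = list(), out_dir) {
  subcommands <- c("simulate", "shape-sim", "motif-scan", "asb-test",
                   "haplo-reg", "satmut-reg")
  if (length(subcommand) != 1 || !subcommand %in% subcommands) {
    abort(paste0("unknown subcommand; expected one of: ",
                 paste(subcommands, collapse = ", ")),
          class = "tstv_error_usage")
  }
  meta <- pipeline_meta(subcommand, config)
  runner <- switch(subcommand,
    "simulate" = pipeline_simulate,
    "shape-sim" = pipeline_shape,
    "motif-scan" = pipeline_motif,
    "asb-test" = pipeline_asb,
    "haplo-reg" = pipeline_haplo,
    "satmut-reg" = pipeline_satmut
  )
  # validate inputs and compute everything before any file is written,
  # so a failing run leaves no partial outputs
  artifacts <- runner(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(artifacts$tsv)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_meta(artifacts$tsv[[nm]], p, meta)
    paths <- c(paths, p)
  }
  for (nm in names(artifacts$json)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    write_json_meta(artifacts$json[[nm]], p, meta, subcommand, config)
    paths <- c(paths, p)
  }
  if (!is.null(artifacts$writer)) paths <- c(paths, artifacts$writer(out_dir))
  invisible(paths)
}

pipeline_simulate <- function(config) {
  seed <- config$seed %||% 1L
  cfg <- sim_config(
    seed = seed, scenario = config$scenario %||% "planted",
    n_amplicons = config$n_amplicons %||% 100L,
    haplotypes_per_amplicon = config$haplotypes_per_amplicon %||% 8L
  )
  hap <- gen_haplotype_dataset(cfg)
  shape_tbl <- gen_shape_table(seed)
  motifs <- gen_motif_library(config$n_motifs %||% 20L, seed = seed + 1L)
  asb <- gen_asb_dataset(
    n_tested = config$n_tested %||% 20000L,
    tested_tv_fraction = cfg$tested_tv_fraction,
    n_asb = config$n_asb %||% 2000L,
    asb_tv_fraction = cfg$asb_tv_fraction,
    seed = seed + 2L
  )
  satmut <- gen_satmut_dataset(
    n_elements = cfg$n_elements, element_length = cfg$element_length,
    tv_multiplier = cfg$tv_shape_multiplier, seed = seed + 3L
  )
  list(
    tsv = list(asb_calls = asb, satmut = satmut),
    json = list(),
    writer = function(out_dir) {
      p1 <- write_shape_table(shape_tbl, file.path(out_dir, "shape_table.tsv"))
      p2 <- write_jaspar(motifs, file.path(out_dir, "motifs.jaspar"))
      p3 <- write_haplotype_dataset(hap, out_dir)
      c(p1, p2, p3)
    }
  )
}

pipeline_shape <- function(config) {
  check_input_files(config$shape_table)
  tbl <- read_shape_table(config$shape_table)
  effects <- run_shape_experiment(
    n_sequences = config$n_sequences %||% 1000L,
    length = config$length %||% 503L,
    table = tbl, seed = config$seed %||% 1L
  )
  cmp <- compare_shape_effects(effects)
  list(
    tsv = list(shape_effects = effects),
    json = list(shape_comparison = list(
      summary = cmp$summary, coefficients = cmp$coefs
    ))
  )
}

pipeline_motif <- function(config) {
  check_input_files(config$motifs)
  pfm <- read_jaspar(config$motifs)
  pssm <- pfm_to_pssm(pfm, pseudocount = config$pseudocount %||% 0.1)
  records <- enumerate_mutation_scores(pssm)
  pos_test <- stratified_ts_tv_test(records, "norm_position",
                                    n_bins = config$position_bins %||% 11L)
  ic_test <- stratified_ts_tv_test(records, "ic",
                                   n_bins = config$ic_bins %||% 20L)
  list(
    tsv = list(mutation_scores = records, position_test = pos_test,
               ic_test = ic_test),
    json = list()
  )
}

pipeline_asb <- function(config) {
  check_input_files(config$asb_table)
  dataset <- read_asb_table(config$asb_table)
  res <- asb_enrichment(dataset,
                        pooling = config$pooling %||% "across_groups_mean_n")
  list(tsv = list(), json = list(asb_result = as.list(res)))
}

pipeline_haplo <- function(config) {
  check_input_files(c(config$effects, config$dhs, config$amplicons))
  haplotypes <- read_haplotype_effects(config$effects)
  amplicons <- read_bed(config$amplicons)
  amplicons <- rename(amplicons, amplicon_id = "name")
  dhs <- read_bed(config$dhs)
  dhs <- rename(dhs, amplicon_id = "name")
  alleles <- if (!is.null(config$alleles)) {
    check_input_files(config$alleles)
    readr::read_tsv(config$alleles, show_col_types = FALSE, comment = "#")
  } else if (!is.null(config$sequences)) {
    check_input_files(config$sequences)
    fa <- read_fasta(config$sequences)
    seqs <- fa |>
      rename(haplotype_id = "name") |>
      inner_join(select(haplotypes, "haplotype_id", "amplicon_id"),
                 by = "haplotype_id")
    alleles_from_sequences(seqs, amplicons)
  } else {
    abort("haplo-reg needs `alleles` or `sequences` in the config",
          class = "tstv_error_usage")
  }
  refs <- choose_reference(haplotypes, seed = config$seed %||% 1L)
  contrasts <- build_contrasts(haplotypes, alleles, refs, dhs = dhs)
  contrasts <- filter_groups(contrasts, haplotypes,
                             alpha = config$alpha %||% 0.05)
  fits <- lapply(
    setNames(c("presence", "count", "count_mid"),
             c("presence", "count", "count_mid")),
    function(m) {
      f <- fit_model(contrasts, model = m)
      list(model = f$model_label, n = f$n_obs, coefficients = f$coefs)
    }
  )
  list(tsv = list(contrasts = contrasts), json = list(haplo_fits = fits))
}

pipeline_satmut <- function(config) {
  check_input_files(config$satmut)
  records <- summarize_effects(read_satmut(config$satmut))
  pooled <- satmut_ts_tv_test(records, "pooled")
  per_elem <- satmut_ts_tv_test(records, "per_element")
  list(
    tsv = list(satmut_effects = records),
    json = list(satmut_fits = list(
      pooled = list(model = pooled$model_label, coefficients = pooled$coefs),
      per_element = lapply(per_elem, function(f) {
        list(model = f$model_label, coefficients = f$coefs)
      })
    ))
  )
}
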
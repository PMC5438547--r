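#' Read and write motif libraries in JASPAR flat-file format
#'
#' The JASPAR format stores one position frequency matrix (PFM) per
#' record: a `>ID NAME` header line followed by four rows of bracketed
#' counts, one per base:
#' ```
#' >MA0001.1 EXAMPLE
#' A [ 4 19  0 ]
#' C [16  0  0 ]
#' G [ 0  1 20 ]
#' T [ 0  0  0 ]
#' ```
#' Counts are returned in long (tidy) form.
#'
#' @param path Path to a JASPAR-format text file.
#' @return A tibble with columns `motif_id`, `name`, `position` (1-based),
#'   `base`, `count`; one row per motif x position x base.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) {
    return(tibble(motif_id = character(), name = character(),
                  position = integer(), base = character(),
                  count = numeric()))
  }
  starts <- grep("^>", lines)
  if (length(starts) == 0 || starts[1] != 1) {
    abort("not a JASPAR file: expected a '>' header first",
          class = "tstv_error_parse")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- purrr::map2(starts, ends, function(s, e) {
    header <- sub("^>\\s*", "", lines[s])
    parts <- strsplit(trimws(header), "\\s+")[[1]]
    motif_id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else NA_character_
    body <- lines[(s + 1):e]
    if (length(body) != 4) {
      abort(paste0("motif ", motif_id, ": expected 4 count rows, got ",
                   length(body)), class = "tstv_error_parse")
    }
    rows <- lapply(body, function(ln) {
      m <- regmatches(ln, regexec("^\\s*([ACGTacgt])\\s*\\[([^]]*)\\]", ln))[[1]]
      if (length(m) != 3) {
        abort(paste0("motif ", motif_id, ": malformed count row: ", ln),
              class = "tstv_error_parse")
      }
      counts <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (any(is.na(counts)) || any(counts < 0)) {
        abort(paste0("motif ", motif_id, ": non-numeric or negative counts"),
              class = "tstv_error_parse")
      }
      list(base = toupper(m[2]), counts = counts)
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, DNA_BASES)) {
      abort(paste0("motif ", motif_id, ": need one row each for A/C/G/T"),
            class = "tstv_error_parse")
    }
    lens <- vapply(rows, function(r) length(r$counts), integer(1))
    if (length(unique(lens)) != 1) {
      abort(paste0("motif ", motif_id, ": unequal row lengths"),
            class = "tstv_error_parse")
    }
    ord <- match(DNA_BASES, bases)
    counts <- do.call(rbind, lapply(rows[ord], `[[`, "counts")) # 4 x L
    tibble(
      motif_id = motif_id, name = name,
      position = rep(seq_len(lens[1]), each = 4),
      base = rep(DNA_BASES, times = lens[1]),
      count = as.vector(counts)
    )
  })
  bind_rows(recs)
}

#' @rdname read_jaspar
#' @param pfm A tidy PFM tibble (columns `motif_id`, `position`, `base`,
#'   `count`, optionally `name`).
#' @export
write_jaspar <- function(pfm, path) {
  pfm <- validate_pfm(pfm)
  lines <- unlist(lapply(split(pfm, pfm$motif_id)[unique(pfm$motif_id)],
                         function(m) {
    nm <- if ("name" %in% names(m) && !is.na(m$name[1])) paste0(" ", m$name[1]) else ""
    wide <- tidyr::pivot_wider(m, id_cols = "position",
                               names_from = "base", values_from = "count")
    wide <- arrange(wide, .data$position)
    c(paste0(">", m$motif_id[1], nm),
      vapply(DNA_BASES, function(b) {
        paste0(b, " [ ", paste(format(wide[[b]], trim = TRUE), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

# check tidy PFM shape: each motif has all 4 bases at positions 1..L
validate_pfm <- function(pfm) {
  pfm <- as_tibble(pfm)
  need <- c("motif_id", "position", "base", "count")
  if (!all(need %in% names(pfm))) {
    abort(paste0("PFM needs columns: ", paste(need, collapse = ", ")),
          class = "tstv_error_parse")
  }
  chk <- pfm |>
    group_by(.data$motif_id) |>
    summarise(
      ok = all(sort(unique(.data$base)) == DNA_BASES) &&
        all(sort(unique(.data$position)) == seq_len(max(.data$position))) &&
        n() == 4 * max(.data$position),
      .groups = "drop"
    )
  if (!all(chk$ok)) {
    abort(paste0("malformed PFM for motif(s): ",
                 paste(chk$motif_id[!chk$ok], collapse = ", ")),
          class = "tstv_error_parse")
  }
  if (any(pfm$count < 0)) {
    abort("PFM counts must be nonnegative", class = "tstv_error_parse")
  }
  pfm
}

#' Convert position frequency matrices to log-odds scoring matrices
#'
#' For each motif column, a pseudocount is added to every count, counts
#' are normalised to frequencies, and log2 odds against the background
#' are taken:
#' `f(b,i) = (count + pc) / (total_i + 4 pc)`;
#' `score(b,i) = log2(f(b,i) / background(b))`.
#' Per-position information content is `ic(i) = 2 + sum_b f log2 f`
#' (bits, in `[0, 2]`; 0 for a uniform column, 2 for a fixed base). The
#' consensus base at each position is the score argmax (ties broken in
#' A < C < G < T order).
#'
#' @param pfm A tidy PFM tibble (see [read_jaspar()]).
#' @param pseudocount Nonnegative number added to every count (default 0.1).
#' @param background Length-4 positive base-frequency vector in A,C,G,T
#'   order, summing to 1; default uniform.
#' @return A tibble with columns `motif_id`, `position`, `base`, `freq`,
#'   `score` (bits), `ic` (bits, repeated across the 4 rows of a
#'   position), `consensus` (logical, TRUE on the consensus base row).
#' @export
pfm_to_pssm <- function(pfm, pseudocount = 0.1,
                        background = rep(0.25, 4)) {
  pfm <- validate_pfm(pfm)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    abort("`pseudocount` must be a single nonnegative number",
          class = "tstv_error_argument")
  }
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    abort("`background` must be 4 positive frequencies summing to 1",
          class = "tstv_error_argument")
  }
  bg <- setNames(background, DNA_BASES)
  pfm |>
    arrange(.data$motif_id, .data$position, .data$base) |>
    group_by(.data$motif_id, .data$position) |>
    mutate(
      freq = (.data$count + pseudocount) /
        (sum(.data$count) + 4 * pseudocount),
      score = log2(.data$freq / unname(bg[.data$base])),
      # 0 * log2(0) taken as 0 so pseudocount = 0 stays well-defined
      ic = 2 + sum(ifelse(.data$freq > 0, .data$freq * log2(.data$freq), 0)),
      # rows are in A<C<G<T order, so which.max breaks ties that way
      consensus = seq_len(n()) == which.max(.data$score)
    ) |>
    ungroup()
}

#' Consensus sequences of a PSSM table
#'
#' @param pssm A PSSM tibble from [pfm_to_pssm()].
#' @return Tibble with `motif_id`, `consensus` (DNA string), `length`.
#' @export
pssm_consensus <- function(pssm) {
  pssm |>
    filter(.data$consensus) |>
    arrange(.data$motif_id, .data$position) |>
    group_by(.data$motif_id) |>
    summarise(consensus = paste(.data$base, collapse = ""),
              length = n(), .groups = "drop")
}

#' Score a sequence against a motif
#'
#' The PSSM score of a sequence is the sum of the per-position log-odds
#' scores of its bases; it is additive, so a single-base change shifts the
#' total by exactly the column score difference.
#'
#' @param pssm A PSSM tibble restricted to (or containing) one motif.
#' @param seq DNA string whose length equals the motif length.
#' @param motif_id Which motif to score against; defaults to the single
#'   motif present.
#' @return Scalar score in bits.
#' @export
score_sequence <- function(pssm, seq, motif_id = NULL) {
  if (is.null(motif_id)) {
    ids <- unique(pssm$motif_id)
    if (length(ids) != 1) {
      abort("`pssm` holds several motifs; pass `motif_id`",
            class = "tstv_error_argument")
    }
    motif_id <- ids
  }
  m <- filter(pssm, .data$motif_id == !!motif_id)
  L <- max(m$position)
  seq <- check_sequences(seq)
  if (nchar(seq) != L) {
    abort(paste0("sequence length ", nchar(seq), " != motif length ", L),
          class = "tstv_error_argument")
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  key <- paste(m$position, m$base)
  sum(setNames(m$score, key)[paste(seq_len(L), bases)])
}

#' Enumerate all single-nucleotide mutation effects of a motif library
#'
#' For every motif position and every unordered base pair (6 per
#' position), records the absolute PSSM score change
#' `|score(b1, i) - score(b2, i)|` caused by swapping the two bases, the
#' substitution class, the position's information content, and its
#' normalised position: `2 * min(i, L-1-i) / (L-1)` with 0-based `i`, so 0
#' at either motif edge and 1 at the centre (defined as 1 for length-1
#' motifs).
#'
#' @param pssm A PSSM tibble from [pfm_to_pssm()] (any number of motifs).
#' @param fold_position Fold positions about the motif centre (default
#'   TRUE); if FALSE, `norm_position` is the unfolded `i / (L-1)`.
#' @return A tibble with `6 * L` rows per motif: `motif_id`, `position`
#'   (0-based), `norm_position`, `ic`, `b1`, `b2`, `klass`, `delta`.
#' @export
enumerate_mutation_scores <- function(pssm, fold_position = TRUE) {
  pair <- tibble(
    b1 = c("A", "A", "A", "C", "C", "G"),
    b2 = c("C", "G", "T", "G", "T", "T")
  )
  pair$klass <- classify_substitution(pair$b1, pair$b2)
  wide <- pssm |>
    select("motif_id", "position", "base", "score", "ic") |>
    tidyr::pivot_wider(names_from = "base", values_from = "score")
  wide <- wide |>
    group_by(.data$motif_id) |>
    mutate(motif_length = max(.data$position)) |>
    ungroup()
  out <- tidyr::crossing(wide, pair) |>
    mutate(
      i0 = .data$position - 1L, # 0-based
      L = .data$motif_length,
      norm_position = dplyr::case_when(
        .data$L == 1 ~ 1,
        fold_position ~ 2 * pmin(.data$i0, .data$L - 1 - .data$i0) / (.data$L - 1),
        TRUE ~ .data$i0 / (.data$L - 1)
      ),
      s1 = dplyr::case_when(.data$b1 == "A" ~ .data$A, .data$b1 == "C" ~ .data$C,
                            .data$b1 == "G" ~ .data$G, TRUE ~ .data$T),
      s2 = dplyr::case_when(.data$b2 == "A" ~ .data$A, .data$b2 == "C" ~ .data$C,
                            .data$b2 == "G" ~ .data$G, TRUE ~ .data$T),
      delta = abs(.data$s1 - .data$s2)
    ) |>
    select(motif_id = "motif_id", position = "i0", "norm_position",
           "ic", "b1", "b2", "klass", "delta") |>
    arrange(.data$motif_id, .data$position, .data$b1, .data$b2)
  out
}

#' Stratified Ts-vs-Tv tests on motif mutation scores
#'
#' Partitions mutation-score records into equal-width bins over the
#' stratifying covariate (`norm_position` on `[0, 1]` or `ic` on
#' `[0, 2]`) and, within each bin, runs a Welch two-sample t-test of
#' transversion |delta score| against transition |delta score|
#' (two-sided). Bins with fewer than 2 records in either class are
#' returned but flagged untestable. The Bonferroni-adjusted significance
#' threshold `alpha / n_bins` is attached as the `alpha_bonferroni`
#' attribute and column.
#'
#' @param records Tibble from [enumerate_mutation_scores()].
#' @param stratify_by `"norm_position"` or `"ic"`.
#' @param n_bins Number of equal-width bins (defaults: 11 for position,
#'   20 for information content).
#' @param alpha Nominal significance level (default 0.05).
#' @return A tibble with one row per bin: `bin`, `bin_lo`, `bin_hi`,
#'   `n_ts`, `n_tv`, `mean_ts`, `mean_tv`, `mean_diff` (TV - TS),
#'   `statistic`, `p.value`, `testable`, `alpha_bonferroni`.
#' @export
stratified_ts_tv_test <- function(records,
                                  stratify_by = c("norm_position", "ic"),
                                  n_bins = NULL, alpha = 0.05) {
  stratify_by <- match.arg(stratify_by)
  if (nrow(records) == 0) {
    abort("`records` is empty", class = "tstv_error_argument")
  }
  if (is.null(n_bins)) n_bins <- if (stratify_by == "norm_position") 11L else 20L
  if (n_bins < 1) abort("`n_bins` must be >= 1", class = "tstv_error_argument")
  hi <- if (stratify_by == "norm_position") 1 else 2
  breaks <- seq(0, hi, length.out = n_bins + 1)
  x <- records[[stratify_by]]
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  records$bin <- bin
  out <- lapply(seq_len(n_bins), function(b) {
    r <- records[records$bin == b, ]
    ts <- r$delta[r$klass == "TS"]
    tv <- r$delta[r$klass == "TV"]
    testable <- length(ts) >= 2 && length(tv) >= 2 &&
      (sd(ts) > 0 || sd(tv) > 0)
    if (testable) {
      tt <- t.test(tv, ts) # Welch two-sided
      stat <- unname(tt$statistic); pv <- tt$p.value
    } else {
      stat <- NA_real_; pv <- NA_real_
    }
    tibble(
      bin = b, bin_lo = breaks[b], bin_hi = breaks[b + 1],
      n_ts = length(ts), n_tv = length(tv),
      mean_ts = if (length(ts)) mean(ts) else NA_real_,
      mean_tv = if (length(tv)) mean(tv) else NA_real_,
      mean_diff = if (length(ts) && length(tv)) mean(tv) - mean(ts) else NA_real_,
      statistic = stat, p.value = pv, testable = testable
    )
  })
  out <- bind_rows(out)
  out$alpha_bonferroni <- alpha / n_bins
  attr(out, "alpha_bonferroni") <- alpha / n_bins
  out
}
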
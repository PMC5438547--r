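#' All 1024 DNA pentamers
#'
#' @return Character vector of the 4^5 = 1024 ACGT 5-mers, lexicographically
#'   ordered.
#' @export
all_pentamers <- function() {
  g <- tidyr::expand_grid(
    b1 = DNA_BASES, b2 = DNA_BASES, b3 = DNA_BASES,
    b4 = DNA_BASES, b5 = DNA_BASES
  )
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5)
}

SHAPE_PARAMS <- c("mgw", "prot", "roll", "helt")

#' Validate a pentamer shape table
#'
#' A shape table maps every ACGT pentamer to four DNA shape parameters:
#' minor groove width (`mgw`, Angstrom) and propeller twist (`prot`,
#' degrees) read out at the central base pair, and roll (`roll`) and
#' helical twist (`helt`, both degrees) read out at the base-pair steps.
#' The table must contain exactly one finite row for each of the 1024
#' pentamers.
#'
#' @param table Data frame with columns `pentamer`, `mgw`, `prot`, `roll`,
#'   `helt` (case-insensitive; `MGW`/`ProT`/`Roll`/`HelT` accepted).
#' @return The validated table as a tibble with lowercase column names.
#' @export
validate_shape_table <- function(table) {
  tbl <- as_tibble(table)
  names(tbl) <- tolower(names(tbl))
  need <- c("pentamer", SHAPE_PARAMS)
  if (!all(need %in% names(tbl))) {
    abort(
      paste0("shape table must have columns: ", paste(need, collapse = ", ")),
      class = "tstv_error_table_format"
    )
  }
  tbl <- select(tbl, dplyr::all_of(need))
  tbl$pentamer <- toupper(tbl$pentamer)
  if (anyDuplicated(tbl$pentamer)) {
    abort("shape table has duplicate pentamers", class = "tstv_error_table_format")
  }
  missing <- setdiff(all_pentamers(), tbl$pentamer)
  if (length(missing) > 0) {
    abort(
      paste0("incomplete table: ", length(missing), " pentamers missing (e.g. ",
             missing[1], ")"),
      class = "tstv_error_table_format"
    )
  }
  extra <- setdiff(tbl$pentamer, all_pentamers())
  if (length(extra) > 0) {
    abort("shape table has non-pentamer keys", class = "tstv_error_table_format")
  }
  vals <- as.matrix(tbl[SHAPE_PARAMS])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("shape table values must all be finite numbers",
          class = "tstv_error_table_format")
  }
  arrange(tbl, .data$pentamer)
}

#' Read / write a pentamer shape table (TSV)
#'
#' @param path Path to a TSV file with columns `pentamer`, `MGW`, `ProT`,
#'   `Roll`, `HelT`.
#' @return `read_shape_table()` returns a validated shape-table tibble.
#' @export
read_shape_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_shape_table(tbl)
}

#' @rdname read_shape_table
#' @param table A shape table (see [validate_shape_table()]).
#' @export
write_shape_table <- function(table, path) {
  tbl <- validate_shape_table(table)
  out <- tbl
  names(out) <- c("pentamer", "MGW", "ProT", "Roll", "HelT")
  readr::write_tsv(out, path)
  invisible(path)
}

# named-vector lookups for fast pentamer indexing
shape_lookup <- function(table) {
  tbl <- validate_shape_table(table)
  lapply(setNames(SHAPE_PARAMS, SHAPE_PARAMS),
         function(p) setNames(tbl[[p]], tbl$pentamer))
}

# Profile matrices for a vector of equal-length sequences.
# mgw/prot: n x L (NA at first/last 2 positions); roll/helt: n x (L-1),
# step j sits between bases j and j+1 and averages the step values of the
# pentamers centered at j and j+1 (NA where either window falls off).
shape_profile_matrix <- function(seqs, lookup) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  if (L < 5) {
    abort("sequences must be at least 5 bp for the pentamer model",
          class = "tstv_error_length")
  }
  n <- length(seqs)
  centers <- 3:(L - 2) # pentamer center positions, 1-based
  pent <- vapply(centers, function(i) substr(seqs, i - 2, i + 2),
                 character(n))
  pent <- matrix(pent, nrow = n) # n x length(centers)

  bp_mat <- function(param) {
    m <- matrix(NA_real_, n, L)
    m[, centers] <- lookup[[param]][pent]
    m
  }
  step_mat <- function(param) {
    v <- matrix(lookup[[param]][pent], nrow = n)
    m <- matrix(NA_real_, n, L - 1)
    if (L >= 6) {
      js <- 3:(L - 3) # defined steps
      # column k of v is the pentamer centered at position centers[k]
      m[, js] <- (v[, js - 2, drop = FALSE] + v[, js - 1, drop = FALSE]) / 2
    }
    m
  }
  list(mgw = bp_mat("mgw"), prot = bp_mat("prot"),
       roll = step_mat("roll"), helt = step_mat("helt"))
}

#' Predict the DNA shape profile of a sequence
#'
#' Slides the pentamer window across `seq` and looks up the four shape
#' parameters. Minor groove width and propeller twist are per base pair
#' (undefined at the first and last two positions, where no pentamer
#' fits); roll and helical twist are per base-pair step, taken as the mean
#' of the step values of the two pentamers flanking the step (undefined at
#' the first and last two steps).
#'
#' @param seq A single DNA string, length >= 5.
#' @param table A pentamer shape table.
#' @return A tibble with one row per base: `position` (1-based), `base`,
#'   `mgw`, `prot`, and `roll`/`helt` for the step between `position` and
#'   `position + 1` (`NA` on the last row and wherever the window does not
#'   fit).
#' @export
shape_profile <- function(seq, table) {
  stopifnot(length(seq) == 1)
  seq <- check_sequences(seq)
  if (nchar(seq) < 5) {
    abort("`seq` must be at least 5 bp", class = "tstv_error_length")
  }
  lookup <- shape_lookup(table)
  prof <- shape_profile_matrix(seq, lookup)
  L <- nchar(seq)
  tibble(
    position = seq_len(L),
    base = strsplit(seq, "", fixed = TRUE)[[1]],
    mgw = prof$mgw[1, ],
    prot = prof$prot[1, ],
    roll = c(prof$roll[1, ], NA_real_),
    helt = c(prof$helt[1, ], NA_real_)
  )
}

# summed |delta| per parameter between two profile-matrix rows
sum_abs_delta <- function(pa, pb) {
  vapply(SHAPE_PARAMS, function(p) {
    d <- abs(pa[[p]] - pb[[p]])
    sum(d, na.rm = TRUE)
  }, numeric(1))
}

#' Shape effect of a single-nucleotide substitution
#'
#' Given two equal-length sequences differing at exactly one position,
#' sums the absolute difference of each shape parameter over all defined
#' positions/steps. Because the pentamer model is local, differences
#' vanish outside the +/-2 bp window around the mutation; with
#' `method = "window"` only that neighbourhood is evaluated (identical
#' result, much faster for long sequences).
#'
#' @param seq_a,seq_b Equal-length DNA strings differing at one position.
#' @param table A pentamer shape table.
#' @param method `"full"` (whole-profile subtraction) or `"window"`.
#' @return One-row tibble: `klass` (`"TS"`/`"TV"`), `d_mgw`, `d_prot`,
#'   `d_roll`, `d_helt` (all >= 0).
#' @export
mutation_shape_effect <- function(seq_a, seq_b, table,
                                  method = c("full", "window")) {
  method <- match.arg(method)
  seq_a <- check_sequences(seq_a, "seq_a")
  seq_b <- check_sequences(seq_b, "seq_b")
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("sequences must have equal length", class = "tstv_error_pairing")
  }
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  diffs <- which(a != b)
  if (length(diffs) != 1) {
    abort(
      paste0("sequences must differ at exactly one position (found ",
             length(diffs), ")"),
      class = "tstv_error_pairing"
    )
  }
  c0 <- diffs
  klass <- classify_substitution(a[c0], b[c0])
  lookup <- shape_lookup(table)
  L <- nchar(seq_a)
  if (method == "window" && c0 >= 9 && c0 <= L - 8) {
    sa <- substr(seq_a, c0 - 8, c0 + 8)
    sb <- substr(seq_b, c0 - 8, c0 + 8)
    prof <- shape_profile_matrix(c(sa, sb), lookup)
  } else {
    prof <- shape_profile_matrix(c(seq_a, seq_b), lookup)
  }
  pa <- lapply(prof, function(m) m[1, ])
  pb <- lapply(prof, function(m) m[2, ])
  d <- sum_abs_delta(pa, pb)
  tibble(
    klass = klass,
    d_mgw = d[["mgw"]], d_prot = d[["prot"]],
    d_roll = d[["roll"]], d_helt = d[["helt"]]
  )
}

#' Random-sequence shape mutation experiment
#'
#' Draws `n_sequences` random sequences of odd `length`, substitutes the
#' middle base with all other bases to form a 4-variant quartet, and emits
#' one shape-effect record for every unordered pair of variants (6 pairs
#' per quartet: 2 transitions, 4 transversions). This is the experiment
#' behind the comparison of Ts and Tv effects on DNA shape.
#'
#' @param n_sequences Number of random starting sequences (quartets).
#' @param length Odd sequence length in bp; default 503 so the middle base
#'   is position 252.
#' @param table A pentamer shape table.
#' @param seed Integer seed for the random sequences.
#' @return A tibble of `6 * n_sequences` rows: `quartet_id`, `base_a`,
#'   `base_b` (the two middle-base alleles), `klass`, `d_mgw`, `d_prot`,
#'   `d_roll`, `d_helt`.
#' @export
run_shape_experiment <- function(n_sequences, length = 503, table, seed) {
  if (length %% 2 == 0) {
    abort("`length` must be odd so the middle base is unique",
          class = "tstv_error_argument")
  }
  if (n_sequences < 1) {
    abort("`n_sequences` must be >= 1", class = "tstv_error_argument")
  }
  lookup <- shape_lookup(table)
  seqs <- random_sequence(length, n = n_sequences, seed = seed)
  c0 <- (length + 1) / 2

  # by pentamer locality only the 17 bp window around the middle base
  # matters; fall back to full length for very short sequences
  if (c0 >= 9 && c0 <= length - 8) {
    win <- substr(seqs, c0 - 8, c0 + 8)
    mut_at <- 9L
  } else {
    win <- seqs
    mut_at <- c0
  }
  variants <- lapply(DNA_BASES, function(b) {
    v <- win
    substr(v, mut_at, mut_at) <- b
    v
  })
  # 4*n windows: rows 1..n are A-variants, n+1..2n C-variants, ...
  prof <- shape_profile_matrix(unlist(variants), lookup)
  n <- n_sequences
  pairs <- utils::combn(4, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ri <- (i - 1) * n + seq_len(n)
    rj <- (j - 1) * n + seq_len(n)
    d <- lapply(SHAPE_PARAMS, function(p) {
      rowSums(abs(prof[[p]][ri, , drop = FALSE] -
                  prof[[p]][rj, , drop = FALSE]), na.rm = TRUE)
    })
    names(d) <- SHAPE_PARAMS
    tibble(
      quartet_id = seq_len(n),
      base_a = DNA_BASES[i], base_b = DNA_BASES[j],
      klass = classify_substitution(DNA_BASES[i], DNA_BASES[j]),
      d_mgw = d$mgw, d_prot = d$prot, d_roll = d$roll, d_helt = d$helt
    )
  })
  arrange(bind_rows(out), .data$quartet_id, .data$base_a, .data$base_b)
}

#' Compare Ts and Tv shape effects
#'
#' For each shape parameter, reports the mean summed |delta| for
#' transitions and transversions, their Tv/Ts ratio, and a class-effect
#' estimate from a linear model with the identity of the starting sequence
#' (quartet) absorbed as a fixed effect. The fixed effect is absorbed by
#' within-quartet demeaning, which is algebraically identical to including
#' one dummy per quartet.
#'
#' @param effects A tibble of shape-effect records as returned by
#'   [run_shape_experiment()] (columns `quartet_id`, `klass`, `d_mgw`,
#'   `d_prot`, `d_roll`, `d_helt`).
#' @return A `tstv_fit` whose coefficient table has one row per shape
#'   parameter (term `tv_<param>`: the TV-minus-TS effect with quartet
#'   fixed effects), with the per-class means and Tv/Ts ratios in
#'   `$summary`.
#' @export
compare_shape_effects <- function(effects) {
  stopifnot(is.data.frame(effects))
  if (dplyr::n_distinct(effects$klass) < 2) {
    abort("effects contain a single substitution class; nothing to compare",
          class = "tstv_error_degenerate_design")
  }
  if (dplyr::n_distinct(effects$quartet_id) < 2) {
    abort("need at least 2 quartets", class = "tstv_error_degenerate_design")
  }
  is_tv <- as.numeric(effects$klass == "TV")
  summary_tbl <- bind_rows(lapply(SHAPE_PARAMS, function(p) {
    d <- effects[[paste0("d_", p)]]
    m_ts <- mean(d[is_tv == 0]); m_tv <- mean(d[is_tv == 1])
    tibble(
      parameter = p,
      mean_ts = m_ts, mean_tv = m_tv,
      median_ts = median(d[is_tv == 0]), median_tv = median(d[is_tv == 1]),
      ratio_tv_ts = m_tv / m_ts
    )
  }))
  coefs <- bind_rows(lapply(SHAPE_PARAMS, function(p) {
    fe_ols(effects[[paste0("d_", p)]], is_tv, effects$quartet_id,
           term = paste0("tv_", p))
  }))
  new_tstv_fit(
    coefs, model_label = "shape |delta| ~ class + quartet (absorbed)",
    n_obs = nrow(effects),
    extra = list(summary = summary_tbl)
  )
}
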
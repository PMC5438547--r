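#' DNA alphabet
#'
#' The four unambiguous DNA bases, in the conventional A < C < G < T order
#' used throughout the package for tie-breaking.
#'
#' @format Character vector of length 4.
#' @export
DNA_BASES <- c("A", "C", "G", "T")

PURINES     <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# normalise a vector of single bases; abort on anything outside ACGT
check_bases <- function(x, arg = "base") {
  x <- toupper(as.character(x))
  bad <- !(x %in% DNA_BASES)
  if (any(bad)) {
    abort(
      paste0(
        "`", arg, "` must be one of A/C/G/T; got: ",
        paste(unique(x[bad]), collapse = ", ")
      ),
      class = "tstv_error_alphabet"
    )
  }
  x
}

#' Classify single-nucleotide substitutions as transitions or transversions
#'
#' A transition (TS) exchanges a purine for the other purine (A<->G) or a
#' pyrimidine for the other pyrimidine (C<->T); every purine<->pyrimidine
#' exchange is a transversion (TV). Of the 12 ordered substitutions, 4 are
#' transitions and 8 are transversions, so uniform mutation yields a 1:2
#' Ts:Tv ratio.
#'
#' @param ref_base,alt_base Character vectors of single bases (A/C/G/T,
#'   case-insensitive), recycled to a common length. `ref_base` and
#'   `alt_base` must differ element-wise.
#' @return Character vector of `"TS"`/`"TV"`, same length as the inputs.
#' @examples
#' classify_substitution("A", "G") # "TS"
#' classify_substitution(c("A", "C"), c("T", "T")) # "TV" "TS"
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref <- check_bases(ref_base, "ref_base")
  alt <- check_bases(alt_base, "alt_base")
  if (length(ref) != length(alt)) {
    n <- max(length(ref), length(alt))
    ref <- rep_len(ref, n)
    alt <- rep_len(alt, n)
  }
  if (any(ref == alt)) {
    abort(
      "`ref_base` and `alt_base` must differ (not a substitution)",
      class = "tstv_error_substitution"
    )
  }
  if_else(
    (ref %in% PURINES) == (alt %in% PURINES),
    "TS", "TV"
  )
}

#' All twelve ordered single-nucleotide substitutions
#'
#' @return A tibble with columns `ref_base`, `alt_base`, `klass`.
#' @export
substitution_table <- function() {
  grid <- tidyr::expand_grid(ref_base = DNA_BASES, alt_base = DNA_BASES)
  grid <- filter(grid, .data$ref_base != .data$alt_base)
  mutate(grid, klass = classify_substitution(.data$ref_base, .data$alt_base))
}

#' Complement and reverse-complement DNA strings
#'
#' Standard Watson-Crick complement over A/C/G/T. `reverse_complement()` is
#' an involution: applying it twice returns the input.
#'
#' @param seq Character vector of DNA strings over A/C/G/T
#'   (case-insensitive; returned uppercase).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("ACGT") # "ACGT"
#' @export
reverse_complement <- function(seq) {
  vapply(complement(seq), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname reverse_complement
#' @export
complement <- function(seq) {
  seq <- toupper(as.character(seq))
  check_sequences(seq)
  chartr("ACGT", "TGCA", seq)
}

# validate DNA strings (vectorized); abort with alphabet error otherwise
check_sequences <- function(seq, arg = "seq") {
  bad <- grepl("[^ACGT]", toupper(seq))
  if (any(bad)) {
    abort(
      paste0("`", arg, "` contains non-ACGT characters"),
      class = "tstv_error_alphabet"
    )
  }
  invisible(toupper(seq))
}

#' Generate random DNA sequences
#'
#' Bases are drawn i.i.d. uniformly over A/C/G/T. With a fixed `seed` the
#' output is reproducible; the global RNG state is left untouched.
#'
#' @param length Sequence length in bp (positive integer).
#' @param n Number of sequences to draw (default 1).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Character vector of `n` DNA strings of the given length.
#' @export
random_sequence <- function(length, n = 1, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    abort("`length` must be a single integer >= 1", class = "tstv_error_argument")
  }
  draw <- function() {
    m <- matrix(sample(DNA_BASES, n * length, replace = TRUE), nrow = n)
    apply(m, 1, paste, collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
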
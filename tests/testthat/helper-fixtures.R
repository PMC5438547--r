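# shared fixture builders and independent oracles

# shape table mapping every pentamer to the same four values
constant_shape_table <- function(mgw = 5, prot = -7, roll = 1, helt = 34) {
  tibble::tibble(
    pentamer = all_pentamers(),
    mgw = mgw, prot = prot, roll = roll, helt = helt
  )
}

# independent naive shape-profile oracle: explicit window sliding with
# scalar lookups, no shared code with shape_profile()
naive_shape_profile <- function(seq, table) {
  L <- nchar(seq)
  tab <- table[order(table$pentamer), ]
  row_of <- function(p) which(tab$pentamer == p)
  mgw <- prot <- rep(NA_real_, L)
  roll_p <- helt_p <- rep(NA_real_, L) # per-pentamer step values at centers
  for (i in 3:(L - 2)) {
    r <- row_of(substr(seq, i - 2, i + 2))
    mgw[i] <- tab$mgw[r]
    prot[i] <- tab$prot[r]
    roll_p[i] <- tab$roll[r]
    helt_p[i] <- tab$helt[r]
  }
  roll <- helt <- rep(NA_real_, L - 1)
  for (j in 3:(L - 3)) {
    roll[j] <- (roll_p[j] + roll_p[j + 1]) / 2
    helt[j] <- (helt_p[j] + helt_p[j + 1]) / 2
  }
  list(mgw = mgw, prot = prot, roll = roll, helt = helt)
}

# tidy single-motif PFM from a 4 x L count matrix (rows A,C,G,T)
pfm_from_matrix <- function(mat, motif_id = "M1") {
  L <- ncol(mat)
  tibble::tibble(
    motif_id = motif_id,
    position = rep(seq_len(L), each = 4),
    base = rep(c("A", "C", "G", "T"), times = L),
    count = as.vector(mat)
  )
}

# small hand-built haplotype fixture: 2 amplicons, explicit alleles
hand_haplo_fixture <- function() {
  haplotypes <- tibble::tibble(
    haplotype_id = c("A1_H1", "A1_H2", "A1_H3", "A2_H1", "A2_H2"),
    amplicon_id = c("A1", "A1", "A1", "A2", "A2"),
    effect_size = c(1.0, 2.0, 1.5, 4.0, 1.0),
    effect_p = c(0.01, 0.2, 0.9, 0.5, 0.6)
  )
  # amplicon A1: 5 segregating sites at pos 101..105
  # H2 differs from H1 by 2 Ts (A>G at 101, C>T at 103) and 1 Tv (A>T at 105)
  # H3 differs from H1 by 1 Tv (G>C at 102)
  alleles <- tibble::tibble(
    haplotype_id = rep(c("A1_H1", "A1_H2", "A1_H3"), each = 5),
    pos = rep(101:105, times = 3),
    base = c(
      "A", "G", "C", "T", "A", # H1 (reference alleles)
      "G", "G", "T", "T", "T", # H2
      "A", "C", "C", "T", "A"  # H3
    )
  )
  alleles <- dplyr::bind_rows(alleles, tibble::tibble(
    haplotype_id = c("A2_H1", "A2_H2"),
    pos = c(501, 501),
    base = c("C", "A") # one Tv difference
  ))
  amplicons <- tibble::tibble(
    amplicon_id = c("A1", "A2"), chrom = "chr3",
    start = c(100, 480), end = c(160, 540)
  )
  dhs <- tibble::tibble(
    amplicon_id = c("A1", "A2"), chrom = "chr3",
    start = c(100, 480), end = c(160, 540)
  )
  refs <- tibble::tibble(
    amplicon_id = c("A1", "A2"),
    reference_id = c("A1_H1", "A2_H1")
  )
  list(haplotypes = haplotypes, alleles = alleles, amplicons = amplicons,
       dhs = dhs, refs = refs)
}

# generative references of a synthetic haplotype dataset
generative_refs <- function(dataset) {
  refs <- dataset$haplotypes[dataset$haplotypes$reference, ]
  tibble::tibble(amplicon_id = refs$amplicon_id,
                 reference_id = refs$haplotype_id)
}
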
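# Shared fixtures, built in code.

# The published classification table: row label and worked example tail.
# (First example per row; the A-rich row prints a second example, kept
# separately below.)
table1_examples <- function() {
  tibble::tribble(
    ~label, ~example,
    "(AAAAC)n", "AAAACAAAACAAAACAAAAGACCAAAAA",
    "(AAAAG)n", "AAAGAAAAAAGAAAAGGAAAAGAAAAGAA",
    "(AAAAT)n", "AAAATAAAATAAAATAAAAA",
    "(AAAC)n",  "AAAACAAACAAACAAAAAA",
    "(AAAG)n",  "AAAAAAAAAAAAAGAAAGAAAGAAAGAAA",
    "(AAAT)n",  "AAATAAATAAATAAATAAATAA",
    "(AAC)n",   "ACAACAACAACAACAACAACAACAACAAAA",
    "(AAG)n",   "AAAAAAGAAGAAGA",
    "(AAT)n",   "AGGCAAATAATAATAATAATAATAATAAAA",
    "(AC)n",    "AACACATACACACACACA",
    "(AG)n",    "AAAAAAAAAAGAGAGAGAGAGAAA",
    "(AT)n",    "AATATACATTATATATATAAAAGGAAAAAA",
    "A-rich",   "AAAAAAAAAAAAAAAAAAAAAA",
    "AC-composite", "GTCCTACAAAGCAAAAAACAAACAACAACA",
    "AG-composite", "AAAAGAGAAGAAG",
    "AT-composite", "AAAAATAAATAATAAATAAAA"
  )
}

arich_second_example <- "TAAAAAGCAAAAAAAAAAAAAAAAAAA"

other_examples <- c("CTCCGACTCAACCCCTAGCCTGGGAACTCC",
                    "TTGGGTGCAGTCCTAAAAA",
                    "TCTGGCTGTGGCTGTGGCTGGCAGCTGCAGTT")

# The 16-bp tail insertion polymorphism: reference-strand and gene-coding
# strand orientations as printed.
vwa8_insert_ref <- "CTTTCTTTATTTATTT"
vwa8_insert_gene <- "AAATAAATAAAGAAAG"

# Default plant spec covering all four structural classes.
default_plant_specs <- function(n_per = 5L, divergence = 0, tail_length = 24L) {
  tibble::tibble(
    subfamily = c("SINEA1", "SINEA2", "SINEB1", "SINEC1"),
    n = n_per,
    divergence = divergence,
    strand = c("+", "-", "+", "-"),
    category = c("A-rich", "(AAAT)n", "AC-composite", "(AG)n"),
    tail_length = tail_length,
    cutoff_intact = TRUE
  )
}

# A tiny RepeatMasker .out file written from literal text.
write_rm_fixture <- function(path) {
  writeLines(c(
    "   SW   perc perc perc  query    position in query    matching repeat",
    "score   div. del. ins.  sequence begin end (left) strand repeat class/family begin end (left) ID",
    "",
    "  225   12.5  0.0  0.0  chr1       101     300  (700)    +  SINEA1  SINE/tRNA  1  200  (0)  el1",
    "  310    3.0  0.1  0.2  chr2       501     800  (200)    C  SINEB1  SINE/tRNA  1  300  (0)  el2 *"
  ), path)
  path
}
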
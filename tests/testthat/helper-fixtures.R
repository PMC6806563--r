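# shared helpers: random targets/editors for property-style tests

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# a random valid editor geometry (both PAM sides, IUPAC-rich patterns)
random_editor <- function() {
  side <- sample(c("three_prime", "five_prime"), 1)
  L <- sample(18:23, 1)
  ws <- sample(1:(L - 4), 1)
  we <- min(L, ws + sample(0:6, 1))
  pam <- paste(sample(c("A", "C", "G", "T", "N", "R", "Y", "V", "W"),
                      sample(2:5, 1), TRUE), collapse = "")
  editor_spec(paste0("rnd_", side, "_", L), pam, side, L, ws, we)
}

# a random 61-mer with a C or G at the centre, as a flanked target
random_center_target <- function(len = 61L) {
  s <- random_seq(len)
  mid <- (len + 1L) %/% 2L
  base <- sample(c("C", "G"), 1)
  substr(s, mid, mid) <- base
  flanked_target(s, mid - 1L, if (base == "C") "+" else "-")
}

strip_diag <- function(df) {
  attr(df, "rejected_ambiguous") <- NULL
  df
}

toy_path <- function(...) system.file("extdata", "toy", ...,
                                      package = "bescan", mustWork = TRUE)
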
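# Shared helpers: random sequences and slow-but-obvious oracles kept
# independent of the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# closed-form Henderson-Hasselbalch charge of one group
hh_oracle <- function(pka, pH, acid) {
  if (acid) -1 / (1 + 10^(pka - pH)) else 1 / (1 + 10^(pH - pka))
}

# brute-force NCPR: loop residue by residue over the EMBOSS defaults
ncpr_oracle <- function(seqstr, pH) {
  pk <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1, H = 6.5, K = 10.8, R = 12.5)
  acid <- c(D = TRUE, E = TRUE, C = TRUE, Y = TRUE,
            H = FALSE, K = FALSE, R = FALSE)
  chars <- strsplit(seqstr, "")[[1]]
  total <- 0
  for (ch in chars) {
    if (ch %in% names(pk)) total <- total + hh_oracle(pk[[ch]], pH, acid[[ch]])
  }
  total / length(chars)
}

# direct (unwindowed) mean lipophilicity oracle over the bundled scale
mean_lipo_oracle <- function(seqstr, pH) {
  sc <- lipophilicity_scale()
  chars <- strsplit(seqstr, "")[[1]]
  mean(vapply(chars, residue_lipophilicity, numeric(1),
              pH = pH, scale = sc))
}

default_pka <- function(group) pka_set()$pka[[group]]
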
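# Amino-acid alphabet shared across the package.
#
# Fragments live over 22 symbols: the 20 standard residues, 'X' for an
# unknown residue, and '-' for terminal padding.  Composition features
# ignore 'X' and '-'; the positional matrix carries a column for '-'
# (the "terminal signal") but none for 'X'.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PAD_SYMBOL <- "-"

ALPHABET21 <- c(AA20, PAD_SYMBOL)

FRAGMENT_SYMBOLS <- c(ALPHABET21, "X")

SS_STATES <- c("H", "E", "C")

FEATURE_NAMES <- c("AA_PWM", "AAC", "ASA", "SS")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
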
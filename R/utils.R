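# Internal helpers: deterministic hashing, seed derivation, rounding, codon translation.

# Polynomial string hash modulo a Mersenne prime. All intermediates stay below
# 2^53 so double arithmetic is exact.
.HASH_MOD <- 2147483647
.HASH_BASE <- 131

.strHash <- function(s) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * .HASH_BASE + x) %% .HASH_MOD
  h
}

# Uniform deviate in [0, 1) derived from a string key. Two rounds decorrelate
# keys sharing long prefixes.
.hashUnif <- function(key) {
  h <- .strHash(key)
  h2 <- .strHash(paste0(h, "#", key))
  h2 / .HASH_MOD
}

# Derive a 32-bit-safe integer seed from a base seed and a context label, so
# that per-sample simulation is a pure function of (config seed, label).
.deriveSeed <- function(seed, label) {
  as.integer(.strHash(paste0(seed, "::", label)) %% 2147483647L)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Round half away from zero (Table-style percentage rounding).
roundHalfAway <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.stopCodons <- c("TAA", "TAG", "TGA")

# Translate a vector of codons with the standard genetic code; stop codons
# become "*". Codons shorter than 3 nt are dropped by the caller.
.translateCodons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return(character(0))
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# Validated TSV reading with NA as the only missing token.
.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = NA, comment.char = "", check.names = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
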
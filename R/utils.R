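# Internal helpers shared across modules.

TAX_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Characters allowed in stored sequences. "." marks columns outside a read's
# coverage in alignment space and never appears in file output.
SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "-")

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_dna <- function(x, allow = SEQ_ALPHABET) {
  !grepl(paste0("[^", paste(allow, collapse = ""), "]"), x)
}

.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Split codons starting at `frame` (0-based offset into the sequence);
# incomplete leading/trailing bases are dropped.
.codons <- function(seq, frame = 0L) {
  n <- nchar(seq)
  if (n - frame < 3L) return(character(0))
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

.has_stop <- function(seq, frame = 0L) {
  any(.codons(seq, frame) %in% STOP_CODONS)
}

# Deterministic sub-seed derivation; keeps values in 32-bit integer range.
.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

.msg_id <- function(x) paste0("'", x, "'")
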
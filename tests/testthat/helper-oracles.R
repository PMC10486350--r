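# Independent brute-force oracles. These deliberately share no code with
# the package internals: the scanner checks every start index directly, the
# digestion oracle enumerates all substrings and filters by boundary
# conditions, and the core matcher enumerates all motif substrings.

oracle_scan <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  if (m > n) return(integer(0))
  which(vapply(seq_len(n - m + 1L), function(i)
    substr(sequence, i, i + m - 1L) == motif, logical(1)))
}

# All cleavage positions (after residue i) under the rule.
oracle_sites <- function(sequence, residues, proline_rule) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  pos <- which(chars %in% residues)
  pos <- pos[pos < n]
  if (proline_rule) pos <- pos[chars[pos + 1L] != "P"]
  pos
}

# Enumerate all substrings of `sequence` and keep those that are valid
# peptides: start at 1 or just after a site, end at n or at a site, span at
# most `mc` internal sites, and have length >= min_len.
oracle_digest <- function(sequence, residues, proline_rule, mc, min_len) {
  n <- nchar(sequence)
  sites <- oracle_sites(sequence, residues, proline_rule)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < min_len) next
      left_ok <- (i == 1L) || ((i - 1L) %in% sites)
      right_ok <- (j == n) || (j %in% sites)
      if (!left_ok || !right_ok) next
      internal <- sum(sites >= i & sites < j)
      if (internal > mc) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, i, j), start = i, end = j,
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# Length of the longest contiguous substring of `motif` present in `pep`.
oracle_longest_core <- function(pep, motif) {
  best <- 0L
  m <- nchar(motif)
  for (len in seq_len(m)) {
    for (off in seq_len(m - len + 1L)) {
      if (grepl(substr(motif, off, off + len - 1L), pep, fixed = TRUE)) {
        best <- max(best, len)
        break
      }
    }
  }
  best
}

random_qp_string <- function(len) {
  paste(sample(c("Q", "P", "F", "L", "S", "Q", "P", "Q"), len,
               replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "K", "L", "M", "P", "Q",
                 "R", "S", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

quiet <- function(expr) withr::with_options(list(glutenscreen.verbose = FALSE),
                                            expr)
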
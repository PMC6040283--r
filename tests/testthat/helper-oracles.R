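# Independent oracles and fixture builders used across the suite.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random ORF of n_codons codons (start + body + stop), no internal stops.
random_orf <- function(n_codons) {
  codons <- expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T"))
  codons <- apply(codons, 1, paste, collapse = "")
  body <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(body, n_codons - 2L, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

# Exhaustive affine-gap global alignment score by recursive enumeration
# (gap of length L costs open + L * extend). Usable for lengths <= 6.
brute_align_score <- function(a, b, mat, open, extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= length(A)) {
      best <- max(best, -(extend + if (state == 1L) 0 else open) +
                    rec(i + 1L, j, 1L))
    }
    if (j <= length(B)) {
      best <- max(best, -(extend + if (state == 2L) 0 else open) +
                    rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Naive per-position six-frame ORF scan (ATG .. next in-frame stop).
orf_scan_oracle <- function(seq_str, min_len_nt) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_str else rc(seq_str)
    n <- nchar(s)
    for (st in seq_len(max(0L, n - 2L))) {
      if (substr(s, st, st + 2L) != "ATG") next
      j <- st + 3L
      while (j + 2L <= n) {
        if (substr(s, j, j + 2L) %in% stops) {
          len <- j + 2L - st + 1L
          if (len >= min_len_nt) {
            if (strand == "+") {
              fs <- st; fe <- j + 2L
            } else {
              fs <- n - (j + 2L) + 1L; fe <- n - st + 1L
            }
            out[[length(out) + 1L]] <- c(fs, fe, strand)
          }
          break
        }
        j <- j + 3L
      }
    }
  }
  if (!length(out)) return(character())
  sort(vapply(out, paste, "", collapse = ":"))
}

# Support value attached to the clade holding exactly `tips`, or NA.
support_of_clade <- function(tree, tips) {
  found <- NA_real_
  walk <- function(node) {
    if (!is.null(node$tip)) return()
    if (setequal(amyprofiler:::node_tips(node), tips)) {
      found <<- node$support
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  found
}

blosum62 <- function() amyprofiler:::get_submatrix("BLOSUM62")

# One fixed codon per residue, for building coding fixtures.
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              E = "GAA", Q = "CAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

encode_orf <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}
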
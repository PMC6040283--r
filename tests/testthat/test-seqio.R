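test_that("FASTA round trip preserves ids and residues exactly", {
  withr::with_seed(11, {
    recs <- lapply(1:5, function(i) {
      seq_record(paste0("rec", i), random_protein(sample(10:200, 1)),
                 "protein", description = paste("synthetic", i))
    })
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 60)
  back <- read_fasta(f, alphabet = "protein")
  expect_identical(unname(vapply(back, `[[`, "", "id")),
                   vapply(recs, `[[`, "", "id"))
  expect_identical(unname(vapply(back, `[[`, "", "residues")),
                   vapply(recs, `[[`, "", "residues"))
})

test_that("FASTA reading preserves order, strips whitespace, upper-cases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">b first", "acg t", "GTA", ">a second", "TTTT"), f)
  recs <- read_fasta(f)
  expect_identical(names(recs), c("b", "a"))
  expect_identical(recs[[1]]$residues, "ACGTGTA")
  expect_identical(recs[[1]]$description, "first")
})

test_that("malformed FASTA is rejected with the offending line", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">a", "ACGT", ">empty"), f)
  expect_error(read_fasta(f), "empty sequence.*line 3")
})

test_that("GenBank ORIGIN parsing strips digits and spaces", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       SYN001       12 bp    DNA     linear   01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "ORIGIN",
    "        1 acgtac gtacgt",
    "//"), f)
  rec <- read_genbank_seq(f)
  expect_identical(rec$id, "SYN001")
  expect_identical(rec$residues, "ACGTACGTACGT")
  writeLines(c("LOCUS  X", "DEFINITION  no origin."), f)
  expect_error(read_genbank_seq(f), "ORIGIN")
})

test_that("translation matches an independent codon-table oracle", {
  # exhaustive over all 64 codons, as internal codon of M<codon>K + stop
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (cod in codons) {
    orf <- paste0("ATG", cod, "AAATAA")
    oracle <- paste(seqinr::translate(seqinr::s2c(orf)), collapse = "")
    if (grepl("\\*", substr(oracle, 1, nchar(oracle) - 1))) {
      expect_error(translate_orf(orf), "internal stop codon at codon 2")
    } else {
      expect_identical(translate_orf(orf),
                       sub("\\*$", "", oracle))
    }
  }
  # random ORFs
  withr::with_seed(5, {
    for (i in 1:10) {
      orf <- random_orf(sample(5:60, 1))
      oracle <- paste(seqinr::translate(seqinr::s2c(orf)), collapse = "")
      expect_identical(translate_orf(orf), sub("\\*$", "", oracle))
    }
  })
})

test_that("translation enforces frame, start and stop contracts", {
  expect_identical(translate_orf("ATGGCATAA"), "MA")
  expect_error(translate_orf("ATGGC"), "multiple of 3")
  expect_error(translate_orf("ATGTAAGCATAA"), "internal stop codon at codon 2")
  expect_error(translate_orf("GTGGCATAA"), "strict")
  expect_identical(translate_orf("GTGGCATAA", strict = FALSE), "MA")
  expect_error(translate_orf("CCCGCATAA", strict = FALSE), "start codon")
})

test_that("ORF finder agrees with a naive six-frame scan", {
  expect_identical(find_orfs(seq_record("x", "ATGAAATAA"), 3L)$protein, "MK")
  expect_identical(nrow(find_orfs(seq_record("x", "CCCCCCCCC"), 3L)), 0L)
  withr::with_seed(21, {
    for (i in 1:8) {
      s <- random_dna(300)
      got <- find_orfs(seq_record("r", s), min_len_nt = 30L)
      got_keys <- sort(paste(got$start, got$end, got$strand, sep = ":"))
      expect_identical(got_keys, orf_scan_oracle(s, 30L))
      # re-translating each reported slice reproduces the stored protein
      for (k in seq_len(nrow(got))) {
        sub <- substr(s, got$start[k], got$end[k])
        if (got$strand[k] == "-") sub <- amyprofiler:::revcomp(sub)
        expect_identical(translate_orf(sub), got$protein[k])
      }
    }
  })
})

test_that("ORFs are sorted by descending length", {
  s <- paste0("ATGAAATAA", "CC", "ATG", strrep("GCA", 10), "TAA")
  got <- find_orfs(seq_record("x", s), 3L)
  lens <- got$end - got$start + 1L
  expect_true(all(diff(lens) <= 0))
})

test_that("signal-peptide trimming conserves residues", {
  m <- trim_signal_peptide(strrep("A", 573), 23, "pre")
  expect_identical(nchar(m$mature), 550L)
  expect_error(trim_signal_peptide("ABCD", 0), "cleavage_after")
  expect_error(trim_signal_peptide("ABCD", 4), "cleavage_after")
  withr::with_seed(3, {
    for (i in 1:5) {
      p <- random_protein(sample(10:100, 1))
      k <- sample(nchar(p) - 1L, 1)
      m <- trim_signal_peptide(p, k)
      expect_identical(nchar(m$mature) + k, nchar(p))
      expect_identical(paste0(substr(p, 1, k), m$mature), p)
    }
  })
})
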
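make_bundle <- function(seed = 4) {
  g <- gen_gh13_sequence("gh13_36_atypical", seed = seed)
  signal <- "MKKTLLAGAILSLFALSACSNDA"  # 23-aa synthetic signal peptide
  precursor <- paste0(signal, g$record$residues)
  withr::with_seed(seed, {
    aln <- c(q = random_dna(150))
    ch <- strsplit(aln[["q"]], "")[[1]]
    for (i in 1:4) {
      x <- ch
      idx <- sample(length(x), 10 * i)
      x[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      aln[[paste0("r", i)]] <- paste(x, collapse = "")
    }
  })
  list(g = g, precursor = precursor, aln = aln,
       panel = default_csr_panel(seed = seed))
}

base_cfg <- function(b, fasta) {
  list(input = fasta, input_type = "protein_fasta", cleavage_after = 23,
       panel = b$panel, alignment = b$aln, distance_model = "p",
       bootstrap_reps = 30, seed = 11,
       kinetics = list(substrate = c(1.25, 2.5, 5, 10, 20),
                       velocity = mm_velocity(c(1.25, 2.5, 5, 10, 20),
                                              2.53, 0.125)),
       profiles = list(
         temperature = list(condition = seq(0, 60, 5),
                            raw = gen_activity_profile()$relative),
         nacl = list(condition = 0:5,
                     raw = c(40, 51, 48, 46, 42, 35.1),
                     mode = "control", control_index = 1)))
}

test_that("the full pipeline report mirrors the synthetic ground truth", {
  b <- make_bundle()
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seq_record("precursor", b$precursor, "protein"), fasta)
  rep <- suppressWarnings(run_pipeline(base_cfg(b, fasta)))
  expect_length(rep$errors, 0)
  expect_identical(rep$sequence$precursor_length_aa, 543L)
  expect_identical(rep$sequence$mature_length_aa, 520L)
  expect_identical(rep$classification$label, "gh13_36_like_atypical_csr5")
  expect_identical(rep$classification$csr5_pentapeptide, "QPDLN")
  # both residue numberings reported: precursor = mature + signal length
  expect_equal(rep$classification$triad$position_precursor,
               rep$classification$triad$position_chain + 23)
  expect_lt(abs(rep$kinetics$km_mg_per_ml - 2.53), 1e-9)
  expect_equal(rep$profiles$temperature$optimum, 25)
  expect_equal(rep$profiles$nacl$relative_pct[2], 127.5)
  expect_identical(rep$phylogeny$n_internal_edges, 2L)
})

test_that("a gene input is translated and trimmed before profiling", {
  b <- make_bundle(seed = 6)
  gene <- paste0(encode_orf(b$precursor))
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seq_record("syngene", gene, "nucleotide"), fasta)
  cfg <- list(input = fasta, input_type = "gene_fasta",
              cleavage_after = 23, panel = b$panel)
  rep <- run_pipeline(cfg)
  expect_identical(rep$sequence$gene_length_bp,
                   nchar(b$precursor) * 3L + 3L)
  expect_identical(rep$sequence$precursor_length_aa, nchar(b$precursor))
  expect_identical(rep$classification$label, "gh13_36_like_atypical_csr5")
  expect_equal(rep$physchem$mw_kda,
               molecular_weight(b$g$record$residues) / 1000)
})

test_that("reports are byte-identical across reruns and validate on disk", {
  b <- make_bundle()
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seq_record("precursor", b$precursor, "protein"), fasta)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- base_cfg(b, fasta)
  cfg$out_dir <- d1
  suppressWarnings(run_pipeline(cfg))
  cfg$out_dir <- d2
  suppressWarnings(run_pipeline(cfg))
  j1 <- readLines(file.path(d1, "report.json"))
  j2 <- readLines(file.path(d2, "report.json"))
  expect_identical(j1, j2)
  parsed <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_identical(parsed$classification$label, "gh13_36_like_atypical_csr5")
  expect_true(file.exists(file.path(d1, "tree.nwk")))
  expect_true(file.exists(file.path(d1, "tables", "csr_table.tsv")))
  expect_true(file.exists(file.path(d1, "report.txt")))
})

test_that("stage failures are named and downstream stages are skipped", {
  b <- make_bundle()
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seq_record("precursor", b$precursor, "protein"), fasta)
  cfg <- list(input = fasta, input_type = "protein_fasta",
              panel = b$panel,
              kinetics = list(substrate = c(1, 2, 4), velocity = c(0, 1, 2)))
  rep <- run_pipeline(cfg)
  # no cleavage annotation: full chain used, flagged as precursor
  expect_identical(rep$sequence$chain_used, "precursor")
  expect_identical(rep$physchem$chain, "precursor")
  # zero velocity: kinetics stage fails loudly, other stages unaffected
  expect_match(rep$errors$kinetics, "nonlinear")
  expect_null(rep$kinetics)
  expect_false(is.null(rep$classification))
})
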
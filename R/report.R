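# Whole-run orchestration: translate -> trim -> physchem -> classify ->
# tree -> kinetics, emitting one structured report. Every number in the
# JSON report carries its unit in the field name; stage errors are
# recorded with the stage name and dependent stages are skipped, never
# silently defaulted.

#' Run the full characterization pipeline
#'
#' @param cfg A list:
#' \describe{
#'   \item{input}{Path to the input sequence (FASTA or GenBank flat
#'     file).}
#'   \item{input_type}{`"gene_fasta"`, `"protein_fasta"` or `"genbank"`.}
#'   \item{cleavage_after}{Signal-peptide cleavage annotation (residue
#'     index); when absent, physicochemistry is computed on the full
#'     chain, flagged `"precursor"`.}
#'   \item{pka_set}{pKa table name for the pI (default `"bjellqvist"`).}
#'   \item{panel}{List of [csr_reference()] objects; or give
#'     `panel_fasta` + `panel_tsv` paths. Default:
#'     [default_csr_panel()].}
#'   \item{alignment}{Optional named character vector of equal-length
#'     aligned sequences for the phylogeny stage (or `aln_fasta`, a path).}
#'   \item{distance_model}{`"p"` or `"poisson"` (default).}
#'   \item{bootstrap_reps}{Bootstrap replicates (default 100).}
#'   \item{kinetics}{Optional data.frame/list with `substrate` and
#'     `velocity` (mg/mL, mg/mL/min), or `kinetics_csv`, a path with those
#'     columns.}
#'   \item{profiles}{Optional named list; each element a list with
#'     `condition`, `raw`, `mode` (`"max"`/`"control"`) and optionally
#'     `control_index`.}
#'   \item{min_orf_nt}{Minimum ORF length for gene input (default 300).}
#'   \item{seed}{RNG seed, recorded in the report (default 1).}
#'   \item{out_dir}{Optional output directory; when given, writes
#'     `report.json`, `report.txt`, `tree.nwk` and `tables/*.tsv`.}
#' }
#' @return The report, an object of class `amy_report` (a nested list);
#'   written to `out_dir` when requested.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is.list(cfg))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  report <- list(config = list(
    input = if (is.null(cfg$input)) "in-memory" else cfg$input,
    input_type = cfg$input_type,
    cleavage_after = cfg$cleavage_after,
    pka_set = if (is.null(cfg$pka_set)) "bjellqvist" else cfg$pka_set,
    distance_model = if (is.null(cfg$distance_model)) "poisson"
                     else cfg$distance_model,
    bootstrap_reps = if (is.null(cfg$bootstrap_reps)) 100L
                     else cfg$bootstrap_reps,
    seed = seed))
  errors <- list()
  fail <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  ## stage: sequence (read, ORF, translate, trim)
  seqstage <- tryCatch({
    type <- match.arg(cfg$input_type,
                      c("gene_fasta", "protein_fasta", "genbank"))
    if (type == "protein_fasta") {
      rec <- read_fasta(cfg$input, alphabet = "protein")[[1]]
      precursor <- rec$residues
      orf <- NULL
    } else {
      rec <- if (type == "genbank") read_genbank_seq(cfg$input)
             else read_fasta(cfg$input, alphabet = "nucleotide")[[1]]
      min_orf <- if (is.null(cfg$min_orf_nt)) 300L else cfg$min_orf_nt
      orfs <- find_orfs(rec, min_len_nt = min_orf)
      if (nrow(orfs) == 0L) stop("no ORF of >= ", min_orf, " nt found")
      orf <- orfs[1, ]
      precursor <- orf$protein
    }
    mature <- NULL
    if (!is.null(cfg$cleavage_after)) {
      mature <- trim_signal_peptide(precursor, cfg$cleavage_after,
                                    precursor_id = rec$id)
    }
    list(record = rec, orf = orf, precursor = precursor, mature = mature)
  }, error = function(e) fail("sequence", e))

  if (!is.null(seqstage)) {
    report$sequence <- list(
      id = seqstage$record$id,
      gene_length_bp = if (!is.null(seqstage$orf))
        seqstage$orf$end - seqstage$orf$start + 1L else NA,
      precursor_length_aa = nchar(seqstage$precursor),
      signal_peptide_aa = if (!is.null(seqstage$mature))
        seqstage$mature$cleavage_after else NA,
      mature_length_aa = if (!is.null(seqstage$mature))
        nchar(seqstage$mature$mature) else NA,
      chain_used = if (is.null(seqstage$mature)) "precursor" else "mature")
  }

  ## stage: physchem (on the mature chain when annotated, else precursor)
  phys <- NULL
  if (!is.null(seqstage)) {
    phys <- tryCatch({
      chain <- if (!is.null(seqstage$mature)) seqstage$mature$mature
               else seqstage$precursor
      prof <- composition(chain)
      list(profile = prof,
           mw_da = molecular_weight(chain),
           pi = isoelectric_point(chain, report$config$pka_set))
    }, error = function(e) fail("physchem", e))
  }
  if (!is.null(phys)) {
    p <- phys$profile
    report$physchem <- list(
      chain = report$sequence$chain_used,
      mw_kda = phys$mw_da / 1000, pi = phys$pi,
      arg_pct = p$arg_pct, lys_pct = p$lys_pct, arg_ratio = p$arg_ratio,
      acidic_pct = p$acidic_pct, basic_pct = p$basic_pct,
      acidic_excess_pct = p$acidic_excess_pct,
      n_x_excluded = p$n_excluded)
  }

  ## stage: classification (CSR mapping + rules)
  cls <- NULL
  if (!is.null(seqstage)) {
    cls <- tryCatch({
      panel <- cfg$panel
      if (is.null(panel) && !is.null(cfg$panel_fasta)) {
        panel <- read_csr_panel(cfg$panel_fasta, cfg$panel_tsv)
      }
      if (is.null(panel)) panel <- default_csr_panel()
      chain <- if (!is.null(seqstage$mature)) seqstage$mature$mature
               else seqstage$precursor
      ann <- map_csrs(chain, panel)
      feats <- extract_features(ann)
      call <- classify_subfamily(feats)
      votes <- panel_vote(chain, panel, k = min(5L, length(panel)))
      list(ann = ann, feats = feats, call = call, votes = votes)
    }, error = function(e) fail("classification", e))
  }
  if (!is.null(cls)) {
    shift <- if (!is.null(seqstage$mature)) seqstage$mature$cleavage_after
             else 0L
    tr <- cls$feats$triad
    report$classification <- list(
      reference_used = cls$ann$reference_used,
      alignment_score = cls$ann$score,
      csr_table = cls$ann$csr[, c("label", "query_start", "query_end",
                                  "peptide", "identity_pct", "present")],
      csr5_pentapeptide = cls$feats$csr5_pentapeptide,
      csr6_has_trp = cls$feats$csr6_has_trp,
      csr7_tyr_before_gee = cls$feats$csr7_tyr_before_gee,
      csr2_terminal_his = cls$feats$csr2_terminal_his,
      csr3_has_aromatic = cls$feats$csr3_has_aromatic,
      # residue numbering depends on whether the signal peptide is counted;
      # both numberings are reported side by side
      triad = data.frame(residue = tr$residue,
                         position_chain = tr$position,
                         position_precursor = tr$position + shift,
                         stringsAsFactors = FALSE),
      label = cls$call$label,
      evidence = cls$call$evidence,
      panel_votes = as.list(cls$votes))
  }

  ## stage: phylogeny
  tree <- NULL
  if (!is.null(cfg$alignment) || !is.null(cfg$aln_fasta)) {
    tree <- tryCatch({
      aln <- cfg$alignment
      if (is.null(aln)) {
        recs <- read_fasta(cfg$aln_fasta, alphabet = "protein")
        aln <- vapply(recs, `[[`, "", "residues")
      }
      bootstrap_support(aln, names(aln),
                        n_reps = report$config$bootstrap_reps,
                        seed = seed, model = report$config$distance_model)
    }, error = function(e) fail("phylogeny", e))
  }
  if (!is.null(tree)) {
    report$phylogeny <- list(
      n_taxa = length(tree$labels),
      n_internal_edges = n_internal_edges(tree),
      n_negative_branches_clamped = tree$n_clamped,
      bootstrap_reps = tree$n_reps,
      newick = write_newick(tree))
  }

  ## stage: kinetics
  kin <- NULL
  if (!is.null(cfg$kinetics) || !is.null(cfg$kinetics_csv)) {
    kin <- tryCatch({
      k <- cfg$kinetics
      if (is.null(k)) k <- utils::read.csv(cfg$kinetics_csv)
      lineweaver_burk_fit(kinetic_dataset(k$substrate, k$velocity))
    }, error = function(e) fail("kinetics", e))
  }
  if (!is.null(kin)) {
    report$kinetics <- list(km_mg_per_ml = kin$km,
                            vmax_mg_per_ml_min = kin$vmax,
                            lb_slope = kin$slope, lb_intercept = kin$intercept,
                            r2 = kin$r2, n_points = kin$n)
  }

  ## stage: activity profiles
  if (!is.null(cfg$profiles)) {
    report$profiles <- lapply(cfg$profiles, function(sp) {
      tryCatch({
        prof <- relative_activity(sp$condition, sp$raw,
                                  mode = if (is.null(sp$mode)) "max"
                                         else sp$mode,
                                  control_index = sp$control_index)
        opt <- find_optimum(prof)
        list(condition = prof$condition, relative_pct = prof$relative,
             optimum = opt$optimum, boundary_optimum = opt$boundary,
             tie = opt$tie)
      }, error = function(e) list(error = conditionMessage(e)))
    })
  }

  report$errors <- errors
  class(report) <- "amy_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (numbers at full double precision), a
#' human-readable `report.txt`, `tree.nwk` when a phylogeny was built, and
#' `tables/*.tsv` for the CSR table and evidence trail. Output is
#' deterministic for a fixed config and seed (no timestamps).
#'
#' @param report An `amy_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  if (!is.null(report$phylogeny)) {
    writeLines(report$phylogeny$newick, file.path(out_dir, "tree.nwk"))
  }
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  if (!is.null(report$classification)) {
    utils::write.table(report$classification$csr_table,
                       file.path(out_dir, "tables", "csr_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$classification$evidence,
                       file.path(out_dir, "tables", "evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.amy_report <- function(x, ...) {
  cat("== GH13 characterization report ==\n")
  if (!is.null(x$sequence)) {
    s <- x$sequence
    cat(sprintf("sequence: %s | ORF %s bp -> precursor %d aa",
                s$id, format(s$gene_length_bp), s$precursor_length_aa))
    if (!is.na(s$mature_length_aa)) {
      cat(sprintf(" | signal peptide %d aa -> mature %d aa",
                  s$signal_peptide_aa, s$mature_length_aa))
    }
    cat("\n")
  }
  if (!is.null(x$physchem)) {
    p <- x$physchem
    cat(sprintf(paste0(
      "physchem (%s): MW %.1f kDa | pI %.1f | Arg %.1f%% | ",
      "Arg/(Arg+Lys) %.2f | acidic %.1f%% | basic %.1f%% | excess %.1f%%\n"),
      p$chain, p$mw_kda, p$pi, p$arg_pct, p$arg_ratio, p$acidic_pct,
      p$basic_pct, p$acidic_excess_pct))
  }
  if (!is.null(x$classification)) {
    c0 <- x$classification
    cat(sprintf("classification: %s (CSR V %s; ref %s, score %.1f)\n",
                c0$label, c0$csr5_pentapeptide, c0$reference_used,
                c0$alignment_score))
    cat(sprintf("  triad: %s\n",
                paste(sprintf("%s%d (precursor %d)", c0$triad$residue,
                              c0$triad$position_chain,
                              c0$triad$position_precursor),
                      collapse = ", ")))
  }
  if (!is.null(x$phylogeny)) {
    cat(sprintf("phylogeny: %d taxa, %d internal edges, %d bootstrap reps\n",
                x$phylogeny$n_taxa, x$phylogeny$n_internal_edges,
                x$phylogeny$bootstrap_reps))
    cat(" ", x$phylogeny$newick, "\n")
  }
  if (!is.null(x$kinetics)) {
    cat(sprintf("kinetics: Km %.4g mg/mL, Vmax %.4g mg/mL/min (R2 %.4f)\n",
                x$kinetics$km_mg_per_ml, x$kinetics$vmax_mg_per_ml_min,
                x$kinetics$r2))
  }
  if (!is.null(x$profiles)) {
    for (nm in names(x$profiles)) {
      pr <- x$profiles[[nm]]
      if (!is.null(pr$error)) {
        cat(sprintf("profile %s: ERROR %s\n", nm, pr$error))
      } else {
        cat(sprintf("profile %s: optimum at %s%s\n", nm, format(pr$optimum),
                    if (isTRUE(pr$boundary_optimum)) " (boundary)" else ""))
      }
    }
  }
  if (length(x$errors)) {
    for (nm in names(x$errors)) {
      cat(sprintf("stage %s FAILED: %s\n", nm, x$errors[[nm]]))
    }
  }
  invisible(x)
}
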
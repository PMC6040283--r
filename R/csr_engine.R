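# GH13 conserved-sequence-region (CSR) diagnostics.
#
# GH13 enzymes carry 4-7 short conserved blocks (CSR I-VII). The CSR V
# pentapeptide separates three closely related subfamilies —
# QPDLN: oligo-1,6-glucosidase, MPKLN: neopullulanase, MPDLN: GH13_36 —
# and GH13_36 members additionally show an invariant Trp in CSR VI, a Tyr
# preceding the "GEE" tripeptide that ends CSR VII, and (in many members)
# a terminal His in CSR II and an aromatic residue in CSR III. The engine
# transfers reference CSR coordinates onto a query through a pairwise
# global alignment and applies that rule set.

CSR_LABELS <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Annotated CSR reference
#'
#' A protein reference carrying the seven CSR windows, the per-window
#' diagnostic offsets, the catalytic-triad positions and a subfamily tag.
#'
#' @param record A protein [seq_record()].
#' @param windows data.frame with columns `label` (I..VII), `start`, `end`
#'   (1-based inclusive), `diag_offset` (1-based offset of the diagnostic
#'   position within the window; `NA` where the diagnostic is positional by
#'   convention: CSR II uses its last residue, CSR VII is searched for
#'   "GEE").
#' @param subfamily_tag Subfamily annotation (e.g. `"gh13_36"`).
#' @param triad Integer vector of three 1-based positions (catalytic Asp,
#'   Glu, Asp) on the reference; each must fall inside a window and carry
#'   the expected residue.
#' @return An object of class `csr_reference`.
#' @export
csr_reference <- function(record, windows, subfamily_tag, triad) {
  stopifnot(inherits(record, "seq_record"), record$alphabet == "protein")
  need <- c("label", "start", "end", "diag_offset")
  if (!all(need %in% names(windows))) {
    stop("windows must have columns ", paste(need, collapse = ", "))
  }
  windows <- windows[match(CSR_LABELS, windows$label), , drop = FALSE]
  if (anyNA(windows$label)) stop("windows must cover CSR I..VII exactly")
  if (any(windows$start > windows$end) || any(windows$start < 1) ||
      any(windows$end > nchar(record$residues))) {
    stop("CSR windows out of range on '", record$id, "'")
  }
  if (any(diff(windows$start) <= 0) ||
      any(windows$start[-1] <= windows$end[-7])) {
    stop("CSR windows must be ordered I..VII and non-overlapping")
  }
  stopifnot(length(triad) == 3L)
  inside <- vapply(triad, function(p) {
    any(p >= windows$start & p <= windows$end)
  }, logical(1))
  if (!all(inside)) stop("triad positions must fall inside CSR windows")
  obs <- substring(record$residues, triad, triad)
  if (!identical(obs, c("D", "E", "D"))) {
    stop("triad residues on '", record$id, "' are ",
         paste(obs, collapse = ""), ", expected DED")
  }
  structure(list(record = record, windows = windows,
                 subfamily_tag = subfamily_tag, triad = as.integer(triad)),
            class = "csr_reference")
}

#' Pairwise global protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`), computed through
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Protein strings.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative penalties (defaults 10, 0.5).
#' @return A list with `a_aln`, `b_aln` (equal-length gapped strings) and
#'   `score`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b), gap_open >= 0, gap_extend >= 0)
  mat <- get_submatrix(matrix)
  for (s in c(a, b)) {
    chars <- unique(strsplit(s, "")[[1]])
    miss <- setdiff(chars, rownames(mat))
    if (length(miss)) {
      stop("residue(s) absent from ", matrix, ": ",
           paste(miss, collapse = ", "))
    }
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  list(a_aln = as.character(Biostrings::alignedPattern(al)),
       b_aln = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

submatrix_cache <- new.env(parent = emptyenv())
get_submatrix <- function(name) {
  if (is.matrix(name)) return(name)
  if (!exists(name, envir = submatrix_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = submatrix_cache)
  }
  get(name, envir = submatrix_cache)
}

# Map 1-based positions of the ungapped 'from' sequence to positions on
# the ungapped 'to' sequence through a pair of aligned (gapped) strings;
# NA where the 'from' position is aligned to a gap.
project_positions <- function(from_aln, to_aln) {
  fa <- strsplit(from_aln, "")[[1]]
  ta <- strsplit(to_aln, "")[[1]]
  from_pos <- cumsum(fa != "-")
  to_pos <- cumsum(ta != "-")
  keep <- fa != "-"
  map <- ifelse(ta[keep] != "-", to_pos[keep], NA_integer_)
  as.integer(map)
}

#' Transfer CSR windows onto a query
#'
#' Aligns the query against every panel member, keeps the best-scoring one
#' (ties broken by panel order), and projects its CSR windows, diagnostic
#' offsets and triad positions onto the query through the alignment
#' columns. Windows whose every reference position is deleted in the query
#' are flagged absent.
#'
#' @param query Protein string (or protein [seq_record()]).
#' @param panel List of [csr_reference()] objects.
#' @param score_floor Minimum acceptable alignment score; all panel scores
#'   below it abort with a "no confident CSR mapping" error.
#' @param ... Passed to [global_align()].
#' @return An object of class `csr_annotation`: `query_id`, `csr` (a
#'   data.frame with `label`, `ref_start`, `ref_end`, `query_start`,
#'   `query_end`, `peptide`, `identity_pct`, `present`, `diag_query_pos`),
#'   `triad_query` (three positions, `NA` where deleted),
#'   `reference_used`, `subfamily_tag_of_reference`, `score`.
#' @export
map_csrs <- function(query, panel, score_floor = 0, ...) {
  if (inherits(query, "seq_record")) {
    qid <- query$id; qseq <- query$residues
  } else {
    qid <- "query"; qseq <- query
  }
  stopifnot(length(panel) >= 1L, nzchar(qseq))
  alns <- lapply(panel, function(ref) {
    global_align(ref$record$residues, qseq, ...)
  })
  scores <- vapply(alns, `[[`, 0, "score")
  if (max(scores) < score_floor) {
    stop("no confident CSR mapping: best panel score ", max(scores),
         " is below the floor ", score_floor)
  }
  best <- which.max(scores)  # first maximum: panel order breaks ties
  ref <- panel[[best]]
  al <- alns[[best]]
  map <- project_positions(al$a_aln, al$b_aln)
  ra <- strsplit(al$a_aln, "")[[1]]
  qa <- strsplit(al$b_aln, "")[[1]]
  w <- ref$windows
  rows <- lapply(seq_len(nrow(w)), function(i) {
    span <- w$start[i]:w$end[i]
    qpos <- map[span]
    present <- any(!is.na(qpos))
    qs <- if (present) min(qpos, na.rm = TRUE) else NA_integer_
    qe <- if (present) max(qpos, na.rm = TRUE) else NA_integer_
    # identity over the reference window columns
    cols <- which(cumsum(ra != "-") %in% span & ra != "-")
    ident <- 100 * sum(ra[cols] == qa[cols]) / length(span)
    dq <- NA_integer_
    if (!is.na(w$diag_offset[i])) {
      dq <- map[w$start[i] + w$diag_offset[i] - 1L]
    }
    data.frame(label = w$label[i], ref_start = w$start[i],
               ref_end = w$end[i], query_start = qs, query_end = qe,
               peptide = if (present) substr(qseq, qs, qe) else NA_character_,
               identity_pct = ident, present = present,
               diag_query_pos = dq, stringsAsFactors = FALSE)
  })
  csr <- do.call(rbind, rows)
  structure(
    list(query_id = qid, query = qseq, csr = csr,
         triad_query = map[ref$triad],
         reference_used = ref$record$id,
         subfamily_tag_of_reference = ref$subfamily_tag,
         score = scores[best]),
    class = "csr_annotation")
}

aromatic <- c("F", "W", "Y")

#' Extract the subfamily-diagnostic features
#'
#' Reads the diagnostic residues off a CSR annotation: the CSR V
#' pentapeptide, the CSR VI invariant Trp, the Tyr immediately preceding
#' "GEE" in CSR VII (searched, since "GEE" terminates the region), the CSR
#' II terminal His, the CSR III aromatic position, and the catalytic-triad
#' residues at the projected positions. Absent windows propagate as `NA`
#' feature values.
#'
#' @param ann A `csr_annotation` from [map_csrs()].
#' @return An object of class `diagnostic_features` with fields
#'   `csr5_pentapeptide`, `csr6_has_trp`, `csr7_tyr_before_gee`,
#'   `csr2_terminal_his`, `csr3_has_aromatic`, `triad` (data.frame
#'   `residue`, `position`), `triad_is_ded`.
#' @export
extract_features <- function(ann) {
  stopifnot(inherits(ann, "csr_annotation"))
  q <- ann$query
  row <- function(lab) ann$csr[ann$csr$label == lab, ]
  v <- row("V")
  csr5 <- NA_character_
  if (v$present && !is.na(v$diag_query_pos) &&
      v$diag_query_pos + 4L <= nchar(q)) {
    csr5 <- substr(q, v$diag_query_pos, v$diag_query_pos + 4L)
  }
  vi <- row("VI")
  csr6 <- if (vi$present && !is.na(vi$diag_query_pos)) {
    substr(q, vi$diag_query_pos, vi$diag_query_pos) == "W"
  } else NA
  vii <- row("VII")
  csr7 <- NA
  if (vii$present && !is.na(vii$peptide)) {
    gee <- regexpr("GEE", vii$peptide, fixed = TRUE)
    csr7 <- if (gee > 1L) {
      substr(vii$peptide, gee - 1L, gee - 1L) == "Y"
    } else FALSE
  }
  ii <- row("II")
  csr2 <- if (ii$present && !is.na(ii$peptide)) {
    substr(ii$peptide, nchar(ii$peptide), nchar(ii$peptide)) == "H"
  } else NA
  iii <- row("III")
  csr3 <- if (iii$present && !is.na(iii$diag_query_pos)) {
    substr(q, iii$diag_query_pos, iii$diag_query_pos) %in% aromatic
  } else NA
  tpos <- ann$triad_query
  tres <- ifelse(is.na(tpos), NA_character_, substring(q, tpos, tpos))
  structure(
    list(csr5_pentapeptide = csr5, csr6_has_trp = csr6,
         csr7_tyr_before_gee = csr7, csr2_terminal_his = csr2,
         csr3_has_aromatic = csr3,
         triad = data.frame(residue = tres, position = tpos,
                            stringsAsFactors = FALSE),
         triad_is_ded = identical(unname(tres), c("D", "E", "D"))),
    class = "diagnostic_features")
}

#' Build a diagnostic feature vector directly
#'
#' Convenience constructor for rule-engine use without an alignment (e.g.
#' when features are read off a published alignment figure).
#'
#' @param csr5_pentapeptide 5-mer CSR V motif.
#' @param csr6_has_trp,csr7_tyr_before_gee,csr2_terminal_his,csr3_has_aromatic
#'   Logical diagnostics.
#' @return A `diagnostic_features` object (triad slots empty).
#' @export
diagnostic_features <- function(csr5_pentapeptide, csr6_has_trp,
                                csr7_tyr_before_gee, csr2_terminal_his,
                                csr3_has_aromatic) {
  stopifnot(is.na(csr5_pentapeptide) || nchar(csr5_pentapeptide) == 5L)
  structure(
    list(csr5_pentapeptide = csr5_pentapeptide, csr6_has_trp = csr6_has_trp,
         csr7_tyr_before_gee = csr7_tyr_before_gee,
         csr2_terminal_his = csr2_terminal_his,
         csr3_has_aromatic = csr3_has_aromatic,
         triad = data.frame(residue = character(), position = integer()),
         triad_is_ded = NA),
    class = "diagnostic_features")
}

CSR5_RULES <- c(QPDLN = "oligo16glucosidase_like",
                MPKLN = "neopullulanase_like",
                MPDLN = "gh13_36_like")

#' Subfamily rule engine
#'
#' Deterministic cascade over the diagnostic features:
#' 1. primary vote from the CSR V pentapeptide (QPDLN ->
#'    oligo-1,6-glucosidase, MPKLN -> neopullulanase, MPDLN -> GH13_36;
#'    anything else -> no primary vote);
#' 2. GH13_36 support score = number of true values among CSR VI Trp and
#'    CSR VII Tyr-GEE (core supports) and CSR II terminal His and CSR III
#'    aromatic (auxiliary);
#' 3. when the primary vote is not GH13_36 but BOTH core supports hold,
#'    the call is `gh13_36_like_atypical_csr5` — a GH13_36-like enzyme
#'    carrying a non-canonical CSR V, the configuration diagnostic of
#'    QPDLN-bearing GH13_36 members;
#' 4. otherwise the call follows the primary vote; an unknown pentapeptide
#'    with insufficient support is `unassigned`.
#'
#' @param f A `diagnostic_features` object.
#' @return An object of class `subfamily_call`: `label`, `evidence` (a
#'   data.frame of `feature`, `observed`, `rule_matched` rows in rule
#'   order), `core_support`, `aux_support`.
#' @export
classify_subfamily <- function(f) {
  stopifnot(inherits(f, "diagnostic_features"))
  pent <- f$csr5_pentapeptide
  primary <- if (!is.na(pent) && pent %in% names(CSR5_RULES)) {
    unname(CSR5_RULES[pent])
  } else NA_character_
  sup <- c(csr6_has_trp = isTRUE(f$csr6_has_trp),
           csr7_tyr_before_gee = isTRUE(f$csr7_tyr_before_gee),
           csr2_terminal_his = isTRUE(f$csr2_terminal_his),
           csr3_has_aromatic = isTRUE(f$csr3_has_aromatic))
  core <- sum(sup[c("csr6_has_trp", "csr7_tyr_before_gee")])
  aux <- sum(sup[c("csr2_terminal_his", "csr3_has_aromatic")])
  label <- if (is.na(primary)) {
    "unassigned"
  } else if (primary != "gh13_36_like" && core == 2L) {
    "gh13_36_like_atypical_csr5"
  } else {
    primary
  }
  evidence <- data.frame(
    feature = c("csr5_pentapeptide", names(sup)),
    observed = c(if (is.na(pent)) "unknown" else pent,
                 as.character(unname(sup))),
    rule_matched = c(
      if (is.na(primary)) "no primary vote" else paste("primary vote:", primary),
      sprintf("%s support (%s)",
              c("core", "core", "auxiliary", "auxiliary"),
              c("CSR VI invariant Trp", "CSR VII Tyr before GEE",
                "CSR II terminal His", "CSR III aromatic"))),
    stringsAsFactors = FALSE)
  structure(list(label = label, evidence = evidence,
                 core_support = core, aux_support = aux,
                 reason = if (is.na(pent)) "CSR V pentapeptide unknown"
                          else NA_character_),
            class = "subfamily_call")
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat("<subfamily_call>", x$label,
      sprintf("(core %d/2, auxiliary %d/2)\n", x$core_support,
              x$aux_support))
  print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Nearest-neighbour subfamily vote
#'
#' Subfamily tags of the k panel members with the highest global alignment
#' score against the query — a similarity-based corroboration of the rule
#' engine.
#'
#' @param query Protein string or [seq_record()].
#' @param panel List of [csr_reference()] objects.
#' @param k Number of neighbours (<= panel size).
#' @param ... Passed to [global_align()].
#' @return Named integer vector: votes per subfamily tag, decreasing.
#' @export
panel_vote <- function(query, panel, k = min(5L, length(panel)), ...) {
  stopifnot(k >= 1L, k <= length(panel))
  qseq <- if (inherits(query, "seq_record")) query$residues else query
  scores <- vapply(panel, function(ref) {
    global_align(ref$record$residues, qseq, ...)$score
  }, 0)
  ord <- order(-scores)  # stable: panel order breaks ties
  tags <- vapply(panel[ord[seq_len(k)]], `[[`, "", "subfamily_tag")
  sort(table(tags), decreasing = TRUE) -> tab
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}

#' Read a CSR reference panel from FASTA + TSV
#'
#' The TSV has one row per (sequence, CSR) with columns `seq_id`,
#' `csr_label`, `start`, `end`, `diag_offset`, `subfamily_tag`, `triad1`,
#' `triad2`, `triad3` (triad columns repeated on every row of a sequence).
#'
#' @param fasta_path Protein FASTA of the panel sequences.
#' @param tsv_path Tab-separated CSR coordinate table.
#' @return List of [csr_reference()] objects in FASTA order.
#' @export
read_csr_panel <- function(fasta_path, tsv_path) {
  recs <- read_fasta(fasta_path, alphabet = "protein")
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("seq_id", "csr_label", "start", "end", "diag_offset",
            "subfamily_tag", "triad1", "triad2", "triad3")
  if (!all(need %in% names(tab))) {
    stop("panel TSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(recs, function(r) {
    rows <- tab[tab$seq_id == r$id, , drop = FALSE]
    if (nrow(rows) != 7L) {
      stop("panel TSV must annotate exactly 7 CSRs for '", r$id, "'")
    }
    csr_reference(
      r,
      data.frame(label = rows$csr_label, start = rows$start, end = rows$end,
                 diag_offset = rows$diag_offset, stringsAsFactors = FALSE),
      subfamily_tag = rows$subfamily_tag[1],
      triad = c(rows$triad1[1], rows$triad2[1], rows$triad3[1]))
  })
}

#' Write a CSR reference panel to FASTA + TSV
#'
#' Inverse of [read_csr_panel()]; also serves as a template for building
#' panels from curated (e.g. UniProt-derived) sequences.
#'
#' @param panel List of [csr_reference()] objects.
#' @param fasta_path,tsv_path Output paths.
#' @return Invisibly, `c(fasta_path, tsv_path)`.
#' @export
write_csr_panel <- function(panel, fasta_path, tsv_path) {
  write_fasta(lapply(panel, `[[`, "record"), fasta_path)
  rows <- lapply(panel, function(ref) {
    data.frame(seq_id = ref$record$id, csr_label = ref$windows$label,
               start = ref$windows$start, end = ref$windows$end,
               diag_offset = ref$windows$diag_offset,
               subfamily_tag = ref$subfamily_tag,
               triad1 = ref$triad[1], triad2 = ref$triad[2],
               triad3 = ref$triad[3], stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, tsv_path))
}
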